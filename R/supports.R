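#' VAF supports for singlets and doublets
#'
#' A droplet with one diploid cell can only present variant allele fractions
#' (VAFs) in \{0, 1/2, 1\} before allelic dropout (ADO); a droplet with two
#' cells (four allele copies) can present \{0, 1/4, 1/2, 3/4, 1\}. After ADO
#' removes individual copies, the observable VAF of a doublet extends to
#' fractions with denominators 1..4, giving \{0, 1/4, 1/3, 1/2, 2/3, 3/4, 1\};
#' a singlet stays on \{0, 1/2, 1\}.
#'
#' @param kind `"singlet"` or `"doublet"`.
#' @return A list with elements `kind`, `pre_ado` (latent VAF support before
#'   dropout) and `post_ado` (support after dropout), both numeric vectors of
#'   exact dyadic/ternary fractions.
#' @examples
#' vaf_support("doublet")$post_ado
#' @export
vaf_support <- function(kind = c("singlet", "doublet")) {
  kind <- match.arg(kind)
  if (kind == "singlet") {
    list(kind = kind, pre_ado = SIGMA_SINGLET, post_ado = THETA_SINGLET)
  } else {
    list(kind = kind, pre_ado = SIGMA_DOUBLET, post_ado = THETA_DOUBLET)
  }
}

SIGMA_SINGLET <- c(0, 1 / 2, 1)
SIGMA_DOUBLET <- c(0, 1 / 4, 1 / 2, 3 / 4, 1)
THETA_SINGLET <- c(0, 1 / 2, 1)
THETA_DOUBLET <- c(0, 1 / 4, 1 / 3, 1 / 2, 2 / 3, 3 / 4, 1)

#' Genotype prior probabilities per locus
#'
#' Container for the per-locus probabilities that a single cell is wild-type,
#' heterozygous or homozygous at each mutation locus. A single global triple
#' may be broadcast to all loci.
#'
#' @param wt,het,hom Numeric vectors (length `m` or 1) of genotype
#'   probabilities; each triple must be non-negative and sum to 1.
#' @param locus_ids Character vector of locus identifiers (length `m`).
#' @return An object of class `locus_priors`: a numeric matrix with `m` rows,
#'   columns `wt`, `het`, `hom`, and `locus_ids` as row names.
#' @examples
#' locus_priors(0.8, 0.15, 0.05, locus_ids = paste0("L", 1:3))
#' @export
locus_priors <- function(wt, het, hom, locus_ids) {
  m <- length(locus_ids)
  if (anyDuplicated(locus_ids)) stop("locus ids must be unique")
  mu <- cbind(wt = rep_len(wt, m), het = rep_len(het, m),
              hom = rep_len(hom, m))
  if (any(mu < 0)) stop("genotype probabilities must be non-negative")
  if (any(abs(rowSums(mu) - 1) > 1e-9)) {
    stop("genotype probabilities must sum to 1 at every locus")
  }
  rownames(mu) <- as.character(locus_ids)
  structure(mu, class = c("locus_priors", "matrix", "array"))
}

#' Global nuisance parameters of the read-count model
#'
#' Bundles the allelic-dropout rate, amplification copy-error rates,
#' beta-binomial precision and the doublet prior into one validated object.
#' The copy-error rates are floored at 1e-6 so that wild-type or homozygous
#' states never assign probability exactly 0 to a stray read.
#'
#' @param beta Per-copy allelic dropout (ADO) rate, in `[0, 1)`.
#' @param alpha_fp Probability of copying a reference template into a variant
#'   read (false positive copy error), in `[0, 1)`.
#' @param alpha_fn Probability of copying a variant template into a reference
#'   read (false negative copy error), in `[0, 1)`.
#' @param s Beta-binomial precision (concentration) of the allelic-imbalance
#'   model; low values mean strong amplification unevenness. Must be > 0.
#' @param delta Prior probability that a droplet is a doublet, in `(0, 1)`.
#' @return An object of class `error_model` (a named list).
#' @examples
#' error_model(beta = 0.05, alpha_fp = 0.015, alpha_fn = 0.0073,
#'             s = 15, delta = 0.2)
#' @export
error_model <- function(beta, alpha_fp, alpha_fn, s, delta) {
  stopifnot(beta >= 0, beta < 1, alpha_fp >= 0, alpha_fp < 1,
            alpha_fn >= 0, alpha_fn < 1, s > 0, delta > 0, delta < 1)
  alpha_fp <- max(alpha_fp, 1e-6)
  alpha_fn <- max(alpha_fn, 1e-6)
  if (alpha_fp + alpha_fn >= 1) stop("alpha_fp + alpha_fn must be < 1")
  structure(list(beta = beta, alpha_fp = alpha_fp, alpha_fn = alpha_fn,
                 s = s, delta = delta),
            class = "error_model")
}

#' @export
print.error_model <- function(x, ...) {
  cat(sprintf(
    "error_model: beta=%g alpha_fp=%g alpha_fn=%g s=%g delta=%g\n",
    x$beta, x$alpha_fp, x$alpha_fn, x$s, x$delta))
  invisible(x)
}
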