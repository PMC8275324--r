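#' Doublet prior from the Poisson cell-capture rate
#'
#' Cell capture loads droplets with a Poisson number of cells (mean
#' `lambda` = loading rate x droplet formation time). Only non-empty droplets
#' are sequenced, and multiplets beyond two cells are negligible at practical
#' loading rates, so the prior probability that a sequenced droplet is a
#' doublet is the two-cell Poisson mass renormalized over one- and two-cell
#' captures.
#'
#' @param lambda Positive Poisson mean of cells per droplet.
#' @return delta = P(doublet) in (0, 1).
#' @examples
#' doublet_prior_from_rate(0.1) # 1/21
#' @export
doublet_prior_from_rate <- function(lambda) {
  if (!is.numeric(lambda) || length(lambda) != 1L || !is.finite(lambda) ||
      lambda <= 0) {
    stop("lambda must be a positive finite scalar")
  }
  p1 <- stats::dpois(1, lambda)
  p2 <- stats::dpois(2, lambda)
  p2 / (p1 + p2)
}

#' Genotype (pre-dropout) VAF distribution of a singlet
#'
#' @param priors A [locus_priors] object.
#' @param locus A locus identifier present in `priors`.
#' @return Named numeric vector of probabilities over the singlet VAF support
#'   \{0, 1/2, 1\} (wild-type, heterozygous, homozygous).
#' @export
singlet_vaf_prior <- function(priors, locus) {
  mu <- prior_row(priors, locus)
  stats::setNames(as.numeric(mu), format_vaf(SIGMA_SINGLET))
}

#' Genotype (pre-dropout) VAF distribution of a doublet
#'
#' A doublet holds two cells with independent genotypes; its latent VAF is
#' the four-copy average of the two cells' VAFs. Each doublet VAF `f`
#' aggregates every ordered pair (g, h) of singlet VAFs with (g + h) / 2 = f,
#' e.g. f = 1/2 arises from (1/2, 1/2), (1, 0) and (0, 1).
#'
#' @inheritParams singlet_vaf_prior
#' @return Named numeric vector of probabilities over
#'   \{0, 1/4, 1/2, 3/4, 1\}.
#' @export
doublet_vaf_prior <- function(priors, locus) {
  p1 <- as.numeric(prior_row(priors, locus))
  out <- stats::setNames(numeric(length(SIGMA_DOUBLET)),
                         format_vaf(SIGMA_DOUBLET))
  for (g in seq_along(SIGMA_SINGLET)) {
    for (h in seq_along(SIGMA_SINGLET)) {
      f <- (SIGMA_SINGLET[g] + SIGMA_SINGLET[h]) / 2
      k <- which(abs(SIGMA_DOUBLET - f) < 1e-12)
      out[k] <- out[k] + p1[g] * p1[h]
    }
  }
  out / sum(out)
}

#' Allelic-dropout transition distribution
#'
#' Given the latent VAF `x` of a droplet (carrying `2z + 2` allele copies:
#' `x * (2z + 2)` variant, the rest reference), each copy independently fails
#' to amplify with probability `beta`. The post-dropout VAF is the fraction
#' of variant copies among retained copies, conditioned on at least one copy
#' being retained (observed reads imply some amplification happened), i.e.
#' renormalized by `1 - beta^(2z + 2)`.
#'
#' @param x Pre-dropout VAF; must lie in the singlet support \{0, 1/2, 1\}
#'   when `z = 0` or the doublet support \{0, 1/4, 1/2, 3/4, 1\} when `z = 1`.
#' @param z 0 for a singlet, 1 for a doublet.
#' @param beta Per-copy dropout rate in `[0, 1)`.
#' @return Named numeric vector of probabilities over the full post-dropout
#'   support (\{0, 1/2, 1\} or \{0, 1/4, 1/3, 1/2, 2/3, 3/4, 1\}); entries
#'   unreachable from `x` are 0.
#' @examples
#' ado_transition(1 / 2, z = 0, beta = 0.25)
#' @export
ado_transition <- function(x, z, beta) {
  stopifnot(z %in% c(0, 1), beta >= 0, beta < 1)
  sigma <- if (z == 1) SIGMA_DOUBLET else SIGMA_SINGLET
  theta <- if (z == 1) THETA_DOUBLET else THETA_SINGLET
  if (!any(abs(sigma - x) < 1e-12)) {
    stop(sprintf("x = %g is not a legal pre-dropout VAF for z = %d", x, z))
  }
  n_copies <- 2L * as.integer(z) + 2L
  n_var <- as.integer(round(x * n_copies))
  n_ref <- n_copies - n_var
  out <- stats::setNames(numeric(length(theta)), format_vaf(theta))
  for (a in 0:n_var) {
    for (b in 0:n_ref) {
      if (a + b == 0L) next
      pr <- stats::dbinom(a, n_var, 1 - beta) *
        stats::dbinom(b, n_ref, 1 - beta)
      k <- which(abs(theta - a / (a + b)) < 1e-12)
      out[k] <- out[k] + pr
    }
  }
  out / (1 - beta^n_copies)
}

#' Per-copy variant probability after amplification copy errors
#'
#' Copy errors during early PCR convert a reference template into a variant
#' read with probability `alpha_fp` and a variant template into a reference
#' read with probability `alpha_fn`, so a molecule drawn from a template pool
#' with variant fraction `y` is a variant copy with probability
#' `alpha_fp + (1 - alpha_fp - alpha_fn) * y`.
#'
#' @param y Post-dropout VAF(s) in `[0, 1]`.
#' @param alpha_fp,alpha_fn Copy-error rates.
#' @return Numeric vector of variant-copy probabilities.
#' @export
amplification_prob <- function(y, alpha_fp, alpha_fn) {
  stopifnot(all(y >= 0), all(y <= 1))
  alpha_fp + (1 - alpha_fp - alpha_fn) * y
}

#' Beta-binomial log-likelihood in mean/precision form
#'
#' Allelic imbalance during amplification makes the variant fraction of the
#' read pool itself random: `pi ~ Beta(p * s, (1 - p) * s)` with mean `p` and
#' precision `s`, and `v | c, pi ~ Binomial(c, pi)`. Computed through
#' log-gamma functions, so counts up to at least 1e5 do not overflow.
#'
#' @param v Variant read counts (vectorized).
#' @param c Total read counts (vectorized, `v <= c`).
#' @param p Mean variant probability, strictly inside (0, 1).
#' @param s Precision, > 0.
#' @return Log of the beta-binomial pmf, vectorized over the inputs.
#' @export
beta_binomial_loglik <- function(v, c, p, s) {
  if (any(p <= 0) || any(p >= 1)) stop("p must be strictly inside (0, 1)")
  if (any(s <= 0)) stop("s must be positive")
  if (any(v < 0) || any(v > c)) stop("need 0 <= v <= c")
  a <- p * s
  b <- (1 - p) * s
  lchoose(c, v) + lbeta(v + a, c - v + b) - lbeta(a, b)
}

# Mixture weights over the post-dropout support for all loci at once:
# W[j, k] = sum_x P(theta_k | x, z) * P(x | z, locus j). Rows sum to 1.
post_ado_weights <- function(priors, z, beta) {
  sigma <- if (z == 1) SIGMA_DOUBLET else SIGMA_SINGLET
  theta <- if (z == 1) THETA_DOUBLET else THETA_SINGLET
  trans <- vapply(sigma, ado_transition, numeric(length(theta)),
                  z = z, beta = beta)      # |theta| x |sigma|
  pri <- if (z == 1) {
    t(vapply(rownames(priors), function(l) doublet_vaf_prior(priors, l),
             numeric(length(sigma))))
  } else {
    unclass(priors)[, c("wt", "het", "hom"), drop = FALSE]
  }
  W <- pri %*% t(trans)                    # m x |theta|
  colnames(W) <- format_vaf(theta)
  W
}

# Conditional log-likelihood matrix log P(c, v | z) for all droplet-locus
# pairs, marginalized over latent VAFs with log-sum-exp. Zero-coverage
# entries are treated as missing and contribute 0.
cond_loglik_matrix <- function(counts, priors, err, z) {
  theta <- if (z == 1) THETA_DOUBLET else THETA_SINGLET
  W <- post_ado_weights(priors, z, err$beta)
  p <- amplification_prob(theta, err$alpha_fp, err$alpha_fn)
  p <- pmin(pmax(p, 1e-9), 1 - 1e-9)
  V <- counts$alt
  C <- counts$total
  n <- nrow(C)
  comps <- lapply(seq_along(theta), function(k) {
    bb <- beta_binomial_loglik(V, C, p[k], err$s)
    bb + matrix(log(W[, k]), n, ncol(C), byrow = TRUE)
  })
  out <- logsumexp_stack(comps)
  out[C == 0] <- 0
  dimnames(out) <- dimnames(C)
  out
}

# Numerically stable log(sum(exp(.))) across a list of equal-shape matrices.
logsumexp_stack <- function(mats) {
  mx <- Reduce(pmax, mats)
  mx_safe <- ifelse(is.finite(mx), mx, 0)
  acc <- 0
  for (m in mats) acc <- acc + exp(m - mx_safe)
  ifelse(is.finite(mx), mx_safe + log(acc), -Inf)
}

#' Single droplet-locus conditional log-likelihood
#'
#' Marginalizes the read-count likelihood over the latent pre- and
#' post-dropout VAFs: `log P(c, v | z) = log sum_x sum_y
#' P(v | c, y) P(y | x, z) P(x | z)`. A zero-coverage entry carries no
#' information about doublet status (the uninformative prior on total depth
#' cancels in the likelihood ratio) and returns 0.
#'
#' @param v,c Variant and total read counts (non-negative scalars, `v <= c`).
#' @param z 0 (singlet) or 1 (doublet).
#' @param priors A [locus_priors] object.
#' @param locus Locus identifier.
#' @param err An [error_model] object.
#' @return Scalar log-probability.
#' @export
droplet_locus_loglik <- function(v, c, z, priors, locus, err) {
  stopifnot(length(v) == 1L, length(c) == 1L, v >= 0, v <= c)
  if (c == 0) return(0)
  loc <- match_locus(priors, locus)
  cnt <- read_counts(
    matrix(as.numeric(v), 1, 1, dimnames = list("d", loc)),
    matrix(as.numeric(c), 1, 1, dimnames = list("d", loc)))
  sub <- locus_priors(priors[loc, "wt"], priors[loc, "het"],
                      priors[loc, "hom"], locus_ids = loc)
  as.numeric(cond_loglik_matrix(cnt, sub, err, z))
}

#' Log-likelihood-ratio matrix and per-droplet scores
#'
#' Computes the droplet-by-locus matrix of log-likelihood ratios
#' `Omega[i, j] = log P(c, v | doublet) - log P(c, v | singlet)` and the
#' per-droplet decision score `sum_j Omega[i, j] + log(delta / (1 - delta))`.
#' Because droplets are independent and the posterior is linear in the
#' doublet indicators, these scores carry the exact maximum a posteriori
#' solution (see [classify()]).
#'
#' @param counts A [read_counts] object.
#' @param priors A [locus_priors] object covering every locus in `counts`
#'   (matched by label).
#' @param err An [error_model] object (its `delta` sets the score offset).
#' @return An object of class `likelihood_result`: list with `omega`,
#'   `row_score`, `log_lik_singlet`, `log_lik_doublet`, `delta`, `phi`
#'   (the score-independent part of the log-posterior) and `objective`
#'   (the log-posterior, up to the dropped normalizing constant, at the
#'   maximizing assignment).
#' @export
omega_matrix <- function(counts, priors, err) {
  if (!setequal(rownames(priors), counts$locus_ids)) {
    stop("locus labels of priors and counts differ")
  }
  pri <- locus_priors(priors[counts$locus_ids, "wt"],
                      priors[counts$locus_ids, "het"],
                      priors[counts$locus_ids, "hom"],
                      locus_ids = counts$locus_ids)
  ll0 <- cond_loglik_matrix(counts, pri, err, z = 0)
  ll1 <- cond_loglik_matrix(counts, pri, err, z = 1)
  omega <- ll1 - ll0
  log_odds <- log(err$delta / (1 - err$delta))
  row_score <- rowSums(omega) + log_odds
  n <- nrow(omega)
  phi <- sum(ll0) + n * log(1 - err$delta)
  structure(list(omega = omega, row_score = row_score,
                 log_lik_singlet = ll0, log_lik_doublet = ll1,
                 delta = err$delta, phi = phi,
                 objective = phi + sum(pmax(row_score, 0))),
            class = "likelihood_result")
}

#' @export
print.likelihood_result <- function(x, ...) {
  cat(sprintf(
    "likelihood_result: %d droplets x %d loci; %d positive scores at delta=%g\n",
    nrow(x$omega), ncol(x$omega), sum(x$row_score > 0), x$delta))
  invisible(x)
}

#' Closed-form doublet calls
#'
#' The log-posterior is linear in the per-droplet doublet indicators, so the
#' global maximum a posteriori assignment decouples: droplet `i` is called a
#' doublet exactly when its score `sum_j Omega[i, j] + log(delta / (1 -
#' delta))` is strictly positive (a score of exactly 0 is a singlet).
#'
#' @param result A `likelihood_result` from [omega_matrix()].
#' @param delta Doublet prior in (0, 1); defaults to the value stored in
#'   `result`.
#' @return A data frame with one row per droplet: `droplet_id`, `score`,
#'   `posterior` (two-state posterior doublet probability), `z` (0/1) and
#'   `call` (`"singlet"`/`"doublet"`), in the input droplet order.
#' @export
classify <- function(result, delta = result$delta) {
  if (!is.numeric(delta) || length(delta) != 1L || delta <= 0 || delta >= 1) {
    stop("delta must be a probability strictly inside (0, 1)")
  }
  score <- unname(rowSums(result$omega)) + log(delta / (1 - delta))
  z <- as.integer(score > 0)
  data.frame(droplet_id = rownames(result$omega),
             score = score,
             posterior = posterior_doublet_prob(score),
             z = z,
             call = ifelse(z == 1L, "doublet", "singlet"),
             row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Posterior doublet probability from a decision score
#'
#' Per-droplet normalization of the two-state posterior: the decision score
#' is the log posterior odds of doublet vs singlet, so the posterior doublet
#' probability is its logistic transform. Saturates cleanly for |score| up to
#' at least 1e4.
#'
#' @param score Numeric vector of log posterior odds.
#' @return Probabilities in `[0, 1]`.
#' @export
posterior_doublet_prob <- function(score) {
  stats::plogis(score)
}

prior_row <- function(priors, locus) {
  priors[match_locus(priors, locus), , drop = TRUE]
}

match_locus <- function(priors, locus) {
  locus <- as.character(locus)
  if (!locus %in% rownames(priors)) {
    stop(sprintf("unknown locus '%s'", locus))
  }
  locus
}

format_vaf <- function(x) {
  vapply(x, function(v) {
    hit <- which(abs(VAF_LABELS$value - v) < 1e-12)
    if (length(hit)) VAF_LABELS$label[hit[1]] else format(v)
  }, character(1))
}

VAF_LABELS <- data.frame(
  value = c(0, 1 / 4, 1 / 3, 1 / 2, 2 / 3, 3 / 4, 1),
  label = c("0", "1/4", "1/3", "1/2", "2/3", "3/4", "1"),
  stringsAsFactors = FALSE
)
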