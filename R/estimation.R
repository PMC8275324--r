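#' Settings for data-driven parameter estimation
#'
#' Controls the crude VAF-threshold genotyping used to seed the estimators,
#' the candidate grid for the doublet prior, and smoothing/fallbacks.
#'
#' @param vaf_low,vaf_high VAF thresholds for crude genotype assignment: a
#'   cell-locus with observed VAF below `vaf_low` is treated as wild-type,
#'   above `vaf_high` as homozygous, otherwise heterozygous.
#' @param min_depth Minimum total depth for a cell-locus to enter estimation.
#' @param delta_grid Strictly increasing candidate doublet priors in (0, 1).
#' @param pseudocount Laplace smoothing added to each genotype class when
#'   estimating per-locus genotype probabilities.
#' @param s_default Precision used when no heterozygous entries are available
#'   to fit one.
#' @param s_max Ceiling for the fitted precision (the binomial limit).
#' @return An object of class `estimation_config` (a named list).
#' @export
estimation_config <- function(vaf_low = 0.15, vaf_high = 0.85,
                              min_depth = 10,
                              delta_grid = seq(0.01, 0.50, by = 0.01),
                              pseudocount = 1,
                              s_default = 15, s_max = 1e6) {
  stopifnot(vaf_low > 0, vaf_low < vaf_high, vaf_high < 1,
            min_depth >= 0, pseudocount >= 0,
            length(delta_grid) >= 1, all(delta_grid > 0), all(delta_grid < 1),
            !is.unsorted(delta_grid, strictly = TRUE),
            s_default > 0, s_max > 0)
  structure(list(vaf_low = vaf_low, vaf_high = vaf_high,
                 min_depth = min_depth, delta_grid = delta_grid,
                 pseudocount = pseudocount, s_default = s_default,
                 s_max = s_max),
            class = "estimation_config")
}

#' Crude per-entry genotype assignment by VAF thresholds
#'
#' @param counts A [read_counts] object.
#' @param cfg An [estimation_config].
#' @return Character matrix (droplets x loci) over
#'   `"wt"`, `"het"`, `"hom"`, `"missing"`; entries with depth below
#'   `min_depth` are `"missing"`.
#' @export
assign_crude_genotypes <- function(counts, cfg = estimation_config()) {
  C <- counts$total
  vaf <- counts$alt / ifelse(C == 0, 1, C)
  states <- matrix("het", nrow(C), ncol(C), dimnames = dimnames(C))
  states[vaf < cfg$vaf_low] <- "wt"
  states[vaf > cfg$vaf_high] <- "hom"
  states[C < cfg$min_depth | C == 0] <- "missing"
  states
}

#' Per-locus genotype probabilities from crude assignments
#'
#' Smoothed relative frequencies of wild-type/heterozygous/homozygous among
#' non-missing droplets at each locus; loci with no usable droplets fall back
#' to the uniform triple. Doublet contamination of the sample is ignored at
#' this stage (droplets are treated as singlets).
#'
#' When the ADO rate `beta` is supplied, the observed class frequencies are
#' corrected for dropout before smoothing: a heterozygous singlet presents an
#' all-reference (all-variant) read pool with probability `beta / (1 + beta)`
#' each, so naive frequencies leak heterozygous mass into the wild-type and
#' homozygous classes — at loci that carry no homozygous cells this invents
#' doublet-like VAF support and costs specificity. Inverting the known
#' singlet dropout transition removes the bias; the corrected frequencies are
#' clamped at zero and renormalized.
#'
#' @param states Character state matrix from [assign_crude_genotypes()].
#' @param cfg An [estimation_config].
#' @param beta ADO rate used for the dropout correction; 0 disables it.
#' @return A [locus_priors] object.
#' @export
estimate_locus_priors <- function(states, cfg = estimation_config(),
                                  beta = 0) {
  stopifnot(beta >= 0, beta < 1)
  pc <- cfg$pseudocount
  leak <- beta / (1 + beta)  # P(het singlet presents as wt or hom)
  mu <- t(apply(states, 2, function(col) {
    k <- c(wt = sum(col == "wt"), het = sum(col == "het"),
           hom = sum(col == "hom"))
    if (sum(k) == 0) return(c(1, 1, 1) / 3)
    q <- (k + pc) / (sum(k) + 3 * pc)
    if (beta > 0) {
      het <- q[2] * (1 + beta) / (1 - beta)
      q <- c(q[1] - q[2] * leak * (1 + beta) / (1 - beta),
             het,
             q[3] - q[2] * leak * (1 + beta) / (1 - beta))
      q <- pmax(q, 0)
      q <- q / sum(q)
    }
    q
  }))
  locus_priors(mu[, 1], mu[, 2], mu[, 3], locus_ids = colnames(states))
}

#' Copy-error rates and beta-binomial precision from assigned entries
#'
#' The false-positive copy-error rate is the pooled VAF (total variant reads
#' over total reads) across wild-type-assigned entries; the false-negative
#' rate is the pooled reference fraction across homozygous entries. The
#' precision `s` is a method-of-moments fit on heterozygous entries: the
#' empirical squared deviation of `v` from its mean `c * p` is matched to the
#' beta-binomial variance `c p (1 - p) (1 + (c - 1) / (s + 1))` with `p` the
#' copy-error-adjusted heterozygous mean, and solved for `s`.
#'
#' @param counts A [read_counts] object.
#' @param states State matrix from [assign_crude_genotypes()].
#' @param cfg An [estimation_config].
#' @return Named list with `alpha_fp`, `alpha_fn`, `s`.
#' @export
estimate_overdispersion <- function(counts, states,
                                    cfg = estimation_config()) {
  V <- counts$alt
  C <- counts$total
  pool <- function(num, den, what, fallback) {
    if (sum(den) == 0) {
      warning(sprintf("no %s entries; falling back to %g", what, fallback))
      return(fallback)
    }
    sum(num) / sum(den)
  }
  wt <- states == "wt"
  hom <- states == "hom"
  het <- states == "het"
  alpha_fp <- pool(V[wt], C[wt], "wild-type", 1e-3)
  alpha_fn <- pool(C[hom] - V[hom], C[hom], "homozygous", 1e-3)
  alpha_fp <- min(max(alpha_fp, 1e-6), 0.3)
  alpha_fn <- min(max(alpha_fn, 1e-6), 0.3)

  if (!any(het)) {
    warning(sprintf(
      "no heterozygous entries; falling back to precision s = %g",
      cfg$s_default))
    s <- cfg$s_default
  } else {
    v <- V[het]
    c <- C[het]
    p <- amplification_prob(0.5, alpha_fp, alpha_fn)
    excess <- sum((v - c * p)^2) - sum(c * p * (1 - p))
    binom_part <- sum(c * (c - 1) * p * (1 - p))
    s <- if (excess <= 0 || binom_part <= 0) cfg$s_max
         else binom_part / excess - 1
    s <- min(max(s, 0.01), cfg$s_max)
  }
  list(alpha_fp = alpha_fp, alpha_fn = alpha_fn, s = s)
}

#' Doublet prior by posterior maximization over a grid
#'
#' For each candidate `delta`, the maximum a posteriori assignment is the
#' closed-form thresholding of the per-droplet scores, and the attained
#' log-posterior (up to a constant that does not involve `delta`) is
#' `n * log(1 - delta) + sum_i max(0, score_i(delta))`. The ratio matrix is
#' computed once; only the `log(delta / (1 - delta))` offset moves across the
#' grid. Ties break toward the smaller candidate.
#'
#' @param counts A [read_counts] object.
#' @param priors A [locus_priors] object.
#' @param err An [error_model]; its `delta` entry is ignored.
#' @param grid Candidate values (defaults to the grid in
#'   [estimation_config()]).
#' @return The maximizing `delta`.
#' @export
estimate_delta <- function(counts, priors, err,
                           grid = estimation_config()$delta_grid) {
  stopifnot(length(grid) >= 1, all(grid > 0), all(grid < 1))
  res <- omega_matrix(counts, priors, err)
  rs <- rowSums(res$omega)
  n <- length(rs)
  obj <- vapply(grid, function(d) {
    n * log(1 - d) + sum(pmax(rs + log(d / (1 - d)), 0))
  }, numeric(1))
  grid[which.max(obj)]
}

#' One-stop data-driven parameter estimation
#'
#' Runs crude genotyping, per-locus genotype priors, copy-error/precision
#' moments and (optionally) the doublet-prior grid search. The ADO rate
#' `beta` is not estimable from the count matrices alone and must be supplied
#' (e.g. a platform estimate).
#'
#' @param counts A [read_counts] object.
#' @param beta Known ADO rate.
#' @param delta Doublet prior; `NULL` to estimate it by grid search.
#' @param cfg An [estimation_config].
#' @return List with `priors` ([locus_priors]) and `err` ([error_model],
#'   `delta` filled in), plus `delta_estimated` (logical).
#' @export
estimate_parameters <- function(counts, beta, delta = NULL,
                                cfg = estimation_config()) {
  states <- assign_crude_genotypes(counts, cfg)
  priors <- estimate_locus_priors(states, cfg, beta = beta)
  od <- estimate_overdispersion(counts, states, cfg)
  delta_estimated <- is.null(delta)
  if (delta_estimated) {
    probe <- error_model(beta, od$alpha_fp, od$alpha_fn, od$s, delta = 0.5)
    delta <- estimate_delta(counts, priors, probe, cfg$delta_grid)
  }
  err <- error_model(beta, od$alpha_fp, od$alpha_fn, od$s, delta = delta)
  list(priors = priors, err = err, delta_estimated = delta_estimated)
}

#' Write / read model parameters as YAML
#'
#' Round-trips the error model and genotype priors through a plain-text YAML
#' file with keys `beta`, `alpha_fp`, `alpha_fn`, `s`, `delta` and `mu`
#' (either a global `[wt, het, hom]` triple or a per-locus table).
#'
#' @param err An [error_model].
#' @param priors A [locus_priors], or `NULL` to omit `mu`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_params_yaml <- function(err, priors = NULL, path) {
  obj <- list(beta = err$beta, alpha_fp = err$alpha_fp,
              alpha_fn = err$alpha_fn, s = err$s, delta = err$delta)
  if (!is.null(priors)) {
    obj$mu <- list(locus = rownames(priors),
                   wt = as.numeric(priors[, "wt"]),
                   het = as.numeric(priors[, "het"]),
                   hom = as.numeric(priors[, "hom"]))
  }
  yaml::write_yaml(obj, path, precision = 15)
  invisible(path)
}

#' @rdname write_params_yaml
#' @param locus_ids Loci to broadcast a global `mu` triple over when the file
#'   stores one (ignored when the file carries a per-locus table).
#' @return For `read_params_yaml`: list with `err` and `priors` (`NULL` when
#'   the file has no `mu` and no `locus_ids` were given).
#' @export
read_params_yaml <- function(path, locus_ids = NULL) {
  obj <- yaml::read_yaml(path)
  err <- error_model(obj$beta, obj$alpha_fp, obj$alpha_fn, obj$s, obj$delta)
  priors <- NULL
  if (!is.null(obj$mu)) {
    mu <- obj$mu
    if (is.list(mu) && !is.null(mu$locus)) {
      priors <- locus_priors(unlist(mu$wt), unlist(mu$het), unlist(mu$hom),
                             locus_ids = unlist(mu$locus))
    } else {
      mu <- unlist(mu)
      if (length(mu) != 3) stop("global mu must be a [wt, het, hom] triple")
      if (is.null(locus_ids)) stop("locus_ids needed to broadcast global mu")
      priors <- locus_priors(mu[1], mu[2], mu[3], locus_ids = locus_ids)
    }
  } else if (!is.null(locus_ids)) {
    priors <- NULL
  }
  list(err = err, priors = priors)
}
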