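#' Score doublet calls against simulation truth
#'
#' Doublet is the positive class. Precision is reported as 0 (not NaN) when
#' nothing is called positive, so medians over benchmark grids stay defined.
#' Recall is additionally broken down by the true doublet type (selflet,
#' nested, neotypic); types absent from the truth yield `NA` recall.
#'
#' @param truth Data frame with `droplet_id`, `is_doublet` (0/1) and
#'   `doublet_type` (as produced by [simulate_droplets()]).
#' @param calls Data frame with `droplet_id` and `z` (0/1) or `call`
#'   (as produced by [classify()]).
#' @return One-row data frame: `precision`, `recall`, `f1`,
#'   `recall_selflet`, `recall_nested`, `recall_neotypic`, `tp`, `fp`, `fn`,
#'   `tn`.
#' @export
score_calls <- function(truth, calls) {
  if (!setequal(truth$droplet_id, calls$droplet_id)) {
    stop("droplet ids of truth and calls differ")
  }
  calls <- calls[match(truth$droplet_id, calls$droplet_id), ]
  pred <- if ("z" %in% names(calls)) calls$z == 1 else calls$call == "doublet"
  pos <- truth$is_doublet == 1
  tp <- sum(pred & pos)
  fp <- sum(pred & !pos)
  fn <- sum(!pred & pos)
  tn <- sum(!pred & !pos)
  precision <- if (tp + fp == 0) 0 else tp / (tp + fp)
  recall <- if (tp + fn == 0) 0 else tp / (tp + fn)
  f1 <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  type_recall <- vapply(c("selflet", "nested", "neotypic"), function(ty) {
    sel <- pos & truth$doublet_type == ty & !is.na(truth$doublet_type)
    if (!any(sel)) return(NA_real_)
    sum(pred & sel) / sum(sel)
  }, numeric(1))
  data.frame(precision = precision, recall = recall, f1 = f1,
             recall_selflet = type_recall[["selflet"]],
             recall_nested = type_recall[["nested"]],
             recall_neotypic = type_recall[["neotypic"]],
             tp = tp, fp = fp, fn = fn, tn = tn)
}

#' Neotypic confidence score of a droplet
#'
#' Counts validation loci whose observed VAF lies in `[lower, upper]`
#' (closed interval; zero-depth loci never count). Validation loci are loci
#' with discordant wild-type/homozygous states between two known cell
#' populations, so an intermediate VAF at several of them is orthogonal
#' evidence that the droplet mixes cells of both populations.
#'
#' @param alt,total Count vectors for one droplet, named by locus.
#' @param validation_loci Locus names to score; must be present.
#' @param lower,upper Closed VAF window (defaults 0.15, 0.85).
#' @return Non-negative integer count.
#' @export
ncs_score <- function(alt, total, validation_loci,
                      lower = 0.15, upper = 0.85) {
  if (!all(validation_loci %in% names(total))) {
    stop("validation loci missing from the count vectors")
  }
  v <- alt[validation_loci]
  c <- total[validation_loci]
  vaf <- ifelse(c > 0, v / ifelse(c == 0, 1, c), NA_real_)
  sum(!is.na(vaf) & vaf >= lower & vaf <= upper)
}

#' Median metrics over a benchmark grid
#'
#' Groups per-run metric reports by the requested configuration columns and
#' returns the median of every metric column in each group (per-type recalls
#' skip runs where the type did not occur). With no grouping keys, one pooled
#' row is returned.
#'
#' @param reports Data frame of per-run metrics, e.g. rows of [score_calls()]
#'   cbound with their configuration.
#' @param by Character vector of grouping column names (may be empty).
#' @return Data frame of medians, ordered by the grouping columns.
#' @export
aggregate_medians <- function(reports, by = character()) {
  stopifnot(nrow(reports) >= 1)
  metric_cols <- intersect(
    c("precision", "recall", "f1",
      "recall_selflet", "recall_nested", "recall_neotypic"),
    names(reports))
  med <- function(df) {
    out <- lapply(df[metric_cols], stats::median, na.rm = TRUE)
    as.data.frame(out)
  }
  if (length(by) == 0) return(med(reports))
  key <- interaction(reports[by], drop = TRUE, lex.order = TRUE)
  parts <- split(reports, key)
  out <- do.call(rbind, lapply(parts, function(df) {
    cbind(df[1, by, drop = FALSE], med(df))
  }))
  rownames(out) <- NULL
  out[do.call(order, out[by]), , drop = FALSE]
}

#' Simulate, call and score one benchmark run
#'
#' One end-to-end run of the benchmark pipeline: simulate a truth-labelled
#' dataset, estimate the genotype priors, copy-error rates and beta-binomial
#' precision from the observed counts alone, classify every droplet and
#' score the calls against the truth. The ADO rate and the doublet prior are
#' passed through as known assay-design parameters: the dropout rate of a
#' platform is characterized externally, and the doublet prior follows from
#' the cell-loading concentration, so neither is re-estimated from the
#' counts in the benchmark (the grid estimator for the doublet prior remains
#' available via [estimate_delta()]).
#'
#' @param cfg A [sim_config].
#' @param est_cfg An [estimation_config].
#' @return One-row data frame: the run configuration, the `delta` used,
#'   and the metric columns of [score_calls()].
#' @export
benchmark_run <- function(cfg, est_cfg = estimation_config()) {
  sim <- simulate_experiment(cfg)
  fit <- estimate_parameters(sim$counts, beta = cfg$beta, delta = cfg$delta,
                             cfg = est_cfg)
  res <- omega_matrix(sim$counts, fit$priors, fit$err)
  calls <- classify(res)
  metrics <- score_calls(sim$truth, calls)
  cbind(data.frame(m = cfg$m, beta = cfg$beta, coverage = cfg$coverage,
                   delta = cfg$delta, gamma = cfg$gamma,
                   loss_prob = cfg$loss_prob, seed = cfg$seed,
                   delta_hat = fit$err$delta),
        metrics)
}

#' Run a grid of benchmark simulations
#'
#' Expands the Cartesian product of the supplied parameter vectors, runs
#' [benchmark_run()] for every combination and returns the per-run metric
#' table. The default grid is the copy-neutral benchmark: m in \{10, 50,
#' 100\} SNVs by ADO rate in \{0, 0.05, 0.25\} by seeds 1..5 at 500 droplets,
#' coverage 50x, doublet probability 0.2 and precision 15.
#'
#' @param m,beta,seeds,coverage,delta,gamma,loss_prob Vectors of scenario
#'   values to cross.
#' @param s,n_droplets,n_clones Scalars shared by every run.
#' @param est_cfg An [estimation_config].
#' @param quiet Suppress per-run progress messages.
#' @return Data frame with one row per run.
#' @export
benchmark_grid <- function(m = c(10, 50, 100), beta = c(0, 0.05, 0.25),
                           seeds = 1:5, coverage = 50, delta = 0.2,
                           gamma = 0, loss_prob = 0.5, s = 15,
                           n_droplets = 500, n_clones = 10,
                           est_cfg = estimation_config(), quiet = TRUE) {
  grid <- expand.grid(m = m, beta = beta, coverage = coverage,
                      delta = delta, gamma = gamma, loss_prob = loss_prob,
                      seed = seeds, KEEP.OUT.ATTRS = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    g <- grid[i, ]
    if (!quiet) {
      message(sprintf("run %d/%d: m=%d beta=%g cov=%g gamma=%g seed=%d",
                      i, nrow(grid), g$m, g$beta, g$coverage, g$gamma,
                      g$seed))
    }
    cfg <- sim_config(n_clones = n_clones, m = g$m, n_droplets = n_droplets,
                      delta = g$delta, coverage = g$coverage, beta = g$beta,
                      s = s, gamma = g$gamma, loss_prob = g$loss_prob,
                      seed = g$seed)
    benchmark_run(cfg, est_cfg)
  })
  do.call(rbind, rows)
}
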