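#' Scenario configuration for the droplet simulator
#'
#' Defaults reproduce the benchmark regime: 10 clonal genotypes, 500
#' droplets, doublet probability 0.2, mean coverage 50x, ADO rate 0.05,
#' beta-binomial precision 15 and no copy-number aberrations. Copy-error
#' rates default to values fitted on a real droplet scDNA-seq platform.
#'
#' @param n_clones Number of clonal genotypes in the sample.
#' @param m Number of SNV loci.
#' @param n_droplets Number of sequenced droplets.
#' @param delta Probability that a droplet captures two cells.
#' @param coverage Mean per-locus sequencing depth of a diploid singlet.
#' @param beta Per-copy allelic dropout rate.
#' @param s Beta-binomial precision of allelic imbalance.
#' @param alpha_fp,alpha_fn Amplification copy-error rates.
#' @param gamma Probability that a locus carries a copy-number aberration.
#' @param loss_prob Given a CNA, probability it is a copy loss (else a gain).
#' @param trunk_prob Probability that an SNV is truncal, i.e. placed on the
#'   founder clone's stem edge and therefore carried (heterozygously) by
#'   every clone. Targeted scDNA-seq panels are ascertained on variants
#'   observed in the sample, which makes truncal mutations a large fraction
#'   of panel loci in practice; the remaining SNVs land on random subclonal
#'   edges.
#' @param seed Integer seed; fixes every random choice of the simulation.
#' @return An object of class `sim_config` (a named list).
#' @export
sim_config <- function(n_clones = 10, m = 100, n_droplets = 500,
                       delta = 0.2, coverage = 50, beta = 0.05, s = 15,
                       alpha_fp = 0.015, alpha_fn = 0.0073,
                       gamma = 0, loss_prob = 0.5, trunk_prob = 1 / 3,
                       seed = 1) {
  stopifnot(n_clones >= 1, m >= 1, n_droplets >= 1,
            delta >= 0, delta <= 1, coverage > 0, beta >= 0, beta < 1,
            s > 0, alpha_fp >= 0, alpha_fp < 1, alpha_fn >= 0, alpha_fn < 1,
            gamma >= 0, gamma <= 1, loss_prob >= 0, loss_prob <= 1,
            trunk_prob >= 0, trunk_prob <= 1)
  structure(list(n_clones = as.integer(n_clones), m = as.integer(m),
                 n_droplets = as.integer(n_droplets), delta = delta,
                 coverage = coverage, beta = beta, s = s,
                 alpha_fp = alpha_fp, alpha_fn = alpha_fn,
                 gamma = gamma, loss_prob = loss_prob,
                 trunk_prob = trunk_prob,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a clonal genotype panel
#'
#' Builds a random clonal tree by sequential clonal expansion: each new clone
#' descends from the most recently added clone with probability 1/2 (chain
#' growth, the dominant mode in published tumor phylogenies at this scale)
#' and otherwise branches off a uniformly chosen earlier clone. Places each
#' SNV as a heterozygous single-copy gain
#' on a random edge (infinite sites: the clade below carries the variant) —
#' truncal with probability `trunk_prob`, i.e. on the founder's stem edge so
#' all clones inherit it — and optionally overlays copy-number aberrations:
#' with probability `gamma` a locus receives a CNA on a random edge (the
#' stem included), a loss of one allele copy with probability `loss_prob`
#' (possibly causing loss of heterozygosity) and a duplication of one copy
#' otherwise. Clone frequencies are symmetric Dirichlet(1).
#'
#' Uses the session RNG; seed it (or use [simulate_experiment()]) for
#' reproducibility.
#'
#' @param cfg A [sim_config].
#' @return An object of class `clone_panel`: list with `parent` (tree),
#'   `ref_copies`/`var_copies` (clone x locus allele copy numbers),
#'   `genotypes` (clone x locus over wt/het/hom), `freqs`, `clone_ids`,
#'   `locus_ids`.
#' @export
simulate_clone_panel <- function(cfg) {
  nc <- cfg$n_clones
  m <- cfg$m
  clone_ids <- paste0("clone", seq_len(nc))
  locus_ids <- paste0("L", seq_len(m))
  parent <- c(NA_integer_,
              if (nc > 1) vapply(2:nc, function(i) {
                if (i == 2 || stats::runif(1) < 0.5) return(i - 1L)
                sample.int(i - 1L, 1L)
              }, integer(1)))
  children <- lapply(seq_len(nc), function(i) which(parent == i))
  clade <- function(i) {
    out <- i
    stack <- children[[i]]
    while (length(stack)) {
      j <- stack[1]
      stack <- stack[-1]
      out <- c(out, j)
      stack <- c(stack, children[[j]])
    }
    out
  }
  ref <- matrix(2L, nc, m, dimnames = list(clone_ids, locus_ids))
  var <- matrix(0L, nc, m, dimnames = list(clone_ids, locus_ids))
  truncal <- stats::runif(m) < cfg$trunk_prob
  origin <- rep(1L, m)
  if (nc > 1) {
    origin[!truncal] <- sample(2:nc, sum(!truncal), replace = TRUE)
  }
  for (j in seq_len(m)) {
    if (!truncal[j] && nc == 1L) next # no subclonal edges in a single clone
    cl <- clade(origin[j])
    ref[cl, j] <- ref[cl, j] - 1L
    var[cl, j] <- var[cl, j] + 1L
  }
  if (cfg$gamma > 0) {
    has_cna <- stats::runif(m) < cfg$gamma
    for (j in which(has_cna)) {
      o <- sample.int(nc, 1L)
      cl <- clade(o)
      tot <- ref[o, j] + var[o, j]
      if (tot == 0L) next
      allele <- if (stats::runif(1) < var[o, j] / tot) "var" else "ref"
      mat <- if (allele == "var") var else ref
      if (stats::runif(1) < cfg$loss_prob) {
        mat[cl, j] <- pmax(mat[cl, j] - 1L, 0L)
      } else {
        mat[cl, j] <- mat[cl, j] + ifelse(mat[cl, j] > 0L, 1L, 0L)
      }
      if (allele == "var") var <- mat else ref <- mat
    }
  }
  genotypes <- matrix("wt", nc, m, dimnames = list(clone_ids, locus_ids))
  genotypes[var > 0L & ref > 0L] <- "het"
  genotypes[var > 0L & ref == 0L] <- "hom"
  freqs <- stats::rexp(nc)
  freqs <- freqs / sum(freqs)
  structure(list(parent = parent, ref_copies = ref, var_copies = var,
                 genotypes = genotypes, freqs = freqs,
                 clone_ids = clone_ids, locus_ids = locus_ids),
            class = "clone_panel")
}

#' Classify a doublet by the relationship of its two genotypes
#'
#' A selflet joins two cells with identical genotypes; a nested doublet joins
#' cells where one cell's mutated-locus set is a proper subset of the
#' other's; every other pair is neotypic (it presents a genotype absent from
#' the sample).
#'
#' @param g1,g2 Equal-length character genotype vectors over
#'   `"wt"`/`"het"`/`"hom"`.
#' @return `"selflet"`, `"nested"` or `"neotypic"`.
#' @export
classify_doublet_type <- function(g1, g2) {
  if (length(g1) != length(g2)) stop("genotype vectors differ in length")
  if (identical(as.character(g1), as.character(g2))) return("selflet")
  m1 <- g1 != "wt"
  m2 <- g2 != "wt"
  sub12 <- all(m2[m1]) # mutated loci of g1 all mutated in g2
  sub21 <- all(m1[m2])
  if ((sub12 || sub21) && !identical(m1, m2)) return("nested")
  "neotypic"
}

#' Fill droplets with one or two cells
#'
#' Each droplet is a doublet with probability `delta`; constituent clones are
#' drawn i.i.d. from the clone frequencies. Doublet allele copy numbers are
#' the per-locus sums over the two cells. Uses the session RNG.
#'
#' @param panel A `clone_panel` from [simulate_clone_panel()].
#' @param cfg A [sim_config].
#' @return List with `truth` (data frame: `droplet_id`, `clone1`, `clone2`,
#'   `is_doublet`, `doublet_type`) and `ref_copies`/`var_copies`
#'   (droplet x locus).
#' @export
simulate_droplets <- function(panel, cfg) {
  n <- cfg$n_droplets
  nc <- length(panel$clone_ids)
  droplet_ids <- sprintf("d%04d", seq_len(n))
  is_dbl <- stats::rbinom(n, 1L, cfg$delta)
  c1 <- sample.int(nc, n, replace = TRUE, prob = panel$freqs)
  c2 <- ifelse(is_dbl == 1L,
               sample.int(nc, n, replace = TRUE, prob = panel$freqs),
               NA_integer_)
  ref <- panel$ref_copies[c1, , drop = FALSE]
  var <- panel$var_copies[c1, , drop = FALSE]
  dbl <- which(is_dbl == 1L)
  if (length(dbl)) {
    ref[dbl, ] <- ref[dbl, , drop = FALSE] +
      panel$ref_copies[c2[dbl], , drop = FALSE]
    var[dbl, ] <- var[dbl, , drop = FALSE] +
      panel$var_copies[c2[dbl], , drop = FALSE]
  }
  rownames(ref) <- rownames(var) <- droplet_ids
  dtype <- rep(NA_character_, n)
  for (i in dbl) {
    dtype[i] <- classify_doublet_type(panel$genotypes[c1[i], ],
                                      panel$genotypes[c2[i], ])
  }
  truth <- data.frame(droplet_id = droplet_ids,
                      clone1 = panel$clone_ids[c1],
                      clone2 = ifelse(is.na(c2), NA_character_,
                                      panel$clone_ids[c2]),
                      is_doublet = is_dbl,
                      doublet_type = dtype,
                      stringsAsFactors = FALSE)
  list(truth = truth, ref_copies = ref, var_copies = var)
}

#' Generate read counts from droplet allele copies
#'
#' The generative chain per droplet-locus: every allele copy is retained
#' independently with probability `1 - beta` (allelic dropout); if no copy
#' survives, the locus yields no reads. Otherwise total depth is Poisson with
#' mean `coverage * k / 2` for `k` retained copies (a doublet carries ~2x the
#' DNA of a singlet), the variant-copy probability follows the retained
#' variant fraction corrected for copy errors, the read-pool variant fraction
#' is Beta-distributed with precision `s` (allelic imbalance), and variant
#' reads are binomial. Uses the session RNG.
#'
#' @param droplets Output of [simulate_droplets()].
#' @param cfg A [sim_config].
#' @return A [read_counts] object.
#' @export
simulate_reads <- function(droplets, cfg) {
  ref <- droplets$ref_copies
  var <- droplets$var_copies
  n <- nrow(ref)
  m <- ncol(ref)
  kv <- matrix(stats::rbinom(n * m, as.vector(var), 1 - cfg$beta), n, m)
  kr <- matrix(stats::rbinom(n * m, as.vector(ref), 1 - cfg$beta), n, m)
  k <- kv + kr
  depth <- matrix(stats::rpois(n * m, cfg$coverage * as.vector(k) / 2), n, m)
  y <- ifelse(k == 0, 0, kv / pmax(k, 1L))
  p <- amplification_prob(y, cfg$alpha_fp, cfg$alpha_fn)
  # degenerate template pools amplify deterministically
  p_safe <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  pii <- matrix(stats::rbeta(n * m, as.vector(p_safe) * cfg$s,
                             (1 - as.vector(p_safe)) * cfg$s), n, m)
  pii[p == 0] <- 0
  pii[p == 1] <- 1
  v <- matrix(stats::rbinom(n * m, as.vector(depth), as.vector(pii)), n, m)
  depth[k == 0] <- 0L
  v[k == 0] <- 0L
  dimnames(depth) <- dimnames(v) <- dimnames(ref)
  read_counts(v, depth)
}

#' Run one full truth-labelled simulation
#'
#' Seeds the RNG from `cfg$seed`, then draws the clone panel, the droplet
#' composition and the read counts, so identical configurations reproduce
#' identical datasets bit for bit.
#'
#' @param cfg A [sim_config].
#' @return List with `panel`, `truth`, `counts` and `config`.
#' @export
simulate_experiment <- function(cfg) {
  set.seed(cfg$seed)
  panel <- simulate_clone_panel(cfg)
  droplets <- simulate_droplets(panel, cfg)
  counts <- simulate_reads(droplets, cfg)
  list(panel = panel, truth = droplets$truth, counts = counts, config = cfg)
}
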