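test_that("doublet prior follows the renormalized Poisson capture model", {
  expect_equal(doublet_prior_from_rate(1), 1 / 3, tolerance = 1e-12)
  expect_equal(doublet_prior_from_rate(0.1), 1 / 21, tolerance = 1e-12)
  expect_lt(doublet_prior_from_rate(1e-8), 1e-7)
  expect_error(doublet_prior_from_rate(0), "positive")
  expect_error(doublet_prior_from_rate(-1), "positive")
})

test_that("singlet VAF prior maps genotype probabilities onto {0, 1/2, 1}", {
  pri <- locus_priors(c(1, 1 / 3), c(0, 1 / 3), c(0, 1 / 3),
                      locus_ids = c("A", "B"))
  pure <- singlet_vaf_prior(pri, "A")
  expect_equal(unname(pure), c(1, 0, 0))
  unif <- singlet_vaf_prior(pri, "B")
  expect_equal(unname(unif), rep(1 / 3, 3))
  expect_equal(sum(unif), 1)
  expect_error(singlet_vaf_prior(pri, "nope"), "unknown locus")
})

test_that("doublet VAF prior convolves ordered pairs of singlet genotypes", {
  pri <- locus_priors(1 / 3, 1 / 3, 1 / 3, locus_ids = "A")
  d <- doublet_vaf_prior(pri, "A")
  expect_equal(unname(d), c(1, 2, 3, 2, 1) / 9, tolerance = 1e-12)
  # f = 1/2 aggregates (het,het), (hom,wt) and (wt,hom)
  set.seed(7)
  for (i in 1:10) {
    mu <- stats::runif(3)
    mu <- mu / sum(mu)
    p <- locus_priors(mu[1], mu[2], mu[3], locus_ids = "A")
    expect_equal(unname(doublet_vaf_prior(p, "A")["1/2"]),
                 mu[2]^2 + 2 * mu[1] * mu[3], tolerance = 1e-12)
    expect_equal(sum(doublet_vaf_prior(p, "A")), 1, tolerance = 1e-9)
  }
  point <- locus_priors(1, 0, 0, locus_ids = "A")
  expect_equal(unname(doublet_vaf_prior(point, "A")), c(1, 0, 0, 0, 0))
})

test_that("dropout transition enumerates per-copy retention and conditions
           on at least one surviving copy", {
  # no dropout: point mass at y = x for every legal state
  for (z in 0:1) {
    sig <- vaf_support(if (z == 1) "doublet" else "singlet")$pre_ado
    for (x in sig) {
      tr <- ado_transition(x, z, beta = 0)
      expect_equal(sum(tr), 1, tolerance = 1e-12)
      theta <- vaf_support(if (z == 1) "doublet" else "singlet")$post_ado
      expect_equal(unname(tr[abs(theta - x) < 1e-12]), 1, tolerance = 1e-12)
    }
  }
  # heterozygous singlet: closed form
  for (beta in c(0.05, 0.25, 0.6)) {
    tr <- ado_transition(1 / 2, 0, beta)
    expect_equal(unname(tr["1/2"]), (1 - beta)^2 / (1 - beta^2),
                 tolerance = 1e-12)
    expect_equal(unname(tr["0"]), beta * (1 - beta) / (1 - beta^2),
                 tolerance = 1e-12)
    expect_equal(unname(tr["1"]), unname(tr["0"]), tolerance = 1e-12)
  }
  # doublet supports cover exactly the printed seven-point set
  theta_d <- vaf_support("doublet")$post_ado
  reached <- rep(FALSE, length(theta_d))
  for (x in vaf_support("doublet")$pre_ado) {
    tr <- ado_transition(x, 1, 0.3)
    reached <- reached | tr > 0
  }
  expect_equal(sort(theta_d[reached]),
               c(0, 1 / 4, 1 / 3, 1 / 2, 2 / 3, 3 / 4, 1))
  expect_error(ado_transition(1 / 4, 0, 0.1), "legal")
})

test_that("dropout transitions are normalized across a parameter grid", {
  for (beta in c(0.01, 0.1, 0.5, 0.9)) {
    for (z in 0:1) {
      sig <- if (z == 1) vaf_support("doublet")$pre_ado else
        vaf_support("singlet")$pre_ado
      for (x in sig) {
        expect_equal(sum(ado_transition(x, z, beta)), 1, tolerance = 1e-9)
      }
    }
  }
})

test_that("copy-error map is affine in the template variant fraction", {
  expect_equal(amplification_prob(0, 0.015, 0.0073), 0.015)
  expect_equal(amplification_prob(1, 0.015, 0.0073), 1 - 0.0073)
  expect_equal(amplification_prob(0.5, 0.015, 0.0073), 0.50385,
               tolerance = 1e-12)
})

test_that("beta-binomial log-pmf normalizes and matches the binomial limit", {
  for (c in c(0, 1, 10, 100)) {
    for (p in c(0.1, 0.5, 0.9)) {
      for (s in c(0.5, 15)) {
        expect_equal(sum(exp(beta_binomial_loglik(0:c, c, p, s))), 1,
                     tolerance = 1e-9)
      }
    }
  }
  expect_identical(beta_binomial_loglik(0, 0, 0.3, 10), 0)
  tv <- 0.5 * sum(abs(exp(beta_binomial_loglik(0:50, 50, 0.3, 1e6)) -
                        stats::dbinom(0:50, 50, 0.3)))
  expect_lt(tv, 1e-3)
  expect_error(beta_binomial_loglik(5, 3, 0.5, 10), "v <= c")
  expect_error(beta_binomial_loglik(1, 3, 0, 10), "strictly inside")
  # no overflow at deep coverage
  expect_true(is.finite(beta_binomial_loglik(40000, 1e5, 0.4, 10)))
})

test_that("droplet-locus likelihood equals the linear-space brute force", {
  set.seed(11)
  maxdiff <- 0
  for (i in 1:50) {
    mu <- stats::runif(3)
    mu <- mu / sum(mu)
    beta <- stats::runif(1, 0.01, 0.5)
    s <- stats::runif(1, 2, 40)
    afp <- stats::runif(1, 1e-4, 0.05)
    afn <- stats::runif(1, 1e-4, 0.05)
    c <- sample(1:30, 1)
    v <- sample(0:c, 1)
    z <- sample(0:1, 1)
    pri <- locus_priors(mu[1], mu[2], mu[3], locus_ids = "L1")
    err <- error_model(beta, afp, afn, s, 0.2)
    got <- droplet_locus_loglik(v, c, z, pri, "L1", err)
    want <- log(oracle_droplet_locus_lik(v, c, z, mu, beta,
                                         err$alpha_fp, err$alpha_fn, s))
    maxdiff <- max(maxdiff, abs(got - want))
  }
  expect_lt(maxdiff, 1e-10)
})

test_that("zero coverage carries no doublet information", {
  pri <- locus_priors(0.5, 0.3, 0.2, locus_ids = "L1")
  err <- error_model(0.1, 0.01, 0.01, 15, 0.2)
  expect_identical(droplet_locus_loglik(0, 0, 0, pri, "L1", err), 0)
  expect_identical(droplet_locus_loglik(0, 0, 1, pri, "L1", err), 0)
  counts <- make_counts(matrix(0L, 3, 4), matrix(0L, 3, 4))
  res <- omega_matrix(counts, locus_priors(0.5, 0.3, 0.2,
                                           locus_ids = counts$locus_ids), err)
  expect_true(all(res$omega == 0))
})

test_that("a VAF of one quarter is doublet evidence", {
  pri <- locus_priors(1 / 3, 1 / 3, 1 / 3, locus_ids = "L1")
  err <- error_model(0, 1e-6, 1e-6, 1e6, 0.2)
  ll1 <- droplet_locus_loglik(25, 100, 1, pri, "L1", err)
  ll0 <- droplet_locus_loglik(25, 100, 0, pri, "L1", err)
  expect_gt(ll1, ll0)
  counts <- make_counts(matrix(25L, 1, 1), matrix(100L, 1, 1))
  res <- omega_matrix(counts, locus_priors(1 / 3, 1 / 3, 1 / 3,
                                           locus_ids = counts$locus_ids), err)
  expect_gt(res$omega[1, 1], 0)
})

test_that("omega matrix is the log-likelihood-ratio of the two conditionals", {
  set.seed(3)
  total <- matrix(rpois(12, 40), 3, 4)
  alt <- matrix(rbinom(12, as.vector(total), 0.4), 3, 4)
  counts <- make_counts(alt, total)
  pri <- locus_priors(0.6, 0.3, 0.1, locus_ids = counts$locus_ids)
  err <- error_model(0.1, 0.01, 0.005, 15, 0.25)
  res <- omega_matrix(counts, pri, err)
  expect_equal(res$omega, res$log_lik_doublet - res$log_lik_singlet)
  expect_equal(res$row_score, rowSums(res$omega) + log(0.25 / 0.75))
  expect_true(all(is.finite(res$omega)))
  bad <- locus_priors(0.6, 0.3, 0.1, locus_ids = c("X1", "X2", "X3", "X4"))
  expect_error(omega_matrix(counts, bad, err), "labels")
})

test_that("classification matches exhaustive maximization of the posterior", {
  set.seed(5)
  for (i in 1:8) {
    n <- sample(4:9, 1)
    omega <- matrix(rnorm(n * 3, sd = 2), n, 3,
                    dimnames = list(paste0("d", 1:n), paste0("L", 1:3)))
    delta <- stats::runif(1, 0.05, 0.6)
    res <- structure(list(omega = omega, delta = delta), class = "likelihood_result")
    calls <- classify(res, delta)
    best <- oracle_best_assignment(omega, delta)
    got_j <- sum(calls$z * (rowSums(omega) + log(delta / (1 - delta))))
    expect_equal(got_j, best$objective, tolerance = 1e-12)
    expect_equal(calls$z, best$z)
  }
})

test_that("tie scores and empty evidence default to singlet", {
  omega <- matrix(0, 3, 2,
                  dimnames = list(paste0("d", 1:3), paste0("L", 1:2)))
  res <- structure(list(omega = omega, delta = 0.5), class = "likelihood_result")
  calls <- classify(res, 0.5) # score exactly 0 everywhere
  expect_true(all(calls$call == "singlet"))
  calls2 <- classify(res, 0.3)
  expect_true(all(calls2$z == 0L))
  expect_error(classify(res, 1), "strictly inside")
})

test_that("raising the doublet prior never flips a call back to singlet", {
  set.seed(9)
  omega <- matrix(rnorm(60, sd = 1.5), 20, 3,
                  dimnames = list(paste0("d", 1:20), paste0("L", 1:3)))
  res <- structure(list(omega = omega, delta = 0.1), class = "likelihood_result")
  prev <- classify(res, 0.02)$z
  for (delta in c(0.05, 0.1, 0.2, 0.4, 0.8)) {
    cur <- classify(res, delta)$z
    expect_true(all(cur >= prev))
    prev <- cur
  }
})

test_that("posterior transform is the stable logistic of the score", {
  expect_equal(posterior_doublet_prob(0), 0.5)
  expect_equal(posterior_doublet_prob(1000), 1, tolerance = 1e-12)
  expect_equal(posterior_doublet_prob(-1000), 0, tolerance = 1e-12)
  s <- c(-30, -1, 0, 2.5, 50)
  expect_equal(posterior_doublet_prob(s) + posterior_doublet_prob(-s),
               rep(1, length(s)), tolerance = 1e-12)
})

test_that("evidence accumulates with loci: clean singlets diverge negative,
           clean quarter-VAF droplets diverge positive", {
  err <- error_model(0, 1e-6, 1e-6, 1e5, 0.3)
  score_at_m <- function(m, vaf) {
    total <- matrix(100L, 1, m)
    alt <- matrix(as.integer(100 * vaf), 1, m)
    counts <- make_counts(alt, total)
    pri <- locus_priors(1 / 3, 1 / 3, 1 / 3, locus_ids = counts$locus_ids)
    omega_matrix(counts, pri, err)$row_score
  }
  # a pure wild-type profile: VAF 1/2 would be uninformative under uniform
  # genotype priors (singlet het mass 1/3 equals doublet mass at f = 1/2)
  s_singlet <- vapply(c(5, 20, 80), score_at_m, numeric(1), vaf = 0)
  expect_true(all(diff(s_singlet) < 0))
  expect_lt(s_singlet[3], -50)
  s_doublet <- vapply(c(5, 20, 80), score_at_m, numeric(1), vaf = 0.25)
  expect_true(all(diff(s_doublet) > 0))
  expect_gt(s_doublet[3], 50)
})

test_that("read_counts validates shapes, labels and count ordering", {
  total <- matrix(10L, 2, 2, dimnames = list(c("a", "b"), c("X", "Y")))
  alt_bad <- matrix(c(3L, 11L, 0L, 0L), 2, 2, dimnames = dimnames(total))
  expect_error(read_counts(alt_bad, total), "alt > total at droplet 'b'")
  alt_perm <- matrix(c(1L, 2L, 3L, 4L), 2, 2,
                     dimnames = list(c("b", "a"), c("Y", "X")))
  rc <- read_counts(alt_perm, total)
  expect_equal(rc$alt["a", "X"], alt_perm["a", "X"])
  expect_equal(rc$droplet_ids, c("a", "b"))
  alt_other <- matrix(0L, 2, 2, dimnames = list(c("a", "b"), c("X", "Z")))
  expect_error(read_counts(alt_other, total), "different labels")
})
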