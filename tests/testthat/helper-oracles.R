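# Independent linear-space oracles used to validate the log-space
# implementation. They deliberately share no code with the package: the
# beta-binomial pmf is computed via rising-factorial products, dropout is
# enumerated over explicit per-copy retention patterns, and sums run in
# linear space.

oracle_bb_pmf <- function(v, c, p, s) {
  a <- p * s
  b <- (1 - p) * s
  num1 <- if (v > 0) prod(a + 0:(v - 1)) else 1
  num2 <- if (c - v > 0) prod(b + 0:(c - v - 1)) else 1
  den <- if (c > 0) prod(a + b + 0:(c - 1)) else 1
  choose(c, v) * num1 * num2 / den
}

oracle_droplet_locus_lik <- function(v, c, z, mu, beta, afp, afn, s) {
  if (c == 0) return(1)
  sig_s <- c(0, 1 / 2, 1)
  sig <- if (z == 1) c(0, 1 / 4, 1 / 2, 3 / 4, 1) else sig_s
  px <- if (z == 0) {
    mu
  } else {
    out <- numeric(5)
    for (g in 1:3) {
      for (h in 1:3) {
        f <- (sig_s[g] + sig_s[h]) / 2
        k <- which(abs(sig - f) < 1e-12)
        out[k] <- out[k] + mu[g] * mu[h]
      }
    }
    out
  }
  n_cop <- 2 * z + 2
  total <- 0
  for (ix in seq_along(sig)) {
    n_var <- round(sig[ix] * n_cop)
    n_ref <- n_cop - n_var
    for (code in 0:(2^n_cop - 1)) {
      keep <- as.integer(intToBits(code))[seq_len(n_cop)]
      kv <- if (n_var > 0) sum(keep[seq_len(n_var)]) else 0
      kr <- if (n_ref > 0) sum(keep[n_var + seq_len(n_ref)]) else 0
      if (kv + kr == 0) next
      pr_keep <- prod(ifelse(keep == 1, 1 - beta, beta)) / (1 - beta^n_cop)
      y <- kv / (kv + kr)
      p <- min(max(afp + (1 - afp - afn) * y, 1e-9), 1 - 1e-9)
      total <- total + px[ix] * pr_keep * oracle_bb_pmf(v, c, p, s)
    }
  }
  total
}

# Exhaustive maximization of the linearized log-posterior over all 2^n
# doublet assignments.
oracle_best_assignment <- function(omega, delta) {
  n <- nrow(omega)
  log_odds <- log(delta / (1 - delta))
  best <- NULL
  best_j <- -Inf
  for (code in 0:(2^n - 1)) {
    z <- as.integer(intToBits(code))[seq_len(n)]
    j <- sum(z * (rowSums(omega) + log_odds))
    if (j > best_j) {
      best_j <- j
      best <- z
    }
  }
  list(z = best, objective = best_j)
}

# Tiny labelled read_counts fixture
make_counts <- function(alt, total, n = nrow(total), m = ncol(total)) {
  dn <- list(paste0("d", seq_len(nrow(total))),
             paste0("L", seq_len(ncol(total))))
  dimnames(alt) <- dn
  dimnames(total) <- dn
  read_counts(alt, total)
}
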