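# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# brute-force reverse complement (table lookup + rev), independent of
# Biostrings
oracle_revcomp <- function(seq) {
  if (nchar(seq) == 0L) return("")
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  paste(rev(comp[strsplit(seq, "")[[1L]]]), collapse = "")
}

random_dna <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# brute-force dispersity from the expanded raw list (multiplicity handling
# oracle): plain definitional formulas on the unrolled sample
oracle_dispersity <- function(values, multiplicities) {
  x <- rep(values, times = multiplicities)
  Ln <- sum(x) / length(x)
  Lw <- sum(x^2) / sum(x)
  sigma <- sqrt(sum((x - Ln)^2) / length(x))
  list(Ln = Ln, Lw = Lw, sigma = sigma, PDI = Lw / Ln)
}

# sample n draws from a zero-truncated Poisson(lambda) by rejection
rztpois <- function(n, lambda) {
  out <- integer(0)
  while (length(out) < n) {
    x <- stats::rpois(2L * n + 10L, lambda)
    out <- c(out, x[x > 0L])
  }
  out[seq_len(n)]
}

# Monte Carlo two-sample-free KS p-value of integer data against a discrete
# CDF: compares the observed sup-distance with the null distribution of the
# statistic under genuine draws from `rfun`
mc_ks_pvalue <- function(x, cdf, rfun, B = 199L) {
  ks_stat <- function(v) {
    kk <- 0:max(v)
    ec <- stats::ecdf(v)(kk)
    max(abs(ec - cdf(kk)))
  }
  d_obs <- ks_stat(x)
  d_null <- replicate(B, ks_stat(rfun(length(x))))
  (1 + sum(d_null >= d_obs)) / (B + 1)
}

# Monte Carlo RMSF oracle: i.i.d. sampling of hinge bend angles (each an
# independent Gaussian under the quadratic bending energy), chain
# reconstruction from angles, and least-squares rigid-body removal. A route
# through the model deliberately different from the stiffness-matrix
# pseudo-inverse used by compute_rmsf().
oracle_mc_rmsf <- function(rod, n_samp = 40000L, seed = 1L) {
  l <- rod$element_len
  B <- rod$element_bend
  N <- length(l) + 1L
  kBT <- rod$params$kBT
  Bh <- 2 / (1 / B[-length(B)] + 1 / B[-1L])
  lbar <- (l[-length(l)] + l[-1L]) / 2
  theta_sd <- sqrt(kBT * lbar / Bh)   # var(theta_i) = kBT / (Bh/lbar)
  withr::with_seed(seed, {
    thetas <- matrix(stats::rnorm(n_samp * (N - 2L), sd = rep(theta_sd, each = n_samp)),
                     nrow = n_samp)
    # slopes per element: s_1 = 0, s_{e+1} = s_e + theta_e
    slopes <- cbind(0, t(apply(thetas, 1L, cumsum)))
    u <- cbind(0, t(apply(sweep(slopes, 2L, l, "*"), 1L, cumsum)))
    # remove rigid-body translation+rotation by unweighted least squares,
    # matching the pseudo-inverse's orthogonal null-space projection
    Q <- qr.Q(qr(cbind(1, rod$node_pos)))
    resid <- u - (u %*% Q) %*% t(Q)
    sqrt(2 * colMeans(resid^2))  # two transverse directions
  })
}

# quick small living population for reuse
tiny_pop <- function(ratio = 2, n = 500, seed = 42)
  simulate_living(ratio, n_initiators = n, seed = seed)
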