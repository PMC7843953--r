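# Independent oracles used across the suite. These deliberately avoid the
# package's own matrix-algebra code paths.

# Path-tracing oracle for the implied twin correlation matrix: every entry
# is accumulated chain by chain (path up to a factor, across a factor
# correlation, down to the other variable), with the cross-twin factor
# correlations 1.0 (MZ) / 0.5 (DZ) for A, 1.0 for C and 0 for E.
path_trace_oracle <- function(paths, rA, rC, rE, zygosity) {
  p <- nrow(paths)
  kA <- if (zygosity == "MZ") 1 else 0.5
  cross <- list(a = kA, c = 1, e = 0)
  within <- list(a = 1, c = 1, e = 1)
  Rf <- list(a = rA, c = rC, e = rE)
  S <- matrix(0, 2 * p, 2 * p)
  for (t1 in 1:2) {
    for (t2 in 1:2) {
      for (i in seq_len(p)) {
        for (j in seq_len(p)) {
          tot <- 0
          for (x in c("a", "c", "e")) {
            k <- if (t1 == t2) within[[x]] else cross[[x]]
            tot <- tot + paths[i, x] * Rf[[x]][i, j] * k * paths[j, x]
          }
          S[(t1 - 1) * p + i, (t2 - 1) * p + j] <- tot
        }
      }
    }
  }
  S
}

# closed-form multivariate Gaussian log-likelihood, written out by hand
gaussian_loglik_oracle <- function(Y, mu, Sigma) {
  d <- ncol(Y)
  Sinv <- solve(Sigma)
  ld <- determinant(Sigma, logarithm = TRUE)$modulus[1]
  tot <- 0
  for (i in seq_len(nrow(Y))) {
    r <- Y[i, ] - mu
    tot <- tot - 0.5 * (d * log(2 * pi) + ld + drop(t(r) %*% Sinv %*% r))
  }
  tot
}

# a random valid correlated-factors model (p traits)
random_cf_model <- function(p = 2) {
  shares <- matrix(stats::runif(p * 3, 0.05, 1), p, 3)
  shares <- shares / rowSums(shares)
  paths <- sqrt(shares)
  colnames(paths) <- c("a", "c", "e")
  rnd_r <- function() {
    R <- diag(1, p)
    if (p == 2) R[1, 2] <- R[2, 1] <- stats::runif(1, -0.7, 0.7)
    R
  }
  list(paths = paths, rA = rnd_r(), rC = rnd_r(), rE = rnd_r())
}

# the study-condition generating values for the baseline-wave bivariate
# model (continuous OCS total, binary suicide attempt at 6% prevalence)
table5_config <- function(n_mz, n_dz, seed = 1, ...) {
  sim_config(
    n_mz, n_dz,
    traits = list(
      trait_spec("ocs", "continuous", a2 = 0.37, e2 = 0.63),
      trait_spec("att", "binary", a2 = 0.61, e2 = 0.39, prevalence = 0.06)
    ),
    rA = 0.42, rE = 0.13, seed = seed, unknown_zygosity_rate = 0, ...
  )
}

biv_traits <- function() {
  rbind(model_trait("ocs", "continuous"), model_trait("att", "binary"))
}
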