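make_binary_pairs <- function(y1, y2, zyg = "MZ") {
  n <- length(y1)
  tibble::tibble(
    family_id = rep(sprintf("f%04d", seq_len(n)), each = 2),
    twin_index = rep(1:2, n),
    zygosity = zyg, sex = 0, age = 18, wave = 18,
    att = as.numeric(rbind(y1, y2))
  )
}

test_that("a 50% binary trait with no twin correlation gives N log(1/2)", {
  # threshold 0 and pure-E paths: every individual is an independent coin
  y <- rep(c(0, 1), length.out = 40)
  dat <- dplyr::bind_rows(
    make_binary_pairs(y[1:20], y[21:40], "MZ"),
    make_binary_pairs(y[21:40], y[1:20], "DZ")
  )
  dat$family_id <- paste0(dat$zygosity, dat$family_id)
  m <- ace_model(model_trait("att", "binary"),
    values = list(paths = matrix(c(0, 0, 1), 1, 3, dimnames = list("att", c("a", "c", "e"))))
  )
  m$values$thresholds$att <- 0
  expect_equal(fiml_loglik(dat, m), 80 * log(0.5), tolerance = 1e-9)
})

test_that("independent bivariate binary traits factorise into univariate likelihoods", {
  set.seed(41)
  n <- 60
  d1 <- rbinom(n, 1, 0.3); d2 <- rbinom(n, 1, 0.3)
  e1 <- rbinom(n, 1, 0.6); e2 <- rbinom(n, 1, 0.6)
  base <- tibble::tibble(
    family_id = rep(sprintf("f%03d", 1:n), each = 2),
    twin_index = rep(1:2, n),
    zygosity = rep(c("MZ", "DZ"), length.out = 2 * n),
    sex = 0, age = 18, wave = 18
  )
  base$zygosity <- rep(rep(c("MZ", "DZ"), each = 2), length.out = 2 * n)
  dat <- base
  dat$u <- as.numeric(rbind(d1, d2))
  dat$v <- as.numeric(rbind(e1, e2))
  # pure-E, zero factor correlations: all four margins independent
  mk <- function(traits, paths) {
    m <- ace_model(traits, components = "ACE")
    m$values$paths <- paths
    if (nrow(paths) == 2) {
      m$values$rA <- 0; m$values$rC <- 0; m$values$rE <- 0
    }
    m
  }
  pe <- function(k) matrix(rep(c(0, 0, 1), each = k), k, 3,
    dimnames = list(NULL, c("a", "c", "e"))
  )
  m_uv <- mk(rbind(model_trait("u", "binary"), model_trait("v", "binary")), pe(2))
  m_uv$values$thresholds <- list(u = 0.5, v = -0.2)
  m_u <- mk(model_trait("u", "binary"), pe(1)); m_u$values$thresholds <- list(u = 0.5)
  m_v <- mk(model_trait("v", "binary"), pe(1)); m_v$values$thresholds <- list(v = -0.2)
  expect_equal(
    fiml_loglik(dat, m_uv),
    fiml_loglik(dat, m_u) + fiml_loglik(dat, m_v),
    tolerance = 1e-8
  )
})

test_that("high-dimensional ordinal rectangles agree with a Monte-Carlo oracle", {
  set.seed(42)
  A <- matrix(rnorm(16), 4)
  S <- cov2cor(A %*% t(A) + diag(4) * 3)
  lo <- c(-Inf, -1.2, -0.4, 0.1)
  up <- c(0.3, 0.8, Inf, 1.5)
  draws <- mvtnorm::rmvnorm(1e6, sigma = S)
  inside <- rep(TRUE, 1e6)
  for (j in 1:4) inside <- inside & draws[, j] > lo[j] & draws[, j] <= up[j]
  p_mc <- mean(inside)
  se_mc <- sqrt(p_mc * (1 - p_mc) / 1e6)
  p_miwa <- twinace:::mvn_rect(lo, up, S)
  p_lat <- twinace:::mvn_rect_vec(matrix(lo, 1), matrix(up, 1), S)
  expect_lt(abs(p_miwa - p_mc), max(3 * se_mc, 1e-3))
  expect_lt(abs(p_lat - p_mc), max(3 * se_mc, 1e-3))
})

test_that("continuous-trait FIML equals the hand-written Gaussian log-likelihood", {
  cfg <- sim_config(200, 250,
    traits = list(
      trait_spec("x", "continuous", a2 = .4, c2 = .15, e2 = .45),
      trait_spec("y", "continuous", a2 = .3, e2 = .7)
    ),
    rA = 0.5, rE = 0.2, seed = 51, unknown_zygosity_rate = 0
  )
  sim <- simulate_twin_cohort(cfg)
  m <- ace_model(
    rbind(model_trait("x", "continuous"), model_trait("y", "continuous")),
    components = "ACE",
    values = list(
      paths = cbind(a = sqrt(c(.4, .3)), c = sqrt(c(.15, 0)), e = sqrt(c(.45, .7))),
      rA = 0.5, rC = 0, rE = 0.2
    )
  )
  m$values$means[] <- c(0.05, -0.1)
  m$values$sds[] <- c(1.1, 0.95)
  prep <- twinace:::prepare_pairs(sim, m)
  want <- 0
  for (z in c("MZ", "DZ")) {
    S <- implied_structure(m, z)
    want <- want + gaussian_loglik_oracle(prep[[z]]$Y, twinace:::model_mu(m), unclass(S))
  }
  expect_equal(fiml_loglik(sim, m), want, tolerance = 1e-6)
})

test_that("missing co-twin data marginalises to the univariate contribution", {
  dat <- tibble::tibble(
    family_id = c("f1", "f1", "f2"),
    twin_index = c(1, 2, 1),
    zygosity = "MZ", sex = 0, age = 18, wave = 18,
    y = c(0.5, -0.3, 1.2)
  )
  m <- ace_model(model_trait("y", "continuous"),
    values = list(paths = matrix(sqrt(c(.4, .1, .5)), 1, 3, dimnames = list("y", c("a", "c", "e"))))
  )
  ll <- fiml_loglik(dat, m)
  S <- implied_structure(m, "MZ")
  ll_pair <- mvtnorm::dmvnorm(c(0.5, -0.3), sigma = unclass(S), log = TRUE)
  ll_single <- dnorm(1.2, 0, 1, log = TRUE)
  expect_equal(ll, ll_pair + ll_single, tolerance = 1e-9)
})

test_that("observed categories with numerically zero probability are floored with a warning", {
  dat <- make_binary_pairs(c(1, 0, 0), c(0, 0, 1))
  m <- ace_model(model_trait("att", "binary"),
    values = list(paths = matrix(c(0, 0, 1), 1, 3, dimnames = list("att", c("a", "c", "e"))))
  )
  m$values$thresholds$att <- 10 # P(category 1) below the 1e-12 floor
  expect_warning(ll <- fiml_loglik(dat, m), "near-zero probability")
  expect_true(is.finite(ll))
})

test_that("threshold covariates shift category probabilities as specified", {
  # one MZ pair, female twin 1, male twin 2, pure E so twins independent
  dat <- tibble::tibble(
    family_id = "f1", twin_index = 1:2, zygosity = "MZ",
    sex = c(1, 0), age = 18, wave = 18, att = c(1, 0)
  )
  m <- ace_model(model_trait("att", "binary"),
    use_sex = TRUE,
    values = list(paths = matrix(c(0, 0, 1), 1, 3, dimnames = list("att", c("a", "c", "e"))))
  )
  m$values$thresholds$att <- 1
  m$values$beta_sex["att"] <- 0.8
  # sex is centred at the observed mean (0.5): shifts are +/-0.4
  ll <- fiml_loglik(dat, m)
  want <- log(1 - pnorm(1 - 0.4)) + log(pnorm(1 + 0.4))
  expect_equal(ll, want, tolerance = 1e-9)
})
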