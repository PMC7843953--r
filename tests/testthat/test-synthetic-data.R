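test_that("trait and config validation rejects malformed inputs", {
  expect_error(trait_spec("x", "continuous", a2 = 0.5, e2 = 0.6), "a2 \\+ c2 \\+ e2")
  expect_error(trait_spec("x", "ordinal", a2 = 0.4, e2 = 0.6, thresholds = c(1, 0.5)), "increasing")
  expect_error(trait_spec("x", "binary", a2 = 0.4, e2 = 0.6), "prevalence")
  tr2 <- list(
    trait_spec("a", "continuous", a2 = .4, e2 = .6),
    trait_spec("b", "continuous", a2 = .4, e2 = .6)
  )
  bad <- matrix(c(1, 1.4, 1.4, 1), 2)
  expect_error(sim_config(10, 10, tr2, rA = bad), "positive semi-definite")
  expect_error(sim_config(10, 10, tr2, rA = matrix(c(1, .2, .3, 1), 2)), "symmetric")
  expect_error(sim_config(10, 10, tr2[[1]], wave_retention = 0), "wave_retention")
})

test_that("a non-PSD implied structure is rejected with a diagnostic naming the block", {
  # valid factor-correlation matrices always imply a PSD structure (the
  # factor model is a Gram construction), so corrupt a config after
  # construction to exercise the guard
  tr <- list(
    trait_spec("a", "continuous", a2 = .1, c2 = .8, e2 = .1),
    trait_spec("b", "continuous", a2 = .1, c2 = .8, e2 = .1)
  )
  cfg <- sim_config(50, 50, tr, rA = 0.9, rC = 0, rE = 0.9, seed = 1)
  cfg$rC[1, 2] <- cfg$rC[2, 1] <- -3
  expect_error(simulate_twin_cohort(cfg), "positive semi-definite.*block")
})

test_that("an E-only trait shows no twin resemblance in either zygosity group", {
  cfg <- sim_config(4000, 4000,
    traits = list(trait_spec("y", "continuous", a2 = 0, c2 = 0, e2 = 1)),
    seed = 101, unknown_zygosity_rate = 0
  )
  sim <- simulate_twin_cohort(cfg)
  tc <- twin_correlations(sim, model_trait("y", "continuous"))
  se <- 1 / sqrt(4000) # null correlation SE ~ 1/sqrt(n)
  expect_lt(abs(tc$r[tc$zygosity == "MZ"]), 3 * se)
  expect_lt(abs(tc$r[tc$zygosity == "DZ"]), 3 * se)
})

test_that("cross-twin cross-trait correlation and prevalence match the generating model", {
  cfg <- table5_config(20000, 20000, seed = 7)
  sim <- simulate_twin_cohort(cfg)
  # target MZ cross-twin cross-trait (liability) correlation: rA*a1*a2
  r_target <- 0.42 * sqrt(0.37 * 0.61)
  # observed Pearson between twin-1 OCS and twin-2 attempt status, mapped to
  # the liability scale through the point-biserial factor phi(tau)/sqrt(p(1-p))
  m <- ace_model(biv_traits(), "ACE")
  prep <- twinace:::prepare_pairs(sim, m)
  Y <- prep$MZ$Y
  ok <- complete.cases(Y[, c(1, 4)])
  prev <- mean(c(Y[, 2], Y[, 4]), na.rm = TRUE)
  tau <- qnorm(1 - prev)
  r_pb <- cor(Y[ok, 1], Y[ok, 4])
  r_liab <- r_pb * sqrt(prev * (1 - prev)) / dnorm(tau)
  se <- 1 / sqrt(sum(ok))
  expect_lt(abs(r_liab - r_target), 3 * se / (dnorm(tau) / sqrt(prev * (1 - prev))))
  # prevalence of the binary trait: 6.0%
  prev_se <- sqrt(0.06 * 0.94 / (4 * 20000))
  expect_lt(abs(prev - 0.06), 3 * prev_se)
})

test_that("thresholded prevalence converges to the normal tail mass for ordinal traits", {
  cfg <- sim_config(8000, 8000,
    traits = list(trait_spec("o", "ordinal", a2 = .3, e2 = .7, thresholds = c(-0.5, 1.0))),
    seed = 5, unknown_zygosity_rate = 0
  )
  sim <- simulate_twin_cohort(cfg)
  pr <- prop.table(table(sim$o))
  want <- diff(c(0, pnorm(c(-0.5, 1.0)), 1))
  n <- nrow(sim)
  for (k in 1:3) {
    expect_lt(abs(pr[k] - want[k]), 3 * sqrt(want[k] * (1 - want[k]) / n))
  }
})

test_that("MZ within-pair correlation exceeds DZ when additive genes contribute", {
  for (seed in 1:3) {
    cfg <- sim_config(3000, 3000,
      traits = list(trait_spec("y", "continuous", a2 = .5, c2 = .1, e2 = .4)),
      seed = seed, unknown_zygosity_rate = 0
    )
    tc <- twin_correlations(simulate_twin_cohort(cfg), model_trait("y", "continuous"))
    expect_gt(tc$r[tc$zygosity == "MZ"], tc$r[tc$zygosity == "DZ"])
  }
})

moments_skew <- function(x) mean((x - mean(x))^3) / sd(x)^3

test_that("skewed continuous scores hit their target moments and stay non-negative", {
  cfg <- sim_config(5000, 5000,
    traits = list(trait_spec("bocs", "continuous",
      a2 = .37, e2 = .63,
      mean = 1.82, sd = 2.24, skew = 0.8
    )),
    seed = 3, unknown_zygosity_rate = 0
  )
  sim <- simulate_twin_cohort(cfg)
  expect_true(all(sim$bocs >= 0))
  expect_lt(abs(mean(sim$bocs) - 1.82), 0.15)
  expect_lt(abs(sd(sim$bocs) - 2.24), 0.3)
  expect_gt(moments_skew(sim$bocs), 0.5) # clearly right-skewed
})

test_that("generation is reproducible under a fixed seed and flags unknown zygosity", {
  cfg <- sim_config(500, 1000,
    traits = list(trait_spec("y", "continuous", a2 = .4, e2 = .6)),
    seed = 99, unknown_zygosity_rate = 0.04
  )
  s1 <- simulate_twin_cohort(cfg)
  s2 <- simulate_twin_cohort(cfg)
  expect_identical(s1, s2)
  fr <- mean(tapply(s1$zygosity, s1$family_id, `[`, 1) == "unknown")
  expect_lt(abs(fr - 0.04), 3 * sqrt(0.04 * 0.96 / 1500))
})

test_that("covariate effects shift the liability before thresholding", {
  cfg <- sim_config(6000, 6000,
    traits = list(trait_spec("att", "binary",
      a2 = .4, e2 = .6,
      prevalence = 0.2, sex_effect = 0.6
    )),
    seed = 21, unknown_zygosity_rate = 0
  )
  sim <- simulate_twin_cohort(cfg)
  p_f <- mean(sim$att[sim$sex == 1])
  p_m <- mean(sim$att[sim$sex == 0])
  expect_gt(p_f, p_m + 0.05)
})

test_that("attrition is pairwise, binomial in rate, reproducible, and a no-op at retention 1", {
  cfg <- sim_config(5000, 5000,
    traits = list(
      trait_spec("y18", "continuous", a2 = .4, e2 = .6, wave = 18),
      trait_spec("y24", "continuous", a2 = .4, e2 = .6, wave = 24)
    ),
    seed = 11, unknown_zygosity_rate = 0
  )
  sim <- simulate_twin_cohort(cfg)
  expect_identical(apply_attrition(sim, 1), sim)
  thinned <- apply_attrition(sim, 0.5, seed = 42)
  expect_identical(apply_attrition(sim, 0.5, seed = 42), thinned)
  # wave-18 untouched
  expect_identical(thinned[thinned$wave == 18, ], sim[sim$wave == 18, ])
  # whole pairs dropped together at wave 24
  n24 <- table(thinned$family_id[thinned$wave == 24])
  expect_true(all(n24 == 2))
  # retained pair count ~ Binomial(10000, 0.5)
  expect_lt(abs(length(n24) - 5000), 3 * sqrt(10000 * 0.25))
})

test_that("twin CSV round-trips bit-exactly and YAML configs load", {
  cfg <- sim_config(30, 60,
    traits = list(
      trait_spec("ocs", "continuous", a2 = .37, e2 = .63),
      trait_spec("att", "binary", a2 = .61, e2 = .39, prevalence = .06)
    ),
    seed = 2
  )
  sim <- simulate_twin_cohort(cfg)
  f <- tempfile(fileext = ".csv")
  write_twin_csv(sim, f)
  back <- read_twin_csv(f)
  expect_equal(as.data.frame(back), as.data.frame(sim[, names(back)]))

  yml <- tempfile(fileext = ".yaml")
  writeLines(c(
    "n_mz_pairs: 10",
    "n_dz_pairs: 20",
    "seed: 3",
    "traits:",
    "  - name: y",
    "    kind: binary",
    "    a2: 0.5",
    "    e2: 0.5",
    "    prevalence: 0.1"
  ), yml)
  cfg2 <- read_sim_config(yml)
  expect_s3_class(cfg2, "sim_config")
  expect_equal(cfg2$traits[[1]]$thresholds, qnorm(0.9))
})
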