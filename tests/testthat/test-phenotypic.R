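test_that("log-standardisation is a z-score of ln(x+1) and preserves order", {
  set.seed(71)
  x <- rpois(500, 2)
  x[c(3, 10)] <- NA
  z <- log_standardize(x)
  expect_equal(mean(z, na.rm = TRUE), 0, tolerance = 1e-10)
  expect_equal(sd(z, na.rm = TRUE), 1, tolerance = 1e-10)
  ok <- !is.na(x)
  expect_true(all(diff(z[ok][order(x[ok])]) >= 0))
  expect_error(log_standardize(rep(2, 10)), "zero variance")
  expect_error(log_standardize(c(-1, 2)), "non-negative")
})

test_that("the suicidality composite follows OR truth-table semantics with missingness", {
  i <- c(0, 1, 0, 1, NA, NA, 0, NA)
  a <- c(0, 0, 1, 1, 1, 0, NA, NA)
  expect_equal(
    composite_suicidality(i, a),
    c(0L, 1L, 1L, 1L, 1L, NA, NA, NA)
  )
  expect_error(composite_suicidality(c(0, 2), c(0, 0)), "only 0, 1 or NA")
})

test_that("tetrachoric is zero under independence and symmetric under transpose", {
  tab <- outer(c(600, 400), c(700, 300)) / 1000 # exactly proportional cells
  expect_equal(as.numeric(tetrachoric(tab)), 0, tolerance = 1e-6)
  set.seed(72)
  tab2 <- matrix(c(312, 91, 144, 453), 2)
  expect_equal(
    as.numeric(tetrachoric(tab2)),
    as.numeric(tetrachoric(t(tab2))),
    tolerance = 1e-7
  )
})

test_that("tetrachoric recovers the latent correlation of BVN-integrated cells", {
  # cells computed by an independent bivariate-normal integrator across a
  # grid of correlations and thresholds
  for (rho in c(-0.8, -0.4, 0, 0.4, 0.8)) {
    for (t1 in c(-1, 0, 1)) {
      for (t2 in c(-1, 0, 1)) {
        R <- matrix(c(1, rho, rho, 1), 2)
        p00 <- mvtnorm::pmvnorm(upper = c(t1, t2), corr = R)[1]
        p01 <- pnorm(t1) - p00
        p10 <- pnorm(t2) - p00
        p11 <- 1 - p00 - p01 - p10
        tab <- 1e6 * matrix(c(p00, p10, p01, p11), 2)
        expect_equal(as.numeric(tetrachoric(tab)), rho, tolerance = 1e-3)
      }
    }
  }
})

test_that("an empty cell drives the tetrachoric to a flagged boundary", {
  tab <- matrix(c(50, 10, 0, 40), 2)
  r <- tetrachoric(tab)
  expect_equal(abs(as.numeric(r)), 1)
  expect_true(attr(r, "boundary"))
  expect_error(tetrachoric(matrix(c(0, 0, 5, 5), 2)), "margins")
})

test_that("tetrachoric PCA recovers a planted four-factor block structure", {
  set.seed(73)
  n <- 4000
  F <- matrix(rnorm(n * 4), n, 4)
  items <- matrix(0L, n, 12)
  for (j in 1:12) {
    f <- (j - 1) %/% 3 + 1
    liab <- 0.7 * F[, f] + sqrt(1 - 0.49) * rnorm(n)
    items[, j] <- as.integer(liab > qnorm(0.7))
  }
  colnames(items) <- paste0("item", 1:12)
  pca <- pca_tetrachoric(items, n_factors = 4)
  # the four signal eigenvalues dominate the rest
  expect_gt(min(pca$eigenvalues[1:4]), max(pca$eigenvalues[5:12]))
  # varimax loadings: each item loads strongest on its own block's factor
  assign <- apply(abs(pca$rotated), 1, which.max)
  blocks <- rep(1:4, each = 3)
  expect_true(all(tapply(assign, blocks, function(x) length(unique(x)) == 1)))
  expect_equal(length(unique(tapply(assign, blocks, `[`, 1))), 4)
})

test_that("single-factor items put most variance on the first component", {
  set.seed(74)
  n <- 3000
  f <- rnorm(n)
  items <- sapply(1:6, function(j) as.integer(0.7 * f + rnorm(n) * 0.71 > 0))
  colnames(items) <- paste0("i", 1:6)
  pca <- pca_tetrachoric(items, n_factors = 2)
  expect_gt(pca$eigenvalues[1], sum(pca$eigenvalues[-1]))
})

test_that("zero-variance items are dropped with a warning", {
  set.seed(75)
  items <- cbind(a = rbinom(200, 1, .5), b = rbinom(200, 1, .5), c = 0L)
  expect_warning(R <- tetrachoric_matrix(items), "zero-variance")
  expect_equal(ncol(R), 2)
})

sim_logistic_twins <- function(n_pairs, beta = 0, icc_liab = 0.5, seed = 1,
                               prevalence = 0.2) {
  withr::with_seed(seed, {
    u <- rnorm(n_pairs) # shared family effect
    x <- rnorm(2 * n_pairs)
    fam <- rep(seq_len(n_pairs), each = 2)
    eta <- qlogis(prevalence) + beta * x + sqrt(icc_liab) * 2 * u[fam]
    y <- rbinom(2 * n_pairs, 1, plogis(eta))
    tibble::tibble(
      family_id = sprintf("f%05d", fam), twin_index = rep(1:2, n_pairs),
      age = 18, sex = rep(rbinom(n_pairs, 1, .5), each = 2), x = x, y = y
    )
  })
}

test_that("cluster-robust logistic regression is calibrated under the null", {
  d <- sim_logistic_twins(5000, beta = 0, seed = 81)
  res <- cluster_robust_logistic(d, "y", "x")
  row <- res[res$term == "x", ]
  expect_lt(abs(row$estimate), 3 * row$robust_se)
  # type-I error across replicates stays near the nominal 5%
  hits <- 0L
  for (s in 1:200) {
    d <- sim_logistic_twins(5000, beta = 0, seed = 1000 + s)
    res <- cluster_robust_logistic(d, "y", "x")
    if (res$p.value[res$term == "x"] < 0.05) hits <- hits + 1L
  }
  rate <- hits / 200
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / 200))
})

test_that("duplicating rows within clusters changes neither estimates nor robust SEs", {
  d <- sim_logistic_twins(800, beta = 0.5, seed = 82)
  res1 <- cluster_robust_logistic(d, "y", "x")
  dd <- dplyr::bind_rows(d, d)
  res2 <- cluster_robust_logistic(dd, "y", "x")
  expect_equal(res1$estimate, res2$estimate, tolerance = 1e-6)
  expect_equal(res1$robust_se, res2$robust_se, tolerance = 1e-6)
})

test_that("the intercept-only model returns the prevalence odds", {
  set.seed(83)
  n <- 40000
  d <- tibble::tibble(
    family_id = sprintf("f%05d", rep(1:(n / 2), each = 2)),
    twin_index = rep(1:2, n / 2), age = 18, sex = 0,
    y = rbinom(n, 1, 0.06)
  )
  res <- cluster_robust_logistic(d, "y", character(0), covariates = character(0))
  or <- res$odds_ratio[res$term == "(Intercept)"]
  expect_equal(or, 0.06 / 0.94, tolerance = 0.08) # within MC error at n = 40k
})

test_that("cluster-robust SEs exceed naive SEs under within-family correlation", {
  bigger <- 0L
  for (s in 1:50) {
    d <- sim_logistic_twins(400, beta = 0.4, icc_liab = 0.6, seed = 2000 + s)
    fit <- glm(y ~ x + age + sex, binomial(), data = d)
    naive <- sqrt(diag(vcov(fit)))["x"]
    robust <- sqrt(diag(sandwich::vcovCL(fit, cluster = d$family_id)))["x"]
    if (robust > naive) bigger <- bigger + 1L
  }
  expect_gt(bigger, 25)
})

test_that("adjusting for a simulated confounder attenuates the OR monotonically", {
  or_for <- function(strength, seed = 90) {
    withr::with_seed(seed, {
      n <- 6000
      conf <- rnorm(n)
      x <- 0.8 * strength * conf + rnorm(n)
      eta <- -1.5 + 1.2 * strength * conf # outcome driven only by the confounder
      y <- rbinom(n, 1, plogis(eta))
      d <- tibble::tibble(
        family_id = sprintf("f%05d", rep(1:(n / 2), each = 2)),
        twin_index = rep(1:2, n / 2), age = 18, sex = 0,
        x = x, y = y, conf = conf
      )
      un <- cluster_robust_logistic(d, "y", "x", covariates = character(0))
      ad <- cluster_robust_logistic(d, "y", "x", covariates = "conf")
      c(
        un = un$odds_ratio[un$term == "x"],
        ad = ad$odds_ratio[ad$term == "x"]
      )
    })
  }
  ors <- sapply(c(0.4, 0.8, 1.2), or_for)
  # unadjusted OR grows with confounder strength; adjusted stays near 1
  expect_true(all(diff(ors["un", ]) > 0))
  expect_true(all(abs(log(ors["ad", ])) < abs(log(ors["un", ]))))
})

test_that("separation is flagged", {
  d <- tibble::tibble(
    family_id = sprintf("f%03d", rep(1:40, each = 2)),
    twin_index = rep(1:2, 40), age = 18, sex = 0,
    x = rep(c(-2, 2), each = 40)
  )
  d$y <- as.integer(d$x > 0)
  expect_warning(res <- cluster_robust_logistic(d, "y", "x"), "separation")
  expect_true(attr(res, "separation"))
})

test_that("formatted OR tables carry CI strings and significance stars", {
  d <- sim_logistic_twins(2000, beta = 0.8, seed = 84)
  res <- cluster_robust_logistic(d, "y", "x")
  ft <- format_or_table(res)
  expect_equal(ft$term, "x")
  expect_match(ft$or_ci, "^\\d+\\.\\d{2} \\(\\d+\\.\\d{2} - \\d+\\.\\d{2}\\)\\*")
})
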