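#' Log-transform and standardise a positively skewed score
#'
#' Questionnaire totals (OCS, depression, anxiety scales) are count-like
#' and positively skewed; they are mapped through `ln(x + 1)` (the offset
#' accommodates zeros) and then z-scored on the non-missing entries so
#' that effects are comparable across scales (mean 0, SD 1).
#'
#' @param values Non-negative numeric vector (may contain `NA`).
#' @return Standardised numeric vector of the same length.
#' @export
log_standardize <- function(values) {
  if (any(values < 0, na.rm = TRUE)) stop("values must be non-negative")
  z <- log1p(values)
  s <- stats::sd(z, na.rm = TRUE)
  if (!is.finite(s) || s < 1e-12) stop("values have zero variance; cannot standardise")
  (z - mean(z, na.rm = TRUE)) / s
}

#' Combine suicidality items into a binary composite
#'
#' OR-combination of a suicidal-ideation item and a suicide-attempt item:
#' an individual scores positive if they endorsed either item. The
#' composite is negative only when both items are observed zero; if one
#' item is missing and the other is zero, endorsement cannot be ruled out
#' and the composite is missing.
#'
#' @param ideation,attempt Vectors in `{0, 1, NA}`.
#' @return Integer vector in `{0, 1, NA}`.
#' @examples
#' composite_suicidality(c(0, 1, 0, NA, NA), c(0, 0, 1, 1, 0))
#' @export
composite_suicidality <- function(ideation, attempt) {
  chk <- function(x, lab) {
    if (!all(x %in% c(0, 1, NA))) stop("`", lab, "` must contain only 0, 1 or NA")
  }
  chk(ideation, "ideation"); chk(attempt, "attempt")
  as.integer(as.logical(ideation) | as.logical(attempt))
}

#' Tetrachoric correlation from a 2x2 table
#'
#' Maximum-likelihood estimate of the correlation of a latent bivariate
#' normal assumed to underlie two binary items: thresholds are fixed from
#' the margins, then the correlation is found by a one-dimensional search
#' on the multinomial likelihood of the four cells (Brent, tolerance
#' 1e-8). An empty cell drives the estimate to the boundary; it is
#' returned at +/-1 with attribute `boundary = TRUE`.
#'
#' @param tab A 2x2 table of counts (rows = item 1 absent/present,
#'   columns = item 2 absent/present), or a matrix coercible to one.
#' @return The correlation estimate, with attributes `thresholds` and
#'   `boundary`.
#' @export
tetrachoric <- function(tab) {
  tab <- as.matrix(tab)
  stopifnot(all(dim(tab) == 2), all(tab >= 0))
  n <- sum(tab)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("both margins of the 2x2 table must be positive")
  }
  p1 <- sum(tab[2, ]) / n # P(item1 = 1)
  p2 <- sum(tab[, 2]) / n
  t1 <- stats::qnorm(1 - p1)
  t2 <- stats::qnorm(1 - p2)
  if (any(tab == 0)) {
    rho <- if (tab[1, 2] == 0 || tab[2, 1] == 0) 1 else -1
    return(structure(rho, thresholds = c(t1, t2), boundary = TRUE))
  }
  nll <- function(rho) {
    p00 <- pbvnorm(t1, t2, rho)
    p01 <- stats::pnorm(t1) - p00
    p10 <- stats::pnorm(t2) - p00
    p11 <- 1 - p00 - p01 - p10
    pr <- pmax(c(p00, p01, p10, p11), 1e-12)
    -sum(c(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2]) * log(pr))
  }
  opt <- stats::optimize(nll, interval = c(-0.9999, 0.9999), tol = 1e-8)
  structure(opt$minimum, thresholds = c(t1, t2), boundary = FALSE)
}

#' Pairwise tetrachoric correlation matrix
#'
#' Computes [tetrachoric()] for every pair of binary item columns, using
#' pairwise-complete observations. Items with zero variance are dropped
#' with a warning.
#'
#' @param items A data frame or matrix of binary items (0/1/NA).
#' @return A symmetric correlation matrix with unit diagonal; attribute
#'   `n_pairwise` holds the per-pair sample sizes.
#' @export
tetrachoric_matrix <- function(items) {
  X <- as.matrix(items)
  keep <- apply(X, 2, function(x) stats::var(x, na.rm = TRUE) > 0)
  if (any(!keep)) {
    warning("dropping zero-variance item(s): ", paste(colnames(X)[!keep], collapse = ", "))
    X <- X[, keep, drop = FALSE]
  }
  k <- ncol(X)
  R <- diag(1, k)
  N <- matrix(NA_real_, k, k)
  dimnames(R) <- dimnames(N) <- list(colnames(X), colnames(X))
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      ok <- !is.na(X[, i]) & !is.na(X[, j])
      tab <- table(factor(X[ok, i], 0:1), factor(X[ok, j], 0:1))
      R[i, j] <- R[j, i] <- as.numeric(tetrachoric(tab))
      N[i, j] <- N[j, i] <- sum(ok)
    }
  }
  attr(R, "n_pairwise") <- N
  R
}

#' Principal components of a tetrachoric correlation matrix
#'
#' Eigendecomposition of the pairwise tetrachoric matrix of binary items,
#' as used to recover the factor structure of a symptom checklist. A
#' pairwise-assembled matrix need not be positive semi-definite; when it
#' is not, the nearest-PSD repair ([Matrix::nearPD()]) is applied and
#' flagged. Loadings are eigenvectors scaled by the root eigenvalues;
#' a varimax rotation of the retained components is included.
#'
#' @param items Binary item matrix / data frame (0/1/NA).
#' @param n_factors Number of components to retain.
#' @return A list of class `tetra_pca`: `eigenvalues`, `loadings`
#'   (items x n_factors), `rotated` (varimax), `explained` (proportion of
#'   total variance per component), `psd_repaired`, `R`.
#' @export
pca_tetrachoric <- function(items, n_factors = 4) {
  R <- tetrachoric_matrix(items)
  repaired <- FALSE
  ev <- eigen(R, symmetric = TRUE)
  if (min(ev$values) < -1e-8) {
    R <- as.matrix(Matrix::nearPD(R, corr = TRUE)$mat)
    repaired <- TRUE
    ev <- eigen(R, symmetric = TRUE)
  }
  n_factors <- min(n_factors, ncol(R))
  lam <- pmax(ev$values, 0)
  load <- ev$vectors[, seq_len(n_factors), drop = FALSE] %*%
    diag(sqrt(lam[seq_len(n_factors)]), n_factors)
  rownames(load) <- rownames(R)
  colnames(load) <- paste0("PC", seq_len(n_factors))
  rot <- if (n_factors > 1) stats::varimax(load)$loadings[, , drop = FALSE] else load
  structure(
    list(
      eigenvalues = ev$values, loadings = load,
      rotated = unclass(rot), explained = lam / sum(lam),
      psd_repaired = repaired, R = R
    ),
    class = "tetra_pca"
  )
}

#' @export
print.tetra_pca <- function(x, ...) {
  cat(
    "<tetra_pca>", length(x$eigenvalues), "items,",
    ncol(x$loadings), "components retained;",
    sprintf("%.1f%% variance in retained set", 100 * sum(x$explained[seq_len(ncol(x$loadings))])),
    if (x$psd_repaired) "(matrix repaired to nearest PSD)" else "", "\n"
  )
  invisible(x)
}

#' Cluster-robust logistic regression for twin data
#'
#' Maximum-likelihood logistic regression with a sandwich variance
#' aggregated at the family level, accounting for the non-independence of
#' twins within pairs. Odds ratios are exponentiated coefficients with
#' Wald 95% confidence intervals on the cluster-robust standard errors.
#' Rows with missing values in any model variable are dropped listwise
#' (the n used is reported). Quasi-complete separation is detected from
#' extreme fitted probabilities or diverging coefficients and flagged;
#' the affected CIs are not reliable.
#'
#' @param data A data frame (one row per individual).
#' @param outcome Name of the binary outcome column.
#' @param predictors Character vector of predictor columns.
#' @param covariates Character vector of adjustment columns (default age
#'   and sex).
#' @param cluster Name of the cluster id column (default `"family_id"`).
#' @param conf_level Confidence level for the Wald intervals.
#' @return A tibble of class `twin_assoc`: `term`, `estimate` (log-odds),
#'   `robust_se`, `odds_ratio`, `conf.low`, `conf.high`, `statistic`,
#'   `p.value`, plus attributes `n`, `n_clusters`, `separation`.
#' @export
cluster_robust_logistic <- function(data, outcome, predictors,
                                    covariates = c("age", "sex"),
                                    cluster = "family_id",
                                    conf_level = 0.95) {
  vars <- c(outcome, predictors, covariates, cluster)
  missing_cols <- setdiff(vars, names(data))
  if (length(missing_cols)) stop("missing column(s): ", paste(missing_cols, collapse = ", "))
  d <- data[stats::complete.cases(data[, vars]), vars, drop = FALSE]
  if (!all(d[[outcome]] %in% 0:1)) stop("outcome must be binary 0/1")
  rhs <- paste(c(predictors, covariates), collapse = " + ")
  if (rhs == "") rhs <- "1"
  fml <- stats::as.formula(paste(outcome, "~", rhs))
  fit <- stats::glm(fml, family = stats::binomial(), data = d)
  beta <- stats::coef(fit)
  aliased <- is.na(beta)
  beta <- beta[!aliased] # constant/collinear terms are dropped
  separation <- any(abs(beta) > 12) ||
    any(fit$fitted.values > 1 - 1e-8) || any(fit$fitted.values < 1e-8)
  V <- sandwich::vcovCL(fit, cluster = d[[cluster]])
  se <- sqrt(diag(V))[names(beta)]
  zq <- stats::qnorm(1 - (1 - conf_level) / 2)
  z <- beta / se
  out <- tibble::tibble(
    term = names(beta),
    estimate = unname(beta),
    robust_se = unname(se),
    odds_ratio = exp(unname(beta)),
    conf.low = exp(unname(beta - zq * se)),
    conf.high = exp(unname(beta + zq * se)),
    statistic = unname(z),
    p.value = unname(2 * stats::pnorm(-abs(z)))
  )
  class(out) <- c("twin_assoc", class(out))
  attr(out, "n") <- nrow(d)
  attr(out, "n_clusters") <- length(unique(d[[cluster]]))
  attr(out, "separation") <- separation
  attr(out, "outcome") <- outcome
  if (separation) warning("possible separation; robust CIs are unreliable")
  out
}

#' Format an odds-ratio table
#'
#' Renders a [cluster_robust_logistic()] result in the conventional
#' journal layout: OR with the 95% CI in parentheses and significance
#' stars at .05 / .01 / .001.
#'
#' @param x A `twin_assoc` tibble.
#' @param drop_terms Terms to omit (default intercept and covariates).
#' @return A tibble with `term` and a formatted `OR (95% CI)` string.
#' @export
format_or_table <- function(x, drop_terms = c("(Intercept)", "age", "sex")) {
  d <- x[!x$term %in% drop_terms, ]
  stars <- ifelse(d$p.value < .001, "***", ifelse(d$p.value < .01, "**", ifelse(d$p.value < .05, "*", "")))
  tibble::tibble(
    term = d$term,
    or_ci = sprintf("%.2f (%.2f - %.2f)%s", d$odds_ratio, d$conf.low, d$conf.high, stars)
  )
}

#' @export
autoplot.twin_assoc <- function(object, drop_terms = c("(Intercept)", "age", "sex"), ...) {
  d <- object[!object$term %in% drop_terms, ]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$odds_ratio, y = .data$term)) +
    ggplot2::geom_vline(xintercept = 1, linetype = 2, colour = "grey50") +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$conf.low, xmax = .data$conf.high),
      height = 0.15
    ) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "odds ratio (log scale)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Latent-scale correlation between two phenotypes
#'
#' Correlation on the scale the liability models work on: Pearson for two
#' continuous variables; the tetrachoric for two binary variables; and
#' for a continuous-binary pair the point-biserial correlation rescaled
#' to the biserial (latent) scale by `sqrt(p(1-p)) / phi(tau)`.
#'
#' @param x,y Numeric vectors.
#' @param kind_x,kind_y `"continuous"` or `"binary"`.
#' @return Scalar correlation estimate.
#' @export
latent_cor <- function(x, y, kind_x = "continuous", kind_y = "continuous") {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (kind_x != "continuous" && kind_y == "continuous") {
    return(latent_cor(y, x, kind_y, kind_x))
  }
  if (kind_x == "continuous" && kind_y == "continuous") {
    return(stats::cor(x, y))
  }
  if (kind_x == "continuous") {
    p <- mean(y)
    tau <- stats::qnorm(1 - p)
    r_pb <- stats::cor(x, y)
    return(max(min(r_pb * sqrt(p * (1 - p)) / stats::dnorm(tau), 1), -1))
  }
  tab <- table(factor(x, 0:1), factor(y, 0:1))
  as.numeric(tetrachoric(tab))
}

#' Within-pair twin correlations by zygosity
#'
#' Computes, per trait and zygosity group, the correlation between
#' co-twins on the latent scale ([latent_cor()]): the MZ-versus-DZ
#' contrast in these correlations is the raw signal the ACE models
#' formalise.
#'
#' @param data A long twin cohort tibble.
#' @param traits A trait tibble ([model_trait()] rows) naming the columns
#'   and kinds.
#' @return A tibble: `trait`, `zygosity`, `r`, `n_pairs`.
#' @export
twin_correlations <- function(data, traits) {
  if (is.list(traits) && !is.data.frame(traits)) traits <- dplyr::bind_rows(traits)
  model <- ace_model(traits,
    components = "ACE",
    form = if (nrow(traits) <= 2) "cf" else "chol"
  )
  prep <- prepare_pairs(data, model)
  p <- nrow(traits)
  purrr::map_dfr(c("MZ", "DZ"), function(z) {
    Y <- prep[[z]]$Y
    purrr::map_dfr(seq_len(p), function(j) {
      ok <- stats::complete.cases(Y[, c(j, j + p)])
      kind <- if (traits$kind[j] == "continuous") "continuous" else "binary"
      tibble::tibble(
        trait = traits$name[j], zygosity = z,
        r = latent_cor(Y[ok, j], Y[ok, j + p], kind, kind),
        n_pairs = sum(ok)
      )
    })
  })
}
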