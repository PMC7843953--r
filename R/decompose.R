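#' Decompose a phenotypic correlation into A/C/E shares
#'
#' For a bivariate correlated-factors fit, the model-implied phenotypic
#' correlation is the sum of the component covariance channels
#' `rA*a1*a2 + rC*c1*c2 + rE*e1*e2`; each channel's share of the total is
#' reported as a percentage (%A, %C, %E). Percentages can carry the sign
#' of their channel and always sum to 100. Confidence intervals, when
#' requested, are likelihood-based: each percentage is profiled as a
#' function of the parameters.
#'
#' @param fit A converged bivariate correlated-factors `twin_fit`.
#' @param ci Compute profile CIs for rPh and the percentage shares
#'   (slower).
#' @param level Confidence level.
#' @return A one-row tibble of class `twin_decomp`: `rPh`, `rA`, `rC`,
#'   `rE`, `pctA`, `pctC`, `pctE` (and `*_lo`/`*_hi` when `ci = TRUE`).
#' @export
decompose_correlation <- function(fit, ci = FALSE, level = 0.95) {
  stopifnot(inherits(fit, "twin_fit"))
  if (fit$model$form != "cf" || nrow(fit$model$traits) != 2) {
    stop("decomposition needs a bivariate correlated-factors fit")
  }
  if (!fit$converged) stop("decomposition requires a converged fit")
  est <- fit$estimates
  pick <- function(t) est$estimate[match(t, est$term)]
  rPh <- pick("rPh")
  if (abs(rPh) < 1e-8) {
    stop("phenotypic correlation is numerically zero; percentage shares are undefined")
  }
  ace <- fit$model$components == "ACE"
  out <- tibble::tibble(
    rPh = rPh, rA = pick("rA"), rC = if (ace) pick("rC") else NA_real_,
    rE = pick("rE"),
    pctA = pick("pctA"), pctC = if (ace) pick("pctC") else NA_real_,
    pctE = pick("pctE")
  )
  if (ci) {
    for (term in c("rPh", "rA", "rE", "pctA", "pctE", if (ace) c("rC", "pctC"))) {
      pc <- profile_ci(fit, term, level = level)
      out[[paste0(term, "_lo")]] <- pc$lower
      out[[paste0(term, "_hi")]] <- pc$upper
    }
  }
  class(out) <- c("twin_decomp", class(out))
  attr(out, "fit") <- fit
  out
}

#' Trivariate Cholesky model for a prospective association
#'
#' Fits a trivariate Cholesky liability model to three ordered traits —
#' baseline suicidality, baseline OCS, and later suicidality — in which
#' the first two factor sets carry the concurrent baseline association
#' (read off as a correlated-factors solution) and both load forward onto
#' the later outcome as directed Cholesky paths. The unique prospective
#' association between baseline OCS and later suicidality is the
#' covariance channel through the OCS-specific factors (the part not
#' routed through baseline suicidality); its A/(C)/E composition is
#' returned as percentages that sum to 100.
#'
#' @param data A long twin cohort tibble with all three traits.
#' @param traits A 3-row trait tibble ([model_trait()] rows) ordered
#'   (baseline suicidality, baseline OCS, later outcome).
#' @param components `"ACE"` or `"AE"`.
#' @param min_pairs_wave2 Minimum pairs with an observed later-wave
#'   outcome.
#' @param ... Passed to [fit_model()].
#' @return A `twin_fit` with extra elements `$unique` (tibble of unique-
#'   association channels and percentage shares) and `$concurrent`
#'   (correlated-factors reading of the baseline block).
#' @export
fit_trivariate_prospective <- function(data, traits, components = c("AE", "ACE"),
                                       min_pairs_wave2 = 30, ...) {
  components <- match.arg(components)
  if (is.list(traits) && !is.data.frame(traits)) traits <- dplyr::bind_rows(traits)
  stopifnot(nrow(traits) == 3)
  out_name <- traits$name[3]
  out_wave <- traits$wave[3]
  n_w2 <- sum(!is.na(data[[out_name]][data$wave == out_wave]))
  if (n_w2 < 2 * min_pairs_wave2) {
    stop(
      "only ", n_w2, " individuals observed on `", out_name,
      "` at wave ", out_wave, "; need at least ", 2 * min_pairs_wave2, " (pairs x 2)"
    )
  }
  model <- ace_model(traits, components = components, form = "chol")
  fit <- fit_model(data, model, ...)

  L <- std_chol(fit$model$values)
  comps <- if (components == "ACE") c("A", "C", "E") else c("A", "E")
  chan <- vapply(comps, function(X) {
    M <- L[[paste0("L", X)]]
    M[3, 2] * M[2, 2]
  }, 0)
  total <- sum(chan)
  pct <- if (abs(total) > 1e-10) 100 * chan / total else rep(NA_real_, length(chan))
  fit$unique <- tibble::tibble(
    component = comps,
    path_to_outcome = vapply(comps, function(X) L[[paste0("L", X)]][3, 2], 0),
    path_on_ocs = vapply(comps, function(X) L[[paste0("L", X)]][2, 2], 0),
    contribution = chan,
    pct = pct
  )
  est <- fit$estimates
  fit$concurrent <- tibble::tibble(
    component = comps,
    r = vapply(comps, function(X) est$estimate[match(sprintf("r%s_12", X), est$term)], 0)
  )
  fit
}

#' @export
autoplot.twin_decomp <- function(object, ...) {
  comps <- c("A", "C", "E")
  pct <- c(object$pctA, object$pctC, object$pctE)
  keep <- !is.na(pct)
  df <- tibble::tibble(
    component = factor(comps[keep], levels = comps),
    pct = pct[keep]
  )
  ggplot2::ggplot(df, ggplot2::aes(x = "rPh", y = .data$pct, fill = .data$component)) +
    ggplot2::geom_col(width = 0.5) +
    ggplot2::labs(
      x = NULL, y = "% of phenotypic correlation",
      title = sprintf("rPh = %.2f decomposed into A/C/E channels", object$rPh)
    ) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.twin_fit <- function(object, ...) {
  df <- tidy(object)
  df <- df[grepl("^(a2|c2|e2)_", df$term) | df$term %in% c("rA", "rC", "rE"), ]
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$estimate, y = .data$term)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "estimate", y = NULL, title = "Variance shares and factor correlations") +
    ggplot2::theme_minimal()
  if ("conf.low" %in% names(df)) {
    p <- p + ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$conf.low, xmax = .data$conf.high),
      height = 0.2
    )
  }
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
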