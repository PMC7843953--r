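#' Declare a trait for an ACE liability model
#'
#' Describes one phenotype entering a twin model: its column name in the
#' cohort data, whether it is continuous or ordinal (binary is ordinal with
#' two categories), and which assessment wave it was measured at.
#'
#' @param name Column name in the twin dataset.
#' @param kind `"continuous"`, `"binary"` or `"ordinal"`.
#' @param wave Assessment wave tag (default 18).
#' @param n_cat Number of ordered categories (ordinal only; binary = 2).
#' @return A one-row tibble describing the trait.
#' @export
model_trait <- function(name, kind = c("continuous", "binary", "ordinal"),
                        wave = 18, n_cat = 2L) {
  kind <- match.arg(kind)
  if (kind == "binary") n_cat <- 2L
  if (kind == "continuous") n_cat <- NA_integer_
  if (kind == "ordinal" && n_cat < 2) stop("ordinal traits need >= 2 categories")
  tibble::tibble(name = name, kind = kind, wave = wave, n_cat = as.integer(n_cat))
}

#' Specify an ACE (or AE) liability-threshold path model
#'
#' Builds the structural specification for a classical twin model. One or
#' two traits use the correlated-factors form: each trait carries
#' standardised paths a, c, e from its own additive-genetic (A), shared-
#' environment (C) and non-shared-environment (E) factors, with
#' aetiological correlations rA, rC, rE linking the factors of different
#' traits. Three or more traits use a Cholesky form with lower-triangular
#' path matrices. Ordinal traits are modelled on an underlying standard
#' normal liability cut by free thresholds; continuous traits get a free
#' mean and scale.
#'
#' The `values` slot holds parameter values (generating values, starting
#' values, or estimates after fitting): `paths` (p x 3 matrix of a, c, e
#' per trait) or `LA`/`LC`/`LE` (lower-triangular matrices), `rA`, `rC`,
#' `rE`, `thresholds` (named list per ordinal trait), `means` and `sds`
#' (named, continuous traits).
#'
#' @param traits A tibble of traits from [model_trait()] (row-bind several),
#'   or a list of such rows.
#' @param components `"ACE"` or `"AE"` (drops the shared-environment paths).
#' @param form `"cf"` (correlated factors; 1-2 traits) or `"chol"`
#'   (Cholesky; any p). Default picks `"cf"` for p <= 2.
#' @param values Optional list of parameter values (see Details).
#' @param use_age,use_sex Include age/sex as covariates in the threshold
#'   equations of ordinal traits.
#' @return An object of class `ace_model`.
#' @examples
#' m <- ace_model(
#'   rbind(model_trait("ocs", "continuous"), model_trait("attempt", "binary")),
#'   components = "AE"
#' )
#' @export
ace_model <- function(traits, components = c("ACE", "AE"), form = NULL,
                      values = NULL, use_age = FALSE, use_sex = FALSE) {
  components <- match.arg(components)
  if (is.list(traits) && !is.data.frame(traits)) traits <- dplyr::bind_rows(traits)
  p <- nrow(traits)
  if (is.null(form)) form <- if (p <= 2) "cf" else "chol"
  form <- match.arg(form, c("cf", "chol"))
  if (form == "cf" && p > 2) stop("correlated-factors form supports at most 2 traits; use form = \"chol\"")
  if (anyDuplicated(traits$name)) stop("trait names must be unique")
  m <- structure(
    list(
      traits = traits, components = components, form = form,
      use_age = use_age, use_sex = use_sex,
      values = NULL
    ),
    class = "ace_model"
  )
  m$values <- default_values(m)
  if (!is.null(values)) m$values <- utils::modifyList(m$values, values)
  validate_values(m)
  m
}

default_values <- function(model) {
  p <- nrow(model$traits)
  ord <- model$traits$kind != "continuous"
  v <- list()
  if (model$form == "cf") {
    a <- rep(sqrt(0.4), p)
    c_ <- if (model$components == "ACE") rep(sqrt(0.1), p) else rep(0, p)
    e <- sqrt(pmax(1 - a^2 - c_^2, 1e-8))
    v$paths <- cbind(a = a, c = c_, e = e)
    rownames(v$paths) <- model$traits$name
    if (p == 2) {
      v$rA <- 0
      v$rC <- if (model$components == "ACE") 0 else NULL
      v$rE <- 0
    }
  } else {
    sc <- if (model$components == "ACE") c(0.4, 0.1, 0.5) else c(0.4, 0, 0.6)
    mk <- function(s) diag(sqrt(s), p)
    v$LA <- mk(sc[1]); v$LC <- mk(sc[2]); v$LE <- mk(sc[3])
  }
  v$thresholds <- stats::setNames(
    lapply(which(ord), function(i) {
      k <- model$traits$n_cat[i]
      stats::qnorm(seq_len(k - 1) / k)
    }),
    model$traits$name[ord]
  )
  cont <- model$traits$name[!ord]
  v$means <- stats::setNames(rep(0, length(cont)), cont)
  v$sds <- stats::setNames(rep(1, length(cont)), cont)
  if (model$use_age || model$use_sex) {
    v$beta_age <- stats::setNames(rep(0, sum(ord)), model$traits$name[ord])
    v$beta_sex <- stats::setNames(rep(0, sum(ord)), model$traits$name[ord])
  }
  v
}

validate_values <- function(model) {
  v <- model$values
  if (model$form == "cf") {
    ss <- rowSums(v$paths^2)
    if (any(abs(ss - 1) > 1e-6)) {
      stop("standardised paths must satisfy a^2 + c^2 + e^2 = 1 per trait")
    }
    for (r in c("rA", "rC", "rE")) {
      if (!is.null(v[[r]]) && abs(v[[r]]) > 1) stop(r, " must lie in [-1, 1]")
    }
  } else {
    for (Lname in c("LA", "LC", "LE")) {
      L <- v[[Lname]]
      if (any(L[upper.tri(L)] != 0)) stop(Lname, " must be lower-triangular")
    }
  }
  for (th in v$thresholds) {
    if (length(th) > 1 && any(diff(th) <= 0)) stop("thresholds must be strictly increasing")
  }
  invisible(model)
}

#' @export
print.ace_model <- function(x, ...) {
  cat(sprintf(
    "<ace_model> %s, %s form, %d trait(s): %s\n",
    x$components, x$form, nrow(x$traits),
    paste0(x$traits$name, " (", x$traits$kind, ", wave ", x$traits$wave, ")",
      collapse = ", "
    )
  ))
  invisible(x)
}

# liability-scale within-person (P) and cross-twin (B) blocks.
# kA is the additive-genetic cross-twin coefficient: 1 for MZ, 0.5 for DZ.
liability_blocks <- function(model, kA) {
  v <- model$values
  p <- nrow(model$traits)
  if (model$form == "cf") {
    a <- v$paths[, "a"]; c_ <- v$paths[, "c"]; e <- v$paths[, "e"]
    RA <- RC <- RE <- diag(1, p)
    if (p == 2) {
      RA[1, 2] <- RA[2, 1] <- v$rA %||% 0
      RC[1, 2] <- RC[2, 1] <- v$rC %||% 0
      RE[1, 2] <- RE[2, 1] <- v$rE %||% 0
    }
    SA <- outer(a, a) * RA
    SC <- outer(c_, c_) * RC
    SE <- outer(e, e) * RE
  } else {
    SA <- tcrossprod(v$LA)
    SC <- tcrossprod(v$LC)
    SE <- tcrossprod(v$LE)
    # standardise each liability to unit variance; the raw diagonal is
    # kept so the fitter can pin the (likelihood-flat) path scale
    raw <- diag(SA + SC + SE)
    D <- outer(1 / sqrt(raw), 1 / sqrt(raw))
    SA <- SA * D; SC <- SC * D; SE <- SE * D
    out <- list(P = SA + SC + SE, B = kA * SA + SC, SA = SA, SC = SC, SE = SE)
    out$raw_diag <- raw
    return(out)
  }
  list(P = SA + SC + SE, B = kA * SA + SC, SA = SA, SC = SC, SE = SE)
}

# row-standardised Cholesky path matrices (paths on the unit-variance
# liability scale)
std_chol <- function(values) {
  raw <- diag(tcrossprod(values$LA) + tcrossprod(values$LC) + tcrossprod(values$LE))
  d <- 1 / sqrt(raw)
  list(LA = values$LA * d, LC = values$LC * d, LE = values$LE * d)
}

#' Model-implied twin covariance structure
#'
#' Assembles the 2p x 2p model-implied covariance matrix over
#' (twin 1 traits, twin 2 traits) for one zygosity group. On the liability
#' scale the within-person diagonal is 1; the cross-twin additive-genetic
#' block is scaled by 1.0 for MZ pairs and 0.5 for DZ pairs (DZ twins share
#' on average half their segregating genes), the shared-environment block
#' by 1.0 for both, and the non-shared block by 0. Continuous traits are
#' scaled by their model standard deviations.
#'
#' @param model An [ace_model()].
#' @param zygosity `"MZ"` or `"DZ"`.
#' @return A 2p x 2p covariance matrix with dimnames `<trait>.1`,
#'   `<trait>.2` and attribute `"zygosity"`.
#' @examples
#' tr <- rbind(model_trait("ocs", "continuous"), model_trait("att", "binary"))
#' m <- ace_model(tr, components = "AE", values = list(
#'   paths = cbind(a = sqrt(c(.37, .61)), c = c(0, 0), e = sqrt(c(.63, .39))),
#'   rA = 0.42, rE = 0.13
#' ))
#' implied_structure(m, "MZ")
#' @export
implied_structure <- function(model, zygosity = c("MZ", "DZ")) {
  zygosity <- match.arg(zygosity)
  kA <- if (zygosity == "MZ") 1 else 0.5
  bl <- liability_blocks(model, kA)
  R <- rbind(cbind(bl$P, bl$B), cbind(t(bl$B), bl$P))
  # scale continuous traits to their model SDs
  sds <- rep(1, nrow(model$traits))
  cont <- model$traits$kind == "continuous"
  sds[cont] <- model$values$sds[model$traits$name[cont]]
  D <- rep(sds, 2)
  S <- R * outer(D, D)
  nm <- c(paste0(model$traits$name, ".1"), paste0(model$traits$name, ".2"))
  dimnames(S) <- list(nm, nm)
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) {
    bad <- if (min(eigen(bl$P, symmetric = TRUE, only.values = TRUE)$values) < -1e-8) {
      "within-person block"
    } else {
      paste0("cross-twin block (", zygosity, ")")
    }
    stop("model-implied covariance is not positive semi-definite: ", bad)
  }
  attr(S, "zygosity") <- zygosity
  S
}

# model-implied mean vector over (twin1 traits, twin2 traits);
# ordinal liabilities have mean 0, continuous traits their free means
model_mu <- function(model) {
  mu <- rep(0, nrow(model$traits))
  cont <- model$traits$kind == "continuous"
  mu[cont] <- model$values$means[model$traits$name[cont]]
  rep(mu, 2)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
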