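#' Specify a simulated twin trait
#'
#' Defines one phenotype for the synthetic cohort generator. Each trait has
#' liability variance shares `a2` (additive genetic), `c2` (shared
#' environment) and `e2` (non-shared environment), which must sum to 1.
#' Ordinal and binary traits are produced by cutting the standard-normal
#' liability at thresholds; a binary trait may instead state its target
#' `prevalence`, from which the threshold is derived. Continuous traits are
#' reported either as the (standard normal) liability rescaled to
#' `mean`/`sd`, or, when `skew` is given, as an exponential transform of
#' the liability rescaled to the same target moments — emulating the
#' positively skewed, count-like questionnaire totals (e.g. OCS scales)
#' that motivate a log-transform before analysis.
#'
#' @param name Column name in the generated dataset.
#' @param kind `"continuous"`, `"binary"` or `"ordinal"`.
#' @param a2,c2,e2 Liability variance shares in \[0, 1\], summing to 1.
#' @param thresholds Strictly increasing liability cut points (ordinal /
#'   binary). For binary traits `prevalence` may be given instead.
#' @param prevalence Target prevalence of the positive category (binary).
#' @param wave Assessment wave the trait is measured at (default 18).
#' @param mean,sd Target observed mean / SD (continuous traits).
#' @param skew Positive scale of the exponential (log-normal) transform for
#'   continuous traits; `NULL` for no skew.
#' @param sex_effect,age_effect Linear effects of (centred) sex and age on
#'   the liability, applied before thresholding.
#' @return A `trait_spec` list.
#' @export
trait_spec <- function(name, kind = c("continuous", "binary", "ordinal"),
                       a2, c2 = 0, e2, thresholds = NULL, prevalence = NULL,
                       wave = 18, mean = 0, sd = 1, skew = NULL,
                       sex_effect = 0, age_effect = 0) {
  kind <- match.arg(kind)
  if (abs(a2 + c2 + e2 - 1) > 1e-10) {
    stop("variance shares must satisfy a2 + c2 + e2 = 1 (got ", a2 + c2 + e2, ")")
  }
  if (any(c(a2, c2, e2) < 0)) stop("variance shares must be non-negative")
  if (kind == "binary" && is.null(thresholds)) {
    if (is.null(prevalence)) stop("binary traits need `thresholds` or `prevalence`")
    thresholds <- stats::qnorm(1 - prevalence)
  }
  if (kind == "ordinal" && is.null(thresholds)) stop("ordinal traits need `thresholds`")
  if (!is.null(thresholds) && length(thresholds) > 1 && any(diff(thresholds) <= 0)) {
    stop("thresholds must be strictly increasing")
  }
  structure(
    list(
      name = name, kind = kind, a2 = a2, c2 = c2, e2 = e2,
      thresholds = thresholds, wave = wave, mean = mean, sd = sd,
      skew = skew, sex_effect = sex_effect, age_effect = age_effect
    ),
    class = "trait_spec"
  )
}

#' Configure a synthetic twin cohort
#'
#' Collects everything the generator needs: pair counts by zygosity, trait
#' specifications, aetiological correlations between traits' A, C and E
#' factors, covariate distributions and bookkeeping rates. Defaults mirror
#' a Swedish young-adult twin register wave: roughly 30% MZ / 66% DZ pairs
#' with a small unknown-zygosity fraction, a slight female majority, and
#' assessment around age 18.
#'
#' @param n_mz_pairs,n_dz_pairs Numbers of monozygotic / dizygotic pairs.
#' @param traits List of [trait_spec()] objects.
#' @param rA,rC,rE Aetiological correlation matrices between traits
#'   (p x p, symmetric, unit diagonal), or a single scalar for the
#'   off-diagonal when p = 2. Defaults: no cross-trait correlation.
#' @param seed Integer seed; all randomness in the generator derives from it.
#' @param wave_retention Probability that a pair is retained at the later
#'   wave (pairwise attrition); 1 keeps everyone.
#' @param sex_ratio Probability an individual is female (MZ co-twins share
#'   sex; DZ pairs are pooled with independent sexes).
#' @param age_mean,age_sd Age distribution (years) at the first wave; later
#'   waves add the wave difference.
#' @param unknown_zygosity_rate Fraction of families whose zygosity is
#'   recorded as `"unknown"` (excluded by model-fitting stages).
#' @param missing_rate Independent per-item missingness probability within
#'   retained rows (exercises FIML).
#' @return A `sim_config` list, validated.
#' @export
sim_config <- function(n_mz_pairs, n_dz_pairs, traits,
                       rA = NULL, rC = NULL, rE = NULL, seed = 1L,
                       wave_retention = 1, sex_ratio = 0.59,
                       age_mean = 18.5, age_sd = 0.4,
                       unknown_zygosity_rate = 0.03, missing_rate = 0) {
  if (inherits(traits, "trait_spec")) traits <- list(traits)
  p <- length(traits)
  as_corr <- function(x, label) {
    if (is.null(x)) x <- diag(1, p)
    if (length(x) == 1 && p == 2 && !is.matrix(x)) {
      x <- matrix(c(1, x, x, 1), 2, 2)
    }
    if (!is.matrix(x) || any(dim(x) != p)) stop(label, " must be a ", p, "x", p, " matrix")
    if (any(abs(x - t(x)) > 1e-12)) stop(label, " must be symmetric")
    if (any(abs(diag(x) - 1) > 1e-12)) stop(label, " must have unit diagonal")
    if (min(eigen(x, symmetric = TRUE, only.values = TRUE)$values) < -1e-10) {
      stop(label, " must be positive semi-definite")
    }
    x
  }
  cfg <- structure(
    list(
      n_mz_pairs = as.integer(n_mz_pairs), n_dz_pairs = as.integer(n_dz_pairs),
      traits = traits,
      rA = as_corr(rA, "rA"), rC = as_corr(rC, "rC"), rE = as_corr(rE, "rE"),
      seed = as.integer(seed), wave_retention = wave_retention,
      sex_ratio = sex_ratio, age_mean = age_mean, age_sd = age_sd,
      unknown_zygosity_rate = unknown_zygosity_rate, missing_rate = missing_rate
    ),
    class = "sim_config"
  )
  if (wave_retention <= 0 || wave_retention > 1) stop("wave_retention must be in (0, 1]")
  cfg
}

# translate a sim_config into an ace_model holding the generating values,
# so the generator and the fitted models share one implied-covariance rule
config_model <- function(config) {
  traits <- dplyr::bind_rows(lapply(config$traits, function(t) {
    model_trait(
      t$name,
      kind = if (t$kind == "continuous") "continuous" else if (length(t$thresholds) == 1) "binary" else "ordinal",
      wave = t$wave,
      n_cat = if (t$kind == "continuous") 2L else length(t$thresholds) + 1L
    )
  }))
  p <- length(config$traits)
  a <- sqrt(vapply(config$traits, `[[`, 0, "a2"))
  c_ <- sqrt(vapply(config$traits, `[[`, 0, "c2"))
  e <- sqrt(vapply(config$traits, `[[`, 0, "e2"))
  if (p <= 2) {
    vals <- list(paths = cbind(a = a, c = c_, e = e))
    if (p == 2) {
      vals$rA <- config$rA[1, 2]; vals$rC <- config$rC[1, 2]; vals$rE <- config$rE[1, 2]
    }
    m <- ace_model(traits, components = "ACE", form = "cf")
    m$values <- utils::modifyList(m$values, vals)
  } else {
    m <- ace_model(traits, components = "ACE", form = "chol")
    m$values$cf_general <- list(
      a = a, c = c_, e = e, RA = config$rA, RC = config$rC, RE = config$rE
    )
  }
  m
}

# liability correlation blocks for arbitrary p with full factor-correlation
# matrices (generator side; the fitted cf form is restricted to p <= 2)
sim_blocks <- function(config, kA) {
  a <- sqrt(vapply(config$traits, `[[`, 0, "a2"))
  c_ <- sqrt(vapply(config$traits, `[[`, 0, "c2"))
  e <- sqrt(vapply(config$traits, `[[`, 0, "e2"))
  SA <- outer(a, a) * config$rA
  SC <- outer(c_, c_) * config$rC
  SE <- outer(e, e) * config$rE
  list(P = SA + SC + SE, B = kA * SA + SC)
}

#' Simulate a twin cohort under a liability ACE model
#'
#' Draws per-pair liabilities from a multivariate normal whose cross-twin
#' additive-genetic block uses coefficient 1.0 for MZ and 0.5 for DZ pairs
#' and whose shared-environment block uses 1.0 for both, then adds
#' covariate effects, thresholds ordinal traits, and rescales (optionally
#' skews) continuous traits. Returns a long-format dataset with one row
#' per individual per wave.
#'
#' @param config A [sim_config()].
#' @return A tibble with columns `family_id`, `twin_index`, `zygosity`
#'   (`MZ`/`DZ`/`unknown`), `sex` (0 male / 1 female), `age`, `wave`, and
#'   one column per trait (traits measured at other waves are `NA`).
#' @examples
#' cfg <- sim_config(
#'   n_mz_pairs = 100, n_dz_pairs = 200,
#'   traits = list(trait_spec("ocs", "continuous", a2 = .37, e2 = .63)),
#'   seed = 42
#' )
#' sim <- simulate_twin_cohort(cfg)
#' @export
simulate_twin_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, simulate_impl(config))
}

simulate_impl <- function(config) {
  p <- length(config$traits)
  tnames <- vapply(config$traits, `[[`, "", "name")
  waves <- sort(unique(vapply(config$traits, `[[`, 0, "wave")))
  n <- c(MZ = config$n_mz_pairs, DZ = config$n_dz_pairs)

  per_zyg <- lapply(c(MZ = "MZ", DZ = "DZ"), function(z) {
    kA <- if (z == "MZ") 1 else 0.5
    bl <- sim_blocks(config, kA)
    S <- rbind(cbind(bl$P, bl$B), cbind(t(bl$B), bl$P))
    ev <- min(eigen(S, symmetric = TRUE, only.values = TRUE)$values)
    if (ev < -1e-10) {
      stop(
        "implied liability correlation matrix for ", z,
        " pairs is not positive semi-definite (min eigenvalue ",
        signif(ev, 3), "); check the cross-twin ", z, " block"
      )
    }
    mvtnorm::rmvnorm(n[[z]], sigma = S, checkSymmetry = FALSE)
  })

  fam_z <- rep(c("MZ", "DZ"), n)
  n_fam <- sum(n)
  fam_id <- sprintf("fam%06d", seq_len(n_fam))
  L <- rbind(per_zyg$MZ, per_zyg$DZ) # n_fam x 2p, twin1 traits then twin2

  # covariates: MZ co-twins share sex; pooled DZ sexes independent
  sex1 <- stats::rbinom(n_fam, 1, config$sex_ratio)
  sex2 <- ifelse(fam_z == "MZ", sex1, stats::rbinom(n_fam, 1, config$sex_ratio))
  age0 <- stats::rnorm(n_fam, config$age_mean, config$age_sd)

  unknown <- stats::runif(n_fam) < config$unknown_zygosity_rate
  zyg_obs <- ifelse(unknown, "unknown", fam_z)

  rows <- list()
  for (w in waves) {
    idx_w <- which(vapply(config$traits, `[[`, 0, "wave") == w)
    age_w <- age0 + (w - waves[1])
    for (twin in 1:2) {
      sex <- if (twin == 1) sex1 else sex2
      df <- tibble::tibble(
        family_id = fam_id, twin_index = twin, zygosity = zyg_obs,
        sex = sex, age = age_w, wave = w
      )
      for (t in tnames) df[[t]] <- NA_real_
      for (j in idx_w) {
        tr <- config$traits[[j]]
        liab <- L[, (twin - 1) * p + j] +
          tr$sex_effect * (sex - config$sex_ratio) +
          tr$age_effect * (age_w - (config$age_mean + (w - waves[1])))
        df[[tr$name]] <- observe_trait(tr, liab)
      }
      rows[[length(rows) + 1]] <- df
    }
  }
  out <- dplyr::arrange(dplyr::bind_rows(rows), .data$wave, .data$family_id, .data$twin_index)

  if (config$missing_rate > 0) {
    for (t in tnames) {
      hit <- !is.na(out[[t]]) & stats::runif(nrow(out)) < config$missing_rate
      out[[t]][hit] <- NA_real_
    }
  }
  if (config$wave_retention < 1 && length(waves) > 1) {
    out <- apply_attrition(out, config$wave_retention,
      seed = config$seed + 1000L, wave = max(waves)
    )
  }
  out
}

# map a liability vector to the observed scale of one trait
observe_trait <- function(tr, liab) {
  if (tr$kind == "continuous") {
    if (is.null(tr$skew)) {
      return(tr$mean + tr$sd * liab)
    }
    # exp-transform scaled by theoretical log-normal moments to hit the
    # target mean/SD; floored at 0 for count-like questionnaire scores
    z <- exp(tr$skew * liab)
    mu <- exp(tr$skew^2 / 2)
    sd <- sqrt((exp(tr$skew^2) - 1) * exp(tr$skew^2))
    return(pmax(tr$mean + tr$sd * (z - mu) / sd, 0))
  }
  as.numeric(findInterval(liab, tr$thresholds))
}

#' Apply pairwise wave attrition
#'
#' Drops the later-wave rows of whole pairs (both twins together) with
#' probability `1 - retention`, leaving earlier waves untouched. Pairwise
#' (rather than individual) dropout is an assumption: registry follow-up
#' response is strongly clustered within families.
#'
#' @param data A twin cohort tibble (see [simulate_twin_cohort()]).
#' @param retention Probability a pair is retained at `wave`, in (0, 1\].
#' @param seed Optional integer seed for reproducible dropout.
#' @param wave The wave subject to attrition (default: the latest present).
#' @return The dataset with dropped rows removed.
#' @export
apply_attrition <- function(data, retention, seed = NULL, wave = NULL) {
  if (retention <= 0 || retention > 1) stop("retention must be in (0, 1]")
  if (retention == 1) return(data)
  if (is.null(wave)) wave <- max(data$wave)
  fams <- unique(data$family_id[data$wave == wave])
  draw <- function() fams[stats::runif(length(fams)) >= retention]
  drop <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  data[!(data$wave == wave & data$family_id %in% drop), , drop = FALSE]
}

#' Read / write a twin cohort as CSV
#'
#' The on-disk format is plain CSV with the fixed leading columns
#' `family_id, twin_index, zygosity, sex, age, wave` followed by one column
#' per trait; zygosity is coded `MZ`/`DZ`/`unknown` and missing phenotypes
#' are empty fields. [read_twin_csv()] restores column types bit-exactly.
#'
#' @param data A twin cohort tibble.
#' @param path File path.
#' @return `write_twin_csv()` returns `path` invisibly; `read_twin_csv()`
#'   returns a tibble.
#' @export
write_twin_csv <- function(data, path) {
  lead <- c("family_id", "twin_index", "zygosity", "sex", "age", "wave")
  stopifnot(all(lead %in% names(data)))
  data <- data[, c(lead, setdiff(names(data), lead))]
  utils::write.csv(data, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' @rdname write_twin_csv
#' @export
read_twin_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "")
  df$twin_index <- as.integer(df$twin_index)
  tibble::as_tibble(df)
}

#' Read a simulation config from YAML
#'
#' Parses a nested key/value file into a [sim_config()]. Top-level keys
#' mirror the `sim_config()` arguments; `traits` is a list of blocks with
#' the [trait_spec()] fields.
#'
#' @param path Path to a YAML file.
#' @return A `sim_config`.
#' @export
read_sim_config <- function(path) {
  y <- yaml::read_yaml(path)
  traits <- lapply(y$traits, function(t) do.call(trait_spec, t))
  y$traits <- traits
  for (r in c("rA", "rC", "rE")) {
    if (!is.null(y[[r]]) && length(y[[r]]) > 1) y[[r]] <- matrix(unlist(y[[r]]), length(traits))
  }
  do.call(sim_config, y)
}
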