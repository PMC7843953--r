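# ---- pair preparation ------------------------------------------------------

# Reshape a long twin dataset to per-pair matrices for one model:
# Y (n_pairs x 2p, twin-1 traits then twin-2 traits), with matching
# age/sex matrices for threshold covariates. Pairs with unknown zygosity
# are dropped (count recorded); rows with no observed trait are dropped.
prepare_pairs <- function(data, model) {
  p <- nrow(model$traits)
  known <- data[data$zygosity %in% c("MZ", "DZ"), , drop = FALSE]
  n_unknown <- length(unique(data$family_id[data$zygosity == "unknown"]))
  missing_tr <- setdiff(model$traits$name, names(data))
  if (length(missing_tr)) {
    stop("data lacks trait column(s): ", paste(missing_tr, collapse = ", "))
  }

  fam_zyg <- known[!duplicated(known$family_id), c("family_id", "zygosity")]
  out <- list()
  for (z in c("MZ", "DZ")) {
    fz <- fam_zyg$family_id[fam_zyg$zygosity == z]
    nf <- length(fz)
    Y <- AGE <- SEX <- matrix(NA_real_, nf, 2 * p)
    for (j in seq_len(p)) {
      w <- model$traits$wave[j]
      nm <- model$traits$name[j]
      sub <- known[known$wave == w, c("family_id", "twin_index", nm, "age", "sex")]
      for (twin in 1:2) {
        s2 <- sub[sub$twin_index == twin, , drop = FALSE]
        idx <- match(s2$family_id, fz)
        keep <- !is.na(idx)
        col <- (twin - 1) * p + j
        Y[idx[keep], col] <- s2[[nm]][keep]
        AGE[idx[keep], col] <- s2$age[keep]
        SEX[idx[keep], col] <- s2$sex[keep]
      }
    }
    keep <- rowSums(!is.na(Y)) > 0
    out[[z]] <- list(
      Y = Y[keep, , drop = FALSE],
      AGE = AGE[keep, , drop = FALSE], SEX = SEX[keep, , drop = FALSE],
      n = sum(keep)
    )
  }
  # centre covariates on the pooled observed means so thresholds keep their
  # marginal interpretation
  all_age <- c(out$MZ$AGE, out$DZ$AGE)
  all_sex <- c(out$MZ$SEX, out$DZ$SEX)
  age_c <- mean(all_age, na.rm = TRUE)
  sex_c <- mean(all_sex, na.rm = TRUE)
  for (z in c("MZ", "DZ")) {
    out[[z]]$AGE <- out[[z]]$AGE - age_c
    out[[z]]$SEX <- out[[z]]$SEX - sex_c
    out[[z]]$AGE[is.na(out[[z]]$AGE)] <- 0
    out[[z]]$SEX[is.na(out[[z]]$SEX)] <- 0
  }
  ord <- model$traits$kind != "continuous"
  for (j in which(ord)) {
    vals <- c(out$MZ$Y[, c(j, j + p)], out$DZ$Y[, c(j, j + p)])
    vals <- vals[!is.na(vals)]
    k <- model$traits$n_cat[j]
    if (length(vals) && (any(vals %% 1 != 0) || any(vals < 0) || any(vals > k - 1))) {
      stop(
        "ordinal trait `", model$traits$name[j],
        "` must be integer-coded 0..", k - 1
      )
    }
  }
  structure(out, n_unknown = n_unknown)
}

# ---- likelihood ------------------------------------------------------------

#' Raw-data full-information likelihood of a twin model
#'
#' Evaluates the log-likelihood of a twin dataset under an [ace_model()]
#' at its current parameter values, summing per-pair contributions over
#' the model-implied 2p-dimensional normal. Ordinal traits contribute
#' multivariate-normal rectangle probabilities between consecutive
#' thresholds (covariate-shifted when the model includes threshold
#' covariates); mixed continuous/ordinal pairs are factored as the
#' continuous marginal Gaussian times the conditional ordinal rectangle;
#' pairs with missing entries marginalise the missing dimensions. Ordinal
#' rectangles use a deterministic quadrature (exact bivariate-normal CDF
#' up to dimension 2, Miwa grid integration above), so repeated
#' evaluations are bit-reproducible.
#'
#' @param data A long twin cohort tibble.
#' @param model An [ace_model()] with parameter values set.
#' @param warn Warn when an observed category has (numerically) zero
#'   probability under the thresholds; its contribution is floored rather
#'   than returning `NaN`.
#' @return The log-likelihood (scalar).
#' @export
fiml_loglik <- function(data, model, warn = TRUE) {
  prep <- prepare_pairs(data, model)
  loglik_prepared(model, prep, warn = warn)
}

loglik_prepared <- function(model, prep, warn = FALSE) {
  ll <- 0
  for (z in c("MZ", "DZ")) {
    dat <- prep[[z]]
    if (dat$n == 0) next
    S <- implied_structure(model, z)
    mu <- model_mu(model)
    ll <- ll + loglik_block(model, dat, S, mu, warn = warn)
  }
  ll
}

loglik_block <- function(model, dat, S, mu, warn = FALSE) {
  p <- nrow(model$traits)
  kinds <- rep(model$traits$kind, 2)
  tnames <- rep(model$traits$name, 2)
  Y <- dat$Y
  n <- nrow(Y)

  # per-column threshold shift (threshold-equation covariates)
  shift <- matrix(0, n, 2 * p)
  if (model$use_age || model$use_sex) {
    for (col in which(kinds != "continuous")) {
      nm <- tnames[col]
      if (model$use_age) shift[, col] <- shift[, col] + model$values$beta_age[[nm]] * dat$AGE[, col]
      if (model$use_sex) shift[, col] <- shift[, col] + model$values$beta_sex[[nm]] * dat$SEX[, col]
    }
  }
  has_shift <- model$use_age || model$use_sex

  obs <- !is.na(Y)
  pat_key <- obs %*% (2^(seq_len(2 * p) - 1))
  total <- 0
  zero_cells <- 0L
  for (key in unique(as.vector(pat_key))) {
    rows <- which(pat_key == key)
    oc <- which(obs[rows[1], ])
    cc <- oc[kinds[oc] == "continuous"]
    oo <- oc[kinds[oc] != "continuous"]
    Yr <- Y[rows, , drop = FALSE]

    ll_rows <- numeric(length(rows))
    if (length(cc)) {
      Yc <- Yr[, cc, drop = FALSE]
      Scc <- S[cc, cc, drop = FALSE]
      ll_rows <- mvtnorm::dmvnorm(Yc, mean = mu[cc], sigma = Scc, log = TRUE, checkSymmetry = FALSE)
    }
    if (length(oo)) {
      # rectangle bounds on the (conditional) ordinal liabilities
      d <- length(oo)
      lo <- up <- matrix(0, length(rows), d)
      for (m in seq_len(d)) {
        col <- oo[m]
        tau <- model$values$thresholds[[tnames[col]]]
        y <- Yr[, col]
        lo[, m] <- c(-Inf, tau)[y + 1] - shift[rows, col]
        up[, m] <- c(tau, Inf)[y + 1] - shift[rows, col]
      }
      if (length(cc)) {
        A <- S[oo, cc, drop = FALSE] %*% solve(S[cc, cc, drop = FALSE])
        condm <- sweep(Yr[, cc, drop = FALSE], 2, mu[cc]) %*% t(A)
        condm <- sweep(condm, 2, mu[oo], `+`)
        Sc <- S[oo, oo, drop = FALSE] - A %*% S[cc, oo, drop = FALSE]
      } else {
        condm <- matrix(mu[oo], length(rows), d, byrow = TRUE)
        Sc <- S[oo, oo, drop = FALSE]
      }
      lo <- lo - condm
      up <- up - condm
      pr <- ord_rect_prob(lo, up, Sc, collapsible = !has_shift && !length(cc))
      zero_cells <- zero_cells + sum(pr < 1e-12)
      ll_rows <- ll_rows + log(pmax(pr, 1e-300))
    }
    total <- total + sum(ll_rows)
  }
  if (warn && zero_cells > 0) {
    warning(zero_cells, " pair(s) fell in cells with near-zero probability; contributions floored")
  }
  total
}

# rectangle probabilities for n centred d-dimensional normal rectangles
# with common covariance Sc; lo/up are n x d matrices. `collapsible`
# marks blocks where rows repeat (pure ordinal, no covariates) so
# higher-dimensional integrals are computed once per distinct cell.
ord_rect_prob <- function(lo, up, Sc, collapsible = FALSE) {
  d <- ncol(lo)
  sd <- sqrt(diag(Sc))
  if (d == 1L) {
    return(pmax(stats::pnorm(up[, 1] / sd) - stats::pnorm(lo[, 1] / sd), 0))
  }
  if (d == 2L) {
    r <- Sc[1, 2] / (sd[1] * sd[2])
    return(pbvnorm_rect(
      lo[, 1] / sd[1], up[, 1] / sd[1],
      lo[, 2] / sd[2], up[, 2] / sd[2], r
    ))
  }
  if (collapsible) {
    # pure-ordinal blocks repeat over a handful of category cells: one
    # high-accuracy deterministic integral (Miwa) per distinct cell
    key <- do.call(paste, c(as.data.frame(lo), as.data.frame(up)))
    first <- !duplicated(key)
    pk <- vapply(which(first), function(i) mvn_rect(lo[i, ], up[i, ], Sc), 0)
    return(pk[match(key, key[first])])
  }
  # pair-specific bounds (continuous conditioning): vectorised lattice rule
  sdm <- matrix(sd, nrow(lo), d, byrow = TRUE)
  mvn_rect_vec(lo / sdm, up / sdm, stats::cov2cor(Sc))
}
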