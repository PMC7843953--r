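# ---- free-parameter packing ------------------------------------------------

# Free parameters use box-constrained transforms that keep every implied
# structure valid: variance shares through spherical angles
# (a = cos phi1, c = sin phi1 cos phi2, e = sin phi1 sin phi2, so
# a^2 + c^2 + e^2 = 1 by construction), factor correlations boxed in
# (-0.999, 0.999), ordinal thresholds as a free first cut plus
# log-increments, and continuous scales on the log scale.
theta_spec <- function(model) {
  nm <- lo <- hi <- character(0)
  add <- function(name, lower, upper) {
    nm <<- c(nm, name); lo <<- c(lo, lower); hi <<- c(hi, upper)
  }
  p <- nrow(model$traits)
  phi_box <- c(0.0125, 1.5583) # keeps every path in ~[0.0125, 0.9999]
  if (model$form == "cf") {
    for (tn in model$traits$name) {
      if (model$components == "ACE") {
        add(paste0("phi1_", tn), phi_box[1], phi_box[2])
        add(paste0("phi2_", tn), phi_box[1], phi_box[2])
      } else {
        add(paste0("phi_", tn), phi_box[1], phi_box[2])
      }
    }
    if (p == 2) {
      add("rA", -0.999, 0.999)
      if (model$components == "ACE") add("rC", -0.999, 0.999)
      add("rE", -0.999, 0.999)
    }
  } else {
    comps <- if (model$components == "ACE") c("A", "C", "E") else c("A", "E")
    for (X in comps) {
      for (i in seq_len(p)) {
        for (j in seq_len(i)) {
          lower <- if (i == j) (if (X == "E") 0.05 else 0) else -3
          add(sprintf("l%s_%d_%d", X, i, j), lower, 3)
        }
      }
    }
  }
  for (i in seq_len(p)) {
    tn <- model$traits$name[i]
    if (model$traits$kind[i] == "continuous") {
      add(paste0("mean_", tn), -10, 10)
      add(paste0("logsd_", tn), -3, 3)
    } else {
      add(paste0("thr_", tn, "_1"), -4.5, 4.5)
      k <- model$traits$n_cat[i]
      if (k > 2) for (m in 2:(k - 1)) add(paste0("lthr_", tn, "_", m), -4, 1.6)
      if (model$use_age) add(paste0("bage_", tn), -2, 2)
      if (model$use_sex) add(paste0("bsex_", tn), -2, 2)
    }
  }
  list(names = nm, lower = as.numeric(lo), upper = as.numeric(hi))
}

unpack_theta <- function(model, theta, spec) {
  names(theta) <- spec$names
  v <- model$values
  p <- nrow(model$traits)
  g <- function(x) unname(theta[x])
  if (model$form == "cf") {
    paths <- matrix(0, p, 3, dimnames = list(model$traits$name, c("a", "c", "e")))
    for (i in seq_len(p)) {
      tn <- model$traits$name[i]
      if (model$components == "ACE") {
        f1 <- g(paste0("phi1_", tn)); f2 <- g(paste0("phi2_", tn))
        paths[i, ] <- c(cos(f1), sin(f1) * cos(f2), sin(f1) * sin(f2))
      } else {
        f <- g(paste0("phi_", tn))
        paths[i, ] <- c(cos(f), 0, sin(f))
      }
    }
    v$paths <- paths
    if (p == 2) {
      v$rA <- g("rA")
      if (model$components == "ACE") v$rC <- g("rC")
      v$rE <- g("rE")
    }
  } else {
    comps <- if (model$components == "ACE") c("A", "C", "E") else c("A", "E")
    for (X in comps) {
      L <- matrix(0, p, p)
      for (i in seq_len(p)) for (j in seq_len(i)) L[i, j] <- g(sprintf("l%s_%d_%d", X, i, j))
      v[[paste0("L", X)]] <- L
    }
    if (model$components == "AE") v$LC <- matrix(0, p, p)
  }
  for (i in seq_len(p)) {
    tn <- model$traits$name[i]
    if (model$traits$kind[i] == "continuous") {
      v$means[tn] <- g(paste0("mean_", tn))
      v$sds[tn] <- exp(g(paste0("logsd_", tn)))
    } else {
      k <- model$traits$n_cat[i]
      tau <- g(paste0("thr_", tn, "_1"))
      if (k > 2) tau <- tau + c(0, cumsum(exp(g(paste0("lthr_", tn, "_", 2:(k - 1))))))
      v$thresholds[[tn]] <- tau
      if (model$use_age) v$beta_age[tn] <- g(paste0("bage_", tn))
      if (model$use_sex) v$beta_sex[tn] <- g(paste0("bsex_", tn))
    }
  }
  v
}

# data-driven starting values: thresholds and moments from the observed
# margins, variance shares from the classical Falconer reading of the
# MZ/DZ within-pair correlations, factor correlations from the observed
# cross-trait correlation
start_theta <- function(model, prep, spec) {
  p <- nrow(model$traits)
  th <- stats::setNames((spec$lower + spec$upper) / 2, spec$names)
  pooled <- function(j) {
    v <- c(prep$MZ$Y[, c(j, j + p)], prep$DZ$Y[, c(j, j + p)])
    v[!is.na(v)]
  }
  pair_cor <- function(z, j) {
    y <- prep[[z]]$Y
    ok <- stats::complete.cases(y[, c(j, j + p)])
    if (sum(ok) < 10) return(0.3)
    suppressWarnings(stats::cor(y[ok, j], y[ok, j + p]))
  }
  shares <- matrix(0, p, 3)
  for (i in seq_len(p)) {
    rmz <- pair_cor("MZ", i); rdz <- pair_cor("DZ", i)
    a2 <- min(max(2 * (rmz - rdz), 0.1), 0.8)
    c2 <- if (model$components == "ACE") min(max(2 * rdz - rmz, 0.02), 0.5) else 0
    if (a2 + c2 > 0.9) c2 <- max(0.9 - a2, 0.02)
    shares[i, ] <- c(a2, c2, 1 - a2 - c2)
  }
  clampbox <- function(x) pmin(pmax(x, 0.02), 1.55)
  for (i in seq_len(p)) {
    tn <- model$traits$name[i]
    if (model$form == "cf") {
      if (model$components == "ACE") {
        th[paste0("phi1_", tn)] <- clampbox(acos(sqrt(shares[i, 1])))
        th[paste0("phi2_", tn)] <- clampbox(acos(sqrt(shares[i, 2] / (1 - shares[i, 1]))))
      } else {
        th[paste0("phi_", tn)] <- clampbox(acos(sqrt(shares[i, 1])))
      }
    }
    if (model$traits$kind[i] == "continuous") {
      v <- pooled(i)
      th[paste0("mean_", tn)] <- mean(v)
      th[paste0("logsd_", tn)] <- log(max(stats::sd(v), 0.05))
    } else {
      v <- pooled(i)
      k <- model$traits$n_cat[i]
      cum <- cumsum(tabulate(v + 1, nbins = k) / length(v))[seq_len(k - 1)]
      tau <- stats::qnorm(pmin(pmax(cum, 0.002), 0.998))
      th[paste0("thr_", tn, "_1")] <- tau[1]
      if (k > 2) {
        for (m in 2:(k - 1)) th[paste0("lthr_", tn, "_", m)] <- log(max(tau[m] - tau[m - 1], 0.05))
      }
      if (model$use_age) th[paste0("bage_", tn)] <- 0
      if (model$use_sex) th[paste0("bsex_", tn)] <- 0
    }
  }
  cross_cor <- function(i, j) {
    y <- rbind(prep$MZ$Y, prep$DZ$Y)
    ok <- stats::complete.cases(y[, c(i, j)])
    if (sum(ok) < 10) return(0.2)
    suppressWarnings(stats::cor(y[ok, i], y[ok, j]))
  }
  if (model$form == "cf" && p == 2) {
    r12 <- cross_cor(1, 2)
    th["rA"] <- min(max(1.4 * r12, -0.9), 0.9)
    th["rE"] <- min(max(0.7 * r12, -0.9), 0.9)
    if (model$components == "ACE") th["rC"] <- 0
  }
  if (model$form == "chol") {
    comps <- if (model$components == "ACE") c("A", "C", "E") else c("A", "E")
    colX <- c(A = 1, C = 2, E = 3)
    for (X in comps) {
      for (i in seq_len(p)) {
        th[sprintf("l%s_%d_%d", X, i, i)] <- max(sqrt(shares[i, colX[[X]]]), 0.1)
        if (i > 1) {
          for (j in seq_len(i - 1)) {
            th[sprintf("l%s_%d_%d", X, i, j)] <- 0.25 * cross_cor(j, i) * sqrt(shares[i, colX[[X]]])
          }
        }
      }
    }
  }
  pmin(pmax(th, spec$lower + 1e-6), spec$upper - 1e-6)
}

make_negll <- function(model, prep, spec) {
  force(model); force(prep); force(spec)
  function(theta) {
    m <- model
    m$values <- unpack_theta(model, theta, spec)
    pen <- 0
    if (m$form == "chol") {
      raw <- liability_blocks(m, 1)$raw_diag
      pen <- 100 * sum((raw - 1)^2)
    }
    ll <- tryCatch(loglik_prepared(m, prep, warn = FALSE), error = function(e) NA_real_)
    if (!is.finite(ll)) return(1e10)
    -ll + pen
  }
}

# ---- fitting ---------------------------------------------------------------

#' Fit an ACE liability-threshold twin model by FIML
#'
#' Maximises the raw-data full-information likelihood of an [ace_model()]
#' over its free parameters with box constraints ([stats::nlminb()]),
#' using data-driven starting values plus deterministic jittered restarts,
#' and reports -2LL, AIC and the estimates. Pairs with unknown zygosity
#' are dropped before fitting (the count is recorded in the result).
#'
#' @param data A long twin cohort tibble (one row per individual per wave).
#' @param model An [ace_model()].
#' @param n_starts Number of deterministic starts (the first is
#'   data-driven; the rest are jittered from it). The best converged
#'   solution is reported.
#' @param min_pairs Minimum pairs required per zygosity group.
#' @param control Passed to [stats::nlminb()].
#' @param jitter_seed Fixed sub-seed for the jittered starts.
#' @return A `twin_fit` object: estimates (`tidy()`), fit statistics
#'   (`glance()`), `minus2LL`, `AIC`, convergence status, and the fitted
#'   model in `$model`.
#' @examples
#' cfg <- sim_config(400, 400,
#'   traits = list(trait_spec("y", "continuous", a2 = .4, c2 = .1, e2 = .5)),
#'   seed = 7
#' )
#' fit <- fit_model(
#'   simulate_twin_cohort(cfg),
#'   ace_model(model_trait("y", "continuous")),
#'   n_starts = 1
#' )
#' glance(fit)
#' @export
fit_model <- function(data, model, n_starts = 5, min_pairs = 10,
                      control = list(iter.max = 600, eval.max = 1200, rel.tol = 1e-8),
                      jitter_seed = 104729L) {
  prep <- prepare_pairs(data, model)
  if (prep$MZ$n < min_pairs || prep$DZ$n < min_pairs) {
    stop(
      "too few pairs to fit: ", prep$MZ$n, " MZ / ", prep$DZ$n,
      " DZ (need >= ", min_pairs, " each)"
    )
  }
  spec <- theta_spec(model)
  th0 <- start_theta(model, prep, spec)
  negll <- make_negll(model, prep, spec)
  starts <- list(th0)
  if (n_starts > 1) {
    rng <- (spec$upper - spec$lower)
    withr::with_seed(jitter_seed, {
      for (i in seq_len(n_starts - 1)) {
        starts[[i + 1]] <- pmin(pmax(
          th0 + stats::rnorm(length(th0), 0, 0.08) * rng,
          spec$lower + 1e-6
        ), spec$upper - 1e-6)
      }
    })
  }
  runs <- lapply(starts, function(s) {
    tryCatch(
      stats::nlminb(s, negll, lower = spec$lower, upper = spec$upper, control = control),
      error = function(e) NULL
    )
  })
  ok <- !vapply(runs, is.null, TRUE)
  obj <- vapply(runs, function(r) if (is.null(r)) Inf else r$objective, 0)
  converged <- vapply(runs, function(r) !is.null(r) && r$convergence == 0, TRUE)
  best_i <- which.min(obj)
  failed <- !any(ok) || obj[best_i] >= 1e9 || !any(converged[obj < obj[best_i] + 1e-4])
  best <- runs[[best_i]]

  fitted <- model
  fitted$values <- unpack_theta(model, best$par, spec)
  ll <- loglik_prepared(fitted, prep, warn = FALSE)
  k <- length(spec$names)
  out <- structure(
    list(
      model = fitted, theta = stats::setNames(best$par, spec$names),
      theta_box = spec,
      minus2LL = -2 * ll, AIC = -2 * ll + 2 * k, npar = k,
      n_pairs = c(MZ = prep$MZ$n, DZ = prep$DZ$n),
      n_unknown_pairs = attr(prep, "n_unknown"),
      converged = !failed, message = best$message,
      negll = negll, prep = prep
    ),
    class = "twin_fit"
  )
  if (failed) {
    warning("model did not converge after ", n_starts, " start(s); estimates are not reliable")
  }
  out$estimates <- natural_estimates(out)
  out
}

#' @export
print.twin_fit <- function(x, ...) {
  cat(sprintf(
    "<twin_fit> %s %s model, %d free parameter(s)\n  -2LL = %.3f, AIC = %.3f, pairs: %d MZ / %d DZ%s\n",
    x$model$components, x$model$form, x$npar, x$minus2LL, x$AIC,
    x$n_pairs[["MZ"]], x$n_pairs[["DZ"]],
    if (x$converged) "" else "  [NOT CONVERGED]"
  ))
  print(x$estimates, n = 20)
  invisible(x)
}

# every reportable quantity as a named tibble; also used as the lookup
# table for profile CIs of derived quantities
natural_estimates <- function(fit) {
  naturals_from_values(fit$model)
}

naturals_from_values <- function(model) {
  v <- model$values
  p <- nrow(model$traits)
  tn <- model$traits$name
  term <- est <- c()
  add <- function(name, val) {
    term <<- c(term, name); est <<- c(est, unname(val))
  }
  if (model$form == "cf") {
    for (i in seq_len(p)) {
      add(paste0("a_", tn[i]), v$paths[i, "a"])
      if (model$components == "ACE") add(paste0("c_", tn[i]), v$paths[i, "c"])
      add(paste0("e_", tn[i]), v$paths[i, "e"])
      add(paste0("a2_", tn[i]), v$paths[i, "a"]^2)
      if (model$components == "ACE") add(paste0("c2_", tn[i]), v$paths[i, "c"]^2)
      add(paste0("e2_", tn[i]), v$paths[i, "e"]^2)
    }
    if (p == 2) {
      add("rA", v$rA)
      if (model$components == "ACE") add("rC", v$rC)
      add("rE", v$rE)
      bl <- liability_blocks(model, 1)
      add("rPh", bl$P[1, 2])
      add("covA", bl$SA[1, 2])
      if (model$components == "ACE") add("covC", bl$SC[1, 2])
      add("covE", bl$SE[1, 2])
      if (abs(bl$P[1, 2]) > 1e-8) {
        add("pctA", 100 * bl$SA[1, 2] / bl$P[1, 2])
        if (model$components == "ACE") add("pctC", 100 * bl$SC[1, 2] / bl$P[1, 2])
        add("pctE", 100 * bl$SE[1, 2] / bl$P[1, 2])
      }
    }
  } else {
    L <- std_chol(v)
    comps <- if (model$components == "ACE") c("A", "C", "E") else c("A", "E")
    for (X in comps) {
      M <- L[[paste0("L", X)]]
      for (i in seq_len(p)) {
        for (j in seq_len(i)) add(sprintf("l%s_%d_%d", X, i, j), M[i, j])
        add(sprintf("%s2_%s", tolower(X), tn[i]), sum(M[i, ]^2))
      }
    }
    bl <- liability_blocks(model, 1)
    for (i in seq_len(p - 1)) {
      for (j in (i + 1):p) {
        add(sprintf("rPh_%d%d", i, j), bl$P[i, j])
        for (X in comps) {
          SX <- bl[[paste0("S", X)]]
          dn <- sqrt(SX[i, i] * SX[j, j])
          add(sprintf("r%s_%d%d", X, i, j), if (dn > 1e-10) SX[i, j] / dn else NA_real_)
        }
      }
    }
  }
  for (i in seq_len(p)) {
    if (model$traits$kind[i] == "continuous") {
      add(paste0("mean_", tn[i]), v$means[tn[i]])
      add(paste0("sd_", tn[i]), v$sds[tn[i]])
    } else {
      tau <- v$thresholds[[tn[i]]]
      for (m in seq_along(tau)) add(paste0("thr_", tn[i], "_", m), tau[m])
      if (model$use_age) add(paste0("bage_", tn[i]), v$beta_age[tn[i]])
      if (model$use_sex) add(paste0("bsex_", tn[i]), v$beta_sex[tn[i]])
    }
  }
  tibble::tibble(term = term, estimate = est)
}

#' Tidy a fitted twin model
#'
#' @param x A `twin_fit`.
#' @param ... Unused.
#' @return A tibble with columns `term`, `estimate` and, when profile CIs
#'   have been attached by [profile_ci()], `conf.low`/`conf.high`.
#' @export
tidy.twin_fit <- function(x, ...) {
  out <- x$estimates
  if (!is.null(x$ci)) {
    out <- dplyr::left_join(
      out,
      dplyr::select(x$ci, "term" = "parameter", "conf.low" = "lower", "conf.high" = "upper"),
      by = "term"
    )
  }
  out
}

#' Fit statistics of a twin model
#'
#' @param x A `twin_fit`.
#' @param ... Unused.
#' @return One-row tibble: `minus2LL`, `AIC`, `npar`, pair counts,
#'   convergence flag.
#' @export
glance.twin_fit <- function(x, ...) {
  tibble::tibble(
    minus2LL = x$minus2LL, AIC = x$AIC, npar = x$npar,
    n_mz = x$n_pairs[["MZ"]], n_dz = x$n_pairs[["DZ"]],
    n_unknown_pairs = x$n_unknown_pairs,
    converged = x$converged
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

# ---- profile likelihood confidence intervals -------------------------------

# terms that map monotonically to a single free parameter can be profiled
# exactly (fix + re-optimise + root-find on the deviance); anything else
# goes through the constrained-function profiler
direct_map <- function(fit, term) {
  sp <- fit$theta_box
  model <- fit$model
  if (term %in% sp$names) {
    return(list(idx = match(term, sp$names), to_nat = identity))
  }
  m <- regmatches(term, regexec("^(a2|e2|sd|mean)_(.+)$", term))[[1]]
  if (length(m)) {
    what <- m[2]; tn <- m[3]
    cand <- switch(what,
      a2 = if (model$components == "ACE") paste0("phi1_", tn) else paste0("phi_", tn),
      e2 = if (model$components == "AE") paste0("phi_", tn) else NA,
      sd = paste0("logsd_", tn),
      mean = paste0("mean_", tn)
    )
    if (!is.na(cand) && cand %in% sp$names) {
      to_nat <- switch(what,
        a2 = function(x) cos(x)^2,
        e2 = function(x) sin(x)^2,
        sd = exp,
        mean = identity
      )
      return(list(idx = match(cand, sp$names), to_nat = to_nat))
    }
  }
  m <- regmatches(term, regexec("^thr_(.+)_1$", term))[[1]]
  if (length(m) && paste0("thr_", m[2], "_1") %in% sp$names) {
    return(list(idx = match(paste0("thr_", m[2], "_1"), sp$names), to_nat = identity))
  }
  NULL
}

refit_fixed <- function(fit, idx, value) {
  sp <- fit$theta_box
  free <- setdiff(seq_along(sp$names), idx)
  obj <- function(th_free) {
    th <- fit$theta
    th[idx] <- value
    th[free] <- th_free
    fit$negll(th)
  }
  r <- stats::nlminb(fit$theta[free], obj,
    lower = sp$lower[free], upper = sp$upper[free],
    control = list(iter.max = 300, eval.max = 600)
  )
  r$objective
}

#' Profile likelihood confidence interval
#'
#' Finds the values of a parameter (or derived quantity such as a variance
#' share or a percentage of covariance) at which -2LL rises by the
#' chi-square(1) quantile for the requested level (3.841 at 95%),
#' re-optimising all other parameters at each step. Bounds that hit a box
#' constraint (e.g. a variance share at 0) are reported truncated and
#' flagged.
#'
#' @param fit A converged `twin_fit`.
#' @param parameter Term name as in `tidy(fit)$term` (e.g. `"rA"`,
#'   `"a2_ocs"`, `"pctA"`).
#' @param level Confidence level (default 0.95).
#' @return One-row tibble: `parameter`, `estimate`, `lower`, `upper`,
#'   `level`, truncation flags and the method used.
#' @export
profile_ci <- function(fit, parameter, level = 0.95) {
  if (!fit$converged) stop("profile CIs require a converged fit")
  est <- fit$estimates$estimate[match(parameter, fit$estimates$term)]
  if (is.na(est)) stop("unknown parameter: ", parameter)
  crit <- stats::qchisq(level, 1)
  m2ll_min <- fit$minus2LL
  dm <- direct_map(fit, parameter)

  if (!is.null(dm)) {
    sp <- fit$theta_box
    idx <- dm$idx
    hat <- fit$theta[idx]
    dev <- function(v) 2 * refit_fixed(fit, idx, v) - m2ll_min
    side <- function(bound) {
      if (abs(bound - hat) < 1e-9) {
        return(list(v = bound, trunc = TRUE))
      }
      db <- dev(bound) - crit
      if (db <= 0) {
        return(list(v = bound, trunc = TRUE))
      }
      r <- stats::uniroot(function(v) dev(v) - crit,
        lower = min(hat, bound), upper = max(hat, bound), tol = 1e-4
      )
      list(v = r$root, trunc = FALSE)
    }
    loside <- side(sp$lower[idx])
    hiside <- side(sp$upper[idx])
    ends <- sort(c(dm$to_nat(loside$v), dm$to_nat(hiside$v)))
    flipped <- dm$to_nat(loside$v) > dm$to_nat(hiside$v)
    tl <- if (flipped) hiside$trunc else loside$trunc
    tu <- if (flipped) loside$trunc else hiside$trunc
    # snap box-truncated shares/correlations to their natural bounds
    nat <- snap_bounds(parameter, ends, c(tl, tu))
    return(tibble::tibble(
      parameter = parameter, estimate = est,
      lower = nat[1], upper = nat[2], level = level,
      truncated_lower = tl, truncated_upper = tu, method = "profile"
    ))
  }

  g_fun <- function(theta) {
    m <- fit$model
    m$values <- unpack_theta(fit$model, theta, fit$theta_box)
    nat <- naturals_from_values(m)
    nat$estimate[match(parameter, nat$term)]
  }
  lo <- profile_fun_bound(fit, g_fun, crit, maximize = FALSE)
  hi <- profile_fun_bound(fit, g_fun, crit, maximize = TRUE)
  nat <- snap_bounds(parameter, c(lo, hi), c(FALSE, FALSE))
  tibble::tibble(
    parameter = parameter, estimate = est,
    lower = nat[1], upper = nat[2], level = level,
    truncated_lower = FALSE, truncated_upper = FALSE, method = "profile-function"
  )
}

snap_bounds <- function(parameter, ends, trunc) {
  share <- grepl("^(a2|c2|e2)_", parameter)
  corr <- grepl("^r(A|C|E|Ph)", parameter)
  if (share) {
    ends <- pmin(pmax(ends, 0), 1)
    if (trunc[1] && ends[1] < 1e-3) ends[1] <- 0
    if (trunc[2] && ends[2] > 1 - 1e-3) ends[2] <- 1
  }
  if (corr) {
    if (trunc[1] && ends[1] < -0.998) ends[1] <- -1
    if (trunc[2] && ends[2] > 0.998) ends[2] <- 1
  }
  ends
}

# one-sided likelihood-based bound for a scalar function of the
# parameters: optimise g subject to -2LL <= min + crit via an exterior
# quadratic penalty with an increasing weight schedule, then pull back
# along the segment to the boundary if the constraint is overshot
profile_fun_bound <- function(fit, g_fun, crit, maximize = TRUE) {
  sp <- fit$theta_box
  sgn <- if (maximize) -1 else 1
  dev <- function(th) 2 * fit$negll(th) - fit$minus2LL
  scale <- abs(g_fun(fit$theta)) + 1
  th <- fit$theta
  for (w in c(2, 20, 200, 2000) * scale) {
    obj <- function(t_) {
      ex <- max(dev(t_) - crit, 0)
      sgn * g_fun(t_) + w * ex^2
    }
    r <- tryCatch(
      stats::nlminb(th, obj,
        lower = sp$lower, upper = sp$upper,
        control = list(iter.max = 250, eval.max = 500)
      ),
      error = function(e) NULL
    )
    if (!is.null(r)) th <- r$par
  }
  d <- dev(th)
  if (d > crit + 0.05) {
    f <- function(s) dev(fit$theta + s * (th - fit$theta)) - crit
    s <- tryCatch(stats::uniroot(f, c(0, 1), tol = 1e-4)$root, error = function(e) 1)
    th <- fit$theta + s * (th - fit$theta)
  }
  g_fun(th)
}

#' Compare nested twin models
#'
#' Likelihood-ratio comparison of two FIML fits: the difference in -2LL is
#' chi-square distributed on the difference in free parameters. The
#' preferred-model call combines the significance of the -2LL difference
#' with the AIC rule (an AIC difference of 3 or more supports the
#' lower-AIC model; otherwise parsimony favours the nested model when the
#' likelihood loss is non-significant).
#'
#' @param full,nested `twin_fit` objects on the same data; `nested` must
#'   have a subset of the free parameters.
#' @param alpha Significance level for the likelihood-ratio test.
#' @return One-row tibble: `delta_m2ll`, `delta_df`, `p_value`,
#'   `delta_aic`, `preferred`, `aic_support`.
#' @export
compare_models <- function(full, nested, alpha = 0.05) {
  stopifnot(inherits(full, "twin_fit"), inherits(nested, "twin_fit"))
  if (!identical(sort(full$model$traits$name), sort(nested$model$traits$name)) ||
    !identical(full$n_pairs, nested$n_pairs)) {
    stop("models must be fitted to the same data and traits")
  }
  if (nested$npar > full$npar) stop("`nested` has more free parameters than `full`; not nested")
  d_m2ll <- max(nested$minus2LL - full$minus2LL, 0)
  d_df <- full$npar - nested$npar
  p <- if (d_df == 0) 1 else stats::pchisq(d_m2ll, d_df, lower.tail = FALSE)
  d_aic <- nested$AIC - full$AIC
  preferred <- if (p > alpha) "nested" else "full"
  aic_support <- if (d_aic <= -3) "nested" else if (d_aic >= 3) "full" else "either"
  tibble::tibble(
    delta_m2ll = d_m2ll, delta_df = d_df, p_value = p,
    delta_aic = d_aic, preferred = preferred, aic_support = aic_support
  )
}
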