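#' Validate a twin cohort table
#'
#' Report-only schema checks: required columns and codings, pair
#' integrity (at most two rows per family per wave, no duplicated
#' twin indices), and zygosity consistency within families.
#'
#' @param data A long twin cohort tibble.
#' @return A tibble of issues (`check`, `detail`); zero rows when the
#'   dataset is well-formed.
#' @export
validate_schema <- function(data) {
  issues <- list()
  note <- function(check, detail) {
    issues[[length(issues) + 1]] <<- tibble::tibble(check = check, detail = detail)
  }
  required <- c("family_id", "twin_index", "zygosity", "sex", "age", "wave")
  miss <- setdiff(required, names(data))
  if (length(miss)) {
    note("columns", paste("missing required column(s):", paste(miss, collapse = ", ")))
    return(dplyr::bind_rows(issues))
  }
  if (!all(data$twin_index %in% 1:2)) note("twin_index", "values outside {1, 2}")
  if (!all(data$zygosity %in% c("MZ", "DZ", "unknown"))) {
    note("zygosity", "values outside {MZ, DZ, unknown}")
  }
  if (!all(data$sex %in% c(0, 1, NA))) note("sex", "values outside {0, 1}")
  counts <- dplyr::count(data, .data$family_id, .data$wave)
  bad <- counts$family_id[counts$n > 2]
  if (length(bad)) {
    note("pair_size", paste(
      "families with > 2 rows in a wave:",
      paste(utils::head(unique(bad), 5), collapse = ", ")
    ))
  }
  dup <- duplicated(data[, c("family_id", "twin_index", "wave")])
  if (any(dup)) note("duplicates", paste(sum(dup), "duplicated (family_id, twin_index, wave) rows"))
  zyg_n <- tapply(data$zygosity, data$family_id, function(z) length(unique(z)))
  if (any(zyg_n > 1)) {
    note("zygosity_consistency", paste(
      sum(zyg_n > 1), "families with inconsistent zygosity, e.g.",
      names(zyg_n)[zyg_n > 1][1]
    ))
  }
  if (!length(issues)) {
    return(tibble::tibble(check = character(), detail = character()))
  }
  dplyr::bind_rows(issues)
}

#' Describe an analysis plan
#'
#' Names the columns each analysis stage uses and sets the twin-model
#' gate. Stages run in order: cross-sectional regressions at each wave
#' over increasing adjustment tiers (unadjusted, + depression,
#' + depression and anxiety), prospective regressions (adding a
#' baseline-attempt tier), bivariate twin decompositions for predictors
#' whose latent correlation with the outcome exceeds the gate, and
#' optionally the trivariate prospective model.
#'
#' @param ocs18,sui18 OCS total score and binary suicidality columns at
#'   the first wave.
#' @param ocs24,sui24 Same for the later wave (`NULL` to skip).
#' @param dep18,anx18,dep24,anx24 Covariate score columns (`NULL` to skip
#'   a tier).
#' @param subscales18,subscales24 Optional character vectors of subscale
#'   columns entered jointly as a second model per wave.
#' @param wave18,wave24 Wave tags (defaults 18 and 24).
#' @param gate Minimum |latent correlation| required to run a bivariate
#'   twin model (default 0.2; decomposing weaker associations gives
#'   unstable solutions).
#' @param trivariate Run the trivariate prospective model
#'   (sui18, ocs18, sui24) when all three columns are present.
#' @param components_reduction Apply the ACE-to-AE reduction rule (drop C
#'   when its shares are below `c_floor` and the likelihood loss is
#'   non-significant).
#' @param c_floor Share threshold below which C is considered negligible
#'   (default 0.05).
#' @return An `analysis_plan` list.
#' @export
analysis_plan <- function(ocs18 = "ocs18", sui18 = "attempt18",
                          ocs24 = NULL, sui24 = NULL,
                          dep18 = NULL, anx18 = NULL,
                          dep24 = NULL, anx24 = NULL,
                          subscales18 = NULL, subscales24 = NULL,
                          wave18 = 18, wave24 = 24,
                          gate = 0.2, trivariate = FALSE,
                          components_reduction = TRUE, c_floor = 0.05) {
  structure(
    list(
      ocs18 = ocs18, sui18 = sui18, ocs24 = ocs24, sui24 = sui24,
      dep18 = dep18, anx18 = anx18, dep24 = dep24, anx24 = anx24,
      subscales18 = subscales18, subscales24 = subscales24,
      wave18 = wave18, wave24 = wave24,
      gate = gate, trivariate = trivariate,
      components_reduction = components_reduction, c_floor = c_floor
    ),
    class = "analysis_plan"
  )
}

# individual-level wide frame across waves (for prospective regressions)
individual_wide <- function(data, plan) {
  w18 <- data[data$wave == plan$wave18, , drop = FALSE]
  out <- w18[, setdiff(names(w18), "wave"), drop = FALSE]
  if (!is.null(plan$sui24) || !is.null(plan$ocs24)) {
    w24 <- data[data$wave == plan$wave24, , drop = FALSE]
    vars24 <- intersect(
      unique(c(plan$ocs24, plan$sui24, plan$dep24, plan$anx24, plan$subscales24)),
      names(w24)
    )
    # drop the off-wave (all-NA) copies of the later-wave columns before
    # joining so the joined columns keep their plain names
    out <- out[, setdiff(names(out), vars24), drop = FALSE]
    out <- dplyr::left_join(out, w24[, c("family_id", "twin_index", vars24), drop = FALSE],
      by = c("family_id", "twin_index")
    )
  }
  out
}

#' Run the full OCS-suicidality analysis sequence
#'
#' Orchestrates, on one twin cohort: schema validation; log-transform
#' standardisation of the continuous scales; cross-sectional
#' cluster-robust logistic regressions of suicidality on OCS at each wave
#' over the adjustment tiers; prospective regressions of later
#' suicidality on baseline OCS (adding a baseline-attempt tier); a
#' bivariate twin decomposition wherever the latent OCS-suicidality
#' correlation passes the gate (with the ACE-to-AE reduction rule); and
#' optionally the trivariate prospective model. Stage failures are logged
#' and independent stages still run.
#'
#' @param data A long twin cohort tibble.
#' @param plan An [analysis_plan()].
#' @param seed Integer seed recorded in the bundle (the pipeline itself
#'   is deterministic given the data; the seed also fixes optimizer
#'   jitter).
#' @param fit_args List of extra arguments for [fit_model()] (e.g.
#'   `n_starts`).
#' @return A `report_bundle`: regression tables, twin decomposition
#'   table, model comparisons, schema report and run log.
#' @export
run_pipeline <- function(data, plan, seed = 1L, fit_args = list()) {
  log_lines <- character()
  say <- function(...) log_lines <<- c(log_lines, sprintf(...))
  bundle <- list(
    schema = validate_schema(data), regressions = NULL, twin = NULL,
    comparisons = NULL, trivariate = NULL, seed = seed
  )
  say("pipeline seed %d; %d rows, %d families", seed, nrow(data), length(unique(data$family_id)))
  if (nrow(bundle$schema)) say("schema issues: %d (see schema table)", nrow(bundle$schema))

  # transforms: ln(x+1) + z-score per continuous scale, within wave
  zcol <- function(df, col) {
    if (is.null(col) || !col %in% names(df)) return(df)
    zn <- paste0(col, "_z")
    df[[zn]] <- NA_real_
    ok <- !is.na(df[[col]])
    df[[zn]][ok] <- log_standardize(df[[col]][ok])
    df
  }
  wide <- individual_wide(data, plan)
  for (col in c(plan$ocs18, plan$ocs24, plan$dep18, plan$anx18, plan$dep24, plan$anx24)) {
    wide <- zcol(wide, col)
  }

  regress <- function(label, outcome, predictor, tiers) {
    purrr::map_dfr(seq_along(tiers), function(i) {
      covs <- c("age", "sex", tiers[[i]])
      res <- tryCatch(
        cluster_robust_logistic(wide, outcome, predictor, covariates = covs),
        error = function(e) {
          say("stage %s tier %d failed: %s", label, i, conditionMessage(e))
          NULL
        }
      )
      if (is.null(res)) return(NULL)
      out <- res[res$term %in% predictor, ]
      tibble::tibble(
        stage = label, tier = names(tiers)[i], term = out$term,
        odds_ratio = out$odds_ratio, conf.low = out$conf.low,
        conf.high = out$conf.high, p.value = out$p.value,
        n = attr(res, "n")
      )
    })
  }
  tiers_cs <- function(dep, anx) {
    t <- list(unadjusted = character())
    if (!is.null(dep)) t[["+depression"]] <- paste0(dep, "_z")
    if (!is.null(dep) && !is.null(anx)) t[["+depression+anxiety"]] <- paste0(c(dep, anx), "_z")
    t
  }
  reg <- list()
  reg$cs18 <- regress(
    "cross-sectional-18", plan$sui18, paste0(plan$ocs18, "_z"),
    tiers_cs(plan$dep18, plan$anx18)
  )
  if (!is.null(plan$subscales18)) {
    for (s in plan$subscales18) wide <- zcol(wide, s)
    reg$sub18 <- regress(
      "subscales-18", plan$sui18, paste0(plan$subscales18, "_z"),
      tiers_cs(plan$dep18, plan$anx18)
    )
  }
  if (!is.null(plan$sui24) && !is.null(plan$ocs24)) {
    reg$cs24 <- regress(
      "cross-sectional-24", plan$sui24, paste0(plan$ocs24, "_z"),
      tiers_cs(plan$dep24, plan$anx24)
    )
    # prospective: baseline OCS predicting later suicidality, with the
    # baseline-attempt tier first
    tiers_p <- list(unadjusted = character())
    tiers_p[["+attempt18"]] <- plan$sui18
    if (!is.null(plan$dep18)) tiers_p[["+attempt18+depression"]] <- c(plan$sui18, paste0(plan$dep18, "_z"))
    if (!is.null(plan$dep18) && !is.null(plan$anx18)) {
      tiers_p[["+attempt18+depression+anxiety"]] <-
        c(plan$sui18, paste0(c(plan$dep18, plan$anx18), "_z"))
    }
    reg$prosp <- regress("prospective", plan$sui24, paste0(plan$ocs18, "_z"), tiers_p)
  }
  bundle$regressions <- dplyr::bind_rows(reg)

  # ---- twin stage ----------------------------------------------------------
  twin_rows <- list()
  comp_rows <- list()
  run_biv <- function(label, ocs_col, sui_col, wave_o, wave_s) {
    sub <- data
    zn <- paste0(ocs_col, "_z")
    ok <- !is.na(sub[[ocs_col]]) & sub$wave == wave_o
    sub[[zn]] <- NA_real_
    sub[[zn]][ok] <- log_standardize(sub[[ocs_col]][ok])
    x <- wide[[paste0(ocs_col, "_z")]]
    y <- wide[[sui_col]]
    r <- latent_cor(x, y, "continuous", "binary")
    say("twin gate %s: latent r = %.3f (gate %.2f)", label, r, plan$gate)
    if (!is.finite(r) || abs(r) <= plan$gate) {
      twin_rows[[label]] <<- tibble::tibble(
        pair = label, gate_r = r, ran = FALSE, model = NA_character_,
        rPh = NA_real_, rA = NA_real_, rC = NA_real_, rE = NA_real_,
        pctA = NA_real_, pctC = NA_real_, pctE = NA_real_
      )
      return(invisible())
    }
    traits <- rbind(
      model_trait(zn, "continuous", wave = wave_o),
      model_trait(sui_col, "binary", wave = wave_s)
    )
    fitA <- tryCatch(
      do.call(fit_model, c(list(sub, ace_model(traits, "ACE")), fit_args)),
      error = function(e) {
        say("twin stage %s ACE failed: %s", label, conditionMessage(e)); NULL
      }
    )
    if (is.null(fitA)) return(invisible())
    final <- fitA
    model_label <- "ACE"
    if (plan$components_reduction) {
      c2 <- fitA$estimates$estimate[grepl("^c2_", fitA$estimates$term)]
      if (all(c2 < plan$c_floor)) {
        fitE <- tryCatch(
          do.call(fit_model, c(list(sub, ace_model(traits, "AE")), fit_args)),
          error = function(e) NULL
        )
        if (!is.null(fitE)) {
          cmp <- compare_models(fitA, fitE)
          comp_rows[[label]] <<- dplyr::mutate(cmp, pair = label, .before = 1)
          if (cmp$preferred == "nested") {
            final <- fitE
            model_label <- "AE"
          }
        }
      }
    }
    dec <- tryCatch(decompose_correlation(final), error = function(e) {
      say("twin stage %s decomposition failed: %s", label, conditionMessage(e)); NULL
    })
    if (is.null(dec)) return(invisible())
    twin_rows[[label]] <<- tibble::tibble(
      pair = label, gate_r = r, ran = TRUE, model = model_label,
      rPh = dec$rPh, rA = dec$rA, rC = dec$rC, rE = dec$rE,
      pctA = dec$pctA, pctC = dec$pctC, pctE = dec$pctE
    )
  }
  run_biv("ocs18-sui18", plan$ocs18, plan$sui18, plan$wave18, plan$wave18)
  if (!is.null(plan$ocs24) && !is.null(plan$sui24)) {
    run_biv("ocs24-sui24", plan$ocs24, plan$sui24, plan$wave24, plan$wave24)
  }
  bundle$twin <- dplyr::bind_rows(twin_rows)
  bundle$comparisons <- dplyr::bind_rows(comp_rows)

  if (isTRUE(plan$trivariate) && !is.null(plan$sui24)) {
    tri <- tryCatch(
      {
        sub <- data
        zn <- paste0(plan$ocs18, "_z")
        ok <- !is.na(sub[[plan$ocs18]]) & sub$wave == plan$wave18
        sub[[zn]] <- NA_real_
        sub[[zn]][ok] <- log_standardize(sub[[plan$ocs18]][ok])
        tfit <- do.call(fit_trivariate_prospective, c(
          list(sub, rbind(
            model_trait(plan$sui18, "binary", wave = plan$wave18),
            model_trait(zn, "continuous", wave = plan$wave18),
            model_trait(plan$sui24, "binary", wave = plan$wave24)
          )),
          fit_args
        ))
        list(unique = tfit$unique, concurrent = tfit$concurrent, glance = glance(tfit))
      },
      error = function(e) {
        say("trivariate stage failed: %s", conditionMessage(e))
        NULL
      }
    )
    bundle$trivariate <- tri
  }

  bundle$log <- log_lines
  class(bundle) <- "report_bundle"
  bundle
}

#' @export
print.report_bundle <- function(x, ...) {
  cat("<report_bundle>\n")
  if (!is.null(x$regressions) && nrow(x$regressions)) {
    cat(" regressions:", nrow(x$regressions), "rows across", length(unique(x$regressions$stage)), "stage(s)\n")
  }
  if (!is.null(x$twin) && nrow(x$twin)) {
    cat(" twin decompositions:", sum(x$twin$ran), "run /", nrow(x$twin), "gated\n")
  }
  if (!is.null(x$trivariate)) cat(" trivariate prospective model: run\n")
  cat(" log:", length(x$log), "line(s)\n")
  invisible(x)
}

#' Serialise a report bundle
#'
#' Writes the bundle as one JSON document (stable key order, fixed
#' precision, so identical runs are byte-identical) plus per-table CSVs
#' and a plain-text log.
#'
#' @param bundle A `report_bundle`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(
    unclass(bundle),
    file.path(dir, "bundle.json"),
    dataframe = "rows", digits = 10, auto_unbox = TRUE, pretty = TRUE, na = "null"
  )
  if (!is.null(bundle$regressions)) {
    utils::write.csv(bundle$regressions, file.path(dir, "regressions.csv"), row.names = FALSE)
  }
  if (!is.null(bundle$twin)) {
    utils::write.csv(bundle$twin, file.path(dir, "twin_decomposition.csv"), row.names = FALSE)
  }
  writeLines(bundle$log, file.path(dir, "run.log"))
  invisible(dir)
}
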