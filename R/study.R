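# Full study orchestration: synthesise -> optimise -> cross-validate ->
# evaluate -> report.

#' Configuration of a full identification study
#'
#' @param generator A [generator_config] (or a dataset directory written by
#'   [generate_cohort()]).
#' @param representations Stiffness representations to run: subset of
#'   `c("uniform", "level_dependent")`.
#' @param load_types Loading directions to run.
#' @param init Initial base stiffness for the optimisation, Nm/rad.
#' @param bounds Multiplier bounds for [optimize_stiffness()].
#' @param level_subset Joint levels entering the error aggregations.
#' @param bonferroni_m Bonferroni family size for the pre/post comparisons.
#' @param cycle_score Coupled-moment range score (`"sum"` or `"max"`).
#' @return Object of class `study_config`.
#' @export
study_config <- function(generator,
                         representations = c("uniform", "level_dependent"),
                         load_types = c("lb", "ar", "fe"),
                         init = literature_base_stiffness(),
                         bounds = c(0.1, 10),
                         level_subset = ivj_levels(),
                         bonferroni_m = 6,
                         cycle_score = "sum") {
  representations <- match.arg(representations,
                               c("uniform", "level_dependent"),
                               several.ok = TRUE)
  load_types <- unique(match_dof(load_types))
  if (length(representations) < 1 || length(load_types) < 1) {
    stop("need at least one representation and one load type", call. = FALSE)
  }
  structure(list(generator = generator, representations = representations,
                 load_types = load_types, init = init, bounds = bounds,
                 level_subset = level_subset, bonferroni_m = bonferroni_m,
                 cycle_score = cycle_score),
            class = "study_config")
}

#' Run the full identification study
#'
#' Executes, per specimen x representation x load type: cycle segmentation
#' and evaluation-cycle selection, static load-case extraction, stiffness
#' optimisation, leave-one-out cross-validation, kinematic error metrics,
#' and the nonparametric statistical battery. Per-cell failures (e.g.
#' non-convergence) are recorded in the report and the run continues. The
#' report is fully determined by the configuration and seed.
#'
#' @param config A [study_config].
#' @return Object of class `study_report`: a list with elements `seed`,
#'   `config`, `config_checksum`, `fits` (per-cell stiffness results),
#'   `errors` (long error table over all model types), `crossval`
#'   (`n_simulations`, `skipped`), `mae_summary`, `rmse_by_specimen`,
#'   `stats` (`wilcoxon`, `kw_representation`), and `non_converged`.
#' @export
run_study <- function(config) {
  stopifnot(inherits(config, "study_config"))
  gen <- config$generator
  cohort <- if (inherits(gen, "generator_config")) {
    generate_cohort(gen)
  } else {
    cv <- read_cohort(gen)
    list(config = NULL, specimens = cv$specimens)
  }
  specimens <- cohort$specimens
  seed <- if (!is.null(cohort$config)) cohort$config$seed else NA_integer_

  # --- stage 1: load-case extraction per specimen x load type -------------
  cases <- list()
  for (sp in names(specimens)) {
    model <- specimens[[sp]]$model %||%
      spine_model(specimens[[sp]]$true_stiffness)
    cases[[sp]] <- list(model = model, loads = list())
    for (lt in config$load_types) {
      hist <- specimens[[sp]]$loads[[lt]]$history
      kin <- specimens[[sp]]$loads[[lt]]$kinematics
      cyc <- segment_cycles(hist)
      sel <- select_evaluation_cycle(hist, cyc, score = config$cycle_score)
      lc <- extract_load_case(hist, sel, cyc)
      measured <- kinematics_at_load_case(kin, lc$sample_index, hist)
      cases[[sp]]$loads[[lt]] <- list(load = lc$load, measured = measured,
                                      cycle = as.integer(sel),
                                      sample_index = lc$sample_index)
    }
  }

  # --- stage 2: optimisation per representation x load type x specimen ----
  fits <- list()
  fit_rows <- list()
  err_rows <- list()
  for (rep_name in config$representations) {
    mode <- if (rep_name == "uniform") "uniform" else "level_ratio"
    lit_tab <- if (rep_name == "uniform") {
      stiffness_table(config$init)
    } else {
      apply_level_ratios(config$init, literature_level_ratios())
    }
    fits[[rep_name]] <- list()
    for (lt in config$load_types) {
      fits[[rep_name]][[lt]] <- list()
      for (sp in names(specimens)) {
        base_model <- cases[[sp]]$model
        lit_model <- base_model
        lit_model$stiffness <- lit_tab
        cell <- cases[[sp]]$loads[[lt]]
        fit <- optimize_stiffness(base_model, cell$load, cell$measured,
                                  mode = mode, init = config$init,
                                  bounds = config$bounds)
        fits[[rep_name]][[lt]][[sp]] <- fit
        fit_rows[[length(fit_rows) + 1L]] <- data.frame(
          specimen = sp, representation = rep_name, load_type = lt,
          dof = ivj_dofs(), k_init = unname(config$init),
          k_opt = unname(coef(fit)), converged = fit$converged,
          termination_reason = fit$termination_reason,
          final_cost = fit$final_cost, stringsAsFactors = FALSE)
        err_rows[[length(err_rows) + 1L]] <- error_table(
          solve_equilibrium(lit_model, cell$load), cell$measured,
          specimen = sp, model_type = "literature",
          representation = rep_name, load_type = lt)
        err_rows[[length(err_rows) + 1L]] <- error_table(
          predict(fit), cell$measured, specimen = sp,
          model_type = "optimized", representation = rep_name,
          load_type = lt)
      }
    }
  }

  # --- stage 3: leave-one-out cross-validation ----------------------------
  cv <- run_cross_validation(cases, fits)
  errors <- do.call(rbind, c(err_rows, list(cv$errors)))

  # --- stage 4: error metrics ---------------------------------------------
  mae_rows <- list()
  rmse_rows <- list()
  for (rep_name in config$representations) {
    for (lt in config$load_types) {
      for (mt in c("literature", "optimized", "cross_validation")) {
        e <- errors[errors$representation == rep_name &
                      errors$load_type == lt & errors$model_type == mt, ]
        if (nrow(e) == 0) next
        mae <- aggregate_mae(e, lt, levels = config$level_subset)
        ref <- reference_motion(e, lt, levels = config$level_subset)
        mae_rows[[length(mae_rows) + 1L]] <- data.frame(
          representation = rep_name, load_type = lt, model_type = mt,
          median_mae_deg = mae$median, iqr_deg = mae$iqr,
          pct_error = percentage_error(mae$median, ref),
          reference_motion_deg = ref, stringsAsFactors = FALSE)
        rmse <- aggregate_rmse(e[e$level %in% config$level_subset, ],
                               "specimen")
        rmse_rows[[length(rmse_rows) + 1L]] <- data.frame(
          representation = rep_name, load_type = lt, model_type = mt,
          specimen = names(rmse), rmse_deg = unname(rmse),
          stringsAsFactors = FALSE)
      }
    }
  }

  # --- stage 5: statistics ------------------------------------------------
  wil_rows <- list()
  for (rep_name in config$representations) {
    for (lt in config$load_types) {
      for (sp in names(specimens)) {
        pick <- function(mt) {
          e <- errors[errors$representation == rep_name &
                        errors$load_type == lt & errors$model_type == mt &
                        errors$specimen == sp &
                        errors$level %in% config$level_subset, ]
          e <- e[order(e$level, e$dof), ]
          abs(e$error_deg)
        }
        for (cmp in list(c("literature", "optimized"),
                         c("optimized", "cross_validation"))) {
          a <- pick(cmp[1]); b <- pick(cmp[2])
          if (length(a) == 0 || length(b) == 0 || length(a) != length(b)) next
          wt <- wilcoxon_bonferroni(a, b, m = config$bonferroni_m)
          wil_rows[[length(wil_rows) + 1L]] <- data.frame(
            comparison = paste(cmp, collapse = "_vs_"),
            representation = rep_name, load_type = lt, specimen = sp,
            statistic = wt$statistic, p_value = wt$p_value,
            p_adjusted = wt$p_adjusted, significant = wt$significant,
            stringsAsFactors = FALSE)
        }
      }
    }
  }

  kw_rows <- list()
  if (all(c("uniform", "level_dependent") %in% config$representations)) {
    for (lt in config$load_types) {
      for (motion in c(ivj_dofs(), "overall")) {
        grp <- lapply(c("uniform", "level_dependent"), function(rep_name) {
          e <- errors[errors$representation == rep_name &
                        errors$load_type == lt &
                        errors$model_type == "optimized" &
                        errors$level %in% config$level_subset, ]
          conv <- fits[[rep_name]][[lt]]
          ok <- names(conv)[vapply(conv, `[[`, logical(1), "converged")]
          e <- e[e$specimen %in% ok, ]
          if (motion != "overall") e <- e[e$dof == motion, ]
          unname(tapply(e$error_deg, e$specimen, function(v) sqrt(mean(v^2))))
        })
        if (any(vapply(grp, length, integer(1)) < 2)) next
        kw <- kruskal_wallis(grp)
        kw_rows[[length(kw_rows) + 1L]] <- data.frame(
          load_type = lt, motion = motion, H = kw$statistic,
          p_value = kw$p_value, H_critical = kw$critical_value,
          significant = kw$significant, stringsAsFactors = FALSE)
      }
    }
  }

  fits_df <- do.call(rbind, fit_rows)
  non_conv <- unique(fits_df[!fits_df$converged,
                             c("specimen", "representation", "load_type",
                               "termination_reason")])
  cfg_list <- list(
    representations = config$representations,
    load_types = config$load_types, init = unname(config$init),
    bounds = config$bounds, level_subset = config$level_subset,
    bonferroni_m = config$bonferroni_m, cycle_score = config$cycle_score,
    generator = if (inherits(gen, "generator_config")) config_as_list(gen)
                else as.character(gen))
  report <- list(
    seed = seed,
    config = cfg_list,
    config_checksum = config_checksum(cfg_list),
    fits = fits_df,
    errors = errors,
    crossval = list(n_simulations = cv$n_simulations, skipped = cv$skipped),
    mae_summary = do.call(rbind, mae_rows),
    rmse_by_specimen = do.call(rbind, rmse_rows),
    stats = list(wilcoxon = do.call(rbind, wil_rows),
                 kw_representation = do.call(rbind, kw_rows)),
    non_converged = non_conv)
  class(report) <- "study_report"
  report
}

config_checksum <- function(x) {
  s <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA)
  v <- utf8ToInt(as.character(s))
  sum(v * (seq_along(v) %% 97 + 1)) %% 2147483647
}

#' @export
print.study_report <- function(x, ...) {
  cat("Stiffness identification study report\n")
  cat("  seed:", x$seed, " config checksum:", x$config_checksum, "\n")
  cat("  optimisations:", nrow(x$fits) / 3, " (",
      nrow(x$non_converged), "non-converged )\n")
  cat("  cross-validation simulations:", x$crossval$n_simulations, "\n")
  cat("MAE summary (degrees / % of reference motion):\n")
  print(x$mae_summary, digits = 3, row.names = FALSE)
  invisible(x)
}

#' Write a study report to disk
#'
#' Serialises the report as `report.json` plus CSV tables (`fits.csv`,
#' `errors.csv`, `mae_summary.csv`, `rmse_by_specimen.csv`,
#' `stats_wilcoxon.csv`, `stats_kw_representation.csv`).
#'
#' @param report A [run_study()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study_report <- function(report, dir) {
  stopifnot(inherits(report, "study_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  json <- report
  class(json) <- NULL
  jsonlite::write_json(json, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  tabs <- list(fits = report$fits, errors = report$errors,
               mae_summary = report$mae_summary,
               rmse_by_specimen = report$rmse_by_specimen,
               stats_wilcoxon = report$stats$wilcoxon,
               stats_kw_representation = report$stats$kw_representation)
  for (nm in names(tabs)) {
    if (!is.null(tabs[[nm]])) {
      utils::write.csv(tabs[[nm]], file.path(dir, paste0(nm, ".csv")),
                       row.names = FALSE)
    }
  }
  invisible(dir)
}
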