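# Kinematic error metrics, leave-one-out cross-validation across a cohort,
# and helpers to assemble long-format error tables.

#' Long-format table of signed kinematic errors
#'
#' One row per level x DoF with the signed prediction error
#' (predicted - measured, degrees; positive values overpredict the rotation)
#' plus the measured and predicted values and the metadata needed for
#' aggregation.
#'
#' @param predicted,measured [joint_rotations] objects, degrees.
#' @param specimen Specimen identifier.
#' @param model_type `"literature"`, `"optimized"` or `"cross_validation"`.
#' @param representation `"uniform"` or `"level_dependent"`.
#' @param load_type Loading direction label.
#' @return Data frame with columns `specimen`, `level`, `dof`, `load_type`,
#'   `representation`, `model_type`, `error_deg`, `predicted_deg`,
#'   `measured_deg`.
#' @export
error_table <- function(predicted, measured, specimen = NA,
                        model_type = NA, representation = NA,
                        load_type = NA) {
  p <- rotations_matrix(predicted)
  m <- rotations_matrix(measured)
  grid <- expand.grid(level = ivj_levels(), dof = ivj_dofs(),
                      stringsAsFactors = FALSE)
  data.frame(
    specimen = specimen,
    level = grid$level,
    dof = grid$dof,
    load_type = if (is.na(load_type)) NA_character_ else match_dof(load_type),
    representation = representation,
    model_type = model_type,
    error_deg = p[cbind(grid$level, grid$dof)] - m[cbind(grid$level, grid$dof)],
    predicted_deg = p[cbind(grid$level, grid$dof)],
    measured_deg = m[cbind(grid$level, grid$dof)],
    stringsAsFactors = FALSE
  )
}

iqr_tukey <- function(x) {
  q <- stats::quantile(x, c(0.25, 0.75), type = 7, names = FALSE)
  q[2] - q[1]
}

#' Per-specimen mean absolute error and its cohort summary
#'
#' For each specimen, the mean of |error| over the joint levels in the given
#' DoF; across specimens, the cohort median and interquartile range
#' (linear-interpolation quartiles).
#'
#' @param errors An [error_table()]-style data frame (already filtered to
#'   one load type / model type / representation).
#' @param dof DoF whose errors are aggregated.
#' @param levels Optional level subset (default: all levels present).
#' @return List with `per_specimen` (named vector, degrees), `median` and
#'   `iqr`.
#' @export
aggregate_mae <- function(errors, dof, levels = NULL) {
  dof <- match_dof(dof)
  sel <- errors$dof == dof
  if (!is.null(levels)) sel <- sel & errors$level %in% levels
  e <- errors[sel, ]
  if (nrow(e) == 0) stop("empty selection", call. = FALSE)
  per <- tapply(abs(e$error_deg), e$specimen, mean)
  per <- per[order(names(per))]
  list(per_specimen = c(per), median = stats::median(per),
       iqr = iqr_tukey(per))
}

#' Root-mean-square error per group
#'
#' RMSE of the signed errors within each group: per specimen (over all its
#' levels and DoFs present in the table) or per level (across specimens).
#' The normalised variant divides each group's RMSE by the range of the
#' measured motion within the group.
#'
#' @param errors An [error_table()]-style data frame.
#' @param group_by `"specimen"` or `"level"`.
#' @param normalise Divide by the measured-motion range of the group.
#' @param dof Optional DoF filter applied before grouping.
#' @return Named numeric vector of (normalised) RMSEs.
#' @export
aggregate_rmse <- function(errors, group_by = c("specimen", "level"),
                           normalise = FALSE, dof = NULL) {
  group_by <- match.arg(group_by)
  if (!is.null(dof)) errors <- errors[errors$dof == match_dof(dof), ]
  if (nrow(errors) == 0) stop("empty group", call. = FALSE)
  g <- errors[[group_by]]
  rmse <- tapply(errors$error_deg, g, function(v) sqrt(mean(v^2)))
  if (normalise) {
    rng <- tapply(errors$measured_deg, g, function(v) max(v) - min(v))
    if (any(rng == 0)) stop("zero measured-motion range in a group; ",
                            "normalised RMSE undefined", call. = FALSE)
    rmse <- rmse / rng
  }
  c(rmse)
}

#' Percentage error relative to a reference motion
#'
#' `100 * median_mae / reference_motion`. The reference is the maximum over
#' specimens of the per-specimen mean absolute measured motion in the DoF of
#' interest (see [reference_motion()]).
#'
#' @param median_mae Median MAE, degrees.
#' @param reference_motion Reference motion, degrees (> 0).
#' @return Percentage (scalar).
#' @export
percentage_error <- function(median_mae, reference_motion) {
  if (!is.finite(reference_motion) || reference_motion <= 0) {
    stop("reference motion must be strictly positive", call. = FALSE)
  }
  100 * median_mae / reference_motion
}

#' @rdname percentage_error
#' @param errors An [error_table()]-style data frame carrying
#'   `measured_deg`.
#' @param dof DoF of interest.
#' @param levels Optional level subset.
#' @return `reference_motion()`: maximum over specimens of the mean (over
#'   levels) absolute measured motion, degrees.
#' @export
reference_motion <- function(errors, dof, levels = NULL) {
  dof <- match_dof(dof)
  sel <- errors$dof == dof
  if (!is.null(levels)) sel <- sel & errors$level %in% levels
  e <- errors[sel, ]
  if (nrow(e) == 0) stop("empty selection", call. = FALSE)
  max(tapply(abs(e$measured_deg), e$specimen, mean))
}

#' Leave-one-out median stiffness
#'
#' Element-wise median (per DoF and per level) of the optimised stiffness
#' tables of all specimens except the one left out. Non-converged fits are
#' excluded from the donor pool with a warning.
#'
#' @param fits Named list of [optimize_stiffness()] results (or
#'   [stiffness_table]s), one per specimen.
#' @param leave_out Name (or index) of the specimen to leave out.
#' @return A [stiffness_table].
#' @export
loo_median_stiffness <- function(fits, leave_out) {
  nm <- names(fits) %||% as.character(seq_along(fits))
  names(fits) <- nm
  keep <- setdiff(nm, as.character(leave_out))
  donors <- fits[keep]
  is_fit <- vapply(donors, inherits, logical(1), "stiffness_fit")
  conv <- vapply(seq_along(donors), function(i) {
    if (is_fit[i]) donors[[i]]$converged else TRUE
  }, logical(1))
  if (any(!conv)) {
    warning("excluding non-converged donor fits: ",
            paste(names(donors)[!conv], collapse = ", "))
    donors <- donors[conv]
  }
  if (length(donors) < 2) {
    stop("need at least 2 converged donor specimens", call. = FALSE)
  }
  tabs <- lapply(donors, function(d) {
    if (inherits(d, "stiffness_fit")) d$table else d
  })
  k_rot <- apply(simplify2array(lapply(tabs, `[[`, "k_rot")), c(1, 2),
                 stats::median)
  k_trans <- apply(simplify2array(lapply(tabs, `[[`, "k_trans")), c(1, 2),
                   stats::median)
  stiffness_table(k_rot, k_trans)
}

#' Leave-one-out cross-validation sweep
#'
#' For every specimen x representation x load type, assigns the left-out
#' specimen the element-wise median stiffness of the other specimens'
#' converged fits (no re-optimisation), solves the equilibrium at that
#' specimen's load case, and collects the kinematic errors. Cells whose
#' donor pool is too small are recorded as skipped rather than aborting the
#' sweep.
#'
#' @param specimens Named list, one element per specimen, each a list with
#'   `model` (a [spine_model]) and `loads`: a named list per load type with
#'   elements `load` (a [load_case]) and `measured` ([joint_rotations]).
#' @param fits Nested named list `fits[[representation]][[load_type]]
#'   [[specimen]]` of [optimize_stiffness()] results.
#' @return List with `errors` (combined [error_table()] rows,
#'   `model_type = "cross_validation"`), `n_simulations`, and `skipped`.
#' @export
run_cross_validation <- function(specimens, fits) {
  rows <- list()
  skipped <- list()
  n_sim <- 0L
  for (rep_name in names(fits)) {
    for (lt in names(fits[[rep_name]])) {
      cell_fits <- fits[[rep_name]][[lt]]
      for (sp in names(specimens)) {
        tab <- tryCatch(loo_median_stiffness(cell_fits, sp),
                        error = function(e) e)
        if (inherits(tab, "error")) {
          skipped[[length(skipped) + 1L]] <- list(
            specimen = sp, representation = rep_name, load_type = lt,
            reason = conditionMessage(tab))
          next
        }
        spec_data <- specimens[[sp]]
        model <- spec_data$model
        model$stiffness <- tab
        pred <- tryCatch(solve_equilibrium(model, spec_data$loads[[lt]]$load),
                         error = function(e) e)
        if (inherits(pred, "error")) {
          skipped[[length(skipped) + 1L]] <- list(
            specimen = sp, representation = rep_name, load_type = lt,
            reason = conditionMessage(pred))
          next
        }
        n_sim <- n_sim + 1L
        rows[[length(rows) + 1L]] <- error_table(
          pred, spec_data$loads[[lt]]$measured, specimen = sp,
          model_type = "cross_validation", representation = rep_name,
          load_type = lt)
      }
    }
  }
  list(errors = if (length(rows)) do.call(rbind, rows) else NULL,
       n_simulations = n_sim, skipped = skipped)
}
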