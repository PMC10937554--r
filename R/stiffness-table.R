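#' Per-level intervertebral joint stiffness table
#'
#' A stiffness table holds, for each of the six T12-sacrum joint levels, the
#' three diagonal rotational stiffnesses (Nm/rad; lateral bending, axial
#' rotation, flexion/extension) and the three translational stiffnesses (N/m).
#' The joint is modelled as an uncoupled 6-DoF bushing, so the table fully
#' parameterises its elastic behaviour.
#'
#' @param k_rot Numeric 6 x 3 matrix of rotational stiffnesses (Nm/rad), rows
#'   in bottom-up level order ([ivj_levels()]), columns `lb`, `ar`, `fe`.
#'   A single 3-vector is recycled to all levels (a uniform table).
#' @param k_trans Translational stiffnesses (N/m), same shape rules as
#'   `k_rot`. Defaults to 4e5 N/m on every axis; under a pure moment the
#'   translational springs carry no load, so this default does not affect
#'   flexibility-test results.
#' @return An object of class `stiffness_table`: a list with elements
#'   `levels`, `k_rot` and `k_trans`.
#' @examples
#' stiffness_table(c(68.8, 291, 51.0))
#' @export
stiffness_table <- function(k_rot, k_trans = 4e5) {
  k_rot <- as_level_matrix(k_rot, "k_rot")
  k_trans <- as_level_matrix(k_trans, "k_trans")
  if (any(!is.finite(k_rot)) || any(k_rot <= 0)) {
    stop("rotational stiffnesses must be finite and strictly positive",
         call. = FALSE)
  }
  if (any(!is.finite(k_trans)) || any(k_trans <= 0)) {
    stop("translational stiffnesses must be finite and strictly positive",
         call. = FALSE)
  }
  structure(
    list(levels = ivj_levels(), k_rot = k_rot, k_trans = k_trans),
    class = "stiffness_table"
  )
}

# Coerce a 3-vector or 6x3 matrix into the canonical level x dof matrix.
as_level_matrix <- function(x, what) {
  lv <- ivj_levels()
  dofs <- ivj_dofs()
  if (is.null(dim(x))) {
    if (length(x) == 1) x <- rep(x, 3)
    if (length(x) != 3) {
      stop(what, " must be a 3-vector or a 6 x 3 matrix", call. = FALSE)
    }
    m <- matrix(rep(as.numeric(x), each = 6), nrow = 6)
  } else {
    m <- as.matrix(x)
    if (!all(dim(m) == c(6, 3))) {
      stop(what, " must be a 3-vector or a 6 x 3 matrix", call. = FALSE)
    }
    if (!is.null(rownames(m))) {
      if (!setequal(rownames(m), lv)) {
        stop(what, " row names must be the six joint levels", call. = FALSE)
      }
      m <- m[lv, , drop = FALSE]
    }
    storage.mode(m) <- "double"
  }
  dimnames(m) <- list(lv, dofs)
  m
}

#' @export
print.stiffness_table <- function(x, ...) {
  cat("Intervertebral joint stiffness table (levels bottom-up)\n")
  cat("Rotational stiffness, Nm/rad:\n")
  print(round(x$k_rot, 3))
  cat("Translational stiffness, N/m:",
      paste(format(x$k_trans[1, ], digits = 4), collapse = " "),
      if (all(x$k_trans == x$k_trans[1, 1])) "(uniform)" else "", "\n")
  invisible(x)
}

#' Literature stiffness values for the lumbar spine bushing model
#'
#' Generic diagonal rotational stiffnesses commonly used to parameterise
#' lumbar intervertebral bushing joints: a uniform set (L3L4-level values
#' applied at every joint) and a level-dependent set obtained by scaling the
#' uniform values with level ratios derived from the meta-analytic
#' moment-rotation literature.
#'
#' @param representation `"uniform"` (same rotational stiffness at every
#'   level) or `"level_dependent"` (level ratios applied).
#' @return A [stiffness_table].
#' @examples
#' literature_stiffness()
#' literature_stiffness("level_dependent")
#' @export
literature_stiffness <- function(representation = c("uniform", "level_dependent")) {
  representation <- match.arg(representation)
  base <- literature_base_stiffness()
  if (representation == "uniform") {
    stiffness_table(base)
  } else {
    apply_level_ratios(base, literature_level_ratios())
  }
}

#' @rdname literature_stiffness
#' @export
literature_base_stiffness <- function() {
  c(lb = 68.8, ar = 291, fe = 51.0)
}

#' Level-dependency ratios for rotational stiffness
#'
#' Dimensionless per-level scaling factors (level value / uniform value)
#' that introduce level dependency into a uniform rotational stiffness set.
#'
#' @return A 6 x 3 matrix, rows in bottom-up level order, columns
#'   `lb`, `ar`, `fe`.
#' @export
literature_level_ratios <- function() {
  # level-dependent table over uniform row, top-down values:
  # T12L1 36.4 136.8 16.3 | L1L2 43.6 128.1 27.5 | L2L3 19.9 291.1 36.7
  # L3L4 12.4 291.1 49.5 | L4L5 13.8 291.1 50.0 | L5S1 68.8 183.4 51.0
  lev <- rbind(
    T12L1 = c(36.4, 136.8, 16.3),
    L1L2  = c(43.6, 128.1, 27.5),
    L2L3  = c(19.9, 291.1, 36.7),
    L3L4  = c(12.4, 291.1, 49.5),
    L4L5  = c(13.8, 291.1, 50.0),
    L5S1  = c(68.8, 183.4, 51.0)
  )
  base <- literature_base_stiffness()
  m <- sweep(lev[ivj_levels(), ], 2, base, "/")
  dimnames(m) <- list(ivj_levels(), ivj_dofs())
  m
}

#' Build a level-dependent stiffness table from base values and level ratios
#'
#' Multiplies a base rotational stiffness 3-vector by per-level, per-DoF
#' ratios. Translational stiffnesses are not scaled.
#'
#' @param base_k_rot Positive 3-vector of base rotational stiffnesses
#'   (Nm/rad), order (lb, ar, fe).
#' @param ratios Positive 6 x 3 matrix of dimensionless ratios (or 3-vector
#'   recycled to all levels).
#' @param k_trans Translational stiffnesses passed to [stiffness_table()].
#' @return A [stiffness_table] with `k_rot[level, dof] = ratios[level, dof] *
#'   base_k_rot[dof]`.
#' @examples
#' tab <- apply_level_ratios(literature_base_stiffness(),
#'                           literature_level_ratios())
#' tab$k_rot["T12L1", "fe"]  # 16.3
#' @export
apply_level_ratios <- function(base_k_rot, ratios, k_trans = 4e5) {
  base_k_rot <- as.numeric(base_k_rot)
  if (length(base_k_rot) != 3 || any(!is.finite(base_k_rot)) ||
      any(base_k_rot <= 0)) {
    stop("base_k_rot must be a strictly positive 3-vector", call. = FALSE)
  }
  ratios <- as_level_matrix(ratios, "ratios")
  if (any(ratios <= 0)) {
    stop("ratios must be strictly positive", call. = FALSE)
  }
  stiffness_table(sweep(ratios, 2, base_k_rot, "*"), k_trans = k_trans)
}

#' Read / write stiffness tables as CSV
#'
#' CSV columns: `level`, `k_lb_Nm_per_rad`, `k_ar_Nm_per_rad`,
#' `k_fe_Nm_per_rad`, `kt_x_N_per_m`, `kt_y_N_per_m`, `kt_z_N_per_m`; one row
#' per joint level (any order; levels must be exactly the six T12-sacrum
#' joints).
#'
#' @param path File path.
#' @return `read_stiffness_csv()` returns a [stiffness_table];
#'   `write_stiffness_csv()` returns `path` invisibly.
#' @export
read_stiffness_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("level", "k_lb_Nm_per_rad", "k_ar_Nm_per_rad", "k_fe_Nm_per_rad",
            "kt_x_N_per_m", "kt_y_N_per_m", "kt_z_N_per_m")
  if (!all(need %in% names(df))) {
    stop("stiffness CSV must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (!setequal(df$level, ivj_levels())) {
    stop("stiffness CSV levels must be exactly: ",
         paste(ivj_levels(), collapse = ", "), call. = FALSE)
  }
  rownames(df) <- df$level
  df <- df[ivj_levels(), ]
  stiffness_table(
    k_rot = as.matrix(df[, need[2:4]]),
    k_trans = as.matrix(df[, need[5:7]])
  )
}

#' @rdname read_stiffness_csv
#' @param table A [stiffness_table].
#' @export
write_stiffness_csv <- function(table, path) {
  stopifnot(inherits(table, "stiffness_table"))
  df <- data.frame(
    level = table$levels,
    k_lb_Nm_per_rad = table$k_rot[, "lb"],
    k_ar_Nm_per_rad = table$k_rot[, "ar"],
    k_fe_Nm_per_rad = table$k_rot[, "fe"],
    kt_x_N_per_m = table$k_trans[, 1],
    kt_y_N_per_m = table$k_trans[, 2],
    kt_z_N_per_m = table$k_trans[, 3]
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
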