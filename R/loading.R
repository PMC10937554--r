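# Pure-moment loading histories: parsing, cycle segmentation, and the
# extraction of the static evaluation load case with its matched kinematics.

#' Pure-moment loading history
#'
#' Time series of the three applied moment components during a flexibility
#' test. One channel carries the commanded load; the other two record the
#' coupled moments that arise from spinal geometry.
#'
#' @param time_s Strictly increasing time, seconds (>= 2 samples).
#' @param moments n x 3 matrix of moments (lb, ar, fe), Nm.
#' @param loaded_dof Which DoF carries the commanded load (`"lb"`, `"ar"`,
#'   `"fe"`, or a long label such as `"flexion"`).
#' @return Object of class `load_history`: a data frame with columns
#'   `time_s`, `m_lb_Nm`, `m_ar_Nm`, `m_fe_Nm` and attribute `loaded_dof`.
#' @export
load_history <- function(time_s, moments, loaded_dof) {
  time_s <- as.numeric(time_s)
  moments <- as.matrix(moments)
  if (length(time_s) < 2) stop("need at least 2 samples", call. = FALSE)
  if (any(diff(time_s) <= 0)) {
    stop("time must be strictly increasing", call. = FALSE)
  }
  if (ncol(moments) != 3 || nrow(moments) != length(time_s)) {
    stop("moments must be an n x 3 matrix matching time", call. = FALSE)
  }
  stopifnot_finite(moments, "moments")
  df <- data.frame(time_s = time_s, m_lb_Nm = moments[, 1],
                   m_ar_Nm = moments[, 2], m_fe_Nm = moments[, 3])
  attr(df, "loaded_dof") <- match_dof(loaded_dof)
  class(df) <- c("load_history", class(df))
  df
}

loaded_dof_of <- function(history) {
  dof <- attr(history, "loaded_dof")
  if (is.null(dof)) stop("history has no loaded_dof", call. = FALSE)
  dof
}

moment_matrix <- function(history) {
  m <- as.matrix(history[, c("m_lb_Nm", "m_ar_Nm", "m_fe_Nm")])
  colnames(m) <- ivj_dofs()
  m
}

#' Segment a loading history into cycles
#'
#' Cycles are delimited by upward zero-crossings of the loaded-DoF moment
#' channel. A cycle is complete iff it lies between two upward
#' zero-crossings and contains both a positive and a negative excursion;
#' leading and trailing part-cycles are kept but marked incomplete.
#'
#' @param history A [load_history].
#' @return A data frame of class `cycle_set` with columns `start`, `end`
#'   (half-open sample range `[start, end)`, 1-based) and `complete`.
#' @export
segment_cycles <- function(history) {
  x <- moment_matrix(history)[, loaded_dof_of(history)]
  n <- length(x)
  up <- which(x[-n] <= 0 & x[-1] > 0)  # crossing between sample i and i+1
  if (length(up) == 0) {
    warning("no zero-crossings in the loaded channel; ",
            "returning a single incomplete cycle")
    cs <- data.frame(start = 1L, end = n + 1L, complete = FALSE)
    class(cs) <- c("cycle_set", class(cs))
    return(cs)
  }
  # a crossing at samples (i, i+1) starts a cycle at the last nonpositive
  # sample i (so an exact zero sample belongs to the cycle it starts)
  starts <- up
  bounds <- c(starts, n + 1L)
  cs <- data.frame(start = integer(0), end = integer(0), complete = logical(0))
  if (starts[1] > 1L) {
    cs <- rbind(cs, data.frame(start = 1L, end = starts[1], complete = FALSE))
  }
  for (i in seq_along(starts)) {
    s <- bounds[i]; e <- bounds[i + 1]
    seg <- x[s:(e - 1L)]
    between_crossings <- i < length(starts)
    complete <- between_crossings && any(seg > 0) && any(seg < 0)
    cs <- rbind(cs, data.frame(start = s, end = e, complete = complete))
  }
  class(cs) <- c("cycle_set", class(cs))
  cs
}

#' Coupled-moment range score of a cycle
#'
#' Sum (default) or maximum, over the two non-loaded moment channels, of the
#' within-cycle range (max - min), Nm. Used to pick the evaluation cycle.
#'
#' @param history A [load_history].
#' @param start,end Half-open sample range of the cycle.
#' @param score `"sum"` or `"max"` over the two coupled channels.
#' @return Scalar score, Nm.
#' @export
coupled_range_score <- function(history, start, end, score = c("sum", "max")) {
  score <- match.arg(score)
  m <- moment_matrix(history)
  coupled <- setdiff(ivj_dofs(), loaded_dof_of(history))
  rng <- vapply(coupled, function(d) {
    v <- m[start:(end - 1L), d]
    max(v) - min(v)
  }, numeric(1))
  if (score == "sum") sum(rng) else max(rng)
}

#' Select the evaluation cycle
#'
#' Among the complete cycles, the first is excluded a priori (the initial
#' recorded load of a test is not reliably zero); of the remaining complete
#' cycles the one with the smallest coupled-moment range score is selected,
#' the earliest on ties.
#'
#' @param history A [load_history].
#' @param cycles The [segment_cycles()] output for `history`.
#' @param score Passed to [coupled_range_score()].
#' @return The row index (into `cycles`) of the selected cycle, with the
#'   per-candidate scores attached as attribute `scores`.
#' @export
select_evaluation_cycle <- function(history, cycles, score = c("sum", "max")) {
  score <- match.arg(score)
  complete_idx <- which(cycles$complete)
  if (length(complete_idx) < 2) {
    stop("insufficient data: need at least 2 complete cycles to select an ",
         "evaluation cycle (the first is excluded a priori)", call. = FALSE)
  }
  candidates <- complete_idx[-1]
  scores <- vapply(candidates, function(i) {
    coupled_range_score(history, cycles$start[i], cycles$end[i], score = score)
  }, numeric(1))
  sel <- candidates[which.min(scores)]  # which.min takes the earliest tie
  attr(sel, "scores") <- stats::setNames(scores, candidates)
  sel
}

#' Extract the static load case from a cycle
#'
#' Finds the sample within the cycle at which the loaded-DoF moment has the
#' largest magnitude, and returns the full three-component moment at that
#' sample (peak moment plus the corresponding coupled moments). No
#' interpolation: the returned moment is a sample actually present in the
#' history.
#'
#' @param history A [load_history].
#' @param cycle Either a row index into a [segment_cycles()] result passed
#'   as `cycles`, or an integer 2-vector `c(start, end)` (half-open).
#' @param cycles Optional [segment_cycles()] output when `cycle` is an index.
#' @return List with `load` (a [load_case]), `sample_index` and `time_s`.
#' @export
extract_load_case <- function(history, cycle, cycles = NULL) {
  if (length(cycle) == 1) {
    if (is.null(cycles)) stop("supply `cycles` when `cycle` is an index",
                              call. = FALSE)
    rng <- c(cycles$start[cycle], cycles$end[cycle])
  } else {
    rng <- as.integer(cycle[1:2])
  }
  if (any(is.na(rng)) || rng[2] <= rng[1]) {
    stop("empty cycle range", call. = FALSE)
  }
  dof <- loaded_dof_of(history)
  m <- moment_matrix(history)
  idx <- rng[1]:(rng[2] - 1L)
  i <- idx[which.max(abs(m[idx, dof]))]
  list(load = load_case(m[i, ], loaded_dof = dof),
       sample_index = i,
       time_s = history$time_s[i])
}

#' Joint kinematics history
#'
#' @param time_s Time axis, seconds.
#' @param rotations_deg n x 18 matrix of per-level, per-DoF rotations in
#'   degrees; columns named `<level>_<dof>_deg` (e.g. `T12L1_fe_deg`).
#' @return Object of class `kinematics_history` (a data frame).
#' @export
kinematics_history <- function(time_s, rotations_deg) {
  time_s <- as.numeric(time_s)
  rotations_deg <- as.matrix(rotations_deg)
  expected <- kinematics_columns()
  if (!identical(sort(colnames(rotations_deg)), sort(expected))) {
    stop("kinematics columns must be ",
         paste(expected, collapse = ", "), call. = FALSE)
  }
  if (nrow(rotations_deg) != length(time_s)) {
    stop("rotations must have one row per time sample", call. = FALSE)
  }
  df <- data.frame(time_s = time_s,
                   rotations_deg[, expected, drop = FALSE],
                   check.names = FALSE)
  class(df) <- c("kinematics_history", class(df))
  df
}

kinematics_columns <- function() {
  as.vector(t(outer(ivj_levels(), ivj_dofs(),
                    function(l, d) paste0(l, "_", d, "_deg"))))
}

#' Measured joint rotations at the load-case instant
#'
#' Reads the per-level rotations at the selected load-case sample. When the
#' kinematics time axis differs from the load history's, the rotations are
#' linearly interpolated at the load-case time.
#'
#' @param kin A [kinematics_history].
#' @param sample_index Sample index into the paired load history.
#' @param history Optional paired [load_history]; required when the time
#'   grids differ (supplies the load-case time for interpolation).
#' @return A [joint_rotations] object (degrees).
#' @export
kinematics_at_load_case <- function(kin, sample_index, history = NULL) {
  cols <- kinematics_columns()
  same_grid <- is.null(history) ||
    (nrow(kin) == nrow(history) &&
       isTRUE(all.equal(kin$time_s, history$time_s, tolerance = 1e-12)))
  if (same_grid) {
    if (sample_index < 1 || sample_index > nrow(kin)) {
      stop("sample index out of range", call. = FALSE)
    }
    vals <- as.numeric(kin[sample_index, cols])
  } else {
    t0 <- history$time_s[sample_index]
    if (is.na(t0) || t0 < min(kin$time_s) || t0 > max(kin$time_s)) {
      stop("load-case time outside the kinematics time axis", call. = FALSE)
    }
    vals <- vapply(cols, function(cl) {
      stats::approx(kin$time_s, kin[[cl]], xout = t0)$y
    }, numeric(1))
  }
  joint_rotations(matrix(vals, nrow = 6, ncol = 3, byrow = TRUE,
                         dimnames = list(ivj_levels(), ivj_dofs())))
}

#' Read / write load-history CSVs
#'
#' CSV columns `time_s`, `m_lb_Nm`, `m_ar_Nm`, `m_fe_Nm`; the loaded DoF is
#' stored in a sidecar JSON file `<path>.json`.
#'
#' @param path CSV file path.
#' @param loaded_dof Fallback loaded-DoF label when no sidecar exists.
#' @return `read_load_history_csv()` returns a [load_history].
#' @export
read_load_history_csv <- function(path, loaded_dof = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar)
    loaded_dof <- meta$loaded_dof %||% loaded_dof
  }
  if (is.null(loaded_dof)) {
    stop("loaded_dof not given and no sidecar JSON found", call. = FALSE)
  }
  load_history(df$time_s,
               as.matrix(df[, c("m_lb_Nm", "m_ar_Nm", "m_fe_Nm")]),
               loaded_dof)
}

#' @rdname read_load_history_csv
#' @param history A [load_history].
#' @export
write_load_history_csv <- function(history, path) {
  utils::write.csv(as.data.frame(history), path, row.names = FALSE,
                   quote = FALSE)
  jsonlite::write_json(list(loaded_dof = loaded_dof_of(history)),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' Read / write kinematics CSVs
#'
#' CSV column `time_s` followed by the 18 `<level>_<dof>_deg` columns.
#'
#' @param path CSV file path.
#' @return `read_kinematics_csv()` returns a [kinematics_history].
#' @export
read_kinematics_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  kinematics_history(df$time_s, as.matrix(df[, kinematics_columns()]))
}

#' @rdname read_kinematics_csv
#' @param kin A [kinematics_history].
#' @export
write_kinematics_csv <- function(kin, path) {
  utils::write.csv(as.data.frame(kin), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
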