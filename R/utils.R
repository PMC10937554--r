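# Internal helpers shared across the package.

#' Joint levels of the T12-sacrum chain, ordered bottom-up (sacrum end first)
#'
#' @return Character vector of the six intervertebral joint labels,
#'   `"L5S1"` first (adjacent to the fixed sacrum) up to `"T12L1"`.
#' @export
ivj_levels <- function() c("L5S1", "L4L5", "L3L4", "L2L3", "L1L2", "T12L1")

#' Rotational degrees of freedom, in canonical order
#'
#' The order (lateral bending, axial rotation, flexion/extension) is used for
#' every 3-vector and matrix column in the package. Left lateral bending, left
#' axial rotation and flexion are positive.
#'
#' @return `c("lb", "ar", "fe")`.
#' @export
ivj_dofs <- function() c("lb", "ar", "fe")

`%||%` <- function(a, b) if (is.null(a)) b else a

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

# Map user-facing DoF labels ("flexion", "lateral_bending", "FE", ...) onto
# the canonical short codes.
match_dof <- function(dof) {
  key <- tolower(gsub("[^a-z]", "", tolower(as.character(dof))))
  lut <- c(
    lb = "lb", lateralbending = "lb", lateral = "lb", rightleftbending = "lb",
    ar = "ar", axialrotation = "ar", axial = "ar",
    fe = "fe", flexion = "fe", flexionextension = "fe", extension = "fe"
  )
  out <- unname(lut[key])
  if (any(is.na(out))) {
    stop("unknown degree-of-freedom label: ",
         paste(dof[is.na(out)], collapse = ", "), call. = FALSE)
  }
  out
}

# Deterministic substream seed derived from a master seed and integer ids;
# kept below 2^31 so it is a valid R integer seed.
derive_seed <- function(seed, ...) {
  ids <- c(...)
  x <- as.double(seed) %% 2147483647
  for (id in ids) {
    x <- (x * 69069 + as.double(id) * 7919 + 1) %% 2147483647
  }
  as.integer(x)
}

stopifnot_finite <- function(x, what) {
  if (!all(is.finite(x))) stop(what, " must be finite", call. = FALSE)
  invisible(x)
}
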