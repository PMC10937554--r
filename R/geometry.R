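# Landmark geometry: sagittal-plane fitting and anatomical joint frames.
#
# Global coordinate convention (right-handed, mm):
#   x = +posterior, y = +superior, z = +left.
# With this choice the rotational DoF axes coincide with the coordinate axes
# in canonical pose (lateral bending about x, axial rotation about y, flexion
# about z) and left lateral bending, left axial rotation and flexion are all
# positive rotations.

#' Total-least-squares plane fit to anatomical landmarks
#'
#' Fits the plane minimising the sum of squared perpendicular distances to a
#' set of 3D landmarks (orthogonal regression via eigen-decomposition of the
#' centred scatter matrix). Used to define the sagittal plane of the spine
#' from midline landmarks.
#'
#' @param landmarks An n x 3 numeric matrix of positions (mm), or a data
#'   frame with columns `x_mm`, `y_mm`, `z_mm`.
#' @return A list with `normal` (unit 3-vector) and `point` (the centroid, a
#'   point on the plane). Sign convention: the normal has nonnegative
#'   component along the global left axis (z); if that component is zero the
#'   sign is chosen toward +anterior (-x), then toward +superior.
#' @examples
#' fit_sagittal_plane(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)))
#' @export
fit_sagittal_plane <- function(landmarks) {
  pts <- landmark_positions(landmarks)
  if (nrow(pts) < 3) {
    stop("plane fit needs at least 3 landmarks", call. = FALSE)
  }
  stopifnot_finite(pts, "landmark positions")
  ctr <- colMeans(pts)
  x <- sweep(pts, 2, ctr)
  ev <- eigen(crossprod(x), symmetric = TRUE)
  # rank < 2 in the plane directions => collinear landmark set
  if (ev$values[2] <= max(ev$values[1], 1) * 1e-12) {
    stop("degenerate landmark set: points are collinear, plane is undefined",
         call. = FALSE)
  }
  n <- ev$vectors[, 3]
  n <- n / sqrt(sum(n^2))
  tol <- 1e-12
  s <- if (abs(n[3]) > tol) sign(n[3])
       else if (abs(n[1]) > tol) -sign(n[1])  # +anterior is -x
       else sign(n[2])
  if (s < 0) n <- -n
  list(normal = as.numeric(n), point = as.numeric(ctr))
}

landmark_positions <- function(landmarks) {
  if (is.data.frame(landmarks)) {
    need <- c("x_mm", "y_mm", "z_mm")
    if (!all(need %in% names(landmarks))) {
      stop("landmark data frame needs columns x_mm, y_mm, z_mm",
           call. = FALSE)
    }
    as.matrix(landmarks[, need])
  } else {
    m <- as.matrix(landmarks)
    if (ncol(m) != 3) stop("landmarks must be n x 3", call. = FALSE)
    m
  }
}

#' Build anatomical joint frames from endplate landmarks
#'
#' Constructs one joint frame per intervertebral level from the four
#' endplate landmarks bounding the joint: the anterior and posterior points
#' of the superior endplate of the lower vertebra (`sup_ant`, `sup_post`)
#' and of the inferior endplate of the upper vertebra (`inf_ant`,
#' `inf_post`). The construction is a simplified anatomical-frame recipe:
#'
#' * origin: centroid of the four landmarks;
#' * flexion axis: the left-right direction, i.e. the unit normal of the
#'   sagittal plane fitted to all landmarks (or `sagittal_normal` if given);
#' * axial axis: the mean of the two endplate normals, orthogonalised
#'   against the flexion axis;
#' * lateral-bending axis: completes the right-handed triad.
#'
#' @param landmarks Data frame with columns `vertebra_id` (one of `sacrum`,
#'   `L5` ... `L1`, `T12`), `landmark_name` (`sup_ant`, `sup_post`,
#'   `inf_ant`, `inf_post`), `x_mm`, `y_mm`, `z_mm`.
#' @param sagittal_normal Optional unit 3-vector overriding the fitted
#'   sagittal-plane normal (useful when the sagittal plane is known).
#' @return A named list of six joint frames in bottom-up level order; each
#'   frame is a list with `origin` (3-vector, mm) and `orientation` (proper
#'   3 x 3 rotation whose columns are the lateral-bending, axial-rotation
#'   and flexion axes).
#' @export
build_joint_frames <- function(landmarks, sagittal_normal = NULL) {
  stopifnot(is.data.frame(landmarks))
  need <- c("vertebra_id", "landmark_name", "x_mm", "y_mm", "z_mm")
  if (!all(need %in% names(landmarks))) {
    stop("landmark data frame needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  vertebrae <- c("sacrum", "L5", "L4", "L3", "L2", "L1", "T12")
  get_pt <- function(vid, name) {
    row <- landmarks$vertebra_id == vid & landmarks$landmark_name == name
    if (sum(row) != 1) {
      stop("missing or duplicated landmark '", name, "' for vertebra '",
           vid, "'", call. = FALSE)
    }
    as.numeric(landmarks[row, c("x_mm", "y_mm", "z_mm")])
  }
  e_fe <- if (is.null(sagittal_normal)) {
    fit_sagittal_plane(landmarks[, c("x_mm", "y_mm", "z_mm")])$normal
  } else {
    v <- as.numeric(sagittal_normal)
    v / sqrt(sum(v^2))
  }

  frames <- vector("list", 6)
  names(frames) <- ivj_levels()
  for (j in seq_len(6)) {
    lower <- vertebrae[j]
    upper <- vertebrae[j + 1]
    p <- list(
      sa = get_pt(lower, "sup_ant"), sp = get_pt(lower, "sup_post"),
      ia = get_pt(upper, "inf_ant"), ip = get_pt(upper, "inf_post")
    )
    origin <- (p$sa + p$sp + p$ia + p$ip) / 4
    a1 <- p$sa - p$sp
    a2 <- p$ia - p$ip
    if (sqrt(sum(a1^2)) < 1e-9 || sqrt(sum(a2^2)) < 1e-9) {
      stop("degenerate endplate landmarks (coincident points) at joint ",
           ivj_levels()[j], call. = FALSE)
    }
    n1 <- cross3(a1 / sqrt(sum(a1^2)), e_fe)
    n2 <- cross3(a2 / sqrt(sum(a2^2)), e_fe)
    e_ar <- n1 + n2
    e_ar <- e_ar - sum(e_ar * e_fe) * e_fe
    nrm <- sqrt(sum(e_ar^2))
    if (nrm < 1e-9) {
      stop("degenerate endplate geometry at joint ", ivj_levels()[j],
           call. = FALSE)
    }
    e_ar <- e_ar / nrm
    e_lb <- cross3(e_ar, e_fe)
    frames[[j]] <- joint_frame(origin, cbind(e_lb, e_ar, e_fe))
  }
  frames
}

joint_frame <- function(origin, orientation) {
  orientation <- as.matrix(orientation)
  dimnames(orientation) <- list(NULL, ivj_dofs())
  err <- max(abs(crossprod(orientation) - diag(3)))
  if (err > 1e-9 || abs(det(orientation) - 1) > 1e-9) {
    stop("joint frame orientation is not a proper rotation (error ",
         format(err, digits = 3), ")", call. = FALSE)
  }
  list(origin = as.numeric(origin), orientation = orientation)
}

#' Identity joint frames
#'
#' Frames aligned with the global axes at stacked origins; the default for
#' synthetic cohorts, where the mechanics do not depend on vertebral
#' geometry.
#'
#' @param spacing Vertical spacing between joint origins, mm.
#' @return Named list of six joint frames (see [build_joint_frames()]).
#' @export
identity_frames <- function(spacing = 35) {
  frames <- lapply(seq_len(6), function(j) {
    joint_frame(c(0, (j - 1) * spacing, 0), diag(3))
  })
  names(frames) <- ivj_levels()
  frames
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Read a landmark CSV
#'
#' Columns: `vertebra_id`, `landmark_name`, `x_mm`, `y_mm`, `z_mm`.
#'
#' @param path File path.
#' @return Data frame of landmarks.
#' @export
read_landmarks_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("vertebra_id", "landmark_name", "x_mm", "y_mm", "z_mm")
  if (!all(need %in% names(df))) {
    stop("landmark CSV must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  df
}
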