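# Quasi-static serial-chain spine mechanics with 6-DoF bushing joints.

#' Bushing damping constants
#'
#' Damping for the spring-damper (bushing) joint elements. Defaults are the
#' literature constants used for lumbar bushing models: 2.3 Nm/(rad/s)
#' rotational, 1000 N/(m/s) translational. Damping does not affect the
#' quasi-static equilibrium; it sets the relaxation rate of the
#' `dynamic_relaxation` solver.
#'
#' @param c_rot Rotational damping, Nm/(rad/s) (scalar or 3-vector).
#' @param c_trans Translational damping, N/(m/s) (scalar or 3-vector).
#' @return Object of class `damping_table`.
#' @export
damping_table <- function(c_rot = 2.3, c_trans = 1000) {
  c_rot <- rep_len(as.numeric(c_rot), 3)
  c_trans <- rep_len(as.numeric(c_trans), 3)
  if (any(!is.finite(c(c_rot, c_trans))) || any(c(c_rot, c_trans) < 0)) {
    stop("damping constants must be finite and nonnegative", call. = FALSE)
  }
  structure(list(c_rot = c_rot, c_trans = c_trans), class = "damping_table")
}

#' Construct a T12-sacrum spine model
#'
#' A serial chain of six rigid vertebral bodies above a fully constrained
#' sacrum, connected by 6-DoF joints with uncoupled linear bushing
#' stiffness. The model is massless and quasi-static: under a pure moment
#' the equilibrium joint rotations balance the applied couple against the
#' rotational springs, and the translational springs stay unloaded.
#'
#' @param stiffness A [stiffness_table].
#' @param damping A [damping_table].
#' @param frames Named list of six joint frames in bottom-up order (see
#'   [build_joint_frames()]); defaults to identity frames.
#' @param solver_mode Equilibrium solution strategy:
#'   `"small_angle_global"` (linear solve with frames fixed in the global
#'   frame), `"frame_propagating"` (finite rotations, each joint frame
#'   carried by its parent body, solved bottom-up), or
#'   `"dynamic_relaxation"` (damped first-order relaxation to the same
#'   fixed-frame balance).
#' @param tol Equilibrium residual tolerance, Nm.
#' @return Object of class `spine_model`.
#' @examples
#' m <- spine_model(literature_stiffness())
#' solve_equilibrium(m, load_case(c(0, 0, 7.5)))
#' @export
spine_model <- function(stiffness,
                        damping = damping_table(),
                        frames = identity_frames(),
                        solver_mode = c("small_angle_global",
                                        "frame_propagating",
                                        "dynamic_relaxation"),
                        tol = 1e-10) {
  solver_mode <- match.arg(solver_mode)
  stopifnot(inherits(stiffness, "stiffness_table"),
            inherits(damping, "damping_table"))
  if (length(frames) != 6) {
    stop("a spine model has exactly 6 joints (one per level)", call. = FALSE)
  }
  frames <- lapply(frames, function(f) joint_frame(f$origin, f$orientation))
  names(frames) <- ivj_levels()
  structure(
    list(stiffness = stiffness, damping = damping, frames = frames,
         solver_mode = solver_mode, tol = tol),
    class = "spine_model"
  )
}

#' @export
print.spine_model <- function(x, ...) {
  cat("Quasi-static T12-sacrum spine model (sacrum fixed)\n")
  cat("  solver_mode:", x$solver_mode, " tol:", format(x$tol), "Nm\n")
  print(x$stiffness)
  invisible(x)
}

#' Pure-moment load case
#'
#' A static three-component moment applied as a pure couple to the topmost
#' body (T12). A pure couple transmits unchanged along the unloaded chain,
#' so every joint sees the same global moment.
#'
#' @param moment 3-vector (M_lb, M_ar, M_fe), Nm.
#' @param loaded_dof Optional label of the commanded DoF (`"lb"`, `"ar"`,
#'   `"fe"`); the other components are coupled moments.
#' @return Object of class `load_case`.
#' @export
load_case <- function(moment, loaded_dof = NULL) {
  moment <- as.numeric(moment)
  if (length(moment) != 3) stop("moment must be a 3-vector", call. = FALSE)
  stopifnot_finite(moment, "moment")
  names(moment) <- ivj_dofs()
  if (!is.null(loaded_dof)) loaded_dof <- match_dof(loaded_dof)
  structure(list(moment = moment, loaded_dof = loaded_dof),
            class = "load_case")
}

as_load_case <- function(load) {
  if (inherits(load, "load_case")) load else load_case(load)
}

#' Per-level joint rotations
#'
#' @param deg 6 x 3 matrix of rotations in degrees (rows: levels bottom-up;
#'   columns lb, ar, fe), or a 3-vector recycled to all levels.
#' @return Object of class `joint_rotations` (a 6 x 3 matrix, degrees).
#' @export
joint_rotations <- function(deg) {
  if (is.null(dim(deg))) {
    if (length(deg) == 1) deg <- rep(deg, 3)
    deg <- matrix(rep(as.numeric(deg), each = 6), 6)
  }
  m <- as.matrix(deg)
  stopifnot(all(dim(m) == c(6, 3)))
  dimnames(m) <- list(ivj_levels(), ivj_dofs())
  class(m) <- c("joint_rotations", class(m))
  m
}

#' @export
print.joint_rotations <- function(x, ...) {
  cat("Joint rotations, degrees (levels bottom-up):\n")
  print(round(unclass(x), 4))
  invisible(x)
}

rotations_matrix <- function(x) {
  m <- unclass(x)
  stopifnot(all(dim(m) == c(6, 3)))
  dimnames(m) <- list(ivj_levels(), ivj_dofs())
  m
}

# Body-fixed rotation sequence flexion -> lateral bending -> axial rotation,
# angles in radians in joint-local axes (x = lb, y = ar, z = fe).
rotation_from_angles <- function(theta) {
  cf <- cos(theta[3]); sf <- sin(theta[3])
  cl <- cos(theta[1]); sl <- sin(theta[1])
  ca <- cos(theta[2]); sa <- sin(theta[2])
  Rz <- matrix(c(cf, sf, 0, -sf, cf, 0, 0, 0, 1), 3)      # flexion (z)
  Rx <- matrix(c(1, 0, 0, 0, cl, sl, 0, -sl, cl), 3)      # lateral bending (x)
  Ry <- matrix(c(ca, 0, -sa, 0, 1, 0, sa, 0, ca), 3)      # axial rotation (y)
  Rz %*% Rx %*% Ry
}

#' Solve the quasi-static equilibrium under a pure moment
#'
#' Finds the joint rotations at which the rotational bushing moment balances
#' the applied couple expressed in each joint's frame. Translational joint
#' displacements are identically zero under a pure couple (no net force, so
#' the translational springs are unloaded).
#'
#' @param model A [spine_model].
#' @param load A [load_case] (or 3-vector of moments, Nm).
#' @return A [joint_rotations] object (degrees), with attribute `residual`
#'   (per-joint residual norms, Nm) and, for `dynamic_relaxation`,
#'   `converged` / `iterations`.
#' @examples
#' m <- spine_model(stiffness_table(c(68.8, 291, 51.0)))
#' th <- solve_equilibrium(m, load_case(c(0, 0, 7.5)))
#' th["T12L1", "fe"]  # 7.5/51 rad in degrees
#' @export
solve_equilibrium <- function(model, load) {
  stopifnot(inherits(model, "spine_model"))
  load <- as_load_case(load)
  M <- load$moment
  k <- model$stiffness$k_rot
  if (any(k <= 0)) stop("singular stiffness", call. = FALSE)

  theta <- matrix(0, 6, 3)  # radians
  if (model$solver_mode == "small_angle_global") {
    for (j in seq_len(6)) {
      A <- model$frames[[j]]$orientation
      theta[j, ] <- crossprod(A, M) / k[j, ]
    }
  } else if (model$solver_mode == "frame_propagating") {
    R_parent <- diag(3)
    for (j in seq_len(6)) {
      A <- model$frames[[j]]$orientation
      frame_cur <- R_parent %*% A
      theta[j, ] <- crossprod(frame_cur, M) / k[j, ]
      R_parent <- R_parent %*% A %*% rotation_from_angles(theta[j, ]) %*% t(A)
    }
  } else {  # dynamic_relaxation
    c_rot <- model$damping$c_rot
    m_loc <- t(vapply(model$frames,
                      function(f) as.numeric(crossprod(f$orientation, M)),
                      numeric(3)))
    cmat <- matrix(rep(c_rot, each = 6), 6)
    dt <- 0.9 * min(cmat / k)
    cap <- 1e6
    it <- 0
    repeat {
      resid <- m_loc - k * theta
      if (max(abs(resid)) <= model$tol) break
      if (it >= cap) {
        warning("dynamic relaxation did not converge within ", cap,
                " iterations (max residual ",
                format(max(abs(resid)), digits = 3), " Nm)")
        break
      }
      theta <- theta + dt * resid / cmat
      it <- it + 1
    }
  }

  out <- joint_rotations(rad2deg(theta))
  res <- equilibrium_residual(model, out, load)
  attr(out, "residual") <- res
  # a pure couple carries no net force: translational springs stay unloaded
  attr(out, "translations_mm") <- matrix(0, 6, 3,
                                         dimnames = list(ivj_levels(), NULL))
  if (model$solver_mode == "dynamic_relaxation") {
    attr(out, "converged") <- max(res) <= model$tol
    attr(out, "iterations") <- it
  }
  out
}

#' Moment-balance residual of a candidate solution
#'
#' Evaluates, per joint, the Euclidean norm of the imbalance between the
#' rotational bushing moment and the applied couple expressed in the joint
#' frame, under the model's solver-mode conventions. The output of
#' [solve_equilibrium()] satisfies `max(residual) <= model$tol`.
#'
#' @param model A [spine_model].
#' @param rotations A [joint_rotations] object (degrees).
#' @param load A [load_case] or moment 3-vector.
#' @return Numeric vector of six per-joint residual norms, Nm.
#' @export
equilibrium_residual <- function(model, rotations, load) {
  stopifnot(inherits(model, "spine_model"))
  load <- as_load_case(load)
  M <- load$moment
  theta <- deg2rad(rotations_matrix(rotations))
  k <- model$stiffness$k_rot
  res <- numeric(6)
  R_parent <- diag(3)
  for (j in seq_len(6)) {
    A <- model$frames[[j]]$orientation
    if (model$solver_mode == "frame_propagating") {
      frame_cur <- R_parent %*% A
      R_parent <- R_parent %*% A %*% rotation_from_angles(theta[j, ]) %*% t(A)
    } else {
      frame_cur <- A
    }
    imbalance <- k[j, ] * theta[j, ] - as.numeric(crossprod(frame_cur, M))
    res[j] <- sqrt(sum(imbalance^2))
  }
  names(res) <- ivj_levels()
  res
}
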