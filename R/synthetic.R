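# Synthetic specimen cohorts with known ground-truth stiffnesses and
# simulated pure-moment flexibility-test data.

#' Configuration of the synthetic cohort generator
#'
#' Defaults emulate the conditions of a cadaveric T12-sacrum flexibility
#' study: six specimens; per-level diagonal rotational stiffness drawn
#' around generic lumbar literature values with substantial inter-specimen
#' spread; 3.5 pure-moment loading cycles to a 7.5 Nm peak at 1.0 deg/s
#' (flexion, lateral bending) and 0.5 deg/s (axial rotation); small coupled
#' moments in the unloaded directions; additive motion-capture-scale noise
#' on the joint angles.
#'
#' @param seed Master seed; every stochastic path of the generator is
#'   derived deterministically from it (mandatory).
#' @param n_specimens Cohort size.
#' @param base_means Mean base rotational stiffness per DoF, Nm/rad.
#' @param cv Inter-specimen coefficient of variation of the base stiffness
#'   per DoF (lognormal).
#' @param ratios True level-ratio table (6 x 3); default the literature
#'   level ratios.
#' @param ratio_jitter_sd Lognormal sigma of the per-level ratio jitter that
#'   creates mismatch with the fixed-ratio assumption (0 = exact ratios).
#' @param peak_moment Peak applied moment, Nm.
#' @param n_cycles Number of loading cycles.
#' @param rate_deg_s Named motion rates, deg/s, per loaded DoF.
#' @param coupled_fraction Amplitude of the coupled moments as a fraction of
#'   the peak moment.
#' @param noise_sd_deg SD of the i.i.d. Gaussian joint-angle noise, degrees.
#' @param sample_rate_hz Sampling rate of the generated histories.
#' @param k_trans Translational stiffness, N/m.
#' @param solver_mode Solver used both to generate and to fit.
#' @return Object of class `generator_config`.
#' @export
generator_config <- function(seed,
                             n_specimens = 6,
                             base_means = c(lb = 68.8, ar = 291, fe = 51.0),
                             cv = c(lb = 0.25, ar = 0.25, fe = 0.25),
                             ratios = literature_level_ratios(),
                             ratio_jitter_sd = 0.10,
                             peak_moment = 7.5,
                             n_cycles = 3.5,
                             rate_deg_s = c(lb = 1.0, ar = 0.5, fe = 1.0),
                             coupled_fraction = 0.05,
                             noise_sd_deg = 0.1,
                             sample_rate_hz = 100,
                             k_trans = 4e5,
                             solver_mode = "small_angle_global") {
  if (missing(seed)) stop("a seed is mandatory", call. = FALSE)
  cfg <- list(seed = as.integer(seed), n_specimens = as.integer(n_specimens),
              base_means = stats::setNames(rep_len(base_means, 3), ivj_dofs()),
              cv = stats::setNames(rep_len(cv, 3), ivj_dofs()),
              ratios = as_level_matrix(ratios, "ratios"),
              ratio_jitter_sd = ratio_jitter_sd,
              peak_moment = peak_moment, n_cycles = n_cycles,
              rate_deg_s = stats::setNames(rep_len(rate_deg_s, 3), ivj_dofs()),
              coupled_fraction = coupled_fraction,
              noise_sd_deg = noise_sd_deg,
              sample_rate_hz = sample_rate_hz, k_trans = k_trans,
              solver_mode = solver_mode)
  pos <- c(cfg$base_means, cfg$peak_moment, cfg$n_cycles, cfg$rate_deg_s,
           cfg$sample_rate_hz, cfg$k_trans)
  if (any(!is.finite(pos)) || any(pos <= 0)) {
    stop("generator config values must be positive", call. = FALSE)
  }
  if (cfg$ratio_jitter_sd < 0 || cfg$coupled_fraction < 0 ||
      cfg$noise_sd_deg < 0 || cfg$cv[1] < 0) {
    stop("spreads and noise must be nonnegative", call. = FALSE)
  }
  class(cfg) <- "generator_config"
  cfg
}

with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv())
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  force(expr)
}

#' Draw a specimen's true stiffness table
#'
#' Base per-DoF values are lognormal with mean `config$base_means` and the
#' configured coefficient of variation; per-level values are the base times
#' the true ratio table times a lognormal per-level jitter (mean 1, sigma
#' `ratio_jitter_sd`). Fully determined by `(config, specimen_index)`.
#'
#' @param config A [generator_config].
#' @param specimen_index Integer specimen index.
#' @return A [stiffness_table] with attributes `base` (the drawn base
#'   3-vector) and `true_ratios` (the jittered per-level ratio matrix).
#' @export
sample_true_stiffness <- function(config, specimen_index) {
  stopifnot(inherits(config, "generator_config"))
  with_local_seed(derive_seed(config$seed, 101, specimen_index), {
    sdlog <- sqrt(log(1 + config$cv^2))
    meanlog <- log(config$base_means) - sdlog^2 / 2
    base <- stats::rlnorm(3, meanlog, sdlog)
    names(base) <- ivj_dofs()
    jitter <- if (config$ratio_jitter_sd > 0) {
      s <- config$ratio_jitter_sd
      matrix(stats::rlnorm(18, -s^2 / 2, s), 6, 3)
    } else {
      matrix(1, 6, 3)
    }
    true_ratios <- config$ratios * jitter
    tab <- apply_level_ratios(base, true_ratios, k_trans = config$k_trans)
    attr(tab, "base") <- base
    attr(tab, "true_ratios") <- true_ratios
    tab
  })
}

#' Generate a pure-moment loading history
#'
#' The loaded channel is a triangular (constant-rate) wave of `n_cycles`
#' cycles peaking at +/- `peak_moment`; its period is set so that the
#' constant rotation rate of the (noiseless) true model matches the
#' configured motion rate for that direction. The quarter period is rounded
#' to a whole number of samples so the peak lies exactly on a sample. The
#' coupled channels are sinusoids with the loaded period, amplitude
#' `coupled_fraction * peak_moment`, and seeded random phases.
#'
#' @param config A [generator_config].
#' @param load_type Loaded DoF (`"lb"`, `"ar"`, `"fe"` or long label).
#' @param stiffness Optional [stiffness_table] of the true model used to set
#'   the period (default: literature ratios at the configured base means).
#' @param specimen_index Used (with `load_type`) to derive the phase seed.
#' @return A [load_history].
#' @export
generate_load_history <- function(config, load_type, stiffness = NULL,
                                  specimen_index = 0) {
  stopifnot(inherits(config, "generator_config"))
  dof <- match_dof(load_type)
  if (is.null(stiffness)) {
    stiffness <- apply_level_ratios(config$base_means, config$ratios,
                                    k_trans = config$k_trans)
  }
  # total rotation at peak moment in the loaded DoF, degrees
  rom <- sum(rad2deg(config$peak_moment / stiffness$k_rot[, dof]))
  dt <- 1 / config$sample_rate_hz
  n_q <- max(2L, as.integer(round((rom / config$rate_deg_s[dof]) / dt)))
  n <- as.integer(round(4 * n_q * config$n_cycles)) + 1L
  s <- seq_len(n) - 1L
  ph <- (s %% (4 * n_q)) / n_q  # cycle phase in [0, 4)
  tri <- ifelse(ph < 1, ph, ifelse(ph < 3, 2 - ph, ph - 4))
  loaded <- config$peak_moment * tri
  time_s <- s * dt

  moments <- matrix(0, n, 3)
  colnames(moments) <- ivj_dofs()
  moments[, dof] <- loaded
  coupled <- setdiff(ivj_dofs(), dof)
  if (config$coupled_fraction > 0) {
    phases <- with_local_seed(
      derive_seed(config$seed, 202, specimen_index, match(dof, ivj_dofs())),
      stats::runif(2, 0, 2 * pi))
    period <- 4 * n_q * dt
    for (i in 1:2) {
      moments[, coupled[i]] <- config$coupled_fraction * config$peak_moment *
        sin(2 * pi * time_s / period + phases[i])
    }
  }
  load_history(time_s, moments, dof)
}

#' Simulate the kinematics of a flexibility test
#'
#' Solves the quasi-static equilibrium of the specimen model at every sample
#' of the loading history and adds i.i.d. Gaussian joint-angle noise. The
#' noiseless rotations are retrievable from the `noiseless` attribute.
#'
#' @param model A [spine_model] (the specimen's true model).
#' @param history A [load_history].
#' @param noise_sd_deg Noise SD, degrees (0 = noiseless).
#' @param seed Seed for the noise draws.
#' @return A [kinematics_history] with attribute `noiseless` (n x 18 matrix,
#'   degrees).
#' @export
simulate_flexibility_test <- function(model, history, noise_sd_deg = 0,
                                      seed = 1) {
  stopifnot(inherits(model, "spine_model"), inherits(history, "load_history"))
  M <- moment_matrix(history)
  n <- nrow(M)
  k <- model$stiffness$k_rot
  out <- matrix(0, n, 18)
  colnames(out) <- kinematics_columns()
  if (model$solver_mode == "small_angle_global") {
    for (j in seq_len(6)) {
      A <- model$frames[[j]]$orientation
      loc <- M %*% A  # n x 3 local moments
      cols <- paste0(ivj_levels()[j], "_", ivj_dofs(), "_deg")
      out[, cols] <- rad2deg(sweep(loc, 2, k[j, ], "/"))
    }
  } else {
    for (i in seq_len(n)) {
      th <- solve_equilibrium(model, load_case(M[i, ]))
      out[i, ] <- as.vector(t(rotations_matrix(th)))
    }
  }
  noiseless <- out
  if (noise_sd_deg > 0) {
    out <- out + with_local_seed(seed,
      matrix(stats::rnorm(n * 18, 0, noise_sd_deg), n, 18))
  }
  kin <- kinematics_history(history$time_s, out)
  attr(kin, "noiseless") <- noiseless
  kin
}

#' Build one synthetic specimen
#'
#' @param config A [generator_config].
#' @param specimen_index Integer index.
#' @return List with `id`, `true_stiffness` (with `base` / `true_ratios`
#'   attributes), `model` (the true [spine_model]), `landmarks`, and
#'   `loads`: per load type, the generated [load_history] and
#'   [kinematics_history].
#' @export
synthetic_specimen <- function(config, specimen_index) {
  tab <- sample_true_stiffness(config, specimen_index)
  model <- spine_model(tab, solver_mode = config$solver_mode)
  loads <- lapply(stats::setNames(ivj_dofs(), ivj_dofs()), function(dof) {
    hist <- generate_load_history(config, dof, stiffness = tab,
                                  specimen_index = specimen_index)
    kin <- simulate_flexibility_test(
      model, hist, noise_sd_deg = config$noise_sd_deg,
      seed = derive_seed(config$seed, 303, specimen_index,
                         match(dof, ivj_dofs())))
    list(history = hist, kinematics = kin)
  })
  list(id = paste0("specimen_", specimen_index), true_stiffness = tab,
       model = model, landmarks = generate_landmarks(),
       loads = loads)
}

#' Parametric endplate landmarks for a lumbar spine
#'
#' Generates the four endplate landmarks per vertebra that
#' [build_joint_frames()] expects, from a simple stacked-vertebra geometry
#' (configurable vertebral body and disc heights, endplate depth, and a
#' per-joint sagittal tilt emulating lordosis). The default upright geometry
#' yields exactly identity joint frames.
#'
#' @param body_height Vertebral body height, mm.
#' @param disc_height Disc height, mm.
#' @param depth Endplate anteroposterior depth, mm.
#' @param lordosis_deg Total sagittal tilt distributed over the joints,
#'   degrees (0 = upright).
#' @return Landmark data frame (see [read_landmarks_csv()]).
#' @export
generate_landmarks <- function(body_height = 28, disc_height = 10,
                               depth = 40, lordosis_deg = 0) {
  vertebrae <- c("sacrum", "L5", "L4", "L3", "L2", "L1", "T12")
  per_joint <- deg2rad(lordosis_deg) / 6
  rows <- list()
  y <- 0
  tilt <- 0
  for (v in seq_along(vertebrae)) {
    ct <- cos(tilt); st <- sin(tilt)
    # endplate in the sagittal (x-y) plane, tilted about z; x = posterior
    plate <- function(y0, name) {
      pa <- c(-depth / 2 * ct, y0 + depth / 2 * st, 0)
      pp <- c(depth / 2 * ct, y0 - depth / 2 * st, 0)
      rbind(
        data.frame(vertebra_id = vertebrae[v], landmark_name = paste0(name, "_ant"),
                   x_mm = pa[1], y_mm = pa[2], z_mm = pa[3]),
        data.frame(vertebra_id = vertebrae[v], landmark_name = paste0(name, "_post"),
                   x_mm = pp[1], y_mm = pp[2], z_mm = pp[3])
      )
    }
    rows[[length(rows) + 1L]] <- plate(y, "inf")
    rows[[length(rows) + 1L]] <- plate(y + body_height, "sup")
    y <- y + body_height + disc_height
    tilt <- tilt + per_joint
  }
  do.call(rbind, rows)
}

#' Generate a synthetic cohort
#'
#' With `dir = NULL` the cohort is returned in memory. With a directory, the
#' dataset is written as plain-text files:
#' `specimen_<k>/loads_<type>.csv` (+ sidecar JSON), `kinematics_<type>.csv`,
#' `stiffness_true.csv`, `landmarks.csv`, and a top-level `manifest.json`
#' echoing the configuration and seed. Re-running with the same
#' configuration reproduces identical numeric content.
#'
#' @param config A [generator_config].
#' @param dir Optional output directory.
#' @return In-memory: list with `config` and `specimens` (see
#'   [synthetic_specimen()]). On disk: the directory path, invisibly.
#' @export
generate_cohort <- function(config, dir = NULL) {
  stopifnot(inherits(config, "generator_config"))
  specimens <- lapply(seq_len(config$n_specimens),
                      function(i) synthetic_specimen(config, i))
  names(specimens) <- vapply(specimens, `[[`, character(1), "id")
  cohort <- list(config = config, specimens = specimens)
  if (is.null(dir)) return(cohort)

  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (sp in specimens) {
    sdir <- file.path(dir, sp$id)
    dir.create(sdir, showWarnings = FALSE)
    for (dof in ivj_dofs()) {
      write_load_history_csv(sp$loads[[dof]]$history,
                             file.path(sdir, paste0("loads_", dof, ".csv")))
      write_kinematics_csv(sp$loads[[dof]]$kinematics,
                           file.path(sdir, paste0("kinematics_", dof, ".csv")))
    }
    write_stiffness_csv(sp$true_stiffness,
                        file.path(sdir, "stiffness_true.csv"))
    utils::write.csv(sp$landmarks, file.path(sdir, "landmarks.csv"),
                     row.names = FALSE, quote = FALSE)
  }
  manifest <- list(format_version = 1L,
                   seed = config$seed,
                   config = config_as_list(config))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

config_as_list <- function(config) {
  out <- unclass(config)
  out$ratios <- as.data.frame(out$ratios)
  out
}

#' Read a synthetic cohort from disk
#'
#' @param dir Dataset directory written by [generate_cohort()].
#' @return List with `manifest` and `specimens`; each specimen carries its
#'   true stiffness table, landmarks, and per-load histories/kinematics.
#' @export
read_cohort <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"))
  sdirs <- sort(list.dirs(dir, recursive = FALSE))
  specimens <- lapply(sdirs, function(sdir) {
    loads <- lapply(stats::setNames(ivj_dofs(), ivj_dofs()), function(dof) {
      list(history = read_load_history_csv(
             file.path(sdir, paste0("loads_", dof, ".csv"))),
           kinematics = read_kinematics_csv(
             file.path(sdir, paste0("kinematics_", dof, ".csv"))))
    })
    list(id = basename(sdir),
         true_stiffness = read_stiffness_csv(
           file.path(sdir, "stiffness_true.csv")),
         landmarks = read_landmarks_csv(file.path(sdir, "landmarks.csv")),
         loads = loads)
  })
  names(specimens) <- vapply(specimens, `[[`, character(1), "id")
  list(manifest = manifest, specimens = specimens)
}
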