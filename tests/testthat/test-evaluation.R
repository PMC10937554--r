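make_errors <- function(err_mat, meas_mat = NULL, specimen = "s1", ...) {
  if (is.null(meas_mat)) meas_mat <- matrix(5, 6, 3)
  error_table(joint_rotations(meas_mat + err_mat),
              joint_rotations(meas_mat), specimen = specimen, ...)
}

test_that("error tables hold element-wise signed differences", {
  z <- error_table(joint_rotations(0), joint_rotations(0), specimen = "a")
  expect_equal(nrow(z), 18)
  expect_true(all(z$error_deg == 0))

  one <- zmat(); one["L3L4", "fe"] <- 2
  e <- make_errors(one)
  expect_equal(e$error_deg[e$level == "L3L4" & e$dof == "fe"], 2)

  set.seed(3)
  p <- matrix(rnorm(18), 6, 3); m <- matrix(rnorm(18), 6, 3)
  e <- error_table(joint_rotations(p), joint_rotations(m))
  for (r in sample(nrow(e), 6)) {
    expect_equal(e$error_deg[r],
                 p[match(e$level[r], ivj_levels()), match(e$dof[r], ivj_dofs())] -
                   m[match(e$level[r], ivj_levels()), match(e$dof[r], ivj_dofs())])
  }
})

test_that("MAE aggregation: per-specimen means, cohort median and IQR", {
  # alternating +-1 deg errors -> MAE exactly 1
  err <- zmat(); err[, "fe"] <- c(1, -1, 1, -1, 1, -1)
  e <- make_errors(err)
  mae <- aggregate_mae(e, "fe")
  expect_equal(unname(mae$per_specimen), 1)

  # cohort MAEs {1..6} -> median 3.5
  rows <- do.call(rbind, lapply(1:6, function(s) {
    err <- zmat(); err[, "fe"] <- s
    make_errors(err, specimen = paste0("s", s))
  }))
  mae <- aggregate_mae(rows, "fe")
  expect_equal(mae$median, 3.5)
  expect_equal(mae$iqr, 2.5)  # linear-interpolation quartiles of 1..6

  # random table matches a brute-force two-stage aggregation
  set.seed(8)
  rows <- do.call(rbind, lapply(1:5, function(s) {
    make_errors(matrix(rnorm(18), 6, 3), specimen = paste0("s", s))
  }))
  mae <- aggregate_mae(rows, "lb")
  brute <- sapply(paste0("s", 1:5), function(s) {
    mean(abs(rows$error_deg[rows$specimen == s & rows$dof == "lb"]))
  })
  expect_equal(unname(mae$per_specimen), unname(brute))
  expect_equal(mae$median, median(brute))
  expect_error(aggregate_mae(rows[0, ], "lb"), "empty")
})

test_that("RMSE aggregation and the MAE <= RMSE inequality", {
  e <- make_errors(matrix(2, 6, 3))
  expect_equal(unname(aggregate_rmse(e, "specimen")), 2)

  err <- zmat(); err["L5S1", c("lb", "ar")] <- c(3, 4)
  e2 <- make_errors(err)
  expect_equal(unname(aggregate_rmse(e2, "level")["L5S1"]),
               sqrt(mean(c(3, 4, 0)^2)))

  set.seed(21)
  rows <- do.call(rbind, lapply(1:4, function(s) {
    make_errors(matrix(rnorm(18, 0, 2), 6, 3), specimen = paste0("s", s))
  }))
  rmse <- aggregate_rmse(rows, "specimen")
  mae <- sapply(paste0("s", 1:4), function(s) {
    mean(abs(rows$error_deg[rows$specimen == s]))
  })
  brute <- sapply(paste0("s", 1:4), function(s) {
    sqrt(mean(rows$error_deg[rows$specimen == s]^2))
  })
  expect_equal(unname(rmse), unname(brute))
  expect_true(all(mae <= rmse + 1e-12))

  # normalised variant divides by the measured-motion range per group
  meas <- matrix(seq(1, 18), 6, 3)
  e3 <- make_errors(matrix(1, 6, 3), meas_mat = meas)
  nr <- aggregate_rmse(e3, "specimen", normalise = TRUE)
  expect_equal(unname(nr), 1 / (18 - 1))

  # metrics are invariant to row (specimen) ordering
  shuf <- rows[sample(nrow(rows)), ]
  expect_equal(aggregate_rmse(shuf, "specimen"), rmse)
})

test_that("percentage errors are anchored to the cohort reference motion", {
  expect_equal(percentage_error(1.5, 6), 25)
  expect_equal(percentage_error(3, 3), 100)
  expect_error(percentage_error(1, 0), "positive")

  # reference = max over specimens of mean |measured| in the DoF
  rows <- do.call(rbind, lapply(1:3, function(s) {
    make_errors(matrix(0, 6, 3), meas_mat = matrix(s * 1.0, 6, 3),
                specimen = paste0("s", s))
  }))
  expect_equal(reference_motion(rows, "fe"), 3)
})

test_that("leave-one-out median reproduces the worked-example value 79.0", {
  ws <- worked_example_stiffness()
  fe <- subset(ws, load_type == "fe" & dof == "fe")
  vals <- as.numeric(fe[paste0("s", 1:6)])  # 61.9 65.2 60.5 79 94.2 102.2
  tabs <- lapply(vals, function(v) stiffness_table(c(68.8, 291, v)))
  names(tabs) <- paste0("s", 1:6)
  loo <- loo_median_stiffness(tabs, "s1")
  expect_equal(unname(loo$k_rot["L3L4", "fe"]), 79.0)

  # five identical donors return that table; donor order is irrelevant
  same <- lapply(1:5, function(i) stiffness_table(c(70, 280, 55)))
  names(same) <- paste0("d", 1:5)
  expect_equal(loo_median_stiffness(same, "none")$k_rot,
               stiffness_table(c(70, 280, 55))$k_rot)
  perm <- loo_median_stiffness(tabs[sample(6)], "s1")
  expect_equal(perm$k_rot, loo$k_rot)

  expect_error(loo_median_stiffness(tabs[1:2], "s1"), "at least 2")
})

test_that("cross-validation sweeps count simulations and honour homogeneity", {
  # three identical specimens, one representation, one load
  truth <- stiffness_table(c(80, 300, 60))
  model <- spine_model(truth)
  lc <- load_case(c(0.2, -0.1, 7.5), loaded_dof = "fe")
  measured <- solve_equilibrium(model, lc)
  specimens <- lapply(1:3, function(i) {
    list(model = model, loads = list(fe = list(load = lc, measured = measured)))
  })
  names(specimens) <- paste0("s", 1:3)
  fits <- lapply(specimens, function(sp) {
    optimize_stiffness(spine_model(literature_stiffness()), lc, measured)
  })
  cv <- run_cross_validation(specimens, list(uniform = list(fe = fits)))
  expect_equal(cv$n_simulations, 3L)
  expect_equal(length(cv$skipped), 0L)

  # identical specimens: cross-validation errors equal the optimised errors
  opt_err <- error_table(predict(fits$s1), measured, specimen = "s1",
                         model_type = "optimized")
  cv_s1 <- cv$errors[cv$errors$specimen == "s1", ]
  expect_equal(cv_s1$error_deg, opt_err$error_deg, tolerance = 1e-6)

  # insufficient donors are skipped, not fatal
  one <- specimens[1]
  cv1 <- run_cross_validation(one, list(uniform = list(fe = fits[1])))
  expect_equal(cv1$n_simulations, 0L)
  expect_equal(length(cv1$skipped), 1L)
  expect_match(cv1$skipped[[1]]$reason, "at least 2")
})
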