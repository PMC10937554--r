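test_that("true stiffness draws are reproducible and respect degenerate spreads", {
  # CV = 0, jitter = 0: every specimen equals means x ratios exactly
  cfg <- fast_config(seed = 5, cv = 0, ratio_jitter_sd = 0)
  tab <- sample_true_stiffness(cfg, 1)
  expect_equal(tab$k_rot,
               apply_level_ratios(cfg$base_means, cfg$ratios)$k_rot,
               tolerance = 1e-12)
  expect_equal(sample_true_stiffness(cfg, 3)$k_rot, tab$k_rot)

  # same seed twice: identical; different specimen index: different
  cfg2 <- fast_config(seed = 9)
  expect_equal(sample_true_stiffness(cfg2, 2)$k_rot,
               sample_true_stiffness(cfg2, 2)$k_rot)
  expect_false(identical(sample_true_stiffness(cfg2, 2)$k_rot,
                         sample_true_stiffness(cfg2, 3)$k_rot))
})

test_that("the base-stiffness draws recover the configured CV", {
  cfg <- fast_config(seed = 11)
  draws <- t(vapply(seq_len(10000),
                    function(i) attr(sample_true_stiffness(cfg, i), "base"),
                    numeric(3)))
  cv_hat <- apply(draws, 2, sd) / colMeans(draws)
  for (j in 1:3) {
    expect_gt(cv_hat[j], 0.23)
    expect_lt(cv_hat[j], 0.27)
  }
  # and the configured means are matched
  expect_equal(unname(colMeans(draws)), unname(cfg$base_means),
               tolerance = 0.02 * max(cfg$base_means))
})

test_that("generated load histories hit the exact peak with 3.5 cycles", {
  cfg <- generator_config(seed = 4)  # study sampling rate
  h <- generate_load_history(cfg, "fe")
  expect_equal(max(abs(h$m_fe_Nm)), 7.5)
  cs <- segment_cycles(h)
  expect_equal(sum(cs$complete), 3)
  expect_equal(sum(!cs$complete), 1)
  # coupled channels bounded by the configured fraction
  expect_lte(max(abs(h$m_lb_Nm)), 0.05 * 7.5 + 1e-12)
  expect_lte(max(abs(h$m_ar_Nm)), 0.05 * 7.5 + 1e-12)

  # coupled_fraction = 0: coupled channels identically zero
  h0 <- generate_load_history(generator_config(seed = 4, coupled_fraction = 0),
                              "fe")
  expect_true(all(h0$m_lb_Nm == 0) && all(h0$m_ar_Nm == 0))

  # two seeds: identical loaded channel, different coupled phases
  h1 <- generate_load_history(generator_config(seed = 1), "fe")
  h2 <- generate_load_history(generator_config(seed = 2), "fe")
  expect_equal(h1$m_fe_Nm, h2$m_fe_Nm)
  expect_false(identical(h1$m_lb_Nm, h2$m_lb_Nm))
})

test_that("the loaded-channel ramp rate approximates the configured motion rate", {
  cfg <- generator_config(seed = 4, cv = 0, ratio_jitter_sd = 0)
  tab <- sample_true_stiffness(cfg, 1)
  h <- generate_load_history(cfg, "fe", stiffness = tab)
  kin <- simulate_flexibility_test(spine_model(tab), h)
  total <- rowSums(attr(kin, "noiseless")[, paste0(ivj_levels(), "_fe_deg")])
  rate <- max(abs(diff(total))) * cfg$sample_rate_hz
  expect_equal(rate, 1.0, tolerance = 0.05)  # deg/s
})

test_that("simulated kinematics invert the mechanics exactly when noiseless", {
  cfg <- fast_config(seed = 21, cv = 0.1, ratio_jitter_sd = 0)
  tab <- sample_true_stiffness(cfg, 1)
  model <- spine_model(tab)
  h <- generate_load_history(cfg, "lb", stiffness = tab)
  kin <- simulate_flexibility_test(model, h, noise_sd_deg = 0)
  i <- sample(nrow(h), 1)
  th <- solve_equilibrium(model, load_case(as.numeric(
    h[i, c("m_lb_Nm", "m_ar_Nm", "m_fe_Nm")])))
  expect_equal(as.numeric(kin[i, -1]), as.vector(t(rotmat(th))),
               tolerance = 1e-9)

  # doubling all stiffnesses halves all rotations
  tab2 <- stiffness_table(tab$k_rot * 2, tab$k_trans)
  kin2 <- simulate_flexibility_test(spine_model(tab2), h, noise_sd_deg = 0)
  expect_equal(attr(kin2, "noiseless"), attr(kin, "noiseless") / 2,
               tolerance = 1e-12)
})

test_that("kinematic noise is calibrated and seeded", {
  cfg <- generator_config(seed = 8)
  tab <- sample_true_stiffness(cfg, 1)
  h <- generate_load_history(cfg, "fe", stiffness = tab)
  kin <- simulate_flexibility_test(spine_model(tab), h, noise_sd_deg = 0.1,
                                   seed = 77)
  resid <- as.matrix(kin[, -1]) - attr(kin, "noiseless")
  expect_equal(sd(resid), 0.1, tolerance = 0.01)
  expect_equal(mean(resid), 0, tolerance = 0.005)

  kin_b <- simulate_flexibility_test(spine_model(tab), h, noise_sd_deg = 0.1,
                                     seed = 77)
  expect_identical(as.matrix(kin[, -1]), as.matrix(kin_b[, -1]))
})

test_that("cohorts are written to disk completely and reproducibly", {
  cfg <- fast_config(seed = 33, n_specimens = 2)
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  generate_cohort(cfg, dir1)
  generate_cohort(cfg, dir2)

  files <- list.files(dir1, recursive = TRUE)
  # per specimen: 3 load CSVs + 3 sidecars + 3 kinematics + truth + landmarks
  expect_equal(sum(grepl("loads_.*csv$", files)), 2 * 3)
  expect_equal(sum(grepl("kinematics_", files)), 2 * 3)
  expect_equal(sum(grepl("stiffness_true", files)), 2)
  expect_true("manifest.json" %in% files)

  # same configuration replays to identical numeric content
  for (f in setdiff(files, "manifest.json")) {
    expect_identical(readLines(file.path(dir1, f)),
                     readLines(file.path(dir2, f)),
                     info = f)
  }

  # truth tables round-trip through the stiffness CSV reader
  sp1 <- synthetic_specimen(cfg, 1)
  back <- read_stiffness_csv(file.path(dir1, "specimen_1",
                                       "stiffness_true.csv"))
  expect_equal(back$k_rot, sp1$true_stiffness$k_rot, tolerance = 1e-12)

  # and read_cohort reconstructs the dataset
  co <- read_cohort(dir1)
  expect_named(co$specimens, c("specimen_1", "specimen_2"))
  expect_equal(co$specimens$specimen_1$loads$fe$history$m_fe_Nm,
               sp1$loads$fe$history$m_fe_Nm, tolerance = 1e-10)
})

test_that("a default-size cohort enumerates 18 paired load/kinematics sets", {
  cfg <- fast_config(seed = 2)  # six specimens, three load types
  cohort <- generate_cohort(cfg)
  expect_length(cohort$specimens, 6)
  n_sets <- sum(vapply(cohort$specimens, function(sp) length(sp$loads),
                       integer(1)))
  expect_equal(n_sets, 18)
  for (sp in cohort$specimens) {
    for (l in sp$loads) {
      expect_s3_class(l$history, "load_history")
      expect_s3_class(l$kinematics, "kinematics_history")
      expect_equal(nrow(l$history), nrow(l$kinematics))
    }
  }
})
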