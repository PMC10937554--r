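test_that("cycle segmentation finds 3 complete cycles in a 3.5-cycle test", {
  h <- make_history(n_q = 50)
  cs <- segment_cycles(h)
  expect_equal(sum(cs$complete), 3)
  expect_equal(sum(!cs$complete), 1)
  # segmentation covers the sample axis without overlap
  expect_equal(cs$start[1], 1L)
  expect_equal(cs$end[nrow(cs)], nrow(h) + 1L)
  expect_true(all(cs$start[-1] == cs$end[-nrow(cs)]))
})

test_that("cycle boundaries of a sinusoid land within one sample of kT", {
  fs <- 100
  T_period <- 1.73  # seconds, not an integer number of samples
  t <- seq(0, 3.5 * T_period, by = 1 / fs)
  m <- matrix(0, length(t), 3)
  m[, 3] <- 7.5 * sin(2 * pi * t / T_period)
  h <- load_history(t, m, "fe")
  cs <- segment_cycles(h)
  comp <- cs[cs$complete, ]
  for (i in seq_len(nrow(comp))) {
    expect_lt(abs(t[comp$start[i]] - (i - 1) * T_period), 1 / fs + 1e-12)
  }
})

test_that("degenerate histories are segmented defensively", {
  t <- seq(0, 1, by = 0.01)
  h <- load_history(t, matrix(0, length(t), 3), "fe")
  expect_warning(cs <- segment_cycles(h), "zero-crossings")
  expect_equal(sum(cs$complete), 0)
})

test_that("evaluation-cycle selection excludes the first cycle and breaks ties early", {
  # coupled lb-channel ranges differ per cycle: 0.1, 0.5, 0.2 (+ half cycle)
  n_q <- 50
  n <- as.integer(4 * n_q * 3.5) + 1L
  cyc_id <- pmin((seq_len(n) - 1) %/% (4 * n_q), 3)
  lb <- c(0.1, 0.5, 0.2, 0.2)[cyc_id + 1] *
    sin(2 * pi * (seq_len(n) - 1) / (4 * n_q)) / 2
  h <- make_history(n_q = n_q, coupled = list(lb = lb))
  cs <- segment_cycles(h)
  expect_equal(sum(cs$complete), 3)
  sel <- select_evaluation_cycle(h, cs)
  # cycle 1 is excluded a priori even though its score is smallest
  expect_equal(which(which(cs$complete) == sel), 3L)

  # equal scores -> earliest candidate
  lb_tie <- c(0.1, 0.3, 0.3, 0.3)[cyc_id + 1] *
    sin(2 * pi * (seq_len(n) - 1) / (4 * n_q)) / 2
  h2 <- make_history(n_q = n_q, coupled = list(lb = lb_tie))
  sel2 <- select_evaluation_cycle(h2, segment_cycles(h2))
  expect_equal(which(which(cs$complete) == sel2), 2L)

  # the selected cycle is never the first complete one
  expect_error(select_evaluation_cycle(h, cs[cs$complete, ][1, ]),
               "insufficient")
})

test_that("cycle scores match a brute-force range enumeration", {
  set.seed(7)
  n_q <- 40
  h <- make_history(n_q = n_q, n_cycles = 5,
                    coupled = list(lb = cumsum(rnorm(4 * n_q * 5 + 1, 0, 0.01)),
                                   ar = cumsum(rnorm(4 * n_q * 5 + 1, 0, 0.01))))
  cs <- segment_cycles(h)
  sel <- select_evaluation_cycle(h, cs)
  comp <- which(cs$complete)
  brute <- vapply(comp[-1], function(i) {
    idx <- cs$start[i]:(cs$end[i] - 1)
    (max(h$m_lb_Nm[idx]) - min(h$m_lb_Nm[idx])) +
      (max(h$m_ar_Nm[idx]) - min(h$m_ar_Nm[idx]))
  }, numeric(1))
  expect_equal(as.integer(sel), comp[-1][which.min(brute)])
  expect_equal(unname(attr(sel, "scores")), brute, tolerance = 1e-12)
})

test_that("load-case extraction returns the in-cycle peak sample unmodified", {
  n_q <- 50
  n <- 4 * n_q * 3.5 + 1
  h <- make_history(n_q = n_q, coupled = list(lb = rep(0.2, n),
                                              ar = rep(-0.1, n)))
  cs <- segment_cycles(h)
  lc <- extract_load_case(h, 2, cs)
  expect_equal(unname(lc$load$moment), c(0.2, -0.1, 7.5))
  expect_equal(lc$load$loaded_dof, "fe")
  # the returned moment is an actual sample of the history
  expect_equal(unname(as.numeric(h[lc$sample_index,
                                   c("m_lb_Nm", "m_ar_Nm", "m_fe_Nm")])),
               unname(lc$load$moment))

  # all-negative loaded segment: largest magnitude, sign preserved
  half <- h[(cs$start[2] + 2 * n_q):(cs$end[2] - 1), ]
  h_neg <- load_history(half$time_s,
                        as.matrix(half[, c("m_lb_Nm", "m_ar_Nm", "m_fe_Nm")]),
                        "fe")
  lc_neg <- extract_load_case(h_neg, c(1L, nrow(h_neg) + 1L))
  expect_equal(unname(lc_neg$load$moment[3]), -7.5)

  # random smooth cycle agrees with an exhaustive scan
  set.seed(11)
  sm <- stats::filter(rnorm(300), rep(1 / 20, 20), circular = TRUE)
  h_r <- load_history(seq_len(300) / 100,
                      cbind(0, 0, as.numeric(sm)), "fe")
  lc_r <- extract_load_case(h_r, c(1L, 301L))
  expect_equal(lc_r$sample_index, which.max(abs(sm)))

  expect_error(extract_load_case(h, c(5L, 5L)), "empty")
})

test_that("kinematics are read at the load-case instant, interpolating across grids", {
  tab <- apply_level_ratios(c(70, 280, 55), literature_level_ratios())
  model <- spine_model(tab)
  h <- make_history(n_q = 50)
  kin <- simulate_flexibility_test(model, h, noise_sd_deg = 0)
  cs <- segment_cycles(h)
  lc <- extract_load_case(h, select_evaluation_cycle(h, cs), cs)
  meas <- kinematics_at_load_case(kin, lc$sample_index, h)
  truth <- solve_equilibrium(model, lc$load)
  expect_equal(rotmat(meas), rotmat(truth), tolerance = 1e-9)

  # shifted time grid: linear interpolation is exact for linear signals
  t2 <- h$time_s + 0.004
  lin <- outer(t2, rep(1, 18)) * rep(seq(0.1, 1.8, by = 0.1), each = length(t2))
  colnames(lin) <- spinestiff:::kinematics_columns()
  kin2 <- kinematics_history(t2, lin)
  got <- kinematics_at_load_case(kin2, 30, load_history(t2 + 0.002,
                                                        matrix(1, length(t2), 3),
                                                        "fe"))
  t_target <- t2[30] + 0.002
  expect_equal(unname(rotmat(got)[1, "lb"]), 0.1 * t_target, tolerance = 1e-9)

  # constant kinematics: any index gives the same value
  kc <- kinematics_history(h$time_s,
                           matrix(2, nrow(h), 18,
                                  dimnames = list(NULL,
                                                  spinestiff:::kinematics_columns())))
  expect_equal(rotmat(kinematics_at_load_case(kc, 1)),
               rotmat(kinematics_at_load_case(kc, nrow(h))))
  expect_error(kinematics_at_load_case(kc, nrow(h) + 10), "out of range")
})

test_that("load-history and kinematics CSVs round-trip", {
  dir <- withr::local_tempdir()
  h <- make_history(n_q = 20, coupled = list(lb = sin(seq_len(281) / 50) * 0.3))
  p <- file.path(dir, "loads_fe.csv")
  write_load_history_csv(h, p)
  h2 <- read_load_history_csv(p)
  expect_equal(attr(h2, "loaded_dof"), "fe")
  expect_equal(h2$m_fe_Nm, h$m_fe_Nm, tolerance = 1e-12)
  expect_equal(h2$m_lb_Nm, h$m_lb_Nm, tolerance = 1e-12)

  model <- spine_model(literature_stiffness())
  kin <- simulate_flexibility_test(model, h, noise_sd_deg = 0.05, seed = 3)
  pk <- file.path(dir, "kin_fe.csv")
  write_kinematics_csv(kin, pk)
  kin2 <- read_kinematics_csv(pk)
  attr(kin, "noiseless") <- NULL
  expect_equal(as.data.frame(kin2), as.data.frame(kin), tolerance = 1e-10)
})
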