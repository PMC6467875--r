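test_that("constructed paths are classified correctly", {
  # clean traversal upper -> membrane -> lower
  ev <- suppressWarnings(detect_crossings(c(2, 0, -2), z_plane = 1.5, Lz = 7))
  expect_equal(nrow(ev), 1)
  expect_equal(ev$direction, "+z->-z")
  expect_equal(ev$entry_frame, 2)
  expect_equal(ev$exit_frame, 3)

  # membrane visit that returns to the entry side: no event
  ev2 <- suppressWarnings(detect_crossings(c(2, 0, 2), z_plane = 1.5, Lz = 7))
  expect_equal(nrow(ev2), 0)

  # periodic water route (upper -> lower with no membrane frames): no event
  expect_warning(
    ev3 <- detect_crossings(c(2, 0, 2, -2, -2.5), z_plane = 1.5, Lz = 7),
    "wrap"
  )
  expect_equal(nrow(ev3), 0)

  # traversals in progress at the ends are discarded
  ev4 <- suppressWarnings(detect_crossings(c(0, -2, 2, 0), z_plane = 1.5,
                                           Lz = 7))
  expect_equal(nrow(ev4), 0)

  # multiple events, both directions, with durations
  z <- c(2, 1, -2, -2, 0, 2)
  ev5 <- suppressWarnings(
    detect_crossings(z, z_plane = 1.5, Lz = 7, sampling_interval = 1000))
  expect_equal(nrow(ev5), 2)
  expect_equal(ev5$direction, c("+z->-z", "-z->+z"))
  expect_equal(ev5$duration_ns, c(1, 1))

  expect_error(detect_crossings(c(2, 0, -2), z_plane = 4, Lz = 7), "inside")
})

test_that("detector is invariant under time reversal", {
  set.seed(31)
  z <- brownian_dynamics_1d(z0 = runif(5, 2, 3.4), t_ns = 100, dt_ps = 0.5,
                            D = 5, temperature = 310, Lz = 7,
                            H = 1.5, sigma = 0.3, z_peak = 1.3)
  n_fwd <- 0; n_rev <- 0
  for (j in seq_len(ncol(z))) {
    n_fwd <- n_fwd + nrow(detect_crossings(z[, j], 1.75, Lz = 7))
    n_rev <- n_rev + nrow(detect_crossings(rev(z[, j]), 1.75, Lz = 7))
  }
  expect_gt(n_fwd, 10)
  expect_equal(n_fwd, n_rev)
})

test_that("direction counts balance in equilibrium", {
  set.seed(32)
  z <- brownian_dynamics_1d(z0 = runif(10, -3.4, 3.4), t_ns = 400,
                            dt_ps = 0.5, D = 5, temperature = 310, Lz = 7,
                            H = 1.5, sigma = 0.3, z_peak = 1.3,
                            burnin_ns = 5)
  ev <- do.call(rbind, lapply(seq_len(ncol(z)), function(j)
    detect_crossings(z[, j], 1.75, Lz = 7)))
  n_down <- sum(ev$direction == "+z->-z")
  n_up <- sum(ev$direction == "-z->+z")
  expect_gt(nrow(ev), 100)
  expect_lt(abs(n_down - n_up), 3 * sqrt(nrow(ev)))
})

test_that("transition rate arithmetic and undersampling flag", {
  r <- transition_rate(11, total_time_us = 10, n_solutes = 20)
  expect_equal(r$rate_per_s, 1.1e6)
  expect_equal(r$rate_stderr_per_s, sqrt(11) / 10e-6)
  expect_equal(r$per_molecule_k_per_s, 1.1e6 / 20)
  expect_false(r$undersampled)

  r0 <- transition_rate(0, total_time_us = 4)
  expect_equal(r0$rate_per_s, 0)
  expect_true(r0$undersampled)
  expect_equal(r0$rate_stderr_per_s, 1 / 4e-6)

  # doubling total time with the same events halves the rate
  r2 <- transition_rate(11, total_time_us = 20)
  expect_equal(r2$rate_per_s, transition_rate(11, 10)$rate_per_s / 2)
  expect_error(transition_rate(5, 0), "positive")
})

test_that("direct permeability follows P = r/(2*S*C) in cm/s", {
  # printed 310 K inputs: 11 events / 10 us, S = 48 x 0.453 nm^2, C = 410 mM
  r <- transition_rate(11, 10, n_solutes = 20, temperature = 310)
  p <- permeability_direct(r, S = 48 * 0.453, C = 410)
  C_nm3 <- 410 * unit_constants()$mM_to_per_nm3
  expect_equal(p$P_cm_s, 1.1e6 / (2 * 21.744 * C_nm3) * 1e-7)
  expect_equal(p$P_cm_s, 1.024e-2, tolerance = 1e-3)
  expect_equal(p$stderr_cm_s / p$P_cm_s, sqrt(11) / 11)

  # zero events give zero permeability
  expect_equal(permeability_direct(transition_rate(0, 4), 21.744, 410)$P_cm_s, 0)

  # halving the concentration doubles P at fixed rate
  p2 <- permeability_direct(r, S = 21.744, C = 205)
  expect_equal(p2$P_cm_s, 2 * p$P_cm_s)
  expect_error(permeability_direct(r, S = -1, C = 410), "positive")
  expect_error(permeability_direct(r, S = 21.744, C = 0), "positive")
})

test_that("transwell permeability arithmetic", {
  expect_equal(transwell_permeability(V_A = 1.5, C_A = 1e-3, C_L = 1,
                                      t = 3600, S = 1.12),
               3.72e-7, tolerance = 1e-3)
  expect_equal(transwell_permeability(1.5, 0, 1, 3600, 1.12), 0)
  # doubling time halves P
  expect_equal(transwell_permeability(1.5, 1e-3, 1, 7200, 1.12),
               transwell_permeability(1.5, 1e-3, 1, 3600, 1.12) / 2)
  expect_warning(transwell_permeability(1.5, 2, 1, 3600, 1.12), "sink")
  expect_error(transwell_permeability(0, 1, 1, 1, 1), "positive")
})

test_that("equilibrium aqueous concentration reflects membrane partitioning", {
  # all solutes always in water: C_aq equals N / (S * L_water)
  z_all_water <- matrix(3, nrow = 100, ncol = 10)
  C <- aqueous_concentration(z_all_water, z_plane = 1.75, S = 21.744, Lz = 7)
  expect_equal(C, 10 / (21.744 * 3.5) / unit_constants()$mM_to_per_nm3,
               tolerance = 1e-12)
  # half the frames membrane-bound halves the aqueous concentration
  z_half <- rbind(matrix(3, 50, 10), matrix(0, 50, 10))
  expect_equal(aqueous_concentration(z_half, 1.75, 21.744, 7), C / 2,
               tolerance = 1e-12)
})

test_that("event and rate outputs serialize with provenance", {
  ev <- suppressWarnings(
    detect_crossings(c(2, 0, -2, 0, 2), z_plane = 1.5, Lz = 7,
                     sampling_interval = 500))
  path <- file.path(tempdir(), "events.tsv")
  write_events(ev, path)
  back <- read.delim(path)
  expect_equal(nrow(back), nrow(ev))
  expect_true(all(c("molecule_id", "direction", "entry_time_ns",
                    "exit_time_ns", "duration_ns") %in% names(back)))
})
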