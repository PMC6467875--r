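test_that("density profile normalizes uniform samples to the bulk plateau", {
  set.seed(1)
  z <- runif(2e5, -3.5, 3.5)
  rho <- density_profile(z, bin_width = 0.1, h = 3.5)
  expect_equal(nrow(rho), 70)
  expect_true(all(abs(rho$rho - 1) < 0.12))
  expect_equal(mean(rho$rho[abs(rho$z_nm) >= 3.0]), 1, tolerance = 0.02)
})

test_that("density profile rejects degenerate inputs", {
  expect_error(density_profile(numeric(0), h = 3.5), "empty")
  # all mass in one central bin: no bulk statistics to normalize against
  expect_error(density_profile(rep(0.01, 100), h = 3.5), "bulk region empty")
  expect_error(density_profile(c(-4, 0, 4), h = 3.5), "outside")
})

test_that("Boltzmann inversion has the right closed forms", {
  z <- runif(1000, -3.5, 3.5)
  rho <- density_profile(z, h = 3.5)
  rho$rho <- rep(1, nrow(rho))
  prof <- free_energy_profile(rho, 310)
  expect_true(all(abs(prof$G_kcal_mol) < 1e-12))

  rho$rho[35] <- exp(-1)
  prof <- free_energy_profile(rho, 310)
  expect_equal(prof$G_kcal_mol[35], kB * 310, tolerance = 1e-10)
  expect_equal(prof$G_kcal_mol[35], 0.61603, tolerance = 1e-4)

  rho$counts[35] <- 0L
  prof <- free_energy_profile(rho, 310)
  expect_true(prof$censored[35])
  expect_true(is.na(prof$G_kcal_mol[35]))
  expect_error(free_energy_profile(rho, -1), "positive")
})

test_that("profile of a Boltzmann sampler recovers the potential", {
  set.seed(42)
  Gfun <- gauss_potential(H = 2, sigma = 0.4, z_peak = 1.3)
  Tt <- 310
  z <- sample_boltzmann(Gfun, 3e5, 3.5, Tt)
  rho <- density_profile(z, bin_width = 0.1, h = 3.5)
  prof <- free_energy_profile(rho, Tt)
  sel <- !prof$censored & Gfun(prof$z_nm) < 2
  # multinomial error: compare where sampling is decent (>= ~190 counts)
  err <- prof$G_kcal_mol[sel] - Gfun(prof$z_nm[sel])
  expect_lt(max(abs(err)), 0.2)
  expect_lt(abs(mean(err)), 0.03)  # bulk reference consistent
})

test_that("symmetrized profiles are even in z", {
  set.seed(15)
  z <- c(runif(5e4, -3.5, 3.5), runif(1e4, 0.5, 1.5))  # one-sided excess
  rho_s <- density_profile(z, h = 3.5, symmetrize = TRUE)
  expect_equal(rho_s$rho, rev(rho_s$rho), tolerance = 1e-12)
  rho <- density_profile(z, h = 3.5)
  expect_gt(max(abs(rho$rho - rev(rho$rho))), 0.1)
})

test_that("block errors: degenerate, closed form, and 1/sqrt(n) scaling", {
  # identical blocks -> stderr 0
  z1 <- rep(seq(-3.45, 3.45, by = 0.1), 4)
  t1 <- c(seq(0, 99.9e3, length.out = length(z1) / 2),
          seq(100e3, 199.9e3, length.out = length(z1) / 2))
  se <- block_errors(z1, t1, 310, block_ns = 100, h = 3.5)
  expect_true(all(se[!is.na(se)] < 1e-12))
  expect_equal(attr(se, "n_blocks"), 2)

  # two blocks with G differing by 2*delta in one bin -> stderr = delta
  base <- seq(-3.45, 3.45, by = 0.1)
  extra <- rep(0.05, 110)  # overweight the central bin in block 2 only
  z2 <- c(rep(base, 100), rep(base, 100), extra)
  t2 <- c(seq(0, 99.999e3, length.out = 100 * length(base)),
          seq(100e3, 199.999e3, length.out = 100 * length(base) + 110))
  se2 <- block_errors(z2, t2, 310, block_ns = 100, h = 3.5)
  i0 <- which.min(abs(base - 0.05))
  G1 <- 0
  G2 <- -kB * 310 * log(210 / 100)  # bin count 210 vs bulk-normalized 100
  delta <- abs(G2 - G1) / 2
  expect_equal(unname(se2[i0]), delta, tolerance = 0.02)

  expect_error(block_errors(z1, t1, 310, block_ns = 300, h = 3.5),
               ">= 2 complete blocks")

  # stationary sampler: quadrupling the data at fixed block size halves se
  set.seed(5)
  mk <- function(nb) {
    n <- nb * 5000
    list(z = runif(n, -3.5, 3.5), t = seq(0, nb * 100e3 - 1, length.out = n))
  }
  a <- mk(4); b <- mk(16)
  sea <- block_errors(a$z, a$t, 310, block_ns = 100, h = 3.5)
  seb <- block_errors(b$z, b$t, 310, block_ns = 100, h = 3.5)
  ratio <- mean(seb / sea, na.rm = TRUE)
  expect_gt(ratio, 0.35); expect_lt(ratio, 0.7)
})

test_that("barrier summary arithmetic matches the flanking-minima rule", {
  # symmetric profile: wells at -1.0, apex at +2.6 -> dG = 3.6
  Gfun <- function(z)
    2.6 * exp(-z^2 / (2 * 0.3^2)) -
    1.0 * exp(-(z - 1.2)^2 / (2 * 0.25^2)) -
    1.0 * exp(-(z + 1.2)^2 / (2 * 0.25^2))
  prof <- analytic_profile(Gfun, h = 3.5, temperature = 310)
  bs <- barrier_summary(prof, z_mem = 2)
  expect_equal(bs$delta_G_kcal_mol, 3.6, tolerance = 0.05)
  expect_lt(abs(bs$z_B), 0.06)
  expect_equal(bs$G_A, -1.0, tolerance = 0.05)
  expect_true(bs$z_A < bs$z_B && bs$z_B < bs$z_C)

  # monotone profile: no interior maximum
  prof2 <- analytic_profile(function(z) 0.5 * z, h = 3.5)
  expect_error(barrier_summary(prof2, z_mem = 2), "monotone|interior")

  # double-peak: apex is the higher of the two peaks (exhaustive scan)
  Gfun3 <- function(z)
    2.0 * exp(-(z + 1.3)^2 / (2 * 0.3^2)) +
    2.3 * exp(-(z - 1.3)^2 / (2 * 0.3^2))
  prof3 <- analytic_profile(Gfun3, h = 3.5)
  bs3 <- barrier_summary(prof3, z_mem = 2)
  expect_equal(bs3$G_B, max(prof3$G_kcal_mol[abs(prof3$z_nm) <= 2]))
  expect_equal(bs3$z_B, 1.25, tolerance = 0.11)

  # censored apex is an error, not a guess
  prof4 <- analytic_profile(Gfun3, h = 3.5)
  apex <- which.max(prof4$G_kcal_mol)
  prof4$censored[apex] <- TRUE
  prof4$G_kcal_mol[apex] <- NA
  prof4$counts[apex] <- 0L
  expect_error(barrier_summary(prof4, z_mem = 2), "undersampled")
})

test_that("barrier width matches its closed forms within 1%", {
  Tt <- 310
  h <- 3.5
  # flat profile, dG = 0 -> lb = 2h
  flat <- analytic_profile(function(z) rep(0, length(z)), h = h)
  expect_rel(barrier_width(flat, Tt, h = h, delta_G = 0), 2 * h, 0.01)

  # square-top barrier of width 1 over a deep background -> lb -> 1
  sq <- analytic_profile(function(z) ifelse(abs(z) < 0.5, 1, -50), h = h)
  expect_rel(barrier_width(sq, Tt, h = h), 1.0, 0.01)

  # parabolic apex -> lb = sqrt(2*pi*kB*T/kappa)
  kappa <- 10
  par <- analytic_profile(function(z) 5 - kappa * z^2 / 2, h = h)
  expect_rel(barrier_width(par, Tt, h = h, delta_G = 5),
             sqrt(2 * pi * kB * Tt / kappa), 0.01)

  expect_error(barrier_width(flat, Tt, h = 10), "exceeds")
})

test_that("adding a constant to G changes neither dG nor lb", {
  Gfun <- gauss_potential(H = 3, sigma = 0.35, z_peak = 1.3)
  p1 <- analytic_profile(Gfun, h = 3.5)
  p2 <- analytic_profile(function(z) Gfun(z) + 1.7, h = 3.5)
  b1 <- barrier_summary(p1, z_mem = 1.75)
  b2 <- barrier_summary(p2, z_mem = 1.75)
  expect_equal(b1$delta_G_kcal_mol, b2$delta_G_kcal_mol, tolerance = 1e-12)
  expect_equal(b1$lb_nm, b2$lb_nm, tolerance = 1e-12)
})

test_that("temperature scaling fits recover known laws", {
  # noiseless barrier line
  Ts <- c(310, 380, 440, 500)
  fit <- suppressWarnings(fit_barrier_vs_T(Ts, 10 - 0.01 * Ts))
  expect_equal(fit$G0, 10, tolerance = 1e-10)
  expect_equal(fit$g, 0.01, tolerance = 1e-12)
  expect_error(fit_barrier_vs_T(310, 3), "distinct")

  # noisy line recovered within 2 stderr (enough points for a stable se)
  set.seed(9)
  Ts8 <- seq(310, 500, length.out = 8)
  dG <- 10 - 0.01 * Ts8 + rnorm(8, 0, 0.05)
  fitn <- fit_barrier_vs_T(Ts8, dG)
  expect_lt(abs(fitn$G0 - 10), 2 * fitn$G0_stderr + 1e-12)

  # noiseless width power law
  wfit <- suppressWarnings(fit_width_vs_T(Ts, 7.3e-6 * Ts^2))
  expect_equal(wfit$ml, 2, tolerance = 1e-10)
  expect_equal(wfit$a, 7.3e-6, tolerance = 1e-8)
  # constrained fit on a single point
  wone <- fit_width_vs_T(400, 7.3e-6 * 400^2, constrain_slope = 2)
  expect_equal(wone$a, 7.3e-6, tolerance = 1e-10)
  expect_error(fit_width_vs_T(Ts, c(-1, 1, 1, 1)), "positive")
  # noisy power law within 2 stderr
  set.seed(10)
  lbs <- 7.3e-6 * Ts^2 * exp(rnorm(4, 0, 0.05))
  wn <- fit_width_vs_T(Ts, lbs)
  expect_lt(abs(wn$ml - 2), 2 * wn$ml_stderr + 1e-12)
})

test_that("two sampling lengths give consistent barrier heights", {
  # short vs long equilibrium runs agree within combined block errors
  set.seed(21)
  spec <- potential_spec(G0 = 3.24, g = 0.004)  # dG(310) = 2.0
  cfg1 <- langevin_config(spec, 310, t_ns = 60, seed = 101, n_particles = 10)
  cfg2 <- langevin_config(spec, 310, t_ns = 150, seed = 102, n_particles = 10)
  run_dG <- function(cfg) {
    sim <- simulate_langevin(cfg)
    z <- as.vector(sim$z)
    tp <- rep(sim$time_ps, ncol(sim$z))
    prof <- compute_free_energy(z, tp, 310, h = cfg$calib$Lz / 2,
                                block_ns = 10)
    barrier_summary(prof, z_mem = spec$z_channel)
  }
  b1 <- run_dG(cfg1); b2 <- run_dG(cfg2)
  comb <- sqrt(b1$delta_G_stderr^2 + b2$delta_G_stderr^2)
  expect_lt(abs(b1$delta_G_kcal_mol - b2$delta_G_kcal_mol), 3 * comb)
  expect_lt(abs(b1$delta_G_kcal_mol - 2.0), 0.25)
})
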