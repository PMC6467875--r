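test_that("free diffusion has MSD slope 2D and is seed-reproducible", {
  set.seed(51)
  z <- brownian_dynamics_1d(z0 = rep(0, 20), t_ns = 20, dt_ps = 0.5,
                            D = 0.3, temperature = 310, Lz = 200)
  # far from the walls: unwrapped free diffusion
  curves <- lapply(seq_len(ncol(z)), function(j)
    msd(z[, j], max_lag_frames = 2000, sampling_interval = 1))
  pooled_D <- mean(sapply(curves, function(cu)
    fit_diffusion(cu, window = c(0.01, 0.2), dimensionality = 1)$D_nm2_ns))
  expect_rel(pooled_D, 0.3, 0.05)

  set.seed(51)
  z2 <- brownian_dynamics_1d(z0 = rep(0, 20), t_ns = 20, dt_ps = 0.5,
                             D = 0.3, temperature = 310, Lz = 200)
  expect_identical(z, z2)
})

test_that("deep Gaussian well reproduces the harmonic stationary variance", {
  set.seed(52)
  kappa <- 6 / 0.5^2  # depth / sigma^2
  z <- brownian_dynamics_1d(z0 = rep(0, 10), t_ns = 400, dt_ps = 0.5,
                            D = 0.5, temperature = 310, Lz = 8,
                            well_depth = 6, well_sigma = 0.5, burnin_ns = 5)
  v <- var(as.vector(z))
  # exact Boltzmann variance of the Gaussian well; the harmonic value
  # kB*T/kappa is its small-kT limit
  zg <- seq(-2, 2, by = 1e-3)
  w <- exp(6 * exp(-zg^2 / (2 * 0.5^2)) / (kB * 310))
  v_exact <- sum(zg^2 * w) / sum(w)
  expect_rel(v, v_exact, 0.08)
  expect_rel(v_exact, kB * 310 / kappa, 0.3)
})

test_that("long-run histogram matches the Boltzmann distribution", {
  spec <- potential_spec(G0 = 3.24, g = 0.004)  # dG(310) = 2.0
  cfg <- langevin_config(spec, 310, t_ns = 500, seed = 53, n_particles = 10)
  sim <- simulate_langevin(cfg)
  # thin to ~decorrelated samples (particles move ~2 nm per 400 ps)
  keep <- seq(1, nrow(sim$z), by = 400)
  zs <- as.vector(sim$z[keep, ])
  Lz <- sim$truth$Lz
  breaks <- seq(-Lz / 2, Lz / 2, by = 0.1)
  obs <- as.vector(table(cut(zs, breaks)))
  Gf <- potential_function(sim$truth)
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  w <- exp(-Gf(mids) / (kB * 310))
  expected <- length(zs) * w / sum(w)
  sel <- expected >= 20
  m <- sum(sel)
  zcrit <- qnorm(1 - 0.01 / (2 * m))  # Bonferroni at alpha = 0.01
  zscore <- (obs[sel] - expected[sel]) /
    sqrt(expected[sel] * (1 - expected[sel] / length(zs)))
  expect_lt(max(abs(zscore)), zcrit)
})

test_that("calibrated potential satisfies the three scaling laws", {
  spec <- potential_spec()
  for (Tt in c(310, 400, 500)) {
    cal <- calibrate_potential(spec, Tt)
    expect_rel(cal$delta_G, spec$G0 - spec$g * Tt, 0.01)
    expect_rel(cal$lb, spec$a * Tt^2, 0.05)
    # measured through the analysis layer on 0.1 nm binned profiles
    # (bin discretization of the sharp apex costs a few percent)
    prof <- analytic_profile(potential_function(cal), h = cal$Lz / 2,
                             temperature = Tt)
    bs <- barrier_summary(prof, z_mem = spec$z_channel)
    expect_rel(bs$delta_G_kcal_mol, spec$G0 - spec$g * Tt, 0.02)
    expect_rel(bs$lb_nm, spec$a * Tt^2, 0.10)
  }
  # reservoir scaling makes the exact rate follow the corrected law
  Ts <- c(440, 460, 480, 500)
  k <- sapply(Ts, function(Tt)
    10 * dl_vogel_fulcher(Tt) * calibrate_potential(spec, Tt)$k1_per_D)
  fit <- fit_corrected_arrhenius(Ts, k, dl_vogel_fulcher(Ts), quantity = "k")
  expect_rel(fit$G0, spec$G0, 0.002)
})

test_that("mfpt oracle matches closed forms and Kramers asymptotics", {
  flat <- function(z) rep(0, length(z))
  expect_rel(mfpt_oracle(flat, 2, 0, 3, 310), 3^2 / (2 * 2), 1e-6)
  # doubling D halves tau
  expect_rel(mfpt_oracle(flat, 1, 0, 3, 310),
             2 * mfpt_oracle(flat, 2, 0, 3, 310), 1e-9)

  # cosine bistable potential: escape time from a full well over a high
  # barrier matches the Kramers formula
  dG <- 8; L <- 4; D <- 1; Tt <- 310
  beta <- 1 / (kB * Tt)
  G <- function(z) dG / 2 * (1 - cos(2 * pi * z / L))
  kap <- dG / 2 * (2 * pi / L)^2
  tauK <- 2 * pi / (beta * D * kap) * exp(beta * dG)
  tauQ <- mfpt_oracle(G, D, -L / 2, L, Tt, n_grid = 20001)
  expect_rel(tauQ, tauK, 0.05)

  expect_error(mfpt_oracle(function(z) 1 / (z - 1), 1, 0, 2, 310),
               "divergent|finite")
})

test_that("flux oracle has the exact flat-box closed form", {
  flat <- function(z) rep(0, length(z))
  o <- crossing_rate_oracle(flat, D = 2, z_plane = 1.5, Lz = 8,
                            temperature = 310)
  expect_rel(o$k1_per_ns, 2 / (8 * 3), 1e-4)
  expect_equal(o$Z_nm, 8, tolerance = 1e-6)
  # at a high single barrier the flux oracle agrees with 1/(2 tau): the
  # reflecting boundary at the water midpoint halves the reservoir that
  # feeds the channel
  Gf <- function(z) 5 * exp(-z^2 / (2 * 0.3^2))
  o2 <- crossing_rate_oracle(Gf, D = 1, z_plane = 0.8, Lz = 8,
                             temperature = 310)
  tau <- mfpt_oracle(Gf, 1, -4, 0.8, 310)
  expect_rel(o2$k1_per_ns, 1 / (2 * tau), 0.1)
})

test_that("halving the time step leaves the crossing rate unchanged", {
  spec <- potential_spec()
  n1 <- local({
    cfg <- langevin_config(spec, 480, t_ns = 100, seed = 54,
                           n_particles = 20)
    sim <- simulate_langevin(cfg)
    ev <- detect_crossings_all(sim_traces(sim), spec$z_channel,
                               Lz = cfg$calib$Lz)
    nrow(ev)
  })
  n2 <- local({
    cfg <- langevin_config(spec, 480, t_ns = 100, seed = 55,
                           n_particles = 20, dt_ps = 0.04)
    sim <- simulate_langevin(cfg)
    ev <- detect_crossings_all(sim_traces(sim), spec$z_channel,
                               Lz = cfg$calib$Lz)
    nrow(ev)
  })
  expect_gt(n1, 100)
  expect_lt(abs(n1 - n2), 3 * sqrt(n1 + n2))
})

test_that("validation bundles are deterministic and respond to G0", {
  b1 <- make_validation_suite(99, fit_temps = c(460), T_low = NULL,
                              events_high = 40, events_low = 0)
  b2 <- make_validation_suite(99, fit_temps = c(460), T_low = NULL,
                              events_high = 40, events_low = 0)
  expect_identical(b1$runs[["460"]]$z, b2$runs[["460"]]$z)

  # lowering G0 raises the low-temperature crossing count at fixed length
  count_events <- function(G0, seed) {
    spec <- potential_spec(G0 = G0)
    cfg <- langevin_config(spec, 310, t_ns = 300, seed = seed,
                           n_particles = 20)
    sim <- simulate_langevin(cfg)
    nrow(detect_crossings_all(sim_traces(sim), spec$z_channel,
                              Lz = cfg$calib$Lz))
  }
  n_hi <- count_events(5.5, 56)
  n_lo <- count_events(5.0, 57)
  expect_gt(n_lo, n_hi)
})
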