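# Ground-truth synthetic data: overdamped Langevin dynamics in a
# temperature-parameterized trans-bilayer potential, plus analytic
# rate/MFPT oracles.
#
# The potential family is a pair of interfacial Gaussian peaks (optional
# central Gaussian well) on a periodic box.  Per temperature, the peak
# height H(T), peak width sigma(T) and box height Lz(T) are calibrated by
# root-finding on exact quadratures so that three laws hold to numerical
# tolerance:
#   (1) barrier height     dG(T) = G0 - g*T        (linear decrease),
#   (2) Aniansson width    lb(T) = a*T^2           (quadratic growth),
#   (3) reservoir scaling  Z(T)*R_chan(T) = const * T^4 * exp(G0/kB*T).
# With the solute diffusion coefficient tied to lipid diffusion
# (D = b*DL), (1)-(3) make the exact per-particle crossing rate
#   k(T) = D / (Z * R_chan) = c'' * DL(T)/T^4 * exp(-G0/(kB*T))
# follow the corrected Arrhenius law exactly, so every scaling law the
# analysis layer fits has a known ground truth.  The growing box emulates
# the growing aqueous partition entropy of a heated system.

.default_grid_dz <- 0.005

#' Ground-truth potential family specification
#'
#' @param G0 barrier-height intercept, kcal/mol (`dG(T) = G0 - g*T`).
#' @param g barrier-height slope, kcal/mol/K.
#' @param a barrier-width coefficient, nm/K^2 (`lb(T) = a*T^2`).
#' @param z_peak interfacial peak positions, +/- nm.
#' @param z_channel membrane-channel half-width, nm: the interfacial plane
#'   used for rate calibration and the natural crossing-detector plane.
#' @param T0 anchor temperature, K (box height is `Lz0` there).
#' @param Lz0 box height at the anchor temperature, nm.
#' @param well_depth optional central well depth, kcal/mol (default 0).
#' @param well_sigma central well width, nm.
#' @return A `potential_spec` object.
#' @export
potential_spec <- function(G0 = 5.5, g = 0.004, a = 7.284e-6,
                           z_peak = 1.3, z_channel = 1.75, T0 = 310,
                           Lz0 = 7, well_depth = 0, well_sigma = 0.5) {
  stopifnot(G0 > 0, g >= 0, a > 0, z_peak > 0, z_channel > z_peak,
            T0 > 0, Lz0 > 2 * z_channel, well_depth >= 0, well_sigma > 0)
  structure(
    list(G0 = G0, g = g, a = a, z_peak = z_peak, z_channel = z_channel,
         T0 = T0, Lz0 = Lz0, well_depth = well_depth,
         well_sigma = well_sigma),
    class = "potential_spec"
  )
}

# quadrature measurements for a concrete (H, sigma, Lz) realization
.measure_potential <- function(spec, H, sigma, Lz, kT,
                               dz = .default_grid_dz) {
  zg <- seq(-Lz / 2, Lz / 2, by = dz)
  G <- .potential_eval(zg, H, sigma, spec$z_peak, spec$well_depth,
                       spec$well_sigma)
  mem <- abs(zg) <= spec$z_channel
  iB <- which(mem)[which.max(G[mem])]
  GA <- min(G[seq_len(iB - 1)])
  GC <- min(G[seq(iB + 1, length(zg))])
  dG <- G[iB] - (GA + GC) / 2
  lb <- .trapz(zg, exp((G - dG) / kT))
  Z <- .trapz(zg, exp(-G / kT))
  R_chan <- .trapz(zg[mem], exp(G[mem] / kT))
  max_grad <- max(abs(diff(G) / dz))
  list(delta_G = dG, lb = lb, Z = Z, R_chan = R_chan, max_grad = max_grad)
}

#' Calibrate the ground-truth potential at a temperature
#'
#' Solves for the peak height, peak width and box height so that the
#' barrier height, Aniansson width and reservoir-scaling laws of the
#' specification hold at temperature `T` (see the package vignette).  The
#' reservoir-scaling constant is anchored at `spec$T0`, where the box
#' height is fixed at `spec$Lz0`.
#'
#' @param spec a [potential_spec].
#' @param temperature kelvin.
#' @param tol relative tolerance of the calibration (default 1e-6).
#' @return A `potential_calibration` list: `temperature`, `H`, `sigma`,
#'   `Lz`, achieved `delta_G`, `lb`, `Z`, `R_chan`, `k1_per_D`
#'   (per-particle one-direction crossing rate divided by D, 1/nm^2),
#'   `anchor_const`, `max_grad`, and the `spec`.
#' @export
calibrate_potential <- function(spec, temperature, tol = 1e-6) {
  kT <- .kB * temperature
  target_dG <- spec$G0 - spec$g * temperature
  if (target_dG <= 0.5)
    stop("barrier height G0 - g*T too small at this temperature for a meaningful barrier")
  target_lb <- spec$a * temperature^2

  at_anchor <- abs(temperature - spec$T0) < 1e-9
  anchor_const <- NA_real_
  target_prod <- NA_real_
  if (!at_anchor) {
    cal0 <- calibrate_potential(spec, spec$T0, tol = tol)
    anchor_const <- cal0$anchor_const
    target_prod <- anchor_const * temperature^4 * exp(spec$G0 / kT)
  }

  H <- target_dG + spec$well_depth / 2
  sigma <- max(0.08, target_lb / 2)
  Lz <- spec$Lz0
  m <- NULL
  for (round in 1:8) {
    H <- stats::uniroot(function(hh)
      .measure_potential(spec, hh, sigma, Lz, kT)$delta_G - target_dG,
      c(1e-3, target_dG + spec$well_depth + 2), tol = tol)$root
    f_lb <- function(ss)
      .measure_potential(spec, H, ss, Lz, kT)$lb - target_lb
    lo <- 0.02; hi <- min(1.4, spec$z_peak)
    if (f_lb(lo) > 0)
      stop("width law unreachable: barrier too low for the requested lb (water weight alone exceeds a*T^2)")
    if (f_lb(hi) < 0)
      stop("width law unreachable: requested lb too large for the peak geometry")
    sigma <- stats::uniroot(f_lb, c(lo, hi), tol = tol)$root
    if (!at_anchor) {
      f_pr <- function(ll) {
        mm <- .measure_potential(spec, H, sigma, ll, kT)
        log(mm$Z * mm$R_chan) - log(target_prod)
      }
      hi_L <- 120
      if (f_pr(2 * spec$z_channel + 0.6) > 0 || f_pr(hi_L) < 0)
        stop("reservoir-scaling law unreachable at this temperature")
      Lz <- stats::uniroot(f_pr, c(2 * spec$z_channel + 0.6, hi_L),
                           tol = tol)$root
    }
    m <- .measure_potential(spec, H, sigma, Lz, kT)
    ok <- abs(m$delta_G - target_dG) < 10 * tol * max(1, target_dG) &&
      abs(m$lb - target_lb) < 10 * tol * max(1, target_lb) &&
      (at_anchor ||
         abs(log(m$Z * m$R_chan) - log(target_prod)) < 100 * tol)
    if (ok && round >= 2) break
  }
  if (at_anchor)
    anchor_const <- m$Z * m$R_chan / (temperature^4 * exp(spec$G0 / kT))
  structure(
    list(temperature = temperature, H = H, sigma = sigma, Lz = Lz,
         delta_G = m$delta_G, lb = m$lb, Z = m$Z, R_chan = m$R_chan,
         k1_per_D = 1 / (m$Z * m$R_chan), anchor_const = anchor_const,
         max_grad = m$max_grad, spec = spec),
    class = "potential_calibration"
  )
}

#' @export
print.potential_calibration <- function(x, ...) {
  cat(sprintf("potential_calibration at %g K: H = %.3f, sigma = %.3f nm, Lz = %.2f nm\n",
              x$temperature, x$H, x$sigma, x$Lz))
  cat(sprintf("  dG = %.4f kcal/mol, lb = %.4f nm, Z = %.3f nm, R_chan = %.4g nm\n",
              x$delta_G, x$lb, x$Z, x$R_chan))
  invisible(x)
}

#' Evaluate the calibrated ground-truth potential
#'
#' @param calib a [calibrate_potential()] result.
#' @return A function `G(z)` in kcal/mol.
#' @export
potential_function <- function(calib) {
  force(calib)
  function(z) .potential_eval(z, calib$H, calib$sigma, calib$spec$z_peak,
                              calib$spec$well_depth, calib$spec$well_sigma)
}

#' Default lateral lipid diffusion rule of the synthetic bilayer
#'
#' A Vogel-Fulcher temperature dependence,
#' `DL(T) = DL_ref * exp(B/(T_ref - T_VF) - B/(T - T_VF))`,
#' the super-Arrhenius form typical of lipid lateral diffusion.  Its
#' curvature in Arrhenius coordinates is what makes naive 1/T
#' extrapolation fail and the lipid-diffusion correction necessary.
#'
#' @param temperature kelvin.
#' @param DL_ref reference value at `T_ref`, nm^2/ns.
#' @param T_ref reference temperature, K.
#' @param B activation scale, K.
#' @param T_VF Vogel-Fulcher divergence temperature, K.
#' @return DL in nm^2/ns.
#' @export
dl_vogel_fulcher <- function(temperature, DL_ref = 0.5, T_ref = 310,
                             B = 361, T_VF = 200) {
  stopifnot(all(temperature > T_VF))
  DL_ref * exp(B / (T_ref - T_VF) - B / (temperature - T_VF))
}

#' Overdamped Langevin trajectories in a 1D trans-bilayer potential
#'
#' Euler-Maruyama updates
#' `z <- z - (D/kB*T) * dG/dz * dt + sqrt(2*D*dt) * xi` with periodic
#' wrapping at +/- Lz/2, recorded at `cadence_ps` resolution after a
#' burn-in.  Uses R's RNG: call `set.seed()` first for reproducibility.
#' The drift-step ratio `max|drift*dt| / sqrt(2*D*dt)` must stay below
#' 0.2, otherwise an error suggests a smaller time step.
#'
#' @param z0 initial positions, nm (length = number of particles).
#' @param t_ns simulated time, ns.
#' @param dt_ps integrator time step, ps.
#' @param D diffusion coefficient, nm^2/ns.
#' @param temperature kelvin.
#' @param Lz box height, nm.
#' @param H,sigma,z_peak,well_depth,well_sigma potential parameters (see
#'   [potential_spec()]); `H = 0` gives free diffusion.
#' @param cadence_ps recording interval, ps (default 1 ps).
#' @param burnin_ns unrecorded equilibration time, ns.
#' @return A frames-by-particles matrix of z coordinates (nm) with
#'   attributes `sampling_interval` (ps), `temperature`, `D`, `Lz`.
#' @export
brownian_dynamics_1d <- function(z0, t_ns, dt_ps, D, temperature, Lz,
                                 H = 0, sigma = 1, z_peak = 0,
                                 well_depth = 0, well_sigma = 1,
                                 cadence_ps = 1, burnin_ns = 0) {
  stopifnot(t_ns > 0, dt_ps > 0, D > 0, temperature > 0, Lz > 0,
            cadence_ps >= dt_ps)
  kT <- .kB * temperature
  D_ps <- D * 1e-3                       # nm^2/ps
  # step-ratio guard on a fine grid of the potential
  if (H != 0 || well_depth != 0) {
    zg <- seq(-Lz / 2, Lz / 2, by = .default_grid_dz)
    G <- .potential_eval(zg, H, sigma, z_peak, well_depth, well_sigma)
    max_grad <- max(abs(diff(G) / .default_grid_dz))
    ratio <- (D_ps / kT) * max_grad * dt_ps / sqrt(2 * D_ps * dt_ps)
    if (ratio > 0.2) {
      dt_sugg <- (0.2 * sqrt(2 * D_ps) * kT / (D_ps * max_grad))^2
      stop(sprintf("time step too large: drift/step ratio %.3f > 0.2; use dt_ps <= %.3g",
                   ratio, dt_sugg))
    }
  }
  thin <- max(1L, round(cadence_ps / dt_ps))
  n_steps <- round(t_ns * 1e3 / dt_ps)
  burnin <- round(burnin_ns * 1e3 / dt_ps)
  out <- .langevin_run(z0, n_steps, thin, burnin, dt_ps, D_ps, kT, Lz,
                       H, sigma, z_peak, well_depth, well_sigma)
  attr(out, "sampling_interval") <- thin * dt_ps
  attr(out, "temperature") <- temperature
  attr(out, "D") <- D
  attr(out, "Lz") <- Lz
  out
}

#' Langevin simulation configuration
#'
#' Binds a [potential_spec] to one temperature, the lipid-diffusion table
#' and the solute-diffusion rule `D = b * DL(T)`.
#'
#' @param spec a [potential_spec].
#' @param temperature kelvin.
#' @param t_ns simulated time, ns.
#' @param seed mandatory RNG seed.
#' @param DL lateral lipid diffusion at this temperature, nm^2/ns
#'   (default: [dl_vogel_fulcher()]).
#' @param b solute/lipid diffusion proportionality constant.
#' @param n_particles number of solute particles.
#' @param dt_ps integrator step, ps.
#' @param cadence_ps recording interval, ps.
#' @param burnin_ns equilibration time, ns.
#' @return A `langevin_config` list (with the calibrated potential under
#'   `$calib`).
#' @export
langevin_config <- function(spec, temperature, t_ns, seed,
                            DL = dl_vogel_fulcher(temperature), b = 10,
                            n_particles = 20, dt_ps = 0.08, cadence_ps = 1,
                            burnin_ns = 10) {
  if (missing(seed) || is.null(seed)) stop("seed is mandatory")
  stopifnot(n_particles >= 1, DL > 0, b > 0)
  calib <- calibrate_potential(spec, temperature)
  D <- b * DL
  kT <- .kB * temperature
  D_ps <- D * 1e-3
  ratio <- (D_ps / kT) * calib$max_grad * dt_ps / sqrt(2 * D_ps * dt_ps)
  if (ratio > 0.2) {
    dt_sugg <- (0.2 * sqrt(2 * D_ps) * kT / (D_ps * calib$max_grad))^2
    stop(sprintf("time step too large: drift/step ratio %.3f > 0.2; use dt_ps <= %.3g",
                 ratio, dt_sugg))
  }
  structure(
    list(spec = spec, calib = calib, temperature = temperature,
         t_ns = t_ns, seed = seed, DL = DL, b = b, D = D,
         n_particles = n_particles, dt_ps = dt_ps,
         cadence_ps = cadence_ps, burnin_ns = burnin_ns),
    class = "langevin_config"
  )
}

#' Simulate solute trajectories in the calibrated bilayer potential
#'
#' Particles start uniformly distributed in the aqueous region (both
#' sides), equilibrate for the burn-in time and are then recorded at the
#' configured cadence.  Bit-reproducible for a fixed config (the seed is
#' part of the config).
#'
#' @param config a [langevin_config].
#' @return A `langevin_sim` list: `z` (frames-by-particles matrix, nm),
#'   `sampling_interval` (ps), `time_ps`, `temperature`, `config`, and
#'   `truth` (the [calibrate_potential()] ground truth, including the
#'   exact per-particle crossing rate `k1_per_ns`).
#' @export
simulate_langevin <- function(config) {
  stopifnot(inherits(config, "langevin_config"))
  calib <- config$calib
  set.seed(config$seed)
  half <- calib$Lz / 2
  z_lo <- config$spec$z_channel + 0.5
  if (z_lo >= half - 0.1) z_lo <- config$spec$z_channel
  n <- config$n_particles
  z0 <- stats::runif(n, z_lo, half) * sample(c(-1, 1), n, replace = TRUE)
  z <- brownian_dynamics_1d(
    z0, t_ns = config$t_ns, dt_ps = config$dt_ps, D = config$D,
    temperature = config$temperature, Lz = calib$Lz,
    H = calib$H, sigma = calib$sigma, z_peak = config$spec$z_peak,
    well_depth = config$spec$well_depth,
    well_sigma = config$spec$well_sigma,
    cadence_ps = config$cadence_ps, burnin_ns = config$burnin_ns
  )
  truth <- calib
  truth$k1_per_ns <- config$D * calib$k1_per_D
  structure(
    list(z = z, sampling_interval = attr(z, "sampling_interval"),
         time_ps = (seq_len(nrow(z)) - 1L) * attr(z, "sampling_interval"),
         temperature = config$temperature, config = config, truth = truth),
    class = "langevin_sim"
  )
}

#' @export
print.langevin_sim <- function(x, ...) {
  cat(sprintf("langevin_sim: %d particles x %d frames at %g ps, T = %g K, D = %.3g nm^2/ns\n",
              ncol(x$z), nrow(x$z), x$sampling_interval, x$temperature,
              x$config$D))
  invisible(x)
}

#' Convert a simulation to solute traces
#'
#' @param sim a `langevin_sim`.
#' @param species species label for the traces.
#' @return List of [solute_trace] objects.
#' @export
sim_traces <- function(sim, species = "synthetic") {
  lapply(seq_len(ncol(sim$z)), function(j)
    solute_trace(sprintf("mol%03d", j), species, sim$z[, j],
                 sampling_interval = sim$sampling_interval))
}

#' Independent 2D Brownian lipid walks
#'
#' Fixture generator for the lateral-diffusion estimator: each lipid
#' performs an independent 2D random walk with exactly the requested
#' diffusion coefficient.  Uses R's RNG (set the seed first, or pass one).
#'
#' @param DL diffusion coefficient, nm^2/ns (0 gives frozen lipids).
#' @param n_lipids number of lipids.
#' @param n_frames number of recorded frames.
#' @param dt_ps frame spacing, ps.
#' @param species species label(s), recycled over lipids.
#' @param seed optional seed (`set.seed` is called when supplied).
#' @return List of [lipid_trace] objects with unwrapped xy coordinates.
#' @export
simulate_lipid_walk <- function(DL, n_lipids, n_frames, dt_ps = 1000,
                                species = "POPC", seed = NULL) {
  stopifnot(DL >= 0, n_lipids >= 1, n_frames >= 2)
  if (!is.null(seed)) set.seed(seed)
  sd_step <- sqrt(2 * DL * dt_ps * 1e-3)  # per-axis step, nm
  species <- rep_len(species, n_lipids)
  lapply(seq_len(n_lipids), function(i) {
    dx <- if (sd_step > 0) stats::rnorm(n_frames - 1, 0, sd_step) else
      numeric(n_frames - 1)
    dy <- if (sd_step > 0) stats::rnorm(n_frames - 1, 0, sd_step) else
      numeric(n_frames - 1)
    lipid_trace(sprintf("lip%03d", i), species[i],
                cbind(cumsum(c(0, dx)), cumsum(c(0, dy))),
                z = rep(0, n_frames), sampling_interval = dt_ps)
  })
}

#' Mean first passage time by double quadrature
#'
#' For 1D diffusion in a potential `G` with a reflecting boundary at `a`
#' and an absorbing boundary at `b`,
#' `tau = int_a^b dz e^{G(z)/kBT}/D int_a^z dy e^{-G(y)/kBT}`.
#' The associated high-barrier rate convention is `1/(2*tau)` per particle
#' per direction (reaching the apex commits with probability one half).
#'
#' @param G potential function of z (kcal/mol), or a
#'   `potential_calibration`.
#' @param D diffusion coefficient, nm^2/ns.
#' @param a reflecting boundary, nm.
#' @param b absorbing boundary, nm (`a < b`).
#' @param temperature kelvin.
#' @param n_grid quadrature points.
#' @return Mean first passage time in ns.
#' @export
mfpt_oracle <- function(G, D, a, b, temperature, n_grid = 4001) {
  stopifnot(a < b, D > 0)
  if (inherits(G, "potential_calibration")) G <- potential_function(G)
  kT <- .kB * temperature
  zg <- seq(a, b, length.out = n_grid)
  Gv <- G(zg)
  if (any(!is.finite(Gv))) stop("divergent integrand: potential not finite on [a, b]")
  em <- exp(-Gv / kT)
  # cumulative inner integral int_a^z e^{-G}
  dz <- diff(zg)
  inner <- c(0, cumsum(dz * (em[-1] + em[-n_grid]) / 2))
  .trapz(zg, exp(Gv / kT) * inner) / D
}

#' Exact equilibrium crossing-rate oracle
#'
#' Transition-path flux for 1D equilibrium diffusion on a periodic box:
#' the per-particle rate of completed traversals of the membrane channel
#' `|z| <= z_plane` in one direction is
#' `k1 = D / (Z * R_chan)`, with `Z = int exp(-G/kBT)` over the whole box
#' and `R_chan = int exp(+G/kBT)` across the channel.  Exact at any
#' barrier height; at high barriers it reduces to the Kramers/MFPT rate
#' `1/(2*tau)`.  The expected number of detector events (both directions,
#' `n` particles, time `t`) is `2 * n * k1 * t`.
#'
#' @param G potential function of z (kcal/mol), or a
#'   `potential_calibration`.
#' @param D diffusion coefficient, nm^2/ns.
#' @param z_plane channel half-width (detector plane), nm.
#' @param Lz box height, nm.
#' @param temperature kelvin.
#' @param n_grid quadrature points.
#' @return A list: `k1_per_ns`, `Z_nm`, `R_chan_nm`.
#' @export
crossing_rate_oracle <- function(G, D, z_plane, Lz, temperature,
                                 n_grid = 8001) {
  stopifnot(D > 0, z_plane > 0, z_plane < Lz / 2)
  if (inherits(G, "potential_calibration")) G <- potential_function(G)
  kT <- .kB * temperature
  zg <- seq(-Lz / 2, Lz / 2, length.out = n_grid)
  Gv <- G(zg)
  Z <- .trapz(zg, exp(-Gv / kT))
  sel <- abs(zg) <= z_plane
  R_chan <- .trapz(zg[sel], exp(Gv[sel] / kT))
  list(k1_per_ns = D / (Z * R_chan), Z_nm = Z, R_chan_nm = R_chan)
}

#' Generate the high/low-temperature validation bundle
#'
#' Simulates the synthetic bilayer at the four high fit temperatures plus
#' one long low-temperature run, with ground truth attached -- the design
#' used to validate extrapolated against directly simulated kinetics.
#' Run lengths are chosen from the analytic rates to reach the requested
#' expected event counts.
#'
#' @param seed RNG seed (drives every run deterministically).
#' @param spec a [potential_spec].
#' @param fit_temps high temperatures, K.
#' @param T_low low target temperature, K.
#' @param events_high expected events per high-temperature run.
#' @param events_low expected events in the low-temperature run (set 0 to
#'   skip the direct run).
#' @param b,n_particles,dt_ps as in [langevin_config()].
#' @param DL_fun function T -> DL (nm^2/ns).
#' @return A `validation_bundle` list: `runs` (named by temperature; each
#'   a `langevin_sim`), `spec`, `DL_table` (data frame T, DL), `seed`.
#' @export
make_validation_suite <- function(seed, spec = potential_spec(),
                                  fit_temps = c(440, 460, 480, 500),
                                  T_low = 310, events_high = 150,
                                  events_low = 60, b = 10,
                                  n_particles = 20, dt_ps = 0.08,
                                  DL_fun = dl_vogel_fulcher) {
  temps <- c(fit_temps, if (events_low > 0 && !is.null(T_low)) T_low)
  runs <- list()
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max, length(temps))
  for (i in seq_along(temps)) {
    Tt <- temps[i]
    DL <- DL_fun(Tt)
    calib <- calibrate_potential(spec, Tt)
    k1 <- b * DL * calib$k1_per_D
    target <- if (!is.null(T_low) && Tt == T_low && !(T_low %in% fit_temps))
      events_low else events_high
    t_ns <- target / (2 * n_particles * k1)
    cfg <- langevin_config(spec, Tt, t_ns = t_ns, seed = seeds[i], DL = DL,
                           b = b, n_particles = n_particles, dt_ps = dt_ps)
    runs[[as.character(Tt)]] <- simulate_langevin(cfg)
  }
  structure(
    list(runs = runs, spec = spec,
         DL_table = data.frame(temperature = temps,
                               DL_nm2_ns = DL_fun(temps)),
         seed = seed, b = b),
    class = "validation_bundle"
  )
}
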