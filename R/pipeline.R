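# Orchestration: simulate/ingest -> profiles -> kinetics -> diffusion ->
# extrapolation -> permeability report.

#' Assemble and validate a pipeline configuration
#'
#' Two input modes: `"simulate"` (the bundled Langevin generator supplies
#' trajectories with ground truth) and `"files"` (canonical tabular
#' trajectories on disk, one per temperature).  Physically impossible
#' values (non-positive temperature, concentration, area, bin width) are
#' rejected here, before any stage runs.
#'
#' @param mode `"simulate"` or `"files"`.
#' @param compound compound label used in reports.
#' @param seed RNG seed (simulate mode).
#' @param simulate named list of arguments for [make_validation_suite()]
#'   (e.g. `spec`, `fit_temps`, `events_high`, `events_low`,
#'   `n_particles`, `b`).
#' @param files named list: temperature (as character) -> list with
#'   `path` and a [system_spec] under `spec`.
#' @param S_nm2 membrane area, nm^2.
#' @param C_mM nominal aqueous concentration, mM.
#' @param target_temp extrapolation target temperature, K.
#' @param fit_temps temperatures used in the corrected Arrhenius fit; the
#'   default takes the four highest available at or above 440 K.
#' @param z_plane crossing-detector plane, nm; defaults to the synthetic
#'   spec's channel half-width (simulate mode) and must be given in files
#'   mode unless half the phosphate-phosphate distance can be derived.
#' @param z_mem apex-search half-window, nm; defaults to `z_plane`.
#' @param bin_width profile bin width, nm.
#' @param block_ns error-block length, ns (`"auto"` scales it down to a
#'   fifth of short runs).
#' @param bulk_width bulk-reference zone width, nm.
#' @param DL_table optional data frame (temperature, DL_nm2_ns) when
#'   lipid traces are absent.
#' @param temperature_unit `"K"` or `"C"` for temperatures quoted in
#'   `files`/`DL_table`/`target_temp`/`fit_temps`.
#' @param outdir optional output directory for TSV/JSON stage outputs.
#' @return A validated `pipeline_config`.
#' @export
pipeline_config <- function(mode = c("simulate", "files"), compound = "synthetic",
                            seed = 1, simulate = list(), files = list(),
                            S_nm2 = 21.744, C_mM = 410, target_temp = 310,
                            fit_temps = NULL, z_plane = NULL, z_mem = NULL,
                            bin_width = 0.1, block_ns = "auto",
                            bulk_width = 0.5, DL_table = NULL,
                            temperature_unit = "K", outdir = NULL) {
  mode <- match.arg(mode)
  target_temp <- as_kelvin(target_temp, temperature_unit)
  if (!is.null(fit_temps)) fit_temps <- as_kelvin(fit_temps, temperature_unit)
  if (S_nm2 <= 0) stop("membrane area must be positive")
  if (C_mM <= 0) stop("concentration must be positive")
  if (bin_width <= 0) stop("bin width must be positive")
  if (!identical(block_ns, "auto") && block_ns <= 0)
    stop("block length must be positive")
  if (!is.null(DL_table)) {
    if (!all(c("temperature", "DL_nm2_ns") %in% names(DL_table)))
      stop("DL_table needs columns temperature, DL_nm2_ns")
    DL_table$temperature <- as_kelvin(DL_table$temperature, temperature_unit)
    if (any(DL_table$DL_nm2_ns <= 0)) stop("DL values must be positive")
  }
  if (mode == "files") {
    if (length(files) == 0) stop("files mode needs at least one trajectory")
    names(files) <- as.character(as_kelvin(as.numeric(names(files)),
                                           temperature_unit))
  }
  structure(
    list(mode = mode, compound = compound, seed = seed, simulate = simulate,
         files = files, S_nm2 = S_nm2, C_mM = C_mM,
         target_temp = target_temp, fit_temps = fit_temps,
         z_plane = z_plane, z_mem = z_mem, bin_width = bin_width,
         block_ns = block_ns, bulk_width = bulk_width,
         DL_table = DL_table, outdir = outdir),
    class = "pipeline_config"
  )
}

# DL at given temperatures: exact table matches, else log-log interpolation
.dl_lookup <- function(DL_tab, temps) {
  vapply(temps, function(Tt) {
    j <- which(abs(DL_tab$temperature - Tt) < 1e-6)
    if (length(j) >= 1) return(DL_tab$DL_nm2_ns[j[1]])
    if (nrow(DL_tab) < 2)
      stop(sprintf("cannot interpolate DL at %g K from a single-entry table", Tt))
    exp(stats::approx(log(DL_tab$temperature), log(DL_tab$DL_nm2_ns),
                      xout = log(Tt), rule = 2)$y)
  }, numeric(1))
}

# analyse one temperature: profile, barrier, crossings, permeability
.analyse_temperature <- function(z_mat, sampling_ps, temperature, Lz,
                                 cfg) {
  n_frames <- nrow(z_mat)
  total_ns <- (n_frames - 1) * sampling_ps / 1e3
  total_us <- total_ns / 1e3
  h <- Lz / 2
  z_pool <- as.vector(z_mat)
  t_pool <- rep((seq_len(n_frames) - 1) * sampling_ps, ncol(z_mat))
  block_ns <- if (identical(cfg$block_ns, "auto"))
    min(100, total_ns / 5) else min(cfg$block_ns, total_ns / 2)
  prof <- compute_free_energy(z_pool, t_pool, temperature, h = h,
                              bin_width = cfg$bin_width,
                              block_ns = block_ns,
                              bulk_width = cfg$bulk_width)
  bar <- barrier_summary(prof, z_mem = cfg$z_mem, h = h)
  ev_n <- 0L
  for (j in seq_len(ncol(z_mat))) {
    ev_n <- ev_n + nrow(detect_crossings(z_mat[, j], z_plane = cfg$z_plane,
                                         Lz = Lz,
                                         sampling_interval = sampling_ps))
  }
  rate <- transition_rate(ev_n, total_us, n_solutes = ncol(z_mat),
                          temperature = temperature)
  perm <- permeability_direct(rate, S = cfg$S_nm2, C = cfg$C_mM)
  list(temperature = temperature, profile = prof, barrier = bar,
       n_events = ev_n, total_time_us = total_us, rate = rate,
       permeability = perm, block_ns = block_ns)
}

#' Run the full permeability pipeline
#'
#' Executes the stages in dependency order for every temperature --
#' free-energy profile with block errors, barrier summary (height and
#' Aniansson width), crossing detection and direct permeability -- then
#' fits the temperature scaling laws (barrier height linear in T, width
#' quadratic in T), fits the corrected Arrhenius model on the
#' high-temperature permeabilities and extrapolates to the target
#' temperature.  Deterministic for a fixed config (one seed drives the
#' simulate mode).
#'
#' @param config a [pipeline_config].
#' @return A `permeability_report`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  cfg <- config
  per_T <- list()
  DL_tab <- cfg$DL_table
  if (cfg$mode == "simulate") {
    args <- cfg$simulate
    args$seed <- cfg$seed
    bundle <- do.call(make_validation_suite, args)
    spec <- bundle$spec
    if (is.null(cfg$z_plane)) cfg$z_plane <- spec$z_channel
    if (is.null(cfg$z_mem)) cfg$z_mem <- cfg$z_plane
    DL_tab <- bundle$DL_table
    for (nm in names(bundle$runs)) {
      sim <- bundle$runs[[nm]]
      per_T[[nm]] <- .analyse_temperature(sim$z, sim$sampling_interval,
                                          sim$temperature, sim$truth$Lz, cfg)
      per_T[[nm]]$truth <- sim$truth
    }
  } else {
    if (is.null(cfg$z_plane))
      stop("files mode needs an explicit z_plane (e.g. half the phosphate-phosphate distance)")
    if (is.null(cfg$z_mem)) cfg$z_mem <- cfg$z_plane
    dl_meas <- list()
    for (nm in names(cfg$files)) {
      entry <- cfg$files[[nm]]
      Tt <- as.numeric(nm)
      tr <- load_trajectory(entry$path, spec = entry$spec)
      if (length(tr$solutes) == 0)
        stop(sprintf("no solute traces in %s", entry$path))
      Lz <- mean(tr$boxes$Lz_nm)
      raw_z <- sapply(tr$solutes, function(s) s$z)
      if (length(tr$lipids) > 0) {
        pz <- sapply(tr$lipids, function(l) l$z)
        z_mat <- recenter_on_bilayer(raw_z, pz, tr$boxes)$z
        dl_est <- tryCatch(lateral_lipid_diffusion(tr$lipids),
                           error = function(e) NULL)
        if (!is.null(dl_est))
          dl_meas[[nm]] <- data.frame(temperature = Tt,
                                      DL_nm2_ns = dl_est$D_nm2_ns)
      } else {
        z_mat <- raw_z
      }
      dt <- tr$solutes[[1]]$sampling_interval
      per_T[[nm]] <- .analyse_temperature(as.matrix(z_mat), dt, Tt, Lz, cfg)
    }
    if (is.null(DL_tab) && length(dl_meas) > 0)
      DL_tab <- do.call(rbind, dl_meas)
  }
  if (is.null(DL_tab))
    stop("no lipid-diffusion information: supply DL_table or lipid traces ",
         "(the slab estimator needs solute apex occupancy, infeasible here)")

  temps <- sapply(per_T, function(x) x$temperature)
  ord <- order(temps)
  per_T <- per_T[ord]; temps <- temps[ord]
  summary_tab <- data.frame(
    temperature = temps,
    delta_G_kcal_mol = sapply(per_T, function(x) x$barrier$delta_G_kcal_mol),
    delta_G_stderr = sapply(per_T, function(x) x$barrier$delta_G_stderr),
    lb_nm = sapply(per_T, function(x) x$barrier$lb_nm),
    n_events = sapply(per_T, function(x) x$n_events),
    total_time_us = sapply(per_T, function(x) x$total_time_us),
    P_cm_s = sapply(per_T, function(x) x$permeability$P_cm_s),
    P_stderr = sapply(per_T, function(x) x$permeability$stderr_cm_s),
    row.names = NULL
  )
  summary_tab$DL_nm2_ns <- .dl_lookup(DL_tab, temps)

  barrier_fit <- if (length(temps) >= 2)
    fit_barrier_vs_T(temps, summary_tab$delta_G_kcal_mol,
                     stderr = if (!anyNA(summary_tab$delta_G_stderr))
                       summary_tab$delta_G_stderr) else NULL
  width_fit <- if (length(temps) >= 2)
    fit_width_vs_T(temps, summary_tab$lb_nm) else NULL

  fit_temps <- cfg$fit_temps
  if (is.null(fit_temps)) {
    hi <- sort(temps[temps >= 440], decreasing = TRUE)
    fit_temps <- if (length(hi) >= 3) sort(utils::head(hi, 4)) else
      sort(temps, decreasing = TRUE)[seq_len(min(4, length(temps)))]
  }
  sel <- summary_tab$temperature %in% fit_temps & summary_tab$P_cm_s > 0
  model <- NULL; prediction <- NULL; dl_interpolated <- FALSE
  if (sum(sel) >= 3) {
    model <- fit_corrected_arrhenius(
      summary_tab$temperature[sel], summary_tab$P_cm_s[sel],
      summary_tab$DL_nm2_ns[sel], stderr = summary_tab$P_stderr[sel])
    i_t <- which(abs(DL_tab$temperature - cfg$target_temp) < 1e-6)
    dl_interpolated <- length(i_t) == 0
    DL_target <- .dl_lookup(DL_tab, cfg$target_temp)
    prediction <- predict_permeability(model, cfg$target_temp, DL_target)
  }
  direct_idx <- which(abs(temps - cfg$target_temp) < 1e-6)
  report <- structure(
    list(compound = cfg$compound, config = cfg, per_temperature = per_T,
         summary = summary_tab, barrier_fit = barrier_fit,
         width_fit = width_fit, model = model, prediction = prediction,
         dl_interpolated = dl_interpolated,
         direct_at_target = if (length(direct_idx) == 1)
           per_T[[direct_idx]]$permeability else NULL,
         DL_table = DL_tab, fit_temps = fit_temps),
    class = "permeability_report"
  )
  if (!is.null(cfg$outdir)) write_report(report, cfg$outdir)
  report
}

#' @export
print.permeability_report <- function(x, ...) {
  cat(sprintf("permeability_report for %s\n", x$compound))
  print(format(x$summary, digits = 4), row.names = FALSE)
  if (!is.null(x$barrier_fit))
    cat(sprintf("barrier law: dG(T) = %.3f - %.5f*T kcal/mol\n",
                x$barrier_fit$G0, x$barrier_fit$g))
  if (!is.null(x$width_fit))
    cat(sprintf("width law:   lb(T) = %.3g*T^%.2f nm\n",
                x$width_fit$a, x$width_fit$ml))
  if (!is.null(x$model))
    cat(sprintf("corrected Arrhenius: G0 = %.3f +/- %.3f kcal/mol (fit %s K)\n",
                x$model$G0, x$model$G0_stderr,
                paste(x$fit_temps, collapse = ", ")))
  if (!is.null(x$prediction))
    cat(sprintf("predicted P(%g K) = %.4g cm/s [%.4g, %.4g]%s\n",
                x$prediction$T_target, x$prediction$P,
                x$prediction$P_lower, x$prediction$P_upper,
                if (x$dl_interpolated) " (DL interpolated)" else ""))
  if (!is.null(x$direct_at_target))
    cat(sprintf("direct P(%g K)    = %.4g +/- %.2g cm/s (%d events)\n",
                x$config$target_temp, x$direct_at_target$P_cm_s,
                x$direct_at_target$stderr_cm_s,
                x$direct_at_target$n_events))
  invisible(x)
}

#' Write a permeability report to disk
#'
#' Writes `report.json` (fits, prediction, config echo), `summary.tsv`
#' and per-temperature profile TSVs into `outdir`.
#'
#' @param report a `permeability_report`.
#' @param outdir output directory (created if missing).
#' @export
write_report <- function(report, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(report$summary, file.path(outdir, "summary.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  for (x in report$per_temperature)
    write_profile(x$profile,
                  file.path(outdir, sprintf("profile_%gK.tsv", x$temperature)))
  obj <- list(
    compound = report$compound,
    units = list(P = "cm/s", G = "kcal/mol", lb = "nm", DL = "nm^2/ns",
                 temperature = "K"),
    summary = report$summary,
    barrier_fit = if (!is.null(report$barrier_fit))
      report$barrier_fit[c("G0", "g", "G0_stderr", "g_stderr")],
    width_fit = if (!is.null(report$width_fit))
      report$width_fit[c("a", "ml", "ml_stderr")],
    corrected_arrhenius = if (!is.null(report$model))
      list(G0_kcal_mol = report$model$G0, ln_c = report$model$ln_c,
           G0_stderr = report$model$G0_stderr,
           fit_temps = report$fit_temps),
    prediction = if (!is.null(report$prediction))
      list(T_target = report$prediction$T_target,
           P_cm_s = report$prediction$P,
           P_lower = report$prediction$P_lower,
           P_upper = report$prediction$P_upper,
           DL_interpolated = report$dl_interpolated),
    direct_at_target = if (!is.null(report$direct_at_target))
      list(P_cm_s = report$direct_at_target$P_cm_s,
           stderr = report$direct_at_target$stderr_cm_s,
           n_events = report$direct_at_target$n_events),
    config = list(S_nm2 = report$config$S_nm2, C_mM = report$config$C_mM,
                  z_plane = report$config$z_plane,
                  bin_width = report$config$bin_width,
                  seed = report$config$seed)
  )
  jsonlite::write_json(obj, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(outdir)
}

#' Compare predicted with experimental permeabilities
#'
#' Per-compound ratio and log10 difference between simulated and measured
#' permeability, plus the orders-of-magnitude span covered.
#'
#' @param predicted data frame with columns `compound`, `P_cm_s` (or a
#'   single `permeability_report`).
#' @param experimental data frame with columns `compound`, `P_app_cm_s`
#'   and optionally `error`; an empty table yields a report without a
#'   comparison section (NULL).
#' @return A `comparison_table` data frame: compound, P_sim, P_app, ratio,
#'   log10_diff; attribute `span_orders` gives the permeability span.
#' @export
compare_to_experiment <- function(predicted, experimental) {
  if (inherits(predicted, "permeability_report")) {
    P <- if (!is.null(predicted$prediction)) predicted$prediction$P
      else predicted$direct_at_target$P_cm_s
    predicted <- data.frame(compound = predicted$compound, P_cm_s = P)
  }
  stopifnot(all(c("compound", "P_cm_s") %in% names(predicted)))
  if (is.null(experimental) || nrow(experimental) == 0) return(NULL)
  if (!"P_app_cm_s" %in% names(experimental)) {
    alt <- grep("^P_app", names(experimental), value = TRUE)
    if (length(alt) == 1)
      stop(sprintf("experimental permeability column '%s' is not in cm/s (expected 'P_app_cm_s')", alt))
    stop("experimental table needs columns compound, P_app_cm_s")
  }
  m <- merge(predicted, experimental, by = "compound")
  if (nrow(m) == 0) stop("no matching compound keys between the tables")
  m$ratio <- m$P_cm_s / m$P_app_cm_s
  m$log10_diff <- log10(m$P_cm_s) - log10(m$P_app_cm_s)
  attr(m, "span_orders") <-
    diff(range(log10(c(m$P_cm_s, m$P_app_cm_s))))
  class(m) <- c("comparison_table", "data.frame")
  m
}
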