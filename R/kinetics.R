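# Spontaneous crossing events, transport rates and permeability.
#
# A crossing is a completed ordered traversal upper water -> membrane ->
# lower water (or the reverse) through the interfacial planes at +/-
# z_plane.  Direct upper <-> lower transitions (the periodic water route)
# are structurally excluded, as are traversals in progress at either end
# of the trajectory.

#' Detect trans-membrane crossing events
#'
#' Classifies each frame of a bilayer-centred, wrapped trace into three
#' states -- upper water (z > z_plane), membrane (|z| <= z_plane), lower
#' water (z < -z_plane) -- and counts ordered traversals
#' upper -> membrane -> lower and lower -> membrane -> upper.  Molecules
#' that hop between the water states directly (through the periodic
#' boundary) are never counted; membrane visits that return to the
#' entry side are not counted; traversals already in progress at the
#' first frame or unfinished at the last frame are discarded.
#'
#' @param trace a [solute_trace] (bilayer-centred, wrapped), or a numeric
#'   vector of z coordinates.
#' @param z_plane interfacial plane position, nm (> 0); a natural default
#'   is half the phosphate-phosphate distance.
#' @param Lz box height, nm; needed to reject `z_plane >= Lz/2` and to
#'   flag single-frame jumps larger than Lz/2 as wrap artefacts.
#' @param sampling_interval frame spacing in ps (taken from the trace if
#'   one is supplied).
#' @return A `crossing_events` data frame with columns `molecule_id`,
#'   `direction` (`"+z->-z"` or `"-z->+z"`), `entry_frame`, `exit_frame`,
#'   `entry_time_ns`, `exit_time_ns`, `duration_ns`.
#' @export
detect_crossings <- function(trace, z_plane, Lz = NULL,
                             sampling_interval = NULL) {
  if (inherits(trace, "solute_trace")) {
    z <- trace$z
    id <- trace$molecule_id
    if (is.null(sampling_interval)) sampling_interval <- trace$sampling_interval
  } else {
    z <- as.numeric(trace)
    id <- "trace"
    if (is.null(sampling_interval)) sampling_interval <- 1
  }
  stopifnot(z_plane > 0)
  if (!is.null(Lz)) {
    if (z_plane >= Lz / 2)
      stop("z_plane must lie inside the box (z_plane < Lz/2)")
    if (length(z) > 1) {
      # routine boundary wraps give raw jumps ~ Lz whose minimum-image
      # displacement is small; a jump that stays large after minimum-image
      # correction cannot be a simple wrap and is flagged
      dz <- diff(z)
      mi <- dz - Lz * round(dz / Lz)
      if (any(abs(mi) > Lz / 4))
        warning(sprintf("%d single-frame jump(s) > Lz/4 after minimum-image correction treated as wrap artefacts (periodic water route)",
                        sum(abs(mi) > Lz / 4)))
    }
  }
  # states: +1 upper water, 0 membrane, -1 lower water
  state <- ifelse(z > z_plane, 1L, ifelse(z < -z_plane, -1L, 0L))
  r <- rle(state)
  v <- r$values
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  ev <- list()
  if (length(v) >= 3) {
    for (i in 2:(length(v) - 1)) {
      if (v[i] != 0L) next
      before <- v[i - 1]; after <- v[i + 1]
      if (before == 0L || after == 0L) next
      if (before == after) next           # re-entry without traversal
      entry <- starts[i]; exit <- ends[i] + 1L
      ev[[length(ev) + 1L]] <- data.frame(
        molecule_id = id,
        direction = if (before == 1L) "+z->-z" else "-z->+z",
        entry_frame = entry, exit_frame = exit,
        stringsAsFactors = FALSE
      )
    }
  }
  out <- if (length(ev)) do.call(rbind, ev) else
    data.frame(molecule_id = character(0), direction = character(0),
               entry_frame = integer(0), exit_frame = integer(0),
               stringsAsFactors = FALSE)
  out$entry_time_ns <- (out$entry_frame - 1L) * sampling_interval / 1e3
  out$exit_time_ns <- (out$exit_frame - 1L) * sampling_interval / 1e3
  out$duration_ns <- out$exit_time_ns - out$entry_time_ns
  class(out) <- c("crossing_events", "data.frame")
  out
}

#' Detect crossings for a list of traces
#'
#' @param traces list of [solute_trace] objects.
#' @inheritParams detect_crossings
#' @return A combined `crossing_events` data frame.
#' @export
detect_crossings_all <- function(traces, z_plane, Lz = NULL) {
  out <- do.call(rbind, lapply(traces, detect_crossings, z_plane = z_plane,
                               Lz = Lz))
  class(out) <- c("crossing_events", "data.frame")
  out
}

#' Transport rate from crossing counts
#'
#' The molecular transport rate is the number of observed events divided
#' by the total simulated time, `r = N/t`, with Poisson standard error
#' `sqrt(N)/t`.  Both flux directions are pooled.  The per-molecule rate
#' constant is `k = r / n_solutes`.
#'
#' @param events a `crossing_events` data frame, or an event count.
#' @param total_time_us total simulated time, microseconds.
#' @param n_solutes number of solute molecules in the system.
#' @param temperature optional temperature tag, kelvin.
#' @return A `rate_estimate` list: `n_events`, `total_time_us`,
#'   `rate_per_s`, `rate_stderr_per_s`, `per_molecule_k_per_s`,
#'   `undersampled` (TRUE when no events were observed; the stderr is then
#'   the 1/t upper-bound scale), `temperature`.
#' @export
transition_rate <- function(events, total_time_us, n_solutes = 1,
                            temperature = NA_real_) {
  if (total_time_us <= 0) stop("total_time_us must be positive")
  n <- if (is.data.frame(events)) nrow(events) else as.integer(events)
  stopifnot(n >= 0, n_solutes >= 1)
  t_s <- total_time_us * 1e-6
  r <- n / t_s
  se <- if (n > 0) sqrt(n) / t_s else 1 / t_s
  structure(
    list(n_events = n, total_time_us = total_time_us,
         rate_per_s = r, rate_stderr_per_s = se,
         per_molecule_k_per_s = r / n_solutes,
         n_solutes = n_solutes,
         undersampled = n == 0, temperature = temperature),
    class = "rate_estimate"
  )
}

#' @export
print.rate_estimate <- function(x, ...) {
  cat(sprintf("rate_estimate: %d events in %g us -> r = %.4g +/- %.2g s^-1%s\n",
              x$n_events, x$total_time_us, x$rate_per_s, x$rate_stderr_per_s,
              if (x$undersampled) " (no events: undersampled, stderr is the 1/t scale)" else ""))
  invisible(x)
}

#' Permeability from a directly observed crossing rate
#'
#' `P = r / (2 * S * C)` with the concentration converted to molecules per
#' nm^3 and the result reported in cm/s.  The factor 2 accounts for the
#' bidirectional flux captured in equilibrium simulations, whereas
#' experiments measure one direction only.
#'
#' @param rate a [transition_rate()] estimate (or a rate in s^-1).
#' @param S membrane area, nm^2.
#' @param C nominal aqueous solute concentration, mM.
#' @param method tag recorded in the result (`"direct"` or
#'   `"extrapolated"`).
#' @return A `permeability_estimate` list: `P_cm_s`, `stderr_cm_s`, `S_nm2`,
#'   `C_mM`, `method`, `temperature`, `n_events`.
#' @export
permeability_direct <- function(rate, S, C, method = "direct") {
  if (S <= 0) stop("membrane area S must be positive")
  if (C <= 0) stop("concentration C must be positive")
  if (is.numeric(rate)) {
    rate <- structure(
      list(rate_per_s = rate, rate_stderr_per_s = 0, n_events = NA_integer_,
           temperature = NA_real_, undersampled = FALSE),
      class = "rate_estimate")
  }
  if (!inherits(rate, "rate_estimate")) stop("rate must be a rate_estimate")
  C_nm3 <- C * .mM_to_per_nm3
  fac <- .nm_per_s_to_cm_per_s / (2 * S * C_nm3)
  structure(
    list(P_cm_s = rate$rate_per_s * fac,
         stderr_cm_s = rate$rate_stderr_per_s * fac,
         S_nm2 = S, C_mM = C, method = method,
         temperature = rate$temperature, n_events = rate$n_events,
         undersampled = isTRUE(rate$undersampled)),
    class = "permeability_estimate"
  )
}

#' @export
print.permeability_estimate <- function(x, ...) {
  cat(sprintf("permeability_estimate (%s): P = %.4g +/- %.2g cm/s (S = %.3f nm^2, C = %g mM)\n",
              x$method, x$P_cm_s, x$stderr_cm_s, x$S_nm2, x$C_mM))
  invisible(x)
}

#' Apparent permeability from a transwell assay
#'
#' `P = V_A * C_A / (t * S * C_L)`: basolateral volume times basolateral
#' concentration, over time, membrane area and luminal (apical donor)
#' concentration.  `C_A` and `C_L` must share units.
#'
#' @param V_A basolateral compartment volume, cm^3.
#' @param C_A basolateral (receiver) concentration.
#' @param C_L luminal/apical (donor) concentration, same units as `C_A`.
#' @param t elapsed time, s.
#' @param S monolayer area, cm^2.
#' @return Apparent permeability in cm/s.
#' @export
transwell_permeability <- function(V_A, C_A, C_L, t, S) {
  if (V_A <= 0 || C_L <= 0 || t <= 0 || S <= 0)
    stop("V_A, C_L, t and S must be positive")
  if (C_A < 0) stop("C_A must be non-negative")
  if (C_A > C_L)
    warning("C_A > C_L: sink condition violated; the linear formula underestimates P")
  V_A * C_A / (t * S * C_L)
}

#' Equilibrium aqueous-phase concentration from occupancy
#'
#' For strongly membrane-partitioning solutes the nominal loading
#' concentration overstates the aqueous-phase concentration driving the
#' flux.  This estimates the equilibrium aqueous concentration from the
#' fraction of frames the solutes spend in the water phase
#' (`|z| > z_plane`) and the aqueous volume `S * (Lz - 2*z_plane)`.
#'
#' @param z_mat frames-by-molecules matrix of bilayer-centred z (nm).
#' @param z_plane interfacial plane, nm.
#' @param S membrane area, nm^2.
#' @param Lz box height, nm.
#' @return Aqueous concentration in mM.
#' @export
aqueous_concentration <- function(z_mat, z_plane, S, Lz) {
  z_mat <- as.matrix(z_mat)
  stopifnot(z_plane > 0, z_plane < Lz / 2, S > 0)
  f_water <- mean(abs(z_mat) > z_plane)
  V_water <- S * (Lz - 2 * z_plane)
  n_aq <- ncol(z_mat) * f_water
  n_aq / V_water / .mM_to_per_nm3
}

#' Write crossing events as TSV
#'
#' @param events a `crossing_events` data frame.
#' @param path output path.
#' @export
write_events <- function(events, path) {
  utils::write.table(
    as.data.frame(events)[, c("molecule_id", "direction", "entry_time_ns",
                              "exit_time_ns", "duration_ns")],
    path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
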