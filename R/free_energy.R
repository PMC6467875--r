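# Trans-bilayer density and free-energy profiles.
#
# G(z) = -kB*T*ln(rho(z)) with rho normalized to the bulk-water plateau, so
# the aqueous phase defines the zero of free energy.  Zero-count bins are
# censored, never interpolated: a censored apex is an error (the data do
# not determine the barrier), not a guess.

#' Trans-bilayer relative density profile
#'
#' Histograms pooled solute z samples over \[-h, h\] in uniform bins and
#' normalizes the density to the bulk-water plateau (mean density over
#' `|z| in [h - bulk_width, h]`), so bulk density is 1 by construction.
#'
#' @param z pooled solute z coordinates (nm), bilayer-centred.
#' @param bin_width histogram bin width, nm (default 0.1 nm).
#' @param h half-window, nm; bins cover \[-h, h\].
#' @param bulk_width width of the bulk-reference zone at each edge, nm.
#' @param symmetrize average the two leaflets by pooling `z` with `-z`
#'   (default FALSE: leaflet asymmetry is data, not noise).
#' @return A `density_profile` data frame with columns `z_nm` (bin
#'   centres), `counts`, `rho`.
#' @export
density_profile <- function(z, bin_width = 0.1, h, bulk_width = 0.5,
                            symmetrize = FALSE) {
  stopifnot(bin_width > 0, h > 0, bulk_width > 0, bulk_width < h)
  if (length(z) == 0) stop("empty sample set")
  if (symmetrize) z <- c(z, -z)
  if (any(abs(z) > h + 1e-9))
    stop("samples outside [-h, h]; wrap or recentre first")
  n_bins <- max(1L, round(2 * h / bin_width))
  breaks <- seq(-h, h, length.out = n_bins + 1L)
  counts <- tabulate(
    findInterval(z, breaks, rightmost.closed = TRUE, all.inside = TRUE),
    nbins = n_bins
  )
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  bulk <- abs(mids) >= h - bulk_width
  if (!any(counts[bulk] > 0))
    stop("bulk region empty: cannot normalize density to the water plateau")
  bulk_mean <- mean(counts[bulk])
  if (bulk_mean == 0) stop("bulk region empty: cannot normalize")
  df <- data.frame(z_nm = mids, counts = counts, rho = counts / bulk_mean)
  # the realized width (2h divided into an integer bin count), not the
  # request: downstream quadrature must use the actual grid
  attr(df, "bin_width") <- breaks[2] - breaks[1]
  attr(df, "h") <- h
  attr(df, "bulk_width") <- bulk_width
  class(df) <- c("density_profile", "data.frame")
  df
}

#' Free-energy profile from a density profile
#'
#' Boltzmann inversion `G(z) = -kB*T*ln(rho(z))`.  Bins with zero counts
#' are censored (`G = NA`, `censored = TRUE`).  Because rho is normalized
#' to the bulk plateau, G is referenced to bulk water (G_bulk = 0).
#'
#' @param rho a [density_profile].
#' @param temperature kelvin.
#' @return A `free_energy_profile` data frame with columns `z_nm`,
#'   `G_kcal_mol`, `counts`, `censored` (and `stderr` once block errors are
#'   attached).
#' @export
free_energy_profile <- function(rho, temperature) {
  if (temperature <= 0) stop("temperature must be positive")
  G <- ifelse(rho$counts > 0, -.kB * temperature * log(rho$rho), NA_real_)
  df <- data.frame(z_nm = rho$z_nm, G_kcal_mol = G, counts = rho$counts,
                   censored = rho$counts == 0, stderr = NA_real_)
  attr(df, "temperature") <- temperature
  attr(df, "bin_width") <- attr(rho, "bin_width")
  attr(df, "h") <- attr(rho, "h")
  attr(df, "bulk_width") <- attr(rho, "bulk_width")
  class(df) <- c("free_energy_profile", "data.frame")
  df
}

#' Block-averaged per-bin standard errors
#'
#' Splits the samples into contiguous temporal blocks (default 100 ns),
#' recomputes the free-energy profile per block, and reports the standard
#' error across blocks per bin.  Bins in which any block has zero counts
#' are censored (stderr `NA`).
#'
#' @param z pooled solute z coordinates (nm).
#' @param time_ps sample times (ps), same length as `z` (one value per
#'   frame per molecule; frames of different molecules share times).
#' @param temperature kelvin.
#' @param block_ns temporal block length, ns (default 100 ns).
#' @param bin_width,h,bulk_width as for [density_profile()].
#' @return Numeric vector of per-bin standard errors (kcal/mol), with
#'   attribute `n_blocks`.
#' @export
block_errors <- function(z, time_ps, temperature, block_ns = 100,
                         bin_width = 0.1, h, bulk_width = 0.5) {
  stopifnot(length(z) == length(time_ps), block_ns > 0)
  t0 <- min(time_ps)
  span_ns <- (max(time_ps) - t0) / 1e3
  # a trailing block missing < 1% of its length counts as complete (sample
  # times end one frame short of the nominal span)
  n_blocks <- floor(span_ns / block_ns + 0.01)
  if (n_blocks < 2)
    stop(sprintf("need >= 2 complete blocks of %g ns (have %.1f ns)",
                 block_ns, span_ns))
  idx <- floor((time_ps - t0) / (block_ns * 1e3) + 1e-12)
  keep <- idx < n_blocks  # drop the trailing partial block
  idx <- idx[keep]; zk <- z[keep]
  Gb <- sapply(seq_len(n_blocks) - 1L, function(b) {
    zb <- zk[idx == b]
    if (length(zb) == 0) stop("block with no samples")
    rho <- density_profile(zb, bin_width = bin_width, h = h,
                           bulk_width = bulk_width)
    free_energy_profile(rho, temperature)$G_kcal_mol
  })
  se <- apply(Gb, 1, function(g) {
    if (anyNA(g)) NA_real_ else stats::sd(g) / sqrt(length(g))
  })
  attr(se, "n_blocks") <- n_blocks
  se
}

#' Full free-energy profile with block errors
#'
#' Convenience wrapper: histogram, Boltzmann inversion and block-averaged
#' errors in one call.
#'
#' @inheritParams block_errors
#' @return A [free_energy_profile] with the `stderr` column filled in.
#' @export
compute_free_energy <- function(z, time_ps, temperature, h, bin_width = 0.1,
                                block_ns = 100, bulk_width = 0.5) {
  rho <- density_profile(z, bin_width = bin_width, h = h,
                         bulk_width = bulk_width)
  prof <- free_energy_profile(rho, temperature)
  prof$stderr <- block_errors(z, time_ps, temperature, block_ns = block_ns,
                              bin_width = bin_width, h = h,
                              bulk_width = bulk_width)
  prof
}

# interior local maxima/minima indices of a numeric vector (NA-tolerant:
# censored bins break the profile into runs scanned separately)
.local_extrema <- function(y, what = c("max", "min")) {
  what <- match.arg(what)
  n <- length(y)
  if (n < 3) return(integer(0))
  out <- integer(0)
  for (i in 2:(n - 1)) {
    if (is.na(y[i - 1]) || is.na(y[i]) || is.na(y[i + 1])) next
    if (what == "max" && y[i] >= y[i - 1] && y[i] >= y[i + 1] &&
        (y[i] > y[i - 1] || y[i] > y[i + 1])) out <- c(out, i)
    if (what == "min" && y[i] <= y[i - 1] && y[i] <= y[i + 1] &&
        (y[i] < y[i - 1] || y[i] < y[i + 1])) out <- c(out, i)
  }
  out
}

#' Barrier height, flanking minima and barrier width
#'
#' Locates the barrier apex `G_B` as the maximum of the profile within the
#' membrane region `|z| <= z_mem`, finds the lowest minimum on each side of
#' the apex (searching out to the profile edges), and reports the barrier
#' height `dG = G_B - (G_A + G_C)/2` together with the Aniansson barrier
#' width from [barrier_width()].  Ties at the apex are broken towards
#' z = 0 for determinism.
#'
#' @param profile a [free_energy_profile].
#' @param z_mem half-width of the membrane region used for the apex search,
#'   nm (a natural choice is half the phosphate-phosphate distance).
#' @param h half-window for the width integral, nm; defaults to the profile
#'   extent.
#' @return A `barrier_summary` list: `z_B`, `G_B`, `z_A`, `G_A`, `z_C`,
#'   `G_C`, `delta_G_kcal_mol`, `delta_G_stderr`, `lb_nm`, `temperature`.
#' @export
barrier_summary <- function(profile, z_mem, h = NULL) {
  temperature <- attr(profile, "temperature")
  if (is.null(h)) h <- attr(profile, "h")
  zv <- profile$z_nm
  G <- profile$G_kcal_mol
  mem <- abs(zv) <= z_mem
  if (!any(mem)) stop("membrane region contains no bins")
  if (anyNA(G[mem]))
    stop("undersampled barrier: censored bins in the membrane region; ",
         "sample longer or simulate at higher temperature")
  # apex: maximum in the membrane region, must be an interior maximum
  Gmem <- G[mem]; zmemv <- zv[mem]
  gmax <- max(Gmem)
  cand <- which(Gmem >= gmax - 1e-12)
  iB_rel <- cand[which.min(abs(zmemv[cand]))]  # tie-break: nearest z = 0
  iB <- which(mem)[iB_rel]
  if (iB <= 1 || iB >= length(zv))
    stop("no interior maximum: barrier apex at profile edge")
  # profile must actually decrease somewhere on both sides
  left_ok <- any(!is.na(G[1:(iB - 1)]) & G[1:(iB - 1)] < G[iB])
  right_ok <- any(!is.na(G[(iB + 1):length(G)]) & G[(iB + 1):length(G)] < G[iB])
  if (!left_ok || !right_ok)
    stop("no interior maximum: profile is monotone on one side of the apex")
  lowest_min <- function(idx) {
    ie <- .local_extrema(G[idx], "min")
    vals <- G[idx]
    if (length(ie) == 0) {
      # no interior minimum: use the lowest uncensored bin on that side
      j <- which.min(vals)
    } else {
      j <- ie[which.min(vals[ie])]
    }
    idx[j]
  }
  iA <- lowest_min(1:(iB - 1))
  iC <- lowest_min((iB + 1):length(zv))
  dG <- G[iB] - (G[iA] + G[iC]) / 2
  se <- profile$stderr
  dG_se <- if (!is.null(se) && !anyNA(se[c(iA, iB, iC)]))
    sqrt(se[iB]^2 + se[iA]^2 / 4 + se[iC]^2 / 4) else NA_real_
  # reference the width integrand to the apex value: equals the barrier
  # height when the flanking minima define the zero, and is invariant
  # under shifting the profile's reference
  lb <- barrier_width(profile, temperature = temperature, h = h,
                      delta_G = G[iB])
  structure(
    list(z_B = zv[iB], G_B = G[iB], z_A = zv[iA], G_A = G[iA],
         z_C = zv[iC], G_C = G[iC], delta_G_kcal_mol = dG,
         delta_G_stderr = dG_se, lb_nm = lb, temperature = temperature),
    class = "barrier_summary"
  )
}

#' @export
print.barrier_summary <- function(x, ...) {
  cat(sprintf("barrier_summary at %g K: dG = %.3f +/- %.3f kcal/mol, lb = %.3f nm\n",
              x$temperature, x$delta_G_kcal_mol,
              ifelse(is.na(x$delta_G_stderr), NaN, x$delta_G_stderr),
              x$lb_nm))
  cat(sprintf("  apex (%.2f, %.3f); minima (%.2f, %.3f) / (%.2f, %.3f)\n",
              x$z_B, x$G_B, x$z_A, x$G_A, x$z_C, x$G_C))
  invisible(x)
}

#' Aniansson barrier width
#'
#' Boltzmann-weighted effective width of the barrier,
#' `lb = integral over [-h, h] of exp((G(z) - dG)/kB*T) dz`, evaluated by
#' the midpoint rule over the profile bins (each bin contributes its width
#' times the Boltzmann weight at its centre, which integrates a flat
#' profile exactly).  Censored bins contribute
#' zero weight; censoring at the apex (within kB*T of the barrier top) is
#' an error because there the weight would be of order one.
#'
#' @param profile a [free_energy_profile] (or data frame with `z_nm`,
#'   `G_kcal_mol`).
#' @param temperature kelvin; defaults to the profile's temperature.
#' @param h integration half-window, nm.
#' @param delta_G reference level of the weight (kcal/mol): the apex free
#'   energy, which equals the barrier height when the flanking minima sit
#'   at the profile's zero.  Defaults to the maximum of the uncensored
#'   profile; referencing the apex value keeps the width invariant under
#'   shifting the profile's zero.
#' @return Barrier width lb in nm.
#' @export
barrier_width <- function(profile, temperature = attr(profile, "temperature"),
                          h = attr(profile, "h"), delta_G = NULL) {
  zv <- profile$z_nm
  G <- profile$G_kcal_mol
  bw0 <- attr(profile, "bin_width")
  if (is.null(bw0)) bw0 <- stats::median(diff(sort(zv)))
  if (is.null(h)) h <- max(abs(zv)) + bw0 / 2
  if (h > max(abs(zv)) + bw0 / 2 + 1e-6)
    stop("integration window h exceeds the profile extent")
  keep <- abs(zv) <= h + 1e-9
  zv <- zv[keep]; G <- G[keep]
  if (is.null(delta_G)) delta_G <- max(G, na.rm = TRUE)
  kT <- .kB * temperature
  cens <- is.na(G)
  if (any(cens & !is.na(delta_G))) {
    # a censored bin near the barrier top cannot be treated as weight zero
    near_apex <- cens  # G unknown; flag if neighbours are within kT of top
    Gn <- G
    for (i in which(cens)) {
      nb <- c(if (i > 1) Gn[i - 1], if (i < length(Gn)) Gn[i + 1])
      nb <- nb[!is.na(nb)]
      if (length(nb) && any(nb > delta_G - temperature * .kB))
        stop("undersampled barrier: censored bin adjacent to the apex")
    }
  }
  w <- ifelse(cens, 0, exp((G - delta_G) / kT))
  bw <- attr(profile, "bin_width")
  if (is.null(bw)) bw <- stats::median(diff(sort(zv)))
  sum(w) * bw
}

#' Linear temperature dependence of the barrier height
#'
#' Ordinary least squares of `dG(T) = G0 - g*T`: the barrier height falls
#' linearly with temperature, with compound-dependent constants `G0`
#' (intercept) and `g` (minus the slope).
#'
#' @param temperature temperatures, kelvin (>= 2 distinct values).
#' @param delta_G barrier heights, kcal/mol.
#' @param stderr optional per-point standard errors (weights 1/se^2).
#' @return A `barrier_temp_fit` list: `G0`, `g`, `G0_stderr`, `g_stderr`,
#'   `residuals`, `temperatures`, `fit` (the underlying `lm`).
#' @export
fit_barrier_vs_T <- function(temperature, delta_G, stderr = NULL) {
  stopifnot(length(temperature) == length(delta_G))
  if (length(unique(temperature)) < 2)
    stop("need >= 2 distinct temperatures")
  w <- if (!is.null(stderr)) 1 / stderr^2 else NULL
  fit <- stats::lm(delta_G ~ temperature, weights = w)
  cf <- summary(fit)$coefficients
  structure(
    list(G0 = unname(cf[1, 1]), g = -unname(cf[2, 1]),
         G0_stderr = unname(cf[1, 2]), g_stderr = unname(cf[2, 2]),
         residuals = unname(stats::residuals(fit)),
         temperatures = temperature, fit = fit),
    class = "barrier_temp_fit"
  )
}

#' @export
print.barrier_temp_fit <- function(x, ...) {
  cat(sprintf("barrier_temp_fit: dG(T) = G0 - g*T, G0 = %.4f +/- %.4f kcal/mol, g = %.3g +/- %.2g kcal/mol/K (%d temperatures)\n",
              x$G0, x$G0_stderr, x$g, x$g_stderr, length(x$temperatures)))
  invisible(x)
}

#' Power-law temperature dependence of the barrier width
#'
#' Fits `ln(lb) = ln(a) + ml * ln(T)`.  The slope `ml` is close to 2 for
#' trans-bilayer barriers (the width grows quadratically with
#' temperature); `constrain_slope = 2` fixes it and fits `a` alone.
#'
#' @param temperature temperatures, kelvin.
#' @param lb barrier widths, nm.
#' @param constrain_slope optional fixed value for `ml` (e.g. 2).
#' @return A `width_temp_fit` list: `a`, `ml`, `a_stderr` (stderr of
#'   ln(a)), `ml_stderr`, `constrained`, `residuals`.
#' @export
fit_width_vs_T <- function(temperature, lb, constrain_slope = NULL) {
  stopifnot(length(temperature) == length(lb))
  if (any(temperature <= 0) || any(lb <= 0))
    stop("temperatures and widths must be positive")
  x <- log(temperature); y <- log(lb)
  if (!is.null(constrain_slope)) {
    if (length(y) < 1) stop("need >= 1 point for a constrained fit")
    ln_a <- mean(y - constrain_slope * x)
    se <- if (length(y) > 1) stats::sd(y - constrain_slope * x) / sqrt(length(y)) else NA_real_
    return(structure(
      list(a = exp(ln_a), ml = constrain_slope, a_stderr = se,
           ml_stderr = NA_real_, constrained = TRUE,
           residuals = y - constrain_slope * x - ln_a),
      class = "width_temp_fit"
    ))
  }
  if (length(unique(temperature)) < 2)
    stop("need >= 2 distinct temperatures (or constrain the slope)")
  fit <- stats::lm(y ~ x)
  cf <- summary(fit)$coefficients
  structure(
    list(a = exp(unname(cf[1, 1])), ml = unname(cf[2, 1]),
         a_stderr = unname(cf[1, 2]), ml_stderr = unname(cf[2, 2]),
         constrained = FALSE, residuals = unname(stats::residuals(fit))),
    class = "width_temp_fit"
  )
}

#' @export
print.width_temp_fit <- function(x, ...) {
  cat(sprintf("width_temp_fit: lb(T) = a*T^ml, a = %.4g nm/K^ml, ml = %.3f%s\n",
              x$a, x$ml, if (x$constrained) " (constrained)" else
                sprintf(" +/- %.3f", x$ml_stderr)))
  invisible(x)
}

#' Write a free-energy profile as TSV
#'
#' Columns: z_nm, G_kcal_mol, stderr, counts, censored.
#'
#' @param profile a [free_energy_profile].
#' @param path output path.
#' @export
write_profile <- function(profile, path) {
  utils::write.table(
    as.data.frame(profile)[, c("z_nm", "G_kcal_mol", "stderr", "counts",
                               "censored")],
    path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
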