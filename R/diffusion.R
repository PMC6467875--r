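# Mean-squared-displacement estimators.
#
# Lateral lipid diffusion DL(T) comes from the pooled 2D MSD of phosphate
# positions after removing per-frame centre-of-mass drift; solute normal
# diffusion DZ(T) comes from short-lag 1D MSD restricted to trajectory
# segments near the barrier apex.  D = slope / (2 * dimensionality).

#' Mean squared displacement with overlapping origins
#'
#' `msd(tau) = <|x(t + tau) - x(t)|^2>` averaged over time origins spaced
#' `origin_stride` frames apart.
#'
#' @param x numeric vector (1D) or frames-by-dims matrix of unwrapped
#'   coordinates (nm).
#' @param max_lag_frames largest lag, frames; defaults to a third of the
#'   series length.
#' @param origin_stride spacing between time origins, frames.
#' @param sampling_interval frame spacing, ps.
#' @param L optional box length(s); if supplied, single-frame jumps larger
#'   than L/2 raise an error (wrapped input).
#' @return An `msd_curve` data frame with columns `lag_ns`, `msd_nm2`,
#'   `n_origins`; attributes `dimensionality` and `sampling_interval`.
#' @export
msd <- function(x, max_lag_frames = NULL, origin_stride = 1L,
                sampling_interval = 1, L = NULL) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 2) stop("need at least 2 frames for an MSD")
  if (!is.null(L)) {
    jumps <- abs(diff(x))
    if (any(t(jumps) > rep_len(L, ncol(x)) / 2))
      stop("wrapped input detected (jump > L/2): unwrap coordinates first")
  }
  if (is.null(max_lag_frames)) max_lag_frames <- max(1L, floor((n - 1) / 3))
  max_lag_frames <- min(max_lag_frames, n - 1L)
  lags <- seq_len(max_lag_frames)
  ms <- numeric(length(lags))
  norig <- integer(length(lags))
  origins_all <- seq(1L, n, by = origin_stride)
  for (i in seq_along(lags)) {
    tau <- lags[i]
    origins <- origins_all[origins_all + tau <= n]
    d <- x[origins + tau, , drop = FALSE] - x[origins, , drop = FALSE]
    ms[i] <- mean(rowSums(d * d))
    norig[i] <- length(origins)
  }
  df <- data.frame(lag_ns = c(0, lags * sampling_interval / 1e3),
                   msd_nm2 = c(0, ms), n_origins = c(n, norig))
  attr(df, "dimensionality") <- ncol(x)
  attr(df, "sampling_interval") <- sampling_interval
  class(df) <- c("msd_curve", "data.frame")
  df
}

# average several msd_curves on a common lag axis, weighting by origins
.pool_msd <- function(curves) {
  lag <- curves[[1]]$lag_ns
  for (cu in curves) stopifnot(isTRUE(all.equal(cu$lag_ns, lag)))
  w <- sapply(curves, function(cu) cu$n_origins)
  m <- sapply(curves, function(cu) cu$msd_nm2)
  tot <- rowSums(w)
  df <- data.frame(lag_ns = lag, msd_nm2 = rowSums(m * w) / pmax(tot, 1),
                   n_origins = tot)
  attr(df, "dimensionality") <- attr(curves[[1]], "dimensionality")
  attr(df, "sampling_interval") <- attr(curves[[1]], "sampling_interval")
  class(df) <- c("msd_curve", "data.frame")
  df
}

#' Diffusion coefficient from an MSD curve
#'
#' Least-squares slope of the MSD over a lag window in the diffusive
#' (linear) regime; `D = slope / (2 * dimensionality)`.
#'
#' @param curve an [msd()] curve.
#' @param window numeric length-2 vector of lag bounds in ns; defaults to
#'   10--50% of the largest available lag.
#' @param dimensionality 1, 2 or 3; defaults to the curve's.
#' @return A `diffusion_estimate` list: `D_nm2_ns` (also `D_cm2_s`),
#'   `stderr`, `r_squared`, `fit_window_ns`, `dimensionality`.  A
#'   warning is raised when r^2 < 0.9 (non-diffusive regime).
#' @export
fit_diffusion <- function(curve, window = NULL,
                          dimensionality = attr(curve, "dimensionality")) {
  if (is.null(dimensionality)) stop("dimensionality unknown")
  maxlag <- max(curve$lag_ns)
  if (is.null(window)) window <- c(0.1, 0.5) * maxlag
  sel <- curve$lag_ns >= window[1] & curve$lag_ns <= window[2] &
    curve$lag_ns > 0
  if (sum(sel) < 2)
    stop("fit window contains fewer than 2 lag points")
  if (sum(sel) < 5)
    warning("fewer than 5 lag points in the fit window")
  fit <- stats::lm(msd_nm2 ~ lag_ns, data = curve[sel, ])
  sm <- summary(fit)
  slope <- unname(stats::coef(fit)[2])
  if (slope <= 0) stop("non-positive MSD slope: not diffusive in this window")
  r2 <- sm$r.squared
  if (!is.nan(r2) && r2 < 0.9)
    warning(sprintf("r^2 = %.3f < 0.9 in the MSD fit window: non-diffusive regime", r2))
  D <- slope / (2 * dimensionality)
  structure(
    list(D_nm2_ns = D, D_cm2_s = D * 1e-5,
         stderr = unname(sm$coefficients[2, 2]) / (2 * dimensionality),
         r_squared = r2, fit_window_ns = window,
         dimensionality = dimensionality),
    class = "diffusion_estimate"
  )
}

#' @export
print.diffusion_estimate <- function(x, ...) {
  cat(sprintf("diffusion_estimate (%dD): D = %.4g +/- %.2g nm^2/ns (%.3g cm^2/s), r^2 = %.3f\n",
              x$dimensionality, x$D_nm2_ns, x$stderr, x$D_cm2_s,
              x$r_squared))
  invisible(x)
}

#' Lateral lipid diffusion coefficient
#'
#' Pools the lateral MSD of all phosphate traces (all species together)
#' after removing per-frame centre-of-mass drift, and fits the 2D
#' diffusive slope.
#'
#' @param lipid_traces list of [lipid_trace] objects with unwrapped xy.
#' @param max_lag_frames,origin_stride,window passed to [msd()] /
#'   [fit_diffusion()].
#' @param remove_drift subtract the per-frame mean displacement of all
#'   lipids (default TRUE).
#' @return A `diffusion_estimate` for DL, with the pooled `msd_curve`
#'   attached as attribute `curve`.
#' @export
lateral_lipid_diffusion <- function(lipid_traces, max_lag_frames = NULL,
                                    origin_stride = 1L, window = NULL,
                                    remove_drift = TRUE) {
  if (length(lipid_traces) < 2)
    stop("need at least 2 lipids for a pooled lateral diffusion estimate")
  dt <- lipid_traces[[1]]$sampling_interval
  xs <- lapply(lipid_traces, function(tr) tr$xy)
  n <- nrow(xs[[1]])
  if (remove_drift) {
    comx <- Reduce(`+`, lapply(xs, function(m) m[, 1])) / length(xs)
    comy <- Reduce(`+`, lapply(xs, function(m) m[, 2])) / length(xs)
    xs <- lapply(xs, function(m) cbind(m[, 1] - comx, m[, 2] - comy))
  } else {
    # crude drift diagnostic: net COM displacement vs diffusive expectation
    comx <- Reduce(`+`, lapply(xs, function(m) m[, 1])) / length(xs)
    comy <- Reduce(`+`, lapply(xs, function(m) m[, 2])) / length(xs)
    net2 <- (comx[n] - comx[1])^2 + (comy[n] - comy[1])^2
    per2 <- mean(sapply(xs, function(m)
      (m[n, 1] - m[1, 1])^2 + (m[n, 2] - m[1, 2])^2))
    if (net2 > per2)
      warning("unremoved collective drift detected: COM displacement exceeds the diffusive expectation")
  }
  curves <- lapply(xs, msd, max_lag_frames = max_lag_frames,
                   origin_stride = origin_stride, sampling_interval = dt)
  pooled <- .pool_msd(curves)
  if (remove_drift) {
    # subtracting the mean of N independent walks shrinks increment
    # variance by (N-1)/N; undo that known factor
    N <- length(xs)
    pooled$msd_nm2 <- pooled$msd_nm2 * N / (N - 1)
  }
  est <- fit_diffusion(pooled, window = window, dimensionality = 2)
  attr(est, "curve") <- pooled
  est
}

#' Solute normal diffusion near the barrier apex (slab-restricted MSD)
#'
#' Collects trajectory segments that stay within
#' `|z - z_apex| < slab_halfwidth` for at least `min_frames` frames,
#' computes their 1D MSD at short lags, pools, and fits the diffusive
#' slope.  Short lags keep the estimate close to the local free diffusion
#' coefficient before the confining potential curvature bends the MSD.
#'
#' @param trace a [solute_trace] (bilayer-centred), or numeric z vector.
#' @param z_apex apex position, nm.
#' @param slab_halfwidth slab half-width, nm.
#' @param max_lag_ps largest lag used, ps (default 20 ps).
#' @param min_frames minimum segment length, frames (default 10).
#' @param window fit window in ns; defaults to the first half of the lags.
#' @return A `diffusion_estimate` for DZ with attributes `curve` and
#'   `n_segments`.
#' @export
slab_normal_diffusion <- function(trace, z_apex, slab_halfwidth,
                                  max_lag_ps = 20, min_frames = 10L,
                                  window = NULL) {
  if (inherits(trace, "solute_trace")) {
    z <- trace$z; dt <- trace$sampling_interval
  } else {
    z <- as.numeric(trace); dt <- 1
  }
  inside <- abs(z - z_apex) < slab_halfwidth
  r <- rle(inside)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  segs <- which(r$values & r$lengths >= min_frames)
  if (length(segs) == 0)
    stop("insufficient slab occupancy near the apex: sample longer, raise the temperature, or supply DZ directly")
  max_lag_frames <- max(1L, floor(max_lag_ps / dt))
  curves <- list()
  for (s in segs) {
    zz <- z[starts[s]:ends[s]]
    ml <- min(max_lag_frames, length(zz) - 1L)
    cu <- msd(zz, max_lag_frames = ml, sampling_interval = dt)
    # pad onto the common axis by truncation handled in pooling: keep only
    # curves with the full lag range to keep the axis common
    if (ml == max_lag_frames) curves[[length(curves) + 1L]] <- cu
  }
  if (length(curves) == 0)
    stop("no slab segment long enough for the requested lag range")
  pooled <- .pool_msd(curves)
  if (is.null(window)) window <- c(0, max_lag_ps / 2e3)
  est <- fit_diffusion(pooled, window = window, dimensionality = 1)
  attr(est, "curve") <- pooled
  attr(est, "n_segments") <- length(curves)
  est
}

#' Scaling of solute normal diffusion with lipid lateral diffusion
#'
#' Fits `ln(DZ) = ln(b) + mD * ln(DL)` across temperatures.  For small
#' solutes the slope mD is 1: the solute diffusion coefficient at the
#' barrier apex is proportional to the lateral lipid diffusion
#' coefficient, with a compound-dependent constant b.
#'
#' @param DZ solute normal diffusion coefficients, nm^2/ns.
#' @param DL lateral lipid diffusion coefficients, nm^2/ns.
#' @param constrain_slope optional fixed mD (e.g. 1).
#' @return A `dz_dl_fit` list: `b`, `mD`, `b_stderr` (stderr of ln b),
#'   `mD_stderr`, `constrained`, `residuals`.
#' @export
fit_dz_vs_dl <- function(DZ, DL, constrain_slope = NULL) {
  stopifnot(length(DZ) == length(DL))
  if (any(DZ <= 0) || any(DL <= 0)) stop("diffusion coefficients must be positive")
  x <- log(DL); y <- log(DZ)
  if (!is.null(constrain_slope)) {
    ln_b <- mean(y - constrain_slope * x)
    se <- if (length(y) > 1) stats::sd(y - constrain_slope * x) / sqrt(length(y)) else NA_real_
    return(structure(
      list(b = exp(ln_b), mD = constrain_slope, b_stderr = se,
           mD_stderr = NA_real_, constrained = TRUE,
           residuals = y - constrain_slope * x - ln_b),
      class = "dz_dl_fit"))
  }
  if (length(unique(x)) < 2) stop("need >= 2 distinct DL values")
  fit <- stats::lm(y ~ x)
  cf <- summary(fit)$coefficients
  structure(
    list(b = exp(unname(cf[1, 1])), mD = unname(cf[2, 1]),
         b_stderr = unname(cf[1, 2]), mD_stderr = unname(cf[2, 2]),
         constrained = FALSE, residuals = unname(stats::residuals(fit))),
    class = "dz_dl_fit")
}

#' @export
print.dz_dl_fit <- function(x, ...) {
  cat(sprintf("dz_dl_fit: DZ = b*DL^mD, b = %.4g, mD = %.3f%s\n",
              x$b, x$mD, if (x$constrained) " (constrained)" else
                sprintf(" +/- %.3f", x$mD_stderr)))
  invisible(x)
}

#' Write an MSD curve as TSV
#'
#' @param curve an `msd_curve`.
#' @param path output path.
#' @export
write_msd <- function(curve, path) {
  utils::write.table(as.data.frame(curve)[, c("lag_ns", "msd_nm2", "n_origins")],
                     path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
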