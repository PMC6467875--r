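# Corrected Arrhenius extrapolation of crossing kinetics.
#
# Combining Kramers' attempt frequency A = c*DZ/lb^2 with the empirical
# scaling laws DZ = b*DL (solute tracks lipid diffusion) and lb = a*T^2
# (barrier width grows quadratically) gives
#     k(T) = c'' * DL(T)/T^4 * exp(-G0/(kB*T)),   c'' = b/a^2 * const,
# where the linear part of dG(T) = G0 - g*T contributes the constant
# exp(g/kB), absorbed into c''.  The fit is linear: y = ln(P*T^4/DL)
# against x = 1/T, slope -G0/kB.

#' Fit the corrected Arrhenius law to high-temperature kinetics
#'
#' Linear regression of `y = ln(P * T^4 / DL)` on `x = 1/T`; the slope
#' gives `G0 = -slope * kB` and the intercept the log-prefactor `ln_c`.
#' Points are weighted by `1/stderr(ln P)^2` when standard errors are
#' supplied.  Permeability P (cm/s) is the default quantity; a
#' per-molecule rate constant k (s^-1) can be fitted instead --- the two
#' give the same G0 because area and concentration are
#' temperature-constant in a fixed system.
#'
#' @param temperature temperatures, kelvin (>= 3 distinct values spanning
#'   at least 20 K; the validated regime is T >= 440 K).
#' @param P permeabilities (cm/s) or rate constants (s^-1), see `quantity`.
#' @param DL lateral lipid diffusion coefficients at the same
#'   temperatures, nm^2/ns.
#' @param stderr optional standard errors of `P` (same units as P).
#' @param quantity `"P"` or `"k"`; tag recorded with the model.
#' @return An `extrapolation_model` list: `G0` (kcal/mol), `ln_c`,
#'   `G0_stderr`, covariance matrix `cov` of `(ln_c, G0)`, `points`
#'   (the fit inputs), `sigma2` (residual variance), `quantity`.
#' @export
fit_corrected_arrhenius <- function(temperature, P, DL, stderr = NULL,
                                    quantity = c("P", "k")) {
  quantity <- match.arg(quantity)
  stopifnot(length(temperature) == length(P), length(P) == length(DL))
  if (any(temperature <= 0) || any(P <= 0) || any(DL <= 0))
    stop("temperature, P and DL must be positive")
  if (length(unique(temperature)) < 3)
    stop("need >= 3 distinct temperatures")
  if (diff(range(temperature)) < 20)
    stop("fit temperatures span < 20 K: ill-conditioned extrapolation")
  y <- log(P * temperature^4 / DL)
  x <- 1 / temperature
  w <- if (!is.null(stderr)) (P / stderr)^2 else NULL  # var(ln P) = (se/P)^2
  fit <- stats::lm(y ~ x, weights = w)
  cf <- summary(fit)$coefficients
  V <- stats::vcov(fit)
  G0 <- -unname(cf[2, 1]) * .kB
  # covariance of (ln_c, G0): G0 = -kB * slope
  cov <- matrix(c(V[1, 1], -.kB * V[1, 2], -.kB * V[2, 1], .kB^2 * V[2, 2]),
                2, 2, dimnames = list(c("ln_c", "G0"), c("ln_c", "G0")))
  structure(
    list(G0 = G0, ln_c = unname(cf[1, 1]),
         G0_stderr = .kB * unname(cf[2, 2]),
         ln_c_stderr = unname(cf[1, 2]),
         cov = cov, sigma2 = summary(fit)$sigma^2,
         points = data.frame(temperature = temperature, P = P, DL = DL,
                             stderr = if (is.null(stderr)) NA_real_ else stderr),
         quantity = quantity, fit = fit),
    class = "extrapolation_model"
  )
}

#' @export
print.extrapolation_model <- function(x, ...) {
  cat(sprintf("extrapolation_model (%s): G0 = %.4f +/- %.4f kcal/mol, ln_c = %.4f (fit on %d temperatures %g-%g K)\n",
              x$quantity, x$G0, x$G0_stderr, x$ln_c,
              nrow(x$points), min(x$points$temperature),
              max(x$points$temperature)))
  invisible(x)
}

#' Predict permeability at a target temperature
#'
#' `P(T) = exp(ln_c) * DL(T) / T^4 * exp(-G0 / (kB*T))` with a first-order
#' (delta-method) standard error from the fit covariance.  The interval
#' widens as the target temperature moves below the fitted range.
#'
#' @param model an [fit_corrected_arrhenius()] model.
#' @param T_target target temperature, kelvin (e.g. 310).
#' @param DL_target lateral lipid diffusion coefficient at the target
#'   temperature, nm^2/ns (measured directly; lipid diffusion is samplable
#'   at low temperature without rare events).
#' @return A `prediction_result` list: `T_target`, `DL_target`, `P`
#'   (same units as the fitted quantity), `ln_P_stderr`, `P_lower`,
#'   `P_upper` (one-stderr interval), `model`.
#' @export
predict_permeability <- function(model, T_target, DL_target) {
  if (!inherits(model, "extrapolation_model")) stop("model unfit")
  if (T_target <= 0) stop("T_target must be positive (kelvin)")
  if (DL_target <= 0) stop("DL_target must be positive")
  lnP <- model$ln_c + log(DL_target) - 4 * log(T_target) -
    model$G0 / (.kB * T_target)
  # d lnP / d(ln_c) = 1; d lnP / d G0 = -1/(kB T)
  gr <- c(1, -1 / (.kB * T_target))
  se <- sqrt(drop(t(gr) %*% model$cov %*% gr))
  structure(
    list(T_target = T_target, DL_target = DL_target,
         P = exp(lnP), ln_P_stderr = se,
         P_lower = exp(lnP - se), P_upper = exp(lnP + se),
         model = model),
    class = "prediction_result"
  )
}

#' @export
print.prediction_result <- function(x, ...) {
  cat(sprintf("prediction_result: P(%g K) = %.4g [%.4g, %.4g] (one-stderr interval)\n",
              x$T_target, x$P, x$P_lower, x$P_upper))
  invisible(x)
}

#' Naive Arrhenius fit
#'
#' Regression of `ln P` on `1/T` with no lipid-diffusion or barrier-width
#' correction.  Used as the deviation diagnostic: when the attempt
#' frequency varies with temperature, the naive fit shows curvature in its
#' residuals and extrapolates poorly below the fitted range.
#'
#' @param temperature temperatures, kelvin (>= 2 distinct values).
#' @param P permeabilities or rate constants (positive).
#' @param stderr optional standard errors of `P`.
#' @return A `naive_arrhenius_fit` list: `slope`, `intercept`, stderrs,
#'   `residuals`, and `predict(T)` convenience closure.
#' @export
fit_naive_arrhenius <- function(temperature, P, stderr = NULL) {
  stopifnot(length(temperature) == length(P))
  if (any(P <= 0) || any(temperature <= 0)) stop("inputs must be positive")
  if (length(unique(temperature)) < 2) stop("need >= 2 distinct temperatures")
  x <- 1 / temperature; y <- log(P)
  w <- if (!is.null(stderr)) (P / stderr)^2 else NULL
  fit <- stats::lm(y ~ x, weights = w)
  cf <- summary(fit)$coefficients
  slope <- unname(cf[2, 1]); intercept <- unname(cf[1, 1])
  structure(
    list(slope = slope, intercept = intercept,
         slope_stderr = unname(cf[2, 2]),
         intercept_stderr = unname(cf[1, 2]),
         residuals = unname(stats::residuals(fit)),
         predict = function(T_target) exp(intercept + slope / T_target),
         fit = fit),
    class = "naive_arrhenius_fit"
  )
}

#' Attempt frequency implied by the model
#'
#' `A(T) = exp(ln_c) * DL / T^4` in the fitted quantity's units.  Additive
#' constants from the linear temperature dependence of the barrier height
#' (the `exp(g/kB)` factor) are absorbed in `ln_c`, so A is reported up to
#' that compound-dependent constant.
#'
#' @param model an `extrapolation_model`.
#' @param DL lateral lipid diffusion coefficient, nm^2/ns.
#' @param temperature kelvin.
#' @return Attempt frequency (model units).
#' @export
attempt_frequency <- function(model, DL, temperature) {
  if (!inherits(model, "extrapolation_model")) stop("model unfit")
  exp(model$ln_c) * DL / temperature^4
}

#' Cross-check kinetic vs thermodynamic G0
#'
#' The same constant G0 appears in the linear barrier law
#' `dG(T) = G0 - g*T` (thermodynamic route: profile barriers vs
#' temperature) and in the corrected Arrhenius law (kinetic route: rates
#' vs temperature) --- the `g*T` term cancels exactly into the kinetic
#' prefactor.  This reports the difference with its combined uncertainty.
#'
#' @param kinetic an `extrapolation_model`.
#' @param thermo a `barrier_temp_fit`.
#' @param compound_kinetic,compound_thermo optional compound labels; a
#'   warning is raised when they differ.
#' @return A `g0_cross_check` list: `G0_kinetic`, `G0_thermo`, `delta`,
#'   `combined_stderr`, `n_sigma`.
#' @export
cross_check_G0 <- function(kinetic, thermo, compound_kinetic = NULL,
                           compound_thermo = NULL) {
  if (!is.null(compound_kinetic) && !is.null(compound_thermo) &&
      !identical(compound_kinetic, compound_thermo))
    warning(sprintf("comparing different compounds: '%s' (kinetic) vs '%s' (thermodynamic)",
                    compound_kinetic, compound_thermo))
  delta <- kinetic$G0 - thermo$G0
  se <- sqrt(kinetic$G0_stderr^2 + thermo$G0_stderr^2)
  structure(
    list(G0_kinetic = kinetic$G0, G0_thermo = thermo$G0, delta = delta,
         combined_stderr = se, n_sigma = abs(delta) / se),
    class = "g0_cross_check"
  )
}

#' @export
print.g0_cross_check <- function(x, ...) {
  cat(sprintf("g0_cross_check: kinetic %.3f vs thermodynamic %.3f kcal/mol; delta = %.3f +/- %.3f (%.2f sigma)\n",
              x$G0_kinetic, x$G0_thermo, x$delta, x$combined_stderr,
              x$n_sigma))
  invisible(x)
}

#' Serialize an extrapolation model to JSON
#'
#' @param model an `extrapolation_model`.
#' @param path output path.
#' @export
write_model <- function(model, path) {
  obj <- list(
    G0_kcal_mol = model$G0, ln_c = model$ln_c,
    G0_stderr = model$G0_stderr, ln_c_stderr = model$ln_c_stderr,
    covariance = model$cov, quantity = model$quantity,
    points = model$points
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
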