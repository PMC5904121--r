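#' Convert optical density to cell dry weight
#'
#' @param od OD600 value(s), dimensionless.
#' @param factor correlation factor in gCDW L^-1 per OD600 unit
#'   (default 0.33).
#' @return Biomass concentration, gCDW L^-1.
#' @export
od_to_cdw <- function(od, factor = 0.33) {
  stopifnot(all(od >= 0), factor > 0)
  od * factor
}

#' Construct a culture time series
#'
#' @param times sampling times in hours, strictly increasing, length >= 2.
#' @param values concentrations (mM) or OD600 readings.
#' @param kind `"substrate"` or `"od"`.
#' @return An object of class `time_series`.
#' @export
time_series <- function(times, values, kind = c("substrate", "od")) {
  kind <- match.arg(kind)
  times <- as.numeric(times); values <- as.numeric(values)
  if (length(times) != length(values))
    stop("times and values must have equal length", call. = FALSE)
  if (length(times) < 2L) stop("need at least two points", call. = FALSE)
  if (any(diff(times) <= 0))
    stop("times must be strictly increasing", call. = FALSE)
  structure(list(times = times, values = values, kind = kind),
            class = "time_series")
}

.ts_value <- function(ts, t) {
  if (t < min(ts$times) || t > max(ts$times))
    stop("time ", t, " outside the sampled interval [",
         min(ts$times), ", ", max(ts$times), "]", call. = FALSE)
  hit <- which(abs(ts$times - t) < 1e-12)
  if (length(hit)) return(ts$values[hit[1]])
  approx(ts$times, ts$values, xout = t)$y
}

#' Fit exponential growth to an OD time series
#'
#' Ordinary least squares on log(OD) versus time: the slope is the specific
#' growth rate mu (h^-1) with its standard error from the residual variance;
#' the intercept gives the initial biomass X0 (gCDW L^-1) through the
#' OD-to-CDW factor.
#'
#' @param od_series a `time_series` of kind `"od"` with positive values.
#' @param factor OD600-to-CDW correlation factor (default 0.33 gCDW L^-1).
#' @return An object of class `growth_fit`: `mu`, `sigma_mu`, `X0`,
#'   `sigma_lnX0`, `r_squared`, and the underlying `lm` fit.
#' @export
fit_exponential_growth <- function(od_series, factor = 0.33) {
  stopifnot(inherits(od_series, "time_series"))
  if (any(od_series$values <= 0))
    stop("exponential fit requires positive OD values", call. = FALSE)
  if (length(od_series$times) < 3L)
    stop("need at least 3 points for a growth rate with error estimate",
         call. = FALSE)
  t <- od_series$times
  fit <- lm(log(od_series$values) ~ t)
  sm <- summary(fit)
  structure(list(mu = unname(coef(fit)[2]),
                 sigma_mu = sm$coefficients[2, 2],
                 X0 = unname(exp(coef(fit)[1])) * factor,
                 sigma_lnX0 = sm$coefficients[1, 2],
                 r_squared = sm$r.squared,
                 cdw_factor = factor,
                 fit = fit),
            class = "growth_fit")
}

#' @export
print.growth_fit <- function(x, ...) {
  cat(sprintf("<growth_fit> mu = %.4g +/- %.2g h^-1, X0 = %.4g gCDW/L, R2 = %.4f\n",
              x$mu, x$sigma_mu, x$X0, x$r_squared))
  invisible(x)
}

#' Volumetric substrate conversion rate between two time points
#'
#' Finite-difference rate (s(t2) - s(t1)) / (t2 - t1); endpoint values are
#' taken from the series by exact match or linear interpolation.
#'
#' @param series a `time_series` of concentrations (mM).
#' @param t1,t2 window limits in hours, t1 < t2, inside the sampled range.
#' @return Rate in mM h^-1 (negative for consumption).
#' @export
substrate_rate <- function(series, t1, t2) {
  stopifnot(inherits(series, "time_series"))
  if (t1 >= t2) stop("t1 must be smaller than t2", call. = FALSE)
  (.ts_value(series, t2) - .ts_value(series, t1)) / (t2 - t1)
}

#' Specific substrate uptake rate with evaporation control
#'
#' Estimates the biomass-specific uptake rate q (mmol gCDW^-1 h^-1) from the
#' substrate drop of the culture over \[t1, t2\], corrected by the drop of a
#' non-consuming evaporation-control culture, divided by the biomass
#' integral. The default `method = "integral"` uses the exact mass balance
#' for exponential growth, q = dS * mu / (X0 * (e^(mu t2) - e^(mu t1)));
#' `method = "midpoint"` divides the interval rate by the biomass at the
#' window midpoint, X0 * e^(mu t), the literal instantaneous-rate reading.
#' Both agree as t2 -> t1. If the fitted mu is not positive the mean-biomass
#' denominator X0 * (t2 - t1) is used with a warning.
#'
#' The uncertainty `sigma_q` is first-order error propagation over the four
#' endpoint concentrations and the growth-fit parameters
#' (see [propagate_variance()]).
#'
#' @param culture substrate `time_series` of the consuming culture.
#' @param evap_control substrate `time_series` of the evaporation control.
#' @param fit a [fit_exponential_growth()] result.
#' @param t1,t2 evaluation window in hours.
#' @param method `"integral"` (default) or `"midpoint"`.
#' @param sigma_s measurement standard deviation of a single concentration
#'   reading (mM); default 0 reports only the growth-fit contribution.
#' @return An object of class `uptake_estimate`: `q` (positive =
#'   consumption), `sigma_q`, and the window used.
#' @export
specific_uptake_rate <- function(culture, evap_control, fit, t1, t2,
                                 method = c("integral", "midpoint"),
                                 sigma_s = 0) {
  method <- match.arg(method)
  stopifnot(inherits(culture, "time_series"),
            inherits(evap_control, "time_series"),
            inherits(fit, "growth_fit"), sigma_s >= 0)
  if (t1 >= t2) stop("t1 must be smaller than t2", call. = FALSE)

  q_of <- function(s_c1, s_c2, s_e1, s_e2, mu, lnX0) {
    dS <- (s_c1 - s_c2) - (s_e1 - s_e2)  # corrected consumption, positive
    X0 <- exp(lnX0) * fit$cdw_factor
    if (mu > 0) {
      denom <- switch(method,
        integral = X0 * (exp(mu * t2) - exp(mu * t1)) / mu,
        midpoint = X0 * exp(mu * (t1 + t2) / 2) * (t2 - t1))
    } else {
      denom <- X0 * (t2 - t1)
    }
    dS / denom
  }

  args <- c(.ts_value(culture, t1), .ts_value(culture, t2),
            .ts_value(evap_control, t1), .ts_value(evap_control, t2),
            fit$mu, log(fit$X0 / fit$cdw_factor))
  if (fit$mu <= 0)
    warning("non-positive growth rate; using mean-biomass denominator",
            call. = FALSE)
  q <- do.call(q_of, as.list(args))

  # numerical partial derivatives for first-order variance propagation
  variances <- c(rep(sigma_s^2, 4), fit$sigma_mu^2, fit$sigma_lnX0^2)
  partials <- vapply(seq_along(args), function(i) {
    h <- max(abs(args[i]), 1) * 1e-6
    up <- args; up[i] <- up[i] + h
    dn <- args; dn[i] <- dn[i] - h
    (do.call(q_of, as.list(up)) - do.call(q_of, as.list(dn))) / (2 * h)
  }, numeric(1))
  structure(list(q = q,
                 sigma_q = sqrt(propagate_variance(partials, variances)),
                 t1 = t1, t2 = t2, method = method),
            class = "uptake_estimate")
}

#' @export
print.uptake_estimate <- function(x, ...) {
  cat(sprintf("<uptake_estimate> q = %.4g +/- %.2g mmol gCDW^-1 h^-1 [%s, %g-%g h]\n",
              x$q, x$sigma_q, x$method, x$t1, x$t2))
  invisible(x)
}

#' Mass-balance regression estimate of the specific uptake rate
#'
#' Joint ordinary least squares over all sampled points of the culture and
#' evaporation-control series under the integrated mass-balance model
#' S_culture(t) = a_c - e t - q X0/mu (e^(mu t) - 1) and
#' S_control(t) = a_e - e t, with the growth parameters taken from the OD
#' fit. Linear in the unknowns (a_c, a_e, e, q), it uses every measurement
#' and is the recommended estimator for multi-point series; the two-point
#' [specific_uptake_rate()] is the exactly-identified special case.
#'
#' @inheritParams specific_uptake_rate
#' @return An `uptake_estimate` with `q`, `sigma_q` (from the regression
#'   covariance) and the evaporation rate estimate `evap_rate` (mM h^-1).
#' @export
fit_uptake_rate <- function(culture, evap_control, fit) {
  stopifnot(inherits(culture, "time_series"),
            inherits(evap_control, "time_series"),
            inherits(fit, "growth_fit"))
  if (fit$mu <= 0)
    stop("mass-balance regression needs a positive growth rate",
         call. = FALSE)
  g <- function(t) fit$X0 / fit$mu * (exp(fit$mu * t) - 1)
  y <- c(culture$values, evap_control$values)
  nc <- length(culture$times); ne <- length(evap_control$times)
  X <- cbind(a_c = c(rep(1, nc), rep(0, ne)),
             a_e = c(rep(0, nc), rep(1, ne)),
             e = -c(culture$times, evap_control$times),
             q = -c(g(culture$times), rep(0, ne)))
  ls <- lm(y ~ X - 1)
  est <- coef(ls)
  se <- summary(ls)$coefficients[, 2]
  structure(list(q = unname(est["Xq"]), sigma_q = unname(se["Xq"]),
                 evap_rate = unname(est["Xe"]),
                 t1 = min(culture$times), t2 = max(culture$times),
                 method = "mass_balance_regression"),
            class = "uptake_estimate")
}

#' First-order (delta-method) variance propagation
#'
#' Variance of f(x_1..x_k) with independent inputs:
#' sum over i of (df/dx_i)^2 * var_i.
#'
#' @param partials sensitivities df/dx_i at the evaluation point.
#' @param variances input variances, same length.
#' @return Propagated variance.
#' @export
propagate_variance <- function(partials, variances) {
  stopifnot(length(partials) == length(variances), all(variances >= 0))
  sum(partials^2 * variances)
}
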