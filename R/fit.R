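#' Fit window for TCSPC decay fits
#'
#' Fits are performed on a window starting a fixed offset before the peak
#' maximum of the measured decay and ending at a fixed time.
#'
#' @param start_offset_before_peak Offset before the data peak in ns
#'   (default 1.0).
#' @param end_time Window end in ns (default 40.0).
#' @return An object of class `fit_window`.
#' @export
fit_window <- function(start_offset_before_peak = 1.0, end_time = 40.0) {
  stopifnot(end_time > 0)
  structure(list(start_offset_before_peak = start_offset_before_peak,
                 end_time = end_time),
            class = "fit_window")
}

# Bin indices of the fit window; the peak is located on the *measured* decay.
window_indices <- function(data, window) {
  t <- grid_times(data$grid)
  peak_t <- t[which.max(data$counts)]
  idx <- which(t >= peak_t - window$start_offset_before_peak &
                 t <= window$end_time)
  if (length(idx) < 10L)
    stop("fit window must contain at least 10 bins")
  idx
}

#' Poisson-weighted reduced chi-square
#'
#' `chi2_r = sum_bins (data - model)^2 / max(data, 1) / (n_bins - n_params)`
#' over the fit window, with Neyman (1/observed-count) weights — the standard
#' TCSPC weighting for Poisson counting noise.
#'
#' @param data,model [tcspc_histogram()]s on the same grid.
#' @param n_params Number of free fit parameters `k`.
#' @param window [fit_window()].
#' @return Reduced chi-square (dimensionless).
#' @export
reduced_chi2 <- function(data, model, n_params, window = fit_window()) {
  if (!same_grid(data$grid, model$grid))
    stop("data and model must share the same time grid")
  idx <- window_indices(data, window)
  nu <- length(idx) - n_params
  if (nu <= 0) stop("degrees of freedom must be positive")
  d <- data$counts[idx]
  m <- model$counts[idx]
  sum((d - m)^2 / pmax(d, 1)) / nu
}

#' Support-plane / F-statistic chi-square ratio threshold
#'
#' The confidence boundary at probability level `P` is the chi-square ratio
#' `F_chi = 1 + (k / nu) * F(k, nu; 1 - P)`, with `F(.,.;.)` the F-distribution
#' quantile, `k` the number of fitted parameters and `nu` the degrees of
#' freedom. `P = 0.32` gives a 68.3% (one standard deviation) confidence
#' region.
#'
#' @param k Number of fitted parameters.
#' @param nu Degrees of freedom.
#' @param P Exceedance probability (default 0.32).
#' @return Threshold ratio (> 1).
#' @export
f_chi_threshold <- function(k, nu, P = 0.32) {
  stopifnot(k >= 1, nu >= 1, P > 0, P < 1)
  1 + (k / nu) * stats::qf(1 - P, k, nu)
}

fit_param_names <- c("mean_R", "sigma_R", "x_D0", "I0", "BG")

params_to_vec <- function(params) {
  c(mean_R = params$distance$mean_R, sigma_R = params$distance$sigma_R,
    x_D0 = params$x_D0, I0 = params$I0, BG = params$BG)
}

vec_to_params <- function(v, template) {
  fret_decay_params(template$donor_components,
                    gaussian_distance(v[["mean_R"]], max(v[["sigma_R"]], 0)),
                    template$R0,
                    x_D0 = min(max(v[["x_D0"]], 0), 1),
                    I0 = v[["I0"]], BG = max(v[["BG"]], 0))
}

default_bounds <- function(start_vec) {
  list(lower = c(mean_R = 2, sigma_R = 1e-3, x_D0 = 0, I0 = 1e-6 * start_vec[["I0"]],
                 BG = 0),
       upper = c(mean_R = 500, sigma_R = 100, x_D0 = 1,
                 I0 = 1e6 * start_vec[["I0"]],
                 BG = max(1e4, 1e3 * (start_vec[["BG"]] + 1))))
}

# Residuals whose sum of squares is the minimized objective. "mle" gives
# signed square-root Poisson deviance contributions (sum of squares = Poisson
# deviance, the -2 log likelihood up to a model-independent constant);
# "pearson" uses model-based weights; "neyman" observed-count weights.
objective_residuals <- function(d, m, weighting) {
  m <- pmax(m, 1e-12)
  switch(weighting,
         mle = {
           term <- m - d
           pos <- d > 0
           term[pos] <- term[pos] + d[pos] * log(d[pos] / m[pos])
           sign(d - m) * sqrt(2 * pmax(term, 0))
         },
         pearson = (d - m) / sqrt(m),
         neyman = (d - m) / sqrt(pmax(d, 1)))
}

# Core bounded Levenberg-Marquardt engine. Returns the optimized full
# parameter vector, the per-dof objective, the Neyman reduced chi2 and
# convergence info.
fit_engine <- function(data, irf, start_vec, template, window, free,
                       weighting = "mle", ftol = 1e-8, maxit = 300,
                       step = 0.25, n_sigma = 4,
                       renormalize = TRUE, wrap = FALSE) {
  idx <- window_indices(data, window)
  d <- data$counts[idx]
  grid <- data$grid
  bounds <- default_bounds(start_vec)
  cur <- start_vec
  last_m <- NULL
  model_fn <- function(v) {
    params <- vec_to_params(v, template)
    fret_model_curve(params, grid, irf = irf, wrap = wrap,
                     step = step, n_sigma = n_sigma,
                     renormalize = renormalize)$counts[idx]
  }
  resid_fn <- function(p) {
    v <- cur
    v[free] <- p
    m <- model_fn(v)
    last_m <<- m
    objective_residuals(d, m, weighting)
  }
  nu <- length(idx) - length(free)
  if (nu <= 0) stop("degrees of freedom must be positive")
  if (length(free) == 0L) {
    r <- resid_fn(numeric(0))
    return(list(vec = cur, obj_r = sum(r^2) / length(idx),
                chi2r = sum((d - last_m)^2 / pmax(d, 1)) / length(idx),
                converged = TRUE, nu = length(idx), n_free = 0L, idx = idx))
  }
  fit <- minpack.lm::nls.lm(
    par = start_vec[free], fn = resid_fn,
    lower = bounds$lower[free], upper = bounds$upper[free],
    control = minpack.lm::nls.lm.control(ftol = ftol, ptol = 1e-10,
                                         maxiter = maxit))
  cur[free] <- fit$par
  m <- model_fn(cur)
  list(vec = cur, obj_r = fit$deviance / nu,
       chi2r = sum((d - m)^2 / pmax(d, 1)) / nu,
       # info 1-3: ftol/xtol satisfied; 4: residual orthogonal to the
       # jacobian to machine precision; an essentially zero deviance
       # (noiseless self-consistency) also counts as converged even when
       # the iteration cap stops the final polishing steps
       converged = fit$info %in% 1:4 || fit$deviance / nu < 1e-6,
       info = fit$info,
       nu = nu, n_free = length(free), idx = idx)
}

#' Fit a TCSPC decay by iterative reconvolution
#'
#' Fits the total donor model (Gaussian distance distribution, donor-only
#' fraction, background) reconvolved with the IRF, minimizing a Poisson
#' objective (maximum-likelihood deviance by default, see `weighting`) with
#' a bounded Levenberg-Marquardt minimizer run until the estimated relative
#' decrease of the objective is below `1e-8`. Bounds `x_D0` in \[0, 1\], `sigma_R > 0`,
#' `mean_R > 0` are enforced. Donor lifetime components and the Forster
#' radius are taken from `start` and held fixed (they come from independent
#' donor-only reference measurements).
#'
#' @param data Measured or simulated [tcspc_histogram()].
#' @param irf [irf_curve()] or `NULL` for an ideal delta IRF.
#' @param start [fret_decay_params()] with the starting guesses.
#' @param window [fit_window()].
#' @param fixed Character vector of parameter names to hold fixed, from
#'   `c("mean_R", "sigma_R", "x_D0", "I0", "BG")`.
#' @param ci Also compute support-plane 68.3% confidence intervals for the
#'   named free parameters (character vector, or `TRUE` for all free ones).
#' @param irf_baseline Subtract a constant IRF background estimated from
#'   pre-peak bins before area normalization.
#' @param weighting Objective minimized: `"mle"` (default, Poisson maximum
#'   likelihood via deviance residuals), `"pearson"` (model-based 1/max(m,1)
#'   weights) or `"neyman"` (observed-count 1/max(d,1) weights). The reported
#'   goodness-of-fit statistic `chi2r` is always the Neyman-weighted reduced
#'   chi-square of [reduced_chi2()], evaluated at the optimum.
#' @param step,n_sigma,renormalize Distance-integration settings, see
#'   [distance_weights()].
#' @param wrap Periodic-wrap reconvolution, see [convolve_with_irf()].
#' @return An object of class `fret_fit` with elements `estimates` (named
#'   vector), `chi2r`, `nu`, `n_free`, `converged`, `ci` (matrix or NULL),
#'   `window`, `params` (the fitted [fret_decay_params()]).
#' @export
fit_decay <- function(data, irf = NULL, start, window = fit_window(),
                      fixed = character(), ci = FALSE,
                      irf_baseline = TRUE,
                      weighting = c("mle", "pearson", "neyman"),
                      step = 0.25, n_sigma = 4,
                      renormalize = TRUE, wrap = FALSE) {
  weighting <- match.arg(weighting)
  stopifnot(inherits(data, "tcspc_histogram"),
            inherits(start, "fret_decay_params"))
  if (all(data$counts == 0)) stop("degenerate data: all counts are zero")
  if (!is.null(irf)) irf <- prepare_irf(irf, baseline = irf_baseline)
  start_vec <- params_to_vec(start)
  if (length(fixed))
    fixed <- match.arg(fixed, fit_param_names, several.ok = TRUE)
  free <- setdiff(fit_param_names, fixed)
  eng <- fit_engine(data, irf, start_vec, start, window, free,
                    weighting = weighting, step = step, n_sigma = n_sigma,
                    renormalize = renormalize, wrap = wrap)
  res <- structure(
    list(estimates = eng$vec, chi2r = eng$chi2r, obj_r = eng$obj_r,
         nu = eng$nu,
         n_free = eng$n_free, converged = eng$converged,
         free = free, fixed = fixed, window = window,
         params = vec_to_params(eng$vec, start), irf = irf,
         data = data, ci = NULL,
         opts = list(weighting = weighting, step = step, n_sigma = n_sigma,
                     renormalize = renormalize, wrap = wrap)),
    class = "fret_fit")
  if (!isFALSE(ci)) {
    ci_params <- if (isTRUE(ci)) free else intersect(ci, free)
    cim <- t(vapply(ci_params, function(p)
      support_plane_interval(res, p), numeric(2)))
    colnames(cim) <- c("low", "high")
    res$ci <- cim
  }
  res
}

#' @export
print.fret_fit <- function(x, ...) {
  cat("FRET decay fit", if (!x$converged) "(NOT converged)", "\n")
  est <- x$estimates
  cat(sprintf("  <R_DA> = %.2f A, sigma_DA = %.2f A, x_D0 = %.3f\n",
              est[["mean_R"]], est[["sigma_R"]], est[["x_D0"]]))
  cat(sprintf("  I0 = %.4g, BG = %.4g, chi2r = %.4f (nu = %d)\n",
              est[["I0"]], est[["BG"]], x$chi2r, x$nu))
  if (!is.null(x$ci)) {
    for (p in rownames(x$ci))
      cat(sprintf("  %s: 68.3%% CI [%.3f, %.3f]\n",
                  p, x$ci[p, 1], x$ci[p, 2]))
  }
  invisible(x)
}

# Subtract the constant IRF offset estimated from pre-peak bins and clamp.
prepare_irf <- function(irf, baseline = TRUE) {
  if (is_delta_irf(irf) || !baseline) return(irf)
  peak <- which.max(irf$values)
  pre <- seq_len(max(0L, peak - 25L))
  if (length(pre) >= 5L) {
    bg <- stats::median(irf$values[pre])
    v <- pmax(irf$values - bg, 0)
    if (sum(v) > 0) return(irf_curve(irf$grid, v, fwhm = irf$fwhm))
  }
  irf
}

#' Support-plane confidence interval for one fitted parameter
#'
#' The named parameter is scanned away from its estimate; at each scan value
#' all other free parameters are re-minimized, and the interval bounds are
#' the points where the re-minimized reduced chi-square crosses
#' `chi2r_min * F_chi(k, nu, P)`. If a parameter bound (e.g. `x_D0 = 0`) is
#' reached before the crossing, the bound itself is reported (one-sided
#' interval).
#'
#' @param fit A converged [fit_decay()] result.
#' @param param One of the fit's free parameter names.
#' @param P Exceedance probability (default 0.32, i.e. 68.3% confidence).
#' @param initial_step Initial scan step (default: 0.5% of the estimate's
#'   magnitude, with a floor).
#' @param grow Geometric step growth factor per scan point.
#' @param max_steps Maximum scan points per direction before a widened retry.
#' @return Numeric `c(low, high)`.
#' @export
support_plane_interval <- function(fit, param, P = 0.32,
                                   initial_step = NULL, grow = 1.7,
                                   max_steps = 30L) {
  stopifnot(inherits(fit, "fret_fit"), param %in% fit$free)
  est <- fit$estimates[[param]]
  thresh <- fit$obj_r * f_chi_threshold(fit$n_free, fit$nu, P)
  bounds <- default_bounds(fit$estimates)
  if (is.null(initial_step))
    initial_step <- max(abs(est) * 0.005, 0.002)
  others <- setdiff(fit$free, param)
  scan_dir <- function(sign, step0) {
    step <- step0
    prev_x <- est
    prev_chi <- fit$obj_r
    start_vec <- fit$estimates
    for (i in seq_len(max_steps)) {
      x <- est + sign * step
      hit_bound <- FALSE
      if (x < bounds$lower[[param]]) { x <- bounds$lower[[param]]; hit_bound <- TRUE }
      if (x > bounds$upper[[param]]) { x <- bounds$upper[[param]]; hit_bound <- TRUE }
      start_vec[param] <- x
      eng <- fit_engine(fit$data, fit$irf, start_vec, fit$params, fit$window,
                        others, weighting = fit$opts$weighting,
                        step = fit$opts$step,
                        n_sigma = fit$opts$n_sigma,
                        renormalize = fit$opts$renormalize,
                        wrap = fit$opts$wrap)
      # objective with the scanned parameter counted among the k parameters
      chi <- eng$obj_r * eng$nu / fit$nu
      start_vec <- eng$vec
      start_vec[param] <- x
      if (chi >= thresh) {
        # linear interpolation of the crossing between the last two points
        frac <- if (chi > prev_chi) (thresh - prev_chi) / (chi - prev_chi) else 1
        return(prev_x + frac * (x - prev_x))
      }
      if (hit_bound) return(x)
      prev_x <- x
      prev_chi <- chi
      step <- step * grow
    }
    NA_real_
  }
  lo <- scan_dir(-1, initial_step)
  if (is.na(lo)) lo <- scan_dir(-1, initial_step * 5)
  hi <- scan_dir(+1, initial_step)
  if (is.na(hi)) hi <- scan_dir(+1, initial_step * 5)
  if (is.na(lo) || is.na(hi))
    stop("support-plane crossing not bracketed for ", param)
  c(lo, hi)
}

#' F-statistic confidence surface over (sigma_DA, <R_DA>, x_D0)
#'
#' Evaluates the reduced chi-square ratio `chi2r(xi) / chi2r_min` on a
#' three-dimensional grid centered on the fitted minimum, with `I0` and `BG`
#' fixed at their estimates, and marks the points inside the 68.3% confidence
#' surface (`ratio <= F_chi(k = 3, nu, P)`).
#'
#' @param fit A converged [fit_decay()] result with `mean_R`, `sigma_R` and
#'   `x_D0` among its free parameters.
#' @param half_widths Named numeric: half-widths of the grid along
#'   `sigma_R`, `mean_R`, `x_D0`.
#' @param n_points Odd number of grid points per axis (center = estimate).
#' @param P Exceedance probability.
#' @return An object of class `confidence_surface`: list with `axes` (list of
#'   3 numeric vectors), `ratio` (3-d array), `threshold`, `inside` (logical
#'   array), `P`.
#' @export
confidence_surface <- function(fit, half_widths = c(sigma_R = 2, mean_R = 2,
                                                    x_D0 = 0.1),
                               n_points = 7L, P = 0.32) {
  stopifnot(inherits(fit, "fret_fit"),
            all(c("mean_R", "sigma_R", "x_D0") %in% fit$free))
  if (!fit$converged) stop("fit must be converged")
  n_points <- as.integer(n_points)
  if (n_points %% 2L == 0L) n_points <- n_points + 1L
  axes <- lapply(c(sigma_R = "sigma_R", mean_R = "mean_R", x_D0 = "x_D0"),
                 function(p) {
                   ax <- fit$estimates[[p]] +
                     seq(-half_widths[[p]], half_widths[[p]],
                         length.out = n_points)
                   lo <- default_bounds(fit$estimates)$lower[[p]]
                   hi <- default_bounds(fit$estimates)$upper[[p]]
                   pmin(pmax(ax, lo), hi)
                 })
  idx <- window_indices(fit$data, fit$window)
  d <- fit$data$counts[idx]
  grid <- fit$data$grid
  ratio <- array(NA_real_, dim = rep(n_points, 3))
  for (k3 in seq_len(n_points)) for (k2 in seq_len(n_points))
    for (k1 in seq_len(n_points)) {
      v <- fit$estimates
      v["sigma_R"] <- axes$sigma_R[k1]
      v["mean_R"] <- axes$mean_R[k2]
      v["x_D0"] <- axes$x_D0[k3]
      m <- fret_model_curve(vec_to_params(v, fit$params), grid,
                            irf = fit$irf, wrap = fit$opts$wrap,
                            step = fit$opts$step, n_sigma = fit$opts$n_sigma,
                            renormalize = fit$opts$renormalize)$counts[idx]
      ratio[k1, k2, k3] <-
        sum(objective_residuals(d, m, fit$opts$weighting)^2) / fit$nu
    }
  ratio <- ratio / fit$obj_r
  thr <- f_chi_threshold(3, fit$nu, P)
  structure(list(axes = axes, ratio = ratio, threshold = thr,
                 inside = ratio <= thr, P = P),
            class = "confidence_surface")
}
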