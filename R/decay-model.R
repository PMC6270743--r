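#' Multi-exponential donor decay components
#'
#' Amplitude fractions and lifetimes of a multi-exponential fluorescence
#' decay, used to describe local quenching of the donor (one or two
#' components for dye-labeled DNA).
#'
#' @param amplitudes Amplitude fractions `x_i`, each in (0, 1], summing to 1
#'   within 1e-9.
#' @param lifetimes Lifetimes `tau_i` in ns, all > 0.
#' @return An object of class `exp_components`.
#' @export
exp_components <- function(amplitudes, lifetimes) {
  amplitudes <- as.numeric(amplitudes)
  lifetimes <- as.numeric(lifetimes)
  if (length(amplitudes) != length(lifetimes) || length(amplitudes) < 1)
    stop("amplitudes and lifetimes must have equal positive length")
  if (any(!is.finite(amplitudes)) || any(amplitudes <= 0) || any(amplitudes > 1))
    stop("all amplitude fractions must lie in (0, 1]")
  if (abs(sum(amplitudes) - 1) > 1e-9)
    stop("amplitude fractions must sum to 1")
  if (any(!is.finite(lifetimes)) || any(lifetimes <= 0))
    stop("all lifetimes must be > 0")
  structure(list(amplitudes = amplitudes, lifetimes = lifetimes),
            class = "exp_components")
}

#' Gaussian inter-dye distance distribution
#'
#' @param mean_R Mean inter-dye distance `<R_DA>` in Angstrom (> 0).
#' @param sigma_R Standard deviation `sigma_DA` in Angstrom (>= 0); the
#'   average amplitude of the inter-dye distance fluctuations. `sigma_R = 0`
#'   denotes a single fixed distance.
#' @return An object of class `gaussian_distance`.
#' @export
gaussian_distance <- function(mean_R, sigma_R) {
  if (!is.numeric(mean_R) || mean_R <= 0) stop("mean_R must be > 0")
  if (!is.numeric(sigma_R) || sigma_R < 0) stop("sigma_R must be >= 0")
  structure(list(mean_R = mean_R, sigma_R = sigma_R),
            class = "gaussian_distance")
}

#' Full donor decay model parameters
#'
#' Parameters of the total donor fluorescence model: the FRET-quenched decay
#' of a Gaussian distance distribution mixed with a donor-only fraction
#' `x_D0`, scaled to peak amplitude `I0`, plus a constant background `BG`.
#'
#' @param donor_components [exp_components()]: unquenched donor lifetimes
#'   `tau_D0,i` and fractions `x_i`.
#' @param distance [gaussian_distance()].
#' @param R0 Forster radius in Angstrom (> 0).
#' @param x_D0 Donor-only molecule fraction in \[0, 1\].
#' @param I0 Peak model amplitude in counts (> 0).
#' @param BG Constant background in counts per bin (>= 0).
#' @return An object of class `fret_decay_params`.
#' @export
fret_decay_params <- function(donor_components, distance, R0,
                              x_D0 = 0, I0 = 1, BG = 0) {
  stopifnot(inherits(donor_components, "exp_components"),
            inherits(distance, "gaussian_distance"))
  if (!is.numeric(R0) || R0 <= 0) stop("R0 must be > 0")
  if (!is.numeric(x_D0) || x_D0 < 0 || x_D0 > 1) stop("x_D0 must be in [0, 1]")
  if (!is.numeric(I0) || I0 <= 0) stop("I0 must be > 0")
  if (!is.numeric(BG) || BG < 0) stop("BG must be >= 0")
  structure(list(donor_components = donor_components, distance = distance,
                 R0 = R0, x_D0 = x_D0, I0 = I0, BG = BG),
            class = "fret_decay_params")
}

#' Evaluate a multi-exponential decay on a time grid
#'
#' `F(t) = I0 * sum_i x_i * exp(-t / tau_i)` at bin centers.
#'
#' @param components [exp_components()].
#' @param I0 Peak amplitude (counts).
#' @param grid [time_grid()].
#' @return A [tcspc_histogram()] with the (noiseless) model values.
#' @export
evaluate_multiexponential <- function(components, I0, grid) {
  stopifnot(inherits(components, "exp_components"), inherits(grid, "time_grid"))
  v <- expsum_grid(grid$origin, grid$bin_width, grid$n_bins,
                   I0 * components$amplitudes, 1 / components$lifetimes)
  tcspc_histogram(grid, v)
}

#' FRET transfer efficiency
#'
#' `E = 1 / (1 + (R/R0)^6)`; at `R = R0` the efficiency is 0.5.
#'
#' @param R Inter-dye distance(s) in Angstrom (> 0).
#' @param R0 Forster radius in Angstrom (> 0).
#' @return Efficiencies in (0, 1).
#' @export
transfer_efficiency <- function(R, R0) {
  if (any(R <= 0)) stop("R must be > 0")
  if (any(R0 <= 0)) stop("R0 must be > 0")
  1 / (1 + (R / R0)^6)
}

#' FRET rate enhancement factor
#'
#' The factor `1 + (R0/R)^6` by which the donor decay rate of each lifetime
#' component is multiplied at inter-dye distance `R`.
#'
#' @inheritParams transfer_efficiency
#' @return Rate factors (>= 1).
#' @export
fret_rate_factor <- function(R, R0) {
  if (any(R <= 0)) stop("R must be > 0")
  if (any(R0 <= 0)) stop("R0 must be > 0")
  1 + (R0 / R)^6
}

#' Gaussian distance density
#'
#' Continuous Gaussian probability density of the inter-dye distance.
#'
#' @param dist [gaussian_distance()] with `sigma_R > 0`.
#' @param R_values Distances (Angstrom) at which to evaluate the density.
#' @return Densities in 1/Angstrom.
#' @export
gaussian_distance_pdf <- function(dist, R_values) {
  stopifnot(inherits(dist, "gaussian_distance"))
  if (dist$sigma_R <= 0) stop("sigma_R must be > 0 for a density")
  stats::dnorm(R_values, mean = dist$mean_R, sd = dist$sigma_R)
}

#' Discrete integration weights for the distance distribution
#'
#' Distance grid over `[mean - n_sigma*sigma, mean + n_sigma*sigma]` with the
#' given step, lower bound clipped to `min_R` (avoiding the `(R0/R)^6`
#' singularity), carrying Gaussian weights. By default the truncated discrete
#' weights are renormalized to unit mass so that the FRET-quenched decay has
#' exactly unit amplitude at t = 0 and `x_D0` keeps its exact interpretation;
#' `renormalize = FALSE` integrates the raw (truncated) Gaussian instead.
#'
#' @param dist [gaussian_distance()].
#' @param step Integration step in Angstrom (default 0.25).
#' @param n_sigma Half-range of the integration interval in units of sigma.
#' @param renormalize Renormalize discrete weights to sum to 1.
#' @param min_R Lower clip bound in Angstrom.
#' @return List with numeric vectors `R` and `w`.
#' @export
distance_weights <- function(dist, step = 0.25, n_sigma = 4,
                             renormalize = TRUE, min_R = 1) {
  stopifnot(inherits(dist, "gaussian_distance"))
  if (dist$sigma_R == 0)
    return(list(R = dist$mean_R, w = 1))
  hi <- dist$mean_R + n_sigma * dist$sigma_R
  if (hi <= min_R) stop("integration interval lies entirely below min_R")
  # symmetric grid centered on the mean so the sigma -> 0 limit is exact
  k <- floor(n_sigma * dist$sigma_R / step)
  R <- dist$mean_R + (-k:k) * step
  R <- R[R >= min_R]
  w <- stats::dnorm(R, dist$mean_R, dist$sigma_R)
  w <- if (renormalize) w / sum(w) else w * step
  list(R = R, w = w)
}

#' Distance-averaged FRET-quenched donor decay
#'
#' Each donor lifetime component is quenched by FRET as a function of the
#' inter-dye distance, and the decay is averaged over the Gaussian distance
#' distribution:
#' `F_DA(t) = sum_i x_i sum_R w(R) exp(-(t/tau_i) * (1 + (R0/R)^6))`,
#' with `w(R)` discrete Gaussian weights over `mean +/- 4 sigma`, step 0.25 A.
#' With `sigma_R = 0` the single-distance decay is returned (no integration).
#' The curve has unit amplitude at t = 0 (when weights are renormalized).
#'
#' @param params [fret_decay_params()] (only the donor components, distance
#'   and `R0` are used; `x_D0`, `I0`, `BG` are applied by
#'   [total_donor_model()]).
#' @param grid [time_grid()].
#' @inheritParams distance_weights
#' @return A [tcspc_histogram()] of the noiseless `F_DA` curve.
#' @export
fret_quenched_decay <- function(params, grid, step = 0.25, n_sigma = 4,
                                renormalize = TRUE, min_R = 1) {
  stopifnot(inherits(params, "fret_decay_params"), inherits(grid, "time_grid"))
  dw <- distance_weights(params$distance, step = step, n_sigma = n_sigma,
                         renormalize = renormalize, min_R = min_R)
  comp <- params$donor_components
  rate_f <- fret_rate_factor(dw$R, params$R0)
  amps <- as.vector(outer(dw$w, comp$amplitudes))
  rates <- as.vector(outer(rate_f, 1 / comp$lifetimes))
  v <- expsum_grid(grid$origin, grid$bin_width, grid$n_bins, amps, rates)
  tcspc_histogram(grid, v)
}

#' Total donor model with donor-only fraction and background
#'
#' `F(t) = I0 * [(1 - x_D0) * F_DA(t) + x_D0 * F_D0(t)] + BG`, where `F_D0`
#' is the unquenched multi-exponential donor decay built from the same
#' components `(x_i, tau_i)` as the FRET-quenched term.
#'
#' @inheritParams fret_quenched_decay
#' @return A [tcspc_histogram()] of the noiseless model.
#' @export
total_donor_model <- function(params, grid, step = 0.25, n_sigma = 4,
                              renormalize = TRUE, min_R = 1) {
  stopifnot(inherits(params, "fret_decay_params"))
  f_d0 <- evaluate_multiexponential(params$donor_components, 1, grid)$counts
  mix <- if (params$x_D0 >= 1) {
    f_d0
  } else {
    f_da <- fret_quenched_decay(params, grid, step = step, n_sigma = n_sigma,
                                renormalize = renormalize, min_R = min_R)$counts
    (1 - params$x_D0) * f_da + params$x_D0 * f_d0
  }
  tcspc_histogram(grid, params$I0 * mix + params$BG)
}

#' Convolve a model decay with an IRF
#'
#' Discrete causal convolution of the area-normalized IRF with the model
#' curve (iterative-reconvolution forward model). With `wrap = TRUE` the
#' convolution tail beyond the laser period is folded back onto the start of
#' the window (periodic excitation at e.g. 20 MHz, 50 ns period); off by
#' default since a fit window ending at 40 ns of a 50 ns period makes wrap
#' effects small. Any constant background is added *after* convolution by
#' the caller (see [fret_model_curve()]).
#'
#' @param model [tcspc_histogram()] of the unconvolved model.
#' @param irf [irf_curve()] on the same grid.
#' @param wrap Fold the convolution tail periodically.
#' @param period Laser period in ns used when `wrap = TRUE`.
#' @return A [tcspc_histogram()].
#' @export
convolve_with_irf <- function(model, irf, wrap = FALSE, period = 50) {
  stopifnot(inherits(model, "tcspc_histogram"), inherits(irf, "irf_curve"))
  if (!same_grid(model$grid, irf$grid))
    stop("model and IRF must share the same time grid")
  if (is_delta_irf(irf))
    return(model)
  n <- model$grid$n_bins
  kern <- irf$values / sum(irf$values)
  m <- stats::nextn(2L * n)
  full <- Re(stats::fft(stats::fft(c(model$counts, numeric(m - n))) *
                          stats::fft(c(kern, numeric(m - n))),
                        inverse = TRUE)) / m
  full <- full[seq_len(2L * n - 1L)]
  out <- full[seq_len(n)]
  if (wrap) {
    p <- as.integer(round(period / model$grid$bin_width))
    beyond <- which(seq_along(full) > max(p, n))
    for (i in beyond) {
      tgt <- ((i - 1L) %% p) + 1L
      if (tgt <= n) out[tgt] <- out[tgt] + full[i]
    }
  }
  out[out < 0] <- 0
  tcspc_histogram(model$grid, out)
}

#' Full forward model curve for fitting
#'
#' Evaluates the total donor model without background, convolves it with the
#' IRF (skipped for an ideal delta IRF), then adds the constant background.
#'
#' @inheritParams total_donor_model
#' @param irf [irf_curve()] or `NULL` for an ideal (delta) IRF.
#' @param wrap,period Passed to [convolve_with_irf()].
#' @return A [tcspc_histogram()] of the noiseless model, IRF-convolved.
#' @export
fret_model_curve <- function(params, grid, irf = NULL, wrap = FALSE,
                             period = 50, step = 0.25, n_sigma = 4,
                             renormalize = TRUE, min_R = 1) {
  bare <- fret_decay_params(params$donor_components, params$distance,
                            params$R0, x_D0 = params$x_D0, I0 = params$I0,
                            BG = 0)
  if (!is.null(irf) && !is_delta_irf(irf)) {
    # sample the impulse response on a zero-origin time axis so that the
    # discrete convolution lands on the grid's absolute times (the IRF
    # carries the grid origin already; sampling both at the origin would
    # shift the model curve early by one origin offset)
    zgrid <- time_grid(grid$bin_width, grid$n_bins, origin = 0)
    curve <- total_donor_model(bare, zgrid, step = step, n_sigma = n_sigma,
                               renormalize = renormalize, min_R = min_R)
    vals <- curve$counts
    # trapezoidal edge weight at the causality step: the t = 0 sample
    # represents a half cell (the decay is zero at negative times), so it
    # enters the convolution with weight 1/2
    vals[1] <- vals[1] / 2
    curve <- convolve_with_irf(tcspc_histogram(grid, vals), irf,
                               wrap = wrap, period = period)
  } else {
    curve <- total_donor_model(bare, grid, step = step, n_sigma = n_sigma,
                               renormalize = renormalize, min_R = min_R)
  }
  tcspc_histogram(grid, curve$counts + params$BG)
}

is_delta_irf <- function(irf) {
  nz <- which(irf$values > 0)
  length(nz) == 1L && nz == 1L
}

#' Amplitude-averaged lifetime and referenced quantum yield
#'
#' The amplitude-averaged lifetime `tau_avg = sum_i x_i tau_i` scales a
#' reference quantum yield: `phi = ref_qy * tau_avg / ref_lifetime`, the
#' standard way to obtain quantum yields of dye-labeled samples from the
#' free-dye reference values.
#'
#' @param components [exp_components()].
#' @param ref_lifetime Reference (free dye) lifetime in ns.
#' @param ref_qy Reference quantum yield.
#' @return List with `tau_avg` (ns) and `qy`.
#' @export
amplitude_averaged_lifetime_qy <- function(components, ref_lifetime, ref_qy) {
  stopifnot(inherits(components, "exp_components"),
            ref_lifetime > 0, ref_qy > 0)
  tau_avg <- sum(components$amplitudes * components$lifetimes)
  list(tau_avg = tau_avg, qy = ref_qy * tau_avg / ref_lifetime)
}
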