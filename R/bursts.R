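#' Intensity correction factors for burst analysis
#'
#' @param gamma_prime Quantum yield ratio `phi_A / phi_D` (default 0.36,
#'   from amplitude-averaged-lifetime quantum yields of the single-labeled
#'   samples).
#' @param g Detection efficiency ratio `g_A / g_D` (default 1.3).
#' @param gamma Combined factor `gamma = gamma' * g`; defaults to 0.47, the
#'   product to the printed two-decimal precision. Must agree with
#'   `gamma_prime * g` within 0.005 when all are set.
#' @param alpha Donor crosstalk probability into the acceptor channel
#'   (default 0.0085, i.e. 0.85%).
#' @param bg_rate_D,bg_rate_A Background count rates per channel in Hz;
#'   `NA` means "estimate from the inter-burst stretches of the stream".
#' @return An object of class `correction_factors`.
#' @export
correction_factors <- function(gamma_prime = 0.36, g = 1.3, gamma = 0.47,
                               alpha = 0.0085,
                               bg_rate_D = NA_real_, bg_rate_A = NA_real_) {
  stopifnot(gamma_prime > 0, g > 0, gamma > 0, alpha >= 0)
  if (abs(gamma - gamma_prime * g) > 0.005)
    stop("gamma must equal gamma_prime * g (within printed precision)")
  structure(list(gamma_prime = gamma_prime, g = g, gamma = gamma,
                 alpha = alpha, bg_rate_D = bg_rate_D, bg_rate_A = bg_rate_A),
            class = "correction_factors")
}

#' Centered moving average of an inter-photon-distance trace
#'
#' @param ipd Numeric trace (e.g. inter-photon distances in microseconds).
#' @param width Odd window width in points (default 7). At the trace edges
#'   the available shorter window is used.
#' @return Smoothed trace of the same length.
#' @export
smooth_ipd <- function(ipd, width = 7L) {
  width <- as.integer(width)
  if (width < 1L || width %% 2L == 0L)
    stop("width must be odd and >= 1")
  n <- length(ipd)
  if (n == 0L || width == 1L) return(ipd)
  half <- width %/% 2L
  cs <- cumsum(c(0, ipd))
  i <- seq_len(n)
  lo <- pmax(i - half, 1L)
  hi <- pmin(i + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Detect single-molecule bursts on the PIE channel
#'
#' Computes inter-photon distances (IPDs) of the directly-excited-acceptor
#' (PIE: acceptor channel, red excitation window) photons, smooths them with
#' a centered moving average (width 7), and marks runs where the smoothed
#' IPD is below the threshold (50 us). Burst start/end are the macrotimes of
#' the first/last photon of each run.
#'
#' @param stream A photon stream (see [simulate_stream()]).
#' @param threshold_us IPD threshold in microseconds.
#' @param width Moving-average width (odd).
#' @return A `data.frame` with columns `start_us`, `end_us`, `n_pie`.
#' @export
detect_bursts <- function(stream, threshold_us = 50, width = 7L) {
  exc <- excitation_window(stream)
  pie <- stream$macrotime_us[stream$channel == "A" & exc == "red"]
  empty <- data.frame(start_us = numeric(0), end_us = numeric(0),
                      n_pie = integer(0))
  if (length(pie) < 2L) return(empty)
  ipd <- smooth_ipd(diff(pie), width = width)
  below <- ipd < threshold_us
  if (!any(below)) return(empty)
  r <- rle(below)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  # IPD run i..j involves photons i..(j+1)
  data.frame(start_us = pie[starts[runs]],
             end_us = pie[ends[runs] + 1L],
             n_pie = ends[runs] + 1L - starts[runs] + 1L)
}

# Background rates (Hz) per channel from inter-burst stretches: the stream
# is cut into chunks, per-chunk rates outside bursts are combined with a
# trimmed mean.
estimate_background <- function(stream, bursts, pad_us = 100,
                                chunk_us = 1e5, trim = 0.2) {
  if (nrow(stream) == 0)
    return(c(D = 0, A = 0))
  total <- max(stream$macrotime_us)
  in_burst <- rep(FALSE, nrow(stream))
  if (nrow(bursts)) {
    # merge padded burst intervals, then locate photons by parity
    s <- bursts$start_us - pad_us
    e <- bursts$end_us + pad_us
    o <- order(s); s <- s[o]; e <- e[o]
    keep_s <- s[1]; keep_e <- e[1]
    for (b in seq_along(s)[-1]) {
      if (s[b] <= keep_e[length(keep_e)]) {
        keep_e[length(keep_e)] <- max(keep_e[length(keep_e)], e[b])
      } else {
        keep_s <- c(keep_s, s[b]); keep_e <- c(keep_e, e[b])
      }
    }
    edges <- as.vector(rbind(keep_s, keep_e))
    in_burst <- findInterval(stream$macrotime_us, edges) %% 2L == 1L
  }
  quiet <- stream[!in_burst, , drop = FALSE]
  burst_time <- if (nrow(bursts))
    sum(pmin(bursts$end_us + pad_us, total) -
          pmax(bursts$start_us - pad_us, 0)) else 0
  quiet_time <- max(total - burst_time, 1)
  rate <- function(ch) {
    tt <- quiet$macrotime_us[quiet$channel == ch]
    if (length(tt) < 10)
      return(length(tt) / quiet_time * 1e6)
    chunk <- floor(tt / chunk_us)
    counts <- tabulate(chunk - min(chunk) + 1L)
    mean(counts, trim = trim) / (chunk_us * (quiet_time / total)) * 1e6
  }
  c(D = rate("D"), A = rate("A"))
}

#' Background- and crosstalk-corrected burst counts
#'
#' `F_D = S_D - BG_D * duration`; `F_A = S_A - BG_A * duration - alpha * F_D`.
#' Negative corrected counts are retained (and flagged by downstream
#' selection), not clipped.
#'
#' @param S_D,S_A Raw burst-integrated counts per channel.
#' @param duration_s Burst duration in seconds.
#' @param cf [correction_factors()] with numeric background rates.
#' @return A list with vectors `F_D` and `F_A`.
#' @export
correct_burst_counts <- function(S_D, S_A, duration_s, cf) {
  stopifnot(inherits(cf, "correction_factors"),
            all(S_D >= 0), all(S_A >= 0))
  F_D <- S_D - cf$bg_rate_D * duration_s
  F_A <- S_A - cf$bg_rate_A * duration_s - cf$alpha * F_D
  list(F_D = F_D, F_A = F_A)
}

#' Burst-wise FRET transfer efficiency
#'
#' `E = F_A / (F_A + gamma * F_D)`.
#'
#' @param F_D,F_A Corrected burst counts.
#' @param gamma Correction factor (default 0.47).
#' @return Efficiencies; `NA` where the denominator vanishes (such bursts
#'   are dropped by the pipeline).
#' @export
efficiency <- function(F_D, F_A, gamma = 0.47) {
  den <- F_A + gamma * F_D
  out <- F_A / den
  out[den == 0] <- NA_real_
  out
}

#' Run the burst selection and correction pipeline on a photon stream
#'
#' Detects bursts on the PIE channel, assigns green-window donor/acceptor
#' photons to bursts by macrotime (closed interval), estimates per-channel
#' background rates from the inter-burst stretches (unless provided),
#' applies the intensity corrections and retains bursts with total corrected
#' intensity `F_D + F_A >= min_total`.
#'
#' @param stream A photon stream.
#' @param cf [correction_factors()].
#' @param threshold_us,width Burst detection settings, see [detect_bursts()].
#' @param min_total Total corrected count threshold `N_T` (default 40).
#' @return An object of class `burst_set`: list with `bursts` (data frame
#'   with raw and corrected counts, efficiency, selection flag), `donor_microtimes`
#'   (list of green-window donor-channel microtimes per burst), `cf` (with
#'   the background rates filled in) and `n_selected`.
#' @export
process_stream <- function(stream, cf = correction_factors(),
                           threshold_us = 50, width = 7L, min_total = 40) {
  bursts <- detect_bursts(stream, threshold_us = threshold_us, width = width)
  if (is.na(cf$bg_rate_D) || is.na(cf$bg_rate_A)) {
    bg <- estimate_background(stream, bursts)
    if (is.na(cf$bg_rate_D)) cf$bg_rate_D <- bg[["D"]]
    if (is.na(cf$bg_rate_A)) cf$bg_rate_A <- bg[["A"]]
  }
  exc <- excitation_window(stream)
  green_d <- stream$channel == "D" & exc == "green"
  green_a <- stream$channel == "A" & exc == "green"
  n <- nrow(bursts)
  # burst membership by macrotime, closed interval; photons are time-ordered
  count_in <- function(times) {
    lo <- findInterval(bursts$start_us, times, left.open = TRUE)
    hi <- findInterval(bursts$end_us, times)
    hi - lo
  }
  t_d <- stream$macrotime_us[green_d]
  m_d <- stream$microtime_ns[green_d]
  t_a <- stream$macrotime_us[green_a]
  S_D <- count_in(t_d)
  S_A <- count_in(t_a)
  lo_d <- findInterval(bursts$start_us, t_d, left.open = TRUE)
  hi_d <- findInterval(bursts$end_us, t_d)
  micro <- lapply(seq_len(n), function(b)
    if (hi_d[b] > lo_d[b]) m_d[(lo_d[b] + 1L):hi_d[b]] else numeric(0))
  dur_s <- (bursts$end_us - bursts$start_us) * 1e-6
  corr <- correct_burst_counts(S_D, S_A, dur_s, cf)
  E <- efficiency(corr$F_D, corr$F_A, cf$gamma)
  selected <- !is.na(E) & (corr$F_D + corr$F_A >= min_total)
  bursts <- cbind(bursts, S_D = S_D, S_A = S_A,
                  F_D = corr$F_D, F_A = corr$F_A, E = E,
                  selected = selected)
  structure(list(bursts = bursts, donor_microtimes = micro, cf = cf,
                 min_total = min_total, n_selected = sum(selected)),
            class = "burst_set")
}

#' @export
print.burst_set <- function(x, ...) {
  cat(sprintf("burst_set: %d bursts detected, %d selected (N_T = %g)\n",
              nrow(x$bursts), x$n_selected, x$min_total))
  if (x$n_selected)
    cat(sprintf("  <E> = %.3f, BG rates D/A = %.0f/%.0f Hz\n",
                mean(x$bursts$E[x$bursts$selected]),
                x$cf$bg_rate_D, x$cf$bg_rate_A))
  invisible(x)
}

#' Shot-noise-limited efficiency variance
#'
#' `sigma_SN^2 = <E> (1 - <E>) / N_T`, the variance of a shot-noise-limited
#' FRET population at the photon threshold `N_T`.
#'
#' @param E_mean Population mean efficiency.
#' @param N_T Total photon threshold per burst (default 40).
#' @return Variance.
#' @export
shot_noise_variance <- function(E_mean, N_T = 40) {
  stopifnot(N_T >= 1)
  E_mean * (1 - E_mean) / N_T
}

#' Fit a Gaussian to a burst efficiency histogram
#'
#' Bins the burst efficiencies over \[-0.1, 1.1\] and fits a Gaussian by
#' least squares. With `shot_noise_limited = TRUE` the variance is fixed to
#' `sigma_SN^2 = <E>(1-<E>)/N_T` and only the mean and amplitude are free.
#'
#' @param efficiencies Burst-wise efficiencies (at least 30).
#' @param N_T Photon threshold used for the shot-noise variance.
#' @param shot_noise_limited Fix the variance to the shot-noise value.
#' @param bin_width Histogram bin width.
#' @return List with `mean_E`, `sd_E`, `sigma_sn2`, `amplitude`,
#'   `shot_noise_limited`, `breaks`, `counts`.
#' @export
fit_efficiency_histogram <- function(efficiencies, N_T = 40,
                                     shot_noise_limited = FALSE,
                                     bin_width = 0.02) {
  e <- efficiencies[!is.na(efficiencies)]
  e <- e[e >= -0.1 & e <= 1.1]
  if (length(e) < 30) stop("need at least 30 bursts to fit the histogram")
  breaks <- seq(-0.1, 1.1 + bin_width, by = bin_width)
  h <- graphics::hist(e, breaks = breaks, plot = FALSE)
  x <- h$mids; y <- h$counts
  m0 <- mean(e); s0 <- max(stats::sd(e), bin_width)
  if (shot_noise_limited) {
    fn <- function(p) {
      s <- sqrt(shot_noise_variance(min(max(p[2], 1e-3), 1 - 1e-3), N_T))
      y - p[1] * exp(-0.5 * ((x - p[2]) / s)^2)
    }
    fit <- minpack.lm::nls.lm(par = c(max(y), m0), fn = fn)
    mean_E <- fit$par[2]
    sd_E <- sqrt(shot_noise_variance(min(max(mean_E, 0), 1), N_T))
  } else {
    fn <- function(p) y - p[1] * exp(-0.5 * ((x - p[2]) / max(p[3], 1e-4))^2)
    fit <- minpack.lm::nls.lm(par = c(max(y), m0, s0), fn = fn)
    mean_E <- fit$par[2]
    sd_E <- abs(fit$par[3])
  }
  list(mean_E = mean_E, sd_E = sd_E,
       sigma_sn2 = shot_noise_variance(min(max(mean_E, 0), 1), N_T),
       amplitude = fit$par[1], shot_noise_limited = shot_noise_limited,
       breaks = breaks, counts = y, n_bursts = length(e))
}

#' Build the donor-only-free filtered lifetime decay
#'
#' Bins the green-window donor-channel microtimes of all selected bursts
#' into a TCSPC histogram (16 ps default binning over the 25 ns green
#' half-cycle). Because burst selection requires PIE-channel (directly
#' excited acceptor) photons, donor-only molecules do not contribute.
#'
#' @param burst_set A [process_stream()] result.
#' @param bin_width Microtime bin width in ns.
#' @return A [tcspc_histogram()].
#' @export
build_filtered_decay <- function(burst_set, bin_width = 0.016) {
  stopifnot(inherits(burst_set, "burst_set"))
  sel <- which(burst_set$bursts$selected)
  if (!length(sel)) stop("no bursts pass selection")
  micro <- unlist(burst_set$donor_microtimes[sel], use.names = FALSE)
  if (!length(micro)) stop("selected bursts contain no donor photons")
  n_bins <- floor(pie_red_start_ns / bin_width)
  bin <- floor(micro / bin_width) + 1L
  bin <- bin[bin >= 1L & bin <= n_bins]
  counts <- tabulate(bin, nbins = n_bins)
  tcspc_histogram(time_grid(bin_width, n_bins, origin = bin_width / 2),
                  counts)
}
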