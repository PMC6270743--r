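#' Configuration of the synthetic PIE photon stream
#'
#' Emulates the data structure of a diffusion-based single-molecule FRET
#' measurement with pulsed interleaved excitation (PIE): a 20 MHz cycle of
#' 50 ns with the donor (green) excitation pulse at 0 ns and the direct
#' acceptor (red) excitation pulse at 25 ns. Molecules transiting the
#' confocal volume appear as bursts — rectangular episodes of elevated count
#' rate (diffusion is not modeled; burst durations are log-normal around
#' 1 ms, sufficient to exercise inter-photon-distance burst selection).
#' Dual-labeled molecules emit donor and acceptor photons in the green
#' window (acceptor via FRET) and acceptor photons in the red (PIE) window;
#' donor-only molecules emit no red-window photons beyond background.
#'
#' Donor photons of dual-labeled molecules carry microtimes drawn from the
#' FRET-quenched decay of the configured Gaussian distance distribution (a
#' distance is drawn per photon — dye motions are fast compared to the
#' inter-photon time), so the filtered decay refits to the configured
#' `(mean_R, sigma_R)`.
#'
#' @param burst_rate Mean burst rate in Hz.
#' @param burst_duration_ms Median burst duration in ms (log-normal,
#'   sdlog 0.4).
#' @param burst_brightness Mean detected photon rate during a burst
#'   (counts/s, green-excitation photons of a dual-labeled molecule).
#' @param pie_brightness_frac Red-window (direct acceptor) photon rate of a
#'   dual-labeled molecule, as a fraction of `burst_brightness`.
#' @param mean_occupancy Average number of molecules in the confocal volume
#'   (metadata echoed to file headers; the burst rate models its effect).
#' @param donor_only_fraction Fraction of molecules lacking an active
#'   acceptor.
#' @param mean_R,sigma_R,R0 Gaussian inter-dye distance distribution
#'   (Angstrom) and Forster radius of the dual-labeled species.
#' @param tau_D,tau_A Donor and acceptor fluorescence lifetimes (ns).
#' @param irf_fwhm Gaussian IRF width (ns) applied to microtimes.
#' @param irf_t0 IRF center relative to the excitation pulse (ns).
#' @param bg_rate_D,bg_rate_A Background count rates per detection channel
#'   (Hz), spread uniformly over both excitation windows.
#' @param crosstalk Probability alpha that a donor photon is registered in
#'   the acceptor channel.
#' @param gamma Correction factor `gamma = gamma' * g` relating detected
#'   count ratios to efficiencies; photons are partitioned so that the
#'   gamma-corrected burst efficiency estimates the species efficiency.
#' @return An object of class `stream_config`.
#' @export
stream_config <- function(burst_rate = 10, burst_duration_ms = 1,
                          burst_brightness = 1e5,
                          pie_brightness_frac = 0.5,
                          mean_occupancy = 0.03,
                          donor_only_fraction = 0,
                          mean_R = 60, sigma_R = 6, R0 = 53.6,
                          tau_D = 4.025, tau_A = 1.053,
                          irf_fwhm = 0.448, irf_t0 = 2,
                          bg_rate_D = 1000, bg_rate_A = 800,
                          crosstalk = 0.0085, gamma = 0.47) {
  stopifnot(burst_rate >= 0, burst_brightness >= 0,
            donor_only_fraction >= 0, donor_only_fraction <= 1,
            bg_rate_D >= 0, bg_rate_A >= 0, crosstalk >= 0, gamma > 0)
  structure(as.list(environment()), class = "stream_config")
}

pie_period_ns <- 50
pie_red_start_ns <- 25

# Species mean transfer efficiency: E_int = <E(R)> over the distance
# distribution (intensity-based definition; equals 1 - F_D/F_D0).
species_efficiency <- function(config) {
  dw <- distance_weights(gaussian_distance(config$mean_R, config$sigma_R))
  sum(dw$w * transfer_efficiency(dw$R, config$R0))
}

# Draw donor microtimes from the FRET-quenched decay: per photon, a distance
# R is drawn with probability proportional to p(R) * (1 - E(R)) (slow-decay
# components are more likely to yield a detected donor photon), then the
# arrival time is exponential with the quenched lifetime.
draw_donor_microtimes <- function(n, config, quenched = TRUE) {
  draw_donor_microtimes_mixed(rep(quenched, n), config)
}

# per-photon quenched flag; vectorized over mixed dual/donor-only photons
draw_donor_microtimes_mixed <- function(quenched, config) {
  n <- length(quenched)
  if (n == 0L) return(numeric(0))
  tau <- rep(config$tau_D, n)
  nq <- sum(quenched)
  if (nq > 0) {
    dw <- distance_weights(gaussian_distance(config$mean_R, config$sigma_R))
    w <- dw$w * (1 - transfer_efficiency(dw$R, config$R0))
    R <- if (length(dw$R) == 1L) rep(dw$R, nq) else
      sample(dw$R, nq, replace = TRUE, prob = w)
    tau[quenched] <- config$tau_D / fret_rate_factor(R, config$R0)
  }
  stats::rexp(n, rate = 1 / tau)
}

irf_jitter <- function(n, config) {
  s <- config$irf_fwhm / (2 * sqrt(2 * log(2)))
  config$irf_t0 + stats::rnorm(n, 0, s)
}

wrap_microtime <- function(t, lo, hi) {
  lo + (t - lo) %% (hi - lo)
}

#' Simulate a PIE two-channel photon stream
#'
#' @param config A [stream_config()].
#' @param duration Acquisition duration in seconds.
#' @param seed Integer seed; identical seed gives an identical stream.
#' @return A `data.frame` of class `photon_stream` with columns
#'   `macrotime_us` (non-decreasing), `microtime_ns` (in \[0, 50)) and
#'   `channel` (`"D"` or `"A"`), plus the config as attribute `"config"`.
#' @export
simulate_stream <- function(config, duration = 10, seed = 1L) {
  stopifnot(inherits(config, "stream_config"), duration > 0)
  with_seed(seed, {
    parts <- list()
    # channel backgrounds: homogeneous Poisson, microtime uniform in cycle
    for (ch in c("D", "A")) {
      rate <- if (ch == "D") config$bg_rate_D else config$bg_rate_A
      n <- stats::rpois(1, rate * duration)
      if (n > 0)
        parts[[length(parts) + 1L]] <- data.frame(
          macrotime_us = stats::runif(n, 0, duration * 1e6),
          microtime_ns = stats::runif(n, 0, pie_period_ns),
          channel = rep(ch, n))
    }
    # bursts (fully vectorized over bursts and photons)
    n_burst <- stats::rpois(1, config$burst_rate * duration)
    E <- species_efficiency(config)
    if (n_burst > 0) {
      starts <- stats::runif(n_burst, 0, duration * 1e6)
      durs <- stats::rlnorm(n_burst, log(config$burst_duration_ms * 1e3), 0.4)
      d_only <- stats::runif(n_burst) < config$donor_only_fraction
      n_green <- stats::rpois(n_burst, config$burst_brightness * durs * 1e-6)
      n_pie <- ifelse(d_only, 0L,
                      stats::rpois(n_burst, config$pie_brightness_frac *
                                     config$burst_brightness * durs * 1e-6))
      # partition green-window photons so that the gamma-corrected count
      # ratio F_A/F_D = gamma * E / (1 - E) in expectation
      p_a <- config$gamma * E / (1 - E + config$gamma * E)
      n_a <- ifelse(d_only, 0L, stats::rbinom(n_burst, n_green, p_a))
      n_d_tot <- n_green - n_a
      # donor crosstalk into the acceptor channel
      n_ct <- stats::rbinom(n_burst, n_d_tot, config$crosstalk)
      n_d <- n_d_tot - n_ct
      expand <- function(counts) {
        idx <- rep.int(seq_len(n_burst), counts)
        starts[idx] + stats::runif(length(idx)) * durs[idx]
      }
      # microtimes wrap at the full 50 ns excitation cycle; decay tails
      # reaching past 25 ns fall into the red (PIE) window and are excluded
      # from green-window analyses rather than folded onto the early bins
      micro_donor <- function(counts, quenched) {
        n <- sum(counts)
        wrap_microtime(draw_donor_microtimes_mixed(
          rep.int(quenched, counts), config) + irf_jitter(n, config),
          0, pie_period_ns)
      }
      quench <- !d_only
      macro_d <- expand(n_d)
      macro_ct <- expand(n_ct)
      micro_d_all <- micro_donor(n_d, quench)
      micro_ct_all <- micro_donor(n_ct, quench)
      macro_a <- expand(n_a)
      micro_a_all <- wrap_microtime(
        stats::rexp(sum(n_a), 1 / config$tau_A) +
          irf_jitter(sum(n_a), config), 0, pie_period_ns)
      macro_p <- expand(n_pie)
      micro_p_all <- wrap_microtime(
        pie_red_start_ns + stats::rexp(sum(n_pie), 1 / config$tau_A) +
          irf_jitter(sum(n_pie), config), 0, pie_period_ns)
      parts[[length(parts) + 1L]] <- data.frame(
        macrotime_us = c(macro_d, macro_ct, macro_a, macro_p),
        microtime_ns = c(micro_d_all, micro_ct_all, micro_a_all,
                         micro_p_all),
        channel = c(rep("D", length(macro_d)),
                    rep("A", length(macro_ct) + length(macro_a) +
                          length(macro_p))))
    }
    stream <- if (length(parts)) do.call(rbind, parts) else
      data.frame(macrotime_us = numeric(0), microtime_ns = numeric(0),
                 channel = character(0))
    stream <- stream[order(stream$macrotime_us), , drop = FALSE]
    rownames(stream) <- NULL
    attr(stream, "config") <- config
    class(stream) <- c("photon_stream", class(stream))
    stream
  })
}

#' Excitation window of photons
#'
#' @param stream A photon stream data frame.
#' @return Factor `"green"`/`"red"` derived from the microtime (green pulse
#'   at 0 ns, red PIE pulse at 25 ns of the 50 ns cycle).
#' @export
excitation_window <- function(stream) {
  factor(ifelse(stream$microtime_ns < pie_red_start_ns, "green", "red"),
         levels = c("green", "red"))
}

#' Write a photon stream as delimited text
#'
#' Tab-separated columns `macrotime_us`, `microtime_ns`, `channel` with `#`
#' header lines echoing the stream configuration.
#'
#' @param stream A photon stream.
#' @param path Output path.
#' @export
write_stream <- function(stream, path) {
  con <- file(path, "w")
  on.exit(close(con))
  cfg <- attr(stream, "config")
  writeLines("# fretdist photon stream", con)
  if (!is.null(cfg)) {
    for (k in names(cfg))
      if (is.numeric(cfg[[k]]) && length(cfg[[k]]) == 1)
        writeLines(sprintf("# config %s = %.8g", k, cfg[[k]]), con)
  }
  writeLines("# columns: macrotime_us microtime_ns channel", con)
  writeLines(sprintf("%.6f\t%.6f\t%s", stream$macrotime_us,
                     stream$microtime_ns, stream$channel), con)
  invisible(path)
}

#' Read a photon stream written by [write_stream()]
#'
#' Validates monotone non-decreasing macrotimes and the channel enumeration.
#'
#' @param path Input path.
#' @return A photon stream data frame.
#' @export
read_stream <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  rows <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0) {
    out <- data.frame(macrotime_us = numeric(0), microtime_ns = numeric(0),
                      channel = character(0))
    class(out) <- c("photon_stream", class(out))
    return(out)
  }
  parts <- strsplit(trimws(lines), "[,[:space:]]+")
  bad <- which(vapply(parts, length, integer(1)) < 3L)
  if (length(bad))
    stop("malformed photon record at line ", rows[bad[1]], " of ", path)
  macro <- as.numeric(vapply(parts, `[[`, "", 1))
  micro <- as.numeric(vapply(parts, `[[`, "", 2))
  ch <- vapply(parts, `[[`, "", 3)
  bad <- which(is.na(macro) | is.na(micro))
  if (length(bad))
    stop("malformed photon record at line ", rows[bad[1]], " of ", path)
  if (any(diff(macro) < 0))
    stop("macrotimes must be monotone non-decreasing in ", path)
  if (!all(ch %in% c("D", "A")))
    stop("channel must be 'D' or 'A' in ", path)
  if (any(micro < 0 | micro >= pie_period_ns))
    stop("microtimes must lie in [0, 50) ns in ", path)
  out <- data.frame(macrotime_us = macro, microtime_ns = micro, channel = ch)
  class(out) <- c("photon_stream", class(out))
  out
}
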