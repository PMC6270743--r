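test_that("moving-average smoother has box-filter behavior", {
  expect_equal(smooth_ipd(rep(3, 20)), rep(3, 20))
  x <- numeric(21); x[11] <- 70
  sm <- smooth_ipd(x, 7)
  expect_equal(sm[8:14], rep(10, 7))
  expect_equal(sm[1:7], rep(0, 7))
  expect_identical(smooth_ipd(c(1, 5, 2), 1), c(1, 5, 2))
  # edges use the available shorter window
  expect_equal(smooth_ipd(c(1, 2, 3), 3)[1], 1.5)
  expect_error(smooth_ipd(1:5, 4), "odd")
})

test_that("burst detection finds injected bursts and little else", {
  # hand-built PIE photon stream: sparse background + one dense burst
  bg <- seq(0, 1e6, by = 5000)
  burst <- seq(5e5, 5e5 + 500, by = 5)
  stream <- data.frame(
    macrotime_us = sort(c(bg, burst)),
    microtime_ns = 30, channel = "A")
  bursts <- detect_bursts(stream)
  expect_equal(nrow(bursts), 1)
  expect_lt(abs(bursts$start_us - 5e5), 7 * 5000)
  expect_lt(abs(bursts$end_us - (5e5 + 500)), 7 * 5000)

  # pure Poisson background at mean IPD 500 us: (almost) no bursts
  n_fp <- vapply(1:3, function(s) {
    set.seed(s)
    tt <- cumsum(rexp(20000, 1 / 500))
    st <- data.frame(macrotime_us = tt, microtime_ns = 30, channel = "A")
    nrow(detect_bursts(st))
  }, numeric(1))
  expect_lt(mean(n_fp) / 10, 1)  # < 1 false positive per 10 s

  expect_equal(nrow(detect_bursts(stream[0, ])), 0)
  expect_equal(nrow(detect_bursts(stream[1, , drop = FALSE])), 0)
})

test_that("intensity corrections follow the background/crosstalk formulas", {
  cf <- correction_factors(bg_rate_D = 10, bg_rate_A = 5, alpha = 0.0085)
  out <- correct_burst_counts(100, 100, 1, cf)
  expect_equal(out$F_D, 90)
  expect_equal(out$F_A, 100 - 5 - 0.0085 * 90)
  expect_equal(out$F_A, 94.235)
  cf0 <- correction_factors(alpha = 1e-12, bg_rate_D = 0, bg_rate_A = 0)
  out0 <- correct_burst_counts(50, 30, 1, cf0)
  expect_equal(out0$F_D, 50)
  expect_equal(out0$F_A, 30, tolerance = 1e-9)
  expect_error(correction_factors(gamma_prime = 0.5, g = 1.3, gamma = 0.47),
               "gamma")
})

test_that("efficiency has its fixed points", {
  expect_equal(efficiency(0, 80), 1)
  expect_equal(efficiency(80, 0), 0)
  expect_equal(efficiency(50, 50, gamma = 0.47), 50 / 73.5)
  expect_true(is.na(efficiency(0, 0)))
})

test_that("shot-noise variance follows the closed form", {
  expect_equal(shot_noise_variance(0.5, 40), 0.00625)
  expect_equal(shot_noise_variance(0, 40), 0)
  expect_equal(shot_noise_variance(1, 40), 0)
})

test_that("efficiency histogram of a single species is shot-noise limited", {
  # mean_R chosen so that the species efficiency is ~0.55
  cfg <- stream_config(burst_rate = 25, mean_R = 51.5, sigma_R = 1,
                       donor_only_fraction = 0)
  s <- simulate_stream(cfg, duration = 20, seed = 31)
  bs <- process_stream(s)
  expect_gt(bs$n_selected, 100)
  e_true <- fretdist:::species_efficiency(cfg)
  eh <- fit_efficiency_histogram(bs$bursts$E[bs$bursts$selected], N_T = 40)
  expect_lt(abs(eh$mean_E - e_true), 0.02)
  sn_sd <- sqrt(shot_noise_variance(eh$mean_E, 40))
  expect_lt(abs(eh$sd_E - sn_sd) / sn_sd, 0.3)
  ehs <- fit_efficiency_histogram(bs$bursts$E[bs$bursts$selected], N_T = 40,
                                  shot_noise_limited = TRUE)
  expect_lt(abs(ehs$mean_E - e_true), 0.02)
  expect_equal(ehs$sd_E^2, shot_noise_variance(ehs$mean_E, 40))
  expect_error(fit_efficiency_histogram(runif(10)), "at least 30")
})

test_that("filtering is a no-op without donor-only molecules", {
  cfg <- stream_config(burst_rate = 25, donor_only_fraction = 0,
                       bg_rate_D = 200, bg_rate_A = 200)
  s <- simulate_stream(cfg, duration = 15, seed = 17)
  bs <- process_stream(s)
  filtered <- build_filtered_decay(bs, bin_width = 0.5)
  # unfiltered: all green donor microtimes inside any detected burst
  exc <- excitation_window(s)
  keep <- s$channel == "D" & exc == "green"
  inb <- rep(FALSE, nrow(s))
  for (b in seq_len(nrow(bs$bursts)))
    inb <- inb | (s$macrotime_us >= bs$bursts$start_us[b] &
                    s$macrotime_us <= bs$bursts$end_us[b])
  micro <- s$microtime_ns[keep & inb]
  unfiltered <- tabulate(floor(micro / 0.5) + 1L, nbins = 50)
  f <- filtered$counts
  # bin-wise agreement within Poisson noise
  z <- (f - unfiltered) / sqrt(pmax(unfiltered, 1))
  expect_lt(mean(abs(z)), 1)

  empty_bs <- bs
  empty_bs$bursts$selected <- FALSE
  expect_error(build_filtered_decay(empty_bs), "no bursts")
})
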