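test_that("multi-exponential decay matches scalar evaluation", {
  g2 <- time_grid(bin_width = 4.025, n_bins = 2)
  h <- evaluate_multiexponential(exp_components(1, 4.025), I0 = 1, grid = g2)
  expect_equal(h$counts[1], 1.0)
  expect_equal(h$counts[2], exp(-1), tolerance = 1e-12)

  # donor-only dsDNA (10 bp) photophysics at t = 2 ns
  comp <- exp_components(c(0.94, 0.06), c(4.06, 1.38))
  g <- time_grid(bin_width = 2, n_bins = 2)
  h <- evaluate_multiexponential(comp, I0 = 1, grid = g)
  oracle <- 0.94 * exp(-2 / 4.06) + 0.06 * exp(-2 / 1.38)
  expect_equal(h$counts[2], oracle, tolerance = 1e-12)

  expect_error(exp_components(1, -1), "lifetimes")
  expect_error(exp_components(c(0.5, 0.4), c(1, 2)), "sum to 1")
})

test_that("transfer efficiency has the right fixed points and limits", {
  expect_equal(transfer_efficiency(53.6, 53.6), 0.5)
  expect_lt(transfer_efficiency(1e5, 53.6), 1e-12)
  expect_equal(transfer_efficiency(1e-3, 53.6), 1, tolerance = 1e-9)
  expect_equal(transfer_efficiency(62.7, 53.6),
               1 / (1 + (62.7 / 53.6)^6), tolerance = 1e-12)
  expect_equal(round(transfer_efficiency(62.7, 53.6), 3), 0.281)
  expect_error(transfer_efficiency(-1, 53.6))
  expect_equal(fret_rate_factor(53.6, 53.6), 2)
})

test_that("Gaussian distance weights are normalized with the right shape", {
  dist <- gaussian_distance(60, 6)
  expect_equal(gaussian_distance_pdf(dist, 60), 1 / (sqrt(2 * pi) * 6),
               tolerance = 1e-12)
  dw <- distance_weights(dist)
  expect_equal(sum(dw$w), 1, tolerance = 1e-12)
  expect_equal(dw$R[1], 60 - 24)
  expect_equal(dw$R[length(dw$R)], 60 + 24)
  i54 <- which(abs(dw$R - 54) < 1e-9)
  i60 <- which(abs(dw$R - 60) < 1e-9)
  expect_equal(dw$w[i54] / dw$w[i60], exp(-0.5), tolerance = 1e-12)
  # lower clip
  dw_lo <- distance_weights(gaussian_distance(3, 2), min_R = 1)
  expect_gte(min(dw_lo$R), 1)
  expect_equal(sum(dw_lo$w), 1, tolerance = 1e-12)
  expect_error(distance_weights(gaussian_distance(0.2, 0.05)), "below")
})

test_that("FRET-quenched decay agrees with fine-grid quadrature", {
  grid <- time_grid(0.1, 400L)
  p <- std_truth(mean_R = 60, sigma_R = 6)
  fda <- fret_quenched_decay(p, grid)
  # independent oracle: 0.01 A steps over +/- 8 sigma
  R <- seq(60 - 48, 60 + 48, by = 0.01)
  w <- dnorm(R, 60, 6); w <- w / sum(w)
  t <- grid_times(grid)
  oracle <- vapply(t, function(tt)
    sum(w * exp(-(tt / 4.025) * (1 + (53.6 / R)^6))), numeric(1))
  expect_lt(max(abs(fda$counts - oracle) / oracle), 1e-3)
})

test_that("sigma -> 0 limit reduces to the single-distance decay", {
  grid <- time_grid(0.1, 400L)
  p0 <- std_truth(mean_R = 53.6, sigma_R = 0)
  f0 <- fret_quenched_decay(p0, grid)
  # E = 0.5 at R = R0: decay rate doubles
  expect_equal(f0$counts, exp(-2 * grid_times(grid) / 4.025),
               tolerance = 1e-12)
  p_eps <- std_truth(mean_R = 53.6, sigma_R = 0.01)
  f_eps <- fret_quenched_decay(p_eps, grid)
  expect_lt(max(abs(f_eps$counts - f0$counts) / f0$counts), 1e-4)
})

test_that("quenched decay is monotone in the mean distance", {
  grid <- time_grid(0.5, 40L)
  means <- seq(35, 75, by = 5)
  curves <- sapply(means, function(m)
    fret_quenched_decay(std_truth(mean_R = m, sigma_R = 6), grid)$counts)
  for (j in seq_len(ncol(curves) - 1))
    expect_true(all(curves[-1, j + 1] > curves[-1, j]))
})

test_that("total donor model combines mixture and background correctly", {
  grid <- std_grid(500L)
  p <- std_truth(x_D0 = 1, I0 = 1e4, BG = 20)
  m <- total_donor_model(p, grid)
  d0 <- evaluate_multiexponential(p$donor_components, 1e4, grid)
  expect_equal(m$counts, d0$counts + 20, tolerance = 1e-12)

  p0 <- std_truth(x_D0 = 0, BG = 0)
  m0 <- total_donor_model(p0, grid)
  expect_equal(m0$counts, 1e4 * fret_quenched_decay(p0, grid)$counts,
               tolerance = 1e-12)

  # value at t = 0: both mixture components are 1 there
  m37 <- total_donor_model(std_truth(), grid)
  expect_equal(m37$counts[1], 10020)
})

test_that("IRF convolution preserves identity, mass and tail slope", {
  grid <- std_grid(3125L)
  p <- std_truth(x_D0 = 0, BG = 0, I0 = 1)
  model <- total_donor_model(p, grid)
  expect_identical(convolve_with_irf(model, delta_irf(grid))$counts,
                   model$counts)
  irf <- gaussian_irf(grid, fwhm = 0.544, t0 = 3)
  conv <- convolve_with_irf(model, irf)
  expect_equal(sum(conv$counts), sum(model$counts), tolerance = 1e-6)
  # 4 ns single-exponential: log-slope of the tail unchanged within 1%
  mono <- evaluate_multiexponential(exp_components(1, 4), 1, grid)
  conv4 <- convolve_with_irf(mono, irf)
  t <- grid_times(grid)
  sel <- t > 6 & t < 30
  slope_in <- coef(lm(log(mono$counts[sel]) ~ t[sel]))[2]
  slope_out <- coef(lm(log(conv4$counts[sel]) ~ t[sel]))[2]
  expect_equal(unname(slope_out / slope_in), 1, tolerance = 0.01)
  expect_error(convolve_with_irf(model, delta_irf(time_grid(0.016, 100L))),
               "grid")
})

test_that("amplitude-averaged lifetime scales reference quantum yields", {
  d17 <- amplitude_averaged_lifetime_qy(
    exp_components(c(0.91, 0.09), c(4.09, 1.52)), 4.025, 0.92)
  expect_equal(d17$tau_avg, 0.91 * 4.09 + 0.09 * 1.52)
  expect_equal(round(d17$qy, 2), 0.88)
  a0 <- amplitude_averaged_lifetime_qy(
    exp_components(c(0.28, 0.72), c(1.38, 0.88)), 1.053, 0.33)
  expect_equal(a0$tau_avg, 1.0200, tolerance = 1e-9)
  expect_equal(round(a0$qy, 2), 0.32)
  one <- amplitude_averaged_lifetime_qy(exp_components(1, 2.5), 2.5, 0.9)
  expect_equal(one$tau_avg, 2.5)
})

test_that("TCSPC histogram text round trip preserves data", {
  grid <- time_grid(0.016, 50L)
  h <- tcspc_histogram(grid, rpois(50, 100))
  path <- withr::local_tempfile(fileext = ".txt")
  write_tcspc(h, path, comment = "round trip")
  h2 <- read_tcspc(path)
  expect_equal(h2$counts, h$counts)
  expect_equal(h2$grid$bin_width, 0.016, tolerance = 1e-9)
  irf <- gaussian_irf(grid, 0.1, t0 = 0.2)
  write_tcspc(irf, path)
  irf2 <- read_tcspc(path, as = "irf")
  expect_equal(irf2$values, irf$values, tolerance = 1e-7)
})
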