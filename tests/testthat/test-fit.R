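test_that("reduced chi-square has its closed forms", {
  grid <- std_grid(600L)
  model <- total_donor_model(std_truth(), grid)
  expect_equal(reduced_chi2(model, model, 3), 0)
  data <- tcspc_histogram(grid, model$counts + 1)
  idx <- fretdist:::window_indices(data, fit_window())
  d <- data$counts[idx]
  expected <- sum(1 / d) / (length(idx) - 3)
  expect_equal(reduced_chi2(data, model, 3), expected, tolerance = 1e-12)
  expect_error(reduced_chi2(data, model, length(idx)), "degrees of freedom")
})

test_that("F-statistic threshold matches the chi-square limit at large nu", {
  # independent oracle: k * F(k, nu) -> chisq_k quantile as nu -> Inf
  thr <- f_chi_threshold(3, 1e6, P = 0.32)
  expect_equal((thr - 1) * 1e6, qchisq(0.68, df = 3), tolerance = 1e-3)
  expect_gt(f_chi_threshold(3, 100, 0.05), f_chi_threshold(3, 100, 0.32))
})

test_that("noiseless decays are recovered to numerical precision", {
  grid <- std_grid()
  truth <- std_truth(mean_R = 60, sigma_R = 6, x_D0 = 0.2)
  noiseless <- total_donor_model(truth, grid)
  start <- std_truth(mean_R = 53, sigma_R = 8, x_D0 = 0.18)
  fit <- fit_decay(noiseless, NULL, start, fixed = c("I0", "BG"))
  expect_true(fit$converged)
  expect_equal(fit$estimates[["mean_R"]], 60, tolerance = 1e-3)
  expect_equal(fit$estimates[["sigma_R"]], 6, tolerance = 1e-3)
  expect_equal(fit$estimates[["x_D0"]], 0.2, tolerance = 1e-3)
})

test_that("fit is invariant to uniform scaling of data and I0", {
  grid <- std_grid(1500L)
  truth <- std_truth(x_D0 = 0.1, BG = 0)
  m1 <- total_donor_model(truth, grid)
  m10 <- tcspc_histogram(grid, m1$counts * 10)
  start1 <- std_truth(mean_R = 55, sigma_R = 7, x_D0 = 0.09, BG = 1e-9)
  start10 <- std_truth(mean_R = 55, sigma_R = 7, x_D0 = 0.09, I0 = 1e5,
                       BG = 1e-9)
  f1 <- fit_decay(m1, NULL, start1, fixed = c("I0", "BG"))
  f10 <- fit_decay(m10, NULL, start10, fixed = c("I0", "BG"))
  expect_equal(f1$estimates[["mean_R"]], f10$estimates[["mean_R"]],
               tolerance = 1e-4)
  expect_equal(f1$estimates[["sigma_R"]], f10$estimates[["sigma_R"]],
               tolerance = 1e-4)
})

test_that("fixing a redundant donor-only fraction does not move the optimum", {
  grid <- std_grid()
  truth <- std_truth(x_D0 = 0)
  # noiseless: both routes land on the exact optimum
  nl <- total_donor_model(truth, grid)
  start <- std_truth(mean_R = 55, sigma_R = 7, x_D0 = 0.05)
  free_nl <- fit_decay(nl, NULL, start, fixed = c("I0", "BG"))
  fixed_nl <- fit_decay(nl, NULL, std_truth(mean_R = 55, sigma_R = 7,
                                            x_D0 = 0),
                        fixed = c("I0", "BG", "x_D0"))
  expect_equal(free_nl$estimates[["mean_R"]], fixed_nl$estimates[["mean_R"]],
               tolerance = 1e-4)
  expect_equal(free_nl$estimates[["sigma_R"]],
               fixed_nl$estimates[["sigma_R"]], tolerance = 1e-4)
  # noisy: estimates agree within the free fit's confidence width
  decay <- generate_synthetic_decay(truth, grid, seed = 42)
  free_fit <- fit_decay(decay, NULL, start, fixed = c("I0", "BG"),
                        ci = c("mean_R", "sigma_R"))
  fixed_fit <- fit_decay(decay, NULL, std_truth(mean_R = 55, sigma_R = 7,
                                                x_D0 = 0),
                         fixed = c("I0", "BG", "x_D0"))
  expect_lt(abs(fixed_fit$estimates[["mean_R"]] -
                  free_fit$estimates[["mean_R"]]),
            diff(free_fit$ci["mean_R", ]))
  expect_lt(abs(fixed_fit$estimates[["sigma_R"]] -
                  free_fit$estimates[["sigma_R"]]),
            diff(free_fit$ci["sigma_R", ]))
})

test_that("fits from the truth and from perturbed starts agree within CI", {
  grid <- std_grid()
  truth <- std_truth(x_D0 = 0.2)
  decay <- generate_synthetic_decay(truth, grid, seed = 7)
  from_truth <- fit_decay(decay, NULL, truth, fixed = c("I0", "BG"))
  from_far <- fit_decay(decay, NULL, std_truth(mean_R = 53, sigma_R = 8,
                                               x_D0 = 0.18),
                        fixed = c("I0", "BG"), ci = "mean_R")
  expect_lt(abs(from_truth$estimates[["mean_R"]] -
                  from_far$estimates[["mean_R"]]),
            diff(from_far$ci["mean_R", ]) / 2 + 1e-3)
  expect_equal(from_truth$estimates[["sigma_R"]],
               from_far$estimates[["sigma_R"]], tolerance = 1e-3)
})

test_that("degenerate inputs are rejected", {
  grid <- std_grid(100L)
  zeros <- tcspc_histogram(grid, rep(0, 100))
  expect_error(fit_decay(zeros, NULL, std_truth()), "degenerate")
})

test_that("support-plane intervals bracket the estimate and respect P", {
  grid <- std_grid()
  truth <- std_truth(x_D0 = 0.1)
  decay <- generate_synthetic_decay(truth, grid, seed = 3)
  fit <- fit_decay(decay, NULL, std_truth(mean_R = 55, sigma_R = 7,
                                          x_D0 = 0.09),
                   fixed = c("I0", "BG"))
  ci32 <- support_plane_interval(fit, "mean_R", P = 0.32)
  ci05 <- support_plane_interval(fit, "mean_R", P = 0.05)
  est <- fit$estimates[["mean_R"]]
  expect_lt(ci32[1], est); expect_gt(ci32[2], est)
  # higher confidence level (smaller P) widens the interval
  expect_lte(ci05[1], ci32[1]); expect_gte(ci05[2], ci32[2])

  # noiseless data: interval collapses toward the estimate
  noiseless <- total_donor_model(truth, grid)
  nl_fit <- fit_decay(noiseless, NULL, truth, fixed = c("I0", "BG"))
  nl_ci <- support_plane_interval(nl_fit, "mean_R",
                                  initial_step = 0.05)
  expect_lt(diff(nl_ci), 0.15)
})

test_that("one-sided interval is reported at the x_D0 = 0 bound", {
  grid <- std_grid()
  decay <- generate_synthetic_decay(std_truth(x_D0 = 0), grid, seed = 5)
  fit <- fit_decay(decay, NULL, std_truth(mean_R = 58, sigma_R = 7,
                                          x_D0 = 0.02),
                   fixed = c("I0", "BG"))
  ci <- support_plane_interval(fit, "x_D0")
  expect_gte(ci[1], 0)
  expect_lte(ci[1], fit$estimates[["x_D0"]] + 1e-9)
})

test_that("confidence surfaces are centered, nested and shrink with x_D0", {
  grid <- std_grid()
  mk_fit <- function(xd0, seed) {
    decay <- generate_synthetic_decay(std_truth(x_D0 = xd0), grid,
                                      seed = seed)
    fit_decay(decay, NULL, std_truth(mean_R = 55, sigma_R = 7,
                                     x_D0 = 0.9 * xd0 + 0.01),
              fixed = c("I0", "BG"))
  }
  fit_hi <- mk_fit(0.5, 21)
  # grid at the scale of the (correlated) minimum: the axis-aligned section
  # with I0, BG and the other two parameters fixed is much narrower than
  # the support-plane intervals
  hw <- c(sigma_R = 0.5, mean_R = 0.4, x_D0 = 0.025)
  surf <- confidence_surface(fit_hi, half_widths = hw, n_points = 11)
  center <- (dim(surf$ratio) + 1) / 2
  expect_equal(surf$ratio[center[1], center[2], center[3]], 1,
               tolerance = 1e-6)
  expect_true(surf$inside[center[1], center[2], center[3]])
  surf05 <- confidence_surface(fit_hi, half_widths = hw, n_points = 11,
                               P = 0.05)
  expect_true(all(surf05$inside[surf$inside]))  # nested masks
  fit_lo <- mk_fit(0.2, 21)
  surf_lo <- confidence_surface(fit_lo, half_widths = hw, n_points = 11)
  expect_lt(sum(surf_lo$inside), sum(surf$inside))
})
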