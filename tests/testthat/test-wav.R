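small_geom <- function(L = 6, w = 4.5, r = 1.5)
  dye_geometry(L_link = L, w_link = w, R_dye_1 = 2, R_dye_2 = 1.8,
               R_dye_3 = r)

test_that("obstacle grid marks linker-blocked cells by surface distance", {
  g0 <- build_obstacle_grid(empty_structure(), small_geom(), c(0, 0, 0),
                            spacing = 0.8)
  expect_false(any(g0$blocked))
  one <- atoms_structure(6, 0, 0, radius = 2)
  g1 <- build_obstacle_grid(one, small_geom(), c(0, 0, 0), spacing = 0.8,
                            exclude_radius = 0)
  centers <- fretdist:::cell_centers(g1, seq_along(g1$blocked))
  d <- sqrt((centers[, 1] - 6)^2 + centers[, 2]^2 + centers[, 3]^2)
  inside <- d < 2 + 4.5 / 2 - 1e-9
  seed_zone <- d > 1e9  # none; seed channel is at the attachment
  d_att <- sqrt(rowSums(centers^2))
  expect_true(all(g1$blocked[inside & d_att > 2]))
  expect_false(any(g1$blocked[!inside]))
  # blocked volume grows with the linker width
  g2 <- build_obstacle_grid(one, small_geom(w = 6), c(0, 0, 0),
                            spacing = 0.8, exclude_radius = 0)
  expect_gt(sum(g2$blocked), sum(g1$blocked))
})

test_that("free-space AV reproduces the analytic sphere volume", {
  av <- compute_av(build_obstacle_grid(empty_structure(), small_geom(L = 10),
                                       c(0, 0, 0), spacing = 0.8))
  vol <- av$M * 0.8^3
  ref <- 4 / 3 * pi * 10^3
  expect_lt(abs(vol - ref) / ref, 0.05)
  expect_equal(sum(av$weights), 1, tolerance = 1e-12)
  expect_true(all(av$path_dist <= 10 + 1e-9))
})

test_that("a plane wall halves the accessible volume", {
  L <- 10
  # wall of atoms whose blocking boundary (r + w/2) sits at z = -0.4,
  # i.e. midway between the z = -0.8 and z = 0 cell layers
  xy <- expand.grid(x = seq(-14, 14, 0.8), y = seq(-14, 14, 0.8))
  r <- 1.5
  z_wall <- -0.4 - r - 4.5 / 2
  wall <- atoms_structure(xy$x, xy$y, rep(z_wall, nrow(xy)), radius = r)
  avw <- compute_av(build_obstacle_grid(wall, small_geom(L = L), c(0, 0, 0),
                                        spacing = 0.8, exclude_radius = 0,
                                        seed_radius = 0.5))
  av0 <- compute_av(build_obstacle_grid(empty_structure(), small_geom(L = L),
                                        c(0, 0, 0), spacing = 0.8))
  expect_lt(abs(avw$M / av0$M - 0.5), 0.05)
})

test_that("pockets behind obstacles respect the path-length criterion", {
  # C-shaped pocket: a disc wall between the attachment and a target point;
  # the target is within Euclidean reach but not within path-length reach
  disc <- expand.grid(y = seq(-8, 8, 0.7), z = seq(-8, 8, 0.7))
  disc <- disc[sqrt(disc$y^2 + disc$z^2) <= 8, ]
  wall <- atoms_structure(rep(4.5, nrow(disc)), disc$y, disc$z, radius = 0.5)
  geom <- small_geom(L = 8, w = 2, r = 0.4)
  av <- compute_av(build_obstacle_grid(wall, geom, c(0, 0, 0), spacing = 0.8,
                                       exclude_radius = 0))
  pts <- av$points
  # (7,0,0) is 7 A away euclidean, but any free path around the disc is > 8 A
  behind <- abs(pts[, 1] - 7) < 0.5 & abs(pts[, 2]) < 0.5 & abs(pts[, 3]) < 0.5
  expect_false(any(behind))
  infront <- abs(pts[, 1] + 7) < 0.5 & abs(pts[, 2]) < 0.5 & abs(pts[, 3]) < 0.5
  expect_true(any(infront))
})

test_that("sigma_av follows the ideal-chain closed form", {
  expect_equal(sigma_av(3, 3), sqrt(3), tolerance = 1e-12)
  expect_equal(sigma_av(3.6, 19.3), sqrt(3.6 * 19.3 / 3), tolerance = 1e-12)
  expect_equal(round(sigma_av(3.6, 19.3), 2), 4.81)
  expect_equal(sigma_av(2, 12, scaling = "rigid"), 2 * sqrt(4))
  b <- seq(0.5, 10, by = 0.5)
  expect_true(all(diff(sigma_av(b, 19.3)) > 0))
  expect_true(all(diff(vapply(b, function(x) sigma_av(1, x * 3), 1)) > 0))
})

test_that("Gaussian AV weighting normalizes and limits correctly", {
  set.seed(1)
  av <- make_av(matrix(rnorm(300, sd = 4), ncol = 3))
  w <- weight_av(av, sigma = 5)
  expect_equal(sum(w$weights), 1, tolerance = 1e-12)
  flat <- weight_av(av, sigma = 1e6)
  expect_true(all(abs(flat$weights - 1 / av$M) < 1e-6))
  # ratio between a point at distance sigma and one at the attachment
  av2 <- make_av(rbind(c(0, 0, 0), c(5, 0, 0)))
  w2 <- weight_av(av2, sigma = 5)
  expect_equal(w2$weights[2] / w2$weights[1], exp(-0.5), tolerance = 1e-12)
})

test_that("pair statistics: exact double sum and sampled estimate agree", {
  d <- make_av(rbind(c(0, 0, 0)))
  a <- make_av(rbind(c(50, 0, 0)))
  res <- interdye_distribution(d, a)
  expect_equal(res$mean_R, 50)
  expect_equal(res$sigma_R, 0)
  expect_identical(res$method, "exact")

  set.seed(2)
  d50 <- make_av(matrix(rnorm(150, sd = 3), ncol = 3))
  a50 <- make_av(matrix(rnorm(150, mean = 15, sd = 3), ncol = 3))
  exact <- interdye_distribution(d50, a50)
  sampled <- interdye_distribution(d50, a50, n_pairs = 2e5, max_exact = 0,
                                   seed = 3)
  expect_identical(sampled$method, "sampled")
  expect_lt(abs(sampled$mean_R - exact$mean_R), 3 * sampled$se_mean)
  expect_lt(abs(sampled$sigma_R - exact$sigma_R) / exact$sigma_R, 0.05)

  # Gaussian weighting concentrates the clouds: wAV width below AV width
  wd <- weight_av(d50, 2); wa <- weight_av(a50, 2)
  expect_lt(interdye_distribution(wd, wa)$sigma_R, exact$sigma_R)
})

test_that("effective bond length calibration inverts the width curve", {
  set.seed(4)
  d <- make_av(matrix(rnorm(900, sd = 5), ncol = 3))
  a <- make_av(matrix(rnorm(900, mean = 12, sd = 5), ncol = 3),
               attachment = c(12, 0, 0))
  L_d <- 19.3; L_a <- 24.6
  widths <- vapply(c(1, 2, 4, 8, 16), function(b)
    interdye_distribution(weight_av(d, sigma_av(b, L_d)),
                          weight_av(a, sigma_av(b, L_a)))$sigma_R,
    numeric(1))
  expect_true(all(diff(widths) > 0))  # monotone in b_eff
  target <- interdye_distribution(weight_av(d, sigma_av(2, L_d)),
                                  weight_av(a, sigma_av(2, L_a)))$sigma_R
  b_hat <- calibrate_beff(d, a, L_d, L_a, target_sigma = target)
  expect_equal(b_hat, 2, tolerance = 0.05)
  # a target at the uniform-AV width is matched by the upper bound
  unif <- interdye_distribution(d, a)$sigma_R
  expect_equal(calibrate_beff(d, a, L_d, L_a, target_sigma = unif,
                              range = c(0.3, 3000)), 3000)
  expect_error(calibrate_beff(d, a, L_d, L_a, target_sigma = 0.01),
               "not bracketed")
})

test_that("distance results are frame independent", {
  seqs <- dsdna_sequences()
  dna <- build_bdna(substr(seqs$donor_17bp, 1, 14),
                    substr(seqs$acceptor, 35, 48))
  sites <- suppressWarnings(  # fixture sites need not be thymines
    attachment_sites(dna, list(list(strand = "top", residue = 3),
                               list(strand = "top", residue = 12))))
  geom <- small_geom(L = 8)
  run <- function(dna, s1, s2) {
    avd <- compute_av(build_obstacle_grid(dna, geom, s1, spacing = 0.8))
    ava <- compute_av(build_obstacle_grid(dna, geom, s2, spacing = 0.8))
    interdye_distribution(avd, ava, seed = 5)
  }
  base <- run(dna, sites[[1]], sites[[2]])
  rot <- random_rotation(6); shift <- c(13.2, -7.7, 4.1)
  dna_t <- transform_structure(dna, rot, shift)
  s1 <- transform_site(sites[[1]], rot, shift)
  s2 <- transform_site(sites[[2]], rot, shift)
  moved <- run(dna_t, s1, s2)
  expect_lt(abs(moved$mean_R - base$mean_R), 0.8)
  expect_lt(abs(moved$sigma_R - base$sigma_R), 0.8)
})
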