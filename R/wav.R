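#' Dye-linker construct geometry
#'
#' Coarse-grained dye-linker dimensions: the linker is a flexible tube of
#' length `L_link` (labeled atom to dye center, extended conformation) and
#' width `w_link`; the dye an ellipsoid with semiaxes `R_dye_1..3`.
#' Defaults for the two constructs used with the dsDNA standards are
#' available via [dye_geometry_table()].
#'
#' @param L_link Linker contour length (Angstrom).
#' @param w_link Linker tube width (Angstrom).
#' @param R_dye_1,R_dye_2,R_dye_3 Dye ellipsoid semiaxes (Angstrom).
#' @return An object of class `dye_geometry`.
#' @export
dye_geometry <- function(L_link, w_link = 4.5, R_dye_1 = 5, R_dye_2 = 4.5,
                         R_dye_3 = 1.5) {
  vals <- c(L_link, w_link, R_dye_1, R_dye_2, R_dye_3)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all dye geometry parameters must be positive")
  structure(list(L_link = L_link, w_link = w_link,
                 R_dye = c(R_dye_1, R_dye_2, R_dye_3)),
            class = "dye_geometry")
}

#' Standard dye-linker geometries for T-C6 attached dyes
#'
#' Dimensions of the donor (Alexa 488) and acceptor (Alexa 647) dye-linker
#' constructs attached to DNA at the 5' position of a thymine via a C6
#' amino linker.
#'
#' @param dye `"donor"` (T-C6-Alexa 488) or `"acceptor"` (T-C6-Alexa 647).
#' @return A [dye_geometry()].
#' @export
dye_geometry_table <- function(dye = c("donor", "acceptor")) {
  dye <- match.arg(dye)
  if (dye == "donor")
    dye_geometry(L_link = 19.3, w_link = 4.5, R_dye_1 = 5.2, R_dye_2 = 4.2,
                 R_dye_3 = 1.5)
  else
    dye_geometry(L_link = 24.6, w_link = 4.5, R_dye_1 = 9.9, R_dye_2 = 7.7,
                 R_dye_3 = 1.5)
}

#' Build the obstacle grid around an attachment site
#'
#' A cubic grid centered on the attachment point with half-width
#' `L_link + max(R_dye)`. For every cell the distance from the cell center
#' to the nearest atom *surface* is stored; a cell is linker-blocked when
#' that distance is below `w_link / 2` (the linker tube cannot pass). The
#' labeled residue's own pseudo-atoms (any atom within `exclude_radius` of
#' the attachment) are excluded from the obstacle set, and cells within
#' `seed_radius` of the attachment are always traversable — the covalent
#' exit channel of the linker, without which the attachment point of a
#' coarse-grained duplex is sterically sealed by the neighboring bases.
#'
#' @param structure A `pseudo_atom_structure`.
#' @param geom [dye_geometry()].
#' @param attachment An attachment site (from [attachment_sites()]), or a
#'   length-3 numeric position.
#' @param spacing Grid spacing in Angstrom (default 0.8).
#' @param exclude_radius Atoms closer than this to the attachment are not
#'   obstacles (default 4 A: the labeled base itself).
#' @param seed_radius Free channel radius around the attachment (A).
#' @return An object of class `av_grid`.
#' @export
build_obstacle_grid <- function(structure, geom, attachment, spacing = 0.8,
                                exclude_radius = 4, seed_radius = 2) {
  stopifnot(inherits(geom, "dye_geometry"))
  pos <- if (is.list(attachment)) attachment$position else attachment
  stopifnot(length(pos) == 3)
  at <- structure$atoms
  d_att <- sqrt((at$x - pos[1])^2 + (at$y - pos[2])^2 + (at$z - pos[3])^2)
  at <- at[d_att > exclude_radius, , drop = FALSE]
  half <- geom$L_link + max(geom$R_dye)
  n_side <- 2L * as.integer(ceiling(half / spacing)) + 1L
  origin <- pos - (n_side - 1L) / 2 * spacing
  dims <- c(n_side, n_side, n_side)
  surf <- if (nrow(at)) {
    surface_distance_field(origin, spacing, dims,
                           as.matrix(at[, c("x", "y", "z")]), at$radius)
  } else rep(Inf, prod(dims))
  blocked <- surf < geom$w_link / 2
  # seed channel around the attachment
  src <- cell_index(pos, origin, spacing, dims)
  centers_near <- which(cell_distance_to(origin, spacing, dims, pos) <=
                          seed_radius)
  blocked[centers_near] <- FALSE
  if (blocked[src])
    stop("attachment cell is blocked; attachment appears buried")
  structure(list(origin = origin, spacing = spacing, dims = dims,
                 surf_dist = surf, blocked = blocked, attachment = pos,
                 geom = geom),
            class = "av_grid")
}

cell_index <- function(pos, origin, spacing, dims) {
  ijk <- pmin(pmax(round((pos - origin) / spacing), 0), dims - 1L)
  as.integer((ijk[3] * dims[2] + ijk[2]) * dims[1] + ijk[1] + 1L)
}

# distances from all cell centers to a point (vectorized, x fastest)
cell_distance_to <- function(origin, spacing, dims, pos) {
  xs <- origin[1] + (0:(dims[1] - 1)) * spacing - pos[1]
  ys <- origin[2] + (0:(dims[2] - 1)) * spacing - pos[2]
  zs <- origin[3] + (0:(dims[3] - 1)) * spacing - pos[3]
  sqrt(outer(outer(xs^2, ys^2, "+"), zs^2, "+"))
}

cell_centers <- function(grid, idx) {
  i <- (idx - 1L) %% grid$dims[1]
  j <- ((idx - 1L) %/% grid$dims[1]) %% grid$dims[2]
  k <- (idx - 1L) %/% (grid$dims[1] * grid$dims[2])
  cbind(x = grid$origin[1] + i * grid$spacing,
        y = grid$origin[2] + j * grid$spacing,
        z = grid$origin[3] + k * grid$spacing)
}

#' Compute the accessible volume of a dye-linker construct
#'
#' A grid point belongs to the accessible volume (AV) when (i) it can be
#' reached from the attachment point through linker-passable space by a
#' path no longer than the linker contour length `L_link` (shortest paths
#' via Dijkstra on a 98-direction grid graph with Euclidean edge lengths,
#' refined by exact Euclidean distances where the attachment has a free
#' line of sight),
#' and (ii) the dye fits there: the distance to the nearest atom surface is
#' at least one of the three ellipsoid semiaxes treated as sphere radii
#' (union-of-radii convention, i.e. at least `min(R_dye)`; free dye
#' rotation justifies the orientational averaging). Points carry uniform
#' weights.
#'
#' @param grid An [build_obstacle_grid()] result.
#' @return An object of class `accessible_volume`: matrix `points` (cell
#'   centers, Angstrom), numeric `weights` (sum 1), `attachment`,
#'   `path_dist`, `spacing`, `M` (point count).
#' @export
compute_av <- function(grid) {
  stopifnot(inherits(grid, "av_grid"))
  geom <- grid$geom
  src <- cell_index(grid$attachment, grid$origin, grid$spacing, grid$dims)
  pd <- grid_dijkstra(!grid$blocked, grid$dims, src - 1L, grid$spacing,
                      geom$L_link)
  los <- grid_line_of_sight(!grid$blocked, grid$dims, src - 1L, grid$spacing,
                            geom$L_link)
  pd <- pmin(pd, los)
  ok <- which(pd <= geom$L_link & grid$surf_dist >= min(geom$R_dye))
  if (!length(ok)) stop("accessible volume is empty")
  pts <- cell_centers(grid, ok)
  structure(list(points = pts, weights = rep(1 / length(ok), length(ok)),
                 attachment = grid$attachment, path_dist = pd[ok],
                 spacing = grid$spacing, M = length(ok)),
            class = "accessible_volume")
}

#' @export
print.accessible_volume <- function(x, ...) {
  cat(sprintf("accessible volume: %d points at %.2g A spacing (%.0f A^3)\n",
              x$M, x$spacing, x$M * x$spacing^3))
  invisible(x)
}

#' Width of the Gaussian AV weighting from an ideal-chain linker model
#'
#' An ideal (Gaussian) chain with effective bond length `b_eff` and contour
#' length `L_link` has mean-square end-to-end distance `b_eff * L_link`;
#' per Cartesian component this gives a Gaussian of width
#' `sigma_AV = sqrt(b_eff * L_link / 3)`. An alternative rigid-linker
#' scaling `sigma_AV = b_eff * sqrt(L_link / 3)` is selectable.
#'
#' @param b_eff Effective bond length (Angstrom).
#' @param L_link Linker contour length (Angstrom).
#' @param scaling `"gaussian-chain"` (default) or `"rigid"`.
#' @return `sigma_AV` in Angstrom.
#' @export
sigma_av <- function(b_eff, L_link, scaling = c("gaussian-chain", "rigid")) {
  stopifnot(b_eff > 0, L_link > 0)
  scaling <- match.arg(scaling)
  if (scaling == "gaussian-chain") sqrt(b_eff * L_link / 3)
  else b_eff * sqrt(L_link / 3)
}

#' Apply Gaussian occupancy weighting to an accessible volume (wAV)
#'
#' Each AV point `R` is weighted by
#' `exp(-|R - R_attach|^2 / (2 sigma_AV^2))`, normalized over the discrete
#' AV points (the discrete analogue of the continuous normalization
#' integral). The weighting penalizes fully-extended linker conformations
#' (conformational entropy and hydrophobicity of the aliphatic chain).
#'
#' @param av An [compute_av()] result.
#' @param sigma Gaussian width `sigma_AV` (Angstrom), see [sigma_av()].
#' @return The weighted `accessible_volume`.
#' @export
weight_av <- function(av, sigma) {
  stopifnot(inherits(av, "accessible_volume"), sigma > 0)
  d2 <- rowSums((av$points - matrix(av$attachment, av$M, 3, byrow = TRUE))^2)
  w <- exp(-d2 / (2 * sigma^2))
  av$weights <- w / sum(w)
  av$sigma_av <- sigma
  av
}

#' Inter-dye distance distribution from two accessible volumes
#'
#' Weighted mean and standard deviation of `|R_D,i - R_A,j|` over all point
#' pairs of the donor and acceptor clouds. The exact double sum is used
#' when `M * N <= max_exact` pairs; otherwise a seeded Monte-Carlo estimate
#' over `n_pairs` weight-sampled pairs is returned together with a standard
#' error of the mean.
#'
#' @param av_d,av_a Donor and acceptor `accessible_volume`s.
#' @param n_pairs Monte-Carlo sample size (default 1e6).
#' @param max_exact Pair-count limit for the exact double sum.
#' @param seed Seed for the pair sampler.
#' @return List with `mean_R`, `sigma_R`, `method` (`"exact"` or
#'   `"sampled"`), `se_mean` (0 for exact), `n_pairs`.
#' @export
interdye_distribution <- function(av_d, av_a, n_pairs = 1e6,
                                  max_exact = 1e7, seed = 1L) {
  stopifnot(inherits(av_d, "accessible_volume"),
            inherits(av_a, "accessible_volume"))
  if (as.double(av_d$M) * av_a$M <= max_exact) {
    m1 <- 0; m2 <- 0
    # chunk over donor points to bound memory
    chunk <- max(1L, floor(2e6 / av_a$M))
    for (s in seq(1L, av_d$M, by = chunk)) {
      e <- min(s + chunk - 1L, av_d$M)
      ii <- s:e
      d2 <- outer(rowSums(av_d$points[ii, , drop = FALSE]^2),
                  rowSums(av_a$points^2), "+") -
        2 * av_d$points[ii, , drop = FALSE] %*% t(av_a$points)
      dd <- sqrt(pmax(d2, 0))
      ww <- av_d$weights[ii] %o% av_a$weights
      m1 <- m1 + sum(ww * dd)
      m2 <- m2 + sum(ww * dd^2)
    }
    return(list(mean_R = m1, sigma_R = sqrt(max(m2 - m1^2, 0)),
                method = "exact", se_mean = 0,
                n_pairs = as.double(av_d$M) * av_a$M))
  }
  with_seed(seed, {
    i <- sample.int(av_d$M, n_pairs, replace = TRUE, prob = av_d$weights)
    j <- sample.int(av_a$M, n_pairs, replace = TRUE, prob = av_a$weights)
    dd <- sqrt(rowSums((av_d$points[i, , drop = FALSE] -
                          av_a$points[j, , drop = FALSE])^2))
    list(mean_R = mean(dd), sigma_R = stats::sd(dd), method = "sampled",
         se_mean = stats::sd(dd) / sqrt(n_pairs), n_pairs = n_pairs)
  })
}

#' Predicted inter-dye distance distribution for a labeled structure
#'
#' Convenience wrapper: builds the obstacle grids and AVs for a donor and an
#' acceptor site, optionally applies the Gaussian (wAV) weighting with a
#' per-dye `sigma_AV` derived from `b_eff`, and returns the distance
#' distribution.
#'
#' @param structure A `pseudo_atom_structure`.
#' @param site_d,site_a Attachment sites.
#' @param geom_d,geom_a [dye_geometry()]s.
#' @param spacing Grid spacing (Angstrom).
#' @param b_eff Effective bond length for wAV weighting; `NULL` for
#'   unweighted AV.
#' @param scaling Passed to [sigma_av()].
#' @param ... Passed to [interdye_distribution()].
#' @return The [interdye_distribution()] result, plus `av_d`, `av_a`.
#' @export
wav_distance_distribution <- function(structure, site_d, site_a,
                                      geom_d = dye_geometry_table("donor"),
                                      geom_a = dye_geometry_table("acceptor"),
                                      spacing = 0.8, b_eff = NULL,
                                      scaling = "gaussian-chain", ...) {
  av_d <- compute_av(build_obstacle_grid(structure, geom_d, site_d, spacing))
  av_a <- compute_av(build_obstacle_grid(structure, geom_a, site_a, spacing))
  if (!is.null(b_eff)) {
    av_d <- weight_av(av_d, sigma_av(b_eff, geom_d$L_link, scaling))
    av_a <- weight_av(av_a, sigma_av(b_eff, geom_a$L_link, scaling))
  }
  out <- interdye_distribution(av_d, av_a, ...)
  out$av_d <- av_d
  out$av_a <- av_a
  out
}

#' Calibrate the effective bond length against a measured width
#'
#' Scans/root-finds `b_eff` such that the wAV-predicted distance
#' distribution width matches a measured `sigma_DA` within `tol`. The
#' Gaussian weighting is applied per dye with its own `L_link`. The wAV
#' width is monotone non-decreasing in `b_eff` (larger `b_eff` widens the
#' occupancy Gaussian toward the uniform-AV limit), which the scan relies
#' on.
#'
#' @param av_d,av_a Unweighted donor/acceptor `accessible_volume`s.
#' @param L_d,L_a Linker contour lengths of the two dyes (Angstrom).
#' @param target_sigma Measured width to match (Angstrom).
#' @param range Search interval for `b_eff` (Angstrom).
#' @param tol Width matching tolerance (Angstrom, default 0.05).
#' @param scaling Passed to [sigma_av()].
#' @param ... Passed to [interdye_distribution()] (shared seed makes the
#'   objective deterministic).
#' @return `b_eff` in Angstrom.
#' @export
calibrate_beff <- function(av_d, av_a, L_d, L_a, target_sigma,
                           range = c(0.3, 30), tol = 0.05,
                           scaling = "gaussian-chain", ...) {
  width_at <- function(b) {
    wd <- weight_av(av_d, sigma_av(b, L_d, scaling))
    wa <- weight_av(av_a, sigma_av(b, L_a, scaling))
    interdye_distribution(wd, wa, ...)$sigma_R
  }
  f_lo <- width_at(range[1]) - target_sigma
  f_hi <- width_at(range[2]) - target_sigma
  if (f_hi < 0) {
    # the wAV width approaches the uniform-AV width from below; a target at
    # or above it is matched by the upper bound (weighting ~ uniform)
    if (f_hi >= -tol) return(range[2])
    stop(sprintf(
      "target width %.2f A not bracketed: achievable range [%.2f, %.2f] A",
      target_sigma, f_lo + target_sigma, f_hi + target_sigma))
  }
  if (f_lo > 0)
    stop(sprintf(
      "target width %.2f A not bracketed: achievable range [%.2f, %.2f] A",
      target_sigma, f_lo + target_sigma, f_hi + target_sigma))
  stats::uniroot(function(b) width_at(b) - target_sigma, interval = range,
                 tol = min(tol, 0.01))$root
}

#' Write an accessible volume as a pseudo-atom PDB cloud
#'
#' @param av An `accessible_volume`.
#' @param path Output path.
#' @param max_points Subsample limit for very large clouds.
#' @export
write_av_pdb <- function(av, path, max_points = 50000L) {
  idx <- seq_len(av$M)
  if (av$M > max_points)
    idx <- round(seq(1, av$M, length.out = max_points))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("REMARK   accessible volume point cloud", con)
  for (n in seq_along(idx)) {
    i <- idx[n]
    writeLines(sprintf(
      "HETATM%5d %-4s %-3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      n %% 100000L, "C", "AVP", "C", 1L, av$points[i, 1], av$points[i, 2],
      av$points[i, 3], 1.0, min(99.99, av$weights[i] * av$M), "C"), con)
  }
  writeLines("END", con)
  invisible(path)
}
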