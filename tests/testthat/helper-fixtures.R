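# shared fixtures: all synthetic, built in code

empty_structure <- function() {
  structure(list(atoms = data.frame(x = numeric(0), y = numeric(0),
                                    z = numeric(0), radius = numeric(0),
                                    residue = integer(0),
                                    strand = character(0),
                                    role = character(0)),
                 mismatches = integer(0)),
            class = "pseudo_atom_structure")
}

atoms_structure <- function(x, y, z, radius) {
  structure(list(atoms = data.frame(x = x, y = y, z = z, radius = radius,
                                    residue = seq_along(x), strand = "top",
                                    role = "atom"),
                 mismatches = integer(0)),
            class = "pseudo_atom_structure")
}

# synthetic accessible-volume object (for weighting/pair-statistics tests)
make_av <- function(points, attachment = c(0, 0, 0), weights = NULL) {
  points <- as.matrix(points)
  M <- nrow(points)
  if (is.null(weights)) weights <- rep(1 / M, M)
  structure(list(points = points, weights = weights,
                 attachment = attachment, path_dist = rep(0, M),
                 spacing = NA_real_, M = M),
            class = "accessible_volume")
}

std_truth <- function(mean_R = 60, sigma_R = 6, x_D0 = 0.2, I0 = 1e4,
                      BG = 20, tau = 4.025, R0 = 53.6) {
  fret_decay_params(exp_components(1, tau), gaussian_distance(mean_R, sigma_R),
                    R0, x_D0 = x_D0, I0 = I0, BG = BG)
}

std_grid <- function(n_bins = 3125L) time_grid(0.016, n_bins)

random_rotation <- function(seed) {
  set.seed(seed)
  qr_q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(qr_q) < 0) qr_q[, 1] <- -qr_q[, 1]
  qr_q
}
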