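#' Discrete TCSPC time grid
#'
#' A uniform microtime grid for TCSPC histograms. Bin centers are located at
#' `origin + (0:(n_bins-1)) * bin_width`; model functions are evaluated at bin
#' centers (the 16 ps default bin width is far below typical nanosecond
#' lifetimes, so center evaluation and bin integration are indistinguishable).
#'
#' @param bin_width Bin width in ns (default 0.016, i.e. 16 ps).
#' @param n_bins Number of bins (>= 2).
#' @param origin Time of the first bin center in ns.
#' @return An object of class `time_grid`.
#' @export
time_grid <- function(bin_width = 0.016, n_bins = 3125L, origin = 0) {
  if (!is.numeric(bin_width) || bin_width <= 0)
    stop("bin_width must be > 0")
  n_bins <- as.integer(n_bins)
  if (is.na(n_bins) || n_bins < 2L)
    stop("n_bins must be >= 2")
  structure(list(bin_width = bin_width, n_bins = n_bins, origin = origin),
            class = "time_grid")
}

#' Bin-center times of a time grid
#' @param grid A [time_grid()].
#' @return Numeric vector of bin-center times (ns).
#' @export
grid_times <- function(grid) {
  grid$origin + (seq_len(grid$n_bins) - 1) * grid$bin_width
}

same_grid <- function(a, b) {
  isTRUE(all.equal(a$bin_width, b$bin_width)) &&
    a$n_bins == b$n_bins &&
    isTRUE(all.equal(a$origin, b$origin))
}

#' TCSPC histogram
#'
#' Counts per microtime bin. Counts may be non-negative integers (measured or
#' simulated data) or non-negative reals (noiseless model curves).
#'
#' @param grid A [time_grid()].
#' @param counts Numeric vector of length `grid$n_bins`, all >= 0.
#' @return An object of class `tcspc_histogram`.
#' @export
tcspc_histogram <- function(grid, counts) {
  stopifnot(inherits(grid, "time_grid"))
  counts <- as.numeric(counts)
  if (length(counts) != grid$n_bins)
    stop("length(counts) must equal grid$n_bins")
  if (any(!is.finite(counts)) || any(counts < 0))
    stop("counts must be finite and >= 0")
  structure(list(grid = grid, counts = counts), class = "tcspc_histogram")
}

#' @export
print.tcspc_histogram <- function(x, ...) {
  cat(sprintf("TCSPC histogram: %d bins x %.4g ns, %.0f total counts, peak %.0f\n",
              x$grid$n_bins, x$grid$bin_width, sum(x$counts), max(x$counts)))
  invisible(x)
}

#' Instrument response function curve
#'
#' @param grid A [time_grid()].
#' @param values Non-negative IRF values per bin; `sum(values) > 0`.
#' @param fwhm Optional full width at half maximum in ns (metadata).
#' @return An object of class `irf_curve`.
#' @export
irf_curve <- function(grid, values, fwhm = NA_real_) {
  stopifnot(inherits(grid, "time_grid"))
  values <- as.numeric(values)
  if (length(values) != grid$n_bins)
    stop("length(values) must equal grid$n_bins")
  if (any(!is.finite(values)) || any(values < 0))
    stop("IRF values must be finite and >= 0")
  if (sum(values) <= 0)
    stop("IRF must have positive total intensity")
  structure(list(grid = grid, values = values, fwhm = fwhm),
            class = "irf_curve")
}

#' Delta (ideal) IRF
#'
#' Unit impulse in the first bin; convolution with it is the identity, so
#' decay models are fitted directly (used for artificial decays).
#'
#' @param grid A [time_grid()].
#' @return An [irf_curve()].
#' @export
delta_irf <- function(grid) {
  v <- numeric(grid$n_bins)
  v[1] <- 1
  irf_curve(grid, v, fwhm = 0)
}

#' Gaussian IRF
#'
#' @param grid A [time_grid()].
#' @param fwhm Full width at half maximum in ns (e.g. 0.448 or 0.544 for the
#'   two detection channels of a typical SPAD setup).
#' @param t0 Center position in ns.
#' @return An [irf_curve()].
#' @export
gaussian_irf <- function(grid, fwhm, t0 = 5 * fwhm) {
  stopifnot(fwhm > 0)
  s <- fwhm / (2 * sqrt(2 * log(2)))
  t <- grid_times(grid)
  h <- grid$bin_width / 2
  # bin-integrated (not midpoint) values: exact for arbitrarily narrow IRFs
  v <- stats::pnorm(t + h, t0, s) - stats::pnorm(t - h, t0, s)
  irf_curve(grid, v, fwhm = fwhm)
}

#' Read a TCSPC histogram or IRF from two-column text
#'
#' Format: two whitespace- or comma-delimited columns (time in ns, counts);
#' header/comment lines start with `#`.
#'
#' @param path File path.
#' @param as One of `"histogram"` or `"irf"`.
#' @return A [tcspc_histogram()] or [irf_curve()].
#' @export
read_tcspc <- function(path, as = c("histogram", "irf")) {
  as <- match.arg(as)
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) < 2) stop("need at least 2 data rows in ", path)
  parts <- strsplit(trimws(lines), "[,[:space:]]+")
  n <- vapply(parts, length, integer(1))
  if (any(n < 2)) stop("malformed row in ", path)
  tm <- as.numeric(vapply(parts, `[[`, "", 1))
  ct <- as.numeric(vapply(parts, `[[`, "", 2))
  if (any(is.na(tm)) || any(is.na(ct))) stop("non-numeric field in ", path)
  dt <- diff(tm)
  if (any(abs(dt - dt[1]) > 1e-9 * max(abs(dt[1]), 1)))
    stop("time column is not uniformly spaced in ", path)
  g <- time_grid(bin_width = dt[1], n_bins = length(tm), origin = tm[1])
  if (as == "histogram") tcspc_histogram(g, ct) else irf_curve(g, ct)
}

#' Write a TCSPC histogram or IRF as two-column text
#'
#' @param x A [tcspc_histogram()] or [irf_curve()].
#' @param path Output file path.
#' @param comment Optional character vector of header lines (written with
#'   a leading `#`).
#' @export
write_tcspc <- function(x, path, comment = NULL) {
  vals <- if (inherits(x, "irf_curve")) x$values else x$counts
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comment))
    writeLines(paste0("# ", comment), con)
  writeLines(sprintf("%.9g\t%.9g", grid_times(x$grid), vals), con)
  invisible(path)
}
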