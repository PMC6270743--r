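#' Generate an artificial Poisson-noise TCSPC decay
#'
#' Adds random Poisson noise to the noiseless total donor model (after
#' reconvolution with the IRF, if one is supplied). Reproducible given the
#' seed.
#'
#' @param params [fret_decay_params()].
#' @param grid [time_grid()].
#' @param irf [irf_curve()] or `NULL` for an ideal delta IRF (the default:
#'   the decay model is then sampled directly).
#' @param seed Integer seed.
#' @inheritParams fret_model_curve
#' @return A [tcspc_histogram()] with integer counts.
#' @export
generate_synthetic_decay <- function(params, grid, irf = NULL, seed = 1L,
                                     step = 0.25, n_sigma = 4,
                                     renormalize = TRUE, wrap = FALSE) {
  model <- fret_model_curve(params, grid, irf = irf, wrap = wrap,
                            step = step, n_sigma = n_sigma,
                            renormalize = renormalize)
  counts <- with_seed(seed, stats::rpois(grid$n_bins, model$counts))
  tcspc_histogram(grid, counts)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(as.integer(seed))
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  force(expr)
}

#' Precision and accuracy of an estimate
#'
#' Precision is the relative error `ci_halfwidth / estimate`; accuracy is the
#' signed relative deviation `(estimate - truth) / truth`.
#'
#' @param estimate Point estimate.
#' @param ci_halfwidth Half-width of the 68.3% confidence interval.
#' @param truth True value (non-zero).
#' @return Named numeric `c(precision, accuracy)`.
#' @export
precision_accuracy <- function(estimate, ci_halfwidth, truth) {
  if (truth == 0) stop("truth must be non-zero")
  c(precision = ci_halfwidth / estimate,
    accuracy = (estimate - truth) / truth)
}

#' Configuration of the donor-only bias simulation study
#'
#' Defaults reproduce the artificial-decay study conditions: mean inter-dye
#' distances of 40 A (high FRET) and 60 A (low FRET), width 6 A, donor-only
#' fractions 0 to 0.5, peak amplitude `I0 = 1e4`, background `BG = 20`
#' counts/bin, start guesses `<R_DA>` = 35/53 A (for truth 40/60), sigma = 8 A
#' and `0.9 * x_D0`, with `I0` and `BG` fixed at their true values. The donor
#' is modeled as a single 4.025 ns component with `R0 = 53.6` A. Decays are
#' 50 ns long at 16 ps binning and fitted from 1 ns before the peak to 40 ns.
#'
#' @param means True mean distances in Angstrom.
#' @param sigma_true True distribution width in Angstrom.
#' @param donor_only_fractions True `x_D0` values.
#' @param I0,BG Peak amplitude and background (fixed in the fits).
#' @param start_means Named start guesses for the mean, one per entry of
#'   `means`.
#' @param start_sigma Start guess for sigma.
#' @param start_xd0_factor Start guess factor applied to the true `x_D0`.
#' @param donor_components,R0 Donor photophysics.
#' @param replicates Noise realizations per condition.
#' @param ci Compute support-plane CIs (`FALSE`, `TRUE`, or names of
#'   parameters).
#' @param grid [time_grid()].
#' @param seed Base seed; replicate `r` of condition `i` uses
#'   `seed + 1000 * i + r`.
#' @return An object of class `study_config`.
#' @export
study_config <- function(means = c(40, 60), sigma_true = 6,
                         donor_only_fractions = c(0, .05, .1, .2, .3, .4, .5),
                         I0 = 1e4, BG = 20,
                         start_means = c("40" = 35, "60" = 53),
                         start_sigma = 8, start_xd0_factor = 0.9,
                         donor_components = exp_components(1, 4.025),
                         R0 = 53.6, replicates = 1L, ci = FALSE,
                         grid = time_grid(0.016, 3125L), seed = 1L) {
  stopifnot(all(donor_only_fractions >= 0), all(donor_only_fractions <= 0.5),
            replicates >= 1)
  if (!all(as.character(means) %in% names(start_means)))
    stop("start_means must carry a named entry for every mean")
  structure(list(means = means, sigma_true = sigma_true,
                 donor_only_fractions = donor_only_fractions,
                 I0 = I0, BG = BG, start_means = start_means,
                 start_sigma = start_sigma,
                 start_xd0_factor = start_xd0_factor,
                 donor_components = donor_components, R0 = R0,
                 replicates = as.integer(replicates), ci = ci,
                 grid = grid, seed = as.integer(seed)),
            class = "study_config")
}

#' Run the donor-only precision/accuracy study
#'
#' For every combination of true mean distance and donor-only fraction,
#' generates a Poisson-noise decay, fits it with the configured start guesses
#' (`I0` and `BG` fixed at truth), and optionally computes support-plane
#' confidence intervals, precisions and accuracies for `sigma_DA`, `<R_DA>`
#' and `x_D0`.
#'
#' @param config A [study_config()].
#' @return A `data.frame` (class `study_result`) with one row per
#'   (mean, fraction, replicate): estimates, chi2r, convergence flag and —
#'   when CIs are enabled — CI bounds, precision and accuracy per parameter.
#' @export
run_study <- function(config) {
  stopifnot(inherits(config, "study_config"))
  rows <- list()
  cond <- 0L
  for (mean_true in config$means) {
    for (xd0_true in config$donor_only_fractions) {
      cond <- cond + 1L
      for (r in seq_len(config$replicates)) {
        seed <- config$seed + 1000L * cond + r
        truth <- fret_decay_params(
          config$donor_components,
          gaussian_distance(mean_true, config$sigma_true),
          config$R0, x_D0 = xd0_true, I0 = config$I0, BG = config$BG)
        decay <- generate_synthetic_decay(truth, config$grid, seed = seed)
        start <- fret_decay_params(
          config$donor_components,
          gaussian_distance(config$start_means[[as.character(mean_true)]],
                            config$start_sigma),
          config$R0, x_D0 = config$start_xd0_factor * xd0_true,
          I0 = config$I0, BG = config$BG)
        fit <- tryCatch(
          fit_decay(decay, irf = NULL, start = start,
                    fixed = c("I0", "BG"), ci = config$ci),
          error = function(e) NULL)
        row <- data.frame(
          mean_true = mean_true, sigma_true = config$sigma_true,
          x_D0_true = xd0_true, replicate = r, seed = seed,
          converged = if (is.null(fit)) FALSE else fit$converged,
          mean_R = if (is.null(fit)) NA_real_ else fit$estimates[["mean_R"]],
          sigma_R = if (is.null(fit)) NA_real_ else fit$estimates[["sigma_R"]],
          x_D0 = if (is.null(fit)) NA_real_ else fit$estimates[["x_D0"]],
          chi2r = if (is.null(fit)) NA_real_ else fit$chi2r)
        if (!is.null(fit) && !is.null(fit$ci)) {
          for (p in rownames(fit$ci)) {
            hw <- (fit$ci[p, "high"] - fit$ci[p, "low"]) / 2
            truth_p <- switch(p, mean_R = mean_true,
                              sigma_R = config$sigma_true,
                              x_D0 = xd0_true, NA_real_)
            row[[paste0(p, "_ci_low")]] <- fit$ci[p, "low"]
            row[[paste0(p, "_ci_high")]] <- fit$ci[p, "high"]
            row[[paste0(p, "_precision")]] <- hw / fit$estimates[[p]]
            row[[paste0(p, "_accuracy")]] <-
              if (!is.na(truth_p) && truth_p != 0)
                (fit$estimates[[p]] - truth_p) / truth_p else NA_real_
          }
        }
        rows[[length(rows) + 1L]] <- row
      }
    }
  }
  out <- do.call(rbind, lapply(rows, function(r) {
    missing <- setdiff(unique(unlist(lapply(rows, names))), names(r))
    for (mname in missing) r[[mname]] <- NA_real_
    r
  }))
  class(out) <- c("study_result", class(out))
  out
}

#' Mean reduced chi-square per mean-distance series
#'
#' @param study A [run_study()] result.
#' @return Named numeric: mean `chi2r` over all fractions and replicates for
#'   each true mean distance.
#' @export
study_mean_chi2r <- function(study) {
  tapply(study$chi2r, study$mean_true, mean, na.rm = TRUE)
}
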