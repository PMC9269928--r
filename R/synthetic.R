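#' Control-like technical noise specification
#'
#' Surrogate for the fluctuations of unstimulated (0 pM) cells, built from
#' three components with distinct time scales: a fast mean-reverting
#' (AR(1)/OU-like) component with correlation time below 100 min, a slow
#' smooth drift with a time scale above 12 h, and white measurement noise.
#' Each trajectory is centered (mean subtracted), matching how measured
#' control traces are normalized before being added to simulations.
#'
#' @param fast_sd marginal standard deviation of the fast component (ratio
#'   units).
#' @param fast_tau correlation time of the fast component (minutes, < 100).
#' @param drift_sd marginal standard deviation of the slow drift.
#' @param drift_tau drift time scale (minutes, > 720).
#' @param white_sd standard deviation of uncorrelated measurement noise.
#' @return list of class `control_noise_spec`.
#' @export
control_noise_spec <- function(fast_sd = 0.05, fast_tau = 30,
                               drift_sd = 0.04, drift_tau = 1440,
                               white_sd = 0.01) {
  stopifnot(fast_sd >= 0, drift_sd >= 0, white_sd >= 0,
            fast_tau > 0, drift_tau > 0)
  structure(list(fast_sd = fast_sd, fast_tau = fast_tau,
                 drift_sd = drift_sd, drift_tau = drift_tau,
                 white_sd = white_sd),
            class = "control_noise_spec")
}

ar1_series <- function(n, sd, tau, dx) {
  phi <- exp(-dx / tau)
  innov_sd <- sd * sqrt(1 - phi^2)
  x <- numeric(n)
  x[1] <- stats::rnorm(1, 0, sd)
  eps <- stats::rnorm(n - 1, 0, innov_sd)
  for (i in 2:n) x[i] <- phi * x[i - 1] + eps[i - 1]
  x
}

#' Generate mean-zero control-noise trajectories
#'
#' @param spec a [control_noise_spec()].
#' @param n_cells number of trajectories.
#' @param horizon length in minutes (default 24 h).
#' @param dx sampling interval (minutes).
#' @param seed integer seed.
#' @return object of class `control_noise`: list with `time`, `noise`
#'   (matrix time x cells, each column exactly mean-zero) and `components`
#'   (named list of the mean-centered `fast`, `drift`, `white` matrices
#'   whose sum equals `noise`, allowing exact attribution in diagnostics).
#' @export
generate_control_noise <- function(spec = control_noise_spec(), n_cells,
                                   horizon = 1440, dx = 5, seed = NULL) {
  stopifnot(horizon > 0, n_cells >= 1)
  if (!is.null(seed)) set.seed(seed)
  n <- round(horizon / dx) + 1
  center <- function(m) sweep(m, 2, colMeans(m))
  gen <- function(sd, tau) {
    if (sd == 0) return(matrix(0, n, n_cells))
    center(vapply(seq_len(n_cells), function(i) ar1_series(n, sd, tau, dx),
                  numeric(n)))
  }
  fast <- gen(spec$fast_sd, spec$fast_tau)
  drift <- gen(spec$drift_sd, spec$drift_tau)
  white <- if (spec$white_sd == 0) matrix(0, n, n_cells) else
    center(matrix(stats::rnorm(n * n_cells, 0, spec$white_sd), n, n_cells))
  noise <- fast + drift + white
  colnames(noise) <- sprintf("cell_%04d", seq_len(n_cells))
  structure(list(time = (seq_len(n) - 1) * dx, noise = noise,
                 components = list(fast = fast, drift = drift, white = white),
                 spec = spec),
            class = "control_noise")
}

#' Injected-burst specification for detection benchmarks
#'
#' Gaussian hills emulating observed activity bursts: per-trajectory count
#' from a truncated Poisson, amplitudes spanning one to a few times the
#' default detection threshold, widths constrained so the full width at
#' half maximum falls inside the 100-300 min burst window.
#'
#' @param count_lambda Poisson mean of the per-trajectory burst count.
#' @param count_range truncation bounds of the count.
#' @param amplitude_range uniform amplitude range (ratio units).
#' @param duration_range uniform FWHM range (minutes); hill standard
#'   deviation is FWHM / 2.355.
#' @param min_separation minimal spacing of burst centers (minutes). Two
#'   equal Gaussian hills merge into a single maximum when their centers
#'   are closer than about twice the hill standard deviation, so the
#'   default keeps injected events individually resolvable.
#' @param margin distance of centers from the trajectory edges (minutes).
#' @return list of class `burst_spec`.
#' @export
burst_spec <- function(count_lambda = 3, count_range = c(1, 5),
                       amplitude_range = c(0.12, 0.5),
                       duration_range = c(100, 300),
                       min_separation = 250, margin = 150) {
  stopifnot(amplitude_range[1] > 0, duration_range[1] < duration_range[2])
  structure(list(count_lambda = count_lambda, count_range = count_range,
                 amplitude_range = amplitude_range,
                 duration_range = duration_range,
                 min_separation = min_separation, margin = margin),
            class = "burst_spec")
}

place_centers <- function(k, horizon, margin, min_sep) {
  lo <- margin; hi <- horizon - margin
  if (hi <= lo) return(numeric(0))
  centers <- numeric(0)
  tries <- 0
  while (length(centers) < k && tries < 200) {
    cand <- stats::runif(1, lo, hi)
    if (!length(centers) || min(abs(centers - cand)) >= min_sep) {
      centers <- c(centers, cand)
    }
    tries <- tries + 1
  }
  sort(centers)
}

#' Generate a labeled burst-detection benchmark
#'
#' Positive trajectories are a baseline plus injected Gaussian hills plus
#' control-like noise; negatives are the baseline plus noise only. The
#' baseline is a deterministic model simulation at the requested dose
#' (`dose = 0`, the default, emulates the unstimulated control, so that
#' every true event is an injected one); a flat baseline is used when no
#' model is given. Ground truth records every injected hill. At a
#' stimulating dose the baseline's own deterministic response peak is a
#' genuine signaling event that is *not* part of the ground truth, so
#' detections of it count against the false-detection rate; benchmarks
#' meant for ROC scoring should use the unstimulated baseline.
#'
#' @param model a [smad_model()] or `NULL` for a flat baseline.
#' @param spec a [burst_spec()].
#' @param noise a [control_noise_spec()].
#' @param n_pos,n_neg numbers of positive / negative trajectories.
#' @param dose bolus dose (pM) of the baseline simulation.
#' @param horizon length in minutes.
#' @param dx sampling interval (minutes).
#' @param seed integer seed; the full benchmark is reproducible from
#'   (spec, seed).
#' @return object of class `burst_benchmark`: list with `time`,
#'   `positives`, `negatives` (matrices), `truth` (tibble `trajectory_id`,
#'   `center`, `amplitude`, `width`), `baseline`.
#' @export
generate_benchmark <- function(model = NULL, spec = burst_spec(),
                               noise = control_noise_spec(),
                               n_pos = 200, n_neg = 200, dose = 0,
                               horizon = 1440, dx = 5, seed = NULL) {
  stopifnot(n_pos >= 1, n_neg >= 1)
  if (!is.null(seed)) set.seed(seed)
  n <- round(horizon / dx) + 1
  tt <- (seq_len(n) - 1) * dx
  baseline <- if (is.null(model)) rep(0, n) else {
    sim <- simulate_ensemble(model, NULL, stimulus_schedule(0, dose),
                             n_cells = 1, horizon = horizon,
                             output_interval = dx)
    sim$ratio[, 1]
  }
  ctrl <- generate_control_noise(noise, n_pos + n_neg, horizon, dx)
  pos <- matrix(baseline, n, n_pos) + ctrl$noise[, seq_len(n_pos)]
  neg <- matrix(baseline, n, n_neg) + ctrl$noise[, n_pos + seq_len(n_neg)]
  colnames(pos) <- sprintf("pos_%04d", seq_len(n_pos))
  colnames(neg) <- sprintf("neg_%04d", seq_len(n_neg))
  truth <- list()
  for (i in seq_len(n_pos)) {
    k <- stats::rpois(1, spec$count_lambda)
    k <- min(max(k, spec$count_range[1]), spec$count_range[2])
    centers <- place_centers(k, horizon, spec$margin, spec$min_separation)
    if (length(centers) < k) {
      warning("separation constraint: placed ", length(centers),
              " of ", k, " hills in ", colnames(pos)[i])
    }
    for (cc in centers) {
      a <- stats::runif(1, spec$amplitude_range[1], spec$amplitude_range[2])
      fwhm <- stats::runif(1, spec$duration_range[1], spec$duration_range[2])
      w <- fwhm / 2.355
      pos[, i] <- pos[, i] + a * exp(-(tt - cc)^2 / (2 * w^2))
      truth[[length(truth) + 1]] <- tibble::tibble(
        trajectory_id = colnames(pos)[i], center = cc, amplitude = a, width = w)
    }
  }
  structure(list(
    time = tt, positives = pos, negatives = neg,
    truth = if (length(truth)) dplyr::bind_rows(truth) else
      tibble::tibble(trajectory_id = character(), center = numeric(),
                     amplitude = numeric(), width = numeric()),
    baseline = baseline, spec = spec, noise_spec = noise
  ), class = "burst_benchmark")
}

#' @export
print.burst_benchmark <- function(x, ...) {
  cat("<burst_benchmark> ", ncol(x$positives), " positive + ",
      ncol(x$negatives), " negative trajectories, ",
      nrow(x$truth), " injected bursts\n", sep = "")
  invisible(x)
}

#' Generate a pseudo-experimental population with tunable burst features
#'
#' Trajectories built as baseline + Gaussian hills + control noise, with
#' the burst amplitude, count and duration scaled by multipliers relative
#' to a base specification. Families of such populations with gradually
#' changing multipliers are used to verify that the objective function
#' responds gradually (dose-sensitivity analog).
#'
#' @param feature_scales named numeric vector/list with entries
#'   `amplitude`, `count`, `duration` (multipliers > 0, or 0 to remove
#'   bursts).
#' @param base_spec a [burst_spec()].
#' @param noise a [control_noise_spec()].
#' @param n_cells number of trajectories.
#' @param baseline numeric baseline vector or single value.
#' @param horizon,dx grid settings (minutes).
#' @param seed integer seed.
#' @return list of class `pseudo_population` with `time`, `ratio` matrix
#'   and `truth` table.
#' @export
generate_pseudo_population <- function(feature_scales = c(amplitude = 1, count = 1,
                                                          duration = 1),
                                       base_spec = burst_spec(),
                                       noise = control_noise_spec(),
                                       n_cells = 100, baseline = 0.25,
                                       horizon = 1440, dx = 5, seed = NULL) {
  fs <- as.list(feature_scales)
  stopifnot(all(unlist(fs) >= 0))
  sp <- base_spec
  sp$amplitude_range <- sp$amplitude_range * (fs$amplitude %||% 1)
  sp$count_lambda <- sp$count_lambda * (fs$count %||% 1)
  sp$count_range <- c(if ((fs$count %||% 1) == 0) 0 else sp$count_range[1],
                      max(1, round(sp$count_range[2] * (fs$count %||% 1))))
  sp$duration_range <- pmin(pmax(sp$duration_range * (fs$duration %||% 1), 40), 600)
  if ((fs$amplitude %||% 1) == 0) sp$count_range <- c(0, 0)
  bench <- generate_benchmark(NULL, sp, noise, n_pos = n_cells, n_neg = 1,
                              horizon = horizon, dx = dx, seed = seed)
  ratio <- bench$positives + baseline
  colnames(ratio) <- sprintf("cell_%04d", seq_len(n_cells))
  truth <- bench$truth
  truth$trajectory_id <- sub("^pos", "cell", truth$trajectory_id)
  structure(list(time = bench$time, ratio = ratio, truth = truth,
                 spec = sp, feature_scales = fs),
            class = "pseudo_population")
}
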