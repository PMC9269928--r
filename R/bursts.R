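#' Burst detection configuration
#'
#' Parameters of the three-step burst-detection algorithm: (1) slow drifts
#' (time scales above ~12 h) are estimated — after peaks have been
#' approximated by a sum of Gaussian hills and removed — and subtracted;
#' (2) fast fluctuations (below ~100 min) are smoothed out by a Gaussian
#' filter; (3) remaining peaks are called and quantified by height and
#' duration. Bursts live on the intermediate 100-300 minute time scale;
#' overlapping bursts are allowed.
#'
#' @param trend_bandwidth standard deviation (minutes) of the Gaussian
#'   kernel used for the long-term trend; large enough to pass multi-hour
#'   drifts while suppressing burst-scale structure.
#' @param burst_bandwidth standard deviation (minutes) of the band
#'   smoothing filter; removes sub-100-min fluctuations while preserving
#'   100-300 min features.
#' @param height_threshold minimum burst-band value at a peak (ratio units).
#' @param duration_bounds admissible full-width-at-half-height range
#'   (minutes) of a called burst.
#' @param window the targeted burst time scale (minutes); documentation of
#'   the band, used for input-length validation.
#' @param max_hills maximum number of Gaussian hills in the trend step.
#' @param hill_width_bounds bounds (minutes) on the fitted hill standard
#'   deviation.
#' @return list of class `detection_config`.
#' @export
detection_config <- function(trend_bandwidth = 150, burst_bandwidth = 25,
                             height_threshold = 0.08,
                             duration_bounds = c(50, 450),
                             window = c(100, 300),
                             max_hills = 10, hill_width_bounds = c(10, 200)) {
  stopifnot(trend_bandwidth > 0, burst_bandwidth > 0, height_threshold > 0,
            length(duration_bounds) == 2, duration_bounds[1] < duration_bounds[2],
            window[1] < window[2], max_hills >= 0)
  structure(list(trend_bandwidth = trend_bandwidth,
                 burst_bandwidth = burst_bandwidth,
                 height_threshold = height_threshold,
                 duration_bounds = duration_bounds,
                 window = window, max_hills = max_hills,
                 hill_width_bounds = hill_width_bounds),
            class = "detection_config")
}

# Gaussian kernel smoother on a uniform grid with edge renormalization.
# Matrix input is smoothed column-wise in a single filter pass; NA entries
# carry zero weight.
gaussian_smooth <- function(x, bw, dx) {
  vec <- is.null(dim(x))
  m <- if (vec) matrix(x, ncol = 1) else x
  n <- nrow(m)
  half <- min(n - 1, max(1L, ceiling(3 * bw / dx)))
  k <- stats::dnorm(seq(-half, half) * dx, sd = bw)
  ok <- !is.na(m)
  m0 <- m
  m0[!ok] <- 0
  # linear convolution by FFT (padded to a power of two), columns at once
  L <- stats::nextn(n + 2 * half, 2)
  fk <- stats::fft(c(k, rep(0, L - length(k))))
  conv <- function(a) {
    pa <- rbind(a, matrix(0, L - n, ncol(a)))
    out <- Re(stats::mvfft(stats::mvfft(pa) * fk, inverse = TRUE)) / L
    out[(half + 1):(half + n), , drop = FALSE]
  }
  num <- conv(m0)
  den <- conv(ok + 0)
  out <- num / den
  out[!ok] <- NA_real_
  if (vec) as.numeric(out) else out
}

# Greedy Gaussian-hill fit per column (two passes, base recomputed between
# passes); returns the hill sum matrix and a list of fitted-hill tables.
fit_hills <- function(sig, pres, config, dx, collect = FALSE) {
  n <- nrow(sig)
  tt <- (seq_len(n) - 1) * dx
  hills <- matrix(0, n, ncol(sig))
  hill_thr <- config$height_threshold / 2
  fitted <- if (collect) vector("list", ncol(sig)) else NULL
  for (pass in 1:2) {
    base <- gaussian_smooth(sig - hills, config$trend_bandwidth, dx)
    for (j in seq_len(ncol(sig))) {
      resid <- pres[, j] - hills[, j] - base[, j]
      resid[is.na(resid)] <- -Inf
      cen <- amp <- wid <- numeric(0)
      for (h in seq_len(config$max_hills)) {
        i <- which.max(resid)
        a <- resid[i]
        if (!is.finite(a) || a < hill_thr) break
        half <- a / 2
        l <- i; while (l > 1 && resid[l - 1] > half) l <- l - 1
        r <- i; while (r < n && resid[r + 1] > half) r <- r + 1
        fwhm <- max(r - l, 1) * dx
        sdw <- min(max(fwhm / 2.355, config$hill_width_bounds[1]),
                   config$hill_width_bounds[2])
        hill <- a * exp(-(tt - tt[i])^2 / (2 * sdw^2))
        hills[, j] <- hills[, j] + hill
        resid <- resid - hill
        if (collect) { cen <- c(cen, tt[i]); amp <- c(amp, a); wid <- c(wid, sdw) }
      }
      if (collect && length(cen)) {
        fitted[[j]] <- rbind(fitted[[j]], cbind(cen, amp, wid))
      }
    }
  }
  list(hills = hills, fitted = fitted)
}

# Lean peak caller on one burst-band column: returns cbind(time, height,
# duration) of called bursts, already ordered by time.
call_peaks <- function(band, config, dx) {
  n <- length(band)
  band[is.na(band)] <- -Inf
  pt <- hh <- dd <- numeric(0)
  if (n >= 3) {
    thr <- config$height_threshold
    up <- which(band[2:(n - 1)] > thr &
                band[2:(n - 1)] > band[1:(n - 2)] &
                band[2:(n - 1)] >= band[3:n]) + 1L
    for (i in up) {
      h <- band[i]
      half <- h / 2
      l <- i; lt <- NA_real_
      while (l > 1) {
        if (band[l - 1] < half) {
          lt <- l - 1 + (band[l - 1] - half) / (band[l - 1] - band[l])
          break
        }
        if (band[l - 1] > band[l]) { lt <- l; break }
        l <- l - 1
      }
      if (is.na(lt)) lt <- 1
      r <- i; rt <- NA_real_
      while (r < n) {
        if (band[r + 1] < half) {
          rt <- r + 1 - (band[r + 1] - half) / (band[r + 1] - band[r])
          break
        }
        if (band[r + 1] > band[r]) { rt <- r; break }
        r <- r + 1
      }
      if (is.na(rt)) rt <- n
      dur <- (rt - lt) * dx
      if (dur < config$duration_bounds[1] || dur > config$duration_bounds[2]) next
      pt <- c(pt, (i - 1) * dx); hh <- c(hh, h); dd <- c(dd, dur)
    }
  }
  cbind(time = pt, height = hh, duration = dd)
}

# Full matrix pipeline: trend, band, peaks for every column.
detect_core <- function(m, config, dx) {
  pres <- gaussian_smooth(m, config$burst_bandwidth, dx)
  hf <- fit_hills(m, pres, config, dx)
  trend <- gaussian_smooth(m - hf$hills, config$trend_bandwidth, dx)
  band <- gaussian_smooth(m - trend, config$burst_bandwidth, dx)
  lapply(seq_len(ncol(m)), function(j) call_peaks(band[, j], config, dx))
}

#' Long-term trend of a single-cell ratio trajectory
#'
#' Approximates peaks by a greedy sum of Gaussian hills (find the largest
#' residual peak, fit one hill by its height and half-width, subtract,
#' repeat), removes them from the signal and heavily smooths the remainder.
#' This prevents the stimulation peak and large bursts from bleeding into
#' the drift estimate.
#'
#' @param signal numeric vector, nuc/cyt ratio on a uniform grid.
#' @param config a [detection_config()].
#' @param dx grid spacing in minutes (default 5).
#' @return numeric trend of the same length, with attribute `hills`
#'   (tibble of fitted hill center/amplitude/width).
#' @export
estimate_trend <- function(signal, config = detection_config(), dx = 5) {
  n <- length(signal)
  if (n * dx < config$window[2]) {
    stop("signal too short: need at least ", config$window[2], " minutes")
  }
  m <- matrix(signal, ncol = 1)
  pres <- gaussian_smooth(m, config$burst_bandwidth, dx)
  hf <- fit_hills(m, pres, config, dx, collect = TRUE)
  trend <- as.numeric(gaussian_smooth(m - hf$hills, config$trend_bandwidth, dx))
  ft <- hf$fitted[[1]]
  attr(trend, "hills") <- if (!is.null(ft)) {
    tibble::tibble(center = ft[, 1], amplitude = ft[, 2], width = ft[, 3])
  } else {
    tibble::tibble(center = numeric(), amplitude = numeric(), width = numeric())
  }
  trend
}

#' Detrend and band-limit a trajectory
#'
#' Subtracts the long-term trend and smooths the remainder with a Gaussian
#' filter whose bandwidth removes fluctuations on scales below ~100 min
#' while preserving the 100-300 min burst band (transfer at a 300-min
#' period above 0.7, at a 30-min period below 0.3 for the default
#' bandwidth).
#'
#' @param signal numeric vector on a uniform grid.
#' @param trend trend of the same length (see [estimate_trend()]).
#' @param config a [detection_config()].
#' @param dx grid spacing in minutes.
#' @return the burst-band series.
#' @export
detrend_and_smooth <- function(signal, trend, config = detection_config(), dx = 5) {
  stopifnot(length(signal) == length(trend))
  gaussian_smooth(signal - trend, config$burst_bandwidth, dx)
}

#' Call bursts in a burst-band series
#'
#' Local maxima above the height threshold become burst records. Height is
#' the burst-band value at the peak; duration is the full width at half
#' the peak height (linearly interpolated), cut at shared valleys so that
#' overlapping bursts are both reported. Peaks whose duration falls
#' outside the plausibility bounds are discarded.
#'
#' @param band burst-band series (see [detrend_and_smooth()]).
#' @param config a [detection_config()].
#' @param dx grid spacing in minutes.
#' @return tibble (`burst_index`, `peak_time`, `height`, `duration`)
#'   ordered by peak time.
#' @export
find_bursts <- function(band, config = detection_config(), dx = 5) {
  pk <- call_peaks(band, config, dx)
  if (!nrow(pk)) {
    return(tibble::tibble(burst_index = integer(), peak_time = numeric(),
                          height = numeric(), duration = numeric()))
  }
  tibble::tibble(burst_index = seq_len(nrow(pk)),
                 peak_time = unname(pk[, "time"]),
                 height = unname(pk[, "height"]),
                 duration = unname(pk[, "duration"]))
}

#' Detect bursts in every cell of a population
#'
#' Runs the full three-step pipeline (trend estimation, detrending and
#' band smoothing, peak calling) per cell and summarizes the catalog.
#'
#' @param x a `smad_ensemble`, or a numeric matrix (time x cells) with
#'   `time` supplied.
#' @param config a [detection_config()].
#' @param time time grid (minutes) when `x` is a matrix.
#' @return object of class `burst_catalog`: list with `bursts` (tibble
#'   `cell`, `burst_index`, `peak_time`, `height`, `duration`) and `cells`
#'   (tibble `cell`, `count`, `auc`, `failed`). The AUC is the
#'   trapezoidal time-integral of the raw ratio; cells without enough
#'   usable samples (computational failures) are flagged.
#' @export
detect_bursts <- function(x, config = detection_config(), time = NULL) {
  m <- ratio_matrix(x)
  tt <- time %||% (if (inherits(x, "smad_ensemble")) x$time else
                     stop("time grid required for matrix input"))
  dx <- tt[2] - tt[1]
  cells <- colnames(m) %||% sprintf("cell_%04d", seq_len(ncol(m)))
  min_len <- ceiling(config$window[2] / dx)
  # a cell is usable up to its first NA (computational failure time)
  first_na <- apply(m, 2, function(y) {
    i <- which(is.na(y))
    if (length(i)) i[1] - 1L else length(y)
  })
  failed <- first_na < min_len
  m2 <- m
  for (j in which(first_na < nrow(m))) {
    m2[(first_na[j] + 1):nrow(m), j] <- NA_real_
  }
  peaks <- detect_core(m2[, !failed, drop = FALSE], config, dx)
  npk <- vapply(peaks, nrow, integer(1))
  live <- which(!failed)
  bursts <- tibble::tibble(
    cell = rep(cells[live], npk),
    burst_index = unlist(lapply(npk, seq_len), use.names = FALSE),
    peak_time = unlist(lapply(peaks, function(p) p[, "time"]), use.names = FALSE),
    height = unlist(lapply(peaks, function(p) p[, "height"]), use.names = FALSE),
    duration = unlist(lapply(peaks, function(p) p[, "duration"]), use.names = FALSE)
  )
  if (!length(npk)) bursts <- bursts[0, ]
  # trapezoidal AUC on the usable part
  auc <- vapply(seq_len(ncol(m)), function(j) {
    if (failed[j]) return(NA_real_)
    y <- m2[seq_len(first_na[j]), j]
    sum((y[-1] + y[-length(y)]) / 2 * dx)
  }, numeric(1))
  counts <- rep(NA_integer_, ncol(m))
  counts[live] <- npk
  structure(list(
    bursts = bursts,
    cells = tibble::tibble(cell = cells, count = counts, auc = auc,
                           failed = failed),
    config = config
  ), class = "burst_catalog")
}

#' @export
print.burst_catalog <- function(x, ...) {
  cat("<burst_catalog> ", nrow(x$cells), " cells, ", nrow(x$bursts),
      " bursts (mean count ", round(mean(x$cells$count, na.rm = TRUE), 2),
      "), ", sum(x$cells$failed), " failed\n", sep = "")
  invisible(x)
}

#' @export
tidy.burst_catalog <- function(x, ...) x$bursts

#' @export
glance.burst_catalog <- function(x, ...) {
  tibble::tibble(n_cells = nrow(x$cells),
                 n_failed = sum(x$cells$failed),
                 mean_count = mean(x$cells$count, na.rm = TRUE),
                 median_height = stats::median(x$bursts$height),
                 median_duration = stats::median(x$bursts$duration))
}

# Greedy one-to-one matching of detections to ground-truth centers within
# a time tolerance; returns the number matched.
match_bursts <- function(det_times, true_times, tol) {
  if (!length(det_times) || !length(true_times)) return(0L)
  dmat <- abs(outer(det_times, true_times, "-"))
  matched <- 0L
  repeat {
    i <- which.min(dmat)
    if (!length(i) || min(dmat, na.rm = TRUE) > tol) break
    rc <- arrayInd(i, dim(dmat))
    matched <- matched + 1L
    dmat[rc[1], ] <- Inf
    dmat[, rc[2]] <- Inf
    if (all(!is.finite(dmat))) break
  }
  matched
}

score_detection <- function(config, pos, neg, truth, time, match_tol) {
  cat_pos <- detect_bursts(pos, config, time = time)
  cat_neg <- detect_bursts(neg, config, time = time)
  tp <- 0L; fp_pos <- 0L
  for (cl in unique(colnames(pos))) {
    dt <- cat_pos$bursts$peak_time[cat_pos$bursts$cell == cl]
    tr <- truth$center[truth$trajectory_id == cl]
    mm <- match_bursts(dt, tr, match_tol)
    tp <- tp + mm
    fp_pos <- fp_pos + (length(dt) - mm)
  }
  fp_neg <- nrow(cat_neg$bursts)
  n_det <- tp + fp_pos + fp_neg
  tibble::tibble(
    sensitivity = if (nrow(truth)) tp / nrow(truth) else NA_real_,
    fdr = if (n_det > 0) (fp_pos + fp_neg) / n_det else 0,
    n_detections = n_det, true_positives = tp
  )
}

#' ROC-based tuning of the burst detector
#'
#' Randomly samples detection-parameter candidates (latin hypercube over
#' threshold, both bandwidths and the duration bounds), scores each on a
#' labeled synthetic benchmark — sensitivity as the fraction of injected
#' bursts matched by a detection within `match_tol` minutes (greedy
#' one-to-one matching), false-detection rate as the fraction of all
#' detections that are unmatched or fall on negative trajectories — and
#' selects the candidate with maximal sensitivity subject to
#' `fdr < fdr_max`.
#'
#' @param benchmark a benchmark object from [generate_benchmark()] (or a
#'   list with `positives`, `negatives` matrices, `truth` table, `time`).
#' @param n_samples number of sampled candidates.
#' @param seed integer seed for the candidate sample.
#' @param fdr_max false-detection-rate constraint (default 0.25).
#' @param match_tol matching tolerance in minutes (default 45).
#' @param ranges optional named list overriding sampling ranges.
#' @return object of class `burst_roc`: list with `best_config`, `best`
#'   (scored row) and `roc` (tibble of all candidates).
#' @export
tune_detection <- function(benchmark, n_samples = 500, seed = NULL,
                           fdr_max = 0.25, match_tol = 45, ranges = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (nrow(benchmark$truth) == 0) {
    warning("degenerate benchmark: no injected bursts; sensitivity undefined")
  }
  rg <- list(height_threshold = c(0.02, 0.5), burst_bandwidth = c(5, 60),
             trend_bandwidth = c(60, 400), dur_min = c(30, 120),
             dur_max = c(250, 600))
  if (!is.null(ranges)) rg[names(ranges)] <- ranges
  u <- lhs::randomLHS(n_samples, 5)
  cand <- tibble::tibble(
    height_threshold = exp(log(rg$height_threshold[1]) +
      u[, 1] * diff(log(rg$height_threshold))),
    burst_bandwidth = rg$burst_bandwidth[1] + u[, 2] * diff(rg$burst_bandwidth),
    trend_bandwidth = rg$trend_bandwidth[1] + u[, 3] * diff(rg$trend_bandwidth),
    dur_min = rg$dur_min[1] + u[, 4] * diff(rg$dur_min),
    dur_max = rg$dur_max[1] + u[, 5] * diff(rg$dur_max)
  )
  scores <- purrr::map_dfr(seq_len(n_samples), function(s) {
    cfg <- detection_config(
      trend_bandwidth = cand$trend_bandwidth[s],
      burst_bandwidth = cand$burst_bandwidth[s],
      height_threshold = cand$height_threshold[s],
      duration_bounds = c(cand$dur_min[s], cand$dur_max[s]))
    score_detection(cfg, benchmark$positives, benchmark$negatives,
                    benchmark$truth, benchmark$time, match_tol)
  })
  roc <- dplyr::bind_cols(cand, scores)
  roc$candidate <- seq_len(n_samples)
  feasible <- which(roc$fdr < fdr_max)
  if (length(feasible)) {
    best <- feasible[order(-roc$sensitivity[feasible], roc$fdr[feasible])][1]
  } else {
    warning("no candidate met the false-detection-rate constraint; ",
            "returning the best-effort candidate")
    best <- order(-roc$sensitivity, roc$fdr)[1]
  }
  best_config <- detection_config(
    trend_bandwidth = roc$trend_bandwidth[best],
    burst_bandwidth = roc$burst_bandwidth[best],
    height_threshold = roc$height_threshold[best],
    duration_bounds = c(roc$dur_min[best], roc$dur_max[best]))
  structure(list(best_config = best_config, best = roc[best, ], roc = roc,
                 fdr_max = fdr_max, match_tol = match_tol),
            class = "burst_roc")
}

#' @export
print.burst_roc <- function(x, ...) {
  cat("<burst_roc> ", nrow(x$roc), " candidates; selected: sensitivity ",
      round(100 * x$best$sensitivity, 1), "%, FDR ",
      round(100 * x$best$fdr, 1), "% (constraint < ",
      100 * x$fdr_max, "%)\n", sep = "")
  invisible(x)
}

#' @export
tidy.burst_roc <- function(x, ...) x$roc

#' Autocorrelation of a trajectory
#'
#' Normalized autocorrelation over lags, after subtracting either the
#' estimated long-term trend or the time average.
#'
#' @param signal numeric vector on a uniform grid.
#' @param detrend subtract the estimated trend (`TRUE`) or the mean.
#' @param max_lag largest lag in minutes.
#' @param dx grid spacing in minutes.
#' @param config a [detection_config()] (trend settings when `detrend`).
#' @return tibble (`lag`, `acf`), `lag` in minutes, `acf[lag = 0] = 1`.
#' @export
autocorrelation <- function(signal, detrend = TRUE, max_lag = 600, dx = 5,
                            config = detection_config()) {
  x <- if (detrend) signal - estimate_trend(signal, config, dx)
       else signal - mean(signal, na.rm = TRUE)
  nl <- min(length(x) - 1, round(max_lag / dx))
  a <- stats::acf(x, lag.max = nl, plot = FALSE, demean = TRUE,
                  na.action = stats::na.pass)
  tibble::tibble(lag = a$lag[, 1, 1] * dx, acf = a$acf[, 1, 1])
}

#' Group a per-cell covariate by signal AUC and burst count
#'
#' Bins cells by their ratio AUC (quantile bins) and sub-classifies each
#' bin by total burst count (low vs high groups), reporting the group
#' mean of an arbitrary per-cell covariate. Used to relate burst activity
#' to covariates such as a motility score while controlling for total
#' signal.
#'
#' @param catalog a `burst_catalog`.
#' @param covariate numeric vector named by cell, or in catalog cell order.
#' @param auc_bins number of AUC quantile bins.
#' @param count_low cells with `count <= count_low` form the low group.
#' @param count_high cells with `count >= count_high` form the high group.
#' @return tibble (`auc_bin`, `group`, `mean_covariate`, `n`); empty
#'   combinations appear with `NA` mean and `n = 0`.
#' @export
burst_covariate_binning <- function(catalog, covariate, auc_bins = 5,
                                    count_low = 8, count_high = 12) {
  cells <- catalog$cells
  cov <- if (!is.null(names(covariate))) covariate[cells$cell]
         else stats::setNames(rep_len(covariate, nrow(cells)), cells$cell)
  if (anyNA(cov[!cells$failed])) stop("covariate must be defined for every cell")
  df <- cells |>
    dplyr::filter(!.data$failed) |>
    dplyr::mutate(covariate = cov[.data$cell],
                  auc_bin = dplyr::ntile(.data$auc, auc_bins),
                  group = dplyr::case_when(
                    .data$count <= count_low ~ "low",
                    .data$count >= count_high ~ "high",
                    TRUE ~ NA_character_)) |>
    dplyr::filter(!is.na(.data$group))
  df |>
    dplyr::group_by(.data$auc_bin, .data$group) |>
    dplyr::summarise(mean_covariate = mean(.data$covariate),
                     n = dplyr::n(), .groups = "drop") |>
    tidyr::complete(auc_bin = seq_len(auc_bins), group = c("low", "high"),
                    fill = list(n = 0L))
}
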