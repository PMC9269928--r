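make_time <- function(horizon = 1440, dx = 5) seq(0, horizon, by = dx)

gauss_hill <- function(tt, center, amplitude, width_sd) {
  amplitude * exp(-(tt - center)^2 / (2 * width_sd^2))
}

test_that("a constant signal yields a constant trend and no hills", {
  tt <- make_time()
  tr <- estimate_trend(rep(2.5, length(tt)))
  expect_equal(tr, rep(2.5, length(tt)), tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(nrow(attr(tr, "hills")), 0)
})

test_that("trend recovers a linear drift while the hill survives detrending", {
  tt <- make_time()
  drift <- 0.5 + 1e-4 * tt
  a <- 0.3
  sig <- drift + gauss_hill(tt, 700, a, 60)
  cfg <- detection_config(height_threshold = 0.05)
  tr <- estimate_trend(sig, cfg)
  inner <- tt > 150 & tt < 1290   # away from smoothing edges
  expect_lt(max(abs(tr - drift)[inner]), 0.2 * a)
  band <- detrend_and_smooth(sig, tr, cfg)
  expect_gt(max(band), 0.8 * a)
  expect_lt(abs(max(band) - a) / a, 0.2)
})

test_that("a slow sinusoid is absorbed by the trend", {
  tt <- make_time()
  sig <- 1 + 0.3 * sin(2 * pi * tt / 2880)   # 48 h period
  cfg <- detection_config(height_threshold = 0.08)
  tr <- estimate_trend(sig, cfg)
  band <- detrend_and_smooth(sig, tr, cfg)
  expect_lt(max(abs(band)), cfg$height_threshold)
  expect_equal(nrow(find_bursts(band, cfg)), 0)
})

test_that("band filter passes the burst window and rejects fast noise", {
  tt <- make_time()
  cfg <- detection_config()
  zero_trend <- rep(0, length(tt))
  # 200-min period preserved within 30 percent
  s200 <- sin(2 * pi * tt / 200)
  out200 <- detrend_and_smooth(s200, zero_trend, cfg)
  expect_gt(max(out200[50:230]), 0.7)
  # 300-min period attenuated by less than 30 percent; 30-min almost gone
  s300 <- sin(2 * pi * tt / 300)
  expect_gt(max(detrend_and_smooth(s300, zero_trend, cfg)[50:230]), 0.7)
  s30 <- sin(2 * pi * tt / 30)
  expect_lt(max(abs(detrend_and_smooth(s30, zero_trend, cfg)[50:230])), 0.3)
  # white noise variance strongly reduced
  set.seed(2)
  wn <- stats::rnorm(length(tt))
  expect_lt(stats::var(detrend_and_smooth(wn, zero_trend, cfg)),
            0.1 * stats::var(wn))
  # zero in, zero out
  expect_equal(detrend_and_smooth(zero_trend, zero_trend, cfg), zero_trend)
})

test_that("peak calling quantifies injected hills", {
  tt <- make_time()
  cfg <- detection_config(height_threshold = 0.1, duration_bounds = c(50, 450))
  expect_equal(nrow(find_bursts(rep(0, length(tt)), cfg)), 0)
  # single hill at twice the threshold, width 40 min
  band <- gauss_hill(tt, 700, 0.2, 40)
  b <- find_bursts(band, cfg)
  expect_equal(nrow(b), 1)
  expect_equal(b$peak_time, 700)
  expect_lt(abs(b$height - 0.2) / 0.2, 0.25)
  expect_lt(abs(b$duration - 2.355 * 40) / (2.355 * 40), 0.3)
  # five well-separated hills
  centers <- c(200, 450, 700, 950, 1200)
  band5 <- rowSums(sapply(centers, function(cc) gauss_hill(tt, cc, 0.3, 40)))
  b5 <- find_bursts(band5, cfg)
  expect_equal(nrow(b5), 5)
  expect_equal(b5$burst_index, 1:5)
  expect_equal(b5$peak_time, centers)
})

test_that("burst features are offset-invariant and scale like the signal", {
  tt <- make_time()
  set.seed(9)
  sig <- 0.8 + gauss_hill(tt, 500, 0.25, 50) + gauss_hill(tt, 1000, 0.18, 45) +
    stats::rnorm(length(tt), 0, 0.01)
  cfg <- detection_config(height_threshold = 0.06)
  cat0 <- detect_bursts(matrix(sig, ncol = 1), cfg, time = tt)
  cat_off <- detect_bursts(matrix(sig + 5, ncol = 1), cfg, time = tt)
  expect_equal(cat0$bursts$height, cat_off$bursts$height, tolerance = 1e-8)
  expect_equal(cat0$bursts$duration, cat_off$bursts$duration, tolerance = 1e-8)
  cfg2 <- detection_config(height_threshold = 0.06 * 3)
  cat_sc <- detect_bursts(matrix(3 * sig, ncol = 1), cfg2, time = tt)
  expect_equal(cat_sc$bursts$height, 3 * cat0$bursts$height, tolerance = 1e-8)
  expect_equal(cat_sc$bursts$duration, cat0$bursts$duration, tolerance = 1e-8)
  # determinism and index ordering
  cat1 <- detect_bursts(matrix(sig, ncol = 1), cfg, time = tt)
  expect_identical(cat0$bursts, cat1$bursts)
  expect_false(is.unsorted(cat0$bursts$peak_time))
})

test_that("autocorrelation is normalized and recovers a known decay time", {
  tt <- make_time(2880)
  set.seed(4)
  tau <- 120
  phi <- exp(-5 / tau)
  n <- length(tt)
  x <- numeric(n); x[1] <- stats::rnorm(1)
  for (i in 2:n) x[i] <- phi * x[i - 1] + stats::rnorm(1, 0, sqrt(1 - phi^2))
  ac <- autocorrelation(x, detrend = FALSE, max_lag = 400)
  expect_equal(ac$acf[ac$lag == 0], 1)
  fit <- stats::lm(log(acf) ~ lag, data = dplyr::filter(ac, lag <= 150, acf > 0))
  expect_lt(abs(-1 / stats::coef(fit)[2] - tau) / tau, 0.2)
  # white noise: all lags near zero
  set.seed(5)
  acw <- autocorrelation(stats::rnorm(n), detrend = FALSE, max_lag = 300)
  expect_lt(mean(abs(acw$acf[acw$lag > 0])), 2 / sqrt(n))
  expect_lt(max(abs(acw$acf[acw$lag > 0])), 4 / sqrt(n))
})

test_that("covariate binning groups cells by AUC and burst count", {
  tt <- make_time()
  set.seed(12)
  n_cells <- 60
  counts <- sample(c(2:6, 13:16), n_cells, replace = TRUE)
  cells <- sprintf("cell_%04d", 1:n_cells)
  catalog <- structure(list(
    bursts = tibble::tibble(cell = character(), burst_index = integer(),
                            peak_time = numeric(), height = numeric(),
                            duration = numeric()),
    cells = tibble::tibble(cell = cells, count = counts,
                           auc = stats::runif(n_cells, 100, 500),
                           failed = FALSE)
  ), class = "burst_catalog")
  # covariate = the count itself: high group must exceed low group
  g <- burst_covariate_binning(catalog, stats::setNames(counts, cells),
                               auc_bins = 3)
  wide <- tidyr::pivot_wider(g, id_cols = "auc_bin", names_from = "group",
                             values_from = "mean_covariate")
  ok <- !is.na(wide$high) & !is.na(wide$low)
  expect_true(any(ok))
  expect_true(all(wide$high[ok] > wide$low[ok]))
  # constant covariate: equal means wherever both groups are present
  gc <- burst_covariate_binning(catalog, stats::setNames(rep(7, n_cells), cells),
                                auc_bins = 3)
  expect_true(all(gc$mean_covariate[gc$n > 0] == 7))
  # count + noise: positive pooled difference recovered
  gn <- burst_covariate_binning(catalog,
                                stats::setNames(counts + stats::rnorm(n_cells),
                                                cells), auc_bins = 3)
  wn <- tidyr::pivot_wider(gn, id_cols = "auc_bin", names_from = "group",
                           values_from = "mean_covariate")
  okn <- !is.na(wn$high) & !is.na(wn$low)
  expect_gt(mean(wn$high[okn] - wn$low[okn]), 0)
})

test_that("ROC tuning reaches near-perfect sensitivity in an easy regime", {
  # amplitudes ten times the noise level
  sp <- burst_spec(amplitude_range = c(0.5, 1), count_lambda = 2,
                   count_range = c(1, 3))
  ns <- control_noise_spec(fast_sd = 0.02, drift_sd = 0.02, white_sd = 0.005)
  b <- suppressWarnings(generate_benchmark(NULL, sp, ns, n_pos = 30, n_neg = 30,
                                           seed = 14))
  roc <- suppressWarnings(tune_detection(b, n_samples = 60, seed = 3))
  expect_gte(roc$best$sensitivity, 0.95)
  expect_lt(roc$best$fdr, 0.25)
  expect_equal(nrow(roc$roc), 60)
})

test_that("a benchmark without injected bursts is reported as degenerate", {
  sp <- burst_spec(count_lambda = 0, count_range = c(0, 0))
  b <- suppressWarnings(generate_benchmark(NULL, sp, n_pos = 5, n_neg = 5,
                                           seed = 1))
  expect_equal(nrow(b$truth), 0)
  expect_warning(tune_detection(b, n_samples = 3, seed = 1), "degenerate")
})

test_that("short inputs are rejected", {
  expect_error(estimate_trend(rep(1, 10)), "too short")
})
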