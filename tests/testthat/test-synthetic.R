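test_that("control noise is mean-zero with attributable components", {
  spec <- control_noise_spec()
  cn <- generate_control_noise(spec, n_cells = 20, horizon = 1440, seed = 6)
  expect_equal(colMeans(cn$noise), rep(0, 20), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(cn$components$fast + cn$components$drift + cn$components$white,
               cn$noise, ignore_attr = TRUE)
  # zero amplitudes give identically zero trajectories
  z <- generate_control_noise(control_noise_spec(fast_sd = 0, drift_sd = 0,
                                                 white_sd = 0),
                              n_cells = 3, seed = 1)
  expect_true(all(z$noise == 0))
  # reproducibility from (spec, seed)
  cn2 <- generate_control_noise(spec, n_cells = 20, horizon = 1440, seed = 6)
  expect_identical(cn$noise, cn2$noise)
})

test_that("long-lag autocovariance is dominated by the drift component", {
  cn <- generate_control_noise(control_noise_spec(), n_cells = 40,
                               horizon = 2880, seed = 9)
  lag <- 60  # 300 minutes at 5-min sampling
  autocov <- function(m) {
    mean(sapply(seq_len(ncol(m)), function(j) {
      x <- m[, j]
      mean(x[seq_len(length(x) - lag)] * x[-seq_len(lag)])
    }))
  }
  total <- autocov(cn$noise)
  fast <- autocov(cn$components$fast)
  drift <- autocov(cn$components$drift)
  expect_gt(drift, 0)
  expect_lt(abs(fast), 0.1 * abs(drift))
  expect_gt(drift / total, 0.8)
})

test_that("the benchmark ground truth matches its injected hills", {
  b <- suppressWarnings(generate_benchmark(NULL, n_pos = 25, n_neg = 10,
                                           seed = 3))
  expect_equal(ncol(b$positives), 25)
  expect_equal(ncol(b$negatives), 10)
  expect_true(all(b$truth$trajectory_id %in% colnames(b$positives)))
  expect_true(all(b$truth$amplitude > 0))
  # widths inside the 100-300 min duration window
  expect_true(all(b$truth$width * 2.355 >= 100 - 1e-9))
  expect_true(all(b$truth$width * 2.355 <= 300 + 1e-9))
  b2 <- suppressWarnings(generate_benchmark(NULL, n_pos = 25, n_neg = 10,
                                            seed = 3))
  expect_identical(b$positives, b2$positives)
  expect_identical(b$truth, b2$truth)
  # re-synthesizing positives from truth + stored parts reproduces them
  tt <- b$time
  rebuilt <- b$positives * 0
  for (i in seq_len(ncol(b$positives))) {
    y <- b$baseline
    tr <- b$truth[b$truth$trajectory_id == colnames(b$positives)[i], ]
    for (k in seq_len(nrow(tr))) {
      y <- y + tr$amplitude[k] * exp(-(tt - tr$center[k])^2 / (2 * tr$width[k]^2))
    }
    rebuilt[, i] <- y
  }
  # positives minus hills/baseline equals pure control noise: mean-zero,
  # identical across reconstruction
  resid <- b$positives - rebuilt[, seq_len(ncol(b$positives))]
  expect_equal(colMeans(resid), rep(0, ncol(resid)), tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("without injected bursts positives equal negatives statistically", {
  sp <- burst_spec(count_lambda = 0, count_range = c(0, 0))
  b <- generate_benchmark(NULL, sp, n_pos = 40, n_neg = 40, seed = 8)
  expect_equal(nrow(b$truth), 0)
  pv <- as.vector(b$positives)
  nv <- as.vector(b$negatives)
  expect_gt(stats::ks.test(pv, nv)$p.value, 0.01)
  expect_lt(abs(stats::sd(pv) - stats::sd(nv)) / stats::sd(nv), 0.1)
})

test_that("a noiseless single hill is located to one sample interval", {
  sp <- burst_spec(count_lambda = 1, count_range = c(1, 1),
                   amplitude_range = c(0.3, 0.3))
  ns0 <- control_noise_spec(fast_sd = 0, drift_sd = 0, white_sd = 0)
  b <- generate_benchmark(NULL, sp, ns0, n_pos = 5, n_neg = 1, seed = 4)
  # light band smoothing: the peak location is not displaced by the filter
  cfg <- detection_config(height_threshold = 0.05, burst_bandwidth = 15,
                          trend_bandwidth = 200, duration_bounds = c(60, 450))
  catal <- detect_bursts(b$positives, cfg, time = b$time)
  for (i in 1:5) {
    cl <- colnames(b$positives)[i]
    det <- catal$bursts$peak_time[catal$bursts$cell == cl]
    expect_equal(length(det), 1)
    expect_lte(abs(det - b$truth$center[b$truth$trajectory_id == cl]), 5)
  }
})

test_that("pseudo-population feature multipliers shape detected statistics", {
  cfg <- bench_detection()
  p1 <- suppressWarnings(generate_pseudo_population(
    c(amplitude = 1, count = 1, duration = 1), n_cells = 60, seed = 10))
  p2 <- suppressWarnings(generate_pseudo_population(
    c(amplitude = 2, count = 1, duration = 1), n_cells = 60, seed = 10))
  c1 <- detect_bursts(p1$ratio, cfg, time = p1$time)
  c2 <- detect_bursts(p2$ratio, cfg, time = p2$time)
  ratio <- stats::median(c2$bursts$height) / stats::median(c1$bursts$height)
  expect_lt(abs(ratio - 2) / 2, 0.25)
  # removing bursts entirely drops counts to the false-positive floor
  p0 <- generate_pseudo_population(c(amplitude = 0, count = 0, duration = 1),
                                   n_cells = 60, seed = 10)
  c0 <- detect_bursts(p0$ratio, cfg, time = p0$time)
  # counts drop to the technical-noise false-positive floor
  floor_ref <- detect_bursts(generate_control_noise(control_noise_spec(),
                                                    60, seed = 20)$noise + 0.25,
                             cfg, time = p0$time)
  expect_lt(mean(c0$cells$count), 0.5 * mean(c1$cells$count))
  expect_lt(abs(mean(c0$cells$count) - mean(floor_ref$cells$count)), 1)
})
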