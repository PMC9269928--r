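# minimal hand-built populations for exact component checks
fake_catalog <- function(counts, heights = NULL, durations = NULL,
                         failed = NULL) {
  n <- length(counts)
  cells <- sprintf("cell_%04d", seq_len(n))
  failed <- failed %||% rep(FALSE, n)
  bursts <- list()
  for (i in seq_len(n)) {
    k <- counts[i]
    if (is.na(k) || k == 0) next
    bursts[[i]] <- tibble::tibble(
      cell = cells[i], burst_index = seq_len(k),
      peak_time = 100 * seq_len(k),
      height = if (is.null(heights)) rep(0.2, k) else rep_len(heights[i], k),
      duration = if (is.null(durations)) rep(150, k) else rep_len(durations[i], k))
  }
  structure(list(
    bursts = if (length(bursts)) dplyr::bind_rows(bursts) else
      tibble::tibble(cell = character(), burst_index = integer(),
                     peak_time = numeric(), height = numeric(),
                     duration = numeric()),
    cells = tibble::tibble(cell = cells, count = counts, auc = 100,
                           failed = failed)
  ), class = "burst_catalog")
}

fake_stats <- function(mean, sd, n_t = 10) {
  tibble::tibble(time = seq(0, by = 5, length.out = n_t),
                 mean = rep(mean, n_t), sd = rep(sd, n_t), n = 10)
}

test_that("feature distances follow the relative-difference formulas", {
  # identical distributions, no failures
  expect_equal(burst_feature_distance(c(1, 2, 3), c(1, 2, 3), 0, "median"), 0)
  # medians 3 (data) vs 1 (model)
  expect_equal(burst_feature_distance(c(1, 1, 1), c(3, 3, 3), 0, "median"), 0.5)
  # the failure rate dominates entirely at r = 1
  expect_equal(burst_feature_distance(numeric(0), c(1), 1, "median"), 1)
  # r = 0.2 mixes in the relative difference
  expect_equal(burst_feature_distance(c(1), c(3), 0.2, "median"),
               0.2 + 0.8 * 0.5)
  # 0/0 convention
  expect_equal(burst_feature_distance(c(0, 0), c(0, 0), 0, "sd"), 0)
})

test_that("count distances follow the mean/sd relative differences", {
  expect_equal(count_distance(c(2, 2), c(2, 2), 0), c(mean = 0, sd = 0))
  expect_equal(count_distance(rep(6, 4), rep(2, 4), 0)[["mean"]], 0.5)
  expect_equal(count_distance(rep(3, 4), c(1, 3, 3, 5), 0)[["sd"]], 1)
})

test_that("population distances sum snapshot differences relatively", {
  x <- fake_stats(2, 0)
  y <- fake_stats(1, 1)
  d <- population_distance(x, y)
  expect_equal(d[["mean"]], 1 / 3)
  expect_equal(d[["sd"]], 1)
  expect_equal(population_distance(x, x), c(mean = 0, sd = 0))
  expect_error(population_distance(x, fake_stats(1, 1) |>
                                     dplyr::mutate(time = time + 1e6)),
               "overlapping")
})

test_that("failure rates deduct the data's missing bursts and clip at zero", {
  xc <- fake_catalog(c(2, 2, NA, 1), failed = c(FALSE, FALSE, TRUE, FALSE))
  yc <- fake_catalog(c(2, 2, 2, 2))
  r <- failure_rates(xc, yc)
  expect_equal(unname(r["r0"]), 0.25)
  expect_equal(unname(r["r1"]), 0.25)  # the failed path lacks burst 1
  expect_equal(unname(r["r2"]), 0.5)   # failed + the one-burst path
  # data with more missing bursts than the model: clipped to 0
  r2 <- failure_rates(fake_catalog(c(2, 2)), fake_catalog(c(0, 0)))
  expect_equal(unname(r2["r1"]), 0)
})

test_that("the assembled objective is zero iff populations match", {
  x <- list(catalog = fake_catalog(c(2, 3, 2)), stats = fake_stats(1.5, 0.2))
  obj <- assemble_objective(x, x)
  expect_equal(objective_scalar(obj), 0)
  expect_true(all(obj$raw == 0))
  expect_equal(nrow(obj), 21)
  expect_equal(obj$weight, unname(objective_weights()))
})

test_that("a pure failure-rate difference weights in at eighty-fold", {
  x <- list(catalog = fake_catalog(c(rep(2, 9), NA),
                                   failed = c(rep(FALSE, 9), TRUE)),
            stats = fake_stats(1.5, 0.2))
  y <- list(catalog = fake_catalog(rep(2, 10)), stats = fake_stats(1.5, 0.2))
  obj <- assemble_objective(x, y)
  expect_equal(obj$value[obj$component == "failed"], 80 * 0.1)
  # burst components inherit r^i = 0.1 through the failure prefactor
  expect_equal(obj$raw[obj$component == "height_med_1"], 0.1)
})

test_that("unweighted components stay in [0, 1] without failures", {
  set.seed(8)
  for (rep in 1:5) {
    x <- list(catalog = fake_catalog(sample(0:5, 8, replace = TRUE),
                                     heights = stats::runif(8, 0.1, 0.5),
                                     durations = stats::runif(8, 100, 300)),
              stats = fake_stats(stats::runif(1, 0.5, 2), stats::runif(1, 0, 0.5)))
    y <- list(catalog = fake_catalog(sample(0:5, 8, replace = TRUE),
                                     heights = stats::runif(8, 0.1, 0.5),
                                     durations = stats::runif(8, 100, 300)),
              stats = fake_stats(stats::runif(1, 0.5, 2), stats::runif(1, 0, 0.5)))
    obj <- assemble_objective(x, y)
    expect_true(all(obj$raw >= 0 & obj$raw <= 1))
    expect_gte(objective_scalar(obj), 0)
  }
})

test_that("the objective ignores cell ordering", {
  set.seed(15)
  pop <- suppressWarnings(generate_pseudo_population(n_cells = 30, seed = 3))
  cfg <- bench_detection()
  s1 <- population_summary(pop$ratio, cfg, time = pop$time)
  perm <- sample(ncol(pop$ratio))
  s2 <- population_summary(pop$ratio[, perm], cfg, time = pop$time)
  ref <- suppressWarnings(generate_pseudo_population(n_cells = 30, seed = 4))
  sref <- population_summary(ref$ratio, cfg, time = ref$time)
  expect_equal(objective_scalar(assemble_objective(s1, sref)),
               objective_scalar(assemble_objective(s2, sref)), tolerance = 1e-12)
})

test_that("the objective grows along a gradually scaled burst-feature family", {
  cfg <- bench_detection()
  base <- suppressWarnings(generate_pseudo_population(
    c(amplitude = 1, count = 1, duration = 1), n_cells = 60, seed = 1))
  s_base <- population_summary(base$ratio, cfg, time = base$time)
  scal <- sapply(c(1, 0.6, 0.2), function(a) {
    p <- suppressWarnings(generate_pseudo_population(
      c(amplitude = a, count = 1, duration = 1), n_cells = 60, seed = 2))
    objective_scalar(assemble_objective(
      population_summary(p$ratio, cfg, time = p$time), s_base))
  })
  expect_true(all(diff(scal) > 0))
  # matched generation stays near zero relative to the scaled variants
  expect_lt(scal[1], 0.25 * scal[2])
})

test_that("residual rescaling has its closed-form minimizer and AIC ratio", {
  a <- aic_rescale(3, groups = "g", n_fitted = 0)
  expect_equal(a$scales$s, 3)
  b <- aic_rescale(c(3, 4), groups = c("g", "g"))
  expect_equal(b$scales$s, sqrt(12.5))
  # identical residuals and parameter counts give AIC ratio 1
  r <- stats::runif(10, 0.1, 1)
  m1 <- aic_rescale(r, groups = rep("g", 10), n_fitted = 3)
  m2 <- aic_rescale(r, groups = rep("g", 10), n_fitted = 3,
                    reference_aic = m1$aic)
  expect_equal(m2$aic_ratio, 1)
  expect_warning(aic_rescale(c(0, 0), groups = c("a", "a")), "degenerate")
})
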