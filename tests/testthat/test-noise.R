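test_that("closed-form CIR moments match their defining limits", {
  m0 <- cir_moments(0.2, 0.05, 0.05, t = 0, p_init = 0.35)
  expect_equal(m0$mean, 0.35)
  expect_equal(m0$variance, 0)
  # sigma = 0: pure relaxation, zero variance
  mr <- cir_moments(0.2, 0, 0.05, t = c(10, 50), p_init = 0.4)
  expect_equal(mr$mean, 0.2 + 0.2 * exp(-0.05 * c(10, 50)))
  expect_equal(mr$variance, c(0, 0))
  # stationary variance p0 sigma^2 / (2 theta)
  ms <- cir_moments(0.2, 0.05, 0.05, t = 1e6)
  expect_equal(ms$variance, 0.2 * 0.05^2 / (2 * 0.05), tolerance = 1e-10)
  # theta = 0 limiting branch
  md <- cir_moments(0.2, 0.05, 0, t = 10, p_init = 0.2)
  expect_true(attr(md, "degenerate"))
  expect_equal(md$mean, 0.2)
  expect_equal(md$variance, 0.05^2 * 0.2 * 10)
})

test_that("sampled CIR paths agree with closed-form moments", {
  m <- the_model()
  nb <- noise_block(m, "internalization", sigma = 0.05, theta = 0.05,
                    p0 = c(0.2, 0.2, 0.2))
  ps <- sample_block_paths(nb[2, ], horizon = 200, dt = 0.5,
                           n_paths = 10000, seed = 7)
  v <- ps$paths[[1]][ps$time == 100, ]
  mom <- cir_moments(0.2, 0.05, 0.05, 100)
  se <- stats::sd(v) / sqrt(length(v))
  expect_lt(abs(mean(v) - mom$mean), 3 * se)
  stat <- as.vector(ps$paths[[1]][ps$time >= 150, ])
  expect_lt(abs(stats::var(stat) / (0.2 * 0.05^2 / 0.1) - 1), 0.05)
})

test_that("CIR paths are non-negative, mean-preserving, variance-bounded", {
  m <- the_model()
  nb <- noise_block_raw(m, "internalization", 5L, "ki_cplx",
                        p0 = 0.1, sigma = 0.08, theta = 0.02)
  ps <- suppressWarnings(sample_block_paths(nb, horizon = 500, dt = 0.5,
                                            n_paths = 3000, seed = 3))
  x <- ps$paths[[1]]
  expect_true(all(x >= 0))
  se <- apply(x, 1, stats::sd) / sqrt(ncol(x))
  expect_true(all(abs(rowMeans(x) - 0.1) < 4 * pmax(se, 1e-12)))
  v <- apply(x[seq(1, nrow(x), by = 40), ], 1, stats::var)
  vmax <- 0.1 * 0.08^2 / (2 * 0.02)
  expect_true(all(v <= vmax * 1.15))
  # variance grows towards its bound
  expect_true(all(diff(v) > -0.25 * vmax))
  expect_gt(v[length(v)], 0.5 * vmax)
})

test_that("sigma = 0 gives constant paths; seeds reproduce bit-exactly", {
  m <- the_model()
  nb0 <- noise_block_raw(m, "internalization", 5L, "ki_cplx",
                         p0 = 0.2, sigma = 0, theta = 0.05)
  ps <- sample_block_paths(nb0, horizon = 50, dt = 1, n_paths = 3, seed = 1)
  expect_equal(ps$paths[[1]], matrix(0.2, nrow(ps$paths[[1]]), 3),
               tolerance = 1e-12, ignore_attr = TRUE)
  nb <- mild_internalization(m)
  a <- sample_block_paths(nb, 50, 0.5, 10, seed = 99)
  b <- sample_block_paths(nb, 50, 0.5, 10, seed = 99)
  expect_identical(a$paths, b$paths)
})

test_that("OU paths go negative where matched CIR paths cannot", {
  m <- the_model()
  p0 <- 0.05; theta <- 0.005; sigma <- 0.05
  cir <- noise_block_raw(m, "internalization", 5L, "ki_cplx",
                         p0 = p0, sigma = sigma, theta = theta)
  ou <- noise_block_raw(m, "internalization", 5L, "ki_cplx",
                        p0 = p0, sigma = sigma * sqrt(p0), theta = theta,
                        process = "ou")
  pc <- sample_block_paths(cir, 3000, 0.5, 30, seed = 8)
  po <- sample_block_paths(ou, 3000, 0.5, 30, seed = 8)
  expect_true(all(pc$paths[[1]] >= 0))
  expect_lt(min(po$paths[[1]]), 0)
})

test_that("stationary distribution is right-skewed with unit mass", {
  m <- the_model()
  nb <- noise_block_raw(m, "internalization", 5L, "ki_cplx",
                        p0 = 0.1, sigma = 0.06, theta = 0.01)
  h <- suppressWarnings(stationary_histogram(nb, horizon = 2000, dt = 1,
                                             n_paths = 100, seed = 4))
  expect_equal(sum(h$prob), 1, tolerance = 1e-9)
  st <- attr(h, "stats")
  expect_gt(st$skewness, 0)
  expect_lt(st$mode, st$mean)
  # sigma = 0: degenerate single-bin histogram
  nb0 <- noise_block_raw(m, "internalization", 5L, "ki_cplx",
                         p0 = 0.1, sigma = 0, theta = 0.01)
  h0 <- stationary_histogram(nb0, horizon = 100, dt = 1, n_paths = 5,
                             burn_in = 50, seed = 4)
  expect_equal(nrow(h0), 1)
  expect_equal(h0$prob, 1)
})

test_that("noise blocks are kinetic-parameter subsets; deterministic is empty", {
  m <- the_model()
  for (b in c("receptor_ligand", "internalization", "endosomal_traffic",
              "synthesis", "degradation")) {
    nb <- noise_block(m, b, sigma = 0.001, theta = 0.05)
    expect_equal(nrow(nb), 3)
    expect_true(all(m$parameters$kinetic[nb$index]))
  }
  expect_equal(nrow(noise_block(m, "deterministic")), 0)
  expect_error(noise_block(m, "nonsense"), "unknown block")
  expect_warning(noise_block(m, "internalization", sigma = 1, theta = 1e-4),
                 "Feller")
})
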