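test_that("solver configuration enforces its invariants", {
  expect_error(solver_config(theta_scheme = 1.5))
  expect_error(solver_config(dt_stim = 1, dt_main = 0.5))
  cfg <- solver_config()
  expect_equal(cfg$theta_scheme, 0.5)
  expect_equal(cfg$dt_stim, 0.04)
  expect_equal(cfg$dt_main, 0.6)
  expect_equal(cfg$output_interval, 5)
})

test_that("noise-free step equals an independent Crank-Nicolson solve", {
  m <- the_model()
  y0 <- as.numeric(pre_equilibrate(m))
  st <- list(L = 50, Y = matrix(y0, m$n_species, 2),
             P = matrix(m$p, length(m$p), 2))
  dt <- 0.5
  out <- advance_step(m, st, dt,
                      config = solver_config(newton_tol = 1e-13,
                                             newton_max_iter = 40))
  # independent trapezoidal-rule implementation: damped Newton with a
  # numerically differenced Jacobian on the full coupled residual
  fmat <- function(L, Y) vapply(1:2, function(i)
    eng_cell_eval(m$net, L, Y[, i], m$p, m$E)$f, numeric(m$n_species))
  csum <- function(L, Y) sum(vapply(1:2, function(i)
    eng_cell_eval(m$net, L, Y[, i], m$p, m$E)$lig_flux, numeric(1)))
  ligsc <- m$p[["ligand_scale"]]
  resfn <- function(x) {
    L1 <- x[1]; Y1 <- matrix(x[-1], m$n_species, 2)
    c(L1 - st$L - dt / 2 * ligsc / 2 * (csum(L1, Y1) + csum(st$L, st$Y)),
      as.vector(Y1 - st$Y - dt / 2 * (fmat(L1, Y1) + fmat(st$L, st$Y))))
  }
  x <- c(st$L, as.vector(st$Y))
  for (it in 1:50) {
    r <- resfn(x)
    if (max(abs(r)) < 1e-13) break
    J <- matrix(0, length(x), length(x))
    for (j in seq_along(x)) {
      xp <- x; xp[j] <- xp[j] + 1e-7
      J[, j] <- (resfn(xp) - r) / 1e-7
    }
    x <- x - solve(J, r)
  }
  expect_lt(abs(out$L - x[1]), 1e-10)
  expect_lt(max(abs(out$Y - matrix(x[-1], m$n_species, 2))), 1e-10)
})

test_that("a zero-rate model leaves the state unchanged", {
  m <- the_model()
  p0 <- stats::setNames(rep(0, length(m$p)), names(m$p))
  e0 <- stats::setNames(rep(0, length(m$E)), names(m$E))
  e0["bolus_delay"] <- 1
  mz <- smad_model(params = p0, experiment = e0)
  y <- random_state(mz)
  st <- list(L = 5, Y = matrix(y, mz$n_species, 1))
  out <- advance_step(mz, st, dt = 1)
  expect_equal(out$Y[, 1], y, tolerance = 1e-14)
  expect_equal(out$L, 5)
})

test_that("deterministic ensembles are identical cells; seeds are byte-stable", {
  m <- the_model()
  sim <- simulate_ensemble(m, noise_block(m, "deterministic"),
                           stimulus_schedule(0, 100), n_cells = 10,
                           horizon = 360)
  expect_equal(max(abs(sim$ratio - sim$ratio[, 1])), 0)
  nb <- mild_internalization(m)
  a <- simulate_ensemble(m, nb, stimulus_schedule(0, 100), n_cells = 6,
                         horizon = 360, seed = 123)
  b <- simulate_ensemble(m, nb, stimulus_schedule(0, 100), n_cells = 6,
                         horizon = 360, seed = 123)
  expect_identical(a$ratio, b$ratio)
  expect_identical(a$ligand, b$ligand)
})

test_that("parameter noise creates cross-cell variability above zero", {
  m <- the_model()
  nb <- mild_internalization(m)
  sim <- simulate_ensemble(m, nb, stimulus_schedule(0, 100), n_cells = 12,
                           horizon = 1440, seed = 5)
  ps <- population_stats(sim)
  expect_gt(mean(ps$sd[ps$time >= 1080]), 0.01)
  expect_false(any(sim$failed))
  # stored output respects the clipping contract
  expect_true(all(sim$ratio >= 0, na.rm = TRUE))
  expect_true(all(sim$ligand >= 0))
})

test_that("adaptive Newton frees easy blocks before stiff ones", {
  # linear system: converges after a single update
  lin <- adaptive_newton(function(x) 2 * x - 4, function(x) matrix(2),
                         x0 = 0, tol = 1e-12)
  expect_true(all(lin$converged))
  expect_equal(lin$n_iter, 1)
  expect_equal(lin$x, 2)
  # two decoupled blocks: benign linear cell vs slowly converging stiff one
  f <- function(x) c(x[1] - 1, x[2]^9 - 1)
  j <- function(x) diag(c(1, 9 * x[2]^8))
  sol <- adaptive_newton(f, j, x0 = c(5, 3), blocks = list(1L, 2L),
                         tol = 1e-10, max_iter = 60)
  expect_true(all(sol$converged))
  expect_lt(sol$iterations[1], sol$iterations[2])
  expect_lt(max(abs(f(sol$x))), 1e-10)
})

test_that("coarse Brownian increments aggregate the fine ones exactly", {
  set.seed(11)
  J <- 2; N <- 3; nf <- 12; m <- 4; delta <- 0.25
  dB <- array(stats::rnorm(J * N * nf, sd = sqrt(delta)), c(J, N, nf))
  dZ <- array(stats::rnorm(J * N * nf, sd = delta^1.5), c(J, N, nf))
  agg <- aggregate_increments(dB, dZ, m, delta)
  # brute-force oracle: dZ over a coarse step is the sum of fine dZ plus
  # delta times the running Brownian increment before each fine step
  for (jj in 1:J) for (ii in 1:N) for (n in 1:(nf / m)) {
    idx <- ((n - 1) * m + 1):(n * m)
    expect_equal(agg$dB[jj, ii, n], sum(dB[jj, ii, idx]))
    z <- 0; b <- 0
    for (k in idx) {
      z <- z + dZ[jj, ii, k] + b * delta
      b <- b + dB[jj, ii, k]
    }
    expect_equal(agg$dZ[jj, ii, n], z, tolerance = 1e-12)
  }
})

test_that("the deterministic limit converges at second order", {
  m <- the_model()
  so <- empirical_strong_order(m, noise_block(m, "deterministic"),
                               dt_list = 0.03 * c(4, 8, 16, 32),
                               dt_ref = 0.03, n_paths = 1,
                               cells_per_ensemble = 1, horizon = 24,
                               L0 = 100, seed = 2)
  expect_gt(so$slope_full, 1.8)
  expect_lt(so$slope_full, 2.2)
  expect_error(empirical_strong_order(m, noise_block(m, "deterministic"),
                                      dt_list = c(0.06, 0.12), dt_ref = 0.03),
               "at least 3")
})

test_that("the discretized OU parameter path converges to its exact solution", {
  m <- the_model()
  p0 <- 0.2; sigma <- 0.03; theta <- 0.05
  ou <- noise_block_raw(m, "internalization", 5L, "ki_cplx",
                        p0 = p0, sigma = sigma, theta = theta, process = "ou")
  # zero-rate model so only the parameter dynamics evolve
  pz <- stats::setNames(rep(0, length(m$p)), names(m$p))
  pz["ligand_scale"] <- 1
  ez <- stats::setNames(rep(0, length(m$E)), names(m$E)); ez["bolus_delay"] <- 1
  mz <- smad_model(params = pz, experiment = ez)
  Tend <- 12; dtr <- 0.003
  nf <- round(Tend / dtr)
  set.seed(31)
  M <- array(stats::rnorm(nf), c(1, 1, nf))
  Nn <- array(stats::rnorm(nf), c(1, 1, nf))
  fine <- list(dB = sqrt(dtr) * M, dZ = 0.5 * dtr^1.5 * (M + Nn / sqrt(3)))
  # exact OU solution driven by the same increments (fine-grid quadrature
  # of the stochastic convolution integral)
  tgrid <- (seq_len(nf) - 0.5) * dtr   # midpoint weights: O((theta*dt)^2) bias
  conv <- sum(exp(-theta * (Tend - tgrid)) * fine$dB[1, 1, ])
  exact <- p0 + sigma * conv   # started at p0, so the drift terms cancel
  errs <- sapply(c(20, 40, 80), function(mm) {
    agg <- aggregate_increments(fine$dB, fine$dZ, mm, dtr)
    sim <- simulate_ensemble(mz, ou, NULL, n_cells = 1,
                             horizon = Tend, y0 = rep(1, mz$n_species),
                             L0 = 0, output_interval = Tend,
                             record_params = TRUE,
                             supplied_noise = list(dB = agg$dB, dZ = agg$dZ,
                                                   dt = mm * dtr),
                             equilibrate = FALSE)
    abs(sim$param_paths[1, 1, 2] - exact)
  })
  expect_true(all(diff(errs) > 0))  # error shrinks as dt shrinks
  expect_lt(errs[1], 1e-5)
})
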