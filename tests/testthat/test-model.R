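test_that("zero state with no ligand leaves only zeroth-order synthesis", {
  m <- the_model()
  f <- cell_rhs(m, 0, L = 0, y = rep(0, m$n_species))
  nz <- f[f != 0]
  expect_setequal(names(nz), c("R1", "R2", "S2c", "S4c"))
  expect_equal(unname(nz["R1"]), m$E[["prod_r1"]] * m$p[["ksyn_r1"]])
  expect_equal(unname(nz["R2"]), m$E[["prod_r2"]] * m$p[["ksyn_r2"]])
  expect_equal(unname(nz["S2c"]), m$E[["prod_s2"]] * m$p[["ksyn_s2"]])
  expect_equal(unname(nz["S4c"]), m$E[["prod_s4"]] * m$p[["ksyn_s4"]])
})

test_that("total SMAD2 is conserved when synthesis and turnover are off", {
  m <- set_params(the_model(), params = c(ksyn_s2 = 0, kdeg_s2 = 0))
  w <- smad2_weights(m)
  set.seed(42)
  for (rep in 1:10) {
    y <- random_state(m)
    f <- cell_rhs(m, 0, L = stats::runif(1, 0, 100), y = y)
    expect_equal(sum(w * f), 0, tolerance = 1e-12)
  }
})

test_that("species fed only by internalization decay when it is switched off", {
  m0 <- the_model()
  # identify species whose producing reactions all carry internalization-
  # block rate constants (term-by-term inspection of the network)
  int_idx <- m0$parameters$index[m0$parameters$block %in% "internalization"] - 1L
  fed_only <- vapply(seq_len(m0$n_species), function(s) {
    prod_rxn <- which(m0$net$S[s, ] > 0)
    length(prod_rxn) > 0 &&
      all(m0$net$ktype[prod_rxn] == 0 & m0$net$kidx[prod_rxn] %in% int_idx)
  }, logical(1))
  expect_true(any(fed_only))
  m <- set_params(m0, params = c(ki_r1 = 0, ki_r2 = 0, ki_cplx = 0, ki_lr2 = 0))
  set.seed(7)
  for (rep in 1:10) {
    f <- cell_rhs(m, 0, L = stats::runif(1, 0, 100), y = random_state(m))
    expect_true(all(f[fed_only] <= 1e-12))
  }
})

test_that("cell_rhs rejects malformed states", {
  m <- the_model()
  expect_error(cell_rhs(m, 0, 0, rep(0, 5)), "length")
  expect_error(cell_rhs(m, 0, 0, c(rep(0, 21), NaN)), "NaN")
})

test_that("ligand equation: no ligand and no complexes means no change", {
  m <- the_model()
  yeq <- pre_equilibrate(m)        # L = 0 equilibrium has no bound complexes
  cells <- list(list(y = yeq))
  expect_equal(ligand_rhs(m, 0, L = 0, cells = cells), 0, tolerance = 1e-12)
  expect_error(ligand_rhs(m, 0, 0, list()), "non-empty")
})

test_that("deterministic ligand consumption is independent of ensemble size", {
  m <- the_model()
  y <- random_state(m)
  set.seed(1)
  one <- ligand_rhs(m, 0, L = 50, cells = list(list(y = y)))
  many <- ligand_rhs(m, 0, L = 50, cells = replicate(100, list(y = y),
                                                     simplify = FALSE))
  expect_equal(one, many, tolerance = 1e-12)
})

test_that("with binding switched off the ligand equation is input only", {
  m <- set_params(the_model(), params = c(kon_l_r2 = 0, koff_l_r2 = 0))
  sched <- stimulus_schedule(0, 100)
  y <- random_state(m)
  inp <- ligand_rhs(m, t = 0.5, L = 10, cells = list(list(y = y)),
                    schedule = sched)
  expect_equal(inp, m$E[["bolus_factor"]] * m$p[["dose_scale"]] * 100 /
                 m$E[["bolus_delay"]])
})

test_that("nuc/cyt ratio follows its defining weights", {
  m <- the_model()
  sp <- function(...) {
    y <- rep(0, m$n_species)
    v <- list(...)
    y[match(names(v), m$species)] <- unlist(v)
    y
  }
  expect_equal(nuc_cyt_ratio(m, sp(S2c = 1)), 0)
  expect_equal(nuc_cyt_ratio(m, sp(pS2n = 1, S2c = 1)), 1)
  expect_equal(nuc_cyt_ratio(m, sp(pS2n = 2, T3n = 1, S2c = 1, T3c = 1)), 1.25)
  expect_error(nuc_cyt_ratio(m, sp(pS2n = 1)), "degenerate")
})

test_that("pre-equilibration returns a fixed point of the kinetics", {
  m <- the_model()
  y <- pre_equilibrate(m, tol = 1e-10)
  expect_lt(attr(y, "residual"), 1e-10)
  expect_lt(max(abs(cell_rhs(m, 0, 0, as.numeric(y)))), 1e-10)
  y2 <- pre_equilibrate(m, tol = 1e-10)
  expect_equal(as.numeric(y), as.numeric(y2), tolerance = 1e-9)
  sim <- simulate_ensemble(m, NULL, stimulus_schedule(0, 100), n_cells = 1,
                           horizon = 720, y0 = as.numeric(y))
  r0 <- nuc_cyt_ratio(m, as.numeric(y))
  expect_gt(r0, 0)
  expect_lt(r0, max(sim$ratio))
})

test_that("saturating bolus produces a transient peak and elevated plateau", {
  m <- the_model()
  sim <- simulate_ensemble(m, NULL, stimulus_schedule(0, 100), n_cells = 1,
                           horizon = 1440)
  r <- sim$ratio[, 1]
  tt <- sim$time
  expect_gt(max(r), r[1])
  expect_gt(tt[which.max(r)], 0)
  expect_lt(tt[which.max(r)], 240)
  plateau <- mean(r[tt >= 1080])
  expect_gt(plateau, r[1])
  expect_lt(plateau, max(r))
})

test_that("deterministic trajectories are identical across ensemble sizes", {
  m <- the_model()
  s1 <- simulate_ensemble(m, NULL, stimulus_schedule(0, 100), n_cells = 1,
                          horizon = 360)
  s8 <- simulate_ensemble(m, NULL, stimulus_schedule(0, 100), n_cells = 8,
                          horizon = 360)
  expect_equal(max(abs(s1$ligand - s8$ligand)), 0)
  expect_equal(max(abs(s8$ratio - s8$ratio[, 1])), 0)
  expect_equal(max(abs(s1$ratio[, 1] - s8$ratio[, 1])), 0)
})

test_that("model definition round-trips parameter overrides", {
  m <- the_model()
  m2 <- set_params(m, params = c(kphos = 0.123),
                   experiment = c(bolus_delay = 2))
  expect_equal(m2$p[["kphos"]], 0.123)
  expect_equal(m2$E[["bolus_delay"]], 2)
  expect_error(set_params(m, params = c(nope = 1)), "unknown")
})
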