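#' Simulate an ensemble with additive control noise
#'
#' Runs the stochastic ensemble at the requested dose and adds
#' control-like technical noise (measured control traces normalized to
#' mean zero, or the synthetic surrogate) to the ratio trajectories after
#' the numerical computation, mirroring how unstimulated-control
#' fluctuations enter the modeled populations. With the `deterministic`
#' block this reproduces the "deterministic model" comparator, whose only
#' temporal noise is the control component.
#'
#' @param model a [smad_model()].
#' @param noise a [noise_block()] or block name (string).
#' @param dose bolus dose in pM.
#' @param n_cells ensemble size.
#' @param config a [solver_config()].
#' @param horizon simulated minutes.
#' @param seed integer seed (covers simulation and noise sampling).
#' @param control_noise `NULL` (none), a [control_noise_spec()], or a
#'   mean-zero matrix of measured control traces (time x cells) from which
#'   columns are resampled with replacement per simulated cell.
#' @param schedule optional [stimulus_schedule()] overriding `dose`.
#' @return a `smad_ensemble` with noise-augmented ratio trajectories.
#' @export
run_simulation <- function(model, noise = "deterministic", dose = 100,
                           n_cells = 100, config = solver_config(),
                           horizon = 1440, seed = NULL,
                           control_noise = NULL, schedule = NULL) {
  if (is.character(noise)) noise <- noise_block(model, noise)
  if (is.null(schedule)) schedule <- stimulus_schedule(0, dose)
  sim <- simulate_ensemble(model, noise, schedule, n_cells = n_cells,
                           config = config, horizon = horizon, seed = seed)
  if (!is.null(control_noise)) {
    nt <- nrow(sim$ratio)
    add <- if (inherits(control_noise, "control_noise_spec")) {
      generate_control_noise(control_noise, n_cells, horizon,
                             dx = sim$meta$output_interval)$noise
    } else {
      m <- as.matrix(control_noise)
      if (nrow(m) < nt) stop("control traces shorter than the simulation")
      m[seq_len(nt), sample.int(ncol(m), n_cells, replace = TRUE), drop = FALSE]
    }
    sim$ratio <- sim$ratio + add[seq_len(nt), , drop = FALSE]
    sim$meta$control_noise <- TRUE
  }
  sim
}

#' Fit configuration for noise-parameter estimation
#'
#' Per stochastic parameter of the chosen block three coefficients are
#' free (initial value `p0`, diffusion `sigma`, reversion `theta`), so the
#' search dimension is `3 |S|` (between 3 and 9 for the shipped blocks).
#' All coefficients are searched on log10 scale inside box bounds.
#'
#' @param n_cells ensemble size per objective evaluation.
#' @param dose fitted stimulation dose (pM).
#' @param horizon simulated minutes per evaluation.
#' @param p0_log_range log10 bounds of `p0` relative to the model default
#'   (e.g. `c(-1, 1)` = a factor of 10 either way).
#' @param sigma_log_range,theta_log_range absolute log10 bounds.
#' @param detection a [detection_config()] shared by model and data.
#' @param control_noise optional [control_noise_spec()] added to the model
#'   trajectories (common seed).
#' @param seed integer seed reused for every evaluation (common random
#'   numbers, making the objective a deterministic function of the
#'   coefficients).
#' @param ess list of [scatter_search()] settings.
#' @param solver a [solver_config()].
#' @param tie_coefficients share one `sigma` and one `theta` across the
#'   block's parameters (used e.g. for self-consistency recovery runs
#'   whose ground truth has a single `(sigma*, theta*)` pair).
#' @param fix_p0 keep `p0` at the block's values instead of fitting it.
#' @return list of class `fit_config`.
#' @export
fit_config <- function(n_cells = 375, dose = 100, horizon = 1440,
                       p0_log_range = c(-1, 1),
                       sigma_log_range = c(-3, -0.5),
                       theta_log_range = c(-3, -0.5),
                       detection = detection_config(),
                       control_noise = NULL, seed = 1,
                       ess = list(), solver = solver_config(),
                       tie_coefficients = FALSE, fix_p0 = FALSE) {
  ess_def <- list(n_lhs = NULL, ref_size = 6, max_iter = 10,
                  stag_tol = 1e-3, stag_patience = 3)
  ess_def[names(ess)] <- ess
  structure(list(n_cells = n_cells, dose = dose, horizon = horizon,
                 p0_log_range = p0_log_range,
                 sigma_log_range = sigma_log_range,
                 theta_log_range = theta_log_range,
                 detection = detection, control_noise = control_noise,
                 seed = seed, ess = ess_def, solver = solver,
                 tie_coefficients = tie_coefficients, fix_p0 = fix_p0),
            class = "fit_config")
}

target_summary <- function(target, detection) {
  if (is.list(target) && !is.null(target$catalog)) return(target)
  if (inherits(target, "smad_ensemble")) {
    return(population_summary(target, detection))
  }
  if (is.list(target) && !is.null(target$ratio)) {
    return(population_summary(target$ratio, detection, time = target$time))
  }
  stop("target must be an ensemble, a list(time, ratio) or a population summary")
}

#' Fit the noise coefficients of a block model
#'
#' Estimates `(p0, sigma, theta)` per stochastic parameter of a block by
#' minimizing the scalar burst-statistics objective against a target
#' population, using scatter search with common random numbers per
#' evaluation. The `deterministic` block has no free coefficients and
#' returns its fixed objective without searching.
#'
#' @param model a [smad_model()].
#' @param block block name or [noise_block()] (whose `p0` seeds the search).
#' @param target the data population: a `smad_ensemble`, a
#'   `list(time, ratio)`, or a [population_summary()].
#' @param config a [fit_config()].
#' @return object of class `smad_fit`: list with `block`, `coefficients`
#'   (tibble `name`, `p0`, `sigma`, `theta`), `value` (scalar objective at
#'   the optimum), `trace` (full evaluation log), `noise` (the fitted
#'   [noise_block()]), `objective` (component table at the optimum).
#' @export
fit_block_model <- function(model, block, target, config = fit_config()) {
  nb0 <- if (is.character(block)) noise_block(model, block) else block
  block_name <- attr(nb0, "block")
  tgt <- target_summary(target, config$detection)

  eval_noise <- function(nb) {
    sim <- run_simulation(model, nb, dose = config$dose,
                          n_cells = config$n_cells, config = config$solver,
                          horizon = config$horizon, seed = config$seed,
                          control_noise = config$control_noise)
    obj <- assemble_objective(population_summary(sim, config$detection), tgt)
    obj
  }
  if (nrow(nb0) == 0) {
    obj <- eval_noise(nb0)
    return(structure(list(block = block_name,
                          coefficients = tibble::tibble(name = character(),
                                                        p0 = numeric(),
                                                        sigma = numeric(),
                                                        theta = numeric()),
                          value = objective_scalar(obj), trace = NULL,
                          noise = nb0, objective = obj, n_eval = 1L),
                     class = "smad_fit"))
  }
  np <- nrow(nb0)
  ns_free <- if (config$tie_coefficients) 1L else np
  lower <- upper <- numeric(0)
  if (!config$fix_p0) {
    lower <- log10(nb0$p0) + config$p0_log_range[1]
    upper <- log10(nb0$p0) + config$p0_log_range[2]
  }
  lower <- c(lower, rep(config$sigma_log_range[1], ns_free),
             rep(config$theta_log_range[1], ns_free))
  upper <- c(upper, rep(config$sigma_log_range[2], ns_free),
             rep(config$theta_log_range[2], ns_free))
  n_p0 <- if (config$fix_p0) 0L else np
  make_block <- function(v) {
    p0 <- if (config$fix_p0) nb0$p0 else 10^v[seq_len(np)]
    sg <- 10^v[n_p0 + seq_len(ns_free)]
    tht <- 10^v[n_p0 + ns_free + seq_len(ns_free)]
    noise_block_raw(model, block_name, nb0$index, nb0$name,
                    p0 = p0, sigma = rep_len(sg, np),
                    theta = rep_len(tht, np),
                    process = attr(nb0, "process"))
  }
  fn <- function(v) objective_scalar(eval_noise(make_block(v)))
  ess <- config$ess
  res <- scatter_search(fn, lower, upper,
                        n_lhs = ess$n_lhs %||% (10 * length(lower)),
                        ref_size = ess$ref_size, max_iter = ess$max_iter,
                        stag_tol = ess$stag_tol,
                        stag_patience = ess$stag_patience,
                        seed = config$seed)
  nb_best <- make_block(res$par)
  obj <- eval_noise(nb_best)
  structure(list(block = block_name,
                 coefficients = tibble::tibble(name = nb_best$name,
                                               p0 = nb_best$p0,
                                               sigma = nb_best$sigma,
                                               theta = nb_best$theta),
                 value = objective_scalar(obj), trace = res$trace,
                 noise = nb_best, objective = obj, n_eval = res$n_eval,
                 stopped = res$stopped),
            class = "smad_fit")
}

# noise_block with explicit indices/values (no table lookup, no warning spam)
noise_block_raw <- function(model, block_name, index, name, p0, sigma, theta,
                            process = "cir") {
  out <- tibble::tibble(index = index, name = name, p0 = p0,
                        sigma = sigma, theta = theta)
  attr(out, "block") <- block_name
  attr(out, "process") <- process
  class(out) <- c("noise_block", class(out))
  out
}

#' @export
print.smad_fit <- function(x, ...) {
  cat("<smad_fit> block '", x$block, "', objective ", format(x$value),
      " after ", x$n_eval, " evaluation(s)\n", sep = "")
  if (nrow(x$coefficients)) print(x$coefficients)
  invisible(x)
}

#' @export
tidy.smad_fit <- function(x, ...) x$coefficients

#' @export
glance.smad_fit <- function(x, ...) {
  tibble::tibble(block = x$block, value = x$value, n_eval = x$n_eval,
                 n_free = 3L * nrow(x$coefficients))
}

#' Compare block models against a common target
#'
#' Builds the model-discrimination report: one row per block model with
#' the summed weighted height/duration contributions for burst indices
#' 1-4, the count, snapshot-mean and snapshot-standard-deviation
#' contributions, the scalar norm, and AIC diagnostics from the rescaled
#' residual model.
#'
#' @param model a [smad_model()].
#' @param target the data population (see [fit_block_model()]).
#' @param fits named list of `smad_fit` objects and/or [noise_block()]s;
#'   names are the report rows.
#' @param config a [fit_config()] (evaluation settings only).
#' @return tibble sorted by `norm`, with attribute `objectives` (the full
#'   component tables).
#' @export
compare_models <- function(model, target, fits, config = fit_config()) {
  tgt <- target_summary(target, config$detection)
  rows <- list(); objs <- list()
  for (nm in names(fits)) {
    f <- fits[[nm]]
    nb <- if (inherits(f, "smad_fit")) f$noise else f
    sim <- run_simulation(model, nb, dose = config$dose,
                          n_cells = config$n_cells, config = config$solver,
                          horizon = config$horizon, seed = config$seed,
                          control_noise = config$control_noise)
    obj <- assemble_objective(population_summary(sim, config$detection), tgt)
    objs[[nm]] <- obj
    v <- stats::setNames(obj$value, obj$component)
    n_free <- if (inherits(f, "smad_fit")) 3L * nrow(f$coefficients) else
      3L * nrow(nb)
    groups <- dplyr::case_when(
      grepl("^height", obj$component) ~ "height",
      grepl("^dur", obj$component) ~ "duration",
      TRUE ~ obj$component)
    ar <- suppressWarnings(aic_rescale(obj$value, groups, n_fitted = n_free))
    rows[[nm]] <- tibble::tibble(
      model = nm,
      height_1 = v["height_med_1"] + v["height_std_1"],
      height_2 = v["height_med_2"] + v["height_std_2"],
      height_3 = v["height_med_3"] + v["height_std_3"],
      height_4 = v["height_med_4"] + v["height_std_4"],
      duration_1 = v["dur_med_1"] + v["dur_std_1"],
      duration_2 = v["dur_med_2"] + v["dur_std_2"],
      duration_3 = v["dur_med_3"] + v["dur_std_3"],
      duration_4 = v["dur_med_4"] + v["dur_std_4"],
      count = v["count_mean"] + v["count_std"],
      mean = v["pop_mean"], std = v["pop_std"],
      norm = objective_scalar(obj),
      n_free = n_free, aic = ar$aic)
  }
  out <- dplyr::arrange(dplyr::bind_rows(rows), .data$norm)
  out$aic_ratio <- out$aic / out$aic[1]
  attr(out, "objectives") <- objs
  out
}

#' Predict burst statistics at new doses
#'
#' Simulates the fitted model at doses not used for fitting (only the
#' stimulus dose changes; coefficients are fixed) and summarizes the
#' detected burst statistics per dose.
#'
#' @param model a [smad_model()].
#' @param fit a `smad_fit` or [noise_block()] with fitted coefficients.
#' @param doses numeric doses in pM.
#' @param n_cells ensemble size per dose.
#' @param config a [fit_config()] (solver/detection/control-noise settings).
#' @param seed integer seed (one stream per dose, derived).
#' @return tibble (`dose`, `mean_count`, `sd_count`, `median_height`,
#'   `median_duration`, `n_cells`, `n_failed`) with attribute `catalogs`.
#' @export
predict_dose <- function(model, fit, doses, n_cells = 100,
                         config = fit_config(), seed = 1) {
  nb <- if (inherits(fit, "smad_fit")) fit$noise else fit
  rows <- list(); cats <- list()
  for (i in seq_along(doses)) {
    sim <- run_simulation(model, nb, dose = doses[i], n_cells = n_cells,
                          config = config$solver, horizon = config$horizon,
                          seed = seed + i - 1,
                          control_noise = config$control_noise)
    cat_i <- detect_bursts(sim, config$detection)
    cats[[as.character(doses[i])]] <- cat_i
    rows[[i]] <- tibble::tibble(
      dose = doses[i],
      mean_count = mean(cat_i$cells$count, na.rm = TRUE),
      sd_count = stats::sd(cat_i$cells$count, na.rm = TRUE),
      median_height = stats::median(cat_i$bursts$height),
      median_duration = stats::median(cat_i$bursts$duration),
      n_cells = n_cells, n_failed = sum(cat_i$cells$failed))
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "catalogs") <- cats
  out
}

#' Restimulation experiment configuration
#'
#' @param doses doses (pM) of the first and second bolus.
#' @param times bolus times (minutes); the second bolus raises the ligand
#'   from its current value to the target dose.
#' @param peak_times read-out times (minutes) of the first and second
#'   population-average peaks.
#' @param horizon simulated minutes.
#' @param n_cells cells per (sub)ensemble.
#' @param dose_factor ligand-charge dose factor.
#' @param feedback_factor scaling of the feedback-induction parameter in
#'   the reduced-feedback variant.
#' @param smad4_factor scaling of SMAD4 production (and hence of the
#'   equilibrated total SMAD4) in the reduced-SMAD4 variant.
#' @param mixture fractions (summing to 1) of the baseline and
#'   SMAD4-reduced subpopulations in the merged ensemble.
#' @param recompute_peaks recompute read-out times from the simulated
#'   population average instead of using `peak_times`.
#' @return list of class `restim_config`.
#' @export
restim_config <- function(doses = c(5, 5), times = c(0, 360),
                          peak_times = c(55, 480), horizon = 720,
                          n_cells = 100, dose_factor = 1,
                          feedback_factor = 0.3, smad4_factor = 0.6,
                          mixture = c(0.5, 0.5), recompute_peaks = FALSE) {
  stopifnot(length(doses) == 2, length(times) == 2, times[1] < times[2],
            all(peak_times <= horizon), abs(sum(mixture) - 1) < 1e-9)
  structure(list(doses = doses, times = times, peak_times = peak_times,
                 horizon = horizon, n_cells = n_cells,
                 dose_factor = dose_factor,
                 feedback_factor = feedback_factor,
                 smad4_factor = smad4_factor, mixture = mixture,
                 recompute_peaks = recompute_peaks),
            class = "restim_config")
}

peak_readout <- function(sim, peak_times) {
  idx <- vapply(peak_times, function(tp) which.min(abs(sim$time - tp)), integer(1))
  tibble::tibble(cell = colnames(sim$ratio),
                 peak1 = sim$ratio[idx[1], ],
                 peak2 = sim$ratio[idx[2], ])
}

#' Simulate repeated stimulation and peak correlations
#'
#' Applies two boluses (the second raising the ligand from its current
#' value to the target dose), reads per-cell peak heights at the
#' population-average peak times, and reports peak statistics, their
#' Pearson correlation and population quantile bands for the baseline
#' model plus variants: reduced feedback induction, homogeneously reduced
#' SMAD4, and a merged ensemble combining baseline and SMAD4-reduced
#' subpopulations (temporally stable noise on top of the fluctuating
#' CIR noise).
#'
#' @param model a [smad_model()].
#' @param noise a [noise_block()] or `smad_fit`.
#' @param config a [restim_config()].
#' @param solver a [solver_config()].
#' @param seed integer seed.
#' @param control_noise optional [control_noise_spec()].
#' @param variants character subset of
#'   `c("baseline", "feedback", "smad4", "merged")`.
#' @return object of class `smad_restim`: list with `peaks` (per variant),
#'   `summary` tibble, `bands` (time-resolved quantiles), `peak_times`.
#' @export
run_restimulation <- function(model, noise, config = restim_config(),
                              solver = solver_config(), seed = 1,
                              control_noise = NULL,
                              variants = c("baseline", "feedback",
                                           "smad4", "merged")) {
  nb <- if (inherits(noise, "smad_fit")) noise$noise else noise
  sched <- stimulus_schedule(time = config$times, dose = config$doses,
                             raise_to = c(FALSE, TRUE),
                             dose_factor = config$dose_factor)
  fb_name <- model$parameters$name[39]
  models <- list(baseline = model)
  if ("feedback" %in% variants || "merged" %in% variants) {
    models$feedback <- set_params(model,
      params = stats::setNames(model$p[[fb_name]] * config$feedback_factor, fb_name))
  }
  if ("smad4" %in% variants || "merged" %in% variants) {
    models$smad4 <- set_params(model,
      experiment = c(prod_s4 = unname(model$E[["prod_s4"]]) * config$smad4_factor))
  }
  sim_one <- function(mod, n, sd_off = 0) {
    run_simulation(mod, nb, n_cells = n, config = solver,
                   horizon = config$horizon, seed = seed + sd_off,
                   control_noise = control_noise, schedule = sched)
  }
  sims <- list()
  for (v in intersect(variants, c("baseline", "feedback", "smad4"))) {
    sims[[v]] <- sim_one(models[[v]], config$n_cells,
                         sd_off = match(v, c("baseline", "feedback", "smad4")) - 1)
  }
  if ("merged" %in% variants) {
    n1 <- round(config$n_cells * config$mixture[1])
    n2 <- config$n_cells - n1
    s1 <- if (!is.null(sims$baseline) && n1 == config$n_cells) sims$baseline else
      sim_one(models$baseline, max(n1, 1), sd_off = 0)
    s2 <- sim_one(models$smad4, max(n2, 1), sd_off = 7)
    merged <- s1
    merged$ratio <- cbind(s1$ratio[, seq_len(n1), drop = FALSE],
                          s2$ratio[, seq_len(n2), drop = FALSE])
    colnames(merged$ratio) <- sprintf("cell_%04d", seq_len(n1 + n2))
    merged$failed <- c(s1$failed[seq_len(n1)], s2$failed[seq_len(n2)])
    merged$meta$n_cells <- n1 + n2
    sims$merged <- merged
  }
  peak_times <- config$peak_times
  if (config$recompute_peaks && !is.null(sims$baseline)) {
    ps <- population_stats(sims$baseline)
    w1 <- ps$time < config$times[2]
    peak_times <- c(ps$time[w1][which.max(ps$mean[w1])],
                    ps$time[!w1][which.max(ps$mean[!w1])])
  }
  peaks <- list(); rows <- list(); bands <- list()
  for (v in names(sims)) {
    pk <- peak_readout(sims[[v]], peak_times)
    peaks[[v]] <- pk
    v1 <- stats::var(pk$peak1, na.rm = TRUE)
    v2 <- stats::var(pk$peak2, na.rm = TRUE)
    degenerate <- !is.finite(v1) || !is.finite(v2) || v1 == 0 || v2 == 0
    rows[[v]] <- tibble::tibble(
      variant = v,
      peak1_mean = mean(pk$peak1, na.rm = TRUE),
      peak2_mean = mean(pk$peak2, na.rm = TRUE),
      peak2_over_peak1 = mean(pk$peak2, na.rm = TRUE) / mean(pk$peak1, na.rm = TRUE),
      peak1_var = v1, peak2_var = v2,
      correlation = if (degenerate) NA_real_ else
        stats::cor(pk$peak1, pk$peak2, use = "complete.obs"),
      degenerate = degenerate)
    qs <- apply(sims[[v]]$ratio, 1, stats::quantile,
                probs = c(0.25, 0.5, 0.75), na.rm = TRUE)
    bands[[v]] <- tibble::tibble(variant = v, time = sims[[v]]$time,
                                 q25 = qs[1, ], median = qs[2, ], q75 = qs[3, ])
  }
  structure(list(peaks = peaks, summary = dplyr::bind_rows(rows),
                 bands = dplyr::bind_rows(bands), peak_times = peak_times,
                 config = config),
            class = "smad_restim")
}

#' @export
print.smad_restim <- function(x, ...) {
  cat("<smad_restim> read-outs at", paste(round(x$peak_times), collapse = " / "),
      "min\n")
  print(x$summary)
  invisible(x)
}

#' Feedback-reduction simulation
#'
#' Simulates a single stimulation with the feedback-induction parameter
#' scaled by `factor` and reports the change in burst statistics and
#' population response relative to the unmodified model (same seed).
#'
#' @param model a [smad_model()].
#' @param noise a [noise_block()] or `smad_fit`.
#' @param factor multiplicative reduction of the feedback-induction
#'   parameter (1 = no change).
#' @param dose stimulation dose (pM).
#' @param n_cells ensemble size.
#' @param config a [fit_config()] (solver/detection settings).
#' @param seed integer seed shared by both runs.
#' @return tibble with one row per arm (`baseline`, `reduced`) and the
#'   deltas as attribute `delta`.
#' @export
feedback_reduction_run <- function(model, noise, factor = 0.3, dose = 100,
                                   n_cells = 100, config = fit_config(),
                                   seed = 1) {
  nb <- if (inherits(noise, "smad_fit")) noise$noise else noise
  fb_name <- model$parameters$name[39]
  m_red <- set_params(model, params = stats::setNames(
    model$p[[fb_name]] * factor, fb_name))
  arms <- list(baseline = model, reduced = m_red)
  rows <- list()
  for (a in names(arms)) {
    sim <- run_simulation(arms[[a]], nb, dose = dose, n_cells = n_cells,
                          config = config$solver, horizon = config$horizon,
                          seed = seed, control_noise = config$control_noise)
    ct <- detect_bursts(sim, config$detection)
    ps <- population_stats(sim)
    rows[[a]] <- tibble::tibble(
      arm = a, factor = if (a == "baseline") 1 else factor,
      mean_count = mean(ct$cells$count, na.rm = TRUE),
      median_height = stats::median(ct$bursts$height),
      median_duration = stats::median(ct$bursts$duration),
      sd_height = stats::sd(ct$bursts$height),
      peak_mean = max(ps$mean, na.rm = TRUE),
      plateau_mean = mean(ps$mean[ps$time >= 0.75 * max(ps$time)], na.rm = TRUE))
  }
  out <- dplyr::bind_rows(rows)
  delta <- out[2, -(1:2)] - out[1, -(1:2)]
  attr(out, "delta") <- delta
  out
}

#' Ligand-charge adjustment
#'
#' Different recombinant ligand charges have slightly different
#' activities. This helper adapts the forward and backward ligand-binding
#' rates and a dose factor so that the deterministic population average
#' matches a target average, using only time points after the second
#' stimulus (to avoid over-adaptation). One-dimensional log-scale
#' optimization per parameter, cycled.
#'
#' @param model a [smad_model()].
#' @param target tibble (`time`, `mean`) of the target population average.
#' @param config a [restim_config()].
#' @param solver a [solver_config()].
#' @param n_sweeps coordinate sweeps.
#' @return list with `params` (named: binding on/off rates, `dose_factor`),
#'   `sse`, and the adjusted `model`.
#' @export
adjust_ligand_charge <- function(model, target, config = restim_config(),
                                 solver = solver_config(), n_sweeps = 2) {
  kon_name <- model$parameters$name[49]
  koff_name <- model$parameters$name[20]
  after <- target$time >= config$times[2]
  stopifnot(any(after))
  cur <- c(log10(model$p[[kon_name]]), log10(model$p[[koff_name]]), 0)
  sse_at <- function(v) {
    m2 <- set_params(model, params = stats::setNames(10^v[1:2],
                                                     c(kon_name, koff_name)))
    sched <- stimulus_schedule(config$times, config$doses,
                               raise_to = c(FALSE, TRUE),
                               dose_factor = 10^v[3])
    sim <- simulate_ensemble(m2, NULL, sched, n_cells = 1,
                             config = solver, horizon = config$horizon)
    idx <- match(target$time[after], sim$time)
    sum((sim$ratio[idx, 1] - target$mean[after])^2)
  }
  for (s in seq_len(n_sweeps)) {
    for (d in 1:3) {
      opt <- stats::optimize(function(z) { v <- cur; v[d] <- z; sse_at(v) },
                             lower = cur[d] - 0.7, upper = cur[d] + 0.7)
      cur[d] <- opt$minimum
    }
  }
  params <- stats::setNames(c(10^cur[1], 10^cur[2], 10^cur[3]),
                            c(kon_name, koff_name, "dose_factor"))
  list(params = params, sse = sse_at(cur),
       model = set_params(model, params = stats::setNames(10^cur[1:2],
                                                          c(kon_name, koff_name))))
}
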