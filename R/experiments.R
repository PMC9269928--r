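#' Burst-detection operating point on the synthetic benchmark
#'
#' Generates the default labeled benchmark (positive trajectories with
#' injected Gaussian-hill bursts plus control-like noise; negatives with
#' noise only; 24-hour horizon at 5-minute sampling), samples detection
#' configurations by latin hypercube, scores each by matched-burst
#' sensitivity and false-detection rate, and returns the operating point
#' of the configuration selected under the false-detection-rate
#' constraint.
#'
#' @param seed integer seed (benchmark and candidate sampling).
#' @param n_pos,n_neg benchmark sizes.
#' @param n_samples number of sampled detection configurations.
#' @param fdr_max constraint on the false-detection rate.
#' @return list with `sensitivity`, `fdr` (fractions), `roc` (the
#'   [tune_detection()] object) and `benchmark`.
#' @export
roc_operating_point <- function(seed = 1, n_pos = 200, n_neg = 200,
                                n_samples = 500, fdr_max = 0.25) {
  bench <- suppressWarnings(
    generate_benchmark(NULL, n_pos = n_pos, n_neg = n_neg, seed = seed))
  roc <- suppressWarnings(
    tune_detection(bench, n_samples = n_samples, seed = seed,
                   fdr_max = fdr_max))
  list(sensitivity = roc$best$sensitivity, fdr = roc$best$fdr,
       roc = roc, benchmark = bench)
}

#' Strong-convergence study of the path scheme on the signaling model
#'
#' Runs [empirical_strong_order()] on the stochastic model in the regime
#' where the scheme's asymptotic order is observable: internalization-block
#' CIR noise with reversion rate 0.2/min and diffusion coefficients at a
#' Feller ratio of 4 (`sigma_j = sqrt(2 theta p0_j / 4)`), strong enough
#' that the stochastic error dominates the deterministic O(dt^2) component
#' over the tested steps and far enough from the zero boundary that
#' clipping never triggers. Reference step 0.03; coarser steps are integer
#' multiples driven by aggregated increments of the same Brownian paths.
#'
#' @param seed integer seed.
#' @param n_paths number of sample paths (cells across coupled ensembles
#'   of 8).
#' @param model a [smad_model()].
#' @param dt_mult integer multiples of the reference step to test.
#' @return a `strong_order` object (slopes over all steps and over the
#'   three finest).
#' @export
solver_order_study <- function(seed = 1, n_paths = 32, model = smad_model(),
                               dt_mult = c(2, 4, 8, 16, 32)) {
  tab <- dplyr::filter(model$parameters, .data$block %in% "internalization")
  theta <- 0.2
  nb <- noise_block_raw(model, "internalization", tab$index, tab$name,
                        p0 = tab$value,
                        sigma = sqrt(2 * theta * tab$value / 4),
                        theta = rep(theta, nrow(tab)))
  empirical_strong_order(model, nb, dt_list = 0.03 * dt_mult, dt_ref = 0.03,
                         n_paths = n_paths, cells_per_ensemble = 8,
                         horizon = 48, L0 = 100, seed = seed)
}

#' Self-consistency recovery of noise coefficients
#'
#' Generates a target population from the internalization block with one
#' known `(sigma*, theta*)` pair shared across the block's parameters,
#' then refits those two coefficients (scatter search, common random
#' numbers, `p0` fixed at the generating values) at a reduced ensemble
#' size. With common random numbers the objective is exactly zero at the
#' truth, so the study measures optimizer accuracy at the desk-scale
#' budget.
#'
#' @param seed integer seed (target generation and search).
#' @param n_cells ensemble size of target and evaluations.
#' @param sigma_true,theta_true generating coefficients.
#' @param budget list of scatter-search settings.
#' @param model a [smad_model()].
#' @return list with `fit` (the `smad_fit`), `sigma_ratio`, `theta_ratio`
#'   (fitted over true).
#' @export
noise_recovery_study <- function(seed = 21, n_cells = 64,
                                 sigma_true = 0.05, theta_true = 0.02,
                                 budget = list(n_lhs = 12, ref_size = 4,
                                               max_iter = 3,
                                               stag_patience = 2),
                                 model = smad_model()) {
  tab <- dplyr::filter(model$parameters, .data$block %in% "internalization")
  det <- detection_config(height_threshold = 0.05, burst_bandwidth = 35,
                          trend_bandwidth = 180, duration_bounds = c(75, 430))
  truth <- noise_block_raw(model, "internalization", tab$index, tab$name,
                           p0 = tab$value,
                           sigma = rep(sigma_true, nrow(tab)),
                           theta = rep(theta_true, nrow(tab)))
  target <- run_simulation(model, truth, dose = 100, n_cells = n_cells,
                           seed = seed)
  fc <- fit_config(n_cells = n_cells, seed = seed, detection = det,
                   tie_coefficients = TRUE, fix_p0 = TRUE,
                   sigma_log_range = c(-2.3, -0.7),
                   theta_log_range = c(-2.7, -1),
                   ess = budget)
  fit <- fit_block_model(model, "internalization", target, fc)
  list(fit = fit,
       sigma_ratio = fit$coefficients$sigma[1] / sigma_true,
       theta_ratio = fit$coefficients$theta[1] / theta_true)
}

#' Dose-response study of burst statistics
#'
#' Simulates the reference internalization-noise model (reversion time
#' 100 min, Feller-safe diffusion) plus the control-noise surrogate at a
#' control, low and high dose and summarizes the detected burst
#' statistics.
#'
#' @param seed integer seed.
#' @param doses doses in pM.
#' @param n_cells cells per dose.
#' @param model a [smad_model()].
#' @return tibble from [predict_dose()].
#' @export
dose_response_study <- function(seed = 9, doses = c(0, 25, 100),
                                n_cells = 24, model = smad_model()) {
  nb <- noise_block(model, "internalization",
                    sigma = c(0.015, 0.06, 0.03), theta = 0.01)
  fc <- fit_config(n_cells = n_cells, horizon = 1440,
                   detection = detection_config(height_threshold = 0.05,
                                                burst_bandwidth = 35,
                                                trend_bandwidth = 180,
                                                duration_bounds = c(75, 430)),
                   control_noise = control_noise_spec())
  predict_dose(model, nb, doses = doses, n_cells = n_cells, config = fc,
               seed = seed)
}
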