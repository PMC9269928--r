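#' Aggregate fine-grid Brownian increments to a coarser grid
#'
#' For a coarse step spanning `m` fine steps of length `delta`, the coarse
#' Brownian increment is the sum of the fine increments, and the coarse
#' iterated integral `dZ = int (W(s) - W(t_n)) ds` satisfies
#' `dZ_coarse = sum_k dZ_k + delta * sum_k (m - k) dB_k`. This coupling is
#' what makes pathwise (strong) errors across step sizes comparable.
#'
#' @param dB,dZ arrays `J x N x n_fine` of fine-grid increments.
#' @param m integer aggregation factor.
#' @param delta fine step size.
#' @return list of arrays `J x N x (n_fine / m)`.
#' @export
aggregate_increments <- function(dB, dZ, m, delta) {
  d <- dim(dB)
  stopifnot(length(d) == 3, d[3] %% m == 0)
  nc <- d[3] %/% m
  dBc <- array(0, c(d[1], d[2], nc))
  dZc <- array(0, c(d[1], d[2], nc))
  w <- (m - seq_len(m)) * delta
  for (n in seq_len(nc)) {
    idx <- ((n - 1) * m + 1):(n * m)
    slice_B <- dB[, , idx, drop = FALSE]
    slice_Z <- dZ[, , idx, drop = FALSE]
    dBc[, , n] <- apply(slice_B, c(1, 2), sum)
    dZc[, , n] <- apply(slice_Z, c(1, 2), sum) +
      apply(sweep(slice_B, 3, w, `*`), c(1, 2), sum)
  }
  list(dB = dBc, dZ = dZc)
}

#' Empirical strong convergence order of the path scheme
#'
#' Runs the coupled ensemble with a fixed Brownian path per cell at a fine
#' reference step and at several coarser steps (integer multiples of the
#' reference, with increments aggregated from the same path), measures the
#' strong error of each coarse run as the mean over paths of the
#' maximum-in-time absolute deviation of the nuc/cyt ratio from the
#' reference, and fits the log-log slope of error versus step size. The
#' deterministic limit (`sigma = 0`) recovers the Crank-Nicolson order 2;
#' with noise the scheme is of strong order 1.5, visible in the small-step
#' regime.
#'
#' @param model a [smad_model()].
#' @param noise a [noise_block()].
#' @param dt_list at least 3 step sizes, each an integer multiple of
#'   `dt_ref`, and each dividing `max(dt_list)`.
#' @param dt_ref reference step size.
#' @param n_paths minimum number of sample paths (cells); rounded up to a
#'   whole number of ensembles.
#' @param cells_per_ensemble cells per coupled ensemble.
#' @param horizon simulated time (minutes); must be a multiple of
#'   `max(dt_list)`.
#' @param L0 initial ligand (pM); the run starts from the stimulated state
#'   directly so that all steps are exactly equal.
#' @param seed integer seed.
#' @param config a [solver_config()]; a tight Newton tolerance keeps the
#'   nonlinear-solve error below the discretization error.
#' @param n_fine number of smallest step sizes for the fine-regime slope.
#' @return object of class `strong_order`: list with `errors` (tibble
#'   `dt`, `error`, `n_paths`), `slope_full`, `slope_fine`, their standard
#'   errors and the fit objects.
#' @export
empirical_strong_order <- function(model, noise, dt_list, dt_ref = 0.03,
                                   n_paths = 24, cells_per_ensemble = 8,
                                   horizon = 48, L0 = 100, seed = NULL,
                                   config = solver_config(newton_tol = 1e-12,
                                                          newton_max_iter = 20),
                                   n_fine = 3) {
  if (length(dt_list) < 3) stop("need at least 3 step sizes")
  dt_list <- sort(dt_list)
  mult <- dt_list / dt_ref
  if (any(abs(mult - round(mult)) > 1e-8) || any(mult < 1 + 1e-8)) {
    stop("all dt must be integer multiples of dt_ref larger than dt_ref")
  }
  out_dt <- max(dt_list)
  if (any(abs(out_dt / dt_list - round(out_dt / dt_list)) > 1e-8)) {
    stop("every dt must divide max(dt_list)")
  }
  if (abs(horizon / out_dt - round(horizon / out_dt)) > 1e-8) {
    stop("horizon must be a multiple of max(dt_list)")
  }
  if (!is.null(seed)) set.seed(seed)
  J <- nrow(noise)
  Nc <- cells_per_ensemble
  n_ens <- ceiling(n_paths / Nc)
  nfine <- round(horizon / dt_ref)
  y0 <- pre_equilibrate(model)

  errs <- matrix(NA_real_, n_ens * Nc, length(dt_list))
  run <- function(noise_arrays, dt) {
    simulate_ensemble(model, noise = noise,
                      schedule = NULL, n_cells = Nc, config = config,
                      horizon = horizon, y0 = y0, L0 = L0,
                      output_interval = out_dt,
                      record_states = TRUE, record_params = TRUE,
                      supplied_noise = c(noise_arrays, list(dt = dt)),
                      equilibrate = FALSE)
  }
  # max-norm over time and solution components (species and stochastic
  # parameters) per cell
  path_error <- function(sol, ref) {
    dev <- apply(abs(sol$states - ref$states), 2, max)  # over species x time
    if (J > 0) dev <- pmax(dev, apply(abs(sol$param_paths - ref$param_paths), 2, max))
    dev
  }
  for (e in seq_len(n_ens)) {
    if (J > 0) {
      M <- array(stats::rnorm(J * Nc * nfine), c(J, Nc, nfine))
      Nn <- array(stats::rnorm(J * Nc * nfine), c(J, Nc, nfine))
      fine <- list(dB = sqrt(dt_ref) * M,
                   dZ = 0.5 * dt_ref^1.5 * (M + Nn / sqrt(3)))
    } else {
      fine <- list(dB = array(0, c(1, Nc, nfine)) [0, , , drop = FALSE],
                   dZ = array(0, c(1, Nc, nfine)) [0, , , drop = FALSE])
    }
    ref <- run(fine[c("dB", "dZ")], dt_ref)
    for (d in seq_along(dt_list)) {
      m <- round(dt_list[d] / dt_ref)
      agg <- if (J > 0) aggregate_increments(fine$dB, fine$dZ, m, dt_ref)
             else fine
      sol <- run(agg[c("dB", "dZ")], dt_list[d])
      errs[(e - 1) * Nc + seq_len(Nc), d] <- path_error(sol, ref)
    }
  }
  err_mean <- colMeans(errs, na.rm = TRUE)
  tab <- tibble::tibble(dt = dt_list, error = err_mean,
                        n_paths = colSums(!is.na(errs)))
  fit_full <- stats::lm(log(error) ~ log(dt), data = tab)
  fine_tab <- tab[seq_len(min(n_fine, nrow(tab))), ]
  fit_fine <- stats::lm(log(error) ~ log(dt), data = fine_tab)
  structure(list(
    errors = tab,
    slope_full = unname(stats::coef(fit_full)[2]),
    slope_fine = unname(stats::coef(fit_fine)[2]),
    se_full = summary(fit_full)$coefficients[2, 2],
    se_fine = if (nrow(fine_tab) > 2) summary(fit_fine)$coefficients[2, 2] else NA_real_,
    fit_full = fit_full, fit_fine = fit_fine,
    dt_ref = dt_ref, n_fine = n_fine
  ), class = "strong_order")
}

#' @export
print.strong_order <- function(x, ...) {
  cat("<strong_order> slope (all dt): ", round(x$slope_full, 3),
      "; slope (", x$n_fine, " finest): ", round(x$slope_fine, 3), "\n", sep = "")
  print(x$errors)
  invisible(x)
}

#' @export
glance.strong_order <- function(x, ...) {
  tibble::tibble(slope_full = x$slope_full, slope_fine = x$slope_fine,
                 se_full = x$se_full, se_fine = x$se_fine,
                 dt_ref = x$dt_ref, n_dt = nrow(x$errors))
}
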