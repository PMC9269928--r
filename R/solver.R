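#' Solver configuration
#'
#' Settings of the semi-implicit Ito-Taylor scheme. `theta_scheme = 1/2`
#' averages the drift between the step endpoints (the deterministic
#' counterpart is the Crank-Nicolson method, second order); `theta_scheme
#' = 1` is fully implicit. Two step-size regimes are used: a small step
#' `dt_stim` during a window of length `stim_window` after each bolus
#' (where the step-like ligand addition makes the system stiff) and a
#' larger step `dt_main` elsewhere. Output is always resampled onto the
#' `output_interval` grid.
#'
#' @param theta_scheme implicitness weight in `[0, 1]`.
#' @param dt_stim step size during the stimulation window (solver time
#'   units, interpreted as minutes).
#' @param dt_main step size elsewhere; must be `>= dt_stim`.
#' @param newton_tol per-cell residual max-norm tolerance.
#' @param newton_max_iter Newton iteration budget per step.
#' @param output_interval sampling interval of the stored output (minutes).
#' @param stim_window length (minutes) of the small-step window after each
#'   bolus.
#' @return list of class `solver_config`.
#' @export
solver_config <- function(theta_scheme = 0.5, dt_stim = 0.04, dt_main = 0.6,
                          newton_tol = 1e-9, newton_max_iter = 12,
                          output_interval = 5, stim_window = 10) {
  stopifnot(theta_scheme >= 0, theta_scheme <= 1,
            dt_stim > 0, dt_main > 0, dt_stim <= dt_main,
            newton_tol > 0, newton_max_iter >= 1,
            output_interval > 0, stim_window >= 0)
  structure(list(theta_scheme = theta_scheme, dt_stim = dt_stim,
                 dt_main = dt_main, newton_tol = newton_tol,
                 newton_max_iter = newton_max_iter,
                 output_interval = output_interval,
                 stim_window = stim_window),
            class = "solver_config")
}

empty_events <- function() matrix(numeric(0), 0, 3)

schedule_events <- function(schedule) {
  if (is.null(schedule) || nrow(schedule) == 0) return(empty_events())
  cbind(schedule$time, schedule$dose, as.numeric(schedule$raise_to))
}

#' Simulate a coupled cell ensemble
#'
#' Integrates `n_cells` copies of the intracellular model coupled through
#' the shared extracellular ligand, with CIR (or OU) noise on the kinetic
#' parameters of `noise`. All cells start from the unstimulated steady
#' state (unless `y0` is given) with stochastic parameters at their `p0`.
#' Given a seed the output is bit-reproducible. Cells whose Newton
#' iteration fails to converge or that reach a non-finite state are
#' flagged as failed and carry no output values from the failure time on;
#' the run errors only if every cell fails or the ligand equation
#' degenerates.
#'
#' @param model a [smad_model()].
#' @param noise a [noise_block()] or `NULL` for the deterministic model.
#' @param schedule a [stimulus_schedule()].
#' @param n_cells ensemble size N.
#' @param config a [solver_config()].
#' @param horizon simulated time (minutes).
#' @param seed integer seed; `NULL` continues the session RNG stream.
#' @param y0 initial state: `NULL` (pre-equilibrated), a vector applied to
#'   every cell, or an `n_species x n_cells` matrix.
#' @param p_cells optional `55 x n_cells` matrix of per-cell kinetic
#'   parameters (used for mixed ensembles); default the model values.
#' @param L0 initial free ligand (pM).
#' @param output_interval overrides `config$output_interval`.
#' @param record_states,record_params store full per-cell state / parameter
#'   paths on the output grid.
#' @param supplied_noise list(`dB`, `dZ`, `dt`) of pre-generated Brownian
#'   increments (arrays `n_stochastic x n_cells x n_steps`), forcing a
#'   fixed step `dt`; used by the strong-convergence harness.
#' @param equilibrate internal flag; skip pre-equilibration when `y0` given.
#' @return object of class `smad_ensemble`.
#' @export
simulate_ensemble <- function(model, noise = NULL,
                              schedule = stimulus_schedule(),
                              n_cells = 10, config = solver_config(),
                              horizon = 1440, seed = NULL, y0 = NULL,
                              p_cells = NULL, L0 = 0,
                              output_interval = NULL,
                              record_states = FALSE, record_params = FALSE,
                              supplied_noise = NULL, equilibrate = TRUE) {
  stopifnot(n_cells >= 1, horizon > 0)
  if (!is.null(seed)) set.seed(seed)
  out_dt <- output_interval %||% config$output_interval
  if (is.null(noise)) noise <- noise_block(model, "deterministic")
  J <- nrow(noise)
  kind <- if (attr(noise, "process") == "ou") 1L else 0L

  if (is.null(y0)) {
    y0 <- if (equilibrate) pre_equilibrate(model) else rep(0, model$n_species)
  }
  Y0 <- if (is.matrix(y0)) y0 else matrix(y0, model$n_species, n_cells)
  stopifnot(nrow(Y0) == model$n_species, ncol(Y0) == n_cells)
  P0 <- p_cells %||% matrix(model$p, length(model$p), n_cells)
  stopifnot(nrow(P0) == length(model$p), ncol(P0) == n_cells)
  if (J > 0) P0[noise$index, ] <- noise$p0

  dB <- dZ <- NULL
  dt_fixed <- -1
  if (!is.null(supplied_noise)) {
    dt_fixed <- supplied_noise$dt
    stopifnot(dt_fixed > 0,
              abs(out_dt / dt_fixed - round(out_dt / dt_fixed)) < 1e-8,
              abs(horizon / out_dt - round(horizon / out_dt)) < 1e-8)
    dB <- as.numeric(supplied_noise$dB %||% numeric(0))
    dZ <- as.numeric(supplied_noise$dZ %||% numeric(0))
    nsteps <- round(horizon / dt_fixed)
    if (J > 0 && length(dB) < nsteps * n_cells * J) {
      stop("supplied noise arrays too short for ", nsteps, " steps")
    }
  }

  df <- if (!is.null(schedule)) attr(schedule, "dose_factor") %||% 1 else 1
  res <- eng_simulate(model$net, Y0, P0, as.numeric(model$E),
                      horizon, out_dt, schedule_events(schedule), df,
                      as.integer(noise$index), noise$p0, noise$sigma,
                      noise$theta, kind,
                      config$theta_scheme, config$dt_stim, config$dt_main,
                      config$stim_window, config$newton_tol,
                      config$newton_max_iter, L0,
                      record_states, record_params, dB, dZ, dt_fixed)
  if (isTRUE(res$ensemble_failed)) {
    stop("ensemble failure: all cells failed or the ligand equation degenerated")
  }
  cells <- sprintf("cell_%04d", seq_len(n_cells))
  ratio <- res$ratio
  dimnames(ratio) <- list(NULL, cells)
  out <- list(
    time = as.numeric(res$time),
    ratio = ratio,
    ligand = as.numeric(res$ligand),
    failed = as.logical(res$failed),
    fail_time = as.numeric(res$fail_time),
    meta = list(n_cells = n_cells, horizon = horizon, seed = seed,
                noise = noise, schedule = schedule, config = config,
                output_interval = out_dt),
    diagnostics = list(newton_iterations = res$newton_iterations,
                       clip_count = res$clip_count, n_steps = res$n_steps)
  )
  if (record_states) {
    st <- res$states
    dimnames(st) <- list(model$species, cells, NULL)
    out$states <- st
  }
  if (record_params && J > 0) {
    pp <- res$param_paths
    dimnames(pp) <- list(noise$name, cells, NULL)
    out$param_paths <- pp
  }
  structure(out, class = "smad_ensemble")
}

#' @export
print.smad_ensemble <- function(x, ...) {
  cat("<smad_ensemble> ", x$meta$n_cells, " cells, ",
      length(x$time), " time points (", min(x$time), "-", max(x$time),
      " min), block '", attr(x$meta$noise, "block"), "', ",
      sum(x$failed), " failed\n", sep = "")
  invisible(x)
}

#' @export
tidy.smad_ensemble <- function(x, ...) {
  tibble::tibble(
    time = rep(x$time, ncol(x$ratio)),
    cell = rep(colnames(x$ratio), each = nrow(x$ratio)),
    ratio = as.vector(x$ratio)
  )
}

#' @importFrom generics glance
#' @export
generics::glance

#' @export
glance.smad_ensemble <- function(x, ...) {
  tibble::tibble(
    n_cells = x$meta$n_cells,
    n_failed = sum(x$failed),
    horizon = x$meta$horizon,
    block = attr(x$meta$noise, "block"),
    final_ligand = x$ligand[length(x$ligand)],
    newton_iterations = x$diagnostics$newton_iterations
  )
}

#' Population snapshot statistics
#'
#' Time-resolved mean and standard deviation of the nuc/cyt ratio over the
#' non-failed cells of an ensemble (or a plain ratio matrix). Time points
#' with fewer than two contributing cells get `NA`.
#'
#' @param x a `smad_ensemble` or a numeric matrix (time x cells) with a
#'   `time` argument.
#' @param time time grid when `x` is a matrix.
#' @return tibble (`time`, `mean`, `sd`, `n`).
#' @export
population_stats <- function(x, time = NULL) {
  m <- ratio_matrix(x)
  tt <- time %||% (if (inherits(x, "smad_ensemble")) x$time else
                     stop("time grid required for matrix input"))
  n_ok <- rowSums(!is.na(m))
  mu <- rowMeans(m, na.rm = TRUE)
  sdv <- apply(m, 1, stats::sd, na.rm = TRUE)
  mu[n_ok < 2] <- NA_real_
  sdv[n_ok < 2] <- NA_real_
  tibble::tibble(time = tt, mean = mu, sd = sdv, n = n_ok)
}

ratio_matrix <- function(x) {
  if (inherits(x, "smad_ensemble")) x$ratio
  else if (is.matrix(x)) x
  else stop("expected a smad_ensemble or a time x cells matrix")
}

#' Advance the coupled system by one step
#'
#' Applies a single step of the semi-implicit order-1.5 scheme to a full
#' coupled state (ligand, all cell states, stochastic parameters), with
#' externally supplied Brownian increments. With all `sigma = 0` and
#' `theta_scheme = 1/2` the update reduces to the deterministic
#' Crank-Nicolson step.
#'
#' @param model a [smad_model()].
#' @param state list with `L` (ligand), `Y` (`n_species x N` matrix) and
#'   optionally `P` (`55 x N` parameter matrix).
#' @param dt step size.
#' @param draws list with matrices `dB` and `dZ` (`J x N`), the Brownian
#'   increment and the iterated-integral surrogate per stochastic
#'   parameter and cell; `NULL` for a deterministic block.
#' @param noise a [noise_block()] or `NULL`.
#' @param config a [solver_config()].
#' @return list with updated `L`, `Y`, `P` and logical `failed` per cell.
#' @export
advance_step <- function(model, state, dt, draws = NULL, noise = NULL,
                         config = solver_config()) {
  stopifnot(dt > 0, is.matrix(state$Y))
  if (any(!is.finite(state$Y)) || !is.finite(state$L)) {
    stop("state must be finite")
  }
  N <- ncol(state$Y)
  if (is.null(noise)) noise <- noise_block(model, "deterministic")
  J <- nrow(noise)
  P <- state$P %||% matrix(model$p, length(model$p), N)
  if (J > 0) {
    stopifnot(!is.null(draws), all(dim(draws$dB) == c(J, N)))
    dB <- array(draws$dB, c(J, N, 1))
    dZ <- array(draws$dZ, c(J, N, 1))
  } else {
    dB <- dZ <- numeric(0)
  }
  kind <- if (attr(noise, "process") == "ou") 1L else 0L
  res <- eng_simulate(model$net, state$Y, P, as.numeric(model$E),
                      dt, dt, empty_events(), 1,
                      as.integer(noise$index), noise$p0, noise$sigma,
                      noise$theta, kind,
                      config$theta_scheme, dt, dt, 0,
                      config$newton_tol, config$newton_max_iter,
                      state$L, TRUE, J > 0,
                      as.numeric(dB), as.numeric(dZ), dt)
  Y1 <- res$states[, , 2, drop = TRUE]
  if (!is.matrix(Y1)) Y1 <- matrix(Y1, model$n_species, N)
  P1 <- P
  if (J > 0) {
    pp <- res$param_paths[, , 2, drop = TRUE]
    P1[noise$index, ] <- matrix(pp, J, N)
  }
  list(L = res$ligand[2], Y = Y1, P = P1, failed = as.logical(res$failed))
}
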