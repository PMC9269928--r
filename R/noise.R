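#' Define a noise block
#'
#' A noise block places independent stochastic dynamics on a themed subset
#' of kinetic parameters. Each stochastic parameter j follows the
#' Cox-Ingersoll-Ross (CIR) square-root diffusion
#' `dp_j = theta_j (p0_j - p_j) dt + sigma_j sqrt(p_j) dB_j`,
#' which keeps parameters non-negative, preserves the mean and has bounded
#' variance; the Ornstein-Uhlenbeck (OU) variant `dp_j = theta_j (p0_j -
#' p_j) dt + sigma_j dB_j` is provided for comparison and may go negative.
#'
#' The five shipped block names follow the pathway biology: binding of the
#' ligand to its receptors (`receptor_ligand`), transport from the
#' membrane into the cell (`internalization`), routing of internalized
#' complexes (`endosomal_traffic`), production of receptors and feedback
#' regulator (`synthesis`) and their decay (`degradation`).
#' `deterministic` is the empty block (no stochastic parameters).
#'
#' @param model a [smad_model()].
#' @param name one of `"receptor_ligand"`, `"internalization"`,
#'   `"endosomal_traffic"`, `"synthesis"`, `"degradation"`,
#'   `"deterministic"`.
#' @param sigma diffusion coefficients (recycled over the block's
#'   parameters; units `sqrt(parameter units)` per `sqrt(minute)`).
#' @param theta mean-reversion rates (1/min, recycled).
#' @param p0 long-run / initial parameter values; default the model's
#'   current values for the block.
#' @param process `"cir"` (default) or `"ou"`.
#' @return a tibble (`index`, `name`, `p0`, `sigma`, `theta`) of class
#'   `noise_block` with attributes `block` and `process`. The Feller
#'   condition `2 theta p0 >= sigma^2` is not enforced (the solver clips);
#'   a warning is emitted when it is violated.
#' @export
noise_block <- function(model, name, sigma = 0.05, theta = 0.01, p0 = NULL,
                        process = c("cir", "ou")) {
  process <- match.arg(process)
  valid <- c(unique(stats::na.omit(model$parameters$block)), "deterministic")
  if (!name %in% valid) {
    stop("unknown block '", name, "'; available: ", paste(valid, collapse = ", "))
  }
  if (name == "deterministic") {
    out <- tibble::tibble(index = integer(), name = character(),
                          p0 = numeric(), sigma = numeric(), theta = numeric())
  } else {
    tab <- dplyr::filter(model$parameters, .data$block == .env$name)
    if (!all(tab$kinetic)) stop("noise blocks may only contain kinetic parameters")
    np <- nrow(tab)
    p0 <- if (is.null(p0)) tab$value else rep_len(p0, np)
    sigma <- rep_len(sigma, np)
    theta <- rep_len(theta, np)
    if (any(p0 < 0) || any(sigma < 0) || any(theta < 0)) {
      stop("p0, sigma, theta must be non-negative")
    }
    out <- tibble::tibble(index = tab$index, name = tab$name,
                          p0 = p0, sigma = sigma, theta = theta)
    feller <- 2 * theta * p0 >= sigma^2
    if (process == "cir" && any(!feller & sigma > 0)) {
      warning("Feller condition 2*theta*p0 >= sigma^2 violated for: ",
              paste(out$name[!feller], collapse = ", "),
              " (zero boundary attainable; solver clipping applies)")
    }
  }
  attr(out, "block") <- name
  attr(out, "process") <- process
  class(out) <- c("noise_block", class(out))
  out
}

#' Closed-form CIR moments
#'
#' Mean and variance of the CIR process at time `t` started from `p_init`:
#' `E p(t) = p0 + (p_init - p0) e^{-theta t}` and
#' `Var p(t) = sigma^2/theta p_init (e^{-theta t} - e^{-2 theta t})
#'  + p0 sigma^2/(2 theta) (1 - e^{-theta t})^2`,
#' obtained from the moment ODEs `dE/dt = theta (p0 - E)` and
#' `dVar/dt = -2 theta Var + sigma^2 E`. For `p_init = p0` the mean is
#' constant and the variance `p0 sigma^2 (1 - e^{-2 theta t})/(2 theta)`
#' is bounded by the stationary value `p0 sigma^2/(2 theta)`.
#'
#' @param p0 long-run mean; @param sigma diffusion coefficient;
#' @param theta mean-reversion rate; @param t time(s) in minutes;
#' @param p_init initial value (default `p0`).
#' @return tibble (`t`, `mean`, `variance`) with attribute
#'   `degenerate = TRUE` when `theta = 0`, in which case the limiting
#'   moments `mean = p_init`, `variance = sigma^2 p_init t` are returned.
#' @export
cir_moments <- function(p0, sigma, theta, t, p_init = p0) {
  stopifnot(all(t >= 0), p0 >= 0, sigma >= 0, theta >= 0)
  degen <- theta == 0
  if (degen) {
    m <- rep(p_init, length(t))
    v <- sigma^2 * p_init * t
  } else {
    e1 <- exp(-theta * t)
    e2 <- exp(-2 * theta * t)
    m <- p0 + (p_init - p0) * e1
    v <- sigma^2 / theta * p_init * (e1 - e2) + p0 * sigma^2 / (2 * theta) * (1 - e1)^2
  }
  structure(tibble::tibble(t = t, mean = m, variance = v), degenerate = degen)
}

#' Sample stochastic parameter paths
#'
#' Simulates the parameter processes of a noise block with the same
#' discretization used inside the ensemble solver (theta-weighted implicit
#' drift, explicit diffusion, Milstein term and order-1.5 corrections;
#' CIR paths clipped at zero, with high-order terms skipped on the step
#' after a clip). Output is bit-reproducible given the seed.
#'
#' @param spec a [noise_block()].
#' @param horizon length of the paths (minutes).
#' @param dt time increment (minutes).
#' @param n_paths number of independent paths per parameter.
#' @param seed integer seed (optional).
#' @param theta_scheme implicitness weight of the drift (default 1/2).
#' @return object of class `cir_paths`: list with `time` and `paths`, a
#'   named list of `n_time x n_paths` matrices.
#' @export
sample_block_paths <- function(spec, horizon, dt, n_paths, seed = NULL,
                               theta_scheme = 0.5) {
  stopifnot(dt > 0, horizon > 0, n_paths >= 1)
  if (!is.null(seed)) set.seed(seed)
  nstep <- ceiling(horizon / dt)
  time <- seq(0, by = dt, length.out = nstep + 1)
  ou <- identical(attr(spec, "process"), "ou")
  th <- theta_scheme
  paths <- list()
  for (j in seq_len(nrow(spec))) {
    p0 <- spec$p0[j]; sg <- spec$sigma[j]; tht <- spec$theta[j]
    out <- matrix(NA_real_, nstep + 1, n_paths)
    p <- rep(p0, n_paths)
    out[1, ] <- p
    skip <- logical(n_paths)
    for (n in seq_len(nstep)) {
      M <- stats::rnorm(n_paths)
      Nn <- stats::rnorm(n_paths)
      dB <- sqrt(dt) * M
      dZ <- 0.5 * dt^1.5 * (M + Nn / sqrt(3))
      if (ou) {
        noise <- sg * dB - ifelse(skip, 0, tht * sg * (dZ - th * dB * dt))
      } else {
        sq <- sqrt(pmax(p, 0))
        noise <- sg * sq * dB
        hi <- !skip & p > 0
        noise[hi] <- noise[hi] + 0.25 * sg^2 * (dB[hi]^2 - dt) +
          (-tht * sg * sq[hi]) * (dZ[hi] - th * dB[hi] * dt) +
          (tht * (p0 - p[hi]) * sg / (2 * sq[hi]) - sg^3 / (8 * sq[hi])) *
            (dB[hi] * dt - dZ[hi])
        zero_noise <- !skip & p == 0
        noise[zero_noise] <- noise[zero_noise] + 0.25 * sg^2 * (dB[zero_noise]^2 - dt)
      }
      p <- (p + tht * dt * (th * p0 + (1 - th) * (p0 - p)) + noise) /
        (1 + tht * dt * th)
      if (!ou) {
        skip <- p <= 0
        p <- pmax(p, 0)
      }
      out[n + 1, ] <- p
    }
    paths[[spec$name[j]]] <- out
  }
  structure(list(time = time, paths = paths, spec = spec),
            class = "cir_paths")
}

#' @export
print.cir_paths <- function(x, ...) {
  cat("<cir_paths> ", length(x$paths), " parameter(s), ",
      ncol(x$paths[[1]]), " paths, horizon ", max(x$time), " min\n", sep = "")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @export
tidy.cir_paths <- function(x, ...) {
  purrr::imap_dfr(x$paths, function(m, nm) {
    tibble::tibble(parameter = nm,
                   path = rep(seq_len(ncol(m)), each = nrow(m)),
                   time = rep(x$time, ncol(m)),
                   value = as.vector(m))
  })
}

#' Empirical temporal distribution of stochastic parameters
#'
#' Pools parameter path values after a burn-in period and returns the
#' normalized histogram per parameter. The CIR stationary law is
#' Gamma(2 theta p0 / sigma^2, scale sigma^2 / (2 theta)); for sigma large
#' relative to theta p0 the distribution is strongly right-skewed
#' (mode below mean), resembling a log-normal.
#'
#' @inheritParams sample_block_paths
#' @param burn_in time (minutes) discarded before pooling; default `3/theta`.
#' @param bins number of histogram bins.
#' @return tibble (`parameter`, `mid`, `density`, `prob`) with attribute
#'   `stats`: a tibble of pooled mean, variance, skewness and mode.
#' @export
stationary_histogram <- function(spec, horizon = NULL, dt = 1, n_paths = 200,
                                 burn_in = NULL, bins = 60, seed = NULL) {
  if (nrow(spec) == 0) stop("empty (deterministic) noise block")
  if (is.null(horizon)) horizon <- max(20 / pmax(spec$theta, 1e-6))
  if (is.null(burn_in)) burn_in <- max(3 / pmax(spec$theta, 1e-6))
  if (burn_in >= horizon) stop("burn_in must be shorter than the horizon")
  sims <- sample_block_paths(spec, horizon, dt, n_paths, seed = seed)
  keep <- sims$time >= burn_in
  res <- list(); st <- list()
  for (nm in names(sims$paths)) {
    v <- as.vector(sims$paths[[nm]][keep, ])
    if (stats::sd(v) <= 1e-12 * max(abs(mean(v)), 1e-300)) {
      res[[nm]] <- tibble::tibble(parameter = nm, mid = v[1], density = Inf, prob = 1)
      st[[nm]] <- tibble::tibble(parameter = nm, mean = v[1], variance = 0,
                                 skewness = NA_real_, mode = v[1])
      next
    }
    h <- graphics::hist(v, breaks = bins, plot = FALSE)
    w <- diff(h$breaks)
    res[[nm]] <- tibble::tibble(parameter = nm, mid = h$mids,
                                density = h$density, prob = h$density * w)
    sk <- mean((v - mean(v))^3) / stats::sd(v)^3
    st[[nm]] <- tibble::tibble(parameter = nm, mean = mean(v), variance = stats::var(v),
                               skewness = sk, mode = h$mids[which.max(h$density)])
  }
  structure(dplyr::bind_rows(res), stats = dplyr::bind_rows(st))
}
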