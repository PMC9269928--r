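#' Load the SMAD signaling ensemble model
#'
#' Reads a declarative reaction-network definition (species, mass-action
#' reactions with optional catalytic modifiers and a Hill factor, the
#' kinetic parameter table P1..P55 with noise-block assignments, and the
#' experiment parameters E1..E9) and compiles it into the internal form
#' used by the simulation engine. The default file shipped with the
#' package describes a 22-species TGF-beta/SMAD pathway: ligand-receptor
#' binding, receptor internalization and endosomal traffic, SMAD2
#' phosphorylation and trimerization with SMAD4, nucleocytoplasmic
#' shuttling, and Hill-form induction of a SMAD7-like feedback regulator
#' that inactivates the active receptor complex. Each cell of an ensemble
#' carries this network; all cells share one extracellular ligand pool
#' whose depletion by receptor binding is scaled by `1/N` against a fixed
#' dish volume so that deterministic dynamics do not depend on the
#' ensemble size.
#'
#' @param path path to a model definition YAML file; `NULL` uses the
#'   shipped default parameterization.
#' @param params optional named numeric vector of kinetic parameter
#'   overrides (names as in the parameter table, e.g. `c(ki_cplx = 0.1)`).
#' @param experiment optional named numeric vector of experiment parameter
#'   overrides (e.g. `c(bolus_delay = 2)`).
#' @return an object of class `smad_model`.
#' @export
smad_model <- function(path = NULL, params = NULL, experiment = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "smad_model.yaml", package = "smadburst")
  }
  def <- yaml::read_yaml(path)

  species <- vapply(def$species, function(s) s$name, character(1))
  ns <- length(species)
  ptab <- dplyr::bind_rows(lapply(def$parameters, function(p) {
    tibble::tibble(
      index = as.integer(p$index), name = p$name, value = as.numeric(p$value),
      kinetic = isTRUE(p$kinetic),
      block = if (is.null(p$block)) NA_character_ else p$block,
      description = p$description %||% ""
    )
  }))
  stopifnot(identical(ptab$index, seq_len(nrow(ptab))))
  etab <- dplyr::bind_rows(lapply(def$experiment, function(p) {
    tibble::tibble(index = as.integer(p$index), name = p$name,
                   value = as.numeric(p$value), description = p$description %||% "")
  }))

  p <- stats::setNames(ptab$value, ptab$name)
  E <- stats::setNames(etab$value, etab$name)
  if (!is.null(params)) {
    bad <- setdiff(names(params), names(p))
    if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "))
    p[names(params)] <- params
  }
  if (!is.null(experiment)) {
    bad <- setdiff(names(experiment), names(E))
    if (length(bad)) stop("unknown experiment parameter(s): ", paste(bad, collapse = ", "))
    E[names(experiment)] <- experiment
  }
  if (any(p < 0) || any(E < 0)) stop("parameters must be non-negative")
  if (E[["bolus_delay"]] < 0) stop("bolus delay must be non-negative")

  sp_idx <- function(nm) {
    i <- match(nm, species)
    if (anyNA(i)) stop("unknown species: ", paste(nm[is.na(i)], collapse = ", "))
    i
  }
  par_idx <- function(nm, where) {
    i <- match(nm, ptab$name)
    j <- match(nm, etab$name)
    if (!is.na(i)) return(list(type = 0L, idx = i))
    if (!is.na(j)) return(list(type = 1L, idx = j))
    stop("unknown rate constant '", nm, "' in ", where)
  }

  nr <- length(def$reactions)
  S <- matrix(0, ns, nr)
  O <- matrix(0, ns, nr)
  M <- matrix(0, ns, nr)
  ktype <- kidx <- integer(nr)
  eidx <- rep(-1L, nr)
  hsp <- hn <- hk <- rep(-1L, nr)
  lig <- numeric(nr)
  ligO <- integer(nr)
  rx_names <- character(nr)
  for (r in seq_len(nr)) {
    rx <- def$reactions[[r]]
    rx_names[r] <- rx$name
    for (nm in names(rx$reactants)) {
      i <- sp_idx(nm)
      S[i, r] <- S[i, r] - rx$reactants[[nm]]
      O[i, r] <- O[i, r] + rx$reactants[[nm]]
    }
    for (nm in names(rx$products)) {
      i <- sp_idx(nm)
      S[i, r] <- S[i, r] + rx$products[[nm]]
    }
    for (nm in names(rx$modifiers)) {
      M[sp_idx(nm), r] <- rx$modifiers[[nm]]
    }
    k <- par_idx(rx$k, rx$name)
    ktype[r] <- k$type
    kidx[r] <- k$idx - 1L
    if (!is.null(rx$e)) {
      j <- match(rx$e, etab$name)
      if (is.na(j)) stop("unknown experiment multiplier '", rx$e, "'")
      eidx[r] <- j - 1L
    }
    if (!is.null(rx$hill)) {
      hsp[r] <- sp_idx(rx$hill$species) - 1L
      hn[r] <- match(rx$hill$coef, ptab$name) - 1L
      hk[r] <- match(rx$hill$half, ptab$name) - 1L
      if (anyNA(c(hn[r], hk[r]))) stop("Hill parameters must be kinetic parameters")
    }
    if (!is.null(rx$ligand)) lig[r] <- rx$ligand
    if (!is.null(rx$ligand_order)) ligO[r] <- as.integer(rx$ligand_order)
  }

  numw <- denw <- numeric(ns)
  for (nm in names(def$readout$numerator)) numw[sp_idx(nm)] <- def$readout$numerator[[nm]]
  for (nm in names(def$readout$denominator)) denw[sp_idx(nm)] <- def$readout$denominator[[nm]]

  net <- list(S = S, O = O, M = M, ktype = ktype, kidx = kidx, eidx = eidx,
              hsp = hsp, hn = hn, hk = hk, lig = lig, ligO = as.integer(ligO),
              numw = numw, denw = denw,
              ligscale = match("ligand_scale", ptab$name))

  structure(
    list(species = species, n_species = ns, reactions = rx_names,
         parameters = ptab, experiment = etab, p = p, E = E,
         net = net, path = path),
    class = "smad_model"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.smad_model <- function(x, ...) {
  cat("<smad_model> ", x$n_species, " species, ", length(x$reactions),
      " reactions, ", sum(x$parameters$kinetic), " kinetic parameters\n", sep = "")
  blocks <- noise_block_table(x)
  cat("noise blocks:",
      paste(sprintf("%s {%s}", unique(blocks$block),
                    tapply(blocks$name, blocks$block, paste, collapse = ",")[unique(blocks$block)]),
            collapse = "; "), "\n")
  invisible(x)
}

#' Kinetic parameters eligible for each noise block
#'
#' @param model a `smad_model`.
#' @return tibble with columns `block`, `index`, `name`, `value`.
#' @export
noise_block_table <- function(model) {
  model$parameters |>
    dplyr::filter(!is.na(.data$block)) |>
    dplyr::select("block", "index", "name", "value")
}

#' Update model parameter values
#'
#' @param model a `smad_model`.
#' @param params,experiment named numeric overrides.
#' @return the modified model.
#' @export
set_params <- function(model, params = NULL, experiment = NULL) {
  p <- model$p
  e <- model$E
  if (!is.null(params)) {
    bad <- setdiff(names(params), names(p))
    if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "))
    p[names(params)] <- params
  }
  if (!is.null(experiment)) {
    bad <- setdiff(names(experiment), names(e))
    if (length(bad)) stop("unknown experiment parameter(s): ", paste(bad, collapse = ", "))
    e[names(experiment)] <- experiment
  }
  smad_model(model$path, params = p, experiment = e)
}

check_state <- function(y, ns) {
  if (!is.numeric(y) || length(y) != ns) {
    stop("state must be a numeric vector of length ", ns, call. = FALSE)
  }
  if (anyNA(y) || any(!is.finite(y))) stop("state contains NA/NaN/Inf", call. = FALSE)
  invisible(y)
}

#' Per-cell reaction kinetics
#'
#' Evaluates the right-hand side f_1..f_22 of the intracellular model for
#' one cell: ligand-receptor binding, internalization, endosomal traffic,
#' recycling, degradation, SMAD phosphorylation and trimerization,
#' nucleocytoplasmic shuttling, and Hill-form feedback induction.
#'
#' @param model a `smad_model`.
#' @param t time (minutes); the rate laws are autonomous, kept for
#'   interface symmetry.
#' @param L free extracellular ligand concentration (pM).
#' @param y state vector (length 22, non-negative).
#' @param p,E kinetic / experiment parameter vectors (defaults from the model).
#' @return named numeric vector of d y / d t.
#' @export
cell_rhs <- function(model, t = 0, L, y, p = model$p, E = model$E) {
  check_state(y, model$n_species)
  if (!is.finite(L) || L < 0) stop("ligand concentration must be finite and >= 0")
  f <- eng_cell_eval(model$net, L, as.numeric(y), as.numeric(p), as.numeric(E))$f
  stats::setNames(as.numeric(f), model$species)
}

#' Jacobian of the per-cell kinetics with respect to the state
#'
#' Analytic (symbolically derived from the rate-law structure) Jacobian
#' used by the semi-implicit solver's Newton iteration.
#'
#' @inheritParams cell_rhs
#' @return 22 x 22 matrix d f / d y.
#' @export
cell_jacobian <- function(model, t = 0, L, y, p = model$p, E = model$E) {
  check_state(y, model$n_species)
  J <- eng_cell_eval(model$net, L, as.numeric(y), as.numeric(p), as.numeric(E))$jac
  dimnames(J) <- list(model$species, model$species)
  J
}

#' Shared-ligand dynamics
#'
#' Right-hand side of the extracellular ligand equation: bolus input minus
#' the ligand consumed by receptor binding summed over cells, scaled by
#' `ligand_scale / N` (fixed dish volume) so the deterministic depletion
#' rate does not depend on the ensemble size.
#'
#' The bolus term uses the memoryless form `E1 * dose_scale * dose_factor
#' * dose / E9` within the smoothing window `[t_b, t_b + E9)`; the full
#' solver additionally supports raise-to-target boluses whose amount is
#' fixed at the event time.
#'
#' @param model a `smad_model`.
#' @param t time in minutes.
#' @param L free ligand (pM).
#' @param cells non-empty list; each element a list with components `y`
#'   (state vector) and optionally `p` (its kinetic parameters).
#' @param schedule a [stimulus_schedule()] or `NULL` for no input.
#' @return dL/dt in pM per minute.
#' @export
ligand_rhs <- function(model, t = 0, L, cells, schedule = NULL) {
  if (length(cells) == 0) stop("cell ensemble must be non-empty")
  N <- length(cells)
  flux <- vapply(cells, function(cl) {
    p <- cl$p %||% model$p
    eng_cell_eval(model$net, L, as.numeric(cl$y), as.numeric(p),
                  as.numeric(model$E))$lig_flux
  }, numeric(1))
  ligsc <- model$p[["ligand_scale"]]
  bolus <- 0
  if (!is.null(schedule)) {
    E1 <- model$E[["bolus_factor"]]
    E9 <- model$E[["bolus_delay"]]
    df <- attr(schedule, "dose_factor")
    sc <- model$p[["dose_scale"]]
    for (i in seq_len(nrow(schedule))) {
      if (E9 > 0 && t >= schedule$time[i] && t < schedule$time[i] + E9) {
        bolus <- bolus + E1 * sc * df * schedule$dose[i] / E9
      }
    }
  }
  bolus + ligsc / N * sum(flux)
}

#' Nuclear-to-cytoplasmic SMAD2 ratio
#'
#' The pathway-activity readout: weighted nuclear SMAD2 species divided by
#' weighted cytoplasmic SMAD2 species, with trimer species counted by
#' their SMAD2 stoichiometry: the ratio is
#' `(y18 + 2 y19 + 3 y20 + y21) / (y10 + y11 + 2 y13 + 3 y14)`.
#'
#' @param model a `smad_model`.
#' @param y state vector.
#' @return the dimensionless ratio.
#' @export
nuc_cyt_ratio <- function(model, y) {
  check_state(y, model$n_species)
  den <- sum(model$net$denw * y)
  if (den <= 0) stop("degenerate state: cytoplasmic SMAD2 species sum to zero")
  sum(model$net$numw * y) / den
}

#' Stimulus schedule
#'
#' @param time bolus times (minutes, strictly increasing).
#' @param dose doses (pM, non-negative).
#' @param raise_to logical (recycled): if `TRUE` the bolus raises the
#'   ligand from its value just before the event to the target
#'   `E1 * dose_scale * dose_factor * dose`, rather than adding that amount.
#' @param dose_factor dimensionless scaling of the effective external
#'   ligand (ligand-charge adjustment).
#' @return a tibble with attribute `dose_factor`, class `stimulus_schedule`.
#' @export
stimulus_schedule <- function(time = 0, dose = 100, raise_to = FALSE, dose_factor = 1) {
  if (is.unsorted(time, strictly = TRUE)) stop("event times must be strictly increasing")
  if (any(dose < 0)) stop("doses must be non-negative")
  out <- tibble::tibble(time = as.numeric(time), dose = as.numeric(dose),
                        raise_to = rep_len(as.logical(raise_to), length(time)))
  attr(out, "dose_factor") <- dose_factor
  class(out) <- c("stimulus_schedule", class(out))
  out
}

#' Unstimulated steady state
#'
#' Computes the pre-stimulation equilibrium (L = 0) used as the initial
#' condition for every cell: a long deterministic relaxation followed by a
#' Newton polish on `f(y) = 0` via [adaptive_newton()].
#'
#' @param model a `smad_model`.
#' @param tol residual tolerance (max-norm of f at the returned state).
#' @param relax_horizon length of the relaxation run (minutes).
#' @param max_iter Newton iteration budget for the polish.
#' @return named state vector with attribute `residual`.
#' @export
pre_equilibrate <- function(model, tol = 1e-10, relax_horizon = 4000, max_iter = 50) {
  cfg <- solver_config(dt_main = 2, dt_stim = 2)
  sim <- simulate_ensemble(model, noise = NULL,
                           schedule = stimulus_schedule(time = 0, dose = 0),
                           n_cells = 1, config = cfg, horizon = relax_horizon,
                           output_interval = relax_horizon,
                           y0 = rep(0.01, model$n_species),
                           record_states = TRUE, equilibrate = FALSE)
  y <- sim$states[, 1, dim(sim$states)[3]]
  fn <- function(x) eng_cell_eval(model$net, 0, pmax(x, 0), model$p, model$E)$f
  jn <- function(x) eng_cell_eval(model$net, 0, pmax(x, 0), model$p, model$E)$jac
  sol <- adaptive_newton(fn, jn, y, tol = tol, max_iter = max_iter)
  if (!all(sol$converged)) {
    stop("equilibration failure: Newton residual ",
         format(sol$residual_norm), " above tolerance ", format(tol))
  }
  out <- pmax(sol$x, 0)
  res <- max(abs(fn(out)))
  if (res > tol) stop("equilibration failure: residual after clipping ", format(res))
  structure(stats::setNames(out, model$species), residual = res)
}
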