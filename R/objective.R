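#' Relative difference of two non-negative statistics
#'
#' `|a - b| / |a + b|`, with the 0/0 case defined as 0 (two populations
#' whose statistic both vanish agree; this is the continuous extension
#' along matched sequences).
#' @noRd
rel_diff <- function(a, b) {
  s <- abs(a + b)
  if (!is.finite(s) || s == 0) return(0)
  abs(a - b) / s
}

#' Failure rates per burst index
#'
#' `r^0` is the relative number of model paths that failed computationally.
#' For burst index `i >= 1`, `r^i` is the relative number of model paths
#' that either failed or have fewer than `i` detected bursts, after
#' deducting the relative number of data paths with fewer than `i` bursts,
#' clipped at zero.
#'
#' @param x_catalog model `burst_catalog`.
#' @param y_catalog data `burst_catalog`.
#' @param n_bursts number of burst indices tracked (default 4).
#' @return numeric vector `r0`, `r1`, ..., values in `[0, 1]`.
#' @export
failure_rates <- function(x_catalog, y_catalog, n_bursts = 4) {
  xc <- x_catalog$cells
  yc <- y_catalog$cells
  r <- numeric(n_bursts + 1)
  names(r) <- paste0("r", 0:n_bursts)
  r[1] <- mean(xc$failed)
  for (i in seq_len(n_bursts)) {
    fx <- mean(xc$failed | dplyr::coalesce(xc$count, 0L) < i)
    fy <- mean(yc$failed | dplyr::coalesce(yc$count, 0L) < i)
    r[i + 1] <- min(max(fx - fy, 0), 1)
  }
  r
}

#' Burst-feature distance component
#'
#' Relative difference of a summary statistic (median or standard
#' deviation) of the i-th burst feature between model and data, inflated
#' by the model's missing-path rate:
#' `d = r_i + (1 - r_i) |s(Y) - s(X)| / |s(Y) + s(X)|`.
#'
#' @param x model feature values (cells with an i-th burst).
#' @param y data feature values.
#' @param r_i failure/missing rate of the model for this index.
#' @param stat `"median"` or `"sd"`.
#' @return the component value.
#' @export
burst_feature_distance <- function(x, y, r_i = 0, stat = c("median", "sd")) {
  stat <- match.arg(stat)
  stopifnot(r_i >= 0, r_i <= 1)
  if (r_i >= 1) return(1)
  if (!length(x) || !length(y)) stop("empty distribution with r_i < 1")
  f <- if (stat == "median") stats::median else stats::sd
  sx <- f(x); sy <- f(y)
  if (is.na(sx)) sx <- 0
  if (is.na(sy)) sy <- 0
  r_i + (1 - r_i) * rel_diff(sy, sx)
}

#' Burst-count distance components
#'
#' Relative differences in mean and standard deviation of the per-cell
#' burst counts, accounting for the rate of failed model paths.
#'
#' @param x_counts model counts (non-failed cells).
#' @param y_counts data counts.
#' @param r0 model failure rate.
#' @return named vector `c(mean = ..., sd = ...)`.
#' @export
count_distance <- function(x_counts, y_counts, r0 = 0) {
  r0 <- unname(r0)
  stopifnot(r0 >= 0, r0 <= 1)
  if (r0 >= 1) return(c(mean = 1, sd = 1))
  mx <- mean(x_counts); my <- mean(y_counts)
  sx <- stats::sd(x_counts); sy <- stats::sd(y_counts)
  if (is.na(sx)) sx <- 0
  if (is.na(sy)) sy <- 0
  c(mean = r0 + (1 - r0) * rel_diff(my, mx),
    sd = r0 + (1 - r0) * rel_diff(sy, sx))
}

#' Population snapshot distance
#'
#' Summed-over-time relative differences of snapshot means and standard
#' deviations:
#' `d_mean = sum_t |m_X - m_Y| / (sum_t |m_X| + sum_t |m_Y|)`, and the
#' same with standard deviations. Populations are compared on the
#' intersection of their time grids.
#'
#' @param x,y `smad_ensemble` objects, or lists with `time` and `ratio`
#'   matrix, or [population_stats()] tibbles.
#' @return named vector `c(mean = ..., sd = ...)`.
#' @export
population_distance <- function(x, y) {
  sx <- if (is.data.frame(x)) x else population_stats(ratio_matrix2(x), time_of(x))
  sy <- if (is.data.frame(y)) y else population_stats(ratio_matrix2(y), time_of(y))
  common <- intersect(sx$time, sy$time)
  if (!length(common)) stop("no overlapping time points")
  sx <- sx[match(common, sx$time), ]
  sy <- sy[match(common, sy$time), ]
  ok <- !is.na(sx$mean) & !is.na(sy$mean)
  dm <- sum(abs(sx$mean[ok] - sy$mean[ok])) /
    max(sum(abs(sx$mean[ok])) + sum(abs(sy$mean[ok])), .Machine$double.eps)
  ok2 <- !is.na(sx$sd) & !is.na(sy$sd)
  ds_num <- sum(abs(sx$sd[ok2] - sy$sd[ok2]))
  ds_den <- sum(abs(sx$sd[ok2])) + sum(abs(sy$sd[ok2]))
  ds <- if (ds_den == 0) 0 else ds_num / ds_den
  c(mean = dm, sd = ds)
}

ratio_matrix2 <- function(x) {
  if (inherits(x, "smad_ensemble")) x$ratio
  else if (is.list(x) && !is.null(x$ratio)) x$ratio
  else if (is.matrix(x)) x
  else stop("cannot extract a ratio matrix")
}
time_of <- function(x) {
  if (is.list(x) && !is.null(x$time)) x$time else stop("missing time grid")
}

#' Objective weight vector
#'
#' The printed weights of the 21 components: burst-height and duration
#' medians (weight 1) and standard deviations (1/2) for burst indices
#' 1-4, burst-count mean (4) and standard deviation (2), the failed-path
#' rate (80), snapshot mean (40) and snapshot standard deviation (4).
#' @return named numeric vector of length 21.
#' @export
objective_weights <- function() {
  c(stats::setNames(rep(1, 4), paste0("height_med_", 1:4)),
    stats::setNames(rep(0.5, 4), paste0("height_std_", 1:4)),
    stats::setNames(rep(1, 4), paste0("dur_med_", 1:4)),
    stats::setNames(rep(0.5, 4), paste0("dur_std_", 1:4)),
    count_mean = 4, count_std = 2, failed = 80,
    pop_mean = 40, pop_std = 4)
}

#' Assemble the burst-statistics objective
#'
#' Computes the 21-component weighted distance vector between a model
#' population X and a data population Y — burst height and duration
#' (median and standard deviation of the first four burst indices),
#' burst-count mean and standard deviation, the failed-path rate, and the
#' time-summed snapshot mean/standard-deviation distances — and its
#' scalar value, the sum of squared weighted components.
#'
#' @param x,y lists with components `catalog` (a `burst_catalog`) and
#'   `stats` (a [population_stats()] tibble), e.g. from
#'   [population_summary()]; `x` is the model, `y` the data.
#' @param n_bursts number of tracked burst indices (default 4).
#' @return object of class `smad_objective`: tibble (`component`, `raw`,
#'   `weight`, `value = weight * raw`) with attribute `scalar`.
#' @export
assemble_objective <- function(x, y, n_bursts = 4) {
  r <- failure_rates(x$catalog, y$catalog, n_bursts)
  xb <- x$catalog$bursts
  yb <- y$catalog$bursts
  comp <- numeric(0)
  feat <- function(b, i, col) b[[col]][b$burst_index == i]
  for (col in c("height", "duration")) {
    for (st in c("median", "sd")) {
      for (i in seq_len(n_bursts)) {
        ri <- unname(r[i + 1])
        fx <- feat(xb, i, col)
        fy <- feat(yb, i, col)
        # conventions for distributions emptied by missing bursts:
        # both empty -> the populations agree on this feature (0 rel. diff.);
        # one empty -> maximal relative difference
        v <- if (ri >= 1) 1
        else if (!length(fx) && !length(fy)) ri
        else if (!length(fx) || !length(fy)) ri + (1 - ri)
        else burst_feature_distance(fx, fy, ri, st)
        nm <- paste0(if (col == "height") "height_" else "dur_",
                     if (st == "median") "med_" else "std_", i)
        comp[nm] <- v
      }
    }
  }
  cd <- count_distance(x$catalog$cells$count[!x$catalog$cells$failed],
                       y$catalog$cells$count[!y$catalog$cells$failed], r[["r0"]])
  comp["count_mean"] <- cd[["mean"]]
  comp["count_std"] <- cd[["sd"]]
  comp["failed"] <- r[["r0"]]
  pd <- population_distance(x$stats, y$stats)
  comp["pop_mean"] <- pd[["mean"]]
  comp["pop_std"] <- pd[["sd"]]
  w <- objective_weights()
  comp <- comp[names(w)]
  out <- tibble::tibble(component = names(w), raw = unname(comp),
                        weight = unname(w), value = unname(w * comp))
  attr(out, "scalar") <- sum(out$value^2)
  attr(out, "failure_rates") <- r
  class(out) <- c("smad_objective", class(out))
  out
}

#' @export
print.smad_objective <- function(x, ...) {
  cat("<smad_objective> scalar =", format(attr(x, "scalar")), "\n")
  NextMethod()
}

#' Scalar value of an objective
#' @param x a `smad_objective`.
#' @return the sum of squared weighted components.
#' @export
objective_scalar <- function(x) attr(x, "scalar")

#' @export
glance.smad_objective <- function(x, ...) {
  tibble::tibble(scalar = attr(x, "scalar"),
                 failed_rate = attr(x, "failure_rates")[["r0"]])
}

#' Bundle a population for objective evaluation
#'
#' Runs burst detection and snapshot statistics on a population so it can
#' be fed to [assemble_objective()].
#'
#' @param x a `smad_ensemble`, or a ratio matrix with `time`.
#' @param config a [detection_config()].
#' @param time time grid for matrix input.
#' @return list with `catalog` and `stats`.
#' @export
population_summary <- function(x, config = detection_config(), time = NULL) {
  tt <- time %||% (if (inherits(x, "smad_ensemble")) x$time else
                     stop("time grid required"))
  m <- ratio_matrix2(x)
  list(catalog = detect_bursts(m, config, time = tt),
       stats = population_stats(m, time = tt))
}

#' Residual rescaling, log-likelihood and AIC
#'
#' Introduces per-group scale factors `s_g` for the objective components
#' `r_k`, chosen to minimize `sum_k (r_k / s_k)^2 + 2 log(s_k)`; the
#' closed-form minimizer per group with `K_g` members is
#' `s_g = sqrt(mean(r_k^2))`. The rescaled residuals define a Gaussian
#' model whose log-likelihood and AIC (with the number of fitted noise
#' parameters as degrees of freedom) are returned.
#'
#' @param residuals numeric vector of objective components.
#' @param groups factor/character of the same length; components sharing a
#'   group share a scale factor (e.g. all burst-height components).
#' @param n_fitted number of fitted noise parameters of the model.
#' @param reference_aic optional AIC of a reference model, for the ratio.
#' @return list with `scales` (tibble `group`, `s`, `n`), `log_likelihood`,
#'   `aic`, and `aic_ratio` when a reference is given. All-zero groups are
#'   flagged with `degenerate = TRUE` in `scales`.
#' @export
aic_rescale <- function(residuals, groups, n_fitted = 0, reference_aic = NULL) {
  stopifnot(length(residuals) == length(groups), all(is.finite(residuals)))
  gs <- split(seq_along(residuals), groups)
  scales <- purrr::imap_dfr(gs, function(idx, g) {
    s <- sqrt(mean(residuals[idx]^2))
    tibble::tibble(group = g, s = s, n = length(idx), degenerate = s == 0)
  })
  if (any(scales$degenerate)) {
    warning("degenerate scale (all residuals zero) in group(s): ",
            paste(scales$group[scales$degenerate], collapse = ", "))
  }
  s_k <- scales$s[match(groups, scales$group)]
  ok <- s_k > 0
  ll <- -0.5 * sum((residuals[ok] / s_k[ok])^2 + log(2 * pi * s_k[ok]^2))
  aic <- 2 * n_fitted - 2 * ll
  out <- list(scales = scales, log_likelihood = ll, aic = aic)
  if (!is.null(reference_aic)) out$aic_ratio <- aic / reference_aic
  out
}
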