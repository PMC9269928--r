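#' Scatter-search global minimizer
#'
#' A compact evolutionary scatter search: a latin-hypercube sample of the
#' (box-constrained) space seeds a reference set combining the best and
#' the most diverse members; pairwise convex/reflective combinations of
#' reference members generate offspring that greedily replace worse
#' members; the search stops when the best value stagnates (relative
#' improvement below `stag_tol` for `stag_patience` consecutive
#' iterations) or after `max_iter` iterations. Every evaluation is logged.
#'
#' @param fn objective function of a numeric vector, to be minimized;
#'   non-finite return values are treated as failures (penalized).
#' @param lower,upper box constraints.
#' @param n_lhs size of the initial latin-hypercube sample (default
#'   `10 * length(lower)`).
#' @param ref_size reference-set size.
#' @param max_iter maximum number of combination rounds.
#' @param stag_tol,stag_patience stagnation stopping rule.
#' @param seed integer seed.
#' @return list with `par`, `value`, `trace` (tibble of all evaluations),
#'   `n_eval`, `stopped` (`"stagnation"` or `"max_iter"`).
#' @export
scatter_search <- function(fn, lower, upper, n_lhs = 10 * length(lower),
                           ref_size = 6, max_iter = 15,
                           stag_tol = 1e-3, stag_patience = 3, seed = NULL) {
  stopifnot(length(lower) == length(upper), all(upper > lower))
  if (!is.null(seed)) set.seed(seed)
  d <- length(lower)
  trace <- list()
  n_eval <- 0L
  evalf <- function(x, iter) {
    v <- tryCatch(fn(x), error = function(e) Inf)
    if (!is.finite(v)) v <- 1e12
    n_eval <<- n_eval + 1L
    trace[[n_eval]] <<- tibble::tibble(eval = n_eval, iter = iter,
                                       value = v,
                                       !!!stats::setNames(as.list(x), paste0("x", seq_len(d))))
    v
  }
  X <- lhs::randomLHS(n_lhs, d)
  X <- sweep(sweep(X, 2, upper - lower, "*"), 2, lower, "+")
  vals <- apply(X, 1, evalf, iter = 0L)

  # reference set: best half + most diverse half
  ord <- order(vals)
  nb <- ceiling(ref_size / 2)
  ref_idx <- ord[seq_len(min(nb, length(ord)))]
  rest <- setdiff(seq_len(nrow(X)), ref_idx)
  while (length(ref_idx) < ref_size && length(rest)) {
    dmin <- vapply(rest, function(i) {
      min(sqrt(colSums((t(X[ref_idx, , drop = FALSE]) - X[i, ])^2)))
    }, numeric(1))
    pick <- rest[which.max(dmin)]
    ref_idx <- c(ref_idx, pick)
    rest <- setdiff(rest, pick)
  }
  R <- X[ref_idx, , drop = FALSE]
  rv <- vals[ref_idx]

  best_hist <- min(rv)
  stag <- 0L
  stopped <- "max_iter"
  ls_radius <- 0.1
  for (it in seq_len(max_iter)) {
    pairs <- utils::combn(nrow(R), 2)
    for (k in seq_len(ncol(pairs))) {
      i <- pairs[1, k]; j <- pairs[2, k]
      alpha <- stats::runif(1, -0.3, 1.3)
      child <- R[i, ] + alpha * (R[j, ] - R[i, ])
      child <- pmin(pmax(child, lower), upper)
      v <- evalf(child, it)
      w <- which.max(rv)
      if (v < rv[w]) { R[w, ] <- child; rv[w] <- v }
    }
    # (1+1)-style local refinement around the incumbent: the step radius
    # grows on success and shrinks on failure, so the search keeps
    # progressing once the reference set has contracted
    best_before <- min(rv)
    b0 <- which.min(rv)
    child <- R[b0, ] + stats::runif(d, -ls_radius, ls_radius) * (upper - lower)
    child <- pmin(pmax(child, lower), upper)
    v <- evalf(child, it)
    if (v < best_before) {
      w <- which.max(rv)
      R[w, ] <- child; rv[w] <- v
      ls_radius <- min(ls_radius * 1.5, 0.25)
    } else {
      ls_radius <- max(ls_radius * 0.6, 1e-7)
      w <- which.max(rv)
      if (v < rv[w]) { R[w, ] <- child; rv[w] <- v }
    }
    new_best <- min(rv)
    rel <- (best_hist - new_best) / max(abs(best_hist), .Machine$double.eps)
    stag <- if (rel < stag_tol) stag + 1L else 0L
    best_hist <- new_best
    if (stag >= stag_patience) { stopped <- "stagnation"; break }
  }
  b <- which.min(rv)
  list(par = R[b, ], value = rv[b], trace = dplyr::bind_rows(trace),
       n_eval = n_eval, stopped = stopped)
}
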