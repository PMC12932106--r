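#' Individual Derringer desirability for a maximized response
#'
#' Maps a response value onto `[0, 1]`: 0 below the lower limit L, 1 above
#' the target T, and ((y - L)/(T - L))^r in between. The exponent r in
#' (0, 1] tunes how quickly partial credit accrues (r = 1 is linear).
#'
#' @param y response value(s).
#' @param L lower limit below which the response is unacceptable.
#' @param T target at and above which the response is fully desirable.
#' @param r shape exponent in (0, 1].
#' @return desirability value(s) in `[0, 1]`.
#' @examples
#' desirability_one(c(0, 5, 10, 20), L = 0, T = 10)
#' @export
desirability_one <- function(y, L, T, r = 1) {
  if (!is.finite(L) || !is.finite(T) || L >= T) {
    stop("`L` must be strictly below `T`")
  }
  if (r <= 0 || r > 1) stop("`r` must lie in (0, 1]")
  d <- pmin(pmax((y - L) / (T - L), 0), 1)^r
  d[y < L] <- 0
  d[y > T] <- 1
  d
}

#' Overall desirability (geometric mean)
#'
#' Merges k individual desirabilities into D = prod(d_i)^(1/k). The
#' geometric mean annihilates at any d_i = 0: a condition unacceptable on
#' one response is unacceptable overall, however good the others.
#'
#' @param d numeric vector of individual desirabilities, or a matrix with
#'   one column per response (rows are evaluated independently).
#' @return overall desirability D in `[0, 1]`.
#' @examples
#' desirability_overall(c(0.25, 0.25, 0.25))   # 0.25
#' @export
desirability_overall <- function(d) {
  dm <- if (is.matrix(d)) d else matrix(d, nrow = 1)
  if (any(dm < 0 | dm > 1)) stop("all d_i must lie in [0, 1]")
  out <- apply(dm, 1, function(z) prod(z)^(1 / length(z)))
  if (!is.matrix(d)) out[1] else out
}

#' Per-response desirability settings
#'
#' @param response character vector of response names.
#' @param L,T,r numeric vectors (recycled) of lower limits, targets and
#'   shape exponents.
#' @return A `desirability_spec` data frame.
#' @export
desirability_spec <- function(response, L, T, r = 1) {
  df <- data.frame(response = response, L = L, T = T, r = r)
  if (any(df$L >= df$T)) stop("every `L` must be strictly below its `T`")
  if (any(df$r <= 0 | df$r > 1)) stop("every `r` must lie in (0, 1]")
  class(df) <- c("desirability_spec", "data.frame")
  df
}

#' Square region of coded factor space
#'
#' The feasible region of an FCCD on the coded scale: the square
#' `[-1, 1]` per factor.
#'
#' @param factors names of the coded factors.
#' @export
coded_square <- function(factors = c("dna", "fv")) {
  structure(list(factors = factors), class = "coded_square")
}

#' Grid of feasible points over an optimization region
#'
#' @param region a [mixture_bounds()] (barycentric lattice inside the
#'   constrained simplex) or a [coded_square()] (regular lattice).
#' @param step grid resolution.
#' @return Matrix of feasible points, one row per grid point.
#' @export
region_grid <- function(region, step) {
  if (inherits(region, "mixture_bounds")) {
    g <- simplex_candidates(region, step)$points
  } else if (inherits(region, "coded_square")) {
    s <- seq(-1, 1, by = step)
    if (abs(s[length(s)] - 1) > 1e-9) s <- c(s, 1)
    g <- as.matrix(expand.grid(rep(list(s), length(region$factors))))
    colnames(g) <- region$factors
  } else {
    stop("`region` must be a mixture_bounds or coded_square object")
  }
  if (nrow(g) == 0) stop("empty feasible region: no grid point satisfies the constraints")
  g
}

default_grid_step <- function(region) {
  if (inherits(region, "mixture_bounds")) 0.02 else 0.05
}

predict_models <- function(models, points) {
  out <- vapply(models, function(m) predict(m, points), numeric(nrow(points)))
  matrix(out, nrow = nrow(points), dimnames = list(NULL, names(models)))
}

#' Auto-scaled desirability settings over a region
#'
#' Sets, for each fitted response model, the lower limit L to the minimum
#' and the target T to the maximum predicted value over the region grid —
#' i.e. optimization is relative to what the explored space can deliver.
#'
#' @param models named list of fitted models (one per response).
#' @param region optimization region.
#' @param grid_step grid resolution (defaults per region type).
#' @param r shape exponent(s).
#' @return A [desirability_spec()].
#' @export
auto_desirability_spec <- function(models, region, grid_step = NULL, r = 1) {
  if (is.null(grid_step)) grid_step <- default_grid_step(region)
  preds <- predict_models(models, region_grid(region, grid_step))
  L <- apply(preds, 2, min)
  T <- apply(preds, 2, max)
  if (any(T - L < 1e-12)) {
    stop("degenerate response surface: predicted range collapses (T = L) for ",
         paste(names(models)[T - L < 1e-12], collapse = ", "))
  }
  desirability_spec(names(models), L, T, r)
}

desirability_matrix <- function(preds, spec) {
  spec <- spec[match(colnames(preds), spec$response), ]
  d <- preds
  for (j in seq_len(ncol(preds))) {
    d[, j] <- desirability_one(preds[, j], spec$L[j], spec$T[j], spec$r[j])
  }
  d
}

#' Maximize overall desirability over a region
#'
#' Scans a dense grid of the feasible region, then polishes the best grid
#' point(s) with a derivative-free local search (Nelder-Mead, penalized
#' outside the region, 200-iteration cap). With `top > 1`, distinct local
#' optima of the grid surface are polished and returned ranked by overall
#' desirability — useful when responses conflict and two operating points
#' are worth reporting.
#'
#' @param models named list of fitted (or true-surface) models sharing the
#'   region's domain convention.
#' @param spec a [desirability_spec()]; `NULL` auto-scales via
#'   [auto_desirability_spec()].
#' @param region a [mixture_bounds()] or [coded_square()].
#' @param grid_step scan resolution (default 0.02 simplex, 0.05 square).
#' @param top number of ranked local optima to return.
#' @param polish logical; run the local refinement after the grid scan.
#' @param maxit iteration cap for the local search.
#' @param seed optional integer seed (the procedure is deterministic; the
#'   seed is recorded in the metadata for provenance).
#' @return An object of class `optimization_result`: `points` (one row per
#'   reported optimum), `predictions`, `d` (individual desirabilities),
#'   `D` (overall), and flags (`plateau`, `all_zero`).
#' @export
optimize_desirability <- function(models, spec = NULL, region,
                                  grid_step = NULL, top = 1, polish = TRUE,
                                  maxit = 200, seed = NULL) {
  if (is.null(grid_step)) grid_step <- default_grid_step(region)
  if (grid_step <= 0) stop("`grid_step` must be positive")
  grid <- region_grid(region, grid_step)
  if (is.null(spec)) spec <- auto_desirability_spec(models, region, grid_step)
  preds <- predict_models(models, grid)
  dmat <- desirability_matrix(preds, spec)
  D <- desirability_overall(dmat)

  all_zero <- max(D) <= 0
  plateau <- sum(D >= 1 - 1e-12) > 1

  picks <- if (top == 1 || all_zero) {
    which.max(D)
  } else {
    local_maxima(grid, D, radius = 1.5 * grid_step, top = top)
  }

  pts <- grid[picks, , drop = FALSE]
  if (polish && !all_zero) {
    for (i in seq_len(nrow(pts))) {
      pts[i, ] <- polish_point(pts[i, ], models, spec, region, maxit)
    }
  }
  preds_opt <- predict_models(models, pts)
  d_opt <- desirability_matrix(preds_opt, spec)
  D_opt <- desirability_overall(d_opt)
  ord <- order(D_opt, decreasing = TRUE)

  structure(list(points = pts[ord, , drop = FALSE],
                 predictions = preds_opt[ord, , drop = FALSE],
                 d = d_opt[ord, , drop = FALSE],
                 D = D_opt[ord],
                 spec = spec,
                 plateau = plateau, all_zero = all_zero,
                 meta = list(grid_step = grid_step, maxit = maxit,
                             seed = seed, n_grid = nrow(grid))),
            class = "optimization_result")
}

# grid-local maxima (no neighbour within `radius` beats the point),
# ranked by D; greedy fallback keeps the global argmax first
local_maxima <- function(grid, D, radius, top) {
  ord <- order(D, decreasing = TRUE)
  chosen <- integer(0)
  for (i in ord) {
    d2 <- rowSums((grid - matrix(grid[i, ], nrow(grid), ncol(grid),
                                 byrow = TRUE))^2)
    nb <- which(d2 <= radius^2 & d2 > 0)
    if (all(D[nb] <= D[i] + 1e-12)) {
      # reject points adjacent to an already chosen (higher) optimum
      if (length(chosen) == 0 ||
          all(rowSums((grid[chosen, , drop = FALSE] -
                       matrix(grid[i, ], length(chosen), ncol(grid),
                              byrow = TRUE))^2) > (2 * radius)^2)) {
        chosen <- c(chosen, i)
      }
    }
    if (length(chosen) >= top) break
  }
  if (length(chosen) == 0) chosen <- ord[1]
  chosen
}

polish_point <- function(x0, models, spec, region, maxit) {
  simplex <- inherits(region, "mixture_bounds")
  to_full <- function(par) {
    if (simplex) {
      x <- c(par[1], 1 - par[1] - par[2], par[2])
      names(x) <- region$components
      x
    } else par
  }
  feasible <- function(x) {
    if (simplex) {
      all(x >= region$lower - 1e-9) && all(x <= region$upper + 1e-9)
    } else {
      all(x >= -1 - 1e-9) && all(x <= 1 + 1e-9)
    }
  }
  objective <- function(par) {
    x <- to_full(par)
    if (!feasible(x)) return(1e6 + sum(pmax(abs(x - 0.5) - 0.5, 0)))
    p <- predict_models(models, matrix(x, 1, dimnames = list(NULL, names(x))))
    -desirability_overall(desirability_matrix(p, spec))
  }
  par0 <- if (simplex) unname(x0[c(1, 3)]) else unname(x0)
  res <- stats::optim(par0, objective, method = "Nelder-Mead",
                      control = list(maxit = maxit))
  x1 <- to_full(res$par)
  if (feasible(x1) && -res$value >= -objective(par0)) {
    if (simplex) x1 <- x1 / sum(x1)
    x1
  } else {
    x0
  }
}

#' @export
print.optimization_result <- function(x, ...) {
  cat("Desirability optimum (overall D =",
      paste(format(x$D, digits = 4), collapse = ", "), ")\n")
  print(round(cbind(x$points, D = x$D), 4))
  invisible(x)
}

#' Threshold (profiler) region mask
#'
#' Evaluates each response model on a region grid and flags, per grid
#' point, whether the prediction meets its threshold. The combined flag
#' marks the "white area": the part of the experimental space where every
#' response exceeds its threshold simultaneously.
#'
#' @param models named list of fitted models.
#' @param thresholds named numeric vector, one threshold per response.
#' @param region optimization region.
#' @param grid_step grid resolution.
#' @return A `region_mask` data frame: grid coordinates, `pred_*`,
#'   `pass_*` and the combined `pass_all` column.
#' @export
threshold_region <- function(models, thresholds, region, grid_step = NULL) {
  if (is.null(grid_step)) grid_step <- default_grid_step(region)
  if (grid_step <= 0) stop("`grid_step` must be positive")
  if (any(!is.finite(thresholds) & !is.infinite(thresholds))) {
    stop("thresholds must be numeric")
  }
  grid <- region_grid(region, grid_step)
  preds <- predict_models(models, grid)
  thresholds <- thresholds[colnames(preds)]
  pass <- sweep(preds, 2, thresholds, ">=")
  out <- data.frame(grid, check.names = FALSE)
  for (nm in colnames(preds)) out[[paste0("pred_", nm)]] <- preds[, nm]
  for (nm in colnames(preds)) out[[paste0("pass_", nm)]] <- pass[, nm]
  out$pass_all <- apply(pass, 1, all)
  class(out) <- c("region_mask", "data.frame")
  attr(out, "thresholds") <- thresholds
  attr(out, "grid_step") <- grid_step
  out
}

#' Equal-desirability thresholds per response
#'
#' Inverts the individual desirability function at a common level: the
#' returned threshold per response is the y-value at which d_i = level
#' given (L, T, r), i.e. y = L + (T - L) * level^(1/r). Drawing the
#' threshold contour at the same level for every response gives each
#' response equal weight in delimiting the acceptable region.
#'
#' @param models named list of fitted models.
#' @param region optimization region.
#' @param level common desirability level in (0, 1].
#' @param spec optional [desirability_spec()]; defaults to the auto-scaled
#'   spec (L = region minimum, T = region maximum per response).
#' @param grid_step grid resolution for the auto-scaled spec.
#' @return Named numeric vector of response thresholds.
#' @export
equal_weight_thresholds <- function(models, region, level, spec = NULL,
                                    grid_step = NULL) {
  if (level <= 0 || level > 1) stop("`level` must lie in (0, 1]")
  if (is.null(spec)) spec <- auto_desirability_spec(models, region, grid_step)
  thr <- spec$L + (spec$T - spec$L) * level^(1 / spec$r)
  stats::setNames(thr, spec$response)
}
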