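#' Per-component bounds for a constrained mixture region
#'
#' Defines the constrained simplex over which plasmid mass fractions are
#' allowed to vary. In the rAAV triple-transfection setting the three
#' components are the pHelper, pRepCap and pGOI plasmids, each bounded
#' between 10% and 60% of the total DNA mass.
#'
#' @param lower numeric vector of lower fraction limits, one per component.
#' @param upper numeric vector of upper fraction limits, one per component.
#' @param components character vector of component names.
#' @return An object of class `mixture_bounds`.
#' @examples
#' mixture_bounds()                      # the 10--60% plasmid region
#' mixture_bounds(c(0, 0, 0), c(1, 1, 1))  # the full simplex
#' @export
mixture_bounds <- function(lower = c(0.1, 0.1, 0.1),
                           upper = c(0.6, 0.6, 0.6),
                           components = c("pHelper", "pRepCap", "pGOI")) {
  lower <- as.numeric(lower)
  upper <- as.numeric(upper)
  k <- length(lower)
  if (length(upper) != k || length(components) != k) {
    stop("`lower`, `upper` and `components` must have the same length")
  }
  if (any(!is.finite(lower)) || any(!is.finite(upper))) {
    stop("bounds must be finite")
  }
  if (any(lower < 0) || any(upper > 1) || any(lower >= upper)) {
    stop("bounds must satisfy 0 <= lower_i < upper_i <= 1 for every component")
  }
  if (sum(lower) > 1 + 1e-12) {
    stop("infeasible bounds: sum of lower limits exceeds 1 (empty region)")
  }
  if (sum(upper) < 1 - 1e-12) {
    stop("infeasible bounds: sum of upper limits is below 1 (empty region)")
  }
  structure(list(lower = lower, upper = upper, components = components),
            class = "mixture_bounds")
}

#' @export
print.mixture_bounds <- function(x, ...) {
  cat("Constrained mixture region (", length(x$components),
      " components)\n", sep = "")
  for (i in seq_along(x$components)) {
    cat(sprintf("  %-8s in [%.3f, %.3f]\n",
                x$components[i], x$lower[i], x$upper[i]))
  }
  invisible(x)
}

#' Lattice candidate set over a constrained simplex
#'
#' Enumerates every composition whose coordinates are integer multiples of
#' `step`, sum to one, and lie inside the component bounds. The lattice is
#' the candidate support from which the D-optimal exchange selects runs.
#'
#' @param bounds a [mixture_bounds()] object.
#' @param step lattice resolution as a fraction; must divide 1.
#' @return An object of class `candidate_set` with a `points` matrix
#'   (rows ordered lexicographically) and the `step` used.
#' @examples
#' cs <- simplex_candidates(mixture_bounds(), step = 0.1)
#' nrow(cs$points)  # 27 compositions at 0.1 resolution
#' @export
simplex_candidates <- function(bounds, step = 0.05) {
  stopifnot(inherits(bounds, "mixture_bounds"))
  if (!is.numeric(step) || length(step) != 1 || step <= 0) {
    stop("`step` must be a single positive fraction")
  }
  N <- round(1 / step)
  if (abs(N * step - 1) > 1e-9) stop("`step` must divide 1 exactly")
  k <- length(bounds$lower)
  lo <- as.integer(ceiling(bounds$lower * N - 1e-9))
  hi <- as.integer(floor(bounds$upper * N + 1e-9))

  # enumerate integer compositions a_1 + ... + a_k = N with lo_i <= a_i <= hi_i
  grids <- lapply(seq_len(k - 1), function(i) seq.int(lo[i], hi[i]))
  head_combos <- as.matrix(rev(expand.grid(rev(grids))))
  last <- N - rowSums(head_combos)
  keep <- last >= lo[k] & last <= hi[k]
  pts <- cbind(head_combos[keep, , drop = FALSE], last[keep]) / N
  colnames(pts) <- bounds$components
  rownames(pts) <- NULL
  ord <- do.call(order, lapply(seq_len(k), function(j) pts[, j]))
  structure(list(points = pts[ord, , drop = FALSE], step = step,
                 bounds = bounds),
            class = "candidate_set")
}

#' Scheffe quadratic model matrix
#'
#' Builds the intercept-free Scheffe quadratic model matrix: one linear
#' blending column per component and one binary blending column per
#' unordered component pair. For k components the matrix has
#' k + k(k-1)/2 columns (6 for the three-plasmid system).
#'
#' @param x matrix or data frame of compositions (rows sum to 1).
#' @param components optional component names (taken from `x` if absent).
#' @return Numeric model matrix with labelled columns.
#' @export
scheffe_matrix <- function(x, components = NULL) {
  x <- as.matrix(x)
  if (is.null(components)) {
    components <- colnames(x)
    if (is.null(components)) components <- paste0("x", seq_len(ncol(x)))
  }
  k <- ncol(x)
  pairs <- utils::combn(k, 2)
  blend <- x[, pairs[1, ], drop = FALSE] * x[, pairs[2, ], drop = FALSE]
  colnames(blend) <- paste(components[pairs[1, ]], components[pairs[2, ]],
                           sep = ":")
  colnames(x) <- components
  cbind(x, blend)
}

log_det_xtx <- function(X) {
  M <- crossprod(X)
  R <- tryCatch(chol(M), error = function(e) NULL)
  if (is.null(R)) return(-Inf)
  2 * sum(log(diag(R)))
}

#' Select a D-optimal mixture design by Fedorov point exchange
#'
#' Searches for the `n_runs`-point subset of the candidate lattice that
#' maximizes the log-determinant of the information matrix X'X, where X is
#' the Scheffe quadratic model matrix. D-optimality minimizes the
#' generalized variance of the coefficient estimators, which is the
#' criterion of choice when the constrained region rules out standard
#' simplex-lattice designs.
#'
#' The search runs `n_starts` random starts of a Fedorov point-exchange:
#' each pass tries every (design point, candidate) swap and accepts the
#' best strict improvement (> 1e-10), with ties broken by lowest candidate
#' index, until no swap improves. Selection is without replacement while
#' `n_runs` does not exceed the candidate count; beyond that the design
#' replicates candidates.
#'
#' @param candidates a [simplex_candidates()] object.
#' @param n_runs number of runs; must be at least the number of model
#'   terms (6 for three components).
#' @param model model form; only `"scheffe_quadratic"` is supported.
#' @param n_starts number of random restarts.
#' @param seed integer seed making the search reproducible.
#' @return An object of class `mixture_design` with the run matrix,
#'   replicate counts, the attained `criterion_value` (log-det) and the
#'   per-swap criterion trace of the winning start.
#' @examples
#' cs <- simplex_candidates(mixture_bounds(), step = 0.1)
#' d <- d_optimal_select(cs, n_runs = 8, seed = 1)
#' d$criterion_value
#' @export
d_optimal_select <- function(candidates, n_runs = 13,
                             model = "scheffe_quadratic",
                             n_starts = 10, seed = NULL) {
  stopifnot(inherits(candidates, "candidate_set"))
  model <- match.arg(model, "scheffe_quadratic")
  pts <- candidates$points
  m <- nrow(pts)
  if (m == 0) stop("candidate set is empty")
  Fmat <- scheffe_matrix(pts)
  p <- ncol(Fmat)
  if (n_runs < p) {
    stop(sprintf("`n_runs` (%d) must be at least the %d Scheffe model terms",
                 n_runs, p))
  }
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", .GlobalEnv)) {
      get(".Random.seed", .GlobalEnv)
    }
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(seed)
  }
  replace <- n_runs > m

  best_idx <- NULL
  best_crit <- -Inf
  best_trace <- numeric(0)
  for (s in seq_len(n_starts)) {
    idx <- sort(sample.int(m, n_runs, replace = replace))
    crit <- log_det_xtx(Fmat[idx, , drop = FALSE])
    trace <- crit
    repeat {
      improved <- FALSE
      for (i in seq_len(n_runs)) {
        cur <- crit
        best_j <- NA_integer_
        for (j in seq_len(m)) {
          if (j == idx[i]) next
          if (!replace && j %in% idx) next
          trial <- idx
          trial[i] <- j
          val <- log_det_xtx(Fmat[trial, , drop = FALSE])
          if (val > cur + 1e-10) {   # strict improvement; first best j wins
            cur <- val
            best_j <- j
          }
        }
        if (!is.na(best_j)) {
          idx[i] <- best_j
          crit <- cur
          trace <- c(trace, crit)
          improved <- TRUE
        }
      }
      if (!improved) break
    }
    if (crit > best_crit + 1e-10) {
      best_crit <- crit
      best_idx <- sort(idx)
      best_trace <- trace
    }
  }
  if (!is.finite(best_crit)) {
    stop("information matrix singular for every start; ",
         "increase `n_runs` or refine the candidate lattice")
  }
  runs <- pts[best_idx, , drop = FALSE]
  rownames(runs) <- NULL
  key <- apply(runs, 1, paste, collapse = ",")
  structure(list(runs = runs,
                 replicate_counts = as.integer(table(key)[unique(key)]),
                 criterion_value = best_crit,
                 trace = best_trace,
                 bounds = candidates$bounds,
                 seed = seed),
            class = "mixture_design")
}

#' @export
print.mixture_design <- function(x, ...) {
  cat("D-optimal mixture design:", nrow(x$runs), "runs,",
      "log|X'X| =", format(x$criterion_value, digits = 6), "\n")
  print(round(x$runs, 4))
  invisible(x)
}

#' Face-centered central composite design for two factors
#'
#' Builds the coded FCCD for the total-DNA and transfection-reagent (FV)
#' factors: the four factorial corners at (+/-1, +/-1), the four face
#' centers at (+/-1, 0) and (0, +/-1), and `n_center` replicates of the
#' center point. The affine decode map sends -1/0/+1 to the low, mid and
#' high actual levels of each factor.
#'
#' @param n_center number of center-point replicates (>= 1).
#' @param dna_range actual (low, high) total DNA in micrograms per mL.
#' @param fv_range actual (low, high) FV-to-DNA ratio.
#' @param factors names of the two coded factors.
#' @return An object of class `fccd_design` with coded and actual run
#'   matrices and the decode limits.
#' @examples
#' d <- fccd_design(n_center = 3)
#' nrow(d$coded)   # 11 runs
#' @export
fccd_design <- function(n_center = 3, dna_range = c(1, 3),
                        fv_range = c(0.5, 2),
                        factors = c("dna", "fv")) {
  if (n_center < 1) stop("`n_center` must be at least 1")
  limits <- list(dna_range, fv_range)
  names(limits) <- factors
  for (f in factors) {
    r <- limits[[f]]
    if (length(r) != 2 || any(!is.finite(r)) || r[1] >= r[2]) {
      stop(sprintf("limits for factor '%s' must be finite with low < high", f))
    }
  }
  corners <- as.matrix(expand.grid(c(-1, 1), c(-1, 1)))
  faces <- rbind(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  centers <- matrix(0, n_center, 2)
  coded <- rbind(corners, faces, centers)
  dimnames(coded) <- list(NULL, factors)
  obj <- structure(list(coded = coded, n_center = n_center, limits = limits,
                        factors = factors),
                   class = "fccd_design")
  obj$actual <- decode_fccd(obj, coded)
  obj
}

#' Decode coded FCCD coordinates to actual factor levels
#'
#' @param design an [fccd_design()] object.
#' @param coded matrix (or vector) of coded coordinates in `[-1, 1]`.
#' @return Matrix of actual levels; `decode(0)` is the factor midpoint.
#' @export
decode_fccd <- function(design, coded) {
  stopifnot(inherits(design, "fccd_design"))
  coded <- matrix(as.numeric(coded), ncol = length(design$factors),
                  dimnames = list(NULL, design$factors))
  out <- coded
  for (i in seq_along(design$factors)) {
    r <- design$limits[[i]]
    out[, i] <- mean(r) + coded[, i] * diff(r) / 2
  }
  out
}

#' Encode actual FCCD factor levels to coded coordinates
#'
#' @inheritParams decode_fccd
#' @param actual matrix (or vector) of actual factor levels.
#' @export
code_fccd <- function(design, actual) {
  stopifnot(inherits(design, "fccd_design"))
  actual <- matrix(as.numeric(actual), ncol = length(design$factors),
                   dimnames = list(NULL, design$factors))
  out <- actual
  for (i in seq_along(design$factors)) {
    r <- design$limits[[i]]
    out[, i] <- (actual[, i] - mean(r)) / (diff(r) / 2)
  }
  out
}

#' Rescale coded coordinates from -1..+1 to a 0..1 display convention
#'
#' Internal model columns always use the centered -1..+1 coding; some
#' profiler displays label the same limits from 0 to 1 instead.
#'
#' @param coded numeric coded values in `[-1, 1]`.
#' @export
coded_to_unit <- function(coded) (coded + 1) / 2

#' @export
print.fccd_design <- function(x, ...) {
  cat("Face-centered central composite design:", nrow(x$coded), "runs (",
      x$n_center, "center )\n")
  print(cbind(x$coded, x$actual))
  invisible(x)
}

#' Write a mixture or FCCD design to CSV
#'
#' Mixture designs use columns `run_id,pHelper,pRepCap,pGOI` (fractions,
#' 6 decimal places); FCCD designs use
#' `run_id,dna_coded,fv_coded,dna_actual,fv_actual`.
#'
#' @param design a `mixture_design` or `fccd_design`.
#' @param path output CSV path.
#' @export
write_design <- function(design, path) {
  if (inherits(design, "mixture_design")) {
    df <- data.frame(run_id = seq_len(nrow(design$runs)),
                     round(design$runs, 6), check.names = FALSE)
  } else if (inherits(design, "fccd_design")) {
    df <- data.frame(run_id = seq_len(nrow(design$coded)),
                     dna_coded = design$coded[, 1],
                     fv_coded = design$coded[, 2],
                     dna_actual = design$actual[, 1],
                     fv_actual = design$actual[, 2])
  } else {
    stop("`design` must be a mixture_design or fccd_design")
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a design CSV written by [write_design()]
#'
#' @param path CSV path.
#' @return A data frame with the design columns.
#' @export
read_design <- function(path) {
  utils::read.csv(path, check.names = FALSE)
}
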