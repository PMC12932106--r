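#' Measurement-noise model for simulated transfection runs
#'
#' Run-to-run scatter of the three responses, expressed on their natural
#' scales: log10 units for Log(Vp), percentage points for % full and for
#' viability. Defaults emulate typical biological-replicate scatter of
#' titer and viability assays.
#'
#' @param sigma_log_vp standard deviation of Log(Vp) noise (log10 units).
#' @param sigma_pct_full standard deviation of % full noise (points).
#' @param sigma_viability standard deviation of viability noise (points).
#' @export
noise_model <- function(sigma_log_vp = 0.1, sigma_pct_full = 2,
                        sigma_viability = 2) {
  s <- c(sigma_log_vp, sigma_pct_full, sigma_viability)
  if (any(!is.finite(s)) || any(s < 0)) {
    stop("noise sigmas must be non-negative and finite")
  }
  structure(list(sigma_log_vp = sigma_log_vp,
                 sigma_pct_full = sigma_pct_full,
                 sigma_viability = sigma_viability),
            class = "noise_model")
}

#' True Scheffe surface as a predictable model object
#'
#' Wraps a known coefficient vector so it can be evaluated (and optimized)
#' through the same `predict()` path as a fitted model.
#'
#' @param beta length-6 coefficient vector (3 linear, 3 blending terms).
#' @param components component names.
#' @export
scheffe_surface <- function(beta, components = c("pHelper", "pRepCap", "pGOI")) {
  k <- length(components)
  labels <- c(components,
              apply(utils::combn(components, 2), 2, paste, collapse = ":"))
  stopifnot(length(beta) == length(labels))
  structure(list(beta = stats::setNames(as.numeric(beta), labels),
                 k = k, components = components),
            class = c("scheffe_surface", "scheffe_model"))
}

#' True second-order surface as a predictable model object
#'
#' @param beta length-6 coefficient vector in the order intercept, linear,
#'   quadratic, interaction.
#' @param factors coded factor names.
#' @export
rsm_surface <- function(beta, factors = c("dna", "fv")) {
  n <- length(factors)
  labels <- c("(Intercept)", factors, paste0(factors, "^2"),
              apply(utils::combn(factors, 2), 2, paste, collapse = ":"))
  stopifnot(length(beta) == length(labels))
  structure(list(beta = stats::setNames(as.numeric(beta), labels),
                 n_factors = n, factors = factors),
            class = c("rsm_surface", "rsm_model"))
}

# Map a quadratic q(s,t) = A + B s + C t + E s^2 + F t^2 + G st, written in
# the (pHelper, pGOI) simplex chart with pRepCap = 1 - s - t, to the six
# Scheffe coefficients (b1, b2, b3, b12, b13, b23).
quad_to_scheffe <- function(A, B, C, E, F, G) {
  b12 <- -E
  b23 <- -F
  b13 <- G - E - F
  c(A + B + E, A, A + C + F, b12, b13, b23)
}

# Scheffe gradient at a composition, projected onto the simplex tangent
# plane (components of the raw gradient centered to sum to zero).
scheffe_tangent_gradient <- function(beta, x) {
  k <- length(x)
  g <- numeric(k)
  pairs <- utils::combn(k, 2)
  for (i in seq_len(k)) {
    g[i] <- beta[i]
    for (p in seq_len(ncol(pairs))) {
      a <- pairs[1, p]; b <- pairs[2, p]
      if (a == i) g[i] <- g[i] + beta[k + p] * x[b]
      if (b == i) g[i] <- g[i] + beta[k + p] * x[a]
    }
  }
  g - mean(g)
}

# Hessian of the Scheffe quadratic in the (x1, x3) simplex chart.
scheffe_chart_hessian <- function(beta) {
  b12 <- beta[4]; b13 <- beta[5]; b23 <- beta[6]
  matrix(c(-2 * b12, b13 - b12 - b23,
           b13 - b12 - b23, -2 * b23), 2, 2)
}

archetype_constants <- function(name) {
  responses <- c("log_vp", "pct_full", "viability")
  if (name == "egfp_like") {
    scheffe <- list(
      log_vp    = c(10.5, 10.4, 8.8, 0.5, -0.5, -0.5),
      pct_full  = c(30, 6, 22, 10, 80, 10),
      viability = c(55, 60, 90, 0, 10, 10))
    rsm <- list(
      log_vp    = c(10.2, 0, 0, -0.15, -0.15, -0.8),
      pct_full  = c(30, -8, 8, 0, 0, -2),
      viability = c(85, 1, -1, -2, -2, 0))
  } else if (name == "msh2_like") {
    scheffe <- list(
      log_vp    = c(9, 10.2, 9, 0, 2, 0),
      pct_full  = c(2, 7, 2, 0, 5, 0),
      viability = c(70, 92, 70, 0, 30, 0))
    rsm <- list(
      log_vp    = c(9.8, -0.1, -0.5, 0, 0, 0),
      pct_full  = c(8, 0, -2, 0, 0.5, -0.5),
      viability = c(88, 2, -3, -1, 0, 0))
  } else if (name == "bdnf_like") {
    # Log(Vp) and % full tilt in opposite directions across the simplex;
    # viability is a saddle whose convex axis runs along the Log(Vp) vs
    # % full trade-off, carving a valley between the two operating points.
    u <- c(-0.3, 0.5); u <- u / sqrt(sum(u^2))   # trade-off axis in (s, t)
    w <- c(u[2], -u[1])                           # perpendicular axis
    H <- 150 * tcrossprod(u) - 25 * tcrossprod(w)
    M <- c(0.35, 0.35)                            # saddle location
    A <- 72 + drop(t(M) %*% H %*% M)
    lin <- -2 * drop(H %*% M)
    scheffe <- list(
      log_vp    = quad_to_scheffe(9.6, 1.2, -2, 0, 0, 0),
      pct_full  = quad_to_scheffe(2, 3, 12, 0, 0, 0),
      viability = quad_to_scheffe(A, lin[1], lin[2], H[1, 1], H[2, 2],
                                  2 * H[1, 2]))
    rsm <- list(
      log_vp    = c(9.3, -0.3, -0.4, 0, 0, 0),
      pct_full  = c(6, -1, -2, 0, 0, 0),
      viability = c(85, -1, -2, 0, 0, -0.5))
  } else {
    stop("unknown archetype '", name,
         "'; use one of egfp_like, msh2_like, bdnf_like")
  }
  names(scheffe) <- responses
  names(rsm) <- responses
  list(scheffe = scheffe, rsm = rsm)
}

#' Construct a GOI response-surface archetype
#'
#' Returns the ground-truth response surfaces of one of three gene-of-
#' interest archetypes, each encoding a qualitatively different
#' optimization landscape over the plasmid simplex and the DNA/FV square:
#'
#' * `egfp_like` — Log(Vp) rises with pHelper and pRepCap and falls with
#'   pGOI, while viability moves the opposite way; % full peaks where
#'   neither is maximal.
#' * `msh2_like` — all three responses peak together in the RepCap-
#'   dominated corner, with a combined optimum at 0.2:0.6:0.2.
#' * `bdnf_like` — Log(Vp) and % full gradients oppose each other and
#'   viability forms a saddle, yielding two distinct operating points.
#'
#' The constructor verifies its own qualitative constraints (gradient
#' signs, Hessian indefiniteness, argmax location, response ranges) and
#' fails loudly if any is violated, so downstream tests can rely on the
#' archetype's structure.
#'
#' @param name one of `"egfp_like"`, `"msh2_like"`, `"bdnf_like"`.
#' @param seed optional integer; adds deterministic relative jitter to
#'   the published coefficients (surfaces remain within their verified
#'   qualitative class or construction fails).
#' @param jitter_sd relative jitter standard deviation applied when
#'   `seed` is given.
#' @return An object of class `goi_archetype` with `$scheffe` and `$rsm`
#'   true-surface objects per response and the default `$noise` model.
#' @export
make_archetype <- function(name = c("egfp_like", "msh2_like", "bdnf_like"),
                           seed = NULL, jitter_sd = 0.01) {
  name <- match.arg(name)
  const <- archetype_constants(name)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", .GlobalEnv)) {
      get(".Random.seed", .GlobalEnv)
    }
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(seed)
    jit <- function(b) b * (1 + stats::rnorm(length(b), 0, jitter_sd))
    const$scheffe <- lapply(const$scheffe, jit)
    const$rsm <- lapply(const$rsm, jit)
  }
  arch <- structure(
    list(name = name,
         scheffe = lapply(const$scheffe, scheffe_surface),
         rsm = lapply(const$rsm, rsm_surface),
         scheffe_beta = const$scheffe,
         rsm_beta = const$rsm,
         noise = noise_model(),
         seed = seed),
    class = "goi_archetype")
  verify_archetype(arch)
  arch
}

#' @export
print.goi_archetype <- function(x, ...) {
  cat("GOI archetype:", x$name, "\n")
  cat("  Scheffe (true) coefficients:\n")
  for (r in names(x$scheffe_beta)) {
    cat(sprintf("    %-9s %s\n", r,
                paste(format(round(x$scheffe_beta[[r]], 3)), collapse = " ")))
  }
  invisible(x)
}

verify_archetype <- function(arch) {
  bounds <- mixture_bounds()
  grid <- region_grid(bounds, 0.02)
  square <- region_grid(coded_square(), 0.05)
  fail <- function(msg) stop("archetype self-check failed (", arch$name, "): ",
                             msg, call. = FALSE)

  # physical ranges over the feasible region
  for (r in c("pct_full", "viability")) {
    pv <- predict(arch$scheffe[[r]], grid)
    if (min(pv) < 0 || max(pv) > 100) fail(paste(r, "outside [0, 100] on the simplex"))
    pz <- predict(arch$rsm[[r]], square)
    if (min(pz) < 0 || max(pz) > 100) fail(paste(r, "outside [0, 100] on the coded square"))
  }

  centroid <- rep(1 / 3, 3)
  u <- c(-0.5, -0.5, 1); u <- u / sqrt(sum(u^2))  # increasing pGOI direction
  dd <- function(resp) {
    sum(scheffe_tangent_gradient(arch$scheffe_beta[[resp]], centroid) * u)
  }

  if (arch$name == "egfp_like") {
    if (dd("log_vp") >= 0) fail("Log(Vp) must fall along increasing pGOI")
    if (dd("viability") <= 0) fail("viability must rise along increasing pGOI")
  } else if (arch$name == "msh2_like") {
    opt <- optimize_desirability(arch$scheffe, region = bounds,
                                 grid_step = 0.02, polish = FALSE)
    if (max(abs(opt$points[1, ] - c(0.2, 0.6, 0.2))) > 0.02 + 1e-9) {
      fail("combined desirability argmax not at 0.2:0.6:0.2")
    }
  } else if (arch$name == "bdnf_like") {
    H <- scheffe_chart_hessian(arch$scheffe_beta$viability)
    ev <- eigen(H, symmetric = TRUE, only.values = TRUE)$values
    if (!(min(ev) < 0 && max(ev) > 0)) fail("viability Hessian is not a saddle")
    g1 <- scheffe_tangent_gradient(arch$scheffe_beta$log_vp, centroid)
    g2 <- scheffe_tangent_gradient(arch$scheffe_beta$pct_full, centroid)
    cossim <- sum(g1 * g2) / sqrt(sum(g1^2) * sum(g2^2))
    if (cossim >= 0) fail("Log(Vp) and % full gradients do not oppose")
    opt <- optimize_desirability(arch$scheffe, region = bounds,
                                 grid_step = 0.02, top = 2, polish = FALSE)
    if (nrow(opt$points) < 2) fail("combined desirability is not bimodal")
    lv <- predict(arch$scheffe$log_vp, opt$points)
    pf <- predict(arch$scheffe$pct_full, opt$points)
    if (sign(lv[1] - lv[2]) == sign(pf[1] - pf[2])) {
      fail("the two optima do not rank oppositely on Log(Vp) vs % full")
    }
  }
  invisible(TRUE)
}

#' Evaluate the archetype's combined true surface
#'
#' The two-stage truth is additive: response(x, z) = Scheffe(x) +
#' (RSM(z) - RSM(0, 0)), so at the FCCD center (total DNA 2 ug/mL, FV 1:1
#' — the conditions of the mixture-design stage) the combined surface
#' reduces to the mixture surface exactly.
#'
#' @param archetype a [make_archetype()] object.
#' @param x matrix of compositions (or single composition).
#' @param z matrix of coded DNA/FV coordinates (default: center).
#' @return Matrix with columns `log_vp`, `pct_full`, `viability`.
#' @export
true_response <- function(archetype, x, z = NULL) {
  x <- if (is.matrix(x)) x else matrix(x, 1)
  if (is.null(z)) z <- matrix(0, nrow(x), 2)
  z <- if (is.matrix(z)) z else matrix(z, 1)
  if (nrow(z) == 1 && nrow(x) > 1) z <- z[rep(1, nrow(x)), , drop = FALSE]
  if (nrow(x) == 1 && nrow(z) > 1) x <- x[rep(1, nrow(z)), , drop = FALSE]
  center <- matrix(0, 1, 2)
  out <- vapply(names(archetype$scheffe), function(r) {
    predict(archetype$scheffe[[r]], x) +
      predict(archetype$rsm[[r]], z) -
      drop(predict(archetype$rsm[[r]], center))
  }, numeric(nrow(x)))
  matrix(out, nrow = nrow(x),
         dimnames = list(NULL, names(archetype$scheffe)))
}

#' Simulate a noisy run table from an archetype
#'
#' Evaluates the archetype's true surfaces at each design run, adds
#' Gaussian measurement noise, clips % full and viability to their
#' physical `[0, 100]` range (clip events are counted in the
#' `"n_clipped"` attribute), and back-computes the raw titers so the
#' derived responses round-trip exactly: vg_titer = 10^log_vp * time and
#' capsid_titer = vg_titer * 100 / % full (with a 1e-3 assay floor on
#' % full keeping the capsid titer finite).
#'
#' @param design a `mixture_design` (runs at the FCCD center conditions)
#'   or an `fccd_design` (runs at a fixed plasmid `ratio`).
#' @param archetype a [make_archetype()] object.
#' @param noise a [noise_model()]; defaults to the archetype's.
#' @param replicates number of replicate measurements per design run.
#' @param ratio plasmid composition at which an FCCD is run (required for
#'   `fccd_design` input).
#' @param time_days harvest time used for the titer back-computation.
#' @param seed optional integer seed; identical seeds give identical
#'   tables.
#' @return A run-table data frame with columns `run_id, pHelper, pRepCap,
#'   pGOI, dna_total, fv_ratio, time_days, vg_titer, capsid_titer,
#'   viability` plus the simulated-truth columns `log_vp` and `pct_full`.
#' @export
simulate_runs <- function(design, archetype, noise = NULL, replicates = 1,
                          ratio = NULL, time_days = 2, seed = NULL) {
  stopifnot(inherits(archetype, "goi_archetype"))
  if (is.null(noise)) noise <- archetype$noise
  stopifnot(inherits(noise, "noise_model"))
  if (replicates < 1) stop("`replicates` must be at least 1")
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", .GlobalEnv)) {
      get(".Random.seed", .GlobalEnv)
    }
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(seed)
  }
  if (inherits(design, "mixture_design")) {
    x <- design$runs
    z <- matrix(0, nrow(x), 2)
    dna <- rep(2, nrow(x))
    fv <- rep(1, nrow(x))
  } else if (inherits(design, "fccd_design")) {
    if (is.null(ratio)) {
      stop("`ratio` (plasmid composition) is required to simulate an FCCD")
    }
    z <- design$coded
    x <- matrix(rep(as.numeric(ratio), each = nrow(z)), nrow(z),
                dimnames = list(NULL, c("pHelper", "pRepCap", "pGOI")))
    dna <- design$actual[, 1]
    fv <- design$actual[, 2]
  } else {
    stop("`design` must be a mixture_design or fccd_design")
  }
  idx <- rep(seq_len(nrow(x)), each = replicates)
  x <- x[idx, , drop = FALSE]
  z <- z[idx, , drop = FALSE]
  truth <- true_response(archetype, x, z)
  n <- nrow(truth)
  lv <- truth[, "log_vp"] + stats::rnorm(n, 0, noise$sigma_log_vp)
  pf <- truth[, "pct_full"] + stats::rnorm(n, 0, noise$sigma_pct_full)
  vb <- truth[, "viability"] + stats::rnorm(n, 0, noise$sigma_viability)
  n_clipped <- sum(pf < 0 | pf > 100) + sum(vb < 0 | vb > 100)
  pf <- pmin(pmax(pf, 0), 100)
  vb <- pmin(pmax(vb, 0), 100)
  vg <- 10^lv * time_days
  capsid <- vg * 100 / pmax(pf, 1e-3)
  out <- data.frame(run_id = seq_len(n),
                    x,
                    dna_total = dna[idx], fv_ratio = fv[idx],
                    time_days = time_days,
                    vg_titer = vg, capsid_titer = capsid,
                    viability = vb,
                    log_vp = lv, pct_full = pf)
  attr(out, "n_clipped") <- n_clipped
  out
}

#' End-to-end recovery of an archetype's optimum
#'
#' Runs the full sequential workflow in silico — D-optimal mixture design,
#' simulated runs, Scheffe fits, desirability optimum, then an FCCD at the
#' recovered plasmid ratio, second-order fits and a DNA/FV optimum — and
#' scores the recovered operating point against the archetype's known
#' truth.
#'
#' @param archetype a [make_archetype()] object.
#' @param noise a [noise_model()] (use zero sigmas for the noiseless
#'   check).
#' @param n_runs mixture-design run count.
#' @param candidate_step candidate-lattice resolution for the D-optimal
#'   search.
#' @param grid_step desirability scan resolution on the simplex.
#' @param n_center FCCD center replicates.
#' @param replicates measurement replicates per design run.
#' @param top number of ranked simplex optima to carry (top-1 is taken
#'   forward to the FCCD stage).
#' @param seed integer seed controlling design search and noise draws.
#' @return A list of class `recovery_report`: recovered and true optima,
#'   Euclidean recovery distances, and the true overall desirability of
#'   stage 1 (MD optimum at center DNA/FV) vs stage 2 (MD + FCCD optimum).
#' @export
end_to_end_recovery <- function(archetype, noise = noise_model(0, 0, 0),
                                n_runs = 13, candidate_step = 0.05,
                                grid_step = 0.02, n_center = 3,
                                replicates = 1, top = 1, seed = 1) {
  bounds <- mixture_bounds()
  cand <- simplex_candidates(bounds, candidate_step)
  md <- d_optimal_select(cand, n_runs = n_runs, seed = seed)
  tbl <- simulate_runs(md, archetype, noise, replicates = replicates,
                       seed = seed + 1)
  runs <- tbl[, c("pHelper", "pRepCap", "pGOI")]
  fits_md <- list(log_vp = fit_scheffe(runs, tbl$log_vp),
                  pct_full = fit_scheffe(runs, tbl$pct_full),
                  viability = fit_scheffe(runs, tbl$viability))
  opt_md <- optimize_desirability(fits_md, region = bounds,
                                  grid_step = grid_step, top = top)
  ratio_hat <- opt_md$points[1, ]

  fccd <- fccd_design(n_center = n_center)
  tbl2 <- simulate_runs(fccd, archetype, noise, replicates = replicates,
                        ratio = ratio_hat, seed = seed + 2)
  fits_rsm <- list(log_vp = fit_rsm(fccd$coded[rep(seq_len(nrow(fccd$coded)),
                                                   each = replicates), ,
                                               drop = FALSE],
                                    tbl2$log_vp),
                   pct_full = fit_rsm(fccd$coded[rep(seq_len(nrow(fccd$coded)),
                                                     each = replicates), ,
                                                 drop = FALSE],
                                      tbl2$pct_full),
                   viability = fit_rsm(fccd$coded[rep(seq_len(nrow(fccd$coded)),
                                                      each = replicates), ,
                                                  drop = FALSE],
                                       tbl2$viability))
  opt_fccd <- optimize_desirability(fits_rsm, region = coded_square(),
                                    grid_step = 0.05)
  z_hat <- opt_fccd$points[1, ]

  # truth: desirability spec fixed from the true combined surface ranges
  sgrid <- region_grid(bounds, grid_step)
  zgrid <- region_grid(coded_square(), 0.05)
  sch_pred <- predict_models(archetype$scheffe, sgrid)
  dev_pred <- predict_models(archetype$rsm, zgrid) -
    matrix(true_rsm_center(archetype), nrow(zgrid), 3, byrow = TRUE)
  spec_true <- desirability_spec(
    colnames(sch_pred),
    L = apply(sch_pred, 2, min) + apply(dev_pred, 2, min),
    T = apply(sch_pred, 2, max) + apply(dev_pred, 2, max))
  true_D <- function(x, z) {
    p <- true_response(archetype, x, z)
    desirability_overall(desirability_matrix(p, spec_true))
  }
  opt_true <- optimize_desirability(archetype$scheffe, region = bounds,
                                    grid_step = grid_step, top = top)
  true_ratio <- opt_true$points[1, ]
  opt_true_z <- optimize_desirability(archetype$rsm, region = coded_square(),
                                      grid_step = 0.05)
  true_z <- opt_true_z$points[1, ]

  structure(list(
    archetype = archetype$name,
    md_design = md,
    md_fits = fits_md,
    md_optima = opt_md,
    ratio_hat = ratio_hat,
    true_ratio = true_ratio,
    z_hat = z_hat,
    true_z = true_z,
    simplex_error = sqrt(sum((ratio_hat - true_ratio)^2)),
    coded_error = sqrt(sum((z_hat - true_z)^2)),
    stage1_true_D = true_D(ratio_hat, c(0, 0)),
    stage2_true_D = true_D(ratio_hat, z_hat),
    fccd_fits = fits_rsm,
    fccd_optimum = opt_fccd,
    grid_step = grid_step,
    seed = seed),
    class = "recovery_report")
}

true_rsm_center <- function(archetype) {
  vapply(archetype$rsm, function(m) {
    drop(predict(m, matrix(0, 1, 2)))
  }, numeric(1))
}

#' @export
print.recovery_report <- function(x, ...) {
  cat("End-to-end recovery:", x$archetype, "\n")
  cat(sprintf("  recovered ratio  %s (true %s, error %.4f)\n",
              paste(round(x$ratio_hat, 3), collapse = ":"),
              paste(round(x$true_ratio, 3), collapse = ":"),
              x$simplex_error))
  cat(sprintf("  recovered DNA/FV %s (true %s)\n",
              paste(round(x$z_hat, 2), collapse = ","),
              paste(round(x$true_z, 2), collapse = ",")))
  cat(sprintf("  true overall D: stage 1 = %.4f, stage 2 = %.4f\n",
              x$stage1_true_D, x$stage2_true_D))
  invisible(x)
}
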