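test_that("egfp archetype encodes opposing productivity/viability gradients", {
  arch <- make_archetype("egfp_like")
  centroid <- rbind(rep(1 / 3, 3))
  h <- 1e-5
  u <- c(-0.5, -0.5, 1); u <- u / sqrt(sum(u^2))  # toward more pGOI
  dd <- function(surf) {
    (predict(surf, centroid + h * matrix(u, 1)) -
       predict(surf, centroid - h * matrix(u, 1))) / (2 * h)
  }
  expect_lt(dd(arch$scheffe$log_vp), 0)     # productivity favors less pGOI
  expect_gt(dd(arch$scheffe$viability), 0)  # viability favors more pGOI
})

test_that("msh2 archetype puts the combined optimum at 0.2:0.6:0.2", {
  arch <- make_archetype("msh2_like")
  opt <- optimize_desirability(arch$scheffe, region = mixture_bounds(),
                               grid_step = 0.02, polish = FALSE)
  expect_lte(max(abs(opt$points[1, ] - c(0.2, 0.6, 0.2))), 0.02)
})

test_that("bdnf archetype has a viability saddle and conflicting objectives", {
  arch <- make_archetype("bdnf_like")
  # indefinite Hessian of viability in the simplex chart, by finite differences
  surf <- arch$scheffe$viability
  f <- function(s, t) {
    drop(predict(surf, matrix(c(s, 1 - s - t, t), 1)))
  }
  h <- 1e-4; s0 <- 0.35; t0 <- 0.35
  H <- matrix(c(
    (f(s0 + h, t0) - 2 * f(s0, t0) + f(s0 - h, t0)) / h^2,
    (f(s0 + h, t0 + h) - f(s0 + h, t0 - h) -
       f(s0 - h, t0 + h) + f(s0 - h, t0 - h)) / (4 * h^2),
    (f(s0 + h, t0 + h) - f(s0 + h, t0 - h) -
       f(s0 - h, t0 + h) + f(s0 - h, t0 - h)) / (4 * h^2),
    (f(s0, t0 + h) - 2 * f(s0, t0) + f(s0, t0 - h)) / h^2), 2, 2)
  ev <- eigen(H, symmetric = TRUE, only.values = TRUE)$values
  expect_lt(min(ev), 0)
  expect_gt(max(ev), 0)
  # top-2 optima differ and rank oppositely on Log(Vp) vs % full truth
  opt <- optimize_desirability(arch$scheffe, region = mixture_bounds(),
                               grid_step = 0.02, top = 2, polish = FALSE)
  expect_equal(nrow(opt$points), 2)
  lv <- predict(arch$scheffe$log_vp, opt$points)
  pf <- predict(arch$scheffe$pct_full, opt$points)
  expect_true(sign(lv[1] - lv[2]) != sign(pf[1] - pf[2]))
})

test_that("archetype construction is validated and deterministic", {
  expect_error(make_archetype("gfp"), "arg")
  a1 <- make_archetype("egfp_like", seed = 9)
  a2 <- make_archetype("egfp_like", seed = 9)
  expect_identical(a1$scheffe_beta, a2$scheffe_beta)
  a3 <- make_archetype("egfp_like", seed = 10)
  expect_false(identical(a1$scheffe_beta, a3$scheffe_beta))
  # surfaces stay physical over the feasible region
  g <- region_grid(mixture_bounds(), 0.02)
  for (nm in c("egfp_like", "msh2_like", "bdnf_like")) {
    arch <- make_archetype(nm)
    for (r in c("pct_full", "viability")) {
      p <- predict(arch$scheffe[[r]], g)
      expect_true(all(p >= 0 & p <= 100))
    }
  }
})

test_that("zero-noise simulation reproduces the true surfaces exactly", {
  arch <- make_archetype("msh2_like")
  cs <- simplex_candidates(mixture_bounds(), 0.1)
  md <- d_optimal_select(cs, n_runs = 8, seed = 2)
  tbl <- simulate_runs(md, arch, noise_model(0, 0, 0), seed = 1)
  truth <- true_response(arch, md$runs)
  expect_equal(tbl$log_vp, unname(truth[, "log_vp"]), tolerance = 1e-10)
  expect_equal(tbl$pct_full, unname(truth[, "pct_full"]), tolerance = 1e-10)
  expect_equal(tbl$viability, unname(truth[, "viability"]), tolerance = 1e-10)
  # derived responses round-trip through the raw titers
  expect_equal(log_vp(tbl$vg_titer, tbl$time_days), tbl$log_vp,
               tolerance = 1e-12)
  expect_equal(as.numeric(pct_full(tbl$vg_titer, tbl$capsid_titer)),
               tbl$pct_full, tolerance = 1e-12)
})

test_that("simulation is seed-deterministic and validates noise", {
  arch <- make_archetype("egfp_like")
  cs <- simplex_candidates(mixture_bounds(), 0.1)
  md <- d_optimal_select(cs, n_runs = 8, seed = 2)
  t1 <- simulate_runs(md, arch, seed = 33)
  t2 <- simulate_runs(md, arch, seed = 33)
  expect_identical(t1, t2)
  t3 <- simulate_runs(md, arch, seed = 34)
  expect_false(identical(t1$vg_titer, t3$vg_titer))
  expect_error(noise_model(-0.1, 2, 2), "non-negative")
})

test_that("replicate means concentrate on the truth (CLT bound)", {
  arch <- make_archetype("egfp_like")
  one_pt <- as_mixture_design(rbind(c(0.4, 0.25, 0.35)))
  tbl <- simulate_runs(one_pt, arch, noise_model(0.1, 0, 0),
                       replicates = 1000, seed = 5)
  truth <- true_response(arch, c(0.4, 0.25, 0.35))
  expect_lt(abs(mean(tbl$log_vp) - truth[, "log_vp"]), 3 * 0.1 / sqrt(1000))
})

test_that("noisy % full is clipped to its physical range and counted", {
  arch <- make_archetype("msh2_like")   # low % full surface near the clip
  one_pt <- as_mixture_design(rbind(c(0.6, 0.1, 0.3)))
  tbl <- simulate_runs(one_pt, arch, noise_model(0, 25, 0),
                       replicates = 400, seed = 8)
  expect_true(all(tbl$pct_full >= 0 & tbl$pct_full <= 100))
  expect_gt(attr(tbl, "n_clipped"), 0)
})

test_that("zero-noise end-to-end recovery pinpoints the true optimum", {
  for (nm in c("egfp_like", "msh2_like", "bdnf_like")) {
    rec <- end_to_end_recovery(make_archetype(nm), noise_model(0, 0, 0),
                               seed = 1)
    expect_lte(rec$simplex_error, sqrt(3) * rec$grid_step)
    expect_gte(rec$stage2_true_D, rec$stage1_true_D - 1e-9)
  }
})

test_that("recovery error shrinks as measurement noise vanishes", {
  arch <- make_archetype("egfp_like")
  bounds <- mixture_bounds()
  cs <- simplex_candidates(bounds, 0.05)
  md <- d_optimal_select(cs, n_runs = 13, seed = 3)
  true_opt <- optimize_desirability(arch$scheffe, region = bounds,
                                    grid_step = 0.02, polish = FALSE)$points[1, ]
  set.seed(99)
  med <- vapply(c(0.2, 0.1, 0.05, 0), function(s) {
    errs <- vapply(1:100, function(i) {
      tbl <- simulate_runs(md, arch, noise_model(s, 20 * s, 20 * s))
      runs <- tbl[, c("pHelper", "pRepCap", "pGOI")]
      fits <- lapply(c(log_vp = "log_vp", pct_full = "pct_full",
                       viability = "viability"),
                     function(r) fit_scheffe(runs, tbl[[r]]))
      opt <- optimize_desirability(fits, region = bounds, grid_step = 0.02,
                                   polish = FALSE)
      sqrt(sum((opt$points[1, ] - true_opt)^2))
    }, numeric(1))
    median(errs)
  }, numeric(1))
  expect_true(all(diff(med) <= 1e-9))  # median distance nonincreasing
  expect_equal(med[4], 0, tolerance = 1e-9)
})
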