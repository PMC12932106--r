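test_that("Log(Vp) is the log10 daily volumetric productivity", {
  expect_equal(log_vp(1e10, 1), 10)
  expect_equal(log_vp(2e9, 2), 9)
  expect_equal(log_vp(5e11, 2), log10(2.5e11))  # 11.39794
  expect_error(log_vp(0, 1), "positive")
  expect_error(log_vp(1e10, 0), "positive")
  # doubling the titer adds log10(2)
  expect_equal(log_vp(2e10, 3) - log_vp(1e10, 3), log10(2))
})

test_that("% full is the genome-to-capsid titer ratio with inconsistency flag", {
  expect_equal(as.numeric(pct_full(5e10, 1e11)), 50)
  expect_equal(as.numeric(pct_full(0, 1e11)), 0)
  expect_warning(p <- pct_full(1.2e11, 1e11), "inconsistency")
  expect_equal(as.numeric(p), 120)
  expect_true(attr(p, "inconsistent"))
  expect_error(pct_full(1e10, 0), "positive")
  # scale consistency: doubling both titers leaves % full unchanged
  expect_equal(as.numeric(pct_full(6e10, 2e11)),
               as.numeric(pct_full(3e10, 1e11)))
})

test_that("mass-to-copy conversion follows the dsDNA molar mass", {
  expect_equal(mass_to_copies(0, 5000), 0)
  expect_equal(mass_to_copies(1, 1000), 1e-6 * 6.02214076e23 / (650 * 1000))
  expect_equal(mass_to_copies(2, 19306), 2e-6 * 6.02214076e23 / (650 * 19306))
  # single-stranded convention halves the molar mass per position
  expect_equal(mass_to_copies(1, 1000, strands = "single"),
               1e-6 * 6.02214076e23 / (330 * 1000))
  expect_error(mass_to_copies(1, 0), "positive")
})

test_that("noiseless Scheffe surfaces are recovered exactly", {
  cs <- simplex_candidates(mixture_bounds(), 0.1)
  design <- d_optimal_select(cs, n_runs = 10, seed = 4)
  set.seed(101)
  for (i in 1:20) {
    beta <- runif(6, -5, 5)
    y <- eval_scheffe_manual(beta, design$runs)
    fit <- fit_scheffe(design, y)
    expect_equal(unname(fit$beta), beta, tolerance = 1e-8)
    expect_equal(unname(predict(fit, design$runs)), y, tolerance = 1e-8)
  }
})

test_that("pure-blend prediction equals the linear coefficient", {
  cs <- simplex_candidates(mixture_bounds(), 0.1)
  design <- d_optimal_select(cs, n_runs = 10, seed = 4)
  beta <- c(3, -1, 2, 0.5, -0.25, 4)
  fit <- fit_scheffe(design, eval_scheffe_manual(beta, design$runs))
  expect_equal(unname(predict(fit, rbind(c(1, 0, 0)))), beta[1],
               tolerance = 1e-8)
  expect_equal(unname(predict(fit, rbind(c(0, 0, 1)))), beta[3],
               tolerance = 1e-8)
  # blending-only surface at the binary midpoint: beta_12 / 4
  fit2 <- fit_scheffe(design, eval_scheffe_manual(c(0, 0, 0, 4, 0, 0),
                                                  design$runs))
  expect_equal(unname(predict(fit2, rbind(c(0.5, 0.5, 0)))), 1,
               tolerance = 1e-8)
})

test_that("under-determined or invalid mixture fits are rejected", {
  runs <- simplex_candidates(mixture_bounds(), 0.1)$points[1:5, ]
  expect_error(fit_scheffe(runs, rnorm(5)), "cannot identify")
  expect_error(fit_scheffe(matrix(c(0.5, 0.4, 0.3), 1, 3), 1), "sum to 1")
  # collinear design: all runs on the pGOI = 0.2 line lose a degree
  bad <- cbind(seq(0.1, 0.6, length.out = 8))
  bad <- cbind(bad, 0.8 - bad, 0.2)
  expect_error(fit_scheffe(bad, rnorm(8)), "rank deficient")
})

test_that("noiseless second-order surfaces are recovered exactly", {
  d <- fccd_design(n_center = 1)
  beta <- c(2, 3, -1, 0.5, -0.25, 1)
  y <- eval_rsm_manual(beta, d$coded)
  fit <- fit_rsm(d, y)
  expect_equal(unname(fit$beta), beta, tolerance = 1e-8)

  set.seed(202)
  for (i in 1:20) {
    b <- runif(6, -3, 3)
    fit_i <- fit_rsm(d, eval_rsm_manual(b, d$coded))
    expect_equal(unname(fit_i$beta), b, tolerance = 1e-8)
  }
})

test_that("constant response collapses to the intercept", {
  d <- fccd_design(n_center = 3)
  fit <- fit_rsm(d, rep(7.5, nrow(d$coded)))
  expect_equal(fit$beta0, 7.5, tolerance = 1e-10)
  expect_true(all(abs(fit$beta[-1]) < 1e-10))
})

test_that("saturated fits are flagged with undefined significance", {
  pts <- rbind(c(-1, -1), c(1, -1), c(-1, 1), c(1, 1), c(1, 0), c(0, 1))
  beta <- c(1, 2, 3, -1, 0.5, 0.25)
  fit <- fit_rsm(pts, eval_rsm_manual(beta, pts))
  expect_equal(unname(fit$beta), beta, tolerance = 1e-8)
  a <- anova_model(fit)
  expect_equal(a$df_residual, 0)
  expect_true(a$undefined)
  expect_true(is.na(a$p_value))
})

test_that("whole-model ANOVA partitions the corrected total sum of squares", {
  cs <- simplex_candidates(mixture_bounds(), 0.1)
  design <- d_optimal_select(cs, n_runs = 13, seed = 6)
  set.seed(303)
  for (i in 1:10) {
    y <- rnorm(13)
    a <- anova_model(fit_scheffe(design, y))
    expect_equal(a$ss_model + a$ss_residual, a$ss_total,
                 tolerance = 1e-8 * max(1, a$ss_total))
    expect_equal(a$df_model + a$df_residual, 13 - 1)
  }
})

test_that("a strong noiseless signal on a replicated design is significant", {
  d <- fccd_design(n_center = 3)
  y <- eval_rsm_manual(c(5, 2, -3, 1, 1, 0.5), d$coded)
  a <- anova_model(fit_rsm(d, y))
  expect_lt(a$p_value, 1e-10)
  expect_true(a$significant)
})

test_that("prediction agrees with term-by-term evaluation on random points", {
  cs <- simplex_candidates(mixture_bounds(), 0.1)
  design <- d_optimal_select(cs, n_runs = 10, seed = 4)
  beta_s <- c(9, 10, 8, 1, -2, 0.5)
  fit_s <- fit_scheffe(design, eval_scheffe_manual(beta_s, design$runs))
  d <- fccd_design(n_center = 1)
  beta_r <- c(10, 0.5, -0.5, -0.2, -0.1, 0.3)
  fit_r <- fit_rsm(d, eval_rsm_manual(beta_r, d$coded))

  set.seed(404)
  w <- matrix(rexp(300), ncol = 3)
  xs <- w / rowSums(w)
  expect_equal(unname(predict(fit_s, xs)),
               unname(eval_scheffe_manual(beta_s, xs)), tolerance = 1e-10)
  zs <- matrix(runif(200, -1, 1), ncol = 2)
  expect_equal(unname(predict(fit_r, zs)),
               unname(eval_rsm_manual(beta_r, zs)), tolerance = 1e-10)
  expect_error(predict(fit_s, matrix(c(0.5, 0.2, 0.2), 1)), "sum to 1")
})

test_that("coefficient intervals have t-based width", {
  cs <- simplex_candidates(mixture_bounds(), 0.1)
  design <- d_optimal_select(cs, n_runs = 13, seed = 6)
  set.seed(55)
  y <- eval_scheffe_manual(c(9, 10, 8, 0, 0, 0), design$runs) + rnorm(13, 0, 0.3)
  fit <- fit_scheffe(design, y)
  ci <- confint_model(fit, 0.95)
  expect_true(all(ci[, "upper"] > ci[, "lower"]))
  # interval centers are the point estimates
  expect_equal(unname((ci[, 1] + ci[, 2]) / 2), unname(fit$beta))
})
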