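#' Log volumetric productivity
#'
#' The volumetric productivity Vp is the genome titer produced per mL and
#' per day of culture; all modelling is done on the log10 scale:
#' Log(Vp) = log10(titer / time).
#'
#' @param titer genome titer in vg/mL (> 0).
#' @param time harvest time in days (> 0).
#' @return log10 volumetric productivity in log10(vg mL^-1 day^-1).
#' @examples
#' log_vp(1e10, 1)   # 10
#' log_vp(2e9, 2)    # 9
#' @export
log_vp <- function(titer, time) {
  if (any(!is.finite(titer)) || any(!is.finite(time)) ||
      any(titer <= 0) || any(time <= 0)) {
    stop("`titer` and `time` must be positive and finite")
  }
  log10(titer / time)
}

#' Percentage of full capsids
#'
#' The full-capsid percentage compares the genome titer (qPCR, counts
#' packaged genomes) with the total capsid titer (ELISA, counts assembled
#' capsids whether full or empty): % full = 100 * genome / capsid. Values
#' above 100% are physically impossible and indicate inconsistent titer
#' measurements; they are returned as-is but flagged via the
#' `"inconsistent"` attribute.
#'
#' @param genome_titer qPCR genome titer in vg/mL (>= 0).
#' @param capsid_titer ELISA capsid titer in capsids/mL (> 0).
#' @return Percent full in `[0, Inf)` with a logical `"inconsistent"`
#'   attribute marking entries above 100%.
#' @examples
#' pct_full(5e10, 1e11)   # 50
#' @export
pct_full <- function(genome_titer, capsid_titer) {
  if (any(!is.finite(capsid_titer)) || any(capsid_titer <= 0)) {
    stop("`capsid_titer` must be positive and finite")
  }
  if (any(!is.finite(genome_titer)) || any(genome_titer < 0)) {
    stop("`genome_titer` must be non-negative and finite")
  }
  out <- 100 * genome_titer / capsid_titer
  flag <- out > 100
  if (any(flag)) {
    warning(sum(flag), " run(s) have % full above 100%: ",
            "genome titer exceeds capsid titer (measurement inconsistency)")
  }
  attr(out, "inconsistent") <- flag
  out
}

#' Convert a plasmid mass concentration to copy number
#'
#' Copies/mL = mass (g/mL) * N_A / (length * molar mass per base pair),
#' using 650 g/mol/bp for double-stranded DNA (plasmids are dosed as
#' dsDNA) or 330 g/mol/nt for single strands.
#'
#' @param mass_conc mass concentration in micrograms per mL (>= 0).
#' @param length_bp construct length in base pairs (> 0).
#' @param strands `"double"` (default) or `"single"`.
#' @return copies per mL.
#' @examples
#' mass_to_copies(1, 1000)   # ~9.27e11 copies/mL
#' @export
mass_to_copies <- function(mass_conc, length_bp, strands = c("double", "single")) {
  strands <- match.arg(strands)
  if (any(mass_conc < 0)) stop("`mass_conc` must be non-negative")
  if (any(length_bp <= 0)) stop("`length_bp` must be positive")
  mm <- if (strands == "double") 650 else 330
  mass_conc * 1e-6 * 6.02214076e23 / (length_bp * mm)
}

rsm_matrix <- function(z, factors = NULL) {
  z <- as.matrix(z)
  if (is.null(factors)) {
    factors <- colnames(z)
    if (is.null(factors)) factors <- paste0("x", seq_len(ncol(z)))
  }
  n <- ncol(z)
  colnames(z) <- factors
  quad <- z^2
  colnames(quad) <- paste0(factors, "^2")
  pairs <- utils::combn(n, 2)
  inter <- z[, pairs[1, ], drop = FALSE] * z[, pairs[2, ], drop = FALSE]
  colnames(inter) <- paste(factors[pairs[1, ]], factors[pairs[2, ]], sep = ":")
  cbind(`(Intercept)` = 1, z, quad, inter)
}

fit_ls <- function(X, y, label) {
  n <- nrow(X)
  p <- ncol(X)
  if (length(y) != n) stop("length of `y` must equal the number of runs")
  if (n < p) {
    stop(sprintf("%d runs cannot identify the %d %s terms", n, p, label))
  }
  qrX <- qr(X)
  if (qrX$rank < p) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1):p]]
    stop("model matrix is rank deficient; collinear terms: ",
         paste(dropped, collapse = ", "))
  }
  beta <- qr.coef(qrX, y)
  fitted <- drop(X %*% beta)
  resid <- y - fitted
  df_res <- n - p
  sigma2 <- if (df_res > 0) sum(resid^2) / df_res else NA_real_
  XtX_inv <- chol2inv(chol(crossprod(X)))
  dimnames(XtX_inv) <- list(colnames(X), colnames(X))
  list(beta = beta, fitted = fitted, residuals = resid, df_residual = df_res,
       sigma2 = sigma2, XtX_inv = XtX_inv, y = y, X = X)
}

#' Fit the Scheffe quadratic mixture model
#'
#' Fits the intercept-free quadratic blending model
#' y = sum_i beta_i x_i + sum_{i<j} beta_ij x_i x_j by least squares.
#' Because the compositions sum to one there is no separate intercept:
#' beta_i is the expected response of the pure blend x_i = 1, and beta_ij
#' captures synergistic (positive) or antagonistic (negative) blending of
#' components i and j.
#'
#' @param design a `mixture_design`, or a matrix/data frame of
#'   compositions whose rows sum to 1.
#' @param y numeric response vector, one value per run.
#' @return An object of class `scheffe_model` with `beta_linear`,
#'   `beta_blend`, `residual_variance` and the least-squares internals.
#' @export
fit_scheffe <- function(design, y) {
  runs <- if (inherits(design, "mixture_design")) design$runs else as.matrix(design)
  if (any(abs(rowSums(runs) - 1) > 1e-6)) {
    stop("mixture design rows must sum to 1")
  }
  X <- scheffe_matrix(runs)
  k <- ncol(runs)
  fit <- fit_ls(X, y, "Scheffe")
  structure(c(fit,
              list(beta_linear = fit$beta[seq_len(k)],
                   beta_blend = fit$beta[(k + 1):ncol(X)],
                   residual_variance = fit$sigma2,
                   term_labels = colnames(X),
                   components = colnames(runs),
                   k = k)),
            class = "scheffe_model")
}

#' Fit the second-order response-surface model
#'
#' Fits y = beta0 + sum beta_i x_i + sum beta_ii x_i^2 +
#' sum_{i<j} beta_ij x_i x_j on the coded factor scale of an FCCD. With
#' two factors the model has 6 coefficients, so at least one center
#' replicate is needed for any residual degrees of freedom.
#'
#' @param design an `fccd_design`, or a matrix of coded coordinates.
#' @param y numeric response vector, one value per run.
#' @return An object of class `rsm_model`.
#' @export
fit_rsm <- function(design, y) {
  coded <- if (inherits(design, "fccd_design")) design$coded else as.matrix(design)
  X <- rsm_matrix(coded)
  n_fac <- ncol(coded)
  fit <- fit_ls(X, y, "second-order")
  nm <- colnames(X)
  structure(c(fit,
              list(beta0 = unname(fit$beta[1]),
                   beta_linear = fit$beta[2:(1 + n_fac)],
                   beta_quad = fit$beta[(2 + n_fac):(1 + 2 * n_fac)],
                   beta_interact = fit$beta[(2 + 2 * n_fac):ncol(X)],
                   residual_variance = fit$sigma2,
                   term_labels = nm,
                   factors = colnames(coded),
                   n_factors = n_fac)),
            class = "rsm_model")
}

#' @export
print.scheffe_model <- function(x, ...) {
  cat("Scheffe quadratic mixture model (", x$k, "components )\n")
  print(round(x$beta, 4))
  invisible(x)
}

#' @export
print.rsm_model <- function(x, ...) {
  cat("Second-order response-surface model (", x$n_factors, "coded factors )\n")
  print(round(x$beta, 4))
  invisible(x)
}

#' Predict from a Scheffe mixture model
#'
#' @param object a `scheffe_model`.
#' @param newdata matrix or data frame of compositions (rows sum to 1).
#' @param ... unused.
#' @export
predict.scheffe_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != object$k) {
    stop("`newdata` must have one column per mixture component")
  }
  if (any(abs(rowSums(newdata) - 1) > 1e-6)) {
    stop("compositions in `newdata` must sum to 1")
  }
  drop(scheffe_matrix(newdata, object$components) %*% object$beta)
}

#' Predict from a second-order response-surface model
#'
#' @param object an `rsm_model`.
#' @param newdata matrix or data frame of coded coordinates.
#' @param ... unused.
#' @export
predict.rsm_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != object$n_factors) {
    stop("`newdata` must have one column per coded factor")
  }
  drop(rsm_matrix(newdata, object$factors) %*% object$beta)
}

#' Whole-model ANOVA for a fitted design model
#'
#' Partitions the mean-corrected total sum of squares into model and
#' residual components and tests the whole model with an F statistic.
#' For the intercept-free Scheffe model the constant lies in the span of
#' the linear blending terms (the compositions sum to one), so the
#' mean-corrected partition with df_model = p - 1 applies to both model
#' families. With zero residual degrees of freedom (saturated fit) the
#' table is returned with the p-value marked undefined.
#'
#' @param model a `scheffe_model` or `rsm_model`.
#' @param alpha significance level used for the `significant` flag.
#' @return An object of class `doe_anova` with degrees of freedom, sums
#'   of squares, the F statistic and its p-value.
#' @export
anova_model <- function(model, alpha = 0.05) {
  stopifnot(inherits(model, "scheffe_model") || inherits(model, "rsm_model"))
  y <- model$y
  n <- length(y)
  p <- ncol(model$X)
  ss_res <- sum(model$residuals^2)
  ss_tot <- sum((y - mean(y))^2)
  ss_model <- ss_tot - ss_res
  df_model <- p - 1
  df_res <- n - p
  if (df_res > 0) {
    f_stat <- (ss_model / df_model) / (ss_res / df_res)
    p_value <- stats::pf(f_stat, df_model, df_res, lower.tail = FALSE)
    undefined <- FALSE
  } else {
    f_stat <- NA_real_
    p_value <- NA_real_
    undefined <- TRUE
  }
  structure(list(df_model = df_model, df_residual = df_res,
                 ss_model = ss_model, ss_residual = ss_res,
                 ss_total = ss_tot,
                 f_statistic = f_stat, p_value = p_value,
                 undefined = undefined,
                 significant = isTRUE(p_value < alpha), alpha = alpha),
            class = "doe_anova")
}

#' @export
print.doe_anova <- function(x, ...) {
  cat("Whole-model ANOVA\n")
  cat(sprintf("  model:    df = %d, SS = %.4g\n", x$df_model, x$ss_model))
  cat(sprintf("  residual: df = %d, SS = %.4g\n", x$df_residual, x$ss_residual))
  if (x$undefined) {
    cat("  saturated model: F and p undefined (zero residual df)\n")
  } else {
    cat(sprintf("  F = %.4g, p = %.4g%s\n", x$f_statistic, x$p_value,
                if (x$significant) " (significant)" else ""))
  }
  invisible(x)
}

#' Coefficient confidence intervals for a fitted design model
#'
#' t-based intervals beta_hat +/- t_{1-a/2, df} * se from the
#' least-squares covariance sigma^2 (X'X)^-1.
#'
#' @param object a `scheffe_model` or `rsm_model`.
#' @param level confidence level.
#' @param ... unused.
#' @return Matrix with `lower` and `upper` columns, one row per term.
#' @export
confint_model <- function(object, level = 0.95, ...) {
  if (object$df_residual < 1) {
    stop("confidence intervals need at least one residual degree of freedom")
  }
  se <- sqrt(object$sigma2 * diag(object$XtX_inv))
  tq <- stats::qt(1 - (1 - level) / 2, object$df_residual)
  out <- cbind(lower = object$beta - tq * se, upper = object$beta + tq * se)
  rownames(out) <- names(object$beta)
  out
}
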