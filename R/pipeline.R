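run_table_columns <- c("run_id", "pHelper", "pRepCap", "pGOI", "dna_total",
                       "fv_ratio", "time_days", "vg_titer", "capsid_titer",
                       "viability")

#' Read a run table CSV
#'
#' Loads per-run measurements (plasmid fractions, total DNA, FV ratio,
#' harvest time, qPCR genome titer, ELISA capsid titer, viability),
#' validates the schema, and computes the derived responses Log(Vp) and
#' % full on load. Unknown extra columns are preserved untouched.
#'
#' @param path CSV file with the documented schema.
#' @return A validated run-table data frame with derived `log_vp` and
#'   `pct_full` columns appended (input row order preserved).
#' @export
read_run_table <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  missing_cols <- setdiff(run_table_columns, names(df))
  if (length(missing_cols) > 0) {
    stop("run table is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  for (col in setdiff(run_table_columns, "run_id")) {
    v <- df[[col]]
    if (!is.numeric(v)) {
      suppressWarnings(vn <- as.numeric(v))
      bad <- which(is.na(vn) & !is.na(v))
      if (length(bad) > 0) {
        stop(sprintf("non-numeric value in column '%s', row %d: '%s'",
                     col, bad[1], v[bad[1]]))
      }
      df[[col]] <- vn
    }
  }
  comp_sum <- df$pHelper + df$pRepCap + df$pGOI
  if (any(abs(comp_sum - 1) > 1e-6)) {
    bad <- which(abs(comp_sum - 1) > 1e-6)[1]
    stop(sprintf("plasmid fractions in row %d sum to %.8f, not 1", bad,
                 comp_sum[bad]))
  }
  df$log_vp <- log_vp(df$vg_titer, df$time_days)
  df$pct_full <- as.numeric(pct_full(df$vg_titer, df$capsid_titer))
  df
}

#' Write a run table CSV
#'
#' @param table run-table data frame.
#' @param path output path.
#' @export
write_run_table <- function(table, path) {
  drop_cols <- intersect(c("log_vp", "pct_full"), names(table))
  utils::write.csv(table[, setdiff(names(table), drop_cols), drop = FALSE],
                   path, row.names = FALSE)
  invisible(path)
}

#' Configuration for the two-stage optimization pipeline
#'
#' Collects every tunable of the MD -> FCCD workflow with its default.
#' The defaults are the study conditions: 10--60% per-plasmid bounds, a
#' 13-run D-optimal mixture design on a 0.05 candidate lattice around a
#' total DNA of 2 ug/mL and FV ratio 1:1, an 11-run FCCD (3 centers)
#' spanning DNA 1--3 ug/mL and FV 0.5--2, auto-scaled linear
#' desirabilities, and the per-run-maximum harvest rule.
#'
#' @param archetype archetype name for simulation mode, or `NULL` when
#'   `run_table` is supplied.
#' @param run_table optional path to a measured run-table CSV (used
#'   instead of simulation for the MD stage).
#' @param bounds [mixture_bounds()] for the plasmid simplex.
#' @param n_runs mixture-design run count.
#' @param candidate_step candidate-lattice resolution.
#' @param dna_range,fv_range actual FCCD factor limits.
#' @param n_center FCCD center replicates.
#' @param noise [noise_model()] for simulation mode.
#' @param spec optional fixed [desirability_spec()]; `NULL` auto-scales.
#' @param simplex_grid_step,square_grid_step desirability scan steps.
#' @param harvest_rule how to collapse multiple harvests of one run:
#'   `"max_log_vp"` keeps the harvest with the highest Log(Vp) (with its
#'   paired % full and viability), `"all"` keeps every row.
#' @param top_m number of ranked simplex optima to report.
#' @param seed integer master seed.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(archetype = "egfp_like", run_table = NULL,
                            bounds = mixture_bounds(), n_runs = 13,
                            candidate_step = 0.05, dna_range = c(1, 3),
                            fv_range = c(0.5, 2), n_center = 3,
                            noise = noise_model(), spec = NULL,
                            simplex_grid_step = 0.02,
                            square_grid_step = 0.05,
                            harvest_rule = c("max_log_vp", "all"),
                            top_m = 1, seed = 1) {
  harvest_rule <- match.arg(harvest_rule)
  if (top_m < 1) stop("`top_m` must be at least 1")
  if (!is.null(run_table) && !file.exists(run_table)) {
    stop("run table file does not exist: ", run_table)
  }
  structure(list(archetype = archetype, run_table = run_table,
                 bounds = bounds, n_runs = n_runs,
                 candidate_step = candidate_step, dna_range = dna_range,
                 fv_range = fv_range, n_center = n_center, noise = noise,
                 spec = spec, simplex_grid_step = simplex_grid_step,
                 square_grid_step = square_grid_step,
                 harvest_rule = harvest_rule, top_m = top_m,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Keys mirror the arguments of [pipeline_config()]; bounds are given as
#' `bounds: {lower: [...], upper: [...]}` and noise as
#' `noise: {sigma_log_vp: ..., sigma_pct_full: ..., sigma_viability: ...}`.
#'
#' @param path YAML configuration file.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$bounds)) {
    raw$bounds <- mixture_bounds(raw$bounds$lower, raw$bounds$upper)
  }
  if (!is.null(raw$noise)) raw$noise <- do.call(noise_model, raw$noise)
  do.call(pipeline_config, raw)
}

select_harvest <- function(tbl, rule) {
  if (rule == "all" || !anyDuplicated(tbl$run_id)) return(tbl)
  keep <- unlist(lapply(split(seq_len(nrow(tbl)), tbl$run_id), function(i) {
    i[which.max(tbl$log_vp[i])]
  }))
  tbl[sort(keep), , drop = FALSE]
}

design_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(paste(format(x, digits = 15), collapse = ","), f)
  unname(tools::md5sum(f))
}

#' Run the sequential MD -> FCCD optimization pipeline
#'
#' Executes the full workflow: D-optimal mixture design, run acquisition
#' (simulated from an archetype, or a measured run table), Scheffe fits
#' with whole-model ANOVA, desirability optimum over the plasmid simplex,
#' then an FCCD at the recovered ratio, second-order fits, and a
#' desirability optimum over the coded DNA/FV square. The report also
#' evaluates the pre-optimization reference condition (plasmid ratio
#' 1:1:1, DNA:FV 1:1 at the 2 ug/mL center) through the same fitted
#' models, so fold improvements are model-consistent.
#'
#' @param config a [pipeline_config()].
#' @return An object of class `pipeline_report`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }
  log <- list()

  md <- stage("design-md", {
    cand <- simplex_candidates(config$bounds, config$candidate_step)
    d_optimal_select(cand, n_runs = config$n_runs, seed = config$seed)
  })
  log$md <- list(seed = config$seed, hash = design_hash(md$runs),
                 criterion = md$criterion_value)

  arch <- if (is.null(config$run_table)) {
    stage("archetype", make_archetype(config$archetype))
  }
  tbl <- stage("acquire-md-runs", {
    if (!is.null(config$run_table)) {
      read_run_table(config$run_table)
    } else {
      simulate_runs(md, arch, config$noise, seed = config$seed + 1)
    }
  })
  tbl <- select_harvest(tbl, config$harvest_rule)

  fits_md <- stage("fit-scheffe", {
    runs <- tbl[, c("pHelper", "pRepCap", "pGOI")]
    lapply(stats::setNames(c("log_vp", "pct_full", "viability"),
                           c("log_vp", "pct_full", "viability")),
           function(r) fit_scheffe(runs, tbl[[r]]))
  })
  anova_md <- lapply(fits_md, anova_model)
  log$md$anova_p <- vapply(anova_md, function(a) a$p_value, numeric(1))

  opt_md <- stage("optimize-md", {
    optimize_desirability(fits_md, spec = config$spec, region = config$bounds,
                          grid_step = config$simplex_grid_step,
                          top = config$top_m)
  })
  ratio_hat <- opt_md$points[1, ]   # MD optimum carried forward exactly

  fccd <- stage("design-fccd", {
    fccd_design(n_center = config$n_center, dna_range = config$dna_range,
                fv_range = config$fv_range)
  })
  log$fccd <- list(hash = design_hash(fccd$coded))

  if (is.null(arch)) arch <- stage("archetype", make_archetype(config$archetype))
  tbl2 <- stage("acquire-fccd-runs", {
    simulate_runs(fccd, arch, config$noise, ratio = ratio_hat,
                  seed = config$seed + 2)
  })

  fits_fccd <- stage("fit-rsm", {
    lapply(stats::setNames(c("log_vp", "pct_full", "viability"),
                           c("log_vp", "pct_full", "viability")),
           function(r) fit_rsm(fccd, tbl2[[r]]))
  })
  anova_fccd <- lapply(fits_fccd, anova_model)
  log$fccd$anova_p <- vapply(anova_fccd, function(a) a$p_value, numeric(1))

  opt_fccd <- stage("optimize-fccd", {
    optimize_desirability(fits_fccd, region = coded_square(),
                          grid_step = config$square_grid_step)
  })
  z_hat <- opt_fccd$points[1, ]

  # reference condition: unoptimized 1:1:1 plasmid ratio at DNA:FV center
  ref_ratio <- rep(1 / 3, 3)
  ref <- c(vapply(fits_md, function(m) {
    drop(predict(m, matrix(ref_ratio, 1)))
  }, numeric(1)))
  opt_pred <- vapply(fits_fccd, function(m) {
    drop(predict(m, matrix(z_hat, 1)))
  }, numeric(1))

  structure(list(
    config = config,
    md_design = md,
    md_fits = fits_md,
    fccd_fits = fits_fccd,
    md_anova = anova_md,
    md_optima = opt_md,
    ratio = ratio_hat,
    fccd_design = fccd,
    fccd_anova = anova_fccd,
    fccd_optimum = opt_fccd,
    coded_point = z_hat,
    actual_point = drop(decode_fccd(fccd, matrix(z_hat, 1))),
    reference = list(ratio = ref_ratio, coded = c(dna = 0, fv = 0),
                     predicted = ref),
    optimum_predicted = opt_pred,
    stage_D = c(stage1 = opt_md$D[1], stage2 = opt_fccd$D[1]),
    log = log),
    class = "pipeline_report")
}

#' Fold improvement of the optimized condition over the reference
#'
#' Vp improves multiplicatively on the raw scale, so its fold change is
#' 10^(Log(Vp)_opt - Log(Vp)_ref); % full and viability fold changes are
#' plain ratios. The reference % full being zero makes its fold infinite
#' (flagged).
#'
#' @param report a [run_pipeline()] report.
#' @return Named numeric vector of per-response fold improvements, with
#'   attribute `"infinite"` marking any undefined ratio.
#' @export
fold_improvement <- function(report) {
  ref <- report$reference$predicted
  opt <- report$optimum_predicted
  out <- c(log_vp = unname(10^(opt["log_vp"] - ref["log_vp"])),
           pct_full = unname(opt["pct_full"] / ref["pct_full"]),
           viability = unname(opt["viability"] / ref["viability"]))
  inf_flag <- !is.finite(out)
  if (ref["pct_full"] == 0) inf_flag["pct_full"] <- TRUE
  attr(out, "infinite") <- inf_flag
  out
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("Two-stage rAAV optimization report\n")
  cat(sprintf("  plasmid ratio (pHelper:pRepCap:pGOI): %s\n",
              paste(round(x$ratio, 3), collapse = ":")))
  cat(sprintf("  DNA/FV coded point: (%s), actual DNA %.3g ug/mL, FV %.3g\n",
              paste(round(x$coded_point, 2), collapse = ", "),
              x$actual_point[1], x$actual_point[2]))
  cat(sprintf("  overall D: MD stage %.4f, FCCD stage %.4f\n",
              x$stage_D[1], x$stage_D[2]))
  fi <- fold_improvement(x)
  cat(sprintf("  fold improvement vs 1:1:1 reference: Vp %.3g, %%full %.3g\n",
              fi["log_vp"], fi["pct_full"]))
  invisible(x)
}

report_payload <- function(report) {
  list(
    archetype = report$config$archetype,
    seed = report$config$seed,
    md = list(runs = unname(report$md_design$runs),
              criterion = report$md_design$criterion_value,
              anova_p = as.list(report$log$md$anova_p),
              hash = report$log$md$hash),
    ratio = as.list(report$ratio),
    md_D = report$md_optima$D,
    fccd = list(anova_p = as.list(report$log$fccd$anova_p),
                hash = report$log$fccd$hash),
    coded_point = as.list(report$coded_point),
    actual_point = as.list(report$actual_point),
    reference_predicted = as.list(report$reference$predicted),
    optimum_predicted = as.list(report$optimum_predicted),
    stage_D = as.list(report$stage_D),
    fold_improvement = as.list(as.numeric(fold_improvement(report)) |>
                                 stats::setNames(c("log_vp", "pct_full",
                                                   "viability")))
  )
}

#' Export a pipeline report to JSON
#'
#' The exported payload carries the numeric results (designs, optima,
#' ANOVA p-values, fold improvements) at full precision; it round-trips
#' through [report_from_json()].
#'
#' @param report a [run_pipeline()] report.
#' @param path output JSON path.
#' @export
report_to_json <- function(report, path) {
  jsonlite::write_json(report_payload(report), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Import a pipeline report payload from JSON
#'
#' @param path JSON path written by [report_to_json()].
#' @return The report payload list.
#' @export
report_from_json <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
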