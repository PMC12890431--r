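## End-to-end orchestration: simulate -> impute -> correlate -> fit ->
## evaluate -> power, with a reproducibility manifest. All outputs are plain
## CSV/JSON; re-running with the same configuration and seed regenerates
## byte-identical tables.

#' Default pipeline configuration
#'
#' @param n Cohort size (the demo default keeps a full run desk-scale).
#' @param power_reps Monte Carlo repetitions for the power stage.
#' @param power_n_grid Sample-size grid for the power stage.
#' @param m Number of imputations.
#' @param ... Overrides for any element (`cohort` takes a full
#'   [cohort_config()]).
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(n = 4000, power_reps = 200L,
                            power_n_grid = c(250, 500, 1000, 2000),
                            m = 5L, ...) {
  cfg <- list(
    cohort = cohort_config(n = n),
    m = m,
    windows = c("baseline", "concurrent"),
    harm_outcome = "harm_alcohol",
    harm_denominator = 9L,
    power = list(reps = power_reps, n_grid = power_n_grid,
                 base_rates = c(0.033, 0.5),
                 measures = list(cbcl_ext = "cbcl_ext_b")),
    penalty_scale = 2.5
  )
  dots <- list(...)
  for (nm in names(dots)) cfg[[nm]] <- dots[[nm]]
  validate_pipeline_config(cfg)
  class(cfg) <- "pipeline_config"
  cfg
}

validate_pipeline_config <- function(cfg) {
  required <- c("cohort", "m", "windows", "harm_outcome", "harm_denominator",
                "power", "penalty_scale")
  missing <- setdiff(required, names(cfg))
  if (length(missing)) {
    stop("pipeline config missing required key(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  invisible(cfg)
}

#' Read a pipeline configuration from YAML or JSON
#'
#' Scalar overrides from the file are applied on top of [pipeline_config()]
#' defaults; nested `cohort` and `power` entries are merged element-wise.
#'
#' @param path File path ending in `.yaml`/`.yml` or `.json`.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop_domain("the yaml package is required to read YAML configs")
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  cfg <- pipeline_config()
  for (nm in setdiff(names(raw), c("cohort", "power"))) cfg[[nm]] <- raw[[nm]]
  if (!is.null(raw$cohort)) {
    cfg$cohort <- do.call(cohort_config, raw$cohort)
  }
  for (nm in names(raw$power)) cfg$power[[nm]] <- raw$power[[nm]]
  cfg
}

#' Run the full analysis pipeline
#'
#' Executes, in order: cohort simulation; multiple imputation of the
#' discovery and validation arms; the Kendall-tau correlation analysis with
#' FDR control and the preregistered threshold; penalized multilevel fits of
#' the initiation and harm models for both measurement windows with pooled
#' effect tables and discovery/validation replication flags; out-of-sample
#' model comparison (AUC/DeLong, PPV/recall, MSE); and the Monte Carlo power
#' grid (generating coefficients taken from the full-model discovery fit).
#' Every stage output is written under `out_dir` and recorded, with an MD5
#' checksum, in `manifest.json`.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @param seed Master seed; stage seeds are derived deterministically.
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir, seed = 1L) {
  stopifnot(inherits(config, "pipeline_config"))
  validate_pipeline_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  outputs <- character(0)
  emit <- function(obj, name) {
    path <- file.path(out_dir, name)
    if (grepl("\\.csv$", name)) {
      utils::write.csv(obj, path, row.names = FALSE)
    } else {
      jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE)
    }
    outputs[[length(outputs) + 1L]] <<- path
    path
  }

  ## simulate
  cohort <- simulate_cohort(config$cohort, seed = derive_seed(seed, 101))
  write_cohort(cohort, file.path(out_dir, "cohort"))
  outputs <- c(outputs, file.path(out_dir, c("cohort.csv", "cohort_wide.csv",
                                             "cohort_truth.json")))
  disc <- cohort[cohort$arm == "discovery", , drop = FALSE]
  val <- cohort[cohort$arm == "validation", , drop = FALSE]

  ## impute (per arm, so no leakage across arms)
  imp_disc <- pmm_impute(disc, m = config$m, seed = derive_seed(seed, 102))
  imp_val <- pmm_impute(val, m = config$m, seed = derive_seed(seed, 103))

  ## correlate (first completed discovery table; baseline window)
  corr <- correlate_measures(imp_disc$completed[[1]])
  emit(corr_long(corr), "correlations.csv")

  ## fit + replication per window, pooled across imputations
  effects_all <- list()
  for (win in config$windows) {
    eff <- lapply(list(discovery = imp_disc, validation = imp_val),
                  function(imp) {
      pooled <- pool_fits(imp, function(d) {
        fit_initiation_model(d, window = win,
                             penalty_scale = config$penalty_scale)
      })
      pooled <- pooled[pooled$term != "(Intercept)", ]
      data.frame(predictor = pooled$term, estimate = exp(pooled$estimate),
                 lo = exp(pooled$estimate - 1.96 * pooled$se),
                 hi = exp(pooled$estimate + 1.96 * pooled$se),
                 p = pooled$p, p_adj = bh_adjust(pooled$p))
    })
    eff$discovery$arm <- "discovery"
    eff$validation$arm <- "validation"
    flags <- replication_flags(eff$discovery, eff$validation, null_value = 1)
    flags$window <- win
    effects_all[[win]] <- flags
  }
  emit(do.call(rbind, effects_all), "effects_initiation.csv")

  ## evaluate: per-imputation model comparison, averaged (median DeLong p)
  comparison <- pooled_comparison(imp_disc, imp_val, window = "baseline",
                                  penalty_scale = config$penalty_scale)
  emit(comparison, "model_comparison.csv")
  harm_cmp <- pooled_comparison(imp_disc, imp_val, outcome_kind = "harm",
                                outcome = config$harm_outcome,
                                denominator = config$harm_denominator,
                                window = "concurrent",
                                penalty_scale = config$penalty_scale)
  emit(harm_cmp, "model_comparison_harm.csv")

  ## power: generating betas from the full-model discovery fit
  full_fit <- fit_initiation_model(imp_disc$completed[[1]],
                                   penalty_scale = config$penalty_scale)
  gen <- generating_model_from_fit(full_fit)
  pcfg <- power_config(n_grid = config$power$n_grid,
                       base_rates = config$power$base_rates,
                       reps = config$power$reps,
                       seed = derive_seed(seed, 104))
  grid <- run_power_grid(pcfg, imp_disc$completed[[1]], gen,
                         measures = config$power$measures,
                         penalty_scale = config$penalty_scale)
  emit(grid, "power_grid.csv")
  emit(summarize_power(grid), "power_summary.csv")

  manifest <- list(
    seed = seed,
    stage_seeds = list(simulate = derive_seed(seed, 101),
                       impute_discovery = derive_seed(seed, 102),
                       impute_validation = derive_seed(seed, 103),
                       power = derive_seed(seed, 104)),
    package_version = as.character(utils::packageVersion("impulsim")),
    config_hash = digest_config(config),
    timestamp = format(Sys.time(), tz = "UTC"),
    outputs = lapply(stats::setNames(outputs, basename(outputs)), function(p) {
      list(path = p, md5 = unname(tools::md5sum(p)))
    })
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

digest_config <- function(config) {
  con <- textConnection(NULL, "w", local = TRUE)
  on.exit(close(con))
  dput(unclass(config), con)
  tmp <- tempfile()
  writeLines(textConnectionValue(con), tmp)
  on.exit(unlink(tmp), add = TRUE)
  unname(tools::md5sum(tmp))
}

# Model comparison on each completed dataset, then pooled: mean AUC/CI
# endpoints, median DeLong p across imputations.
pooled_comparison <- function(imp_disc, imp_val, ...) {
  m <- length(imp_disc$completed)
  per <- lapply(seq_len(m), function(i) {
    compare_predictor_sets(imp_disc$completed[[i]], imp_val$completed[[i]], ...)
  })
  out <- per[[1]]
  num <- c("auc", "ci_lo", "ci_hi", "ppv", "recall", "mse")
  for (col in num) {
    out[[col]] <- rowMeans(sapply(per, function(d) d[[col]]))
  }
  out$delong_p_vs_A <- apply(sapply(per, function(d) d$delong_p_vs_A), 1,
                             stats::median)
  out$m <- m
  out
}
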