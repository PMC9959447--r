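## End-to-end orchestration: simulate (or load) -> carbon accounting -> DEA
## scoring -> composite index -> regressions, with a hashed run manifest so a
## rerun under the same configuration is verifiably identical.

#' Pipeline configuration
#'
#' @param out_dir output directory for stage CSVs and the manifest.
#' @param simulate a [synthetic_config()] describing the synthetic study, or
#'   NULL when `paths` provide real inputs.
#' @param paths named list of input CSV paths (`activity_quantities`,
#'   `crops`, `activities`, `regression_panel`) used when `simulate` is NULL;
#'   every referenced path must exist.
#' @param hi_mode harvest-index convention for sequestration.
#' @param rts returns-to-scale choices to score (`"crs"`, `"vrs"` or both).
#' @param frontier DEA frontier pooling, `"pooled"` or `"by_year"`.
#' @param entropy_eps normalisation shift for entropy weighting.
#' @param composite_weights expert weights for the composite index.
#' @param models regression models to fit (subset of `"baseline"`,
#'   `"threshold"`, `"moderation"`, `"lag"`, `"tobit"`, `"iv"`,
#'   `"subsample"`).
#' @param winsor winsorization fraction for the baseline-type fits.
#' @param n_boot bootstrap replications for the threshold test.
#' @param seed seed for the regression-stage randomness (bootstrap).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir = tempfile("agrecoeff_run_"),
                            simulate = synthetic_config(),
                            paths = NULL,
                            hi_mode = "divide",
                            rts = c("crs", "vrs"),
                            frontier = "pooled",
                            entropy_eps = 1e-4,
                            composite_weights = c(0.4, 0.3, 0.3),
                            models = c("baseline", "threshold", "moderation",
                                       "lag", "tobit"),
                            winsor = 0.01,
                            n_boot = 300L,
                            seed = 1L) {
  assert_that(xor(!is.null(simulate), !is.null(paths)),
              "provide either a simulate config or input paths, not both",
              class = "agrecoeff_config_error")
  if (!is.null(simulate))
    assert_that(inherits(simulate, "synthetic_config"),
                "simulate must be a synthetic_config",
                class = "agrecoeff_config_error")
  if (!is.null(paths)) {
    missing_paths <- paths[!vapply(unlist(paths), file.exists, logical(1))]
    assert_that(length(missing_paths) == 0L,
                paste("input path(s) do not exist:",
                      paste(unlist(missing_paths), collapse = ", ")),
                class = "agrecoeff_config_error")
  }
  assert_that(abs(sum(composite_weights) - 1) < 1e-12,
              "composite weights must sum to 1",
              class = "agrecoeff_config_error")
  rts <- match.arg(rts, c("crs", "vrs"), several.ok = TRUE)
  frontier <- match.arg(frontier, c("pooled", "by_year"))
  known <- c("baseline", "threshold", "moderation", "lag", "tobit", "iv",
             "subsample")
  assert_that(all(models %in% known),
              paste("unknown model(s):",
                    paste(setdiff(models, known), collapse = ", ")),
              class = "agrecoeff_config_error")
  structure(list(out_dir = out_dir, simulate = simulate, paths = paths,
                 hi_mode = hi_mode, rts = rts, frontier = frontier,
                 entropy_eps = entropy_eps,
                 composite_weights = composite_weights, models = models,
                 winsor = winsor, n_boot = as.integer(n_boot),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys mirror the [pipeline_config()] arguments; a `simulate`
#' block is passed to [synthetic_config()].
#'
#' @param file YAML file path.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(file) {
  y <- yaml::read_yaml(file)
  if (!is.null(y$simulate)) {
    if (!is.null(y$simulate$control_coefs))
      y$simulate$control_coefs <- unlist(y$simulate$control_coefs)
    y$simulate <- do.call(synthetic_config, y$simulate)
  }
  if (!is.null(y$composite_weights))
    y$composite_weights <- as.numeric(y$composite_weights)
  do.call(pipeline_config, y)
}

stage_write <- function(df, out_dir, name) {
  path <- file.path(out_dir, name)
  utils::write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
  list(file = name, md5 = unname(tools::md5sum(path)), n_rows = nrow(df))
}

#' Run the full pipeline
#'
#' Executes the stages in dependency order -- accounting, DEA scoring, index
#' construction, regressions -- writing every stage output as CSV with a
#' content hash, and returns (and writes) a run manifest. Reruns under the
#' same configuration and seeds are bit-identical.
#'
#' @param cfg a [pipeline_config()].
#' @return list of class `run_manifest`: package version, seeds, per-stage
#'   output records (file, md5, row count). The manifest is also written to
#'   `manifest.json` in the output directory.
#' @export
run_pipeline <- function(cfg) {
  assert_that(inherits(cfg, "pipeline_config"), "cfg must be a pipeline_config",
              class = "agrecoeff_config_error")
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop_agrecoeff(paste0("stage '", name, "' failed: ",
                            conditionMessage(e)),
                     "agrecoeff_stage_error")
    })
  }

  # inputs
  if (!is.null(cfg$simulate)) {
    ap <- run_stage("simulate", generate_activity_panel(cfg$simulate))
    panel <- run_stage("simulate", generate_regression_panel(cfg$simulate))
    write_panel_csv(panel, file.path(cfg$out_dir, "inputs_panel.csv"))
  } else {
    ap <- run_stage("load", list(
      crops = utils::read.csv(cfg$paths$crops),
      activities = utils::read.csv(cfg$paths$activities),
      quantities = utils::read.csv(cfg$paths$activity_quantities)))
    panel <- run_stage("load", utils::read.csv(cfg$paths$regression_panel))
  }

  outputs <- list()

  # stage 1: carbon accounting / DMU assembly
  dmu_tab <- run_stage("account", assemble_dmu_table(ap, hi_mode = cfg$hi_mode))
  outputs$account <- stage_write(dmu_tab, cfg$out_dir, "accounts.csv")

  # stage 2: DEA scoring
  roles <- dea_roles()
  dmus <- dmu_set(dmu_tab, inputs = roles$inputs,
                  good_outputs = roles$good_outputs,
                  bad_outputs = roles$bad_outputs, id = "id", year = "year")
  scores <- run_stage("dea", {
    sc <- lapply(cfg$rts, function(r)
      score_panel(dmus, rts = r, frontier = cfg$frontier))
    out <- sc[[1]][c("id", "year")]
    for (i in seq_along(cfg$rts))
      out[[paste0("aee_", cfg$rts[i])]] <- round(sc[[i]]$score, 4)
    out
  })
  outputs$dea <- stage_write(scores, cfg$out_dir, "dea_scores.csv")

  # stage 3: composite index (from the panel's sub-indices)
  ndi_tab <- run_stage("index", {
    cbind(panel[c("unit", "year")],
          composite_ndi(panel$infi, panel$ci, panel$inni,
                        weights = cfg$composite_weights))
  })
  outputs$index <- stage_write(ndi_tab, cfg$out_dir, "ndi_index.csv")

  # stage 4: regressions
  fit_rows <- run_stage("fit", {
    rows <- list()
    add <- function(model, fit, keep = NULL) {
      cf <- fit$coefficients; se <- fit$se; tt <- fit$t
      if (!is.null(keep)) { cf <- cf[keep]; se <- se[keep]; tt <- tt[keep] }
      rows[[length(rows) + 1L]] <<- data.frame(
        model = model, term = names(cf), coef = unname(cf), se = unname(se),
        t = unname(tt), n_obs = fit$n_obs, stringsAsFactors = FALSE)
    }
    if ("baseline" %in% cfg$models)
      for (oc in c("vrs", "crs"))
        add(paste0("baseline_", oc),
            pooled_ols(panel, outcome = oc, winsor = cfg$winsor))
    if ("threshold" %in% cfg$models) {
      tf <- threshold_fit(panel, n_boot = cfg$n_boot, seed = cfg$seed)
      rows[[length(rows) + 1L]] <- data.frame(
        model = "threshold", term = c("theta", "reg_low", "reg_high",
                                      "f_stat", "boot_p"),
        coef = c(tf$theta_hat, tf$regime_coefs, tf$f_stat, tf$boot_p),
        se = NA_real_, t = NA_real_, n_obs = tf$n_obs,
        stringsAsFactors = FALSE)
    }
    if ("moderation" %in% cfg$models)
      add("moderation", moderation_fit(panel, time_fe = TRUE))
    if ("lag" %in% cfg$models)
      add("lag", lagged_regressor_fit(panel, winsor = cfg$winsor))
    if ("tobit" %in% cfg$models) {
      tr <- attr(panel, "truth")
      lo <- if (!is.null(tr) && is.finite(tr$censor_bound)) tr$censor_bound
            else min(panel$aee_vrs) - 1
      add("tobit", tobit_fit(panel, spec = tobit_spec(lower = lo)))
    }
    if ("iv" %in% cfg$models) {
      ivf <- iv_2sls(panel)
      add("iv_first_stage", ivf$first_stage)
      add("iv_second_stage", ivf$second_stage)
    }
    if ("subsample" %in% cfg$models) {
      yrs <- sort(unique(panel$year))
      cut <- yrs[ceiling(length(yrs) * 0.6)]
      sf <- subsample_fit(panel, panel$year <= cut, winsor = cfg$winsor)
      add("subsample_early", sf$fit_a)
      add("subsample_late", sf$fit_b)
    }
    do.call(rbind, rows)
  })
  outputs$fit <- stage_write(fit_rows, cfg$out_dir, "fits.csv")

  manifest <- structure(list(
    package_version = as.character(utils::packageVersion("agrecoeff")),
    seeds = list(pipeline = cfg$seed,
                 simulate = if (!is.null(cfg$simulate)) cfg$simulate$seed),
    out_dir = cfg$out_dir,
    outputs = outputs
  ), class = "run_manifest")
  jsonlite::write_json(unclass(manifest),
                       file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  manifest
}

#' @export
print.run_manifest <- function(x, ...) {
  cat("<run_manifest> agrecoeff", x$package_version, "->", x$out_dir, "\n")
  for (nm in names(x$outputs)) {
    o <- x$outputs[[nm]]
    cat(sprintf("  %-8s %-16s %5d rows  md5 %s\n", nm, o$file, o$n_rows, o$md5))
  }
  invisible(x)
}

#' Verify the integrity of a pipeline run
#'
#' Recomputes the hash of every stage output recorded in a manifest and
#' errors on any mismatch or missing file.
#'
#' @param manifest a `run_manifest` or the path to a `manifest.json`.
#' @return TRUE invisibly when all hashes match.
#' @export
verify_manifest <- function(manifest) {
  if (is.character(manifest)) {
    m <- jsonlite::read_json(manifest)
    dir <- dirname(manifest)
  } else {
    m <- manifest
    dir <- manifest$out_dir
  }
  for (nm in names(m$outputs)) {
    o <- m$outputs[[nm]]
    path <- file.path(dir, o$file)
    if (!file.exists(path))
      stop_agrecoeff(paste("stage output missing:", o$file),
                     "agrecoeff_integrity_error")
    h <- unname(tools::md5sum(path))
    if (!identical(h, o$md5))
      stop_agrecoeff(paste0("hash mismatch for ", o$file, ": manifest ",
                            o$md5, ", file ", h),
                     "agrecoeff_integrity_error")
  }
  invisible(TRUE)
}
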