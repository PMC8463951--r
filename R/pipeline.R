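# Map export and pipeline driver -----------------------------------------

#' Export a choropleth-ready GeoJSON
#'
#' Writes the tract polygons with the value column, a quantile bin label
#' (default 5 bins) and, when available, a local-significance flag — the
#' static-data counterpart of an interactive cancellation-rate map.
#'
#' @param tracts A `tract_frame` with geometry.
#' @param value_column Name of the numeric column to map.
#' @param path Output GeoJSON path.
#' @param bins Number of quantile bins.
#' @param significance_column Optional logical column name (e.g. from a
#'   merged [gw_pearson()] result).
#' @return `path`, invisibly.
#' @export
export_map <- function(tracts, value_column, path, bins = 5,
                       significance_column = NULL) {
  stopifnot(is_tract_frame(tracts))
  if (!value_column %in% names(tracts)) {
    abort_arg("column '", value_column, "' not found")
  }
  v <- tracts[[value_column]]
  qs <- unique(quantile(v, probs = seq(0, 1, length.out = bins + 1),
                        na.rm = TRUE))
  if (length(qs) <= 2) {
    bin <- rep(1L, length(v))  # constant (or near-constant) values: one bin
  } else {
    bin <- as.integer(cut(v, qs, include.lowest = TRUE))
  }
  out <- tracts
  out[[paste0(value_column, "_bin")]] <- bin
  if (!is.null(significance_column)) {
    stopifnot(significance_column %in% names(tracts))
    out$significant <- as.logical(tracts[[significance_column]])
  }
  write_tract_geojson(out, path)
  invisible(path)
}

pipeline_schema <- c("synthetic", "input_geojson", "input_csv", "out_dir",
                     "min_cases", "alpha", "vif_threshold", "families",
                     "penalty_grid", "outer_k", "inner_k", "n_perm",
                     "seed", "map_column")

#' Run the full tract-rate analysis pipeline
#'
#' Drives all stages in order on one configuration: simulate (or read) the
#' tract table, preprocess (exclusion + empirical Bayes rates), build
#' weights, screen covariates, cross-validate the requested model
#' families, compute permutation importance for the best family, and
#' export a map. All outputs are plain CSV/GeoJSON/JSON under `out_dir`,
#' regenerable from the configuration and seed alone; a manifest records
#' seeds and selections.
#'
#' @param config Named list. Keys: `synthetic` (a [synth_config()] list of
#'   arguments) or `input_geojson`/`input_csv`; `out_dir`; thresholds
#'   `min_cases`, `alpha`, `vif_threshold`; `families` (character);
#'   `penalty_grid`; `outer_k`, `inner_k`, `n_perm`, `seed`, `map_column`.
#'   Unknown keys are rejected.
#' @return Invisible list with the tract table, weights, diagnostics,
#'   CV results, importance table and manifest.
#' @export
run_dosc_pipeline <- function(config) {
  unknown <- setdiff(names(config), pipeline_schema)
  if (length(unknown)) {
    abort_arg("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  seed <- config$seed %||% 1
  out_dir <- config$out_dir %||% tempfile("dosc_run_")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(config$synthetic)) {
    cfg <- do.call(synth_config, c(config$synthetic, list(seed = seed)))
    sim <- simulate_tract_data(cfg)
    tracts <- sim$tracts
    w <- sim$weights
  } else {
    if (is.null(config$input_geojson)) {
      abort_arg("config needs either 'synthetic' or 'input_geojson'")
    }
    tracts <- if (!is.null(config$input_csv)) {
      read_tract_fixture(config$input_geojson, config$input_csv)
    } else read_tract_geojson(config$input_geojson)
    w <- tract_weights(tracts)
  }
  tracts <- filter_tracts(tracts, min_cases = config$min_cases %||% 20)
  tracts <- add_eb_rate(tracts)
  keep <- !tracts$excluded_flag
  model_tab <- tracts[keep, , drop = FALSE]
  w_keep <- subset_weights(w, which(keep))

  covars <- grep("^x[0-9]+$", names(model_tab), value = TRUE)
  if (length(covars) < 2) {
    covars <- setdiff(names(model_tab)[vapply(model_tab, is.numeric,
                                              logical(1))],
                      c("n_cases", "n_cancel", "crude_rate", "eb_rate",
                        "row", "col", "centroid_x", "centroid_y"))
  }
  seeds <- derive_seeds(seed, 4)
  diag_tab <- screen_covariates(model_tab, covars, w_keep,
                                alpha = config$alpha %||% 0.05,
                                vif_threshold = config$vif_threshold %||% 10,
                                n_perm = config$n_perm %||% 999,
                                seed = seeds[1])
  use <- diag_tab$variable[diag_tab$retained]
  if (length(use) == 0) use <- covars  # nothing clusters: keep all, note it
  fml <- stats::as.formula(paste("eb_rate ~", paste(use, collapse = " + ")))

  families <- config$families %||% c("glm", "ridge_glm", "sar")
  cvs <- lapply(families, function(fam) {
    nested_cv(model_tab, fml, w_keep, family = fam,
              grid = config$penalty_grid,
              outer_k = config$outer_k %||% 10,
              inner_k = config$inner_k %||% 10, seed = seeds[2])
  })
  names(cvs) <- families
  means <- vapply(cvs, `[[`, numeric(1), "mean_rmse")
  best <- families[which.min(means)]
  best_pen <- cvs[[best]]$selected[[1]] %||% 0
  fit <- spreg(fml, model_tab, w_keep, family = best, penalty = best_pen)
  imp <- permutation_importance(fit, model_tab, w_keep, seed = seeds[3])

  # artifacts
  cv_df <- do.call(rbind, lapply(families, function(fam) {
    r <- cvs[[fam]]
    data.frame(family = fam, mean_rmse = r$mean_rmse, ci_low = r$ci_low,
               ci_high = r$ci_high)
  }))
  write_precise_csv(cv_df, file.path(out_dir, "cv_results.csv"))
  write_precise_csv(as.data.frame(imp), file.path(out_dir, "importance.csv"))
  write_precise_csv(diag_tab, file.path(out_dir, "diagnostics.csv"))
  tab_out <- as.data.frame(model_tab)
  tab_out <- tab_out[, setdiff(names(tab_out), "geometry"), drop = FALSE]
  write_precise_csv(tab_out, file.path(out_dir, "modeling_table.csv"))
  if (!is.null(tracts$geometry)) {
    export_map(tracts, config$map_column %||% "eb_rate",
               file.path(out_dir, "rate_map.geojson"))
  }
  manifest <- list(seed = seed, seeds = seeds, families = families,
                   best_family = best, retained_covariates = use,
                   provenance = provenance(tracts),
                   version = as.character(utils::packageVersion("spatialdosc")))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(tracts = tracts, weights = w, diagnostics = diag_tab,
                 cv = cvs, importance = imp, best_family = best,
                 manifest = manifest, out_dir = out_dir))
}
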