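#' Default run configuration
#'
#' Collects every tunable constant of the pipeline with its standard
#' default: 65 km/h speed filter, 1000 km pseudo-absence limit, Spearman
#' r 0.6 collinearity threshold, 2-point AIC rule for quadratic effects,
#' 0.90 single-model and 0.95 cumulative Akaike-weight thresholds, 70/30
#' cross-validation splits repeated 1000 times, 15 quadrature nodes. All
#' values can be overridden; the configuration round-trips losslessly
#' through YAML ([write_config()]/[read_config()]).
#'
#' @return Nested named list.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    grid = list(bbox = c(40, 50, -24, -14), resolution = 0.25),
    period = list(years = 2008:2010, months = 9:12),
    taxa = list(
      frigatebird = list(coef = list(INT = -0.4, Chloa = 0.8, SST = -0.7,
                                     Bathy = 0.5),
                         sigma = 0.5),
      tern = list(coef = list(INT = -0.5, Chloa = 0.9, SST = -0.5),
                  sigma = 0.5),
      booby = list(coef = list(INT = -0.6, Chloa = 0.6, Bathy = 0.8),
                   sigma = 0.5),
      subsurface = list(coef = list(INT = -0.3, SST = -0.6, SLA = 0.5),
                        sigma = 0.5)),
    tracking = list(n_animals = 12, n_steps = 300, cadence_h = 1.57,
                    outlier_rate = 0.05, max_range_km = 1000,
                    colony_radius_km = 5,
                    variables = c("Chloa", "SST", "SLA", "Bathy")),
    survey = list(n_campaigns = 6, bins_per_campaign = 150,
                  bin_spacing_km = NULL),
    model = list(variables = c("Chloa", "SST", "SLA", "Bathy"),
                 nAGQ = 15, aicc = FALSE),
    thresholds = list(vmax_kmh = 65, limit_km = 1000, r_threshold = 0.6,
                      delta_aic = 2, single_aw = 0.90, cum_aw = 0.95,
                      train_frac = 0.7, n_reps = 1000),
    overlap_method = "literal"
  )
}

#' Small demonstration configuration
#'
#' A desk-scale variant of [default_config()] (fewer animals, bins and
#' cross-validation replicates) that runs the full pipeline in about a
#' minute.
#'
#' @return Nested named list.
#' @export
demo_config <- function() {
  cfg <- default_config()
  cfg$period$years <- 2008:2009
  cfg$tracking$n_animals <- 6
  cfg$tracking$n_steps <- 200
  cfg$survey$n_campaigns <- 4
  cfg$survey$bins_per_campaign <- 120
  cfg$thresholds$n_reps <- 25
  cfg
}

#' @rdname default_config
#' @param config Configuration list.
#' @param path YAML file path.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname default_config
#' @export
read_config <- function(path) {
  yaml::as.yaml  # force namespace load
  cfg <- yaml::read_yaml(path)
  ## yaml collapses length-1 vectors; restore known numeric vectors
  cfg$grid$bbox <- as.numeric(cfg$grid$bbox)
  cfg$period$years <- as.integer(cfg$period$years)
  cfg$period$months <- as.integer(cfg$period$months)
  cfg
}

truth_from_config <- function(tx_cfg, seed = NULL) {
  truth_record(unlist(tx_cfg$coef), sigma = tx_cfg$sigma %||% 0, seed = seed)
}

## Fit one occurrence dataset end to end: normalize -> collinearity
## screen -> shape screen -> all subsets -> confidence set -> average.
fit_taxon_model <- function(occ, variables, cfg, group_field = "group") {
  th <- cfg$thresholds
  occ$group <- occ[[group_field]]
  norm_tab <- normalize_covariates(occ, variables)
  norm <- attr(norm_tab, "norm")
  screen <- collinearity_screen(norm_tab, variables, th$r_threshold)
  shapes <- shape_screen(norm_tab, screen$retained, delta_aic = th$delta_aic)
  mset <- all_subsets(norm_tab, screen$retained, shapes = shapes,
                      nAGQ = cfg$model$nAGQ, aicc = isTRUE(cfg$model$aicc))
  cset <- confidence_set(mset, th$cum_aw, th$single_aw)
  avg <- average_model(cset, norm)
  list(table = norm_tab, screen = screen, shapes = shapes, mset = mset,
       cset = cset, avg = avg)
}

#' Run the full analysis pipeline
#'
#' Executes simulate - process tracks - build occurrence - fit - evaluate
#' - map - overlap on synthetic data described by `config`, logging row
#' and cell counts per stage, and (optionally) writing all tables, model
#' rankings, maps and the summary report into a run directory. Every
#' stochastic stage is seeded from `config$seed`, so a rerun with the
#' same configuration is bit-identical.
#'
#' @param config Configuration list (see [default_config()]).
#' @param out_dir Optional run directory; created if missing.
#' @param quiet Suppress stage messages (default FALSE).
#' @return Invisibly, a list with the seascape, tracks, survey, per-taxon
#'   fits (`$vessel`), the tracking-data fit (`$tracking`), validation
#'   reports, thresholds, prediction stacks and the `suitability_maps`
#'   object; plus `$report`, the summary written by [make_report()].
#' @export
run_pipeline <- function(config = default_config(), out_dir = NULL,
                         quiet = FALSE) {
  say <- function(...) if (!quiet) message(sprintf(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  cfg <- config
  seed <- cfg$seed
  taxa <- names(cfg$taxa)
  if (!length(taxa)) stop("config lists no taxa")

  ## -- simulate ---------------------------------------------------------
  res <- stage("simulate", {
    ss <- generate_seascape(cfg$grid$bbox, cfg$period$years, cfg$period$months,
                            seed = derive_seed(seed, 1),
                            resolution = cfg$grid$resolution)
    truths <- lapply(cfg$taxa, truth_from_config, seed = seed)
    tracks <- simulate_tracks(ss, truths[[1]],
                              n_animals = cfg$tracking$n_animals,
                              cadence_h = cfg$tracking$cadence_h,
                              max_range_km = cfg$tracking$max_range_km,
                              outlier_rate = cfg$tracking$outlier_rate,
                              n_steps = cfg$tracking$n_steps,
                              seed = derive_seed(seed, 2))
    survey <- simulate_survey(ss, truths, cfg$survey$n_campaigns,
                              cfg$survey$bins_per_campaign,
                              seed = derive_seed(seed, 3),
                              bin_spacing_km = cfg$survey$bin_spacing_km)
    list(seascape = ss, truths = truths, tracks = tracks, survey = survey)
  })
  say("simulate: %d track fixes, %d survey bins", nrow(res$tracks),
      nrow(res$survey))

  ## -- process tracks ---------------------------------------------------
  res$tracks_clean <- stage("tracks", {
    tr <- speed_filter(res$tracks, cfg$thresholds$vmax_kmh)
    split_trips(tr, res$seascape$colony, cfg$tracking$colony_radius_km)
  })
  say("tracks: %d fixes kept of %d; %d trips", nrow(res$tracks_clean),
      nrow(res$tracks), length(unique(stats::na.omit(res$tracks_clean$trip))))

  ## -- build occurrence -------------------------------------------------
  res$occ <- stage("build", {
    grid <- res$seascape$grid
    pres <- tracks_to_presence(res$tracks_clean, grid)
    pres <- pres[pres$status == "breeding", , drop = FALSE]
    tocc <- tracking_occurrence(pres, grid, res$seascape$colony,
                                cfg$thresholds$limit_km,
                                seed = derive_seed(seed, 4))
    tocc <- tocc[tocc$month %in% cfg$period$months, , drop = FALSE]
    tocc <- attach_covariates(tocc, res$seascape)
    vocc <- lapply(taxa, function(tx) {
      v <- surveys_to_occurrence(res$survey, grid, tx)
      rows <- v$rows[v$rows$month %in% cfg$period$months, , drop = FALSE]
      attach_covariates(rows, res$seascape)
    })
    names(vocc) <- taxa
    list(tracking = tocc, vessel = vocc)
  })
  say("build: tracking rows %d; vessel rows %s", nrow(res$occ$tracking),
      paste(vapply(res$occ$vessel, nrow, 1L), collapse = "/"))

  ## -- fit --------------------------------------------------------------
  res$fits <- stage("fit", {
    tracking <- fit_taxon_model(res$occ$tracking, cfg$tracking$variables, cfg)
    vessel <- lapply(taxa, function(tx)
      fit_taxon_model(res$occ$vessel[[tx]], cfg$model$variables, cfg))
    names(vessel) <- taxa
    list(tracking = tracking, vessel = vessel)
  })
  say("fit: confidence sets %s (tracking %d)",
      paste(vapply(res$fits$vessel, function(f) length(f$cset$models), 1L),
            collapse = "/"),
      length(res$fits$tracking$cset$models))

  ## -- evaluate ---------------------------------------------------------
  res$validation <- stage("evaluate", {
    out <- lapply(seq_along(taxa), function(i)
      cross_validate(res$fits$vessel[[i]]$table, res$fits$vessel[[i]]$cset,
                     cfg$thresholds$train_frac, cfg$thresholds$n_reps,
                     seed = derive_seed(seed, 10 + i), nAGQ = cfg$model$nAGQ))
    names(out) <- taxa
    out$tracking <- cross_validate(res$fits$tracking$table,
                                   res$fits$tracking$cset,
                                   cfg$thresholds$train_frac,
                                   cfg$thresholds$n_reps,
                                   seed = derive_seed(seed, 20),
                                   nAGQ = cfg$model$nAGQ)
    out
  })

  ## -- map + overlap ----------------------------------------------------
  res$maps <- stage("map", {
    stacks <- lapply(taxa, function(tx)
      predict_maps(res$fits$vessel[[tx]]$avg, res$seascape))
    names(stacks) <- taxa
    p_th <- vapply(taxa, function(tx) {
      f <- res$fits$vessel[[tx]]
      scores <- plogis(lp_from_coef(f$avg$coef,
                                    ensure_sq_columns(f$table,
                                                      names(f$avg$coef))))
      roc_threshold(f$table$response, scores)$p_th
    }, 0)
    list(stacks = stacks, p_th = p_th)
  })
  res$suitability <- stage("overlap",
    suitability_maps(res$maps$stacks, res$maps$p_th, cfg$overlap_method))
  say("overlap: mean index %.2f, max %d", mean(res$suitability$index_mean),
      max(unlist(res$suitability$index)))

  res$report <- build_report(res, cfg)
  if (!is.null(out_dir)) write_run_dir(res, cfg, out_dir)
  invisible(res)
}

build_report <- function(res, cfg) {
  taxa <- names(cfg$taxa)
  per_taxon <- lapply(taxa, function(tx) {
    f <- res$fits$vessel[[tx]]; v <- res$validation[[tx]]
    list(estimates = as.list(round(f$avg$coef, 4)),
         se = as.list(round(f$avg$se, 4)),
         n_models = length(f$cset$models),
         auc_average_model = v$auc_full,
         auc_category = v$category,
         auc_training = v$training, auc_test = v$test,
         transferable = v$transferable,
         p_th = unname(res$maps$p_th[[tx]]))
  })
  names(per_taxon) <- taxa
  pairs <- utils::combn(taxa, 2)
  overlap <- lapply(seq_len(ncol(pairs)), function(k) {
    a <- pairs[1, k]; b <- pairs[2, k]
    list(pair = c(a, b),
         mean = res$suitability$overlap_mean[a, b],
         sd = res$suitability$overlap_sd[a, b])
  })
  list(taxa = per_taxon, overlap = overlap,
       tracking = list(
         estimates = as.list(round(res$fits$tracking$avg$coef, 4)),
         se = as.list(round(res$fits$tracking$avg$se, 4)),
         auc_average_model = res$validation$tracking$auc_full,
         auc_test = res$validation$tracking$test),
       config = cfg)
}

write_run_dir <- function(res, cfg, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_config(cfg, file.path(out_dir, "config.yaml"))
  write_trajectory_csv(res$tracks, file.path(out_dir, "tracks_raw.csv"))
  write_trajectory_csv(res$tracks_clean, file.path(out_dir, "tracks_clean.csv"))
  write_survey_csv(res$survey, file.path(out_dir, "survey.csv"))
  write.csv(res$occ$tracking, file.path(out_dir, "occurrence_tracking.csv"),
            row.names = FALSE)
  for (tx in names(res$occ$vessel))
    write.csv(res$occ$vessel[[tx]],
              file.path(out_dir, sprintf("occurrence_vessel_%s.csv", tx)),
              row.names = FALSE)
  for (tx in names(res$fits$vessel))
    write.csv(res$fits$vessel[[tx]]$mset$table,
              file.path(out_dir, sprintf("models_%s.csv", tx)),
              row.names = FALSE)
  grid <- res$seascape$grid
  write_layer_csv(res$suitability$index_mean, grid,
                  file.path(out_dir, "suitability_index_mean.csv"))
  write_layer_csv(res$suitability$index_sd, grid,
                  file.path(out_dir, "suitability_index_sd.csv"))
  jsonlite::write_json(res$report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' Summarize a completed run directory
#'
#' Reads `report.json` from a [run_pipeline()] output directory and
#' returns the parsed summary (per-taxon averaged estimates with
#' unconditional SEs, AUCs and cross-validation summaries, thresholds,
#' and the pairwise overlap entries).
#'
#' @param run_dir Run directory.
#' @return The report list, class `run_report`.
#' @export
make_report <- function(run_dir) {
  path <- file.path(run_dir, "report.json")
  if (!file.exists(path)) stop("incomplete run: no report.json in ", run_dir)
  structure(jsonlite::read_json(path, simplifyVector = TRUE),
            class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  for (tx in names(x$taxa)) {
    t <- x$taxa[[tx]]
    cat(sprintf("%-12s AUC %.3f (%s), test AUC %.3f [%.3f, %.3f], P_th %.3f\n",
                tx, t$auc_average_model, t$auc_category, t$auc_test$mean,
                t$auc_test$ci[1], t$auc_test$ci[2], t$p_th))
  }
  cat("pairwise overlap (mean +/- SD):\n")
  for (ov in x$overlap)
    cat(sprintf("  %s - %s: %.3f +/- %.3f\n", ov$pair[1], ov$pair[2],
                ov$mean, ov$sd))
  invisible(x)
}
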