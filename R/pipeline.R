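#' Configuration for a full pipeline run
#'
#' Bundles every tunable the pipeline uses so that one config plus one
#' master seed reproduces a run bit-identically. The master seed fans
#' out to per-stage, per-species child seeds by stable hashing, so
#' stages are independently reproducible.
#'
#' @param world A [synthetic_world_config()] describing the study region.
#' @param n_species Number of virtual species to simulate and model.
#' @param min_records Minimum record count per species (see
#'   [min_records_filter()]).
#' @param n_occurrences Records drawn per species.
#' @param thin_distance Spatial thinning distance (map units).
#' @param k_folds Cross-validation folds.
#' @param cor_threshold Collinearity screen cutoff on |r|.
#' @param feature_classes,n_knots,regularization_multiplier Feature
#'   configuration (see [feature_spec()]).
#' @param background_n Background points per species.
#' @param transform Suitability output scale.
#' @param delta_temperature,precip_scale Future climate shift.
#' @param loss_fraction Native-vegetation loss fraction.
#' @param pa_coverage,pa_patches Protected-area extent and patch count.
#' @param reporting_fraction Per-PA recommendation threshold.
#' @param mop_fraction MOP nearest-reference fraction.
#' @param seed Master seed.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(world = synthetic_world_config(),
                            n_species = 5, min_records = 10,
                            n_occurrences = 120, thin_distance = 2,
                            k_folds = 5, cor_threshold = 0.7,
                            feature_classes = c("linear", "quadratic",
                                                "hinge"),
                            n_knots = 5, regularization_multiplier = 1,
                            background_n = 2000,
                            transform = "cloglog",
                            delta_temperature = 1.4, precip_scale = 1.1,
                            loss_fraction = 0.3,
                            pa_coverage = 0.12, pa_patches = 12,
                            reporting_fraction = 0.25,
                            mop_fraction = 0.1, seed = 1) {
  structure(
    list(world = world, n_species = n_species, min_records = min_records,
         n_occurrences = n_occurrences, thin_distance = thin_distance,
         k_folds = k_folds, cor_threshold = cor_threshold,
         feature_classes = feature_classes, n_knots = n_knots,
         regularization_multiplier = regularization_multiplier,
         background_n = background_n, transform = transform,
         delta_temperature = delta_temperature,
         precip_scale = precip_scale, loss_fraction = loss_fraction,
         pa_coverage = pa_coverage, pa_patches = pa_patches,
         reporting_fraction = reporting_fraction,
         mop_fraction = mop_fraction, seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

#' Run the full stacked-SDM pipeline on a synthetic world
#'
#' Executes every stage in order: world generation, occurrence cleaning,
#' minimum-record filter, thinning, fold assignment, collinearity
#' screening, per-species Maxent fitting with k-fold evaluation, maxTSS
#' binarization, projection to the future climate (threshold reused),
#' MOP extrapolation analysis, occurrence-based restriction, richness
#' stacking, range shifts, richness change, four-region prioritization,
#' and protected-area summaries with the KS effectiveness test. All
#' randomness derives from the config's master seed, so two runs of one
#' config are identical. If `outdir` is given, rasters (ASCII grids) and
#' tables (CSV/JSON) are written there along with a provenance manifest.
#'
#' @param config A [pipeline_config()].
#' @param outdir Optional output directory.
#' @return A named list of all pipeline artifacts.
#' @export
run_pipeline <- function(config, outdir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  seed <- config$seed
  sys <- synthetic_study_system(
    config$world, n_species = config$n_species,
    delta_temperature = config$delta_temperature,
    precip_scale = config$precip_scale,
    pa_coverage = config$pa_coverage, pa_patches = config$pa_patches,
    loss_fraction = config$loss_fraction)

  raw <- purrr::map_dfr(sys$species, function(sp)
    sample_occurrences(sp, sys$current, config$n_occurrences,
                       seed = child_seed(seed, "occ", sp$name)))
  cleaned <- clean_occurrences(raw, sys$current)
  filt <- min_records_filter(cleaned, config$min_records)
  thinned <- thin_occurrences(filt$kept, config$thin_distance, seed = seed)
  folded <- assign_folds(thinned, k = config$k_folds, seed = seed)

  screen <- collinearity_screen(sys$current,
                                threshold = config$cor_threshold)
  env <- screen$kept
  fut <- subset_layers(sys$future, layer_names(env))

  spec <- feature_spec(config$feature_classes, n_knots = config$n_knots,
                       regularization_multiplier =
                         config$regularization_multiplier)
  species_names <- unique(folded$species)
  sp_lookup <- stats::setNames(sys$species,
                               vapply(sys$species, `[[`, character(1),
                                      "name"))
  per_species <- lapply(species_names, function(nm) {
    occ <- folded[folded$species == nm, , drop = FALSE]
    vsp <- sp_lookup[[nm]]
    acc <- define_accessible_area(occ, env, vsp$dispersal_radius)
    bg <- sample_background(acc, env, config$background_n,
                            seed = child_seed(seed, "bg", nm))
    ev <- kfold_evaluate(occ, env, bg, spec = spec,
                         seed = child_seed(seed, "cv", nm))
    model <- ev$full_model
    model$accessible <- acc
    cur_bin <- project_model(model, env, ev$chosen_threshold,
                             scenario = "current",
                             transform = config$transform)
    fut_bin <- project_model(model, fut, ev$chosen_threshold,
                             scenario = "future",
                             transform = config$transform)
    ref <- land_matrix(env, which(acc & !env$nodata))
    mop_map <- mop(ref, fut, reference_fraction = config$mop_fraction)
    cur_obr <- obr_restrict(cur_bin, occ)
    fut_obr <- obr_restrict(fut_bin, occ)
    list(name = nm, occ = occ, background = bg, evaluation = ev,
         model = model, binary_current = cur_obr, binary_future = fut_obr,
         binary_current_raw = cur_bin, binary_future_raw = fut_bin,
         mop = mop_map)
  })
  names(per_species) <- species_names

  rich_cur <- stack_richness(lapply(per_species, `[[`, "binary_current"),
                             scenario = "current")
  rich_fut <- stack_richness(lapply(per_species, `[[`, "binary_future"),
                             scenario = "future")
  shifts <- purrr::map_dfr(per_species, function(ps)
    range_shift(ps$binary_current, ps$binary_future))
  shift_summary <- summarize_shifts(shifts)
  delta_s <- richness_change(rich_cur, rich_fut)
  veg <- vegetation_change_class(sys$landuse$current, sys$landuse$future)
  priority <- classify_regions(delta_s, veg)
  pa_summary <- summarize_protected_areas(
    priority, sys$pa, reporting_fraction = config$reporting_fraction,
    richness_current = rich_cur, richness_future = rich_fut)
  ks_current <- pa_effectiveness_test(rich_cur, sys$pa)
  ks_future <- pa_effectiveness_test(rich_fut, sys$pa)

  evaluation_summary <- purrr::map_dfr(per_species, function(ps)
    glance(ps$evaluation))

  result <- list(
    config = config, system = sys, occurrences = folded,
    excluded_species = filt$excluded, screening = screen,
    env = env, future_env = fut, species = per_species,
    evaluation_summary = evaluation_summary,
    richness_current = rich_cur, richness_future = rich_fut,
    shifts = shifts, shift_summary = shift_summary,
    delta_richness = delta_s, vegetation_change = veg,
    priority = priority, pa_summary = pa_summary,
    ks_current = ks_current, ks_future = ks_future
  )
  if (!is.null(outdir)) write_pipeline_artifacts(result, outdir)
  result
}

# Persist the deterministic artifacts of a run as plain-text files.
write_pipeline_artifacts <- function(result, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  grid <- result$env$grid
  write_env_stack(result$env, file.path(outdir, "env_current"))
  write_env_stack(result$future_env, file.path(outdir, "env_future"))
  write_occurrences(result$occurrences,
                    file.path(outdir, "occurrences.csv"))
  utils::write.csv(result$shifts, file.path(outdir, "range_shifts.csv"),
                   row.names = FALSE)
  utils::write.csv(result$evaluation_summary,
                   file.path(outdir, "evaluation_summary.csv"),
                   row.names = FALSE)
  utils::write.csv(result$pa_summary$per_pa,
                   file.path(outdir, "pa_summary.csv"), row.names = FALSE)
  write_ascii_grid(result$richness_current$values, grid,
                   file.path(outdir, "richness_current.asc"))
  write_ascii_grid(result$richness_future$values, grid,
                   file.path(outdir, "richness_future.asc"))
  write_ascii_grid(result$delta_richness$values, grid,
                   file.path(outdir, "delta_richness.asc"))
  pv <- result$priority$values
  write_ascii_grid(pv, grid, file.path(outdir, "priority.asc"))
  for (nm in names(result$species)) {
    ps <- result$species[[nm]]
    write_ascii_grid(ps$binary_current$values, grid,
                     file.path(outdir, paste0("binary_current_", nm,
                                              ".asc")))
    write_ascii_grid(ps$binary_future$values, grid,
                     file.path(outdir, paste0("binary_future_", nm,
                                              ".asc")))
    write_ascii_grid(ps$mop$values, grid,
                     file.path(outdir, paste0("mop_", nm, ".asc")))
  }
  jsonlite::write_json(
    list(seed = result$config$seed,
         n_species = length(result$species),
         ks_current = as.list(result$ks_current),
         ks_future = as.list(result$ks_future),
         parameters = result$config[setdiff(names(result$config),
                                            "world")]),
    file.path(outdir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(outdir)
}
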