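#' Cross-species summary statistics
#'
#' Arithmetic mean and sample SD (n - 1 denominator) of the effect-size and
#' scale-of-effect columns, strict sign counts of effect sizes (zero effects
#' count as neither positive nor negative) and effect-size extremes.
#'
#' @param responses a `SpeciesResponse`-style data frame with columns
#'   `effect` and `scale_km`.
#' @return A `SummaryStats` list: `n_species`, `mean_effect`, `sd_effect`,
#'   `mean_scale`, `sd_scale`, `n_positive`, `n_negative`, `n_zero`,
#'   `min_effect`, `max_effect`.
#' @export
summarize_effects <- function(responses) {
  if (nrow(responses) == 0) stop("empty response table")
  e <- responses$effect
  s <- responses$scale_km
  structure(list(
    n_species = length(e),
    mean_effect = mean(e),
    sd_effect = if (length(e) > 1) sd(e) else NA_real_,
    mean_scale = mean(s),
    sd_scale = if (length(s) > 1) sd(s) else NA_real_,
    n_positive = sum(e > 0),
    n_negative = sum(e < 0),
    n_zero = sum(e == 0),
    min_effect = min(e),
    max_effect = max(e)
  ), class = "SummaryStats")
}

#' @export
print.SummaryStats <- function(x, ...) {
  cat("Species analyzed:", x$n_species, "\n")
  cat(sprintf("  effect size: mean %.2f (SD %.2f), range [%.2f, %.2f]\n",
              x$mean_effect, x$sd_effect, x$min_effect, x$max_effect))
  cat(sprintf("  scale of effect: mean %.2f km (SD %.2f)\n",
              x$mean_scale, x$sd_scale))
  cat(sprintf("  %d positive / %d negative associations\n",
              x$n_positive, x$n_negative))
  invisible(x)
}

#' Packaged transcription fixtures
#'
#' `read_table1_fixture()` returns the published per-species effect sizes
#' and scales of effect (58 forest bird species; transcribed printed values,
#' not computed by this package). `read_model_table_fixture()` returns the
#' printed model-selection tables of the published trait analysis (model
#' label, K, AIC, delta AIC and Akaike weight per candidate model, by
#' table), used to validate the Akaike-weight arithmetic.
#'
#' @return Data frames; see column headers.
#' @export
read_table1_fixture <- function() {
  read.csv(system.file("extdata", "table1_responses.csv",
                       package = "urbanscape"))
}

#' @rdname read_table1_fixture
#' @export
read_model_table_fixture <- function() {
  read.csv(system.file("extdata", "model_tables.csv", package = "urbanscape"))
}

#' Default demonstration configuration
#'
#' A small configuration (200 locations, 12 species, 4 radii) for the full
#' pipeline; every entry can be overridden. All randomness is driven by
#' `seed`.
#'
#' @param seed integer master seed.
#' @return Named list of configuration entries.
#' @export
default_config <- function(seed = 1) {
  list(
    seed = seed,
    landscape = list(extent = 16000, cell_size = 100, urban_strength = 0.6,
                     forest_frac = 0.58, agri_frac = 0.2, autocorr_range = 10),
    design = list(n_locations = 200),
    radii = c(0.2, 0.5, 1, 2),
    species = list(n_species = 12, lambda_true = 0,
                   beta_weights = c(granivory = 0.5),
                   scale_weights = c(clutch_size = 0.4),
                   beta_mean = -0.36, beta_noise_sd = 0.1,
                   missing_rate = 0.1, alpha = 0),
    stage1 = list(predictors = c("urb", "forest", "agri", "elev_mean"),
                  delta_max = 2, cap = 15, min_locations = 5),
    dependency = list(alpha = 0.05, n_perm = 200),
    stage2 = list(delta_max = 2,
                  trait_cols = c("clutch_size", "fledglings", "wingspan",
                                 "granivory", "frugivory", "omnivory",
                                 "cavity_nesting", "resident"))
  )
}

#' Run the full pipeline
#'
#' simulate -> metrics -> forest-dependency filter -> stage 1 -> stage 2 ->
#' report, writing all artifacts (CSV/JSON/plain-text grids, a manifest with
#' seeds and a config hash, and a structured log) to `out_dir`. The manifest
#' seed fully determines every stochastic output: rerunning with the same
#' config yields identical numbers.
#'
#' @param config configuration list from [default_config()], or the path to
#'   a YAML file holding one.
#' @param out_dir output directory (created if needed).
#' @return Invisibly, a list with every intermediate object (`landscape`,
#'   `design`, `metrics`, `truth`, `detections`, `dependency`, `responses`,
#'   `summary`, `trait_fits`).
#' @export
run_pipeline <- function(config = default_config(), out_dir = tempfile("urbanscape_")) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  req <- c("seed", "landscape", "design", "radii", "species", "stage1", "stage2")
  missing_keys <- setdiff(req, names(config))
  if (length(missing_keys))
    stop("invalid config; missing keys: ", paste(missing_keys, collapse = ", "))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  logf <- file.path(out_dir, "pipeline.log")
  logmsg <- function(...) cat(format(Sys.time(), "%H:%M:%S"), ..., "\n",
                              file = logf, append = TRUE)

  seed <- config$seed
  lc <- config$landscape
  logmsg("generate_landscape")
  stack <- generate_landscape(extent = lc$extent, cell_size = lc$cell_size,
                              urban_strength = lc$urban_strength,
                              forest_frac = lc$forest_frac,
                              agri_frac = lc$agri_frac,
                              max_radius = max(config$radii) * 1000,
                              autocorr_range = lc$autocorr_range,
                              seed = seed)
  logmsg("place_count_locations")
  design <- place_count_locations(stack, config$design$n_locations,
                                  seed = seed + 1,
                                  margin = max(config$radii) * 1000)
  logmsg("assemble_metrics")
  metrics <- assemble_metrics(stack, design, config$radii)

  sp <- config$species
  logmsg("generate_traits_and_tree")
  tt <- generate_traits_and_tree(
    n_species = sp$n_species, lambda_true = sp$lambda_true,
    beta_weights = unlist(sp$beta_weights),
    scale_weights = unlist(sp$scale_weights),
    beta_mean = sp$beta_mean, beta_noise_sd = sp$beta_noise_sd,
    radii = config$radii, alpha = sp$alpha,
    missing_rate = sp$missing_rate, seed = seed + 2)
  logmsg("simulate_occurrences")
  detections <- simulate_occurrences(design, metrics, tt$truth, seed = seed + 3)

  logmsg("forest dependency")
  dep_cfg <- config$dependency %||% list(alpha = 0.05, n_perm = 200)
  dependency <- classify_forest_dependency(detections, metrics,
                                           alpha = dep_cfg$alpha,
                                           n_perm = dep_cfg$n_perm,
                                           seed = seed + 4)
  occ <- aggregate(detected ~ species_id, detections, sum)
  summary_tab <- data.frame(species_id = occ$species_id,
                            n_locations = occ$detected)
  elig <- eligibility_filter(summary_tab,
                             min_locations = config$stage1$min_locations %||% 30)
  keep_sp <- intersect(
    elig$species_id[elig$keep],
    dependency$species_id[dependency$classification == "forest-dependent"])
  logmsg("stage 1 on", length(keep_sp), "species")
  det1 <- detections[detections$species_id %in% keep_sp, ]
  if (nrow(det1) == 0) stop("no species pass the eligibility and dependency filters")
  responses <- fit_species_responses(det1, metrics,
                                     predictors = config$stage1$predictors,
                                     delta_max = config$stage1$delta_max,
                                     cap = config$stage1$cap)
  summ <- summarize_effects(responses)

  logmsg("phylogenetic screen + stage 2")
  eff_named <- setNames(responses$effect, responses$species_id)
  signal <- tryCatch(
    phylo_signal_screen(tt$traits, eff_named, tt$tree,
                        trait_cols = config$stage2$trait_cols),
    error = function(e) NULL)
  trait_fits <- tryCatch(
    list(effect = fit_trait_effects(responses, tt$traits, "effect",
                                    trait_cols = config$stage2$trait_cols,
                                    delta_max = config$stage2$delta_max),
         scale = fit_trait_effects(responses, tt$traits, "scale",
                                   trait_cols = config$stage2$trait_cols,
                                   delta_max = config$stage2$delta_max)),
    error = function(e) {
      logmsg("stage 2 skipped:", conditionMessage(e))
      NULL
    })

  # artifacts
  write_landscape(stack, file.path(out_dir, "landscape"))
  write_design(design, file.path(out_dir, "design.csv"))
  write_detections(detections, file.path(out_dir, "detections.csv"))
  write.csv(as.data.frame(metrics), file.path(out_dir, "metrics.csv"),
            row.names = FALSE)
  write.csv(dependency, file.path(out_dir, "dependency.csv"), row.names = FALSE)
  write.csv(as.data.frame(responses), file.path(out_dir, "responses.csv"),
            row.names = FALSE)
  ape::write.tree(tt$tree, file.path(out_dir, "tree.nwk"))
  write.csv(tt$traits, file.path(out_dir, "traits.csv"), row.names = FALSE)
  jsonlite::write_json(as.data.frame(tt$truth), file.path(out_dir, "truth.json"),
                       digits = NA)
  if (!is.null(signal))
    write.csv(signal, file.path(out_dir, "phylo_signal.csv"), row.names = FALSE)
  if (!is.null(trait_fits)) {
    write.csv(trait_fits$effect$effects,
              file.path(out_dir, "trait_effects_effect.csv"), row.names = FALSE)
    write.csv(trait_fits$scale$effects,
              file.path(out_dir, "trait_effects_scale.csv"), row.names = FALSE)
    write.csv(trait_fits$effect$fits$complete$table,
              file.path(out_dir, "model_table_effect_complete.csv"),
              row.names = FALSE)
  }
  cfg_json <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA)
  manifest <- list(
    package_version = as.character(utils::packageVersion("urbanscape")),
    seed = seed,
    config_hash = sum(utf8ToInt(as.character(cfg_json))),
    summary = unclass(summ))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  logmsg("done")

  invisible(list(landscape = stack, design = design, metrics = metrics,
                 traits = tt$traits, tree = tt$tree, truth = tt$truth,
                 detections = detections, dependency = dependency,
                 eligibility = elig, responses = responses, summary = summ,
                 signal = signal, trait_fits = trait_fits,
                 out_dir = out_dir))
}
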