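#' Pipeline configuration
#'
#' Bundles every tunable of the analysis with defaults encoding the
#' standard protocol: 5 km presence rarefaction, 100 km absence spacing
#' (one absence per 10,000 km2 neighbourhood), VIF threshold 5, 10
#' replicates of an 80/20 split, gating at AUC >= 0.9 and TSS >= 0.7,
#' equal-interval class bounds (0.25, 0.5, 0.75), change cutoff at the
#' moderate class, and two scenarios x two periods of SSP-style forcing.
#'
#' @param synthetic list: `world` ([synthetic_world_spec()]), `truth`
#'   ([truth_model()]), `n_presence`, `scenarios` (named list of
#'   `list(delta_T_C, precip_factor)`).
#' @param prepare list: `presence_min_dist_km`, `absence_min_dist_km`,
#'   `presence_buffer_km`, `n_absence` (`NULL` = number of presences).
#' @param screening list: `vif_threshold`.
#' @param modelling list: `algorithms`, `n_reps`, `train_frac`, `auc_min`,
#'   `tss_min`, `ensemble_weighting` (`"none"` or `"tss"`).
#' @param classification list: `bounds`, `cutoff_class`.
#' @param thornthwaite list: `linear_term_sign`.
#' @param seed master integer seed; stage seeds are derived from it.
#' @return a validated `pipeline_config` list.
#' @export
pipeline_config <- function(synthetic = NULL, prepare = NULL,
                            screening = NULL, modelling = NULL,
                            classification = NULL, thornthwaite = NULL,
                            seed = 42L) {
  defaults <- list(
    synthetic = list(
      world = synthetic_world_spec(grid_rows = 100, grid_cols = 160,
                                   seed = seed),
      truth = default_truth_model(),
      n_presence = 256L,
      scenarios = list(
        ssp245_2050 = list(delta_T_C = 1.8, precip_factor = 0.96),
        ssp245_2090 = list(delta_T_C = 2.8, precip_factor = 0.93),
        ssp585_2050 = list(delta_T_C = 2.3, precip_factor = 0.94),
        ssp585_2090 = list(delta_T_C = 4.5, precip_factor = 0.86)
      )
    ),
    prepare = list(presence_min_dist_km = 5, absence_min_dist_km = 100,
                   presence_buffer_km = 5, n_absence = NULL),
    screening = list(vif_threshold = 5),
    modelling = list(algorithms = SDM_ALGORITHMS, n_reps = 10L,
                     train_frac = 0.8, auc_min = 0.9, tss_min = 0.7,
                     ensemble_weighting = "none"),
    classification = list(bounds = c(0.25, 0.5, 0.75),
                          cutoff_class = "moderate"),
    thornthwaite = list(linear_term_sign = "canonical"),
    seed = as.integer(seed)
  )
  cfg <- defaults
  for (block in c("synthetic", "prepare", "screening", "modelling",
                  "classification", "thornthwaite")) {
    ov <- get(block)
    if (!is.null(ov)) {
      cfg[[block]] <- utils::modifyList(cfg[[block]], ov)
      # a supplied scenario set replaces the default wholesale (modifyList
      # would merge the two named lists)
      if (block == "synthetic" && !is.null(ov$scenarios)) {
        cfg$synthetic$scenarios <- ov$scenarios
      }
    }
  }
  validate_config(cfg)
  structure(cfg, class = "pipeline_config")
}

default_truth_model <- function() {
  # olive-like niche driven by the two factors such studies find dominant:
  # a strong lowland preference (frost/temperature limitation acting through
  # elevation) and a winter-precipitation requirement. The niche is sharply
  # defined on the logit scale (near-binary suitability) and the intercept
  # places it on roughly the lowest-elevation, wettest-winter twentieth of
  # the default world, the "single niche crop" regime.
  co <- c(elevation = -0.022, bio19 = 0.15)
  design_means <- c(elevation = 720, bio19 = 335)
  truth_model(co, intercept = -26 - sum(co * design_means))
}

validate_config <- function(cfg) {
  m <- cfg$modelling
  if (length(m$algorithms) == 0L) {
    stop("config error: empty algorithm list", call. = FALSE)
  }
  stopifnot(all(m$algorithms %in% SDM_ALGORITHMS),
            m$train_frac > 0, m$train_frac < 1,
            m$n_reps >= 1, m$auc_min <= 1, m$tss_min <= 1,
            m$ensemble_weighting %in% c("none", "tss"),
            cfg$screening$vif_threshold > 1,
            length(cfg$classification$bounds) == 3L,
            all(diff(cfg$classification$bounds) > 0))
  for (sc in cfg$synthetic$scenarios) {
    if (sc$precip_factor <= 0) {
      stop("config error: precip_factor must be positive", call. = FALSE)
    }
  }
  invisible(cfg)
}

#' Load a pipeline configuration from YAML
#'
#' Recognized top-level keys mirror the [pipeline_config()] arguments; the
#' `synthetic.world` and `synthetic.truth` blocks are plain maps converted
#' to [synthetic_world_spec()] / [truth_model()] objects.
#'
#' @param path YAML file path.
#' @return a `pipeline_config`.
#' @export
pipeline_config_from_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  syn <- y$synthetic
  if (!is.null(syn$world)) syn$world <- do.call(synthetic_world_spec, syn$world)
  if (!is.null(syn$truth)) {
    syn$truth <- truth_model(unlist(syn$truth$coefficients),
                             intercept = syn$truth$intercept %||% 0)
  }
  pipeline_config(synthetic = syn, prepare = y$prepare,
                  screening = y$screening, modelling = y$modelling,
                  classification = y$classification,
                  thornthwaite = y$thornthwaite,
                  seed = y$seed %||% 42L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Average several monthly climate stacks
#'
#' The multi-model (GCM-ensemble) mechanism: per-cell, per-month arithmetic
#' mean across aligned climate stacks.
#'
#' @param stacks list of climate normals, each `list(temp = 12 rasters,
#'   precip = 12 rasters)` on one grid.
#' @return one climate normals list of the same shape.
#' @export
average_climate_stacks <- function(stacks) {
  stopifnot(length(stacks) >= 1L)
  tmpl <- stacks[[1L]]$temp[[1L]]
  for (st in stacks) for (r in c(st$temp, st$precip)) check_aligned(tmpl, r)
  avg <- function(field) {
    lapply(stats::setNames(1:12, sprintf("m%02d", 1:12)), function(m) {
      new_like(tmpl, Reduce(`+`, lapply(stacks,
                                        function(st) st[[field]][[m]]$values)) /
                 length(stacks))
    })
  }
  list(temp = avg("temp"), precip = avg("precip"))
}

# environmental layer stack for one period: terrain + bioclim subset
period_layers <- function(normals, terrain, diurnal_range_C) {
  bio <- derive_bioclim_subset(normals$temp, normals$precip,
                               diurnal_range_C = diurnal_range_C)
  c(terrain, bio)
}

#' Run the full analysis pipeline on a synthetic world
#'
#' Executes simulate -> prepare -> screen -> fit -> gate -> ensemble ->
#' classify -> change -> aridity -> attribute for the reference period and
#' every configured scenario, optionally writing all artifacts (ASCII-grid
#' rasters, CSV tables, JSON report) under `out_dir`.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (`NULL` = no files written).
#' @param quiet suppress progress messages.
#' @return a `run_report` list with every intermediate and final product.
#' @export
run_all <- function(config, out_dir = NULL, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (!quiet) message(...)
  spec <- config$synthetic$world
  seed <- config$seed

  say("simulate: terrain, monthly normals, scenarios")
  terrain <- generate_terrain(spec)
  normals_ref <- generate_monthly_normals(spec, elevation = terrain$elevation)
  scenarios <- lapply(config$synthetic$scenarios, function(sc) {
    apply_scenario(normals_ref, sc$delta_T_C, sc$precip_factor)
  })
  layers_ref <- period_layers(normals_ref, terrain, spec$diurnal_range_C)
  mask <- new_like(layers_ref[[1L]],
                   matrix(1, spec$grid_rows, spec$grid_cols))
  areas <- cell_area_km2(mask)

  say("prepare: occurrences, rarefaction, pseudo-absences, covariates")
  truth <- config$synthetic$truth
  occ_raw <- sample_occurrences(truth, layers_ref,
                                n_presence = config$synthetic$n_presence,
                                seed = seed + 1L)
  occ <- rarefy(occ_raw, config$prepare$presence_min_dist_km,
                seed = seed + 2L, crs = mask$crs)
  n_abs <- config$prepare$n_absence %||% nrow(occ)
  abs_pts <- generate_pseudo_absences(
    mask, n_target = n_abs,
    min_dist_km = config$prepare$absence_min_dist_km,
    seed = seed + 3L, presences = occ,
    presence_buffer_km = config$prepare$presence_buffer_km)
  table <- build_feature_table(occ, abs_pts, layers_ref)

  say("screen: iterative VIF pruning at threshold ",
      config$screening$vif_threshold)
  all_vars <- names(layers_ref)
  screen <- iterative_prune(table[, all_vars, drop = FALSE],
                            threshold = config$screening$vif_threshold)
  vars <- screen$retained

  say("fit: ", length(config$modelling$algorithms), " algorithms x ",
      config$modelling$n_reps, " replicates")
  fits <- fit_all(table, vars, algorithms = config$modelling$algorithms,
                  n_reps = config$modelling$n_reps,
                  train_frac = config$modelling$train_frac, seed = seed + 4L)
  gates <- gate(fits$evals, auc_min = config$modelling$auc_min,
                tss_min = config$modelling$tss_min)
  kept_algs <- gates$algorithm[gates$kept]
  say("gate: kept ", paste(kept_algs, collapse = ", "))
  kept_scorers <- unlist(fits$scorers[kept_algs], recursive = FALSE)
  weights <- if (config$modelling$ensemble_weighting == "tss") {
    key <- paste(fits$evals$algorithm, fits$evals$replicate)
    tssv <- stats::setNames(fits$evals$tss, key)
    vapply(kept_scorers, function(sc) {
      unname(tssv[paste(sc$algorithm, sc$replicate_id)])
    }, numeric(1))
  } else NULL
  importance <- importance_table(fits$scorers[kept_algs], table,
                                 seed = seed + 5L)

  say("ensemble + classify: reference and ", length(scenarios), " scenarios")
  ens <- list(reference = ensemble_predict(kept_scorers, layers_ref,
                                           weights = weights))
  for (nm in names(scenarios)) {
    lay <- period_layers(scenarios[[nm]], terrain, spec$diurnal_range_C)
    ens[[nm]] <- ensemble_predict(kept_scorers, lay, weights = weights)
  }
  classmaps <- lapply(ens, classify_suitability,
                      bounds = config$classification$bounds)
  area_tabs <- lapply(classmaps, class_areas, cell_areas = areas)
  changemaps <- lapply(names(scenarios), function(nm) {
    change_map(classmaps$reference, classmaps[[nm]],
               cutoff_class = config$classification$cutoff_class)
  })
  names(changemaps) <- names(scenarios)
  change_tabs <- lapply(changemaps, change_areas, cell_areas = areas)

  say("aridity: Thornthwaite PET and UNEP AI per period")
  lats <- synthetic_latitudes(mask, spec$origin_lat)
  aridity <- lapply(c(list(reference = normals_ref), scenarios),
                    function(nrm) {
    pet <- thornthwaite_pet(nrm, lats,
                            linear_term_sign = config$thornthwaite$linear_term_sign)
    p_ann <- annual_precip(nrm$precip)
    ai <- unep_ai(p_ann, pet$annual_pet_mm)
    list(pet = pet, ai = ai$ai, undefined = ai$undefined,
         classes = classify_ai(ai$ai, undefined = ai$undefined))
  })

  say("attribute: frequencies across aridity classes, loss regressions")
  freq_tabs <- lapply(names(classmaps), function(nm) {
    suit <- suitable_mask(classmaps[[nm]])
    if (!any(suit)) {
      # a period can lose all suitable habitat; report an all-zero table
      tab <- data.frame(aridity_class = unname(ARIDITY_CLASSES),
                        label = names(ARIDITY_CLASSES),
                        km2 = 0, percent = NA_real_)
      attr(tab, "empty_suitable_mask") <- TRUE
      return(tab)
    }
    frequency_by_aridity(suit, aridity[[nm]]$classes, areas)
  })
  names(freq_tabs) <- names(classmaps)
  loss_fits <- lapply(names(scenarios), function(nm) {
    fit_loss_logistic(changemaps[[nm]], aridity[[nm]]$ai)
  })
  names(loss_fits) <- names(scenarios)

  report <- list(
    config = config,
    counts = list(
      n_presence_raw = nrow(occ_raw), n_presence = nrow(occ),
      n_absence = nrow(abs_pts), n_rows = nrow(table),
      n_dropped_nodata = attr(table, "n_dropped_nodata"),
      n_vars_screened = length(all_vars), n_vars_retained = length(vars)
    ),
    screen = screen, evals = fits$evals, gates = gates,
    importance = importance,
    ensemble = ens, classmaps = classmaps, area_tables = area_tabs,
    changemaps = changemaps, change_tables = change_tabs,
    aridity = aridity, frequency_tables = freq_tabs,
    loss_regressions = loss_fits,
    occurrences = occ, absences = abs_pts,
    seeds = seed + 0:5
  )
  class(report) <- "run_report"
  if (!is.null(out_dir)) write_run_report(report, out_dir)
  report
}

#' Write a run report's artifacts to disk
#'
#' Rasters go out as ASCII grids, tables as CSV, scalar results as JSON.
#'
#' @param report a `run_report` from [run_all()].
#' @param out_dir directory (created if needed).
#' @return invisibly, the directory.
#' @export
write_run_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(...) file.path(out_dir, ...)
  utils::write.csv(report$evals, fp("model_evaluations.csv"),
                   row.names = FALSE)
  utils::write.csv(report$gates, fp("gate_decisions.csv"), row.names = FALSE)
  utils::write.csv(report$screen$table, fp("vif_screen.csv"),
                   row.names = FALSE)
  utils::write.csv(report$importance, fp("variable_importance.csv"),
                   row.names = FALSE)
  utils::write.csv(cbind(report$occurrences, label = 1),
                   fp("presences.csv"), row.names = FALSE)
  utils::write.csv(cbind(report$absences, label = 0),
                   fp("absences.csv"), row.names = FALSE)
  for (nm in names(report$ensemble)) {
    write_ascii_grid(report$ensemble[[nm]],
                     fp(paste0("suitability_", nm, ".asc")))
    write_ascii_grid(report$classmaps[[nm]],
                     fp(paste0("classes_", nm, ".asc")))
    utils::write.csv(report$area_tables[[nm]],
                     fp(paste0("areas_", nm, ".csv")), row.names = FALSE)
    utils::write.csv(report$frequency_tables[[nm]],
                     fp(paste0("aridity_frequency_", nm, ".csv")),
                     row.names = FALSE)
    write_ascii_grid(report$aridity[[nm]]$classes,
                     fp(paste0("aridity_classes_", nm, ".asc")))
  }
  for (nm in names(report$changemaps)) {
    write_ascii_grid(report$changemaps[[nm]],
                     fp(paste0("change_", nm, ".asc")))
    utils::write.csv(report$change_tables[[nm]],
                     fp(paste0("change_areas_", nm, ".csv")),
                     row.names = FALSE)
  }
  loss <- lapply(report$loss_regressions, function(x) {
    x[c("beta", "se", "p_value", "odds_ratio", "pseudo_r2_pct", "auc",
        "n_cells", "n_loss")]
  })
  jsonlite::write_json(loss, fp("loss_regressions.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
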