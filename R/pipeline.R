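# End-to-end orchestration: read-or-simulate, transform, aggregate,
# variography with stability test, distribution indices, kriging and area
# classification, collocation; all outputs written as delimited text plus
# a JSON run manifest.

#' Default pipeline configuration
#'
#' Returns the full configuration list with every tunable of the pipeline
#' at its default. Any subset can be overridden via `...` or supplied from
#' a YAML file through [run_pipeline()].
#'
#' @param ... Named overrides of top-level entries.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    input = NULL,                 # path to a survey CSV; NULL = simulate
    seed = 1,
    n_years = 10,
    log_offset = 0.05,            # tons, see log_transform()
    lag_width = 2, n_lags = 25, angular_tol = 15,
    n_structures = 2,
    n_sim_envelope = 1000,
    stability_tolerance = 0.05,
    patch_d_along = 6, patch_d_across = 24, patch_min_share = 0.10,
    krige_radius_along = 12, krige_radius_across = 30,
    krige_min_neighbours = 4, krige_max_neighbours = 32,
    grid_resolution = 1,
    n_resamples = 1000,
    out_dir = NULL)
  over <- list(...)
  cfg[names(over)] <- over
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the full spatial-analysis pipeline
#'
#' Stages, in order: load or simulate the survey; log-transform biomass;
#' annual aggregation summaries and indicator-vs-log-biomass regressions;
#' per-species mean variogram on annually standardized log-biomass, its
#' simulation envelope and the interannual stability test; centre of
#' gravity, inertia and patches per species and year; ordinary kriging of
#' annual log-biomass (mean model when every year is stable, annual
#' models otherwise), average/variability maps and area classification;
#' pairwise collocation tables. All stochastic stages are seeded from
#' `config$seed`, so a rerun with the same configuration reproduces every
#' output bit for bit. When `config$out_dir` is set, each stage's table
#' is written as CSV along with a JSON manifest recording parameters and
#' output checksums.
#'
#' @param config A [pipeline_config()], a named list of overrides, or a
#'   path to a YAML file with the same fields.
#' @return A list of class `pipeline_result` with elements `dataset`,
#'   `summaries`, `regressions`, `variography`, `indices`, `patches`,
#'   `maps`, `classification`, `collocation` and `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!inherits(config, "pipeline_config")) {
    config <- do.call(pipeline_config, config)
  }
  cfg <- config
  dataset <- if (is.null(cfg$input)) {
    simulate_survey(simulation_spec(n_years = cfg$n_years, seed = cfg$seed))
  } else {
    read_survey(cfg$input)
  }
  azimuth <- dataset$design$transect_azimuth
  rec <- dataset$records
  rec$year_chr <- as.character(rec$year)

  ## aggregation ------------------------------------------------------
  summaries <- annual_summaries(dataset, c = cfg$log_offset)
  regressions <- do.call(rbind, lapply(dataset$species, function(sp) {
    s <- summaries[summaries$species == sp & is.finite(summaries$log_biomass), ]
    do.call(rbind, lapply(c("presence_area_pct", "mean_density_presence",
                            "selectivity"), function(metric) {
      if (sum(is.finite(s[[metric]])) < 3) return(NULL)
      ok <- is.finite(s[[metric]])
      r <- metric_vs_logbiomass(s[[metric]][ok], s$log_biomass[ok])
      data.frame(species = sp, metric = metric, slope = r$slope,
                 r2_adj = r$r2_adj, p_value = r$p_value)
    }))
  }))

  ## variography ------------------------------------------------------
  variography <- list()
  for (sp in dataset$species) {
    logb <- log_transform(rec[[sp]], cfg$log_offset)
    years_ok <- names(which(tapply(logb, rec$year_chr, stats::sd) > 0))
    sub <- rec$year_chr %in% years_ok
    mv <- mean_variogram(rec$x[sub], rec$y[sub], logb[sub],
                         rec$year_chr[sub], lag_width = cfg$lag_width,
                         n_lags = cfg$n_lags, angular_tol = cfg$angular_tol,
                         azimuth = azimuth, n_structures = cfg$n_structures)
    loc1 <- rec[rec$year_chr == years_ok[1], c("x", "y")]
    env <- variogram_envelope(mv$model, loc1, n_sim = cfg$n_sim_envelope,
                              seed = cfg$seed + 1000L,
                              lag_width = cfg$lag_width, n_lags = cfg$n_lags,
                              angular_tol = cfg$angular_tol,
                              azimuth = azimuth)
    std <- standardize_by_year(logb[sub], rec$year_chr[sub])
    ann <- lapply(years_ok, function(yr) {
      i <- rec$year_chr[sub] == yr
      empirical_variogram(rec$x[sub][i], rec$y[sub][i], std[i],
                          lag_width = cfg$lag_width, n_lags = cfg$n_lags,
                          angular_tol = cfg$angular_tol, azimuth = azimuth)
    })
    names(ann) <- years_ok
    stability <- test_annual_stability(ann, env, cfg$stability_tolerance)
    variography[[sp]] <- list(mean = mv, envelope = env, annual = ann,
                              stability = stability)
  }

  ## distribution indices ---------------------------------------------
  indices <- list(); patches <- list()
  for (sp in dataset$species) {
    for (yr in dataset$years) {
      v <- species_year(dataset, sp, yr)
      if (sum(v$values) <= 0) next
      g <- inertia(v$x, v$y, v$values)
      indices[[length(indices) + 1]] <- data.frame(
        species = sp, year = yr, cg_x = unname(g$cg["x"]),
        cg_y = unname(g$cg["y"]), inertia = g$inertia,
        ellipse_a = g$ellipse$a, ellipse_b = g$ellipse$b,
        ellipse_angle = g$ellipse$angle)
      ps <- identify_patches(v$x, v$y, v$values, cfg$patch_d_along,
                             cfg$patch_d_across, cfg$patch_min_share,
                             azimuth)
      p <- ps$patches
      p$species <- sp; p$year <- yr
      patches[[length(patches) + 1]] <- p
    }
  }
  indices <- do.call(rbind, indices)
  patches <- do.call(rbind, patches)

  ## EOF and pointwise CV ---------------------------------------------
  eof_cv <- list()
  for (sp in dataset$species) {
    mats <- t(sapply(dataset$years,
                     function(yr) species_year(dataset, sp, yr)$values))
    tot <- rowSums(mats)
    if (any(tot <= 0) || nrow(mats) < 2) next
    eof_cv[[sp]] <- list(eof = eof(mats, "relative"),
                         cv = pointwise_cv(mats / tot))
  }

  ## kriging and classification ---------------------------------------
  grid <- make_grid(rec$x, rec$y, cfg$grid_resolution,
                    dataset$design$domain_polygon)
  nbhd <- neighbourhood_spec(cfg$krige_radius_along, cfg$krige_radius_across,
                             cfg$krige_min_neighbours,
                             cfg$krige_max_neighbours)
  maps <- list(); classification <- list()
  for (sp in dataset$species) {
    stab <- variography[[sp]]$stability
    all_stable <- all(stab$stable)
    yearly <- list()
    for (yr in dataset$years) {
      v <- species_year(dataset, sp, yr)
      logb <- log_transform(v$values, cfg$log_offset)
      model <- if (all_stable || stats::sd(logb) == 0) {
        variography[[sp]]$mean$model
      } else {
        emp <- empirical_variogram(v$x, v$y, logb, lag_width = cfg$lag_width,
                                   n_lags = cfg$n_lags,
                                   angular_tol = cfg$angular_tol,
                                   azimuth = azimuth)
        tryCatch(fit_variogram_model(emp, n_structures = cfg$n_structures),
                 error = function(e) variography[[sp]]$mean$model)
      }
      yearly[[as.character(yr)]] <- krige(v$x, v$y, logb, model, grid, nbhd,
                                          azimuth)
    }
    maps[[sp]] <- yearly
    av <- average_variability_maps(yearly)
    classification[[sp]] <- classify_areas(av)
  }

  ## collocation -------------------------------------------------------
  pairs <- utils::combn(dataset$species, 2, simplify = FALSE)
  collocation <- do.call(rbind, lapply(seq_along(pairs), function(k) {
    collocation_table(dataset, pairs[[k]][1], pairs[[k]][2],
                      d_along = cfg$patch_d_along,
                      d_across = cfg$patch_d_across,
                      min_share = cfg$patch_min_share,
                      n_resamples = cfg$n_resamples,
                      seed = cfg$seed + 2000L + 100L * k)
  }))

  manifest <- list(package = "pelagostat",
                   version = as.character(utils::packageVersion("pelagostat")),
                   seed = cfg$seed,
                   parameters = unclass(cfg)[!vapply(cfg, is.null,
                                                     logical(1))],
                   species = dataset$species,
                   years = dataset$years,
                   n_records = nrow(rec))

  result <- structure(list(dataset = dataset, summaries = summaries,
                           regressions = regressions,
                           variography = variography, indices = indices,
                           patches = patches, eof_cv = eof_cv, maps = maps,
                           classification = classification,
                           collocation = collocation, manifest = manifest),
                      class = "pipeline_result")
  if (!is.null(cfg$out_dir)) write_pipeline_outputs(result, cfg$out_dir)
  result
}

# Write stage outputs as CSV plus a JSON manifest with md5 checksums.
write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(df, name) {
    path <- file.path(out_dir, paste0(name, ".csv"))
    utils::write.csv(df, path, row.names = FALSE)
    path
  }
  files <- c(wr(result$summaries, "summaries"),
             wr(result$regressions, "regressions"),
             wr(result$indices, "indices"),
             wr(result$patches, "patches"),
             wr(result$collocation, "collocation"))
  for (sp in names(result$classification)) {
    files <- c(files, wr(as.data.frame(result$classification[[sp]]),
                         paste0("classification_", sp)))
  }
  for (sp in names(result$variography)) {
    files <- c(files, wr(result$variography[[sp]]$stability,
                         paste0("stability_", sp)))
  }
  manifest <- result$manifest
  manifest$files <- lapply(stats::setNames(files, basename(files)),
                           function(f) unname(tools::md5sum(f)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("pelagostat pipeline result\n")
  print(x$dataset)
  cat(sprintf("  %d patches identified; %d collocation rows\n",
              nrow(x$patches), nrow(x$collocation)))
  stab <- do.call(rbind, lapply(names(x$variography), function(sp) {
    s <- x$variography[[sp]]$stability
    data.frame(species = sp, stable_years = sum(s$stable),
               years = nrow(s))
  }))
  print(stab)
  invisible(x)
}
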