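#' Project geographic coordinates to local nautical-mile coordinates
#'
#' Local equirectangular projection: one minute of latitude is one nautical
#' mile everywhere, and one minute of longitude is \code{cos(ref_lat)}
#' nautical miles. Adequate for study areas a few degrees across, which is
#' the scale of a shelf acoustic survey; all distances downstream are in nm.
#'
#' @param lon,lat Geographic coordinates (WGS84 degrees).
#' @param ref_lon,ref_lat Reference point mapped to the planar origin.
#' @return A two-column matrix with columns \code{x}, \code{y} in nautical
#'   miles.
#' @seealso [unproject_from_nm()] for the inverse.
#' @export
#' @examples
#' project_to_nm(4.5, 43.2, ref_lon = 4, ref_lat = 43)
project_to_nm <- function(lon, lat, ref_lon, ref_lat) {
  if (any(abs(lat) > 90) || any(abs(lon) > 180)) {
    stopf("lon/lat outside valid ranges")
  }
  cbind(x = (lon - ref_lon) * 60 * cos(ref_lat * pi / 180),
        y = (lat - ref_lat) * 60)
}

#' @rdname project_to_nm
#' @param x,y Planar coordinates in nautical miles.
#' @export
unproject_from_nm <- function(x, y, ref_lon, ref_lat) {
  cbind(lon = ref_lon + x / (60 * cos(ref_lat * pi / 180)),
        lat = ref_lat + y / 60)
}

#' Log transform of biomass densities
#'
#' Computes \code{log(biomass + c)}. Acoustic biomass densities are strongly
#' skewed with many zeros and a variance proportional to the mean; a log
#' transform with a small positive offset removes the proportionality effect
#' while keeping zeros finite. The offset defaults to 0.05 tons and is a
#' single global constant so log-biomasses stay comparable across species
#' and years.
#'
#' @param biomass Non-negative biomass values (tons per sampling unit).
#' @param c Positive offset in tons.
#' @return Log-transformed values; `inv_log_transform()` is the exact inverse.
#' @export
log_transform <- function(biomass, c = 0.05) {
  if (c <= 0) stopf("log-transform offset c must be > 0")
  if (any(biomass < 0, na.rm = TRUE)) stopf("negative biomass in log_transform")
  log(biomass + c)
}

#' @rdname log_transform
#' @param y Log-transformed values.
#' @export
inv_log_transform <- function(y, c = 0.05) exp(y) - c

#' Target strength of a pelagic fish from its length
#'
#' Standard 38 kHz target-strength/length relation for small pelagic
#' species, \code{TS = 20 log10(L) - 71.2} dB with L in cm. Used when
#' converting acoustic energies to biomass; provided here as a utility.
#'
#' @param length_cm Fish length in centimetres (> 0).
#' @return Target strength in dB.
#' @export
target_strength <- function(length_cm) {
  if (any(length_cm <= 0)) stopf("fish length must be positive")
  20 * log10(length_cm) - 71.2
}

#' Describe a parallel-transect acoustic survey design
#'
#' @param n_transects Number of parallel transects.
#' @param transect_spacing Distance between adjacent transects (nm).
#' @param edsu_length Length of the elementary sampling distance unit (nm).
#' @param transect_length Length of each transect (nm).
#' @param transect_azimuth Direction of travel along a transect, degrees
#'   clockwise from north. 0 means transects run south-north, so the
#'   along-transect coordinate is latitudinal.
#' @param domain_polygon Optional two-column matrix of planar (nm) vertices
#'   bounding the study area; defaults to the rectangle spanned by the
#'   transect layout.
#' @param grid_resolution Interpolation grid step (nm).
#' @return An object of class `survey_design`.
#' @export
survey_design <- function(n_transects = 9, transect_spacing = 12,
                          edsu_length = 1, transect_length = 31,
                          transect_azimuth = 0, domain_polygon = NULL,
                          grid_resolution = 1) {
  if (transect_spacing <= 0 || edsu_length <= 0 || grid_resolution <= 0) {
    stopf("spacing, EDSU length and grid resolution must all be positive")
  }
  if (n_transects < 1 || transect_length < edsu_length) {
    stopf("design needs >= 1 transect at least one EDSU long")
  }
  if (is.null(domain_polygon)) {
    w <- (n_transects - 1) * transect_spacing
    domain_polygon <- cbind(x = c(0, w, w, 0), y = c(0, 0, transect_length,
                                                     transect_length))
  }
  structure(list(n_transects = n_transects,
                 transect_spacing = transect_spacing,
                 edsu_length = edsu_length,
                 transect_length = transect_length,
                 transect_azimuth = transect_azimuth,
                 domain_polygon = domain_polygon,
                 grid_resolution = grid_resolution),
            class = "survey_design")
}

#' @export
print.survey_design <- function(x, ...) {
  cat(sprintf("Acoustic survey design: %d parallel transects, %g nm apart\n",
              x$n_transects, x$transect_spacing))
  cat(sprintf("  transect length %g nm, EDSU %g nm, azimuth %g deg\n",
              x$transect_length, x$edsu_length, x$transect_azimuth))
  invisible(x)
}

#' EDSU centre locations implied by a survey design
#'
#' EDSU (elementary sampling distance unit) centres are placed every
#' `edsu_length` nm along each transect, transects being parallel and
#' regularly spaced.
#'
#' @param design A [survey_design()].
#' @return Data frame with `x`, `y` (nm) and `transect_id`.
#' @export
design_locations <- function(design) {
  k <- floor(design$transect_length / design$edsu_length)
  along <- (seq_len(k) - 0.5) * design$edsu_length
  across <- (seq_len(design$n_transects) - 1) * design$transect_spacing
  a <- design$transect_azimuth * pi / 180
  grid <- expand.grid(along = along, across = across)
  data.frame(x = grid$across * cos(a) + grid$along * sin(a),
             y = -grid$across * sin(a) + grid$along * cos(a),
             transect_id = rep(seq_len(design$n_transects), each = k))
}

# Internal constructor shared by read_survey() and simulate_survey().
# `records` must already hold year, lon, lat, x, y, transect_id and one
# biomass column per species.
new_survey_dataset <- function(records, species, design, ref) {
  years <- sort(unique(records$year))
  rownames(records) <- NULL
  structure(list(records = records, species = species, years = years,
                 design = design, ref = ref),
            class = "survey_dataset")
}

validate_survey <- function(ds, min_per_year = 1) {
  rec <- ds$records
  for (sp in ds$species) {
    if (any(rec[[sp]] < 0)) stopf("negative biomass for species '%s'", sp)
  }
  key <- paste(rec$year, rec$lon, rec$lat)
  if (anyDuplicated(key)) stopf("duplicate (year, lon, lat) records")
  tab <- table(rec$year)
  if (any(tab < min_per_year)) {
    stopf("every year needs >= %d records", min_per_year)
  }
  invisible(ds)
}

#' Read an acoustic survey dataset from a delimited text file
#'
#' The file must contain a header with columns `year`, `lon`, `lat` and one
#' biomass column per species (tons per EDSU). Coordinates are projected to
#' local nautical-mile coordinates about the dataset centroid and transects
#' are inferred by clustering the across-transect coordinate: sorted
#' across-transect positions are split wherever the gap exceeds half the
#' design spacing.
#'
#' @param path Path to a CSV (or `sep`-delimited) file.
#' @param species Character vector naming the biomass columns; defaults to
#'   every column other than year/lon/lat.
#' @param design A [survey_design()]; defaults to the standard 9-transect,
#'   12-nm layout.
#' @param sep Field separator.
#' @return A `survey_dataset`: a list with a `records` data frame (year,
#'   lon, lat, x, y, transect_id, one column per species), the species and
#'   year lists, the design, and the projection reference.
#' @export
read_survey <- function(path, species = NULL, design = survey_design(),
                        sep = ",") {
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE)
  needed <- c("year", "lon", "lat")
  if (!all(needed %in% names(raw))) {
    stopf("missing required column(s): %s",
          paste(setdiff(needed, names(raw)), collapse = ", "))
  }
  if (is.null(species)) species <- setdiff(names(raw), needed)
  if (length(species) == 0) stopf("no biomass columns found")
  missing_sp <- setdiff(species, names(raw))
  if (length(missing_sp)) {
    stopf("missing species column(s): %s", paste(missing_sp, collapse = ", "))
  }
  ref <- c(lon = mean(raw$lon), lat = mean(raw$lat))
  xy <- project_to_nm(raw$lon, raw$lat, ref["lon"], ref["lat"])
  across <- along_across(xy[, 1], xy[, 2], design$transect_azimuth)[, "across"]
  rec <- data.frame(year = as.integer(raw$year), lon = raw$lon, lat = raw$lat,
                    x = xy[, 1], y = xy[, 2],
                    transect_id = infer_transects(across,
                                                  design$transect_spacing))
  for (sp in species) rec[[sp]] <- as.numeric(raw[[sp]])
  validate_survey(new_survey_dataset(rec, species, design, ref))
}

# Cluster across-transect coordinates into transects by splitting sorted
# positions at gaps wider than half the nominal spacing.
infer_transects <- function(across, spacing) {
  o <- order(across)
  gaps <- diff(across[o])
  id_sorted <- cumsum(c(1, gaps > spacing / 2))
  id <- integer(length(across))
  id[o] <- id_sorted
  id
}

#' @rdname read_survey
#' @param dataset A `survey_dataset`.
#' @export
write_survey <- function(dataset, path, sep = ",") {
  rec <- dataset$records
  out <- rec[, c("year", "lon", "lat", dataset$species), drop = FALSE]
  utils::write.table(out, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.survey_dataset <- function(x, ...) {
  cat(sprintf("Acoustic survey dataset: %d EDSU records, %d year(s), %d species\n",
              nrow(x$records), length(x$years), length(x$species)))
  cat("  species:", paste(x$species, collapse = ", "), "\n")
  cat("  years:  ", paste(x$years, collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.survey_dataset <- function(object, ...) {
  rec <- object$records
  out <- do.call(rbind, lapply(object$species, function(sp) {
    do.call(rbind, lapply(object$years, function(yr) {
      v <- rec[[sp]][rec$year == yr]
      data.frame(species = sp, year = yr, n_edsu = length(v),
                 total_biomass = sum(v),
                 presence_area_pct = 100 * mean(v > 0))
    }))
  }))
  rownames(out) <- NULL
  out
}

# Extract (x, y, value) for one species/year.
species_year <- function(dataset, species, year) {
  rec <- dataset$records[dataset$records$year == year, ]
  list(x = rec$x, y = rec$y, values = rec[[species]])
}
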