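# Writers for the synthetic generator's external formats and readers for the
# same formats as the ingest stage consumes them. Every writer embeds the
# generator version and seed as metadata so outputs are self-describing and
# byte-reproducible given (config, seed).

#' Write a region's neighborhoods as a GeoJSON FeatureCollection
#'
#' Emits the Mapping-Inequality-style dialect the ingest stage reads:
#' per-feature `neighborhood_id`, `city`, `holc_grade` and `area_km2`
#' properties with Polygon geometry, plus a top-level `generator` member
#' carrying version and seed.
#'
#' @param region A [make_region()] result.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_region_geojson <- function(region, path) {
  stopifnot(inherits(region, "holc_region"))
  nb <- region$neighborhoods
  features <- lapply(seq_len(nrow(nb)), function(i) {
    ring <- close_ring(nb$polygon[[i]])
    list(
      type = "Feature",
      properties = list(
        neighborhood_id = nb$neighborhood_id[i],
        city = nb$city[i],
        holc_grade = nb$holc_grade[i],
        area_km2 = round(nb$area_km2[i], 8)
      ),
      geometry = list(
        type = "Polygon",
        coordinates = list(lapply(seq_len(nrow(ring)), function(j) {
          c(round(ring[j, 1], 8), round(ring[j, 2], 8))
        }))
      )
    )
  })
  fc <- list(
    type = "FeatureCollection",
    generator = list(version = pkg_version_string(), seed = region$seed),
    features = features
  )
  writeLines(jsonlite::toJSON(fc, auto_unbox = TRUE, digits = NA), path)
  invisible(path)
}

#' Write / read an impervious-surface grid as ESRI ASCII
#'
#' The standard six-line ESRI ASCII header followed by row-major cell values
#' (top row first). The writer prepends one `#`-prefixed metadata line, which
#' [read_impervious_asc()] (and comment-aware readers generally) skip.
#'
#' @param grid A grid list as produced by [make_region()] (`$grid`).
#' @param path File path.
#' @param seed Seed recorded in the metadata line.
#' @return The path (writer) or a grid list (reader).
#' @export
write_impervious_asc <- function(grid, path, seed = NA_integer_) {
  lines <- c(
    sprintf("# %s seed=%s", pkg_version_string(), seed),
    sprintf("ncols %d", grid$nx),
    sprintf("nrows %d", grid$ny),
    sprintf("xllcorner %.8f", grid$x0),
    sprintf("yllcorner %.8f", grid$y0),
    sprintf("cellsize %.8f", grid$cell),
    "NODATA_value -9999",
    vapply(seq_len(grid$ny), function(r) {
      paste(format(grid$values[grid$ny - r + 1, ], trim = TRUE), collapse = " ")
    }, character(1))
  )
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_impervious_asc
#' @export
read_impervious_asc <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines)]
  if (length(lines) < 7) abort("not an ESRI ASCII grid: too few lines")
  hdr <- list()
  for (i in 1:6) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(kv) != 2) abort(sprintf("malformed ESRI ASCII header line: %s", lines[i]))
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
  }
  for (key in c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")) {
    if (is.null(hdr[[key]]) || is.na(hdr[[key]])) {
      abort(sprintf("ESRI ASCII header missing `%s`", key))
    }
  }
  nx <- as.integer(hdr$ncols)
  ny <- as.integer(hdr$nrows)
  vals <- as.numeric(unlist(strsplit(trimws(lines[-(1:6)]), "\\s+")))
  if (length(vals) != nx * ny) {
    abort(sprintf("ESRI ASCII body has %d values, expected %d",
                  length(vals), nx * ny))
  }
  values_top_first <- matrix(vals, nrow = ny, ncol = nx, byrow = TRUE)
  values <- values_top_first[ny:1, , drop = FALSE]
  if (!is.null(hdr$nodata_value)) {
    values[values == hdr$nodata_value] <- NA_real_
  }
  list(x0 = hdr$xllcorner, y0 = hdr$yllcorner, cell = hdr$cellsize,
       nx = nx, ny = ny, values = values)
}

#' Write observation records as an iNaturalist-export-style CSV
#'
#' Columns: `id, observed_on, latitude, longitude, scientific_name, clade,
#' quality_grade, establishment`. One `#`-prefixed metadata line precedes the
#' header; [read_observations_csv()] skips it.
#'
#' @param records Tibble from [simulate_observation_records()].
#' @param path Output path.
#' @param seed Seed recorded in the metadata line.
#' @return `path`, invisibly.
#' @export
write_records_csv <- function(records, path, seed = NA_integer_) {
  cols <- c("id", "observed_on", "latitude", "longitude",
            "scientific_name", "clade", "quality_grade", "establishment")
  missing_cols <- setdiff(cols, names(records))
  if (length(missing_cols)) {
    abort(paste0("records lack column(s): ", paste(missing_cols, collapse = ", ")))
  }
  con <- file(path, "w")
  on.exit(close(con), add = TRUE)
  writeLines(sprintf("# %s seed=%s", pkg_version_string(), seed), con)
  out <- records[cols]
  out$latitude <- round(out$latitude, 8)
  out$longitude <- round(out$longitude, 8)
  utils::write.csv(out, con, row.names = FALSE)
  invisible(path)
}

#' Serialize / load ground-truth parameters as JSON
#'
#' Round-trips a [truth_params()] object bit-identically. The reader validates
#' presence of every field and positivity of the SD terms, erroring with the
#' offending field's name.
#'
#' @param truth A [truth_params()] object.
#' @param path File path.
#' @return `path` (writer); a `truth_params` object (reader).
#' @export
write_truth <- function(truth, path) {
  stopifnot(inherits(truth, "truth_params"))
  payload <- list(
    generator = pkg_version_string(),
    b0 = truth$b0,
    b_grade = as.list(truth$b_grade),
    b_imp = truth$b_imp,
    sigma_city_intercept = truth$sigma_city_intercept,
    sigma_city_slope = truth$sigma_city_slope
  )
  if (!is.null(truth$city_effects)) {
    payload$city_effects <- truth$city_effects
  }
  writeLines(jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
                              dataframe = "columns"), path)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  payload <- tryCatch(
    jsonlite::fromJSON(path),
    error = function(e) abort(paste0("cannot parse truth file: ", conditionMessage(e)))
  )
  required <- c("b0", "b_grade", "b_imp",
                "sigma_city_intercept", "sigma_city_slope")
  for (field in required) {
    if (is.null(payload[[field]])) {
      abort(sprintf("truth file is missing field `%s`", field))
    }
  }
  for (field in c("sigma_city_intercept", "sigma_city_slope")) {
    if (payload[[field]] <= 0) {
      abort(sprintf("truth file field `%s` must be > 0", field))
    }
  }
  ce <- NULL
  if (!is.null(payload$city_effects)) {
    ce <- tibble::as_tibble(payload$city_effects)
  }
  truth_params(
    b0 = payload$b0,
    b_grade = unlist(payload$b_grade),
    b_imp = payload$b_imp,
    sigma_city_intercept = payload$sigma_city_intercept,
    sigma_city_slope = payload$sigma_city_slope,
    city_effects = ce
  )
}
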