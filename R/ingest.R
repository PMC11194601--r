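# Ingest: read the three external formats, apply the record filters in the
# fixed rule order, join records to neighborhoods, and build the
# analysis-ready per-neighborhood tables. Each filtering step accounts for
# every record (retained + dropped = input), captured in a filter report.

new_filter_report <- function(rule, n_input, n_dropped) {
  tibble::tibble(
    rule = rule,
    n_input = as.integer(n_input),
    n_dropped = as.integer(n_dropped),
    n_retained = as.integer(n_input - n_dropped)
  )
}

#' Retrieve the filter report attached to an ingest result
#'
#' Ingest functions return tibbles that carry a per-rule accounting table
#' (`rule`, `n_input`, `n_dropped`, `n_retained`) as an attribute; this
#' accessor extracts it.
#'
#' @param x A tibble returned by [filter_records()],
#'   [assign_points_to_polygons()], [city_clade_inclusion()],
#'   [read_holc_geojson()], or [richness_table()].
#' @return A tibble, or `NULL` when no report is attached.
#' @export
filter_report <- function(x) {
  attr(x, "filter_report", exact = TRUE)
}

#' Read HOLC neighborhood polygons from GeoJSON
#'
#' Accepts the Mapping Inequality dialect: a FeatureCollection whose features
#' carry a `holc_grade` property (and optionally `neighborhood_id`, `city`,
#' `area_km2`). Features with grades outside A-D are dropped and counted;
#' unreadable geometries are dropped with a warning; area is computed from the
#' polygon (planar shoelace, squared coordinate units) when absent.
#'
#' @param path Path to a GeoJSON file.
#' @return Neighborhood tibble (`neighborhood_id`, `city`, `holc_grade`,
#'   `area_km2`, `polygon` list-column) with a [filter_report()] attribute.
#' @export
read_holc_geojson <- function(path) {
  gj <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                 error = function(e) abort(paste0("cannot parse GeoJSON: ",
                                                  conditionMessage(e))))
  feats <- gj$features
  if (is.null(feats) || !length(feats)) abort("GeoJSON has no features")
  has_grade <- vapply(feats, function(f) !is.null(f$properties$holc_grade),
                      logical(1))
  if (!any(has_grade)) {
    abort("no feature carries a `holc_grade` property; not a HOLC file")
  }
  rows <- vector("list", length(feats))
  n_bad_grade <- 0L
  n_bad_geom <- 0L
  for (i in seq_along(feats)) {
    f <- feats[[i]]
    grade <- f$properties$holc_grade
    if (is.null(grade) || !grade %in% holc_grades) {
      n_bad_grade <- n_bad_grade + 1L
      next
    }
    ring <- tryCatch({
      if (is.null(f$geometry) || !identical(f$geometry$type, "Polygon")) {
        stop("geometry is not a Polygon")
      }
      coords <- f$geometry$coordinates[[1]] # exterior ring
      close_ring(do.call(rbind, lapply(coords, unlist)))
    }, error = function(e) NULL)
    if (is.null(ring)) {
      warn(sprintf("feature %d: unreadable geometry, dropped", i))
      n_bad_geom <- n_bad_geom + 1L
      next
    }
    area <- f$properties$area_km2
    if (is.null(area)) area <- polygon_area(ring)
    rows[[i]] <- tibble::tibble(
      neighborhood_id = f$properties$neighborhood_id %||% sprintf("feature_%04d", i),
      city = f$properties$city %||% "unknown",
      holc_grade = grade,
      area_km2 = as.numeric(area),
      polygon = list(ring)
    )
  }
  out <- bind_rows(rows)
  if (nrow(out) && anyDuplicated(out$neighborhood_id)) {
    out$neighborhood_id <- make.unique(out$neighborhood_id, sep = "_dup")
  }
  attr(out, "filter_report") <- bind_rows(
    new_filter_report("holc_grade_in_A_to_D", length(feats), n_bad_grade),
    new_filter_report("readable_geometry", length(feats) - n_bad_grade, n_bad_geom)
  )
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# clade labels (taxon or common names) normalized to the closed six-label set
default_clade_map <- c(
  bird = "bird", birds = "bird", aves = "bird",
  mammal = "mammal", mammals = "mammal", mammalia = "mammal",
  insect = "insect", insects = "insect", insecta = "insect",
  arachnid = "arachnid", arachnids = "arachnid", arachnida = "arachnid",
  reptile = "reptile", reptiles = "reptile", reptilia = "reptile",
  amphibian = "amphibian", amphibians = "amphibian", amphibia = "amphibian"
)

#' Read observation records from an iNaturalist-export-like CSV
#'
#' Parses dates, normalizes clade labels to the closed six-label set
#' (`bird, mammal, insect, arachnid, reptile, amphibian`), and maps the
#' `establishment` column to the tri-state `native` flag
#' (`native` / `introduced` / `unknown`). Rows with unparseable dates,
#' out-of-range coordinates, or unmappable clades are dropped and counted.
#'
#' @param path Path to a CSV with a header row; `#`-prefixed lines are
#'   skipped.
#' @param column_map Named character vector mapping required field names
#'   (`id`, `observed_on`, `latitude`, `longitude`, `scientific_name`,
#'   `clade`, `quality_grade`, `establishment`) to the file's column names;
#'   defaults to the identity mapping.
#' @return Record tibble (`record_id`, `observed_on`, `latitude`,
#'   `longitude`, `species`, `clade`, `quality`, `native`) with a
#'   [filter_report()] attribute.
#' @export
read_observations_csv <- function(path, column_map = NULL) {
  required <- c("id", "observed_on", "latitude", "longitude",
                "scientific_name", "clade", "quality_grade", "establishment")
  cmap <- stats::setNames(required, required)
  if (!is.null(column_map)) cmap[names(column_map)] <- column_map
  raw <- readr::read_csv(path, comment = "#", show_col_types = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  missing_cols <- setdiff(unname(cmap), names(raw))
  if (length(missing_cols)) {
    abort(paste0("CSV is missing required column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  rec <- tibble::tibble(
    record_id = raw[[cmap[["id"]]]],
    observed_on = suppressWarnings(as.Date(raw[[cmap[["observed_on"]]]])),
    latitude = suppressWarnings(as.numeric(raw[[cmap[["latitude"]]]])),
    longitude = suppressWarnings(as.numeric(raw[[cmap[["longitude"]]]])),
    species = raw[[cmap[["scientific_name"]]]],
    clade_raw = tolower(trimws(raw[[cmap[["clade"]]]])),
    quality = raw[[cmap[["quality_grade"]]]],
    establishment = tolower(trimws(raw[[cmap[["establishment"]]]]))
  )
  n0 <- nrow(rec)
  rec <- rec[!is.na(rec$observed_on), ]
  n1 <- nrow(rec)
  rec <- rec[!is.na(rec$latitude) & !is.na(rec$longitude), ]
  n2 <- nrow(rec)
  rec$clade <- unname(default_clade_map[rec$clade_raw])
  ok_clade <- !is.na(rec$clade)
  rec <- rec[ok_clade, ]
  out <- rec %>%
    mutate(native = dplyr::case_when(
      .data$establishment == "native" ~ "native",
      .data$establishment == "introduced" ~ "introduced",
      TRUE ~ "unknown"
    )) %>%
    select("record_id", "observed_on", "latitude", "longitude",
           "species", "clade", "quality", "native")
  attr(out, "filter_report") <- bind_rows(
    new_filter_report("parseable_date", n0, n0 - n1),
    new_filter_report("numeric_coordinates", n1, n1 - n2),
    new_filter_report("known_clade", n2, n2 - nrow(out))
  )
  out
}

#' Apply the record-quality filters in fixed order
#'
#' Rule order: research-grade quality, then species name present, then
#' observation date inside the half-open window
#' `[window_start, window_end)`. The default window is the five study years
#' 2017-2021.
#'
#' @param records Record tibble (see [read_observations_csv()]).
#' @param window_start,window_end `Date` bounds of the study window;
#'   `window_end` is exclusive.
#' @return Filtered tibble with a [filter_report()] attribute (one row per
#'   rule; `retained + dropped = input` at every step).
#' @export
filter_records <- function(records,
                           window_start = as.Date("2017-01-01"),
                           window_end = as.Date("2022-01-01")) {
  window_start <- as.Date(window_start)
  window_end <- as.Date(window_end)
  if (window_end <= window_start) {
    abort("`window_end` must be after `window_start`")
  }
  n0 <- nrow(records)
  keep_q <- !is.na(records$quality) & tolower(records$quality) == "research"
  r1 <- records[keep_q, ]
  keep_sp <- !is.na(r1$species) & nzchar(trimws(r1$species))
  r2 <- r1[keep_sp, ]
  keep_d <- !is.na(r2$observed_on) &
    r2$observed_on >= window_start & r2$observed_on < window_end
  out <- r2[keep_d, ]
  attr(out, "filter_report") <- bind_rows(
    new_filter_report("research_grade", n0, n0 - nrow(r1)),
    new_filter_report("species_present", nrow(r1), nrow(r1) - nrow(r2)),
    new_filter_report("date_window", nrow(r2), nrow(r2) - nrow(out))
  )
  out
}

#' Assign observation records to neighborhood polygons
#'
#' Point-in-polygon containment by even-odd ray casting, boundary inclusive.
#' When polygons overlap (or a point sits on a shared boundary), the
#' neighborhood with the lexicographically lowest id wins and a warning is
#' issued. Records falling outside every polygon are dropped and counted.
#'
#' @param records Record tibble with `longitude`/`latitude` (planar frame
#'   matching the polygons).
#' @param neighborhoods Neighborhood tibble with a `polygon` list-column.
#' @return Records with a `neighborhood_id` column, plus a [filter_report()]
#'   attribute and an `n_unassigned` attribute.
#' @export
assign_points_to_polygons <- function(records, neighborhoods) {
  if (!nrow(neighborhoods)) abort("no neighborhoods to assign to")
  ord <- order(neighborhoods$neighborhood_id)
  nb <- neighborhoods[ord, ]
  assigned <- rep(NA_character_, nrow(records))
  multi_hit <- FALSE
  for (i in seq_len(nrow(nb))) {
    ring <- nb$polygon[[i]]
    bb <- ring_bbox(ring)
    cand <- which(records$longitude >= bb["xmin"] & records$longitude <= bb["xmax"] &
                  records$latitude >= bb["ymin"] & records$latitude <= bb["ymax"])
    if (!length(cand)) next
    inside <- points_in_ring(records$longitude[cand], records$latitude[cand], ring)
    hit <- cand[inside]
    already <- !is.na(assigned[hit])
    if (any(already)) multi_hit <- TRUE
    hit <- hit[!already] # first-by-id wins
    assigned[hit] <- nb$neighborhood_id[i]
  }
  if (multi_hit) {
    warn("some records fall in more than one polygon; lowest neighborhood_id kept")
  }
  n_unassigned <- sum(is.na(assigned))
  out <- records[!is.na(assigned), ]
  out$neighborhood_id <- assigned[!is.na(assigned)]
  attr(out, "filter_report") <-
    new_filter_report("inside_a_polygon", nrow(records), n_unassigned)
  attr(out, "n_unassigned") <- n_unassigned
  out
}

#' Apply the city-inclusion rule
#'
#' A city is retained only when every HOLC grade x clade cell has at least
#' `min_per_cell` records (the default 5 mirrors the study's inclusion rule);
#' all records of dropped cities are removed.
#'
#' @param records Records with `neighborhood_id` (see
#'   [assign_points_to_polygons()]).
#' @param neighborhoods Neighborhood tibble (`neighborhood_id`, `city`,
#'   `holc_grade`).
#' @param min_per_cell Minimum records per grade-by-clade cell.
#' @return Records of retained cities, with attributes `retained_cities`,
#'   `cell_counts` (per-city diagnostics) and a [filter_report()].
#' @export
city_clade_inclusion <- function(records, neighborhoods, min_per_cell = 5) {
  joined <- records %>%
    left_join(select(neighborhoods, "neighborhood_id", "city", "holc_grade"),
              by = "neighborhood_id")
  grades <- sort(unique(neighborhoods$holc_grade))
  cells <- joined %>%
    count(.data$city, .data$holc_grade, .data$clade) %>%
    tidyr::complete(city = unique(neighborhoods$city),
                    holc_grade = grades,
                    clade = holc_clades,
                    fill = list(n = 0L))
  keep <- cells %>%
    group_by(.data$city) %>%
    summarise(ok = all(.data$n >= min_per_cell), .groups = "drop")
  retained <- keep$city[keep$ok]
  if (!length(retained)) {
    bad <- cells %>% filter(.data$n < min_per_cell)
    abort(paste0(
      "no city satisfies the inclusion rule (>= ", min_per_cell,
      " records per grade x clade cell); deficient cells:\n",
      paste(utils::capture.output(print(as.data.frame(bad))), collapse = "\n")
    ))
  }
  out <- joined %>%
    filter(.data$city %in% retained) %>%
    select(-"city", -"holc_grade")
  attr(out, "retained_cities") <- sort(retained)
  attr(out, "cell_counts") <- cells
  attr(out, "filter_report") <-
    new_filter_report("city_inclusion", nrow(records), nrow(records) - nrow(out))
  out
}

#' Zonal mean of a raster over a polygon
#'
#' Mean of the cells whose centers fall inside the polygon. When no cell
#' center falls inside (sliver polygons), the value of the cell nearest the
#' polygon centroid is used and a warning is issued.
#'
#' @param grid Grid list (`x0`, `y0`, `cell`, `nx`, `ny`, `values`) as read
#'   by [read_impervious_asc()]; `values` row 1 is the bottom row.
#' @param polygon Two-column vertex matrix in the grid's planar frame.
#' @param quiet Suppress the sliver-polygon warning.
#' @return Mean cell value (numeric scalar).
#' @export
zonal_mean_impervious <- function(grid, polygon, quiet = FALSE) {
  ring <- close_ring(polygon)
  bb <- ring_bbox(ring)
  gx <- grid$x0 + (seq_len(grid$nx) - 0.5) * grid$cell
  gy <- grid$y0 + (seq_len(grid$ny) - 0.5) * grid$cell
  if (bb["xmax"] < grid$x0 || bb["xmin"] > grid$x0 + grid$nx * grid$cell ||
      bb["ymax"] < grid$y0 || bb["ymin"] > grid$y0 + grid$ny * grid$cell) {
    abort("polygon lies entirely outside the grid extent")
  }
  jx <- which(gx >= bb["xmin"] - grid$cell & gx <= bb["xmax"] + grid$cell)
  jy <- which(gy >= bb["ymin"] - grid$cell & gy <= bb["ymax"] + grid$cell)
  pts <- expand.grid(x = gx[jx], y = gy[jy])
  inside <- if (nrow(pts)) points_in_ring(pts$x, pts$y, ring) else logical()
  if (any(inside)) {
    idx <- cbind(match(pts$y[inside], gy), match(pts$x[inside], gx))
    return(mean(grid$values[idx], na.rm = TRUE))
  }
  if (!quiet) warn("no cell center inside polygon; using nearest cell to centroid")
  ctr <- polygon_centroid(ring)
  ix <- which.min(abs(gx - ctr[1]))
  iy <- which.min(abs(gy - ctr[2]))
  grid$values[iy, ix]
}

#' Per-neighborhood species richness table
#'
#' Counts distinct species per neighborhood under a subset rule, together
#' with the neighborhood's record count under that subset. Neighborhoods with
#' zero qualifying records are excluded (the model's effort offset requires
#' at least one observation) and counted in the report.
#'
#' @param records Records with `neighborhood_id`.
#' @param neighborhoods Neighborhood tibble; its covariates are carried into
#'   the result.
#' @param subset One of `"all"`, `"native"`, `"nonnative"`, or a clade name
#'   (`"bird"`, `"mammal"`, `"insect"`, `"arachnid"`, `"reptile"`,
#'   `"amphibian"`). Records with unknown native status count toward `"all"`
#'   but neither native-status subset.
#' @return Tibble (`neighborhood_id`, `city`, `holc_grade`, `area_km2`,
#'   `impervious`, `richness`, `n_obs`) with a [filter_report()] attribute
#'   counting excluded zero-observation neighborhoods.
#' @export
richness_table <- function(records, neighborhoods, subset = "all") {
  sub <- subset_records(records, subset)
  tab <- sub %>%
    group_by(.data$neighborhood_id) %>%
    summarise(richness = n_distinct(.data$species), n_obs = n(),
              .groups = "drop")
  nb_cols <- intersect(c("neighborhood_id", "city", "holc_grade",
                         "area_km2", "impervious"), names(neighborhoods))
  out <- neighborhoods[nb_cols] %>%
    dplyr::inner_join(tab, by = "neighborhood_id") %>%
    arrange(.data$neighborhood_id)
  n_zero <- nrow(neighborhoods) - nrow(out)
  attr(out, "filter_report") <-
    new_filter_report("has_observations", nrow(neighborhoods), n_zero)
  attr(out, "subset") <- subset
  out
}

subset_records <- function(records, subset) {
  valid <- c("all", "native", "nonnative", holc_clades)
  if (length(subset) != 1 || !subset %in% valid) {
    abort(paste0("unknown subset `", paste(subset, collapse = ","),
                 "`; use one of: ", paste(valid, collapse = ", ")))
  }
  if (subset == "all") {
    records
  } else if (subset == "native") {
    filter(records, .data$native == "native")
  } else if (subset == "nonnative") {
    filter(records, .data$native == "introduced")
  } else {
    filter(records, .data$clade == subset)
  }
}
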