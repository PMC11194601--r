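#' Configuration for a synthetic HOLC-like study region
#'
#' Describes a set of cities, each containing rectangular neighborhoods of
#' every HOLC grade, together with an impervious-surface raster. Defaults
#' emulate the scale of the four-city California study system the package is
#' designed around: four cities with 44 graded neighborhoods each
#' (11 per grade), grade-ordered urban intensity, and heavy-tailed
#' per-neighborhood observation effort.
#'
#' @param n_cities Number of cities (>= 1).
#' @param grades Ordered character vector of HOLC grades; `"A"` is always the
#'   reference ("greenlined") grade and `"D"` the "redlined" grade.
#' @param neighborhoods_per_grade_per_city Count of neighborhoods of each
#'   grade in each city (>= 1).
#' @param area_range_km2 Length-2 positive interval from which neighborhood
#'   areas are drawn uniformly (km^2).
#' @param impervious_by_grade Named numeric vector (one entry per grade) of
#'   mean impervious-surface percentages, each in \[0, 100\]. The default is
#'   grade-ordered: redlined neighborhoods are the most paved.
#' @param impervious_sd Between-neighborhood SD (percentage points) around the
#'   grade mean.
#' @param grid_cell_km Side length of one impervious raster cell (km).
#' @param effort_mean,effort_dispersion Mean and negative-binomial size of the
#'   per-neighborhood observation-effort distribution used for model-mode
#'   simulation (see [simulate_richness()]); effort is floored at 1.
#' @return A `region_config` list.
#' @seealso [make_region()]
#' @export
region_config <- function(n_cities = 4,
                          grades = c("A", "B", "C", "D"),
                          neighborhoods_per_grade_per_city = 11,
                          area_range_km2 = c(0.5, 3),
                          impervious_by_grade = c(A = 30, B = 45, C = 60, D = 75),
                          impervious_sd = 3,
                          grid_cell_km = 0.25,
                          effort_mean = 60,
                          effort_dispersion = 2) {
  if (length(n_cities) != 1 || n_cities < 1 || n_cities != round(n_cities)) {
    abort("`n_cities` must be a positive integer")
  }
  if (length(grades) < 1 || anyDuplicated(grades)) {
    abort("`grades` must be distinct labels")
  }
  if (neighborhoods_per_grade_per_city < 1 ||
      neighborhoods_per_grade_per_city != round(neighborhoods_per_grade_per_city)) {
    abort("`neighborhoods_per_grade_per_city` must be a positive integer")
  }
  if (length(area_range_km2) != 2 || any(area_range_km2 <= 0) ||
      diff(area_range_km2) < 0) {
    abort("`area_range_km2` must be a positive non-degenerate interval")
  }
  if (!all(grades %in% names(impervious_by_grade))) {
    abort("`impervious_by_grade` must name every grade")
  }
  if (any(impervious_by_grade < 0) || any(impervious_by_grade > 100)) {
    abort("`impervious_by_grade` means must lie in [0, 100]")
  }
  if (grid_cell_km <= 0) abort("`grid_cell_km` must be positive")
  if (effort_mean < 1 || effort_dispersion <= 0) {
    abort("effort parameters must be positive (mean >= 1)")
  }
  structure(
    list(
      n_cities = as.integer(n_cities),
      grades = as.character(grades),
      neighborhoods_per_grade_per_city = as.integer(neighborhoods_per_grade_per_city),
      area_range_km2 = as.numeric(area_range_km2),
      impervious_by_grade = impervious_by_grade[grades],
      impervious_sd = impervious_sd,
      grid_cell_km = grid_cell_km,
      effort_mean = effort_mean,
      effort_dispersion = effort_dispersion
    ),
    class = "region_config"
  )
}

#' Generate a synthetic study region
#'
#' Lays out non-overlapping rectangular neighborhood polygons on a per-city
#' grid, draws each neighborhood's area, grade, impervious surface and
#' observation effort, and rasterizes impervious cover onto an ESRI-ASCII-style
#' grid. All coordinates are planar kilometres (written as longitude/latitude
#' columns for format compatibility).
#'
#' @param config A [region_config()].
#' @param seed Integer seed; the region is a pure function of
#'   `(config, seed)`.
#' @return A `holc_region` list with elements `neighborhoods` (tibble with a
#'   `polygon` list-column of closed rings), `grid` (impervious raster), and
#'   the `config`/`seed` used.
#' @examples
#' region <- make_region(region_config(n_cities = 1,
#'   neighborhoods_per_grade_per_city = 2), seed = 1)
#' region$neighborhoods
#' @export
make_region <- function(config = region_config(), seed = 1L) {
  stopifnot(inherits(config, "region_config"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))

  grades <- config$grades
  n_per <- config$neighborhoods_per_grade_per_city
  n_city_nb <- length(grades) * n_per
  slot_km <- sqrt(max(config$area_range_km2)) * 1.35
  ncol_slots <- ceiling(sqrt(n_city_nb))
  nrow_slots <- ceiling(n_city_nb / ncol_slots)
  city_span_x <- ncol_slots * slot_km + slot_km # gap between cities

  rows <- vector("list", config$n_cities)
  for (ci in seq_len(config$n_cities)) {
    city <- sprintf("city_%d", ci)
    grade_of_slot <- sample(rep(grades, n_per))
    x_city <- (ci - 1) * city_span_x
    nb <- vector("list", n_city_nb)
    for (k in seq_len(n_city_nb)) {
      slot_col <- (k - 1) %% ncol_slots
      slot_row <- (k - 1) %/% ncol_slots
      area <- runif(1, config$area_range_km2[1], config$area_range_km2[2])
      aspect <- runif(1, 0.7, 1.4)
      w <- min(sqrt(area * aspect), slot_km * 0.96)
      h <- area / w
      if (h > slot_km * 0.96) {
        h <- slot_km * 0.96
        w <- area / h
      }
      x0 <- x_city + slot_col * slot_km + runif(1, 0, slot_km - w)
      y0 <- slot_row * slot_km + runif(1, 0, slot_km - h)
      grade <- grade_of_slot[k]
      nb[[k]] <- tibble::tibble(
        neighborhood_id = sprintf("%s_%s%02d", city, grade,
                                  sum(grade_of_slot[seq_len(k)] == grade)),
        city = city,
        holc_grade = grade,
        area_km2 = w * h,
        imp_target = min(99, max(1,
          config$impervious_by_grade[[grade]] + rnorm(1, 0, config$impervious_sd))),
        polygon = list(rbind(
          c(x0, y0), c(x0 + w, y0), c(x0 + w, y0 + h), c(x0, y0 + h), c(x0, y0)
        ))
      )
    }
    rows[[ci]] <- bind_rows(nb)
  }
  neighborhoods <- bind_rows(rows) %>% arrange(.data$neighborhood_id)

  # per-neighborhood observation effort for model-mode simulation
  neighborhoods$n_obs <- pmax(
    1L,
    stats::rnbinom(nrow(neighborhoods),
                   mu = config$effort_mean, size = config$effort_dispersion)
  )

  grid <- rasterize_impervious(neighborhoods, config$grid_cell_km)
  neighborhoods$impervious <- vapply(
    neighborhoods$polygon,
    function(p) zonal_mean_impervious(grid, p, quiet = TRUE),
    numeric(1)
  )
  neighborhoods <- select(neighborhoods, -"imp_target") %>%
    select("neighborhood_id", "city", "holc_grade", "area_km2",
           "impervious", "n_obs", "polygon")

  structure(
    list(neighborhoods = neighborhoods, grid = grid,
         config = config, seed = as.integer(seed)),
    class = "holc_region"
  )
}

#' @export
print.holc_region <- function(x, ...) {
  cat(sprintf(
    "<holc_region> %d neighborhoods, %d cities, grades %s (seed %d)\n",
    nrow(x$neighborhoods), length(unique(x$neighborhoods$city)),
    paste(x$config$grades, collapse = ","), x$seed
  ))
  print(x$neighborhoods, ...)
  invisible(x)
}

# Background (non-neighborhood) cells carry a low impervious value so zonal
# means over polygons are dominated by neighborhood cover.
rasterize_impervious <- function(neighborhoods, cell, background = 5) {
  bb <- do.call(rbind, lapply(neighborhoods$polygon, ring_bbox))
  x0 <- floor(min(bb[, "xmin"]) / cell) * cell - cell
  y0 <- floor(min(bb[, "ymin"]) / cell) * cell - cell
  nx <- ceiling((max(bb[, "xmax"]) - x0) / cell) + 1
  ny <- ceiling((max(bb[, "ymax"]) - y0) / cell) + 1
  values <- matrix(background, nrow = ny, ncol = nx)
  cx <- x0 + (seq_len(nx) - 0.5) * cell
  cy <- y0 + (seq_len(ny) - 0.5) * cell
  for (i in seq_len(nrow(neighborhoods))) {
    ring <- neighborhoods$polygon[[i]]
    bbx <- ring_bbox(ring)
    jx <- which(cx >= bbx["xmin"] - cell & cx <= bbx["xmax"] + cell)
    jy <- which(cy >= bbx["ymin"] - cell & cy <= bbx["ymax"] + cell)
    if (!length(jx) || !length(jy)) next
    pts <- expand.grid(x = cx[jx], y = cy[jy])
    inside <- points_in_ring(pts$x, pts$y, ring)
    if (!any(inside)) next
    val <- pmin(100, pmax(0,
      neighborhoods$imp_target[i] + runif(sum(inside), -1, 1)))
    idx <- cbind(
      match(pts$y[inside], cy),
      match(pts$x[inside], cx)
    )
    values[idx] <- val
  }
  list(x0 = x0, y0 = y0, cell = cell, nx = nx, ny = ny, values = values)
}

# Save/restore the global RNG state so generators are pure in (config, seed).
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
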