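test_that("GeoJSON written by the generator reads back faithfully", {
  region <- tiny_region(seed = 2)
  path <- withr::local_tempfile(fileext = ".geojson")
  write_region_geojson(region, path)
  nb <- read_holc_geojson(path)
  expect_equal(nrow(nb), 4)
  expect_setequal(nb$holc_grade, c("A", "B", "C", "D"))
  expect_equal(sort(nb$neighborhood_id),
               sort(region$neighborhoods$neighborhood_id))
  expect_equal(nb$area_km2[order(nb$neighborhood_id)],
               region$neighborhoods$area_km2[
                 order(region$neighborhoods$neighborhood_id)],
               tolerance = 1e-6)
})

test_that("features with out-of-set grades are dropped and counted", {
  gj <- list(
    type = "FeatureCollection",
    features = list(
      list(type = "Feature",
           properties = list(neighborhood_id = "n1", city = "x", holc_grade = "A"),
           geometry = list(type = "Polygon",
                           coordinates = list(list(c(0, 0), c(1, 0), c(1, 1),
                                                   c(0, 1), c(0, 0))))),
      list(type = "Feature",
           properties = list(neighborhood_id = "n2", city = "x", holc_grade = "E"),
           geometry = list(type = "Polygon",
                           coordinates = list(list(c(2, 0), c(3, 0), c(3, 1),
                                                   c(2, 1), c(2, 0)))))
    )
  )
  path <- withr::local_tempfile(fileext = ".geojson")
  writeLines(jsonlite::toJSON(gj, auto_unbox = TRUE), path)
  nb <- read_holc_geojson(path)
  expect_equal(nb$neighborhood_id, "n1")
  rep <- filter_report(nb)
  expect_equal(rep$n_dropped[rep$rule == "holc_grade_in_A_to_D"], 1L)
})

test_that("area falls back to planar polygon area when the property is absent", {
  gj <- list(
    type = "FeatureCollection",
    features = list(
      list(type = "Feature",
           properties = list(holc_grade = "B"),
           geometry = list(type = "Polygon",
                           coordinates = list(list(c(0, 0), c(1, 0), c(1, 1),
                                                   c(0, 1), c(0, 0)))))
    )
  )
  path <- withr::local_tempfile(fileext = ".geojson")
  writeLines(jsonlite::toJSON(gj, auto_unbox = TRUE), path)
  nb <- read_holc_geojson(path)
  expect_equal(nb$area_km2, 1)
  expect_match(nb$neighborhood_id, "feature_")
})

test_that("a file without holc_grade anywhere is a format error", {
  gj <- list(type = "FeatureCollection",
             features = list(list(type = "Feature",
                                  properties = list(name = "x"),
                                  geometry = NULL)))
  path <- withr::local_tempfile(fileext = ".geojson")
  writeLines(jsonlite::toJSON(gj, auto_unbox = TRUE), path)
  expect_error(read_holc_geojson(path), "holc_grade")
})

test_that("observation CSVs parse, normalize clades, and count malformed rows", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "# metadata line",
    "id,observed_on,latitude,longitude,scientific_name,clade,quality_grade,establishment",
    "r1,2019-01-02,0.5,0.5,Turdus migratorius,Aves,research,native",
    "r2,2019-03-04,0.6,0.6,Apis mellifera,Insecta,research,introduced",
    "r3,not-a-date,0.7,0.7,Canis latrans,Mammalia,research,native",
    "r4,2019-05-06,0.8,0.8,Sciurus niger,mammal,casual,",
    "r5,2019-07-08,0.9,0.9,Mystery thing,Plantae,research,native"
  ), path)
  rec <- read_observations_csv(path)
  expect_equal(nrow(rec), 3) # r3 bad date, r5 unknown clade
  expect_equal(rec$clade[rec$record_id == "r1"], "bird")
  expect_equal(rec$clade[rec$record_id == "r2"], "insect")
  expect_equal(rec$native[rec$record_id == "r4"], "unknown")
  rep <- filter_report(rec)
  expect_equal(rep$n_dropped[rep$rule == "parseable_date"], 1L)
  expect_equal(rep$n_dropped[rep$rule == "known_clade"], 1L)
})

test_that("a missing required column is named in the error", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,observed_on,latitude,longitude,scientific_name,clade,quality_grade",
               "r1,2019-01-01,0,0,x,Aves,research"), path)
  expect_error(read_observations_csv(path), "establishment")
})

test_that("column_map remaps nonstandard headers", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("uuid,date,lat,lon,taxon,group,qa,origin",
               "r1,2019-01-01,0.5,0.5,Turdus merula,Aves,research,native"), path)
  rec <- read_observations_csv(path, column_map = c(
    id = "uuid", observed_on = "date", latitude = "lat", longitude = "lon",
    scientific_name = "taxon", clade = "group", quality_grade = "qa",
    establishment = "origin"))
  expect_equal(rec$species, "Turdus merula")
})

test_that("record filters apply in order and account for every record", {
  rec <- make_records(5)
  rec$quality[1] <- "casual"
  rec$species[2] <- NA
  out <- filter_records(rec)
  expect_equal(nrow(out), 3)
  rep <- filter_report(out)
  expect_equal(rep$rule, c("research_grade", "species_present", "date_window"))
  expect_equal(rep$n_dropped, c(1L, 1L, 0L))
  expect_true(all(rep$n_input == rep$n_dropped + rep$n_retained))
  expect_true(all(rep$n_retained[-3] == rep$n_input[-1]))
})

test_that("the date window is half-open: the end date itself is excluded", {
  rec <- make_records(3, observed_on = as.Date(c("2017-01-01", "2021-12-31",
                                                 "2022-01-01")))
  out <- filter_records(rec)
  expect_equal(out$record_id, c("r001", "r002"))
  expect_error(filter_records(rec, as.Date("2022-01-01"), as.Date("2017-01-01")),
               "after")
})

test_that("empty input filters to an empty output with a zero-count report", {
  rec <- make_records(0)
  out <- filter_records(rec)
  expect_equal(nrow(out), 0)
  expect_true(all(filter_report(out)$n_input == 0))
})

test_that("filter accounting holds on fuzzed record tables", {
  set.seed(404)
  for (rep_i in 1:20) {
    n <- sample(0:60, 1)
    rec <- make_records(n)
    if (n > 0) {
      rec$quality <- sample(c("research", "casual", NA), n, replace = TRUE)
      rec$species <- sample(c("sp1", "", NA), n, replace = TRUE)
      rec$observed_on <- as.Date("2015-01-01") +
        sample(0:4000, n, replace = TRUE)
    }
    out <- filter_records(rec)
    report <- filter_report(out)
    expect_true(all(report$n_input == report$n_dropped + report$n_retained))
    expect_equal(report$n_input[1], n)
    expect_equal(report$n_retained[3], nrow(out))
  }
})

test_that("points assign to containing polygons with boundary tie-breaks", {
  nb <- tibble::tibble(
    neighborhood_id = c("n1", "n2"),
    city = "x",
    holc_grade = c("A", "B"),
    area_km2 = 1,
    polygon = list(
      rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1), c(0, 0)),
      rbind(c(1, 0), c(2, 0), c(2, 1), c(1, 1), c(1, 0))
    )
  )
  rec <- make_records(3, latitude = c(0.5, 0.5, 5), longitude = c(0.5, 1, 5))
  expect_warning(out <- assign_points_to_polygons(rec, nb), "more than one")
  expect_equal(nrow(out), 2)
  expect_equal(out$neighborhood_id[out$record_id == "r001"], "n1")
  # the shared edge point belongs to both; the lowest id wins
  expect_equal(out$neighborhood_id[out$record_id == "r002"], "n1")
  expect_equal(attr(out, "n_unassigned"), 1L)
  rep <- filter_report(out)
  expect_equal(rep$n_dropped, 1L)
})

test_that("a point on a shared vertex goes to the lowest neighborhood id", {
  nb <- tibble::tibble(
    neighborhood_id = c("b2", "a1"),
    city = "x", holc_grade = c("A", "B"), area_km2 = 1,
    polygon = list(
      rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1), c(0, 0)),
      rbind(c(1, 1), c(2, 1), c(2, 2), c(1, 2), c(1, 1))
    )
  )
  rec <- make_records(1, latitude = 1, longitude = 1)
  expect_warning(out <- assign_points_to_polygons(rec, nb), "more than one")
  expect_equal(out$neighborhood_id, "a1")
})

test_that("synthetic records re-assign to their source neighborhoods exactly", {
  region <- make_region(region_config(n_cities = 2,
                                      neighborhoods_per_grade_per_city = 3),
                        seed = 17)
  rec <- simulate_observation_records(region, community_config(), seed = 18)
  parsed <- tibble::tibble(
    record_id = rec$id, observed_on = rec$observed_on,
    latitude = rec$latitude, longitude = rec$longitude,
    species = rec$scientific_name, clade = rec$clade,
    quality = rec$quality_grade,
    native = ifelse(rec$establishment == "native", "native", "introduced")
  )
  filtered <- filter_records(parsed)
  expect_equal(nrow(filtered), nrow(rec)) # all in-window, research grade
  out <- assign_points_to_polygons(filtered, region$neighborhoods)
  expect_equal(attr(out, "n_unassigned"), 0L)
  expect_equal(out$neighborhood_id,
               rec$source_neighborhood[match(out$record_id, rec$id)])
})

test_that("city inclusion requires every grade-by-clade cell to be filled", {
  nb <- tibble::tibble(
    neighborhood_id = sprintf("n%02d", 1:8),
    city = rep(c("good", "bad"), each = 4),
    holc_grade = rep(c("A", "B", "C", "D"), 2),
    area_km2 = 1
  )
  cells <- tidyr::expand_grid(
    nb_id = nb$neighborhood_id,
    clade = c("bird", "mammal", "insect", "arachnid", "reptile", "amphibian"),
    i = 1:5
  )
  rec <- tibble::tibble(
    record_id = sprintf("r%05d", seq_len(nrow(cells))),
    neighborhood_id = cells$nb_id,
    clade = cells$clade,
    species = "sp", native = "native",
    observed_on = as.Date("2019-01-01"),
    latitude = 0, longitude = 0, quality = "research"
  )
  # "bad" city: knock one record out of a single cell (4 < 5 left)
  drop_one <- which(rec$neighborhood_id == "n05" & rec$clade == "bird")[1]
  rec_bad <- rec[-drop_one, ]
  out <- city_clade_inclusion(rec_bad, nb, min_per_cell = 5)
  expect_equal(attr(out, "retained_cities"), "good")
  expect_true(all(out$neighborhood_id %in% nb$neighborhood_id[nb$city == "good"]))
  # boundary case: exactly 5 everywhere retains both cities
  out_all <- city_clade_inclusion(rec, nb, min_per_cell = 5)
  expect_setequal(attr(out_all, "retained_cities"), c("good", "bad"))
  # nothing retained is a hard error with diagnostics
  expect_error(city_clade_inclusion(rec[rec$clade == "bird", ], nb, 5),
               "no city")
})

test_that("zonal means average cell centers inside the polygon", {
  grid <- list(x0 = 0, y0 = 0, cell = 1, nx = 2, ny = 1,
               values = matrix(c(20, 60), nrow = 1))
  poly_both <- rbind(c(0, 0), c(2, 0), c(2, 1), c(0, 1), c(0, 0))
  expect_equal(zonal_mean_impervious(grid, poly_both), 40)
  uniform <- list(x0 = 0, y0 = 0, cell = 0.5, nx = 8, ny = 8,
                  values = matrix(40, 8, 8))
  poly_any <- rbind(c(0.3, 0.2), c(3.1, 0.4), c(2.9, 3.3), c(0.2, 2.8),
                    c(0.3, 0.2))
  expect_equal(zonal_mean_impervious(uniform, poly_any), 40)
})

test_that("sliver polygons fall back to the nearest cell with a warning", {
  grid <- list(x0 = 0, y0 = 0, cell = 1, nx = 2, ny = 1,
               values = matrix(c(20, 60), nrow = 1))
  sliver <- rbind(c(1.9, 0.9), c(1.95, 0.9), c(1.95, 0.95), c(1.9, 0.95),
                  c(1.9, 0.9))
  expect_warning(v <- zonal_mean_impervious(grid, sliver), "nearest")
  expect_equal(v, 60)
  far <- rbind(c(100, 100), c(101, 100), c(101, 101), c(100, 101), c(100, 100))
  expect_error(zonal_mean_impervious(grid, far), "outside")
})

test_that("richness tables count distinct species under each subset", {
  nb <- tibble::tibble(neighborhood_id = c("n1", "n2"), city = "x",
                       holc_grade = c("A", "D"), area_km2 = 1,
                       impervious = 50)
  rec <- tibble::tibble(
    record_id = sprintf("r%d", 1:4),
    neighborhood_id = c("n1", "n1", "n1", "n2"),
    species = c("sp1", "sp1", "sp2", "sp3"),
    native = c("native", "native", "introduced", "unknown"),
    clade = "bird",
    observed_on = as.Date("2019-01-01"),
    latitude = 0, longitude = 0, quality = "research"
  )
  all_tab <- richness_table(rec, nb)
  expect_equal(all_tab$richness[all_tab$neighborhood_id == "n1"], 2L)
  expect_equal(all_tab$n_obs[all_tab$neighborhood_id == "n1"], 3L)
  expect_equal(sum(all_tab$n_obs), nrow(rec))

  native_tab <- richness_table(rec, nb, subset = "native")
  expect_equal(native_tab$richness[native_tab$neighborhood_id == "n1"], 1L)
  # n2's only record has unknown status: excluded from the native subset
  expect_false("n2" %in% native_tab$neighborhood_id)
  expect_equal(filter_report(native_tab)$n_dropped, 1L)

  expect_error(richness_table(rec, nb, subset = "fungi"), "unknown subset")
})
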