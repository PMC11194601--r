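#' Ground-truth parameters for model-mode richness simulation
#'
#' The generative twin of the hierarchical Poisson richness model: a global
#' log-scale intercept, per-grade log-scale effects (grade A is the reference
#' and fixed at zero), an impervious-surface slope per SD, and city-level
#' random intercept/slope SDs. City deviations may be supplied explicitly
#' (`city_effects`) or left `NULL` to be drawn at simulation time.
#'
#' @param b0 Global intercept, log scale.
#' @param b_grade Named numeric vector of non-reference grade effects (log
#'   scale), e.g. `c(B = -0.2, C = -0.5, D = -1)`.
#' @param b_imp Impervious-surface slope per SD of impervious cover.
#' @param sigma_city_intercept,sigma_city_slope Positive SDs of city-level
#'   intercept and grade-slope deviations.
#' @param city_effects Optional tibble of realized deviations with columns
#'   `city`, `u0`, and one `u_<grade>` column per non-reference grade.
#' @return A `truth_params` list.
#' @export
truth_params <- function(b0 = -1.5,
                         b_grade = c(B = -0.3, C = -0.6, D = -1.2),
                         b_imp = -0.2,
                         sigma_city_intercept = 0.3,
                         sigma_city_slope = 0.2,
                         city_effects = NULL) {
  if (sigma_city_intercept <= 0 || sigma_city_slope <= 0) {
    abort("random-effect SDs must be strictly positive")
  }
  if (is.null(names(b_grade)) || any(!nzchar(names(b_grade)))) {
    abort("`b_grade` must be a named vector of non-reference grade effects")
  }
  structure(
    list(
      b0 = as.numeric(b0),
      b_grade = b_grade,
      b_imp = as.numeric(b_imp),
      sigma_city_intercept = as.numeric(sigma_city_intercept),
      sigma_city_slope = as.numeric(sigma_city_slope),
      city_effects = city_effects
    ),
    class = "truth_params"
  )
}

#' Simulate per-neighborhood species richness from the Poisson model
#'
#' Model-mode data: richness counts are drawn directly from the hierarchical
#' Poisson model at known parameter values, with offset
#' `log(area_km2) + log(n_obs)` and impervious cover standardized across the
#' region's neighborhoods. Used to verify the fitting machinery against known
#' truth.
#'
#' @param region A [make_region()] result; every neighborhood must have
#'   `area_km2 > 0` and recorded effort `n_obs >= 1`.
#' @param truth A [truth_params()].
#' @param seed Integer seed (city deviations and Poisson draws).
#' @return Tibble with one row per neighborhood: identifiers, covariates,
#'   `offset`, the true mean `mu`, and the simulated `richness`; the realized
#'   `city_effects` are attached as an attribute of the same name.
#' @export
simulate_richness <- function(region, truth = truth_params(), seed = 1L) {
  stopifnot(inherits(region, "holc_region"), inherits(truth, "truth_params"))
  nb <- region$neighborhoods
  if (any(nb$n_obs < 1)) {
    abort("every neighborhood needs effort n_obs >= 1 (offset undefined at 0)")
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))

  cities <- sort(unique(nb$city))
  grades <- region$config$grades
  ref <- grades[1]
  nonref <- setdiff(grades, ref)
  missing_g <- setdiff(nonref, names(truth$b_grade))
  if (length(missing_g)) {
    abort(paste0("`truth$b_grade` lacks effects for grade(s): ",
                 paste(missing_g, collapse = ", ")))
  }

  ce <- truth$city_effects
  if (is.null(ce)) {
    ce <- tibble::tibble(city = cities,
                         u0 = rnorm(length(cities), 0, truth$sigma_city_intercept))
    for (g in nonref) {
      ce[[paste0("u_", g)]] <- rnorm(length(cities), 0, truth$sigma_city_slope)
    }
  }

  imp_sd <- sd(nb$impervious)
  imp_z <- if (is.na(imp_sd) || imp_sd == 0) {
    rep(0, nrow(nb))
  } else {
    as.numeric(scale(nb$impervious))
  }
  b_g <- c(stats::setNames(0, ref), truth$b_grade[nonref])
  u0 <- ce$u0[match(nb$city, ce$city)]
  ug <- mapply(function(g, city) {
    if (g == ref) 0 else ce[[paste0("u_", g)]][match(city, ce$city)]
  }, nb$holc_grade, nb$city)
  offset <- log(nb$area_km2) + log(nb$n_obs)
  eta <- offset + truth$b0 + u0 + b_g[nb$holc_grade] + ug + truth$b_imp * imp_z
  mu <- exp(eta)
  out <- nb %>%
    select(-"polygon") %>%
    mutate(impervious_z = imp_z, offset = offset, mu = mu,
           richness = rpois(length(mu), mu))
  attr(out, "city_effects") <- ce
  out
}

#' Configuration of the synthetic species community
#'
#' Controls the species pools behind record-mode simulation. Pools are
#' grade-ordered in size (richer pools in greenlined grades) and nested:
#' grade A's pool is drawn first and each lower grade reuses a
#' `pool_overlap` fraction of the adjacent grade's pool, which creates the
#' assemblage dissimilarity the beta-diversity machinery must detect. A
#' fraction of each city's pool is relabeled to city-endemic species
#' (`city_species_fraction`), identically across grades, so cities differ in
#' composition without disturbing within-city grade structure.
#'
#' @param pool_size_by_grade Named species-pool sizes, one per grade. The
#'   grade-ordered defaults give adjacent-grade gaps of at least ~0.3 on the
#'   log-richness scale at the default effort, so the generated disparity is
#'   strictly ordered and decisively recoverable at the four-city study
#'   scale. Every pool is guaranteed at least one species of each
#'   positive-weight clade.
#' @param pool_overlap Fraction (0-1) of species a grade shares with the
#'   adjacent better grade. `1` makes equal-size pools identical (the
#'   beta-diversity null); `0` makes all grade pools disjoint.
#' @param native_fraction Proportion of species flagged native, assigned once
#'   per species at pool creation.
#' @param abundance_shape Geometric rank-abundance parameter in (0, 1); rank
#'   r has sampling weight `(1 - abundance_shape)^(r - 1)`.
#' @param effort_mean,effort_dispersion Negative-binomial mean and size of
#'   per-neighborhood record counts.
#' @param clade_weights Named probabilities over the six clades; must sum
#'   to 1.
#' @param city_species_fraction Fraction of each city's pool relabeled as
#'   city-endemic.
#' @return A `community_config` list.
#' @export
community_config <- function(pool_size_by_grade = c(A = 120, B = 60, C = 26, D = 10),
                             pool_overlap = 0.7,
                             native_fraction = 0.7,
                             abundance_shape = 0.02,
                             effort_mean = 90,
                             effort_dispersion = 2,
                             clade_weights = c(bird = 0.35, insect = 0.30,
                                               mammal = 0.12, reptile = 0.10,
                                               arachnid = 0.08, amphibian = 0.05),
                             city_species_fraction = 0.15) {
  if (any(pool_size_by_grade < 1)) abort("pool sizes must be >= 1")
  for (f in c(pool_overlap, native_fraction, city_species_fraction)) {
    if (f < 0 || f > 1) abort("fractions must lie in [0, 1]")
  }
  if (abundance_shape <= 0 || abundance_shape >= 1) {
    abort("`abundance_shape` must lie in (0, 1)")
  }
  if (abs(sum(clade_weights) - 1) > 1e-8) abort("`clade_weights` must sum to 1")
  if (any(clade_weights < 0)) abort("`clade_weights` must be non-negative")
  if (effort_mean <= 0 || effort_dispersion <= 0) {
    abort("effort parameters must be positive")
  }
  structure(
    list(
      pool_size_by_grade = pool_size_by_grade,
      pool_overlap = pool_overlap,
      native_fraction = native_fraction,
      abundance_shape = abundance_shape,
      effort_mean = effort_mean,
      effort_dispersion = effort_dispersion,
      clade_weights = clade_weights,
      city_species_fraction = city_species_fraction
    ),
    class = "community_config"
  )
}

#' Simulate observation records (record-mode data)
#'
#' Draws iNaturalist-style observation records for every neighborhood of a
#' region: per-neighborhood record counts are negative binomial, species are
#' sampled from the neighborhood's grade/city pool with geometric-series
#' abundances, and each record falls uniformly inside its neighborhood's
#' polygon with an observation date uniform in the study window.
#'
#' @param region A [make_region()] result.
#' @param community A [community_config()].
#' @param seed Integer seed.
#' @param window Length-2 `Date` vector; dates are drawn uniformly in
#'   `[window[1], window[2])`.
#' @return Tibble of records with columns `id`, `observed_on`, `latitude`,
#'   `longitude`, `scientific_name`, `clade`, `quality_grade`,
#'   `establishment`, and the generating `source_neighborhood` (kept for
#'   round-trip checks; not written by [write_records_csv()]).
#' @export
simulate_observation_records <- function(region,
                                         community = community_config(),
                                         seed = 1L,
                                         window = as.Date(c("2017-01-01",
                                                            "2022-01-01"))) {
  stopifnot(inherits(region, "holc_region"),
            inherits(community, "community_config"))
  nb <- region$neighborhoods
  if (nrow(nb) == 0) abort("region has no neighborhoods")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))

  pools <- build_species_pools(region$config$grades, community)
  cities <- sort(unique(nb$city))
  city_pools <- relabel_city_endemics(pools, cities,
                                      community$city_species_fraction)

  n_rec <- stats::rnbinom(nrow(nb), mu = community$effort_mean,
                          size = community$effort_dispersion)
  rows <- vector("list", nrow(nb))
  for (i in seq_len(nrow(nb))) {
    k <- n_rec[i]
    if (k == 0) next
    pool <- city_pools[[nb$city[i]]][[nb$holc_grade[i]]]
    w <- (1 - community$abundance_shape)^(seq_len(nrow(pool)) - 1)
    pick <- sample.int(nrow(pool), k, replace = TRUE, prob = w)
    ring <- nb$polygon[[i]]
    bb <- ring_bbox(ring)
    # rectangles: uniform in the bounding box is uniform in the polygon
    rows[[i]] <- tibble::tibble(
      observed_on = window[1] +
        floor(runif(k, 0, as.numeric(window[2] - window[1]))),
      latitude = runif(k, bb["ymin"], bb["ymax"]),
      longitude = runif(k, bb["xmin"], bb["xmax"]),
      scientific_name = pool$species[pick],
      clade = pool$clade[pick],
      quality_grade = "research",
      establishment = ifelse(pool$native[pick], "native", "introduced"),
      source_neighborhood = nb$neighborhood_id[i]
    )
  }
  out <- bind_rows(rows)
  if (nrow(out) == 0) {
    abort("simulation produced no records; increase `effort_mean`")
  }
  out %>%
    mutate(id = sprintf("rec%07d", row_number())) %>%
    select("id", dplyr::everything())
}

# Nested-overlap grade pools over a global species list with per-species
# clade and native status fixed at creation.
build_species_pools <- function(grades, community) {
  sizes <- community$pool_size_by_grade
  missing_g <- setdiff(grades, names(sizes))
  if (length(missing_g)) {
    abort(paste0("`pool_size_by_grade` lacks grade(s): ",
                 paste(missing_g, collapse = ", ")))
  }
  total <- sum(sizes[grades])
  clades <- names(community$clade_weights)[community$clade_weights > 0]
  clade_draw <- sample(clades, total, replace = TRUE,
                       prob = community$clade_weights[clades])
  # guarantee every positive-weight clade appears in the pool
  short <- setdiff(clades, unique(clade_draw))
  if (length(short)) clade_draw[seq_along(short)] <- short
  master <- tibble::tibble(
    species = sprintf("Genus species%04d", seq_len(total)),
    clade = clade_draw,
    native = runif(total) < community$native_fraction
  )
  next_new <- 1L
  take_new <- function(n) {
    idx <- seq.int(next_new, length.out = n)
    next_new <<- next_new + n
    master[idx, ]
  }
  # every pool must host every positive-weight clade or downstream
  # grade-by-clade inclusion rules become unsatisfiable; repairs replace a
  # species of the commonest clade and propagate down the nested chain
  repair_clades <- function(pool) {
    missing <- setdiff(clades, unique(pool$clade))
    for (cl in missing) {
      donor <- which(pool$clade == names(which.max(table(pool$clade))))
      idx <- donor[sample.int(length(donor), 1)]
      repl <- take_new(1)
      repl$clade <- cl
      pool[idx, ] <- repl
    }
    pool
  }
  pools <- list()
  for (gi in seq_along(grades)) {
    g <- grades[gi]
    n_g <- sizes[[g]]
    if (gi == 1) {
      # random rank-abundance order for the top grade
      pools[[g]] <- take_new(n_g)[sample.int(n_g), ]
    } else {
      # shared species keep their relative abundance ranks from the adjacent
      # pool (so full overlap with equal sizes reproduces it exactly: the
      # beta-diversity null); new species are interleaved at random ranks
      prev <- pools[[grades[gi - 1]]]
      n_shared <- min(round(community$pool_overlap * n_g), nrow(prev))
      shared <- prev[sort(sample.int(nrow(prev), n_shared)), ]
      fresh <- take_new(n_g - n_shared)
      pos_new <- if (nrow(fresh)) sort(sample.int(n_g, nrow(fresh))) else integer()
      target <- integer(n_g)
      target[pos_new] <- n_shared + seq_len(nrow(fresh))
      target[setdiff(seq_len(n_g), pos_new)] <- seq_len(n_shared)
      pools[[g]] <- bind_rows(shared, fresh)[target, ]
    }
    if (n_g >= length(clades)) pools[[g]] <- repair_clades(pools[[g]])
  }
  pools
}

# Relabel a per-city subset of the master species list to city-endemic names,
# identically across grades within a city, so between-city composition
# differs while within-city grade structure is untouched.
relabel_city_endemics <- function(pools, cities, fraction) {
  all_species <- unique(unlist(lapply(pools, function(p) p$species)))
  n_swap <- floor(fraction * length(all_species))
  out <- list()
  for (city in cities) {
    swap <- if (n_swap > 0) sample(all_species, n_swap) else character()
    out[[city]] <- lapply(pools, function(p) {
      hit <- p$species %in% swap
      p$species[hit] <- paste0(p$species[hit], " (", city, ")")
      p
    })
  }
  out
}
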