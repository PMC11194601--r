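# Shared fixtures: all synthetic, built in code at test time.

# A minimal region: one city, one neighborhood per grade.
tiny_region <- function(seed = 1) {
  make_region(region_config(n_cities = 1, neighborhoods_per_grade_per_city = 1),
              seed = seed)
}

# A hand-rolled region-shaped object whose neighborhood table is fully
# controlled (unit areas, unit effort), for closed-form model-mode checks.
flat_region <- function(n_per_grade = 1, n_cities = 1, area = 1, n_obs = 1) {
  grades <- c("A", "B", "C", "D")
  nb <- tidyr::expand_grid(
    city = sprintf("city_%d", seq_len(n_cities)),
    holc_grade = grades,
    rep = seq_len(n_per_grade)
  )
  nb <- dplyr::mutate(nb,
    neighborhood_id = sprintf("%s_%s%03d", city, holc_grade, rep),
    area_km2 = area,
    impervious = 50,
    n_obs = n_obs,
    polygon = purrr::map(dplyr::row_number(), function(i) {
      x0 <- (i - 1) * 2
      rbind(c(x0, 0), c(x0 + 1, 0), c(x0 + 1, 1), c(x0, 1), c(x0, 0))
    })
  )
  nb <- dplyr::select(nb, neighborhood_id, city, holc_grade, area_km2,
                      impervious, n_obs, polygon)
  structure(list(neighborhoods = nb, grid = NULL,
                 config = region_config(n_cities = n_cities), seed = 0L),
            class = "holc_region")
}

# Zero-effect truth with explicit zero city deviations (no random effects).
null_truth <- function(cities = "city_1") {
  ce <- tibble::tibble(city = cities, u0 = 0, u_B = 0, u_C = 0, u_D = 0)
  truth_params(b0 = 0, b_grade = c(B = 0, C = 0, D = 0), b_imp = 0,
               sigma_city_intercept = 1e-6 + 0.001,
               sigma_city_slope = 0.001, city_effects = ce)
}

# Record tibble builder for filter tests.
make_records <- function(n = 5, species = paste0("sp", seq_len(n)),
                         quality = "research",
                         observed_on = as.Date("2019-06-01"),
                         native = "native",
                         clade = "bird",
                         latitude = 0.5, longitude = 0.5) {
  tibble::tibble(
    record_id = sprintf("r%03d", seq_len(n)),
    observed_on = rep(as.Date(observed_on), length.out = n),
    latitude = rep(latitude, length.out = n),
    longitude = rep(longitude, length.out = n),
    species = rep(species, length.out = n),
    clade = rep(clade, length.out = n),
    quality = rep(quality, length.out = n),
    native = rep(native, length.out = n)
  )
}

# Small richness table for model-data tests.
toy_richness <- function() {
  tibble::tibble(
    neighborhood_id = c("n1", "n2", "n3", "n4"),
    city = "city_1",
    holc_grade = c("A", "B", "C", "D"),
    area_km2 = c(2, 1, 1, 1),
    impervious = c(30, 45, 60, 75),
    richness = c(5L, 4L, 3L, 2L),
    n_obs = c(3L, 10L, 10L, 10L)
  )
}

# Independent term-by-term log-posterior oracle (kept deliberately naive and
# separate from the package implementation).
oracle_log_posterior <- function(params, data, priors) {
  total <- 0
  ref <- data$grades[1]
  for (i in seq_along(data$y)) {
    g <- as.character(data$grade[i])
    city <- as.character(data$city[i])
    eta <- data$offset[i] + params$b0 + params$u0[[city]] +
      params$b_imp * data$x[i]
    if (g != ref) {
      eta <- eta + params$b_grade[[g]] + params$u_grade[g, city]
    }
    mu <- exp(eta)
    total <- total + data$y[i] * log(mu) - mu - lfactorial(data$y[i])
  }
  fx <- c(params$b0, params$b_imp,
          unlist(params$b_grade[setdiff(data$grades, ref)]))
  for (b in fx) {
    total <- total + dnorm(b, 0, priors$fixed_sd, log = TRUE)
  }
  for (city in data$cities) {
    total <- total + dnorm(params$u0[[city]], 0, params$sigma0, log = TRUE)
    for (g in setdiff(data$grades, ref)) {
      total <- total + dnorm(params$u_grade[g, city], 0,
                             params$sigma_grade[[g]], log = TRUE)
    }
  }
  sig <- c(params$sigma0, unlist(params$sigma_grade[setdiff(data$grades, ref)]))
  total + sum(dgamma(sig, priors$sd_shape, priors$sd_rate, log = TRUE))
}
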