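toy_model_data <- function() build_model_data(toy_richness())

toy_params <- function(data) {
  nonref <- setdiff(data$grades, data$grades[1])
  list(
    b0 = 0.2,
    b_grade = c(B = -0.1, C = -0.4, D = -0.9),
    b_imp = -0.15,
    u0 = stats::setNames(rep(0.05, length(data$cities)), data$cities),
    u_grade = matrix(0.02, length(nonref), length(data$cities),
                     dimnames = list(nonref, data$cities)),
    sigma0 = 0.4,
    sigma_grade = c(B = 0.3, C = 0.3, D = 0.3)
  )
}

test_that("model data carries the log(area) + log(effort) offset", {
  md <- suppressWarnings(toy_model_data())
  # area 2, n_obs 3 -> log 6
  expect_equal(md$offset[1], log(6))
  expect_equal(mean(md$x), 0, tolerance = 1e-12)
  expect_equal(sd(md$x), 1, tolerance = 1e-12)
  expect_equal(levels(md$grade)[1], "A")
  md_sum <- build_model_data(toy_richness(), offset_mode = "log_sum")
  expect_equal(md_sum$offset[1], log(2 + 3))
})

test_that("zero-observation neighborhoods are rejected by name", {
  bad <- toy_richness()
  bad$n_obs[2] <- 0L
  expect_error(build_model_data(bad), "n2")
  bad$n_obs[2] <- 10L
  bad$area_km2[1] <- 0
  expect_error(build_model_data(bad), "positive")
})

test_that("a single-neighborhood city triggers an identifiability warning", {
  rich <- dplyr::bind_rows(
    toy_richness(),
    dplyr::mutate(toy_richness(), city = "city_2",
                  neighborhood_id = paste0("m", 1:4))[1, ]
  )
  expect_warning(build_model_data(rich), "single neighborhood")
})

test_that("the linear predictor obeys log-link algebra", {
  md <- toy_model_data()
  p <- toy_params(md)
  zero <- p
  zero$b0 <- 0; zero$b_imp <- 0
  zero$b_grade[] <- 0; zero$u0[] <- 0; zero$u_grade[] <- 0
  expect_equal(exp(log_mean(zero, md))[1], 6) # offset ln 6 alone
  # grade D alone at zero offset
  md1 <- build_model_data(tibble::tibble(
    neighborhood_id = c("a", "d"), city = "c", holc_grade = c("A", "D"),
    area_km2 = 1, impervious = 50, richness = 1L, n_obs = 1L
  ))
  pD <- list(b0 = 0, b_grade = c(D = -0.5), b_imp = 0,
             u0 = c(c = 0), u_grade = matrix(0, 1, 1, dimnames = list("D", "c")))
  mu <- exp(log_mean(pD, md1))
  expect_equal(mu[[1]], 1)
  expect_equal(mu[[2]], exp(-0.5))
  # adding 1 to b0 multiplies every mu by e
  p1 <- p; p1$b0 <- p$b0 + 1
  expect_equal(exp(log_mean(p1, md)), exp(1) * exp(log_mean(p, md)))
})

test_that("the log posterior matches an independent term-by-term oracle", {
  md <- toy_model_data()
  p <- toy_params(md)
  priors <- prior_config()
  expect_equal(log_posterior(p, md, priors),
               oracle_log_posterior(p, md, priors), tolerance = 1e-12)
  # a second parameter point, asymmetric
  p2 <- p
  p2$b_grade[["D"]] <- 1.4
  p2$u0[1] <- -0.6
  p2$sigma0 <- 1.7
  expect_equal(log_posterior(p2, md, priors),
               oracle_log_posterior(p2, md, priors), tolerance = 1e-12)
})

test_that("single observation with mu = 1 contributes -1 to the likelihood", {
  md <- build_model_data(tibble::tibble(
    neighborhood_id = "a", city = "c", holc_grade = "A",
    area_km2 = 1, impervious = 50, richness = 1L, n_obs = 1L
  )) |> suppressWarnings()
  expect_equal(sum(dpois(md$y, 1, log = TRUE)), -1)
})

test_that("changing y at fixed parameters changes only the likelihood term", {
  md <- toy_model_data()
  p <- toy_params(md)
  priors <- prior_config()
  lp1 <- log_posterior(p, md, priors)
  md2 <- md
  md2$y <- md$y * 2L
  lp2 <- log_posterior(p, md2, priors)
  eta <- log_mean(p, md)
  dll <- sum(dpois(md2$y, exp(eta), log = TRUE)) -
    sum(dpois(md$y, exp(eta), log = TRUE))
  expect_equal(lp2 - lp1, dll, tolerance = 1e-12)
})

test_that("non-positive sigmas yield -Inf, not an error", {
  md <- toy_model_data()
  p <- toy_params(md)
  p$sigma0 <- 0
  expect_identical(log_posterior(p, md, prior_config()), -Inf)
  p$sigma0 <- -1
  expect_identical(log_posterior(p, md, prior_config()), -Inf)
})

test_that("gelman_rubin reproduces hand-computed values", {
  # two identical non-constant chains: B = 0, rhat = sqrt((n-1)/n)
  ch <- cbind(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(gelman_rubin(ch), sqrt(3 / 4), tolerance = 1e-12)
  # hand worked 2x2 example: W = 2, B = 1, rhat = sqrt(1/2 + 1/4)
  expect_equal(gelman_rubin(cbind(c(0, 2), c(1, 3))), sqrt(0.75),
               tolerance = 1e-12)
  # far-separated chains blow past the 1.10 threshold
  expect_gt(gelman_rubin(cbind(c(1, 2, 1, 2), c(101, 102, 101, 102))), 1.10)
  # degenerate chains are an error
  expect_error(gelman_rubin(cbind(rep(1, 4), rep(1, 4))), "variance")
  expect_error(gelman_rubin(matrix(1:4, ncol = 1)), "2 chains")
})

sim_fit_data <- function(seed = 1, n_per_grade = 10, n_cities = 2,
                         b_grade = c(B = -0.2, C = -0.5, D = -1),
                         b_imp = -0.2) {
  region <- make_region(
    region_config(n_cities = n_cities,
                  neighborhoods_per_grade_per_city = n_per_grade),
    seed = seed)
  truth <- truth_params(b0 = -1, b_grade = b_grade, b_imp = b_imp,
                        sigma_city_intercept = 0.2, sigma_city_slope = 0.15)
  sim <- simulate_richness(region, truth, seed = seed + 1)
  build_model_data(dplyr::select(sim, neighborhood_id, city, holc_grade,
                                 area_km2, impervious, richness, n_obs))
}

test_that("sampling is bit-reproducible under a fixed seed", {
  md <- sim_fit_data(seed = 3, n_per_grade = 3)
  cfg <- mcmc_config("test", burn_in = 200, samples = 200, chains = 2, seed = 5)
  f1 <- sample_posterior(md, mcmc = cfg)
  f2 <- sample_posterior(md, mcmc = cfg)
  expect_identical(f1$chains, f2$chains)
  f3 <- sample_posterior(md, mcmc = mcmc_config("test", burn_in = 200,
                                                samples = 200, chains = 2,
                                                seed = 6))
  expect_false(identical(f1$chains, f3$chains))
})

test_that("the posterior of a null impervious slope covers zero", {
  md <- sim_fit_data(seed = 11, n_per_grade = 12, n_cities = 1, b_imp = 0)
  fit <- sample_posterior(md, mcmc = mcmc_config("test", seed = 2))
  draws <- holcdiv:::all_draws(fit, "b_imp")
  ci <- quantile(draws, c(0.025, 0.975))
  expect_lt(ci[1], 0)
  expect_gt(ci[2], 0)
})

test_that("with pinned near-zero random effects the posterior matches the GLM MLE", {
  # independent covariate and ample counts keep the flat-ish Normal(0, 2)
  # prior's shrinkage well below the comparison tolerance
  set.seed(77)
  n <- 240
  grade <- rep(c("A", "B", "C", "D"), each = n / 4)
  x <- rnorm(n)
  eta <- log(30) + c(A = 0, B = -0.2, C = -0.5, D = -1)[grade] - 0.2 * x
  rich <- tibble::tibble(
    neighborhood_id = sprintf("n%03d", 1:n),
    city = "c1", holc_grade = grade,
    area_km2 = 1, impervious = 50 + 10 * x,
    richness = rpois(n, exp(eta)), n_obs = 30L
  )
  md <- build_model_data(rich)
  fit <- sample_posterior(md, mcmc = mcmc_config("test", seed = 9),
                          fix_sigma = 1e-4)
  # IRLS oracle: fixed-effect Poisson regression with the same offset
  glm_fit <- stats::glm(md$y ~ md$grade + md$x + offset(md$offset),
                        family = stats::poisson())
  mle <- stats::coef(glm_fit)
  post <- colMeans(holcdiv:::all_draws(fit))
  expect_lt(abs(post[["b0"]] - mle[["(Intercept)"]]), 0.05)
  expect_lt(abs(post[["b_B"]] - mle[["md$gradeB"]]), 0.05)
  expect_lt(abs(post[["b_C"]] - mle[["md$gradeC"]]), 0.05)
  expect_lt(abs(post[["b_D"]] - mle[["md$gradeD"]]), 0.05)
  expect_lt(abs(post[["b_imp"]] - mle[["md$x"]]), 0.05)
})

test_that("MCMC matches fine-grid numerical integration on a 2-parameter reduction", {
  # single city, grades A/D only, no impervious variation, sigmas pinned:
  # free parameters are (b0, b_D)
  rich <- tibble::tibble(
    neighborhood_id = sprintf("n%02d", 1:12),
    city = "c1",
    holc_grade = rep(c("A", "D"), each = 6),
    area_km2 = 1,
    impervious = 50, # constant: slope dropped
    richness = c(7L, 9L, 11L, 8L, 10L, 9L, 3L, 4L, 2L, 5L, 3L, 4L),
    n_obs = 5L
  )
  md <- build_model_data(rich)
  expect_false(md$include_x)
  fit <- sample_posterior(md,
                          mcmc = mcmc_config("test", burn_in = 4000,
                                             samples = 10000, seed = 31),
                          fix_sigma = 1e-5)
  draws <- holcdiv:::all_draws(fit, c("b0", "b_D"))

  # independent oracle: brute-force grid integration of the joint posterior
  b0_grid <- seq(-1.5, 1.5, length.out = 400)
  bd_grid <- seq(-2.5, 1.5, length.out = 400)
  yA <- md$y[md$grade == "A"]; yD <- md$y[md$grade == "D"]
  off <- log(5)
  loglik <- outer(b0_grid, bd_grid, function(b0, bd) {
    sapply(seq_along(b0), function(i) {
      sum(dpois(yA, exp(off + b0[i]), log = TRUE)) +
        sum(dpois(yD, exp(off + b0[i] + bd[i]), log = TRUE))
    })
  })
  logpost <- loglik + outer(dnorm(b0_grid, 0, 2, log = TRUE),
                            dnorm(bd_grid, 0, 2, log = TRUE), "+")
  w <- exp(logpost - max(logpost))
  w <- w / sum(w)
  m_b0 <- sum(rowSums(w) * b0_grid)
  m_bd <- sum(colSums(w) * bd_grid)
  sd_b0 <- sqrt(sum(rowSums(w) * (b0_grid - m_b0)^2))
  sd_bd <- sqrt(sum(colSums(w) * (bd_grid - m_bd)^2))

  expect_lt(abs(mean(draws[, "b0"]) - m_b0), 0.02 * max(abs(m_b0), sd_b0))
  expect_lt(abs(mean(draws[, "b_D"]) - m_bd), 0.02 * abs(m_bd))
  expect_lt(abs(sd(draws[, "b0"]) / sd_b0 - 1), 0.02)
  expect_lt(abs(sd(draws[, "b_D"]) / sd_bd - 1), 0.02)
})

test_that("rescaling every area shifts only the intercept by -log(c)", {
  # at the study scale (4 cities) the intercept is data-dominated and the
  # proper prior's attenuation of the shift is negligible
  rich <- sim_fit_data(seed = 41, n_per_grade = 11, n_cities = 4)$tbl
  md1 <- build_model_data(rich)
  rich2 <- dplyr::mutate(rich, area_km2 = area_km2 * 10)
  md2 <- build_model_data(rich2)
  cfg <- mcmc_config("test", seed = 13)
  f1 <- sample_posterior(md1, mcmc = cfg)
  f2 <- sample_posterior(md2, mcmc = cfg)
  b0_shift <- mean(holcdiv:::all_draws(f2, "b0")) -
    mean(holcdiv:::all_draws(f1, "b0"))
  expect_lt(abs(b0_shift + log(10)), 0.1)
  c1 <- grade_contrasts(f1, "city")
  c2 <- grade_contrasts(f2, "city")
  expect_equal(c1$significant, c2$significant)
})

test_that("degenerate posteriors give zero-width prediction intervals", {
  md <- suppressWarnings(toy_model_data())
  fit <- sample_posterior(md, mcmc = mcmc_config("test", burn_in = 50,
                                                 samples = 50, chains = 2,
                                                 seed = 1))
  # freeze every chain at one common draw to emulate a point posterior
  point <- fit$chains[[1]][1, ]
  fit$chains <- lapply(fit$chains, function(ch) {
    matrix(point, nrow = nrow(ch), ncol = ncol(ch), byrow = TRUE,
           dimnames = dimnames(ch))
  })
  pred <- predict_neighborhood_richness(fit)
  expect_equal(pred$lower, pred$upper)
  expect_equal(pred$lower, pred$median)
  s <- summarize_grades(fit, "city")
  expect_equal(s$lower, s$upper)
  ct <- grade_contrasts(fit, "city")
  expect_true(all(ct$lower == ct$upper))
})

test_that("neighborhood prediction intervals cover the true means", {
  # moderate-size calibration check; the full 50-replicate coverage study
  # runs with the acceptance suite
  covered <- 0L; total <- 0L
  for (r in 1:5) {
    region <- make_region(region_config(n_cities = 2,
                                        neighborhoods_per_grade_per_city = 6),
                          seed = 100 + r)
    truth <- truth_params(b0 = -1, sigma_city_intercept = 0.2,
                          sigma_city_slope = 0.15)
    sim <- simulate_richness(region, truth, seed = 200 + r)
    md <- build_model_data(dplyr::select(sim, neighborhood_id, city,
                                         holc_grade, area_km2, impervious,
                                         richness, n_obs))
    fit <- sample_posterior(md, mcmc = mcmc_config("test", seed = 300 + r))
    pred <- predict_neighborhood_richness(fit)
    hit <- sim$mu >= pred$lower & sim$mu <= pred$upper
    covered <- covered + sum(hit); total <- total + length(hit)
  }
  expect_gte(covered / total, 0.9)
})

test_that("overall grade intervals are wider than within-city intervals", {
  md <- sim_fit_data(seed = 51, n_per_grade = 8, n_cities = 3)
  fit <- sample_posterior(md, mcmc = mcmc_config("test", seed = 17))
  by_city <- summarize_grades(fit, "city")
  overall <- summarize_grades(fit, "overall", seed = 4)
  for (g in c("A", "B", "C", "D")) {
    w_city <- max((by_city$upper - by_city$lower)[by_city$holc_grade == g])
    w_all <- (overall$upper - overall$lower)[overall$holc_grade == g]
    expect_gt(w_all, w_city)
  }
})

test_that("contrast tables are internally consistent", {
  md <- sim_fit_data(seed = 61, n_per_grade = 6, n_cities = 2)
  fit <- sample_posterior(md, mcmc = mcmc_config("test", seed = 19))
  ct <- grade_contrasts(fit, "overall", seed = 2)
  expect_equal(nrow(ct), 6)
  expect_true(all(ct$lower <= ct$median & ct$median <= ct$upper))
  expect_equal(ct$significant, ct$lower > 0 | ct$upper < 0)
  s <- summarize_grades(fit, "overall", seed = 2)
  expect_setequal(s$holc_grade, c("A", "B", "C", "D"))
})
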