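# Hierarchical Bayesian Poisson model of neighborhood species richness:
# fixed HOLC-grade and impervious-surface effects, city-level random
# intercepts and grade slopes, and a log(area) + log(effort) offset.

#' Prior configuration for the richness model
#'
#' Fixed effects get Normal(0, `fixed_sd`) priors; the SDs of the city-level
#' random effects get Gamma(`sd_shape`, `sd_rate`) priors. Defaults are
#' Normal(0, 2) and Gamma(1, 1).
#'
#' @param fixed_sd SD of the zero-mean normal prior on fixed effects.
#' @param sd_shape,sd_rate Shape and rate of the gamma prior on
#'   random-effect SDs.
#' @return A `prior_config` list.
#' @export
prior_config <- function(fixed_sd = 2, sd_shape = 1, sd_rate = 1) {
  if (fixed_sd <= 0 || sd_shape <= 0 || sd_rate <= 0) {
    abort("all prior parameters must be strictly positive")
  }
  structure(list(fixed_sd = fixed_sd, sd_shape = sd_shape, sd_rate = sd_rate),
            class = "prior_config")
}

#' MCMC configuration
#'
#' The `"paper"` profile (110,000-step burn-in, 40,000 retained iterations,
#' 4 chains) is the full-length run; the `"test"` profile (2,000 / 2,000 / 4)
#' is for simulation studies and test suites.
#'
#' @param profile `"paper"` or `"test"`; sets defaults that the explicit
#'   arguments override.
#' @param burn_in,samples,chains Iteration counts (all >= 1).
#' @param seed Integer master seed; per-chain seeds are derived from it.
#' @return An `mcmc_config` list.
#' @export
mcmc_config <- function(profile = c("paper", "test"),
                        burn_in = NULL, samples = NULL, chains = 4,
                        seed = 1L) {
  profile <- match.arg(profile)
  defaults <- switch(profile,
    paper = list(burn_in = 110000L, samples = 40000L),
    test = list(burn_in = 2000L, samples = 2000L)
  )
  burn_in <- as.integer(burn_in %||% defaults$burn_in)
  samples <- as.integer(samples %||% defaults$samples)
  chains <- as.integer(chains)
  if (burn_in < 1 || samples < 1 || chains < 1) {
    abort("`burn_in`, `samples`, and `chains` must all be >= 1")
  }
  structure(list(profile = profile, burn_in = burn_in, samples = samples,
                 chains = chains, seed = as.integer(seed)),
            class = "mcmc_config")
}

#' Assemble model-ready data from a richness table
#'
#' Builds the response, treatment-coded grade (reference A), standardized
#' impervious covariate, city index, and the exposure offset
#' `log(area_km2) + log(n_obs)` (or `log(area_km2 + n_obs)` under the
#' `"log_sum"` reading).
#'
#' @param richness A [richness_table()] tibble (columns `neighborhood_id`,
#'   `city`, `holc_grade`, `area_km2`, `impervious`, `richness`, `n_obs`).
#' @param offset_mode `"log_product"` (default): `log(area) + log(n_obs)`;
#'   `"log_sum"`: `log(area + n_obs)`.
#' @return A `model_data` list: `y`, `grade`/`city` factors, standardized
#'   `x`, `offset`, level sets, and the input tibble.
#' @export
build_model_data <- function(richness,
                             offset_mode = c("log_product", "log_sum")) {
  offset_mode <- match.arg(offset_mode)
  needed <- c("neighborhood_id", "city", "holc_grade", "area_km2",
              "impervious", "richness", "n_obs")
  missing_cols <- setdiff(needed, names(richness))
  if (length(missing_cols)) {
    abort(paste0("richness table lacks column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  bad <- richness$n_obs < 1
  if (any(bad)) {
    abort(paste0("neighborhood(s) with zero observations: ",
                 paste(richness$neighborhood_id[bad], collapse = ", "),
                 " (the effort offset requires n_obs >= 1)"))
  }
  if (any(richness$area_km2 <= 0)) abort("all areas must be positive")
  single <- richness %>% count(.data$city) %>% filter(.data$n == 1)
  if (nrow(single)) {
    warn(paste0("city with a single neighborhood (random effects weakly ",
                "identified): ", paste(single$city, collapse = ", ")))
  }
  grades <- sort(unique(richness$holc_grade))
  cities <- sort(unique(richness$city))
  x_sd <- sd(richness$impervious)
  x <- if (is.na(x_sd) || x_sd == 0) {
    rep(0, nrow(richness))
  } else {
    as.numeric(scale(richness$impervious))
  }
  offset <- switch(offset_mode,
    log_product = log(richness$area_km2) + log(richness$n_obs),
    log_sum = log(richness$area_km2 + richness$n_obs)
  )
  structure(
    list(
      y = as.integer(richness$richness),
      grade = factor(richness$holc_grade, levels = grades),
      city = factor(richness$city, levels = cities),
      x = x,
      offset = offset,
      grades = grades,
      cities = cities,
      include_x = !(is.na(x_sd) || x_sd == 0),
      offset_mode = offset_mode,
      tbl = richness
    ),
    class = "model_data"
  )
}

#' Linear predictor of the richness model
#'
#' `log mu_i = offset_i + b0 + u0_city(i) + (b_g + u_g,city(i)) + b_imp x_i`,
#' with the reference grade's effect and slope deviations identically zero.
#'
#' @param params List with `b0`, named `b_grade` (non-reference grades),
#'   `b_imp`, named `u0` (one per city), and `u_grade` (matrix, non-reference
#'   grades x cities).
#' @param data A [build_model_data()] object.
#' @return Numeric vector `log mu`, one entry per neighborhood.
#' @export
log_mean <- function(params, data) {
  ref <- data$grades[1]
  nonref <- setdiff(data$grades, ref)
  g_chr <- as.character(data$grade)
  c_chr <- as.character(data$city)
  if (!all(nonref %in% names(params$b_grade))) {
    abort("`params$b_grade` must name every non-reference grade")
  }
  if (!all(data$cities %in% names(params$u0))) {
    abort("`params$u0` must name every city")
  }
  b_g <- c(stats::setNames(0, ref), params$b_grade[nonref])
  u_g <- rbind(matrix(0, 1, length(data$cities),
                      dimnames = list(ref, data$cities)),
               params$u_grade[nonref, data$cities, drop = FALSE])
  unname(data$offset + params$b0 + params$u0[c_chr] + b_g[g_chr] +
           u_g[cbind(g_chr, c_chr)] + params$b_imp * data$x)
}

#' Unnormalized log posterior of the richness model
#'
#' Poisson log-likelihood plus Normal(0, `fixed_sd`) log-priors on the fixed
#' effects, Normal(0, sigma) log-densities on the city deviations, and
#' Gamma log-priors on the sigma terms. Non-positive sigmas yield `-Inf`
#' (a rejected state), not an error.
#'
#' @param params As in [log_mean()], plus `sigma0` (scalar) and named
#'   `sigma_grade` (one per non-reference grade).
#' @inheritParams log_mean
#' @param priors A [prior_config()].
#' @return Scalar log density (finite for valid inputs).
#' @export
log_posterior <- function(params, data, priors = prior_config()) {
  nonref <- setdiff(data$grades, data$grades[1])
  sigmas <- c(params$sigma0, params$sigma_grade[nonref])
  if (any(!is.finite(sigmas)) || any(sigmas <= 0)) return(-Inf)
  eta <- log_mean(params, data)
  ll <- sum(dpois(data$y, exp(eta), log = TRUE))
  lp_fixed <- sum(dnorm(c(params$b0, params$b_grade[nonref], params$b_imp),
                        0, priors$fixed_sd, log = TRUE))
  lp_u <- sum(dnorm(params$u0[data$cities], 0, params$sigma0, log = TRUE))
  for (g in nonref) {
    lp_u <- lp_u + sum(dnorm(params$u_grade[g, data$cities], 0,
                             params$sigma_grade[[g]], log = TRUE))
  }
  lp_sigma <- sum(dgamma(sigmas, shape = priors$sd_shape,
                         rate = priors$sd_rate, log = TRUE))
  ll + lp_fixed + lp_u + lp_sigma
}

#' Sample the richness model's posterior
#'
#' Adaptive random-walk Metropolis-within-Gibbs in a non-centered
#' parameterization (deviations x sigma), mathematically identical to the
#' stated model. Chains start from independent over-dispersed prior draws and
#' the whole run is reproducible from the seed in `mcmc`.
#'
#' @param data A [build_model_data()] object.
#' @param priors A [prior_config()].
#' @param mcmc An [mcmc_config()].
#' @param fix_sigma Optional: pin the random-effect SDs instead of sampling
#'   them; a scalar or a vector of length `length(grades)` ordered
#'   (intercept SD, then one slope SD per non-reference grade). Used for
#'   fixed-effect (GLM-limit) checks.
#' @return A `richness_fit` object: per-chain draw matrices (columns `b0`,
#'   `b_B`, ..., `b_imp`, `sigma_0`, `sigma_B`, ..., `u0_<city>`,
#'   `u_<grade>_<city>`), plus the data, configs, and acceptance rates.
#' @export
sample_posterior <- function(data, priors = prior_config(),
                             mcmc = mcmc_config("test"),
                             fix_sigma = NULL) {
  stopifnot(inherits(data, "model_data"), inherits(priors, "prior_config"),
            inherits(mcmc, "mcmc_config"))
  grades <- data$grades
  nonref <- setdiff(grades, grades[1])
  K <- length(nonref)
  C <- length(data$cities)
  n_sd <- K + 1
  if (!is.null(fix_sigma)) {
    fix_sigma <- as.numeric(fix_sigma)
    if (length(fix_sigma) == 1) fix_sigma <- rep(fix_sigma, n_sd)
    if (length(fix_sigma) != n_sd || any(fix_sigma <= 0)) {
      abort("`fix_sigma` must be positive, scalar or length (grades)")
    }
  }
  city_i <- as.integer(data$city) - 1L
  grade_i <- as.integer(data$grade) - 1L

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(mcmc$seed)
  chain_seeds <- sample.int(.Machine$integer.max - 1L, mcmc$chains)

  par_names <- c("b0",
                 if (K) paste0("b_", nonref),
                 "b_imp",
                 "sigma_0",
                 if (K) paste0("sigma_", nonref),
                 paste0("u0_", data$cities),
                 if (K) as.vector(t(outer(nonref, data$cities,
                                          function(g, c) paste0("u_", g, "_", c)))))

  chains <- vector("list", mcmc$chains)
  acc <- vector("list", mcmc$chains)
  for (ch in seq_len(mcmc$chains)) {
    set.seed(chain_seeds[ch])
    init <- NULL
    for (try in seq_len(100)) {
      cand <- c(
        rnorm(1, 0, priors$fixed_sd),            # b0
        rnorm(K, 0, priors$fixed_sd),            # beta_g
        rnorm(1, 0, priors$fixed_sd),            # bimp
        rnorm(C),                                # z0
        rnorm(K * C),                            # zg
        log(stats::rgamma(n_sd, priors$sd_shape, priors$sd_rate)) # t
      )
      if (init_is_finite(cand, data, city_i, grade_i, K, C, fix_sigma)) {
        init <- cand
        break
      }
    }
    if (is.null(init)) {
      abort("could not find a finite-posterior initialization in 100 tries")
    }
    res <- .mwg_sample(
      as.numeric(data$y), data$offset, data$x, city_i, grade_i,
      C, K + 1L, isTRUE(data$include_x), init,
      mcmc$burn_in, mcmc$samples,
      priors$fixed_sd, priors$sd_shape, priors$sd_rate,
      if (is.null(fix_sigma)) numeric(0) else fix_sigma
    )
    colnames(res$draws) <- par_names
    chains[[ch]] <- res$draws
    acc[[ch]] <- res$acceptance
  }

  structure(
    list(chains = chains, par_names = par_names, data = data,
         priors = priors, mcmc = mcmc, fix_sigma = fix_sigma,
         chain_seeds = chain_seeds, acceptance = acc),
    class = "richness_fit"
  )
}

init_is_finite <- function(init, data, city_i, grade_i, K, C, fix_sigma) {
  pos <- 1
  b0 <- init[pos]; pos <- pos + 1
  beta <- if (K) init[pos:(pos + K - 1)] else numeric(0); pos <- pos + K
  bimp <- init[pos]; pos <- pos + 1
  z0 <- init[pos:(pos + C - 1)]; pos <- pos + C
  zg <- if (K) init[pos:(pos + K * C - 1)] else numeric(0); pos <- pos + K * C
  t <- init[pos:(pos + K)]
  sig <- if (is.null(fix_sigma)) exp(t) else fix_sigma
  eta <- data$offset + b0 + sig[1] * z0[city_i + 1] +
    (if (isTRUE(data$include_x)) bimp * data$x else 0)
  hit <- grade_i > 0
  if (any(hit)) {
    g <- grade_i[hit]
    eta[hit] <- eta[hit] + beta[g] + sig[g + 1] * zg[(g - 1) * C + city_i[hit] + 1]
  }
  all(is.finite(eta)) && max(eta) < 500
}

#' Gelman-Rubin potential scale reduction
#'
#' Classic formula: with m chains of length n, `W` the mean within-chain
#' variance and `B` the between-chain variance (`n` times the variance of the
#' chain means), `rhat = sqrt((n - 1)/n + B / (n W))`.
#'
#' @param chains Matrix (iterations x chains) or list of equal-length
#'   numeric vectors, for one parameter.
#' @return The scalar potential scale reduction factor.
#' @examples
#' gelman_rubin(cbind(c(0, 2), c(1, 3))) # sqrt(3)/2
#' @export
gelman_rubin <- function(chains) {
  if (is.list(chains)) chains <- do.call(cbind, chains)
  chains <- as.matrix(chains)
  n <- nrow(chains)
  m <- ncol(chains)
  if (m < 2 || n < 2) abort("need >= 2 chains with >= 2 draws each")
  w <- mean(apply(chains, 2, var))
  if (w == 0) abort("zero within-chain variance: degenerate chains")
  b <- n * var(colMeans(chains))
  sqrt((n - 1) / n + b / (n * w))
}

#' Convergence report for a fitted model
#'
#' Computes the Gelman-Rubin statistic for every sampled parameter; the run
#' passes when every rhat is below 1.10.
#'
#' @param fit A [sample_posterior()] result.
#' @param threshold Pass threshold on the largest rhat.
#' @return Tibble (`parameter`, `rhat`) with attributes `pass` and
#'   `max_rhat`.
#' @export
convergence_report <- function(fit, threshold = 1.10) {
  stopifnot(inherits(fit, "richness_fit"))
  sampled <- sampled_parameters(fit)
  rhat <- vapply(sampled, function(p) {
    gelman_rubin(lapply(fit$chains, function(ch) ch[, p]))
  }, numeric(1))
  out <- tibble::tibble(parameter = sampled, rhat = unname(rhat))
  attr(out, "max_rhat") <- max(out$rhat)
  attr(out, "pass") <- max(out$rhat) < threshold
  out
}

# Parameters that are actually sampled (sigmas drop out when pinned; the
# impervious slope drops out for constant covariates).
sampled_parameters <- function(fit) {
  p <- fit$par_names
  if (!is.null(fit$fix_sigma)) p <- p[!grepl("^sigma", p)]
  if (!isTRUE(fit$data$include_x)) p <- setdiff(p, "b_imp")
  p
}

all_draws <- function(fit, parameters = NULL) {
  m <- do.call(rbind, fit$chains)
  if (!is.null(parameters)) m <- m[, parameters, drop = FALSE]
  m
}

#' @export
print.richness_fit <- function(x, ...) {
  cat(sprintf(
    "<richness_fit> %d neighborhoods, %d cities, grades %s\n  %d chains x %d draws (burn-in %d, profile %s)\n",
    length(x$data$y), length(x$data$cities),
    paste(x$data$grades, collapse = ","),
    x$mcmc$chains, x$mcmc$samples, x$mcmc$burn_in, x$mcmc$profile
  ))
  print(tidy(x), ...)
  invisible(x)
}

#' @export
tidy.richness_fit <- function(x, ...) {
  draws <- all_draws(x)
  qs <- t(apply(draws, 2, quantile, probs = c(0.5, 0.025, 0.975)))
  rep_tbl <- convergence_report(x)
  tibble::tibble(
    parameter = colnames(draws),
    median = qs[, 1],
    conf.low = qs[, 2],
    conf.high = qs[, 3]
  ) %>%
    left_join(rep_tbl, by = "parameter")
}

#' @export
glance.richness_fit <- function(x, ...) {
  rep_tbl <- convergence_report(x)
  tibble::tibble(
    n_neighborhoods = length(x$data$y),
    n_cities = length(x$data$cities),
    chains = x$mcmc$chains,
    draws_per_chain = x$mcmc$samples,
    max_rhat = attr(rep_tbl, "max_rhat"),
    converged = attr(rep_tbl, "pass")
  )
}

#' @export
autoplot.richness_fit <- function(object, ...) {
  td <- tidy(object)
  td <- filter(td, !grepl("^u", .data$parameter))
  ggplot2::ggplot(td, ggplot2::aes(x = .data$median, y = .data$parameter)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$conf.low, xmax = .data$conf.high),
      height = 0.2) +
    ggplot2::labs(x = "posterior median (95% CI)", y = NULL) +
    ggplot2::theme_minimal()
}
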