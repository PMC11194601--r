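# Posterior summaries on the response (expected-richness) scale:
# per-neighborhood predictions, grade-level means by city and overall, and
# pairwise grade contrasts with 95% credible intervals.

# n x npar design matrix mapping a draw vector to linear predictors
linear_design <- function(data, par_names) {
  n <- length(data$y)
  D <- matrix(0, n, length(par_names),
              dimnames = list(NULL, par_names))
  D[, "b0"] <- 1
  if (isTRUE(data$include_x)) D[, "b_imp"] <- data$x
  g_chr <- as.character(data$grade)
  c_chr <- as.character(data$city)
  nonref <- setdiff(data$grades, data$grades[1])
  for (g in nonref) D[g_chr == g, paste0("b_", g)] <- 1
  for (city in data$cities) D[c_chr == city, paste0("u0_", city)] <- 1
  for (g in nonref) {
    for (city in data$cities) {
      D[g_chr == g & c_chr == city, paste0("u_", g, "_", city)] <- 1
    }
  }
  D
}

# n x ndraws matrix of expected richness mu_i per retained draw
mu_draws <- function(fit) {
  draws <- all_draws(fit)
  D <- linear_design(fit$data, fit$par_names)
  eta <- fit$data$offset + D %*% t(draws)
  exp(eta)
}

#' Per-neighborhood posterior predictions of expected richness
#'
#' Quantiles (2.5, 50, 97.5%) of each neighborhood's expected richness
#' `mu_i` across all retained draws; `mu_i` includes the neighborhood's own
#' area-by-effort offset.
#'
#' @param fit A [sample_posterior()] result.
#' @return Tibble `neighborhood_id`, `city`, `holc_grade`, `median`,
#'   `lower`, `upper`.
#' @export
predict_neighborhood_richness <- function(fit) {
  stopifnot(inherits(fit, "richness_fit"))
  mu <- mu_draws(fit)
  qs <- t(apply(mu, 1, quantile, probs = c(0.025, 0.5, 0.975)))
  tibble::tibble(
    neighborhood_id = fit$data$tbl$neighborhood_id,
    city = as.character(fit$data$city),
    holc_grade = as.character(fit$data$grade),
    median = qs[, 2],
    lower = qs[, 1],
    upper = qs[, 3]
  )
}

# Per-draw grade-level mean richness.
#  - city level: for each (city, grade), the draw-wise average of mu_i over
#    that cell's neighborhoods.
#  - overall level: for each draw, a hypothetical city is drawn from the
#    fitted random-effect distributions (one intercept deviation shared
#    across grades, one slope deviation per non-reference grade) and
#    evaluated at the grade's average offset and covariate.
grade_mean_draws <- function(fit, level = c("city", "overall"), seed = 1L) {
  level <- match.arg(level)
  data <- fit$data
  draws <- all_draws(fit)
  grades <- data$grades
  nonref <- setdiff(grades, grades[1])
  if (level == "city") {
    mu <- mu_draws(fit)
    cells <- distinct(tibble::tibble(city = as.character(data$city),
                                     holc_grade = as.character(data$grade)))
    cells <- arrange(cells, .data$city, .data$holc_grade)
    out <- lapply(seq_len(nrow(cells)), function(i) {
      rows <- which(as.character(data$city) == cells$city[i] &
                    as.character(data$grade) == cells$holc_grade[i])
      colMeans(mu[rows, , drop = FALSE])
    })
    names(out) <- paste(cells$city, cells$holc_grade, sep = "|")
    list(level = "city", cells = cells, draws = do.call(cbind, out))
  } else {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(as.integer(seed))
    nd <- nrow(draws)
    u0_star <- rnorm(nd, 0, draws[, "sigma_0"])
    g_chr <- as.character(data$grade)
    out <- matrix(NA_real_, nd, length(grades),
                  dimnames = list(NULL, grades))
    for (g in grades) {
      rows <- which(g_chr == g)
      off_bar <- mean(data$offset[rows])
      x_bar <- if (isTRUE(data$include_x)) mean(data$x[rows]) else 0
      eta <- off_bar + draws[, "b0"] + u0_star +
        (if (isTRUE(data$include_x)) draws[, "b_imp"] * x_bar else 0)
      if (g %in% nonref) {
        ug_star <- rnorm(nd, 0, draws[, paste0("sigma_", g)])
        eta <- eta + draws[, paste0("b_", g)] + ug_star
      }
      out[, g] <- exp(eta)
    }
    cells <- tibble::tibble(city = "ALL", holc_grade = grades)
    colnames(out) <- paste("ALL", grades, sep = "|")
    list(level = "overall", cells = cells, draws = out)
  }
}

#' Grade-level mean richness with 95% credible intervals
#'
#' The Table-1-style summary. At the `"city"` level each (city, grade) cell
#' is the draw-wise average expected richness of its neighborhoods. At the
#' `"overall"` level (`city = "ALL"`) grade means marginalize over a new
#' city drawn from the fitted random-effect distributions, so the intervals
#' include between-city variance and are wider than any within-city
#' interval.
#'
#' @param fit A [sample_posterior()] result.
#' @param level `"city"` or `"overall"`.
#' @param seed Seed for the overall level's random-effect marginalization.
#' @return Tibble `city`, `holc_grade`, `mean`, `median`, `lower`, `upper`.
#' @export
summarize_grades <- function(fit, level = c("city", "overall"), seed = 1L) {
  level <- match.arg(level)
  gm <- grade_mean_draws(fit, level, seed)
  qs <- t(apply(gm$draws, 2, quantile, probs = c(0.025, 0.5, 0.975)))
  gm$cells %>%
    mutate(
      mean = colMeans(gm$draws),
      median = qs[, 2],
      lower = qs[, 1],
      upper = qs[, 3]
    ) %>%
    arrange(.data$city, .data$holc_grade)
}

#' Pairwise grade contrasts of mean richness
#'
#' For every grade pair, the draw-wise difference of grade-level mean
#' richness (response scale, as in [summarize_grades()]), summarized by its
#' posterior median and 95% credible interval; a contrast is flagged
#' significant when the interval excludes zero. No multiplicity correction
#' is applied across the contrasts.
#'
#' @inheritParams summarize_grades
#' @return Tibble `city`, `grade_1`, `grade_2`, `median`, `lower`, `upper`,
#'   `significant` (difference is grade_1 minus grade_2).
#' @export
grade_contrasts <- function(fit, level = c("overall", "city"), seed = 1L) {
  level <- match.arg(level)
  gm <- grade_mean_draws(fit, level, seed)
  cells <- gm$cells
  rows <- list()
  for (city in unique(cells$city)) {
    gr <- cells$holc_grade[cells$city == city]
    if (length(gr) < 2) next
    pairs <- utils::combn(sort(gr), 2)
    for (j in seq_len(ncol(pairs))) {
      g1 <- pairs[1, j]; g2 <- pairs[2, j]
      diff <- gm$draws[, paste(city, g1, sep = "|")] -
        gm$draws[, paste(city, g2, sep = "|")]
      ci <- quantile(diff, c(0.025, 0.975))
      rows[[length(rows) + 1]] <- tibble::tibble(
        city = city, grade_1 = g1, grade_2 = g2,
        median = median(diff), lower = ci[[1]], upper = ci[[2]],
        significant = ci[[1]] > 0 | ci[[2]] < 0
      )
    }
  }
  bind_rows(rows)
}

#' Bar-and-interval plot of grade-level richness
#'
#' @param object A [summarize_grades()] tibble.
#' @param ... Unused.
#' @return A ggplot object: grade means with 95% credible intervals,
#'   faceted by city.
#' @export
plot_grade_richness <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$holc_grade, y = .data$mean,
                                       fill = .data$holc_grade)) +
    ggplot2::geom_col() +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$lower, ymax = .data$upper), width = 0.25) +
    ggplot2::facet_wrap(~city, scales = "free_y") +
    ggplot2::scale_fill_manual(values = c(A = "#4daf4a", B = "#377eb8",
                                          C = "#ffff99", D = "#e41a1c"),
                               guide = "none") +
    ggplot2::labs(x = "HOLC grade", y = "expected species richness") +
    ggplot2::theme_minimal()
}
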