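# Species-accumulation (collector's) curves per stratum, the
# observations-to-reach comparison between strata, and the closed-form
# rarefaction expectation that serves as the analytic oracle for
# permutation-averaged curves.

#' Accumulated species richness for one record stream
#'
#' Walks the records in order and counts cumulative distinct species: record
#' k increments the curve exactly when its species is unseen among records
#' 1..k-1, so repeat observations add to the observation count but not to
#' richness.
#'
#' @param records Record tibble; every record must have a non-missing
#'   `species`. Chronological order sorts by `observed_on` with ties broken
#'   by `record_id`.
#' @param order `"chronological"` (default) or `"permuted"` (uniform random
#'   order under `seed`).
#' @param seed Seed for the permuted order.
#' @return Tibble with columns `k` (observation count) and `s` (accumulated
#'   richness); zero rows for an empty stream.
#' @export
accumulate_curve <- function(records, order = c("chronological", "permuted"),
                             seed = 1L) {
  order <- match.arg(order)
  if (nrow(records) == 0) {
    return(tibble::tibble(k = integer(), s = integer()))
  }
  if (any(is.na(records$species) | !nzchar(records$species))) {
    abort("every record needs a species name; filter first")
  }
  idx <- if (order == "chronological") {
    if (is.null(records$record_id)) {
      order(records$observed_on)
    } else {
      order(records$observed_on, records$record_id)
    }
  } else {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(as.integer(seed))
    sample.int(nrow(records))
  }
  sp <- records$species[idx]
  tibble::tibble(k = seq_along(sp), s = cumsum(!duplicated(sp)))
}

#' Accumulation curves for every stratum
#'
#' Splits records by one or more stratifying columns (typically
#' `holc_grade`, optionally with `city`, `clade`, or the native flag) and
#' computes one accumulation curve per stratum.
#'
#' @inheritParams accumulate_curve
#' @param by Character vector of stratifying column names; the stratum label
#'   joins their values with `"/"`.
#' @return Tibble `stratum`, `k`, `s` of class `accumulation_curves`.
#' @export
accumulation_curves <- function(records, by = "holc_grade",
                                order = c("chronological", "permuted"),
                                seed = 1L) {
  order <- match.arg(order)
  missing_cols <- setdiff(by, names(records))
  if (length(missing_cols)) {
    abort(paste0("records lack stratifying column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  strata <- records %>%
    mutate(stratum = do.call(paste, c(unname(as.list(records[by])), sep = "/")))
  out <- strata %>%
    group_by(.data$stratum) %>%
    dplyr::group_modify(~ accumulate_curve(.x, order = order, seed = seed)) %>%
    ungroup()
  class(out) <- c("accumulation_curves", class(out))
  out
}

#' Observations needed to reach a target richness
#'
#' @param curve Accumulation-curve tibble (`k`, `s`) from
#'   [accumulate_curve()].
#' @param target_richness Target richness (>= 1).
#' @return The smallest `k` with `s >= target_richness`, or `NA` when the
#'   curve never reaches the target.
#' @export
observations_to_reach <- function(curve, target_richness) {
  if (nrow(curve) == 0) abort("empty curve")
  if (target_richness < 1) abort("`target_richness` must be >= 1")
  hit <- which(curve$s >= target_richness)
  if (!length(hit)) return(NA_integer_)
  curve$k[hit[1]]
}

#' Compare strata to a reference stratum's maximum richness
#'
#' Takes the reference stratum's final (maximum observed) richness `S*` and,
#' for every stratum, finds the observation count needed to reach `S*` and
#' the difference from the reference's own count (the delta of the
#' accumulation comparison). Strata that never reach `S*` are flagged
#' unreached with a missing delta.
#'
#' @param curves An [accumulation_curves()] tibble.
#' @param reference Reference stratum label (default `"A"`, the greenlined
#'   grade).
#' @return Tibble `stratum`, `s_star`, `obs_to_reach`, `delta`, `reached`.
#' @export
compare_to_reference <- function(curves, reference = "A") {
  if (!reference %in% curves$stratum) {
    abort(sprintf("reference stratum `%s` not present", reference))
  }
  ref <- filter(curves, .data$stratum == reference)
  s_star <- max(ref$s)
  ref_obs <- observations_to_reach(ref, s_star)
  curves %>%
    group_by(.data$stratum) %>%
    summarise(
      s_star = s_star,
      obs_to_reach = observations_to_reach(dplyr::pick("k", "s"), s_star),
      .groups = "drop"
    ) %>%
    mutate(
      delta = .data$obs_to_reach - ref_obs,
      reached = !is.na(.data$obs_to_reach)
    )
}

#' Expected richness under rarefaction (closed form)
#'
#' Expected number of distinct species in a uniform random subsample of `k`
#' records drawn without replacement:
#' `E[S_k] = sum_s (1 - choose(N - n_s, k) / choose(N, k))` over species `s`
#' with `n_s` records and `N` records in total. This is the analytic oracle
#' the permutation-averaged accumulation curves are checked against.
#'
#' @param species_counts Named (or unnamed) vector of per-species record
#'   counts.
#' @param k Subsample size(s), each between 0 and `sum(species_counts)`.
#' @return Numeric vector of expectations, one per `k`.
#' @examples
#' expected_rarefaction(c(a = 2, b = 1), 2) # 5/3
#' @export
expected_rarefaction <- function(species_counts, k) {
  species_counts <- species_counts[species_counts > 0]
  n_total <- sum(species_counts)
  if (any(k > n_total)) abort("`k` cannot exceed the total record count")
  if (any(k < 0)) abort("`k` must be non-negative")
  vapply(k, function(kk) {
    # log-scale hypergeometric tail: P(species s absent from the subsample)
    p_absent <- exp(lchoose(n_total - species_counts, kk) - lchoose(n_total, kk))
    sum(1 - p_absent)
  }, numeric(1))
}

#' @rdname expected_rarefaction
#' @details `rarefaction_sd()` gives the exact standard deviation of the
#'   subsample richness, from the per-species and pairwise joint absence
#'   probabilities; dividing by the square root of the replicate count gives
#'   the exact Monte-Carlo standard error of a mean accumulation curve.
#' @export
rarefaction_sd <- function(species_counts, k) {
  species_counts <- species_counts[species_counts > 0]
  n_total <- sum(species_counts)
  if (any(k > n_total)) abort("`k` cannot exceed the total record count")
  if (any(k < 0)) abort("`k` must be non-negative")
  vapply(k, function(kk) {
    p <- exp(lchoose(n_total - species_counts, kk) - lchoose(n_total, kk))
    pp <- exp(lchoose(outer(n_total - species_counts, species_counts, "-"),
                      kk) - lchoose(n_total, kk))
    diag(pp) <- 0
    v <- sum(p * (1 - p)) + sum(pp - outer(p, p)) + sum(p^2)
    sqrt(max(v, 0))
  }, numeric(1))
}

#' @export
autoplot.accumulation_curves <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$k, y = .data$s,
                                       colour = .data$stratum)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "observations", y = "accumulated species richness",
                  colour = "stratum") +
    ggplot2::theme_minimal()
}
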