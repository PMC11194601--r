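# Beta diversity: presence-absence community matrices, Jaccard
# dissimilarities (0 = identical assemblages, 1 = completely disjoint), and
# PERMANOVA with sequential sums of squares and permutation p-values.
# Note: one reading of the field's prose flips the 0/1 direction; the
# conventional dissimilarity direction is used throughout.

#' Build a neighborhood-by-species presence-absence matrix
#'
#' Cell (i, s) is 1 when neighborhood i has at least one record of species s
#' under the chosen subset. Neighborhoods left with no species are dropped
#' and counted.
#'
#' @param records Records with `neighborhood_id` (see
#'   [assign_points_to_polygons()]).
#' @param subset As in [richness_table()].
#' @return Integer 0/1 matrix with neighborhood-id rownames and species
#'   colnames; attributes `subset` and `n_dropped_rows`.
#' @export
build_presence_matrix <- function(records, subset = "all") {
  if (nrow(records) == 0) abort("empty record set")
  sub <- subset_records(records, subset)
  ids <- sort(unique(records$neighborhood_id))
  species <- sort(unique(sub$species))
  m <- matrix(0L, length(ids), length(species),
              dimnames = list(ids, species))
  m[cbind(match(sub$neighborhood_id, ids), match(sub$species, species))] <- 1L
  empty <- rowSums(m) == 0
  out <- m[!empty, , drop = FALSE]
  attr(out, "subset") <- subset
  attr(out, "n_dropped_rows") <- sum(empty)
  out
}

#' Jaccard dissimilarity matrix
#'
#' `d(A, B) = 1 - |A intersect B| / |A union B|` over the species sets of
#' each pair of rows: 0 for identical assemblages, 1 for disjoint ones.
#'
#' @param m 0/1 presence matrix without all-zero rows (see
#'   [build_presence_matrix()]).
#' @return Square symmetric numeric matrix with zero diagonal and the input
#'   rownames as labels.
#' @export
jaccard_matrix <- function(m) {
  m <- as.matrix(m)
  if (!all(m %in% c(0, 1))) abort("presence matrix entries must be 0/1")
  if (any(rowSums(m) == 0)) abort("all-zero rows must be excluded first")
  inter <- tcrossprod(m)
  sizes <- rowSums(m)
  union <- outer(sizes, sizes, "+") - inter
  d <- 1 - inter / union
  diag(d) <- 0
  dimnames(d) <- list(rownames(m), rownames(m))
  d
}

#' PERMANOVA with sequential sums of squares
#'
#' Partitions the total sum of squared dissimilarities by the model terms in
#' order (Type-I), using the Gower-centered inner-product matrix
#' `G = -1/2 C A C` with `A = d^2`: each term's SS is the trace of its
#' incremental projection applied to `G`, the pseudo-F is the ratio of
#' term to residual mean squares, and p-values come from free permutation of
#' the observation labels with the "include the observed" convention
#' `p = (1 + #{F* >= F}) / (1 + n_perm)`. With `exhaustive = TRUE` all `n!`
#' label permutations are enumerated and `p = #{F* >= F} / n!` (the identity
#' permutation included), exact for small n.
#'
#' @param d Square symmetric dissimilarity matrix with row labels.
#' @param data Data frame of factors, one row per object, aligned with `d`'s
#'   labels (matched by rowname when present).
#' @param terms Character vector of column names in `data`, in model order.
#' @param n_perm Number of random permutations (ignored when
#'   `exhaustive = TRUE`).
#' @param seed Integer seed for the permutations.
#' @param exhaustive Enumerate all permutations (requires n <= 8).
#' @return A `permanova` tibble: one row per term plus `Residual` and
#'   `Total` rows, with columns `term`, `df`, `ss`, `r_squared`,
#'   `pseudo_f`, `p_value`; attributes `n_perm` and `seed`.
#' @export
permanova <- function(d, data, terms, n_perm = 10000, seed = 1L,
                      exhaustive = FALSE) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (n != ncol(d) || any(abs(d - t(d)) > 1e-10)) {
    abort("`d` must be a square symmetric matrix")
  }
  if (nrow(data) != n) abort("`data` must have one row per object in `d`")
  if (!is.null(rownames(d)) && !is.null(data[["neighborhood_id"]])) {
    data <- data[match(rownames(d), data[["neighborhood_id"]]), , drop = FALSE]
  }
  missing_terms <- setdiff(terms, names(data))
  if (length(missing_terms)) {
    abort(paste0("`data` lacks term column(s): ",
                 paste(missing_terms, collapse = ", ")))
  }
  fac <- lapply(terms, function(tm) factor(data[[tm]]))
  names(fac) <- terms
  for (tm in terms) {
    if (nlevels(fac[[tm]]) < 2) {
      abort(sprintf("term `%s` has a single level", tm))
    }
  }
  model_df <- sum(vapply(fac, nlevels, integer(1)) - 1L)
  if (n < model_df + 2) abort("too few observations for the model terms")

  G <- gower_center(d)
  hats <- sequential_hats(fac, n)
  obs <- permanova_stats(G, hats)
  if (any(!is.finite(obs$f))) {
    abort("degenerate dissimilarities: residual sum of squares is zero")
  }

  exceed <- rep(0, length(terms))
  if (exhaustive) {
    if (n > 8) abort("exhaustive enumeration is limited to n <= 8")
    perms <- all_permutations(n)
    for (j in seq_len(ncol(perms))) {
      p <- perms[, j]
      fs <- permanova_stats(G[p, p], hats)$f
      exceed <- exceed + (fs >= obs$f - 1e-12)
    }
    p_values <- exceed / ncol(perms)
    n_perm_used <- ncol(perms)
  } else {
    if (n_perm < 1) abort("`n_perm` must be >= 1")
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(as.integer(seed))
    for (j in seq_len(n_perm)) {
      p <- sample.int(n)
      fs <- permanova_stats(G[p, p], hats)$f
      exceed <- exceed + (fs >= obs$f - 1e-12)
    }
    p_values <- (1 + exceed) / (1 + n_perm)
    n_perm_used <- n_perm
  }

  ss_total <- sum(diag(G))
  out <- tibble::tibble(
    term = c(terms, "Residual", "Total"),
    df = c(obs$df, n - 1 - model_df, n - 1),
    ss = c(obs$ss, obs$ss_res, ss_total),
    r_squared = c(obs$ss, obs$ss_res, ss_total) / ss_total,
    pseudo_f = c(obs$f, NA_real_, NA_real_),
    p_value = c(p_values, NA_real_, NA_real_)
  )
  attr(out, "n_perm") <- n_perm_used
  attr(out, "seed") <- if (exhaustive) NA_integer_ else as.integer(seed)
  class(out) <- c("permanova", class(out))
  out
}

gower_center <- function(d) {
  n <- nrow(d)
  A <- -0.5 * d^2
  C <- diag(n) - matrix(1 / n, n, n)
  C %*% A %*% C
}

# Incremental projection matrices for sequential (Type-I) SS: one per term,
# plus the residual projector.
sequential_hats <- function(fac, n) {
  X <- matrix(1, n, 1)
  H_prev <- hat_matrix(X)
  hat_diffs <- vector("list", length(fac))
  dfs <- integer(length(fac))
  rank_prev <- 1L
  for (k in seq_along(fac)) {
    X <- cbind(X, stats::model.matrix(~ f - 1, data.frame(f = fac[[k]])))
    H_k <- hat_matrix(X)
    rank_k <- qr(X)$rank
    hat_diffs[[k]] <- H_k - H_prev
    dfs[k] <- rank_k - rank_prev
    H_prev <- H_k
    rank_prev <- rank_k
  }
  list(diffs = hat_diffs, resid = diag(n) - H_prev, dfs = dfs,
       df_res = n - rank_prev)
}

hat_matrix <- function(X) {
  q <- qr(X)
  Q <- qr.Q(q)[, seq_len(q$rank), drop = FALSE]
  tcrossprod(Q)
}

permanova_stats <- function(G, hats) {
  ss <- vapply(hats$diffs, function(H) sum(H * G), numeric(1))
  ss_res <- sum(hats$resid * G)
  f <- (ss / hats$dfs) / (ss_res / hats$df_res)
  list(ss = ss, ss_res = ss_res, f = f, df = hats$dfs)
}

# all n! permutations of 1..n as the columns of an n x n! matrix
all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1)
  blocks <- vector("list", n)
  for (pos in seq_len(n)) {
    top <- if (pos > 1) sub[seq_len(pos - 1), , drop = FALSE] else NULL
    bot <- if (pos <= n - 1) sub[seq(pos, n - 1), , drop = FALSE] else NULL
    blocks[[pos]] <- rbind(top, matrix(n, 1, ncol(sub)), bot)
  }
  do.call(cbind, blocks)
}

#' Pairwise grade PERMANOVAs within each city
#'
#' For every city and every pair of HOLC grades, runs a two-group PERMANOVA
#' restricted to that city's neighborhoods; p-values are
#' Benjamini-Hochberg-adjusted across the grade pairs within each city.
#' Pairs with fewer than two neighborhoods in either grade are reported as
#' untestable.
#'
#' @param d Dissimilarity matrix labeled by neighborhood id.
#' @param data Tibble with `neighborhood_id`, `city`, and `holc_grade`.
#' @param n_perm,seed Permutation settings (see [permanova()]).
#' @return Tibble `city`, `grade_1`, `grade_2`, `pseudo_f`, `p_value`,
#'   `p_adjusted`, `testable`, `stars`.
#' @export
pairwise_permanova <- function(d, data, n_perm = 10000, seed = 1L) {
  d <- as.matrix(d)
  if (!is.null(rownames(d))) {
    data <- data[match(rownames(d), data[["neighborhood_id"]]), , drop = FALSE]
  }
  rows <- list()
  cities <- sort(unique(data$city))
  pair_seed <- as.integer(seed)
  for (city in cities) {
    in_city <- data$city == city
    grades <- sort(unique(data$holc_grade[in_city]))
    if (length(grades) < 2) next
    pairs <- utils::combn(grades, 2)
    for (j in seq_len(ncol(pairs))) {
      g1 <- pairs[1, j]; g2 <- pairs[2, j]
      sel <- which(in_city & data$holc_grade %in% c(g1, g2))
      ok <- sum(data$holc_grade[sel] == g1) >= 2 &&
        sum(data$holc_grade[sel] == g2) >= 2
      if (!ok) {
        rows[[length(rows) + 1]] <- tibble::tibble(
          city = city, grade_1 = g1, grade_2 = g2,
          pseudo_f = NA_real_, p_value = NA_real_, testable = FALSE
        )
        next
      }
      pair_seed <- pair_seed + 1L
      res <- permanova(d[sel, sel, drop = FALSE],
                       data[sel, , drop = FALSE],
                       terms = "holc_grade", n_perm = n_perm,
                       seed = pair_seed)
      rows[[length(rows) + 1]] <- tibble::tibble(
        city = city, grade_1 = g1, grade_2 = g2,
        pseudo_f = res$pseudo_f[1], p_value = res$p_value[1],
        testable = TRUE
      )
    }
  }
  out <- bind_rows(rows)
  out <- out %>%
    group_by(.data$city) %>%
    mutate(p_adjusted = replace_testable(.data$p_value)) %>%
    ungroup() %>%
    mutate(stars = dplyr::case_when(
      is.na(.data$p_adjusted) ~ "",
      .data$p_adjusted < 0.001 ~ "***",
      .data$p_adjusted < 0.01 ~ "**",
      .data$p_adjusted < 0.05 ~ "*",
      TRUE ~ ""
    ))
  out
}

replace_testable <- function(p) {
  out <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  out[ok] <- bh_adjust(p[ok])
  out
}

#' Benjamini-Hochberg step-up adjustment
#'
#' False-discovery-rate control across a family of p-values: sort ascending,
#' take `adj_(i) = min_(j >= i) m p_(j) / j` capped at 1, and map back to the
#' input order.
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values in input order.
#' @examples
#' bh_adjust(c(0.04, 0.5)) # 0.08, 0.50
#' @export
bh_adjust <- function(p_values) {
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1)) {
    abort("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}

#' @export
glance.permanova <- function(x, ...) {
  terms <- filter(x, !.data$term %in% c("Residual", "Total"))
  tibble::tibble(
    n_terms = nrow(terms),
    n_perm = attr(x, "n_perm"),
    min_p = min(terms$p_value)
  )
}
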