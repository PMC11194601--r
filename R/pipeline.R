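# End-to-end orchestration: simulate -> ingest -> accumulate -> alpha ->
# beta -> report, with per-stage seeds derived deterministically from one
# master seed so stages are individually reproducible and independent.

#' Pipeline run configuration
#'
#' @param out_dir Directory for all stage outputs (created if needed).
#' @param master_seed Integer master seed; each stage uses
#'   [stage_seed()]`(master_seed, stage)`.
#' @param stages Character vector of stages to run, in fixed order
#'   `simulate, ingest, accumulate, alpha, beta`.
#' @param region,community Configurations for the simulate stage.
#' @param truth Optional [truth_params()] written alongside the simulated
#'   data for downstream recovery checks.
#' @param inputs Named list of existing input paths (`geojson`,
#'   `records_csv`, `grid_asc`); required when the simulate stage is
#'   skipped, validated before any stage runs.
#' @param window_start,window_end Study date window (half-open).
#' @param min_per_cell City-inclusion threshold (records per grade x clade
#'   cell).
#' @param mcmc_profile `"paper"` or `"test"` MCMC lengths for the alpha
#'   stage.
#' @param n_perm Permutations for the beta stage.
#' @param stage_seeds Named list of per-stage seed overrides; unnamed stages
#'   keep their derived seed, so overriding one stage leaves the others'
#'   random streams untouched.
#' @return A `run_config` list.
#' @export
run_config <- function(out_dir,
                       master_seed = 1L,
                       stages = c("simulate", "ingest", "accumulate",
                                  "alpha", "beta"),
                       region = region_config(),
                       community = community_config(),
                       truth = NULL,
                       inputs = NULL,
                       window_start = as.Date("2017-01-01"),
                       window_end = as.Date("2022-01-01"),
                       min_per_cell = 5,
                       mcmc_profile = c("test", "paper"),
                       n_perm = 10000,
                       stage_seeds = list()) {
  mcmc_profile <- match.arg(mcmc_profile)
  known <- c("simulate", "ingest", "accumulate", "alpha", "beta")
  bad <- setdiff(stages, known)
  if (length(bad)) {
    abort(paste0("unknown stage(s): ", paste(bad, collapse = ", ")))
  }
  structure(
    list(out_dir = out_dir, master_seed = as.integer(master_seed),
         stages = known[known %in% stages], region = region,
         community = community, truth = truth, inputs = inputs,
         window_start = as.Date(window_start),
         window_end = as.Date(window_end),
         min_per_cell = min_per_cell, mcmc_profile = mcmc_profile,
         n_perm = n_perm, stage_seeds = stage_seeds),
    class = "run_config"
  )
}

#' Deterministic per-stage seed
#'
#' Hashes the master seed with the stage name so changing one stage's seed
#' (or adding stages) never perturbs another stage's random stream.
#'
#' @param master_seed Integer master seed.
#' @param stage Stage name.
#' @return An integer seed in `[1, 2^31 - 2]`.
#' @export
stage_seed <- function(master_seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)) * 131L)
  as.integer((as.double(master_seed) * 48271 + h) %% (2^31 - 2)) + 1L
}

#' Run the pipeline end to end
#'
#' Stages run in fixed order; each stage's outputs are written to
#' `config$out_dir` before the next starts. The returned manifest records
#' every seed, output path and row count.
#'
#' @param config A [run_config()].
#' @return A `run_manifest` list (per-stage `outputs`, `seed`, row counts,
#'   and in-memory results for downstream use).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  validate_run_config(config)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(version = pkg_version_string(),
                   master_seed = config$master_seed, stages = list())

  paths <- config$inputs %||% list()
  seed_for <- function(stage) {
    as.integer(config$stage_seeds[[stage]] %||%
                 stage_seed(config$master_seed, stage))
  }
  run_stage <- function(stage, fn) {
    if (!stage %in% config$stages) return(invisible(NULL))
    res <- tryCatch(fn(), error = function(e) {
      abort(sprintf("stage `%s` failed: %s", stage, conditionMessage(e)),
            parent = e)
    })
    manifest$stages[[stage]] <<- res
  }

  run_stage("simulate", function() {
    seed <- seed_for("simulate")
    region <- make_region(config$region, seed = seed)
    records <- simulate_observation_records(region, config$community,
                                            seed = seed + 1L)
    paths$geojson <<- file.path(config$out_dir, "region.geojson")
    paths$records_csv <<- file.path(config$out_dir, "records.csv")
    paths$grid_asc <<- file.path(config$out_dir, "impervious.asc")
    write_region_geojson(region, paths$geojson)
    write_records_csv(records, paths$records_csv, seed = seed + 1L)
    write_impervious_asc(region$grid, paths$grid_asc, seed = seed)
    if (!is.null(config$truth)) {
      write_truth(config$truth, file.path(config$out_dir, "truth.json"))
    }
    list(seed = seed, n_neighborhoods = nrow(region$neighborhoods),
         n_records = nrow(records),
         outputs = unlist(paths[c("geojson", "records_csv", "grid_asc")]))
  })

  run_stage("ingest", function() {
    nb <- read_holc_geojson(paths$geojson)
    grid <- read_impervious_asc(paths$grid_asc)
    nb$impervious <- vapply(nb$polygon,
                            function(p) zonal_mean_impervious(grid, p),
                            numeric(1))
    rec <- read_observations_csv(paths$records_csv)
    rec <- filter_records(rec, config$window_start, config$window_end)
    filt_rep <- filter_report(rec)
    rec <- assign_points_to_polygons(rec, nb)
    assign_rep <- filter_report(rec)
    rec <- city_clade_inclusion(rec, nb, config$min_per_cell)
    city_rep <- filter_report(rec)
    rich <- richness_table(rec, nb)
    report <- bind_rows(filt_rep, assign_rep, city_rep, filter_report(rich))
    out_nb <- file.path(config$out_dir, "neighborhoods.csv")
    out_rec <- file.path(config$out_dir, "records_assigned.csv")
    out_rich <- file.path(config$out_dir, "richness.csv")
    out_rep <- file.path(config$out_dir, "filter_report.json")
    readr::write_csv(select(nb, -"polygon"), out_nb)
    readr::write_csv(rec, out_rec)
    readr::write_csv(rich, out_rich)
    writeLines(jsonlite::toJSON(report, auto_unbox = TRUE, digits = NA), out_rep)
    list(neighborhoods = nb, records = rec, richness = rich,
         report = report, n_records = nrow(rec), n_neighborhoods = nrow(nb),
         outputs = c(out_nb, out_rec, out_rich, out_rep))
  })

  run_stage("accumulate", function() {
    ing <- manifest$stages$ingest
    if (is.null(ing)) abort("accumulate requires the ingest stage")
    rec <- ing$records %>%
      left_join(select(ing$neighborhoods, "neighborhood_id", "holc_grade"),
                by = "neighborhood_id")
    curves <- accumulation_curves(rec, by = "holc_grade")
    comparison <- compare_to_reference(curves, reference = "A")
    out_curves <- file.path(config$out_dir, "accumulation_curves.csv")
    out_cmp <- file.path(config$out_dir, "accumulation_comparison.csv")
    readr::write_csv(curves, out_curves)
    readr::write_csv(comparison, out_cmp)
    list(curves = curves, comparison = comparison,
         outputs = c(out_curves, out_cmp))
  })

  run_stage("alpha", function() {
    ing <- manifest$stages$ingest
    if (is.null(ing)) abort("alpha requires the ingest stage")
    seed <- seed_for("alpha")
    data <- build_model_data(ing$richness)
    fit <- sample_posterior(data, mcmc = mcmc_config(config$mcmc_profile,
                                                     seed = seed))
    conv <- convergence_report(fit)
    by_city <- summarize_grades(fit, "city")
    overall <- summarize_grades(fit, "overall", seed = seed)
    contrasts <- grade_contrasts(fit, "overall", seed = seed)
    out_sum <- file.path(config$out_dir, "grade_richness.csv")
    out_con <- file.path(config$out_dir, "grade_contrasts.csv")
    out_cnv <- file.path(config$out_dir, "convergence.json")
    readr::write_csv(bind_rows(overall, by_city), out_sum)
    readr::write_csv(contrasts, out_con)
    writeLines(jsonlite::toJSON(
      list(max_rhat = attr(conv, "max_rhat"), pass = attr(conv, "pass"),
           parameters = conv),
      auto_unbox = TRUE, digits = NA), out_cnv)
    list(seed = seed, fit = fit, convergence = conv,
         summary = bind_rows(overall, by_city), contrasts = contrasts,
         outputs = c(out_sum, out_con, out_cnv))
  })

  run_stage("beta", function() {
    ing <- manifest$stages$ingest
    if (is.null(ing)) abort("beta requires the ingest stage")
    seed <- seed_for("beta")
    rec <- ing$records %>%
      left_join(select(ing$neighborhoods, "neighborhood_id", "city",
                       "holc_grade"),
                by = "neighborhood_id")
    pm <- build_presence_matrix(rec)
    d <- jaccard_matrix(pm)
    meta <- ing$richness
    # single-level terms (e.g. one retained city) carry no information
    terms <- c("city", "holc_grade")
    terms <- terms[vapply(terms, function(tm) {
      dplyr::n_distinct(meta[[tm]]) > 1
    }, logical(1))]
    overall <- permanova(d, meta, terms = terms,
                         n_perm = config$n_perm, seed = seed)
    pairwise <- pairwise_permanova(d, meta, n_perm = config$n_perm,
                                   seed = seed + 1L)
    out_d <- file.path(config$out_dir, "jaccard.csv")
    out_ov <- file.path(config$out_dir, "permanova_overall.csv")
    out_pw <- file.path(config$out_dir, "permanova_pairwise.csv")
    utils::write.csv(d, out_d)
    readr::write_csv(overall, out_ov)
    readr::write_csv(pairwise, out_pw)
    list(seed = seed, overall = overall, pairwise = pairwise,
         outputs = c(out_d, out_ov, out_pw))
  })

  class(manifest) <- "run_manifest"
  manifest
}

validate_run_config <- function(config) {
  if ("simulate" %in% config$stages) return(invisible(TRUE))
  needed <- c("geojson", "records_csv", "grid_asc")
  for (key in needed) {
    path <- config$inputs[[key]]
    if (is.null(path) || !file.exists(path)) {
      abort(sprintf(
        "input `%s` is missing or does not exist (%s); nothing was run",
        key, path %||% "unset"))
    }
  }
  invisible(TRUE)
}

#' Render a human-readable pipeline report
#'
#' One table per analysis, grade rows ordered A-D, credible intervals
#' printed as `median (lower, upper)`. Sections whose stage did not run are
#' marked "not run". Regeneration from the same manifest is idempotent.
#'
#' @param manifest A [run_pipeline()] manifest.
#' @return Character vector of report lines, invisibly printable with
#'   `cat(..., sep = "\n")`.
#' @export
render_report <- function(manifest) {
  stopifnot(inherits(manifest, "run_manifest"))
  lines <- c(sprintf("HOLC biodiversity pipeline report (%s, master seed %d)",
                     manifest$version, manifest$master_seed), "")
  fmt_ci <- function(m, lo, hi) sprintf("%.2f (%.2f, %.2f)", m, lo, hi)

  alpha <- manifest$stages$alpha
  lines <- c(lines, "== Species richness by HOLC grade ==")
  if (is.null(alpha)) {
    lines <- c(lines, "not run", "")
  } else {
    s <- alpha$summary %>%
      mutate(holc_grade = factor(.data$holc_grade, levels = holc_grades)) %>%
      arrange(.data$city != "ALL", .data$city, .data$holc_grade)
    lines <- c(lines, sprintf("%-12s %-6s %s", "city", "grade",
                              "mean richness (95% CI)"))
    lines <- c(lines, sprintf("%-12s %-6s %s", s$city, s$holc_grade,
                              fmt_ci(s$mean, s$lower, s$upper)))
    lines <- c(lines, "", "-- Grade contrasts (response scale) --")
    ct <- alpha$contrasts
    lines <- c(lines, sprintf("%s-%s: %s%s", ct$grade_1, ct$grade_2,
                              fmt_ci(ct$median, ct$lower, ct$upper),
                              ifelse(ct$significant, " *", "")))
    lines <- c(lines, sprintf("max Gelman-Rubin rhat: %.4f",
                              attr(alpha$convergence, "max_rhat")), "")
  }

  lines <- c(lines, "== Accumulated species richness ==")
  acc <- manifest$stages$accumulate
  if (is.null(acc)) {
    lines <- c(lines, "not run", "")
  } else {
    cmp <- acc$comparison %>%
      mutate(stratum = factor(.data$stratum, levels = holc_grades)) %>%
      arrange(.data$stratum)
    lines <- c(lines, sprintf(
      "grade %s: S* = %d, observations to reach = %s, delta = %s",
      cmp$stratum, cmp$s_star,
      ifelse(cmp$reached, as.character(cmp$obs_to_reach), "unreached"),
      ifelse(cmp$reached, as.character(cmp$delta), "-")), "")
  }

  lines <- c(lines, "== Beta diversity (PERMANOVA, Jaccard) ==")
  beta <- manifest$stages$beta
  if (is.null(beta)) {
    lines <- c(lines, "not run", "")
  } else {
    ov <- beta$overall
    lines <- c(lines, sprintf(
      "%-12s df=%3d  SS=%8.3f  R2=%.4f  F=%s  p=%s",
      ov$term, ov$df, ov$ss, ov$r_squared,
      ifelse(is.na(ov$pseudo_f), "-", sprintf("%.4f", ov$pseudo_f)),
      ifelse(is.na(ov$p_value), "-", sprintf("%.4f", ov$p_value))))
    pw <- beta$pairwise
    lines <- c(lines, "", "-- Pairwise grade tests (BH-adjusted within city) --",
               sprintf("%-10s %s-%s: F=%s p.adj=%s %s", pw$city, pw$grade_1,
                       pw$grade_2,
                       ifelse(pw$testable, sprintf("%.3f", pw$pseudo_f),
                              "untestable"),
                       ifelse(pw$testable, sprintf("%.4f", pw$p_adjusted), "-"),
                       pw$stars), "")
  }
  lines
}
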