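#' @title End-to-end pipeline orchestration
#' @description Runs the full analysis over a synthetic (or supplied) cohort:
#'   exclusion ledger, scoring of the 13-model family, surface cluster
#'   inference, subcortical partial-correlation screen, seed-based RSFC
#'   second-level analysis and PRS-adjusted reruns, collecting every table in
#'   a single report with provenance.
#' @name pipeline
NULL

#' Pipeline run configuration
#'
#' @param simulation a [cohort_spec()] describing the synthetic cohort.
#' @param stages character subset of
#'   `c("surface", "subcortical", "rsfc", "prs")`; scoring and the exclusion
#'   ledger always run.
#' @param models `"all"` for the full 13-model family or a character vector of
#'   model labels (see [enumerate_models()]).
#' @param mesh_dim grid mesh dimensions for the surface stage.
#' @param n_iter_surface,n_perm_rsfc null-distribution iterations.
#' @param surface_correction `"montecarlo"` or `"permutation"`.
#' @param cluster_forming_p surface cluster-forming threshold (two-sided).
#' @param rsfc_n,rsfc_timepoints participants and frames for the RSFC stage.
#' @param outlier_k SD multiple for score outlier exclusion.
#' @param seed master RNG seed; stage seeds derive from it.
#' @param output_dir optional directory for TSV/JSON outputs.
#' @return List of class `run_config`.
#' @export
run_config <- function(simulation = cohort_spec(),
                       stages = c("surface", "subcortical", "rsfc", "prs"),
                       models = "all",
                       mesh_dim = c(30L, 30L),
                       n_iter_surface = 300L,
                       n_perm_rsfc = 200L,
                       surface_correction = "montecarlo",
                       cluster_forming_p = 0.05,
                       rsfc_n = 40L,
                       rsfc_timepoints = 120L,
                       outlier_k = 3,
                       seed = 1L,
                       output_dir = NULL) {
  stages <- if (length(stages))
    match.arg(stages, c("surface", "subcortical", "rsfc", "prs"),
              several.ok = TRUE)
  else character(0)  # scoring and the exclusion ledger only
  structure(list(simulation = simulation, stages = stages, models = models,
                 mesh_dim = mesh_dim, n_iter_surface = n_iter_surface,
                 n_perm_rsfc = n_perm_rsfc,
                 surface_correction = surface_correction,
                 cluster_forming_p = cluster_forming_p, rsfc_n = rsfc_n,
                 rsfc_timepoints = rsfc_timepoints, outlier_k = outlier_k,
                 seed = as.integer(seed), output_dir = output_dir),
            class = "run_config")
}

config_hash <- function(config) {
  txt <- paste(deparse(config), collapse = "")
  v <- utf8ToInt(txt)
  sprintf("%08x", sum(v * (seq_along(v) %% 97 + 1)) %% .Machine$integer.max)
}

#' Run the full pipeline on a configuration
#'
#' Stage order: simulate, exclusion ledger, scoring (all configured models),
#' surface inference, subcortical screen, RSFC second level, PRS-adjusted
#' surface rerun. Every table is stamped with the model label; reruns with an
#' identical configuration are byte-identical.
#'
#' @param config a [run_config()].
#' @return List of class `run_report`: `ledger` (data.frame of exclusion steps
#'   with counts), `scores` (per-model score table), `surface`, `subcortical`,
#'   `rsfc`, `prs` stage results, and `provenance` (config hash, seed).
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  seed <- config$seed

  cohort <- generate_cohort(config$simulation)
  n0 <- nrow(cohort)
  ledger <- data.frame(step = "available", removed = 0L, remaining = n0)
  note <- function(step, removed, remaining) {
    ledger <<- rbind(ledger, data.frame(step = step, removed = removed,
                                        remaining = remaining))
  }

  cohort <- cohort[!cohort$excl_incidental, , drop = FALSE]
  note("incidental_findings", n0 - nrow(cohort), nrow(cohort))
  n1 <- nrow(cohort)
  cohort <- cohort[!cohort$excl_imaging, , drop = FALSE]
  note("unusable_imaging", n1 - nrow(cohort), nrow(cohort))

  derived <- derive_lifestyle(cohort)
  note("missing_behavior", attr(derived, "n_dropped_missing"), nrow(derived))

  combined <- combine_risk_score(derived[c("ACT", "ALC", "SOC", "SMO")])
  out_mask <- exclude_outliers(combined$score, k = config$outlier_k)
  derived <- derived[!out_mask, , drop = FALSE]
  note("score_outliers", sum(out_mask), nrow(derived))

  # re-standardize over the analysis sample and score every model
  z <- data.frame(ACT = z_transform(derived$met_total),
                  ALC = z_transform(derived$alcohol_g),
                  SOC = z_transform(derived$social_index),
                  SMO = z_transform(derived$pack_years))
  family <- enumerate_models()
  if (!identical(config$models, "all")) {
    labels <- vapply(family, `[[`, character(1), "label")
    family <- family[labels %in% config$models]
  }
  scores <- lapply(family, function(m) combine_risk_score(z, m))
  names(scores) <- vapply(family, `[[`, character(1), "label")
  score_table <- data.frame(id = derived$id,
                            as.data.frame(lapply(scores, `[[`, "score"),
                                          check.names = FALSE))

  covars <- data.frame(age = derived$age, gender = derived$gender)
  main_score <- scores[[1L]]$score
  report <- list(ledger = ledger, scores = score_table, models = names(scores))

  mesh <- NULL
  fields <- NULL
  if ("surface" %in% config$stages) {
    mesh <- grid_mesh(config$mesh_dim[1L], config$mesh_dim[2L])
    center <- round(nrow(mesh$vertices) / 2)
    eff <- planted_effects(cluster_vertices = mesh_disk(mesh, center, 4))
    fields <- generate_surface_data(mesh, main_score, eff, seed = seed + 1L)
    surf <- surface_analysis(fields, main_score, covars, mesh,
                             correction = config$surface_correction,
                             cluster_forming_p = config$cluster_forming_p,
                             n_iter = config$n_iter_surface, seed = seed + 2L)
    report$surface <- list(model = names(scores)[1L], result = surf,
                           planted = eff$cluster_vertices)
  }

  if ("subcortical" %in% config$stages) {
    cov_sub <- data.frame(age = derived$age, gender = derived$gender,
                          tiv = 1.4e6 + 1e5 * stats::rnorm(nrow(derived)))
    vols <- generate_volumes(main_score, cov_sub, seed = seed + 3L)
    screen <- correlation_matrix(lapply(scores, `[[`, "score"), vols, cov_sub)
    report$subcortical <- screen
  }

  if ("rsfc" %in% config$stages) {
    idx <- seq_len(min(config$rsfc_n, nrow(derived)))
    ts_set <- generate_timeseries(main_score[idx],
                                  n_timepoints = config$rsfc_timepoints,
                                  seed = seed + 4L)
    voi <- voi_from_sphere(ts_set$seed_center, 5, ts_set$grid)
    zmaps <- t(vapply(ts_set$bundles,
                      function(b) rsfc_pipeline(b, voi)$z,
                      numeric(prod(ts_set$grid$dim))))
    zmaps[, voi$voxels] <- 0  # exclude seed-member voxels from inference
    fc <- fc_second_level(zmaps, main_score[idx], covars[idx, ], ts_set$grid,
                          cluster_forming_p = 0.001,
                          n_perm = config$n_perm_rsfc, seed = seed + 5L)
    report$rsfc <- list(model = names(scores)[1L], result = fc,
                        target_voxels = ts_set$target_voxels)
  }

  if ("prs" %in% config$stages) {
    panel <- qc_filter(load_snp_panel(candidates = TRUE))
    dosages <- generate_genotypes(panel, nrow(derived), seed = seed + 6L)
    prs <- weighted_score(dosages, panel)
    report$prs <- list(panel_n = nrow(panel), prs = prs)
    if (!is.null(fields)) {
      covars_prs <- adjust_for_prs(covars, prs$prs)
      keep <- !is.na(prs$prs)
      surf_prs <- surface_analysis(fields[keep, , drop = FALSE],
                                   main_score[keep], covars_prs, mesh,
                                   correction = config$surface_correction,
                                   cluster_forming_p = config$cluster_forming_p,
                                   n_iter = config$n_iter_surface,
                                   seed = seed + 2L)
      report$surface_prs <- list(result = surf_prs)
    }
  }

  report$provenance <- list(config_hash = config_hash(config), seed = seed,
                            package_version = as.character(utils::packageVersion("brainrisk")))
  class(report) <- "run_report"

  if (!is.null(config$output_dir)) write_report(report, config$output_dir)
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("run_report (config", x$provenance$config_hash, ")\n")
  cat("exclusion ledger:\n")
  print(x$ledger, row.names = FALSE)
  cat("models scored:", length(x$models), "\n")
  invisible(x)
}

write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(report$ledger, file.path(dir, "exclusion_ledger.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(report$scores, file.path(dir, "model_scores.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  if (!is.null(report$subcortical))
    utils::write.table(as.data.frame(report$subcortical),
                       file.path(dir, "subcortical_screen.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  if (!is.null(report$surface)) {
    cl <- report$surface$result
    tab <- cluster_table(cl)
    utils::write.table(tab, file.path(dir, "surface_clusters.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  invisible(dir)
}

#' Tabulate a cluster result
#'
#' @param x a `cluster_result` (surface) with cwp attached.
#' @return data.frame with peak vertex, size (mm^2), sign and cwp per cluster.
#' @export
cluster_table <- function(x) {
  stopifnot(inherits(x, "cluster_result"))
  if (!length(x$clusters))
    return(data.frame(peak_vertex = integer(0), area_mm2 = numeric(0),
                      sign = integer(0), cwp = numeric(0)))
  data.frame(peak_vertex = vapply(x$clusters, `[[`, numeric(1), "peak_vertex"),
             area_mm2 = vapply(x$clusters, `[[`, numeric(1), "area_mm2"),
             sign = vapply(x$clusters, `[[`, numeric(1), "sign"),
             cwp = if (is.null(x$cwp)) NA_real_ else x$cwp)
}

#' Concordance between matched runs with different covariate sets
#'
#' Compares two surface cluster results from the same data analysed with
#' different covariate sets (e.g. with and without PRS adjustment): Dice
#' overlap of the significant vertex sets and agreement of the
#' significance decision.
#'
#' @param result_a,result_b `cluster_result` objects with `cwp`.
#' @param cwp_threshold significance level (default 0.01).
#' @return List with `dice`, `significant_a`, `significant_b`, `concordant`
#'   (logical: same significance status).
#' @export
compare_covariate_sets <- function(result_a, result_b, cwp_threshold = 0.01) {
  sig_vertices <- function(r) {
    if (is.null(r$cwp) || !length(r$clusters)) return(integer(0))
    idx <- which(r$cwp < cwp_threshold)
    if (!length(idx)) return(integer(0))
    sort(unique(unlist(lapply(r$clusters[idx], `[[`, "vertices"))))
  }
  a <- sig_vertices(result_a)
  b <- sig_vertices(result_b)
  dice <- if (!length(a) && !length(b)) 1
          else 2 * length(intersect(a, b)) / (length(a) + length(b))
  list(dice = dice, significant_a = length(a) > 0, significant_b = length(b) > 0,
       concordant = (length(a) > 0) == (length(b) > 0))
}
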