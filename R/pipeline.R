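# End-to-end orchestration: simulate/load -> harmonize -> MS matrices ->
# node & subnetwork comparisons -> NBS -> graph metrics -> clinical
# associations, with a run manifest. The numbered scripts under analysis/
# are thin narrative drivers over these functions.

#' Pipeline configuration
#'
#' @param cohort Either an `ms_cohort` or a directory readable by
#'   [read_cohort()].
#' @param output_dir Directory for the report bundle (created if needed).
#' @param run_combat Harmonize sites before analysis (default TRUE).
#' @param nbs_directions Which one-sided NBS analyses to run.
#' @param nbs_alpha Family-wise alpha for NBS components.
#' @param n_permutations NBS permutations.
#' @param candidate_grid Candidate sparsity grid.
#' @param n_random_surrogates Surrogates per small-worldness estimate.
#' @param sigma_min Small-worldness criterion (default 1.1).
#' @param fdr_alpha BH-FDR significance level.
#' @param edge_universe Optional override of the edge count used for the
#'   Bonferroni-derived initial NBS threshold (default C(N,2); the override
#'   exists so a printed, slightly different connection count can be
#'   reproduced exactly).
#' @param seed Master seed; all stage seeds derive from it.
#' @return A list of class `ms_pipeline_config`.
#' @export
pipeline_config <- function(cohort, output_dir,
                            run_combat = TRUE,
                            nbs_directions = c("HC_gt_SCZ", "HC_lt_SCZ"),
                            nbs_alpha = 0.05,
                            n_permutations = 5000L,
                            candidate_grid = sparsity_grid(),
                            n_random_surrogates = 20L,
                            sigma_min = 1.1,
                            fdr_alpha = 0.05,
                            edge_universe = NULL,
                            seed = 1L) {
  structure(list(cohort = cohort, output_dir = output_dir,
                 run_combat = isTRUE(run_combat),
                 nbs_directions = match.arg(nbs_directions,
                                            c("HC_gt_SCZ", "HC_lt_SCZ"),
                                            several.ok = TRUE),
                 nbs_alpha = nbs_alpha,
                 n_permutations = as.integer(n_permutations),
                 candidate_grid = candidate_grid,
                 n_random_surrogates = as.integer(n_random_surrogates),
                 sigma_min = sigma_min, fdr_alpha = fdr_alpha,
                 edge_universe = edge_universe,
                 seed = as.integer(seed)),
            class = "ms_pipeline_config")
}

#' Demo cohort configuration
#'
#' A desk-scale analogue of the four-site case-control study the package
#' emulates: 60 regions, 40 + 40 subjects over four sites, with a
#' half-strength decorrelation effect implanted in 6 patient-group regions.
#' @param seed Integer seed.
#' @param n_regions,n_hc,n_scz Scale overrides.
#' @param effect_regions 0-based ids (default: 6 spread regions).
#' @param effect_strength Decorrelation fraction.
#' @return An `ms_cohort_config`.
#' @export
demo_cohort_config <- function(seed = 42L, n_regions = 60L,
                               n_hc = 40L, n_scz = 40L,
                               effect_regions = c(3L, 12L, 21L, 30L, 39L, 48L),
                               effect_strength = 0.5) {
  cohort_config(n_regions = n_regions, n_hc = n_hc, n_scz = n_scz,
                sites = default_sites(),
                effect_regions = effect_regions,
                effect_strength = effect_strength,
                seed = seed)
}

.stage_msg <- function(...) message("[mscortex] ", ...)

#' Run the full MS-network analysis pipeline
#'
#' Produces, under `config$output_dir`: regional and subnetwork MS
#' comparison tables, NBS component tables for both directions, the global
#' network measure table, nodal measure comparisons, clinical association
#' tables, and a JSON run manifest recording seeds, thresholds and counts.
#'
#' @param config An [pipeline_config()] object.
#' @return Invisibly, a list with every stage's in-memory result.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "ms_pipeline_config"))
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  out <- list()

  cohort <- config$cohort
  if (is.character(cohort)) {
    .stage_msg("reading cohort from ", cohort)
    cohort <- read_cohort(cohort)
  }
  stopifnot(inherits(cohort, "ms_cohort"))
  meta <- cohort_metadata(cohort)
  atlas <- cohort$atlas
  n_regions <- nrow(atlas)
  .stage_msg("cohort: ", nrow(meta), " subjects (",
             sum(meta$group == "HC"), " HC / ", sum(meta$group == "SCZ"),
             " SCZ), ", n_regions, " regions, ",
             length(unique(meta$site)), " site(s)")

  # -- harmonization ---------------------------------------------------
  combat_model <- NULL
  if (config$run_combat) {
    .stage_msg("site harmonization (EB location/scale)")
    harm <- combat_cohort(cohort)
    cohort <- harm$cohort
    combat_model <- harm$model
  }

  # -- MS matrices and node summaries ----------------------------------
  .stage_msg("building per-subject MS matrices")
  ms_list <- cohort_ms_matrices(cohort)
  summaries <- cohort_ms_summaries(ms_list, atlas)
  out$ms_summaries <- summaries

  .stage_msg("regional and subnetwork group comparisons")
  regional_cmp <- run_family(t(summaries$regional), meta, "regional_mean_ms")
  subnet_cmp <- run_family(t(summaries$subnetwork), meta, "subnetwork_mean_ms")
  write_table_csv(regional_cmp, file.path(config$output_dir,
                                          "regional_ms_comparisons.csv"))
  write_table_csv(subnet_cmp, file.path(config$output_dir,
                                        "subnetwork_ms_comparisons.csv"))
  out$regional_cmp <- regional_cmp
  out$subnet_cmp <- subnet_cmp

  # -- NBS -------------------------------------------------------------
  stack <- ms_edge_stack(ms_list)
  n_edges_universe <- config$edge_universe %||% stack$pairs$n_edges
  if (!is.null(config$edge_universe) &&
      config$edge_universe != stack$pairs$n_edges) {
    .stage_msg("edge universe override: ", config$edge_universe,
               " (computed C(N,2) = ", stack$pairs$n_edges, ")")
  }
  thr <- bonferroni_initial_threshold(config$nbs_alpha, n_edges_universe)
  out$nbs <- list()
  for (dir in config$nbs_directions) {
    .stage_msg("NBS ", dir, ": threshold ", signif(thr, 3), ", ",
               config$n_permutations, " permutations")
    res <- nbs_test(stack, meta, direction = dir, initial_threshold = thr,
                    n_perm = config$n_permutations,
                    seed = config$seed + match(dir, c("HC_gt_SCZ", "HC_lt_SCZ")))
    tabs <- nbs_tables(res, atlas$region_name)
    sig <- if (nrow(tabs$summary)) sum(tabs$summary$fwer_p < config$nbs_alpha) else 0L
    .stage_msg("  ", length(res$components), " component(s), ", sig,
               " significant at FWER < ", config$nbs_alpha)
    if (nrow(tabs$edges)) {
      utils::write.table(tabs$edges,
                         file.path(config$output_dir,
                                   paste0("nbs_edges_", dir, ".tsv")),
                         sep = "\t", row.names = FALSE, quote = FALSE)
    }
    jsonlite::write_json(tabs$summary,
                         file.path(config$output_dir,
                                   paste0("nbs_summary_", dir, ".json")),
                         digits = NA)
    out$nbs[[dir]] <- res
  }

  # -- graph metrics ---------------------------------------------------
  .stage_msg("small-worldness over candidate grid (",
             length(config$candidate_grid), " thresholds)")
  sw <- evaluate_smallworld_grid(ms_list, config$candidate_grid,
                                 n_random = config$n_random_surrogates,
                                 seed = config$seed + 100L)
  grid <- select_threshold_range(sw, sigma_min = config$sigma_min)
  .stage_msg("selected sparsity range ", min(grid), "-", max(grid),
             " (", length(grid), " thresholds)")
  measures <- cohort_network_measures(ms_list, grid,
                                      seed = config$seed + 200L)
  out$smallworld <- sw
  out$selected_grid <- grid
  out$measures <- measures

  .stage_msg("global and nodal measure comparisons")
  global_cmp <- run_family(t(measures$global), meta, "global_measures",
                           m_override = 4L)
  nodal_flat <- do.call(rbind, lapply(seq_len(dim(measures$nodal)[3]),
    function(m) {
      mat <- t(measures$nodal[, , m])
      rownames(mat) <- paste0(dimnames(measures$nodal)[[3]][m], ".",
                              atlas$region_name)
      mat
    }))
  nodal_cmp <- run_family(nodal_flat, meta, "nodal_measures",
                          m_override = 4L * n_regions)
  write_table_csv(global_cmp, file.path(config$output_dir,
                                        "global_measure_comparisons.csv"))
  write_table_csv(nodal_cmp, file.path(config$output_dir,
                                       "nodal_measure_comparisons.csv"))
  out$global_cmp <- global_cmp
  out$nodal_cmp <- nodal_cmp

  # -- clinical associations -------------------------------------------
  .stage_msg("clinical associations (within the patient group, on units ",
             "significant in the group comparisons)")
  assoc <- clinical_associations(
    meta = meta,
    regional = summaries$regional, regional_cmp = regional_cmp,
    nodal = measures$nodal, nodal_cmp = nodal_cmp,
    global = measures$global, global_cmp = global_cmp,
    atlas = atlas, alpha = config$fdr_alpha)
  if (nrow(assoc)) {
    write_table_csv(assoc, file.path(config$output_dir,
                                     "clinical_associations.csv"))
  }
  out$associations <- assoc

  manifest <- list(
    n_subjects = nrow(meta), n_hc = sum(meta$group == "HC"),
    n_scz = sum(meta$group == "SCZ"), n_regions = n_regions,
    sites = as.list(table(meta$site)),
    run_combat = config$run_combat,
    nbs = list(initial_threshold = thr, edge_universe = n_edges_universe,
               n_permutations = config$n_permutations,
               directions = config$nbs_directions),
    candidate_grid = config$candidate_grid,
    selected_grid = grid, sigma_min = config$sigma_min,
    n_random_surrogates = config$n_random_surrogates,
    fdr_alpha = config$fdr_alpha, seed = config$seed,
    package_version = as.character(utils::packageVersion("mscortex"))
  )
  jsonlite::write_json(manifest, file.path(config$output_dir, "manifest.json"),
                       digits = NA, auto_unbox = TRUE)
  out$manifest <- manifest
  .stage_msg("done; outputs in ", config$output_dir)
  invisible(out)
}

#' Clinical association tables across measurement levels
#'
#' Follows the study design: associations are computed within the patient
#' group for illness duration, symptom scores and antipsychotic dose, and
#' within each group for the cognitive scores, restricted to units that
#' were significant in the corresponding group comparison; BH correction is
#' applied per clinical variable.
#' @noRd
clinical_associations <- function(meta, regional, regional_cmp,
                                  nodal, nodal_cmp, global, global_cmp,
                                  atlas, alpha = 0.05) {
  scz <- which(meta$group == "SCZ")
  out <- list()
  clin_vars <- c("illness_duration", "panss_positive", "panss_negative",
                 "antipsychotic_dose")
  cog_vars <- intersect(c("fsiq", "color_trail_1", "word_fluency"), names(meta))

  unit_sets <- list()
  sig_reg <- regional_cmp$unit_id[regional_cmp$significant]
  if (length(sig_reg)) {
    unit_sets$regional <- t(regional[, sig_reg, drop = FALSE])
  }
  sig_glob <- global_cmp$unit_id[global_cmp$significant]
  if (length(sig_glob)) {
    unit_sets$global <- t(global[, sig_glob, drop = FALSE])
  }
  sig_nodal <- nodal_cmp$unit_id[nodal_cmp$significant]
  if (length(sig_nodal)) {
    flat <- do.call(rbind, lapply(seq_len(dim(nodal)[3]), function(m) {
      mat <- t(nodal[, , m])
      rownames(mat) <- paste0(dimnames(nodal)[[3]][m], ".", atlas$region_name)
      mat
    }))
    unit_sets$nodal <- flat[sig_nodal, , drop = FALSE]
  }
  if (!length(unit_sets)) {
    return(data.frame())
  }
  for (level in names(unit_sets)) {
    units <- unit_sets[[level]]
    for (v in clin_vars) {
      if (!v %in% names(meta)) next
      clin <- meta[[v]][scz]
      if (sum(stats::complete.cases(clin)) < 4) next
      for (mth in c("raw", "age_adjusted")) {
        tab <- run_association_family(units[, scz, drop = FALSE], clin,
                                      variable_name = v,
                                      age = meta$age[scz], method = mth,
                                      alpha = alpha)
        tab$level <- level
        tab$population <- "SCZ"
        tab$method <- mth
        out[[length(out) + 1L]] <- tab
      }
    }
    for (v in cog_vars) {
      for (grp in c("HC", "SCZ")) {
        idx <- which(meta$group == grp)
        clin <- meta[[v]][idx]
        if (sum(stats::complete.cases(clin)) < 4) next
        tab <- run_association_family(units[, idx, drop = FALSE], clin,
                                      variable_name = v, method = "raw",
                                      alpha = alpha)
        tab$level <- level
        tab$population <- grp
        tab$method <- "raw"
        out[[length(out) + 1L]] <- tab
      }
    }
  }
  if (!length(out)) return(data.frame())
  do.call(rbind, out)
}
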