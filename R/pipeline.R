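#' Run the full connectomic percolation analysis
#'
#' End-to-end driver: generate (or accept) a two-group cohort, preprocess
#' each group (average, normalize, threshold at the configured density),
#' compute global and nodal quantifier tables, compare individually
#' prethresholded subject quantifiers across groups, run every configured
#' attack scheme on both group-average networks, and compare attacked
#' control trajectories with the intact disease baseline (the progression
#' model). All randomness is derived from `seed`.
#'
#' @param cohort list with `control`, `disease` (raw matrices) and `atlas`;
#'   default: a synthetic cohort from `cohort_config(seed = seed)`.
#' @param density proportional threshold density (default 0.10).
#' @param attack_quantifiers nodal quantifiers attacked with both basis and
#'   iterative schemes (collective influence is added as basis only).
#' @param n_random_reps repetitions of the random ensemble (default 100).
#' @param ci_ell collective-influence ball radius (default 2).
#' @param seed master seed.
#' @param track global quantifiers snapshotted along trajectories.
#' @param out_dir optional directory; when given, tables are written as CSVs
#'   plus a JSON manifest of seeds and parameters.
#' @return list with `averages` (thresholded group networks), `baselines`
#'   (full global quantifier sets per group), `subject_global` (per-subject
#'   global quantifier data frames per group), `comparison` (group stats
#'   table), `trajectories` (named list of `attack_trajectory`, both groups),
#'   `progression` (list of `progression_result` for control attacks vs
#'   disease baseline), and `manifest`.
#' @export
run_full_analysis <- function(cohort = NULL, density = 0.10,
                              attack_quantifiers = c("degree", "strength",
                                                     "betweenness", "eigenvector"),
                              n_random_reps = 100L, ci_ell = 2L, seed = 1L,
                              track = c("largest_cluster", "n_edges",
                                        "avg_degree", "avg_strength",
                                        "cpl", "global_efficiency",
                                        "avg_betweenness", "avg_clustering"),
                              out_dir = NULL) {
  if (density <= 0 || density > 1) stop("config error: density must be in (0, 1]")
  if (is.null(cohort)) cohort <- generate_cohort(cohort_config(seed = seed))

  prep <- function(ms) {
    threshold_proportional(normalize_matrix(group_average(ms)), density)
  }
  averages <- list(control = prep(cohort$control), disease = prep(cohort$disease))
  baselines <- lapply(averages, global_quantifiers, which = "all", seed = seed)

  # individually prethresholded subject-level quantifiers -> group comparison
  subj_global <- function(ms) {
    do.call(rbind, lapply(ms, function(m) {
      mt <- threshold_proportional(normalize_matrix(m), density)
      g <- global_quantifiers(mt, which = c("largest_cluster", "avg_degree",
                                            "avg_strength", "cpl",
                                            "global_efficiency", "radius",
                                            "diameter", "avg_betweenness",
                                            "avg_clustering"), seed = seed)
      cbind(data.frame(subject_id = m$subject_id), as.data.frame(g))
    }))
  }
  subject_global <- list(control = subj_global(cohort$control),
                         disease = subj_global(cohort$disease))
  comparison <- compare_quantifiers(subject_global$control[, -1],
                                    subject_global$disease[, -1])

  trajectories <- list()
  for (grp in c("control", "disease")) {
    m <- averages[[grp]]
    for (q in attack_quantifiers) {
      for (sch in c("basis", "iterative")) {
        trajectories[[paste(grp, sch, q, sep = ".")]] <-
          run_targeted_attack(m, scheme = sch, quantifier = q, seed = seed,
                              track = track)
      }
    }
    trajectories[[paste(grp, "basis", "ci", sep = ".")]] <-
      run_targeted_attack(m, scheme = "basis", quantifier = "ci", seed = seed,
                          track = track, ci_ell = ci_ell)
    trajectories[[paste(grp, "random", sep = ".")]] <-
      random_attack_ensemble(m, n_reps = n_random_reps, seed = seed,
                             track = track)
  }

  ctrl_names <- grep("^control\\.", names(trajectories), value = TRUE)
  progression <- lapply(trajectories[ctrl_names], progression_analysis,
                        baseline = baselines$disease)

  manifest <- list(density = density, seed = seed, ci_ell = ci_ell,
                   n_random_reps = n_random_reps,
                   attack_quantifiers = attack_quantifiers,
                   n_control = length(cohort$control),
                   n_disease = length(cohort$disease),
                   n_regions = n_regions(averages$control))

  res <- list(averages = averages, baselines = baselines,
              subject_global = subject_global, comparison = comparison,
              trajectories = trajectories, progression = progression,
              manifest = manifest)
  if (!is.null(out_dir)) export_analysis(res, cohort$atlas, out_dir)
  res
}

# internal: write the report bundle as plain-text tables + manifest
export_analysis <- function(res, atlas, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(res$comparison, file.path(out_dir, "group_comparison.csv"),
                   row.names = FALSE)
  for (grp in names(res$subject_global)) {
    utils::write.csv(res$subject_global[[grp]],
                     file.path(out_dir, paste0("subject_global_", grp, ".csv")),
                     row.names = FALSE)
  }
  for (nm in names(res$trajectories)) {
    tr <- res$trajectories[[nm]]
    utils::write.csv(tr$snapshots,
                     file.path(out_dir, paste0("trajectory_", nm, ".csv")),
                     row.names = FALSE)
  }
  cross <- do.call(rbind, lapply(names(res$progression), function(nm) {
    pr <- res$progression[[nm]]
    data.frame(attack = nm, quantifier = names(pr$crossings),
               crossing_step = unname(pr$crossings))
  }))
  utils::write.csv(cross, file.path(out_dir, "progression_crossings.csv"),
                   row.names = FALSE)
  for (grp in names(res$averages)) {
    write_brainnet_files(binarize(res$averages[[grp]]), atlas,
                         file.path(out_dir, paste0("brainnet_", grp)))
  }
  jsonlite::write_json(res$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
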