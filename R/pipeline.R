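#' Run the full coordination-dynamics pipeline
#'
#' Orchestrates the analysis end to end: (optionally) simulate a study or
#' load one from disk, condition every run and extract phases, stack
#' phase-coherence frames, cluster them (fixed k or [select_k()] over a
#' range), rank patterns by structure-function correlation, compute per-run
#' occupancy / entropy / slope metrics, build per-condition transition
#' matrices with permutation-null envelopes, and test each stimulation
#' condition against the baseline with Bonferroni-corrected t-tests. All
#' randomness flows from `seed`; rerunning with the same inputs reproduces
#' every number.
#'
#' @param simulation a [simulation_config()], or `NULL` when `study_dir`
#'   is given.
#' @param study_dir directory readable by [read_study()] (one delimited-text
#'   matrix per run plus `manifest.json` and `connectome.tsv`).
#' @param k fixed number of patterns, or `NULL` to choose via [select_k()].
#' @param k_range candidate range when `k` is `NULL`.
#' @param gsr apply global-signal regression.
#' @param n_init,max_iter k-means restarts and iteration cap.
#' @param n_permutations,levels transition-null settings.
#' @param welch use Welch rather than pooled t-tests.
#' @param baseline name of the reference condition for group tests;
#'   defaults to the first condition.
#' @param seed master seed.
#' @param output_dir if non-`NULL`, artifacts (centroids, labels, metrics,
#'   transition tables, JSON summary) are written there as delimited text.
#' @return a result bundle (list) with elements `frames`, `patterns`,
#'   `labels`, `metrics`, `condition_occupancy`, `transitions`,
#'   `group_tests`, `selection`, `config`.
#' @export
run_pipeline <- function(simulation = NULL, study_dir = NULL, k = NULL,
                         k_range = 3:10, gsr = TRUE, n_init = 100,
                         max_iter = 200, n_permutations = 10000,
                         levels = c(0.90, 0.95, 0.99), welch = FALSE,
                         baseline = NULL, seed = 1, output_dir = NULL) {
  if (is.null(simulation) == is.null(study_dir)) {
    stop_invalid("provide exactly one of simulation config or study_dir")
  }
  if (!is.null(simulation)) {
    study <- generate_study(simulation)
    runs <- study$runs
    connectome <- study$connectome
  } else {
    loaded <- read_study(study_dir)
    runs <- loaded$runs
    connectome <- loaded$connectome
    if (is.null(connectome)) stop_invalid("study_dir has no connectome.tsv")
  }
  phase_runs <- lapply(runs, prepare_phases, gsr = gsr)
  frames <- build_dataset_frames(phase_runs)

  selection <- NULL
  if (is.null(k)) {
    selection <- select_k(frames, k_range, n_init = n_init,
                          max_iter = max_iter, seed = child_seed(seed, 11))
    k <- selection$k
  }
  fit <- fit_kmeans(frames, k, n_init = n_init, max_iter = max_iter,
                    seed = child_seed(seed, 12))
  ranked <- order_by_sfc(fit$patterns, connectome, fit$labels)
  patterns <- ranked$patterns
  labels <- ranked$labels

  metrics <- run_metrics(labels, patterns$sfc_values)
  cond_occ <- occupancy_rates(labels, group_by = "condition")

  conditions <- unique(frames$frame_index$condition)
  transitions <- lapply(seq_along(conditions), function(ci) {
    cond <- conditions[ci]
    sel <- frames$frame_index$condition == cond
    sub <- new_state_sequence(labels$labels[sel], k,
                              frames = NULL)
    sub$frame_index <- frames$frame_index[sel, , drop = FALSE]
    emp <- transition_matrix(sub, k)
    env <- bootstrap_envelope(sub, k, n_permutations = n_permutations,
                              levels = levels,
                              seed = child_seed(seed, 20 + ci))
    masks <- lapply(levels, function(lv) significant_transitions(emp, env, lv))
    names(masks) <- sprintf("%g", levels)
    list(condition = cond, empirical = emp, envelope = env,
         significant = masks)
  })
  names(transitions) <- conditions

  baseline <- baseline %||% conditions[1L]
  group_tests <- NULL
  if (length(conditions) > 1L && baseline %in% conditions) {
    others <- setdiff(conditions, baseline)
    rows <- list()
    for (metric in c("entropy_bits", "entropy_norm", "slope",
                     paste0("p", seq_len(k)))) {
      base_v <- metrics[[metric]][metrics$condition == baseline]
      for (oc in others) {
        v <- metrics[[metric]][metrics$condition == oc]
        if (length(v) < 2L || length(base_v) < 2L) next
        tt <- ttest_from_samples(v, base_v, welch = welch)
        rows[[length(rows) + 1L]] <- data.frame(
          metric = metric, condition = oc, baseline = baseline,
          mean = mean(v), sd = stats::sd(v),
          baseline_mean = mean(base_v), baseline_sd = stats::sd(base_v),
          t = tt$t, df = tt$df, p = tt$p)
      }
    }
    group_tests <- do.call(rbind, rows)
    ## Bonferroni family: the condition contrasts tested per metric
    group_tests$p_adjusted <- stats::ave(
      group_tests$p, group_tests$metric,
      FUN = function(p) bonferroni(p, m = length(p)))
  }

  bundle <- list(frames = frames, patterns = patterns, labels = labels,
                 metrics = metrics, condition_occupancy = cond_occ,
                 transitions = transitions, group_tests = group_tests,
                 selection = selection,
                 config = list(k = k, gsr = gsr, n_init = n_init,
                               max_iter = max_iter,
                               n_permutations = n_permutations,
                               levels = levels, welch = welch,
                               baseline = baseline, seed = seed))
  if (!is.null(output_dir)) write_bundle(bundle, output_dir)
  bundle
}

write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(bundle$patterns$centroids,
                     file.path(dir, "centroids.tsv"),
                     sep = "\t", quote = FALSE,
                     row.names = sprintf("pattern%d", seq_len(bundle$patterns$k)),
                     col.names = FALSE)
  lab <- cbind(bundle$frames$frame_index,
               label = bundle$labels$labels)
  utils::write.table(lab, file.path(dir, "labels.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(bundle$metrics, file.path(dir, "run_metrics.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  for (tr in bundle$transitions) {
    utils::write.table(tr$empirical$probs,
                       file.path(dir, sprintf("transitions_%s.tsv", tr$condition)),
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
  }
  summary <- list(
    schema_version = "1.0",
    k = bundle$patterns$k,
    sfc_values = bundle$patterns$sfc_values,
    condition_occupancy = bundle$condition_occupancy,
    selection = if (!is.null(bundle$selection))
      list(k = bundle$selection$k, elbow_k = bundle$selection$elbow_k),
    config = bundle$config)
  jsonlite::write_json(summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       dataframe = "rows")
  invisible(dir)
}
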