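#' Structure-function correlation of a pattern
#'
#' Pearson correlation between the vectorised strict upper triangles of a
#' coordination pattern and of the structural connectome. The pattern with
#' the highest SFC is the "anatomical" pattern; its dominance characterises
#' dynamics anchored to the anatomical backbone.
#'
#' @param pattern_matrix N x N symmetric pattern (coherence scale).
#' @param connectome N x N symmetric structural matrix.
#' @return correlation in `[-1, 1]`.
#' @export
sfc <- function(pattern_matrix, connectome) {
  check_square(pattern_matrix, "pattern_matrix")
  check_square(connectome, "connectome")
  if (nrow(pattern_matrix) != nrow(connectome)) {
    stop_invalid("pattern and connectome dimensions differ")
  }
  a <- vectorize_upper(pattern_matrix, tol = Inf)
  b <- vectorize_upper(connectome, tol = Inf)
  if (stats::sd(a) < .Machine$double.eps^0.5 ||
      stats::sd(b) < .Machine$double.eps^0.5) {
    stop_invalid("zero variance in upper triangle: correlation undefined")
  }
  stats::cor(a, b)
}

#' Pattern occupancy rates
#'
#' Fraction of frames assigned to each pattern, per run or per condition.
#' Unvisited patterns get occupancy zero; each row sums to one.
#'
#' @param labels a `state_sequence` (with frame index) or an integer vector.
#' @param k number of patterns; defaults to the sequence's k.
#' @param group_by `"run"`, `"condition"`, or `NULL` for one overall row.
#' @return a data frame: grouping columns plus `p1 ... pk` occupancy columns.
#' @export
occupancy_rates <- function(labels, k = NULL, group_by = c("run", "condition", "none")) {
  group_by <- match.arg(group_by)
  lab <- if (inherits(labels, "state_sequence")) labels$labels else as.integer(labels)
  if (is.null(k)) {
    k <- if (inherits(labels, "state_sequence")) labels$k else max(lab)
  }
  if (any(lab < 1L | lab > k)) stop_invalid("labels must lie in 1..k")
  idx <- if (inherits(labels, "state_sequence")) labels$frame_index else NULL
  if (group_by == "none" || is.null(idx)) {
    groups <- factor(rep("all", length(lab)))
    meta <- data.frame(group = "all")
  } else if (group_by == "run") {
    groups <- factor(idx$run_id, levels = unique(idx$run_id))
    meta <- unique(idx[c("run_id", "subject", "condition")])
    meta <- meta[match(levels(groups), meta$run_id), , drop = FALSE]
  } else {
    groups <- factor(idx$condition, levels = unique(idx$condition))
    meta <- data.frame(condition = levels(groups))
  }
  if (any(tabulate(groups) == 0L)) stop_invalid("empty group in occupancy table")
  occ <- t(vapply(levels(groups), function(g) {
    tabulate(lab[groups == g], k) / sum(groups == g)
  }, numeric(k)))
  colnames(occ) <- paste0("p", seq_len(k))
  rownames(meta) <- NULL
  cbind(meta, as.data.frame(occ))
}

occupancy_matrix <- function(occ_table) {
  as.matrix(occ_table[, grep("^p[0-9]+$", names(occ_table)), drop = FALSE])
}

#' Shannon entropy of an occupancy distribution
#'
#' `S = -sum p_i log2 p_i` in bits, with `0 log 0 := 0`. With
#' `normalized = TRUE` the entropy is divided by `log2 k`, mapping the
#' uniform distribution to 1.
#'
#' @param probs non-negative vector summing to 1 (tolerance 1e-9).
#' @param normalized divide by the maximum attainable entropy.
#' @return entropy in bits (or a fraction of the maximum).
#' @export
shannon_entropy <- function(probs, normalized = FALSE) {
  if (any(probs < -1e-12) || abs(sum(probs) - 1) > 1e-9) {
    stop_invalid("probs must be a probability vector summing to 1")
  }
  p <- probs[probs > 0]
  s <- -sum(p * log2(p))
  if (normalized) s / log2(length(probs)) else s
}

#' Slope of occupancy against structure-function correlation
#'
#' Ordinary least-squares slope of pattern occupancy (response) on pattern
#' SFC (predictor) across the k patterns. A large positive slope means time
#' is spent preferentially in patterns resembling the anatomy, the signature
#' of unconscious-like dynamics.
#'
#' @param occupancy k occupancy fractions.
#' @param sfc_values k structure-function correlations (not all equal).
#' @return the OLS slope.
#' @export
sfc_slope <- function(occupancy, sfc_values) {
  if (length(occupancy) != length(sfc_values) || length(occupancy) < 2L) {
    stop_invalid("occupancy and sfc_values must have equal length >= 2")
  }
  if (stats::sd(sfc_values) < .Machine$double.eps^0.5) {
    stop_invalid("constant SFC predictor: slope undefined")
  }
  stats::cov(occupancy, sfc_values) / stats::var(sfc_values)
}

#' Per-pattern coherence-variance map
#'
#' Sample (n-1) variance of each region pair's phase coherence over the
#' frames assigned to one pattern, returned in matrix form with a zero
#' diagonal. High-variance pairs mark regions whose synchrony with the rest
#' of the brain fluctuates while the pattern is visited.
#'
#' @param frames a `coherence_frames` object.
#' @param labels matching `state_sequence` (or integer vector).
#' @param pattern pattern index to map.
#' @return N x N variance matrix.
#' @export
coherence_variance_map <- function(frames, labels, pattern) {
  x <- frames_matrix(frames)
  lab <- if (inherits(labels, "state_sequence")) labels$labels else as.integer(labels)
  rows <- which(lab == pattern)
  if (length(rows) < 2L) {
    stop_invalid("pattern ", pattern, " has fewer than 2 frames; variance undefined")
  }
  v <- apply(x[rows, , drop = FALSE], 2L, stats::var)
  unvectorize_upper(v, diag_value = 0)
}

#' Per-run summary metrics for a clustered dataset
#'
#' Convenience wrapper computing, for every run, the pattern occupancies,
#' raw and normalised Shannon entropy, and the occupancy-SFC slope.
#'
#' @param labels a `state_sequence` with frame index.
#' @param sfc_values the patterns' SFC values (from [order_by_sfc()]).
#' @return tidy data frame, one row per run.
#' @export
run_metrics <- function(labels, sfc_values) {
  occ <- occupancy_rates(labels, group_by = "run")
  pm <- occupancy_matrix(occ)
  occ$entropy_bits <- apply(pm, 1L, shannon_entropy)
  occ$entropy_norm <- apply(pm, 1L, shannon_entropy, normalized = TRUE)
  occ$slope <- apply(pm, 1L, sfc_slope, sfc_values = sfc_values)
  occ
}
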