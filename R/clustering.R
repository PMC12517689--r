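## k-means++ seeding (Arthur & Vassilvitskii): each new centre drawn with
## probability proportional to squared distance from the nearest chosen one.
kmeanspp_centers <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(0, k, ncol(x))
  pick <- sample.int(n, 1L)
  centers[1L, ] <- x[pick, ]
  d2 <- rowSums(sweep(x, 2L, centers[1L, ])^2)
  for (j in seq_len(k - 1L) + 1L) {
    tot <- sum(d2)
    pick <- if (tot <= 0) sample.int(n, 1L) else
      sample.int(n, 1L, prob = d2 / tot)
    centers[j, ] <- x[pick, ]
    d2 <- pmin(d2, rowSums(sweep(x, 2L, centers[j, ])^2))
  }
  centers
}

frames_matrix <- function(frames) {
  if (inherits(frames, "coherence_frames")) frames$frames
  else if (is.matrix(frames)) frames
  else stop_invalid("frames must be a coherence_frames object or a matrix")
}

#' Discover coordination patterns with k-means
#'
#' Clusters coherence frames with Euclidean k-means (Lloyd iterations via
#' [stats::kmeans()]), k-means++ seeding, and the best of `n_init`
#' initialisations by total within-cluster sum of squares. An initialisation
#' that collapses to an empty cluster is redrawn (counted in the
#' diagnostics). Labels are re-derived as exact nearest-centroid assignments
#' of the winning solution.
#'
#' @param frames a `coherence_frames` object (or plain frames matrix).
#' @param k number of patterns; must not exceed the number of frames.
#' @param n_init number of k-means++ restarts.
#' @param max_iter Lloyd iteration cap per restart.
#' @param seed RNG seed governing seeding; fixed seed gives identical fits.
#' @return a list with `patterns` (a `pattern_set`: `centroids` k x D,
#'   `k`, `wss`, per-cluster sizes, diagnostics) and `labels` (a
#'   `state_sequence`: integer labels aligned with the frame index).
#' @export
fit_kmeans <- function(frames, k, n_init = 100, max_iter = 200, seed = NULL) {
  x <- frames_matrix(frames)
  if (!is_count(k) || k > nrow(x)) {
    stop_invalid("k must be a positive integer no larger than the number of frames")
  }
  fit <- with_seed(seed, {
    best <- NULL
    redraws <- 0L
    for (i in seq_len(n_init)) {
      res <- NULL
      attempts <- 0L
      while (is.null(res) && attempts < 20L) {
        attempts <- attempts + 1L
        res <- tryCatch(
          suppressWarnings(stats::kmeans(x, centers = kmeanspp_centers(x, k),
                                         iter.max = max_iter,
                                         algorithm = "Lloyd")),
          error = function(e) NULL)
        if (is.null(res)) redraws <- redraws + 1L
      }
      if (is.null(res)) stop_invalid("k-means failed repeatedly with empty clusters")
      if (is.null(best) || res$tot.withinss < best$tot.withinss) best <- res
    }
    list(best = best, redraws = redraws)
  })
  centroids <- unname(fit$best$centers)
  labels <- nearest_centroid(x, centroids)
  wss <- sum((x - centroids[labels, , drop = FALSE])^2)
  patterns <- structure(
    list(centroids = centroids, k = k, wss = wss,
         sizes = tabulate(labels, k), sfc_values = NULL,
         diagnostics = list(n_init = n_init, max_iter = max_iter,
                            seed = seed, empty_cluster_redraws = fit$redraws,
                            iterations = fit$best$iter)),
    class = "pattern_set")
  labels <- new_state_sequence(labels, k, frames)
  list(patterns = patterns, labels = labels)
}

nearest_centroid <- function(x, centroids) {
  ## squared distances via ||x||^2 - 2 x.c + ||c||^2; ||x||^2 constant per row
  cross <- x %*% t(centroids)
  cn <- rowSums(centroids^2)
  max.col(2 * cross - rep(cn, each = nrow(x)), ties.method = "first")
}

new_state_sequence <- function(labels, k, frames = NULL) {
  structure(
    list(labels = as.integer(labels), k = as.integer(k),
         frame_index = if (inherits(frames, "coherence_frames"))
           frames$frame_index else NULL),
    class = "state_sequence")
}

#' @export
print.pattern_set <- function(x, ...) {
  cat(sprintf("<pattern_set> k = %d patterns, WSS = %.4g\n", x$k, x$wss))
  if (!is.null(x$sfc_values)) {
    cat("  SFC (ascending): ", paste(sprintf("%.3f", x$sfc_values),
                                     collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
print.state_sequence <- function(x, ...) {
  cat(sprintf("<state_sequence> %d frames, k = %d\n", length(x$labels), x$k))
  invisible(x)
}

#' Inter-pattern correlation variance
#'
#' The population variance (divide by the number of pairs) of the Pearson
#' correlations between every pair of centroid vectors. Used as the primary
#' criterion for choosing the number of patterns: a high value means the
#' discovered repertoire mixes very similar and very dissimilar patterns.
#'
#' @param patterns a `pattern_set` (or plain k x D centroid matrix), k >= 2.
#' @return non-negative scalar.
#' @export
ipcv <- function(patterns) {
  cen <- if (inherits(patterns, "pattern_set")) patterns$centroids else patterns
  if (!is.matrix(cen) || nrow(cen) < 2L) stop_invalid("need at least 2 centroids")
  sds <- apply(cen, 1L, stats::sd)
  if (any(sds < .Machine$double.eps^0.5)) {
    stop_invalid("zero-variance centroid: pairwise correlations undefined")
  }
  cc <- stats::cor(t(cen))
  v <- cc[upper.tri(cc)]
  mean((v - mean(v))^2)
}

#' Within-cluster sum-of-squares curve over a range of k
#'
#' Fits k-means for each candidate k and reports the best-of-`n_init` WSS
#' together with first differences, the ingredients of the elbow heuristic.
#'
#' @inheritParams fit_kmeans
#' @param k_range integer vector of candidate pattern counts.
#' @return data frame with columns `k`, `wss`, `drop` (WSS decrease from the
#'   previous k), and `ipcv`.
#' @export
wss_curve <- function(frames, k_range = 3:10, n_init = 100, max_iter = 200,
                      seed = NULL) {
  x <- frames_matrix(frames)
  if (any(k_range < 2L) || any(k_range > nrow(x))) {
    stop_invalid("k_range must lie within [2, number of frames]")
  }
  rows <- lapply(seq_along(k_range), function(i) {
    fit <- fit_kmeans(x, k_range[i], n_init = n_init, max_iter = max_iter,
                      seed = child_seed(seed, i))
    data.frame(k = k_range[i], wss = fit$patterns$wss,
               ipcv = ipcv(fit$patterns))
  })
  out <- do.call(rbind, rows)
  out$drop <- c(NA, -diff(out$wss))
  out
}

#' Choose the number of patterns
#'
#' Picks the k that maximises the inter-pattern correlation variance
#' ([ipcv()]) over the candidate range, breaking exact ties toward the
#' smaller k, and records whether the elbow heuristic (largest WSS drop)
#' agrees.
#'
#' @inheritParams wss_curve
#' @return list: `k` (the selection), `curve` (the [wss_curve()] table),
#'   `elbow_k`, `elbow_agrees`.
#' @export
select_k <- function(frames, k_range = 3:10, n_init = 100, max_iter = 200,
                     seed = NULL) {
  curve <- wss_curve(frames, k_range, n_init = n_init, max_iter = max_iter,
                     seed = seed)
  best <- which(curve$ipcv >= max(curve$ipcv) - 1e-12)[1L]  # tie -> smaller k
  drops <- curve$drop[-1L]
  elbow_k <- if (length(drops)) curve$k[-1L][which.max(drops)] else curve$k[1L]
  list(k = curve$k[best], curve = curve, elbow_k = elbow_k,
       elbow_agrees = isTRUE(elbow_k == curve$k[best]))
}

#' Rank patterns by structure-function correlation
#'
#' Reorders a pattern set so that pattern 1 has the lowest and pattern k the
#' highest Pearson correlation with the structural connectome (the
#' "anatomical" pattern), relabelling any state sequence consistently.
#' Ties within 1e-12 are broken by original index with a warning.
#'
#' @param patterns a `pattern_set`.
#' @param connectome N x N structural matrix.
#' @param labels optional `state_sequence` to relabel.
#' @return list: `patterns` (ordered, with `sfc_values` filled in and the
#'   applied `permutation`), and `labels` (relabelled, if supplied).
#' @export
order_by_sfc <- function(patterns, connectome, labels = NULL) {
  stopifnot(inherits(patterns, "pattern_set"))
  check_square(connectome, "connectome")
  n <- length(attr(patterns, "roi_names")) # may be NULL; infer from D instead
  d <- ncol(patterns$centroids)
  n <- (1 + sqrt(1 + 8 * d)) / 2
  if (nrow(connectome) != n) {
    stop_invalid("connectome dimension does not match the patterns' regions")
  }
  vals <- vapply(seq_len(patterns$k), function(m) {
    sfc(unvectorize_upper(patterns$centroids[m, ]), connectome)
  }, numeric(1))
  if (any(diff(sort(vals)) < 1e-12)) {
    warning("SFC ties; breaking deterministically by original pattern index")
  }
  perm <- order(vals)  # stable: ties keep original order
  out <- patterns
  out$centroids <- patterns$centroids[perm, , drop = FALSE]
  out$sizes <- patterns$sizes[perm]
  out$sfc_values <- vals[perm]
  out$permutation <- perm
  res <- list(patterns = out)
  if (!is.null(labels)) {
    stopifnot(inherits(labels, "state_sequence"))
    relabel <- integer(patterns$k)
    relabel[perm] <- seq_len(patterns$k)  # old label -> new rank
    new_labels <- labels
    new_labels$labels <- relabel[labels$labels]
    res$labels <- new_labels
  }
  res
}
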