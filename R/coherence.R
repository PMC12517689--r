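#' Phase-coherence matrix of one time point
#'
#' Entry (i, j) is the cosine of the instantaneous phase difference between
#' regions i and j: 1 for synchronised regions, -1 for anti-phase, values in
#' between otherwise. The matrix is symmetric with a unit diagonal.
#'
#' @param phases numeric vector of N finite angles (radians).
#' @return an N x N phase-coherence matrix.
#' @export
phase_coherence_frame <- function(phases) {
  if (!is.numeric(phases) || any(!is.finite(phases))) {
    stop_invalid("phases must be finite numeric angles")
  }
  cos(outer(phases, phases, "-"))
}

## row-major (i < j) linear indices into an N x N matrix, as used by
## vectorize_upper; pairs (1,2),(1,3),...,(1,N),(2,3),...
upper_pairs <- function(n, roi_names = NULL) {
  i <- rep.int(seq_len(n - 1L), times = (n - 1L):1L)
  j <- unlist(lapply(seq_len(n - 1L), function(a) (a + 1L):n), use.names = FALSE)
  out <- data.frame(i = i, j = j)
  if (!is.null(roi_names)) {
    out$roi_i <- roi_names[i]
    out$roi_j <- roi_names[j]
  }
  out
}

#' Vectorise the upper triangle of a symmetric matrix
#'
#' Returns the strict upper triangle in row-major pair order
#' (1,2),(1,3),...,(2,3),..., length N(N-1)/2. This fixed ordering is the
#' interchange format for frames and centroids throughout the package;
#' [unvectorize_upper()] inverts it, restoring a symmetric matrix with the
#' requested diagonal.
#'
#' @param m symmetric numeric matrix.
#' @param tol symmetry tolerance.
#' @return numeric vector of length `N(N-1)/2`.
#' @export
vectorize_upper <- function(m, tol = 1e-9) {
  check_square(m, "m")
  if (max(abs(m - t(m))) > tol) {
    stop_invalid("matrix is not symmetric within tolerance ", tol)
  }
  t(m)[lower.tri(m)]  # column-major lower triangle of t(m) == row-major upper
}

#' @rdname vectorize_upper
#' @param v vector of length `N(N-1)/2`.
#' @param diag_value value placed on the diagonal (1 for coherence frames).
#' @export
unvectorize_upper <- function(v, diag_value = 1) {
  n <- (1 + sqrt(1 + 8 * length(v))) / 2
  if (n != round(n)) stop_invalid("length is not N(N-1)/2 for integer N")
  n <- as.integer(n)
  m <- matrix(0, n, n)
  m[lower.tri(m)] <- v  # fill column-major lower = row-major upper of t
  m <- t(m)
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  diag(m) <- diag_value
  m
}

#' Stack phase-coherence frames across runs and conditions
#'
#' Converts each phase run into per-timepoint vectorised coherence frames and
#' concatenates them in a canonical deterministic order (condition, subject,
#' run id, volume), so that shuffled input ordering cannot change the result.
#' The frame index records provenance for every row and the pair index maps
#' columns back to region pairs.
#'
#' @param phase_runs list of `phase_run` objects sharing regions.
#' @return a `coherence_frames` object: `frames` (F x N(N-1)/2 matrix, values
#'   in `[-1, 1]`), `frame_index` (data frame: run_id, tr, subject,
#'   condition), `pair_index`, `roi_names`.
#' @export
build_dataset_frames <- function(phase_runs) {
  stopifnot(length(phase_runs) >= 1L)
  roi <- phase_runs[[1L]]$roi_names
  for (p in phase_runs) {
    if (!identical(p$roi_names, roi)) {
      stop_invalid("runs have mismatched regions: ",
                   paste(union(setdiff(p$roi_names, roi),
                               setdiff(roi, p$roi_names)), collapse = ", "))
    }
  }
  ids <- vapply(seq_along(phase_runs),
                function(i) run_id_of(phase_runs[[i]], sprintf("run%03d", i)),
                character(1))
  subj <- vapply(phase_runs, function(p)
    as.character(p$metadata$subject %||% NA_character_), character(1))
  cond <- vapply(phase_runs, function(p)
    as.character(p$metadata$condition %||% NA_character_), character(1))
  ord <- order(cond, subj, ids, method = "radix")

  n <- length(roi)
  pairs <- upper_pairs(n, roi)
  blocks <- vector("list", length(phase_runs))
  index <- vector("list", length(phase_runs))
  for (k in seq_along(ord)) {
    p <- phase_runs[[ord[k]]]
    ## cos(phi_i - phi_j) for all pairs at once: rows = pairs, cols = time
    d <- p$phases[pairs$i, , drop = FALSE] - p$phases[pairs$j, , drop = FALSE]
    blocks[[k]] <- t(cos(d))
    index[[k]] <- data.frame(
      run_id = ids[ord[k]], tr = as.integer(p$tr_index),
      subject = subj[ord[k]], condition = cond[ord[k]],
      stringsAsFactors = FALSE, row.names = NULL)
  }
  structure(
    list(frames = do.call(rbind, blocks),
         frame_index = do.call(rbind, index),
         pair_index = pairs,
         roi_names = roi),
    class = "coherence_frames")
}

#' @export
print.coherence_frames <- function(x, ...) {
  cat(sprintf("<coherence_frames> %d frames x %d region pairs (%d regions, %d runs)\n",
              nrow(x$frames), ncol(x$frames), length(x$roi_names),
              length(unique(x$frame_index$run_id))))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
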