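split_by_run <- function(labels) {
  if (inherits(labels, "state_sequence")) {
    if (!is.null(labels$frame_index)) {
      split(labels$labels, factor(labels$frame_index$run_id,
                                  levels = unique(labels$frame_index$run_id)))
    } else list(labels$labels)
  } else if (is.list(labels)) {
    lapply(labels, as.integer)
  } else {
    list(as.integer(labels))
  }
}

count_transitions <- function(seqs, k) {
  counts <- matrix(0L, k, k)
  for (s in seqs) {
    if (length(s) < 2L) next
    a <- s[-length(s)]
    b <- s[-1L]
    keep <- a != b  # self-transitions are not counted
    if (any(keep)) {
      tab <- tabulate((a[keep] - 1L) * k + b[keep], nbins = k * k)
      counts <- counts + matrix(tab, k, k, byrow = TRUE)
    }
  }
  counts
}

#' Off-diagonal Markov transition matrix of a state sequence
#'
#' Counts transitions between distinct consecutive patterns (self-transitions
#' are ignored; with a frame index, consecutive frames from different runs
#' are never paired) and row-normalises the counts. Rows without any
#' outgoing transition are left all-zero and flagged.
#'
#' @param labels a `state_sequence`, an integer vector, or a list of
#'   per-run integer vectors.
#' @param k number of patterns.
#' @return a `transition_matrix`: `probs` (k x k, zero diagonal), `counts`,
#'   and `zero_rows` (patterns with no outgoing transitions).
#' @export
transition_matrix <- function(labels, k = NULL) {
  seqs <- split_by_run(labels)
  if (is.null(k)) {
    k <- if (inherits(labels, "state_sequence")) labels$k else
      max(unlist(seqs))
  }
  lab <- unlist(seqs, use.names = FALSE)
  if (length(lab) < 2L) stop_invalid("need at least 2 frames")
  if (any(lab < 1L | lab > k)) stop_invalid("labels must lie in 1..k")
  counts <- count_transitions(seqs, k)
  rs <- rowSums(counts)
  probs <- counts / ifelse(rs > 0, rs, 1)
  diag(probs) <- 0
  structure(
    list(probs = probs, counts = counts,
         zero_rows = which(rs == 0), n_transitions = sum(counts)),
    class = "transition_matrix")
}

#' @export
print.transition_matrix <- function(x, ...) {
  cat(sprintf("<transition_matrix> %d patterns, %d counted transitions\n",
              nrow(x$probs), x$n_transitions))
  print(round(x$probs, 3))
  invisible(x)
}

## all permutations of seq_len(n), one per row (n <= 7 kept small by caller)
all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  r <- 0L
  for (pos in seq_len(n)) {
    block <- cbind(sub, n)[, append(seq_len(n - 1L), n, after = pos - 1L),
                           drop = FALSE]
    out[r + seq_len(nrow(sub)), ] <- block
    r <- r + nrow(sub)
  }
  out
}

#' Permutation-null envelope for transition probabilities
#'
#' Builds the null distribution of each off-diagonal transition probability
#' by uniformly shuffling the label order within each run (preserving every
#' run's label multiset while destroying temporal dependence) and
#' recomputing the transition matrix. The envelope stores the upper
#' quantiles (inclusive, type 7) at the requested confidence levels. For a
#' single short sequence whose permutation count does not exceed
#' `n_permutations`, all distinct orderings are enumerated so the envelope
#' is exact.
#'
#' @param labels as in [transition_matrix()]; needs >= 2 distinct labels.
#' @param k number of patterns.
#' @param n_permutations number of random shuffles (10,000 by default).
#' @param levels upper-quantile confidence levels.
#' @param seed RNG seed for reproducible envelopes.
#' @return a `bootstrap_envelope`: `quantiles` (named list of k x k
#'   matrices, one per level), `n_permutations`, `exact`, `seed`.
#' @export
bootstrap_envelope <- function(labels, k = NULL, n_permutations = 10000,
                               levels = c(0.90, 0.95, 0.99), seed = NULL) {
  seqs <- split_by_run(labels)
  if (is.null(k)) {
    k <- if (inherits(labels, "state_sequence")) labels$k else
      max(unlist(seqs))
  }
  if (length(unique(unlist(seqs))) < 2L) {
    stop_invalid("sequence has fewer than 2 distinct labels; no transitions under any permutation")
  }
  levels <- sort(levels)
  n_tot <- sum(lengths(seqs))
  exact <- length(seqs) == 1L && n_tot <= 7L &&
    factorial(n_tot) <= n_permutations
  draw <- function(perm_fn, n_draws) {
    sims <- array(0, dim = c(k, k, n_draws))
    for (b in seq_len(n_draws)) {
      shuffled <- perm_fn(b)
      counts <- count_transitions(shuffled, k)
      rs <- rowSums(counts)
      p <- counts / ifelse(rs > 0, rs, 1)
      diag(p) <- 0
      sims[, , b] <- p
    }
    sims
  }
  sims <- if (exact) {
    perms <- all_permutations(n_tot)
    s <- seqs[[1L]]
    draw(function(b) list(s[perms[b, ]]), nrow(perms))
  } else {
    with_seed(seed,
      draw(function(b) lapply(seqs, function(s) s[sample.int(length(s))]),
           n_permutations))
  }
  qs <- lapply(levels, function(lv) {
    apply(sims, c(1L, 2L), stats::quantile, probs = lv, type = 7, names = FALSE)
  })
  names(qs) <- sprintf("%g", levels)
  structure(
    list(quantiles = qs, levels = levels,
         n_permutations = if (exact) dim(sims)[3L] else n_permutations,
         exact = exact, seed = seed),
    class = "bootstrap_envelope")
}

#' Transitions exceeding the permutation null
#'
#' Marks the transitions whose empirical probability strictly exceeds the
#' null envelope's upper quantile at the chosen confidence level. The
#' diagonal is always `FALSE`.
#'
#' @param empirical a `transition_matrix`.
#' @param envelope a matching `bootstrap_envelope`.
#' @param level one of the envelope's confidence levels.
#' @return logical k x k mask.
#' @export
significant_transitions <- function(empirical, envelope, level = 0.95) {
  stopifnot(inherits(empirical, "transition_matrix"),
            inherits(envelope, "bootstrap_envelope"))
  key <- sprintf("%g", level)
  if (!key %in% names(envelope$quantiles)) {
    stop_invalid("level ", level, " not present in the envelope")
  }
  q <- envelope$quantiles[[key]]
  if (!all(dim(q) == dim(empirical$probs))) stop_invalid("shape mismatch")
  mask <- empirical$probs > q
  diag(mask) <- FALSE
  mask
}
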