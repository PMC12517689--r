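# Shared fixtures, built in code at test time.

tiny_run <- function(values, tr = 2.4, ...) {
  roi_run(values, tr_seconds = tr, metadata = list(...))
}

cosine_run <- function(freqs_hz, n = 200, tr = 2.4, phases = 0, noise = 0,
                       seed = NULL, ...) {
  if (length(freqs_hz) == 1L) {  # roi_run needs >= 2 regions
    freqs_hz <- rep(freqs_hz, 2)
    phases <- c(phases[1], phases[1] + 1)
  }
  tt <- (seq_len(n) - 1) * tr
  phases <- rep_len(phases, length(freqs_hz))
  v <- t(mapply(function(f, p) cos(2 * pi * f * tt + p), freqs_hz, phases))
  if (noise > 0) {
    v <- v + with_seed_helper(seed, matrix(rnorm(length(v), 0, noise),
                                           nrow(v), ncol(v)))
  }
  tiny_run(v, tr = tr, ...)
}

with_seed_helper <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  force(code)
}

# small symmetric hollow connectome with distinct weights
toy_connectome <- function(n = 10, seed = 3) {
  with_seed_helper(seed, {
    w <- matrix(0, n, n)
    w[upper.tri(w)] <- runif(n * (n - 1) / 2, 0.1, 2)
    w <- w + t(w)
    rownames(w) <- colnames(w) <- sprintf("ROI%03d", seq_len(n))
    w
  })
}

# a small two-condition synthetic study run end to end (used by several files)
small_study <- function(n_rois = 12, n_runs = 3, k = 3, n_volumes = 80,
                        seed = 17) {
  cfg <- simulation_config(
    n_rois = n_rois, n_volumes = n_volumes, k_states = k,
    conditions = list(
      list(name = "a", n_runs = n_runs, occupancy = rep(1 / k, k)),
      list(name = "b", n_runs = n_runs, occupancy = c(rep(0.5 / (k - 1), k - 1), 0.5))),
    seed = seed)
  generate_study(cfg)
}

# brute-force minimal WSS over all k^F assignments (tiny instances only)
brute_force_wss <- function(x, k) {
  f <- nrow(x)
  best <- Inf
  grid <- rep(1L, f)
  repeat {
    if (length(unique(grid)) == k) {
      wss <- 0
      for (g in unique(grid)) {
        rows <- x[grid == g, , drop = FALSE]
        cen <- colMeans(rows)
        wss <- wss + sum(sweep(rows, 2, cen)^2)
      }
      if (wss < best) best <- wss
    }
    i <- 1L
    while (i <= f && grid[i] == k) { grid[i] <- 1L; i <- i + 1L }
    if (i > f) break
    grid[i] <- grid[i] + 1L
  }
  best
}

# transition probabilities of one label ordering, self-transitions ignored
manual_transition_probs <- function(s, k) {
  counts <- matrix(0, k, k)
  for (t in seq_len(length(s) - 1)) {
    if (s[t] != s[t + 1]) counts[s[t], s[t + 1]] <- counts[s[t], s[t + 1]] + 1
  }
  rs <- rowSums(counts)
  p <- counts / ifelse(rs > 0, rs, 1)
  diag(p) <- 0
  p
}
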