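#' Configuration for a synthetic coordination study
#'
#' Collects every knob of the generator. The defaults emulate the
#' acquisition this package targets: 82 cortical regions, runs of 111
#' volumes at a 2.4 s repetition time, band-limited signals carried at
#' 0.02 Hz (mid-passband, clear of the 0.03 Hz notch), and state-switching
#' phase templates driven by a sticky Markov chain.
#'
#' Each condition is a list with `name`, `n_runs`, and either a k x k
#' row-stochastic `transition` matrix or an `occupancy` vector pi (from
#' which a sticky chain `P = persistence * I + (1 - persistence) * 1 pi'`
#' with stationary distribution pi is built).
#'
#' @param n_rois number of regions.
#' @param n_volumes volumes per run (>= 3).
#' @param tr_seconds repetition time in seconds.
#' @param carrier_hz carrier frequency; must lie strictly inside the
#'   band-pass (0.0025, 0.05) Hz.
#' @param snr ratio of carrier amplitude to additive white-noise standard
#'   deviation (> 0).
#' @param k_states number of planted coordination templates.
#' @param persistence probability of staying in the current state per
#'   volume for conditions specified through an occupancy vector.
#' @param conditions list of condition specifications (see Details);
#'   defaults to [awake_study_conditions()] scaled down to 4 runs each.
#' @param connectome_density fraction of nonzero region pairs.
#' @param seed master seed for the whole study.
#' @return a `simulation_config` list.
#' @export
simulation_config <- function(n_rois = 82, n_volumes = 111, tr_seconds = 2.4,
                              carrier_hz = 0.02, snr = 5, k_states = 6,
                              persistence = 0.85,
                              conditions = NULL,
                              connectome_density = 0.3, seed = 1) {
  if (!is_count(n_rois, 2)) stop_invalid("n_rois must be an integer >= 2")
  if (!is_count(n_volumes, 3)) stop_invalid("n_volumes must be an integer >= 3")
  if (!(carrier_hz > 0.0025 && carrier_hz < 0.05)) {
    stop_invalid("carrier_hz must lie strictly inside the 0.0025-0.05 Hz passband")
  }
  if (!(snr > 0)) stop_invalid("snr must be positive")
  if (!is_count(k_states, 2)) stop_invalid("k_states must be an integer >= 2")
  if (!(persistence >= 0 && persistence < 1)) {
    stop_invalid("persistence must lie in [0, 1)")
  }
  if (is.null(conditions)) {
    conditions <- awake_study_conditions(k_states, n_runs = NULL)
  }
  if (!length(conditions)) stop_invalid("need at least one condition")
  for (cn in conditions) {
    if (is.null(cn$name) || is.null(cn$n_runs) || cn$n_runs < 1L) {
      stop_invalid("each condition needs a name and n_runs >= 1")
    }
    if (!is.null(cn$transition)) check_stochastic(cn$transition, k_states)
    else if (is.null(cn$occupancy)) {
      stop_invalid("condition ", cn$name, " needs a transition matrix or occupancy vector")
    } else if (length(cn$occupancy) != k_states ||
               abs(sum(cn$occupancy) - 1) > 1e-9 || any(cn$occupancy < 0)) {
      stop_invalid("condition ", cn$name, " occupancy must be a k-simplex vector")
    }
  }
  structure(
    list(n_rois = n_rois, n_volumes = n_volumes, tr_seconds = tr_seconds,
         carrier_hz = carrier_hz, snr = snr, k_states = k_states,
         persistence = persistence, conditions = conditions,
         connectome_density = connectome_density, seed = seed),
    class = "simulation_config")
}

check_stochastic <- function(p, k, tol = 1e-9) {
  check_square(p, "transition matrix")
  if (nrow(p) != k) stop_invalid("transition matrix must be k x k")
  if (any(p < 0) || any(abs(rowSums(p) - 1) > tol)) {
    stop_invalid("transition matrix rows must be non-negative and sum to 1")
  }
  invisible(p)
}

#' Stimulation-study condition set
#'
#' Five awake conditions (pre-stimulation baseline, anodal and cathodal
#' stimulation, and their post-stimulation phases) whose anatomical-pattern
#' occupancies (0.37, 0.33, 0.34, 0.50, 0.51) reproduce the published
#' effect sizes of prefrontal stimulation on the anatomically anchored
#' pattern; the remaining probability mass is spread evenly over the other
#' patterns. Run counts default to the study's per-condition totals
#' (82, 38, 39, 15, 16).
#'
#' @param k_states number of patterns (the anatomical pattern is the k-th).
#' @param n_runs optional vector of run counts per condition (recycled);
#'   `NULL` keeps the study's counts.
#' @return a list of condition specifications for [simulation_config()].
#' @export
awake_study_conditions <- function(k_states = 6, n_runs = NULL) {
  tab <- data.frame(
    name = c("before", "anodal", "post_anodal", "cathodal", "post_cathodal"),
    montage = c("none", "F4/O1", "F4/O1", "O1/F4", "O1/F4"),
    stim_phase = c("before", "during", "after", "during", "after"),
    n_runs = c(82, 38, 39, 15, 16),
    anatomical = c(0.37, 0.33, 0.34, 0.50, 0.51))
  if (!is.null(n_runs)) tab$n_runs <- rep_len(n_runs, nrow(tab))
  lapply(seq_len(nrow(tab)), function(i) {
    rest <- (1 - tab$anatomical[i]) / (k_states - 1)
    list(name = tab$name[i], n_runs = tab$n_runs[i],
         montage = tab$montage[i], stim_phase = tab$stim_phase[i],
         occupancy = c(rep(rest, k_states - 1), tab$anatomical[i]))
  })
}

#' Generate a synthetic structural connectome
#'
#' Symmetric, non-negative, hollow weight matrix with lognormal
#' (heavy-tailed) weights and a bilaterally mirrored two-hemisphere block
#' structure when `n_rois` is even: both within-hemisphere blocks share the
#' same wiring, within-hemisphere connections are enriched relative to
#' interhemispheric ones, and most homotopic (mirror-region) pairs are
#' connected. The number of nonzero upper-triangle entries matches
#' `round(density * N(N-1)/2)` to within one entry.
#'
#' @param n_rois number of regions (>= 2).
#' @param density fraction of connected pairs, in (0, 1].
#' @param seed RNG seed.
#' @return N x N numeric matrix with region names.
#' @export
generate_connectome <- function(n_rois, density = 0.3, seed = NULL) {
  if (!is_count(n_rois, 2)) stop_invalid("n_rois must be an integer >= 2")
  if (!(density > 0 && density <= 1)) stop_invalid("density must lie in (0, 1]")
  with_seed(seed, {
    n_pairs <- n_rois * (n_rois - 1) / 2
    target <- round(density * n_pairs)
    w <- matrix(0, n_rois, n_rois)
    if (n_rois %% 2 == 0 && n_rois >= 4) {
      h <- n_rois %/% 2
      pa <- h * (h - 1) / 2           # pairs per within-hemisphere block
      enrich <- 1.6                    # within- vs inter-hemisphere odds
      na <- min(pa, round(target * (2 * pa * enrich) /
                            (2 * pa * enrich + h * h) / 2))
      nb <- min(h * h, target - 2 * na)
      pick <- function(pool, m) pool[sample.int(length(pool), m)]
      a <- matrix(0, h, h)
      idx_a <- pick(which(upper.tri(a)), na)
      a[idx_a] <- stats::rlnorm(na, 0, 1)
      a <- a + t(a)
      b <- matrix(0, h, h)
      n_hom <- min(nb, round(0.8 * h))  # favour homotopic pairs
      hom <- sample(h, n_hom)
      b[cbind(hom, hom)] <- stats::rlnorm(n_hom, 0.5, 0.5)
      off <- which(b == 0)
      extra <- nb - n_hom
      if (extra > 0) b[pick(off, extra)] <- stats::rlnorm(extra, 0, 1)
      w[1:h, 1:h] <- a
      w[(h + 1):n_rois, (h + 1):n_rois] <- a
      w[1:h, (h + 1):n_rois] <- b
      w[(h + 1):n_rois, 1:h] <- t(b)
    } else {
      pool <- which(upper.tri(w))
      w[pool[sample.int(length(pool), target)]] <- stats::rlnorm(target, 0, 1)
      w <- w + t(w)
    }
    rownames(w) <- colnames(w) <- sprintf("ROI%03d", seq_len(n_rois))
    w
  })
}

#' Planted coordination templates from graded phase offsets
#'
#' Builds `k_states` coherence templates as exact cosine-difference matrices
#' of per-region phase-offset vectors with geometrically increasing
#' dispersion. Template m's offsets scale the m-th non-trivial harmonic of
#' the connectome's graph Laplacian (plus fresh jitter), so each template
#' follows a different anatomically grounded spatial gradient: strongly
#' connected regions get similar offsets along that gradient. Low-dispersion
#' templates are globally coherent; high-dispersion templates mix in- and
#' anti-phase relations; distinct harmonics keep the templates mutually
#' well separated. Templates are returned sorted by ascending
#' structure-function correlation and must have pairwise distinct SFC
#' values (redrawn a bounded number of times otherwise).
#'
#' @param k_states number of templates (>= 2).
#' @param connectome structural matrix used for the gradient and the SFC
#'   ordering.
#' @param dispersions optional increasing vector of offset dispersions in
#'   radians; default geometric from 0.4 to 2.4.
#' @param jitter fractional jitter of each template's dispersion.
#' @param seed RNG seed.
#' @return list: `templates` (list of N x N matrices, ascending SFC),
#'   `phase_offsets` (k x N matrix of angles in `[-pi, pi)`), `sfc_values`,
#'   `dispersions`.
#' @export
generate_templates <- function(k_states, connectome, dispersions = NULL,
                               jitter = 0.1, seed = NULL) {
  if (!is_count(k_states, 2)) stop_invalid("k_states must be an integer >= 2")
  check_square(connectome, "connectome")
  n <- nrow(connectome)
  if (k_states > n - 1L) stop_invalid("k_states must be < n_rois")
  if (is.null(dispersions)) {
    dispersions <- 0.4 * (2.4 / 0.4)^((seq_len(k_states) - 1) / (k_states - 1))
  }
  if (length(dispersions) != k_states || any(diff(dispersions) <= 0)) {
    stop_invalid("dispersions must be an increasing vector of length k_states")
  }
  lap <- diag(rowSums(connectome)) - connectome
  harm <- eigen(lap, symmetric = TRUE)$vectors  # columns: descending eigenvalue
  with_seed(seed, {
    for (attempt in seq_len(25L)) {
      offs <- t(vapply(seq_len(k_states), function(m) {
        u <- harm[, n - m]               # m-th non-trivial harmonic
        u <- (u - mean(u)) / stats::sd(u)
        o <- dispersions[m] * u + stats::rnorm(n, 0, jitter * dispersions[m])
        (o + pi) %% (2 * pi) - pi   # wrap; cosine differences are unchanged
      }, numeric(n)))
      tmpl <- lapply(seq_len(k_states), function(m) {
        cos(outer(offs[m, ], offs[m, ], "-"))
      })
      vals <- vapply(tmpl, sfc, numeric(1), connectome = connectome)
      if (min(diff(sort(vals))) > 1e-6) {
        ord <- order(vals)
        colnames(offs) <- rownames(connectome)
        return(list(templates = tmpl[ord],
                    phase_offsets = offs[ord, , drop = FALSE],
                    sfc_values = vals[ord],
                    dispersions = dispersions[ord]))
      }
    }
    stop_invalid("could not achieve pairwise-distinct template SFCs")
  })
}

#' Stationary distribution of a finite Markov chain
#'
#' Leading left eigenvector of the transition matrix, renormalised to a
#' probability vector (ties between equal leading eigenvalues broken by
#' first index).
#'
#' @param transition k x k row-stochastic matrix.
#' @return length-k probability vector.
#' @export
stationary_distribution <- function(transition) {
  check_stochastic(transition, nrow(transition))
  e <- eigen(t(transition))
  i <- which(abs(Re(e$values) - 1) < 1e-8 & abs(Im(e$values)) < 1e-8)[1L]
  if (is.na(i)) i <- which.max(Re(e$values))
  v <- abs(Re(e$vectors[, i]))
  v / sum(v)
}

sticky_chain <- function(occupancy, persistence) {
  k <- length(occupancy)
  persistence * diag(k) + (1 - persistence) *
    matrix(occupancy, k, k, byrow = TRUE)
}

#' Sample a hidden state sequence from a Markov chain
#'
#' The first state is drawn from the chain's stationary distribution; each
#' subsequent state from the corresponding transition row.
#'
#' @param transition k x k row-stochastic matrix (rows sum to 1 within 1e-9).
#' @param n_volumes sequence length.
#' @param seed RNG seed.
#' @return integer vector of states in 1..k.
#' @export
generate_state_sequence <- function(transition, n_volumes, seed = NULL) {
  check_stochastic(transition, nrow(transition))
  if (!is_count(n_volumes)) stop_invalid("n_volumes must be a positive integer")
  k <- nrow(transition)
  pi0 <- stationary_distribution(transition)
  with_seed(seed, {
    s <- integer(n_volumes)
    s[1L] <- sample.int(k, 1L, prob = pi0)
    if (n_volumes > 1L) {
      u <- stats::runif(n_volumes - 1L)
      cum <- t(apply(transition, 1L, cumsum))
      for (t in 2:n_volumes) {
        s[t] <- sum(u[t - 1L] > cum[s[t - 1L], ]) + 1L
      }
    }
    s
  })
}

#' Synthesise one narrowband state-switching run
#'
#' Region i's signal is `cos(2 pi f t + offset_i(state(t)))` plus white
#' Gaussian noise of standard deviation `1/snr`. At every state switch the
#' old and new carriers are blended with a raised-cosine cross-fade over the
#' 2 volumes following the switch, avoiding broadband transients that would
#' corrupt the instantaneous phase.
#'
#' @param state_sequence integer states in 1..k, length `n_volumes`.
#' @param phase_offsets k x N matrix of per-state regional offsets in
#'   `[-pi, pi)`.
#' @param config a [simulation_config()].
#' @param metadata metadata list attached to the run.
#' @param seed RNG seed for the noise.
#' @return an [roi_run()].
#' @export
synthesize_run <- function(state_sequence, phase_offsets, config,
                           metadata = list(), seed = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  tn <- length(state_sequence)
  if (tn != config$n_volumes) {
    stop_invalid("state sequence length must equal n_volumes")
  }
  if (any(phase_offsets < -pi | phase_offsets >= pi)) {
    stop_invalid("phase offsets must lie in [-pi, pi)")
  }
  if (any(state_sequence < 1L | state_sequence > nrow(phase_offsets))) {
    stop_invalid("state sequence and phase offsets disagree on k")
  }
  n <- ncol(phase_offsets)
  tt <- (seq_len(tn) - 1) * config$tr_seconds
  arg <- 2 * pi * config$carrier_hz * tt
  ## carrier for the state active at each volume, regions x time
  x <- cos(outer(rep(1, n), arg) + t(phase_offsets[state_sequence, , drop = FALSE]))
  ## raised-cosine cross-fade over the 2 samples after each switch
  switches <- which(diff(state_sequence) != 0) + 1L
  fade <- 2L
  for (p in switches) {
    old <- state_sequence[p - 1L]
    for (j in seq_len(fade)) {
      t_i <- p + j - 1L
      if (t_i > tn) break
      if (state_sequence[t_i] != state_sequence[p]) break  # a newer switch wins
      w_new <- 0.5 * (1 - cos(pi * j / (fade + 1)))
      x_old <- cos(arg[t_i] + phase_offsets[old, ])
      x[, t_i] <- (1 - w_new) * x_old + w_new * x[, t_i]
    }
  }
  x <- x + with_seed(seed, matrix(stats::rnorm(n * tn, 0, 1 / config$snr), n, tn))
  roi_run(x, roi_names = colnames(phase_offsets),
          tr_seconds = config$tr_seconds, metadata = metadata)
}

#' Generate a full synthetic study
#'
#' Draws a connectome, planted templates, per-run hidden state sequences
#' (one sticky Markov chain per condition), and -- unless `signals = FALSE`
#' -- the narrowband regional time series for every run. Deterministic under
#' the config seed.
#'
#' @param config a [simulation_config()].
#' @param signals synthesise the time series (set `FALSE` for studies where
#'   only the hidden sequences and templates are needed, e.g. large
#'   occupancy-calibration experiments).
#' @return list: `runs` (list of `roi_run`, empty when `signals = FALSE`),
#'   `connectome`, and `truth` (templates, phase offsets, SFC values, state
#'   sequences, condition per run, generator transition matrices).
#' @export
generate_study <- function(config, signals = TRUE) {
  stopifnot(inherits(config, "simulation_config"))
  seed <- config$seed
  connectome <- generate_connectome(config$n_rois, config$connectome_density,
                                    seed = child_seed(seed, 1))
  truth_tmpl <- generate_templates(config$k_states, connectome,
                                   seed = child_seed(seed, 2))
  runs <- list()
  sequences <- list()
  run_condition <- character(0)
  transitions <- list()
  subjects <- c("S1", "S2")
  r_global <- 0L
  for (ci in seq_along(config$conditions)) {
    cond <- config$conditions[[ci]]
    p <- cond$transition %||% sticky_chain(cond$occupancy, config$persistence)
    transitions[[cond$name]] <- p
    for (r in seq_len(cond$n_runs)) {
      r_global <- r_global + 1L
      s <- generate_state_sequence(p, config$n_volumes,
                                   seed = child_seed(seed, 100 + r_global))
      run_id <- sprintf("%s_run%03d", cond$name, r)
      sequences[[run_id]] <- s
      run_condition[run_id] <- cond$name
      if (signals) {
        md <- list(run_id = run_id,
                   subject = subjects[(r_global %% 2L) + 1L],
                   condition = cond$name,
                   montage = cond$montage %||% NA_character_,
                   stim_phase = cond$stim_phase %||% NA_character_)
        runs[[run_id]] <- synthesize_run(
          s, truth_tmpl$phase_offsets, config, metadata = md,
          seed = child_seed(seed, 500000 + r_global))
      }
    }
  }
  list(runs = runs, connectome = connectome,
       truth = list(templates = truth_tmpl$templates,
                    phase_offsets = truth_tmpl$phase_offsets,
                    sfc_values = truth_tmpl$sfc_values,
                    state_sequences = sequences,
                    run_condition = run_condition,
                    transition_matrices = transitions))
}
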