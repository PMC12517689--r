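test_that("synthetic connectomes are symmetric, hollow, and hit the target density", {
  w <- generate_connectome(2, density = 1, seed = 1)
  expect_equal(w, t(w))
  expect_equal(unname(diag(w)), c(0, 0))
  expect_gt(w[1, 2], 0)

  w <- generate_connectome(82, density = 0.3, seed = 1)
  nz <- sum(w[upper.tri(w)] > 0)
  expect_lte(abs(nz - round(0.3 * 82 * 81 / 2)), 1)
  expect_true(all(w >= 0))
  expect_equal(w, t(w))
  expect_equal(max(abs(diag(w))), 0)
  ## mirrored hemispheres: the two within-hemisphere blocks coincide
  expect_equal(w[1:41, 1:41], w[42:82, 42:82],
               ignore_attr = TRUE)

  expect_identical(generate_connectome(20, 0.4, seed = 7),
                   generate_connectome(20, 0.4, seed = 7))
  expect_error(generate_connectome(1), "n_rois")
  expect_error(generate_connectome(10, density = 0), "density")
  expect_error(generate_connectome(10, density = 1.2), "density")
})

test_that("templates are exact cosine-difference matrices in ascending SFC order", {
  conn <- generate_connectome(10, 0.5, seed = 2)
  g <- generate_templates(3, conn, seed = 7)
  for (m in 1:3) {
    o <- unname(g$phase_offsets[m, ])
    expect_true(all(o >= -pi & o < pi))
    expect_identical(g$templates[[m]], cos(outer(o, o, "-")))  # max deviation 0
    expect_equal(g$templates[[m]], t(g$templates[[m]]))
    expect_equal(diag(g$templates[[m]]), rep(1, 10), ignore_attr = TRUE)
  }
  expect_true(all(diff(g$sfc_values) > 1e-6))
  recomputed <- vapply(g$templates, sfc, numeric(1), connectome = conn)
  expect_equal(recomputed, g$sfc_values)

  ## near-zero dispersion gives a near-all-ones template
  flat <- generate_templates(2, conn, dispersions = c(1e-3, 1), seed = 8)
  low <- flat$templates[[which.min(flat$dispersions)]]
  expect_gt(min(low), 1 - 1e-3)
})

test_that("hidden state sequences follow the generator chain", {
  expect_equal(generate_state_sequence(diag(3), 10, seed = 1),
               rep(generate_state_sequence(diag(3), 1, seed = 1), 10))

  p <- matrix(0.5, 2, 2)
  s <- generate_state_sequence(p, 10000, seed = 4)
  expect_lt(abs(mean(s == 1) - 0.5), 0.02)

  expect_identical(generate_state_sequence(p, 50, seed = 9),
                   generate_state_sequence(p, 50, seed = 9))
  expect_error(generate_state_sequence(matrix(c(0.5, 0.2, 0.5, 0.7), 2, 2), 10),
               "sum to 1")

  ## occupancy converges to the analytic stationary distribution
  sticky <- 0.8 * diag(3) + 0.2 * matrix(c(0.2, 0.3, 0.5), 3, 3, byrow = TRUE)
  pi0 <- stationary_distribution(sticky)
  expect_equal(pi0, c(0.2, 0.3, 0.5), tolerance = 1e-9)
  s <- generate_state_sequence(sticky, 10000, seed = 12)
  expect_lt(max(abs(tabulate(s, 3) / 10000 - pi0)), 0.02)
})

test_that("synthesised runs carry the planted phase structure", {
  ## single state, all offsets zero, negligible noise: identical regions
  cfg <- simulation_config(n_rois = 4, n_volumes = 50, k_states = 2, snr = 1e9,
    conditions = list(list(name = "x", n_runs = 1, occupancy = c(0.5, 0.5))))
  offs <- matrix(0, 2, 4, dimnames = list(NULL, paste0("R", 1:4)))
  run <- synthesize_run(rep(1L, 50), offs, cfg, seed = 1)
  expect_lt(max(abs(sweep(run$values, 2, run$values[1, ]))), 1e-6)

  ## two regions a quarter-cycle apart: the phase difference is recovered
  cfg2 <- simulation_config(n_rois = 2, n_volumes = 500, k_states = 2, snr = 1e9,
    conditions = list(list(name = "x", n_runs = 1, occupancy = c(0.5, 0.5))))
  offs2 <- matrix(rep(c(0, pi / 2), each = 2), 2, 2,
                  dimnames = list(NULL, c("Ra", "Rb")))
  run2 <- synthesize_run(rep(1L, 500), offs2, cfg2, seed = 2)
  ph <- analytic_phase(zscore_run(run2))
  d <- ph$phases[1, ] - ph$phases[2, ]
  d <- (d + pi) %% (2 * pi) - pi
  core <- d[10:(length(d) - 10)]
  expect_lt(max(abs(abs(core) - pi / 2)), 0.05)

  expect_error(synthesize_run(rep(1L, 10), offs2, cfg2), "n_volumes")
})

test_that("generated runs stay narrowband through the conditioning filters", {
  st <- small_study(n_rois = 6, n_runs = 1, n_volumes = 200)
  run <- temporal_filter(st$runs[[1]])
  fs <- 1 / run$tr_seconds
  for (i in 1:3) {
    x <- run$values[i, ] - mean(run$values[i, ])
    pw <- Mod(fft(x))^2
    freqs <- (seq_along(x) - 1) / length(x) * fs
    freqs[freqs > fs / 2] <- freqs[freqs > fs / 2] - fs
    in_band <- abs(freqs) >= 0.0025 & abs(freqs) <= 0.05
    expect_gt(sum(pw[in_band]) / sum(pw), 0.9)
  }
})

test_that("whole studies are deterministic with faithful bookkeeping", {
  st <- small_study(n_rois = 6, n_runs = 2, n_volumes = 40)
  expect_length(st$runs, 4)
  conds <- vapply(st$runs, function(r) r$metadata$condition, "")
  expect_equal(unname(table(conds)[c("a", "b")]), c(2L, 2L), ignore_attr = TRUE)
  expect_identical(names(st$truth$state_sequences), names(st$runs))

  st2 <- small_study(n_rois = 6, n_runs = 2, n_volumes = 40)
  expect_identical(lapply(st$runs, `[[`, "values"),
                   lapply(st2$runs, `[[`, "values"))

  ## serialisation round trip is byte-identical under a fixed seed
  d1 <- file.path(tempdir(), "study_a"); d2 <- file.path(tempdir(), "study_b")
  write_study(st$runs, d1, connectome = st$connectome, seed = 17)
  write_study(st2$runs, d2, connectome = st2$connectome, seed = 17)
  for (f in list.files(d1)) {
    expect_identical(readBin(file.path(d1, f), "raw", 1e6),
                     readBin(file.path(d2, f), "raw", 1e6))
  }
  back <- read_study(d1)
  expect_equal(back$runs[[1]]$values, st$runs[[1]]$values, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(back$connectome, st$connectome, tolerance = 1e-12)

  expect_error(simulation_config(conditions = list()), "condition")
})
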