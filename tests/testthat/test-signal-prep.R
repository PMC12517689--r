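test_that("global-signal regression leaves residuals orthogonal to the global mean", {
  set.seed(1)
  g <- cumsum(rnorm(120))
  v <- rbind(g + rnorm(120, sd = 0.3),
             -0.5 * g + rnorm(120, sd = 0.3),
             rnorm(120))
  out <- regress_global_signal(tiny_run(v))
  global <- colMeans(v)
  for (i in 1:3) {
    expect_lt(abs(cor(out$values[i, ], global)), 1e-10)
  }

  ## identical rows: the global signal explains everything
  same <- tiny_run(rbind(g, g, g))
  expect_equal(max(abs(regress_global_signal(same)$values)), 0, tolerance = 1e-12)

  ## constant run goes through the degenerate branch and yields zero residuals
  const <- tiny_run(matrix(5, 3, 50))
  expect_warning(res <- regress_global_signal(const), "zero variance")
  expect_equal(max(abs(res$values)), 0)
})

test_that("temporal filter passes the band, kills the notch and DC, and is zero-phase", {
  ## constant series -> (numerically) zero
  const <- tiny_run(matrix(3, 2, 200))
  out <- temporal_filter(const)
  expect_lt(max(abs(out$values)), 1e-6 * 3)

  rms <- function(x) sqrt(mean(x^2))
  ## 0.03 Hz tone is attenuated by the notch (>= 20 dB)
  at_notch <- cosine_run(c(0.03, 0.03), n = 1000, phases = c(0, 1))
  out <- temporal_filter(at_notch)
  expect_lt(rms(out$values[1, ]) / rms(at_notch$values[1, ]), 0.1)

  ## 0.01 and 0.02 Hz tones pass with near-unit gain
  for (f in c(0.01, 0.02)) {
    tone <- cosine_run(f, n = 1000)
    out <- temporal_filter(tone)
    expect_gt(rms(out$values[1, ]) / rms(tone$values[1, ]), 0.9)
    expect_lt(rms(out$values[1, ]) / rms(tone$values[1, ]), 1.1)
  }

  ## exact zero-phase: filtering a reversed series == reversing the filtered one
  set.seed(2)
  v <- matrix(rnorm(2 * 300), 2, 300)
  fwd <- temporal_filter(tiny_run(v))$values
  rev_ <- temporal_filter(tiny_run(v[, 300:1]))$values
  expect_lt(max(abs(fwd - rev_[, 300:1])), 1e-8)

  ## precondition violations
  expect_error(temporal_filter(tiny_run(v), low_cut = 0.06, high_cut = 0.05),
               "cutoffs")
  expect_error(temporal_filter(tiny_run(v), notch = 0.2), "notch")
  expect_error(temporal_filter(tiny_run(matrix(rnorm(8 * 2), 2, 8)),
                               high_cut = 0.05), "at least 9")
})

test_that("z-scoring normalises rows, is idempotent, and rejects flat regions", {
  r <- tiny_run(rbind(c(1, 2, 3, 4), c(10, 0, 5, 5)))
  z <- zscore_run(r)
  expect_equal(unname(rowMeans(z$values)), c(0, 0), tolerance = 1e-10)
  expect_equal(unname(apply(z$values, 1, sd)), c(1, 1), tolerance = 1e-10)
  expect_equal(zscore_run(z)$values, z$values, tolerance = 1e-10)

  flat <- roi_run(rbind(c(1, 2, 3), c(7, 7, 7)),
                  roi_names = c("good", "flat"), tr_seconds = 2.4)
  expect_error(zscore_run(flat), "flat")
})

test_that("analytic phase tracks a pure cosine and reconstructs the signal", {
  ## 12 carrier cycles in the window keep the discrete transform leak-free
  r <- cosine_run(c(0.01, 0.01), n = 500, phases = c(0, -pi / 2))
  p <- analytic_phase(zscore_run(r))
  expect_equal(ncol(p$phases), 498)
  expect_true(all(p$phases >= -pi & p$phases < pi))

  inc <- diff(p$phases[1, ])
  inc <- (inc + pi) %% (2 * pi) - pi
  target <- 2 * pi * 0.01 * 2.4
  core <- inc[6:(length(inc) - 5)]
  expect_lt(max(abs(core - target)), 0.01)

  ## quadrature pair: cos vs sin of the same carrier differ by pi/2
  d <- p$phases[1, ] - p$phases[2, ]
  d <- (d + pi) %% (2 * pi) - pi
  expect_lt(max(abs(abs(d[6:490]) - pi / 2)), 0.02)

  ## reconstruction identity on the retained samples
  z <- zscore_run(r)
  recon <- p$amplitudes * cos(p$phases)
  expect_lt(max(abs(recon - z$values[, 2:499])) / max(abs(z$values)), 1e-6)

  ## trim rule: 111 volumes -> 109 phase columns
  r111 <- cosine_run(c(0.02, 0.02), n = 111, phases = c(0, 1))
  expect_equal(ncol(analytic_phase(zscore_run(r111))$phases), 109)
})
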