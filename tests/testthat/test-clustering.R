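test_that("k-means degenerate and scaling properties hold", {
  set.seed(4)
  x <- matrix(rnorm(60), 20, 3)
  fit1 <- fit_kmeans(x, 1, n_init = 2, seed = 1)
  expect_equal(drop(fit1$patterns$centroids), colMeans(x), tolerance = 1e-12)

  ## well-separated data: duplicating every frame doubles the WSS only
  y <- rbind(matrix(rnorm(30), 10, 3), matrix(rnorm(30, mean = 8), 10, 3))
  f1 <- fit_kmeans(y, 2, n_init = 10, seed = 2)
  f2 <- fit_kmeans(rbind(y, y), 2, n_init = 10, seed = 3)
  expect_equal(f2$patterns$wss, 2 * f1$patterns$wss, tolerance = 1e-8)
  ord1 <- order(f1$patterns$centroids[, 1])
  ord2 <- order(f2$patterns$centroids[, 1])
  expect_equal(f1$patterns$centroids[ord1, ], f2$patterns$centroids[ord2, ],
               tolerance = 1e-8)

  expect_error(fit_kmeans(x, 25), "no larger")
})

test_that("labels are exact nearest-centroid assignments and fits are seed-deterministic", {
  st <- small_study(n_rois = 8, n_runs = 2, n_volumes = 60)
  fr <- build_dataset_frames(lapply(st$runs, prepare_phases, gsr = FALSE))
  fit <- fit_kmeans(fr, 3, n_init = 4, seed = 11)
  cen <- fit$patterns$centroids
  for (row in seq_len(nrow(fr$frames))) {
    d <- colSums((t(cen) - fr$frames[row, ])^2)
    expect_equal(fit$labels$labels[row], which.min(d))
  }
  fit2 <- fit_kmeans(fr, 3, n_init = 4, seed = 11)
  expect_identical(fit$patterns$centroids, fit2$patterns$centroids)
  expect_identical(fit$labels$labels, fit2$labels$labels)
})

test_that("best-of-many k-means attains the exhaustive-search optimum on tiny instances", {
  set.seed(9)
  for (k in 2:3) {
    x <- matrix(rnorm(8 * 3), 8, 3)
    fit <- fit_kmeans(x, k, n_init = 60, seed = k)
    expect_equal(fit$patterns$wss, brute_force_wss(x, k), tolerance = 1e-8)
  }
})

test_that("inter-pattern correlation variance follows the population-variance convention", {
  ## a single pair has variance zero
  expect_equal(ipcv(matrix(rnorm(20), 2, 10)), 0)

  ## positively proportional centroids all correlate at 1
  base <- rnorm(12)
  cen <- rbind(base, 2 * base, 0.5 * base)
  expect_equal(ipcv(cen), 0, tolerance = 1e-12)

  ## hand-built correlations {1, 0, 0} -> population variance 2/9
  c1 <- c(1, 2, 3)
  c3 <- c(1, -2, 1)      # cor(c1, c3) = 0
  cen <- rbind(c1, 2 * c1, c3)
  expect_equal(ipcv(cen), 2 / 9, tolerance = 1e-12)

  expect_error(ipcv(rbind(rep(1, 5), rnorm(5))), "zero-variance")
})

test_that("k selection maximises IPCV with ties broken toward smaller k", {
  ## three exactly equi-correlated cluster centres: IPCV is 0 at both k,
  ## so the tie rule must pick the smaller k
  a <- c(1, -1, 1, -1); b <- c(1, 1, -1, -1); cc <- c(1, -1, -1, 1)
  x <- rbind(a, a, a, b, b, b, cc, cc, cc)
  sel <- select_k(x, 2:3, n_init = 20, seed = 5)
  expect_equal(sel$k, 2)

  ## planted well-separated clusters: WSS non-increasing, zero at k = F
  set.seed(10)
  y <- matrix(rnorm(10 * 4), 10, 4)
  curve <- wss_curve(y, 2:10, n_init = 20, seed = 6)
  expect_true(all(diff(curve$wss) <= 1e-8))
  expect_equal(curve$wss[curve$k == 10], 0, tolerance = 1e-10)
})

test_that("SFC ordering permutes patterns and labels consistently", {
  st <- small_study(n_rois = 8, n_runs = 2, n_volumes = 60)
  fr <- build_dataset_frames(lapply(st$runs, prepare_phases, gsr = FALSE))
  fit <- fit_kmeans(fr, 3, n_init = 4, seed = 11)
  ranked <- order_by_sfc(fit$patterns, st$connectome, fit$labels)

  expect_true(all(diff(ranked$patterns$sfc_values) >= 0))
  ## occupancies are invariant under the relabelling
  occ_old <- tabulate(fit$labels$labels, 3) / length(fit$labels$labels)
  occ_new <- tabulate(ranked$labels$labels, 3) / length(ranked$labels$labels)
  expect_equal(sort(occ_old), sort(occ_new))
  ## label m now points at the centroid with the m-th smallest SFC
  perm <- ranked$patterns$permutation
  expect_identical(ranked$labels$labels,
                   match(fit$labels$labels, perm))

  ## an already-ordered set comes back unchanged
  again <- order_by_sfc(ranked$patterns, st$connectome)
  expect_identical(again$patterns$permutation, 1:3)
  expect_equal(again$patterns$centroids, ranked$patterns$centroids)
})
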