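test_that("simulated datasets have the declared dimensions and structure", {
  sim <- simulate_peaks(sim_config(seed = 1))   # reference conditions
  expect_equal(dim(sim$dataset), c(49L, 14L))
  expect_equal(dim(sim$similarity$Q), c(14L, 49L, 49L))
  expect_equal(max(sim$truth$labels), 7L)
  expect_equal(sim$truth$alpha[, 2], c(2, -1, 0.5, 0, 0, 0, 0))
  expect_equal(table(sim$dataset$sample_meta$group),
               table(rep(1:2, each = 7)), ignore_attr = TRUE)
  # reproducibility from the seed
  sim2 <- simulate_peaks(sim_config(seed = 1))
  expect_identical(sim2$dataset$heights, sim$dataset$heights)
  expect_identical(sim2$similarity$Q, sim$similarity$Q)
})

test_that("the noiseless limit exposes the latent cluster means", {
  sim <- simulate_peaks(sim_config(sigma_sq = 0, p_missing = 0,
                                   n_clusters = 3, peaks_per_cluster = 4,
                                   true_alpha = cbind(0, c(1, -1, 0)),
                                   seed = 2))
  H <- sim$dataset$heights
  z <- sim$truth$labels
  for (k in 1:3) {
    rows <- H[z == k, , drop = FALSE]
    expect_lt(max(apply(rows, 2, function(col) diff(range(col)))), 1e-12)
  }
  # similarity mask fully observed at p_missing = 0
  expect_true(all(sim$similarity$R == 1L))
})

test_that("null effects produce group differences at the noise level only", {
  K <- 7
  sim <- simulate_peaks(sim_config(n_per_group = 25,
                                   true_alpha = cbind(0, rep(0, K)),
                                   seed = 3))
  a <- sim$dataset$sample_meta$group
  p <- vapply(seq_len(K), function(k) {
    m <- colMeans(sim$dataset$heights[sim$truth$labels == k, , drop = FALSE])
    t.test(m[a == 2], m[a == 1])$p.value
  }, 0)
  expect_lte(sum(p < 0.05), 3)   # ~0.35 expected false positives
})

test_that("NID matches direct contingency-table computation", {
  expect_equal(nid(c(1, 1, 2, 2), c(2, 2, 1, 1)), 0)    # relabeling
  expect_equal(nid(1:6, rep(1, 6)), 1)                   # I = 0, maxH > 0
  expect_equal(nid(rep(1, 4), rep(1, 4)), 0)             # both trivial

  a <- c(1, 1, 1, 2, 2, 3); b <- c(1, 1, 2, 2, 3, 3)
  tab <- table(a, b) / 6
  pa <- rowSums(tab); pb <- colSums(tab)
  Ha <- -sum(pa * log(pa)); Hb <- -sum(pb * log(pb))
  I <- 0
  for (i in 1:3) for (j in 1:3) if (tab[i, j] > 0)
    I <- I + tab[i, j] * log(tab[i, j] / (pa[i] * pb[j]))
  expect_equal(nid(a, b), unname(1 - I / max(Ha, Hb)), tolerance = 1e-12)

  # metric properties on random partitions
  set.seed(4)
  for (r in 1:5) {
    x <- sample(1:3, 8, TRUE); y <- sample(1:4, 8, TRUE)
    expect_equal(nid(x, y), nid(y, x))
    expect_gte(nid(x, y), 0); expect_lte(nid(x, y), 1)
    expect_equal(nid(x, x), 0)
  }
})

test_that("BH step-up matches the textbook walkthrough", {
  expect_equal(bh_fdr(rep(1, 5)), rep(FALSE, 5))
  expect_equal(bh_fdr(0.01, 0.05), TRUE)
  # hand-worked example at q = 0.05, m = 10: sorted p against k q / m =
  # 0.005, 0.010, ..., 0.050; p_(5) = 0.024 <= 0.025 and p_(k) > k q / m
  # for k > 5, so the step-up rule rejects exactly the five smallest
  p <- c(0.2, 0.019, 0.004, 0.014, 0.4, 0.024, 0.06, 0.001, 0.5, 0.9)
  expect_equal(bh_fdr(p, 0.05),
               p %in% c(0.001, 0.004, 0.014, 0.019, 0.024))
})

test_that("effect MSE and detection accuracy match naive enumeration", {
  expect_equal(mse_effects(diag(3), diag(3)), 0)
  expect_equal(mse_effects(matrix(1, 2, 3), matrix(0, 2, 3)), 1)
  set.seed(5)
  A <- matrix(rnorm(12), 3); B <- matrix(rnorm(12), 3)
  acc <- 0
  for (i in seq_along(A)) acc <- acc + (A[i] - B[i])^2
  expect_equal(mse_effects(A, B), acc / 12)

  truth <- c(2, -1, 0, 0)
  expect_equal(detection_accuracy(c(TRUE, TRUE, FALSE, FALSE),
                                  c(1, -1, 0, 0), truth), 1)
  expect_equal(detection_accuracy(rep(FALSE, 4), rep(0, 4), c(0, 0, 0, 0)), 1)
  # mixed case, counted by hand: effect 1 flagged wrong sign (not TP),
  # effect 2 missed, effect 3 correctly negative, effect 4 falsely flagged
  acc_hand <- (0 + 0 + 1 + 0) / 4
  expect_equal(detection_accuracy(c(TRUE, FALSE, FALSE, TRUE),
                                  c(-1, 0, 0, 1), truth), acc_hand)
})

test_that("cluster matching is greedy by overlap and permutation-stable", {
  truth <- rep(1:3, each = 4)
  inferred <- c(rep(7L, 4), rep(2L, 4), rep(5L, 4))
  expect_equal(unname(match_clusters(inferred, truth)), c(7L, 2L, 5L))
  # an inferred cluster split across two true ones goes to the larger overlap
  inferred2 <- c(rep(1L, 4), rep(1L, 3), 2L, rep(3L, 4))
  m <- match_clusters(inferred2, truth)
  expect_equal(unname(m[1]), 1L)
  expect_equal(unname(m[3]), 3L)
})

test_that("noise injection perturbs only observed heights", {
  sim <- simulate_peaks(sim_config(n_clusters = 2, peaks_per_cluster = 3,
                                   seed = 6))
  ds <- sim$dataset
  ds$heights[1, 1] <- NA
  noisy <- add_height_noise(ds, sigma = 2, seed = 9)
  expect_true(is.na(noisy$heights[1, 1]))
  expect_false(any(noisy$heights == ds$heights, na.rm = TRUE))
  same <- add_height_noise(ds, sigma = 0, seed = 9)
  expect_identical(same$heights, ds$heights)
})

test_that("the grid runner aggregates per cell and is reproducible", {
  grid <- data.frame(n_per_group = 3, sigma_sq = 1, peaks_per_cluster = 3)
  res <- run_grid(grid, n_reps = 2, models = 3, seed = 17)
  expect_equal(nrow(res$results), 1L)
  expect_true(is.finite(res$results$mean_mse))
  expect_equal(res$results$n_ok, 2L)
  res2 <- run_grid(grid, n_reps = 2, models = 3, seed = 17)
  expect_identical(res$results, res2$results)
  expect_identical(res$reps, res2$reps)
})
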