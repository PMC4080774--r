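test_that("spike-and-slab pair log-likelihood matches closed forms", {
  p <- beta_params(a_in = 5, b_in = 1, p0_in = 0.2)
  # spike only: unobserved same-cluster pair
  expect_equal(pair_loglik(NA, 0, 1, p), log(0.2))
  # flat beta with no spike has density 1
  p_flat <- beta_params(a_in = 1, b_in = 1, p0_in = 0)
  expect_equal(pair_loglik(0.5, 1, 1, p_flat), 0)
  # dbeta(q; 5, 1) = 5 q^4, computed by hand
  p2 <- beta_params(a_in = 5, b_in = 1, p0_in = 0.1)
  expect_equal(pair_loglik(0.9, 1, 1, p2), log(0.9 * 5 * 0.9^4),
               tolerance = 1e-10)
  expect_error(pair_loglik(NaN, 1, 1, p), "non-finite")
})

test_that("data log-likelihood equals the brute-force pair sum", {
  p <- beta_params()
  # single peak: empty product
  sim1 <- sim_from_matrices(matrix(1, 1, 1), matrix(1L, 1, 1))
  expect_equal(data_loglik(sim1, 1L, p), 0)

  # two peaks, one sample: exactly one pair term
  sim2 <- sim_from_matrices(matrix(c(1, .8, .8, 1), 2, 2), matrix(1L, 2, 2))
  expect_equal(data_loglik(sim2, c(1L, 1L), p), pair_loglik(.8, 1, 1, p))
  expect_equal(data_loglik(sim2, c(1L, 2L), p), pair_loglik(.8, 1, 0, p))

  # P = 3, N = 2 against a naive double loop
  set.seed(7)
  qm <- matrix(runif(9, .1, .9), 3, 3); qm <- (qm + t(qm)) / 2; diag(qm) <- 1
  rm_ <- matrix(1L, 3, 3); rm_[1, 3] <- rm_[3, 1] <- 0L
  sim3 <- sim_from_matrices(qm, rm_, n_samples = 2)
  z <- c(1L, 1L, 2L)
  ll_loop <- 0
  for (i in 1:2) for (j in 1:2) for (jp in (j + 1):3) {
    ll_loop <- ll_loop + pair_loglik(sim3$Q[i, j, jp], sim3$R[i, j, jp],
                                     as.integer(z[j] == z[jp]), p)
  }
  expect_equal(data_loglik(sim3, z, p), ll_loop, tolerance = 1e-12)
})

test_that("DP prior pair probability is exact and monotone", {
  expect_identical(prior_pair_prob(2, 1), 0.5)
  expect_identical(prior_pair_prob(10, 1), 0.1)
  a <- c(0.1, 1, 10, 100, 1000)
  expect_true(all(diff(prior_pair_prob(5, a)) < 0))
  expect_error(prior_pair_prob(1, 1), "at least 2")
})

test_that("strong similarity forces a merge; identical seeds reproduce", {
  # q ~ 1 with a_in >> b_in and small alpha_dp: co-clustering certain
  sim <- sim_from_matrices(matrix(c(1, .98, .98, 1), 2, 2),
                           matrix(1L, 2, 2), n_samples = 3)
  p <- beta_params(a_in = 50, b_in = 1, a_out = 1, b_out = 1,
                   p0_in = 0, p0_out = 0)
  fit <- dp_cluster(sim, p, alpha_dp = 1e-3, n_sweeps = 200, burn_in = 50,
                    thin = 1, seed = 2)
  expect_gt(fit$cooccur[1, 2], 0.99)
  expect_equal(unname(fit$labels), c(1L, 1L))

  fit2 <- dp_cluster(sim, p, alpha_dp = 1e-3, n_sweeps = 200, burn_in = 50,
                     thin = 1, seed = 2)
  expect_identical(fit$samples, fit2$samples)
  expect_identical(fit$cooccur, fit2$cooccur)
})

test_that("least-squares point estimate minimizes distance to co-occurrence", {
  # all draws identical -> that clustering; S = 1 -> that draw
  f1 <- list(samples = matrix(c(1L, 1L, 2L), 3, 3, byrow = TRUE),
             cooccur = diag(3), peak_ids = paste0("P", 1:3))
  f1$cooccur <- matrix(rowMeans(apply(f1$samples, 1, function(z)
    as.numeric(outer(z, z, "==")))), 3, 3)
  expect_equal(unname(least_squares_clustering(f1)), c(1L, 1L, 2L))
  f2 <- list(samples = matrix(c(1L, 2L, 2L), 1), cooccur = diag(3),
             peak_ids = paste0("P", 1:3))
  expect_equal(unname(least_squares_clustering(f2)), c(1L, 2L, 2L))

  # three distinct draws: exhaustively score each against the co-occurrence
  draws <- rbind(c(1L, 1L, 2L, 2L), c(1L, 1L, 1L, 2L), c(1L, 2L, 3L, 3L))
  co <- matrix(0, 4, 4)
  for (s in 1:3) co <- co + outer(draws[s, ], draws[s, ], "==")
  co <- co / 3
  ut <- upper.tri(co)
  scores <- apply(draws, 1, function(z)
    sum((outer(z, z, "==")[ut] - co[ut])^2))
  f3 <- list(samples = draws, cooccur = co, peak_ids = paste0("P", 1:4))
  expect_equal(unname(least_squares_clustering(f3)),
               unname(draws[which.min(scores), ]))
})

test_that("stored log-likelihoods equal from-scratch recomputation", {
  sim <- fixture_p4()
  p <- beta_params()
  fit <- dp_cluster(sim, p, n_sweeps = 60, burn_in = 20, thin = 1, seed = 4)
  recomputed <- apply(fit$samples, 1, function(z) data_loglik(sim, z, p))
  expect_equal(fit$loglik, unname(recomputed), tolerance = 1e-10)
})

test_that("posterior co-occurrence is equivariant under peak permutation", {
  sim <- fixture_blocks(P = 6, b1 = 3, n_samples = 2)
  fit <- dp_cluster(sim, n_sweeps = 400, burn_in = 100, seed = 11)
  perm <- c(4L, 6L, 1L, 3L, 5L, 2L)
  Qp <- sim$Q[, perm, perm, drop = FALSE]
  Rp <- sim$R[, perm, perm, drop = FALSE]
  simp <- similarity_data(Qp, Rp)
  fitp <- dp_cluster(simp, n_sweeps = 400, burn_in = 100, seed = 12)
  # strong-signal case: both posteriors are essentially deterministic, so
  # the permuted co-occurrence matches up to Monte-Carlo noise
  expect_lt(max(abs(fitp$cooccur - fit$cooccur[perm, perm])), 0.05)
  expect_equal(unname(fitp$labels), unname(canonical_perm <-
    match(fit$labels[perm], unique(fit$labels[perm]))))
})

test_that("with no observed pairs and equal spikes the CRP prior governs K", {
  P <- 6
  sim <- sim_from_matrices(matrix(1, P, P), {
    r <- matrix(0L, P, P); diag(r) <- 1L; r
  })
  p_eq <- beta_params(p0_in = 0.3, p0_out = 0.3)  # spike terms cancel
  alpha <- 1.5
  fit <- dp_cluster(sim, p_eq, alpha_dp = alpha, n_sweeps = 6000,
                    burn_in = 1000, thin = 1, seed = 8)
  k_mean <- mean(apply(fit$samples, 1, max))
  k_expect <- sum(alpha / (alpha + seq_len(P) - 1))
  ses <- sd(apply(fit$samples, 1, max)) / sqrt(200)  # generous ESS guess
  expect_lt(abs(k_mean - k_expect), max(4 * ses, 0.15))
})

test_that("posterior cluster count grows with the concentration parameter", {
  sim <- fixture_blocks(P = 8, b1 = 4, n_samples = 1,
                        q_in = 0.75, q_out = 0.35)
  kmean <- vapply(c(0.1, 1, 10), function(a) {
    fit <- dp_cluster(sim, alpha_dp = a, n_sweeps = 1500, burn_in = 500,
                      thin = 1, seed = 21)
    mean(apply(fit$samples, 1, max))
  }, 0)
  expect_true(all(diff(kmean) > -0.1))
  expect_gt(kmean[3], kmean[1])
})

test_that("partition enumeration produces Bell numbers and valid posteriors", {
  expect_equal(length(enumerate_partitions(4)), 15L)
  expect_equal(length(enumerate_partitions(5)), 52L)
  post <- exact_partition_posterior(fixture_p4(), beta_params(), 1)
  expect_equal(sum(post$prob), 1)
  expect_true(all(post$prob >= 0))
})
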