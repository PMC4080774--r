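test_that("design layout covers main effects and interactions", {
  sm <- data.frame(sample_id = paste0("S", 1:8),
                   trt = c(1L, 1L, 2L, 2L, 1L, 1L, 2L, 2L),
                   time = c(1L, 1L, 1L, 1L, 2L, 2L, 2L, 2L))
  # one covariate with two levels: baseline (fixed zero) plus one column
  d1 <- build_design(sm, "trt")
  expect_equal(ncol(d1$Z), 1L)
  expect_equal(d1$terms$term, "trt:2")
  expect_equal(d1$Z[, 1], as.integer(sm$trt == 2L))

  # two 2-level covariates, no interaction: 3 columns including baseline
  d2 <- build_design(sm, c("trt", "time"))
  expect_equal(ncol(d2$Z), 2L)

  d3 <- build_design(sm, c("trt", "time"), interaction = TRUE)
  expect_equal(ncol(d3$Z), 3L)
  expect_equal(d3$Z[, 3], as.integer(sm$trt == 2L & sm$time == 2L))

  expect_error(build_design(sm, "trt", interaction = TRUE), "two covariates")
  expect_error(build_design(sm, c("a", "b", "c")), "1 or 2")
})

test_that("posterior mean matches the closed-form Gaussian posterior", {
  # K = 1, P = 1, noise pinned tiny by a massive variance prior: the
  # latent means equal the observations, and the effect posterior is the
  # conjugate normal with precision 1 + n over the level-2 samples
  set.seed(5)
  n <- 60
  x2 <- rnorm(n, 1.8, 1)
  H <- matrix(c(rnorm(n, 0, 1), x2), 1, 2 * n,
              dimnames = list("P1", NULL))
  ds <- fixture_dataset(H, groups = rep(c(1, 2), each = n))
  fit <- cluster_effects(ds, setNames(1L, "P1"), n0 = 1e7,
                         sigma0_sq = 1e-6, n_sweeps = 3000, burn_in = 1000,
                         seed = 3)
  expected <- sum(x2) / (1 + n)
  expect_equal(unname(coef(fit)[1, "group:2"]), expected, tolerance = 0.05)
})

test_that("a cluster with no observed heights keeps its prior effect", {
  set.seed(6)
  H <- rbind(P1 = rnorm(20), P2 = rep(NA_real_, 20))
  ds <- fixture_dataset(H, groups = rep(c(1, 2), each = 10))
  z <- setNames(c(1L, 2L), c("P1", "P2"))
  fit <- cluster_effects(ds, z, n_sweeps = 6000, burn_in = 1000, thin = 1,
                         seed = 4)
  d <- fit$alpha_draws[, 2, 1]     # effect of the data-free cluster
  expect_lt(abs(mean(d)), 3 * sd(d) / sqrt(100))  # conservative ESS
  expect_equal(sd(d), 1, tolerance = 0.1)
})

test_that("baseline column is identically zero and draws are reproducible", {
  set.seed(1)
  H <- matrix(rnorm(3 * 8), 3, 8, dimnames = list(paste0("P", 1:3), NULL))
  ds <- fixture_dataset(H, groups = rep(c(1, 2), each = 4))
  z <- setNames(c(1L, 1L, 2L), paste0("P", 1:3))
  fit <- cluster_effects(ds, z, n_sweeps = 300, burn_in = 100, seed = 9)
  expect_true(all(coef(fit)[, "baseline"] == 0))
  fit2 <- cluster_effects(ds, z, n_sweeps = 300, burn_in = 100, seed = 9)
  expect_identical(fit$alpha_draws, fit2$alpha_draws)
})

test_that("an all-missing peak does not shift effect summaries", {
  set.seed(12)
  sim <- simulate_peaks(sim_config(n_per_group = 10, n_clusters = 3,
                                   peaks_per_cluster = 4, seed = 33))
  ds <- sim$dataset
  fit <- cluster_effects(ds, sim$truth$labels, n_sweeps = 2000,
                         burn_in = 500, seed = 7)
  # append a peak of cluster 1 with every height missing
  H2 <- rbind(ds$heights, EXTRA = NA_real_)
  pm2 <- rbind(ds$peak_meta[c("peak_id", "mz", "rt")],
               data.frame(peak_id = "EXTRA", mz = 1, rt = 1))
  ds2 <- peak_dataset(H2, pm2, ds$sample_meta, covariates = "group",
                      log_base = 2, centered = TRUE)
  z2 <- c(sim$truth$labels, EXTRA = 1L)
  fit2 <- cluster_effects(ds2, z2, n_sweeps = 2000, burn_in = 500, seed = 7)
  expect_lt(max(abs(coef(fit2)[, -1] - coef(fit)[, -1])), 0.15)
})

test_that("noiseless interaction design recovers the generating decomposition", {
  a_main <- 1.5; b_main <- -1; ab_int <- 0.8
  n <- 30
  cells <- expand.grid(trt = 1:2, time = 1:2)
  sm <- data.frame(sample_id = paste0("S", seq_len(4 * n)),
                   trt = rep(cells$trt, each = n),
                   time = rep(cells$time, each = n))
  mu <- a_main * (sm$trt == 2) + b_main * (sm$time == 2) +
    ab_int * (sm$trt == 2 & sm$time == 2)
  set.seed(10)
  lat <- mu + rnorm(4 * n)          # unit latent scatter, as modelled
  H <- rbind(P1 = lat, P2 = lat, P3 = lat) +
    matrix(rnorm(3 * 4 * n, 0, 0.05), 3)
  pm <- data.frame(peak_id = paste0("P", 1:3))
  ds <- peak_dataset(H, pm, sm, covariates = c("trt", "time"),
                     log_base = 2, centered = TRUE)
  fit <- cluster_effects(ds, setNames(rep(1L, 3), paste0("P", 1:3)),
                         covariates = c("trt", "time"), interaction = TRUE,
                         n_sweeps = 3000, burn_in = 1000, seed = 2)
  est <- coef(fit)[1, c("trt:2", "time:2", "trt:2xtime:2")]
  expect_equal(unname(est), c(a_main, b_main, ab_int), tolerance = 0.3)
})

test_that("significance flags follow the posterior interval", {
  set.seed(20)
  H <- matrix(c(rnorm(8, 0, .3), rnorm(8, 3, .3)), 1, 16, byrow = TRUE,
              dimnames = list("P1", NULL))
  ds <- fixture_dataset(H, groups = rep(c(1, 2), each = 8))
  fit <- cluster_effects(ds, setNames(1L, "P1"), n_sweeps = 1500,
                         burn_in = 500, seed = 5)
  s <- significance(fit, 0.95)
  expect_true(s$significant[1])
  expect_equal(s$sign[1], 1L)
  expect_error(significance(fit, 1.5), "level")

  tiny <- cluster_effects(ds, setNames(1L, "P1"), n_sweeps = 60,
                          burn_in = 10, thin = 1, seed = 5)
  expect_error(significance(tiny), "100")
})

test_that("effect recovery sharpens with more samples and peaks", {
  mse_at <- function(n, ppc, seeds) {
    mean(vapply(seeds, function(s) {
      sim <- simulate_peaks(sim_config(n_per_group = n,
                                       peaks_per_cluster = ppc, seed = s))
      fit_models(sim, models = 1, seed = s + 1L)$model1$mse
    }, 0))
  }
  small <- mse_at(3, 3, 101:103)
  large <- mse_at(15, 15, 101:103)
  expect_lt(large, small)
})
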