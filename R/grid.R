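#' Fit the three models to one simulated dataset
#'
#' Convenience wrapper used by [run_grid()] and scripted experiments:
#' fits the shape-based two-stage model (Model 1), the height-only joint
#' model (Model 2) and the single-peak baseline (Model 3) to one
#' [simulate_peaks()] draw, and scores each against the generating truth
#' (effect MSE, sign-sensitive detection accuracy, and clustering NID for
#' the models that cluster).
#'
#' @param sim a `peak_sim` object.
#' @param models subset of `1:3`.
#' @param seed RNG seed for the samplers.
#' @param cl_sweeps,cl_burn sweeps/burn-in of the clustering sampler.
#' @param ef_sweeps,ef_burn sweeps/burn-in of the effects samplers.
#' @param thin thinning for all samplers.
#' @return named list (`model1`, `model2`, `model3` as requested), each a
#'   list with `mse`, `accuracy`, `nid` (NA for Model 3) and `estimate`.
#' @export
fit_models <- function(sim, models = 1:3, seed = 1,
                       cl_sweeps = 300, cl_burn = 150,
                       ef_sweeps = 1000, ef_burn = 400, thin = 2) {
  stopifnot(inherits(sim, "peak_sim"))
  out <- list()
  truth <- sim$truth
  if (1 %in% models) {
    cl <- dp_cluster(sim$similarity, n_sweeps = cl_sweeps, burn_in = cl_burn,
                     thin = thin, seed = seed)
    ef <- cluster_effects(sim$dataset, cl, n_sweeps = ef_sweeps,
                          burn_in = ef_burn, thin = thin, seed = seed + 1L)
    sc <- score_effect_fit(ef$summaries, ef$labels, truth)
    sc$nid <- nid(cluster_labels(cl)[names(truth$labels)], truth$labels)
    out$model1 <- sc
  }
  if (2 %in% models) {
    m2 <- model2_effects(sim$dataset, n_sweeps = ef_sweeps,
                         burn_in = ef_burn, thin = thin, seed = seed + 2L)
    sc <- score_effect_fit(m2$effects$summaries, m2$effects$labels, truth)
    sc$nid <- nid(m2$labels[names(truth$labels)], truth$labels)
    out$model2 <- sc
  }
  if (3 %in% models) {
    s3 <- single_peak_effects(sim$dataset, truth$labels)
    sc <- score_effect_fit(s3, truth$labels, truth)
    sc$nid <- NA_real_
    out$model3 <- sc
  }
  out
}

#' Run the simulated experiment grid
#'
#' Repeats the simulation over a grid of study conditions, fits the
#' requested models to every replicate, and aggregates per-cell mean MSE,
#' detection accuracy and NID. The per-cell difference in MSE between
#' Model 1 and each comparison model is tested with a paired one-sided
#' t-test (alternative: Model 1 smaller), Benjamini-Hochberg-adjusted
#' across cells.
#'
#' @param grid data.frame of cells; recognized columns `n_per_group`,
#'   `sigma_sq`, `peaks_per_cluster` (missing columns take the
#'   [sim_config()] defaults).
#' @param n_reps independent replicates per cell (>= 2).
#' @param models subset of `1:3`.
#' @param seed master seed; per-replicate seeds are derived from it.
#' @param ... sampler settings passed to [fit_models()].
#' @return list of class `grid_results`: `results` (one row per cell and
#'   model), `tests` (paired MSE tests), and `reps` (per-replicate
#'   metrics for uncertainty assessment). Failed replicates are recorded
#'   as `NA`, not fatal.
#' @export
run_grid <- function(grid, n_reps = 10, models = 1:3, seed = 1, ...) {
  stopifnot(is.data.frame(grid), nrow(grid) >= 1, n_reps >= 2)
  set.seed(seed)
  rep_seeds <- matrix(sample.int(.Machine$integer.max - 10L,
                                 nrow(grid) * n_reps),
                      nrow(grid), n_reps)
  metrics <- c("mse", "accuracy", "nid")
  reps <- array(NA_real_,
                c(nrow(grid), length(models), n_reps, length(metrics)),
                dimnames = list(NULL, paste0("model", models), NULL, metrics))
  for (g in seq_len(nrow(grid))) {
    args <- list()
    for (cc in intersect(c("n_per_group", "sigma_sq", "peaks_per_cluster"),
                         names(grid)))
      args[[cc]] <- grid[[cc]][g]
    for (r in seq_len(n_reps)) {
      sr <- rep_seeds[g, r]
      cfg <- do.call(sim_config, c(args, list(seed = sr)))
      res <- tryCatch(
        fit_models(simulate_peaks(cfg), models = models, seed = sr + 1L, ...),
        error = function(e) {
          warning("replicate failed in cell ", g, ": ", conditionMessage(e))
          NULL
        })
      if (is.null(res)) next
      for (m in seq_along(models)) {
        sc <- res[[paste0("model", models[m])]]
        reps[g, m, r, ] <- c(sc$mse, sc$accuracy, sc$nid)
      }
    }
  }
  results <- do.call(rbind, lapply(seq_len(nrow(grid)), function(g)
    do.call(rbind, lapply(seq_along(models), function(m) {
      cell <- grid[g, , drop = FALSE]
      rownames(cell) <- NULL
      cbind(cell, data.frame(
        model = models[m],
        mean_mse = mean(reps[g, m, , "mse"], na.rm = TRUE),
        mean_accuracy = mean(reps[g, m, , "accuracy"], na.rm = TRUE),
        mean_nid = mean(reps[g, m, , "nid"], na.rm = TRUE),
        n_ok = sum(!is.na(reps[g, m, , "mse"]))))
    }))))
  tests <- NULL
  if (1 %in% models) {
    for (comp in intersect(c(2, 3), models)) {
      ps <- vapply(seq_len(nrow(grid)), function(g) {
        x <- reps[g, "model1", , "mse"]
        y <- reps[g, paste0("model", comp), , "mse"]
        ok <- !is.na(x) & !is.na(y)
        if (sum(ok) < 2 || stats::sd(x[ok] - y[ok]) == 0) return(NA_real_)
        stats::t.test(x[ok], y[ok], paired = TRUE,
                      alternative = "less")$p.value
      }, 0)
      tests <- rbind(tests, cbind(grid, data.frame(
        comparison = paste0("model1<model", comp), p = ps)))
    }
    tests$p_adj <- stats::p.adjust(tests$p, method = "BH")
  }
  structure(list(results = results, tests = tests, reps = reps,
                 models = models, n_reps = n_reps, seed = seed),
            class = "grid_results")
}

#' @export
print.grid_results <- function(x, ...) {
  cat("Simulated-grid evaluation (", x$n_reps, " replicates per cell)\n",
      sep = "")
  print(x$results, digits = 3, row.names = FALSE)
  if (!is.null(x$tests)) {
    cat("\nPaired one-sided MSE tests (BH-adjusted):\n")
    print(x$tests, digits = 3, row.names = FALSE)
  }
  invisible(x)
}
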