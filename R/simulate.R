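#' Simulation configuration
#'
#' Study conditions for the generative simulator ([simulate_peaks()]),
#' mirroring the model's own latent structure: clusters of peaks whose
#' heights share a latent per-sample concentration, group-specific effect
#' shifts, peak-specific Gaussian noise, and high within- / low
#' between-cluster shape similarity with spike missingness.
#'
#' Defaults are the reference simulated-experiment conditions: 7 clusters
#' of 7 peaks, 2 groups of 7 samples, unit peak noise, second-group
#' effects `(2, -1, 0.5, 0, 0, 0, 0)`, within-cluster similarities
#' `Beta(10, 1)`, between-cluster `Beta(1, 1)`, and spike missingness
#' `(0.1, 0.5)` within/between clusters.
#'
#' @param n_per_group samples per covariate level.
#' @param n_groups number of covariate levels (level 1 = control).
#' @param n_clusters number of compounds (clusters).
#' @param peaks_per_cluster peaks generated per cluster.
#' @param sigma_sq peak-specific noise variance.
#' @param true_alpha K x L effect matrix, first column zero. Default: the
#'   reference effects above, padded/truncated to `n_clusters` rows and
#'   recycled over non-control groups.
#' @param sim_in,sim_out beta shape pairs generating within- and
#'   between-cluster similarities.
#' @param p_missing similarity spike missingness; length 2
#'   (within, between) or a single rate used for both.
#' @param baseline_range range of the uniform per-peak baseline log2
#'   intensity. The default `c(0, 0)` generates heights directly on the
#'   centered scale of the latent model (control latents fluctuate around
#'   zero), exactly as the generative hierarchy specifies; a non-trivial
#'   range adds per-peak baselines, which downstream fits must then
#'   remove by empirical control-group centering.
#' @param seed RNG seed.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(n_per_group = 7, n_groups = 2, n_clusters = 7,
                       peaks_per_cluster = 7, sigma_sq = 1,
                       true_alpha = NULL,
                       sim_in = c(10, 1), sim_out = c(1, 1),
                       p_missing = c(0.1, 0.5),
                       baseline_range = c(0, 0), seed = 1) {
  stopifnot(n_per_group >= 1, n_groups >= 2, n_clusters >= 1,
            peaks_per_cluster >= 1, sigma_sq >= 0,
            length(sim_in) == 2, length(sim_out) == 2,
            all(c(sim_in, sim_out) > 0))
  if (length(p_missing) == 1L) p_missing <- rep(p_missing, 2)
  stopifnot(length(p_missing) == 2, all(p_missing >= 0 & p_missing <= 1))
  K <- n_clusters
  if (is.null(true_alpha)) {
    ref <- c(2, -1, 0.5, 0, 0, 0, 0)
    col <- rep_len(ref, K)
    true_alpha <- cbind(0, matrix(rep(col, n_groups - 1), K))
  }
  true_alpha <- as.matrix(true_alpha)
  if (nrow(true_alpha) != K || ncol(true_alpha) != n_groups)
    stop("true_alpha must be n_clusters x n_groups")
  if (any(true_alpha[, 1] != 0)) stop("true_alpha column 1 (baseline) must be zero")
  structure(list(n_per_group = n_per_group, n_groups = n_groups,
                 n_clusters = K, peaks_per_cluster = peaks_per_cluster,
                 sigma_sq = sigma_sq, true_alpha = true_alpha,
                 sim_in = sim_in, sim_out = sim_out, p_missing = p_missing,
                 baseline_range = baseline_range, seed = seed),
            class = "sim_config")
}

#' Simulate clustered peak data
#'
#' Draws one dataset from the generative model: per-sample latent cluster
#' concentrations `N(alpha[, a_i], 1)`, peak heights equal to a per-peak
#' baseline plus the cluster's latent value plus `N(0, sigma_sq)` noise,
#' and per-sample pairwise shape similarities drawn from the within- or
#' between-cluster beta with spike missingness. Fully reproducible from
#' the config seed.
#'
#' @param config a [sim_config()].
#' @return list of class `peak_sim` with elements `dataset`
#'   ([peak_dataset()], log2 scale), `similarity` ([similarity_data()])
#'   and `truth` (generating labels, effect matrix, noise variance and
#'   nonzero-effect flags).
#' @export
simulate_peaks <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  K <- config$n_clusters; L <- config$n_groups
  ppc <- config$peaks_per_cluster
  P <- K * ppc
  N <- config$n_per_group * L
  a <- rep(seq_len(L), each = config$n_per_group)
  alpha <- config$true_alpha

  xlat <- alpha[, a, drop = FALSE] + matrix(stats::rnorm(K * N), K, N)
  z <- rep(seq_len(K), each = ppc)
  base <- stats::runif(P, config$baseline_range[1], config$baseline_range[2])
  X <- base + xlat[z, , drop = FALSE] +
    matrix(stats::rnorm(P * N, 0, sqrt(config$sigma_sq)), P, N)

  peak_ids <- sprintf("P%03d", seq_len(P))
  cl_rt <- sort(stats::runif(K, 60, 1140))       # cluster elution times (s)
  peak_meta <- data.frame(
    peak_id = peak_ids,
    mz = round(stats::runif(P, 100, 1000), 4),
    rt = round(cl_rt[z] + stats::rnorm(P, 0, 1), 2),
    stringsAsFactors = FALSE)
  sample_meta <- data.frame(sample_id = sprintf("S%02d", seq_len(N)),
                            group = a, stringsAsFactors = FALSE)
  dataset <- peak_dataset(X, peak_meta, sample_meta,
                          covariates = "group", log_base = 2,
                          centered = all(config$baseline_range == 0))

  ut <- which(upper.tri(diag(P)), arr.ind = TRUE)
  same <- z[ut[, 1]] == z[ut[, 2]]
  p0 <- ifelse(same, config$p_missing[1], config$p_missing[2])
  sh1 <- ifelse(same, config$sim_in[1], config$sim_out[1])
  sh2 <- ifelse(same, config$sim_in[2], config$sim_out[2])
  Np <- nrow(ut)
  Q <- array(NA_real_, c(N, P, P))
  R <- array(0L, c(N, P, P))
  for (i in seq_len(N)) {
    obs <- stats::runif(Np) >= p0
    q <- rep(NA_real_, Np)
    q[obs] <- stats::rbeta(sum(obs), sh1[obs], sh2[obs])
    Q[cbind(i, ut[, 1], ut[, 2])] <- q
    Q[cbind(i, ut[, 2], ut[, 1])] <- q
    R[cbind(i, ut[, 1], ut[, 2])] <- as.integer(obs)
    R[cbind(i, ut[, 2], ut[, 1])] <- as.integer(obs)
    diag(Q[i, , ]) <- 1; diag(R[i, , ]) <- 1L
  }
  similarity <- similarity_data(Q, R, peak_ids, sample_meta$sample_id)

  truth <- list(labels = stats::setNames(z, peak_ids), alpha = alpha,
                sigma_sq = config$sigma_sq,
                nonzero = alpha[, -1, drop = FALSE] != 0)
  structure(list(dataset = dataset, similarity = similarity, truth = truth,
                 config = config), class = "peak_sim")
}

#' @export
print.peak_sim <- function(x, ...) {
  cfg <- x$config
  cat("Simulated peak experiment:", cfg$n_clusters, "clusters x",
      cfg$peaks_per_cluster, "peaks,", ncol(x$dataset$heights), "samples in",
      cfg$n_groups, "groups, sigma^2 =", cfg$sigma_sq, "\n")
  invisible(x)
}

#' Add measurement noise to peak heights
#'
#' Adds independent `N(0, sigma^2)` noise to every observed height; used
#' for robustness-to-noise experiments.
#'
#' @param dataset a [peak_dataset()].
#' @param sigma noise standard deviation.
#' @param seed optional RNG seed.
#' @return the perturbed [peak_dataset()].
#' @export
add_height_noise <- function(dataset, sigma, seed = NULL) {
  stopifnot(inherits(dataset, "peak_dataset"), sigma >= 0)
  if (!is.null(seed)) set.seed(seed)
  H <- dataset$heights
  obs <- !is.na(H)
  H[obs] <- H[obs] + stats::rnorm(sum(obs), 0, sigma)
  out <- dataset
  out$heights <- H
  out
}
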