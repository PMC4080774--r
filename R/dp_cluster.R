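#' Spike-and-slab beta likelihood parameters
#'
#' Parameters of the pairwise similarity likelihood. A similarity observed
#' for a pair of peaks follows a beta distribution whose shape depends on
#' whether the pair shares a cluster: `Beta(a_in, b_in)` for same-cluster
#' pairs (defaults put the mass near 1: co-eluting peaks from one compound
#' have nearly identical shapes) and `Beta(a_out, b_out)` (default flat)
#' otherwise. The spike carries the probability that the pair is not
#' co-observed: `p0_in` within clusters, `p0_out` between clusters (a
#' missing co-observation is more likely for unrelated peaks, hence the
#' larger default).
#'
#' @param a_in,b_in beta shapes for same-cluster similarities (> 0).
#' @param a_out,b_out beta shapes for different-cluster similarities (> 0).
#' @param p0_in,p0_out missingness probabilities in `[0, 1]`.
#' @return Object of class `beta_params`.
#' @export
beta_params <- function(a_in = 10, b_in = 1, a_out = 1, b_out = 1,
                        p0_in = 0.1, p0_out = 0.5) {
  stopifnot(a_in > 0, b_in > 0, a_out > 0, b_out > 0,
            p0_in >= 0, p0_in <= 1, p0_out >= 0, p0_out <= 1)
  structure(list(a_in = a_in, b_in = b_in, a_out = a_out, b_out = b_out,
                 p0_in = p0_in, p0_out = p0_out), class = "beta_params")
}

# beta densities blow up at 0/1 for shapes < 1 (and the truncated Pearson
# similarity can be exactly 0), so q is clamped away from the boundary at
# likelihood time only; stored similarities are untouched.
clamp_q <- function(q, eps = 1e-6) pmin(pmax(q, eps), 1 - eps)

#' Pairwise similarity log-likelihood
#'
#' Log-density of one (similarity, observed-flag) pair under the
#' spike-and-slab beta model: `log(1 - p0) + log Beta(q; a, b)` when the
#' pair is observed, `log(p0)` when it is not, with `(a, b, p0)` selected
#' by the co-cluster indicator. Vectorized over `q`, `r`, `same_cluster`.
#'
#' @param q similarity values (ignored, may be `NA`, where `r = 0`).
#' @param r binary observation flags.
#' @param same_cluster binary co-cluster indicators.
#' @param params a [beta_params()] object.
#' @return log-density vector.
#' @export
pair_loglik <- function(q, r, same_cluster, params) {
  n <- max(length(q), length(r), length(same_cluster))
  q <- rep_len(q, n); r <- rep_len(r, n)
  same <- rep_len(as.logical(same_cluster), n)
  if (any(r == 1 & !is.finite(q)))
    stop("non-finite similarity for an observed pair")
  a <- ifelse(same, params$a_in, params$a_out)
  b <- ifelse(same, params$b_in, params$b_out)
  p0 <- ifelse(same, params$p0_in, params$p0_out)
  out <- log(p0)
  obs <- r == 1
  qc <- clamp_q(q[obs])
  out[obs] <- log1p(-p0[obs]) +
    stats::dbeta(qc, a[obs], b[obs], log = TRUE)
  out
}

# Per-pair evidence, summed over samples:
#   Lin[j,j']  = sum_i pair_loglik(q_ijj', r_ijj', same = 1)
#   Lout[j,j'] = sum_i pair_loglik(q_ijj', r_ijj', same = 0)
# D = Lin - Lout drives every Gibbs conditional; const = sum_{j<j'} Lout
# completes the full log-likelihood. Both depend on data and params only,
# so they are computed once per run.
pair_evidence <- function(sim, params) {
  P <- dim(sim$Q)[2]; N <- dim(sim$Q)[1]
  ut <- which(upper.tri(diag(P)), arr.ind = TRUE)
  lin <- numeric(nrow(ut)); lout <- numeric(nrow(ut))
  for (i in seq_len(N)) {
    q <- sim$Q[cbind(i, ut[, 1], ut[, 2])]
    r <- sim$R[cbind(i, ut[, 1], ut[, 2])]
    lin <- lin + pair_loglik(q, r, 1, params)
    lout <- lout + pair_loglik(q, r, 0, params)
  }
  D <- matrix(0, P, P)
  D[ut] <- lin - lout
  D <- D + t(D)
  list(D = D, const = sum(lout))
}

#' Full data log-likelihood of a clustering
#'
#' Sum of [pair_loglik()] over every sample and unordered peak pair, with
#' the co-cluster indicator taken from the given cluster labels.
#'
#' @param sim a [similarity_data()] object.
#' @param labels integer cluster label per peak.
#' @param params a [beta_params()] object.
#' @return scalar log-likelihood (0 when `P = 1`: empty product).
#' @export
data_loglik <- function(sim, labels, params) {
  P <- dim(sim$Q)[2]
  if (length(labels) != P) stop("labels length does not match similarity data")
  if (P == 1L) return(0)
  ev <- pair_evidence(sim, params)
  ut <- upper.tri(ev$D)
  same <- outer(labels, labels, "==")
  ev$const + sum(ev$D[ut & same])
}

#' Prior co-cluster probability under the Dirichlet process
#'
#' Probability that any two of `P` exchangeable peaks share a cluster a
#' priori: `1 / (P - 1 + alpha_dp)`.
#'
#' @param P number of peaks (>= 2).
#' @param alpha_dp concentration parameter (> 0).
#' @return probability.
#' @export
prior_pair_prob <- function(P, alpha_dp) {
  stopifnot(alpha_dp > 0)
  if (P < 2) stop("P must be at least 2")
  1 / (P - 1 + alpha_dp)
}

# One Gibbs sweep over peaks in ascending index order. Each peak is removed
# from its cluster (empty clusters deleted, last label moved into the hole)
# and reassigned with probability s_k * L for existing cluster k and
# alpha_dp * L for a fresh singleton; only the pairs involving the peak
# enter (the rest cancel), giving the O(K P^2)-per-sweep cost.
dp_sweep <- function(z, sizes, D, alpha_dp) {
  P <- length(z)
  if (P == 1L) return(list(z = z, sizes = sizes))
  for (j in seq_len(P)) {
    k <- z[j]
    sizes[k] <- sizes[k] - 1L
    if (sizes[k] == 0L) {
      K <- length(sizes)
      if (k != K) {
        z[z == K] <- k
        sizes[k] <- sizes[K]
      }
      sizes <- sizes[-length(sizes)]
    }
    K <- length(sizes)
    grp <- z[-j]
    csum <- rowsum(D[-j, j], grp, reorder = TRUE)[, 1]
    logw <- c(log(sizes) + csum, log(alpha_dp))
    w <- exp(logw - max(logw))
    knew <- sample.int(K + 1L, 1L, prob = w)
    if (knew > K) sizes <- c(sizes, 1L) else sizes[knew] <- sizes[knew] + 1L
    z[j] <- knew
  }
  list(z = z, sizes = sizes)
}

# relabel clusters by order of first appearance (canonical form)
canonical_labels <- function(z) {
  match(z, unique(z))
}

#' Cluster peaks by shape similarity (Dirichlet-process Gibbs sampler)
#'
#' Fits the nonparametric clustering model: peaks are partitioned under a
#' Dirichlet-process prior with concentration `alpha_dp`, and every
#' (sample, peak-pair) similarity contributes a spike-and-slab beta
#' likelihood term ([pair_loglik()]) whose parameters depend on whether
#' the pair is currently co-clustered. Posterior partitions are explored
#' by collapsed Gibbs sampling over peak assignments; the posterior is
#' summarized by the co-occurrence matrix and its least-squares point
#' estimate ([least_squares_clustering()]).
#'
#' @param sim a [similarity_data()] object.
#' @param params a [beta_params()] likelihood specification.
#' @param alpha_dp Dirichlet-process concentration (> 0); larger values
#'   favor more clusters.
#' @param n_sweeps total Gibbs sweeps.
#' @param burn_in sweeps discarded before collecting (must be < n_sweeps).
#' @param thin keep every `thin`-th sweep after burn-in.
#' @param seed RNG seed; identical seeds give identical fits.
#' @param init `"singletons"` (each peak its own cluster; default, avoids
#'   biasing toward merged solutions) or `"together"` (one cluster).
#' @return Object of class `dp_clustering`: retained label draws
#'   (`samples`, S x P), co-occurrence matrix (`cooccur`), point-estimate
#'   labels (`labels`), per-draw cluster counts and log-likelihoods.
#' @export
dp_cluster <- function(sim, params = beta_params(), alpha_dp = 1,
                       n_sweeps = 500, burn_in = 250, thin = 2,
                       seed = 1, init = c("singletons", "together")) {
  stopifnot(inherits(sim, "similarity_data"), alpha_dp > 0,
            n_sweeps >= 1, burn_in >= 0, burn_in < n_sweeps, thin >= 1)
  init <- match.arg(init)
  P <- dim(sim$Q)[2]
  ev <- pair_evidence(sim, params)
  set.seed(seed)

  z <- if (init == "singletons") seq_len(P) else rep(1L, P)
  sizes <- as.integer(tabulate(z))
  keep <- seq.int(burn_in + 1L, n_sweeps, by = thin)
  if (!length(keep)) stop("no sweeps retained after burn-in/thinning")
  keepv <- logical(n_sweeps); keepv[keep] <- TRUE
  S <- length(keep)
  samples <- matrix(0L, S, P)
  loglik <- numeric(S)
  cooccur <- matrix(0, P, P)
  s <- 0L
  ut <- upper.tri(cooccur)
  for (sw in seq_len(n_sweeps)) {
    st <- dp_sweep(z, sizes, ev$D, alpha_dp)
    z <- st$z; sizes <- st$sizes
    if (keepv[sw]) {
      s <- s + 1L
      samples[s, ] <- canonical_labels(z)
      eps <- outer(z, z, "==")
      cooccur <- cooccur + eps
      loglik[s] <- ev$const + sum(ev$D[ut & eps])
    }
  }
  cooccur <- cooccur / S
  dimnames(cooccur) <- list(sim$peak_ids, sim$peak_ids)
  fit <- structure(list(samples = samples, cooccur = cooccur,
                        loglik = loglik, peak_ids = sim$peak_ids,
                        alpha_dp = alpha_dp, params = params,
                        n_sweeps = n_sweeps, burn_in = burn_in, thin = thin,
                        seed = seed, init = init),
                   class = "dp_clustering")
  fit$labels <- least_squares_clustering(fit)
  fit
}

#' Least-squares clustering point estimate
#'
#' Among the retained posterior draws, returns the partition whose
#' co-cluster indicator matrix is closest (in summed squared difference
#' over unordered pairs) to the posterior co-occurrence matrix. Ties are
#' broken by the earliest draw.
#'
#' @param fit a `dp_clustering` object (or a list with elements `samples`,
#'   `cooccur`, `peak_ids`).
#' @return named integer vector of cluster labels (canonical form).
#' @export
least_squares_clustering <- function(fit) {
  S <- nrow(fit$samples)
  if (S < 1L) stop("no posterior samples")
  ut <- upper.tri(fit$cooccur)
  co <- fit$cooccur[ut]
  score <- vapply(seq_len(S), function(s) {
    eps <- outer(fit$samples[s, ], fit$samples[s, ], "==")[ut]
    sum((eps - co)^2)
  }, 0)
  best <- which.min(score)  # which.min takes the first minimum: earliest draw
  z <- canonical_labels(fit$samples[best, ])
  names(z) <- fit$peak_ids
  z
}

#' Extract cluster labels
#'
#' @param x a `dp_clustering`/`model2_fit` object or a bare label vector.
#' @param ... unused.
#' @return named integer vector of cluster labels.
#' @export
cluster_labels <- function(x, ...) UseMethod("cluster_labels")

#' @export
cluster_labels.dp_clustering <- function(x, ...) x$labels

#' @export
cluster_labels.default <- function(x, ...) {
  z <- as.integer(x)
  names(z) <- names(x)
  z
}

#' @export
print.dp_clustering <- function(x, ...) {
  K <- max(x$labels)
  cat("Dirichlet-process peak clustering\n")
  cat("  peaks:", length(x$labels), " retained draws:", nrow(x$samples), "\n")
  cat("  point estimate:", K, "clusters (sizes:",
      paste(sort(tabulate(x$labels), decreasing = TRUE), collapse = ", "), ")\n")
  cat("  alpha_dp:", x$alpha_dp, "\n")
  invisible(x)
}

#' @export
summary.dp_clustering <- function(object, ...) {
  ks <- apply(object$samples, 1, max)
  out <- list(
    n_peaks = length(object$labels),
    n_draws = nrow(object$samples),
    k_point = max(object$labels),
    k_posterior = summary(ks),
    mean_k = mean(ks),
    sizes = sort(tabulate(object$labels), decreasing = TRUE)
  )
  class(out) <- "summary.dp_clustering"
  out
}

#' @export
print.summary.dp_clustering <- function(x, ...) {
  cat("Dirichlet-process peak clustering\n")
  cat("  peaks:", x$n_peaks, " retained draws:", x$n_draws, "\n")
  cat("  posterior mean number of clusters:", format(x$mean_k, digits = 4), "\n")
  cat("  point estimate:", x$k_point, "clusters, sizes",
      paste(x$sizes, collapse = ", "), "\n")
  invisible(x)
}

#' @export
plot.dp_clustering <- function(x, ...) {
  ord <- order(x$labels)
  P <- length(ord)
  image(seq_len(P), seq_len(P), x$cooccur[ord, ord][, P:1],
        col = grey.colors(64, 1, 0), axes = FALSE,
        xlab = "peaks (ordered by cluster)", ylab = "",
        main = "posterior co-clustering probability", ...)
  box()
  invisible(x)
}

#' Enumerate set partitions
#'
#' All partitions of `1..P` as canonical label vectors (restricted-growth
#' order). Intended for exact-posterior diagnostics at small `P` (the
#' count is the Bell number: 15 at `P = 4`, 52 at `P = 5`).
#'
#' @param P number of items (1..10).
#' @return list of integer label vectors.
#' @export
enumerate_partitions <- function(P) {
  stopifnot(P >= 1, P <= 10)
  parts <- list(1L)
  for (n in seq_len(P)[-1]) {
    parts <- unlist(lapply(parts, function(z) {
      K <- max(z)
      lapply(seq_len(K + 1L), function(k) c(z, k))
    }), recursive = FALSE)
  }
  parts
}

#' Exact partition posterior by enumeration
#'
#' Normalized posterior over all set partitions of the peaks:
#' Dirichlet-process prior mass `alpha_dp^K * prod_k (s_k - 1)!` times the
#' spike-and-slab likelihood of [data_loglik()]. Feasible for small peak
#' counts only; used to validate the Gibbs sampler.
#'
#' @param sim a [similarity_data()] object with few peaks.
#' @param params a [beta_params()] object.
#' @param alpha_dp concentration parameter.
#' @return data.frame with columns `partition` (label string) and `prob`.
#' @export
exact_partition_posterior <- function(sim, params = beta_params(),
                                      alpha_dp = 1) {
  P <- dim(sim$Q)[2]
  parts <- enumerate_partitions(P)
  lp <- vapply(parts, function(z) {
    sizes <- tabulate(z)
    max(z) * log(alpha_dp) + sum(lgamma(sizes)) +
      data_loglik(sim, z, params)
  }, 0)
  pr <- exp(lp - max(lp))
  data.frame(partition = vapply(parts, paste, "", collapse = ""),
             prob = pr / sum(pr), stringsAsFactors = FALSE)
}
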