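#' Single-peak fold change
#'
#' The conventional single-peak effect estimate: the mean observed height
#' of a peak in the samples at a covariate level minus its mean observed
#' height in the control group (level 1). On log2 heights this is the log2
#' fold change reported by the usual peak-table analysis platforms.
#'
#' @param dataset a [peak_dataset()].
#' @param peak_id the peak.
#' @param level covariate level to contrast against level 1.
#' @param covariate covariate name (default: the dataset's first).
#' @return the mean difference, or `NA` (with a warning) when either group
#'   has no observed value for the peak.
#' @export
fold_change <- function(dataset, peak_id, level, covariate = NULL) {
  stopifnot(inherits(dataset, "peak_dataset"))
  if (is.null(covariate)) covariate <- dataset$covariates[1]
  x <- dataset$heights[peak_id, ]
  a <- dataset$sample_meta[[covariate]]
  xl <- x[a == level]; x1 <- x[a == 1L]
  if (!sum(!is.na(xl)) || !sum(!is.na(x1))) {
    warning("fold change undefined for peak ", peak_id,
            ": a group has no observed value")
    return(NA_real_)
  }
  mean(xl, na.rm = TRUE) - mean(x1, na.rm = TRUE)
}

#' Strongest peak of a cluster
#'
#' The representative peak used by the single-peak approach: the member
#' with the largest mean observed (pre-centering) intensity. When any
#' member carries an annotation, annotated peaks take priority over
#' unannotated ones. Ties are broken by peak id.
#'
#' @param dataset a [peak_dataset()].
#' @param peaks character vector of member peak ids.
#' @return a single peak id.
#' @export
strongest_peak <- function(dataset, peaks) {
  stopifnot(length(peaks) >= 1)
  pm <- dataset$peak_meta
  ann <- if ("annotation" %in% names(pm)) {
    v <- pm$annotation[match(peaks, pm$peak_id)]
    !is.na(v) & nzchar(v)
  } else rep(FALSE, length(peaks))
  if (any(ann)) peaks <- peaks[ann]
  m <- rowMeans(dataset$heights[peaks, , drop = FALSE], na.rm = TRUE)
  peaks[order(-m, peaks)][1]
}

#' Single-peak effect analysis (Model 3 baseline)
#'
#' For each cluster, estimates every non-baseline covariate effect by the
#' [fold_change()] of the cluster's [strongest_peak()], with a Welch
#' two-sample t-test against the control group providing the significance
#' flag.
#'
#' @param dataset a [peak_dataset()].
#' @param clustering cluster labels (any input accepted by
#'   [cluster_labels()]).
#' @param covariate covariate name (default: the dataset's first).
#' @param p_cutoff significance threshold on the t-test p-value.
#' @return data.frame with one row per (cluster, non-baseline level):
#'   the chosen peak, estimate, p-value, `significant` and `sign`.
#' @export
single_peak_effects <- function(dataset, clustering, covariate = NULL,
                                p_cutoff = 0.05) {
  if (is.null(covariate)) covariate <- dataset$covariates[1]
  z <- cluster_labels(clustering)
  if (is.null(names(z))) names(z) <- rownames(dataset$heights)
  a <- dataset$sample_meta[[covariate]]
  levs <- setdiff(sort(unique(a)), 1L)
  rows <- list()
  for (k in sort(unique(z))) {
    pk <- strongest_peak(dataset, names(z)[z == k])
    x <- dataset$heights[pk, ]
    for (l in levs) {
      est <- fold_change(dataset, pk, l, covariate)
      xl <- x[a == l]; x1 <- x[a == 1L]
      p <- if (sum(!is.na(xl)) > 1 && sum(!is.na(x1)) > 1)
        tryCatch(stats::t.test(xl, x1)$p.value, error = function(e) NA_real_)
      else NA_real_
      rows[[length(rows) + 1L]] <- data.frame(
        cluster = k, term = paste0(covariate, ":", l), peak = pk,
        mean = est, p_value = p,
        significant = !is.na(p) && p < p_cutoff,
        sign = ifelse(is.na(est) | est == 0, 0L, ifelse(est > 0, 1L, -1L)),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Height-only joint clustering and effects (Model 2 baseline)
#'
#' The comparison model that uses peak heights only: the same Gaussian
#' latent-variable hierarchy as [cluster_effects()], but with the
#' clustering unknown and given a uniform multinomial prior over `k_max`
#' labels. Cluster assignments are resampled jointly with the effects by
#' Gibbs: a peak's conditional over labels is proportional to the Gaussian
#' likelihood of its heights under each cluster's current latent means.
#' Label switching is resolved at summary time: the clustering is
#' summarized by its co-occurrence matrix and least-squares point
#' estimate, and effect posteriors are then obtained by re-running the
#' fixed-clustering sampler at that point estimate.
#'
#' @param dataset a [peak_dataset()].
#' @param covariates covariate name(s); see [cluster_effects()].
#' @param k_max number of multinomial labels (default: one per peak, so
#'   every partition is expressible).
#' @param n0,sigma0_sq,n_sweeps,burn_in,thin,seed,level as in
#'   [cluster_effects()].
#' @return Object of class `model2_fit`: `labels` (point-estimate
#'   clustering), `cooccur`, and `effects` (a `cluster_effects` fit at the
#'   point estimate).
#' @export
model2_effects <- function(dataset, covariates = NULL, k_max = NULL,
                           n0 = 1, sigma0_sq = 1,
                           n_sweeps = 1500, burn_in = 500, thin = 2,
                           seed = 1, level = 0.95) {
  stopifnot(inherits(dataset, "peak_dataset"), burn_in < n_sweeps)
  if (is.null(covariates)) covariates <- dataset$covariates
  Xc <- center_heights(dataset)
  P <- nrow(Xc)
  if (is.null(k_max)) k_max <- P
  stopifnot(k_max >= 1)
  des <- build_design(dataset$sample_meta, covariates, FALSE)

  sample_z <- function(X0, O, xlat, sigma2) {
    # B[k, j] = sum_i O_ji (x_ji - xlat_ki)^2; terms constant in k dropped
    T1 <- xlat %*% t(X0)            # sum_i x_ji xlat_ki (missing are 0)
    T2 <- (xlat^2) %*% t(O)         # sum_i O_ji xlat_ki^2
    lw <- sweep(2 * T1 - T2, 2, 2 * sigma2, "/")
    vapply(seq_len(ncol(lw)), function(j) {
      w <- exp(lw[, j] - max(lw[, j]))
      sample.int(nrow(lw), 1L, prob = w)
    }, 0L)
  }
  set.seed(seed)
  dr <- gibbs_effects_engine(Xc, z = rep(1L, P), K = k_max, Z = des$Z,
                             n0 = n0, sigma0_sq = sigma0_sq,
                             n_sweeps = n_sweeps, burn_in = burn_in,
                             thin = thin, allow_empty = TRUE,
                             sample_z = sample_z)
  zs <- t(apply(dr$z_draws, 1, canonical_labels))
  S <- nrow(zs)
  cooccur <- matrix(0, P, P)
  for (s in seq_len(S)) cooccur <- cooccur + outer(zs[s, ], zs[s, ], "==")
  cooccur <- cooccur / S
  dimnames(cooccur) <- list(rownames(Xc), rownames(Xc))
  labels <- least_squares_clustering(
    list(samples = zs, cooccur = cooccur, peak_ids = rownames(Xc)))
  effects <- cluster_effects(dataset, labels, covariates = covariates,
                             n0 = n0, sigma0_sq = sigma0_sq,
                             n_sweeps = n_sweeps, burn_in = burn_in,
                             thin = thin, seed = seed + 1L, level = level)
  structure(list(labels = labels, cooccur = cooccur, effects = effects,
                 k_max = k_max, seed = seed),
            class = "model2_fit")
}

#' @export
cluster_labels.model2_fit <- function(x, ...) x$labels

#' @export
print.model2_fit <- function(x, ...) {
  cat("Height-only joint clustering + effects (uniform multinomial prior)\n")
  cat("  k_max:", x$k_max, " point-estimate clusters:", max(x$labels), "\n")
  print(x$effects)
  invisible(x)
}
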