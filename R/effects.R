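#' Build the covariate design for the effects model
#'
#' Lays out the columns of the effect matrix for up to two covariates:
#' the baseline (every covariate at level 1) is fixed to zero and gets no
#' column; each non-baseline level of each covariate gets one main-effect
#' column; with `interaction = TRUE`, every pair of non-baseline levels of
#' the two covariates gets one interaction column. The modelled cluster
#' mean of a sample is the sum of its applicable effect columns.
#'
#' @param sample_meta data.frame with one integer level column per
#'   covariate (1 = baseline).
#' @param covariates character vector of 1 or 2 covariate names.
#' @param interaction add pairwise interaction columns (two covariates
#'   only).
#' @return list with `Z` (N x C binary design over the free columns) and
#'   `terms` (data.frame describing each column: term label, covariate(s),
#'   level(s)).
#' @export
build_design <- function(sample_meta, covariates, interaction = FALSE) {
  if (length(covariates) < 1L || length(covariates) > 2L)
    stop("1 or 2 covariates supported")
  if (interaction && length(covariates) < 2L)
    stop("interaction requires two covariates")
  N <- nrow(sample_meta)
  cols <- list()
  terms <- list()
  for (cv in covariates) {
    lev <- sample_meta[[cv]]
    if (is.null(lev)) stop("covariate '", cv, "' not in sample_meta")
    for (l in setdiff(sort(unique(lev)), 1L)) {
      cols[[length(cols) + 1L]] <- as.integer(lev == l)
      terms[[length(terms) + 1L]] <-
        data.frame(term = paste0(cv, ":", l), covariate = cv, level = l,
                   stringsAsFactors = FALSE)
    }
  }
  if (interaction) {
    l1 <- sample_meta[[covariates[1]]]
    l2 <- sample_meta[[covariates[2]]]
    for (a in setdiff(sort(unique(l1)), 1L))
      for (b in setdiff(sort(unique(l2)), 1L)) {
        cols[[length(cols) + 1L]] <- as.integer(l1 == a & l2 == b)
        terms[[length(terms) + 1L]] <-
          data.frame(term = paste0(covariates[1], ":", a, "x",
                                   covariates[2], ":", b),
                     covariate = paste(covariates, collapse = "x"),
                     level = NA_integer_, stringsAsFactors = FALSE)
      }
  }
  if (!length(cols)) stop("no non-baseline levels: nothing to estimate")
  Z <- do.call(cbind, cols)
  terms <- do.call(rbind, terms)
  colnames(Z) <- terms$term
  list(Z = Z, terms = terms)
}

#' Single-site full-conditional draws of the effects model
#'
#' The three conjugate full conditionals of the Gaussian latent-variable
#' model, exposed individually (the Gibbs sampler alternates vectorized
#' versions of the same formulas):
#'
#' * `draw_latent_mean()`: cluster mean for one sample, prior
#'   `N(prior_mean, 1)` combined with the likelihood of the cluster's
#'   observed peak heights `x` with variances `sigma2` —
#'   precision `1 + sum(1/sigma2)`.
#' * `draw_effect()`: one effect entry, prior `N(0, 1)` combined with the
#'   unit-variance latent-mean residuals `resid` of the samples the column
#'   applies to — precision `1 + length(resid)`.
#' * `draw_peak_var()`: one peak variance, scaled inverse-chi-squared
#'   prior `(n0, sigma0_sq)` updated by the squared residuals `resid` of
#'   that peak's observed heights — `Scale-Inv-chi2(n0 + n,
#'   (n0*sigma0_sq + sum(resid^2)) / (n0 + n))`.
#'
#' @param prior_mean prior mean of the latent cluster mean.
#' @param x observed centered heights of the cluster's peaks in the sample
#'   (length 0 if none observed).
#' @param sigma2 peak variances matching `x`.
#' @param resid residuals (see above; length 0 allowed).
#' @param n0,sigma0_sq prior pseudo-count and scale of the variance prior.
#' @return one posterior draw (numeric scalar).
#' @export
draw_latent_mean <- function(prior_mean, x, sigma2) {
  prec <- 1 + sum(1 / sigma2)
  m <- (prior_mean + sum(x / sigma2)) / prec
  stats::rnorm(1, m, 1 / sqrt(prec))
}

#' @rdname draw_latent_mean
#' @export
draw_effect <- function(resid) {
  prec <- 1 + length(resid)
  stats::rnorm(1, sum(resid) / prec, 1 / sqrt(prec))
}

#' @rdname draw_latent_mean
#' @export
draw_peak_var <- function(resid, n0, sigma0_sq) {
  df <- n0 + length(resid)
  (n0 * sigma0_sq + sum(resid^2)) / stats::rchisq(1, df)
}

# Core Gibbs engine over (xlat, alpha, sigma2) at a fixed clustering.
# Xc: centered P x N heights (NA = missing); z: cluster label per peak,
# labels 1..K (empty labels permitted when allow_empty, as in the
# height-only baseline where K = k_max); Z: N x C binary design.
# Caller seeds the RNG.
gibbs_effects_engine <- function(Xc, z, K, Z, n0, sigma0_sq,
                                 n_sweeps, burn_in, thin,
                                 allow_empty = FALSE, sample_z = NULL) {
  P <- nrow(Xc); N <- ncol(Xc); C <- ncol(Z)
  if (!allow_empty && length(setdiff(seq_len(K), unique(z))))
    stop("empty cluster in the clustering")
  O <- !is.na(Xc)
  X0 <- ifelse(O, Xc, 0)
  n_obs <- rowSums(O)
  A <- matrix(0, K, P); A[cbind(z, seq_len(P))] <- 1  # cluster indicator

  alpha <- matrix(0, K, C)
  sigma2 <- rep(sigma0_sq, P)
  xlat <- alpha %*% t(Z)

  keep <- seq.int(burn_in + 1L, n_sweeps, by = thin)
  keepv <- logical(n_sweeps); keepv[keep] <- TRUE
  S <- length(keep)
  alpha_draws <- array(0, c(S, K, C))
  xlat_draws <- array(0, c(S, K, N))
  sigma_draws <- matrix(0, S, P)
  z_draws <- if (!is.null(sample_z)) matrix(0L, S, P) else NULL
  nZ <- colSums(Z)
  s <- 0L
  for (sw in seq_len(n_sweeps)) {
    if (!is.null(sample_z)) {           # baseline model: resample clustering
      z <- sample_z(X0, O, xlat, sigma2)
      A <- matrix(0, K, P); A[cbind(z, seq_len(P))] <- 1
    }
    # peak variances | rest
    resid <- X0 - xlat[z, , drop = FALSE]
    resid[!O] <- 0
    sigma2 <- (n0 * sigma0_sq + rowSums(resid^2)) /
      stats::rchisq(P, n0 + n_obs)
    # latent cluster means | rest (clusters x samples, all independent)
    w <- 1 / sigma2
    Wk <- A %*% (O * w)
    Xw <- A %*% (X0 * w)
    prec <- 1 + Wk
    m <- (alpha %*% t(Z) + Xw) / prec
    xlat <- m + matrix(stats::rnorm(K * N), K, N) / sqrt(prec)
    # effects | rest, column by column (columns may overlap with
    # interactions present)
    for (cc in seq_len(C)) {
      idx <- Z[, cc] == 1L
      other <- alpha[, -cc, drop = FALSE] %*% t(Z[idx, -cc, drop = FALSE])
      r <- xlat[, idx, drop = FALSE] - other
      prec_a <- 1 + nZ[cc]
      alpha[, cc] <- stats::rnorm(K, rowSums(r) / prec_a, 1 / sqrt(prec_a))
    }
    if (keepv[sw]) {
      s <- s + 1L
      alpha_draws[s, , ] <- alpha
      xlat_draws[s, , ] <- xlat
      sigma_draws[s, ] <- sigma2
      if (!is.null(z_draws)) z_draws[s, ] <- z
    }
  }
  list(alpha_draws = alpha_draws, xlat_draws = xlat_draws,
       sigma_draws = sigma_draws, z_draws = z_draws)
}

#' Infer covariate effects on peak clusters
#'
#' Stage-2 fit: given a clustering of the peaks (one compound per
#' cluster), infers the covariate effects on each cluster from the
#' centered heights of all its member peaks. The model is a Gaussian
#' latent-variable hierarchy — heights are noisy observations (peak
#' variance `sigma2_j`, scaled inverse-chi-squared prior) of a latent
#' per-cluster, per-sample mean, which has a unit-variance normal prior
#' centered on the sample's covariate effect; effects have standard
#' normal priors, with the baseline level fixed at zero. All conditionals
#' are conjugate and the posterior is sampled by Gibbs. Missing heights
#' simply drop out of every conditional.
#'
#' @param dataset a [peak_dataset()] (heights on the log scale).
#' @param clustering a `dp_clustering` fit, or a cluster-label vector
#'   named by peak id.
#' @param covariates covariate name(s) to model (default: all declared in
#'   the dataset; at most 2).
#' @param interaction include interaction effects (two covariates only).
#' @param n0 prior pseudo-sample count of the peak-variance prior.
#' @param sigma0_sq prior scale of the peak-variance prior.
#' @param n_sweeps,burn_in,thin Gibbs schedule.
#' @param seed RNG seed.
#' @param level credible level used for the significance flag.
#' @param one_sided flag significance by a one-sided posterior sign
#'   probability instead of the central interval.
#' @return Object of class `cluster_effects` with posterior draws of the
#'   effect matrix (clusters x effect columns), latent means and peak
#'   variances, plus per-effect summaries.
#' @export
cluster_effects <- function(dataset, clustering,
                            covariates = NULL, interaction = FALSE,
                            n0 = 1, sigma0_sq = 1,
                            n_sweeps = 1500, burn_in = 500, thin = 2,
                            seed = 1, level = 0.95, one_sided = FALSE) {
  stopifnot(inherits(dataset, "peak_dataset"), n0 > 0, sigma0_sq > 0,
            burn_in < n_sweeps)
  if (is.null(covariates)) covariates <- dataset$covariates
  z <- cluster_labels(clustering)
  Xc <- center_heights(dataset)
  if (is.null(names(z))) {
    if (length(z) != nrow(dataset$heights))
      stop("unnamed clustering must cover every peak of the dataset")
    names(z) <- rownames(dataset$heights)
  }
  miss <- setdiff(rownames(Xc), names(z))
  if (length(miss)) stop("peaks missing from the clustering: ",
                         paste(utils::head(miss, 5), collapse = ", "))
  z <- z[rownames(Xc)]
  z <- match(z, sort(unique(z)))  # contiguous labels after any drops
  K <- max(z)
  des <- build_design(dataset$sample_meta, covariates, interaction)
  ctl <- control_samples(dataset)
  # sanity check, deliberately loose: control latents legitimately
  # fluctuate around zero, so only a gross offset is flagged
  gm <- mean(Xc[, ctl, drop = FALSE], na.rm = TRUE)
  if (is.finite(gm) && abs(gm) > 0.75)
    warning("heights do not appear centered on the control group ",
            sprintf("(control grand mean %.2f)", gm))

  set.seed(seed)
  dr <- gibbs_effects_engine(Xc, z, K, des$Z, n0, sigma0_sq,
                             n_sweeps, burn_in, thin)
  fit <- structure(c(dr, list(
    labels = stats::setNames(z, rownames(Xc)),
    terms = des$terms, design = des$Z,
    peak_ids = rownames(Xc), sample_ids = colnames(Xc),
    covariates = covariates, interaction = interaction,
    n0 = n0, sigma0_sq = sigma0_sq, level = level, one_sided = one_sided,
    n_sweeps = n_sweeps, burn_in = burn_in, thin = thin, seed = seed)),
    class = "cluster_effects")
  fit$summaries <- effect_summaries(fit, level, one_sided)
  fit
}

# per-(cluster, effect column) posterior summaries
effect_summaries <- function(fit, level, one_sided) {
  S <- dim(fit$alpha_draws)[1]
  K <- dim(fit$alpha_draws)[2]
  C <- dim(fit$alpha_draws)[3]
  out <- expand.grid(cluster = seq_len(K), term = fit$terms$term,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out <- out[order(out$cluster), , drop = FALSE]
  rownames(out) <- NULL
  qs <- c((1 - level) / 2, 1 - (1 - level) / 2)
  stat <- t(apply(out, 1, function(row) {
    k <- as.integer(row[["cluster"]])
    cc <- match(row[["term"]], fit$terms$term)
    d <- fit$alpha_draws[, k, cc]
    c(mean(d), stats::quantile(d, qs, names = FALSE),
      mean(d > 0))
  }))
  out$mean <- stat[, 1]; out$lo <- stat[, 2]; out$hi <- stat[, 3]
  pgt <- stat[, 4]
  out$significant <- if (one_sided) pmax(pgt, 1 - pgt) >= level
                     else out$lo > 0 | out$hi < 0
  out$sign <- ifelse(out$mean > 0, 1L, ifelse(out$mean < 0, -1L, 0L))
  out
}

#' Significance flags for inferred effects
#'
#' An effect is flagged significant when its central credible interval at
#' the given level excludes zero (or, one-sided, when the posterior
#' probability of one sign reaches the level).
#'
#' @param fit a `cluster_effects` fit.
#' @param level credible level in (0, 1).
#' @param one_sided use the one-sided sign-probability rule.
#' @return data.frame of per-(cluster, term) summaries with `significant`
#'   and `sign` columns.
#' @export
significance <- function(fit, level = 0.95, one_sided = FALSE) {
  stopifnot(inherits(fit, "cluster_effects"))
  if (level <= 0 || level >= 1) stop("level must be in (0, 1)")
  if (dim(fit$alpha_draws)[1] < 100)
    stop("need at least 100 retained draws for significance calls")
  effect_summaries(fit, level, one_sided)
}

#' @export
coef.cluster_effects <- function(object, ...) {
  m <- apply(object$alpha_draws, c(2, 3), mean)
  m <- cbind(0, m)
  colnames(m) <- c("baseline", object$terms$term)
  rownames(m) <- paste0("cluster", seq_len(nrow(m)))
  m
}

#' @export
print.cluster_effects <- function(x, ...) {
  K <- dim(x$alpha_draws)[2]
  cat("Cluster covariate effects (Gibbs posterior)\n")
  cat("  clusters:", K, " peaks:", length(x$peak_ids),
      " samples:", length(x$sample_ids), "\n")
  cat("  effect columns:", paste(x$terms$term, collapse = ", "),
      "(baseline fixed at 0)\n")
  cat("  retained draws:", dim(x$alpha_draws)[1], "\n")
  nsig <- sum(x$summaries$significant)
  cat("  significant effects at", x$level, "level:", nsig, "of",
      nrow(x$summaries), "\n")
  invisible(x)
}

#' @export
summary.cluster_effects <- function(object, ...) {
  out <- list(effects = object$summaries, level = object$level,
              n_draws = dim(object$alpha_draws)[1],
              sigma2 = colMeans(object$sigma_draws))
  class(out) <- "summary.cluster_effects"
  out
}

#' @export
print.summary.cluster_effects <- function(x, ...) {
  cat("Posterior effect summaries (", x$n_draws, " draws, ",
      x$level * 100, "% intervals)\n", sep = "")
  print(x$effects, digits = 3)
  invisible(x)
}

#' @export
plot.cluster_effects <- function(x, ...) {
  s <- x$summaries
  n <- nrow(s)
  plot(s$mean, seq_len(n), xlim = range(s$lo, s$hi, 0),
       pch = 19, yaxt = "n", xlab = "effect (log2 scale)", ylab = "",
       main = "posterior covariate effects", ...)
  segments(s$lo, seq_len(n), s$hi, seq_len(n))
  abline(v = 0, lty = 2)
  axis(2, at = seq_len(n), labels = paste0("c", s$cluster, " ", s$term),
       las = 1, cex.axis = 0.7)
  invisible(x)
}
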