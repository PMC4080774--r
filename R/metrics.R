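#' Normalized information distance between two clusterings
#'
#' `1 - I(A; B) / max(H(A), H(B))`, computed from the contingency table of
#' the two label vectors. 0 for identical partitions (up to relabeling),
#' 1 for independent ones; defined as 0 when both entropies are zero
#' (both partitions trivial).
#'
#' @param a,b cluster label vectors over the same items.
#' @return distance in `[0, 1]`.
#' @export
nid <- function(a, b) {
  if (length(a) != length(b)) stop("clusterings cover different item sets")
  n <- length(a)
  tab <- table(a, b) / n
  pa <- rowSums(tab); pb <- colSums(tab)
  Ha <- -sum(pa[pa > 0] * log(pa[pa > 0]))
  Hb <- -sum(pb[pb > 0] * log(pb[pb > 0]))
  if (Ha == 0 && Hb == 0) return(0)
  nz <- tab > 0
  I <- sum(tab[nz] * log(tab[nz] / outer(pa, pb)[nz]))
  d <- 1 - I / max(Ha, Hb)
  min(max(d, 0), 1)
}

#' Mean squared error between effect matrices
#'
#' Mean of squared differences over all non-baseline effects.
#'
#' @param estimated,truth numeric matrices of matching shape (clusters x
#'   non-baseline levels), or full matrices whose zero first column has
#'   already been dropped.
#' @return scalar MSE.
#' @export
mse_effects <- function(estimated, truth) {
  estimated <- as.matrix(estimated); truth <- as.matrix(truth)
  if (!all(dim(estimated) == dim(truth))) stop("shape mismatch")
  mean((estimated - truth)^2)
}

#' Significance-detection accuracy
#'
#' Fraction of effects called correctly: an effect counts as a true
#' positive only when it is flagged significant, truly nonzero, and the
#' estimated sign matches the true sign; a true negative is an unflagged
#' truly-zero effect.
#'
#' @param significant logical matrix/vector of significance flags.
#' @param est_sign estimated effect signs (-1/0/1), same shape.
#' @param true_alpha true effects, same shape (non-baseline columns).
#' @return accuracy in `[0, 1]`.
#' @export
detection_accuracy <- function(significant, est_sign, true_alpha) {
  significant <- as.logical(significant)
  est_sign <- sign(as.numeric(est_sign))
  true_alpha <- as.numeric(true_alpha)
  if (length(significant) != length(true_alpha) ||
      length(est_sign) != length(true_alpha)) stop("shape mismatch")
  tp <- significant & true_alpha != 0 & est_sign == sign(true_alpha)
  tn <- !significant & true_alpha == 0
  (sum(tp) + sum(tn)) / length(true_alpha)
}

#' Benjamini-Hochberg step-up rejections
#'
#' Standard BH procedure controlling the false discovery rate at `q`.
#'
#' @param p_values p-values in `[0, 1]`.
#' @param q FDR level.
#' @return logical rejection flags.
#' @export
bh_fdr <- function(p_values, q = 0.05) {
  stopifnot(all(p_values >= 0 & p_values <= 1, na.rm = TRUE), q > 0, q < 1)
  stats::p.adjust(p_values, method = "BH") <= q
}

#' Match inferred clusters to true clusters
#'
#' Greedy maximum peak-overlap matching: repeatedly pair the (true,
#' inferred) cluster pair sharing the most peaks, without replacement;
#' any true cluster left unmatched falls back to the inferred cluster
#' holding most of its peaks.
#'
#' @param inferred,truth cluster label vectors over the same peaks.
#' @return integer vector: for each true cluster id (1..K), the matched
#'   inferred cluster id.
#' @export
match_clusters <- function(inferred, truth) {
  tk <- sort(unique(truth)); ik <- sort(unique(inferred))
  tab <- as.matrix(table(factor(truth, tk), factor(inferred, ik)))
  map <- stats::setNames(rep(NA_integer_, length(tk)), tk)
  free_r <- rep(TRUE, nrow(tab)); free_c <- rep(TRUE, ncol(tab))
  repeat {
    sub <- tab
    sub[!free_r, ] <- -1; sub[, !free_c] <- -1
    if (all(sub < 0) || max(sub) <= 0) break
    idx <- which(sub == max(sub), arr.ind = TRUE)[1, ]
    map[idx[1]] <- ik[idx[2]]
    free_r[idx[1]] <- FALSE; free_c[idx[2]] <- FALSE
  }
  for (r in which(is.na(map))) map[r] <- ik[which.max(tab[r, ])]
  map
}

# Align a Bayesian fit's effect summaries to the true clusters of a
# simulation and score it. `summaries` needs columns cluster/term/mean/
# significant/sign ordered as build_design lays terms out.
score_effect_fit <- function(summaries, est_labels, truth) {
  map <- match_clusters(est_labels[names(truth$labels)], truth$labels)
  terms <- unique(summaries$term)
  Ktrue <- length(map)
  est <- matrix(NA_real_, Ktrue, length(terms))
  sig <- matrix(FALSE, Ktrue, length(terms))
  sgn <- matrix(0L, Ktrue, length(terms))
  for (k in seq_len(Ktrue)) {
    rows <- summaries[summaries$cluster == map[k], , drop = FALSE]
    rows <- rows[match(terms, rows$term), , drop = FALSE]
    est[k, ] <- rows$mean
    sig[k, ] <- rows$significant
    sgn[k, ] <- rows$sign
  }
  truth_mat <- truth$alpha[, -1, drop = FALSE]
  list(mse = mse_effects(est, truth_mat),
       accuracy = detection_accuracy(sig, sgn, truth_mat),
       estimate = est, significant = sig, sign = sgn)
}
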