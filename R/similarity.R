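#' Read extracted-ion-chromatogram traces
#'
#' Long-format delimited text with columns `sample_id, peak_id, rt,
#' intensity`: the chromatographic trace of each peak in each sample.
#' Rows are grouped per (sample, peak) and sorted by retention time;
#' the result does not depend on the row order of the file.
#'
#' @param path CSV path (TSV if the file ends in `.tsv`).
#' @return data.frame of class `eic_table`, sorted by (sample_id, peak_id,
#'   rt).
#' @export
read_eic_table <- function(path) {
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  d <- utils::read.table(path, header = TRUE, sep = sep,
                         stringsAsFactors = FALSE)
  need <- c("sample_id", "peak_id", "rt", "intensity")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("EIC table lacks column(s): ", paste(miss, collapse = ", "))
  d$sample_id <- as.character(d$sample_id)
  d$peak_id <- as.character(d$peak_id)
  d$rt <- as.numeric(d$rt)
  d$intensity <- as.numeric(d$intensity)
  if (any(d$intensity < 0, na.rm = TRUE)) stop("negative intensities in EIC table")
  d <- d[order(d$sample_id, d$peak_id, d$rt), , drop = FALSE]
  key <- paste(d$sample_id, d$peak_id, sep = "\r")
  dup <- duplicated(cbind(key, d$rt))
  if (any(dup) || any(stats::ave(d$rt, key, FUN = function(x) c(1, diff(x))) <= 0))
    stop("retention times not strictly increasing within a trace")
  rownames(d) <- NULL
  class(d) <- c("eic_table", "data.frame")
  d
}

#' Shape similarity of two chromatographic traces
#'
#' The similarity of two peak shapes is their Pearson correlation over the
#' shared retention-time window, with negative values truncated to zero.
#' Traces are linearly interpolated onto the union of observed time points
#' inside the overlap of their rt ranges.
#'
#' @param rt_a,int_a retention times (s) and intensities of the first trace.
#' @param rt_b,int_b second trace.
#' @return Similarity in `[0, 1]`, or `NA` when the pair is unobservable
#'   (fewer than 3 common grid points, or a zero-variance trace).
#' @export
pair_similarity <- function(rt_a, int_a, rt_b, int_b) {
  lo <- max(min(rt_a), min(rt_b))
  hi <- min(max(rt_a), max(rt_b))
  if (hi < lo) return(NA_real_)
  grid <- sort(unique(c(rt_a[rt_a >= lo & rt_a <= hi],
                        rt_b[rt_b >= lo & rt_b <= hi])))
  if (length(grid) < 3L) return(NA_real_)
  ya <- stats::approx(rt_a, int_a, xout = grid, rule = 1)$y
  yb <- stats::approx(rt_b, int_b, xout = grid, rule = 1)$y
  if (stats::sd(ya) == 0 || stats::sd(yb) == 0) return(NA_real_)
  max(0, stats::cor(ya, yb))
}

#' Construct similarity data
#'
#' Container for the per-sample peak-shape similarity tensor `Q`
#' (N x P x P, values in `[0, 1]`) and the binary observation mask `R`
#' (`r[i, j, j'] = 1` iff peaks j and j' are both observed in sample i
#' within the similarity window). Similarities are defined only where the
#' mask is 1.
#'
#' @param Q numeric array N x P x P, symmetric in its last two dimensions.
#' @param R binary array of the same shape.
#' @param peak_ids,sample_ids id vectors (lengths P and N).
#' @return Object of class `similarity_data`.
#' @export
similarity_data <- function(Q, R, peak_ids = NULL, sample_ids = NULL) {
  stopifnot(length(dim(Q)) == 3L, dim(Q)[2] == dim(Q)[3],
            all(dim(R) == dim(Q)))
  N <- dim(Q)[1]; P <- dim(Q)[2]
  if (is.null(peak_ids)) peak_ids <- paste0("P", seq_len(P))
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(N))
  storage.mode(R) <- "integer"
  if (!all(R %in% c(0L, 1L))) stop("mask R must be binary")
  for (i in seq_len(N)) {
    Ri <- matrix(R[i, , ], P, P); Qi <- matrix(Q[i, , ], P, P)
    if (!isTRUE(all.equal(Ri, t(Ri)))) stop("mask not symmetric in sample ", i)
    obs <- Ri == 1L
    if (any(!is.finite(Qi[obs]))) stop("non-finite similarity where observed")
    if (any(Qi[obs] < 0 | Qi[obs] > 1)) stop("similarities outside [0,1]")
    if (any(abs(Qi[obs] - t(Qi)[obs]) > 1e-12)) stop("Q not symmetric in sample ", i)
  }
  Q[R == 0L] <- NA_real_
  structure(list(Q = Q, R = R, peak_ids = peak_ids, sample_ids = sample_ids),
            class = "similarity_data")
}

#' @export
print.similarity_data <- function(x, ...) {
  d <- dim(x$Q)
  off <- d[2] * (d[2] - 1) / 2 * d[1]
  nobs <- sum(x$R[rep(upper.tri(matrix(0, d[2], d[2])), each = d[1])])
  cat("similarity_data:", d[1], "samples,", d[2], "peaks;",
      sprintf("%.1f%% of off-diagonal pairs observed\n", 100 * nobs / off))
  invisible(x)
}

#' Build per-sample similarity matrices from EIC traces
#'
#' For every sample and every peak pair whose apex retention times fall
#' within `window` seconds of each other and whose traces are both present,
#' computes the truncated Pearson shape similarity ([pair_similarity()])
#' and marks the pair observed. All other pairs are masked out. One
#' similarity matrix is produced per sample; shapes are never pooled
#' across samples.
#'
#' @param eic an [read_eic_table()] table (or data.frame with the same
#'   columns).
#' @param dataset a [peak_dataset()]; defines the peak and sample universe.
#' @param window co-elution window in seconds (apex-to-apex; default 30,
#'   roughly a UPLC peak width).
#' @return A [similarity_data()] object.
#' @export
build_similarity <- function(eic, dataset, window = 30) {
  stopifnot(inherits(dataset, "peak_dataset"), window > 0)
  peaks <- dataset$peak_meta$peak_id
  samples <- dataset$sample_meta$sample_id
  bad <- setdiff(unique(eic$peak_id), peaks)
  if (length(bad))
    stop("peak(s) in EIC table absent from dataset: ", paste(bad, collapse = ", "))
  P <- length(peaks); N <- length(samples)
  Q <- array(NA_real_, c(N, P, P))
  R <- array(0L, c(N, P, P))
  for (i in seq_len(N)) {
    di <- eic[eic$sample_id == samples[i], , drop = FALSE]
    traces <- split(di[c("rt", "intensity")], factor(di$peak_id, levels = peaks))
    have <- which(vapply(traces, nrow, 0L) > 0L)
    apex <- vapply(traces[have],
                   function(tr) tr$rt[which.max(tr$intensity)], 0)
    for (a in seq_along(have)) {
      ja <- have[a]
      Q[i, ja, ja] <- 1; R[i, ja, ja] <- 1L
      if (a == length(have)) next
      for (b in seq((a + 1), length(have))) {
        jb <- have[b]
        if (abs(apex[a] - apex[b]) > window) next
        q <- pair_similarity(traces[[ja]]$rt, traces[[ja]]$intensity,
                             traces[[jb]]$rt, traces[[jb]]$intensity)
        if (is.na(q)) next
        Q[i, ja, jb] <- Q[i, jb, ja] <- q
        R[i, ja, jb] <- R[i, jb, ja] <- 1L
      }
    }
  }
  similarity_data(Q, R, peaks, samples)
}

#' Export similarity data as long-format CSV
#'
#' One row per (sample, unordered peak pair): `sample_id, peak_a, peak_b,
#' q, r`. Unobserved pairs have empty `q` and `r = 0`.
#'
#' @param sim a [similarity_data()] object.
#' @param path output CSV path.
#' @export
write_similarity <- function(sim, path) {
  stopifnot(inherits(sim, "similarity_data"))
  P <- length(sim$peak_ids); N <- length(sim$sample_ids)
  ut <- which(upper.tri(diag(P)), arr.ind = TRUE)
  rows <- do.call(rbind, lapply(seq_len(N), function(i)
    data.frame(sample_id = sim$sample_ids[i],
               peak_a = sim$peak_ids[ut[, 1]],
               peak_b = sim$peak_ids[ut[, 2]],
               q = sim$Q[cbind(i, ut[, 1], ut[, 2])],
               r = sim$R[cbind(i, ut[, 1], ut[, 2])])))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read similarity data from long-format CSV
#'
#' Inverse of [write_similarity()].
#'
#' @param path CSV path.
#' @return A [similarity_data()] object.
#' @export
read_similarity <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  peaks <- sort(unique(c(d$peak_a, d$peak_b)))
  samples <- unique(d$sample_id)
  P <- length(peaks); N <- length(samples)
  Q <- array(NA_real_, c(N, P, P))
  R <- array(0L, c(N, P, P))
  i <- match(d$sample_id, samples)
  a <- match(d$peak_a, peaks); b <- match(d$peak_b, peaks)
  obs <- d$r == 1L
  Q[cbind(i, a, b)[obs, , drop = FALSE]] <- d$q[obs]
  Q[cbind(i, b, a)[obs, , drop = FALSE]] <- d$q[obs]
  R[cbind(i, a, b)[obs, , drop = FALSE]] <- 1L
  R[cbind(i, b, a)[obs, , drop = FALSE]] <- 1L
  for (s in seq_len(N)) { diag(Q[s, , ]) <- 1; diag(R[s, , ]) <- 1L }
  similarity_data(Q, R, peaks, samples)
}
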