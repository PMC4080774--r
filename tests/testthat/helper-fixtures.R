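# fixtures built in code: tiny similarity tensors, peak tables, EIC traces

# similarity data for one sample from explicit q / r matrices
sim_from_matrices <- function(qmat, rmat, n_samples = 1) {
  P <- nrow(qmat)
  Q <- array(NA_real_, c(n_samples, P, P))
  R <- array(0L, c(n_samples, P, P))
  for (i in seq_len(n_samples)) {
    qi <- qmat
    qi[rmat == 0L] <- NA_real_
    Q[i, , ] <- qi
    R[i, , ] <- rmat
  }
  similarity_data(Q, R)
}

# the small fixed 4-peak, 1-sample similarity problem used against the
# enumerated partition posterior: peaks 1-3 similar, peak 4 dissimilar,
# pair (1,4) unobserved
fixture_p4 <- function() {
  qv <- matrix(c(1, .92, .85, .2,
                 .92, 1, .7, .15,
                 .85, .7, 1, .3,
                 .2, .15, .3, 1), 4, 4)
  rv <- matrix(1L, 4, 4)
  rv[1, 4] <- rv[4, 1] <- 0L
  sim_from_matrices(qv, rv)
}

# well-separated two-block similarity data (P peaks, first `b1` in block 1)
fixture_blocks <- function(P = 6, b1 = 3, n_samples = 2,
                           q_in = 0.95, q_out = 0.1) {
  z <- rep(c(1L, 2L), c(b1, P - b1))
  qmat <- ifelse(outer(z, z, "=="), q_in, q_out)
  diag(qmat) <- 1
  sim_from_matrices(qmat, matrix(1L, P, P), n_samples)
}

# small peak dataset with two groups (n per group), heights supplied or
# generated flat
fixture_dataset <- function(H, groups, centered = TRUE, annotation = NULL) {
  P <- nrow(H)
  pm <- data.frame(peak_id = rownames(H) %||% paste0("P", seq_len(P)),
                   stringsAsFactors = FALSE)
  if (!is.null(annotation)) pm$annotation <- annotation
  sm <- data.frame(sample_id = paste0("S", seq_along(groups)),
                   group = as.integer(groups), stringsAsFactors = FALSE)
  peak_dataset(H, pm, sm, covariates = "group", log_base = 2,
               centered = centered)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# triangular EIC trace: apex at `apex` (s), half-width w, scaled by `scale`
tri_trace <- function(apex, w = 5, scale = 1, npts = 11) {
  rt <- seq(apex - w, apex + w, length.out = npts)
  data.frame(rt = rt, intensity = scale * pmax(0, 1 - abs(rt - apex) / w))
}

# build a long EIC table from a list of per-(sample, peak) traces
eic_from_traces <- function(traces) {
  do.call(rbind, lapply(traces, function(tr)
    data.frame(sample_id = tr$sample_id, peak_id = tr$peak_id,
               rt = tr$trace$rt, intensity = tr$trace$intensity,
               stringsAsFactors = FALSE)))
}

write_temp_csv <- function(df, ext = ".csv") {
  f <- tempfile(fileext = ext)
  utils::write.csv(df, f, row.names = FALSE, quote = FALSE, na = "")
  f
}
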