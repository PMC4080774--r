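#' Construct a peak dataset
#'
#' Bundles an aligned peak-height matrix with peak and sample metadata.
#' Rows are peaks, columns are samples; entries are (typically log2)
#' intensities and may be `NA` where a peak was not detected in a sample.
#'
#' @param heights numeric matrix, peaks x samples. Row names are taken as
#'   peak ids and column names as sample ids when `peak_meta`/`sample_meta`
#'   are not supplied.
#' @param peak_meta data.frame with columns `peak_id` and optionally `mz`
#'   (Da), `rt` (seconds) and `annotation`.
#' @param sample_meta data.frame with column `sample_id` plus one integer
#'   column per covariate. Covariate levels are coded `1..L`, level 1 being
#'   the control/baseline; level 1 must occur for every covariate.
#' @param covariates character vector naming the covariate columns of
#'   `sample_meta`. Defaults to every column other than `sample_id`.
#' @param log_base base of the log transform already applied to `heights`
#'   (`NA` if intensities are on the raw scale). Recorded so the transform
#'   is applied at most once.
#' @param centered set `TRUE` when `heights` are already centered on the
#'   control group (e.g. data generated directly on the centered scale);
#'   recorded so centering too is applied at most once.
#'
#' @return An object of class `peak_dataset`.
#' @export
peak_dataset <- function(heights, peak_meta = NULL, sample_meta = NULL,
                         covariates = NULL, log_base = NA,
                         centered = FALSE) {
  heights <- as.matrix(heights)
  storage.mode(heights) <- "double"
  P <- nrow(heights)
  N <- ncol(heights)
  if (P < 1L) stop("need at least one peak")
  if (N < 2L) stop("need at least two samples")

  if (is.null(peak_meta)) {
    ids <- rownames(heights)
    if (is.null(ids)) ids <- paste0("P", seq_len(P))
    peak_meta <- data.frame(peak_id = ids, stringsAsFactors = FALSE)
  }
  peak_meta <- as.data.frame(peak_meta)
  if (!"peak_id" %in% names(peak_meta)) stop("peak_meta needs a 'peak_id' column")
  peak_meta$peak_id <- as.character(peak_meta$peak_id)
  if (anyDuplicated(peak_meta$peak_id))
    stop("duplicate peak ids: ",
         paste(unique(peak_meta$peak_id[duplicated(peak_meta$peak_id)]), collapse = ", "))
  if (nrow(peak_meta) != P) stop("peak_meta rows do not match heights rows")

  if (is.null(sample_meta)) {
    ids <- colnames(heights)
    if (is.null(ids)) ids <- paste0("S", seq_len(N))
    sample_meta <- data.frame(sample_id = ids, stringsAsFactors = FALSE)
  }
  sample_meta <- as.data.frame(sample_meta)
  if (!"sample_id" %in% names(sample_meta)) stop("sample_meta needs a 'sample_id' column")
  sample_meta$sample_id <- as.character(sample_meta$sample_id)
  if (nrow(sample_meta) != N) stop("sample_meta rows do not match heights columns")
  if (anyDuplicated(sample_meta$sample_id)) stop("duplicate sample ids")

  if (is.null(covariates))
    covariates <- setdiff(names(sample_meta), "sample_id")
  for (cv in covariates) {
    if (!cv %in% names(sample_meta))
      stop("covariate '", cv, "' not found in sample_meta")
    lev <- sample_meta[[cv]]
    if (is.factor(lev)) lev <- as.integer(lev)
    lev <- as.integer(lev)
    if (anyNA(lev)) stop("covariate '", cv, "' has missing levels")
    if (!1L %in% lev)
      stop("covariate '", cv, "' has no samples at the control level 1")
    sample_meta[[cv]] <- lev
  }

  rownames(heights) <- peak_meta$peak_id
  colnames(heights) <- sample_meta$sample_id
  structure(list(heights = heights, peak_meta = peak_meta,
                 sample_meta = sample_meta, covariates = covariates,
                 log_base = log_base, centered = isTRUE(centered)),
            class = "peak_dataset")
}

#' @export
print.peak_dataset <- function(x, ...) {
  cat("peak_dataset:", nrow(x$heights), "peaks x", ncol(x$heights), "samples\n")
  nm <- sum(is.na(x$heights))
  cat("  missing height entries:", nm,
      sprintf("(%.1f%%)", 100 * nm / length(x$heights)), "\n")
  if (length(x$covariates))
    cat("  covariates:", paste(x$covariates, collapse = ", "), "\n")
  cat("  intensity scale:",
      if (is.na(x$log_base)) "raw" else paste0("log", x$log_base), "\n")
  invisible(x)
}

#' @export
dim.peak_dataset <- function(x) dim(x$heights)

#' Read an aligned peak table
#'
#' Reads a delimited peak-height table: one row per peak, one intensity
#' column per sample, with optional m/z, retention-time and annotation
#' columns. The MZmine 2 aligned-peak-list export is accepted through
#' `dialect = "mzmine"` (columns `row ID`, `row m/z`, `row retention time`,
#' and one `<sample> Peak height` column per sample; retention times in
#' minutes are converted to seconds).
#'
#' @param path path to a CSV/TSV file with a header.
#' @param sample_meta optional data.frame (or path to a CSV) of sample
#'   metadata; see [peak_dataset()]. Its `sample_id` values must match the
#'   sample columns of the table.
#' @param dialect `"generic"` (columns `peak_id[,mz][,rt][,annotation]`,
#'   then sample columns) or `"mzmine"`.
#' @param sep field separator; `","` by default, `"\t"` for `.tsv` files.
#' @param log_base log-transform intensities on input with this base
#'   (default 2, so group differences read as log2 fold changes); `NA`
#'   to keep the raw scale.
#' @param missing_codes values treated as missing in addition to empty
#'   cells and `"NA"`; MZmine writes 0 for undetected peaks, so `0` is
#'   included by default.
#'
#' @return A [peak_dataset()].
#' @export
read_peak_table <- function(path, sample_meta = NULL,
                            dialect = c("generic", "mzmine"),
                            sep = NULL, log_base = 2,
                            missing_codes = c("", "NA", "0")) {
  dialect <- match.arg(dialect)
  if (is.null(sep)) sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  # a provenance header written by write_peak_table() declares the scale;
  # a declared transform is never re-applied
  centered <- FALSE
  first <- readLines(path, n = 1L)
  skip <- 0L
  if (grepl("^# multipeak ", first)) {
    skip <- 1L
    lb <- sub(".*log_base=([^ ]+).*", "\\1", first)
    log_base_applied <- suppressWarnings(as.numeric(lb))
    centered <- grepl("centered=TRUE", first)
    log_base <- if (is.na(log_base_applied)) log_base else NA
    # zero-coded missingness is a raw-intensity convention; on a declared
    # log scale a zero is a legitimate height
    if (missing(missing_codes)) missing_codes <- c("", "NA")
  } else log_base_applied <- NA
  raw <- utils::read.table(path, header = TRUE, sep = sep, skip = skip,
                           check.names = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character", comment.char = "")
  if (dialect == "mzmine") {
    idc <- grep("^row ID$", names(raw))
    if (!length(idc)) stop("not an MZmine aligned peak list: no 'row ID' column")
    ht <- grep(" Peak height$", names(raw))
    peak_meta <- data.frame(peak_id = raw[["row ID"]], stringsAsFactors = FALSE)
    if ("row m/z" %in% names(raw)) peak_meta$mz <- as.numeric(raw[["row m/z"]])
    if ("row retention time" %in% names(raw))
      peak_meta$rt <- 60 * as.numeric(raw[["row retention time"]])  # min -> s
    if ("row identity (main ID)" %in% names(raw))
      peak_meta$annotation <- raw[["row identity (main ID)"]]
    samp_cols <- names(raw)[ht]
    samp_ids <- sub(" Peak height$", "", samp_cols)
  } else {
    if (!"peak_id" %in% names(raw)) stop("no 'peak_id' column in ", path)
    meta_cols <- intersect(c("peak_id", "mz", "rt", "annotation"), names(raw))
    peak_meta <- raw[meta_cols]
    for (cc in intersect(c("mz", "rt"), meta_cols))
      peak_meta[[cc]] <- as.numeric(peak_meta[[cc]])
    samp_cols <- setdiff(names(raw), meta_cols)
    samp_ids <- samp_cols
  }
  if (!length(samp_cols)) stop("no sample columns found in ", path)

  H <- sapply(samp_cols, function(cc) {
    v <- trimws(raw[[cc]])
    v[v %in% missing_codes] <- NA
    as.numeric(v)
  })
  H <- matrix(H, nrow = nrow(raw), dimnames = list(peak_meta$peak_id, samp_ids))
  effective_base <- log_base_applied
  if (!is.na(log_base)) {
    if (any(H <= 0, na.rm = TRUE))
      stop("non-positive intensities cannot be log-transformed; ",
           "add them to missing_codes or set log_base = NA")
    H <- log(H, base = log_base)
    effective_base <- log_base
  }

  if (is.character(sample_meta)) sample_meta <- read_sample_meta(sample_meta)
  if (!is.null(sample_meta)) {
    unknown <- setdiff(samp_ids, sample_meta$sample_id)
    if (length(unknown))
      stop("sample column(s) not in sample metadata: ",
           paste(unknown, collapse = ", "))
    sample_meta <- sample_meta[match(samp_ids, sample_meta$sample_id), ,
                               drop = FALSE]
  }
  peak_dataset(H, peak_meta, sample_meta, log_base = effective_base,
               centered = centered)
}

#' Read sample metadata
#'
#' CSV with a `sample_id` column and one column per covariate, levels coded
#' as integers with 1 = control.
#'
#' @param path path to the CSV file.
#' @return data.frame suitable for [peak_dataset()]'s `sample_meta`.
#' @export
read_sample_meta <- function(path) {
  sm <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"sample_id" %in% names(sm)) stop("no 'sample_id' column in ", path)
  sm$sample_id <- as.character(sm$sample_id)
  sm
}

#' Write a peak dataset back to delimited text
#'
#' Inverse of [read_peak_table()] (generic dialect): heights at full
#' precision, missing entries as empty cells. The intensity scale
#' (log base, centering) is declared in a header comment line so that a
#' round-trip read never re-applies a transform.
#'
#' @param dataset a [peak_dataset()].
#' @param path output CSV path.
#' @export
write_peak_table <- function(dataset, path) {
  stopifnot(inherits(dataset, "peak_dataset"))
  H <- dataset$heights
  out <- cbind(dataset$peak_meta,
               as.data.frame(H, check.names = FALSE))
  con <- file(path, "w")
  on.exit(close(con))
  cat(sprintf("# multipeak log_base=%s centered=%s rt=seconds mz=Da\n",
              dataset$log_base, dataset$centered), file = con)
  utils::write.table(format(out, digits = 17, trim = TRUE, nsmall = 0,
                            scientific = FALSE),
                     con, sep = ",", row.names = FALSE, quote = FALSE,
                     na = "")
  invisible(path)
}

#' Write clustering and effect results
#'
#' Writes two delimited files under `dir`: `clusters.csv` mapping each peak
#' to its cluster, and `effects.csv` with the posterior mean, central 95%
#' interval and significance flag of every non-baseline covariate effect.
#'
#' @param clustering a `dp_clustering` fit or an integer cluster-label
#'   vector named by peak id.
#' @param effects a `cluster_effects` fit.
#' @param dir output directory (created if needed).
#' @return Invisibly, the two file paths.
#' @export
write_results <- function(clustering, effects, dir) {
  z <- cluster_labels(clustering)
  s <- summary(effects)$effects
  if (!nrow(s)) stop("empty effect posterior")
  if (!all(unique(s$cluster) %in% unique(z)))
    stop("effect table refers to clusters absent from the clustering")
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  cl_path <- file.path(dir, "clusters.csv")
  ef_path <- file.path(dir, "effects.csv")
  utils::write.csv(data.frame(peak_id = names(z), cluster_id = unname(z)),
                   cl_path, row.names = FALSE, quote = FALSE)
  utils::write.csv(s, ef_path, row.names = FALSE, quote = FALSE)
  invisible(c(clusters = cl_path, effects = ef_path))
}

# control-group samples: every declared covariate at level 1
control_samples <- function(dataset) {
  sm <- dataset$sample_meta
  ctl <- rep(TRUE, nrow(sm))
  for (cv in dataset$covariates) ctl <- ctl & sm[[cv]] == 1L
  ctl
}

#' Center peak heights on the control group
#'
#' Subtracts from each peak's row the mean of its observed control-group
#' heights (the control group are the samples with every covariate at
#' level 1). Peaks with no observed control value cannot be centered and
#' are dropped with a warning. Datasets whose heights are recorded as
#' already centered (`dataset$centered`) are returned unchanged, so
#' centering is applied at most once.
#'
#' @param dataset a [peak_dataset()].
#' @return numeric matrix of centered heights (possibly fewer rows than
#'   `dataset`), missing entries kept as `NA`.
#' @export
center_heights <- function(dataset) {
  stopifnot(inherits(dataset, "peak_dataset"))
  H <- dataset$heights
  if (isTRUE(dataset$centered)) return(H)
  ctl <- control_samples(dataset)
  if (!any(ctl)) stop("no control-group samples (all covariates at level 1)")
  m <- rowMeans(H[, ctl, drop = FALSE], na.rm = TRUE)
  bad <- !is.finite(m)
  if (any(bad)) {
    warning(sum(bad), " peak(s) with no observed control-group value dropped: ",
            paste(utils::head(rownames(H)[bad], 5), collapse = ", "))
    H <- H[!bad, , drop = FALSE]
    m <- m[!bad]
  }
  H - m
}
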