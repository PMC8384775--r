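#' Per-sample read depth and zero-count fractions
#'
#' Computed on raw counts with no normalization or pre-filtering: per-sample
#' total read count and fraction of probes with zero reads.
#'
#' @param mat an ExpressionMatrix of raw counts.
#' @return data.frame with sample_id, total_reads, zero_fraction.
#' @export
read_depth_summary <- function(mat) {
  stopifnot(inherits(mat, "ExpressionMatrix"))
  data.frame(sample_id = colnames(mat$counts),
             total_reads = colSums(mat$counts),
             zero_fraction = colMeans(mat$counts == 0),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Fraction of probes with zero counts in every sample
#'
#' @param mat an ExpressionMatrix with at least 2 samples.
#' @return a proportion in [0, 1].
#' @export
consistent_zero_fraction <- function(mat) {
  stopifnot(inherits(mat, "ExpressionMatrix"), ncol(mat$counts) >= 2L)
  mean(rowSums(mat$counts != 0) == 0L)
}

# Locate the triplicate samples of one treatment; errors name the missing
# (chemical, concentration, batch, replicate).
find_replicates <- function(mat, chemical, concentration, batch) {
  s <- mat$samples
  out <- character(3L)
  for (r in 1:3) {
    i <- which(s$chemical == chemical & s$concentration == concentration &
                 s$batch == batch & s$replicate == r)
    if (length(i) != 1L)
      stop("missing replicate: chemical=", chemical, " concentration=",
           concentration, " batch=", batch, " replicate=", r)
    out[r] <- s$sample_id[i]
  }
  out
}

#' Pearson correlations between technical replicates
#'
#' Raw counts over all probes, for the three unordered pairs of the
#' triplicate within one batch: (1,2), (1,3), (2,3).
#'
#' @param mat an ExpressionMatrix of raw counts.
#' @param chemical,concentration treatment selector.
#' @param batch batch number.
#' @return named numeric vector c(r12, r13, r23).
#' @export
technical_replicate_correlations <- function(mat, chemical, concentration,
                                             batch) {
  ids <- find_replicates(mat, chemical, concentration, batch)
  x <- mat$counts[, ids, drop = FALSE]
  c(r12 = stats::cor(x[, 1L], x[, 2L]),
    r13 = stats::cor(x[, 1L], x[, 3L]),
    r23 = stats::cor(x[, 2L], x[, 3L]))
}

#' Pearson correlations between biological replicates across batches
#'
#' Replicate-index-matched pairs between batch 1 and batch 2: replicate 1 of
#' both batches, replicate 2 of both, replicate 3 of both.
#'
#' @param mat an ExpressionMatrix of raw counts with both batches present.
#' @param chemical,concentration treatment selector.
#' @param batches the two batches to compare (default 1 and 2).
#' @return named numeric vector c(r1, r2, r3).
#' @export
biological_replicate_correlations <- function(mat, chemical, concentration,
                                              batches = c(1L, 2L)) {
  a <- find_replicates(mat, chemical, concentration, batches[1L])
  b <- find_replicates(mat, chemical, concentration, batches[2L])
  out <- vapply(1:3, function(r)
    stats::cor(mat$counts[, a[r]], mat$counts[, b[r]]), numeric(1L))
  names(out) <- c("r1", "r2", "r3")
  out
}

#' Median-of-ratios size factors
#'
#' Reference pseudo-sample is the per-probe geometric mean across samples;
#' each sample's size factor is the median of its count ratios to that
#' reference, over probes whose geometric mean is positive.
#'
#' @param mat an ExpressionMatrix (typically after [filter_low_counts()]).
#' @return named numeric vector of size factors, one per sample.
#' @export
size_factors <- function(mat) {
  stopifnot(inherits(mat, "ExpressionMatrix"))
  x <- mat$counts
  if (any(colSums(x) == 0))
    stop("sample with all-zero counts")
  loggeo <- rowMeans(log(x))          # -Inf whenever the probe has a zero
  use <- is.finite(loggeo)
  if (!any(use))
    stop("no probe has all-positive counts; cannot estimate size factors")
  geo <- exp(loggeo[use])
  apply(x[use, , drop = FALSE], 2L, function(cnt)
    stats::median(cnt / geo))
}

#' Variance-stabilizing stand-in transform
#'
#' Divides each sample by its median-of-ratios size factor and applies
#' log2(x + 1). This is a documented stand-in for a model-based variance
#' stabilizing transformation: it preserves the rank and gross variance
#' structure needed for PCA visualization but is not equivalent to a fitted
#' mean-dispersion transform.
#'
#' @param mat an ExpressionMatrix, low-count filtered.
#' @return numeric matrix of transformed values (probes x samples).
#' @export
variance_stabilize <- function(mat) {
  sf <- size_factors(mat)
  log2(sweep(mat$counts, 2L, sf, "/") + 1)
}

#' PCA scores of samples
#'
#' Columns (samples) are observations; probes are variables. Centered, not
#' scaled.
#'
#' @param x transformed matrix (probes x samples), e.g. from
#'   [variance_stabilize()].
#' @param n_components number of components to return.
#' @return matrix of scores (samples x components) with attribute
#'   \code{variance_explained}.
#' @export
pca_scores <- function(x, n_components = 2L) {
  stopifnot(ncol(x) >= 2L)
  if (n_components > ncol(x))
    stop("n_components exceeds the number of samples")
  p <- stats::prcomp(t(x), center = TRUE, scale. = FALSE)
  k <- min(n_components, ncol(p$x))
  scores <- p$x[, seq_len(k), drop = FALSE]
  attr(scores, "variance_explained") <- (p$sdev^2 / sum(p$sdev^2))[seq_len(k)]
  scores
}

#' Full QC summary table
#'
#' One row per sample with depth and zero fraction; correlation rows are
#' produced per treatment by the replicate-correlation functions.
#'
#' @param mat an ExpressionMatrix of raw counts.
#' @return data.frame as from [read_depth_summary()] plus the consistent-zero
#'   fraction as an attribute.
#' @export
qc_summary <- function(mat) {
  out <- read_depth_summary(mat)
  attr(out, "consistent_zero_fraction") <-
    if (ncol(mat$counts) >= 2L) consistent_zero_fraction(mat) else NA_real_
  out
}
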