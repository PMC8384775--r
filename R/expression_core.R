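#' Construct an ExpressionMatrix
#'
#' The root container for the pipeline: a probes x samples matrix of raw
#' non-negative integer counts, with probe annotation (probe -> gene symbol,
#' panel) and per-sample metadata (chemical, concentration, batch, replicate,
#' panel, vehicle flag).
#'
#' @param counts numeric matrix of non-negative integers, probes in rows,
#'   samples in columns. Row and column names must match the annotation and
#'   metadata tables.
#' @param probes data.frame with columns probe_id, gene_symbol, panel.
#' @param samples data.frame with columns sample_id, chemical, concentration,
#'   batch, replicate, panel, is_vehicle.
#' @return an object of class \code{ExpressionMatrix}.
#' @export
expression_matrix <- function(counts, probes, samples) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "double"
  probes <- as.data.frame(probes, stringsAsFactors = FALSE)
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  req_p <- c("probe_id", "gene_symbol", "panel")
  req_s <- c("sample_id", "chemical", "concentration", "batch", "replicate",
             "panel", "is_vehicle")
  if (!all(req_p %in% names(probes)))
    stop("probe annotation must have columns: ", paste(req_p, collapse = ", "))
  if (!all(req_s %in% names(samples)))
    stop("sample metadata must have columns: ", paste(req_s, collapse = ", "))
  if (anyDuplicated(probes$probe_id))
    stop("duplicate probe_id in annotation")
  if (any(!nzchar(probes$gene_symbol)) || anyNA(probes$gene_symbol))
    stop("empty gene_symbol in annotation")
  if (nrow(counts) != nrow(probes) || ncol(counts) != nrow(samples))
    stop("count matrix dimensions do not match annotation/metadata")
  if (is.null(rownames(counts))) rownames(counts) <- probes$probe_id
  if (is.null(colnames(counts))) colnames(counts) <- samples$sample_id
  if (nrow(counts) > 0L &&
      !identical(rownames(counts), as.character(probes$probe_id)))
    stop("count matrix row names do not match probe annotation order")
  if (ncol(counts) > 0L &&
      !identical(colnames(counts), as.character(samples$sample_id)))
    stop("count matrix column names do not match sample metadata order")
  if (anyNA(counts) || any(counts < 0))
    stop("counts must be non-negative and non-missing")
  key <- do.call(paste, c(samples[c("chemical", "concentration", "batch",
                                    "replicate", "panel")], sep = "\r"))
  if (anyDuplicated(key))
    stop("(chemical, concentration, batch, replicate, panel) must be unique")
  if (any(samples$is_vehicle & samples$concentration != 0))
    stop("vehicle samples must have concentration 0")
  structure(list(counts = counts, probes = probes, samples = samples),
            class = "ExpressionMatrix")
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat("ExpressionMatrix:", nrow(x$counts), "probes x", ncol(x$counts),
      "samples\n")
  cat("panels:", paste(unique(x$probes$panel), collapse = ", "),
      "| chemicals:", length(setdiff(unique(x$samples$chemical), NA)), "\n")
  invisible(x)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$counts)

#' Load a count matrix with annotation and metadata from TSV files
#'
#' The counts file has probe_id in the first column and one column per
#' sample; annotation and metadata follow the schemas documented in
#' [expression_matrix()].
#'
#' @param counts_path,annotation_path,meta_path paths to TSV files.
#' @return an [expression_matrix()] object.
#' @export
load_counts <- function(counts_path, annotation_path, meta_path) {
  cts <- read_tsv(counts_path)
  ann <- read_tsv(annotation_path)
  meta <- read_tsv(meta_path)
  probe_ids <- as.character(cts[[1L]])
  mat <- as.matrix(cts[, -1L, drop = FALSE])
  rownames(mat) <- probe_ids
  if (any(mat != floor(mat), na.rm = TRUE))
    stop("non-integer count found in ", counts_path)
  missing <- setdiff(probe_ids, ann$probe_id)
  if (length(missing) > 0L)
    stop("probe(s) missing from annotation: ",
         paste(utils::head(missing, 5L), collapse = ", "))
  ann <- ann[match(probe_ids, ann$probe_id), , drop = FALSE]
  if ("concentration_uM" %in% names(meta) && !"concentration" %in% names(meta))
    names(meta)[names(meta) == "concentration_uM"] <- "concentration"
  meta$is_vehicle <- as.logical(meta$is_vehicle)
  meta <- meta[match(colnames(mat), meta$sample_id), , drop = FALSE]
  if (anyNA(meta$sample_id))
    stop("sample(s) missing from metadata")
  message("loaded ", nrow(mat), " probes x ", ncol(mat), " samples")
  expression_matrix(mat, ann, meta)
}

#' Write an ExpressionMatrix to TSV files
#'
#' Inverse of [load_counts()]; writes counts, annotation and metadata.
#'
#' @param mat an ExpressionMatrix.
#' @param counts_path,annotation_path,meta_path output paths.
#' @export
write_counts <- function(mat, counts_path, annotation_path, meta_path) {
  df <- data.frame(probe_id = rownames(mat$counts), mat$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(df, counts_path)
  write_tsv(mat$probes, annotation_path)
  meta <- mat$samples
  names(meta)[names(meta) == "concentration"] <- "concentration_uM"
  write_tsv(meta, meta_path)
  invisible(mat)
}

#' Remove probes with low average counts
#'
#' Probes whose mean raw count across all samples is strictly below
#' \code{min_mean} are removed; a probe averaging exactly \code{min_mean}
#' is kept. Samples are untouched. Idempotent.
#'
#' @param mat an ExpressionMatrix.
#' @param min_mean minimum mean count (default 10).
#' @return a filtered ExpressionMatrix.
#' @export
filter_low_counts <- function(mat, min_mean = 10) {
  stopifnot(inherits(mat, "ExpressionMatrix"), nrow(mat$counts) > 0L)
  keep <- rowMeans(mat$counts) >= min_mean
  if (!any(keep))
    warning("all probes removed by low-count filter")
  expression_matrix(mat$counts[keep, , drop = FALSE],
                    mat$probes[keep, , drop = FALSE],
                    mat$samples)
}

#' Sum isoform probes into one count per gene
#'
#' Probes sharing a gene symbol are combined by addition, giving one read
#' count per gene per sample; per-sample totals are conserved exactly.
#'
#' @param mat an ExpressionMatrix.
#' @return an ExpressionMatrix with one row per gene symbol (rows ordered by
#'   gene symbol).
#' @export
aggregate_isoforms <- function(mat) {
  stopifnot(inherits(mat, "ExpressionMatrix"))
  g <- mat$probes$gene_symbol
  agg <- rowsum(mat$counts, group = g, reorder = TRUE)
  panel <- mat$probes$panel[match(rownames(agg), g)]
  probes <- data.frame(probe_id = rownames(agg),
                       gene_symbol = rownames(agg),
                       panel = panel, stringsAsFactors = FALSE)
  expression_matrix(agg, probes, mat$samples)
}

#' Construct an L2FC profile object
#'
#' @param treatment_id identifier, conventionally from [make_treatment_id()].
#' @param values named numeric vector of log2 fold-changes, one per gene or
#'   probe; names unique, values finite.
#' @param platform free-text platform label.
#' @return an object of class \code{L2FCProfile}.
#' @export
l2fc_profile <- function(treatment_id, values, platform = "unknown") {
  stopifnot(is.numeric(values), !is.null(names(values)))
  if (anyDuplicated(names(values))) stop("duplicate gene symbols in profile")
  if (any(!is.finite(values))) stop("non-finite L2FC values")
  structure(list(treatment_id = treatment_id, values = values,
                 platform = platform),
            class = "L2FCProfile")
}

#' @export
print.L2FCProfile <- function(x, ...) {
  cat("L2FCProfile", x$treatment_id, "-", length(x$values), "features (",
      x$platform, ")\n")
  invisible(x)
}

#' Average log2 fold-change profile of a treatment versus control
#'
#' In \code{mode = "counts"} the value for each feature is
#' \code{log2((mean_trt + pseudocount) / (mean_ctl + pseudocount))}.
#' In \code{mode = "intensity"} the input matrix already holds log2-scale
#' values (e.g. RMA-normalized intensities) and the profile is the simple
#' difference of group means.
#'
#' @param mat an ExpressionMatrix (counts mode) or any matrix-bearing
#'   ExpressionMatrix whose values are log2 intensities (intensity mode).
#' @param treatment_samples,control_samples disjoint, non-empty vectors of
#'   sample ids from the same panel.
#' @param pseudocount added to both group means in counts mode; must be
#'   positive if any control mean is zero.
#' @param mode "counts" or "intensity".
#' @param treatment_id identifier for the resulting profile.
#' @param platform platform label.
#' @return an [l2fc_profile()] object.
#' @export
compute_l2fc_profile <- function(mat, treatment_samples, control_samples,
                                 pseudocount = 0.5,
                                 mode = c("counts", "intensity"),
                                 treatment_id = "treatment",
                                 platform = "counts") {
  mode <- match.arg(mode)
  stopifnot(inherits(mat, "ExpressionMatrix"),
            length(treatment_samples) > 0L, length(control_samples) > 0L)
  if (length(intersect(treatment_samples, control_samples)) > 0L)
    stop("treatment and control samples must be disjoint")
  miss <- setdiff(c(treatment_samples, control_samples), colnames(mat$counts))
  if (length(miss) > 0L)
    stop("unknown sample id(s): ", paste(miss, collapse = ", "))
  pan <- unique(mat$samples$panel[match(c(treatment_samples, control_samples),
                                        mat$samples$sample_id)])
  if (length(pan) > 1L)
    stop("treatment and control samples must come from the same panel")
  mt <- rowMeans(mat$counts[, treatment_samples, drop = FALSE])
  mc <- rowMeans(mat$counts[, control_samples, drop = FALSE])
  if (mode == "counts") {
    if (pseudocount <= 0 && any(mc == 0 | mt == 0))
      stop("zero group mean with non-positive pseudocount; ",
           "use a positive pseudocount")
    vals <- log2((mt + pseudocount) / (mc + pseudocount))
  } else {
    vals <- mt - mc
  }
  names(vals) <- rownames(mat$counts)
  l2fc_profile(treatment_id, vals, platform)
}

#' Collapse a probe-level profile to gene level
#'
#' Multi-probe genes are collapsed with the chosen rule: \code{"mean"}
#' averages the probe values, \code{"max_abs"} keeps the value of largest
#' magnitude (sign preserved).
#'
#' @param profile an L2FCProfile whose names are probe ids.
#' @param annotation data.frame with probe_id and gene_symbol columns.
#' @param rule "mean" or "max_abs".
#' @return a gene-level L2FCProfile.
#' @export
collapse_probes_to_genes <- function(profile, annotation,
                                     rule = c("mean", "max_abs")) {
  rule <- match.arg(rule)
  stopifnot(inherits(profile, "L2FCProfile"))
  sym <- annotation$gene_symbol[match(names(profile$values),
                                      annotation$probe_id)]
  if (anyNA(sym))
    stop("probe(s) in profile missing from annotation")
  f <- switch(rule,
              mean = function(v) mean(v),
              max_abs = function(v) v[which.max(abs(v))])
  vals <- vapply(split(profile$values, sym), f, numeric(1L))
  l2fc_profile(profile$treatment_id, vals, profile$platform)
}

#' Relative viability percentage
#'
#' Mean luminescence of the treatment group as a percentage of the mean of
#' the vehicle control group.
#'
#' @param lum_treatment,lum_vehicle numeric vectors of luminescence readings.
#' @return a single percentage.
#' @export
relative_viability <- function(lum_treatment, lum_vehicle) {
  stopifnot(length(lum_treatment) > 0L, length(lum_vehicle) > 0L)
  mv <- mean(lum_vehicle)
  if (!is.finite(mv) || mv <= 0)
    stop("vehicle mean must be positive")
  100 * mean(lum_treatment) / mv
}

#' Construct a reference profile database
#'
#' @param profiles list of [l2fc_profile()] objects with unique treatment ids.
#' @param chemical_of named character vector mapping treatment_id to chemical.
#' @return an object of class \code{ProfileDatabase}.
#' @export
profile_database <- function(profiles, chemical_of) {
  ids <- vapply(profiles, function(p) p$treatment_id, character(1L))
  if (anyDuplicated(ids)) stop("duplicate treatment ids in database")
  if (!all(ids %in% names(chemical_of)))
    stop("every profile's chemical must be resolvable in chemical_of")
  names(profiles) <- ids
  structure(list(profiles = profiles, chemical_of = chemical_of[ids]),
            class = "ProfileDatabase")
}

#' @export
print.ProfileDatabase <- function(x, ...) {
  cat("ProfileDatabase:", length(x$profiles), "profiles,",
      length(unique(x$chemical_of)), "chemicals\n")
  invisible(x)
}

#' @export
length.ProfileDatabase <- function(x) length(x$profiles)

#' Write a profile database as a genes x treatments TSV matrix
#'
#' Genes missing from a profile are written as NA. The chemical map is
#' recoverable from the treatment ids via [parse_treatment_id()].
#'
#' @param db a ProfileDatabase.
#' @param path output TSV path.
#' @export
write_profile_db <- function(db, path) {
  genes <- sort(unique(unlist(lapply(db$profiles,
                                     function(p) names(p$values)))))
  m <- vapply(db$profiles, function(p) p$values[genes], numeric(length(genes)))
  df <- data.frame(gene = genes, m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv(df, path)
  invisible(db)
}

#' Read a profile database from a genes x treatments TSV matrix
#'
#' @param path TSV path, first column \code{gene}, one column per treatment.
#' @param chemical_of optional named character vector mapping treatment ids to
#'   chemicals; when NULL the chemical is parsed from the treatment id.
#' @return a ProfileDatabase.
#' @export
read_profile_db <- function(path, chemical_of = NULL) {
  df <- read_tsv(path)
  genes <- as.character(df[[1L]])
  ids <- names(df)[-1L]
  profiles <- lapply(ids, function(id) {
    v <- df[[id]]
    names(v) <- genes
    l2fc_profile(id, v[!is.na(v)], platform = "reference")
  })
  if (is.null(chemical_of)) {
    chemical_of <- vapply(ids, function(id)
      parse_treatment_id(id)$chemical, character(1L))
    names(chemical_of) <- ids
  }
  profile_database(profiles, chemical_of)
}
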