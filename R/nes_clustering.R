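#' Ward hierarchical clustering of matrix columns
#'
#' Agglomerative clustering of columns with Euclidean distance and the
#' "ward.D2" criterion (Ward on unsquared Euclidean input, i.e. the method
#' squares distances internally). Cluster labels after cutting at \code{k}
#' are relabeled by first appearance in column order, so the partition is
#' deterministic and stable.
#'
#' @param m numeric matrix; columns are the objects to cluster. No missing
#'   values (imputation is refused; the caller must handle missingness).
#' @param k number of clusters for the cut.
#' @return list of class \code{cluster_result}: hclust tree, assignment
#'   (named integer vector), k, distance, linkage.
#' @export
ward_cluster <- function(m, k) {
  if (anyNA(m)) stop("missing values in matrix; refusing to impute")
  stopifnot(ncol(m) >= k, k >= 1L)
  hc <- stats::hclust(stats::dist(t(m), method = "euclidean"),
                      method = "ward.D2")
  raw <- stats::cutree(hc, k = k)
  lab <- match(raw, unique(raw))          # relabel by first appearance
  names(lab) <- colnames(m)
  structure(list(hclust = hc, assignment = lab, k = k,
                 distance = "euclidean", linkage = "ward.D2"),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat("cluster_result: k =", x$k, "(", x$linkage, "on", x$distance,
      "distance )\n")
  print(table(x$assignment))
  invisible(x)
}

#' Export a clustering dendrogram in newick format
#'
#' @param cl a cluster_result.
#' @param path output path.
#' @export
write_dendrogram <- function(cl, path) {
  ape::write.tree(ape::as.phylo(cl$hclust), file = path)
  invisible(cl)
}

#' Cross-assay nearest-neighbor pairing of treatments
#'
#' Each treatment must appear as exactly two columns, one per assay. For
#' every treatment, checks whether the Euclidean nearest neighbor of its ST
#' column (self excluded) is that treatment's WT column.
#'
#' @param m numeric matrix, columns = treatment/assay profiles.
#' @param treatment character vector, one entry per column.
#' @param assay character vector per column with exactly two levels; the
#'   first sorted level plays the "ST" role (the side whose neighbor is
#'   inspected).
#' @return list(fraction_paired, unpaired (treatments whose nearest neighbor
#'   test failed), n).
#' @export
nearest_neighbor_pairing <- function(m, treatment, assay) {
  stopifnot(ncol(m) == length(treatment), length(assay) == length(treatment))
  lv <- sort(unique(assay))
  if (length(lv) != 2L) stop("exactly two assays required")
  tab <- table(treatment, assay)
  if (any(tab != 1L))
    stop("every treatment needs exactly one column per assay; offending: ",
         paste(rownames(tab)[rowSums(tab != 1L) > 0], collapse = ", "))
  d <- as.matrix(stats::dist(t(m)))
  diag(d) <- Inf
  st_cols <- which(assay == lv[1L])
  ok <- vapply(st_cols, function(j) {
    nn <- which.min(d[j, ])
    treatment[nn] == treatment[j] && assay[nn] == lv[2L]
  }, logical(1L))
  list(fraction_paired = mean(ok),
       unpaired = treatment[st_cols[!ok]],
       n = length(st_cols))
}

#' Per-set NES difference test between two clusters
#'
#' Welch two-sample t-test on each gene set's NES values between the columns
#' of cluster A and cluster B, BH adjustment across sets, and the absolute
#' difference of cluster means. A Mann-Whitney test is available behind
#' \code{test = "wilcoxon"}.
#'
#' @param nes numeric matrix, gene sets x treatments.
#' @param labels integer/character vector of cluster labels per column (e.g.
#'   a [ward_cluster()] assignment).
#' @param cluster_a,cluster_b the two labels to compare; each must cover at
#'   least 2 columns.
#' @param alpha significance level recorded in the report.
#' @param test "welch" or "wilcoxon".
#' @return data.frame of class \code{cluster_difference_report}: set,
#'   mean_NES_A, mean_NES_B, delta, stat, pval, fdr.
#' @export
cluster_difference_test <- function(nes, labels, cluster_a, cluster_b,
                                    alpha = 0.05,
                                    test = c("welch", "wilcoxon")) {
  test <- match.arg(test)
  a_cols <- which(labels == cluster_a)
  b_cols <- which(labels == cluster_b)
  if (length(a_cols) < 2L || length(b_cols) < 2L)
    stop("both clusters need at least 2 columns")
  rows <- lapply(seq_len(nrow(nes)), function(i) {
    xa <- nes[i, a_cols]; xb <- nes[i, b_cols]
    st <- NA_real_; pv <- NA_real_
    if (stats::sd(xa) > 0 || stats::sd(xb) > 0) {
      ht <- if (test == "welch") stats::t.test(xa, xb)
            else suppressWarnings(stats::wilcox.test(xa, xb))
      st <- unname(ht$statistic); pv <- ht$p.value
    } else if (mean(xa) != mean(xb)) {
      pv <- 0; st <- Inf * sign(mean(xa) - mean(xb))
    }
    data.frame(set = rownames(nes)[i], mean_NES_A = mean(xa),
               mean_NES_B = mean(xb), delta = abs(mean(xa) - mean(xb)),
               stat = st, pval = pv, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr <- NA_real_
  ok <- !is.na(out$pval)
  out$fdr[ok] <- benjamini_hochberg(out$pval[ok])
  attr(out, "alpha") <- alpha
  class(out) <- c("cluster_difference_report", "data.frame")
  out
}

#' Select gene sets discriminating two clusters
#'
#' Sets with \code{delta > delta_min} and \code{fdr < fdr_max} (both strict),
#' ordered by descending delta.
#'
#' @param report a cluster_difference_report.
#' @param delta_min minimum absolute mean-NES difference (default 2.5).
#' @param fdr_max maximum FDR (default 5e-4).
#' @return character vector of set names.
#' @export
select_discriminating_sets <- function(report, delta_min = 2.5,
                                       fdr_max = 5e-4) {
  keep <- !is.na(report$fdr) & report$delta > delta_min &
    report$fdr < fdr_max
  sel <- report[keep, , drop = FALSE]
  sel$set[order(-sel$delta, sel$set, method = "radix")]
}

#' Identify the A/B clusters from tagged gene sets
#'
#' After cutting at k clusters, cluster "A" is the one with the highest mean
#' NES over the metabolism-tagged sets, "B" the one with the highest mean
#' over the injury-tagged sets (labels assigned by inspection in manual
#' workflows; this automates the choice).
#'
#' @param nes gene sets x treatments NES matrix.
#' @param assignment cluster labels per column.
#' @param metabolism_sets,injury_sets tagged set names.
#' @return list(A = label, B = label).
#' @export
identify_ab_clusters <- function(nes, assignment, metabolism_sets,
                                 injury_sets) {
  labs <- unique(assignment)
  mean_over <- function(lab, sets) {
    rows <- intersect(sets, rownames(nes))
    if (length(rows) == 0L) return(NA_real_)
    mean(nes[rows, assignment == lab, drop = FALSE])
  }
  a <- labs[which.max(vapply(labs, mean_over, numeric(1L),
                             sets = metabolism_sets))]
  b <- labs[which.max(vapply(labs, mean_over, numeric(1L),
                             sets = injury_sets))]
  if (identical(a, b))
    warning("same cluster maximizes both tag groups; A/B identification ",
            "ambiguous")
  list(A = a, B = b)
}
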