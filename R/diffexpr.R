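#' Benjamini-Hochberg adjusted p-values
#'
#' Standard step-up procedure with monotonicity enforcement; output clipped
#' to [0, 1]. Invariant to input order.
#'
#' @param p numeric vector of p-values in [0, 1].
#' @return adjusted p-values in input order.
#' @export
benjamini_hochberg <- function(p) {
  if (anyNA(p) || any(p < 0 | p > 1))
    stop("p-values must be finite and within [0, 1]")
  n <- length(p)
  if (n == 0L) return(numeric(0L))
  o <- order(p)
  ro <- order(o)
  adj <- pmin(1, cummin((n / seq(n, 1)) * p[o][n:1]))[n:1]
  adj[ro]
}

#' Call differentially expressed genes
#'
#' Documented stand-in for a negative-binomial GLM: a per-gene ordinary
#' linear model on \code{log2(count / size_factor + 0.5)} with a treatment
#' indicator and, when \code{batch_mode = "corrected"}, an additive batch
#' covariate. Two-sided t-test on the treatment coefficient, BH adjustment
#' across genes, \code{is_deg = adj_p < alpha}. Externally computed DEG
#' tables in the same schema can be substituted anywhere downstream.
#'
#' @param mat an ExpressionMatrix (filtered; isoform-aggregated for
#'   cross-assay comparisons).
#' @param treatment_samples,control_samples sample id vectors, each with at
#'   least 2 samples.
#' @param alpha significance level on adjusted p (default 0.05).
#' @param batch_mode "separate" (no batch covariate; caller typically
#'   subsets one batch) or "corrected" (additive batch term).
#' @return data.frame of class \code{deg_table} with gene, l2fc, stat, p,
#'   adj_p, is_deg. \code{l2fc} is the treatment coefficient on the log2
#'   scale and \code{stat} its t statistic (the GSEA ranking statistic).
#' @export
call_degs <- function(mat, treatment_samples, control_samples, alpha = 0.05,
                      batch_mode = c("corrected", "separate")) {
  batch_mode <- match.arg(batch_mode)
  stopifnot(inherits(mat, "ExpressionMatrix"))
  if (length(treatment_samples) < 2L || length(control_samples) < 2L)
    stop("at least 2 replicates per group are required")
  ids <- c(control_samples, treatment_samples)
  sub <- expression_matrix(mat$counts[, ids, drop = FALSE], mat$probes,
                           mat$samples[match(ids, mat$samples$sample_id), ,
                                       drop = FALSE])
  sf <- size_factors(sub)
  y <- log2(sweep(sub$counts, 2L, sf, "/") + 0.5)
  group <- rep(c(0, 1), c(length(control_samples), length(treatment_samples)))
  batch <- factor(sub$samples$batch)
  X <- if (batch_mode == "corrected" && nlevels(batch) > 1L)
    stats::model.matrix(~ group + batch) else stats::model.matrix(~ group)
  qr_x <- qr(X)
  df_res <- ncol(y) - qr_x$rank
  if (df_res < 1L)
    stop("not enough residual degrees of freedom for the design")
  coefs <- t(qr.coef(qr_x, t(y)))
  fitted <- coefs %*% t(X)
  rss <- rowSums((y - fitted)^2)
  sigma2 <- rss / df_res
  xtx_inv <- chol2inv(qr.R(qr_x))
  j <- match("group", colnames(X))
  se <- sqrt(sigma2 * xtx_inv[j, j])
  tstat <- coefs[, j] / se
  pval <- 2 * stats::pt(-abs(tstat), df = df_res)
  pval[se == 0] <- ifelse(abs(coefs[se == 0, j]) > 0, 0, 1)
  adj <- benjamini_hochberg(pval)
  out <- data.frame(gene = rownames(y), l2fc = coefs[, j], stat = tstat,
                    p = pval, adj_p = adj, is_deg = adj < alpha,
                    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("deg_table", "data.frame")
  out
}

#' Overlap of DEG calls between two analyses
#'
#' Set overlap of \code{is_deg} genes plus the Pearson correlation of log2
#' fold-changes over the overlapping DEGs (NA with \code{r_defined = FALSE}
#' when fewer than 2 genes overlap).
#'
#' @param a,b deg_table data.frames over the same gene universe.
#' @return list with counts, union fractions, pearson_r_overlap, r_defined.
#' @export
deg_overlap <- function(a, b) {
  ga <- a$gene[a$is_deg]
  gb <- b$gene[b$is_deg]
  shared <- intersect(ga, gb)
  only_a <- setdiff(ga, gb)
  only_b <- setdiff(gb, ga)
  n_union <- length(shared) + length(only_a) + length(only_b)
  r <- NA_real_
  defined <- length(shared) >= 2L
  if (defined) {
    va <- a$l2fc[match(shared, a$gene)]
    vb <- b$l2fc[match(shared, b$gene)]
    r <- suppressWarnings(stats::cor(va, vb))
    defined <- is.finite(r)
  }
  list(n_overlap = length(shared), n_only_a = length(only_a),
       n_only_b = length(only_b),
       frac_overlap = if (n_union > 0) length(shared) / n_union else NA_real_,
       frac_only_a = if (n_union > 0) length(only_a) / n_union else NA_real_,
       frac_only_b = if (n_union > 0) length(only_b) / n_union else NA_real_,
       pearson_r_overlap = r, r_defined = defined)
}

#' L2FC matrix over the union of DEGs
#'
#' Rows are the union of \code{is_deg} genes across all treatments; values
#' are each treatment's l2fc for those genes, significant or not.
#'
#' @param tables named list of deg_table data.frames sharing a gene universe.
#' @return numeric matrix (genes x treatments); empty (0-row) with a warning
#'   when no gene is a DEG anywhere.
#' @export
union_deg_matrix <- function(tables) {
  stopifnot(length(tables) > 0L, !is.null(names(tables)))
  genes <- sort(unique(unlist(lapply(tables, function(t) t$gene[t$is_deg]))))
  if (length(genes) == 0L) {
    warning("no DEGs in any treatment; returning empty matrix")
    return(matrix(numeric(0L), nrow = 0L, ncol = length(tables),
                  dimnames = list(NULL, names(tables))))
  }
  vapply(tables, function(t) t$l2fc[match(genes, t$gene)],
         numeric(length(genes))) |>
    `rownames<-`(genes)
}

#' Two-set Venn partition counts
#'
#' @param union_a,union_b gene sets (character vectors).
#' @return named integer vector c(only_a, shared, only_b).
#' @export
venn_counts <- function(union_a, union_b) {
  union_a <- unique(union_a)
  union_b <- unique(union_b)
  c(only_a = length(setdiff(union_a, union_b)),
    shared = length(intersect(union_a, union_b)),
    only_b = length(setdiff(union_b, union_a)))
}

#' Read / write DEG tables
#'
#' TSV schema: gene, l2fc, p, adj_p, is_deg. The same schema is used to
#' import externally computed differential-expression results.
#'
#' @param x a deg_table.
#' @param path TSV path.
#' @export
write_deg_table <- function(x, path) {
  write_tsv(as.data.frame(x), path)
  invisible(x)
}

#' @rdname write_deg_table
#' @export
read_deg_table <- function(path) {
  out <- read_tsv(path)
  out$is_deg <- as.logical(out$is_deg)
  class(out) <- c("deg_table", "data.frame")
  out
}
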