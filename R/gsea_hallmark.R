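#' Load a gene set collection from a GMT file
#'
#' One set per line: name, description, then member genes, tab-separated.
#' Duplicate genes within a set are removed (logged); gene symbols are
#' upper-cased.
#'
#' @param path GMT file path.
#' @return named list of character vectors of class
#'   \code{gene_set_collection}, with a \code{source} attribute.
#' @export
load_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L)
      stop("malformed GMT line ", i, " in ", path,
           ": expected name, description and at least one gene")
    genes <- toupper(f[-(1:2)])
    if (anyDuplicated(genes)) {
      message("GMT line ", i, " (", f[1L], "): removing duplicate genes")
      genes <- unique(genes)
    }
    if (f[1L] %in% names(sets)) stop("duplicate set name: ", f[1L])
    sets[[f[1L]]] <- genes
  }
  structure(sets, class = "gene_set_collection", source = path)
}

#' Write a gene set collection to GMT
#'
#' @param col a gene_set_collection (or plain named list of gene vectors).
#' @param path output path.
#' @param description description field written for every set.
#' @export
write_gmt <- function(col, path, description = "na") {
  lines <- vapply(names(col), function(nm)
    paste(c(nm, description, col[[nm]]), collapse = "\t"), character(1L))
  writeLines(lines, path)
  invisible(col)
}

#' Restrict a collection to a gene universe, with size flags
#'
#' Sets are intersected with the universe. Sets that end up below
#' \code{min_size} or above \code{max_size} are retained but flagged, since
#' enrichment on out-of-range sets is interpretable only with caution; empty
#' sets are flagged \code{"empty"} and skipped by [run_gsea()].
#'
#' @param col a gene_set_collection.
#' @param universe character vector of gene symbols.
#' @param min_size,max_size recommended size window (defaults 15 and 500).
#' @return restricted collection with a \code{flags} attribute
#'   (data.frame: set, size, flag in {"ok","small","large","empty"}).
#' @export
restrict_collection <- function(col, universe, min_size = 15L,
                                max_size = 500L) {
  universe <- toupper(universe)
  out <- lapply(col, function(g) intersect(toupper(g), universe))
  sizes <- lengths(out)
  flag <- ifelse(sizes == 0L, "empty",
                 ifelse(sizes < min_size, "small",
                        ifelse(sizes > max_size, "large", "ok")))
  structure(out, class = "gene_set_collection",
            source = attr(col, "source"),
            flags = data.frame(set = names(out), size = as.integer(sizes),
                               flag = flag, stringsAsFactors = FALSE))
}

#' Gene set enrichment with permutation normalization
#'
#' The enrichment score of each set is the weighted-KS running-sum statistic
#' ([weighted_ks_es()]) over the descending ranking. The null distribution
#' comes from gene-label permutation: \code{n_perm} size-matched random sets
#' drawn from the ranking universe (shared across sets of equal size). For
#' each set, \code{NES = ES / mean(|null ES| of the same sign)},
#' \code{pval = (1 + #same-sign nulls with |null| >= |ES|) / (1 + #same-sign
#' nulls)} (permutation floor 1/(n_perm+1)), and FDR is BH across scored
#' sets.
#'
#' @param ranking named numeric vector, gene -> ranking statistic (need not
#'   be pre-sorted; duplicated gene names are an error).
#' @param col a gene_set_collection (ideally passed through
#'   [restrict_collection()] first).
#' @param n_perm number of permutations (>= 100).
#' @param weight_p weight exponent for the running sum.
#' @param seed optional integer seed for bit-reproducible permutations.
#' @return data.frame of class \code{enrichment_result}: set, size_used, ES,
#'   NES, pval, fdr, flag.
#' @export
run_gsea <- function(ranking, col, n_perm = 1000L, weight_p = 1,
                     seed = NULL) {
  stopifnot(is.numeric(ranking), !is.null(names(ranking)))
  if (anyDuplicated(names(ranking))) stop("duplicate genes in ranking")
  if (n_perm < 100L) stop("n_perm must be at least 100")
  if (!is.null(seed)) set.seed(seed)
  names(ranking) <- toupper(names(ranking))
  ranked <- order_profile(ranking)
  n <- length(ranked)
  w_all <- abs(ranked)^weight_p
  flags <- attr(col, "flags")
  usable <- lapply(col, function(g) intersect(toupper(g), names(ranked)))
  sizes <- lengths(usable)
  scored <- sizes > 0L & sizes < n
  # shared null ES draws per distinct set size
  null_es <- list()
  for (s in sort(unique(sizes[scored]))) {
    null_es[[as.character(s)]] <- vapply(seq_len(n_perm), function(i) {
      idx <- sort(sample.int(n, s))
      es_core(idx, w_all[idx], n)
    }, numeric(1L))
  }
  rows <- lapply(names(col), function(nm) {
    fl <- if (!is.null(flags)) flags$flag[flags$set == nm] else "ok"
    if (length(fl) == 0L) fl <- "ok"
    if (!scored[[nm]]) {
      if (sizes[[nm]] == 0L) fl <- "empty"
      return(data.frame(set = nm, size_used = sizes[[nm]], ES = NA_real_,
                        NES = NA_real_, pval = NA_real_, fdr = NA_real_,
                        flag = fl, stringsAsFactors = FALSE))
    }
    idx <- which(names(ranked) %in% usable[[nm]])
    es <- es_core(idx, w_all[idx], n)
    nulls <- null_es[[as.character(sizes[[nm]])]]
    same <- nulls[sign(nulls) == sign(es)]
    if (es == 0 || length(same) == 0L) {
      nes <- 0; pv <- 1
    } else {
      nes <- es / mean(abs(same))
      pv <- (1 + sum(abs(same) >= abs(es))) / (1 + length(same))
    }
    data.frame(set = nm, size_used = sizes[[nm]], ES = es, NES = nes,
               pval = pv, fdr = NA_real_, flag = fl,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  ok <- !is.na(out$pval)
  out$fdr[ok] <- benjamini_hochberg(out$pval[ok])
  class(out) <- c("enrichment_result", "data.frame")
  out
}

#' NES concordance between two enrichment runs
#'
#' Pearson correlation of NES over sets scored in both runs, plus the size
#' of the intersection of the two top-5 set lists (ranked by descending
#' NES).
#'
#' @param a,b enrichment_result data.frames sharing set names.
#' @return list(pearson_r, top5_overlap, n_shared, defined).
#' @export
nes_concordance <- function(a, b) {
  shared <- intersect(a$set[!is.na(a$NES)], b$set[!is.na(b$NES)])
  if (length(shared) < 2L)
    return(list(pearson_r = NA_real_, top5_overlap = NA_integer_,
                n_shared = length(shared), defined = FALSE))
  na <- a$NES[match(shared, a$set)]
  nb <- b$NES[match(shared, b$set)]
  top5 <- function(v) shared[order(-v, shared, method = "radix")][
    seq_len(min(5L, length(shared)))]
  r <- suppressWarnings(stats::cor(na, nb))
  list(pearson_r = r,
       top5_overlap = length(intersect(top5(na), top5(nb))),
       n_shared = length(shared), defined = is.finite(r))
}

#' Classify sets by signed significant enrichment
#'
#' Three-way classification at an FDR threshold: positively enriched
#' (fdr < alpha, NES > 0), negatively enriched (fdr < alpha, NES < 0), or
#' not significant.
#'
#' @param results an enrichment_result data.frame.
#' @param fdr_alpha FDR threshold (default 0.05).
#' @return data.frame set, class in {"positive","negative","ns"}; unscored
#'   sets are "ns".
#' @export
significant_sets <- function(results, fdr_alpha = 0.05) {
  cls <- rep("ns", nrow(results))
  sig <- !is.na(results$fdr) & results$fdr < fdr_alpha
  cls[sig & results$NES > 0] <- "positive"
  cls[sig & results$NES < 0] <- "negative"
  data.frame(set = results$set, class = cls, stringsAsFactors = FALSE)
}

#' NES matrix across treatments
#'
#' Runs [run_gsea()] once per treatment ranking and assembles the gene sets
#' x treatments NES matrix used for clustering. Per-column seeds are derived
#' from \code{seed} so the matrix is bit-reproducible.
#'
#' @param rankings named list of named numeric ranking vectors, one per
#'   treatment.
#' @param col a gene_set_collection.
#' @param n_perm,weight_p passed to [run_gsea()].
#' @param seed integer base seed.
#' @return numeric matrix (sets x treatments); NA where a set was not
#'   scored.
#' @export
nes_matrix <- function(rankings, col, n_perm = 1000L, weight_p = 1,
                       seed = 1L) {
  stopifnot(length(rankings) > 0L, !is.null(names(rankings)))
  res <- lapply(seq_along(rankings), function(j)
    run_gsea(rankings[[j]], col, n_perm = n_perm, weight_p = weight_p,
             seed = as.integer((seed + j) %% 2000000000)))
  sets <- res[[1L]]$set
  m <- vapply(res, function(r) r$NES[match(sets, r$set)],
              numeric(length(sets)))
  dimnames(m) <- list(sets, names(rankings))
  m
}
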