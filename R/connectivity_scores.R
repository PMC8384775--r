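# Core running-sum computation given sorted hit positions idx (1-based) in a
# ranking of length n, and the hit weights w (already |value|^p, unnormalized).
# Hits increment by w/sum(w); misses decrement by 1/(n - k). The enrichment
# score is the extremum of the running sum (max-deviation convention; the
# positive extremum wins exact ties in magnitude).
es_core <- function(idx, w, n) {
  k <- length(idx)
  if (k == 0L) stop("gene set has no genes in the ranking")
  if (k >= n) stop("gene set covers the whole ranking")
  tw <- sum(w)
  hit <- if (tw > 0) cumsum(w) / tw else seq_len(k) / k
  miss <- (idx - seq_len(k)) / (n - k)
  after <- hit - miss                       # running sum just after each hit
  before <- c(0, hit[-k]) - miss            # just before each hit
  mx <- max(after)
  mn <- min(before, 0)
  if (mx >= -mn) mx else mn
}

#' Weighted Kolmogorov-Smirnov enrichment score
#'
#' Running-sum statistic over a ranked gene list: positions in the gene set
#' increment the sum by \code{|value|^p} (normalized over set members),
#' positions outside it decrement by \code{1/(N - N_hit)}. The enrichment
#' score is the signed extremum of the running sum and lies in [-1, 1].
#' With \code{weight_p = 0} this reduces to the classic KS statistic.
#'
#' @param gene_set character vector of gene symbols.
#' @param ranking named numeric vector of ranking statistics, ordered by
#'   descending value (use [order_profile()] to sort). Values are only used
#'   for the hit weights.
#' @param weight_p weight exponent (0 for unweighted, 1 for the standard
#'   weighted statistic).
#' @return the enrichment score.
#' @export
weighted_ks_es <- function(gene_set, ranking, weight_p = 1) {
  stopifnot(is.numeric(ranking), !is.null(names(ranking)))
  idx <- which(names(ranking) %in% gene_set)
  n <- length(ranking)
  if (length(idx) == 0L)
    stop("gene set does not intersect the ranking")
  if (length(idx) >= n)
    stop("gene set covers the entire ranking")
  es_core(idx, abs(ranking[idx])^weight_p, n)
}

# Jaccard index with the empty-union convention J(0/0) = 0.
jaccard <- function(a, b) {
  u <- length(union(a, b))
  if (u == 0L) return(0)
  length(intersect(a, b)) / u
}

#' Signed Jaccard index between a signature and a restricted profile
#'
#' \code{[J(up,up) + J(down,down) - J(up,down) - J(down,up)] / 2}, bounded in
#' [-1, 1]. The /2, per-pair-Jaccard normalization is this package's
#' convention for bounding the score; other signed-Jaccard variants differ
#' in normalization.
#'
#' @param q a QuerySignature.
#' @param r a RestrictedProfile.
#' @return score in [-1, 1].
#' @export
score_sji <- function(q, r) {
  (jaccard(q$up, r$up) + jaccard(q$down, r$down) -
     jaccard(q$up, r$down) - jaccard(q$down, r$up)) / 2
}

#' Gene set total enrichment score
#'
#' Bidirectional composition of four weighted-KS enrichment scores
#' (weight_p = 1): the query's up/down sets scored in the reference ranking
#' plus the reference's up/down sets scored in the query ranking:
#' \deqn{[ES(q_{up}|r) - ES(q_{down}|r)] + [ES(r_{up}|q) - ES(r_{down}|q)]}
#' Range [-4, 4]. Sets are intersected with the opposing ranking's universe
#' first; a component with empty intersection contributes 0.
#'
#' @param q a QuerySignature.
#' @param q_full named numeric vector: the query's full profile values
#'   ordered descending (see [order_profile()]).
#' @param r a RestrictedProfile.
#' @return score in [-4, 4].
#' @export
score_gtes <- function(q, q_full, r) {
  es_or_zero <- function(set, ranking) {
    idx <- which(names(ranking) %in% set)
    if (length(idx) == 0L || length(idx) >= length(ranking)) return(0)
    es_core(idx, abs(ranking[idx]), length(ranking))
  }
  (es_or_zero(q$up, r$full_values) - es_or_zero(q$down, r$full_values)) +
    (es_or_zero(r$up, q_full) - es_or_zero(r$down, q_full))
}

#' Extreme cosine / Pearson / Spearman connectivity scores
#'
#' The gene vector is the query signature (up and down genes); \code{x} is
#' the query L2FC and \code{y} the reference L2FC with genes outside the
#' reference extremes (and genes absent from the reference universe) masked
#' to 0. \code{xc} is the cosine of x and y, \code{xcp} the Pearson and
#' \code{xcs} the Spearman correlation of the masked vectors. Undefined
#' when fewer than 3 signature genes survive masking, or on zero-variance /
#' zero-norm vectors; undefined scores are returned as NA and rank last.
#'
#' @param q a QuerySignature.
#' @param r a RestrictedProfile.
#' @param flavor "xc", "xcp" or "xcs".
#' @return score in [-1, 1], or NA when undefined.
#' @export
score_extreme <- function(q, r, flavor = c("xc", "xcp", "xcs")) {
  flavor <- match.arg(flavor)
  genes <- c(q$up, q$down)
  x <- unname(q$values[genes])
  y <- r$full_values[genes]          # NA for genes absent from the reference
  extreme <- c(r$up, r$down)
  y[is.na(y) | !(genes %in% extreme)] <- 0
  y <- unname(y)
  if (sum(y != 0) < 3L) return(NA_real_)
  if (flavor == "xc") {
    nx <- sqrt(sum(x^2)); ny <- sqrt(sum(y^2))
    if (nx == 0 || ny == 0) return(NA_real_)
    return(sum(x * y) / (nx * ny))
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  suppressWarnings(stats::cor(x, y,
                              method = if (flavor == "xcp") "pearson"
                                       else "spearman"))
}

#' Score a query against every profile in a reference database
#'
#' Computes the requested connectivity scores for every reference treatment
#' at restriction length \code{nr} and ranks them by the first algorithm,
#' descending. Undefined (NA) scores sort after all defined scores; exact
#' ties break deterministically by reference id.
#'
#' @param q a QuerySignature.
#' @param q_full the query's full descending ranking (named values), needed
#'   for gtes; may be NULL when gtes is not requested.
#' @param db a ProfileDatabase.
#' @param nr reference restriction length.
#' @param algorithms character vector from {"sji","gtes","xc","xcp","xcs"};
#'   ranking uses the first element.
#' @param restricted optional precomputed list of RestrictedProfile objects
#'   named by treatment id (performance path for grid evaluation).
#' @return data.frame of class \code{ranked_hits}: rank, reference_id,
#'   chemical and one column per algorithm, ordered by rank.
#' @export
rank_references <- function(q, q_full = NULL, db, nr,
                            algorithms = c("sji", "gtes", "xc", "xcp", "xcs"),
                            restricted = NULL) {
  stopifnot(inherits(db, "ProfileDatabase"), length(db$profiles) > 0L)
  algorithms <- match.arg(algorithms, several.ok = TRUE)
  if ("gtes" %in% algorithms && is.null(q_full))
    stop("gtes scoring needs the full query ranking (q_full)")
  if (is.null(restricted))
    restricted <- lapply(db$profiles, restrict_reference, nr = nr)
  ids <- names(db$profiles)
  scores <- lapply(algorithms, function(alg) {
    vapply(restricted, function(r) {
      switch(alg,
             sji = score_sji(q, r),
             gtes = score_gtes(q, q_full, r),
             score_extreme(q, r, flavor = alg))
    }, numeric(1L))
  })
  names(scores) <- algorithms
  primary <- scores[[1L]]
  # defined scores first (descending), NA last, ties broken by reference id
  ord <- order(is.na(primary), -ifelse(is.na(primary), Inf, primary), ids,
               method = "radix")
  out <- data.frame(rank = seq_along(ids), reference_id = ids[ord],
                    chemical = unname(db$chemical_of[ids[ord]]),
                    stringsAsFactors = FALSE)
  for (alg in algorithms) out[[alg]] <- unname(scores[[alg]][ord])
  class(out) <- c("ranked_hits", "data.frame")
  attr(out, "sorted_by") <- algorithms[1L]
  out
}
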