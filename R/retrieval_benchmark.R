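#' Rank of the correct hit in a ranked retrieval list
#'
#' The rank of the highest-ranked reference whose chemical matches the
#' query's chemical (names compared after [normalize_chemical()]). Returns
#' NA when the chemical is absent from the database entirely, or when every
#' matching reference's primary score is undefined; the two cases are logged
#' distinctly.
#'
#' @param hits a \code{ranked_hits} data.frame from [rank_references()].
#' @param query_chemical the query's chemical name.
#' @param chemical_of optional named map treatment_id -> chemical; defaults
#'   to the \code{chemical} column of \code{hits}.
#' @return integer rank (>= 1) or NA.
#' @export
correct_hit_rank <- function(hits, query_chemical, chemical_of = NULL) {
  chems <- if (is.null(chemical_of)) hits$chemical
           else unname(chemical_of[hits$reference_id])
  match_rows <- which(normalize_chemical(chems) ==
                        normalize_chemical(query_chemical))
  if (length(match_rows) == 0L) {
    message("chemical ", query_chemical, " absent from the database")
    return(NA_integer_)
  }
  primary <- hits[[attr(hits, "sorted_by") %||% names(hits)[4L]]]
  usable <- match_rows[!is.na(primary[match_rows])]
  if (length(usable) == 0L) {
    message("chemical ", query_chemical,
            " present but all its reference scores are undefined")
    return(NA_integer_)
  }
  as.integer(min(hits$rank[usable]))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Fraction of correct hits in the top k
#'
#' \code{Frk} is the fraction of evaluated chemicals whose correct-hit rank
#' is at most k, for k in {1, 5, 10}. Chemicals with no usable hit (NA rank)
#' count in the denominator, never the numerator.
#'
#' @param ranks vector of integer ranks with NA for no-hit chemicals.
#' @return named numeric vector c(Fr1, Fr5, Fr10).
#' @export
fraction_metrics <- function(ranks) {
  if (length(ranks) == 0L) stop("no ranks supplied")
  frk <- function(k) sum(!is.na(ranks) & ranks <= k) / length(ranks)
  c(Fr1 = frk(1L), Fr5 = frk(5L), Fr10 = frk(10L))
}

#' Exhaustive retrieval benchmark over a parameter grid
#'
#' Evaluates every combination of signature length, profile restriction and
#' scoring algorithm. For each query treatment the correct-hit rank is
#' computed; per chemical, ranks are aggregated over that chemical's query
#' treatments by taking the best (minimum) rank, and Fr1/Fr5/Fr10 are
#' computed over chemicals.
#'
#' @param queries named list of [l2fc_profile()] objects (query treatments).
#' @param db a ProfileDatabase.
#' @param chemical_of_query named map query treatment_id -> chemical name.
#' @param nq_grid,nr_grid integer grids.
#' @param algorithms scoring algorithms to evaluate.
#' @param assay label recorded in the output (e.g. "ST"/"WT").
#' @return list of class \code{benchmark_grid} with \code{cells} (one row per
#'   (assay, algorithm, nq, nr) with Fr metrics) and \code{ranks} (one row
#'   per (assay, algorithm, nq, nr, chemical) with the best rank).
#' @export
grid_evaluate <- function(queries, db, chemical_of_query,
                          nq_grid = default_grids()$nq,
                          nr_grid = default_grids()$nr,
                          algorithms = c("sji", "gtes", "xc", "xcp", "xcs"),
                          assay = "query") {
  stopifnot(length(nq_grid) > 0L, length(nr_grid) > 0L,
            length(queries) > 0L, !is.null(names(queries)))
  algorithms <- match.arg(algorithms, several.ok = TRUE)
  q_full <- lapply(queries, function(p) order_profile(p$values))
  chems <- unique(unname(chemical_of_query[names(queries)]))
  cells <- list(); rank_rows <- list(); ci <- 1L; ri <- 1L
  for (nr in nr_grid) {
    restricted <- lapply(db$profiles, restrict_reference, nr = nr)
    for (nq in nq_grid) {
      # rank lists per query, one scoring pass for all algorithms
      per_query <- vector("list", length(queries))
      names(per_query) <- names(queries)
      for (qid in names(queries)) {
        if (2L * nq > length(queries[[qid]]$values)) {
          message("skipping query ", qid, " at nq=", nq,
                  ": profile too short")
          next
        }
        sig <- suppressMessages(make_query_signature(queries[[qid]], nq))
        per_query[[qid]] <- lapply(algorithms, function(alg)
          rank_references(sig, q_full[[qid]], db, nr, algorithms = alg,
                          restricted = restricted))
      }
      for (a in seq_along(algorithms)) {
        alg <- algorithms[a]
        best <- sapply(chems, function(ch) {
          qids <- names(queries)[normalize_chemical(
            chemical_of_query[names(queries)]) == normalize_chemical(ch)]
          rks <- vapply(qids, function(qid) {
            if (is.null(per_query[[qid]])) return(NA_integer_)
            suppressMessages(
              correct_hit_rank(per_query[[qid]][[a]], ch, db$chemical_of))
          }, integer(1L))
          if (all(is.na(rks))) NA_integer_ else min(rks, na.rm = TRUE)
        })
        fr <- fraction_metrics(best)
        cells[[ci]] <- data.frame(assay = assay, algorithm = alg, nq = nq,
                                  nr = nr, Fr1 = fr[["Fr1"]],
                                  Fr5 = fr[["Fr5"]], Fr10 = fr[["Fr10"]],
                                  stringsAsFactors = FALSE)
        ci <- ci + 1L
        rank_rows[[ri]] <- data.frame(assay = assay, algorithm = alg,
                                      nq = nq, nr = nr, chemical = chems,
                                      rank = as.integer(best),
                                      stringsAsFactors = FALSE)
        ri <- ri + 1L
      }
    }
  }
  structure(list(cells = do.call(rbind, cells),
                 ranks = do.call(rbind, rank_rows)),
            class = "benchmark_grid")
}

#' @export
print.benchmark_grid <- function(x, ...) {
  cat("benchmark_grid:", nrow(x$cells), "cells,",
      length(unique(x$ranks$chemical)), "chemicals\n")
  invisible(x)
}

#' Per-algorithm optimal parameters and best ranks
#'
#' For each algorithm, picks the (nq, nr) cell maximizing the selection
#' metric (ties resolved toward the shortest nq, then the shortest nr) and
#' reports the per-chemical best rank at that cell plus the median and mean
#' rank across chemicals (NA ranks excluded from median/mean).
#'
#' @param grid a \code{benchmark_grid}.
#' @param selection_metric "Fr1", "Fr5" or "Fr10".
#' @return list of class \code{best_rank_table}: \code{params} (one row per
#'   algorithm with chosen nq, nr, metric, median_rank, mean_rank) and
#'   \code{ranks} (chemicals x algorithms matrix of best ranks).
#' @export
best_rank_table <- function(grid, selection_metric = c("Fr1", "Fr5", "Fr10")) {
  selection_metric <- match.arg(selection_metric)
  cells <- grid$cells
  algs <- unique(cells$algorithm)
  chems <- unique(grid$ranks$chemical)
  rank_mat <- matrix(NA_integer_, nrow = length(chems), ncol = length(algs),
                     dimnames = list(chems, algs))
  params <- list()
  for (a in seq_along(algs)) {
    sub <- cells[cells$algorithm == algs[a], , drop = FALSE]
    sub <- sub[order(-sub[[selection_metric]], sub$nq, sub$nr), , drop = FALSE]
    pick <- sub[1L, ]
    rr <- grid$ranks[grid$ranks$algorithm == algs[a] &
                       grid$ranks$nq == pick$nq & grid$ranks$nr == pick$nr, ]
    rank_mat[rr$chemical, a] <- rr$rank
    params[[a]] <- data.frame(algorithm = algs[a], nq = pick$nq, nr = pick$nr,
                              metric = pick[[selection_metric]],
                              median_rank = stats::median(rr$rank, na.rm = TRUE),
                              mean_rank = mean(rr$rank, na.rm = TRUE),
                              stringsAsFactors = FALSE)
  }
  structure(list(params = do.call(rbind, params), ranks = rank_mat,
                 selection_metric = selection_metric),
            class = "best_rank_table")
}
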