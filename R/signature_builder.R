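#' Build a query signature from an L2FC profile
#'
#' The signature is the \code{nq} most up-regulated plus the \code{nq} most
#' down-regulated genes by L2FC rank (rank-based, not sign-based: in a
#' skewed profile a "down" gene may have a positive L2FC). Ties at a rank
#' boundary are broken by ascending lexicographic gene symbol so results are
#' deterministic across platforms.
#'
#' @param profile an [l2fc_profile()].
#' @param nq signature length per direction; the profile must contain at
#'   least \code{2 * nq} genes.
#' @return object of class \code{QuerySignature} with fields up, down
#'   (ordered gene vectors), values (L2FC over signature genes) and nq.
#' @export
make_query_signature <- function(profile, nq) {
  stopifnot(inherits(profile, "L2FCProfile"), nq >= 1L)
  v <- profile$values
  if (2L * nq > length(v))
    stop("profile has ", length(v), " genes; need at least ", 2L * nq)
  desc <- order_profile(v)
  up <- names(desc)[seq_len(nq)]
  down <- rev(names(desc))[seq_len(nq)]
  down <- down[order(v[down], down, method = "radix")]   # ascending L2FC
  if (any(v[down] > 0) || any(v[up] < 0))
    message("signature of ", profile$treatment_id,
            ": sign-inconsistent ranks (skewed profile)")
  structure(list(up = up, down = down, values = v[c(up, down)], nq = nq,
                 treatment_id = profile$treatment_id),
            class = "QuerySignature")
}

#' Restrict a reference profile to its extremes
#'
#' Keeps the \code{nr} most up- and \code{nr} most down-regulated genes and
#' retains the full descending ranking (with values) for enrichment scoring.
#' When the profile holds fewer than \code{2 * nr} genes, \code{nr} is
#' clamped to half the universe (logged), so up and down together cover the
#' whole profile.
#'
#' @param profile an [l2fc_profile()].
#' @param nr restriction length per direction.
#' @return object of class \code{RestrictedProfile} with fields up, down
#'   (gene sets), values (L2FC over up and down), full_ranking (all genes in
#'   descending L2FC order), full_values (named values in that order) and nr.
#' @export
restrict_reference <- function(profile, nr) {
  stopifnot(inherits(profile, "L2FCProfile"), nr >= 1L)
  v <- profile$values
  n <- length(v)
  if (2L * nr > n) {
    nr_eff <- n %/% 2L
    message("clamping nr from ", nr, " to ", nr_eff, " for ",
            profile$treatment_id, " (", n, " genes)")
    nr <- max(1L, nr_eff)
  }
  desc <- order_profile(v)
  up <- names(desc)[seq_len(nr)]
  down <- rev(names(desc))[seq_len(nr)]
  structure(list(up = up, down = down, values = v[c(up, down)],
                 full_ranking = names(desc), full_values = desc, nr = nr,
                 treatment_id = profile$treatment_id),
            class = "RestrictedProfile")
}

#' Default parameter grids for signature and profile lengths
#'
#' @return list with \code{nq} (100 to 1000 by 100) and \code{nr} (1000 to
#'   6000 by 1000).
#' @export
default_grids <- function() {
  list(nq = seq(100L, 1000L, by = 100L),
       nr = seq(1000L, 6000L, by = 1000L))
}

#' Serialize a signature to TSV
#'
#' Two-column layout (gene, direction) plus the signature L2FC value.
#'
#' @param sig a QuerySignature.
#' @param path output TSV path.
#' @export
write_signature <- function(sig, path) {
  df <- data.frame(gene = c(sig$up, sig$down),
                   direction = rep(c("up", "down"), each = sig$nq),
                   l2fc = unname(sig$values[c(sig$up, sig$down)]),
                   stringsAsFactors = FALSE)
  write_tsv(df, path)
  invisible(sig)
}

#' Export a signature as a two-line GMT file
#'
#' One line per direction, named \code{<treatment>_up} / \code{<treatment>_down}.
#'
#' @param sig a QuerySignature.
#' @param path output GMT path.
#' @export
signature_to_gmt <- function(sig, path) {
  lines <- c(paste(c(paste0(sig$treatment_id, "_up"), "signature", sig$up),
                   collapse = "\t"),
             paste(c(paste0(sig$treatment_id, "_down"), "signature", sig$down),
                   collapse = "\t"))
  writeLines(lines, path)
  invisible(sig)
}
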