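#' Build a treatment identifier
#'
#' Treatment identifiers concatenate the chemical, the concentration with two
#' decimals and a "uM" suffix, the exposure duration, species, cell type and
#' study token, joined by hyphens, e.g.
#' \code{"valproic-acid-400.00uM-24h-rn-hep-mystudy"}.
#'
#' @param chemical chemical name; lower-cased, internal whitespace replaced by
#'   hyphens.
#' @param concentration treatment concentration in micromolar.
#' @param duration,species,cell,study remaining identifier tokens.
#' @return a single string.
#' @export
make_treatment_id <- function(chemical, concentration, duration = "24h",
                              species = "rn", cell = "hep", study = "study") {
  chem <- gsub("\\s+", "-", tolower(trimws(chemical)))
  paste(chem, sprintf("%.2fuM", concentration), duration, species, cell, study,
        sep = "-")
}

#' Parse a treatment identifier
#'
#' Splits from the right so that chemical names containing hyphens (e.g.
#' "wy-14643") survive. The concentration token must match
#' \code{<number>uM}; everything before it is the chemical, the first three
#' tokens after it are duration, species and cell, and the remainder (which
#' may itself contain hyphens, e.g. "e-mtab-797") is the study.
#'
#' @param treatment_id string produced by [make_treatment_id()] or following
#'   the same convention.
#' @return a list with elements chemical, concentration, duration, species,
#'   cell, study.
#' @export
parse_treatment_id <- function(treatment_id) {
  stopifnot(is.character(treatment_id), length(treatment_id) == 1L)
  m <- regexec("^(.+)-([0-9]+(?:\\.[0-9]+)?)uM-(.+)$", treatment_id)
  parts <- regmatches(treatment_id, m)[[1]]
  if (length(parts) == 0L)
    stop("cannot parse treatment id: ", treatment_id)
  rest <- strsplit(parts[4L], "-", fixed = TRUE)[[1]]
  if (length(rest) < 4L)
    stop("treatment id has too few tokens after the concentration: ",
         treatment_id)
  list(chemical = parts[2L],
       concentration = as.numeric(parts[3L]),
       duration = rest[1L],
       species = rest[2L],
       cell = rest[3L],
       study = paste(rest[-(1:3)], collapse = "-"))
}

#' Normalize a chemical name for matching
#'
#' Lower-cases and strips all non-alphanumeric characters so that
#' "WY14643" and "wy-14643" compare equal.
#'
#' @param x character vector of chemical names.
#' @return normalized character vector.
#' @export
normalize_chemical <- function(x) {
  gsub("[^a-z0-9]", "", tolower(x))
}

# Deterministic TSV writer shared by all CLI outputs: fixed quoting,
# separator and NA encoding so identical inputs give identical bytes.
write_tsv <- function(df, path, row_names = FALSE) {
  utils::write.table(df, file = path, sep = "\t", quote = FALSE,
                     row.names = row_names, col.names = TRUE, na = "NA",
                     eol = "\n")
  invisible(path)
}

read_tsv <- function(path, ...) {
  utils::read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE, ...)
}

# Order profile values descending with a deterministic lexicographic
# tie-break on gene symbol; returns the named, ordered numeric vector.
order_profile <- function(values) {
  stopifnot(!is.null(names(values)))
  values[order(-values, names(values), method = "radix")]
}
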