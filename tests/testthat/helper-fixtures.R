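# Small in-code fixtures shared across test files.

toy_probes <- function(ids, genes = ids, panel = "ST") {
  data.frame(probe_id = ids, gene_symbol = genes, panel = panel,
             stringsAsFactors = FALSE)
}

toy_samples <- function(ids, chemical = "drugA", concentration = 10,
                        batch = 1L, replicate = seq_along(ids),
                        panel = "ST", is_vehicle = FALSE) {
  data.frame(sample_id = ids, chemical = chemical,
             concentration = concentration, batch = batch,
             replicate = replicate, panel = panel, is_vehicle = is_vehicle,
             stringsAsFactors = FALSE)
}

toy_em <- function(counts, genes = NULL, ...) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)))
    rownames(counts) <- sprintf("p%02d", seq_len(nrow(counts)))
  if (is.null(colnames(counts)))
    colnames(counts) <- sprintf("s%02d", seq_len(ncol(counts)))
  if (is.null(genes)) genes <- rownames(counts)
  expression_matrix(counts, toy_probes(rownames(counts), genes),
                    toy_samples(colnames(counts), ...))
}

# full two-batch triplicate design for one treatment plus vehicle
replicate_em <- function(counts, chemical = "drugA", concentration = 10) {
  counts <- as.matrix(counts)
  stopifnot(ncol(counts) == 6L)
  if (is.null(rownames(counts)))
    rownames(counts) <- sprintf("p%02d", seq_len(nrow(counts)))
  ids <- sprintf("b%dr%d", rep(1:2, each = 3), rep(1:3, 2))
  colnames(counts) <- ids
  meta <- data.frame(sample_id = ids, chemical = chemical,
                     concentration = concentration,
                     batch = rep(1:2, each = 3), replicate = rep(1:3, 2),
                     panel = "ST", is_vehicle = FALSE,
                     stringsAsFactors = FALSE)
  expression_matrix(counts, toy_probes(rownames(counts)), meta)
}

named_profile <- function(values, id = "t", platform = "test") {
  if (is.null(names(values)))
    names(values) <- sprintf("g%03d", seq_along(values))
  l2fc_profile(id, values, platform)
}

# minimal query/reference pair over a shared universe
random_pair <- function(n_genes = 300L, nq = 20L, nr = 50L) {
  genes <- sprintf("g%03d", seq_len(n_genes))
  qp <- l2fc_profile("q", stats::setNames(stats::rnorm(n_genes), genes))
  rp <- l2fc_profile("r", stats::setNames(stats::rnorm(n_genes), genes))
  list(q = make_query_signature(qp, nq),
       q_full = order_profile(qp$values),
       rp = rp,
       r = restrict_reference(rp, nr))
}

small_cfg <- function(seed = 1L, ...) {
  generator_config(n_genes_wt = 1200L, program_size = 40L,
                   n_chemicals = 6L, n_decoy_chemicals = 4L, seed = seed, ...)
}
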