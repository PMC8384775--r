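#' Configuration for the synthetic study generator
#'
#' Defaults emulate the data structure the pipeline is designed for: a
#' whole-transcriptome panel of ~20k genes with a nested surrogate panel
#' (~12%), 14 chemicals at two concentrations (1:5 effect scaling) plus
#' vehicle, triplicate wells in two batches, negative-binomial counts with
#' lognormal library sizes and a multiplicative per-gene batch effect,
#' extra dropout tuned so per-sample zero fractions land in the 15-40%
#' band, and a reference L2FC database with the same chemicals at three
#' concentrations (1:5:25) plus decoy chemicals.
#'
#' @param n_genes_wt whole-panel gene count.
#' @param surrogate_fraction fraction of genes on the surrogate panel.
#' @param n_programs,program_size mechanism programs and their core sizes.
#' @param n_chemicals,n_decoy_chemicals real and decoy chemicals.
#' @param effect_ratio low:high concentration effect scaling (1:5 design).
#' @param replicates,batches well design.
#' @param conc_low_uM,conc_high_uM nominal query concentrations (micromolar).
#' @param baseline_meanlog,baseline_sdlog lognormal baseline expression.
#' @param dispersion_meanlog,dispersion_sdlog lognormal per-gene NB
#'   dispersion.
#' @param batch_sd log2-scale sd of the per-gene multiplicative batch effect.
#' @param libsize_sdlog lognormal sd of per-sample library size factors.
#' @param st_depth_factor total surrogate-panel depth relative to the whole
#'   panel (0.2 emulates 5x lower read depth).
#' @param dropout extra dropout probability applied to every count.
#' @param effect_loading_low,effect_loading_high per-(chemical, program)
#'   loading magnitude range (log2 units at high concentration).
#' @param effect_jitter_sd lognormal sd of the per-(gene, chemical)
#'   multiplicative effect jitter, which gives every chemical a unique
#'   gene-level fingerprint inside shared programs.
#' @param intermediate_scale loading scale of the intermediate archetype.
#' @param background_effect_sd sd of the dense, chemical-specific effects on
#'   background (non-program) genes, in log2 units at high concentration.
#' @param set_jitter_fraction fraction of each program gene set swapped for
#'   background genes, emulating imperfect curated sets.
#' @param noise_sd default sd of reference-profile noise.
#' @param ref_gene_drop fraction of genes missing from the reference
#'   platform's universe.
#' @param decoy_share_fraction fraction of decoys sharing one program with a
#'   real chemical.
#' @param seed integer master seed; all generator randomness derives from it.
#' @return list of class \code{generator_config}.
#' @export
generator_config <- function(n_genes_wt = 20000L,
                             surrogate_fraction = 0.12,
                             n_programs = 8L,
                             program_size = 100L,
                             n_chemicals = 14L,
                             n_decoy_chemicals = 20L,
                             effect_ratio = 5,
                             replicates = 3L,
                             batches = 2L,
                             conc_low_uM = 2,
                             conc_high_uM = 10,
                             baseline_meanlog = log(1.5),
                             baseline_sdlog = 2.4,
                             dispersion_meanlog = log(0.2),
                             dispersion_sdlog = 0.5,
                             batch_sd = 0.15,
                             libsize_sdlog = 0.25,
                             st_depth_factor = 0.2,
                             dropout = 0.02,
                             effect_loading_low = 1.2,
                             effect_loading_high = 3.0,
                             effect_jitter_sd = 0.35,
                             intermediate_scale = 0.35,
                             background_effect_sd = 0.15,
                             set_jitter_fraction = 0.10,
                             noise_sd = 0.5,
                             ref_gene_drop = 0.05,
                             decoy_share_fraction = 0.5,
                             seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(cfg$n_programs * cfg$program_size <= cfg$n_genes_wt,
            cfg$surrogate_fraction > 0, cfg$surrogate_fraction <= 1,
            cfg$n_chemicals >= 1L, cfg$effect_ratio > 1,
            cfg$seed == floor(cfg$seed), abs(cfg$seed) < 2^31 - 10)
  class(cfg) <- "generator_config"
  cfg
}

# derived sub-seeds stay below 2^31
sub_seed <- function(cfg, offset) as.integer((cfg$seed + offset) %% 2000000000)

#' Build the synthetic gene universe, ground truth and gene sets
#'
#' Genes are assigned to disjoint mechanism program cores (the first half of
#' the programs tagged "metabolism", the second half "injury") plus
#' background. Chemicals follow three archetypes: "A" loads metabolism
#' programs positively and injury programs negatively, "B" the reverse, and
#' "C" loads both weakly and positively (intermediate). Each (chemical,
#' program) loading magnitude is drawn independently and each (gene,
#' chemical) effect gets multiplicative lognormal jitter, so chemicals
#' sharing programs still have distinct gene-level fingerprints. The gene
#' set collection holds one jittered set per program core, two pooled tag
#' sets (union of metabolism / injury cores), deliberately tiny sets to
#' exercise size flags, and off-program decoy sets.
#'
#' @param cfg a [generator_config()].
#' @return list with \code{annotation} (probe data.frame), \code{truth}
#'   (ground-truth list: programs, tags, baseline, dispersion, loadings,
#'   per-gene effect matrix \code{beta}, archetypes, tagged set names) and
#'   \code{collection} (gene_set_collection).
#' @export
make_universe <- function(cfg) {
  stopifnot(inherits(cfg, "generator_config"))
  if (cfg$n_programs * cfg$program_size > cfg$n_genes_wt)
    stop("programs do not fit in the gene universe")
  set.seed(sub_seed(cfg, 0L))
  genes <- sprintf("G%05d", seq_len(cfg$n_genes_wt))
  program <- integer(cfg$n_genes_wt)
  core_idx <- sample.int(cfg$n_genes_wt, cfg$n_programs * cfg$program_size)
  program[core_idx] <- rep(seq_len(cfg$n_programs), each = cfg$program_size)
  n_met <- ceiling(cfg$n_programs / 2)
  program_tag <- rep(c("metabolism", "injury"),
                     c(n_met, cfg$n_programs - n_met))
  baseline <- stats::rlnorm(cfg$n_genes_wt, cfg$baseline_meanlog,
                            cfg$baseline_sdlog)
  dispersion <- stats::rlnorm(cfg$n_genes_wt, cfg$dispersion_meanlog,
                              cfg$dispersion_sdlog)
  chems <- sprintf("chem%02d", seq_len(cfg$n_chemicals))
  archetype <- rep_len(c("A", "B", "C"), cfg$n_chemicals)
  # each chemical loads every tagged program except one per tag side; the
  # left-out (metabolism, injury) pair is unique per chemical, so chemicals
  # keep archetype-coherent signs yet distinct program memberships
  met <- which(program_tag == "metabolism")
  inj <- which(program_tag == "injury")
  leave_out <- expand.grid(met = met, inj = inj)
  if (cfg$n_chemicals > nrow(leave_out))
    warning("more chemicals than distinct program combinations; ",
            "chemical identifiability is degraded")
  lo_idx <- rep_len(seq_len(nrow(leave_out)), cfg$n_chemicals)
  loadings <- matrix(0, cfg$n_chemicals, cfg$n_programs,
                     dimnames = list(chems, NULL))
  for (k in seq_len(cfg$n_chemicals)) {
    mag <- stats::runif(cfg$n_programs, cfg$effect_loading_low,
                        cfg$effect_loading_high)
    sgn <- ifelse(program_tag == "metabolism", 1, -1)
    if (archetype[k] == "B") sgn <- -sgn
    if (archetype[k] == "C") {
      sgn <- rep(1, cfg$n_programs)
      mag <- mag * cfg$intermediate_scale
    }
    mag[c(leave_out$met[lo_idx[k]], leave_out$inj[lo_idx[k]])] <- 0
    loadings[k, ] <- sgn * mag
  }
  beta <- matrix(0, cfg$n_genes_wt, cfg$n_chemicals,
                 dimnames = list(genes, chems))
  in_prog <- program > 0L
  for (k in seq_len(cfg$n_chemicals)) {
    jit <- exp(stats::rnorm(sum(in_prog), 0, cfg$effect_jitter_sd))
    beta[in_prog, k] <- loadings[k, program[in_prog]] * jit
    # dense, chemical-specific background effects: real treatments perturb
    # far more genes weakly than any curated program captures, and they
    # keep reference rankings tie-free
    beta[!in_prog, k] <- stats::rnorm(sum(!in_prog), 0,
                                      cfg$background_effect_sd)
  }
  # gene sets: jittered program cores, pooled tag sets, tiny and decoy sets
  bg <- genes[program == 0L]
  sets <- list()
  for (p in seq_len(cfg$n_programs)) {
    core <- genes[program == p]
    n_swap <- round(cfg$set_jitter_fraction * length(core))
    members <- core
    if (n_swap > 0L) {
      members <- c(sample(core, length(core) - n_swap),
                   sample(bg, n_swap))
    }
    sets[[sprintf("PROGRAM_%02d_%s", p, toupper(program_tag[p]))]] <-
      sort(members)
  }
  sets[["METABOLISM_RESPONSE"]] <-
    sort(genes[program %in% which(program_tag == "metabolism")])
  sets[["INJURY_RESPONSE"]] <-
    sort(genes[program %in% which(program_tag == "injury")])
  sets[["TINY_SET_1"]] <- sort(sample(bg, 8L))
  sets[["TINY_SET_2"]] <- sort(sample(bg, 10L))
  for (d in 1:4)
    sets[[sprintf("DECOY_SET_%d", d)]] <-
      sort(sample(bg, min(100L, length(bg))))
  collection <- structure(sets, class = "gene_set_collection",
                          source = "synthetic programs")
  truth <- list(genes = genes, program = program, program_tag = program_tag,
                baseline = baseline, dispersion = dispersion,
                chemicals = chems, archetype = archetype,
                loadings = loadings, beta = beta,
                conc_scale = c(low = 1 / cfg$effect_ratio, high = 1),
                tags = list(
                  metabolism = c(grep("METABOLISM", names(sets),
                                      value = TRUE)),
                  injury = c(grep("INJURY", names(sets), value = TRUE))))
  annotation <- data.frame(probe_id = genes, gene_symbol = genes,
                           panel = "WT", stringsAsFactors = FALSE)
  list(annotation = annotation, truth = truth, collection = collection)
}

#' Select the surrogate gene panel
#'
#' Stratified: half of every program core is kept (so each program retains
#' at least \code{min(15, core size)} members and the panel covers every
#' program), and the remainder is filled from background genes with
#' sampling weight proportional to baseline expression
#' (surrogate panels target genes that are actually measurable, which is
#' why their zero fractions sit well below the whole panel's).
#' Deterministic under the configuration seed.
#'
#' @param truth ground truth from [make_universe()].
#' @param cfg the [generator_config()].
#' @return character vector of panel genes (sorted).
#' @export
make_surrogate_panel <- function(truth, cfg) {
  set.seed(sub_seed(cfg, 1L))
  n_panel <- round(cfg$surrogate_fraction * length(truth$genes))
  picked <- character(0L)
  for (p in seq_len(max(truth$program))) {
    core <- truth$genes[truth$program == p]
    keep <- max(min(15L, length(core)), ceiling(length(core) / 2))
    picked <- c(picked, sample(core, min(keep, length(core))))
  }
  bg <- setdiff(truth$genes, picked)
  n_fill <- max(0L, n_panel - length(picked))
  w <- truth$baseline[match(bg, truth$genes)]
  picked <- c(picked, sample(bg, min(n_fill, length(bg)), prob = w))
  sort(picked)
}

#' Simulate a count matrix for one assay panel
#'
#' Counts are negative binomial with mean
#' \code{baseline * 2^(beta * conc_scale) * batch_factor * libsize} and
#' per-gene dispersion, followed by extra Bernoulli dropout. Vehicle wells
#' have fold-change 1. The surrogate panel is the whole-panel row subset
#' with independent, lower library sizes (total depth
#' \code{st_depth_factor} of the whole panel, spread over fewer genes).
#'
#' @param cfg a [generator_config()].
#' @param truth ground truth from [make_universe()].
#' @param panel "WT" or "ST".
#' @param surrogate panel gene vector from [make_surrogate_panel()]
#'   (required for "ST").
#' @return an [expression_matrix()].
#' @export
simulate_counts <- function(cfg, truth, panel = c("WT", "ST"),
                            surrogate = NULL) {
  panel <- match.arg(panel)
  set.seed(sub_seed(cfg, if (panel == "WT") 2L else 3L))
  genes <- if (panel == "WT") truth$genes else {
    if (is.null(surrogate)) stop("ST simulation needs the surrogate panel")
    surrogate
  }
  gi <- match(genes, truth$genes)
  # scale ST library sizes so the expected total depth is st_depth_factor
  # of the whole panel, accounting for the expression-weighted panel
  depth <- if (panel == "WT") 1 else
    cfg$st_depth_factor * sum(truth$baseline) / sum(truth$baseline[gi])
  conditions <- data.frame(chemical = c(NA, rep(truth$chemicals, each = 2L)),
                           level = c("veh", rep(c("low", "high"),
                                                cfg$n_chemicals)),
                           stringsAsFactors = FALSE)
  conditions$concentration <- ifelse(conditions$level == "veh", 0,
                                     ifelse(conditions$level == "low",
                                            cfg$conc_low_uM,
                                            cfg$conc_high_uM))
  samples <- expand.grid(replicate = seq_len(cfg$replicates),
                         batch = seq_len(cfg$batches),
                         cond = seq_len(nrow(conditions)))
  n_s <- nrow(samples)
  meta <- data.frame(
    sample_id = sprintf("%s_b%d_r%d_%s", panel, samples$batch,
                        samples$replicate,
                        ifelse(conditions$level[samples$cond] == "veh",
                               "vehicle",
                               paste0(conditions$chemical[samples$cond], "_",
                                      conditions$level[samples$cond]))),
    chemical = ifelse(is.na(conditions$chemical[samples$cond]), "vehicle",
                      conditions$chemical[samples$cond]),
    concentration = conditions$concentration[samples$cond],
    batch = samples$batch,
    replicate = samples$replicate,
    panel = panel,
    is_vehicle = conditions$level[samples$cond] == "veh",
    stringsAsFactors = FALSE)
  batch_fac <- matrix(1, length(genes), cfg$batches)
  if (cfg$batches > 1L)
    for (b in 2:cfg$batches)
      batch_fac[, b] <- 2^stats::rnorm(length(genes), 0, cfg$batch_sd)
  libsize <- depth * stats::rlnorm(n_s, 0, cfg$libsize_sdlog)
  counts <- matrix(0, length(genes), n_s,
                   dimnames = list(genes, meta$sample_id))
  base_g <- truth$baseline[gi]
  disp_g <- truth$dispersion[gi]
  for (j in seq_len(n_s)) {
    cond <- conditions[samples$cond[j], ]
    fc <- rep(1, length(genes))
    if (cond$level != "veh") {
      sc <- truth$conc_scale[[cond$level]]
      fc <- 2^(truth$beta[gi, cond$chemical] * sc)
    }
    mu <- base_g * fc * batch_fac[, samples$batch[j]] * libsize[j]
    counts[, j] <- stats::rnbinom(length(genes), mu = mu, size = 1 / disp_g)
  }
  if (cfg$dropout > 0)
    counts[stats::runif(length(counts)) < cfg$dropout] <- 0
  probes <- data.frame(probe_id = genes, gene_symbol = genes, panel = panel,
                       stringsAsFactors = FALSE)
  expression_matrix(counts, probes, meta)
}

#' Noise-free expected L2FC query profiles
#'
#' The ground-truth L2FC of each (chemical, concentration) treatment:
#' \code{beta * conc_scale}, with no sampling noise. Useful as the idealized
#' query side of retrieval experiments.
#'
#' @param truth ground truth from [make_universe()].
#' @param cfg the [generator_config()].
#' @param study study token for the treatment ids.
#' @return list with \code{profiles} (named list of [l2fc_profile()]) and
#'   \code{chemical_of} (named map treatment_id -> chemical).
#' @export
true_query_profiles <- function(truth, cfg, study = "synth-query") {
  profiles <- list()
  chemical_of <- character(0L)
  for (k in seq_along(truth$chemicals)) {
    for (lev in c("low", "high")) {
      conc <- if (lev == "low") cfg$conc_low_uM else cfg$conc_high_uM
      id <- make_treatment_id(truth$chemicals[k], conc, study = study)
      vals <- truth$beta[, k] * truth$conc_scale[[lev]]
      names(vals) <- truth$genes
      profiles[[id]] <- l2fc_profile(id, vals, platform = "synthetic")
      chemical_of[id] <- truth$chemicals[k]
    }
  }
  list(profiles = profiles, chemical_of = chemical_of)
}

#' Build the synthetic reference profile database
#'
#' Emulates an external reference platform: a slightly different gene
#' universe (a fraction of genes dropped), the real chemicals at three
#' concentrations with 1:5:25 effect scaling, and decoy chemicals that
#' either share one mechanism program with a real chemical or load
#' unrelated programs. Profile values are the true per-gene effects plus
#' independent Gaussian noise of sd \code{noise_sd}; with the same seed the
#' underlying noise draws are identical across \code{noise_sd} values
#' (common random numbers), so degradation studies are smooth in the noise
#' level.
#'
#' @param cfg a [generator_config()].
#' @param truth ground truth from [make_universe()].
#' @param noise_sd reference noise sd (defaults to \code{cfg$noise_sd}).
#' @return a [profile_database()] with attributes \code{answer_key}
#'   (data.frame treatment_id, chemical, is_decoy) and \code{genes}.
#' @export
build_reference_db <- function(cfg, truth, noise_sd = cfg$noise_sd) {
  set.seed(sub_seed(cfg, 5L))
  n <- length(truth$genes)
  keep <- sort(sample.int(n, round((1 - cfg$ref_gene_drop) * n)))
  ref_genes <- truth$genes[keep]
  conc_scale <- c(1 / cfg$effect_ratio, 1, cfg$effect_ratio)
  conc_uM <- c(cfg$conc_high_uM / cfg$effect_ratio, cfg$conc_high_uM,
               cfg$conc_high_uM * cfg$effect_ratio)
  # decoy effect vectors
  n_dec <- cfg$n_decoy_chemicals
  dec_names <- sprintf("decoy%02d", seq_len(n_dec))
  dec_beta <- matrix(0, n, n_dec, dimnames = list(truth$genes, dec_names))
  is_shared <- seq_len(n_dec) <= round(cfg$decoy_share_fraction * n_dec)
  in_prog <- truth$program > 0L
  for (d in seq_len(n_dec)) {
    load <- numeric(cfg$n_programs)
    own <- sample.int(cfg$n_programs, 2L)
    load[own] <- sample(c(-1, 1), 2L, replace = TRUE) *
      stats::runif(2L, cfg$effect_loading_low, cfg$effect_loading_high)
    if (is_shared[d]) {
      src <- sample(seq_along(truth$chemicals), 1L)
      p <- sample.int(cfg$n_programs, 1L)
      load[p] <- truth$loadings[src, p]
    }
    jit <- exp(stats::rnorm(sum(in_prog), 0, cfg$effect_jitter_sd))
    dec_beta[in_prog, d] <- load[truth$program[in_prog]] * jit
  }
  all_chems <- c(truth$chemicals, dec_names)
  all_beta <- cbind(truth$beta, dec_beta)
  profiles <- list()
  chemical_of <- character(0L)
  key <- list()
  for (k in seq_along(all_chems)) {
    for (ci in seq_along(conc_scale)) {
      id <- make_treatment_id(all_chems[k], conc_uM[ci], study = "synth-ref")
      vals <- all_beta[keep, k] * conc_scale[ci] +
        stats::rnorm(length(keep)) * noise_sd
      names(vals) <- ref_genes
      profiles[[id]] <- l2fc_profile(id, vals, platform = "synthetic-ref")
      chemical_of[id] <- all_chems[k]
      key[[id]] <- data.frame(treatment_id = id, chemical = all_chems[k],
                              is_decoy = k > length(truth$chemicals),
                              stringsAsFactors = FALSE)
    }
  }
  db <- profile_database(profiles, chemical_of)
  attr(db, "answer_key") <- do.call(rbind, unname(key))
  attr(db, "genes") <- ref_genes
  db
}

#' Run the full synthetic study
#'
#' Orchestrates [make_universe()], [make_surrogate_panel()],
#' [simulate_counts()] for both panels and [build_reference_db()] under the
#' configuration seed. Bit-reproducible for a fixed configuration.
#'
#' @param cfg a [generator_config()].
#' @return list with cfg, annotation, truth, collection, surrogate,
#'   counts_wt, counts_st, db, queries (from [true_query_profiles()]).
#' @export
simulate_study <- function(cfg = generator_config()) {
  uni <- make_universe(cfg)
  surrogate <- make_surrogate_panel(uni$truth, cfg)
  counts_wt <- simulate_counts(cfg, uni$truth, "WT")
  counts_st <- simulate_counts(cfg, uni$truth, "ST", surrogate = surrogate)
  db <- build_reference_db(cfg, uni$truth)
  queries <- true_query_profiles(uni$truth, cfg)
  list(cfg = cfg, annotation = uni$annotation, truth = uni$truth,
       collection = uni$collection, surrogate = surrogate,
       counts_wt = counts_wt, counts_st = counts_st, db = db,
       queries = queries)
}
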