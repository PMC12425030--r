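#' Planted ground truth for a synthetic study
#'
#' Draws every latent quantity the downstream stages are later asked to
#' recover: the signed per-gene MWF effect, the cell types in which each
#' specific gene is enriched, the names of the over-represented pathways,
#' the latent myelin level of every atlas region, and the designated stable
#' probe of every microarray gene.
#'
#' Planted cell-type patterns use one enriched type (`single`) or exactly two
#' (`oligoMultiCell` when one of them is oligodendrocyte/OPC, `multiCell`
#' otherwise): with geometric z-scoring across all cell types the attainable
#' z-score shrinks quickly with the number of jointly enriched types, and two
#' is the largest count that clears the z >= 2 threshold with a wide margin
#' at the default panel size.
#'
#' @param config a [sim_config()].
#' @param regions a region table, by default [region_table()] for `config`.
#' @return an object of class `"ground_truth"`: a list with elements
#'   `aptamers` (aptamer_id, gene_symbol), `genes` (gene_symbol, true_beta,
#'   planted_category, enriched_cells list-column), `cell_types` (a
#'   [cell_type_vocabulary()]), `pathways` (set_name, direction),
#'   `region_myelin` (named numeric in `[0,1]` keyed by region_id),
#'   and `spatial_genes` (gene_symbol, slope, stable_probe).
#' @export
simulate_truth <- function(config, regions = region_table(config)) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(child_seed(config, "truth"))

  # aptamer panel: a small fraction of genes carry two aptamers so the
  # gene-collapse rule downstream is exercised by default
  n_multi <- max(1L, floor(0.04 * config$n_proteins))
  if (config$n_proteins < 3L) n_multi <- 0L
  n_genes <- config$n_proteins - n_multi
  genes <- sprintf("GENE%04d", seq_len(n_genes))
  gene_of_aptamer <- c(genes, genes[seq_len(n_multi)])
  aptamers <- data.frame(
    aptamer_id = sprintf("APT%05d", seq_along(gene_of_aptamer)),
    gene_symbol = gene_of_aptamer,
    stringsAsFactors = FALSE)

  # planted MWF effects, at gene level (all aptamers of a gene share beta)
  true_beta <- stats::setNames(numeric(n_genes), genes)
  planted <- sample(genes, config$n_true_pos + config$n_true_neg)
  pos_genes <- planted[seq_len(config$n_true_pos)]
  neg_genes <- setdiff(planted, pos_genes)
  true_beta[pos_genes] <- config$effect_size_sd
  true_beta[neg_genes] <- -config$effect_size_sd

  vocab <- default_vocabulary(config$n_cell_types)
  oligo <- vocab$oligo_lineage
  other_brain <- setdiff(vocab$brain_related, oligo)

  n_spec <- round(config$frac_specific * n_genes)
  spec_genes <- sample(genes, n_spec)
  planted_category <- stats::setNames(rep("none", n_genes), genes)
  enriched_cells <- stats::setNames(vector("list", n_genes), genes)
  enriched_cells[] <- list(character(0))
  if (n_spec > 0) {
    kind <- sample(c("single", "oligoMultiCell", "multiCell"), n_spec,
                   replace = TRUE, prob = c(0.4, 0.3, 0.3))
    for (i in seq_len(n_spec)) {
      g <- spec_genes[i]
      enriched_cells[[g]] <- switch(kind[i],
        single        = sample(vocab$brain_related, 1L),
        oligoMultiCell = c(sample(oligo, 1L), sample(other_brain, 1L)),
        multiCell     = sample(other_brain, 2L))
      planted_category[g] <- kind[i]
    }
  }

  pathways <- data.frame(
    set_name = c("myelination", "acute_inflammatory_response"),
    direction = c("positive", "negative"),
    stringsAsFactors = FALSE)

  wm <- regions$region_id[regions$tissue_class == "white_matter"]
  dgm <- regions$region_id[regions$tissue_class == "deep_gray"]
  region_myelin <- stats::setNames(numeric(nrow(regions)),
                                   as.character(regions$region_id))
  region_myelin[as.character(wm)] <- stats::runif(length(wm), 0.55, 0.90)
  region_myelin[as.character(dgm)] <- stats::runif(length(dgm), 0.10, 0.35)

  sg_pool <- c("MBP", "GFAP", "SLC1A2", "SNAP25", "PLP1", "MOG", "AQP4",
               "CX3CR1", "GAD1", "SLC17A7")
  n_sg <- config$n_spatial_genes
  sg <- if (n_sg <= length(sg_pool)) sg_pool[seq_len(n_sg)] else
    c(sg_pool, sprintf("SGENE%02d", seq_len(n_sg - length(sg_pool))))
  # the MBP-like gene carries the maximal regional-expression slope; the
  # stable probe is always the first probe label of each gene, so that the
  # deterministic probe_id tie-break also selects it in the noiseless limit
  spatial_genes <- data.frame(
    gene_symbol = sg,
    slope = c(1, stats::runif(n_sg - 1L, 0.3, 0.8))[seq_len(n_sg)],
    stable_probe = paste0(sg, "_p1"),
    stringsAsFactors = FALSE)

  out <- list(aptamers = aptamers,
              genes = data.frame(gene_symbol = genes,
                                 true_beta = unname(true_beta),
                                 planted_category = unname(planted_category),
                                 stringsAsFactors = FALSE),
              enriched_cells = enriched_cells,
              cell_types = vocab,
              pathways = pathways,
              region_myelin = region_myelin,
              spatial_genes = spatial_genes)
  class(out) <- "ground_truth"
  out
}

#' Synthetic subject cohort with covariates and MWF
#'
#' Ages are uniform on \[22, 94\] (mean 58, matching the demography the
#' generator emulates), sex is Bernoulli(0.56) coded 1 = male, and eGFR is
#' log-normal around 75 mL/min/1.73m2. Global MWF follows an inverted-U
#' quadratic age trend (peak near age 45) plus a between-subject biological
#' deviation (`mwf_subject_sd`) plus measurement noise (`mwf_noise_sd`).
#' Regional MWF is the subject's global level rescaled by the latent myelin
#' content of each region plus regional measurement noise, so that with the
#' noise scales at zero each subject's regional profile is exactly
#' proportional to the planted regional myelin gradient.
#'
#' @param config a [sim_config()].
#' @param truth a [simulate_truth()] object from the same config.
#' @return a `data.frame` with columns `subject_id`, `age_protein`, `sex`,
#'   `egfr`, `mwf_global`, and one `mwf_region_<id>` column per atlas region.
#' @export
simulate_cohort <- function(config, truth = simulate_truth(config)) {
  stopifnot(inherits(config, "sim_config"), inherits(truth, "ground_truth"))
  set.seed(child_seed(config, "cohort"))
  n <- config$n_subjects
  age <- stats::runif(n, 22, 94)
  sex <- stats::rbinom(n, 1L, 0.56)
  egfr <- stats::rlnorm(n, log(75), 0.2)
  mwf_trend <- 0.22 - 2e-5 * (age - 45)^2
  mwf_true <- mwf_trend + stats::rnorm(n, 0, config$mwf_subject_sd)
  mwf_global <- mwf_true + stats::rnorm(n, 0, config$mwf_noise_sd)
  cohort <- data.frame(subject_id = sprintf("S%03d", seq_len(n)),
                       age_protein = age, sex = sex, egfr = egfr,
                       mwf_global = mwf_global, stringsAsFactors = FALSE)
  ref_myelin <- 0.5  # latent myelin level at which a region matches global MWF
  for (rid in names(truth$region_myelin)) {
    cohort[[paste0("mwf_region_", rid)]] <-
      (mwf_global / ref_myelin) * truth$region_myelin[[rid]] +
      stats::rnorm(n, 0, config$regional_noise_sd)
  }
  cohort
}

#' Synthetic aptamer-level plasma proteome
#'
#' Generates, for each aptamer, log2 abundance as an intercept plus the
#' planted gene effect times the cohort's standardized global MWF, plus
#' small random age/sex/eGFR nuisance loadings, plus Gaussian residual noise
#' of SD `protein_noise_sd`. Abundances are returned on the linear
#' (unlogged) scale, as an assay would deliver them. Null genes have a
#' planted effect of exactly zero.
#'
#' @param config a [sim_config()].
#' @param cohort a [simulate_cohort()] table from the same seed lineage.
#' @param truth the matching [simulate_truth()] object.
#' @return a `data.frame` with columns `aptamer_id`, `gene_symbol`, then one
#'   positive abundance column per subject (named by `subject_id`).
#' @export
simulate_proteome <- function(config, cohort, truth) {
  stopifnot(inherits(config, "sim_config"), inherits(truth, "ground_truth"))
  if (!is.data.frame(cohort) || nrow(cohort) != config$n_subjects)
    stop("input error: cohort does not match the configuration's n_subjects",
         call. = FALSE)
  set.seed(child_seed(config, "proteome"))
  n <- nrow(cohort)
  mwf <- cohort$mwf_global
  mwf_z <- (mwf - mean(mwf)) / stats::sd(mwf)
  beta <- stats::setNames(truth$genes$true_beta, truth$genes$gene_symbol)
  napt <- nrow(truth$aptamers)
  b0 <- stats::rnorm(napt, 10, 2)
  a_age <- stats::rnorm(napt, 0, 0.01)
  a_sex <- stats::rnorm(napt, 0, 0.3)
  a_egfr <- stats::rnorm(napt, 0, 0.005)
  log2a <- matrix(0, nrow = napt, ncol = n)
  for (j in seq_len(napt)) {
    bj <- beta[[truth$aptamers$gene_symbol[j]]]
    log2a[j, ] <- b0[j] + bj * mwf_z +
      a_age[j] * cohort$age_protein + a_sex[j] * cohort$sex +
      a_egfr[j] * cohort$egfr +
      stats::rnorm(n, 0, config$protein_noise_sd)
  }
  out <- data.frame(aptamer_id = truth$aptamers$aptamer_id,
                    gene_symbol = truth$aptamers$gene_symbol,
                    stringsAsFactors = FALSE)
  abun <- 2^log2a
  colnames(abun) <- cohort$subject_id
  cbind(out, as.data.frame(abun, optional = TRUE))
}

#' Synthetic gene-by-cell-type nTPM matrix
#'
#' Each gene gets a log-normal baseline shared across cell types; cell types
#' in the gene's planted enriched set receive an additive boost of
#' `ntpm_boost_log` on the log scale (~150-fold at the default), sized so
#' the geometric z-score of a boosted type exceeds 2 in expectation; each
#' entry then receives log-scale scatter of SD `ntpm_log_noise_sd`. All
#' values are strictly positive.
#'
#' @param config a [sim_config()].
#' @param truth the matching [simulate_truth()] object.
#' @return a wide `data.frame`: `gene_symbol` then one nTPM column per cell
#'   type.
#' @export
simulate_ntpm <- function(config, truth) {
  stopifnot(inherits(config, "sim_config"), inherits(truth, "ground_truth"))
  set.seed(child_seed(config, "ntpm"))
  genes <- truth$genes$gene_symbol
  types <- truth$cell_types$all_types
  base_log <- stats::rnorm(length(genes), 2, 1)
  m <- matrix(0, nrow = length(genes), ncol = length(types),
              dimnames = list(genes, types))
  for (i in seq_along(genes)) {
    boost <- as.numeric(types %in% truth$enriched_cells[[genes[i]]]) *
      config$ntpm_boost_log
    m[i, ] <- exp(base_log[i] + boost +
                    stats::rnorm(length(types), 0, config$ntpm_log_noise_sd))
  }
  cbind(data.frame(gene_symbol = genes, stringsAsFactors = FALSE),
        as.data.frame(m, optional = TRUE))
}

#' Synthetic GMT gene-set library with planted pathways
#'
#' Builds one library containing a pathway enriched for planted-positive
#' genes, a pathway enriched for planted-negative genes, and uniform decoy
#' sets drawn from the whole panel background.
#'
#' @param config a [sim_config()].
#' @param truth the matching [simulate_truth()] object.
#' @return a `gene_set_library` (see [read_gmt()]).
#' @export
simulate_genesets <- function(config, truth) {
  stopifnot(inherits(config, "sim_config"), inherits(truth, "ground_truth"))
  set.seed(child_seed(config, "genesets"))
  background <- truth$genes$gene_symbol
  beta <- stats::setNames(truth$genes$true_beta, background)
  pos <- background[beta > 0]
  neg <- background[beta < 0]
  size <- min(config$geneset_size, length(background))
  planted_members <- function(core) {
    n_core <- min(length(core), max(1L, ceiling(0.75 * size)))
    members <- sample(core, n_core)
    filler <- setdiff(background, members)
    if (n_core < size)
      members <- c(members, sample(filler, size - n_core))
    members
  }
  sets <- list()
  if (length(pos) > 0) sets[["myelination"]] <- planted_members(pos)
  if (length(neg) > 0)
    sets[["acute_inflammatory_response"]] <- planted_members(neg)
  for (i in seq_len(config$n_decoy_sets))
    sets[[sprintf("random_set_%02d", i)]] <- sample(background, size)
  gene_set_library(sets, library_name = "synthetic_pathways")
}

#' Run the full synthetic-study generator
#'
#' Convenience wrapper drawing every input the pipeline consumes from one
#' configuration: region table, label volume, ground truth, cohort,
#' proteome, nTPM matrix, gene-set library, and donor samples with their
#' probe table.
#'
#' @param config a [sim_config()].
#' @return a list of class `"mwf_simulation"` with elements `config`,
#'   `regions`, `labels`, `truth`, `cohort`, `proteome`, `ntpm`, `genesets`,
#'   `donor_samples`, `probes`.
#' @export
simulate_study <- function(config = sim_config()) {
  regions <- region_table(config)
  labels <- simulate_label_volume(config)
  truth <- simulate_truth(config, regions)
  cohort <- simulate_cohort(config, truth)
  proteome <- simulate_proteome(config, cohort, truth)
  ntpm <- simulate_ntpm(config, truth)
  genesets <- simulate_genesets(config, truth)
  donors <- simulate_donors(config, truth, labels, regions)
  out <- list(config = config, regions = regions, labels = labels,
              truth = truth, cohort = cohort, proteome = proteome,
              ntpm = ntpm, genesets = genesets,
              donor_samples = donors$samples, probes = donors$probes)
  class(out) <- "mwf_simulation"
  out
}
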