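#' Configuration for the synthetic multi-omics study generator
#'
#' Bundles every tunable of the synthetic-data generator into a validated
#' object. The defaults emulate, at desk scale, a cross-sectional aging cohort
#' with myelin water fraction (MWF) imaging, a SomaScan-like plasma proteome,
#' an HPA-like cell-type nTPM resource, GMT gene-set libraries, and an
#' AHBA-like multi-donor microarray sample set over white-matter and
#' deep-gray-matter atlas regions.
#'
#' @param seed integer master seed. Every component derives its own child
#'   seed from it by a fixed offset, so components are independently
#'   reproducible. Must be below `2^31 - 1000`.
#' @param n_subjects cohort size (default 85).
#' @param n_proteins number of aptamers on the synthetic panel (default 500;
#'   the full-scale resource has thousands, which is a config choice here,
#'   not a different code path).
#' @param n_cell_types number of cell types in the nTPM matrix (default 24,
#'   the scale of single-cell expression atlases). With z-scores taken across
#'   all cell types, the attainable z for a gene enriched in k of n types is
#'   bounded by `(1-k/n)*sqrt(n-1)/sqrt(k*(1-k/n)^2+(n-k)*k^2/n^2)`; at
#'   n = 10 this bound is 1.90 for k = 2, below the z >= 2 enrichment
#'   threshold, so small cell-type panels cannot represent multi-cell-type
#'   enrichment at all. n = 24 puts the k = 2 bound at 3.25.
#' @param frac_specific fraction of genes given a planted cell-type-specific
#'   expression pattern.
#' @param n_true_pos,n_true_neg numbers of genes with a planted positive /
#'   negative MWF association.
#' @param effect_size_sd magnitude of the planted standardized effect
#'   (log2-abundance residual SDs per MWF SD). `NULL` (default) sets it to
#'   3x the slope detectable at two-sided alpha = 0.05 with 80% power at
#'   `n_subjects`, i.e. `3*(qnorm(.975)+qnorm(.8))/sqrt(n_subjects)`.
#' @param n_regions_wm,n_regions_dgm numbers of white-matter and deep-gray
#'   atlas regions (defaults 6 + 6).
#' @param n_donors number of expression donors (default 6).
#' @param samples_per_donor tissue samples per donor (default 60).
#' @param probes_per_gene microarray probes per gene (default 4).
#' @param probe_noise_sd_stable,probe_noise_sd_unstable per-sample expression
#'   noise SD for the designated stable probe and for the remaining probes
#'   (defaults 0.1 and 0.5, a 1:5 ratio).
#' @param grid_shape integer length-3 voxel grid of the synthetic label
#'   volume.
#' @param voxel_size_mm isotropic voxel size in mm (> 0).
#' @param mwf_subject_sd between-subject biological SD of global MWF around
#'   its age trend. This is signal, not noise: it is what the planted plasma
#'   proteins respond to, and it is deliberately untouched by
#'   [zero_noise()].
#' @param mwf_noise_sd measurement noise SD added to global MWF.
#' @param regional_noise_sd measurement noise SD on regional MWF.
#' @param protein_noise_sd residual SD of log2 protein abundance (default 1;
#'   planted effects are expressed in units of this SD).
#' @param ntpm_log_noise_sd SD of log-normal scatter of nTPM across cell
#'   types.
#' @param ntpm_boost_log additive log-boost applied to a gene's nTPM in its
#'   planted enriched cell types (default 5, i.e. ~150-fold enrichment,
#'   the order of magnitude of canonical cell-type markers).
#' @param jitter_sd_mm per-axis Gaussian jitter of donor sample coordinates
#'   around labeled voxel centers (default 1.5 mm, so that some samples fall
#'   outside their region but within the 2 mm assignment tolerance and a few
#'   beyond it).
#' @param n_spatial_genes number of genes simulated in the donor microarray
#'   (default 3; the first is an MBP-like gene with the maximal regional
#'   expression slope).
#' @param n_decoy_sets number of decoy gene sets per library direction.
#' @param geneset_size nominal size of each synthetic gene set.
#'
#' @return an object of class `"sim_config"` (a validated named list).
#' @seealso [simulate_study()], [zero_noise()]
#' @export
sim_config <- function(seed = 1L,
                       n_subjects = 85L,
                       n_proteins = 500L,
                       n_cell_types = 24L,
                       frac_specific = 0.15,
                       n_true_pos = 25L,
                       n_true_neg = 25L,
                       effect_size_sd = NULL,
                       n_regions_wm = 6L,
                       n_regions_dgm = 6L,
                       n_donors = 6L,
                       samples_per_donor = 60L,
                       probes_per_gene = 4L,
                       probe_noise_sd_stable = 0.1,
                       probe_noise_sd_unstable = 0.5,
                       grid_shape = c(24L, 24L, 24L),
                       voxel_size_mm = 2,
                       mwf_subject_sd = 0.02,
                       mwf_noise_sd = 0.005,
                       regional_noise_sd = 0.01,
                       protein_noise_sd = 1,
                       ntpm_log_noise_sd = 0.5,
                       ntpm_boost_log = 5,
                       jitter_sd_mm = 1.5,
                       n_spatial_genes = 3L,
                       n_decoy_sets = 10L,
                       geneset_size = 20L) {
  counts <- list(n_subjects = n_subjects, n_proteins = n_proteins,
                 n_cell_types = n_cell_types, n_regions_wm = n_regions_wm,
                 n_regions_dgm = n_regions_dgm, n_donors = n_donors,
                 samples_per_donor = samples_per_donor,
                 probes_per_gene = probes_per_gene,
                 n_spatial_genes = n_spatial_genes,
                 n_decoy_sets = n_decoy_sets, geneset_size = geneset_size)
  for (nm in names(counts)) {
    v <- counts[[nm]]
    if (length(v) != 1L || !is.finite(v) || v < 1 || v != round(v))
      stop("configuration error: '", nm, "' must be a positive integer count",
           call. = FALSE)
  }
  if (length(seed) != 1L || !is.finite(seed) || seed != round(seed) ||
      abs(seed) >= 2^31 - 1000)
    stop("configuration error: 'seed' must be an integer below 2^31 - 1000",
         call. = FALSE)
  if (n_true_pos < 0 || n_true_neg < 0)
    stop("configuration error: planted counts must be non-negative",
         call. = FALSE)
  if (n_true_pos + n_true_neg > n_proteins)
    stop("configuration error: n_true_pos + n_true_neg exceeds n_proteins",
         call. = FALSE)
  if (frac_specific < 0 || frac_specific > 1)
    stop("configuration error: frac_specific must lie in [0, 1]",
         call. = FALSE)
  if (voxel_size_mm <= 0)
    stop("configuration error: voxel_size_mm must be positive", call. = FALSE)
  if (length(grid_shape) != 3L || any(grid_shape < 4))
    stop("configuration error: grid_shape must be 3 dimensions of >= 4 voxels",
         call. = FALSE)
  if (n_cell_types < 2)
    stop("configuration error: need at least 2 cell types", call. = FALSE)
  noise <- c(probe_noise_sd_stable = probe_noise_sd_stable,
             probe_noise_sd_unstable = probe_noise_sd_unstable,
             mwf_subject_sd = mwf_subject_sd, mwf_noise_sd = mwf_noise_sd,
             regional_noise_sd = regional_noise_sd,
             protein_noise_sd = protein_noise_sd,
             ntpm_log_noise_sd = ntpm_log_noise_sd,
             jitter_sd_mm = jitter_sd_mm)
  if (any(!is.finite(noise)) || any(noise < 0))
    stop("configuration error: noise scales must be finite and >= 0",
         call. = FALSE)
  if (is.null(effect_size_sd))
    effect_size_sd <- 3 * detectable_effect(n_subjects)
  cfg <- list(seed = as.integer(seed),
              n_subjects = as.integer(n_subjects),
              n_proteins = as.integer(n_proteins),
              n_cell_types = as.integer(n_cell_types),
              frac_specific = frac_specific,
              n_true_pos = as.integer(n_true_pos),
              n_true_neg = as.integer(n_true_neg),
              effect_size_sd = effect_size_sd,
              n_regions_wm = as.integer(n_regions_wm),
              n_regions_dgm = as.integer(n_regions_dgm),
              n_donors = as.integer(n_donors),
              samples_per_donor = as.integer(samples_per_donor),
              probes_per_gene = as.integer(probes_per_gene),
              probe_noise_sd_stable = probe_noise_sd_stable,
              probe_noise_sd_unstable = probe_noise_sd_unstable,
              grid_shape = as.integer(grid_shape),
              voxel_size_mm = voxel_size_mm,
              mwf_subject_sd = mwf_subject_sd,
              mwf_noise_sd = mwf_noise_sd,
              regional_noise_sd = regional_noise_sd,
              protein_noise_sd = protein_noise_sd,
              ntpm_log_noise_sd = ntpm_log_noise_sd,
              ntpm_boost_log = ntpm_boost_log,
              jitter_sd_mm = jitter_sd_mm,
              n_spatial_genes = as.integer(n_spatial_genes),
              n_decoy_sets = as.integer(n_decoy_sets),
              geneset_size = as.integer(geneset_size))
  class(cfg) <- "sim_config"
  cfg
}

#' Smallest detectable standardized regression slope
#'
#' Slope (in residual-SD per predictor-SD units) detectable at two-sided
#' significance level `alpha` with the requested power in a simple linear
#' regression with `n` observations, by the usual normal approximation
#' `(z_{1-alpha/2} + z_{power}) / sqrt(n)`.
#'
#' @param n sample size.
#' @param alpha two-sided significance level.
#' @param power target power.
#' @return the detectable standardized slope.
#' @export
detectable_effect <- function(n, alpha = 0.05, power = 0.8) {
  (stats::qnorm(1 - alpha / 2) + stats::qnorm(power)) / sqrt(n)
}

#' Switch off every measurement-noise scale of a simulation configuration
#'
#' Returns a copy of `config` with all measurement noise (protein residual,
#' MWF measurement, regional MWF, nTPM scatter, probe noise, coordinate
#' jitter) set to zero. The between-subject biological MWF deviation
#' (`mwf_subject_sd`) is kept: it is the signal the planted proteins track,
#' and without it covariate-adjusted regression on MWF is degenerate.
#'
#' @param config a [sim_config()] object.
#' @return a modified `sim_config`.
#' @export
zero_noise <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  config$mwf_noise_sd <- 0
  config$regional_noise_sd <- 0
  config$protein_noise_sd <- 0
  config$ntpm_log_noise_sd <- 0
  config$probe_noise_sd_stable <- 0
  config$probe_noise_sd_unstable <- 0
  config$jitter_sd_mm <- 0
  config
}

# fixed child-seed offsets: components are independently reproducible
child_seed <- function(config, component) {
  offsets <- c(truth = 101L, cohort = 202L, proteome = 303L, ntpm = 404L,
               donors = 505L, genesets = 606L)
  off <- offsets[[component]]
  as.integer(config$seed + off)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic multi-omics study configuration (seed ", x$seed, ")\n",
      sep = "")
  cat("  cohort:   ", x$n_subjects, " subjects\n", sep = "")
  cat("  proteome: ", x$n_proteins, " aptamers (",
      x$n_true_pos, " planted +, ", x$n_true_neg, " planted -, |beta| = ",
      signif(x$effect_size_sd, 3), " SD)\n", sep = "")
  cat("  nTPM:     ", x$n_cell_types, " cell types\n", sep = "")
  cat("  atlas:    ", x$n_regions_wm, " WM + ", x$n_regions_dgm,
      " DGM regions on a ", paste(x$grid_shape, collapse = "x"),
      " grid (", x$voxel_size_mm, " mm voxels)\n", sep = "")
  cat("  donors:   ", x$n_donors, " x ", x$samples_per_donor,
      " samples, ", x$probes_per_gene, " probes/gene\n", sep = "")
  invisible(x)
}
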