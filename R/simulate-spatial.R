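#' Region table for the synthetic atlas
#'
#' White-matter regions are named after major tracts and deep-gray regions
#' after subcortical structures; beyond the built-in names, generic labels
#' are generated. Region ids are consecutive positive integers, white matter
#' first.
#'
#' @param config a [sim_config()].
#' @return a `data.frame` with columns `region_id`, `name`, `tissue_class`
#'   (`"white_matter"` or `"deep_gray"`).
#' @export
region_table <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  wm_names <- c("corpus_callosum", "internal_capsule", "corona_radiata",
                "optic_radiation", "cingulum",
                "superior_longitudinal_fasciculus")
  dgm_names <- c("caudate", "putamen", "thalamus", "globus_pallidus",
                 "hippocampus", "amygdala")
  pick <- function(pool, k, prefix) {
    if (k <= length(pool)) pool[seq_len(k)]
    else c(pool, sprintf("%s_%02d", prefix, seq_len(k - length(pool))))
  }
  nw <- config$n_regions_wm
  nd <- config$n_regions_dgm
  data.frame(
    region_id = seq_len(nw + nd),
    name = c(pick(wm_names, nw, "wm_tract"), pick(dgm_names, nd, "dgm")),
    tissue_class = rep(c("white_matter", "deep_gray"), c(nw, nd)),
    stringsAsFactors = FALSE)
}

#' Construct a label volume object
#'
#' @param labels 3-D integer array; 0 is background, positive values are
#'   region ids.
#' @param affine invertible 4x4 voxel-index-to-mm transform. R's 1-based
#'   voxel index `(i, j, k)` maps to the mm center
#'   `affine %*% c(i-1, j-1, k-1, 1)`.
#' @return an object of class `"label_volume"`.
#' @export
label_volume <- function(labels, affine) {
  if (length(dim(labels)) != 3L || any(labels < 0))
    stop("input error: labels must be a 3-D array of non-negative integers",
         call. = FALSE)
  if (!is.matrix(affine) || any(dim(affine) != c(4L, 4L)) ||
      abs(det(affine)) < .Machine$double.eps)
    stop("input error: affine must be an invertible 4x4 matrix",
         call. = FALSE)
  structure(list(labels = labels, affine = affine), class = "label_volume")
}

#' Synthetic integer label volume
#'
#' Lays the configured regions out as disjoint 4-voxel axis-aligned cubes on
#' a regular lattice with 3-voxel gaps, inside a grid of the configured
#' shape. The geometry is deliberately simple: the downstream statistics
#' depend only on region membership, not on anatomical shape, while the
#' NIfTI affine handling stays fully real. The affine is a pure scaling by
#' the voxel size with the grid centered on the mm origin.
#'
#' @param config a [sim_config()].
#' @return a [label_volume()].
#' @export
simulate_label_volume <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  dims <- config$grid_shape
  box <- 4L; gap <- 3L
  slots <- pmax(0L, (dims - 2L * gap + gap) %/% (box + gap))
  n_regions <- config$n_regions_wm + config$n_regions_dgm
  if (prod(slots) < n_regions)
    stop("configuration error: grid_shape too small for ", n_regions,
         " regions (fits ", prod(slots), ")", call. = FALSE)
  origin_axis <- function(s) gap + 1L + (box + gap) * seq(0L, s - 1L)
  ox <- origin_axis(slots[1]); oy <- origin_axis(slots[2])
  oz <- origin_axis(slots[3])
  combos <- expand.grid(x = ox, y = oy, z = oz, KEEP.OUT.ATTRS = FALSE)
  labels <- array(0L, dims)
  for (r in seq_len(n_regions)) {
    o <- as.integer(combos[r, ])
    labels[o[1]:(o[1] + box - 1L), o[2]:(o[2] + box - 1L),
           o[3]:(o[3] + box - 1L)] <- r
  }
  vs <- config$voxel_size_mm
  affine <- diag(c(vs, vs, vs, 1))
  affine[1:3, 4] <- -vs * (dims - 1) / 2
  label_volume(labels, affine)
}

#' Synthetic multi-donor microarray samples over the label volume
#'
#' Each donor receives `samples_per_donor` samples cycled over the atlas
#' regions (so every region is covered), placed at a random labeled voxel
#' center of the region and jittered per axis by Gaussian noise of SD
#' `jitter_sd_mm` - the jitter deliberately pushes some samples slightly
#' outside their region and a few beyond the 2 mm assignment tolerance.
#' Probe expression is `offset_p + gain_p * slope_g * myelin(region)` plus
#' probe-specific Gaussian noise; the designated stable probe (the first
#' probe of each gene) uses `probe_noise_sd_stable`, all others
#' `probe_noise_sd_unstable`.
#'
#' @param config a [sim_config()].
#' @param truth the matching [simulate_truth()] object.
#' @param labels a [label_volume()] covering the configured regions.
#' @param regions the matching [region_table()].
#' @return a list with `samples` (data.frame: `donor_id`, `sample_id`,
#'   `mni_x`, `mni_y`, `mni_z`, `region_planted`, then one expression column
#'   per probe) and `probes` (data.frame: `probe_id`, `gene_symbol`).
#' @export
simulate_donors <- function(config, truth, labels,
                            regions = region_table(config)) {
  stopifnot(inherits(config, "sim_config"), inherits(truth, "ground_truth"),
            inherits(labels, "label_volume"))
  if (!any(labels$labels > 0))
    stop("input error: label volume contains no labeled voxels",
         call. = FALSE)
  set.seed(child_seed(config, "donors"))

  probes <- data.frame(
    probe_id = as.vector(t(outer(truth$spatial_genes$gene_symbol,
                                 paste0("_p", seq_len(config$probes_per_gene)),
                                 paste0))),
    gene_symbol = rep(truth$spatial_genes$gene_symbol,
                      each = config$probes_per_gene),
    stringsAsFactors = FALSE)
  np <- nrow(probes)
  gain <- stats::runif(np, 0.7, 1.3)
  offset <- stats::runif(np, 2, 6)
  slope <- stats::setNames(truth$spatial_genes$slope,
                           truth$spatial_genes$gene_symbol)
  stable <- probes$probe_id %in% truth$spatial_genes$stable_probe
  noise_sd <- ifelse(stable, config$probe_noise_sd_stable,
                     config$probe_noise_sd_unstable)

  lab_idx <- which(labels$labels > 0, arr.ind = TRUE)
  lab_region <- labels$labels[lab_idx]
  centers <- voxel_centers_mm(lab_idx, labels$affine)

  region_ids <- regions$region_id
  rows <- list()
  for (d in seq_len(config$n_donors)) {
    reg_seq <- rep_len(region_ids, config$samples_per_donor)
    for (s in seq_len(config$samples_per_donor)) {
      r <- reg_seq[s]
      cand <- which(lab_region == r)
      v <- cand[sample.int(length(cand), 1L)]
      xyz <- centers[v, ] + stats::rnorm(3, 0, config$jitter_sd_mm)
      expr <- offset + gain * slope[probes$gene_symbol] *
        truth$region_myelin[[as.character(r)]] +
        stats::rnorm(np, 0, noise_sd)
      rows[[length(rows) + 1L]] <- c(list(donor_id = sprintf("D%d", d),
                                          sample_id = sprintf("D%d_S%03d", d, s),
                                          mni_x = xyz[1], mni_y = xyz[2],
                                          mni_z = xyz[3],
                                          region_planted = r),
                                     as.list(stats::setNames(expr,
                                                             probes$probe_id)))
    }
  }
  samples <- do.call(rbind, lapply(rows, function(r)
    as.data.frame(r, stringsAsFactors = FALSE, optional = TRUE)))
  rownames(samples) <- NULL
  list(samples = samples, probes = probes)
}

# mm centers of (possibly many) 1-based voxel indices under an affine
voxel_centers_mm <- function(idx, affine) {
  idx <- matrix(idx, ncol = 3L)
  h <- cbind(idx - 1, 1)
  out <- h %*% t(affine)
  out[, 1:3, drop = FALSE]
}
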