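#' Assign donor samples to atlas regions by MNI coordinates
#'
#' A sample falling inside a labeled voxel (its nearest voxel under the
#' affine is labeled) takes that voxel's region. Otherwise it takes the
#' region of the nearest labeled voxel *center* if that Euclidean distance
#' in mm is at most `max_dist_mm`, else it stays unassigned. Distance ties
#' are broken by the smaller region id, then by lexicographic voxel index.
#' Distance is measured to voxel centers, not to an interpolated region
#' surface: simple, resolution-honest, and exhaustively checkable.
#'
#' @param samples a donor sample table with columns `sample_id`, `mni_x`,
#'   `mni_y`, `mni_z` (finite mm coordinates).
#' @param vol a [label_volume()].
#' @param regions the matching region table (used only to validate ids).
#' @param max_dist_mm assignment tolerance in mm (default 2).
#' @return `samples` with two added columns: `region_id` (`NA` when
#'   unassigned) and `dist_mm` (0 for in-voxel assignments).
#' @export
assign_samples <- function(samples, vol, regions, max_dist_mm = 2.0) {
  stopifnot(inherits(vol, "label_volume"))
  if (max_dist_mm < 0)
    stop("parameter error: max_dist_mm must be >= 0", call. = FALSE)
  xyz <- as.matrix(samples[, c("mni_x", "mni_y", "mni_z")])
  bad <- which(!apply(is.finite(xyz), 1L, all))
  if (length(bad) > 0L)
    stop("input error: non-finite coordinates for sample ",
         samples$sample_id[bad[1]], call. = FALSE)
  present <- sort(unique(vol$labels[vol$labels > 0]))
  if (!all(present %in% regions$region_id))
    stop("input error: label volume contains region id(s) missing from ",
         "the region table", call. = FALSE)

  lab_idx <- which(vol$labels > 0, arr.ind = TRUE)
  if (nrow(lab_idx) == 0L)
    stop("input error: label volume contains no labeled voxels",
         call. = FALSE)
  lab_region <- vol$labels[lab_idx]
  centers <- voxel_centers_mm(lab_idx, vol$affine)
  # canonical tie-break order: region id, then voxel index lexicographically
  ord <- order(lab_region, lab_idx[, 1], lab_idx[, 2], lab_idx[, 3])
  lab_idx <- lab_idx[ord, , drop = FALSE]
  lab_region <- lab_region[ord]
  centers <- centers[ord, , drop = FALSE]

  inv <- solve(vol$affine)
  vox <- cbind(xyz, 1) %*% t(inv)
  vox_round <- round(vox[, 1:3, drop = FALSE]) + 1  # back to 1-based indices
  dims <- dim(vol$labels)

  region_id <- rep(NA_integer_, nrow(samples))
  dist_mm <- rep(NA_real_, nrow(samples))
  for (s in seq_len(nrow(samples))) {
    v <- vox_round[s, ]
    if (all(v >= 1) && all(v <= dims)) {
      lab <- vol$labels[v[1], v[2], v[3]]
      if (lab > 0) {
        region_id[s] <- lab
        dist_mm[s] <- 0
        next
      }
    }
    d2 <- colSums((t(centers) - xyz[s, ])^2)
    jmin <- which.min(d2)  # centers are pre-sorted in tie-break order
    near <- which(d2 <= d2[jmin] + 1e-9)
    j <- near[1]
    d <- sqrt(d2[j])
    if (d <= max_dist_mm + 1e-12) {
      region_id[s] <- lab_region[j]
      dist_mm[s] <- d
    }
  }
  samples$region_id <- region_id
  samples$dist_mm <- dist_mm
  samples
}

#' Per-donor regional expression profiles of one probe
#'
#' Means the probe's expression over each donor's assigned samples within
#' each region. Regions without samples for a donor are absent from that
#' donor's profile; unassigned samples are ignored.
#'
#' @param assigned an [assign_samples()] table that also carries `donor_id`
#'   and one expression column per probe.
#' @param probe_id the probe column to aggregate.
#' @return a `data.frame` with `donor_id`, `region_id`, `mean_expr`.
#' @export
regional_profiles <- function(assigned, probe_id) {
  if (!probe_id %in% names(assigned))
    stop("input error: unknown probe '", probe_id, "'", call. = FALSE)
  keep <- !is.na(assigned$region_id)
  dat <- assigned[keep, , drop = FALSE]
  agg <- stats::aggregate(dat[[probe_id]],
                          by = list(donor_id = dat$donor_id,
                                    region_id = dat$region_id),
                          FUN = mean)
  names(agg)[3] <- "mean_expr"
  agg <- agg[order(agg$donor_id, agg$region_id), , drop = FALSE]
  rownames(agg) <- NULL
  agg
}

#' Differential stability and probe selection
#'
#' For each probe of a gene, computes the Spearman correlation (midranks for
#' ties) of its regional profile between every unordered donor pair, over
#' the regions present in both donors' profiles; the probe's differential
#' stability (DS) is the mean over pairs. Donor pairs with fewer than 3
#' common regions are skipped with a warning; a probe with no valid pair
#' gets `DS = NA` and is never selected. The probe with the highest DS is
#' selected, ties broken by probe id order.
#'
#' @param profiles long table `probe_id`, `donor_id`, `region_id`,
#'   `mean_expr` covering all probes of one gene (e.g. built by row-binding
#'   [regional_profiles()] per probe).
#' @return a list with `ds` (data.frame `probe_id`, `ds`, `n_pairs`) and
#'   `selected` (probe id).
#' @export
differential_stability <- function(profiles) {
  donors <- unique(profiles$donor_id)
  if (length(donors) < 2L)
    stop("undefined differential stability: need at least 2 donors",
         call. = FALSE)
  probe_ids <- sort(unique(profiles$probe_id))
  pairs <- utils::combn(sort(donors), 2L, simplify = FALSE)
  ds <- numeric(length(probe_ids))
  n_pairs <- integer(length(probe_ids))
  for (pi in seq_along(probe_ids)) {
    pp <- profiles[profiles$probe_id == probe_ids[pi], , drop = FALSE]
    rho <- c()
    for (pr in pairs) {
      a <- pp[pp$donor_id == pr[1], , drop = FALSE]
      b <- pp[pp$donor_id == pr[2], , drop = FALSE]
      common <- intersect(a$region_id, b$region_id)
      if (length(common) < 3L) {
        warning("differential_stability: donor pair ", pr[1], "/", pr[2],
                " has < 3 common regions for probe ", probe_ids[pi],
                "; skipped", call. = FALSE)
        next
      }
      va <- a$mean_expr[match(common, a$region_id)]
      vb <- b$mean_expr[match(common, b$region_id)]
      rho <- c(rho, stats::cor(va, vb, method = "spearman"))
    }
    ds[pi] <- if (length(rho) > 0) mean(rho) else NA_real_
    n_pairs[pi] <- length(rho)
  }
  tab <- data.frame(probe_id = probe_ids, ds = ds, n_pairs = n_pairs,
                    stringsAsFactors = FALSE)
  valid <- which(!is.na(ds))
  if (length(valid) == 0L)
    stop("undefined differential stability: no probe has a valid donor pair",
         call. = FALSE)
  selected <- probe_ids[valid[which.max(ds[valid])]]
  list(ds = tab, selected = selected)
}

#' Aggregate per-donor regional profiles across donors
#'
#' Unweighted mean of donor-level regional means: each donor counts once per
#' region regardless of how many samples contributed to its mean, so donors
#' with denser sampling do not dominate. Regions covered by no donor are
#' absent.
#'
#' @param profiles a `data.frame` with `donor_id`, `region_id`, `mean_expr`.
#' @return a named numeric vector: mean expression keyed by region id.
#' @export
aggregate_donors <- function(profiles) {
  if (nrow(profiles) == 0L)
    stop("input error: no donor profiles to aggregate", call. = FALSE)
  agg <- stats::aggregate(profiles$mean_expr,
                          by = list(region_id = profiles$region_id),
                          FUN = mean)
  stats::setNames(agg$x, as.character(agg$region_id))
}

#' Correlate regional expression with regional MWF
#'
#' Over the regions present in both inputs, fits ordinary least squares
#' with mean regional MWF as the dependent variable and mean regional
#' expression as the independent variable, and reports the signed Pearson
#' correlation with its two-sided p-value from
#' `t = r * sqrt((n-2)/(1-r^2))` on `n - 2` degrees of freedom. The
#' Spearman rank alternative is emitted alongside.
#'
#' @param regional_mwf named numeric: mean MWF per region id.
#' @param regional_mrna named numeric: mean expression per region id.
#' @param regions optional region table contributing `tissue_class` to the
#'   per-region output.
#' @return an object of class `"spatial_result"`: list with `r`, `p_value`,
#'   `slope`, `intercept`, `spearman_r`, `n_regions`, and `table`
#'   (region_id, mean_mwf, mean_mrna, and tissue_class when available).
#' @export
spatial_correlation <- function(regional_mwf, regional_mrna,
                                regions = NULL) {
  common <- intersect(names(regional_mwf), names(regional_mrna))
  n <- length(common)
  if (n < 3L)
    stop("insufficient regions: need >= 3 common regions, have ", n,
         call. = FALSE)
  y <- as.numeric(regional_mwf[common])
  x <- as.numeric(regional_mrna[common])
  if (stats::sd(y) == 0 || stats::sd(x) == 0)
    stop("degenerate input: zero variance on one axis", call. = FALSE)
  r <- stats::cor(x, y)
  slope <- r * stats::sd(y) / stats::sd(x)
  intercept <- mean(y) - slope * mean(x)
  p <- if (abs(r) >= 1) 0 else {
    tt <- r * sqrt((n - 2) / (1 - r^2))
    2 * stats::pt(-abs(tt), n - 2)
  }
  tab <- data.frame(region_id = common, mean_mwf = y, mean_mrna = x,
                    stringsAsFactors = FALSE)
  if (!is.null(regions))
    tab$tissue_class <-
      regions$tissue_class[match(as.integer(common), regions$region_id)]
  structure(list(r = r, p_value = p, slope = slope, intercept = intercept,
                 spearman_r = stats::cor(x, y, method = "spearman"),
                 n_regions = n, table = tab),
            class = "spatial_result")
}

#' @export
print.spatial_result <- function(x, ...) {
  cat("Regional expression-MWF correlation over ", x$n_regions,
      " regions\n", sep = "")
  cat(sprintf("  Pearson r = %.3f (p = %.4g), Spearman r = %.3f\n",
              x$r, x$p_value, x$spearman_r))
  cat(sprintf("  MWF = %.4g + %.4g * expression\n", x$intercept, x$slope))
  invisible(x)
}
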