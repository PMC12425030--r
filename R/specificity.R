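#' Cell-type vocabulary
#'
#' Defines which cell types count as brain-related for enrichment calls and
#' which of those form the oligodendrocyte lineage. Only brain-related types
#' can enter a gene's enriched set, but *all* types participate in the
#' z-score normalization.
#'
#' @param all_types character vector of every cell type in the nTPM matrix.
#' @param brain_related subset of `all_types` treated as brain cell types.
#' @param oligo_lineage subset of `brain_related` forming the oligodendrocyte
#'   lineage (oligodendrocytes and their precursors).
#' @return an object of class `"cell_type_vocabulary"`.
#' @export
cell_type_vocabulary <- function(all_types, brain_related, oligo_lineage) {
  if (!all(brain_related %in% all_types))
    stop("input error: brain_related must be a subset of all_types",
         call. = FALSE)
  if (!all(oligo_lineage %in% brain_related))
    stop("input error: oligo_lineage must be a subset of brain_related",
         call. = FALSE)
  structure(list(all_types = all_types, brain_related = brain_related,
                 oligo_lineage = oligo_lineage),
            class = "cell_type_vocabulary")
}

#' Default cell-type vocabulary
#'
#' Seven brain-related types (oligodendrocyte, OPC, astrocyte, microglia,
#' excitatory and inhibitory neurons, endothelial) followed by common
#' peripheral cell types, up to `n` types in total; beyond the built-in 24,
#' generic non-brain labels are appended. The brain-related list is a
#' defensible default, not a canonical standard - override it via
#' [cell_type_vocabulary()] when a real resource defines its own.
#'
#' @param n total number of cell types (>= 2).
#' @return a [cell_type_vocabulary()].
#' @export
default_vocabulary <- function(n = 24L) {
  brain <- c("oligodendrocyte", "OPC", "astrocyte", "microglia",
             "excitatory_neuron", "inhibitory_neuron", "endothelial")
  periph <- c("hepatocyte", "cardiomyocyte", "adipocyte", "keratinocyte",
              "enterocyte", "fibroblast", "t_cell", "b_cell", "nk_cell",
              "monocyte", "plasma_cell", "erythroid_cell",
              "pancreatic_beta_cell", "alveolar_cell", "podocyte",
              "melanocyte", "skeletal_myocyte")
  pool <- c(brain, periph)
  all_types <- if (n <= length(pool)) pool[seq_len(n)]
               else c(pool, sprintf("cell_type_%02d",
                                    seq_len(n - length(pool))))
  cell_type_vocabulary(all_types,
                       brain_related = intersect(brain, all_types),
                       oligo_lineage = intersect(c("oligodendrocyte", "OPC"),
                                                 all_types))
}

#' Geometric-mean z-scores of an expression profile
#'
#' Standardizes a gene's nTPM values across cell types using the geometric
#' mean and geometric standard deviation: values are shifted by a
#' pseudocount `eps`, logged (natural log; the z-scores are base-invariant),
#' and z-scored with the sample (n-1) standard deviation. A profile with
#' zero log-scale spread returns all-zero z-scores (degenerate, not an
#' error).
#'
#' @param x non-negative nTPM values across cell types (length >= 2),
#'   optionally named.
#' @param eps pseudocount added before logging (default 0.1 nTPM, small
#'   relative to the conventional 1 nTPM detection cutoff).
#' @return numeric z-scores, same length and names as `x`.
#' @export
geometric_zscores <- function(x, eps = 0.1) {
  if (length(x) < 2L)
    stop("input error: need at least 2 cell types", call. = FALSE)
  if (any(!is.finite(x)) || any(x < 0))
    stop("input error: nTPM values must be finite and >= 0", call. = FALSE)
  l <- log(x + eps)
  s <- stats::sd(l)
  if (s == 0) return(stats::setNames(rep(0, length(x)), names(x)))
  (l - mean(l)) / s
}

#' Classify a z-score profile into a cell-specificity category
#'
#' A gene's enriched set is the brain-related cell types with z-score at or
#' above `z_threshold` (ties at exactly the threshold count as enriched);
#' non-brain types never enter the set regardless of their z. Categories:
#' `none` (empty set), `single` (one type), `oligoMultiCell` (two or more
#' types including an oligodendrocyte-lineage member), `multiCell` (two or
#' more, none oligo-lineage).
#'
#' @param z named numeric z-scores covering all vocabulary types.
#' @param vocab a [cell_type_vocabulary()].
#' @param z_threshold enrichment threshold (default 2).
#' @return a list with `enriched` (character vector), `category`, and
#'   `single_type` (the enriched type when `category == "single"`, else
#'   `NA`).
#' @export
classify_specificity <- function(z, vocab, z_threshold = 2) {
  stopifnot(inherits(vocab, "cell_type_vocabulary"))
  if (!all(vocab$all_types %in% names(z)))
    stop("input error: z must cover every vocabulary cell type",
         call. = FALSE)
  enriched <- vocab$brain_related[z[vocab$brain_related] >= z_threshold]
  category <- if (length(enriched) == 0L) "none"
    else if (length(enriched) == 1L) "single"
    else if (length(intersect(enriched, vocab$oligo_lineage)) > 0L)
      "oligoMultiCell"
    else "multiCell"
  list(enriched = enriched, category = category,
       single_type = if (category == "single") enriched else NA_character_)
}

#' Specificity calls for every gene of an nTPM matrix
#'
#' Applies [geometric_zscores()] and [classify_specificity()] row-wise.
#'
#' @param ntpm wide nTPM table: `gene_symbol` plus one column per cell type.
#' @param vocab a [cell_type_vocabulary()]; its `all_types` must all be
#'   columns of `ntpm`.
#' @param z_threshold enrichment threshold (default 2).
#' @param eps pseudocount for [geometric_zscores()].
#' @return a `data.frame` with `gene_symbol`, `category`, `enriched_types`
#'   (semicolon-joined), `single_type`, and one `z_<type>` column per cell
#'   type.
#' @export
specificity_calls <- function(ntpm, vocab = NULL, z_threshold = 2,
                              eps = 0.1) {
  types <- setdiff(names(ntpm), "gene_symbol")
  if (is.null(vocab)) {
    brain <- intersect(default_vocabulary(24L)$brain_related, types)
    vocab <- cell_type_vocabulary(types, brain,
                                  intersect(c("oligodendrocyte", "OPC"),
                                            brain))
  }
  if (!all(vocab$all_types %in% types))
    stop("input error: nTPM table lacks column(s) ",
         paste(setdiff(vocab$all_types, types), collapse = ", "),
         call. = FALSE)
  m <- as.matrix(ntpm[, vocab$all_types, drop = FALSE])
  zs <- t(apply(m, 1L, geometric_zscores, eps = eps))
  colnames(zs) <- vocab$all_types
  calls <- apply(zs, 1L, classify_specificity, vocab = vocab,
                 z_threshold = z_threshold)
  out <- data.frame(
    gene_symbol = ntpm$gene_symbol,
    category = vapply(calls, `[[`, "", "category"),
    enriched_types = vapply(calls, function(cl)
      paste(cl$enriched, collapse = ";"), ""),
    single_type = vapply(calls, `[[`, "", "single_type"),
    stringsAsFactors = FALSE)
  zdf <- as.data.frame(zs, optional = TRUE)
  names(zdf) <- paste0("z_", vocab$all_types)
  cbind(out, zdf)
}

#' Annotate scan records with cell-specificity categories
#'
#' Joins specificity calls onto the association records by gene symbol and
#' summarizes the significant hits: how many distinct hit genes are
#' cell-specific at all, and how many involve the oligodendrocyte lineage
#' (a single oligo/OPC call or an oligoMultiCell call). Significant genes
#' absent from the nTPM matrix are categorized `unannotated` and excluded
#' from the cell-specific denominator.
#'
#' @param records a scan table from [run_scan()].
#' @param calls a [specificity_calls()] table.
#' @param vocab the [cell_type_vocabulary()] used for the calls.
#' @param alpha significance threshold defining "hit" (default 0.05).
#' @return a list with `table` (records plus `category`, `enriched_types`)
#'   and `summary` (named counts: `n_hit_genes`, `n_unannotated`,
#'   `n_cell_specific`, `n_oligo_involved`).
#' @export
annotate_scan <- function(records, calls, vocab, alpha = 0.05) {
  check_alpha(alpha)
  idx <- match(records$gene_symbol, calls$gene_symbol)
  category <- ifelse(is.na(idx), "unannotated", calls$category[idx])
  enriched <- ifelse(is.na(idx), "", calls$enriched_types[idx])
  single <- ifelse(is.na(idx), NA_character_, calls$single_type[idx])
  tab <- cbind(records,
               data.frame(category = category, enriched_types = enriched,
                          stringsAsFactors = FALSE))
  hit <- !is.na(records$p_value) & records$p_value < alpha &
    records$direction != "null"
  # gene-level view of the hits
  hit_genes <- unique(records$gene_symbol[hit])
  gi <- match(hit_genes, records$gene_symbol)
  gcat <- category[gi]
  gsingle <- single[gi]
  oligo_involved <- gcat == "oligoMultiCell" |
    (gcat == "single" & !is.na(gsingle) & gsingle %in% vocab$oligo_lineage)
  summary <- c(n_hit_genes = length(hit_genes),
               n_unannotated = sum(gcat == "unannotated"),
               n_cell_specific = sum(!gcat %in% c("none", "unannotated")),
               n_oligo_involved = sum(oligo_involved))
  list(table = tab, summary = summary)
}
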