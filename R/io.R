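#' @name io
#' @title Readers and writers for the pipeline's file formats
#'
#' @description Plain-text interchange: cohort CSV, aptamer-by-subject
#' protein CSV, wide or long nTPM TSV, GMT gene-set libraries, NIfTI label
#' volumes (int16, affine honored), region / donor-sample / probe TSVs,
#' vocabulary YAML, and ground-truth JSON. All writers emit full-precision
#' numbers and deterministic output for identical inputs.
NULL

#' @rdname io
#' @param cohort,path see individual functions.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname io
#' @export
read_cohort <- function(path) {
  cohort <- utils::read.csv(path, stringsAsFactors = FALSE,
                            check.names = FALSE)
  need <- c("subject_id", "age_protein", "sex", "egfr", "mwf_global")
  if (!all(need %in% names(cohort)))
    stop("input error: cohort file lacks column(s) ",
         paste(setdiff(need, names(cohort)), collapse = ", "),
         call. = FALSE)
  cohort
}

#' @rdname io
#' @param proteins aptamer-by-subject table.
#' @export
write_protein_matrix <- function(proteins, path) {
  utils::write.csv(proteins, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname io
#' @export
read_protein_matrix <- function(path) {
  m <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!all(c("aptamer_id", "gene_symbol") %in% names(m)[1:2]))
    stop("input error: protein matrix must start with aptamer_id, ",
         "gene_symbol columns", call. = FALSE)
  m
}

#' @rdname io
#' @param ntpm wide nTPM table.
#' @export
write_ntpm <- function(ntpm, path) {
  utils::write.table(ntpm, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname io
#' @details `read_ntpm` accepts the wide layout (`gene_symbol` plus one
#'   column per cell type) or the long layout (`gene_symbol`, `cell_type`,
#'   `ntpm`), which it reshapes to wide.
#' @export
read_ntpm <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (all(c("gene_symbol", "cell_type", "ntpm") %in% names(x))) {
    wide <- stats::reshape(x[, c("gene_symbol", "cell_type", "ntpm")],
                           idvar = "gene_symbol", timevar = "cell_type",
                           direction = "wide")
    names(wide) <- sub("^ntpm\\.", "", names(wide))
    rownames(wide) <- NULL
    attr(wide, "reshapeWide") <- NULL
    return(wide)
  }
  if (!"gene_symbol" %in% names(x))
    stop("input error: nTPM file lacks a gene_symbol column", call. = FALSE)
  x
}

#' @rdname io
#' @param library a [gene_set_library()].
#' @export
write_gmt <- function(library, path) {
  stopifnot(inherits(library, "gene_set_library"))
  lines <- vapply(names(library$sets), function(sn)
    paste(c(sn, library$library_name, library$sets[[sn]]), collapse = "\t"),
    "")
  writeLines(lines, path)
  invisible(path)
}

#' @rdname io
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(fields) < 3L
  if (any(bad))
    stop("input error: GMT line(s) without members: ",
         paste(which(bad), collapse = ", "), call. = FALSE)
  sets <- lapply(fields, function(f) f[-(1:2)])
  names(sets) <- vapply(fields, `[[`, "", 1L)
  gene_set_library(sets,
                   library_name = sub("\\.gmt$", "", basename(path)))
}

#' @rdname io
#' @param vol a [label_volume()].
#' @details Label volumes are written as uncompressed int16 NIfTI-1 with the
#'   affine stored in both sform and qform.
#' @export
write_label_volume <- function(vol, path) {
  stopifnot(inherits(vol, "label_volume"))
  img <- RNifti::asNifti(vol$labels, datatype = "int16")
  RNifti::sform(img) <- structure(vol$affine, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname io
#' @export
read_label_volume <- function(path) {
  img <- RNifti::readNifti(path)
  aff <- unclass(RNifti::xform(img))
  attributes(aff) <- list(dim = c(4L, 4L))
  label_volume(array(as.integer(img), dim(img)), aff)
}

#' @rdname io
#' @param regions a region table.
#' @export
write_region_table <- function(regions, path) {
  utils::write.table(regions, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname io
#' @export
read_region_table <- function(path) {
  regions <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("region_id", "name", "tissue_class")
  if (!all(need %in% names(regions)))
    stop("input error: region table lacks column(s) ",
         paste(setdiff(need, names(regions)), collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(regions$region_id) || any(regions$region_id <= 0))
    stop("input error: region ids must be unique and > 0", call. = FALSE)
  regions
}

#' @rdname io
#' @param samples a donor sample table.
#' @export
write_donor_samples <- function(samples, path) {
  utils::write.table(samples, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname io
#' @export
read_donor_samples <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}

#' @rdname io
#' @param probes a probe table.
#' @export
write_probe_table <- function(probes, path) {
  utils::write.table(probes, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname io
#' @export
read_probe_table <- function(path) {
  probes <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("probe_id", "gene_symbol") %in% names(probes)))
    stop("input error: probe table needs probe_id, gene_symbol columns",
         call. = FALSE)
  if (anyDuplicated(probes$probe_id))
    stop("input error: probe ids must be unique", call. = FALSE)
  probes
}

#' @rdname io
#' @param vocab a [cell_type_vocabulary()].
#' @export
write_vocabulary <- function(vocab, path) {
  stopifnot(inherits(vocab, "cell_type_vocabulary"))
  yaml::write_yaml(unclass(vocab), path)
  invisible(path)
}

#' @rdname io
#' @export
read_vocabulary <- function(path) {
  v <- yaml::read_yaml(path)
  cell_type_vocabulary(unlist(v$all_types), unlist(v$brain_related),
                       unlist(v$oligo_lineage))
}

#' @rdname io
#' @param truth a [simulate_truth()] object.
#' @export
write_ground_truth <- function(truth, path) {
  stopifnot(inherits(truth, "ground_truth"))
  obj <- list(aptamers = truth$aptamers,
              genes = truth$genes,
              enriched_cells = truth$enriched_cells,
              cell_types = unclass(truth$cell_types),
              pathways = truth$pathways,
              region_myelin = as.list(truth$region_myelin),
              spatial_genes = truth$spatial_genes)
  jsonlite::write_json(obj, path, auto_unbox = FALSE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Write every synthetic input to a directory
#'
#' Materializes a [simulate_study()] result in the pipeline's interchange
#' formats: `cohort.csv`, `proteins.csv`, `ntpm.tsv`,
#' `synthetic_pathways.gmt`, `atlas_labels.nii`, `regions.tsv`,
#' `donor_samples.tsv`, `probes.tsv`, `vocabulary.yaml`,
#' `ground_truth.json`.
#'
#' @param sim a [simulate_study()] result.
#' @param dir output directory (created if missing).
#' @return invisibly, a named vector of file paths.
#' @export
write_simulated_inputs <- function(sim, dir) {
  stopifnot(inherits(sim, "mwf_simulation"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(dir, f)
  write_cohort(sim$cohort, p("cohort.csv"))
  write_protein_matrix(sim$proteome, p("proteins.csv"))
  write_ntpm(sim$ntpm, p("ntpm.tsv"))
  write_gmt(sim$genesets, p("synthetic_pathways.gmt"))
  write_label_volume(sim$labels, p("atlas_labels.nii"))
  write_region_table(sim$regions, p("regions.tsv"))
  write_donor_samples(sim$donor_samples, p("donor_samples.tsv"))
  write_probe_table(sim$probes, p("probes.tsv"))
  write_vocabulary(sim$truth$cell_types, p("vocabulary.yaml"))
  write_ground_truth(sim$truth, p("ground_truth.json"))
  invisible(c(cohort = p("cohort.csv"), proteins = p("proteins.csv"),
              ntpm = p("ntpm.tsv"), gmt = p("synthetic_pathways.gmt"),
              labels = p("atlas_labels.nii"), regions = p("regions.tsv"),
              donor_samples = p("donor_samples.tsv"),
              probes = p("probes.tsv"), vocabulary = p("vocabulary.yaml"),
              ground_truth = p("ground_truth.json")))
}
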