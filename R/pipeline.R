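#' Pipeline run configuration
#'
#' Collects every knob of [run_pipeline()]: stage toggles, input paths,
#' thresholds, and the seed all randomness flows from. Thresholds default to
#' the analysis constants of the validation design: unadjusted p < 0.05 for
#' hits, z >= 2 for cell-type enrichment, 2 mm for sample-to-region
#' assignment, and at most 5 reported pathways per library.
#'
#' @param out_dir output directory.
#' @param seed integer seed; the only entropy source of a run.
#' @param stages character subset of
#'   `c("simulate", "associate", "annotate", "enrich", "spatial")`.
#' @param alpha significance threshold in (0, 1).
#' @param max_dist_mm sample-assignment tolerance in mm.
#' @param z_threshold cell-type enrichment z threshold.
#' @param top_k_report maximum reported pathways per library.
#' @param mwf_field MWF selector for the scan (`"global"` or
#'   `"region:<id>"`).
#' @param swap_direction regress log2 abundance on MWF instead (see
#'   [run_scan()]).
#' @param spatial_gene gene whose probes enter the spatial stage (default
#'   `"MBP"`).
#' @param background optional explicit background gene universe for
#'   enrichment; default is every gene on the protein panel.
#' @param sim named list of overrides passed to [sim_config()] when the
#'   simulate stage is enabled.
#' @param inputs named list of input paths (`cohort`, `proteins`, `ntpm`,
#'   `gmt`, `labels`, `regions`, `donor_samples`, `probes`, `vocabulary`);
#'   filled in automatically by the simulate stage.
#' @return an object of class `"run_config"`.
#' @export
run_config <- function(out_dir,
                       seed = 1L,
                       stages = c("simulate", "associate", "annotate",
                                  "enrich", "spatial"),
                       alpha = 0.05,
                       max_dist_mm = 2.0,
                       z_threshold = 2.0,
                       top_k_report = 5L,
                       mwf_field = "global",
                       swap_direction = FALSE,
                       spatial_gene = "MBP",
                       background = NULL,
                       sim = list(),
                       inputs = list()) {
  all_stages <- c("simulate", "associate", "annotate", "enrich", "spatial")
  if (!all(stages %in% all_stages))
    stop("config schema violation: unknown stage(s) ",
         paste(setdiff(stages, all_stages), collapse = ", "), call. = FALSE)
  check_alpha(alpha)
  if (max_dist_mm < 0)
    stop("config schema violation: max_dist_mm must be >= 0", call. = FALSE)
  if (z_threshold <= 0)
    stop("config schema violation: z_threshold must be positive",
         call. = FALSE)
  if (top_k_report < 0)
    stop("config schema violation: top_k_report must be >= 0", call. = FALSE)
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 stages = stages, alpha = alpha, max_dist_mm = max_dist_mm,
                 z_threshold = z_threshold,
                 top_k_report = as.integer(top_k_report),
                 mwf_field = mwf_field, swap_direction = swap_direction,
                 spatial_gene = spatial_gene, background = background,
                 sim = sim, inputs = inputs),
            class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' Keys mirror the arguments of [run_config()]; missing keys take the
#' defaults.
#'
#' @param path YAML file.
#' @param ... overrides applied on top of the file (e.g. from CLI flags).
#' @return a [run_config()].
#' @export
read_run_config <- function(path, ...) {
  y <- yaml::read_yaml(path)
  over <- list(...)
  y[names(over)] <- over
  known <- names(formals(run_config))
  unknown <- setdiff(names(y), known)
  if (length(unknown) > 0)
    stop("config schema violation: unknown field(s) ",
         paste(unknown, collapse = ", "), call. = FALSE)
  do.call(run_config, y)
}

log_line <- function(stage, msg, logfile = NULL) {
  line <- sprintf("[%s] [%s] %s",
                  format(Sys.time(), "%Y-%m-%d %H:%M:%S"), stage, msg)
  message(line)
  if (!is.null(logfile)) cat(line, "\n", file = logfile, append = TRUE,
                             sep = "")
  invisible(NULL)
}

#' Run the multi-omics MWF validation pipeline
#'
#' Executes the enabled stages in order: `simulate` (generate and write
#' every synthetic input), `associate` (proteome-wide covariate-adjusted
#' scan and hit lists), `annotate` (cell-type specificity of the hits),
#' `enrich` (Fisher over-representation of the positive and negative
#' lists), `spatial` (probe selection by differential stability, sample
#' assignment, donor aggregation, regional correlation). A failure in the
#' proteomic branch does not abort the transcriptomic branch, and vice
#' versa; failed stages are recorded in the summary.
#'
#' Output tables carry no timestamps, so re-running with the same config
#' and inputs reproduces them byte for byte; wall-clock information goes to
#' `run.log` only.
#'
#' @param config a [run_config()].
#' @return an object of class `"run_summary"`: per-stage status, headline
#'   counts, input checksums, the config echo, and the package version.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  logfile <- file.path(out, "run.log")
  cat("", file = logfile)
  status <- stats::setNames(
    rep("skipped", 5L),
    c("simulate", "associate", "annotate", "enrich", "spatial"))
  counts <- list()
  inputs <- config$inputs

  if ("simulate" %in% config$stages) {
    log_line("simulate", paste0("generating synthetic study (seed ",
                                config$seed, ")"), logfile)
    sim_args <- config$sim
    sim_args$seed <- config$seed
    sim <- simulate_study(do.call(sim_config, sim_args))
    paths <- write_simulated_inputs(sim, file.path(out, "inputs"))
    inputs <- utils::modifyList(as.list(paths), inputs)
    status["simulate"] <- "ok"
    log_line("simulate", "inputs written", logfile)
  }

  need <- function(keys, stage) {
    missing <- keys[!vapply(keys, function(k)
      !is.null(inputs[[k]]) && file.exists(inputs[[k]]), TRUE)]
    if (length(missing) > 0)
      stop(stage, ": missing input(s) ", paste(missing, collapse = ", "),
           call. = FALSE)
  }

  records <- NULL
  hits <- NULL
  proteomic <- tryCatch({
    if ("associate" %in% config$stages) {
      need(c("cohort", "proteins"), "associate")
      log_line("associate", "running proteome-wide scan", logfile)
      cohort <- read_cohort(inputs$cohort)
      proteins <- read_protein_matrix(inputs$proteins)
      records <- run_scan(cohort, proteins, mwf_field = config$mwf_field,
                           alpha = config$alpha,
                           swap_direction = config$swap_direction)
      utils::write.table(records, file.path(out, "association_scan.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
      volcano <- data.frame(aptamer_id = records$aptamer_id,
                            gene_symbol = records$gene_symbol,
                            beta = records$beta,
                            neg_log10_p = -log10(records$p_value),
                            direction = records$direction)
      utils::write.table(volcano, file.path(out, "volcano.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
      hits <- split_significant(records, alpha = config$alpha)
      writeLines(hits$positive, file.path(out, "hits_positive.txt"))
      writeLines(hits$negative, file.path(out, "hits_negative.txt"))
      counts$n_hits_positive <- hits$n_positive
      counts$n_hits_negative <- hits$n_negative
      status["associate"] <- "ok"
      log_line("associate", paste0(hits$n_positive, " positive / ",
                                   hits$n_negative, " negative hit genes"),
               logfile)
    }
    if ("annotate" %in% config$stages) {
      if (is.null(records))
        stop("annotate: requires the associate stage", call. = FALSE)
      need("ntpm", "annotate")
      log_line("annotate", "classifying cell-type specificity", logfile)
      ntpm <- read_ntpm(inputs$ntpm)
      vocab <- if (!is.null(inputs$vocabulary) &&
                   file.exists(inputs$vocabulary))
        read_vocabulary(inputs$vocabulary)
      else NULL
      calls <- specificity_calls(ntpm, vocab,
                                 z_threshold = config$z_threshold)
      if (is.null(vocab)) {
        types <- setdiff(names(ntpm), "gene_symbol")
        brain <- intersect(default_vocabulary(24L)$brain_related, types)
        vocab <- cell_type_vocabulary(types, brain,
                                      intersect(c("oligodendrocyte", "OPC"),
                                                brain))
      }
      ann <- annotate_scan(records, calls, vocab, alpha = config$alpha)
      utils::write.table(calls, file.path(out, "specificity_calls.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
      utils::write.table(ann$table, file.path(out, "annotated_scan.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
      counts$n_cell_specific <- unname(ann$summary[["n_cell_specific"]])
      counts$n_oligo_involved <- unname(ann$summary[["n_oligo_involved"]])
      status["annotate"] <- "ok"
      log_line("annotate",
               paste0(counts$n_cell_specific, " cell-specific hits, ",
                      counts$n_oligo_involved, " oligo-lineage involved"),
               logfile)
    }
    if ("enrich" %in% config$stages) {
      if (is.null(hits))
        stop("enrich: requires the associate stage", call. = FALSE)
      need(c("gmt", "proteins"), "enrich")
      log_line("enrich", "running over-representation analysis", logfile)
      lib <- read_gmt(inputs$gmt)
      background <- config$background
      if (is.null(background))
        background <- unique(read_protein_matrix(inputs$proteins)$gene_symbol)
      reported <- list()
      for (dir_name in c("positive", "negative")) {
        res <- run_enrichment(hits[[dir_name]], lib, background)
        res <- report_top(res, alpha = config$alpha,
                          top_k = config$top_k_report)
        utils::write.table(res,
                           file.path(out, paste0("enrichment_", dir_name,
                                                 ".tsv")),
                           sep = "\t", row.names = FALSE, quote = FALSE)
        if (nrow(res) > 0 && any(res$reported)) {
          rep_rows <- res[res$reported, , drop = FALSE]
          rep_rows$direction <- dir_name
          reported[[dir_name]] <- rep_rows
        }
        counts[[paste0("n_reported_", dir_name)]] <-
          if (nrow(res) > 0) sum(res$reported) else 0L
      }
      combined <- if (length(reported) > 0) do.call(rbind, reported)
        else data.frame()
      utils::write.table(combined, file.path(out, "reported_pathways.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
      status["enrich"] <- "ok"
      log_line("enrich", paste0(counts$n_reported_positive, " + ",
                                counts$n_reported_negative,
                                " reported pathways"), logfile)
    }
    TRUE
  }, error = function(e) {
    log_line("proteomic-branch", paste("FAILED:", conditionMessage(e)),
             logfile)
    failed <- intersect(config$stages,
                        c("associate", "annotate", "enrich"))
    status[failed[status[failed] == "skipped"]] <<- "failed"
    e
  })

  spatial_res <- NULL
  transcriptomic <- tryCatch({
    if ("spatial" %in% config$stages) {
      need(c("labels", "regions", "donor_samples", "probes", "cohort"),
           "spatial")
      log_line("spatial", "assigning samples and selecting probes", logfile)
      vol <- read_label_volume(inputs$labels)
      regions <- read_region_table(inputs$regions)
      samples <- read_donor_samples(inputs$donor_samples)
      probes <- read_probe_table(inputs$probes)
      cohort <- read_cohort(inputs$cohort)
      assigned <- assign_samples(samples, vol, regions,
                                 max_dist_mm = config$max_dist_mm)
      utils::write.table(
        assigned[, c("donor_id", "sample_id", "mni_x", "mni_y", "mni_z",
                     "region_id", "dist_mm")],
        file.path(out, "assignment.tsv"), sep = "\t", row.names = FALSE,
        quote = FALSE)
      gene_probes <- probes$probe_id[probes$gene_symbol ==
                                       config$spatial_gene]
      if (length(gene_probes) == 0L)
        stop("spatial: no probes for gene ", config$spatial_gene,
             call. = FALSE)
      profiles <- do.call(rbind, lapply(gene_probes, function(p) {
        pr <- regional_profiles(assigned, p)
        pr$probe_id <- p
        pr
      }))
      ds <- differential_stability(profiles)
      utils::write.table(ds$ds, file.path(out, "ds_table.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
      agg <- aggregate_donors(
        profiles[profiles$probe_id == ds$selected, , drop = FALSE])
      mwf_cols <- grep("^mwf_region_", names(cohort), value = TRUE)
      regional_mwf <- stats::setNames(
        colMeans(cohort[, mwf_cols, drop = FALSE]),
        sub("^mwf_region_", "", mwf_cols))
      spatial_res <- spatial_correlation(regional_mwf, agg,
                                          regions = regions)
      utils::write.table(spatial_res$table,
                         file.path(out, "region_scatter.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
      jsonlite::write_json(
        list(r = spatial_res$r, p_value = spatial_res$p_value,
             slope = spatial_res$slope, intercept = spatial_res$intercept,
             spearman_r = spatial_res$spearman_r,
             n_regions = spatial_res$n_regions,
             selected_probe = ds$selected),
        file.path(out, "spatial_result.json"), auto_unbox = TRUE,
        digits = NA)
      counts$n_regions <- spatial_res$n_regions
      counts$spatial_r <- spatial_res$r
      counts$spatial_p <- spatial_res$p_value
      counts$selected_probe <- ds$selected
      status["spatial"] <- "ok"
      log_line("spatial", sprintf("r = %.3f (p = %.3g) over %d regions",
                                  spatial_res$r, spatial_res$p_value,
                                  spatial_res$n_regions), logfile)
    }
    TRUE
  }, error = function(e) {
    log_line("spatial", paste("FAILED:", conditionMessage(e)), logfile)
    if ("spatial" %in% config$stages) status["spatial"] <<- "failed"
    e
  })

  checksums <- lapply(inputs, function(p)
    if (is.character(p) && file.exists(p)) unname(tools::md5sum(p))
    else NA_character_)
  summary <- structure(
    list(status = as.list(status), counts = counts,
         input_checksums = checksums,
         config = unclass(config)[setdiff(names(unclass(config)),
                                          "background")],
         version = as.character(utils::packageVersion("mwfomics")),
         ok = !any(unlist(status) == "failed")),
    class = "run_summary")
  jsonlite::write_json(
    summary[c("status", "counts", "input_checksums", "config", "version",
              "ok")],
    file.path(out, "run_summary.json"), auto_unbox = TRUE, digits = NA,
    null = "null", force = TRUE)
  if (!summary$ok) {
    errs <- Filter(function(x) inherits(x, "error"),
                   list(proteomic, transcriptomic))
    warning("run_pipeline: stage failure - ",
            paste(vapply(errs, conditionMessage, ""), collapse = "; "),
            call. = FALSE)
  }
  invisible(summary)
}

#' @export
print.run_summary <- function(x, ...) {
  cat("Pipeline run (mwfomics ", x$version, "): ",
      if (x$ok) "ok" else "FAILED", "\n", sep = "")
  for (s in names(x$status))
    cat(sprintf("  %-9s %s\n", s, x$status[[s]]))
  if (length(x$counts) > 0) {
    cat("  counts:\n")
    for (nm in names(x$counts))
      cat("    ", nm, " = ",
          if (is.numeric(x$counts[[nm]])) signif(x$counts[[nm]], 4)
          else x$counts[[nm]], "\n", sep = "")
  }
  invisible(x)
}
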