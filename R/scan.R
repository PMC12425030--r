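#' Proteome-wide covariate-adjusted association scan against MWF
#'
#' For every aptamer on the panel, fits the ordinary least squares model
#'
#' `MWF ~ intercept + log2(abundance) + age + age^2 + sex + eGFR`
#'
#' and records the log2-abundance coefficient, its standard error, t
#' statistic and two-sided p-value. Subjects with missing values are dropped
#' per aptamer (complete-case), and the number used is recorded.
#' Benjamini-Hochberg q-values across the panel are emitted for reference
#' but do not gate the hit lists, which use the unadjusted p at `alpha`.
#'
#' Aptamers whose log2 abundance is exactly collinear with the covariates
#' (possible in noise-free simulated data) are recorded with `NA`
#' coefficients and `direction = "null"` rather than aborting the scan.
#'
#' @param cohort a cohort table as produced by [simulate_cohort()] or
#'   [read_cohort()]: columns `subject_id`, `age_protein`, `sex`, `egfr`,
#'   `mwf_global` and optionally `mwf_region_<id>` columns.
#' @param proteins an aptamer-by-subject abundance table (columns
#'   `aptamer_id`, `gene_symbol`, then one positive abundance column per
#'   subject).
#' @param mwf_field which MWF to analyze: `"global"` or `"region:<id>"`.
#' @param alpha unadjusted two-sided significance threshold defining hit
#'   directions (default 0.05).
#' @param swap_direction if `TRUE`, fit log2 abundance as the dependent
#'   variable and MWF as the predictor instead. t and p for the shared term
#'   are identical either way; only the beta scale changes.
#' @return a `data.frame` with one row per aptamer: `aptamer_id`,
#'   `gene_symbol`, `beta`, `se`, `t_stat`, `p_value`, `q_bh`, `n_used`,
#'   `direction` (`"positive"`, `"negative"` or `"null"`).
#' @export
run_scan <- function(cohort, proteins, mwf_field = "global", alpha = 0.05,
                     swap_direction = FALSE) {
  check_alpha(alpha)
  if (nrow(proteins) < 1L)
    stop("input error: protein matrix is empty", call. = FALSE)
  ycol <- if (identical(mwf_field, "global")) "mwf_global"
          else if (grepl("^region:", mwf_field))
            paste0("mwf_region_", sub("^region:", "", mwf_field))
          else stop("parameter error: mwf_field must be 'global' or ",
                    "'region:<id>'", call. = FALSE)
  if (!ycol %in% names(cohort))
    stop("input error: cohort has no column '", ycol, "'", call. = FALSE)

  subj_cols <- setdiff(names(proteins), c("aptamer_id", "gene_symbol"))
  common <- intersect(cohort$subject_id, subj_cols)
  if (length(common) == 0L)
    stop("empty join: no subjects shared between cohort and protein matrix",
         call. = FALSE)
  cohort <- cohort[match(common, cohort$subject_id), , drop = FALSE]
  abun <- as.matrix(proteins[, common, drop = FALSE])
  if (any(abun <= 0, na.rm = TRUE))
    stop("input error: abundances must be positive (log2 must be defined)",
         call. = FALSE)

  mwf <- cohort[[ycol]]
  covars <- cbind(age = cohort$age_protein,
                  age2 = cohort$age_protein^2,
                  sex = cohort$sex, egfr = cohort$egfr)
  n_apt <- nrow(proteins)
  beta <- se <- tval <- pval <- rep(NA_real_, n_apt)
  n_used <- integer(n_apt)
  for (j in seq_len(n_apt)) {
    x <- log2(abun[j, ])
    cc <- stats::complete.cases(mwf, x, covars)
    n_used[j] <- sum(cc)
    if (swap_direction) {
      yj <- x[cc]
      Xj <- cbind(intercept = 1, mwf = mwf[cc], covars[cc, , drop = FALSE])
      term <- "mwf"
    } else {
      yj <- mwf[cc]
      Xj <- cbind(intercept = 1, log2_abundance = x[cc],
                  covars[cc, , drop = FALSE])
      term <- "log2_abundance"
    }
    fit <- tryCatch(fit_ols(yj, Xj), error = function(e) NULL)
    if (!is.null(fit)) {
      beta[j] <- fit$coefficients[[term]]
      se[j] <- fit$se[[term]]
      tval[j] <- fit$t_stat[[term]]
      pval[j] <- fit$p_value[[term]]
    }
  }
  direction <- rep("null", n_apt)
  sig <- !is.na(pval) & pval < alpha
  direction[sig & beta > 0] <- "positive"
  direction[sig & beta < 0] <- "negative"
  data.frame(aptamer_id = proteins$aptamer_id,
             gene_symbol = proteins$gene_symbol,
             beta = beta, se = se, t_stat = tval, p_value = pval,
             q_bh = stats::p.adjust(pval, method = "BH"),
             n_used = n_used, direction = direction,
             stringsAsFactors = FALSE)
}

#' Split scan records into positive and negative gene hit lists
#'
#' Collapses aptamers to unique gene symbols: a gene enters a list if any of
#' its aptamers is significant in that direction. A gene with significant
#' aptamers in both directions (not observed in practice, but possible) is
#' assigned to the direction of its smallest-p significant aptamer, so the
#' two lists are always disjoint. Lists are ordered by ascending best p.
#'
#' @param records a scan table from [run_scan()].
#' @param alpha significance threshold in (0, 1).
#' @return a list with character vectors `positive` and `negative`, plus
#'   `n_positive`, `n_negative`.
#' @export
split_significant <- function(records, alpha = 0.05) {
  check_alpha(alpha)
  if (nrow(records) == 0L)
    stop("input error: records are empty", call. = FALSE)
  sig <- records[!is.na(records$p_value) & records$p_value < alpha &
                   records$direction != "null", , drop = FALSE]
  pick <- function(dir) {
    if (nrow(sig) == 0L) return(character(0))
    best <- sig[order(sig$p_value, sig$aptamer_id), , drop = FALSE]
    best <- best[!duplicated(best$gene_symbol), , drop = FALSE]  # best per gene
    best$gene_symbol[best$direction == dir]
  }
  pos <- pick("positive"); neg <- pick("negative")
  list(positive = pos, negative = neg,
       n_positive = length(pos), n_negative = length(neg))
}

check_alpha <- function(alpha) {
  if (length(alpha) != 1L || !is.finite(alpha) || alpha <= 0 || alpha >= 1)
    stop("parameter error: alpha must lie strictly inside (0, 1)",
         call. = FALSE)
  invisible(alpha)
}
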