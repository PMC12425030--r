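#' Construct a gene-set library
#'
#' @param sets named list of character vectors of member gene symbols; names
#'   must be unique and members non-empty.
#' @param library_name label for the library.
#' @return an object of class `"gene_set_library"`.
#' @export
gene_set_library <- function(sets, library_name = "library") {
  if (length(sets) == 0L || is.null(names(sets)) ||
      anyDuplicated(names(sets)) || any(names(sets) == ""))
    stop("input error: sets must be a uniquely named list", call. = FALSE)
  if (any(lengths(sets) == 0L))
    stop("input error: gene sets must be non-empty", call. = FALSE)
  structure(list(library_name = library_name,
                 sets = lapply(sets, as.character)),
            class = "gene_set_library")
}

#' Right-tail Fisher exact (hypergeometric) p-value
#'
#' Probability of observing `k` or more query genes inside a set of size
#' `K`, for a query of size `n` drawn from a background of size `N`:
#' `p = sum_{i >= k} C(K,i) C(N-K,n-i) / C(N,n)`. The sum is accumulated in
#' log space (via `lchoose` and a log-sum-exp) for numerical stability at
#' large `N`. When `k` is at or below the smallest achievable overlap the
#' tail is the whole distribution and `p = 1` exactly.
#'
#' @param k overlap count, `0 <= k <= min(K, n)`.
#' @param K set size within the background.
#' @param n query size within the background.
#' @param N background size; `K, n <= N`.
#' @return the right-tail p-value in (0, 1].
#' @export
fisher_right_tail <- function(k, K, n, N) {
  vals <- c(k = k, K = K, n = n, N = N)
  if (any(!is.finite(vals)) || any(vals != round(vals)) || any(vals < 0))
    stop("parameter error: k, K, n, N must be non-negative integers",
         call. = FALSE)
  if (K > N || n > N || k > min(K, n))
    stop("parameter error: need k <= min(K, n) and K, n <= N", call. = FALSE)
  lo <- max(0, n + K - N)
  if (k <= lo) return(1)
  i <- k:min(K, n)
  lp <- lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n)
  m <- max(lp)
  min(1, exp(m + log(sum(exp(lp - m)))))
}

#' Over-representation analysis of a query gene list
#'
#' Tests each set of a library for over-representation of the query within
#' the assay background using the one-sided (enrichment) Fisher exact test.
#' Genes outside the background are dropped from both the query and the
#' sets; sets left empty within the background are omitted. Results are
#' sorted by ascending p, ties broken by descending overlap then set name.
#' Benjamini-Hochberg q-values across the library's sets are emitted for
#' reference.
#'
#' The odds ratio is `(k (N-K-n+k)) / ((K-k) (n-k))`; when the denominator
#' is zero with `k > 0` it is reported as `Inf`.
#'
#' @param query character vector of gene symbols.
#' @param library a [gene_set_library()].
#' @param background character vector: the gene universe (typically all
#'   genes on the assay panel).
#' @return a `data.frame` with `library_name`, `set_name`, `k`, `K`, `n`,
#'   `N`, `odds_ratio`, `p_value`, `q_bh`. Attribute `n_query_dropped`
#'   records how many query genes fell outside the background. An empty
#'   query (after intersection) returns a zero-row result with a warning.
#' @export
run_enrichment <- function(query, library, background) {
  stopifnot(inherits(library, "gene_set_library"))
  background <- unique(as.character(background))
  query0 <- unique(as.character(query))
  query <- intersect(query0, background)
  dropped <- length(query0) - length(query)
  if (dropped > 0)
    message("run_enrichment: dropped ", dropped,
            " query gene(s) outside the background")
  empty <- data.frame(library_name = character(0), set_name = character(0),
                      k = integer(0), K = integer(0), n = integer(0),
                      N = integer(0), odds_ratio = numeric(0),
                      p_value = numeric(0), q_bh = numeric(0),
                      stringsAsFactors = FALSE)
  if (length(query) == 0L) {
    warning("run_enrichment: query is empty after background intersection")
    attr(empty, "n_query_dropped") <- dropped
    return(empty)
  }
  N <- length(background)
  n <- length(query)
  rows <- lapply(names(library$sets), function(sn) {
    members <- intersect(unique(library$sets[[sn]]), background)
    K <- length(members)
    if (K == 0L) return(NULL)
    k <- length(intersect(members, query))
    denom <- (K - k) * (n - k)
    or <- if (denom == 0) { if (k > 0) Inf else NA_real_ }
          else (k * (N - K - n + k)) / denom
    data.frame(library_name = library$library_name, set_name = sn,
               k = k, K = K, n = n, N = N, odds_ratio = or,
               p_value = fisher_right_tail(k, K, n, N),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (length(rows) == 0L) {
    attr(empty, "n_query_dropped") <- dropped
    return(empty)
  }
  res <- do.call(rbind, rows)
  res$q_bh <- stats::p.adjust(res$p_value, method = "BH")
  res <- res[order(res$p_value, -res$k, res$set_name), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "n_query_dropped") <- dropped
  res
}

#' Apply the per-library reporting rule
#'
#' Flags the first `min(top_k, #{p < alpha})` rows of a sorted enrichment
#' result as reported - i.e. the top-`top_k` most significant pathways, or
#' all nominally significant ones, whichever is fewer.
#'
#' @param results a sorted [run_enrichment()] table.
#' @param alpha nominal significance threshold (default 0.05).
#' @param top_k maximum number of reported rows per library (default 5).
#' @return `results` with a logical `reported` column.
#' @export
report_top <- function(results, alpha = 0.05, top_k = 5L) {
  check_alpha(alpha)
  n_rep <- min(top_k, sum(results$p_value < alpha))
  results$reported <- seq_len(nrow(results)) <= n_rep
  results
}
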