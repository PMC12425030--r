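#' Ordinary least squares with standard errors and t-based p-values
#'
#' Fits `y = X b + e` by QR decomposition. Standard errors use the unbiased
#' residual variance estimate; p-values come from the t distribution with
#' `n - k` residual degrees of freedom. Rank-deficient designs raise an
#' error naming the offending (aliased) columns; designs with no residual
#' degrees of freedom raise an insufficient-data error.
#'
#' If the fit is numerically exact (residual sum of squares below
#' `1e-13 * sum(y^2)`), standard errors collapse to zero; coefficients that
#' are clearly nonzero are then reported with `p = 0` and infinite t, and
#' coefficients indistinguishable from zero with `p = 1`. This keeps
#' noise-free simulations well defined.
#'
#' @param y numeric response vector.
#' @param X numeric design matrix, including an intercept column if one is
#'   wanted; `nrow(X)` must equal `length(y)`.
#' @return a list with `coefficients`, `se`, `t_stat`, `p_value` (named by
#'   the columns of `X`), `df_residual`, `sigma2`, `residuals`, `exact_fit`.
#' @export
fit_ols <- function(y, X) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  n <- nrow(X); k <- ncol(X)
  if (length(y) != n)
    stop("input error: length(y) != nrow(X)", call. = FALSE)
  if (!all(is.finite(y)) || !all(is.finite(X)))
    stop("input error: non-finite values in y or X", call. = FALSE)
  if (n <= k)
    stop("insufficient data: ", n, " rows for ", k, " coefficients",
         call. = FALSE)
  qrx <- qr(X)
  if (qrx$rank < k) {
    bad <- colnames(X)[qrx$pivot[(qrx$rank + 1L):k]]
    stop("singular design: column(s) ", paste(bad, collapse = ", "),
         " are linearly dependent on the others", call. = FALSE)
  }
  coef <- qr.coef(qrx, y)
  res <- qr.resid(qrx, y)
  df <- n - k
  rss <- sum(res^2)
  exact <- rss <= 1e-13 * max(sum(y^2), .Machine$double.xmin)
  sigma2 <- rss / df
  R <- qr.R(qrx)
  xtx_inv <- chol2inv(R)
  unpivot <- order(qrx$pivot)
  xtx_inv <- xtx_inv[unpivot, unpivot, drop = FALSE]
  se <- sqrt(pmax(diag(xtx_inv), 0) * sigma2)
  if (exact) {
    tol <- 1e-8 * max(abs(coef), 1)
    t_stat <- ifelse(abs(coef) > tol, sign(coef) * Inf, 0)
    p <- ifelse(abs(coef) > tol, 0, 1)
    se <- rep(0, k)
  } else {
    t_stat <- coef / se
    p <- 2 * stats::pt(-abs(t_stat), df)
  }
  names(se) <- names(t_stat) <- names(p) <- colnames(X)
  list(coefficients = coef, se = se, t_stat = t_stat, p_value = p,
       df_residual = df, sigma2 = sigma2, residuals = res,
       exact_fit = exact)
}
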