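## Correlation screening: Pearson matrix with t-based p-values,
## Benjamini-Hochberg FDR over the tested family, Spearman rank agreement.

#' Pearson correlation matrix with FDR-adjusted significance
#'
#' Pairwise Pearson correlations over a genotype x variable table with
#' two-sided p-values from the t transform (`t = r sqrt((n-2)/(1-r^2))`,
#' n-2 df) and pairwise-complete handling of missing cells.
#' Benjamini-Hochberg adjustment is applied jointly over the upper
#' triangle (all tested pairs as one family). Zero-variance variables give
#' missing correlations with a warning.
#'
#' @param data Numeric data frame or matrix (rows = genotypes, columns =
#'   variables).
#' @param fdr Apply BH adjustment (default `TRUE`).
#' @return A list of class `corr_screen` with symmetric matrices `r`, `p`,
#'   `q`, `n` (pairwise-complete counts), and `pairs`, a tidy long-format
#'   data frame of the upper triangle with significance stars
#'   (`**` q < 0.01, `***` q < 0.001).
#' @export
pearson_matrix <- function(data, fdr = TRUE) {
  x <- as.matrix(data)
  if (!is.numeric(x)) stop("`data` must be numeric")
  v <- colnames(x)
  if (is.null(v)) v <- paste0("V", seq_len(ncol(x)))
  m <- ncol(x)
  if (m < 2) stop("need at least two variables")
  const <- apply(x, 2L, function(col) stats::var(col, na.rm = TRUE) == 0)
  if (any(const, na.rm = TRUE))
    warning("zero-variance variable(s): ",
            paste(v[which(const)], collapse = ", "),
            "; their correlations are reported as missing")
  r <- p <- q <- matrix(NA_real_, m, m, dimnames = list(v, v))
  nmat <- matrix(0L, m, m, dimnames = list(v, v))
  diag(r) <- 1
  diag(p) <- 0
  for (i in seq_len(m - 1)) {
    for (j in seq.int(i + 1, m)) {
      ok <- stats::complete.cases(x[, i], x[, j])
      nij <- sum(ok)
      nmat[i, j] <- nmat[j, i] <- nij
      if (nij < 3 || isTRUE(const[i]) || isTRUE(const[j])) next
      rij <- stats::cor(x[ok, i], x[ok, j])
      r[i, j] <- r[j, i] <- rij
      pij <- if (abs(rij) >= 1) 0 else {
        tstat <- rij * sqrt((nij - 2) / (1 - rij^2))
        2 * stats::pt(-abs(tstat), df = nij - 2)
      }
      p[i, j] <- p[j, i] <- pij
    }
  }
  ut <- upper.tri(p)
  if (fdr) {
    pv <- p[ut]
    qv <- rep(NA_real_, length(pv))
    qv[!is.na(pv)] <- bh_fdr(pv[!is.na(pv)])
    q[ut] <- qv
    q <- pmax(q, t(q), na.rm = TRUE)
    diag(q) <- 0
  }
  idx <- which(ut, arr.ind = TRUE)
  pairs <- data.frame(var1 = v[idx[, 1]], var2 = v[idx[, 2]],
                      r = r[ut], p = p[ut], q = q[ut], n = nmat[ut],
                      stringsAsFactors = FALSE)
  pairs$stars <- ifelse(is.na(pairs$q), "",
                        ifelse(pairs$q < 0.001, "***",
                               ifelse(pairs$q < 0.01, "**", "")))
  structure(list(r = r, p = p, q = q, n = nmat, pairs = pairs),
            class = "corr_screen")
}

#' @export
print.corr_screen <- function(x, ...) {
  cat("Correlation screen over", ncol(x$r), "variables\n")
  sig <- x$pairs[!is.na(x$pairs$q) & x$pairs$q < 0.01, , drop = FALSE]
  cat(nrow(sig), "pair(s) significant at q < 0.01\n")
  invisible(x)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted values `q_(i) = min_{j >= i} min(1, p_(j) m / j)`,
#' mapped back to input order (delegates to [stats::p.adjust()]).
#'
#' @param pvalues Numeric vector of raw p-values in `[0, 1]`.
#' @return Adjusted values in input order.
#' @export
bh_fdr <- function(pvalues) {
  if (!length(pvalues)) return(numeric(0))
  if (anyNA(pvalues) || any(pvalues < 0) || any(pvalues > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' Spearman rank correlation
#'
#' Pearson correlation of midranks (average ranks for ties). Constant
#' input gives `NA` with a warning.
#'
#' @param x,y Equal-length numeric vectors (length >= 3).
#' @return Rho in `[-1, 1]`, or `NA` for degenerate input.
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("need at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("constant input: Spearman rho undefined")
    return(NA_real_)
  }
  stats::cor(rank(x), rank(y))
}
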