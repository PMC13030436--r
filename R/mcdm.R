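## Multi-criteria genotype ranking: min-max normalisation, entropy
## weighting with information utility, TOPSIS closeness to the ideal
## solution, CRITIC weighting as an independent cross-check, and rank
## agreement between the two weightings.

#' Decision matrix for multi-criteria evaluation
#'
#' Genotypes (alternatives) by indicators, with a per-indicator direction
#' flag: `benefit` indicators are better when larger, `cost` indicators
#' when smaller.
#'
#' @param x Numeric matrix or data frame; row names identify alternatives.
#' @param directions Character vector (`"benefit"`/`"cost"`), one per
#'   indicator or a single value recycled; default all-benefit.
#' @return A numeric matrix of class `decision_matrix` with a
#'   `"directions"` attribute.
#' @export
decision_matrix <- function(x, directions = "benefit") {
  x <- as.matrix(x)
  if (!is.numeric(x)) stop("decision matrix must be numeric")
  if (anyNA(x)) stop("decision matrix must have no missing cells")
  if (nrow(x) < 2 || ncol(x) < 2)
    stop("need at least 2 alternatives and 2 indicators")
  if (is.null(rownames(x))) rownames(x) <- paste0("alt", seq_len(nrow(x)))
  if (is.null(colnames(x))) colnames(x) <- paste0("ind", seq_len(ncol(x)))
  if (length(directions) == 1) directions <- rep(directions, ncol(x))
  if (length(directions) != ncol(x))
    stop("need one direction per indicator")
  if (!all(directions %in% c("benefit", "cost")))
    stop("directions must be 'benefit' or 'cost'")
  structure(x, directions = stats::setNames(directions, colnames(x)),
            class = c("decision_matrix", "matrix"))
}

#' Min-max normalisation of a decision matrix
#'
#' Benefit indicators map to `(x - min) / (max - min)`, cost indicators to
#' `(max - x) / (max - min)`, so every column lies in `[0, 1]` with 1 the
#' preferred end. Constant columns normalise to all-zero and are flagged
#' (attribute `"degenerate"`) rather than treated as fatal.
#'
#' @param dm A [decision_matrix()] (or plain matrix, taken as all-benefit).
#' @return Normalised numeric matrix `Z` in `[0, 1]`.
#' @export
normalize_decision <- function(dm) {
  if (!inherits(dm, "decision_matrix")) dm <- decision_matrix(dm)
  dirs <- attr(dm, "directions")
  x <- unclass(dm)
  attr(x, "directions") <- NULL
  z <- x
  degenerate <- logical(ncol(x))
  for (j in seq_len(ncol(x))) {
    rng <- range(x[, j])
    if (diff(rng) == 0) {
      z[, j] <- 0
      degenerate[j] <- TRUE
    } else if (dirs[j] == "benefit") {
      z[, j] <- (x[, j] - rng[1]) / diff(rng)
    } else {
      z[, j] <- (rng[2] - x[, j]) / diff(rng)
    }
  }
  if (any(degenerate))
    warning("constant indicator column(s) normalised to zero: ",
            paste(colnames(x)[degenerate], collapse = ", "))
  attr(z, "degenerate") <- stats::setNames(degenerate, colnames(x))
  z
}

#' Entropy weights and information utility
#'
#' For each normalised column, proportions `p_ij = z_ij / sum_i z_ij`,
#' information entropy `e_j = -(1/ln n) sum_i p_ij ln p_ij` (with
#' `0 ln 0 := 0`), information utility `d_j = 1 - e_j`, and weights
#' `w_j = d_j / sum_k d_k`. A column with zero sum (degenerate after
#' normalisation) carries no information and gets weight 0.
#'
#' @param Z Normalised matrix from [normalize_decision()].
#' @return A data frame of class `weight_result` with columns `indicator`,
#'   `entropy`, `utility`, `weight`, and attribute `method = "entropy"`.
#' @export
entropy_weights <- function(Z) {
  Z <- as.matrix(Z)
  n <- nrow(Z)
  if (n < 2) stop("entropy weights need at least 2 alternatives")
  if (any(Z < 0)) stop("normalised values must be non-negative")
  cs <- colSums(Z)
  e <- vapply(seq_len(ncol(Z)), function(j) {
    if (cs[j] == 0) return(1)  # no information
    p <- Z[, j] / cs[j]
    plp <- ifelse(p > 0, p * log(p), 0)
    -sum(plp) / log(n)
  }, numeric(1))
  d <- 1 - e
  if (all(d <= 0))
    stop("every indicator is degenerate: no information to weight")
  w <- d / sum(d)
  structure(data.frame(indicator = colnames(Z), entropy = e, utility = d,
                       weight = w, stringsAsFactors = FALSE,
                       row.names = NULL),
            method = "entropy", class = c("weight_result", "data.frame"))
}

#' CRITIC weights
#'
#' Criteria Importance Through Intercriteria Correlation: each indicator's
#' importance is its sample SD times its summed conflict with the others,
#' `C_j = sigma_j * sum_{k != j} (1 - r_jk)`; weights are `C_j / sum C`.
#' Constant columns carry zero weight and are excluded from the
#' correlation (with a warning).
#'
#' @param Z Normalised matrix from [normalize_decision()] (any numeric
#'   matrix is accepted).
#' @return A data frame of class `weight_result` with columns `indicator`,
#'   `sd`, `conflict`, `weight`, and attribute `method = "critic"`.
#' @export
critic_weights <- function(Z) {
  Z <- as.matrix(Z)
  if (ncol(Z) < 2)
    stop("CRITIC conflict is undefined for a single indicator")
  sds <- apply(Z, 2L, stats::sd)
  live <- sds > 0
  if (sum(live) < 2)
    stop("CRITIC needs at least 2 non-degenerate indicators")
  if (any(!live))
    warning("constant indicator column(s) get zero CRITIC weight: ",
            paste(colnames(Z)[!live], collapse = ", "))
  conflict <- rep(0, ncol(Z))
  r <- stats::cor(Z[, live, drop = FALSE])
  conflict[live] <- rowSums(1 - r) # diagonal contributes 1 - 1 = 0
  C <- sds * conflict
  C[!live] <- 0
  if (sum(C) == 0) {
    ## all live columns perfectly correlated: no conflict anywhere, so
    ## importance is shared equally among them
    w <- as.numeric(live) / sum(live)
  } else {
    w <- C / sum(C)
  }
  structure(data.frame(indicator = colnames(Z), sd = sds,
                       conflict = conflict, weight = w,
                       stringsAsFactors = FALSE, row.names = NULL),
            method = "critic", class = c("weight_result", "data.frame"))
}

#' TOPSIS ranking by closeness to the ideal solution
#'
#' Weighted-Euclidean TOPSIS: with `v_ij = w_j z_ij`, the ideal and
#' anti-ideal points are the column-wise maxima and minima of `v`;
#' `D_i+ = sqrt(sum_j (Zmax_j - v_ij)^2)` and
#' `D_i- = sqrt(sum_j (v_ij - Zmin_j)^2)` are the distances to them, and
#' the comprehensive score is `Ci = D- / (D+ + D-)`. Ranking is by
#' descending `Ci`, ties broken by alternative ID. `weighted = FALSE`
#' computes the distances on `Z` itself (exact-formula mode).
#'
#' @param Z Normalised matrix from [normalize_decision()].
#' @param w Weight vector summing to 1 (e.g. the `weight` column of a
#'   [entropy_weights()] result), or a `weight_result`.
#' @param weighted Apply weights before the distance computation
#'   (default `TRUE`).
#' @return A data frame of class `topsis_result` with columns
#'   `alternative`, `d_plus`, `d_minus`, `ci`, `rank`, sorted by rank.
#' @export
topsis <- function(Z, w, weighted = TRUE) {
  Z <- as.matrix(Z)
  if (inherits(w, "weight_result")) w <- w$weight
  if (length(w) != ncol(Z)) stop("need one weight per indicator")
  if (abs(sum(w) - 1) > 1e-9) stop("weights must sum to 1")
  if (any(w < 0)) stop("weights must be non-negative")
  v <- if (weighted) sweep(Z, 2L, w, `*`) else Z
  zmax <- apply(v, 2L, max)
  zmin <- apply(v, 2L, min)
  d_plus <- sqrt(rowSums(sweep(v, 2L, zmax)^2))
  d_minus <- sqrt(rowSums(sweep(v, 2L, zmin)^2))
  ci <- rep(0.5, nrow(Z))
  tot <- d_plus + d_minus
  if (any(tot == 0))
    warning("alternative(s) equidistant from identical ideal and worst ",
            "points; Ci set to 0.5")
  ci[tot > 0] <- d_minus[tot > 0] / tot[tot > 0]
  ids <- rownames(Z)
  if (is.null(ids)) ids <- paste0("alt", seq_len(nrow(Z)))
  ord <- order(-ci, ids)
  res <- data.frame(alternative = ids, d_plus = d_plus, d_minus = d_minus,
                    ci = ci, stringsAsFactors = FALSE, row.names = NULL)
  res$rank <- match(seq_len(nrow(res)), ord)
  res <- res[ord, , drop = FALSE]
  rownames(res) <- NULL
  structure(res, class = c("topsis_result", "data.frame"))
}

#' Integrated multi-criteria evaluation with rank agreement
#'
#' Runs the full ranking pipeline: min-max normalisation, entropy and
#' CRITIC weighting, TOPSIS under each weighting, and the Spearman rank
#' correlation between the two rankings as an agreement check.
#'
#' @param dm A [decision_matrix()].
#' @param weighted Passed to [topsis()].
#' @return A list of class `mcdm_evaluation`: `weights` (named list of
#'   `weight_result`s), `rankings` (named list of `topsis_result`s, the
#'   entropy one being the headline ranking), and `agreement`
#'   (`spearman_rho` between the rankings).
#' @export
evaluate_genotypes <- function(dm, weighted = TRUE) {
  if (!inherits(dm, "decision_matrix")) dm <- decision_matrix(dm)
  Z <- normalize_decision(dm)
  w_ent <- entropy_weights(Z)
  w_cri <- critic_weights(Z)
  t_ent <- topsis(Z, w_ent, weighted = weighted)
  t_cri <- topsis(Z, w_cri, weighted = weighted)
  r1 <- t_ent$rank[order(t_ent$alternative)]
  r2 <- t_cri$rank[order(t_cri$alternative)]
  rho <- if (length(r1) < 3) stats::cor(r1, r2) else spearman_rho(r1, r2)
  structure(list(weights = list(entropy = w_ent, critic = w_cri),
                 rankings = list(entropy = t_ent, critic = t_cri),
                 agreement = list(spearman_rho = rho)),
            class = "mcdm_evaluation")
}

#' @export
print.mcdm_evaluation <- function(x, ...) {
  top <- utils::head(x$rankings$entropy, 3)
  cat("Entropy-weighted TOPSIS ranking (top 3):\n")
  print(top)
  cat(sprintf("Rank agreement with CRITIC weighting: Spearman rho = %.3f\n",
              x$agreement$spearman_rho))
  invisible(x)
}

#' Build a decision matrix from a long trait table
#'
#' Extracts genotype-level means for the requested indicators. For each
#' indicator the preferred month is used when that trait was measured
#' there; otherwise the mean over all available months is taken (single-
#' campaign leaf and fluorescence traits keep their own month).
#'
#' @param tt Long trait table.
#' @param indicators Trait names to use as indicators.
#' @param month Preferred month for multi-month traits (default: the last
#'   month present).
#' @param directions Passed to [decision_matrix()].
#' @return A [decision_matrix()] with genotypes as rows.
#' @export
decision_matrix_from_traits <- function(tt, indicators = unique(tt$trait),
                                        month = NULL,
                                        directions = "benefit") {
  if (is.null(month)) month <- utils::tail(levels(tt$month), 1)
  cols <- lapply(indicators, function(tr) {
    sub <- trait_subset(tt, tr)
    mo <- if (month %in% as.character(unique(sub$month))) month else NULL
    gm <- genotype_means(tt, tr, mo)
    stats::setNames(gm$mean, gm$genotype)
  })
  ids <- sort(unique(tt$genotype))
  x <- vapply(cols, function(v) v[ids], numeric(length(ids)))
  dimnames(x) <- list(ids, indicators)
  if (anyNA(x)) stop("indicator(s) missing for some genotypes")
  decision_matrix(x, directions)
}
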