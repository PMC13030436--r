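## Descriptive and comparative phenotype statistics: growth dynamics,
## dispersion, phenotypic diversity, leaf classification, group contrasts
## and post-hoc letters.

trait_subset <- function(tt, trait, month = NULL) {
  x <- tt[tt$trait == trait, , drop = FALSE]
  if (!nrow(x)) stop("trait not present in table: ", trait)
  if (!is.null(month)) {
    x <- x[x$month == month, , drop = FALSE]
    if (!nrow(x)) stop("trait ", trait, " has no observations in ", month)
  }
  x
}

#' Genotype-level trait means
#'
#' Mean observation per genotype (over replicates, and over months unless
#' one is given), carrying the P/NP group label.
#'
#' @param tt Long trait table (see [generate_trait_tables()]).
#' @param trait Trait name.
#' @param month Optional month label.
#' @return Data frame `genotype`, `group`, `mean`.
#' @export
genotype_means <- function(tt, trait, month = NULL) {
  x <- trait_subset(tt, trait, month)
  agg <- stats::aggregate(value ~ genotype + group, data = x, FUN = mean)
  names(agg)[names(agg) == "value"] <- "mean"
  agg[order(agg$genotype), , drop = FALSE]
}

#' Monthly relative growth rates and growth phases
#'
#' Rates are computed on monthly means `m_t` pooled over genotypes:
#' `rate(t -> t+1) = 100 (m_{t+1} - m_t) / m_t`. Each month pair is
#' labelled `stagnation` when its rate falls below the 12% threshold,
#' `rapid` when it is the maximum over pairs, else `stable`. The overall
#' relative change `100 (m_last - m_first) / m_first` is reported as
#' `total_rate`, alongside the additive sum of the monthly rates
#' (`rate_sum`); the two aggregate the same trajectory differently.
#'
#' @inheritParams genotype_means
#' @param stagnation_threshold Growth-rate threshold (%) below which a
#'   month pair counts as stagnation.
#' @return Data frame `from`, `to`, `rate`, `phase`, with attributes
#'   `total_rate`, `rate_sum` and `monthly_means`.
#' @export
monthly_growth_rates <- function(tt, trait = NULL,
                                 stagnation_threshold = 12) {
  if (is.null(trait)) {
    trait <- unique(tt$trait)
    if (length(trait) != 1)
      stop("several traits present; name the one to analyse")
  }
  x <- trait_subset(tt, trait)
  m <- tapply(x$value, x$month, mean)
  m <- m[!is.na(m)]
  if (length(m) < 2) stop("growth rates need at least two months")
  if (any(m <= 0)) stop("non-positive monthly mean for trait ", trait)
  rate <- 100 * diff(m) / utils::head(m, -1)
  phase <- ifelse(rate < stagnation_threshold, "stagnation",
                  ifelse(rate == max(rate), "rapid", "stable"))
  out <- data.frame(from = utils::head(names(m), -1),
                    to = names(m)[-1],
                    rate = as.numeric(rate),
                    phase = phase,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "total_rate") <- 100 * (m[[length(m)]] - m[[1]]) / m[[1]]
  attr(out, "rate_sum") <- sum(rate)
  attr(out, "monthly_means") <- m
  out
}

#' Coefficient of variation (%)
#'
#' `CV = 100 * SD / AVG` with the sample SD (n-1 denominator). Either a
#' vector of values or a precomputed `(avg, sd)` pair may be supplied.
#'
#' @param values Numeric vector (ignored when `avg`/`sd` given).
#' @param avg,sd Precomputed mean and sample SD.
#' @return CV as a percentage.
#' @examples
#' cv_percent(avg = 4.54, sd = 0.906)  # ~20
#' @export
cv_percent <- function(values = NULL, avg = NULL, sd = NULL) {
  if (is.null(avg)) {
    if (is.null(values) || length(values) < 2)
      stop("supply `values` (length >= 2) or both `avg` and `sd`")
    avg <- mean(values)
    sd <- stats::sd(values)
  }
  if (is.null(sd)) stop("`sd` missing")
  if (avg <= 0) stop("CV undefined for non-positive mean (", avg, ")")
  100 * sd / avg
}

#' Average of monthly CVs
#'
#' Arithmetic mean of per-month CV percentages, the "Average CV"
#' aggregation used in seasonal trait-dispersion tables.
#'
#' @param monthly_cvs Numeric vector of CV percentages.
#' @return Their mean.
#' @export
average_cv <- function(monthly_cvs) {
  if (!length(monthly_cvs)) stop("no monthly CVs supplied")
  mean(monthly_cvs)
}

#' Shannon-Wiener phenotypic diversity index
#'
#' `H' = -sum Pi ln Pi` over phenotype classes. Values are binned into
#' `n_classes` equal-width classes spanning `[mean - 2 SD, mean + 2 SD]`
#' with open-ended extreme classes (the usual germplasm-study convention);
#' empty classes contribute nothing. Zero-variance input puts all mass in
#' one class and returns 0. Explicit `breaks` override the default binning.
#'
#' @param values Numeric vector (typically genotype-level trait means).
#' @param n_classes Number of phenotype classes (default 10).
#' @param breaks Optional explicit break points (overrides `n_classes`).
#' @return H-prime (non-negative; at most `log(n_classes)`).
#' @export
shannon_index <- function(values, n_classes = 10, breaks = NULL) {
  if (!length(values)) stop("no values supplied")
  if (is.null(breaks)) {
    if (n_classes < 1) stop("n_classes must be >= 1")
    m <- mean(values)
    s <- stats::sd(values)
    if (!is.finite(s) || s == 0) return(0)
    breaks <- seq(m - 2 * s, m + 2 * s, length.out = n_classes + 1)
  }
  breaks[1] <- -Inf
  breaks[length(breaks)] <- Inf
  counts <- table(cut(values, breaks = breaks, include.lowest = TRUE))
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log(p))
}

#' Trait summary table (AVG, SD, CV%, H')
#'
#' Per-trait (optionally per-month) descriptive statistics computed over
#' genotype-level means: mean, sample SD, CV% and the Shannon-Wiener index.
#'
#' @inheritParams genotype_means
#' @param traits Traits to summarise (default: all present).
#' @param by_month Split by month?
#' @param n_classes Classes for [shannon_index()].
#' @return Data frame `trait`, `month` (optional), `avg`, `sd`, `cv`, `h`.
#' @export
trait_summary <- function(tt, traits = unique(tt$trait), by_month = FALSE,
                          n_classes = 10) {
  rows <- list()
  for (tr in traits) {
    months <- if (by_month) {
      sub <- trait_subset(tt, tr)
      as.character(sort(unique(sub$month)))
    } else list(NULL)
    for (mo in months) {
      gm <- genotype_means(tt, tr, mo)$mean
      rows[[length(rows) + 1L]] <- data.frame(
        trait = tr, month = if (is.null(mo)) NA_character_ else mo,
        avg = mean(gm), sd = stats::sd(gm),
        cv = if (mean(gm) > 0) cv_percent(values = gm) else NA_real_,
        h = shannon_index(gm, n_classes),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Leaf size classification
#'
#' Classifies genotypes by mean leaf area (cm^2): `large` when
#' `LA >= large_min` (default 2.50), `small` when `LA < small_max`
#' (default 1.80), else `medium`. The shape coefficient is not a
#' classifier; agreement of SC with the class's conventional range
#' (large >= 0.68, medium 0.66-0.68, small < 0.66) is reported as the
#' `sc_consistent` flag.
#'
#' @param leaf Data frame with columns `genotype`, `LA` and optionally `SC`
#'   (one row per genotype, genotype-mean values).
#' @param large_min,small_max Leaf-area thresholds (cm^2).
#' @return List of class `leaf_classification`: `classes` (per-genotype
#'   data frame) and `summary` (per-class count and percentage, rounded to
#'   one decimal).
#' @export
classify_leaves <- function(leaf, large_min = 2.50, small_max = 1.80) {
  stopifnot(is.data.frame(leaf), "genotype" %in% names(leaf))
  if (!"LA" %in% names(leaf) || anyNA(leaf$LA))
    stop("leaf area (LA) is required for every genotype")
  cls <- ifelse(leaf$LA >= large_min, "large",
                ifelse(leaf$LA < small_max, "small", "medium"))
  sc_ok <- rep(NA, nrow(leaf))
  if ("SC" %in% names(leaf)) {
    sc_ok <- (cls == "large" & leaf$SC >= 0.68) |
      (cls == "medium" & leaf$SC >= 0.66 & leaf$SC < 0.68) |
      (cls == "small" & leaf$SC < 0.66)
  }
  classes <- data.frame(genotype = leaf$genotype, LA = leaf$LA,
                        class = cls, sc_consistent = sc_ok,
                        stringsAsFactors = FALSE)
  lev <- c("large", "medium", "small")
  counts <- table(factor(cls, levels = lev))
  summary <- data.frame(class = lev,
                        count = as.integer(counts),
                        percentage = round(100 * as.integer(counts) /
                                             nrow(leaf), 1),
                        stringsAsFactors = FALSE)
  structure(list(classes = classes, summary = summary),
            class = "leaf_classification")
}

#' Group means and proportion above the overall mean
#'
#' Contrasts the P and NP groups on genotype-level means: per-group mean
#' and SD, plus the percentage of each group's genotypes whose mean lies
#' strictly above the overall (all-genotype) mean.
#'
#' @inheritParams genotype_means
#' @return List with `overall_mean` and a data frame `groups`
#'   (`group`, `n`, `mean`, `sd`, `pct_above_overall`).
#' @export
group_summary <- function(tt, trait, month = NULL) {
  gm <- genotype_means(tt, trait, month)
  if (length(unique(gm$group)) < 2)
    stop("both P and NP groups must be present")
  overall <- mean(gm$mean)
  rows <- lapply(split(gm, gm$group), function(g) {
    data.frame(group = g$group[1], n = nrow(g),
               mean = mean(g$mean), sd = stats::sd(g$mean),
               pct_above_overall = 100 * mean(g$mean > overall),
               stringsAsFactors = FALSE)
  })
  groups <- do.call(rbind, rows)
  rownames(groups) <- NULL
  list(overall_mean = overall, groups = groups)
}

#' One-way ANOVA with Duncan's multiple range test
#'
#' Fits a one-way layout and performs Duncan's multiple range test:
#' critical ranges `R_p = q(1 - alpha_p, p, df) * sqrt(MSE / n_h)` with the
#' protection levels `alpha_p = 1 - (1 - alpha)^(p-1)`, `n_h` the harmonic
#' mean of the group sizes. Means spanned by a non-significant range are
#' not further subdivided; the resulting maximal homogeneous blocks are
#' lettered `a, b, ...` from the largest mean downward, so groups sharing a
#' letter do not differ at level `alpha`.
#'
#' @param x Either a named list of numeric vectors, or a numeric vector
#'   (with `g` giving group labels).
#' @param g Group labels when `x` is a vector.
#' @param alpha Significance level (default 0.05).
#' @return A list of class `duncan_test` with `F`, `p`, `df`, `MSE` and a
#'   data frame `groups` (`group`, `n`, `mean`, `letters`), sorted by
#'   decreasing mean.
#' @export
anova_duncan <- function(x, g = NULL, alpha = 0.05) {
  if (is.list(x) && !is.data.frame(x)) {
    g <- rep(names(x), lengths(x))
    x <- unlist(x, use.names = FALSE)
  }
  stopifnot(length(x) == length(g))
  g <- factor(g)
  if (nlevels(g) < 2) stop("need at least two groups")
  if (any(table(g) < 2)) stop("every group needs at least two values")
  fit <- stats::aov(x ~ g)
  a <- suppressWarnings(stats::anova(fit))  # perfect-fit warning precedes
                                            # the MSE = 0 error below
  MSE <- a$`Mean Sq`[2]
  dfe <- a$Df[2]
  if (MSE <= 0 || !is.finite(MSE))
    stop("zero within-group variance in every group: F undefined")
  means <- sort(tapply(x, g, mean), decreasing = TRUE)
  ns <- table(g)[names(means)]
  k <- length(means)
  n_h <- k / sum(1 / ns)
  se <- sqrt(MSE / n_h)
  crit <- vapply(2:k, function(p) {
    stats::qtukey(1 - (1 - (1 - alpha)^(p - 1)), p, dfe) * se
  }, numeric(1))

  ## non-significance over spans, with the protection rule that a
  ## non-significant range shields all of its sub-ranges
  ns_mat <- diag(TRUE, k)
  for (span in k:2) {
    for (i in seq_len(k - span + 1)) {
      j <- i + span - 1
      raw <- (means[i] - means[j]) < crit[span - 1]
      if (raw) ns_mat[i:j, i:j] <- TRUE
    }
  }
  ## maximal homogeneous intervals -> letters
  intervals <- list()
  i <- 1
  while (i <= k) {
    j <- i
    while (j < k && ns_mat[i, j + 1]) j <- j + 1
    covered <- length(intervals) &&
      intervals[[length(intervals)]][2] >= j
    if (!covered) intervals[[length(intervals) + 1L]] <- c(i, j)
    i <- i + 1
  }
  letters_of <- rep("", k)
  for (ii in seq_along(intervals)) {
    rng <- intervals[[ii]]
    letters_of[rng[1]:rng[2]] <- paste0(letters_of[rng[1]:rng[2]],
                                        letters[ii])
  }
  groups <- data.frame(group = names(means), n = as.integer(ns),
                       mean = as.numeric(means), letters = letters_of,
                       stringsAsFactors = FALSE)
  rownames(groups) <- NULL
  structure(list(F = a$`F value`[1], p = a$`Pr(>F)`[1],
                 df = c(a$Df[1], dfe), MSE = MSE, alpha = alpha,
                 critical_ranges = crit, groups = groups),
            class = "duncan_test")
}

#' @export
print.duncan_test <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F(%d, %d) = %.3f, p = %.4g\n",
              x$df[1], x$df[2], x$F, x$p))
  cat(sprintf("Duncan's multiple range test at alpha = %.2f\n", x$alpha))
  print(x$groups)
  invisible(x)
}
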