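## Shared fixture builders and independent oracles.

# Long trait table from per-month means, one genotype / one replicate.
tt_from_months <- function(values, trait = "H", months = NULL,
                           genotype = "G1", group = "P") {
  if (is.null(months)) months <- paste0("M", seq_along(values))
  tt <- data.frame(genotype = genotype, group = group, month = months,
                   replicate = 1L, trait = trait, value = values,
                   stringsAsFactors = FALSE)
  tt$month <- factor(tt$month, levels = months, ordered = TRUE)
  tt
}

# Long trait table from genotype-level means (one month, one replicate).
tt_from_genotype_means <- function(means, groups, trait = "X") {
  tt <- data.frame(genotype = sprintf("G%02d", seq_along(means)),
                   group = groups, month = "September", replicate = 1L,
                   trait = trait, value = means, stringsAsFactors = FALSE)
  tt$month <- factor(tt$month, levels = "September", ordered = TRUE)
  tt
}

# Random unrooted tree with positive branch lengths plus its (additive)
# patristic distance matrix: the round-trip oracle for neighbor joining.
rand_additive <- function(n_leaves) {
  tr <- ape::rtree(n_leaves, rooted = FALSE,
                   br = function(k) stats::runif(k, 0.1, 1))
  list(tree = tr, d = ape::cophenetic.phylo(tr))
}

# Brute-force Benjamini-Hochberg step-up: min over tails of p_(j)*m/j.
brute_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    q[o[i]] <- min(vapply(i:m, function(j) min(1, p[o[j]] * m / j),
                          numeric(1)))
  }
  q
}

# Brute-force mean pairwise per-site difference over gap-free columns.
brute_pi <- function(seqs) {
  mat <- do.call(rbind, strsplit(toupper(seqs), ""))
  keep <- apply(mat, 2, function(col) !any(col %in% c("-", "N")))
  mat <- mat[, keep, drop = FALSE]
  n <- nrow(mat)
  d <- c()
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) d <- c(d, mean(mat[i, ] != mat[j, ]))
  }
  mean(d)
}
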