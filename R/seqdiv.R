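#' Per-sequence and mean GC content
#'
#' GC fraction of each sequence, `(G+C)/(A+C+G+T)`, ignoring gaps and `N`.
#'
#' @param aln An [its_alignment].
#' @return List with `per_sequence` (named fractions) and `mean`.
#' @examples
#' gc_content(its_alignment(c(a = "GGCC", b = "AT-G")))
#' @export
gc_content <- function(aln) {
  stopifnot(inherits(aln, "its_alignment"))
  mat <- unclass(aln)
  per <- apply(mat, 1L, function(s) {
    acgt <- sum(s %in% c("A", "C", "G", "T"))
    if (acgt == 0) return(NA_real_)
    sum(s %in% c("G", "C")) / acgt
  })
  if (anyNA(per))
    stop("sequence(s) with no unambiguous bases: ",
         paste(names(per)[is.na(per)], collapse = ", "))
  list(per_sequence = per, mean = mean(per))
}

#' Collapse an alignment into haplotypes
#'
#' Accessions with identical sequences over the analysed columns share a
#' haplotype. Under the default gap policy any column containing `-` or `N`
#' is removed before comparison (so indels do not distinguish haplotypes);
#' under `include_gaps` the gap acts as a fifth state for identity.
#' Labels `H1, H2, ...` are assigned by first occurrence in accession order.
#'
#' @inheritParams analyzed_columns
#' @return A list of class `haplotype_assignment`: `haplotype_of`
#'   (accession -> label), `counts` (label -> accession count) and
#'   `sequences` (label -> representative analysed-column string).
#' @export
collapse_haplotypes <- function(aln,
                                gap_policy = c("exclude_gap_columns",
                                               "include_gaps")) {
  gap_policy <- match.arg(gap_policy)
  keep <- analyzed_columns(aln, gap_policy)
  if (!any(keep))
    stop("no alignment columns left after applying the gap policy")
  mat <- unclass(aln)[, keep, drop = FALSE]
  key <- apply(mat, 1L, paste, collapse = "")
  lab <- match(key, unique(key))
  labels <- paste0("H", lab)
  counts <- table(factor(labels, levels = paste0("H", seq_along(unique(key)))))
  reps <- stats::setNames(unique(key), paste0("H", seq_along(unique(key))))
  structure(list(haplotype_of = stats::setNames(labels, rownames(aln)),
                 counts = stats::setNames(as.integer(counts), names(counts)),
                 sequences = reps,
                 gap_policy = gap_policy),
            class = "haplotype_assignment")
}

#' @export
print.haplotype_assignment <- function(x, ...) {
  cat(length(x$counts), "haplotypes over", sum(x$counts), "accessions\n")
  print(x$counts)
  invisible(x)
}

#' Segregating sites and per-genotype polymorphic-site counts
#'
#' `S` counts analysed columns with at least two distinct bases. The
#' per-genotype count is the number of analysed columns at which that
#' accession differs from the strict-majority consensus base (ties broken
#' to the alphabetically first base), the per-accession reading of
#' "polymorphic sites per genotype".
#'
#' @inheritParams analyzed_columns
#' @return List with `S`, `per_genotype` (named counts) and `consensus`
#'   (character vector over the analysed columns).
#' @export
polymorphic_sites <- function(aln,
                              gap_policy = c("exclude_gap_columns",
                                             "include_gaps")) {
  gap_policy <- match.arg(gap_policy)
  stopifnot(nrow(aln) >= 2)
  keep <- analyzed_columns(aln, gap_policy)
  if (!any(keep))
    stop("no alignment columns left after applying the gap policy")
  mat <- unclass(aln)[, keep, drop = FALSE]
  segregating <- apply(mat, 2L, function(col) length(unique(col)) > 1L)
  consensus <- apply(mat, 2L, function(col) {
    tab <- table(col)
    names(tab)[which.max(tab)]  # which.max takes the first = alphabetical tie
  })
  per <- apply(mat, 1L, function(s) sum(s != consensus))
  list(S = sum(segregating),
       per_genotype = per,
       consensus = consensus)
}

#' Nucleotide diversity (pi)
#'
#' Average per-site pairwise difference over the analysed columns:
#' `pi = 2/(n(n-1)) * sum_{i<j} d_ij / L`, with `d_ij` the Hamming distance
#' between sequences i and j restricted to analysed columns and `L` the
#' analysed-column count.
#'
#' @inheritParams analyzed_columns
#' @return A single numeric value.
#' @export
nucleotide_diversity <- function(aln,
                                 gap_policy = c("exclude_gap_columns",
                                                "include_gaps")) {
  gap_policy <- match.arg(gap_policy)
  n <- nrow(aln)
  stopifnot(n >= 2)
  keep <- analyzed_columns(aln, gap_policy)
  if (!any(keep))
    stop("no analysed columns: pi undefined")
  mat <- unclass(aln)[, keep, drop = FALSE]
  L <- ncol(mat)
  total <- 0
  for (i in seq_len(n - 1)) {
    for (j in seq.int(i + 1, n)) {
      total <- total + sum(mat[i, ] != mat[j, ])
    }
  }
  2 * total / (n * (n - 1)) / L
}

#' Haplotype diversity (Hd)
#'
#' Small-sample-corrected probability that two random accessions carry
#' different haplotypes: `Hd = n/(n-1) * (1 - sum p_i^2)`.
#'
#' @param ha A `haplotype_assignment` from [collapse_haplotypes()], or a
#'   bare vector of haplotype accession counts.
#' @return A value in `[0, 1]`.
#' @export
haplotype_diversity <- function(ha) {
  counts <- if (inherits(ha, "haplotype_assignment")) ha$counts else ha
  n <- sum(counts)
  if (n < 2) stop("haplotype diversity requires at least 2 accessions")
  p <- counts / n
  n / (n - 1) * (1 - sum(p^2))
}

#' Pairwise genetic distance matrix
#'
#' Distances over the analysed columns. `p` is the proportion of differing
#' columns; `K2P` is the Kimura two-parameter distance
#' `-1/2 log((1-2P-Q) sqrt(1-2Q))` with `P` and `Q` the transition and
#' transversion proportions. A K2P logarithm argument outside its domain
#' raises an error naming the offending pair.
#'
#' @inheritParams analyzed_columns
#' @param model `"p"` (default) or `"K2P"`.
#' @return A symmetric numeric matrix with zero diagonal, accession IDs as
#'   dimnames and the model recorded in attribute `"model"`.
#' @export
distance_matrix <- function(aln, model = c("p", "K2P"),
                            gap_policy = c("exclude_gap_columns",
                                           "include_gaps")) {
  model <- match.arg(model)
  gap_policy <- match.arg(gap_policy)
  n <- nrow(aln)
  stopifnot(n >= 2)
  keep <- analyzed_columns(aln, gap_policy)
  if (!any(keep)) stop("no analysed columns: distances undefined")
  mat <- unclass(aln)[, keep, drop = FALSE]
  L <- ncol(mat)
  ids <- rownames(aln)
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  purines <- c("A", "G")
  for (i in seq_len(n - 1)) {
    for (j in seq.int(i + 1, n)) {
      diff <- mat[i, ] != mat[j, ]
      if (model == "p") {
        dij <- sum(diff) / L
      } else {
        a <- mat[i, diff]; b <- mat[j, diff]
        ts <- sum((a %in% purines) == (b %in% purines))
        P <- ts / L
        Q <- (sum(diff) - ts) / L
        arg1 <- 1 - 2 * P - Q
        arg2 <- 1 - 2 * Q
        if (arg1 <= 0 || arg2 <= 0)
          stop("K2P distance undefined for pair ", ids[i], " / ", ids[j],
               ": log argument out of domain")
        dij <- -0.5 * log(arg1 * sqrt(arg2))
      }
      d[i, j] <- d[j, i] <- dij
    }
  }
  attr(d, "model") <- model
  d
}

#' Neighbor-joining tree
#'
#' Saitou-Nei agglomeration of a pairwise distance matrix (via
#' [ape::nj()]), post-processed so that negative branch lengths are clamped
#' to zero with the negative amount transferred to the adjacent branch,
#' keeping root-to-tip path lengths approximately unchanged. On additive
#' matrices the generating tree is recovered exactly.
#'
#' @param dm Symmetric distance matrix with zero diagonal (e.g. from
#'   [distance_matrix()]).
#' @return An [ape] `phylo` object (unrooted), serialisable with
#'   [ape::write.tree()].
#' @export
nj_tree <- function(dm) {
  dm <- as.matrix(dm)
  if (nrow(dm) < 3) stop("neighbor-joining requires at least 3 taxa")
  if (!isSymmetric(unname(dm), tol = 1e-8))
    stop("distance matrix must be symmetric")
  tr <- ape::nj(dm)
  clamp_negative_branches(tr)
}

## Zero out negative branch lengths, pushing the deficit onto the adjacent
## branch (descendant edges of the child node if any, else the sibling).
clamp_negative_branches <- function(tr, max_iter = 10L) {
  for (iter in seq_len(max_iter)) {
    neg <- which(tr$edge.length < -1e-12)
    if (!length(neg)) break
    e <- neg[which.min(tr$edge.length[neg])]
    w <- tr$edge.length[e]
    tr$edge.length[e] <- 0
    child <- tr$edge[e, 2]
    adj <- which(tr$edge[, 1] == child)
    if (!length(adj))
      adj <- setdiff(which(tr$edge[, 1] == tr$edge[e, 1]), e)
    if (length(adj))
      tr$edge.length[adj] <- tr$edge.length[adj] + w / length(adj)
  }
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

#' Minimum-spanning haplotype network
#'
#' Builds the union of all minimum spanning trees (epsilon = 0
#' minimum-spanning network) over haplotypes, with Hamming-distance
#' mutational steps as edge weights: an edge is retained exactly when its
#' endpoints are disconnected in the subgraph of strictly lighter edges.
#'
#' @param ha A `haplotype_assignment` from [collapse_haplotypes()] (its
#'   representative sequences provide the distances), or a list with
#'   `counts` and `sequences`.
#' @return A list of class `haplo_network` with `nodes` (data frame
#'   `haplotype`, `freq`) and `edges` (data frame `from`, `to`, `steps`).
#' @export
haplotype_network <- function(ha) {
  counts <- ha$counts
  seqs <- ha$sequences
  stopifnot(!is.null(counts), !is.null(seqs),
            identical(names(counts), names(seqs)))
  k <- length(seqs)
  nodes <- data.frame(haplotype = names(counts),
                      freq = as.integer(counts),
                      stringsAsFactors = FALSE)
  if (k == 1)
    return(structure(list(nodes = nodes,
                          edges = data.frame(from = character(0),
                                             to = character(0),
                                             steps = integer(0))),
                     class = "haplo_network"))
  smat <- matrix(unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE),
                 nrow = k, byrow = TRUE)
  pairs <- utils::combn(k, 2)
  w <- apply(pairs, 2L, function(p) sum(smat[p[1], ] != smat[p[2], ]))
  edges <- data.frame(from = names(seqs)[pairs[1, ]],
                      to = names(seqs)[pairs[2, ]],
                      steps = as.integer(w), stringsAsFactors = FALSE)
  keep <- logical(nrow(edges))
  for (wt in sort(unique(edges$steps))) {
    lighter <- edges[edges$steps < wt, , drop = FALSE]
    g <- igraph::graph_from_data_frame(lighter, directed = FALSE,
                                       vertices = nodes$haplotype)
    comp <- igraph::components(g)$membership
    at <- which(edges$steps == wt)
    keep[at] <- comp[edges$from[at]] != comp[edges$to[at]]
  }
  structure(list(nodes = nodes,
                 edges = edges[keep, , drop = FALSE]),
            class = "haplo_network")
}

#' @export
print.haplo_network <- function(x, ...) {
  cat("haplotype network:", nrow(x$nodes), "haplotypes,",
      nrow(x$edges), "edges\n")
  invisible(x)
}

#' Full sequence-diversity summary
#'
#' Convenience wrapper computing GC content, segregating and per-genotype
#' polymorphic sites, nucleotide diversity, haplotype collapse and
#' diversity, the distance matrix, NJ tree and haplotype network in one
#' pass.
#'
#' @inheritParams distance_matrix
#' @return A list of class `seqdiv_summary`.
#' @export
seqdiv_summary <- function(aln, model = "p",
                           gap_policy = "exclude_gap_columns") {
  gc <- gc_content(aln)
  poly <- polymorphic_sites(aln, gap_policy)
  ha <- collapse_haplotypes(aln, gap_policy)
  dm <- distance_matrix(aln, model, gap_policy)
  structure(list(
    mean_gc = gc$mean,
    gc_per_sequence = gc$per_sequence,
    segregating_sites = poly$S,
    per_genotype_polymorphic_sites = poly$per_genotype,
    nucleotide_diversity = nucleotide_diversity(aln, gap_policy),
    haplotypes = ha,
    n_haplotypes = length(ha$counts),
    haplotype_diversity = haplotype_diversity(ha),
    distance_matrix = dm,
    tree = nj_tree(dm),
    network = haplotype_network(ha)),
    class = "seqdiv_summary")
}

#' @export
print.seqdiv_summary <- function(x, ...) {
  cat("Sequence diversity summary\n")
  cat(sprintf("  mean GC:            %.4f\n", x$mean_gc))
  cat(sprintf("  segregating sites:  %d\n", x$segregating_sites))
  cat(sprintf("  nucleotide div. pi: %.5f\n", x$nucleotide_diversity))
  cat(sprintf("  haplotypes:         %d (Hd = %.4f)\n",
              x$n_haplotypes, x$haplotype_diversity))
  invisible(x)
}
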