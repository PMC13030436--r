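#' Configuration for the synthetic ITS alignment generator
#'
#' Defines the haplotype-sharing structure the generator must realise. The
#' defaults are the study conditions of the host-screening system: 31
#' accessions, ~644 bp ITS, GC fraction 0.5835, 22 haplotypes with sharing
#' counts \{5, 3, 2, 2, 2\} plus 17 singletons, and one 1-bp plus one 2-bp
#' deletion carried by individual haplotypes.
#'
#' Each non-reference haplotype is distinguished by a private set of
#' substitution sites, so `n_variable_sites` must be at least
#' `length(sharing_multiset) - 1`. `private_site_counts` (one entry per
#' haplotype, summing to `n_variable_sites`) controls how many private
#' substitutions each haplotype carries; at most one haplotype (the
#' reference, by default the first) may carry none.
#'
#' @param n_accessions Number of accessions (rows of the alignment).
#' @param seq_length Alignment length in bp.
#' @param gc_target Target GC fraction of the ungapped consensus, in (0,1).
#' @param sharing_multiset Integer vector of accession counts per haplotype;
#'   must sum to `n_accessions`.
#' @param n_variable_sites Total number of substitution columns.
#' @param private_site_counts Optional integer vector (length = number of
#'   haplotypes) of private substitution sites per haplotype; defaults to an
#'   even split over haplotypes 2..k with haplotype 1 as the reference.
#' @param indel_spec List of deletions, each `list(width =, carrier =)` with
#'   width 1 or 2 bp and `carrier` a haplotype index. Defaults to a 1-bp
#'   deletion on haplotype 2 and a 2-bp deletion on haplotype 3 when the
#'   configuration has enough haplotypes.
#' @param accession_ids Optional character vector of accession IDs; defaults
#'   to [sequencing_panel()] IDs when `n_accessions == 31`, else `A01...`.
#' @param seed Integer seed; the generator is deterministic given the seed.
#' @return A validated list of class `haplo_config`.
#' @seealso [generate_its_alignment()]
#' @export
haplo_config <- function(n_accessions = 31L,
                         seq_length = 644L,
                         gc_target = 0.5835,
                         sharing_multiset = c(5L, 3L, 2L, 2L, 2L, rep(1L, 17)),
                         n_variable_sites = 40L,
                         private_site_counts = NULL,
                         indel_spec = NULL,
                         accession_ids = NULL,
                         seed = 1L) {
  k <- length(sharing_multiset)
  if (k < 1 || any(sharing_multiset < 1))
    stop("sharing_multiset must contain positive accession counts")
  if (sum(sharing_multiset) != n_accessions)
    stop("sharing_multiset sums to ", sum(sharing_multiset),
         " but n_accessions is ", n_accessions)
  if (gc_target <= 0 || gc_target >= 1)
    stop("gc_target must lie strictly inside (0, 1)")
  if (n_variable_sites < k - 1)
    stop("n_variable_sites (", n_variable_sites, ") is too small to ",
         "separate ", k, " haplotypes; need at least ", k - 1)
  if (k == 1 && n_variable_sites != 0)
    stop("a single-haplotype configuration admits no variable sites")

  if (is.null(private_site_counts)) {
    private_site_counts <- integer(k)
    if (k > 1) {
      base <- n_variable_sites %/% (k - 1)
      extra <- n_variable_sites %% (k - 1)
      private_site_counts[-1] <- base + c(rep(1L, extra), rep(0L, k - 1 - extra))
    }
  }
  if (length(private_site_counts) != k)
    stop("private_site_counts must have one entry per haplotype")
  if (sum(private_site_counts) != n_variable_sites)
    stop("private_site_counts must sum to n_variable_sites")
  if (sum(private_site_counts == 0) > 1)
    stop("at most one haplotype (the reference) may carry zero private sites")

  if (is.null(indel_spec)) {
    indel_spec <- list()
    if (k >= 2) indel_spec <- c(indel_spec, list(list(width = 1L, carrier = 2L)))
    if (k >= 3) indel_spec <- c(indel_spec, list(list(width = 2L, carrier = 3L)))
  }
  for (spec in indel_spec) {
    if (!all(c("width", "carrier") %in% names(spec)))
      stop("each indel_spec entry needs `width` and `carrier`")
    if (!spec$width %in% c(1L, 2L))
      stop("indel widths are restricted to 1 or 2 bp")
    if (spec$carrier < 1 || spec$carrier > k)
      stop("indel carrier ", spec$carrier, " is not a haplotype index")
  }
  n_indel_cols <- sum(vapply(indel_spec, `[[`, numeric(1), "width"))
  if (n_indel_cols + n_variable_sites > seq_length)
    stop("seq_length too short for the requested variable and indel columns")

  if (is.null(accession_ids)) {
    accession_ids <- if (n_accessions == 31L) sequencing_panel()$id
                     else sprintf("A%02d", seq_len(n_accessions))
  }
  if (length(accession_ids) != n_accessions || anyDuplicated(accession_ids))
    stop("accession_ids must supply ", n_accessions, " unique IDs")

  structure(list(n_accessions = as.integer(n_accessions),
                 seq_length = as.integer(seq_length),
                 gc_target = gc_target,
                 sharing_multiset = as.integer(sharing_multiset),
                 n_variable_sites = as.integer(n_variable_sites),
                 private_site_counts = as.integer(private_site_counts),
                 indel_spec = indel_spec,
                 accession_ids = accession_ids,
                 seed = as.integer(seed)),
            class = "haplo_config")
}

#' Generate a synthetic ITS alignment with known haplotype structure
#'
#' Builds a gapped alignment whose distinct sequences (under the default
#' gap policy of [collapse_haplotypes()]) realise exactly the configured
#' sharing multiset. The consensus base composition hits the GC target by
#' construction (GC positions are counted out exactly, then placed at
#' random); each non-reference haplotype carries its configured number of
#' private substitutions, drawn to preserve the target composition in
#' expectation; deletions are realised as `-` runs in carrier haplotypes.
#'
#' @param cfg A [haplo_config].
#' @return A list with elements `alignment` (an [its_alignment]) and
#'   `assignment`, the true haplotype assignment: a list with
#'   `haplotype_of` (accession -> label, labelled `H1...` by first
#'   occurrence), `counts` (label -> accession count) and `sequences`
#'   (label -> full gapped haplotype string).
#' @examples
#' sim <- generate_its_alignment(haplo_config(seed = 7))
#' length(sim$assignment$counts)  # 22 haplotypes
#' @export
generate_its_alignment <- function(cfg) {
  stopifnot(inherits(cfg, "haplo_config"))
  withr::with_seed(cfg$seed, {
    k <- length(cfg$sharing_multiset)
    L <- cfg$seq_length

    ## deletion columns: non-overlapping runs placed left to right
    indel_cols <- list()
    used <- integer(0)
    offset <- 0L
    for (spec in cfg$indel_spec) {
      w <- spec$width
      start <- sample(seq.int(offset + 1L, L - w + 1L - 10L), 1L)
      cols <- seq.int(start, start + w - 1L)
      indel_cols <- c(indel_cols, list(list(cols = cols, carrier = spec$carrier)))
      used <- c(used, cols)
      offset <- max(cols)
    }

    ## consensus with exact GC count
    n_gc <- round(cfg$gc_target * L)
    gc_pos <- sample.int(L, n_gc)
    base <- character(L)
    base[gc_pos] <- sample(c("G", "C"), n_gc, replace = TRUE)
    base[-gc_pos] <- sample(c("A", "T"), L - n_gc, replace = TRUE)

    ## private substitution sites per haplotype
    free_cols <- setdiff(seq_len(L), used)
    var_sites <- sample(free_cols, cfg$n_variable_sites)
    owner <- rep.int(seq_len(k), cfg$private_site_counts)

    hap_seqs <- matrix(rep(base, each = k), nrow = k)
    comp <- c(A = (1 - cfg$gc_target) / 2, C = cfg$gc_target / 2,
              G = cfg$gc_target / 2, T = (1 - cfg$gc_target) / 2)
    for (i in seq_along(var_sites)) {
      site <- var_sites[i]
      cur <- base[site]
      alt <- setdiff(names(comp), cur)
      hap_seqs[owner[i], site] <- sample(alt, 1L, prob = comp[alt])
    }
    for (spec in indel_cols) hap_seqs[spec$carrier, spec$cols] <- "-"

    ## accessions -> haplotypes (seeded shuffle of the sharing multiset)
    hap_of <- sample(rep.int(seq_len(k), cfg$sharing_multiset))
    seqs <- apply(hap_seqs, 1L, paste, collapse = "")[hap_of]
    names(seqs) <- cfg$accession_ids
    aln <- its_alignment(seqs)

    ## canonical labels by first occurrence among accessions
    first <- order(match(seq_len(k), hap_of))
    label <- character(k)
    label[first] <- paste0("H", seq_len(k))
    haplotype_of <- stats::setNames(label[hap_of], cfg$accession_ids)
    counts <- stats::setNames(cfg$sharing_multiset[first], label[first])
    hseq <- stats::setNames(apply(hap_seqs, 1L, paste, collapse = "")[first],
                            label[first])
    attr(aln, "seed") <- cfg$seed
    list(alignment = aln,
         assignment = list(haplotype_of = haplotype_of,
                           counts = counts,
                           sequences = hseq))
  })
}
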