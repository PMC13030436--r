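test_that("GC content ignores gaps and flags empty sequences", {
  aln <- its_alignment(c(a = "GGCC", b = "AT-G"))
  gc <- gc_content(aln)
  expect_equal(unname(gc$per_sequence), c(1, 1 / 3))
  expect_equal(gc$mean, (1 + 1 / 3) / 2)
  expect_error(gc_content(its_alignment(c(a = "ACGT", b = "----"))), "b")
})

test_that("haplotype collapse follows the gap-column policy", {
  aln <- its_alignment(c(s1 = "ACGT", s2 = "ACGA", s3 = "AC-T"))
  ha <- collapse_haplotypes(aln)
  # column 3 carries the gap and is dropped; projections ACT, ACA, ACT
  expect_identical(length(ha$counts), 2L)
  expect_identical(unname(ha$counts), c(2L, 1L))
  expect_identical(unname(ha$haplotype_of), c("H1", "H2", "H1"))
  # with gaps as a fifth state all three are distinct
  expect_identical(length(collapse_haplotypes(aln, "include_gaps")$counts), 3L)

  same <- its_alignment(stats::setNames(rep("ACGT", 4), paste0("s", 1:4)))
  expect_identical(unname(collapse_haplotypes(same)$counts), 4L)
})

test_that("haplotype collapse is idempotent under accession reordering", {
  sim <- generate_its_alignment(haplo_config(seed = 31))
  aln <- sim$alignment
  perm <- withr::with_seed(1, sample(nrow(aln)))
  shuffled <- its_alignment(aln_sequences(aln)[perm])
  ha1 <- collapse_haplotypes(aln)
  ha2 <- collapse_haplotypes(shuffled)
  expect_identical(sort(as.integer(ha1$counts)), sort(as.integer(ha2$counts)))
  # same partition: accessions sharing a haplotype in one do so in the other
  ids <- aln_ids(aln)
  part1 <- split(ids, ha1$haplotype_of[ids])
  part2 <- split(ids, ha2$haplotype_of[ids])
  expect_setequal(unname(vapply(part1, paste, "", collapse = ",")),
                  unname(vapply(part2, paste, "", collapse = ",")))
})

test_that("segregating sites and per-genotype counts match a column-scan oracle", {
  same <- its_alignment(stats::setNames(rep("ACGT", 3), paste0("s", 1:3)))
  ps0 <- polymorphic_sites(same)
  expect_identical(ps0$S, 0L)
  expect_true(all(ps0$per_genotype == 0))

  aln <- its_alignment(c(s1 = "AAAA", s2 = "AAAT", s3 = "AATT"))
  ps <- polymorphic_sites(aln)
  # independent column scan
  mat <- do.call(rbind, strsplit(c("AAAA", "AAAT", "AATT"), ""))
  seg <- sum(apply(mat, 2, function(col) length(unique(col)) > 1))
  cons <- apply(mat, 2, function(col) {
    tab <- sort(table(col), decreasing = TRUE)
    cand <- names(tab)[tab == max(tab)]
    sort(cand)[1]
  })
  expect_identical(ps$S, seg)
  expect_identical(unname(ps$per_genotype),
                   apply(mat, 1, function(s) sum(s != cons)))
  expect_identical(paste(ps$consensus, collapse = ""), "AAAT")
})

test_that("a haplotype's private substitutions appear as its polymorphic-site count", {
  counts <- c(0L, 13L, rep(3L, 9))  # 11 haplotypes, one carrying 13
  cfg <- haplo_config(n_accessions = 20,
                      sharing_multiset = c(10L, rep(1L, 10)),
                      n_variable_sites = sum(counts),
                      private_site_counts = counts,
                      accession_ids = sprintf("A%02d", 1:20),
                      seed = 3)
  sim <- generate_its_alignment(cfg)
  ps <- polymorphic_sites(sim$alignment)
  expect_identical(max(ps$per_genotype), 13L)
  expect_identical(sum(ps$per_genotype == 13L), 1L)
  # the reference haplotype's accessions sit at zero differences
  expect_identical(sum(ps$per_genotype == 0L), 10L)
})

test_that("nucleotide diversity equals the brute-force pairwise oracle", {
  two <- its_alignment(c(a = "ACGT", b = "ACGA"))
  expect_equal(nucleotide_diversity(two), 0.25)
  same <- its_alignment(stats::setNames(rep("ACGT", 3), paste0("s", 1:3)))
  expect_equal(nucleotide_diversity(same), 0)

  withr::with_seed(7, {
    seqs <- vapply(1:5, function(i)
      paste(sample(c("A", "C", "G", "T"), 10, replace = TRUE), collapse = ""),
      character(1))
  })
  names(seqs) <- paste0("s", 1:5)
  aln <- its_alignment(seqs)
  expect_equal(nucleotide_diversity(aln), brute_pi(seqs))
})

test_that("haplotype diversity matches the small-sample formula", {
  expect_equal(haplotype_diversity(c(1, 1)), 1)
  expect_equal(haplotype_diversity(c(5)), 0)
  expect_error(haplotype_diversity(c(1)), "at least 2")
  # frozen arithmetic for the study sharing multiset {5,3,2,2,2,1x17}, n=31
  expect_equal(haplotype_diversity(c(5, 3, 2, 2, 2, rep(1, 17))),
               0.9655913978, tolerance = 1e-9)
})

test_that("genetic distances match closed forms and ape's implementations", {
  pair0 <- its_alignment(c(a = "ACGT", b = "ACGT"))
  expect_equal(unname(distance_matrix(pair0)["a", "b"]), 0)
  expect_equal(unname(distance_matrix(pair0, "K2P")["a", "b"]), 0)

  # one transition (A<->G) among 100 columns
  s <- strrep("AC", 50)
  s2 <- paste0("G", substr(s, 2, 100))
  pair <- its_alignment(c(a = s, b = s2))
  expect_equal(unname(distance_matrix(pair)["a", "b"]), 0.01)
  expect_equal(unname(distance_matrix(pair, "K2P")["a", "b"]),
               0.01010135366, tolerance = 1e-9)

  # saturated pair: K2P domain violation names the pair
  sat <- its_alignment(c(x = "AAAA", y = "GGGG"))
  expect_error(distance_matrix(sat, "K2P"), "x / y")

  withr::with_seed(12, {
    base <- sample(c("A", "C", "G", "T"), 200, replace = TRUE)
    seqs <- vapply(1:6, function(i) {
      s <- base
      at <- sample(200, 8)
      s[at] <- vapply(s[at], function(ch)
        sample(setdiff(c("A", "C", "G", "T"), ch), 1), character(1))
      paste(s, collapse = "")
    }, character(1))
  })
  names(seqs) <- paste0("t", 1:6)
  aln <- its_alignment(seqs)
  dp <- distance_matrix(aln, "p")
  expect_true(isSymmetric(unname(dp)))
  expect_true(all(diag(dp) == 0))
  dnab <- ape::as.DNAbin(do.call(rbind, strsplit(tolower(seqs), "")))
  expect_equal(unclass(dp)[lower.tri(dp)],
               as.vector(ape::dist.dna(dnab, model = "raw")),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(unclass(distance_matrix(aln, "K2P"))[lower.tri(dp)],
               as.vector(ape::dist.dna(dnab, model = "K80")),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("neighbor joining solves the three-taxon closed form", {
  d <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3, 3,
              dimnames = list(letters[1:3], letters[1:3]))
  tr <- nj_tree(d)
  co <- ape::cophenetic.phylo(tr)[letters[1:3], letters[1:3]]
  expect_equal(co, d, ignore_attr = TRUE)
  # leaf branch lengths solve the three-point formulas
  lens <- tr$edge.length[match(1:3, tr$edge[, 2])]
  names(lens) <- tr$tip.label
  expect_equal(unname(lens[letters[1:3]]), c(1, 2, 3))
})

test_that("neighbor joining round-trips additive matrices and ignores row order", {
  withr::with_seed(99, {
    gen <- rand_additive(4)
  })
  tr <- nj_tree(gen$d)
  expect_equal(ape::cophenetic.phylo(tr)[rownames(gen$d), colnames(gen$d)],
               gen$d, tolerance = 1e-8, ignore_attr = TRUE)

  perm <- c(3, 1, 4, 2)
  tr2 <- nj_tree(gen$d[perm, perm])
  expect_equal(as.numeric(ape::dist.topo(ape::unroot(tr), ape::unroot(tr2))),
               0)
  expect_equal(sum(tr$edge.length), sum(tr2$edge.length), tolerance = 1e-8)

  bad <- gen$d; bad[1, 2] <- bad[1, 2] + 1
  expect_error(nj_tree(bad), "symmetric")
})

test_that("the haplotype network keeps exactly the minimum-spanning-tree edges", {
  one <- list(counts = c(H1 = 5L), sequences = c(H1 = "AAAA"))
  net1 <- haplotype_network(one)
  expect_identical(nrow(net1$edges), 0L)
  expect_identical(net1$nodes$freq, 5L)

  # three haplotypes at mutual distance 1: every edge lies in some MST
  tri <- list(counts = c(A = 1L, B = 1L, C = 1L),
              sequences = c(A = "AAA", B = "AAT", C = "AAG"))
  expect_identical(nrow(haplotype_network(tri)$edges), 3L)

  # chain A-B-C: the long A-C edge is in no MST
  chain <- list(counts = c(A = 1L, B = 2L, C = 1L),
                sequences = c(A = "AAA", B = "AAT", C = "ATT"))
  net <- haplotype_network(chain)
  expect_identical(nrow(net$edges), 2L)
  expect_setequal(paste(net$edges$from, net$edges$to),
                  c("A B", "B C"))
})

test_that("network frequencies sum to accessions and the graph spans all haplotypes", {
  sim <- generate_its_alignment(haplo_config(seed = 13))
  ha <- collapse_haplotypes(sim$alignment)
  net <- haplotype_network(ha)
  expect_identical(sum(net$nodes$freq), 31L)
  g <- igraph::graph_from_data_frame(net$edges, directed = FALSE,
                                     vertices = net$nodes$haplotype)
  expect_equal(igraph::components(g)$no, 1)
  # a spanning tree survives inside the retained edge set
  mst <- igraph::mst(igraph::set_edge_attr(g, "weight",
                                           value = net$edges$steps))
  expect_equal(igraph::ecount(mst), nrow(net$nodes) - 1)
})

test_that("the full-panel summary reproduces the configured structure", {
  sim <- generate_its_alignment(haplo_config(seed = 17))
  sdv <- seqdiv_summary(sim$alignment)
  expect_identical(sdv$n_haplotypes, 22L)
  expect_equal(sdv$haplotype_diversity, 898 / 930)
  expect_lt(abs(sdv$mean_gc - 0.5835), 0.02)
  expect_identical(sdv$segregating_sites, 40L)
  # pi equals the mean pairwise p-distance (cross-operation consistency)
  dp <- sdv$distance_matrix
  expect_equal(sdv$nucleotide_diversity, mean(dp[lower.tri(dp)]))
})
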