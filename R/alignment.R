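#' Aligned ITS sequence set
#'
#' Light container for a gapped multiple alignment: one row per accession,
#' equal-length sequences over the alphabet `A, C, G, T, -, N`. Lowercase
#' input is normalised to uppercase; accession IDs must be unique.
#'
#' @param seqs Named character vector of equal-length aligned sequences.
#' @return An object of class `its_alignment` (a single-character matrix
#'   with accession IDs as row names).
#' @examples
#' aln <- its_alignment(c(a = "ACGT", b = "AC-T"))
#' aln_length(aln)
#' @export
its_alignment <- function(seqs) {
  if (!is.character(seqs) || length(seqs) == 0)
    stop("`seqs` must be a non-empty character vector")
  ids <- names(seqs)
  if (is.null(ids) || any(!nzchar(ids)))
    stop("every sequence must carry a non-empty accession ID")
  if (anyDuplicated(ids))
    stop("duplicated accession IDs: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  seqs <- toupper(seqs)
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L)
    stop("sequences are not aligned: lengths differ (",
         paste(range(lens), collapse = "-"), ")")
  mat <- matrix(unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE),
                nrow = length(seqs), byrow = TRUE,
                dimnames = list(ids, NULL))
  bad <- setdiff(unique(as.vector(mat)), c("A", "C", "G", "T", "-", "N"))
  if (length(bad))
    stop("disallowed characters in alignment: ", paste(bad, collapse = ", "))
  structure(mat, class = c("its_alignment", "matrix"))
}

#' @export
print.its_alignment <- function(x, ...) {
  cat("ITS alignment:", nrow(x), "accessions x", ncol(x), "columns\n")
  gap <- sum(x == "-")
  cat("  gap characters:", gap, "\n")
  invisible(x)
}

#' @rdname its_alignment
#' @param aln An `its_alignment`.
#' @export
aln_ids <- function(aln) rownames(aln)

#' @rdname its_alignment
#' @export
aln_length <- function(aln) ncol(aln)

#' @rdname its_alignment
#' @export
aln_sequences <- function(aln) {
  out <- apply(unclass(aln), 1L, paste, collapse = "")
  stats::setNames(out, rownames(aln))
}

#' Columns retained for analysis under a gap policy
#'
#' The default policy mirrors DnaSP-style complete deletion: any column
#' containing a gap (`-`) or an ambiguous base (`N`) in any sequence is
#' dropped from all diversity statistics. Under `include_gaps` every column
#' is kept and `-` acts as a fifth character state (used for haplotype
#' identity only).
#'
#' @param aln An [its_alignment].
#' @param gap_policy `"exclude_gap_columns"` (default) or `"include_gaps"`.
#' @return Logical vector over alignment columns (`TRUE` = analysed).
#' @export
analyzed_columns <- function(aln,
                             gap_policy = c("exclude_gap_columns",
                                            "include_gaps")) {
  gap_policy <- match.arg(gap_policy)
  if (gap_policy == "include_gaps") return(rep(TRUE, ncol(aln)))
  apply(unclass(aln), 2L, function(col) !any(col %in% c("-", "N")))
}

#' Read / write an aligned FASTA file
#'
#' Thin wrappers over [ape::read.FASTA()] / [ape::write.FASTA()] that
#' enforce the alignment contract (equal lengths, restricted alphabet,
#' unique IDs).
#'
#' @param path Path to a FASTA file.
#' @return [read_alignment()] returns an [its_alignment];
#'   [write_alignment()] returns `path` invisibly.
#' @export
read_alignment <- function(path) {
  dna <- ape::read.FASTA(path)
  chars <- as.character(dna)
  seqs <- vapply(chars, paste, character(1), collapse = "")
  its_alignment(seqs)
}

#' @rdname read_alignment
#' @param aln An [its_alignment].
#' @export
write_alignment <- function(aln, path) {
  mat <- unclass(aln)
  dimnames(mat) <- list(rownames(aln), NULL)
  ape::write.FASTA(ape::as.DNAbin(tolower(mat)), path)
  invisible(path)
}
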