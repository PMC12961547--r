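#' Lineage-exclusive substitutions in an aligned protein set
#'
#' Scans an aligned set of orthologous protein sequences (e.g. TF DNA-binding
#' domains) for alignment columns where every non-focal taxon carries one and
#' the same residue while the focal taxon carries a different one — the
#' decision kernel of a screen for taxon-exclusive amino-acid changes.
#' Columns containing any gap are skipped.
#'
#' @param aln Named character vector of equal-length aligned sequences
#'   (names = taxa), or a tibble with `taxon` and `seq`.
#' @param focal_taxon Name of the focal taxon.
#' @return Tibble `column` (1-based alignment coordinate), `focal_residue`,
#'   `consensus_residue`.
#' @examples
#' aln <- c(mouse = "MKRAQ", rat = "MKRTQ", human = "MKRTQ", chicken = "MKRTQ")
#' find_exclusive_substitutions(aln, "mouse")
#' @export
find_exclusive_substitutions <- function(aln, focal_taxon) {
  aln <- as_alignment(aln)
  if (!focal_taxon %in% names(aln)) {
    abort(sprintf("focal taxon '%s' not in alignment", focal_taxon))
  }
  if (length(aln) < 3) abort("at least 3 taxa required")
  mat <- alignment_matrix(aln)
  focal <- mat[focal_taxon, ]
  others <- mat[setdiff(rownames(mat), focal_taxon), , drop = FALSE]
  gap <- c("-", ".")
  no_gap <- !focal %in% gap &
    apply(others, 2, function(col) !any(col %in% gap))
  consensus_ok <- apply(others, 2, function(col) length(unique(col)) == 1L)
  hit <- which(no_gap & consensus_ok & focal != others[1, ])
  tibble(column = hit, focal_residue = unname(focal[hit]),
         consensus_residue = unname(others[1, hit]))
}

#' Pairwise percent-identity table of an alignment
#'
#' Identity over mutually ungapped columns for every pair of rows; the matrix
#' is symmetric with 100 on the diagonal.
#'
#' @inheritParams find_exclusive_substitutions
#' @return Numeric taxa x taxa matrix of percent identities.
#' @export
pairwise_identity_table <- function(aln) {
  aln <- as_alignment(aln)
  mat <- alignment_matrix(aln)
  n <- nrow(mat)
  gap <- c("-", ".")
  out <- matrix(100, n, n, dimnames = list(rownames(mat), rownames(mat)))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j <= i) next
      ok <- !(mat[i, ] %in% gap) & !(mat[j, ] %in% gap)
      out[i, j] <- out[j, i] <-
        if (any(ok)) 100 * mean(mat[i, ok] == mat[j, ok]) else NA_real_
    }
  }
  out
}

#' Read an aligned protein FASTA
#'
#' @param path Path to an aligned (equal-length) protein FASTA.
#' @return Named character vector of aligned sequences.
#' @export
read_protein_alignment <- function(path) {
  ss <- Biostrings::readAAStringSet(path)
  setNames(as.character(ss), names(ss))
}

as_alignment <- function(aln) {
  if (is.data.frame(aln)) aln <- setNames(aln$seq, aln$taxon)
  if (is.null(names(aln)) || anyDuplicated(names(aln))) {
    abort("alignment rows must have unique taxon names")
  }
  if (length(unique(nchar(aln))) != 1L) {
    abort("alignment rows must have equal length")
  }
  toupper(aln)
}

alignment_matrix <- function(aln) {
  mat <- do.call(rbind, strsplit(aln, ""))
  rownames(mat) <- names(aln)
  mat
}
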