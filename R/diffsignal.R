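#' High-confidence peak filter
#'
#' Keeps peaks with `-log10(q-value)` strictly greater than the cutoff
#' (default 4), the filter applied to both ATAC and ChIP peak sets before
#' any differential comparison.
#'
#' @param peaks Tibble with a `qvalue_neglog10` column.
#' @param min_neglog10_q Strict lower bound (default 4).
#' @return The filtered tibble.
#' @examples
#' filter_high_confidence(tibble::tibble(qvalue_neglog10 = c(3.9, 4, 4.1, 10)))
#' @export
filter_high_confidence <- function(peaks, min_neglog10_q = 4) {
  filter(peaks, .data$qvalue_neglog10 > min_neglog10_q)
}

#' Library-size normalisation by total-count scaling
#'
#' Scales each count column so that every library has the mean total count.
#' Within-sample count ratios are preserved exactly.
#'
#' @param counts Tibble of per-feature counts.
#' @param cols Character vector of count column names.
#' @return `counts` with `norm_` columns added for each scaled column.
#' @export
scale_libraries <- function(counts, cols) {
  if (any(purrr::map_lgl(cols, function(cl) any(counts[[cl]] < 0)))) {
    abort("negative counts are not allowed")
  }
  totals <- purrr::map_dbl(cols, function(cl) sum(counts[[cl]]))
  target <- mean(totals)
  for (i in seq_along(cols)) {
    f <- if (totals[i] > 0) target / totals[i] else 1
    counts[[paste0("norm_", cols[i])]] <- counts[[cols[i]]] * f
  }
  counts
}

#' UP/DOWN/COMMON classification of accessibility changes
#'
#' Applies the declared differential rule to a pair of normalised counts per
#' feature: UP when `log2fc > fc_thresh` (condition 2 over condition 1, with
#' pseudocount) and the total normalised count is at least `min_total`; DOWN
#' symmetrically; everything else COMMON.
#'
#' @param counts Tibble with normalised count columns.
#' @param cond1,cond2 Names of the two normalised count columns.
#' @param fc_thresh log2 fold-change threshold (default 1).
#' @param min_total Minimum total normalised count (default 40, inclusive).
#' @param pseudocount Added to each normalised count before log2 (default 1).
#' @return `counts` with `log2fc`, `total` and `change` columns.
#' @examples
#' classify_atac(tibble::tibble(n1 = c(10, 5, 50), n2 = c(80, 30, 50)),
#'               "n1", "n2")
#' @export
classify_atac <- function(counts, cond1 = "norm1", cond2 = "norm2",
                          fc_thresh = 1, min_total = 40, pseudocount = 1) {
  if (any(counts[[cond1]] < 0) || any(counts[[cond2]] < 0)) {
    abort("negative counts are not allowed")
  }
  mutate(counts,
         log2fc = log2((.data[[cond2]] + pseudocount) /
                         (.data[[cond1]] + pseudocount)),
         total = .data[[cond1]] + .data[[cond2]],
         change = case_when(
           .data$log2fc > fc_thresh & .data$total >= min_total ~ "UP",
           .data$log2fc < -fc_thresh & .data$total >= min_total ~ "DOWN",
           TRUE ~ "COMMON"
         ))
}

#' Allele-stronger classification of binding intensity
#'
#' Compares the two alleles' normalised counts per peak at a fold-change
#' threshold (default 2): `A_stronger` when allele A reaches `fold` times
#' allele B (after pseudocount), `B_stronger` symmetrically, otherwise
#' `similar`.
#'
#' @param counts Tibble with per-allele normalised count columns.
#' @param allele_a,allele_b Column names.
#' @param fold Fold-change threshold (default 2).
#' @param pseudocount Added to both counts (default 1).
#' @return `counts` with a `stronger` column.
#' @export
classify_chip_stronger <- function(counts, allele_a = "norm_a",
                                   allele_b = "norm_b", fold = 2,
                                   pseudocount = 1) {
  a <- counts[[allele_a]] + pseudocount
  b <- counts[[allele_b]] + pseudocount
  mutate(counts, stronger = case_when(
    a >= fold * b ~ "A_stronger",
    b >= fold * a ~ "B_stronger",
    TRUE ~ "similar"
  ))
}

#' Binned read density around site summits
#'
#' Counts assigned-read midpoints in fixed-width bins of a `[-flank, flank)`
#' window around each site summit, scaled to reads per million, rows ordered
#' by total signal.
#'
#' @param reads Tibble with `chrom`, `start`, `end` of aligned reads (e.g.
#'   mapped assignments).
#' @param sites Tibble with `peak_id` (or `site_id`), `chrom`, `summit`.
#' @param flank Half-window in bp (default 2000).
#' @param bin_width Bin width in bp (default 100).
#' @param library_size Total reads used for per-million scaling; defaults to
#'   `nrow(reads)`.
#' @return Numeric matrix, one row per site (rownames = site ids), one
#'   column per bin; attribute `bin_start` gives bin offsets.
#' @export
signal_matrix <- function(reads, sites, flank = 2000L, bin_width = 100L,
                          library_size = nrow(reads)) {
  id_col <- if ("peak_id" %in% names(sites)) "peak_id" else "site_id"
  nb <- as.integer(2L * flank / bin_width)
  mat <- matrix(0, nrow(sites), nb,
                dimnames = list(sites[[id_col]], NULL))
  if (nrow(reads) > 0) {
    mid <- (reads$start + reads$end) %/% 2L
    for (i in seq_len(nrow(sites))) {
      rel <- mid[reads$chrom == sites$chrom[i]] - sites$summit[i]
      rel <- rel[rel >= -flank & rel < flank]
      if (!length(rel)) next
      mat[i, ] <- tabulate((rel + flank) %/% bin_width + 1L, nbins = nb)
    }
  }
  scale <- if (library_size > 0) 1e6 / library_size else 1
  mat <- mat * scale
  mat <- mat[order(rowSums(mat), decreasing = TRUE), , drop = FALSE]
  attr(mat, "bin_start") <- seq(-flank, flank - bin_width, by = bin_width)
  mat
}
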