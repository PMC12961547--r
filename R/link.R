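#' Link classified peaks to genes through a TSS-centred window
#'
#' A peak is linked to a gene exactly when its summit falls inside the
#' half-open window `[tss - window/2, tss + window/2)` around the gene's
#' strand-aware transcription start site (60 kb total by default). A peak
#' may link to several genes.
#'
#' @param genes Tibble with `gene_id`, `chrom`, `tss` (0-based, strand-aware
#'   start), optionally `strand`.
#' @param peaks Tibble with `peak_id`, `chrom`, `summit`, and (typically) a
#'   `klass` column carried through.
#' @param window Total window width in bp (default 60000).
#' @return Tibble of links: `gene_id`, `peak_id`, plus any `klass` column of
#'   `peaks`.
#' @examples
#' genes <- tibble::tibble(gene_id = "g1", chrom = "chr1", tss = 50000)
#' peaks <- tibble::tibble(peak_id = "p1", chrom = "chr1", summit = 79999,
#'                         klass = "conserved")
#' link_peaks_to_genes(genes, peaks)
#' @export
link_peaks_to_genes <- function(genes, peaks, window = 60000L) {
  half <- as.integer(window) %/% 2L
  out <- list()
  for (ch in intersect(unique(genes$chrom), unique(peaks$chrom))) {
    g <- filter(genes, .data$chrom == ch)
    p <- filter(peaks, .data$chrom == ch)
    ov <- IRanges::findOverlaps(
      IRanges::IRanges(pmax(g$tss - half, 0L) + 1L, g$tss + half),
      IRanges::IRanges(p$summit + 1L, p$summit + 1L))
    if (!length(ov)) next
    res <- tibble(gene_id = g$gene_id[S4Vectors::queryHits(ov)],
                  peak_id = p$peak_id[S4Vectors::subjectHits(ov)])
    if ("klass" %in% names(p)) res$klass <- p$klass[S4Vectors::subjectHits(ov)]
    out[[ch]] <- res
  }
  if (!length(out)) {
    res <- tibble(gene_id = character(), peak_id = character())
    if ("klass" %in% names(peaks)) res$klass <- character()
    return(res)
  }
  bind_rows(out)
}

#' Peak-class composition per regulation type
#'
#' For each regulation type in {0, 1, 3, 4} (type 2 is excluded because it is
#' represented by a single gene), the proportion of linked peaks falling in
#' each orthology class. A type group with no linked peaks is reported with
#' `NA` proportions, not zeros.
#'
#' @param links Output of [link_peaks_to_genes()] (with `klass`).
#' @param gene_types Tibble with `gene_id` and `type`.
#' @param types Types to report (default `c(0, 1, 3, 4)`).
#' @return Tibble `type`, `klass`, `n`, `prop`; proportions within a type
#'   sum to 1 when any peaks are linked.
#' @export
class_composition_by_type <- function(links, gene_types,
                                      types = c(0L, 1L, 3L, 4L)) {
  klasses <- c("conserved", "loss", "unaligned")
  joined <- inner_join(links, gene_types, by = "gene_id") |>
    filter(.data$type %in% types, !is.na(.data$klass))
  tidyr::expand_grid(type = as.integer(types), klass = klasses) |>
    left_join(count(joined, .data$type, .data$klass), by = c("type", "klass")) |>
    mutate(n = dplyr::coalesce(.data$n, 0L)) |>
    group_by(.data$type) |>
    mutate(prop = if (sum(.data$n) > 0) .data$n / sum(.data$n) else NA_real_) |>
    ungroup()
}
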