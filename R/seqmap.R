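#' Extract summit-centred peak windows
#'
#' Returns the sequence of the window `[summit - flank, summit + flank)` for
#' each peak (400 bp at the default flank of 200). Windows running off a
#' chromosome end are clipped and flagged.
#'
#' @param peaks Tibble with `peak_id`, `chrom`, `summit` (absolute 0-based).
#' @param genome Named character vector of chromosome sequences.
#' @param flank Half-window in bp.
#' @return Tibble `peak_id`, `chrom`, `win_start`, `win_end`, `clipped`,
#'   `seq`.
#' @export
extract_window <- function(peaks, genome, flank = 200L) {
  bad <- setdiff(unique(peaks$chrom), names(genome))
  if (length(bad)) {
    abort(paste0("peak(s) on unknown chromosome: ", paste(bad, collapse = ", ")))
  }
  chrom_len <- nchar(genome)[peaks$chrom]
  if (any(peaks$summit < 0 | peaks$summit >= chrom_len)) {
    abort("peak summit outside chromosome bounds")
  }
  ws <- pmax(0L, peaks$summit - as.integer(flank))
  we <- pmin(as.integer(chrom_len), peaks$summit + as.integer(flank))
  tibble(peak_id = peaks$peak_id, chrom = peaks$chrom,
         win_start = as.integer(ws), win_end = as.integer(we),
         clipped = ws > peaks$summit - flank | we < peaks$summit + flank,
         seq = substring(genome[peaks$chrom], ws + 1L, we))
}

#' Seeded alignment of query windows against a target genome
#'
#' A blat-style aligner: exact 11-mer seed matches on both strands (with
#' occurrence masking of over-represented seeds, as with blat's `.ooc`
#' files) are clustered by chromosome and diagonal, and each cluster's span
#' is aligned to the query by a unit-score Smith-Waterman local alignment,
#' so partially homologous windows yield partial aligned fractions. Hits are
#' scored as
#' `matches - mismatches - gap_opens` and kept when identity
#' (`matches / (matches + mismatches) * 100`) and score pass the thresholds.
#'
#' @param queries Character vector of query sequences (or tibble with
#'   `peak_id` and `seq`, e.g. from [extract_window()]).
#' @param genome Named character vector of target chromosome sequences.
#' @param min_identity Minimum percent identity (default 70).
#' @param min_score Minimum score (default 100).
#' @param seed_len Seed k-mer length (default 11).
#' @param max_occ Mask seeds occurring more often than this in the target.
#' @param min_seeds Minimum clustered seeds before alignment is attempted.
#' @param diag_tol Diagonal drift allowed within one seed cluster (bp).
#' @return Tibble of hits sorted by descending score within query: `peak_id`,
#'   `chrom`, `t_start`, `t_end`, `strand`, `matches`, `mismatches`,
#'   `gap_opens`, `gapped`, `score`, `identity`, `aligned_fraction`.
#' @export
seeded_align <- function(queries, genome, min_identity = 70, min_score = 100,
                         seed_len = 11L, max_occ = 1024L, min_seeds = 2L,
                         diag_tol = 50L) {
  if (is.character(queries)) {
    queries <- tibble(peak_id = names(queries) %||%
                        sprintf("query_%d", seq_along(queries)),
                      seq = unname(queries))
  }
  qlen <- nchar(queries$seq)
  hits <- cpp_project_queries(toupper(queries$seq), unname(genome),
                              as.integer(seed_len), as.integer(max_occ),
                              as.integer(min_seeds), as.integer(diag_tol))
  hits <- as_tibble(hits) |>
    mutate(
      peak_id = queries$peak_id[.data$query_idx],
      chrom = names(genome)[.data$chrom_idx],
      score = .data$matches - .data$mismatches - .data$gap_opens,
      identity = 100 * .data$matches /
        pmax(.data$matches + .data$mismatches, 1L),
      aligned_fraction = (.data$matches + .data$mismatches) /
        qlen[.data$query_idx]
    ) |>
    filter(.data$identity >= min_identity, .data$score >= min_score) |>
    arrange(.data$peak_id, desc(.data$score)) |>
    select("peak_id", "chrom", "t_start", "t_end", "strand", "matches",
           "mismatches", "gap_opens", "gapped", "score", "identity",
           "aligned_fraction")
  hits
}

#' Reduce hits per peak to a single best alignment
#'
#' Drops hits covering less than `min_aligned_fraction` of the query. A peak
#' with no surviving hit gets status `no_hit`; a peak whose second-best score
#' is at least `single_hit_ratio` of the best is `multi_mapped` (and excluded
#' from classification); otherwise the top hit is kept with status
#' `single_hit`.
#'
#' @param hits Output of [seeded_align()].
#' @param peak_ids All projected peak ids (so peaks with no hit appear).
#' @param min_aligned_fraction Minimum fraction of the query aligned (0.7).
#' @param single_hit_ratio Near-tie ratio declaring a multi-mapper (0.95).
#' @return Tibble with one row per peak: `peak_id`, `status`, and the best
#'   hit's columns (NA for `no_hit`/`multi_mapped`).
#' @export
best_hit_filter <- function(hits, peak_ids = unique(hits$peak_id),
                            min_aligned_fraction = 0.7,
                            single_hit_ratio = 0.95) {
  kept <- filter(hits, .data$aligned_fraction >= min_aligned_fraction) |>
    group_by(.data$peak_id) |>
    arrange(desc(.data$score), .by_group = TRUE) |>
    summarise(
      status = if (n() >= 2L && .data$score[2] >= single_hit_ratio * .data$score[1])
        "multi_mapped" else "single_hit",
      across(c("chrom", "strand"), first),
      across(c("t_start", "t_end", "matches", "mismatches", "gap_opens",
               "gapped", "score", "identity", "aligned_fraction"), first)
    )
  out <- tibble(peak_id = peak_ids) |>
    left_join(kept, by = "peak_id") |>
    mutate(status = dplyr::coalesce(.data$status, "no_hit"))
  blank <- out$status != "single_hit"
  out[blank, c("chrom", "strand")] <- NA_character_
  out[blank, c("t_start", "t_end", "matches", "mismatches", "gap_opens",
               "gapped", "score", "identity", "aligned_fraction")] <- NA
  out
}

#' Classify projected peaks as conserved, loss or unaligned
#'
#' A peak with no alignable hit is `unaligned`. A single-hit peak whose
#' aligned target interval covers strictly more than half the length of any
#' target-genome peak is `conserved`; otherwise `loss`. Multi-mapped peaks
#' keep an undefined class (`NA`) and are excluded.
#'
#' @param projections Output of [best_hit_filter()].
#' @param target_peaks Tibble of peaks on the target genome (`chrom`,
#'   `start`, `end`).
#' @param min_overlap Fraction of the target peak that must be covered
#'   (strictly exceeded) to call conservation; default 0.5.
#' @return `projections` with a `klass` column.
#' @export
classify_peaks <- function(projections, target_peaks, min_overlap = 0.5) {
  single <- filter(projections, .data$status == "single_hit")
  conserved_ids <- character()
  if (nrow(single) > 0 && nrow(target_peaks) > 0) {
    for (ch in intersect(unique(single$chrom), unique(target_peaks$chrom))) {
      si <- which(single$chrom == ch)
      tp <- filter(target_peaks, .data$chrom == ch)
      ov <- IRanges::findOverlaps(
        IRanges::IRanges(single$t_start[si] + 1L, single$t_end[si]),
        IRanges::IRanges(tp$start + 1L, tp$end))
      if (length(ov) == 0) next
      w <- IRanges::width(IRanges::pintersect(
        IRanges::IRanges(single$t_start[si] + 1L, single$t_end[si])[S4Vectors::queryHits(ov)],
        IRanges::IRanges(tp$start + 1L, tp$end)[S4Vectors::subjectHits(ov)]))
      frac <- w / (tp$end - tp$start)[S4Vectors::subjectHits(ov)]
      hit <- unique(S4Vectors::queryHits(ov)[frac > min_overlap])
      conserved_ids <- c(conserved_ids, single$peak_id[si][hit])
    }
  }
  mutate(projections, klass = case_when(
    .data$status == "multi_mapped" ~ NA_character_,
    .data$status == "no_hit" ~ "unaligned",
    .data$peak_id %in% conserved_ids ~ "conserved",
    TRUE ~ "loss"
  ))
}

#' Matched bases of a projection
#'
#' Identically aligned bases of the best hit; 0 for peaks with no hit.
#'
#' @param projections Output of [best_hit_filter()] or [classify_peaks()].
#' @return `projections` with a `matched_bases` column.
#' @export
matched_bases <- function(projections) {
  mutate(projections,
         matched_bases = if_else(.data$status == "single_hit",
                                 as.integer(.data$matches), 0L))
}

#' Project peaks from one genome onto the other and classify them
#'
#' End-to-end peak orthology classification: summit-centred 400 bp windows
#' are extracted ([extract_window()]), aligned to the target genome
#' ([seeded_align()]), reduced to genome-wide best hits
#' ([best_hit_filter()]), and classified against the target peak set
#' ([classify_peaks()]).
#'
#' @param peaks Source-genome peaks (`peak_id`, `chrom`, `summit`,
#'   `start`, `end`).
#' @param source_genome,target_genome Named character vectors of chromosome
#'   sequences.
#' @param target_peaks Target-genome peaks used for the conserved/loss call.
#' @param flank Half-window around the summit (default 200 bp).
#' @param tss Optional tibble (`chrom`, `tss`) of source-genome transcription
#'   start sites; when given, peaks are stratified as `proximal` (window
#'   midpoint within `proximal_dist` of a TSS) versus `distal`.
#' @param proximal_dist Proximal distance threshold in bp (default 3000).
#' @inheritParams seeded_align
#' @inheritParams best_hit_filter
#' @inheritParams classify_peaks
#' @return Tibble with one row per source peak: projection status, best-hit
#'   fields, `klass`, `matched_bases`, and `locality` when `tss` was given.
#' @export
project_peaks <- function(peaks, source_genome, target_genome, target_peaks,
                          flank = 200L, min_identity = 70, min_score = 100,
                          seed_len = 11L, max_occ = 1024L, min_seeds = 2L,
                          diag_tol = 50L, min_aligned_fraction = 0.7,
                          single_hit_ratio = 0.95, min_overlap = 0.5,
                          tss = NULL, proximal_dist = 3000L) {
  windows <- extract_window(peaks, source_genome, flank)
  hits <- seeded_align(windows, target_genome, min_identity, min_score,
                       seed_len, max_occ, min_seeds, diag_tol)
  proj <- best_hit_filter(hits, peak_ids = peaks$peak_id,
                          min_aligned_fraction = min_aligned_fraction,
                          single_hit_ratio = single_hit_ratio) |>
    classify_peaks(target_peaks, min_overlap) |>
    matched_bases()
  if (!is.null(tss)) {
    mid <- (windows$win_start + windows$win_end) %/% 2L
    prox <- purrr::map_lgl(seq_len(nrow(windows)), function(i) {
      cand <- tss$tss[tss$chrom == windows$chrom[i]]
      length(cand) > 0 && min(abs(cand - mid[i])) <= proximal_dist
    })
    proj <- left_join(proj,
                      tibble(peak_id = windows$peak_id,
                             locality = if_else(prox, "proximal", "distal")),
                      by = "peak_id")
  }
  proj
}

#' Tally peak classes
#'
#' @param projections Classified projections ([classify_peaks()] output).
#' @return Tibble `klass`, `n`, `percent` (conserved/loss/unaligned share of
#'   classified peaks; multi-mapped peaks are counted separately and excluded
#'   from the denominator, as in the projection protocol).
#' @export
peak_class_summary <- function(projections) {
  classified <- filter(projections, !is.na(.data$klass))
  out <- count(classified, .data$klass, name = "n") |>
    tidyr::complete(klass = c("conserved", "loss", "unaligned"),
                    fill = list(n = 0L))
  class_percentages(setNames(out$n, out$klass))
}
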