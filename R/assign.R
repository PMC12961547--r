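#' Find the best alignment of reads against one genome
#'
#' Locates candidate loci with exact k-mer seeds over a genome index (both
#' strands) and verifies each by an edit-distance alignment of the full read
#' against the candidate window with free end gaps on the genome side. The
#' hit with the minimum edit distance no greater than `max_edit` is returned;
#' ties between loci go to the lowest chromosome name, then the leftmost
#' start.
#'
#' @param reads Character vector of read sequences, a tibble with `read_id`
#'   and `seq` columns, or a `Biostrings::DNAStringSet`.
#' @param genome Named character vector of chromosome sequences (or one
#'   element of `pair$genomes`).
#' @param k Seed length (>= 8).
#' @param max_edit Maximum edit distance; default 10 percent of read length.
#' @param max_occ Seeds occurring more often than this in the genome are
#'   skipped.
#' @return Tibble with one row per read: `read_id`, `chrom`, `start`, `end`
#'   (0-based half-open), `strand`, `edit_distance`, `n_matches`; `NA` fields
#'   where no hit within `max_edit` exists.
#' @export
find_best_hits <- function(reads, genome, k = 12L, max_edit = NULL,
                           max_occ = 64L) {
  reads <- as_read_tibble(reads)
  if (k < 8L) abort("seed length k must be >= 8")
  if (is.null(max_edit)) {
    max_edit <- max(1L, as.integer(floor(0.1 * max(nchar(reads$seq), 1L))))
  }
  if (any(nchar(reads$seq) < k)) {
    warn(sprintf("%d read(s) shorter than k = %d treated as unmapped",
                 sum(nchar(reads$seq) < k), k))
  }
  ord <- order(names(genome))   # leftmost tie-break is by chromosome name
  genome <- genome[ord]
  hits <- cpp_map_reads(reads$seq, unname(genome), as.integer(k),
                        as.integer(max_edit), as.integer(max_occ))
  tibble(read_id = reads$read_id,
         chrom = names(genome)[hits$chrom_idx],
         start = hits$start, end = hits$end, strand = hits$strand,
         edit_distance = hits$edit_distance, n_matches = hits$n_matches)
}

as_read_tibble <- function(reads) {
  if (inherits(reads, "DNAStringSet")) {
    reads <- tibble(read_id = names(reads) %||% as.character(seq_along(reads)),
                    seq = as.character(reads))
  } else if (is.character(reads)) {
    reads <- tibble(read_id = names(reads) %||% sprintf("read_%d", seq_along(reads)),
                    seq = unname(reads))
  }
  if (!all(c("read_id", "seq") %in% names(reads))) {
    abort("reads must provide read_id and seq")
  }
  as_tibble(reads)[, c("read_id", "seq")] |>
    mutate(seq = toupper(.data$seq))
}

#' Competitive allele assignment by edit distance
#'
#' Labels each read by comparing its best edit distance against the two
#' parental genomes: the allele with the strictly smaller distance wins; equal
#' distances give `ambiguous`; no hit in either genome gives `unmapped`.
#' Ambiguous and unmapped reads are excluded from downstream per-allele
#' counting.
#'
#' @inheritParams find_best_hits
#' @param genome_a,genome_b Named character vectors of chromosome sequences
#'   for the two alleles, or a `cisdiv_genome_pair` as `genome_a`.
#' @return Tibble: `read_id`, `label` (A/B/ambiguous/unmapped), `edit_a`,
#'   `edit_b`, and the winning hit's `chrom`, `start`, `end`, `strand`.
#' @examples
#' g <- c(chr1 = paste(rep("ACGT", 30), collapse = ""))
#' assign_reads(c(r1 = substr(g, 11, 40)), g, c(chr1 = paste(rep("A", 120), collapse = "")))
#' @export
assign_reads <- function(reads, genome_a, genome_b, k = 12L, max_edit = NULL,
                         max_occ = 64L) {
  if (inherits(genome_a, "cisdiv_genome_pair")) {
    genome_b <- genome_a$genomes$B
    genome_a <- genome_a$genomes$A
  }
  reads <- as_read_tibble(reads)
  hit_a <- find_best_hits(reads, genome_a, k, max_edit, max_occ)
  hit_b <- suppressWarnings(find_best_hits(reads, genome_b, k, max_edit, max_occ))
  label <- assign_label(hit_a$edit_distance, hit_b$edit_distance)
  win_a <- label == "A"
  pick <- function(col) if_else(win_a, hit_a[[col]], hit_b[[col]])
  tibble(read_id = reads$read_id, label = label,
         edit_a = hit_a$edit_distance, edit_b = hit_b$edit_distance,
         chrom = pick("chrom"), start = pick("start"), end = pick("end"),
         strand = pick("strand"))
}

#' Label a read from its two competitive edit distances
#'
#' @param edit_a,edit_b Integer edit distances (NA where no hit).
#' @return Character vector over `A`, `B`, `ambiguous`, `unmapped`.
#' @export
assign_label <- function(edit_a, edit_b) {
  case_when(
    is.na(edit_a) & is.na(edit_b) ~ "unmapped",
    is.na(edit_b) ~ "A",
    is.na(edit_a) ~ "B",
    edit_a < edit_b ~ "A",
    edit_b < edit_a ~ "B",
    TRUE ~ "ambiguous"
  )
}

#' Per-feature, per-allele read counts
#'
#' A read increments a feature exactly when the midpoint of its aligned
#' interval lies within the feature (0-based half-open), on the genome the
#' read was assigned to. Ambiguous and unmapped reads are never counted.
#'
#' @param assignments Output of [assign_reads()].
#' @param features Tibble with `feature_id`, `genome` (A/B), `chrom`,
#'   `start`, `end`.
#' @param chrom_names Optional character vector of valid chromosome names;
#'   a feature on an unknown chromosome raises an error naming it.
#' @return Tibble `feature_id`, `count_a`, `count_b` (all features, zeros
#'   kept).
#' @export
count_matrix <- function(assignments, features, chrom_names = NULL) {
  if (!is.null(chrom_names)) {
    bad <- setdiff(unique(features$chrom), chrom_names)
    if (length(bad)) {
      abort(paste0("feature(s) on unknown chromosome: ",
                   paste(bad, collapse = ", ")))
    }
  }
  mapped <- filter(assignments, .data$label %in% c("A", "B")) |>
    mutate(mid = (.data$start + .data$end) %/% 2L)
  count_one <- function(g) {
    fg <- filter(features, .data$genome == g)
    rg <- filter(mapped, .data$label == g)
    if (nrow(fg) == 0) return(tibble(feature_id = character(), n = integer()))
    n <- integer(nrow(fg))
    for (ch in unique(fg$chrom)) {
      fi <- which(fg$chrom == ch)
      mids <- rg$mid[rg$chrom == ch]
      if (!length(mids)) next
      ov <- IRanges::countOverlaps(
        IRanges::IRanges(fg$start[fi] + 1L, fg$end[fi]),
        IRanges::IRanges(mids + 1L, mids + 1L))
      n[fi] <- ov
    }
    tibble(feature_id = fg$feature_id, n = n)
  }
  ca <- count_one("A"); cb <- count_one("B")
  distinct(features, .data$feature_id) |>
    left_join(rename(ca, count_a = "n"), by = "feature_id") |>
    left_join(rename(cb, count_b = "n"), by = "feature_id") |>
    mutate(count_a = dplyr::coalesce(.data$count_a, 0L),
           count_b = dplyr::coalesce(.data$count_b, 0L))
}
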