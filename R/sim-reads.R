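#' Simulate ChIP-style reads from a peak-bearing genome pair
#'
#' Draws `reads_per_peak` reads per planted peak from the allele carrying the
#' peak: the read start is uniform within half a fragment length of the
#' summit, the strand is random, and optional per-base errors are applied at
#' `read_error_rate`. Poisson background reads at `background_read_rate` per
#' kb are added uniformly from both alleles. Every read is labelled with its
#' allele of origin in the returned truth columns.
#'
#' @param pair A peak-bearing `cisdiv_genome_pair` (after [plant_peaks()]).
#' @param config Defaults to `pair$config`.
#' @param out_fasta Optional path; reads are also written as FASTA.
#' @return Tibble with `read_id`, `seq`, and truth columns `true_genome`,
#'   `true_chrom`, `true_start`, `origin` ("peak"/"background") and `peak_id`.
#' @export
simulate_reads <- function(pair, config = pair$config, out_fasta = NULL) {
  if (is.null(pair$peaks)) abort("plant_peaks() must be run first")
  set.seed(stage_seed(config$seed, "reads"))
  rl <- config$read_len
  frag <- config$fragment_len
  if (any(rl > nchar(pair$genomes$A)) || any(rl > nchar(pair$genomes$B))) {
    abort("read_len exceeds a chromosome length")
  }

  draw_from <- function(genome, chrom, start) {
    chrom_len <- nchar(pair$genomes[[genome[1]]])[chrom]
    start <- pmax(0L, pmin(start, as.integer(chrom_len - rl)))
    seqs <- substring(pair$genomes[[genome[1]]][chrom], start + 1L, start + rl)
    minus <- runif(length(seqs)) < 0.5
    seqs[minus] <- revcomp_chr(seqs[minus])
    if (config$read_error_rate > 0) seqs <- add_read_errors(seqs, config$read_error_rate)
    tibble(seq = seqs, true_chrom = chrom, true_start = start)
  }

  per_genome <- function(g) {
    pk <- filter(pair$peaks, .data$genome == g)
    pk <- pk[rep(seq_len(nrow(pk)), each = config$reads_per_peak), ]
    lo <- pk$summit - frag %/% 2L
    start <- lo + floor(runif(nrow(pk)) * (frag - rl + 1L))
    peak_reads <- draw_from(g, pk$chrom, as.integer(start)) |>
      mutate(origin = "peak", peak_id = pk$peak_id)

    chrom_len <- nchar(pair$genomes[[g]])
    n_bg <- rpois(1, config$background_read_rate * sum(chrom_len) / 1000)
    bg_reads <- if (n_bg > 0) {
      ch <- sample(names(chrom_len), n_bg, replace = TRUE,
                   prob = chrom_len / sum(chrom_len))
      st <- as.integer(floor(runif(n_bg) * (chrom_len[ch] - rl + 1L)))
      draw_from(g, ch, st) |> mutate(origin = "background", peak_id = NA_character_)
    } else {
      tibble()
    }
    bind_rows(peak_reads, bg_reads) |> mutate(true_genome = g)
  }

  reads <- bind_rows(per_genome("A"), per_genome("B")) |>
    mutate(read_id = sprintf("read_%07d", row_number())) |>
    select("read_id", "seq", "true_genome", "true_chrom", "true_start",
           "origin", "peak_id")
  if (!is.null(out_fasta)) {
    Biostrings::writeXStringSet(
      setNames(Biostrings::DNAStringSet(reads$seq), reads$read_id), out_fasta)
  }
  reads
}

add_read_errors <- function(seqs, rate) {
  vapply(seqs, function(s) {
    ch <- strsplit(s, "")[[1]]
    pos <- which(runif(length(ch)) < rate)
    if (length(pos)) {
      shift <- sample.int(3L, length(pos), replace = TRUE)
      old <- match(ch[pos], DNA_BASES)
      ch[pos] <- DNA_BASES[((old - 1L + shift) %% 4L) + 1L]
    }
    paste(ch, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}
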