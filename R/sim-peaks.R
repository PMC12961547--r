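#' Plant TF-binding peaks of known orthology class into a genome pair
#'
#' Embeds the motif consensus at chosen summits and records summit-centred
#' peaks in three truth classes: *conserved* (consensus embedded at homologous
#' positions in both genomes, a peak emitted in both), *loss* (consensus and
#' peak in one genome only, the homologous region exists but is unbound) and
#' *unaligned* (consensus and peak inside a lineage-specific block). Loss and
#' unaligned peaks are planted in each genome separately so both projection
#' directions carry all three classes; conserved peaks are shared.
#'
#' @param pair A `cisdiv_genome_pair` from [simulate_genome_pair()].
#' @param pwm Motif to embed; defaults to the packaged demo matrix
#'   ([cdx2_demo_pwm()]).
#' @param config Defaults to `pair$config`.
#' @return The genome pair with motif-bearing genomes and two new elements:
#'   `peaks` (tibble `genome`, `chrom`, `start`, `end`, `summit`, `peak_id`,
#'   `signal`, `qvalue_neglog10`) and `peak_truth` (tibble `genome`,
#'   `peak_id`, `klass`). Peaks are non-overlapping within each genome.
#' @export
plant_peaks <- function(pair, pwm = cdx2_demo_pwm(), config = pair$config) {
  set.seed(stage_seed(config$seed, "peaks"))
  W <- config$peak_window
  half <- W %/% 2L
  consensus <- pwm_consensus(pwm)
  w <- nchar(consensus)

  # homologous slots: windows fully inside one coordinate-map block
  margin <- 10L
  rows <- filter(pair$coord_map, .data$len >= W + 2L * margin)
  slots <- purrr::pmap(rows, function(chrom, a_start, b_start, len) {
    off <- seq(margin, len - W - margin, by = W + 40L)
    tibble(chrom = chrom, a_summit = a_start + off + half,
           b_summit = b_start + off + half)
  }) |> list_rbind()
  n_need <- config$n_peaks_conserved + 2L * config$n_peaks_loss
  if (nrow(slots) < n_need) {
    abort(sprintf(
      "cannot place %d homologous peak windows: only %d non-overlapping slots available; increase chrom_length",
      n_need, nrow(slots)))
  }
  slots <- slots[sample.int(nrow(slots), n_need), ]

  take <- function(n) {
    out <- slots[seq_len(n), , drop = FALSE]
    slots <<- slots[-seq_len(n), , drop = FALSE]
    out
  }
  cons <- take(config$n_peaks_conserved)
  loss_a <- take(config$n_peaks_loss)
  loss_b <- take(config$n_peaks_loss)

  # unaligned peaks: one per lineage-specific block, centred
  pick_blocks <- function(g) {
    bl <- filter(pair$blocks, .data$genome == g)
    if (nrow(bl) < config$n_peaks_unaligned) {
      abort(sprintf(
        "genome %s has %d lineage-specific blocks but %d unaligned peaks requested",
        g, nrow(bl), config$n_peaks_unaligned))
    }
    bl[sample.int(nrow(bl), config$n_peaks_unaligned), ]
  }
  una_a <- pick_blocks("A")
  una_b <- pick_blocks("B")

  mk_peaks <- function(genome, chrom, summit, klass, idx) {
    n <- length(summit)
    tibble(
      genome = genome, chrom = chrom,
      start = as.integer(summit - half), end = as.integer(summit + half),
      summit = as.integer(summit),
      peak_id = sprintf("%s_%s_%03d", genome, klass, idx),
      signal = round(runif(n, 5, 20), 3),
      qvalue_neglog10 = round(runif(n, 5, 50), 3),
      klass = klass
    )
  }
  peaks <- bind_rows(
    mk_peaks("A", cons$chrom, cons$a_summit, "conserved", seq_len(nrow(cons))),
    mk_peaks("B", cons$chrom, cons$b_summit, "conserved", seq_len(nrow(cons))),
    mk_peaks("A", loss_a$chrom, loss_a$a_summit, "loss", seq_len(nrow(loss_a))),
    mk_peaks("B", loss_b$chrom, loss_b$b_summit, "loss", seq_len(nrow(loss_b))),
    mk_peaks("A", una_a$chrom, (una_a$start + una_a$end) %/% 2L, "unaligned",
             seq_len(nrow(una_a))),
    mk_peaks("B", una_b$chrom, (una_b$start + una_b$end) %/% 2L, "unaligned",
             seq_len(nrow(una_b)))
  )

  # embed the consensus at every summit in the carrying genome
  for (g in c("A", "B")) {
    pg <- filter(peaks, .data$genome == g)
    for (ch in unique(pg$chrom)) {
      s <- pair$genomes[[g]][[ch]]
      for (sm in pg$summit[pg$chrom == ch]) {
        at <- sm - w %/% 2L          # 0-based embed start
        substr(s, at + 1L, at + w) <- consensus
      }
      pair$genomes[[g]][[ch]] <- s
    }
  }

  pair$peaks <- select(peaks, -"klass")
  pair$peak_truth <- select(peaks, "genome", "peak_id", "klass")
  pair
}
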