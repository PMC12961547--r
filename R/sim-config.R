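#' Simulation configuration for a synthetic allodiploid experiment
#'
#' Bundles every knob of the synthetic data generator: two related genomes at a
#' stated substitution/indel divergence, lineage-specific (unalignable)
#' insertions, planted TF-binding peaks in three orthology classes, ChIP-style
#' reads enriched at planted summits, and per-allele expression responses drawn
#' from the five regulation types.
#'
#' Defaults describe the study conditions the package is validated under:
#' ~5 percent substitution divergence with sparse short indels (a rodent-like
#' mouse/rat scale of sequence divergence), 400 bp peak windows, 100-500 bp
#' ChIP fragments (default 250), and regulation-type proportions echoing the
#' observed 5592/496/1/425/858 split.
#'
#' @param seed Integer seed; every stage derives its own sub-stream from it.
#' @param n_chrom_per_genome Number of chromosomes per genome.
#' @param chrom_length Chromosome length in bp (before lineage-specific
#'   insertions).
#' @param subst_rate Per-site substitution probability between the alleles.
#' @param indel_rate Per-site indel event probability between the alleles.
#' @param mean_indel_len Mean indel length in bp (geometric).
#' @param n_unalignable_blocks Lineage-specific random-sequence insertions per
#'   genome; each is `3 * peak_window` bp so it cannot align at 70 percent
#'   identity.
#' @param n_peaks_conserved,n_peaks_loss,n_peaks_unaligned Planted peak counts
#'   per class. Conserved peaks are shared; loss and unaligned counts apply to
#'   each genome separately so both projection directions carry all classes.
#' @param peak_window Peak width in bp (summit-centred, even).
#' @param reads_per_peak ChIP reads drawn around each planted summit.
#' @param read_len Read length in bp.
#' @param fragment_len ChIP fragment size in bp; reads start uniformly within
#'   `fragment_len / 2` of the summit.
#' @param background_read_rate Background reads per kb per genome (Poisson).
#' @param read_error_rate Per-base sequencing error probability.
#' @param n_genes Homologous gene pairs to simulate.
#' @param type_proportions Length-5 probability vector over regulation types
#'   0-4; must sum to 1.
#' @param effect_size_log2 Mean absolute log2 fold change for responsive
#'   alleles.
#' @param dispersion Negative-binomial overdispersion (0 gives Poisson counts).
#' @param mean_expression Baseline mean counts per allele per condition.
#'
#' @return A `cisdiv_config` list with validated fields.
#' @examples
#' cfg <- sim_config(seed = 1, n_peaks_conserved = 5, n_peaks_loss = 5)
#' cfg$subst_rate
#' @export
sim_config <- function(seed = 1L,
                       n_chrom_per_genome = 2L,
                       chrom_length = 200000L,
                       subst_rate = 0.05,
                       indel_rate = 0.002,
                       mean_indel_len = 3,
                       n_unalignable_blocks = 8L,
                       n_peaks_conserved = 50L,
                       n_peaks_loss = 50L,
                       n_peaks_unaligned = 8L,
                       peak_window = 400L,
                       reads_per_peak = 50L,
                       read_len = 100L,
                       fragment_len = 250L,
                       background_read_rate = 0.05,
                       read_error_rate = 0,
                       n_genes = 500L,
                       type_proportions = c(0.7585, 0.0673, 0.0001, 0.0577, 0.1164),
                       effect_size_log2 = 3,
                       dispersion = 0.05,
                       mean_expression = 200) {
  cfg <- list(
    seed = as.integer(seed),
    n_chrom_per_genome = as.integer(n_chrom_per_genome),
    chrom_length = as.integer(chrom_length),
    subst_rate = subst_rate,
    indel_rate = indel_rate,
    mean_indel_len = mean_indel_len,
    n_unalignable_blocks = as.integer(n_unalignable_blocks),
    n_peaks_conserved = as.integer(n_peaks_conserved),
    n_peaks_loss = as.integer(n_peaks_loss),
    n_peaks_unaligned = as.integer(n_peaks_unaligned),
    peak_window = as.integer(peak_window),
    reads_per_peak = as.integer(reads_per_peak),
    read_len = as.integer(read_len),
    fragment_len = as.integer(fragment_len),
    background_read_rate = background_read_rate,
    read_error_rate = read_error_rate,
    n_genes = as.integer(n_genes),
    type_proportions = type_proportions,
    effect_size_log2 = effect_size_log2,
    dispersion = dispersion,
    mean_expression = mean_expression
  )
  validate_sim_config(cfg)
  structure(cfg, class = "cisdiv_config")
}

validate_sim_config <- function(cfg) {
  rates <- c(subst_rate = cfg$subst_rate, indel_rate = cfg$indel_rate,
             read_error_rate = cfg$read_error_rate)
  bad <- rates < 0 | rates >= 1
  if (any(bad)) {
    abort(paste0("rates must lie in [0, 1): ",
                 paste(names(rates)[bad], collapse = ", ")))
  }
  if (length(cfg$type_proportions) != 5L) {
    abort("type_proportions must have length 5 (types 0-4)")
  }
  if (abs(sum(cfg$type_proportions) - 1) > 1e-9) {
    abort("type_proportions must sum to 1")
  }
  if (any(cfg$type_proportions < 0)) abort("type_proportions must be non-negative")
  counts <- c(cfg$n_peaks_conserved, cfg$n_peaks_loss, cfg$n_peaks_unaligned)
  if (any(counts < 0)) abort("peak counts must be non-negative")
  if (cfg$peak_window < 2L || cfg$peak_window %% 2L != 0L) {
    abort("peak_window must be an even number of bp >= 2")
  }
  if (cfg$chrom_length < 10L * cfg$peak_window) {
    abort("chrom_length too small to host peak windows")
  }
  invisible(cfg)
}

#' @export
print.cisdiv_config <- function(x, ...) {
  cat("<cisdiv_config>\n")
  cat(sprintf("  genomes : %d x %s bp, subst %.3g, indel %.3g (mean len %.3g)\n",
              x$n_chrom_per_genome, format(x$chrom_length, big.mark = ","),
              x$subst_rate, x$indel_rate, x$mean_indel_len))
  cat(sprintf("  peaks   : %d conserved, %d loss, %d unaligned per genome (window %d bp)\n",
              x$n_peaks_conserved, x$n_peaks_loss, x$n_peaks_unaligned,
              x$peak_window))
  cat(sprintf("  reads   : %d per peak, %d bp, fragment %d bp, background %.3g/kb\n",
              x$reads_per_peak, x$read_len, x$fragment_len,
              x$background_read_rate))
  cat(sprintf("  genes   : %d pairs, types (%s), effect %.3g log2, dispersion %.3g\n",
              x$n_genes, paste(signif(x$type_proportions, 3), collapse = ", "),
              x$effect_size_log2, x$dispersion))
  cat(sprintf("  seed    : %d\n", x$seed))
  invisible(x)
}
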