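# Shared simulated dataset, built once per test run.

.sim_cache <- new.env(parent = emptyenv())

shared_sim <- function() {
  if (is.null(.sim_cache$sim)) {
    cfg <- sim_config(seed = 42, n_chrom_per_genome = 2,
                      chrom_length = 100000, n_peaks_conserved = 20,
                      n_peaks_loss = 20, n_peaks_unaligned = 5,
                      n_unalignable_blocks = 6, reads_per_peak = 20,
                      background_read_rate = 0.02)
    pair <- plant_peaks(simulate_genome_pair(cfg))
    reads <- simulate_reads(pair)
    .sim_cache$sim <- list(cfg = cfg, pair = pair, reads = reads)
  }
  .sim_cache$sim
}
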