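test_that("extract_window returns the summit-centred half-open 400 bp window", {
  g <- c(chr1 = random_dna_str(10000))
  pk <- tibble::tibble(peak_id = "p", chrom = "chr1", summit = 500L)
  w <- extract_window(pk, g)
  expect_equal(w$win_start, 300L)
  expect_equal(w$win_end, 700L)
  expect_false(w$clipped)
  expect_equal(w$seq, substring(g, 301, 700))

  clipped <- extract_window(tibble::tibble(peak_id = "p", chrom = "chr1",
                                           summit = 100L), g)
  expect_equal(clipped$win_start, 0L)
  expect_equal(clipped$win_end, 300L)
  expect_true(clipped$clipped)

  expect_error(extract_window(tibble::tibble(peak_id = "p", chrom = "chr1",
                                             summit = 10001L), g),
               "outside")
})

test_that("an exact substring aligns with full identity and score", {
  set.seed(41)
  g <- c(chr1 = random_dna_str(20000))
  q <- substring(g, 5001, 5400)
  hits <- seeded_align(c(p = q), g)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$identity, 100)
  expect_equal(hits$score, 400L)
  expect_equal(hits$aligned_fraction, 1)
  expect_equal(hits$t_start, 5000L)
  expect_equal(hits$t_end, 5400L)
  expect_equal(hits$strand, "+")
})

test_that("a reverse-complement query yields the same locus on the minus strand", {
  set.seed(42)
  g <- c(chr1 = random_dna_str(20000))
  q <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(substring(g, 5001, 5400))))
  hits <- seeded_align(c(p = q), g)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$strand, "-")
  expect_equal(hits$t_start, 5000L)
  expect_equal(hits$identity, 100)
})

test_that("hit identity tracks a full Needleman-Wunsch oracle on divergent pairs", {
  set.seed(43)
  for (i in 1:10) {
    span <- random_dna_str(600)
    target <- c(chr1 = paste0(random_dna_str(500), span, random_dna_str(500)))
    q <- mutate_no_indel(span, 0.05)
    hits <- seeded_align(c(p = q), target)
    expect_gte(nrow(hits), 1L)
    expect_lt(abs(hits$identity[1] - oracle_nw_identity(q, span)), 2)
  }
})

test_that("best_hit_filter separates single, multiple and missing hits", {
  set.seed(44)
  core <- random_dna_str(400)
  g <- c(chr1 = paste0(random_dna_str(300), core, random_dna_str(300),
                       core, random_dna_str(300)))
  dup <- best_hit_filter(seeded_align(c(p = core), g), peak_ids = "p")
  expect_equal(dup$status, "multi_mapped")

  g1 <- c(chr1 = paste0(random_dna_str(300), core, random_dna_str(300)))
  single <- best_hit_filter(seeded_align(c(p = core), g1), peak_ids = "p")
  expect_equal(single$status, "single_hit")

  none <- best_hit_filter(seeded_align(c(p = random_dna_str(400)),
                                       c(chr1 = random_dna_str(5000))),
                          peak_ids = "p")
  expect_equal(none$status, "no_hit")

  # dropping low aligned-fraction hits can empty the hit list
  frag <- paste0(substring(core, 1, 150), random_dna_str(250))
  part <- best_hit_filter(seeded_align(c(p = frag), g1, min_score = 50),
                          peak_ids = "p", min_aligned_fraction = 0.99)
  expect_equal(part$status, "no_hit")
})

test_that("classification follows the strict majority-overlap rule", {
  proj <- tibble::tibble(peak_id = c("full", "half", "none"),
                         status = c("single_hit", "single_hit", "no_hit"),
                         chrom = c("chr1", "chr1", NA),
                         t_start = c(1000L, 2000L, NA),
                         t_end = c(1400L, 2200L, NA))
  target <- tibble::tibble(chrom = "chr1",
                           start = c(1000L, 2000L), end = c(1400L, 2400L))
  out <- classify_peaks(proj, target)
  expect_equal(out$klass[out$peak_id == "full"], "conserved")
  # hit covers exactly 50.0% of the 400 bp target peak: strict rule -> loss
  expect_equal(out$klass[out$peak_id == "half"], "loss")
  expect_equal(out$klass[out$peak_id == "none"], "unaligned")
})

test_that("matched_bases reports matches for hits and zero otherwise", {
  proj <- tibble::tibble(peak_id = c("a", "b"),
                         status = c("single_hit", "no_hit"),
                         matches = c(371L, NA))
  out <- matched_bases(proj)
  expect_equal(out$matched_bases, c(371L, 0L))
})

test_that("projection classes partition the peak set and recover the truth", {
  sim <- shared_sim()
  pair <- sim$pair
  pa <- dplyr::filter(pair$peaks, genome == "A")
  pb <- dplyr::filter(pair$peaks, genome == "B")
  proj <- project_peaks(pa, pair$genomes$A, pair$genomes$B, pb)
  expect_equal(nrow(proj), nrow(pa))
  n_multi <- sum(proj$status == "multi_mapped")
  expect_equal(sum(!is.na(proj$klass)) + n_multi, nrow(pa))
  truth <- dplyr::filter(pair$peak_truth, genome == "A")
  joined <- dplyr::left_join(proj, truth, by = "peak_id")
  agree <- mean(joined$klass.x == joined$klass.y, na.rm = TRUE)
  expect_gte(agree, 0.95)
})

test_that("identical genomes with identical peaks classify 100% conserved both ways", {
  cfg <- sim_config(seed = 45, n_chrom_per_genome = 1, chrom_length = 40000,
                    subst_rate = 0, indel_rate = 0, n_unalignable_blocks = 0,
                    n_peaks_conserved = 8, n_peaks_loss = 0,
                    n_peaks_unaligned = 0)
  pair <- plant_peaks(simulate_genome_pair(cfg))
  pa <- dplyr::filter(pair$peaks, genome == "A")
  pb <- dplyr::filter(pair$peaks, genome == "B")
  ab <- project_peaks(pa, pair$genomes$A, pair$genomes$B, pb)
  ba <- project_peaks(pb, pair$genomes$B, pair$genomes$A, pa)
  expect_true(all(ab$klass == "conserved"))
  expect_true(all(ba$klass == "conserved"))
  expect_equal(nrow(ab), nrow(ba))
})

test_that("raising min_identity never increases the conserved count", {
  sim <- shared_sim()
  pair <- sim$pair
  pa <- dplyr::filter(pair$peaks, genome == "A")
  pb <- dplyr::filter(pair$peaks, genome == "B")
  counts <- purrr::map_int(c(70, 85, 95), function(mi) {
    proj <- project_peaks(pa, pair$genomes$A, pair$genomes$B, pb,
                          min_identity = mi)
    sum(proj$klass == "conserved", na.rm = TRUE)
  })
  expect_true(all(diff(counts) <= 0))
})

test_that("proximal/distal stratification uses the window midpoint distance", {
  g <- c(chr1 = random_dna_str(20000))
  core <- substring(g, 5001, 5400)
  pk <- tibble::tibble(peak_id = "p", chrom = "chr1", summit = 5200L,
                       start = 5000L, end = 5400L)
  tss <- tibble::tibble(chrom = "chr1", tss = 6000L)
  proj <- project_peaks(pk, g, c(chr1 = paste0(core, random_dna_str(5000))),
                        pk[0, ], tss = tss)
  expect_equal(proj$locality, "proximal")
  far <- project_peaks(pk, g, c(chr1 = paste0(core, random_dna_str(5000))),
                       pk[0, ], tss = tibble::tibble(chrom = "chr1",
                                                     tss = 15000L))
  expect_equal(far$locality, "distal")
})
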