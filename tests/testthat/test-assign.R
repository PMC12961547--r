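test_that("exact substrings map back to their source locus with edit 0", {
  set.seed(21)
  g <- c(chr1 = random_dna_str(5000), chr2 = random_dna_str(5000))
  starts <- c(137, 2048, 4700)
  reads <- substring(g["chr2"], starts + 1, starts + 100)
  hits <- find_best_hits(setNames(reads, paste0("r", 1:3)), g)
  expect_equal(hits$chrom, rep("chr2", 3))
  expect_equal(hits$start, starts)
  expect_equal(hits$end, starts + 100L)
  expect_equal(hits$edit_distance, rep(0L, 3))
  expect_equal(hits$n_matches, rep(100L, 3))
})

test_that("planted substitutions are counted exactly", {
  set.seed(22)
  g <- c(chr1 = random_dna_str(3000))
  read <- substring(g, 501, 600)
  ch <- strsplit(read, "")[[1]]
  for (p in c(10, 60)) {
    ch[p] <- setdiff(c("A", "C", "G", "T"), ch[p])[1]
  }
  hit <- find_best_hits(c(r = paste(ch, collapse = "")), g, max_edit = 5)
  expect_equal(hit$edit_distance, 2L)
  expect_equal(hit$start, 500L)
})

test_that("a foreign read finds no hit, in agreement with the full DP oracle", {
  set.seed(23)
  g <- c(chr1 = random_dna_str(100000))
  read <- random_dna_str(100)
  hit <- find_best_hits(c(r = read), g, max_edit = 10)
  expect_true(is.na(hit$edit_distance))
  # oracle: best infix edit distance over the whole genome, both strands
  best <- min(oracle_edit_infix(read, g),
              oracle_edit_infix(read, as.character(
                Biostrings::reverseComplement(Biostrings::DNAString(g)))))
  expect_gt(best, 10)
})

test_that("reported edit distance equals the full DP oracle on divergent loci", {
  set.seed(24)
  for (i in 1:15) {
    g <- c(chr1 = random_dna_str(4000))
    start <- sample(0:3899, 1)
    read <- mutate_no_indel(substring(g, start + 1, start + 100), 0.05)
    hit <- find_best_hits(c(r = read), g, max_edit = 12)
    oracle <- min(oracle_edit_infix(read, g),
                  oracle_edit_infix(read, as.character(
                    Biostrings::reverseComplement(Biostrings::DNAString(g)))))
    expect_false(is.na(hit$edit_distance))
    expect_equal(hit$edit_distance, oracle)
  }
})

test_that("reverse-complement reads map to the same locus on the minus strand", {
  set.seed(25)
  g <- c(chr1 = random_dna_str(3000))
  fwd <- substring(g, 1001, 1100)
  rev <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(fwd)))
  h_f <- find_best_hits(c(r = fwd), g)
  h_r <- find_best_hits(c(r = rev), g)
  expect_equal(h_r$start, h_f$start)
  expect_equal(h_r$strand, "-")
  expect_equal(h_r$edit_distance, 0L)
})

test_that("assignment labels follow the competitive edit-distance rule", {
  expect_equal(assign_label(1L, 4L), "A")
  expect_equal(assign_label(4L, 1L), "B")
  expect_equal(assign_label(3L, 3L), "ambiguous")
  expect_equal(assign_label(NA_integer_, NA_integer_), "unmapped")
  expect_equal(assign_label(NA_integer_, 2L), "B")
  expect_equal(assign_label(c(0L, 5L, 2L, NA), c(3L, 5L, NA, NA)),
               c("A", "ambiguous", "A", "unmapped"))
})

test_that("labels partition reads and swap exactly under genome exchange", {
  sim <- shared_sim()
  reads <- dplyr::slice_head(sim$reads, n = 400)
  asg <- assign_reads(reads, sim$pair$genomes$A, sim$pair$genomes$B)
  expect_equal(nrow(asg), 400L)
  expect_true(all(asg$label %in% c("A", "B", "ambiguous", "unmapped")))
  swapped <- assign_reads(reads, sim$pair$genomes$B, sim$pair$genomes$A)
  relabel <- c(A = "B", B = "A", ambiguous = "ambiguous",
               unmapped = "unmapped")
  expect_equal(swapped$label, unname(relabel[asg$label]))
  expect_equal(swapped$edit_a, asg$edit_b)
})

test_that("identical alleles leave every mapped read ambiguous", {
  cfg <- sim_config(seed = 31, n_chrom_per_genome = 1, chrom_length = 30000,
                    subst_rate = 0, indel_rate = 0, n_unalignable_blocks = 0,
                    n_peaks_conserved = 5, n_peaks_loss = 0,
                    n_peaks_unaligned = 0, reads_per_peak = 20,
                    background_read_rate = 0)
  pair <- plant_peaks(simulate_genome_pair(cfg))
  reads <- simulate_reads(pair)
  asg <- assign_reads(reads, pair)
  mapped <- dplyr::filter(asg, label != "unmapped")
  expect_gt(nrow(mapped), 0)
  expect_true(all(mapped$label == "ambiguous"))
})

test_that("assignment recovers the allele of origin at rodent-scale divergence", {
  sim <- shared_sim()
  asg <- assign_reads(sim$reads, sim$pair)
  joined <- dplyr::left_join(asg,
                             sim$reads[c("read_id", "true_genome")],
                             by = "read_id")
  informative <- dplyr::filter(joined, label %in% c("A", "B"))
  expect_gte(mean(informative$label == informative$true_genome), 0.99)
})

test_that("short reads warn and return unmapped", {
  g <- c(chr1 = random_dna_str(1000))
  expect_warning(h <- find_best_hits(c(r = "ACGTACG"), g, k = 12),
                 "unmapped")
  expect_true(is.na(h$edit_distance))
})

test_that("count_matrix applies the midpoint rule and ignores ambiguous reads", {
  features <- tibble::tibble(
    feature_id = c("f1", "f2"), genome = "A", chrom = "chr1",
    start = c(100L, 200L), end = c(200L, 300L))
  asg <- tibble::tibble(
    read_id = c("r1", "r2", "r3", "r4"),
    label = c("A", "A", "ambiguous", "B"),
    chrom = "chr1",
    start = c(150L, 150L, 150L, 150L),
    end = c(250L, 180L, 250L, 250L))
  # r1 spans both features; its midpoint (200) is in f2 only
  out <- count_matrix(asg, features)
  expect_equal(out$count_a[out$feature_id == "f1"], 1L)
  expect_equal(out$count_a[out$feature_id == "f2"], 1L)
  expect_equal(sum(out$count_a), 2L)
  expect_equal(sum(out$count_b), 0L)
  # empty assignment gives an all-zero matrix
  zero <- count_matrix(asg[0, ], features)
  expect_true(all(zero$count_a == 0L & zero$count_b == 0L))
  expect_error(count_matrix(asg, dplyr::mutate(features, chrom = "chrX"),
                            chrom_names = "chr1"), "chrX")
})

test_that("per-peak counts account for every peak read in a clean simulation", {
  cfg <- sim_config(seed = 33, n_chrom_per_genome = 1, chrom_length = 60000,
                    n_peaks_conserved = 8, n_peaks_loss = 4,
                    n_peaks_unaligned = 2, n_unalignable_blocks = 3,
                    reads_per_peak = 10, background_read_rate = 0)
  pair <- plant_peaks(simulate_genome_pair(cfg))
  reads <- simulate_reads(pair)
  asg <- assign_reads(reads, pair)
  features <- dplyr::mutate(pair$peaks, feature_id = peak_id)
  counts <- count_matrix(asg, features)
  n_informative <- sum(asg$label %in% c("A", "B"))
  # reads whose fragment midpoint drifted outside the 400 bp peak are the
  # only legitimate loss; totals must not exceed the informative reads
  total_counted <- sum(counts$count_a) + sum(counts$count_b)
  expect_lte(total_counted, n_informative)
  expect_gte(total_counted, 0.6 * nrow(reads))
})
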