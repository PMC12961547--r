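test_that("the consensus scores maximally at position 0 on the plus strand", {
  x <- cdx2_demo_pwm()
  hits <- scan_pwm(c(s = pwm_consensus(x)), x, p_threshold = 1)
  plus <- dplyr::filter(hits, strand == "+")
  expect_equal(plus$position, 0L)
  # no window anywhere can score higher than the consensus
  tab_max <- sum(apply(log2(sweep(x$probs, 2, x$background, "/")), 1, max))
  expect_lt(abs(plus$score - tab_max), 0.05)
})

test_that("reverse-complementing a sequence mirrors the hit set", {
  set.seed(51)
  x <- cdx2_demo_pwm()
  seq <- paste0(random_dna_str(40), pwm_consensus(x), random_dna_str(40))
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
  h1 <- scan_pwm(c(s = seq), x)
  h2 <- scan_pwm(c(s = rc), x)
  expect_equal(nrow(h1), nrow(h2))
  L <- nchar(seq); w <- x$width
  mirrored <- sort(L - w - h2$position)
  expect_equal(sort(h1$position), mirrored)
  expect_equal(sort(h1$score), sort(h2$score))
})

test_that("DP p-values equal exhaustive enumeration for a width-6 PWM", {
  set.seed(52)
  probs <- matrix(runif(24, 0.05, 1), ncol = 4)
  x <- pwm(probs, pseudocount = 0.05)
  tab <- cisdiverge:::pwm_score_table(x, precision = 100L)
  enum <- oracle_pwm_enum(x, precision = 100L)
  test_scores <- seq(tab$smin, tab$smax, length.out = 25) |> round()
  expect_equal(cisdiverge:::pwm_pvalue(tab, test_scores),
               enum(test_scores), tolerance = 1e-12)
})

test_that("p-values are monotone non-increasing in score", {
  x <- cdx2_demo_pwm()
  tab <- cisdiverge:::pwm_score_table(x)
  s <- seq(tab$smin, tab$smax, by = 25L)
  p <- cisdiverge:::pwm_pvalue(tab, s)
  expect_true(all(diff(p) <= 1e-15))
})

test_that("N bases contribute zero log-odds and all-N sequences yield no hits", {
  x <- cdx2_demo_pwm()
  allN <- paste(rep("N", 50), collapse = "")
  expect_equal(nrow(scan_pwm(c(s = allN), x)), 0L)
  # a consensus with one N scores lower but still near-maximal
  withN <- sub("^.", "N", pwm_consensus(x))
  h <- scan_pwm(c(s = withN), x, p_threshold = 1)
  full <- scan_pwm(c(s = pwm_consensus(x)), x, p_threshold = 1)
  expect_lt(max(h$score), max(full$score))
})

test_that("motif fractions are 1 when the consensus is planted in every peak", {
  sim <- shared_sim()
  pair <- sim$pair
  pa <- dplyr::filter(pair$peaks, genome == "A")
  pb <- dplyr::filter(pair$peaks, genome == "B")
  proj <- project_peaks(pa, pair$genomes$A, pair$genomes$B, pb)
  win <- extract_window(pa, pair$genomes$A)
  frac <- motif_fraction_by_class(proj, win, cdx2_demo_pwm())
  expect_true(all(frac$fraction == 1))
  expect_setequal(frac$klass, c("conserved", "loss", "unaligned"))
})

test_that("background-sequence hit fraction matches the closed-form expectation", {
  set.seed(53)
  x <- cdx2_demo_pwm()
  L <- 400L; n <- 400L
  seqs <- setNames(vapply(seq_len(n), function(i) random_dna_str(L),
                          character(1)), sprintf("s%03d", seq_len(n)))
  hits <- scan_pwm(seqs, x, p_threshold = 1e-4)
  observed <- length(unique(hits$peak_id)) / n
  # realised per-window rate: the exact tail probability at the hit cutoff
  tab <- cisdiverge:::pwm_score_table(x)
  p_realised <- max(tab$tail[tab$tail <= 1e-4])
  expected <- 1 - (1 - p_realised)^(2 * (L - x$width + 1))
  se <- sqrt(expected * (1 - expected) / n)
  expect_lt(abs(observed - expected), 4 * se + 0.01)
})

test_that("ablating motifs in loss windows orders class fractions", {
  set.seed(54)
  x <- cdx2_demo_pwm()
  n <- 60L
  cons_win <- vapply(seq_len(n), function(i) {
    paste0(random_dna_str(196), pwm_consensus(x), random_dna_str(196))
  }, character(1))
  loss_win <- vapply(seq_len(n), function(i) random_dna_str(400),
                     character(1))
  windows <- tibble::tibble(
    peak_id = c(sprintf("c%02d", 1:n), sprintf("l%02d", 1:n)),
    seq = c(cons_win, loss_win))
  proj <- tibble::tibble(peak_id = windows$peak_id,
                         klass = rep(c("conserved", "loss"), each = n))
  frac <- motif_fraction_by_class(proj, windows, x)
  expect_gt(frac$fraction[frac$klass == "conserved"],
            frac$fraction[frac$klass == "loss"])
})

test_that("MEME text round-trips through the reader and writer", {
  x <- cdx2_demo_pwm()
  path <- withr::local_tempfile(fileext = ".meme")
  write_meme(x, path)
  y <- read_meme(path, pseudocount = 0)   # probs were already regularised
  expect_equal(y$width, x$width)
  expect_equal(y$probs, x$probs, tolerance = 1e-4)
  expect_equal(pwm_consensus(y), pwm_consensus(x))
})

test_that("malformed PWMs are rejected", {
  expect_error(pwm(matrix(1, 3, 3)), "4 columns")
  expect_error(pwm(matrix(-1, 3, 4)), "non-negative")
  expect_error(pwm(matrix(1, 3, 4), background = c(0.5, 0.5, 0.5, 0.5)),
               "sum to 1")
})
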