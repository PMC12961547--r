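# Independent oracles used to validate the package's own aligners and
# statistics. All are built on Biostrings dynamic programming or exhaustive
# enumeration, not on the package's code paths.

# Minimum Levenshtein distance of `read` against any substring of `text`
# (free end gaps on the text): full DP via pairwiseAlignment.
oracle_edit_infix <- function(read, text) {
  sm <- Biostrings::nucleotideSubstitutionMatrix(match = 0, mismatch = -1)
  -Biostrings::score(Biostrings::pairwiseAlignment(
    read, text, type = "global-local", substitutionMatrix = sm,
    gapOpening = 0, gapExtension = 1))
}

# Levenshtein distance of two whole strings (base R full DP).
oracle_edit_global <- function(a, b) {
  as.integer(utils::adist(a, b))
}

# Percent identity of a full Needleman-Wunsch alignment of two sequences.
oracle_nw_identity <- function(a, b) {
  sm <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1)
  pa <- Biostrings::pairwiseAlignment(a, b, type = "global",
                                      substitutionMatrix = sm,
                                      gapOpening = 2, gapExtension = 1)
  Biostrings::pid(pa, type = "PID1")
}

# Exhaustive tail p-values for a PWM of small width: enumerate all 4^w
# windows, score with the same discretised log-odds used by the scanner,
# and accumulate exact background-model tail probabilities.
oracle_pwm_enum <- function(x, precision = 100L) {
  li <- round(log2(sweep(x$probs, 2, x$background, "/")) * precision)
  w <- x$width
  grid <- expand.grid(rep(list(1:4), w))
  scores <- integer(nrow(grid))
  probs <- numeric(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    idx <- as.integer(grid[i, ])
    scores[i] <- sum(li[cbind(seq_len(w), idx)])
    probs[i] <- prod(x$background[idx])
  }
  function(score_int) {
    vapply(score_int, function(s) sum(probs[scores >= s]), numeric(1))
  }
}

# Mutate a DNA string at a per-site substitution rate (no indels).
mutate_no_indel <- function(seq, rate) {
  ch <- strsplit(seq, "")[[1]]
  pos <- which(runif(length(ch)) < rate)
  if (length(pos)) {
    bases <- c("A", "C", "G", "T")
    shift <- sample.int(3L, length(pos), replace = TRUE)
    ch[pos] <- bases[((match(ch[pos], bases) - 1L + shift) %% 4L) + 1L]
  }
  paste(ch, collapse = "")
}

random_dna_str <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
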