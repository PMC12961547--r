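#' Construct a position weight matrix
#'
#' Stores base probabilities per motif position after pseudocount
#' regularisation against the background, together with discretised log-odds
#' scores used for scanning and exact p-values.
#'
#' @param probs width x 4 numeric matrix of base probabilities, columns
#'   A, C, G, T. Rows are renormalised after adding
#'   `pseudocount * background`.
#' @param background Length-4 background distribution (default uniform, the
#'   0-order background used by FIMO-style scanners by default).
#' @param pseudocount Pseudocount mass added per row.
#' @param name Optional motif name.
#' @return A `cisdiv_pwm` object.
#' @export
pwm <- function(probs, background = rep(0.25, 4), pseudocount = 0.1,
                name = "motif") {
  probs <- as.matrix(probs)
  if (ncol(probs) != 4) abort("probs must have 4 columns (A, C, G, T)")
  if (any(probs < 0)) abort("probs must be non-negative")
  if (abs(sum(background) - 1) > 1e-9) abort("background must sum to 1")
  probs <- sweep(probs, 1, rowSums(probs), "/")
  probs <- sweep(probs + pseudocount * matrix(background, nrow(probs), 4,
                                              byrow = TRUE),
                 1, 1 + pseudocount, "/")
  colnames(probs) <- DNA_BASES
  structure(list(width = nrow(probs), probs = probs,
                 background = background, pseudocount = pseudocount,
                 name = name),
            class = "cisdiv_pwm")
}

#' @export
print.cisdiv_pwm <- function(x, ...) {
  cat(sprintf("<cisdiv_pwm> %s, width %d, consensus %s\n",
              x$name, x$width, pwm_consensus(x)))
  invisible(x)
}

#' Consensus sequence of a PWM
#' @param x A `cisdiv_pwm`.
#' @return Character scalar: the most probable base at each position.
#' @export
pwm_consensus <- function(x) {
  paste(DNA_BASES[apply(x$probs, 1, which.max)], collapse = "")
}

#' Read a motif in MEME text format
#'
#' Parses the minimal MEME motif format: a `MOTIF` line followed by a
#' `letter-probability matrix` block of width rows over A, C, G, T. Only the
#' first motif in the file is read. A `Background letter frequencies` line is
#' honoured when present.
#'
#' @param path Path to a MEME-format text file.
#' @inheritParams pwm
#' @return A `cisdiv_pwm`.
#' @export
read_meme <- function(path, pseudocount = 0.1) {
  lines <- readLines(path)
  mline <- grep("^MOTIF", lines)
  if (!length(mline)) abort("no MOTIF line found")
  name <- trimws(sub("^MOTIF\\s+", "", lines[mline[1]]))
  bg <- rep(0.25, 4)
  bgl <- grep("^Background letter frequencies", lines)
  if (length(bgl) && bgl[1] + 1 <= length(lines)) {
    tok <- strsplit(trimws(lines[bgl[1] + 1]), "\\s+")[[1]]
    vals <- suppressWarnings(as.numeric(tok))
    named <- vals[!is.na(vals)]
    if (length(named) == 4) bg <- named
  }
  hline <- grep("letter-probability matrix", lines)
  if (!length(hline)) abort("no letter-probability matrix found")
  rows <- list()
  i <- hline[1] + 1
  while (i <= length(lines)) {
    tok <- suppressWarnings(as.numeric(strsplit(trimws(lines[i]), "\\s+")[[1]]))
    if (length(tok) != 4 || anyNA(tok)) break
    rows[[length(rows) + 1]] <- tok
    i <- i + 1
  }
  if (!length(rows)) abort("empty letter-probability matrix")
  pwm(do.call(rbind, rows), background = bg, pseudocount = pseudocount,
      name = name)
}

#' Write a motif in MEME text format
#' @param x A `cisdiv_pwm`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_meme <- function(x, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "",
               "strands: + -", "", "Background letter frequencies",
               paste(sprintf("%s %.5f", DNA_BASES, x$background),
                     collapse = " "), "",
               sprintf("MOTIF %s", x$name),
               sprintf("letter-probability matrix: alength= 4 w= %d", x$width)),
             con)
  writeLines(apply(x$probs, 1, function(r) paste(sprintf("%.6f", r),
                                                 collapse = " ")), con)
  invisible(path)
}

#' Demo caudal-type homeodomain-like motif
#'
#' A synthetic A/T-rich homeodomain-like matrix shipped for examples and
#' simulations. It is not the experimentally derived CDX2 matrix; drop in any
#' MEME-format PWM (e.g. from JASPAR) via [read_meme()] for real analyses.
#'
#' @return A `cisdiv_pwm` of width 8.
#' @export
cdx2_demo_pwm <- function() {
  read_meme(system.file("extdata", "cdx2_like_synthetic.meme",
                        package = "cisdiverge"))
}

# Discretised log-odds scores (integer units of 1/precision bits) and the
# exact tail distribution of the window score under the background model,
# computed by dynamic programming (convolution across motif positions).
pwm_score_table <- function(x, precision = 100L) {
  lo <- log2(sweep(x$probs, 2, x$background, "/"))
  li <- round(lo * precision)          # width x 4 integer scores
  smin <- sum(apply(li, 1, min)); smax <- sum(apply(li, 1, max))
  dist <- numeric(smax - smin + 1)     # over offset score - smin
  # running support bounds keep the vector small
  cmin <- 0L; cmax <- 0L
  dist_cur <- c(1)                     # P(score_0 = 0) = 1
  for (i in seq_len(x$width)) {
    nmin <- cmin + min(li[i, ]); nmax <- cmax + max(li[i, ])
    nxt <- numeric(nmax - nmin + 1)
    for (b in 1:4) {
      off <- cmin + li[i, b] - nmin
      idx <- seq_along(dist_cur) + off
      nxt[idx] <- nxt[idx] + dist_cur * x$background[b]
    }
    dist_cur <- nxt; cmin <- nmin; cmax <- nmax
  }
  tail_p <- rev(cumsum(rev(dist_cur)))  # P(score >= s)
  list(scores_int = li, smin = cmin, smax = cmax, tail = tail_p,
       precision = precision)
}

# p-value of integer window scores from the score table
pwm_pvalue <- function(table, score_int) {
  idx <- pmin(pmax(score_int - table$smin + 1L, 1L),
              length(table$tail))
  p <- table$tail[idx]
  p[score_int > table$smax] <- 0
  p[score_int < table$smin] <- 1
  p
}

# integer window scores along one sequence (positions 0-based); N bases
# contribute 0 log-odds
score_windows_int <- function(seq, li) {
  w <- nrow(li)
  code <- match(strsplit(toupper(seq), "")[[1]], DNA_BASES)
  L <- length(code)
  if (L < w) return(integer(0))
  n <- L - w + 1L
  s <- numeric(n)
  for (i in seq_len(w)) {
    contrib <- li[i, code[i:(i + n - 1L)]]
    contrib[is.na(contrib)] <- 0
    s <- s + contrib
  }
  as.integer(round(s))
}

#' Scan sequences with a PWM and exact p-values
#'
#' Scores every window on both strands with the log-odds of the PWM against
#' its background, and converts scores to exact p-values: the tail
#' probability of the window score under the background model, computed by
#' dynamic programming over scores discretised at `1/precision` bit.
#' Windows with `p <= p_threshold` are reported as hits.
#'
#' @param seqs Character vector of sequences or a tibble with `peak_id` and
#'   `seq` (e.g. from [extract_window()]).
#' @param x A `cisdiv_pwm`.
#' @param p_threshold Hit p-value threshold (default 1e-4, the FIMO default).
#' @param precision Score discretisation (bins per bit).
#' @return Tibble of hits: `peak_id`, `position` (0-based window start on the
#'   forward strand), `strand`, `score` (bits), `p_value`.
#' @export
scan_pwm <- function(seqs, x, p_threshold = 1e-4, precision = 100L) {
  if (is.character(seqs)) {
    seqs <- tibble(peak_id = names(seqs) %||%
                     sprintf("seq_%d", seq_along(seqs)),
                   seq = unname(seqs))
  }
  tab <- pwm_score_table(x, precision)
  w <- x$width
  out <- purrr::map(seq_len(nrow(seqs)), function(i) {
    s <- seqs$seq[i]
    L <- nchar(s)
    if (L < w) return(NULL)
    res <- list()
    for (st in c("+", "-")) {
      sc <- score_windows_int(if (st == "+") s else revcomp_chr(s),
                              tab$scores_int)
      p <- pwm_pvalue(tab, sc)
      hit <- which(p <= p_threshold)
      if (!length(hit)) next
      pos <- if (st == "+") hit - 1L else L - w - (hit - 1L)
      res[[st]] <- tibble(peak_id = seqs$peak_id[i], position = pos,
                          strand = st, score = sc[hit] / precision,
                          p_value = p[hit])
    }
    bind_rows(res)
  }) |> list_rbind()
  if (nrow(out) == 0) {
    out <- tibble(peak_id = character(), position = integer(),
                  strand = character(), score = numeric(), p_value = numeric())
  }
  arrange(out, .data$peak_id, .data$position)
}

#' Fraction of peaks carrying a motif, by orthology class
#'
#' @param projections Classified projections (with `peak_id`, `klass`).
#' @param windows Peak windows (`peak_id`, `seq`), e.g. [extract_window()].
#' @param x A `cisdiv_pwm`.
#' @inheritParams scan_pwm
#' @return Tibble `klass`, `n_peaks`, `n_with_motif`, `fraction`.
#' @export
motif_fraction_by_class <- function(projections, windows, x,
                                    p_threshold = 1e-4, precision = 100L) {
  hits <- scan_pwm(windows, x, p_threshold, precision)
  with_hit <- unique(hits$peak_id)
  filter(projections, !is.na(.data$klass)) |>
    group_by(.data$klass) |>
    summarise(n_peaks = n(),
              n_with_motif = sum(.data$peak_id %in% with_hit)) |>
    mutate(fraction = .data$n_with_motif / .data$n_peaks)
}
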