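#' Read peaks from a narrowPeak/BED file
#'
#' Accepts ENCODE narrowPeak (10 columns, summit as offset from start in the
#' last column) or BED6+summit. Coordinates are 0-based half-open; the
#' returned `summit` is absolute.
#'
#' @param path Path to the peak file.
#' @return Tibble `chrom`, `start`, `end`, `peak_id`, `signal`,
#'   `qvalue_neglog10`, `summit`.
#' @export
read_narrowpeak <- function(path) {
  df <- readr::read_tsv(path, col_names = FALSE, comment = "#",
                        show_col_types = FALSE, progress = FALSE)
  if (ncol(df) < 7) abort("expected at least 7 columns (BED6 + summit)")
  if (ncol(df) >= 10) {
    out <- tibble(chrom = as.character(df[[1]]), start = as.integer(df[[2]]),
                  end = as.integer(df[[3]]), peak_id = as.character(df[[4]]),
                  signal = as.numeric(df[[7]]),
                  qvalue_neglog10 = as.numeric(df[[9]]),
                  summit = as.integer(df[[2]]) + as.integer(df[[10]]))
  } else {
    out <- tibble(chrom = as.character(df[[1]]), start = as.integer(df[[2]]),
                  end = as.integer(df[[3]]), peak_id = as.character(df[[4]]),
                  signal = as.numeric(df[[5]]), qvalue_neglog10 = NA_real_,
                  summit = as.integer(df[[2]]) + as.integer(df[[7]]))
  }
  if (any(out$summit < out$start | out$summit >= out$end)) {
    abort("summit outside peak interval")
  }
  out
}

#' Write peaks as narrowPeak
#'
#' @param peaks Tibble as returned by [read_narrowpeak()] (absolute
#'   `summit`).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_narrowpeak <- function(peaks, path) {
  df <- tibble(
    chrom = peaks$chrom, start = peaks$start, end = peaks$end,
    name = peaks$peak_id, score = 0L, strand = ".",
    signalValue = peaks$signal, pValue = -1,
    qValue = peaks$qvalue_neglog10 %||% -1,
    peak = peaks$summit - peaks$start
  )
  readr::write_tsv(df, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Read a genome FASTA as a named character vector
#'
#' @param path FASTA path.
#' @return Named character vector of chromosome sequences.
#' @export
read_genome_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  setNames(toupper(as.character(ss)), sub("\\s.*$", "", names(ss)))
}
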