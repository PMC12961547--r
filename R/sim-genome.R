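#' Simulate a pair of homologous parental genomes
#'
#' Builds genome A as random sequence and derives genome B from it by point
#' substitution and short indels, then splices lineage-specific random-sequence
#' blocks into each genome. The true base-level homology between the two
#' genomes is recorded as a coordinate map of aligned blocks, so downstream
#' stages (read assignment, peak projection) can be scored against truth.
#'
#' All coordinates are 0-based half-open. Chromosomes carry the same names in
#' both genomes; homology is chromosome-wise.
#'
#' @param config A [sim_config()].
#' @param out_dir Optional directory; when given, the two genomes are also
#'   written as `genome_A.fa` / `genome_B.fa`.
#' @return A `cisdiv_genome_pair`: list with `genomes` (named list `A`, `B` of
#'   named character vectors of chromosome sequence), `coord_map` (tibble
#'   `chrom`, `a_start`, `b_start`, `len` of exactly-paired homologous runs),
#'   `blocks` (tibble `genome`, `chrom`, `start`, `end` of lineage-specific
#'   insertions, in final coordinates) and `config`.
#' @examples
#' pair <- simulate_genome_pair(sim_config(seed = 7, chrom_length = 20000,
#'                                         n_unalignable_blocks = 2))
#' head(pair$coord_map)
#' @export
simulate_genome_pair <- function(config, out_dir = NULL) {
  validate_sim_config(config)
  block_len <- 3L * config$peak_window
  if (config$chrom_length < 4L * block_len + 4L * config$peak_window) {
    abort("chrom_length too small to host lineage-specific blocks and peaks")
  }
  set.seed(stage_seed(config$seed, "genome"))

  chrom_names <- sprintf("chr%d", seq_len(config$n_chrom_per_genome))
  # spread the per-genome block budget over chromosomes
  blocks_per_chrom <- function(n) {
    tabulate(sample.int(config$n_chrom_per_genome, n, replace = TRUE),
             nbins = config$n_chrom_per_genome)
  }
  n_blocks_a <- blocks_per_chrom(config$n_unalignable_blocks)
  n_blocks_b <- blocks_per_chrom(config$n_unalignable_blocks)

  genomes_a <- list(); genomes_b <- list()
  maps <- list(); blocks <- list()
  for (ci in seq_along(chrom_names)) {
    chars_a <- sample(DNA_BASES, config$chrom_length, replace = TRUE)
    mut <- mutate_chrom(chars_a, config$subst_rate, config$indel_rate,
                        config$mean_indel_len)
    spliced <- splice_blocks(chars_a, mut$chars_b, mut$map,
                             n_blocks_a[ci], n_blocks_b[ci], block_len)
    genomes_a[[chrom_names[ci]]] <- paste(spliced$chars_a, collapse = "")
    genomes_b[[chrom_names[ci]]] <- paste(spliced$chars_b, collapse = "")
    maps[[ci]] <- mutate(spliced$map, chrom = chrom_names[ci])
    if (nrow(spliced$blocks) > 0) {
      blocks[[ci]] <- mutate(spliced$blocks, chrom = chrom_names[ci])
    }
  }
  pair <- structure(list(
    genomes = list(A = unlist(genomes_a), B = unlist(genomes_b)),
    coord_map = select(bind_rows(maps), "chrom", "a_start", "b_start", "len"),
    blocks = if (length(blocks)) {
      select(bind_rows(blocks), "genome", "chrom", "start", "end")
    } else {
      tibble(genome = character(), chrom = character(),
             start = integer(), end = integer())
    },
    config = config
  ), class = "cisdiv_genome_pair")
  if (!is.null(out_dir)) write_genome_fasta(pair, out_dir)
  pair
}

# Substitute and indel-mutate one chromosome (character vector in, list out).
# The returned map pairs positions of A with positions of B for every
# homologous (non-indel) site, as blocks (a_start, b_start, len), 0-based.
mutate_chrom <- function(chars_a, subst_rate, indel_rate, mean_indel_len) {
  L <- length(chars_a)
  chars_sub <- chars_a
  if (subst_rate > 0) {
    pos <- which(runif(L) < subst_rate)
    if (length(pos)) {
      # substitute with one of the three other bases, uniformly
      shift <- sample.int(3L, length(pos), replace = TRUE)
      old <- match(chars_a[pos], DNA_BASES)
      chars_sub[pos] <- DNA_BASES[((old - 1L + shift) %% 4L) + 1L]
    }
  }
  events <- if (indel_rate > 0) which(runif(L) < indel_rate) else integer()
  if (length(events) == 0) {
    return(list(chars_b = chars_sub,
                map = tibble(a_start = 0L, b_start = 0L, len = L)))
  }
  is_ins <- runif(length(events)) < 0.5
  lens <- rgeom(length(events), prob = 1 / mean_indel_len) + 1L

  out <- vector("list", 2L * length(events) + 1L)
  map_a <- integer(); map_b <- integer(); map_len <- integer()
  a_cur <- 0L; b_cur <- 0L; oi <- 0L
  for (k in seq_along(events)) {
    p <- events[k] - 1L           # 0-based event position
    if (p < a_cur) next           # swallowed by a previous deletion
    seg_len <- p - a_cur
    if (seg_len > 0) {
      oi <- oi + 1L
      out[[oi]] <- chars_sub[(a_cur + 1L):p]
      map_a <- c(map_a, a_cur); map_b <- c(map_b, b_cur)
      map_len <- c(map_len, seg_len)
      b_cur <- b_cur + seg_len
    }
    a_cur <- p
    if (is_ins[k]) {
      oi <- oi + 1L
      out[[oi]] <- sample(DNA_BASES, lens[k], replace = TRUE)
      b_cur <- b_cur + lens[k]
    } else {
      a_cur <- min(L, a_cur + lens[k])
    }
  }
  if (a_cur < L) {
    oi <- oi + 1L
    out[[oi]] <- chars_sub[(a_cur + 1L):L]
    map_a <- c(map_a, a_cur); map_b <- c(map_b, b_cur)
    map_len <- c(map_len, L - a_cur)
  }
  list(chars_b = unlist(out[seq_len(oi)]),
       map = tibble(a_start = map_a, b_start = map_b, len = map_len))
}

# Insert lineage-specific random blocks into each genome and lift the
# coordinate map onto the final coordinates.
splice_blocks <- function(chars_a, chars_b, map, n_a, n_b, block_len) {
  insert_blocks <- function(chars, n) {
    L <- length(chars)
    if (n == 0) {
      return(list(chars = chars,
                  at = integer(),
                  blocks = tibble(start = integer(), end = integer())))
    }
    # insertion points away from chromosome ends, mutually separated
    at <- sort(sample(seq(block_len, L - block_len), n))
    pieces <- vector("list", 2L * n + 1L)
    prev <- 0L
    starts <- integer(n)
    for (i in seq_len(n)) {
      pieces[[2L * i - 1L]] <- if (at[i] > prev) chars[(prev + 1L):at[i]] else character()
      pieces[[2L * i]] <- sample(DNA_BASES, block_len, replace = TRUE)
      starts[i] <- at[i] + (i - 1L) * block_len
      prev <- at[i]
    }
    pieces[[2L * n + 1L]] <- if (prev < L) chars[(prev + 1L):L] else character()
    list(chars = unlist(pieces), at = at,
         blocks = tibble(start = starts, end = starts + block_len))
  }
  sa <- insert_blocks(chars_a, n_a)
  sb <- insert_blocks(chars_b, n_b)

  # split map rows at the insertion points, then shift coordinates
  map <- split_map_rows(map, sa$at, "a_start")
  map <- split_map_rows(map, sb$at, "b_start")
  shift <- function(pos, at) pos + block_len * findInterval(pos, at)
  map$a_start <- shift(map$a_start, sa$at)
  map$b_start <- shift(map$b_start, sb$at)

  blocks <- bind_rows(
    mutate(sa$blocks, genome = "A"),
    mutate(sb$blocks, genome = "B")
  )
  list(chars_a = sa$chars, chars_b = sb$chars, map = map, blocks = blocks)
}

# Split any map row that straddles one of the cut positions (given on the
# `col` coordinate), so block insertion points never fall inside a row.
split_map_rows <- function(map, cuts, col) {
  other <- if (col == "a_start") "b_start" else "a_start"
  for (cut in cuts) {
    hit <- which(map[[col]] < cut & map[[col]] + map$len > cut)
    if (length(hit) == 1L) {
      row <- map[hit, ]
      left_len <- cut - row[[col]]
      right <- row
      right[[col]] <- row[[col]] + left_len
      right[[other]] <- row[[other]] + left_len
      right$len <- row$len - left_len
      map$len[hit] <- left_len
      map <- bind_rows(map, right)
    }
  }
  arrange(map, .data[[col]])
}

#' Map positions between the two genomes through the truth coordinate map
#'
#' @param pair A `cisdiv_genome_pair`.
#' @param chrom Chromosome name (recycled).
#' @param pos 0-based positions.
#' @param from `"A"` or `"B"`: the genome `pos` lives in.
#' @return Integer vector of homologous positions in the other genome, `NA`
#'   where the position has no homologue (indel or lineage-specific block).
#' @export
map_position <- function(pair, chrom, pos, from = c("A", "B")) {
  from <- match.arg(from)
  src <- if (from == "A") "a_start" else "b_start"
  dst <- if (from == "A") "b_start" else "a_start"
  out <- rep(NA_integer_, length(pos))
  chrom <- rep_len(chrom, length(pos))
  for (ch in unique(chrom)) {
    m <- arrange(filter(pair$coord_map, .data$chrom == ch), .data[[src]])
    sel <- which(chrom == ch)
    idx <- findInterval(pos[sel], m[[src]])
    ok <- idx > 0 & pos[sel] < (m[[src]][pmax(idx, 1L)] + m$len[pmax(idx, 1L)])
    out[sel[ok]] <- as.integer(m[[dst]][idx[ok]] + pos[sel][ok] - m[[src]][idx[ok]])
  }
  out
}

#' Write the two simulated genomes as FASTA
#'
#' @param pair A `cisdiv_genome_pair`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the two file paths.
#' @export
write_genome_fasta <- function(pair, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("genome_A.fa", "genome_B.fa"))
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(pair$genomes$A), paths[1])
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(pair$genomes$B), paths[2])
  invisible(paths)
}

#' @export
print.cisdiv_genome_pair <- function(x, ...) {
  cat("<cisdiv_genome_pair>\n")
  cat(sprintf("  %d chromosome(s); A: %s bp, B: %s bp\n",
              length(x$genomes$A),
              format(sum(nchar(x$genomes$A)), big.mark = ","),
              format(sum(nchar(x$genomes$B)), big.mark = ",")))
  cat(sprintf("  coordinate map: %d homologous blocks; %d lineage-specific blocks\n",
              nrow(x$coord_map), nrow(x$blocks)))
  invisible(x)
}
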