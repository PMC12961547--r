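#' Percentages per peak class
#'
#' Converts class counts to percentages of the total, rounded half away from
#' zero to one decimal (two decimals under 1 percent), always reported next
#' to the raw counts.
#'
#' @param counts Named non-negative numeric vector (names = classes) or a
#'   tibble with `klass` and `n`.
#' @return Tibble `klass`, `n`, `percent`.
#' @examples
#' class_percentages(c(conserved = 17321, loss = 41430, unaligned = 13580))
#' @export
class_percentages <- function(counts) {
  if (is.data.frame(counts)) counts <- setNames(counts$n, counts$klass)
  if (any(counts < 0)) abort("counts must be non-negative")
  total <- sum(counts)
  if (total <= 0) abort("total count must be positive")
  tibble(klass = names(counts), n = unname(as.numeric(counts)),
         percent = unname(round_percent(100 * counts / total)))
}

#' Differential-expression summary
#'
#' @param n_up,n_down Non-negative integers.
#' @return One-row tibble: `total`, `up_percent`, `down_percent` (NA when
#'   the total is 0).
#' @examples
#' de_summary(1463, 1140)
#' @export
de_summary <- function(n_up, n_down) {
  if (n_up < 0 || n_down < 0) abort("counts must be non-negative")
  total <- n_up + n_down
  tibble(n_up = n_up, n_down = n_down, total = total,
         up_percent = if (total > 0) round_percent(100 * n_up / total) else NA_real_,
         down_percent = if (total > 0) round_percent(100 * n_down / total) else NA_real_)
}

#' Regulation-type summary
#'
#' Totals the five regulation-type counts and reports the conserved-regulation
#' share: the fraction of responding pairs (types 1-4) that respond
#' concordantly on both alleles (type 4).
#'
#' @param counts Length-5 non-negative vector of counts for types 0-4.
#' @return One-row tibble: `total`, `n_responding`, `conserved_share`
#'   (percent, NA when no pair responds).
#' @examples
#' type_summary(c(5592, 496, 1, 425, 858))
#' @export
type_summary <- function(counts) {
  if (length(counts) != 5) abort("counts must have length 5 (types 0-4)")
  if (any(counts < 0)) abort("counts must be non-negative")
  responding <- sum(counts[2:5])
  tibble(total = sum(counts), n_responding = responding,
         conserved_share = if (responding > 0) {
           round_percent(100 * counts[5] / responding)
         } else {
           NA_real_
         })
}

#' Run the full synthetic allodiploid pipeline
#'
#' Simulates a genome pair with planted peaks, reads and expression; assigns
#' reads to alleles, counts them per peak, compares allele binding strength,
#' projects and classifies peaks in both directions, measures motif
#' occurrence per class, types homolog pairs, links peaks to genes and
#' tabulates class composition per type — and scores every recovered
#' quantity against the planted truth.
#'
#' @param config A [sim_config()].
#' @param pwm Motif used for planting and scanning (default
#'   [cdx2_demo_pwm()]).
#' @param k,max_edit Read-mapping parameters (see [find_best_hits()]).
#' @param link_window Peak-to-gene window in bp (default 60000).
#' @return A `cisdiv_report` list: configuration, per-stage result tibbles
#'   and truth-versus-recovered confusion tables.
#' @export
run_pipeline <- function(config = sim_config(), pwm = cdx2_demo_pwm(),
                         k = 12L, max_edit = NULL, link_window = 60000L) {
  pair <- simulate_genome_pair(config)
  pair <- plant_peaks(pair, pwm, config)
  reads <- simulate_reads(pair, config)

  asg <- assign_reads(reads, pair, k = k, max_edit = max_edit)
  truth_lab <- left_join(asg, select(reads, "read_id", "true_genome"),
                         by = "read_id")
  assignment <- truth_lab |>
    count(.data$label, name = "n") |>
    mutate(fraction = .data$n / sum(.data$n))
  informative <- filter(truth_lab, .data$label %in% c("A", "B"))
  assignment_accuracy <- if (nrow(informative) > 0) {
    mean(informative$label == informative$true_genome)
  } else {
    NA_real_
  }

  features <- pair$peaks |>
    mutate(feature_id = .data$peak_id) |>
    select("feature_id", "genome", "chrom", "start", "end")
  peak_counts <- count_matrix(asg, features)
  # allele binding strength on conserved peak pairs: A-genome count vs the
  # homologous B-genome peak's count
  cons_a <- filter(pair$peak_truth, .data$genome == "A",
                   .data$klass == "conserved")$peak_id
  stronger <- tibble(
    peak_id = cons_a,
    norm_a = peak_counts$count_a[match(cons_a, peak_counts$feature_id)],
    norm_b = peak_counts$count_b[match(sub("^A_", "B_", cons_a),
                                       peak_counts$feature_id)]
  ) |> classify_chip_stronger()

  project_dir <- function(src, dst) {
    src_peaks <- filter(pair$peaks, .data$genome == src)
    dst_peaks <- filter(pair$peaks, .data$genome == dst)
    project_peaks(src_peaks, pair$genomes[[src]], pair$genomes[[dst]],
                  dst_peaks)
  }
  proj_ab <- project_dir("A", "B")
  proj_ba <- project_dir("B", "A")
  confusion <- function(proj, g) {
    left_join(proj, filter(pair$peak_truth, .data$genome == g),
              by = "peak_id") |>
      count(planted = .data$klass.y, recovered = .data$klass.x)
  }

  windows_a <- extract_window(filter(pair$peaks, .data$genome == "A"),
                              pair$genomes$A)
  motif_frac <- motif_fraction_by_class(proj_ab, windows_a, pwm)

  expr <- simulate_expression(config)
  typed <- type_genes(expr$counts)
  type_counts <- tabulate(typed$type + 1L, nbins = 5L)
  type_confusion <- left_join(typed, expr$truth, by = "pair_id") |>
    count(planted = .data$type.y, recovered = .data$type.x)

  genes <- simulate_gene_anchors(pair, expr$truth$pair_id, config)
  links <- link_peaks_to_genes(genes,
                               left_join(filter(pair$peaks, .data$genome == "A"),
                                         select(proj_ab, "peak_id", "klass"),
                                         by = "peak_id"),
                               window = link_window)
  composition <- class_composition_by_type(
    links, tibble(gene_id = typed$pair_id, type = typed$type))

  structure(list(
    config = config,
    reads = select(reads, -"seq"),
    assignment = assignment,
    assignment_accuracy = assignment_accuracy,
    peak_counts = peak_counts,
    chip_stronger = count(stronger, .data$stronger, name = "n"),
    projection = list(A_to_B = proj_ab, B_to_A = proj_ba),
    peak_class_summary = list(A_to_B = peak_class_summary(proj_ab),
                              B_to_A = peak_class_summary(proj_ba)),
    peak_confusion = list(A_to_B = confusion(proj_ab, "A"),
                          B_to_A = confusion(proj_ba, "B")),
    motif_fractions = motif_frac,
    typed = typed,
    type_counts = type_counts,
    type_summary = type_summary(type_counts),
    type_confusion = type_confusion,
    composition = composition
  ), class = "cisdiv_report")
}

# Deterministic gene anchors on genome A for peak-to-gene linking: TSSs are
# drawn near planted A peaks (within 25 kb) so links exist, others uniform.
simulate_gene_anchors <- function(pair, pair_ids, config) {
  set.seed(stage_seed(config$seed, "genes"))
  n <- length(pair_ids)
  chrom_len <- nchar(pair$genomes$A)
  pk <- filter(pair$peaks, .data$genome == "A")
  near <- runif(n) < 0.5 & nrow(pk) > 0
  idx <- sample.int(max(nrow(pk), 1L), n, replace = TRUE)
  tss_near <- pk$summit[idx] + as.integer(runif(n, -25000, 25000))
  ch_near <- pk$chrom[idx]
  ch_unif <- sample(names(chrom_len), n, replace = TRUE,
                    prob = chrom_len / sum(chrom_len))
  tss_unif <- as.integer(floor(runif(n) * (chrom_len[ch_unif] - 1L)))
  tibble(gene_id = pair_ids,
         chrom = if_else(near, ch_near, ch_unif),
         tss = pmax(0L, pmin(if_else(near, tss_near, tss_unif),
                             as.integer(chrom_len[if_else(near, ch_near, ch_unif)]) - 1L)),
         strand = sample(c("+", "-"), n, replace = TRUE))
}

#' @export
print.cisdiv_report <- function(x, ...) {
  cat("<cisdiv_report>\n\n")
  cat(sprintf("Reads: %d assigned (accuracy vs truth among A/B: %.4f)\n",
              sum(x$assignment$n), x$assignment_accuracy))
  print(x$assignment)
  cat("\nPeak classes, A -> B:\n"); print(x$peak_class_summary$A_to_B)
  cat("\nPeak classes, B -> A:\n"); print(x$peak_class_summary$B_to_A)
  cat("\nMotif fraction by class (A -> B):\n"); print(x$motif_fractions)
  cat(sprintf("\nRegulation types (0-4): %s\n",
              paste(x$type_counts, collapse = " / ")))
  print(x$type_summary)
  invisible(x)
}
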