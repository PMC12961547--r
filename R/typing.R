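#' Call the per-allele transcriptional response to TF induction
#'
#' Computes a per-allele log2 fold change (induced over control, with
#' pseudocount) after total-count library normalisation, averaging replicate
#' libraries when a `replicate` column is present, and calls each allele
#' `up`, `down` or `none`: a call requires `|log2fc| > fc_thresh` and the
#' allele to pass the expression floor (normalised count above `expr_floor`
#' in at least one condition).
#'
#' @param counts Long tibble: `pair_id`, `allele` (A/B), `condition`
#'   (ctrl/induced), `count`, optionally `replicate`.
#' @param fc_thresh log2 fold-change threshold (default 1).
#' @param expr_floor Expression floor on the normalised scale (default 3,
#'   strict).
#' @param pseudocount Added before log2 (default 1).
#' @param normalize Library normalisation across (condition x replicate)
#'   libraries: `"median_ratio"` (default) scales each library by the median
#'   ratio of its counts to a geometric-mean reference profile, which is
#'   robust to the asymmetric count inflation a strong induction response
#'   produces; `"total"` scales to the mean library total; `"none"` leaves
#'   counts as given.
#' @return Tibble, one row per pair: `pair_id`, per-allele normalised means,
#'   `log2fc_a`, `log2fc_b`, `expressed_a`, `expressed_b`, `call_a`,
#'   `call_b`, `candidate` (both alleles pass the floor).
#' @export
call_allele_response <- function(counts, fc_thresh = 1, expr_floor = 3,
                                 pseudocount = 1,
                                 normalize = c("median_ratio", "total", "none")) {
  normalize <- match.arg(normalize)
  if (any(counts$count < 0)) abort("negative counts are not allowed")
  if (!"replicate" %in% names(counts)) counts$replicate <- 1L
  counts <- mutate(ungroup(counts),
                   library = paste(.data$condition, .data$replicate, sep = "."),
                   feature = paste(.data$pair_id, .data$allele, sep = "."))
  sf <- library_size_factors(counts, normalize)
  counts <- left_join(counts, sf, by = "library") |>
    mutate(norm = .data$count / .data$size_factor)
  wide <- counts |>
    group_by(.data$pair_id, .data$allele, .data$condition) |>
    summarise(norm = mean(.data$norm), .groups = "drop") |>
    tidyr::pivot_wider(names_from = c("allele", "condition"),
                       values_from = "norm",
                       names_glue = "{tolower(allele)}_{condition}",
                       values_fill = 0)
  call_one <- function(fc, expressed) {
    case_when(!expressed ~ "none",
              fc > fc_thresh ~ "up",
              fc < -fc_thresh ~ "down",
              TRUE ~ "none")
  }
  wide |>
    mutate(
      log2fc_a = log2((.data$a_induced + pseudocount) /
                        (.data$a_ctrl + pseudocount)),
      log2fc_b = log2((.data$b_induced + pseudocount) /
                        (.data$b_ctrl + pseudocount)),
      expressed_a = pmax(.data$a_ctrl, .data$a_induced) > expr_floor,
      expressed_b = pmax(.data$b_ctrl, .data$b_induced) > expr_floor,
      call_a = call_one(.data$log2fc_a, .data$expressed_a),
      call_b = call_one(.data$log2fc_b, .data$expressed_b),
      candidate = .data$expressed_a & .data$expressed_b
    )
}

# Per-library size factors.  median_ratio: median over features of the
# ratio to the geometric-mean reference profile (features positive in all
# libraries); total: library total over the mean total; none: 1.
library_size_factors <- function(counts, method) {
  libs <- unique(counts$library)
  if (method == "none" || length(libs) < 2) {
    return(tibble(library = libs, size_factor = 1))
  }
  if (method == "total") {
    tot <- counts |> group_by(.data$library) |>
      summarise(total = sum(.data$count), .groups = "drop")
    return(mutate(tot, size_factor = if_else(.data$total > 0,
                                             .data$total / mean(.data$total), 1)) |>
             select("library", "size_factor"))
  }
  mat <- counts |>
    select("feature", "library", "count") |>
    tidyr::pivot_wider(names_from = "library", values_from = "count",
                       values_fn = sum, values_fill = 0)
  m <- as.matrix(mat[, libs, drop = FALSE])
  keep <- rowSums(m > 0) == ncol(m)
  if (!any(keep)) return(tibble(library = libs, size_factor = 1))
  logref <- rowMeans(log(m[keep, , drop = FALSE]))
  sf <- apply(m[keep, , drop = FALSE], 2, function(col) {
    exp(stats::median(log(col) - logref))
  })
  tibble(library = libs, size_factor = unname(sf[libs]))
}

#' Map per-allele calls to regulation types 0-4
#'
#' Type 0: neither allele responds; type 1: allele A (mouse-like) only;
#' type 2: the alleles move in opposite directions; type 3: allele B
#' (rat-like) only; type 4: both move in the same direction.
#'
#' @param call_a,call_b Character vectors over `up`, `down`, `none`.
#' @return Integer vector of types; the mapping is total.
#' @examples
#' assign_type(c("up", "up", "none"), c("up", "down", "none"))
#' @export
assign_type <- function(call_a, call_b) {
  dplyr::case_when(
    call_a == "none" & call_b == "none" ~ 0L,
    call_b == "none" ~ 1L,
    call_a == "none" ~ 3L,
    call_a == call_b ~ 4L,
    TRUE ~ 2L
  )
}

#' Type candidate homolog pairs by their allele-specific response
#'
#' Convenience wrapper: calls per-allele responses, restricts to candidate
#' pairs (both alleles passing the expression floor) and assigns types 0-4.
#'
#' @inheritParams call_allele_response
#' @return Tibble of candidate pairs with a `type` column.
#' @export
type_genes <- function(counts, fc_thresh = 1, expr_floor = 3,
                       pseudocount = 1,
                       normalize = c("median_ratio", "total", "none")) {
  call_allele_response(counts, fc_thresh, expr_floor, pseudocount,
                       normalize) |>
    filter(.data$candidate) |>
    mutate(type = assign_type(.data$call_a, .data$call_b))
}

#' Welch two-sample t test (native computation)
#'
#' The test statistic, Welch-Satterthwaite degrees of freedom and two-sided
#' p-value are computed directly from group means and variances.
#'
#' @param x,y Numeric vectors, each with at least 2 values.
#' @return One-row tibble: `estimate1`, `estimate2`, `statistic`,
#'   `parameter` (df), `p.value`.
#' @export
welch_t <- function(x, y) {
  if (length(x) < 2 || length(y) < 2) abort("each group needs n >= 2")
  m1 <- mean(x); m2 <- mean(y)
  v1 <- var(x) / length(x); v2 <- var(y) / length(y)
  se2 <- v1 + v2
  stat <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / (v1^2 / (length(x) - 1) + v2^2 / (length(y) - 1))
  p <- if (se2 == 0) {
    if (m1 == m2) 1 else 0
  } else {
    2 * pt(-abs(stat), df)
  }
  tibble(estimate1 = m1, estimate2 = m2,
         statistic = if (se2 == 0 && m1 == m2) 0 else stat,
         parameter = df, p.value = p)
}

#' Compare response magnitudes between regulation types
#'
#' Tests whether concordantly responding pairs (type 4) change more strongly
#' than allele-specific responders: `|log2fc_a|` of type 4 versus type 1 for
#' allele A, and `|log2fc_b|` of type 4 versus type 3 for allele B, by
#' Welch's t test.
#'
#' @param typed Output of [type_genes()].
#' @return A `cisdiv_magnitude` object; [tidy()] returns the two-row result
#'   table, [glance()] a one-row summary.
#' @export
magnitude_test <- function(typed) {
  cmp <- list(
    list(allele = "A", types = c(4L, 1L), col = "log2fc_a"),
    list(allele = "B", types = c(4L, 3L), col = "log2fc_b")
  )
  res <- purrr::map(cmp, function(cc) {
    g1 <- abs(typed[[cc$col]][typed$type == cc$types[1]])
    g2 <- abs(typed[[cc$col]][typed$type == cc$types[2]])
    if (length(g1) < 2 || length(g2) < 2) {
      return(tibble(allele = cc$allele,
                    comparison = sprintf("type %d vs type %d", cc$types[1],
                                         cc$types[2]),
                    n1 = length(g1), n2 = length(g2), estimate1 = NA_real_,
                    estimate2 = NA_real_, statistic = NA_real_,
                    parameter = NA_real_, p.value = NA_real_))
    }
    bind_cols(tibble(allele = cc$allele,
                     comparison = sprintf("type %d vs type %d",
                                          cc$types[1], cc$types[2]),
                     n1 = length(g1), n2 = length(g2)),
              welch_t(g1, g2))
  }) |> list_rbind()
  structure(list(table = res, typed = typed), class = "cisdiv_magnitude")
}

#' @export
print.cisdiv_magnitude <- function(x, ...) {
  cat("<cisdiv_magnitude> Welch t on |log2FC|, type 4 vs allele-specific types\n")
  print(x$table)
  invisible(x)
}

#' @rdname magnitude_test
#' @param x A `cisdiv_magnitude`.
#' @param ... Unused.
#' @export
tidy.cisdiv_magnitude <- function(x, ...) x$table

#' @rdname magnitude_test
#' @export
glance.cisdiv_magnitude <- function(x, ...) {
  tibble(n_pairs = nrow(x$typed),
         n_type4 = sum(x$typed$type == 4L),
         min_p = suppressWarnings(min(x$table$p.value, na.rm = TRUE)))
}

#' Pearson correlation of two expression profiles
#'
#' Pearson's r with a two-sided p-value from the t transform, as used for
#' comparing log-expression profiles between samples.
#'
#' @param x,y Equal-length numeric vectors, n >= 3.
#' @return One-row tibble: `estimate` (r), `statistic`, `parameter` (df),
#'   `p.value`.
#' @export
expression_correlation <- function(x, y) {
  if (length(x) != length(y)) abort("vectors must have equal length")
  if (length(x) < 3) abort("n >= 3 required")
  ct <- stats::cor.test(x, y, method = "pearson")
  tibble(estimate = unname(ct$estimate), statistic = unname(ct$statistic),
         parameter = unname(ct$parameter), p.value = ct$p.value)
}
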