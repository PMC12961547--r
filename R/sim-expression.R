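#' Simulate allele-specific expression responses to TF induction
#'
#' For each homologous gene pair a regulation type 0-4 is drawn from
#' `type_proportions` and per-allele counts are generated for the control and
#' induced conditions as negative binomial draws around `mean_expression`.
#' Responsive alleles shift their induced mean by `effect_size_log2` log2
#' units (with a small per-gene jitter), with the sign pattern dictated by the
#' type: type 0 no allele responds, type 1 only allele A (mouse-like), type 2
#' the two alleles move in opposite directions, type 3 only allele B
#' (rat-like), type 4 both move in the same direction.
#'
#' @param config A [sim_config()].
#' @return List with `counts` (long tibble `pair_id`, `allele` in A/B,
#'   `condition` in ctrl/induced, `count`) and `truth` (tibble `pair_id`,
#'   `type`, `sign_a`, `sign_b`).
#' @export
simulate_expression <- function(config) {
  validate_sim_config(config)
  set.seed(stage_seed(config$seed, "expression"))
  n <- config$n_genes
  type <- sample(0:4, n, replace = TRUE, prob = config$type_proportions)
  s <- sample(c(-1L, 1L), n, replace = TRUE)    # direction of the response
  sign_a <- dplyr::case_when(type %in% c(1L, 2L, 4L) ~ s, TRUE ~ 0L)
  sign_b <- dplyr::case_when(type %in% c(3L, 4L) ~ s, type == 2L ~ -s, TRUE ~ 0L)
  effect <- config$effect_size_log2 * runif(n, 0.8, 1.2)

  pair_id <- sprintf("pair_%05d", seq_len(n))
  draw <- function(mu) {
    if (config$dispersion > 0) {
      rnbinom(length(mu), mu = mu, size = 1 / config$dispersion)
    } else {
      rpois(length(mu), mu)
    }
  }
  base <- config$mean_expression
  counts <- tidyr::expand_grid(pair_idx = seq_len(n),
                               allele = c("A", "B"),
                               condition = c("ctrl", "induced")) |>
    mutate(
      pair_id = pair_id[.data$pair_idx],
      sgn = if_else(.data$allele == "A", sign_a[.data$pair_idx],
                    sign_b[.data$pair_idx]),
      mu = if_else(.data$condition == "induced",
                   base * 2^(.data$sgn * effect[.data$pair_idx]), base),
      count = draw(.data$mu)
    ) |>
    select("pair_id", "allele", "condition", "count")

  list(counts = counts,
       truth = tibble(pair_id = pair_id, type = type,
                      sign_a = sign_a, sign_b = sign_b))
}
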