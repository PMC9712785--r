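#' Upper-tail hypergeometric over-representation p-value
#'
#' Probability of observing `k` or more annotated genes when drawing
#' `n` query genes from a universe of `N` genes of which `K` carry the
#' annotation: `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`.
#'
#' @param k Overlap between query and term.
#' @param n Query size.
#' @param K Term size within the universe.
#' @param N Universe size.
#' @return The p-value.
#' @examples
#' hypergeom_test(5, 5, 5, 20) # 1 / choose(20, 5)
#' @export
hypergeom_test <- function(k, n, K, N) {
  ok <- k >= 0 & n >= 0 & K >= 0 & N >= 0 & k <= n & k <= K &
    n <= N & K <= N
  if (any(!ok)) stop_domain("need 0 <= k <= min(n, K) <= N")
  phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Benjamini–Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment with monotonicity enforcement;
#' values are returned in input order and capped at 1.
#'
#' @param p_values Vector of p-values.
#' @return Adjusted p-values.
#' @export
bh_adjust <- function(p_values) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) {
    stop_domain("p-values must lie in [0, 1]")
  }
  p.adjust(p_values, method = "BH")
}

#' Over-representation analysis of a gene set
#'
#' Tests each annotation set for enrichment of the query via the
#' upper-tail hypergeometric test, adjusts p-values by Benjamini–Hochberg
#' within each namespace (BP, MF, CC and pathway collections are treated
#' as separate families), and returns the top terms per namespace by
#' adjusted p-value. The universe defaults to the union of all annotation
#' members; query genes outside the universe are dropped with a warning.
#'
#' @param query Character vector of gene ids.
#' @param sets Annotation tibble from [read_gmt()] (rows from several
#'   namespaces may be combined with `rbind`).
#' @param universe Optional background gene ids.
#' @param top Terms to keep per namespace (default 10); `Inf` keeps all.
#' @param keep_zero Keep terms with zero overlap (default `FALSE`).
#' @return A tibble of enrichment results sorted by p-value within
#'   namespace, with counts `k_overlap`, `n_query`, `K_term`,
#'   `N_universe`, the `overlap_ids` list-column, `p_value` and
#'   `p_adjusted`.
#' @export
run_ora <- function(query, sets, universe = NULL, top = 10,
                    keep_zero = FALSE) {
  query <- unique(query)
  universe <- unique(universe %||% unlist(sets$members))
  outside <- setdiff(query, universe)
  if (length(outside) > 0L) {
    warn(paste0(length(outside),
                " query gene(s) outside the universe were dropped"))
    query <- intersect(query, universe)
  }
  n <- length(query)
  N <- length(universe)
  res <- sets
  res$members <- lapply(res$members, intersect, y = universe)
  res$K_term <- vapply(res$members, length, integer(1))
  res$overlap_ids <- lapply(res$members, intersect, y = query)
  res$k_overlap <- vapply(res$overlap_ids, length, integer(1))
  res$n_query <- n
  res$N_universe <- N
  res$n_query_dropped <- length(outside)
  res$p_value <- hypergeom_test(res$k_overlap, res$n_query, res$K_term,
                                res$N_universe)
  res <- res |>
    dplyr::group_by(.data$namespace) |>
    dplyr::mutate(p_adjusted = bh_adjust(.data$p_value)) |>
    dplyr::ungroup()
  if (!keep_zero) res <- res[res$k_overlap > 0L, ]
  res <- res[order(res$namespace, res$p_value, res$term_id), ]
  res <- res |>
    dplyr::group_by(.data$namespace) |>
    dplyr::slice_min(.data$p_adjusted, n = top, with_ties = FALSE) |>
    dplyr::ungroup()
  res[order(res$namespace, res$p_value, res$term_id),
      c("term_id", "term_name", "namespace", "k_overlap", "n_query",
        "K_term", "N_universe", "p_value", "p_adjusted", "overlap_ids",
        "n_query_dropped")]
}
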