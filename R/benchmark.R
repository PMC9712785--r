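# Ground-truth recovery harness: run the analysis stages on a simulated
# dataset and score them against the planted truth.

#' Analyse a simulated dataset end to end
#'
#' Runs the analysis stages the pipeline applies to real data — per-class
#' differential screening, seed-match interaction prediction on the DE
#' subsets, sponge-network construction with centralities, hub ranking,
#' and direction-consistent triad assembly — on the output of
#' [simulate_dataset()].
#'
#' @param sim A simulated dataset.
#' @param rule Screening rule.
#' @param hub_k Hub circRNAs to retain (capped at the number of circRNA
#'   nodes present).
#' @param min_score,min_sites Prediction thresholds.
#' @return A list with `screened` (per-class DE tibbles), `sponge_edges`,
#'   `target_edges`, `network`, `hubs`, `hub_edges` and `triads`.
#' @export
sim_analysis <- function(sim, rule = screening_rule(), hub_k = 5,
                         min_score = 3, min_sites = 1) {
  de <- lapply(setNames(RNA_CLASSES, RNA_CLASSES), function(cl) {
    de_from_counts(sim$counts[[cl]], sim$group, cl)
  })
  screened <- lapply(de, screen, rule = rule)

  seqs <- sim$sequences
  circ_ids <- screened$circRNA$feature_id
  mirna_ids <- screened$miRNA$feature_id
  mrna_ids <- screened$mRNA$feature_id
  mirna_fa <- seqs$mirna_seqs[intersect(names(seqs$mirna_seqs), mirna_ids)]
  circ_fa <- seqs$target_seqs[intersect(names(seqs$target_seqs), circ_ids)]
  mrna_fa <- seqs$target_seqs[intersect(names(seqs$target_seqs), mrna_ids)]

  quiet_predict <- function(...) suppressWarnings(predict_interactions(...))
  sponge_edges <- quiet_predict(mirna_fa, circ_fa, target_class = "circRNA",
                                min_score = min_score, min_sites = min_sites)
  target_edges <- quiet_predict(mirna_fa, mrna_fa, target_class = "mRNA",
                                min_score = min_score, min_sites = min_sites)

  all_de <- dplyr::bind_rows(screened)
  out <- list(screened = screened, sponge_edges = sponge_edges,
              target_edges = target_edges, network = NULL,
              hubs = NULL, hub_edges = sponge_edges[0, ],
              triads = assemble_triads(sponge_edges[0, ],
                                       list(), screened$mRNA))
  if (nrow(sponge_edges) == 0L) return(out)

  net <- add_centralities(build_network(sponge_edges, all_de))
  k <- min(hub_k, sum(igraph::V(net)$rna_class == "circRNA"))
  hubs <- rank_hub_circrnas(net, k = k)
  hub_edges <- hub_mirna_edges(hubs$circ_id, sponge_edges, mirna_ids)
  tmap <- expand_to_mrnas(unique(hub_edges$target_id), target_edges)
  triads <- assemble_triads(hub_edges, tmap, de_mrnas = screened$mRNA,
                            de_circs = screened$circRNA,
                            de_mirnas = screened$miRNA)
  out$network <- net
  out$hubs <- hubs
  out$hub_edges <- hub_edges
  out$triads <- triads
  out
}

#' Score an analysis of a simulated dataset against the planted truth
#'
#' @param sim A simulated dataset.
#' @param analysis Result of [sim_analysis()] on `sim`.
#' @return A one-row tibble with screening `sensitivity` and `precision`
#'   (pooled over the three RNA classes) and planted-triad `recall` and
#'   `triad_precision` in the assembled ceRNA network.
#' @export
evaluate_recovery <- function(sim, analysis) {
  truth_ids <- sim$truth$de$feature_id
  called <- unlist(lapply(analysis$screened, `[[`, "feature_id"),
                   use.names = FALSE)
  tp <- length(intersect(called, truth_ids))
  sens <- tp / length(truth_ids)
  prec <- if (length(called) == 0L) NA_real_ else tp / length(called)

  key <- function(x) paste(x$circ_id, x$mirna_id, x$mrna_id)
  truth_triads <- key(sim$truth$triads)
  found <- key(analysis$triads)
  recall <- if (length(truth_triads) == 0L) NA_real_ else
    mean(truth_triads %in% found)
  tprec <- if (length(found) == 0L) NA_real_ else
    mean(found %in% truth_triads)
  tibble::tibble(sensitivity = sens, precision = prec,
                 recall = recall, triad_precision = tprec)
}

#' Benchmark screening and triad recovery over replicate simulations
#'
#' Repeats simulate-analyse-score over `n_seeds` consecutive seeds and
#' averages the recovery metrics.
#'
#' @param n_seeds Number of replicate seeds.
#' @param cfg Base [sim_config()]; its `seed` is replaced by
#'   `base_seed + 0 ... n_seeds - 1`.
#' @param base_seed First seed.
#' @param hub_k Passed to [sim_analysis()].
#' @return A list with `per_seed` (tibble of per-seed metrics) and
#'   `means` (named vector of metric means).
#' @export
benchmark_recovery <- function(n_seeds = 50, cfg = sim_config(),
                               base_seed = 1L, hub_k = 5) {
  rows <- lapply(seq_len(n_seeds) - 1L, function(off) {
    cfg$seed <- as.integer(base_seed + off)
    sim <- simulate_dataset(cfg)
    res <- evaluate_recovery(sim, sim_analysis(sim, hub_k = hub_k))
    res$seed <- cfg$seed
    res
  })
  per_seed <- dplyr::bind_rows(rows)
  means <- colMeans(per_seed[, c("sensitivity", "precision", "recall",
                                 "triad_precision")], na.rm = TRUE)
  list(per_seed = per_seed, means = means)
}
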