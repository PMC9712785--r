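#' Build a sponge network from interaction edges
#'
#' Creates an undirected, typed graph from circRNA–miRNA (and optionally
#' miRNA–mRNA) interaction edges. Node direction of regulation is inherited
#' from differential-expression annotations when available; unannotated
#' nodes carry `NA`.
#'
#' @param edges Edge tibble as returned by [read_edge_list()] or
#'   [predict_interactions()].
#' @param de_annotations Optional DE-record tibble (any mix of RNA classes)
#'   supplying per-node `direction`.
#' @return An `igraph` object with vertex attributes `rna_class` and
#'   `direction` and edge attributes `sources` and `score`.
#' @examples
#' edges <- read_edge_list(spongenet_example("table4_sponge_edges.tsv"))
#' net <- build_network(edges)
#' igraph::vcount(net)
#' @export
build_network <- function(edges, de_annotations = NULL) {
  validate_edges(edges)
  nodes <- tibble::tibble(
    name = c(edges$source_id, edges$target_id),
    rna_class = c(edges$source_class, edges$target_class)
  ) |> dplyr::distinct()
  dup <- nodes$name[duplicated(nodes$name)]
  if (length(dup) > 0L) {
    stop_valid(paste0("node id used in more than one RNA class: ",
                      paste(unique(dup), collapse = ", ")))
  }
  nodes$direction <- NA_character_
  if (!is.null(de_annotations)) {
    idx <- match(nodes$name, de_annotations$feature_id)
    nodes$direction <- de_annotations$direction[idx]
  }
  edf <- data.frame(from = edges$source_id, to = edges$target_id,
                    sources = edges$sources %||% NA_character_,
                    score = edges$score %||% NA_real_,
                    stringsAsFactors = FALSE)
  igraph::graph_from_data_frame(edf, directed = FALSE,
                                vertices = as.data.frame(nodes))
}

#' Restrict a sponge network to differentially expressed miRNAs
#'
#' Removes miRNA nodes that are not in the supplied DE set, together with
#' their incident edges. circRNA (and mRNA) nodes are kept even if they
#' become isolated; the number of isolated circRNAs is reported.
#'
#' @param net A sponge network.
#' @param de_ids Character vector of DE miRNA ids, or a DE-record tibble.
#' @return The filtered network.
#' @export
restrict_to_de <- function(net, de_ids) {
  de_ids <- as_feature_ids(de_ids)
  v <- igraph::V(net)
  drop <- v$name[v$rna_class == "miRNA" & !(v$name %in% de_ids)]
  out <- igraph::delete_vertices(net, drop)
  iso <- sum(igraph::degree(out) == 0 &
               igraph::V(out)$rna_class == "circRNA")
  inform(paste0("restrict_to_de: removed ", length(drop), " miRNA node(s); ",
                iso, " circRNA node(s) now isolated"))
  out
}

#' Annotate a network with degree, betweenness and closeness centralities
#'
#' Degree is the incident-edge count. Betweenness follows the Freeman
#' definition with pair normalisation `2 / ((n-1)(n-2))`. Closeness uses
#' the Wasserman–Faust within-component scaling, the product of the
#' reachable-set fraction and the inverse mean distance to reachable
#' nodes, so that disconnected graphs are handled without infinities;
#' isolated nodes get closeness and betweenness 0.
#'
#' @param net A sponge network.
#' @return The network with vertex attributes `degree`, `betweenness`,
#'   `closeness` added.
#' @export
add_centralities <- function(net) {
  n <- igraph::vcount(net)
  deg <- igraph::degree(net)
  btw <- if (n >= 3) {
    igraph::betweenness(net, directed = FALSE, normalized = TRUE)
  } else {
    rep(0, n)
  }
  d <- igraph::distances(net)
  clo <- vapply(seq_len(n), function(i) {
    di <- d[i, -i]
    di <- di[is.finite(di)]
    r <- length(di)
    if (r == 0L || n == 1L) return(0)
    (r / (n - 1)) * (r / sum(di))
  }, double(1))
  net <- igraph::set_vertex_attr(net, "degree", value = deg)
  net <- igraph::set_vertex_attr(net, "betweenness", value = btw)
  igraph::set_vertex_attr(net, "closeness", value = clo)
}

#' Select key miRNAs by the median-multiple degree rule
#'
#' Computes the median degree over miRNA nodes and returns the miRNA nodes
#' whose degree is strictly greater than `multiplier` times that median.
#' The median over the middle pair is used for an even count. With
#' `scope = "all"` the median is taken over every node instead.
#'
#' @param net A sponge network.
#' @param multiplier Median multiplier (default 3).
#' @param scope `"miRNA"` (default) or `"all"`: which nodes enter the
#'   median.
#' @return A list with `mirna_ids` (selected miRNAs), `median_degree` and
#'   `threshold`.
#' @export
select_key_mirnas <- function(net, multiplier = 3, scope = c("miRNA", "all")) {
  scope <- match.arg(scope)
  v <- igraph::V(net)
  deg <- igraph::degree(net)
  mi <- v$rna_class == "miRNA"
  if (!any(mi)) {
    warn("network contains no miRNA nodes; returning empty selection")
    return(list(mirna_ids = character(), median_degree = NA_real_,
                threshold = NA_real_))
  }
  med <- median(if (scope == "miRNA") deg[mi] else deg)
  thr <- multiplier * med
  list(mirna_ids = sort(v$name[mi & deg > thr]),
       median_degree = med, threshold = thr)
}

#' Rank hub circRNAs by combined betweenness and closeness
#'
#' Among circRNA nodes not in `exclude` (a manually curated list, e.g. of
#' circRNAs already reported in the disease context), each node is ranked
#' separately by betweenness and by closeness; nodes are ordered by the
#' mean of the two ranks, with ties broken by higher degree and then by
#' id, and the top `k` are returned.
#'
#' @param net A sponge network (centralities are computed if absent).
#' @param exclude Character vector of circRNA ids to exclude.
#' @param k Number of hubs to return (default 5).
#' @return A tibble of the top `k` circRNAs with their centralities and
#'   combined `rank_score` (smaller is better).
#' @export
rank_hub_circrnas <- function(net, exclude = character(), k = 5) {
  if (is.null(igraph::vertex_attr(net, "betweenness"))) {
    net <- add_centralities(net)
  }
  v <- igraph::V(net)
  eligible <- v$rna_class == "circRNA" & !(v$name %in% exclude)
  tab <- tibble::tibble(
    circ_id = v$name[eligible],
    degree = v$degree[eligible],
    betweenness = v$betweenness[eligible],
    closeness = v$closeness[eligible]
  )
  if (nrow(tab) < k) {
    warn(paste0("only ", nrow(tab), " eligible circRNA node(s) for k = ", k))
  }
  tab$rank_score <- (rank(-tab$betweenness, ties.method = "average") +
                       rank(-tab$closeness, ties.method = "average")) / 2
  tab <- tab[order(tab$rank_score, -tab$degree, tab$circ_id), ]
  head(tab, k)
}

# Edge tibble view of a network (inverse of build_network for attributes
# the graph carries).
network_edges <- function(net) {
  if (igraph::ecount(net) == 0L) {
    return(tibble::tibble(source_id = character(), source_class = character(),
                          target_id = character(), target_class = character(),
                          sources = character(), score = double()))
  }
  ends <- igraph::as_edgelist(net)
  v <- igraph::V(net)
  cls <- setNames(v$rna_class, v$name)
  # orient edges canonically: circRNA->miRNA, miRNA->mRNA
  rank_of <- c(circRNA = 1L, miRNA = 2L, mRNA = 3L)
  swap <- rank_of[cls[ends[, 1]]] > rank_of[cls[ends[, 2]]]
  src <- ifelse(swap, ends[, 2], ends[, 1])
  tgt <- ifelse(swap, ends[, 1], ends[, 2])
  tibble::tibble(
    source_id = src, source_class = unname(cls[src]),
    target_id = tgt, target_class = unname(cls[tgt]),
    sources = igraph::edge_attr(net, "sources") %||%
      rep(NA_character_, nrow(ends)),
    score = igraph::edge_attr(net, "score") %||% rep(NA_real_, nrow(ends))
  )
}

network_nodes <- function(net) {
  v <- igraph::V(net)
  tibble::tibble(name = v$name, rna_class = v$rna_class,
                 direction = v$direction)
}
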