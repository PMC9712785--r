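#' Restrict sponge edges to hub circRNAs and DE miRNAs
#'
#' Keeps the circRNA–miRNA edges whose circRNA is one of the selected
#' hubs and whose miRNA is differentially expressed, deduplicating
#' repeated pairs.
#'
#' @param hubs Character vector of hub circRNA ids (or the tibble from
#'   [rank_hub_circrnas()]).
#' @param edges Sponge edge tibble (circRNA -> miRNA).
#' @param de_mirnas DE miRNA ids or DE-record tibble.
#' @return The filtered, deduplicated edge tibble.
#' @export
hub_mirna_edges <- function(hubs, edges, de_mirnas) {
  if (is.data.frame(hubs) && "circ_id" %in% names(hubs)) hubs <- hubs$circ_id
  de_mirnas <- as_feature_ids(de_mirnas)
  keep <- edges$source_class == "circRNA" & edges$target_class == "miRNA" &
    edges$source_id %in% hubs & edges$target_id %in% de_mirnas
  out <- edges[keep, ]
  if (nrow(out) == 0L) return(out)
  dedup_edges(out)
}

#' Expand miRNAs to their consensus mRNA targets
#'
#' Collects, for each miRNA, the mRNAs it targets according to the
#' supplied consensus edge list (the union/intersection policy is applied
#' upstream when the edges are predicted).
#'
#' @param mirna_ids miRNA ids to expand.
#' @param mirna_mrna_edges miRNA -> mRNA edge tibble.
#' @return A list with `targets_by_mirna` (named list of mRNA id vectors)
#'   and `union` (the merged mRNA set across the miRNAs).
#' @export
expand_to_mrnas <- function(mirna_ids, mirna_mrna_edges) {
  mirna_ids <- unique(as_feature_ids(mirna_ids))
  e <- mirna_mrna_edges[mirna_mrna_edges$source_class == "miRNA" &
                          mirna_mrna_edges$target_class == "mRNA" &
                          mirna_mrna_edges$source_id %in% mirna_ids, ]
  by_mirna <- lapply(setNames(mirna_ids, mirna_ids), function(mi) {
    sort(unique(e$target_id[e$source_id == mi]))
  })
  list(targets_by_mirna = by_mirna,
       union = sort(unique(unlist(by_mirna, use.names = FALSE))))
}

#' Assemble circRNA–miRNA–mRNA ceRNA triads
#'
#' Forms every (circRNA, miRNA, mRNA) combination along the hub sponge
#' edges and the miRNA->mRNA target map, annotates each triad with
#' direction-opposition flags, and filters by them. By default the mRNA
#' must be differentially expressed with direction opposite to its miRNA
#' (the ceRNA expectation: a sponged miRNA de-represses its targets);
#' circRNA–miRNA opposition is recorded but not required, since sponge
#' networks can legitimately retain same-direction pairs.
#'
#' @param hub_edges circRNA -> miRNA edge tibble; circRNA and miRNA
#'   directions are taken from its `source_regulation`/
#'   `target_regulation` columns when present, else from `de_circs` /
#'   `de_mirnas`.
#' @param mirna_mrna_map Result of [expand_to_mrnas()] (or a named list of
#'   mRNA vectors).
#' @param de_mrnas DE-record tibble for mRNAs (id + direction).
#' @param require_opposite_mrna Keep only triads whose mRNA is DE in the
#'   direction opposite to the miRNA (default `TRUE`).
#' @param require_opposite_circ Also require circRNA–miRNA opposition
#'   (default `FALSE`).
#' @param de_circs,de_mirnas Optional DE-record tibbles used to look up
#'   circRNA/miRNA directions.
#' @return A tibble of triads with per-member directions and logical
#'   flags `circ_mirna_opposite`, `mirna_mrna_opposite`.
#' @export
assemble_triads <- function(hub_edges, mirna_mrna_map, de_mrnas,
                            require_opposite_mrna = TRUE,
                            require_opposite_circ = FALSE,
                            de_circs = NULL, de_mirnas = NULL) {
  if (is.list(mirna_mrna_map) && !is.null(mirna_mrna_map$targets_by_mirna)) {
    mirna_mrna_map <- mirna_mrna_map$targets_by_mirna
  }
  lookup_dir <- function(ids, reg_col, de_tbl) {
    dir <- rep(NA_character_, length(ids))
    if (!is.null(reg_col)) dir <- tolower(as.character(reg_col))
    miss <- is.na(dir)
    if (any(miss) && !is.null(de_tbl)) {
      dir[miss] <- de_tbl$direction[match(ids[miss], de_tbl$feature_id)]
    }
    dir
  }
  col_or_null <- function(tab, col) {
    if (col %in% names(tab)) tab[[col]] else NULL
  }
  circ_dir <- lookup_dir(hub_edges$source_id,
                         col_or_null(hub_edges, "source_regulation"),
                         de_circs)
  mirna_dir <- lookup_dir(hub_edges$target_id,
                          col_or_null(hub_edges, "target_regulation"),
                          de_mirnas)
  mrna_dir_of <- setNames(de_mrnas$direction, de_mrnas$feature_id)

  rows <- lapply(seq_len(nrow(hub_edges)), function(i) {
    mi <- hub_edges$target_id[i]
    mrnas <- mirna_mrna_map[[mi]]
    if (is.null(mrnas) || length(mrnas) == 0L) return(NULL)
    tibble::tibble(
      circ_id = hub_edges$source_id[i], circ_direction = circ_dir[i],
      mirna_id = mi, mirna_direction = mirna_dir[i],
      mrna_id = mrnas,
      mrna_direction = unname(mrna_dir_of[mrnas]))
  })
  triads <- dplyr::bind_rows(rows)
  if (nrow(triads) == 0L) {
    return(tibble::tibble(
      circ_id = character(), circ_direction = character(),
      mirna_id = character(), mirna_direction = character(),
      mrna_id = character(), mrna_direction = character(),
      circ_mirna_opposite = logical(), mirna_mrna_opposite = logical()))
  }
  triads <- dplyr::distinct(triads)
  triads$circ_mirna_opposite <-
    opposite_direction(triads$circ_direction, triads$mirna_direction)
  triads$mirna_mrna_opposite <-
    opposite_direction(triads$mirna_direction, triads$mrna_direction)
  if (require_opposite_mrna) {
    triads <- triads[!is.na(triads$mirna_mrna_opposite) &
                       triads$mirna_mrna_opposite, ]
  }
  if (require_opposite_circ) {
    triads <- triads[!is.na(triads$circ_mirna_opposite) &
                       triads$circ_mirna_opposite, ]
  }
  triads
}

#' Export a ceRNA triad set as a tripartite network
#'
#' Builds the circRNA–miRNA–mRNA graph implied by a triad table (sponge
#' edges plus targeting edges, with node classes and directions) and
#' writes it via [write_network()].
#'
#' @param triads Triad tibble from [assemble_triads()].
#' @param path Output file.
#' @param dialect Network dialect (see [write_network()]).
#' @return The igraph object, invisibly.
#' @export
export_cerna <- function(triads, path,
                         dialect = c("edge_tsv", "graphml", "sif")) {
  net <- cerna_graph(triads)
  write_network(net, path, dialect)
  inform(paste0("ceRNA network: ", igraph::vcount(net), " node(s), ",
                igraph::ecount(net), " edge(s)"))
  invisible(net)
}

cerna_graph <- function(triads) {
  sponge <- dplyr::distinct(tibble::tibble(
    source_id = triads$circ_id, source_class = "circRNA",
    target_id = triads$mirna_id, target_class = "miRNA",
    sources = "cerna", score = NA_real_))
  targeting <- dplyr::distinct(tibble::tibble(
    source_id = triads$mirna_id, source_class = "miRNA",
    target_id = triads$mrna_id, target_class = "mRNA",
    sources = "cerna", score = NA_real_))
  dirs <- dplyr::distinct(tibble::tibble(
    feature_id = c(triads$circ_id, triads$mirna_id, triads$mrna_id),
    direction = c(triads$circ_direction, triads$mirna_direction,
                  triads$mrna_direction)))
  build_network(rbind(sponge, targeting), de_annotations = dirs)
}
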