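#' Write a network to disk
#'
#' Supported dialects:
#' * `"edge_tsv"` — a single TSV holding one row per node and per edge with
#'   all attributes; lossless round-trip.
#' * `"graphml"` — GraphML via igraph, suitable for Cytoscape import;
#'   node classes and directions are carried as attributes.
#' * `"sif"` — Cytoscape simple-interaction format
#'   (`node<TAB>interaction<TAB>node`); the interaction label encodes the
#'   class pair (e.g. `circRNA-miRNA`) so classes of connected nodes
#'   survive a round-trip. Isolated nodes are written as bare ids and lose
#'   class and direction, a limitation of the format.
#'
#' @param net An igraph network with `rna_class`/`direction` vertex
#'   attributes.
#' @param path Output file.
#' @param dialect One of `"edge_tsv"`, `"graphml"`, `"sif"`.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path, dialect = c("edge_tsv", "graphml", "sif")) {
  if (length(dialect) == 1L && !dialect %in% c("edge_tsv", "graphml", "sif")) {
    stop_usage(paste0("unknown network dialect '", dialect, "'"))
  }
  dialect <- match.arg(dialect)
  nodes <- network_nodes(net)
  edges <- network_edges(net)
  if (dialect == "edge_tsv") {
    node_rows <- tibble::tibble(
      record = "node", source_id = nodes$name, source_class = nodes$rna_class,
      source_direction = nodes$direction, target_id = NA_character_,
      target_class = NA_character_, target_direction = NA_character_,
      sources = NA_character_, score = NA_real_)
    dirs <- setNames(nodes$direction, nodes$name)
    edge_rows <- tibble::tibble(
      record = "edge", source_id = edges$source_id,
      source_class = edges$source_class,
      source_direction = unname(dirs[edges$source_id]),
      target_id = edges$target_id, target_class = edges$target_class,
      target_direction = unname(dirs[edges$target_id]),
      sources = edges$sources, score = edges$score)
    readr::write_tsv(rbind(node_rows, edge_rows), path, progress = FALSE)
  } else if (dialect == "graphml") {
    g <- net
    # igraph's GraphML writer has no notion of NA strings; encode them.
    dir_attr <- igraph::vertex_attr(g, "direction")
    if (!is.null(dir_attr)) {
      dir_attr[is.na(dir_attr)] <- "none"
      g <- igraph::set_vertex_attr(g, "direction", value = dir_attr)
    }
    src_attr <- igraph::edge_attr(g, "sources")
    if (!is.null(src_attr)) {
      src_attr[is.na(src_attr)] <- "none"
      g <- igraph::set_edge_attr(g, "sources", value = src_attr)
    }
    igraph::write_graph(g, path, format = "graphml")
  } else {
    lines <- character()
    if (nrow(edges) > 0L) {
      lines <- paste(edges$source_id,
                     paste0(edges$source_class, "-", edges$target_class),
                     edges$target_id, sep = "\t")
    }
    isolated <- setdiff(nodes$name, c(edges$source_id, edges$target_id))
    writeLines(c(lines, isolated), path)
  }
  invisible(path)
}

#' Read a network written by [write_network()]
#'
#' @param path Input file.
#' @param dialect Dialect the file was written in.
#' @return An igraph network.
#' @export
read_network <- function(path, dialect = c("edge_tsv", "graphml", "sif")) {
  if (length(dialect) == 1L && !dialect %in% c("edge_tsv", "graphml", "sif")) {
    stop_usage(paste0("unknown network dialect '", dialect, "'"))
  }
  dialect <- match.arg(dialect)
  if (dialect == "edge_tsv") {
    tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                           col_types = readr::cols(
                             score = readr::col_double(),
                             .default = readr::col_character()))
    nodes <- tab[tab$record == "node",
                 c("source_id", "source_class", "source_direction")]
    names(nodes) <- c("name", "rna_class", "direction")
    er <- tab[tab$record == "edge", ]
    edf <- data.frame(from = er$source_id, to = er$target_id,
                      sources = er$sources, score = er$score,
                      stringsAsFactors = FALSE)
    igraph::graph_from_data_frame(edf, directed = FALSE,
                                  vertices = as.data.frame(nodes))
  } else if (dialect == "graphml") {
    g <- igraph::read_graph(path, format = "graphml")
    g <- igraph::as_undirected(g, mode = "each")
    dir_attr <- igraph::vertex_attr(g, "direction")
    if (!is.null(dir_attr)) {
      dir_attr[dir_attr == "none"] <- NA_character_
      g <- igraph::set_vertex_attr(g, "direction", value = dir_attr)
    }
    src_attr <- igraph::edge_attr(g, "sources")
    if (!is.null(src_attr)) {
      src_attr[src_attr == "none"] <- NA_character_
      g <- igraph::set_edge_attr(g, "sources", value = src_attr)
    }
    num <- igraph::edge_attr(g, "score")
    if (!is.null(num)) {
      num[is.nan(num)] <- NA_real_
      g <- igraph::set_edge_attr(g, "score", value = num)
    }
    g
  } else {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(lines)]
    parts <- strsplit(lines, "\t", fixed = TRUE)
    is_edge <- vapply(parts, length, integer(1)) >= 3L
    nodes <- tibble::tibble(name = character(), rna_class = character())
    edf <- NULL
    if (any(is_edge)) {
      ep <- parts[is_edge]
      cls <- strsplit(vapply(ep, `[[`, character(1), 2L), "-", fixed = TRUE)
      edf <- data.frame(
        from = vapply(ep, `[[`, character(1), 1L),
        to = vapply(ep, `[[`, character(1), 3L),
        stringsAsFactors = FALSE)
      nodes <- tibble::tibble(
        name = c(edf$from, edf$to),
        rna_class = c(vapply(cls, `[[`, character(1), 1L),
                      vapply(cls, `[[`, character(1), 2L))) |>
        dplyr::distinct()
    }
    iso <- vapply(parts[!is_edge], `[[`, character(1), 1L)
    if (length(iso) > 0L) {
      nodes <- rbind(nodes, tibble::tibble(name = iso, rna_class = NA))
    }
    nodes$direction <- NA_character_
    if (is.null(edf)) edf <- data.frame(from = character(), to = character())
    igraph::graph_from_data_frame(edf, directed = FALSE,
                                  vertices = as.data.frame(nodes))
  }
}
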