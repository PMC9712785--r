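#' Run the full ceRNA network pipeline
#'
#' Orchestrates the analysis end to end from a configuration (a YAML file
#' or an equivalent nested list): simulate or ingest differential
#' expression tables, screen them, predict or ingest interaction edges,
#' build the circRNA–miRNA sponge network restricted to DE miRNAs,
#' compute centralities, select key miRNAs and hub circRNAs, assemble
#' direction-consistent circRNA–miRNA–mRNA triads, and optionally run
#' over-representation analysis and qPCR quantification. Every
#' intermediate table is written under the output directory together
#' with a run manifest (config hash, seed, package version) and a
#' summary of node, edge and triad counts. A fixed seed and config give
#' byte-identical outputs.
#'
#' Recognised configuration blocks (all optional unless noted):
#' \describe{
#'   \item{`seed`}{Integer seed for simulation mode.}
#'   \item{`out_dir`}{Output directory (may instead be given as the
#'     function argument, which wins).}
#'   \item{`simulate`}{[sim_config()] arguments; presence switches the
#'     pipeline to simulation mode.}
#'   \item{`inputs`}{Paths: `de_circrna`, `de_mirna`, `de_mrna`,
#'     `sponge_edges`, `target_edges`, `mirna_fasta`, `circ_fasta`,
#'     `mrna_fasta`, `ct_table`, `gmt` (list of `path`/`namespace`).}
#'   \item{`screening`}{`min_abs_log2fc`, `max_p`, `adjust`.}
#'   \item{`prediction`}{`min_score`, `min_sites`, `sponge_policy`,
#'     `target_policy`.}
#'   \item{`network`}{`key_mirna_multiplier`, `hub_k`, `exclude`.}
#'   \item{`cerna`}{`require_opposite_mrna`, `require_opposite_circ`.}
#'   \item{`enrichment`}{`top`.}
#' }
#'
#' @param config Path to a YAML configuration file, or a list.
#' @param out_dir Output directory; overrides `config$out_dir`.
#' @return Invisibly, a list with the pipeline objects (`screened`,
#'   `sponge_edges`, `network`, `key_mirnas`, `hubs`, `hub_edges`,
#'   `triads`, `enrichment`, `qpcr`), the `summary` count list and
#'   `out_dir`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop_usage("config must be a YAML path or a list")
  out_dir <- out_dir %||% config$out_dir
  if (is.null(out_dir)) stop_usage("an output directory is required")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("pipeline stage '", name, "' failed: ",
                   conditionMessage(e)),
            class = "spongenet_stage_error", parent = e)
    })
  }
  save_tsv <- function(x, file) {
    readr::write_tsv(x, file.path(out_dir, file), progress = FALSE)
  }
  summary <- list()
  res <- list(out_dir = out_dir)

  ## --- inputs: simulate or read -------------------------------------
  simulate_mode <- !is.null(config$simulate)
  inputs <- config$inputs %||% list()
  sim <- NULL
  de <- list()
  if (simulate_mode) {
    sim <- stage("simulate", {
      args <- config$simulate
      if (!is.null(config$seed)) args$seed <- config$seed
      cfg <- do.call(sim_config, args)
      s <- simulate_dataset(cfg)
      write_simulation(s, file.path(out_dir, "simulated"))
      s
    })
    de <- stage("differential_expression", {
      lapply(setNames(RNA_CLASSES, RNA_CLASSES), function(cl) {
        de_from_counts(sim$counts[[cl]], sim$group, cl)
      })
    })
  } else {
    de <- stage("read_de_tables", {
      paths <- c(circRNA = inputs$de_circrna %||% NA,
                 miRNA = inputs$de_mirna %||% NA,
                 mRNA = inputs$de_mrna %||% NA)
      out <- list()
      for (cl in RNA_CLASSES) {
        if (!is.na(paths[cl])) out[[cl]] <- read_de_table(paths[cl], cl)
      }
      out
    })
  }

  ## --- screening ----------------------------------------------------
  rule <- do.call(screening_rule, config$screening %||% list())
  screened <- stage("screen", lapply(de, screen, rule = rule))
  for (cl in names(screened)) {
    save_tsv(screened[[cl]], paste0("de_", cl, "_screened.tsv"))
    summary[[paste0("n_de_", cl)]] <- nrow(screened[[cl]])
    summary[[paste0("n_de_", cl, "_up")]] <-
      sum(screened[[cl]]$direction == "up")
    summary[[paste0("n_de_", cl, "_down")]] <-
      sum(screened[[cl]]$direction == "down")
    inform(paste0("screen[", cl, "]: ", nrow(de[[cl]]), " -> ",
                  nrow(screened[[cl]]), " feature(s)"))
  }
  res$screened <- screened

  ## --- interaction edges --------------------------------------------
  pred <- config$prediction %||% list()
  edges <- stage("edges", {
    sponge <- NULL
    target <- NULL
    if (simulate_mode) {
      seqs <- sim$sequences
      keep <- function(s, ids) s[intersect(names(s), ids)]
      sponge <- suppressWarnings(predict_interactions(
        keep(seqs$mirna_seqs, screened$miRNA$feature_id),
        keep(seqs$target_seqs, screened$circRNA$feature_id),
        target_class = "circRNA",
        policy = pred$sponge_policy %||% NULL,
        min_score = pred$min_score %||% 3,
        min_sites = pred$min_sites %||% 1))
      target <- suppressWarnings(predict_interactions(
        keep(seqs$mirna_seqs, screened$miRNA$feature_id),
        keep(seqs$target_seqs, screened$mRNA$feature_id),
        target_class = "mRNA",
        policy = pred$target_policy %||% NULL,
        min_score = pred$min_score %||% 3,
        min_sites = pred$min_sites %||% 1))
    } else {
      if (!is.null(inputs$sponge_edges)) {
        sponge <- read_edge_list(inputs$sponge_edges, "circRNA", "miRNA")
      } else if (!is.null(inputs$mirna_fasta) &&
                 !is.null(inputs$circ_fasta)) {
        sponge <- predict_interactions(
          inputs$mirna_fasta, inputs$circ_fasta, target_class = "circRNA",
          policy = pred$sponge_policy %||% NULL,
          min_score = pred$min_score %||% 3,
          min_sites = pred$min_sites %||% 1)
      }
      if (!is.null(inputs$target_edges)) {
        target <- read_edge_list(inputs$target_edges, "miRNA", "mRNA")
      } else if (!is.null(inputs$mirna_fasta) &&
                 !is.null(inputs$mrna_fasta)) {
        target <- predict_interactions(
          inputs$mirna_fasta, inputs$mrna_fasta, target_class = "mRNA",
          policy = pred$target_policy %||% NULL,
          min_score = pred$min_score %||% 3,
          min_sites = pred$min_sites %||% 1)
      }
    }
    list(sponge = sponge, target = target)
  })
  if (is.null(edges$sponge)) {
    stop_usage("no circRNA-miRNA edges available (supply sponge_edges or sequences)")
  }
  save_tsv(edges$sponge, "sponge_edges.tsv")
  if (!is.null(edges$target)) save_tsv(edges$target, "target_edges.tsv")
  summary$n_sponge_edges_predicted <- nrow(edges$sponge)
  res$sponge_edges <- edges$sponge
  res$target_edges <- edges$target

  ## --- sponge network, key miRNAs, hubs -----------------------------
  netcfg <- config$network %||% list()
  all_de <- dplyr::bind_rows(screened)
  net <- stage("network", {
    n <- build_network(edges$sponge, all_de)
    if (!is.null(screened$miRNA)) {
      n <- suppressMessages(restrict_to_de(n, screened$miRNA))
    }
    add_centralities(n)
  })
  node_tab <- tibble::as_tibble(
    igraph::as_data_frame(net, what = "vertices"))
  save_tsv(node_tab, "network_nodes.tsv")
  write_network(net, file.path(out_dir, "sponge_network.graphml"), "graphml")
  summary$n_network_nodes <- igraph::vcount(net)
  summary$n_network_edges <- igraph::ecount(net)
  summary$n_network_mirnas <- sum(igraph::V(net)$rna_class == "miRNA")
  inform(paste0("network: ", summary$n_network_nodes, " node(s), ",
                summary$n_network_edges, " edge(s) after DE restriction"))
  res$network <- net

  key <- stage("key_mirnas", suppressWarnings(
    select_key_mirnas(net, multiplier = netcfg$key_mirna_multiplier %||% 3)))
  summary$n_key_mirnas <- length(key$mirna_ids)
  res$key_mirnas <- key

  hub_k <- min(netcfg$hub_k %||% 5,
               sum(igraph::V(net)$rna_class == "circRNA"))
  hubs <- stage("hubs", suppressWarnings(
    rank_hub_circrnas(net, exclude = unlist(netcfg$exclude) %||% character(),
                      k = hub_k)))
  save_tsv(hubs, "hub_circrnas.tsv")
  summary$hub_circrnas <- hubs$circ_id
  res$hubs <- hubs

  ## --- ceRNA triads --------------------------------------------------
  cerna_cfg <- config$cerna %||% list()
  hub_edges <- stage("hub_edges", hub_mirna_edges(
    hubs$circ_id, edges$sponge,
    screened$miRNA %||% tibble::tibble(feature_id = character())))
  save_tsv(hub_edges, "hub_edges.tsv")
  summary$n_hub_edges <- nrow(hub_edges)
  summary$n_hub_circrnas <- length(unique(hub_edges$source_id))
  summary$n_hub_mirnas <- length(unique(hub_edges$target_id))
  inform(paste0("ceRNA core: ", summary$n_hub_edges, " edge(s) over ",
                summary$n_hub_circrnas, " circRNA(s) and ",
                summary$n_hub_mirnas, " miRNA(s)"))
  res$hub_edges <- hub_edges

  triads <- NULL
  if (!is.null(edges$target)) {
    triads <- stage("cerna", {
      tmap <- expand_to_mrnas(unique(hub_edges$target_id), edges$target)
      summary$n_target_mrnas_union <- length(tmap$union)
      tr <- assemble_triads(
        hub_edges, tmap,
        de_mrnas = screened$mRNA %||%
          tibble::tibble(feature_id = character(), direction = character()),
        require_opposite_mrna = cerna_cfg$require_opposite_mrna %||% TRUE,
        require_opposite_circ = cerna_cfg$require_opposite_circ %||% FALSE,
        de_circs = screened$circRNA, de_mirnas = screened$miRNA)
      save_tsv(tr, "cerna_triads.tsv")
      if (nrow(tr) > 0L) {
        suppressMessages(export_cerna(
          tr, file.path(out_dir, "cerna_network.graphml"), "graphml"))
      }
      tr
    })
    summary$n_triads <- nrow(triads)
    summary$n_triad_mrnas <- length(unique(triads$mrna_id))
  }
  res$triads <- triads

  ## --- enrichment -----------------------------------------------------
  if (!is.null(inputs$gmt)) {
    res$enrichment <- stage("enrich", {
      sets <- dplyr::bind_rows(lapply(inputs$gmt, function(g) {
        read_gmt(g$path %||% g, namespace = g$namespace %||% "pathway")
      }))
      query <- if (!is.null(triads) && nrow(triads) > 0L) {
        unique(triads$mrna_id)
      } else {
        unique(unlist(lapply(edges$target$target_id, identity)))
      }
      enr <- run_ora(query, sets, top = config$enrichment$top %||% 10)
      save_tsv(dplyr::select(enr, -"overlap_ids"), "enrichment.tsv")
      enr
    })
  }

  ## --- qPCR -----------------------------------------------------------
  ct <- NULL
  if (simulate_mode) {
    ct <- sim$ct
  } else if (!is.null(inputs$ct_table)) {
    ct <- stage("read_ct", read_ct_table(inputs$ct_table))
  }
  if (!is.null(ct)) {
    res$qpcr <- stage("qpcr", {
      q <- qpcr_summary(ct)
      save_tsv(q, "qpcr_summary.tsv")
      q
    })
  }

  ## --- manifest and summary -------------------------------------------
  manifest <- list(
    package = "spongenet",
    version = as.character(utils::packageVersion("spongenet")),
    seed = config$seed %||% config$simulate$seed %||% NA,
    config_hash = rlang::hash(config),
    simulate_mode = simulate_mode)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  res$summary <- summary
  res$manifest <- manifest
  invisible(res)
}
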