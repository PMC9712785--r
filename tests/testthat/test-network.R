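table4_network <- function() {
  edges <- read_edge_list(spongenet_example("table4_sponge_edges.tsv"))
  de <- rbind(
    read_de_table(spongenet_example("table2_circrna_de.tsv"),
                  "circRNA")[, 1:5],
    read_de_table(spongenet_example("table3_mirna_de.tsv"), "miRNA"))
  build_network(edges, de)
}

test_that("networks inherit structure and annotations from their inputs", {
  net <- table4_network()
  expect_equal(igraph::vcount(net), 9)
  expect_equal(igraph::ecount(net), 6)
  expect_equal(unname(igraph::degree(net)["circRNA00723"]), 2)
  v <- igraph::as_data_frame(net, what = "vertices")
  expect_equal(v[v$name == "circRNA00723", "direction"], "down")
  expect_equal(v[v$name == "miR-6240", "direction"], "up")

  dup <- tibble::tibble(
    source_id = "x", source_class = "circRNA",
    target_id = "y", target_class = "miRNA", sources = "t", score = NA_real_)
  dup2 <- tibble::tibble(
    source_id = "y", source_class = "miRNA",
    target_id = "x", target_class = "mRNA", sources = "t", score = NA_real_)
  expect_error(build_network(rbind(dup, dup2)),
               class = "spongenet_validation_error")
})

test_that("degree sum equals twice the edge count on random networks", {
  set.seed(20)
  for (i in 1:20) {
    edges <- random_sponge_edges(sample(2:8, 1), sample(2:8, 1))
    if (nrow(edges) == 0) next
    net <- build_network(edges)
    expect_equal(sum(igraph::degree(net)), 2 * igraph::ecount(net))
  }
})

test_that("DE restriction keeps circRNAs and matches a rebuild oracle", {
  net <- table4_network()
  all_mirnas <- igraph::V(net)$name[igraph::V(net)$rna_class == "miRNA"]
  expect_equal(igraph::vcount(suppressMessages(
    restrict_to_de(net, all_mirnas))), 9)
  none <- suppressMessages(restrict_to_de(net, character()))
  expect_equal(sum(igraph::V(none)$rna_class == "miRNA"), 0)
  expect_equal(sum(igraph::V(none)$rna_class == "circRNA"), 5)

  set.seed(30)
  for (i in 1:10) {
    edges <- random_sponge_edges(5, 8)
    if (nrow(edges) == 0) next
    g <- build_network(edges)
    keep <- sample(unique(edges$target_id),
                   sample(0:length(unique(edges$target_id)), 1))
    got <- suppressMessages(restrict_to_de(g, keep))
    # oracle: filter the edge list, rebuild, and re-add surviving circRNAs
    kept_edges <- edges[edges$target_id %in% keep, ]
    expect_setequal(
      paste(network_edges(got)$source_id, network_edges(got)$target_id),
      paste(kept_edges$source_id, kept_edges$target_id))
    expect_setequal(igraph::V(got)$name[igraph::V(got)$rna_class == "circRNA"],
                    unique(edges$source_id))
  }
})

test_that("centralities match closed forms on canonical graphs", {
  path3 <- build_network(tibble::tibble(
    source_id = c("c1", "c1"), source_class = "circRNA",
    target_id = c("m1", "m2"), target_class = "miRNA",
    sources = "t", score = NA_real_))
  path3 <- add_centralities(path3)
  v <- igraph::as_data_frame(path3, what = "vertices")
  expect_equal(v[v$name == "c1", "betweenness"], 1)
  expect_equal(v[v$name == "c1", "closeness"], 1)
  expect_equal(v[v$name == "m1", "closeness"], (2 / 2) * (2 / 3))

  # K4: no shortest path passes through an intermediate
  k4 <- igraph::make_full_graph(4)
  k4 <- igraph::set_vertex_attr(k4, "name", value = paste0("n", 1:4))
  k4 <- igraph::set_vertex_attr(k4, "rna_class", value = "circRNA")
  k4 <- add_centralities(k4)
  expect_equal(igraph::V(k4)$betweenness, rep(0, 4))
  expect_equal(igraph::V(k4)$closeness, rep(1, 4))

  # isolated nodes score zero in both measures
  iso <- igraph::make_empty_graph(3, directed = FALSE)
  iso <- igraph::set_vertex_attr(iso, "name", value = paste0("i", 1:3))
  iso <- igraph::set_vertex_attr(iso, "rna_class", value = "circRNA")
  iso <- add_centralities(iso)
  expect_equal(igraph::V(iso)$betweenness, rep(0, 3))
  expect_equal(igraph::V(iso)$closeness, rep(0, 3))
})

test_that("centralities agree with the brute-force oracle on random graphs", {
  set.seed(40)
  for (i in 1:40) {
    n <- sample(2:7, 1)
    adj <- matrix(0L, n, n)
    adj[upper.tri(adj)] <- rbinom(sum(upper.tri(adj)), 1, 0.5)
    adj <- adj + t(adj)
    g <- add_centralities(graph_from_adj(adj))
    want <- oracle_centralities(adj)
    expect_equal(unname(igraph::V(g)$degree), unname(want$degree))
    expect_equal(igraph::V(g)$betweenness, want$betweenness,
                 tolerance = 1e-12)
    expect_equal(igraph::V(g)$closeness, want$closeness, tolerance = 1e-12)
  }
})

test_that("key-miRNA selection applies the strict 3x-median degree rule", {
  star <- tibble::tibble(
    source_id = c(paste0("c", 1:10), "c1", "c2", "c3", "c4"),
    source_class = "circRNA",
    target_id = c(rep("hub", 10), "m1", "m2", "m3", "m4"),
    target_class = "miRNA", sources = "t", score = NA_real_)
  net <- build_network(star)
  sel <- select_key_mirnas(net)
  # miRNA degrees {10, 1, 1, 1, 1}: median 1, threshold 3, one survivor
  expect_equal(sel$median_degree, 1)
  expect_equal(sel$threshold, 3)
  expect_equal(sel$mirna_ids, "hub")

  # all-equal degrees select nothing (d > 3d is false)
  ring <- build_network(tibble::tibble(
    source_id = rep(c("ca", "cb"), 2), source_class = "circRNA",
    target_id = c("ma", "mb", "mb", "ma"), target_class = "miRNA",
    sources = "t", score = NA_real_))
  expect_length(select_key_mirnas(ring)$mirna_ids, 0)

  # selection shrinks (or stays) as the multiplier grows
  set.seed(50)
  for (i in 1:10) {
    edges <- random_sponge_edges(6, 9)
    if (nrow(edges) == 0) next
    g <- build_network(edges)
    sizes <- vapply(c(1, 2, 3, 5),
                    function(m) length(select_key_mirnas(g, m)$mirna_ids),
                    double(1))
    expect_true(all(diff(sizes) <= 0))
  }

  no_mirna <- igraph::make_empty_graph(1, directed = FALSE)
  no_mirna <- igraph::set_vertex_attr(no_mirna, "name", value = "c")
  no_mirna <- igraph::set_vertex_attr(no_mirna, "rna_class", value = "circRNA")
  expect_warning(out <- select_key_mirnas(no_mirna), "no miRNA")
  expect_length(out$mirna_ids, 0)
})

test_that("hub ranking follows centrality ranks with documented tie-breaks", {
  # single candidate wins regardless of k
  single <- add_centralities(build_network(tibble::tibble(
    source_id = "c1", source_class = "circRNA", target_id = "m1",
    target_class = "miRNA", sources = "t", score = NA_real_)))
  expect_equal(suppressWarnings(rank_hub_circrnas(single, k = 3))$circ_id,
               "c1")

  # a circRNA dominating both centralities ranks first
  dom <- add_centralities(build_network(tibble::tibble(
    source_id = c("big", "big", "big", "small"), source_class = "circRNA",
    target_id = c("m1", "m2", "m3", "m3"), target_class = "miRNA",
    sources = "t", score = NA_real_)))
  expect_equal(rank_hub_circrnas(dom, k = 2)$circ_id[1], "big")

  # random networks: agree with an exhaustive rank-combination oracle
  set.seed(60)
  for (i in 1:15) {
    edges <- random_sponge_edges(7, 10)
    if (nrow(edges) == 0) next
    g <- add_centralities(build_network(edges))
    v <- igraph::as_data_frame(g, what = "vertices")
    cv <- v[v$rna_class == "circRNA", ]
    score <- (rank(-cv$betweenness) + rank(-cv$closeness)) / 2
    want <- cv$name[order(score, -cv$degree, cv$name)][1:min(3, nrow(cv))]
    got <- suppressWarnings(rank_hub_circrnas(g, k = min(3, nrow(cv))))
    expect_equal(got$circ_id, want)

    # exclusion consistency: dropping a non-top-k node changes nothing
    not_top <- setdiff(cv$name, got$circ_id)
    if (length(not_top) > 0) {
      got2 <- suppressWarnings(
        rank_hub_circrnas(g, exclude = not_top[1], k = min(3, nrow(cv) - 1)))
      expect_equal(got2$circ_id, got$circ_id[seq_len(nrow(got2))])
    }
  }
})
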