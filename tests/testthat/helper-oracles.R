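# Independent reference implementations used to cross-check the package.
# These deliberately share no code with the implementations under test.

# Shortest-path distances and path counts from powers of the adjacency
# matrix: the number of walks of minimal length s->t equals the number of
# shortest paths.
oracle_paths <- function(adj) {
  n <- nrow(adj)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  sigma <- diag(1, n)
  P <- diag(1, n)
  if (n > 1) {
    for (L in seq_len(n - 1)) {
      P <- P %*% adj
      new_hit <- is.infinite(d) & P > 0
      d[new_hit] <- L
      sigma[new_hit] <- P[new_hit]
    }
  }
  list(d = d, sigma = sigma)
}

# Freeman betweenness with 2/((n-1)(n-2)) pair normalisation and
# Wasserman-Faust closeness, both straight from their definitions.
oracle_centralities <- function(adj) {
  n <- nrow(adj)
  sp <- oracle_paths(adj)
  d <- sp$d
  sigma <- sp$sigma
  btw <- numeric(n)
  if (n >= 3) {
    for (v in seq_len(n)) {
      acc <- 0
      for (s in seq_len(n - 1)) {
        for (t in seq(s + 1, n)) {
          if (s == v || t == v || is.infinite(d[s, t])) next
          if (d[s, v] + d[v, t] == d[s, t]) {
            acc <- acc + sigma[s, v] * sigma[v, t] / sigma[s, t]
          }
        }
      }
      btw[v] <- acc * 2 / ((n - 1) * (n - 2))
    }
  }
  clo <- vapply(seq_len(n), function(v) {
    dv <- d[v, -v]
    dv <- dv[is.finite(dv)]
    if (length(dv) == 0 || n == 1) return(0)
    (length(dv) / (n - 1)) * (length(dv) / sum(dv))
  }, double(1))
  list(degree = rowSums(adj), betweenness = btw, closeness = clo)
}

# igraph network for an adjacency matrix with all nodes labelled as
# miRNA/circRNA alternately (classes are irrelevant to centralities).
graph_from_adj <- function(adj) {
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  igraph::set_vertex_attr(g, "rna_class",
                          value = rep(c("circRNA", "miRNA"),
                                      length.out = nrow(adj)))
}

# Brute-force seed-site scan: linear sweep with per-position substring
# comparison and independent classification logic.
oracle_seed_scan <- function(mirna, target) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  mm <- strsplit(chartr("Uu", "Tt", toupper(mirna)), "")[[1]]
  tt <- strsplit(chartr("Uu", "Tt", toupper(target)), "")[[1]]
  core <- rev(unname(comp[mm[2:7]]))
  rows <- list()
  if (length(tt) >= 6) {
    for (s in 0:(length(tt) - 6)) {
      if (!all(tt[(s + 1):(s + 6)] == core)) next
      m8 <- s >= 1 && tt[s] == comp[[mm[8]]]
      a1 <- (s + 7) <= length(tt) && tt[s + 7] == "A"
      type <- if (m8 && a1) "8mer" else if (m8) "7mer_m8" else
        if (a1) "7mer_A1" else "6mer"
      start <- if (m8) s - 1 else s
      len <- if (type == "6mer") 6L else if (type == "8mer") 8L else 7L
      rows[[length(rows) + 1L]] <-
        data.frame(start = start, end = start + len, site_type = type,
                   stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0) {
    return(data.frame(start = integer(), end = integer(),
                      site_type = character()))
  }
  do.call(rbind, rows)
}

# Benjamini-Hochberg step-up from the definition.
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- p[o] * n / seq_len(n)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(n)
  out[o] <- q
  out
}

# Upper-tail hypergeometric probability by combinatorial enumeration.
oracle_hypergeom <- function(k, n, K, N) {
  js <- k:min(n, K)
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}

random_sequence <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# Random sponge edge tibble over nc circRNAs and nm miRNAs.
random_sponge_edges <- function(nc, nm, p = 0.3) {
  grid <- expand.grid(ci = seq_len(nc), mi = seq_len(nm))
  keep <- runif(nrow(grid)) < p
  grid <- grid[keep, , drop = FALSE]
  tibble::tibble(
    source_id = sprintf("circ%02d", grid$ci), source_class = "circRNA",
    target_id = sprintf("miR-%02d", grid$mi), target_class = "miRNA",
    sources = "test", score = NA_real_)
}
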