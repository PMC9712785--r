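test_that("the generator is deterministic for a given seed", {
  a <- simulate_dataset(sim_config(seed = 11))
  b <- simulate_dataset(sim_config(seed = 11))
  expect_identical(a$counts, b$counts)
  expect_identical(a$sequences, b$sequences)
  expect_identical(a$ct, b$ct)
  expect_identical(a$truth, b$truth)
  c <- simulate_counts(sim_config(seed = 12))
  expect_false(identical(a$counts, c$counts))
})

test_that("configuration invariants are enforced", {
  expect_error(sim_config(n_per_group = 1), class = "spongenet_domain_error")
  expect_error(sim_config(n_de = c(circRNA = 50, miRNA = 5, mRNA = 5)),
               class = "spongenet_domain_error")
  expect_error(sim_config(n_triads = 99), class = "spongenet_domain_error")
  expect_error(sim_config(dispersion = -1), class = "spongenet_domain_error")
  cfg <- sim_config()
  expect_equal(cfg$n_per_group, 3L)
  expect_equal(unname(cfg$n_features), c(40L, 60L, 150L))
  expect_equal(cfg$effect_log2fc, 2)
})

test_that("counts have the planted structure and group layout", {
  cfg <- sim_config(seed = 21)
  sim <- simulate_counts(cfg)
  expect_equal(names(sim$counts), c("circRNA", "miRNA", "mRNA"))
  expect_equal(dim(sim$counts$circRNA), c(40, 6))
  expect_equal(sim$group, rep(c("case", "control"), each = 3))
  expect_equal(as.vector(table(sim$truth$de$rna_class)[
    c("circRNA", "miRNA", "mRNA")]), c(8, 10, 16))
  expect_equal(nrow(sim$truth$triads), 4)
  # triad members are all DE and direction-consistent with the pattern
  tri <- sim$truth$triads
  expect_true(all(c(tri$circ_id, tri$mirna_id, tri$mrna_id) %in%
                    sim$truth$de$feature_id))
  expect_true(all((tri$circ_direction != tri$mirna_direction) &
                    (tri$mrna_direction != tri$mirna_direction)))

  # planted case means really shift by the effect size
  de_up <- sim$truth$de[sim$truth$de$rna_class == "mRNA" &
                          sim$truth$de$direction == "up", ]
  m <- sim$counts$mRNA[de_up$feature_id, , drop = FALSE]
  obs <- log2(rowMeans(m[, 1:3, drop = FALSE]) /
                rowMeans(m[, 4:6, drop = FALSE]))
  expect_true(all(obs > 0.5))
})

test_that("a zero effect size yields a null dataset", {
  cfg <- sim_config(seed = 22, effect_log2fc = 0, n_per_group = 10)
  sim <- simulate_counts(cfg)
  de <- de_from_counts(do.call(rbind, sim$counts), sim$group)
  # fold changes hover near zero even for 'planted' features
  expect_lt(max(abs(de$log2fc)), 1)
  expect_gt(mean(de$p_value > 0.05), 0.85)
})

test_that("zero dispersion reproduces Poisson count variance", {
  cfg <- sim_config(seed = 23, dispersion = 0, n_per_group = 100,
                    n_circ = 200, n_mirna = 2, n_mrna = 2,
                    baseline_log2_sd = 0, n_de = c(0, 0, 0), n_triads = 0)
  sim <- simulate_counts(cfg)
  m <- sim$counts$circRNA
  # for Poisson, var == mean; the variance/mean ratio concentrates at 1
  ratio <- apply(m, 1, var) / rowMeans(m)
  expect_lt(abs(mean(ratio) - 1), 0.05)
  # with dispersion 0.5 the ratio is far larger (mean 500 -> ~251)
  cfg2 <- sim_config(seed = 23, dispersion = 0.5, n_per_group = 100,
                     n_circ = 200, n_mirna = 2, n_mrna = 2,
                     baseline_log2_sd = 0, n_de = c(0, 0, 0), n_triads = 0)
  m2 <- simulate_counts(cfg2)$counts$circRNA
  ratio2 <- apply(m2, 1, var) / rowMeans(m2)
  expect_gt(mean(ratio2), 50)
})

test_that("planted seed sites are present verbatim in the targets", {
  cfg <- sim_config(seed = 24)
  sim <- simulate_counts(cfg)
  seqs <- simulate_sequences(cfg, sim$truth)
  ps <- seqs$planted_sites
  expect_equal(nrow(ps), 2 * cfg$n_triads)
  for (i in seq_len(nrow(ps))) {
    m <- chartr("U", "T", seqs$mirna_seqs[[ps$mirna_id[i]]])
    expected <- paste(rev(chartr("ACGT", "TGCA",
                                 strsplit(substr(m, 2, 8), "")[[1]])),
                      collapse = "")
    got <- substr(seqs$target_seqs[[ps$target_id[i]]],
                  ps$start[i] + 1, ps$start[i] + 7)
    expect_equal(got, expected)
  }
  # after scrubbing, the only core matches left belong to planted pairs
  expect_equal(nrow(seqs$collisions), 0)
  hits <- scan_seed_matches(seqs$mirna_seqs, seqs$target_seqs)
  expect_true(all(paste(hits$mirna_id, hits$target_id) %in%
                    paste(ps$mirna_id, ps$target_id)))
})

test_that("zero triads produce no planted sites", {
  cfg <- sim_config(seed = 25, n_triads = 0)
  sim <- simulate_counts(cfg)
  expect_equal(nrow(sim$truth$triads), 0)
  seqs <- simulate_sequences(cfg, sim$truth)
  expect_equal(nrow(seqs$planted_sites), 0)
})

test_that("chance seed-core matches occur at the binomial rate", {
  # without scrubbing, each of the L-5 windows of a random target matches
  # a fixed 6mer with probability 4^-6
  cfg <- sim_config(seed = 26, n_triads = 0, n_circ = 0, n_mrna = 350,
                    n_mirna = 4, n_de = c(0, 0, 0), mrna_len = 500)
  sim <- simulate_counts(cfg)
  seqs <- simulate_sequences(cfg, sim$truth, avoid_collisions = FALSE)
  hits <- scan_seed_matches(seqs$mirna_seqs, seqs$target_seqs)
  n_windows <- 4 * 350 * (500 - 5)
  expected <- n_windows * 4^-6
  sd3 <- 3 * sqrt(n_windows * 4^-6 * (1 - 4^-6))
  expect_lt(abs(nrow(hits) - expected), sd3)
})

test_that("noise-free CT tables recover planted folds exactly", {
  cfg <- sim_config(seed = 27)
  sim <- simulate_counts(cfg)
  ct <- simulate_ct_table(cfg, sim$truth, noise_sd = 0)
  tri <- sim$truth$triads
  for (i in seq_len(nrow(tri))) {
    for (col in c("circ_id", "mirna_id", "mrna_id")) {
      gene <- tri[[col]][i]
      lfc <- sim$truth$de$log2fc[sim$truth$de$feature_id == gene]
      q <- delta_delta_ct(ct, gene)
      folds <- q$per_sample$fold[q$per_sample$group == "case"]
      expect_equal(folds, rep(2^lfc, 3), tolerance = 1e-12)
    }
  }
  # miRNAs are normalised to U6, the rest to GAPDH
  expect_equal(unique(ct$reference_gene[ct$gene_id %in% tri$mirna_id]), "U6")
  expect_equal(unique(ct$reference_gene[ct$gene_id %in% tri$circ_id]),
               "GAPDH")
})

test_that("noisy CT tables recover planted folds approximately", {
  cfg <- sim_config(seed = 28, n_per_group = 30)
  sim <- simulate_counts(cfg)
  ct <- simulate_ct_table(cfg, sim$truth)
  gene <- sim$truth$triads$mrna_id[1]
  lfc <- sim$truth$de$log2fc[sim$truth$de$feature_id == gene]
  q <- delta_delta_ct(ct, gene)
  obs <- mean(q$per_sample$ddct[q$per_sample$group == "case"])
  expect_equal(-obs, lfc, tolerance = 0.25)
})

test_that("written simulations round-trip through the readers", {
  dir <- withr::local_tempdir()
  cfg <- sim_config(seed = 29, n_circ = 8, n_mirna = 8, n_mrna = 12,
                    n_de = c(2, 2, 2), n_triads = 2)
  sim <- simulate_dataset(cfg)
  write_simulation(sim, dir)
  counts <- readr::read_tsv(file.path(dir, "counts_circRNA.tsv"),
                            show_col_types = FALSE)
  expect_equal(counts$feature_id, rownames(sim$counts$circRNA))
  expect_equal(as.matrix(counts[, -1]), sim$counts$circRNA,
               ignore_attr = TRUE)
  fasta <- Biostrings::readDNAStringSet(file.path(dir, "targets.fasta"))
  expect_equal(as.character(fasta), sim$sequences$target_seqs)
  ct <- read_ct_table(file.path(dir, "ct_table.tsv"))
  expect_equal(nrow(ct), nrow(sim$ct))
  truth <- jsonlite::read_json(file.path(dir, "ground_truth.json"),
                               simplifyVector = TRUE)
  expect_setequal(truth$triads$circ_id, sim$truth$triads$circ_id)
})
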