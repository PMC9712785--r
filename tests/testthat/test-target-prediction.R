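test_that("constructed sites are found and classified", {
  # GCATTCGA = rev-comp of positions 1-8 of the miRNA with a target 'A'
  # opposite position 1 -> a single 8mer
  sites <- find_seed_sites("UCGAAUGCAAAA", "CCCGCATTCGAACC")
  expect_equal(nrow(sites), 1)
  expect_equal(sites$site_type, "8mer")
  expect_equal(sites$end - sites$start, 8)

  expect_equal(nrow(find_seed_sites("UCGAAUGCAAAA", "TTTTTTTTTTTT")), 0)

  # U/T equivalence in both inputs
  a <- find_seed_sites("UCGAAUGCAAAA", "CCCGCAUUCGAACC")
  b <- find_seed_sites("TCGAATGCAAAA", "CCCGCATTCGAACC")
  expect_identical(a, b)

  expect_error(find_seed_sites("UCGAAUGCNAAA", "ACGT"),
               class = "spongenet_validation_error")
  expect_error(find_seed_sites("UCGAAUG", "ACGT"),
               class = "spongenet_validation_error")
})

test_that("seed-site finder agrees with a brute-force scan", {
  set.seed(101)
  for (i in 1:200) {
    mirna <- random_sequence(22, c("A", "C", "G", "U"))
    target <- random_sequence(80)
    got <- find_seed_sites(mirna, target)
    want <- oracle_seed_scan(mirna, target)
    expect_equal(got$start, want$start)
    expect_equal(got$end, want$end)
    expect_equal(got$site_type, want$site_type)
  }
})

test_that("existing sites are stable under appending downstream sequence", {
  set.seed(5)
  for (i in 1:25) {
    mirna <- random_sequence(22, c("A", "C", "G", "U"))
    target <- random_sequence(60)
    before <- find_seed_sites(mirna, target)
    after <- find_seed_sites(mirna, paste0(target, random_sequence(40)))
    # every original site persists at its coordinate with the same class,
    # except possibly the one abutting the old 3' end, whose A1 status the
    # new sequence can legitimately change
    interior <- before[before$end < nchar(target) - 1, ]
    expect_true(all(paste(interior$start, interior$site_type) %in%
                      paste(after$start, after$site_type)))
    expect_gte(nrow(after), nrow(interior))
  }
})

test_that("duplex score equals seed weight plus hand-counted 3' pairs", {
  mirna <- "UCGAAUGCAAAAGCUAUUUUUU" # positions 13-16 = GCUA
  comp <- c(A = "T", C = "G", G = "C", U = "A", T = "A")
  # enumerate all 256 four-base flanks upstream of a planted core
  core <- "CATTCG" # rev-comp of positions 2-7; no m8, no A1 by design
  flanks <- expand.grid(b1 = c("A", "C", "G", "T"), b2 = c("A", "C", "G", "T"),
                        b3 = c("A", "C", "G", "T"), b4 = c("A", "C", "G", "T"),
                        stringsAsFactors = FALSE)
  m13_16 <- strsplit("GCUA", "")[[1]]
  for (i in seq_len(nrow(flanks))) {
    fl <- unlist(flanks[i, ])
    # target runs 5'->3': flank bases pair miRNA 16..13 going left to right;
    # miRNA position k sits opposite target index core_start + 7 - k
    target <- paste0("TT", paste(fl, collapse = ""), "CCCCC", core, "G")
    sites <- find_seed_sites(mirna, target)
    site <- sites[sites$site_type == "6mer", ][1, ]
    core_start <- site$start
    expected_bonus <- 0
    tt <- strsplit(target, "")[[1]]
    for (k in 13:16) {
      j <- core_start + 7 - k
      if (j >= 0 && tt[j + 1] == comp[[m13_16[k - 12]]]) {
        expected_bonus <- expected_bonus + 1
      }
    }
    expect_equal(site$score, 1 + expected_bonus)
    expect_equal(score_duplex(site, mirna, target), site$score)
  }
})

test_that("circular targets expose junction-spanning sites", {
  mirna <- "UCGAAUGCAAAA"
  core <- "CATTCG"
  # place the core across the end/start junction: last 3 nt + first 3 nt
  target <- paste0("TCG", "CCCCCCCCCCCCCCCCCCCC", "CAT")
  expect_equal(nrow(find_seed_sites(mirna, target, circular = FALSE)), 0)
  circ <- find_seed_sites(mirna, target, circular = TRUE)
  expect_equal(nrow(circ), 1)
  expect_equal(circ$start, nchar(target) - 3)
})

test_that("two-source consensus respects the combination policy", {
  mirna <- c(m1 = "UCGAAUGCAAAAGCUAUUUUUU")
  # t1: two sites incl. an 8mer (passes both sources)
  # t2: one lone 6mer, score below the default threshold (count source only)
  t1 <- "CCCGCATTCGAACCCCCCGCATTCGAACC"
  lone <- "ACTTCCCCCCATTCGTT"
  stopifnot(nrow(find_seed_sites(mirna[[1]], lone)) == 1,
            max(find_seed_sites(mirna[[1]], lone)$score) < 3)
  targets <- c(t1 = t1, t2 = lone)

  uni <- predict_interactions(mirna, targets, "mRNA", policy = "union",
                              circular = FALSE)
  int <- predict_interactions(mirna, targets, "mRNA",
                              policy = "intersection", circular = FALSE)
  expect_setequal(uni$target_id, c("t1", "t2"))
  expect_equal(int$target_id, "t1")
  expect_equal(int$sources, "seedmatch_sites,seedmatch_score")
  # intersection output is a subset of union output
  expect_true(all(int$target_id %in% uni$target_id))
  # orientation: sponge edges run circRNA -> miRNA
  sponge <- predict_interactions(mirna, targets, "circRNA",
                                 policy = "union", circular = FALSE)
  expect_true(all(sponge$source_class == "circRNA"))
  expect_true(all(sponge$target_id == "m1"))

  expect_warning(
    out <- predict_interactions(character(), targets, "mRNA"),
    "empty")
  expect_equal(nrow(out), 0)
})

test_that("predictions recover planted pairs exactly when collision-free", {
  cfg <- sim_config(seed = 3, n_circ = 10, n_mirna = 12, n_mrna = 20,
                    n_de = c(circRNA = 4, miRNA = 4, mRNA = 4), n_triads = 3)
  sim <- simulate_counts(cfg)
  seqs <- simulate_sequences(cfg, sim$truth)
  expect_equal(nrow(seqs$collisions), 0)
  planted_sponge <- unique(paste(sim$truth$triads$circ_id,
                                 sim$truth$triads$mirna_id))
  planted_target <- unique(paste(sim$truth$triads$mirna_id,
                                 sim$truth$triads$mrna_id))
  circ_seqs <- seqs$target_seqs[grep("^circ", names(seqs$target_seqs))]
  mrna_seqs <- seqs$target_seqs[grep("^gene", names(seqs$target_seqs))]
  for (policy in c("union", "intersection")) {
    sp <- predict_interactions(seqs$mirna_seqs, circ_seqs, "circRNA",
                               policy = policy)
    tg <- predict_interactions(seqs$mirna_seqs, mrna_seqs, "mRNA",
                               policy = policy)
    expect_setequal(paste(sp$source_id, sp$target_id), planted_sponge)
    expect_setequal(paste(tg$source_id, tg$target_id), planted_target)
  }
})
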