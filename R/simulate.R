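#' Configuration for the synthetic ceRNA study generator
#'
#' Defines the study conditions the generator emulates: a two-group
#' (case vs control) design with `n_per_group` animals per group
#' (default 3, the sequenced cohort size), negative-binomial counts for
#' three RNA classes with log-normally jittered baseline means, planted
#' differentially expressed features at a fixed effect size, planted
#' direction-consistent sponge triads, and sequences carrying planted
#' seed-match sites.
#'
#' @param seed Integer seed; one global seed drives a single generator
#'   stream through all stages (counts, then sequences, then CT values).
#' @param n_per_group Samples per group (default 3).
#' @param n_circ,n_mirna,n_mrna Features per RNA class.
#' @param baseline_mean Baseline negative-binomial mean (default 500).
#' @param baseline_log2_sd Log-normal jitter of per-feature baselines on
#'   the log2 scale (default 1).
#' @param dispersion NB dispersion `phi` with `var = mu + phi mu^2`
#'   (default 0.1); 0 gives the Poisson limit.
#' @param n_de Planted DE features per class, either named by RNA class
#'   or unnamed in circRNA, miRNA, mRNA order.
#' @param effect_log2fc Planted absolute log2 fold change (default 2).
#' @param n_triads Planted sponge triads; at most `min(n_de)`. Triad
#'   directions are drawn as (circRNA down, miRNA up, mRNA down) or its
#'   mirror image with equal probability.
#' @param seed_len Planted seed-site length (7: reverse complement of
#'   miRNA positions 2–8).
#' @param mirna_len,circ_len,mrna_len Sequence lengths (nt).
#' @param ct_reference_mean,ct_reference_sd Reference-gene CT
#'   distribution (Normal(20, 0.2) by default).
#' @param ct_baseline_dct Control-group dCT offset of target genes.
#' @param ct_noise_sd Gaussian CT noise (default 0.2).
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(seed = 1L, n_per_group = 3L,
                       n_circ = 40L, n_mirna = 60L, n_mrna = 150L,
                       baseline_mean = 500, baseline_log2_sd = 1,
                       dispersion = 0.1,
                       n_de = c(circRNA = 8L, miRNA = 10L, mRNA = 16L),
                       effect_log2fc = 2, n_triads = 4L, seed_len = 7L,
                       mirna_len = 22L, circ_len = 400L, mrna_len = 500L,
                       ct_reference_mean = 20, ct_reference_sd = 0.2,
                       ct_baseline_dct = 5, ct_noise_sd = 0.2) {
  cfg <- list(seed = as.integer(seed), n_per_group = as.integer(n_per_group),
              n_features = c(circRNA = as.integer(n_circ),
                             miRNA = as.integer(n_mirna),
                             mRNA = as.integer(n_mrna)),
              baseline_mean = baseline_mean,
              baseline_log2_sd = baseline_log2_sd,
              dispersion = dispersion,
              n_de = normalize_n_de(n_de),
              effect_log2fc = effect_log2fc,
              n_triads = as.integer(n_triads),
              seed_len = as.integer(seed_len),
              seq_len = c(miRNA = as.integer(mirna_len),
                          circRNA = as.integer(circ_len),
                          mRNA = as.integer(mrna_len)),
              ct_reference_mean = ct_reference_mean,
              ct_reference_sd = ct_reference_sd,
              ct_baseline_dct = ct_baseline_dct,
              ct_noise_sd = ct_noise_sd)
  if (cfg$n_per_group < 2L) stop_domain("n_per_group must be >= 2")
  if (any(cfg$n_features < 0L) || any(cfg$n_de < 0L)) {
    stop_domain("feature and DE counts must be non-negative")
  }
  if (any(cfg$n_de > cfg$n_features)) {
    stop_domain("n_de cannot exceed the number of features")
  }
  if (cfg$n_triads > min(cfg$n_de)) {
    stop_domain("n_triads must be <= min(n_de)")
  }
  if (cfg$baseline_mean <= 0 || cfg$dispersion < 0) {
    stop_domain("baseline_mean must be positive and dispersion >= 0")
  }
  if (cfg$effect_log2fc < 0) stop_domain("effect_log2fc must be >= 0")
  if (any(cfg$seq_len[c("circRNA", "mRNA")] < cfg$seed_len)) {
    stop_domain("target length below planted-site length")
  }
  structure(cfg, class = "sim_config")
}

# Accepts n_de either named by RNA class or unnamed in circRNA, miRNA,
# mRNA order.
normalize_n_de <- function(n_de) {
  if (length(n_de) != 3L) stop_domain("n_de must have one entry per class")
  if (is.null(names(n_de))) names(n_de) <- RNA_CLASSES
  if (!setequal(names(n_de), RNA_CLASSES)) {
    stop_domain("n_de names must be the three RNA classes")
  }
  setNames(as.integer(n_de[RNA_CLASSES]), RNA_CLASSES)
}

sim_ids <- function(cfg) {
  list(circRNA = sprintf("circSIM%04d", seq_len(cfg$n_features["circRNA"])),
       miRNA = sprintf("miR-sim-%03d", seq_len(cfg$n_features["miRNA"])),
       mRNA = sprintf("geneSIM%04d", seq_len(cfg$n_features["mRNA"])))
}

#' Simulate two-group counts with planted DE features and sponge triads
#'
#' Seeds the generator stream with `cfg$seed` and draws, in documented
#' order: (1) planted triad members and their mirrored direction
#' patterns, (2) remaining DE features and their signs, (3) per-feature
#' log-normal baselines, (4) negative-binomial counts class by class
#' (circRNA, miRNA, mRNA; case columns before control columns). Planted
#' case-group means are scaled by `2^(+-effect_log2fc)`. Identical seeds
#' give identical output.
#'
#' @param cfg A [sim_config()].
#' @return A list with `counts` (named list of integer matrices,
#'   features x samples), `group` (column group labels) and `truth`
#'   (planted DE table and triads).
#' @export
simulate_counts <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  ids <- sim_ids(cfg)

  # (1) planted DE features and triads
  de_idx <- lapply(RNA_CLASSES, function(cl) {
    sort(sample.int(cfg$n_features[cl], cfg$n_de[cl]))
  })
  names(de_idx) <- RNA_CLASSES
  triad_pos <- lapply(RNA_CLASSES, function(cl) {
    if (cfg$n_triads > 0L) sample(de_idx[[cl]], cfg$n_triads) else integer()
  })
  names(triad_pos) <- RNA_CLASSES
  mirrored <- if (cfg$n_triads > 0L) {
    sample(c(TRUE, FALSE), cfg$n_triads, replace = TRUE)
  } else {
    logical()
  }
  # base pattern: circRNA down, miRNA up, mRNA down; mirrored flips all
  sign_of <- function(base_sign, m) ifelse(m, -base_sign, base_sign)
  de_sign <- lapply(RNA_CLASSES, function(cl) {
    s <- setNames(sample(c(-1, 1), cfg$n_de[cl], replace = TRUE),
                  de_idx[[cl]])
    base <- if (cl == "miRNA") 1 else -1
    s[as.character(triad_pos[[cl]])] <- sign_of(base, mirrored)
    s
  })
  names(de_sign) <- RNA_CLASSES

  # (2) baselines, (3) counts
  n_s <- cfg$n_per_group
  counts <- list()
  for (cl in RNA_CLASSES) {
    nf <- cfg$n_features[cl]
    base <- cfg$baseline_mean * 2^rnorm(nf, 0, cfg$baseline_log2_sd)
    lfc <- rep(0, nf)
    lfc[de_idx[[cl]]] <- unname(de_sign[[cl]]) * cfg$effect_log2fc
    mu_case <- base * 2^lfc
    draw <- function(mu) {
      if (cfg$dispersion == 0) {
        matrix(stats::rpois(nf * n_s, mu), nrow = nf, ncol = n_s)
      } else {
        matrix(rnbinom(nf * n_s, mu = mu, size = 1 / cfg$dispersion),
               nrow = nf, ncol = n_s)
      }
    }
    m <- cbind(draw(mu_case), draw(base))
    dimnames(m) <- list(ids[[cl]],
                        c(paste0("case_", seq_len(n_s)),
                          paste0("control_", seq_len(n_s))))
    counts[[cl]] <- m
  }

  de_truth <- dplyr::bind_rows(lapply(RNA_CLASSES, function(cl) {
    idx <- de_idx[[cl]]
    lfc <- unname(de_sign[[cl]][as.character(idx)]) * cfg$effect_log2fc
    tibble::tibble(feature_id = ids[[cl]][idx], rna_class = cl,
                   log2fc = lfc, direction = up_down(lfc))
  }))
  dir_of <- function(cl) {
    up_down(unname(de_sign[[cl]][as.character(triad_pos[[cl]])]))
  }
  triads <- tibble::tibble(
    circ_id = ids$circRNA[triad_pos$circRNA],
    mirna_id = ids$miRNA[triad_pos$miRNA],
    mrna_id = ids$mRNA[triad_pos$mRNA],
    circ_direction = dir_of("circRNA"),
    mirna_direction = dir_of("miRNA"),
    mrna_direction = dir_of("mRNA"))

  list(counts = counts,
       group = rep(c("case", "control"), each = n_s),
       truth = list(de = de_truth, triads = triads))
}

# All core (6mer, miRNA positions 2-7) matches of each miRNA in each
# target; used both for collision detection and Monte-Carlo checks.
scan_seed_matches <- function(mirna_seqs, target_seqs, seed_start = 2L,
                              seed_len = 6L) {
  tset <- Biostrings::DNAStringSet(
    chartr("Uu", "Tt", unlist(target_seqs)))
  rows <- list()
  for (mi in names(mirna_seqs)) {
    m <- chartr("Uu", "Tt", toupper(mirna_seqs[[mi]]))
    pat <- revcomp(substr(m, seed_start, seed_start + seed_len - 1L))
    hits <- Biostrings::vmatchPattern(pat, tset)
    n_hits <- S4Vectors::elementNROWS(hits)
    if (sum(n_hits) == 0L) next
    for (j in which(n_hits > 0L)) {
      rows[[length(rows) + 1L]] <- tibble::tibble(
        mirna_id = mi, target_id = names(target_seqs)[j],
        start = Biostrings::start(hits[[j]]) - 1L)
    }
  }
  if (length(rows) == 0L) {
    return(tibble::tibble(mirna_id = character(), target_id = character(),
                          start = integer()))
  }
  dplyr::bind_rows(rows)
}

random_seq <- function(n, alphabet) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

#' Simulate miRNA and target sequences with planted seed sites
#'
#' Draws uniform-random background sequences (miRNAs over ACGU with
#' pairwise-distinct seed cores, circRNA and mRNA targets over ACGT) and, for every planted triad, inserts one
#' exact reverse complement of the miRNA seed (positions 2 to
#' `1 + seed_len`) into the triad's circRNA and mRNA sequences at a
#' recorded coordinate. An exhaustive seed-core scan then detects chance
#' matches for non-planted (miRNA, target) pairs; with
#' `avoid_collisions = TRUE` (the default) those windows are resampled
#' until the background is collision-free, so planted interactions are
#' the only ones present. Consumes the generator stream seeded by
#' [simulate_counts()]; call the two in order (or use
#' [simulate_dataset()]).
#'
#' @param cfg A [sim_config()].
#' @param truth The `truth` element returned by [simulate_counts()].
#' @param avoid_collisions Scrub chance seed matches of non-planted
#'   pairs (default `TRUE`).
#' @param max_iter Scrub iterations before giving up with a warning.
#' @return A list with `mirna_seqs` (RNA alphabet), `target_seqs` (DNA
#'   alphabet; circRNAs then mRNAs), `planted_sites` (0-based starts)
#'   and `collisions` (chance matches remaining).
#' @export
simulate_sequences <- function(cfg, truth, avoid_collisions = TRUE,
                               max_iter = 50L) {
  stopifnot(inherits(cfg, "sim_config"))
  ids <- sim_ids(cfg)
  # miRNA seed windows (positions 2-7 and 3-8) must be globally unique:
  # if one miRNA's core matched inside another's planted site (which is
  # the reverse complement of positions 2-8), that chance match could
  # never be scrubbed without destroying the planted site
  mirna_seqs <- character(0)
  windows_seen <- character(0)
  for (id in ids$miRNA) {
    repeat {
      s <- random_seq(cfg$seq_len["miRNA"], c("A", "C", "G", "U"))
      w <- c(substr(s, 2L, 7L), substr(s, 3L, 8L))
      if (!any(w %in% windows_seen) && w[1] != w[2]) break
    }
    windows_seen <- c(windows_seen, w)
    mirna_seqs[[id]] <- s
  }
  target_seqs <- c(
    setNames(vapply(ids$circRNA, function(i) {
      random_seq(cfg$seq_len["circRNA"], c("A", "C", "G", "T"))
    }, character(1)), ids$circRNA),
    setNames(vapply(ids$mRNA, function(i) {
      random_seq(cfg$seq_len["mRNA"], c("A", "C", "G", "T"))
    }, character(1)), ids$mRNA))

  site_of <- function(mirna_id) {
    m <- chartr("U", "T", mirna_seqs[[mirna_id]])
    revcomp(substr(m, 2L, 1L + cfg$seed_len))
  }
  planted <- list()
  plant <- function(mirna_id, target_id) {
    site <- site_of(mirna_id)
    L <- nchar(target_seqs[[target_id]])
    pos0 <- sample.int(L - nchar(site) + 1L, 1L) - 1L
    tibble::tibble(mirna_id = mirna_id, target_id = target_id,
                   start = pos0)
  }
  tri <- truth$triads
  for (i in seq_len(nrow(tri))) {
    planted[[length(planted) + 1L]] <- plant(tri$mirna_id[i], tri$circ_id[i])
    planted[[length(planted) + 1L]] <- plant(tri$mirna_id[i], tri$mrna_id[i])
  }
  planted_sites <- if (length(planted) > 0L) dplyr::bind_rows(planted) else
    tibble::tibble(mirna_id = character(), target_id = character(),
                   start = integer())
  replant <- function(seqs) {
    for (i in seq_len(nrow(planted_sites))) {
      tg <- planted_sites$target_id[i]
      s <- planted_sites$start[i]
      site <- site_of(planted_sites$mirna_id[i])
      substr(seqs[[tg]], s + 1L, s + nchar(site)) <- site
    }
    seqs
  }
  target_seqs <- replant(target_seqs)

  planted_pairs <- paste(planted_sites$mirna_id, planted_sites$target_id)
  find_collisions <- function(seqs) {
    hits <- scan_seed_matches(mirna_seqs, seqs)
    hits[!(paste(hits$mirna_id, hits$target_id) %in% planted_pairs), ]
  }
  collisions <- find_collisions(target_seqs)
  if (avoid_collisions) {
    iter <- 0L
    while (nrow(collisions) > 0L && iter < max_iter) {
      for (i in seq_len(nrow(collisions))) {
        tg <- collisions$target_id[i]
        s <- collisions$start[i]
        substr(target_seqs[[tg]], s + 1L, s + 6L) <-
          random_seq(6L, c("A", "C", "G", "T"))
      }
      target_seqs <- replant(target_seqs)
      collisions <- find_collisions(target_seqs)
      iter <- iter + 1L
    }
    if (nrow(collisions) > 0L) {
      warn(paste0(nrow(collisions),
                  " chance seed match(es) could not be scrubbed"))
    }
  }
  list(mirna_seqs = mirna_seqs, target_seqs = target_seqs,
       planted_sites = planted_sites, collisions = collisions)
}

#' Simulate a qPCR cycle-threshold table around planted fold changes
#'
#' Reference-gene CTs are drawn Normal(`ct_reference_mean`,
#' `ct_reference_sd`) per sample; target CTs are offset from the
#' sample's reference so that the expected `2^-ddCT` equals the planted
#' fold change (`2^log2fc` from the ground truth, 1 for unplanted
#' genes), with Gaussian noise of standard deviation `noise_sd`. With
#' `noise_sd = 0` the planted fold is recovered exactly. Reference genes
#' follow the usual convention: GAPDH for circRNAs and mRNAs, U6 for
#' miRNAs.
#'
#' @param cfg A [sim_config()].
#' @param truth The `truth` element from [simulate_counts()].
#' @param genes Genes to include (default: all planted triad members).
#' @param noise_sd CT noise (default `cfg$ct_noise_sd`).
#' @return A CT tibble accepted by [delta_delta_ct()].
#' @export
simulate_ct_table <- function(cfg, truth, genes = NULL,
                              noise_sd = cfg$ct_noise_sd) {
  stopifnot(inherits(cfg, "sim_config"))
  tri <- truth$triads
  genes <- genes %||% unique(c(tri$circ_id, tri$mirna_id, tri$mrna_id))
  de <- truth$de
  cls <- de$rna_class[match(genes, de$feature_id)]
  cls[is.na(cls)] <- "mRNA"
  ref_of <- ifelse(cls == "miRNA", "U6", "GAPDH")
  lfc <- de$log2fc[match(genes, de$feature_id)]
  lfc[is.na(lfc)] <- 0
  samples <- c(paste0("case_", seq_len(cfg$n_per_group)),
               paste0("control_", seq_len(cfg$n_per_group)))
  grp <- rep(c("case", "control"), each = cfg$n_per_group)
  refs <- unique(ref_of)
  ref_ct <- matrix(rnorm(length(refs) * length(samples),
                         cfg$ct_reference_mean, cfg$ct_reference_sd),
                   nrow = length(refs), dimnames = list(refs, samples))
  rows <- list()
  for (r in refs) {
    rows[[length(rows) + 1L]] <- tibble::tibble(
      sample_id = samples, group = grp, gene_id = r,
      ct = unname(ref_ct[r, ]), reference_gene = r)
  }
  for (i in seq_along(genes)) {
    shift <- ifelse(grp == "case", -lfc[i], 0)
    rows[[length(rows) + 1L]] <- tibble::tibble(
      sample_id = samples, group = grp, gene_id = genes[i],
      ct = unname(ref_ct[ref_of[i], ]) + cfg$ct_baseline_dct + shift +
        rnorm(length(samples), 0, noise_sd),
      reference_gene = ref_of[i])
  }
  dplyr::bind_rows(rows)
}

#' Simulate a complete synthetic ceRNA study
#'
#' Runs [simulate_counts()], [simulate_sequences()] and
#' [simulate_ct_table()] on one generator stream seeded with
#' `cfg$seed`.
#'
#' @param cfg A [sim_config()].
#' @param avoid_collisions Passed to [simulate_sequences()].
#' @return A list with `counts`, `group`, `truth`, `sequences` and `ct`.
#' @export
simulate_dataset <- function(cfg = sim_config(), avoid_collisions = TRUE) {
  sim <- simulate_counts(cfg)
  sim$sequences <- simulate_sequences(cfg, sim$truth,
                                      avoid_collisions = avoid_collisions)
  sim$ct <- simulate_ct_table(cfg, sim$truth)
  sim$config <- cfg
  sim
}

#' Write a simulated dataset to a directory
#'
#' Emits one counts TSV per RNA class, miRNA and target FASTA files, the
#' CT table as TSV and the ground truth as JSON.
#'
#' @param sim Result of [simulate_dataset()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (cl in names(sim$counts)) {
    tab <- tibble::as_tibble(sim$counts[[cl]], rownames = "feature_id")
    readr::write_tsv(tab, file.path(dir, paste0("counts_", cl, ".tsv")),
                     progress = FALSE)
  }
  Biostrings::writeXStringSet(
    Biostrings::RNAStringSet(sim$sequences$mirna_seqs),
    file.path(dir, "mirna.fasta"))
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(sim$sequences$target_seqs),
    file.path(dir, "targets.fasta"))
  readr::write_tsv(sim$ct, file.path(dir, "ct_table.tsv"), progress = FALSE)
  truth <- list(de = sim$truth$de, triads = sim$truth$triads,
                planted_sites = sim$sequences$planted_sites)
  jsonlite::write_json(truth, file.path(dir, "ground_truth.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
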