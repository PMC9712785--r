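# Seed-match miRNA target prediction.
#
# Geometry (0-based, target stored 5'->3'): a canonical site is anchored by
# the 6mer seed core, the exact reverse complement of miRNA positions 2-7,
# occupying target interval [s, s+6). Because the duplex is antiparallel,
# miRNA position k pairs with target index s + 7 - k: position 8 pairs the
# base just upstream (s-1), position 1 faces the base just downstream
# (s+6). Site classes follow the canonical nomenclature:
#   6mer     core only                         [s,   s+6)
#   7mer_m8  core + position-8 pair            [s-1, s+6)
#   7mer_A1  core + 'A' across position 1      [s,   s+7)
#   8mer     both                              [s-1, s+7)

SEED_WEIGHTS <- c("6mer" = 1, "7mer_A1" = 2, "7mer_m8" = 3, "8mer" = 4)

norm_seq <- function(seq, what = "sequence") {
  s <- chartr("u", "U", toupper(seq))
  s <- chartr("U", "T", s)
  if (grepl("[^ACGT]", s)) {
    stop_valid(paste0(what, " contains non-ACGU/T characters (ambiguity codes",
                      " are not supported)"))
  }
  s
}

comp_base <- function(b) chartr("ACGT", "TGCA", b)

revcomp <- function(seq) {
  paste(rev(strsplit(comp_base(seq), "", fixed = TRUE)[[1]]), collapse = "")
}

# Character at 0-based index j, wrapping when circular; NA off the ends.
target_char <- function(chars, j, circular) {
  L <- length(chars)
  if (circular) return(chars[(j %% L) + 1L])
  if (j < 0 || j >= L) return(NA_character_)
  chars[j + 1L]
}

#' Find canonical miRNA seed-match sites on a target sequence
#'
#' Scans the target (5'->3') for exact Watson–Crick reverse complements of
#' the miRNA seed core (positions 2–7) and classifies each occurrence as
#' `6mer`, `7mer_m8`, `7mer_A1` or `8mer` depending on position-8 pairing
#' and a target adenosine opposite position 1. Overlapping sites are all
#' reported. `U` and `T` are treated equivalently in both inputs.
#'
#' @param mirna_seq miRNA sequence, 5'->3', length >= 8.
#' @param target_seq Target sequence, 5'->3'.
#' @param circular If `TRUE` the target is treated as circular (a
#'   back-spliced RNA): the scan also covers the junction-spanning window
#'   and flank/anchor positions wrap around the junction. Reported starts
#'   stay in `[0, length)`; `end` may exceed the length for
#'   junction-spanning sites.
#' @param flank Width of the 3'-supplementary window passed to
#'   [score_duplex()].
#' @return A tibble with 0-based half-open `start`/`end`, `site_type` and
#'   `score`, ordered by `start`.
#' @examples
#' find_seed_sites("UCGAAUGCAAAA", "CCCGCATTCGAACC")
#' @export
find_seed_sites <- function(mirna_seq, target_seq, circular = FALSE,
                            flank = 4) {
  m <- norm_seq(mirna_seq, "miRNA sequence")
  if (nchar(m) < 8L) stop_valid("miRNA sequence must be at least 8 nt")
  t_lin <- norm_seq(target_seq, "target sequence")
  L <- nchar(t_lin)
  core_rc <- revcomp(substr(m, 2L, 7L))
  scan_seq <- if (circular && L >= 7L) {
    paste0(t_lin, substr(t_lin, 1L, 7L))
  } else {
    t_lin
  }
  hits <- Biostrings::matchPattern(core_rc, Biostrings::DNAString(scan_seq))
  starts0 <- Biostrings::start(hits) - 1L
  starts0 <- starts0[starts0 < L]            # de-duplicate wrapped copies
  if (length(starts0) == 0L) {
    return(tibble::tibble(start = integer(), end = integer(),
                          site_type = character(), score = double()))
  }
  tchars <- strsplit(t_lin, "", fixed = TRUE)[[1]]
  mchars <- strsplit(m, "", fixed = TRUE)[[1]]
  rows <- lapply(starts0, function(s) {
    up <- target_char(tchars, s - 1L, circular)
    dn <- target_char(tchars, s + 6L, circular)
    has_m8 <- !is.na(up) && up == comp_base(mchars[8L])
    has_a1 <- !is.na(dn) && dn == "A"
    type <- if (has_m8 && has_a1) "8mer" else if (has_m8) "7mer_m8"
            else if (has_a1) "7mer_A1" else "6mer"
    start <- if (type %in% c("7mer_m8", "8mer")) s - 1L else s
    if (circular) start <- start %% L
    len <- switch(type, "6mer" = 6L, "8mer" = 8L, 7L)
    list(start = start, end = start + len, site_type = type, core_start = s)
  })
  out <- tibble::tibble(
    start = vapply(rows, `[[`, integer(1), "start"),
    end = vapply(rows, `[[`, integer(1), "end"),
    site_type = vapply(rows, `[[`, character(1), "site_type")
  )
  out$score <- vapply(seq_len(nrow(out)), function(i) {
    duplex_score(rows[[i]]$core_start, out$site_type[i], mchars, tchars,
                 flank, circular)
  }, double(1))
  out[order(out$start), ]
}

duplex_score <- function(core_start, site_type, mchars, tchars, flank,
                         circular) {
  bonus <- 0
  ks <- seq(13L, 12L + flank)
  ks <- ks[ks <= length(mchars)]
  for (k in ks) {
    tc <- target_char(tchars, core_start + 7L - k, circular)
    if (!is.na(tc) && tc == comp_base(mchars[k])) bonus <- bonus + 1
  }
  unname(SEED_WEIGHTS[site_type]) + bonus
}

#' Score a seed site with a 3'-supplementary bonus
#'
#' The score is the seed-type weight (8mer 4 > 7mer_m8 3 > 7mer_A1 2 >
#' 6mer 1) plus the number of Watson–Crick pairs formed between miRNA
#' positions 13 to `12 + flank` and the target bases they face upstream of
#' the seed. Deterministic in its inputs.
#'
#' @param site One row of a [find_seed_sites()] result (list or
#'   single-row data frame with `start` and `site_type`).
#' @param mirna_seq,target_seq The sequences the site was found on.
#' @param flank 3'-supplementary window width (default 4, miRNA positions
#'   13–16).
#' @param circular Whether the target is circular (flank indexing wraps).
#' @return The numeric score.
#' @export
score_duplex <- function(site, mirna_seq, target_seq, flank = 4,
                         circular = FALSE) {
  m <- norm_seq(mirna_seq, "miRNA sequence")
  t_lin <- norm_seq(target_seq, "target sequence")
  core_start <- site$start + (site$site_type %in% c("7mer_m8", "8mer"))
  duplex_score(as.integer(core_start), site$site_type,
               strsplit(m, "", fixed = TRUE)[[1]],
               strsplit(t_lin, "", fixed = TRUE)[[1]], flank, circular)
}

as_named_seqs <- function(x, what) {
  if (inherits(x, "XStringSet")) {
    out <- as.character(x)
  } else if (is.character(x) && length(x) == 1L && file.exists(x) &&
             is.null(names(x))) {
    out <- as.character(Biostrings::readBStringSet(x))
  } else if (is.character(x)) {
    out <- x
  } else {
    stop_usage(paste0(what, " must be a FASTA path, a named character ",
                      "vector, or an XStringSet"))
  }
  if (length(out) > 0L &&
      (is.null(names(out)) || any(!nzchar(names(out))))) {
    stop_valid(paste0("every ", what, " sequence needs a name"))
  }
  # FASTA headers may carry descriptions after the id
  names(out) <- sub("\\s.*$", "", names(out))
  out
}

#' Predict miRNA-target interactions by two-source seed-match consensus
#'
#' Runs two predictor variants over every (miRNA, target) pair — a
#' site-count rule (`"seedmatch_sites"`: at least `min_sites` canonical
#' sites) and a score-threshold rule (`"seedmatch_score"`: best
#' [score_duplex()] score at least `min_score`) — and combines them per
#' pair by the chosen policy, mirroring a two-database consensus lookup.
#' Edges are emitted class-correct: circRNA->miRNA for sponge edges,
#' miRNA->mRNA for targeting edges.
#'
#' @param mirna_fasta miRNA sequences: FASTA path, named character vector
#'   or XStringSet.
#' @param target_fasta Target sequences, same forms.
#' @param target_class `"mRNA"` or `"circRNA"`.
#' @param policy `"union"` or `"intersection"`. Defaults to intersection
#'   for mRNA targets (overlap of the two sources) and union for circRNA
#'   targets.
#' @param min_score Score threshold of the score-based source (default 3,
#'   the weight of an unsupported 7mer_m8 site).
#' @param min_sites Site-count threshold of the count-based source.
#' @param circular Scan targets as circular sequences; defaults to `TRUE`
#'   for circRNA targets.
#' @return An edge tibble with `site_count`, `best_site_type`, `score` and
#'   `sources` columns.
#' @export
predict_interactions <- function(mirna_fasta, target_fasta,
                                 target_class = c("mRNA", "circRNA"),
                                 policy = NULL, min_score = 3,
                                 min_sites = 1,
                                 circular = NULL) {
  target_class <- match.arg(target_class)
  policy <- policy %||% if (target_class == "mRNA") "intersection" else "union"
  if (!policy %in% c("union", "intersection")) {
    stop_usage(paste0("unknown policy '", policy, "'"))
  }
  circular <- circular %||% (target_class == "circRNA")
  mirnas <- as_named_seqs(mirna_fasta, "miRNA")
  targets <- as_named_seqs(target_fasta, "target")
  empty <- tibble::tibble(
    source_id = character(), source_class = character(),
    target_id = character(), target_class = character(),
    site_count = integer(), best_site_type = character(),
    score = double(), sources = character())
  if (length(mirnas) == 0L || length(targets) == 0L) {
    warn("empty sequence set; no interactions predicted")
    return(empty)
  }
  rows <- list()
  for (mi in names(mirnas)) {
    for (tg in names(targets)) {
      sites <- find_seed_sites(mirnas[[mi]], targets[[tg]],
                               circular = circular)
      if (nrow(sites) == 0L) next
      by_count <- nrow(sites) >= min_sites
      by_score <- max(sites$score) >= min_score
      keep <- if (policy == "union") by_count || by_score else
        by_count && by_score
      if (!keep) next
      labels <- c(if (by_count) "seedmatch_sites",
                  if (by_score) "seedmatch_score")
      best <- which.max(sites$score)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        mirna_id = mi, other_id = tg, site_count = nrow(sites),
        best_site_type = sites$site_type[best], score = sites$score[best],
        sources = paste(labels, collapse = ","))
    }
  }
  if (length(rows) == 0L) return(empty)
  hits <- dplyr::bind_rows(rows)
  if (target_class == "circRNA") {
    tibble::tibble(
      source_id = hits$other_id, source_class = "circRNA",
      target_id = hits$mirna_id, target_class = "miRNA",
      site_count = hits$site_count, best_site_type = hits$best_site_type,
      score = hits$score, sources = hits$sources)
  } else {
    tibble::tibble(
      source_id = hits$mirna_id, source_class = "miRNA",
      target_id = hits$other_id, target_class = "mRNA",
      site_count = hits$site_count, best_site_type = hits$best_site_type,
      score = hits$score, sources = hits$sources)
  }
}
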