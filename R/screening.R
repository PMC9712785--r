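#' Differential-expression screening rule
#'
#' The study's screening rule keeps features with an absolute log2 fold
#' change of at least `min_abs_log2fc` AND a raw p-value strictly below
#' `max_p`. The printed rule "|Fold Change| >= 1, p < 0.05" is read as a
#' threshold on the log2 fold change (fold change >= 2 or <= 0.5): every
#' differentially expressed feature the study reports satisfies
#' |log2FC| >= 1.03, while a literal linear-scale reading would keep every
#' feature. Raw p-values are thresholded; BH-adjusted screening is
#' available via `adjust = "BH"` but off by default, matching the stated
#' rule.
#'
#' @param min_abs_log2fc Minimum |log2 fold change| (default 1; `>=`).
#' @param max_p Maximum p-value (default 0.05; strict `<`).
#' @param adjust `"none"` (default) or `"BH"`.
#' @return A `screening_rule` list.
#' @export
screening_rule <- function(min_abs_log2fc = 1, max_p = 0.05,
                           adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  if (!is.numeric(min_abs_log2fc) || min_abs_log2fc < 0) {
    stop_domain("min_abs_log2fc must be >= 0")
  }
  if (!is.numeric(max_p) || max_p <= 0 || max_p >= 1) {
    stop_domain("max_p must be in (0, 1)")
  }
  structure(list(min_abs_log2fc = min_abs_log2fc, max_p = max_p,
                 adjust = adjust), class = "screening_rule")
}

#' RPKM of a circRNA from back-splice-junction reads
#'
#' circRNA abundance is quantified as reads per kilobase per million
#' mapped reads computed on back-splice-junction (BSJ) reads:
#' `bsj_reads * 1e9 / (circ_length_nt * total_mapped_reads)`. The
#' denominator uses the library's total mapped reads.
#'
#' @param bsj_reads Non-negative BSJ read count (vectorised).
#' @param circ_length_nt Positive circRNA length in nucleotides.
#' @param total_mapped_reads Positive library size in reads.
#' @return RPKM value(s).
#' @examples
#' rpkm_bsj(10, 1000, 1e6) # 10
#' @export
rpkm_bsj <- function(bsj_reads, circ_length_nt, total_mapped_reads) {
  if (any(bsj_reads < 0)) stop_domain("bsj_reads must be non-negative")
  if (any(circ_length_nt <= 0)) stop_domain("circ_length_nt must be positive")
  if (any(total_mapped_reads <= 0)) {
    stop_domain("total_mapped_reads must be positive")
  }
  bsj_reads * 1e9 / (circ_length_nt * total_mapped_reads)
}

#' Two-group expression test on counts
#'
#' A transparent small-sample test used when no externally computed DE
#' table is supplied: the log2 fold change is
#' `log2((mean(case) + c) / (mean(control) + c))` with pseudocount `c`,
#' and the p-value comes from a pooled-variance Student's t-test on
#' `log2(count + c)`; with balanced groups drawn under a shared
#' dispersion model, pooling keeps the degrees of freedom stable at
#' small sample sizes. A feature that is all-zero in both groups returns
#' `log2fc = 0, p = 1`.
#'
#' @param case_counts,control_counts Count vectors (>= 2 samples each).
#' @param pseudocount Pseudocount `c` (default 0.5).
#' @return A list with `log2fc` and `p_value`.
#' @export
two_group_test <- function(case_counts, control_counts, pseudocount = 0.5) {
  if (length(case_counts) < 2L || length(control_counts) < 2L) {
    stop_domain("each group needs at least 2 samples")
  }
  if (all(case_counts == 0) && all(control_counts == 0)) {
    return(list(log2fc = 0, p_value = 1))
  }
  lfc <- log2((mean(case_counts) + pseudocount) /
                (mean(control_counts) + pseudocount))
  la <- log2(case_counts + pseudocount)
  lb <- log2(control_counts + pseudocount)
  if (stats::var(la) == 0 && stats::var(lb) == 0) {
    p <- if (mean(la) == mean(lb)) 1 else 0
  } else {
    p <- t.test(la, lb, var.equal = TRUE)$p.value
  }
  list(log2fc = lfc, p_value = p)
}

#' Differential-expression table from a count matrix
#'
#' Applies [two_group_test()] to every row of a two-group count matrix.
#'
#' @param counts Integer matrix, features x samples.
#' @param group Character/factor vector per column, `"case"`/`"control"`.
#' @param rna_class RNA class of the features.
#' @param pseudocount Passed to [two_group_test()].
#' @return A DE-record tibble (features with `log2fc == 0` carry
#'   `direction = NA` and never pass a screening rule with a positive
#'   fold-change threshold).
#' @export
de_from_counts <- function(counts, group,
                           rna_class = c("circRNA", "miRNA", "mRNA"),
                           pseudocount = 0.5) {
  rna_class <- match.arg(rna_class)
  group <- as.character(group)
  if (!all(group %in% c("case", "control"))) {
    stop_usage("group must be 'case'/'control' per column")
  }
  ca <- counts[, group == "case", drop = FALSE]
  co <- counts[, group == "control", drop = FALSE]
  res <- lapply(seq_len(nrow(counts)), function(i) {
    two_group_test(ca[i, ], co[i, ], pseudocount)
  })
  lfc <- vapply(res, `[[`, double(1), "log2fc")
  tibble::tibble(
    feature_id = rownames(counts) %||% as.character(seq_len(nrow(counts))),
    rna_class = rna_class,
    log2fc = lfc,
    p_value = vapply(res, `[[`, double(1), "p_value"),
    direction = up_down(lfc)
  )
}

#' Screen DE records under a fold-change and p-value rule
#'
#' Keeps records with `|log2fc| >= min_abs_log2fc` and `p < max_p`
#' (on BH-adjusted p-values when the rule says so). Input order is
#' preserved; the operation is idempotent.
#'
#' @param records DE-record tibble.
#' @param rule A [screening_rule()].
#' @return The kept records.
#' @examples
#' de <- read_de_table(spongenet_example("table2_circrna_de.tsv"), "circRNA")
#' nrow(screen(de)) # 34
#' @export
screen <- function(records, rule = screening_rule()) {
  if (nrow(records) == 0L) return(records)
  p <- if (rule$adjust == "BH") bh_adjust(records$p_value) else records$p_value
  records[abs(records$log2fc) >= rule$min_abs_log2fc & p < rule$max_p, ]
}

#' Summarise a screened DE table
#'
#' Reports counts by direction, the extreme log2 fold changes and GC
#' contents (with the features attaining them), and chromosome and
#' length-bin histograms when those extras are present.
#'
#' @param records DE-record tibble.
#' @param length_breaks Breakpoints (nt) for the length histogram.
#' @return A list of summary statistics.
#' @export
summarize_screened <- function(records,
                               length_breaks = c(0, 200, 400, 600, 800,
                                                 1000, Inf)) {
  if (nrow(records) == 0L) stop_usage("no records to summarise")
  out <- list(
    n = nrow(records),
    n_up = sum(records$direction == "up", na.rm = TRUE),
    n_down = sum(records$direction == "down", na.rm = TRUE),
    max_log2fc = max(records$log2fc),
    max_log2fc_id = records$feature_id[which.max(records$log2fc)],
    min_log2fc = min(records$log2fc),
    min_log2fc_id = records$feature_id[which.min(records$log2fc)]
  )
  if ("gc_percent" %in% names(records)) {
    out$max_gc <- max(records$gc_percent)
    out$max_gc_id <- records$feature_id[which.max(records$gc_percent)]
    out$min_gc <- min(records$gc_percent)
    out$min_gc_id <- records$feature_id[which.min(records$gc_percent)]
  }
  if ("chromosome" %in% names(records)) {
    out$chromosome_counts <- table(records$chromosome)
  }
  if ("length_nt" %in% names(records)) {
    out$length_histogram <- table(cut(records$length_nt, length_breaks))
  }
  out
}
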