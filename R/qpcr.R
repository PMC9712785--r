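#' Relative expression by the 2^-ddCt method
#'
#' For one gene, computes per-sample `dCT = CT_gene - CT_reference`,
#' calibrates against the mean control-group dCT
#' (`ddCT = dCT - mean(dCT_control)`), and reports the per-sample fold
#' change `2^-ddCT` together with group means and standard deviations.
#' With this calibration the control-group ddCTs average exactly 0 and
#' the geometric mean of control folds is exactly 1. Fold changes are
#' invariant to adding a constant to every CT of a sample, since the
#' reference subtraction cancels it.
#'
#' @param ct A CT table as returned by [read_ct_table()] or
#'   [simulate_ct_table()].
#' @param gene Gene id to quantify.
#' @return A list with `per_sample` (sample, group, dct, ddct, fold) and
#'   `summary` (per-group mean/sd of fold and ddct).
#' @export
delta_delta_ct <- function(ct, gene) {
  validate_ct_table(ct)
  g <- ct[ct$gene_id == gene, ]
  if (nrow(g) == 0L) stop_usage(paste0("gene '", gene, "' not in CT table"))
  ref_gene <- unique(g$reference_gene)
  if (length(ref_gene) != 1L) {
    stop_valid(paste0("gene '", gene, "' maps to several reference genes"))
  }
  r <- ct[ct$gene_id == ref_gene, ]
  idx <- match(g$sample_id, r$sample_id)
  dct <- unname(g$ct - r$ct[idx])
  is_control <- g$group == "control"
  if (!any(is_control)) stop_domain("no control samples in CT table")
  ddct <- dct - mean(dct[is_control])
  per_sample <- tibble::tibble(
    sample_id = g$sample_id, group = g$group,
    dct = dct, ddct = ddct, fold = 2^(-ddct))
  summary <- per_sample |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(mean_fold = mean(.data$fold),
                     sd_fold = stats::sd(.data$fold),
                     mean_ddct = mean(.data$ddct),
                     sd_ddct = stats::sd(.data$ddct), .groups = "drop")
  list(per_sample = per_sample, summary = summary)
}

#' Two-group comparison of qPCR quantities
#'
#' Two-sided, equal-variance Student's t-test between case and control
#' values (fold changes as typically plotted, or ddCT values).
#'
#' @param case_values,control_values Numeric vectors.
#' @return A list with `t` and `p_value`.
#' @export
group_compare <- function(case_values, control_values) {
  if (stats::var(case_values) == 0 && stats::var(control_values) == 0) {
    equal <- isTRUE(all.equal(mean(case_values), mean(control_values)))
    return(list(t = if (equal) 0 else Inf, p_value = if (equal) 1 else 0))
  }
  ht <- t.test(case_values, control_values, var.equal = TRUE)
  list(t = unname(ht$statistic), p_value = ht$p.value)
}

#' Per-gene qPCR validation summary
#'
#' Runs [delta_delta_ct()] and [group_compare()] for each requested gene.
#'
#' @param ct A CT table.
#' @param genes Genes to quantify (default: every non-reference gene).
#' @param on Test on `"fold"` changes (default) or on `"dct"` values.
#' @return A tibble with one row per gene: case/control mean folds and
#'   the t-test statistic and p-value.
#' @export
qpcr_summary <- function(ct, genes = NULL, on = c("fold", "dct")) {
  on <- match.arg(on)
  genes <- genes %||% setdiff(unique(ct$gene_id), unique(ct$reference_gene))
  rows <- lapply(genes, function(g) {
    q <- delta_delta_ct(ct, g)
    ps <- q$per_sample
    vals <- if (on == "fold") ps$fold else ps$dct
    cmp <- group_compare(vals[ps$group == "case"],
                         vals[ps$group == "control"])
    tibble::tibble(
      gene_id = g,
      mean_fold_case = mean(ps$fold[ps$group == "case"]),
      mean_fold_control = mean(ps$fold[ps$group == "control"]),
      t = cmp$t, p_value = cmp$p_value)
  })
  dplyr::bind_rows(rows)
}
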