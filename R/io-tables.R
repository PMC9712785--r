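#' Read a differential-expression table
#'
#' Parses a delimited text table of differential-expression results for one
#' RNA class into a validated tibble of DE records. The canonical delimiter
#' is tab; comma-separated files are detected automatically. Mandatory
#' columns are a feature identifier, `log2fc` and `p_value` (common header
#' variants such as `log2Fold change` or `P-value` are recognised);
#' `regulation`, `gc_percent`, `circ_type`, `length_nt` and `chromosome`
#' are carried along when present.
#'
#' The `direction` of each record is taken from the regulation column when
#' one exists — and must then agree with the sign of `log2fc` — or is
#' derived from that sign otherwise. A `log2fc` of exactly 0 is rejected as
#' directionless.
#'
#' @param path Path to the table.
#' @param rna_class One of `"circRNA"`, `"miRNA"`, `"mRNA"`.
#' @return A tibble with columns `feature_id`, `rna_class`, `log2fc`,
#'   `p_value`, `direction` (`"up"`/`"down"`) plus any recognised extras.
#' @examples
#' de <- read_de_table(spongenet_example("table2_circrna_de.tsv"), "circRNA")
#' nrow(de)
#' @export
read_de_table <- function(path, rna_class = c("circRNA", "miRNA", "mRNA")) {
  rna_class <- match.arg(rna_class)
  tab <- read_sniffed(path)
  names(tab) <- normalize_names(names(tab))

  for (col in c("feature_id", "log2fc", "p_value")) {
    if (!col %in% names(tab)) {
      stop_format(paste0("missing mandatory column '", col, "' in ", path))
    }
  }
  if (nrow(tab) == 0L) {
    return(tibble::tibble(feature_id = character(), rna_class = character(),
                          log2fc = double(), p_value = double(),
                          direction = character()))
  }

  tab$log2fc <- as.numeric(tab$log2fc)
  tab$p_value <- as.numeric(tab$p_value)
  if (any(!is.finite(tab$log2fc))) {
    stop_valid(paste0("non-finite log2fc in rows: ",
                      paste(tab$feature_id[!is.finite(tab$log2fc)], collapse = ", ")))
  }
  bad_p <- !is.finite(tab$p_value) | tab$p_value <= 0 | tab$p_value > 1
  if (any(bad_p)) {
    stop_valid(paste0("p_value outside (0, 1] in rows: ",
                      paste(tab$feature_id[bad_p], collapse = ", ")))
  }
  if (any(tab$log2fc == 0)) {
    stop_valid(paste0("log2fc == 0 is directionless; rows: ",
                      paste(tab$feature_id[tab$log2fc == 0], collapse = ", ")))
  }

  derived <- up_down(tab$log2fc)
  if ("regulation" %in% names(tab)) {
    stated <- tolower(as.character(tab$regulation))
    conflict <- stated != derived
    if (any(conflict)) {
      stop_valid(paste0("regulation column conflicts with sign(log2fc) for: ",
                        paste(tab$feature_id[conflict], collapse = ", ")))
    }
  }
  tab$direction <- derived
  tab$rna_class <- rna_class
  tab$regulation <- NULL

  extras <- intersect(c("gc_percent", "circ_type", "length_nt", "chromosome"),
                      names(tab))
  tibble::as_tibble(tab[, c("feature_id", "rna_class", "log2fc", "p_value",
                            "direction", extras)])
}

#' Read an interaction edge list
#'
#' Reads a delimited table of predicted sponge (circRNA–miRNA) or targeting
#' (miRNA–mRNA) interactions. Per-row `source_class`/`target_class` columns
#' override the defaults; repeated (source, target) pairs are merged into a
#' single edge whose evidence labels are the union of the rows' labels and
#' whose score is the maximum.
#'
#' @param path Path to the edge list.
#' @param source_class,target_class RNA classes assumed for rows that carry
#'   no class columns. Must form a (circRNA, miRNA) or (miRNA, mRNA) pair.
#' @return A tibble with columns `source_id`, `source_class`, `target_id`,
#'   `target_class`, `sources` (comma-joined evidence labels), `score`,
#'   plus any `source_regulation`/`target_regulation` columns present.
#' @examples
#' read_edge_list(spongenet_example("table4_sponge_edges.tsv"))
#' @export
read_edge_list <- function(path, source_class = "circRNA", target_class = "miRNA") {
  tab <- read_sniffed(path)
  names(tab) <- normalize_names(names(tab))
  for (col in c("source_id", "target_id")) {
    if (!col %in% names(tab)) {
      stop_format(paste0("missing mandatory column '", col, "' in ", path))
    }
  }
  if (!"source_class" %in% names(tab)) tab$source_class <- source_class
  if (!"target_class" %in% names(tab)) tab$target_class <- target_class
  if (!"sources" %in% names(tab)) tab$sources <- basename(path)
  if (!"score" %in% names(tab)) tab$score <- NA_real_
  keep_reg <- intersect(c("source_regulation", "target_regulation"), names(tab))
  validate_edges(tab)
  edges <- dedup_edges(tibble::as_tibble(
    tab[, c("source_id", "source_class", "target_id", "target_class",
            "sources", "score", keep_reg)]))
  edges
}

validate_edges <- function(tab) {
  ok_pair <- (tab$source_class == "circRNA" & tab$target_class == "miRNA") |
    (tab$source_class == "miRNA" & tab$target_class == "mRNA")
  if (any(!ok_pair)) {
    stop_valid(paste0(
      "edge class pair must be circRNA->miRNA or miRNA->mRNA; offending rows: ",
      paste(which(!ok_pair), collapse = ", ")))
  }
  loops <- tab$source_id == tab$target_id
  if (any(loops)) {
    stop_valid(paste0("self-loop edges: ",
                      paste(tab$source_id[loops], collapse = ", ")))
  }
  invisible(tab)
}

# Union evidence labels and keep the best score for repeated pairs.
dedup_edges <- function(edges) {
  edges |>
    dplyr::group_by(.data$source_id, .data$source_class,
                    .data$target_id, .data$target_class) |>
    dplyr::summarise(
      sources = paste(sort(unique(unlist(strsplit(.data$sources, ",")))),
                      collapse = ","),
      score = if (all(is.na(.data$score))) NA_real_ else
        max(.data$score, na.rm = TRUE),
      dplyr::across(dplyr::any_of(c("source_regulation", "target_regulation")),
                    dplyr::first),
      .groups = "drop"
    )
}

#' Read gene-set annotations in GMT format
#'
#' Each GMT line is `term_id<TAB>term_name<TAB>member1<TAB>member2...`.
#' Duplicate members within a set are counted once; sets with no members
#' are skipped with a warning.
#'
#' @param path Path to a GMT file.
#' @param namespace Annotation namespace attached to every set in the file:
#'   `"BP"`, `"MF"`, `"CC"` or `"pathway"`.
#' @return A tibble with columns `term_id`, `term_name`, `namespace` and a
#'   list-column `members` of unique gene-id vectors.
#' @export
read_gmt <- function(path, namespace = c("pathway", "BP", "MF", "CC")) {
  namespace <- match.arg(namespace)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- vapply(parts, length, integer(1)) < 3L
  if (any(short)) {
    warn(paste0("skipping ", sum(short), " GMT line(s) with no members"))
    parts <- parts[!short]
  }
  tibble::tibble(
    term_id = vapply(parts, `[[`, character(1), 1L),
    term_name = vapply(parts, `[[`, character(1), 2L),
    namespace = namespace,
    members = lapply(parts, function(p) unique(p[-(1:2)]))
  )
}

#' Read a qPCR cycle-threshold table
#'
#' Expects columns `sample_id`, `group` (`case`/`control`), `gene_id`,
#' `ct` and `reference_gene`. Every (sample, gene) measurement must be
#' matched by a measurement of its reference gene in the same sample.
#'
#' @param path Path to the table.
#' @return A validated tibble of CT measurements.
#' @export
read_ct_table <- function(path) {
  tab <- read_sniffed(path)
  names(tab) <- normalize_names(names(tab))
  for (col in c("sample_id", "group", "gene_id", "ct", "reference_gene")) {
    if (!col %in% names(tab)) {
      stop_format(paste0("missing mandatory column '", col, "' in ", path))
    }
  }
  tab$group <- tolower(tab$group)
  validate_ct_table(tibble::as_tibble(tab))
}

validate_ct_table <- function(tab) {
  if (!all(tab$group %in% c("case", "control"))) {
    stop_valid("group must be 'case' or 'control'")
  }
  if (any(!is.finite(tab$ct) | tab$ct <= 0)) {
    stop_valid("ct values must be finite and > 0")
  }
  need_ref <- unique(tab[tab$gene_id != tab$reference_gene,
                         c("sample_id", "reference_gene")])
  have <- paste(tab$sample_id, tab$gene_id)
  missing <- !(paste(need_ref$sample_id, need_ref$reference_gene) %in% have)
  if (any(missing)) {
    stop_valid(paste0("missing reference-gene measurement for sample(s): ",
                      paste(need_ref$sample_id[missing], collapse = ", ")))
  }
  tab
}
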