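# Internal helpers: error signalling, delimiter sniffing, id extraction.

stop_format <- function(msg) abort(msg, class = "spongenet_format_error")
stop_valid  <- function(msg) abort(msg, class = "spongenet_validation_error")
stop_domain <- function(msg) abort(msg, class = "spongenet_domain_error")
stop_usage  <- function(msg) abort(msg, class = "spongenet_usage_error")

RNA_CLASSES <- c("circRNA", "miRNA", "mRNA")

# Tab is the canonical delimiter; comma accepted by sniffing the header line.
sniff_delim <- function(path) {
  first <- readLines(path, n = 1L, warn = FALSE)
  if (length(first) == 0L || grepl("\t", first)) "\t" else ","
}

read_sniffed <- function(path) {
  readr::read_delim(path, delim = sniff_delim(path),
                    show_col_types = FALSE, progress = FALSE,
                    trim_ws = TRUE)
}

# Map heterogeneous header spellings onto canonical column names.
normalize_names <- function(nms) {
  key <- tolower(gsub("[^a-z0-9]", "", tolower(nms)))
  map <- c(
    featureid = "feature_id", id = "feature_id", circrnas = "feature_id",
    cicrrnas = "feature_id", circrna = "feature_id", mirnas = "feature_id",
    mirna = "feature_id", mrnas = "feature_id", mrna = "feature_id",
    gene = "feature_id", name = "feature_id",
    log2fc = "log2fc", log2foldchange = "log2fc", logfc = "log2fc",
    pvalue = "p_value", p = "p_value", pval = "p_value",
    regulation = "regulation", direction = "regulation",
    gccontent = "gc_percent", gcpercent = "gc_percent", gc = "gc_percent",
    circrnastype = "circ_type", circtype = "circ_type", type = "circ_type",
    lengthnt = "length_nt", length = "length_nt",
    chromosome = "chromosome", chr = "chromosome",
    sourceid = "source_id", source = "source_id", from = "source_id",
    targetid = "target_id", target = "target_id", to = "target_id",
    sourceclass = "source_class", targetclass = "target_class",
    sources = "sources", evidence = "sources", database = "sources",
    sourcelabel = "sources", score = "score",
    sourceregulation = "source_regulation",
    targetregulation = "target_regulation",
    sampleid = "sample_id", sample = "sample_id",
    group = "group", geneid = "gene_id", ct = "ct",
    referencegene = "reference_gene", reference = "reference_gene"
  )
  out <- nms
  hit <- key %in% names(map)
  out[hit] <- unname(map[key[hit]])
  out
}

# Accept a DeRecord tibble, a data frame with a feature_id column, or a
# plain character vector wherever a set of feature ids is expected.
as_feature_ids <- function(x) {
  if (is.character(x)) return(x)
  if (is.data.frame(x) && "feature_id" %in% names(x)) return(x$feature_id)
  stop_usage("expected a character vector or a table with a 'feature_id' column")
}

up_down <- function(log2fc) ifelse(log2fc > 0, "up", ifelse(log2fc < 0, "down", NA_character_))

opposite_direction <- function(a, b) {
  ifelse(is.na(a) | is.na(b), NA, a != b)
}
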