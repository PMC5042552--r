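#' Load a transmembrane gene list
#'
#' Reads a Biomart-style tab-separated export (header row, one gene id
#' column) listing the genes that contain at least one transmembrane
#' segment. The gene-id column is located by name (`gene_id`, or any column
#' whose name contains "gene"); identifiers are deduplicated.
#'
#' The transmembrane gene set is an input, not a computation: which annotation
#' source and genome build define "transmembrane" is the caller's choice, and
#' the file's provenance is kept alongside the ids.
#'
#' @param tsv_path Path to the gene-list TSV.
#' @return An object of class `tm_gene_set`: a list with `gene_ids`
#'   (character vector, unique) and `source_label`.
#' @export
load_tm_genes <- function(tsv_path) {
  if (!file.exists(tsv_path)) {
    abort_config(paste0("transmembrane gene list not found: ", tsv_path))
  }
  df <- readr::read_tsv(tsv_path, comment = "#", progress = FALSE,
                        show_col_types = FALSE)
  col <- if ("gene_id" %in% names(df)) {
    "gene_id"
  } else {
    hit <- grep("gene", names(df), ignore.case = TRUE, value = TRUE)
    if (length(hit) == 0) {
      abort_config(paste0("no gene-id column found in ", tsv_path))
    }
    hit[1]
  }
  ids <- unique(as.character(df[[col]]))
  ids <- ids[!is.na(ids) & ids != ""]
  if (length(ids) == 0) {
    abort_config(paste0("transmembrane gene list is empty: ", tsv_path))
  }
  message(length(ids), " transmembrane gene id(s) loaded")
  structure(
    list(gene_ids = ids, source_label = basename(tsv_path)),
    class = "tm_gene_set"
  )
}

#' @export
print.tm_gene_set <- function(x, ...) {
  cat("Transmembrane gene set:", length(x$gene_ids), "ids from",
      x$source_label, "\n")
  invisible(x)
}

#' Build the scoreable site panel P
#'
#' Restricts a paired-genotype stream to the set P of scoreable sites: sites
#' whose gene contains a transmembrane segment and whose consequence belongs
#' to the admitted classes (missense only, by default). Exclusions are
#' tallied by reason so that `|panel| + exclusions = |input|` always holds.
#'
#' @param paired A paired-genotype tibble from [pair_genotypes()].
#' @param tm A `tm_gene_set` from [load_tm_genes()], or a character vector of
#'   gene ids.
#' @param consequences Character vector of admitted consequence classes.
#' @return An object of class `site_panel`: a list with `sites` (the
#'   filtered paired tibble, ordered by chrom/pos), `exclusions` (named
#'   integer vector: `non_tm_gene`, `non_admitted_consequence`) and
#'   `selection_config`.
#' @export
build_panel <- function(paired, tm, consequences = "missense_variant") {
  gene_ids <- if (inherits(tm, "tm_gene_set")) tm$gene_ids else as.character(tm)
  source_label <- if (inherits(tm, "tm_gene_set")) tm$source_label else "gene-id vector"

  in_tm <- paired$gene_id %in% gene_ids
  admitted <- paired$consequence %in% consequences
  keep <- in_tm & admitted
  exclusions <- c(
    non_tm_gene = sum(!in_tm),
    non_admitted_consequence = sum(in_tm & !admitted)
  )
  sites <- dplyr::arrange(paired[keep, ], .data$chrom, .data$pos)
  structure(
    list(
      sites = sites,
      exclusions = exclusions,
      selection_config = list(
        consequences = consequences,
        gene_set = source_label,
        n_tm_genes = length(gene_ids)
      )
    ),
    class = "site_panel"
  )
}

#' @export
print.site_panel <- function(x, ...) {
  cat("Site panel P:", nrow(x$sites), "site(s) admitted\n")
  cat("  consequences:", paste(x$selection_config$consequences, collapse = ", "), "\n")
  cat("  gene set:", x$selection_config$gene_set,
      sprintf("(%d ids)", x$selection_config$n_tm_genes), "\n")
  cat("  excluded: ", x$exclusions["non_tm_gene"], " non-TM gene, ",
      x$exclusions["non_admitted_consequence"], " non-admitted consequence\n",
      sep = "")
  invisible(x)
}
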