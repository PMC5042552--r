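# Protein-level variant annotation: a side-car TSV table or VEP-style CSQ
# strings declared in the VCF header. Either source is normalised to one
# tibble with one row per (site, transcript, alternate allele).

ANNOTATION_COLS <- c(
  "chrom", "pos", "ref", "alt", "gene_id", "transcript_id",
  "protein_pos", "ref_aa", "alt_aa", "consequence"
)

# Consequence terms ordered from most to least severe; used to pick one
# transcript per site and unknown terms rank after all listed ones.
CONSEQUENCE_SEVERITY <- c(
  "stop_gained", "stop_lost", "start_lost", "missense_variant",
  "inframe_insertion", "inframe_deletion", "protein_altering_variant",
  "synonymous_variant"
)

severity_rank <- function(consequence) {
  r <- match(consequence, CONSEQUENCE_SEVERITY)
  r[is.na(r)] <- length(CONSEQUENCE_SEVERITY) + 1L
  r
}

#' Read a protein annotation table
#'
#' Reads a tab-separated annotation table with columns `chrom`, `pos`, `ref`,
#' `alt`, `gene_id`, `transcript_id`, `protein_pos`, `ref_aa`, `alt_aa`,
#' `consequence` and optionally `canonical` (logical flag used to prefer a
#' transcript). One row per (site, transcript, alternate allele). Lines
#' starting with `#` are ignored.
#'
#' @param path Path to the TSV file.
#' @return An annotation tibble.
#' @export
read_annotation_table <- function(path) {
  if (!file.exists(path)) {
    abort_config(paste0("annotation table not found: ", path))
  }
  df <- readr::read_tsv(path, comment = "#", progress = FALSE,
                        show_col_types = FALSE)
  missing <- setdiff(ANNOTATION_COLS, names(df))
  if (length(missing) > 0) {
    abort_config(paste0(
      "annotation table ", path, " lacks column(s): ",
      paste(missing, collapse = ", ")
    ))
  }
  df$chrom <- as.character(df$chrom)
  df$pos <- as.integer(df$pos)
  df$protein_pos <- as.integer(df$protein_pos)
  if (any(df$protein_pos < 1, na.rm = TRUE)) {
    abort_data("annotation table contains protein_pos < 1")
  }
  tibble::as_tibble(df)
}

#' Extract protein annotations from VEP CSQ strings in a VCF
#'
#' Parses the `CSQ` INFO field of a VCF according to the field layout
#' declared in its `##INFO=<ID=CSQ,...>` header line. Only entries that
#' describe an amino-acid substitution (an `Amino_acids` value of the form
#' `X/Y` with a numeric `Protein_position`) are returned; entries without a
#' protein change (intronic, UTR, synonymous) are skipped, since they cannot
#' contribute a residue mismatch.
#'
#' @param vcf_path Path to a VCF file with VEP CSQ annotation.
#' @return An annotation tibble (see [read_annotation_table()]).
#' @export
vcf_annotations <- function(vcf_path) {
  vcf <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  meta <- vcf@meta
  csq_line <- grep("^##INFO=<ID=CSQ", meta, value = TRUE)
  if (length(csq_line) == 0) {
    abort_config(paste0("no CSQ INFO declaration in header of ", vcf_path))
  }
  fmt <- sub('.*Format: *([^">]+).*', "\\1", csq_line[1])
  fields <- strsplit(fmt, "|", fixed = TRUE)[[1]]
  required <- c("Allele", "Consequence", "Gene", "Feature",
                "Protein_position", "Amino_acids")
  missing <- setdiff(required, fields)
  if (length(missing) > 0) {
    abort_config(paste0(
      "CSQ Format in ", vcf_path, " lacks field(s): ",
      paste(missing, collapse = ", ")
    ))
  }

  info <- vcf@fix[, "INFO"]
  csq <- sub(".*(?:^|;)CSQ=([^;]*).*", "\\1", info)
  csq[!grepl("(^|;)CSQ=", info)] <- NA_character_

  rows <- lapply(seq_along(csq), function(i) {
    if (is.na(csq[i])) return(NULL)
    entries <- strsplit(csq[i], ",", fixed = TRUE)[[1]]
    parts <- strsplit(entries, "|", fixed = TRUE)
    ok <- vapply(parts, function(p) length(p) <= length(fields), logical(1))
    if (!all(ok)) {
      abort_data(paste0(
        "malformed CSQ entry at record ", i, ": more values than Format fields"
      ))
    }
    get <- function(p, f) {
      v <- p[match(f, fields)]
      if (is.na(v) || v == "") NA_character_ else v
    }
    out <- lapply(parts, function(p) {
      aas <- get(p, "Amino_acids")
      ppos <- suppressWarnings(as.integer(get(p, "Protein_position")))
      if (is.na(aas) || !grepl("/", aas, fixed = TRUE) || is.na(ppos)) {
        return(NULL)  # no amino-acid change at the protein level
      }
      aa <- strsplit(aas, "/", fixed = TRUE)[[1]]
      # a CSQ Consequence may list several &-joined terms; keep the most severe
      terms <- strsplit(get(p, "Consequence"), "&", fixed = TRUE)[[1]]
      tibble::tibble(
        chrom = as.character(vcf@fix[i, "CHROM"]),
        pos = as.integer(vcf@fix[i, "POS"]),
        ref = as.character(vcf@fix[i, "REF"]),
        alt = get(p, "Allele"),
        gene_id = get(p, "Gene"),
        transcript_id = get(p, "Feature"),
        protein_pos = ppos,
        ref_aa = aa[1],
        alt_aa = aa[2],
        consequence = terms[which.min(severity_rank(terms))]
      )
    })
    dplyr::bind_rows(out)
  })
  dplyr::bind_rows(rows)
}

#' Resolve one transcript per site
#'
#' A variant site annotated on several transcripts must be counted once: the
#' canonical transcript is used when a logical `canonical` column flags one,
#' otherwise the transcript whose most severe consequence at the site ranks
#' highest, with ties broken lexicographically by transcript id.
#'
#' @param annotations An annotation tibble.
#' @return The annotation tibble restricted to the chosen transcript at each
#'   site.
#' @export
resolve_transcripts <- function(annotations) {
  ann <- tibble::as_tibble(annotations)
  if (nrow(ann) == 0) return(ann)
  if (!"canonical" %in% names(ann)) {
    ann$canonical <- FALSE
  }
  ann$canonical[is.na(ann$canonical)] <- FALSE
  ranking <- ann |>
    dplyr::mutate(.rank = severity_rank(.data$consequence)) |>
    dplyr::group_by(.data$chrom, .data$pos, .data$transcript_id) |>
    dplyr::summarise(
      .canon = any(.data$canonical),
      .best = min(.data$.rank),
      .groups = "drop_last"
    ) |>
    dplyr::arrange(
      dplyr::desc(.data$.canon), .data$.best, .data$transcript_id,
      .by_group = TRUE
    ) |>
    dplyr::slice(1) |>
    dplyr::ungroup() |>
    dplyr::select("chrom", "pos", "transcript_id")
  chosen <- dplyr::inner_join(
    ann, ranking, by = c("chrom", "pos", "transcript_id")
  )
  chosen$canonical <- NULL
  chosen
}
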