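#' Read one sample's genotypes from a VCF file
#'
#' Parses a VCF v4.x file (plain or bgzip-compressed) and returns the diploid
#' genotype of one named sample at every record, together with the per-allele
#' read support (`AD`) and the number of distinct read start indices (`RI`)
#' when those FORMAT fields are present. Multiallelic records are preserved
#' with their ordered alternate alleles; missing genotypes (`./.`) are kept as
#' no-calls rather than dropped, so that downstream pairing can distinguish
#' "not called" from "not present in the file".
#'
#' @param vcf_path Path to a VCF file.
#' @param sample_id Name of the sample column to extract.
#' @return A tibble with one row per VCF record and columns `sample_id`,
#'   `chrom`, `pos` (1-based), `ref`, `alt` (comma-separated alternate
#'   alleles, in VCF order), `a1`/`a2` (integer allele indices, 0 = reference;
#'   both `NA` for a no-call), `ad` (comma-separated per-allele depths,
#'   reference first; `NA` if absent) and `ri` (distinct read indices, `NA`
#'   if absent).
#' @export
read_sample_vcf <- function(vcf_path, sample_id) {
  if (!file.exists(vcf_path)) {
    abort_data(paste0("VCF file not found: ", vcf_path))
  }
  vcf <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  samples <- colnames(vcf@gt)[-1]
  if (!sample_id %in% samples) {
    abort_data(paste0(
      "sample '", sample_id, "' not present in ", vcf_path,
      " (samples: ", paste(samples, collapse = ", "), ")"
    ))
  }
  gt <- vcfR::extract.gt(vcf, element = "GT", as.numeric = FALSE)[, sample_id]
  fmt <- strsplit(vcf@gt[, "FORMAT"], ":", fixed = TRUE)
  has_ad <- vapply(fmt, function(f) "AD" %in% f, logical(1))
  has_ri <- vapply(fmt, function(f) "RI" %in% f, logical(1))
  ad <- if (any(has_ad)) {
    vcfR::extract.gt(vcf, element = "AD", as.numeric = FALSE)[, sample_id]
  } else {
    rep(NA_character_, nrow(vcf@fix))
  }
  ri <- if (any(has_ri)) {
    suppressWarnings(as.integer(
      vcfR::extract.gt(vcf, element = "RI", as.numeric = FALSE)[, sample_id]
    ))
  } else {
    rep(NA_integer_, nrow(vcf@fix))
  }

  alleles <- parse_gt_strings(gt)
  tibble::tibble(
    sample_id = sample_id,
    chrom = as.character(vcf@fix[, "CHROM"]),
    pos = as.integer(vcf@fix[, "POS"]),
    ref = as.character(vcf@fix[, "REF"]),
    alt = as.character(vcf@fix[, "ALT"]),
    a1 = alleles$a1,
    a2 = alleles$a2,
    ad = as.character(ad),
    ri = ri
  )
}

# Parse GT strings ("0/1", "1|2", "./.", ".") into two integer allele indices.
# A genotype with any missing allele is treated as a no-call; phase separators
# are ignored because scoring is phase-free.
parse_gt_strings <- function(gt) {
  gt <- as.character(gt)
  parts <- strsplit(gt, "[/|]")
  bad <- !is.na(gt) & !vapply(
    parts, function(p) length(p) %in% c(1L, 2L) && all(grepl("^(\\.|[0-9]+)$", p)),
    logical(1)
  )
  if (any(bad)) {
    abort_data(paste0(
      "malformed GT string at record ", which(bad)[1], ": '", gt[which(bad)[1]], "'"
    ))
  }
  one <- function(p, i) {
    if (is.null(p) || length(p) < i || p[i] == "." || is.na(p[i])) NA_integer_ else as.integer(p[i])
  }
  a1 <- vapply(parts, one, integer(1), i = 1L)
  a2 <- vapply(parts, one, integer(1), i = 2L)
  nocall <- is.na(a1) | is.na(a2)
  a1[nocall] <- NA_integer_
  a2[nocall] <- NA_integer_
  list(a1 = a1, a2 = a2)
}

#' Apply genotype-call quality filters
#'
#' Retains a call only if every non-reference allele it carries has read
#' support of at least `min_support` and the call has at least
#' `min_distinct_read_indices` distinct read indices. Calls failing a
#' threshold are demoted to no-calls (both allele indices set to `NA`), never
#' silently dropped, so site bookkeeping stays intact. Homozygous-reference
#' calls carry no alternate allele and always pass. Calls lacking the support
#' metadata (`ad`/`ri` columns `NA`) are retained unchanged: the filter
#' applies where the caller reported the statistics it thresholds.
#'
#' @param genotypes A sample-genotype tibble from [read_sample_vcf()].
#' @param min_support Minimum read support for each non-reference allele.
#' @param min_distinct_read_indices Minimum number of distinct read indices.
#' @return The same tibble with failing calls demoted to no-calls. The number
#'   of demoted calls is attached as attribute `n_demoted` and reported with
#'   a message.
#' @export
apply_quality_filters <- function(genotypes, min_support = 3,
                                  min_distinct_read_indices = 3) {
  stopifnot(min_support >= 0, min_distinct_read_indices >= 0)
  a1 <- genotypes$a1
  a2 <- genotypes$a2
  called <- !is.na(a1)
  has_alt <- called & (a1 > 0 | a2 > 0)

  ad_list <- strsplit(genotypes$ad, ",", fixed = TRUE)
  alt_support_ok <- vapply(seq_len(nrow(genotypes)), function(i) {
    if (!has_alt[i]) return(TRUE)
    depths <- suppressWarnings(as.integer(ad_list[[i]]))
    if (length(depths) == 0 || all(is.na(depths))) return(TRUE)  # no AD metadata
    idx <- unique(c(a1[i], a2[i]))
    idx <- idx[idx > 0]
    all(!is.na(depths[idx + 1L]) & depths[idx + 1L] >= min_support)
  }, logical(1))

  ri_ok <- !has_alt | is.na(genotypes$ri) | genotypes$ri >= min_distinct_read_indices
  demote <- has_alt & !(alt_support_ok & ri_ok)

  out <- genotypes
  out$a1[demote] <- NA_integer_
  out$a2[demote] <- NA_integer_
  n <- sum(demote)
  if (n > 0) {
    message(n, " genotype call(s) demoted to no-call by quality filters")
  }
  attr(out, "n_demoted") <- n
  out
}

#' Pair donor and recipient genotypes at the amino-acid level
#'
#' Takes the donor's and the recipient's genotype streams, translates each
#' diploid genotype into a multiset of two amino acids via the site
#' annotation (reference allele to the reference residue, each alternate
#' allele to its annotated substituted residue), and joins them site by site.
#' Sites carried by either sample but lacking a protein-level annotation are
#' excluded and tallied. When a site is annotated on several transcripts one
#' transcript is chosen per site (see [resolve_transcripts()]) so that one
#' physical mismatch is never counted twice.
#'
#' Two policies govern sites called in only one sample:
#' * `"require-both"` (default): the site is emitted with its true
#'   `call_status` (`donor-only`, `recipient-only` or `neither`) and the
#'   missing side left `NA`; the scorer skips such sites. Conservative: a
#'   site contributes only when both genotypes were observed, so coverage
#'   asymmetry between capture kits cannot inflate the score.
#' * `"assume-hom-ref"`: the uncalled side is completed as homozygous
#'   reference, the usual assumption for exome data at covered positions.
#'
#' @param donor,recipient Sample-genotype tibbles (see [read_sample_vcf()]).
#' @param annotations An annotation tibble (see [read_annotation_table()] or
#'   [vcf_annotations()]); resolved to one transcript per site internally.
#' @param policy No-call policy, `"require-both"` or `"assume-hom-ref"`.
#' @param pair_id Identifier recorded on every emitted row.
#' @return A tibble with columns `pair_id`, `chrom`, `pos`, `gene_id`,
#'   `transcript_id`, `protein_pos`, `consequence`, `ref_aa`,
#'   `recipient_aa1`, `recipient_aa2`, `donor_aa1`, `donor_aa2` and
#'   `call_status`, ordered by (`chrom`, `pos`). The number of sites dropped
#'   for missing annotation is attached as attribute `n_unannotated`.
#' @export
pair_genotypes <- function(donor, recipient, annotations,
                           policy = c("require-both", "assume-hom-ref"),
                           pair_id = "pair") {
  policy <- match.arg(policy)
  ann <- resolve_transcripts(annotations)

  d <- translate_sample(donor, ann)
  r <- translate_sample(recipient, ann)
  n_unann <- attr(d, "n_unannotated") + attr(r, "n_unannotated")
  if (n_unann > 0) {
    message(n_unann, " site record(s) excluded: no protein-level annotation")
  }

  # One row per site: with several alternate alleles the site-level
  # consequence is the most severe among the chosen transcript's entries.
  site_info <- ann |>
    dplyr::group_by(.data$chrom, .data$pos) |>
    dplyr::summarise(
      gene_id = .data$gene_id[1],
      transcript_id = .data$transcript_id[1],
      protein_pos = .data$protein_pos[1],
      ref_aa = .data$ref_aa[1],
      consequence = .data$consequence[which.min(severity_rank(.data$consequence))],
      .groups = "drop"
    )

  paired <- dplyr::full_join(
    dplyr::select(d, "chrom", "pos", donor_aa1 = "aa1", donor_aa2 = "aa2"),
    dplyr::select(r, "chrom", "pos", recipient_aa1 = "aa1", recipient_aa2 = "aa2"),
    by = c("chrom", "pos")
  )
  paired <- dplyr::inner_join(paired, site_info, by = c("chrom", "pos"))

  donor_called <- !is.na(paired$donor_aa1)
  recip_called <- !is.na(paired$recipient_aa1)
  paired$call_status <- dplyr::case_when(
    donor_called & recip_called ~ "both-called",
    donor_called & !recip_called ~ "donor-only",
    !donor_called & recip_called ~ "recipient-only",
    TRUE ~ "neither"
  )

  if (policy == "assume-hom-ref") {
    fill_d <- paired$call_status == "recipient-only"
    paired$donor_aa1[fill_d] <- paired$ref_aa[fill_d]
    paired$donor_aa2[fill_d] <- paired$ref_aa[fill_d]
    fill_r <- paired$call_status == "donor-only"
    paired$recipient_aa1[fill_r] <- paired$ref_aa[fill_r]
    paired$recipient_aa2[fill_r] <- paired$ref_aa[fill_r]
  }

  out <- dplyr::arrange(
    dplyr::select(
      paired, "chrom", "pos", "gene_id", "transcript_id", "protein_pos",
      "consequence", "ref_aa", "recipient_aa1", "recipient_aa2",
      "donor_aa1", "donor_aa2", "call_status"
    ),
    .data$chrom, .data$pos
  )
  out <- tibble::add_column(out, pair_id = pair_id, .before = 1)
  attr(out, "n_unannotated") <- n_unann
  out
}

# Translate one sample's allele-index genotypes into amino-acid pairs.
# Sites where a carried non-reference allele has no annotated residue are
# dropped (tallied in attribute n_unannotated); uncalled genotypes keep NA
# residues so pairing can classify their call status.
translate_sample <- function(genotypes, ann) {
  alt_map <- setNames(ann$alt_aa, paste(ann$chrom, ann$pos, ann$alt, sep = "\r"))
  site_map <- dplyr::distinct(ann, .data$chrom, .data$pos, .data$ref_aa)
  ref_map <- setNames(site_map$ref_aa, paste(site_map$chrom, site_map$pos, sep = "\r"))

  alts <- strsplit(genotypes$alt, ",", fixed = TRUE)
  site_keys <- paste(genotypes$chrom, genotypes$pos, sep = "\r")
  aa_of <- function(i) {
    idx <- if (i == 1L) genotypes$a1 else genotypes$a2
    res <- rep(NA_character_, length(idx))
    is_ref <- !is.na(idx) & idx == 0L
    res[is_ref] <- unname(ref_map[site_keys[is_ref]])
    is_alt <- which(!is.na(idx) & idx > 0L)
    if (length(is_alt) > 0) {
      allele <- vapply(is_alt, function(j) {
        if (idx[j] <= length(alts[[j]])) alts[[j]][idx[j]] else NA_character_
      }, character(1))
      res[is_alt] <- unname(alt_map[paste(site_keys[is_alt], allele, sep = "\r")])
    }
    res
  }
  out <- tibble::tibble(
    chrom = genotypes$chrom, pos = genotypes$pos,
    called = !is.na(genotypes$a1),
    aa1 = aa_of(1L), aa2 = aa_of(2L)
  )
  # A called genotype translating to NA means a carried allele lacks
  # annotation at a site that is otherwise annotated, or the whole site is
  # unannotated; both are excluded from P.
  bad <- out$called & (is.na(out$aa1) | is.na(out$aa2))
  res <- out[!bad, c("chrom", "pos", "aa1", "aa2")]
  attr(res, "n_unannotated") <- sum(bad)
  res
}

#' Write / read the paired-genotype interchange TSV
#'
#' Plain tab-separated interchange format for paired amino-acid genotypes;
#' the writer and reader round-trip exactly. Lines beginning with `#` are
#' provenance comments.
#'
#' @param paired A paired-genotype tibble from [pair_genotypes()].
#' @param path Output (or input) file path.
#' @param header Optional character vector of provenance comment lines
#'   (written prefixed with `#`).
#' @return `write_paired_tsv()` returns `path` invisibly;
#'   `read_paired_tsv()` returns the tibble.
#' @export
write_paired_tsv <- function(paired, path, header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) {
    writeLines(paste0("# ", header), con)
  }
  cols <- c(
    "pair_id", "chrom", "pos", "gene_id", "transcript_id", "protein_pos",
    "consequence", "ref_aa", "recipient_aa1", "recipient_aa2",
    "donor_aa1", "donor_aa2", "call_status"
  )
  df <- as.data.frame(paired[, cols])
  writeLines(paste(cols, collapse = "\t"), con)
  if (nrow(df) > 0) {
    lines <- do.call(paste, c(lapply(df, function(x) {
      x <- as.character(x)
      x[is.na(x)] <- "."
      x
    }), sep = "\t"))
    writeLines(lines, con)
  }
  invisible(path)
}

#' @rdname write_paired_tsv
#' @export
read_paired_tsv <- function(path) {
  df <- readr::read_tsv(
    path, comment = "#", na = ".", progress = FALSE,
    col_types = readr::cols(
      pair_id = "c", chrom = "c", pos = "i", gene_id = "c",
      transcript_id = "c", protein_pos = "i", consequence = "c",
      ref_aa = "c", recipient_aa1 = "c", recipient_aa2 = "c",
      donor_aa1 = "c", donor_aa2 = "c", call_status = "c"
    )
  )
  tibble::as_tibble(df)
}
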