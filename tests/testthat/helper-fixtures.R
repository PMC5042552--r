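# Shared fixtures: all built in code at test time.

# Independent scoring oracle: literal reading of the per-site definition on
# explicit multisets, kept separate from the vectorised implementation.
oracle_contribution <- function(recipient, donor, mode = "distinct") {
  novel <- donor[!(donor %in% recipient)]
  if (mode == "allele-copy") length(novel) else length(unique(novel))
}

# All unordered two-element genotypes over an alphabet.
genotypes_over <- function(alphabet) {
  idx <- which(upper.tri(diag(length(alphabet)), diag = TRUE), arr.ind = TRUE)
  lapply(seq_len(nrow(idx)), function(i) alphabet[c(idx[i, 1], idx[i, 2])])
}

# Minimal VCF writer for hand-built records. Each record is a list with
# chrom, pos, ref, alt (comma-joined string), and per-sample genotype
# strings like "0/1:10,10:10" (GT:AD:RI) or plain "0/1".
write_test_vcf <- function(path, records, samples, format = "GT:AD:RI",
                           info_header = character()) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=1>",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Per-allele read depth">',
    '##FORMAT=<ID=RI,Number=1,Type=Integer,Description="Distinct read indices">',
    info_header,
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  body <- vapply(records, function(r) {
    info <- if (is.null(r$info)) "." else r$info
    paste(c(r$chrom, r$pos, ".", r$ref, r$alt, ".", "PASS", info, format,
            r$gt), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  path
}

# Annotation tibble builder with sensible defaults.
ann_row <- function(chrom = "1", pos, ref = "A", alt = "G",
                    gene_id = "TMG0001", transcript_id = paste0("T-", gene_id),
                    protein_pos = 100L, ref_aa = "A", alt_aa = "F",
                    consequence = "missense_variant") {
  tibble::tibble(
    chrom = chrom, pos = as.integer(pos), ref = ref, alt = alt,
    gene_id = gene_id, transcript_id = transcript_id,
    protein_pos = as.integer(protein_pos), ref_aa = ref_aa, alt_aa = alt_aa,
    consequence = consequence
  )
}

# Paired-genotype row builder matching the pair_genotypes() schema.
paired_row <- function(pair_id = "pair", chrom = "1", pos,
                       gene_id = "TMG0001", protein_pos = 100L,
                       consequence = "missense_variant", ref_aa = "A",
                       recipient = c("A", "A"), donor = c("A", "A"),
                       call_status = "both-called") {
  tibble::tibble(
    pair_id = pair_id, chrom = chrom, pos = as.integer(pos),
    gene_id = gene_id, transcript_id = paste0("T-", gene_id),
    protein_pos = as.integer(protein_pos), consequence = consequence,
    ref_aa = ref_aa,
    recipient_aa1 = recipient[1], recipient_aa2 = recipient[2],
    donor_aa1 = donor[1], donor_aa2 = donor[2],
    call_status = call_status
  )
}

# Random paired-genotype tibble over a small amino-acid alphabet.
random_paired <- function(n, alphabet = c("A", "F", "D"), n_genes = 5) {
  draw <- function() matrix(sample(alphabet, 2 * n, replace = TRUE), ncol = 2)
  r <- draw(); d <- draw()
  dplyr::bind_rows(lapply(seq_len(n), function(i) {
    paired_row(
      pos = i * 10,
      gene_id = sprintf("TMG%04d", sample.int(n_genes, 1)),
      ref_aa = alphabet[1],
      recipient = r[i, ], donor = d[i, ]
    )
  }))
}
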