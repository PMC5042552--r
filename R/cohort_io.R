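# Serialisation of a synthetic cohort into the file formats the scoring and
# association pipeline consumes: VCF v4.2 genotypes, a side-car annotation
# TSV, a Biomart-style transmembrane gene list, a pair manifest, the clinical
# CSV, a site MAF table and a truth JSON for end-to-end checks.

#' Write a synthetic cohort to disk
#'
#' Writes the complete input bundle for the pipeline. Genotypes are written
#' either as one two-sample VCF per pair (default; both genotypes explicit
#' at any site variant in the pair, so the conservative `require-both`
#' pairing policy sees every genotype) or as two single-sample VCFs per pair
#' containing only that sample's variant sites (in which case scoring must
#' use the `assume-hom-ref` policy to recover sites variant in one sample
#' only). Every text output starts with provenance comment lines recording
#' the generator seed.
#'
#' @param cohort An `ams_cohort` from [simulate_cohort()].
#' @param dir Output directory (created if absent).
#' @param two_sample_vcf One two-sample VCF per pair (default) or two
#'   single-sample VCFs per pair.
#' @return Invisibly, a list of the file paths written: `manifest`,
#'   `annotation`, `tm_genes`, `clinical`, `maf`, `truth`, `vcfs`.
#' @export
write_cohort <- function(cohort, dir, two_sample_vcf = TRUE) {
  stopifnot(inherits(cohort, "ams_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  prov <- paste0("generated by allogenomics simulate, seed=",
                 cohort$params$seed)
  panel <- cohort$panel
  pairs <- cohort$pairs

  vcf_paths <- character(0)
  manifest <- vector("list", nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    pid <- pairs$pair_id[i]
    d <- cohort$donor_counts[, i]
    r <- cohort$recipient_counts[, i]
    if (two_sample_vcf) {
      path <- file.path(dir, paste0(pid, ".vcf"))
      write_pair_vcf(panel, list(d, r), c(paste0(pid, "_D"), paste0(pid, "_R")),
                     path, prov)
      manifest[[i]] <- tibble::tibble(
        pair_id = pid,
        donor_vcf = basename(path), donor_sample = paste0(pid, "_D"),
        recipient_vcf = basename(path), recipient_sample = paste0(pid, "_R")
      )
      vcf_paths <- c(vcf_paths, path)
    } else {
      dpath <- file.path(dir, paste0(pid, "_D.vcf"))
      rpath <- file.path(dir, paste0(pid, "_R.vcf"))
      write_pair_vcf(panel[d > 0, ], list(d[d > 0]), paste0(pid, "_D"), dpath, prov)
      write_pair_vcf(panel[r > 0, ], list(r[r > 0]), paste0(pid, "_R"), rpath, prov)
      manifest[[i]] <- tibble::tibble(
        pair_id = pid,
        donor_vcf = basename(dpath), donor_sample = paste0(pid, "_D"),
        recipient_vcf = basename(rpath), recipient_sample = paste0(pid, "_R")
      )
      vcf_paths <- c(vcf_paths, dpath, rpath)
    }
  }

  manifest_path <- file.path(dir, "manifest.csv")
  write_commented_csv(dplyr::bind_rows(manifest), manifest_path, prov)

  annotation_path <- file.path(dir, "annotation.tsv")
  ann <- dplyr::select(
    panel, "chrom", "pos", "ref", "alt", "gene_id", "transcript_id",
    "protein_pos", "ref_aa", "alt_aa", "consequence"
  )
  write_commented_tsv(ann, annotation_path, prov)

  tm_path <- file.path(dir, "tm_genes.tsv")
  tm_ids <- sort(unique(panel$gene_id[panel$tm_gene]))
  write_commented_tsv(tibble::tibble(gene_id = tm_ids), tm_path, prov)

  clinical_path <- file.path(dir, "clinical.csv")
  write_commented_csv(
    dplyr::select(cohort$clinical, -"egfr_expected"), clinical_path, prov
  )

  maf_path <- file.path(dir, "maf.tsv")
  write_commented_tsv(
    dplyr::select(panel, "chrom", "pos", "maf"), maf_path, prov
  )

  truth_path <- file.path(dir, "truth.json")
  truth <- list(
    seed = cohort$params$seed,
    n_pairs = cohort$params$n_pairs,
    n_sites = cohort$params$n_sites,
    beta = list(
      ams = cohort$params$beta_ams, age = cohort$params$beta_age,
      t = cohort$params$beta_t, hla = cohort$params$beta_hla,
      intercept = cohort$params$intercept
    ),
    pairs = as.data.frame(dplyr::select(
      pairs, "pair_id", "related", "ams_distinct", "ams_allele_copy"
    ))
  )
  jsonlite::write_json(truth, truth_path, auto_unbox = TRUE, digits = NA)

  invisible(list(
    manifest = manifest_path, annotation = annotation_path,
    tm_genes = tm_path, clinical = clinical_path, maf = maf_path,
    truth = truth_path, vcfs = vcf_paths
  ))
}

# Write one VCF with the given samples' alternate-allele counts. Only sites
# variant in at least one of the samples are emitted (a VCF records
# departures from the reference). AD/RI FORMAT fields carry nominal support
# (10 reads per allele copy, 10 distinct read indices) consistent with the
# default quality thresholds.
write_pair_vcf <- function(panel, count_list, sample_names, path, provenance) {
  any_alt <- Reduce(`|`, lapply(count_list, function(x) x > 0))
  keep <- which(any_alt)
  header <- c(
    "##fileformat=VCFv4.2",
    paste0("##source=allogenomics (", provenance, ")"),
    "##contig=<ID=1>",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Per-allele read depth">',
    '##FORMAT=<ID=RI,Number=1,Type=Integer,Description="Distinct read indices">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", sample_names), collapse = "\t")
  )
  gt_field <- function(counts) {
    gt <- c("0/0", "0/1", "1/1")[counts + 1L]
    ad <- paste(10L * (2L - counts), 10L * counts, sep = ",")
    paste(gt, ad, "10", sep = ":")
  }
  fields <- lapply(count_list, function(x) gt_field(x[keep]))
  body <- do.call(paste, c(
    list(panel$chrom[keep], panel$pos[keep], ".", panel$ref[keep],
         panel$alt[keep], ".", "PASS", ".", "GT:AD:RI"),
    fields, sep = "\t"
  ))
  writeLines(c(header, body), path)
  invisible(path)
}

write_commented_tsv <- function(df, path, provenance) {
  writeLines(paste0("# ", provenance), path)
  readr::write_tsv(df, path, append = TRUE, col_names = TRUE, progress = FALSE)
  invisible(path)
}

write_commented_csv <- function(df, path, provenance) {
  writeLines(paste0("# ", provenance), path)
  readr::write_csv(df, path, append = TRUE, col_names = TRUE, progress = FALSE)
  invisible(path)
}
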