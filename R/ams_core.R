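#' Per-site mismatch contribution
#'
#' The contribution of one protein site to the allogenomics mismatch score:
#' the number of amino acids encoded by the donor genotype at that site that
#' do not occur in the recipient genotype. Both genotypes are unordered
#' multisets of exactly two one-letter residues (phase is irrelevant), and
#' the reference residue is an ordinary genotype member — a donor homozygous
#' for the reference at a site where the recipient is homozygous-alternate
#' contributes, because the reference residue is then novel to the recipient.
#'
#' Two counting modes are provided:
#' * `"distinct"` (default): the number of *different* donor amino acids
#'   absent from the recipient; a donor homozygous for one novel residue
#'   contributes 1.
#' * `"allele-copy"`: the number of donor allele *copies* whose residue is
#'   absent from the recipient; the same homozygous-novel donor contributes 2.
#'
#' Either way the result lies in `{0, 1, 2}`, and the score is directional:
#' swapping donor and recipient can change the contribution, since only
#' donor residues novel to the recipient can present non-self epitopes.
#'
#' @param recipient_aas,donor_aas Character vectors of exactly two one-letter
#'   amino acids.
#' @param mode `"distinct"` or `"allele-copy"`.
#' @return Integer contribution in `{0, 1, 2}`.
#' @examples
#' site_contribution(c("A", "A"), c("F", "D"))       # 2
#' site_contribution(c("A", "F"), c("F", "F"))       # 0
#' site_contribution(c("A", "A"), c("F", "F"))       # 1
#' site_contribution(c("A", "A"), c("F", "F"), mode = "allele-copy")  # 2
#' @export
site_contribution <- function(recipient_aas, donor_aas,
                              mode = c("distinct", "allele-copy")) {
  mode <- match.arg(mode)
  if (length(recipient_aas) != 2 || length(donor_aas) != 2 ||
      anyNA(recipient_aas) || anyNA(donor_aas)) {
    abort_contract("genotypes must be multisets of exactly 2 amino acids")
  }
  novel <- !(donor_aas %in% recipient_aas)
  if (mode == "allele-copy") {
    sum(novel)
  } else {
    length(unique(donor_aas[novel]))
  }
}

# Vectorised contribution over paired rows; used by compute_ams. Rows with
# any missing residue yield NA (ineligible call status).
contribution_vec <- function(r1, r2, d1, d2, mode) {
  novel1 <- d1 != r1 & d1 != r2
  novel2 <- d2 != r1 & d2 != r2
  if (mode == "allele-copy") {
    as.integer(novel1) + as.integer(novel2)
  } else {
    as.integer(novel1) + as.integer(novel2 & d2 != d1)
  }
}

#' Compute the allogenomics mismatch score for one pair
#'
#' Sums per-site mismatch contributions across all sites of the panel P to
#' yield the pair's allogenomics mismatch score. Only sites where both the
#' donor and the recipient genotype are available are scored; sites with an
#' ineligible call status are counted in `n_sites_skipped` but contribute
#' nothing (under the `assume-hom-ref` pairing policy such sites have been
#' completed upstream and are eligible).
#'
#' @param paired_sites A paired-genotype tibble restricted to the panel
#'   (e.g. the `sites` element of a [build_panel()] result, or a
#'   `site_panel` object itself).
#' @param pair_id Pair identifier recorded on the result; defaults to the
#'   `pair_id` of the first row.
#' @param mode Contribution counting mode, see [site_contribution()].
#' @return An object of class `ams_result`: list with `pair_id`, `total`,
#'   `n_sites_considered`, `n_sites_contributing`, `n_sites_skipped`,
#'   `per_site` (tibble ordered by chrom/pos with a `contribution` column),
#'   `per_gene` (tibble of summed contributions per gene) and `mode`.
#' @export
compute_ams <- function(paired_sites, pair_id = NULL,
                        mode = c("distinct", "allele-copy")) {
  mode <- match.arg(mode)
  if (inherits(paired_sites, "site_panel")) {
    paired_sites <- paired_sites$sites
  }
  if (is.null(pair_id)) {
    pair_id <- if (nrow(paired_sites) > 0) paired_sites$pair_id[1] else "pair"
  }
  if (nrow(paired_sites) == 0) {
    warn("empty site panel: score is 0 but uninformative")
  }

  eligible <- !is.na(paired_sites$recipient_aa1) &
    !is.na(paired_sites$recipient_aa2) &
    !is.na(paired_sites$donor_aa1) & !is.na(paired_sites$donor_aa2)
  scored <- dplyr::arrange(paired_sites[eligible, ], .data$chrom, .data$pos)

  contrib <- contribution_vec(
    scored$recipient_aa1, scored$recipient_aa2,
    scored$donor_aa1, scored$donor_aa2, mode
  )
  per_site <- scored |>
    dplyr::mutate(contribution = contrib) |>
    dplyr::select(
      "chrom", "pos", "gene_id", "protein_pos", "recipient_aa1",
      "recipient_aa2", "donor_aa1", "donor_aa2", "contribution"
    )
  per_gene <- per_site |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(contribution = sum(.data$contribution), .groups = "drop") |>
    dplyr::arrange(.data$gene_id)

  structure(
    list(
      pair_id = pair_id,
      total = sum(contrib),
      n_sites_considered = nrow(scored),
      n_sites_contributing = sum(contrib > 0),
      n_sites_skipped = sum(!eligible),
      per_site = per_site,
      per_gene = per_gene,
      mode = mode
    ),
    class = "ams_result"
  )
}

#' @export
print.ams_result <- function(x, ...) {
  cat("Allogenomics mismatch score for pair '", x$pair_id, "'\n", sep = "")
  cat("  total: ", x$total, " (mode: ", x$mode, ")\n", sep = "")
  cat("  sites considered: ", x$n_sites_considered,
      ", contributing: ", x$n_sites_contributing,
      ", skipped (call status): ", x$n_sites_skipped, "\n", sep = "")
  invisible(x)
}

#' Minor-allele-frequency summary of contributing sites
#'
#' Restricts a population MAF table to the sites that actually contribute to
#' a pair's score (contribution > 0), for assessing how rare the
#' score-driving polymorphisms are. Sites missing from the table are tallied,
#' not fatal.
#'
#' @param result An `ams_result` from [compute_ams()].
#' @param maf_table A tibble with columns `chrom`, `pos` and `maf`
#'   (population minor allele frequency, in `[0, 0.5]`).
#' @param breaks Histogram break points over `[0, 0.5]`.
#' @return A list of class `maf_summary` with `site_mafs` (tibble: chrom,
#'   pos, contribution, maf), `histogram` (tibble: bin, count), `n_missing`
#'   and `median_maf`.
#' @export
maf_summary <- function(result, maf_table,
                        breaks = c(0, 0.001, 0.005, 0.01, 0.05, 0.1, 0.25, 0.5)) {
  stopifnot(inherits(result, "ams_result"))
  if (any(maf_table$maf < 0 | maf_table$maf > 0.5, na.rm = TRUE)) {
    abort_data("minor allele frequencies must lie in [0, 0.5]")
  }
  contributing <- result$per_site[result$per_site$contribution > 0, ]
  merged <- dplyr::left_join(
    dplyr::select(contributing, "chrom", "pos", "contribution"),
    dplyr::select(maf_table, "chrom", "pos", "maf"),
    by = c("chrom", "pos")
  )
  known <- merged[!is.na(merged$maf), ]
  hist_counts <- if (nrow(known) > 0) {
    cut_bins <- cut(known$maf, breaks = breaks, include.lowest = TRUE)
    tibble::tibble(bin = levels(cut_bins),
                   count = as.integer(table(cut_bins)))
  } else {
    tibble::tibble(bin = character(), count = integer())
  }
  structure(
    list(
      site_mafs = merged,
      histogram = hist_counts,
      n_missing = sum(is.na(merged$maf)),
      median_maf = if (nrow(known) > 0) median(known$maf) else NA_real_
    ),
    class = "maf_summary"
  )
}

#' @export
print.maf_summary <- function(x, ...) {
  cat("MAF summary over", nrow(x$site_mafs), "contributing site(s)\n")
  cat("  median MAF:", format(x$median_maf, digits = 3),
      "| sites without MAF:", x$n_missing, "\n")
  invisible(x)
}
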