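#' Parameters for the synthetic transplant-cohort generator
#'
#' Bundles and validates the generator truths: panel size and allele
#' frequency spectrum, the fraction of parent-child (haplotype-sharing)
#' donor/recipient pairs, the fixed-effect coefficients of the generating
#' eGFR model, variance components, and the observation schedule.
#'
#' Defaults describe the study conditions the package targets: 53 pairs
#' observed at up to five timepoints (~239 eGFR measurements), a panel of
#' 13,000 scoreable missense sites in transmembrane genes with a rare-skewed
#' allele-frequency spectrum (Beta(0.2, 2) truncated to (0.0005, 0.5)), 60%
#' related pairs, and fixed effects `beta_ams = -0.01307` (eGFR units per
#' score unit), `beta_age = -0.47`, `beta_t = -0.24`, `beta_hla = -0.57`.
#' The variance components (`sigma_pair = 12`, `sigma_resid = 8`
#' mL/min/1.73 m2) and the intercept (101, placing mean eGFR near 55 at mean
#' covariates) are generator calibration values, not estimates.
#'
#' @param n_pairs Number of donor/recipient pairs (>= 2).
#' @param n_sites Number of scoreable (missense, transmembrane-gene) sites.
#' @param decoy_fraction Extra non-scoreable sites written alongside the
#'   panel (half missense in non-transmembrane genes, half synonymous in
#'   transmembrane genes) so that site selection has real work to do.
#' @param maf_shape1,maf_shape2 Beta shape parameters of the allele-frequency
#'   spectrum.
#' @param maf_min,maf_max Truncation bounds for the spectrum, in (0, 0.5].
#' @param fraction_related Proportion of parent-child pairs.
#' @param beta_ams,beta_age,beta_t,beta_hla,intercept Fixed effects of the
#'   generating model.
#' @param sigma_pair,sigma_resid Random-intercept and residual SDs.
#' @param timepoints Months post-transplant at which eGFR may be observed.
#' @param obs_prob Probability that a scheduled observation is present.
#' @param seed Integer seed; regenerating with the same seed reproduces the
#'   cohort bit-for-bit.
#' @return A validated list of class `sim_params`.
#' @export
sim_params <- function(n_pairs = 53,
                       n_sites = 13000,
                       decoy_fraction = 0.1,
                       maf_shape1 = 0.2,
                       maf_shape2 = 2,
                       maf_min = 5e-4,
                       maf_max = 0.5,
                       fraction_related = 0.6,
                       beta_ams = -0.01307,
                       beta_age = -0.47,
                       beta_t = -0.24,
                       beta_hla = -0.57,
                       intercept = 101,
                       sigma_pair = 12,
                       sigma_resid = 8,
                       timepoints = c(12, 24, 36, 48, 60),
                       obs_prob = 0.9,
                       seed = 1L) {
  p <- list(
    n_pairs = as.integer(n_pairs), n_sites = as.integer(n_sites),
    decoy_fraction = decoy_fraction, maf_shape1 = maf_shape1,
    maf_shape2 = maf_shape2, maf_min = maf_min, maf_max = maf_max,
    fraction_related = fraction_related, beta_ams = beta_ams,
    beta_age = beta_age, beta_t = beta_t, beta_hla = beta_hla,
    intercept = intercept, sigma_pair = sigma_pair,
    sigma_resid = sigma_resid, timepoints = timepoints,
    obs_prob = obs_prob, seed = as.integer(seed)
  )
  validate_sim_params(p)
  structure(p, class = "sim_params")
}

validate_sim_params <- function(p) {
  check <- function(ok, field, why) {
    if (!ok) abort_config(paste0("invalid simulation parameter '", field, "': ", why))
  }
  check(p$n_pairs >= 2, "n_pairs", "need at least 2 pairs (mixed model unfittable otherwise)")
  check(p$n_sites >= 1, "n_sites", "need at least 1 site")
  check(p$decoy_fraction >= 0, "decoy_fraction", "must be >= 0")
  check(p$maf_min > 0 && p$maf_max <= 0.5 && p$maf_min < p$maf_max,
        "maf_min/maf_max", "must satisfy 0 < maf_min < maf_max <= 0.5")
  check(p$fraction_related >= 0 && p$fraction_related <= 1,
        "fraction_related", "must lie in [0, 1]")
  check(p$sigma_pair >= 0, "sigma_pair", "must be >= 0")
  check(p$sigma_resid >= 0, "sigma_resid", "must be >= 0")
  check(length(p$timepoints) >= 1 && all(p$timepoints >= 0),
        "timepoints", "must be non-negative months")
  check(p$obs_prob > 0 && p$obs_prob <= 1, "obs_prob", "must lie in (0, 1]")
  invisible(p)
}

AA_LETTERS <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' Simulate a site panel
#'
#' Draws the synthetic site panel: `n_sites` missense sites assigned to
#' synthetic transmembrane genes, each with a minor allele frequency from
#' the rare-skewed spectrum, a reference/alternate nucleotide pair and a
#' reference/alternate amino-acid pair. A further `decoy_fraction` of sites
#' is added that the site-selection step must reject: missense sites in
#' non-transmembrane genes and synonymous sites in transmembrane genes.
#' Consumes the caller's RNG stream; seed management is done by
#' [simulate_cohort()].
#'
#' @param params A [sim_params()] object.
#' @return A tibble with columns `chrom`, `pos`, `ref`, `alt`, `gene_id`,
#'   `transcript_id`, `protein_pos`, `ref_aa`, `alt_aa`, `consequence`,
#'   `maf`, `tm_gene` (gene has a transmembrane segment) and `in_panel`
#'   (site belongs to the scoreable set P).
#' @export
simulate_panel <- function(params) {
  n <- params$n_sites
  n_decoy <- round(params$decoy_fraction * n)
  n_total <- n + n_decoy
  n_tm_genes <- max(1L, ceiling(n / 13))

  maf <- draw_maf(n_total, params)
  nt <- c("A", "C", "G", "T")
  ref <- sample(nt, n_total, replace = TRUE)
  # alternate drawn as a cyclic offset from the reference: uniform over the
  # other letters without a per-site sample() call
  alt <- nt[(match(ref, nt) - 1L + sample.int(3L, n_total, replace = TRUE)) %% 4L + 1L]
  ref_aa <- sample(AA_LETTERS, n_total, replace = TRUE)
  alt_aa <- AA_LETTERS[
    (match(ref_aa, AA_LETTERS) - 1L +
       sample.int(19L, n_total, replace = TRUE)) %% 20L + 1L
  ]

  # decoys: first half in non-TM genes (missense), second half synonymous
  n_nontm <- if (n_decoy > 0) ceiling(n_decoy / 2) else 0L
  type <- c(rep("panel", n), rep("nontm", n_nontm),
            rep("synon", n_decoy - n_nontm))
  type <- sample(type)  # interleave along the chromosome

  gene_id <- character(n_total)
  is_nontm <- type == "nontm"
  gene_id[!is_nontm] <- sprintf(
    "TMG%04d", sample.int(n_tm_genes, sum(!is_nontm), replace = TRUE)
  )
  n_cy_genes <- max(1L, ceiling(max(1L, n_nontm) / 13))
  gene_id[is_nontm] <- sprintf(
    "CYG%04d", sample.int(n_cy_genes, sum(is_nontm), replace = TRUE)
  )
  is_syn <- type == "synon"
  alt_aa[is_syn] <- ref_aa[is_syn]

  tibble::tibble(
    chrom = "1",
    pos = seq_len(n_total) * 100L,
    ref = ref,
    alt = alt,
    gene_id = gene_id,
    transcript_id = paste0("T-", gene_id),
    protein_pos = sample.int(500L, n_total, replace = TRUE),
    ref_aa = ref_aa,
    alt_aa = alt_aa,
    consequence = ifelse(is_syn, "synonymous_variant", "missense_variant"),
    maf = maf,
    tm_gene = !is_nontm,
    in_panel = type == "panel"
  )
}

draw_maf <- function(n, params) {
  # inverse-CDF draw from the truncated Beta spectrum: deterministic in the
  # number of RNG calls, unlike rejection sampling
  lo <- stats::pbeta(params$maf_min, params$maf_shape1, params$maf_shape2)
  hi <- stats::pbeta(params$maf_max, params$maf_shape1, params$maf_shape2)
  stats::qbeta(runif(n, lo, hi), params$maf_shape1, params$maf_shape2)
}

#' Simulate one donor/recipient genotype pair
#'
#' Draws diploid genotypes for a donor and a recipient over the panel sites.
#' Unrelated pairs: all four haplotypes drawn independently under
#' Hardy-Weinberg equilibrium at each site's allele frequency. Related
#' (parent-child) pairs: the recipient inherits one allele identical by
#' descent from the donor at every site (the transmitted haplotype samples
#' either donor haplotype per site, as free recombination would), and the
#' other haplotype is drawn from the population frequencies.
#'
#' @param panel A panel tibble from [simulate_panel()].
#' @param related Logical: parent-child pair?
#' @return A list with `donor` and `recipient`, each an integer matrix of
#'   `nrow(panel)` rows and 2 haplotype columns (0 = reference allele,
#'   1 = alternate allele).
#' @export
simulate_pair <- function(panel, related = FALSE) {
  n <- nrow(panel)
  p <- panel$maf
  d1 <- rbinom(n, 1, p)
  d2 <- rbinom(n, 1, p)
  if (related) {
    pick <- rbinom(n, 1, 0.5)
    r1 <- ifelse(pick == 1L, d1, d2)
  } else {
    r1 <- rbinom(n, 1, p)
  }
  r2 <- rbinom(n, 1, p)
  list(
    donor = cbind(h1 = d1, h2 = d2),
    recipient = cbind(h1 = r1, h2 = r2)
  )
}

# Per-site contribution from alternate-allele counts at a biallelic site with
# ref_aa != alt_aa. Rows: recipient count 0..2; columns: donor count 0..2.
CONTRIB_BY_COUNTS <- list(
  distinct = matrix(c(
    0L, 1L, 1L,
    0L, 0L, 0L,
    1L, 1L, 0L
  ), nrow = 3, byrow = TRUE),
  `allele-copy` = matrix(c(
    0L, 1L, 2L,
    0L, 0L, 0L,
    2L, 1L, 0L
  ), nrow = 3, byrow = TRUE)
)

ams_from_counts <- function(recipient_counts, donor_counts, mode, site_mask) {
  lut <- CONTRIB_BY_COUNTS[[mode]]
  r <- recipient_counts[site_mask]
  d <- donor_counts[site_mask]
  sum(lut[cbind(r + 1L, d + 1L)])
}

#' Simulate a full synthetic transplant cohort
#'
#' Generates the complete study material for one cohort: the site panel,
#' paired diploid genotypes for every donor/recipient pair (with the
#' configured fraction of parent-child pairs), clinical covariates, and
#' longitudinal eGFR observations drawn from the generating mixed model
#'
#' `eGFR = intercept + beta_age * donor_age + beta_ams * AMS +
#'  beta_t * months + beta_hla * HLA + b_pair + eps`,
#'
#' with `b_pair ~ N(0, sigma_pair^2)` and `eps ~ N(0, sigma_resid^2)`. The
#' AMS entering the model is the pair's true score in `distinct` mode,
#' tallied directly from the generated genotypes over the panel sites; the
#' `allele-copy` tally is recorded alongside. Donor ages are drawn from a
#' normal distribution (mean 45, SD 12) truncated to 18-75 years; HLA-ABDR
#' mismatch counts uniformly from 0-6. A serum creatinine consistent with
#' each observed eGFR (by inverting the MDRD equation at the recipient's age
#' at observation) is included so the clinical table exercises the eGFR
#' computation path.
#'
#' All randomness comes from `params$seed`: the same parameters reproduce
#' the cohort exactly.
#'
#' @param params A [sim_params()] object.
#' @return An object of class `ams_cohort`: list with `params`, `panel`,
#'   `donor_counts` / `recipient_counts` (site x pair matrices of
#'   alternate-allele counts), `pairs` (tibble: pair_id, related,
#'   ams_distinct, ams_allele_copy, donor_age, hla_abdr, recipient_sex,
#'   recipient_race, recipient_age, b_pair) and `clinical` (tibble with one
#'   row per observation, including the noiseless fixed-effect eGFR
#'   `egfr_expected`).
#' @export
simulate_cohort <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  set.seed(params$seed)

  panel <- simulate_panel(params)
  n_pairs <- params$n_pairs
  pair_ids <- sprintf("P%03d", seq_len(n_pairs))

  n_rel <- round(params$fraction_related * n_pairs)
  related <- sample(c(rep(TRUE, n_rel), rep(FALSE, n_pairs - n_rel)))

  n_sites_total <- nrow(panel)
  donor_counts <- matrix(0L, n_sites_total, n_pairs)
  recipient_counts <- matrix(0L, n_sites_total, n_pairs)
  ams_distinct <- integer(n_pairs)
  ams_copy <- integer(n_pairs)
  for (i in seq_len(n_pairs)) {
    g <- simulate_pair(panel, related = related[i])
    donor_counts[, i] <- g$donor[, 1] + g$donor[, 2]
    recipient_counts[, i] <- g$recipient[, 1] + g$recipient[, 2]
    ams_distinct[i] <- ams_from_counts(
      recipient_counts[, i], donor_counts[, i], "distinct", panel$in_panel
    )
    ams_copy[i] <- ams_from_counts(
      recipient_counts[, i], donor_counts[, i], "allele-copy", panel$in_panel
    )
  }

  donor_age <- rnorm_trunc(n_pairs, 45, 12, 18, 75)
  recipient_age <- rnorm_trunc(n_pairs, 48, 12, 18, 75)
  hla <- sample(0:6, n_pairs, replace = TRUE)
  recipient_sex <- sample(c("male", "female"), n_pairs, replace = TRUE)
  recipient_race <- sample(c("black", "non-black"), n_pairs,
                           replace = TRUE, prob = c(0.25, 0.75))
  b_pair <- rnorm(n_pairs, 0, params$sigma_pair)

  pairs <- tibble::tibble(
    pair_id = pair_ids,
    related = related,
    ams_distinct = ams_distinct,
    ams_allele_copy = ams_copy,
    donor_age = donor_age,
    hla_abdr = hla,
    recipient_sex = recipient_sex,
    recipient_race = recipient_race,
    recipient_age = recipient_age,
    b_pair = b_pair
  )

  obs <- tidyr::expand_grid(pair_id = pair_ids, months = params$timepoints)
  obs <- dplyr::inner_join(obs, pairs, by = "pair_id")
  keep <- rbinom(nrow(obs), 1, params$obs_prob) == 1L
  obs <- obs[keep, ]
  obs$egfr_expected <- params$intercept +
    params$beta_age * obs$donor_age +
    params$beta_ams * obs$ams_distinct +
    params$beta_t * obs$months +
    params$beta_hla * obs$hla_abdr
  obs$egfr <- obs$egfr_expected + obs$b_pair +
    rnorm(nrow(obs), 0, params$sigma_resid)
  obs$serum_creatinine <- ifelse(
    obs$egfr > 1,
    mdrd_invert(obs$egfr, obs$recipient_age + obs$months / 12,
                female = obs$recipient_sex == "female",
                black = obs$recipient_race == "black"),
    NA_real_
  )

  clinical <- dplyr::select(
    obs, "pair_id", "months", "donor_age", "hla_abdr", "recipient_sex",
    "recipient_race", "recipient_age", "serum_creatinine", "egfr",
    "egfr_expected"
  )

  structure(
    list(
      params = params,
      panel = panel,
      donor_counts = donor_counts,
      recipient_counts = recipient_counts,
      pairs = pairs,
      clinical = clinical
    ),
    class = "ams_cohort"
  )
}

rnorm_trunc <- function(n, mean, sd, lower, upper) {
  # inverse-CDF truncation: one uniform draw per value, reproducible
  lo <- stats::pnorm(lower, mean, sd)
  hi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(runif(n, lo, hi), mean, sd)
}

#' @export
print.ams_cohort <- function(x, ...) {
  cat("Synthetic transplant cohort:", x$params$n_pairs, "pairs,",
      sum(x$panel$in_panel), "panel sites (+",
      sum(!x$panel$in_panel), "decoys),",
      nrow(x$clinical), "eGFR observations\n")
  cat("  related pairs:", sum(x$pairs$related),
      "| mean AMS (distinct):", round(mean(x$pairs$ams_distinct), 1), "\n")
  invisible(x)
}

#' True mismatch scores of a synthetic cohort
#'
#' The generator's own per-pair score tally, as a tibble ready to join with
#' the clinical table in the model-fitting functions.
#'
#' @param cohort An `ams_cohort` from [simulate_cohort()].
#' @param mode Scoring mode the tally was made under.
#' @return A tibble with columns `pair_id` and `ams`.
#' @export
truth_scores <- function(cohort, mode = c("distinct", "allele-copy")) {
  mode <- match.arg(mode)
  col <- if (mode == "distinct") "ams_distinct" else "ams_allele_copy"
  tibble::tibble(pair_id = cohort$pairs$pair_id, ams = cohort$pairs[[col]])
}
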