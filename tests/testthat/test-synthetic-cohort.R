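test_that("simulation parameters are validated field by field", {
  expect_s3_class(sim_params(), "sim_params")
  expect_error(sim_params(n_pairs = 1), class = "allogenomics_config_error")
  expect_error(sim_params(sigma_pair = -1), class = "allogenomics_config_error")
  expect_error(sim_params(maf_min = 0), class = "allogenomics_config_error")
  expect_error(sim_params(maf_max = 0.7), class = "allogenomics_config_error")
  expect_error(sim_params(fraction_related = 1.5),
               class = "allogenomics_config_error")
  expect_error(sim_params(obs_prob = 0), class = "allogenomics_config_error")
})

test_that("the same seed reproduces the cohort bit-for-bit", {
  p <- sim_params(n_pairs = 6, n_sites = 300, seed = 99)
  a <- simulate_cohort(p)
  b <- simulate_cohort(p)
  expect_identical(a$panel, b$panel)
  expect_identical(a$donor_counts, b$donor_counts)
  expect_identical(a$recipient_counts, b$recipient_counts)
  expect_identical(a$pairs, b$pairs)
  expect_identical(a$clinical, b$clinical)

  c <- simulate_cohort(sim_params(n_pairs = 6, n_sites = 300, seed = 100))
  expect_false(identical(a$clinical$egfr, c$clinical$egfr))
})

test_that("the allele-frequency spectrum is rare-skewed and bounded", {
  set.seed(1)
  panel <- simulate_panel(sim_params(n_sites = 10000, decoy_fraction = 0))
  expect_true(all(panel$maf > 0 & panel$maf <= 0.5))
  expect_lt(median(panel$maf), 0.05)
})

test_that("panel composition separates scoreable sites from decoys", {
  set.seed(2)
  p <- sim_params(n_sites = 1000, decoy_fraction = 0.2)
  panel <- simulate_panel(p)
  expect_equal(sum(panel$in_panel), 1000)
  expect_equal(nrow(panel), 1200)
  expect_true(all(panel$consequence[panel$in_panel] == "missense_variant"))
  expect_true(all(panel$tm_gene[panel$in_panel]))
  # decoys are either non-TM missense or TM synonymous, never scoreable
  decoys <- panel[!panel$in_panel, ]
  expect_true(all(!decoys$tm_gene | decoys$consequence == "synonymous_variant"))
  # missense sites always change the residue; synonymous never do
  expect_true(all((panel$ref_aa != panel$alt_aa) ==
                    (panel$consequence == "missense_variant")))
})

test_that("related pairs share at least one allele at every site", {
  set.seed(3)
  panel <- simulate_panel(sim_params(n_sites = 2000, decoy_fraction = 0))
  g <- simulate_pair(panel, related = TRUE)
  shares <- vapply(seq_len(nrow(panel)), function(i) {
    any(g$recipient[i, ] %in% g$donor[i, ]) ||
      any(g$donor[i, ] %in% g$recipient[i, ])
  }, logical(1))
  # the IBD haplotype guarantees a shared allele value at every site
  ibd_ok <- vapply(seq_len(nrow(panel)), function(i) {
    g$recipient[i, 1] %in% g$donor[i, ]
  }, logical(1))
  expect_true(all(ibd_ok))
  expect_true(all(shares))
})

test_that("a monomorphic site yields homozygous-reference genotypes always", {
  panel <- tibble::tibble(maf = rep(0, 50))
  g <- simulate_pair(panel, related = FALSE)
  expect_true(all(g$donor == 0) && all(g$recipient == 0))
})

test_that("genotype frequencies follow Hardy-Weinberg expectations", {
  set.seed(4)
  maf <- 0.3
  panel <- tibble::tibble(maf = rep(maf, 1))
  counts <- replicate(2000, {
    g <- simulate_pair(panel[rep(1, 1), ], related = FALSE)
    sum(g$donor[1, ])
  })
  freq <- table(factor(counts, levels = 0:2)) / 2000
  expected <- c((1 - maf)^2, 2 * maf * (1 - maf), maf^2)
  chisq <- suppressWarnings(stats::chisq.test(table(factor(counts, levels = 0:2)),
                                              p = expected))
  expect_gt(chisq$p.value, 0.001)
})

test_that("mean per-site contribution matches the closed-form HWE enumeration", {
  # enumeration over the 9 recipient/donor genotype-count combinations
  expected_contrib <- function(p, mode = "distinct") {
    probs <- c((1 - p)^2, 2 * p * (1 - p), p^2)
    lut <- if (mode == "distinct") {
      rbind(c(0, 1, 1), c(0, 0, 0), c(1, 1, 0))
    } else {
      rbind(c(0, 1, 2), c(0, 0, 0), c(2, 1, 0))
    }
    sum(outer(probs, probs) * lut)
  }
  set.seed(5)
  p <- 0.2
  n <- 40000
  panel <- tibble::tibble(maf = rep(p, n))
  g <- simulate_pair(panel, related = FALSE)
  r <- g$recipient[, 1] + g$recipient[, 2]
  d <- g$donor[, 1] + g$donor[, 2]
  lut <- rbind(c(0, 1, 1), c(0, 0, 0), c(1, 1, 0))
  mc <- mean(lut[cbind(r + 1, d + 1)])
  expect_equal(mc, expected_contrib(p), tolerance = 0.05)
})

test_that("observed eGFR decomposes into fixed effects, pair intercept and noise", {
  p <- sim_params(n_pairs = 10, n_sites = 200, seed = 6)
  co <- simulate_cohort(p)
  cl <- dplyr::inner_join(co$clinical,
                          dplyr::select(co$pairs, pair_id, b_pair, ams_distinct),
                          by = "pair_id")
  fixed <- p$intercept + p$beta_age * cl$donor_age +
    p$beta_ams * cl$ams_distinct + p$beta_t * cl$months +
    p$beta_hla * cl$hla_abdr
  expect_equal(cl$egfr_expected, fixed)
  resid <- cl$egfr - cl$egfr_expected - cl$b_pair
  expect_lt(max(abs(resid)), 5 * p$sigma_resid)
  # creatinine is consistent with the recorded eGFR under the MDRD equation
  ok <- !is.na(cl$serum_creatinine)
  back <- egfr_mdrd(cl$serum_creatinine[ok],
                    cl$recipient_age[ok] + cl$months[ok] / 12,
                    female = cl$recipient_sex[ok] == "female",
                    black = cl$recipient_race[ok] == "black")
  expect_equal(back, cl$egfr[ok], tolerance = 1e-8)
})

test_that("pipeline scores on written VCFs equal the generator truth", {
  p <- sim_params(n_pairs = 5, n_sites = 250, seed = 8)
  co <- simulate_cohort(p)

  # two-sample VCFs under the conservative require-both policy
  dir2 <- withr::local_tempdir()
  suppressMessages(write_cohort(co, dir2, two_sample_vcf = TRUE))
  for (mode in c("distinct", "allele-copy")) {
    scores <- suppressMessages(cmd_score(
      file.path(dir2, "manifest.csv"), dir2, file.path(dir2, "tm_genes.tsv"),
      annotation_path = file.path(dir2, "annotation.tsv"),
      mode = mode, out_dir = file.path(dir2, "out")
    ))
    truth <- truth_scores(co, mode = mode)
    merged <- dplyr::inner_join(scores, truth, by = "pair_id",
                                suffix = c("_pipe", "_truth"))
    expect_equal(merged$ams_pipe, merged$ams_truth)
  }

  # single-sample VCFs only list each sample's variant sites, so sites
  # variant in one sample alone need the assume-hom-ref completion
  dir1 <- withr::local_tempdir()
  suppressMessages(write_cohort(co, dir1, two_sample_vcf = FALSE))
  scores1 <- suppressMessages(cmd_score(
    file.path(dir1, "manifest.csv"), dir1, file.path(dir1, "tm_genes.tsv"),
    annotation_path = file.path(dir1, "annotation.tsv"),
    policy = "assume-hom-ref", out_dir = file.path(dir1, "out")
  ))
  merged1 <- dplyr::inner_join(scores1, truth_scores(co), by = "pair_id",
                               suffix = c("_pipe", "_truth"))
  expect_equal(merged1$ams_pipe, merged1$ams_truth)
})

test_that("related pairs score lower than unrelated pairs on the same panel", {
  co <- simulate_cohort(sim_params(n_pairs = 40, n_sites = 2000,
                                   fraction_related = 0.5, seed = 9))
  rel <- co$pairs$ams_distinct[co$pairs$related]
  unrel <- co$pairs$ams_distinct[!co$pairs$related]
  expect_lt(mean(rel), mean(unrel))
})
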