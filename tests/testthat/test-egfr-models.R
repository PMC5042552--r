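test_that("the MDRD equation reproduces hand-computed values and scalings", {
  # 175 * 1.0^-1.154 * 50^-0.203, male, non-black
  expect_equal(egfr_mdrd(1.0, 50, female = FALSE, black = FALSE),
               79.0947, tolerance = 1e-5)
  # power-law in creatinine: doubling scr scales by 2^-1.154
  expect_equal(egfr_mdrd(2.0, 50) / egfr_mdrd(1.0, 50), 2^-1.154)
  # demographic factors are exact multipliers
  expect_equal(
    egfr_mdrd(1.3, 47, female = TRUE, black = TRUE),
    egfr_mdrd(1.3, 47) * 0.742 * 1.212
  )
  # strictly decreasing in creatinine and age
  scr <- seq(0.5, 5, by = 0.5)
  expect_true(all(diff(egfr_mdrd(scr, 50)) < 0))
  ages <- seq(20, 80, by = 5)
  expect_true(all(diff(egfr_mdrd(1.2, ages)) < 0))
  expect_error(egfr_mdrd(0, 50), class = "allogenomics_contract_error")
  expect_error(egfr_mdrd(1, -3), class = "allogenomics_contract_error")
})

test_that("clinical tables compute eGFR from creatinine only when absent", {
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(tibble::tibble(
    pair_id = c("p1", "p2"), months = c(12, 12), donor_age = c(40, 50),
    hla_abdr = c(3, 4),
    recipient_sex = c("male", "female"),
    recipient_race = c("non-black", "black"),
    recipient_age = c(49, 39),
    serum_creatinine = c(1.0, 1.2),
    egfr = c(NA, 88)
  ), path)
  cl <- read_clinical(path)
  expect_equal(cl$egfr[1],
               egfr_mdrd(1.0, 50, female = FALSE, black = FALSE))
  expect_equal(cl$egfr[2], 88)  # provided value untouched
})

test_that("a noiseless linear relationship is recovered exactly cross-sectionally", {
  scores <- tibble::tibble(pair_id = paste0("p", 1:10), ams = c(1:10) * 100)
  clinical <- tibble::tibble(
    pair_id = scores$pair_id, months = 36, donor_age = 45,
    egfr = 2 * scores$ams
  )
  fit <- suppressWarnings(fit_cross_sectional(scores, clinical, month = 36))
  expect_equal(fit$slope, 2)
  expect_equal(fit$adj_r_squared, 1)
  expect_equal(fit$n, 10)

  const <- dplyr::mutate(scores, ams = 500)
  expect_error(fit_cross_sectional(const, clinical, month = 36),
               class = "allogenomics_model_error")
  expect_error(fit_cross_sectional(scores, clinical, month = 99),
               class = "allogenomics_data_error")
})

test_that("cross-sectional p-values are uniform under permutation of the score", {
  set.seed(202)
  n <- 100
  scores <- tibble::tibble(pair_id = paste0("p", 1:n), ams = rnorm(n, 1000, 300))
  y <- rnorm(n, 55, 15)
  pvals <- vapply(1:200, function(i) {
    cl <- tibble::tibble(pair_id = sample(scores$pair_id), months = 12,
                         donor_age = 45, egfr = y)
    fit_cross_sectional(scores, cl, month = 12)$p_value
  }, numeric(1))
  expect_gt(suppressWarnings(stats::ks.test(pvals, "punif"))$p.value, 0.01)
})

test_that("a noiseless cohort is refit to the generating coefficients", {
  p <- sim_params(n_pairs = 20, n_sites = 600, sigma_pair = 0, sigma_resid = 0,
                  seed = 31)
  co <- simulate_cohort(p)
  # a zero-noise fit triggers lme4 convergence-check warnings even though the
  # solution is exact; the coefficient assertions below are the real check
  fit <- suppressWarnings(suppressMessages(
    fit_longitudinal(co$clinical, truth_scores(co), include_hla = TRUE)
  ))
  est <- setNames(fit$coefficients$estimate, fit$coefficients$term)
  expect_equal(est[["donor_age"]], p$beta_age, tolerance = 1e-6)
  expect_equal(est[["ams"]], p$beta_ams, tolerance = 1e-6)
  expect_equal(est[["months"]], p$beta_t, tolerance = 1e-6)
  expect_equal(est[["hla_abdr"]], p$beta_hla, tolerance = 1e-6)
  expect_equal(est[["(Intercept)"]], p$intercept, tolerance = 1e-6)
})

test_that("degenerate designs are flagged", {
  scores <- tibble::tibble(pair_id = paste0("p", 1:6), ams = c(1:6) * 100)
  one_obs <- tibble::tibble(
    pair_id = scores$pair_id, months = 12, donor_age = rnorm(6, 45, 5),
    egfr = rnorm(6, 55, 10)
  )
  expect_warning(
    suppressMessages(fit_longitudinal(one_obs, scores)),
    "confounded|singular"
  )
  expect_error(
    fit_longitudinal(one_obs, scores[1:3, ]),
    class = "allogenomics_data_error"
  )
  expect_error(
    fit_longitudinal(one_obs[one_obs$pair_id == "p1", ], scores),
    class = "allogenomics_data_error"
  )
})

make_test_cohort <- function(seed = 404) {
  co <- simulate_cohort(sim_params(n_pairs = 25, n_sites = 800, seed = seed))
  list(clinical = co$clinical, scores = truth_scores(co))
}

test_that("model comparison follows the likelihood-ratio recipe and its guards", {
  d <- make_test_cohort()
  full <- fit_longitudinal(d$clinical, d$scores, reml = FALSE)
  reduced <- fit_longitudinal(d$clinical, d$scores, include_ams = FALSE,
                              reml = FALSE)
  cmp <- compare_models(full, reduced)
  expect_equal(cmp$chi2, 2 * (full$log_lik - reduced$log_lik))
  expect_equal(cmp$df, 1)
  expect_equal(cmp$p_value, pchisq(cmp$chi2, 1, lower.tail = FALSE))

  # comparing a model with itself short-circuits
  self <- compare_models(full, full)
  expect_equal(self$chi2, 0)
  expect_equal(self$p_value, 1)

  # REML fits are rejected
  reml_fit <- fit_longitudinal(d$clinical, d$scores)
  expect_error(compare_models(reml_fit, reduced),
               class = "allogenomics_contract_error")
  # non-nested models are rejected
  hla_only <- fit_longitudinal(d$clinical, d$scores, include_hla = TRUE,
                               include_ams = FALSE, reml = FALSE)
  expect_error(compare_models(full, hla_only),
               class = "allogenomics_contract_error")
})

test_that("the LRT statistic is invariant to affine rescaling of the score", {
  d <- make_test_cohort(seed = 405)
  reduced <- fit_longitudinal(d$clinical, d$scores, include_ams = FALSE,
                              reml = FALSE)
  full <- fit_longitudinal(d$clinical, d$scores, reml = FALSE)
  rescaled <- dplyr::mutate(d$scores, ams = ams / 1000)
  full2 <- fit_longitudinal(d$clinical, rescaled, reml = FALSE)
  chi_a <- compare_models(full, reduced)$chi2
  chi_b <- compare_models(full2, reduced)$chi2
  expect_equal(chi_a, chi_b, tolerance = 1e-6)
})

test_that("impacts scale estimates and interval endpoints by the range", {
  fit <- structure(list(
    coefficients = tibble::tibble(
      term = c("(Intercept)", "donor_age", "ams"),
      estimate = c(100, -0.47, -0.011),
      se = c(5, 0.16, 0.005),
      conf_low = c(90, -0.78, -0.022),
      conf_high = c(110, -0.15, -0.00063)
    ),
    terms = c("donor_age", "ams")
  ), class = "ams_lmm")

  rep <- impact_report(fit, ranges = c(donor_age = 60, ams = 1700))
  expect_equal(rep$impact[rep$term == "donor_age"], -0.47 * 60)  # -28.2
  expect_equal(rep$impact_low[rep$term == "ams"], -0.022 * 1700)  # -37.4
  expect_equal(rep$impact_high[rep$term == "ams"], -0.00063 * 1700,
               tolerance = 1e-9)  # -1.071
  # impact sign follows the estimate for positive ranges
  expect_equal(sign(rep$impact), sign(rep$estimate))

  zero <- fit
  zero$coefficients$estimate[3] <- 0
  expect_equal(
    impact_report(zero, ranges = c(donor_age = 60, ams = 1700))$impact[2], 0
  )
  expect_error(impact_report(fit, ranges = c(donor_age = 60)),
               class = "allogenomics_config_error")
  expect_error(impact_report(fit, ranges = c(donor_age = -60, ams = 1700)),
               class = "allogenomics_config_error")
})
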