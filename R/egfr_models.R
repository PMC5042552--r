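#' Estimated GFR by the four-variable MDRD equation
#'
#' `eGFR = 175 * Scr^(-1.154) * age^(-0.203) * 0.742^[female] * 1.212^[black]`
#' in mL/min/1.73 m2, with serum creatinine in mg/dL and age in years.
#'
#' @param scr Serum creatinine, mg/dL (> 0).
#' @param age Age in years (> 0).
#' @param female,black Logical flags (vectorised).
#' @return eGFR in mL/min/1.73 m2.
#' @examples
#' egfr_mdrd(1.0, 50, female = FALSE, black = FALSE)  # ~79.1
#' @export
egfr_mdrd <- function(scr, age, female = FALSE, black = FALSE) {
  if (any(scr <= 0, na.rm = TRUE) || any(age <= 0, na.rm = TRUE)) {
    abort_contract("serum creatinine and age must be positive")
  }
  175 * scr^(-1.154) * age^(-0.203) *
    ifelse(female, 0.742, 1) * ifelse(black, 1.212, 1)
}

# Inverse of egfr_mdrd in creatinine: used by the cohort generator to derive
# a serum creatinine consistent with a generated eGFR.
mdrd_invert <- function(egfr, age, female = FALSE, black = FALSE) {
  base <- 175 * age^(-0.203) * ifelse(female, 0.742, 1) * ifelse(black, 1.212, 1)
  (egfr / base)^(-1 / 1.154)
}

#' Read a longitudinal clinical table
#'
#' Reads the clinical CSV: one row per (pair, timepoint) with columns
#' `pair_id`, `months` (post-transplant), `donor_age` (years at transplant),
#' `hla_abdr` (0-6 ABDR mismatches; optional), `recipient_sex`
#' (`male`/`female`), `recipient_race` (`black`/`non-black`),
#' `recipient_age` (optional), `serum_creatinine` (mg/dL; optional) and
#' `egfr` (optional). At least one of `serum_creatinine`/`egfr` must be
#' present per row; when `egfr` is absent it is computed from creatinine by
#' [egfr_mdrd()] using the recipient's age at observation — a provided eGFR
#' is never overwritten.
#'
#' @param path Path to the CSV file.
#' @return A tibble with a complete `egfr` column.
#' @export
read_clinical <- function(path) {
  if (!file.exists(path)) {
    abort_config(paste0("clinical table not found: ", path))
  }
  df <- readr::read_csv(path, comment = "#", progress = FALSE,
                        show_col_types = FALSE)
  required <- c("pair_id", "months", "donor_age")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    abort_config(paste0("clinical table lacks column(s): ",
                        paste(missing, collapse = ", ")))
  }
  if (!"egfr" %in% names(df)) df$egfr <- NA_real_
  need <- is.na(df$egfr)
  if (any(need)) {
    if (!all(c("serum_creatinine", "recipient_age", "recipient_sex",
               "recipient_race") %in% names(df))) {
      abort_config(
        "rows without egfr require serum_creatinine, recipient_age, recipient_sex, recipient_race"
      )
    }
    df$egfr[need] <- egfr_mdrd(
      df$serum_creatinine[need],
      df$recipient_age[need] + df$months[need] / 12,
      female = df$recipient_sex[need] == "female",
      black = df$recipient_race[need] == "black"
    )
  }
  if (any(df$months < 0, na.rm = TRUE)) {
    abort_data("months post-transplant must be >= 0")
  }
  if ("hla_abdr" %in% names(df) &&
      any(df$hla_abdr < 0 | df$hla_abdr > 6, na.rm = TRUE)) {
    abort_data("hla_abdr mismatch counts must lie in 0..6")
  }
  tibble::as_tibble(df)
}

#' Cross-sectional regression of graft function on the mismatch score
#'
#' Ordinary least-squares simple regression of the outcome (eGFR or serum
#' creatinine) at one fixed month post-transplant on the pairs' mismatch
#' scores, reporting the slope, adjusted r-squared and two-sided p-value.
#'
#' @param scores A tibble with columns `pair_id` and `ams`.
#' @param clinical A clinical tibble (see [read_clinical()]).
#' @param month Month post-transplant at which to evaluate.
#' @param outcome `"egfr"` or `"creatinine"`.
#' @return A one-row tibble: `month`, `outcome`, `slope`, `intercept`,
#'   `adj_r_squared`, `p_value`, `n`.
#' @export
fit_cross_sectional <- function(scores, clinical, month,
                                outcome = c("egfr", "creatinine")) {
  outcome <- match.arg(outcome)
  ycol <- if (outcome == "egfr") "egfr" else "serum_creatinine"
  df <- clinical |>
    dplyr::filter(.data$months == month) |>
    dplyr::inner_join(scores, by = "pair_id")
  df <- df[!is.na(df[[ycol]]) & !is.na(df$ams), ]
  if (nrow(df) < 3) {
    abort_data(paste0("need >= 3 pairs with ", outcome, " at month ", month))
  }
  if (sd(df$ams) == 0) {
    abort_model("mismatch score is constant across pairs: singular fit")
  }
  fit <- lm(df[[ycol]] ~ df$ams)
  s <- summary(fit)
  tibble::tibble(
    month = month,
    outcome = outcome,
    slope = unname(coef(fit)[2]),
    intercept = unname(coef(fit)[1]),
    adj_r_squared = s$adj.r.squared,
    p_value = s$coefficients[2, 4],
    n = nrow(df)
  )
}

#' Longitudinal mixed model of eGFR
#'
#' Fits the linear mixed model
#' `eGFR ~ donor_age + ams + months (+ hla_abdr) + (1 | pair_id)`:
#' fixed effects for donor age at transplant, the allogenomics mismatch
#' score, time post-transplant in months and optionally the HLA-ABDR
#' mismatch count, plus a random intercept per transplant pair capturing
#' baseline graft-function differences and the correlation of repeated
#' measurements within a pair.
#'
#' @param records A clinical tibble (see [read_clinical()]).
#' @param scores A tibble with columns `pair_id` and `ams`.
#' @param include_hla Include the HLA-ABDR mismatch count as a fixed effect.
#' @param include_ams Include the mismatch score as a fixed effect. Setting
#'   this to `FALSE` fits the reduced model used as the null in the
#'   likelihood-ratio test of the score's effect.
#' @param reml Fit by REML (default) or maximum likelihood. Model
#'   comparisons require ML fits, see [compare_models()].
#' @return An object of class `ams_lmm`: list with the `lme4` fit (`fit`),
#'   `coefficients` (tibble: term, estimate, se, conf_low, conf_high — 95%
#'   Wald intervals), `sigma_pair` (random-intercept SD), `sigma_resid`,
#'   `log_lik`, `reml`, `n_obs`, `n_pairs` and `terms` (fixed-effect names).
#' @export
fit_longitudinal <- function(records, scores, include_hla = FALSE,
                             include_ams = TRUE, reml = TRUE) {
  df <- dplyr::inner_join(records, scores, by = "pair_id")
  unmatched <- setdiff(unique(records$pair_id), unique(scores$pair_id))
  if (length(unmatched) > 0) {
    abort_data(paste0(
      "clinical pair id(s) without a score: ",
      paste(unmatched, collapse = ", ")
    ))
  }
  if (include_hla && !"hla_abdr" %in% names(df)) {
    abort_config("include_hla = TRUE but clinical table has no hla_abdr column")
  }
  vars <- c("egfr", "donor_age", "months",
            if (include_ams) "ams", if (include_hla) "hla_abdr")
  df <- df[complete.cases(df[, vars]), ]
  if (length(unique(df$pair_id)) < 2) {
    abort_data("mixed model requires >= 2 transplant pairs")
  }
  if (max(table(df$pair_id)) < 2) {
    warn(paste(
      "no pair has repeated observations:",
      "random-intercept variance is confounded with residual variance"
    ))
  }

  rhs <- c("donor_age", if (include_ams) "ams", "months",
           if (include_hla) "hla_abdr", "(1 | pair_id)")
  fml <- stats::as.formula(
    paste("egfr ~", paste(rhs, collapse = " + ")),
    env = environment()
  )
  # allow the degenerate one-observation-per-pair design to fit (the random
  # intercept is then confounded with the residual; warned about above)
  ctrl <- lme4::lmerControl(check.nobs.vs.nlev = "ignore",
                            check.nobs.vs.rankZ = "ignore",
                            check.nobs.vs.nRE = "ignore")
  fit <- tryCatch(
    lme4::lmer(fml, data = df, REML = reml, control = ctrl),
    error = function(e) {
      abort_model(paste0(
        "mixed model failed to converge (",
        if (include_hla) "with" else "without", " HLA): ",
        conditionMessage(e)
      ))
    }
  )
  if (lme4::isSingular(fit)) {
    warn("singular random-effect variance (pair intercept SD estimated at 0)")
  }

  est <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  z <- qnorm(0.975)
  coefs <- tibble::tibble(
    term = names(est),
    estimate = unname(est),
    se = unname(se),
    conf_low = unname(est - z * se),
    conf_high = unname(est + z * se)
  )
  vc <- as.data.frame(lme4::VarCorr(fit))
  structure(
    list(
      fit = fit,
      coefficients = coefs,
      sigma_pair = vc$sdcor[vc$grp == "pair_id"][1],
      sigma_resid = vc$sdcor[vc$grp == "Residual"][1],
      log_lik = as.numeric(logLik(fit)),
      reml = reml,
      n_obs = nrow(df),
      n_pairs = length(unique(df$pair_id)),
      terms = setdiff(names(est), "(Intercept)")
    ),
    class = "ams_lmm"
  )
}

#' @export
print.ams_lmm <- function(x, ...) {
  cat("Longitudinal eGFR mixed model (",
      if (x$reml) "REML" else "ML", " fit)\n", sep = "")
  cat("  ", x$n_obs, " observations, ", x$n_pairs, " pairs; logLik ",
      format(x$log_lik, digits = 6), "\n", sep = "")
  print(as.data.frame(x$coefficients), row.names = FALSE, digits = 4)
  cat("  random intercept SD (pair):", format(x$sigma_pair, digits = 4),
      "| residual SD:", format(x$sigma_resid, digits = 4), "\n")
  invisible(x)
}

#' Likelihood-ratio comparison of nested mixed models
#'
#' Compares two nested maximum-likelihood fits by the likelihood-ratio test:
#' `chi2 = 2 (logLik_full - logLik_reduced)`, with degrees of freedom equal
#' to the difference in fixed-effect count and the p-value from the upper
#' chi-squared tail. Both fits must be ML (REML likelihoods are not
#' comparable across fixed-effect structures). Comparing a model with itself
#' (no added fixed effect) short-circuits to `chi2 = 0`, `p = 1` with
#' `df = 0`.
#'
#' @param full,reduced `ams_lmm` fits from [fit_longitudinal()]; the reduced
#'   model's fixed effects must be a subset of the full model's.
#' @return A tibble: `chi2`, `df`, `p_value`, `full`, `reduced`.
#' @export
compare_models <- function(full, reduced) {
  stopifnot(inherits(full, "ams_lmm"), inherits(reduced, "ams_lmm"))
  if (full$reml || reduced$reml) {
    abort_contract("model comparison requires ML fits (reml = FALSE)")
  }
  if (!all(reduced$terms %in% full$terms)) {
    abort_contract("reduced model is not nested in the full model")
  }
  df_diff <- length(full$terms) - length(reduced$terms)
  chi2 <- max(0, 2 * (full$log_lik - reduced$log_lik))
  p <- if (df_diff == 0) 1 else pchisq(chi2, df_diff, lower.tail = FALSE)
  tibble::tibble(
    chi2 = chi2,
    df = df_diff,
    p_value = p,
    full = paste(full$terms, collapse = "+"),
    reduced = paste(reduced$terms, collapse = "+")
  )
}

#' Effect-impact report over predictor ranges
#'
#' Converts fitted coefficients into the expected impact on eGFR when each
#' predictor is varied over its effective range (impact = estimate x range;
#' the 95% CI endpoints are scaled likewise). Default ranges: 480 months of
#' follow-up, 60 years of donor age, 1700 score units, 6 HLA-ABDR
#' mismatches.
#'
#' @param fit An `ams_lmm` fit.
#' @param ranges Named numeric vector mapping each fitted predictor to its
#'   effective range (must be positive and cover every fixed effect except
#'   the intercept).
#' @return A tibble: `term`, `estimate`, `conf_low`, `conf_high`, `range`,
#'   `impact`, `impact_low`, `impact_high`.
#' @export
impact_report <- function(fit, ranges = c(months = 480, donor_age = 60,
                                          ams = 1700, hla_abdr = 6)) {
  stopifnot(inherits(fit, "ams_lmm"))
  if (any(ranges <= 0)) {
    abort_config("effective ranges must be positive")
  }
  terms <- fit$terms
  missing <- setdiff(terms, names(ranges))
  if (length(missing) > 0) {
    abort_config(paste0("no effective range given for predictor(s): ",
                        paste(missing, collapse = ", ")))
  }
  co <- fit$coefficients[fit$coefficients$term %in% terms, ]
  rng <- unname(ranges[co$term])
  tibble::tibble(
    term = co$term,
    estimate = co$estimate,
    conf_low = co$conf_low,
    conf_high = co$conf_high,
    range = rng,
    impact = co$estimate * rng,
    impact_low = co$conf_low * rng,
    impact_high = co$conf_high * rng
  )
}
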