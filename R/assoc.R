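# PRS -> side-effect association: logistic regressions adjusted for sex,
# age and 20 genetic principal components; Nagelkerke pseudo R-squared;
# Bonferroni significance families.

#' Nagelkerke pseudo R-squared
#'
#' `R2 = (1 - exp((2/n) (ll_null - ll_full))) / (1 - exp((2/n) ll_null))`.
#' `ll_full < ll_null` (possible only through numerical noise) is clamped
#' to zero improvement with a warning.
#'
#' @param ll_full,ll_null log-likelihoods of the model with and without
#'   the predictor of interest.
#' @param n sample size.
#' @return scalar in \[0, 1).
#' @export
nagelkerke <- function(ll_full, ll_null, n) {
  stopifnot(n > 0)
  if (ll_full < ll_null) {
    warning("ll_full < ll_null; clamping Nagelkerke R2 to 0", call. = FALSE)
    ll_full <- ll_null
  }
  cox_snell <- 1 - exp((2 / n) * (ll_null - ll_full))
  max_r2 <- 1 - exp((2 / n) * ll_null)
  cox_snell / max_r2
}

#' Logistic association between a PRS and a side-effect outcome
#'
#' Maximum-likelihood logistic regression of the binary outcome on the PRS
#' plus covariates (sex, age, principal components); complete cases only.
#' The odds ratio is `exp` of the PRS coefficient with a 95% Wald interval;
#' the null model refits without the PRS term only, giving the Nagelkerke
#' R-squared attributable to the PRS. Separation or non-convergence yields
#' a flagged result with `NA` estimates, never a silent drop.
#'
#' @param y binary outcome vector (0/1, `NA` allowed and dropped).
#' @param prs numeric score vector aligned with `y`.
#' @param covars data.frame or matrix of covariates aligned with `y`
#'   (e.g. sex indicator, age, PC1..PC20); may be `NULL`.
#' @return one-row data.frame (`assoc_result`): n, beta, se, odds_ratio,
#'   ci_low, ci_high, pvalue, r2_nagelkerke, ll_full, ll_null, converged.
#' @export
fit_assoc <- function(y, prs, covars = NULL) {
  stopifnot(length(prs) == length(y))
  if (!is.null(covars)) {
    covars <- as.data.frame(covars)
    stopifnot(nrow(covars) == length(y))
  }
  complete <- !is.na(y) & !is.na(prs)
  if (!is.null(covars)) complete <- complete & stats::complete.cases(covars)
  y <- y[complete]; prs <- prs[complete]
  if (!is.null(covars)) covars <- covars[complete, , drop = FALSE]
  n <- length(y)
  if (stats::sd(prs) == 0) {
    stop("fit_assoc: degenerate predictor 'prs' has zero variance",
         call. = FALSE)
  }
  dat <- data.frame(y = y, prs = prs)
  rhs_null <- "1"
  if (!is.null(covars) && ncol(covars) > 0) {
    dat <- cbind(dat, covars)
    rhs_null <- paste(colnames(covars), collapse = " + ")
  }
  f_full <- stats::as.formula(paste("y ~ prs +", rhs_null))
  f_null <- stats::as.formula(paste("y ~", rhs_null))
  fit <- suppressWarnings(stats::glm(f_full, family = stats::binomial(),
                                     data = dat))
  fit0 <- suppressWarnings(stats::glm(f_null, family = stats::binomial(),
                                      data = dat))
  co <- summary(fit)$coefficients
  # separation shows up as runaway coefficients/standard errors or
  # fitted probabilities at the boundary
  eps <- 1e-8
  boundary <- any(fit$fitted.values < eps | fit$fitted.values > 1 - eps)
  converged <- fit$converged && fit0$converged && !boundary &&
    abs(co["prs", "Estimate"]) < 15 && co["prs", "Std. Error"] < 10
  if (!converged) {
    return(data.frame(n = n, beta = NA_real_, se = NA_real_,
                      odds_ratio = NA_real_, ci_low = NA_real_,
                      ci_high = NA_real_, pvalue = NA_real_,
                      r2_nagelkerke = NA_real_, ll_full = NA_real_,
                      ll_null = NA_real_, converged = FALSE))
  }
  beta <- co["prs", "Estimate"]
  se <- co["prs", "Std. Error"]
  ll_full <- as.numeric(stats::logLik(fit))
  ll_null <- as.numeric(stats::logLik(fit0))
  z <- stats::qnorm(0.975)
  data.frame(n = n, beta = beta, se = se,
             odds_ratio = exp(beta),
             ci_low = exp(beta - z * se), ci_high = exp(beta + z * se),
             pvalue = co["prs", "Pr(>|z|)"],
             r2_nagelkerke = nagelkerke(ll_full, ll_null, n),
             ll_full = ll_full, ll_null = ll_null, converged = TRUE)
}

#' Pooled-across-medications outcome for one side effect
#'
#' 1 if the participant endorsed the side effect for at least one
#' medication taken; 0 if exposed to at least one medication and never
#' endorsed it; `NA` (excluded) if exposed to none.
#'
#' @param cohort a `cohort_table`.
#' @param side_effect a side-effect id.
#' @return integer vector aligned with the cohort rows.
#' @export
pooled_outcome <- function(cohort, side_effect) {
  m <- endorsement_matrix(cohort, side_effect)
  n_obs <- rowSums(!is.na(m))
  out <- as.integer(rowSums(m == 1L, na.rm = TRUE) > 0L)
  out[n_obs == 0L] <- NA_integer_
  out
}

#' Bonferroni significance families
#'
#' Flags results against the family-wise threshold: `mdd_25` (one PRS
#' against 25 side effects pooled across medications, 0.05/25 = 0.002),
#' `per_drug_10` (one PRS and side effect over ten medications,
#' 0.05/10 = 0.005), `ct_80` (clumping-and-thresholding sensitivity:
#' eight thresholds times ten medications, 0.05/80 = 0.000625). A nominal
#' `p < 0.05` flag is set as well.
#'
#' @param results data.frame of association results with a `pvalue` column.
#' @param family one of `"mdd_25"`, `"per_drug_10"`, `"ct_80"`.
#' @return `results` with added columns `significant_nominal`,
#'   `significant_bonferroni` and `bonferroni_family`.
#' @export
bonferroni_family <- function(results,
                              family = c("mdd_25", "per_drug_10", "ct_80")) {
  family <- match.arg(family)
  threshold <- switch(family, mdd_25 = 0.05 / 25,
                      per_drug_10 = 0.05 / 10, ct_80 = 0.05 / 80)
  results$significant_nominal <- !is.na(results$pvalue) &
    results$pvalue < 0.05
  results$significant_bonferroni <- !is.na(results$pvalue) &
    results$pvalue < threshold
  results$bonferroni_family <- family
  attr(results, "bonferroni_threshold") <- threshold
  results
}

# assemble the standard covariate frame: sex indicator, age, PCs
assoc_covariates <- function(cohort, pcs = NULL, extra = NULL) {
  cv <- data.frame(sex_female = as.integer(cohort$sex == "female"),
                   age = cohort$age)
  if (!is.null(pcs)) {
    pcs <- pcs[match(cohort$participant_id, rownames(pcs)), , drop = FALSE]
    cv <- cbind(cv, as.data.frame(pcs))
  }
  if (!is.null(extra)) cv <- cbind(cv, extra)
  cv
}

#' PRS association scan over medications and side effects
#'
#' Runs [fit_assoc()] for one PRS against one side effect, either pooled
#' across medications (participant-level collapse) or per medication
#' (outcome restricted to participants exposed to that medication).
#'
#' @param cohort a `cohort_table`.
#' @param prs named score vector (names = participant ids) or
#'   `prs_result` column.
#' @param side_effect side-effect id.
#' @param pcs optional PC matrix from [pca_covariates()].
#' @param medications `"pooled"` or a vector of drug ids.
#' @param prs_trait label recorded in the output.
#' @param extra_covariates optional data.frame of additional covariates
#'   aligned with the cohort (e.g. an indication flag).
#' @return data.frame of `assoc_result` rows with prs_trait, medication
#'   and side_effect columns.
#' @export
assoc_scan <- function(cohort, prs, side_effect, pcs = NULL,
                       medications = "pooled", prs_trait = "trait",
                       extra_covariates = NULL) {
  if (is.null(names(prs))) {
    stopifnot(length(prs) == nrow(cohort))
    names(prs) <- cohort$participant_id
  }
  score <- prs[match(cohort$participant_id, names(prs))]
  cv <- assoc_covariates(cohort, pcs, extra_covariates)
  one <- function(med) {
    y <- if (med == "pooled") pooled_outcome(cohort, side_effect) else
      cohort[[paste0("se_", med, "_", side_effect)]]
    res <- fit_assoc(y, score, cv)
    cbind(data.frame(prs_trait = prs_trait, medication = med,
                     side_effect = side_effect,
                     stringsAsFactors = FALSE), res)
  }
  do.call(rbind, lapply(medications, one))
}

#' Amitriptyline-for-insomnia sensitivity analysis
#'
#' Refits the insomnia-from-amitriptyline association with the
#' "took amitriptyline for insomnia" indication flag appended to the
#' covariates, to check whether prescribing bias confounds the PRS
#' association.
#'
#' @param cohort a `cohort_table` carrying the flag column.
#' @param prs named insomnia-PRS vector.
#' @param pcs optional PC matrix.
#' @param flag_column name of the indication column (default
#'   `"ami_for_insomnia"`).
#' @return two `assoc_result` rows: unadjusted and adjusted.
#' @export
insomnia_sensitivity <- function(cohort, prs, pcs = NULL,
                                 flag_column = "ami_for_insomnia") {
  if (!flag_column %in% names(cohort)) {
    stop("insomnia_sensitivity: cohort lacks the indication flag column '",
         flag_column, "'", call. = FALSE)
  }
  unadj <- assoc_scan(cohort, prs, "insomnia", pcs,
                      medications = "amitriptyline",
                      prs_trait = "INSOMNIA")
  flag <- cohort[, flag_column, drop = FALSE]
  adj <- assoc_scan(cohort, prs, "insomnia", pcs,
                    medications = "amitriptyline",
                    prs_trait = "INSOMNIA",
                    extra_covariates = flag)
  unadj$adjusted <- FALSE
  adj$adjusted <- TRUE
  rbind(unadj, adj)
}
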