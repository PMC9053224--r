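# association stage: logistic fits, Nagelkerke, pooling, families

test_that("nagelkerke evaluates the printed formula", {
  expect_equal(nagelkerke(-69.31, -69.31, 100), 0)
  # direct evaluation of the formula as oracle
  r2 <- (1 - exp((2 / 100) * (-69.31 + 60))) /
    (1 - exp((2 / 100) * (-69.31)))
  expect_equal(nagelkerke(-60, -69.31, 100), r2)
  expect_equal(round(nagelkerke(-60, -69.31, 100), 4), 0.2265)
  expect_lt(nagelkerke(-1, -200, 300), 1)
  expect_warning(out <- nagelkerke(-70, -69.31, 100), "clamping")
  expect_equal(out, 0)
})

test_that("logistic fit matches a generic optimizer oracle", {
  set.seed(61)
  n <- 50
  x <- rnorm(n); sexf <- rbinom(n, 1, 0.5); age <- rnorm(n, 45, 10)
  y <- rbinom(n, 1, plogis(-0.3 + 0.6 * x + 0.2 * sexf))
  res <- fit_assoc(y, x, data.frame(sex_female = sexf, age = age))
  # oracle: hand-rolled Newton-Raphson on the logistic log-likelihood
  X <- cbind(1, x, sexf, age)
  b <- rep(0, 4)
  for (it in 1:50) {
    p <- plogis(as.vector(X %*% b))
    grad <- crossprod(X, y - p)
    H <- crossprod(X * (p * (1 - p)), X)
    step <- solve(H, grad)
    b <- b + step
    if (max(abs(step)) < 1e-12) break
  }
  ll_b <- sum(y * (X %*% b) - log(1 + exp(X %*% b)))
  expect_lt(abs(res$beta - b[2]), 1e-6)
  expect_equal(res$ll_full, ll_b, tolerance = 1e-10)
  # Wald CI consistency with the coefficient
  expect_equal(res$ci_low, exp(res$beta - qnorm(0.975) * res$se))
  expect_equal(res$ci_high, exp(res$beta + qnorm(0.975) * res$se))
})

test_that("degenerate predictors and separation are surfaced", {
  y <- rbinom(80, 1, 0.4)
  expect_error(fit_assoc(y, rep(1, 80)), "zero variance")
  x <- c(rep(-2, 40), rep(2, 40))
  ysep <- as.integer(x > 0)
  res <- fit_assoc(ysep, x)
  expect_false(res$converged)
  expect_true(is.na(res$odds_ratio))
})

test_that("pooled outcome follows the >=1-medication definition", {
  coh <- small_study()$cohort
  y <- pooled_outcome(coh, "nausea")
  m <- endorsement_matrix(coh, "nausea")
  i_one <- which(rowSums(m == 1L, na.rm = TRUE) >= 1L)[1]
  expect_equal(y[i_one], 1L)
  unexposed <- rowSums(!is.na(m)) == 0L
  expect_true(all(is.na(y[unexposed])))
  expect_true(all(y[!unexposed] %in% c(0L, 1L)))

  # union bound: pooled prevalence >= per-medication prevalence on the
  # same participants
  for (d in c("sertraline", "venlafaxine")) {
    v <- coh[[paste0("se_", d, "_nausea")]]
    expect_gte(mean(y[!is.na(v)] == 1L, na.rm = TRUE),
               mean(v == 1L, na.rm = TRUE))
  }
})

test_that("Bonferroni families use their stated thresholds", {
  res <- data.frame(pvalue = c(0.004, 0.0007, 0.04, NA))
  out <- bonferroni_family(res, "per_drug_10")
  expect_equal(out$significant_bonferroni, c(TRUE, TRUE, FALSE, FALSE))
  out2 <- bonferroni_family(res, "mdd_25")
  expect_equal(out2$significant_bonferroni[1], FALSE)   # 0.004 > 0.002
  expect_equal(out2$significant_bonferroni[2], TRUE)
  out3 <- bonferroni_family(res, "ct_80")
  expect_equal(out3$significant_bonferroni[2], FALSE)   # 0.0007 > 0.000625
  expect_equal(attr(out3, "bonferroni_threshold"), 0.05 / 80)
  expect_equal(out$significant_nominal, c(TRUE, TRUE, TRUE, FALSE))
})

test_that("assoc_scan runs per medication and pooled with covariates", {
  st <- small_study()
  pcs <- pca_covariates(st$panel, 5)
  g <- attr(st$cohort, "truth")$genetic_scores[, "BMI"]
  names(g) <- st$cohort$participant_id
  res <- assoc_scan(st$cohort, g, "weight_gain", pcs,
                    medications = c("pooled", "sertraline"),
                    prs_trait = "BMI")
  expect_equal(res$medication, c("pooled", "sertraline"))
  expect_true(all(res$n > 0))
  expect_true(all(res$ci_low <= res$odds_ratio &
                    res$odds_ratio <= res$ci_high))
})

test_that("insomnia sensitivity adjustment behaves like a null confounder
          when the flag is independent", {
  cfg <- sim_config(n_participants = 4000L, n_variants = 60L, n_blocks = 6L,
                    seed = 63L, emit_indication_flag = TRUE,
                    indication_gamma = 0, indication_liability_effect = 0)
  st <- simulate_study(cfg)
  g <- attr(st$cohort, "truth")$genetic_scores[, "INSOMNIA"]
  names(g) <- st$cohort$participant_id
  res <- insomnia_sensitivity(st$cohort, g)
  expect_equal(nrow(res), 2L)
  # adjusted and unadjusted agree within Monte-Carlo error
  expect_lt(abs(log(res$odds_ratio[2]) - log(res$odds_ratio[1])),
            2 * sqrt(res$se[1]^2 + res$se[2]^2))
  expect_error(insomnia_sensitivity(generate_cohort(
    sim_config(n_participants = 200L, n_variants = 20L, n_blocks = 2L,
               seed = 1L)), g), "indication flag")
})

test_that("a strong common-cause flag attenuates the PRS association", {
  mk <- function(gamma_flag, liab_flag, seed) {
    cfg <- sim_config(n_participants = 9000L, n_variants = 60L,
                      n_blocks = 6L, seed = seed,
                      emit_indication_flag = TRUE,
                      exposure_probs = setNames(
                        c(rep(0.3, 8), 0.9, 0.3), sidefx_drugs()),
                      indication_gamma = gamma_flag,
                      indication_liability_effect = liab_flag)
    simulate_study(cfg)
  }
  st <- mk(gamma_flag = 2.5, liab_flag = 1.2, seed = 64L)
  g <- attr(st$cohort, "truth")$genetic_scores[, "INSOMNIA"]
  names(g) <- st$cohort$participant_id
  res <- insomnia_sensitivity(st$cohort, g)
  # the flag channels part of the genetic effect; adjusting for it pulls
  # the odds ratio toward 1
  expect_lt(abs(log(res$odds_ratio[2])), abs(log(res$odds_ratio[1])))
})
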