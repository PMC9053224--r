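# bifactor liability model: likelihood oracles, fitting, model comparison

test_that("zero loadings reduce to independent probit likelihoods", {
  set.seed(31)
  Y <- matrix(rbinom(500, 1, 0.35), 50, 10)
  Y[sample(length(Y), 120)] <- NA
  tau <- rnorm(10, 0.4, 0.3)
  ll <- marginal_loglik(Y, CLASSES10, general = rep(0, 10),
                        thresholds = tau, model_class = "full")
  p <- pnorm(-tau)
  closed <- sum(vapply(1:10, function(j) {
    y <- Y[, j]
    sum(ifelse(is.na(y), 0, ifelse(y == 1, log(p[j]), log(1 - p[j]))))
  }, 0))
  expect_equal(ll, closed, tolerance = 1e-10)
})

test_that("quadrature matches adaptive integration on a 3-manifest toy", {
  set.seed(32)
  Y <- matrix(rbinom(60, 1, 0.4), 20, 3)
  lg <- c(0.7, 0.5, 0.6); tau <- c(0.2, -0.1, 0.4)
  ll <- marginal_loglik(Y, rep("other", 3), general = lg, thresholds = tau,
                        model_class = "common_only", nodes = 21)
  sig <- sqrt(1 - lg^2)
  oracle <- sum(log(vapply(seq_len(nrow(Y)), function(i) {
    integrand <- function(f) {
      vapply(f, function(fk) {
        pr <- pnorm((lg * fk - tau) / sig)
        prod(ifelse(Y[i, ] == 1, pr, 1 - pr)) * dnorm(fk)
      }, 0)
    }
    integrate(integrand, -9, 9, rel.tol = 1e-12)$value
  }, 0)))
  expect_equal(ll, oracle, tolerance = 1e-8)
})

test_that("log-likelihood is stable under node doubling", {
  # absolute 1e-6 stability on the 3-manifest toy scale
  # Gauss-Hermite converges geometrically but the rate degrades as
  # loadings grow (the integrand steepens); 21 nodes is converged to
  # ~1e-9 for loadings up to 0.7, while 0.8 needs ~42 nodes for 1e-6.
  set.seed(35)
  Y3 <- matrix(rbinom(60, 1, 0.4), 20, 3)
  lg <- c(0.7, 0.5, 0.6)
  l21 <- marginal_loglik(Y3, rep("other", 3), general = lg,
                         thresholds = rep(0.2, 3),
                         model_class = "common_only", nodes = 21)
  l42 <- marginal_loglik(Y3, rep("other", 3), general = lg,
                         thresholds = rep(0.2, 3),
                         model_class = "common_only", nodes = 42)
  expect_lt(abs(l21 - l42), 1e-6)
  h42 <- marginal_loglik(Y3, rep("other", 3), general = rep(0.8, 3),
                         thresholds = rep(0.2, 3),
                         model_class = "common_only", nodes = 42)
  h84 <- marginal_loglik(Y3, rep("other", 3), general = rep(0.8, 3),
                         thresholds = rep(0.2, 3),
                         model_class = "common_only", nodes = 84)
  expect_lt(abs(h42 - h84), 1e-6)

  # cohort-scale matrices: per-observation stability at the same level
  Y <- endorsement_matrix(small_study()$cohort, "nausea")
  lg <- rep(0.75, 10); tau <- rep(0.6, 10)
  ssri <- rep(0.35, 10); snri <- rep(0.35, 10)
  f21 <- marginal_loglik(Y, CLASSES10, lg, tau, ssri, snri, "full", 21)
  f42 <- marginal_loglik(Y, CLASSES10, lg, tau, ssri, snri, "full", 42)
  expect_lt(abs(f21 - f42) / sum(!is.na(Y)), 1e-6)
})

test_that("residual-variance violations are penalized, not evaluated", {
  Y <- matrix(rbinom(30, 1, 0.4), 10, 3)
  ll <- marginal_loglik(Y, rep("other", 3), general = rep(1.01, 3),
                        thresholds = rep(0, 3), model_class = "common_only")
  expect_true(isTRUE(attr(ll, "variance_violation")))
  expect_lt(ll, -1e9)
})

test_that("analytic gradient agrees with numerical differentiation", {
  skip_if_not_installed("numDeriv")
  set.seed(33)
  Y <- simulate_bifactor_data(150, CLASSES10, general = rep(0.6, 10),
                              thresholds = rep(0.4, 10),
                              ssri = rep(0.3, 10), snri = rep(0.3, 10),
                              p_observed = 0.7, seed = 8)
  pat <- sidefx:::collapse_patterns(Y)
  gh <- sidefx:::gauss_hermite_norm(9)
  theta <- c(rep(0.5, 10), rep(0.2, 8), rnorm(10, 0.6, 0.2))
  an <- sidefx:::bifactor_core(theta, pat, CLASSES10, "full", gh,
                               gradient = TRUE)
  nu <- numDeriv::grad(function(t) {
    sidefx:::bifactor_core(t, pat, CLASSES10, "full", gh)
  }, theta)
  expect_equal(an$gradient, nu, tolerance = 1e-6)
})

test_that("null data recover a near-zero correlation structure", {
  # With true loadings all 0 the individual loadings are only weakly
  # identified (maximum likelihood can trade one large loading against
  # many tiny ones while implying the same near-zero correlations), so
  # the assertions target the identified quantities: implied pairwise
  # latent correlations lambda_i * lambda_j and the thresholds.
  Y <- simulate_bifactor_data(1500, CLASSES10, general = rep(0, 10),
                              thresholds = rep(0.5, 10), seed = 41)
  fit <- fit_bifactor(Y, CLASSES10, "common_only", nodes = 9, starts = 2,
                      seed = 1)
  lg <- fit$loadings$general
  implied <- tcrossprod(lg)
  off <- abs(implied[upper.tri(implied)])
  expect_lt(mean(off), 0.03)
  expect_lt(max(off), 0.2)
  expect_true(all(abs(fit$thresholds - 0.5) < 0.1))
})

test_that("common-factor data recover the generating loadings", {
  Y <- simulate_bifactor_data(2000, CLASSES10, general = rep(0.7, 10),
                              thresholds = rep(0.3, 10), seed = 42)
  fit <- fit_bifactor(Y, CLASSES10, "common_only", nodes = 11, starts = 2,
                      seed = 1)
  expect_true(fit$converged)
  expect_true(all(abs(fit$loadings$general - 0.7) < 0.1))
  expect_true(all(abs(fit$thresholds - 0.3) < 0.1))
})

test_that("nesting monotonicity and k_params bookkeeping hold", {
  Y <- simulate_bifactor_data(600, CLASSES10, general = rep(0.6, 10),
                              thresholds = rep(0.4, 10), p_observed = 0.7,
                              seed = 43)
  fits <- lapply(c("full", "ssri_only", "snri_only", "common_only"),
                 function(mc) fit_bifactor(Y, CLASSES10, mc, nodes = 9,
                                           starts = 2, seed = 1))
  names(fits) <- c("full", "ssri_only", "snri_only", "common_only")
  expect_equal(fits$full$k_params, 28L)        # 10 + 5 + 3 + 10
  expect_equal(fits$ssri_only$k_params, 25L)
  expect_equal(fits$snri_only$k_params, 23L)
  expect_equal(fits$common_only$k_params, 20L)
  for (mc in c("ssri_only", "snri_only", "common_only")) {
    expect_gte(fits$full$loglik, fits[[mc]]$loglik - 1e-3)
    cmp <- compare_bifactor(fits$full, fits[[mc]])
    expect_gte(cmp$lrt_stat, 0)
    expect_equal(cmp$df, fits$full$k_params - fits[[mc]]$k_params)
  }
})

test_that("identical fits compare with LRT 0 and p 1", {
  Y <- simulate_bifactor_data(300, CLASSES10, general = rep(0.5, 10),
                              thresholds = rep(0.5, 10), seed = 44)
  f1 <- fit_bifactor(Y, CLASSES10, "common_only", nodes = 9, starts = 1,
                     seed = 1)
  f2 <- f1
  f2$k_params <- f1$k_params - 8L   # pretend-nested copy of the same fit
  cmp <- compare_bifactor(f1, f2)
  expect_equal(cmp$lrt_stat, 0)
  expect_equal(cmp$pvalue, 1)
})

test_that("fits are deterministic given seed and starts", {
  Y <- endorsement_matrix(small_study()$cohort, "sweating")
  f1 <- fit_bifactor(Y, CLASSES10, "snri_only", nodes = 9, starts = 2,
                     seed = 7)
  f2 <- fit_bifactor(Y, CLASSES10, "snri_only", nodes = 9, starts = 2,
                     seed = 7)
  expect_identical(f1$loglik, f2$loglik)
  expect_identical(f1$loadings, f2$loadings)
})

test_that("run_all_side_effects flags the planted SNRI factor first", {
  effects24 <- c(sidefx_checklist_effects(), "other")
  cl <- list(SSRI = c(), SNRI = c(sweating = 0.55))
  cfg <- sim_config(n_participants = 2500L, n_variants = 20L, n_blocks = 2L,
                    seed = 46L, class_loadings = cl,
                    genetic_betas = data.frame(side_effect = character(0),
                                               trait = character(0),
                                               gamma = numeric(0)),
                    sex_effects = c(),
                    exposure_probs = setNames(rep(0.6, 10), sidefx_drugs()))
  coh <- generate_cohort(cfg)
  res <- run_all_side_effects(coh, c("sweating", "nausea", "headache"),
                              nodes = 9, starts = 2, seed = 1)
  # evidence FOR an SNRI factor = cost of removing it, i.e. the LRT of
  # the reduction full -> ssri_only
  snri_removal <- res[res$reduced_model == "ssri_only", ]
  expect_equal(snri_removal$side_effect[which.min(snri_removal$pvalue)],
               "sweating")
  expect_lt(snri_removal$pvalue[snri_removal$side_effect == "sweating"],
            0.01)
})

test_that("an unidentifiable side effect is skipped with a log entry", {
  coh <- as.data.frame(small_study()$cohort)
  # leave only sertraline exposure so no two manifests are jointly observed
  for (d in setdiff(DRUGS, "sertraline")) {
    coh[[paste0("taken_", d)]] <- 0L
    coh[, paste0("se_", d, "_", sidefx_effects())] <- NA_integer_
  }
  coh <- as_cohort_table(coh)
  res <- run_all_side_effects(coh, c("nausea"), nodes = 7, starts = 1,
                              seed = 1)
  expect_null(res)
})
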