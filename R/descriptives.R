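# Descriptive epidemiology: per-medication side-effect prevalence with
# Wilson confidence intervals, sex-difference proportion tests and
# endorsed-vs-not age comparisons, plus the single-antidepressant subset.

#' Wilson score interval
#' @param k successes, `n` trials, `conf` confidence level.
#' @param n number of trials.
#' @param conf confidence level.
#' @return c(low, high).
#' @keywords internal
wilson_interval <- function(k, n, conf = 0.95) {
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- k / n
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  c(max(0, centre - half), min(1, centre + half))
}

#' Side-effect prevalence with 95% confidence interval
#'
#' Prevalence of endorsing `side_effect` among participants exposed to
#' `medication` (or to at least one medication when
#' `medication = "any"`, counting a participant once if they endorse the
#' effect for any medication taken), optionally within a sex stratum.
#' The interval is the Wilson score interval.
#'
#' @param cohort a `cohort_table`.
#' @param medication drug id or `"any"`.
#' @param side_effect side-effect id.
#' @param stratum `"all"`, `"male"` or `"female"`.
#' @return one-row data.frame (`prevalence_cell`): medication, side_effect,
#'   stratum, k, n, prev, ci_low, ci_high. When no participant is exposed,
#'   `n = 0` and the estimate columns are `NA` (an explicit empty-cell
#'   marker, not NaN propagation).
#' @export
prevalence <- function(cohort, medication, side_effect,
                       stratum = c("all", "male", "female")) {
  stratum <- match.arg(stratum)
  stopifnot(side_effect %in% .EFFECTS,
            medication %in% c(.DRUGS, "any"))
  keep <- if (stratum == "all") rep(TRUE, nrow(cohort)) else
    cohort$sex == stratum
  sub <- cohort[keep, , drop = FALSE]
  if (medication == "any") {
    y <- pooled_outcome(sub, side_effect)
    k <- sum(y, na.rm = TRUE)
    n <- sum(!is.na(y))
  } else {
    v <- sub[[paste0("se_", medication, "_", side_effect)]]
    k <- sum(v == 1L, na.rm = TRUE)
    n <- sum(!is.na(v))
  }
  if (n == 0L) {
    return(data.frame(medication = medication, side_effect = side_effect,
                      stratum = stratum, k = 0L, n = 0L, prev = NA_real_,
                      ci_low = NA_real_, ci_high = NA_real_,
                      stringsAsFactors = FALSE))
  }
  ci <- wilson_interval(k, n)
  data.frame(medication = medication, side_effect = side_effect,
             stratum = stratum, k = k, n = n, prev = k / n,
             ci_low = ci[1], ci_high = ci[2], stringsAsFactors = FALSE)
}

#' Prevalence table over all (medication, side effect, stratum) cells
#'
#' @param cohort a `cohort_table`.
#' @param medications drugs to tabulate (default all ten plus "any").
#' @param side_effects effects to tabulate (default all 25).
#' @param strata strata to tabulate.
#' @return data.frame of prevalence cells.
#' @export
prevalence_table <- function(cohort, medications = c(.DRUGS, "any"),
                             side_effects = .EFFECTS,
                             strata = c("all", "male", "female")) {
  grid <- expand.grid(medication = medications, side_effect = side_effects,
                      stratum = strata, stringsAsFactors = FALSE)
  do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
    prevalence(cohort, grid$medication[i], grid$side_effect[i],
               grid$stratum[i])
  }))
}

#' Two-sample Z proportion test
#'
#' Pooled-proportion two-sided Z test without continuity correction — the
#' variant that reproduces the published sex-difference p-values from the
#' printed counts.
#'
#' @param k1,n1 endorsed and exposed counts in group 1.
#' @param k2,n2 endorsed and exposed counts in group 2.
#' @return list of class `group_test`: statistic (z), pvalue, test,
#'   group_summaries.
#' @export
two_prop_z <- function(k1, n1, k2, n2) {
  stopifnot(n1 >= 1, n2 >= 1)
  if (k1 > n1 || k2 > n2 || k1 < 0 || k2 < 0) {
    stop("two_prop_z domain error: need 0 <= k <= n", call. = FALSE)
  }
  p1 <- k1 / n1
  p2 <- k2 / n2
  pool <- (k1 + k2) / (n1 + n2)
  se <- sqrt(pool * (1 - pool) * (1 / n1 + 1 / n2))
  z <- if (se == 0) 0 else (p1 - p2) / se
  structure(list(statistic = z,
                 pvalue = 2 * stats::pnorm(-abs(z)),
                 test = "two_prop_z",
                 group_summaries = data.frame(
                   group = c(1, 2), k = c(k1, k2), n = c(n1, n2))),
            class = "group_test")
}

#' Two-sample t test (raw data or summary form)
#'
#' Student pooled-variance two-sided t test by default (Welch optionally).
#' Accepts either raw vectors or summary statistics
#' `(mean, sd, n)` per group, as printed in demographic tables.
#'
#' @param group1,group2 numeric vectors, or lists/vectors
#'   `c(mean=, sd=, n=)` when `summary = TRUE`.
#' @param summary interpret inputs as summary statistics.
#' @param welch use the Welch (unequal-variance) statistic.
#' @return a `group_test` list: statistic (t), pvalue, df, test,
#'   group_summaries. Zero variance in both groups with equal means yields
#'   p = 1 with `degenerate = TRUE`.
#' @export
two_sample_t <- function(group1, group2, summary = FALSE, welch = FALSE) {
  if (summary) {
    g1 <- as.list(group1); g2 <- as.list(group2)
    m1 <- g1$mean; s1 <- g1$sd; n1 <- g1$n
    m2 <- g2$mean; s2 <- g2$sd; n2 <- g2$n
  } else {
    stopifnot(length(group1) >= 2, length(group2) >= 2)
    m1 <- mean(group1); s1 <- stats::sd(group1); n1 <- length(group1)
    m2 <- mean(group2); s2 <- stats::sd(group2); n2 <- length(group2)
  }
  stopifnot(n1 >= 2, n2 >= 2)
  degenerate <- FALSE
  if (welch) {
    se <- sqrt(s1^2 / n1 + s2^2 / n2)
    df <- se^4 / ((s1^2 / n1)^2 / (n1 - 1) + (s2^2 / n2)^2 / (n2 - 1))
  } else {
    sp2 <- ((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  }
  if (se == 0) {
    degenerate <- TRUE
    tstat <- 0
    pv <- 1
    if (m1 != m2) stop("zero variance with unequal means", call. = FALSE)
  } else {
    tstat <- (m1 - m2) / se
    pv <- 2 * stats::pt(-abs(tstat), df)
  }
  structure(list(statistic = tstat, pvalue = pv, df = df,
                 test = if (welch) "welch_t" else "two_sample_t",
                 degenerate = degenerate,
                 group_summaries = data.frame(
                   group = c(1, 2), mean = c(m1, m2), sd = c(s1, s2),
                   n = c(n1, n2))),
            class = "group_test")
}

#' @export
print.group_test <- function(x, ...) {
  cat("<group_test> ", x$test, ": statistic = ",
      signif(x$statistic, 4), ", p = ", signif(x$pvalue, 3), "\n", sep = "")
  invisible(x)
}

#' Sex-difference and age tests for every side effect
#'
#' For each side effect: the male-vs-female pooled Z proportion test on
#' pooled-across-medications endorsement, and the endorsed-vs-not-endorsed
#' two-sample t test on age.
#'
#' @param cohort a `cohort_table`.
#' @param side_effects effects to test.
#' @return data.frame with one row per side effect: counts, z, sex p-value,
#'   age means/sds and age p-value.
#' @export
table_one_tests <- function(cohort, side_effects = .EFFECTS) {
  do.call(rbind, lapply(side_effects, function(s) {
    y <- pooled_outcome(cohort, s)
    male <- cohort$sex == "male" & !is.na(y)
    female <- cohort$sex == "female" & !is.na(y)
    zt <- two_prop_z(sum(y[male]), sum(male), sum(y[female]), sum(female))
    yes <- !is.na(y) & y == 1L
    no <- !is.na(y) & y == 0L
    at <- if (sum(yes) >= 2 && sum(no) >= 2) {
      two_sample_t(cohort$age[yes], cohort$age[no])
    } else NULL
    data.frame(side_effect = s,
               k_male = sum(y[male]), n_male = sum(male),
               k_female = sum(y[female]), n_female = sum(female),
               z_sex = zt$statistic, p_sex = zt$pvalue,
               age_mean_endorsed = if (is.null(at)) NA else
                 at$group_summaries$mean[1],
               age_mean_not = if (is.null(at)) NA else
                 at$group_summaries$mean[2],
               p_age = if (is.null(at)) NA else at$pvalue,
               stringsAsFactors = FALSE)
  }))
}

#' Restrict to participants who took exactly one antidepressant
#'
#' The sensitivity subset used to check that prevalence estimates are not
#' driven by participants cycling through several medications.
#'
#' @param cohort a `cohort_table`.
#' @return a `cohort_table` containing the single-medication participants.
#' @export
single_drug_subset <- function(cohort) {
  n_drugs <- rowSums(as.matrix(cohort[, exposure_col(.DRUGS)]))
  out <- cohort[n_drugs == 1L, , drop = FALSE]
  class(out) <- class(cohort)
  attr(out, "truth") <- NULL
  out
}
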