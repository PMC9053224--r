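# PRS engine: QC, harmonization, clumping, scoring, PCA

make_panel <- function(dosages, chrom = "1", pos = NULL, ref = "A",
                       alt = "G", r2 = 0.99) {
  m <- ncol(dosages)
  if (is.null(pos)) pos <- seq_len(m) * 1000L
  if (is.null(colnames(dosages))) colnames(dosages) <- paste0("v", seq_len(m))
  if (is.null(rownames(dosages))) rownames(dosages) <- paste0("i", seq_len(nrow(dosages)))
  genotype_panel(dosages, data.frame(
    variant_id = colnames(dosages), chrom = rep_len(chrom, m),
    pos = pos, ref = rep_len(ref, m), alt = rep_len(alt, m),
    imputation_r2 = rep_len(r2, m), stringsAsFactors = FALSE))
}

make_stats <- function(ids, pval, beta = 0.1, ea = "G", oa = "A") {
  as_sumstats(data.frame(
    variant_id = ids, chrom = "1", pos = seq_along(ids) * 1000L,
    effect_allele = rep_len(ea, length(ids)),
    other_allele = rep_len(oa, length(ids)),
    freq = 0.3, beta = rep_len(beta, length(ids)), se = 0.02,
    pval = pval, n = 1e5, stringsAsFactors = FALSE))
}

test_that("qc_filter removes ambiguous and low-quality variants", {
  set.seed(51)
  dos <- matrix(rbinom(60, 2, 0.3), 10, 6)
  colnames(dos) <- paste0("v", 1:6)
  rownames(dos) <- paste0("i", 1:10)
  panel <- genotype_panel(dos, data.frame(
    variant_id = paste0("v", 1:6), chrom = "1", pos = 1:6 * 1000L,
    ref = c("A", "C", "A", "G", "T", "C"),
    alt = c("T", "G", "G", "T", "C", "T"),     # v1, v2 ambiguous
    imputation_r2 = c(0.9, 0.95, 0.59, 0.60, 0.8, 0.7)))
  stats <- make_stats(paste0("v", 1:6), pval = rep(0.01, 6))
  keep <- qc_filter(stats, panel)
  # hand enumeration: v1 (A/T), v2 (C/G) ambiguous; v3 r2 = 0.59 < 0.6;
  # v4 at the 0.60 boundary is retained
  expect_setequal(keep, c("v4", "v5", "v6"))
  expect_equal(attr(keep, "qc_log")$n_low_info, 1L)
  expect_equal(attr(keep, "qc_log")$n_strand_ambiguous, 2L)
})

test_that("harmonize flips ref-coded effects and drops mismatches", {
  dos <- matrix(c(0, 1, 2, 2, 1, 0), 3, 2)
  panel <- make_panel(dos, ref = c("A", "A"), alt = c("G", "C"))
  stats <- as_sumstats(data.frame(
    variant_id = c("v1", "v2"), chrom = "1", pos = c(1000L, 2000L),
    effect_allele = c("A", "G"), other_allele = c("G", "A"),
    freq = 0.3, beta = c(0.5, 0.2), se = 0.02, pval = 0.5, n = 1e4))
  h <- harmonize(stats, panel)
  # v1: effect allele is the panel ref -> beta negated
  expect_equal(h$variant_id, "v1")
  expect_equal(h$beta, -0.5)
  expect_true(h$flipped)

  # flip identity: score on flipped beta equals original on 2 - dosage
  s1 <- sum(-0.5 * dos[, 1])
  s2 <- sum(0.5 * (2 - dos[, 1])) - 2 * 0.5 * nrow(dos)
  expect_equal(s1, s2)
})

test_that("clumping keeps independents and drops LD partners", {
  set.seed(52)
  base <- rbinom(200, 2, 0.4)
  dos <- cbind(v1 = base, v2 = base, v3 = rbinom(200, 2, 0.4))
  rownames(dos) <- paste0("i", 1:200)
  panel <- make_panel(dos)
  stats <- make_stats(c("v1", "v2", "v3"), pval = c(0.001, 0.5, 0.2))
  idx <- clump(stats, panel)
  expect_setequal(idx, c("v1", "v3"))    # v2 is a perfect copy of v1

  # all mutually independent -> everything retained
  set.seed(53)
  dos2 <- matrix(rbinom(600, 2, 0.4), 200, 3,
                 dimnames = list(paste0("i", 1:200), paste0("w", 1:3)))
  panel2 <- make_panel(dos2)
  stats2 <- make_stats(paste0("w", 1:3), pval = c(0.9, 0.5, 0.1))
  expect_setequal(clump(stats2, panel2), paste0("w", 1:3))
})

test_that("clumping equals the independent brute-force oracle", {
  set.seed(54)
  for (rep in 1:25) {
    m <- 50L; n <- 120L
    cfg <- sim_config(n_participants = n, n_variants = m, n_blocks = 10L,
                      block_rho = runif(1, 0.3, 0.9),
                      seed = 1000L + rep)
    panel <- generate_genotypes(cfg)
    pv <- runif(m)
    stats <- make_stats(panel$variants$variant_id, pval = pv)
    stats$pos <- panel$variants$pos
    mine <- clump(stats, panel,
                  clump_config(r2 = 0.1, window_kb = 20))
    oracle_idx <- clump_oracle(pv, panel$variants$chrom,
                               panel$variants$pos, panel$dosages,
                               r2_max = 0.1, window_kb = 20)
    expect_setequal(mine, panel$variants$variant_id[oracle_idx])
  }
})

test_that("scores are simple dosage-weighted sums, order-invariant", {
  dos <- matrix(c(1, 0, 2, 2, 2, 0), 3, 2)
  panel <- make_panel(dos)
  aligned <- data.frame(variant_id = c("v1", "v2"), beta = c(0.5, -0.2),
                        pval = c(1e-10, 1e-10), flipped = FALSE)
  res <- prs_score(panel, aligned, thresholds = 1, standardize = FALSE)
  expect_equal(unname(res$scores[1, 1]), 0.5 * 1 - 0.2 * 2)

  resr <- prs_score(panel, aligned[2:1, ], thresholds = 1,
                    standardize = FALSE)
  expect_equal(res$scores, resr$scores)

  null <- prs_score(panel, transform(aligned, beta = 0), thresholds = 1,
                    standardize = FALSE)
  expect_true(all(null$scores == 0))
})

test_that("variant count and score variance grow with the threshold", {
  st <- small_study()
  res <- prs_pipeline(st$sumstats$MDD, st$panel, standardize = FALSE)
  expect_true(all(diff(res$n_variants) >= 0))
  vars <- apply(res$scores, 2, var)
  expect_true(all(diff(vars) >= -1e-12))
})

test_that("missing dosages abort scoring", {
  dos <- matrix(c(1, NA, 2, 2, 2, 0), 3, 2)
  panel <- list(dosages = dos, variants = data.frame(
    variant_id = c("v1", "v2")))
  class(panel) <- "genotype_panel"
  colnames(panel$dosages) <- c("v1", "v2")
  aligned <- data.frame(variant_id = c("v1", "v2"), beta = c(0.5, -0.2),
                        pval = 0.5, flipped = FALSE)
  expect_error(prs_score(panel, aligned), "missing dosages")
})

test_that("PC1 separates two simulated subpopulations", {
  set.seed(55)
  n <- 150; m <- 80
  pop <- rep(0:1, each = n / 2)
  f1 <- runif(m, 0.1, 0.4)
  f2 <- pmin(f1 + runif(m, 0.1, 0.3), 0.9)
  dos <- t(vapply(pop, function(p) {
    rbinom(m, 2, if (p == 1) f2 else f1)
  }, numeric(m)))
  panel <- make_panel(dos)
  pcs <- pca_covariates(panel, 5)
  expect_gt(abs(cor(pcs[, 1], pop)), 0.9)
  # orthogonal within tolerance
  g <- crossprod(pcs)
  expect_lt(max(abs(g[upper.tri(g)])), 1e-8)
  # rank bound error names the achievable k
  expect_error(pca_covariates(panel, 10000), "achievable rank")
})

test_that("PRS at the loosest threshold tracks the true genetic score", {
  cfg <- sim_config(n_participants = 2000L, n_variants = 300L,
                    n_blocks = 30L, seed = 57L)
  st <- simulate_study(cfg)
  g <- attr(st$cohort, "truth")$genetic_scores[, "BMI"]
  res <- prs_pipeline(st$sumstats$BMI, st$panel)
  expect_gt(cor(res$scores[, 8], g), 0.5)
})
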