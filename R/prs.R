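# Polygenic risk scoring by clumping and thresholding.
#
# QC removes low-imputation-quality (r2 < 0.6, strictly) and
# strand-ambiguous (A/T, C/G) variants; greedy clumping (p1 = 1, p2 = 1,
# r2 = 0.1, window 10,000 kb) picks approximately LD-independent index
# variants by ascending p-value, with LD computed in the target panel
# itself; scores are dosage-weighted sums of harmonized effect sizes at a
# ladder of eight p-value cutoffs. Pre-computed external weights (e.g.
# from a Bayesian shrinkage method) can be supplied as a sumstats-shaped
# file with p = 0-like placeholder below every threshold, bypassing
# thresholding.

#' The eight p-value thresholds of the scoring ladder
#' @return numeric vector of the eight cutoffs.
#' @export
prs_thresholds <- function() c(5e-8, 1e-5, 0.001, 0.01, 0.05, 0.1, 0.5, 1)

#' Clumping configuration
#' @param p1,p2 index/secondary p-value ceilings (default 1, "conservative"
#'   clumping: every variant is eligible).
#' @param r2 LD pruning threshold (squared dosage correlation), default 0.1.
#' @param window_kb clumping window in kilobases, default 10,000.
#' @return a `clump_config` list.
#' @export
clump_config <- function(p1 = 1, p2 = 1, r2 = 0.1, window_kb = 10000) {
  stopifnot(r2 > 0, r2 < 1, window_kb > 0, p1 > 0, p1 <= 1, p2 > 0, p2 <= 1)
  structure(list(p1 = p1, p2 = p2, r2 = r2, window_kb = window_kb),
            class = "clump_config")
}

is_strand_ambiguous <- function(a1, a2) {
  (a1 == "A" & a2 == "T") | (a1 == "T" & a2 == "A") |
    (a1 == "C" & a2 == "G") | (a1 == "G" & a2 == "C")
}

#' Quality-control filter for scoring variants
#'
#' Restricts to variants present in both the summary statistics and the
#' panel, then removes those with imputation `r2 < 0.6` (strictly less
#' than: 0.60 itself is retained) or strand-ambiguous A/T and C/G allele
#' pairs (judged on the panel's ref/alt). Removal counts are logged and
#' attached as the `"qc_log"` attribute.
#'
#' @param stats a `sumstats` data.frame.
#' @param panel a `genotype_panel`.
#' @param min_info imputation-quality floor (default 0.6).
#' @return character vector of retained variant ids.
#' @export
qc_filter <- function(stats, panel, min_info = 0.6) {
  v <- panel$variants
  shared <- intersect(stats$variant_id, v$variant_id)
  vv <- v[match(shared, v$variant_id), , drop = FALSE]
  low_info <- vv$imputation_r2 < min_info
  ambiguous <- is_strand_ambiguous(vv$ref, vv$alt)
  keep <- shared[!low_info & !ambiguous]
  log <- list(n_input_stats = nrow(stats), n_shared = length(shared),
              n_low_info = sum(low_info),
              n_strand_ambiguous = sum(ambiguous & !low_info),
              n_retained = length(keep))
  sidefx_log("qc_filter: ", log$n_shared, " shared; removed ",
             log$n_low_info, " low-quality and ",
             log$n_strand_ambiguous, " strand-ambiguous; retained ",
             log$n_retained)
  attr(keep, "qc_log") <- log
  keep
}

#' Harmonize GWAS effect alleles to the panel's alt allele
#'
#' Where the effect allele equals the panel's alt allele the effect size is
#' kept; where it equals the ref allele the effect size is negated (the
#' alt-dosage of the effect allele is `2 - dosage`, an equivalent flip);
#' variants whose allele pairs do not match the panel are dropped with a
#' log entry.
#'
#' @param stats a `sumstats` data.frame.
#' @param panel a `genotype_panel`.
#' @param variants optional subset of variant ids (default: all shared).
#' @return data.frame: variant_id, beta (aligned to alt dosage), pval,
#'   flipped flag.
#' @export
harmonize <- function(stats, panel, variants = NULL) {
  v <- panel$variants
  if (is.null(variants)) variants <- intersect(stats$variant_id,
                                               v$variant_id)
  s <- stats[match(variants, stats$variant_id), , drop = FALSE]
  pv <- v[match(variants, v$variant_id), , drop = FALSE]
  same <- s$effect_allele == pv$alt & s$other_allele == pv$ref
  flip <- s$effect_allele == pv$ref & s$other_allele == pv$alt
  drop <- !(same | flip)
  if (any(drop)) {
    sidefx_log("harmonize: dropped ", sum(drop),
               " variant(s) with mismatching allele pairs")
  }
  data.frame(variant_id = variants[!drop],
             beta = ifelse(flip[!drop], -s$beta[!drop], s$beta[!drop]),
             pval = s$pval[!drop],
             flipped = flip[!drop],
             stringsAsFactors = FALSE)
}

#' Greedy LD clumping
#'
#' Sorts eligible variants by ascending p-value (ties by chromosome then
#' position), repeatedly takes the best remaining variant as an index and
#' removes every remaining variant on the same chromosome within
#' `window_kb` whose squared dosage correlation with the index exceeds
#' `cfg$r2`. LD is computed in the target panel (in-sample). Variants in
#' the statistics but absent from the panel are skipped with a log entry.
#'
#' @param stats a `sumstats` data.frame (or harmonized subset with columns
#'   variant_id, pval).
#' @param panel a `genotype_panel`.
#' @param cfg a [clump_config()].
#' @param variants optional pre-filtered variant ids (e.g. [qc_filter()]
#'   output).
#' @return character vector of index variant ids (ascending p order).
#' @export
clump <- function(stats, panel, cfg = clump_config(), variants = NULL) {
  v <- panel$variants
  ids <- if (is.null(variants)) stats$variant_id else variants
  absent <- setdiff(ids, v$variant_id)
  if (length(absent) > 0L) {
    sidefx_log("clump: ", length(absent),
               " variant(s) absent from panel; skipped")
    ids <- setdiff(ids, absent)
  }
  s <- stats[match(ids, stats$variant_id), , drop = FALSE]
  meta <- v[match(ids, v$variant_id), , drop = FALSE]
  elig <- s$pval <= cfg$p2
  ids <- ids[elig]; s <- s[elig, , drop = FALSE]
  meta <- meta[elig, , drop = FALSE]
  if (length(ids) == 0L) return(character(0))
  ord <- order(s$pval, meta$chrom, meta$pos)
  ids <- ids[ord]; s <- s[ord, , drop = FALSE]
  meta <- meta[ord, , drop = FALSE]
  X <- panel$dosages[, ids, drop = FALSE]
  sds <- apply(X, 2L, stats::sd)
  remaining <- seq_along(ids)
  index <- integer(0)
  while (length(remaining) > 0L) {
    i <- remaining[1L]
    if (s$pval[i] > cfg$p1) break
    index <- c(index, i)
    remaining <- remaining[-1L]
    if (length(remaining) == 0L) break
    cand <- remaining[meta$chrom[remaining] == meta$chrom[i] &
                        abs(meta$pos[remaining] - meta$pos[i]) <=
                        cfg$window_kb * 1000]
    if (length(cand) > 0L) {
      r <- rep(0, length(cand))
      ok <- sds[cand] > 0 & sds[i] > 0
      if (any(ok)) {
        r[ok] <- as.vector(stats::cor(X[, i], X[, cand[ok], drop = FALSE]))
      }
      kill <- cand[r^2 > cfg$r2]
      remaining <- setdiff(remaining, kill)
    }
  }
  ids[index]
}

#' Dosage-weighted polygenic scores at a threshold ladder
#'
#' For each p-value cutoff, the score is the sum over selected variants of
#' the harmonized effect size times the alt-allele dosage. Missing dosages
#' are a hard error (the generator never produces them; the contract stays
#' visible).
#'
#' @param panel a `genotype_panel`.
#' @param aligned output of [harmonize()] restricted to clumped index
#'   variants.
#' @param thresholds p-value cutoffs (default the eight-threshold ladder).
#' @param standardize scale each column to zero mean, unit variance
#'   (default TRUE; the flag is recorded in the result).
#' @return object of class `prs_result`: `scores` (participants x
#'   thresholds matrix), `n_variants` per threshold, `thresholds`,
#'   `standardized`.
#' @export
prs_score <- function(panel, aligned, thresholds = prs_thresholds(),
                      standardize = TRUE) {
  if (anyNA(panel$dosages)) {
    stop("prs_score: missing dosages are not supported", call. = FALSE)
  }
  X <- panel$dosages[, aligned$variant_id, drop = FALSE]
  scores <- matrix(0, nrow(X), length(thresholds),
                   dimnames = list(rownames(X),
                                   paste0("p_", format(thresholds,
                                                       scientific = FALSE,
                                                       trim = TRUE,
                                                       drop0trailing = TRUE))))
  n_var <- integer(length(thresholds))
  for (t in seq_along(thresholds)) {
    # strict "<" at every cutoff, as the clumping-and-thresholding
    # procedure prints them; external weight files encode "always keep"
    # as pval = 0
    sel <- aligned$pval < thresholds[t]
    n_var[t] <- sum(sel)
    if (any(sel)) {
      scores[, t] <- as.vector(X[, sel, drop = FALSE] %*%
                                 aligned$beta[sel])
    }
  }
  if (standardize) {
    for (t in seq_along(thresholds)) {
      s <- stats::sd(scores[, t])
      if (s > 0) scores[, t] <- (scores[, t] - mean(scores[, t])) / s
    }
  }
  structure(list(scores = scores, n_variants = n_var,
                 thresholds = thresholds, standardized = standardize),
            class = "prs_result")
}

#' Full clumping-and-thresholding PRS for one trait
#'
#' QC filter, allele harmonization, greedy clumping and threshold-ladder
#' scoring in one call; the per-stage variant counts are attached as the
#' `"prs_log"` attribute.
#'
#' @param stats a `sumstats` data.frame.
#' @param panel a `genotype_panel`.
#' @param cfg a [clump_config()].
#' @inheritParams prs_score
#' @return a `prs_result`.
#' @export
prs_pipeline <- function(stats, panel, cfg = clump_config(),
                         thresholds = prs_thresholds(),
                         standardize = TRUE) {
  keep <- qc_filter(stats, panel)
  aligned <- harmonize(stats, panel, keep)
  idx <- clump(stats, panel, cfg, aligned$variant_id)
  res <- prs_score(panel, aligned[match(idx, aligned$variant_id), ,
                                  drop = FALSE],
                   thresholds, standardize)
  attr(res, "prs_log") <- c(attr(keep, "qc_log"),
                            list(n_harmonized = nrow(aligned),
                                 n_index = length(idx),
                                 n_per_threshold = res$n_variants))
  res
}

#' Genetic principal components for covariate adjustment
#'
#' PCs of the column-standardized dosage matrix (zero-variance variants
#' dropped). Sign convention: each component's largest-magnitude loading
#' is made positive, so results are reproducible across runs.
#'
#' @param panel a `genotype_panel`.
#' @param k number of components (default 20).
#' @return matrix participants x k of PC coordinates (columns `PC1`...).
#' @export
pca_covariates <- function(panel, k = 20L) {
  X <- panel$dosages
  sds <- apply(X, 2L, stats::sd)
  X <- X[, sds > 0, drop = FALSE]
  X <- scale(X)
  maxk <- min(nrow(X) - 1L, ncol(X))
  if (k > maxk) {
    stop("pca_covariates: k = ", k, " exceeds achievable rank ", maxk,
         call. = FALSE)
  }
  pc <- stats::prcomp(X, center = FALSE, scale. = FALSE, rank. = k)
  for (j in seq_len(k)) {
    if (pc$rotation[which.max(abs(pc$rotation[, j])), j] < 0) {
      pc$x[, j] <- -pc$x[, j]
      pc$rotation[, j] <- -pc$rotation[, j]
    }
  }
  out <- pc$x[, seq_len(k), drop = FALSE]
  colnames(out) <- paste0("PC", seq_len(k))
  rownames(out) <- rownames(panel$dosages)
  out
}
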