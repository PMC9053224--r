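# Synthetic cohort generator.
#
# Emulates the statistical structure the downstream analyses assume:
# binary side-effect endorsements from a liability-threshold bifactor model
# (orthogonal general factor plus SSRI and SNRI drug-class factors),
# medication-exposure-driven missingness, a true polygenic component flowing
# from block-LD genotypes into the liabilities, and sex/age effects.

# Default per-effect endorsement prevalence among exposed participants,
# chosen to resemble the published sex-pooled margins of a large
# Australian antidepressant cohort.
.DEFAULT_PREV <- c(
  reduced_sex_drive = 0.40, weight_gain = 0.34, dry_mouth = 0.28,
  nausea = 0.25, drowsiness = 0.23, insomnia = 0.23, dizziness = 0.23,
  fatigue = 0.20, sweating = 0.20, headache = 0.19,
  suicidal_thoughts = 0.16, anxiety = 0.18, agitation = 0.17,
  shaking = 0.15, constipation = 0.09, diarrhoea = 0.07,
  suicide_attempt = 0.06, blurred_vision = 0.06, muscle_pain = 0.05,
  vomiting = 0.05, weight_loss = 0.05, runny_nose = 0.02, rash = 0.015,
  other = 0.12)

# Drug-class factor loadings for the side effects the class factors act on
# (SNRI-specific sweating/insomnia/suicidality, SSRI-specific nausea/
# vomiting/drowsiness, both for dizziness and constipation).
.DEFAULT_CLASS_LOADINGS <- list(
  SSRI = c(nausea = 0.35, vomiting = 0.35, drowsiness = 0.35,
           dizziness = 0.35, constipation = 0.35),
  SNRI = c(sweating = 0.35, insomnia = 0.35, suicidal_thoughts = 0.35,
           suicide_attempt = 0.35, dizziness = 0.35, constipation = 0.35))

# Liability-scale genetic paths: side effect -> (GWAS trait, gamma).
.DEFAULT_GENETIC <- data.frame(
  side_effect = c("weight_gain", "insomnia", "headache",
                  "suicidal_thoughts", "suicide_attempt", "anxiety"),
  trait = c("BMI", "INSOMNIA", "HEADACHE", "MDD", "MDD", "MDD"),
  gamma = c(0.12, 0.10, 0.10, 0.15, 0.15, 0.10),
  stringsAsFactors = FALSE)

# Additive liability shift for females (sex coded female = 1).
.DEFAULT_SEX_EFFECTS <- c(
  reduced_sex_drive = -0.12, weight_gain = 0.20, nausea = 0.30,
  headache = 0.20, dizziness = 0.15, shaking = 0.15, vomiting = 0.30,
  weight_loss = 0.20)

#' Simulation configuration
#'
#' Builds the generative configuration for the synthetic cohort. Defaults
#' mirror the cohort the pipeline was designed around: 20,941 participants,
#' 75.6% female, age 43 (sd 15.3), exposure probabilities declining across
#' the ten medications, a strong general liability factor (0.75) on every
#' side effect with SSRI/SNRI class factors (0.35) on class-specific
#' effects, and modest genetic (gamma <= 0.15) and sex paths.
#'
#' @param n_participants cohort size.
#' @param seed integer master seed; every generator call derives its stream
#'   from it.
#' @param sex_frac_female probability a participant is female.
#' @param age_mean,age_sd age distribution in years (normal, floored at 18).
#' @param exposure_probs named probability per medication of ever taking it.
#' @param general_loadings named vector (length 24: checklist + "other") of
#'   general-factor loadings.
#' @param class_loadings list with `SSRI` and `SNRI` named loading vectors.
#' @param prevalence named target endorsement prevalence among exposed;
#'   thresholds are `qnorm(1 - prevalence)`.
#' @param genetic_betas data.frame (side_effect, trait, gamma) of
#'   liability-scale genetic paths.
#' @param sex_effects named vector of additive female liability shifts.
#' @param effect_factor_cor fraction of each side effect's general-factor
#'   variance shared across side effects (0 = side effects independent,
#'   1 = one global propensity). The default 0.47 reproduces the observed
#'   ordering of within-side-effect (~0.57) versus across-side-effect
#'   (~0.27) median co-occurrence at the default loadings.
#' @param n_variants,n_blocks,block_rho,maf_range LD-block genotype panel:
#'   `n_variants` split evenly into `n_blocks`, within-block dosage
#'   correlation `block_rho`, per-block minor allele frequency uniform on
#'   `maf_range`.
#' @param frac_causal fraction of variants with nonzero true effect per trait.
#' @param h2_trait variance of the true genetic value `X b` per trait (the
#'   mini-genome's explained variance on the trait scale). The default
#'   0.01 makes a causal variant's discovery chi-square about
#'   `gwas_n * h2_trait / n_causal` (~ 30 at the defaults), comparable to
#'   real GWAS loci, so the p-value ladder is exercised rather than
#'   saturated.
#' @param gwas_n simulated discovery-GWAS sample size.
#' @param age_exposure_slope per-SD-age log-odds slope on exposure.
#' @param confound_exposure log-odds slope of the general factor on
#'   exposure (0 = exposure independent of liability, the default).
#' @param indication_gamma,indication_liability_effect control the optional
#'   "took amitriptyline for insomnia" flag: the first is the log-odds
#'   slope of the true insomnia genetic score on the flag, the second the
#'   additive liability effect of the flag on insomnia under amitriptyline.
#' @param emit_indication_flag emit the `ami_for_insomnia` column.
#' @return a validated `sim_config` list.
#' @export
sim_config <- function(n_participants = 20941L,
                       seed = 2021L,
                       sex_frac_female = 0.756,
                       age_mean = 43, age_sd = 15.3,
                       exposure_probs = NULL,
                       general_loadings = NULL,
                       class_loadings = .DEFAULT_CLASS_LOADINGS,
                       prevalence = .DEFAULT_PREV,
                       genetic_betas = .DEFAULT_GENETIC,
                       sex_effects = .DEFAULT_SEX_EFFECTS,
                       effect_factor_cor = 0.47,
                       n_variants = 1000L, n_blocks = 50L,
                       block_rho = 0.8, maf_range = c(0.05, 0.5),
                       frac_causal = 0.1, h2_trait = 0.01, gwas_n = 1e5,
                       age_exposure_slope = 0.1,
                       confound_exposure = 0,
                       indication_gamma = 0.2,
                       indication_liability_effect = 0,
                       emit_indication_flag = FALSE) {
  if (is.null(exposure_probs)) {
    exposure_probs <- c(sertraline = 0.55, escitalopram = 0.45,
                        venlafaxine = 0.35, fluoxetine = 0.30,
                        citalopram = 0.25, desvenlafaxine = 0.22,
                        duloxetine = 0.18, mirtazapine = 0.20,
                        amitriptyline = 0.15, paroxetine = 0.12)
  }
  sim_effects <- c(.CHECKLIST, "other")
  if (is.null(general_loadings)) {
    general_loadings <- stats::setNames(rep(0.75, length(sim_effects)),
                                        sim_effects)
  }
  cfg <- list(
    n_participants = as.integer(n_participants), seed = as.integer(seed),
    sex_frac_female = sex_frac_female, age_mean = age_mean, age_sd = age_sd,
    exposure_probs = exposure_probs,
    general_loadings = general_loadings,
    class_loadings = class_loadings,
    prevalence = prevalence,
    thresholds = stats::qnorm(1 - prevalence),
    genetic_betas = genetic_betas,
    sex_effects = sex_effects,
    effect_factor_cor = effect_factor_cor,
    n_variants = as.integer(n_variants), n_blocks = as.integer(n_blocks),
    block_rho = block_rho, maf_range = maf_range,
    frac_causal = frac_causal, h2_trait = h2_trait, gwas_n = gwas_n,
    age_exposure_slope = age_exposure_slope,
    confound_exposure = confound_exposure,
    indication_gamma = indication_gamma,
    indication_liability_effect = indication_liability_effect,
    emit_indication_flag = emit_indication_flag)
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

# class loading for (side effect, drug class), 0 when absent
class_loading_of <- function(cfg, cl, s) {
  v <- cfg$class_loadings[[cl]]
  if (is.null(v) || !(s %in% names(v))) return(0)
  unname(v[[s]])
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$n_participants > 0,
            cfg$effect_factor_cor >= 0, cfg$effect_factor_cor <= 1,
            all(cfg$exposure_probs > 0), all(cfg$exposure_probs <= 1),
            cfg$n_variants %% cfg$n_blocks == 0,
            cfg$block_rho >= 0, cfg$block_rho < 1,
            all(cfg$maf_range > 0), all(cfg$maf_range <= 0.5),
            identical(sort(names(cfg$exposure_probs)), sort(.DRUGS)))
  sim_effects <- names(cfg$general_loadings)
  # variance budget: residual variance must be non-negative per
  # (side effect, drug class) cell
  for (s in sim_effects) {
    lg <- cfg$general_loadings[[s]]
    gm <- cfg$genetic_betas$gamma[match(s, cfg$genetic_betas$side_effect)]
    if (is.na(gm)) gm <- 0
    for (cl in c("SSRI", "SNRI", "other")) {
      lc <- class_loading_of(cfg, cl, s)
      resid <- 1 - lg^2 - lc^2 - gm^2
      if (resid < 0) {
        stop("sim config error: liability variance budget exceeded for ",
             s, " (", cl, "): residual variance ", round(resid, 4),
             call. = FALSE)
      }
    }
  }
  invisible(cfg)
}

# latent within-block correlation that yields a target dosage correlation
# after dichotomizing at the MAF threshold (tetrachoric-style inversion)
latent_block_rho <- function(target, maf) {
  if (target <= 0) return(0)
  tau <- stats::qnorm(1 - maf)
  f <- function(r) {
    p11 <- pbvnorm(-tau, -tau, r)
    (p11 - maf^2) / (maf * (1 - maf)) - target
  }
  if (f(0.999999) < 0) return(0.999999)
  stats::uniroot(f, c(target, 0.999999), tol = 1e-9)$root
}

#' Generate a block-LD genotype panel
#'
#' Dosages are sums of two haplotypes; each haplotype arises from a
#' compound-symmetric latent Gaussian per block, dichotomized at the
#' allele-frequency threshold. The latent correlation is calibrated (by
#' tetrachoric inversion) so the realized *dosage* correlation within a
#' block matches `block_rho`; blocks are mutually independent. Each block
#' shares one MAF drawn uniformly from `maf_range` (equal within-block MAFs
#' are what make a common pairwise dosage correlation attainable).
#' Imputation quality `r2` is drawn from a mixture with 15% of mass below
#' 0.8 (10% below 0.6) so quality-control filters are exercised.
#'
#' @param config a [sim_config()].
#' @param n_individuals optional override of `config$n_participants`.
#' @param ids optional participant ids (default `P000001`, ...).
#' @return a [genotype_panel()].
#' @export
generate_genotypes <- function(config, n_individuals = NULL, ids = NULL) {
 with_seed(config$seed + 11L, {
  n <- if (is.null(n_individuals)) config$n_participants else n_individuals
  if (is.null(ids)) ids <- sprintf("P%06d", seq_len(n))
  m <- config$n_variants
  per_block <- m %/% config$n_blocks
  maf_block <- stats::runif(config$n_blocks, config$maf_range[1],
                            config$maf_range[2])
  dos <- matrix(0, n, m)
  for (b in seq_len(config$n_blocks)) {
    maf <- maf_block[b]
    tau <- stats::qnorm(1 - maf)
    rho_lat <- latent_block_rho(config$block_rho, maf)
    cols <- ((b - 1L) * per_block + 1L):(b * per_block)
    for (h in 1:2) {
      shared <- stats::rnorm(n)
      z <- sqrt(rho_lat) * matrix(shared, n, per_block) +
        sqrt(1 - rho_lat) * matrix(stats::rnorm(n * per_block), n, per_block)
      dos[, cols] <- dos[, cols] + (z > tau)
    }
  }
  # strand: alleles drawn uniformly over ordered distinct base pairs, so
  # about a third of variants are strand-ambiguous (A/T or C/G)
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, m, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), "")
  u <- stats::runif(m)
  r2 <- ifelse(u < 0.85, stats::runif(m, 0.8, 1),
               ifelse(u < 0.90, stats::runif(m, 0.6, 0.8),
                      stats::runif(m, 0.2, 0.6)))
  variants <- data.frame(
    variant_id = sprintf("rs%06d", seq_len(m)),
    chrom = "1",
    pos = seq_len(m) * 5000L,
    ref = unname(ref), alt = unname(alt),
    imputation_r2 = round(r2, 4),
    stringsAsFactors = FALSE)
  rownames(dos) <- ids
  colnames(dos) <- variants$variant_id
  genotype_panel(dos, variants)
 })
}

#' Generate true per-variant effects for each simulated trait
#'
#' A fraction `frac_causal` of variants per trait receive normal effects;
#' traits are drawn independently. When a panel is supplied, each trait's
#' effect vector is rescaled so the realized genetic value `X b` has
#' variance `config$h2_trait` in that panel.
#'
#' @param config a [sim_config()].
#' @param traits trait labels (default: those in `config$genetic_betas`).
#' @param panel optional [genotype_panel()] used to calibrate the variance
#'   of the genetic value.
#' @return matrix variants x traits of true allelic effects.
#' @export
generate_trait_effects <- function(config, traits = NULL, panel = NULL) {
  if (is.null(traits)) traits <- unique(config$genetic_betas$trait)
 with_seed(config$seed + 23L, {
  m <- config$n_variants
  eff <- matrix(0, m, length(traits), dimnames = list(NULL, traits))
  for (t in seq_along(traits)) {
    causal <- stats::runif(m) < config$frac_causal
    eff[causal, t] <- stats::rnorm(sum(causal))
    if (!is.null(panel) && any(causal)) {
      v <- stats::var(as.vector(panel$dosages %*% eff[, t]))
      if (v > 0) eff[, t] <- eff[, t] * sqrt(config$h2_trait / v)
    }
  }
  eff
 })
}

#' Simulate GWAS summary statistics for one trait
#'
#' Marginal per-variant effects are the population regression of the true
#' genetic value on each variant's dosage (so LD partners of causal
#' variants carry signal), plus sampling noise with
#' `se = 1 / sqrt(2 * maf * (1 - maf) * gwas_n)`; p-values come from the
#' two-sided Wald statistic.
#'
#' @param config a [sim_config()].
#' @param panel a [genotype_panel()].
#' @param true_betas per-variant true allelic effects (one trait).
#' @param stream integer offset so different traits get independent noise.
#' @return a `sumstats` data.frame.
#' @export
generate_gwas <- function(config, panel, true_betas, stream = 0L) {
  stopifnot(length(true_betas) == ncol(panel$dosages))
 with_seed(config$seed + 37L + stream, {
  X <- panel$dosages
  g <- as.vector(X %*% true_betas)
  xbar <- colMeans(X)
  vx <- apply(X, 2L, stats::var)
  vx[vx == 0] <- NA
  beta_marg <- as.vector(crossprod(X - rep(xbar, each = nrow(X)),
                                   g - mean(g))) / (nrow(X) - 1) / vx
  beta_marg[is.na(beta_marg)] <- 0
  freq <- xbar / 2
  maf <- pmin(freq, 1 - freq)
  se <- 1 / sqrt(2 * pmax(maf, 1e-4) * (1 - pmax(maf, 1e-4)) * config$gwas_n)
  beta_hat <- beta_marg + stats::rnorm(length(se)) * se
  z <- beta_hat / se
  pval <- pmax(2 * stats::pnorm(-abs(z)), .Machine$double.xmin)
  as_sumstats(data.frame(
    variant_id = panel$variants$variant_id,
    chrom = panel$variants$chrom,
    pos = panel$variants$pos,
    effect_allele = panel$variants$alt,
    other_allele = panel$variants$ref,
    freq = freq, beta = beta_hat, se = se, pval = pval,
    n = config$gwas_n, stringsAsFactors = FALSE))
 })
}

#' Generate a synthetic cohort of side-effect endorsements
#'
#' Per participant, orthogonal standard-normal factors `F` (general),
#' `C_SSRI` and `C_SNRI` are drawn once and shared across that
#' participant's medications — the mechanism that makes side effects
#' co-occur across medications. For each medication taken and side effect
#' `s`, endorsement occurs iff
#' `lambda_g[s]*F + lambda_class[s]*C_class + gamma[s]*G_trait +
#'  delta[s]*female + e > tau[s]`
#' with `e` normal and residual variance chosen so the total liability
#' variance is 1. `G_trait` is the standardized true polygenic score from
#' the panel. Exposure is sampled per medication with a log-odds age slope
#' and (optionally) a liability-confounding slope.
#'
#' @param config a [sim_config()].
#' @param panel a [genotype_panel()] with one row per participant; if
#'   `NULL`, genetic paths are silently dropped (gamma = 0).
#' @param trait_effects optional matrix from [generate_trait_effects()].
#' @return a `cohort_table`; attribute `"truth"` records the latent factors,
#'   standardized genetic scores and all generative parameters.
#' @export
generate_cohort <- function(config, panel = NULL, trait_effects = NULL) {
 with_seed(config$seed + 53L, {
  n <- config$n_participants
  ids <- if (!is.null(panel)) rownames(panel$dosages) else
    sprintf("P%06d", seq_len(n))
  stopifnot(length(ids) == n)
  female <- stats::rbinom(n, 1L, config$sex_frac_female)
  age <- pmax(stats::rnorm(n, config$age_mean, config$age_sd), 18)
  zage <- (age - config$age_mean) / config$age_sd

  sim_effects <- names(config$general_loadings)
  traits <- unique(config$genetic_betas$trait)
  G <- matrix(0, n, length(traits), dimnames = list(NULL, traits))
  if (!is.null(panel)) {
    if (is.null(trait_effects)) trait_effects <- generate_trait_effects(config)
    for (t in traits) {
      raw <- as.vector(panel$dosages %*% trait_effects[, t])
      G[, t] <- if (stats::sd(raw) > 0) (raw - mean(raw)) / stats::sd(raw)
      else 0
    }
  }

  # Per side effect s, the general factor is
  #   F_s = sqrt(w) F_common + sqrt(1 - w) F_s_specific,
  # so endorsements of the same side effect correlate fully through F_s
  # across medications while different side effects share only the
  # common fraction w of their propensity variance. Class factors are
  # specific to each (side effect, drug class).
  w <- config$effect_factor_cor
  Fc <- stats::rnorm(n)
  nS <- length(sim_effects)
  Fs <- sqrt(w) * Fc + sqrt(1 - w) *
    matrix(stats::rnorm(n * nS), n, nS, dimnames = list(NULL, sim_effects))
  Cssri <- matrix(stats::rnorm(n * nS), n, nS,
                  dimnames = list(NULL, sim_effects))
  Csnri <- matrix(stats::rnorm(n * nS), n, nS,
                  dimnames = list(NULL, sim_effects))

  # exposure per medication (independent of liability unless confounded)
  cls <- stats::setNames(drug_class_map()$class, drug_class_map()$drug)
  exposure <- matrix(0L, n, length(.DRUGS), dimnames = list(NULL, .DRUGS))
  for (d in .DRUGS) {
    lp <- stats::qlogis(config$exposure_probs[[d]]) +
      config$age_exposure_slope * zage + config$confound_exposure * Fc
    exposure[, d] <- stats::rbinom(n, 1L, stats::plogis(lp))
  }

  # optional indication flag: amitriptyline prescribed for insomnia
  ami_flag <- NULL
  if (config$emit_indication_flag) {
    g_ins <- if ("INSOMNIA" %in% traits) G[, "INSOMNIA"] else 0
    lp <- stats::qlogis(0.3) + config$indication_gamma * g_ins
    ami_flag <- as.integer(exposure[, "amitriptyline"] == 1L &
                             stats::rbinom(n, 1L, stats::plogis(lp)) == 1L)
  }

  out <- data.frame(participant_id = ids,
                    sex = ifelse(female == 1L, "female", "male"),
                    age = round(age, 1), stringsAsFactors = FALSE)
  for (d in .DRUGS) out[[exposure_col(d)]] <- exposure[, d]

  endorse <- matrix(NA_integer_, n, length(.DRUGS) * length(.EFFECTS))
  colnames(endorse) <- as.vector(vapply(
    .DRUGS, function(d) endorse_col(d, .EFFECTS),
    character(length(.EFFECTS))))
  for (d in .DRUGS) {
    taken <- exposure[, d] == 1L
    nd <- sum(taken)
    if (nd == 0L) next
    dclass <- cls[[d]]
    any_endorsed <- rep(FALSE, nd)
    for (s in sim_effects) {
      lg <- config$general_loadings[[s]]
      lc <- class_loading_of(config, dclass, s)
      i <- match(s, config$genetic_betas$side_effect)
      gm <- if (is.na(i)) 0 else config$genetic_betas$gamma[i]
      gscore <- if (is.na(i)) 0 else G[taken, config$genetic_betas$trait[i]]
      dl <- if (s %in% names(config$sex_effects))
        config$sex_effects[[s]] else 0
      resid_sd <- sqrt(1 - lg^2 - lc^2 - gm^2)
      cfac <- if (dclass == "SSRI") Cssri[taken, s] else
        if (dclass == "SNRI") Csnri[taken, s] else 0
      liab <- lg * Fs[taken, s] + lc * cfac + gm * gscore +
        dl * female[taken] + resid_sd * stats::rnorm(nd)
      if (s == "insomnia" && d == "amitriptyline" &&
          !is.null(ami_flag) && config$indication_liability_effect != 0) {
        liab <- liab + config$indication_liability_effect * ami_flag[taken]
      }
      y <- as.integer(liab > config$thresholds[[s]])
      col <- paste0("se_", d, "_", s)
      endorse[taken, col] <- y
      any_endorsed <- any_endorsed | y == 1L
    }
    endorse[taken, paste0("se_", d, "_none")] <-
      as.integer(!any_endorsed)
  }
  out <- cbind(out, as.data.frame(endorse))
  if (!is.null(ami_flag)) out$ami_for_insomnia <- ami_flag
  cohort <- as_cohort_table(out)
  attr(cohort, "truth") <- list(
    common_factor = Fc,
    effect_factors = Fs,
    class_factors = list(SSRI = Cssri, SNRI = Csnri),
    genetic_scores = G,
    config = config)
  cohort
 })
}

#' Generate every input the pipeline consumes
#'
#' Convenience wrapper: genotypes, per-trait true effects, per-trait GWAS
#' summary statistics and the cohort, all from one configuration and seed.
#'
#' @param config a [sim_config()].
#' @return list with `panel`, `trait_effects`, `sumstats` (named list per
#'   trait) and `cohort`.
#' @export
simulate_study <- function(config) {
  panel <- generate_genotypes(config)
  eff <- generate_trait_effects(config, panel = panel)
  ss <- lapply(seq_len(ncol(eff)), function(t) {
    generate_gwas(config, panel, eff[, t], stream = t)
  })
  names(ss) <- colnames(eff)
  cohort <- generate_cohort(config, panel, eff)
  list(panel = panel, trait_effects = eff, sumstats = ss, cohort = cohort)
}
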