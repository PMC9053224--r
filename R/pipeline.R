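# End-to-end orchestration: simulate -> descriptives -> cooccurrence ->
# sem -> prs -> assoc, from a single configuration with one seed,
# writing every table plus a manifest of output hashes.

#' Default pipeline configuration
#'
#' All analysis defaults mirror the published procedure: clump r2 = 0.1
#' over a 10,000 kb window, the eight p-value thresholds, 20 principal
#' components, and the Bonferroni families. Simulation defaults come from
#' [sim_config()]; the demo scale is reduced so a full run takes minutes.
#'
#' @param seed master seed.
#' @param overrides named list merged over the defaults (nested lists are
#'   merged one level deep).
#' @return a `run_config` list.
#' @export
run_config <- function(seed = 2021L, overrides = list()) {
  cfg <- list(
    seed = as.integer(seed),
    sim = list(n_participants = 1500L, n_variants = 400L, n_blocks = 40L,
               block_rho = 0.8, gwas_n = 1e5, emit_indication_flag = TRUE),
    cooccurrence = list(min_pair_n = 30L,
                        medications = .DRUGS,
                        side_effects = c("nausea", "headache", "insomnia",
                                         "sweating", "weight_gain",
                                         "dizziness")),
    sem = list(side_effects = c("sweating", "nausea"), nodes = 15L,
               starts = 2L),
    prs = list(r2 = 0.1, window_kb = 10000, k_pcs = 20L,
               thresholds = prs_thresholds(), standardize = TRUE),
    assoc = list(
      cells = data.frame(
        trait = c("BMI", "INSOMNIA", "HEADACHE", "MDD"),
        side_effect = c("weight_gain", "insomnia", "headache",
                        "suicidal_thoughts"),
        stringsAsFactors = FALSE),
      family = "per_drug_10"))
  for (k in names(overrides)) {
    if (is.list(overrides[[k]]) && is.list(cfg[[k]])) {
      for (kk in names(overrides[[k]])) cfg[[k]][[kk]] <- overrides[[k]][[kk]]
    } else {
      cfg[[k]] <- overrides[[k]]
    }
  }
  class(cfg) <- "run_config"
  cfg
}

#' Read a pipeline configuration from YAML or JSON
#' @param path file ending in .yaml/.yml or .json.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) {
    stop("config error: file does not exist: ", path, call. = FALSE)
  }
  raw <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path) else
    jsonlite::read_json(path, simplifyVector = TRUE)
  seed <- raw$seed %||% 2021L
  raw$seed <- NULL
  run_config(seed = seed, overrides = raw)
}

fmt_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  path
}

#' Run the full pipeline
#'
#' Executes the stages in dependency order against a synthetic study
#' generated from the configuration, writing all outputs and a
#' `manifest.json` (parameters, seed, package version, per-file md5
#' hashes) into `out_dir`. A stage failure aborts downstream stages.
#'
#' @param config a `run_config` (or path readable by [read_run_config()]).
#' @param out_dir output directory (created if needed).
#' @return the manifest, invisibly.
#' @export
run_pipeline <- function(config = run_config(), out_dir) {
  if (is.character(config)) config <- read_run_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  outputs <- character(0)
  add <- function(path) outputs <<- c(outputs, path)

  # -- simulate ------------------------------------------------------------
  sim_args <- config$sim
  sim_args$seed <- config$seed
  scfg <- do.call(sim_config, sim_args)
  study <- simulate_study(scfg)
  add(fmt_tsv(study$cohort, file.path(out_dir, "phenotypes.tsv")))
  write_dosages(study$panel, file.path(out_dir, "dosages.tsv"))
  add(file.path(out_dir, "dosages.tsv"))
  add(file.path(out_dir, "dosages.tsv.variants.tsv"))
  for (tr in names(study$sumstats)) {
    add(fmt_tsv(study$sumstats[[tr]],
                file.path(out_dir, paste0("sumstats_", tr, ".tsv"))))
  }
  truth <- list(seed = config$seed,
                prevalence = as.list(scfg$prevalence),
                general_loadings = as.list(scfg$general_loadings),
                class_loadings = lapply(scfg$class_loadings, as.list),
                genetic = scfg$genetic_betas)
  jsonlite::write_json(truth, file.path(out_dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  add(file.path(out_dir, "truth.json"))

  # -- descriptives --------------------------------------------------------
  prev <- prevalence_table(study$cohort)
  prev[c("prev", "ci_low", "ci_high")] <-
    lapply(prev[c("prev", "ci_low", "ci_high")], function(v) signif(v, 8))
  add(fmt_tsv(prev, file.path(out_dir, "prevalence.tsv")))
  t1 <- table_one_tests(study$cohort)
  t1[sapply(t1, is.numeric)] <- lapply(t1[sapply(t1, is.numeric)],
                                       function(v) signif(v, 8))
  add(fmt_tsv(t1, file.path(out_dir, "tests.tsv")))

  # -- cooccurrence --------------------------------------------------------
  cc <- config$cooccurrence
  tm <- tetra_matrix(study$cohort, medications = cc$medications,
                     side_effects = cc$side_effects,
                     min_pair_n = cc$min_pair_n)
  add(fmt_tsv(data.frame(label = rownames(tm$rho),
                         signif(as.data.frame(tm$rho), 8),
                         check.names = FALSE),
              file.path(out_dir, "rho.tsv")))
  add(fmt_tsv(data.frame(label = rownames(tm$n_pair),
                         as.data.frame(tm$n_pair), check.names = FALSE),
              file.path(out_dir, "npair.tsv")))
  tree <- ward_cluster(corr_to_dist(tm))
  add(fmt_tsv(data.frame(node_a = tree$merge[, 1], node_b = tree$merge[, 2],
                         height = signif(tree$height, 8)),
              file.path(out_dir, "linkage.tsv")))
  med <- summarize_cooccurrence(tm)
  jsonlite::write_json(
    lapply(med, function(m) list(median = signif(m$median, 8),
                                 n_pairs = m$n_pairs)),
    file.path(out_dir, "medians.json"), auto_unbox = TRUE, digits = NA)
  add(file.path(out_dir, "medians.json"))

  # -- sem -----------------------------------------------------------------
  sem <- run_all_side_effects(study$cohort,
                              side_effects = config$sem$side_effects,
                              nodes = config$sem$nodes,
                              starts = config$sem$starts,
                              seed = config$seed)
  sem[sapply(sem, is.numeric)] <- lapply(sem[sapply(sem, is.numeric)],
                                         function(v) signif(v, 8))
  add(fmt_tsv(sem, file.path(out_dir, "sem_comparisons.tsv")))

  # -- prs -----------------------------------------------------------------
  ccfg <- clump_config(r2 = config$prs$r2, window_kb = config$prs$window_kb)
  prs_list <- lapply(study$sumstats, function(ss) {
    prs_pipeline(ss, study$panel, ccfg, config$prs$thresholds,
                 config$prs$standardize)
  })
  prs_tab <- data.frame(participant_id = rownames(study$panel$dosages),
                        stringsAsFactors = FALSE)
  for (tr in names(prs_list)) {
    sc <- prs_list[[tr]]$scores
    colnames(sc) <- paste0(tr, "_", colnames(sc))
    prs_tab <- cbind(prs_tab, signif(as.data.frame(sc), 8))
  }
  add(fmt_tsv(prs_tab, file.path(out_dir, "prs.tsv")))
  pcs <- pca_covariates(study$panel, config$prs$k_pcs)
  add(fmt_tsv(data.frame(participant_id = rownames(pcs),
                         signif(as.data.frame(pcs), 8)),
              file.path(out_dir, "pcs.tsv")))
  jsonlite::write_json(lapply(prs_list, function(p) attr(p, "prs_log")),
                       file.path(out_dir, "prs_log.json"),
                       auto_unbox = TRUE, digits = NA)
  add(file.path(out_dir, "prs_log.json"))

  # -- assoc ---------------------------------------------------------------
  cells <- config$assoc$cells
  res <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    tr <- cells$trait[i]
    sc <- prs_list[[tr]]$scores[, ncol(prs_list[[tr]]$scores)]
    assoc_scan(study$cohort, sc, cells$side_effect[i], pcs,
               medications = c("pooled", .DRUGS), prs_trait = tr)
  }))
  res <- bonferroni_family(res, config$assoc$family)
  num <- sapply(res, is.numeric)
  res[num] <- lapply(res[num], function(v) signif(v, 8))
  add(fmt_tsv(res, file.path(out_dir, "assoc.tsv")))

  manifest <- list(
    seed = config$seed,
    package_version = as.character(utils::packageVersion("sidefx")),
    parameters = list(sim = config$sim, cooccurrence = config$cooccurrence,
                      sem = config$sem, prs = config$prs,
                      assoc_family = config$assoc$family),
    outputs = lapply(stats::setNames(outputs, basename(outputs)),
                     function(f) unname(tools::md5sum(f))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
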