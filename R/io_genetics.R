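# GWAS summary statistics and genotype dosage I/O.
#
# Coordinates are 1-based as in VCF; dosages count copies of the alt allele
# and must lie in [0, 2] (out-of-range is an error, never clipped).

# Header alias table for summary statistics. First match wins; matching is
# case-insensitive. Documented in the README.
.SUMSTAT_ALIASES <- list(
  variant_id    = c("variant_id", "snp", "id", "rsid", "markername"),
  chrom         = c("chrom", "chr", "chromosome"),
  pos           = c("pos", "bp", "position", "base_pair_location"),
  effect_allele = c("effect_allele", "a1", "ea", "allele1"),
  other_allele  = c("other_allele", "a2", "oa", "nea", "allele2"),
  freq          = c("freq", "eaf", "af", "maf", "frq"),
  beta          = c("beta", "b", "effect"),
  se            = c("se", "stderr", "standard_error"),
  pval          = c("pval", "p", "p_value", "pvalue"),
  n             = c("n", "ntotal", "n_total")
)

resolve_aliases <- function(headers) {
  lower <- tolower(headers)
  out <- vapply(names(.SUMSTAT_ALIASES), function(field) {
    hit <- which(lower %in% .SUMSTAT_ALIASES[[field]])
    if (length(hit) == 0L) NA_integer_ else hit[1L]
  }, integer(1))
  out
}

#' Read GWAS summary statistics
#'
#' Reads a whitespace- or tab-delimited summary-statistics file. Column
#' headers are resolved case-insensitively through an alias table
#' (e.g. SNP/ID -> variant_id, A1/EA -> effect_allele, BP/POS -> pos);
#' unknown extra columns are ignored with a warning.
#'
#' @param path input file path.
#' @return data.frame of class `sumstats` with columns `variant_id`,
#'   `chrom`, `pos`, `effect_allele`, `other_allele`, `freq`, `beta`, `se`,
#'   `pval`, `n`.
#' @export
read_sumstats <- function(path) {
  x <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE,
                         check.names = FALSE)
  idx <- resolve_aliases(names(x))
  required <- c("variant_id", "effect_allele", "other_allele", "beta",
                "se", "pval")
  miss <- required[is.na(idx[required])]
  if (length(miss) > 0L) {
    stop("sumstats schema error: no column resolves to: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  extra <- setdiff(seq_along(names(x)), idx[!is.na(idx)])
  if (length(extra) > 0L) {
    warning("ignoring unrecognized sumstats column(s): ",
            paste(names(x)[extra], collapse = ", "), call. = FALSE)
  }
  out <- data.frame(
    variant_id = as.character(x[[idx["variant_id"]]]),
    chrom = if (!is.na(idx["chrom"])) as.character(x[[idx["chrom"]]]) else NA,
    pos = if (!is.na(idx["pos"])) as.integer(x[[idx["pos"]]]) else NA,
    effect_allele = toupper(as.character(x[[idx["effect_allele"]]])),
    other_allele = toupper(as.character(x[[idx["other_allele"]]])),
    freq = if (!is.na(idx["freq"])) as.numeric(x[[idx["freq"]]]) else NA,
    beta = as.numeric(x[[idx["beta"]]]),
    se = as.numeric(x[[idx["se"]]]),
    pval = as.numeric(x[[idx["pval"]]]),
    n = if (!is.na(idx["n"])) as.numeric(x[[idx["n"]]]) else NA,
    stringsAsFactors = FALSE
  )
  as_sumstats(out)
}

#' Validate a summary-statistics table
#'
#' @param x data.frame with the canonical sumstats columns.
#' @return `x` with class `sumstats` after validation.
#' @export
as_sumstats <- function(x) {
  dup <- x$variant_id[duplicated(x$variant_id)]
  if (length(dup) > 0L) {
    stop("sumstats error: duplicated variant_id: ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  }
  bases <- c("A", "C", "G", "T")
  bad_allele <- which(!(x$effect_allele %in% bases) |
                        !(x$other_allele %in% bases) |
                        x$effect_allele == x$other_allele)
  if (length(bad_allele) > 0L) {
    stop("sumstats record error: unresolvable alleles at line(s): ",
         paste(utils::head(bad_allele, 10L), collapse = ", "),
         call. = FALSE)
  }
  bad_p <- which(!(x$pval > 0 & x$pval <= 1))
  if (length(bad_p) > 0L) {
    stop("sumstats record error: p-value outside (0,1] at line(s): ",
         paste(utils::head(bad_p, 10L), collapse = ", "), call. = FALSE)
  }
  class(x) <- c("sumstats", "data.frame")
  x
}

#' Write summary statistics
#' @param stats a `sumstats` data.frame.
#' @param path output TSV path (canonical headers).
#' @export
write_sumstats <- function(stats, path) {
  utils::write.table(stats, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Genotype dosage panel
#'
#' A `genotype_panel` holds a participants x variants matrix of alt-allele
#' dosages in \[0, 2\] plus per-variant metadata (id, chrom, pos, ref, alt,
#' imputation r2). Variants are stored sorted by (chrom, pos).
#'
#' @param dosages numeric matrix, rownames = participant ids, colnames =
#'   variant ids.
#' @param variants data.frame with columns `variant_id`, `chrom`, `pos`,
#'   `ref`, `alt`, `imputation_r2`.
#' @return object of class `genotype_panel`.
#' @export
genotype_panel <- function(dosages, variants) {
  stopifnot(is.matrix(dosages), is.data.frame(variants),
            ncol(dosages) == nrow(variants),
            identical(colnames(dosages), variants$variant_id))
  bad <- which(dosages < 0 | dosages > 2, arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop("dosage out of [0,2]: variant ", colnames(dosages)[bad[1L, 2L]],
         ", sample ", rownames(dosages)[bad[1L, 1L]], call. = FALSE)
  }
  if (any(variants$imputation_r2 < 0 | variants$imputation_r2 > 1)) {
    stop("imputation_r2 must lie in [0,1]", call. = FALSE)
  }
  ord <- order(variants$chrom, variants$pos)
  variants <- variants[ord, , drop = FALSE]
  rownames(variants) <- NULL
  dosages <- dosages[, ord, drop = FALSE]
  structure(list(dosages = dosages, variants = variants),
            class = "genotype_panel")
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat("<genotype_panel> ", nrow(x$dosages), " individuals x ",
      ncol(x$dosages), " variants\n", sep = "")
  invisible(x)
}

#' Read genotype dosages
#'
#' Two supported layouts:
#' * `format = "matrix"`: a TSV with participant ids in the first column and
#'   one dosage column per variant, plus a sidecar TSV (`<path>.variants.tsv`
#'   or `sidecar`) with columns variant_id, chrom, pos, ref, alt,
#'   imputation_r2;
#' * `format = "vcf"`: an uncompressed VCF with per-genotype dosage in
#'   FORMAT field `DS` and imputation quality in INFO key `R2`.
#'
#' @param path input path.
#' @param format `"matrix"` or `"vcf"`.
#' @param sidecar variant metadata path for matrix format (default
#'   `<path>.variants.tsv`).
#' @param cohort optional `cohort_table`; panel individuals absent from the
#'   cohort trigger a logged warning.
#' @return a `genotype_panel`.
#' @export
read_dosages <- function(path, format = c("matrix", "vcf"),
                         sidecar = NULL, cohort = NULL) {
  format <- match.arg(format)
  panel <- if (format == "matrix") {
    if (is.null(sidecar)) sidecar <- paste0(path, ".variants.tsv")
    x <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                           check.names = FALSE)
    ids <- as.character(x[[1L]])
    dos <- as.matrix(x[, -1L, drop = FALSE])
    rownames(dos) <- ids
    v <- utils::read.delim(sidecar, sep = "\t", stringsAsFactors = FALSE)
    v$variant_id <- as.character(v$variant_id)
    v$chrom <- as.character(v$chrom)
    if (!identical(sort(colnames(dos)), sort(v$variant_id))) {
      stop("matrix columns and sidecar variant ids disagree", call. = FALSE)
    }
    genotype_panel(dos[, v$variant_id, drop = FALSE], v)
  } else {
    read_vcf_dosages(path)
  }
  if (!is.null(cohort)) {
    orphan <- setdiff(rownames(panel$dosages), cohort$participant_id)
    if (length(orphan) > 0L) {
      warning(length(orphan), " panel individual(s) absent from cohort: ",
              paste(utils::head(orphan, 5L), collapse = ", "),
              call. = FALSE)
    }
  }
  panel
}

read_vcf_dosages <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "##")]
  if (length(lines) == 0L || !startsWith(lines[1L], "#CHROM")) {
    stop("not a VCF: missing #CHROM header line", call. = FALSE)
  }
  header <- strsplit(sub("^#", "", lines[1L]), "\t")[[1L]]
  samples <- header[-(1:9)]
  body <- lines[-1L]
  fields <- strsplit(body, "\t")
  n_var <- length(fields)
  variants <- data.frame(
    variant_id = vapply(fields, `[`, "", 3L),
    chrom = vapply(fields, `[`, "", 1L),
    pos = as.integer(vapply(fields, `[`, "", 2L)),
    ref = vapply(fields, `[`, "", 4L),
    alt = vapply(fields, `[`, "", 5L),
    imputation_r2 = NA_real_,
    stringsAsFactors = FALSE
  )
  info <- vapply(fields, `[`, "", 8L)
  has_r2 <- grepl("(^|;)R2=", info)
  variants$imputation_r2[has_r2] <-
    as.numeric(sub(".*R2=", "", regmatches(info, regexpr("(^|;)R2=[0-9.eE+-]+", info))))
  if (anyNA(variants$imputation_r2)) {
    stop("VCF INFO is missing R2 (imputation quality) for some variants",
         call. = FALSE)
  }
  dos <- matrix(NA_real_, nrow = length(samples), ncol = n_var,
                dimnames = list(samples, variants$variant_id))
  for (i in seq_len(n_var)) {
    fmt <- strsplit(fields[[i]][9L], ":")[[1L]]
    ds_idx <- which(fmt == "DS")
    if (length(ds_idx) == 0L) {
      stop("VCF FORMAT lacks DS (dosage) field for variant ",
           variants$variant_id[i], call. = FALSE)
    }
    gt <- fields[[i]][-(1:9)]
    dos[, i] <- as.numeric(vapply(strsplit(gt, ":"), `[`, "", ds_idx))
  }
  genotype_panel(dos, variants)
}

#' Write genotype dosages
#'
#' @param panel a `genotype_panel`.
#' @param path output path.
#' @param format `"matrix"` (writes `<path>` and `<path>.variants.tsv`) or
#'   `"vcf"`.
#' @export
write_dosages <- function(panel, path, format = c("matrix", "vcf")) {
  format <- match.arg(format)
  if (format == "matrix") {
    df <- data.frame(participant_id = rownames(panel$dosages),
                     panel$dosages, check.names = FALSE,
                     stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    utils::write.table(panel$variants, paste0(path, ".variants.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    v <- panel$variants
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("##fileformat=VCFv4.2",
                 "##INFO=<ID=R2,Number=1,Type=Float,Description=\"Imputation quality\">",
                 "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Alt allele dosage\">",
                 paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                         "FILTER", "INFO", "FORMAT",
                         rownames(panel$dosages)), collapse = "\t")), con)
    for (i in seq_len(nrow(v))) {
      writeLines(paste(c(v$chrom[i], v$pos[i], v$variant_id[i], v$ref[i],
                         v$alt[i], ".", "PASS",
                         sprintf("R2=%g", v$imputation_r2[i]), "DS",
                         sprintf("%g", panel$dosages[, i])),
                       collapse = "\t"), con)
    }
  }
  invisible(path)
}
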