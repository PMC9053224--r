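#' Cohort phenotype table
#'
#' A `cohort_table` is a data.frame with one row per participant and columns:
#' `participant_id`, `sex` ("male"/"female"), `age` (years), ten exposure
#' indicators `taken_<drug>` (0/1) and 250 endorsement columns
#' `se_<drug>_<effect>` coded tri-state: `NA` = medication not taken,
#' `0` = taken but side effect not endorsed, `1` = taken and endorsed.
#'
#' Invariants enforced by [as_cohort_table()]:
#' * endorsement is `NA` if and only if the medication was not taken;
#' * `se_<drug>_none = 1` implies all 23 checklist endorsements are 0 for
#'   that drug (a participant cannot report "no side effects" and a specific
#'   side effect for the same medication).
#'
#' @param x data.frame with the columns described above.
#' @param drop_incomplete drop rows with missing sex or age (logged count);
#'   how such participants were handled upstream is not documented for the
#'   source study, so dropping is explicit and audited.
#' @return A validated `cohort_table` (data.frame subclass).
#' @export
as_cohort_table <- function(x, drop_incomplete = TRUE) {
  stopifnot(is.data.frame(x))
  mandatory <- c("participant_id", "sex", "age", exposure_col(.DRUGS))
  missing_cols <- setdiff(mandatory, names(x))
  if (length(missing_cols) > 0L) {
    stop("cohort schema error: missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  # endorsement columns: add missing ones as all-NA only if drug never taken
  ecols <- as.vector(vapply(.DRUGS, function(d) endorse_col(d, .EFFECTS),
                            character(length(.EFFECTS))))
  missing_e <- setdiff(ecols, names(x))
  if (length(missing_e) > 0L) {
    stop("cohort schema error: missing endorsement column(s): ",
         paste(utils::head(missing_e, 5L), collapse = ", "),
         if (length(missing_e) > 5L) " ...", call. = FALSE)
  }
  x <- x[, c(mandatory, ecols,
             setdiff(names(x), c(mandatory, ecols))), drop = FALSE]
  x$participant_id <- as.character(x$participant_id)
  if (anyDuplicated(x$participant_id)) {
    stop("cohort schema error: duplicated participant_id", call. = FALSE)
  }
  bad_sex <- !(x$sex %in% c("male", "female")) & !is.na(x$sex)
  if (any(bad_sex)) {
    stop("cohort schema error: sex must be 'male' or 'female'; offending ",
         "rows: ", paste(which(bad_sex), collapse = ", "), call. = FALSE)
  }
  incomplete <- is.na(x$sex) | is.na(x$age)
  if (any(incomplete)) {
    if (!drop_incomplete) {
      stop("cohort has ", sum(incomplete), " row(s) with missing sex or age",
           call. = FALSE)
    }
    sidefx_log("dropped ", sum(incomplete),
               " participant(s) with missing sex or age")
    x <- x[!incomplete, , drop = FALSE]
  }
  if (any(x$age <= 0, na.rm = TRUE)) {
    stop("cohort schema error: age must be positive", call. = FALSE)
  }
  for (d in .DRUGS) {
    taken <- x[[exposure_col(d)]]
    if (!all(taken %in% c(0L, 1L))) {
      stop("cohort schema error: ", exposure_col(d), " must be 0/1",
           call. = FALSE)
    }
    ec <- endorse_col(d, .EFFECTS)
    em <- as.matrix(x[, ec, drop = FALSE])
    # tri-state consistency: endorsement recorded for a drug never taken
    offending <- which(taken == 0L & rowSums(em == 1L, na.rm = TRUE) > 0L)
    if (length(offending) > 0L) {
      stop("cohort consistency error: endorsement with exposure = 0 for ",
           d, "; offending row(s): ",
           paste(utils::head(offending, 10L), collapse = ", "),
           call. = FALSE)
    }
    # force not_taken coding; 0s under exposure 0 are coerced to NA
    em[taken == 0L, ] <- NA_integer_
    if (any(is.na(em[taken == 1L, ]))) {
      stop("cohort consistency error: missing endorsement under exposure ",
           "for ", d, call. = FALSE)
    }
    none <- em[, paste0("se_", d, "_none")]
    chk <- em[, endorse_col(d, .CHECKLIST), drop = FALSE]
    bad_none <- which(none == 1L & rowSums(chk, na.rm = TRUE) > 0L)
    if (length(bad_none) > 0L) {
      stop("cohort consistency error: 'none' endorsed together with ",
           "checklist items for ", d, "; row(s): ",
           paste(utils::head(bad_none, 10L), collapse = ", "),
           call. = FALSE)
    }
    x[, ec] <- em
  }
  class(x) <- c("cohort_table", "data.frame")
  x
}

#' Read a phenotype table
#'
#' Reads the tab-separated phenotype layout (`participant_id`, `sex`, `age`,
#' `taken_<drug>`, `se_<drug>_<effect>`) and validates the tri-state coding.
#'
#' @param path path to a TSV file.
#' @inheritParams as_cohort_table
#' @return A `cohort_table`.
#' @seealso [write_cohort()]
#' @export
read_cohort <- function(path, drop_incomplete = TRUE) {
  x <- utils::read.delim(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE, check.names = FALSE)
  as_cohort_table(x, drop_incomplete = drop_incomplete)
}

#' Write a phenotype table
#'
#' @param cohort a `cohort_table`.
#' @param path output TSV path. Not-taken endorsements are written as `NA`.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "cohort_table"))
  utils::write.table(cohort, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' @export
print.cohort_table <- function(x, ...) {
  cat("<cohort_table> ", nrow(x), " participants, ",
      sum(vapply(.DRUGS, function(d) sum(x[[exposure_col(d)]]), 0)),
      " medication exposures\n", sep = "")
  invisible(x)
}

#' Endorsement matrix for one side effect
#'
#' Extracts the 10 per-medication endorsement columns for a single side
#' effect as an integer matrix (participants x drugs) with `NA` where the
#' medication was not taken.
#'
#' @param cohort a `cohort_table`.
#' @param effect a side-effect id from [sidefx_effects()].
#' @return integer matrix with drug ids as column names.
#' @export
endorsement_matrix <- function(cohort, effect) {
  stopifnot(effect %in% .EFFECTS)
  m <- as.matrix(cohort[, paste0("se_", .DRUGS, "_", effect), drop = FALSE])
  storage.mode(m) <- "integer"
  colnames(m) <- .DRUGS
  rownames(m) <- cohort$participant_id
  m
}
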