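#' Medication and side-effect vocabularies
#'
#' The pipeline studies the ten most commonly prescribed antidepressants in
#' Australia and a checklist of 23 commonly reported side effects, plus two
#' derived columns: "other" (a free-text catch-all) and "none" (no side
#' effects reported for that medication).
#'
#' @format `sidefx_drugs()` returns a character vector of 10 medication ids;
#'   `sidefx_effects()` returns the 25 side-effect column ids (23 checklist
#'   items plus `other` and `none`); `sidefx_checklist_effects()` returns the
#'   23 checklist items only.
#' @name vocabularies
NULL

# Medication ids, ordered roughly by prescription frequency.
.DRUGS <- c("sertraline", "escitalopram", "venlafaxine", "fluoxetine",
            "citalopram", "desvenlafaxine", "duloxetine", "mirtazapine",
            "amitriptyline", "paroxetine")

.SSRI <- c("sertraline", "escitalopram", "fluoxetine", "citalopram",
           "paroxetine")
.SNRI <- c("venlafaxine", "desvenlafaxine", "duloxetine")

# 23-item side-effect checklist.
.CHECKLIST <- c("reduced_sex_drive", "weight_gain", "dry_mouth", "nausea",
                "drowsiness", "insomnia", "dizziness", "fatigue", "sweating",
                "headache", "suicidal_thoughts", "anxiety", "agitation",
                "shaking", "constipation", "diarrhoea", "suicide_attempt",
                "blurred_vision", "muscle_pain", "vomiting", "weight_loss",
                "runny_nose", "rash")
.EFFECTS <- c(.CHECKLIST, "other", "none")

#' @rdname vocabularies
#' @export
sidefx_drugs <- function() .DRUGS

#' @rdname vocabularies
#' @export
sidefx_effects <- function() .EFFECTS

#' @rdname vocabularies
#' @export
sidefx_checklist_effects <- function() .CHECKLIST

#' Drug class map
#'
#' Maps each medication to its pharmacological class: SSRI (selective
#' serotonin reuptake inhibitor), SNRI (serotonin-norepinephrine reuptake
#' inhibitor), or other (mirtazapine, a tetracyclic, and amitriptyline, a
#' tricyclic).
#'
#' @return A data.frame with columns `drug` and `class`.
#' @export
#' @examples
#' drug_class_map()
drug_class_map <- function() {
  cls <- ifelse(.DRUGS %in% .SSRI, "SSRI",
                ifelse(.DRUGS %in% .SNRI, "SNRI", "other"))
  data.frame(drug = .DRUGS, class = cls, stringsAsFactors = FALSE)
}

# Column-name helpers for the phenotype table layout.
exposure_col <- function(drug) paste0("taken_", drug)
endorse_col <- function(drug, effect) {
  paste0("se_", rep(drug, each = length(effect)), "_", effect)
}

# run code under a fixed seed without clobbering the caller's RNG stream
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# internal logger: messages with a [sidefx] prefix, suppressible via option
sidefx_log <- function(...) {
  if (isTRUE(getOption("sidefx.quiet", FALSE))) return(invisible(NULL))
  message("[sidefx] ", ...)
}
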