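# Patient-level classifiers: clinical-course subgroup, arterial "vascular"
# lesion pattern, cardiovascular risk score.

SUBGROUP_LEVELS <- c("ssnhl_no_vertigo", "ssnhl_vertigo", "md")
VASCULAR_LEVELS <- c("VCA", "CCA", "IAA", "none")
RISK_FACTORS <- c("hypertension", "hypercholesterolemia",
                  "prior_cardiocerebrovascular", "diabetes",
                  "bmi_over_25", "smoker")

#' Construct a clinical-course record
#'
#' Symptom-course flags used to assign a patient to one of the three
#' clinical subgroups.
#'
#' @param vestibular_symptoms_at_onset Vertigo/unsteadiness simultaneous
#'   with the hearing loss.
#' @param vestibular_symptoms_followup Vestibular symptoms at any point
#'   during follow-up.
#' @param fluctuating_relapsing_hl Fluctuating or relapsing hearing loss
#'   over follow-up.
#' @param meets_md_criteria Definite or probable Meniere's disease per the
#'   2015 diagnostic guidelines (supplied as input; the criteria themselves
#'   are not re-implemented here).
#' @param onset_to_treatment_days Days from symptom onset to treatment
#'   start, 0--30 (the cohort inclusion window).
#' @return An object of class `clinical_course`.
#' @export
clinical_course <- function(vestibular_symptoms_at_onset = FALSE,
                            vestibular_symptoms_followup = FALSE,
                            fluctuating_relapsing_hl = FALSE,
                            meets_md_criteria = FALSE,
                            onset_to_treatment_days = 0L) {
  flags <- c(vestibular_symptoms_at_onset, vestibular_symptoms_followup,
             fluctuating_relapsing_hl, meets_md_criteria)
  stopifnot(is.logical(flags), length(flags) == 4L, !anyNA(flags))
  if (onset_to_treatment_days < 0 || onset_to_treatment_days > 30) {
    stop("onset_to_treatment_days must be in [0, 30]")
  }
  structure(
    list(vestibular_symptoms_at_onset = vestibular_symptoms_at_onset,
         vestibular_symptoms_followup = vestibular_symptoms_followup,
         fluctuating_relapsing_hl = fluctuating_relapsing_hl,
         meets_md_criteria = meets_md_criteria,
         onset_to_treatment_days = as.integer(onset_to_treatment_days)),
    class = "clinical_course"
  )
}

#' Assign the clinical-course subgroup
#'
#' Precedence: Meniere's disease (`"md"`) when the 2015 criteria are met, or
#' when hearing loss fluctuates/relapses with vestibular symptoms during
#' follow-up; otherwise `"ssnhl_vertigo"` when vestibular symptoms
#' accompanied the hearing loss at onset; otherwise `"ssnhl_no_vertigo"`.
#'
#' @param course A `clinical_course`.
#' @return One of `"ssnhl_no_vertigo"`, `"ssnhl_vertigo"`, `"md"`.
#' @export
assign_subgroup <- function(course) {
  stopifnot(inherits(course, "clinical_course"))
  if (course$meets_md_criteria ||
      (course$fluctuating_relapsing_hl && course$vestibular_symptoms_followup)) {
    "md"
  } else if (course$vestibular_symptoms_at_onset) {
    "ssnhl_vertigo"
  } else {
    "ssnhl_no_vertigo"
  }
}

#' Construct a cardiovascular risk profile
#'
#' Six boolean risk factors, a laboratory-biomarker abnormality flag and
#' the Fazekas white-matter-lesion grade (0--3) from brain MRI.
#'
#' @param hypertension,hypercholesterolemia,prior_cardiocerebrovascular,diabetes,bmi_over_25,smoker
#'   Logical risk-factor flags.
#' @param any_lab_biomarker_abnormal Logical; at least one out-of-range
#'   cardiovascular-disease biomarker assay.
#' @param fazekas Integer 0--3.
#' @return An object of class `risk_profile`.
#' @export
risk_profile <- function(hypertension = FALSE, hypercholesterolemia = FALSE,
                         prior_cardiocerebrovascular = FALSE,
                         diabetes = FALSE, bmi_over_25 = FALSE,
                         smoker = FALSE, any_lab_biomarker_abnormal = FALSE,
                         fazekas = 0L) {
  flags <- c(hypertension, hypercholesterolemia, prior_cardiocerebrovascular,
             diabetes, bmi_over_25, smoker, any_lab_biomarker_abnormal)
  stopifnot(is.logical(flags), length(flags) == 7L, !anyNA(flags))
  if (!fazekas %in% 0:3) stop("fazekas must be in {0, 1, 2, 3}")
  structure(
    list(hypertension = hypertension,
         hypercholesterolemia = hypercholesterolemia,
         prior_cardiocerebrovascular = prior_cardiocerebrovascular,
         diabetes = diabetes, bmi_over_25 = bmi_over_25, smoker = smoker,
         any_lab_biomarker_abnormal = any_lab_biomarker_abnormal,
         fazekas = as.integer(fazekas)),
    class = "risk_profile"
  )
}

#' Cardiovascular risk score
#'
#' Sum of the six risk-factor booleans (0 = absent, 1 = present) plus 1 when
#' any cardiovascular-disease laboratory biomarker is out of range; range
#' 0--7.
#'
#' @param r A `risk_profile`.
#' @return Integer in 0--7.
#' @examples
#' compute_risk_score(risk_profile(hypertension = TRUE, bmi_over_25 = TRUE))
#' @export
compute_risk_score <- function(r) {
  stopifnot(inherits(r, "risk_profile"))
  sum(vapply(RISK_FACTORS, function(f) r[[f]], logical(1))) +
    as.integer(r$any_lab_biomarker_abnormal)
}

#' Construct a hearing-loss profile
#'
#' @param pta PTA in dB HL.
#' @param degree One of `"mild"`, `"moderate"`, `"severe"`,
#'   `"profound_anacusis"`; derived from `pta` when omitted.
#' @param configuration One of `"low_frequency"`, `"high_frequency"`,
#'   `"flat"`.
#' @return An object of class `hl_profile`.
#' @export
hl_profile <- function(pta, degree = classify_degree(pta),
                       configuration = c("flat", "low_frequency",
                                         "high_frequency")) {
  configuration <- match.arg(configuration)
  degree <- match.arg(degree, c("mild", "moderate", "severe",
                                "profound_anacusis"))
  structure(list(pta = as.numeric(pta), degree = degree,
                 configuration = configuration),
            class = "hl_profile")
}

#' Classify the arterial ("vascular") lesion pattern
#'
#' Patterns of combined cochlear and vestibular impairment consistent with
#' ischemia in an inner-ear arterial territory, evaluated in order:
#' \describe{
#'   \item{IAA}{Severe or profound hearing loss with complete vestibular
#'     damage: internal auditory artery. With the default `"strict"` rule
#'     all five receptors (saccule, utricle, all three canals) must be
#'     impaired; with `"loose"`, both otolith organs plus at least one
#'     canal.}
#'   \item{CCA}{Severe or profound hearing loss with saccular and PSC
#'     impairment (utricle free to vary), HSC and ASC spared: common
#'     cochlear artery.}
#'   \item{VCA}{High-frequency hearing loss with saccular and PSC
#'     impairment (utricle free to vary), HSC and ASC spared:
#'     vestibulo-cochlear artery.}
#' }
#' Anything else is `"none"`.
#'
#' @param hl An `hl_profile` from the admission exam.
#' @param lesion A `lesion_pattern`.
#' @param iaa_rule `"strict"` (default) or `"loose"`.
#' @return One of `"VCA"`, `"CCA"`, `"IAA"`, `"none"`.
#' @export
classify_vascular_pattern <- function(hl, lesion,
                                      iaa_rule = c("strict", "loose")) {
  stopifnot(inherits(hl, "hl_profile"), inherits(lesion, "lesion_pattern"))
  iaa_rule <- match.arg(iaa_rule)
  severe_plus <- hl$degree %in% c("severe", "profound_anacusis")
  s <- lesion$saccule_impaired; u <- lesion$utricle_impaired
  h <- lesion$hsc_impaired; a <- lesion$asc_impaired; p <- lesion$psc_impaired

  iaa <- severe_plus && if (iaa_rule == "strict") {
    s && u && h && a && p
  } else {
    s && u && (h || a || p)
  }
  if (iaa) return("IAA")
  if (severe_plus && s && p && !h && !a) return("CCA")
  if (hl$configuration == "high_frequency" && s && p && !h && !a) return("VCA")
  "none"
}
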