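# VEMP and vHIT scoring: asymmetry ratio, otolith impairment, enhanced
# responses, cVEMP frequency tuning, canal impairment, lesion patterns.

# vHIT VOR-gain cut-offs below which, with corrective saccades, a canal is
# called impaired.
VHIT_GAIN_THRESHOLDS <- c(HSC = 0.8, ASC = 0.7, PSC = 0.7)

# AR cut-off (percent) for otolith impairment (>= +33) and enhanced
# responses (<= -33).
AR_CUTOFF <- 33

#' Construct a VEMP amplitude pair
#'
#' Peak-to-peak amplitudes for one VEMP modality (cervical or ocular) on the
#' ipsilesional and contralesional sides. Cervical VEMPs carry an additional
#' 1-kHz amplitude per side used for frequency tuning; ocular VEMPs are
#' recorded at 500 Hz only.
#'
#' @param kind `"cervical"` or `"ocular"`.
#' @param ipsi_500,contra_500 Peak-to-peak amplitudes at 500 Hz
#'   (microvolts, >= 0).
#' @param ipsi_1k,contra_1k 1-kHz amplitudes (cervical only).
#' @param absent_ipsi,absent_contra Logical; `TRUE` when no repeatable
#'   response could be recorded on that side (the 500-Hz amplitude is then
#'   forced to 0).
#' @param threshold_ipsi Optional ipsilesional VEMP threshold in dB nHL
#'   (stored, not used by any classifier).
#' @return An object of class `vemp_pair`.
#' @examples
#' vemp_pair("cervical", ipsi_500 = 0, contra_500 = 110, absent_ipsi = TRUE)
#' @export
vemp_pair <- function(kind = c("cervical", "ocular"),
                      ipsi_500, contra_500,
                      ipsi_1k = NA_real_, contra_1k = NA_real_,
                      absent_ipsi = FALSE, absent_contra = FALSE,
                      threshold_ipsi = NA_real_) {
  kind <- match.arg(kind)
  stopifnot(is.logical(absent_ipsi), is.logical(absent_contra))
  if (absent_ipsi) ipsi_500 <- 0
  if (absent_contra) contra_500 <- 0
  amps <- c(ipsi_500, contra_500, ipsi_1k, contra_1k)
  if (any(!is.na(amps) & (amps < 0 | !is.finite(amps)))) {
    stop("VEMP amplitudes must be finite and non-negative")
  }
  if (kind == "ocular" && (!is.na(ipsi_1k) || !is.na(contra_1k))) {
    stop("1-kHz amplitudes are recorded for cervical VEMPs only")
  }
  structure(
    list(kind = kind, ipsi_500 = as.numeric(ipsi_500),
         contra_500 = as.numeric(contra_500),
         ipsi_1k = as.numeric(ipsi_1k), contra_1k = as.numeric(contra_1k),
         absent_ipsi = absent_ipsi, absent_contra = absent_contra,
         threshold_ipsi = as.numeric(threshold_ipsi)),
    class = "vemp_pair"
  )
}

#' @export
print.vemp_pair <- function(x, ...) {
  cat(sprintf("<vemp_pair> %s: ipsi %s uV, contra %s uV",
              x$kind,
              if (x$absent_ipsi) "absent" else format(x$ipsi_500),
              if (x$absent_contra) "absent" else format(x$contra_500)))
  if (!x$absent_ipsi && !x$absent_contra) {
    cat(sprintf(" (AR %.1f%%)", vemp_ar(x)))
  }
  cat("\n")
  invisible(x)
}

#' VEMP inter-aural asymmetry ratio
#'
#' `AR = (Acontra - Aipsi) / (Acontra + Aipsi) x 100`, in percent. Positive
#' values mean the ipsilesional response is the smaller one; an absent
#' ipsilesional response with a preserved contralesional one gives AR = 100.
#'
#' @param amp_contra,amp_ipsi Peak-to-peak amplitudes (microvolts, >= 0).
#' @return AR in percent, in \[-100, 100\]; `NA` with a warning when both
#'   amplitudes are zero (use the bilateral-absence rule instead).
#' @examples
#' asymmetry_ratio(10, 0)  # 100
#' asymmetry_ratio(8, 4)   # 33.33
#' @export
asymmetry_ratio <- function(amp_contra, amp_ipsi) {
  stopifnot(is.numeric(amp_contra), is.numeric(amp_ipsi))
  if (any(c(amp_contra, amp_ipsi) < 0, na.rm = TRUE)) {
    stop("amplitudes must be non-negative")
  }
  tot <- amp_contra + amp_ipsi
  out <- (amp_contra - amp_ipsi) / tot * 100
  zero <- !is.na(tot) & tot == 0
  if (any(zero)) {
    warning("asymmetry ratio undefined when both amplitudes are zero")
    out[zero] <- NA_real_
  }
  out
}

# AR of a pair on the 500-Hz (primary stimulus) amplitudes.
vemp_ar <- function(v) {
  stopifnot(inherits(v, "vemp_pair"))
  asymmetry_ratio(v$contra_500, v$ipsi_500)
}

#' Call otolith impairment from a VEMP pair
#'
#' The otolith receptor on the pathologic side is called impaired when the
#' 500-Hz asymmetry ratio is >= 33% (inclusive), or when responses are
#' bilaterally absent.
#'
#' @param v A `vemp_pair`.
#' @return `"impaired"` or `"spared"`.
#' @export
call_otolith_impairment <- function(v) {
  stopifnot(inherits(v, "vemp_pair"))
  if (v$absent_ipsi && v$absent_contra) return("impaired")
  ar <- vemp_ar(v)
  if (!is.na(ar) && ar >= AR_CUTOFF) "impaired" else "spared"
}

#' Call an enhanced (hyper-responsive) VEMP on the affected side
#'
#' An asymmetry ratio <= -33% marks an enhanced otolith reflex of the
#' affected ear, a pattern described in early endolymphatic hydrops.
#'
#' @param v A `vemp_pair`, not bilaterally absent.
#' @return Logical.
#' @export
call_enhanced_response <- function(v) {
  stopifnot(inherits(v, "vemp_pair"))
  if (v$absent_ipsi && v$absent_contra) {
    stop("enhanced-response call undefined for bilaterally absent responses")
  }
  ar <- vemp_ar(v)
  !is.na(ar) && ar <= -AR_CUTOFF
}

#' cVEMP frequency tuning (1 kHz vs 500 Hz)
#'
#' Tuning is positive when the 1-kHz amplitude minus the 500-Hz amplitude is
#' >= 0 microvolts (1-kHz dominance, an endolymphatic-hydrops marker).
#' Defined for cervical VEMPs only.
#'
#' @param v A cervical `vemp_pair`.
#' @param side `"ipsi"` or `"contra"`.
#' @return Logical; `NA` when the side is absent or an amplitude is missing.
#' @export
cvemp_tuning <- function(v, side = c("ipsi", "contra")) {
  stopifnot(inherits(v, "vemp_pair"))
  side <- match.arg(side)
  if (v$kind != "cervical") stop("tuning defined for cVEMPs only")
  absent <- if (side == "ipsi") v$absent_ipsi else v$absent_contra
  a500 <- if (side == "ipsi") v$ipsi_500 else v$contra_500
  a1k <- if (side == "ipsi") v$ipsi_1k else v$contra_1k
  if (absent || is.na(a500) || is.na(a1k)) return(NA)
  (a1k - a500) >= 0
}

#' Construct a vHIT exam of the affected side
#'
#' Mean VOR gains and corrective-saccade flags for the horizontal (HSC),
#' anterior (ASC) and posterior (PSC) semicircular canals.
#'
#' @param gain_hsc,gain_asc,gain_psc VOR gains (dimensionless, in
#'   \[0, 1.5\]).
#' @param saccades_hsc,saccades_asc,saccades_psc Logical; corrective
#'   saccades (overt and/or covert) present.
#' @return An object of class `vhit_exam`.
#' @export
vhit_exam <- function(gain_hsc, gain_asc, gain_psc,
                      saccades_hsc = FALSE, saccades_asc = FALSE,
                      saccades_psc = FALSE) {
  gains <- c(gain_hsc, gain_asc, gain_psc)
  if (any(!is.na(gains) & (gains < 0 | gains > 1.5))) {
    stop("VOR gains must be in [0, 1.5]")
  }
  structure(
    list(gain = c(HSC = as.numeric(gain_hsc), ASC = as.numeric(gain_asc),
                  PSC = as.numeric(gain_psc)),
         saccades = c(HSC = isTRUE(saccades_hsc), ASC = isTRUE(saccades_asc),
                      PSC = isTRUE(saccades_psc))),
    class = "vhit_exam"
  )
}

#' @export
print.vhit_exam <- function(x, ...) {
  cat("<vhit_exam>",
      paste(sprintf("%s %.2f%s", names(x$gain), x$gain,
                    ifelse(x$saccades, "*", "")), collapse = ", "),
      "(* = corrective saccades)\n")
  invisible(x)
}

#' Call semicircular-canal impairment from vHIT
#'
#' A canal is impaired when its VOR gain is below the canal-specific cut-off
#' (0.8 for HSC, 0.7 for ASC and PSC) AND corrective saccades are present.
#' A low gain without saccades is classed spared (reported as isolated low
#' gain in QC output).
#'
#' @param exam A `vhit_exam`.
#' @param canal `"HSC"`, `"ASC"` or `"PSC"`.
#' @return `"impaired"` or `"spared"`.
#' @examples
#' ex <- vhit_exam(1.0, 0.95, 0.42, saccades_psc = TRUE)
#' call_canal_impairment(ex, "PSC")  # "impaired"
#' @export
call_canal_impairment <- function(exam, canal = c("HSC", "ASC", "PSC")) {
  stopifnot(inherits(exam, "vhit_exam"))
  canal <- match.arg(canal)
  g <- exam$gain[[canal]]
  if (is.na(g)) stop("gain missing for ", canal)
  if (g < VHIT_GAIN_THRESHOLDS[[canal]] && exam$saccades[[canal]]) {
    "impaired"
  } else {
    "spared"
  }
}

otolith_pattern_label <- function(s, u) {
  if (s && u) "S_U" else if (s) "S" else if (u) "U" else "none"
}

canal_pattern_label <- function(h, a, p) {
  parts <- c("HSC", "ASC", "PSC")[c(h, a, p)]
  if (length(parts)) paste(parts, collapse = "+") else "none"
}

#' Build the vestibular lesion pattern of one patient
#'
#' Combines the cVEMP (saccule), oVEMP (utricle) and vHIT (canals)
#' impairment calls into otolith, canal and end-organ lesion-pattern labels
#' and the total number of impaired receptors (0--5). Also records enhanced
#' responses and cVEMP frequency tuning.
#'
#' @param cvemp Cervical `vemp_pair`.
#' @param ovemp Ocular `vemp_pair`.
#' @param vhit A `vhit_exam`.
#' @return A list of class `lesion_pattern` with logical flags
#'   `saccule_impaired`, `utricle_impaired`, `hsc_impaired`, `asc_impaired`,
#'   `psc_impaired`; labels `otolith_pattern` (`none`/`S`/`U`/`S_U`) and
#'   `canal_pattern` (e.g. `"PSC"`, `"HSC+ASC+PSC"`); `n_receptors`;
#'   `cvemp_enhanced`, `ovemp_enhanced`; and ipsi/contra cVEMP tuning flags.
#' @export
build_lesion_pattern <- function(cvemp, ovemp, vhit) {
  stopifnot(inherits(cvemp, "vemp_pair"), inherits(ovemp, "vemp_pair"),
            inherits(vhit, "vhit_exam"))
  if (cvemp$kind != "cervical" || ovemp$kind != "ocular") {
    stop("expected a cervical and an ocular vemp_pair, in that order")
  }
  s <- call_otolith_impairment(cvemp) == "impaired"
  u <- call_otolith_impairment(ovemp) == "impaired"
  h <- call_canal_impairment(vhit, "HSC") == "impaired"
  a <- call_canal_impairment(vhit, "ASC") == "impaired"
  p <- call_canal_impairment(vhit, "PSC") == "impaired"
  bilat <- function(v) v$absent_ipsi && v$absent_contra
  structure(
    list(
      saccule_impaired = s, utricle_impaired = u,
      hsc_impaired = h, asc_impaired = a, psc_impaired = p,
      otolith_pattern = otolith_pattern_label(s, u),
      canal_pattern = canal_pattern_label(h, a, p),
      n_receptors = sum(s, u, h, a, p),
      cvemp_enhanced = if (bilat(cvemp)) FALSE else call_enhanced_response(cvemp),
      ovemp_enhanced = if (bilat(ovemp)) FALSE else call_enhanced_response(ovemp),
      cvemp_tuning_positive_ipsi = cvemp_tuning(cvemp, "ipsi"),
      cvemp_tuning_positive_contra = cvemp_tuning(cvemp, "contra")
    ),
    class = "lesion_pattern"
  )
}

#' @export
print.lesion_pattern <- function(x, ...) {
  cat(sprintf("<lesion_pattern> otolith %s, canals %s (n = %d receptor%s)\n",
              x$otolith_pattern, x$canal_pattern, x$n_receptors,
              if (x$n_receptors == 1L) "" else "s"))
  invisible(x)
}

#' Construct a lesion pattern directly from impairment flags
#'
#' Convenience constructor used when the five receptor calls are already
#' known (e.g. enumerating patterns); labels and receptor count are derived.
#'
#' @param saccule,utricle,hsc,asc,psc Logical impairment flags.
#' @return A `lesion_pattern` (enhanced/tuning fields `FALSE`/`NA`).
#' @export
lesion_pattern <- function(saccule = FALSE, utricle = FALSE, hsc = FALSE,
                           asc = FALSE, psc = FALSE) {
  flags <- c(saccule, utricle, hsc, asc, psc)
  stopifnot(is.logical(flags), length(flags) == 5L, !anyNA(flags))
  structure(
    list(
      saccule_impaired = saccule, utricle_impaired = utricle,
      hsc_impaired = hsc, asc_impaired = asc, psc_impaired = psc,
      otolith_pattern = otolith_pattern_label(saccule, utricle),
      canal_pattern = canal_pattern_label(hsc, asc, psc),
      n_receptors = sum(flags),
      cvemp_enhanced = FALSE, ovemp_enhanced = FALSE,
      cvemp_tuning_positive_ipsi = NA, cvemp_tuning_positive_contra = NA
    ),
    class = "lesion_pattern"
  )
}
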