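# Pure-tone audiometry: audiogram container, PTA, degree/configuration,
# SSNHL eligibility and hearing-recovery outcome.

#' Canonical audiometric frequency grids
#'
#' Air conduction is tested at 125--8,000 Hz, bone conduction at
#' 250--4,000 Hz (octave steps).
#'
#' @format Integer vectors of frequencies in Hz.
#' @export
AC_FREQS <- c(125L, 250L, 500L, 1000L, 2000L, 4000L, 8000L)

#' @rdname AC_FREQS
#' @export
BC_FREQS <- c(250L, 500L, 1000L, 2000L, 4000L)

#' Construct a pure-tone audiogram exam
#'
#' One ear at one timepoint: air-conduction (AC) thresholds on the
#' 125--8,000 Hz grid, bone-conduction (BC) thresholds on the 250--4,000 Hz
#' grid, word recognition score (WRS), and an anacusis flag for ears with no
#' measurable hearing.
#'
#' @param ac Named numeric vector of AC thresholds (dB HL); names are
#'   frequencies in Hz, a subset of `AC_FREQS`. `NA` marks untested
#'   frequencies.
#' @param bc Named numeric vector of BC thresholds (dB HL); names a subset of
#'   `BC_FREQS`.
#' @param wrs Word recognition score, percent in \[0, 100\], or `NA`.
#' @param anacusis Logical; `TRUE` if the ear has no measurable hearing.
#'   Anacusic ears are assigned a PTA of 120 dB.
#' @param ear `"affected"` or `"contralateral"`.
#' @param exam_time One of `"admission"`, `"d15"`, `"m3"`, `"m6"`, `"m12"`.
#'
#' @return An object of class `audiogram`.
#' @examples
#' audiogram(ac = setNames(rep(60, 7), AC_FREQS),
#'           bc = setNames(rep(55, 5), BC_FREQS), wrs = 70)
#' @export
audiogram <- function(ac = NULL, bc = NULL, wrs = NA_real_, anacusis = FALSE,
                      ear = c("affected", "contralateral"),
                      exam_time = c("admission", "d15", "m3", "m6", "m12")) {
  ear <- match.arg(ear)
  exam_time <- match.arg(exam_time)
  ac <- normalize_thresholds(ac, AC_FREQS, "ac")
  bc <- normalize_thresholds(bc, BC_FREQS, "bc")
  stopifnot(is.logical(anacusis), length(anacusis) == 1L, !is.na(anacusis))
  if (!is.na(wrs) && (wrs < 0 || wrs > 100)) {
    stop("wrs must be in [0, 100], got ", wrs)
  }
  structure(
    list(ac = ac, bc = bc, wrs = as.numeric(wrs), anacusis = anacusis,
         ear = ear, exam_time = exam_time),
    class = "audiogram"
  )
}

# Coerce a (possibly partial) named threshold vector onto the canonical grid.
normalize_thresholds <- function(x, grid, what) {
  out <- setNames(rep(NA_real_, length(grid)), as.character(grid))
  if (is.null(x)) return(out)
  if (is.null(names(x)) || any(!nzchar(names(x)))) {
    stop(what, " thresholds must be named by frequency (Hz)")
  }
  bad <- setdiff(names(x), as.character(grid))
  if (length(bad)) {
    stop(what, " thresholds at non-canonical frequencies: ",
         paste(bad, collapse = ", "))
  }
  vals <- as.numeric(x)
  ok <- is.na(vals) | (vals >= -10 & vals <= 120)
  if (!all(ok)) {
    stop(what, " thresholds out of [-10, 120] dB HL at ",
         paste(names(x)[!ok], collapse = ", "))
  }
  out[names(x)] <- vals
  out
}

#' @export
print.audiogram <- function(x, ...) {
  cat(sprintf("<audiogram> %s ear, %s%s\n", x$ear, x$exam_time,
              if (x$anacusis) " (anacusis)" else ""))
  cat("  AC:", paste(names(x$ac), x$ac, sep = "=", collapse = " "), "\n")
  cat("  BC:", paste(names(x$bc), x$bc, sep = "=", collapse = " "), "\n")
  if (!is.na(x$wrs)) cat("  WRS:", x$wrs, "%\n")
  invisible(x)
}

#' Pure-tone average over the four most impaired contiguous BC frequencies
#'
#' The PTA is the mean of the bone-conduction thresholds of the four most
#' impaired contiguous frequencies (250--4,000 Hz grid). An anacusic ear is
#' assigned 120 dB. When `window` is supplied the mean is taken over exactly
#' those frequencies instead: this is how the follow-up and contralateral
#' PTAs are evaluated "for the corresponding affected frequencies" when
#' assessing recovery.
#'
#' @param exam An `audiogram`.
#' @param window Optional character/numeric vector of frequencies (Hz) to
#'   average over, typically the attribute `"window"` of a previous result.
#' @param tie For equal-mean windows, `"high"` (default) picks the
#'   higher-frequency window, `"low"` the lower one.
#'
#' @return PTA in dB HL, with attribute `"window"` giving the frequencies
#'   averaged (`NULL` for anacusis).
#' @examples
#' ex <- audiogram(bc = c(`250` = 30, `500` = 40, `1000` = 50,
#'                        `2000` = 60, `4000` = 70))
#' compute_pta(ex)  # 55: the 500-4000 Hz window
#' @export
compute_pta <- function(exam, window = NULL, tie = c("high", "low")) {
  stopifnot(inherits(exam, "audiogram"))
  tie <- match.arg(tie)
  if (exam$anacusis) {
    return(structure(120, window = NULL))
  }
  bc <- exam$bc
  if (!is.null(window)) {
    window <- as.character(window)
    miss <- window[is.na(bc[window])]
    if (length(miss)) {
      stop("insufficient audiogram: BC missing at ",
           paste(miss, collapse = ", "))
    }
    return(structure(mean(bc[window]), window = window))
  }
  present <- !is.na(bc)
  # candidate windows: 4 contiguous frequencies on the canonical grid,
  # all present
  nb <- length(bc)
  starts <- which(vapply(seq_len(nb - 3L), function(i) all(present[i:(i + 3L)]),
                         logical(1)))
  if (!length(starts)) {
    stop("insufficient audiogram: need >= 4 contiguous BC thresholds")
  }
  means <- vapply(starts, function(i) mean(bc[i:(i + 3L)]), numeric(1))
  best <- if (tie == "high") {
    starts[max(which(means == max(means)))]
  } else {
    starts[min(which(means == max(means)))]
  }
  win <- names(bc)[best:(best + 3L)]
  structure(mean(bc[win]), window = win)
}

#' Classify hearing-loss degree from a PTA
#'
#' Cut-offs: mild (PTA <= 40 dB), moderate (> 40 and <= 70), severe (> 70 and
#' <= 90), profound/anacusis (> 90).
#'
#' @param pta PTA in dB HL (vectorized).
#' @return Character vector with values in
#'   `c("mild", "moderate", "severe", "profound_anacusis")`.
#' @examples
#' classify_degree(c(40, 70, 90, 120))
#' @export
classify_degree <- function(pta) {
  stopifnot(is.numeric(pta), all(is.na(pta) | (pta >= -10 & pta <= 120)))
  out <- ifelse(pta <= 40, "mild",
         ifelse(pta <= 70, "moderate",
         ifelse(pta <= 90, "severe", "profound_anacusis")))
  out[is.na(pta)] <- NA_character_
  out
}

#' Classify audiogram configuration (low-frequency / high-frequency / flat)
#'
#' Compares the mean AC threshold over the low band (125, 250, 500 Hz)
#' against the high band (2,000, 4,000, 8,000 Hz). A band dominating by at
#' least `delta` dB names the configuration; otherwise the audiogram is flat.
#' Down-sloping audiograms correspond to `"high_frequency"`.
#'
#' @param exam `audiogram` for the affected ear with AC thresholds at the
#'   full 125--8,000 Hz grid (the 1,000 Hz mid frequency may be missing).
#' @param delta Band-difference criterion in dB (default 15).
#' @return One of `"low_frequency"`, `"high_frequency"`, `"flat"`.
#' @examples
#' ex <- audiogram(ac = c(`125` = 60, `250` = 60, `500` = 60, `1000` = 40,
#'                        `2000` = 25, `4000` = 25, `8000` = 25))
#' classify_configuration(ex)  # "low_frequency"
#' @export
classify_configuration <- function(exam, delta = 15) {
  stopifnot(inherits(exam, "audiogram"), is.numeric(delta), delta >= 0)
  low <- exam$ac[c("125", "250", "500")]
  high <- exam$ac[c("2000", "4000", "8000")]
  if (anyNA(low) || anyNA(high)) {
    stop("missing AC threshold in the 125-500 or 2000-8000 Hz band")
  }
  l <- mean(low); h <- mean(high)
  if (l - h >= delta) "low_frequency"
  else if (h - l >= delta) "high_frequency"
  else "flat"
}

#' Check SSNHL eligibility (>= 30 dB loss at >= 3 consecutive frequencies)
#'
#' Sudden sensorineural hearing loss is defined by a loss of at least
#' `loss_db` dB at a minimum of `run_len` consecutive audiometric
#' frequencies. In the default `"relative"` mode the loss is the affected
#' ear's AC threshold minus the contralateral ear's at the same frequency
#' (patients with prior loss in the affected ear are excluded from such
#' cohorts, so the contralateral ear is the premorbid reference); in
#' `"absolute"` mode the affected ear's AC threshold itself is used.
#'
#' @param affected,contra `audiogram` objects for the two ears with AC on
#'   the same frequency grid.
#' @param mode `"relative"` (default) or `"absolute"`.
#' @param loss_db Minimum loss in dB (default 30).
#' @param run_len Minimum number of consecutive frequencies (default 3).
#' @return Logical.
#' @export
check_ssnhl_eligibility <- function(affected, contra = NULL,
                                    mode = c("relative", "absolute"),
                                    loss_db = 30, run_len = 3L) {
  mode <- match.arg(mode)
  stopifnot(inherits(affected, "audiogram"))
  if (isTRUE(affected$anacusis)) return(TRUE)
  if (mode == "relative") {
    stopifnot(inherits(contra, "audiogram"))
    a <- affected$ac
    b <- contra$ac
    shared <- !is.na(a) & !is.na(b)
    if (!identical(names(a), names(b))) stop("AC frequency grids mismatch")
    loss <- (a - b)[shared]
  } else {
    loss <- affected$ac[!is.na(affected$ac)]
  }
  if (length(loss) < run_len) stop("too few shared AC frequencies")
  hit <- loss >= loss_db
  max_run(hit) >= run_len
}

max_run <- function(x) {
  if (!length(x)) return(0L)
  r <- rle(x)
  runs <- r$lengths[r$values]
  if (length(runs)) max(runs) else 0L
}

#' Assess hearing recovery between admission and follow-up
#'
#' The presenting PTA (`PTApre`) is computed on the four most impaired
#' contiguous BC frequencies of the admission exam; the follow-up PTA
#' (`PTApost`) and the contralateral PTA (`PTAcontra`) are computed on that
#' same frequency window. Recovery is `"complete"` if `PTApost` returned
#' within 10 dB of the unaffected ear with a follow-up WRS > 50%;
#' `"partial"` if the PTA improved by more than 10 dB without returning
#' within 10 dB of the unaffected ear, with WRS > 50%; `"none"` otherwise
#' (improvement of 10 dB or less, or WRS <= 50%). The percent recovery is
#' `(PTApre - PTApost) / (PTApre - PTAcontra) x 100`, reported unclipped
#' (values above 100 or below 0 flag over-recovery or deterioration).
#'
#' @param pre Admission `audiogram` of the affected ear.
#' @param post Follow-up (6-month) `audiogram` of the affected ear; its
#'   `wrs` enters the category rule.
#' @param contra Contralateral `audiogram` (admission).
#' @return A list of class `recovery_outcome`: `category`, `pta_pre`,
#'   `pta_post`, `pta_contra`, `pta_recovered`, `percent_recovery`
#'   (`NA` with a warning when `PTApre <= PTAcontra`, i.e. no measurable
#'   deficit), and the frequency `window` used.
#' @examples
#' pre <- audiogram(bc = setNames(rep(80, 5), BC_FREQS))
#' post <- audiogram(bc = setNames(rep(40, 5), BC_FREQS), wrs = 80)
#' con <- audiogram(bc = setNames(rep(30, 5), BC_FREQS))
#' assess_recovery(pre, post, con)$percent_recovery  # 80
#' @export
assess_recovery <- function(pre, post, contra) {
  stopifnot(inherits(pre, "audiogram"), inherits(post, "audiogram"),
            inherits(contra, "audiogram"))
  pta_pre <- compute_pta(pre)
  win <- attr(pta_pre, "window")
  if (is.null(win) && !post$anacusis) {
    # anacusic admission ear: every frequency is maximally impaired, so the
    # follow-up exam's own four most impaired contiguous frequencies define
    # the comparison window
    p <- compute_pta(post)
    win <- attr(p, "window")
  }
  pta_post <- if (post$anacusis) 120 else as.numeric(compute_pta(post, window = win))
  pta_contra <- if (contra$anacusis) 120 else
    as.numeric(compute_pta(contra, window = win))
  pta_pre <- as.numeric(pta_pre)

  improved <- pta_pre - pta_post
  wrs_ok <- !is.na(post$wrs) && post$wrs > 50
  category <- if (pta_post <= pta_contra + 10 && wrs_ok) {
    "complete"
  } else if (improved > 10 && wrs_ok) {
    "partial"
  } else {
    "none"
  }

  if (pta_pre <= pta_contra) {
    warning("no measurable deficit: PTApre <= PTAcontra, percent recovery undefined")
    pct <- NA_real_
  } else {
    pct <- improved / (pta_pre - pta_contra) * 100
  }

  structure(
    list(category = category, pta_pre = pta_pre, pta_post = pta_post,
         pta_contra = pta_contra, pta_recovered = improved,
         percent_recovery = pct, window = win),
    class = "recovery_outcome"
  )
}

#' @export
print.recovery_outcome <- function(x, ...) {
  cat(sprintf(
    "<recovery_outcome> %s: PTA %g -> %g dB (contra %g), recovered %g dB (%s%%)\n",
    x$category, x$pta_pre, x$pta_post, x$pta_contra, x$pta_recovered,
    if (is.na(x$percent_recovery)) "NA" else sprintf("%.1f", x$percent_recovery)))
  invisible(x)
}
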