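# Cohort CSV schema, reading/writing with validation, per-patient scoring
# and the end-to-end pipeline.

#' The wide cohort CSV schema
#'
#' One row per patient. `format` drives on-disk number formatting: `"db"`
#' thresholds are written as integers, `"amp"` (microvolts) and `"gain"`
#' with 2 decimals, `"pct"` with 2 decimals. Columns with
#' `required = FALSE` (follow-up audiometry, oculomotor categories and the
#' synthetic-truth `subgroup`/`lat_*` columns) may be absent from a cohort
#' file.
#'
#' @return A tibble: `column`, `type`, `required`, `min`, `max`, `format`.
#' @export
cohort_schema <- function() {
  col <- function(column, type, required = TRUE, min = NA, max = NA,
                  format = "plain") {
    tibble::tibble(column = column, type = type, required = required,
                   min = min, max = max, format = format)
  }
  db <- function(names, required = TRUE) {
    col(names, "numeric", required, min = -10, max = 120, format = "db")
  }
  rbind(
    col("patient_id", "integer"),
    col("subgroup", "character", required = FALSE),
    col("age", "integer", min = 18, max = 110),
    col("side", "character", required = FALSE),
    col(c("vert_onset", "vert_followup", "fluct_hl", "md_criteria"),
        "logical"),
    col("days_onset_treat", "integer", min = 0, max = 30),
    col(c("htn", "chol", "prior_cvd", "dm", "bmi25", "smoke", "lab_abn"),
        "logical"),
    col("fazekas", "integer", min = 0, max = 3),
    db(paste0("ac_aff_", AC_FREQS)),
    db(paste0("bc_aff_", BC_FREQS)),
    db(paste0("ac_con_", AC_FREQS)),
    db(paste0("bc_con_", BC_FREQS)),
    col("wrs_aff", "numeric", min = 0, max = 100),
    col("anacusis", "logical"),
    db(paste0("ac_aff_", AC_FREQS, "_m6"), required = FALSE),
    db(paste0("bc_aff_", BC_FREQS, "_m6"), required = FALSE),
    db(paste0("ac_con_", AC_FREQS, "_m6"), required = FALSE),
    db(paste0("bc_con_", BC_FREQS, "_m6"), required = FALSE),
    col("wrs_aff_m6", "numeric", required = FALSE, min = 0, max = 100),
    col("anacusis_m6", "logical", required = FALSE),
    col(c("cvemp_ipsi_500", "cvemp_con_500"), "numeric", min = 0,
        format = "amp"),
    col(c("cvemp_ipsi_1k", "cvemp_con_1k"), "numeric", required = FALSE,
        min = 0, format = "amp"),
    col(c("cvemp_absent_ipsi", "cvemp_absent_con"), "logical"),
    col(c("ovemp_ipsi_500", "ovemp_con_500"), "numeric", min = 0,
        format = "amp"),
    col(c("ovemp_absent_ipsi", "ovemp_absent_con"), "logical"),
    col(paste0("vhit_gain_", c("hsc", "asc", "psc")), "numeric",
        min = 0, max = 1.5, format = "gain"),
    col(paste0("vhit_sacc_", c("hsc", "asc", "psc")), "logical"),
    col(c("sn", "pn", "hsn", "vin", "hvn"), "character", required = FALSE),
    col(c("lat_sacc", "lat_utr", "lat_hsc", "lat_asc", "lat_psc"),
        "logical", required = FALSE),
    col("lat_pct_recovery", "numeric", required = FALSE, format = "pct")
  )
}

#' Read a cohort CSV
#'
#' Reads and validates a wide cohort file against [cohort_schema()]: all
#' required columns must be present, `patient_id` must be unique, and every
#' cell must be of the declared type and within its declared range. Empty
#' cells become missing values.
#'
#' @param path Path to the CSV file.
#' @param strict If `TRUE` (default), any malformed cell aborts with a
#'   message listing the violations; if `FALSE`, violations are reported as
#'   a warning and attached as attribute `"validation"`.
#' @return A tibble of typed patient records.
#' @export
read_cohort <- function(path, strict = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", check.names = FALSE)
  sch <- cohort_schema()
  missing_req <- setdiff(sch$column[sch$required], names(raw))
  if (length(missing_req)) {
    stop("missing mandatory column(s): ", paste(missing_req, collapse = ", "))
  }
  problems <- character(0)
  out <- list()
  for (k in seq_len(nrow(sch))) {
    nm <- sch$column[k]
    if (!nm %in% names(raw)) next
    v <- raw[[nm]]
    v[!nzchar(trimws(v))] <- NA
    parsed <- switch(sch$type[k],
      integer = suppressWarnings(as.integer(v)),
      numeric = suppressWarnings(as.numeric(v)),
      logical = parse_logical(v),
      character = as.character(v))
    bad_parse <- which(!is.na(v) & is.na(parsed))
    if (length(bad_parse)) {
      problems <- c(problems, sprintf(
        "%s: row %d not a valid %s (%s)", nm, bad_parse,
        sch$type[k], v[bad_parse]))
    }
    if (sch$type[k] %in% c("integer", "numeric")) {
      lo <- sch$min[k]; hi <- sch$max[k]
      bad_rng <- which(!is.na(parsed) &
                         ((!is.na(lo) & parsed < lo) |
                          (!is.na(hi) & parsed > hi)))
      if (length(bad_rng)) {
        problems <- c(problems, sprintf(
          "%s: row %d out of [%s, %s] (%s)", nm, bad_rng,
          ifelse(is.na(lo), "-Inf", lo), ifelse(is.na(hi), "Inf", hi),
          parsed[bad_rng]))
      }
    }
    out[[nm]] <- parsed
  }
  tbl <- tibble::as_tibble(out)
  if (anyDuplicated(tbl$patient_id)) {
    stop("duplicate patient_id: ",
         paste(unique(tbl$patient_id[duplicated(tbl$patient_id)]),
               collapse = ", "))
  }
  if (length(problems)) {
    msg <- paste0("cohort validation failed:\n  ",
                  paste(problems, collapse = "\n  "))
    if (strict) stop(msg) else warning(msg)
    attr(tbl, "validation") <- problems
  }
  attr(tbl, "provenance") <- list(source = "file", path = path)
  tbl
}

parse_logical <- function(v) {
  up <- toupper(trimws(v))
  out <- rep(NA, length(v))
  out[up %in% c("TRUE", "T", "1", "YES")] <- TRUE
  out[up %in% c("FALSE", "F", "0", "NO")] <- FALSE
  out
}

#' Write a cohort CSV
#'
#' Writes UTF-8 CSV in the deterministic schema column order with fixed
#' number formatting: dB thresholds as integers, VEMP amplitudes and VOR
#' gains to 2 decimals. `write -> read -> write` is byte-stable.
#'
#' @param table Cohort tibble (schema columns; extra columns are appended
#'   unformatted).
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_cohort <- function(table, path) {
  sch <- cohort_schema()
  cols <- c(intersect(sch$column, names(table)),
            setdiff(names(table), sch$column))
  out <- table[cols]
  for (k in seq_len(nrow(sch))) {
    nm <- sch$column[k]
    if (!nm %in% names(out)) next
    v <- out[[nm]]
    out[[nm]] <- switch(sch$format[k],
      db = ifelse(is.na(v), "", sprintf("%d", as.integer(round(v)))),
      amp = ,
      gain = ,
      pct = ifelse(is.na(v), "", sprintf("%.2f", v)),
      ifelse(is.na(v), "", as.character(v)))
  }
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

row_audiogram <- function(row, ear = c("aff", "con"), m6 = FALSE) {
  ear <- match.arg(ear)
  sfx <- if (m6) "_m6" else ""
  ac_names <- paste0("ac_", ear, "_", AC_FREQS, sfx)
  bc_names <- paste0("bc_", ear, "_", BC_FREQS, sfx)
  if (!all(c(ac_names, bc_names) %in% names(row))) return(NULL)
  ac <- setNames(as.numeric(unlist(row[ac_names])), AC_FREQS)
  bc <- setNames(as.numeric(unlist(row[bc_names])), BC_FREQS)
  wrs <- if (ear == "aff") {
    w <- row[[paste0("wrs_aff", sfx)]]
    if (is.null(w)) NA_real_ else as.numeric(w)
  } else NA_real_
  ana <- if (ear == "aff") {
    a <- row[[paste0("anacusis", sfx)]]
    isTRUE(as.logical(a))
  } else FALSE
  audiogram(ac = ac[!is.na(ac)], bc = bc[!is.na(bc)], wrs = wrs,
            anacusis = ana,
            ear = if (ear == "aff") "affected" else "contralateral",
            exam_time = if (m6) "m6" else "admission")
}

row_vemp <- function(row, kind = c("cervical", "ocular")) {
  kind <- match.arg(kind)
  p <- if (kind == "cervical") "cvemp" else "ovemp"
  vemp_pair(
    kind = kind,
    ipsi_500 = as.numeric(row[[paste0(p, "_ipsi_500")]]),
    contra_500 = as.numeric(row[[paste0(p, "_con_500")]]),
    ipsi_1k = if (kind == "cervical")
      as.numeric(row[[paste0(p, "_ipsi_1k")]] %||% NA) else NA_real_,
    contra_1k = if (kind == "cervical")
      as.numeric(row[[paste0(p, "_con_1k")]] %||% NA) else NA_real_,
    absent_ipsi = isTRUE(as.logical(row[[paste0(p, "_absent_ipsi")]])),
    absent_contra = isTRUE(as.logical(row[[paste0(p, "_absent_con")]]))
  )
}

row_vhit <- function(row) {
  vhit_exam(
    gain_hsc = as.numeric(row[["vhit_gain_hsc"]]),
    gain_asc = as.numeric(row[["vhit_gain_asc"]]),
    gain_psc = as.numeric(row[["vhit_gain_psc"]]),
    saccades_hsc = isTRUE(as.logical(row[["vhit_sacc_hsc"]])),
    saccades_asc = isTRUE(as.logical(row[["vhit_sacc_asc"]])),
    saccades_psc = isTRUE(as.logical(row[["vhit_sacc_psc"]]))
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Score a cohort table
#'
#' Applies the full per-patient scoring battery to every record: PTA,
#' degree, configuration, SSNHL eligibility, VEMP asymmetry ratios and
#' otolith calls, frequency tuning, canal impairment, lesion pattern and
#' receptor count, clinical-course subgroup, vascular pattern, risk score,
#' and (when follow-up audiometry is present) the recovery outcome with
#' unclipped and clipped percent recovery.
#'
#' @param table A cohort tibble (from [read_cohort()] or
#'   [generate_cohort()]).
#' @param iaa_rule Passed to [classify_vascular_pattern()].
#' @param config_delta Band-difference criterion (dB) for
#'   [classify_configuration()].
#' @return The input tibble with scoring columns appended (prefix-free:
#'   `eligible`, `pta_pre`, `degree`, `configuration`, `cvemp_ar`,
#'   `ovemp_ar`, `sacc_imp` ... `psc_imp`, `otolith_pattern`,
#'   `canal_pattern`, `n_receptors`, `subgroup_assigned`,
#'   `vascular_pattern`, `risk_score`, `recovery`, `pta_recovered`,
#'   `pct_recovery`, `pct_recovery_clipped`, ...).
#' @examples
#' scored <- score_cohort(generate_cohort(cohort_config(10, seed = 7)))
#' table(scored$vascular_pattern)
#' @export
score_cohort <- function(table, iaa_rule = c("strict", "loose"),
                         config_delta = 15) {
  iaa_rule <- match.arg(iaa_rule)
  stopifnot(is.data.frame(table))
  n <- nrow(table)
  cols <- as.list(table)
  res <- vector("list", n)
  for (i in seq_len(n)) {
    row <- lapply(cols, `[[`, i)
    res[[i]] <- tryCatch(
      score_patient(row, iaa_rule = iaa_rule, config_delta = config_delta),
      error = function(e) {
        stop("scoring failed for patient_id ", row$patient_id, ": ",
             conditionMessage(e), call. = FALSE)
      })
  }
  scored <- tibble::as_tibble(data.table::rbindlist(res))
  tibble::as_tibble(cbind(table, scored))
}

score_patient <- function(row, iaa_rule = "strict", config_delta = 15) {
  aff <- row_audiogram(row, "aff")
  con <- row_audiogram(row, "con")
  pta_pre <- compute_pta(aff)
  win <- attr(pta_pre, "window")
  pta_contra <- if (is.null(win)) {
    as.numeric(compute_pta(con))
  } else {
    as.numeric(compute_pta(con, window = win))
  }
  degree <- classify_degree(as.numeric(pta_pre))
  configuration <- if (isTRUE(row$anacusis)) "flat"
                   else classify_configuration(aff, delta = config_delta)
  eligible <- check_ssnhl_eligibility(aff, con)

  cv <- row_vemp(row, "cervical")
  ov <- row_vemp(row, "ocular")
  vh <- row_vhit(row)
  lp <- build_lesion_pattern(cv, ov, vh)
  cv_ar <- if (cv$absent_ipsi && cv$absent_contra) NA_real_ else vemp_ar(cv)
  ov_ar <- if (ov$absent_ipsi && ov$absent_contra) NA_real_ else vemp_ar(ov)

  course <- clinical_course(
    vestibular_symptoms_at_onset = isTRUE(as.logical(row$vert_onset)),
    vestibular_symptoms_followup = isTRUE(as.logical(row$vert_followup)),
    fluctuating_relapsing_hl = isTRUE(as.logical(row$fluct_hl)),
    meets_md_criteria = isTRUE(as.logical(row$md_criteria)),
    onset_to_treatment_days = as.integer(row$days_onset_treat)
  )
  subgroup <- assign_subgroup(course)
  hl <- hl_profile(as.numeric(pta_pre), degree, configuration)
  vascular <- classify_vascular_pattern(hl, lp, iaa_rule = iaa_rule)
  risk <- risk_profile(
    hypertension = isTRUE(as.logical(row$htn)),
    hypercholesterolemia = isTRUE(as.logical(row$chol)),
    prior_cardiocerebrovascular = isTRUE(as.logical(row$prior_cvd)),
    diabetes = isTRUE(as.logical(row$dm)),
    bmi_over_25 = isTRUE(as.logical(row$bmi25)),
    smoker = isTRUE(as.logical(row$smoke)),
    any_lab_biomarker_abnormal = isTRUE(as.logical(row$lab_abn)),
    fazekas = as.integer(row$fazekas)
  )

  aff_m6 <- row_audiogram(row, "aff", m6 = TRUE)
  if (is.null(aff_m6) || all(is.na(aff_m6$bc)) && !aff_m6$anacusis) {
    rec <- list(category = NA_character_, pta_post = NA_real_,
                pta_recovered = NA_real_, percent_recovery = NA_real_)
  } else {
    rec <- suppressWarnings(assess_recovery(aff, aff_m6, con))
  }
  pct <- rec$percent_recovery

  list(
    eligible = eligible,
    pta_pre = as.numeric(pta_pre),
    pta_contra = pta_contra,
    pta_post = rec$pta_post,
    degree = degree,
    configuration = configuration,
    cvemp_ar = cv_ar,
    ovemp_ar = ov_ar,
    sacc_imp = lp$saccule_impaired,
    utr_imp = lp$utricle_impaired,
    hsc_imp = lp$hsc_impaired,
    asc_imp = lp$asc_impaired,
    psc_imp = lp$psc_impaired,
    otolith_pattern = lp$otolith_pattern,
    canal_pattern = lp$canal_pattern,
    n_receptors = lp$n_receptors,
    cvemp_enhanced = lp$cvemp_enhanced,
    ovemp_enhanced = lp$ovemp_enhanced,
    tuning_ipsi = lp$cvemp_tuning_positive_ipsi,
    tuning_contra = lp$cvemp_tuning_positive_contra,
    subgroup_assigned = subgroup,
    vascular_pattern = vascular,
    risk_score = compute_risk_score(risk),
    recovery = rec$category,
    pta_recovered = rec$pta_recovered,
    pct_recovery = pct,
    pct_recovery_clipped = if (is.na(pct)) NA_real_ else min(100, max(0, pct))
  )
}

# Short stable hash of a configuration for the run manifest.
config_hash <- function(x) {
  s <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, force = TRUE)
  bytes <- utf8ToInt(as.character(s))
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Run the full pipeline: simulate/read, score, analyze
#'
#' Composes the stages in order: obtain a cohort (from a generator
#' configuration or an existing table/file), score every patient, and
#' assemble the cohort report. Optionally writes `cohort.csv`,
#' `phenotypes.csv`, per-table report CSVs, `report.json` and a
#' `manifest.json` (package version, seed, configuration hash) under
#' `out`.
#'
#' @param config A `cohort_config` (simulate) — or `NULL` when `cohort` is
#'   given.
#' @param cohort A cohort tibble or a path to a cohort CSV.
#' @param out Optional output directory.
#' @param iaa_rule Passed to [score_cohort()].
#' @return Invisibly, a list: `cohort` (scored tibble), `report`
#'   (`cohort_report`), `manifest`.
#' @examples
#' res <- run_pipeline(cohort_config(n_patients = 50, seed = 11))
#' res$report$trend$rho
#' @export
run_pipeline <- function(config = NULL, cohort = NULL, out = NULL,
                         iaa_rule = c("strict", "loose")) {
  iaa_rule <- match.arg(iaa_rule)
  if (is.null(config) && is.null(cohort)) {
    stop("stage input: provide a cohort_config or a cohort")
  }
  if (!is.null(config)) {
    tbl <- generate_cohort(config)
    prov <- list(source = "synthetic", seed = as.integer(config$seed),
                 config_hash = config_hash(unclass(config)))
  } else if (is.character(cohort)) {
    tbl <- read_cohort(cohort)
    prov <- list(source = "file", path = cohort,
                 config_hash = config_hash(list(path = cohort)))
  } else {
    tbl <- cohort
    prov <- list(source = "table", config_hash = config_hash(list(n = nrow(tbl))))
  }
  scored <- score_cohort(tbl, iaa_rule = iaa_rule)
  report <- cohort_report(scored)
  manifest <- list(
    package = "vestscore",
    version = as.character(utils::packageVersion("vestscore")),
    n_patients = nrow(scored),
    provenance = prov,
    iaa_rule = iaa_rule
  )
  if (!is.null(out)) {
    dir.create(out, recursive = TRUE, showWarnings = FALSE)
    write_cohort(tbl, file.path(out, "cohort.csv"))
    pheno_cols <- c("patient_id", "subgroup_assigned", "degree",
                    "configuration", "otolith_pattern", "canal_pattern",
                    "n_receptors", "vascular_pattern", "risk_score",
                    "recovery", "pct_recovery", "pct_recovery_clipped")
    utils::write.csv(scored[intersect(pheno_cols, names(scored))],
                     file.path(out, "phenotypes.csv"), row.names = FALSE)
    for (nm in names(report$tables)) {
      utils::write.csv(report$tables[[nm]]$counts,
                       file.path(out, paste0("table_", nm, ".csv")))
    }
    jsonlite::write_json(report_to_json(report),
                         file.path(out, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(list(cohort = scored, report = report, manifest = manifest))
}

report_to_json <- function(report) {
  list(
    n = report$n,
    tests = lapply(report$tests, function(t) {
      t[c("statistic", "p", "method")]
    }),
    kruskal = lapply(report$kruskal, function(k) {
      if (is.null(k)) NULL else list(H = k$H, df = k$df, p = k$p)
    }),
    trend = if (is.null(report$trend)) NULL else {
      list(rho = report$trend$rho, p = report$trend$p,
           strata = report$trend$strata)
    },
    regression = if (is.null(report$regression) ||
                     report$regression$separation) NULL else {
      report$regression$coefficients
    }
  )
}
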