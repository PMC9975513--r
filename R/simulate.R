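# Seeded synthetic-cohort generator emulating the three-subgroup SSNHL
# study structure, plus the three worked-example fixture patients.

#' Configuration for the synthetic cohort generator
#'
#' Bundles every distributional parameter of the generator. Defaults encode
#' the study conditions: three clinical subgroups with proportions
#' 29.1/31.4/39.5%, per-subgroup receptor-impairment prevalences whose
#' weighted marginals reproduce the cohort fractions (saccule 39/86,
#' utricle 37/86, HSC 14/86, ASC 10/86, PSC 18/86, with e.g. cVEMP 74.1%
#' and PSC 55.6% in the vertigo subgroup and no ASC involvement without
#' vertigo), per-subgroup hearing-loss configuration/degree mixtures and
#' Fazekas distributions, and a recovery model in which the expected percent
#' recovery falls linearly with the number of impaired receptors:
#' `clip(base - penalty x n_receptors + Normal(0, sd), 0, 100)`.
#'
#' @param n_patients Number of patients to simulate (>= 1).
#' @param seed Integer seed; the same seed yields a bit-identical cohort.
#' @param subgroup_props Named 3-vector of subgroup probabilities
#'   (`ssnhl_no_vertigo`, `ssnhl_vertigo`, `md`), summing to 1.
#' @param prevalences 5 x 3 numeric matrix of impairment probabilities,
#'   rows `saccule, utricle, hsc, asc, psc`, columns the subgroups.
#' @param config_mix 3 x 3 matrix of hearing-loss configuration
#'   probabilities (rows `low_frequency, high_frequency, flat`) per
#'   subgroup; columns sum to 1.
#' @param degree_mix 4 x 3 matrix of degree probabilities (rows
#'   `mild, moderate, severe, profound_anacusis`) per subgroup.
#' @param fazekas_probs 4 x 3 matrix of Fazekas grade (0--3) probabilities
#'   per subgroup.
#' @param base_recovery_pct,per_receptor_penalty,noise_sd Recovery model:
#'   mean percent recovery with no receptor damage, drop per impaired
#'   receptor, and Gaussian noise SD (all in percent points).
#' @param bilateral_absent_prob Probability that an impaired otolith
#'   presents as bilaterally absent responses rather than AR >= 33%.
#' @param enhanced_prob Named 3-vector: per-subgroup probability that a
#'   spared otolith shows an enhanced response (AR <= -33%).
#' @param tuning_pos_prob_ipsi Named 3-vector: per-subgroup probability of
#'   positive ipsilesional cVEMP frequency tuning (default 29.4% in MD).
#' @param tuning_pos_prob_contra Scalar probability of positive
#'   contralesional tuning (subgroup-independent).
#' @param cvemp_meanlog,cvemp_sdlog,ovemp_meanlog,ovemp_sdlog Lognormal
#'   location/scale of the contralesional (reference) 500-Hz amplitudes, in
#'   microvolts.
#' @param gain_noise_sd SD of spared VOR gains around 0.98.
#' @param anacusis_prob Probability that a profound ear is anacusic.
#' @param risk_probs Named probabilities of the six cardiovascular risk
#'   factors and the lab-abnormality flag.
#' @return A validated list of class `cohort_config`.
#' @export
cohort_config <- function(
    n_patients,
    seed = 1L,
    subgroup_props = c(ssnhl_no_vertigo = 0.291, ssnhl_vertigo = 0.314,
                       md = 0.395),
    prevalences = default_prevalences(),
    config_mix = default_config_mix(),
    degree_mix = default_degree_mix(),
    fazekas_probs = default_fazekas_probs(),
    base_recovery_pct = 75,
    per_receptor_penalty = 12,
    noise_sd = 20,
    bilateral_absent_prob = 0.3,
    enhanced_prob = c(ssnhl_no_vertigo = 0.10, ssnhl_vertigo = 0.055,
                      md = 0.09),
    tuning_pos_prob_ipsi = c(ssnhl_no_vertigo = 0.12, ssnhl_vertigo = 0.11,
                             md = 0.294),
    tuning_pos_prob_contra = 0.12,
    cvemp_meanlog = log(80), cvemp_sdlog = 0.4,
    ovemp_meanlog = log(8), ovemp_sdlog = 0.4,
    gain_noise_sd = 0.06,
    anacusis_prob = 0.4,
    risk_probs = c(htn = 0.30, chol = 0.30, prior_cvd = 0.10, dm = 0.12,
                   bmi25 = 0.40, smoke = 0.25, lab_abn = 0.30)) {
  cfg <- list(
    n_patients = n_patients, seed = seed, subgroup_props = subgroup_props,
    prevalences = prevalences, config_mix = config_mix,
    degree_mix = degree_mix, fazekas_probs = fazekas_probs,
    base_recovery_pct = base_recovery_pct,
    per_receptor_penalty = per_receptor_penalty, noise_sd = noise_sd,
    bilateral_absent_prob = bilateral_absent_prob,
    enhanced_prob = enhanced_prob,
    tuning_pos_prob_ipsi = tuning_pos_prob_ipsi,
    tuning_pos_prob_contra = tuning_pos_prob_contra,
    cvemp_meanlog = cvemp_meanlog, cvemp_sdlog = cvemp_sdlog,
    ovemp_meanlog = ovemp_meanlog, ovemp_sdlog = ovemp_sdlog,
    gain_noise_sd = gain_noise_sd, anacusis_prob = anacusis_prob,
    risk_probs = risk_probs
  )
  validate_cohort_config(cfg)
  structure(cfg, class = "cohort_config")
}

#' @rdname cohort_config
#' @export
default_prevalences <- function() {
  matrix(
    c(0.28, 0.741, 0.353,   # saccule (cVEMP)
      0.44, 0.481, 0.382,   # utricle (oVEMP)
      0.04, 0.296, 0.147,   # HSC
      0.00, 0.222, 0.118,   # ASC
      0.08, 0.556, 0.029),  # PSC
    nrow = 5, byrow = TRUE,
    dimnames = list(c("saccule", "utricle", "hsc", "asc", "psc"),
                    SUBGROUP_LEVELS)
  )
}

#' @rdname cohort_config
#' @export
default_config_mix <- function() {
  matrix(
    c(0.08, 0.00, 0.53,
      0.44, 0.37, 0.09,
      0.48, 0.63, 0.38),
    nrow = 3, byrow = TRUE,
    dimnames = list(c("low_frequency", "high_frequency", "flat"),
                    SUBGROUP_LEVELS)
  )
}

#' @rdname cohort_config
#' @export
default_degree_mix <- function() {
  matrix(
    c(0.080, 0.037, 0.235,
      0.480, 0.185, 0.559,
      0.280, 0.333, 0.118,
      0.160, 0.445, 0.088),
    nrow = 4, byrow = TRUE,
    dimnames = list(c("mild", "moderate", "severe", "profound_anacusis"),
                    SUBGROUP_LEVELS)
  )
}

#' @rdname cohort_config
#' @export
default_fazekas_probs <- function() {
  matrix(
    c(0.52, 0.15, 0.50,
      0.36, 0.33, 0.38,
      0.12, 0.37, 0.12,
      0.00, 0.15, 0.00),
    nrow = 4, byrow = TRUE,
    dimnames = list(as.character(0:3), SUBGROUP_LEVELS)
  )
}

validate_cohort_config <- function(cfg) {
  err <- function(field, msg) stop("invalid cohort_config$", field, ": ", msg,
                                   call. = FALSE)
  if (!is.numeric(cfg$n_patients) || length(cfg$n_patients) != 1L ||
      is.na(cfg$n_patients) || cfg$n_patients < 1) {
    err("n_patients", "must be a single integer >= 1")
  }
  if (!is.numeric(cfg$seed) || length(cfg$seed) != 1L || is.na(cfg$seed)) {
    err("seed", "must be a single integer")
  }
  p <- cfg$subgroup_props
  if (length(p) != 3L || any(p < 0) || abs(sum(p) - 1) > 1e-8) {
    err("subgroup_props", "must be 3 non-negative probabilities summing to 1")
  }
  check_prob_mat <- function(m, field, nrow_exp, colsum1 = TRUE) {
    if (!is.matrix(m) || nrow(m) != nrow_exp || ncol(m) != 3L) {
      err(field, sprintf("must be a %d x 3 matrix", nrow_exp))
    }
    if (any(m < 0 | m > 1)) err(field, "probabilities must be in [0, 1]")
    if (colsum1 && any(abs(colSums(m) - 1) > 1e-8)) {
      err(field, "columns must sum to 1")
    }
  }
  check_prob_mat(cfg$prevalences, "prevalences", 5, colsum1 = FALSE)
  check_prob_mat(cfg$config_mix, "config_mix", 3)
  check_prob_mat(cfg$degree_mix, "degree_mix", 4)
  check_prob_mat(cfg$fazekas_probs, "fazekas_probs", 4)
  for (f in c("base_recovery_pct", "per_receptor_penalty", "noise_sd",
              "gain_noise_sd")) {
    if (!is.numeric(cfg[[f]]) || length(cfg[[f]]) != 1L || is.na(cfg[[f]])) {
      err(f, "must be a single number")
    }
  }
  for (f in c("bilateral_absent_prob", "anacusis_prob",
              "tuning_pos_prob_contra")) {
    if (cfg[[f]] < 0 || cfg[[f]] > 1) err(f, "must be a probability")
  }
  for (f in c("enhanced_prob", "tuning_pos_prob_ipsi")) {
    if (length(cfg[[f]]) != 3L || any(cfg[[f]] < 0 | cfg[[f]] > 1)) {
      err(f, "must be 3 probabilities")
    }
  }
  if (length(cfg$risk_probs) != 7L ||
      any(cfg$risk_probs < 0 | cfg$risk_probs > 1)) {
    err("risk_probs", "must be 7 probabilities")
  }
  invisible(cfg)
}

#' @export
print.cohort_config <- function(x, ...) {
  cat(sprintf("<cohort_config> n = %d, seed = %d\n", x$n_patients,
              as.integer(x$seed)))
  cat("  subgroup props:",
      paste(names(x$subgroup_props), round(x$subgroup_props, 3),
            sep = "=", collapse = " "), "\n")
  cat(sprintf("  recovery: %.0f%% - %.0f%%/receptor, sd %.0f%%\n",
              x$base_recovery_pct, x$per_receptor_penalty, x$noise_sd))
  invisible(x)
}

round5 <- function(x) 5 * round(x / 5)
rbern <- function(p) stats::runif(1) < p
rcat <- function(levels, probs) {
  levels[findInterval(stats::runif(1), cumsum(probs / sum(probs))) + 1L]
}

# AC/BC shape templates per configuration, scaled so the worst contiguous
# 4-frequency BC window has mean weight 1 (the target PTA lands on target).
audiogram_shapes <- function(configuration) {
  sh <- switch(configuration,
    flat = list(ac = rep(1, 7), bc = rep(1, 5)),
    low_frequency = list(ac = c(1.30, 1.25, 1.15, 1.00, 0.70, 0.50, 0.45),
                         bc = c(1.25, 1.15, 1.00, 0.70, 0.50)),
    high_frequency = list(ac = c(0.45, 0.50, 0.70, 1.00, 1.15, 1.25, 1.30),
                          bc = c(0.50, 0.70, 1.00, 1.15, 1.25))
  )
  w <- max(vapply(1:2, function(i) mean(sh$bc[i:(i + 3L)]), numeric(1)))
  sh$bc <- sh$bc / w
  sh
}

eligibility_band <- function(configuration) {
  switch(configuration,
         low_frequency = 1:3,      # 125-500 Hz
         high_frequency = 5:7,     # 2000-8000 Hz
         flat = 1:7)
}

draw_degree_target <- function(degree) {
  switch(degree,
    mild = sample(c(30, 35, 40), 1L),
    moderate = sample(seq(45, 70, by = 5), 1L),
    severe = sample(seq(75, 90, by = 5), 1L),
    profound_anacusis = sample(seq(95, 110, by = 5), 1L)
  )
}

# Draw a VEMP side pair (contra, ipsi, absence flags) consistent with the
# latent impairment flag, so re-scoring reproduces the flag exactly.
draw_vemp <- function(impaired, enhanced_p, bilat_p, meanlog, sdlog) {
  contra <- round(stats::rlnorm(1, meanlog, sdlog), 2)
  if (impaired) {
    if (rbern(bilat_p)) {
      return(list(ipsi = 0, contra = 0, absent_ipsi = TRUE,
                  absent_contra = TRUE))
    }
    ar <- stats::runif(1, 33.5, 100)
    if (ar > 95) {
      return(list(ipsi = 0, contra = contra, absent_ipsi = TRUE,
                  absent_contra = FALSE))
    }
  } else if (rbern(enhanced_p)) {
    ar <- stats::runif(1, -95, -34)
  } else {
    ar <- stats::runif(1, -28, 28)
  }
  ipsi <- round(contra * (1 - ar / 100) / (1 + ar / 100), 2)
  list(ipsi = ipsi, contra = contra, absent_ipsi = FALSE,
       absent_contra = FALSE)
}

# Gain consistent with the latent canal flag: impaired = low gain with
# saccades; spared = normal gain (occasionally saccades with normal gain, or
# isolated low gain without saccades - both classed spared).
draw_gain <- function(impaired, canal, gain_noise_sd) {
  thr <- VHIT_GAIN_THRESHOLDS[[canal]]
  if (impaired) {
    list(gain = round(stats::runif(1, 0.25, thr - 0.03), 2), saccades = TRUE)
  } else {
    u <- stats::runif(1)
    if (u < 0.03) {
      list(gain = round(stats::runif(1, thr - 0.15, thr - 0.03), 2),
           saccades = FALSE)
    } else {
      g <- min(1.45, max(thr + 0.02, stats::rnorm(1, 0.98, gain_noise_sd)))
      list(gain = round(g, 2), saccades = stats::runif(1) < 0.05)
    }
  }
}

NYSTAGMUS_PROBS <- list(
  sn = c(absent = 0.605, contra = 0.209, ipsi = 0.140, downbeating = 0.023,
         upbeating = 0.023),
  pn = c(absent = 0.790, apogeotropic = 0.116, geotropic = 0.035,
         paroxysmal_upbeating = 0.035, persistent_downbeating = 0.012,
         persistent_upbeating = 0.012),
  hsn = c(absent = 0.616, contra = 0.174, ipsi = 0.094, downbeating = 0.116,
          upbeating = 0.000),
  vin = c(absent = 0.732, contra = 0.140, ipsi = 0.116, downbeating = 0.012,
          upbeating = 0.000),
  hvn = c(absent = 0.872, contra = 0.058, ipsi = 0.058, downbeating = 0.012,
          upbeating = 0.000)
)

#' Generate a synthetic SSNHL cohort
#'
#' Draws `n_patients` patient records under the study's statistical
#' structure: subgroup, latent receptor-impairment flags, VEMP amplitudes
#' and vHIT gains consistent with those flags (re-scoring the amplitudes
#' and gains reproduces the latent flags exactly), admission audiograms
#' that satisfy the SSNHL eligibility rule, and a 6-month follow-up
#' audiogram generated from the recovery model
#' `clip(base - penalty x n_receptors + Normal(0, sd), 0, 100)`.
#'
#' Draws are made per patient in a fixed order (subgroup, lesion flags,
#' amplitudes, gains, audiogram, recovery, then covariates), so increasing
#' `n_patients` extends the cohort without perturbing earlier patients.
#' Latent truth is kept in `subgroup`, `lat_*` and `lat_pct_recovery`
#' columns for generator validation.
#'
#' @param config A `cohort_config`.
#' @return A tibble with one row per patient, columns per `cohort_schema()`.
#' @examples
#' head(generate_cohort(cohort_config(n_patients = 20, seed = 42)))
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "cohort_config")) {
    config <- do.call(cohort_config, config)
  }
  validate_cohort_config(config)
  withr::with_seed(as.integer(config$seed), {
    rows <- lapply(seq_len(config$n_patients), function(i) {
      generate_patient(i, config)
    })
  })
  cols <- cohort_schema()$column
  tbl <- tibble::as_tibble(data.table::rbindlist(lapply(rows, `[`, cols)))
  attr(tbl, "provenance") <- list(source = "synthetic",
                                  seed = as.integer(config$seed))
  tbl
}

generate_patient <- function(i, cfg) {
  sg <- rcat(SUBGROUP_LEVELS, cfg$subgroup_props)

  # latent receptor-impairment flags
  prev <- cfg$prevalences[, sg]
  lat <- vapply(prev, rbern, logical(1))
  names(lat) <- rownames(cfg$prevalences)
  n_rec <- sum(lat)

  # VEMP amplitudes (500 Hz) consistent with the flags
  cv <- draw_vemp(lat[["saccule"]], cfg$enhanced_prob[[sg]],
                  cfg$bilateral_absent_prob, cfg$cvemp_meanlog,
                  cfg$cvemp_sdlog)
  ov <- draw_vemp(lat[["utricle"]], cfg$enhanced_prob[[sg]],
                  cfg$bilateral_absent_prob, cfg$ovemp_meanlog,
                  cfg$ovemp_sdlog)

  # cVEMP 1-kHz amplitudes per side from the tuning flag
  draw_1k <- function(a500, absent, p_pos) {
    if (absent) return(NA_real_)
    if (rbern(p_pos)) round(a500 + abs(stats::rnorm(1, 5, 4)), 2)
    else round(max(0.5, a500 - abs(stats::rnorm(1, a500 * 0.3, 5))), 2)
  }
  cv_1k_ipsi <- draw_1k(cv$ipsi, cv$absent_ipsi, cfg$tuning_pos_prob_ipsi[[sg]])
  cv_1k_con <- draw_1k(cv$contra, cv$absent_contra, cfg$tuning_pos_prob_contra)

  # vHIT gains consistent with the flags
  g_h <- draw_gain(lat[["hsc"]], "HSC", cfg$gain_noise_sd)
  g_a <- draw_gain(lat[["asc"]], "ASC", cfg$gain_noise_sd)
  g_p <- draw_gain(lat[["psc"]], "PSC", cfg$gain_noise_sd)

  # admission audiograms
  configuration <- rcat(rownames(cfg$config_mix), cfg$config_mix[, sg])
  degree <- rcat(rownames(cfg$degree_mix), cfg$degree_mix[, sg])
  anacusis <- degree == "profound_anacusis" && rbern(cfg$anacusis_prob)
  target <- draw_degree_target(degree)

  ac_con <- round5(stats::runif(7, 0, 20))
  bc_con <- pmax(-10, ac_con[2:6] - round5(stats::runif(5, 0, 7)))
  if (anacusis) {
    ac_aff <- rep(120, 7)
    bc_aff <- rep(120, 5)
    wrs <- 0
  } else {
    sh <- audiogram_shapes(configuration)
    ac_aff <- pmin(120, pmax(0, round5(target * sh$ac + stats::rnorm(7, 0, 3))))
    bc_aff <- pmin(120, pmax(-10, round5(target * sh$bc + stats::rnorm(5, 0, 3))))
    band <- eligibility_band(configuration)
    ac_aff[band] <- pmin(120, pmax(ac_aff[band], ac_con[band] + 35))
    wrs <- min(100, max(0, round(100 - 0.8 * target + stats::rnorm(1, 0, 10))))
  }

  # recovery
  lat_pct <- min(100, max(0, cfg$base_recovery_pct -
                            cfg$per_receptor_penalty * n_rec +
                            stats::rnorm(1, 0, cfg$noise_sd)))
  frac <- lat_pct / 100
  ac_aff_m6 <- round(ac_con + (1 - frac) * (ac_aff - ac_con))
  bc_aff_m6 <- round(bc_con + (1 - frac) * (bc_aff - bc_con))
  anacusis_m6 <- anacusis && lat_pct < 5
  wrs_m6 <- min(100, max(0, round(45 + 0.5 * lat_pct + stats::rnorm(1, 0, 8))))
  if (anacusis_m6) wrs_m6 <- 0

  # clinical course consistent with the subgroup
  if (sg == "ssnhl_no_vertigo") {
    vert_onset <- FALSE; vert_followup <- FALSE; fluct <- FALSE; md <- FALSE
  } else if (sg == "ssnhl_vertigo") {
    vert_onset <- TRUE; vert_followup <- FALSE; fluct <- FALSE; md <- FALSE
  } else {
    md <- TRUE; vert_onset <- rbern(0.5); vert_followup <- TRUE
    fluct <- rbern(0.6)
  }

  # covariates
  risk <- vapply(cfg$risk_probs, rbern, logical(1))
  fazekas <- as.integer(rcat(as.character(0:3), cfg$fazekas_probs[, sg]))
  age <- as.integer(min(90, max(18, round(stats::rnorm(1, 55.7, 14.4)))))
  days <- as.integer(min(30, max(1, round(stats::rnorm(1, 14.4, 10.7)))))
  side <- if (rbern(0.419)) "right" else "left"
  ocu <- vapply(names(NYSTAGMUS_PROBS), function(k) {
    rcat(names(NYSTAGMUS_PROBS[[k]]), NYSTAGMUS_PROBS[[k]])
  }, character(1))

  out <- c(
    list(patient_id = i, subgroup = sg, age = age, side = side,
         vert_onset = vert_onset, vert_followup = vert_followup,
         fluct_hl = fluct, md_criteria = md, days_onset_treat = days),
    as.list(setNames(as.logical(risk), names(cfg$risk_probs))),
    list(fazekas = fazekas),
    as.list(setNames(as.numeric(ac_aff), paste0("ac_aff_", AC_FREQS))),
    as.list(setNames(as.numeric(bc_aff), paste0("bc_aff_", BC_FREQS))),
    as.list(setNames(as.numeric(ac_con), paste0("ac_con_", AC_FREQS))),
    as.list(setNames(as.numeric(bc_con), paste0("bc_con_", BC_FREQS))),
    list(wrs_aff = as.numeric(wrs), anacusis = anacusis),
    as.list(setNames(as.numeric(ac_aff_m6), paste0("ac_aff_", AC_FREQS, "_m6"))),
    as.list(setNames(as.numeric(bc_aff_m6), paste0("bc_aff_", BC_FREQS, "_m6"))),
    as.list(setNames(as.numeric(ac_con), paste0("ac_con_", AC_FREQS, "_m6"))),
    as.list(setNames(as.numeric(bc_con), paste0("bc_con_", BC_FREQS, "_m6"))),
    list(wrs_aff_m6 = as.numeric(wrs_m6), anacusis_m6 = anacusis_m6,
         cvemp_ipsi_500 = cv$ipsi, cvemp_con_500 = cv$contra,
         cvemp_ipsi_1k = cv_1k_ipsi, cvemp_con_1k = cv_1k_con,
         cvemp_absent_ipsi = cv$absent_ipsi,
         cvemp_absent_con = cv$absent_contra,
         ovemp_ipsi_500 = ov$ipsi, ovemp_con_500 = ov$contra,
         ovemp_absent_ipsi = ov$absent_ipsi,
         ovemp_absent_con = ov$absent_contra,
         vhit_gain_hsc = g_h$gain, vhit_gain_asc = g_a$gain,
         vhit_gain_psc = g_p$gain,
         vhit_sacc_hsc = g_h$saccades, vhit_sacc_asc = g_a$saccades,
         vhit_sacc_psc = g_p$saccades,
         sn = ocu[["sn"]], pn = ocu[["pn"]], hsn = ocu[["hsn"]],
         vin = ocu[["vin"]], hvn = ocu[["hvn"]],
         lat_sacc = lat[["saccule"]], lat_utr = lat[["utricle"]],
         lat_hsc = lat[["hsc"]], lat_asc = lat[["asc"]],
         lat_psc = lat[["psc"]], lat_pct_recovery = lat_pct)
  )
  out
}

#' Worked-example fixture patients
#'
#' Deterministic single-patient records reproducing the printed findings of
#' the three published case illustrations of arterial lesion patterns:
#' `"vca"` (high-frequency loss, PSC gain 0.42 with overt saccades, absent
#' ipsilesional cVEMP with AR = 100%, oVEMP AR = 29% within normal range),
#' `"cca"` (severe down-sloping loss, PSC gain 0.6 with saccades, absent
#' ipsilesional cVEMP, oVEMP AR = 33%), and `"iaa"` (severe flat loss,
#' VOR-gain impairment of all three canals, absent ipsilesional cVEMP and
#' oVEMP, AR = 100%). They classify as VCA, CCA and IAA respectively; the
#' IAA patient has all five receptors impaired.
#'
#' @param which `"vca"`, `"cca"` or `"iaa"`.
#' @return A one-row tibble in the cohort schema.
#' @examples
#' make_worked_example("vca")$vhit_gain_psc  # 0.42
#' @export
make_worked_example <- function(which = c("vca", "cca", "iaa")) {
  which <- match.arg(which)

  base <- list(
    patient_id = 1L, subgroup = "ssnhl_vertigo", age = 58L,
    vert_onset = TRUE, vert_followup = FALSE, fluct_hl = FALSE,
    md_criteria = FALSE, days_onset_treat = 5L,
    htn = TRUE, chol = FALSE, prior_cvd = FALSE, dm = FALSE, bmi25 = TRUE,
    smoke = FALSE, lab_abn = TRUE, fazekas = 2L,
    wrs_aff = 60, anacusis = FALSE, anacusis_m6 = FALSE,
    cvemp_ipsi_1k = NA_real_, cvemp_con_1k = 70,
    sn = "contra", pn = "absent", hsn = "contra", vin = "contra",
    hvn = "absent",
    lat_pct_recovery = NA_real_
  )
  aud <- function(ac_aff, bc_aff, ac_con, bc_con, frac, wrs_m6) {
    c(setNames(as.list(as.numeric(ac_aff)), paste0("ac_aff_", AC_FREQS)),
      setNames(as.list(as.numeric(bc_aff)), paste0("bc_aff_", BC_FREQS)),
      setNames(as.list(as.numeric(ac_con)), paste0("ac_con_", AC_FREQS)),
      setNames(as.list(as.numeric(bc_con)), paste0("bc_con_", BC_FREQS)),
      setNames(as.list(round(ac_con + (1 - frac) * (ac_aff - ac_con))),
               paste0("ac_aff_", AC_FREQS, "_m6")),
      setNames(as.list(round(bc_con + (1 - frac) * (bc_aff - bc_con))),
               paste0("bc_aff_", BC_FREQS, "_m6")),
      setNames(as.list(as.numeric(ac_con)), paste0("ac_con_", AC_FREQS, "_m6")),
      setNames(as.list(as.numeric(bc_con)), paste0("bc_con_", BC_FREQS, "_m6")),
      list(wrs_aff_m6 = wrs_m6))
  }
  vemp <- function(prefix, ipsi, contra, absent_ipsi) {
    setNames(list(ipsi, contra, absent_ipsi, FALSE),
             paste0(prefix, c("_ipsi_500", "_con_500", "_absent_ipsi",
                              "_absent_con")))
  }
  vhit <- function(h, a, p, sh, sa, sp) {
    list(vhit_gain_hsc = h, vhit_gain_asc = a, vhit_gain_psc = p,
         vhit_sacc_hsc = sh, vhit_sacc_asc = sa, vhit_sacc_psc = sp)
  }

  rec <- switch(which,
    vca = c(base, list(side = "right",
                       lat_sacc = TRUE, lat_utr = FALSE, lat_hsc = FALSE,
                       lat_asc = FALSE, lat_psc = TRUE),
            aud(ac_aff = c(20, 20, 25, 40, 60, 70, 75),
                bc_aff = c(20, 25, 40, 60, 65),
                ac_con = c(10, 10, 10, 15, 15, 20, 20),
                bc_con = c(10, 10, 10, 15, 15),
                frac = 0.5, wrs_m6 = 80),
            vemp("cvemp", ipsi = 0, contra = 98.5, absent_ipsi = TRUE),
            vemp("ovemp", ipsi = 3.55, contra = 6.45, absent_ipsi = FALSE),
            vhit(0.95, 0.90, 0.42, FALSE, FALSE, TRUE)),
    cca = c(base, list(side = "right",
                       lat_sacc = TRUE, lat_utr = TRUE, lat_hsc = FALSE,
                       lat_asc = FALSE, lat_psc = TRUE),
            aud(ac_aff = c(45, 55, 65, 75, 85, 90, 95),
                bc_aff = c(50, 65, 75, 85, 90),
                ac_con = c(10, 10, 15, 15, 20, 20, 25),
                bc_con = c(10, 15, 15, 20, 20),
                frac = 0.05, wrs_m6 = 40),
            vemp("cvemp", ipsi = 0, contra = 110, absent_ipsi = TRUE),
            vemp("ovemp", ipsi = 3.35, contra = 6.65, absent_ipsi = FALSE),
            vhit(0.82, 0.75, 0.60, FALSE, FALSE, TRUE)),
    iaa = c(base, list(side = "left",
                       lat_sacc = TRUE, lat_utr = TRUE, lat_hsc = TRUE,
                       lat_asc = TRUE, lat_psc = TRUE),
            aud(ac_aff = rep(85, 7),
                bc_aff = rep(85, 5),
                ac_con = c(10, 10, 10, 10, 15, 15, 20),
                bc_con = c(10, 10, 10, 15, 15),
                frac = 0.02, wrs_m6 = 20),
            vemp("cvemp", ipsi = 0, contra = 90, absent_ipsi = TRUE),
            vemp("ovemp", ipsi = 0, contra = 8.5, absent_ipsi = TRUE),
            vhit(0.35, 0.40, 0.30, TRUE, TRUE, TRUE))
  )
  tibble::as_tibble(rec[cohort_schema()$column])
}
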