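# Shared builders for small test objects.

flat_audiogram <- function(level, wrs = NA_real_, anacusis = FALSE,
                           ear = "affected") {
  audiogram(ac = setNames(rep(level, 7), AC_FREQS),
            bc = setNames(rep(level, 5), BC_FREQS),
            wrs = wrs, anacusis = anacusis, ear = ear)
}

bc_audiogram <- function(bc, wrs = NA_real_) {
  audiogram(bc = setNames(bc, BC_FREQS), wrs = wrs)
}

# VEMP pair with a given asymmetry ratio on 500-Hz amplitudes.
vemp_with_ar <- function(ar, kind = "cervical", scale = 100) {
  contra <- scale * (1 + ar / 100) / 2
  ipsi <- scale * (1 - ar / 100) / 2
  vemp_pair(kind, ipsi_500 = ipsi, contra_500 = contra)
}

# Exams whose scoring reproduces the given five impairment flags.
exams_for_flags <- function(s, u, h, a, p) {
  mk_vemp <- function(kind, impaired) {
    if (impaired) vemp_pair(kind, ipsi_500 = 0, contra_500 = 10,
                            absent_ipsi = TRUE)
    else vemp_pair(kind, ipsi_500 = 10, contra_500 = 10)
  }
  list(
    cvemp = mk_vemp("cervical", s),
    ovemp = mk_vemp("ocular", u),
    vhit = vhit_exam(gain_hsc = if (h) 0.50 else 1.00,
                     gain_asc = if (a) 0.45 else 0.95,
                     gain_psc = if (p) 0.40 else 0.90,
                     saccades_hsc = h, saccades_asc = a, saccades_psc = p)
  )
}
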