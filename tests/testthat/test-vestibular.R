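test_that("asymmetry ratio evaluates the printed formula", {
  expect_equal(asymmetry_ratio(10, 0), 100)
  expect_equal(asymmetry_ratio(5, 5), 0)
  expect_equal(asymmetry_ratio(8, 4), 100 / 3, tolerance = 1e-10)
  expect_error(asymmetry_ratio(-1, 5), "non-negative")
  expect_warning(expect_true(is.na(asymmetry_ratio(0, 0))), "undefined")
})

test_that("asymmetry ratio is antisymmetric and scale-invariant", {
  set.seed(11)
  for (i in 1:200) {
    a <- runif(1, 0.1, 200)
    b <- runif(1, 0.1, 200)
    k <- runif(1, 0.01, 50)
    expect_equal(asymmetry_ratio(a, b), -asymmetry_ratio(b, a))
    expect_equal(asymmetry_ratio(k * a, k * b), asymmetry_ratio(a, b),
                 tolerance = 1e-9)
    expect_true(abs(asymmetry_ratio(a, b)) <= 100)
  }
})

test_that("otolith impairment uses AR >= 33 inclusive or bilateral absence", {
  bilat <- vemp_pair("cervical", 0, 0, absent_ipsi = TRUE,
                     absent_contra = TRUE)
  expect_equal(call_otolith_impairment(bilat), "impaired")
  expect_equal(call_otolith_impairment(vemp_with_ar(33)), "impaired")
  expect_equal(call_otolith_impairment(vemp_with_ar(32.9)), "spared")
  expect_equal(call_otolith_impairment(vemp_with_ar(0)), "spared")
  # unilateral absence goes through the AR = 100 path
  uni <- vemp_pair("ocular", ipsi_500 = 0, contra_500 = 7, absent_ipsi = TRUE)
  expect_equal(call_otolith_impairment(uni), "impaired")
})

test_that("enhanced responses are AR <= -33 inclusive", {
  expect_true(call_enhanced_response(vemp_pair("cervical", 8, 4)))
  expect_false(call_enhanced_response(vemp_pair("cervical", 5, 5)))
  expect_false(call_enhanced_response(vemp_pair("cervical", 4, 8)))
  expect_true(call_enhanced_response(vemp_with_ar(-33)))
  expect_error(call_enhanced_response(
    vemp_pair("cervical", 0, 0, absent_ipsi = TRUE, absent_contra = TRUE)),
    "bilaterally absent")
})

test_that("cVEMP frequency tuning is positive when the 1 kHz - 500 Hz difference is >= 0", {
  v <- vemp_pair("cervical", ipsi_500 = 20, contra_500 = 22,
                 ipsi_1k = 20, contra_1k = 10)
  expect_true(cvemp_tuning(v, "ipsi"))    # difference exactly 0
  expect_false(cvemp_tuning(v, "contra")) # -12
  v2 <- vemp_pair("cervical", ipsi_500 = 20, contra_500 = 20,
                  ipsi_1k = 25, contra_1k = 25)
  expect_true(cvemp_tuning(v2, "ipsi"))
  expect_error(cvemp_tuning(vemp_pair("ocular", 5, 5), "ipsi"),
               "cVEMPs only")
  absent <- vemp_pair("cervical", 0, 30, ipsi_1k = NA, contra_1k = 25,
                      absent_ipsi = TRUE)
  expect_true(is.na(cvemp_tuning(absent, "ipsi")))
})

test_that("canal impairment needs gain below the cut-off AND saccades", {
  ex <- vhit_exam(1.0, 0.95, 0.42, saccades_psc = TRUE)
  expect_equal(call_canal_impairment(ex, "PSC"), "impaired")
  expect_equal(call_canal_impairment(vhit_exam(0.8, 1, 1), "HSC"), "spared")
  expect_equal(
    call_canal_impairment(vhit_exam(0.8, 1, 1, saccades_hsc = TRUE), "HSC"),
    "spared")  # boundary gain not below the cut-off
  expect_equal(
    call_canal_impairment(vhit_exam(1, 1, 0.6, saccades_psc = TRUE), "PSC"),
    "impaired")
  # low gain without corrective saccades is classed spared
  expect_equal(
    call_canal_impairment(vhit_exam(0.5, 1, 1), "HSC"), "spared")
  # thresholds differ per canal: 0.75 impairs HSC but not ASC/PSC
  ex2 <- vhit_exam(0.75, 0.75, 0.75, TRUE, TRUE, TRUE)
  expect_equal(call_canal_impairment(ex2, "HSC"), "impaired")
  expect_equal(call_canal_impairment(ex2, "ASC"), "spared")
  expect_equal(call_canal_impairment(ex2, "PSC"), "spared")
})

test_that("lesion patterns match a brute-force enumeration over all 32 flag states", {
  oracle_labels <- function(s, u, h, a, p) {
    oto <- if (s && u) "S_U" else if (s) "S" else if (u) "U" else "none"
    canals <- c("HSC", "ASC", "PSC")[c(h, a, p)]
    can <- if (length(canals)) paste(canals, collapse = "+") else "none"
    list(oto = oto, can = can, n = s + u + h + a + p)
  }
  for (bits in 0:31) {
    f <- as.logical(bitwAnd(bits, c(16L, 8L, 4L, 2L, 1L)) > 0)
    ex <- exams_for_flags(f[1], f[2], f[3], f[4], f[5])
    lp <- build_lesion_pattern(ex$cvemp, ex$ovemp, ex$vhit)
    expect_equal(c(lp$saccule_impaired, lp$utricle_impaired, lp$hsc_impaired,
                   lp$asc_impaired, lp$psc_impaired), f)
    orc <- oracle_labels(f[1], f[2], f[3], f[4], f[5])
    expect_equal(lp$otolith_pattern, orc$oto)
    expect_equal(lp$canal_pattern, orc$can)
    expect_equal(lp$n_receptors, orc$n)
  }
})

test_that("bilateral absence dominates stored amplitudes", {
  # absence flags zero the amplitudes, so the call never sees an AR
  v <- vemp_pair("cervical", ipsi_500 = 50, contra_500 = 50,
                 absent_ipsi = TRUE, absent_contra = TRUE)
  expect_equal(v$ipsi_500, 0)
  expect_equal(call_otolith_impairment(v), "impaired")
})

test_that("constructors validate amplitudes and gains", {
  expect_error(vemp_pair("cervical", -1, 5), "non-negative")
  expect_error(vemp_pair("ocular", 5, 5, ipsi_1k = 10), "cervical VEMPs only")
  expect_error(vhit_exam(1.8, 1, 1), "\\[0, 1.5\\]")
})
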