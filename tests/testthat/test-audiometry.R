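test_that("PTA is the mean of the four most impaired contiguous BC frequencies", {
  expect_equal(as.numeric(compute_pta(flat_audiogram(60))), 60)
  # rising audiogram: the 500-4000 Hz window wins
  pta <- compute_pta(bc_audiogram(c(30, 40, 50, 60, 70)))
  expect_equal(as.numeric(pta), (40 + 50 + 60 + 70) / 4)
  expect_equal(attr(pta, "window"), c("500", "1000", "2000", "4000"))
})

test_that("anacusis is assigned a PTA of 120 dB", {
  ex <- audiogram(anacusis = TRUE)
  expect_equal(as.numeric(compute_pta(ex)), 120)
})

test_that("PTA errors with fewer than 4 contiguous BC thresholds", {
  ex <- audiogram(bc = c(`250` = 30, `500` = 40, `1000` = 50))
  expect_error(compute_pta(ex), "insufficient audiogram")
  # a gap breaks contiguity even with 4 thresholds present
  ex2 <- audiogram(bc = c(`250` = 30, `500` = 40, `2000` = 50, `4000` = 60))
  expect_error(compute_pta(ex2), "insufficient audiogram")
})

test_that("PTA equals a brute-force maximum over contiguous windows", {
  set.seed(101)
  for (i in 1:1000) {
    bc <- round(runif(5, -10, 120))
    oracle <- max(mean(bc[1:4]), mean(bc[2:5]))
    expect_equal(as.numeric(compute_pta(bc_audiogram(bc))), oracle)
  }
})

test_that("equal-mean windows break ties toward the higher frequencies", {
  pta <- compute_pta(bc_audiogram(c(50, 50, 50, 50, 50)))
  expect_equal(attr(pta, "window"), c("500", "1000", "2000", "4000"))
  pta_low <- compute_pta(bc_audiogram(c(50, 50, 50, 50, 50)), tie = "low")
  expect_equal(attr(pta_low, "window"), c("250", "500", "1000", "2000"))
})

test_that("degree cut-offs partition the PTA range with inclusive boundaries", {
  expect_equal(classify_degree(40), "mild")
  expect_equal(classify_degree(70), "moderate")
  expect_equal(classify_degree(90), "severe")
  expect_equal(classify_degree(120), "profound_anacusis")
  grid <- seq(-10, 120, by = 0.5)
  deg <- classify_degree(grid)
  expect_true(all(deg %in% c("mild", "moderate", "severe",
                             "profound_anacusis")))
  expect_equal(deg[grid <= 40], rep("mild", sum(grid <= 40)))
  expect_equal(unique(deg[grid > 40 & grid <= 70]), "moderate")
  expect_equal(unique(deg[grid > 70 & grid <= 90]), "severe")
  expect_equal(unique(deg[grid > 90]), "profound_anacusis")
})

test_that("configuration compares low-band vs high-band AC means", {
  lf <- audiogram(ac = c(`125` = 60, `250` = 60, `500` = 60, `1000` = 40,
                         `2000` = 25, `4000` = 25, `8000` = 25))
  expect_equal(classify_configuration(lf), "low_frequency")
  expect_equal(classify_configuration(flat_audiogram(45)), "flat")
  hf <- audiogram(ac = c(`125` = 20, `250` = 20, `500` = 25, `1000` = 50,
                         `2000` = 70, `4000` = 80, `8000` = 85))
  expect_equal(classify_configuration(hf), "high_frequency")
  # just under the band criterion stays flat
  near <- audiogram(ac = c(`125` = 30, `250` = 30, `500` = 30, `1000` = 35,
                           `2000` = 44, `4000` = 44, `8000` = 44))
  expect_equal(classify_configuration(near), "flat")
  expect_error(classify_configuration(audiogram(ac = c(`125` = 30))),
               "missing AC")
})

test_that("SSNHL eligibility needs >= 30 dB at >= 3 consecutive frequencies", {
  con <- flat_audiogram(10, ear = "contralateral")
  expect_false(check_ssnhl_eligibility(flat_audiogram(10), con))
  aff <- audiogram(ac = c(`125` = 10, `250` = 10, `500` = 10, `1000` = 45,
                          `2000` = 45, `4000` = 45, `8000` = 10))
  expect_true(check_ssnhl_eligibility(aff, con))
  # 35 dB loss at 1k and 4k but not 2k: no 3-frequency run
  aff2 <- audiogram(ac = c(`125` = 10, `250` = 10, `500` = 10, `1000` = 45,
                           `2000` = 10, `4000` = 45, `8000` = 10))
  expect_false(check_ssnhl_eligibility(aff2, con))
})

test_that("eligibility is invariant to adding a constant to both ears", {
  set.seed(7)
  for (i in 1:50) {
    a <- round(runif(7, 0, 80))
    b <- round(runif(7, 0, 40))
    k <- sample(0:30, 1)
    aff <- audiogram(ac = setNames(a, AC_FREQS))
    con <- audiogram(ac = setNames(b, AC_FREQS), ear = "contralateral")
    aff_k <- audiogram(ac = setNames(a + k, AC_FREQS))
    con_k <- audiogram(ac = setNames(b + k, AC_FREQS), ear = "contralateral")
    expect_equal(check_ssnhl_eligibility(aff, con),
                 check_ssnhl_eligibility(aff_k, con_k))
  }
})

test_that("recovery categories follow the PTA and WRS rules", {
  con <- flat_audiogram(30, ear = "contralateral")
  out <- assess_recovery(flat_audiogram(80), flat_audiogram(45, wrs = 80), con)
  expect_equal(out$category, "partial")   # 45 > 30 + 10, improved 35 > 10
  expect_equal(out$percent_recovery, 70)
  expect_equal(out$pta_recovered, 35)

  # "within 10 dB of the unaffected ear" is inclusive
  boundary <- assess_recovery(flat_audiogram(80), flat_audiogram(40, wrs = 80),
                              con)
  expect_equal(boundary$category, "complete")
  expect_equal(boundary$percent_recovery, 80)

  full <- assess_recovery(flat_audiogram(80), flat_audiogram(30, wrs = 100), con)
  expect_equal(full$category, "complete")
  expect_equal(full$percent_recovery, 100)

  none <- assess_recovery(flat_audiogram(80), flat_audiogram(75, wrs = 90), con)
  expect_equal(none$category, "none")     # improvement 5 < 10 dB

  # large improvement but poor speech discrimination is still no recovery
  poor_wrs <- assess_recovery(flat_audiogram(80), flat_audiogram(40, wrs = 40),
                              con)
  expect_equal(poor_wrs$category, "none")
})

test_that("percent recovery is 100 iff PTApost equals PTAcontra", {
  con <- flat_audiogram(20, ear = "contralateral")
  pre <- flat_audiogram(90)
  for (post_level in seq(20, 90, by = 10)) {
    out <- assess_recovery(pre, flat_audiogram(post_level, wrs = 80), con)
    expect_equal(out$percent_recovery == 100, post_level == 20)
  }
})

test_that("lowering PTApost never downgrades the recovery category", {
  rank <- c(none = 0, partial = 1, complete = 2)
  con <- flat_audiogram(25, ear = "contralateral")
  pre <- flat_audiogram(85)
  prev <- -Inf
  for (post_level in seq(85, 25, by = -5)) {
    out <- assess_recovery(pre, flat_audiogram(post_level, wrs = 80), con)
    expect_gte(rank[[out$category]], prev)
    prev <- rank[[out$category]]
  }
})

test_that("percent recovery is undefined without a measurable deficit", {
  con <- flat_audiogram(50, ear = "contralateral")
  expect_warning(
    out <- assess_recovery(flat_audiogram(40), flat_audiogram(35, wrs = 90),
                           con),
    "no measurable deficit")
  expect_true(is.na(out$percent_recovery))
})

test_that("audiogram construction validates ranges and frequencies", {
  expect_error(audiogram(ac = c(`125` = 135)), "out of")
  expect_error(audiogram(ac = c(`300` = 30)), "non-canonical")
  expect_error(audiogram(wrs = 150), "wrs")
})
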