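test_that("percentages reproduce printed cohort fractions to one decimal", {
  pairs <- rbind(
    c(39, 86, 45.3), c(37, 86, 43.0), c(20, 27, 74.1), c(15, 27, 55.6),
    c(15, 86, 17.4), c(24, 86, 27.9), c(11, 86, 12.8), c(41, 86, 47.7),
    c(16, 86, 18.6), c(18, 86, 20.9), c(22, 86, 25.6), c(21, 86, 24.4),
    c(43, 86, 50.0), c(25, 86, 29.1), c(27, 86, 31.4), c(34, 86, 39.5),
    c(14, 86, 16.3), c(10, 86, 11.6), c(8, 27, 29.6), c(5, 34, 14.7),
    c(6, 27, 22.2), c(31, 34, 91.2), c(18, 27, 66.7), c(22, 25, 88.0),
    c(9, 27, 33.3), c(36, 86, 41.9), c(45, 86, 52.3)
  )
  expect_equal(percent_of(pairs[, 1], pairs[, 2]), pairs[, 3])
})

test_that("percentages round half up, not half to even", {
  expect_equal(percent_of(1, 8), 12.5)
  expect_equal(percent_of(1, 800, digits = 0), 0)
  expect_equal(round_half_up(0.25, 1), 0.3)   # round() would give 0.2
  expect_equal(round_half_up(0.35, 1), 0.4)
})

test_that("tabulation reports counts and column percentages", {
  d <- data.frame(g = rep(c("a", "b"), c(50, 36)),
                  imp = c(rep(c("yes", "no"), c(20, 30)),
                          rep(c("yes", "no"), c(19, 17))))
  tb <- tabulate_cohort(d, "imp", "g")
  expect_equal(sum(tb$counts), 86)
  expect_equal(unname(tb$col_pct["yes", "a"]), 40.0)
  expect_equal(unname(colSums(tb$counts)), unname(tb$n))
  # single category tabulates to 100%
  one <- tabulate_cohort(data.frame(g = "a", v = rep("x", 5)), "v", "g")
  expect_equal(unname(one$col_pct[1, 1]), 100.0)
  # missing values form an explicit row
  dm <- data.frame(g = "a", v = c("x", NA, "x"))
  tbm <- tabulate_cohort(dm, "v", "g")
  expect_true("(missing)" %in% rownames(tbm$counts))
  expect_error(tabulate_cohort(d, "nope", "g"), "unknown variable")
})

test_that("categorical comparison picks chi-square or Fisher and records it", {
  flat <- compare_categorical(matrix(c(10, 10, 10, 10), 2))
  expect_equal(flat$method, "pearson_chisq")
  expect_equal(flat$statistic, 0)
  expect_equal(flat$p, 1)
  small <- compare_categorical(matrix(c(8, 1, 2, 9), 2))
  expect_equal(small$method, "fisher_exact")
  expect_true(small$p >= 0 && small$p <= 1)
  expect_error(compare_categorical(matrix(c(0, 0, 5, 5), 2)), "degenerate")
  expect_error(compare_categorical(matrix(1:3, 1)), "2 x 2")
})

test_that("Fisher exact p matches direct hypergeometric enumeration", {
  # oracle: sum of the probabilities of all tables with the same margins
  # that are no more probable than the observed one
  fisher_oracle <- function(tab) {
    m <- rowSums(tab); n <- colSums(tab)
    support <- max(0, n[1] - m[2]):min(m[1], n[1])
    probs <- dhyper(support, m[1], m[2], n[1])
    p_obs <- dhyper(tab[1, 1], m[1], m[2], n[1])
    sum(probs[probs <= p_obs * (1 + 1e-7)])
  }
  set.seed(33)
  for (i in 1:50) {
    tab <- matrix(rpois(4, 3) + 1, 2)
    expect_equal(stats::fisher.test(tab)$p.value, fisher_oracle(tab),
                 tolerance = 1e-8)
  }
})

test_that("Kruskal-Wallis H matches hand computation and handles ties", {
  d <- data.frame(v = c(1, 2, 3, 4, 5, 6), g = rep(c("a", "b"), each = 3))
  res <- compare_continuous(d, "v", "g")
  expect_equal(res$H, 27 / 7, tolerance = 1e-10)  # rank-formula value 3.857
  # identical samples in each group: no separation, H = 0
  d0 <- data.frame(v = rep(c(1, 2, 3), 2), g = rep(c("a", "b"), each = 3))
  expect_equal(compare_continuous(d0, "v", "g")$H, 0)
  expect_error(compare_continuous(data.frame(v = 1:3, g = "a"), "v", "g"),
               "2 groups")
})

test_that("Kruskal-Wallis H is invariant under monotone transformations", {
  set.seed(17)
  d <- data.frame(v = rexp(60), g = sample(c("a", "b", "c"), 60, TRUE))
  h0 <- compare_continuous(d, "v", "g")$H
  for (f in list(exp, sqrt, function(x) x^3 + 1)) {
    d2 <- d; d2$v <- f(d$v)
    expect_equal(compare_continuous(d2, "v", "g")$H, h0, tolerance = 1e-10)
  }
})

test_that("Dunn post-hoc p-values are adjusted upward", {
  set.seed(23)
  d <- data.frame(v = c(rnorm(20), rnorm(20, 1), rnorm(20, 2)),
                  g = rep(c("a", "b", "c"), each = 20))
  res <- compare_continuous(d, "v", "g")
  expect_equal(nrow(res$posthoc), 3L)
  expect_true(all(res$posthoc$p_adj >= res$posthoc$p_unadj - 1e-12))
  holm <- compare_continuous(d, "v", "g", adjust = "holm")
  expect_true(all(holm$posthoc$p_adj <= res$posthoc$p_adj + 1e-12))
})

test_that("recovery trend is negative under a positive per-receptor penalty", {
  scored <- score_cohort(generate_cohort(cohort_config(500, seed = 14)))
  tr <- recovery_trend(scored)
  expect_lt(tr$rho, 0)
  expect_lt(tr$p, 0.05)
  expect_true(all(diff(tr$strata$n_receptors) > 0))
})

test_that("recovery trend vanishes under the null generator", {
  cfg <- cohort_config(2000, seed = 15, per_receptor_penalty = 0)
  scored <- score_cohort(generate_cohort(cfg))
  tr <- recovery_trend(scored)
  expect_lt(abs(tr$rho), 0.1)
})

test_that("a single receptor-count stratum gives an undefined correlation", {
  d <- data.frame(n_receptors = rep(2L, 10), pct_recovery = runif(10))
  expect_warning(tr <- recovery_trend(d), "single")
  expect_true(is.na(tr$rho))
  expect_error(recovery_trend(data.frame(n_receptors = NA_integer_,
                                         pct_recovery = NA_real_)),
               "no non-missing")
})

test_that("the recovery regression recovers a saccule-only effect", {
  set.seed(31)
  n <- 2000
  d <- data.frame(
    sacc_imp = runif(n) < 0.45,
    utr_imp = runif(n) < 0.4,
    psc_imp = runif(n) < 0.2
  )
  lin <- 1.0 - 1.2 * d$sacc_imp
  d$recovery <- ifelse(runif(n) < plogis(lin), "partial", "none")
  fit <- fit_recovery_regression(d, predictors = c("sacc_imp", "utr_imp",
                                                   "psc_imp"))
  expect_false(fit$separation)
  co <- fit$coefficients
  sacc <- co[co$term == "sacc_imp", ]
  expect_lt(sacc$odds_ratio, 1)
  expect_lt(sacc$or_high, 1)        # CI excludes 1
  # the null predictors carry no signal: estimates near zero
  utr <- co[co$term == "utr_imp", ]
  expect_lt(abs(utr$estimate), 3.5 * utr$se)
})

test_that("constant predictors are dropped with a warning", {
  d <- data.frame(sacc_imp = rep(TRUE, 50),
                  utr_imp = runif(50) < 0.5,
                  recovery = sample(c("none", "partial"), 50, TRUE))
  expect_warning(fit <- fit_recovery_regression(
    d, predictors = c("sacc_imp", "utr_imp")), "constant")
  expect_equal(fit$dropped, "sacc_imp")
})

test_that("permuted outcomes leave confidence intervals covering the null", {
  set.seed(41)
  n <- 300
  base <- data.frame(sacc_imp = runif(n) < 0.5, psc_imp = runif(n) < 0.3)
  cover <- c(sacc_imp = 0, psc_imp = 0)
  reps <- 100
  for (r in 1:reps) {
    d <- base
    d$recovery <- sample(rep(c("partial", "none"), c(180, 120)))
    fit <- suppressWarnings(
      fit_recovery_regression(d, predictors = c("sacc_imp", "psc_imp")))
    if (fit$separation) next
    co <- fit$coefficients
    for (term in names(cover)) {
      row <- co[co$term == term, ]
      if (row$or_low < 1 && row$or_high > 1) {
        cover[[term]] <- cover[[term]] + 1
      }
    }
  }
  # each 95% CI covers the null in at least 90% of permutation replicates
  expect_true(all(cover >= 0.9 * reps))
})

test_that("separation is flagged and coefficients withheld", {
  d <- data.frame(sacc_imp = rep(c(TRUE, FALSE), each = 30),
                  recovery = rep(c("none", "partial"), each = 30))
  expect_warning(fit <- fit_recovery_regression(d, predictors = "sacc_imp"),
                 "separation")
  expect_true(fit$separation)
  expect_null(fit$coefficients)
})

test_that("the cohort report assembles tables, tests, trend and regression", {
  scored <- score_cohort(generate_cohort(cohort_config(250, seed = 19)))
  rep_ <- cohort_report(scored)
  expect_s3_class(rep_, "cohort_report")
  expect_true(all(c("sacc_imp", "recovery", "vascular_pattern") %in%
                    names(rep_$tables)))
  # counts in every table sum to the number of patients with a group value
  for (tb in rep_$tables) expect_equal(sum(tb$counts), nrow(scored))
  expect_false(is.null(rep_$trend))
  expect_output(print(rep_), "cohort_report")
})
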