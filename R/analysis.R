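# Cohort-level statistics: contingency tabulations with printed-style
# percentages, chi-square/Fisher comparisons, Kruskal-Wallis with Dunn
# post-hoc, the receptor-count vs percent-recovery trend, and logistic
# regression of hearing recovery.

#' Percentage as printed in clinical tables (round half-up, 1 decimal)
#'
#' `percent_of(39, 86)` is 45.3. R's `round()` rounds half to even; clinical
#' tables round half up, so 0.05 at the first decimal always rounds away
#' from zero.
#'
#' @param count,n Non-negative counts, `n > 0` (vectorized).
#' @param digits Decimal places (default 1).
#' @return Numeric percentage(s).
#' @export
percent_of <- function(count, n, digits = 1L) {
  stopifnot(all(count >= 0), all(n > 0))
  round_half_up(100 * count / n, digits)
}

round_half_up <- function(x, digits = 0L) {
  p <- 10^digits
  # +1e-9 guards against binary representation just below .5
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

#' Contingency tabulation with column percentages
#'
#' Cross-tabulates two categorical variables of a cohort table, reporting
#' counts and column percentages rounded half-up to one decimal, the style
#' of clinical cohort tables. Missing values form an explicit `"(missing)"`
#' row when present.
#'
#' @param records A data frame (e.g. a scored cohort).
#' @param row_var,col_var Column names of categorical variables.
#' @return A list of class `cohort_table`: `counts` (matrix),
#'   `col_pct` (matrix, 1 decimal), `n` (column totals).
#' @examples
#' d <- data.frame(g = rep(c("a", "b"), c(39, 47)),
#'                 imp = rep(c("yes", "no"), c(39, 47)))
#' tabulate_cohort(d, "imp", "g")
#' @export
tabulate_cohort <- function(records, row_var, col_var) {
  for (v in c(row_var, col_var)) {
    if (!v %in% names(records)) stop("unknown variable: ", v)
  }
  r <- as.character(records[[row_var]])
  c_ <- as.character(records[[col_var]])
  r[is.na(r)] <- "(missing)"
  keep <- !is.na(c_)
  counts <- table(row = r[keep], col = c_[keep])
  counts <- unclass(counts)
  n <- colSums(counts)
  pct <- sweep(counts, 2L, n, function(x, tot) percent_of(x, pmax(tot, 1)))
  structure(list(counts = counts, col_pct = pct, n = n,
                 row_var = row_var, col_var = col_var),
            class = "cohort_table")
}

#' @export
print.cohort_table <- function(x, ...) {
  cat(sprintf("<cohort_table> %s x %s\n", x$row_var, x$col_var))
  shown <- matrix(sprintf("%d (%.1f%%)", x$counts, x$col_pct),
                  nrow = nrow(x$counts), dimnames = dimnames(x$counts))
  print(shown, quote = FALSE)
  invisible(x)
}

#' Compare a contingency table (Pearson chi-square or Fisher exact)
#'
#' Fisher's exact test is used for 2 x 2 tables with any expected count
#' below 5; otherwise the (uncorrected) Pearson chi-square test. The method
#' used is recorded in the result.
#'
#' @param table A matrix of non-negative integer counts (at least 2 x 2),
#'   or a `cohort_table`.
#' @return A list: `statistic` (chi-square X^2; `NA` for Fisher), `p`,
#'   `method`.
#' @examples
#' compare_categorical(matrix(c(10, 10, 10, 10), 2))  # X^2 = 0, p = 1
#' @export
compare_categorical <- function(table) {
  if (inherits(table, "cohort_table")) table <- table$counts
  tab <- as.matrix(table)
  if (nrow(tab) < 2L || ncol(tab) < 2L) stop("need at least a 2 x 2 table")
  if (any(tab < 0) || any(tab != round(tab))) {
    stop("counts must be non-negative integers")
  }
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("degenerate table: zero row or column margin")
  }
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (all(dim(tab) == c(2L, 2L)) && any(expected < 5)) {
    ft <- stats::fisher.test(tab)
    list(statistic = NA_real_, p = unname(ft$p.value),
         method = "fisher_exact")
  } else {
    ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    list(statistic = unname(ct$statistic), p = unname(ct$p.value),
         method = "pearson_chisq")
  }
}

#' Kruskal-Wallis comparison with Dunn post-hoc tests
#'
#' Tie-corrected Kruskal-Wallis H across groups, followed by Dunn's
#' pairwise rank comparisons with Bonferroni (default) or Holm adjustment.
#'
#' @param records A data frame.
#' @param value_var Name of the numeric column.
#' @param group_var Name of the grouping column.
#' @param adjust `"bonferroni"` (default) or `"holm"`.
#' @return A list: `H`, `df`, `p`, and `posthoc` (data frame with one row
#'   per group pair: `z`, `p_unadj`, `p_adj`).
#' @export
compare_continuous <- function(records, value_var, group_var,
                               adjust = c("bonferroni", "holm")) {
  adjust <- match.arg(adjust)
  for (v in c(value_var, group_var)) {
    if (!v %in% names(records)) stop("unknown variable: ", v)
  }
  x <- records[[value_var]]
  g <- as.factor(records[[group_var]])
  ok <- !is.na(x) & !is.na(g)
  x <- x[ok]; g <- droplevels(g[ok])
  if (nlevels(g) < 2L) stop("need at least 2 groups")
  kw <- stats::kruskal.test(x, g)
  list(H = unname(kw$statistic), df = unname(kw$parameter),
       p = unname(kw$p.value),
       posthoc = dunn_posthoc(x, g, adjust = adjust))
}

# Dunn's z-statistics on mean ranks with the tie correction
# sum(t^3 - t) / (12 (N - 1)); two-sided normal p-values.
dunn_posthoc <- function(x, g, adjust = "bonferroni") {
  N <- length(x)
  r <- rank(x)
  lev <- levels(g)
  ni <- tapply(r, g, length)
  ri <- tapply(r, g, mean)
  ties <- table(x)
  tie_corr <- sum(ties^3 - ties) / (12 * (N - 1))
  v0 <- N * (N + 1) / 12 - tie_corr
  pairs <- utils::combn(lev, 2L)
  res <- apply(pairs, 2L, function(pr) {
    i <- pr[1]; j <- pr[2]
    se <- sqrt(v0 * (1 / ni[[i]] + 1 / ni[[j]]))
    z <- (ri[[i]] - ri[[j]]) / se
    c(z = z, p_unadj = 2 * stats::pnorm(-abs(z)))
  })
  out <- data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
                    z = res["z", ], p_unadj = res["p_unadj", ],
                    row.names = NULL)
  out$p_adj <- stats::p.adjust(out$p_unadj, method = adjust)
  out
}

#' Receptor-count vs percent-recovery trend
#'
#' Mean percent hearing recovery per receptor-count stratum (0--5) and the
#' Spearman rank correlation between the number of impaired vestibular
#' receptors and percent recovery.
#'
#' @param records A data frame with columns `n_receptors` and
#'   `pct_recovery` (or names passed via `count_var`/`value_var`).
#' @param count_var,value_var Column names.
#' @return A list: `strata` (data frame `n_receptors`, `n`, `mean_pct`),
#'   `rho`, `p`. When only a single stratum is present the correlation is
#'   undefined and `rho`/`p` are `NA` with a warning.
#' @export
recovery_trend <- function(records, count_var = "n_receptors",
                           value_var = "pct_recovery") {
  for (v in c(count_var, value_var)) {
    if (!v %in% names(records)) stop("unknown variable: ", v)
  }
  k <- records[[count_var]]
  y <- records[[value_var]]
  ok <- !is.na(k) & !is.na(y)
  if (!any(ok)) stop("no non-missing recovery observations")
  k <- k[ok]; y <- y[ok]
  strata <- data.frame(
    n_receptors = sort(unique(k)),
    n = as.integer(table(k)),
    mean_pct = as.numeric(tapply(y, k, mean))
  )
  if (length(unique(k)) < 2L) {
    warning("single receptor-count stratum: correlation undefined")
    return(list(strata = strata, rho = NA_real_, p = NA_real_))
  }
  ct <- suppressWarnings(
    stats::cor.test(k, y, method = "spearman", exact = FALSE))
  list(strata = strata, rho = unname(ct$estimate), p = unname(ct$p.value))
}

#' Logistic regression of hearing recovery on vestibular predictors
#'
#' Fits `glm(outcome ~ predictors, family = binomial)` where the outcome is
#' hearing recovery dichotomized as any recovery (complete or partial) vs
#' none (default) or complete vs not. Constant predictors are dropped with
#' a warning; complete separation (divergent coefficients) is flagged and
#' coefficients are withheld.
#'
#' @param records A scored cohort data frame with a `recovery` column.
#' @param predictors Character vector of predictor column names.
#' @param outcome `"any_recovery"` (default) or `"complete"`.
#' @param joint If `TRUE` (default) one joint model; if `FALSE`, one
#'   single-predictor model per predictor.
#' @return For a joint fit, a list of class `recovery_regression`:
#'   `coefficients` (data frame with estimates, SE, OR, 95% CI, p),
#'   `converged`, `separation`, `dropped`, `n`. For `joint = FALSE`, a
#'   named list of such objects.
#' @export
fit_recovery_regression <- function(records,
                                    predictors = c("sacc_imp", "utr_imp",
                                                   "hsc_imp", "asc_imp",
                                                   "psc_imp"),
                                    outcome = c("any_recovery", "complete"),
                                    joint = TRUE) {
  outcome <- match.arg(outcome)
  if (!"recovery" %in% names(records)) stop("records must have a recovery column")
  y <- if (outcome == "any_recovery") {
    records$recovery %in% c("complete", "partial")
  } else {
    records$recovery == "complete"
  }
  y[is.na(records$recovery)] <- NA
  miss <- setdiff(predictors, names(records))
  if (length(miss)) stop("unknown predictors: ", paste(miss, collapse = ", "))

  if (!joint) {
    fits <- lapply(predictors, function(p) {
      fit_recovery_regression(records, predictors = p, outcome = outcome,
                              joint = TRUE)
    })
    names(fits) <- predictors
    return(fits)
  }

  dat <- records[predictors]
  dat <- as.data.frame(lapply(dat, function(col) {
    if (is.logical(col)) as.numeric(col) else as.numeric(col)
  }))
  dropped <- names(dat)[vapply(dat, function(col) {
    length(unique(col[!is.na(col)])) < 2L
  }, logical(1))]
  if (length(dropped)) {
    warning("dropping constant predictor(s): ",
            paste(dropped, collapse = ", "))
    dat <- dat[setdiff(names(dat), dropped)]
  }
  if (!ncol(dat)) stop("no non-constant predictors remain")
  dat$.y <- as.numeric(y)
  dat <- dat[stats::complete.cases(dat), , drop = FALSE]

  fit <- suppressWarnings(
    stats::glm(.y ~ ., data = dat, family = stats::binomial()))
  coefs <- summary(fit)$coefficients
  separation <- !fit$converged || any(abs(coefs[, "Estimate"]) > 15) ||
    any(coefs[, "Std. Error"] > 100)
  if (separation) {
    warning("possible complete separation: coefficients withheld; ",
            "consider penalized regression or pooling sparse predictors")
    coef_tab <- NULL
  } else {
    ci <- suppressMessages(suppressWarnings(stats::confint.default(fit)))
    coef_tab <- data.frame(
      term = rownames(coefs),
      estimate = coefs[, "Estimate"],
      se = coefs[, "Std. Error"],
      odds_ratio = exp(coefs[, "Estimate"]),
      or_low = exp(ci[, 1]),
      or_high = exp(ci[, 2]),
      p = coefs[, "Pr(>|z|)"],
      row.names = NULL
    )
  }
  structure(list(coefficients = coef_tab, converged = fit$converged,
                 separation = separation, dropped = dropped,
                 outcome = outcome, n = nrow(dat)),
            class = "recovery_regression")
}

#' @export
print.recovery_regression <- function(x, ...) {
  cat(sprintf("<recovery_regression> outcome = %s, n = %d\n", x$outcome, x$n))
  if (x$separation) {
    cat("  separation detected; coefficients withheld\n")
  } else {
    print(transform(x$coefficients,
                    odds_ratio = signif(odds_ratio, 3),
                    or_low = signif(or_low, 3), or_high = signif(or_high, 3),
                    estimate = signif(estimate, 3), se = signif(se, 3),
                    p = signif(p, 3)))
  }
  if (length(x$dropped)) cat("  dropped:", paste(x$dropped, collapse = ", "), "\n")
  invisible(x)
}

#' Assemble the cohort report
#'
#' Runs the study's cohort-level comparisons on a scored cohort: receptor
#' impairment, lesion patterns, hearing-loss degree/configuration, recovery
#' and vascular-pattern tabulations by subgroup; categorical tests on each;
#' Kruskal-Wallis of presenting PTA and percent recovery across subgroups;
#' the receptor-count recovery trend; and the recovery regression.
#'
#' @param scored A scored cohort (see [score_cohort()]).
#' @param group_var Column defining the comparison groups (default the
#'   assigned clinical subgroup).
#' @return A list of class `cohort_report`: `tables`, `tests`, `trend`,
#'   `regression`, `n`.
#' @export
cohort_report <- function(scored, group_var = "subgroup_assigned") {
  row_vars <- c("sacc_imp", "utr_imp", "hsc_imp", "asc_imp", "psc_imp",
                "otolith_pattern", "canal_pattern", "n_receptors",
                "degree", "configuration", "recovery", "vascular_pattern",
                "fazekas")
  row_vars <- intersect(row_vars, names(scored))
  tables <- lapply(row_vars, function(v) tabulate_cohort(scored, v, group_var))
  names(tables) <- row_vars
  tests <- lapply(tables, function(tb) {
    tryCatch(compare_categorical(tb$counts), error = function(e) {
      list(statistic = NA_real_, p = NA_real_,
           method = paste("not_testable:", conditionMessage(e)))
    })
  })
  kw <- list()
  for (v in intersect(c("pta_pre", "pct_recovery", "risk_score"),
                      names(scored))) {
    kw[[v]] <- tryCatch(compare_continuous(scored, v, group_var),
                        error = function(e) NULL)
  }
  trend <- tryCatch(recovery_trend(scored), error = function(e) NULL)
  regression <- tryCatch(
    suppressWarnings(fit_recovery_regression(scored)),
    error = function(e) NULL)
  structure(list(tables = tables, tests = tests, kruskal = kw,
                 trend = trend, regression = regression, n = nrow(scored)),
            class = "cohort_report")
}

#' @export
print.cohort_report <- function(x, ...) {
  cat(sprintf("<cohort_report> n = %d patients\n", x$n))
  for (nm in names(x$tests)) {
    t <- x$tests[[nm]]
    cat(sprintf("  %-16s %s p = %s\n", nm, t$method,
                if (is.na(t$p)) "NA" else format.pval(t$p, digits = 3)))
  }
  if (!is.null(x$trend)) {
    cat(sprintf("  recovery trend: rho = %.3f, p = %s\n", x$trend$rho,
                format.pval(x$trend$p, digits = 3)))
  }
  invisible(x)
}
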