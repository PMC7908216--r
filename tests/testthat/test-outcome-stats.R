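test_that("the reconstructed responder-by-high-RSPI table yields the printed diagnostics", {
  tab <- two_by_two(tp = 18, fp = 1, fn = 18, tn = 12)
  d <- diagnostics(tab)
  expect_equal(d$sensitivity, 0.50)
  expect_equal(d$specificity, 12 / 13)
  expect_equal(d$ppv, 18 / 19)
  expect_equal(d$npv, 0.40)
  expect_equal(d$odds_ratio, 12.0)
  expect_equal(d$prevalence_test_pos, 19 / 49)
  expect_true(d$or_ci[1] < 12 && 12 < d$or_ci[2])
  # Wald CI on the log odds ratio
  se <- sqrt(1 / 18 + 1 / 1 + 1 / 18 + 1 / 12)
  expect_equal(d$or_ci, exp(log(12) + c(-1, 1) * qnorm(0.975) * se))
})

test_that("degenerate tables are handled: separation, zero margins, Haldane", {
  perfect <- diagnostics(two_by_two(10, 0, 0, 10))
  expect_equal(perfect$sensitivity, 1)
  expect_equal(perfect$specificity, 1)
  expect_true(is.infinite(perfect$odds_ratio) || is.nan(perfect$odds_ratio))
  expect_true(all(is.na(perfect$or_ci)))

  hald <- diagnostics(two_by_two(10, 0, 0, 10), haldane = TRUE)
  expect_true(is.finite(hald$odds_ratio))
  expect_true(all(is.finite(hald$or_ci)))

  null_tab <- diagnostics(two_by_two(5, 5, 5, 5))
  expect_equal(null_tab$sensitivity, 0.5)
  expect_equal(null_tab$odds_ratio, 1.0)

  no_neg <- diagnostics(two_by_two(5, 0, 5, 0))
  expect_true(is.na(no_neg$specificity))
  expect_equal(no_neg$sensitivity, 0.5)

  expect_error(two_by_two(-1, 0, 0, 0), "non-negative")
})

test_that("ROC handles no-discrimination and perfect separation with the tie rule", {
  flat <- roc_curve(rep(5, 20), rep(c(TRUE, FALSE), 10))
  expect_equal(flat$auc, 0.5)

  sep <- roc_curve(c(rep(10, 8), rep(2, 7)),
                   c(rep(TRUE, 8), rep(FALSE, 7)))
  expect_equal(sep$auc, 1.0)
  # every cutoff in 3..10 attains J = 1; ties resolve to the largest
  expect_equal(sep$optimal_cutoff, 10)

  expect_error(roc_curve(1:5, rep(TRUE, 5)), "both outcome classes")
})

test_that("trapezoid AUC equals the all-pairs concordance oracle", {
  set.seed(71)
  for (i in 1:300) {
    n <- sample(10:40, 1)
    labels <- c(TRUE, FALSE, runif(n - 2) < 0.5)
    scores <- sample(0:12, n, replace = TRUE)
    r <- roc_curve(scores, labels)
    expect_equal(r$auc, oracle_auc(scores, labels), tolerance = 1e-12)
  }
})

test_that("logistic regression on a binary predictor equals the cross-product OR", {
  set.seed(72)
  for (i in 1:25) {
    cells <- sample(3:30, 4)
    x <- rep(c(1, 1, 0, 0), cells)
    y <- rep(c(TRUE, FALSE, TRUE, FALSE), cells)
    fit <- logistic_univariate(x, y)
    expect_true(fit$estimable)
    or_2x2 <- (cells[1] * cells[4]) / (cells[2] * cells[3])
    expect_equal(fit$or, or_2x2, tolerance = 1e-6)
  }

  # the reconstructed cohort: high-RSPI indicator vs response
  x <- rep(c(1, 1, 0, 0), c(18, 1, 18, 12))
  y <- rep(c(TRUE, FALSE, TRUE, FALSE), c(18, 1, 18, 12))
  fit <- logistic_univariate(x, y)
  expect_equal(fit$or, 12.0, tolerance = 1e-6)
  expect_lt(fit$p_wald, 0.05)
})

test_that("degenerate predictors are flagged, not estimated", {
  y <- rep(c(TRUE, FALSE), 10)
  expect_false(logistic_univariate(rep(0, 20), y)$estimable)
  # quasi-separation: a zero cell
  x <- c(rep(1, 10), rep(0, 10))
  ysep <- c(rep(TRUE, 10), rep(c(TRUE, FALSE), 5))
  fit <- logistic_univariate(x, ysep)
  expect_true(fit$separation)
  expect_false(fit$estimable)
  expect_error(logistic_univariate(1:10, rep(TRUE, 10)), "both classes")
})

test_that("logistic slope recovery stays within 3 SE at n = 500", {
  set.seed(73)
  hits <- 0
  reps <- 200
  for (i in 1:reps) {
    x <- rnorm(500)
    y <- runif(500) < plogis(-0.5 + 1.0 * x)
    fit <- logistic_univariate(x, y)
    if (fit$estimable && abs(fit$beta - 1.0) <= 3 * fit$se) hits <- hits + 1
  }
  expect_gte(hits / reps, 0.95)
})

test_that("the nonparametric test wrappers reproduce small-sample exact results", {
  mw <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(mw$u, 0)
  expect_equal(mw$p_value, 0.1)

  w <- wilcoxon_paired(c(3, 5, 7, 9), c(3, 5, 7, 9))
  expect_equal(w$p_value, 1)

  mc <- mcnemar_paired(c(TRUE, TRUE, FALSE), c(TRUE, TRUE, FALSE))
  expect_equal(mc$discordant, 0L)
  expect_equal(mc$p_value, 1)

  sp <- spearman_rho(1:10, (1:10)^3)
  expect_equal(sp$rho, 1)

  cs <- chisq_unpaired(matrix(c(20, 5, 5, 20), 2))
  expect_lt(cs$p_value, 0.01)
})

test_that("group_tests compares every numeric index between responder groups", {
  set.seed(74)
  df <- data.frame(
    responder = rep(c(TRUE, FALSE), c(20, 15)),
    rspi = c(rnorm(20, 6, 2), rnorm(15, 4, 2)),
    yu = rnorm(35, 40, 10)
  )
  res <- group_tests(df)
  expect_setequal(res$variable, c("rspi", "yu"))
  expect_true(all(res$p_value >= 0 & res$p_value <= 1))
  expect_error(group_tests(data.frame(responder = rep(TRUE, 5), x = 1:5)),
               "both groups")
})
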