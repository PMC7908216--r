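#' 2x2 diagnostic table
#'
#' Cross-classification of a binary test (e.g. RSPI at or above the cutoff)
#' against the condition (CRT responder).
#'
#' @param tp,fp,fn,tn Non-negative integer counts: test-positive responders,
#'   test-positive non-responders, test-negative responders, test-negative
#'   non-responders.
#' @return An object of class `two_by_two`.
#' @export
two_by_two <- function(tp, fp, fn, tn) {
  counts <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (anyNA(counts) || any(counts < 0) || any(counts != round(counts))) {
    stop("cell counts must be non-negative integers", call. = FALSE)
  }
  structure(as.list(as.integer(counts)), names = names(counts),
            class = "two_by_two")
}

#' Build a 2x2 table from per-patient indicators
#'
#' @param test Logical vector: test positive (e.g. high RSPI).
#' @param condition Logical vector: condition present (responder).
#' @return A [two_by_two()] table.
#' @export
two_by_two_from_labels <- function(test, condition) {
  stopifnot(length(test) == length(condition))
  keep <- !(is.na(test) | is.na(condition))
  test <- test[keep]; condition <- condition[keep]
  two_by_two(tp = sum(test & condition), fp = sum(test & !condition),
             fn = sum(!test & condition), tn = sum(!test & !condition))
}

#' @export
print.two_by_two <- function(x, ...) {
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2, 2,
              dimnames = list(test = c("positive", "negative"),
                              condition = c("responder", "non-responder")))
  print(m)
  invisible(x)
}

#' Diagnostic summary of a 2x2 table
#'
#' Sensitivity, specificity, predictive values and the diagnostic odds ratio
#' with a 95% Wald confidence interval on the log odds ratio. A zero margin
#' leaves the affected proportion `NA`; a zero cell gives an infinite (or
#' zero) odds ratio with an undefined CI unless the Haldane-Anscombe +0.5
#' correction is enabled.
#'
#' @param table A [two_by_two()].
#' @param conf_level Confidence level for the Wald interval. Default 0.95.
#' @param haldane Add 0.5 to every cell for the odds ratio and its CI when
#'   any cell is zero. Default `FALSE`.
#' @return An object of class `diagnostic_summary` with fields `sensitivity`,
#'   `specificity`, `ppv`, `npv`, `odds_ratio`, `or_ci`, `prevalence_test_pos`
#'   and the input counts.
#' @export
diagnostics <- function(table, conf_level = 0.95, haldane = FALSE) {
  stopifnot(inherits(table, "two_by_two"))
  tp <- table$tp; fp <- table$fp; fn <- table$fn; tn <- table$tn
  prop <- function(num, den) if (den == 0) NA_real_ else num / den
  z <- stats::qnorm(1 - (1 - conf_level) / 2)

  cells <- c(tp, fp, fn, tn)
  if (any(cells == 0) && haldane) cells <- cells + 0.5
  or <- (cells[1] * cells[4]) / (cells[2] * cells[3])
  or_ci <- c(NA_real_, NA_real_)
  if (all(cells > 0) && is.finite(or)) {
    se <- sqrt(sum(1 / cells))
    or_ci <- exp(log(or) + c(-1, 1) * z * se)
  }

  structure(
    list(sensitivity = prop(tp, tp + fn),
         specificity = prop(tn, tn + fp),
         ppv = prop(tp, tp + fp),
         npv = prop(tn, tn + fn),
         odds_ratio = or,
         or_ci = or_ci,
         conf_level = conf_level,
         haldane = haldane && any(c(tp, fp, fn, tn) == 0),
         prevalence_test_pos = prop(tp + fp, tp + fp + fn + tn),
         counts = c(tp = tp, fp = fp, fn = fn, tn = tn)),
    class = "diagnostic_summary"
  )
}

#' @export
print.diagnostic_summary <- function(x, digits = 3, ...) {
  pc <- function(p) if (is.na(p)) "NA" else sprintf("%.1f%%", 100 * p)
  cat(sprintf("sensitivity %s, specificity %s, PPV %s, NPV %s\n",
              pc(x$sensitivity), pc(x$specificity), pc(x$ppv), pc(x$npv)))
  cat(sprintf("odds ratio %s (%.0f%% CI %s-%s)%s\n",
              format(x$odds_ratio, digits = digits), 100 * x$conf_level,
              format(x$or_ci[1], digits = digits),
              format(x$or_ci[2], digits = digits),
              if (x$haldane) " [Haldane-corrected]" else ""))
  invisible(x)
}

#' Empirical ROC curve with Youden-optimal cutoff
#'
#' Builds the empirical ROC of a score against a binary outcome over integer
#' thresholds (predict positive at score >= threshold), computes the area
#' under the curve by the trapezoid rule (equal to the probability that a
#' random responder outscores a random non-responder, ties counting one half)
#' and picks the cutoff maximizing Youden's J = sensitivity + specificity - 1,
#' breaking ties toward the larger (more specific) cutoff.
#'
#' @param scores Numeric scores (higher = more likely positive); RSPI totals
#'   use the integer thresholds 0..13.
#' @param labels Logical outcome (responder).
#' @param thresholds Optional threshold grid; defaults to `0:13` for integer
#'   scores within 0..12, otherwise all distinct score values plus sentinels.
#' @return An object of class `roc_result`: `curve` (data.frame with
#'   threshold, sensitivity, specificity, fpr), `auc`, `optimal_cutoff`,
#'   `youden`.
#' @export
roc_curve <- function(scores, labels, thresholds = NULL) {
  stopifnot(length(scores) == length(labels))
  labels <- as.logical(labels)
  keep <- !(is.na(scores) | is.na(labels))
  scores <- scores[keep]; labels <- labels[keep]
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0L || n0 == 0L) {
    stop("both outcome classes must be present for ROC analysis", call. = FALSE)
  }
  if (is.null(thresholds)) {
    thresholds <- if (all(scores == round(scores)) && all(scores >= 0) &&
                      all(scores <= 12)) {
      0:13
    } else {
      c(min(scores), sort(unique(scores)), max(scores) + 1)
    }
  }
  thresholds <- sort(unique(thresholds))
  sens <- vapply(thresholds, function(th) sum(scores >= th & labels) / n1,
                 numeric(1))
  spec <- vapply(thresholds, function(th) sum(scores < th & !labels) / n0,
                 numeric(1))
  curve <- data.frame(threshold = thresholds, sensitivity = sens,
                      specificity = spec, fpr = 1 - spec)
  ## trapezoid over the curve ordered by increasing FPR
  ord <- order(curve$fpr, curve$sensitivity)
  x <- c(0, curve$fpr[ord], 1)
  y <- c(0, curve$sensitivity[ord], 1)
  auc <- sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
  j <- sens + spec - 1
  best <- which(j == max(j))
  optimal <- thresholds[best[length(best)]]   # ties -> larger cutoff
  structure(list(curve = curve, auc = auc, optimal_cutoff = optimal,
                 youden = max(j), n_pos = n1, n_neg = n0),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("ROC: AUC %.3f (%d positives, %d negatives); optimal cutoff >= %g (Youden J %.3f)\n",
              x$auc, x$n_pos, x$n_neg, x$optimal_cutoff, x$youden))
  invisible(x)
}

#' Univariate logistic regression of a binary outcome
#'
#' Maximum-likelihood fit of `logit P(y = 1) = alpha + beta x` (iteratively
#' reweighted least squares via [stats::glm()], convergence tolerance 1e-10)
#' with the Wald odds ratio, confidence interval and p-value. For a binary
#' predictor the fitted odds ratio equals the 2x2 cross-product ratio. With
#' complete or quasi-complete separation (a zero cell for binary predictors,
#' or fitted probabilities degenerating to 0/1) no estimate is returned and
#' the `separation` flag is set.
#'
#' @param x Numeric or logical predictor.
#' @param y Logical (or 0/1) outcome; both classes must be present.
#' @param conf_level Confidence level. Default 0.95.
#' @return List with `estimable`, `separation`, `beta`, `se`, `or`, `or_ci`,
#'   `p_wald`, `n`.
#' @export
logistic_univariate <- function(x, y, conf_level = 0.95) {
  y <- as.logical(y)
  keep <- !(is.na(x) | is.na(y))
  x <- as.numeric(x[keep]); y <- y[keep]
  out <- list(estimable = FALSE, separation = FALSE, beta = NA_real_,
              se = NA_real_, or = NA_real_, or_ci = c(NA_real_, NA_real_),
              p_wald = NA_real_, n = length(y))
  if (length(unique(y)) < 2L) {
    stop("outcome must include both classes", call. = FALSE)
  }
  if (length(unique(x)) < 2L) {
    return(out)   # constant predictor: not estimable
  }
  if (all(x %in% c(0, 1))) {
    cells <- c(sum(x == 1 & y), sum(x == 1 & !y), sum(x == 0 & y), sum(x == 0 & !y))
    if (any(cells == 0)) {
      out$separation <- TRUE
      return(out)
    }
  }
  sep <- FALSE
  fit <- withCallingHandlers(
    stats::glm(y ~ x, family = stats::binomial(),
               control = stats::glm.control(epsilon = 1e-10, maxit = 100)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        sep <<- TRUE
      }
      invokeRestart("muffleWarning")
    }
  )
  beta <- unname(stats::coef(fit)["x"])
  se <- unname(sqrt(diag(stats::vcov(fit)))["x"])
  if (sep || !fit$converged || se > 1e3) {
    out$separation <- TRUE
    return(out)
  }
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  out$estimable <- TRUE
  out$beta <- beta
  out$se <- se
  out$or <- exp(beta)
  out$or_ci <- exp(beta + c(-1, 1) * z * se)
  out$p_wald <- 2 * stats::pnorm(-abs(beta / se))
  out
}

#' Nonparametric and categorical group tests
#'
#' Wrappers for the tests used at cohort level: Mann-Whitney U for unpaired
#' continuous comparisons (exact p by enumeration when both groups have at
#' most 10 untied observations, normal approximation with continuity
#' correction otherwise), Wilcoxon signed-rank for paired pre/post changes,
#' chi-squared for unpaired categorical tables, McNemar for paired binary
#' changes and Spearman rank correlation.
#'
#' @param x,y Numeric vectors (the two groups for `mann_whitney`; paired
#'   samples for `wilcoxon_paired`; paired variables for `spearman_rho`).
#' @return List with the statistic, `p_value` and method label.
#' @export
mann_whitney <- function(x, y) {
  if (length(x) == 0L || length(y) == 0L) stop("empty group", call. = FALSE)
  exact <- length(x) <= 10L && length(y) <= 10L && !any(duplicated(c(x, y)))
  ht <- stats::wilcox.test(x, y, exact = exact, correct = TRUE)
  list(u = unname(ht$statistic), p_value = ht$p.value,
       method = if (exact) "Mann-Whitney U (exact)" else
         "Mann-Whitney U (normal approximation)")
}

#' @rdname mann_whitney
#' @export
wilcoxon_paired <- function(x, y) {
  if (length(x) != length(y) || length(x) == 0L) {
    stop("paired samples must be equal-length and non-empty", call. = FALSE)
  }
  d <- x - y
  if (all(d == 0)) {
    return(list(v = 0, p_value = 1, method = "Wilcoxon signed-rank (no change)"))
  }
  nz <- sum(d != 0)
  exact <- nz <= 10L && !any(duplicated(abs(d[d != 0])))
  ht <- suppressWarnings(stats::wilcox.test(x, y, paired = TRUE, exact = exact,
                                            correct = TRUE))
  list(v = unname(ht$statistic), p_value = ht$p.value,
       method = "Wilcoxon signed-rank")
}

#' @param table A 2x2 (or r x c) contingency matrix.
#' @param correct Continuity correction for the 2x2 chi-squared. Default
#'   `FALSE` (plain Pearson statistic).
#' @rdname mann_whitney
#' @export
chisq_unpaired <- function(table, correct = FALSE) {
  ht <- suppressWarnings(stats::chisq.test(table, correct = correct))
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p_value = ht$p.value, method = "Pearson chi-squared")
}

#' @param before,after Paired logical/0-1 vectors for the McNemar test (e.g.
#'   classical pattern before and after CRT).
#' @rdname mann_whitney
#' @export
mcnemar_paired <- function(before, after) {
  before <- as.logical(before); after <- as.logical(after)
  stopifnot(length(before) == length(after))
  b <- sum(before & !after)
  c_ <- sum(!before & after)
  if (b + c_ == 0L) {
    return(list(discordant = 0L, p_value = 1,
                method = "McNemar (no discordant pairs)"))
  }
  tab <- table(factor(before, c(FALSE, TRUE)), factor(after, c(FALSE, TRUE)))
  ht <- stats::mcnemar.test(tab)
  list(discordant = b + c_, statistic = unname(ht$statistic),
       p_value = ht$p.value, method = "McNemar")
}

#' @rdname mann_whitney
#' @export
spearman_rho <- function(x, y) {
  ht <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
  list(rho = unname(ht$estimate), p_value = ht$p.value,
       method = "Spearman rank correlation")
}

#' Responder-vs-non-responder comparisons across a cohort table
#'
#' Runs Mann-Whitney comparisons of every numeric index column between
#' responders and non-responders in a patient-level data frame.
#'
#' @param data Data frame with one row per patient.
#' @param group Name of the logical grouping column (default `"responder"`).
#' @param vars Character vector of numeric columns to compare; defaults to
#'   all numeric columns except the group.
#' @return Data frame with variable, group medians and the Mann-Whitney p.
#' @export
group_tests <- function(data, group = "responder", vars = NULL) {
  stopifnot(is.data.frame(data), group %in% names(data))
  g <- as.logical(data[[group]])
  if (sum(g, na.rm = TRUE) == 0L || sum(!g, na.rm = TRUE) == 0L) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  if (is.null(vars)) {
    vars <- names(data)[vapply(data, is.numeric, logical(1))]
    vars <- setdiff(vars, group)
  }
  rows <- lapply(vars, function(v) {
    x <- data[[v]][g & !is.na(data[[v]])]
    y <- data[[v]][!g & !is.na(data[[v]])]
    mw <- mann_whitney(x, y)
    data.frame(variable = v, median_group1 = stats::median(x),
               median_group0 = stats::median(y), u = mw$u,
               p_value = mw$p_value, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
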