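# Agreement and diagnostic statistics.
#
# ICC: single-measure intraclass correlation from two-way ANOVA mean squares,
# in the two common forms — two-way random effects / absolute agreement
# (ICC(A,1), the conservative default for inter-method comparisons) and
# two-way mixed / consistency (ICC(C,1)) — with 95% confidence intervals from
# F-distribution bounds (McGraw & Wong). AUC uses the rank (Mann-Whitney)
# formulation with ties counted 1/2 and a DeLong variance CI; correlated AUCs
# are compared with the DeLong test on paired structural components. Rank
# tests and correlations wrap the standard R implementations.

#' Statistical result container
#'
#' @param estimate point estimate.
#' @param ci_low,ci_high confidence bounds (`ci_low <= estimate <= ci_high`).
#' @param statistic test statistic.
#' @param p_value two-sided p-value unless stated otherwise in `method`.
#' @param method label of the procedure.
#' @param n problem size (subjects, pairs, ...).
#' @export
stat_result <- function(estimate, ci_low = NA_real_, ci_high = NA_real_,
                        statistic = NA_real_, p_value = NA_real_,
                        method = "", n = NA_integer_) {
  if (!is.na(p_value) && (p_value < 0 || p_value > 1)) stop("p outside [0,1]")
  if (!is.na(ci_low) && !is.na(ci_high) &&
      (ci_low > estimate + 1e-12 || ci_high < estimate - 1e-12))
    stop("estimate outside its confidence interval")
  structure(list(estimate = estimate, ci_low = ci_low, ci_high = ci_high,
                 statistic = statistic, p_value = p_value, method = method,
                 n = n), class = "stat_result")
}

#' @export
print.stat_result <- function(x, ...) {
  cat(sprintf("%s: estimate %.4f (95%% CI %.4f-%.4f), statistic %.4g, p %.4g, n %d\n",
              x$method, x$estimate, x$ci_low, x$ci_high, x$statistic,
              x$p_value, x$n))
  invisible(x)
}

# Two-way ANOVA mean squares of a subjects x raters matrix.
twoway_ms <- function(x) {
  n <- nrow(x); k <- ncol(x)
  g <- mean(x)
  ri <- rowMeans(x); cj <- colMeans(x)
  msr <- k * sum((ri - g)^2) / (n - 1)
  msc <- n * sum((cj - g)^2) / (k - 1)
  sse <- sum((x - outer(ri, rep(1, k)) - outer(rep(1, n), cj) + g)^2)
  mse <- sse / ((n - 1) * (k - 1))
  list(msr = msr, msc = msc, mse = mse, n = n, k = k)
}

#' Intraclass correlation coefficient (single measures)
#'
#' @param table numeric matrix subjects x raters/methods (>= 2 each, no NA).
#' @param form `two_way_random_absolute` (ICC(A,1)) or
#'   `two_way_mixed_consistency` (ICC(C,1)).
#' @param conf confidence level.
#' @export
icc <- function(table,
                form = c("two_way_random_absolute", "two_way_mixed_consistency"),
                conf = 0.95) {
  form <- match.arg(form)
  x <- as.matrix(table)
  if (nrow(x) < 2L || ncol(x) < 2L) stop("need >= 2 subjects and >= 2 raters")
  if (any(!is.finite(x))) stop("missing or non-finite cells")
  ms <- twoway_ms(x)
  n <- ms$n; k <- ms$k
  alpha <- 1 - conf
  f0 <- ms$msr / ms$mse
  p <- pf(f0, n - 1, (n - 1) * (k - 1), lower.tail = FALSE)

  if (ms$msr <= ms$mse && ms$msr <= 1e-300) {
    # no between-subject variance: degenerate, agreement undefined
    out <- stat_result(0, -1, 1, f0, 1, method = paste0("ICC ", form), n = n)
    out$degenerate <- TRUE
    return(out)
  }

  if (form == "two_way_mixed_consistency") {
    est <- (ms$msr - ms$mse) / (ms$msr + (k - 1) * ms$mse)
    fl <- f0 / qf(1 - alpha / 2, n - 1, (n - 1) * (k - 1))
    fu <- f0 * qf(1 - alpha / 2, (n - 1) * (k - 1), n - 1)
    lo <- (fl - 1) / (fl + k - 1)
    hi <- (fu - 1) / (fu + k - 1)
  } else {
    est <- (ms$msr - ms$mse) /
      (ms$msr + (k - 1) * ms$mse + k * (ms$msc - ms$mse) / n)
    a <- (k * est) / (n * (1 - est))
    b <- 1 + (k * est * (n - 1)) / (n * (1 - est))
    v <- (a * ms$msc + b * ms$mse)^2 /
      ((a * ms$msc)^2 / (k - 1) + (b * ms$mse)^2 / ((n - 1) * (k - 1)))
    fstar <- qf(1 - alpha / 2, n - 1, v)
    lo <- n * (ms$msr - fstar * ms$mse) /
      (fstar * (k * ms$msc + (k * n - k - n) * ms$mse) + n * ms$msr)
    fstar2 <- qf(1 - alpha / 2, v, n - 1)
    hi <- n * (fstar2 * ms$msr - ms$mse) /
      (k * ms$msc + (k * n - k - n) * ms$mse + n * fstar2 * ms$msr)
  }
  stat_result(est, min(lo, est), max(hi, est), f0, p,
              method = paste0("ICC ", form), n = n)
}

# DeLong structural components: V10 (per positive) and V01 (per negative).
delong_components <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  m <- length(pos); n <- length(neg)
  psi <- outer(pos, neg, function(x, y) (x > y) + 0.5 * (x == y))
  list(v10 = rowMeans(psi), v01 = colMeans(psi), auc = mean(psi),
       m = m, n = n)
}

check_binary_labels <- function(labels) {
  labels <- as.integer(as.logical(labels))
  if (length(unique(labels)) < 2L) stop("both classes must be present")
  labels
}

#' Area under the ROC curve
#'
#' Rank (Mann-Whitney) formulation with ties counted 1/2; CI from the DeLong
#' variance (clipped to [0, 1]).
#'
#' @param scores numeric predictor (higher = more likely positive).
#' @param labels binary outcome (1/TRUE = positive).
#' @param conf confidence level.
#' @export
roc_auc <- function(scores, labels, conf = 0.95) {
  labels <- check_binary_labels(labels)
  dc <- delong_components(scores, labels)
  v <- var(dc$v10) / dc$m + var(dc$v01) / dc$n
  se <- sqrt(v)
  z <- if (se > 0) (dc$auc - 0.5) / se else NA_real_
  p <- if (!is.na(z)) 2 * pnorm(-abs(z)) else NA_real_
  q <- qnorm(1 - (1 - conf) / 2)
  stat_result(dc$auc, max(0, dc$auc - q * se), min(1, dc$auc + q * se),
              z, p, method = "AUC (DeLong CI)", n = dc$m + dc$n)
}

#' DeLong test for two correlated AUCs
#'
#' Both score sets are measured on the same subjects; the difference in AUCs
#' is tested with the paired structural-component covariance.
#'
#' @param scores_a,scores_b paired predictors.
#' @param labels binary outcome (1/TRUE = positive).
#' @export
delong_test <- function(scores_a, scores_b, labels) {
  labels <- check_binary_labels(labels)
  if (length(scores_a) != length(scores_b) ||
      length(scores_a) != length(labels)) stop("paired inputs required")
  da <- delong_components(scores_a, labels)
  db <- delong_components(scores_b, labels)
  s10 <- cov(cbind(da$v10, db$v10))
  s01 <- cov(cbind(da$v01, db$v01))
  v <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / da$m +
       (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / da$n
  diff <- da$auc - db$auc
  if (v <= 0) {
    if (abs(diff) < 1e-12)
      return(stat_result(0, 0, 0, 0, 1, method = "DeLong test",
                         n = da$m + da$n))
    stop("degenerate DeLong variance with unequal AUCs")
  }
  se <- sqrt(v)
  z <- diff / se
  p <- 2 * pnorm(-abs(z))
  q <- qnorm(0.975)
  stat_result(diff, diff - q * se, diff + q * se, z, p,
              method = "DeLong test", n = da$m + da$n)
}

#' Mann-Whitney U test
#'
#' Exact p for combined n <= 10 without ties, normal approximation (with tie
#' correction) otherwise.
#'
#' @param x,y samples.
#' @param alternative as in [stats::wilcox.test()].
#' @export
mann_whitney <- function(x, y, alternative = "two.sided") {
  if (length(x) == 0L || length(y) == 0L) stop("empty sample")
  ties <- any(duplicated(c(x, y)))
  exact <- (length(x) + length(y) <= 10L) && !ties
  wt <- suppressWarnings(wilcox.test(x, y, alternative = alternative,
                                     exact = exact, correct = !exact))
  stat_result(unname(wt$statistic), statistic = unname(wt$statistic),
              p_value = wt$p.value,
              method = paste0("Mann-Whitney U (", alternative, ")"),
              n = length(x) + length(y))
}

#' Paired t-test
#' @param x,y paired samples (equal length >= 3).
#' @export
paired_t <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L) stop("paired samples of length >= 3 required")
  if (sd(x - y) == 0) stop("zero variance of differences")
  tt <- t.test(x, y, paired = TRUE)
  stat_result(unname(tt$estimate), tt$conf.int[1], tt$conf.int[2],
              unname(tt$statistic), tt$p.value, method = "paired t-test",
              n = length(x))
}

#' Spearman rank correlation
#' @param x,y samples (equal length >= 3).
#' @export
spearman_cor <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L) stop("samples of length >= 3 required")
  if (sd(x) == 0 || sd(y) == 0) stop("constant input")
  ct <- suppressWarnings(cor.test(x, y, method = "spearman", exact = FALSE))
  rho <- unname(ct$estimate)
  n <- length(x)
  # Fisher-transform approximate CI
  if (n > 3 && abs(rho) < 1) {
    zr <- atanh(rho); se <- 1.03 / sqrt(n - 3)
    lo <- tanh(zr - qnorm(0.975) * se); hi <- tanh(zr + qnorm(0.975) * se)
  } else { lo <- -1; hi <- 1 }
  stat_result(rho, min(lo, rho), max(hi, rho), unname(ct$statistic),
              ct$p.value, method = "Spearman correlation", n = n)
}
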