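# Brute-force oracles, assembled with explicit loops, independent of the
# mean-squares implementation.
oracle_icc <- function(x, form) {
  n <- nrow(x); k <- ncol(x); g <- mean(x)
  ssr <- 0; ssc <- 0; sse <- 0
  ri <- numeric(n); cj <- numeric(k)
  for (i in 1:n) ri[i] <- mean(x[i, ])
  for (j in 1:k) cj[j] <- mean(x[, j])
  for (i in 1:n) ssr <- ssr + k * (ri[i] - g)^2
  for (j in 1:k) ssc <- ssc + n * (cj[j] - g)^2
  for (i in 1:n) for (j in 1:k) sse <- sse + (x[i, j] - ri[i] - cj[j] + g)^2
  msr <- ssr / (n - 1); msc <- ssc / (k - 1); mse <- sse / ((n - 1) * (k - 1))
  if (form == "two_way_mixed_consistency")
    (msr - mse) / (msr + (k - 1) * mse)
  else
    (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
}

oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

oracle_u <- function(x, y) {
  u <- 0
  for (a in x) for (b in y) u <- u + (a > b) + 0.5 * (a == b)
  u
}

test_that("icc matches the brute-force ANOVA oracle and perfect agreement", {
  subj <- rnorm(12, 1e-3, 2e-4)
  tab <- cbind(subj, subj, subj)
  expect_equal(icc(tab, "two_way_random_absolute")$estimate, 1, tolerance = 1e-9)
  set.seed(9)
  for (i in 1:5) {
    x <- matrix(rnorm(15 * 3, 1, 0.5), 15, 3) + rnorm(15)
    for (form in c("two_way_random_absolute", "two_way_mixed_consistency")) {
      r <- icc(x, form)
      expect_lt(abs(r$estimate - oracle_icc(x, form)), 1e-10)
      expect_lte(r$ci_low, r$estimate); expect_gte(r$ci_high, r$estimate)
    }
  }
})

test_that("icc of independent noise columns is near zero (null Monte-Carlo)", {
  set.seed(10)
  x <- matrix(rnorm(200 * 2), 200, 2)
  expect_lt(abs(icc(x, "two_way_random_absolute")$estimate), 0.15)
})

test_that("icc invariances: global shift always, rater shift for consistency", {
  set.seed(11)
  x <- matrix(rnorm(20 * 3, 2, 1), 20, 3) + rnorm(20, sd = 2)
  for (form in c("two_way_random_absolute", "two_way_mixed_consistency"))
    expect_equal(icc(x + 5, form)$estimate, icc(x, form)$estimate,
                 tolerance = 1e-10)
  shifted <- sweep(x, 2, c(0, 1, 2), "+")
  expect_equal(icc(shifted, "two_way_mixed_consistency")$estimate,
               icc(x, "two_way_mixed_consistency")$estimate, tolerance = 1e-10)
  expect_lt(icc(shifted, "two_way_random_absolute")$estimate,
            icc(x, "two_way_random_absolute")$estimate)
})

test_that("auc matches enumeration cases and the pair-counting oracle", {
  expect_identical(roc_auc(c(1, 2, 3, 4), c(0, 0, 1, 1))$estimate, 1)
  expect_identical(roc_auc(c(1, 2, 3, 4), c(0, 1, 0, 1))$estimate, 0.75)
  expect_identical(roc_auc(rep(2, 8), rep(0:1, 4))$estimate, 0.5)
  set.seed(12)
  for (i in 1:5) {
    s <- round(rnorm(30), 1)  # ties likely
    l <- rbinom(30, 1, 0.5)
    if (length(unique(l)) < 2) next
    expect_lt(abs(roc_auc(s, l)$estimate - oracle_auc(s, l)), 1e-12)
  }
  s <- rnorm(40); l <- rep(0:1, 20)
  expect_equal(roc_auc(s, l)$estimate + roc_auc(-s, l)$estimate, 1,
               tolerance = 1e-12)
  expect_error(roc_auc(1:5, rep(1, 5)), "classes")
})

test_that("delong test: identical scores, antisymmetry, pROC agreement", {
  set.seed(13)
  l <- rep(0:1, each = 20)
  a <- rnorm(40) + l
  r <- delong_test(a, a, l)
  expect_identical(r$statistic, 0)
  expect_identical(r$p_value, 1)

  b <- rnorm(40) + 0.8 * l
  r1 <- delong_test(a, b, l)
  r2 <- delong_test(b, a, l)
  expect_equal(r1$statistic, -r2$statistic, tolerance = 1e-12)
  expect_equal(r1$p_value, r2$p_value, tolerance = 1e-12)

  pr <- pROC::roc.test(pROC::roc(l, a, quiet = TRUE),
                       pROC::roc(l, b, quiet = TRUE), method = "delong",
                       paired = TRUE)
  expect_equal(abs(r1$statistic), abs(unname(pr$statistic)), tolerance = 1e-9)
  expect_equal(r1$p_value, pr$p.value, tolerance = 1e-9)
})

test_that("delong p agrees with a method-permutation oracle at n = 40", {
  set.seed(14)
  l <- rep(0:1, each = 20)
  base <- rnorm(40) + 1.2 * l
  a <- base + rnorm(40, sd = 0.6)
  b <- base + rnorm(40, sd = 0.6)
  obs <- roc_auc(a, l)$estimate - roc_auc(b, l)$estimate
  nperm <- 10000L
  swaps <- matrix(runif(nperm * 40) < 0.5, nperm, 40)
  perm <- vapply(seq_len(nperm), function(i) {
    ai <- ifelse(swaps[i, ], b, a)
    bi <- ifelse(swaps[i, ], a, b)
    roc_auc(ai, l)$estimate - roc_auc(bi, l)$estimate
  }, numeric(1))
  p_perm <- mean(abs(perm) >= abs(obs) - 1e-12)
  p_delong <- delong_test(a, b, l)$p_value
  expect_lt(abs(p_delong - p_perm), 0.05)
})

test_that("delong null p-values are uniform (KS over 500 simulations)", {
  set.seed(15)
  l <- rep(0:1, each = 20)
  ps <- vapply(1:500, function(i)
    delong_test(rnorm(40), rnorm(40), l)$p_value, numeric(1))
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("mann-whitney: exact enumeration case, null case, U oracle", {
  r <- mann_whitney(c(1, 2, 3), c(4, 5, 6), alternative = "less")
  expect_identical(r$statistic, 0)
  expect_equal(r$p_value, 0.05, tolerance = 1e-12)   # 1 / choose(6, 3) = 1/20
  x <- c(1.2, 3.4, 2.2, 5.1)
  expect_gt(mann_whitney(x, x)$p_value, 0.9)
  set.seed(16)
  for (i in 1:5) {
    a <- rnorm(12); b <- rnorm(15, 0.5)
    expect_equal(mann_whitney(a, b)$statistic, oracle_u(a, b),
                 tolerance = 1e-12)
  }
  expect_error(mann_whitney(numeric(0), 1:3), "empty")
})

test_that("paired t and spearman behave on canonical cases", {
  x <- c(5, 3, 6, 2); y <- x - c(1, -1, 1, -1)
  r <- paired_t(x, y)
  expect_equal(r$statistic, 0, tolerance = 1e-12)
  expect_equal(r$p_value, 1, tolerance = 1e-12)
  expect_error(paired_t(1:5, 1:5 + 2), "zero variance")

  up <- c(1, 2, 5, 9); mono <- c(0.1, 0.4, 0.9, 3.2)
  expect_identical(spearman_cor(up, mono)$estimate, 1)
  expect_identical(spearman_cor(up, rev(mono))$estimate, -1)
  expect_error(spearman_cor(rep(1, 5), 1:5), "constant")
})
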