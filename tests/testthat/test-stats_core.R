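test_that("Mann-Whitney U, p and delta match hand-derived cases", {
  mw <- mann_whitney_one_sided(c(1, 2, 3), c(4, 5, 6))
  expect_equal(mw$U, 0)
  expect_equal(mw$p, 1 / 20)          # enumeration of all 20 arrangements
  expect_equal(mw$method, "exact")
  expect_equal(mw$delta, 1)

  expect_equal(mann_whitney_one_sided(1, 0)$p, 1)  # worst ordering

  x <- c(2, 5, 9, 9, 1)
  mw <- mann_whitney_one_sided(x, x)   # identical multisets
  expect_equal(mw$U, length(x)^2 / 2)
  expect_equal(mw$delta, 0)

  expect_error(mann_whitney_one_sided(numeric(0), 1), "empty")
})

test_that("exact p equals full enumeration on random tie-free samples", {
  set.seed(42)
  for (i in 1:20) {
    v <- sample(seq(1, 200), 9)
    ref <- v[1:4]; comp <- v[5:9]
    expect_equal(mann_whitney_one_sided(ref, comp)$p, bf_mw_p_enum(ref, comp))
  }
})

test_that("exact and tie-corrected normal p agree within 0.01 at n = 15", {
  set.seed(7)
  for (i in 1:25) {
    ref <- rnorm(15); comp <- rnorm(15, mean = runif(1, -1, 1))
    mw <- mann_whitney_one_sided(ref, comp)
    expect_equal(mw$method, "exact")
    # normal approximation computed directly in the test
    u <- bf_u(ref, comp); mu <- 225 / 2
    sigma <- sqrt(15 * 15 / 12 * 31)
    p_norm <- pnorm((u - mu + 0.5) / sigma)
    expect_lt(abs(mw$p - p_norm), 0.01)
  }
})

test_that("one-sided MW type-I error is at most nominal under the null", {
  set.seed(123)
  rej <- replicate(2000, {
    mann_whitney_one_sided(rnorm(10), rnorm(10))$p <= 0.05
  })
  # binomial 3-sigma allowance around 0.05
  expect_lte(mean(rej), 0.05 + 3 * sqrt(0.05 * 0.95 / 2000))
})

test_that("Cliff's delta matches brute force and its boundary cases", {
  expect_equal(cliffs_delta(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(cliffs_delta(c(1, 2), c(5, 6)), 1)
  expect_equal(cliffs_delta(c(1, 3, 5), c(2, 4, 6)), 1 / 3)  # 6 wins, 3 losses
  set.seed(9)
  for (i in 1:30) {
    ref <- sample(0:20, sample(2:12, 1), replace = TRUE)
    comp <- sample(0:20, sample(2:12, 1), replace = TRUE)
    expect_equal(cliffs_delta(ref, comp), bf_delta(ref, comp), tolerance = 1e-12)
  }
})

test_that("BH q-values reproduce the hand-applied step-up procedure", {
  expect_equal(bh_adjust(c(0.005, 0.01, 0.03, 0.04)),
               c(0.02, 0.02, 0.04, 0.04))
  expect_equal(bh_adjust(0.37), 0.37)
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "input error")
})

test_that("BH is applied within families and is order invariant", {
  p <- c(0.005, 0.01, 0.03, 0.04, 0.001, 0.9)
  fam <- c("a", "a", "a", "a", "b", "b")
  q <- bh_adjust(p, fam)
  expect_equal(q[1:4], c(0.02, 0.02, 0.04, 0.04))
  expect_equal(q[5:6], p.adjust(p[5:6], "BH"))
  set.seed(5)
  for (i in 1:50) {
    pv <- runif(sample(2:20, 1))
    fm <- sample(c("x", "y"), length(pv), replace = TRUE)
    q1 <- bh_adjust(pv, fm)
    perm <- sample(length(pv))
    q2 <- bh_adjust(pv[perm], fm[perm])
    expect_equal(q2, q1[perm])
    expect_true(all(q1 >= pv))
  }
})

test_that("empirical ROC matches the pairwise statistic and pROC", {
  expect_equal(empirical_roc(c(5, 6, 1, 2), c(TRUE, TRUE, FALSE, FALSE))$auc, 1)
  expect_equal(empirical_roc(rep(3, 6), rep(c(TRUE, FALSE), 3))$auc, 0.5)
  expect_equal(
    empirical_roc(c(3, 1, 2, 0),
                  c("positive", "positive", "negative", "negative"))$auc, 0.75)
  expect_error(empirical_roc(1:3, c(TRUE, TRUE, TRUE)), "undefined AUC")

  set.seed(31)
  for (i in 1:20) {
    n1 <- sample(3:15, 1); n2 <- sample(3:15, 1)
    pos <- sample(0:10, n1, replace = TRUE)
    neg <- sample(0:10, n2, replace = TRUE)
    r <- empirical_roc(c(pos, neg), rep(c(TRUE, FALSE), c(n1, n2)))
    expect_equal(r$auc, bf_auc(pos, neg), tolerance = 1e-12)
    # trapezoidal integral of the step curve equals the pair statistic
    trap <- sum(diff(r$fpr) * (utils::head(r$tpr, -1) + utils::tail(r$tpr, -1)) / 2)
    expect_equal(trap, r$auc, tolerance = 1e-12)
  }
  set.seed(32)
  sc <- rnorm(60); lb <- rep(c(TRUE, FALSE), 30)
  expect_equal(
    empirical_roc(sc, lb)$auc,
    as.numeric(suppressMessages(pROC::auc(pROC::roc(lb, sc, quiet = TRUE)))),
    tolerance = 1e-12)
})

test_that("delta / U / AUC identities hold on random samples", {
  set.seed(77)
  for (i in 1:40) {
    ref <- sample(0:30, sample(2:25, 1), replace = TRUE)
    comp <- sample(0:30, sample(2:25, 1), replace = TRUE)
    d <- cliffs_delta(ref, comp)
    u <- mann_whitney_one_sided(ref, comp)$U
    a <- empirical_roc(c(comp, ref),
                       rep(c(TRUE, FALSE), c(length(comp), length(ref))))$auc
    expect_equal(a, (d + 1) / 2, tolerance = 1e-12)
    expect_equal(d, 1 - 2 * u / (length(ref) * length(comp)), tolerance = 1e-12)
  }
})

test_that("stratified bootstrap band is reproducible and brackets the curve", {
  set.seed(1)
  sc <- c(rnorm(40, 1), rnorm(40))
  lb <- rep(c("positive", "negative"), each = 40)
  b1 <- bootstrap_roc_band(sc, lb, n_resamples = 50, seed = 5)
  b2 <- bootstrap_roc_band(sc, lb, n_resamples = 50, seed = 5)
  expect_identical(b1, b2)
  expect_true(all(b1$lower <= b1$upper))
  expect_true(all(b1$lower <= b1$tpr + 1e-9))

  # separable scores: the band collapses onto TPR = 1 for FPR > 0
  sep <- bootstrap_roc_band(c(10:19, 0:9), rep(c("positive", "negative"), each = 10),
                            n_resamples = 30, seed = 2)
  expect_true(all(sep$lower[sep$grid > 0] == 1))
  expect_equal(sep$auc, 1)
})

test_that("Wilson interval matches its closed form and boundaries", {
  expect_equal(wilson_interval(0, 10)[["lower"]], 0)
  expect_equal(wilson_interval(10, 10)[["upper"]], 1)
  ci <- wilson_interval(8, 10)
  expect_equal(unname(ci), c(0.4901625, 0.9433178), tolerance = 1e-6)
  # prop.test without continuity correction uses the Wilson interval
  for (k in c(1, 4, 7)) {
    ref <- prop.test(k, 12, correct = FALSE)$conf.int
    expect_equal(unname(wilson_interval(k, 12)), as.numeric(ref), tolerance = 1e-9)
  }
  expect_error(wilson_interval(1, 0), "input error")
})

test_that("matched operating-point comparison is zero for self-comparison", {
  scores <- c(1:10, 6:15)
  labels <- rep(c("negative", "positive"), each = 10)
  call <- scores >= 8
  for (m in c("specificity", "sensitivity")) {
    cmp <- compare_at_matched_operating_point(
      scores, labels, call, matching = m, n_resamples = 20, seed = 3)
    expect_equal(cmp$delta, 0, tolerance = 1e-12)
  }
  # determinism
  c1 <- compare_at_matched_operating_point(scores, labels, call,
                                           n_resamples = 10, seed = 4)
  c2 <- compare_at_matched_operating_point(scores, labels, call,
                                           n_resamples = 10, seed = 4)
  expect_identical(c1$p, c2$p)
})

test_that("a strictly better AI score beats the human rule at matched specificity", {
  set.seed(2024)
  n <- 200
  truth <- rep(c(1, 0), each = n)
  ai <- truth * 2 + rnorm(2 * n)          # high-AUC score
  noisy <- truth * 0.8 + rnorm(2 * n)     # weaker reader
  call <- noisy > 0.4
  labels <- ifelse(truth == 1, "positive", "negative")
  cmp <- compare_at_matched_operating_point(
    ai, labels, call, matching = "specificity", n_resamples = 400, seed = 8)
  expect_gt(cmp$delta, 0)
  expect_lt(cmp$p, 0.05)
})

test_that("matched-sensitivity extrapolation is flagged", {
  # human rule perfect on positives, AI curve cannot reach TPR 1 before FPR 1
  scores <- c(5, 4, 3, 6, 2, 1)
  labels <- c("positive", "positive", "positive", "negative", "negative", "negative")
  call <- c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE)
  expect_warning(
    cmp <- compare_at_matched_operating_point(
      scores, labels, call, matching = "sensitivity",
      n_resamples = 10, seed = 1),
    "extrapolated|boundary")
  expect_true(cmp$extrapolated || cmp$human$sensitivity == 1)
})

test_that("LOWESS trend reproduces exact fits and is reproducible", {
  x <- seq(1, 60)
  y <- 2 + 0.5 * x
  tr <- lowess_trend(x, y, n_boot = 20, seed = 1)
  interior <- tr$x > 10 & tr$x < 50
  expect_lt(max(abs(tr$fit[interior] - (2 + 0.5 * tr$x[interior]))), 1e-6)

  ye <- exp(0.3 + 0.05 * x)
  tre <- lowess_trend(x, ye, log_y = TRUE, n_boot = 20, seed = 1)
  expect_lt(max(abs(log(tre$fit[interior]) - (0.3 + 0.05 * tre$x[interior]))), 1e-6)

  t1 <- lowess_trend(x, y + rnorm(60), n_boot = 15, seed = 9)
  t2 <- lowess_trend(x, y + rnorm(60), n_boot = 15, seed = 9)
  # same seed governs the bootstrap only; feed identical data
  set.seed(33); yn <- y + rnorm(60)
  t1 <- lowess_trend(x, yn, n_boot = 15, seed = 9)
  t2 <- lowess_trend(x, yn, n_boot = 15, seed = 9)
  expect_identical(t1, t2)
  expect_error(lowess_trend(1:5, 1:5), "at least 10")
  expect_error(lowess_trend(x, c(0, y[-1]), log_y = TRUE), "y > 0")
})
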