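test_that("the Wald ratio is by/bx with first-order standard error", {
  e <- waldRatio(0.1, 0.01, 0.05, 0.01)
  expect_equal(e@beta, 0.5)
  expect_equal(e@se, 0.1)
  e0 <- waldRatio(0.1, 0.01, 0, 0.01)
  expect_equal(e0@beta, 0)
  expect_equal(e0@or_, 1)
  expect_error(waldRatio(0, 0.01, 0.05, 0.01), "undefined")
  set.seed(3)
  for (i in 1:20) {
    bx <- rnorm(1); by <- rnorm(1); sy <- runif(1, 0.01, 1)
    if (bx == 0) next
    e <- waldRatio(bx, 0.01, by, sy)
    expect_equal(e@beta, by / bx)
    expect_equal(e@se, sy / abs(bx))
  }
})

test_that("IVW equals the origin-constrained WLS oracle", {
  # two identical ratios collapse to that ratio
  h <- HarmonizedSet(bx = c(0.1, 0.2), se_x = 0.01, by = c(0.05, 0.10),
                     se_y = c(0.02, 0.05))
  expect_equal(mrIVW(h)@beta, 0.5)

  set.seed(11)
  for (i in 1:100) {
    k <- sample(5:20, 1)
    hh <- make_hs(k, theta = runif(1, -1, 1), se_y = runif(1, 0.01, 0.2))
    o <- oracle_ivw(hh@bx, hh@by, hh@se_y)
    expect_equal(mrIVW(hh)@beta, o$beta, tolerance = 1e-10)
    expect_equal(mrIVW(hh, model = "fixed")@se, o$se_fixed,
                 tolerance = 1e-10)
  }
})

test_that("IVW with one instrument is exactly the Wald ratio", {
  h <- HarmonizedSet(bx = 0.2, se_x = 0.01, by = 0.08, se_y = 0.03)
  expect_equal(mrIVW(h)@beta, waldRatio(0.2, 0.01, 0.08, 0.03)@beta)
  expect_equal(mrIVW(h)@se, waldRatio(0.2, 0.01, 0.08, 0.03)@se)
})

test_that("IVW is invariant to jointly negating any variant", {
  h <- make_hs(10, theta = 0.4, seed = 21)
  h2 <- HarmonizedSet(bx = h@bx * c(-1, rep(1, 9)),
                      se_x = h@se_x,
                      by = h@by * c(-1, rep(1, 9)), se_y = h@se_y)
  expect_equal(mrIVW(h2)@beta, mrIVW(h)@beta, tolerance = 1e-12)
})

test_that("IVW recovers a simulated causal effect", {
  set.seed(101)
  bx <- runif(50, 0.1, 0.5)
  by <- 0.30 * bx + rnorm(50, 0, 0.01)
  h <- HarmonizedSet(bx = bx, se_x = 0.001, by = by, se_y = 0.01)
  o <- oracle_ivw(bx, by, rep(0.01, 50))
  expect_lt(abs(mrIVW(h)@beta - 0.30), 3 * o$se_fixed)
})

test_that("MR-Egger is exact on noiseless linear data", {
  bx <- c(0.1, 0.2, 0.3, 0.4, 0.5)
  by <- 0.02 + 0.5 * bx
  h <- HarmonizedSet(bx = bx, se_x = 0.01, by = by, se_y = 0.05)
  fit <- mrEgger(h)
  expect_equal(fit$estimate@beta, 0.5, tolerance = 1e-12)
  expect_equal(fit$pleiotropy@intercept, 0.02, tolerance = 1e-12)

  # proportional data: zero intercept, p near 1
  h2 <- HarmonizedSet(bx = bx, se_x = 0.01, by = 0.5 * bx, se_y = 0.05)
  fit2 <- mrEgger(h2)
  expect_equal(fit2$pleiotropy@intercept, 0, tolerance = 1e-12)
  expect_gt(fit2$pleiotropy@pval, 0.99)

  expect_error(mrEgger(HarmonizedSet(bx = 1:2 / 10, se_x = 0.01,
                                     by = 1:2 / 10, se_y = 0.05)),
               "at least 3")
  expect_error(mrEgger(HarmonizedSet(bx = c(0.2, -0.2, 0.2),
                                     se_x = 0.01, by = rep(0.1, 3),
                                     se_y = 0.05)),
               "no spread")
})

test_that("MR-Egger matches a generic weighted-regression oracle", {
  set.seed(17)
  for (i in 1:100) {
    k <- sample(5:20, 1)
    h <- make_hs(k, theta = runif(1, -1, 1),
                 intercept = runif(1, -0.05, 0.05),
                 se_y = runif(1, 0.02, 0.2))
    fit <- mrEgger(h)
    co <- oracle_egger(h@bx, h@by, h@se_y)
    expect_equal(fit$pleiotropy@intercept, unname(co[1]),
                 tolerance = 1e-8)
    expect_equal(fit$estimate@beta, unname(co[2]), tolerance = 1e-8)
  }
})

test_that("the weighted median matches the exhaustive oracle", {
  # equal weights, odd count: the middle ratio
  h <- HarmonizedSet(bx = rep(1, 3), se_x = 0.01,
                     by = c(0.2, 0.5, 0.9), se_y = 0.05)
  expect_equal(mrWeightedMedian(h, n_boot = 50)@beta, 0.5)

  # identical ratios: that ratio, bootstrap se near zero
  h2 <- HarmonizedSet(bx = c(1, 2, 4), se_x = 1e-6,
                      by = 0.3 * c(1, 2, 4), se_y = c(1e-6, 2e-6, 4e-6))
  wm2 <- mrWeightedMedian(h2, n_boot = 100)
  expect_equal(wm2@beta, 0.3)
  expect_lt(wm2@se, 1e-4)

  set.seed(29)
  for (i in 1:100) {
    k <- sample(5:20, 1)
    h <- make_hs(k, theta = runif(1, -1, 1), se_y = runif(1, 0.02, 0.2))
    est <- mrWeightedMedian(h, n_boot = 10, seed = i)
    o <- oracle_weighted_median(h@by / h@bx, (h@bx / h@se_y)^2)
    expect_equal(est@beta, o, tolerance = 1e-10)
  }
})

test_that("equal-weight odd-count weighted median is the sample median", {
  set.seed(31)
  for (k in c(3, 5, 9, 15)) {
    r <- rnorm(k)
    h <- HarmonizedSet(bx = rep(1, k), se_x = 0.01, by = r, se_y = 1)
    expect_equal(mrWeightedMedian(h, n_boot = 10)@beta, median(r),
                 tolerance = 1e-10)
  }
})

test_that("mode estimators find the dominant ratio cluster", {
  h <- HarmonizedSet(bx = rep(1, 4), se_x = 0.01,
                     by = c(0.5, 0.5, 0.5, 2.0), se_y = 0.05)
  expect_equal(mrMode(h, weighted = FALSE, n_boot = 50)@beta, 0.5,
               tolerance = 0.02)

  # degenerate: all ratios equal returns the common ratio with a flag
  h2 <- HarmonizedSet(bx = c(1, 2, 4), se_x = 0.01,
                      by = 0.7 * c(1, 2, 4), se_y = 0.05)
  m2 <- mrMode(h2, n_boot = 10)
  expect_equal(m2@beta, 0.7)
  expect_equal(m2@se, 0)
  expect_match(m2@flags, "degenerate")

  # 7-variant case against the dense-grid oracle
  set.seed(37)
  for (i in 1:20) {
    h <- make_hs(7, theta = 0.4, se_y = 0.1)
    r <- h@by / h@bx
    w <- (abs(h@bx) / h@se_y)^2
    est <- mrMode(h, weighted = TRUE, n_boot = 10, seed = i)
    o <- oracle_mode(r, w / sum(w))
    expect_lt(abs(est@beta - o), diff(range(r)) / 400)
  }
})

test_that("the panel dispatches by instrument count", {
  h1 <- HarmonizedSet(bx = 0.2, se_x = 0.01, by = 0.1, se_y = 0.05)
  p1 <- runPanel(h1)
  expect_named(estimates(p1), "Wald")
  expect_true("IVW" %in% names(p1@skipped))

  h2 <- make_hs(2, seed = 2)
  p2 <- runPanel(h2)
  expect_named(estimates(p2), "IVW")

  # a 28-variant set carries all five methods plus diagnostics
  h28 <- make_hs(28, theta = 0.3, seed = 28)
  p28 <- runPanel(h28, n_boot = 50)
  expect_setequal(names(estimates(p28)),
                  c("IVW", "MR-Egger", "weighted_median", "simple_mode",
                    "weighted_mode"))
  expect_s4_class(heterogeneity(p28, "ivw"), "HeterogeneityResult")
  expect_s4_class(pleiotropy(p28), "PleiotropyResult")
  expect_equal(nsnp(p28), 28L)
})

test_that("odds ratios and intervals print in the field's format", {
  beta <- log(1.962)
  se <- (log(2.964) - log(1.298)) / (2 * 1.96)
  h <- HarmonizedSet(bx = 1, se_x = 1e-6, by = beta, se_y = se)
  est <- mrIVW(h)
  expect_equal(est@or_, 1.962, tolerance = 1e-6)
  expect_equal(est@ci_low, 1.298, tolerance = 1e-3)
  expect_equal(est@ci_high, 2.964, tolerance = 1e-3)
  expect_match(formatOR(est), "^1\\.962 \\(1\\.298, 2\\.96[45]\\)$")
})

test_that("estimate tables are tidy, one row per method", {
  p <- runPanel(make_hs(10, seed = 44), n_boot = 20)
  tab <- asTable(p)
  expect_equal(nrow(tab), 5L)
  expect_true(all(c("exposure", "outcome", "method", "nsnp", "beta",
                    "se", "pval", "or", "ci_low", "ci_high")
                  %in% names(tab)))
  expect_true(all(tab$ci_low < tab$or & tab$or < tab$ci_high))
})
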