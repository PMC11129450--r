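# group-by-outcome counts underlying the six crude odds ratios
table4_counts <- list(
  cyp2d6_impm_disc = c(a = 22, b = 60, c = 88, d = 352),
  cyp2d6_impm_switch = c(a = 51, b = 60, c = 223, d = 352),
  cyp2c19_um_disc = c(a = 4, b = 13, c = 24, d = 120),
  cyp2c19_um_switch = c(a = 9, b = 13, c = 67, d = 120),
  cyp2c19_impm_disc = c(a = 7, b = 41, c = 24, d = 120),
  cyp2c19_impm_switch = c(a = 28, b = 41, c = 67, d = 120)
)

test_that("Wald odds ratios reproduce the published worked examples", {
  est <- odds_ratio_wald(22, 60, 88, 352)
  expect_equal(round(est$odds_ratio, 2), 1.47)
  expect_equal(round(est$ci_low, 2), 0.85)
  expect_equal(round(est$ci_high, 2), 2.52)
  expect_equal(round(odds_ratio_wald(4, 13, 24, 120)$odds_ratio, 2), 1.54)
  published <- list(
    cyp2d6_impm_disc = c(1.47, 0.85, 2.52),
    cyp2d6_impm_switch = c(1.34, 0.89, 2.02),
    cyp2c19_um_disc = c(1.54, 0.46, 5.13),
    cyp2c19_um_switch = c(1.24, 0.50, 3.05),
    cyp2c19_impm_disc = c(0.85, 0.34, 2.13),
    cyp2c19_impm_switch = c(1.22, 0.70, 2.15)
  )
  # two endpoints (5.13, 0.70) carry a one-unit rounding discrepancy in the
  # source table; recomputation gives 5.1248 and 0.6946 for any z convention
  for (nm in names(table4_counts)) {
    ct <- table4_counts[[nm]]
    est <- odds_ratio_wald(ct["a"], ct["b"], ct["c"], ct["d"])
    got <- c(est$odds_ratio, est$ci_low, est$ci_high)
    expect_equal(round(got[1], 2), published[[nm]][1], info = nm)
    expect_true(all(abs(got[2:3] - published[[nm]][2:3]) < 0.011), info = nm)
  }
  expect_equal(round(odds_ratio_wald(4, 13, 24, 120)$ci_high, 4), 5.1248)
  expect_equal(round(odds_ratio_wald(28, 41, 67, 120)$ci_low, 4), 0.6946)
})

test_that("odds ratio accepts a 2x2 matrix and is 1 under equal proportions", {
  m <- matrix(c(22, 88, 60, 352), nrow = 2) # cols: event, reference outcome
  expect_equal(odds_ratio_wald(m)$odds_ratio,
               odds_ratio_wald(22, 60, 88, 352)$odds_ratio)
  expect_equal(odds_ratio_wald(10, 30, 20, 60)$odds_ratio, 1.0)
})

test_that("zero cells error unless the Haldane correction is requested", {
  expect_error(odds_ratio_wald(0, 10, 5, 20), "zero cell")
  est <- odds_ratio_wald(0, 10, 5, 20, haldane = TRUE)
  expect_equal(est$odds_ratio, (0.5 * 20.5) / (10.5 * 5.5))
  expect_error(odds_ratio_wald(-1, 10, 5, 20), "non-negative")
})

test_that("IRLS logistic regression matches the closed-form 2x2 estimator", {
  set.seed(42)
  for (i in 1:200) {
    ct <- rpois(4, lambda = sample(c(5, 20, 80), 1)) + 1
    dat <- expand_2x2(ct[1], ct[2], ct[3], ct[4])
    fit <- logistic_fit(dat$y, dat$X, weights = dat$weights)
    closed <- log((ct[1] * ct[4]) / (ct[2] * ct[3]))
    expect_equal(fit$coefficients[["group"]], closed, tolerance = 1e-9)
    expect_equal(fit$se[["group"]], sqrt(sum(1 / ct)), tolerance = 1e-7)
  }
})

test_that("IRLS agrees with glm on expanded published counts", {
  for (nm in names(table4_counts)) {
    ct <- table4_counts[[nm]]
    dat <- expand_2x2(ct["a"], ct["b"], ct["c"], ct["d"])
    fit <- logistic_fit(dat$y, dat$X, weights = dat$weights)
    ref <- glm(dat$y ~ dat$X[, "group"], weights = dat$weights,
               family = binomial())
    expect_equal(unname(fit$coefficients), unname(coef(ref)), tolerance = 1e-7)
  }
  dat <- expand_2x2(51, 60, 223, 352)
  expect_equal(round(logistic_fit(dat$y, dat$X, weights = dat$weights)$
                       odds_ratio[["group"]], 2), 1.34)
})

test_that("degenerate and separable outcomes are refused", {
  X <- cbind(1, c(0, 0, 1, 1))
  expect_error(logistic_fit(c(0, 0, 0, 0), X), "degenerate")
  # quasi-complete separation: group perfectly predicts outcome
  Xs <- cbind(1, rep(c(0, 1), each = 20))
  ys <- rep(c(0, 1), each = 20)
  expect_error(logistic_fit(ys, Xs), "separation|converge")
  expect_error(logistic_fit(c(0, 1, 0, 1), cbind(1, c(1, 1, 1, 1))),
               "rank deficient")
})

test_that("Mann-Whitney U matches the hand examples", {
  res <- mann_whitney_u(c(1, 2), c(3, 4), exact = TRUE)
  expect_equal(res$U, 0)
  expect_equal(res$p_value, 2 / 6)
  # identical multisets: U = n^2 / 2, z = 0
  x <- c(1, 2, 3, 4)
  res2 <- mann_whitney_u(x, x)
  expect_equal(res2$U, length(x)^2 / 2)
  expect_equal(res2$z, 0)
  expect_equal(res2$p_value, 1)
  # all values tied across both samples: zero variance, p = 1
  res3 <- mann_whitney_u(rep(2, 5), rep(2, 3))
  expect_equal(res3$p_value, 1)
  expect_error(mann_whitney_u(numeric(0), 1), "non-empty")
})

test_that("tie-corrected z agrees with wilcox.test without continuity correction", {
  set.seed(31)
  for (i in 1:50) {
    x <- sample(1:6, 8, replace = TRUE)
    y <- sample(1:6, 10, replace = TRUE)
    res <- mann_whitney_u(x, y)
    ref <- suppressWarnings(wilcox.test(x, y, correct = FALSE, exact = FALSE))
    expect_equal(res$U, unname(ref$statistic))
    expect_equal(res$p_value, ref$p.value, tolerance = 1e-10)
  }
})

test_that("exact enumeration agrees with the exact Wilcoxon distribution", {
  set.seed(8)
  for (i in 1:20) {
    x <- runif(4); y <- runif(5) # continuous, no ties
    res <- mann_whitney_u(x, y, exact = TRUE)
    ref <- wilcox.test(x, y, exact = TRUE)
    expect_equal(res$p_value, ref$p.value, tolerance = 1e-12)
  }
})

test_that("the normal approximation's worst-case error shrinks with sample size", {
  # exhaustive over all no-tie rank configurations at balanced sizes
  worst_gap <- function(n1, n2) {
    N <- n1 + n2
    max(apply(combn(N, n1), 2, function(ix) {
      x <- ix; y <- setdiff(1:N, ix)
      abs(mann_whitney_u(x, y)$p_value -
            mann_whitney_u(x, y, exact = TRUE)$p_value)
    }))
  }
  gaps <- sapply(2:6, function(n) worst_gap(n, n))
  expect_true(all(diff(gaps) < 0))
  expect_lt(gaps[5], 0.07) # n1 = n2 = 6
})

test_that("Mann-Whitney is invariant under strictly monotone transforms", {
  set.seed(19)
  x <- rnorm(12); y <- rnorm(15, 0.5)
  base <- mann_whitney_u(x, y)
  for (f in list(function(v) exp(v), function(v) v^3, function(v) atan(v))) {
    res <- mann_whitney_u(f(x), f(y))
    expect_equal(res$U, base$U)
    expect_equal(res$p_value, base$p_value)
  }
})

test_that("arcsine power reproduces the published post-hoc value", {
  pw <- power_two_proportions(223 / 575, 51 / 111, 575, 111)
  expect_equal(round(pw$power, 2), 0.29)
})

test_that("power equals alpha under the null and is monotone", {
  expect_equal(power_two_proportions(0.3, 0.3, 50, 80)$power, 0.05,
               tolerance = 1e-12)
  expect_equal(power_two_proportions(0.3, 0.3, 50, 80, alpha = 0.1)$power, 0.1,
               tolerance = 1e-12)
  # doubling both n never decreases power
  grid <- expand.grid(p1 = c(0.2, 0.4), p2 = c(0.25, 0.5, 0.6),
                      n = c(20, 50, 200))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    expect_gte(power_two_proportions(g$p1, g$p2, 2 * g$n, 2 * g$n)$power,
               power_two_proportions(g$p1, g$p2, g$n, g$n)$power)
  }
  # monotone in |h|: moving p2 away from p1 increases power
  p2s <- c(0.35, 0.45, 0.55, 0.65)
  pws <- sapply(p2s, function(p2) power_two_proportions(0.3, p2, 60, 60)$power)
  expect_true(all(diff(pws) > 0))
  # monotone in alpha
  expect_gt(power_two_proportions(0.3, 0.5, 60, 60, alpha = 0.1)$power,
            power_two_proportions(0.3, 0.5, 60, 60, alpha = 0.01)$power)
  expect_error(power_two_proportions(0, 0.5, 10, 10), "strictly inside")
})
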