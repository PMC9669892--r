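test_that("exact intervals match brute-force binomial tail inversion", {
  # boundary behaviour
  expect_equal(clopper_pearson(0, 10)[["low"]], 0)
  expect_equal(clopper_pearson(10, 10)[["high"]], 1)
  expect_error(clopper_pearson(3, 0), "n >= 1")
  expect_error(clopper_pearson(5, 3), "0 <= k <= n")

  # all k <= n <= 12 against the bisection oracle
  for (n in 1:12) {
    for (k in 0:n) {
      got <- clopper_pearson(k, n)
      oracle <- cp_bisect_oracle(k, n)
      expect_equal(got[["low"]], oracle[["low"]], tolerance = 1e-7)
      expect_equal(got[["high"]], oracle[["high"]], tolerance = 1e-7)
    }
  }
  # and against the standard exact test implementation
  for (case in list(c(3, 8), c(423, 953), c(110, 686))) {
    bt <- stats::binom.test(case[1], case[2])$conf.int
    got <- clopper_pearson(case[1], case[2])
    expect_equal(unname(got), base::c(bt[1], bt[2]), tolerance = 1e-12)
  }
})

test_that("interval width shrinks with n at fixed proportion", {
  widths <- sapply(base::c(20, 80, 320, 1280), function(n) {
    ci <- clopper_pearson(round(0.3 * n), n)
    ci[["high"]] - ci[["low"]]
  })
  expect_true(all(diff(widths) < 0))
})

test_that("exact intervals are conservative in coverage", {
  set.seed(77)
  for (p in base::c(0.1, 0.5, 0.9)) {
    for (n in base::c(20, 200)) {
      k <- rbinom(1000, n, p)
      cover <- vapply(k, function(ki) {
        ci <- clopper_pearson(ki, n)
        ci[["low"]] <= p && p <= ci[["high"]]
      }, logical(1))
      expect_gte(mean(cover), 0.95)
    }
  }
})

test_that("rate constructors carry exact intervals and invariants", {
  r <- concordance_rate(423, 686, variable = "physician_visit")
  expect_equal(round(100 * r$rate, 1), 61.7)
  expect_true(r$ci_low <= r$rate && r$rate <= r$ci_high)
  r2 <- concordance_rate(619, 686)
  expect_equal(round(100 * r2$rate, 1), 90.2)
  r3 <- concordance_rate(10, 10)
  expect_equal(r3$ci_high, 1)
  c1 <- completeness_rate(423, 953)
  expect_equal(round(100 * c1$rate, 1), 44.4)
  expect_equal(round(100 * base::c(c1$ci_low, c1$ci_high), 1),
               base::c(41.2, 47.6))
  c0 <- completeness_rate(0, 50)
  expect_equal(c0$rate, 0)
  expect_equal(c0$ci_low, 0)
})

test_that("Yates chi-square matches the cell-sum form and chisq.test", {
  expect_equal(chi_square_yates(90, 334, 20, 242)$statistic, 21.225,
               tolerance = 1e-4)
  # perfectly proportional table: statistic 0 (continuity term capped)
  expect_equal(chi_square_yates(20, 40, 10, 20)$statistic, 0)
  expect_error(chi_square_yates(0, 0, 3, 5), "marginal")

  cellsum_oracle <- function(a, b, c, d) {
    o <- base::c(a, b, c, d)
    n <- sum(o)
    e <- base::c((a + b) * (a + c), (a + b) * (b + d),
                 (c + d) * (a + c), (c + d) * (b + d)) / n
    sum((abs(o - e) - pmin(0.5, abs(o - e)))^2 / e)
  }
  set.seed(55)
  for (i in 1:25) {
    tb <- rpois(4, 12) + 1
    got <- chi_square_yates(tb[1], tb[2], tb[3], tb[4])
    expect_equal(got$statistic,
                 cellsum_oracle(tb[1], tb[2], tb[3], tb[4]),
                 tolerance = 1e-10)
    ct <- suppressWarnings(
      stats::chisq.test(matrix(tb, 2, 2, byrow = TRUE), correct = TRUE))
    expect_equal(got$statistic, unname(ct$statistic), tolerance = 1e-10)
    expect_equal(got$p_value, ct$p.value, tolerance = 1e-10)
    # uncorrected form on request
    ct0 <- suppressWarnings(
      stats::chisq.test(matrix(tb, 2, 2, byrow = TRUE), correct = FALSE))
    expect_equal(chi_square_yates(tb[1], tb[2], tb[3], tb[4],
                                  correct = FALSE)$statistic,
                 unname(ct0$statistic), tolerance = 1e-10)
  }
})

test_that("rank-sum test matches permutation enumeration on small samples", {
  expect_error(mann_whitney(numeric(0), 1:3), "non-empty")
  # complete separation: U = 0 for x
  expect_equal(mann_whitney(base::c(1, 2, 3), base::c(4, 5, 6))$statistic, 0)
  # identical samples: direction-free p near 1
  p_same <- mann_whitney(base::c(1, 2, 3, 4), base::c(1, 2, 3, 4))$p_value
  expect_gte(p_same, 0.99)

  set.seed(66)
  for (i in 1:10) {
    m <- sample(3:6, 1); n <- sample(3:6, 1)
    x <- round(runif(m, 0, 10), 3)  # continuous: tie-free
    y <- round(runif(n, 0, 10), 3)
    expect_equal(mann_whitney(x, y, exact = TRUE)$p_value,
                 mw_permutation_oracle(x, y), tolerance = 1e-10)
  }
})

test_that("threshold checks are inclusive at the boundary", {
  expect_true(threshold_check(concordance_rate(9931, 10000)))
  expect_false(threshold_check(concordance_rate(617, 1000)))
  expect_true(threshold_check(concordance_rate(95, 100)))
  expect_false(threshold_check(concordance_rate(94, 100)))
  expect_true(threshold_check(concordance_rate(80, 100), threshold = 0.8))
})

test_that("quartiles use the inclusive interpolation convention", {
  expect_equal(median_iqr(1:5),
               base::c(median = 3, q1 = 2, q3 = 4, min = 1, max = 5))
  expect_equal(unname(median_iqr(7)), rep(7, 5))
  set.seed(88)
  for (i in 1:10) {
    x <- runif(sample(2:40, 1))
    got <- median_iqr(x)
    s <- sort(x)
    q_oracle <- function(p) {
      h <- (length(s) - 1) * p + 1
      lo <- floor(h); hi <- ceiling(h)
      s[lo] + (h - lo) * (s[hi] - s[lo])
    }
    expect_equal(got[["q1"]], q_oracle(0.25), tolerance = 1e-12)
    expect_equal(got[["median"]], q_oracle(0.5), tolerance = 1e-12)
    expect_equal(got[["q3"]], q_oracle(0.75), tolerance = 1e-12)
  }
})

test_that("p-values format in report style", {
  expect_equal(format_p(0.0004), "<.001")
  expect_equal(format_p(0.043), ".043")
})
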