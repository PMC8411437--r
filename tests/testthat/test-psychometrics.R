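test_that("ICC limiting cases behave as the model dictates", {
  # identical scores within case, case means differ -> MSW = 0, ICC = 1
  r <- estimate_icc_oneway(list(a = c(2, 2, 2), b = c(5, 5, 5),
                                c = c(9, 9, 9)))
  expect_identical(r$icc, 1)
  expect_identical(c(r$ci_lower, r$ci_upper), c(1, 1))

  # equal case means, within-case spread -> ICC <= 0
  r <- estimate_icc_oneway(list(a = c(1, 3), b = c(0, 4), c = c(2, 2)))
  expect_lte(r$icc, 0)

  # all identical -> degenerate
  expect_error(estimate_icc_oneway(list(a = c(1, 1), b = c(1, 1))),
               "degenerate")

  # single-rating cases are dropped with a warning
  expect_warning(
    r <- estimate_icc_oneway(list(a = c(1, 2), b = c(4, 5), c = 7)),
    "fewer than 2 ratings")
  expect_identical(r$n_subjects, 2L)
  expect_identical(r$dropped, "c")
})

test_that("ICC matches the ANOVA sums-of-squares oracle on fixtures", {
  fixture <- list(c1 = c(9, 2, 5), c2 = c(6, 1, 7), c3 = c(8, 2, 6),
                  c4 = c(7, 1, 2))
  r <- estimate_icc_oneway(fixture)
  o <- oracle_icc(fixture)
  expect_equal(r$icc, o$icc, tolerance = 1e-10)
  expect_equal(r$msb, o$msb, tolerance = 1e-10)
  expect_equal(r$msw, o$msw, tolerance = 1e-10)
  expect_equal(r$k0, o$k0, tolerance = 1e-10)
  # cross-check mean squares against stats::aov
  df <- data.frame(y = unlist(fixture),
                   g = rep(names(fixture), lengths(fixture)))
  ms <- summary(stats::aov(y ~ g, df))[[1]][["Mean Sq"]]
  expect_equal(r$msb, ms[1], tolerance = 1e-10)
  expect_equal(r$msw, ms[2], tolerance = 1e-10)
})

test_that("ICC equals the oracle on 100 random designs", {
  set.seed(2024)
  for (rep in 1:100) {
    balanced <- rep %% 2 == 0
    scores <- if (balanced) {
      k <- sample(2:5, 1)
      random_scores(sample(4:12, 1), k_range = c(k, k))
    } else {
      random_scores(sample(4:12, 1))
    }
    r <- estimate_icc_oneway(scores)
    o <- oracle_icc(scores)
    expect_equal(r$icc, o$icc, tolerance = 1e-10)
    if (balanced) {
      # balanced design: textbook closed form with k0 = k
      k <- unname(lengths(scores)[1])
      expect_equal(r$k0, unname(k), tolerance = 1e-12)
      expect_equal(r$icc,
                   (r$msb - r$msw) / (r$msb + (k - 1) * r$msw),
                   tolerance = 1e-12)
    }
  }
})

test_that("ICC is invariant to row order and report shape is sane", {
  set.seed(5)
  scores <- random_scores(8)
  r1 <- estimate_icc_oneway(scores)
  r2 <- estimate_icc_oneway(rev(scores))
  expect_equal(r1$icc, r2$icc, tolerance = 1e-12)
  expect_equal(c(r1$ci_lower, r1$ci_upper), c(r2$ci_lower, r2$ci_upper),
               tolerance = 1e-12)
  expect_lte(r1$ci_lower, r1$icc)
  expect_gte(r1$ci_upper, r1$icc)
  expect_lte(r1$k0, max(lengths(scores)))
  # data-frame input path
  df <- data.frame(case_id = rep(names(scores), lengths(scores)),
                   score = unlist(scores))
  expect_equal(estimate_icc_oneway(df)$icc, r1$icc, tolerance = 1e-12)
})

test_that("the F-pivot CI covers a known ICC at nominal rate", {
  set.seed(99)
  rho <- 0.6
  n <- 25L
  k <- 4L
  hits <- 0L
  reps <- 500L
  for (i in seq_len(reps)) {
    b <- stats::rnorm(n, sd = sqrt(rho))
    y <- rep(b, each = k) + stats::rnorm(n * k, sd = sqrt(1 - rho))
    r <- estimate_icc_oneway(split(y, rep(seq_len(n), each = k)))
    if (r$ci_lower <= rho && rho <= r$ci_upper) hits <- hits + 1L
  }
  expect_gte(hits / reps, 0.90)
})

test_that("Cronbach's alpha agrees with closed forms and the oracle", {
  # identical columns -> alpha 1
  m <- matrix(rep(c(1, 4, 2, 5), 3), ncol = 3)
  expect_equal(cronbach_alpha(m)$alpha, 1, tolerance = 1e-12)

  # two items, zero sample covariance, equal variance -> alpha 0
  x <- c(-1, 0, 1)
  y <- c(1, -2, 1) / sqrt(3)
  expect_equal(stats::cov(x, y), 0, tolerance = 1e-12)
  expect_equal(cronbach_alpha(cbind(x, y))$alpha, 0, tolerance = 1e-12)

  # fixture 6 x 3 against the covariance-matrix oracle
  set.seed(8)
  m <- matrix(stats::rnorm(18), nrow = 6, ncol = 3,
              dimnames = list(NULL, c("i1", "i2", "i3")))
  a <- cronbach_alpha(m)
  expect_equal(a$alpha, oracle_alpha(m), tolerance = 1e-12)
  expect_identical(a$interitem, t(a$interitem))
  expect_identical(unname(diag(a$interitem)), rep(1, 3))
  expect_lte(a$alpha, 1)
  # interitem matrix positive semi-definite up to tolerance
  expect_gte(min(eigen(a$interitem, symmetric = TRUE)$values), -1e-12)
})

test_that("alpha oracle equivalence holds over random matrices", {
  set.seed(31)
  for (rep in 1:50) {
    n <- sample(5:12, 1)
    k <- sample(2:6, 1)
    m <- matrix(stats::rnorm(n * k), nrow = n, ncol = k)
    a <- cronbach_alpha(m)
    expect_equal(a$alpha, oracle_alpha(m), tolerance = 1e-12)
  }
})

test_that("alpha flags redundancy and handles degenerate items", {
  set.seed(12)
  base <- stats::rnorm(60)
  m <- cbind(a = base, b = base + stats::rnorm(60, sd = 0.05),
             c = stats::rnorm(60))
  a <- cronbach_alpha(m, redundancy_threshold = 0.7)
  expect_identical(nrow(a$redundant), 1L)
  expect_setequal(c(a$redundant$item_a, a$redundant$item_b), c("a", "b"))
  expect_gt(a$redundant$r, 0.7)

  mz <- cbind(m, z = rep(2, 60))
  expect_warning(az <- cronbach_alpha(mz), "zero-variance")
  expect_identical(az$excluded_items, "z")
  expect_identical(az$n_items, 3L)
  expect_error(suppressWarnings(cronbach_alpha(cbind(rep(1, 5),
                                                     rep(2, 5)))),
               "fewer than 2 usable")
  expect_error(cronbach_alpha(m[1:2, ]), "at least 3 cases")
})

test_that("Spearman rho matches the rank-transform oracle", {
  x <- c(3, 1, 4, 1, 5, 9, 2, 6)      # ties present
  y <- c(2, 7, 1, 8, 2, 8, 1, 8)
  r <- spearman_with_ci(x, y)
  expect_equal(r$rho, stats::cor(x, y, method = "spearman"),
               tolerance = 1e-12)
  expect_equal(r$rho, stats::cor(rank(x), rank(y)), tolerance = 1e-12)

  xs <- 1:10
  expect_equal(spearman_with_ci(xs, exp(xs))$rho, 1, tolerance = 1e-12)
  expect_equal(spearman_with_ci(xs, rev(xs))$rho, -1, tolerance = 1e-12)
  expect_error(spearman_with_ci(xs, rep(1, 10)), "constant")
  expect_error(spearman_with_ci(1:3, 1:3), "at least 4")
})

test_that("Spearman CI methods agree in location and bands are assigned", {
  set.seed(21)
  x <- stats::rnorm(40)
  y <- 0.6 * x + stats::rnorm(40, sd = 0.8)
  rf <- spearman_with_ci(x, y, method = "fisher")
  rb <- spearman_with_ci(x, y, method = "bootstrap", seed = 7)
  expect_equal(rf$rho, rb$rho, tolerance = 1e-12)
  for (r in list(rf, rb)) {
    expect_lte(r$ci_lower, r$rho)
    expect_gte(r$ci_upper, r$rho)
  }
  # bootstrap is reproducible under a fixed seed
  rb2 <- spearman_with_ci(x, y, method = "bootstrap", seed = 7)
  expect_identical(rb$ci_lower, rb2$ci_lower)

  # fixed permutations with known rank correlations: sum(d^2) = 28 gives
  # rho = 1 - 6*28/210 = 0.2 (weak); 36 gives rho = -6/210 (negligible)
  expect_identical(spearman_with_ci(1:10, (1:10)^3)$strength_band, "strong")
  expect_identical(spearman_with_ci(1:6, c(2, 4, 6, 1, 3, 5))$strength_band,
                   "weak")
  expect_identical(spearman_with_ci(1:6, c(3, 4, 6, 1, 2, 5))$strength_band,
                   "negligible")
})

test_that("mean_per_case averages raters and enforces the minimum", {
  rt <- data.frame(
    case_id = c("a", "a", "a", "b", "b", "c", "c", "c", "c"),
    total = c(4, 5, 6, 1, 3, 2, 2, 2, 6)
  )
  m <- mean_per_case(rt, "total", min_raters = 3L)
  expect_equal(m[["a"]], 5)
  expect_equal(m[["c"]], 3)
  expect_false("b" %in% names(m))
  # oracle: naive group-by
  oracle <- tapply(rt$total, rt$case_id, mean)
  expect_equal(as.numeric(m[c("a", "c")]),
               as.numeric(oracle[c("a", "c")]), tolerance = 1e-12)
  expect_error(mean_per_case(rt, "total", min_raters = 5L), "no case")
})
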