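instr <- canonical_addi()

test_that("default design mirrors the reference study layout", {
  d <- study_design()
  expect_identical(d$n_cases, 110L)
  expect_identical(d$diseases,
                   c(CAPS = 29L, TRAPS = 27L, FMF = 29L, MKD = 25L))
  expect_identical(d$n_groups * d$cases_per_group, d$n_cases)
  expect_identical(d$raters_per_group, 4L)
  expect_identical(d$min_item_occurrences, 4L)
  # proportional apportionment for other sizes
  d2 <- study_design(n_cases = 100L, n_groups = 10L)
  expect_identical(sum(d2$diseases), 100L)
  expect_error(study_design(n_cases = 100L, n_groups = 7L),
               "must equal n_cases")
  expect_error(study_design(diseases = c(CAPS = 10L)), "must sum")
})

test_that("generated cases satisfy the design constraints", {
  d <- study_design(seed = 42L)
  cases <- generate_cases(d, instr)
  expect_length(cases, 110L)
  expect_identical(table(vapply(cases, `[[`, character(1), "disease")),
                   table(rep(names(d$diseases), d$diseases)))

  # every item represented as eligible damage in >= 4 cases
  eligible_counts <- sapply(names(instr$items), function(id) {
    sum(vapply(cases, function(case) {
      ev <- case$evidence[[id]]
      !is.null(ev) && is_damage_eligible(ev)$eligible &&
        score_item(instr, ev, case) > 0L
    }, logical(1)))
  })
  expect_true(all(eligible_counts >= d$min_item_occurrences))

  # applicability respected
  for (case in cases) {
    if (case$age_years > 18) {
      expect_null(case$evidence[["developmental_delay"]])
    }
    if (case$sex == "male") expect_null(case$evidence[["amenorrhea"]])
  }

  # mixture of asserted and measured evidence
  modes <- unlist(lapply(cases, function(c) {
    vapply(c$evidence, `[[`, character(1), "mode")
  }))
  expect_setequal(unique(modes), c("asserted", "measured"))

  # determinism and the empty design
  expect_identical(generate_cases(d, instr), cases)
  expect_identical(generate_cases(study_design(n_cases = 0L, n_groups = 0L,
                                               cases_per_group = 0L),
                                  instr),
                   list())
})

test_that("allocation is nested: disjoint case blocks, disjoint rater sets", {
  d <- study_design(n_cases = 100L, n_groups = 10L, seed = 1L)
  cases <- generate_cases(d, instr)
  al <- allocate_design(cases, d)
  expect_length(al, 10L)
  all_cases <- unlist(lapply(al, `[[`, "case_ids"))
  all_raters <- unlist(lapply(al, `[[`, "rater_ids"))
  expect_identical(anyDuplicated(all_cases), 0L)
  expect_identical(anyDuplicated(all_raters), 0L)
  expect_length(all_cases, 100L)
  expect_true(all(lengths(lapply(al, `[[`, "rater_ids")) == 4L))

  expect_error(allocate_design(cases[1:5], d), "5 cases")

  d1 <- study_design(n_cases = 1L, n_groups = 1L, cases_per_group = 1L,
                     raters_per_group = 1L, diseases = c(FMF = 1L),
                     min_item_occurrences = 0L, seed = 2L)
  al1 <- allocate_design(generate_cases(d1, instr), d1)
  expect_length(al1, 1L)
  expect_length(al1$G01$case_ids, 1L)
})

test_that("noiseless raters reproduce the true scorecards exactly", {
  d <- study_design(n_cases = 20L, n_groups = 2L, seed = 4L)
  cases <- generate_cases(d, instr)
  al <- allocate_design(cases, d)
  silent <- rater_model(0, 0, 0, 0)
  rt <- simulate_ratings(cases, al, silent, instr, seed = 1L)
  truth <- vapply(cases, function(c) score_case(instr, c)$total, integer(1))
  names(truth) <- vapply(cases, `[[`, character(1), "case_id")
  expect_equal(rt$total, unname(truth[rt$case_id]))
  # per-item equality too
  for (i in sample(nrow(rt), 10)) {
    sc <- score_case(instr, cases[[match(rt$case_id[i],
                                         names(truth))]])
    expect_equal(unlist(rt[i, names(instr$items)]),
                 sc$item_points[names(instr$items)],
                 ignore_attr = TRUE)
  }
  expect_identical(estimate_icc_oneway(ratings_to_scores(rt))$icc, 1)
})

test_that("total miss drives the study degenerate", {
  d <- study_design(n_cases = 20L, n_groups = 2L, seed = 4L)
  cases <- generate_cases(d, instr)
  al <- allocate_design(cases, d)
  rt <- simulate_ratings(cases, al, rater_model(p_miss = 1, p_false = 0,
                                                p_grade_confusion = 0),
                         instr, seed = 1L)
  expect_true(all(rt$total == 0))
  expect_error(estimate_icc_oneway(ratings_to_scores(rt)), "degenerate")
})

test_that("rating simulation is deterministic and matches a re-run oracle", {
  d <- study_design(n_cases = 30L, n_groups = 3L, cases_per_group = 10L,
                    seed = 6L)
  cases <- generate_cases(d, instr)
  al <- allocate_design(cases, d)
  model <- rater_model()
  rt1 <- simulate_ratings(cases, al, model, instr, seed = 7L)
  rt2 <- simulate_ratings(cases, al, model, instr, seed = 7L)
  expect_identical(rt1, rt2)
  rt3 <- simulate_ratings(cases, al, model, instr, seed = 8L)
  expect_false(identical(rt1$total, rt3$total))
  # schema and internal consistency: totals re-derivable from item scores
  expect_silent(validate_ratings(rt1, instr))
})

test_that("estimated ICC decreases with the noise scale", {
  d <- study_design(n_cases = 40L, n_groups = 4L, seed = 10L)
  cases <- generate_cases(d, instr)
  al <- allocate_design(cases, d)
  base <- rater_model()
  mean_icc <- function(s) {
    mean(vapply(1:5, function(r) {
      rt <- simulate_ratings(cases, al, scale_rater_model(base, s), instr,
                             seed = 100L * r + round(10 * s))
      estimate_icc_oneway(ratings_to_scores(rt))$icc
    }, numeric(1)))
  }
  grid <- vapply(c(0, 1, 4, 16), mean_icc, numeric(1))
  expect_true(all(diff(grid) < 0))
  expect_identical(grid[[1]], 1)
})

test_that("noise calibration brackets and hits its target", {
  d <- study_design(n_cases = 40L, n_groups = 4L, seed = 12L)
  cal_lo <- calibrate_noise_to_icc(0.3, d, instr, tol = 0.05, n_rep = 5L,
                                   seed = 2L)
  cal_hi <- calibrate_noise_to_icc(0.8, d, instr, tol = 0.05, n_rep = 5L,
                                   seed = 2L)
  expect_gt(cal_lo$scale, cal_hi$scale)
  expect_lt(abs(cal_hi$achieved_icc - 0.8), 0.1)
  expect_error(calibrate_noise_to_icc(1.2, d), "between 0 and 1")
})

test_that("scale_rater_model scales jointly and caps at 0.95", {
  m <- rater_model(p_miss = 0.1, p_false = 0.04, p_grade_confusion = 0.2,
                   pga_noise_sd = 0.5)
  s <- scale_rater_model(m, 3)
  expect_equal(s$p_miss, 0.3)
  expect_equal(s$p_false, 0.12)
  expect_equal(s$p_grade_confusion, 0.6)
  expect_equal(s$pga_noise_sd, 0.5)   # unscaled
  expect_equal(scale_rater_model(m, 100)$p_miss, 0.95)
  expect_equal(scale_rater_model(m, 0)$p_miss, 0)
})

test_that("ground-truth variance components are coherent", {
  d <- study_design(n_cases = 30L, n_groups = 3L, cases_per_group = 10L,
                    seed = 20L)
  cases <- generate_cases(d, instr)
  tr <- estimate_truth(cases, rater_model(), instr, n_raters_mc = 50L,
                       seed = 3L)
  expect_gte(tr$icc_expected, 0)
  expect_lte(tr$icc_expected, 1)
  expect_equal(tr$icc_expected,
               tr$sigma2_between / (tr$sigma2_between + tr$sigma2_within),
               tolerance = 1e-12)
  truth0 <- estimate_truth(cases, rater_model(0, 0, 0, 0), instr,
                           n_raters_mc = 10L, seed = 3L)
  expect_identical(truth0$sigma2_within, 0)
  expect_identical(truth0$icc_expected, 1)
})
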