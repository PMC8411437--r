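instr <- canonical_addi()

test_that("damage eligibility follows the 6-month / attribution rule", {
  cases <- list(
    list(ev = evidence("serosal_scarring", "asserted",
                       asserted_grade = "present", duration_months = 8,
                       resolved = TRUE),
         eligible = TRUE, reason = NA_character_),
    list(ev = evidence("serosal_scarring", "asserted",
                       asserted_grade = "present", duration_months = 3),
         eligible = FALSE, reason = "duration<6mo"),
    list(ev = evidence("serosal_scarring", "asserted",
                       asserted_grade = "present", duration_months = 12,
                       attributed_to_active_disease = TRUE),
         eligible = FALSE, reason = "attributed_to_active_disease"),
    list(ev = evidence("serosal_scarring", "asserted",
                       asserted_grade = "present", duration_months = 12,
                       onset_after_aid_onset = FALSE),
         eligible = FALSE, reason = "onset_before_aid_onset"),
    list(ev = evidence("serosal_scarring", "asserted",
                       asserted_grade = "present", duration_months = 6),
         eligible = TRUE, reason = NA_character_)
  )
  for (tc in cases) {
    el <- is_damage_eligible(tc$ev)
    expect_identical(el$eligible, tc$eligible)
    expect_identical(el$reason, tc$reason)
  }
})

test_that("renal insufficiency grades partition on GFR 15 / 60", {
  expect_identical(grade_renal_insufficiency(40), "moderate")
  expect_identical(grade_renal_insufficiency(10), "severe")
  expect_identical(grade_renal_insufficiency(NA, TRUE), "severe")
  expect_identical(grade_renal_insufficiency(90), NA_character_)
  # boundaries: 15 is moderate, 60 is not insufficiency
  expect_identical(grade_renal_insufficiency(15), "moderate")
  expect_identical(grade_renal_insufficiency(14.99), "severe")
  expect_identical(grade_renal_insufficiency(60), NA_character_)
  expect_error(grade_renal_insufficiency(-5), "non-negative")
  expect_error(grade_renal_insufficiency(NA), "required")
})

test_that("proteinuria thresholds are strict inequalities", {
  expect_true(grade_proteinuria(pcr_mg_mmol = 25))
  expect_false(grade_proteinuria(pcr_mg_mmol = 20))
  expect_false(grade_proteinuria(protein_g_24h = 0.3))
  expect_true(grade_proteinuria(protein_g_24h = 0.31))
  expect_true(grade_proteinuria(acr_mg_mmol = 16))
  expect_false(grade_proteinuria(acr_mg_mmol = 15))
  expect_true(grade_proteinuria(pcr_mg_mmol = 5, acr_mg_mmol = 16))
  expect_error(grade_proteinuria(), "at least one")
})

test_that("growth failure needs two of three features (adult: short stature)", {
  expect_true(grade_growth_failure(c(TRUE, FALSE, TRUE)))
  expect_false(grade_growth_failure(c(TRUE, FALSE, FALSE)))
  expect_true(grade_growth_failure(c(TRUE, TRUE, TRUE)))
  expect_true(grade_growth_failure(adult = TRUE, adult_short_stature = TRUE))
  expect_false(grade_growth_failure(c(TRUE, TRUE, TRUE), adult = TRUE,
                                    adult_short_stature = FALSE))
})

test_that("hearing loss grading keys on the aid/implant requirement", {
  expect_identical(grade_hearing_loss(TRUE, FALSE), "moderate")
  expect_identical(grade_hearing_loss(TRUE, TRUE), "severe")
  expect_identical(grade_hearing_loss(FALSE, FALSE), NA_character_)
  expect_error(grade_hearing_loss(FALSE, TRUE), "without confirmed")
})

test_that("ocular grading keys on visual impairment", {
  expect_identical(grade_ocular(TRUE, "none"), "mild")
  expect_identical(grade_ocular(TRUE, "impaired"), "moderate")
  expect_identical(grade_ocular(TRUE, "legal_blindness"), "severe")
  expect_identical(grade_ocular(FALSE, "none"), NA_character_)
  expect_error(grade_ocular(FALSE, "impaired"), "without documented")
})

test_that("osteoporosis requires both low density and fracture", {
  expect_true(grade_osteoporosis(TRUE, TRUE))
  expect_false(grade_osteoporosis(TRUE, FALSE))
  expect_false(grade_osteoporosis(FALSE, TRUE))
  expect_false(grade_osteoporosis(FALSE, FALSE))
})

test_that("score_item composes grading with the eligibility gate", {
  case <- case_record("c1", "FMF", 30, "female")
  ev <- evidence("amyloidosis", "asserted", asserted_grade = "extensive",
                 duration_months = 24)
  expect_identical(as.integer(score_item(instr, ev, case)), 3L)

  ev <- evidence("renal_insufficiency", "measured",
                 measurements = list(gfr = 40), duration_months = 12)
  expect_identical(as.integer(score_item(instr, ev, case)), 2L)

  ev <- evidence("cns_involvement", "asserted", asserted_grade = "present",
                 duration_months = 2)
  s <- score_item(instr, ev, case)
  expect_identical(as.integer(s), 0L)
  expect_identical(attr(s, "reason"), "duration<6mo")

  expect_error(score_item(instr, evidence("amyloidosis", "asserted",
                                          asserted_grade = "massive"),
                          case),
               "unknown asserted grade")
  expect_error(score_item(instr, evidence("developmental_delay", "asserted",
                                          asserted_grade = "present"),
                          case),
               "paediatric-only")
  male <- case_record("c2", "FMF", 30, "male")
  expect_error(score_item(instr, evidence("amenorrhea", "asserted",
                                          asserted_grade = "present"),
                          male),
               "cannot be asserted for male")
  expect_error(score_item(instr, evidence("cns_involvement", "measured",
                                          measurements = list(gfr = 10)),
                          case),
               "no measurement grader")
})

test_that("score_case caps categories and sums capped subtotals", {
  case <- case_record("renal_case", "FMF", 30, "female", list(
    evidence("amyloidosis", "asserted", asserted_grade = "extensive"),
    evidence("proteinuria", "asserted", asserted_grade = "present"),
    evidence("renal_insufficiency", "asserted", asserted_grade = "severe")
  ))
  sc <- score_case(instr, case)
  expect_identical(sum(sc$item_points[c("amyloidosis", "proteinuria",
                                        "renal_insufficiency")]), 7L)
  expect_identical(sc$category_points[["renal_amyloidosis"]], 6L)
  expect_identical(sc$total, 6L)

  empty <- case_record("empty", "MKD", 10, "male")
  sc0 <- score_case(instr, empty)
  expect_identical(sc0$total, 0L)
  expect_setequal(sc0$exclusions$item_id, names(instr$items))
  expect_true(all(sc0$exclusions$reason == "not_assessed"))

  expect_identical(score_case(instr, max_damage_case(instr))$total, 27L)
})

test_that("scoring is idempotent and respects caps on random cases", {
  set.seed(77)
  design <- study_design(n_cases = 30L, n_groups = 3L,
                         cases_per_group = 10L, seed = 15L)
  cases <- generate_cases(design, instr)
  caps <- vapply(instr$categories, `[[`, integer(1), "max_points")
  for (case in cases) {
    sc1 <- score_case(instr, case)
    sc2 <- score_case(instr, case)
    expect_identical(sc1, sc2)
    expect_true(all(sc1$category_points <= caps))
    expect_lte(sc1$total, 27L)
    expect_identical(sc1$total, as.integer(sum(sc1$category_points)))
  }
})

test_that("adding eligible evidence never decreases any subtotal", {
  set.seed(42)
  base_items <- sample(names(instr$items), 6)
  case <- case_record("mono", "CAPS", 12, "female", lapply(
    base_items, function(id) {
      it <- instr$items[[id]]
      lab <- if (length(it$levels)) it$levels[[1L]]$label else "present"
      evidence(id, "asserted", asserted_grade = lab, duration_months = 12)
    }))
  sc <- score_case(instr, case)
  for (id in setdiff(names(instr$items), base_items)) {
    it <- instr$items[[id]]
    lab <- if (length(it$levels)) it$levels[[1L]]$label else "present"
    bigger <- case
    bigger$evidence[[id]] <- evidence(id, "asserted", asserted_grade = lab,
                                      duration_months = 12)
    sc2 <- score_case(instr, bigger)
    expect_true(all(sc2$category_points >= sc$category_points))
    expect_gte(sc2$total, sc$total)
  }
})

test_that("renal points are non-increasing in GFR", {
  pts_of <- function(gfr) {
    lab <- grade_renal_insufficiency(gfr)
    if (is.na(lab)) 0L else {
      lv <- instr$items$renal_insufficiency$levels
      vapply(lv, `[[`, integer(1), "points")[
        match(lab, vapply(lv, `[[`, character(1), "label"))]
    }
  }
  gfr_grid <- seq(1, 120, by = 0.5)
  pts <- vapply(gfr_grid, pts_of, integer(1))
  expect_true(all(diff(pts) <= 0L))
})

test_that("case files round-trip through JSON and CSV", {
  design <- study_design(n_cases = 10L, n_groups = 1L,
                         cases_per_group = 10L, seed = 33L)
  cases <- generate_cases(design, instr)
  jp <- withr::local_tempfile(fileext = ".json")
  cp <- withr::local_tempfile(fileext = ".csv")
  write_cases_json(cases, jp)
  write_cases_csv(cases, cp)
  back_j <- read_cases_json(jp)
  back_c <- read_cases_csv(cp)
  totals <- vapply(cases, function(c) score_case(instr, c)$total, integer(1))
  expect_identical(
    vapply(back_j, function(c) score_case(instr, c)$total, integer(1)),
    totals)
  expect_identical(
    vapply(back_c, function(c) score_case(instr, c)$total, integer(1)),
    totals)
  expect_identical(vapply(back_j, `[[`, character(1), "case_id"),
                   vapply(cases, `[[`, character(1), "case_id"))
})
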