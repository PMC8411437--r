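# ---------------------------------------------------------------------------
# Synthetic validation studies: cases with controlled per-disease item
# prevalence, grouped rater allocation (observer nested within subject),
# a misclassification rater-noise model, and PGA scales — so every
# estimator can be tested against known ground truth.
# ---------------------------------------------------------------------------

# Run expr with a locally seeded RNG, restoring global state afterwards.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", .GlobalEnv)) {
    get(".Random.seed", .GlobalEnv)
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", .GlobalEnv)) {
        rm(".Random.seed", envir = .GlobalEnv)
      }
    } else {
      assign(".Random.seed", old, .GlobalEnv)
    }
  })
  set.seed(seed)
  expr
}

# Named substreams from one root seed, kept below 2^31.
derive_seed <- function(seed, stream) {
  offsets <- c(cases = 101L, allocation = 211L, ratings = 307L,
               calibration = 401L, truth = 503L, activity = 601L)
  stopifnot(stream %in% names(offsets))
  (as.integer(seed) %% 20000000L) * 97L + offsets[[stream]]
}

#' Define a validation study design
#'
#' Defaults mirror the reference study layout: 110 cases (29 CAPS, 27
#' TRAPS, 29 FMF, 25 MKD) split into 11 groups of 10 cases, each group
#' scored by its own set of 4 raters, and every damage item represented (as
#' eligible damage) in at least 4 cases.
#'
#' @param n_cases Total number of cases.
#' @param diseases Named integer vector of cases per disease; must sum to
#'   `n_cases`. When `NULL`, the reference proportions (29:27:29:25 for
#'   CAPS:TRAPS:FMF:MKD) are apportioned to `n_cases` by largest remainder.
#' @param n_groups Number of disjoint case blocks / rater groups.
#' @param cases_per_group Cases per block; `n_groups * cases_per_group` must
#'   equal `n_cases`.
#' @param raters_per_group Raters per group (each scores every case in the
#'   block).
#' @param min_item_occurrences Minimum number of cases in which each item
#'   must appear as eligible damage.
#' @param pediatric_fraction Fraction of paediatric (<= 18 y) cases.
#' @param seed Root seed for all generation substreams.
#' @return A `study_design` list.
#' @export
study_design <- function(n_cases = 110L, diseases = NULL,
                         n_groups = 11L, cases_per_group = 10L,
                         raters_per_group = 4L, min_item_occurrences = 4L,
                         pediatric_fraction = 0.6, seed = 42L) {
  n_cases <- as.integer(n_cases)
  if (is.null(diseases)) {
    ref <- c(CAPS = 29, TRAPS = 27, FMF = 29, MKD = 25)
    quota <- n_cases * ref / sum(ref)
    diseases <- floor(quota)
    rem <- n_cases - sum(diseases)
    if (rem > 0) {
      top <- order(quota - floor(quota), decreasing = TRUE)[seq_len(rem)]
      diseases[top] <- diseases[top] + 1
    }
    diseases <- stats::setNames(as.integer(diseases), names(ref))
  }
  if (n_cases > 0L) {
    if (sum(diseases) != n_cases) {
      stop("disease counts (", sum(diseases), ") must sum to n_cases (",
           n_cases, ")")
    }
    if (as.integer(n_groups) * as.integer(cases_per_group) != n_cases) {
      stop("n_groups * cases_per_group must equal n_cases")
    }
  }
  structure(
    list(n_cases = n_cases, diseases = diseases,
         n_groups = as.integer(n_groups),
         cases_per_group = as.integer(cases_per_group),
         raters_per_group = as.integer(raters_per_group),
         min_item_occurrences = as.integer(min_item_occurrences),
         pediatric_fraction = pediatric_fraction, seed = as.integer(seed)),
    class = "study_design"
  )
}

#' Define a rater-noise model
#'
#' A misclassification stand-in for expert disagreement (the original
#' study's raw per-item disagreement rates are unpublished): a present item
#' is missed with probability `p_miss`, an absent item is falsely scored
#' (at the lowest grade) with probability `p_false`, and a graded item
#' shifts one severity level with probability `p_grade_confusion`. PGA
#' scores receive Gaussian noise before rounding to the 0-10 integer scale.
#'
#' @param p_miss,p_false,p_grade_confusion Probabilities in \[0, 1\].
#' @param pga_noise_sd SD of the PGA noise on the 10-point scale. The
#'   default (0.5) makes the simulated PGA-damage reliability match the
#'   reported PGA-damage ICC of about 0.75 at the default study scale.
#' @param activity_coupling Coupling of the latent disease-activity variable
#'   to true damage in \[0, 1\]; the default (0.6) yields a damage-activity
#'   Spearman of roughly 0.4 at study scale.
#' @return A `rater_model` list.
#' @export
rater_model <- function(p_miss = 0.05, p_false = 0.02,
                        p_grade_confusion = 0.10, pga_noise_sd = 0.5,
                        activity_coupling = 0.6) {
  probs <- c(p_miss = p_miss, p_false = p_false,
             p_grade_confusion = p_grade_confusion)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (pga_noise_sd < 0) stop("pga_noise_sd must be >= 0")
  if (activity_coupling < 0 || activity_coupling > 1) {
    stop("activity_coupling must lie in [0, 1]")
  }
  structure(
    list(p_miss = p_miss, p_false = p_false,
         p_grade_confusion = p_grade_confusion, pga_noise_sd = pga_noise_sd,
         activity_coupling = activity_coupling),
    class = "rater_model"
  )
}

#' Scale a rater model's misclassification probabilities
#'
#' A single multiplier jointly scales `p_miss`, `p_false` and
#' `p_grade_confusion` (capped at 0.95), keeping the calibration search
#' one-dimensional. PGA noise is left unchanged.
#'
#' @param model A [rater_model()].
#' @param s Non-negative scale.
#' @return A scaled `rater_model`.
#' @export
scale_rater_model <- function(model, s) {
  stopifnot(s >= 0)
  rater_model(
    p_miss = min(model$p_miss * s, 0.95),
    p_false = min(model$p_false * s, 0.95),
    p_grade_confusion = min(model$p_grade_confusion * s, 0.95),
    pga_noise_sd = model$pga_noise_sd,
    activity_coupling = model$activity_coupling
  )
}

#' Default per-disease item prevalence profiles
#'
#' Probability that a case of each disease carries eligible damage for each
#' item. The profiles are invented for plausibility (hearing loss enriched
#' in CAPS, amyloidosis and serosal scarring in FMF/TRAPS, developmental
#' items in MKD/CAPS); they are editable and make no claim to reproduce
#' registry epidemiology.
#'
#' @return Matrix, 18 items x 4 diseases.
#' @export
default_prevalence <- function() {
  m <- rbind(
    sub_infertility               = c(0.05, 0.08, 0.10, 0.05),
    amenorrhea                    = c(0.08, 0.08, 0.08, 0.08),
    amyloidosis                   = c(0.10, 0.20, 0.25, 0.08),
    proteinuria                   = c(0.12, 0.20, 0.25, 0.10),
    renal_insufficiency           = c(0.08, 0.12, 0.15, 0.06),
    growth_failure                = c(0.15, 0.10, 0.10, 0.20),
    puberty_delay                 = c(0.10, 0.08, 0.08, 0.15),
    serosal_scarring              = c(0.05, 0.20, 0.25, 0.08),
    developmental_delay           = c(0.20, 0.05, 0.05, 0.15),
    cognitive_impairment          = c(0.18, 0.05, 0.05, 0.12),
    elevated_intracranial_pressure = c(0.20, 0.04, 0.04, 0.04),
    cns_involvement               = c(0.18, 0.05, 0.04, 0.08),
    hearing_loss                  = c(0.40, 0.06, 0.04, 0.08),
    ocular_involvement            = c(0.25, 0.12, 0.06, 0.06),
    joint_restriction             = c(0.15, 0.12, 0.12, 0.12),
    bone_deformity                = c(0.15, 0.06, 0.06, 0.10),
    osteoporosis                  = c(0.08, 0.08, 0.08, 0.08),
    musculoskeletal_pain          = c(0.20, 0.20, 0.20, 0.20)
  )
  colnames(m) <- c("CAPS", "TRAPS", "FMF", "MKD")
  m
}

# Sample a grade index for an item that is present (lower severities more
# common).
sample_grade <- function(n_levels) {
  if (n_levels == 1L) return(1L)
  w <- switch(n_levels - 1L, c(0.6, 0.4), c(0.5, 0.3, 0.2))
  sample.int(n_levels, 1L, prob = w)
}

# Build one evidence entry for an item at a given grade, choosing asserted
# or measured mode so every grader path gets exercised; optionally make the
# evidence ineligible (short duration or activity attribution).
make_evidence <- function(it, grade, eligible, adult) {
  duration <- if (eligible) stats::runif(1, 6, 120) else {
    if (stats::runif(1) < 0.5) stats::runif(1, 0, 5.9) else
      stats::runif(1, 6, 60)
  }
  attributed <- !eligible && duration >= 6
  resolved <- stats::runif(1) < 0.1
  measurable <- it$item_id %in% c(
    "renal_insufficiency", "proteinuria", "growth_failure", "hearing_loss",
    "ocular_involvement", "osteoporosis"
  )
  if (measurable && stats::runif(1) < 0.5) {
    m <- switch(
      it$item_id,
      renal_insufficiency = if (grade == 2L) {
        if (stats::runif(1) < 0.3) {
          list(gfr = stats::runif(1, 1, 14.9), dialysis_or_transplant = TRUE)
        } else list(gfr = stats::runif(1, 1, 14.9))
      } else list(gfr = stats::runif(1, 15, 59.5)),
      proteinuria = switch(
        sample.int(3L, 1L),
        list(pcr_mg_mmol = stats::runif(1, 21, 300)),
        list(protein_g_24h = stats::runif(1, 0.35, 3)),
        list(acr_mg_mmol = stats::runif(1, 16, 100))
      ),
      growth_failure = if (adult) list(adult_short_stature = TRUE) else {
        flags <- c(FALSE, FALSE, FALSE)
        flags[sample.int(3L, sample(2:3, 1L))] <- TRUE
        list(height_below_p3 = flags[1L], velocity_below_p3 = flags[2L],
             centile_crossing = flags[3L])
      },
      hearing_loss = list(impairment_confirmed = TRUE,
                          hearing_aid_required = grade == 2L),
      ocular_involvement = list(
        damage_documented = TRUE,
        visual_impairment = c("none", "impaired", "legal_blindness")[grade]
      ),
      osteoporosis = list(low_bone_density = TRUE, fracture_present = TRUE)
    )
    evidence(it$item_id, "measured", measurements = m,
             duration_months = duration, resolved = resolved,
             attributed_to_active_disease = attributed)
  } else {
    lab <- if (length(it$levels)) it$levels[[grade]]$label else "present"
    evidence(it$item_id, "asserted", asserted_grade = lab,
             duration_months = duration, resolved = resolved,
             attributed_to_active_disease = attributed)
  }
}

item_applicable <- function(it, adult, sex) {
  !(it$pediatric_only && adult) &&
    !(it$applicable_sex == "female_relevant" && sex != "female")
}

#' Generate synthetic patient cases
#'
#' Draws cases from per-disease item prevalence profiles, mixing asserted
#' and measured evidence so every grader path is exercised, and including a
#' small fraction of ineligible evidence (short duration or attribution to
#' ongoing activity) to exercise the eligibility gate. Rejection resampling
#' (injection of additional eligible evidence) guarantees that every item
#' appears as eligible damage in at least `design$min_item_occurrences`
#' cases.
#'
#' @param design A [study_design()].
#' @param instr Instrument (default [canonical_addi()]).
#' @param prevalence Items x diseases probability matrix (default
#'   [default_prevalence()]).
#' @param p_ineligible Probability that a drawn damage item is generated in
#'   ineligible form.
#' @return List of [case_record()] objects (deterministic under
#'   `design$seed`).
#' @export
generate_cases <- function(design, instr = canonical_addi(),
                           prevalence = default_prevalence(),
                           p_ineligible = 0.1) {
  if (design$n_cases == 0L) return(list())
  missing_items <- setdiff(names(instr$items), rownames(prevalence))
  if (length(missing_items)) {
    stop("prevalence matrix lacks item(s): ",
         paste(missing_items, collapse = ", "))
  }
  missing_dis <- setdiff(names(design$diseases), colnames(prevalence))
  if (length(missing_dis)) {
    stop("prevalence matrix lacks disease(s): ",
         paste(missing_dis, collapse = ", "))
  }
  with_seed(derive_seed(design$seed, "cases"), {
    disease_of <- sample(rep(names(design$diseases), design$diseases))
    cases <- vector("list", design$n_cases)
    for (i in seq_len(design$n_cases)) {
      dis <- disease_of[i]
      adult <- stats::runif(1) > design$pediatric_fraction
      age <- if (adult) stats::runif(1, 19, 50) else stats::runif(1, 2, 18)
      sex <- sample(c("female", "male"), 1L)
      evs <- list()
      for (it in instr$items) {
        if (!item_applicable(it, adult, sex)) next
        if (stats::runif(1) >= prevalence[it$item_id, dis]) next
        n_lv <- if (length(it$levels)) length(it$levels) else 1L
        eligible <- stats::runif(1) >= p_ineligible
        evs[[length(evs) + 1L]] <-
          make_evidence(it, sample_grade(n_lv), eligible, adult)
      }
      cases[[i]] <- case_record(sprintf("case_%03d", i), dis, age, sex, evs)
    }
    # injection pass: guarantee minimum eligible representation per item
    eligible_count <- function(item_id) {
      sum(vapply(cases, function(case) {
        ev <- case$evidence[[item_id]]
        !is.null(ev) && is_damage_eligible(ev)$eligible &&
          evidence_grade(instr, ev, case)$grade > 0L
      }, logical(1)))
    }
    for (it in instr$items) {
      deficit <- design$min_item_occurrences - eligible_count(it$item_id)
      if (deficit <= 0L) next
      candidates <- which(vapply(cases, function(case) {
        is.null(case$evidence[[it$item_id]]) &&
          item_applicable(it, case$age_years > 18, case$sex)
      }, logical(1)))
      if (length(candidates) < deficit) {
        stop("cannot represent item '", it$item_id, "' in ",
             design$min_item_occurrences, " cases: only ",
             length(candidates), " applicable cases available")
      }
      chosen <- candidates[sample.int(length(candidates))][seq_len(deficit)]
      for (ci in chosen) {
        case <- cases[[ci]]
        n_lv <- if (length(it$levels)) length(it$levels) else 1L
        ev <- make_evidence(it, sample_grade(n_lv), eligible = TRUE,
                            adult = case$age_years > 18)
        case$evidence[[it$item_id]] <- ev
        cases[[ci]] <- case
      }
    }
    cases
  })
}

#' Allocate cases and raters to groups
#'
#' Splits the cases into `n_groups` disjoint blocks of `cases_per_group` and
#' assigns each group its own disjoint set of raters (the
#' observer-nested-within-subject design: every rater scores every case in
#' their block and nothing else).
#'
#' @param cases List of cases from [generate_cases()].
#' @param design The [study_design()].
#' @return Named list: `group_id` -> list(case_ids, rater_ids).
#' @export
allocate_design <- function(cases, design) {
  if (length(cases) != design$n_cases) {
    stop("got ", length(cases), " cases for a design of ", design$n_cases)
  }
  if (design$n_cases == 0L) return(stats::setNames(list(), character(0)))
  case_ids <- vapply(cases, `[[`, character(1), "case_id")
  order <- with_seed(derive_seed(design$seed, "allocation"),
                     sample.int(length(case_ids)))
  blocks <- split(case_ids[order],
                  rep(seq_len(design$n_groups),
                      each = design$cases_per_group))
  rater_ids <- sprintf("R%03d",
                       seq_len(design$n_groups * design$raters_per_group))
  rater_sets <- split(rater_ids, rep(seq_len(design$n_groups),
                                     each = design$raters_per_group))
  stats::setNames(
    lapply(seq_len(design$n_groups), function(g) {
      list(case_ids = blocks[[g]], rater_ids = rater_sets[[g]])
    }),
    sprintf("G%02d", seq_len(design$n_groups))
  )
}

# True grade vector of a case (eligibility already applied), in instrument
# item order.
case_grades <- function(instr, case, lookup = instrument_lookup(instr)) {
  g <- stats::setNames(integer(length(lookup$item_ids)), lookup$item_ids)
  for (ev in case$evidence) {
    g[ev$item_id] <- evidence_grade(instr, ev, case)$grade
  }
  g
}

#' Simulate a rating table from cases and an allocation
#'
#' Each (case, rater) pair perturbs the case's true eligible grades through
#' the rater-noise model and re-scores the perturbed grades through the
#' scoring engine (item points, category caps, total). PGA-damage is the
#' true total rescaled to 0-10 plus noise; PGA-activity derives from a
#' latent per-case activity variable weakly coupled to true damage.
#'
#' @param cases List of cases.
#' @param allocation From [allocate_design()].
#' @param model A [rater_model()].
#' @param instr Instrument.
#' @param seed Seed for the rating noise (defaults to a substream of the
#'   allocation order).
#' @return A rating table data frame (long format, one row per case-rater).
#' @export
simulate_ratings <- function(cases, allocation, model,
                             instr = canonical_addi(), seed = 7L) {
  lookup <- instrument_lookup(instr)
  n_items <- length(lookup$item_ids)
  case_ids <- vapply(cases, `[[`, character(1), "case_id")
  names(cases) <- case_ids
  G0 <- vapply(cases, function(c) case_grades(instr, c, lookup),
               integer(n_items))
  if (!is.matrix(G0)) G0 <- matrix(G0, nrow = n_items,
                                   dimnames = list(lookup$item_ids, case_ids))
  applicable <- vapply(cases, function(case) {
    vapply(instr$items, item_applicable, logical(1),
           adult = case$age_years > 18, sex = case$sex)
  }, logical(n_items))
  true_totals <- score_grades(lookup, G0)$totals
  damage10 <- 10 * true_totals / instrument_max_total(instr)

  # long observation index: one column per (case, rater)
  obs_case <- integer(0)
  obs_rater <- character(0)
  obs_group <- character(0)
  for (g in names(allocation)) {
    al <- allocation[[g]]
    ci <- match(al$case_ids, case_ids)
    if (anyNA(ci)) stop("allocation names unknown case ids")
    for (r in al$rater_ids) {
      obs_case <- c(obs_case, ci)
      obs_rater <- c(obs_rater, rep(r, length(ci)))
      obs_group <- c(obs_group, rep(g, length(ci)))
    }
  }
  n_obs <- length(obs_case)

  with_seed(seed, {
    # latent per-case activity on the 0-10 scale, weakly coupled to damage
    u <- stats::runif(length(cases), 0, 10)
    latent_activity <- model$activity_coupling * damage10 +
      (1 - model$activity_coupling) * u

    G <- G0[, obs_case, drop = FALSE]
    A <- applicable[, obs_case, drop = FALSE]
    graded <- lookup$n_levels > 1L
    # grade confusion: shift one level, clamped to the item's range
    conf <- matrix(stats::runif(n_items * n_obs) < model$p_grade_confusion,
                   n_items) & G > 0L & graded
    shift <- matrix(sample(c(-1L, 1L), n_items * n_obs, replace = TRUE),
                    n_items)
    G[conf] <- pmin(pmax(G[conf] + shift[conf], 1L),
                    lookup$n_levels[row(G)[conf]])
    # misses and false positives (false positives only where applicable)
    miss <- matrix(stats::runif(n_items * n_obs) < model$p_miss, n_items) &
      G > 0L
    false <- matrix(stats::runif(n_items * n_obs) < model$p_false, n_items) &
      G == 0L & A
    G[miss] <- 0L
    G[false] <- 1L

    sc <- score_grades(lookup, G)
    # A noiseless rater reports the exact rescaled value; rounding to the
    # 0-10 integer survey scale only applies to noisy assessments (so the
    # zero-noise limit reproduces the true ordering exactly).
    clamp10 <- function(v) {
      if (model$pga_noise_sd > 0) v <- round(v)
      pmin(pmax(v, 0), 10)
    }
    pga_damage <- clamp10(damage10[obs_case] +
                            stats::rnorm(n_obs, sd = model$pga_noise_sd))
    pga_activity <- clamp10(latent_activity[obs_case] +
                              stats::rnorm(n_obs, sd = model$pga_noise_sd))
    out <- data.frame(
      case_id = case_ids[obs_case],
      rater_id = obs_rater,
      group_id = obs_group,
      disease = vapply(cases[obs_case], `[[`, character(1), "disease"),
      stringsAsFactors = FALSE
    )
    item_df <- as.data.frame(t(sc$item_points))
    names(item_df) <- lookup$item_ids
    out <- cbind(out, item_df)
    out$total <- as.numeric(sc$totals)
    out$pga_damage <- as.numeric(pga_damage)
    out$pga_activity <- as.numeric(pga_activity)
    rownames(out) <- NULL
    out
  })
}

#' Monte-Carlo ground truth for a simulated study
#'
#' Estimates the variance components implied by the case set and rater
#' model: the between-case variance of expected observed totals, the mean
#' within-case variance under rater noise, and the implied expected ICC.
#'
#' @param cases List of cases.
#' @param model A [rater_model()].
#' @param instr Instrument.
#' @param n_raters_mc Simulated raters per case for the Monte-Carlo
#'   estimate.
#' @param seed Seed.
#' @return List: `sigma2_between`, `sigma2_within`, `icc_expected`,
#'   `true_totals`.
#' @export
estimate_truth <- function(cases, model, instr = canonical_addi(),
                           n_raters_mc = 200L, seed = 11L) {
  lookup <- instrument_lookup(instr)
  n_items <- length(lookup$item_ids)
  case_ids <- vapply(cases, `[[`, character(1), "case_id")
  G0 <- vapply(cases, function(c) case_grades(instr, c, lookup),
               integer(n_items))
  applicable <- vapply(cases, function(case) {
    vapply(instr$items, item_applicable, logical(1),
           adult = case$age_years > 18, sex = case$sex)
  }, logical(n_items))
  true_totals <- score_grades(lookup, G0)$totals
  with_seed(seed, {
    obs_case <- rep(seq_along(cases), each = n_raters_mc)
    n_obs <- length(obs_case)
    G <- G0[, obs_case, drop = FALSE]
    A <- applicable[, obs_case, drop = FALSE]
    graded <- lookup$n_levels > 1L
    conf <- matrix(stats::runif(n_items * n_obs) < model$p_grade_confusion,
                   n_items) & G > 0L & graded
    shift <- matrix(sample(c(-1L, 1L), n_items * n_obs, replace = TRUE),
                    n_items)
    G[conf] <- pmin(pmax(G[conf] + shift[conf], 1L),
                    lookup$n_levels[row(G)[conf]])
    miss <- matrix(stats::runif(n_items * n_obs) < model$p_miss, n_items) &
      G > 0L
    false <- matrix(stats::runif(n_items * n_obs) < model$p_false, n_items) &
      G == 0L & A
    G[miss] <- 0L
    G[false] <- 1L
    totals <- score_grades(lookup, G)$totals
    per_case <- split(totals, obs_case)
    mu <- vapply(per_case, mean, numeric(1))
    s2w <- mean(vapply(per_case, stats::var, numeric(1)))
    s2b <- stats::var(mu)
    list(sigma2_between = s2b, sigma2_within = s2w,
         icc_expected = s2b / (s2b + s2w),
         true_totals = stats::setNames(as.numeric(true_totals), case_ids))
  })
}

#' Calibrate the rater noise to a target ICC
#'
#' Monotone bisection on a single noise-scale multiplier (applied jointly
#' to `p_miss`, `p_false`, `p_grade_confusion`) until the Monte-Carlo mean
#' estimated ICC over `n_rep` simulated studies is within `tol` of the
#' target.
#'
#' @param target_icc Target in (0, 1).
#' @param design A [study_design()].
#' @param instr Instrument.
#' @param base_model Rater model whose probabilities set the scale-1 noise
#'   mix.
#' @param tol Absolute tolerance on the achieved mean ICC (default 0.02).
#' @param max_iter Maximum bisection iterations (default 20).
#' @param n_rep Simulated studies per evaluation (default 20).
#' @param seed Seed for the calibration replicates.
#' @return List: `model` (calibrated), `scale`, `achieved_icc`,
#'   `target_icc`, `n_iter`.
#' @export
calibrate_noise_to_icc <- function(target_icc, design,
                                   instr = canonical_addi(),
                                   base_model = rater_model(),
                                   tol = 0.02, max_iter = 20L, n_rep = 20L,
                                   seed = 1L) {
  if (target_icc <= 0 || target_icc >= 1) {
    stop("target_icc must lie strictly between 0 and 1")
  }
  cases <- generate_cases(design, instr)
  allocation <- allocate_design(cases, design)
  seed0 <- derive_seed(seed, "calibration")
  mean_icc <- function(s) {
    model <- scale_rater_model(base_model, s)
    mean(vapply(seq_len(n_rep), function(r) {
      rt <- simulate_ratings(cases, allocation, model, instr,
                             seed = seed0 + 1000L * r + round(1e5 * s))
      estimate_icc_oneway(ratings_to_scores(rt))$icc
    }, numeric(1)))
  }
  lo <- 0
  f_lo <- 1       # zero noise reproduces the truth exactly
  hi <- 1
  f_hi <- mean_icc(hi)
  n_eval <- 1L
  while (f_hi > target_icc && hi < 64) {
    lo <- hi
    f_lo <- f_hi
    hi <- hi * 2
    f_hi <- mean_icc(hi)
    n_eval <- n_eval + 1L
  }
  if (f_hi > target_icc) {
    stop("calibration failed to bracket target ICC ", target_icc,
         ": even at noise scale ", hi, " the mean ICC is ", round(f_hi, 3))
  }
  achieved <- f_hi
  mid <- hi
  for (iter in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    f_mid <- mean_icc(mid)
    n_eval <- n_eval + 1L
    achieved <- f_mid
    if (abs(f_mid - target_icc) < tol) break
    if (f_mid > target_icc) lo <- mid else hi <- mid
  }
  list(model = scale_rater_model(base_model, mid), scale = mid,
       achieved_icc = achieved, target_icc = target_icc, n_iter = n_eval)
}

#' Simulate a complete validation study
#'
#' Convenience wrapper: generates cases, allocates groups and raters,
#' simulates the rating table, and computes ground truth.
#'
#' @param design A [study_design()].
#' @param model A [rater_model()].
#' @param instr Instrument.
#' @param truth Also compute Monte-Carlo variance components (slower).
#' @return List: `cases`, `allocation`, `ratings`, `true_totals`, and
#'   optionally `truth`.
#' @export
simulate_study <- function(design = study_design(), model = rater_model(),
                           instr = canonical_addi(), truth = FALSE) {
  cases <- generate_cases(design, instr)
  allocation <- allocate_design(cases, design)
  ratings <- simulate_ratings(cases, allocation, model, instr,
                              seed = derive_seed(design$seed, "ratings"))
  lookup <- instrument_lookup(instr)
  G0 <- vapply(cases, function(c) case_grades(instr, c, lookup),
               integer(length(lookup$item_ids)))
  out <- list(
    cases = cases, allocation = allocation, ratings = ratings,
    true_totals = stats::setNames(
      as.numeric(score_grades(lookup, G0)$totals),
      vapply(cases, `[[`, character(1), "case_id"))
  )
  if (truth) {
    out$truth <- estimate_truth(cases, model, instr,
                                seed = derive_seed(design$seed, "truth"))
  }
  out
}
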