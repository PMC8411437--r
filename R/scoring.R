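# ---------------------------------------------------------------------------
# Scoring engine: damage-eligibility filtering, glossary graders, item and
# case scoring with category caps.
#
# Damage is a persistent or irreversible change in structure or function
# present for at least 6 months, not attributable to ongoing disease
# activity, arising after onset of the autoinflammatory disease. Damage that
# later resolves is still scored.
# ---------------------------------------------------------------------------

#' Known measurement keys for measured-mode evidence
#'
#' Units: `gfr` in mL/min/1.73 m2; `pcr_mg_mmol` urine protein:creatinine in
#' mg/mmol (first morning void); `protein_g_24h` in g/24 h; `acr_mg_mmol`
#' urine albumin:creatinine in mg/mmol. The remaining keys are logical flags
#' except `visual_impairment` (`"none"`, `"impaired"`, `"legal_blindness"`).
#' @export
MEASUREMENT_KEYS <- c(
  "gfr", "dialysis_or_transplant",
  "pcr_mg_mmol", "protein_g_24h", "acr_mg_mmol",
  "height_below_p3", "velocity_below_p3", "centile_crossing",
  "adult_short_stature",
  "impairment_confirmed", "hearing_aid_required",
  "damage_documented", "visual_impairment",
  "low_bone_density", "fracture_present"
)

#' Construct one piece of clinical evidence for a damage item
#'
#' @param item_id Item identifier (slug).
#' @param mode `"asserted"` (a grade label is asserted directly, as raters
#'   did in the validation study) or `"measured"` (raw measurements are
#'   routed through the matching `grade_*` function).
#' @param asserted_grade For asserted mode: a level label of a graded item,
#'   or `"present"` for an ungraded item.
#' @param measurements For measured mode: named list using
#'   [MEASUREMENT_KEYS].
#' @param duration_months How long the change has been present.
#' @param resolved Damage later resolved (still scored if it lasted >= 6
#'   months).
#' @param attributed_to_active_disease Change attributed to ongoing disease
#'   activity (never scored as damage).
#' @param onset_after_aid_onset Change arose after onset of the
#'   autoinflammatory disease.
#' @return An `addi_evidence` list.
#' @export
evidence <- function(item_id, mode = c("asserted", "measured"),
                     asserted_grade = NULL, measurements = NULL,
                     duration_months = 12, resolved = FALSE,
                     attributed_to_active_disease = FALSE,
                     onset_after_aid_onset = TRUE) {
  mode <- match.arg(mode)
  if (mode == "asserted") {
    if (is.null(asserted_grade) || !is.null(measurements)) {
      stop("asserted evidence needs asserted_grade and no measurements")
    }
  } else {
    if (is.null(measurements) || !is.null(asserted_grade)) {
      stop("measured evidence needs measurements and no asserted_grade")
    }
    unknown <- setdiff(names(measurements), MEASUREMENT_KEYS)
    if (length(unknown)) {
      stop("unknown measurement key(s): ", paste(unknown, collapse = ", "))
    }
  }
  duration_months <- as.numeric(duration_months)
  if (is.na(duration_months) || duration_months < 0) {
    stop("duration_months must be >= 0")
  }
  structure(
    list(
      item_id = as.character(item_id), mode = mode,
      asserted_grade = asserted_grade, measurements = measurements,
      duration_months = duration_months, resolved = isTRUE(resolved),
      attributed_to_active_disease = isTRUE(attributed_to_active_disease),
      onset_after_aid_onset = isTRUE(onset_after_aid_onset)
    ),
    class = "addi_evidence"
  )
}

#' Construct a patient case record
#'
#' @param case_id Identifier.
#' @param disease One of `"FMF"`, `"CAPS"`, `"TRAPS"`, `"MKD"`.
#' @param age_years Age in years (paediatric: <= 18).
#' @param sex `"female"` or `"male"`.
#' @param evidence List of [evidence()] objects, at most one per item.
#' @return An `addi_case` list.
#' @export
case_record <- function(case_id, disease = c("FMF", "CAPS", "TRAPS", "MKD"),
                        age_years, sex = c("female", "male"),
                        evidence = list()) {
  disease <- match.arg(disease)
  sex <- match.arg(sex)
  ids <- vapply(evidence, `[[`, character(1), "item_id")
  if (anyDuplicated(ids)) {
    stop("case '", case_id, "': more than one evidence entry for item '",
         ids[duplicated(ids)][1L], "'")
  }
  structure(
    list(case_id = as.character(case_id), disease = disease,
         age_years = as.numeric(age_years), sex = sex,
         evidence = stats::setNames(evidence, ids)),
    class = "addi_case"
  )
}

#' Damage-eligibility rule
#'
#' Evidence scores as damage only when the change has been present for at
#' least 6 months, is not attributed to ongoing disease activity, and arose
#' after disease onset. Damage that lasted >= 6 months but later resolved
#' remains eligible.
#'
#' @param ev An [evidence()] object.
#' @return A list with `eligible` (logical) and `reason` (`NA` when
#'   eligible).
#' @export
is_damage_eligible <- function(ev) {
  if (ev$duration_months < 6) {
    return(list(eligible = FALSE, reason = "duration<6mo"))
  }
  if (ev$attributed_to_active_disease) {
    return(list(eligible = FALSE, reason = "attributed_to_active_disease"))
  }
  if (!ev$onset_after_aid_onset) {
    return(list(eligible = FALSE, reason = "onset_before_aid_onset"))
  }
  list(eligible = TRUE, reason = NA_character_)
}

# --- glossary graders ------------------------------------------------------

#' Grade renal insufficiency from GFR
#'
#' Severe: GFR < 15 mL/min/1.73 m2, dialysis or transplantation. Moderate:
#' 15 <= GFR < 60. GFR >= 60 is not renal insufficiency.
#'
#' @param gfr Glomerular filtration rate, mL/min/1.73 m2; may be `NA` when
#'   `dialysis_or_transplant` is set.
#' @param dialysis_or_transplant Logical.
#' @return `"severe"`, `"moderate"` or `NA_character_`.
#' @export
grade_renal_insufficiency <- function(gfr, dialysis_or_transplant = FALSE) {
  if (isTRUE(dialysis_or_transplant)) return("severe")
  if (is.null(gfr) || is.na(gfr)) stop("gfr required unless dialysis/transplant")
  if (gfr < 0) stop("gfr must be non-negative")
  if (gfr < 15) return("severe")
  if (gfr < 60) return("moderate")
  NA_character_
}

#' Grade proteinuria from urine measurements
#'
#' Present iff protein:creatinine ratio > 20 mg/mmol, or 24 h protein
#' excretion > 0.3 g, or albumin:creatinine ratio > 15 mg/mmol (all strict
#' inequalities).
#'
#' @param pcr_mg_mmol Urinary protein-to-creatinine ratio, mg/mmol.
#' @param protein_g_24h Daily protein excretion, g/24 h.
#' @param acr_mg_mmol Urine albumin-to-creatinine ratio, mg/mmol.
#' @return Logical.
#' @export
grade_proteinuria <- function(pcr_mg_mmol = NULL, protein_g_24h = NULL,
                              acr_mg_mmol = NULL) {
  vals <- list(pcr_mg_mmol, protein_g_24h, acr_mg_mmol)
  ok <- !vapply(vals, function(v) is.null(v) || is.na(v), logical(1))
  if (!any(ok)) stop("at least one urine measurement required")
  (ok[1L] && pcr_mg_mmol > 20) ||
    (ok[2L] && protein_g_24h > 0.3) ||
    (ok[3L] && acr_mg_mmol > 15)
}

#' Grade growth failure
#'
#' Paediatric: present iff at least two of the three chart features (height
#' below the 3rd percentile / -2 SD; 6-month growth velocity below the 3rd
#' percentile / -2 SD; crossing of at least two centile lines). Adults (> 18
#' years): pathological short stature.
#'
#' @param criteria Logical vector of length 3 (height, velocity, centile
#'   crossing).
#' @param adult Logical; use the adult rule.
#' @param adult_short_stature Logical; pathological short stature.
#' @return Logical.
#' @export
grade_growth_failure <- function(criteria = c(FALSE, FALSE, FALSE),
                                 adult = FALSE, adult_short_stature = FALSE) {
  if (isTRUE(adult)) return(isTRUE(adult_short_stature))
  criteria <- as.logical(criteria)
  if (length(criteria) != 3L || anyNA(criteria)) {
    stop("criteria must be three logical flags")
  }
  sum(criteria) >= 2L
}

#' Grade hearing loss
#'
#' Severe: hearing impairment requiring hearing aids or a cochlear implant.
#' Moderate: confirmed impairment without requirement of aids.
#'
#' @param impairment_confirmed Sensorineural impairment of the better ear
#'   confirmed by audiometry or an age-appropriate technique.
#' @param aid_or_implant Hearing aids or cochlear implant required.
#' @return `"severe"`, `"moderate"` or `NA_character_`.
#' @export
grade_hearing_loss <- function(impairment_confirmed = FALSE,
                               aid_or_implant = FALSE) {
  if (isTRUE(aid_or_implant) && !isTRUE(impairment_confirmed)) {
    stop("hearing aid/implant asserted without confirmed impairment")
  }
  if (isTRUE(aid_or_implant)) return("severe")
  if (isTRUE(impairment_confirmed)) return("moderate")
  NA_character_
}

#' Grade ocular involvement
#'
#' Mild: documented ocular damage of the better eye without visual
#' impairment. Moderate: with visual impairment. Severe: legal blindness.
#'
#' @param damage_documented Ocular damage documented by an ophthalmologist.
#' @param visual `"none"`, `"impaired"` or `"legal_blindness"`.
#' @return `"mild"`, `"moderate"`, `"severe"` or `NA_character_`.
#' @export
grade_ocular <- function(damage_documented = FALSE,
                         visual = c("none", "impaired", "legal_blindness")) {
  visual <- match.arg(visual)
  if (!isTRUE(damage_documented)) {
    if (visual != "none") {
      stop("visual impairment asserted without documented ocular damage")
    }
    return(NA_character_)
  }
  switch(visual, none = "mild", impaired = "moderate",
         legal_blindness = "severe")
}

#' Grade osteoporosis
#'
#' Requires both reduced bone mineral density and vertebral collapse and/or
#' pathological fracture; low bone density by itself is insufficient.
#'
#' @param low_density Reduced bone mineral density on imaging.
#' @param fracture_or_collapse Vertebral collapse or pathological fracture.
#' @return Logical.
#' @export
grade_osteoporosis <- function(low_density = FALSE,
                               fracture_or_collapse = FALSE) {
  isTRUE(low_density) && isTRUE(fracture_or_collapse)
}

# --- instrument lookup tables (shared fast path) ---------------------------

# Precomputed arrays for grade -> points scoring; used by score_case and by
# the rating simulator so both route through the same engine.
instrument_lookup <- function(instr) {
  item_ids <- names(instr$items)
  n_levels <- vapply(instr$items, function(it) {
    if (length(it$levels)) length(it$levels) else 1L
  }, integer(1))
  max_lv <- max(n_levels)
  pts <- matrix(0L, nrow = length(item_ids), ncol = max_lv,
                dimnames = list(item_ids, NULL))
  labels <- vector("list", length(item_ids))
  names(labels) <- item_ids
  for (i in seq_along(item_ids)) {
    it <- instr$items[[i]]
    if (length(it$levels)) {
      pts[i, seq_along(it$levels)] <-
        vapply(it$levels, `[[`, integer(1), "points")
      labels[[i]] <- vapply(it$levels, `[[`, character(1), "label")
    } else {
      pts[i, 1L] <- it$base_points
      labels[[i]] <- "present"
    }
  }
  cat_ids <- names(instr$categories)
  item_cat <- vapply(instr$items, `[[`, character(1), "category_id")
  list(
    item_ids = item_ids, cat_ids = cat_ids,
    n_levels = n_levels, points = pts, labels = labels,
    item_cat = factor(item_cat, levels = cat_ids),
    caps = vapply(instr$categories, `[[`, integer(1), "max_points")
  )
}

# Grade-vector scoring core. G: matrix n_items x n_obs of grade indices
# (0 = absent). Returns item points, capped category points and totals.
score_grades <- function(lookup, G) {
  n_items <- length(lookup$item_ids)
  stopifnot(nrow(G) == n_items)
  P <- matrix(lookup$points[cbind(rep(seq_len(n_items), ncol(G)),
                                  pmax(as.vector(G), 1L))],
              nrow = n_items)
  P[G == 0L] <- 0L
  dimnames(P) <- list(lookup$item_ids, colnames(G))
  C <- rowsum(P, lookup$item_cat)
  C <- pmin(C, matrix(lookup$caps, nrow = length(lookup$caps),
                      ncol = ncol(C)))
  dimnames(C) <- list(lookup$cat_ids, colnames(G))
  list(item_points = P, category_points = C, totals = colSums(C))
}

# Resolve one evidence entry to a grade index (0 = not scored) with an
# exclusion reason where applicable. Hard errors for applicability
# violations and unknown grade labels.
evidence_grade <- function(instr, ev, case) {
  it <- instr$items[[ev$item_id]]
  if (is.null(it)) stop("unknown item_id '", ev$item_id, "'")
  if (it$pediatric_only && case$age_years > 18) {
    stop("item '", ev$item_id, "' is paediatric-only; case '", case$case_id,
         "' is ", case$age_years, " years old")
  }
  if (it$applicable_sex == "female_relevant" && case$sex != "female") {
    stop("item '", ev$item_id, "' cannot be asserted for ", case$sex,
         " case '", case$case_id, "'")
  }
  el <- is_damage_eligible(ev)
  if (!el$eligible) return(list(grade = 0L, reason = el$reason))

  if (ev$mode == "asserted") {
    labels <- if (length(it$levels)) {
      vapply(it$levels, `[[`, character(1), "label")
    } else "present"
    g <- match(ev$asserted_grade, labels)
    if (is.na(g)) {
      stop("item '", ev$item_id, "': unknown asserted grade '",
           ev$asserted_grade, "' (expected one of: ",
           paste(labels, collapse = ", "), ")")
    }
    return(list(grade = g, reason = NA_character_))
  }

  m <- ev$measurements
  flag <- function(key) isTRUE(m[[key]])
  lab <- switch(
    ev$item_id,
    renal_insufficiency = grade_renal_insufficiency(
      m$gfr, flag("dialysis_or_transplant")),
    proteinuria = if (grade_proteinuria(m$pcr_mg_mmol, m$protein_g_24h,
                                        m$acr_mg_mmol)) "present"
                  else NA_character_,
    growth_failure = if (grade_growth_failure(
      c(flag("height_below_p3"), flag("velocity_below_p3"),
        flag("centile_crossing")),
      adult = case$age_years > 18,
      adult_short_stature = flag("adult_short_stature"))) "present"
      else NA_character_,
    hearing_loss = grade_hearing_loss(flag("impairment_confirmed"),
                                      flag("hearing_aid_required")),
    ocular_involvement = grade_ocular(
      flag("damage_documented"),
      if (is.null(m$visual_impairment)) "none" else m$visual_impairment),
    osteoporosis = if (grade_osteoporosis(flag("low_bone_density"),
                                          flag("fracture_present"))) "present"
                   else NA_character_,
    stop("item '", ev$item_id, "' has no measurement grader; ",
         "use asserted mode")
  )
  if (is.na(lab)) return(list(grade = 0L, reason = "measurement_below_threshold"))
  labels <- if (length(it$levels)) {
    vapply(it$levels, `[[`, character(1), "label")
  } else "present"
  list(grade = match(lab, labels), reason = NA_character_)
}

#' Score a single evidence entry
#'
#' Applies the damage-eligibility rule, then grades the evidence: asserted
#' mode takes the asserted level's points, measured mode routes raw
#' measurements through the matching `grade_*` function.
#'
#' @param instr An `addi_instrument`.
#' @param ev An [evidence()] object.
#' @param case The owning [case_record()] (supplies age and sex for
#'   applicability).
#' @return Integer points; attribute `"reason"` carries the exclusion reason
#'   when the result is 0 because the evidence was ineligible or below the
#'   measurement threshold.
#' @export
score_item <- function(instr, ev, case) {
  g <- evidence_grade(instr, ev, case)
  pts <- if (g$grade == 0L) 0L else {
    it <- instr$items[[ev$item_id]]
    if (length(it$levels)) it$levels[[g$grade]]$points else it$base_points
  }
  structure(pts, reason = g$reason)
}

#' Score a complete case
#'
#' Scores every evidenced item, applies the category caps and sums the
#' capped category subtotals into the total score. Items without evidence
#' score 0 and are listed in `exclusions` as `"not_assessed"` (missing is
#' not the same as absent, but both contribute 0 points).
#'
#' @param instr An `addi_instrument`.
#' @param case An [case_record()].
#' @return An `addi_scorecard`: `case_id`, `item_points` (named integer
#'   vector over all instrument items), `category_points` (post-cap),
#'   `total`, and `exclusions` (data frame of item_id/reason pairs).
#' @export
score_case <- function(instr, case) {
  lookup <- instrument_lookup(instr)
  grades <- stats::setNames(integer(length(lookup$item_ids)),
                            lookup$item_ids)
  reasons <- character(0)
  reason_items <- character(0)
  for (ev in case$evidence) {
    g <- tryCatch(evidence_grade(instr, ev, case), error = function(e) {
      stop("case '", case$case_id, "': ", conditionMessage(e), call. = FALSE)
    })
    grades[ev$item_id] <- g$grade
    if (!is.na(g$reason)) {
      reason_items <- c(reason_items, ev$item_id)
      reasons <- c(reasons, g$reason)
    }
  }
  missing_items <- setdiff(lookup$item_ids, names(case$evidence))
  sc <- score_grades(lookup, matrix(grades, ncol = 1L,
                                    dimnames = list(names(grades), NULL)))
  structure(
    list(
      case_id = case$case_id,
      item_points = stats::setNames(as.integer(sc$item_points[, 1L]),
                                    lookup$item_ids),
      category_points = stats::setNames(as.integer(sc$category_points[, 1L]),
                                        lookup$cat_ids),
      total = as.integer(sc$totals[[1L]]),
      exclusions = data.frame(
        item_id = c(reason_items, missing_items),
        reason = c(reasons, rep("not_assessed", length(missing_items))),
        stringsAsFactors = FALSE
      )
    ),
    class = "addi_scorecard"
  )
}

#' @export
print.addi_scorecard <- function(x, ...) {
  cat(sprintf("<scorecard %s> total %d\n", x$case_id, x$total))
  nz <- x$category_points[x$category_points > 0]
  if (length(nz)) {
    cat(paste(sprintf("  %s: %d", names(nz), nz), collapse = "\n"), "\n")
  }
  invisible(x)
}

# --- case / scorecard I/O --------------------------------------------------

case_to_plain <- function(case) {
  list(
    case_id = case$case_id, disease = case$disease,
    age_years = case$age_years, sex = case$sex,
    evidence = lapply(unname(case$evidence), function(ev) {
      out <- list(
        item_id = ev$item_id, mode = ev$mode,
        duration_months = ev$duration_months, resolved = ev$resolved,
        attributed_to_active_disease = ev$attributed_to_active_disease,
        onset_after_aid_onset = ev$onset_after_aid_onset
      )
      if (ev$mode == "asserted") out$asserted_grade <- ev$asserted_grade
      else out$measurements <- ev$measurements
      out
    })
  )
}

plain_to_case <- function(x) {
  evs <- lapply(x$evidence, function(e) {
    evidence(
      e$item_id, e$mode, asserted_grade = e$asserted_grade,
      measurements = e$measurements,
      duration_months = e$duration_months,
      resolved = isTRUE(e$resolved),
      attributed_to_active_disease = isTRUE(e$attributed_to_active_disease),
      onset_after_aid_onset = !isFALSE(e$onset_after_aid_onset)
    )
  })
  case_record(x$case_id, x$disease, x$age_years, x$sex, evs)
}

#' Write / read case records as JSON
#'
#' @param cases List of [case_record()] objects.
#' @param path File path.
#' @return `write_cases_json` returns `path` invisibly; `read_cases_json`
#'   returns a list of cases.
#' @export
write_cases_json <- function(cases, path) {
  txt <- jsonlite::toJSON(lapply(cases, case_to_plain), auto_unbox = TRUE,
                          pretty = 2, digits = NA)
  writeLines(txt, path)
  invisible(path)
}

#' @rdname write_cases_json
#' @export
read_cases_json <- function(path) {
  lapply(jsonlite::fromJSON(path, simplifyVector = FALSE), plain_to_case)
}

#' Write / read case records as flat CSV
#'
#' One row per case-item evidence entry; measurement columns follow
#' [MEASUREMENT_KEYS]. Cases without any evidence get a single row with an
#' empty `item_id`.
#'
#' @param cases List of [case_record()] objects.
#' @param path File path.
#' @return `write_cases_csv` returns `path` invisibly; `read_cases_csv`
#'   returns a list of cases.
#' @export
write_cases_csv <- function(cases, path) {
  rows <- list()
  for (case in cases) {
    base <- data.frame(
      case_id = case$case_id, disease = case$disease,
      age_years = case$age_years, sex = case$sex,
      stringsAsFactors = FALSE
    )
    if (!length(case$evidence)) {
      r <- base
      r$item_id <- ""
      r$mode <- ""
      r$asserted_grade <- ""
      for (k in MEASUREMENT_KEYS) r[[k]] <- NA
      r$duration_months <- NA_real_
      r$resolved <- NA
      r$attributed_to_active_disease <- NA
      r$onset_after_aid_onset <- NA
      rows[[length(rows) + 1L]] <- r
      next
    }
    for (ev in case$evidence) {
      r <- base
      r$item_id <- ev$item_id
      r$mode <- ev$mode
      r$asserted_grade <- if (is.null(ev$asserted_grade)) ""
                          else ev$asserted_grade
      for (k in MEASUREMENT_KEYS) {
        v <- ev$measurements[[k]]
        r[[k]] <- if (is.null(v)) NA else v
      }
      r$duration_months <- ev$duration_months
      r$resolved <- ev$resolved
      r$attributed_to_active_disease <- ev$attributed_to_active_disease
      r$onset_after_aid_onset <- ev$onset_after_aid_onset
      rows[[length(rows) + 1L]] <- r
    }
  }
  df <- do.call(rbind, rows)
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_cases_csv
#' @export
read_cases_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("case_id", "disease", "age_years", "sex", "item_id", "mode")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("case CSV missing column(s): ", paste(miss, collapse = ", "))
  }
  logical_keys <- setdiff(MEASUREMENT_KEYS,
                          c("gfr", "pcr_mg_mmol", "protein_g_24h",
                            "acr_mg_mmol", "visual_impairment"))
  lapply(split(df, factor(df$case_id, levels = unique(df$case_id))),
         function(sub) {
    evs <- list()
    for (i in seq_len(nrow(sub))) {
      row <- sub[i, ]
      if (is.na(row$item_id) || !nzchar(row$item_id)) next
      ev <- tryCatch({
        if (row$mode == "asserted") {
          evidence(row$item_id, "asserted",
                   asserted_grade = row$asserted_grade,
                   duration_months = row$duration_months,
                   resolved = isTRUE(row$resolved),
                   attributed_to_active_disease =
                     isTRUE(row$attributed_to_active_disease),
                   onset_after_aid_onset = !isFALSE(row$onset_after_aid_onset))
        } else {
          m <- list()
          for (k in intersect(MEASUREMENT_KEYS, names(row))) {
            v <- row[[k]]
            if (is.na(v) || identical(v, "")) next
            m[[k]] <- if (k %in% logical_keys) as.logical(v) else v
          }
          evidence(row$item_id, "measured", measurements = m,
                   duration_months = row$duration_months,
                   resolved = isTRUE(row$resolved),
                   attributed_to_active_disease =
                     isTRUE(row$attributed_to_active_disease),
                   onset_after_aid_onset = !isFALSE(row$onset_after_aid_onset))
        }
      }, error = function(e) {
        stop("case CSV row for case '", row$case_id, "', item '",
             row$item_id, "': ", conditionMessage(e), call. = FALSE)
      })
      evs[[length(evs) + 1L]] <- ev
    }
    case_record(sub$case_id[1L], sub$disease[1L], sub$age_years[1L],
                sub$sex[1L], evs)
  }) |> unname()
}

#' Convert scorecards to a wide data frame
#'
#' One row per case: `case_id`, 18 item columns, 8 category columns,
#' `total`.
#'
#' @param scorecards List of `addi_scorecard` objects.
#' @return A data frame.
#' @export
scorecards_to_df <- function(scorecards) {
  do.call(rbind, lapply(scorecards, function(sc) {
    cbind(
      data.frame(case_id = sc$case_id, stringsAsFactors = FALSE),
      as.data.frame(as.list(sc$item_points)),
      as.data.frame(as.list(stats::setNames(
        sc$category_points, paste0("cat_", names(sc$category_points))))),
      data.frame(total = sc$total)
    )
  }))
}

#' Write scorecards to CSV and JSON
#'
#' @param scorecards List of `addi_scorecard` objects.
#' @param csv_path,json_path Output paths (`NULL` to skip either).
#' @return Invisibly, the wide data frame written to CSV.
#' @export
write_scorecards <- function(scorecards, csv_path = NULL, json_path = NULL) {
  df <- scorecards_to_df(scorecards)
  if (!is.null(csv_path)) {
    utils::write.csv(df, csv_path, row.names = FALSE)
  }
  if (!is.null(json_path)) {
    plain <- lapply(scorecards, function(sc) {
      list(case_id = sc$case_id, item_points = as.list(sc$item_points),
           category_points = as.list(sc$category_points), total = sc$total,
           exclusions = sc$exclusions)
    })
    writeLines(jsonlite::toJSON(plain, auto_unbox = TRUE, pretty = 2,
                                digits = NA), json_path)
  }
  invisible(df)
}
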