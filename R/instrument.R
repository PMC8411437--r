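#' @keywords internal
"_PACKAGE"

# ---------------------------------------------------------------------------
# Instrument definition: the damage index as data.
#
# An instrument is a list of capped categories, each owning items; items are
# either ungraded (fixed base points when present) or graded (ordered severity
# levels with strictly increasing points). The canonical instrument shipped
# with the package is the definitive ADDI: 8 categories, 18 items, maximum
# total 27.
# ---------------------------------------------------------------------------

#' Construct a grading level
#'
#' @param label Level label, e.g. `"moderate"`.
#' @param points Points awarded at this level (integer >= 1).
#' @param criterion Human-readable grading criterion (documentation only,
#'   never parsed).
#' @return A `grading_level` list.
#' @export
grading_level <- function(label, points, criterion = "") {
  stopifnot(is.character(label), length(label) == 1L, nzchar(label))
  points <- as.integer(points)
  if (is.na(points) || points < 1L) {
    stop("grading level '", label, "': points must be an integer >= 1")
  }
  structure(
    list(label = label, points = points, criterion = as.character(criterion)),
    class = "grading_level"
  )
}

#' Construct an item definition
#'
#' Items are ungraded (scored `base_points` when present) or graded (scored
#' according to an ordered list of severity levels).
#'
#' @param item_id Stable identifier (lowercase snake-case slug).
#' @param name Display name.
#' @param category_id Identifier of the owning category.
#' @param base_points Points for an ungraded item (ignored when `levels`
#'   given).
#' @param levels List of [grading_level()] objects, ordered by increasing
#'   severity; empty for ungraded items.
#' @param pediatric_only Item can only be asserted for paediatric cases.
#' @param applicable_sex `"any"` or `"female_relevant"`.
#' @param criterion Glossary definition text (documentation only).
#' @return An `item_definition` list.
#' @export
item_definition <- function(item_id, name, category_id, base_points = 0L,
                            levels = list(), pediatric_only = FALSE,
                            applicable_sex = c("any", "female_relevant"),
                            criterion = "") {
  applicable_sex <- match.arg(applicable_sex)
  base_points <- as.integer(base_points)
  if (length(levels)) {
    if (length(levels) < 2L) {
      stop("item '", item_id, "': graded items need >= 2 levels")
    }
    pts <- vapply(levels, `[[`, integer(1), "points")
    if (any(diff(pts) <= 0L)) {
      stop("item '", item_id, "': level points must be strictly increasing")
    }
    labs <- vapply(levels, `[[`, character(1), "label")
    if (anyDuplicated(labs)) {
      stop("item '", item_id, "': level labels must be unique")
    }
    base_points <- 0L
  } else if (is.na(base_points) || base_points < 1L) {
    stop("item '", item_id, "': ungraded items need base_points >= 1")
  }
  structure(
    list(
      item_id = as.character(item_id), name = as.character(name),
      category_id = as.character(category_id), base_points = base_points,
      levels = levels, pediatric_only = isTRUE(pediatric_only),
      applicable_sex = applicable_sex, criterion = as.character(criterion)
    ),
    class = "item_definition"
  )
}

#' Construct a category definition
#'
#' @param category_id Stable identifier.
#' @param name Display name.
#' @param max_points Cap applied to the summed item points of this category.
#' @param item_ids Identifiers of member items.
#' @return A `category_definition` list.
#' @export
category_definition <- function(category_id, name, max_points, item_ids) {
  max_points <- as.integer(max_points)
  if (is.na(max_points) || max_points < 1L) {
    stop("category '", category_id, "': max_points must be a positive integer")
  }
  structure(
    list(
      category_id = as.character(category_id), name = as.character(name),
      max_points = max_points, item_ids = as.character(item_ids)
    ),
    class = "category_definition"
  )
}

#' Maximum attainable points of a single item
#' @param item An [item_definition()].
#' @return Integer.
#' @export
item_max_points <- function(item) {
  if (length(item$levels)) {
    item$levels[[length(item$levels)]]$points
  } else {
    item$base_points
  }
}

#' Assemble and validate an instrument definition
#'
#' @param name Instrument name.
#' @param version Version string.
#' @param categories List of [category_definition()] objects.
#' @param items List of [item_definition()] objects.
#' @return An `addi_instrument` object. `max_total` (sum of category caps) is
#'   derived, never stored independently.
#' @export
instrument_definition <- function(name, version, categories, items) {
  instr <- structure(
    list(
      name = as.character(name), version = as.character(version),
      categories = stats::setNames(
        categories, vapply(categories, `[[`, character(1), "category_id")
      ),
      items = stats::setNames(
        items, vapply(items, `[[`, character(1), "item_id")
      )
    ),
    class = "addi_instrument"
  )
  validate_instrument(instr)
  instr
}

#' Validate instrument invariants
#'
#' Checks identifier uniqueness, item/category membership consistency, level
#' monotonicity, and that no item can exceed (alone) or undercut its
#' category's cap.
#'
#' @param instr An `addi_instrument`.
#' @return The instrument, invisibly; stops with a message naming the
#'   offending field otherwise.
#' @export
validate_instrument <- function(instr) {
  if (!inherits(instr, "addi_instrument")) stop("not an addi_instrument")
  item_ids <- names(instr$items)
  cat_ids <- names(instr$categories)
  if (anyDuplicated(item_ids)) {
    stop("duplicate item_id: ", item_ids[duplicated(item_ids)][1L])
  }
  if (anyDuplicated(cat_ids)) {
    stop("duplicate category_id: ", cat_ids[duplicated(cat_ids)][1L])
  }
  claimed <- unlist(lapply(instr$categories, `[[`, "item_ids"))
  if (anyDuplicated(claimed)) {
    stop("item claimed by more than one category: ",
         claimed[duplicated(claimed)][1L])
  }
  if (!setequal(claimed, item_ids)) {
    orphan <- c(setdiff(item_ids, claimed), setdiff(claimed, item_ids))
    stop("item/category membership mismatch: ", paste(orphan, collapse = ", "))
  }
  for (it in instr$items) {
    if (!it$category_id %in% cat_ids) {
      stop("item '", it$item_id, "': unknown category_id '",
           it$category_id, "'")
    }
    cap <- instr$categories[[it$category_id]]$max_points
    if (item_max_points(it) > cap) {
      stop("item '", it$item_id, "': max points ", item_max_points(it),
           " exceed category cap ", cap)
    }
  }
  for (ca in instr$categories) {
    cat_sum <- sum(vapply(
      instr$items[ca$item_ids], item_max_points, integer(1)
    ))
    if (ca$max_points > cat_sum) {
      stop("category '", ca$category_id, "': cap ", ca$max_points,
           " exceeds member item sum ", cat_sum)
    }
  }
  invisible(instr)
}

#' Maximum attainable total score of an instrument
#'
#' The sum of the category caps (27 for the canonical ADDI).
#'
#' @param instr An `addi_instrument`.
#' @return Integer.
#' @export
instrument_max_total <- function(instr) {
  sum(vapply(instr$categories, `[[`, integer(1), "max_points"))
}

#' The canonical definitive ADDI
#'
#' Builds the definitive Autoinflammatory Disease Damage Index: eight capped
#' categories (reproductive 2, renal/amyloidosis 6, developmental 3, serosal
#' 1, neurological 6, ears 2, ocular 3, musculoskeletal 4) holding 18 damage
#' items, maximum total 27 points. Grading criteria are stored verbatim as
#' documentation strings.
#'
#' @return An `addi_instrument`.
#' @export
#' @examples
#' instr <- canonical_addi()
#' instrument_max_total(instr) # 27
canonical_addi <- function() {
  items <- list(
    item_definition(
      "sub_infertility", "Sub/infertility", "reproductive", base_points = 2L,
      criterion = paste(
        "A disease of the reproductive system defined by the failure to",
        "achieve a clinical pregnancy after 12 months or more of regular",
        "unprotected sexual intercourse, not due to known disorders in the",
        "unaffected partner."
      )
    ),
    item_definition(
      "amenorrhea", "Amenorrhea", "reproductive", base_points = 1L,
      applicable_sex = "female_relevant",
      criterion = paste(
        "Primary amenorrhea: absence of menarche at the age of 16 years or",
        "absence of menarche 5 years after thelarche. Secondary amenorrhea:",
        "absence of the menses for six consecutive months or more in a woman",
        "who previously had menstrual cycles."
      )
    ),
    item_definition(
      "amyloidosis", "Amyloidosis", "renal_amyloidosis",
      levels = list(
        grading_level("limited", 2L, "Amyloidosis affecting one organ."),
        grading_level("extensive", 3L,
                      "Amyloidosis affecting more than one organ.")
      ),
      criterion = paste(
        "Symptomatic amyloidosis confirmed by examination of tissue sections",
        "by Congo red dye or serum amyloid P component (SAP) scintigraphy."
      )
    ),
    item_definition(
      "proteinuria", "Proteinuria", "renal_amyloidosis", base_points = 1L,
      criterion = paste(
        "Persistent urinary protein-to-creatinine ratio of >20 mg/mmol in",
        "the first morning void; and/or a daily protein excretion of",
        ">0.3 g/24 hours, or urine albumin-to-creatinine ratio of",
        ">15 mg/mmol."
      )
    ),
    item_definition(
      "renal_insufficiency", "Renal insufficiency", "renal_amyloidosis",
      levels = list(
        grading_level(
          "moderate", 2L,
          "Glomerular filtration rate (GFR) between 15 and 60 mL/min/1.73 m2."
        ),
        grading_level(
          "severe", 3L,
          "GFR <15 mL/min/1.73 m2, dialysis or transplantation."
        )
      ),
      criterion = paste(
        "Glomerular filtration rate (GFR) of <60 mL/min/1.73 m2, dialysis",
        "or transplantation."
      )
    ),
    item_definition(
      "growth_failure", "Growth failure", "developmental", base_points = 2L,
      criterion = paste(
        "Presence of at least two of the three features: height lower than",
        "the third percentile or -2 SD for age; growth velocity over 6",
        "months lower than the third percentile or -2 SD for age; crossing",
        "at least two centiles on the growth chart. For patients older than",
        "18 years: pathological short stature."
      )
    ),
    item_definition(
      "puberty_delay", "Puberty delay", "developmental", base_points = 1L,
      criterion = paste(
        "A Tanner stage below -2 SDs for age or below the third percentile",
        "for age, or any Tanner stage after pharmacological induction of",
        "puberty."
      )
    ),
    item_definition(
      "serosal_scarring", "Serosal scarring", "serosal", base_points = 1L,
      criterion = paste(
        "Symptomatic adhesions or fibrosis affecting pericardium, pleura,",
        "peritoneum and/or retroperitoneum, supported by imaging techniques,",
        "endoscopy or surgery."
      )
    ),
    item_definition(
      "developmental_delay", "Developmental delay", "neurological",
      base_points = 2L, pediatric_only = TRUE,
      criterion = paste(
        "Failure to reach age-appropriate developmental milestones,",
        "including language/speech, motor, social/emotional and cognitive",
        "milestones. Only for paediatric patients."
      )
    ),
    item_definition(
      "cognitive_impairment", "Cognitive impairment", "neurological",
      base_points = 3L,
      criterion = paste(
        "Requirement of special education because of cognitive impairment",
        "or IQ below 70 as defined by neuropsychological assessment."
      )
    ),
    item_definition(
      "elevated_intracranial_pressure", "Elevated intracranial pressure",
      "neurological", base_points = 2L,
      criterion = paste(
        "Signs and/or symptoms of elevated intracranial pressure supported",
        "by appropriate techniques such as funduscopy, neuroimaging or",
        "lumbar CSF pressure measurement."
      )
    ),
    item_definition(
      "cns_involvement", "Central nervous system involvement", "neurological",
      base_points = 3L,
      criterion = paste(
        "Focal deficits (gross and/or fine sensorimotor), diffuse deficits",
        "(eg, memory, behaviour), seizures and spinal cord symptoms.",
        "Neuropsychiatric disorders unrelated to the disease should not be",
        "scored."
      )
    ),
    item_definition(
      "hearing_loss", "Hearing loss", "ears",
      levels = list(
        grading_level(
          "moderate", 1L,
          "Hearing impairment without requirement of hearing aids or a cochlear implant."
        ),
        grading_level(
          "severe", 2L,
          "Hearing impairment requiring hearing aids or a cochlear implant."
        )
      ),
      criterion = paste(
        "Sensorineural hearing impairment of better ear, confirmed by",
        "audiometry or another age-appropriate technique, or requirement of",
        "hearing aids or a cochlear implant."
      )
    ),
    item_definition(
      "ocular_involvement", "Ocular involvement", "ocular",
      levels = list(
        grading_level("mild", 1L,
                      "Ocular damage without visual impairment."),
        grading_level("moderate", 2L, "Ocular damage with visual impairment."),
        grading_level("severe", 3L, "Legal blindness.")
      ),
      criterion = paste(
        "Ocular damage (eg, optic nerve atrophy, elevated intraocular",
        "pressure or cataract) of better eye, documented by an",
        "ophthalmologist, with or without visual impairment."
      )
    ),
    item_definition(
      "joint_restriction", "Joint restriction", "musculoskeletal",
      base_points = 2L,
      criterion = paste(
        "Fixed limitation in the normal range of motion of joints affecting",
        "function, with or without destructive arthropathy or avascular",
        "necrosis."
      )
    ),
    item_definition(
      "bone_deformity", "Bone deformity", "musculoskeletal", base_points = 2L,
      criterion = paste(
        "Bone deformation or overgrowth on clinical examination and/or",
        "imaging studies."
      )
    ),
    item_definition(
      "osteoporosis", "Osteoporosis", "musculoskeletal", base_points = 1L,
      criterion = paste(
        "Reduced bone mineral density with vertebral collapse and/or",
        "pathological fractures confirmed with imaging. Requires both",
        "evidence of decreased bone density and fracture; 'low bone",
        "density' by itself is insufficient."
      )
    ),
    item_definition(
      "musculoskeletal_pain", "Musculoskeletal pain", "musculoskeletal",
      base_points = 1L,
      criterion = paste(
        "Non-inflammatory musculoskeletal pain impairing activities of",
        "daily living."
      )
    )
  )
  categories <- list(
    category_definition("reproductive", "Reproductive", 2L,
                        c("sub_infertility", "amenorrhea")),
    category_definition("renal_amyloidosis", "Renal/amyloidosis", 6L,
                        c("amyloidosis", "proteinuria", "renal_insufficiency")),
    category_definition("developmental", "Developmental", 3L,
                        c("growth_failure", "puberty_delay")),
    category_definition("serosal", "Serosal", 1L, "serosal_scarring"),
    category_definition("neurological", "Neurological", 6L,
                        c("developmental_delay", "cognitive_impairment",
                          "elevated_intracranial_pressure",
                          "cns_involvement")),
    category_definition("ears", "Ears", 2L, "hearing_loss"),
    category_definition("ocular", "Ocular", 3L, "ocular_involvement"),
    category_definition("musculoskeletal", "Musculoskeletal", 4L,
                        c("joint_restriction", "bone_deformity",
                          "osteoporosis", "musculoskeletal_pain"))
  )
  instrument_definition("ADDI", "1.0", categories, items)
}

# --- serialization ---------------------------------------------------------

instrument_to_plain <- function(instr) {
  list(
    name = instr$name,
    version = instr$version,
    max_total = instrument_max_total(instr),
    categories = lapply(unname(instr$categories), function(ca) {
      list(category_id = ca$category_id, name = ca$name,
           max_points = ca$max_points, item_ids = as.list(ca$item_ids))
    }),
    items = lapply(unname(instr$items), function(it) {
      list(
        item_id = it$item_id, name = it$name, category_id = it$category_id,
        base_points = it$base_points,
        levels = lapply(it$levels, function(lv) {
          list(label = lv$label, points = lv$points, criterion = lv$criterion)
        }),
        pediatric_only = it$pediatric_only,
        applicable_sex = it$applicable_sex,
        criterion = it$criterion
      )
    })
  )
}

plain_to_instrument <- function(x) {
  need <- c("name", "version", "categories", "items")
  miss <- setdiff(need, names(x))
  if (length(miss)) {
    stop("instrument document missing field(s): ", paste(miss, collapse = ", "))
  }
  as_flag <- function(v, field) {
    if (is.null(v)) return(FALSE)
    if (!is.logical(v) || length(v) != 1L || is.na(v)) {
      stop("field '", field, "' must be a logical flag")
    }
    v
  }
  items <- lapply(x$items, function(it) {
    for (f in c("item_id", "name", "category_id")) {
      if (is.null(it[[f]])) stop("item entry missing field '", f, "'")
    }
    levels <- lapply(it$levels, function(lv) {
      if (is.null(lv$label) || is.null(lv$points)) {
        stop("grading level missing field 'label' or 'points'")
      }
      grading_level(lv$label, lv$points,
                    if (is.null(lv$criterion)) "" else lv$criterion)
    })
    item_definition(
      it$item_id, it$name, it$category_id,
      base_points = if (is.null(it$base_points)) 0L else it$base_points,
      levels = levels,
      pediatric_only = as_flag(it$pediatric_only, "pediatric_only"),
      applicable_sex = if (is.null(it$applicable_sex)) "any"
                       else it$applicable_sex,
      criterion = if (is.null(it$criterion)) "" else it$criterion
    )
  })
  categories <- lapply(x$categories, function(ca) {
    for (f in c("category_id", "name", "max_points", "item_ids")) {
      if (is.null(ca[[f]])) stop("category entry missing field '", f, "'")
    }
    category_definition(ca$category_id, ca$name, ca$max_points,
                        unlist(ca$item_ids))
  })
  instr <- instrument_definition(x$name, x$version, categories, items)
  if (!is.null(x$max_total) &&
      as.integer(x$max_total) != instrument_max_total(instr)) {
    stop("field 'max_total' (", x$max_total,
         ") disagrees with the sum of category caps (",
         instrument_max_total(instr), ")")
  }
  instr
}

#' Save an instrument definition to YAML or JSON
#'
#' Serialization is deterministic: fixed field order, fixed formatting, so
#' saving the same instrument twice yields byte-identical output.
#'
#' @param instr An `addi_instrument`.
#' @param path Output path; format inferred from extension (`.yaml`/`.yml` or
#'   `.json`) unless `format` is given. If `NULL`, the serialized text is
#'   returned instead of written.
#' @param format `"yaml"` or `"json"`.
#' @return The serialized text, invisibly when written to `path`.
#' @export
save_instrument <- function(instr, path = NULL, format = NULL) {
  validate_instrument(instr)
  if (is.null(format)) {
    format <- if (!is.null(path) && grepl("\\.json$", path, ignore.case = TRUE))
      "json" else "yaml"
  }
  format <- match.arg(format, c("yaml", "json"))
  plain <- instrument_to_plain(instr)
  txt <- if (format == "json") {
    paste0(jsonlite::toJSON(plain, auto_unbox = TRUE, pretty = 2,
                            digits = NA), "\n")
  } else {
    yaml::as.yaml(plain, indent = 2)
  }
  if (is.null(path)) return(txt)
  writeLines(txt, path, sep = "")
  invisible(txt)
}

#' Load an instrument definition from YAML or JSON
#'
#' All instrument invariants are validated on load; `load_instrument` is the
#' exact inverse of [save_instrument()].
#'
#' @param source Path to a `.yaml`/`.yml`/`.json` file, or a single string of
#'   serialized text.
#' @return An `addi_instrument`.
#' @export
load_instrument <- function(source) {
  is_path <- length(source) == 1L && !grepl("\n", source) &&
    file.exists(source)
  txt <- if (is_path) paste(readLines(source, warn = FALSE), collapse = "\n")
         else paste(source, collapse = "\n")
  x <- if (grepl("^\\s*\\{", txt)) {
    jsonlite::fromJSON(txt, simplifyVector = FALSE)
  } else {
    yaml::yaml.load(txt)
  }
  plain_to_instrument(x)
}

#' Path of the bundled canonical instrument file
#' @return Path to `addi_v1.yaml` inside the installed package.
#' @export
addi_instrument_file <- function() {
  system.file("extdata", "addi_v1.yaml", package = "addiscore",
              mustWork = TRUE)
}

#' @export
print.addi_instrument <- function(x, ...) {
  cat(sprintf("<%s v%s> %d categories, %d items, max total %d\n",
              x$name, x$version, length(x$categories), length(x$items),
              instrument_max_total(x)))
  for (ca in x$categories) {
    cat(sprintf("  %-18s (max %d): %s\n", ca$category_id, ca$max_points,
                paste(ca$item_ids, collapse = ", ")))
  }
  invisible(x)
}
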