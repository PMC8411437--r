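# ---------------------------------------------------------------------------
# Validation pipeline: from a long-format rating table to the full
# reliability report (overall / per-disease / per-category / per-item ICCs,
# PGA reliability, construct validity on per-case means, interitem
# redundancy).
# ---------------------------------------------------------------------------

#' Validation run configuration
#'
#' @param min_raters Minimum responding raters per group; groups below this
#'   are dropped (study rule: at least three doctors per group). Also the
#'   minimum raters per case for per-case means.
#' @param ci_alpha Two-sided CI alpha for ICCs (default 0.05).
#' @param redundancy_threshold Interitem correlation above which a pair is
#'   flagged (default 0.7).
#' @param spearman_method `"fisher"` or `"bootstrap"`.
#' @param spearman_seed Seed for the bootstrap CI.
#' @param pga_reliability_gate Minimum PGA ICC considered sufficiently
#'   reliable to anchor construct validity (default 0.6; the reference
#'   study states no numeric gate).
#' @return A `validation_config` list.
#' @export
validation_config <- function(min_raters = 3L, ci_alpha = 0.05,
                              redundancy_threshold = 0.7,
                              spearman_method = "fisher",
                              spearman_seed = 1L,
                              pga_reliability_gate = 0.6) {
  structure(
    list(min_raters = as.integer(min_raters), ci_alpha = ci_alpha,
         redundancy_threshold = redundancy_threshold,
         spearman_method = spearman_method,
         spearman_seed = as.integer(spearman_seed),
         pga_reliability_gate = pga_reliability_gate),
    class = "validation_config"
  )
}

# ICC wrapper that converts degenerate-variance errors into a
# not-estimable cell instead of aborting the run.
safe_icc <- function(scores, alpha_level) {
  tryCatch(
    suppressWarnings(estimate_icc_oneway(scores, alpha_level)),
    error = function(e) {
      structure(list(icc = NA_real_, ci_lower = NA_real_,
                     ci_upper = NA_real_, reason = conditionMessage(e)),
                class = c("icc_not_estimable", "icc_result"))
    }
  )
}

# Per-row capped category scores from the item columns of a rating table.
ratings_category_scores <- function(ratings, lookup) {
  G <- t(as.matrix(ratings[, lookup$item_ids]))
  C <- rowsum(G, lookup$item_cat)
  C <- pmin(C, matrix(lookup$caps, nrow = length(lookup$caps), ncol = ncol(C)))
  as.data.frame(t(C))
}

# Per-case mean item score matrix (cases x items), min_raters filter.
ratings_item_means <- function(ratings, lookup, min_raters = 3L) {
  counts <- table(ratings$case_id)
  keep <- names(counts)[counts >= min_raters]
  sub <- ratings[ratings$case_id %in% keep, ]
  f <- factor(sub$case_id, levels = sort(unique(sub$case_id)))
  m <- vapply(lookup$item_ids, function(id) {
    vapply(split(sub[[id]], f), mean, numeric(1))
  }, numeric(nlevels(f)))
  if (!is.matrix(m)) m <- matrix(m, nrow = 1L,
                                 dimnames = list(levels(f), lookup$item_ids))
  m
}

#' Run the full validation analysis
#'
#' Drops under-responded groups, then computes the complete report: ICC of
#' the total score overall and per disease, per-category and per-item ICCs,
#' PGA-damage and PGA-activity ICCs (with a reliability gate), construct
#' validity via Spearman correlations of per-case means, and interitem
#' redundancy via Cronbach's alpha overall and per category. Degenerate
#' cells (e.g. an item never scored) are reported as not-estimable with a
#' reason; the run continues.
#'
#' @param ratings Rating table (validated against `instr`).
#' @param instr Instrument (default [canonical_addi()]).
#' @param config A [validation_config()].
#' @return A `reliability_report` list.
#' @export
run_validation <- function(ratings, instr = canonical_addi(),
                           config = validation_config()) {
  validate_ratings(ratings, instr, check_totals = FALSE)
  lookup <- instrument_lookup(instr)
  exclusions <- data.frame(scope = character(0), id = character(0),
                           reason = character(0), stringsAsFactors = FALSE)

  raters_per_group <- tapply(ratings$rater_id, ratings$group_id,
                             function(r) length(unique(r)))
  bad_groups <- names(raters_per_group)[raters_per_group < config$min_raters]
  for (g in bad_groups) {
    n_lost <- length(unique(ratings$case_id[ratings$group_id == g]))
    exclusions <- rbind(exclusions, data.frame(
      scope = "group", id = g,
      reason = sprintf("only %d responding raters (< %d); %d cases dropped",
                       raters_per_group[[g]], config$min_raters, n_lost),
      stringsAsFactors = FALSE
    ))
  }
  ratings <- ratings[!ratings$group_id %in% bad_groups, ]
  if (!nrow(ratings)) stop("all groups dropped: no analyzable ratings")

  al <- config$ci_alpha
  overall <- safe_icc(ratings_to_scores(ratings, "total"), al)

  diseases <- sort(unique(ratings$disease))
  per_disease <- stats::setNames(lapply(diseases, function(d) {
    safe_icc(ratings_to_scores(ratings[ratings$disease == d, ], "total"), al)
  }), diseases)

  cat_scores <- ratings_category_scores(ratings, lookup)
  per_category <- stats::setNames(lapply(lookup$cat_ids, function(cid) {
    safe_icc(split(cat_scores[[cid]],
                   factor(ratings$case_id, levels = unique(ratings$case_id))),
             al)
  }), lookup$cat_ids)

  per_item <- stats::setNames(lapply(lookup$item_ids, function(id) {
    safe_icc(ratings_to_scores(ratings, id), al)
  }), lookup$item_ids)

  pga_damage_icc <- safe_icc(ratings_to_scores(ratings, "pga_damage"), al)
  pga_activity_icc <- safe_icc(ratings_to_scores(ratings, "pga_activity"), al)

  mean_total <- mean_per_case(ratings, "total", config$min_raters)
  mean_pd <- mean_per_case(ratings, "pga_damage", config$min_raters)
  mean_pa <- mean_per_case(ratings, "pga_activity", config$min_raters)
  stopifnot(identical(names(mean_total), names(mean_pd)))
  construct <- list(
    vs_pga_damage = spearman_with_ci(
      mean_total, mean_pd, method = config$spearman_method,
      seed = config$spearman_seed),
    vs_pga_activity = spearman_with_ci(
      mean_total, mean_pa, method = config$spearman_method,
      seed = config$spearman_seed),
    pga_damage_reliable =
      isTRUE(pga_damage_icc$icc >= config$pga_reliability_gate),
    pga_activity_reliable =
      isTRUE(pga_activity_icc$icc >= config$pga_reliability_gate),
    mean_addi = mean_total, mean_pga_damage = mean_pd,
    mean_pga_activity = mean_pa
  )

  item_means <- ratings_item_means(ratings, lookup, config$min_raters)
  safe_alpha <- function(m) {
    tryCatch(suppressWarnings(
      cronbach_alpha(m, config$redundancy_threshold)),
      error = function(e) list(alpha = NA_real_,
                               reason = conditionMessage(e)))
  }
  interitem <- list(overall = safe_alpha(item_means))
  for (cid in lookup$cat_ids) {
    ids <- instr$categories[[cid]]$item_ids
    if (length(ids) >= 2L) {
      interitem[[cid]] <- safe_alpha(item_means[, ids, drop = FALSE])
    }
  }

  structure(
    list(overall = overall, per_disease = per_disease,
         per_category = per_category, per_item = per_item,
         pga_damage_icc = pga_damage_icc, pga_activity_icc = pga_activity_icc,
         construct = construct, interitem = interitem,
         exclusions = exclusions, config = config,
         n_ratings = nrow(ratings),
         n_cases = length(unique(ratings$case_id))),
    class = "reliability_report"
  )
}

#' @export
print.reliability_report <- function(x, ...) {
  cat(sprintf("<reliability report> %d cases, %d ratings\n",
              x$n_cases, x$n_ratings))
  cat("overall: ")
  print(x$overall)
  cat(sprintf("construct: vs PGA-damage rho = %.3f, vs PGA-activity rho = %.3f\n",
              x$construct$vs_pga_damage$rho, x$construct$vs_pga_activity$rho))
  if (nrow(x$exclusions)) {
    cat("exclusions:\n")
    print(x$exclusions)
  }
  invisible(x)
}

icc_row <- function(scope, name, r) {
  data.frame(
    scope = scope, name = name,
    icc = if (is.na(r$icc)) NA_real_ else r$icc,
    ci_lower = r$ci_lower, ci_upper = r$ci_upper,
    n_subjects = if (is.null(r$n_subjects)) NA_integer_ else r$n_subjects,
    n_ratings = if (is.null(r$n_ratings)) NA_integer_ else r$n_ratings,
    reason = if (is.null(r$reason)) "" else r$reason,
    stringsAsFactors = FALSE
  )
}

#' Flatten a report's ICC cells to a data frame
#'
#' One row per granularity cell, mirroring the reference report layout:
#' overall, each disease, each category, each item, and the two PGA scales.
#'
#' @param report A `reliability_report`.
#' @return Data frame with columns scope, name, icc, ci_lower, ci_upper,
#'   n_subjects, n_ratings, reason.
#' @export
report_icc_table <- function(report) {
  rows <- list(icc_row("overall", "overall", report$overall))
  for (d in names(report$per_disease)) {
    rows[[length(rows) + 1L]] <- icc_row("disease", d, report$per_disease[[d]])
  }
  for (cid in names(report$per_category)) {
    rows[[length(rows) + 1L]] <-
      icc_row("category", cid, report$per_category[[cid]])
  }
  for (id in names(report$per_item)) {
    rows[[length(rows) + 1L]] <- icc_row("item", id, report$per_item[[id]])
  }
  rows[[length(rows) + 1L]] <-
    icc_row("pga", "pga_damage", report$pga_damage_icc)
  rows[[length(rows) + 1L]] <-
    icc_row("pga", "pga_activity", report$pga_activity_icc)
  do.call(rbind, rows)
}

report_to_plain <- function(report) {
  plain_icc <- function(r) {
    out <- unclass(r)
    out$dropped <- NULL
    out
  }
  plain_cor <- function(r) unclass(r)
  plain_alpha <- function(a) {
    if (!is.null(a$interitem)) {
      a$interitem <- as.data.frame(a$interitem)
    }
    unclass(a)
  }
  list(
    n_cases = report$n_cases, n_ratings = report$n_ratings,
    overall = plain_icc(report$overall),
    per_disease = lapply(report$per_disease, plain_icc),
    per_category = lapply(report$per_category, plain_icc),
    per_item = lapply(report$per_item, plain_icc),
    pga_damage_icc = plain_icc(report$pga_damage_icc),
    pga_activity_icc = plain_icc(report$pga_activity_icc),
    construct = list(
      vs_pga_damage = plain_cor(report$construct$vs_pga_damage),
      vs_pga_activity = plain_cor(report$construct$vs_pga_activity),
      pga_damage_reliable = report$construct$pga_damage_reliable,
      pga_activity_reliable = report$construct$pga_activity_reliable
    ),
    interitem = lapply(report$interitem, plain_alpha),
    exclusions = report$exclusions,
    config = unclass(report$config)
  )
}

#' Write a reliability report to disk
#'
#' Emits a Table-1-style CSV of all ICC cells, a construct-validity CSV,
#' scatter-plot data files (per-case mean ADDI vs mean PGA), and a JSON
#' file with full detail. Output is deterministic: identical reports yield
#' byte-identical files.
#'
#' @param report A `reliability_report`.
#' @param dir Destination directory (created if needed).
#' @return Invisibly, the named vector of written paths.
#' @export
write_report <- function(report, dir) {
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok && !dir.exists(dir)) stop("cannot create directory '", dir, "'")
  }
  paths <- c(
    icc = file.path(dir, "report_icc.csv"),
    construct = file.path(dir, "report_construct.csv"),
    damage_pairs = file.path(dir, "construct_pga_damage_pairs.csv"),
    activity_pairs = file.path(dir, "construct_pga_activity_pairs.csv"),
    json = file.path(dir, "report.json")
  )
  utils::write.csv(report_icc_table(report), paths[["icc"]],
                   row.names = FALSE)
  cons <- do.call(rbind, lapply(
    c("vs_pga_damage", "vs_pga_activity"), function(k) {
      r <- report$construct[[k]]
      data.frame(comparison = k, rho = r$rho, ci_lower = r$ci_lower,
                 ci_upper = r$ci_upper, p_value = r$p_value,
                 n_pairs = r$n_pairs, strength_band = r$strength_band,
                 method = r$method, stringsAsFactors = FALSE)
    }))
  utils::write.csv(cons, paths[["construct"]], row.names = FALSE)
  utils::write.csv(
    data.frame(case_id = names(report$construct$mean_addi),
               mean_addi = unname(report$construct$mean_addi),
               mean_pga_damage = unname(report$construct$mean_pga_damage),
               stringsAsFactors = FALSE),
    paths[["damage_pairs"]], row.names = FALSE)
  utils::write.csv(
    data.frame(case_id = names(report$construct$mean_addi),
               mean_addi = unname(report$construct$mean_addi),
               mean_pga_activity = unname(report$construct$mean_pga_activity),
               stringsAsFactors = FALSE),
    paths[["activity_pairs"]], row.names = FALSE)
  writeLines(jsonlite::toJSON(report_to_plain(report), auto_unbox = TRUE,
                              pretty = 2, digits = 12, na = "null"),
             paths[["json"]])
  invisible(paths)
}

#' Screen item pairs for redundancy
#'
#' Computes pairwise interitem Pearson correlations on per-case mean item
#' scores, within each multi-item category, and lists the pairs exceeding
#' the threshold.
#'
#' @param ratings Rating table.
#' @param instr Instrument.
#' @param threshold Redundancy threshold in (0, 1), default 0.7.
#' @param min_raters Minimum raters per case for the per-case means.
#' @return Data frame: category, item_a, item_b, r (only pairs with
#'   r > threshold).
#' @export
redundancy_screen <- function(ratings, instr = canonical_addi(),
                              threshold = 0.7, min_raters = 3L) {
  stopifnot(threshold > 0, threshold < 1)
  lookup <- instrument_lookup(instr)
  item_means <- ratings_item_means(ratings, lookup, min_raters)
  out <- data.frame(category = character(0), item_a = character(0),
                    item_b = character(0), r = numeric(0),
                    stringsAsFactors = FALSE)
  for (cid in lookup$cat_ids) {
    ids <- instr$categories[[cid]]$item_ids
    if (length(ids) < 2L) next
    m <- item_means[, ids, drop = FALSE]
    usable <- apply(m, 2L, stats::var) > 0
    m <- m[, usable, drop = FALSE]
    if (ncol(m) < 2L) next
    cc <- stats::cor(m)
    ut <- which(upper.tri(cc) & cc > threshold, arr.ind = TRUE)
    if (nrow(ut)) {
      out <- rbind(out, data.frame(
        category = cid, item_a = colnames(m)[ut[, 1L]],
        item_b = colnames(m)[ut[, 2L]], r = cc[ut],
        stringsAsFactors = FALSE
      ))
    }
  }
  out
}
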