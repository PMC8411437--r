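# ---------------------------------------------------------------------------
# Psychometric estimators for the observer-nested-within-subject design.
#
# Rater groups are disjoint across case blocks (raters are not crossed with
# cases), which mandates the one-way random-effects model ICC(1). Under this
# model absolute-agreement and consistency coincide, and single-measures
# reliability is
#     ICC = (MSB - MSW) / (MSB + (k0 - 1) MSW)
# with k0 the effective number of ratings per subject for unbalanced groups.
# ---------------------------------------------------------------------------

#' One-way random-effects intraclass correlation (single measures)
#'
#' Estimates ICC(1) by one-way ANOVA on subjects: between-case mean square
#' on n - 1 df, within-case mean square on N - n df, effective group size
#' `k0 = (N - sum(k_i^2)/N) / (n - 1)` for unbalanced designs. The 95% CI
#' uses the F pivot `F = MSB/MSW` with quantiles
#' `F(alpha/2; n-1, N-n)` and `F(alpha/2; N-n, n-1)` mapped through the same
#' ICC transform. Negative estimates are reported as computed, never
#' clipped.
#'
#' @param scores Named list mapping each case to its vector of rater scores,
#'   or a data frame with columns `case_id` and `score`.
#' @param alpha_level Two-sided CI level is `1 - alpha_level` (default 0.05).
#' @return An `icc_result`: `icc`, `ci_lower`, `ci_upper`, `n_subjects`,
#'   `n_ratings`, `k0`, `msb`, `msw`, `f`, `dropped` (case ids with fewer
#'   than 2 ratings, dropped with a warning).
#' @export
estimate_icc_oneway <- function(scores, alpha_level = 0.05) {
  if (is.data.frame(scores)) {
    stopifnot(all(c("case_id", "score") %in% names(scores)))
    scores <- split(scores$score, scores$case_id)
  }
  scores <- lapply(scores, function(v) as.numeric(v[!is.na(v)]))
  sizes <- lengths(scores)
  dropped <- names(scores)[sizes < 2L]
  if (length(dropped)) {
    warning("dropping ", length(dropped),
            " case(s) with fewer than 2 ratings: ",
            paste(utils::head(dropped, 5L), collapse = ", "))
    scores <- scores[sizes >= 2L]
    sizes <- sizes[sizes >= 2L]
  }
  n <- length(scores)
  if (n < 2L) stop("need at least 2 cases with >= 2 ratings each")
  N <- sum(sizes)
  y <- unlist(scores, use.names = FALSE)
  grand <- mean(y)
  means <- vapply(scores, mean, numeric(1))
  ssb <- sum(sizes * (means - grand)^2)
  ssw <- sum((y - rep(means, sizes))^2)
  msb <- ssb / (n - 1)
  msw <- ssw / (N - n)
  k0 <- (N - sum(sizes^2) / N) / (n - 1)
  if (msb == 0 && msw == 0) {
    stop("degenerate variance: all scores identical, ICC undefined")
  }
  if (msw == 0) {
    icc <- 1
    ci <- c(1, 1)
    fobs <- Inf
  } else {
    icc <- (msb - msw) / (msb + (k0 - 1) * msw)
    fobs <- msb / msw
    fl <- fobs / stats::qf(1 - alpha_level / 2, n - 1, N - n)
    fu <- fobs * stats::qf(1 - alpha_level / 2, N - n, n - 1)
    ci <- c((fl - 1) / (fl + k0 - 1), (fu - 1) / (fu + k0 - 1))
  }
  structure(
    list(icc = icc, ci_lower = ci[1L], ci_upper = ci[2L],
         n_subjects = n, n_ratings = N, k0 = k0, msb = msb, msw = msw,
         f = fobs, alpha_level = alpha_level, dropped = dropped),
    class = "icc_result"
  )
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("ICC(1) = %.3f (%d%% CI %.3f to %.3f), n = %d cases, %d ratings, k0 = %.2f\n",
              x$icc, round(100 * (1 - x$alpha_level)), x$ci_lower,
              x$ci_upper, x$n_subjects, x$n_ratings, x$k0))
  invisible(x)
}

#' Cronbach's alpha with interitem redundancy screen
#'
#' `alpha = m/(m-1) * (1 - sum(var_i)/var_total)` on sample variances, with
#' the pairwise Pearson interitem correlation matrix. Item pairs whose
#' correlation exceeds `redundancy_threshold` are flagged as potentially
#' redundant. Zero-variance items are excluded with a warning.
#'
#' @param item_matrix Numeric matrix or data frame, cases in rows, items in
#'   columns.
#' @param redundancy_threshold Flagging threshold (default 0.7).
#' @return An `alpha_result`: `alpha`, `n_items`, `n_cases`, `interitem`
#'   (symmetric, unit diagonal), `redundant` (data frame of flagged pairs),
#'   `excluded_items`.
#' @export
cronbach_alpha <- function(item_matrix, redundancy_threshold = 0.7) {
  m0 <- as.matrix(item_matrix)
  if (is.null(colnames(m0))) {
    colnames(m0) <- paste0("item", seq_len(ncol(m0)))
  }
  if (nrow(m0) < 3L) stop("need at least 3 cases")
  v <- apply(m0, 2L, stats::var)
  excluded <- colnames(m0)[v == 0]
  if (length(excluded)) {
    warning("excluding zero-variance item(s): ",
            paste(excluded, collapse = ", "))
    m0 <- m0[, v > 0, drop = FALSE]
  }
  m <- ncol(m0)
  if (m < 2L) stop("fewer than 2 usable items")
  total_var <- stats::var(rowSums(m0))
  alpha <- (m / (m - 1)) * (1 - sum(apply(m0, 2L, stats::var)) / total_var)
  interitem <- stats::cor(m0)
  diag(interitem) <- 1
  ut <- which(upper.tri(interitem) & interitem > redundancy_threshold,
              arr.ind = TRUE)
  redundant <- data.frame(
    item_a = colnames(m0)[ut[, 1L]], item_b = colnames(m0)[ut[, 2L]],
    r = interitem[ut], stringsAsFactors = FALSE
  )
  structure(
    list(alpha = alpha, n_items = m, n_cases = nrow(m0),
         interitem = interitem, redundant = redundant,
         redundancy_threshold = redundancy_threshold,
         excluded_items = excluded),
    class = "alpha_result"
  )
}

#' @export
print.alpha_result <- function(x, ...) {
  cat(sprintf("Cronbach's alpha = %.3f (%d items, %d cases)\n",
              x$alpha, x$n_items, x$n_cases))
  if (nrow(x$redundant)) {
    cat("redundant pairs (r > ", x$redundancy_threshold, "):\n", sep = "")
    print(x$redundant)
  }
  invisible(x)
}

#' Spearman rank correlation with confidence interval
#'
#' Computes rho as the Pearson correlation of average ranks (ties allowed).
#' The Fisher CI uses the z transform with the Spearman standard error
#' `1.06/sqrt(n-3)`; the bootstrap CI is the percentile interval over
#' `n_boot` case resamples under a fixed seed. Strength bands follow the
#' conventional cutoffs: |rho| in [0.1, 0.3) weak, [0.3, 0.5] moderate,
#' > 0.5 strong.
#'
#' @param x,y Numeric vectors of equal length >= 4.
#' @param method `"fisher"` (default, deterministic) or `"bootstrap"`.
#' @param conf_level Confidence level (default 0.95).
#' @param n_boot Bootstrap resamples (default 2000).
#' @param seed Seed for the bootstrap resampling.
#' @return A `correlation_result`: `rho`, `ci_lower`, `ci_upper`, `p_value`
#'   (two-sided t approximation), `n_pairs`, `strength_band`, `method`.
#' @export
spearman_with_ci <- function(x, y, method = c("fisher", "bootstrap"),
                             conf_level = 0.95, n_boot = 2000, seed = NULL) {
  method <- match.arg(method)
  stopifnot(length(x) == length(y))
  ok <- !(is.na(x) | is.na(y))
  x <- x[ok]
  y <- y[ok]
  n <- length(x)
  if (n < 4L) stop("need at least 4 complete pairs")
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    stop("undefined correlation: constant input vector")
  }
  spearman_rho <- function(x, y) stats::cor(rank(x), rank(y))
  rho <- spearman_rho(x, y)
  zq <- stats::qnorm(1 - (1 - conf_level) / 2)
  if (method == "fisher") {
    z <- atanh(min(max(rho, -1 + 1e-15), 1 - 1e-15))
    se <- 1.06 / sqrt(n - 3)
    ci <- tanh(c(z - zq * se, z + zq * se))
  } else {
    if (!is.null(seed)) {
      old <- if (exists(".Random.seed", .GlobalEnv)) {
        get(".Random.seed", .GlobalEnv)
      }
      on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
      set.seed(seed)
    }
    boot <- vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      if (stats::var(x[idx]) == 0 || stats::var(y[idx]) == 0) {
        return(NA_real_)
      }
      spearman_rho(x[idx], y[idx])
    }, numeric(1))
    ci <- unname(stats::quantile(boot, c((1 - conf_level) / 2,
                                         1 - (1 - conf_level) / 2),
                                 na.rm = TRUE))
  }
  p <- if (abs(rho) >= 1) 0 else {
    tval <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * stats::pt(-abs(tval), n - 2)
  }
  band <- if (abs(rho) > 0.5) "strong"
          else if (abs(rho) >= 0.3) "moderate"
          else if (abs(rho) >= 0.1) "weak"
          else "negligible"
  structure(
    list(rho = rho, ci_lower = ci[1L], ci_upper = ci[2L], p_value = p,
         n_pairs = n, strength_band = band, method = method,
         conf_level = conf_level),
    class = "correlation_result"
  )
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf(
    "Spearman rho = %.3f (%d%% CI %.3f to %.3f, %s), p = %.3g, n = %d (%s)\n",
    x$rho, round(100 * x$conf_level), x$ci_lower, x$ci_upper,
    x$strength_band, x$p_value, x$n_pairs, x$method))
  invisible(x)
}

#' Per-case mean of a rating-table field
#'
#' Cases rated by fewer than `min_raters` raters are excluded (the study
#' convention: at least three observers per case).
#'
#' @param ratings A rating table (see [read_ratings_csv()]).
#' @param field Column to average: `"total"`, `"pga_damage"` or
#'   `"pga_activity"` (any numeric column accepted).
#' @param min_raters Minimum raters per case (default 3).
#' @return Named numeric vector of per-case means.
#' @export
mean_per_case <- function(ratings, field = c("total", "pga_damage",
                                             "pga_activity"),
                          min_raters = 3L) {
  if (length(field) > 1L) field <- match.arg(field)
  stopifnot(field %in% names(ratings), min_raters >= 1L)
  counts <- table(ratings$case_id)
  keep <- names(counts)[counts >= min_raters]
  if (!length(keep)) stop("no case has >= ", min_raters, " ratings")
  sub <- ratings[ratings$case_id %in% keep, ]
  vapply(split(sub[[field]], factor(sub$case_id, levels = unique(sub$case_id))),
         mean, numeric(1))
}

# --- rating table I/O ------------------------------------------------------

#' Validate a rating table
#'
#' Checks the mandated long-format schema: one row per (case, rater), columns
#' `case_id, rater_id, group_id, disease, <item slugs>, total, pga_damage,
#' pga_activity`; uniqueness of (case_id, rater_id); each case in exactly one
#' group; scores within instrument bounds. Totals are recomputed from the
#' item columns through the category caps and mismatches raise a warning.
#'
#' @param ratings Data frame.
#' @param instr Instrument (default [canonical_addi()]).
#' @param check_totals Cross-check the `total` column (default TRUE).
#' @return The validated data frame, invisibly.
#' @export
validate_ratings <- function(ratings, instr = canonical_addi(),
                             check_totals = TRUE) {
  lookup <- instrument_lookup(instr)
  need <- c("case_id", "rater_id", "group_id", "disease", lookup$item_ids,
            "total", "pga_damage", "pga_activity")
  miss <- setdiff(need, names(ratings))
  if (length(miss)) {
    stop("rating table missing column(s): ", paste(miss, collapse = ", "))
  }
  key <- paste(ratings$case_id, ratings$rater_id)
  if (anyDuplicated(key)) {
    stop("duplicate (case_id, rater_id) pair: ", key[duplicated(key)][1L])
  }
  cg <- unique(ratings[, c("case_id", "group_id")])
  if (anyDuplicated(cg$case_id)) {
    stop("case assigned to more than one group: ",
         cg$case_id[duplicated(cg$case_id)][1L])
  }
  for (i in seq_along(lookup$item_ids)) {
    id <- lookup$item_ids[i]
    mx <- max(lookup$points[i, ])
    bad <- which(ratings[[id]] < 0 | ratings[[id]] > mx)
    if (length(bad)) {
      stop("item '", id, "': score out of bounds [0, ", mx, "] in row ",
           bad[1L])
    }
  }
  if (any(ratings$pga_damage < 0 | ratings$pga_damage > 10) ||
      any(ratings$pga_activity < 0 | ratings$pga_activity > 10)) {
    stop("PGA scores must lie in [0, 10]")
  }
  if (check_totals) {
    G <- t(as.matrix(ratings[, lookup$item_ids]))
    C <- rowsum(G, lookup$item_cat)
    C <- pmin(C, matrix(lookup$caps, nrow = length(lookup$caps),
                        ncol = ncol(C)))
    recomputed <- colSums(C)
    bad <- which(abs(recomputed - ratings$total) > 1e-9)
    if (length(bad)) {
      warning(length(bad), " rating row(s) have totals inconsistent with ",
              "their item scores under the category caps (first: row ",
              bad[1L], ", stated ", ratings$total[bad[1L]], ", recomputed ",
              recomputed[bad[1L]], ")")
    }
  }
  invisible(ratings)
}

#' Read / write a rating table as long-format CSV
#'
#' @param path File path.
#' @param instr Instrument used for schema validation.
#' @param check_totals Cross-check stated totals against the scoring engine.
#' @return `read_ratings_csv` returns the validated data frame.
#' @export
read_ratings_csv <- function(path, instr = canonical_addi(),
                             check_totals = TRUE) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  validate_ratings(df, instr, check_totals = check_totals)
  df
}

#' @rdname read_ratings_csv
#' @param ratings Rating table data frame.
#' @export
write_ratings_csv <- function(ratings, path) {
  utils::write.csv(ratings, path, row.names = FALSE)
  invisible(path)
}

#' Split a rating-table column into the case -> scores map used by
#' [estimate_icc_oneway()]
#'
#' @param ratings Rating table data frame.
#' @param field Score column to split (default `"total"`).
#' @return Named list, case_id -> numeric vector of rater scores.
#' @export
ratings_to_scores <- function(ratings, field = "total") {
  split(ratings[[field]], factor(ratings$case_id,
                                 levels = unique(ratings$case_id)))
}
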