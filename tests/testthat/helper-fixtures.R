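# Independent oracles (coded separately from the estimators under test) and
# small fixtures built in code.

# Brute-force one-way ANOVA sums of squares -> ICC(1), looped explicitly.
oracle_icc <- function(scores) {
  scores <- scores[lengths(scores) >= 2L]
  y <- numeric(0)
  for (id in names(scores)) y <- c(y, scores[[id]])
  n <- length(scores)
  N <- length(y)
  gm <- sum(y) / N
  ssb <- 0
  ssw <- 0
  for (id in names(scores)) {
    v <- scores[[id]]
    ssb <- ssb + length(v) * (mean(v) - gm)^2
    for (x in v) ssw <- ssw + (x - mean(v))^2
  }
  msb <- ssb / (n - 1)
  msw <- ssw / (N - n)
  k0 <- (N - sum(lengths(scores)^2) / N) / (n - 1)
  list(icc = (msb - msw) / (msb + (k0 - 1) * msw),
       msb = msb, msw = msw, k0 = k0)
}

# Covariance-matrix form of Cronbach's alpha.
oracle_alpha <- function(m) {
  C <- stats::cov(m)
  k <- ncol(m)
  (k / (k - 1)) * (1 - sum(diag(C)) / sum(C))
}

# Random unbalanced case -> scores maps for oracle-equivalence sweeps.
random_scores <- function(n_cases, k_range = 2:5, between_sd = 1,
                          within_sd = 0.7) {
  stats::setNames(lapply(seq_len(n_cases), function(i) {
    stats::rnorm(1, sd = between_sd) +
      stats::rnorm(sample(k_range, 1), sd = within_sd)
  }), paste0("c", seq_len(n_cases)))
}

# Case asserting every instrument item at its most severe grade (eligible:
# 12 months duration, no activity attribution). Female paediatric so all
# applicability rules pass.
max_damage_case <- function(instr = canonical_addi(),
                            case_id = "max_case") {
  evs <- lapply(unname(instr$items), function(it) {
    lab <- if (length(it$levels)) {
      it$levels[[length(it$levels)]]$label
    } else "present"
    evidence(it$item_id, "asserted", asserted_grade = lab,
             duration_months = 12)
  })
  case_record(case_id, "CAPS", age_years = 10, sex = "female",
              evidence = evs)
}

# Tiny two-category instrument for serialization property tests.
tiny_instrument <- function(serosal_cap = 1L) {
  instrument_definition(
    "tiny", "0.1",
    categories = list(
      category_definition("renal", "Renal", 4L, c("amyl", "prot")),
      category_definition("serosal", "Serosal", serosal_cap, "scar")
    ),
    items = list(
      item_definition("amyl", "Amyloidosis", "renal", levels = list(
        grading_level("limited", 2L), grading_level("extensive", 3L)
      )),
      item_definition("prot", "Proteinuria", "renal", base_points = 1L),
      item_definition("scar", "Serosal scarring", "serosal",
                      base_points = 1L)
    )
  )
}

# Randomized valid instrument for round-trip property tests.
random_instrument <- function() {
  n_cat <- sample(1:3, 1)
  items <- list()
  cats <- list()
  for (ci in seq_len(n_cat)) {
    cid <- paste0("cat", ci)
    n_it <- sample(1:3, 1)
    ids <- character(0)
    for (ii in seq_len(n_it)) {
      id <- paste0("item", ci, "_", ii)
      ids <- c(ids, id)
      if (stats::runif(1) < 0.5) {
        n_lv <- sample(2:3, 1)
        pts <- sort(sample(1:5, n_lv))
        items[[id]] <- item_definition(
          id, toupper(id), cid,
          levels = lapply(seq_len(n_lv), function(l) {
            grading_level(paste0("lv", l), pts[l], "criterion text")
          }),
          pediatric_only = stats::runif(1) < 0.2
        )
      } else {
        items[[id]] <- item_definition(
          id, toupper(id), cid, base_points = sample(1:3, 1),
          applicable_sex = sample(c("any", "female_relevant"), 1)
        )
      }
    }
    max_it <- max(vapply(items[ids], item_max_points, integer(1)))
    total <- sum(vapply(items[ids], item_max_points, integer(1)))
    cap <- if (max_it == total) total else sample(seq(max_it, total), 1)
    cats[[cid]] <- category_definition(cid, toupper(cid), cap, ids)
  }
  instrument_definition("rand", "0", unname(cats), unname(items))
}

# Small complete simulated study for pipeline/CLI tests.
small_study <- function(seed = 9L, model = rater_model(), n_cases = 40L,
                        n_groups = 4L) {
  design <- study_design(n_cases = n_cases, n_groups = n_groups,
                         cases_per_group = n_cases / n_groups, seed = seed)
  simulate_study(design, model)
}
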