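#' Default CTCAE v5.0-style grading bands for hematologic adverse events
#'
#' Maps analyte values to grades 0-4 through ordered half-open bands
#' `[lower, upper)`; for every hematologic AE a lower value is worse. Counts
#' are in 10^9/L, hemoglobin in g/L. The anemia grade-4 bound (65 g/L) is a
#' package convention — the clinical definition is "life-threatening"
#' without a numeric cutoff — and, like every other band, can be edited
#' before passing the table to [grade_series()].
#'
#' @return Tibble with columns `ae`, `analyte`, `grade`, `lower`, `upper`.
#' @export
#' @examples
#' ctcae_thresholds()
ctcae_thresholds <- function() {
  band <- function(ae, analyte, cuts) {
    # cuts: grade-4..grade-1 upper bounds ascending; grade 0 is [last, Inf)
    tibble(ae = ae, analyte = analyte, grade = 4:0,
           lower = c(0, cuts), upper = c(cuts, Inf))
  }
  dplyr::bind_rows(
    band("leukopenia", "wbc", c(1, 2, 3, 4)),
    band("neutropenia", "anc", c(0.5, 1, 1.5, 2)),
    band("lymphopenia", "alc", c(0.2, 0.5, 0.8, 1)),
    band("anemia", "hgb", c(65, 80, 100, 120)),
    band("thrombocytopenia", "plt", c(25, 50, 75, 150))
  )
}

validate_thresholds <- function(thresholds) {
  thresholds <- as_tibble(thresholds)
  need <- c("ae", "analyte", "grade", "lower", "upper")
  if (!all(need %in% names(thresholds))) {
    abort("`thresholds` needs columns ae, analyte, grade, lower, upper.")
  }
  by_ae <- split(thresholds, thresholds$ae)
  for (tb in by_ae) {
    tb <- tb[order(tb$lower), ]
    if (tb$lower[1] != 0 || !is.infinite(tb$upper[nrow(tb)]) ||
        any(tb$upper[-nrow(tb)] != tb$lower[-1])) {
      abort(sprintf("bands for %s must be contiguous and cover (0, Inf).",
                    tb$ae[1]))
    }
    if (any(diff(tb$grade) >= 0)) {
      abort(sprintf("grade must strictly increase as %s decreases.",
                    tb$ae[1]))
    }
  }
  thresholds
}

#' Grade hematologic adverse events from a longitudinal lab series
#'
#' Each week's analyte value is graded independently through the threshold
#' bands and the per-patient maximum over weeks is reported, so the profile
#' records the worst toxicity reached during treatment. The baseline week
#' (week 0) is included in the scan by default.
#'
#' @param labs Long tibble (`patient`, `week`, `analyte`, `value`), e.g.
#'   from [simulate_cohort()].
#' @param thresholds Grading bands as in [ctcae_thresholds()].
#' @param include_baseline Include week 0 in the maximum-grade scan?
#'
#' @return Tibble (`patient`, `ae`, `grade`) with one row per patient per
#'   AE covered by `thresholds`; grades are integers 0-4.
#' @export
grade_series <- function(labs, thresholds = ctcae_thresholds(),
                         include_baseline = TRUE) {
  labs <- as_tibble(labs)
  if (!all(c("patient", "week", "analyte", "value") %in% names(labs))) {
    abort("`labs` needs columns patient, week, analyte, value.")
  }
  if (nrow(labs) == 0) abort("`labs` is empty.")
  thresholds <- validate_thresholds(thresholds)
  if (!include_baseline) labs <- labs[labs$week != 0, ]
  need <- unique(thresholds$analyte)
  missing_an <- setdiff(need, unique(labs$analyte))
  if (length(missing_an)) {
    abort(sprintf("analytes required by thresholds missing from labs: %s",
                  paste(missing_an, collapse = ", ")))
  }
  bad <- is.na(labs$value) | labs$value < 0
  if (any(bad)) {
    abort(sprintf(
      "negative or missing analyte values for: %s",
      paste(sprintf("%s week %s (%s)", labs$patient[bad], labs$week[bad],
                    labs$analyte[bad])[seq_len(min(5, sum(bad)))],
            collapse = "; ")))
  }
  graded <- dplyr::inner_join(labs, thresholds, by = "analyte",
                              relationship = "many-to-many")
  graded <- graded[graded$value >= graded$lower & graded$value < graded$upper, ]
  out <- dplyr::summarise(dplyr::group_by(graded, .data$patient, .data$ae),
                          grade = as.integer(max(.data$grade)),
                          .groups = "drop")
  # patients whose values never fall in a sub-zero band still need rows
  full <- tidyr::expand_grid(patient = unique(labs$patient),
                             ae = unique(thresholds$ae))
  out <- dplyr::left_join(full, out, by = c("patient", "ae"))
  out$grade[is.na(out$grade)] <- 0L
  dplyr::arrange(out, .data$patient, .data$ae)
}

#' Hematologic toxicity index of a set of AE grades
#'
#' The index is an order-weighted sum of a patient's AE grades: with
#' grades sorted in descending order `X1 >= X2 >= ...`,
#' `HTI = X1 + X2/(1+X1) + X3/((1+X1)(1+X2)) + ...`. Sorting descending
#' makes the index a severity measure dominated by the worst toxicity: for
#' any non-empty grade set with maximum grade `g >= 1`,
#' `g <= HTI < g + 1`, and adding any grade >= 1 strictly increases it.
#' Zero grades contribute nothing (their denominators multiply by 1), so
#' the index is a pure function of the grade multiset.
#'
#' @param grades Integer vector of grades in 0-4 (any order).
#' @return A single non-negative number.
#' @export
#' @examples
#' hti_index(c(2, 2, 2, 2, 2)) # ~2.9877
#' hti_index(c(3, 1)) # 3.25
hti_index <- function(grades) {
  if (length(grades) == 0) return(0)
  if (anyNA(grades) || !all(grades %in% 0:4)) {
    abort("`grades` must be integers in 0..4.")
  }
  g <- sort(as.numeric(grades), decreasing = TRUE)
  sum(g / cumprod(c(1, 1 + g[-length(g)])))
}

#' Compute per-patient hematologic toxicity indices
#'
#' Applies [hti_index()] to each patient's maximum-grade AE profile.
#'
#' @param profiles Tibble (`patient`, `ae`, `grade`) from [grade_series()].
#' @return Tibble (`patient`, `hti`).
#' @export
compute_hti <- function(profiles) {
  profiles <- as_tibble(profiles)
  if (!all(c("patient", "grade") %in% names(profiles))) {
    abort("`profiles` needs columns patient and grade.")
  }
  dplyr::summarise(dplyr::group_by(profiles, .data$patient),
                   hti = hti_index(.data$grade), .groups = "drop")
}

validate_2x2 <- function(m) {
  m <- as.matrix(m)
  if (!all(dim(m) == c(2, 2)) || anyNA(m) || any(m < 0) ||
      any(m != round(m))) {
    abort("`table` must be a 2x2 matrix of non-negative integer counts.")
  }
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    abort("test undefined: a margin of the 2x2 table is zero.")
  }
  m
}

#' Pearson chi-square test of a 2x2 table (no continuity correction)
#'
#' One-degree-of-freedom Pearson chi-square with a two-sided p-value from
#' the upper chi-square tail. The statistic equals the squared
#' two-proportion z statistic. No Yates correction is applied, matching
#' how the cohort table's printed p-values were produced.
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @return One-row tibble (`statistic`, `df`, `p_value`).
#' @export
#' @examples
#' chisq_2x2(matrix(c(140, 39, 98, 52), 2)) # sex x lymphopenia
chisq_2x2 <- function(table) {
  m <- validate_2x2(table)
  ct <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
  tibble(statistic = unname(ct$statistic), df = 1L,
         p_value = unname(ct$p.value))
}

#' Fisher's exact test of a 2x2 table
#'
#' Two-sided p-value: the sum of hypergeometric probabilities, over all
#' tables with the observed margins, of tables whose point probability
#' does not exceed that of the observed table.
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @return One-row tibble (`p_value`, `odds_ratio` conditional MLE).
#' @export
fisher_exact_2x2 <- function(table) {
  m <- validate_2x2(table)
  ft <- stats::fisher.test(m)
  tibble(p_value = unname(ft$p.value), odds_ratio = unname(ft$estimate))
}

#' Cohort comparison table for hematologic toxicity
#'
#' Reproduces the layout of a clinical "Table 1": every AE is split into a
#' binary outcome (grade 0 vs >= 1, except lymphopenia: 0-2 vs 3-4) and
#' the HTI into <= median vs > median (ties to the lower group); each
#' clinical stratifier is then cross-tabulated against each outcome and
#' tested. Two-level stratifiers use the Pearson chi-square without
#' continuity correction by default (`fisher = TRUE` switches to Fisher's
#' exact test); stratifiers with more levels use an r x c chi-square; age
#' uses a t test (Student by default, `welch = TRUE` for unequal
#' variances).
#'
#' @param profiles Tibble from [grade_series()].
#' @param hti Tibble from [compute_hti()].
#' @param metadata Patient metadata tibble; `patient` plus stratifiers.
#' @param stratifiers Character vector of metadata columns to compare;
#'   numeric columns are compared by group means (t test), others by
#'   counts. Single-level stratifiers are skipped with a warning.
#' @param fisher Use Fisher's exact test for 2x2 tables?
#' @param welch Use the Welch t test for numeric stratifiers?
#'
#' @return Tibble (`outcome`, `variable`, `test`, `statistic`, `p_value`,
#'   `n`) with one row per outcome x stratifier; the underlying stratified
#'   counts (or group means) are in `attr(, "counts")`, and the outcome
#'   group sizes in `attr(, "groups")`.
#' @export
cohort_table <- function(profiles, hti, metadata,
                         stratifiers = c("sex", "age", "location", "stage",
                                         "nstage", "oxaliplatin"),
                         fisher = FALSE, welch = FALSE) {
  metadata <- as_tibble(metadata)
  if (!all(metadata$patient %in% unique(profiles$patient)) ||
      !all(metadata$patient %in% hti$patient)) {
    abort("every patient in `metadata` needs a profile and an HTI value.")
  }
  wide <- tidyr::pivot_wider(profiles, names_from = "ae",
                             values_from = "grade")
  dat <- dplyr::inner_join(dplyr::inner_join(wide, hti, by = "patient"),
                           metadata, by = "patient")
  aes <- setdiff(names(wide), "patient")
  outcomes <- lapply(setNames(aes, aes), function(a) {
    if (a == "lymphopenia") {
      factor(ifelse(dat[[a]] >= 3, "3-4", "0-2"), levels = c("0-2", "3-4"))
    } else {
      factor(ifelse(dat[[a]] >= 1, ">=1", "0"), levels = c("0", ">=1"))
    }
  })
  med <- median(dat$hti)
  outcomes$hti_group <- factor(ifelse(dat$hti <= med, "<=median", ">median"),
                               levels = c("<=median", ">median"))

  rows <- list(); counts <- list()
  for (v in stratifiers) {
    if (!v %in% names(dat)) abort(sprintf("stratifier `%s` not found.", v))
    x <- dat[[v]]
    if (!is.numeric(x) && dplyr::n_distinct(x) < 2) {
      warn(sprintf("stratifier `%s` has a single level; skipped.", v))
      next
    }
    for (oc in names(outcomes)) {
      y <- outcomes[[oc]]
      if (is.numeric(x)) {
        tt <- stats::t.test(x ~ y, var.equal = !welch)
        rows[[length(rows) + 1]] <- tibble(
          outcome = oc, variable = v,
          test = if (welch) "welch_t" else "student_t",
          statistic = unname(tt$statistic), p_value = tt$p.value,
          n = length(x))
        counts[[length(counts) + 1]] <- tibble(
          outcome = oc, variable = v, level = levels(y),
          value = as.numeric(tapply(x, y, mean)))
      } else {
        tab <- table(x, y)
        if (all(dim(tab) == c(2, 2))) {
          res <- if (fisher) {
            r <- fisher_exact_2x2(tab)
            tibble(test = "fisher_exact", statistic = NA_real_,
                   p_value = r$p_value)
          } else {
            r <- chisq_2x2(tab)
            tibble(test = "chisq", statistic = r$statistic,
                   p_value = r$p_value)
          }
        } else {
          ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
          res <- tibble(test = "chisq_rxc",
                        statistic = unname(ct$statistic),
                        p_value = unname(ct$p.value))
        }
        rows[[length(rows) + 1]] <- dplyr::bind_cols(
          tibble(outcome = oc, variable = v), res, tibble(n = sum(tab)))
        tl <- as_tibble(as.data.frame(tab))
        names(tl) <- c("stratum", "level", "value")
        counts[[length(counts) + 1]] <- dplyr::bind_cols(
          tibble(outcome = oc, variable = v), tl)
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "counts") <- dplyr::bind_rows(counts)
  attr(out, "groups") <- purrr::map_dfr(outcomes, function(y) {
    tibble(level = levels(y), n = as.integer(table(y)))
  }, .id = "outcome")
  attr(out, "hti_median") <- med
  class(out) <- c("toxbiome_cohort_table", class(out))
  out
}
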