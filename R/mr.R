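validate_sumstats <- function(x, name = "summary statistics") {
  x <- as_tibble(x)
  need <- c("snp", "chr", "pos", "effect_allele", "other_allele", "eaf",
            "beta", "se", "pval")
  miss <- setdiff(need, names(x))
  if (length(miss)) {
    abort(sprintf("%s missing columns: %s", name,
                  paste(miss, collapse = ", ")))
  }
  if (any(x$se <= 0, na.rm = TRUE)) abort("standard errors must be > 0.")
  ok_allele <- c("A", "C", "G", "T")
  if (!all(x$effect_allele %in% ok_allele) ||
      !all(x$other_allele %in% ok_allele)) {
    abort("alleles must be single bases A/C/G/T.")
  }
  if (any(!is.na(x$eaf) & (x$eaf <= 0 | x$eaf >= 1))) {
    abort("`eaf` must lie in (0, 1) when present.")
  }
  if (anyDuplicated(x$snp)) abort(sprintf("%s has duplicate SNP ids.", name))
  x
}

ld_r2 <- function(ld, a, b) {
  if (is.null(ld)) return(0)
  if (!(a %in% rownames(ld)) || !(b %in% colnames(ld))) return(0)
  unname(ld[a, b]^2)
}

#' Select approximately independent genetic instruments
#'
#' Greedy LD clumping of exposure SNPs: candidates below the association
#' p-value threshold are visited in ascending p order; each kept SNP
#' removes every remaining candidate on the same chromosome within
#' `window_kb` whose squared LD correlation with it exceeds `clump_r2`
#' (strict inequality). SNP pairs absent from the LD matrix are treated as
#' independent.
#'
#' @param exposure Exposure summary statistics (`snp`, `chr`, `pos`,
#'   `effect_allele`, `other_allele`, `eaf`, `beta`, `se`, `pval`).
#' @param ld SNP-by-SNP LD correlation matrix (r scale) with SNP ids as
#'   dimnames; `NULL` means all pairs independent.
#' @param p_threshold Instrument inclusion threshold (default 1e-5).
#' @param clump_r2 Maximum allowed r^2 between retained SNPs (default
#'   0.01).
#' @param window_kb Clumping window in kilobases (default 1000).
#' @return List with `instruments` (tibble of retained exposure rows, p
#'   ascending) and `provenance` (tibble `snp`, `status` of every
#'   candidate: `kept` or `removed_ld`). An empty candidate set returns
#'   zero-row tibbles.
#' @export
select_instruments <- function(exposure, ld = NULL, p_threshold = 1e-5,
                               clump_r2 = 0.01, window_kb = 1000) {
  exposure <- validate_sumstats(exposure, "exposure")
  cand <- exposure[exposure$pval < p_threshold, ]
  cand <- cand[order(cand$pval), ]
  if (nrow(cand) == 0) {
    inform("no SNP passes the instrument p-value threshold.")
    return(list(instruments = cand,
                provenance = tibble(snp = character(),
                                    status = character())))
  }
  status <- setNames(rep(NA_character_, nrow(cand)), cand$snp)
  for (i in seq_len(nrow(cand))) {
    s <- cand$snp[i]
    if (!is.na(status[s])) next
    status[s] <- "kept"
    near <- which(is.na(status) & cand$chr == cand$chr[i] &
                    abs(cand$pos - cand$pos[i]) <= window_kb * 1000)
    for (j in near) {
      if (ld_r2(ld, s, cand$snp[j]) > clump_r2) status[cand$snp[j]] <- "removed_ld"
    }
  }
  list(instruments = cand[status[cand$snp] == "kept", ],
       provenance = tibble(snp = cand$snp, status = unname(status)))
}

flip_allele <- function(a) c(A = "T", C = "G", G = "C", T = "A")[a]

is_palindromic <- function(ea, oa) flip_allele(ea) == oa

#' Harmonize exposure and outcome summary statistics
#'
#' Expresses exposure and outcome effects for the same effect allele, SNP
#' by SNP. Outcome records with swapped alleles get their beta negated and
#' eaf reflected; strand-complement records are complemented first.
#' Palindromic SNPs (A/T or C/G) are kept only when the minor-allele
#' frequency is at most `palindromic_maf` on both sides and the
#' frequencies agree in orientation — otherwise the strand is ambiguous
#' and the SNP is dropped. Instruments absent from the outcome are
#' replaced by their highest-r^2 LD proxy at `r^2 >= proxy_r2` (proxy
#' effect sizes used as-is), else dropped. Harmonization is idempotent.
#'
#' @param exposure Instrument exposure rows (e.g.
#'   `select_instruments()$instruments`).
#' @param outcome Outcome summary statistics.
#' @param ld Optional LD matrix (r scale) for proxy search.
#' @param proxy_r2 Minimum r^2 for a proxy (default 0.8).
#' @param palindromic_maf Maximum minor-allele frequency at which a
#'   palindromic SNP is considered resolvable (default 0.42).
#' @return Tibble of class `harmonized_set`, one row per instrument:
#'   `snp`, `effect_allele`, `other_allele`, `beta_exposure`,
#'   `se_exposure`, `eaf_exposure`, `beta_outcome`, `se_outcome`,
#'   `eaf_outcome`, `action` (kept / flipped / proxied / dropped reasons),
#'   `proxy_snp`, `retained`.
#' @export
harmonize_gwas <- function(exposure, outcome, ld = NULL, proxy_r2 = 0.8,
                           palindromic_maf = 0.42) {
  exposure <- validate_sumstats(exposure, "exposure")
  outcome <- validate_sumstats(outcome, "outcome")
  out_idx <- setNames(seq_len(nrow(outcome)), outcome$snp)

  align_one <- function(ex, oc) {
    # returns list(beta, eaf, action) for the outcome aligned to ex alleles
    pal <- is_palindromic(ex$effect_allele, ex$other_allele)
    if (pal) {
      if (!setequal(c(oc$effect_allele, oc$other_allele),
                    c(ex$effect_allele, ex$other_allele))) {
        return(list(action = "dropped_mismatch"))
      }
      maf_ok <- function(f) !is.na(f) && min(f, 1 - f) <= palindromic_maf
      if (!maf_ok(ex$eaf) || !maf_ok(oc$eaf)) {
        return(list(action = "dropped_palindromic"))
      }
      ocf <- if (oc$effect_allele == ex$effect_allele) oc$eaf else 1 - oc$eaf
      if ((ex$eaf < 0.5) != (ocf < 0.5)) {
        return(list(action = "dropped_palindromic"))
      }
      if (oc$effect_allele == ex$effect_allele) {
        return(list(beta = oc$beta, eaf = oc$eaf, action = "kept"))
      }
      return(list(beta = -oc$beta, eaf = 1 - oc$eaf, action = "flipped"))
    }
    ea <- oc$effect_allele; oa <- oc$other_allele
    if (ea == ex$effect_allele && oa == ex$other_allele) {
      return(list(beta = oc$beta, eaf = oc$eaf, action = "kept"))
    }
    if (ea == ex$other_allele && oa == ex$effect_allele) {
      return(list(beta = -oc$beta, eaf = 1 - oc$eaf, action = "flipped"))
    }
    # try the other strand
    ea2 <- flip_allele(ea); oa2 <- flip_allele(oa)
    if (ea2 == ex$effect_allele && oa2 == ex$other_allele) {
      return(list(beta = oc$beta, eaf = oc$eaf, action = "kept"))
    }
    if (ea2 == ex$other_allele && oa2 == ex$effect_allele) {
      return(list(beta = -oc$beta, eaf = 1 - oc$eaf, action = "flipped"))
    }
    list(action = "dropped_mismatch")
  }

  rows <- purrr::map_dfr(seq_len(nrow(exposure)), function(i) {
    ex <- exposure[i, ]
    base <- tibble(snp = ex$snp, effect_allele = ex$effect_allele,
                   other_allele = ex$other_allele, beta_exposure = ex$beta,
                   se_exposure = ex$se, eaf_exposure = ex$eaf,
                   beta_outcome = NA_real_, se_outcome = NA_real_,
                   eaf_outcome = NA_real_, action = NA_character_,
                   proxy_snp = NA_character_)
    target <- ex$snp
    if (!target %in% names(out_idx)) {
      # look for the best available proxy
      if (!is.null(ld) && ex$snp %in% rownames(ld)) {
        r2 <- ld[ex$snp, ]^2
        r2 <- r2[names(r2) %in% outcome$snp & names(r2) != ex$snp]
        r2 <- r2[r2 >= proxy_r2]
        if (length(r2)) {
          target <- names(which.max(r2))
          base$proxy_snp <- target
        }
      }
      if (target == ex$snp) {
        base$action <- "dropped_no_proxy"
        return(base)
      }
      oc <- outcome[out_idx[target], ]
      # proxy effect sizes are used as-is on the proxy's own alleles
      base$beta_outcome <- oc$beta
      base$se_outcome <- oc$se
      base$eaf_outcome <- oc$eaf
      base$action <- "proxied"
      return(base)
    }
    oc <- outcome[out_idx[target], ]
    al <- align_one(ex, oc)
    base$action <- al$action
    if (al$action %in% c("kept", "flipped")) {
      base$beta_outcome <- al$beta
      base$se_outcome <- oc$se
      base$eaf_outcome <- al$eaf
    }
    base
  })
  rows$retained <- rows$action %in% c("kept", "flipped", "proxied")
  class(rows) <- c("harmonized_set", class(rows))
  rows
}

retained_effects <- function(h) {
  stopifnot(inherits(h, "harmonized_set") || is.data.frame(h))
  h <- h[h$retained, ]
  list(bx = h$beta_exposure, by = h$beta_outcome, sx = h$se_exposure,
       sy = h$se_outcome, snp = h$snp)
}

ivw_fit <- function(bx, by, sy, random_effects = TRUE) {
  n <- length(bx)
  if (n == 1) {
    return(list(estimate = by / bx, se = sy / abs(bx), n = 1))
  }
  w <- 1 / sy^2
  est <- sum(w * bx * by) / sum(w * bx^2)
  se <- sqrt(1 / sum(w * bx^2))
  if (random_effects && n > 1) {
    sigma <- sqrt(sum(w * (by - est * bx)^2) / (n - 1))
    se <- se * max(1, sigma)
  }
  list(estimate = est, se = se, n = n)
}

egger_fit <- function(bx, by, sy) {
  # orient so every exposure effect is positive, flipping outcomes with it
  s <- sign(bx); s[s == 0] <- 1
  bx <- bx * s; by <- by * s
  w <- 1 / sy^2
  fit <- stats::lm(by ~ bx, weights = w)
  sm <- summary(fit)
  sigma <- sm$sigma
  scale <- max(1, sigma) / sigma
  list(estimate = unname(stats::coef(fit)[2]),
       se = unname(sm$coefficients[2, 2]) * scale,
       intercept = unname(stats::coef(fit)[1]),
       # the plain weighted-LS se keeps the intercept t test exactly
       # calibrated under the no-pleiotropy null
       intercept_se = unname(sm$coefficients[1, 2]),
       df = length(bx) - 2)
}

weighted_median_est <- function(ratios, weights) {
  o <- order(ratios)
  ratios <- ratios[o]; weights <- weights[o]
  cw <- (cumsum(weights) - weights / 2) / sum(weights)
  if (cw[1] >= 0.5) return(ratios[1])
  below <- max(which(cw < 0.5))
  if (below == length(ratios)) return(ratios[length(ratios)])
  ratios[below] + (ratios[below + 1] - ratios[below]) *
    (0.5 - cw[below]) / (cw[below + 1] - cw[below])
}

#' Two-sample Mendelian randomization estimates
#'
#' Estimates the causal effect of the exposure on the outcome from a
#' harmonized instrument set.
#'
#' * `ivw`: weighted regression of outcome on exposure effects through
#'   the origin, weights `1/se_out^2`; with more than one SNP the
#'   standard error is inflated by `max(1, residual SD)` (multiplicative
#'   random effects; `random_effects = FALSE` for fixed effect). A single
#'   SNP gives the Wald ratio `by/bx` with `se = se_out/|bx|`.
#' * `egger`: the same regression with a free intercept after orienting
#'   exposure effects positive; the slope is robust to directional
#'   pleiotropy, which loads on the intercept. Needs >= 3 SNPs.
#' * `weighted_median`: weighted median of per-SNP Wald ratios (weights
#'   proportional to `bx^2/se_out^2`, cumulative-weight interpolation at
#'   0.5); its standard error comes from a seeded parametric bootstrap.
#'   Needs >= 3 SNPs. Consistent when at least half the weight is on
#'   valid instruments.
#'
#' @param h A [harmonize_gwas()] result (only retained SNPs are used).
#' @param method Methods to run (default all three).
#' @param random_effects Multiplicative random-effects IVW scaling?
#' @param n_boot Bootstrap draws for the weighted-median standard error.
#' @param seed Seed for the bootstrap.
#' @return Tibble of class `mr_result`, one row per method (`method`,
#'   `estimate`, `std_error`, `conf_low`, `conf_high`, `p_value`,
#'   `n_snp`, `odds_ratio`); the 95% CI is `estimate +/- 1.96 se`.
#' @export
mr_estimate <- function(h, method = c("ivw", "egger", "weighted_median"),
                        random_effects = TRUE, n_boot = 1000, seed = 1L) {
  method <- match.arg(method, several.ok = TRUE)
  e <- retained_effects(h)
  n <- length(e$bx)
  rows <- list()
  for (mth in method) {
    if (mth == "ivw") {
      if (n < 1) abort("IVW needs at least 1 SNP.")
      f <- ivw_fit(e$bx, e$by, e$sy, random_effects)
      p <- 2 * pnorm(-abs(f$estimate / f$se))
      est <- f$estimate; se <- f$se
    } else if (mth == "egger") {
      if (n < 3) abort("MR-Egger needs at least 3 SNPs.")
      f <- egger_fit(e$bx, e$by, e$sy)
      est <- f$estimate; se <- f$se
      p <- 2 * pt(-abs(est / se), f$df)
    } else {
      if (n < 3) abort("the weighted median needs at least 3 SNPs.")
      ratios <- e$by / e$bx
      wts <- e$bx^2 / e$sy^2
      est <- weighted_median_est(ratios, wts)
      set.seed(seed)
      boots <- vapply(seq_len(n_boot), function(i) {
        bx_b <- rnorm(n, e$bx, e$sx)
        by_b <- rnorm(n, e$by, e$sy)
        weighted_median_est(by_b / bx_b, bx_b^2 / e$sy^2)
      }, numeric(1))
      se <- sd(boots)
      p <- 2 * pnorm(-abs(est / se))
    }
    rows[[mth]] <- tibble(method = mth, estimate = est, std_error = se,
                          conf_low = est - 1.96 * se,
                          conf_high = est + 1.96 * se, p_value = p,
                          n_snp = n, odds_ratio = exp(est))
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("mr_result", class(out))
  out
}

#' Sensitivity analyses for a Mendelian randomization estimate
#'
#' Cochran's Q heterogeneity test over per-SNP Wald ratios
#' (`Q = sum w_i (theta_i - theta_IVW)^2`, `w_i = 1/se(theta_i)^2` with
#' the first-order `se(theta_i) = se_out/|bx|`; chi-square, df n-1); the
#' MR-Egger intercept t test for directional pleiotropy (df n-2); and a
#' leave-one-out table of IVW estimates with each SNP removed in turn.
#' Components whose SNP minimum is not met are returned as `NULL`.
#'
#' @param h A [harmonize_gwas()] result.
#' @param random_effects Passed to the leave-one-out IVW fits.
#' @return Object of class `mr_sensitivity`: list with `heterogeneity`
#'   (tibble `q`, `df`, `p_value`), `egger_intercept` (tibble `estimate`,
#'   `std_error`, `p_value`), `loo` (tibble `snp_dropped`, `estimate`,
#'   `std_error`, `p_value`).
#' @export
mr_sensitivity <- function(h, random_effects = TRUE) {
  e <- retained_effects(h)
  n <- length(e$bx)
  het <- NULL; egg <- NULL; loo <- NULL
  if (n >= 2) {
    theta <- e$by / e$bx
    w <- e$bx^2 / e$sy^2
    theta_ivw <- sum(w * theta) / sum(w)
    q <- sum(w * (theta - theta_ivw)^2)
    het <- tibble(q = q, df = n - 1,
                  p_value = pchisq(q, n - 1, lower.tail = FALSE))
  }
  if (n >= 3) {
    f <- egger_fit(e$bx, e$by, e$sy)
    tstat <- f$intercept / f$intercept_se
    egg <- tibble(estimate = f$intercept, std_error = f$intercept_se,
                  p_value = 2 * pt(-abs(tstat), f$df))
  }
  if (n >= 2) {
    loo <- purrr::map_dfr(seq_len(n), function(i) {
      f <- ivw_fit(e$bx[-i], e$by[-i], e$sy[-i], random_effects)
      tibble(snp_dropped = e$snp[i], estimate = f$estimate,
             std_error = f$se,
             p_value = 2 * pnorm(-abs(f$estimate / f$se)))
    })
  }
  structure(list(heterogeneity = het, egger_intercept = egg, loo = loo),
            class = "mr_sensitivity")
}
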