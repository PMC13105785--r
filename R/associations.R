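#' Filtering and transformation spec for association models
#'
#' Pins down the "default parameters" of the multivariable association
#' stage: features must be present (abundance above `min_abundance`) in at
#' least `min_prevalence` of samples; surviving features are total-sum
#' normalized per sample and log2-transformed after adding a per-feature
#' pseudocount equal to half the feature's minimum positive normalized
#' value.
#'
#' @param min_prevalence Minimum fraction of samples a feature must be
#'   detected in (default 0.1).
#' @param min_abundance Detection threshold on the raw abundance.
#' @return An object of class `transform_spec`.
#' @export
transform_spec <- function(min_prevalence = 0.1, min_abundance = 0) {
  check_fraction(min_prevalence, "min_prevalence")
  check_positive(min_abundance, "min_abundance", strict = FALSE)
  structure(list(min_prevalence = min_prevalence,
                 min_abundance = min_abundance),
            class = "transform_spec")
}

#' Filter and transform a feature table for linear association models
#'
#' Applies a [transform_spec()]: prevalence/abundance filtering, total-sum
#' normalization, then `log2(relative abundance + pseudocount)` with the
#' per-feature half-minimum-positive pseudocount. The transform is
#' strictly monotone in the raw value within a sample.
#'
#' @param table Samples-by-features tibble (with `sample` column) or
#'   matrix of non-negative abundances.
#' @param spec A [transform_spec()].
#' @return Tibble (`sample` + transformed features) with attributes
#'   `dropped` (features removed by the filters) and `n_nonzero`
#'   (per-feature detected-sample counts).
#' @export
filter_transform <- function(table, spec = transform_spec()) {
  if (!inherits(spec, "transform_spec")) {
    abort("`spec` must be created by transform_spec().")
  }
  m <- feature_matrix(table)
  if (any(m < 0)) abort("abundances must be non-negative.")
  detected <- m > spec$min_abundance
  prevalence <- colMeans(detected)
  keep <- prevalence >= spec$min_prevalence
  if (!any(keep)) abort("no feature passes the prevalence filter.")
  dropped <- colnames(m)[!keep]
  if (length(dropped)) {
    inform(sprintf("%d feature(s) failed the prevalence filter.",
                   length(dropped)))
  }
  n_nonzero <- colSums(m[, keep, drop = FALSE] > 0)
  rel <- m[, keep, drop = FALSE] / rowSums(m)
  pc <- apply(rel, 2, function(x) {
    pos <- x[x > 0]
    if (!length(pos)) 1e-6 else min(pos) / 2
  })
  tr <- log2(sweep(rel, 2, pc, "+"))
  out <- dplyr::bind_cols(tibble(sample = rownames(m)),
                          as_tibble(tr, .name_repair = "minimal"))
  attr(out, "dropped") <- dropped
  attr(out, "n_nonzero") <- n_nonzero
  out
}

#' Benjamini-Hochberg step-up adjusted p-values
#'
#' `q_i = min_{j >= rank(i)} p_(j) * m / j`, capped at 1; ties keep a
#' stable rank. Controls the false discovery rate under independence or
#' positive dependence.
#'
#' @param pvals Numeric vector of p-values in `[0, 1]`.
#' @return Numeric vector of q-values, same order as the input.
#' @export
#' @examples
#' bh_adjust(c(0.005, 0.04, 0.04, 0.8))
bh_adjust <- function(pvals) {
  if (!is.numeric(pvals) || anyNA(pvals) || any(pvals < 0 | pvals > 1)) {
    abort("`pvals` must be numbers in [0, 1].")
  }
  m <- length(pvals)
  if (m == 0) return(numeric())
  o <- order(pvals)
  q_sorted <- rev(cummin(rev(pvals[o] * m / seq_len(m))))
  pmin(q_sorted, 1)[order(o)]
}

#' Multivariable linear associations of features with clinical targets
#'
#' For each target variable, each (transformed) feature is regressed by
#' ordinary least squares on the target plus the adjustment covariates —
#' fixed effects only, because few repeated measurements per subject make
#' random-effect variances unstable. The target coefficient's t test gives
#' the p-value; q-values are Benjamini-Hochberg adjusted across features
#' separately per target, with significance declared at `q < q_threshold`
#' (default 0.25, the screening convention of the association tooling this
#' mirrors).
#'
#' @param transformed Tibble from [filter_transform()] (`sample` +
#'   feature columns).
#' @param metadata Per-sample metadata tibble (`sample` + variables).
#' @param targets Character vector of metadata columns to test. A
#'   two-level categorical target is coded 0/1 (second level = 1).
#' @param covariates Character vector of adjustment columns.
#' @param q_threshold Significance threshold on the q-value.
#' @return Tibble of class `toxbiome_associations` (`feature`, `target`,
#'   `estimate`, `std_error`, `statistic`, `p_value`, `q_value`, `n`,
#'   `n_nonzero`, `significant`), sorted by q then p.
#' @export
fit_associations <- function(transformed, metadata, targets,
                             covariates = character(), q_threshold = 0.25) {
  metadata <- as_tibble(metadata)
  dat <- dplyr::inner_join(as_tibble(transformed), metadata, by = "sample")
  feats <- setdiff(names(as_tibble(transformed)), "sample")
  vars <- c(targets, covariates)
  miss <- setdiff(vars, names(metadata))
  if (length(miss)) {
    abort(sprintf("metadata columns not found: %s",
                  paste(miss, collapse = ", ")))
  }
  cc <- complete.cases(dat[vars])
  if (!all(cc)) {
    inform(sprintf("%d sample(s) dropped for missing covariates.",
                   sum(!cc)))
    dat <- dat[cc, ]
  }
  y_all <- as.matrix(dat[feats])
  nnz <- attr(transformed, "n_nonzero")

  res <- purrr::map_dfr(targets, function(tg) {
    rhs <- paste(c(tg, covariates), collapse = " + ")
    x <- stats::model.matrix(stats::as.formula(paste("~", rhs)), data = dat)
    if (qr(x)$rank < ncol(x)) {
      abort(sprintf("design for target `%s` is rank-deficient (collinear).",
                    tg))
    }
    # the design is shared across features: one QR, all features at once
    fit <- stats::lm.fit(x, y_all)
    coefs <- fit$coefficients
    rss <- colSums(as.matrix(fit$residuals)^2)
    df_res <- nrow(x) - ncol(x)
    if (df_res <= 0) abort("not enough samples for the model.")
    xtx_inv <- solve(crossprod(x))
    tcols <- grep(paste0("^", tg), colnames(x), value = TRUE)
    tcol <- tcols[1] # first non-reference level of the target
    j <- match(tcol, colnames(x))
    se <- sqrt(rss / df_res * xtx_inv[j, j])
    est <- coefs[j, ]
    tstat <- ifelse(se > 0, est / se, 0)
    p <- 2 * pt(-abs(tstat), df_res)
    p[se == 0] <- 1
    tibble(feature = feats, target = tg, estimate = unname(est),
           std_error = unname(se), statistic = unname(tstat),
           p_value = unname(p), q_value = bh_adjust(p), n = nrow(x),
           n_nonzero = if (is.null(nnz)) colSums(y_all > min(y_all)) else
             unname(nnz[feats]))
  })
  res$significant <- res$q_value < q_threshold
  res <- dplyr::arrange(res, .data$target, .data$q_value, .data$p_value)
  class(res) <- c("toxbiome_associations", class(res))
  res
}

#' LEfSe-style differential-abundance screen
#'
#' Two-stage screen for features enriched in one class: a Kruskal-Wallis
#' test across classes at `kw_alpha`, then an effect size on abundances
#' rescaled per sample to sum to 1e6 —
#' `LDA = log10(max(|difference of class means|, 1))` — optionally
#' averaged over seeded 2/3 subsamples. Features are reported when they
#' pass both the p and the effect-size threshold; the enriched class is
#' the one with the larger mean. The floor of 1 inside the log10 prevents
#' negative infinities for tiny differences. The canonical method's
#' subclass (one-against-all Wilcoxon) stage is omitted: this design has
#' no subclass.
#'
#' @param table Samples-by-features counts/abundances (tibble with
#'   `sample` column, or matrix).
#' @param classes Per-sample class labels: either a vector aligned with
#'   the table rows or a two-column tibble (`sample`, `class`).
#' @param kw_alpha Kruskal-Wallis significance level.
#' @param lda_threshold Minimum log10 effect size to report.
#' @param n_boot Number of 2/3 subsamples to average the effect over;
#'   0 disables bootstrapping (deterministic).
#' @param seed Seed for the subsampling.
#' @return Tibble of class `toxbiome_lefse` (`feature`, `enriched`,
#'   `kw_p`, `lda`), effect-size descending; only reported features.
#' @export
lefse_like <- function(table, classes, kw_alpha = 0.05, lda_threshold = 2.0,
                       n_boot = 30, seed = 1L) {
  m <- feature_matrix(table)
  if (is.data.frame(classes)) {
    idx <- match(rownames(m), classes$sample)
    if (anyNA(idx)) abort("`classes` must cover every sample.")
    cls <- factor(classes$class[idx])
  } else {
    if (length(classes) != nrow(m)) {
      abort("`classes` must have one label per sample.")
    }
    cls <- factor(classes)
  }
  if (nlevels(cls) < 2) abort("need at least two classes.")
  if (any(table(cls) < 3)) abort("every class needs at least 3 samples.")
  tot <- rowSums(m)
  scaled <- m / ifelse(tot == 0, 1, tot) * 1e6

  kw_p <- apply(m, 2, function(x) {
    if (length(unique(x)) == 1) return(1)
    suppressWarnings(stats::kruskal.test(x, cls)$p.value)
  })

  effect_of <- function(rows) {
    mu <- rowsum(scaled[rows, , drop = FALSE], cls[rows]) /
      as.vector(table(cls[rows]))
    # max pairwise separation of class means, per feature
    apply(mu, 2, function(v) max(stats::dist(v)))
  }
  if (n_boot > 0) {
    set.seed(seed)
    eff <- rowMeans(vapply(seq_len(n_boot), function(i) {
      rows <- unlist(lapply(split(seq_len(nrow(m)), cls), function(ix) {
        sample(ix, max(3, ceiling(2 * length(ix) / 3)))
      }), use.names = FALSE)
      effect_of(rows)
    }, numeric(ncol(m))))
  } else {
    eff <- effect_of(seq_len(nrow(m)))
  }
  lda <- log10(pmax(eff, 1))
  mu_all <- rowsum(scaled, cls) / as.vector(table(cls))
  enriched <- rownames(mu_all)[apply(mu_all, 2, which.max)]

  out <- tibble(feature = colnames(m), enriched = enriched,
                kw_p = unname(kw_p), lda = unname(lda))
  out <- out[out$kw_p < kw_alpha & out$lda >= lda_threshold, ]
  out <- dplyr::arrange(out, dplyr::desc(.data$lda))
  class(out) <- c("toxbiome_lefse", class(out))
  out
}
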