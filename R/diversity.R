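#' Alpha diversity per sample
#'
#' Counts are total-sum normalized to relative abundances `p_i` per sample
#' (no rarefaction, for determinism); Shannon is `-sum(p_i log p_i)` with
#' the natural log and zeros excluded, inverse Simpson is `1 / sum(p_i^2)`.
#' Empty samples get `NA` with a warning.
#'
#' @param table Samples-by-features counts: a tibble with a `sample`
#'   column, or a numeric matrix with sample rownames.
#' @param metric Which indices to compute.
#' @return Tibble with `sample` and one column per requested metric.
#' @export
#' @examples
#' alpha_diversity(tibble::tibble(sample = "a", t1 = 5, t2 = 5, t3 = 5,
#'                                t4 = 5))
alpha_diversity <- function(table, metric = c("shannon", "inv_simpson")) {
  metric <- match.arg(metric, several.ok = TRUE)
  m <- feature_matrix(table)
  if (any(m < 0)) abort("counts must be non-negative.")
  tot <- rowSums(m)
  empty <- tot == 0
  if (any(empty)) {
    warn(sprintf("empty samples get NA diversity: %s",
                 paste(rownames(m)[empty], collapse = ", ")))
  }
  out <- tibble(sample = rownames(m))
  if ("shannon" %in% metric) {
    sh <- vegan::diversity(m, index = "shannon", base = exp(1))
    sh[empty] <- NA_real_
    out$shannon <- unname(sh)
  }
  if ("inv_simpson" %in% metric) {
    is1 <- suppressWarnings(vegan::diversity(m, index = "invsimpson"))
    is1[empty] <- NA_real_
    out$inv_simpson <- unname(is1)
  }
  out
}

#' Bray-Curtis dissimilarity between samples
#'
#' Computed on total-sum-normalized relative abundances:
#' `d(x, y) = sum |x_i - y_i| / sum (x_i + y_i)`, which lies in `[0, 1]`.
#'
#' @inheritParams alpha_diversity
#' @return A [stats::dist] object labeled by sample id.
#' @export
bray_curtis <- function(table) {
  m <- feature_matrix(table)
  if (any(m < 0)) abort("abundances must be non-negative.")
  tot <- rowSums(m)
  if (sum(tot == 0) >= 2) {
    abort("Bray-Curtis undefined between two all-zero samples.")
  }
  rel <- m / ifelse(tot == 0, 1, tot)
  vegan::vegdist(rel, method = "bray")
}

#' Principal coordinates analysis of a dissimilarity matrix
#'
#' Classical metric ordination: Gower double-centering of `-d^2/2` followed
#' by an eigendecomposition. Negative eigenvalues (from non-Euclidean
#' dissimilarities such as Bray-Curtis) are reported, not corrected, unless
#' the Cailliez correction is requested; coordinates exist only for
#' positive eigenvalues, and the proportion explained is relative to the
#' sum of positive eigenvalues.
#'
#' @param d A [stats::dist] or symmetric zero-diagonal matrix.
#' @param correction `"none"` (default) or `"cailliez"`.
#' @return An object of class `toxbiome_pcoa`: list with `coordinates`
#'   (tibble: `sample`, `axis1`, ...), `eigenvalues` (descending), and
#'   `prop_explained`.
#' @export
pcoa_ord <- function(d, correction = c("none", "cailliez")) {
  correction <- match.arg(correction)
  if (!inherits(d, "dist")) {
    m <- as.matrix(d)
    if (!isSymmetric(unname(m)) || any(diag(m) != 0)) {
      abort("`d` must be symmetric with a zero diagonal.")
    }
    d <- stats::as.dist(m)
  }
  res <- ape::pcoa(d, correction = if (correction == "cailliez") "cailliez"
                   else "none")
  vals <- if (correction == "cailliez" && !is.null(res$values$Corr_eig)) {
    res$values$Corr_eig
  } else {
    res$values$Eigenvalues
  }
  vecs <- if (correction == "cailliez" && !is.null(res$vectors.cor)) {
    res$vectors.cor
  } else {
    res$vectors
  }
  k <- ncol(vecs)
  coords <- as_tibble(vecs, .name_repair = "minimal")
  names(coords) <- paste0("axis", seq_len(k))
  coords <- dplyr::bind_cols(tibble(sample = attr(d, "Labels") %||%
                                      rownames(as.matrix(d))), coords)
  pos <- vals[vals > 0]
  structure(
    list(coordinates = coords,
         eigenvalues = sort(vals, decreasing = TRUE),
         prop_explained = pmax(sort(vals, decreasing = TRUE), 0) / sum(pos)),
    class = "toxbiome_pcoa")
}

#' Distance-based permutational multivariate ANOVA (PERMANOVA)
#'
#' Sequential (type-I) partitioning of the distance-based total sum of
#' squares over the model terms, with pseudo-F statistics and permutation
#' p-values `p = (1 + #{F_perm >= F_obs}) / (1 + n_perm)` from seeded
#' whole-row permutations. Delegates the partitioning to
#' [vegan::adonis2()]; term order matters under sequential sums of
#' squares, and marginal sums of squares are available with
#' `by = "margin"`.
#'
#' @param d Dissimilarities ([stats::dist]) over samples.
#' @param metadata Tibble with a `sample` column covering all samples in
#'   `d` plus the term columns.
#' @param terms Character vector of metadata columns, in model order.
#' @param n_perm Number of permutations (>= 1).
#' @param seed Integer seed for the permutation stream.
#' @param by `"terms"` (sequential, default) or `"margin"`.
#' @return Tibble of class `toxbiome_permanova`: one row per term plus
#'   `Residual` and `Total` (`term`, `df`, `sum_sq`, `r_squared`,
#'   `pseudo_f`, `p_value`, `n_perm`).
#' @export
permanova <- function(d, metadata, terms, n_perm = 999, seed = 1L,
                      by = c("terms", "margin")) {
  by <- match.arg(by)
  if (!inherits(d, "dist")) d <- stats::as.dist(as.matrix(d))
  if (n_perm < 1) abort("`n_perm` must be >= 1.")
  ids <- attr(d, "Labels")
  metadata <- as_tibble(metadata)
  if (is.null(ids)) {
    # unlabeled distances: rows are taken in order
    if (nrow(metadata) != attr(d, "Size")) {
      abort("`metadata` must have one row per sample in `d`.")
    }
  } else {
    if (!all(ids %in% metadata$sample)) {
      abort("`metadata` must cover every sample in `d`.")
    }
    metadata <- metadata[match(ids, metadata$sample), , drop = FALSE]
  }
  for (tm in terms) {
    if (!tm %in% names(metadata)) abort(sprintf("term `%s` not found.", tm))
    if (dplyr::n_distinct(metadata[[tm]]) < 2) {
      abort(sprintf("term `%s` has a single level.", tm))
    }
  }
  fml <- stats::as.formula(paste("d ~", paste(terms, collapse = " + ")))
  env <- new.env(parent = environment())
  assign("d", d, envir = env)
  environment(fml) <- env
  set.seed(seed)
  fit <- vegan::adonis2(fml, data = as.data.frame(metadata),
                        permutations = n_perm, by = by)
  out <- tibble(term = rownames(fit), df = fit$Df, sum_sq = fit$SumOfSqs,
                r_squared = fit$R2, pseudo_f = fit$F,
                p_value = fit$`Pr(>F)`, n_perm = n_perm)
  class(out) <- c("toxbiome_permanova", class(out))
  out
}

#' Scheirer-Ray-Hare test: two-factor ANOVA on ranks
#'
#' Rank-based extension of the Kruskal-Wallis test to a two-factor design
#' with interaction. All `N` observations are mid-ranked together; a
#' sequential (type-I) two-way ANOVA on the ranks provides the sums of
#' squares for factor A, factor B, and A:B, and each effect's statistic is
#' `H = SS_effect / MS_total`, where `MS_total` is the variance of the
#' mid-ranks — equivalently `H = [SS_effect / (N(N+1)/12)] / D` with the
#' tie-correction factor `D = 1 - sum(t^3 - t) / (N^3 - N)`. P-values come
#' from the chi-square distribution with `(a-1)`, `(b-1)`, and
#' `(a-1)(b-1)` degrees of freedom. When one factor has a single level the
#' other factor's H reduces exactly to the tie-corrected Kruskal-Wallis
#' statistic.
#'
#' @param data Tibble holding the response and both factors.
#' @param value,factor_a,factor_b Column names (strings) of the response
#'   and the two factors.
#' @return Tibble of class `toxbiome_srh` (`term`, `df`, `h`, `p_value`,
#'   `tie_correction`).
#' @export
scheirer_ray_hare <- function(data, value, factor_a, factor_b) {
  data <- as_tibble(data)
  for (cn in c(value, factor_a, factor_b)) {
    if (!cn %in% names(data)) abort(sprintf("column `%s` not found.", cn))
  }
  y <- data[[value]]
  a <- factor(data[[factor_a]])
  b <- factor(data[[factor_b]])
  if (anyNA(y) || anyNA(a) || anyNA(b)) abort("missing values not allowed.")
  if (nlevels(a) < 2 && nlevels(b) < 2) {
    abort("at least one factor needs 2 or more levels.")
  }
  # a constant factor collapses the design to one-way ANOVA on ranks, i.e.
  # the (tie-corrected) Kruskal-Wallis test on the remaining factor
  collapse <- nlevels(a) < 2 || nlevels(b) < 2
  if (collapse) {
    inform(sprintf("factor `%s` has a single level; reducing to one-way.",
                   if (nlevels(a) < 2) factor_a else factor_b))
  }
  n <- length(y)
  r <- rank(y)  # mid-ranks
  tie_tab <- table(y)
  d_corr <- 1 - sum(tie_tab^3 - tie_tab) / (n^3 - n)
  df_a <- nlevels(a) - 1
  df_b <- nlevels(b) - 1
  df_ab <- df_a * df_b
  if (d_corr <= 0) {
    warn("all values tied; H set to 0, p to 1.")
    out <- tibble(term = c(factor_a, factor_b,
                           paste0(factor_a, ":", factor_b)),
                  df = c(df_a, df_b, df_ab), h = 0, p_value = 1,
                  tie_correction = 0)
    class(out) <- c("toxbiome_srh", class(out))
    return(out)
  }
  ms_total <- sum((r - mean(r))^2) / (n - 1) # = D * N(N+1)/12
  if (collapse) {
    f <- if (nlevels(a) < 2) b else a
    nm <- if (nlevels(a) < 2) factor_b else factor_a
    ss <- stats::anova(stats::lm(r ~ f))$`Sum Sq`[1]
    df <- nlevels(f) - 1
    h <- ss / ms_total
    out <- tibble(term = nm, df = df, h = h,
                  p_value = pchisq(h, df, lower.tail = FALSE),
                  tie_correction = d_corr)
    class(out) <- c("toxbiome_srh", class(out))
    return(out)
  }
  ss <- stats::anova(stats::lm(r ~ a * b))$`Sum Sq`
  h <- ss[1:3] / ms_total
  df <- c(df_a, df_b, df_ab)
  out <- tibble(term = c(factor_a, factor_b,
                         paste0(factor_a, ":", factor_b)),
                df = df, h = h, p_value = pchisq(h, df, lower.tail = FALSE),
                tie_correction = d_corr)
  class(out) <- c("toxbiome_srh", class(out))
  out
}
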