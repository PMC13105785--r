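#' @export
tidy.toxbiome_pcoa <- function(x, ...) x$coordinates

#' @export
glance.toxbiome_pcoa <- function(x, ...) {
  tibble(n_axes = ncol(x$coordinates) - 1L,
         prop_axis1 = x$prop_explained[1],
         prop_axis2 = x$prop_explained[2],
         negative_eigenvalues = sum(x$eigenvalues < 0))
}

#' @export
tidy.toxbiome_permanova <- function(x, ...) as_tibble(x)

#' @export
glance.toxbiome_permanova <- function(x, ...) {
  terms <- x[!x$term %in% c("Residual", "Total"), ]
  tibble(n_terms = nrow(terms), r_squared_model = sum(terms$r_squared),
         n_perm = x$n_perm[1])
}

#' @export
tidy.toxbiome_srh <- function(x, ...) as_tibble(x)

#' @export
tidy.mr_result <- function(x, ...) as_tibble(x)

#' @export
glance.mr_result <- function(x, ...) {
  tibble(n_methods = nrow(x), n_snp = x$n_snp[1],
         sign_agreement = dplyr::n_distinct(sign(x$estimate)) == 1)
}

#' @export
tidy.mr_sensitivity <- function(x, ...) {
  dplyr::bind_rows(
    if (!is.null(x$heterogeneity)) {
      tibble(component = "cochran_q", statistic = x$heterogeneity$q,
             p_value = x$heterogeneity$p_value)
    },
    if (!is.null(x$egger_intercept)) {
      tibble(component = "egger_intercept",
             statistic = x$egger_intercept$estimate,
             p_value = x$egger_intercept$p_value)
    })
}

#' @export
tidy.cooccurrence_network <- function(x, ...) x$edges

#' @export
glance.cooccurrence_network <- function(x, ...) {
  tibble(n_nodes = nrow(x$nodes), n_edges = nrow(x$edges),
         n_samples = x$n_samples,
         prop_positive = if (nrow(x$edges)) {
           mean(x$edges$sign == "positive")
         } else {
           NA_real_
         })
}

#' @export
print.cooccurrence_network <- function(x, ...) {
  cat(sprintf("Co-occurrence network: %d nodes, %d edges (%d samples)\n",
              nrow(x$nodes), nrow(x$edges), x$n_samples))
  invisible(x)
}

#' @export
print.toxbiome_pcoa <- function(x, ...) {
  cat(sprintf("PCoA: %d samples, %d axes; axis 1-2 explain %.1f%% + %.1f%%\n",
              nrow(x$coordinates), ncol(x$coordinates) - 1L,
              100 * x$prop_explained[1], 100 * x$prop_explained[2]))
  invisible(x)
}

#' @export
print.mr_sensitivity <- function(x, ...) {
  if (!is.null(x$heterogeneity)) {
    cat(sprintf("Cochran's Q = %.3f (df %d), p = %.3g\n",
                x$heterogeneity$q, x$heterogeneity$df,
                x$heterogeneity$p_value))
  }
  if (!is.null(x$egger_intercept)) {
    cat(sprintf("Egger intercept = %.4f (se %.4f), p = %.3g\n",
                x$egger_intercept$estimate, x$egger_intercept$std_error,
                x$egger_intercept$p_value))
  }
  if (!is.null(x$loo)) {
    cat(sprintf("Leave-one-out IVW range: [%.4f, %.4f] over %d SNPs\n",
                min(x$loo$estimate), max(x$loo$estimate), nrow(x$loo)))
  }
  invisible(x)
}
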