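#' Build a microbial co-occurrence network
#'
#' Edges are significant pairwise Spearman correlations between the
#' relative abundances of prevalent taxa: p-values (t approximation; an
#' exact zero for |rho| = 1) are Benjamini-Hochberg adjusted across all
#' tested pairs, and an edge is retained when `q <= q_max` and
#' `|rho| >= rho_min`. Edge retention is monotone: raising `rho_min` or
#' lowering `q_max` never adds edges. Fewer than 10 samples is refused —
#' rank correlations are too unstable below that.
#'
#' @param table Samples-by-taxa counts (tibble with `sample` column, or
#'   matrix).
#' @param min_prevalence Minimum fraction of samples a taxon must appear
#'   in (> 0) to enter the network.
#' @param rho_min Minimum absolute Spearman correlation for an edge.
#' @param q_max Maximum BH q-value for an edge.
#' @return An object of class `cooccurrence_network`: list with `nodes`
#'   (`taxon`, `prevalence`, `degree`), `edges` (`from`, `to`, `rho`,
#'   `sign`, `p_value`, `q_value`) and `n_samples`.
#' @export
build_network <- function(table, min_prevalence = 0.2, rho_min = 0.3,
                          q_max = 0.05) {
  m <- feature_matrix(table)
  if (nrow(m) < 10) {
    abort("co-occurrence networks need at least 10 samples.")
  }
  rel <- m / rowSums(m)
  prevalence <- colMeans(m > 0)
  keep <- prevalence >= min_prevalence
  rel <- rel[, keep, drop = FALSE]
  taxa <- colnames(rel)
  n <- nrow(rel)
  k <- length(taxa)
  edges <- tibble(from = character(), to = character(), rho = double(),
                  sign = character(), p_value = double(),
                  q_value = double())
  if (k >= 2) {
    rho <- stats::cor(rel, method = "spearman")
    ut <- upper.tri(rho)
    pair <- which(ut, arr.ind = TRUE)
    r <- rho[ut]
    tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
    p <- 2 * pt(-abs(tstat), n - 2)
    p[abs(r) >= 1 - 1e-12] <- 0
    q <- bh_adjust(p)
    sel <- q <= q_max & abs(r) >= rho_min
    edges <- tibble(from = taxa[pair[sel, 1]], to = taxa[pair[sel, 2]],
                    rho = r[sel],
                    sign = ifelse(r[sel] >= 0, "positive", "negative"),
                    p_value = p[sel], q_value = q[sel])
  }
  degree <- setNames(rep(0L, k), taxa)
  if (nrow(edges)) {
    dtab <- table(c(edges$from, edges$to))
    degree[names(dtab)] <- as.integer(dtab)
  }
  structure(
    list(nodes = tibble(taxon = taxa,
                        prevalence = unname(prevalence[keep]),
                        degree = unname(degree)),
         edges = edges, n_samples = n),
    class = "cooccurrence_network")
}

as_igraph <- function(net) {
  g <- igraph::graph_from_data_frame(
    net$edges[c("from", "to")], directed = FALSE,
    vertices = net$nodes["taxon"])
  g
}

#' Normalized betweenness centrality of network nodes
#'
#' Shortest-path betweenness on the unweighted, undirected edge set,
#' normalized by `(n-1)(n-2)/2`; isolated nodes score 0.
#'
#' @param net A [build_network()] result.
#' @return Tibble (`taxon`, `betweenness`).
#' @export
node_betweenness <- function(net) {
  stopifnot(inherits(net, "cooccurrence_network"))
  g <- as_igraph(net)
  b <- igraph::betweenness(g, directed = FALSE, normalized = TRUE)
  tibble(taxon = names(b), betweenness = unname(b))
}

#' Rank taxa driving the shift between two co-occurrence networks
#'
#' A NetShift-inspired (not the published NESH formula, which is not
#' reproduced here) driver score for each taxon present in both networks:
#' the neighbor shift is the Jaccard distance between its two neighbor
#' sets, `1 - |N_low ∩ N_high| / |N_low ∪ N_high|` (0 when both are
#' empty); the betweenness delta is `B_high - B_low` (normalized
#' betweenness in each network); and the combined score is
#' `neighbor_shift * max(delta, 0)` rescaled to `[0, 1]` over the nodes.
#' Drivers are flagged above a combined-score quantile and require a
#' positive betweenness increase.
#'
#' @param net_low,net_high [build_network()] results for the low- and
#'   high-toxicity groups (same taxonomy space).
#' @param driver_quantile Quantile of the combined score above which a
#'   node is flagged (default 0.9).
#' @return Tibble of class `toxbiome_drivers` (`taxon`,
#'   `betweenness_low`, `betweenness_high`, `delta_betweenness`,
#'   `neighbor_shift`, `driver_score`, `driver`), score descending.
#' @export
driver_scores <- function(net_low, net_high, driver_quantile = 0.9) {
  stopifnot(inherits(net_low, "cooccurrence_network"),
            inherits(net_high, "cooccurrence_network"))
  shared <- intersect(net_low$nodes$taxon, net_high$nodes$taxon)
  if (!length(shared)) {
    warn("node sets are disjoint; no driver scores.")
    out <- tibble(taxon = character(), betweenness_low = double(),
                  betweenness_high = double(),
                  delta_betweenness = double(), neighbor_shift = double(),
                  driver_score = double(), driver = logical())
    class(out) <- c("toxbiome_drivers", class(out))
    return(out)
  }
  nbrs <- function(net) {
    nb <- lapply(setNames(net$nodes$taxon, net$nodes$taxon),
                 function(x) character())
    for (i in seq_len(nrow(net$edges))) {
      u <- net$edges$from[i]; v <- net$edges$to[i]
      nb[[u]] <- c(nb[[u]], v)
      nb[[v]] <- c(nb[[v]], u)
    }
    nb
  }
  nb_lo <- nbrs(net_low)
  nb_hi <- nbrs(net_high)
  b_lo <- setNames(node_betweenness(net_low)$betweenness,
                   net_low$nodes$taxon)
  b_hi <- setNames(node_betweenness(net_high)$betweenness,
                   net_high$nodes$taxon)
  shift <- vapply(shared, function(x) {
    u <- union(nb_lo[[x]], nb_hi[[x]])
    if (!length(u)) return(0)
    1 - length(intersect(nb_lo[[x]], nb_hi[[x]])) / length(u)
  }, numeric(1))
  delta <- b_hi[shared] - b_lo[shared]
  raw <- shift * pmax(delta, 0)
  score <- if (max(raw) > 0) raw / max(raw) else raw
  flag <- raw > 0 & score >= quantile(score, driver_quantile)
  out <- tibble(taxon = shared, betweenness_low = unname(b_lo[shared]),
                betweenness_high = unname(b_hi[shared]),
                delta_betweenness = unname(delta),
                neighbor_shift = unname(shift),
                driver_score = unname(score), driver = unname(flag))
  out <- dplyr::arrange(out, dplyr::desc(.data$driver_score))
  class(out) <- c("toxbiome_drivers", class(out))
  out
}
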