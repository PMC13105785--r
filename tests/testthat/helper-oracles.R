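# Independent brute-force oracles used across the suite. These must stay
# naive re-derivations: they never call the code paths they check.

# two-sided Fisher p by full enumeration of the hypergeometric support
fisher_enum_p <- function(m) {
  r1 <- sum(m[1, ]); r2 <- sum(m[2, ]); c1 <- sum(m[, 1])
  ks <- max(0, c1 - r2):min(r1, c1)
  probs <- vapply(ks, function(k) {
    exp(lchoose(r1, k) + lchoose(r2, c1 - k) - lchoose(r1 + r2, c1))
  }, numeric(1))
  obs <- probs[ks == m[1, 1]]
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# two-proportion z statistic (pooled); its square is the Pearson chi-square
two_prop_z <- function(m) {
  n1 <- sum(m[1, ]); n2 <- sum(m[2, ])
  p1 <- m[1, 1] / n1; p2 <- m[2, 1] / n2
  pp <- (m[1, 1] + m[2, 1]) / (n1 + n2)
  (p1 - p2) / sqrt(pp * (1 - pp) * (1 / n1 + 1 / n2))
}

# grade one lab value through threshold bands, week by week, then take max
grade_oracle <- function(values, bands) {
  g <- vapply(values, function(v) {
    bands$grade[which(v >= bands$lower & v < bands$upper)]
  }, numeric(1))
  max(g)
}

# PERMANOVA one-way pseudo-F from squared distances (direct partition)
permanova_f_oracle <- function(dm, groups) {
  n <- nrow(dm)
  ss_total <- sum(dm[upper.tri(dm)]^2) / n
  ss_within <- 0
  for (g in unique(groups)) {
    idx <- which(groups == g)
    sub <- dm[idx, idx, drop = FALSE]
    ss_within <- ss_within + sum(sub[upper.tri(sub)]^2) / length(idx)
  }
  a <- length(unique(groups))
  ((ss_total - ss_within) / (a - 1)) / (ss_within / (n - a))
}

# exhaustive permutations of 1..n (n small)
all_perms <- function(n) {
  if (n == 1) return(matrix(1, 1, 1))
  sub <- all_perms(n - 1)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- setdiff(seq_len(n), i)
    cbind(i, matrix(rest[sub], nrow(sub)))
  }))
}

# normalized betweenness by explicit shortest-path enumeration (<= 8 nodes)
betweenness_oracle <- function(edges, nodes) {
  adj <- lapply(setNames(nodes, nodes), function(x) character())
  for (i in seq_len(nrow(edges))) {
    u <- edges$from[i]; v <- edges$to[i]
    adj[[u]] <- c(adj[[u]], v); adj[[v]] <- c(adj[[v]], u)
  }
  paths_between <- function(s, t) {
    # all shortest s-t paths via BFS layering + DFS
    dist <- setNames(rep(Inf, length(nodes)), nodes)
    dist[s] <- 0
    queue <- s
    while (length(queue)) {
      cur <- queue[1]; queue <- queue[-1]
      for (nb in adj[[cur]]) {
        if (is.infinite(dist[nb])) {
          dist[nb] <- dist[cur] + 1
          queue <- c(queue, nb)
        }
      }
    }
    if (is.infinite(dist[t])) return(list())
    walk <- function(v) {
      if (v == s) return(list(s))
      preds <- adj[[v]][dist[adj[[v]]] == dist[v] - 1]
      unlist(lapply(preds, function(p) {
        lapply(walk(p), function(pth) c(pth, v))
      }), recursive = FALSE)
    }
    walk(t)
  }
  b <- setNames(rep(0, length(nodes)), nodes)
  for (i in seq_along(nodes)) for (j in seq_along(nodes)) {
    if (i >= j) next
    ps <- paths_between(nodes[i], nodes[j])
    if (!length(ps)) next
    for (p in ps) {
      inner <- setdiff(p, c(nodes[i], nodes[j]))
      b[inner] <- b[inner] + 1 / length(ps)
    }
  }
  n <- length(nodes)
  b / ((n - 1) * (n - 2) / 2)
}

# convenience: samples-by-features tibble from a plain matrix
ft <- function(m, ids = sprintf("s%02d", seq_len(nrow(m)))) {
  colnames(m) <- colnames(m) %||% sprintf("f%02d", seq_len(ncol(m)))
  dplyr::bind_cols(tibble::tibble(sample = ids),
                   tibble::as_tibble(m, .name_repair = "minimal"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# minimal harmonized set built directly from effect vectors
fake_harmonized <- function(bx, by, sx = rep(0.02, length(bx)),
                            sy = rep(0.02, length(bx))) {
  h <- tibble::tibble(
    snp = sprintf("rs%03d", seq_along(bx)),
    effect_allele = "A", other_allele = "G",
    beta_exposure = bx, se_exposure = sx, eaf_exposure = 0.3,
    beta_outcome = by, se_outcome = sy, eaf_outcome = 0.3,
    action = "kept", proxy_snp = NA_character_, retained = TRUE)
  class(h) <- c("harmonized_set", class(h))
  h
}
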