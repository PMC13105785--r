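test_that("alpha diversity matches closed forms and the hand formula", {
  uni <- ft(matrix(c(5, 5, 5, 5), 1))
  a <- alpha_diversity(uni)
  expect_equal(a$shannon, log(4), tolerance = 1e-12)
  expect_equal(a$inv_simpson, 4, tolerance = 1e-12)

  single <- ft(matrix(c(9, 0, 0), 1))
  a1 <- alpha_diversity(single)
  expect_equal(a1$shannon, 0)
  expect_equal(a1$inv_simpson, 1)

  p <- c(6, 2, 2) / 10
  a2 <- alpha_diversity(ft(matrix(c(6, 2, 2), 1)))
  expect_equal(a2$shannon, -sum(p * log(p)), tolerance = 1e-12)
  expect_equal(a2$inv_simpson, 1 / sum(p^2), tolerance = 1e-12)

  expect_warning(ae <- alpha_diversity(ft(rbind(c(1, 2, 3), c(0, 0, 0)))),
                 "empty")
  expect_true(is.na(ae$shannon[2]))
})

test_that("alpha diversity invariants: uniform maximum, inv-Simpson range", {
  set.seed(5)
  for (i in 1:20) {
    k <- sample(3:12, 1)
    counts <- rmultinom(1, 500, prob = runif(k))[, 1] + 1
    a <- alpha_diversity(ft(matrix(counts, 1)))
    expect_lte(a$shannon, log(k) + 1e-12)
    expect_gte(a$inv_simpson, 1)
    expect_lte(a$inv_simpson, k + 1e-12)
  }
})

test_that("bray_curtis matches hand values and is a proper dissimilarity", {
  m <- rbind(c(6, 2), c(2, 2), c(6, 2), c(0, 7), c(5, 0))
  d <- as.matrix(bray_curtis(ft(m)))
  expect_equal(d["s01", "s02"], 0.25, tolerance = 1e-12)
  expect_equal(d["s01", "s03"], 0) # identical composition
  expect_equal(d["s04", "s05"], 1) # disjoint support
  expect_true(all(d >= 0 & d <= 1))
  expect_equal(d, t(d))
  expect_true(all(diag(d) == 0))
  expect_error(bray_curtis(ft(rbind(c(0, 0), c(0, 0), c(1, 2)))),
               "all-zero")
})

test_that("pcoa recovers collinear configurations and the trace identity", {
  x <- c(0, 1, 3, 7, 8)
  d <- dist(x)
  ord <- pcoa_ord(d)
  # one informative axis; its coordinates reproduce the line up to
  # sign/translation
  ax1 <- ord$coordinates$axis1
  expect_equal(abs(cor(ax1, x)), 1, tolerance = 1e-9)
  expect_equal(as.matrix(dist(ax1)), unname(as.matrix(d)),
               tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(ord$prop_explained[1], 1, tolerance = 1e-9)

  d2 <- dist(c(0, 3))
  ord2 <- pcoa_ord(d2)
  expect_equal(max(ord2$eigenvalues), 9 / 2, tolerance = 1e-10)

  # trace identity on a Bray-Curtis matrix: sum of eigenvalues equals the
  # trace of the Gower-centered -d^2/2 matrix
  set.seed(8)
  m <- matrix(rpois(60, 20), nrow = 6)
  db <- bray_curtis(ft(m))
  a <- -as.matrix(db)^2 / 2
  n <- nrow(a)
  j <- diag(n) - matrix(1 / n, n, n)
  b <- j %*% a %*% j
  ord3 <- pcoa_ord(db)
  expect_equal(sum(ord3$eigenvalues), sum(diag(b)), tolerance = 1e-8)
  expect_equal(ord3$eigenvalues, sort(ord3$eigenvalues, decreasing = TRUE))
  expect_error(pcoa_ord(matrix(c(0, 1, 2, 0), 2)), "symmetric")
})

test_that("permanova pins the extreme-separation p at its floor and sums
           R-squared to one", {
  set.seed(9)
  m <- rbind(matrix(rnorm(40, 0), 8), matrix(rnorm(40, 10), 8))
  tb <- ft(m)
  meta <- tibble::tibble(sample = tb$sample,
                         grp = rep(c("a", "b"), each = 8),
                         one = "x")
  d <- dist(m)
  res <- permanova(d, meta, "grp", n_perm = 199, seed = 1)
  expect_equal(res$p_value[res$term == "grp"], 1 / 200)
  terms <- res[res$term != "Total", ]
  expect_equal(sum(terms$r_squared), 1, tolerance = 1e-10)
  expect_error(permanova(d, meta, "one", n_perm = 99), "one")
})

test_that("permanova p agrees with exhaustive enumeration at n = 6", {
  set.seed(10)
  m <- matrix(rnorm(18), 6)
  m[1:3, 1] <- m[1:3, 1] + 1.2
  groups <- rep(c("a", "b"), each = 3)
  dm <- as.matrix(dist(m))
  f_obs <- permanova_f_oracle(dm, groups)
  perms <- all_perms(6)
  f_all <- apply(perms, 1, function(p) permanova_f_oracle(dm, groups[p]))
  p_exact <- mean(f_all >= f_obs - 1e-12)

  tb <- ft(m)
  meta <- tibble::tibble(sample = tb$sample, grp = groups)
  res <- permanova(dist(m), meta, "grp", n_perm = 4999, seed = 2)
  p_mc <- res$p_value[res$term == "grp"]
  expect_lt(abs(p_mc - p_exact),
            3 * sqrt(p_exact * (1 - p_exact) / 5000) + 1e-3)
  # the observed pseudo-F also matches the direct partition
  expect_equal(res$pseudo_f[res$term == "grp"], f_obs, tolerance = 1e-8)
})

test_that("scheirer_ray_hare reduces to tie-corrected Kruskal-Wallis when a
           factor collapses", {
  set.seed(12)
  df <- tibble::tibble(y = sample(rep(1:8, each = 3)),
                       a = rep(c("x", "y", "z"), each = 8),
                       b = "only")
  expect_message(res <- scheirer_ray_hare(df, "y", "a", "b"), "single level")
  kw <- kruskal.test(df$y, factor(df$a))
  expect_equal(res$h, unname(kw$statistic), tolerance = 1e-10)
  expect_equal(res$p_value, kw$p.value, tolerance = 1e-10)
  expect_equal(res$df, 2)
})

test_that("scheirer_ray_hare matches a direct balanced-design rank ANOVA", {
  set.seed(13)
  df <- tidyr::expand_grid(a = c("a1", "a2"), b = c("b1", "b2"),
                           rep = 1:6)
  df$y <- rnorm(nrow(df)) + (df$a == "a2") * 1.5 + (df$b == "b2") * 0.5
  res <- scheirer_ray_hare(df, "y", "a", "b")

  # independent oracle: balanced two-way ANOVA on ranks from cell means
  r <- rank(df$y)
  n <- length(r)
  cell <- tapply(r, list(df$a, df$b), mean)
  amean <- rowMeans(cell); bmean <- colMeans(cell); grand <- mean(r)
  ss_a <- 12 * sum((amean - grand)^2)
  ss_b <- 12 * sum((bmean - grand)^2)
  ss_ab <- 6 * sum((cell - outer(amean, rep(1, 2)) -
                      outer(rep(1, 2), bmean) + grand)^2)
  ms_total <- sum((r - grand)^2) / (n - 1)
  expect_equal(res$h, c(ss_a, ss_b, ss_ab) / ms_total, tolerance = 1e-10)
  expect_true(all(res$h >= 0))
  expect_true(all(res$tie_correction > 0 & res$tie_correction <= 1))
})

test_that("scheirer_ray_hare degenerates gracefully when all values tie", {
  df <- tibble::tibble(y = rep(1, 12), a = rep(c("u", "v"), 6),
                       b = rep(c("p", "q"), each = 6))
  expect_warning(res <- scheirer_ray_hare(df, "y", "a", "b"), "tied")
  expect_true(all(res$h == 0))
  expect_true(all(res$p_value == 1))
})

test_that("planted diversity dip is detected by SRH with good power", {
  # group x time design with the generator's low-HTI dip at time point 2
  hits <- vapply(1:20, function(r) {
    sim <- simulate_cohort(cohort_params(n_patients = 30, seed = 300 + r))
    hti <- compute_hti(grade_series(sim$labs))
    mb <- simulate_microbiome(
      sim$metadata, hti,
      microbiome_sim_params(n_taxa = 80, depth = 4000, lowhti_dip = 0.8,
                            seed = 300 + r))
    a <- alpha_diversity(mb$counts, metric = "shannon")
    df <- dplyr::inner_join(a, mb$samples, by = "sample")
    res <- scheirer_ray_hare(df, "shannon", "hti_group", "timepoint")
    any(res$p_value[res$term != "timepoint"] < 0.05)
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})
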