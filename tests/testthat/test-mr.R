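sumstats <- function(snp, chr, pos, ea, oa, eaf, beta, se) {
  tibble::tibble(snp = snp, chr = chr, pos = pos, effect_allele = ea,
                 other_allele = oa, eaf = eaf, beta = beta, se = se,
                 pval = 2 * pnorm(-abs(beta / se)))
}

test_that("select_instruments clumps by p order, window, and r-squared", {
  exp1 <- sumstats(c("s1", "s2"), 1, c(1e5, 1.1e5), "A", "G", 0.3,
                   c(0.30, 0.25), 0.02)
  ld <- diag(2); ld[1, 2] <- ld[2, 1] <- sqrt(0.5)
  dimnames(ld) <- list(c("s1", "s2"), c("s1", "s2"))
  sel <- select_instruments(exp1, ld)
  expect_equal(sel$instruments$snp, "s1") # smaller p wins
  expect_equal(sel$provenance$status[sel$provenance$snp == "s2"],
               "removed_ld")

  # independent SNPs all survive
  sel2 <- select_instruments(exp1, diag(2) |>
                               `dimnames<-`(list(c("s1", "s2"),
                                                 c("s1", "s2"))))
  expect_setequal(sel2$instruments$snp, c("s1", "s2"))

  # outside the window, LD is ignored
  exp3 <- exp1
  exp3$pos <- c(1e5, 1e5 + 2e6)
  expect_setequal(select_instruments(exp3, ld)$instruments$snp,
                  c("s1", "s2"))

  none <- select_instruments(
    sumstats("s1", 1, 1, "A", "G", 0.3, 0.01, 0.02), NULL)
  expect_equal(nrow(none$instruments), 0)
})

test_that("clumped sets obey the pairwise r-squared constraint on random
           candidate panels", {
  for (r in 1:5) {
    gw <- simulate_gwas_pair(gwas_sim_params(n_snps = 150,
                                             n_instruments = 25,
                                             ld_block_size = 5,
                                             ld_rho = 0.5, seed = 400 + r))
    # dense candidate panel: every SNP clears the threshold, so clumping
    # must prune inside the correlated blocks
    set.seed(400 + r)
    cand <- gw$exposure
    cand$beta <- runif(150, 0.15, 0.4) * sample(c(-1, 1), 150, TRUE)
    cand$pval <- 2 * pnorm(-abs(cand$beta / cand$se))
    sel <- select_instruments(cand, gw$ld)
    kept <- sel$instruments
    expect_gt(nrow(kept), 0)
    expect_true(all(kept$pval < 1e-5))
    # exhaustive pair check of the invariant
    for (i in seq_len(nrow(kept))) for (j in seq_len(nrow(kept))) {
      if (i >= j) next
      same_chr <- kept$chr[i] == kept$chr[j]
      close <- abs(kept$pos[i] - kept$pos[j]) <= 1e6
      if (same_chr && close) {
        expect_lte(gw$ld[kept$snp[i], kept$snp[j]]^2, 0.01)
      }
    }
    # every removed candidate has a kept neighbor that explains it
    removed <- sel$provenance$snp[sel$provenance$status == "removed_ld"]
    for (s in removed) {
      r2s <- gw$ld[s, kept$snp]^2
      expect_true(any(r2s > 0.01))
    }
  }
})

test_that("harmonize_gwas aligns, flips, proxies, and drops as specified", {
  exp1 <- sumstats(c("s1", "s2", "s3", "s4"), 1,
                   c(1e5, 2e5, 3e5, 4e5), c("A", "A", "A", "A"),
                   c("G", "T", "G", "C"), c(0.30, 0.50, 0.30, 0.30),
                   0.1, 0.02)
  # s1: swapped alleles; s2: palindromic at eaf 0.5; s3: missing but has a
  # proxy; s4: un-matchable alleles
  outc <- sumstats(c("s1", "s2", "s5", "s4"), 1,
                   c(1e5, 2e5, 3.1e5, 4e5), c("G", "A", "C", "A"),
                   c("A", "T", "T", "G"), c(0.70, 0.50, 0.40, 0.30),
                   c(-0.05, 0.02, 0.07, 0.01), 0.01)
  ld <- diag(5)
  dimnames(ld) <- list(c("s1", "s2", "s3", "s4", "s5"),
                       c("s1", "s2", "s3", "s4", "s5"))
  ld["s3", "s5"] <- ld["s5", "s3"] <- sqrt(0.9)
  h <- harmonize_gwas(exp1, outc, ld)
  expect_equal(h$action,
               c("flipped", "dropped_palindromic", "proxied",
                 "dropped_mismatch"))
  expect_equal(h$beta_outcome[h$snp == "s1"], 0.05)
  expect_equal(h$eaf_outcome[h$snp == "s1"], 0.30)
  expect_equal(h$proxy_snp[h$snp == "s3"], "s5")
  expect_equal(h$beta_outcome[h$snp == "s3"], 0.07)
  expect_equal(sum(h$retained), 2)

  # strand-complement alleles are matched via the flipped strand
  exp2 <- sumstats("c1", 1, 1e5, "A", "G", 0.2, 0.1, 0.02)
  outc2 <- sumstats("c1", 1, 1e5, "T", "C", 0.2, 0.04, 0.01)
  h2 <- harmonize_gwas(exp2, outc2)
  expect_equal(h2$action, "kept")
  expect_equal(h2$beta_outcome, 0.04)
})

test_that("harmonization is idempotent", {
  gw <- simulate_gwas_pair(gwas_sim_params(n_snps = 100, n_instruments = 12,
                                           seed = 31))
  sel <- select_instruments(gw$exposure, gw$ld)
  h1 <- harmonize_gwas(sel$instruments, gw$outcome, gw$ld)
  kept <- h1[h1$retained, ]
  # rebuild exposure/outcome views from the harmonized set and re-run
  exp2 <- tibble::tibble(
    snp = kept$snp, chr = 1, pos = seq_len(nrow(kept)) * 2e6,
    effect_allele = kept$effect_allele, other_allele = kept$other_allele,
    eaf = kept$eaf_exposure, beta = kept$beta_exposure,
    se = kept$se_exposure, pval = 1e-8)
  out2 <- exp2
  out2$eaf <- kept$eaf_outcome
  out2$beta <- kept$beta_outcome
  out2$se <- kept$se_outcome
  h2 <- harmonize_gwas(exp2, out2)
  expect_true(all(h2$action == "kept"))
  expect_equal(h2$beta_outcome, kept$beta_outcome)
  expect_equal(h2$beta_exposure, kept$beta_exposure)
})

test_that("mr_estimate reproduces hand-computed and exact-line cases", {
  # single-SNP Wald ratio
  h1 <- fake_harmonized(bx = 0.2, by = 0.06, sy = 0.01)
  r1 <- mr_estimate(h1, method = "ivw")
  expect_equal(r1$estimate, 0.3, tolerance = 1e-12)
  expect_equal(r1$std_error, 0.05, tolerance = 1e-12)
  expect_equal(r1$conf_low, 0.3 - 1.96 * 0.05)
  expect_equal(r1$odds_ratio, exp(0.3))

  # noiseless proportional effects: every method finds the slope
  bx <- seq(0.1, 0.5, length.out = 8)
  h2 <- fake_harmonized(bx, 0.4 * bx, sy = rep(1e-4, 8))
  r2 <- mr_estimate(h2, n_boot = 200, seed = 1)
  expect_equal(r2$estimate, rep(0.4, 3), tolerance = 1e-6)

  # exact affine line: Egger recovers intercept and slope, IVW is biased
  h3 <- fake_harmonized(bx, 0.1 + 0.3 * bx, sy = rep(1e-4, 8))
  r3 <- mr_estimate(h3, method = c("ivw", "egger"))
  expect_equal(r3$estimate[r3$method == "egger"], 0.3, tolerance = 1e-6)
  sens3 <- mr_sensitivity(h3)
  expect_equal(sens3$egger_intercept$estimate, 0.1, tolerance = 1e-6)
  expect_gt(abs(r3$estimate[r3$method == "ivw"] - 0.3), 0.05)

  expect_error(mr_estimate(fake_harmonized(0.2, 0.1), method = "egger"),
               "3 SNPs")
  expect_error(mr_estimate(fake_harmonized(c(0.2, 0.3), c(0.1, 0.1)),
                           method = "weighted_median"), "3 SNPs")
})

test_that("the weighted median lies within the Wald-ratio range", {
  set.seed(33)
  for (i in 1:15) {
    n <- sample(3:12, 1)
    bx <- runif(n, 0.1, 0.5)
    by <- 0.3 * bx + rnorm(n, 0, 0.05)
    h <- fake_harmonized(bx, by)
    est <- mr_estimate(h, method = "weighted_median", n_boot = 50,
                       seed = i)$estimate
    ratios <- by / bx
    expect_gte(est, min(ratios) - 1e-12)
    expect_lte(est, max(ratios) + 1e-12)
  }
})

test_that("mr_sensitivity: degenerate Q, leave-one-out recomputation", {
  # identical Wald ratios -> no heterogeneity
  h0 <- fake_harmonized(c(0.2, 0.4), c(0.06, 0.12))
  s0 <- mr_sensitivity(h0)
  expect_equal(s0$heterogeneity$q, 0, tolerance = 1e-20)
  expect_equal(s0$heterogeneity$p_value, 1)
  expect_null(s0$egger_intercept) # needs >= 3 SNPs

  set.seed(34)
  bx <- runif(6, 0.1, 0.4)
  h <- fake_harmonized(bx, 0.3 * bx + rnorm(6, 0, 0.03))
  s <- mr_sensitivity(h)
  expect_equal(nrow(s$loo), 6)
  for (i in 1:6) {
    direct <- mr_estimate(fake_harmonized(bx[-i],
                                          h$beta_outcome[-i]),
                          method = "ivw")
    expect_equal(s$loo$estimate[i], direct$estimate, tolerance = 1e-12)
  }
})

test_that("IVW is unbiased under no pleiotropy while Egger wins under
           directional pleiotropy", {
  # parameter recovery at the stated design
  gw <- simulate_gwas_pair(gwas_sim_params(n_snps = 500,
                                           n_instruments = 50, seed = 35))
  sel <- select_instruments(gw$exposure, gw$ld)
  h <- harmonize_gwas(sel$instruments, gw$outcome, gw$ld)
  est <- mr_estimate(h, method = "ivw")$estimate
  expect_lt(abs(est - 0.3), 0.05)

  # directional pleiotropy: Egger slope beats IVW on average
  errs <- vapply(1:60, function(r) {
    gp <- gwas_sim_params(n_snps = 120, n_instruments = 30,
                          ld_block_size = 4, pleiotropy_mean = 0.05,
                          seed = 5000 + r)
    gw <- simulate_gwas_pair(gp)
    sel <- select_instruments(gw$exposure, gw$ld)
    h <- harmonize_gwas(sel$instruments, gw$outcome, gw$ld)
    res <- mr_estimate(h, method = c("ivw", "egger"))
    c(ivw = abs(res$estimate[res$method == "ivw"] - 0.3),
      egger = abs(res$estimate[res$method == "egger"] - 0.3))
  }, numeric(2))
  expect_lt(mean(errs["egger", ]), mean(errs["ivw", ]))
})
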