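---
title: "Methods: hematologic toxicity, the gut microbiome, and causal follow-up"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hematologic toxicity, the gut microbiome, and causal follow-up}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(toxbiome)
```

`toxbiome` implements, end to end, the analysis chain of a study design
that links sex-biased hematologic toxicity of neoadjuvant
chemoradiotherapy (nCRT) in rectal cancer to gut-microbiome composition
and metabolism: weekly blood counts are graded into adverse-event (AE)
grades, summarized into a single toxicity index, compared across clinical
strata; fecal microbiome tables are analyzed for diversity, composition,
feature-level associations and co-occurrence structure; and genetic
summary statistics support two-sample Mendelian randomization (MR) of
microbiome-related exposures against hematopoietic outcomes. Every stage
can be exercised on synthetic data with planted, recorded ground truth.

## Grading and the hematologic toxicity index

Weekly values of five analytes (WBC, ANC, ALC, hemoglobin, platelets;
counts in 10⁹/L, hemoglobin in g/L) are graded through ordered half-open
bands `[lower, upper)` into grades 0–4, lower values being worse. The
shipped bands follow CTCAE v5.0; they are data (`ctcae_thresholds()`),
not code, because published reports rarely print them and users may need
local laboratory limits. Anemia grade 4 has no numeric definition in
CTCAE ("life-threatening"); the default band boundary of 65 g/L is a
package convention and is editable like every other band. The baseline
week is included in the maximum-grade scan by default (grading "during
treatment" does not exclude baseline; a flag removes it).

A patient's AE profile — the per-AE maximum grade $X_1, \dots, X_n$ —
is collapsed into the hematologic toxicity index

$$\mathrm{HTI} = X_1 + \frac{X_2}{1+X_1} + \frac{X_3}{(1+X_1)(1+X_2)}
  + \dots + \frac{X_n}{\prod_{j<n}(1+X_j)}.$$

The formula is order dependent. `toxbiome` sorts the grades in
*descending* order before applying it, for three reasons: (i) the index
is then dominated by the worst toxicity and provably satisfies
$g \le \mathrm{HTI} < g+1$ whenever the maximum grade is $g \ge 1$ (the
test suite asserts this over all $5^5$ grade tuples); (ii) the index
becomes a pure function of the grade multiset, i.e. invariant under
input ordering; (iii) the published worked example (five grade-2 AEs,
HTI ≈ 2.9877) uses equal grades and therefore cannot discriminate
orderings — the descending convention is what makes the index a severity
measure. Zero grades are harmless no-ops, so all five AEs always enter.

```{r hti}
hti_index(c(2, 2, 2, 2, 2))
hti_index(c(3, 1))
```

## Cohort comparisons

`cohort_table()` reproduces a clinical "Table 1": each AE becomes a
binary outcome (grade 0 vs ≥ 1; lymphopenia, being near-universal, is
split 0–2 vs 3–4) and the HTI is split at the cohort median with ties to
the lower group. Although such reports typically cite Fisher's exact
test, the printed p-values of the motivating cohort are reproduced to
three decimals by the Pearson chi-square without continuity correction —
verified here against the two-proportion z statistic ($\chi^2 = z^2$) —
so chi-square is the default and Fisher's exact test sits behind a flag.
Age uses the Student t test by default (Welch behind a flag).

## Diversity, ordination, PERMANOVA, Scheirer–Ray–Hare

Counts are total-sum normalized before all diversity computations; no
rarefaction is performed (determinism, and the upstream workflow this
mirrors normalizes rather than rarefies). Shannon entropy uses the
natural log — the convention of the R package this stage delegates to —
which matters because the base rescales values. Inverse Simpson is
$1/\sum p_i^2$. Bray–Curtis dissimilarities feed principal-coordinates
analysis (Gower centering of $-d^2/2$); negative eigenvalues are
reported raw (a Cailliez correction is available by flag), coordinates
exist only for positive eigenvalues, and proportions explained are
relative to the sum of positive eigenvalues.

PERMANOVA uses sequential (type-I) sums of squares in the user's term
order — the cited tooling's default — so term order matters in
unbalanced designs; marginal SS are available via `by = "margin"`. The
permutation p-value is $(1 + \#\{F_\pi \ge F_{obs}\})/(1 + n_{perm})$
with whole-row permutations and an explicit seed, so it can never drop
below its floor $1/(n_{perm}+1)$.

The Scheirer–Ray–Hare test extends Kruskal–Wallis to a two-factor
design: mid-ranks of all $N$ observations enter a sequential two-way
ANOVA on ranks, and each effect's $H = SS_{effect}/MS_{total}$ is
referred to a chi-square distribution. $MS_{total}$ is computed from the
observed mid-ranks, which equals the textbook
$D \cdot N(N+1)/12$ with tie-correction
$D = 1 - \sum(t^3 - t)/(N^3 - N)$ — so ties are corrected exactly once.
If one factor collapses to a single level the test reduces, exactly, to
the tie-corrected Kruskal–Wallis statistic (asserted in the suite); if
every value ties, $H = 0$ and $p = 1$ with a warning.

## Feature associations

`filter_transform()` pins down the "default parameters" of the
MaAsLin-style stage explicitly: features detected in fewer than 10% of
samples are dropped; survivors are total-sum normalized and transformed
as $\log_2(\text{rel. abundance} + pc)$ with a per-feature pseudocount
equal to half the smallest positive normalized value. The pseudocount is
added to all values (not only zeros), keeping the transform strictly
monotone and matching the hand-checked example in the tests.

`fit_associations()` fits, per feature and per target, ordinary least
squares of the transformed abundance on the target plus adjustment
covariates. Fixed effects only: with at most a handful of repeated
samples per subject, random-effect variance components are unstable —
the same argument the motivating study makes. The design matrix is
shared across features, so one QR factorization serves the whole table.
Benjamini–Hochberg correction is applied across features separately per
target (matching per-association q-values in the motivating figures),
with the screening threshold q < 0.25. A rank-deficient design is
refused with an informative error rather than skipped per feature,
because collinearity is a property of the shared design, not of any one
feature.

One calibration fact worth knowing: under a global null, "at least one
feature at q < 0.25" is exactly a level-0.25 Simes test, so roughly a
quarter of null datasets will show some discovery. The suite asserts
that bound; expecting near-always-empty null results would be wrong.

The LEfSe-style screen keeps the canonical two stages — Kruskal–Wallis
filter, then an effect size on abundances rescaled to sum to $10^6$ per
sample, $\mathrm{LDA} = \log_{10}\max(|\Delta \text{class means}|, 1)$,
optionally averaged over seeded 2/3 subsamples. The floor of 1 inside
the log prevents negative infinities. The one-against-all subclass
(Wilcoxon) stage of canonical LEfSe is omitted deliberately: this design
has no subclass.

## Co-occurrence networks and driver taxa

Networks are built per toxicity group on post-treatment samples:
Spearman correlations between relative abundances of taxa prevalent in
≥ 20% of samples, p-values by the t approximation (exact zero at
|ρ| = 1), BH correction across all pairs, and edges kept at q ≤ 0.05 and
|ρ| ≥ 0.3. The estimator is deliberately plain Spearman;
compositionality-aware estimators (SparCC and kin) are out of scope.

Driver ranking is **NetShift-inspired, not the published NESH formula**
(which the source material does not reproduce): for each taxon in both
networks, the neighbor shift is the Jaccard distance between its two
neighbor sets, the betweenness delta is the change in normalized
shortest-path betweenness, and the combined score is
`neighbor_shift * max(delta, 0)` rescaled to [0, 1]. Drivers are flagged
above the 0.9 quantile and must have gained betweenness.

## Mendelian randomization

Instrument selection is greedy LD clumping: candidates at p < 1e-5 in
ascending p order, each kept SNP removing candidates within 1000 kb at
r² > 0.01 (strict, as the threshold is phrased as an exclusion at
"r² > 0.01"). Harmonization aligns outcome to exposure alleles (sign
flip on swapped alleles, strand complementing when needed), resolves
palindromic SNPs only when the minor-allele frequency is ≤ 0.42 on both
sides and orientations agree (the 0.42 convention of the standard
tooling; the source is silent), substitutes the best LD proxy at
r² ≥ 0.8 for instruments missing from the outcome (proxy effects used
as-is, a documented simplification — no r²-attenuation adjustment), and
is idempotent.

Estimators: IVW is the weighted through-origin regression with
multiplicative random-effects scaling `max(1, residual SD)` of the
standard error (fixed-effect by flag); MR-Egger adds a free intercept
after orienting exposure effects positive; the weighted median uses
cumulative-weight interpolation with weights $\beta_x^2/se_y^2$ and a
seeded parametric bootstrap for its standard error (the closed form is
less standard; a recorded-seed bootstrap is reproducible and easy to
audit). Sensitivity analyses: Cochran's Q over Wald ratios, the Egger
intercept t test, and leave-one-out IVW. The intercept test uses the
plain weighted-LS standard error, not the `max(1, σ)`-inflated one: the
inflation is a conservative convention for the slope, but it would
detune the intercept's type-I error away from its nominal level, and the
null-calibration tests require the nominal level.

## The synthetic-data generators: what they emulate, and what not

The generators' defaults are the stated study world, chosen once:

* **Cohort** (`cohort_params()`): 329 patients, male fraction 238/329,
  oxaliplatin in 116/329 regimens (both read off the motivating cohort
  table), five weekly on-treatment measurements plus baseline.
  Population-typical adult baselines (WBC 6.5, ANC 4.0, ALC 1.8 ×10⁹/L,
  Hgb 135 g/L, Plt 250 ×10⁹/L) because per-analyte baseline
  distributions are not published; they are configurable, not
  calibrated. Counts evolve *multiplicatively* with lognormal noise
  (sd 0.12), which keeps values positive and yields realistic grade
  mixes; weekly decline factors (0.88/0.88/0.72/0.97/0.93) make
  lymphopenia near-universal and severe, anemia mild — the qualitative
  pattern of the motivating cohort. The sex effect multiplies the
  *decline rate* (default 0.93/week for females), not the baseline,
  because the disparity being modeled is treatment-induced.
* **Microbiome** (`microbiome_sim_params()`): 4 time points, depth
  50 000, 200 taxa with N(0, 2) log-scale basis abundances; planted sex
  and per-HTI-unit log-fold effects; Dirichlet-multinomial counts
  (concentration 200) so per-sample totals equal depth exactly. The
  low-HTI diversity dip at time point 2 is implemented as *dominance
  sharpening* — centered log-abundances scaled by (1 + dip) — because a
  uniform log-shift would cancel in the composition and could not move
  alpha diversity. Metabolites are log-normal with planted linear
  effects on the log scale, matching the downstream log-linear model.
* **GWAS pair** (`gwas_sim_params()`): 500 SNPs in AR(1) LD blocks of
  10, 50 instruments with exposure effects drawn U(0.2, 0.4) —
  *one-signed*, as in real instrument sets after orientation; with
  random signs, constant directional pleiotropy would cancel in IVW and
  the IVW-vs-Egger contrast could not be demonstrated. Outcome effects
  are θ·βx plus pleiotropy plus noise; about 30% of outcome rows have
  swapped alleles to exercise harmonization. LD is summary-level only:
  no genotypes are simulated.

A single user seed expands into fixed-offset child seeds per stage, so
regenerating one table never perturbs another, and every generator is a
pure function of its parameter object.

What a green test establishes — and what it does not: the synthetic
world has no batch effects, no read-level error model, no phylogeny, no
real LD panel, and its planted effects are log-linear by construction.
Passing recovery tests therefore demonstrates that the estimators
recover the effects they model, at the stated sizes, in clean
compositional data; they say nothing about robustness to the messier
failure modes of real sequencing data.

## Numerical and scale choices

* Scaled-down Monte Carlo in unit tests (documented per test): the
  planted-sex-effect check runs 100 replicates at n = 200 (the planted
  0.8/week effect is far stronger than the ≥ 95% detection bar needs);
  null-calibration and coverage acceptance checks run at their stated
  ≥ 500 replicates.
* Spearman edge p-values use the t approximation rather than exact
  small-n permutation nulls; networks refuse < 10 samples anyway.
* BH is hand-implemented (five lines) and cross-checked against
  `p.adjust(method = "BH")`, keeping the dual implementation/oracle
  route.
* Chi-square/Fisher, diversity indices, Bray–Curtis, PCoA, PERMANOVA
  partitioning, and betweenness delegate to `stats`, `vegan`, `ape`,
  and `igraph`; each is checked in the suite against an independent
  brute-force oracle (enumeration, closed forms, z², trace identities).

## Known limitations

Grading assumes the five shipped analytes; non-hematologic AEs are out
of scope. The driver score is a documented stand-in for NESH. MR omits
Steiger filtering and multivariable MR. Reference levels of categorical
covariates follow R's default (alphabetical) contrasts; coefficient
signs depend on that choice. Real-data effect sizes from the motivating
study (ordination R², specific taxa, odds ratios) are not reproducible
without its cohort and are not targets of this package.
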