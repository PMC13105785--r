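#' Parameters for the synthetic chemoradiotherapy cohort
#'
#' Describes a cohort of rectal-cancer patients under neoadjuvant
#' chemoradiotherapy with weekly blood counts. Blood values evolve
#' multiplicatively from a per-patient baseline: each week every analyte is
#' multiplied by its `weekly_decline` factor, by `sex_effect` for the
#' affected sex, by `oxaliplatin_effect` (lymphocytes only) for patients on
#' an oxaliplatin-containing regimen, and by lognormal noise. Multiplicative
#' dynamics keep counts positive and produce realistic grade distributions.
#'
#' Defaults mirror the structure of the motivating cohort: 329 patients,
#' male fraction 238/329, five treatment weeks, oxaliplatin in 116/329
#' regimens, and population-typical adult baselines (counts in 10^9/L,
#' hemoglobin in g/L).
#'
#' @param n_patients Number of patients.
#' @param male_fraction Proportion of male patients.
#' @param n_weeks Number of on-treatment weeks; week 0 is baseline.
#' @param baseline_means Named numeric vector of baseline locations for
#'   `wbc`, `anc`, `alc` (10^9/L), `hgb` (g/L), `plt` (10^9/L).
#' @param weekly_decline Named per-analyte multiplicative factor per week,
#'   each in (0, 1].
#' @param sex_effect Extra multiplicative decline per week applied to
#'   `sex_affected`, in (0, 1]; 1 means no sex effect.
#' @param sex_affected `"female"` or `"male"`.
#' @param oxaliplatin_fraction Proportion of patients on oxaliplatin.
#' @param oxaliplatin_effect Extra weekly decline on lymphocytes for
#'   oxaliplatin patients, in (0, 1].
#' @param noise_sd Lognormal scale of the weekly measurement noise.
#' @param seed Integer seed; the generator is a pure function of the params.
#'
#' @return An object of class `cohort_params`.
#' @export
cohort_params <- function(n_patients = 329,
                          male_fraction = 238 / 329,
                          n_weeks = 5,
                          baseline_means = c(wbc = 6.5, anc = 4.0, alc = 1.8,
                                             hgb = 135, plt = 250),
                          weekly_decline = c(wbc = 0.88, anc = 0.88,
                                             alc = 0.72, hgb = 0.97,
                                             plt = 0.93),
                          sex_effect = 0.93,
                          sex_affected = c("female", "male"),
                          oxaliplatin_fraction = 116 / 329,
                          oxaliplatin_effect = 0.93,
                          noise_sd = 0.12,
                          seed = 1L) {
  sex_affected <- match.arg(sex_affected)
  n_patients <- check_count(n_patients, "n_patients")
  n_weeks <- check_count(n_weeks, "n_weeks")
  check_fraction(male_fraction, "male_fraction")
  check_fraction(oxaliplatin_fraction, "oxaliplatin_fraction")
  analytes <- c("wbc", "anc", "alc", "hgb", "plt")
  if (!all(analytes %in% names(baseline_means))) {
    abort("`baseline_means` must name wbc, anc, alc, hgb, plt.")
  }
  if (!all(analytes %in% names(weekly_decline))) {
    abort("`weekly_decline` must name wbc, anc, alc, hgb, plt.")
  }
  check_positive(baseline_means, "baseline_means")
  if (any(weekly_decline <= 0) || any(weekly_decline > 1)) {
    abort("`weekly_decline` factors must lie in (0, 1].")
  }
  for (nm in c("sex_effect", "oxaliplatin_effect")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1 || v <= 0 || v > 1) {
      abort(sprintf("`%s` must lie in (0, 1].", nm))
    }
  }
  check_positive(noise_sd, "noise_sd", strict = FALSE)
  structure(
    list(n_patients = n_patients, male_fraction = male_fraction,
         n_weeks = n_weeks, baseline_means = baseline_means[analytes],
         weekly_decline = weekly_decline[analytes], sex_effect = sex_effect,
         sex_affected = sex_affected,
         oxaliplatin_fraction = oxaliplatin_fraction,
         oxaliplatin_effect = oxaliplatin_effect, noise_sd = noise_sd,
         seed = as.integer(seed)),
    class = "cohort_params")
}

#' Parameters for the synthetic microbiome and metabolome tables
#'
#' Describes compositional taxon counts sampled at several time points per
#' patient. Per-taxon log-scale basis abundances are shifted by planted sex
#' and per-HTI-unit effects, by a per-time-point shift, and by a diversity
#' dip at time point 2 restricted to low-HTI patients; counts are then
#' drawn Dirichlet-multinomial at fixed depth. Metabolite intensities are
#' log-normal with the same planted linear effects on the log scale.
#'
#' @param n_taxa Number of taxa.
#' @param n_timepoints Sampling time points per patient (default 4: two
#'   before and two after treatment).
#' @param depth Sequencing depth per sample; every sample's counts sum to
#'   exactly this value.
#' @param basis_log_mean Optional numeric vector (length `n_taxa`) of
#'   log-scale basis abundances; drawn N(0, 2) from `seed` when `NULL`.
#' @param basis_log_sd Per-taxon lognormal spread of the basis.
#' @param sex_assoc_taxa Data frame with columns `taxon`, `logfc`: log-fold
#'   shift in the affected sex (female).
#' @param hti_assoc_taxa Data frame with columns `taxon`, `logfc`: log-fold
#'   shift per HTI unit.
#' @param time_shift Numeric vector (length `n_timepoints`) of log-scale
#'   community shifts common to all patients.
#' @param lowhti_dip Log-scale depression applied at time point 2 to
#'   patients in the low-HTI half, emulating the transient diversity dip
#'   seen in low-toxicity subjects.
#' @param overdispersion Dirichlet concentration; smaller values give more
#'   sample-to-sample compositional noise.
#' @param n_metabolites Number of metabolite features.
#' @param sex_assoc_metabolites,hti_assoc_metabolites Planted metabolite
#'   effects, same layout as the taxon effect tables.
#' @param seed Integer seed.
#'
#' @return An object of class `microbiome_sim_params`.
#' @export
microbiome_sim_params <- function(n_taxa = 200,
                                  n_timepoints = 4,
                                  depth = 50000,
                                  basis_log_mean = NULL,
                                  basis_log_sd = 0.5,
                                  sex_assoc_taxa = NULL,
                                  hti_assoc_taxa = NULL,
                                  time_shift = NULL,
                                  lowhti_dip = 0.6,
                                  overdispersion = 200,
                                  n_metabolites = 50,
                                  sex_assoc_metabolites = NULL,
                                  hti_assoc_metabolites = NULL,
                                  seed = 1L) {
  n_taxa <- check_count(n_taxa, "n_taxa")
  n_timepoints <- check_count(n_timepoints, "n_timepoints")
  depth <- check_count(depth, "depth")
  check_positive(overdispersion, "overdispersion")
  check_positive(basis_log_sd, "basis_log_sd", strict = FALSE)
  n_metabolites <- check_count(n_metabolites, "n_metabolites", min = 0)
  if (!is.null(basis_log_mean) && length(basis_log_mean) != n_taxa) {
    abort("`basis_log_mean` must have length `n_taxa`.")
  }
  if (is.null(time_shift)) time_shift <- rep(0, n_timepoints)
  if (length(time_shift) != n_timepoints) {
    abort("`time_shift` must have length `n_timepoints`.")
  }
  as_effects <- function(x, name) {
    if (is.null(x)) return(tibble(taxon = character(), logfc = double()))
    x <- as_tibble(x)
    if (!all(c("taxon", "logfc") %in% names(x))) {
      abort(sprintf("`%s` needs columns `taxon` and `logfc`.", name))
    }
    x[c("taxon", "logfc")]
  }
  structure(
    list(n_taxa = n_taxa, n_timepoints = n_timepoints, depth = depth,
         basis_log_mean = basis_log_mean, basis_log_sd = basis_log_sd,
         sex_assoc_taxa = as_effects(sex_assoc_taxa, "sex_assoc_taxa"),
         hti_assoc_taxa = as_effects(hti_assoc_taxa, "hti_assoc_taxa"),
         time_shift = time_shift, lowhti_dip = lowhti_dip,
         overdispersion = overdispersion, n_metabolites = n_metabolites,
         sex_assoc_metabolites = as_effects(sex_assoc_metabolites,
                                            "sex_assoc_metabolites"),
         hti_assoc_metabolites = as_effects(hti_assoc_metabolites,
                                            "hti_assoc_metabolites"),
         seed = as.integer(seed)),
    class = "microbiome_sim_params")
}

#' Parameters for a synthetic exposure/outcome GWAS pair
#'
#' Generates per-SNP summary statistics for a two-sample Mendelian
#' randomization design with a known causal effect. Instrument SNPs get
#' exposure effects large enough to pass the p < 1e-5 inclusion threshold;
#' outcome effects are `true_effect` times the exposure effect plus optional
#' directional pleiotropy and estimation noise. LD is summary-level only: a
#' block-diagonal AR(1) correlation matrix over consecutive SNPs.
#'
#' @param n_snps Total SNPs reported in both GWAS.
#' @param n_instruments SNPs with real exposure effects (<= `n_snps`).
#' @param true_effect Causal effect of the exposure on the outcome.
#' @param pleiotropy_mean Mean of per-SNP direct (horizontal) effects on the
#'   outcome; nonzero values create directional pleiotropy that biases IVW
#'   but not the Egger slope.
#' @param pleiotropy_sd Spread of the per-SNP pleiotropic effects.
#' @param ld_block_size SNPs per LD block.
#' @param ld_rho AR(1) correlation (r) between adjacent SNPs in a block,
#'   |ld_rho| < 1.
#' @param exposure_se,outcome_se Standard-error scales of the two GWAS.
#' @param maf_range Interval for simulated effect-allele frequencies.
#' @param seed Integer seed.
#'
#' @return An object of class `gwas_sim_params`.
#' @export
gwas_sim_params <- function(n_snps = 500,
                            n_instruments = 50,
                            true_effect = 0.3,
                            pleiotropy_mean = 0,
                            pleiotropy_sd = 0,
                            ld_block_size = 10,
                            ld_rho = 0,
                            exposure_se = 0.02,
                            outcome_se = 0.02,
                            maf_range = c(0.05, 0.5),
                            seed = 1L) {
  n_snps <- check_count(n_snps, "n_snps")
  n_instruments <- check_count(n_instruments, "n_instruments", min = 0)
  if (n_instruments > n_snps) abort("`n_instruments` must be <= `n_snps`.")
  ld_block_size <- check_count(ld_block_size, "ld_block_size")
  if (!is.numeric(ld_rho) || abs(ld_rho) >= 1) {
    abort("`ld_rho` must satisfy |ld_rho| < 1.")
  }
  check_positive(exposure_se, "exposure_se")
  check_positive(outcome_se, "outcome_se")
  check_positive(pleiotropy_sd, "pleiotropy_sd", strict = FALSE)
  if (length(maf_range) != 2 || maf_range[1] <= 0 || maf_range[2] > 0.5 ||
      maf_range[1] > maf_range[2]) {
    abort("`maf_range` must be an interval inside (0, 0.5].")
  }
  structure(
    list(n_snps = n_snps, n_instruments = n_instruments,
         true_effect = true_effect, pleiotropy_mean = pleiotropy_mean,
         pleiotropy_sd = pleiotropy_sd, ld_block_size = ld_block_size,
         ld_rho = ld_rho, exposure_se = exposure_se,
         outcome_se = outcome_se, maf_range = maf_range,
         seed = as.integer(seed)),
    class = "gwas_sim_params")
}
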