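#' Simulate a chemoradiotherapy cohort with weekly blood counts
#'
#' Draws per-patient clinical metadata and a longitudinal laboratory series
#' with a planted sex effect on treatment-induced myelosuppression. Week 0
#' is the pre-treatment baseline; each subsequent week multiplies every
#' analyte by its weekly decline factor, the sex effect (affected sex
#' only), the oxaliplatin effect (lymphocytes of oxaliplatin patients
#' only), and lognormal noise. Identical params (including seed) give
#' byte-identical output.
#'
#' @param params A [cohort_params()] object.
#'
#' @return A list with elements
#'   * `metadata`: tibble with one row per patient (`patient`, `sex`,
#'     `age`, `location`, `stage`, `nstage`, `differentiation`,
#'     `oxaliplatin`),
#'   * `labs`: long tibble (`patient`, `week`, `analyte`, `value`) with
#'     `n_weeks + 1` weeks per analyte per patient.
#' @export
#' @examples
#' sim <- simulate_cohort(cohort_params(n_patients = 20, seed = 7))
#' dplyr::count(sim$labs, analyte)
simulate_cohort <- function(params) {
  if (!inherits(params, "cohort_params")) {
    abort("`params` must be created by cohort_params().")
  }
  p <- params
  set.seed(child_seed(p$seed, 11))
  ids <- sprintf("P%04d", seq_len(p$n_patients))
  sex <- ifelse(runif(p$n_patients) < p$male_fraction, "male", "female")
  metadata <- tibble(
    patient = ids,
    sex = sex,
    age = round(pmin(pmax(rnorm(p$n_patients, 57, 10), 25), 85)),
    location = sample(c("low", "mid-high"), p$n_patients, TRUE,
                      prob = c(0.59, 0.41)),
    stage = sample(c("cT2", "cT3", "cT4"), p$n_patients, TRUE,
                   prob = c(0.11, 0.69, 0.20)),
    nstage = sample(c("cN-", "cN+"), p$n_patients, TRUE,
                    prob = c(0.08, 0.92)),
    differentiation = sample(c("well", "moderate", "poor"), p$n_patients,
                             TRUE, prob = c(0.15, 0.65, 0.20)),
    oxaliplatin = runif(p$n_patients) < p$oxaliplatin_fraction
  )

  analytes <- names(p$baseline_means)
  grid <- tidyr::expand_grid(patient = ids, analyte = analytes,
                             week = 0:p$n_weeks)
  grid <- dplyr::left_join(grid, metadata[c("patient", "sex", "oxaliplatin")],
                           by = "patient")
  base <- p$baseline_means[grid$analyte] *
    exp(rnorm(p$n_patients)[match(grid$patient, ids)] * p$noise_sd)
  decline <- p$weekly_decline[grid$analyte]
  sex_mult <- ifelse(grid$sex == p$sex_affected, p$sex_effect, 1)
  oxa_mult <- ifelse(grid$oxaliplatin & grid$analyte == "alc",
                     p$oxaliplatin_effect, 1)
  value <- base * (decline * sex_mult * oxa_mult)^grid$week *
    exp(rnorm(nrow(grid), 0, p$noise_sd))
  labs <- tibble(patient = grid$patient, week = grid$week,
                 analyte = grid$analyte, value = value)
  labs <- dplyr::arrange(labs, .data$patient, .data$analyte, .data$week)
  list(metadata = metadata, labs = labs)
}

# one Dirichlet draw per column of a log-abundance matrix, then a
# multinomial of fixed depth, so per-sample totals are conserved exactly
rdirichlet_multinom <- function(log_abund, depth, concentration) {
  comp <- exp(log_abund - max(log_abund))
  comp <- comp / sum(comp)
  alpha <- concentration * comp
  g <- rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(g) <= 0) g[which.max(alpha)] <- 1
  drop(rmultinom(1, size = depth, prob = g / sum(g)))
}

#' Simulate compositional microbiome counts and metabolite intensities
#'
#' Generates one fecal sample per patient per time point. Each sample's
#' taxon composition comes from a per-taxon log-normal basis shifted on the
#' log scale by the planted sex and per-HTI-unit effects, a per-time-point
#' community shift, and (time point 2, low-HTI patients only) a dominance
#' sharpening that depresses alpha diversity; counts are then drawn
#' Dirichlet-multinomial at exactly `depth` reads. Metabolite intensities
#' are log-normal with the same kind of planted linear effects on the log
#' scale. The planted ground truth is returned alongside the tables.
#'
#' @param metadata Patient metadata tibble from [simulate_cohort()] (needs
#'   `patient` and `sex`).
#' @param hti Tibble with `patient` and `hti` columns (one value per
#'   patient), e.g. from [compute_hti()].
#' @param params A [microbiome_sim_params()] object.
#'
#' @return A list with `counts` (tibble, `sample` + one column per taxon;
#'   rows sum to `depth`), `metabolites` (tibble, `sample` + intensities),
#'   `samples` (per-sample metadata: `sample`, `patient`, `timepoint`,
#'   `sex`, `hti`, `hti_group`), and `truth` (planted effects).
#' @export
simulate_microbiome <- function(metadata, hti, params) {
  if (!inherits(params, "microbiome_sim_params")) {
    abort("`params` must be created by microbiome_sim_params().")
  }
  p <- params
  hti <- as_tibble(hti)
  if (!all(c("patient", "hti") %in% names(hti))) {
    abort("`hti` needs columns `patient` and `hti`.")
  }
  if (!all(metadata$patient %in% hti$patient)) {
    abort("every patient in `metadata` needs an HTI value.")
  }
  set.seed(child_seed(p$seed, 23))
  taxa <- sprintf("taxon_%03d", seq_len(p$n_taxa))
  mets <- sprintf("met_%03d", seq_len(p$n_metabolites))
  for (eff in list(p$sex_assoc_taxa, p$hti_assoc_taxa)) {
    bad <- setdiff(eff$taxon, taxa)
    if (length(bad)) {
      abort(sprintf("effect taxa absent from basis: %s",
                    paste(bad, collapse = ", ")))
    }
  }
  for (eff in list(p$sex_assoc_metabolites, p$hti_assoc_metabolites)) {
    bad <- setdiff(eff$taxon, mets)
    if (length(bad)) {
      abort(sprintf("effect metabolites absent from basis: %s",
                    paste(bad, collapse = ", ")))
    }
  }
  basis <- p$basis_log_mean %||% rnorm(p$n_taxa, 0, 2)
  names(basis) <- taxa

  samples <- tidyr::expand_grid(patient = metadata$patient,
                                timepoint = seq_len(p$n_timepoints))
  samples <- dplyr::left_join(samples, metadata[c("patient", "sex")],
                              by = "patient")
  samples <- dplyr::left_join(samples, hti[c("patient", "hti")],
                              by = "patient")
  med <- median(hti$hti[hti$patient %in% metadata$patient])
  samples$hti_group <- ifelse(samples$hti <= med, "low", "high")
  samples$sample <- sprintf("%s_T%d", samples$patient, samples$timepoint)
  samples <- samples[c("sample", "patient", "timepoint", "sex", "hti",
                       "hti_group")]

  sex_shift <- setNames(rep(0, p$n_taxa), taxa)
  sex_shift[p$sex_assoc_taxa$taxon] <- p$sex_assoc_taxa$logfc
  hti_shift <- setNames(rep(0, p$n_taxa), taxa)
  hti_shift[p$hti_assoc_taxa$taxon] <- p$hti_assoc_taxa$logfc

  counts <- matrix(0L, nrow(samples), p$n_taxa,
                   dimnames = list(samples$sample, taxa))
  for (i in seq_len(nrow(samples))) {
    la <- basis + rnorm(p$n_taxa, 0, p$basis_log_sd) +
      p$time_shift[samples$timepoint[i]] +
      (samples$sex[i] == "female") * sex_shift +
      samples$hti[i] * hti_shift
    if (samples$timepoint[i] == 2 && samples$hti_group[i] == "low") {
      la <- mean(la) + (la - mean(la)) * (1 + p$lowhti_dip)
    }
    counts[i, ] <- rdirichlet_multinom(la, p$depth, p$overdispersion)
  }

  met_tbl <- NULL
  if (p$n_metabolites > 0) {
    msex <- setNames(rep(0, p$n_metabolites), mets)
    msex[p$sex_assoc_metabolites$taxon] <- p$sex_assoc_metabolites$logfc
    mhti <- setNames(rep(0, p$n_metabolites), mets)
    mhti[p$hti_assoc_metabolites$taxon] <- p$hti_assoc_metabolites$logfc
    mu <- rnorm(p$n_metabolites, 10, 1)
    logint <- matrix(rnorm(nrow(samples) * p$n_metabolites, 0, 0.5),
                     nrow(samples), p$n_metabolites)
    logint <- sweep(logint, 2, mu, "+")
    logint <- logint + outer(as.numeric(samples$sex == "female"), msex)
    logint <- logint + outer(samples$hti, mhti)
    met_tbl <- as_tibble(exp(logint), .name_repair = "minimal")
    names(met_tbl) <- mets
    met_tbl <- dplyr::bind_cols(tibble(sample = samples$sample), met_tbl)
  }

  list(
    counts = dplyr::bind_cols(tibble(sample = samples$sample),
                              as_tibble(counts)),
    metabolites = met_tbl,
    samples = samples,
    truth = list(sex_assoc_taxa = p$sex_assoc_taxa,
                 hti_assoc_taxa = p$hti_assoc_taxa,
                 sex_assoc_metabolites = p$sex_assoc_metabolites,
                 hti_assoc_metabolites = p$hti_assoc_metabolites,
                 time_shift = p$time_shift, lowhti_dip = p$lowhti_dip,
                 hti_median = med)
  )
}

#' Simulate an exposure/outcome GWAS summary-statistic pair
#'
#' Produces per-SNP summary statistics for a two-sample Mendelian
#' randomization analysis with known causal effect. Instrument SNPs (one
#' per LD block while blocks last) carry exposure effects strong enough to
#' pass the p < 1e-5 inclusion threshold; all other SNPs have null
#' exposure effects. Outcome effects are `true_effect` times the true
#' exposure effect plus per-SNP pleiotropy and sampling noise. About 30%
#' of outcome records have their allele columns swapped (with beta
#' negated) to exercise harmonization.
#'
#' @param params A [gwas_sim_params()] object.
#'
#' @return A list with `exposure` and `outcome` summary-statistic tibbles
#'   (`snp`, `chr`, `pos`, `effect_allele`, `other_allele`, `eaf`, `beta`,
#'   `se`, `pval`), `ld` (SNP-by-SNP correlation matrix, r scale), and
#'   `truth` (`true_effect`, per-SNP `pleiotropy`, instrument ids).
#' @export
simulate_gwas_pair <- function(params) {
  if (!inherits(params, "gwas_sim_params")) {
    abort("`params` must be created by gwas_sim_params().")
  }
  p <- params
  set.seed(child_seed(p$seed, 37))
  n <- p$n_snps
  snp <- sprintf("rs%05d", seq_len(n))
  block <- (seq_len(n) - 1) %/% p$ld_block_size
  n_block <- max(block) + 1
  chr <- (block %% 22) + 1
  block_on_chr <- block %/% 22
  within <- (seq_len(n) - 1) %% p$ld_block_size
  pos <- 1e5 + block_on_chr * 2e6 + within * 1e4

  pairs <- rbind(c("A", "C"), c("A", "G"), c("A", "T"), c("C", "G"),
                 c("C", "T"), c("G", "T"))
  pick <- sample(nrow(pairs), n, TRUE)
  flip <- runif(n) < 0.5
  ea <- ifelse(flip, pairs[pick, 2], pairs[pick, 1])
  oa <- ifelse(flip, pairs[pick, 1], pairs[pick, 2])
  eaf <- runif(n, p$maf_range[1], p$maf_range[2])

  # one instrument per block (first SNP), recycling if more are requested
  inst_idx <- which(within == 0)[seq_len(min(p$n_instruments, n_block))]
  if (p$n_instruments > n_block) {
    extra <- setdiff(seq_len(n), inst_idx)[seq_len(p$n_instruments - n_block)]
    inst_idx <- sort(c(inst_idx, extra))
  }
  # instrument effects are one-signed, as after orientation in real
  # instrument sets; this is what lets directional pleiotropy bias IVW
  beta_x_true <- numeric(n)
  beta_x_true[inst_idx] <- runif(length(inst_idx), 0.2, 0.4)
  beta_x <- beta_x_true + rnorm(n, 0, p$exposure_se)
  se_x <- rep(p$exposure_se, n)

  pleio <- rnorm(n, p$pleiotropy_mean, p$pleiotropy_sd)
  beta_y <- p$true_effect * beta_x_true + pleio + rnorm(n, 0, p$outcome_se)
  se_y <- rep(p$outcome_se, n)

  exposure <- tibble(snp = snp, chr = chr, pos = pos, effect_allele = ea,
                     other_allele = oa, eaf = eaf, beta = beta_x, se = se_x,
                     pval = 2 * pnorm(-abs(beta_x / se_x)))
  swap <- runif(n) < 0.3
  outcome <- tibble(snp = snp, chr = chr, pos = pos,
                    effect_allele = ifelse(swap, oa, ea),
                    other_allele = ifelse(swap, ea, oa),
                    eaf = ifelse(swap, 1 - eaf, eaf),
                    beta = ifelse(swap, -beta_y, beta_y), se = se_y,
                    pval = 2 * pnorm(-abs(beta_y / se_y)))

  ld <- matrix(0, n, n, dimnames = list(snp, snp))
  for (b in unique(block)) {
    idx <- which(block == b)
    ld[idx, idx] <- p$ld_rho^abs(outer(seq_along(idx), seq_along(idx), "-"))
  }
  diag(ld) <- 1

  list(exposure = exposure, outcome = outcome, ld = ld,
       truth = list(true_effect = p$true_effect,
                    pleiotropy = tibble(snp = snp, alpha = pleio),
                    instruments = snp[inst_idx],
                    beta_exposure_true = beta_x_true))
}
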