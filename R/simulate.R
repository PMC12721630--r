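#' Simulate genotypes at the LPA instrument variants
#'
#' Draws diploid dosages (0/1/2) at the configured variants with linkage
#' disequilibrium induced by a Gaussian copula: for each of the two haploid
#' draws per subject a latent multivariate normal vector with correlation
#' `latent_corr` is thresholded at the allele-frequency quantile of each
#' variant, so marginal alternative-allele frequencies are exact in
#' expectation while pairwise r2 grows with the latent correlation. No
#' haplotype reference panel is needed.
#'
#' @param config an [sim_config()] object.
#' @return A `genotype_matrix`: list with `dosage` (subjects x variants
#'   integer matrix, possibly with NA for missing), `subject_id`, `rsid`.
#' @export
simulate_genotypes <- function(config) {
  validate_sim_config(config)
  set.seed(stage_seed(config$seed, "genotypes"))
  n <- config$n_subjects
  v <- config$variants
  m <- nrow(v)
  L <- chol(config$latent_corr + diag(1e-10, m))
  thr <- stats::qnorm(v$alt_freq)
  hap <- function() {
    Z <- matrix(stats::rnorm(n * m), n, m) %*% L
    sweep(Z, 2, thr, `<`) * 1L
  }
  dos <- hap() + hap()
  storage.mode(dos) <- "integer"
  ids <- sprintf("S%05d", seq_len(n))
  dimnames(dos) <- list(ids, v$rsid)
  genotype_matrix(dos)
}

#' Construct a genotype matrix object
#'
#' @param dosage subjects x variants matrix of dosages in {0,1,2}, NA for
#'   missing; must carry subject ids as rownames and rsids as colnames.
#' @return A `genotype_matrix` object.
#' @export
genotype_matrix <- function(dosage) {
  if (is.null(rownames(dosage)) || is.null(colnames(dosage)))
    stop("dosage matrix must have subject ids as rownames and rsids as colnames")
  bad <- !(dosage %in% c(0L, 1L, 2L, NA))
  if (any(bad)) stop("dosage values must be 0, 1, 2 or NA")
  storage.mode(dosage) <- "integer"
  structure(list(dosage = dosage,
                 subject_id = rownames(dosage),
                 rsid = colnames(dosage),
                 missing_fraction = colMeans(is.na(dosage))),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", length(x$subject_id), "subjects x",
      length(x$rsid), "variants\n")
  cat("  variants:", paste(x$rsid, collapse = ", "), "\n")
  mf <- x$missing_fraction
  if (any(mf > 0)) cat("  missing fraction, max:", max(mf), "\n")
  invisible(x)
}

#' Simulate phenotypes and the redox panel given genotypes
#'
#' Generates the per-subject phenotype table (survival fields left empty):
#' log-Lp(a) is the additive genetic score plus a diabetes shift plus Gaussian
#' noise (exponentiated, hence right-skewed and strictly positive); the
#' eNOS-linked superoxide component rises linearly with plasma Lp(a) with
#' slope `theta_lpa_enos` in nondiabetics and `theta_lpa_enos_diabetic`
#' (default 0) in diabetics; NADPH-stimulated superoxide is independent of
#' Lp(a); the BH4/BH2 ratio declines with Lp(a); hsCRP and MDA are
#' independent of Lp(a). Clinical covariates are generated independent of
#' genotype, encoding the Mendelian-randomization independence assumption by
#' construction.
#'
#' When `genetic_var_fraction` is set, the residual SD of log-Lp(a) is derived
#' from the realized genetic variance so that the genetic fraction of
#' log-Lp(a) variance matches the target; a zero genetic variance with a
#' positive target is reported as a configuration error.
#'
#' @param genotypes a `genotype_matrix` from [simulate_genotypes()].
#' @param config the same [sim_config()] object.
#' @return A data.frame cohort table (one row per subject).
#' @export
simulate_exposures <- function(genotypes, config) {
  validate_sim_config(config)
  set.seed(stage_seed(config$seed, "exposures"))
  n <- length(genotypes$subject_id)
  v <- config$variants
  dos <- genotypes$dosage
  dos0 <- dos
  dos0[is.na(dos0)] <- 0L
  g <- as.numeric(dos0 %*% v$beta_lpa)

  f <- config$genetic_var_fraction
  if (!is.null(f)) {
    var_g <- stats::var(g)
    if (var_g <= 0 && f > 0)
      stop("configuration error: genetic_var_fraction = ", f,
           " unattainable: the configured betas/frequencies give zero ",
           "genetic variance of log-Lp(a)")
    noise_sd <- if (f >= 1) 0 else sqrt(var_g * (1 - f) / f)
  } else {
    if (is.null(config$lpa_noise_sd))
      stop("configuration error: either genetic_var_fraction or lpa_noise_sd must be set")
    noise_sd <- config$lpa_noise_sd
  }

  diabetes <- stats::rbinom(n, 1L, config$diabetes_prev)
  log_lpa <- config$lpa_log_mean + g + config$lpa_diabetes_shift * diabetes +
    stats::rnorm(n, 0, noise_sd)
  lpa <- exp(log_lpa)

  # clinical covariates, independent of genotype by construction
  age <- round(stats::rnorm(n, 67, 9), 1)
  sex <- stats::rbinom(n, 1L, 0.80)
  hypertension <- stats::rbinom(n, 1L, 0.75)
  smoking <- stats::rbinom(n, 1L, 0.15)
  family_history <- stats::rbinom(n, 1L, 0.40)
  prior_mi <- stats::rbinom(n, 1L, 0.30)
  urgent_surgery <- stats::rbinom(n, 1L, 0.15)
  bmi <- round(stats::rnorm(n, 28.5, 4), 1)

  ln <- function(p) stats::rlnorm(n, p$meanlog, p$sdlog)
  apob <- ln(config$apob_params)
  hscrp <- ln(config$hscrp_params)
  mda <- ln(config$mda_params)

  rp <- config$redox_params
  nox_raw <- stats::rlnorm(n, log(rp$nox_mean), rp$nox_sdlog)
  theta <- ifelse(diabetes == 1L, rp$theta_lpa_enos_diabetic, rp$theta_lpa_enos)
  enos <- pmax(0, rp$enos_base + theta * lpa + stats::rnorm(n, 0, rp$noise_sd))
  basal_o2 <- pmax(nox_raw + enos + stats::rnorm(n, 0, rp$noise_sd), 0.5)
  # NOS inhibition unmasks the eNOS-linked signal: the post-L-NAME readout
  # exceeds basal by that component, so the L-NAME delta indexes uncoupling.
  post_lname_o2 <- pmax(basal_o2 + enos + stats::rnorm(n, 0, rp$noise_sd), 0.5)
  nadph_o2 <- pmax(3 * nox_raw + stats::rnorm(n, 0, rp$noise_sd), 0.5)
  post_vas2870_o2 <- pmax(nadph_o2 - 2.4 * nox_raw + stats::rnorm(n, 0, rp$noise_sd), 0.5)

  bp <- config$bh4_params
  bh2 <- stats::rlnorm(n, bp$bh2_meanlog, bp$bh2_sdlog)
  log_ratio <- log(bp$base_ratio) + bp$slope_vs_lpa * lpa +
    stats::rnorm(n, 0, bp$noise_sd)
  bh4 <- bh2 * exp(log_ratio)

  data.frame(
    subject_id = genotypes$subject_id,
    age = age, sex = sex, diabetes = diabetes,
    hypertension = hypertension, smoking = smoking,
    family_history = family_history, prior_mi = prior_mi,
    urgent_surgery = urgent_surgery, bmi = bmi,
    lpa = lpa, apob = apob, hscrp = hscrp, mda = mda,
    bh4 = bh4, bh2 = bh2,
    basal_o2 = basal_o2, post_lname_o2 = post_lname_o2,
    nadph_o2 = nadph_o2, post_vas2870_o2 = post_vas2870_o2,
    followup_years = NA_real_, cv_death = NA_integer_,
    stringsAsFactors = FALSE
  )
}

#' Simulate censored survival on top of the cohort table
#'
#' Event times are drawn from an exponential hazard
#' `baseline_rate * exp(beta_o2 * log(basal_o2) + beta_lpa_direct * log(lpa)
#' + beta_age * (age - 67) + beta_diabetes * diabetes)`; censoring is an
#' independent exponential with rate `censor_rate`, truncated at
#' `max_followup_years`. With `beta_lpa_direct = 0` (the default) the Lp(a)
#' effect on death is fully mediated by arterial superoxide.
#'
#' @param cohort cohort table from [simulate_exposures()].
#' @param config the same [sim_config()] object.
#' @return The cohort table with `followup_years` and `cv_death` filled in.
#' @export
simulate_survival <- function(cohort, config) {
  validate_sim_config(config)
  sp <- config$survival_params
  if (any(unlist(sp[c("baseline_rate", "censor_rate", "max_followup_years")]) < 0))
    stop("configuration error: negative rate in survival_params")
  set.seed(stage_seed(config$seed, "survival"))
  n <- nrow(cohort)
  lp <- sp$beta_o2 * log(cohort$basal_o2) +
    sp$beta_lpa_direct * log(cohort$lpa) +
    sp$beta_age * (cohort$age - 67) +
    sp$beta_diabetes * cohort$diabetes
  rate <- sp$baseline_rate * exp(lp)
  t_event <- if (sp$baseline_rate > 0) stats::rexp(n, rate) else rep(Inf, n)
  t_cens <- if (sp$censor_rate > 0) stats::rexp(n, sp$censor_rate) else rep(Inf, n)
  t_cens <- pmin(t_cens, sp$max_followup_years)
  cohort$followup_years <- pmin(t_event, t_cens)
  cohort$cv_death <- as.integer(t_event <= t_cens)
  cohort
}

#' Generate a complete synthetic cohort on disk
#'
#' Runs [simulate_genotypes()], [simulate_exposures()] and
#' [simulate_survival()] and writes genotypes as an uncompressed VCF v4.2
#' subset (`genotypes.vcf`) and a dosage TSV (`dosages.tsv`), the phenotype
#' table as `phenotypes.tsv`, and an echo of the configuration as
#' `config.yaml`, all under `out_dir`. The files round-trip losslessly
#' through [read_genotypes()] and [read_phenotypes()].
#'
#' @param config an [sim_config()] object.
#' @param out_dir output directory (created if needed).
#' @return Invisibly, a list with the in-memory `genotypes` and `cohort`
#'   objects and the file `paths`.
#' @export
generate_cohort <- function(config, out_dir) {
  if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE))
    stop("cannot create output directory: ", out_dir)
  geno <- simulate_genotypes(config)
  cohort <- simulate_exposures(geno, config)
  cohort <- simulate_survival(cohort, config)
  paths <- list(vcf = file.path(out_dir, "genotypes.vcf"),
                dosage = file.path(out_dir, "dosages.tsv"),
                phenotypes = file.path(out_dir, "phenotypes.tsv"),
                config = file.path(out_dir, "config.yaml"))
  write_genotypes(geno, paths$vcf, format = "vcf")
  write_genotypes(geno, paths$dosage, format = "tsv")
  write_phenotypes(cohort, paths$phenotypes)
  cfg_echo <- config
  cfg_echo$latent_corr <- apply(config$latent_corr, 1, as.numeric, simplify = FALSE)
  cfg_echo$variants <- as.list(config$variants)
  yaml::write_yaml(unclass(cfg_echo), paths$config)
  invisible(list(genotypes = geno, cohort = cohort, paths = paths))
}
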