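#' The seven LPA-region instrument variants
#'
#' Default variant panel for the synthetic cohort generator and the genetic
#' risk score: the seven LPA-region SNPs used as cis-instruments for plasma
#' Lp(a). Published per-variant allele frequencies and effect sizes for the
#' source cohort are not available, so the defaults are plausible placeholders
#' (rare-to-low-frequency alternative alleles, 0.02-0.15, with log-scale
#' Lp(a) effects of the magnitude needed for a strong instrument), not
#' estimates.
#'
#' @return A data.frame with columns `rsid`, `alt_freq` (alternative allele
#'   frequency, in (0, 0.5]) and `beta_lpa` (additive effect of one
#'   alternative allele on log mg/dL Lp(a)).
#' @export
default_variants <- function() {
  data.frame(
    rsid = c("rs10455872", "rs3798220", "rs186696265", "rs76735376",
             "rs1800589", "rs140570886", "rs1801693"),
    alt_freq = c(0.08, 0.02, 0.02, 0.03, 0.15, 0.04, 0.12),
    beta_lpa = c(0.60, 0.50, 0.70, 0.25, 0.15, 0.55, 0.12),
    stringsAsFactors = FALSE
  )
}

#' Build a simulation configuration
#'
#' Assembles and validates the full parameter set of the synthetic cohort
#' generator. The defaults encode the study conditions the analysis assumes:
#' a cardiac-surgery cohort of 1027 subjects, ~21% diabetes prevalence,
#' right-skewed plasma Lp(a) that is 90% genetically determined by the seven
#' LPA variants, lower Lp(a) in diabetics, an Lp(a) effect on eNOS-derived
#' superoxide confined to nondiabetics, and cardiovascular death whose Lp(a)
#' effect is fully mediated by arterial superoxide
#' (`beta_lpa_direct = 0`).
#'
#' @param n_subjects number of subjects.
#' @param variants data.frame as returned by [default_variants()].
#' @param latent_corr symmetric positive semi-definite correlation matrix of
#'   the latent Gaussian copula used to induce linkage disequilibrium between
#'   the variants (unit diagonal). Default: exchangeable 0.6, giving high D'
#'   with modest r2, as typical for low-frequency variants in a single locus.
#' @param lpa_log_mean intercept of log-Lp(a) (log mg/dL) in nondiabetic
#'   non-carriers.
#' @param lpa_noise_sd residual SD of log-Lp(a); only used when
#'   `genetic_var_fraction` is `NULL`.
#' @param genetic_var_fraction target fraction of log-Lp(a) variance explained
#'   by genotype, in (0, 1]. When non-NULL the residual SD is derived from the
#'   realized genetic variance to hit this target.
#' @param diabetes_prev diabetes prevalence.
#' @param lpa_diabetes_shift additive shift of log-Lp(a) in diabetics
#'   (negative: diabetics have lower Lp(a)).
#' @param apob_params,hscrp_params,mda_params lognormal location/scale pairs
#'   `list(meanlog=, sdlog=)` for plasma ApoB (mg/dL), hsCRP (mg/L) and MDA
#'   (umol/L), generated independent of Lp(a).
#' @param redox_params list with `nox_mean` (RLU, median of the NOX-derived
#'   superoxide component), `nox_sdlog`, `enos_base` (RLU), `theta_lpa_enos`
#'   (RLU per mg/dL Lp(a), nondiabetics), `theta_lpa_enos_diabetic` (same,
#'   diabetics; 0 = effect absent), `noise_sd` (RLU measurement noise).
#' @param bh4_params list with `base_ratio` (BH4/BH2 at Lp(a)=0),
#'   `slope_vs_lpa` (change of log ratio per mg/dL; negative), `bh2_meanlog`,
#'   `bh2_sdlog`, `noise_sd` (log-ratio noise).
#' @param survival_params list with `baseline_rate` (events/year at linear
#'   predictor 0), `beta_o2` (log-hazard per log-RLU basal superoxide),
#'   `beta_lpa_direct` (log-hazard per log mg/dL Lp(a) not through the
#'   mediator; 0 encodes full mediation), `beta_age`, `beta_diabetes`,
#'   `censor_rate` (1/year), `max_followup_years`.
#' @param seed integer seed; all generator randomness derives from it.
#'
#' @return A validated list of class `lpa_sim_config`.
#' @export
sim_config <- function(n_subjects = 1027L,
                       variants = default_variants(),
                       latent_corr = NULL,
                       lpa_log_mean = log(10),
                       lpa_noise_sd = NULL,
                       genetic_var_fraction = 0.90,
                       diabetes_prev = 0.209,
                       lpa_diabetes_shift = -0.25,
                       apob_params = list(meanlog = log(90), sdlog = 0.20),
                       hscrp_params = list(meanlog = log(2), sdlog = 0.80),
                       mda_params = list(meanlog = log(1), sdlog = 0.40),
                       redox_params = list(nox_mean = 150, nox_sdlog = 0.30,
                                           enos_base = 20,
                                           theta_lpa_enos = 1.58,
                                           theta_lpa_enos_diabetic = 0,
                                           noise_sd = 10),
                       bh4_params = list(base_ratio = 2.0,
                                         slope_vs_lpa = -0.004,
                                         bh2_meanlog = log(3), bh2_sdlog = 0.30,
                                         noise_sd = 0.20),
                       survival_params = list(baseline_rate = 1e-7,
                                              beta_o2 = 2.0,
                                              beta_lpa_direct = 0,
                                              beta_age = 0.05,
                                              beta_diabetes = 0.30,
                                              censor_rate = 0.12,
                                              max_followup_years = 10),
                       seed = 20251L) {
  m <- nrow(variants)
  if (is.null(latent_corr)) {
    latent_corr <- matrix(0.6, m, m)
    diag(latent_corr) <- 1
  }
  cfg <- structure(list(
    n_subjects = as.integer(n_subjects), variants = variants,
    latent_corr = latent_corr, lpa_log_mean = lpa_log_mean,
    lpa_noise_sd = lpa_noise_sd, genetic_var_fraction = genetic_var_fraction,
    diabetes_prev = diabetes_prev, lpa_diabetes_shift = lpa_diabetes_shift,
    apob_params = apob_params, hscrp_params = hscrp_params,
    mda_params = mda_params, redox_params = redox_params,
    bh4_params = bh4_params, survival_params = survival_params,
    seed = as.integer(seed)), class = "lpa_sim_config")
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  v <- cfg$variants
  if (anyDuplicated(v$rsid)) stop("configuration error: duplicated rsid in variants")
  if (any(v$alt_freq <= 0 | v$alt_freq > 0.5))
    stop("configuration error: alt_freq must lie in (0, 0.5]")
  R <- cfg$latent_corr
  if (!is.matrix(R) || nrow(R) != nrow(v) || ncol(R) != nrow(v))
    stop("configuration error: latent_corr must be a ", nrow(v), "x", nrow(v), " matrix")
  if (max(abs(R - t(R))) > 1e-8) stop("configuration error: latent_corr not symmetric")
  if (max(abs(diag(R) - 1)) > 1e-8) stop("configuration error: latent_corr must have unit diagonal")
  if (min(eigen(R, symmetric = TRUE, only.values = TRUE)$values) < -1e-8)
    stop("configuration error: latent_corr is not positive semi-definite")
  probs <- c(cfg$diabetes_prev)
  if (any(probs < 0 | probs > 1)) stop("configuration error: probabilities must be in [0,1]")
  f <- cfg$genetic_var_fraction
  if (!is.null(f) && (f < 0 || f > 1))
    stop("configuration error: genetic_var_fraction must be in [0,1]")
  sp <- cfg$survival_params
  if (sp$baseline_rate < 0 || sp$censor_rate < 0 || sp$max_followup_years < 0)
    stop("configuration error: survival rates and follow-up must be nonnegative")
  invisible(cfg)
}

# Stable derivation of per-stage child seeds from the single config seed, so
# individual stages rerun reproducibly. Kept below 2^31 - 1.
stage_seed <- function(seed, stage) {
  offsets <- c(genotypes = 1L, exposures = 2L, survival = 3L, bootstrap = 4L,
               pipeline = 5L)
  k <- offsets[[stage]]
  as.integer((as.numeric(seed) + 104729 * k) %% 2147483647)
}
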