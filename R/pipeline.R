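#' Run the full analysis pipeline
#'
#' Orchestrates the analysis chain on either a freshly simulated cohort
#' (pass a [sim_config()] or a YAML config path) or user-supplied genotype +
#' phenotype files: per-variant association and variant selection, the LPA
#' genetic risk score, pairwise linkage disequilibrium, derived redox
#' indices, tertile contrasts, diabetes moderation, instrument validation
#' (first-stage F, independence screen, MR-Egger intercept), MR effect
#' estimates, Cox survival models for both the genetic and the plasma
#' exposure, mediation through arterial superoxide, and the design power
#' calculation. Results are returned as a `pipeline_report` and, when
#' `out_dir` is given, written as `report.json` (full precision,
#' byte-reproducible for a given config + seed), stage TSVs and a text log.
#'
#' If the phenotype table lacks survival fields (`cv_death`,
#' `followup_years`), the survival and mediation stages are skipped with an
#' explicit warning and all other stages complete.
#'
#' @param config an [sim_config()], a YAML path, or NULL when files are given.
#' @param out_dir optional output directory.
#' @param genotype_file,phenotype_file optional input files (used when
#'   `config` is NULL).
#' @param stages character vector of stages to run, or `"all"`. Stage names:
#'   `assoc`, `grs`, `ld`, `redox`, `contrasts`, `moderation`, `mr`,
#'   `survive`, `mediate`, `power`.
#' @param boot_reps bootstrap replicates used by the moderation CI and MR
#'   standard errors.
#' @return A `pipeline_report` list, invisibly when `out_dir` is given.
#' @export
run_pipeline <- function(config = NULL, out_dir = NULL,
                         genotype_file = NULL, phenotype_file = NULL,
                         stages = "all", boot_reps = 500L) {
  t0 <- Sys.time()
  log_lines <- character(0)
  note <- function(...) {
    log_lines <<- c(log_lines, paste0(...))
    invisible(NULL)
  }
  if (is.character(config)) config <- read_sim_config(config)
  if (!is.null(config)) {
    note("stage simulate: n = ", config$n_subjects, ", seed = ", config$seed)
    geno <- simulate_genotypes(config)
    cohort <- simulate_exposures(geno, config)
    cohort <- simulate_survival(cohort, config)
    seed <- config$seed
  } else {
    if (is.null(genotype_file) || is.null(phenotype_file))
      stop("either a config (synthetic mode) or genotype_file + phenotype_file must be given")
    geno <- read_genotypes(genotype_file)
    cohort <- read_phenotypes(phenotype_file)
    if (!all(geno$subject_id == cohort$subject_id))
      stop("genotype and phenotype subject ids do not match")
    seed <- 1L
    note("stage load: ", length(geno$subject_id), " subjects from files")
  }
  all_stages <- c("assoc", "grs", "ld", "redox", "contrasts", "moderation",
                  "mr", "survive", "mediate", "power")
  if (identical(stages, "all")) stages <- all_stages
  bad <- setdiff(stages, all_stages)
  if (length(bad)) stop("unknown stages: ", paste(bad, collapse = ", "))
  have_survival <- all(c("followup_years", "cv_death") %in% names(cohort)) &&
    !all(is.na(cohort$cv_death))
  if (!have_survival && any(c("survive", "mediate") %in% stages)) {
    warning("phenotype table lacks survival fields (cv_death/followup_years); ",
            "skipping the survival and mediation stages")
    note("stages survive/mediate skipped: no survival fields")
    stages <- setdiff(stages, c("survive", "mediate"))
  }
  if ("mediate" %in% stages && !("survive" %in% stages))
    stop("stage dependency violation: mediate requires survive")

  report <- list(software = list(package = "lpamr",
                                 version = as.character(utils::packageVersion("lpamr"))),
                 seed = seed,
                 n_subjects = nrow(cohort))
  if (!is.null(config)) {
    cfg_echo <- unclass(config)
    cfg_echo$latent_corr <- apply(config$latent_corr, 1, as.numeric, simplify = FALSE)
    cfg_echo$variants <- as.list(config$variants)
    report$config <- cfg_echo
  }

  cohort <- derive_redox_indices(cohort)
  grs <- build_grs(geno)
  grp01 <- ifelse(grs$group == "alternative", 1,
                  ifelse(grs$group == "reference", 0, NA))
  covar_names <- intersect(c("age", "sex", "hypertension", "smoking", "bmi",
                             "diabetes", "family_history", "prior_mi",
                             "urgent_surgery", "apob"), names(cohort))
  covars <- cohort[, covar_names, drop = FALSE]

  if ("assoc" %in% stages) {
    assoc <- snp_association(geno, cohort$lpa)
    report$association <- assoc$table
    report$selected_rsids <- assoc$selected
    note("stage assoc: ", length(assoc$selected), "/", length(geno$rsid),
         " variants below the genome-wide threshold")
  }
  if ("grs" %in% stages) {
    report$grs_group_sizes <- as.list(table(grs$group))
    note("stage grs: group sizes ",
         paste(names(table(grs$group)), table(grs$group), sep = "=", collapse = ", "))
  }
  if ("ld" %in% stages) {
    ldm <- ld_matrix(geno)
    report$ld <- list(layout = attr(ldm, "layout"),
                      matrix = apply(ldm, 1, as.numeric, simplify = FALSE),
                      rsids = geno$rsid)
    note("stage ld: ", length(geno$rsid), "x", length(geno$rsid), " matrix")
  }
  lpa_tert <- tertile_groups(cohort$lpa, "low_vs_medhigh")
  if ("redox" %in% stages) {
    report$redox_summary <- lapply(
      cohort[, c("basal_o2", "lname_delta_derived", "nadph_o2",
                 "vas2870_inhibitable_derived", "bh_ratio_derived")],
      function(v) list(median = stats::median(v, na.rm = TRUE),
                       iqr = unname(stats::quantile(v, c(0.25, 0.75), na.rm = TRUE))))
    note("stage redox: derived indices appended")
  }
  if ("contrasts" %in% stages) {
    ct <- function(y, g) {
      tr <- two_group_test(y[g == levels(g)[1]], y[g == levels(g)[2]])
      list(method = tr$method, statistic = tr$statistic, p = tr$p,
           n = as.list(tr$n),
           medians = as.list(tapply(y, g, stats::median, na.rm = TRUE)))
    }
    nd <- cohort$diabetes == 0
    report$contrasts <- list(
      lpa_by_grs_group = ct(cohort$lpa[!is.na(grp01)],
                            factor(grp01[!is.na(grp01)], labels = c("reference", "alternative"))),
      basal_o2_by_grs_group = ct(cohort$basal_o2[!is.na(grp01)],
                                 factor(grp01[!is.na(grp01)], labels = c("reference", "alternative"))),
      lpa_by_diabetes = ct(cohort$lpa, factor(cohort$diabetes, labels = c("nondiabetic", "diabetic"))),
      basal_o2_by_lpa_tertile = ct(cohort$basal_o2, lpa_tert$contrast),
      basal_o2_by_lpa_tertile_nondiabetic = ct(cohort$basal_o2[nd],
                                               tertile_groups(cohort$lpa[nd])$contrast),
      lname_delta_by_lpa_tertile_nondiabetic = ct(cohort$lname_delta_derived[nd],
                                                  tertile_groups(cohort$lpa[nd])$contrast),
      bh_ratio_by_lpa_tertile_nondiabetic = ct(cohort$bh_ratio_derived[nd],
                                               tertile_groups(cohort$lpa[nd])$contrast))
    note("stage contrasts: 7 two-group contrasts")
  }
  if ("moderation" %in% stages) {
    mod <- moderation(cohort$basal_o2, cohort$lpa, cohort$diabetes,
                      reps = boot_reps, seed = stage_seed(seed, "bootstrap"))
    report$moderation <- list(interaction_b = mod$interaction_b,
                              ci = mod$ci, p = mod$p,
                              bootstrap_reps = mod$bootstrap_reps)
    note("stage moderation: b = ", signif(mod$interaction_b, 4))
  }
  if ("mr" %in% stages) {
    pv_x <- per_variant_assoc(geno, cohort$lpa)
    pv_y <- per_variant_assoc(geno, cohort$basal_o2)
    eg <- mr_egger(pv_x$beta, pv_x$se, pv_y$beta, pv_y$se)
    chk <- validate_instrument(grp01, cohort$lpa, covars, egger_fit = eg)
    est_basal <- mr_estimate(grp01, cohort$lpa, log(cohort$basal_o2),
                             method = "two_stage", boot_reps = boot_reps,
                             seed = stage_seed(seed, "bootstrap"))
    nd <- cohort$diabetes == 0
    est_enos <- mr_estimate(grp01[nd], cohort$lpa[nd],
                            cohort$lname_delta_derived[nd],
                            method = "two_stage", boot_reps = boot_reps,
                            seed = stage_seed(seed, "bootstrap"))
    report$instrument_check <- list(
      f_statistic = chk$f_statistic, relevance_pass = chk$relevance_pass,
      r2 = chk$r2, n = chk$n, egger_intercept_p = chk$egger_intercept_p,
      independence = chk$independence_table)
    report$mr <- list(
      egger = list(slope = eg$slope, slope_se = eg$slope_se,
                   intercept = eg$intercept, intercept_se = eg$intercept_se,
                   intercept_p = eg$intercept_p),
      log_basal_o2_per_mgdl = list(estimate = est_basal$estimate,
                                   se = est_basal$se, ci = est_basal$ci,
                                   p = est_basal$p),
      lname_delta_per_mgdl_nondiabetic = list(estimate = est_enos$estimate,
                                              se = est_enos$se, ci = est_enos$ci,
                                              p = est_enos$p))
    note("stage mr: F = ", signif(chk$f_statistic, 5),
         ", Egger intercept p = ", signif(eg$intercept_p, 3))
  }
  if ("survive" %in% stages) {
    surv_triple <- function(exposure) {
      keep <- !is.na(exposure)
      cv <- screen_cox_covariates(covars[keep, , drop = FALSE],
                                  cohort$cv_death[keep])
      fit <- cox_fit(cohort$followup_years[keep], cohort$cv_death[keep],
                     cbind(exposure = exposure[keep],
                           covars[keep, cv$keep, drop = FALSE]))
      list(hr = unname(fit$hrs["exposure"]),
           ci = unname(fit$wald_cis["exposure", ]),
           p = unname(fit$wald_ps["exposure"]),
           n = fit$n, n_events = fit$n_events,
           covariates_dropped = cv$dropped)
    }
    report$survival <- list(
      grs_group = surv_triple(grp01),
      lpa_medhigh = surv_triple(as.numeric(lpa_tert$contrast == "medhigh")))
    note("stage survive: ", report$survival$grs_group$n_events, " events (GRS model)")
  }
  if ("mediate" %in% stages) {
    med_block <- function(exposure) {
      keep <- !is.na(exposure)
      cv <- screen_cox_covariates(covars[keep, , drop = FALSE],
                                  cohort$cv_death[keep])
      md <- mediation_cox(cohort$followup_years[keep], cohort$cv_death[keep],
                          exposure[keep], cohort$log_basal_o2_derived[keep],
                          covars[keep, cv$keep, drop = FALSE])
      list(unadjusted = md$unadjusted, mediator_adjusted = md$mediator_adjusted,
           attenuation_pct = md$attenuation_pct,
           exposure_mediator_rho = list(rho = md$exposure_mediator_rho$statistic,
                                        p = md$exposure_mediator_rho$p),
           n = md$n)
    }
    report$mediation <- list(
      grs_group = med_block(grp01),
      lpa_medhigh = med_block(as.numeric(lpa_tert$contrast == "medhigh")))
    note("stage mediate: attenuation (GRS) = ",
         signif(report$mediation$grs_group$attenuation_pct, 4), "%")
  }
  if ("power" %in% stages) {
    pw <- power_two_sample(delta = 0.67, sd = 0.28, n1 = 33, n2 = 67,
                           alpha = 0.05)
    report$power <- list(delta = pw$delta, sd = pw$sd, n1 = pw$n1, n2 = pw$n2,
                         alpha = pw$alpha, power = pw$power)
  }

  report <- c(report, list(stages_run = stages))
  out <- structure(report, class = "pipeline_report")
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE))
      stop("cannot create output directory: ", out_dir)
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         na = "null")
    if (!is.null(report$association))
      utils::write.table(report$association, file.path(out_dir, "association.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(as.data.frame(grs), file.path(out_dir, "grs.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(report$ld)) {
      ldm <- ld_matrix(geno)
      utils::write.table(cbind(rsid = rownames(ldm), as.data.frame(ldm)),
                         file.path(out_dir, "ld_matrix.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    write_phenotypes(cohort, file.path(out_dir, "phenotypes_derived.tsv"))
    note("runtime: ", format(round(difftime(Sys.time(), t0, units = "secs"), 2)))
    writeLines(log_lines, file.path(out_dir, "pipeline.log"))
    return(invisible(out))
  }
  attr(out, "log") <- log_lines
  out
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("pipeline report (", x$n_subjects, " subjects, seed ", x$seed, ")\n", sep = "")
  cat("stages:", paste(x$stages_run, collapse = ", "), "\n")
  if (!is.null(x$instrument_check))
    cat(sprintf("first-stage F = %.3f; Egger intercept p = %.3f\n",
                x$instrument_check$f_statistic, x$instrument_check$egger_intercept_p))
  if (!is.null(x$survival))
    cat(sprintf("GRS group HR = %.3f [%.3f, %.3f], p = %.3g\n",
                x$survival$grs_group$hr, x$survival$grs_group$ci[1],
                x$survival$grs_group$ci[2], x$survival$grs_group$p))
  if (!is.null(x$mediation))
    cat(sprintf("mediator-adjusted GRS HR = %.3f [%.3f, %.3f], p = %.3g\n",
                x$mediation$grs_group$mediator_adjusted$hr,
                x$mediation$grs_group$mediator_adjusted$ci[1],
                x$mediation$grs_group$mediator_adjusted$ci[2],
                x$mediation$grs_group$mediator_adjusted$p))
  invisible(x)
}

# Positivity screen for Cox adjustment covariates: a low-cardinality
# covariate whose observed levels do not all contain at least one event gives
# a monotone partial likelihood (infinite coefficient), so it is dropped from
# the adjustment set and reported.
screen_cox_covariates <- function(covars, event) {
  ok <- vapply(names(covars), function(nm) {
    v <- covars[[nm]]
    lv <- unique(v[!is.na(v)])
    if (length(lv) > 3) return(TRUE)
    ev_lv <- unique(v[event == 1 & !is.na(v)])
    length(ev_lv) == length(lv)
  }, logical(1))
  list(keep = names(covars)[ok], dropped = names(covars)[!ok])
}

#' Read a simulation configuration from YAML
#'
#' Inverse of the `config.yaml` echo written by [generate_cohort()].
#'
#' @param path YAML file path.
#' @return An `lpa_sim_config` object.
#' @export
read_sim_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  y <- yaml::read_yaml(path)
  variants <- as.data.frame(y$variants, stringsAsFactors = FALSE)
  latent_corr <- do.call(rbind, lapply(y$latent_corr, as.numeric))
  sim_config(n_subjects = y$n_subjects, variants = variants,
             latent_corr = latent_corr, lpa_log_mean = y$lpa_log_mean,
             lpa_noise_sd = y$lpa_noise_sd,
             genetic_var_fraction = y$genetic_var_fraction,
             diabetes_prev = y$diabetes_prev,
             lpa_diabetes_shift = y$lpa_diabetes_shift,
             apob_params = y$apob_params, hscrp_params = y$hscrp_params,
             mda_params = y$mda_params, redox_params = y$redox_params,
             bh4_params = y$bh4_params, survival_params = y$survival_params,
             seed = y$seed)
}
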