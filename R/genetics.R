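#' Per-variant association of a quantitative trait with dosage
#'
#' Simple additive-coding linear regression of `trait` on dosage, one variant
#' at a time, over the subjects with nonmissing dosage at that variant.
#' Closed-form simple regression with a two-sided t-test p-value. Monomorphic
#' variants are flagged and excluded, not an abort.
#'
#' @param genotypes a `genotype_matrix`.
#' @param trait numeric per-subject vector, aligned with the genotype rows.
#' @return data.frame with `rsid`, `beta`, `se`, `p`, `n`, `monomorphic`.
#' @export
per_variant_assoc <- function(genotypes, trait) {
  dos <- genotypes$dosage
  if (length(trait) != nrow(dos))
    stop("trait length does not match the number of subjects")
  res <- lapply(seq_len(ncol(dos)), function(j) {
    keep <- !is.na(dos[, j]) & !is.na(trait)
    x <- as.numeric(dos[keep, j]); y <- trait[keep]
    n <- length(x)
    if (n < 3 || stats::var(x) == 0)
      return(data.frame(rsid = genotypes$rsid[j], beta = NA_real_,
                        se = NA_real_, p = NA_real_, n = n,
                        monomorphic = stats::var(x) == 0 || n < 3))
    sxx <- sum((x - mean(x))^2)
    beta <- sum((x - mean(x)) * (y - mean(y))) / sxx
    a <- mean(y) - beta * mean(x)
    rss <- sum((y - a - beta * x)^2)
    se <- sqrt(rss / (n - 2) / sxx)
    tstat <- if (se > 0) beta / se else Inf
    p <- if (is.finite(tstat)) 2 * stats::pt(-abs(tstat), df = n - 2) else 0
    data.frame(rsid = genotypes$rsid[j], beta = beta, se = se,
               p = max(p, .Machine$double.xmin), n = n, monomorphic = FALSE)
  })
  do.call(rbind, res)
}

#' Quantitative-trait association of the variants with plasma Lp(a)
#'
#' Regresses log-Lp(a) on additive dosage per variant, adjusts the two-sided
#' p-values by Benjamini-Hochberg across tested (polymorphic) variants, and
#' selects the variants below the genome-wide significance threshold.
#'
#' @param genotypes a `genotype_matrix`.
#' @param lpa per-subject plasma Lp(a), mg/dL (positive).
#' @param gw_threshold genome-wide significance threshold on the raw p-value.
#' @return list with `table` (rsid, beta, se, p, q, n, selected) and
#'   `selected` (character vector of selected rsids).
#' @export
snp_association <- function(genotypes, lpa, gw_threshold = 5.0e-8) {
  if (any(lpa <= 0, na.rm = TRUE)) stop("lpa must be positive (mg/dL)")
  tab <- per_variant_assoc(genotypes, log(lpa))
  tested <- !tab$monomorphic
  tab$q <- NA_real_
  tab$q[tested] <- bh_fdr(tab$p[tested])
  tab$selected <- tested & tab$p < gw_threshold
  list(table = tab, selected = tab$rsid[tab$selected])
}

#' Build the unweighted LPA genetic risk score
#'
#' For each subject, `carrier_count` is the number of instrument variants at
#' which the subject carries at least one alternative allele (unweighted
#' summative model over carrier indicators). Grouping follows the dominant
#' contrast: `reference` = no alternative allele at any of the 7 variants,
#' `alternative` = carriers at 3 or more variants, 1-2 carried variants are
#' `unassigned` and excluded from the dichotomous contrast. The continuous
#' score is the carrier count standardized to unit SD within the stratum of
#' subjects carrying alternative alleles at more than one variant
#' (`carrier_count >= 2`).
#'
#' Missing dosage is handled complete-case per subject: carrier counting runs
#' over the nonmissing variants (with a completeness flag), and a subject is
#' `reference` only if observed homozygous reference at all instruments.
#'
#' @param genotypes a `genotype_matrix`.
#' @param instrument_rsids the instrument variant ids (default: all columns).
#' @return A `grs_result`: data.frame with `subject_id`, `carrier_count`,
#'   `complete`, `group` (factor reference/unassigned/alternative),
#'   `continuous_score`.
#' @export
build_grs <- function(genotypes, instrument_rsids = genotypes$rsid) {
  miss <- setdiff(instrument_rsids, genotypes$rsid)
  if (length(miss))
    stop("instrument variants absent from genotype matrix: ",
         paste(miss, collapse = ", "))
  dos <- genotypes$dosage[, instrument_rsids, drop = FALSE]
  carrier <- dos >= 1L
  carrier_count <- rowSums(carrier, na.rm = TRUE)
  complete <- rowSums(is.na(dos)) == 0L
  group <- rep("unassigned", nrow(dos))
  group[carrier_count == 0 & complete] <- "reference"
  group[carrier_count >= 3] <- "alternative"
  group <- factor(group, levels = c("reference", "unassigned", "alternative"))
  cont <- rep(NA_real_, nrow(dos))
  in_stratum <- carrier_count >= 2
  if (sum(in_stratum) >= 2 && stats::sd(carrier_count[in_stratum]) > 0) {
    cc <- carrier_count[in_stratum]
    cont[in_stratum] <- (cc - mean(cc)) / stats::sd(cc)
  }
  structure(data.frame(subject_id = genotypes$subject_id,
                       carrier_count = as.integer(carrier_count),
                       complete = complete, group = group,
                       continuous_score = cont,
                       stringsAsFactors = FALSE),
            class = c("grs_result", "data.frame"))
}

#' @export
print.grs_result <- function(x, ...) {
  cat("LPA genetic risk score over", nrow(x), "subjects\n")
  print(table(x$group))
  invisible(as.data.frame(x))
}
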