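#' Derive superoxide bioassay and biopterin indices
#'
#' Appends the derived vascular redox quantities to a cohort table:
#' `lname_delta_derived = post_lname_o2 - basal_o2` (the L-NAME-induced
#' change in chemiluminescence; positive values index uncoupled-eNOS-derived
#' superoxide, negative values carry recoupled / NO-scavenging physiology and
#' are retained, never clipped), `vas2870_inhibitable_derived = nadph_o2 -
#' post_vas2870_o2` (the pan-NOX-inhibitable component of NADPH-stimulated
#' superoxide), `bh_ratio_derived = bh4 / bh2`, and natural-log transforms of
#' the basal and NADPH readouts for analysis.
#'
#' @param cohort data.frame with positive columns `basal_o2`,
#'   `post_lname_o2`, `nadph_o2`, `post_vas2870_o2`, `bh4`, `bh2`.
#' @return The cohort with `*_derived` columns appended.
#' @export
derive_redox_indices <- function(cohort) {
  raw <- c("basal_o2", "post_lname_o2", "nadph_o2", "post_vas2870_o2",
           "bh4", "bh2")
  miss <- setdiff(raw, names(cohort))
  if (length(miss)) stop("missing redox columns: ", paste(miss, collapse = ", "))
  for (cl in raw) {
    bad <- !is.na(cohort[[cl]]) & cohort[[cl]] <= 0
    if (any(bad))
      stop("nonpositive ", cl, " rejected for subject ",
           cohort$subject_id[which(bad)[1]])
  }
  cohort$lname_delta_derived <- cohort$post_lname_o2 - cohort$basal_o2
  cohort$vas2870_inhibitable_derived <- cohort$nadph_o2 - cohort$post_vas2870_o2
  cohort$bh_ratio_derived <- cohort$bh4 / cohort$bh2
  cohort$log_basal_o2_derived <- log(cohort$basal_o2)
  cohort$log_nadph_o2_derived <- log(cohort$nadph_o2)
  cohort
}

#' Tertile grouping of a continuous variable
#'
#' Cuts at the 1/3 and 2/3 empirical quantiles (linear-interpolation
#' quantiles); subjects exactly at a cut point go to the lower group. The
#' default contrast compares the bottom tertile against the upper two
#' (low vs medium/high); `high_vs_lowmed` contrasts the top tertile against
#' the bottom two.
#'
#' @param values numeric vector with at least 3 distinct values.
#' @param contrast `"low_vs_medhigh"` or `"high_vs_lowmed"`.
#' @return list with `tertile` (factor low/medium/high), `contrast` (factor
#'   with the two contrast groups, group 2 = the "exposed" side), and
#'   `cutpoints`.
#' @export
tertile_groups <- function(values, contrast = c("low_vs_medhigh", "high_vs_lowmed")) {
  contrast <- match.arg(contrast)
  v <- values[!is.na(values)]
  if (length(unique(v)) < 3) stop("tertile grouping needs at least 3 distinct values")
  q <- stats::quantile(v, c(1 / 3, 2 / 3), names = FALSE, type = 7)
  if (q[1] >= q[2]) {
    tie_mass <- mean(v == q[1])
    stop("empty tertile: tie mass ", signif(tie_mass, 3), " at value ",
         signif(q[1], 6), " collapses the cut points")
  }
  tert <- cut(values, breaks = c(-Inf, q[1], q[2], Inf),
              labels = c("low", "medium", "high"), right = TRUE)
  sizes <- table(tert)
  if (any(sizes == 0)) {
    tie_val <- if (sizes[1] == 0) q[1] else q[2]
    tie_mass <- mean(v == tie_val)
    stop("empty tertile: tie mass ", signif(tie_mass, 3),
         " at value ", signif(tie_val, 6), " prevents a three-way split")
  }
  grp <- if (contrast == "low_vs_medhigh") {
    factor(ifelse(tert == "low", "low", "medhigh"), levels = c("low", "medhigh"))
  } else {
    factor(ifelse(tert == "high", "high", "lowmed"), levels = c("lowmed", "high"))
  }
  list(tertile = tert, contrast = grp, cutpoints = q)
}
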