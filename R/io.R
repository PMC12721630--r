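#' Write genotypes to disk
#'
#' `format = "vcf"` emits an uncompressed VCF v4.2 subset: biallelic records
#' on chromosome 6 (the LPA locus) with a GT-only FORMAT, `0/0`, `0/1`,
#' `1/1`, and `./.` for missing. `format = "tsv"` emits a dosage table with a
#' `subject_id` column and one integer column per rsid (NA for missing).
#'
#' @param genotypes a `genotype_matrix`.
#' @param path output file path.
#' @param format `"vcf"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(genotypes, path, format = c("vcf", "tsv")) {
  format <- match.arg(format)
  dos <- genotypes$dosage
  if (format == "tsv") {
    df <- data.frame(subject_id = genotypes$subject_id, dos,
                     check.names = FALSE, stringsAsFactors = FALSE)
    ok <- tryCatch({
      utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
      TRUE
    }, error = function(e) FALSE)
    if (!ok) stop("failed to write dosage TSV to ", path)
    return(invisible(path))
  }
  m <- length(genotypes$rsid)
  gt <- c("0/0", "0/1", "1/1")
  body <- vapply(seq_len(m), function(j) {
    calls <- ifelse(is.na(dos[, j]), "./.", gt[dos[, j] + 1L])
    paste(c("6", 160500000L + 1000L * j, genotypes$rsid[j], "A", "G", ".",
            "PASS", ".", "GT", calls), collapse = "\t")
  }, character(1))
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=lpamr",
    "##contig=<ID=6>",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", genotypes$subject_id), collapse = "\t"))
  ok <- tryCatch({
    writeLines(c(header, body), path)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) stop("failed to write VCF to ", path)
  invisible(path)
}

#' Read genotypes from a VCF v4.2 subset or dosage TSV
#'
#' VCF records must be biallelic (multiallelic records are rejected, naming
#' the offending rsid). GT calls `0/0`, `0/1`, `1/0`, `1/1` (or their phased
#' `|` forms) map to dosages 0/1/2; `./.` maps to missing and is excluded
#' from association denominators downstream. Malformed GT fields are reported
#' with the file line number.
#'
#' @param path input file.
#' @param format `"auto"` (by extension), `"vcf"` or `"tsv"`.
#' @return A `genotype_matrix`.
#' @export
read_genotypes <- function(path, format = c("auto", "vcf", "tsv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("genotype file not found: ", path)
  if (format == "auto")
    format <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "tsv"
  if (format == "tsv") {
    df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
    if (names(df)[1] != "subject_id")
      stop("dosage TSV must have subject_id as its first column: ", path)
    dos <- as.matrix(df[, -1, drop = FALSE])
    rownames(dos) <- df$subject_id
    return(genotype_matrix(dos))
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  alt <- fix[, "ALT"]
  multi <- grepl(",", alt)
  if (any(multi))
    stop("multiallelic record rejected: ", paste(fix[multi, "ID"], collapse = ", "))
  gt <- vcfR::extract.gt(v, element = "GT")
  n_meta <- length(v@meta)
  parse_gt <- function(calls, record_idx) {
    calls_n <- gsub("\\|", "/", calls)
    out <- rep(NA_integer_, length(calls_n))
    out[calls_n == "0/0"] <- 0L
    out[calls_n %in% c("0/1", "1/0")] <- 1L
    out[calls_n == "1/1"] <- 2L
    bad <- is.na(out) & !(calls_n %in% c("./.", ".")) & !is.na(calls_n)
    if (any(bad))
      stop("malformed GT '", calls[which(bad)[1]], "' at line ",
           n_meta + 1L + record_idx, " of ", path)
    out
  }
  dos <- vapply(seq_len(nrow(gt)), function(i) parse_gt(gt[i, ], i),
                integer(ncol(gt)))
  if (is.null(dim(dos))) dos <- matrix(dos, nrow = ncol(gt))
  dimnames(dos) <- list(colnames(gt), fix[, "ID"])
  genotype_matrix(dos)
}

#' Write the phenotype table
#' @param cohort cohort data.frame.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_phenotypes <- function(cohort, path) {
  ok <- tryCatch({
    utils::write.table(cohort, path, sep = "\t", quote = FALSE, row.names = FALSE)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) stop("failed to write phenotype TSV to ", path)
  invisible(path)
}

#' Read a phenotype table
#'
#' @param path TSV with the cohort-table schema (see [simulate_exposures()]);
#'   survival columns may be absent.
#' @param require_survival if TRUE, `followup_years` and `cv_death` must be
#'   present.
#' @return A data.frame.
#' @export
read_phenotypes <- function(path, require_survival = FALSE) {
  if (!file.exists(path)) stop("phenotype file not found: ", path)
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  needed <- c("subject_id", "lpa", "diabetes")
  if (require_survival) needed <- c(needed, "followup_years", "cv_death")
  miss <- setdiff(needed, names(df))
  if (length(miss))
    stop("phenotype file missing required columns: ", paste(miss, collapse = ", "))
  df
}
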