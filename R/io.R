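# Tab-delimited readers and writers for the table dialects the analysis
# modules exchange, with schema validation that names the offending file
# and column.

require_columns <- function(df, cols, file) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop(sprintf("file '%s' is missing required column(s): %s",
                 file, paste(missing, collapse = ", ")), call. = FALSE)
  }
  invisible(df)
}

read_tsv_checked <- function(path, required) {
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                   check.names = FALSE)
  require_columns(df, required, path)
  df
}

#' Read a MAF-like variant table
#'
#' Tab-delimited with columns `sample_id`, `gene`, `hgvs_p`,
#' `pathogenicity`; `effect` and `vaf` are optional.
#' @param path File path.
#' @return Data frame.
#' @export
read_variant_table <- function(path) {
  read_tsv_checked(path, c("sample_id", "gene", "hgvs_p", "pathogenicity"))
}

#' Read a per-sample copy-number table
#'
#' Tab-delimited with columns `sample_id`, `gene`, `copies`.
#' @param path File path.
#' @return Data frame.
#' @export
read_copy_number_table <- function(path) {
  read_tsv_checked(path, c("sample_id", "gene", "copies"))
}

#' Read a claims event table
#'
#' Tab-delimited with columns `patient_id`, `date` (ISO-8601), `kind`
#' (`claim`, `treatment_start`, `last_contact`), `drug`, `drug_category`.
#' @param path File path.
#' @return Data frame with `date` parsed as `Date`.
#' @export
read_claims_table <- function(path) {
  df <- read_tsv_checked(path, c("patient_id", "date", "kind"))
  df$date <- as.Date(df$date)
  if (anyNA(df$date)) stop(sprintf("file '%s': column 'date' contains unparseable dates", path))
  bad <- !(df$kind %in% EVENT_KINDS)
  if (any(bad)) {
    stop(sprintf("file '%s': column 'kind' contains invalid value '%s'",
                 path, df$kind[which(bad)[1]]))
  }
  df
}

#' Read a per-sample feature table
#'
#' Tab-delimited with at least `sample_id`; typical columns include
#' `patient_id`, `biopsy_site`, `histology`, `race`, `tmb`, `msi_high`
#' and fusion/mutation flags.
#' @param path File path.
#' @return Data frame.
#' @export
read_feature_table <- function(path) {
  read_tsv_checked(path, "sample_id")
}

#' Read an expression matrix (samples x genes, TPM)
#'
#' Tab-delimited with samples in rows (first column `sample_id`) and genes
#' in columns.
#' @param path File path.
#' @return Numeric matrix with sample ids as row names.
#' @export
read_expression_matrix <- function(path) {
  df <- read_tsv_checked(path, "sample_id")
  m <- as.matrix(df[, setdiff(names(df), "sample_id"), drop = FALSE])
  mode(m) <- "numeric"
  rownames(m) <- df$sample_id
  if (any(m < 0, na.rm = TRUE)) {
    stop(sprintf("file '%s': negative expression values", path))
  }
  m
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a synthetic cohort to a directory of TSV files
#'
#' Emits `variants.tsv`, `copy_number.tsv`, `claims.tsv`, `features.tsv`,
#' `expression.tsv`, `ground_truth.tsv` and `cohort_meta.json` (seed and
#' cutoff date) in the dialects the readers of this package consume.
#'
#' @param cohort A `foxa1_cohort` from [generate_cohort()].
#' @param dir Output directory (created if absent).
#' @return The directory path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "foxa1_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_tsv(cohort$variants, file.path(dir, "variants.tsv"))
  write_tsv(cohort$copy_number, file.path(dir, "copy_number.tsv"))
  write_tsv(cohort$claims, file.path(dir, "claims.tsv"))
  write_tsv(cohort$samples, file.path(dir, "features.tsv"))
  expr <- data.frame(sample_id = rownames(cohort$expression),
                     cohort$expression, check.names = FALSE,
                     stringsAsFactors = FALSE)
  write_tsv(expr, file.path(dir, "expression.tsv"))
  write_tsv(cohort$ground_truth, file.path(dir, "ground_truth.tsv"))
  jsonlite::write_json(
    list(seed = cohort$seed, cutoff_date = format(cohort$cutoff_date),
         n_patients = nrow(cohort$samples)),
    file.path(dir, "cohort_meta.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' Read a cohort directory written by [write_cohort()]
#'
#' @param dir Directory containing the cohort TSV files.
#' @return A list with the same table elements as a generated cohort
#'   (ground truth included only when present).
#' @export
read_cohort <- function(dir) {
  meta_path <- file.path(dir, "cohort_meta.json")
  meta <- if (file.exists(meta_path)) jsonlite::read_json(meta_path) else list()
  gt_path <- file.path(dir, "ground_truth.tsv")
  list(
    samples = read_feature_table(file.path(dir, "features.tsv")),
    variants = read_variant_table(file.path(dir, "variants.tsv")),
    copy_number = read_copy_number_table(file.path(dir, "copy_number.tsv")),
    claims = read_claims_table(file.path(dir, "claims.tsv")),
    expression = read_expression_matrix(file.path(dir, "expression.tsv")),
    ground_truth = if (file.exists(gt_path)) read.delim(gt_path) else NULL,
    cutoff_date = if (!is.null(meta$cutoff_date)) as.Date(meta$cutoff_date) else NULL,
    seed = meta$seed %||% NA_integer_
  )
}
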