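# Numeric-by-class comparisons (expression, VAF) and gene-set signature
# scoring. Comparisons are rank-based (two-sided Mann-Whitney against WT
# with BH adjustment); signature scores are the per-sample mean of
# per-gene z-scores of log2(TPM + 1), so a constant matrix scores 0 and
# scores are invariant to per-gene affine rescaling of log expression.

#' Compare a numeric sample attribute across alteration classes
#'
#' Summarizes a per-sample numeric value (e.g. FOXA1 TPM, VAF) by class
#' and tests each non-WT class against wild type with a two-sided
#' Mann-Whitney (Wilcoxon rank-sum) test, BH-adjusted across classes.
#' Arms smaller than `min_n` are flagged untestable.
#'
#' @param values Numeric vector, one value per sample.
#' @param classes Class label per sample.
#' @param wt_label Reference label (default `"WT"`).
#' @param min_n Minimum arm size for testing (default 3).
#' @return Data frame with one row per class present: `class`, `n`,
#'   `median`, `q25`, `q75`, `p`, `q`, `testable`.
#' @export
compare_numeric_by_class <- function(values, classes, wt_label = "WT",
                                     min_n = 3L) {
  stopifnot(length(values) == length(classes))
  keep <- !is.na(values) & !is.na(classes)
  values <- values[keep]; classes <- classes[keep]
  lvls <- intersect(FOXA1_CLASSES, unique(classes))
  wt_vals <- values[classes == wt_label]
  out <- do.call(rbind, lapply(lvls, function(cl) {
    v <- values[classes == cl]
    row <- data.frame(class = cl, n = length(v),
                      median = median(v),
                      q25 = unname(quantile(v, 0.25)),
                      q75 = unname(quantile(v, 0.75)),
                      p = NA_real_, q = NA_real_, testable = FALSE,
                      stringsAsFactors = FALSE)
    if (cl != wt_label && length(v) >= min_n && length(wt_vals) >= min_n) {
      row$p <- suppressWarnings(
        wilcox.test(v, wt_vals, alternative = "two.sided")$p.value)
      row$testable <- TRUE
    }
    row
  }))
  sel <- !is.na(out$p)
  out$q[sel] <- p.adjust(out$p[sel], method = "BH")
  rownames(out) <- NULL
  out
}

#' Score gene-set signatures per sample
#'
#' Computes, for each signature, the per-sample mean of per-gene z-scores
#' of `log2(TPM + 1)`; z-scores are taken across samples, and genes with
#' zero variance contribute 0. Signature genes absent from the matrix are
#' dropped with a warning; a signature with no overlap raises an error.
#'
#' @param expr Numeric matrix of TPM values, samples in rows, genes in
#'   columns (unique column names).
#' @param gene_sets Named list of character vectors of gene symbols.
#' @param log_transform Apply `log2(x + 1)` before z-scoring (default
#'   `TRUE`; set `FALSE` if `expr` is already on log scale).
#' @return Data frame with columns `sample_id`, `signature`, `score`.
#' @examples
#' expr <- matrix(c(1, 2, 4, 8, 8, 4, 2, 1), nrow = 4,
#'                dimnames = list(paste0("s", 1:4), c("KLK3", "SYP")))
#' score_signature(expr, list(ar = "KLK3"))
#' @export
score_signature <- function(expr, gene_sets, log_transform = TRUE) {
  stopifnot(is.matrix(expr), !is.null(colnames(expr)))
  if (anyDuplicated(colnames(expr))) stop("gene identifiers must be unique")
  if (any(expr < 0, na.rm = TRUE) && log_transform) {
    stop("TPM matrix contains negative values")
  }
  lx <- if (log_transform) log2(expr + 1) else expr
  mu <- colMeans(lx)
  sdv <- apply(lx, 2, stats::sd)
  z <- sweep(lx, 2, mu, "-")
  nz <- sdv > 0
  z[, nz] <- sweep(z[, nz, drop = FALSE], 2, sdv[nz], "/")
  z[, !nz] <- 0

  ids <- rownames(expr) %||% as.character(seq_len(nrow(expr)))
  rows <- lapply(names(gene_sets), function(sig) {
    genes <- gene_sets[[sig]]
    hit <- intersect(genes, colnames(expr))
    if (length(hit) == 0L) {
      stop(sprintf("signature '%s' shares no genes with the expression matrix", sig))
    }
    missing <- setdiff(genes, hit)
    if (length(missing)) {
      warning(sprintf("signature '%s': %d gene(s) absent from the matrix (%s)",
                      sig, length(missing),
                      paste(head(missing, 5), collapse = ", ")))
    }
    data.frame(sample_id = ids, signature = sig,
               score = rowMeans(z[, hit, drop = FALSE]),
               stringsAsFactors = FALSE, row.names = NULL)
  })
  do.call(rbind, rows)
}
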