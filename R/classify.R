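# Class assignment rules. A variant is labelled by its effect and by where
# its anchor residue (lowest affected residue) falls relative to the FKH
# domain; the R219C/S hotspot takes precedence over the positional rule.

#' Classify a protein-level alteration
#'
#' Assigns each variant row to one alteration class:
#' \itemize{
#'   \item `C2` — missense at the hotspot residue (default R219) changing to
#'     one of the hotspot alternates (default C or S).
#'   \item `C1A`/`C1B`/`C1C` — other missense or in-frame indel/delins
#'     variants, by anchor residue: first portion of the FKH domain
#'     (168-246), Wing2 (247-269), or outside the FKH domain (1-167, 270+).
#'   \item `C3A`/`C3B` — predicted truncating variants (nonsense,
#'     frameshift and, by default, splice): anchor at or before the FKH
#'     domain end (1-269) versus after it (270+).
#'   \item `WT` — synonymous variants (not counted as alterations).
#' }
#' In-frame indels spanning a boundary are classified by the anchor
#' (lowest) residue; `anchor_policy = "any_overlap_wing2"` instead assigns
#' class 1B whenever the span touches the Wing2 region. Non-C/S missense at
#' the hotspot residue (e.g. R219H) falls through to the positional rule
#' (class 1A), and in-frame indels touching the hotspot are never class 2.
#'
#' @param v Variant data frame as returned by [parse_hgvs_p()] (columns
#'   `effect`, `start_aa`, `end_aa`, `alt_aa`).
#' @param domains A [foxa1_domains()] model.
#' @param anchor_policy `"anchor"` (default) or `"any_overlap_wing2"`.
#' @param splice_policy `"truncating"` (default; splice variants are
#'   classified with class 3 at the nearest affected codon) or `"exclude"`
#'   (labelled `WT`).
#' @param other_policy `"error"` (default) or `"wt"` for variants whose
#'   effect is `other`.
#'
#' @return Character vector of class labels, one per row of `v`.
#' @examples
#' v <- parse_hgvs_p(c("p.R219C", "p.R219H", "p.F254del", "p.E100*"))
#' classify_variant(v, foxa1_domains())
#' @export
classify_variant <- function(v, domains = foxa1_domains(),
                             anchor_policy = c("anchor", "any_overlap_wing2"),
                             splice_policy = c("truncating", "exclude"),
                             other_policy = c("error", "wt")) {
  anchor_policy <- match.arg(anchor_policy)
  splice_policy <- match.arg(splice_policy)
  other_policy <- match.arg(other_policy)
  validate_domains(domains)
  n <- nrow(v)
  if (n == 0L) return(character(0))
  if (any(v$end_aa > domains$protein_length)) {
    stop("variant residue span exceeds protein length")
  }
  out <- character(n)
  inframe <- c("missense", "inframe_insertion", "inframe_deletion", "inframe_delins")
  truncating <- c("nonsense", "frameshift")
  for (i in seq_len(n)) {
    eff <- v$effect[i]
    s <- v$start_aa[i]
    e <- v$end_aa[i]
    if (eff == "missense" && s == domains$class2_residue &&
        toupper(v$alt_aa[i]) %in% domains$class2_alt_residues) {
      out[i] <- "C2"
    } else if (eff %in% inframe) {
      in_wing2 <- if (anchor_policy == "any_overlap_wing2") {
        s <= domains$fkh_end && e >= domains$wing2_start
      } else {
        s >= domains$wing2_start && s <= domains$fkh_end
      }
      out[i] <- if (in_wing2) "C1B"
        else if (s >= domains$fkh_start && s < domains$wing2_start) "C1A"
        else "C1C"
    } else if (eff %in% truncating ||
               (eff == "splice" && splice_policy == "truncating")) {
      out[i] <- if (s <= domains$fkh_end) "C3A" else "C3B"
    } else if (eff == "synonymous" || eff == "splice") {
      out[i] <- "WT"
    } else if (eff == "other") {
      if (other_policy == "error") {
        stop("variant with effect 'other' cannot be classified; map or exclude it (other_policy)")
      }
      out[i] <- "WT"
    } else {
      stop(sprintf("unknown variant effect '%s'", eff))
    }
  }
  out
}

#' Classify a copy-number call
#'
#' @param copies Numeric vector of absolute gene copy numbers (>= 0).
#' @param domains A [foxa1_domains()] model supplying the amplification
#'   threshold (default >= 6 copies).
#' @return Character vector: `"C4"` where `copies >=` the threshold,
#'   `NA` otherwise (no amplification call).
#' @examples
#' classify_copy_number(c(2, 5, 6, 11))
#' @export
classify_copy_number <- function(copies, domains = foxa1_domains()) {
  if (any(copies < 0, na.rm = TRUE)) stop("copy number cannot be negative")
  ifelse(!is.na(copies) & copies >= domains$amplification_min_copies,
         "C4", NA_character_)
}

#' Filter variants by pathogenicity call
#'
#' Keeps pathogenic and likely pathogenic variants; benign, likely benign
#' and (by default) variants of unknown significance are excluded from all
#' mutation counting, matching clinical reporting practice.
#'
#' @param variants Data frame with a `pathogenicity` column taking values
#'   in `pathogenic`, `likely_pathogenic`, `VUS`, `likely_benign`, `benign`.
#' @param include_vus Keep VUS calls as well (sensitivity analyses).
#' @param allow_missing Pass rows with missing pathogenicity through
#'   unfiltered instead of raising an error.
#' @return The filtered data frame.
#' @export
filter_pathogenic <- function(variants, include_vus = FALSE,
                              allow_missing = FALSE) {
  if (nrow(variants) == 0L) return(variants)
  p <- variants$pathogenicity
  if (is.null(p)) stop("variants table lacks a 'pathogenicity' column")
  known <- c("pathogenic", "likely_pathogenic", "VUS", "likely_benign", "benign")
  bad <- is.na(p) | !(p %in% known)
  if (any(bad) && !allow_missing) {
    stop(sprintf("%d variant(s) have missing or unrecognized pathogenicity; set allow_missing = TRUE to pass them through", sum(bad)))
  }
  keep_levels <- c("pathogenic", "likely_pathogenic", if (include_vus) "VUS")
  keep <- p %in% keep_levels | (allow_missing & bad)
  variants[keep, , drop = FALSE]
}

DEFAULT_PRECEDENCE <- c("C2", "C1B", "C1A", "C3A", "C3B", "C1C", "C4")

#' Classify one sample from its alterations
#'
#' Labels every alteration in a sample and resolves a single sample-level
#' class by precedence. The default precedence puts the rarest and most
#' prognostically extreme classes first
#' (`C2 > C1B > C1A > C3A > C3B > C1C > C4`); samples with no qualifying
#' alteration are `WT`.
#'
#' @param variants Variant data frame for one sample (possibly empty);
#'   pathogenicity filtering is the caller's responsibility (see
#'   [filter_pathogenic()]).
#' @param copies Numeric vector of FOXA1 copy-number calls for the sample
#'   (usually length 1), or `NULL`.
#' @param domains A [foxa1_domains()] model.
#' @param precedence Character vector ordering the non-WT labels.
#' @param ... Passed to [classify_variant()].
#' @return List with `sample_class` (length-1 character) and
#'   `alteration_classes` (one label per alteration, variants first then
#'   copy-number calls).
#' @export
classify_sample <- function(variants, copies = NULL,
                            domains = foxa1_domains(),
                            precedence = DEFAULT_PRECEDENCE, ...) {
  stopifnot(all(precedence %in% setdiff(FOXA1_CLASSES, "WT")))
  labels <- character(0)
  if (!is.null(variants) && nrow(variants) > 0L) {
    labels <- classify_variant(variants, domains, ...)
  }
  if (!is.null(copies) && length(copies) > 0L) {
    cn <- classify_copy_number(copies, domains)
    labels <- c(labels, cn[!is.na(cn)])
  }
  present <- precedence[precedence %in% labels]
  list(
    sample_class = if (length(present)) present[1] else "WT",
    alteration_classes = labels
  )
}

#' Classify a whole cohort of samples
#'
#' Vectorized cohort-level wrapper: parses HGVS strings where needed,
#' filters by pathogenicity, labels every alteration and resolves one class
#' per sample.
#'
#' @param variant_table Data frame with columns `sample_id`, `gene`,
#'   `hgvs_p`, `pathogenicity` and optionally `effect` and `vaf`. When
#'   `effect` is absent it is parsed from `hgvs_p`. Only rows for
#'   `gene == target_gene` are considered.
#' @param cn_table Data frame with columns `sample_id`, `gene`, `copies`,
#'   or `NULL`.
#' @param sample_ids Optional vector of all sample identifiers in the
#'   cohort (samples without any alteration rows are reported as `WT`).
#' @param domains A [foxa1_domains()] model.
#' @param target_gene Gene symbol to classify (default `"FOXA1"`).
#' @param include_vus,precedence,... See [filter_pathogenic()],
#'   [classify_sample()] and [classify_variant()].
#' @return List with `per_sample` (data frame `sample_id`, `class`) and
#'   `per_alteration` (variant rows plus a `class` column).
#' @export
classify_cohort <- function(variant_table, cn_table = NULL,
                            sample_ids = NULL,
                            domains = foxa1_domains(),
                            target_gene = "FOXA1",
                            include_vus = FALSE,
                            precedence = DEFAULT_PRECEDENCE, ...) {
  vt <- variant_table[variant_table$gene == target_gene, , drop = FALSE]
  vt <- filter_pathogenic(vt, include_vus = include_vus)
  if (nrow(vt) > 0L) {
    parsed <- parse_hgvs_p(vt$hgvs_p, protein_length = domains$protein_length)
    if (is.null(vt$effect)) {
      vt$effect <- parsed$effect
    } else {
      # splice calls cannot be expressed in p. notation; trust the caller's
      # effect column where it disagrees on splice, else the parsed form
      vt$effect <- ifelse(vt$effect == "splice", "splice", parsed$effect)
    }
    vt$start_aa <- parsed$start_aa
    vt$end_aa <- parsed$end_aa
    vt$ref_aa <- parsed$ref_aa
    vt$alt_aa <- parsed$alt_aa
    vt$class <- classify_variant(vt, domains, ...)
  } else {
    vt$class <- character(0)
  }

  amp_samples <- character(0)
  if (!is.null(cn_table) && nrow(cn_table) > 0L) {
    cn <- cn_table[cn_table$gene == target_gene, , drop = FALSE]
    cn$class <- classify_copy_number(cn$copies, domains)
    amp_samples <- unique(cn$sample_id[!is.na(cn$class)])
  }

  ids <- unique(c(sample_ids, vt$sample_id, if (!is.null(cn_table)) cn_table$sample_id))
  per_sample <- data.frame(sample_id = ids, class = "WT",
                           stringsAsFactors = FALSE)
  lab_by_sample <- split(vt$class[vt$class != "WT"],
                         vt$sample_id[vt$class != "WT"])
  for (i in seq_len(nrow(per_sample))) {
    id <- per_sample$sample_id[i]
    labels <- lab_by_sample[[id]]
    if (id %in% amp_samples) labels <- c(labels, "C4")
    present <- precedence[precedence %in% labels]
    if (length(present)) per_sample$class[i] <- present[1]
  }
  list(per_sample = per_sample, per_alteration = vt)
}

#' Per-residue alteration counts (lollipop table)
#'
#' Summarizes classified alterations into one row per (residue, effect,
#' class) with a count, ready for lollipop-style plotting along the
#' protein body.
#'
#' @param per_alteration Data frame as returned in
#'   `classify_cohort()$per_alteration`.
#' @return Data frame with columns `residue`, `effect`, `class`, `count`,
#'   ordered by residue.
#' @export
residue_counts <- function(per_alteration) {
  if (nrow(per_alteration) == 0L) {
    return(data.frame(residue = integer(), effect = character(),
                      class = character(), count = integer(),
                      stringsAsFactors = FALSE))
  }
  tab <- aggregate(
    list(count = rep(1L, nrow(per_alteration))),
    by = list(residue = per_alteration$start_aa,
              effect = per_alteration$effect,
              class = per_alteration$class),
    FUN = sum
  )
  tab[order(tab$residue, tab$effect), c("residue", "effect", "class", "count")]
}
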