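# HGVS protein-level (p.) notation: parsing and canonical formatting.
# Supported forms are those emitted by clinical NGS reports for a single
# gene: substitutions, in-frame del/ins/delins/dup, nonsense, frameshift
# and synonymous changes, in one- or three-letter amino-acid code, with or
# without surrounding parentheses. DNA-level (c.) notation is out of scope.

AA3_TO_1 <- c(
  Ala = "A", Arg = "R", Asn = "N", Asp = "D", Cys = "C", Gln = "Q",
  Glu = "E", Gly = "G", His = "H", Ile = "I", Leu = "L", Lys = "K",
  Met = "M", Phe = "F", Pro = "P", Ser = "S", Thr = "T", Trp = "W",
  Tyr = "Y", Val = "V", Ter = "*", Sec = "U"
)

VARIANT_EFFECTS <- c("missense", "inframe_insertion", "inframe_deletion",
                     "inframe_delins", "nonsense", "frameshift", "splice",
                     "synonymous", "other")

# Collapse three-letter amino-acid codes to one-letter. Case-sensitive on
# purpose: lowercase keywords (del, ins, fs) and all-caps one-letter runs
# are left untouched.
normalize_aa3 <- function(x) {
  for (code in names(AA3_TO_1)) {
    x <- gsub(code, AA3_TO_1[[code]], x, fixed = TRUE)
  }
  x
}

empty_variant_frame <- function() {
  data.frame(
    hgvs_p = character(), effect = character(),
    start_aa = integer(), end_aa = integer(),
    ref_aa = character(), alt_aa = character(),
    stringsAsFactors = FALSE
  )
}

parse_one_hgvs <- function(raw) {
  if (is.na(raw) || !nzchar(trimws(raw))) {
    stop("cannot parse empty HGVS protein string")
  }
  body <- trimws(raw)
  body <- sub("^p\\.", "", body)
  body <- sub("^\\((.*)\\)$", "\\1", body)
  body <- normalize_aa3(body)

  fail <- function() {
    stop(sprintf("cannot parse HGVS protein change '%s' (offending token: '%s')",
                 raw, body), call. = FALSE)
  }
  rec <- function(effect, start, end, ref, alt) {
    list(effect = effect, start_aa = as.integer(start), end_aa = as.integer(end),
         ref_aa = ref, alt_aa = alt)
  }

  aa <- "[ACDEFGHIKLMNPQRSTVWYU]"

  # frameshift: P358fs, P358Lfs, P358Lfs*13
  m <- regmatches(body, regexec(paste0("^(", aa, ")([0-9]+)(", aa, "?)fs(\\*?[0-9]*)$"), body))[[1]]
  if (length(m)) {
    return(rec("frameshift", m[3], m[3], m[2], m[4]))
  }
  # nonsense: E100*, E100X
  m <- regmatches(body, regexec(paste0("^(", aa, ")([0-9]+)(\\*|X)$"), body))[[1]]
  if (length(m)) {
    return(rec("nonsense", m[3], m[3], m[2], "*"))
  }
  # delins: D226delinsEV, A100_T101delinsGG
  m <- regmatches(body, regexec(
    paste0("^(", aa, ")([0-9]+)(?:_(", aa, ")([0-9]+))?delins(", aa, "+)$"), body))[[1]]
  if (length(m)) {
    end <- if (nzchar(m[5])) m[5] else m[3]
    ref <- paste0(m[2], m[4])
    return(rec("inframe_delins", m[3], end, ref, m[6]))
  }
  # deletion: F254del, F254_E255del
  m <- regmatches(body, regexec(
    paste0("^(", aa, ")([0-9]+)(?:_(", aa, ")([0-9]+))?del$"), body))[[1]]
  if (length(m)) {
    end <- if (nzchar(m[5])) m[5] else m[3]
    ref <- paste0(m[2], m[4])
    return(rec("inframe_deletion", m[3], end, ref, ""))
  }
  # duplication: A100dup, A100_T101dup (represented as an insertion of ref)
  m <- regmatches(body, regexec(
    paste0("^(", aa, ")([0-9]+)(?:_(", aa, ")([0-9]+))?dup$"), body))[[1]]
  if (length(m)) {
    end <- if (nzchar(m[5])) m[5] else m[3]
    ref <- paste0(m[2], m[4])
    return(rec("inframe_insertion", m[3], end, ref, ref))
  }
  # insertion: A100_T101insG
  m <- regmatches(body, regexec(
    paste0("^(", aa, ")([0-9]+)_(", aa, ")([0-9]+)ins(", aa, "+)$"), body))[[1]]
  if (length(m)) {
    return(rec("inframe_insertion", m[3], m[5], paste0(m[2], m[4]), m[6]))
  }
  # synonymous: R219=, R219R
  m <- regmatches(body, regexec(paste0("^(", aa, ")([0-9]+)=$"), body))[[1]]
  if (length(m)) {
    return(rec("synonymous", m[3], m[3], m[2], m[2]))
  }
  # missense (or same-letter synonymous): R219C
  m <- regmatches(body, regexec(paste0("^(", aa, ")([0-9]+)(", aa, ")$"), body))[[1]]
  if (length(m)) {
    eff <- if (m[2] == m[4]) "synonymous" else "missense"
    return(rec(eff, m[3], m[3], m[2], m[4]))
  }
  fail()
}

#' Parse HGVS protein-change strings
#'
#' Parses clinical-report style protein-level HGVS notation into a variant
#' table with an effect call and a 1-based residue span. One- and
#' three-letter amino-acid codes are accepted, as are surrounding
#' parentheses (`p.(R219C)`). Supported forms: missense (`p.R219C`),
#' synonymous (`p.R219=`/`p.R219R`), nonsense (`p.E100*`, `p.E100X`),
#' frameshift (`p.P358fs`, `p.P358Lfs*13`), in-frame deletion
#' (`p.F254del`, `p.F254_E255del`), insertion (`p.A100_T101insG`),
#' duplication (`p.A100dup`) and delins (`p.D226delinsEV`).
#'
#' @param x Character vector of HGVS protein strings.
#' @param protein_length Optional residue count of the reference protein;
#'   when supplied, spans beyond it raise a range error.
#'
#' @return A data frame with one row per input: `hgvs_p` (canonical
#'   formatting), `effect`, `start_aa`, `end_aa`, `ref_aa`, `alt_aa`.
#'   For frameshift and nonsense variants `start_aa` is the first affected
#'   residue. `ref_aa`/`alt_aa` may be empty for indels.
#' @examples
#' parse_hgvs_p(c("p.R219C", "p.Pro358LeufsTer13", "p.F254_E255del"))
#' @export
parse_hgvs_p <- function(x, protein_length = NULL) {
  if (length(x) == 0L) return(empty_variant_frame())
  parsed <- lapply(x, parse_one_hgvs)
  out <- data.frame(
    hgvs_p = NA_character_,
    effect = vapply(parsed, `[[`, "", "effect"),
    start_aa = vapply(parsed, `[[`, 0L, "start_aa"),
    end_aa = vapply(parsed, `[[`, 0L, "end_aa"),
    ref_aa = vapply(parsed, `[[`, "", "ref_aa"),
    alt_aa = vapply(parsed, `[[`, "", "alt_aa"),
    stringsAsFactors = FALSE
  )
  if (any(out$start_aa < 1L | out$end_aa < out$start_aa)) {
    stop("parsed residue span is invalid (start < 1 or end < start)")
  }
  if (!is.null(protein_length)) {
    bad <- out$end_aa > protein_length
    if (any(bad)) {
      stop(sprintf("residue index %d in '%s' exceeds protein length %d",
                   max(out$end_aa[bad]), x[which(bad)[1]], protein_length))
    }
  }
  out$hgvs_p <- format_hgvs_p(out)
  out
}

#' Format variant rows as canonical one-letter HGVS strings
#'
#' Inverse of [parse_hgvs_p()]: renders a variant table back into compact
#' one-letter `p.` notation. Parsing the formatted string reproduces the
#' same effect, span and amino-acid fields (round-trip identity).
#'
#' @param v Data frame with columns `effect`, `start_aa`, `end_aa`,
#'   `ref_aa`, `alt_aa` as produced by [parse_hgvs_p()].
#' @return Character vector of HGVS protein strings.
#' @export
format_hgvs_p <- function(v) {
  n <- nrow(v)
  out <- character(n)
  for (i in seq_len(n)) {
    eff <- v$effect[i]; s <- v$start_aa[i]; e <- v$end_aa[i]
    ref <- v$ref_aa[i]; alt <- v$alt_aa[i]
    r1 <- substr(ref, 1, 1); r2 <- substr(ref, 2, 2)
    out[i] <- switch(eff,
      missense = sprintf("p.%s%d%s", r1, s, alt),
      synonymous = sprintf("p.%s%d=", r1, s),
      nonsense = sprintf("p.%s%d*", r1, s),
      frameshift = if (nzchar(alt) && !grepl("^\\*", alt)) {
        sprintf("p.%s%d%sfs", r1, s, substr(alt, 1, 1))
      } else sprintf("p.%s%dfs", r1, s),
      inframe_deletion = if (e > s) {
        sprintf("p.%s%d_%s%ddel", r1, s, r2, e)
      } else sprintf("p.%s%ddel", r1, s),
      inframe_insertion = if (nzchar(r2)) {
        sprintf("p.%s%d_%s%dins%s", r1, s, r2, e, alt)
      } else sprintf("p.%s%ddup", r1, s),
      inframe_delins = if (e > s) {
        sprintf("p.%s%d_%s%ddelins%s", r1, s, r2, e, alt)
      } else sprintf("p.%s%ddelins%s", r1, s, alt),
      stop(sprintf("cannot format effect '%s' as HGVS", eff))
    )
  }
  out
}
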