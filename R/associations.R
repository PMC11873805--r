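# Class-versus-WT categorical enrichment. Each (feature, class) pair forms
# a 2x2 table against wild type; Fisher's exact test is used when any
# expected cell count is below 5, otherwise a chi-squared test. q values
# are Benjamini-Hochberg adjusted across the features tested within one
# class comparison.

#' Flag high tumor mutational burden
#'
#' @param tmb Numeric vector of tumor mutational burden values in
#'   mutations per megabase (>= 0).
#' @param threshold TMB-high threshold (default 10 mutations/Mb,
#'   inclusive).
#' @return Logical vector: `TRUE` where `tmb >= threshold`.
#' @examples
#' flag_tmb_high(c(0, 9.99, 10, 42))
#' @export
flag_tmb_high <- function(tmb, threshold = 10) {
  if (any(tmb < 0, na.rm = TRUE)) stop("TMB cannot be negative")
  tmb >= threshold
}

# Sample odds ratio with Haldane-Anscombe correction when any cell is 0.
odds_ratio_2x2 <- function(a, b, c, d) {
  if (any(c(a, b, c, d) == 0)) {
    a <- a + 0.5; b <- b + 0.5; c <- c + 0.5; d <- d + 0.5
  }
  (a * d) / (b * c)
}

test_one_2x2 <- function(a, b, c, d, chi2_correct = TRUE) {
  tab <- matrix(c(a, b, c, d), nrow = 2, byrow = TRUE)
  n <- sum(tab)
  if (n == 0) return(list(p = NA_real_, test = "untestable"))
  expected <- outer(rowSums(tab), colSums(tab)) / n
  if (any(expected < 5)) {
    list(p = fisher.test(tab)$p.value, test = "fisher")
  } else {
    list(p = suppressWarnings(chisq.test(tab, correct = chi2_correct)$p.value),
         test = "chi2")
  }
}

#' Test feature enrichment in each class versus wild type
#'
#' For every requested logical feature and every non-WT class present, a
#' 2x2 table (feature present/absent in class vs in WT) is tested
#' two-sided: Fisher's exact test when any expected count is < 5, else a
#' chi-squared test (continuity corrected by default). Odds ratios use the
#' sample cross-product with a Haldane-Anscombe 0.5 correction when a cell
#' is zero. Within each class, q values are BH-adjusted across the feature
#' family.
#'
#' @param samples Data frame with a class column and logical (or 0/1)
#'   feature columns.
#' @param features Character vector of feature column names.
#' @param class_col Name of the class column (default `"class"`).
#' @param classes Classes to test (default: all non-WT classes present).
#' @param wt_label Reference label (default `"WT"`).
#' @param chi2_correct Apply Yates continuity correction in the
#'   chi-squared branch (default `TRUE`).
#' @return Tidy data frame: `feature`, `class`, `n_class`, `pos_class`,
#'   `n_wt`, `pos_wt`, `odds_ratio`, `p`, `q`, `test` (one of `fisher`,
#'   `chi2`, `untestable`).
#' @export
test_feature_enrichment <- function(samples, features, class_col = "class",
                                    classes = NULL, wt_label = "WT",
                                    chi2_correct = TRUE) {
  cls <- samples[[class_col]]
  if (is.null(cls)) stop(sprintf("missing class column '%s'", class_col))
  if (is.null(classes)) {
    classes <- intersect(setdiff(FOXA1_CLASSES, wt_label), unique(cls))
  }
  wt <- samples[cls == wt_label, , drop = FALSE]
  rows <- list()
  for (cl in classes) {
    grp <- samples[cls == cl, , drop = FALSE]
    for (f in features) {
      fx <- as.logical(grp[[f]]); fw <- as.logical(wt[[f]])
      a <- sum(fx, na.rm = TRUE); b <- sum(!fx, na.rm = TRUE)
      cc <- sum(fw, na.rm = TRUE); dd <- sum(!fw, na.rm = TRUE)
      if (nrow(grp) == 0L) {
        rows[[length(rows) + 1L]] <- data.frame(
          feature = f, class = cl, n_class = 0L, pos_class = 0L,
          n_wt = cc + dd, pos_wt = cc, odds_ratio = NA_real_,
          p = NA_real_, q = NA_real_, test = "untestable",
          stringsAsFactors = FALSE)
        next
      }
      tst <- test_one_2x2(a, b, cc, dd, chi2_correct)
      rows[[length(rows) + 1L]] <- data.frame(
        feature = f, class = cl, n_class = a + b, pos_class = a,
        n_wt = cc + dd, pos_wt = cc,
        odds_ratio = odds_ratio_2x2(a, b, cc, dd),
        p = tst$p, q = NA_real_, test = tst$test,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) return(out)
  # BH within each class across its feature family
  for (cl in unique(out$class)) {
    sel <- out$class == cl & !is.na(out$p)
    out$q[sel] <- p.adjust(out$p[sel], method = "BH")
  }
  rownames(out) <- NULL
  out
}

#' Class distribution by self-reported race, with pairwise tests
#'
#' Tabulates alteration-class frequencies within each race stratum and,
#' when more than one race is present, tests each class's prevalence in
#' every non-reference race against the reference (default European
#' American) via [test_feature_enrichment()]. Patients with unknown race
#' are excluded.
#'
#' @param samples Data frame with `class` and `race` columns; race values
#'   are expected among `EA`, `AF`, `AP`, `other` (`other`/`NA` excluded
#'   from testing).
#' @param reference_race Race stratum used as the comparator (default
#'   `"EA"`).
#' @return List with `table` (data frame of per-race counts and
#'   frequencies per class) and `tests` (tidy enrichment results, or
#'   `NULL` with a single race).
#' @export
race_distribution <- function(samples, reference_race = "EA") {
  known <- c("EA", "AF", "AP")
  keep <- samples$race %in% known
  if (any(!keep)) samples <- samples[keep, , drop = FALSE]
  races <- intersect(known, unique(samples$race))
  if (length(races) == 0L) stop("no samples with characterized race")

  tab <- do.call(rbind, lapply(races, function(r) {
    sub <- samples[samples$race == r, , drop = FALSE]
    counts <- table(factor(sub$class, levels = FOXA1_CLASSES))
    data.frame(race = r, class = names(counts),
               n = as.integer(counts),
               frequency = as.numeric(counts) / nrow(sub),
               stringsAsFactors = FALSE)
  }))

  tests <- NULL
  others <- setdiff(races, reference_race)
  if (length(others) > 0L && reference_race %in% races) {
    rows <- list()
    for (r in others) {
      sub <- samples[samples$race %in% c(r, reference_race), , drop = FALSE]
      for (cl in setdiff(FOXA1_CLASSES, "WT")) {
        sub$in_class <- sub$class == cl
        # 2x2: class membership vs race, tested through the same machinery
        tmp <- sub
        tmp$race_grp <- ifelse(tmp$race == r, r, "REF")
        a <- sum(tmp$in_class & tmp$race_grp == r)
        b <- sum(!tmp$in_class & tmp$race_grp == r)
        cc <- sum(tmp$in_class & tmp$race_grp == "REF")
        dd <- sum(!tmp$in_class & tmp$race_grp == "REF")
        tst <- test_one_2x2(a, b, cc, dd)
        rows[[length(rows) + 1L]] <- data.frame(
          race = r, reference = reference_race, class = cl,
          n_race = a + b, pos_race = a, n_ref = cc + dd, pos_ref = cc,
          odds_ratio = odds_ratio_2x2(a, b, cc, dd),
          p = tst$p, q = NA_real_, test = tst$test,
          stringsAsFactors = FALSE)
      }
    }
    tests <- do.call(rbind, rows)
    for (r in unique(tests$race)) {
      sel <- tests$race == r & !is.na(tests$p)
      tests$q[sel] <- p.adjust(tests$p[sel], method = "BH")
    }
  }
  list(table = tab, tests = tests)
}
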