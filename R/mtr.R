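# Missense tolerance ratio (MTR) profiling. For every codon of a coding
# sequence, all nine possible single-nucleotide changes are classified as
# missense, synonymous or nonsense via the standard genetic code; a
# centered sliding window then compares the observed missense fraction
# among observed variants with the fraction expected from the possible
# changes. MTR = 1 is neutrality; low values mark intolerant residues.
# Nonsense changes are excluded from both sides of the expected fraction.

#' Enumerate single-nucleotide consequences per codon
#'
#' Classifies all 9 possible single-nucleotide substitutions of each codon
#' of a coding sequence as missense, synonymous or nonsense under the
#' standard genetic code. A trailing stop codon, if present, is dropped so
#' rows correspond to protein residues. For every internal codon the three
#' counts sum to 9.
#'
#' @param cds Coding sequence: a character string, a
#'   `Biostrings::DNAString`, or a length-1 `DNAStringSet` (e.g. from
#'   `readDNAStringSet()` on a FASTA file). Length must be a multiple of
#'   3; characters must be A/C/G/T.
#' @return Data frame with columns `residue`, `aa`, `missense`,
#'   `synonymous`, `nonsense`.
#' @examples
#' enumerate_codon_consequences("ATGCTGTAA")
#' @export
enumerate_codon_consequences <- function(cds) {
  if (inherits(cds, "DNAStringSet")) {
    if (length(cds) != 1L) stop("expected a single coding sequence")
    cds <- as.character(cds[[1]])
  } else if (inherits(cds, "DNAString")) {
    cds <- as.character(cds)
  }
  cds <- toupper(gsub("\\s", "", cds))
  if (!grepl("^[ACGT]+$", cds)) {
    stop("coding sequence contains characters other than A/C/G/T")
  }
  if (nchar(cds) %% 3L != 0L) {
    stop(sprintf("coding sequence length %d is not a multiple of 3", nchar(cds)))
  }
  code <- Biostrings::GENETIC_CODE
  n_codon <- nchar(cds) %/% 3L
  codons <- substring(cds, 3L * seq_len(n_codon) - 2L, 3L * seq_len(n_codon))
  if (codons[1] != "ATG") warning("coding sequence does not start with ATG")
  aas <- unname(code[codons])
  if (!is.na(aas[n_codon]) && aas[n_codon] == "*") {
    codons <- codons[-n_codon]; aas <- aas[-n_codon]
    n_codon <- n_codon - 1L
  }
  if (any(aas == "*")) warning("internal stop codon in coding sequence")

  nts <- c("A", "C", "G", "T")
  res <- data.frame(residue = seq_len(n_codon), aa = aas,
                    missense = 0L, synonymous = 0L, nonsense = 0L,
                    stringsAsFactors = FALSE)
  for (i in seq_len(n_codon)) {
    ref <- codons[i]
    ref_aa <- aas[i]
    for (pos in 1:3) {
      for (nt in setdiff(nts, substr(ref, pos, pos))) {
        alt <- ref
        substr(alt, pos, pos) <- nt
        alt_aa <- code[[alt]]
        if (alt_aa == "*") {
          res$nonsense[i] <- res$nonsense[i] + 1L
        } else if (alt_aa == ref_aa) {
          res$synonymous[i] <- res$synonymous[i] + 1L
        } else {
          res$missense[i] <- res$missense[i] + 1L
        }
      }
    }
  }
  res
}

#' Compute a sliding-window missense tolerance ratio profile
#'
#' For each residue, a centered window of `window` codons (truncated at
#' the protein termini) collects the observed missense and synonymous
#' variant counts and the possible (expected) counts from
#' [enumerate_codon_consequences()]. The expected missense fraction is
#' `possible missense / (possible missense + possible synonymous)`;
#' MTR is the observed missense fraction divided by the expected fraction,
#' and is missing where the window holds no observed variants.
#'
#' @param observed Data frame of observed variants with columns `residue`
#'   and `consequence` (`missense` or `synonymous`); repeated rows count
#'   multiply, or an optional `count` column may supply weights.
#' @param table Codon consequence table from
#'   [enumerate_codon_consequences()].
#' @param window Odd window width in codons (default 31).
#' @return Data frame per residue: `residue`, `obs_missense`,
#'   `obs_synonymous`, `exp_missense_fraction`, `mtr`.
#' @export
compute_mtr <- function(observed, table, window = 31L) {
  window <- as.integer(window)
  if (window < 1L || window %% 2L == 0L) {
    stop("window must be a positive odd number of codons")
  }
  n <- nrow(table)
  if (nrow(observed) > 0L) {
    if (any(observed$residue < 1L | observed$residue > n)) {
      stop("observed variant residue outside the coding sequence")
    }
    if (!all(observed$consequence %in% c("missense", "synonymous"))) {
      stop("observed consequences must be 'missense' or 'synonymous'")
    }
  }
  cnt <- observed$count %||% rep(1L, nrow(observed))
  obs_mis <- obs_syn <- numeric(n)
  if (nrow(observed) > 0L) {
    mis <- observed$consequence == "missense"
    obs_mis <- as.numeric(tapply2(observed$residue[mis], cnt[mis], n))
    obs_syn <- as.numeric(tapply2(observed$residue[!mis], cnt[!mis], n))
  }
  half <- (window - 1L) %/% 2L
  csum <- function(x) cumsum(c(0, x))
  wsum <- function(cs, lo, hi) cs[hi + 1L] - cs[lo]
  lo <- pmax(1L, seq_len(n) - half)
  hi <- pmin(n, seq_len(n) + half)
  w_obs_mis <- wsum(csum(obs_mis), lo, hi)
  w_obs_syn <- wsum(csum(obs_syn), lo, hi)
  w_exp_mis <- wsum(csum(table$missense), lo, hi)
  w_exp_syn <- wsum(csum(table$synonymous), lo, hi)
  exp_frac <- w_exp_mis / (w_exp_mis + w_exp_syn)
  obs_tot <- w_obs_mis + w_obs_syn
  mtr <- ifelse(obs_tot > 0, (w_obs_mis / obs_tot) / exp_frac, NA_real_)
  data.frame(residue = seq_len(n),
             obs_missense = w_obs_mis, obs_synonymous = w_obs_syn,
             exp_missense_fraction = exp_frac, mtr = mtr,
             window = window)
}

# sum weights w at integer positions idx into a length-n vector
tapply2 <- function(idx, w, n) {
  out <- numeric(n)
  if (length(idx)) {
    s <- tapply(w, idx, sum)
    out[as.integer(names(s))] <- s
  }
  out
}

#' Exact binomial tests on an MTR profile
#'
#' Per residue, a two-sided exact binomial test (minimum-likelihood
#' method) of the window's observed missense count out of observed
#' missense + synonymous variants against the expected missense fraction,
#' with BH adjustment across residues. A one-sided (intolerance,
#' `less`) alternative is available since profiles are usually screened
#' for depressed MTR. Windows with zero observed variants get missing p.
#'
#' @param profile Data frame from [compute_mtr()].
#' @param alternative `"two.sided"` (default) or `"less"`.
#' @return `profile` with added `p` and `q` columns.
#' @export
residue_binomial_tests <- function(profile,
                                   alternative = c("two.sided", "less")) {
  alternative <- match.arg(alternative)
  n_trial <- profile$obs_missense + profile$obs_synonymous
  p <- rep(NA_real_, nrow(profile))
  for (i in seq_len(nrow(profile))) {
    if (n_trial[i] > 0 && is.finite(profile$exp_missense_fraction[i])) {
      p[i] <- binom.test(round(profile$obs_missense[i]), round(n_trial[i]),
                         p = profile$exp_missense_fraction[i],
                         alternative = alternative)$p.value
    }
  }
  profile$p <- p
  profile$q <- NA_real_
  sel <- !is.na(p)
  profile$q[sel] <- p.adjust(p[sel], method = "BH")
  profile
}

#' Gene-specific MTR percentile thresholds
#'
#' Quantiles of the defined (non-missing) MTR values, used as horizontal
#' reference lines when plotting a profile (5th, 25th and 50th percentile
#' by default, alongside neutrality at 1.0).
#'
#' @param profile Data frame from [compute_mtr()].
#' @param probs Percentile probabilities (default `c(0.05, 0.25, 0.5)`).
#' @return Named numeric vector of thresholds.
#' @export
mtr_percentiles <- function(profile, probs = c(0.05, 0.25, 0.5)) {
  quantile(profile$mtr, probs = probs, na.rm = TRUE, names = TRUE)
}
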