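# Independent brute-force oracles used to validate the package's
# implementations on small inputs.

# Flat truth-table classifier: a direct transcription of the rule set as a
# lookup over (effect, anchor residue, alt amino acid), written without
# reference to the rule-ordered implementation.
truth_table_classify <- function(effect, residue, alt = "", d = foxa1_domains()) {
  stopifnot(length(effect) == 1L)
  fkh <- seq(d$fkh_start, d$fkh_end)
  wing2 <- seq(d$wing2_start, d$fkh_end)
  pre_wing2 <- setdiff(fkh, wing2)
  if (effect == "missense" && residue == d$class2_residue &&
      alt %in% d$class2_alt_residues) return("C2")
  if (effect %in% c("missense", "inframe_insertion", "inframe_deletion",
                    "inframe_delins")) {
    if (residue %in% pre_wing2) return("C1A")
    if (residue %in% wing2) return("C1B")
    return("C1C")
  }
  if (effect %in% c("nonsense", "frameshift", "splice")) {
    if (residue <= d$fkh_end) return("C3A")
    return("C3B")
  }
  "WT"
}

# Two-sided Fisher p as an exhaustive hypergeometric tail sum: sum the
# probabilities of all tables (with the observed margins) no more likely
# than the observed one.
fisher_oracle_p <- function(a, b, c, d) {
  m <- a + b          # row 1 total
  n_ <- c + d         # row 2 total
  k <- a + c          # column 1 total
  lo <- max(0L, k - n_)
  hi <- min(k, m)
  support <- lo:hi
  probs <- stats::dhyper(support, m, n_, k)
  p_obs <- stats::dhyper(a, m, n_, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Log-rank statistic by direct enumeration of the 2x2 risk table at every
# distinct event time (no ties handling subtleties beyond the standard
# hypergeometric variance).
logrank_oracle <- function(time, event, group) {
  stopifnot(all(group %in% c(0, 1)))
  times <- sort(unique(time[event == 1]))
  O <- E <- V <- 0
  for (t in times) {
    at_risk <- time >= t
    n1 <- sum(at_risk & group == 1)
    n0 <- sum(at_risk & group == 0)
    n <- n1 + n0
    d1 <- sum(time == t & event == 1 & group == 1)
    d0 <- sum(time == t & event == 1 & group == 0)
    dt <- d1 + d0
    O <- O + d1
    E <- E + dt * n1 / n
    if (n > 1) V <- V + dt * (n1 / n) * (n0 / n) * (n - dt) / (n - 1)
  }
  chisq <- (O - E)^2 / V
  list(chisq = chisq, p = stats::pchisq(chisq, df = 1, lower.tail = FALSE))
}

# MTR profile recomputed from scratch: every window rebuilt by explicit
# subsetting rather than cumulative sums.
mtr_oracle <- function(observed, table, window) {
  n <- nrow(table)
  half <- (window - 1) / 2
  out <- data.frame(residue = seq_len(n), mtr = NA_real_)
  for (r in seq_len(n)) {
    win <- max(1, r - half):min(n, r + half)
    om <- sum(observed$residue %in% win &
                observed$consequence == "missense")
    os <- sum(observed$residue %in% win &
                observed$consequence == "synonymous")
    em <- sum(table$missense[win])
    es <- sum(table$synonymous[win])
    if (om + os > 0) {
      out$mtr[r] <- (om / (om + os)) / (em / (em + es))
    }
  }
  out
}

# Exact Mann-Whitney p for tiny samples by enumerating all group
# assignments of the pooled values.
mann_whitney_oracle <- function(x, y) {
  pooled <- c(x, y)
  n <- length(pooled)
  idx <- utils::combn(n, length(x))
  u_stat <- function(sel) {
    xs <- pooled[sel]; ys <- pooled[-sel]
    sum(outer(xs, ys, ">")) + 0.5 * sum(outer(xs, ys, "=="))
  }
  u_obs <- u_stat(seq_along(x))
  us <- apply(idx, 2, u_stat)
  mu <- length(x) * (n - length(x)) / 2
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
}

# small classified cohort shared by several tests
make_small_cohort <- function(n = 300, seed = 42, null = FALSE) {
  cfg <- cohort_config(n_patients = n)
  co <- if (null) generate_null_cohort(cfg, seed) else generate_cohort(cfg, seed)
  cls <- classify_cohort(co$variants, co$copy_number,
                         sample_ids = co$samples$sample_id)
  co$samples$class <- cls$per_sample$class[
    match(co$samples$sample_id, cls$per_sample$sample_id)]
  co$per_alteration <- cls$per_alteration
  co
}
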