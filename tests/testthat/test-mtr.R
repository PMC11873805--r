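test_that("codon consequence enumeration matches exhaustive SNV counts", {
  # ATG: all 9 single-nucleotide changes are missense
  atg <- enumerate_codon_consequences("ATGGGGTAA")
  expect_equal(atg[1, c("missense", "synonymous", "nonsense")],
               data.frame(missense = 9L, synonymous = 0L, nonsense = 0L),
               ignore_attr = TRUE)
  # CTG (Leu): 5 missense, 4 synonymous, 0 nonsense
  ctg <- suppressWarnings(enumerate_codon_consequences("CTGGGG"))
  expect_equal(unlist(ctg[1, c("missense", "synonymous", "nonsense")]),
               c(missense = 5L, synonymous = 4L, nonsense = 0L))
  # every internal codon's consequences sum to 9
  set.seed(2)
  cds <- paste0("ATG", paste(sample(c("A", "C", "G", "T"), 30, TRUE),
                             collapse = ""), "TAA")
  tab <- suppressWarnings(enumerate_codon_consequences(cds))
  expect_true(all(tab$missense + tab$synonymous + tab$nonsense == 9L))
  # trailing stop codon is dropped from the residue table
  expect_equal(nrow(tab), 11L)
})

test_that("malformed coding sequences raise format errors", {
  expect_error(enumerate_codon_consequences("ATGCTGTACA"), "multiple of 3")
  expect_error(enumerate_codon_consequences("ATGNNNTAA"), "other than A/C/G/T")
  expect_warning(enumerate_codon_consequences("CTGGGG"), "does not start with ATG")
})

test_that("MTR formula reproduces its defining ratios", {
  tab <- data.frame(residue = 1:1, aa = "X", missense = 6L, synonymous = 2L,
                    nonsense = 1L)
  # expected missense fraction 6/8 = 0.75; observed 2 of 4 -> MTR = 0.667
  obs <- data.frame(residue = c(1, 1, 1, 1),
                    consequence = c("missense", "missense",
                                    "synonymous", "synonymous"))
  prof <- compute_mtr(obs, tab, window = 1)
  expect_equal(prof$mtr, (2 / 4) / 0.75, tolerance = 1e-12)
  # zero observed variants -> MTR missing
  prof0 <- compute_mtr(obs[0, ], tab, window = 1)
  expect_true(is.na(prof0$mtr))
  # observed proportional to possible in every window -> MTR exactly 1
  cds <- "ATGCTGCGATTACCGTAA"
  tab2 <- enumerate_codon_consequences(cds)
  obs2 <- rbind(
    data.frame(residue = tab2$residue, consequence = "missense",
               count = tab2$missense),
    data.frame(residue = tab2$residue, consequence = "synonymous",
               count = tab2$synonymous)
  )
  prof2 <- compute_mtr(obs2, tab2, window = 3)
  expect_equal(prof2$mtr, rep(1, nrow(tab2)), tolerance = 1e-12)
  expect_error(compute_mtr(obs, tab, window = 4), "odd")
})

test_that("windowed MTR agrees with a brute-force recomputation on tiny genes", {
  set.seed(7)
  for (rep in 1:10) {
    n_codon <- sample(2:5, 1)
    cds <- paste0("ATG", paste(sample(c("A", "C", "G", "T"),
                                      3 * (n_codon - 1), TRUE), collapse = ""))
    tab <- suppressWarnings(enumerate_codon_consequences(cds))
    n_obs <- sample(0:12, 1)
    obs <- data.frame(
      residue = sample(nrow(tab), n_obs, replace = TRUE),
      consequence = sample(c("missense", "synonymous"), n_obs, TRUE)
    )
    for (w in c(1, 3, 5)) {
      got <- compute_mtr(obs, tab, window = w)
      want <- mtr_oracle(obs, tab, w)
      expect_equal(got$mtr, want$mtr, tolerance = 1e-12,
                   info = sprintf("n_codon=%d w=%d", n_codon, w))
    }
  }
})

test_that("binomial residue tests are exact and BH-adjusted", {
  prof <- data.frame(residue = 1:3,
                     obs_missense = c(4, 2, 0),
                     obs_synonymous = c(0, 2, 0),
                     exp_missense_fraction = c(0.5, 0.5, 0.5))
  out <- residue_binomial_tests(prof)
  # 4/4 at expected 0.5: two-sided p = 2 * 0.5^4 = 0.125
  expect_equal(out$p[1], 0.125, tolerance = 1e-12)
  # observed fraction equal to expected -> maximal p
  expect_equal(out$p[2], 1)
  # zero-trial window -> missing
  expect_true(is.na(out$p[3]))
  # uniform p across windows -> q equals the common p
  prof_same <- prof[c(1, 1, 1), ]
  out_same <- residue_binomial_tests(prof_same)
  expect_equal(out_same$q, rep(0.125, 3))
  # one-sided intolerance alternative
  low <- data.frame(residue = 1, obs_missense = 0, obs_synonymous = 5,
                    exp_missense_fraction = 0.75)
  p_less <- residue_binomial_tests(low, alternative = "less")$p
  expect_equal(p_less, 0.25^5, tolerance = 1e-12)
})

test_that("percentile thresholds partition the defined MTR values", {
  set.seed(31)
  prof <- data.frame(mtr = c(runif(200), rep(NA, 20)))
  pct <- mtr_percentiles(prof)
  expect_named(pct, c("5%", "25%", "50%"))
  defined <- prof$mtr[!is.na(prof$mtr)]
  for (i in seq_along(pct)) {
    frac <- mean(defined <= pct[i])
    expect_equal(frac, c(0.05, 0.25, 0.5)[i], tolerance = 0.02)
  }
})

test_that("a neutral variant generator keeps MTR near 1 with <= 5% discoveries", {
  set.seed(17)
  # synthetic gene of 120 codons; variants sampled proportional to the
  # possible consequence counts (the neutral model)
  cds <- paste0("ATG", paste(sample(c("A", "C", "G", "T"), 357, TRUE),
                             collapse = ""))
  tab <- suppressWarnings(enumerate_codon_consequences(cds))
  weights <- c(tab$missense, tab$synonymous)
  labels <- rep(c("missense", "synonymous"), each = nrow(tab))
  residues <- rep(tab$residue, 2)
  qs <- mtrs <- numeric(0)
  for (s in 1:10) {
    pick <- sample(length(weights), 400, replace = TRUE, prob = weights)
    obs <- data.frame(residue = residues[pick], consequence = labels[pick])
    prof <- residue_binomial_tests(compute_mtr(obs, tab, window = 31))
    mtrs <- c(mtrs, prof$mtr)
    qs <- c(qs, prof$q)
  }
  expect_equal(mean(mtrs, na.rm = TRUE), 1, tolerance = 0.05)
  expect_lte(mean(qs < 0.05, na.rm = TRUE), 0.05 + 0.03)
})
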