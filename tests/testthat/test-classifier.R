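test_that("classification rules reproduce the schema's worked examples", {
  d <- foxa1_domains()
  v <- parse_hgvs_p(c("p.R219C", "p.R219S", "p.R219H", "p.F250_Q252del",
                      "p.A50V", "p.E100*", "p.G300fs"))
  expect_equal(classify_variant(v, d),
               c("C2", "C2", "C1A", "C1B", "C1C", "C3A", "C3B"))
})

test_that("class boundaries flip exactly at residues 168, 247 and 270", {
  d <- foxa1_domains()
  mis <- function(r) data.frame(effect = "missense", start_aa = r, end_aa = r,
                                ref_aa = "A", alt_aa = "V")
  trunc <- function(r) data.frame(effect = "nonsense", start_aa = r, end_aa = r,
                                  ref_aa = "A", alt_aa = "*")
  expect_equal(classify_variant(mis(167), d), "C1C")
  expect_equal(classify_variant(mis(168), d), "C1A")
  expect_equal(classify_variant(mis(246), d), "C1A")
  expect_equal(classify_variant(mis(247), d), "C1B")
  expect_equal(classify_variant(mis(269), d), "C1B")
  expect_equal(classify_variant(mis(270), d), "C1C")
  expect_equal(classify_variant(trunc(269), d), "C3A")
  expect_equal(classify_variant(trunc(270), d), "C3B")
})

test_that("rule-ordered classifier agrees with a flat truth table on an exhaustive sweep", {
  d <- foxa1_domains()
  effects <- c("missense", "inframe_deletion", "inframe_insertion",
               "inframe_delins", "nonsense", "frameshift")
  alts <- c("C", "S", "H")
  labels <- character(0)
  for (eff in effects) {
    for (alt in alts) {
      v <- data.frame(effect = eff, start_aa = seq_len(d$protein_length),
                      end_aa = seq_len(d$protein_length),
                      ref_aa = "R",
                      alt_aa = if (eff == "missense") alt else "")
      got <- classify_variant(v, d)
      want <- vapply(seq_len(d$protein_length), function(r) {
        truth_table_classify(eff, r, if (eff == "missense") alt else "", d)
      }, "")
      expect_identical(got, want,
                       info = sprintf("effect=%s alt=%s", eff, alt))
      labels <- union(labels, got)
    }
  }
  labels <- union(labels, classify_copy_number(6, d))
  # sweep + one amplification yields exactly the 7 non-WT subclasses
  expect_setequal(labels, c("C1A", "C1B", "C1C", "C2", "C3A", "C3B", "C4"))
})

test_that("amplification calls flip at the copy-number threshold", {
  expect_equal(classify_copy_number(c(0, 2, 5, 5.9, 6, 7, 40)),
               c(NA, NA, NA, NA, "C4", "C4", "C4"))
  expect_error(classify_copy_number(-1), "negative")
})

test_that("pathogenicity filtering keeps only pathogenic/likely pathogenic", {
  v <- data.frame(hgvs_p = paste0("p.A", 1:5, "V"),
                  pathogenicity = c("pathogenic", "VUS", "benign",
                                    "likely_pathogenic", "likely_benign"))
  expect_equal(filter_pathogenic(v)$pathogenicity,
               c("pathogenic", "likely_pathogenic"))
  expect_equal(nrow(filter_pathogenic(v[0, , drop = FALSE])), 0L)
  expect_equal(filter_pathogenic(v, include_vus = TRUE)$pathogenicity,
               c("pathogenic", "VUS", "likely_pathogenic"))
  v$pathogenicity[1] <- NA
  expect_error(filter_pathogenic(v), "missing or unrecognized")
  expect_equal(nrow(filter_pathogenic(v, allow_missing = TRUE)), 2L)
})

test_that("splice handling and anchor policy behave per their flags", {
  d <- foxa1_domains()
  spl <- data.frame(effect = "splice", start_aa = c(100L, 300L),
                    end_aa = c(100L, 300L), ref_aa = "A", alt_aa = "")
  expect_equal(classify_variant(spl, d), c("C3A", "C3B"))
  expect_equal(classify_variant(spl, d, splice_policy = "exclude"),
               c("WT", "WT"))
  # deletion anchored before Wing2 but overlapping it
  del <- data.frame(effect = "inframe_deletion", start_aa = 245L,
                    end_aa = 250L, ref_aa = "AQ", alt_aa = "")
  expect_equal(classify_variant(del, d), "C1A")
  expect_equal(classify_variant(del, d, anchor_policy = "any_overlap_wing2"),
               "C1B")
  oth <- data.frame(effect = "other", start_aa = 1L, end_aa = 1L,
                    ref_aa = "", alt_aa = "")
  expect_error(classify_variant(oth, d), "cannot be classified")
  expect_equal(classify_variant(oth, d, other_policy = "wt"), "WT")
})

test_that("sample-level labels follow the precedence policy", {
  d <- foxa1_domains()
  r219s <- parse_hgvs_p("p.R219S")
  expect_equal(classify_sample(r219s, copies = 9, d)$sample_class, "C2")
  expect_equal(classify_sample(NULL, NULL, d)$sample_class, "WT")
  expect_equal(classify_sample(parse_hgvs_p("p.F254del"), NULL, d)$sample_class,
               "C1B")
  both <- parse_hgvs_p(c("p.A50V", "p.E300fs"))
  expect_equal(classify_sample(both, NULL, d)$sample_class, "C3B")
  expect_equal(classify_sample(both, NULL, d,
                               precedence = c("C1C", "C3B"))$sample_class,
               "C1C")
})

test_that("cohort classification resolves per-sample labels and lollipop counts", {
  variants <- data.frame(
    sample_id = c("s1", "s1", "s2", "s3"),
    gene = c("FOXA1", "FOXA1", "FOXA1", "FOXA1"),
    hgvs_p = c("p.R219C", "p.A400V", "p.F254del", "p.M1V"),
    pathogenicity = c("pathogenic", "VUS", "likely_pathogenic", "benign"),
    stringsAsFactors = FALSE
  )
  cn <- data.frame(sample_id = c("s2", "s4"), gene = "FOXA1",
                   copies = c(2, 8), stringsAsFactors = FALSE)
  out <- classify_cohort(variants, cn, sample_ids = paste0("s", 1:5))
  got <- setNames(out$per_sample$class, out$per_sample$sample_id)
  expect_equal(got[c("s1", "s2", "s3", "s4", "s5")],
               c(s1 = "C2", s2 = "C1B", s3 = "WT", s4 = "C4", s5 = "WT"))
  rc <- residue_counts(out$per_alteration)
  expect_equal(rc$residue, c(219, 254))
  expect_equal(rc$count, c(1L, 1L))
})
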