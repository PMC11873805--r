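events_df <- function(days, kinds = "claim", categories = NA) {
  data.frame(patient_id = rep("p1", length(days)),
             date = as.Date("2020-01-01") + days,
             kind = rep(kinds, length.out = length(days)),
             drug = rep(NA_character_, length(days)),
             drug_category = rep(categories, length.out = length(days)),
             stringsAsFactors = FALSE)
}

test_that("the no-claim gap rule infers death strictly beyond the threshold", {
  cutoff <- as.Date("2020-01-01") + 200
  # gap 140 days -> assumed death at the last claim
  r <- infer_vital_status(events_df(c(0, 30, 60)), cutoff)
  expect_equal(r$event, 1L)
  expect_equal(r$terminal_date, as.Date("2020-01-01") + 60)
  # gap exactly 100 days -> censored
  r <- infer_vital_status(events_df(c(0, 100)), cutoff)
  expect_equal(r$event, 0L)
  expect_equal(r$terminal_date, as.Date("2020-01-01") + 100)
  # gap 101 days -> death
  r <- infer_vital_status(events_df(c(0, 99)), cutoff)
  expect_equal(r$event, 1L)
  # gap 50 days -> censored at last contact
  r <- infer_vital_status(events_df(c(0, 150)), cutoff)
  expect_equal(r$event, 0L)
  expect_error(infer_vital_status(events_df(numeric(0)), cutoff), "no events")
  expect_error(infer_vital_status(events_df(0), as.Date("2019-01-01")),
               "precedes")
})

test_that("raising the gap threshold never converts censoring into death", {
  set.seed(5)
  cutoff <- as.Date("2020-01-01") + 400
  for (i in 1:50) {
    ev <- events_df(sort(sample(0:360, sample(2:8, 1))))
    flags <- vapply(c(60, 100, 150, 250),
                    function(g) infer_vital_status(ev, cutoff, g)$event, 0L)
    expect_true(all(diff(flags) <= 0))  # monotone non-increasing in gap_days
  }
})

test_that("castration state follows the 90-day rule with a strict boundary", {
  ev <- events_df(c(0, 30, 90, 91, 200),
                  kinds = c("treatment_start", "treatment_start",
                            "treatment_start", "treatment_start",
                            "treatment_start"),
                  categories = c("first_line_ADT", "second_gen_ARSI",
                                 "second_gen_ARSI", "second_gen_ARSI",
                                 "taxane"))
  out <- annotate_castration_state(ev)
  expect_equal(out$castration_state,
               c("hormone_sensitive", "hormone_sensitive",
                 "hormone_sensitive", "castration_resistant",
                 "castration_resistant"))
  # no ADT on record -> unknown
  ev2 <- events_df(10, kinds = "treatment_start", categories = "taxane")
  expect_equal(annotate_castration_state(ev2)$castration_state, "unknown")
})

test_that("survival records index at the first start of the category", {
  samples <- data.frame(patient_id = c("p1", "p2"), class = c("C2", "WT"),
                        stringsAsFactors = FALSE)
  claims <- rbind(
    data.frame(patient_id = "p1", date = as.Date("2020-01-01") + c(0, 10, 400, 500),
               kind = c("claim", "treatment_start", "treatment_start", "claim"),
               drug = NA, drug_category = c(NA, "second_gen_ARSI",
                                            "second_gen_ARSI", NA)),
    data.frame(patient_id = "p2", date = as.Date("2020-01-01") + c(0, 40),
               kind = "claim", drug = NA, drug_category = NA)
  )
  cutoff <- as.Date("2020-01-01") + 700
  rec <- build_survival_records(samples, claims, category = "second_gen_ARSI",
                                cutoff_date = cutoff)
  expect_equal(nrow(rec), 1L)  # p2 never received the category
  expect_equal(rec$index_date, as.Date("2020-01-01") + 10)
  expect_equal(rec$event, 1L)  # last claim 500, gap 200 > 100
  expect_equal(rec$time_days, 490)

  # index coinciding with the imputed death date -> dropped with a warning
  claims3 <- data.frame(patient_id = "p1",
                        date = as.Date("2020-01-01") + c(0, 50),
                        kind = c("claim", "treatment_start"),
                        drug = NA, drug_category = "taxane")
  expect_warning(
    rec3 <- build_survival_records(samples[1, ], claims3, category = "taxane",
                                   cutoff_date = cutoff),
    "non-positive")
  expect_equal(nrow(rec3), 0L)
})

test_that("two-arm Cox fit is symmetric, invertible and matches the log-rank oracle", {
  # identical event-time multisets in the two arms -> HR 1
  rec <- data.frame(patient_id = as.character(1:8), class = rep(c("C2", "WT"), each = 4),
                    time_days = rep(c(30, 60, 90, 120), 2), event = 1L)
  fit <- fit_class_vs_wt(rec, "C2")
  expect_equal(fit$hr, 1, tolerance = 1e-8)
  expect_true(fit$converged)

  # 4-patient toy: arm A events at {1,2}, arm B at {3,4}
  toy <- data.frame(patient_id = as.character(1:4),
                    class = c("C2", "C2", "WT", "WT"),
                    time_days = c(1, 2, 3, 4), event = 1L)
  got <- suppressWarnings(fit_class_vs_wt(toy, "C2"))
  oracle <- logrank_oracle(toy$time_days, toy$event,
                           as.integer(toy$class == "C2"))
  expect_equal(got$p_logrank, oracle$p, tolerance = 1e-10)

  # larger random data still matches the enumeration oracle
  set.seed(1)
  rnd <- data.frame(patient_id = as.character(1:40),
                    class = rep(c("C2", "WT"), each = 20),
                    time_days = sample(1:100, 40), event = rbinom(40, 1, 0.7))
  got <- fit_class_vs_wt(rnd, "C2")
  oracle <- logrank_oracle(rnd$time_days, rnd$event,
                           as.integer(rnd$class == "C2"))
  expect_equal(got$p_logrank, oracle$p, tolerance = 1e-8)

  # relabeling arms inverts the hazard ratio
  swapped <- rnd
  swapped$class <- ifelse(rnd$class == "C2", "WT", "C2")
  expect_equal(fit_class_vs_wt(swapped, "C2")$hr, 1 / got$hr,
               tolerance = 1e-8)
})

test_that("arms without events are reported as non-convergent", {
  rec <- data.frame(patient_id = as.character(1:10),
                    class = rep(c("C2", "WT"), each = 5),
                    time_days = 1:10,
                    event = rep(c(0L, 1L), each = 5))
  fit <- fit_class_vs_wt(rec, "C2")
  expect_false(fit$converged)
  expect_true(is.na(fit$hr))
})

test_that("the fitted hazard ratio recovers a known generating value", {
  # two-arm exponential data with true HR = 2 at moderate n
  set.seed(99)
  n <- 1500
  grp <- rep(c(1, 0), each = n / 2)
  t <- rexp(n, rate = 0.01 * ifelse(grp == 1, 2, 1))
  cens <- runif(n, 0, 250)
  rec <- data.frame(patient_id = as.character(1:n),
                    class = ifelse(grp == 1, "C2", "WT"),
                    time_days = pmin(t, cens),
                    event = as.integer(t <= cens))
  fit <- fit_class_vs_wt(rec, "C2")
  se <- (log(fit$ci_high) - log(fit$ci_low)) / (2 * 1.96)
  expect_lt(abs(log(fit$hr) - log(2)) / se, 3)
})
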