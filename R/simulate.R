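# Synthetic cohort generation. The generator emits the same table dialects
# the analysis modules read (variants, copy number, claims, per-sample
# features, expression) plus a ground-truth table, with class prevalences,
# race mix, biopsy-site mix, class-conditional outcome hazards, feature
# probabilities and expression shifts set to the summary statistics of the
# 5,014-sample real-world prostate cohort the package's analyses target.
# Per-class prevalence splits are approximate (the aggregate alteration
# rate is 16%); they are configuration values, not claims of fidelity.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

default_gene_sets <- function() {
  # illustrative placeholder sets; real analyses should supply published
  # signature gene lists via the gene-set config
  list(
    ar_signature = c("KLK3", "KLK2", "NKX3-1", "TMPRSS2", "FKBP5", "PART1"),
    nepc_signature = c("SYP", "CHGA", "ENO2", "NCAM1", "INSM1", "ASCL1"),
    ifng_signature = c("STAT1", "IDO1", "CXCL9", "CXCL10", "HLA-DRA", "GZMA"),
    tcell_inflammation = c("CD8A", "GZMB", "PRF1", "CCL5", "CD274", "LAG3")
  )
}

class_vec <- function(default, ...) {
  v <- setNames(rep(default, 8L), FOXA1_CLASSES)
  ov <- c(...)
  v[names(ov)] <- ov
  v
}

#' Default synthetic-cohort configuration
#'
#' Returns the generator configuration. Defaults encode the target
#' cohort's published structure: 5,014 patients, ~16% FOXA1-altered with
#' class 1B the most and class 2 (R219C/S) the rarest subclass; 60.3%
#' prostate / 39.7% metastatic biopsies; race mix 74.7% EA / 17.3% AF /
#' 3.0% AP with class tilts (class 1B 17.5% in AP vs 7.0% in EA, class 1C
#' 3.2% in AF vs 1.8% in EA, class 3A 3.2% in AP vs 1.7% in EA);
#' class-conditional overall-survival hazard ratios versus WT (class 2 =
#' 2.05, class 3A = 0.70, class 3B = 1.50, with modest non-significant
#' effects elsewhere) on a Weibull baseline (shape 1.2, WT median 36
#' months); TMPRSS2-ERG fusion 34.5% in WT and essentially absent in
#' classes 1B/2; TP53 mutation 35.8% WT vs 20.4% class 1B; MSI-high 3.3%
#' WT vs 13.1% class 1C and 15.5% class 3B; TMB-high 3.4% WT vs 12.1%
#' class 1C and 19.0% class 3B; FOXA1 transcript overexpression in classes
#' 1A/1B/3A/3B/4. Claims arrive with a mean 30-day inter-claim gap (capped
#' at 90 days for actively followed patients, reflecting routine billing),
#' loss to follow-up is an independent low-rate process, and the
#' administrative cutoff falls 3,900 days after the 120-day accrual
#' window closes.
#'
#' @param n_patients Cohort size (default 5014).
#' @param ... Named overrides of any configuration entry.
#' @return A list of class `foxa1_cohort_config`.
#' @export
cohort_config <- function(n_patients = 5014L, ...) {
  cfg <- list(
    n_patients = as.integer(n_patients),
    origin_date = as.Date("2015-01-01"),
    domains = foxa1_domains(),
    race_mix = c(EA = 0.747, AF = 0.173, AP = 0.0301, other = 0.0499),
    # per-race class prevalences (fraction of that race's patients);
    # the base vector applies to EA and 'other'
    class_prev_base = c(C1A = 0.020, C1B = 0.070, C1C = 0.018,
                        C2 = 0.0048, C3A = 0.017, C3B = 0.018, C4 = 0.018),
    class_prev_overrides = list(
      AP = c(C1B = 0.175, C3A = 0.032),
      AF = c(C1C = 0.032)
    ),
    site_mix = c(prostate = 0.603, metastatic = 0.397),
    hazard_ratio = class_vec(1, C1A = 0.85, C1B = 0.90, C1C = 1.10,
                             C2 = 2.05, C3A = 0.70, C3B = 1.50, C4 = 1.20),
    weibull_shape = 1.2,
    wt_median_os_days = 1095,
    treat_prob = c(first_line_ADT = 0.678, second_gen_ARSI = 0.475,
                   taxane = 0.317),
    accrual_days = 120L,
    followup_days = 3900L,
    claim_gap_mean = 30,
    claim_gap_max = 90,
    ltfu_rate = 1e-5,
    vus_rate = 0.03,
    erg_prob = class_vec(0.30, WT = 0.345, C1B = 0.005, C2 = 0.005,
                         C3A = 0.15, C3B = 0.15),
    tp53_prob = class_vec(0.358, C1B = 0.204),
    msi_prob = class_vec(0.033, C1C = 0.131, C3B = 0.155),
    tmb_high_prob = class_vec(0.034, C1C = 0.121, C3B = 0.190),
    nepc_prob = class_vec(0.021, C2 = 0.33),
    gene_sets = default_gene_sets(),
    expr_sd = 1,
    foxa1_shift = class_vec(0, C1A = 1, C1B = 1, C3A = 1, C3B = 1, C4 = 1.3),
    ar_shift = class_vec(0, C2 = -0.5),
    sig_shift = list(
      ar_signature = class_vec(0, C1A = 0.5, C1B = 0.5, C3A = 0.3, C2 = -1),
      nepc_signature = class_vec(0, C2 = 1.5),
      ifng_signature = class_vec(0, C1B = -0.7, C4 = -0.5),
      tcell_inflammation = class_vec(0, C1A = -0.5, C1B = -0.7)
    )
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) {
    stop(sprintf("unknown configuration entries: %s",
                 paste(unknown, collapse = ", ")))
  }
  cfg[names(dots)] <- dots
  class(cfg) <- "foxa1_cohort_config"
  validate_cohort_config(cfg)
  cfg
}

validate_cohort_config <- function(cfg) {
  stopifnot(cfg$n_patients >= 1L)
  probs <- c(cfg$class_prev_base, cfg$race_mix, cfg$site_mix, cfg$treat_prob,
             cfg$erg_prob, cfg$tp53_prob, cfg$msi_prob, cfg$tmb_high_prob,
             cfg$nepc_prob, cfg$vus_rate)
  if (any(probs < 0 | probs > 1)) stop("all probabilities must lie in [0, 1]")
  for (ov in cfg$class_prev_overrides) {
    prev <- cfg$class_prev_base; prev[names(ov)] <- ov
    if (sum(prev) > 1) stop("per-race class prevalences exceed 1")
  }
  if (sum(cfg$class_prev_base) > 1) stop("class prevalences exceed 1")
  if (any(cfg$hazard_ratio <= 0)) stop("hazard ratios must be positive")
  if (cfg$claim_gap_mean <= 1 || cfg$claim_gap_max <= cfg$claim_gap_mean) {
    stop("claim gap parameters must satisfy 1 < mean < max")
  }
  invisible(cfg)
}

race_prevalence <- function(cfg, race) {
  prev <- cfg$class_prev_base
  ov <- cfg$class_prev_overrides[[race]]
  if (!is.null(ov)) prev[names(ov)] <- ov
  prev
}

# One synthetic alteration (HGVS fields) whose classification is `cl` by
# construction under the default anchor policy.
synth_variant_fields <- function(cl, d) {
  len <- d$protein_length
  pick_aa <- function(exclude = character()) {
    sample(setdiff(AA20, exclude), 1L)
  }
  if (cl == "C2") {
    return(list(effect = "missense", start_aa = d$class2_residue,
                end_aa = d$class2_residue, ref_aa = "R",
                alt_aa = sample(d$class2_alt_residues, 1L)))
  }
  if (cl %in% c("C1A", "C1B", "C1C")) {
    region <- switch(cl,
      C1A = d$fkh_start:(d$wing2_start - 1L),
      C1B = d$wing2_start:d$fkh_end,
      C1C = c(seq_len(d$fkh_start - 1L), (d$fkh_end + 1L):len))
    eff <- sample(c("missense", "inframe_deletion", "inframe_insertion",
                    "inframe_delins"),
                  1L, prob = c(0.80, 0.12, 0.04, 0.04))
    s <- sample(region, 1L)
    if (eff == "missense") {
      excl <- if (s == d$class2_residue) d$class2_alt_residues else character()
      ref <- pick_aa()
      alt <- pick_aa(exclude = c(ref, excl))
      return(list(effect = eff, start_aa = s, end_aa = s,
                  ref_aa = ref, alt_aa = alt))
    }
    if (eff == "inframe_insertion") {
      if (s >= len) s <- len - 1L
      return(list(effect = eff, start_aa = s, end_aa = s + 1L,
                  ref_aa = paste0(pick_aa(), pick_aa()),
                  alt_aa = paste(sample(AA20, sample(1:2, 1L),
                                        replace = TRUE), collapse = "")))
    }
    span <- sample(1:3, 1L)
    e <- min(s + span - 1L, len)
    ref <- if (e > s) paste0(pick_aa(), pick_aa()) else pick_aa()
    alt <- if (eff == "inframe_delins") {
      paste(sample(AA20, sample(1:2, 1L), replace = TRUE), collapse = "")
    } else ""
    return(list(effect = eff, start_aa = s, end_aa = e,
                ref_aa = ref, alt_aa = alt))
  }
  if (cl %in% c("C3A", "C3B")) {
    region <- if (cl == "C3A") seq_len(d$fkh_end) else (d$fkh_end + 1L):len
    s <- sample(region, 1L)
    eff <- sample(c("nonsense", "frameshift"), 1L, prob = c(0.45, 0.55))
    alt <- if (eff == "nonsense") "*" else {
      if (runif(1) < 0.5) pick_aa() else ""
    }
    return(list(effect = eff, start_aa = s, end_aa = s,
                ref_aa = pick_aa(), alt_aa = alt))
  }
  stop(sprintf("no variant synthesis for class %s", cl))
}

rweibull_ph <- function(n, shape, scale, log_hr) {
  scale * (-log(runif(n)) / exp(log_hr))^(1 / shape)
}

# inter-claim gaps: geometric (mean `gap_mean`) capped at `gap_max` days,
# so an actively followed patient can never show a rule-triggering gap
claim_gaps <- function(n, gap_mean, gap_max) {
  pmin(rgeom(n, 1 / gap_mean), gap_max - 1) + 1
}

#' Generate a synthetic prostate-cancer cohort
#'
#' Deterministic given `(config, seed)`. Classes are assigned
#' multinomially (per race, honoring the configured tilts); alteration
#' classes receive synthesized HGVS protein strings drawn from the class's
#' legal residue region and effect set, so re-classifying the emitted
#' variant tables reproduces the ground-truth class for every sample.
#' Survival times are Weibull with per-class proportional hazards indexed
#' at the first systemic treatment; claims streams are emitted so that
#' true deaths manifest as claim gaps longer than the inference threshold
#' while followed patients keep claiming through the cutoff; molecular
#' features and expression are drawn from the class-conditional
#' configuration.
#'
#' @param config A [cohort_config()].
#' @param seed Integer random seed.
#' @return A list of class `foxa1_cohort` with elements `samples`,
#'   `variants`, `copy_number`, `claims`, `expression` (TPM matrix,
#'   samples x genes), `ground_truth`, `cutoff_date`, `config`, `seed`.
#' @examples
#' cohort <- generate_cohort(cohort_config(n_patients = 200), seed = 1)
#' table(cohort$ground_truth$true_class)
#' @export
generate_cohort <- function(config = cohort_config(), seed = 1L) {
  validate_cohort_config(config)
  set.seed(as.integer(seed))
  n <- config$n_patients
  d <- config$domains
  origin <- as.Date(config$origin_date)
  cutoff_day <- config$accrual_days + config$followup_days
  ids <- sprintf("PT%05d", seq_len(n))

  race <- sample(names(config$race_mix), n, replace = TRUE,
                 prob = config$race_mix)
  cls <- character(n)
  for (r in unique(race)) {
    sel <- race == r
    prev <- race_prevalence(config, r)
    cls[sel] <- sample(c(names(prev), "WT"), sum(sel), replace = TRUE,
                       prob = c(prev, 1 - sum(prev)))
  }
  site <- sample(names(config$site_mix), n, replace = TRUE,
                 prob = config$site_mix)
  histology <- ifelse(runif(n) < config$nepc_prob[cls],
                      "NEPC_small_cell", "adenocarcinoma")

  # ---- variants & copy number -------------------------------------------
  mut_classes <- c("C1A", "C1B", "C1C", "C2", "C3A", "C3B")
  mut_idx <- which(cls %in% mut_classes)
  var_rows <- lapply(mut_idx, function(i) {
    f <- synth_variant_fields(cls[i], d)
    vaf_shape <- if (site[i] == "metastatic") c(2.8, 4) else c(2, 6)
    data.frame(sample_id = ids[i], gene = "FOXA1",
               hgvs_p = format_hgvs_p(as.data.frame(f, stringsAsFactors = FALSE)),
               effect = f$effect,
               pathogenicity = sample(c("pathogenic", "likely_pathogenic"),
                                      1L, prob = c(0.7, 0.3)),
               vaf = round(rbeta(1, vaf_shape[1], vaf_shape[2]), 4),
               stringsAsFactors = FALSE)
  })
  # non-qualifying passengers exercise the pathogenicity filter
  n_vus <- rbinom(1, n, config$vus_rate)
  if (n_vus > 0) {
    vus_idx <- sample.int(n, n_vus)
    vus_rows <- lapply(vus_idx, function(i) {
      s <- sample.int(d$protein_length, 1L)
      ref <- sample(AA20, 1L); alt <- sample(setdiff(AA20, ref), 1L)
      data.frame(sample_id = ids[i], gene = "FOXA1",
                 hgvs_p = sprintf("p.%s%d%s", ref, s, alt),
                 effect = "missense",
                 pathogenicity = sample(c("VUS", "likely_benign", "benign"),
                                        1L, prob = c(0.8, 0.1, 0.1)),
                 vaf = round(rbeta(1, 2, 6), 4),
                 stringsAsFactors = FALSE)
    })
    var_rows <- c(var_rows, vus_rows)
  }
  variants <- if (length(var_rows)) do.call(rbind, var_rows) else
    data.frame(sample_id = character(), gene = character(),
               hgvs_p = character(), effect = character(),
               pathogenicity = character(), vaf = numeric(),
               stringsAsFactors = FALSE)

  copies <- ifelse(cls == "C4",
                   d$amplification_min_copies + rpois(n, 2),
                   sample(2:5, n, replace = TRUE,
                          prob = c(0.85, 0.09, 0.04, 0.02)))
  copy_number <- data.frame(sample_id = ids, gene = "FOXA1",
                            copies = copies, stringsAsFactors = FALSE)

  # ---- molecular features ------------------------------------------------
  tmb_high <- runif(n) < config$tmb_high_prob[cls]
  tmb <- ifelse(tmb_high,
                round(10 + rexp(n, 1 / 10), 1),
                round(pmin(exp(rnorm(n, log(3), 0.5)), 9.9), 1))
  samples <- data.frame(
    sample_id = ids, patient_id = ids, race = race, biopsy_site = site,
    histology = histology, tmb = tmb,
    msi_high = runif(n) < config$msi_prob[cls],
    tmprss2_erg = runif(n) < config$erg_prob[cls],
    tp53_mut = runif(n) < config$tp53_prob[cls],
    stringsAsFactors = FALSE
  )

  # ---- expression --------------------------------------------------------
  sig_genes <- unique(unlist(config$gene_sets))
  genes <- c("FOXA1", "AR", sig_genes)
  mu <- matrix(5, n, length(genes), dimnames = list(ids, genes))
  mu[, "FOXA1"] <- 6 + config$foxa1_shift[cls]
  mu[, "AR"] <- 6 + config$ar_shift[cls]
  for (sig in names(config$sig_shift)) {
    g <- intersect(config$gene_sets[[sig]], genes)
    mu[, g] <- mu[, g] + config$sig_shift[[sig]][cls]
  }
  log_tpm <- mu + matrix(rnorm(n * length(genes), sd = config$expr_sd),
                         n, length(genes))
  expression <- pmax(2^log_tpm - 1, 0)

  # ---- survival & treatments --------------------------------------------
  log_hr <- log(config$hazard_ratio[cls])
  has_adt <- runif(n) < config$treat_prob["first_line_ADT"]
  has_arsi <- runif(n) < config$treat_prob["second_gen_ARSI"]
  has_tax <- runif(n) < config$treat_prob["taxane"]
  t_adt <- ifelse(has_adt, floor(runif(n, 0, config$accrual_days)), NA)
  hs <- runif(n) < 0.4  # ARSI within the hormone-sensitive window
  t_arsi <- ifelse(has_arsi,
                   ifelse(has_adt,
                          t_adt + ifelse(hs, floor(runif(n, 0, 91)),
                                         floor(runif(n, 91, 720))),
                          floor(runif(n, 0, 180))),
                   NA)
  t_tax <- ifelse(has_tax, floor(runif(n, 180, 1000)), NA)
  first_trt <- pmin(t_adt, t_arsi, t_tax, na.rm = TRUE)
  first_trt[is.infinite(first_trt)] <- NA

  scale_wt <- config$wt_median_os_days / log(2)^(1 / config$weibull_shape)
  os <- rweibull_ph(n, config$weibull_shape, scale_wt, log_hr)
  death_day <- ifelse(is.na(first_trt), ceiling(os), first_trt + ceiling(os))
  ltfu_day <- floor(rexp(n, config$ltfu_rate))
  follow_end <- pmin(death_day, ltfu_day, cutoff_day)

  trt_rows <- function(t, category, drugs) {
    keep <- which(!is.na(t) & t <= follow_end & t <= cutoff_day)
    if (!length(keep)) return(NULL)
    data.frame(patient_id = ids[keep], day = t[keep],
               kind = "treatment_start",
               drug = sample(drugs, length(keep), replace = TRUE),
               drug_category = category, stringsAsFactors = FALSE)
  }
  treatments <- rbind(
    trt_rows(t_adt, "first_line_ADT",
             c("goserelin", "leuprolide", "triptorelin", "degarelix", "relugolix")),
    trt_rows(t_arsi, "second_gen_ARSI",
             c("apalutamide", "abiraterone", "darolutamide", "enzalutamide")),
    trt_rows(t_tax, "taxane", c("docetaxel", "cabazitaxel"))
  )

  # ---- claims stream -----------------------------------------------------
  K <- ceiling(cutoff_day / config$claim_gap_mean * 2) + 30L
  gaps <- matrix(claim_gaps(n * K, config$claim_gap_mean,
                            config$claim_gap_max), n, K)
  times <- t(apply(gaps, 1, cumsum))
  while (any(times[, K] < follow_end)) {
    extra <- matrix(claim_gaps(n * 10L, config$claim_gap_mean,
                               config$claim_gap_max), n, 10L)
    times <- cbind(times, times[, K] + t(apply(extra, 1, cumsum)))
    K <- K + 10L
  }
  keep <- times <= follow_end[row(times)]
  claim_df <- data.frame(
    patient_id = ids[row(times)[keep]],
    day = as.numeric(times[keep]),
    kind = "claim", drug = NA_character_, drug_category = NA_character_,
    stringsAsFactors = FALSE
  )
  baseline <- data.frame(patient_id = ids, day = 0, kind = "claim",
                         drug = NA_character_, drug_category = NA_character_,
                         stringsAsFactors = FALSE)
  claims <- rbind(baseline, claim_df, treatments)
  claims$date <- origin + claims$day
  claims <- claims[order(claims$patient_id, claims$day), ]
  claims$day <- NULL
  claims <- claims[, c("patient_id", "date", "kind", "drug", "drug_category")]
  rownames(claims) <- NULL

  ground_truth <- data.frame(
    patient_id = ids, true_class = cls, true_log_hr = unname(log_hr),
    true_death_day = death_day, ltfu_day = ltfu_day,
    first_treatment_day = first_trt,
    true_event = as.integer(death_day <= cutoff_day),
    stringsAsFactors = FALSE
  )

  structure(list(
    samples = samples, variants = variants, copy_number = copy_number,
    claims = claims, expression = expression, ground_truth = ground_truth,
    cutoff_date = origin + cutoff_day, config = config, seed = as.integer(seed)
  ), class = "foxa1_cohort")
}

#' Generate a null cohort (no class effects)
#'
#' Identical to [generate_cohort()] except that every class hazard ratio
#' is 1, all class-conditional feature probabilities collapse to the WT
#' values, and expression shifts are zero; classes are still assigned and
#' variants still synthesized, so the full pipeline runs but every test of
#' class effect is under the null. Used for type-I error calibration.
#'
#' @inheritParams generate_cohort
#' @return A `foxa1_cohort`, as for [generate_cohort()].
#' @export
generate_null_cohort <- function(config = cohort_config(), seed = 1L) {
  config$hazard_ratio[] <- 1
  config$erg_prob[] <- config$erg_prob["WT"]
  config$tp53_prob[] <- config$tp53_prob["WT"]
  config$msi_prob[] <- config$msi_prob["WT"]
  config$tmb_high_prob[] <- config$tmb_high_prob["WT"]
  config$nepc_prob[] <- config$nepc_prob["WT"]
  config$foxa1_shift[] <- 0
  config$ar_shift[] <- 0
  for (sig in names(config$sig_shift)) config$sig_shift[[sig]][] <- 0
  generate_cohort(config, seed)
}

#' @export
print.foxa1_cohort <- function(x, ...) {
  cat(sprintf("Synthetic prostate cohort: %d patients (seed %d)\n",
              nrow(x$samples), x$seed))
  tab <- table(factor(x$ground_truth$true_class, levels = FOXA1_CLASSES))
  print(tab)
  cat(sprintf("claims: %d events through %s\n",
              nrow(x$claims), format(x$cutoff_date)))
  invisible(x)
}
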