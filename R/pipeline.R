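# End-to-end orchestration: simulate (or load) -> classify -> analyze,
# writing tabular reports plus a run manifest so identical inputs and
# seeds reproduce identical analysis tables.

json_md5 <- function(x) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(x, tmp, auto_unbox = TRUE, digits = NA, force = TRUE)
  unname(tools::md5sum(tmp))
}

#' Run the full classification and analysis pipeline
#'
#' With `input_dir = NULL`, a synthetic cohort is generated from `config`
#' and `seed`; otherwise the cohort tables are read from `input_dir` (see
#' [read_cohort()] for the expected files). The pipeline then classifies
#' every sample, derives overall-survival records (overall and per
#' treatment category), fits class-versus-WT forest tables (overall, by
#' biopsy site, by treatment category) and a class-2-versus-other-classes
#' table, runs molecular enrichment and race-distribution tests,
#' summarizes FOXA1 expression and signature scores by class, and writes
#' everything as TSV files plus `manifest.json` under `out_dir`.
#'
#' @param out_dir Output directory (created if absent).
#' @param config A [cohort_config()]; also supplies thresholds
#'   (`gap_days`/`window_days` arguments override the 100-day and 90-day
#'   defaults).
#' @param seed Integer seed for the simulation branch.
#' @param input_dir Optional directory of input tables replacing the
#'   simulation.
#' @param include_vus Retain VUS variants during classification.
#' @param gap_days No-claim gap for death inference (default 100).
#' @param window_days Castration-state window (default 90).
#' @return Invisibly, a list of the analysis tables that were written.
#' @export
run_pipeline <- function(out_dir, config = cohort_config(), seed = 1L,
                         input_dir = NULL, include_vus = FALSE,
                         gap_days = 100, window_days = 90) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (is.null(input_dir)) {
    cohort <- generate_cohort(config, seed)
  } else {
    cohort <- read_cohort(input_dir)
    cohort$config <- config
  }
  domains <- config$domains %||% foxa1_domains()
  cutoff <- cohort$cutoff_date %||% (max(as.Date(cohort$claims$date)) + 1L)

  cls <- classify_cohort(cohort$variants, cohort$copy_number,
                         sample_ids = cohort$samples$sample_id,
                         domains = domains, include_vus = include_vus)
  samples <- merge(cohort$samples, cls$per_sample, by = "sample_id",
                   sort = TRUE)
  samples$tmb_high <- flag_tmb_high(samples$tmb)
  write_tsv(cls$per_sample, file.path(out_dir, "sample_classes.tsv"))
  if (nrow(cls$per_alteration)) {
    write_tsv(cls$per_alteration, file.path(out_dir, "alteration_classes.tsv"))
    write_tsv(residue_counts(cls$per_alteration),
              file.path(out_dir, "residue_counts.tsv"))
  }

  # ---- survival ----------------------------------------------------------
  recs <- build_survival_records(samples, cohort$claims, category = "any",
                                 cutoff_date = cutoff, gap_days = gap_days,
                                 window_days = window_days)
  with_label <- function(label, df) {
    cbind(subset_label = rep(label, nrow(df)), df)
  }
  forest <- with_label("all_tumors", forest_table(recs))
  for (s in unique(recs$biopsy_site)) {
    forest <- rbind(forest, with_label(paste0("site_", s),
                                       forest_table(recs[recs$biopsy_site == s, ])))
  }
  for (cat in c("first_line_ADT", "second_gen_ARSI", "taxane")) {
    rc <- build_survival_records(samples, cohort$claims, category = cat,
                                 cutoff_date = cutoff, gap_days = gap_days,
                                 window_days = window_days)
    if (nrow(rc)) {
      forest <- rbind(forest, with_label(paste0("treatment_", cat),
                                         forest_table(rc)))
    }
  }
  # class 2 versus each other alteration class
  c2_rows <- NULL
  other_classes <- intersect(setdiff(FOXA1_CLASSES, c("WT", "C2")),
                             unique(recs$class))
  if ("C2" %in% recs$class) {
    c2_rows <- do.call(rbind, lapply(other_classes, function(cl) {
      fit_class_vs_wt(recs, "C2", wt_label = cl)
    }))
  }
  write_tsv(forest, file.path(out_dir, "forest_os.tsv"))
  if (!is.null(c2_rows)) {
    write_tsv(c2_rows, file.path(out_dir, "forest_c2_vs_classes.tsv"))
  }
  km <- do.call(rbind, lapply(intersect(setdiff(FOXA1_CLASSES, "WT"),
                                        unique(recs$class)), function(cl) {
    cbind(comparison = paste0(cl, "_vs_WT"), km_coordinates(recs, cl))
  }))
  if (!is.null(km)) write_tsv(km, file.path(out_dir, "km_coordinates.tsv"))

  # ---- molecular associations -------------------------------------------
  feat_cols <- intersect(c("tmprss2_erg", "tp53_mut", "msi_high", "tmb_high"),
                         names(samples))
  assoc <- test_feature_enrichment(samples, feat_cols)
  write_tsv(assoc, file.path(out_dir, "class_associations.tsv"))
  race <- tryCatch(race_distribution(samples), error = function(e) NULL)
  if (!is.null(race)) {
    write_tsv(race$table, file.path(out_dir, "race_class_table.tsv"))
    if (!is.null(race$tests)) {
      write_tsv(race$tests, file.path(out_dir, "race_class_tests.tsv"))
    }
  }

  # ---- expression --------------------------------------------------------
  expr_summary <- sig_by_class <- NULL
  if (!is.null(cohort$expression) && "FOXA1" %in% colnames(cohort$expression)) {
    idx <- match(rownames(cohort$expression), samples$sample_id)
    expr_cls <- samples$class[idx]
    expr_summary <- compare_numeric_by_class(
      cohort$expression[, "FOXA1"], expr_cls)
    write_tsv(expr_summary, file.path(out_dir, "foxa1_expression_by_class.tsv"))
    gene_sets <- config$gene_sets %||% default_gene_sets()
    scores <- suppressWarnings(score_signature(cohort$expression, gene_sets))
    write_tsv(scores, file.path(out_dir, "signature_scores.tsv"))
    sig_by_class <- do.call(rbind, lapply(names(gene_sets), function(sig) {
      s <- scores[scores$signature == sig, ]
      cbind(signature = sig,
            compare_numeric_by_class(
              s$score, samples$class[match(s$sample_id, samples$sample_id)]))
    }))
    write_tsv(sig_by_class, file.path(out_dir, "signature_scores_by_class.tsv"))
  }

  manifest <- list(
    package_version = as.character(packageVersion("foxa1class")),
    seed = as.integer(seed),
    config_hash = json_md5(config[setdiff(names(config), "domains")]),
    cutoff_date = format(cutoff),
    n_samples = nrow(samples),
    input_checksums = if (!is.null(input_dir)) {
      fl <- list.files(input_dir, full.names = TRUE)
      setNames(as.list(unname(tools::md5sum(fl))), basename(fl))
    } else NULL,
    outputs = list.files(out_dir),
    timestamp = format(Sys.time(), tz = "UTC")
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  invisible(list(samples = samples, records = recs, forest = forest,
                 associations = assoc, race = race,
                 expression_summary = expr_summary,
                 signature_summary = sig_by_class))
}
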