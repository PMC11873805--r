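# YAML configuration: one structured file carries every tunable threshold
# (domain boundaries, amplification copies, TMB cutoff, claim-gap and
# castration windows) plus generator parameters, so a run is fully
# described by (config file, seed).

#' Read an analysis/generator configuration from YAML
#'
#' Recognized top-level keys: `domains` (fields of [foxa1_domains()]),
#' `thresholds` (`gap_days`, `castration_window_days`,
#' `tmb_high_threshold`), `generator` (fields of [cohort_config()];
#' simple named vectors such as `hazard_ratio` or `class_prev_base` may be
#' given as mappings) and `gene_sets` (signature name -> gene list).
#' Missing keys fall back to package defaults.
#'
#' @param path Path to a YAML file; `NULL` returns the defaults.
#' @return List with elements `config` (a [cohort_config()]),
#'   `gap_days`, `castration_window_days`, `tmb_high_threshold`.
#' @export
read_analysis_config <- function(path = NULL) {
  y <- if (is.null(path)) list() else yaml::read_yaml(path)
  dom_args <- y$domains %||% list()
  domains <- do.call(foxa1_domains, dom_args)
  gen <- y$generator %||% list()
  gen <- lapply(gen, function(v) if (is.list(v)) unlist(v) else v)
  merge_named <- function(field) {
    if (!is.null(gen[[field]])) {
      base <- cohort_config()[[field]]
      base[names(gen[[field]])] <- gen[[field]]
      gen[[field]] <<- base
    }
  }
  for (f in c("hazard_ratio", "class_prev_base", "erg_prob", "tp53_prob",
              "msi_prob", "tmb_high_prob", "nepc_prob",
              "foxa1_shift", "ar_shift")) merge_named(f)
  if (!is.null(y$gene_sets)) {
    gen$gene_sets <- lapply(y$gene_sets, unlist)
  }
  gen$domains <- domains
  config <- do.call(cohort_config, gen)
  th <- y$thresholds %||% list()
  list(
    config = config,
    gap_days = th$gap_days %||% 100,
    castration_window_days = th$castration_window_days %||% 90,
    tmb_high_threshold = th$tmb_high_threshold %||% 10
  )
}
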