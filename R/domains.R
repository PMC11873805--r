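#' FOXA1 domain model and classification boundaries
#'
#' Builds the residue-coordinate model that drives variant classification.
#' Defaults describe the canonical human FOXA1 protein (UniProt P55317-1,
#' 472 residues): the forkhead (FKH) DNA-binding domain spans residues
#' 168-269, its C-terminal Wing2 region residues 247-269, and the hotspot
#' residue R219 defines class 2 when mutated to cysteine or serine.
#' Amplification is called at >= 6 gene copies.
#'
#' All coordinates are 1-based inclusive residue indices (HGVS convention).
#' The boundaries are parameters rather than constants so the same rule
#' engine can be pointed at another transcript or another gene.
#'
#' @param fkh_start First residue of the FKH domain (default 168).
#' @param fkh_end Last residue of the FKH domain (default 269).
#' @param wing2_start First residue of the Wing2 region; missense/in-frame
#'   alterations anchored at `wing2_start..fkh_end` are class 1B, those at
#'   `fkh_start..wing2_start - 1` class 1A (default 247).
#' @param class2_residue Hotspot residue whose missense substitutions to
#'   `class2_alt_residues` define class 2 (default 219).
#' @param class2_alt_residues One-letter amino acids that trigger class 2 at
#'   the hotspot (default `c("C", "S")`).
#' @param protein_length Number of residues in the reference protein
#'   (default 472).
#' @param amplification_min_copies Minimum copy number for an amplification
#'   (class 4) call (default 6).
#'
#' @return An object of class `foxa1_domains` (a validated list).
#' @examples
#' d <- foxa1_domains()
#' d$fkh_start
#' @export
foxa1_domains <- function(fkh_start = 168L,
                          fkh_end = 269L,
                          wing2_start = 247L,
                          class2_residue = 219L,
                          class2_alt_residues = c("C", "S"),
                          protein_length = 472L,
                          amplification_min_copies = 6L) {
  d <- list(
    fkh_start = as.integer(fkh_start),
    fkh_end = as.integer(fkh_end),
    wing2_start = as.integer(wing2_start),
    class2_residue = as.integer(class2_residue),
    class2_alt_residues = toupper(as.character(class2_alt_residues)),
    protein_length = as.integer(protein_length),
    amplification_min_copies = as.integer(amplification_min_copies)
  )
  class(d) <- "foxa1_domains"
  validate_domains(d)
  d
}

validate_domains <- function(d) {
  stopifnot(inherits(d, "foxa1_domains"))
  with(d, {
    if (!(1L <= fkh_start && fkh_start < wing2_start &&
          wing2_start <= fkh_end && fkh_end <= protein_length)) {
      stop("invalid domain boundaries: require 1 <= fkh_start < wing2_start <= fkh_end <= protein_length")
    }
    if (class2_residue < fkh_start || class2_residue > fkh_end) {
      stop("class2_residue must lie within the FKH domain")
    }
    if (amplification_min_copies < 1L) {
      stop("amplification_min_copies must be >= 1")
    }
  })
  invisible(d)
}

#' @export
print.foxa1_domains <- function(x, ...) {
  cat("FOXA1 domain model\n")
  cat(sprintf("  protein length : %d aa\n", x$protein_length))
  cat(sprintf("  FKH domain     : %d-%d\n", x$fkh_start, x$fkh_end))
  cat(sprintf("  Wing2 region   : %d-%d\n", x$wing2_start, x$fkh_end))
  cat(sprintf("  class 2 hotspot: residue %d -> {%s}\n",
              x$class2_residue, paste(x$class2_alt_residues, collapse = ",")))
  cat(sprintf("  amplification  : >= %d copies\n", x$amplification_min_copies))
  invisible(x)
}
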