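#' Default vitamin D SNP panel
#'
#' The four-SNP panel used throughout the pipeline: two variants in genes
#' acting upstream of 25-hydroxyvitamin D production (*DHCR7* rs12785878 and
#' the functional *CYP2R1* variant rs12794714), which form the synthesis
#' allele score, and two variants in downstream transport/clearance genes
#' (*GC* rs2282679, *CYP24A1* rs6013897), which form the metabolism allele
#' score. Effect alleles are oriented to the 25(OH)D-increasing allele.
#'
#' The `eaf` and `beta_ln25ohd` columns are simulation defaults chosen so
#' that, under the default generator, the unweighted synthesis score shifts
#' ln 25(OH)D by about 2.8% per allele and the metabolism score by about
#' 5.4% per allele — the magnitudes typical of European-ancestry cohorts.
#' They parameterise the simulator; they are not estimates.
#'
#' @return A tibble with columns `snp_id`, `gene`, `effect_allele`,
#'   `other_allele`, `eaf`, `beta_ln25ohd` (additive per-allele effect on
#'   ln 25(OH)D), and `role` (`"synthesis"` or `"metabolism"`).
#' @examples
#' default_snp_panel()
#' @export
default_snp_panel <- function() {
  panel <- tibble::tribble(
    ~snp_id,      ~gene,     ~effect_allele, ~other_allele, ~eaf, ~beta_ln25ohd, ~role,
    "rs12785878", "DHCR7",   "T",            "G",           0.71, 0.023,         "synthesis",
    "rs12794714", "CYP2R1",  "A",            "G",           0.42, 0.032,         "synthesis",
    "rs2282679",  "GC",      "T",            "G",           0.72, 0.067,         "metabolism",
    "rs6013897",  "CYP24A1", "T",            "A",           0.79, 0.035,         "metabolism"
  )
  validate_snp_panel(panel)
}

#' Validate a SNP panel
#'
#' Checks the structural invariants a panel must satisfy before it can be
#' used for simulation, scoring or harmonisation: allele frequencies strictly
#' inside (0, 1), single-character distinct alleles, and — when both score
#' roles are present — exactly two SNPs per role.
#'
#' @param panel A data frame with at least `snp_id`, `effect_allele`,
#'   `other_allele`, `eaf`, `role` columns.
#' @return The panel as a tibble, invisibly checked.
#' @export
validate_snp_panel <- function(panel) {
  panel <- tibble::as_tibble(panel)
  req <- c("snp_id", "effect_allele", "other_allele", "eaf", "role")
  missing_cols <- setdiff(req, names(panel))
  if (length(missing_cols) > 0) {
    abort(paste0("SNP panel is missing columns: ", toString(missing_cols)))
  }
  if (anyDuplicated(panel$snp_id)) {
    abort("SNP panel contains duplicated snp_id values.")
  }
  if (!all(panel$eaf > 0 & panel$eaf < 1)) {
    abort("All effect-allele frequencies must lie strictly between 0 and 1.")
  }
  alleles <- c(panel$effect_allele, panel$other_allele)
  if (!all(alleles %in% c("A", "C", "G", "T"))) {
    abort("Alleles must be single characters in {A, C, G, T}.")
  }
  if (any(panel$effect_allele == panel$other_allele)) {
    abort("effect_allele and other_allele must differ for every SNP.")
  }
  if (!all(panel$role %in% c("synthesis", "metabolism"))) {
    abort("role must be 'synthesis' or 'metabolism'.")
  }
  counts <- table(panel$role)
  for (r in names(counts)) {
    if (counts[[r]] != 2L) {
      abort(paste0("Score '", r, "' must have exactly two component SNPs, got ",
                   counts[[r]], "."))
    }
  }
  panel
}

#' Component SNPs of one allele score
#'
#' @param panel A SNP panel (see [default_snp_panel()]).
#' @param score `"synthesis"` or `"metabolism"`.
#' @return The two panel rows for the requested score.
#' @export
score_snps <- function(panel, score = c("synthesis", "metabolism")) {
  score <- match.arg(score)
  rows <- dplyr::filter(validate_snp_panel(panel), .data$role == score)
  rows
}

allele_complement <- function(x) {
  unname(c(A = "T", T = "A", C = "G", G = "C")[x])
}

is_palindromic <- function(effect_allele, other_allele) {
  other_allele == allele_complement(effect_allele)
}
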