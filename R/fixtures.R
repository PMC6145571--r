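#' Bundled reference differential-expression call sets
#'
#' The package ships a reference set of significant age-group calls from
#' a cardiopulmonary developmental sequencing study of fetal and neonatal
#' sheep, for use in reporting examples and consistency checks:
#' the near-term versus neonate calls (per-tissue fold changes, average
#' log expression and FDR, already filtered at FDR < 0.15 and
#' AveLogExp > 1 and sorted by FDR within tissue) and the six preterm
#' versus near-term calls (tissue and direction only).
#'
#' @param which `"nt_vs_neo"` (full table) or `"nt_vs_pt"` (direction
#'   list).
#' @return data.frame; the full table has columns tissue, mirna_id,
#'   ave_log_exp, fc, fdr.
#' @export
reference_calls <- function(which = c("nt_vs_neo", "nt_vs_pt")) {
  which <- match.arg(which)
  f <- system.file("extdata", paste0("ngs_calls_", which, ".tsv"),
                   package = "ovimirnome", mustWork = TRUE)
  utils::read.delim(f, stringsAsFactors = FALSE, check.names = FALSE)
}
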