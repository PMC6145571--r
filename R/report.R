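#' Percent change implied by a fold change
#'
#' A fold change of 2.683 is a 168% increase; 0.476 is a 52% decrease.
#' Rounding is half away from zero.
#'
#' @param fc positive fold change(s).
#' @return signed integer percent (positive = increase, negative =
#'   decrease).
#' @export
percent_change <- function(fc) {
  if (any(fc <= 0)) err("fold changes must be positive")
  p <- ifelse(fc >= 1, (fc - 1) * 100, -(1 - fc) * 100)
  as.integer(sign(p) * floor(abs(p) + 0.5))
}

#' Cross-tabulate sequencing and qPCR calls
#'
#' Full outer join of the two result sets on (miRNA, tissue, contrast),
#' after optionally translating qPCR assay names to annotation ids via an
#' alias table.  A change is confirmed when it is significant by both
#' techniques (`ngs_fdr < fdr_max` and `qpcr_p_adj < p_max`) with fold
#' changes in the same direction.
#'
#' @param ngs_calls data.frame with `mirna_id`, `tissue`, `contrast`,
#'   `fc`, `fdr`.
#' @param qpcr_calls data.frame with `mirna_id`, `tissue`, `contrast`,
#'   `fc`, `p_adj`.
#' @param aliases optional data.frame with `assay_id`, `mirna_id`
#'   translating qPCR assay names.
#' @param fdr_max,p_max significance thresholds for the two techniques.
#' @return list with `entries` (one row per joined key: mirna_id, tissue,
#'   contrast, ngs_fc, ngs_fdr, qpcr_fc, qpcr_p_adj, confirmed) and
#'   `confirmed` (data.frame mirna_id, tissues: comma-separated tissues
#'   with a confirmed change).
#' @export
concordance <- function(ngs_calls, qpcr_calls, aliases = NULL,
                        fdr_max = 0.15, p_max = 0.05) {
  if (!is.null(aliases)) {
    m <- match(qpcr_calls$mirna_id, aliases$assay_id)
    qpcr_calls$mirna_id[!is.na(m)] <- aliases$mirna_id[m[!is.na(m)]]
  }
  keyize <- function(d) paste(d$mirna_id, d$tissue, d$contrast, sep = "|")
  kn <- keyize(ngs_calls); kq <- keyize(qpcr_calls)
  if (anyDuplicated(kn)) err("duplicate (miRNA, tissue, contrast) in NGS calls")
  if (anyDuplicated(kq)) err("duplicate (miRNA, tissue, contrast) in qPCR calls")
  keys <- union(kn, kq)
  i_n <- match(keys, kn); i_q <- match(keys, kq)
  parts <- do.call(rbind, strsplit(keys, "|", fixed = TRUE))
  entries <- data.frame(
    mirna_id = parts[, 1], tissue = parts[, 2], contrast = parts[, 3],
    ngs_fc = ngs_calls$fc[i_n], ngs_fdr = ngs_calls$fdr[i_n],
    qpcr_fc = qpcr_calls$fc[i_q], qpcr_p_adj = qpcr_calls$p_adj[i_q],
    stringsAsFactors = FALSE)
  entries$confirmed <- !is.na(entries$ngs_fdr) & !is.na(entries$qpcr_p_adj) &
    entries$ngs_fdr < fdr_max & entries$qpcr_p_adj < p_max &
    sign(log2(entries$ngs_fc)) == sign(log2(entries$qpcr_fc))
  conf <- entries[entries$confirmed, , drop = FALSE]
  confirmed <- if (nrow(conf) == 0) {
    data.frame(mirna_id = character(0), tissues = character(0),
               stringsAsFactors = FALSE)
  } else {
    agg <- tapply(conf$tissue, conf$mirna_id, function(x)
      paste(sort(unique(x)), collapse = ", "))
    data.frame(mirna_id = names(agg), tissues = unname(agg),
               stringsAsFactors = FALSE)
  }
  list(entries = entries, confirmed = confirmed)
}

#' Render significant calls as a results table
#'
#' Columns Tissue, miRNA ID, AvgLogExp (cpm), FC, FDR; rows grouped by
#' tissue with FDR ascending, numeric columns to three decimals.
#'
#' @param calls output of [call_significant()].
#' @param tissue_order optional tissue ordering for the grouping.
#' @return data.frame of formatted character columns.
#' @export
export_table2 <- function(calls, tissue_order = NULL) {
  if (nrow(calls) == 0) {
    return(data.frame(Tissue = character(0), `miRNA ID` = character(0),
                      `AvgLogExp (cpm)` = character(0), FC = character(0),
                      FDR = character(0), check.names = FALSE))
  }
  if (is.null(tissue_order)) tissue_order <- unique(calls$tissue)
  tiss <- factor(calls$tissue, levels = tissue_order)
  ord <- order(tiss, calls$fdr, calls$mirna_id)
  calls <- calls[ord, , drop = FALSE]
  fmt <- function(x) formatC(x, format = "f", digits = 3)
  data.frame(Tissue = calls$tissue,
             `miRNA ID` = calls$mirna_id,
             `AvgLogExp (cpm)` = fmt(calls$ave_log_exp),
             FC = fmt(calls$fc),
             FDR = fmt(calls$fdr),
             check.names = FALSE, stringsAsFactors = FALSE)
}
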