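#' Select reference miRNAs from sequencing data
#'
#' Ranks miRNAs by the sample standard deviation of their log2-cpm across
#' all samples and returns the `n_refs` most stable, breaking ties
#' lexicographically by id.  This mirrors the practice of normalizing
#' qPCR Ct values to the miRNAs with the lowest SD in a companion
#' sequencing experiment.
#'
#' @param logcpm numeric matrix (miRNA x sample) with rownames.
#' @param n_refs number of reference miRNAs to return.
#' @return character vector of ids, most stable first.
#' @export
select_reference_mirnas <- function(logcpm, n_refs = 2) {
  if (n_refs > nrow(logcpm)) err("n_refs exceeds the number of miRNAs")
  if (ncol(logcpm) < 2) err("need at least two samples")
  sds <- apply(logcpm, 1, stats::sd)
  ord <- order(sds, rownames(logcpm))
  rownames(logcpm)[ord[seq_len(n_refs)]]
}

## Collapse technical replicates: mean Ct over the ct1..ct3 columns,
## ignoring missing wells.
collapse_ct <- function(records) {
  ctcols <- grep("^ct[0-9]+$", names(records), value = TRUE)
  if (length(ctcols) == 0) err("no ct columns (ct1, ct2, ...) found")
  ct <- as.matrix(records[, ctcols, drop = FALSE])
  if (any(ct <= 0 | ct > 45, na.rm = TRUE)) {
    err("Ct values must lie in (0, 45]")
  }
  mean_ct <- rowMeans(ct, na.rm = TRUE)
  if (any(!is.finite(mean_ct))) err("record with no Ct measurement")
  data.frame(records[, c("sample_id", "tissue", "group", "mirna_id")],
             mean_ct = mean_ct, stringsAsFactors = FALSE)
}

#' Normalize Ct values to reference miRNAs
#'
#' Technical replicates are collapsed to their mean first; then, per
#' sample, `delta_ct = mean Ct(test) - average of the two reference mean
#' Cts`.
#'
#' @param records data.frame with columns `sample_id`, `tissue`, `group`,
#'   `mirna_id` and technical-replicate columns `ct1`, `ct2`, `ct3`
#'   (missing wells as `NA`).
#' @param ref_ids the two reference miRNA ids.
#' @return data.frame: sample_id, tissue, group, mirna_id, delta_ct
#'   (reference rows excluded).
#' @export
compute_delta_ct <- function(records, ref_ids) {
  stopifnot(length(ref_ids) == 2)
  cc <- collapse_ct(records)
  refs <- cc[cc$mirna_id %in% ref_ids, , drop = FALSE]
  ref_mean <- tapply(refs$mean_ct, refs$sample_id, function(x) mean(x))
  per_sample_n <- tapply(refs$mirna_id, refs$sample_id,
                         function(x) length(unique(x)))
  tests <- cc[!cc$mirna_id %in% ref_ids, , drop = FALSE]
  bad <- setdiff(unique(tests$sample_id),
                 names(per_sample_n)[per_sample_n == 2])
  if (length(bad) > 0) {
    err("sample(s) missing a reference miRNA: ",
        paste(bad, collapse = ", "))
  }
  tests$delta_ct <- tests$mean_ct - ref_mean[tests$sample_id]
  tests$mean_ct <- NULL
  rownames(tests) <- NULL
  tests
}

#' Fold change between two groups from delta-Ct values
#'
#' `delta_delta_ct = mean delta_ct(group_b) - mean delta_ct(group_a)`
#' over the per-animal delta-Ct values of one miRNA in one tissue, and
#' `fc = 2^(-delta_delta_ct)`.
#'
#' @param delta_cts output of [compute_delta_ct()].
#' @param tissue,mirna the tissue and miRNA to evaluate.
#' @param contrast character pair `c(group_b, group_a)` (later group
#'   first, e.g. `c("Neo", "NT")`).
#' @return one-row data.frame: tissue, mirna_id, contrast,
#'   delta_delta_ct, fc, direction (up/down/none).
#' @export
compute_fold_change <- function(delta_cts, tissue, mirna, contrast) {
  stopifnot(length(contrast) == 2)
  d <- delta_cts[delta_cts$tissue == tissue &
                   delta_cts$mirna_id == mirna, , drop = FALSE]
  b <- d$delta_ct[d$group == contrast[1]]
  a <- d$delta_ct[d$group == contrast[2]]
  if (length(b) == 0 || length(a) == 0) {
    err("empty group for ", mirna, " in ", tissue)
  }
  ddct <- mean(b) - mean(a)
  fc <- 2^(-ddct)
  data.frame(tissue = tissue, mirna_id = mirna,
             contrast = paste0(contrast[1], "_vs_", contrast[2]),
             delta_delta_ct = ddct, fc = fc,
             direction = if (ddct < 0) "up" else if (ddct > 0) "down"
             else "none",
             stringsAsFactors = FALSE)
}

#' Group statistics on delta-Ct values
#'
#' One-way ANOVA across all groups, followed by unpaired two-sided
#' Student's t-tests (pooled variance) for each group pair, with
#' Bonferroni adjustment `p_adj = min(1, p * m)` over the `m` pairwise
#' comparisons.
#'
#' @param delta_cts output of [compute_delta_ct()].
#' @param tissue,mirna the tissue and miRNA to test.
#' @param m Bonferroni family size (default: number of group pairs).
#' @return list with `anova_p` and `pairwise` (data.frame: group_b,
#'   group_a, p, p_adj).
#' @export
group_tests <- function(delta_cts, tissue, mirna, m = NULL) {
  d <- delta_cts[delta_cts$tissue == tissue &
                   delta_cts$mirna_id == mirna, , drop = FALSE]
  d$group <- factor(d$group)
  if (nlevels(d$group) < 2) err("need at least two groups")
  if (any(table(d$group) < 2)) err("need >= 2 samples per group")
  fit <- stats::aov(delta_ct ~ group, data = d)
  tab <- summary(fit)[[1]]
  fstat <- tab["group", "F value"]
  anova_p <- if (is.finite(fstat)) tab["group", "Pr(>F)"] else 1
  pairs <- utils::combn(levels(d$group), 2)
  if (is.null(m)) m <- ncol(pairs)
  pw <- apply(pairs, 2, function(pr) {
    x <- d$delta_ct[d$group == pr[2]]   # later level listed first below
    y <- d$delta_ct[d$group == pr[1]]
    if (stats::sd(c(x - mean(x), y - mean(y))) == 0) {
      ## degenerate: no within-group variance
      p <- if (isTRUE(all.equal(mean(x), mean(y)))) 1 else 0
      warning("zero within-group variance for ", mirna, " in ", tissue,
              call. = FALSE)
    } else {
      p <- stats::t.test(x, y, var.equal = TRUE)$p.value
    }
    p
  })
  data.frame(group_b = pairs[2, ], group_a = pairs[1, ],
             p = pw, p_adj = pmin(1, pw * m),
             stringsAsFactors = FALSE) -> pairwise
  list(anova_p = anova_p, pairwise = pairwise)
}

#' Full qPCR relative-quantification analysis
#'
#' For every (tissue, miRNA) with data, computes fold changes for the
#' requested contrasts and attaches the Bonferroni-adjusted pairwise
#' p-value of each contrast (and the one-way ANOVA p).
#'
#' @param records Ct table as in [compute_delta_ct()].
#' @param ref_ids the two reference miRNA ids.
#' @param contrasts list of `c(group_b, group_a)` pairs.
#' @param m Bonferroni family size (default: all group pairs).
#' @return data.frame: tissue, mirna_id, contrast, delta_delta_ct, fc,
#'   direction, p, p_adj, anova_p.
#' @export
run_qpcr <- function(records, ref_ids,
                     contrasts = list(c("NT", "PT"), c("Neo", "NT")),
                     m = NULL) {
  delta_cts <- compute_delta_ct(records, ref_ids)
  combos <- unique(delta_cts[, c("tissue", "mirna_id")])
  out <- list()
  for (i in seq_len(nrow(combos))) {
    ti <- combos$tissue[i]; mi <- combos$mirna_id[i]
    gt <- group_tests(delta_cts, ti, mi, m = m)
    for (ctr in contrasts) {
      fc <- compute_fold_change(delta_cts, ti, mi, ctr)
      hit <- gt$pairwise$group_b == ctr[1] & gt$pairwise$group_a == ctr[2]
      if (!any(hit)) {
        hit <- gt$pairwise$group_b == ctr[2] & gt$pairwise$group_a == ctr[1]
      }
      fc$p <- gt$pairwise$p[hit][1]
      fc$p_adj <- gt$pairwise$p_adj[hit][1]
      fc$anova_p <- gt$anova_p
      out[[length(out) + 1L]] <- fc
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
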