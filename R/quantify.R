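#' Construct a count matrix container
#'
#' @param counts non-negative integer matrix, miRNAs in rows (rownames =
#'   ids), samples in columns (colnames = sample ids).
#' @param samples sample sheet data.frame with columns `sample_id`,
#'   `tissue`, `group`, `replicate`, one row per column of `counts`.
#' @param lib_sizes per-sample library sizes; defaults to column sums.
#' @return object of class `count_matrix`.
#' @export
count_matrix <- function(counts, samples, lib_sizes = NULL) {
  stopifnot(is.matrix(counts), !is.null(rownames(counts)),
            !is.null(colnames(counts)))
  if (any(counts < 0)) err("counts must be non-negative")
  need <- c("sample_id", "tissue", "group", "replicate")
  if (!all(need %in% names(samples))) {
    err("sample sheet needs columns ", paste(need, collapse = ", "))
  }
  if (!identical(colnames(counts), samples$sample_id)) {
    m <- match(colnames(counts), samples$sample_id)
    if (anyNA(m)) err("sample sheet is missing samples present in counts")
    samples <- samples[m, , drop = FALSE]
  }
  if (anyDuplicated(samples[, c("tissue", "group", "replicate")])) {
    err("(tissue, group, replicate) must be unique")
  }
  cs <- colSums(counts)
  if (is.null(lib_sizes)) {
    lib_sizes <- cs
  } else {
    stopifnot(length(lib_sizes) == ncol(counts))
    if (any(lib_sizes < cs)) {
      err("supplied lib_sizes must be >= column sums of retained counts")
    }
  }
  if (any(lib_sizes <= 0)) err("library sizes must be positive")
  structure(list(counts = counts, samples = samples,
                 lib_sizes = stats::setNames(as.numeric(lib_sizes),
                                             colnames(counts))),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat("count_matrix:", nrow(x$counts), "miRNAs x", ncol(x$counts),
      "samples; median library size",
      format(stats::median(x$lib_sizes), big.mark = ","), "\n")
  invisible(x)
}

#' Count retained alignments over a miRNome
#'
#' A read increments a locus iff its interval overlaps the locus by at
#' least one base.  Counting is strand-blind by default (a read is
#' assigned regardless of strand); reads overlapping two or more loci are
#' ambiguous and left unassigned, as are reads flagged non-unique unless
#' `count_multi = TRUE`.
#'
#' @param alignments_by_sample named list (by sample id) of alignment
#'   data.frames from [align_batch()].
#' @param mirnome a `mirnome`.
#' @param samples sample sheet covering every sample in
#'   `alignments_by_sample`.
#' @param strand_aware require read and locus strand to agree.
#' @param count_multi count reads flagged non-unique (default: drop).
#' @return a [count_matrix()] with an `assignment_summary` attribute
#'   (per-sample data.frame: mapped, assigned, ambiguous, no_feature,
#'   multimapped_dropped).
#' @export
assign_counts <- function(alignments_by_sample, mirnome, samples,
                          strand_aware = FALSE, count_multi = FALSE) {
  missing <- setdiff(names(alignments_by_sample), samples$sample_id)
  if (length(missing) > 0) {
    err("sample(s) absent from sample sheet: ",
        paste(missing, collapse = ", "))
  }
  loci <- mirnome$loci
  gr_loci <- GenomicRanges::GRanges(
    seqnames = loci$chrom,
    ranges = IRanges::IRanges(start = loci$start + 1L, end = loci$end),
    strand = loci$strand)
  ids <- names(alignments_by_sample)
  counts <- matrix(0L, nrow(loci), length(ids),
                   dimnames = list(loci$locus_id, ids))
  summ <- data.frame(sample_id = ids, mapped = 0L, assigned = 0L,
                     ambiguous = 0L, no_feature = 0L,
                     multimapped_dropped = 0L, stringsAsFactors = FALSE)
  for (j in seq_along(ids)) {
    aln <- alignments_by_sample[[j]]
    summ$mapped[j] <- nrow(aln)
    if (nrow(aln) == 0) next
    if (!count_multi) {
      drop <- !aln$is_unique_best
      summ$multimapped_dropped[j] <- sum(drop)
      aln <- aln[!drop, , drop = FALSE]
    }
    if (nrow(aln) == 0) next
    gr_reads <- GenomicRanges::GRanges(
      seqnames = aln$chrom,
      ranges = IRanges::IRanges(start = aln$start + 1L, end = aln$end),
      strand = aln$strand)
    ov <- GenomicRanges::findOverlaps(gr_reads, gr_loci, minoverlap = 1L,
                                      ignore.strand = !strand_aware)
    nhits <- tabulate(S4Vectors::queryHits(ov), nbins = nrow(aln))
    uniq <- nhits == 1L
    summ$ambiguous[j] <- sum(nhits >= 2L)
    summ$no_feature[j] <- sum(nhits == 0L)
    keep <- S4Vectors::queryHits(ov) %in% which(uniq)
    hits <- S4Vectors::subjectHits(ov)[keep]
    counts[, j] <- counts[, j] + tabulate(hits, nbins = nrow(loci))
    summ$assigned[j] <- sum(uniq)
  }
  cm <- count_matrix(counts, samples[match(ids, samples$sample_id), ,
                                     drop = FALSE])
  attr(cm, "assignment_summary") <- summ
  cm
}

#' Counts per million
#'
#' `cpm[i, s] = counts[i, s] / lib_sizes[s] * 1e6`.
#'
#' @param cm a [count_matrix()].
#' @return numeric matrix of the same shape.
#' @export
compute_cpm <- function(cm) {
  if (any(cm$lib_sizes <= 0)) err("zero library size")
  sweep(cm$counts, 2, cm$lib_sizes, "/") * 1e6
}

#' Filter lowly expressed miRNAs
#'
#' Keeps miRNAs with cpm >= `min_cpm` in at least `min_samples` samples
#' (counted across all samples, any tissue or group).  Library sizes are
#' retained unchanged so the cpm scale is unaffected by filtering.
#'
#' @param cm a [count_matrix()].
#' @param min_cpm cpm threshold (inclusive).
#' @param min_samples number of qualifying samples required (inclusive).
#' @return the filtered [count_matrix()], row order preserved.
#' @export
filter_expressed <- function(cm, min_cpm = 1, min_samples = 3) {
  stopifnot(min_cpm > 0, min_samples > 0)
  cpm <- compute_cpm(cm)
  keep <- rowSums(cpm >= min_cpm) >= min_samples
  count_matrix(cm$counts[keep, , drop = FALSE], cm$samples,
               lib_sizes = cm$lib_sizes)
}
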