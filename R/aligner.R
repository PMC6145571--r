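#' Build a k-mer index of a genome
#'
#' Indexes every forward-strand k-mer and, under the same coordinates,
#' the reverse complement of every window (strand `-`), so that a seed
#' lookup finds placements on either strand.  The default seed length of
#' 5 guarantees, by the pigeonhole principle, that every placement of a
#' query of length >= 15 with at most two mismatches contains an exact
#' seed (a query of length L is covered when `L >= (max_mm + 1) * k`).
#'
#' @param genome named character vector of chromosome sequences
#'   (uppercase A/C/G/T/N).
#' @param k seed length (>= 4).
#' @return object of class `kmer_index`.
#' @export
build_index <- function(genome, k = 5) {
  if (k < 4) err("seed length k must be >= 4")
  if (is.null(names(genome)) || anyDuplicated(names(genome)) ||
        any(names(genome) == "")) {
    err("chromosome names must be unique and non-empty")
  }
  env <- new.env(parent = emptyenv(), size = 4L^min(k, 10))
  keys <- character(0); chroms <- character(0)
  offs <- integer(0); strands <- character(0)
  for (ch in names(genome)) {
    s <- genome[[ch]]
    n <- nchar(s)
    if (n < k) next
    o <- 0:(n - k)                     # 0-based window offsets
    fwd <- substring(s, o + 1L, o + k)
    rev <- revcomp(fwd)
    keys <- c(keys, fwd, rev)
    chroms <- c(chroms, rep(ch, 2L * length(o)))
    offs <- c(offs, o, o)
    strands <- c(strands, rep("+", length(o)), rep("-", length(o)))
  }
  groups <- split(seq_along(keys), keys)
  for (km in names(groups)) {
    i <- groups[[km]]
    assign(km, list(chrom = chroms[i], offset = offs[i],
                    strand = strands[i]), envir = env)
  }
  structure(list(k = as.integer(k), positions = env),
            class = "kmer_index")
}

## Precomputed per-chromosome raw byte vectors (hot path).
genome_raw <- function(genome) lapply(unclass(genome), charToRaw)

## Core single-query alignment against a prepared (index, raw genome).
## Returns all minimal-mismatch ungapped placements with <= max_mm
## mismatches, sorted by (chrom, start, strand).
align_core <- function(index, graw, query, max_mm) {
  k <- index$k
  L <- nchar(query)
  if (L < (max_mm + 1L) * k) {
    err("query of length ", L, " too short for ", max_mm,
        " mismatches with seed length ", k,
        " (need length >= ", (max_mm + 1L) * k, ")")
  }
  seg_len <- L %/% (max_mm + 1L)
  seed_starts <- 1L + (0:max_mm) * seg_len     # first k bases of each segment
  qraw <- charToRaw(query)
  rcraw <- charToRaw(revcomp(query))
  nraw <- charToRaw("N")
  cand_chrom <- character(0); cand_start <- integer(0)
  cand_strand <- character(0)
  for (s in seed_starts) {
    seed <- substr(query, s, s + k - 1L)
    hits <- get0(seed, envir = index$positions)
    if (is.null(hits)) next
    ## '+': query position s sits at genome offset o  =>  start = o - (s-1)
    ## '-': seed matches the '-' strand window at o; within revcomp(query)
    ##      the seed occupies positions (L-s-k+2)..(L-s+1), so the forward
    ##      footprint starts at o - (L - s - k + 1).
    st <- ifelse(hits$strand == "+",
                 hits$offset - (s - 1L),
                 hits$offset - (L - s - k + 1L))
    cand_chrom <- c(cand_chrom, hits$chrom)
    cand_start <- c(cand_start, st)
    cand_strand <- c(cand_strand, hits$strand)
  }
  if (length(cand_start) == 0) return(empty_alignments())
  key <- paste(cand_chrom, cand_start, cand_strand)
  keep <- !duplicated(key)
  cand_chrom <- cand_chrom[keep]
  cand_start <- cand_start[keep]
  cand_strand <- cand_strand[keep]
  mm <- rep(NA_integer_, length(cand_start))
  for (i in seq_along(cand_start)) {
    g <- graw[[cand_chrom[i]]]
    a <- cand_start[i]
    if (a < 0L || a + L > length(g)) next
    win <- g[(a + 1L):(a + L)]
    q <- if (cand_strand[i] == "+") qraw else rcraw
    mm[i] <- sum(win != q | win == nraw | q == nraw)
  }
  ok <- !is.na(mm) & mm <= max_mm
  if (!any(ok)) return(empty_alignments())
  best <- min(mm[ok])
  sel <- which(ok & mm == best)
  out <- data.frame(chrom = cand_chrom[sel],
                    start = cand_start[sel],
                    end = cand_start[sel] + L,
                    strand = cand_strand[sel],
                    mismatches = mm[sel],
                    stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out$is_unique_best <- nrow(out) == 1L
  out
}

empty_alignments <- function() {
  data.frame(chrom = character(0), start = integer(0), end = integer(0),
             strand = character(0), mismatches = integer(0),
             is_unique_best = logical(0), stringsAsFactors = FALSE)
}

#' Align one sequence to the genome
#'
#' Seed-and-extend ungapped alignment: seeds are taken from `max_mm + 1`
#' disjoint query segments (so every placement within the mismatch budget
#' contains an exact seed), candidate placements are verified by Hamming
#' comparison on both strands, and only placements tying the minimum
#' mismatch count are returned.  N positions (in query or genome) always
#' count as mismatches.  Coordinates are 0-based, half-open.
#'
#' @param index a [build_index()] result.
#' @param genome the genome the index was built from.
#' @param query A/C/G/T/N query sequence of length >= `(max_mm + 1) * k`.
#' @param max_mm mismatch budget (0, 1 or 2).
#' @return data.frame with columns chrom, start, end, strand, mismatches,
#'   is_unique_best; zero rows if unmapped.
#' @export
align_sequence <- function(index, genome, query, max_mm = 2) {
  if (!max_mm %in% 0:2) err("max_mm must be 0, 1 or 2")
  align_core(index, genome_raw(genome), query, max_mm)
}

#' Align a batch of reads, retaining one best hit per read
#'
#' Each read is aligned with [align_sequence()] semantics; among
#' equal-best placements the lexicographically smallest
#' (chrom, start, strand) is retained and the record is flagged
#' non-unique.  Under `policy = "unique"` multi-mapped reads are moved to
#' the unmapped list instead.  Alignment is computed once per distinct
#' read sequence.
#'
#' @param index a [build_index()] result.
#' @param genome the genome the index was built from.
#' @param reads data.frame with `read_id` and `sequence` (trimmed,
#'   size-selected).
#' @param max_mm mismatch budget.
#' @param policy `"best"` (retain multi-mapped reads at the tie-broken
#'   placement) or `"unique"` (discard them).
#' @return list with `alignments` (read_id, chrom, start, end, strand,
#'   mismatches, is_unique_best) and `unmapped` (read ids).
#' @export
align_batch <- function(index, genome, reads, max_mm = 2,
                        policy = c("best", "unique")) {
  policy <- match.arg(policy)
  graw <- genome_raw(genome)
  k <- index$k
  uniq <- unique(reads$sequence)
  hit <- lapply(uniq, function(q) {
    if (nchar(q) < (max_mm + 1L) * k) return(NULL)   # unalignable length
    h <- align_core(index, graw, q, max_mm)
    if (nrow(h) == 0) NULL else h[1L, , drop = FALSE]  # lexicographic best
  })
  idx <- match(reads$sequence, uniq)
  mapped <- !vapply(hit, is.null, logical(1))[idx]
  if (policy == "unique") {
    uniq_ok <- vapply(hit, function(h) !is.null(h) && h$is_unique_best,
                      logical(1))[idx]
    mapped <- mapped & uniq_ok
  }
  aln <- if (any(mapped)) {
    rows <- do.call(rbind, hit[idx[mapped]])
    cbind(data.frame(read_id = reads$read_id[mapped],
                     stringsAsFactors = FALSE), rows)
  } else {
    cbind(data.frame(read_id = character(0), stringsAsFactors = FALSE),
          empty_alignments())
  }
  rownames(aln) <- NULL
  list(alignments = aln, unmapped = reads$read_id[!mapped])
}

#' Write alignments as SAM
#'
#' Minimal single-end SAM writer: `@SQ` header lines from the genome,
#' ungapped CIGAR, `NM` tag carrying the mismatch count, flag 16 for
#' minus-strand placements.  Sequence/quality columns are emitted as
#' `*` unless supplied.
#'
#' @param alignments alignment data.frame from [align_batch()].
#' @param genome the reference genome.
#' @param path output file.
#' @export
write_sam <- function(alignments, genome, path) {
  hdr <- c("@HD\tVN:1.6\tSO:unknown",
           sprintf("@SQ\tSN:%s\tLN:%d", names(genome),
                   nchar(unclass(genome))))
  body <- sprintf("%s\t%d\t%s\t%d\t255\t%dM\t*\t0\t0\t*\t*\tNM:i:%d",
                  alignments$read_id,
                  ifelse(alignments$strand == "-", 16L, 0L),
                  alignments$chrom,
                  alignments$start + 1L,
                  alignments$end - alignments$start,
                  alignments$mismatches)
  writeLines(c(hdr, body), path)
}
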