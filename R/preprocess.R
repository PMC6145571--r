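#' Adapter trimming configuration
#'
#' @param adapter_5p,adapter_3p adapter sequences (uppercase A/C/G/T;
#'   empty string disables that adapter).
#' @param min_len,max_len inclusive size-selection bounds (nt) applied by
#'   [size_select()].
#' @param min_overlap minimum adapter/read overlap for a match.
#' @param max_error_rate allowed mismatches per matched base: a match of
#'   length L tolerates `floor(max_error_rate * L)` mismatches.
#' @return object of class `adapter_config`.
#' @export
adapter_config <- function(adapter_5p = "", adapter_3p = "",
                           min_len = 15, max_len = 32,
                           min_overlap = 5, max_error_rate = 0.1) {
  if (!grepl("^[ACGT]*$", adapter_5p) || !grepl("^[ACGT]*$", adapter_3p)) {
    err("adapters must be uppercase A/C/G/T")
  }
  stopifnot(min_len > 0, min_len <= max_len, min_overlap >= 1)
  check_prob(max_error_rate, "max_error_rate")
  structure(list(adapter_5p = adapter_5p, adapter_3p = adapter_3p,
                 min_len = as.integer(min_len), max_len = as.integer(max_len),
                 min_overlap = as.integer(min_overlap),
                 max_error_rate = max_error_rate),
            class = "adapter_config")
}

## Best 3'-adapter match: the adapter's prefix aligned at read position p
## through the read end (overlap capped at the adapter length).  Returns
## the smallest p (longest match) whose mismatches fit the error budget,
## or 0L for no match.  N positions count as mismatches.
match_adapter_3p <- function(rseq, radap, min_overlap, max_error_rate) {
  L <- length(rseq); la <- length(radap)
  if (la == 0 || L < min_overlap) return(0L)
  nraw <- charToRaw("N")
  for (p in seq_len(L - min_overlap + 1L)) {
    ov <- min(la, L - p + 1L)
    if (ov < min_overlap) break
    a <- rseq[p:(p + ov - 1L)]
    b <- radap[seq_len(ov)]
    if (sum(a != b | a == nraw | b == nraw) <=
          floor(max_error_rate * ov)) {
      return(p)
    }
  }
  0L
}

## Best 5'-adapter match: the adapter's suffix aligned over the read
## prefix of length e (adapter may hang off the 5' end).  Returns the
## largest within-budget e, or 0L.
match_adapter_5p <- function(rseq, radap, min_overlap, max_error_rate) {
  L <- length(rseq); la <- length(radap)
  if (la == 0) return(0L)
  nraw <- charToRaw("N")
  for (e in rev(seq_len(min(la, L)))) {
    if (e < min_overlap) break
    a <- rseq[seq_len(e)]
    b <- radap[(la - e + 1L):la]
    if (sum(a != b | a == nraw | b == nraw) <=
          floor(max_error_rate * e)) {
      return(e)
    }
  }
  0L
}

## Start/end of the retained insert after the full trimming cascade:
## (1) strip the leading N run; (2) 5' adapter; (3) 3' adapter;
## (4) repeat (2)-(3) with the reverse-complemented adapters.
## Returns c(a, b), 1-based inclusive bounds into the original sequence
## (b < a means the read was trimmed away entirely).
trim_bounds <- function(seq, cfg) {
  a <- 1L
  b <- nchar(seq)
  nrun <- attr(regexpr("^N*", seq), "match.length")
  a <- a + nrun
  adapters_5p <- c(cfg$adapter_5p, revcomp_or_empty(cfg$adapter_5p))
  adapters_3p <- c(cfg$adapter_3p, revcomp_or_empty(cfg$adapter_3p))
  for (round in 1:2) {
    cur <- if (b >= a) substr(seq, a, b) else ""
    rcur <- charToRaw(cur)
    a5 <- adapters_5p[round]
    if (nchar(a5) > 0 && nchar(cur) > 0) {
      e <- match_adapter_5p(rcur, charToRaw(a5), cfg$min_overlap,
                            cfg$max_error_rate)
      if (e > 0) {
        a <- a + e
        cur <- if (b >= a) substr(seq, a, b) else ""
        rcur <- charToRaw(cur)
      }
    }
    a3 <- adapters_3p[round]
    if (nchar(a3) > 0 && nchar(cur) > 0) {
      p <- match_adapter_3p(rcur, charToRaw(a3), cfg$min_overlap,
                            cfg$max_error_rate)
      if (p > 0) b <- a + p - 2L
    }
  }
  c(a, b)
}

revcomp_or_empty <- function(x) if (nchar(x) == 0) "" else revcomp(x)

#' Trim one small-RNA read
#'
#' Applies, in order: stripping of the leading N run, removal of the 5'
#' adapter (matched against the read prefix), removal of the 3' adapter
#' (matched from the read suffix inward), and a second pass of both steps
#' with the reverse-complemented adapters.  Adapter matches must span at
#' least `min_overlap` bases and tolerate `floor(max_error_rate * span)`
#' mismatches; the longest within-budget match is removed.  The quality
#' string is trimmed in lockstep.
#'
#' @param read list or one-row data.frame with `read_id`, `sequence`,
#'   `quality`.
#' @param cfg an [adapter_config()].
#' @return the read with trimmed `sequence` and `quality` (possibly empty;
#'   empty reads are later dropped by [size_select()]).
#' @export
trim_read <- function(read, cfg) {
  if (is.null(read$sequence) || nchar(read$sequence) == 0) {
    err("empty read")
  }
  if (nchar(read$sequence) != nchar(read$quality)) {
    err("sequence/quality length mismatch for read ", read$read_id)
  }
  ab <- trim_bounds(read$sequence, cfg)
  read$sequence <- if (ab[2] >= ab[1]) substr(read$sequence, ab[1], ab[2]) else ""
  read$quality <- if (ab[2] >= ab[1]) substr(read$quality, ab[1], ab[2]) else ""
  read
}

#' Trim a batch of reads
#'
#' Vectorised [trim_read()]; trimming is computed once per distinct
#' sequence.
#'
#' @param reads data.frame with columns `read_id`, `sequence`, `quality`.
#' @param cfg an [adapter_config()].
#' @return data.frame of the same shape with trimmed reads (zero-length
#'   reads retained; use [size_select()] to drop them).
#' @export
trim_reads <- function(reads, cfg) {
  stopifnot(all(c("read_id", "sequence", "quality") %in% names(reads)))
  if (nrow(reads) == 0) return(reads)
  if (any(nchar(reads$sequence) == 0)) err("empty read")
  if (any(nchar(reads$sequence) != nchar(reads$quality))) {
    err("sequence/quality length mismatch")
  }
  uniq <- unique(reads$sequence)
  bounds <- vapply(uniq, trim_bounds, numeric(2), cfg = cfg)
  idx <- match(reads$sequence, uniq)
  a <- bounds[1, idx]; b <- bounds[2, idx]
  keep <- b >= a
  out <- reads
  out$sequence <- ifelse(keep, substring(reads$sequence, a, b), "")
  out$quality <- ifelse(keep, substring(reads$quality, a, b), "")
  out
}

#' Size-select trimmed reads
#'
#' Retains exactly the reads whose length lies inside the inclusive
#' `[min_len, max_len]` window of the configuration (15-32 nt by default,
#' the common mature-miRNA size range).
#'
#' @param reads data.frame of trimmed reads.
#' @param cfg an [adapter_config()].
#' @return the retained subset, original order preserved.
#' @export
size_select <- function(reads, cfg) {
  n <- nchar(reads$sequence)
  reads[n >= cfg$min_len & n <= cfg$max_len, , drop = FALSE]
}
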