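## Independent oracles used to validate the package's implementations.
## These deliberately use naive exhaustive algorithms.

## Exhaustive ungapped scan: Hamming distance of the query (both strands)
## at every placement on every chromosome; returns the minimal-mismatch
## placements with <= max_mm mismatches, sorted like the aligner output.
## N on either side counts as a mismatch.
oracle_hamming_scan <- function(genome, query, max_mm) {
  L <- nchar(query)
  nraw <- charToRaw("N")
  qs <- list("+" = charToRaw(query),
             "-" = charToRaw(ovimirnome::revcomp(query)))
  out <- list()
  for (ch in names(genome)) {
    g <- charToRaw(genome[[ch]])
    npos <- length(g) - L + 1
    if (npos < 1) next
    for (strand in c("+", "-")) {
      q <- qs[[strand]]
      mm <- integer(npos)
      for (j in seq_len(L)) {
        gj <- g[j:(j + npos - 1)]
        mm <- mm + as.integer(gj != q[j] | gj == nraw | q[j] == nraw)
      }
      hit <- which(mm <= max_mm)
      if (length(hit) > 0) {
        out[[length(out) + 1]] <- data.frame(
          chrom = ch, start = hit - 1L, end = hit - 1L + L,
          strand = strand, mismatches = mm[hit],
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      mismatches = integer(0), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res <- res[res$mismatches == min(res$mismatches), , drop = FALSE]
  res <- res[order(res$chrom, res$start, res$strand), , drop = FALSE]
  rownames(res) <- NULL
  res
}

## Brute-force Benjamini-Hochberg: p * m / rank with a cumulative minimum
## from the largest p down, restored to input order.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

## Brute-force best suffix alignment of an adapter against a read: for
## every alignment start, the overlap with the read suffix and its
## mismatch count; returns the smallest start within the error budget
## (0 = no match).
oracle_adapter_suffix <- function(seq, adapter, min_overlap, err_rate) {
  L <- nchar(seq); la <- nchar(adapter)
  sv <- strsplit(seq, "")[[1]]
  av <- strsplit(adapter, "")[[1]]
  for (p in seq_len(L)) {
    ov <- min(la, L - p + 1)
    if (ov < min_overlap) break
    s <- sv[p:(p + ov - 1)]
    a <- av[seq_len(ov)]
    mm <- sum(s != a | s == "N" | a == "N")
    if (mm <= floor(err_rate * ov)) return(p)
  }
  0L
}

## One-way ANOVA by explicit sums of squares (textbook oracle).
oracle_anova <- function(values, groups) {
  groups <- as.factor(groups)
  grand <- mean(values)
  ss_between <- sum(tapply(values, groups, function(x)
    length(x) * (mean(x) - grand)^2))
  ss_within <- sum(tapply(values, groups, function(x)
    sum((x - mean(x))^2)))
  df_b <- nlevels(groups) - 1
  df_w <- length(values) - nlevels(groups)
  f <- (ss_between / df_b) / (ss_within / df_w)
  list(f = f, p = stats::pf(f, df_b, df_w, lower.tail = FALSE))
}

## Stepwise TMM factor for one sample pair, following the published
## trimmed weighted-mean recipe literally (oracle for tmm_factors).
oracle_tmm_pair <- function(obs, ref, n_obs, n_ref,
                            logratio_trim = 0.3, abs_expr_trim = 0.05) {
  fin <- obs > 0 & ref > 0
  obs <- obs[fin]; ref <- ref[fin]
  m <- log2((obs / n_obs) / (ref / n_ref))
  a <- 0.5 * log2((obs / n_obs) * (ref / n_ref))
  w <- (n_obs - obs) / (n_obs * obs) + (n_ref - ref) / (n_ref * ref)
  n <- length(m)
  ## keep the genes whose M and A both lie strictly inside the trimmed
  ## tails, identified by explicit sorting rather than rank arithmetic
  m_keep_ids <- order(m)[(floor(n * logratio_trim) + 1):
                           (n - floor(n * logratio_trim))]
  a_keep_ids <- order(a)[(floor(n * abs_expr_trim) + 1):
                           (n - floor(n * abs_expr_trim))]
  keep <- intersect(m_keep_ids, a_keep_ids)
  2^(sum(m[keep] / w[keep]) / sum(1 / w[keep]))
}
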