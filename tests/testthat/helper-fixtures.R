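## Small in-code fixture builders shared across test files.

## A count_matrix from a plain matrix, with a minimal sample sheet.
toy_cm <- function(counts, groups = NULL, tissue = "lung",
                   lib_sizes = NULL) {
  if (is.null(colnames(counts))) {
    colnames(counts) <- paste0("s", seq_len(ncol(counts)))
  }
  if (is.null(rownames(counts))) {
    rownames(counts) <- paste0("miR-", seq_len(nrow(counts)))
  }
  if (is.null(groups)) {
    groups <- rep(c("NT", "Neo"), length.out = ncol(counts))
  }
  samples <- data.frame(
    sample_id = colnames(counts), tissue = tissue, group = groups,
    replicate = stats::ave(seq_len(ncol(counts)), groups,
                           FUN = seq_along),
    stringsAsFactors = FALSE)
  count_matrix(counts, samples, lib_sizes = lib_sizes)
}

## One-tissue two-group sample sheet (first half NT, second half Neo).
mk_de_samples <- function(n) {
  data.frame(sample_id = paste0("s", seq_len(n)), tissue = "lung",
             group = rep(c("NT", "Neo"), each = n / 2),
             replicate = rep(seq_len(n / 2), 2), stringsAsFactors = FALSE)
}

## A random genome + catalog instance for miRNome property tests:
## entries are slices of the genome (overlaps allowed, either strand)
## with a mixed-prefix naming scheme, plus optional duplicated
## placements under different names.
random_catalog_instance <- function(genome, n_entries, seed) {
  set.seed(seed)
  chrom <- sample(names(genome), n_entries, replace = TRUE)
  len <- sample(18:25, n_entries, replace = TRUE)
  start <- vapply(seq_len(n_entries), function(i) {
    sample.int(nchar(genome[[chrom[i]]]) - len[i], 1) - 1L
  }, integer(1))
  strand <- sample(c("+", "-"), n_entries, replace = TRUE)
  slice <- substring(unname(unclass(genome)[chrom]), start + 1, start + len)
  seq_dna <- ifelse(strand == "-", revcomp(slice), slice)
  prefix <- sample(c("oar", "bta", "hsa", "PC", "NONE", "ssc"),
                   n_entries, replace = TRUE)
  ids <- vapply(seq_len(n_entries), function(i) {
    switch(prefix[i],
           PC = sprintf("PC-5p-%d_%d", i, seed %% 97 + i),
           NONE = sprintf("miR-%d", i),
           sprintf("%s-miR-%d", prefix[i], i))
  }, character(1))
  data.frame(entry_id = ids, sequence = chartr("T", "U", seq_dna),
             stringsAsFactors = FALSE)
}
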