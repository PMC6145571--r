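#' Convert RNA to DNA alphabet
#'
#' U -> T substitution only; DNA input passes through unchanged.
#'
#' @param seq character vector over A/C/G/U/T/N.
#' @return the sequences in the DNA alphabet.
#' @export
rna_to_dna <- function(seq) {
  if (!all(grepl("^[ACGUTN]*$", seq))) {
    err("sequences must be over the A/C/G/U (or T/N) alphabet")
  }
  chartr("U", "T", seq)
}

## Species prefix of a miRNA name: the token before the first '-'.
## "PC-..." -> PC; names starting "miR-"/"let-" carry no species token
## (conserved) -> NONE; anything unparseable -> OTHER with a warning.
parse_prefix <- function(ids) {
  token <- sub("-.*$", "", ids)
  out <- character(length(ids))
  out[startsWith(ids, "PC-")] <- "PC"
  conserved <- out == "" & token %in% c("miR", "let")
  out[conserved] <- "NONE"
  species <- out == "" & grepl("^[a-z]{3}$", token) & grepl("-", ids)
  out[species] <- token[species]
  bad <- out == ""
  if (any(bad)) {
    warning("unparseable miRNA id(s) counted as OTHER: ",
            paste(utils::head(ids[bad], 5), collapse = ", "), call. = FALSE)
    out[bad] <- "OTHER"
  }
  out
}

#' Map a mature-miRNA catalog to the genome exactly
#'
#' Converts catalog sequences to the DNA alphabet and aligns them with a
#' zero-mismatch budget, retaining one placement per entry under the
#' aligner tie policy (lexicographically smallest chrom/start/strand among
#' equal-best placements).
#'
#' @param index a [build_index()] result.
#' @param genome the genome the index was built from.
#' @param catalog data.frame with `entry_id`, `sequence` (RNA or DNA
#'   alphabet) and optionally `source`.
#' @return list with `mapped` (catalog columns plus chrom, start, end,
#'   strand, mismatches, is_unique_best) and `unmapped` (entry ids with no
#'   exact placement).
#' @export
map_catalog <- function(index, genome, catalog) {
  stopifnot(all(c("entry_id", "sequence") %in% names(catalog)))
  if (anyDuplicated(catalog$entry_id)) err("duplicate catalog entry ids")
  dna <- rna_to_dna(catalog$sequence)
  reads <- data.frame(read_id = catalog$entry_id, sequence = dna,
                      stringsAsFactors = FALSE)
  res <- align_batch(index, genome, reads, max_mm = 0, policy = "best")
  aln <- res$alignments
  m <- match(aln$read_id, catalog$entry_id)
  mapped <- data.frame(entry_id = aln$read_id,
                       sequence = dna[m],
                       source = if ("source" %in% names(catalog))
                         catalog$source[m] else "other",
                       chrom = aln$chrom, start = aln$start, end = aln$end,
                       strand = aln$strand, mismatches = aln$mismatches,
                       is_unique_best = aln$is_unique_best,
                       stringsAsFactors = FALSE)
  list(mapped = mapped, unmapped = res$unmapped)
}

#' Consolidate mapped catalog entries into a non-overlapping miRNome
#'
#' Greedy redundancy removal: candidates are sorted by species-prefix
#' priority, then descending length, then entry id, and accepted iff they
#' overlap no already-accepted locus on the same (chrom, strand) (or on
#' either strand when `strand_aware = FALSE`).  Rejected entries are
#' recorded in the provenance of the accepted locus they overlap.
#'
#' @param mapped `mapped` data.frame from [map_catalog()].
#' @param priority ordered character vector of preferred species
#'   prefixes; prefixes not listed rank after all listed ones,
#'   alphabetically.
#' @param strand_aware if `TRUE` (default) opposite-strand loci may
#'   overlap.
#' @return object of class `mirnome`: list with `loci` (locus_id, chrom,
#'   start, end, strand, sequence, species_prefix) and `provenance`
#'   (named list: accepted locus id -> entry ids collapsed into it,
#'   itself included).
#' @export
consolidate_loci <- function(mapped,
                             priority = c("oar", "PC", "NONE", "bta",
                                          "hsa", "mmu"),
                             strand_aware = TRUE) {
  if (nrow(mapped) == 0) {
    return(structure(list(loci = data.frame(
      locus_id = character(0), chrom = character(0), start = integer(0),
      end = integer(0), strand = character(0), sequence = character(0),
      species_prefix = character(0), stringsAsFactors = FALSE),
      provenance = list()), class = "mirnome"))
  }
  prefix <- parse_prefix(mapped$entry_id)
  rank <- match(prefix, priority)
  ## unlisted prefixes follow the listed ones, in alphabetical order
  unlisted <- sort(unique(prefix[is.na(rank)]))
  rank[is.na(rank)] <- length(priority) +
    match(prefix[is.na(rank)], unlisted)
  len <- mapped$end - mapped$start
  ord <- order(rank, -len, mapped$entry_id)
  cand <- mapped[ord, , drop = FALSE]
  cand$species_prefix <- prefix[ord]
  acc <- integer(0)                  # row indices into cand
  assigned_to <- integer(nrow(cand)) # accepted row each reject overlaps
  for (i in seq_len(nrow(cand))) {
    if (length(acc) == 0) { acc <- i; next }
    same <- cand$chrom[acc] == cand$chrom[i] &
      cand$start[acc] < cand$end[i] & cand$end[acc] > cand$start[i]
    if (strand_aware) same <- same & cand$strand[acc] == cand$strand[i]
    hit <- acc[same]
    if (length(hit) == 0) {
      acc <- c(acc, i)
    } else {
      assigned_to[i] <- hit[1L]
    }
  }
  acc <- sort(acc)
  loci <- data.frame(locus_id = cand$entry_id[acc], chrom = cand$chrom[acc],
                     start = cand$start[acc], end = cand$end[acc],
                     strand = cand$strand[acc], sequence = cand$sequence[acc],
                     species_prefix = cand$species_prefix[acc],
                     stringsAsFactors = FALSE)
  loci <- loci[order(loci$chrom, loci$start, loci$strand), , drop = FALSE]
  rownames(loci) <- NULL
  provenance <- lapply(acc, function(i) {
    c(cand$entry_id[i], cand$entry_id[assigned_to == i])
  })
  names(provenance) <- cand$entry_id[acc]
  provenance <- provenance[loci$locus_id]
  structure(list(loci = loci, provenance = provenance), class = "mirnome")
}

#' Build a miRNome from genome and catalog in one step
#'
#' Convenience wrapper: [map_catalog()] then [consolidate_loci()].
#'
#' @inheritParams map_catalog
#' @inheritParams consolidate_loci
#' @return a `mirnome` with an extra attribute `unmapped` (entry ids with
#'   no exact genomic placement).
#' @export
build_mirnome <- function(index, genome, catalog,
                          priority = c("oar", "PC", "NONE", "bta",
                                       "hsa", "mmu"),
                          strand_aware = TRUE) {
  m <- map_catalog(index, genome, catalog)
  out <- consolidate_loci(m$mapped, priority = priority,
                          strand_aware = strand_aware)
  attr(out, "unmapped") <- m$unmapped
  out
}

#' Census of species prefixes in a miRNome
#'
#' Counts loci by the species token of their name (the part before the
#' first '-'): `PC` for recently-published picked candidates, `NONE` for
#' prefix-free conserved names (`miR-...`, `let-...`), otherwise the
#' three-letter species code (`oar`, `bta`, `hsa`, ...).  The counts
#' partition the loci.
#'
#' @param mirnome a `mirnome`.
#' @return named integer vector of counts, decreasing.
#' @export
census_prefixes <- function(mirnome) {
  pf <- parse_prefix(mirnome$loci$locus_id)
  tab <- sort(table(pf), decreasing = TRUE)
  stats::setNames(as.integer(tab), names(tab))
}

#' @export
print.mirnome <- function(x, ...) {
  cat("miRNome with", nrow(x$loci), "non-overlapping loci on",
      length(unique(x$loci$chrom)), "chromosome(s)\n")
  invisible(x)
}
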