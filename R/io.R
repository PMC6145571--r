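#' Read and write FASTA genomes
#'
#' Thin wrappers around Biostrings keeping the package's named-character
#' genome representation.
#'
#' @param genome named character vector of sequences.
#' @param path file path.
#' @return `read_fasta` returns a named character vector (class
#'   `ref_genome`).
#' @export
write_fasta <- function(genome, path) {
  x <- Biostrings::DNAStringSet(unclass(genome))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' @rdname write_fasta
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  structure(stats::setNames(as.character(x), names(x)), class = "ref_genome")
}

#' Read and write FASTQ reads
#'
#' Reads are held as data.frames with `read_id`, `sequence`, `quality`
#' (Sanger encoding).
#'
#' @param reads data.frame of reads.
#' @param path file path.
#' @export
write_fastq <- function(reads, path) {
  x <- Biostrings::DNAStringSet(reads$sequence)
  names(x) <- reads$read_id
  Biostrings::writeXStringSet(x, path, format = "fastq",
                              qualities = Biostrings::BStringSet(reads$quality))
  invisible(path)
}

#' @rdname write_fastq
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq",
                                    with.qualities = TRUE)
  data.frame(read_id = names(x),
             sequence = as.character(x),
             quality = as.character(S4Vectors::mcols(x)$qualities),
             stringsAsFactors = FALSE)
}

#' Write a catalog as FASTA (RNA alphabet preserved as text)
#'
#' @param catalog data.frame with `entry_id`, `sequence`.
#' @param path file path.
#' @export
write_catalog_fasta <- function(catalog, path) {
  writeLines(paste0(">", catalog$entry_id, "\n", catalog$sequence), path)
  invisible(path)
}

#' @rdname write_catalog_fasta
#' @export
read_catalog_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  data.frame(entry_id = names(x), sequence = as.character(x),
             stringsAsFactors = FALSE)
}

#' Export a miRNome annotation
#'
#' `write_bed` emits BED6 (0-based half-open, score 0); `write_saf` emits
#' the five-column SAF layout (GeneID, Chr, Start, End, Strand) with
#' 1-based inclusive coordinates; `write_provenance` emits a two-column
#' TSV mapping each locus to the catalog entries collapsed into it.
#'
#' @param mirnome a `mirnome`.
#' @param path file path.
#' @export
write_bed <- function(mirnome, path) {
  l <- mirnome$loci
  utils::write.table(
    data.frame(l$chrom, l$start, l$end, l$locus_id, 0L, l$strand),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_bed
#' @export
write_saf <- function(mirnome, path) {
  l <- mirnome$loci
  utils::write.table(
    data.frame(GeneID = l$locus_id, Chr = l$chrom, Start = l$start + 1L,
               End = l$end, Strand = l$strand),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_bed
#' @export
write_provenance <- function(mirnome, path) {
  utils::write.table(
    data.frame(locus_id = names(mirnome$provenance),
               entries = vapply(mirnome$provenance, paste, character(1),
                                collapse = ",")),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a count matrix and its sample sheet as TSV
#'
#' @param cm a [count_matrix()].
#' @param counts_path,samples_path output files.
#' @export
write_counts <- function(cm, counts_path, samples_path = NULL) {
  utils::write.table(data.frame(mirna_id = rownames(cm$counts), cm$counts,
                                check.names = FALSE),
                     counts_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(samples_path)) {
    utils::write.table(cm$samples, samples_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(counts_path)
}

#' Read a qPCR Ct table from CSV
#'
#' Expected columns: sample_id, tissue, group, mirna_id, ct1, ct2, ct3.
#'
#' @param path CSV file.
#' @return data.frame of Ct records.
#' @export
read_ct_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "tissue", "group", "mirna_id", "ct1")
  if (!all(need %in% names(d))) {
    err("Ct table needs columns ", paste(need, collapse = ", "))
  }
  d
}
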