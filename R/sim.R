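#' Simulation design for a cardiopulmonary developmental study
#'
#' Describes the factorial layout and distributional parameters used by all
#' synthetic-data generators: tissues crossed with ordered age groups
#' (preterm fetus, near-term fetus, neonate by default), a sequencing arm
#' with `replicates_ngs` animals per tissue/group cell and a qPCR arm with
#' `replicates_qpcr`, negative-binomially distributed miRNA counts, and a
#' configurable fraction of miRNAs carrying planted log2 fold-change
#' effects.
#'
#' @param tissues character vector of tissue labels.
#' @param groups ordered character vector of age-group labels (earliest
#'   first); at least two.
#' @param replicates_ngs biological replicates per cell in the sequencing
#'   arm.
#' @param replicates_qpcr biological replicates per cell in the qPCR arm.
#' @param n_mirnas number of miRNA loci to simulate.
#' @param de_fraction fraction of miRNAs given a planted effect.
#' @param effect_log2fc magnitude of planted log2 fold changes (> 0).
#' @param dispersion negative-binomial overdispersion phi, with
#'   variance = mu + mu^2 * phi; 0 gives Poisson counts.
#' @param mean_libsize expected reads (or counts) per sample.
#' @param libsize_imbalance optional named numeric vector of per-tissue
#'   library-size multipliers (default: all 1).
#' @param seed integer seed; every generator derives its stream from it.
#' @return an object of class `sim_design`.
#' @export
sim_design <- function(tissues = c("lung", "PA", "LV", "RV"),
                       groups = c("PT", "NT", "Neo"),
                       replicates_ngs = 3,
                       replicates_qpcr = 4,
                       n_mirnas = 100,
                       de_fraction = 0.2,
                       effect_log2fc = 2,
                       dispersion = 0.1,
                       mean_libsize = 1e6,
                       libsize_imbalance = NULL,
                       seed = 1) {
  if (length(groups) < 2) err("need at least two age groups")
  if (length(tissues) < 1) err("need at least one tissue")
  stopifnot(replicates_ngs >= 1, replicates_qpcr >= 1, n_mirnas >= 1,
            effect_log2fc > 0, dispersion >= 0, mean_libsize >= 1)
  check_prob(de_fraction, "de_fraction")
  if (is.null(libsize_imbalance)) {
    libsize_imbalance <- stats::setNames(rep(1, length(tissues)), tissues)
  }
  if (!all(tissues %in% names(libsize_imbalance))) {
    err("libsize_imbalance must name every tissue")
  }
  structure(list(
    tissues = tissues, groups = groups,
    replicates_ngs = as.integer(replicates_ngs),
    replicates_qpcr = as.integer(replicates_qpcr),
    n_mirnas = as.integer(n_mirnas),
    de_fraction = de_fraction,
    effect_log2fc = effect_log2fc,
    dispersion = dispersion,
    mean_libsize = as.integer(mean_libsize),
    libsize_imbalance = libsize_imbalance,
    seed = as.integer(seed)
  ), class = "sim_design")
}

## Contrast labels implied by the ordered group list: each consecutive
## pair, later group versus earlier ("NT_vs_PT", "Neo_vs_NT" by default).
design_contrasts <- function(design) {
  g <- design$groups
  paste0(g[-1], "_vs_", g[-length(g)])
}

## Sample sheet for one assay arm.
sim_samples <- function(design, assay = c("ngs", "qpcr")) {
  assay <- match.arg(assay)
  reps <- if (assay == "ngs") design$replicates_ngs else design$replicates_qpcr
  grid <- expand.grid(replicate = seq_len(reps),
                      group = design$groups,
                      tissue = design$tissues,
                      stringsAsFactors = FALSE)
  grid <- grid[, c("tissue", "group", "replicate")]
  grid$sample_id <- paste(grid$tissue, grid$group, grid$replicate, sep = "_")
  grid[, c("sample_id", "tissue", "group", "replicate")]
}

#' Generate a toy reference genome
#'
#' Uniform-random A/C/G/T chromosomes, reproducible for a fixed seed.
#'
#' @param n_chrom number of chromosomes (>= 1).
#' @param chrom_length length of each chromosome (>= 1000).
#' @param seed integer seed.
#' @return named character vector of chromosome sequences
#'   (`chr1`, `chr2`, ...), class `ref_genome`.
#' @export
generate_genome <- function(n_chrom, chrom_length, seed = 1) {
  if (n_chrom < 1 || chrom_length < 1000) {
    err("need n_chrom >= 1 and chrom_length >= 1000")
  }
  with_seed(seed, {
    seqs <- random_dna(rep(as.integer(chrom_length), n_chrom))
    names(seqs) <- paste0("chr", seq_len(n_chrom))
    structure(seqs, class = "ref_genome")
  })
}

## id generator for one catalog entry; index keeps names unique.
sim_mirna_id <- function(prefix, i) {
  switch(prefix,
    "PC" = sprintf("PC-5p-%d_%d", 100 + i, 1000 + i),
    "NONE" = sprintf("miR-%d", 100 + i),
    sprintf("%s-miR-%d", prefix, 100 + i))
}

#' Plant a multi-species miRNA catalog on a genome
#'
#' Places `n_mirnas` non-overlapping 18-25 nt loci on the genome (either
#' strand), emits the corresponding mature-miRNA catalog in the RNA
#' alphabet with species-prefixed names, and optionally adds decoy entries
#' whose sequences occur nowhere in the genome.  The default prefix mix
#' mirrors the composition typical of a cross-species cardiopulmonary
#' catalog: mostly recently-published (PC) and conserved (no prefix)
#' names, with cattle (bta), human (hsa), sheep (oar) and mouse (mmu)
#' entries.
#'
#' @param genome a `ref_genome` (named character vector).
#' @param design a [sim_design()].
#' @param decoy_fraction fraction (of `n_mirnas`) of extra catalog entries
#'   with no genomic match.
#' @param prefix_weights named numeric vector of sampling weights for the
#'   species prefixes (`NONE` = prefix-free conserved names).
#' @return list with `catalog` (data.frame: entry_id, sequence in the RNA
#'   alphabet, source) and `loci` (data.frame of the planted true loci:
#'   locus_id, chrom, start, end, strand, sequence, species_prefix).
#'   Coordinates are 0-based, half-open.
#' @export
plant_catalog <- function(genome, design, decoy_fraction = 0.1,
                          prefix_weights = c(PC = 504, NONE = 288, bta = 236,
                                             hsa = 130, oar = 80, mmu = 62)) {
  check_prob(decoy_fraction, "decoy_fraction")
  n <- design$n_mirnas
  chrom_len <- nchar(genome)
  if (sum(pmax(chrom_len - 25, 0)) < n * 26 * 2) {
    err("genome too small to place ", n, " non-overlapping loci")
  }
  with_seed(design$seed + 1L, {
    lens <- sample(18:25, n, replace = TRUE)
    prefixes <- sample(names(prefix_weights), n, replace = TRUE,
                       prob = prefix_weights)
    ids <- vapply(seq_len(n), function(i) sim_mirna_id(prefixes[i], i),
                  character(1))
    ## greedy random placement, rejecting overlaps with accepted loci
    occ <- lapply(genome, function(s) matrix(numeric(0), ncol = 2))
    chrom <- character(n); start <- integer(n); strand <- character(n)
    for (i in seq_len(n)) {
      placed <- FALSE
      for (try in seq_len(200L)) {
        ch <- sample(names(genome), 1)
        st <- sample.int(chrom_len[[ch]] - lens[i], 1) - 1L  # 0-based
        en <- st + lens[i]
        o <- occ[[ch]]
        if (nrow(o) == 0 || all(en <= o[, 1] | st >= o[, 2])) {
          occ[[ch]] <- rbind(o, c(st, en))
          chrom[i] <- ch; start[i] <- st
          strand[i] <- sample(c("+", "-"), 1)
          placed <- TRUE
          break
        }
      }
      if (!placed) err("genome too crowded: could not place locus ", i)
    }
    end <- start + lens
    slice <- substring(unname(unclass(genome)[chrom]), start + 1L, end)
    ## mature sequence is read off the locus strand
    seq_dna <- ifelse(strand == "-", revcomp(slice), slice)
    loci <- data.frame(locus_id = ids, chrom = chrom, start = start,
                       end = end, strand = strand, sequence = seq_dna,
                       species_prefix = prefixes, stringsAsFactors = FALSE)
    source <- ifelse(prefixes == "PC", "published_sheep", "mirbase")
    catalog <- data.frame(entry_id = ids,
                          sequence = chartr("T", "U", seq_dna),
                          source = source, stringsAsFactors = FALSE)
    n_decoy <- round(decoy_fraction * n)
    if (n_decoy > 0) {
      decoys <- character(0)
      while (length(decoys) < n_decoy) {
        cand <- random_dna(sample(18:25, n_decoy - length(decoys),
                                  replace = TRUE))
        hit <- vapply(cand, function(s) {
          any(vapply(genome, function(g) {
            grepl(s, g, fixed = TRUE) || grepl(revcomp(s), g, fixed = TRUE)
          }, logical(1)))
        }, logical(1))
        decoys <- c(decoys, cand[!hit])
      }
      catalog <- rbind(catalog, data.frame(
        entry_id = sprintf("decoy-miR-%d", seq_len(n_decoy)),
        sequence = chartr("T", "U", decoys),
        source = "other", stringsAsFactors = FALSE))
    }
    list(catalog = catalog, loci = loci)
  })
}

#' Draw the planted ground-truth effects for a design
#'
#' Selects `round(de_fraction * n_mirnas)` loci and assigns each a tissue,
#' a consecutive-group contrast, and a signed log2 fold change of
#' magnitude `effect_log2fc`.  An effect for contrast "B_vs_A" multiplies
#' the mean of group B and of every later group, so each planted effect is
#' visible in exactly one consecutive contrast.
#'
#' @param design a [sim_design()].
#' @param locus_ids ids of all simulated loci.
#' @param exclude ids never given an effect (e.g. reference miRNAs).
#' @return data.frame with columns locus_id, tissue, contrast,
#'   true_log2fc (possibly zero rows).
#' @export
plant_effects <- function(design, locus_ids, exclude = character(0)) {
  n_de <- round(design$de_fraction * design$n_mirnas)
  pool <- setdiff(locus_ids, exclude)
  if (n_de > length(pool)) err("not enough loci to plant ", n_de, " effects")
  with_seed(design$seed + 2L, {
    if (n_de == 0) {
      return(data.frame(locus_id = character(0), tissue = character(0),
                        contrast = character(0), true_log2fc = numeric(0),
                        stringsAsFactors = FALSE))
    }
    chosen <- sample(pool, n_de)
    data.frame(
      locus_id = chosen,
      tissue = sample(design$tissues, n_de, replace = TRUE),
      contrast = sample(design_contrasts(design), n_de, replace = TRUE),
      true_log2fc = sample(c(-1, 1), n_de, replace = TRUE) *
        design$effect_log2fc,
      stringsAsFactors = FALSE)
  })
}

## log2 effect matrix (locus x sample) implied by the truth table:
## contrast "B_vs_A" shifts group B and all later groups in that tissue.
effect_matrix <- function(design, truth, locus_ids, samples) {
  E <- matrix(0, length(locus_ids), nrow(samples),
              dimnames = list(locus_ids, samples$sample_id))
  if (nrow(truth) == 0) return(E)
  contrasts <- design_contrasts(design)
  for (r in seq_len(nrow(truth))) {
    j <- match(truth$contrast[r], contrasts)
    if (is.na(j)) err("unknown contrast in truth: ", truth$contrast[r])
    affected <- design$groups[(j + 1):length(design$groups)]
    cols <- samples$tissue == truth$tissue[r] & samples$group %in% affected
    E[truth$locus_id[r], cols] <- E[truth$locus_id[r], cols] +
      truth$true_log2fc[r]
  }
  E
}

#' Simulate a miRNA count matrix directly (no reads)
#'
#' Negative-binomial counts over the design's sequencing arm, with planted
#' group-by-tissue effects and two designated reference miRNAs that carry
#' no effects and near-zero dispersion (emulating stable normalizer
#' candidates).  Useful for testing normalization and differential
#' expression without the alignment steps.
#'
#' @param design a [sim_design()].
#' @param truth optional truth table from [plant_effects()]; generated
#'   from the design when `NULL`.
#' @param locus_ids optional ids (length `n_mirnas`); autogenerated when
#'   `NULL`, in which case the last two ids are the reference miRNAs
#'   `bta-miR-2284x_R+1` and `PC-5p-592_3212`.
#' @param vary_libsize jitter library sizes by +/- 15% (default `TRUE`;
#'   `FALSE` fixes every library at `mean_libsize` times the tissue
#'   imbalance factor).
#' @return list with `counts` (a [count_matrix()]), `truth`, and
#'   `ref_ids` (the two reference miRNA ids).
#' @export
simulate_counts <- function(design, truth = NULL, locus_ids = NULL,
                            vary_libsize = TRUE) {
  if (is.null(locus_ids)) {
    if (design$n_mirnas < 3) err("need n_mirnas >= 3")
    locus_ids <- c(sprintf("miR-sim-%03d", seq_len(design$n_mirnas - 2)),
                   "bta-miR-2284x_R+1", "PC-5p-592_3212")
  }
  stopifnot(length(locus_ids) == design$n_mirnas)
  ref_ids <- locus_ids[c(design$n_mirnas - 1L, design$n_mirnas)]
  if (is.null(truth)) truth <- plant_effects(design, locus_ids, exclude = ref_ids)
  samples <- sim_samples(design, "ngs")
  with_seed(design$seed + 3L, {
    S <- nrow(samples)
    jitter <- if (vary_libsize) stats::runif(S, 0.85, 1.15) else rep(1, S)
    lib <- round(design$mean_libsize * jitter *
                   design$libsize_imbalance[samples$tissue])
    b <- stats::runif(design$n_mirnas, 2, 12)
    b[locus_ids %in% ref_ids] <- 10
    E <- effect_matrix(design, truth, locus_ids, samples)
    abund <- 2^(b + E)
    p <- sweep(abund, 2, colSums(abund), "/")
    mu <- sweep(p, 2, lib, "*")
    phi <- rep(design$dispersion, design$n_mirnas)
    phi[locus_ids %in% ref_ids] <- 1e-4
    counts <- matrix(0L, design$n_mirnas, S,
                     dimnames = list(locus_ids, samples$sample_id))
    for (i in seq_len(design$n_mirnas)) {
      counts[i, ] <- if (phi[i] == 0) {
        stats::rpois(S, mu[i, ])
      } else {
        stats::rnbinom(S, mu = mu[i, ], size = 1 / phi[i])
      }
    }
    list(counts = count_matrix(counts, samples), truth = truth,
         ref_ids = ref_ids)
  })
}

#' Simulate adapter-flanked small-RNA FASTQ reads
#'
#' For each sample of the sequencing arm, draws per-locus read counts from
#' the same negative-binomial model as [simulate_counts()], emits each
#' read as the locus sequence flanked by the 3' adapter (truncated to
#' `read_length`), adds a background fraction of random-sequence reads,
#' and prepends short N runs to a fraction of reads.  Base qualities are
#' fixed at Q30.
#'
#' @param loci planted loci from [plant_catalog()].
#' @param design a [sim_design()].
#' @param adapter_3p 3' adapter sequence appended to every insert.
#' @param truth optional truth table; generated when `NULL`.
#' @param reads_per_sample expected reads per sample (default
#'   `design$mean_libsize`).
#' @param error_rate per-base substitution error rate in inserts.
#' @param background_frac fraction of the library that is random-sequence
#'   background (non-miRNA small RNA species).
#' @param n5_frac fraction of reads with 1-3 leading N's.
#' @param read_length sequencer read length (cycles).
#' @return list with `samples` (sample sheet), `reads` (named list of
#'   data.frames: read_id, sequence, quality), `truth`, and
#'   `locus_counts` (true pre-sequencing counts, locus x sample).
#' @export
simulate_fastq <- function(loci, design,
                           adapter_3p = "TGGAATTCTCGGGTGCCAAGG",
                           truth = NULL, reads_per_sample = NULL,
                           error_rate = 0, background_frac = 0.1,
                           n5_frac = 0.05, read_length = 50) {
  if (nchar(adapter_3p) == 0) err("adapter_3p must be non-empty")
  check_prob(error_rate, "error_rate")
  check_prob(background_frac, "background_frac")
  check_prob(n5_frac, "n5_frac")
  if (is.null(reads_per_sample)) reads_per_sample <- design$mean_libsize
  stopifnot(nrow(loci) == design$n_mirnas)
  if (is.null(truth)) truth <- plant_effects(design, loci$locus_id)
  samples <- sim_samples(design, "ngs")
  with_seed(design$seed + 4L, {
    S <- nrow(samples)
    lib <- round(reads_per_sample * stats::runif(S, 0.85, 1.15) *
                   design$libsize_imbalance[samples$tissue])
    b <- stats::runif(design$n_mirnas, 2, 12)
    E <- effect_matrix(design, truth, loci$locus_id, samples)
    abund <- 2^(b + E)
    p <- sweep(abund, 2, colSums(abund), "/")
    locus_counts <- matrix(0L, design$n_mirnas, S,
                           dimnames = list(loci$locus_id, samples$sample_id))
    reads <- vector("list", S)
    names(reads) <- samples$sample_id
    size <- if (design$dispersion == 0) Inf else 1 / design$dispersion
    for (s in seq_len(S)) {
      mu <- p[, s] * lib[s] * (1 - background_frac)
      cnt <- if (is.infinite(size)) stats::rpois(design$n_mirnas, mu) else
        stats::rnbinom(design$n_mirnas, mu = mu, size = size)
      locus_counts[, s] <- cnt
      inserts <- rep(loci$sequence, cnt)
      if (error_rate > 0 && length(inserts) > 0) {
        inserts <- vapply(inserts, function(sq) {
          bases <- strsplit(sq, "", fixed = TRUE)[[1]]
          hit <- stats::runif(length(bases)) < error_rate
          if (any(hit)) {
            bases[hit] <- vapply(bases[hit], function(x) {
              sample(setdiff(c("A", "C", "G", "T"), x), 1)
            }, character(1))
          }
          paste(bases, collapse = "")
        }, character(1), USE.NAMES = FALSE)
      }
      n_bg <- round(background_frac * lib[s])
      if (n_bg > 0) {
        inserts <- c(inserts, random_dna(sample(18:25, n_bg, replace = TRUE)))
      }
      sq <- paste0(inserts, adapter_3p)
      nn <- length(sq)
      if (nn > 0) {
        with_n <- stats::runif(nn) < n5_frac
        sq[with_n] <- paste0(strrep("N", sample(1:3, sum(with_n),
                                                replace = TRUE)), sq[with_n])
        sq <- substr(sq, 1L, read_length)
        sq <- sq[sample.int(nn)]
      }
      reads[[s]] <- data.frame(
        read_id = sprintf("%s_read%06d", samples$sample_id[s], seq_len(nn)),
        sequence = sq,
        quality = strrep("?", nchar(sq)),  # Sanger Q30
        stringsAsFactors = FALSE)
    }
    list(samples = samples, reads = reads, truth = truth,
         locus_counts = locus_counts)
  })
}

#' Simulate qPCR Ct tables
#'
#' Ct values follow `baseline - log2(relative abundance) + noise`, with
#' three technical replicates per well group and planted effects applied
#' on the log2-abundance scale.  Reference targets have constant
#' abundance, so their Ct varies only by noise.
#'
#' @param design a [sim_design()]; the qPCR arm (`replicates_qpcr`) is
#'   used.
#' @param truth truth table from [plant_effects()] (zero rows allowed).
#' @param ref_ids two reference target ids (no planted effects).
#' @param targets target miRNA ids to assay; defaults to the truth loci
#'   plus the references.
#' @param noise_sd Gaussian Ct noise SD per technical replicate.
#' @param baseline Ct of a target at unit relative abundance.
#' @return data.frame with columns sample_id, tissue, group, mirna_id,
#'   ct1, ct2, ct3.
#' @export
simulate_ct <- function(design, truth, ref_ids, targets = NULL,
                        noise_sd = 0.2, baseline = 30) {
  stopifnot(length(ref_ids) == 2, noise_sd >= 0)
  if (is.null(targets)) targets <- unique(c(truth$locus_id, ref_ids))
  if (!all(ref_ids %in% targets)) err("ref_ids must be among the targets")
  if (any(truth$locus_id %in% ref_ids)) {
    err("reference targets cannot carry planted effects")
  }
  samples <- sim_samples(design, "qpcr")
  with_seed(design$seed + 5L, {
    b <- stats::setNames(stats::runif(length(targets), 2, 8), targets)
    b[ref_ids] <- 6
    E <- effect_matrix(design, truth[truth$locus_id %in% targets, ,
                                     drop = FALSE], targets, samples)
    grid <- expand.grid(mirna_id = targets, sample_id = samples$sample_id,
                        stringsAsFactors = FALSE)
    grid <- merge(grid, samples, by = "sample_id", sort = FALSE)
    log2rel <- b[grid$mirna_id] +
      E[cbind(grid$mirna_id, grid$sample_id)]
    ct0 <- baseline - log2rel
    n <- nrow(grid)
    out <- data.frame(sample_id = grid$sample_id, tissue = grid$tissue,
                      group = grid$group, mirna_id = grid$mirna_id,
                      ct1 = ct0 + stats::rnorm(n, 0, noise_sd),
                      ct2 = ct0 + stats::rnorm(n, 0, noise_sd),
                      ct3 = ct0 + stats::rnorm(n, 0, noise_sd),
                      stringsAsFactors = FALSE)
    out[order(out$sample_id, out$mirna_id), , drop = FALSE]
  })
}
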