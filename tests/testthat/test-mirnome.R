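test_that("RNA to DNA conversion is a U->T substitution", {
  expect_identical(rna_to_dna("UUGACU"), "TTGACT")
  expect_identical(rna_to_dna("ACGT"), "ACGT")
  x <- "ACGUUGCA"
  expect_identical(chartr("T", "U", rna_to_dna(x)), x)
  expect_error(rna_to_dna("ACGX"), "alphabet")
})

test_that("catalog mapping is exact-only with tie-broken placements", {
  g0 <- generate_genome(1, 2000, seed = 14)[["chr1"]]
  dup <- substr(g0, 301, 322)
  g <- structure(
    c(chr1 = paste0(substr(g0, 1, 900), dup, substr(g0, 923, 2000))),
    class = "ref_genome")                 # dup at 0-based 300 and 900
  idx <- build_index(g, k = 5)
  planted <- substr(g0, 601, 620)
  catalog <- data.frame(
    entry_id = c("oar-miR-1", "decoy-1", "bta-miR-dup"),
    sequence = chartr("T", "U", c(planted, strrep("AC", 10), dup)),
    stringsAsFactors = FALSE)
  m <- map_catalog(idx, g, catalog)
  expect_identical(m$unmapped, "decoy-1")
  one <- m$mapped[m$mapped$entry_id == "oar-miR-1", ]
  expect_equal(one$start, 600)
  expect_equal(one$mismatches, 0)
  d <- m$mapped[m$mapped$entry_id == "bta-miR-dup", ]
  expect_equal(nrow(d), 1)
  expect_equal(d$start, 300)             # tie policy: smallest start
  expect_false(d$is_unique_best)
})

test_that("consolidation applies priority, keeps disjoint loci, and is greedy", {
  base <- data.frame(chrom = "chr1", strand = "+", mismatches = 0,
                     is_unique_best = TRUE, stringsAsFactors = FALSE)
  ## identical placements: sheep-named entry wins over cattle-named
  mapped <- cbind(data.frame(
    entry_id = c("oar-miR-370-3p_R-2", "bta-miR-370"),
    sequence = "A", start = c(100, 100), end = c(122, 122)), base)
  mir <- consolidate_loci(mapped)
  expect_identical(mir$loci$locus_id, "oar-miR-370-3p_R-2")
  expect_setequal(mir$provenance[["oar-miR-370-3p_R-2"]],
                  c("oar-miR-370-3p_R-2", "bta-miR-370"))

  ## disjoint loci are all retained
  mapped2 <- cbind(data.frame(
    entry_id = c("miR-1", "miR-2"), sequence = "A",
    start = c(0, 50), end = c(22, 72)), base)
  expect_equal(nrow(consolidate_loci(mapped2)$loci), 2)

  ## chain A-B-C with equal priority and length: A and C survive
  mapped3 <- cbind(data.frame(
    entry_id = c("miR-a", "miR-b", "miR-c"), sequence = "A",
    start = c(0, 10, 20), end = c(20, 30, 40)), base)
  mir3 <- consolidate_loci(mapped3)
  expect_setequal(mir3$loci$locus_id, c("miR-a", "miR-c"))
  expect_true("miR-b" %in% mir3$provenance[["miR-a"]])

  ## opposite strands may overlap under the strand-aware default
  mapped4 <- cbind(data.frame(
    entry_id = c("miR-f", "miR-r"), sequence = "A",
    start = c(0, 5), end = c(22, 27)),
    data.frame(chrom = "chr1", strand = c("+", "-"), mismatches = 0,
               is_unique_best = TRUE))
  expect_equal(nrow(consolidate_loci(mapped4)$loci), 2)
  expect_equal(nrow(consolidate_loci(mapped4, strand_aware = FALSE)$loci), 1)
})

test_that("species-prefix census parses names and partitions the loci", {
  loci <- data.frame(locus_id = c("bta-miR-22-3p_R+1", "miR-210",
                                  "PC-5p-592_3212", "let-7",
                                  "oar-miR-485-5p", "hsa-miR-335*",
                                  "bta-let-7a-2-p3"),
                     stringsAsFactors = FALSE)
  mir <- structure(list(loci = loci, provenance = list()),
                   class = "mirnome")
  cen <- census_prefixes(mir)
  expect_equal(cen[["bta"]], 2)
  expect_equal(cen[["NONE"]], 2)        # miR-210 and let-7
  expect_equal(cen[["PC"]], 1)
  expect_equal(cen[["oar"]], 1)
  expect_equal(cen[["hsa"]], 1)
  expect_equal(sum(cen), nrow(loci))
  expect_warning(parse_prefix_warn <- ovimirnome:::parse_prefix("??bad"),
                 "OTHER")
  expect_identical(parse_prefix_warn, "OTHER")
})

test_that("miRNome invariants hold on random catalogs", {
  set.seed(99)
  n_ok <- 0
  for (case in 1:40) {
    g <- generate_genome(sample(1:2, 1), 1200, seed = 5000 + case)
    idx <- build_index(g, k = 5)
    catalog <- random_catalog_instance(g, sample(10:30, 1), seed = case)
    catalog <- catalog[!duplicated(catalog$entry_id), , drop = FALSE]
    mir <- build_mirnome(idx, g, catalog)
    l <- mir$loci
    ## pairwise non-overlap per (chrom, strand)
    if (nrow(l) > 1) {
      for (key in unique(paste(l$chrom, l$strand))) {
        sub <- l[paste(l$chrom, l$strand) == key, , drop = FALSE]
        sub <- sub[order(sub$start), , drop = FALSE]
        if (nrow(sub) > 1) {
          expect_true(all(sub$start[-1] >= sub$end[-nrow(sub)]))
        }
      }
    }
    ## permutation invariance of the accepted set
    perm <- catalog[sample(nrow(catalog)), , drop = FALSE]
    mir_p <- build_mirnome(idx, g, perm)
    expect_identical(mir$loci, mir_p$loci)
    ## every accepted locus re-aligns exactly to its own coordinates
    for (i in seq_len(nrow(l))) {
      h <- align_sequence(idx, g, l$sequence[i], 0)
      expect_true(any(h$chrom == l$chrom[i] & h$start == l$start[i] &
                        h$strand == l$strand[i]))
    }
    n_ok <- n_ok + 1
  }
  expect_equal(n_ok, 40)
})
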