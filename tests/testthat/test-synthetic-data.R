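test_that("genome generation honours dimensions and seeds", {
  g <- generate_genome(1, 10000, seed = 7)
  expect_length(g, 1)
  expect_equal(nchar(g[["chr1"]]), 10000)
  expect_true(grepl("^[ACGT]+$", g[["chr1"]]))

  expect_identical(unclass(generate_genome(2, 5000, seed = 7)),
                   unclass(generate_genome(2, 5000, seed = 7)))
  expect_false(identical(generate_genome(2, 5000, seed = 1),
                         generate_genome(2, 5000, seed = 2)))
  expect_error(generate_genome(0, 5000), "n_chrom")
  expect_error(generate_genome(1, 10), "n_chrom")
})

test_that("planted catalogs map back exactly; decoys do not", {
  des <- sim_design(tissues = "lung", n_mirnas = 50, seed = 11)
  g <- generate_genome(2, 5000, seed = 11)

  pc0 <- plant_catalog(g, des, decoy_fraction = 0)
  expect_equal(nrow(pc0$loci), 50)
  expect_equal(nrow(pc0$catalog), 50)
  idx <- build_index(g, k = 5)
  m0 <- map_catalog(idx, g, pc0$catalog)
  expect_length(m0$unmapped, 0)

  pc <- plant_catalog(g, des, decoy_fraction = 0.2)
  m <- map_catalog(idx, g, pc$catalog)
  expect_length(m$unmapped, 10)
  expect_true(all(startsWith(m$unmapped, "decoy-")))

  ## minus-strand loci carry the reverse complement of the genome slice,
  ## and catalog sequences are in the RNA alphabet
  minus <- pc$loci[pc$loci$strand == "-", ]
  expect_gt(nrow(minus), 0)
  for (i in seq_len(min(5, nrow(minus)))) {
    slice <- substr(g[[minus$chrom[i]]], minus$start[i] + 1, minus$end[i])
    expect_identical(minus$sequence[i], revcomp(slice))
  }
  expect_true(all(grepl("^[ACGU]+$", pc$catalog$sequence)))
})

test_that("simulated reads reduce to planted locus sequences after trimming", {
  des <- sim_design(tissues = "lung", groups = c("NT", "Neo"),
                    n_mirnas = 20, de_fraction = 0, mean_libsize = 500,
                    seed = 3)
  g <- generate_genome(1, 4000, seed = 3)
  pc <- plant_catalog(g, des, decoy_fraction = 0)
  fq <- simulate_fastq(pc$loci, des, background_frac = 0, n5_frac = 0.2)
  cfg <- adapter_config(adapter_3p = "TGGAATTCTCGGGTGCCAAGG")
  for (s in names(fq$reads)[1:2]) {
    tr <- size_select(trim_reads(fq$reads[[s]], cfg), cfg)
    expect_true(all(tr$sequence %in% pc$loci$sequence))
    expect_equal(nrow(tr), nrow(fq$reads[[s]]))
  }
  ## byte-identical regeneration under the same seed
  fq2 <- simulate_fastq(pc$loci, des, background_frac = 0, n5_frac = 0.2)
  expect_identical(fq$reads, fq2$reads)
})

test_that("planted fold changes are recovered in expectation from read counts", {
  ## Monte-Carlo over 70 replicates per group (210 samples): a planted
  ## log2FC of 1 for Neo vs NT should double the mean locus read count.
  des <- sim_design(tissues = "lung", groups = c("PT", "NT", "Neo"),
                    replicates_ngs = 70, n_mirnas = 20, de_fraction = 0,
                    effect_log2fc = 1, mean_libsize = 2000, seed = 5)
  g <- generate_genome(1, 4000, seed = 5)
  pc <- plant_catalog(g, des, decoy_fraction = 0)
  truth <- data.frame(locus_id = pc$loci$locus_id[1], tissue = "lung",
                      contrast = "Neo_vs_NT", true_log2fc = 1,
                      stringsAsFactors = FALSE)
  fq <- simulate_fastq(pc$loci, des, truth = truth, background_frac = 0,
                       n5_frac = 0)
  grp <- fq$samples$group[match(colnames(fq$locus_counts),
                                fq$samples$sample_id)]
  cnt <- fq$locus_counts[truth$locus_id, ]
  ratio <- mean(cnt[grp == "Neo"]) / mean(cnt[grp == "NT"])
  expect_gt(ratio, 1.8)
  expect_lt(ratio, 2.2)
  ## the earlier contrast is untouched
  ratio0 <- mean(cnt[grp == "NT"]) / mean(cnt[grp == "PT"])
  expect_gt(ratio0, 0.9)
  expect_lt(ratio0, 1.1)
})

test_that("direct count simulation matches its distributional contract", {
  des0 <- sim_design(tissues = "lung", n_mirnas = 20, de_fraction = 0,
                     seed = 2)
  sim0 <- simulate_counts(des0)
  expect_equal(nrow(sim0$truth), 0)

  ## Poisson limit: dispersion 0 with fixed library sizes gives
  ## variance approximately equal to the mean
  desP <- sim_design(tissues = "lung", groups = c("A", "B"),
                     replicates_ngs = 500, n_mirnas = 10, de_fraction = 0,
                     dispersion = 0, mean_libsize = 50000, seed = 9)
  simP <- simulate_counts(desP, vary_libsize = FALSE)
  cnt <- simP$counts$counts
  ord <- setdiff(rownames(cnt), simP$ref_ids)
  vmr <- apply(cnt[ord, ], 1, stats::var) / rowMeans(cnt[ord, ])
  big <- rowMeans(cnt[ord, ]) > 50
  expect_true(all(abs(vmr[big] - 1) < 0.25))

  ## the designated reference miRNAs have the smallest log2-cpm SD
  desR <- sim_design(tissues = "lung", replicates_ngs = 30, n_mirnas = 50,
                     de_fraction = 0.2, seed = 13)
  simR <- simulate_counts(desR)
  lc <- log2(compute_cpm(simR$counts) + 0.5)
  sds <- apply(lc, 1, stats::sd)
  expect_setequal(names(sort(sds))[1:2], simR$ref_ids)
})

test_that("Ct simulation honours its construction", {
  des <- sim_design(tissues = "lung", replicates_qpcr = 4,
                    n_mirnas = 10, effect_log2fc = 1, seed = 21)
  truth <- data.frame(locus_id = "miR-x", tissue = "lung",
                      contrast = "Neo_vs_NT", true_log2fc = 1,
                      stringsAsFactors = FALSE)
  refs <- c("ref-a", "ref-b")
  ct0 <- simulate_ct(des, truth, refs, targets = c("miR-x", "miR-flat", refs),
                     noise_sd = 0)
  expect_true(all(ct0$ct1 == ct0$ct2 & ct0$ct2 == ct0$ct3))
  ## a no-effect target has identical delta-Ct in every group
  d <- compute_delta_ct(ct0, refs)
  flat <- d[d$mirna_id == "miR-flat", ]
  expect_equal(length(unique(round(flat$delta_ct, 10))), 1)
  ## planted log2FC 1 for Neo vs NT: delta-delta-Ct -1, fold change 2
  fc <- compute_fold_change(d, "lung", "miR-x", c("Neo", "NT"))
  expect_equal(fc$delta_delta_ct, -1)
  expect_equal(fc$fc, 2)
})

test_that("qPCR fold-change recovery from noisy Ct values", {
  des <- sim_design(tissues = "lung", replicates_qpcr = 4, n_mirnas = 10,
                    effect_log2fc = 1, seed = 31)
  truth <- data.frame(locus_id = "miR-x", tissue = "lung",
                      contrast = "Neo_vs_NT", true_log2fc = 1,
                      stringsAsFactors = FALSE)
  refs <- c("ref-a", "ref-b")
  ok <- 0L
  n_rep <- 200L
  for (r in seq_len(n_rep)) {
    des$seed <- 31L + r
    ct <- simulate_ct(des, truth, refs, targets = c("miR-x", refs),
                      noise_sd = 0.2)
    d <- compute_delta_ct(ct, refs)
    fc <- compute_fold_change(d, "lung", "miR-x", c("Neo", "NT"))$fc
    if (fc >= 1.7 && fc <= 2.3) ok <- ok + 1L
  }
  expect_gte(ok / n_rep, 0.9)
})
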