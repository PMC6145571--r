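test_that("TMM factors are unity for identical or purely scaled columns", {
  set.seed(41)
  base <- rnbinom(200, mu = 100, size = 2) + 1
  counts <- cbind(s1 = base, s2 = base, s3 = base)
  rownames(counts) <- paste0("m", 1:200)
  cm <- toy_cm(counts, groups = c("NT", "Neo", "NT"))
  expect_equal(unname(tmm_factors(cm)), rep(1, 3), tolerance = 1e-10)
  ## doubling a column changes its library size, not its composition
  counts2 <- cbind(s1 = base, s2 = base * 2L, s3 = base)
  cm2 <- toy_cm(counts2, groups = c("NT", "Neo", "NT"))
  expect_equal(unname(tmm_factors(cm2)), rep(1, 3), tolerance = 1e-8)
})

test_that("TMM matches the stepwise trimmed weighted-mean oracle", {
  set.seed(43)
  counts <- matrix(rnbinom(400, mu = 80, size = 3) + 1, 100, 4,
                   dimnames = list(paste0("m", 1:100), paste0("s", 1:4)))
  counts[1:5, 2] <- counts[1:5, 2] * 20L   # composition-biased genes
  cm <- toy_cm(counts, groups = c("NT", "NT", "Neo", "Neo"))
  f <- tmm_factors(cm, ref_sample = "s1")
  lib <- colSums(counts)
  raw <- vapply(1:4, function(j) {
    oracle_tmm_pair(counts[, j], counts[, 1], lib[j], lib[1])
  }, numeric(1))
  want <- raw / exp(mean(log(raw)))
  expect_equal(unname(f), unname(want), tolerance = 1e-12)
})

test_that("TMM agrees with the established implementation", {
  skip_if_not_installed("edgeR")
  set.seed(47)
  counts <- matrix(rnbinom(600, mu = 200, size = 2) + 1, 100, 6,
                   dimnames = list(paste0("m", 1:100), paste0("s", 1:6)))
  counts[1:8, 4] <- counts[1:8, 4] * 15L
  cm <- toy_cm(counts)
  f_pkg <- tmm_factors(cm, ref_sample = "s1")
  f_ext <- edgeR::calcNormFactors(counts, method = "TMM", refColumn = 1)
  expect_equal(unname(f_pkg), unname(f_ext), tolerance = 0.02)
})

test_that("log-cpm follows its closed form and scale invariances", {
  counts <- matrix(c(0, 10, 100, 0, 10, 100), 3, 2,
                   dimnames = list(c("a", "b", "c"), c("s1", "s2")))
  cm <- toy_cm(counts, lib_sizes = rep(1e6 - 1, 2))
  expect_warning(vm <- voom_logcpm(cm, factors = c(1, 1),
                                   cyclic_loess = FALSE), "unit weights")
  ## count 0 with lib * factor + 1 = 1e6: log2(0.5) = -1
  expect_equal(vm$logcpm["a", "s1"], -1)
  expect_equal(vm$logcpm["b", "s1"], log2(10.5))
  ## doubling counts and library sizes leaves log-cpm essentially
  ## unchanged (the +0.5/+1 offsets break exactness at low counts)
  set.seed(51)
  big <- matrix(rnbinom(200, mu = 500, size = 5) + 50, 20, 10,
                dimnames = list(paste0("m", 1:20), paste0("s", 1:10)))
  cmA <- toy_cm(big)
  cmB <- toy_cm(big * 2L)
  vA <- voom_logcpm(cmA, cyclic_loess = FALSE)
  vB <- voom_logcpm(cmB, cyclic_loess = FALSE)
  expect_equal(vA$logcpm, vB$logcpm, tolerance = 0.005)
})

test_that("flat mean-variance data yields nearly equal weights", {
  set.seed(53)
  counts <- matrix(rpois(600, lambda = 500), 60, 10,
                   dimnames = list(paste0("m", 1:60), paste0("s", 1:10)))
  cm <- toy_cm(counts)
  vm <- voom_logcpm(cm, cyclic_loess = FALSE)
  expect_true(all(vm$weights > 0))
  expect_lt(stats::sd(vm$weights) / mean(vm$weights), 0.2)
  ## tiny matrices fall back to unit weights with a warning
  expect_warning(small <- voom_logcpm(toy_cm(counts[1:4, ]),
                                      cyclic_loess = FALSE), "unit weights")
  expect_true(all(small$weights == 1))
})

test_that("moderated t collapses to the ordinary t when d0 = 0", {
  set.seed(57)
  n <- 6
  y <- matrix(rnorm(40 * n, mean = 8), 40, n,
              dimnames = list(paste0("m", 1:40), paste0("s", 1:n)))
  w <- matrix(1, 40, n, dimnames = dimnames(y))
  samples <- mk_de_samples(n)
  fit <- fit_moderated_t(y, w, samples, "lung", c("Neo", "NT"),
                         d0_override = 0)
  for (g in c(1, 7, 23)) {
    tt <- stats::t.test(y[g, samples$group == "Neo"],
                        y[g, samples$group == "NT"], var.equal = TRUE)
    expect_equal(fit$t_mod[g], unname(tt$statistic), tolerance = 1e-10)
    expect_equal(fit$p[g], tt$p.value, tolerance = 1e-10)
    expect_equal(fit$log2fc[g], unname(diff(rev(tt$estimate))),
                 tolerance = 1e-10)
  }
})

test_that("moderated t reaches the normal-like limit when d0 = Inf", {
  set.seed(59)
  n <- 6
  y <- matrix(rnorm(30 * n, mean = 8), 30, n,
              dimnames = list(paste0("m", 1:30), paste0("s", 1:n)))
  w <- matrix(1, 30, n, dimnames = dimnames(y))
  samples <- mk_de_samples(n)
  fit <- fit_moderated_t(y, w, samples, "lung", c("Neo", "NT"),
                         d0_override = Inf)
  s0 <- attr(fit, "s0_sq")
  v <- 1 / 3 + 1 / 3                      # contrast variance, 3 vs 3
  expect_equal(fit$t_mod, fit$log2fc / sqrt(s0 * v), tolerance = 1e-10)
  expect_equal(fit$p, 2 * stats::pnorm(-abs(fit$t_mod)), tolerance = 1e-10)
})

test_that("a zero contrast gives t = 0 and p = 1", {
  samples <- mk_de_samples(6)
  ## both groups have mean 6 in gene 1; gene 2 differs
  y <- rbind(m1 = c(5, 6, 7, 7, 6, 5), m2 = c(5, 6, 7, 9, 8, 10))
  colnames(y) <- samples$sample_id
  w <- matrix(1, 2, 6, dimnames = dimnames(y))
  fit <- fit_moderated_t(y, w, samples, "lung", c("Neo", "NT"))
  expect_equal(fit$t_mod[1], 0)
  expect_equal(fit$p[1], 1)
})

test_that("moderated statistics track the established implementation", {
  skip_if_not_installed("limma")
  set.seed(61)
  n <- 6
  y <- matrix(rnorm(200 * n, mean = 8, sd = rep(runif(200, 0.3, 1.5), n)),
              200, n, dimnames = list(paste0("m", 1:200), paste0("s", 1:n)))
  samples <- mk_de_samples(n)
  w <- matrix(1, 200, n, dimnames = dimnames(y))
  fit <- fit_moderated_t(y, w, samples, "lung", c("Neo", "NT"))
  design <- stats::model.matrix(~ 0 + factor(samples$group,
                                             c("NT", "Neo")))
  colnames(design) <- c("NT", "Neo")
  lf <- limma::lmFit(y, design)
  lf <- limma::contrasts.fit(lf, limma::makeContrasts(Neo - NT,
                                                      levels = design))
  eb <- limma::eBayes(lf)
  expect_equal(attr(fit, "d0"), eb$df.prior, tolerance = 0.05)
  expect_equal(attr(fit, "s0_sq"), eb$s2.prior, tolerance = 0.02)
  expect_equal(fit$t_mod, unname(eb$t[, 1]), tolerance = 1e-6)
  expect_equal(fit$p, unname(eb$p.value[, 1]), tolerance = 1e-6)
})

test_that("BH adjustment equals the brute-force step-up definition", {
  expect_equal(bh_adjust(0.05), 0.05)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(63)
  for (i in 1:50) {
    p <- runif(sample(1:40, 1))
    adj <- bh_adjust(p)
    expect_equal(adj, oracle_bh(p), tolerance = 1e-12)
    expect_true(all(adj >= p - 1e-15))
  }
  expect_error(bh_adjust(c(0.1, 1.2)), "\\[0, 1\\]")
})

test_that("the call rule applies strict thresholds and sorts by FDR", {
  res <- data.frame(
    mirna_id = c("a", "b", "c", "d", "e"),
    tissue = "lung",
    ave_log_exp = c(13.670, 1.0, 5, 2, 8),
    log2fc = 1, fc = 2,
    fdr = c(0.022, 0.01, 0.15, 0.149, 0.001),
    stringsAsFactors = FALSE)
  calls <- call_significant(res)
  expect_setequal(calls$mirna_id, c("a", "d", "e"))  # b: ALE == 1; c: FDR == 0.15
  expect_identical(calls$mirna_id, c("e", "a", "d"))  # FDR ascending
  expect_equal(calls$fc, 2^calls$log2fc, tolerance = 1e-12)
})

test_that("null simulations control the type-I error of the moderated test", {
  des <- sim_design(tissues = "lung", groups = c("NT", "Neo"),
                    replicates_ngs = 3, n_mirnas = 200, de_fraction = 0,
                    mean_libsize = 5e5, seed = 100)
  hits <- 0L; total <- 0L; clean_runs <- 0L
  n_rep <- 30L
  for (r in seq_len(n_rep)) {
    des$seed <- 100L + r
    sim <- simulate_counts(des)
    vm <- voom_logcpm(sim$counts, tmm_factors(sim$counts),
                      cyclic_loess = FALSE)
    fit <- fit_moderated_t(vm$logcpm, vm$weights, sim$counts$samples,
                           "lung", c("Neo", "NT"))
    hits <- hits + sum(fit$p < 0.05)
    total <- total + nrow(fit)
    if (!any(bh_adjust(fit$p) < 0.05)) clean_runs <- clean_runs + 1L
  }
  expect_gte(hits / total, 0.02)
  expect_lte(hits / total, 0.09)
  ## BH at 5% on null data almost never declares a discovery
  expect_gte(clean_runs / n_rep, 0.9)
})
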