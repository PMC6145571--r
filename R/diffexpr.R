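#' TMM normalization factors
#'
#' Trimmed mean of M-values between each sample and a reference sample
#' (by default the sample whose cpm upper quartile is closest to the mean
#' upper quartile).  Gene-wise log2 ratios (M) and average log2 abundance
#' (A) are computed over genes with positive counts in both samples;
#' 30% of M values and 5% of A values are trimmed from each tail, and the
#' factor is two to the precision-weighted mean of the remaining M values
#' (inverse asymptotic binomial variances as weights).  Factors are
#' rescaled to geometric mean 1.
#'
#' @param cm a [count_matrix()].
#' @param ref_sample optional reference sample id.
#' @param logratio_trim,abs_expr_trim total trim fractions for M and A.
#' @return named numeric vector of normalization factors.
#' @export
tmm_factors <- function(cm, ref_sample = NULL,
                        logratio_trim = 0.3, abs_expr_trim = 0.05) {
  x <- cm$counts
  lib <- cm$lib_sizes
  if (ncol(x) < 2) err("need at least two samples")
  if (any(colSums(x) == 0)) err("all-zero sample column")
  if (is.null(ref_sample)) {
    f75 <- apply(sweep(x, 2, lib, "/"), 2, stats::quantile, probs = 0.75)
    r <- which.min(abs(f75 - mean(f75)))
  } else {
    r <- match(ref_sample, colnames(x))
    if (is.na(r)) err("unknown reference sample ", ref_sample)
  }
  f <- vapply(seq_len(ncol(x)), function(j) {
    tmm_pair(x[, j], x[, r], lib[j], lib[r],
             logratio_trim, abs_expr_trim)
  }, numeric(1))
  f <- f / exp(mean(log(f)))
  stats::setNames(f, colnames(x))
}

## One TMM factor: sample obs against reference ref.
tmm_pair <- function(obs, ref, n_obs, n_ref,
                     logratio_trim, abs_expr_trim) {
  fin <- obs > 0 & ref > 0
  if (!any(fin)) err("sample shares no expressed genes with the reference")
  obs <- obs[fin]; ref <- ref[fin]
  m <- log2((obs / n_obs) / (ref / n_ref))
  a <- 0.5 * log2((obs / n_obs) * (ref / n_ref))
  w <- (n_obs - obs) / (n_obs * obs) + (n_ref - ref) / (n_ref * ref)
  n <- length(m)
  ## trim fractions apply to each tail (classic trimmed-mean convention)
  lo_m <- floor(n * logratio_trim) + 1
  hi_m <- n + 1 - lo_m
  lo_a <- floor(n * abs_expr_trim) + 1
  hi_a <- n + 1 - lo_a
  keep <- rank(m) >= lo_m & rank(m) <= hi_m &
    rank(a) >= lo_a & rank(a) <= hi_a
  if (!any(keep)) return(1)
  f <- sum(m[keep] / w[keep]) / sum(1 / w[keep])
  if (!is.finite(f) || abs(f) < 1e-10) f <- 0
  2^f
}

## Cyclic pairwise local-regression normalization of a log-expression
## matrix: for each ordered sample pair, the loess trend of M on A is
## split evenly between the two samples.
cyclic_loess_normalize <- function(y, span = 0.5, iterations = 1) {
  n <- ncol(y)
  for (it in seq_len(iterations)) {
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        m <- y[, j] - y[, i]
        a <- (y[, j] + y[, i]) / 2
        lw <- stats::lowess(a, m, f = span)
        fit <- stats::approx(lw$x, lw$y, xout = a, rule = 2,
                             ties = mean)$y
        y[, j] <- y[, j] - fit / 2
        y[, i] <- y[, i] + fit / 2
      }
    }
  }
  y
}

#' Log-cpm transformation with precision weights
#'
#' Computes `log2((counts + 0.5) / (lib_size * factor + 1) * 1e6)`,
#' optionally applies cyclic pairwise loess normalization across samples,
#' fits the mean-variance trend (local regression of the square root of
#' per-gene residual standard deviation on average log2 count under the
#' group-means model), and converts the predicted standard deviation of
#' each observation into an inverse-variance weight.
#'
#' @param cm a [count_matrix()].
#' @param factors normalization factors from [tmm_factors()]; unit
#'   factors when `NULL`.
#' @param design model matrix for the residual fit; defaults to the
#'   tissue-by-group cell-means model from the sample sheet.
#' @param span local-regression span.
#' @param cyclic_loess apply cyclic loess normalization (default `TRUE`).
#' @return list with `logcpm` and strictly positive `weights`, both
#'   miRNA x sample, plus the `design` used.
#' @export
voom_logcpm <- function(cm, factors = NULL, design = NULL, span = 0.5,
                        cyclic_loess = TRUE) {
  if (is.null(factors)) factors <- rep(1, ncol(cm$counts))
  stopifnot(length(factors) == ncol(cm$counts), all(factors > 0))
  lib <- cm$lib_sizes * factors
  logcpm <- log2(sweep(cm$counts + 0.5, 2, lib + 1, "/") * 1e6)
  if (cyclic_loess) logcpm <- cyclic_loess_normalize(logcpm, span = span)
  if (is.null(design)) {
    cell <- interaction(cm$samples$tissue, cm$samples$group, drop = TRUE)
    design <- stats::model.matrix(~ 0 + cell)
  }
  G <- nrow(logcpm)
  if (G < 10) {
    warning("fewer than 10 miRNAs: mean-variance trend unreliable, ",
            "using unit weights", call. = FALSE)
    w <- matrix(1, G, ncol(logcpm), dimnames = dimnames(logcpm))
    return(list(logcpm = logcpm, weights = w, design = design))
  }
  fit <- stats::lm.fit(design, t(logcpm))
  df_resid <- nrow(design) - fit$rank
  if (df_resid < 1) {
    warning("no residual degrees of freedom: using unit weights",
            call. = FALSE)
    w <- matrix(1, G, ncol(logcpm), dimnames = dimnames(logcpm))
    return(list(logcpm = logcpm, weights = w, design = design))
  }
  sigma <- sqrt(colSums(as.matrix(fit$residuals)^2) / df_resid)
  sx <- rowMeans(logcpm) + mean(log2(lib + 1)) - log2(1e6)
  sy <- sqrt(sigma)
  lw <- stats::lowess(sx, sy, f = span)
  trend <- stats::approxfun(lw$x, lw$y, rule = 2, ties = mean)
  fitted_logcount <- t(as.matrix(fit$fitted.values)) +
    matrix(log2(lib + 1), G, ncol(logcpm), byrow = TRUE) - log2(1e6)
  pred_sqrt_sd <- pmax(trend(fitted_logcount), 1e-3)
  w <- matrix(1 / pred_sqrt_sd^4, G, ncol(logcpm),
              dimnames = dimnames(logcpm))
  list(logcpm = logcpm, weights = w, design = design)
}

## Newton inversion of the trigamma function (for the prior df fit).
trigamma_inverse <- function(y) {
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (i in 1:50) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, 2)
    x <- x + dif
    if (abs(dif) / x < 1e-8) break
  }
  x
}

## Empirical-Bayes hyperparameters (d0, s0_sq) of the scaled-F model for
## residual variances, by moment matching on log variances.  With
## robust = TRUE the most extreme variances are trimmed symmetrically
## before matching.
fit_f_dist <- function(s2, df, robust = FALSE, trim = 0.1) {
  ok <- is.finite(s2) & s2 > 0 & df > 0
  s2 <- s2[ok]; df <- rep_len(df, length(ok))[ok]
  if (length(s2) < 2) return(list(d0 = Inf, s0_sq = mean(s2)))
  if (robust) {
    qs <- stats::quantile(s2, c(trim / 2, 1 - trim / 2))
    keep <- s2 >= qs[1] & s2 <= qs[2]
    s2 <- s2[keep]; df <- df[keep]
  }
  z <- log(s2)
  e <- z - digamma(df / 2) + log(df / 2)
  emean <- mean(e)
  evar <- stats::var(e) - mean(trigamma(df / 2))
  if (is.finite(evar) && evar > 0) {
    d0 <- 2 * trigamma_inverse(evar)
    s0_sq <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  } else {
    d0 <- Inf
    s0_sq <- exp(emean)
  }
  list(d0 = d0, s0_sq = s0_sq)
}

#' Moderated t-tests within one tissue
#'
#' Fits, per miRNA, a weighted least-squares group-means model on the
#' tissue's samples, shrinks the residual variances toward a common prior
#' via empirical Bayes (prior degrees of freedom `d0` and prior variance
#' `s0_sq` estimated by moment matching of the scaled-F distribution of
#' the variances), and tests the `contrast[1] - contrast[2]` group
#' difference with a t-statistic on `d0 + residual df` degrees of
#' freedom.
#'
#' @param logcpm,weights matrices from [voom_logcpm()] (all samples).
#' @param samples sample sheet matching the columns.
#' @param tissue tissue to analyse.
#' @param contrast character pair `c(group_b, group_a)`: the estimate is
#'   mean(group_b) - mean(group_a) on the log2 scale.
#' @param d0_override force the prior df: `0` gives the ordinary
#'   (unmoderated) weighted t-test, `Inf` the large-prior normal-like
#'   limit.
#' @param robust trim extreme variances before moment matching.
#' @return data.frame (one row per miRNA): mirna_id, tissue, contrast,
#'   log2fc, fc, ave_log_exp, t_mod, p; hyperparameters in attributes
#'   `d0` and `s0_sq`.
#' @export
fit_moderated_t <- function(logcpm, weights, samples, tissue,
                            contrast, d0_override = NULL, robust = FALSE) {
  stopifnot(length(contrast) == 2)
  sel <- samples$tissue == tissue
  if (!any(sel)) err("no samples for tissue ", tissue)
  y_all <- logcpm[, sel, drop = FALSE]
  w_all <- weights[, sel, drop = FALSE]
  grp <- factor(samples$group[sel])
  if (!all(contrast %in% levels(grp))) {
    err("contrast groups absent in tissue ", tissue, ": ",
        paste(setdiff(contrast, levels(grp)), collapse = ", "))
  }
  if (any(table(grp)[contrast] < 2)) {
    err("need >= 2 samples per contrasted group in tissue ", tissue)
  }
  X <- stats::model.matrix(~ 0 + grp)
  colnames(X) <- levels(grp)
  if (qr(X)$rank < ncol(X)) err("singular design in tissue ", tissue)
  cvec <- stats::setNames(rep(0, ncol(X)), colnames(X))
  cvec[contrast[1]] <- 1
  cvec[contrast[2]] <- -1
  G <- nrow(y_all)
  est <- v <- s2 <- numeric(G)
  df_resid <- nrow(X) - ncol(X)
  for (g in seq_len(G)) {
    w <- w_all[g, ]
    xtwx <- crossprod(X, w * X)
    xtwxi <- solve(xtwx)
    beta <- xtwxi %*% crossprod(X, w * y_all[g, ])
    res <- y_all[g, ] - as.vector(X %*% beta)
    est[g] <- sum(cvec * beta)
    v[g] <- as.numeric(t(cvec) %*% xtwxi %*% cvec)
    s2[g] <- sum(w * res^2) / df_resid
  }
  if (is.null(d0_override)) {
    eb <- fit_f_dist(s2, df_resid, robust = robust)
    d0 <- eb$d0; s0_sq <- eb$s0_sq
  } else {
    d0 <- d0_override
    s0_sq <- fit_f_dist(s2, df_resid, robust = robust)$s0_sq
  }
  s2_post <- if (is.infinite(d0)) rep(s0_sq, G) else
    (d0 * s0_sq + df_resid * s2) / (d0 + df_resid)
  t_mod <- est / sqrt(s2_post * v)
  t_mod[est == 0 & !is.finite(t_mod)] <- 0   # 0/0 when a variance is 0
  df_total <- d0 + df_resid
  p <- 2 * stats::pt(-abs(t_mod), df = df_total)
  p[est == 0] <- 1
  out <- data.frame(
    mirna_id = rownames(y_all),
    tissue = tissue,
    contrast = paste0(contrast[1], "_vs_", contrast[2]),
    log2fc = est, fc = 2^est,
    ave_log_exp = rowMeans(y_all),
    t_mod = t_mod, p = p,
    stringsAsFactors = FALSE)
  attr(out, "d0") <- d0
  attr(out, "s0_sq") <- s0_sq
  rownames(out) <- NULL
  out
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment, returned in the input order.
#'
#' @param pvals numeric vector of p-values in \[0, 1\].
#' @return adjusted p-values.
#' @export
bh_adjust <- function(pvals) {
  check_prob(pvals, "p-values")
  stats::p.adjust(pvals, method = "BH")
}

#' Apply the significance call rule
#'
#' Retains results with `fdr < fdr_max` (strict) and
#' `ave_log_exp > ave_log_exp_min` (strict), sorted by FDR ascending
#' within tissue.
#'
#' @param results data.frame with at least `tissue`, `fdr`,
#'   `ave_log_exp`.
#' @param fdr_max FDR threshold (exclusive).
#' @param ave_log_exp_min average log2-cpm threshold (exclusive).
#' @return the retained rows, re-sorted.
#' @export
call_significant <- function(results, fdr_max = 0.15,
                             ave_log_exp_min = 1.0) {
  keep <- results$fdr < fdr_max & results$ave_log_exp > ave_log_exp_min
  out <- results[keep, , drop = FALSE]
  tiss <- factor(out$tissue, levels = unique(results$tissue))
  out <- out[order(tiss, out$fdr), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Full differential-expression analysis
#'
#' TMM normalization across all samples, precision-weighted log-cpm, then
#' moderated t-tests per tissue for each consecutive-group contrast, with
#' BH adjustment performed separately per (tissue, contrast) family.
#'
#' @param cm a filtered [count_matrix()].
#' @param groups ordered group labels (earliest first); defaults to the
#'   order of first appearance in the sample sheet.
#' @param tissues tissues to analyse (default: all).
#' @param robust trim extreme variances in the empirical-Bayes step.
#' @param cyclic_loess passed to [voom_logcpm()].
#' @return data.frame of all per-miRNA results with an `fdr` column;
#'   the log-cpm matrix is attached as attribute `logcpm`.
#' @export
run_de <- function(cm, groups = NULL, tissues = NULL, robust = FALSE,
                   cyclic_loess = TRUE) {
  if (is.null(groups)) groups <- unique(cm$samples$group)
  if (is.null(tissues)) tissues <- unique(cm$samples$tissue)
  factors <- tmm_factors(cm)
  vm <- voom_logcpm(cm, factors, cyclic_loess = cyclic_loess)
  res <- list()
  for (ti in tissues) {
    for (j in seq_len(length(groups) - 1)) {
      fit <- fit_moderated_t(vm$logcpm, vm$weights, cm$samples, ti,
                             contrast = c(groups[j + 1], groups[j]),
                             robust = robust)
      fit$fdr <- bh_adjust(fit$p)
      res[[paste(ti, j)]] <- fit
    }
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  attr(out, "logcpm") <- vm$logcpm
  out
}
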