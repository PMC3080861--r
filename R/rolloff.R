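#' Frequency-difference SNP weights
#'
#' The per-SNP weight used by the admixture-LD dating method: with `a`,
#' `b` the empirical allele frequencies in two populations close to the
#' mixing sources and `p = (a + b) / 2`,
#' `w = (a - b) / sqrt(p (1 - p))`. The weight is positive when the
#' allele is more frequent on the `a` side, negative on the `b` side, and
#' undefined (`NA`) when `p` is 0 or 1. When no surrogate source
#' populations with trustworthy absolute frequencies are available the
#' unnormalised difference `w = a - b` remains useful
#' (`normalize = FALSE`).
#'
#' @param a,b Allele-frequency vectors in the two reference populations.
#' @param normalize Divide by `sqrt(p(1-p))` (default `TRUE`).
#' @return Numeric weight vector; `NA` where undefined.
#' @export
snp_weights <- function(a, b, normalize = TRUE) {
  stopifnot(length(a) == length(b))
  if (!normalize) return(a - b)
  p <- (a + b) / 2
  w <- (a - b) / sqrt(p * (1 - p))
  w[!is.na(p) & (p <= 0 | p >= 1)] <- NA_real_
  w
}

#' Pairwise LD score for one SNP pair
#'
#' The signed, approximately standard-normal LD score between two SNPs:
#' the Pearson correlation `r` of the diploid genotype values over the
#' `N` samples non-missing at both markers, clipped to \[-0.9, 0.9\],
#' Fisher z-transformed and variance-stabilised:
#' `z = atanh(r_clipped) * sqrt(N - 3)`. Pairs with `N < 4` or a constant
#' genotype vector are skipped.
#'
#' This scalar form documents the score and serves as a readable
#' reference; [rolloff_date()] computes the same quantity for all pairs
#' with vectorised linear algebra.
#'
#' @param g1,g2 Integer genotype vectors (0/1/2, `NA` missing) at the two
#'   SNPs, over the same samples.
#' @return A one-row tibble with `n`, `r`, `z` and `skipped`; `r` and `z`
#'   are `NA` when the pair is skipped.
#' @export
pair_ld_score <- function(g1, g2) {
  stopifnot(length(g1) == length(g2))
  ok <- !is.na(g1) & !is.na(g2)
  n <- sum(ok)
  if (n < 4 || sd(g1[ok]) == 0 || sd(g2[ok]) == 0) {
    return(tibble(n = n, r = NA_real_, z = NA_real_, skipped = TRUE))
  }
  r <- cor(g1[ok], g2[ok])
  z <- atanh(pmin(pmax(r, -0.9), 0.9)) * sqrt(n - 3)
  tibble(n = n, r = r, z = z, skipped = FALSE)
}

#' Bin SNP-pair scores by genetic distance
#'
#' Assigns pairs to half-open uniform distance bins
#' `[k * bin_cm, (k+1) * bin_cm)` and computes, per bin, the Pearson
#' correlation between the LD score `z` and the weight product `ww`
#' across the pairs it contains. Bins with fewer than 2 pairs are
#' reported with `corr = NA`.
#'
#' @param pairs Tibble with columns `d_cm` (genetic separation in cM,
#'   > 0), `z` (LD score) and `ww` (weight product).
#' @param bin_cm Bin width in centimorgans (default 0.1); simulations
#'   show bins need to be at least 0.05 cM, below which very short
#'   inter-SNP intervals let background LD in.
#' @param max_cm Maximum separation retained (default 30).
#' @return Tibble with `bin_cm` (bin midpoint), `corr`, `n_pairs`.
#' @export
bin_pairs <- function(pairs, bin_cm = 0.1, max_cm = 30) {
  if (bin_cm <= 0) abort("bin_cm must be > 0")
  keep <- !is.na(pairs$z) & !is.na(pairs$ww) & pairs$d_cm > 0 & pairs$d_cm <= max_cm
  d <- pairs$d_cm[keep]; z <- pairs$z[keep]; ww <- pairs$ww[keep]
  n_bins <- ceiling(max_cm / bin_cm)
  b <- pmin(floor(d / bin_cm) + 1L, n_bins)
  b[d >= n_bins * bin_cm] <- NA # half-open upper edge
  acc <- matrix(0, n_bins, 6)
  ok <- !is.na(b)
  if (any(ok)) {
    acc[sort(unique(b[ok])), ] <- rowsum(
      cbind(1, z[ok], ww[ok], z[ok]^2, ww[ok]^2, z[ok] * ww[ok]), b[ok]
    )
  }
  bins_from_acc(acc, bin_cm)
}

# acc: n_bins x 6 matrix of per-bin sums (n, sz, sw, szz, sww, szw)
bins_from_acc <- function(acc, bin_cm) {
  n <- acc[, 1]
  cov_zw <- n * acc[, 6] - acc[, 2] * acc[, 3]
  var_z <- n * acc[, 4] - acc[, 2]^2
  var_w <- n * acc[, 5] - acc[, 3]^2
  corr <- ifelse(n >= 2 & var_z > 0 & var_w > 0,
                 cov_zw / sqrt(var_z * var_w), NA_real_)
  tibble(
    bin_cm = (seq_len(nrow(acc)) - 0.5) * bin_cm,
    corr = corr,
    n_pairs = as.integer(n)
  )
}

#' Fit an exponential to the decay of binned LD correlation
#'
#' Least-squares fit of `corr(d) = A * exp(-n * d)` to the binned
#' correlation curve, with `d` in Morgans so that the fitted rate `n` is
#' the admixture date in generations. Starting values come from a
#' log-linear regression on the positive bins; the fit itself is
#' unweighted Levenberg-Marquardt least squares (optionally weighted by
#' pair counts). Bins closer than `min_cm` are excluded: at such short
#' ranges admixture LD is confounded by background LD.
#'
#' By default the model carries an additive constant,
#' `corr(d) = A exp(-n d) + c`: a cohort of finitely many admixed
#' individuals whose ancestry fractions differ shows a small
#' distance-independent baseline correlation (every pair of SNPs covaries
#' through individual ancestry), and without the constant the fitted rate
#' is biased downward for recent events. Set `offset = FALSE` for the
#' pure exponential.
#'
#' @param bins Tibble from [bin_pairs()] (`bin_cm`, `corr`, `n_pairs`).
#' @param min_cm,max_cm Fit window in centimorgans (defaults 0.5 and 30).
#' @param weight_by_pairs Weight bins by `n_pairs` in the least squares
#'   (default `FALSE`).
#' @param offset Include the constant term `c` (default `TRUE`).
#' @return List with `n` (generations), `amplitude`, `n_bins_used`, and
#'   `offset` when fitted. Errors with "no detectable admixture LD
#'   decay" when the fit fails, the fitted rate is not positive, or the
#'   amplitude is not distinguishable from zero.
#' @export
fit_exponential <- function(bins, min_cm = 0.5, max_cm = 30,
                            weight_by_pairs = FALSE, offset = TRUE) {
  use <- !is.na(bins$corr) & bins$n_pairs >= 2 &
    bins$bin_cm >= min_cm & bins$bin_cm <= max_cm
  if (sum(use) < 5) abort("fewer than 5 usable bins in the fit window")
  d <- bins$bin_cm[use] / 100 # Morgans
  y <- bins$corr[use]
  if (sd(y) == 0) abort("no detectable admixture LD decay")
  wts <- if (weight_by_pairs) bins$n_pairs[use] else rep(1, length(y))
  # log-linear start on positive bins
  pos <- y > 0
  start <- if (sum(pos) >= 3) {
    sl <- lm(log(y[pos]) ~ d[pos])
    list(A = exp(unname(coef(sl)[1])), n = max(-unname(coef(sl)[2]), 1))
  } else {
    list(A = max(abs(y)), n = 1 / stats::median(d))
  }
  par <- fit_decay_ls(d, y, wts, start, offset)
  if (is.null(par)) abort("no detectable admixture LD decay")
  if (!is.finite(par["n"]) || par["n"] <= 0 || par["A"] <= 0) {
    abort("no detectable admixture LD decay")
  }
  # a real decay must have an amplitude the bins can resolve
  se_a <- amplitude_se(par, d, y, wts, offset)
  if (is.finite(se_a) && se_a > 0 && par["A"] < 2 * se_a) {
    abort("no detectable admixture LD decay")
  }
  est <- par
  out <- list(n = unname(est["n"]), amplitude = unname(est["A"]),
              n_bins_used = length(y))
  if (offset) out$offset <- unname(est["c0"])
  out
}

# Weighted least squares for A exp(-n d) (+ c0): Levenberg-Marquardt,
# falling back to port-algorithm nls and then to a direct quasi-Newton
# minimisation of the weighted residual sum of squares (the latter copes
# with the degenerate zero-residual case).
fit_decay_ls <- function(d, y, wts, start, offset) {
  form <- if (offset) y ~ A * exp(-n * d) + c0 else y ~ A * exp(-n * d)
  st <- if (offset) c(start, c0 = 0) else start
  dat <- data.frame(d = d, y = y)
  f1 <- tryCatch(
    coef(minpack.lm::nlsLM(form, data = dat, start = st, weights = wts,
                           control = minpack.lm::nls.lm.control(maxiter = 200))),
    error = function(e) NULL
  )
  if (!is.null(f1)) return(f1)
  f2 <- tryCatch(
    coef(nls(form, data = dat, start = st, weights = wts,
             algorithm = "port",
             control = stats::nls.control(maxiter = 200, warnOnly = FALSE))),
    error = function(e) NULL
  )
  if (!is.null(f2)) return(f2)
  ssr <- function(p) {
    mu <- p[1] * exp(-p[2] * d) + if (offset) p[3] else 0
    sum(wts * (y - mu)^2)
  }
  p0 <- unlist(st)
  opt <- tryCatch(stats::optim(p0, ssr, method = "BFGS",
                               control = list(maxit = 500)),
                  error = function(e) NULL)
  if (is.null(opt)) return(NULL)
  out <- opt$par
  names(out) <- names(p0)
  names(out)[1:2] <- c("A", "n")
  out
}

# Asymptotic standard error of the amplitude from the weighted Jacobian.
amplitude_se <- function(par, d, y, wts, offset) {
  e <- exp(-par[["n"]] * d)
  jac <- cbind(A = e, n = -par[["A"]] * d * e)
  if (offset) jac <- cbind(jac, c0 = 1)
  mu <- par[["A"]] * e + if (offset) par[["c0"]] else 0
  dof <- length(y) - ncol(jac)
  if (dof <= 0) return(NA_real_)
  sigma2 <- sum(wts * (y - mu)^2) / dof
  jtj <- crossprod(jac * sqrt(wts))
  vc <- tryCatch(solve(jtj), error = function(e) NULL)
  if (is.null(vc)) return(NA_real_)
  sqrt(sigma2 * vc["A", "A"])
}

#' Fit a sum of two exponentials to the binned LD correlation
#'
#' Experimental: `corr(d) = A1 exp(-n1 d) + A2 exp(-n2 d) + c`, for
#' probing double-admixture histories. Fitting sums of exponentials to
#' noisy data is notoriously ill-conditioned, and this routine is a
#' diagnostic, not a dating method — the single-exponential
#' [fit_exponential()] remains the supported estimator.
#'
#' @inheritParams fit_exponential
#' @param start_rates Starting values for the two rates (generations);
#'   default `c(5, 50)`.
#' @return List with `rates` (sorted ascending), `amplitudes`, `offset`,
#'   `n_bins_used`; errors when the fit fails or either rate is not
#'   positive.
#' @export
fit_two_exponentials <- function(bins, min_cm = 0.5, max_cm = 30,
                                 start_rates = c(5, 50)) {
  use <- !is.na(bins$corr) & bins$n_pairs >= 2 &
    bins$bin_cm >= min_cm & bins$bin_cm <= max_cm
  if (sum(use) < 7) abort("fewer than 7 usable bins in the fit window")
  d <- bins$bin_cm[use] / 100
  y <- bins$corr[use]
  a0 <- max(y, 0.01)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ A1 * exp(-n1 * d) + A2 * exp(-n2 * d) + c0,
      start = list(A1 = a0 / 2, n1 = start_rates[1],
                   A2 = a0 / 2, n2 = start_rates[2], c0 = 0),
      control = minpack.lm::nls.lm.control(maxiter = 500)
    ),
    error = function(e) NULL
  )
  if (is.null(fit)) abort("two-exponential fit failed to converge")
  est <- coef(fit)
  rates <- c(est["n1"], est["n2"])
  amps <- c(est["A1"], est["A2"])
  if (any(!is.finite(rates)) || any(rates <= 0)) {
    abort("two-exponential fit failed (non-positive rate)")
  }
  ord <- order(rates)
  list(rates = unname(rates[ord]), amplitudes = unname(amps[ord]),
       offset = unname(est["c0"]), n_bins_used = length(y))
}

# Streaming per-chromosome accumulation of (n, sum z, sum ww, sum z^2,
# sum ww^2, sum z*ww) over all within-chromosome SNP pairs with genetic
# separation in (0, d_max]. Returns a list of n_bins x 6 matrices, one
# per chromosome, plus per-chromosome usable-SNP counts. Pairs are
# enumerated in chunks against a sliding window so memory stays bounded;
# with complete data the correlations come from one BLAS crossprod of the
# standardised genotype matrix.
rolloff_accumulate <- function(geno, chrom, gpos, w, bin_m, d_max_m,
                               chunk = 512L) {
  n_bins <- ceiling(round(d_max_m / bin_m, 9))
  chroms <- unique(chrom)
  acc <- list()
  snp_counts <- integer(length(chroms))
  names(snp_counts) <- as.character(chroms)
  for (ci in seq_along(chroms)) {
    ch <- chroms[ci]
    idx <- which(chrom == ch & !is.na(w) & !is.na(gpos))
    idx <- idx[order(gpos[idx])]
    snp_counts[ci] <- length(idx)
    a <- matrix(0, n_bins, 6)
    if (length(idx) >= 2) {
      a <- rolloff_chrom_acc(geno[idx, , drop = FALSE], gpos[idx], w[idx],
                             bin_m, d_max_m, n_bins, chunk)
    }
    acc[[as.character(ch)]] <- a
  }
  list(acc = acc, snp_counts = snp_counts)
}

rolloff_chrom_acc <- function(g, pos, w, bin_m, d_max_m, n_bins, chunk) {
  storage.mode(g) <- "integer"
  .rolloff_chrom_acc_cpp(g, as.numeric(pos), as.numeric(w), bin_m, d_max_m,
                         as.integer(n_bins))
}

#' Date an admixture event from the decay of admixture LD
#'
#' The full dating pipeline: per-SNP frequency-difference weights from
#' two reference populations ([snp_weights()]), Fisher-transformed
#' pairwise genotype LD scores in the target population across all
#' within-chromosome SNP pairs, binning of the score-by-weight-product
#' correlation by genetic distance, and a least-squares exponential fit
#' whose rate is the number of generations since mixture. The standard
#' error is a weighted jackknife over chromosomes: the fit is repeated
#' leaving each chromosome out, weighting each run by the number of SNPs
#' excluded.
#'
#' @param x Target genotypes: an `admix_geno`/`admix_cohort` object, or a
#'   SNP-by-individual genotype matrix (then supply `snp`).
#' @param ref_freqs Long frequency table (as from [allele_frequencies()]
#'   or [sample_pool_freqs()]) holding the two reference populations.
#' @param ref_a,ref_b Labels of the reference populations within
#'   `ref_freqs` (defaults `"A"` and `"B"`).
#' @param snp SNP tibble (`snp_id`, `chrom`, `genetic_pos` in Morgans);
#'   taken from `x` when `x` is an `admix_geno` object.
#' @param bin_cm Distance bin width in cM (default 0.1).
#' @param min_cm Smallest inter-SNP distance used in the exponential fit
#'   (default 0.5 cM); shorter pairs are binned but excluded from the fit
#'   because background LD confounds them.
#' @param max_cm Largest inter-SNP distance considered (default 30 cM).
#' @param normalize_weights Use the variance-normalised weight (default
#'   `TRUE`); see [snp_weights()].
#' @param jackknife Compute the delete-one-chromosome standard error
#'   (default `TRUE`).
#' @param weight_by_pairs,offset Passed to [fit_exponential()]; the
#'   default fit includes an additive constant absorbing the
#'   finite-cohort baseline correlation (see [fit_exponential()]).
#' @return An object of class `rolloff_date`: a list with `date`
#'   (generations), `se`, `amplitude`, `bins` (the binned decay curve for
#'   plotting), `loo` (leave-one-chromosome-out dates and weights),
#'   `n_snps_used`, `fit_range_cm` and the configuration. Supports
#'   [print()], [generics::tidy()], [generics::glance()] and
#'   [ggplot2::autoplot()].
#' @export
rolloff_date <- function(x, ref_freqs, ref_a = "A", ref_b = "B", snp = NULL,
                         bin_cm = 0.1, min_cm = 0.5, max_cm = 30,
                         normalize_weights = TRUE, jackknife = TRUE,
                         weight_by_pairs = FALSE, offset = TRUE) {
  if (is.list(x) && !is.null(x$geno)) {
    snp <- snp %||% x$snp
    geno <- x$geno
  } else {
    geno <- x
    if (is.null(snp)) abort("supply `snp` when `x` is a bare genotype matrix")
  }
  stopifnot(nrow(geno) == nrow(snp))
  fa <- ref_freqs[ref_freqs$population == ref_a, ]
  fb <- ref_freqs[ref_freqs$population == ref_b, ]
  if (!nrow(fa) || !nrow(fb)) {
    abort("reference population(s) absent from ref_freqs")
  }
  a <- fa$p[match(snp$snp_id, fa$snp_id)]
  b <- fb$p[match(snp$snp_id, fb$snp_id)]
  w <- snp_weights(a, b, normalize = normalize_weights)
  if (length(unique(snp$chrom)) < 2 && jackknife) {
    abort("need >= 2 chromosomes for the chromosome jackknife")
  }
  bin_m <- bin_cm / 100
  d_max_m <- max_cm / 100
  st <- rolloff_accumulate(geno, snp$chrom, snp$genetic_pos, w, bin_m, d_max_m)
  total <- Reduce(`+`, st$acc)
  bins <- bins_from_acc(total, bin_cm)
  fit <- fit_exponential(bins, min_cm = min_cm, max_cm = max_cm,
                         weight_by_pairs = weight_by_pairs, offset = offset)
  loo <- NULL
  se <- NA_real_
  if (jackknife) {
    jd <- jackknife_date(st, fit$n, bin_cm, min_cm, max_cm,
                         weight_by_pairs, offset)
    loo <- jd$loo
    se <- jd$se
  }
  structure(
    list(
      date = fit$n, se = se, amplitude = fit$amplitude,
      offset = fit$offset, bins = bins, loo = loo,
      n_snps_used = sum(st$snp_counts),
      snps_per_chrom = st$snp_counts,
      fit_range_cm = c(min_cm, max_cm), bin_cm = bin_cm,
      n_bins_used = fit$n_bins_used,
      references = c(ref_a = ref_a, ref_b = ref_b)
    ),
    class = "rolloff_date"
  )
}

# Weighted delete-one-chromosome jackknife of the fitted date. Each
# leave-one-out fit reuses the streaming accumulators (total minus the
# dropped chromosome); runs whose fit fails are excluded with a warning.
jackknife_date <- function(st, full_date, bin_cm, min_cm, max_cm,
                           weight_by_pairs = FALSE, offset = FALSE) {
  chroms <- names(st$acc)
  if (length(chroms) < 2) abort("need >= 2 chromosomes for the chromosome jackknife")
  total <- Reduce(`+`, st$acc)
  loo <- purrr::map(chroms, function(ch) {
    bins <- bins_from_acc(total - st$acc[[ch]], bin_cm)
    date <- tryCatch(
      fit_exponential(bins, min_cm = min_cm, max_cm = max_cm,
                      weight_by_pairs = weight_by_pairs, offset = offset)$n,
      error = function(e) NA_real_
    )
    tibble(chrom = ch, date = date, weight = st$snp_counts[[ch]])
  }) %>% bind_rows()
  bad <- !is.finite(loo$date)
  if (any(bad)) {
    warn(paste0("leave-one-out fit failed for chromosome(s) ",
                paste(loo$chrom[bad], collapse = ", "), "; excluded"))
  }
  ok <- loo[!bad & loo$weight > 0, ]
  if (nrow(ok) < 2) abort("fewer than 2 successful jackknife runs")
  list(se = busing_jackknife_se(full_date, ok$date, ok$weight), loo = loo)
}

#' @export
print.rolloff_date <- function(x, ...) {
  cat(sprintf(
    "Admixture date: %.1f +/- %.1f generations (amplitude %.4g; %d SNPs, fit %g-%g cM)\n",
    x$date, x$se, x$amplitude, x$n_snps_used,
    x$fit_range_cm[1], x$fit_range_cm[2]
  ))
  invisible(x)
}

#' @method tidy rolloff_date
#' @export
tidy.rolloff_date <- function(x, ...) {
  dplyr::mutate(x$bins,
                fitted = x$amplitude * exp(-x$date * .data$bin_cm / 100) +
                  (x$offset %||% 0))
}

#' @method glance rolloff_date
#' @export
glance.rolloff_date <- function(x, ...) {
  tibble(
    date = x$date, se = x$se, amplitude = x$amplitude,
    n_snps = x$n_snps_used, n_bins_used = x$n_bins_used,
    min_cm = x$fit_range_cm[1], max_cm = x$fit_range_cm[2]
  )
}

#' Simulation-based bias estimate for an admixture date
#'
#' The dating estimator is biased upward when the signal is weak (old
#' dates, small mixture proportions, few samples). This mirrors the
#' matched-simulation correction: simulate the fitted scenario many
#' times, date each replicate, and report
#' `bias = mean(estimated dates) - true date`; a corrected date is then
#' `estimate - bias`.
#'
#' @param theta Mixture proportion (pool-A ancestry) used in the
#'   replicates.
#' @param lambda True date in generations used in the replicates.
#' @param n_diploid Number of admixed diploids per replicate.
#' @param estimate Observed date to correct (optional; `corrected_date`
#'   is `NA` without it).
#' @param n_replicates Number of simulation replicates (default 100).
#' @param pool_args List of arguments for [generate_ancestral_pools()]
#'   (fresh pools are drawn each replicate).
#' @param rolloff_args List of arguments passed on to [rolloff_date()].
#' @param ref_n_hap Size of the reference panels resampled each
#'   replicate (haploid count; default 100).
#' @param seed Integer seed.
#' @return List with `bias`, `corrected_date`, `dates` (per-replicate
#'   estimates) and `n_failed`. Errors if more than half the replicates
#'   fail.
#' @export
estimate_bias <- function(theta, lambda, n_diploid, estimate = NULL,
                          n_replicates = 100, pool_args = list(),
                          rolloff_args = list(), ref_n_hap = 100,
                          seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  seeds <- sample.int(.Machine$integer.max, 3 * n_replicates)
  dates <- purrr::map_dbl(seq_len(n_replicates), function(r) {
    tryCatch({
      pools <- do.call(generate_ancestral_pools,
                       c(pool_args, list(seed = seeds[3 * r - 2])))
      cohort <- simulate_pulse(pools, n_diploid = n_diploid, theta = theta,
                               lambda = lambda, seed = seeds[3 * r - 1])
      refs <- sample_pool_freqs(pools, n_hap = ref_n_hap,
                                seed = seeds[3 * r])
      do.call(rolloff_date, c(list(cohort, refs), rolloff_args))$date
    }, error = function(e) NA_real_)
  })
  n_failed <- sum(!is.finite(dates))
  if (n_failed > n_replicates / 2) {
    abort("more than half of the bias-correction replicates failed")
  }
  bias <- mean(dates, na.rm = TRUE) - lambda
  list(
    bias = bias,
    corrected_date = if (is.null(estimate)) NA_real_ else estimate - bias,
    dates = dates, n_failed = n_failed
  )
}
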