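test_that("SNP weights follow the normalised frequency-difference form", {
  w <- snp_weights(c(1, 0.3, 0.8), c(0, 0.3, 0.2))
  expect_equal(w[1], 2)            # p = 0.5 -> (1-0)/0.5
  expect_equal(w[2], 0)
  expect_equal(w[3], 1.2)          # 0.6 / sqrt(0.25)
  expect_true(is.na(snp_weights(1, 1)))  # p = 1 undefined
  expect_true(is.na(snp_weights(0, 0)))
  expect_equal(snp_weights(c(0.9, 0.2), c(0.1, 0.6), normalize = FALSE),
               c(0.8, -0.4))
})

test_that("the pairwise LD score clips, transforms and skips as specified", {
  g <- c(0L, 1L, 2L, 0L, 2L, 1L, 0L, 2L, 1L, 0L)
  # N = 3 non-missing -> skipped
  g3 <- c(0L, 1L, 2L, rep(NA_integer_, 7))
  expect_true(pair_ld_score(g, g3)$skipped)
  # constant vector -> skipped
  expect_true(pair_ld_score(g, rep(1L, 10))$skipped)
  # r = 0 -> z = 0
  s0 <- pair_ld_score(c(0L, 0L, 2L, 2L), c(0L, 2L, 0L, 2L))
  expect_equal(s0$r, 0)
  expect_equal(s0$z, 0)
  # perfect correlation, N = 10: clip 0.9, z = atanh(0.9) * sqrt(7)
  sp <- pair_ld_score(g, g)
  expect_equal(sp$r, 1)
  expect_equal(sp$z, atanh(0.9) * sqrt(7), tolerance = 1e-12)
  expect_equal(sp$z, 3.8949, tolerance = 1e-4)
})

test_that("distance bins are half-open and correlation behaves at the limits", {
  # a single pair at 0.15 cM with 0.1 cM bins lands in [0.1, 0.2)
  pairs <- tibble::tibble(d_cm = c(0.15, 0.15, 0.15), z = c(1, 2, 3),
                          ww = c(1, 2, 3))
  b <- bin_pairs(pairs, bin_cm = 0.1, max_cm = 1)
  expect_equal(b$n_pairs[2], 3L) # bin midpoint 0.15
  expect_equal(sum(b$n_pairs), 3L)
  expect_equal(b$corr[2], 1) # z == ww exactly
  expect_error(bin_pairs(pairs, bin_cm = 0), "> 0")

  # permuted scores decorrelate: |corr| < 3/sqrt(n) in almost every bin
  withr::local_seed(71)
  n <- 20000
  pairs2 <- tibble::tibble(
    d_cm = runif(n, 0, 5),
    z = rnorm(n),
    ww = sample(rnorm(n))
  )
  b2 <- bin_pairs(pairs2, bin_cm = 0.5, max_cm = 5)
  frac <- mean(abs(b2$corr) < 3 / sqrt(b2$n_pairs))
  expect_gte(frac, 0.9)
})

test_that("the compiled pair accumulator matches the scalar oracle", {
  withr::local_seed(72)
  for (missing_rate in c(0, 0.15)) {
    x <- random_geno(n_snp = 80, n_ind = 9, n_chr = 2,
                     missing_rate = missing_rate)
    a <- runif(80, 0.1, 0.9)
    b <- runif(80, 0.1, 0.9)
    w <- snp_weights(a, b)
    oracle <- naive_rolloff_bins(x$geno, x$snp, w, bin_cm = 0.5, max_cm = 30)
    st <- admixdate:::rolloff_accumulate(
      x$geno, x$snp$chrom, x$snp$genetic_pos, w,
      bin_m = 0.5 / 100, d_max_m = 30 / 100
    )
    got <- admixdate:::bins_from_acc(Reduce(`+`, st$acc), 0.5)
    expect_equal(got$n_pairs, oracle$n_pairs)
    expect_equal(got$corr, oracle$corr, tolerance = 1e-10)
  }
})

test_that("exponential fitting recovers noiseless and noisy decay rates", {
  d_cm <- seq(0.55, 29.95, by = 0.1)
  clean <- tibble::tibble(bin_cm = d_cm,
                          corr = 0.3 * exp(-50 * d_cm / 100),
                          n_pairs = 1000L)
  for (off in c(FALSE, TRUE)) {
    f <- fit_exponential(clean, offset = off)
    expect_equal(f$n, 50, tolerance = 1e-6)
    expect_equal(f$amplitude, 0.3, tolerance = 1e-6)
  }

  # constant curve: no decay to fit
  flat <- tibble::tibble(bin_cm = d_cm, corr = 0.1, n_pairs = 1000L)
  expect_error(fit_exponential(flat), "no detectable")

  # too few usable bins
  expect_error(fit_exponential(clean[1:3, ]), "usable bins")

  # noisy recovery: n = 50 +/- 5 across seeds
  withr::local_seed(73)
  ests <- replicate(100, {
    noisy <- dplyr::mutate(clean, corr = .data$corr + rnorm(length(d_cm), 0, 0.005))
    fit_exponential(noisy)$n
  })
  expect_lt(abs(mean(ests) - 50), 2)
  expect_lt(sd(ests), 5)
})

test_that("two-exponential fitting resolves well-separated clean components", {
  d_cm <- seq(0.55, 29.95, by = 0.1)
  bins <- tibble::tibble(
    bin_cm = d_cm,
    corr = 0.2 * exp(-8 * d_cm / 100) + 0.1 * exp(-60 * d_cm / 100),
    n_pairs = 1000L
  )
  f <- fit_two_exponentials(bins)
  expect_equal(f$rates, c(8, 60), tolerance = 1e-3)
  expect_equal(f$amplitudes, c(0.2, 0.1), tolerance = 1e-3)
})

test_that("rolloff dating recovers a pulse and fails cleanly without signal", {
  pools <- generate_ancestral_pools(n_hap = 80, n_snp = 12000, n_chr = 6,
                                    seed = 74)
  refs <- sample_pool_freqs(pools, seed = 75)
  cohort <- simulate_pulse(pools, n_diploid = 10, theta = 0.2, lambda = 30,
                           seed = 76)
  rd <- rolloff_date(cohort, refs)
  expect_s3_class(rd, "rolloff_date")
  expect_gt(rd$se, 0)
  expect_lt(abs(rd$date - 30), 3 * rd$se)
  expect_equal(nrow(rd$loo), 6)
  expect_named(glance(rd),
               c("date", "se", "amplitude", "n_snps", "n_bins_used",
                 "min_cm", "max_cm"))
  expect_equal(nrow(tidy(rd)), 300) # 0.1 cM bins to 30 cM

  # unadmixed target carries no decay
  unadmixed <- simulate_pulse(pools, n_diploid = 10, theta = 1, lambda = 30,
                              seed = 77)
  expect_error(rolloff_date(unadmixed, refs), "no detectable|usable bins")

  # single-chromosome data cannot be jackknifed
  one_chr <- which(cohort$snp$chrom == 1)
  expect_error(
    rolloff_date(cohort$geno[one_chr, ], refs, snp = cohort$snp[one_chr, ]),
    ">= 2 chromosomes"
  )
})

test_that("flipping reference-allele polarity of every SNP leaves bins intact", {
  pools <- generate_ancestral_pools(n_hap = 60, n_snp = 6000, n_chr = 3,
                                    seed = 78)
  refs <- sample_pool_freqs(pools, seed = 79)
  cohort <- simulate_pulse(pools, n_diploid = 8, theta = 0.3, lambda = 20,
                           seed = 80)
  rd <- rolloff_date(cohort, refs, jackknife = FALSE)

  flipped_refs <- dplyr::mutate(refs, p = 1 - .data$p)
  flipped <- cohort
  flipped$geno <- 2L - cohort$geno
  rd_f <- rolloff_date(flipped, flipped_refs, jackknife = FALSE)
  expect_equal(rd_f$bins$corr, rd$bins$corr, tolerance = 1e-9)
  expect_equal(rd_f$date, rd$date, tolerance = 1e-6)
})

test_that("normalised and difference-only weights give compatible dates", {
  pools <- generate_ancestral_pools(seed = 81)
  refs <- sample_pool_freqs(pools, seed = 82)
  cohort <- simulate_pulse(pools, n_diploid = 10, theta = 0.2, lambda = 40,
                           seed = 83)
  rd_norm <- rolloff_date(cohort, refs)
  rd_diff <- rolloff_date(cohort, refs, normalize_weights = FALSE)
  expect_lt(abs(rd_norm$date - rd_diff$date),
            2 * sqrt(rd_norm$se^2 + rd_diff$se^2))
})

test_that("dates are robust to a misspecified reference population", {
  pools <- generate_ancestral_pools(seed = 84)
  cohort <- simulate_pulse(pools, n_diploid = 10, theta = 0.2, lambda = 40,
                           seed = 85)
  refs <- sample_pool_freqs(pools, seed = 86)
  rd <- rolloff_date(cohort, refs)
  # replace reference A by a population drifted away from the true source
  withr::local_seed(87)
  drifted <- admixdate:::bn_draw(pools$freq$p_a, 0.05)
  refs_wrong <- dplyr::bind_rows(
    sample_freq_table(drifted, pools$snp, "A", n_alleles = 100),
    refs[refs$population == "B", ]
  )
  rd_w <- rolloff_date(cohort, refs_wrong)
  expect_lt(abs(rd$date - rd_w$date), 2 * sqrt(rd$se^2 + rd_w$se^2))
})

test_that("the chromosome jackknife behaves at its degenerate limits", {
  # identical per-chromosome accumulators -> se ~ 0
  acc <- matrix(c(100, 10, 5, 120, 30, 40), nrow = 50, ncol = 6, byrow = TRUE)
  d <- (seq_len(50) - 0.5) * 0.5 / 100
  acc[, 6] <- 100 * 0.3 * exp(-20 * d) # force corr = A exp(-nd) shape
  acc[, 2] <- 0; acc[, 3] <- 0
  acc[, 4] <- 100; acc[, 5] <- 100
  st <- list(acc = stats::setNames(rep(list(acc), 4), 1:4),
             snp_counts = stats::setNames(rep(100, 4), 1:4))
  full <- fit_exponential(admixdate:::bins_from_acc(Reduce(`+`, st$acc), 0.5),
                          max_cm = 25)$n
  jd <- admixdate:::jackknife_date(st, full, 0.5, 0.5, 25)
  expect_lt(jd$se, 1e-6)

  # a chromosome with no usable bins leaves the estimate unchanged
  st$acc[["5"]] <- matrix(0, 50, 6)
  st$snp_counts <- c(st$snp_counts, "5" = 0)
  jd2 <- admixdate:::jackknife_date(st, full, 0.5, 0.5, 25)
  expect_equal(jd2$loo$date[jd2$loo$chrom == "5"], full, tolerance = 1e-9)
})

test_that("bias estimation applies the matched-simulation correction", {
  # correction arithmetic: estimate 99, bias 27 -> corrected 72
  pool_args <- list(n_hap = 60, n_snp = 6000, n_chr = 4)
  out <- estimate_bias(theta = 0.2, lambda = 10, n_diploid = 8,
                       estimate = 99, n_replicates = 3,
                       pool_args = pool_args, seed = 88)
  expect_equal(out$corrected_date, 99 - out$bias)
  expect_length(out$dates, 3)
  expect_lt(abs(out$bias), 8) # matched replicates centre near the truth
})
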