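test_that("ancestral pools are reproducible and hit the FST target", {
  p1 <- generate_ancestral_pools(n_hap = 30, n_snp = 3000, n_chr = 2, seed = 91)
  p2 <- generate_ancestral_pools(n_hap = 30, n_snp = 3000, n_chr = 2, seed = 91)
  expect_identical(p1$pool_a, p2$pool_a)
  expect_identical(p1$pool_b, p2$pool_b)
  expect_error(generate_ancestral_pools(fst = 0.7), "fst")

  # realised Hudson FST on the emitted pool frequencies
  big <- generate_ancestral_pools(n_snp = 100000, n_chr = 10, seed = 92)
  pf <- pool_freqs(big)
  fst <- hudson_fst(pf$p[pf$population == "A"], pf$p[pf$population == "B"],
                    100, 100)
  expect_lt(abs(fst - 0.15), 0.01)

  # the oracle formula agrees with an independent hand computation
  p1v <- c(0.2, 0.8); p2v <- c(0.3, 0.5)
  num <- (p1v - p2v)^2 - p1v * (1 - p1v) / 49 - p2v * (1 - p2v) / 99
  den <- p1v * (1 - p2v) + p2v * (1 - p1v)
  expect_equal(hudson_fst(p1v, p2v, 50, 100), sum(num) / sum(den))
})

test_that("background LD decays on the requested scale", {
  adj_cor <- function(pool) {
    m <- pool$pool_a
    cors <- vapply(seq_len(ncol(m) - 1), function(j) {
      if (sd(m[, j]) == 0 || sd(m[, j + 1]) == 0) return(NA_real_)
      cor(m[, j], m[, j + 1])
    }, numeric(1))
    mean(cors, na.rm = TRUE)
  }
  free <- generate_ancestral_pools(n_hap = 200, n_snp = 2000, n_chr = 1,
                                   ld_scale = 0, seed = 93)
  expect_lt(abs(adj_cor(free)), 0.03)
  # default scale: adjacent SNPs 0.05 cM apart share the latent with
  # probability exp(-0.5)
  ld <- generate_ancestral_pools(n_hap = 200, n_snp = 2000, n_chr = 1,
                                 ld_scale = 0.001, seed = 94)
  expect_gt(adj_cor(ld), 0.2)
})

test_that("pulse cohorts honour theta, lambda and the mosaic bookkeeping", {
  pools <- generate_ancestral_pools(n_hap = 80, n_snp = 8000, n_chr = 4,
                                    seed = 95)
  # theta = 1: all ancestry A
  all_a <- simulate_pulse(pools, n_diploid = 5, theta = 1, lambda = 10,
                          seed = 96)
  expect_true(all(all_a$tracts$ancestry == "A"))
  expect_equal(all_a$realized_ancestry$ancestry_a, rep(1, 5))

  # lambda -> 0: one tract per haploid chromosome
  lam0 <- simulate_pulse(pools, n_diploid = 5, theta = 0.5, lambda = 1e-9,
                         seed = 97)
  per_hap_chr <- dplyr::count(lam0$tracts, .data$haploid, .data$chrom)
  expect_true(all(per_hap_chr$n == 1))

  # genotype equals the sum of two haploid alleles: all entries in 0..2
  expect_true(all(all_a$geno %in% 0:2))
  # pool exhaustion guards the no-reuse invariant
  expect_error(simulate_pulse(pools, n_diploid = 50, theta = 0.5, lambda = 5),
               "pool exhaustion")
})

test_that("no donor segment is reused across admixed haploids", {
  pools <- generate_ancestral_pools(n_hap = 60, n_snp = 4000, n_chr = 2,
                                    seed = 98)
  cohort <- simulate_pulse(pools, n_diploid = 10, theta = 0.3, lambda = 30,
                           seed = 99)
  seg <- cohort$segments
  overlaps <- seg %>%
    dplyr::group_by(.data$source, .data$donor, .data$chrom) %>%
    dplyr::arrange(.data$start_idx, .by_group = TRUE) %>%
    dplyr::summarise(
      overlap = dplyr::n() > 1 &&
        any(.data$start_idx[-1] <= cummax(utils::head(.data$end_idx, -1))),
      .groups = "drop"
    )
  # every marker of every haploid is covered exactly once
  covered <- seg %>%
    dplyr::group_by(.data$haploid) %>%
    dplyr::summarise(n_markers = sum(.data$end_idx - .data$start_idx + 1))
  expect_true(all(covered$n_markers == nrow(cohort$snp)))
  expect_false(any(overlaps$overlap))
})

test_that("tract lengths and switch rates match the marker-process theory", {
  pools <- generate_ancestral_pools(seed = 100)
  cohort <- simulate_pulse(pools, n_diploid = 10, theta = 0.2, lambda = 50,
                           seed = 101)
  tr <- cohort$tracts

  # mean realized pool-A fraction ~ theta
  expect_lt(abs(mean(cohort$realized_ancestry$ancestry_a) - 0.2), 0.05)

  # ancestry change points per Morgan ~ lambda * 2 theta (1 - theta) = 16
  switches <- tr %>%
    dplyr::count(.data$haploid, .data$chrom) %>%
    dplyr::mutate(switches = .data$n - 1)
  total_m <- 20 * 10 * 1 # haploids x chromosomes x Morgans
  rate <- sum(switches$switches) / total_m
  expect_lt(abs(rate - 16), 1.6)

  # uncensored A-tract lengths ~ Exponential(mean 1/(lambda (1 - theta)))
  len <- tr$end_m[tr$ancestry == "A" & !tr$censored] -
    tr$start_m[tr$ancestry == "A" & !tr$censored]
  expect_gt(length(len), 1000)
  expect_lt(abs(mean(len) - 1 / (50 * 0.8)), 0.1 / (50 * 0.8))
  ks <- suppressWarnings(stats::ks.test(len, "pexp", rate = 1 / mean(len)))
  expect_gt(ks$p.value, 0.01)
})

test_that("cohort allele frequencies track the ancestry-weighted pool mix", {
  pools <- generate_ancestral_pools(seed = 102)
  cohort <- simulate_pulse(pools, n_diploid = 50, theta = 0.2, lambda = 50,
                           seed = 103)
  expect_true(cohort$params$large_n) # 100 haplotypes for 100 haploids
  f <- allele_frequencies(cohort)
  theta_hat <- mean(cohort$realized_ancestry$ancestry_a)
  expected <- theta_hat * pools$freq$p_a + (1 - theta_hat) * pools$freq$p_b
  slope <- coef(lm(f$p ~ expected))[2]
  expect_lt(abs(slope - 1), 0.02)
})

test_that("double-pulse composition yields the product ancestry proportion", {
  pools <- generate_ancestral_pools(n_hap = 120, n_snp = 10000, n_chr = 5,
                                    seed = 104)
  cohort <- simulate_double_pulse(pools, n_diploid = 10, lambda1 = 30,
                                  theta1 = 0.5, lambda2 = 10, theta2 = 0.5,
                                  seed = 105)
  expect_lt(abs(mean(cohort$realized_ancestry$ancestry_a) - 0.25), 0.07)
  expect_error(
    simulate_double_pulse(pools, 10, lambda1 = 5, theta1 = 0.5,
                          lambda2 = 10, theta2 = 0.5),
    "lambda1 > lambda2"
  )

  # a second pulse that admits no fresh ancestry keeps theta1 ancestry
  keep_all <- simulate_double_pulse(pools, n_diploid = 10, lambda1 = 30,
                                    theta1 = 0.5, lambda2 = 10, theta2 = 1,
                                    seed = 106)
  expect_lt(abs(mean(keep_all$realized_ancestry$ancestry_a) - 0.5), 0.07)
})

test_that("continuous gene flow reaches the requested total ancestry", {
  pools <- generate_ancestral_pools(n_hap = 120, n_snp = 10000, n_chr = 5,
                                    seed = 107)
  cohort <- simulate_continuous(pools, n_diploid = 50, a = 10, b = 50,
                                total_theta = 0.2, seed = 108)
  migrant <- 1 - mean(cohort$realized_ancestry$ancestry_a)
  expect_lt(abs(migrant - 0.2), 0.015)
  expect_error(simulate_continuous(pools, 10, a = 10, b = 50,
                                   total_theta = 1.2), "total_theta")

  # a = b collapses to a single pulse at that generation: compare the
  # ancestry switch rate against the pulse expectation
  one <- simulate_continuous(pools, n_diploid = 10, a = 20, b = 20,
                             total_theta = 0.3, seed = 109)
  switches <- one$tracts %>%
    dplyr::count(.data$haploid, .data$chrom) %>%
    dplyr::mutate(switches = .data$n - 1)
  rate <- sum(switches$switches) / (20 * 5)
  expect_lt(abs(rate - 20 * 2 * 0.3 * 0.7), 2)
})

test_that("outgroup panels sit on the expected side of the frequency tree", {
  pools <- generate_ancestral_pools(n_snp = 30000, n_chr = 5, seed = 110)
  og <- sample_outgroup_freqs(pools, seed = 111)
  o2 <- og$p[og$population == "O2"]
  # O2 branches from the pool-B internal node: closer to B than to A
  fst_b <- hudson_fst(o2, pools$freq$p_b, 100, 1e6)
  fst_a <- hudson_fst(o2, pools$freq$p_a, 100, 1e6)
  expect_lt(fst_b, fst_a)
})
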