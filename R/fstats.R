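#' The 4 Population Test for admixture
#'
#' Tests the unrooted tree ((A,B),(C,D)): if the tree is correct, the
#' genetic drift separating A and B is uncorrelated with the drift
#' separating C and D, so the mean over SNPs of
#' `(p_A - p_B)(p_C - p_D)` is zero in expectation. A Z-score more than 3
#' standard deviations from zero (block-jackknife standard error) is the
#' conventional evidence of gene flow.
#'
#' @param freqs Long frequency table from [allele_frequencies()] (columns
#'   `snp_id`, `chrom`, `genetic_pos`, `population`, `p`, `n_alleles`).
#' @param a,b,c,d Population labels for the tree ((a,b),(c,d)).
#' @param block_cm Jackknife block size in centimorgans (default 5).
#' @return An object of class `f_test` with fields `statistic`,
#'   `se`, `z`, `n_snps`, `n_blocks`, plus `corr`, a normalised version of
#'   the statistic (cosine similarity of the two frequency-difference
#'   vectors) reported for description only — the Z-score carries the
#'   test.
#' @export
f4_test <- function(freqs, a, b, c, d, block_cm = 5) {
  pops <- c(a, b, c, d)
  if (anyDuplicated(pops)) abort("the four population labels must be distinct")
  w <- freq_wide(freqs, pops)
  w <- filter_informative(w, 4)
  d1 <- w$p_1 - w$p_2
  d2 <- w$p_3 - w$p_4
  v <- d1 * d2
  blocks <- block_partition(w$chrom, w$genetic_pos, block_cm)
  if (length(unique(blocks)) < 2) abort("fewer than 2 jackknife blocks after filtering")
  jk <- jackknife_mean(v, blocks)
  corr <- sum(v) / sqrt(sum(d1^2) * sum(d2^2))
  new_f_test("f4", pops, jk, n_snps = nrow(w), block_cm = block_cm, corr = corr)
}

#' The 3 Population Test for admixture
#'
#' Computes the mean over SNPs of `(p_X - p_A)(p_X - p_B)`. If X descends
#' from A and B through a simple tree this product is positive in
#' expectation; a significantly negative value (Z < -3) is an unambiguous
#' signal that X is admixed between populations related to A and B. A
#' positive value does not rule mixture out.
#'
#' Because `p_X` enters both factors, its sampling noise inflates the raw
#' product; by default the unbiased estimate of that variance,
#' `p_X(1-p_X)/(n_alleles_X - 1)`, is subtracted per SNP so that the
#' "simple tree implies positive" contract holds at small sample sizes.
#'
#' @param freqs Long frequency table from [allele_frequencies()].
#' @param x Label of the population tested for mixture.
#' @param a,b Labels of the two proposed source-related populations.
#' @param block_cm Jackknife block size in centimorgans (default 5).
#' @param correct_sample_bias Subtract the `p_X` sampling-variance term
#'   (default `TRUE`). SNPs with fewer than 4 X alleles are dropped when
#'   the correction is on.
#' @return An object of class `f_test`; see [f4_test()].
#' @export
f3_test <- function(freqs, x, a, b, block_cm = 5, correct_sample_bias = TRUE) {
  if (x == a || x == b) abort("the target X must differ from both reference labels")
  pops <- c(x, a, b)
  w <- freq_wide(freqs, pops)
  w <- filter_informative(w, 3)
  if (correct_sample_bias) w <- w[w$n_1 >= 4, ]
  v <- (w$p_1 - w$p_2) * (w$p_1 - w$p_3)
  if (correct_sample_bias) {
    v <- v - w$p_1 * (1 - w$p_1) / (w$n_1 - 1)
  }
  blocks <- block_partition(w$chrom, w$genetic_pos, block_cm)
  if (length(unique(blocks)) < 2) abort("fewer than 2 jackknife blocks after filtering")
  jk <- jackknife_mean(v, blocks)
  new_f_test("f3", pops, jk, n_snps = nrow(w), block_cm = block_cm)
}

#' f4-ratio estimation of an ancestry proportion
#'
#' Estimates the proportion of `ref_a`-related ancestry in population `x`
#' as the ratio of two 4 Population Test statistics computed on the same
#' SNPs:
#' `sum (p_o1 - p_o2)(p_x - p_refb) / sum (p_o1 - p_o2)(p_refa - p_refb)`.
#' With outgroup `o1` splitting before the `ref_a`/`ref_b` ancestor and
#' `o2` branching from the `ref_b` lineage, both sums are proportional to
#' the drift on the shared internal branch, and the mixture proportion
#' cancels everything else — no data from the true ancestral populations
#' are needed. Standard errors come from a block jackknife of the ratio.
#'
#' @param freqs Long frequency table covering all five populations.
#' @param x Target (possibly admixed) population label.
#' @param o1,o2 Outgroup labels (e.g. San-like and Papuan-like).
#' @param ref_a Reference for the ancestry being quantified (e.g.
#'   YRI-like: the proportion returned is `ref_a`-related ancestry).
#' @param ref_b Reference for the other side of the mixture (e.g.
#'   CEU-like).
#' @param block_cm Jackknife block size in centimorgans (default 5).
#' @return An object of class `f4_ratio` with fields `proportion`, `se`,
#'   `z`, `n_snps`, `n_blocks` and the labels used. The proportion may
#'   fall slightly outside \[0,1\] from sampling noise; it is reported as
#'   computed.
#' @export
f4_ratio <- function(freqs, x, o1, o2, ref_a, ref_b, block_cm = 5) {
  pops <- c(o1, o2, x, ref_a, ref_b)
  if (anyDuplicated(pops)) abort("the five population labels must be distinct")
  w <- freq_wide(freqs, pops)
  w <- filter_informative(w, 5)
  dout <- w$p_1 - w$p_2
  num <- dout * (w$p_3 - w$p_5)
  den <- dout * (w$p_4 - w$p_5)
  blocks <- block_partition(w$chrom, w$genetic_pos, block_cm)
  if (length(unique(blocks)) < 2) abort("fewer than 2 jackknife blocks after filtering")
  den_jk <- jackknife_mean(den, blocks)
  if (abs(den_jk$estimate) < 3 * den_jk$se) {
    abort("uninformative reference configuration: f4 denominator within jackknife noise of 0")
  }
  jk <- jackknife_ratio(num, den, blocks)
  structure(
    list(
      proportion = jk$estimate, se = jk$se, z = jk$estimate / jk$se,
      n_snps = nrow(w), n_blocks = jk$n_blocks, block_cm = block_cm,
      populations = stats::setNames(pops, c("o1", "o2", "x", "ref_a", "ref_b"))
    ),
    class = "f4_ratio"
  )
}

# Drop SNPs with any undefined frequency among the first k populations of
# the wide table, and SNPs monomorphic across all of them.
filter_informative <- function(w, k) {
  pcols <- paste0("p_", seq_len(k))
  pm <- as.matrix(w[pcols])
  defined <- rowSums(is.na(pm)) == 0
  poly <- rowSums(pm != 0, na.rm = TRUE) > 0 & rowSums(pm != 1, na.rm = TRUE) > 0
  w[defined & poly & !is.na(w$genetic_pos), ]
}

new_f_test <- function(type, pops, jk, n_snps, block_cm, corr = NULL) {
  structure(
    list(
      type = type, populations = pops, statistic = jk$estimate, se = jk$se,
      z = if (jk$se > 0) jk$estimate / jk$se else 0,
      n_snps = n_snps, n_blocks = jk$n_blocks, block_cm = block_cm,
      corr = corr
    ),
    class = "f_test"
  )
}

#' @export
print.f_test <- function(x, ...) {
  lab <- if (x$type == "f4") {
    sprintf("f4(%s, %s; %s, %s)", x$populations[1], x$populations[2],
            x$populations[3], x$populations[4])
  } else {
    sprintf("f3(%s; %s, %s)", x$populations[1], x$populations[2], x$populations[3])
  }
  cat(sprintf("%s = %.6g +/- %.3g  (Z = %.2f, %d SNPs, %d blocks of %g cM)\n",
              lab, x$statistic, x$se, x$z, x$n_snps, x$n_blocks, x$block_cm))
  invisible(x)
}

#' @export
print.f4_ratio <- function(x, ...) {
  p <- x$populations
  cat(sprintf(
    "f4-ratio ancestry of %s: %.1f%% +/- %.1f%%  (refs %s/%s, outgroups %s/%s; %d SNPs)\n",
    p["x"], 100 * x$proportion, 100 * x$se, p["ref_a"], p["ref_b"],
    p["o1"], p["o2"], x$n_snps
  ))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @method tidy f_test
#' @export
tidy.f_test <- function(x, ...) {
  tibble(
    test = x$type,
    populations = paste(x$populations, collapse = ","),
    estimate = x$statistic, std.error = x$se, statistic = x$z,
    n_snps = x$n_snps, n_blocks = x$n_blocks
  )
}

#' @method glance f_test
#' @export
glance.f_test <- function(x, ...) {
  tibble(n_snps = x$n_snps, n_blocks = x$n_blocks, block_cm = x$block_cm,
         significant = abs(x$z) > 3)
}

#' @method tidy f4_ratio
#' @export
tidy.f4_ratio <- function(x, ...) {
  tibble(
    population = unname(x$populations["x"]),
    estimate = x$proportion, std.error = x$se, statistic = x$z,
    n_snps = x$n_snps, n_blocks = x$n_blocks
  )
}

#' @method glance f4_ratio
#' @export
glance.f4_ratio <- function(x, ...) {
  tibble(n_snps = x$n_snps, n_blocks = x$n_blocks, block_cm = x$block_cm)
}
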