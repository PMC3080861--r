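#' Assign SNPs to contiguous jackknife blocks
#'
#' Partitions SNPs into contiguous blocks of at most `block_cm`
#' centimorgans within each chromosome (blocks never span chromosomes).
#' The default 5 cM matches the convention used for f-statistic standard
#' errors; passing `block_cm = Inf` yields whole-chromosome blocks, the
#' conservative choice used when jackknifing admixture-LD dates.
#'
#' @param chrom Integer chromosome label per SNP.
#' @param genetic_pos Genetic position per SNP, in Morgans.
#' @param block_cm Block size in centimorgans (default 5).
#' @return Integer block id per SNP (consecutive, starting at 1).
#' @export
block_partition <- function(chrom, genetic_pos, block_cm = 5) {
  stopifnot(length(chrom) == length(genetic_pos), block_cm > 0)
  g_cm <- genetic_pos * 100
  key <- paste0(chrom, ":", if (is.finite(block_cm)) {
    floor((g_cm - stats::ave(g_cm, chrom, FUN = min)) / block_cm)
  } else 0L)
  as.integer(factor(key, levels = unique(key)))
}

# Busing-style weighted delete-one-block jackknife standard error.
# full: estimate on all data; loo: leave-one-block-out estimates;
# weights: size of each dropped block (> 0).
busing_jackknife_se <- function(full, loo, weights) {
  g <- length(loo)
  stopifnot(g >= 2, length(weights) == g, all(weights > 0))
  n <- sum(weights)
  h <- n / weights
  est_j <- g * full - sum((1 - weights / n) * loo)
  pseudo <- h * full - (h - 1) * loo
  sqrt(mean((pseudo - est_j)^2 / (h - 1)))
}

#' Weighted delete-one-block jackknife
#'
#' Computes an estimate on the full data and its standard error from
#' delete-one-block pseudovalues, with each dropped block weighted by its
#' size (Busing-style weighted jackknife). With equal block weights this
#' reduces to the standard delete-one jackknife.
#'
#' @param values Numeric vector, matrix or data frame of per-observation
#'   (typically per-SNP) values.
#' @param blocks Block id per observation (from [block_partition()]).
#' @param estimator Function mapping a subset of `values` (same type) to a
#'   scalar. Default: the mean (of a vector) — the form taken by the
#'   f-statistics.
#' @param weights Optional per-observation weights; a block's jackknife
#'   weight is the sum over its observations (default: 1 per observation,
#'   i.e. block weight = number of SNPs).
#' @return List with `estimate`, `se`, `n_blocks`, and a tibble `loo` of
#'   leave-one-out estimates and block weights.
#' @export
block_jackknife <- function(values, blocks, estimator = NULL, weights = NULL) {
  take <- function(v, idx) if (is.null(dim(v))) v[idx] else v[idx, , drop = FALSE]
  n_obs <- if (is.null(dim(values))) length(values) else nrow(values)
  stopifnot(length(blocks) == n_obs)
  estimator <- estimator %||% function(v) mean(v)
  weights <- weights %||% rep(1, n_obs)
  ids <- unique(blocks)
  if (length(ids) < 2) abort("block jackknife needs >= 2 blocks")
  full <- estimator(values)
  loo <- vapply(ids, function(b) {
    est <- tryCatch(estimator(take(values, blocks != b)), error = function(e) NA_real_)
    if (!is.finite(est)) {
      abort(sprintf("estimator undefined when dropping block %s", b))
    }
    est
  }, numeric(1))
  w <- vapply(ids, function(b) sum(weights[blocks == b]), numeric(1))
  list(
    estimate = full,
    se = busing_jackknife_se(full, loo, w),
    n_blocks = length(ids),
    loo = tibble(block = ids, estimate = loo, weight = w)
  )
}

# Fast jackknife for a mean of per-SNP values: leave-one-out means via
# block sums, avoiding repeated subsetting.
jackknife_mean <- function(v, blocks) {
  sums <- rowsum(v, blocks)
  cnt <- rowsum(rep(1, length(v)), blocks)
  full <- sum(v) / length(v)
  loo <- (sum(v) - sums[, 1]) / (length(v) - cnt[, 1])
  list(estimate = full, se = busing_jackknife_se(full, loo, cnt[, 1]),
       n_blocks = nrow(sums))
}

# Fast jackknife for a ratio of sums (f4-ratio).
jackknife_ratio <- function(num, den, blocks) {
  sn <- rowsum(num, blocks)[, 1]
  sd_ <- rowsum(den, blocks)[, 1]
  cnt <- rowsum(rep(1, length(num)), blocks)[, 1]
  full <- sum(num) / sum(den)
  loo <- (sum(num) - sn) / (sum(den) - sd_)
  list(estimate = full, se = busing_jackknife_se(full, loo, cnt),
       n_blocks = length(sn), loo_den = sum(den) - sd_)
}
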