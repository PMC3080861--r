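#' Per-population allele frequencies
#'
#' Computes, for each SNP and requested population, the reference-allele
#' frequency `p` and the number of non-missing alleles used. With diploid
#' genotypes in \{0,1,2\}, `p` is the mean allele count divided by two and
#' `n_alleles` is twice the number of non-missing genotypes. SNPs where a
#' population has no data get `p = NA` with `n_alleles = 0`.
#'
#' @param x An `admix_geno` or `admix_cohort` object (list with `geno`,
#'   `snp`, `ind`).
#' @param populations Character vector of population labels to tabulate;
#'   default all populations present.
#' @return A tibble in long format: `snp_id`, `chrom`, `genetic_pos`
#'   (Morgans), `population`, `p`, `n_alleles`. This is the frequency
#'   table consumed by [f4_test()], [f3_test()], [f4_ratio()] and
#'   [snp_weights()].
#' @export
allele_frequencies <- function(x, populations = NULL) {
  stopifnot(is.list(x), !is.null(x$geno), !is.null(x$ind), !is.null(x$snp))
  pops <- populations %||% unique(x$ind$population)
  missing_pops <- setdiff(pops, x$ind$population)
  if (length(missing_pops)) {
    abort(paste0("population(s) with zero individuals: ",
                 paste(missing_pops, collapse = ", ")))
  }
  per_pop <- purrr::map(pops, function(pop) {
    cols <- which(x$ind$population == pop)
    g <- x$geno[, cols, drop = FALSE]
    n_obs <- rowSums(!is.na(g))
    s <- rowSums(g, na.rm = TRUE)
    tibble(
      snp_id = x$snp$snp_id,
      chrom = x$snp$chrom,
      genetic_pos = x$snp$genetic_pos,
      population = pop,
      p = ifelse(n_obs > 0, s / (2 * n_obs), NA_real_),
      n_alleles = 2L * n_obs
    )
  })
  bind_rows(per_pop)
}

# Wide layout used internally by the f-statistics: one row per SNP,
# columns p_<k>/n_<k> in the order of `pops`.
freq_wide <- function(freqs, pops) {
  stopifnot(all(c("snp_id", "population", "p", "n_alleles") %in% names(freqs)))
  missing_pops <- setdiff(pops, unique(freqs$population))
  if (length(missing_pops)) {
    abort(paste0("population(s) absent from frequency table: ",
                 paste(missing_pops, collapse = ", ")))
  }
  base <- freqs %>%
    filter(.data$population == pops[1]) %>%
    select("snp_id", "chrom", "genetic_pos")
  for (k in seq_along(pops)) {
    fk <- freqs[freqs$population == pops[k], ]
    i <- match(base$snp_id, fk$snp_id)
    base[[paste0("p_", k)]] <- fk$p[i]
    base[[paste0("n_", k)]] <- fk$n_alleles[i]
  }
  base
}

#' Hudson's FST estimator from allele frequencies
#'
#' Ratio-of-sums form with the finite-sample correction for each
#' population: the numerator per SNP is
#' `(p1-p2)^2 - p1(1-p1)/(n1-1) - p2(1-p2)/(n2-1)` and the denominator is
#' `p1(1-p2) + p2(1-p1)`; the estimate is the ratio of their sums across
#' SNPs.
#'
#' @param p1,p2 Allele-frequency vectors for the two populations.
#' @param n1,n2 Allele counts (number of sampled alleles) per SNP; scalars
#'   are recycled.
#' @return The FST estimate (scalar).
#' @export
hudson_fst <- function(p1, p2, n1, n2) {
  keep <- !is.na(p1) & !is.na(p2)
  p1 <- p1[keep]; p2 <- p2[keep]
  n1 <- rep_len(n1, length(keep))[keep]
  n2 <- rep_len(n2, length(keep))[keep]
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  sum(num) / sum(den)
}
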