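# Shared fixture builders. Everything is generated in code; no binary
# files ship with the package.

# Write a tiny EIGENSTRAT triplet into `dir` and return the three paths.
write_triplet <- function(geno_lines, snp_df, ind_df, dir = NULL) {
  if (is.null(dir)) {
    dir <- tempfile("eig")
    dir.create(dir)
  }
  paths <- file.path(dir, c("x.geno", "x.snp", "x.ind"))
  writeLines(geno_lines, paths[1])
  utils::write.table(snp_df, paths[2], quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  utils::write.table(ind_df, paths[3], quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  paths
}

snp_df_for <- function(n, chrom = 1, spacing_m = 0.001) {
  data.frame(
    id = paste0("rs", seq_len(n)),
    chrom = chrom,
    genetic = seq_len(n) * spacing_m,
    physical = seq_len(n) * 1000
  )
}

ind_df_for <- function(pops) {
  data.frame(
    id = paste0("ind", seq_along(pops)),
    sex = "U",
    pop = pops
  )
}

# A random admix_geno-like object for property tests.
random_geno <- function(n_snp = 60, n_ind = 8, n_chr = 2, missing_rate = 0.05,
                        pops = rep("P", n_ind)) {
  g <- matrix(sample(0:2, n_snp * n_ind, replace = TRUE), n_snp, n_ind)
  if (missing_rate > 0) {
    g[runif(length(g)) < missing_rate] <- NA_integer_
  }
  per <- n_snp / n_chr
  snp <- tibble::tibble(
    snp_id = paste0("rs", seq_len(n_snp)),
    chrom = rep(seq_len(n_chr), each = per),
    genetic_pos = rep(seq_len(per), n_chr) * 0.00213,
    physical_pos = rep(seq_len(per), n_chr) * 2000
  )
  ind <- tibble::tibble(individual_id = paste0("i", seq_len(n_ind)),
                        sex = "U", population = pops)
  structure(list(geno = g, snp = snp, ind = ind), class = "admix_geno")
}

# Reference-quality oracle for the binned decay curve: enumerate every
# within-chromosome pair with the scalar pair_ld_score() and feed
# bin_pairs(); used to validate the compiled accumulation path.
naive_rolloff_bins <- function(geno, snp, w, bin_cm = 0.5, max_cm = 30) {
  rows <- list()
  for (ch in unique(snp$chrom)) {
    idx <- which(snp$chrom == ch & !is.na(w))
    for (a in seq_along(idx)) {
      for (b in seq_along(idx)) {
        if (b <= a) next
        i <- idx[a]; j <- idx[b]
        d_cm <- (snp$genetic_pos[j] - snp$genetic_pos[i]) * 100
        if (d_cm <= 0 || d_cm > max_cm) next
        sc <- pair_ld_score(geno[i, ], geno[j, ])
        if (sc$skipped) next
        rows[[length(rows) + 1]] <-
          tibble::tibble(d_cm = d_cm, z = sc$z, ww = w[i] * w[j])
      }
    }
  }
  bin_pairs(dplyr::bind_rows(rows), bin_cm = bin_cm, max_cm = max_cm)
}

# Frequency table from explicit per-population vectors (infinite-sample
# panels unless n_alleles given).
freq_table_from <- function(snp, ..., n_alleles = .Machine$integer.max) {
  pops <- list(...)
  dplyr::bind_rows(purrr::imap(pops, function(p, nm) {
    tibble::tibble(
      snp_id = snp$snp_id, chrom = snp$chrom,
      genetic_pos = snp$genetic_pos, population = nm,
      p = p, n_alleles = n_alleles
    )
  }))
}

# Uniformly spaced SNP tibble spanning several chromosomes.
snp_grid <- function(n_snp, n_chr = 2, chr_length_m = 1) {
  admixdate:::uniform_snp_table(n_snp, n_chr, chr_length_m)
}
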