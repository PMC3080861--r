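#' Generate two diverged ancestral haplotype pools
#'
#' Synthetic stand-in for phased reference haplotype panels: per-SNP
#' ancestral frequencies are drawn uniformly, the two pool frequencies
#' disperse around them under a Balding-Nichols model whose branch
#' parameters are calibrated so the Hudson FST between the pools equals
#' `fst`, and haplotypes are realised by a first-order copying process
#' along each chromosome so background LD decays on the genetic scale
#' `ld_scale`. SNPs are uniformly spaced. The pool-B branch passes
#' through a recorded internal node, and the root frequencies are kept,
#' so outgroup populations for f4-ratio work can be hung off either
#' point with [sample_outgroup_freqs()].
#'
#' @param n_hap Haplotypes per pool (default 100).
#' @param n_snp Total SNP count (default 20000).
#' @param n_chr Number of chromosomes (default 10).
#' @param chr_length_m Genetic length of each chromosome in Morgans
#'   (default 1).
#' @param fst Target allele-frequency differentiation between the pools
#'   (default 0.15); must lie in (0, 0.5].
#' @param ld_scale Background-LD decay distance in Morgans (default
#'   0.001, i.e. 0.1 cM); 0 gives LD-free pools.
#' @param seed Integer seed; the same seed reproduces the pools
#'   bit-identically.
#' @return Object of class `hap_pools`: list with `pool_a`, `pool_b`
#'   (haplotype-by-SNP 0/1 matrices), `snp` (SNP tibble with positions),
#'   `freq` (true per-SNP frequencies: root `q`, `p_a`, `p_b`, internal
#'   node `p_node`) and `params`.
#' @export
generate_ancestral_pools <- function(n_hap = 100, n_snp = 20000, n_chr = 10,
                                     chr_length_m = 1, fst = 0.15,
                                     ld_scale = 0.001, seed = NULL) {
  if (fst <= 0 || fst > 0.5) abort("fst must lie in (0, 0.5]")
  if (ld_scale < 0) abort("ld_scale must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  snp <- uniform_snp_table(n_snp, n_chr, chr_length_m)
  q <- runif(n_snp, 0.1, 0.9)
  # branch Balding-Nichols parameters: pool A drifts `fst` from the root;
  # pool B accumulates the same total drift through an internal node at
  # fst/2, so pairwise Hudson FST(A, B) = fst.
  c_e <- fst / 2
  c_b <- 1 - (1 - fst) / (1 - c_e)
  p_a <- bn_draw(q, fst)
  p_node <- bn_draw(q, c_e)
  p_b <- bn_draw(p_node, c_b)
  pool_a <- draw_haplotypes(p_a, snp, n_hap, ld_scale)
  pool_b <- draw_haplotypes(p_b, snp, n_hap, ld_scale)
  structure(
    list(
      pool_a = pool_a, pool_b = pool_b, snp = snp,
      freq = tibble(snp_id = snp$snp_id, q = q, p_a = p_a, p_b = p_b,
                    p_node = p_node),
      params = list(n_hap = n_hap, n_snp = n_snp, n_chr = n_chr,
                    chr_length_m = chr_length_m, fst = fst,
                    ld_scale = ld_scale)
    ),
    class = "hap_pools"
  )
}

#' @export
print.hap_pools <- function(x, ...) {
  cat(sprintf(
    "<hap_pools> 2 pools x %d haplotypes, %d SNPs on %d chromosome(s) of %g M (target FST %.3g)\n",
    x$params$n_hap, x$params$n_snp, x$params$n_chr, x$params$chr_length_m,
    x$params$fst
  ))
  invisible(x)
}

uniform_snp_table <- function(n_snp, n_chr, chr_length_m) {
  per <- rep(n_snp %/% n_chr, n_chr)
  if (n_snp %% n_chr) per[seq_len(n_snp %% n_chr)] <- per[seq_len(n_snp %% n_chr)] + 1
  purrr::map2(seq_len(n_chr), per, function(ch, k) {
    g <- (seq_len(k) - 0.5) / k * chr_length_m
    tibble(
      snp_id = sprintf("snp_%d_%d", ch, seq_len(k)),
      chrom = ch,
      genetic_pos = g,
      physical_pos = round(g * 1e8) + 1 # 1 cM per Mb
    )
  }) %>% bind_rows()
}

# Balding-Nichols draw of population frequencies around p with parameter f.
bn_draw <- function(p, f) {
  if (f == 0) return(p)
  rbeta(length(p), p * (1 - f) / f, (1 - p) * (1 - f) / f)
}

# Haplotypes with exact marginal frequencies p and background LD decaying
# as exp(-d / ld_scale): a latent uniform persists along the chromosome
# and is redrawn with probability 1 - exp(-gap / ld_scale); the allele is
# the indicator latent < p. Adjacent SNPs sharing the latent are
# comonotone, so correlation decays geometrically with map distance.
draw_haplotypes <- function(p, snp, n_hap, ld_scale) {
  out <- matrix(0L, n_hap, length(p))
  for (ch in unique(snp$chrom)) {
    idx <- which(snp$chrom == ch)
    gaps <- c(Inf, diff(snp$genetic_pos[idx]))
    r <- if (ld_scale > 0) 1 - exp(-gaps / ld_scale) else rep(1, length(gaps))
    r[1] <- 1
    pc <- p[idx]
    for (h in seq_len(n_hap)) {
      e <- runif(length(idx)) < r
      seg <- cumsum(e)
      u <- runif(seg[length(seg)])[seg]
      out[h, idx] <- as.integer(u < pc)
    }
  }
  out
}

#' Exact frequencies of the haplotype pools
#'
#' @param pools A `hap_pools` object.
#' @return Long frequency table (populations `"A"` and `"B"`) with `p`
#'   computed from the pool haplotypes and `n_alleles` equal to the pool
#'   size.
#' @export
pool_freqs <- function(pools) {
  bind_rows(
    freq_rows(pools$snp, colMeans(pools$pool_a), nrow(pools$pool_a), "A"),
    freq_rows(pools$snp, colMeans(pools$pool_b), nrow(pools$pool_b), "B")
  )
}

freq_rows <- function(snp, p, n_alleles, population) {
  tibble(
    snp_id = snp$snp_id, chrom = snp$chrom, genetic_pos = snp$genetic_pos,
    population = population, p = p, n_alleles = as.integer(n_alleles)
  )
}

#' Sample independent reference panels from the pools' true frequencies
#'
#' Draws fresh binomial samples of the true per-SNP pool frequencies, as
#' an independent reference panel would — reference individuals disjoint
#' from the donors of the admixed genomes.
#'
#' @param pools A `hap_pools` object.
#' @param n_hap Alleles sampled per SNP per panel (default 100).
#' @param pops Labels for the two panels (default `c("A", "B")`).
#' @param seed Integer seed.
#' @return Long frequency table for the two reference panels.
#' @export
sample_pool_freqs <- function(pools, n_hap = 100, pops = c("A", "B"),
                              seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(pools$freq)
  bind_rows(
    freq_rows(pools$snp, rbinom(n, n_hap, pools$freq$p_a) / n_hap, n_hap, pops[1]),
    freq_rows(pools$snp, rbinom(n, n_hap, pools$freq$p_b) / n_hap, n_hap, pops[2])
  )
}

#' Sample outgroup frequency panels for f4-ratio estimation
#'
#' Hangs two outgroup populations off the generator's frequency tree:
#' the first drifts from the root ancestor (a deep outgroup, San-like in
#' the human application), the second from the internal node on the
#' pool-B branch (Papuan-like: an outgroup on the non-African side).
#' With this placement the f4-ratio of a cohort admixed between the
#' pools equals its pool-A ancestry proportion in expectation.
#'
#' @param pools A `hap_pools` object.
#' @param n_hap Alleles sampled per SNP per panel (default 100).
#' @param drift Balding-Nichols drift of the two outgroups from their
#'   attachment points (default `c(0.2, 0.1)`).
#' @param pops Labels for the two outgroups (default `c("O1", "O2")`).
#' @param seed Integer seed.
#' @return Long frequency table for the two outgroup panels.
#' @export
sample_outgroup_freqs <- function(pools, n_hap = 100, drift = c(0.2, 0.1),
                                  pops = c("O1", "O2"), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(pools$freq)
  p1 <- bn_draw(pools$freq$q, drift[1])
  p2 <- bn_draw(pools$freq$p_node, drift[2])
  bind_rows(
    freq_rows(pools$snp, rbinom(n, n_hap, p1) / n_hap, n_hap, pops[1]),
    freq_rows(pools$snp, rbinom(n, n_hap, p2) / n_hap, n_hap, pops[2])
  )
}

#' Simulate population frequencies on a simple four-population tree
#'
#' Frequency-level generator for f-statistic calibration: on the
#' unrooted tree ((A,B),(C,D)), the root frequency drifts independently
#' into two internal nodes (Balding-Nichols parameter `drift_internal`),
#' each of which splits into two tips (`drift_tip`); observed
#' frequencies are binomial samples of `n_alleles` alleles per tip. No
#' LD is simulated — appropriate for tests whose statistics are
#' functions of frequencies only.
#'
#' @param n_snp SNP count (default 50000).
#' @param n_chr Chromosomes (default 10); positions uniform, 1 Morgan
#'   each unless changed.
#' @param chr_length_m Chromosome genetic length in Morgans (default 1).
#' @param drift_internal,drift_tip Balding-Nichols parameters of the
#'   internal and tip branches (defaults 0.05).
#' @param n_alleles Alleles sampled per tip population (default 50).
#' @param seed Integer seed.
#' @return List with `freqs` (long sampled frequency table, populations
#'   A-D), `true` (tibble of the underlying true frequencies, including
#'   the internal nodes) and `snp`.
#' @export
simulate_tree_freqs <- function(n_snp = 50000, n_chr = 10, chr_length_m = 1,
                                drift_internal = 0.05, drift_tip = 0.05,
                                n_alleles = 50, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  snp <- uniform_snp_table(n_snp, n_chr, chr_length_m)
  q <- runif(n_snp, 0.1, 0.9)
  q_ab <- bn_draw(q, drift_internal)
  q_cd <- bn_draw(q, drift_internal)
  true <- tibble(
    snp_id = snp$snp_id, q = q, q_ab = q_ab, q_cd = q_cd,
    p_a = bn_draw(q_ab, drift_tip), p_b = bn_draw(q_ab, drift_tip),
    p_c = bn_draw(q_cd, drift_tip), p_d = bn_draw(q_cd, drift_tip)
  )
  freqs <- bind_rows(
    freq_rows(snp, rbinom(n_snp, n_alleles, true$p_a) / n_alleles, n_alleles, "A"),
    freq_rows(snp, rbinom(n_snp, n_alleles, true$p_b) / n_alleles, n_alleles, "B"),
    freq_rows(snp, rbinom(n_snp, n_alleles, true$p_c) / n_alleles, n_alleles, "C"),
    freq_rows(snp, rbinom(n_snp, n_alleles, true$p_d) / n_alleles, n_alleles, "D")
  )
  list(freqs = freqs, true = true, snp = snp)
}

#' Binomial sampling of a frequency vector into a frequency table
#'
#' Utility for constructing observed frequency panels from true per-SNP
#' frequencies (e.g. an admixed population built as a convex combination
#' of two tips).
#'
#' @param p True frequency vector (one value per row of `snp`).
#' @param snp SNP tibble.
#' @param population Population label for the output rows.
#' @param n_alleles Alleles sampled per SNP (default 50); `Inf` returns
#'   `p` unchanged (an infinite-sample panel).
#' @param seed Integer seed.
#' @return Long frequency table rows for one population.
#' @export
sample_freq_table <- function(p, snp, population, n_alleles = 50, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.infinite(n_alleles)) {
    out <- freq_rows(snp, p, .Machine$integer.max, population)
  } else {
    out <- freq_rows(snp, rbinom(length(p), n_alleles, p) / n_alleles,
                     n_alleles, population)
  }
  out
}
# ---------------------------------------------------------------------------
# Mosaic construction of admixed genomes

# Low-level engine. `anc_fun(gaps, hap)` returns, for one haploid
# chromosome, list(anc = 0/1 per marker (1 = source "a"), events =
# logical per marker marking ancestry-resampling points). Donor
# haplotypes in each source matrix are partitioned into disjoint private
# subsets per admixed haploid, so no donor segment is ever copied into
# two admixed genomes; a resampling event always switches donors when
# more than one private donor is available, even if the redrawn ancestry
# is unchanged (with a single private donor — the large-n regime — the
# donor is necessarily retained).
mosaic_haplotypes <- function(src_a, src_b, snp, n_haploid, anc_fun) {
  n_snp <- nrow(snp)
  dph_a <- nrow(src_a) %/% n_haploid
  dph_b <- nrow(src_b) %/% n_haploid
  if (min(dph_a, dph_b) < 1) {
    abort(paste0(
      "pool exhaustion: need at least ", n_haploid,
      " donor haplotypes per source for ", n_haploid,
      " admixed haploids (one private donor each; large-n mode)"
    ))
  }
  priv_a <- split_private(nrow(src_a), n_haploid, dph_a)
  priv_b <- split_private(nrow(src_b), n_haploid, dph_b)
  haps <- matrix(0L, n_haploid, n_snp)
  anc <- matrix(0L, n_haploid, n_snp)
  donor <- matrix(0L, n_haploid, n_snp)
  segs <- vector("list", n_haploid)
  chr_idx <- split(seq_len(n_snp), snp$chrom)
  for (h in seq_len(n_haploid)) {
    sg_h <- vector("list", length(chr_idx))
    for (ci in seq_along(chr_idx)) {
      idx <- chr_idx[[ci]]
      pos <- snp$genetic_pos[idx]
      la <- anc_fun(c(Inf, diff(pos)), h)
      a <- la$anc
      events <- la$events
      events[1] <- TRUE
      seg <- cumsum(events)
      anc_seg <- a[!duplicated(seg)]
      donor_seg <- pick_donors(anc_seg, priv_a[[h]], priv_b[[h]])
      dm <- donor_seg[seg]
      is_a <- a == 1L
      alle <- integer(length(idx))
      if (any(is_a)) alle[is_a] <- src_a[cbind(dm[is_a], idx[is_a])]
      if (any(!is_a)) alle[!is_a] <- src_b[cbind(dm[!is_a], idx[!is_a])]
      haps[h, idx] <- alle
      anc[h, idx] <- a
      donor[h, idx] <- dm
      seg_starts <- which(events)
      seg_ends <- c(seg_starts[-1] - 1L, length(idx))
      sg_h[[ci]] <- tibble(
        haploid = h, chrom = snp$chrom[idx[1]],
        start_idx = idx[seg_starts], end_idx = idx[seg_ends],
        source = ifelse(anc_seg == 1L, "a", "b"),
        donor = donor_seg
      )
    }
    segs[[h]] <- bind_rows(sg_h)
  }
  list(haps = haps, anc = anc, donor = donor, segments = bind_rows(segs),
       large_n = min(dph_a, dph_b) == 1,
       donors_per_haploid = c(a = dph_a, b = dph_b))
}

split_private <- function(n_pool, n_haploid, dph) {
  perm <- sample.int(n_pool)
  purrr::map(seq_len(n_haploid), function(h) perm[((h - 1) * dph + 1):(h * dph)])
}

# One donor per segment from the haploid's private subsets; a new
# segment never keeps the previous donor unless it is the only private
# donor of that ancestry.
pick_donors <- function(anc_seg, priv_a, priv_b) {
  out <- integer(length(anc_seg))
  prev <- NA_integer_
  for (s in seq_along(anc_seg)) {
    set <- if (anc_seg[s] == 1L) priv_a else priv_b
    choices <- if (length(set) > 1 && !is.na(prev)) setdiff(set, prev) else set
    out[s] <- choices[sample.int(length(choices), 1)]
    prev <- out[s]
  }
  out
}

# Ancestry tracts (runs of constant ancestry per haploid chromosome)
# from a haploid-by-SNP 0/1 ancestry matrix.
tracts_from_anc <- function(anc, snp) {
  chr_idx <- split(seq_len(nrow(snp)), snp$chrom)
  out <- vector("list", nrow(anc) * length(chr_idx))
  k <- 0
  for (h in seq_len(nrow(anc))) {
    for (ci in seq_along(chr_idx)) {
      idx <- chr_idx[[ci]]
      r <- rle(anc[h, idx])
      ends <- cumsum(r$lengths)
      starts <- c(1L, head(ends, -1) + 1L)
      k <- k + 1
      out[[k]] <- tibble(
        haploid = h, chrom = snp$chrom[idx[1]],
        start_m = snp$genetic_pos[idx[starts]],
        end_m = snp$genetic_pos[idx[ends]],
        start_bp = snp$physical_pos[idx[starts]],
        end_bp = snp$physical_pos[idx[ends]],
        ancestry = ifelse(r$values == 1L, "A", "B"),
        n_snps = r$lengths,
        censored = starts == 1L | ends == length(idx)
      )
    }
  }
  bind_rows(out)
}

# Assemble the user-facing cohort object from engine output.
build_cohort <- function(mh, snp, n_diploid, params, anc = NULL) {
  anc <- anc %||% mh$anc
  n_haploid <- 2L * n_diploid
  tracts <- tracts_from_anc(anc, snp)
  ind <- tibble(
    individual_id = sprintf("adm%03d", seq_len(n_diploid)),
    sex = "U", population = "ADMIXED"
  )
  tracts$individual_id <- ind$individual_id[(tracts$haploid + 1L) %/% 2L]
  geno <- t(mh$haps[seq(1, n_haploid, by = 2), , drop = FALSE] +
              mh$haps[seq(2, n_haploid, by = 2), , drop = FALSE])
  realized <- tracts %>%
    group_by(.data$individual_id) %>%
    summarise(
      ancestry_a = sum((.data$end_m - .data$start_m)[.data$ancestry == "A"]) /
        sum(.data$end_m - .data$start_m),
      .groups = "drop"
    )
  structure(
    list(
      geno = geno, snp = snp, ind = ind, tracts = tracts,
      segments = mh$segments, realized_ancestry = realized,
      params = c(params, list(n_diploid = n_diploid, large_n = mh$large_n,
                              donors_per_haploid = mh$donors_per_haploid))
    ),
    class = c("admix_cohort", "admix_geno")
  )
}

#' Simulate a single-pulse admixed cohort
#'
#' Builds admixed diploid genomes as mosaics of donor haplotypes from
#' the two ancestral pools. Along each haploid chromosome, ancestry is
#' initialised as pool A with probability `theta`, and at each marker a
#' resampling event occurs with probability `1 - exp(-lambda * g)` (`g`
#' the genetic gap in Morgans), after which ancestry is redrawn with
#' probability `theta` — the marker-level realisation of recombination
#' over `lambda` generations since a one-off mixture event. True
#' local-ancestry tracts are recorded; the expected length of a pool-A
#' tract is `1 / (lambda (1 - theta))` Morgans.
#'
#' @param pools A `hap_pools` object.
#' @param n_diploid Number of admixed diploids (default 10).
#' @param theta Pool-A mixture proportion: a scalar, or one value per
#'   diploid (both haploids of an individual share its value).
#' @param lambda Generations since mixture (> 0).
#' @param seed Integer seed.
#' @return An `admix_cohort`: `geno` (SNP x individual), `snp`, `ind`,
#'   `tracts` (true ancestry tracts with genetic/physical bounds and a
#'   censoring flag for tracts touching chromosome ends), `segments`
#'   (donor-copy segments), `realized_ancestry` and `params`. Usable
#'   directly by [allele_frequencies()], [rolloff_date()] and
#'   [write_eigenstrat()].
#' @export
simulate_pulse <- function(pools, n_diploid = 10, theta = 0.2, lambda,
                           seed = NULL) {
  stopifnot(lambda > 0, all(theta >= 0 & theta <= 1))
  if (!is.null(seed)) set.seed(seed)
  th <- rep(rep_len(theta, n_diploid), each = 2)
  anc_fun <- function(gaps, hap) {
    e <- runif(length(gaps)) < -expm1(-lambda * gaps)
    e[1] <- TRUE
    seg <- cumsum(e)
    anc_seg <- rbinom(seg[length(seg)], 1L, th[hap])
    list(anc = anc_seg[seg], events = e)
  }
  mh <- mosaic_haplotypes(pools$pool_a, pools$pool_b, pools$snp,
                          2L * n_diploid, anc_fun)
  build_cohort(mh, pools$snp, n_diploid,
               list(schedule = "pulse", theta = theta, lambda = lambda))
}

#' Simulate two successive admixture pulses
#'
#' Sequential composition of two mixture events, mirroring the
#' two-stage construction used to probe single-exponential dating of
#' multi-pulse histories: first an intermediate admixed population is
#' built from the pools at `lambda1` generations with pool-A proportion
#' `theta1`; then the final cohort is built at `lambda2` generations by
#' copying segments from those intermediate mosaic haplotypes (kept with
#' probability `theta2`) or from fresh pool-B haplotypes. Crossing a
#' recent-event breakpoint therefore lands on a different intermediate
#' individual, decorrelating the older event's ancestry — the behaviour
#' of a real two-pulse genealogy. Expected final pool-A ancestry is
#' `theta1 * theta2`. The pool-B haplotypes are split between the two
#' stages so no donor serves both.
#'
#' @param pools A `hap_pools` object.
#' @param n_diploid Number of admixed diploids (default 10).
#' @param lambda1,theta1 Age (generations) and pool-A proportion of the
#'   older event; `lambda1 > lambda2`.
#' @param lambda2,theta2 Age of the recent event and the proportion of
#'   incumbent (admixed) lineages retained by it.
#' @param n_intermediate Haploids in the intermediate population
#'   (default `4 * n_diploid`).
#' @param seed Integer seed.
#' @return An `admix_cohort`; see [simulate_pulse()]. `segments` refer
#'   to the final-stage copy (donor source `"a"` = intermediate
#'   population).
#' @export
simulate_double_pulse <- function(pools, n_diploid = 10, lambda1, theta1,
                                  lambda2, theta2,
                                  n_intermediate = 4 * n_diploid,
                                  seed = NULL) {
  stopifnot(lambda1 > lambda2, lambda2 > 0,
            theta1 >= 0, theta1 <= 1, theta2 >= 0, theta2 <= 1)
  if (!is.null(seed)) set.seed(seed)
  nb <- nrow(pools$pool_b)
  b1 <- seq_len(nb %/% 2)
  pulse_fun <- function(lambda, p) {
    function(gaps, hap) {
      e <- runif(length(gaps)) < -expm1(-lambda * gaps)
      e[1] <- TRUE
      seg <- cumsum(e)
      anc_seg <- rbinom(seg[length(seg)], 1L, p)
      list(anc = anc_seg[seg], events = e)
    }
  }
  stage1 <- mosaic_haplotypes(pools$pool_a, pools$pool_b[b1, , drop = FALSE],
                              pools$snp, n_intermediate,
                              pulse_fun(lambda1, theta1))
  stage2 <- mosaic_haplotypes(stage1$haps, pools$pool_b[-b1, , drop = FALSE],
                              pools$snp, 2L * n_diploid,
                              pulse_fun(lambda2, theta2))
  # final ancestry: fresh pool-B segments are B; incumbent segments carry
  # the local ancestry of the intermediate donor they copied
  keep <- stage2$anc == 1L
  anc <- matrix(0L, nrow(stage2$anc), ncol(stage2$anc))
  col_idx <- col(stage2$anc)
  anc[keep] <- stage1$anc[cbind(stage2$donor[keep], col_idx[keep])]
  build_cohort(stage2, pools$snp, n_diploid,
               list(schedule = "double_pulse", lambda1 = lambda1,
                    theta1 = theta1, lambda2 = lambda2, theta2 = theta2,
                    n_intermediate = n_intermediate),
               anc = anc)
}

#' Simulate continuous gene flow over an interval of generations
#'
#' Gene flow from pool B into a pool-A population during generations
#' `[a, b]` before present: in each of the `k = b - a + 1` generations a
#' migrant fraction `m`, solved from `(1 - m)^k = 1 - total_theta`,
#' enters the population. Lineages are claimed by generation `t`'s
#' migrants with probability `m` on segments of that generation's
#' breakpoint process; breakpoints are nested across generations (a
#' lineage switch at generation `t` also re-draws all older claims), so
#' each migrant cohort's tracts break down at the rate set by its own
#' residence time. A locus is pool-B if any generation claimed it.
#'
#' @param pools A `hap_pools` object.
#' @param n_diploid Number of admixed diploids (default 10).
#' @param a,b Start (recent end) and end (old end) of the gene-flow
#'   interval in generations before present, `0 < a <= b` (integers).
#' @param total_theta Total pool-B ancestry after the interval, in
#'   (0, 1) (default 0.2).
#' @param seed Integer seed.
#' @return An `admix_cohort`; see [simulate_pulse()]. Ancestry `"A"` in
#'   the tracts is the incumbent pool-A population.
#' @export
simulate_continuous <- function(pools, n_diploid = 10, a, b,
                                total_theta = 0.2, seed = NULL) {
  if (total_theta <= 0 || total_theta >= 1) abort("total_theta must lie in (0, 1)")
  stopifnot(a > 0, b >= a, a == round(a), b == round(b))
  if (!is.null(seed)) set.seed(seed)
  k <- b - a + 1
  m <- 1 - (1 - total_theta)^(1 / k)
  anc_fun <- function(gaps, hap) {
    n <- length(gaps)
    # per-generation breakpoints at 1 Morgan per generation, accumulated
    # so that generation t's claims resample at union(gen 1..t) events
    p_gen <- -expm1(-gaps)
    e_cum <- rep(FALSE, n)
    claimed <- rep(FALSE, n)
    events <- rep(FALSE, n)
    for (t in seq_len(b)) {
      e_cum <- e_cum | (runif(n) < p_gen)
      e_cum[1] <- TRUE
      if (t >= a) {
        seg <- cumsum(e_cum)
        lab <- rbinom(seg[n], 1L, m)[seg]
        claimed <- claimed | lab == 1L
        events <- events | e_cum
      }
    }
    list(anc = 1L - as.integer(claimed), events = events)
  }
  mh <- mosaic_haplotypes(pools$pool_a, pools$pool_b, pools$snp,
                          2L * n_diploid, anc_fun)
  build_cohort(mh, pools$snp, n_diploid,
               list(schedule = "continuous", a = a, b = b,
                    total_theta = total_theta, m = m))
}

#' @export
print.admix_cohort <- function(x, ...) {
  cat(sprintf(
    "<admix_cohort> %d diploids (%s schedule), %d SNPs, mean pool-A ancestry %.3f\n",
    x$params$n_diploid, x$params$schedule, nrow(x$snp),
    mean(x$realized_ancestry$ancestry_a)
  ))
  invisible(x)
}
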