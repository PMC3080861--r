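#' Read an EIGENSTRAT geno/snp/ind triplet
#'
#' Reads genotypes in the EIGENSTRAT text convention: the `.geno` file has
#' one row per SNP and one character per individual, with `0`, `1`, `2`
#' counting copies of the reference allele and `9` marking a missing call.
#' The `.snp` file gives, per SNP, its identifier, chromosome, genetic
#' position in Morgans and physical position in base pairs; the `.ind`
#' file gives individual id, sex code and population label.
#'
#' @param geno_path,snp_path,ind_path Paths to the three files.
#' @return An object of class `admix_geno`: a list with
#'   * `geno` — integer matrix, SNPs in rows, individuals in columns,
#'     `NA` for missing calls;
#'   * `snp` — tibble with `snp_id`, `chrom`, `genetic_pos` (Morgans),
#'     `physical_pos` (bp, 1-based);
#'   * `ind` — tibble with `individual_id`, `sex`, `population`.
#' @seealso [write_eigenstrat()], [allele_frequencies()]
#' @export
read_eigenstrat <- function(geno_path, snp_path, ind_path) {
  for (p in c(geno_path, snp_path, ind_path)) {
    if (!file.exists(p)) abort(paste0("file not found: ", p))
  }
  snp <- read_snp_file(snp_path)
  ind <- read_ind_file(ind_path)
  lines <- readLines(geno_path)
  lines <- lines[nzchar(lines)]
  if (length(lines) != nrow(snp)) {
    abort(sprintf(
      "geno/snp dimension mismatch: %d genotype rows but %d SNPs in '%s'",
      length(lines), nrow(snp), snp_path
    ))
  }
  widths <- nchar(lines)
  bad <- which(widths != nrow(ind))
  if (length(bad)) {
    abort(sprintf(
      "geno/ind dimension mismatch at geno row %d: %d characters but %d individuals",
      bad[1], widths[bad[1]], nrow(ind)
    ))
  }
  chars <- strsplit(lines, "", fixed = TRUE)
  flat <- unlist(chars, use.names = FALSE)
  ok <- flat %in% c("0", "1", "2", "9")
  if (!all(ok)) {
    row <- ceiling(which(!ok)[1] / nrow(ind))
    abort(sprintf(
      "invalid genotype character '%s' at geno row %d (allowed: 0, 1, 2, 9)",
      flat[which(!ok)[1]], row
    ))
  }
  g <- matrix(as.integer(flat), nrow = nrow(snp), ncol = nrow(ind), byrow = TRUE)
  g[g == 9L] <- NA_integer_
  new_admix_geno(g, snp, ind)
}

read_snp_file <- function(path) {
  tab <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 4) abort("snp file needs >= 4 columns (id, chrom, genetic, physical)")
  tibble(
    snp_id = as.character(tab[[1]]),
    chrom = as.integer(tab[[2]]),
    genetic_pos = as.numeric(tab[[3]]),
    physical_pos = as.numeric(tab[[4]])
  )
}

read_ind_file <- function(path) {
  tab <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 3) abort("ind file needs 3 columns (id, sex, population)")
  out <- tibble(
    individual_id = as.character(tab[[1]]),
    sex = as.character(tab[[2]]),
    population = as.character(tab[[3]])
  )
  if (anyDuplicated(out$individual_id)) abort("duplicated individual_id in ind file")
  if (any(!nzchar(out$population))) abort("empty population label in ind file")
  out
}

new_admix_geno <- function(geno, snp, ind) {
  stopifnot(nrow(geno) == nrow(snp), ncol(geno) == nrow(ind))
  structure(list(geno = geno, snp = snp, ind = ind), class = "admix_geno")
}

#' @export
print.admix_geno <- function(x, ...) {
  cat(sprintf(
    "<admix_geno> %d SNPs x %d individuals, %d chromosome(s), %d population(s)\n",
    nrow(x$snp), nrow(x$ind), length(unique(x$snp$chrom)),
    length(unique(x$ind$population))
  ))
  invisible(x)
}

#' Write an EIGENSTRAT geno/snp/ind triplet
#'
#' Inverse of [read_eigenstrat()]; `NA` genotypes are written as `9`.
#'
#' @param x An `admix_geno` (or `admix_cohort`) object.
#' @param prefix Output path prefix; writes `<prefix>.geno`, `<prefix>.snp`,
#'   `<prefix>.ind`.
#' @return `prefix`, invisibly.
#' @export
write_eigenstrat <- function(x, prefix) {
  g <- x$geno
  g[is.na(g)] <- 9L
  lines <- apply(g, 1, paste, collapse = "")
  writeLines(lines, paste0(prefix, ".geno"))
  snp <- x$snp
  utils::write.table(
    data.frame(snp$snp_id, snp$chrom, format(snp$genetic_pos, digits = 10),
               snp$physical_pos),
    paste0(prefix, ".snp"),
    quote = FALSE, row.names = FALSE, col.names = FALSE
  )
  ind <- x$ind
  sex <- if ("sex" %in% names(ind)) ind$sex else "U"
  utils::write.table(
    data.frame(ind$individual_id, sex, ind$population),
    paste0(prefix, ".ind"),
    quote = FALSE, row.names = FALSE, col.names = FALSE
  )
  invisible(prefix)
}

#' Read a genetic map
#'
#' Whitespace-delimited text with three columns: chromosome, physical
#' position (bp) and cumulative genetic position (cM). A header line is
#' detected and skipped if the second field is non-numeric.
#'
#' @param path Path to the map file.
#' @return Tibble with `chrom`, `physical_pos` (bp) and `genetic_cm`.
#' @export
read_genetic_map <- function(path) {
  first <- readLines(path, n = 1)
  fields <- strsplit(trimws(first), "[[:space:]]+")[[1]]
  skip <- if (length(fields) >= 2 && is.na(suppressWarnings(as.numeric(fields[2])))) 1 else 0
  tab <- utils::read.table(path, header = FALSE, skip = skip, stringsAsFactors = FALSE)
  if (ncol(tab) < 3) abort("genetic map needs 3 columns (chrom, bp, cM)")
  tibble(
    chrom = as.integer(tab[[1]]),
    physical_pos = as.numeric(tab[[2]]),
    genetic_cm = as.numeric(tab[[3]])
  )
}

#' Interpolate genetic positions from a genetic map
#'
#' Fills `genetic_pos` (Morgans) for each SNP by linear interpolation of
#' the map's cumulative cM against physical position, per chromosome.
#' Positions beyond the ends of the map are clamped to the terminal map
#' value rather than extrapolated, which avoids negative or runaway
#' distances at chromosome ends.
#'
#' @param snps SNP tibble with `snp_id`, `chrom`, `physical_pos` (as in
#'   [read_eigenstrat()]'s `$snp`).
#' @param map Genetic map tibble from [read_genetic_map()] (columns
#'   `chrom`, `physical_pos`, `genetic_cm`).
#' @return `snps` with `genetic_pos` replaced by interpolated Morgans.
#' @export
interpolate_genetic_map <- function(snps, map) {
  missing_chr <- setdiff(unique(snps$chrom), unique(map$chrom))
  if (length(missing_chr)) {
    abort(paste0(
      "chromosome(s) absent from genetic map: ",
      paste(missing_chr, collapse = ", ")
    ))
  }
  out <- snps
  out$genetic_pos <- NA_real_
  for (ch in unique(snps$chrom)) {
    mi <- map[map$chrom == ch, ]
    mi <- mi[order(mi$physical_pos), ]
    if (nrow(mi) < 2) abort(sprintf("need >= 2 map points on chromosome %s", ch))
    sel <- out$chrom == ch
    g <- approx(mi$physical_pos, mi$genetic_cm, xout = out$physical_pos[sel],
                rule = 2, ties = "ordered")$y
    out$genetic_pos[sel] <- g / 100 # cM -> Morgans
  }
  out
}

#' Import genotypes from a VCF file
#'
#' Reduces a VCF to biallelic SNPs and returns the same `admix_geno`
#' container as [read_eigenstrat()]. Genotypes count ALT alleles; a
#' population label must be supplied per sample (default: one population
#' named `"POP"`). Requires the `vcfR` package.
#'
#' @param path Path to a VCF (plain or bgzipped).
#' @param populations Named character vector mapping sample id to
#'   population label, or a single label recycled to all samples.
#' @return An `admix_geno` object. `genetic_pos` is set to `NA` and should
#'   be filled with [interpolate_genetic_map()].
#' @export
read_vcf_genotypes <- function(path, populations = "POP") {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    abort("read_vcf_genotypes() requires the 'vcfR' package")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  biallelic <- vcfR::is.biallelic(v)
  v <- v[biallelic, ]
  gt <- vcfR::extract.gt(v, element = "GT")
  count_alt <- function(s) {
    ifelse(is.na(s) | grepl("\\.", s), NA_integer_,
           vapply(strsplit(gsub("\\|", "/", s), "/", fixed = TRUE),
                  function(a) sum(a == "1"), integer(1)))
  }
  g <- apply(gt, 2, count_alt)
  if (is.null(dim(g))) g <- matrix(g, nrow = nrow(gt))
  fix <- vcfR::getFIX(v)
  snp <- tibble(
    snp_id = ifelse(is.na(fix[, "ID"]) | fix[, "ID"] == ".",
                    paste0(fix[, "CHROM"], "_", fix[, "POS"]), fix[, "ID"]),
    chrom = suppressWarnings(as.integer(fix[, "CHROM"])),
    genetic_pos = NA_real_,
    physical_pos = as.numeric(fix[, "POS"])
  )
  samples <- colnames(gt)
  pop <- if (length(populations) == 1 && is.null(names(populations))) {
    rep(populations, length(samples))
  } else {
    unname(populations[samples])
  }
  ind <- tibble(individual_id = samples, sex = "U", population = pop)
  new_admix_geno(matrix(as.integer(g), nrow = nrow(snp)), snp, ind)
}
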