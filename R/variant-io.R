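#' Read a multi-sample VCF into a genotype matrix
#'
#' Reads biallelic SNP records from a VCF (via vcfR) together with a
#' sample-to-population map. Phase is preserved for sites whose GT field uses
#' the `|` separator in every sample; sites with any unphased genotype keep
#' their dosages but are flagged as phase-unavailable. Multi-allelic and
#' non-SNP records are skipped and counted.
#'
#' @param path Path to a VCF (4.x) file.
#' @param population_map Either a path to a headerless two-column TSV
#'   (`sample<TAB>population`) or a `data.frame` with columns `sample` and
#'   `population`. Every VCF sample must be present.
#' @return A [genotype_matrix()]; the number of skipped records is attached as
#'   attribute `n_skipped`.
#' @export
read_vcf <- function(path, population_map) {
  popmap <- read_population_map(population_map)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]
  keep <- !is.na(alt) & nchar(ref) == 1 & nchar(alt) == 1 &
    ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  n_skipped <- sum(!keep)
  if (n_skipped > 0) {
    message(n_skipped, " multi-allelic or non-SNP record(s) skipped")
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = 1, dimnames = list(NULL, names(gt)))
  gt <- gt[keep, , drop = FALSE]
  fix <- fix[keep, , drop = FALSE]
  samples <- colnames(gt)
  missing <- setdiff(samples, popmap$sample)
  if (length(missing) > 0) {
    stop("sample(s) missing from population map: ", paste(missing, collapse = ", "))
  }

  ok <- is.na(gt) | grepl("^[0-9.]([|/][0-9.])?$", gt)
  if (any(!ok)) {
    bad <- which(!ok, arr.ind = TRUE)[1, ]
    stop("malformed GT '", gt[!ok][1], "' at record ", bad[1],
         " (", fix[bad[1], "CHROM"], ":", fix[bad[1], "POS"],
         "), sample ", samples[bad[2]])
  }

  a1c <- substr(gt, 1, 1)
  sep <- substr(gt, 2, 2)
  a2c <- substr(gt, 3, 3)
  haploid <- !is.na(gt) & sep == ""
  a2c[haploid] <- a1c[haploid]
  a1 <- matrix(suppressWarnings(as.integer(a1c)), nrow = nrow(gt))
  a2 <- matrix(suppressWarnings(as.integer(a2c)), nrow = nrow(gt))
  dos <- a1 + a2
  phased_cell <- !is.na(gt) & sep == "|"
  # a site offers haplotypes only if every sample is phased and genotyped there
  phased_site <- rowSums(phased_cell & !is.na(a1) & !is.na(a2)) == length(samples)

  m <- nrow(gt)
  hap <- matrix(NA_integer_, nrow = 2L * length(samples), ncol = m)
  for (j in seq_along(samples)) {
    hap[2L * j - 1L, phased_site] <- a1[phased_site, j]
    hap[2L * j, phased_site] <- a2[phased_site, j]
  }
  dosages <- t(dos)
  rownames(dosages) <- samples

  chrom_lengths <- vcf_contig_lengths(v)
  pops <- stats::setNames(popmap$population, popmap$sample)
  gm <- genotype_matrix(
    dosages = dosages,
    chrom = fix[, "CHROM"], pos = as.numeric(fix[, "POS"]),
    ref = ref[keep], alt = alt[keep],
    populations = pops[samples],
    haplotypes = if (any(phased_site)) hap,
    phased = phased_site,
    chrom_lengths = chrom_lengths
  )
  attr(gm, "n_skipped") <- n_skipped
  gm
}

#' Read a sample-to-population map
#' @param x Path to a headerless TSV (`sample<TAB>population`) or a
#'   `data.frame` with columns `sample` and `population`.
#' @return `data.frame` with columns `sample`, `population`.
#' @export
read_population_map <- function(x) {
  if (is.data.frame(x)) {
    stopifnot(all(c("sample", "population") %in% names(x)))
    return(x[, c("sample", "population")])
  }
  df <- utils::read.table(x, sep = "\t", header = FALSE,
                          col.names = c("sample", "population"),
                          stringsAsFactors = FALSE)
  df
}

vcf_contig_lengths <- function(v) {
  meta <- v@meta
  contig <- grep("^##contig=", meta, value = TRUE)
  if (length(contig) == 0) return(NULL)
  ids <- sub(".*ID=([^,>]+).*", "\\1", contig)
  lens <- suppressWarnings(as.numeric(sub(".*length=([0-9]+).*", "\\1", contig)))
  if (anyNA(lens)) return(NULL)
  stats::setNames(lens, ids)
}

#' Write a genotype matrix as VCF 4.2
#'
#' Emits GT-only records; phased sites use the `|` separator, unphased sites
#' `/`. Contig headers carry the chromosome lengths.
#'
#' @param gm A [genotype_matrix()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_vcf <- function(gm, path) {
  n <- n_samples(gm)
  m <- n_sites(gm)
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=charrscan",
    sprintf("##contig=<ID=%s,length=%d>", names(gm$chrom_lengths),
            as.integer(gm$chrom_lengths)),
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", gm$samples), collapse = "\t")
  )
  gt <- matrix("./.", nrow = m, ncol = n)
  if (!is.null(gm$haplotypes)) {
    h1 <- t(gm$haplotypes[seq(1L, 2L * n, 2L), , drop = FALSE])
    h2 <- t(gm$haplotypes[seq(2L, 2L * n, 2L), , drop = FALSE])
  } else {
    h1 <- h2 <- NULL
  }
  dos <- t(gm$dosages)
  for (j in seq_len(n)) {
    if (!is.null(h1)) {
      ph <- gm$phased & !is.na(h1[, j])
      gt[ph, j] <- paste0(h1[ph, j], "|", h2[ph, j])
      un <- !ph & !is.na(dos[, j])
    } else {
      un <- !is.na(dos[, j])
    }
    gt[un, j] <- c("0/0", "0/1", "1/1")[dos[un, j] + 1L]
  }
  body <- paste(gm$chrom, format(gm$pos, scientific = FALSE, trim = TRUE),
                ".", gm$ref, gm$alt, ".", "PASS", ".", "GT",
                apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Filter sites on minor allele frequency and call rate
#'
#' Mirrors the usual resequencing-panel filter ("MAF above 5%, call rate
#' 100%"). The MAF comparison is strict (`maf > maf_min`) by default, matching
#' a reading of "above"; set `maf_inclusive = TRUE` for `>=`. `maf_min = 0`
#' disables the MAF filter entirely, so `filter_sites(gm, 0, 0)` is the
#' identity.
#'
#' @param gm A [genotype_matrix()].
#' @param maf_min Minor allele frequency threshold in `[0, 1]`.
#' @param call_rate_min Minimum fraction of genotyped samples per site.
#' @param maf_inclusive Use `>=` instead of `>` for the MAF comparison.
#' @return The filtered `genotype_matrix` (a warning is emitted when no site
#'   survives).
#' @export
filter_sites <- function(gm, maf_min = 0.05, call_rate_min = 1.0,
                         maf_inclusive = FALSE) {
  stopifnot(maf_min >= 0, maf_min <= 1, call_rate_min >= 0, call_rate_min <= 1)
  af <- allele_freq(gm)
  maf <- pmin(af, 1 - af)
  call_rate <- colMeans(!is.na(gm$dosages))
  keep_maf <- if (maf_min == 0) {
    rep(TRUE, n_sites(gm))
  } else if (maf_inclusive) {
    !is.na(maf) & maf >= maf_min
  } else {
    !is.na(maf) & maf > maf_min
  }
  keep <- keep_maf & call_rate >= call_rate_min
  if (!any(keep)) warning("no site passed the filters; returning an empty matrix")
  subset_sites(gm, keep)
}

#' SNP density in non-overlapping windows
#'
#' Tiles each chromosome with non-overlapping windows starting at 0 and counts
#' SNPs per window; density is reported in SNPs/kb.
#'
#' @param gm A [genotype_matrix()].
#' @param window Window size in bp (default 100 kb).
#' @return `data.frame` with columns `chrom`, `start`, `end` (0-based
#'   half-open), `n_snps`, `density` (SNPs/kb).
#' @export
snp_density <- function(gm, window = 1e5) {
  stopifnot(window > 0)
  out <- list()
  for (cc in names(gm$chrom_lengths)) {
    len <- gm$chrom_lengths[[cc]]
    starts <- seq(0, max(0, len - 1), by = window)
    p <- gm$pos[gm$chrom == cc]
    # positions are 1-based; window [s, s+window) covers pos s+1 .. s+window
    counts <- as.vector(table(factor(
      findInterval(p - 1, starts), levels = seq_along(starts))))
    out[[cc]] <- data.frame(
      chrom = cc, start = starts, end = pmin(starts + window, len),
      n_snps = counts, density = counts / (window / 1000)
    )
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
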