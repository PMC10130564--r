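#' Genotype matrix container
#'
#' The central data structure of the package: an ordered set of biallelic SNP
#' sites genotyped across samples from (typically two) populations. Dosages
#' count copies of the alternate allele (0, 1, 2 or `NA` for missing). When
#' phase is known, haplotypes are stored as a `2 * n_samples x n_sites` 0/1
#' matrix whose rows `2i - 1` and `2i` are the two chromosomes of sample `i`.
#'
#' @param dosages Integer matrix, samples in rows (rownames are sample ids),
#'   sites in columns, entries in `{0, 1, 2, NA}`.
#' @param chrom Character vector of chromosome ids per site. Sites must be
#'   grouped by chromosome with strictly increasing positions inside each.
#' @param pos Integer vector of 1-based physical positions per site.
#' @param ref,alt Single-character reference / alternate alleles per site
#'   (defaults `"A"` / `"C"` when not supplied, e.g. for simulated data).
#' @param populations Named character vector mapping sample id to population
#'   label; every sample must be present.
#' @param haplotypes Optional integer matrix of phased haplotypes
#'   (`2 * n_samples` rows, sites in columns, entries 0/1 or `NA`).
#' @param phased Optional logical per site: is phase available at this site for
#'   all samples? Defaults to all `TRUE` when `haplotypes` is given.
#' @param chrom_lengths Optional named numeric vector of chromosome lengths in
#'   bp; defaults to the last observed position per chromosome.
#'
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(dosages, chrom, pos, ref = NULL, alt = NULL,
                            populations, haplotypes = NULL, phased = NULL,
                            chrom_lengths = NULL) {
  dosages <- as.matrix(dosages)
  if (is.null(rownames(dosages))) {
    stop("`dosages` must carry sample ids as rownames")
  }
  n <- nrow(dosages)
  m <- ncol(dosages)
  chrom <- as.character(chrom)
  pos <- as.numeric(pos)
  if (length(chrom) != m || length(pos) != m) {
    stop("`chrom` and `pos` must have one entry per site (column of `dosages`)")
  }
  if (is.null(ref)) ref <- rep("A", m)
  if (is.null(alt)) alt <- rep("C", m)
  bad <- setdiff(rownames(dosages), names(populations))
  if (length(bad) > 0) {
    stop("samples missing from population map: ", paste(bad, collapse = ", "))
  }
  populations <- populations[rownames(dosages)]

  # sites grouped by chromosome, strictly increasing positions within each
  blocks <- rle(chrom)$values
  if (anyDuplicated(blocks)) {
    stop("sites of one chromosome must form a single contiguous block")
  }
  for (cc in blocks) {
    p <- pos[chrom == cc]
    if (length(p) > 1 && any(diff(p) <= 0)) {
      stop("positions must be strictly increasing within chromosome ", cc)
    }
  }

  if (!is.null(haplotypes)) {
    haplotypes <- as.matrix(haplotypes)
    if (nrow(haplotypes) != 2L * n || ncol(haplotypes) != m) {
      stop("`haplotypes` must be a (2 * n_samples) x n_sites matrix")
    }
    if (is.null(phased)) phased <- rep(TRUE, m)
  } else if (is.null(phased)) {
    phased <- rep(FALSE, m)
  }
  phased <- rep_len(as.logical(phased), m)

  if (!is.null(haplotypes) && any(phased)) {
    h1 <- haplotypes[seq(1L, 2L * n, by = 2L), , drop = FALSE]
    h2 <- haplotypes[seq(2L, 2L * n, by = 2L), , drop = FALSE]
    sum_h <- h1 + h2
    chk <- phased & colSums(sum_h != dosages, na.rm = TRUE) > 0
    if (any(chk)) {
      stop("haplotypes inconsistent with dosages at ", sum(chk), " phased site(s)")
    }
  }

  if (is.null(chrom_lengths)) {
    chrom_lengths <- vapply(blocks, function(cc) max(pos[chrom == cc]), numeric(1))
  }
  chrom_lengths <- chrom_lengths[blocks[blocks %in% names(chrom_lengths)]]

  structure(
    list(
      samples = rownames(dosages),
      populations = populations,
      chrom = chrom,
      pos = pos,
      ref = ref,
      alt = alt,
      dosages = dosages,
      haplotypes = haplotypes,
      phased = phased,
      chrom_lengths = chrom_lengths
    ),
    class = "genotype_matrix"
  )
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf(
    "genotype_matrix: %d samples x %d sites on %d chromosome(s)\n",
    n_samples(x), n_sites(x), length(unique(x$chrom))
  ))
  tab <- table(x$populations)
  cat("populations:", paste(sprintf("%s (n=%d)", names(tab), tab), collapse = ", "), "\n")
  cat(sprintf(
    "phase: %d/%d sites phased; missing dosages: %d\n",
    sum(x$phased), n_sites(x), sum(is.na(x$dosages))
  ))
  invisible(x)
}

#' Number of samples / sites in a genotype matrix
#' @param gm A `genotype_matrix`.
#' @return Integer count.
#' @export
n_samples <- function(gm) length(gm$samples)

#' @rdname n_samples
#' @export
n_sites <- function(gm) length(gm$pos)

#' Site table of a genotype matrix
#' @param gm A `genotype_matrix`.
#' @return `data.frame` with columns chrom, pos, ref, alt.
#' @export
site_info <- function(gm) {
  data.frame(chrom = gm$chrom, pos = gm$pos, ref = gm$ref, alt = gm$alt,
             stringsAsFactors = FALSE)
}

#' Subset a genotype matrix by site index
#' @param gm A `genotype_matrix`.
#' @param idx Logical or integer site index (kept in genomic order).
#' @return A `genotype_matrix` restricted to the selected sites.
#' @export
subset_sites <- function(gm, idx) {
  if (is.logical(idx)) idx <- which(idx)
  idx <- sort(unique(as.integer(idx)))
  genotype_matrix(
    dosages = gm$dosages[, idx, drop = FALSE],
    chrom = gm$chrom[idx], pos = gm$pos[idx],
    ref = gm$ref[idx], alt = gm$alt[idx],
    populations = gm$populations,
    haplotypes = if (!is.null(gm$haplotypes)) gm$haplotypes[, idx, drop = FALSE],
    phased = gm$phased[idx],
    chrom_lengths = gm$chrom_lengths
  )
}

#' Subset a genotype matrix by sample id
#' @param gm A `genotype_matrix`.
#' @param samples Character vector of sample ids to keep.
#' @return A `genotype_matrix` restricted to the selected samples.
#' @export
subset_samples <- function(gm, samples) {
  miss <- setdiff(samples, gm$samples)
  if (length(miss) > 0) stop("unknown sample(s): ", paste(miss, collapse = ", "))
  ri <- match(samples, gm$samples)
  hap <- NULL
  if (!is.null(gm$haplotypes)) {
    hr <- as.vector(rbind(2L * ri - 1L, 2L * ri))
    hap <- gm$haplotypes[hr, , drop = FALSE]
  }
  genotype_matrix(
    dosages = gm$dosages[ri, , drop = FALSE],
    chrom = gm$chrom, pos = gm$pos, ref = gm$ref, alt = gm$alt,
    populations = gm$populations[samples],
    haplotypes = hap, phased = gm$phased,
    chrom_lengths = gm$chrom_lengths
  )
}

#' Samples belonging to one population
#' @param gm A `genotype_matrix`.
#' @param population Population label.
#' @return Character vector of sample ids.
#' @export
pop_samples <- function(gm, population) {
  s <- gm$samples[gm$populations[gm$samples] == population]
  if (length(s) == 0) stop("no samples in population '", population, "'")
  s
}

#' Alternate-allele frequencies
#'
#' Missing dosages are excluded from both numerator and denominator.
#'
#' @param gm A `genotype_matrix`.
#' @param samples Optional subset of sample ids.
#' @return Numeric vector of per-site ALT allele frequencies (`NaN` when no
#'   sample is genotyped).
#' @export
allele_freq <- function(gm, samples = NULL) {
  d <- gm$dosages
  if (!is.null(samples)) d <- d[match(samples, gm$samples), , drop = FALSE]
  colSums(d, na.rm = TRUE) / (2 * colSums(!is.na(d)))
}

# haplotype row indices for the given samples (interleaved hap1/hap2)
hap_rows <- function(gm, samples) {
  ri <- match(samples, gm$samples)
  as.vector(rbind(2L * ri - 1L, 2L * ri))
}
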