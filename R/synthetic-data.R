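#' Configuration for the two-population genotype simulator
#'
#' The simulator emulates a resequencing panel of two diverged farmed
#' populations: per-site population allele frequencies follow the
#' Balding-Nichols model around an ancestral frequency, and phased haplotypes
#' are built as mosaics of a small founder-haplotype pool so that linkage
#' disequilibrium decays with physical distance. Defaults reproduce the study
#' conditions the package is tested under: 2 x 24 diploids, SNP density of
#' ~2.6 SNPs/kb, between-population differentiation of ~0.12, and mean r^2
#' around 0.1 at 100 kb.
#'
#' In mosaic mode the finite founder pool itself adds differentiation on top
#' of the Balding-Nichols draw (an extra `(1 - F)/n_founders` in apparent
#' F_ST). The generator compensates by shrinking the Beta-draw parameter so
#' that the *realized* differentiation matches `fst_target`; targets below
#' `1/n_founders` cannot be reached in mosaic mode and trigger a warning.
#'
#' @param n_per_pop Diploid individuals per population.
#' @param chrom_lengths Named numeric vector of chromosome lengths in bp.
#' @param snp_spacing_mean Mean spacing between adjacent SNPs in bp
#'   (385 bp gives ~2.6 SNPs/kb).
#' @param spacing_dist `"poisson"` (exponential gaps, the default) or
#'   `"regular"` (gaps uniform in 0.5-1.5 times the mean). Regular spacing is
#'   useful when a gap-capped analysis (e.g. ROH detection with a 10 kb
#'   maximum gap) is run at coarse SNP density, where exponential gaps would
#'   exceed the cap by sampling noise alone -- a situation that does not arise
#'   at the resequencing density the defaults emulate.
#' @param fst_target Balding-Nichols divergence parameter F in `[0, 1)`.
#'   `0` means both populations share the ancestral frequencies.
#' @param ld_block_scale Mean founder-mosaic segment length in bp (per
#'   population; a length-2 vector gives each population its own scale).
#'   `0` disables the mosaic: sites are unlinked and drawn independently.
#' @param n_founders Founder haplotypes per population in mosaic mode.
#' @param ancestral_freq Either a length-2 numeric range for a Uniform draw of
#'   ancestral frequencies (default `c(0.1, 0.9)`, avoiding near-fixed sites
#'   that destabilize the Weir-Cockerham estimator) or a single positive
#'   number, used as the shape of a symmetric Beta draw (values below 1 give
#'   U-shaped frequency spectra and lower heterozygosity).
#' @param pop_labels Labels of the two populations.
#' @param seed Integer root seed; identical config + seed gives bit-identical
#'   output. Child streams are derived per chromosome and stage in a fixed
#'   order, so enlarging one chromosome does not reshuffle the others.
#'
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_per_pop = 24,
                       chrom_lengths = c(chr1 = 5e6, chr2 = 5e6),
                       snp_spacing_mean = 385,
                       fst_target = 0.12,
                       ld_block_scale = 3e5,
                       n_founders = 10,
                       ancestral_freq = c(0.1, 0.9),
                       pop_labels = c("pop1", "pop2"),
                       spacing_dist = c("poisson", "regular"),
                       seed = 1) {
  spacing_dist <- match.arg(spacing_dist)
  stopifnot(n_per_pop >= 1, snp_spacing_mean > 0, n_founders >= 2)
  if (fst_target < 0 || fst_target >= 1) stop("`fst_target` must lie in [0, 1)")
  if (is.null(names(chrom_lengths))) {
    names(chrom_lengths) <- paste0("chr", seq_along(chrom_lengths))
  }
  if (any(chrom_lengths <= 0)) stop("chromosome lengths must be positive")
  ld_block_scale <- rep_len(ld_block_scale, 2)
  if (any(ld_block_scale < 0)) stop("`ld_block_scale` must be >= 0")
  if (length(pop_labels) != 2 || anyDuplicated(pop_labels)) {
    stop("`pop_labels` must be two distinct labels")
  }
  structure(
    list(n_per_pop = as.integer(n_per_pop),
         chrom_lengths = chrom_lengths,
         snp_spacing_mean = snp_spacing_mean,
         fst_target = fst_target,
         ld_block_scale = ld_block_scale,
         n_founders = as.integer(n_founders),
         ancestral_freq = ancestral_freq,
         pop_labels = pop_labels,
         spacing_dist = spacing_dist,
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

# deterministic child seed, kept inside 32-bit integer range
child_seed <- function(seed, i) {
  as.integer((as.numeric(seed) + 104729 * as.numeric(i)) %% 2147483647)
}

draw_ancestral <- function(m, ancestral_freq) {
  if (length(ancestral_freq) == 2) {
    stats::runif(m, ancestral_freq[1], ancestral_freq[2])
  } else {
    a <- ancestral_freq[1]
    stopifnot(a > 0)
    pmin(pmax(stats::rbeta(m, a, a), 0.02), 0.98)
  }
}

# Balding-Nichols population frequency around ancestral p with parameter F
bn_freq <- function(p, f) {
  if (f == 0) return(p)  # degenerate Beta: both populations share p
  stats::rbeta(length(p), p * (1 - f) / f, (1 - p) * (1 - f) / f)
}

#' Simulate two diverged populations of phased diploids
#'
#' @param config A [sim_config()].
#' @return A [genotype_matrix()] with `2 * n_per_pop` phased samples.
#' @export
simulate_divergent_populations <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_per_pop
  k <- config$n_founders
  f_target <- config$fst_target
  mosaic <- config$ld_block_scale > 0

  # founder-pool drift adds (1 - F)/K of apparent differentiation per
  # population; shrink the Beta parameter so realized F_ST ~ fst_target
  f_eff <- f_target
  if (any(mosaic) && f_target > 0) {
    floor_f <- 1 / k
    if (f_target <= floor_f) {
      warning(sprintf(
        "fst_target %.3f is below the mosaic founder-drift floor 1/%d = %.3f; realized differentiation will be ~%.3f",
        f_target, k, floor_f, floor_f))
      f_eff <- 0
    } else {
      f_eff <- (f_target - floor_f) / (1 - floor_f)
    }
  }

  samples <- c(sprintf("%s_%02d", config$pop_labels[1], seq_len(n)),
               sprintf("%s_%02d", config$pop_labels[2], seq_len(n)))
  populations <- stats::setNames(rep(config$pop_labels, each = n), samples)

  chrom_l <- list(); pos_l <- list(); hap_l <- list()
  for (ci in seq_along(config$chrom_lengths)) {
    cc <- names(config$chrom_lengths)[ci]
    len <- config$chrom_lengths[ci]

    set.seed(child_seed(config$seed, 10 * ci))
    n_est <- ceiling(len / config$snp_spacing_mean * 1.4) + 20
    gaps <- if (identical(config$spacing_dist, "regular")) {
      pmax(1, round(stats::runif(n_est, 0.5, 1.5) * config$snp_spacing_mean))
    } else {
      pmax(1, round(stats::rexp(n_est, 1 / config$snp_spacing_mean)))
    }
    pos <- cumsum(gaps)
    pos <- pos[pos <= len]
    m <- length(pos)
    if (m == 0) next

    set.seed(child_seed(config$seed, 10 * ci + 1))
    p_anc <- draw_ancestral(m, config$ancestral_freq)
    p_pop <- list(bn_freq(p_anc, f_eff), bn_freq(p_anc, f_eff))

    hap <- matrix(0L, nrow = 4L * n, ncol = m)
    for (pi in 1:2) {
      rows <- (pi - 1L) * 2L * n + seq_len(2L * n)
      scale <- config$ld_block_scale[pi]
      set.seed(child_seed(config$seed, 10 * ci + 1 + pi))
      if (scale <= 0) {
        hap[rows, ] <- matrix(
          stats::rbinom(2L * n * m, 1L, rep(p_pop[[pi]], each = 2L * n)),
          nrow = 2L * n)
      } else {
        founders <- matrix(stats::rbinom(k * m, 1L, rep(p_pop[[pi]], each = k)),
                           nrow = k)
        n_seg_est <- ceiling(len / scale * 1.6) + 10
        for (h in rows) {
          seg_len <- stats::rexp(n_seg_est, 1 / scale)
          while (sum(seg_len) < len) {
            seg_len <- c(seg_len, stats::rexp(n_seg_est, 1 / scale))
          }
          bounds <- cumsum(seg_len)
          n_seg <- which(bounds >= len)[1]
          fid <- sample.int(k, n_seg, replace = TRUE)
          seg_of_site <- findInterval(pos, c(0, bounds[seq_len(n_seg - 1)]))
          hap[h, ] <- founders[cbind(fid[seg_of_site], seq_len(m))]
        }
      }
    }
    chrom_l[[cc]] <- rep(cc, m)
    pos_l[[cc]] <- pos
    hap_l[[cc]] <- hap
  }

  hap <- do.call(cbind, hap_l)
  chrom <- unlist(chrom_l, use.names = FALSE)
  pos <- unlist(pos_l, use.names = FALSE)
  h1 <- hap[seq(1L, nrow(hap), by = 2L), , drop = FALSE]
  h2 <- hap[seq(2L, nrow(hap), by = 2L), , drop = FALSE]
  dos <- h1 + h2
  rownames(dos) <- samples

  genotype_matrix(
    dosages = dos, chrom = chrom, pos = pos,
    populations = populations, haplotypes = hap,
    chrom_lengths = config$chrom_lengths
  )
}

#' Overwrite haplotypes with a core haplotype to mimic a selective sweep
#'
#' Within the given interval, a fraction of the target population's haplotypes
#' is replaced by one randomly chosen core haplotype, creating the extended
#' haplotype homozygosity that XP-EHH-style scans detect. The other population
#' is untouched.
#'
#' @param gm A phased [genotype_matrix()].
#' @param population Target population label.
#' @param chrom Chromosome id.
#' @param interval Numeric `[start, end)` in bp.
#' @param carrier_fraction Proportion of target-population haplotypes replaced,
#'   in `(0, 1]`.
#' @param seed Integer seed for the choice of core and carrier haplotypes.
#' @return The modified `genotype_matrix`.
#' @export
inject_sweep <- function(gm, population, chrom, interval, carrier_fraction,
                         seed = 1) {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (is.null(gm$haplotypes)) stop("`gm` carries no haplotypes; phase is required")
  if (carrier_fraction <= 0 || carrier_fraction > 1) {
    stop("`carrier_fraction` must lie in (0, 1]")
  }
  sites <- which(gm$chrom == chrom & gm$pos >= interval[1] & gm$pos < interval[2])
  if (length(sites) == 0) {
    stop("no SNPs in interval [", interval[1], ", ", interval[2], ") on ", chrom)
  }
  rows <- hap_rows(gm, pop_samples(gm, population))
  set.seed(seed)
  core <- sample(rows, 1)
  n_carrier <- max(1L, round(carrier_fraction * length(rows)))
  carriers <- sample(rows, n_carrier)
  core_hap <- gm$haplotypes[core, sites]
  gm$haplotypes[carriers, sites] <- matrix(core_hap, nrow = n_carrier,
                                           ncol = length(sites), byrow = TRUE)
  h1 <- gm$haplotypes[seq(1L, nrow(gm$haplotypes), 2L), sites, drop = FALSE]
  h2 <- gm$haplotypes[seq(2L, nrow(gm$haplotypes), 2L), sites, drop = FALSE]
  gm$dosages[, sites] <- h1 + h2
  gm
}

#' Inject autozygous tracts (runs of homozygosity)
#'
#' Within each specified interval the individual's second haplotype is
#' overwritten by its first, so every covered site becomes homozygous.
#'
#' @param gm A phased [genotype_matrix()].
#' @param specs `data.frame` with columns `individual`, `chrom`, `start`,
#'   `end` (bp, `[start, end)`); intervals of one individual must not overlap.
#' @return The modified `genotype_matrix`.
#' @export
inject_roh <- function(gm, specs) {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (is.null(gm$haplotypes)) stop("`gm` carries no haplotypes; phase is required")
  stopifnot(all(c("individual", "chrom", "start", "end") %in% names(specs)))
  if (any(specs$end - specs$start < 1)) stop("tract length must be >= 1 bp")
  for (ind in unique(specs$individual)) {
    s <- specs[specs$individual == ind, ]
    for (cc in unique(s$chrom)) {
      si <- s[s$chrom == cc, ]
      si <- si[order(si$start), ]
      if (nrow(si) > 1 && any(si$start[-1] < si$end[-nrow(si)])) {
        stop("overlapping tracts for individual ", ind, " on ", cc)
      }
    }
  }
  for (i in seq_len(nrow(specs))) {
    ind <- specs$individual[i]
    ri <- match(ind, gm$samples)
    if (is.na(ri)) stop("unknown individual: ", ind)
    sites <- which(gm$chrom == specs$chrom[i] &
                     gm$pos >= specs$start[i] & gm$pos < specs$end[i])
    if (length(sites) == 0) {
      warning("tract ", specs$chrom[i], ":", specs$start[i], "-", specs$end[i],
              " for ", ind, " contains no SNPs; genotypes unchanged")
      next
    }
    gm$haplotypes[2L * ri, sites] <- gm$haplotypes[2L * ri - 1L, sites]
    gm$dosages[ri, sites] <- 2L * gm$haplotypes[2L * ri - 1L, sites]
  }
  gm
}

#' Sample non-overlapping autozygous-tract specifications
#'
#' Draws, for every individual, tract lengths uniformly from `length_range`
#' until their sum reaches `total_fraction` of the genome exactly (the last
#' tract is trimmed; a remainder shorter than `length_range[1]` is folded into
#' the previous tract), then places them uniformly without overlap.
#'
#' @param gm A [genotype_matrix()] (provides chromosome lengths and samples).
#' @param total_fraction Target autozygous genome fraction per individual.
#' @param length_range Tract length range in bp (default 1-10 Mb).
#' @param min_gap Minimum distance between tracts of one individual (bp).
#' @param seed Integer seed.
#' @param samples Optional subset of individuals (default: all).
#' @return `data.frame` suitable for [inject_roh()].
#' @export
sample_roh_specs <- function(gm, total_fraction, length_range = c(1e6, 1e7),
                             min_gap = 5e4, seed = 1, samples = NULL) {
  stopifnot(total_fraction > 0, total_fraction < 1)
  if (is.null(samples)) samples <- gm$samples
  genome <- sum(gm$chrom_lengths)
  target <- total_fraction * genome
  set.seed(seed)
  out <- list()
  for (ind in samples) {
    lens <- numeric(0)
    while (sum(lens) < target) {
      lens <- c(lens, stats::runif(1, length_range[1], length_range[2]))
    }
    excess <- sum(lens) - target
    lens[length(lens)] <- lens[length(lens)] - excess
    if (lens[length(lens)] < length_range[1] && length(lens) > 1) {
      lens[length(lens) - 1] <- lens[length(lens) - 1] + lens[length(lens)]
      lens <- lens[-length(lens)]
    }
    lens <- round(lens)
    lens[1] <- lens[1] + (round(target) - sum(lens))  # keep the total exact
    placed <- data.frame(chrom = character(0), start = numeric(0), end = numeric(0))
    for (len in lens) {
      ok <- FALSE
      for (try in 1:2000) {
        cc <- sample(names(gm$chrom_lengths), 1,
                     prob = as.numeric(gm$chrom_lengths))
        cl <- gm$chrom_lengths[[cc]]
        if (cl < len) next
        st <- floor(stats::runif(1, 0, cl - len))
        en <- st + len
        same <- placed[placed$chrom == cc, ]
        if (nrow(same) == 0 ||
            all(en + min_gap <= same$start | st >= same$end + min_gap)) {
          placed <- rbind(placed, data.frame(chrom = cc, start = st, end = en))
          ok <- TRUE
          break
        }
      }
      if (!ok) stop("could not place tract of ", len, " bp for ", ind)
    }
    out[[ind]] <- data.frame(individual = ind, placed)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Write a simulated panel as a plain-text fixture set
#'
#' Emits a phased VCF 4.2, a population map TSV, a toy GFF3 with genes tiled
#' along each chromosome, and a term-to-gene TSV assigning the toy genes to
#' synthetic functional terms (for exercising the enrichment stage).
#'
#' @param gm A [genotype_matrix()].
#' @param out_dir Output directory (created if needed).
#' @param prefix File name prefix.
#' @param gene_every Gene spacing in bp (one gene starts every `gene_every`).
#' @param gene_width Gene width in bp.
#' @param n_terms Number of synthetic terms in the term map.
#' @return Invisibly, a named list of the written file paths.
#' @export
write_fixture <- function(gm, out_dir, prefix = "panel", gene_every = 2e5,
                          gene_width = 1e5, n_terms = 20) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    vcf = file.path(out_dir, paste0(prefix, ".vcf")),
    popmap = file.path(out_dir, paste0(prefix, ".popmap.tsv")),
    gff3 = file.path(out_dir, paste0(prefix, ".genes.gff3")),
    term_map = file.path(out_dir, paste0(prefix, ".terms.tsv"))
  )
  write_vcf(gm, paths$vcf)
  utils::write.table(
    data.frame(sample = gm$samples, population = unname(gm$populations[gm$samples])),
    paths$popmap, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)

  genes <- toy_genes(gm$chrom_lengths, gene_every, gene_width)
  gff <- c("##gff-version 3",
           sprintf("##sequence-region %s 1 %d", names(gm$chrom_lengths),
                   as.integer(gm$chrom_lengths)),
           sprintf("%s\tcharrscan\tgene\t%d\t%d\t.\t+\t.\tID=%s;Name=%s",
                   genes$chrom, genes$start1, genes$end1, genes$gene_id,
                   genes$gene_id))
  writeLines(gff, paths$gff3)

  # deterministic many-to-many term assignment with varied set sizes
  g <- seq_len(nrow(genes))
  term <- c(sprintf("term%02d", (g %% n_terms) + 1),
            sprintf("term%02d", ((g * 7L + 3L) %% n_terms) + 1))
  tg <- unique(data.frame(term = term, gene = rep(genes$gene_id, 2)))
  tg <- tg[order(tg$term, tg$gene), ]
  utils::write.table(tg, paths$term_map, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(paths)
}

# gene models tiled every `gene_every` bp; 1-based inclusive coordinates
toy_genes <- function(chrom_lengths, gene_every = 2e5, gene_width = 1e5) {
  out <- list()
  for (cc in names(chrom_lengths)) {
    starts0 <- seq(gene_every / 4, chrom_lengths[[cc]] - gene_width,
                   by = gene_every)
    if (length(starts0) == 0) next
    out[[cc]] <- data.frame(
      chrom = cc,
      start1 = as.integer(starts0 + 1),
      end1 = as.integer(starts0 + gene_width),
      gene_id = sprintf("%s_g%03d", cc, seq_along(starts0))
    )
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Simulate aligned mitogenome sequences with programmed mutation distances
#'
#' Builds haplotype groups on a star-like topology with disjoint mutated
#' positions, so that every pairwise Hamming distance is the exact sum of the
#' private mutation counts along the path: within a group, haplotypes `j` and
#' `k` differ by `intra[[g]][j] + intra[[g]][k]` sites; between groups `g` and
#' `h`, reference haplotypes differ by `inter[g] + inter[h]` sites.
#'
#' @param counts_per_hap List (one element per group) of integer vectors: the
#'   number of individuals carrying each haplotype.
#' @param inter_group_mutations Integer vector, one per group: mutation count
#'   of each group's reference haplotype relative to the common root (group 1
#'   is conventionally the root, i.e. 0).
#' @param intra_group_mutations List of integer vectors matching
#'   `counts_per_hap`: private mutation counts of each haplotype relative to
#'   its group reference (first haplotype of a group is typically 0).
#' @param length Sequence length in nt; must exceed the total mutation count.
#' @param group_labels Optional group (population) labels.
#' @param seed Integer seed.
#' @return List with `sequences` (named character vector, one entry per
#'   individual), `populations` and `haplotype` (named by individual), and
#'   `haplotype_seqs` (one representative sequence per haplotype).
#' @export
simulate_mito_sequences <- function(counts_per_hap,
                                    inter_group_mutations,
                                    intra_group_mutations,
                                    length = 16658,
                                    group_labels = NULL,
                                    seed = 1) {
  n_groups <- length(counts_per_hap)
  stopifnot(length(inter_group_mutations) == n_groups,
            length(intra_group_mutations) == n_groups)
  for (g in seq_len(n_groups)) {
    stopifnot(length(counts_per_hap[[g]]) == length(intra_group_mutations[[g]]))
  }
  if (is.null(group_labels)) group_labels <- paste0("grp", seq_len(n_groups))
  total_mut <- sum(inter_group_mutations) +
    sum(unlist(intra_group_mutations))
  if (length <= total_mut) stop("`length` must exceed the total mutation count")

  set.seed(seed)
  bases <- c("a", "c", "g", "t")
  root <- sample(bases, length, replace = TRUE)
  # disjoint positions across all branches => additive Hamming distances
  all_pos <- sample.int(length, total_mut)
  take <- function(k) {
    if (k == 0) return(integer(0))
    p <- all_pos[seq_len(k)]
    all_pos <<- all_pos[-seq_len(k)]
    p
  }
  mutate <- function(seq, positions) {
    for (p in positions) seq[p] <- sample(setdiff(bases, seq[p]), 1)
    seq
  }

  hap_seqs <- character(0)
  populations <- character(0)
  haplotype <- character(0)
  sequences <- character(0)
  for (g in seq_len(n_groups)) {
    ref <- mutate(root, take(inter_group_mutations[g]))
    for (j in seq_along(counts_per_hap[[g]])) {
      hs <- mutate(ref, take(intra_group_mutations[[g]][j]))
      hid <- sprintf("%s_h%d", group_labels[g], j)
      hap_seqs[hid] <- paste(hs, collapse = "")
      for (r in seq_len(counts_per_hap[[g]][j])) {
        sid <- sprintf("%s_h%d_s%d", group_labels[g], j, r)
        sequences[sid] <- hap_seqs[hid]
        populations[sid] <- group_labels[g]
        haplotype[sid] <- hid
      }
    }
  }
  list(sequences = sequences, populations = populations,
       haplotype = haplotype, haplotype_seqs = hap_seqs)
}

#' Write named sequences as FASTA
#' @param sequences Named character vector of equal-length sequences.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(sequences, path) {
  lines <- as.vector(rbind(paste0(">", names(sequences)),
                           toupper(unname(sequences))))
  writeLines(lines, path)
  invisible(path)
}
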