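#' Parameters of the sliding-window ROH detector
#'
#' Defaults follow the resequencing-scale settings the package targets:
#' 2500-SNP windows, 10 kb maximum gap, 1 Mb minimum run length, at most 150
#' "opposite" (heterozygous or missing) genotypes per window (6% of the
#' window), minimum SNPs per run equal to the window size, and a per-SNP
#' window-hit fraction of 0.05 (the detectRUNS-documented default).
#'
#' @param window_snps Sliding-window length in SNPs.
#' @param max_gap_bp Maximum allowed gap between adjacent SNPs inside a
#'   window, in bp.
#' @param min_length_bp Minimum physical run length, in bp.
#' @param max_opposite_per_window Maximum heterozygous-or-missing genotypes
#'   per homozygous window.
#' @param min_snps_in_run Minimum SNPs a run must span (default: the window
#'   size).
#' @param min_window_hit_fraction Minimum fraction of windows covering a SNP
#'   that must be homozygous for the SNP to be part of a run.
#' @param count_missing_as_opposite Count missing genotypes toward the
#'   opposite-genotype budget (conservative default).
#' @return List of class `roh_params`.
#' @export
roh_params <- function(window_snps = 2500,
                       max_gap_bp = 1e4,
                       min_length_bp = 1e6,
                       max_opposite_per_window = 150,
                       min_snps_in_run = window_snps,
                       min_window_hit_fraction = 0.05,
                       count_missing_as_opposite = TRUE) {
  stopifnot(window_snps >= 1, max_gap_bp > 0, min_length_bp > 0,
            max_opposite_per_window >= 0, min_snps_in_run >= 1,
            min_window_hit_fraction > 0, min_window_hit_fraction <= 1)
  if (max_opposite_per_window > window_snps) {
    stop("`max_opposite_per_window` cannot exceed `window_snps`")
  }
  structure(list(window_snps = as.integer(window_snps),
                 max_gap_bp = max_gap_bp,
                 min_length_bp = min_length_bp,
                 max_opposite_per_window = as.integer(max_opposite_per_window),
                 min_snps_in_run = as.integer(min_snps_in_run),
                 min_window_hit_fraction = min_window_hit_fraction,
                 count_missing_as_opposite = count_missing_as_opposite),
            class = "roh_params")
}

#' Detect runs of homozygosity with a sliding window
#'
#' For each individual and chromosome a window of `window_snps` SNPs slides
#' one SNP at a time. A window is homozygous when its count of heterozygous
#' (and, by default, missing) genotypes does not exceed
#' `max_opposite_per_window` and no adjacent-SNP gap inside it exceeds
#' `max_gap_bp`. A SNP belongs to a run when at least
#' `min_window_hit_fraction` of the windows covering it are homozygous;
#' maximal stretches of such SNPs are emitted as segments when their physical
#' length (first to last SNP) reaches `min_length_bp` and their SNP count
#' reaches `min_snps_in_run`. Chromosomes with fewer SNPs than the window are
#' skipped with a warning.
#'
#' @param gm A [genotype_matrix()].
#' @param params A [roh_params()].
#' @return `data.frame` with columns `individual`, `population`, `chrom`,
#'   `start`, `end`, `length`, `n_snps`, `length_class`.
#' @export
detect_roh <- function(gm, params = roh_params()) {
  stopifnot(inherits(params, "roh_params"))
  w <- params$window_snps
  out <- list()
  for (cc in unique(gm$chrom)) {
    ci <- which(gm$chrom == cc)
    m <- length(ci)
    if (m < w) {
      warning("chromosome ", cc, " has ", m, " SNPs (< window of ", w,
              "); skipped")
      next
    }
    pos <- gm$pos[ci]
    gaps_big <- c(diff(pos) > params$max_gap_bp)
    gb <- c(0, cumsum(gaps_big))
    n_win <- m - w + 1
    # window s covers SNPs s..s+w-1, hence gaps s..s+w-2
    win_gap_ok <- (gb[seq_len(n_win) + w - 1] - gb[seq_len(n_win)]) == 0
    j <- seq_len(m)
    lo <- pmax(1, j - w + 1)
    hi <- pmin(j, n_win)
    n_cover <- hi - lo + 1

    for (si in seq_along(gm$samples)) {
      dvec <- gm$dosages[si, ci]
      opp <- dvec == 1
      if (params$count_missing_as_opposite) {
        opp <- opp | is.na(dvec)
      } else {
        opp[is.na(opp)] <- FALSE
      }
      cs <- c(0, cumsum(opp))
      win_opp <- cs[seq_len(n_win) + w] - cs[seq_len(n_win)]
      hom_win <- (win_opp <= params$max_opposite_per_window) & win_gap_ok
      hw <- c(0, cumsum(hom_win))
      n_hom <- hw[hi + 1] - hw[lo]
      in_run <- (n_hom / n_cover) >= params$min_window_hit_fraction

      r <- rle(in_run)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1
      sel <- which(r$values)
      for (k in sel) {
        i1 <- starts[k]; i2 <- ends[k]
        len <- pos[i2] - pos[i1]
        nsnp <- i2 - i1 + 1
        if (len >= params$min_length_bp && nsnp >= params$min_snps_in_run) {
          out[[length(out) + 1]] <- data.frame(
            individual = gm$samples[si],
            population = unname(gm$populations[gm$samples[si]]),
            chrom = cc, start = pos[i1], end = pos[i2],
            length = len, n_snps = nsnp
          )
        }
      }
    }
  }
  if (length(out) == 0) {
    res <- data.frame(individual = character(0), population = character(0),
                      chrom = character(0), start = numeric(0), end = numeric(0),
                      length = numeric(0), n_snps = integer(0))
  } else {
    res <- do.call(rbind, out)
  }
  res$length_class <- roh_length_class(res$length)
  rownames(res) <- NULL
  res
}

# length classes in Mb; the first class is conventionally labelled "0-2 Mb"
# even though runs shorter than the 1 Mb minimum cannot occur
roh_length_class <- function(length_bp) {
  mb <- length_bp / 1e6
  cls <- cut(mb, breaks = c(0, 2, 4, 8, 16, Inf),
             labels = c("0-2 Mb", "2-4 Mb", "4-8 Mb", "8-16 Mb", ">16 Mb"),
             right = FALSE)
  if (any(cls == ">16 Mb", na.rm = TRUE)) {
    warning(sum(cls == ">16 Mb"), " run(s) exceed the 8-16 Mb class")
  }
  cls
}

#' Per-class ROH counts and mean lengths by population
#'
#' @param segments A [detect_roh()] result (columns `population`, `length`).
#' @return `data.frame` with `length_class`, `population`, `n`,
#'   `mean_length_mb`; all classes are present even when empty.
#' @export
classify_roh <- function(segments) {
  classes <- c("0-2 Mb", "2-4 Mb", "4-8 Mb", "8-16 Mb")
  pops <- unique(segments$population)
  if (length(pops) == 0) pops <- NA_character_
  grid <- expand.grid(length_class = classes, population = pops,
                      stringsAsFactors = FALSE)
  grid$n <- 0L
  grid$mean_length_mb <- NA_real_
  if (nrow(segments) > 0) {
    segments$length_class <- roh_length_class(segments$length)
    for (i in seq_len(nrow(grid))) {
      sel <- segments$length_class == grid$length_class[i] &
        segments$population == grid$population[i]
      grid$n[i] <- sum(sel, na.rm = TRUE)
      if (grid$n[i] > 0) {
        grid$mean_length_mb[i] <- mean(segments$length[sel] / 1e6, na.rm = TRUE)
      }
    }
  }
  grid
}

#' Genomic inbreeding coefficient from ROH segments
#'
#' `F_ROH = sum(L_ROH) / L_genome`: the fraction of the genome covered by an
#' individual's runs of homozygosity.
#'
#' @param segments ROH segments of one individual (columns `start`, `end`,
#'   `length`; must be non-overlapping).
#' @param genome_length_bp Total genome length in bp.
#' @return Proportion in `[0, 1]`.
#' @export
froh <- function(segments, genome_length_bp) {
  stopifnot(genome_length_bp > 0)
  if (is.null(segments) || nrow(segments) == 0) return(0)
  sum(segments$length) / genome_length_bp
}

#' Per-individual F_ROH table
#'
#' @param segments A [detect_roh()] result.
#' @param genome_length_bp Total genome length in bp (e.g.
#'   `sum(gm$chrom_lengths)`).
#' @param samples Optional character vector of individuals to report
#'   (individuals without segments get `F_ROH = 0`).
#' @return `data.frame` with `individual`, `froh`.
#' @export
froh_by_individual <- function(segments, genome_length_bp, samples = NULL) {
  if (is.null(samples)) samples <- unique(segments$individual)
  vals <- vapply(samples, function(ind) {
    froh(segments[segments$individual == ind, , drop = FALSE], genome_length_bp)
  }, numeric(1))
  data.frame(individual = samples, froh = unname(vals))
}
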