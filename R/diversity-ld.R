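#' Observed heterozygosity
#'
#' Per individual: the fraction of non-missing sites with a heterozygous
#' genotype (dosage 1). Per population: the mean over its members.
#'
#' @param gm A [genotype_matrix()].
#' @param per `"individual"` or `"population"`.
#' @return `data.frame` with `sample`, `population`, `het` (per individual) or
#'   `population`, `het` (per population).
#' @export
observed_heterozygosity <- function(gm, per = c("individual", "population")) {
  per <- match.arg(per)
  if (n_sites(gm) == 0) stop("empty genotype matrix")
  d <- gm$dosages
  het <- rowSums(d == 1, na.rm = TRUE) / rowSums(!is.na(d))
  ind <- data.frame(sample = gm$samples,
                    population = unname(gm$populations[gm$samples]),
                    het = unname(het))
  if (per == "individual") return(ind)
  agg <- stats::aggregate(het ~ population, data = ind, FUN = mean)
  agg
}

#' Genotype-correlation linkage disequilibrium between two sites
#'
#' Squared Pearson correlation of the dosage vectors over samples that are
#' non-missing at both sites (the usual genotype r^2 of LD-decay software).
#'
#' @param gm A [genotype_matrix()].
#' @param site_i,site_j Site indices (columns of the dosage matrix).
#' @param samples Optional subset of sample ids.
#' @return r^2 in `[0, 1]`, or `NA` when either site is monomorphic in the
#'   analysed subset.
#' @export
ld_r2_pair <- function(gm, site_i, site_j, samples = NULL) {
  d <- gm$dosages
  if (!is.null(samples)) d <- d[match(samples, gm$samples), , drop = FALSE]
  x <- d[, site_i]
  y <- d[, site_j]
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 2 || stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y)^2
}

#' Linkage-disequilibrium decay curve
#'
#' Mean genotype r^2 of all intra-chromosomal site pairs within `max_dist`,
#' binned by physical distance. Monomorphic sites and pairs spanning missing
#' data are excluded. For sex-stratified runs, pass the relevant sample ids
#' through `samples` instead of a population label.
#'
#' @param gm A [genotype_matrix()].
#' @param population Population label (ignored when `samples` is given).
#' @param max_dist Maximum pair distance in bp (default 500 kb).
#' @param bin_width Distance bin width in bp.
#' @param samples Optional explicit sample subset.
#' @return `data.frame` of class `ld_decay` with columns `dist_lo`, `dist_hi`,
#'   `mean_r2`, `n_pairs`.
#' @export
ld_decay <- function(gm, population = NULL, max_dist = 5e5, bin_width = 1e4,
                     samples = NULL) {
  if (is.null(samples)) {
    samples <- if (is.null(population)) gm$samples else pop_samples(gm, population)
  }
  d <- gm$dosages[match(samples, gm$samples), , drop = FALSE]
  n <- nrow(d)
  breaks <- seq(0, max_dist, by = bin_width)
  if (breaks[length(breaks)] < max_dist) breaks <- c(breaks, max_dist)
  nb <- length(breaks) - 1
  sums <- numeric(nb)
  counts <- numeric(nb)

  for (cc in unique(gm$chrom)) {
    ci <- which(gm$chrom == cc)
    if (length(ci) < 2) next
    pos <- gm$pos[ci]
    x <- d[, ci, drop = FALSE]
    if (anyNA(x)) {
      ok <- colSums(is.na(x)) == 0
      x <- x[, ok, drop = FALSE]
      pos <- pos[ok]
      if (length(pos) < 2) next
    }
    sdv <- apply(x, 2, stats::sd)
    poly <- sdv > 0
    x <- x[, poly, drop = FALSE]
    pos <- pos[poly]
    m <- ncol(x)
    if (m < 2) next
    z <- scale(x)  # columns standardized; r = crossprod / (n - 1)
    for (lag in seq_len(m - 1)) {
      dist <- pos[(1 + lag):m] - pos[1:(m - lag)]
      inrange <- dist <= max_dist
      if (!any(inrange)) {
        if (min(dist) > max_dist) break
        next
      }
      r <- colSums(z[, 1:(m - lag), drop = FALSE] *
                     z[, (1 + lag):m, drop = FALSE]) / (n - 1)
      r2 <- r[inrange]^2
      bin <- findInterval(dist[inrange], breaks, rightmost.closed = TRUE,
                          left.open = TRUE)
      bin[bin == 0] <- 1  # distance exactly 0 cannot occur; guard anyway
      sums <- sums + as.vector(tapply(r2, factor(bin, levels = seq_len(nb)),
                                      sum, default = 0))
      counts <- counts + as.vector(table(factor(bin, levels = seq_len(nb))))
    }
  }
  res <- data.frame(
    dist_lo = breaks[-length(breaks)], dist_hi = breaks[-1],
    mean_r2 = ifelse(counts > 0, sums / counts, NA_real_),
    n_pairs = counts
  )
  class(res) <- c("ld_decay", "data.frame")
  attr(res, "n_samples") <- n
  res
}

#' Historical effective population size from an LD-decay curve
#'
#' Inverts Sved's drift expectation `E[r^2] = 1/(alpha + 4 N c) + 1/(2 n)`
#' bin by bin: each distance bin midpoint is mapped to a recombination
#' fraction `c` through a constant cM/Mb rate and Haldane's map function, the
#' bin's mean r^2 is corrected for the finite sample (`- 1/(2 n)`), and
#' `Ne = (1/r2_adj - alpha) / (4 c)` is assigned to `1/(2 c)` generations ago.
#' Bins whose corrected r^2 or Ne is non-positive are dropped with a warning.
#'
#' @param curve An [ld_decay()] result (or any data.frame with `dist_lo`,
#'   `dist_hi`, `mean_r2`, `n_pairs`).
#' @param n_samples Number of diploid samples behind the curve.
#' @param alpha Sved constant: 1 for pure drift, 2.2 adjusts for mutation.
#' @param cm_per_mb Constant genetic-map rate used to convert bp to Morgans.
#' @return `data.frame` with `generations_ago`, `ne`, `n_pairs`, ordered from
#'   recent to ancient.
#' @export
estimate_ne_history <- function(curve, n_samples, alpha = 1, cm_per_mb = 1) {
  stopifnot(n_samples > 1, alpha > 0, cm_per_mb > 0)
  use <- curve$n_pairs > 0 & !is.na(curve$mean_r2)
  cv <- curve[use, ]
  mid <- (cv$dist_lo + cv$dist_hi) / 2
  morgans <- mid / 1e6 * cm_per_mb / 100
  c_rec <- 0.5 * (1 - exp(-2 * morgans))  # Haldane
  r2_adj <- cv$mean_r2 - 1 / (2 * n_samples)
  ne <- (1 / r2_adj - alpha) / (4 * c_rec)
  gen <- 1 / (2 * c_rec)
  keep <- is.finite(ne) & ne > 0 & r2_adj > 0
  if (any(!keep)) {
    warning(sum(!keep), " bin(s) dropped (non-positive corrected r^2 or Ne)")
  }
  res <- data.frame(generations_ago = gen[keep], ne = ne[keep],
                    n_pairs = cv$n_pairs[keep])
  res[order(res$generations_ago), , drop = FALSE]
}
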