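#' Greedy LD pruning
#'
#' Left-to-right windowed pruning: inside each window, while any pair of
#' retained sites has r^2 above the threshold, the pair with the highest r^2
#' is located and its lower-MAF member removed (ties: the right-hand site).
#' Windows advance by `step`; both bp-based windows (e.g. 50 kb / 10 kb) and
#' SNP-count windows (e.g. 100 SNPs / 10 SNPs) are supported. The surviving
#' set has no intra-window pair above the threshold.
#'
#' @param gm A [genotype_matrix()].
#' @param r2_max Retain only pairs with r^2 not exceeding this threshold.
#' @param window Window size, in bp (`unit = "bp"`) or SNP count
#'   (`unit = "snps"`).
#' @param step Step size in the same unit.
#' @param unit `"bp"` or `"snps"`.
#' @return Sorted integer vector of retained site indices.
#' @export
ld_prune <- function(gm, r2_max = 0.15, window = 5e4, step = 1e4,
                     unit = c("bp", "snps")) {
  unit <- match.arg(unit)
  stopifnot(r2_max >= 0, window > 0, step > 0)
  af <- allele_freq(gm)
  maf <- pmin(af, 1 - af)
  keep <- rep(TRUE, n_sites(gm))

  prune_window <- function(idx) {
    idx <- idx[keep[idx]]
    if (length(idx) < 2) return(invisible())
    x <- gm$dosages[, idx, drop = FALSE]
    r2 <- suppressWarnings(stats::cor(x, use = "pairwise.complete.obs")^2)
    r2[!is.finite(r2)] <- 0
    diag(r2) <- 0
    alive <- rep(TRUE, length(idx))
    repeat {
      sub <- r2
      sub[!alive, ] <- 0
      sub[, !alive] <- 0
      mx <- max(sub)
      if (mx <= r2_max) break
      hit <- which(sub == mx, arr.ind = TRUE)[1, ]
      i <- idx[hit[1]]; j <- idx[hit[2]]
      drop_local <- if (maf[i] < maf[j]) hit[1]
      else if (maf[j] < maf[i]) hit[2]
      else max(hit)
      alive[drop_local] <- FALSE
    }
    keep[idx[!alive]] <<- FALSE
    invisible()
  }

  for (cc in unique(gm$chrom)) {
    ci <- which(gm$chrom == cc)
    if (unit == "bp") {
      pos <- gm$pos[ci]
      starts <- seq(0, max(pos), by = step)
      for (s in starts) {
        idx <- ci[pos > s & pos <= s + window]
        prune_window(idx)
      }
    } else {
      starts <- seq(1, length(ci), by = step)
      for (s in starts) {
        idx <- ci[s:min(s + window - 1, length(ci))]
        prune_window(idx)
      }
    }
  }
  which(keep)
}

#' Genomic relationship matrix (Yang estimator)
#'
#' Off-diagonal entries are per-site standardized cross-products
#' `(x_i - 2p)(x_j - 2p) / (2p(1-p))` averaged over sites where both samples
#' are genotyped; diagonal entries use the dedicated estimator
#' `1 + (x^2 - (1 + 2p)x + 2p^2) / (2p(1-p))`, as in PLINK's `--make-rel`.
#' Allele frequencies are computed from the data; monomorphic sites are
#' excluded.
#'
#' @param gm A [genotype_matrix()].
#' @return Symmetric numeric matrix with sample ids as dimnames, class
#'   `c("grm", "matrix")`.
#' @export
grm <- function(gm) {
  p <- allele_freq(gm)
  use <- !is.na(p) & p > 0 & p < 1
  x <- gm$dosages[, use, drop = FALSE]
  p <- p[use]
  n <- nrow(x)
  denom <- 2 * p * (1 - p)

  w <- sweep(x, 2, 2 * p, "-") / rep(sqrt(denom), each = n)
  obs <- !is.na(w)
  w0 <- w; w0[!obs] <- 0
  num <- tcrossprod(w0)
  cnt <- tcrossprod(obs * 1)
  g <- num / cnt

  # Yang's diagonal estimator
  dnum <- x^2 - sweep(x, 2, 1 + 2 * p, "*") + rep(2 * p^2, each = n)
  dterm <- sweep(dnum, 2, denom, "/")
  diag(g) <- 1 + rowMeans(dterm, na.rm = TRUE)

  dimnames(g) <- list(gm$samples, gm$samples)
  class(g) <- c("grm", class(g))
  g
}

#' Principal component analysis of standardized genotypes
#'
#' Genotypes are centered by `2p` and scaled by `sqrt(2p(1-p))`; missing
#' entries are mean-imputed (zero after centering). Scores are the projections
#' onto the leading right-singular axes; explained-variance proportions are
#' eigenvalue shares of the total standardized variance.
#'
#' @param gm A [genotype_matrix()] (typically LD-pruned).
#' @param n_components Number of components to return.
#' @return List with `scores` (samples x components, dimnames set),
#'   `prop_var` (explained-variance proportions, non-increasing), and
#'   `sdev`.
#' @export
pca_genotypes <- function(gm, n_components = 10) {
  stopifnot(n_samples(gm) >= 2)
  p <- allele_freq(gm)
  use <- !is.na(p) & p > 0 & p < 1
  x <- gm$dosages[, use, drop = FALSE]
  p <- p[use]
  n <- nrow(x)
  w <- sweep(x, 2, 2 * p, "-") / rep(sqrt(2 * p * (1 - p)), each = n)
  w[is.na(w)] <- 0
  pc <- stats::prcomp(w, center = FALSE, scale. = FALSE)
  k <- min(n_components, ncol(pc$x))
  scores <- pc$x[, seq_len(k), drop = FALSE]
  rownames(scores) <- gm$samples
  list(scores = scores,
       prop_var = (pc$sdev^2 / sum(pc$sdev^2))[seq_len(k)],
       sdev = pc$sdev[seq_len(k)])
}

#' Welch's unequal-variance t-test
#'
#' Thin wrapper around [stats::t.test()] with `var.equal = FALSE`, used to
#' compare within-population genomic relatedness between two groups.
#'
#' @param x,y Numeric vectors (each of length >= 2).
#' @return Named numeric vector `c(t, df, p)`.
#' @export
welch_t <- function(x, y) {
  stopifnot(length(x) >= 2, length(y) >= 2)
  tt <- stats::t.test(x, y, var.equal = FALSE)
  c(t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value)
}

#' Mean within- and between-population relationship
#'
#' Summarises a GRM by the mean off-diagonal entry within each population and
#' between the two.
#'
#' @param g A [grm()] result.
#' @param populations Named character vector mapping sample id to population.
#' @return `data.frame` with `group` and `mean_rel`.
#' @export
grm_group_means <- function(g, populations) {
  ids <- rownames(g)
  pops <- populations[ids]
  lv <- unique(pops)
  out <- list()
  for (a in lv) {
    ia <- which(pops == a)
    sub <- g[ia, ia, drop = FALSE]
    out[[paste0("within_", a)]] <- mean(sub[upper.tri(sub)])
  }
  if (length(lv) >= 2) {
    for (i in seq_len(length(lv) - 1)) for (j in (i + 1):length(lv)) {
      ia <- which(pops == lv[i]); ib <- which(pops == lv[j])
      out[[paste0("between_", lv[i], "_", lv[j])]] <- mean(g[ia, ib])
    }
  }
  data.frame(group = names(out), mean_rel = unlist(out), row.names = NULL)
}

#' Pairwise within-population relationship values
#'
#' Extracts the upper-triangle GRM entries of pairs belonging to the same
#' population (input for Welch's t comparison of within-stock relatedness).
#'
#' @param g A [grm()] result.
#' @param populations Named character vector mapping sample id to population.
#' @param population Population label.
#' @return Numeric vector of pairwise relationships.
#' @export
within_pop_relationships <- function(g, populations, population) {
  ids <- rownames(g)[populations[rownames(g)] == population]
  sub <- g[ids, ids, drop = FALSE]
  sub[upper.tri(sub)]
}
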