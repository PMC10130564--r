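# Independent reference implementations ("oracles") used to cross-check the
# package code. These are deliberately written in naive loop/enumeration form,
# straight from the published formulas, and share no code with R/.

# small genotype-matrix builder: dosage matrix samples x sites
make_gm <- function(dos, pos = NULL, chrom = "chr1", pops = NULL,
                    chrom_lengths = NULL, haplotypes = NULL, phased = NULL) {
  dos <- as.matrix(dos)
  n <- nrow(dos)
  if (is.null(rownames(dos))) rownames(dos) <- sprintf("s%02d", seq_len(n))
  if (is.null(pos)) pos <- seq_len(ncol(dos)) * 1000
  if (is.null(pops)) {
    pops <- stats::setNames(rep(c("A", "B"), length.out = n), rownames(dos))
  }
  genotype_matrix(dos, chrom = rep(chrom, length.out = ncol(dos)), pos = pos,
                  populations = pops, chrom_lengths = chrom_lengths,
                  haplotypes = haplotypes, phased = phased)
}

# Weir & Cockerham (1984) two-population variance components, scalar form
wc_oracle <- function(d1, d2) {
  x <- list(d1, d2)
  r <- 2
  n_i <- sapply(x, function(v) sum(!is.na(v)))
  p_i <- sapply(x, function(v) sum(v, na.rm = TRUE) / (2 * sum(!is.na(v))))
  h_i <- sapply(x, function(v) mean(v[!is.na(v)] == 1))
  nbar <- mean(n_i)
  nc <- (r * nbar - sum(n_i^2) / (r * nbar)) / (r - 1)
  pbar <- sum(n_i * p_i) / (r * nbar)
  s2 <- sum(n_i * (p_i - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(n_i * h_i) / (r * nbar)
  a <- nbar / nc * (s2 - 1 / (nbar - 1) *
                      (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4))
  b <- nbar / (nbar - 1) * (pbar * (1 - pbar) - (r - 1) / r * s2 -
                              (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  c(a = a, b = b, c = cc, theta = a / (a + b + cc))
}

# genome-wide weighted (ratio-of-sums) W&C estimate from a wc_fst() table
fst_weighted <- function(f) {
  sum(f$a, na.rm = TRUE) / sum(f$a + f$b + f$c, na.rm = TRUE)
}

# brute-force sliding-window ROH scanner for one individual's dosage vector
roh_oracle <- function(dvec, pos, p) {
  m <- length(dvec)
  w <- p$window_snps
  empty <- data.frame(start = numeric(0), end = numeric(0),
                      length = numeric(0), n_snps = integer(0))
  if (m < w) return(empty)
  n_win <- m - w + 1
  hom <- logical(n_win)
  for (s in seq_len(n_win)) {
    win <- s:(s + w - 1)
    opp <- if (p$count_missing_as_opposite) {
      sum(dvec[win] == 1, na.rm = TRUE) + sum(is.na(dvec[win]))
    } else {
      sum(dvec[win] == 1, na.rm = TRUE)
    }
    hom[s] <- opp <= p$max_opposite_per_window &&
      all(diff(pos[win]) <= p$max_gap_bp)
  }
  in_run <- logical(m)
  for (j in seq_len(m)) {
    cov <- max(1, j - w + 1):min(j, n_win)
    in_run[j] <- mean(hom[cov]) >= p$min_window_hit_fraction
  }
  segs <- empty
  j <- 1
  while (j <= m) {
    if (in_run[j]) {
      k <- j
      while (k < m && in_run[k + 1]) k <- k + 1
      len <- pos[k] - pos[j]
      if (len >= p$min_length_bp && (k - j + 1) >= p$min_snps_in_run) {
        segs <- rbind(segs, data.frame(start = pos[j], end = pos[k],
                                       length = len, n_snps = k - j + 1))
      }
      j <- k + 1
    } else {
      j <- j + 1
    }
  }
  segs
}

# exhaustive minimum-spanning-tree weight for small graphs
mst_weight_oracle <- function(dist_mat) {
  n <- nrow(dist_mat)
  if (n == 1) return(0)
  pairs <- which(upper.tri(dist_mat), arr.ind = TRUE)
  ne <- nrow(pairs)
  best <- Inf
  for (sel in utils::combn(ne, n - 1, simplify = FALSE)) {
    # check the chosen edges form a spanning tree (connected, n-1 edges)
    parent <- seq_len(n)
    find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
    ok <- TRUE
    for (e in sel) {
      ri <- find(pairs[e, 1]); rj <- find(pairs[e, 2])
      if (ri == rj) { ok <- FALSE; break }
      parent[ri] <- rj
    }
    if (ok) best <- min(best, sum(dist_mat[pairs[sel, , drop = FALSE]]))
  }
  best
}

# mean silhouette width of a 2-group labelling along a single coordinate
silhouette_1d <- function(x, labels) {
  s <- vapply(seq_along(x), function(i) {
    same <- x[setdiff(which(labels == labels[i]), i)]
    other <- x[labels != labels[i]]
    a <- mean(abs(x[i] - same))
    b <- mean(abs(x[i] - other))
    (b - a) / max(a, b)
  }, numeric(1))
  mean(s)
}
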