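#' Per-site Weir & Cockerham F-statistic between two populations
#'
#' Computes the 1984 variance components from sample sizes, allele frequencies
#' and observed heterozygote counts of the two populations: `a` (among
#' populations), `b` (among individuals within populations) and `c` (within
#' individuals); `theta = a / (a + b + c)`. Sites where the total variance is
#' zero (e.g. monomorphic in both samples) are undefined (`NA`).
#'
#' @param gm A [genotype_matrix()].
#' @param pops Two population labels (default: the two populations present).
#' @param sites Optional site index subset.
#' @return `data.frame` with `chrom`, `pos`, `a`, `b`, `c`, `theta`.
#' @export
wc_fst <- function(gm, pops = NULL, sites = NULL) {
  if (is.null(pops)) pops <- unique(unname(gm$populations))
  if (length(pops) != 2) stop("exactly two populations are required")
  if (is.null(sites)) sites <- seq_len(n_sites(gm))
  d1 <- gm$dosages[match(pop_samples(gm, pops[1]), gm$samples), sites, drop = FALSE]
  d2 <- gm$dosages[match(pop_samples(gm, pops[2]), gm$samples), sites, drop = FALSE]

  n1 <- colSums(!is.na(d1))
  n2 <- colSums(!is.na(d2))
  p1 <- colSums(d1, na.rm = TRUE) / (2 * n1)
  p2 <- colSums(d2, na.rm = TRUE) / (2 * n2)
  h1 <- colSums(d1 == 1, na.rm = TRUE) / n1
  h2 <- colSums(d2 == 1, na.rm = TRUE) / n2

  r <- 2
  n_bar <- (n1 + n2) / r
  nc <- (r * n_bar - (n1^2 + n2^2) / (r * n_bar)) / (r - 1)
  p_bar <- (n1 * p1 + n2 * p2) / (r * n_bar)
  s2 <- (n1 * (p1 - p_bar)^2 + n2 * (p2 - p_bar)^2) / ((r - 1) * n_bar)
  h_bar <- (n1 * h1 + n2 * h2) / (r * n_bar)

  a <- n_bar / nc *
    (s2 - 1 / (n_bar - 1) *
       (p_bar * (1 - p_bar) - (r - 1) / r * s2 - h_bar / 4))
  b <- n_bar / (n_bar - 1) *
    (p_bar * (1 - p_bar) - (r - 1) / r * s2 -
       (2 * n_bar - 1) / (4 * n_bar) * h_bar)
  cc <- h_bar / 2

  tot <- a + b + cc
  theta <- ifelse(is.finite(tot) & tot != 0, a / tot, NA_real_)
  bad <- n1 < 1 | n2 < 1
  theta[bad] <- NA_real_
  data.frame(chrom = gm$chrom[sites], pos = gm$pos[sites],
             a = a, b = b, c = cc, theta = theta)
}

#' Sliding-window means of a per-site statistic
#'
#' Tiles each chromosome with windows of `window` bp starting at 0 and spaced
#' `step` bp (half-overlapping by default) and averages the per-site values
#' whose position falls in `[start, start + window)`. `NA` site values are
#' ignored in the mean; windows with fewer than `min_snps` sites report `NA`.
#'
#' @param chrom,pos,values Per-site chromosome, position (sorted within
#'   chromosome) and statistic value.
#' @param window Window size in bp.
#' @param step Step between window starts in bp.
#' @param min_snps Minimum sites for a window mean to be reported.
#' @param chrom_lengths Optional named chromosome lengths; windows tile up to
#'   the chromosome length (default: up to the last SNP).
#' @return `data.frame` with `chrom`, `start`, `end`, `n_snps`, `value`.
#' @export
windowed_mean <- function(chrom, pos, values, window = 5e4, step = 2.5e4,
                          min_snps = 1, chrom_lengths = NULL) {
  stopifnot(window > 0, step > 0, length(pos) == length(values))
  out <- list()
  for (cc in unique(chrom)) {
    ci <- which(chrom == cc)
    p <- pos[ci]
    v <- values[ci]
    len <- if (!is.null(chrom_lengths) && cc %in% names(chrom_lengths)) {
      chrom_lengths[[cc]]
    } else {
      max(p)
    }
    starts <- seq(0, max(0, len - 1), by = step)
    csum <- c(0, cumsum(ifelse(is.na(v), 0, v)))
    cnt_ok <- c(0, cumsum(!is.na(v)))
    # sites with 1-based pos in [s+1, s+window]
    i_lo <- findInterval(starts, p)            # sites with pos <= s
    i_hi <- findInterval(starts + window, p)   # sites with pos <= s+window
    n_all <- i_hi - i_lo
    n_ok <- cnt_ok[i_hi + 1] - cnt_ok[i_lo + 1]
    vsum <- csum[i_hi + 1] - csum[i_lo + 1]
    val <- ifelse(n_all >= min_snps & n_ok > 0, vsum / n_ok, NA_real_)
    out[[cc]] <- data.frame(chrom = cc, start = starts, end = starts + window,
                            n_snps = n_all, value = val)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Extended haplotype homozygosity curve around a core site
#'
#' EHH at extension site `x` is the probability that two random haplotypes of
#' the panel are identical over all sites from the core (exclusive) to `x`
#' (inclusive): `sum_h C(n_h, 2) / C(n, 2)` over haplotype classes `h`. At the
#' core itself EHH is 1 by convention. The curve is truncated once EHH falls
#' below `min_ehh` (that point is still reported), at a gap larger than
#' `max_gap`, or at the chromosome edge.
#'
#' @param haplotypes 0/1 integer matrix, haplotypes in rows, sites in columns.
#' @param positions Site positions in bp (sorted).
#' @param core Core site column index.
#' @param min_ehh Truncation threshold.
#' @param max_gap Maximum bridged gap in bp.
#' @return `data.frame` with `position`, `distance`, `side`
#'   (`"left"`/`"core"`/`"right"`), `ehh`.
#' @export
ehh <- function(haplotypes, positions, core, min_ehh = 0.05, max_gap = 2e5) {
  n <- nrow(haplotypes)
  m <- ncol(haplotypes)
  stopifnot(core >= 1, core <= m, n >= 2)
  denom <- n * (n - 1) / 2
  one_side <- function(dir) {
    res <- list()
    key <- rep("", n)
    prev_pos <- positions[core]
    j <- core + dir
    while (j >= 1 && j <= m) {
      if (abs(positions[j] - prev_pos) > max_gap) break
      al <- haplotypes[, j]
      al[is.na(al)] <- 2L
      key <- paste(key, al)
      cnt <- table(key)
      e <- sum(cnt * (cnt - 1) / 2) / denom
      res[[length(res) + 1]] <- data.frame(
        position = positions[j],
        distance = abs(positions[j] - positions[core]),
        side = if (dir < 0) "left" else "right",
        ehh = e
      )
      prev_pos <- positions[j]
      if (e < min_ehh) break
      j <- j + dir
    }
    if (length(res) == 0) return(NULL)
    do.call(rbind, res)
  }
  left <- one_side(-1)
  if (!is.null(left)) left <- left[rev(seq_len(nrow(left))), , drop = FALSE]
  core_row <- data.frame(position = positions[core], distance = 0,
                         side = "core", ehh = 1)
  right <- one_side(1)
  res <- rbind(left, core_row, right)
  rownames(res) <- NULL
  res
}

#' Integrated EHH (iES) at a core site
#'
#' Trapezoid integral of the [ehh()] curve over physical distance, both
#' directions summed. A curve truncated immediately on both sides (no flanking
#' point reachable) integrates to 0 and triggers a warning.
#'
#' @inheritParams ehh
#' @return Non-negative scalar (bp-scaled).
#' @export
ies <- function(haplotypes, positions, core, min_ehh = 0.05, max_gap = 2e5) {
  curve <- ehh(haplotypes, positions, core, min_ehh, max_gap)
  total <- 0
  for (s in c("left", "right")) {
    seg <- curve[curve$side %in% c(s, "core"), ]
    seg <- seg[order(seg$distance), ]
    if (nrow(seg) >= 2) {
      total <- total + sum(diff(seg$distance) *
                             (utils::head(seg$ehh, -1) + utils::tail(seg$ehh, -1)) / 2)
    }
  }
  if (total == 0) warning("EHH truncated immediately on both sides; iES = 0")
  total
}

#' Cross-population extended haplotype homozygosity (XP-EHH)
#'
#' Computes site-wise iES in each population (compiled scan), takes
#' `raw = ln(iES_a / iES_b)`, standardizes genome-wide, and converts the
#' standardized score to a two-sided normal p-value. Sites where either iES is
#' zero are dropped.
#'
#' @param gm A phased [genotype_matrix()].
#' @param pops Two population labels (default: the two populations present;
#'   the first is the numerator).
#' @param min_ehh EHH truncation threshold.
#' @param max_gap Maximum bridged gap in bp.
#' @return `data.frame` with `chrom`, `pos`, `ies_a`, `ies_b`, `raw`, `z`,
#'   `p`, `neglogp`.
#' @export
xpehh <- function(gm, pops = NULL, min_ehh = 0.05, max_gap = 2e5) {
  if (is.null(gm$haplotypes)) stop("`gm` carries no haplotypes; phase is required")
  if (!all(gm$phased)) {
    gm <- subset_sites(gm, gm$phased)
  }
  if (is.null(pops)) pops <- unique(unname(gm$populations))
  if (length(pops) != 2) stop("exactly two populations are required")
  rows_a <- hap_rows(gm, pop_samples(gm, pops[1]))
  rows_b <- hap_rows(gm, pop_samples(gm, pops[2]))

  ies_a <- numeric(n_sites(gm))
  ies_b <- numeric(n_sites(gm))
  for (cc in unique(gm$chrom)) {
    ci <- which(gm$chrom == cc)
    hap <- gm$haplotypes[, ci, drop = FALSE]
    storage.mode(hap) <- "integer"
    pos <- gm$pos[ci]
    ies_a[ci] <- ies_scan_cpp(hap[rows_a, , drop = FALSE], pos, min_ehh, max_gap)
    ies_b[ci] <- ies_scan_cpp(hap[rows_b, , drop = FALSE], pos, min_ehh, max_gap)
  }
  ok <- ies_a > 0 & ies_b > 0
  raw <- rep(NA_real_, n_sites(gm))
  raw[ok] <- log(ies_a[ok] / ies_b[ok])
  z <- (raw - mean(raw, na.rm = TRUE)) / stats::sd(raw, na.rm = TRUE)
  p <- 2 * stats::pnorm(-abs(z))
  res <- data.frame(chrom = gm$chrom, pos = gm$pos, ies_a = ies_a,
                    ies_b = ies_b, raw = raw, z = z, p = p,
                    neglogp = -log10(p))
  res[ok, , drop = FALSE]
}

#' Empirical right-tail p-values
#'
#' `p_i = (1 + #\{j != i : v_j >= v_i\}) / (N + 1)`; never exactly 0 or 1.
#'
#' @param values Numeric vector (>= 2 finite values).
#' @return Numeric vector of p-values, same length/order as `values`.
#' @export
empirical_right_tail_p <- function(values) {
  stopifnot(sum(is.finite(values)) >= 2)
  n <- length(values)
  # #\{j: v_j >= v_i\} (including i) = n - rank_min + 1; excluding i adds the +1 back
  (n - rank(values, ties.method = "min", na.last = "keep") + 1) / (n + 1)
}

#' De-correlated composite of multiple signals (DCMS)
#'
#' For window `w` and statistics `t = 1..n` with per-window p-values `p_wt`,
#' `DCMS_w = sum_t log((1 - p_wt) / p_wt) / sum_i |r_it|`, where `r` is the
#' n x n correlation matrix of the statistics across the included windows
#' (unit diagonal). Each statistic's logit score is thereby down-weighted by
#' its total correlation with all statistics, so duplicated (perfectly
#' correlated) signals are not double counted. P-values are clamped to
#' `[1e-10, 1 - 1e-10]`.
#'
#' @param stats_mat Numeric matrix (or data.frame) of the statistics, windows
#'   in rows, one column per statistic.
#' @param p_mat Matching matrix of per-window p-values.
#' @param method Correlation method for `r` (`"pearson"` or `"spearman"`).
#' @return Numeric vector of DCMS values per window; the correlation matrix is
#'   attached as attribute `correlation`.
#' @export
dcms <- function(stats_mat, p_mat, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  stats_mat <- as.matrix(stats_mat)
  p_mat <- as.matrix(p_mat)
  if (ncol(stats_mat) == 0) stop("at least one statistic is required")
  stopifnot(all(dim(stats_mat) == dim(p_mat)))
  sds <- apply(stats_mat, 2, stats::sd, na.rm = TRUE)
  if (any(!is.finite(sds) | sds == 0)) {
    bad <- colnames(stats_mat)[!is.finite(sds) | sds == 0]
    if (is.null(bad)) bad <- which(!is.finite(sds) | sds == 0)
    stop("constant statistic column (undefined correlation): ",
         paste(bad, collapse = ", "))
  }
  r <- stats::cor(stats_mat, method = method, use = "pairwise.complete.obs")
  denom <- colSums(abs(r))
  p <- pmin(pmax(p_mat, 1e-10), 1 - 1e-10)
  logits <- log((1 - p) / p)
  out <- rowSums(sweep(logits, 2, denom, "/"))
  attr(out, "correlation") <- r
  out
}

#' Flag windows above an empirical quantile cutoff
#'
#' @param values Numeric vector (NA allowed; never flagged).
#' @param quantile Empirical quantile defining the cutoff (default top 0.5%).
#' @return List with `cutoff` and logical `hits` (`value >= cutoff`, so ties
#'   at the cutoff are all included).
#' @export
call_hits <- function(values, quantile = 0.995) {
  stopifnot(quantile > 0, quantile < 1)
  ok <- sum(is.finite(values))
  if (ok < 1 / (1 - quantile)) {
    warning("fewer than ", ceiling(1 / (1 - quantile)),
            " values; the empirical cutoff is unstable")
  }
  cutoff <- stats::quantile(values, quantile, na.rm = TRUE, names = FALSE,
                            type = 7)
  hits <- !is.na(values) & values >= cutoff
  if (all(hits[is.finite(values)])) {
    warning("all values reach the cutoff (degenerate distribution)")
  }
  list(cutoff = cutoff, hits = hits)
}

#' Intersections of named hit-window sets
#'
#' Windows are keyed by `(chrom, start, end)`. Reports the size of every
#' non-empty combination of the input sets (Venn-style exclusive regions) as
#' well as all pairwise and higher-order intersection counts.
#'
#' @param hit_sets Named list of data.frames with columns `chrom`, `start`,
#'   `end`.
#' @return List with `exclusive` (data.frame: combination, count) and
#'   `intersections` (data.frame: combination, count, for every subset of the
#'   input names of size >= 2).
#' @export
intersect_hits <- function(hit_sets) {
  stopifnot(length(hit_sets) >= 2, !is.null(names(hit_sets)))
  keys <- lapply(hit_sets, function(df) {
    unique(paste(df$chrom, df$start, df$end, sep = ":"))
  })
  all_keys <- unique(unlist(keys))
  member <- vapply(keys, function(k) all_keys %in% k, logical(length(all_keys)))
  if (length(all_keys) == 1) member <- matrix(member, nrow = 1,
                                              dimnames = list(NULL, names(keys)))
  sig <- apply(member, 1, function(z) paste(names(keys)[z], collapse = "&"))
  excl <- as.data.frame(table(sig), stringsAsFactors = FALSE)
  names(excl) <- c("combination", "count")

  nm <- names(keys)
  combs <- list()
  for (k in 2:length(nm)) {
    cb <- utils::combn(nm, k, simplify = FALSE)
    for (s in cb) {
      combs[[paste(s, collapse = "&")]] <-
        length(Reduce(intersect, keys[s]))
    }
  }
  inter <- data.frame(combination = names(combs), count = unlist(combs),
                      row.names = NULL)
  list(exclusive = excl, intersections = inter)
}

#' Composite two-population selection scan
#'
#' Runs the full window-level scan: per-site Weir-Cockerham theta averaged in
#' half-overlapping windows (plus the ratio-of-sums variant), per-site XP-EHH
#' converted to -log10 p and averaged in the same windows, empirical
#' right-tail p-values of both window statistics over the DCMS-eligible
#' windows (those with at least `min_snps_dcms` SNPs), the DCMS composite,
#' and quantile hit flags for all three statistics.
#'
#' @param gm A phased, filtered [genotype_matrix()].
#' @param pops Two population labels (default: those present).
#' @param window,step Window tiling in bp.
#' @param min_snps_dcms Minimum SNPs per window for DCMS eligibility.
#' @param quantile Hit-calling quantile.
#' @param min_ehh,max_gap XP-EHH parameters.
#' @param cor_method Correlation method for the DCMS denominator.
#' @return List of class `selection_scan`: `windows` (one row per window with
#'   statistics, p-values, `dcms`, hit flags), `cutoffs`, `correlation`, and
#'   the per-site tables `fst_sites`, `xpehh_sites`.
#' @export
selection_scan <- function(gm, pops = NULL, window = 5e4, step = 2.5e4,
                           min_snps_dcms = 30, quantile = 0.995,
                           min_ehh = 0.05, max_gap = 2e5,
                           cor_method = "pearson") {
  if (is.null(pops)) pops <- unique(unname(gm$populations))
  fst <- wc_fst(gm, pops)
  xp <- xpehh(gm, pops, min_ehh = min_ehh, max_gap = max_gap)

  win_fst <- windowed_mean(fst$chrom, fst$pos, fst$theta, window, step,
                           chrom_lengths = gm$chrom_lengths)
  tot <- fst$a + fst$b + fst$c
  win_a <- windowed_mean(fst$chrom, fst$pos, fst$a, window, step,
                         chrom_lengths = gm$chrom_lengths)
  win_tot <- windowed_mean(fst$chrom, fst$pos, tot, window, step,
                           chrom_lengths = gm$chrom_lengths)
  win_xp <- windowed_mean(xp$chrom, xp$pos, xp$neglogp, window, step,
                          chrom_lengths = gm$chrom_lengths)

  w <- win_fst[, c("chrom", "start", "end", "n_snps")]
  w$fst_mean <- win_fst$value
  w$fst_ratio_of_sums <- win_a$value / win_tot$value
  key <- paste(w$chrom, w$start)
  w$xpehh_neglogp_mean <- win_xp$value[match(key, paste(win_xp$chrom, win_xp$start))]

  eligible <- w$n_snps >= min_snps_dcms &
    !is.na(w$fst_mean) & !is.na(w$xpehh_neglogp_mean)
  w$p_fst <- NA_real_
  w$p_xpehh <- NA_real_
  w$p_fst[eligible] <- empirical_right_tail_p(w$fst_mean[eligible])
  w$p_xpehh[eligible] <- empirical_right_tail_p(w$xpehh_neglogp_mean[eligible])

  w$dcms <- NA_real_
  dv <- dcms(w[eligible, c("fst_mean", "xpehh_neglogp_mean")],
             w[eligible, c("p_fst", "p_xpehh")], method = cor_method)
  w$dcms[eligible] <- dv

  h_fst <- call_hits(w$fst_mean, quantile)
  h_xp <- call_hits(w$xpehh_neglogp_mean, quantile)
  h_dcms <- call_hits(w$dcms, quantile)
  w$hit_fst <- h_fst$hits
  w$hit_xpehh <- h_xp$hits
  w$hit_dcms <- h_dcms$hits

  structure(
    list(windows = w,
         cutoffs = c(fst = h_fst$cutoff, xpehh = h_xp$cutoff,
                     dcms = h_dcms$cutoff),
         correlation = attr(dv, "correlation"),
         fst_sites = fst, xpehh_sites = xp),
    class = "selection_scan"
  )
}

#' @export
print.selection_scan <- function(x, ...) {
  w <- x$windows
  cat(sprintf("selection_scan: %d windows (%d DCMS-eligible)\n",
              nrow(w), sum(!is.na(w$dcms))))
  cat(sprintf("cutoffs: F_ST %.4f | -log10 p(XP-EHH) %.4f | DCMS %.4f\n",
              x$cutoffs["fst"], x$cutoffs["xpehh"], x$cutoffs["dcms"]))
  cat(sprintf("hits: F_ST %d | XP-EHH %d | DCMS %d\n",
              sum(w$hit_fst), sum(w$hit_xpehh), sum(w$hit_dcms)))
  invisible(x)
}
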