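test_that("per-site theta handles fixed and absent differentiation", {
  dos <- matrix(c(rep(2, 12), rep(0, 12)), ncol = 1)
  gm <- make_gm(dos, pops = stats::setNames(rep(c("A", "B"), each = 12),
                                            sprintf("s%02d", 1:24)))
  expect_equal(wc_fst(gm)$theta, 1)

  same <- c(0, 1, 2, 1, 0, 2, 1, 1, 0, 2, 2, 1)
  gm2 <- make_gm(matrix(c(same, same), ncol = 1),
                 pops = stats::setNames(rep(c("A", "B"), each = 12),
                                        sprintf("s%02d", 1:24)))
  expect_lte(wc_fst(gm2)$theta, 0)
})

test_that("theta components equal the independent component-formula oracle", {
  set.seed(30)
  for (i in 1:100) {
    n1 <- sample(4:24, 1); n2 <- sample(4:24, 1)
    d1 <- rbinom(n1, 2, runif(1, 0.1, 0.9))
    d2 <- rbinom(n2, 2, runif(1, 0.1, 0.9))
    if (i %% 7 == 0) d1[1] <- NA
    dos <- matrix(c(d1, d2), ncol = 1)
    rownames(dos) <- sprintf("s%03d", seq_len(n1 + n2))
    gm <- make_gm(dos, pops = stats::setNames(rep(c("A", "B"), c(n1, n2)),
                                              rownames(dos)))
    f <- wc_fst(gm)
    o <- wc_oracle(d1, d2)
    expect_equal(f$a, unname(o["a"]), tolerance = 1e-12)
    expect_equal(f$b, unname(o["b"]), tolerance = 1e-12)
    expect_equal(f$c, unname(o["c"]), tolerance = 1e-12)
    if (is.finite(o["theta"])) {
      expect_equal(f$theta, unname(o["theta"]), tolerance = 1e-12)
    }
  }
})

test_that("windowed means tile half-overlapping windows from zero", {
  pos <- c(10000, 30000, 60000, 90000)
  w <- windowed_mean(rep("c1", 4), pos, rep(3.5, 4), window = 5e4,
                     step = 2.5e4, chrom_lengths = c(c1 = 1e5))
  expect_equal(w$start, c(0, 25000, 50000, 75000))
  expect_true(all(w$value[w$n_snps > 0] == 3.5))

  set.seed(31)
  pos2 <- sort(sample(1:2e5, 20))
  val2 <- rnorm(20)
  w2 <- windowed_mean(rep("c1", 20), pos2, val2, window = 5e4, step = 2.5e4,
                      chrom_lengths = c(c1 = 2e5))
  for (i in seq_len(nrow(w2))) {
    inw <- pos2 >= w2$start[i] + 1 & pos2 <= w2$start[i] + 5e4
    expect_equal(w2$n_snps[i], sum(inw))
    if (sum(inw) > 0) expect_equal(w2$value[i], mean(val2[inw]))
  }
})

test_that("EHH follows the combinatorial definition and never increases", {
  # four haplotypes forming two identical pairs one SNP out: EHH = 2/6
  hap <- rbind(c(1, 0, 0), c(1, 0, 1), c(1, 1, 0), c(1, 1, 1))
  curve <- ehh(hap, c(1000, 2000, 3000), core = 1, min_ehh = 0.01)
  expect_equal(curve$ehh[curve$side == "core"], 1)
  expect_equal(curve$ehh[curve$position == 2000], 2 / 6)

  # all haplotypes identical: EHH = 1 everywhere
  hap2 <- matrix(1, nrow = 5, ncol = 4)
  curve2 <- ehh(hap2, (1:4) * 1000, core = 2)
  expect_true(all(curve2$ehh == 1))

  # all haplotypes distinct after the first flanking SNP: EHH drops to 0
  hap3 <- rbind(c(0, 0, 1), c(0, 1, 1))
  curve3 <- ehh(hap3, (1:3) * 1000, core = 1)
  expect_equal(curve3$ehh[curve3$position == 2000], 0)
  expect_false(3000 %in% curve3$position)  # truncated at the drop

  # monotone non-increasing away from the core, on random panels
  set.seed(32)
  for (r in 1:5) {
    hap4 <- matrix(rbinom(8 * 12, 1, 0.5), nrow = 8)
    cv <- ehh(hap4, (1:12) * 500, core = 6, min_ehh = 0)
    for (s in c("left", "right")) {
      seg <- cv[cv$side %in% c(s, "core"), ]
      seg <- seg[order(seg$distance), ]
      expect_true(all(diff(seg$ehh) <= 1e-12))
    }
  }
})

test_that("iES integrates the EHH curve by trapezoids", {
  # identical haplotypes, core centred: rectangle integral = L_left + L_right
  hap <- matrix(0, nrow = 4, ncol = 5)
  pos <- c(0, 5000, 10000, 15000, 20000)
  expect_equal(ies(hap, pos, core = 3, max_gap = 1e5), 20000)

  # hand-computed piecewise-linear case (one side only)
  hap2 <- rbind(c(0, 0, 0), c(0, 0, 1), c(0, 1, 1), c(0, 1, 0))
  # right side from core 1: at 2000 EHH = 2/6, at 3000 EHH = 0
  # trapezoids: (1 + 1/3)/2 * 1000 + (1/3 + 0)/2 * 1000 = 833.33
  got <- ies(hap2, c(1000, 2000, 3000), core = 1, min_ehh = 0.05)
  expect_equal(got, (1 + 1 / 3) / 2 * 1000 + (1 / 3) / 2 * 1000)

  # immediate truncation on both sides: single core point, iES = 0
  expect_warning(z <- ies(hap2, c(1000, 2e6, 4e6), core = 1, max_gap = 1e5),
                 "iES = 0")
  expect_equal(z, 0)
})

test_that("compiled iES scan equals the R integration path", {
  set.seed(33)
  for (r in 1:5) {
    m <- 30
    hap <- matrix(rbinom(12 * m, 1, 0.5), nrow = 12)
    pos <- sort(sample(1:5e4, m))
    scan <- charrscan:::ies_scan_cpp(hap, pos, 0.05, 2e5)
    for (core in c(1, 7, 15, 30)) {
      expect_equal(scan[core], ies(hap, pos, core), tolerance = 1e-9)
    }
  }
})

test_that("XP-EHH is antisymmetric under population swap and self-zero", {
  cfg <- sim_config(n_per_pop = 8, chrom_lengths = c(chr1 = 1e6),
                    snp_spacing_mean = 1000, fst_target = 0.05,
                    n_founders = 24, seed = 34)
  gm <- simulate_divergent_populations(cfg)
  ab <- xpehh(gm, c("pop1", "pop2"))
  ba <- xpehh(gm, c("pop2", "pop1"))
  expect_equal(ab$raw, -ba$raw)
  expect_equal(abs(ab$z), abs(ba$z), tolerance = 1e-12)
  expect_equal(ab$p, ba$p, tolerance = 1e-12)

  # identical panels: raw log-ratio is zero at every retained site
  rows <- charrscan:::hap_rows(gm, pop_samples(gm, "pop1"))
  hap1 <- gm$haplotypes[rows, , drop = FALSE]
  dos1 <- gm$dosages[match(pop_samples(gm, "pop1"), gm$samples), , drop = FALSE]
  dos_both <- rbind(dos1, dos1)
  rownames(dos_both) <- c(paste0("x", 1:8), paste0("y", 1:8))
  gm_same <- genotype_matrix(
    dos_both, gm$chrom, gm$pos,
    populations = stats::setNames(rep(c("X", "Y"), each = 8),
                                  rownames(dos_both)),
    haplotypes = rbind(hap1, hap1), chrom_lengths = gm$chrom_lengths)
  same <- xpehh(gm_same, c("X", "Y"))
  expect_true(all(same$raw == 0))
})

test_that("standardized XP-EHH is calibrated on a neutral simulation", {
  cfg <- sim_config(n_per_pop = 16, chrom_lengths = c(chr1 = 3e6, chr2 = 3e6),
                    snp_spacing_mean = 1000, fst_target = 0.12, seed = 35)
  gm <- simulate_divergent_populations(cfg)
  xp <- xpehh(gm)
  expect_gte(nrow(xp), 5000)
  expect_lt(abs(mean(xp$z)), 0.05)
  expect_lt(abs(sd(xp$z) - 1), 0.05)
})

test_that("empirical right-tail p-values follow the rank arithmetic", {
  set.seed(36)
  v <- c(rnorm(998), 50)
  p <- empirical_right_tail_p(v)
  expect_equal(p[999], 1 / 1000)           # the maximum of N = 999 values
  expect_true(all(p > 0 & p < 1))

  same <- rep(2.5, 10)
  expect_equal(empirical_right_tail_p(same), rep(10 / 11, 10))

  # monotone decreasing in the value; matches a sort-based oracle
  v2 <- rnorm(200)
  p2 <- empirical_right_tail_p(v2)
  o <- vapply(v2, function(x) (1 + sum(v2 >= x) - 1) / 201, numeric(1))
  expect_equal(p2, o)
  expect_true(all(diff(p2[order(v2)]) <= 0))
})

test_that("DCMS reproduces the composite formula and its invariances", {
  set.seed(37)
  n <- 200
  s1 <- rnorm(n); s2 <- 0.5 * s1 + rnorm(n)
  p1 <- empirical_right_tail_p(s1); p2 <- empirical_right_tail_p(s2)
  got <- dcms(cbind(a = s1, b = s2), cbind(p1, p2))

  # direct evaluation of the definition
  r <- cor(cbind(s1, s2))
  ref <- log((1 - p1) / p1) / (abs(r[1, 1]) + abs(r[2, 1])) +
    log((1 - p2) / p2) / (abs(r[1, 2]) + abs(r[2, 2]))
  expect_equal(as.vector(got), ref, tolerance = 1e-12)

  # all p = 0.5 gives 0 regardless of correlations
  p05 <- matrix(0.5, n, 2)
  expect_equal(as.vector(dcms(cbind(s1, s2), p05)), rep(0, n))

  # a single statistic at p = 0.01 scores ln(99)
  one <- dcms(matrix(s1, ncol = 1), matrix(c(0.01, rep(0.5, n - 1)), ncol = 1))
  expect_equal(one[1], log(99))

  # duplicating a statistic column halves each term: composite unchanged
  dup <- dcms(cbind(s1, s1), cbind(p1, p1))
  single <- dcms(matrix(s1, ncol = 1), matrix(p1, ncol = 1))
  expect_equal(as.vector(dup), as.vector(single), tolerance = 1e-12)

  expect_error(dcms(cbind(s1, rep(1, n)), cbind(p1, p2)), "constant")
  expect_error(dcms(matrix(numeric(0), 0, 0), matrix(numeric(0), 0, 0)),
               "at least one")
})

test_that("hit calling flags the top quantile including cutoff ties", {
  set.seed(38)
  v <- rnorm(1000)
  h <- call_hits(v, 0.995)
  expect_equal(sum(h$hits), 5)
  expect_true(all(v[h$hits] >= h$cutoff))

  expect_warning(hd <- call_hits(rep(1, 1000)), "degenerate")
  expect_true(all(hd$hits))
})

test_that("hit-set intersections equal brute-force set operations", {
  w <- function(ch, st) data.frame(chrom = ch, start = st, end = st + 5e4)
  a <- w("c1", seq(0, 25000 * 302, by = 25000))          # 303 windows
  set.seed(39)
  b <- a[sample(303, 150), ]
  c3 <- a[sample(303, 150), ]
  res <- intersect_hits(list(fst = a, xpehh = b, dcms = c3))
  key <- function(df) paste(df$chrom, df$start)
  expect_equal(res$intersections$count[res$intersections$combination == "fst&xpehh"],
               length(intersect(key(a), key(b))))
  expect_equal(res$intersections$count[
    res$intersections$combination == "fst&xpehh&dcms"],
    length(Reduce(intersect, list(key(a), key(b), key(c3)))))

  same <- intersect_hits(list(x = a, y = a))
  expect_equal(same$intersections$count, nrow(a))
  disjoint <- intersect_hits(list(x = a[1:10, ], y = a[11:20, ]))
  expect_equal(disjoint$intersections$count, 0)
})
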