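chrlen <- c(c1 = 1e8, c2 = 1e8)

test_that("half-overlapping windows merge into the documented regions", {
  # two 50-kb windows offset by 25 kb -> one 75-kb merged core
  two <- data.frame(chrom = "c1", start = c(1e6, 1.025e6),
                    end = c(1.05e6, 1.075e6))
  m <- merge_extend(two, chrlen, extend = 1e4)
  expect_equal(nrow(m), 1)
  expect_equal(m$core_end - m$core_start, 75000)
  expect_equal(m$end - m$start, 95000)  # + 10 kb each side

  # 21 windows of which 12 half-overlap pairwise: 6 x 75 kb + 9 x 50 kb
  pair_starts <- seq(0, by = 2e6, length.out = 6)
  iso_starts <- seq(5e7, by = 2e6, length.out = 9)
  windows <- rbind(
    data.frame(chrom = "c1", start = c(pair_starts, pair_starts + 25000),
               end = c(pair_starts, pair_starts + 25000) + 5e4),
    data.frame(chrom = "c2", start = iso_starts, end = iso_starts + 5e4))
  expect_equal(nrow(windows), 21)
  m21 <- merge_extend(windows, chrlen, extend = 1e4)
  expect_equal(nrow(m21), 15)
  sizes <- m21$core_end - m21$core_start
  expect_equal(sum(sizes == 75000), 6)
  expect_equal(sum(sizes == 50000), 9)
})

test_that("merging is idempotent, order-independent, and clips extensions", {
  set.seed(40)
  w <- data.frame(chrom = "c1",
                  start = sample(seq(0, 5e6, by = 2.5e4), 30))
  w$end <- w$start + 5e4
  m1 <- merge_extend(w, chrlen)
  m2 <- merge_extend(w[sample(nrow(w)), ], chrlen)
  expect_equal(m1, m2)
  again <- merge_extend(
    data.frame(chrom = m1$chrom, start = m1$core_start, end = m1$core_end),
    chrlen)
  expect_equal(again$core_start, m1$core_start)
  expect_equal(again$core_end, m1$core_end)
  # core intervals are non-overlapping after merging
  by_chr <- split(m1, m1$chrom)
  for (b in by_chr) {
    if (nrow(b) > 1) expect_true(all(b$core_start[-1] >= b$core_end[-nrow(b)]))
  }

  edge <- merge_extend(data.frame(chrom = "c1", start = 0, end = 5e4), chrlen)
  expect_equal(edge$start, 0)  # clipped at the chromosome start
  expect_error(merge_extend(data.frame(chrom = "nope", start = 0, end = 1),
                            chrlen), "unknown")
})

write_toy_gff <- function(genes) {
  path <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               sprintf("%s\ttoy\tgene\t%d\t%d\t.\t+\t.\tID=%s;Name=%s",
                       genes$chrom, genes$start1, genes$end1,
                       genes$id, genes$id)), path)
  path
}

test_that("gene assignment uses >= 1 bp overlap with correct boundaries", {
  genes <- data.frame(chrom = "c1",
                      start1 = c(1e6 + 1, 2e6 + 1, 3e6 + 1),
                      end1 = c(1e6 + 1e4, 2e6 + 1e4, 3e6 + 1e4),
                      id = c("inside", "abut", "far"))
  gff <- write_toy_gff(genes)
  # region [1e6, 2e6) 0-based half-open: covers 1-based 1e6+1 .. 2e6
  regions <- data.frame(chrom = "c1", start = 1e6, end = 2e6)
  out <- intersect_genes(regions, gff)
  expect_equal(out$genes, "inside")  # "abut" starts at end+1: excluded

  set.seed(41)
  rg <- data.frame(chrom = "c1", start = sort(sample(seq(0, 9e6, 1e5), 8)))
  rg$end <- rg$start + sample(c(5e4, 1.5e5), 8, replace = TRUE)
  gn <- data.frame(chrom = "c1", start1 = sort(sample(1:1e7, 40)))
  gn$end1 <- gn$start1 + sample(1e3:5e4, 40)
  gn$id <- sprintf("g%02d", 1:40)
  out2 <- intersect_genes(rg, write_toy_gff(gn))
  for (i in seq_len(nrow(rg))) {
    # brute-force interval intersection, 1-based inclusive vs half-open region
    hits <- gn$id[gn$end1 >= rg$start[i] + 1 & gn$start1 <= rg$end[i]]
    got <- setdiff(strsplit(out2$genes[i], ",")[[1]], "")
    expect_setequal(got, hits)
  }
})

test_that("enrichment fold and p follow the hypergeometric contingency", {
  # k=5, n=100, K=50, N=20000 -> fold = 20
  bg <- sprintf("g%05d", 1:20000)
  ts <- term_gene_sets(list(t1 = bg[1:50]), background = bg)
  hits <- c(bg[1:5], bg[1000:1094])
  out <- enrich(hits, ts)
  expect_equal(out$fold, 20)
  expect_equal(out$p, phyper(4, 50, 19950, 100, lower.tail = FALSE))

  # k = 0 scores fold 0, p 1
  out0 <- enrich(bg[1000:1099], ts)
  expect_equal(out0$fold, 0)
  expect_equal(out0$p, 1)

  # EASE mode shifts the tail by one
  oute <- enrich(hits, ts, mode = "ease")
  expect_equal(oute$p, phyper(3, 50, 19950, 100, lower.tail = FALSE))

  expect_error(enrich(c("not_a_gene"), ts), "outside the background")
})

test_that("enrichment agrees with exhaustive enumeration on tiny universes", {
  bg <- letters[1:12]
  ts <- term_gene_sets(list(tA = letters[1:4]), background = bg)
  n <- 5
  for (k in 0:4) {
    hits <- c(letters[seq_len(k)], letters[5:12][seq_len(n - k)])
    out <- enrich(hits, ts)
    # enumerate all 5-subsets of the 12-gene background
    cnt <- 0; tot <- 0
    for (s in utils::combn(12, n, simplify = FALSE)) {
      tot <- tot + 1
      if (length(intersect(s, 1:4)) >= max(k, 1)) cnt <- cnt + 1
    }
    ref_p <- if (k == 0) 1 else cnt / tot
    expect_equal(out$p, ref_p, tolerance = 1e-12)
    expect_equal(out$fold, (k / n) / (4 / 12))
  }
})

test_that("null enrichment p-values are calibrated uniform", {
  set.seed(43)
  N <- 2e5; K <- 1e5; n <- 2e4
  k <- rhyper(10000, K, N - K, n)
  p <- enrichment_pvalue(k, n, K, N)
  # a discrete upper-tail p is super-uniform; its randomized version
  # p - V * P(X = k), V ~ U(0,1), is exactly Uniform(0,1) under the null --
  # the standard calibration check for discrete tests
  u <- p - runif(10000) * dhyper(k, K, N - K, n)
  ks <- suppressWarnings(ks.test(u, "punif"))
  expect_gt(ks$p.value, 0.01)
  # raw p-values never exceed the nominal level (super-uniformity)
  for (alpha in c(0.01, 0.05, 0.1, 0.5)) {
    expect_lte(mean(p <= alpha), alpha + 3 * sqrt(alpha / 10000))
  }
})

test_that("Jaccard matrix follows the set-ratio definition", {
  ts <- term_gene_sets(list(A = c("x", "y", "z"),
                            B = c("x", "u"),
                            C = c("q", "r")))
  J <- jaccard_matrix(ts)
  expect_equal(unname(diag(J)), rep(1, 3))
  expect_equal(J["A", "B"], 1 / 4)
  expect_equal(J["A", "C"], 0)
  expect_equal(J, t(J))
  # |A ∩ B| = 1, |A ∪ B| = 3
  ts2 <- term_gene_sets(list(A = c("x", "y"), B = c("x", "z")))
  expect_equal(jaccard_matrix(ts2)["A", "B"], 1 / 3)
})
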