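test_that("simulation with F = 0 produces no differentiation", {
  cfg <- sim_config(n_per_pop = 24, chrom_lengths = c(chr1 = 4e6),
                    snp_spacing_mean = 400, fst_target = 0,
                    ld_block_scale = 0, seed = 1)
  gm <- simulate_divergent_populations(cfg)
  f <- wc_fst(gm)
  expect_lt(abs(mean(f$theta, na.rm = TRUE)), 0.01)
})

test_that("Balding-Nichols frequency law holds across sites (unlinked)", {
  cfg <- sim_config(n_per_pop = 200, chrom_lengths = c(chr1 = 6e6),
                    snp_spacing_mean = 500, fst_target = 0.12,
                    ld_block_scale = 0, seed = 2)
  gm <- simulate_divergent_populations(cfg)
  p1 <- allele_freq(gm, pop_samples(gm, "pop1"))
  p2 <- allele_freq(gm, pop_samples(gm, "pop2"))
  # Var(p1 - p2) = 2 F E[p(1-p)] with p ~ U(0.1, 0.9): E[p(1-p)] = 0.5 - E[p^2]
  expected <- 2 * 0.12 * (0.5 - (0.25 + 0.64 / 12))
  # subtract binomial sampling noise of the 2n-chromosome frequency estimates
  obs <- var(p1 - p2) - mean(p1 * (1 - p1) + p2 * (1 - p2)) / (2 * 200)
  expect_lt(abs(obs - expected) / expected, 0.10)
})

test_that("identical config and seed give byte-identical fixtures", {
  cfg <- sim_config(n_per_pop = 4, chrom_lengths = c(chr1 = 5e5),
                    snp_spacing_mean = 1000, seed = 42)
  d1 <- tempfile(); d2 <- tempfile()
  f1 <- write_fixture(simulate_divergent_populations(cfg), d1)
  f2 <- write_fixture(simulate_divergent_populations(cfg), d2)
  expect_identical(readLines(f1$vcf), readLines(f2$vcf))
  expect_identical(readLines(f1$gff3), readLines(f2$gff3))
})

test_that("mosaic LD decays monotonically across distance bins", {
  cfg <- sim_config(n_per_pop = 24, chrom_lengths = c(chr1 = 4e6),
                    snp_spacing_mean = 1000, fst_target = 0.12, seed = 3)
  gm <- simulate_divergent_populations(cfg)
  curve <- ld_decay(gm, "pop1", max_dist = 2e5, bin_width = 1e4)
  expect_true(all(diff(curve$mean_r2) <= 0.01))
  expect_true(all(curve$mean_r2 >= 0 & curve$mean_r2 <= 1))
})

test_that("population-specific block scales order the LD curves", {
  cfg <- sim_config(n_per_pop = 24, chrom_lengths = c(chr1 = 4e6),
                    snp_spacing_mean = 1000, fst_target = 0.12,
                    ld_block_scale = c(5e5, 5e4), seed = 4)
  gm <- simulate_divergent_populations(cfg)
  c1 <- ld_decay(gm, "pop1", max_dist = 1e5, bin_width = 5e4)
  c2 <- ld_decay(gm, "pop2", max_dist = 1e5, bin_width = 5e4)
  expect_gt(c1$mean_r2[2], c2$mean_r2[2])
})

test_that("inject_sweep fixes the target population's haplotypes", {
  cfg <- sim_config(n_per_pop = 12, chrom_lengths = c(chr1 = 2e6),
                    snp_spacing_mean = 1000, fst_target = 0.05,
                    n_founders = 24, seed = 5)
  gm <- simulate_divergent_populations(cfg)
  p2_before <- allele_freq(gm, pop_samples(gm, "pop2"))
  gm2 <- inject_sweep(gm, "pop1", "chr1", c(5e5, 1e6), 1.0, seed = 6)

  sites <- which(gm2$pos >= 5e5 & gm2$pos < 1e6)
  rows <- charrscan:::hap_rows(gm2, pop_samples(gm2, "pop1"))
  hap <- gm2$haplotypes[rows, sites]
  expect_true(all(apply(hap, 2, function(col) length(unique(col)) == 1)))
  # EHH = 1 across the swept interval within the target population
  curve <- ehh(gm2$haplotypes[rows, sites, drop = FALSE], gm2$pos[sites],
               core = 1, min_ehh = 0.05, max_gap = 1e6)
  expect_true(all(curve$ehh == 1))
  # the other population's allele frequencies are untouched
  expect_identical(allele_freq(gm2, pop_samples(gm2, "pop2")), p2_before)
})

test_that("inject_sweep rejects empty intervals and bad fractions", {
  cfg <- sim_config(n_per_pop = 4, chrom_lengths = c(chr1 = 1e6),
                    snp_spacing_mean = 1000, seed = 7)
  gm <- simulate_divergent_populations(cfg)
  expect_error(inject_sweep(gm, "pop1", "chr1", c(1e6, 1e6 + 10), 0.5),
               "no SNPs")
  expect_error(inject_sweep(gm, "pop1", "chr1", c(0, 1e5), 0), "carrier_fraction")
})

test_that("inject_roh makes tracts autozygous and validates overlap", {
  cfg <- sim_config(n_per_pop = 4, chrom_lengths = c(chr1 = 1e7),
                    snp_spacing_mean = 1000, fst_target = 0, seed = 8)
  gm <- simulate_divergent_populations(cfg)
  ind <- gm$samples[1]
  specs <- data.frame(individual = ind, chrom = "chr1", start = 2e6, end = 3e6)
  gm2 <- inject_roh(gm, specs)
  sites <- which(gm2$pos >= 2e6 & gm2$pos < 3e6)
  expect_true(all(gm2$dosages[1, sites] %in% c(0, 2)))
  # true autozygous fraction of a 1-Mb tract on a 10-Mb genome
  expect_equal((3e6 - 2e6) / sum(gm$chrom_lengths), 0.10)

  overlapping <- rbind(specs,
                       data.frame(individual = ind, chrom = "chr1",
                                  start = 2.5e6, end = 4e6))
  expect_error(inject_roh(gm, overlapping), "overlapping")
  empty <- data.frame(individual = ind, chrom = "chr1",
                      start = 5e6 + 100, end = 5e6 + 200)
  expect_warning(gm3 <- inject_roh(gm, empty), "no SNPs")
  expect_identical(gm3$dosages, gm$dosages)
})

test_that("sample_roh_specs hits the requested fraction exactly", {
  cfg <- sim_config(n_per_pop = 2, chrom_lengths = c(chr1 = 2e7, chr2 = 2e7),
                    snp_spacing_mean = 5000, seed = 9)
  gm <- simulate_divergent_populations(cfg)
  specs <- sample_roh_specs(gm, 0.0623, length_range = c(1e6, 5e6), seed = 10)
  for (ind in gm$samples) {
    s <- specs[specs$individual == ind, ]
    expect_equal(sum(s$end - s$start) / sum(gm$chrom_lengths), 0.0623,
                 tolerance = 1e-6)
  }
})

test_that("fixture files round-trip and are internally consistent", {
  cfg <- sim_config(n_per_pop = 5, chrom_lengths = c(chrA = 1e6, chrB = 8e5),
                    snp_spacing_mean = 2000, seed = 11)
  gm <- simulate_divergent_populations(cfg)
  dir <- tempfile()
  fx <- write_fixture(gm, dir)

  gm2 <- read_vcf(fx$vcf, fx$popmap)
  expect_identical(unname(gm2$dosages), unname(gm$dosages))
  expect_identical(unname(gm2$haplotypes), unname(gm$haplotypes))
  expect_identical(gm2$pos, gm$pos)
  expect_identical(gm2$chrom, gm$chrom)

  gff <- readLines(fx$gff3)
  body <- grep("^[^#]", gff, value = TRUE)
  fields <- strsplit(body, "\t")
  expect_true(all(lengths(fields) == 9))
  starts <- as.numeric(sapply(fields, `[`, 4))
  ends <- as.numeric(sapply(fields, `[`, 5))
  expect_true(all(starts >= 1 & ends >= starts))

  tm <- read.table(fx$term_map, sep = "\t", col.names = c("term", "gene"))
  gene_ids <- sub(".*ID=([^;]+);.*", "\\1", body)
  expect_true(all(tm$gene %in% gene_ids))
})

test_that("mito generator reproduces programmed mutation distances exactly", {
  mito <- simulate_mito_sequences(
    counts_per_hap = list(c(10, 4, 3, 2, 2, 1, 1, 1), c(16, 6, 2)),
    inter_group_mutations = c(0, 17),
    intra_group_mutations = list(c(0, 1, 2, 3, 3, 4, 4, 40), c(0, 3, 8)),
    length = 16658, group_labels = c("NOR", "SWE"), seed = 12)
  tab <- collapse_haplotypes(mito$sequences, mito$populations)
  expect_equal(nrow(tab$counts), 11)
  expect_equal(sum(tab$counts[, "NOR"] > 0), 8)
  expect_equal(sum(tab$counts[, "SWE"] > 0), 3)

  d <- mutation_distances(tab)
  hap_pop <- ifelse(tab$counts[, "NOR"] > 0, "NOR", "SWE")
  between <- d[hap_pop == "NOR", hap_pop == "SWE"]
  expect_equal(min(between), 17)
  expect_equal(max(between), 65)
  within_nor <- d[hap_pop == "NOR", hap_pop == "NOR"]
  expect_equal(max(within_nor), 44)
  within_swe <- d[hap_pop == "SWE", hap_pop == "SWE"]
  expect_equal(max(within_swe), 11)
})

test_that("mito generator is deterministic and degenerates gracefully", {
  args <- list(counts_per_hap = list(5), inter_group_mutations = 0,
               intra_group_mutations = list(0), length = 500, seed = 13)
  m1 <- do.call(simulate_mito_sequences, args)
  m2 <- do.call(simulate_mito_sequences, args)
  expect_identical(m1$sequences, m2$sequences)
  expect_equal(length(unique(m1$sequences)), 1)
  tab <- collapse_haplotypes(m1$sequences, m1$populations)
  net <- build_network(tab)
  expect_equal(nrow(net$nodes), 1)
  expect_equal(nrow(net$edges), 0)
})
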