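---
title: "Methods: models, parameters and design choices in charrscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in charrscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

charrscan analyses two diverged populations genotyped at dense biallelic SNPs
— the motivating system is a pair of farmed Arctic charr stocks of anadromous
and landlocked origin — and every stage is exercised end-to-end on a seeded
synthetic panel. This vignette documents the statistical models, the
parameters that matter, and the choices made where the design was genuinely
open.

## The synthetic two-population panel

`simulate_divergent_populations()` draws, per site, an ancestral frequency
`p ~ Uniform(0.1, 0.9)` and population frequencies from the Balding–Nichols
model, `Beta(p(1-F)/F, (1-p)(1-F)/F)`, whose variance is exactly
`F·p(1-p)`. `F = 0` bypasses the Beta draw (the distribution degenerates),
so a zero-divergence panel never divides by zero. The uniform range excludes
near-fixed sites because they destabilize the per-site Weir–Cockerham ratio;
a symmetric-Beta alternative (`ancestral_freq = 0.71` gives expected
heterozygosity ≈ 0.30, matching the observed heterozygosity of the study
populations) is available for analyses where the background heterozygosity
level matters, such as ROH detection.

Linkage is produced by a copying model: each haplotype is a mosaic of a
per-population pool of `n_founders` founder haplotypes, with segment lengths
exponential with mean `ld_block_scale`. Two haplotypes are correlated at
nearby sites exactly when they copy the same founder across the interval, so
r² decays with distance toward the background sampling level. This is a
deliberately simple stand-in: it matches no explicit demographic model, has
no recombination map, and its short-range LD ceiling is governed by the
founder-pool size.

Two consequences are handled explicitly:

- **Founder drift inflates differentiation.** The pool mean frequency has
  variance `(1-F)p(1-p)/n_founders` around the Balding–Nichols draw, adding
  `(1-F)/n_founders` of apparent F_ST. The generator inverts this analytically
  and shrinks the Beta parameter so the *realized* differentiation matches
  `fst_target`; targets below the floor `1/n_founders` trigger a warning.
- **Default calibration.** `n_founders = 10`, `ld_block_scale = 300` kb were
  fixed once by a small grid calibration targeting the study conditions the
  package is tested under — mean r² near 0.1 at 100 kb with realized
  F_ST ≈ 0.12 at 2 × 24 diploids. Unlinked mode (`ld_block_scale = 0`) draws
  genotypes independently and is used wherever exact frequency-model
  properties are asserted.

SNP positions form a Poisson process (`snp_spacing_mean`, default 385 bp ≈
2.6 SNPs/kb). A `spacing_dist = "regular"` option (gaps uniform in 0.5–1.5 ×
mean) exists for gap-capped analyses run at coarse density: with exponential
gaps at 2 kb mean spacing, gaps above a 10-kb ROH gap cap occur at rate
`exp(-5)` and would fragment genuinely autozygous tracts — a sampling
artefact that cannot arise at the resequencing density the defaults emulate
(at 385 bp spacing the same probability is `exp(-26)`).

`inject_sweep()` replaces a fraction of one population's haplotypes by a
single core haplotype inside an interval, creating the extended haplotype
homozygosity and allele-frequency shift that the scan statistics detect.
`inject_roh()` copies the first haplotype over the second inside per-individual
intervals; `sample_roh_specs()` draws non-overlapping tract sets whose summed
length hits a target genome fraction exactly (the last tract is trimmed, and a
sub-minimum remainder is folded into the previous tract).

The mitogenome generator builds haplotype groups on a star topology with
*disjoint* mutated positions, so every pairwise Hamming distance is the exact
sum of branch mutation counts — distances are programmable and verifiable by
direct counting. Its default-style usage in the tests mirrors the study
setting: 11 haplotypes in two clusters (8 + 3), minimum and maximum
between-cluster distances of 17 and 65 mutations, and within-cluster maxima
of 44 and 11.

What passing tests on this generator do *not* show: behaviour under real
site-frequency spectra, genotyping error, missingness structure, variable
recombination or mutation-rate heterogeneity. The generator is a correctness
harness, not a demographic simulator.

## Filtering, density, heterozygosity

`filter_sites()` retains sites with minor allele frequency strictly above
`maf_min` (default 0.05) and call rate at least `call_rate_min` (default 1.0).
Strict `>` was chosen for "MAF above 5%"; the comparison is switchable
(`maf_inclusive = TRUE`) because either reading is defensible. `maf_min = 0`
disables the MAF filter so the zero-threshold call is the identity. Missing
genotypes never enter allele-frequency numerators or denominators.
`snp_density()` tiles non-overlapping 100-kb windows from coordinate 0 and
reports SNPs/kb. Observed heterozygosity is the per-individual fraction of
non-missing genotypes that are heterozygous, averaged per population.

## LD decay and historical Ne

LD is the squared Pearson correlation of dosage vectors (genotype r², the
convention of LD-decay tools for unphased-dosage input), computed for all
intra-chromosomal pairs within 500 kb and binned by distance. Monomorphic
sites are excluded; the implementation requires complete data in the analysed
subset (sites with missingness are dropped with a message), which matches the
100% call-rate filter upstream.

`estimate_ne_history()` inverts Sved's drift expectation
`E[r²] = 1/(alpha + 4Nc) + 1/(2n)` bin by bin: distances map to recombination
fractions through a constant 1 cM/Mb and Haldane's function, the bin mean is
corrected by `1/(2n)`, and `Ne = (1/r²_adj − alpha)/(4c)` is dated
`1/(2c)` generations ago. `alpha = 1` (drift only) is the default; 2.2 is the
usual mutation-adjusted alternative. Bins whose corrected r² or Ne is
non-positive are dropped with a warning. On noiseless forward-generated Sved
curves the inversion is exact to machine precision; no attempt is made to
reproduce any particular published tool's binning heuristics, and the
trajectory should be read as comparative, not absolute (the approach is known
to carry large standard errors).

## Relationships, PCA, pruning

The GRM uses Yang's estimator: off-diagonal entries average
`(x_i − 2p)(x_j − 2p)/(2p(1−p))` over sites where both samples are genotyped;
diagonals use the dedicated `1 + (x² − (1+2p)x + 2p²)/(2p(1−p))` form.
Frequencies come from the sample itself, which makes the mean off-diagonal
sit near `−1/(n−1)` rather than 0 — a property of all in-sample GRMs, worth
remembering when reading the within/between-population summaries. PCA
standardizes by `2p` and `sqrt(2p(1−p))`, mean-imputes missing entries, and
reports eigenvalue shares of the standardized variance.

`ld_prune()` scans windows left to right (bp-based, e.g. r² < 0.15 / 50 kb /
10 kb, or SNP-count-based, e.g. r² ≤ 0.01 / 100 SNPs / 10 SNPs — both
parameterizations used in this kind of study are supported). Within a window
the highest-r² offending pair is resolved by removing its lower-MAF member
(ties: the right-hand site), deterministically; the surviving set provably
contains no intra-window pair above the threshold, but the output is not
claimed bit-identical to any external pruner.

## Runs of homozygosity and F_ROH

The detector slides a `window_snps` window one SNP at a time per individual
and chromosome. A window is homozygous when its heterozygous-or-missing count
is at most `max_opposite_per_window` *and* no internal adjacent-SNP gap
exceeds `max_gap_bp`. A SNP is in a run when at least
`min_window_hit_fraction` (default 0.05, the documented default of the
reference sliding-window implementation) of the windows covering it are
homozygous. Maximal qualifying stretches become segments when they span at
least `min_length_bp` and `min_snps_in_run` SNPs; boundaries are the first
and last SNP positions. Defaults mirror the resequencing-scale setting:
2500-SNP windows, 10-kb gap, 1-Mb minimum, 150 opposite genotypes (6% of the
window), minimum SNPs equal to window size. Missing genotypes count as
opposite (conservative; configurable). Segments bin into 1–2, 2–4, 4–8 and
8–16 Mb classes — the first class is labelled "0–2 Mb" by convention even
though sub-1-Mb runs cannot pass the filter — and `F_ROH` divides summed
segment length by genome length (sum of the analysed chromosome lengths; a
whole-reference length can be passed instead).

The exact window-versus-run gap semantics of published ROH tools are not
fully specified; the rule above is therefore oracle-tested against an
independent brute-force scanner (property-based sweep over random parameter
sets, instances ≤ 300 SNPs) rather than claimed identical to any tool. Runs
overhang true tract edges by a few window-lengths' worth of SNPs (the hit
fraction is permissive), a small upward bias (~+0.05 percentage points of
F_ROH at the recovery-test settings) well inside the tested ±0.5-point band.

## The selection scan

Per-site Weir–Cockerham variance components `a`, `b`, `c` (1984 formulation,
two populations) give `θ = a/(a+b+c)`, undefined where the total is zero.
Negative per-site θ are retained. Windows are 50 kb with 25-kb step from
coordinate 0; the window statistic is the unweighted mean of per-site θ
("averaged"), with the ratio-of-sums (`Σa/Σ(a+b+c)`) variant also emitted.
The two differ systematically: averaging ratios is Jensen-biased low (about
18% at F = 0.12 under Balding–Nichols), while the ratio-of-sums form is the
standard genome-wide estimator and inverts the frequency model exactly —
which is why the package's F_ST recovery check reports the weighted form.

EHH at extension site x is the probability that two random haplotypes are
identical over all sites from the core (exclusive — EHH(core) = 1 by
convention) to x (inclusive): `Σ_h C(n_h,2)/C(n,2)`. Curves truncate below
`min_ehh` (0.05; the sub-threshold point is included in the integral), at
gaps over `max_gap` (200 kb), or at chromosome edges; iES is the two-sided
trapezoid integral over physical distance in bp. XP-EHH is
`ln(iES_A/iES_B)`, standardized genome-wide, converted to a *two-sided*
normal p-value — sidedness is a genuine choice; two-sided was picked because
sweeps in either population are of interest — and `−log10 p` is averaged in
the same windows. The scan core is compiled (Rcpp) and cross-checked against
the plain-R curve integration.

Per-window empirical right-tail p-values,
`p_i = (1 + #{j≠i: v_j ≥ v_i})/(N+1)`, are computed for both window
statistics over DCMS-eligible windows (≥ 30 SNPs). The composite is

`DCMS_w = Σ_t log((1 − p_wt)/p_wt) / Σ_i |r_it|`

with `r` the Pearson (optionally Spearman) correlation matrix of the window
statistics across eligible windows. Absolute correlations are used in the
denominator, following the method's source formulation; signed summation
would let negatively correlated statistics *inflate* each other's weight.
Natural logarithms throughout; p-values clamped to `[1e-10, 1 − 1e-10]`.
Duplicating a statistic column halves each copy's weight and leaves the
composite unchanged — this invariance is asserted in the tests. Hits are
windows at or above the empirical 99.5% quantile (type-7 interpolation; ties
at the cutoff are all included).

## Sweep regions, annotation, enrichment

Candidate windows sharing at least 50% of the shorter interval merge
(repeatedly, to a fixed point) — so two 50-kb windows offset by 25 kb become
one 75-kb region, and 21 windows of which 12 half-overlap pairwise become
6 + 9 = 15 regions — then regions extend ±10 kb, clipped to chromosome
bounds. Genes are assigned on ≥ 1 bp overlap (the common interval-intersection
default), with GFF3's 1-based inclusive coordinates converted to the internal
0-based half-open convention at the boundary. Enrichment of the hit gene list
against user-supplied term→gene sets reports fold `(k/n)/(K/N)` and the
hypergeometric upper tail (mode `"fisher"`; `"ease"` shifts the tail by one
for the conservative DAVID-style score); p-values are unadjusted by default
with Benjamini–Hochberg behind a flag. Published enrichment scores depend on
a curated background universe that is not recoverable here, so no external
fold value is treated as a test target. Term similarity is the Jaccard
matrix; the Jaccard *similarity* is not a metric, so no triangle property is
asserted.

## Mitogenome haplotype networks

Aligned sequences are haplotyped after complete deletion of any column
containing a gap or ambiguity (simple, order-independent; per-pair deletion
would keep more sites but make distances non-additive). Distances are raw
differing-site counts. The network is a Kruskal MST with ties broken by the
lexicographic node-id pair, so outputs are reproducible; a non-tree edge is
reported as an alternative link exactly when its weight equals the maximum
edge weight on the tree path between its endpoints (swapping it in gives an
equally parsimonious tree). An MST was chosen over statistical-parsimony
networks as the simplest reproducible structure; assembly, rotation and
alignment of the mitogenomes are expected upstream.

## Pipeline, determinism, problem sizes

`run_pipeline()` validates its configuration before any stage runs, executes
stages in dependency order, writes one TSV per stage plus a JSON manifest
(package version, seed, parameters), and is deterministic given the seed: a
rerun reproduces every numeric table byte for byte. All randomness in the
package flows from explicit integer seeds; internal child streams are derived
per chromosome and stage so that enlarging one chromosome does not reshuffle
another's draws.

The test suite runs the recovery simulations at deliberately modest sizes
chosen to make the checks sharp but quick: F_ST recovery at 2 × 24 diploids ×
20,000 unlinked SNPs × 5 seeds; F_ROH recovery on a 25-chromosome, 500-Mb
genome at 2-kb spacing with scaled detector parameters (window 50, minimum
run 1 Mb); sweep-detection power over 20 seeded replicates of a 10-Mb genome
(~26,000 SNPs, 400 windows) with a carrier fraction of 0.8 against an F = 0.02
background; oracle equivalences on instances small enough for exhaustive
enumeration (≤ 300 SNPs, ≤ 7 network nodes).

## Known limitations

- The generator's LD is mosaic-based: it cannot produce high short-range r²
  and a low F_ST floor simultaneously (both are controlled by the founder
  pool size), and its decay shape is exponential-ish by construction.
- XP-EHH standardization is genome-wide, not frequency-bin-wise; on panels
  with strong frequency structure binned standardization would be preferable.
- The Ne trajectory inherits every caveat of Sved-type inversions: constant
  recombination rate, equilibrium assumptions, and large sampling error.
- ROH detection semantics are oracle-defined (see above), not bit-compatible
  with any specific external tool.
- Enrichment results are only as meaningful as the supplied term map and
  background universe.
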