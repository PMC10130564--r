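#' Configuration for the full analysis pipeline
#'
#' Bundles input paths and every stage parameter (defaults are the
#' resequencing-scale settings the package targets throughout: MAF > 0.05,
#' call rate 1.0, 50 kb windows with 25 kb step, 2500-SNP ROH windows with
#' 10 kb gap and 1 Mb minimum length, DCMS eligibility at 30 SNPs, top-0.5%
#' hit calling, 10 kb region extension). Validation happens here, before any
#' stage runs.
#'
#' @param vcf Path to the (phased) input VCF.
#' @param population_map Path to the sample-to-population TSV.
#' @param gff3 Optional GFF3 annotation path (enables region annotation).
#' @param term_map Optional term-to-gene TSV path (enables enrichment).
#' @param mito_fasta Optional aligned mitogenome FASTA (enables the haplotype
#'   network stage).
#' @param out_dir Output directory.
#' @param maf_min,call_rate_min Site filters.
#' @param window,step Scan window tiling in bp.
#' @param min_snps_dcms DCMS window eligibility.
#' @param quantile Hit-calling quantile.
#' @param roh A [roh_params()].
#' @param extend Region extension in bp.
#' @param merge_overlap_fraction Window merge rule.
#' @param ld_max_dist,ld_bin_width LD-decay parameters in bp.
#' @param seed Integer seed (stages are deterministic given it).
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(vcf, population_map, gff3 = NULL, term_map = NULL,
                            mito_fasta = NULL, out_dir,
                            maf_min = 0.05, call_rate_min = 1.0,
                            window = 5e4, step = 2.5e4,
                            min_snps_dcms = 30, quantile = 0.995,
                            roh = roh_params(),
                            extend = 1e4, merge_overlap_fraction = 0.5,
                            ld_max_dist = 5e5, ld_bin_width = 2.5e4,
                            seed = 1) {
  for (p in c(vcf, population_map, gff3, term_map, mito_fasta)) {
    if (!is.null(p) && !file.exists(p)) stop("input file not found: ", p)
  }
  if (quantile <= 0 || quantile >= 1) stop("`quantile` must lie in (0, 1)")
  if (maf_min < 0 || maf_min > 1 || call_rate_min < 0 || call_rate_min > 1) {
    stop("filter thresholds must lie in [0, 1]")
  }
  stopifnot(inherits(roh, "roh_params"), window > 0, step > 0, extend >= 0)
  structure(
    list(vcf = vcf, population_map = population_map, gff3 = gff3,
         term_map = term_map, mito_fasta = mito_fasta, out_dir = out_dir,
         maf_min = maf_min, call_rate_min = call_rate_min,
         window = window, step = step, min_snps_dcms = min_snps_dcms,
         quantile = quantile, roh = roh, extend = extend,
         merge_overlap_fraction = merge_overlap_fraction,
         ld_max_dist = ld_max_dist, ld_bin_width = ld_bin_width,
         seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Run the full two-population analysis pipeline
#'
#' Stages, in dependency order: read + filter genotypes; SNP density and
#' observed heterozygosity; LD pruning, GRM, PCA and Welch's t on
#' within-population relatedness; LD decay and historical Ne per population;
#' ROH detection, length classes and F_ROH; the composite selection scan
#' (windowed F_ST, XP-EHH, DCMS, hit calling, hit-set intersections); region
#' merging/extension, gene annotation, enrichment and the Jaccard term
#' matrix; and, when an aligned mitogenome FASTA is supplied, haplotype
#' collapsing and the MST network. Every stage's table is written as TSV
#' under `out_dir`, plus a JSON run manifest with the package version, seed
#' and parameter set.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a named list with the in-memory stage results and
#'   `files` (paths written).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- list()
  log_stage <- function(fmt, ...) {
    message(sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                    sprintf(fmt, ...)))
  }
  emit <- function(df, name) {
    path <- file.path(config$out_dir, paste0(name, ".tsv"))
    write_tsv(df, path)
    files[[name]] <<- path
  }

  set.seed(config$seed)
  log_stage("reading %s", config$vcf)
  gm <- read_vcf(config$vcf, config$population_map)
  log_stage("%d samples, %d sites read (%d record(s) skipped)",
            n_samples(gm), n_sites(gm), attr(gm, "n_skipped"))
  gm <- filter_sites(gm, config$maf_min, config$call_rate_min)
  log_stage("%d sites after MAF/call-rate filtering", n_sites(gm))
  pops <- unique(unname(gm$populations))

  emit(snp_density(gm), "snp_density")
  emit(observed_heterozygosity(gm, "individual"), "heterozygosity_individual")
  emit(observed_heterozygosity(gm, "population"), "heterozygosity_population")

  log_stage("LD pruning + GRM + PCA")
  pruned_idx <- ld_prune(gm, r2_max = 0.15, window = 5e4, step = 1e4)
  gm_pruned <- subset_sites(gm, pruned_idx)
  g <- grm(gm)
  emit(data.frame(sample = rownames(g), as.data.frame(unclass(g))), "grm")
  pc <- pca_genotypes(gm_pruned, n_components = min(10, n_samples(gm) - 1))
  emit(data.frame(sample = rownames(pc$scores), pc$scores,
                  population = unname(gm$populations[rownames(pc$scores)])),
       "pca_scores")
  emit(data.frame(component = seq_along(pc$prop_var),
                  prop_var = pc$prop_var), "pca_prop_var")
  emit(grm_group_means(g, gm$populations), "grm_group_means")
  if (length(pops) == 2) {
    wt <- welch_t(within_pop_relationships(g, gm$populations, pops[1]),
                  within_pop_relationships(g, gm$populations, pops[2]))
    emit(data.frame(statistic = names(wt), value = unname(wt)),
         "welch_within_relatedness")
  }

  log_stage("LD decay + Ne history")
  ne_list <- list()
  for (pp in pops) {
    curve <- ld_decay(gm, pp, max_dist = config$ld_max_dist,
                      bin_width = config$ld_bin_width)
    emit(as.data.frame(curve), paste0("ld_decay_", pp))
    ne <- suppressWarnings(
      estimate_ne_history(curve, n_samples = length(pop_samples(gm, pp))))
    ne_list[[pp]] <- ne
    emit(ne, paste0("ne_history_", pp))
  }

  log_stage("ROH detection")
  segments <- suppressWarnings(detect_roh(gm, config$roh))
  emit(segments, "roh_segments")
  emit(classify_roh(segments), "roh_classes")
  froh_tab <- froh_by_individual(segments, sum(gm$chrom_lengths),
                                 samples = gm$samples)
  froh_tab$population <- unname(gm$populations[froh_tab$individual])
  emit(froh_tab, "froh")

  log_stage("selection scan (F_ST + XP-EHH + DCMS)")
  scan <- selection_scan(gm, pops, window = config$window, step = config$step,
                         min_snps_dcms = config$min_snps_dcms,
                         quantile = config$quantile)
  emit(scan$windows, "scan_windows")
  emit(data.frame(statistic = names(scan$cutoffs),
                  cutoff = unname(scan$cutoffs)), "scan_cutoffs")
  w <- scan$windows
  sets <- list(fst = w[w$hit_fst, c("chrom", "start", "end")],
               xpehh = w[w$hit_xpehh, c("chrom", "start", "end")],
               dcms = w[w$hit_dcms, c("chrom", "start", "end")])
  iv <- intersect_hits(sets)
  emit(iv$exclusive, "hit_overlap_exclusive")
  emit(iv$intersections, "hit_overlap_intersections")

  regions <- merge_extend(sets$dcms, gm$chrom_lengths, config$extend,
                          config$merge_overlap_fraction)
  annotated <- NULL
  enrichment <- NULL
  jaccard <- NULL
  if (!is.null(config$gff3) && nrow(regions) > 0) {
    log_stage("annotating %d candidate region(s)", nrow(regions))
    annotated <- intersect_genes(regions, config$gff3)
    emit(annotated, "sweep_regions")
    if (!is.null(config$term_map)) {
      ts <- read_term_map(config$term_map)
      hits <- intersect(unique(unlist(strsplit(annotated$genes, ","))),
                        ts$background)
      hits <- setdiff(hits, "")
      if (length(hits) > 0) {
        enrichment <- enrich(hits, ts)
        emit(enrichment, "enrichment")
        sig <- enrichment$term[enrichment$p < 0.05 & enrichment$k > 0]
        if (length(sig) >= 2) {
          jaccard <- jaccard_matrix(term_gene_sets(ts$sets[sig],
                                                   ts$background))
          emit(data.frame(term = rownames(jaccard), as.data.frame(jaccard)),
               "jaccard")
        }
      }
    }
  } else {
    emit(regions, "sweep_regions")
  }

  mito <- NULL
  if (!is.null(config$mito_fasta)) {
    log_stage("mitogenome haplotype network")
    dna <- ape::read.FASTA(config$mito_fasta)
    seqs <- vapply(as.character(dna), paste, character(1), collapse = "")
    popmap <- read_population_map(config$population_map)
    pops_named <- stats::setNames(popmap$population, popmap$sample)
    keep <- names(seqs) %in% names(pops_named)
    tab <- collapse_haplotypes(seqs[keep], pops_named)
    net <- build_network(tab)
    emit(data.frame(haplotype = rownames(tab$counts), tab$counts,
                    size = lengths(tab$members)), "mito_haplotypes")
    emit(net$edges, "mito_network_edges")
    write_haplonet(net, file.path(config$out_dir, "mito_network.graphml"))
    files[["mito_network"]] <- file.path(config$out_dir, "mito_network.graphml")
    mito <- list(table = tab, network = net)
  }

  manifest <- list(
    package = "charrscan",
    version = as.character(utils::packageVersion("charrscan")),
    seed = config$seed,
    parameters = config[setdiff(names(config),
                                c("vcf", "population_map", "gff3", "term_map",
                                  "mito_fasta", "out_dir"))],
    inputs = config[c("vcf", "population_map", "gff3", "term_map",
                      "mito_fasta")],
    n_samples = n_samples(gm), n_sites = n_sites(gm)
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null",
                       force = TRUE)
  files[["manifest"]] <- file.path(config$out_dir, "manifest.json")
  log_stage("done: %d file(s) under %s", length(files), config$out_dir)

  invisible(list(gm = gm, grm = g, pca = pc, ne = ne_list,
                 roh = segments, froh = froh_tab, scan = scan,
                 regions = regions, annotated = annotated,
                 enrichment = enrichment, jaccard = jaccard, mito = mito,
                 files = files))
}
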