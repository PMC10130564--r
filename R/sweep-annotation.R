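#' Merge overlapping candidate windows and extend them
#'
#' Windows sharing at least `merge_overlap_fraction` of the shorter interval
#' are unioned (repeatedly, until stable), then every resulting region is
#' extended by `extend` bp on either side and clipped to `[0, chrom_length]`.
#' With the default fraction of 0.5, two 50-kb windows offset by 25 kb merge
#' into one 75-kb region, while windows that merely touch do not merge.
#'
#' @param windows `data.frame` with columns `chrom`, `start`, `end` (0-based
#'   half-open).
#' @param chrom_lengths Named numeric vector of chromosome lengths in bp.
#' @param extend Extension on either side in bp (default 10 kb).
#' @param merge_overlap_fraction Minimum shared fraction (of the shorter
#'   interval) for two windows to be merged; 0 merges any positive overlap.
#' @return `data.frame` with `chrom`, `start`, `end` (extended, clipped),
#'   `core_start`, `core_end` (pre-extension), `n_windows`.
#' @export
merge_extend <- function(windows, chrom_lengths, extend = 1e4,
                         merge_overlap_fraction = 0.5) {
  stopifnot(all(c("chrom", "start", "end") %in% names(windows)),
            extend >= 0, merge_overlap_fraction >= 0,
            merge_overlap_fraction <= 1)
  unknown <- setdiff(unique(windows$chrom), names(chrom_lengths))
  if (length(unknown) > 0) {
    stop("windows on unknown chromosome(s): ", paste(unknown, collapse = ", "))
  }
  out <- list()
  for (cc in unique(windows$chrom)) {
    v <- windows[windows$chrom == cc, c("start", "end")]
    v <- v[order(v$start, v$end), ]
    n_merged <- rep(1L, nrow(v))
    repeat {
      merged_any <- FALSE
      i <- 1
      while (i < nrow(v)) {
        ov <- min(v$end[i], v$end[i + 1]) - max(v$start[i], v$start[i + 1])
        shorter <- min(v$end[i] - v$start[i], v$end[i + 1] - v$start[i + 1])
        if (ov > 0 && ov / shorter >= merge_overlap_fraction &&
            (merge_overlap_fraction > 0 || ov > 0)) {
          v$start[i] <- min(v$start[i], v$start[i + 1])
          v$end[i] <- max(v$end[i], v$end[i + 1])
          n_merged[i] <- n_merged[i] + n_merged[i + 1]
          v <- v[-(i + 1), ]
          n_merged <- n_merged[-(i + 1)]
          merged_any <- TRUE
        } else {
          i <- i + 1
        }
      }
      if (!merged_any) break
    }
    out[[cc]] <- data.frame(
      chrom = cc,
      start = pmax(0, v$start - extend),
      end = pmin(chrom_lengths[[cc]], v$end + extend),
      core_start = v$start, core_end = v$end,
      n_windows = n_merged
    )
  }
  res <- do.call(rbind, out)
  res <- res[order(match(res$chrom, names(chrom_lengths)), res$start), ]
  rownames(res) <- NULL
  res
}

#' Read gene models from a GFF3 file
#'
#' @param path GFF3 path (1-based inclusive coordinates on disk).
#' @param feature Feature type to keep (default `"gene"`).
#' @return A `GRanges` with metadata columns `gene_id` and `gene_name`.
#' @export
read_gff3_genes <- function(path, feature = "gene") {
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[gr$type == feature]
  id <- if ("ID" %in% names(S4Vectors::mcols(gr))) gr$ID else NA_character_
  nm <- if ("Name" %in% names(S4Vectors::mcols(gr))) gr$Name else id
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    gene_id = as.character(id),
    gene_name = as.character(ifelse(is.na(nm) | nm == "", id, nm))
  )
  gr
}

#' Assign genes to candidate sweep regions
#'
#' A gene is assigned to a region when the intervals overlap by at least one
#' bp (regions are 0-based half-open internally; the GFF3's 1-based inclusive
#' coordinates are handled by the import).
#'
#' @param regions `data.frame` with `chrom`, `start`, `end` (0-based
#'   half-open), e.g. from [merge_extend()].
#' @param genes Path to a GFF3 file or a `GRanges` from [read_gff3_genes()].
#' @param feature Feature type when `genes` is a path.
#' @return `regions` with added columns `n_genes` and `genes`
#'   (comma-separated gene ids; `""` when none).
#' @export
intersect_genes <- function(regions, genes, feature = "gene") {
  if (is.character(genes)) genes <- read_gff3_genes(genes, feature)
  reg <- GenomicRanges::GRanges(
    seqnames = regions$chrom,
    ranges = IRanges::IRanges(start = regions$start + 1, end = regions$end)
  )
  hits <- GenomicRanges::findOverlaps(reg, genes, minoverlap = 1L)
  gene_lists <- split(genes$gene_id[S4Vectors::subjectHits(hits)],
                      factor(S4Vectors::queryHits(hits),
                             levels = seq_len(nrow(regions))))
  regions$n_genes <- lengths(gene_lists)
  regions$genes <- vapply(gene_lists, paste, character(1), collapse = ",")
  regions
}

#' Read a term-to-gene map
#'
#' @param path Headerless two-column TSV: `term<TAB>gene`.
#' @param background Optional explicit background gene universe (default: all
#'   genes appearing in the map).
#' @return List of class `term_gene_sets`: `sets` (named list of gene-id
#'   vectors) and `background` (character vector).
#' @export
read_term_map <- function(path, background = NULL) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("term", "gene"),
                          stringsAsFactors = FALSE)
  term_gene_sets(split(df$gene, df$term), background)
}

#' Construct a term-to-gene-set object
#' @param sets Named list of gene-id vectors (non-empty).
#' @param background Optional background universe; defaults to the union of
#'   all sets. Every set member must be in the background.
#' @return List of class `term_gene_sets`.
#' @export
term_gene_sets <- function(sets, background = NULL) {
  sets <- lapply(sets, unique)
  if (any(lengths(sets) == 0)) stop("empty term set(s)")
  if (is.null(background)) background <- unique(unlist(sets))
  stray <- setdiff(unique(unlist(sets)), background)
  if (length(stray) > 0) {
    stop("term-set gene(s) outside the background: ",
         paste(utils::head(stray, 5), collapse = ", "))
  }
  structure(list(sets = sets, background = unique(background)),
            class = "term_gene_sets")
}

#' Hypergeometric enrichment p-value
#'
#' Upper-tail probability of drawing at least `k` (mode `"fisher"`) or at
#' least `k - 1` (mode `"ease"`, the DAVID-style conservative score) term
#' genes when sampling `n` genes from a background of `N` containing `K` term
#' genes. `k = 0` returns 1.
#'
#' @param k Observed term genes in the hit list.
#' @param n Hit-list size.
#' @param K Term size in the background.
#' @param N Background size.
#' @param mode `"fisher"` or `"ease"`.
#' @return P-value in `(0, 1]`.
#' @export
enrichment_pvalue <- function(k, n, K, N, mode = c("fisher", "ease")) {
  mode <- match.arg(mode)
  kk <- if (mode == "ease") pmax(k - 1, 0) else k
  ifelse(k == 0, 1, stats::phyper(kk - 1, K, N - K, n, lower.tail = FALSE))
}

#' Gene-set enrichment of a hit list
#'
#' Fold enrichment `(k/n) / (K/N)` and hypergeometric p-value per term;
#' p-values are reported unadjusted by default (Benjamini-Hochberg optionally
#' added as `p_adj`).
#'
#' @param gene_hits Character vector of hit gene ids (must be a subset of the
#'   background).
#' @param term_sets A [term_gene_sets()].
#' @param mode `"fisher"` or `"ease"`.
#' @param adjust Add Benjamini-Hochberg adjusted p-values.
#' @return `data.frame` with `term`, `k`, `n`, `K`, `N`, `fold`, `p`
#'   (and `p_adj` when requested), ordered by `p`.
#' @export
enrich <- function(gene_hits, term_sets, mode = c("fisher", "ease"),
                   adjust = FALSE) {
  mode <- match.arg(mode)
  stopifnot(inherits(term_sets, "term_gene_sets"))
  gene_hits <- unique(gene_hits)
  stray <- setdiff(gene_hits, term_sets$background)
  if (length(stray) > 0) {
    stop("hit gene(s) outside the background: ",
         paste(utils::head(stray, 5), collapse = ", "))
  }
  n <- length(gene_hits)
  N <- length(term_sets$background)
  res <- do.call(rbind, lapply(names(term_sets$sets), function(tm) {
    K <- length(term_sets$sets[[tm]])
    k <- length(intersect(gene_hits, term_sets$sets[[tm]]))
    data.frame(term = tm, k = k, n = n, K = K, N = N,
               fold = if (n > 0) (k / n) / (K / N) else 0,
               p = enrichment_pvalue(k, n, K, N, mode))
  }))
  if (adjust) res$p_adj <- stats::p.adjust(res$p, method = "BH")
  res <- res[order(res$p, -res$fold), ]
  rownames(res) <- NULL
  res
}

#' Jaccard similarity matrix of term gene sets
#'
#' `J(A, B) = |A intersect B| / |A union B|`; the diagonal is 1 and empty
#' intersections score 0.
#'
#' @param term_sets A [term_gene_sets()] (>= 2 terms).
#' @return Symmetric numeric matrix with term names as dimnames.
#' @export
jaccard_matrix <- function(term_sets) {
  stopifnot(inherits(term_sets, "term_gene_sets"))
  sets <- term_sets$sets
  if (length(sets) < 2) stop("at least two terms are required")
  nm <- names(sets)
  J <- matrix(0, length(sets), length(sets), dimnames = list(nm, nm))
  for (i in seq_along(sets)) {
    J[i, i] <- 1
    if (i < length(sets)) for (j in (i + 1):length(sets)) {
      J[i, j] <- J[j, i] <-
        length(intersect(sets[[i]], sets[[j]])) /
        length(union(sets[[i]], sets[[j]]))
    }
  }
  J
}
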