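#' Collapse aligned sequences into haplotypes
#'
#' Alignment columns containing any gap or ambiguity character (anything
#' other than A, C, G, T) are removed across all sequences (complete
#' deletion); identical remaining sequences are grouped into haplotypes,
#' ordered by decreasing carrier count (ties: order of first appearance).
#'
#' @param sequences Aligned sequences of equal length: a named character
#'   vector, a character matrix (sequences in rows), or an `ape` `DNAbin`.
#' @param populations Named character vector mapping sequence name to
#'   population label.
#' @return List of class `haplotype_table`: `seqs` (named representative
#'   sequences after column deletion), `members` (named list of sequence
#'   ids), `counts` (haplotype x population matrix), `n_sites_used`.
#' @export
collapse_haplotypes <- function(sequences, populations) {
  mat <- as_char_matrix(sequences)
  if (is.null(rownames(mat))) stop("sequences must be named")
  miss <- setdiff(rownames(mat), names(populations))
  if (length(miss) > 0) {
    stop("sequence(s) missing from population map: ", paste(miss, collapse = ", "))
  }
  ok_col <- apply(mat, 2, function(col) all(col %in% c("a", "c", "g", "t")))
  mat <- mat[, ok_col, drop = FALSE]
  seq_str <- apply(mat, 1, paste, collapse = "")
  groups <- split(rownames(mat), seq_str)
  ord <- order(-lengths(groups),
               match(vapply(groups, `[`, character(1), 1), rownames(mat)))
  groups <- groups[ord]
  hap_ids <- sprintf("H%02d", seq_along(groups))
  names(groups) <- hap_ids
  seqs <- stats::setNames(vapply(groups, function(g) seq_str[[g[1]]], character(1)),
                          hap_ids)
  pops <- sort(unique(unname(populations[rownames(mat)])))
  counts <- matrix(0L, nrow = length(groups), ncol = length(pops),
                   dimnames = list(hap_ids, pops))
  for (i in seq_along(groups)) {
    tab <- table(factor(populations[groups[[i]]], levels = pops))
    counts[i, ] <- as.integer(tab)
  }
  structure(list(seqs = seqs, members = groups, counts = counts,
                 n_sites_used = ncol(mat)),
            class = "haplotype_table")
}

as_char_matrix <- function(sequences) {
  if (inherits(sequences, "DNAbin")) {
    mat <- as.character(as.matrix(sequences))
  } else if (is.matrix(sequences)) {
    mat <- sequences
  } else {
    lens <- nchar(sequences)
    if (length(unique(lens)) != 1) stop("sequences must have equal length")
    mat <- do.call(rbind, strsplit(unname(sequences), ""))
    rownames(mat) <- names(sequences)
  }
  if (is.matrix(mat) && length(unique(rowSums(!is.na(mat)))) != 1) {
    stop("sequences must have equal length")
  }
  tolower(mat)
}

#' Mutation count (Hamming distance) between two sequences
#'
#' @param h1,h2 Equal-length sequences (character strings or character
#'   vectors), typically post-deletion haplotype representatives.
#' @return Integer count of differing columns.
#' @export
mutation_distance <- function(h1, h2) {
  a <- if (length(h1) == 1) strsplit(tolower(h1), "")[[1]] else tolower(h1)
  b <- if (length(h2) == 1) strsplit(tolower(h2), "")[[1]] else tolower(h2)
  if (length(a) != length(b)) stop("sequences must have equal length")
  sum(a != b)
}

#' Pairwise mutation-count matrix of a haplotype table
#'
#' Computed with `ape::dist.dna(model = "N")` (raw count of differing sites).
#'
#' @param table A [collapse_haplotypes()] result.
#' @return Symmetric integer matrix of mutation counts.
#' @export
mutation_distances <- function(table) {
  stopifnot(inherits(table, "haplotype_table"))
  mat <- do.call(rbind, strsplit(unname(table$seqs), ""))
  rownames(mat) <- names(table$seqs)
  dna <- ape::as.DNAbin(mat)
  as.matrix(ape::dist.dna(dna, model = "N"))
}

#' Build a haplotype network (MST with alternative links)
#'
#' Deterministic Kruskal minimum spanning tree over the mutation-count
#' distance matrix, with ties broken by the lexicographic order of the node-id
#' pair. A non-tree edge `(u, v)` is recorded as an *alternative link* when
#' its weight equals the maximum edge weight on the tree path between `u` and
#' `v` (i.e. swapping it in would yield an equally parsimonious tree).
#'
#' @param table A [collapse_haplotypes()] result (or `NULL` when `distances`
#'   and `sizes` are given directly).
#' @param distances Optional distance matrix (default:
#'   [mutation_distances()] of `table`).
#' @param sizes Optional named haplotype sizes (default: member counts).
#' @return List of class `haplo_network`: `nodes` (`data.frame` with `id`,
#'   `size`, per-population counts when available) and `edges` (`data.frame`
#'   with `from`, `to`, `mutations`, `type` = `"tree"`/`"alternative"`).
#' @export
build_network <- function(table = NULL, distances = NULL, sizes = NULL) {
  if (is.null(distances)) {
    stopifnot(inherits(table, "haplotype_table"))
    distances <- mutation_distances(table)
  }
  distances <- as.matrix(distances)
  ids <- rownames(distances)
  if (is.null(ids)) ids <- colnames(distances) <- rownames(distances) <-
      sprintf("H%02d", seq_len(nrow(distances)))
  n <- length(ids)
  if (is.null(sizes)) {
    sizes <- if (!is.null(table)) lengths(table$members)[ids] else
      stats::setNames(rep(1L, n), ids)
  }

  nodes <- data.frame(id = ids, size = as.integer(sizes[ids]))
  if (!is.null(table)) {
    nodes <- cbind(nodes, as.data.frame(table$counts[ids, , drop = FALSE]))
  }
  if (n == 1) {
    return(structure(list(nodes = nodes,
                          edges = data.frame(from = character(0),
                                             to = character(0),
                                             mutations = numeric(0),
                                             type = character(0))),
                     class = "haplo_network"))
  }

  pairs <- which(upper.tri(distances), arr.ind = TRUE)
  edges <- data.frame(i = pairs[, 1], j = pairs[, 2],
                      w = distances[pairs])
  edges <- edges[order(edges$w, ids[edges$i], ids[edges$j]), ]

  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) x <- parent[x]
    x
  }
  tree <- logical(nrow(edges))
  for (e in seq_len(nrow(edges))) {
    ri <- find(edges$i[e]); rj <- find(edges$j[e])
    if (ri != rj) {
      parent[ri] <- rj
      tree[e] <- TRUE
    }
  }

  # adjacency of the tree for path-maximum queries
  adj <- vector("list", n)
  for (e in which(tree)) {
    adj[[edges$i[e]]] <- rbind(adj[[edges$i[e]]], c(edges$j[e], edges$w[e]))
    adj[[edges$j[e]]] <- rbind(adj[[edges$j[e]]], c(edges$i[e], edges$w[e]))
  }
  path_max <- function(u, v) {
    best <- rep(-Inf, n)
    best[u] <- 0
    queue <- u
    while (length(queue) > 0) {
      x <- queue[1]; queue <- queue[-1]
      if (x == v) break
      for (r in seq_len(NROW(adj[[x]]))) {
        y <- adj[[x]][r, 1]; w <- adj[[x]][r, 2]
        if (!is.finite(best[y])) {
          best[y] <- max(best[x], w)
          queue <- c(queue, y)
        }
      }
    }
    best[v]
  }
  alternative <- !tree &
    vapply(seq_len(nrow(edges)), function(e) {
      !tree[e] && edges$w[e] == path_max(edges$i[e], edges$j[e])
    }, logical(1))

  keep <- tree | alternative
  out_edges <- data.frame(
    from = ids[edges$i[keep]],
    to = ids[edges$j[keep]],
    mutations = edges$w[keep],
    type = ifelse(tree[keep], "tree", "alternative")
  )
  rownames(out_edges) <- NULL
  structure(list(nodes = nodes, edges = out_edges), class = "haplo_network")
}

#' @export
print.haplo_network <- function(x, ...) {
  cat(sprintf("haplo_network: %d haplotypes, %d tree edge(s), %d alternative link(s)\n",
              nrow(x$nodes), sum(x$edges$type == "tree"),
              sum(x$edges$type == "alternative")))
  invisible(x)
}

#' Convert a haplotype network to igraph
#' @param net A [build_network()] result.
#' @return An `igraph` graph with node attribute `size` and edge attributes
#'   `mutations`, `type`.
#' @export
haplonet_igraph <- function(net) {
  igraph::graph_from_data_frame(net$edges, directed = FALSE,
                                vertices = net$nodes)
}

#' Write a haplotype network to GraphML or DOT
#' @param net A [build_network()] result.
#' @param path Output path.
#' @param format `"graphml"` or `"dot"`.
#' @return Invisibly, `path`.
#' @export
write_haplonet <- function(net, path, format = c("graphml", "dot")) {
  format <- match.arg(format)
  igraph::write_graph(haplonet_igraph(net), path, format = format)
  invisible(path)
}
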