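#' Variant-character matrix for haplotype analysis
#'
#' One row per sample, one column per variant: SNP columns carry the base,
#' InDel columns carry `+`/`-` (block present/absent).
#'
#' @param variants a `variant_table`.
#' @return character matrix (samples x variants).
#' @export
haplotype_matrix <- function(variants) {
  t(variant_genotypes(variants))
}

#' Collapse samples into haplotypes
#'
#' Samples with identical characters at every variant position (SNP alleles
#' plus InDel presence/absence) share a haplotype. Haplotypes are labelled by
#' their first member in input order.
#'
#' @param x character matrix (samples x characters) — an alignment, a
#'   genotype matrix, or [haplotype_matrix()] output.
#' @return data.frame of class `haplotype_assignment` (`sample`,
#'   `haplotype`); attribute `classes` lists members per haplotype.
#' @export
collapse_haplotypes <- function(x) {
  stopifnot(is.matrix(x))
  key <- apply(x, 1L, paste, collapse = "")
  first <- !duplicated(key)
  labels <- stats::setNames(rownames(x)[first], key[first])
  out <- data.frame(sample = rownames(x), haplotype = unname(labels[key]),
                    stringsAsFactors = FALSE)
  attr(out, "classes") <- split(out$sample, out$haplotype)[unique(out$haplotype)]
  class(out) <- c("haplotype_assignment", "data.frame")
  out
}

# Maximal gap blocks of one gapped sequence as "start-end" interval keys.
gap_blocks <- function(x) {
  r <- rle(x == "-")
  if (!any(r$values)) return(character(0))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  paste0(starts[r$values], "-", ends[r$values])
}

#' Indel-block distance between two gapped sequences
#'
#' The number of positions where both sequences have bases and the bases
#' differ (ambiguity codes and `N` are skipped), plus the number of maximal
#' gap blocks present in exactly one of the two sequences. A gap block shared
#' with identical extent contributes 0; any block contributes 1 regardless of
#' its length (simple indel coding).
#'
#' @param a,b character vectors (or single strings) of equal length.
#' @return non-negative integer distance.
#' @export
indelblock_distance <- function(a, b) {
  if (length(a) == 1L) a <- strsplit(a, "")[[1]]
  if (length(b) == 1L) b <- strsplit(b, "")[[1]]
  if (length(a) != length(b)) stop("sequences have unequal lengths")
  both <- a %in% .BASES & b %in% .BASES
  subs <- sum(a[both] != b[both])
  ba <- gap_blocks(a); bb <- gap_blocks(b)
  blocks <- length(setdiff(ba, bb)) + length(setdiff(bb, ba))
  as.integer(subs + blocks)
}

#' Pairwise indel-block distance matrix
#'
#' @param alignment character matrix (samples x columns).
#' @return symmetric matrix of class `dist`-compatible plain matrix.
#' @export
indelblock_dist_matrix <- function(alignment) {
  n <- nrow(alignment)
  d <- matrix(0, n, n, dimnames = list(rownames(alignment), rownames(alignment)))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    d[i, j] <- d[j, i] <- indelblock_distance(alignment[i, ], alignment[j, ])
  }
  d
}

.check_dmat <- function(dmat) {
  stopifnot(is.matrix(dmat), nrow(dmat) == ncol(dmat))
  if (any(dmat < 0) || any(abs(diag(dmat)) > 1e-12) ||
      any(abs(dmat - t(dmat)) > 1e-9))
    stop("invalid distance matrix")
  if (is.null(rownames(dmat)))
    rownames(dmat) <- colnames(dmat) <- paste0("H", seq_len(nrow(dmat)))
  dmat
}

#' Randomized minimum-spanning-tree haplotype network
#'
#' Repeats Kruskal's algorithm `iterations` times with the edge order randomly
#' permuted before the stable sort by weight, so ties among equal-weight edges
#' are broken at random. The network is the union of all spanning trees
#' obtained; each edge's `support` is its inclusion fraction and edges with
#' support < 1 are flagged `alternative` (the dashed "alternative pathways" of
#' a haplotype genealogy).
#'
#' @param dmat symmetric distance matrix over haplotypes.
#' @param iterations number of randomized Kruskal runs.
#' @param seed integer seed.
#' @param haplotypes optional `haplotype_assignment` supplying node members.
#' @param popmap optional sample -> population map for node composition.
#' @return object of class `haplotype_network`: list with `nodes` and `edges`
#'   data.frames and `mst_weight`.
#' @export
rmst_network <- function(dmat, iterations = 200L, seed = 1L,
                         haplotypes = NULL, popmap = NULL) {
  dmat <- .check_dmat(dmat)
  n <- nrow(dmat)
  labels <- rownames(dmat)
  if (n == 1L) {
    edges <- data.frame(from = character(), to = character(),
                        weight = numeric(), support = numeric(),
                        alternative = logical(), stringsAsFactors = FALSE)
    return(.make_network(labels, edges, 0, haplotypes, popmap))
  }
  idx <- which(upper.tri(dmat), arr.ind = TRUE)
  ei <- idx[, 1]; ej <- idx[, 2]; w <- dmat[idx]
  m <- length(w)
  hits <- numeric(m)
  mst_weight <- NA_real_
  with_seed(seed, {
    for (it in seq_len(iterations)) {
      perm <- sample.int(m)
      ord <- perm[order(w[perm])]  # stable sort: random tie-breaking
      parent <- seq_len(n)
      find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
      taken <- 0L; wsum <- 0
      for (k in ord) {
        ri <- find(ei[k]); rj <- find(ej[k])
        if (ri != rj) {
          parent[ri] <- rj
          hits[k] <- hits[k] + 1
          wsum <- wsum + w[k]
          taken <- taken + 1L
          if (taken == n - 1L) break
        }
      }
      mst_weight <- wsum
    }
  })
  keep <- hits > 0
  edges <- data.frame(from = labels[ei[keep]], to = labels[ej[keep]],
                      weight = w[keep], support = hits[keep] / iterations,
                      alternative = hits[keep] < iterations,
                      stringsAsFactors = FALSE)
  edges <- edges[order(-edges$support, edges$from, edges$to), ]
  rownames(edges) <- NULL
  .make_network(labels, edges, mst_weight, haplotypes, popmap)
}

.make_network <- function(labels, edges, mst_weight, haplotypes, popmap) {
  nodes <- data.frame(haplotype = labels, size = 1L,
                      members = labels, populations = NA_character_,
                      stringsAsFactors = FALSE)
  if (!is.null(haplotypes)) {
    classes <- attr(haplotypes, "classes")
    idx <- match(nodes$haplotype, names(classes))
    nodes$size <- lengths(classes)[idx]
    nodes$members <- vapply(classes[idx], paste, character(1), collapse = ",")
    if (!is.null(popmap)) {
      nodes$populations <- vapply(classes[idx], function(s) {
        tab <- table(popmap[s])
        paste(sprintf("%s:%d", names(tab), tab), collapse = ",")
      }, character(1))
    }
  }
  structure(list(nodes = nodes, edges = edges, mst_weight = mst_weight),
            class = "haplotype_network")
}

#' @export
print.haplotype_network <- function(x, ...) {
  cat(sprintf("<haplotype_network> %d nodes, %d edges (%d alternative), MST weight %g\n",
              nrow(x$nodes), nrow(x$edges), sum(x$edges$alternative),
              x$mst_weight))
  invisible(x)
}

#' Convert a haplotype network to an igraph object
#' @param network a `haplotype_network`.
#' @return an igraph graph with edge attributes `weight`, `support`,
#'   `alternative`.
#' @export
network_igraph <- function(network) {
  igraph::graph_from_data_frame(network$edges, directed = FALSE,
                                vertices = network$nodes)
}

#' Exhaustive minimum-spanning-tree union (test oracle)
#'
#' Enumerates every labelled spanning tree of the complete graph (via Pruefer
#' sequences) and returns the union of all minimum-weight ones. Exponential in
#' the node count; refused above 8 nodes.
#'
#' @param dmat symmetric distance matrix (<= 8 nodes).
#' @return list with `edges` (data.frame `from`, `to`, `weight`) and
#'   `mst_weight`.
#' @export
mst_union_oracle <- function(dmat) {
  dmat <- .check_dmat(dmat)
  n <- nrow(dmat)
  if (n > 8L) stop("refused: oracle enumerates all spanning trees, max 8 nodes")
  labels <- rownames(dmat)
  if (n == 1L)
    return(list(edges = data.frame(from = character(), to = character(),
                                   weight = numeric()), mst_weight = 0))
  res <- cpp_mst_union(dmat)
  adj <- res$union
  idx <- which(upper.tri(adj) & adj, arr.ind = TRUE)
  edges <- data.frame(from = labels[idx[, 1]], to = labels[idx[, 2]],
                      weight = dmat[idx], stringsAsFactors = FALSE)
  edges <- edges[order(edges$from, edges$to), ]
  rownames(edges) <- NULL
  list(edges = edges, mst_weight = res$weight)
}

# canonical "a|b" edge keys for set comparison in tests
edge_keys <- function(edges) {
  sort(paste(pmin(edges$from, edges$to), pmax(edges$from, edges$to), sep = "|"))
}
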