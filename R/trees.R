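#' Minimum-spanning haplotype network
#'
#' Builds a minimum-spanning tree (Kruskal) over the haplotype
#' Hamming-distance graph; edge weights are mutation counts. Equal-weight
#' ties are broken deterministically by the smaller haplotype index pair.
#' With `epsilon_ties = TRUE` every edge that joins two still-separate
#' components at the current weight level is retained, which can produce
#' reticulations (a network rather than a strict tree) exactly where
#' alternative equally short connections exist.
#'
#' @param haps a `haplotype_table`.
#' @param epsilon_ties keep all co-minimal edges at each weight level.
#' @return An object of class `haplotype_network`: list with `nodes`
#'   (data.frame: hap_id, total, per-group counts) and `edges`
#'   (data.frame: hap_a, hap_b, n_mutations).
#' @export
min_spanning_network <- function(haps, epsilon_ties = FALSE) {
  stopifnot(inherits(haps, "haplotype_table"))
  k <- length(haps$hap_id)
  d <- pairwise_difference_matrix(haps)
  edges <- data.frame(hap_a = character(), hap_b = character(),
                      n_mutations = integer())
  if (k >= 2) {
    idx <- which(upper.tri(d), arr.ind = TRUE)
    cand <- data.frame(i = idx[, 1L], j = idx[, 2L], w = d[idx])
    cand <- cand[order(cand$w, cand$i, cand$j), ]
    comp <- seq_len(k)                       # union-find by relabelling
    keep <- logical(nrow(cand))
    for (lvl in unique(cand$w)) {
      rows <- which(cand$w == lvl)
      comp_at_level <- comp
      for (r in rows) {
        a <- comp_at_level[cand$i[r]]; b <- comp_at_level[cand$j[r]]
        ab <- comp[cand$i[r]]; bb <- comp[cand$j[r]]
        joins_now <- ab != bb
        joined_at_level <- a != b
        if (if (epsilon_ties) joined_at_level else joins_now) {
          keep[r] <- TRUE
          if (joins_now) comp[comp == bb] <- ab
        }
      }
    }
    kept <- cand[keep, ]
    edges <- data.frame(hap_a = haps$hap_id[kept$i],
                        hap_b = haps$hap_id[kept$j],
                        n_mutations = as.integer(kept$w),
                        row.names = NULL)
  }
  nodes <- as.data.frame(haps)
  structure(list(nodes = nodes, edges = edges,
                 epsilon_ties = epsilon_ties),
            class = "haplotype_network")
}

#' @export
print.haplotype_network <- function(x, ...) {
  cat("Haplotype network: ", nrow(x$nodes), " nodes, ", nrow(x$edges),
      " edges", if (x$epsilon_ties) " (epsilon ties retained)", "\n",
      sep = "")
  print(x$edges)
  invisible(x)
}

# two-taxon phylo (ape::nj needs >= 3 tips)
two_taxon_tree <- function(labels, dist) {
  structure(list(edge = matrix(c(3L, 1L, 3L, 2L), 2L, byrow = TRUE),
                 edge.length = rep(dist / 2, 2L),
                 tip.label = labels, Nnode = 1L),
            class = "phylo", order = "cladewise")
}

#' Neighbor-joining tree
#'
#' Saitou-Nei neighbor joining on a symmetric distance matrix (via
#' [ape::nj()]). Negative branch lengths, which NJ can produce on
#' non-additive matrices, are clamped to zero with the deficit moved to
#' the adjacent (sister) branch so that path lengths through the parent
#' node are preserved.
#'
#' @param d symmetric numeric distance matrix with dimnames.
#' @return An [ape::read.tree()]-compatible `phylo` object.
#' @export
nj_tree <- function(d) {
  stopifnot(is.matrix(d), nrow(d) >= 2)
  if (nrow(d) == 2) return(two_taxon_tree(rownames(d), d[1L, 2L]))
  tr <- ape::nj(stats::as.dist(d))
  clamp_negative_branches(tr)
}

clamp_negative_branches <- function(tr) {
  for (iter in seq_len(2L * length(tr$edge.length))) {
    neg <- which(tr$edge.length < 0)
    if (!length(neg)) break
    e <- neg[1L]
    parent <- tr$edge[e, 1L]
    sib <- setdiff(which(tr$edge[, 1L] == parent), e)
    deficit <- tr$edge.length[e]
    tr$edge.length[e] <- 0
    if (length(sib)) tr$edge.length[sib[1L]] <-
        tr$edge.length[sib[1L]] + deficit
  }
  # any residual negatives (pathological sibling ping-pong) are floored
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

#' UPGMA (average-linkage) tree
#'
#' Average-linkage agglomerative clustering of a distance matrix,
#' returned as an ultrametric `phylo` tree. Cophenetic distances between
#' leaves equal the merge heights of [stats::hclust()]. Merge ties are
#' resolved by `hclust`'s deterministic ordering.
#'
#' @inheritParams nj_tree
#' @return Rooted ultrametric `phylo` object.
#' @export
upgma_tree <- function(d) {
  stopifnot(is.matrix(d), nrow(d) >= 2)
  if (nrow(d) == 2) return(two_taxon_tree(rownames(d), d[1L, 2L]))
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  ape::as.phylo(hc)
}

#' Bootstrap support for an NJ haplotype tree
#'
#' Resamples alignment sites with replacement `B` times, rebuilds the NJ
#' tree from each replicate's pairwise-difference matrix, and reports for
#' every internal node the percentage of replicates containing the same
#' bipartition. Values are stored unmasked in `node.label`; rendering
#' conventions (e.g. showing only supports above 50) are left to output
#' formatting.
#'
#' @param haps a `haplotype_table` (one sequence per haplotype).
#' @param tree the reference `phylo` tree to annotate (default: NJ tree of
#'   the haplotype distances).
#' @param B bootstrap replicates (default 1000).
#' @param seed integer seed.
#' @return `tree` with `node.label` set to integer percentage supports
#'   (NA on the root).
#' @export
bootstrap_support <- function(haps, tree = NULL, B = 1000, seed = 1) {
  stopifnot(inherits(haps, "haplotype_table"), B >= 1)
  m <- aln_matrix(hap_alignment(haps))
  keep <- included_sites(m)
  m <- m[, keep, drop = FALSE]
  if (is.null(tree)) tree <- nj_tree(hamming_from_chars(m))
  if (nrow(m) < 3) { tree$node.label <- rep(NA, tree$Nnode); return(tree) }
  boots <- with_local_seed(seed, {
    lapply(seq_len(B), function(b) {
      cols <- sample.int(ncol(m), ncol(m), replace = TRUE)
      nj_tree(hamming_from_chars(m[, cols, drop = FALSE]))
    })
  })
  counts <- ape::prop.clades(tree, boots, rooted = FALSE)
  counts[is.na(counts)] <- 0L
  tree$node.label <- as.integer(round(100 * counts / B))
  tree
}

hamming_from_chars <- function(m) {
  k <- nrow(m)
  d <- matrix(0L, k, k, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(k - 1L)) for (j in seq.int(i + 1L, k))
    d[i, j] <- d[j, i] <- sum(m[i, ] != m[j, ])
  d
}

#' PCA of the haplotype SNP matrix
#'
#' Encodes every polymorphic site of the haplotype sequences as one 0/1
#' indicator column per non-major allele, column-centres the matrix, and
#' eigendecomposes its covariance (via [stats::prcomp()]). One row per
#' haplotype, unweighted. Axis signs are fixed by forcing the
#' largest-magnitude loading of each component positive, so score plots
#' are reproducible.
#'
#' @param haps a `haplotype_table` with at least 2 haplotypes and at least
#'   one polymorphic site.
#' @return An object of class `haplotype_pca`: list with `scores`
#'   (haplotype x component), `explained_variance_ratio`, and `sdev`.
#' @export
haplotype_pca <- function(haps) {
  stopifnot(inherits(haps, "haplotype_table"))
  m <- aln_matrix(hap_alignment(haps))
  if (nrow(m) < 2)
    stop("PCA needs at least two haplotypes", call. = FALSE)
  m <- m[, included_sites(m), drop = FALSE]
  cols <- list()
  for (j in seq_len(ncol(m))) {
    tab <- sort(table(m[, j]), decreasing = TRUE)
    if (length(tab) < 2L) next
    for (allele in names(tab)[-1L])
      cols[[paste0("s", j, allele)]] <- as.numeric(m[, j] == allele)
  }
  if (!length(cols))
    stop("degenerate input: no polymorphic sites among haplotypes",
         call. = FALSE)
  X <- do.call(cbind, cols)
  rownames(X) <- rownames(m)
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  # sign convention: largest |loading| positive per component
  for (k in seq_len(ncol(pc$rotation))) {
    i <- which.max(abs(pc$rotation[, k]))
    if (pc$rotation[i, k] < 0) {
      pc$rotation[, k] <- -pc$rotation[, k]
      pc$x[, k] <- -pc$x[, k]
    }
  }
  ev <- pc$sdev^2
  structure(list(scores = pc$x,
                 explained_variance_ratio = ev / sum(ev),
                 sdev = pc$sdev),
            class = "haplotype_pca")
}

#' @export
print.haplotype_pca <- function(x, ...) {
  cat("Haplotype PCA: ", nrow(x$scores), " haplotypes\n", sep = "")
  evr <- round(100 * x$explained_variance_ratio, 1)
  cat("explained variance (%):", paste(evr, collapse = ", "), "\n")
  invisible(x)
}
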