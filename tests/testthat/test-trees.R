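hap_table_from <- function(...) collapse_haplotypes(aln_from(...))

test_that("minimum spanning network handles degenerate and chain cases", {
  single <- hap_table_from(a = "ACGT", b = "ACGT")
  net1 <- min_spanning_network(single)
  expect_equal(nrow(net1$edges), 0L)

  # A-B one step, B-C one step, A-C two steps: Kruskal keeps the chain
  chain <- hap_table_from(a = "AAAA", b = "AAAG", c = "AAGG")
  net <- min_spanning_network(chain)
  expect_equal(nrow(net$edges), 2L)
  expect_true(all(net$edges$n_mutations == 1L))
  expect_false(any(net$edges$hap_a == net$edges$hap_b))
})

test_that("star-graph haplotypes attach through their intermediates", {
  haps <- collapse_haplotypes(as_alignment(
    build_haplotypes(sim_config(seed = 19))))
  net <- min_spanning_network(haps)
  # the network is a tree over 11 nodes
  expect_equal(nrow(net$edges), 10L)
  key <- function(a, b) paste(sort(c(a, b)), collapse = "-")
  edges <- mapply(key, net$edges$hap_a, net$edges$hap_b)
  # ids are reassigned by frequency on collapse of the unit-count table,
  # so recover the original labels through the sequences
  orig <- build_haplotypes(sim_config(seed = 19))
  lab <- names(orig)[match(haps$sequence, orig)]
  relabel <- stats::setNames(lab, haps$hap_id)
  edges_orig <- mapply(function(a, b) key(relabel[[a]], relabel[[b]]),
                       net$edges$hap_a, net$edges$hap_b)
  expect_true(key("Hap7", "Hap8") %in% edges_orig)
  expect_true(key("Hap8", "Hap1") %in% edges_orig)
  expect_false(key("Hap7", "Hap1") %in% edges_orig)
})

test_that("MST weight matches exhaustive spanning-tree enumeration", {
  set.seed(53)
  for (rep in 1:12) {
    k <- sample(3:6, 1)
    aln <- random_alignment(n = k, L = 25, n_hap = k)
    haps <- collapse_haplotypes(aln)
    k_eff <- length(haps$hap_id)
    net <- min_spanning_network(haps)
    d <- pairwise_difference_matrix(haps)
    expect_equal(sum(net$edges$n_mutations), brute_mst_weight(d))
    expect_equal(nrow(net$edges), k_eff - 1L)
  }
})

test_that("epsilon ties retain co-minimal alternative connections", {
  # B and C both one step from A and two steps from each other;
  # D two steps from B and from C: both D attachments are co-minimal
  ht <- hap_table_from(a = "AAAA", b = "AAAG", c = "AAGA", d = "AAGG")
  strict <- min_spanning_network(ht)
  loose <- min_spanning_network(ht, epsilon_ties = TRUE)
  expect_equal(nrow(strict$edges), 3L)
  expect_gt(nrow(loose$edges), nrow(strict$edges))
})

test_that("NJ recovers additive distances exactly", {
  d2 <- matrix(c(0, 4, 4, 0), 2, dimnames = list(c("a", "b"),
                                                 c("a", "b")))
  tr2 <- nj_tree(d2)
  expect_equal(sort(tr2$tip.label), c("a", "b"))
  expect_equal(tr2$edge.length, c(2, 2))

  set.seed(59)
  for (rep in 1:15) {
    n <- sample(4:8, 1)
    tr <- ape::rtree(n)
    d <- ape::cophenetic.phylo(tr)
    rec <- nj_tree(d)
    expect_equal(ape::cophenetic.phylo(rec)[rownames(d), colnames(d)],
                 d, tolerance = 1e-8)
  }
})

test_that("NJ on a star matrix has a zero-length internal branch", {
  d <- matrix(2, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  diag(d) <- 0
  tr <- nj_tree(d)
  internal <- tr$edge[, 2L] > length(tr$tip.label)
  expect_true(any(abs(tr$edge.length[internal]) < 1e-12))
  expect_true(all(tr$edge.length >= 0))
})

test_that("UPGMA produces the expected ultrametric dendrogram", {
  d <- matrix(c(0, 1, 4,
                1, 0, 4,
                4, 4, 0), 3, byrow = TRUE,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- upgma_tree(d)
  co <- ape::cophenetic.phylo(tr)
  expect_equal(co["A", "B"], 1)
  expect_equal(co["A", "C"], 4)
  expect_equal(co["B", "C"], 4)

  set.seed(61)
  for (rep in 1:8) {
    gen <- ape::rcoal(sample(4:7, 1))
    d0 <- ape::cophenetic.phylo(gen)
    rec <- upgma_tree(d0)
    expect_equal(ape::cophenetic.phylo(rec)[rownames(d0), colnames(d0)],
                 d0, tolerance = 1e-8)
    # ultrametric: two largest distances of every leaf triple are equal
    co <- ape::cophenetic.phylo(rec)
    trio <- utils::combn(rownames(co), 3)
    for (t in seq_len(ncol(trio))) {
      dd <- sort(c(co[trio[1, t], trio[2, t]], co[trio[1, t], trio[3, t]],
                   co[trio[2, t], trio[3, t]]))
      expect_equal(dd[2], dd[3], tolerance = 1e-8)
    }
  }
})

test_that("UPGMA on the four-group FST matrix pairs the two river duos", {
  fst <- matrix(c(0, 0.00376, 0.11987, 0.17764,
                  0.00376, 0, 0.05632, 0.11845,
                  0.11987, 0.05632, 0, 0.05701,
                  0.17764, 0.11845, 0.05701, 0), 4, byrow = TRUE)
  grp <- c("Padma", "Jamuna", "Halda", "Culture")
  dimnames(fst) <- list(grp, grp)
  tr <- upgma_tree(fst)
  expect_true(ape::is.monophyletic(tr, c("Padma", "Jamuna")))
  expect_true(ape::is.monophyletic(tr, c("Halda", "Culture")))
  co <- ape::cophenetic.phylo(tr)
  expect_equal(co["Padma", "Jamuna"], 0.00376)
  expect_equal(co["Halda", "Culture"], 0.05701)
})

test_that("bootstrap supports are deterministic and saturate on deep splits", {
  # two clades separated by many fixed differences
  left <- paste(rep("A", 40), collapse = "")
  right <- paste(c(rep("A", 20), rep("T", 20)), collapse = "")
  near <- function(s, i, to) { substr(s, i, i) <- to; s }
  aln <- aln_from(l1 = left, l2 = near(left, 1, "C"),
                  r1 = right, r2 = near(right, 1, "G"))
  haps <- collapse_haplotypes(aln)
  tr <- bootstrap_support(haps, B = 100, seed = 21)
  tr_again <- bootstrap_support(haps, B = 100, seed = 21)
  expect_identical(tr$node.label, tr_again$node.label)
  expect_true(all(tr$node.label >= 0 & tr$node.label <= 100))
  # the split between the two clades is recovered essentially always
  expect_gte(max(tr$node.label), 95)
})

test_that("haplotype PCA explains variance as expected", {
  # two haplotypes one substitution apart: a single axis carries all
  # variance
  pair <- hap_table_from(a = "AAAA", b = "AAAT")
  pc <- haplotype_pca(pair)
  expect_equal(pc$explained_variance_ratio[1], 1)

  haps <- collapse_haplotypes(as_alignment(
    build_haplotypes(sim_config(seed = 23))))
  pc <- haplotype_pca(haps)
  expect_equal(sum(pc$explained_variance_ratio), 1, tolerance = 1e-9)
  expect_true(all(diff(pc$sdev) <= 1e-9))
  # independent oracle: eigendecomposition of the covariance of the
  # minor-allele indicator matrix built directly from the sequences
  m <- char_mat(as_alignment(haps$sequence))
  X <- NULL
  for (j in seq_len(ncol(m))) {
    tab <- sort(table(m[, j]), decreasing = TRUE)
    if (length(tab) >= 2)
      for (al in names(tab)[-1]) X <- cbind(X, as.numeric(m[, j] == al))
  }
  ev <- eigen(stats::cov(X), symmetric = TRUE, only.values = TRUE)$values
  expect_equal(pc$explained_variance_ratio[1:3], (ev / sum(ev))[1:3],
               tolerance = 1e-9)

  # site order only affects scores up to sign-fixed equality (chain of
  # haplotypes with distinct eigenvalues)
  chain <- hap_table_from(a = "AAAAAA", b = "AAAAAT", c = "AAAATT",
                          d = "ATTTTT")
  pc_a <- haplotype_pca(chain)
  m <- char_mat(as_alignment(chain$sequence))
  set.seed(67)
  perm <- sample(ncol(m))
  shuffled <- as_alignment(apply(m[, perm], 1, paste, collapse = ""))
  pc_b <- haplotype_pca(collapse_haplotypes(shuffled))
  expect_equal(abs(pc_b$scores[rownames(pc_a$scores), 1:2]),
               abs(pc_a$scores[, 1:2]), tolerance = 1e-8)

  mono <- hap_table_from(a = "AAAA", b = "AAAA")
  expect_error(haplotype_pca(mono), "polymorphic|at least two")
})
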