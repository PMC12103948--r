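test_that("haplotype collapsing counts and orders by frequency", {
  aln <- aln_from(a = "ACGT", b = "ACGT", c = "ACGT", d = "AGGT")
  haps <- collapse_haplotypes(aln)
  expect_equal(length(haps$hap_id), 2L)
  expect_equal(unname(haps$total), c(3L, 1L))
  expect_identical(unname(haps$sequence[["Hap1"]]), "ACGT")
  expect_identical(unname(haps$membership[["d"]]), "Hap2")

  same <- aln_from(x = "AAAA", y = "AAAA", z = "AAAA")
  expect_equal(unname(collapse_haplotypes(same)$total), 3L)
})

test_that("collapsing conserves the sequence multiset and group sums", {
  set.seed(42)
  for (rep in 1:5) {
    aln <- random_alignment(n = 12, L = 30, n_hap = 4)
    pops <- stats::setNames(sample(c("g1", "g2"), 12, replace = TRUE),
                            aln$ids)
    haps <- collapse_haplotypes(aln, pops)
    expanded <- rep(unname(haps$sequence), haps$total)
    expect_equal(sort(expanded), sort(unname(aln$seq)))
    expect_equal(rowSums(haps$counts), haps$total)
    expect_equal(sum(haps$total), 12L)
  }
})

test_that("site classification follows column base multisets", {
  # one A/G singleton column, one A/A/G/G parsimony column
  aln <- aln_from(a = "AA", b = "AA", c = "AG", d = "GG")
  sc <- classify_sites(aln)
  expect_equal(unname(sc$counts[c("singleton", "parsimony")]), c(1L, 1L))
  expect_equal(as.character(sc$labels), c("singleton", "parsimony"))

  mono <- classify_sites(aln_from(a = "ACGT", b = "ACGT"))
  expect_equal(unname(mono$counts["monomorphic"]), 4L)
  expect_equal(unname(mono$counts["polymorphic"]), 0L)

  # column {A,A,G,G,T}: two bases with >= 2 copies -> parsimony
  mixed <- classify_sites(aln_from(a = "A", b = "A", c = "G", d = "G",
                                   e = "T"))
  expect_equal(as.character(mixed$labels), "parsimony")
})

test_that("columns containing N or gaps are excluded but accounted for", {
  aln <- aln_from(a = "ANG-T", b = "AAGCT", c = "AAGCG")
  sc <- classify_sites(aln)
  expect_equal(unname(sc$counts["excluded"]), 2L)
  expect_equal(unname(sc$counts["monomorphic"] + sc$counts["polymorphic"] +
                        sc$counts["excluded"]), aln$L)
  expect_equal(unname(sc$counts["singleton"] + sc$counts["parsimony"]),
               unname(sc$counts["polymorphic"]))
})

test_that("weighted haplotype classification equals raw-alignment classification", {
  set.seed(7)
  for (rep in 1:8) {
    aln <- random_alignment(n = 15, L = 40, n_hap = 5)
    haps <- collapse_haplotypes(aln)
    raw <- classify_sites(aln)
    weighted <- classify_sites(as_alignment(haps$sequence),
                               weights = unname(haps$total))
    expect_identical(weighted$counts, raw$counts)
  }
})

test_that("per-group classification treats each subset independently", {
  aln <- aln_from(a = "ACGT", b = "ACGT", c = "ACGA", d = "TCGA")
  pops <- stats::setNames(c("g1", "g1", "g2", "g2"), aln$ids)
  by_grp <- classify_sites_by_group(aln, pops)
  expect_equal(unname(by_grp$g1$counts["polymorphic"]), 0L)
  expect_equal(unname(by_grp$g2$counts[c("polymorphic", "singleton")]),
               c(1L, 1L))
  expect_named(by_grp, c("g1", "g2", "All"))

  # single-sequence group: every site monomorphic by convention
  solo <- classify_sites_by_group(aln, stats::setNames(
    c("g1", "g1", "g1", "g2"), aln$ids))
  expect_equal(unname(solo$g2$counts["monomorphic"]), 4L)
})

test_that("a Halda-like group shows only parsimony-informative variation", {
  # hub, a 2-step neighbour (5 copies) and a shared 1-step haplotype
  # (4 copies): 3 variable columns, each with both bases duplicated
  cfg <- sim_config(seed = 3)
  sim <- generate_alignment(cfg)
  halda <- names(sim$popmap)[sim$popmap == "Halda"]
  sc <- classify_sites(as_alignment(sim$alignment$seq[halda]))
  expect_equal(unname(sc$counts["parsimony"]), 3L)
  expect_equal(unname(sc$counts["singleton"]), 0L)
})

test_that("default synthetic design collapses to 11 haplotypes with a 107-copy hub", {
  sim <- generate_alignment(sim_config(seed = 9))
  haps <- collapse_haplotypes(sim$alignment, sim$popmap)
  expect_equal(length(haps$hap_id), 11L)
  expect_equal(unname(haps$total[["Hap1"]]), 107L)
  sc <- classify_sites(sim$alignment)
  expect_equal(unname(sc$counts["monomorphic"] + sc$counts["polymorphic"]),
               616L)
})
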