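# Independent brute-force oracles. These deliberately re-derive each
# quantity from its definition by explicit enumeration, not by calling the
# package's computational path.

# random alignment drawn from a small pool of random haplotypes, so that
# sites show realistic shared variation
random_alignment <- function(n, L, n_hap = max(2L, n %/% 2L),
                             alphabet = c("A", "C", "G", "T")) {
  haps <- replicate(n_hap,
                    paste(sample(alphabet, L, replace = TRUE),
                          collapse = ""))
  seqs <- sample(haps, n, replace = TRUE)
  as_alignment(stats::setNames(seqs, sprintf("s%02d", seq_len(n))))
}

char_mat <- function(aln) {
  m <- do.call(rbind, strsplit(aln$seq, "", fixed = TRUE))
  rownames(m) <- aln$ids
  m
}

# mean pairwise difference per analysable site, by explicit double loop
brute_pi <- function(aln) {
  m <- char_mat(aln)
  keep <- !apply(m == "N" | m == "-", 2L, any)
  m <- m[, keep, drop = FALSE]
  n <- nrow(m)
  tot <- 0
  for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n))
    tot <- tot + sum(m[i, ] != m[j, ])
  tot / (n * (n - 1) / 2) / ncol(m)
}

# Excoffier-style one-level AMOVA, written as literal sums over pairs
brute_amova <- function(d, g) {
  n <- length(g)
  labs <- unique(g)
  G <- length(labs)
  sst <- 0
  for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n))
    sst <- sst + d[i, j]^2
  sst <- sst / n
  ssw <- 0
  for (lab in labs) {
    idx <- which(g == lab)
    s <- 0
    if (length(idx) >= 2)
      for (a in seq_len(length(idx) - 1L))
        for (b in seq.int(a + 1L, length(idx)))
          s <- s + d[idx[a], idx[b]]^2
    ssw <- ssw + s / length(idx)
  }
  ssa <- sst - ssw
  ms_a <- ssa / (G - 1)
  ms_w <- ssw / (n - G)
  ng <- as.numeric(table(g))
  n_prime <- (n - sum(ng^2) / n) / (G - 1)
  va <- (ms_a - ms_w) / n_prime
  vb <- ms_w
  list(ss_total = sst, ss_within = ssw, ss_among = ssa,
       Va = va, Vb = vb,
       fst = if (va + vb > 0) va / (va + vb) else NaN)
}

# minimum spanning-tree weight by exhaustive enumeration of edge subsets
brute_mst_weight <- function(d) {
  k <- nrow(d)
  if (k == 1L) return(0)
  idx <- which(upper.tri(d), arr.ind = TRUE)
  best <- Inf
  for (cmb in utils::combn(nrow(idx), k - 1L, simplify = FALSE)) {
    comp <- seq_len(k)
    for (r in cmb) {
      a <- comp[idx[r, 1L]]; b <- comp[idx[r, 2L]]
      if (a != b) comp[comp == b] <- a
    }
    if (length(unique(comp)) == 1L)
      best <- min(best, sum(d[idx[cmb, , drop = FALSE]]))
  }
  best
}

# small alignment built directly from explicit sequences
aln_from <- function(...) {
  seqs <- c(...)
  if (is.null(names(seqs)))
    names(seqs) <- sprintf("s%d", seq_along(seqs))
  as_alignment(seqs)
}
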