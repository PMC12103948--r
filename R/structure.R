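#' Pairwise difference matrix
#'
#' Symmetric matrix of raw nucleotide differences (Hamming counts over the
#' complete-deletion site set) between all sequences of an alignment, or
#' between the haplotypes of a haplotype table. These unsquared counts are
#' the p-distance numerators; AMOVA squares them internally.
#'
#' @param x an `hd_alignment` or `haplotype_table`.
#' @return Integer matrix with zero diagonal and dimnames set to sample
#'   (or haplotype) ids.
#' @export
pairwise_difference_matrix <- function(x) {
  if (inherits(x, "haplotype_table")) {
    m <- aln_matrix(hap_alignment(x))
    return(hamming_matrix(m))
  }
  stopifnot(inherits(x, "hd_alignment"))
  # collapse to unique strings, compute once, expand to individuals
  uniq <- unique(unname(x$seq))
  idx <- match(x$seq, uniq)
  mu <- do.call(rbind, strsplit(uniq, "", fixed = TRUE))
  dh <- hamming_matrix(mu)
  d <- dh[idx, idx, drop = FALSE]
  diag(d) <- 0L
  dimnames(d) <- list(x$ids, x$ids)
  d
}

hamming_matrix <- function(m) {
  keep <- included_sites(m)
  m <- m[, keep, drop = FALSE]
  k <- nrow(m)
  d <- matrix(0L, k, k, dimnames = list(rownames(m), rownames(m)))
  if (k >= 2)
    for (i in seq_len(k - 1L))
      for (j in seq.int(i + 1L, k))
        d[i, j] <- d[j, i] <- sum(m[i, ] != m[j, ])
  d
}

# sums of squared distances for AMOVA; g is an integer/ factor group vector
amova_ssd <- function(d2, g) {
  n <- nrow(d2)
  gf <- factor(g)
  ng <- tabulate(gf)
  ss_total <- sum(d2) / (2 * n)
  bygroup <- rowsum(d2, gf)               # G x N
  within_blocks <- rowsum(t(bygroup), gf) # G x G, entry [a,b] = sum over a,b
  ss_within <- sum(diag(as.matrix(within_blocks)) / (2 * ng))
  list(ss_total = ss_total, ss_within = ss_within,
       ss_among = ss_total - ss_within, ng = ng, n = n, G = nlevels(gf))
}

amova_components <- function(d2, g) {
  s <- amova_ssd(d2, g)
  df_among <- s$G - 1L
  df_within <- s$n - s$G
  ms_among <- s$ss_among / df_among
  ms_within <- s$ss_within / df_within
  n_prime <- (s$n - sum(s$ng^2) / s$n) / (s$G - 1)
  vb <- ms_within
  va <- (ms_among - ms_within) / n_prime
  fst <- if (va + vb > 0) va / (va + vb) else NaN
  list(df_among = df_among, df_within = df_within, df_total = s$n - 1L,
       ss_among = s$ss_among, ss_within = s$ss_within,
       ss_total = s$ss_total, Va = va, Vb = vb, n_prime = n_prime,
       fst = fst)
}

#' One-level analysis of molecular variance (AMOVA)
#'
#' Partitions the total squared pairwise distance among individuals into
#' among-group and within-group variance components (Excoffier-style
#' distance AMOVA with pairwise-difference distances), and attaches a
#' permutation p-value for the fixation index obtained by shuffling group
#' labels over individuals.
#'
#' The fixation index is `FST = Va / (Va + Vb)`. `Va` can be negative for
#' small or unbalanced samples; it is reported as computed, and percentage
#' components are additionally given with `Va` floored at zero in the
#' display fields.
#'
#' @param d symmetric matrix of pairwise differences (see
#'   [pairwise_difference_matrix()]); entries are squared internally.
#' @param pops named group vector covering the rows of `d` (or an unnamed
#'   vector in row order).
#' @param n_perms number of label permutations (default 10000).
#' @param seed integer seed for the permutations.
#' @return An object of class `amova_result`.
#' @export
amova <- function(d, pops, n_perms = 10000, seed = 1) {
  stopifnot(is.matrix(d), nrow(d) == ncol(d))
  g <- if (!is.null(names(pops)) && !is.null(rownames(d)))
    unname(pops[rownames(d)]) else unname(pops)
  stopifnot(length(g) == nrow(d))
  if (length(unique(g)) < 2)
    stop("AMOVA needs at least two groups", call. = FALSE)
  d2 <- d^2
  obs <- amova_components(d2, g)
  if (is.nan(obs$fst))
    warning("no molecular variance: all sequences identical; FST is NaN")
  p <- NA_real_
  if (n_perms > 0 && !is.nan(obs$fst)) {
    n_exceed <- with_local_seed(seed, {
      hits <- 0L
      for (b in seq_len(n_perms)) {
        fst_b <- amova_components(d2, sample(g))$fst
        if (!is.nan(fst_b) && fst_b >= obs$fst - 1e-12) hits <- hits + 1L
      }
      hits
    })
    p <- (1 + n_exceed) / (n_perms + 1)
  }
  va_disp <- max(obs$Va, 0)
  tot <- va_disp + obs$Vb
  structure(c(obs, list(
    pct_among = if (tot > 0) 100 * va_disp / tot else NA_real_,
    pct_within = if (tot > 0) 100 * obs$Vb / tot else NA_real_,
    p_value = p, n_perms = n_perms, seed = seed,
    groups = unique(g))), class = "amova_result")
}

#' @export
print.amova_result <- function(x, ...) {
  cat("AMOVA (", length(x$groups), " groups, ", x$df_total + 1,
      " individuals)\n", sep = "")
  tab <- data.frame(
    df = c(x$df_among, x$df_within, x$df_total),
    SS = round(c(x$ss_among, x$ss_within, x$ss_total), 3),
    variance = round(c(x$Va, x$Vb, x$Va + x$Vb), 5),
    pct = round(c(x$pct_among, x$pct_within, 100), 2),
    row.names = c("Among groups", "Within groups", "Total"))
  print(tab)
  cat("FST =", format(round(x$fst, 5)), " permutation p =",
      format(x$p_value), "(", x$n_perms, "permutations )\n")
  invisible(x)
}

#' Pairwise FST matrix with permutation significance
#'
#' For every pair of groups, runs a two-group AMOVA restricted to that
#' pair and reports its fixation index and permutation p-value. Negative
#' FST values (possible in near-panmictic pairs) are reported as computed,
#' not clamped.
#'
#' @inheritParams amova
#' @return An object of class `pairwise_fst`: list with `groups`, `fst`
#'   and `p` (symmetric matrices, zero/NA diagonal).
#' @export
pairwise_fst <- function(d, pops, n_perms = 10000, seed = 1) {
  g <- if (!is.null(names(pops)) && !is.null(rownames(d)))
    unname(pops[rownames(d)]) else unname(pops)
  groups <- unique(g)
  G <- length(groups)
  if (G < 2) stop("pairwise FST needs at least two groups", call. = FALSE)
  fst <- matrix(0, G, G, dimnames = list(groups, groups))
  p <- matrix(NA_real_, G, G, dimnames = list(groups, groups))
  pair_seeds <- with_local_seed(seed,
    matrix(sample.int(.Machine$integer.max, G * G), G, G))
  for (a in seq_len(G - 1L)) for (b in seq.int(a + 1L, G)) {
    idx <- which(g %in% groups[c(a, b)])
    res <- suppressWarnings(
      amova(d[idx, idx, drop = FALSE], g[idx], n_perms, pair_seeds[a, b]))
    fst[a, b] <- fst[b, a] <- res$fst
    p[a, b] <- p[b, a] <- res$p_value
  }
  structure(list(groups = groups, fst = fst, p = p,
                 n_perms = n_perms, seed = seed),
            class = "pairwise_fst")
}

fst_stars <- function(p) {
  ifelse(is.na(p), "", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "ns")))
}

#' @export
print.pairwise_fst <- function(x, ...) {
  cat("Pairwise FST (", x$n_perms, " permutations; * p<0.05, ** p<0.01)\n",
      sep = "")
  m <- matrix("", nrow(x$fst), ncol(x$fst), dimnames = dimnames(x$fst))
  low <- lower.tri(m)
  m[low] <- paste0(format(round(x$fst[low], 5)), fst_stars(x$p[low]))
  print(as.data.frame(m), right = TRUE)
  invisible(x)
}

#' @export
as.data.frame.pairwise_fst <- function(x, ...) {
  idx <- which(lower.tri(x$fst), arr.ind = TRUE)
  data.frame(group_a = x$groups[idx[, 2L]], group_b = x$groups[idx[, 1L]],
             fst = x$fst[idx], p = x$p[idx], stars = fst_stars(x$p[idx]),
             row.names = NULL)
}
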