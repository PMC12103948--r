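#' Nei's haplotype (gene) diversity
#'
#' Unbiased estimator `h = n/(n-1) * (1 - sum((c_i/n)^2))` for haplotype
#' counts `c_i` summing to `n`. This is the probability that two sequences
#' drawn without replacement carry different haplotypes.
#'
#' @param counts positive integer haplotype counts.
#' @return `h` in `[0, 1]`.
#' @examples
#' haplotype_diversity(c(35, 3, 2))  # 0.232 at 3 dp
#' @export
haplotype_diversity <- function(counts) {
  counts <- counts[counts > 0]
  n <- sum(counts)
  if (n < 2) stop("haplotype diversity needs at least 2 sequences",
                  call. = FALSE)
  n / (n - 1) * (1 - sum((counts / n)^2))
}

# per-site pair-mismatch contributions c_s over the complete-deletion site
# set, for sequences with integer multiplicities. c_s = (# unordered pairs
# differing at site s) / (n choose 2); pi = sum(c_s) / L_eff.
site_contributions <- function(m, weights) {
  keep <- included_sites(m)
  n <- sum(weights)
  npairs <- n * (n - 1) / 2
  contrib <- vapply(which(keep), function(j) {
    cnt <- rowsum(weights, m[, j])[, 1L]
    (npairs - sum(cnt * (cnt - 1) / 2)) / npairs
  }, 0)
  list(contrib = contrib, L_eff = sum(keep), n = n)
}

resolve_seqs <- function(x) {
  if (inherits(x, "hd_alignment"))
    list(m = aln_matrix(x), weights = rep(1L, length(x$ids)))
  else if (inherits(x, "haplotype_table"))
    list(m = aln_matrix(hap_alignment(x)), weights = unname(x$total))
  else stop("expected an hd_alignment or haplotype_table", call. = FALSE)
}

#' Nucleotide diversity (mean pairwise p-distance per site)
#'
#' `pi` is the average number of differing sites between two sequences
#' drawn without replacement, divided by the number of analysable sites.
#' Sites containing `N` or `-` in any sequence are excluded (complete
#' deletion), so site classification and `pi` share one site universe.
#' No small-sample correction is applied here; the `n/(n-1)`-style factor
#' used by the coalescent theta estimator enters only in
#' [theta_from_pi()].
#'
#' @param x an `hd_alignment` or a `haplotype_table` (counts used as
#'   multiplicities; both routes give identical values).
#' @return `pi >= 0`, dimensionless (per site).
#' @export
nucleotide_diversity <- function(x) {
  s <- resolve_seqs(x)
  if (sum(s$weights) < 2)
    stop("nucleotide diversity needs at least 2 sequences", call. = FALSE)
  sc <- site_contributions(s$m, s$weights)
  if (sc$L_eff < 1) stop("no analysable sites after complete deletion",
                         call. = FALSE)
  sum(sc$contrib) / sc$L_eff
}

#' Site-bootstrap standard error of nucleotide diversity
#'
#' Resamples the analysable site columns with replacement `B` times,
#' recomputes `pi` for each replicate, and returns the sample standard
#' deviation (denominator `B - 1`) of the replicate values. This is the
#' p-distance site bootstrap commonly used to attach a standard error to
#' `pi`.
#'
#' @inheritParams nucleotide_diversity
#' @param B number of bootstrap replicates (default 1000).
#' @param seed integer seed; a fixed seed gives byte-identical results.
#' @return `se_pi >= 0`.
#' @export
bootstrap_se_pi <- function(x, B = 1000, seed = 1) {
  stopifnot(B >= 1)
  s <- resolve_seqs(x)
  sc <- site_contributions(s$m, s$weights)
  if (sc$L_eff < 1) stop("no analysable sites after complete deletion",
                         call. = FALSE)
  if (all(sc$contrib == 0)) return(0)
  reps <- with_local_seed(seed, {
    vapply(seq_len(B), function(b)
      mean(sc$contrib[sample.int(sc$L_eff, sc$L_eff, replace = TRUE)]), 0)
  })
  stats::sd(reps)
}

# evaluate expr with a private RNG state seeded from `seed`
with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Per-group diversity summary
#'
#' Computes, for every group and for the pooled sample, the sequence count,
#' haplotype count, Nei haplotype diversity, nucleotide diversity and its
#' site-bootstrap standard error.
#'
#' @inheritParams collapse_haplotypes
#' @param B bootstrap replicates for the standard error of `pi`.
#' @param seed integer seed for the bootstrap.
#' @return data.frame with columns `group`, `n`, `n_hap`, `hap_div`, `pi`,
#'   `se_pi`.
#' @export
diversity_stats <- function(aln, pops, B = 1000, seed = 1) {
  pops <- as_popmap(pops, aln)
  groups <- unique(unname(pops))
  subs <- c(lapply(groups, function(g)
    aln_subset(aln, names(pops)[pops == g])), list(aln))
  sub_seeds <- with_local_seed(seed,
    sample.int(.Machine$integer.max, length(subs)))
  rows <- Map(function(a, g, s) {
    haps <- collapse_haplotypes(a)
    data.frame(group = g, n = length(a$ids), n_hap = length(haps$hap_id),
               hap_div = if (length(a$ids) >= 2) haplotype_diversity(haps$total)
                         else NA_real_,
               pi = if (length(a$ids) >= 2) nucleotide_diversity(haps)
                    else NA_real_,
               se_pi = if (length(a$ids) >= 2) bootstrap_se_pi(haps, B, s)
                       else NA_real_)
  }, subs, c(groups, "All"), as.list(sub_seeds))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
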