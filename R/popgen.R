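#' Full population-genetics analysis of an aligned mtDNA fragment
#'
#' Runs the whole estimator pipeline on an alignment plus group map:
#' haplotype collapsing and site classification, per-group diversity with
#' bootstrap standard errors, one-level AMOVA and pairwise FST with
#' permutation tests, the minimum-spanning haplotype network, an NJ
#' haplotype tree with bootstrap supports, a UPGMA tree of the groups
#' (built from the pairwise FST matrix, negative values floored at zero),
#' a PCA of the haplotype SNP matrix, and per-group coalescent Ne
#' estimates.
#'
#' A single master seed deterministically spawns independent sub-seeds
#' for the bootstrap, permutation and tree-support stages, so the whole
#' object is reproducible byte-for-byte from `(inputs, parameters, seed)`.
#'
#' @param aln an [as_alignment()] object (or FASTA path).
#' @param pops named group vector (or popmap TSV path).
#' @param mu per-site mutation rate for Ne (default `3.11e-8`).
#' @param B bootstrap replicates for `SE(pi)` and tree supports
#'   (default 1000).
#' @param n_perms label permutations for AMOVA / pairwise FST
#'   (default 10000).
#' @param seed master integer seed.
#' @param epsilon_ties retain co-minimal ties in the haplotype network.
#' @param use_sample_size sample-size-corrected theta (see
#'   [theta_from_pi()]).
#' @return An object of class `popgen` with components `haplotypes`,
#'   `sites`, `diversity`, `amova`, `pairwise_fst`, `network`, `nj`,
#'   `upgma`, `pca`, `ne` and `params`.
#' @examples
#' sim <- generate_alignment(sim_config(seed = 7))
#' fit <- popgen(sim$alignment, sim$popmap, B = 50, n_perms = 100)
#' fit
#' @export
popgen <- function(aln, pops, mu = 3.11e-8, B = 1000, n_perms = 10000,
                   seed = 1, epsilon_ties = FALSE,
                   use_sample_size = FALSE) {
  if (is.character(aln) && length(aln) == 1L) aln <- read_alignment(aln)
  stopifnot(inherits(aln, "hd_alignment"))
  pops <- if (is.character(pops) && length(pops) == 1L &&
              file.exists(pops)) read_popmap(pops, aln)
          else as_popmap(pops, aln)
  stopifnot(mu > 0, B >= 1, n_perms >= 0)
  sub <- with_local_seed(seed, sample.int(.Machine$integer.max, 5L))
  haps <- collapse_haplotypes(aln, pops)
  sites <- classify_sites_by_group(aln, pops)
  div <- diversity_stats(aln, pops, B = B, seed = sub[1L])
  d_ind <- pairwise_difference_matrix(aln)
  am <- amova(d_ind, pops, n_perms = n_perms, seed = sub[2L])
  pw <- pairwise_fst(d_ind, pops, n_perms = n_perms, seed = sub[3L])
  net <- min_spanning_network(haps, epsilon_ties = epsilon_ties)
  nj <- if (length(haps$hap_id) >= 2)
    bootstrap_support(haps, B = B, seed = sub[4L]) else NULL
  up <- if (length(pw$groups) >= 2) upgma_tree(pmax(pw$fst, 0)) else NULL
  pca <- tryCatch(haplotype_pca(haps), error = function(e) NULL)
  ne <- estimate_ne(aln, pops, mu = mu, B = B, seed = sub[1L],
                    use_sample_size = use_sample_size)
  structure(list(
    haplotypes = haps, sites = sites, diversity = div, amova = am,
    pairwise_fst = pw, network = net, nj = nj, upgma = up, pca = pca,
    ne = ne,
    params = list(n = length(aln$ids), L = aln$L,
                  groups = table(factor(pops, levels = unique(pops))),
                  mu = mu, B = B, n_perms = n_perms, seed = seed,
                  epsilon_ties = epsilon_ties,
                  use_sample_size = use_sample_size)),
    class = "popgen")
}

#' @export
print.popgen <- function(x, ...) {
  p <- x$params
  cat("Population-genetic analysis: ", p$n, " sequences x ", p$L,
      " bp in ", length(p$groups), " groups\n", sep = "")
  cat("Haplotypes: ", length(x$haplotypes$hap_id), " (modal ",
      x$haplotypes$hap_id[1L], ", ", x$haplotypes$total[1L], "/", p$n,
      " = ", round(100 * x$haplotypes$total[1L] / p$n), "%)\n", sep = "")
  all_div <- x$diversity[x$diversity$group == "All", ]
  cat("Overall haplotype diversity ", round(all_div$hap_div, 3),
      ", nucleotide diversity ", signif(all_div$pi, 3), "\n", sep = "")
  cat("AMOVA: ", round(x$amova$pct_among, 2), "% among / ",
      round(x$amova$pct_within, 2), "% within groups, FST = ",
      round(x$amova$fst, 4), " (p = ", format(x$amova$p_value), ")\n",
      sep = "")
  invisible(x)
}

#' @export
summary.popgen <- function(object, ...) {
  x <- object
  print(x)
  cat("\nDiversity by group:\n")
  print(transform(x$diversity, hap_div = round(hap_div, 3),
                  pi = round(pi, 5), se_pi = signif(se_pi, 3)),
        row.names = FALSE)
  cat("\n"); print(x$amova)
  cat("\n"); print(x$pairwise_fst)
  cat("\nEffective population sizes:\n")
  print(transform(x$ne, pi = round(pi, 5), theta = signif(theta, 5),
                  ne = round(ne, 2), se_ne = round(se_ne, 2),
                  se_pi = signif(se_pi, 3)), row.names = FALSE)
  invisible(x)
}

#' Plot method for popgen fits
#'
#' `type = "ne"` draws the per-group Ne estimates with standard-error
#' bars and the 1000-individual adaptability reference line;
#' `type = "pca"` plots haplotype scores on the first two components;
#' `type = "network"` draws the minimum-spanning network with node size
#' proportional to haplotype frequency.
#'
#' @param x a `popgen` object.
#' @param type one of `"ne"`, `"pca"`, `"network"`.
#' @param ... passed to the underlying base-graphics calls.
#' @return `x`, invisibly.
#' @export
plot.popgen <- function(x, type = c("ne", "pca", "network"), ...) {
  type <- match.arg(type)
  if (type == "ne") {
    ne <- x$ne
    up <- ne$ne + ne$se_ne
    lo <- pmax(ne$ne - ne$se_ne, 0)
    bp <- graphics::barplot(ne$ne, names.arg = ne$group,
                            ylim = c(0, max(up, 1000) * 1.1),
                            ylab = "Effective population size", ...)
    graphics::arrows(bp, lo, bp, up, angle = 90, code = 3, length = 0.05)
    graphics::abline(h = 1000, lty = 2)
  } else if (type == "pca") {
    if (is.null(x$pca)) stop("no PCA available", call. = FALSE)
    s <- x$pca$scores
    evr <- round(100 * x$pca$explained_variance_ratio[1:2], 1)
    graphics::plot(s[, 1L], s[, 2L],
                   xlab = paste0("PC1 (", evr[1L], "%)"),
                   ylab = paste0("PC2 (", evr[2L], "%)"), ...)
    graphics::text(s[, 1L], s[, 2L], rownames(s), pos = 3, cex = 0.8)
  } else {
    net <- x$network
    k <- nrow(net$nodes)
    ang <- seq(0, 2 * pi, length.out = k + 1L)[-1L]
    xy <- cbind(cos(ang), sin(ang))
    graphics::plot(xy, type = "n", axes = FALSE, xlab = "", ylab = "",
                   xlim = c(-1.3, 1.3), ylim = c(-1.3, 1.3), asp = 1, ...)
    ia <- match(net$edges$hap_a, net$nodes$hap_id)
    ib <- match(net$edges$hap_b, net$nodes$hap_id)
    graphics::segments(xy[ia, 1L], xy[ia, 2L], xy[ib, 1L], xy[ib, 2L])
    graphics::points(xy, cex = 1 + 2 * sqrt(net$nodes$total /
                                              max(net$nodes$total)),
                     pch = 21, bg = "grey85")
    graphics::text(xy[, 1L] * 1.18, xy[, 2L] * 1.18, net$nodes$hap_id,
                   cex = 0.8)
  }
  invisible(x)
}
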