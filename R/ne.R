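#' Coalescent theta from nucleotide diversity
#'
#' `theta = pi * L / (L - 1)`, where `L` is the length in base pairs of
#' the analysed fragment. The length-based correction factor is the form
#' used with this estimator chain for single-fragment mtDNA data; a
#' sample-size-based correction can be selected instead via
#' `use_sample_size` together with `n_samples`.
#'
#' @param pi per-site nucleotide diversity (non-negative).
#' @param L fragment length in bp (default 616), must be >= 2.
#' @param use_sample_size if `TRUE`, correct by `n_samples/(n_samples-1)`
#'   instead of `L/(L-1)`.
#' @param n_samples number of sequences (only used with
#'   `use_sample_size = TRUE`).
#' @return `theta` (dimensionless, per site).
#' @export
theta_from_pi <- function(pi, L = 616, use_sample_size = FALSE,
                          n_samples = NULL) {
  stopifnot(all(pi >= 0))
  if (use_sample_size) {
    if (is.null(n_samples) || n_samples < 2)
      stop("use_sample_size = TRUE needs n_samples >= 2", call. = FALSE)
    return(pi * n_samples / (n_samples - 1))
  }
  if (L < 2) stop("fragment length L must be >= 2", call. = FALSE)
  pi * L / (L - 1)
}

#' Effective population size from theta
#'
#' `Ne = theta / (4 * mu)` with `mu` the per-site mutation rate of the
#' locus. The default rate 3.11e-8 is a literature cytochrome-b rate for
#' fishes; its time unit is inherited by `Ne`.
#'
#' @param theta population-scaled mutation parameter (non-negative).
#' @param mu per-site mutation rate (> 0), default `3.11e-8`.
#' @return `Ne` in individuals.
#' @export
ne_from_theta <- function(theta, mu = 3.11e-8) {
  stopifnot(all(theta >= 0))
  if (mu <= 0) stop("mutation rate mu must be positive", call. = FALSE)
  theta / (4 * mu)
}

#' Standard error of Ne from the standard error of pi
#'
#' `SE(Ne) = SE(pi) / (4 * mu)`, i.e. the delta-method image of the
#' bootstrap standard error of nucleotide diversity under the linear map
#' pi -> Ne (the `L/(L-1)` factor is ignored here, matching the estimator
#' chain this package implements).
#'
#' @param se_pi standard error of nucleotide diversity (non-negative).
#' @inheritParams ne_from_theta
#' @return `SE(Ne)` in individuals.
#' @export
se_ne_from_se_pi <- function(se_pi, mu = 3.11e-8) {
  stopifnot(all(se_pi >= 0))
  if (mu <= 0) stop("mutation rate mu must be positive", call. = FALSE)
  se_pi / (4 * mu)
}

#' Per-group effective population size estimates
#'
#' Composes the pipeline per group and for the pooled sample: nucleotide
#' diversity and its site-bootstrap standard error, then
#' `theta = pi * L/(L-1)`, `Ne = theta/(4 mu)` and
#' `SE(Ne) = SE(pi)/(4 mu)`. Groups with `Ne` below 1000 individuals are
#' flagged against the commonly cited minimum for long-term adaptability.
#'
#' @inheritParams diversity_stats
#' @param mu per-site mutation rate (default `3.11e-8`).
#' @param use_sample_size correct theta by sample size instead of fragment
#'   length (off by default; see [theta_from_pi()]).
#' @return data.frame with columns `group`, `n`, `pi`, `se_pi`, `theta`,
#'   `mu`, `ne`, `se_ne`, `below_1000`.
#' @export
estimate_ne <- function(aln, pops, mu = 3.11e-8, B = 1000, seed = 1,
                        use_sample_size = FALSE) {
  div <- diversity_stats(aln, pops, B = B, seed = seed)
  theta <- mapply(function(pi, n) {
    if (is.na(pi)) NA_real_
    else theta_from_pi(pi, L = aln$L, use_sample_size = use_sample_size,
                       n_samples = n)
  }, div$pi, div$n)
  ne <- ifelse(is.na(theta), NA_real_, ne_from_theta(pmax(theta, 0), mu))
  se_ne <- ifelse(is.na(div$se_pi), NA_real_,
                  se_ne_from_se_pi(div$se_pi, mu))
  data.frame(group = div$group, n = div$n, pi = div$pi, se_pi = div$se_pi,
             theta = theta, mu = mu, ne = ne, se_ne = se_ne,
             below_1000 = !is.na(ne) & ne < 1000)
}
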