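#' Default haplotype substitution graph
#'
#' A star-like graph rooted at the hub haplotype `Hap1`: most haplotypes
#' sit one substitution from the hub, one (`Hap8`) sits two steps away,
#' `Hap7` hangs one further step off `Hap8`, and `Hap11` lies four steps
#' from the hub. Each row gives a haplotype, its parent, and the number of
#' new substitutions on the connecting edge.
#'
#' @return data.frame with columns `hap`, `parent`, `steps`.
#' @export
default_substitution_graph <- function() {
  data.frame(
    hap    = paste0("Hap", c(2:6, 8, 7, 9:11)),
    parent = c(rep("Hap1", 6), "Hap8", rep("Hap1", 3)),
    steps  = c(1L, 1L, 1L, 1L, 1L, 2L, 1L, 1L, 1L, 4L))
}

#' Default per-group haplotype counts
#'
#' An illustrative four-group design: a hub haplotype carried by 107 of
#' 137 individuals, group-private haplotypes (Padma: Hap2; Jamuna: Hap4,
#' Hap5; Halda: Hap8; Culture: Hap9-Hap11) and group-shared ones (Hap3
#' Padma/Jamuna, Hap6 Jamuna/Halda, Hap7 Jamuna/Culture). These counts
#' are a plausible reconstruction of a real sampling design and are
#' intended for simulation only, not as observed data.
#'
#' @return named list: one named integer count vector per group.
#' @export
default_frequency_table <- function() {
  list(
    Padma   = c(Hap1 = 35L, Hap2 = 2L, Hap3 = 3L),
    Jamuna  = c(Hap1 = 31L, Hap3 = 1L, Hap4 = 1L, Hap5 = 1L, Hap6 = 1L,
                Hap7 = 1L),
    Halda   = c(Hap1 = 23L, Hap6 = 4L, Hap8 = 5L),
    Culture = c(Hap1 = 18L, Hap7 = 6L, Hap9 = 2L, Hap10 = 2L,
                Hap11 = 1L))
}

#' Simulation configuration
#'
#' Bundles and validates everything the generator needs: fragment length,
#' group sizes, the haplotype substitution graph, per-group haplotype
#' counts (exact mode) or probabilities (multinomial mode), and a seed.
#'
#' @param L fragment length in bp (default 616).
#' @param groups named integer vector of group sizes (default Padma 40,
#'   Jamuna 36, Halda 32, Culture 29).
#' @param graph substitution graph data.frame (`hap`, `parent`, `steps`)
#'   rooted at `Hap1`; see [default_substitution_graph()].
#' @param freqs named list of per-group named count vectors (exact mode)
#'   or probability vectors (multinomial mode).
#' @param seed integer seed.
#' @param mode `"exact"` (counts placed verbatim; default) or
#'   `"multinomial"` (counts drawn with the configured probabilities).
#' @return Validated list of class `sim_config`.
#' @export
sim_config <- function(L = 616, groups = NULL, graph = NULL, freqs = NULL,
                       seed = 1, mode = c("exact", "multinomial")) {
  mode <- match.arg(mode)
  if (is.null(groups))
    groups <- c(Padma = 40L, Jamuna = 36L, Halda = 32L, Culture = 29L)
  if (is.null(graph)) graph <- default_substitution_graph()
  if (is.null(freqs)) {
    freqs <- default_frequency_table()
    if (mode == "multinomial")
      freqs <- lapply(names(freqs), function(g) freqs[[g]] / groups[[g]])
    names(freqs) <- names(groups)
  }
  stopifnot(L >= 2, length(groups) >= 1, all(groups >= 1),
            !is.null(names(groups)),
            all(c("hap", "parent", "steps") %in% names(graph)),
            all(graph$steps >= 1),
            setequal(names(freqs), names(groups)))
  haps <- c("Hap1", graph$hap)
  if (anyDuplicated(haps))
    stop("duplicate haplotype id in substitution graph", call. = FALSE)
  if (!all(graph$parent %in% haps))
    stop("substitution graph parent not defined: ",
         paste(setdiff(graph$parent, haps), collapse = ", "), call. = FALSE)
  if (sum(graph$steps) > L)
    stop("capacity error: ", sum(graph$steps),
         " substitutions requested but only ", L, " sites available",
         call. = FALSE)
  for (g in names(groups)) {
    f <- freqs[[g]]
    if (!all(names(f) %in% haps))
      stop("frequency table of group '", g, "' names unknown haplotype(s)",
           call. = FALSE)
    if (mode == "exact") {
      if (any(f != round(f)) || sum(f) != groups[[g]])
        stop("exact-mode counts of group '", g, "' must be integers ",
             "summing to the group size (", groups[[g]], ")", call. = FALSE)
    } else if (abs(sum(f) - 1) > 1e-9)
      stop("multinomial-mode probabilities of group '", g,
           "' must sum to 1", call. = FALSE)
  }
  structure(list(L = as.integer(L), groups = groups, graph = graph,
                 freqs = freqs, seed = as.integer(seed), mode = mode),
            class = "sim_config")
}

#' Build haplotype sequences from a substitution graph
#'
#' Draws a random ancestral sequence of length `L`, then derives each
#' child haplotype from its parent by placing the configured number of
#' substitutions at fresh, uniformly chosen positions (infinite-sites
#' placement: no position is reused across edges), each to a different
#' base. Pairwise Hamming distances between the resulting haplotypes
#' therefore equal path sums in the graph.
#'
#' @param config a [sim_config()].
#' @return Named character vector of haplotype sequences (hub first).
#' @export
build_haplotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  bases <- c("A", "C", "G", "T")
  with_local_seed(config$seed, {
    anc <- sample(bases, config$L, replace = TRUE)
    pool <- sample.int(config$L)           # fresh positions, never reused
    used <- 0L
    seqs <- list(Hap1 = anc)
    todo <- config$graph
    while (nrow(todo)) {
      ready <- todo$parent %in% names(seqs)
      if (!any(ready))
        stop("substitution graph is not rooted at Hap1", call. = FALSE)
      for (r in which(ready)) {
        child <- seqs[[todo$parent[r]]]
        pos <- pool[used + seq_len(todo$steps[r])]
        used <- used + todo$steps[r]
        for (p in pos)
          child[p] <- sample(setdiff(bases, child[p]), 1L)
        seqs[[todo$hap[r]]] <- child
      }
      todo <- todo[!ready, , drop = FALSE]
    }
    vapply(seqs, paste, "", collapse = "")
  })
}

#' Generate a synthetic alignment, population map and truth object
#'
#' Places individuals on the configured haplotypes, either with the exact
#' configured counts (`mode = "exact"`) or by multinomial draws from the
#' configured probabilities. Sample ids encode group and replicate index
#' (`Padma_001`, ...). The returned truth object records the haplotype
#' sequences, realized counts, and the target values of haplotype
#' diversity, nucleotide diversity, theta and Ne per group and pooled: in
#' exact mode these are the estimator values implied by the configured
#' counts (so a correct pipeline reproduces them with zero error); in
#' multinomial mode they are the population values implied by the
#' configured probabilities.
#'
#' @param config a [sim_config()].
#' @param mu mutation rate used for the truth theta/Ne values.
#' @return list with elements `alignment` (`hd_alignment`), `popmap`
#'   (named group vector) and `truth`.
#' @export
generate_alignment <- function(config, mu = 3.11e-8) {
  stopifnot(inherits(config, "sim_config"))
  hapseq <- build_haplotypes(config)
  m <- do.call(rbind, strsplit(hapseq, "", fixed = TRUE))
  rownames(m) <- names(hapseq)
  dhap <- hamming_from_chars(m)
  counts <- with_local_seed(config$seed + 1L, {
    lapply(names(config$groups), function(g) {
      f <- config$freqs[[g]]
      if (config$mode == "exact") f
      else stats::setNames(
        as.integer(stats::rmultinom(1L, config$groups[[g]], f)), names(f))
    })
  })
  names(counts) <- names(config$groups)
  ids <- seqs <- groups <- character(0)
  for (g in names(config$groups)) {
    hap_of_ind <- rep(names(counts[[g]]), counts[[g]])
    n <- length(hap_of_ind)
    ids <- c(ids, sprintf("%s_%03d", g, seq_len(n)))
    seqs <- c(seqs, unname(hapseq[hap_of_ind]))
    groups <- c(groups, rep(g, n))
  }
  aln <- as_alignment(stats::setNames(seqs, ids))
  popmap <- stats::setNames(groups, ids)
  truth <- sim_truth(config, hapseq, dhap, counts, mu)
  list(alignment = aln, popmap = popmap, truth = truth)
}

sim_truth <- function(config, hapseq, dhap, counts, mu) {
  groups <- names(config$groups)
  one <- function(w) { # named weight vector: counts (exact) or probs
    haps <- names(w)
    d <- dhap[haps, haps, drop = FALSE]
    if (config$mode == "exact") {
      n <- sum(w)
      h <- if (n >= 2) haplotype_diversity(w) else NA_real_
      pi <- if (n >= 2)
        sum(outer(w, w) * d) / 2 / (n * (n - 1) / 2) / config$L
      else NA_real_
    } else {
      h <- 1 - sum(w^2)
      pi <- sum(outer(w, w) * d) / config$L
    }
    theta <- theta_from_pi(pi, config$L)
    c(h = h, pi = pi, theta = theta, ne = ne_from_theta(theta, mu))
  }
  per_group <- lapply(counts, one)
  pooled_w <- if (config$mode == "exact") {
    tot <- unlist(counts)
    tapply(tot, sub("^.*\\.", "", names(tot)), sum)
  } else {
    sizes <- config$groups[groups]
    tot <- unlist(Map(function(f, n) f * n, config$freqs[groups],
                      as.list(sizes)))
    w <- tapply(tot, sub("^.*\\.", "", names(tot)), sum)
    w / sum(w)
  }
  pooled_w <- stats::setNames(as.numeric(pooled_w), names(pooled_w))
  tab <- rbind(do.call(rbind, per_group), All = one(pooled_w))
  truth <- data.frame(group = c(groups, "All"), tab, row.names = NULL)
  list(haplotypes = hapseq, distance = dhap,
       counts = counts, pooled_counts = pooled_w, values = truth,
       mode = config$mode, seed = config$seed)
}

#' Parameter-recovery report for the simulator and pipeline
#'
#' Runs the generator `n_replicates` times (fresh sub-seed per replicate),
#' re-estimates haplotype diversity, nucleotide diversity and Ne from each
#' generated alignment with the package's own estimators, and reports bias
#' and RMSE against the truth values recorded by [generate_alignment()].
#' In exact mode the error is structurally zero (no sampling), which makes
#' this the pipeline's zero-noise fixed point; in multinomial mode the
#' bias shrinks as group sizes grow.
#'
#' @param config a [sim_config()].
#' @param n_replicates number of simulated datasets.
#' @param seed integer seed used to derive per-replicate generator seeds.
#' @param mu mutation rate for Ne.
#' @return list with `estimates` (per replicate/group data.frame of
#'   estimate minus truth) and `summary` (bias and RMSE per group and
#'   statistic).
#' @export
parameter_recovery <- function(config, n_replicates = 50, seed = 1,
                               mu = 3.11e-8) {
  stopifnot(inherits(config, "sim_config"), n_replicates >= 1)
  rep_seeds <- with_local_seed(seed,
    sample.int(.Machine$integer.max %/% 2L, n_replicates))
  rows <- lapply(seq_len(n_replicates), function(r) {
    cfg <- config
    cfg$seed <- rep_seeds[r]
    sim <- generate_alignment(cfg, mu = mu)
    est <- lapply(c(as.list(names(cfg$groups)), list(NULL)), function(g) {
      a <- if (is.null(g)) sim$alignment
           else aln_subset(sim$alignment,
                           names(sim$popmap)[sim$popmap == g])
      haps <- collapse_haplotypes(a)
      pi <- nucleotide_diversity(haps)
      c(h = haplotype_diversity(haps$total), pi = pi,
        ne = ne_from_theta(theta_from_pi(pi, cfg$L), mu))
    })
    est <- do.call(rbind, est)
    truth <- sim$truth$values
    data.frame(replicate = r, group = truth$group,
               err_h = est[, "h"] - truth$h,
               err_pi = est[, "pi"] - truth$pi,
               err_ne = est[, "ne"] - truth$ne)
  })
  est <- do.call(rbind, rows)
  agg <- function(v) c(bias = mean(v), rmse = sqrt(mean(v^2)))
  summ <- do.call(rbind, lapply(split(est, est$group), function(d)
    data.frame(group = d$group[1L],
               t(c(h = agg(d$err_h), pi = agg(d$err_pi),
                   ne = agg(d$err_ne))))))
  rownames(summ) <- NULL
  list(estimates = est, summary = summ)
}
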