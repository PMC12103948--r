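#' Collapse aligned sequences into haplotypes
#'
#' Groups sequences by exact string identity over all sites and tabulates
#' per-group and total counts. Haplotype ids `Hap1, Hap2, ...` are assigned
#' by decreasing total count, ties broken by first occurrence in the input,
#' so the modal haplotype is always `Hap1`. Sequences containing `N` or `-`
#' collapse only with byte-identical strings; no attempt is made to resolve
#' ambiguity.
#'
#' @param aln an [as_alignment()] object.
#' @param pops optional named group vector (see [as_popmap()]); when `NULL`
#'   all samples are counted in a single group `"All"`.
#' @return An object of class `haplotype_table`: list with `hap_id`,
#'   `sequence` (named by hap id), `counts` (haplotype x group integer
#'   matrix), `total` (named integer vector) and `membership` (hap id per
#'   input sample).
#' @export
collapse_haplotypes <- function(aln, pops = NULL) {
  stopifnot(inherits(aln, "hd_alignment"))
  if (is.null(pops))
    pops <- stats::setNames(rep("All", length(aln$ids)), aln$ids)
  else
    pops <- as_popmap(pops, aln)
  uniq <- unique(unname(aln$seq))
  idx <- match(aln$seq, uniq)                    # sample -> haplotype index
  tot <- tabulate(idx, nbins = length(uniq))
  ord <- order(-tot, seq_along(uniq))            # frequency, then first seen
  rank <- integer(length(uniq)); rank[ord] <- seq_along(uniq)
  hap_id <- paste0("Hap", rank[idx])             # per sample
  ids <- paste0("Hap", seq_along(uniq))
  seqs <- stats::setNames(uniq[ord], ids)
  glev <- unique(unname(pops))
  counts <- table(factor(paste0("Hap", rank[idx]), levels = ids),
                  factor(pops, levels = glev))
  counts <- matrix(as.integer(counts), nrow = length(ids),
                   dimnames = list(ids, glev))
  structure(list(hap_id = ids, sequence = seqs, counts = counts,
                 total = stats::setNames(as.integer(rowSums(counts)), ids),
                 membership = stats::setNames(hap_id, aln$ids),
                 L = aln$L),
            class = "haplotype_table")
}

#' @export
print.haplotype_table <- function(x, ...) {
  cat("Haplotype table: ", length(x$hap_id), " haplotypes, ",
      sum(x$total), " sequences, L = ", x$L, "\n", sep = "")
  print(cbind(x$counts, total = x$total))
  invisible(x)
}

#' @export
as.data.frame.haplotype_table <- function(x, ...) {
  data.frame(hap_id = x$hap_id, total = unname(x$total),
             as.data.frame.matrix(x$counts), row.names = NULL,
             check.names = FALSE)
}

# rebuild an hd_alignment carrying one record per haplotype
hap_alignment <- function(haps) {
  as_alignment(haps$sequence)
}

#' Classify alignment sites
#'
#' Classifies each site under complete deletion: any column containing `N`
#' or `-` in at least one sequence is excluded and counted separately.
#' Included columns are monomorphic (one base), singleton-variable (every
#' minority base occurs in exactly one sequence) or parsimony-informative
#' (at least two bases each carried by at least two sequences). With a
#' single sequence every site is monomorphic by convention.
#'
#' @param aln an `hd_alignment`.
#' @param weights optional non-negative integer multiplicities, one per
#'   sequence (used when classifying haplotype sequences by their counts).
#' @return A list of class `site_classification` with `labels` (length-L
#'   factor over `monomorphic`, `singleton`, `parsimony`, `excluded`) and
#'   `counts` (named vector: monomorphic, polymorphic, singleton,
#'   parsimony, excluded).
#' @export
classify_sites <- function(aln, weights = NULL) {
  m <- aln_matrix(aln)
  if (is.null(weights)) weights <- rep(1L, nrow(m))
  stopifnot(length(weights) == nrow(m), all(weights >= 0))
  keep <- included_sites(m)
  lab <- rep("excluded", ncol(m))
  for (j in which(keep)) {
    cnt <- rowsum(weights, m[, j])
    cnt <- cnt[cnt > 0, , drop = FALSE]
    lab[j] <- if (nrow(cnt) <= 1L) "monomorphic"
              else if (sum(cnt >= 2L) >= 2L) "parsimony"
              else "singleton"
  }
  lab <- factor(lab, levels = c("monomorphic", "singleton", "parsimony",
                                "excluded"))
  n <- table(lab)
  counts <- c(monomorphic = unname(n[["monomorphic"]]),
              polymorphic = unname(n[["singleton"]] + n[["parsimony"]]),
              singleton = unname(n[["singleton"]]),
              parsimony = unname(n[["parsimony"]]),
              excluded = unname(n[["excluded"]]))
  structure(list(labels = lab, counts = counts),
            class = "site_classification")
}

#' @export
print.site_classification <- function(x, ...) {
  print(x$counts)
  invisible(x)
}

#' Classify sites within each population group
#'
#' Applies [classify_sites()] independently to each group's subset of the
#' alignment. In a group with a single sequence every site is monomorphic
#' (the singleton definition degenerates).
#'
#' @inheritParams collapse_haplotypes
#' @return Named list of `site_classification`, one per group (in first
#'   appearance order), plus an `"All"` entry for the pooled alignment.
#' @export
classify_sites_by_group <- function(aln, pops) {
  pops <- as_popmap(pops, aln)
  out <- lapply(split(names(pops), factor(pops, levels = unique(pops))),
                function(ids) classify_sites(aln_subset(aln, ids)))
  c(out, list(All = classify_sites(aln)))
}
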