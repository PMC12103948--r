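#' Aligned sequence container
#'
#' An `hd_alignment` holds equal-length, uppercased nucleotide sequences
#' keyed by unique sample id. The allowed alphabet is `A`, `C`, `G`, `T`,
#' `N` and the gap character `-`; any other character (including IUPAC
#' ambiguity codes) is rejected, because unresolved ambiguity silently
#' inflates haplotype counts in a diversity analysis.
#'
#' @param seqs named character vector of sequences (one string per sample).
#' @return An object of class `hd_alignment`: a list with elements
#'   `ids` (character), `seq` (named character vector, uppercase) and
#'   `L` (integer alignment length).
#' @examples
#' aln <- as_alignment(c(s1 = "ACGT", s2 = "ACGA"))
#' aln$L
#' @export
as_alignment <- function(seqs) {
  if (length(seqs) == 0L)
    stop("empty input: no sequences", call. = FALSE)
  ids <- names(seqs)
  if (is.null(ids) || any(!nzchar(ids)))
    stop("all sequences must carry a non-empty sample id", call. = FALSE)
  if (anyDuplicated(ids))
    stop("duplicate sample ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  seqs <- toupper(as.character(seqs))
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L) {
    bad <- ids[lens != lens[1L]][1L]
    stop("length mismatch: record '", bad, "' has ", lens[ids == bad][1L],
         " sites, expected ", lens[1L], call. = FALSE)
  }
  bad <- regexpr("[^ACGTN-]", seqs)
  if (any(bad > 0L)) {
    i <- which(bad > 0L)[1L]
    stop("illegal character '", substr(seqs[i], bad[i], bad[i]),
         "' in record '", ids[i], "' at position ", bad[i],
         " (allowed: A, C, G, T, N, -)", call. = FALSE)
  }
  names(seqs) <- ids
  structure(list(ids = ids, seq = seqs, L = as.integer(lens[1L])),
            class = "hd_alignment")
}

#' Read a multiple-sequence alignment from FASTA
#'
#' Reads an aligned multi-record FASTA file and validates it into an
#' [as_alignment()] container. Input case is ignored; sequences are stored
#' uppercase and file order is preserved.
#'
#' @param path path to a FASTA file of equal-length sequences.
#' @return An `hd_alignment`.
#' @export
read_alignment <- function(path) {
  if (!file.exists(path))
    stop("alignment file not found: ", path, call. = FALSE)
  dna <- tryCatch(suppressWarnings(ape::read.FASTA(path)),
                  error = function(e) stop("could not parse FASTA '", path,
                                           "': ", conditionMessage(e),
                                           call. = FALSE))
  if (length(dna) == 0L)
    stop("empty input: no FASTA records in ", path, call. = FALSE)
  seqs <- vapply(as.character(dna), paste, "", collapse = "")
  names(seqs) <- names(dna)
  as_alignment(seqs)
}

#' Write an alignment (or haplotype sequences) to FASTA
#'
#' @param aln an `hd_alignment`, or any named character vector of sequences.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(aln, path) {
  seqs <- if (inherits(aln, "hd_alignment")) aln$seq else aln
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0(">", names(seqs), "\n", unname(seqs)), con)
  invisible(path)
}

#' Read a sample-to-group population map
#'
#' Reads a two-column TSV (`sample_id`, `group`), with an optional header
#' line `sample<TAB>group`, and checks it against an alignment: every
#' alignment sample must appear exactly once.
#'
#' @param path path to the TSV file.
#' @param aln the `hd_alignment` the map must cover.
#' @return A named character vector mapping sample id to group label, in
#'   alignment order.
#' @export
read_popmap <- function(path, aln) {
  if (!file.exists(path))
    stop("popmap file not found: ", path, call. = FALSE)
  raw <- utils::read.table(path, sep = "\t", header = FALSE,
                           colClasses = "character", quote = "",
                           comment.char = "")
  if (ncol(raw) != 2L)
    stop("popmap must have exactly two tab-separated columns", call. = FALSE)
  if (nrow(raw) > 0L && identical(tolower(unlist(raw[1L, ])),
                                  c("sample", "group")))
    raw <- raw[-1L, , drop = FALSE]
  as_popmap(stats::setNames(raw[[2L]], raw[[1L]]), aln)
}

#' Validate a sample-to-group mapping against an alignment
#'
#' @param groups named character vector (names = sample ids, values = group
#'   labels).
#' @param aln the `hd_alignment` to cover.
#' @return The mapping reordered to alignment order.
#' @export
as_popmap <- function(groups, aln) {
  stopifnot(inherits(aln, "hd_alignment"))
  ids <- names(groups)
  if (is.null(ids))
    stop("popmap must be a named vector (sample id -> group)", call. = FALSE)
  if (anyDuplicated(ids))
    stop("duplicate popmap entry for sample(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  missing <- setdiff(aln$ids, ids)
  if (length(missing))
    stop("popmap does not cover alignment sample(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  groups <- groups[aln$ids]
  if (any(!nzchar(groups)))
    stop("empty group label in popmap", call. = FALSE)
  groups
}

#' @export
print.hd_alignment <- function(x, ...) {
  cat("Alignment: ", length(x$ids), " sequences x ", x$L, " sites\n",
      sep = "")
  invisible(x)
}

# character matrix view (rows = samples, cols = sites)
aln_matrix <- function(aln) {
  m <- do.call(rbind, strsplit(aln$seq, "", fixed = TRUE))
  rownames(m) <- aln$ids
  m
}

# subset an alignment by sample ids
aln_subset <- function(aln, ids) {
  as_alignment(aln$seq[ids])
}

# complete-deletion mask: TRUE for sites free of N and '-' in every sequence
included_sites <- function(m) {
  !apply(m == "N" | m == "-", 2L, any)
}
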