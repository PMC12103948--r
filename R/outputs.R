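write_tsv <- function(d, path) {
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Write every result table of a popgen fit to a directory
#'
#' Emits a deterministic, documented file set: `haplotypes.fasta`,
#' `haplotype_table.tsv`, `sites.tsv`, `diversity.tsv`, `amova.tsv`,
#' `pairwise_fst.tsv`, `msn_edges.tsv`, `nj.nwk`, `upgma.nwk`,
#' `pca_scores.tsv`, `pca_variance.tsv`, `ne.tsv` and a machine-readable
#' `summary.json` enumerating the artifacts, the parameters (including
#' the seed) and the headline numbers. Numeric TSVs carry full-precision
#' columns plus rounded `display` columns (haplotype diversity to 3 dp,
#' nucleotide diversity to 5 dp, FST to 5 dp, Ne to 2 dp).
#'
#' @param fit a [popgen()] object.
#' @param out_dir output directory (created if needed).
#' @return Named character vector of the written file paths, invisibly.
#' @export
write_popgen_outputs <- function(fit, out_dir) {
  stopifnot(inherits(fit, "popgen"))
  ok <- dir.exists(out_dir) || dir.create(out_dir, recursive = TRUE,
                                          showWarnings = FALSE)
  if (!ok || file.access(out_dir, 2L) != 0L)
    stop("cannot write to output directory: ", out_dir, call. = FALSE)
  f <- function(name) file.path(out_dir, name)
  paths <- c(
    haplotypes_fasta = write_alignment(fit$haplotypes$sequence,
                                       f("haplotypes.fasta")),
    haplotype_table = write_tsv(as.data.frame(fit$haplotypes),
                                f("haplotype_table.tsv")),
    sites = write_tsv(
      do.call(rbind, lapply(names(fit$sites), function(g)
        data.frame(group = g, t(fit$sites[[g]]$counts)))),
      f("sites.tsv")),
    diversity = write_tsv(
      transform(fit$diversity,
                hap_div_display = round(hap_div, 3),
                pi_display = round(pi, 5)),
      f("diversity.tsv")),
    amova = write_tsv(with(fit$amova, data.frame(
      source = c("among", "within", "total"),
      df = c(df_among, df_within, df_total),
      ss = c(ss_among, ss_within, ss_total),
      variance = c(Va, Vb, Va + Vb),
      pct = c(pct_among, pct_within, 100))), f("amova.tsv")),
    pairwise_fst = write_tsv(
      transform(as.data.frame(fit$pairwise_fst),
                fst_display = round(fst, 5),
                negative = fst < 0), f("pairwise_fst.tsv")),
    msn_edges = write_tsv(fit$network$edges, f("msn_edges.tsv")),
    ne = write_tsv(
      transform(fit$ne, ne_display = round(ne, 2),
                se_ne_display = round(se_ne, 2)), f("ne.tsv")))
  if (!is.null(fit$nj)) {
    nj_disp <- fit$nj
    # display convention: mask supports at or below 50%
    if (!is.null(nj_disp$node.label))
      nj_disp$node.label[!is.na(nj_disp$node.label) &
                           nj_disp$node.label <= 50] <- ""
    ape::write.tree(fit$nj, f("nj.nwk"))
    ape::write.tree(nj_disp, f("nj_display.nwk"))
    paths <- c(paths, nj = f("nj.nwk"), nj_display = f("nj_display.nwk"))
  }
  if (!is.null(fit$upgma)) {
    ape::write.tree(fit$upgma, f("upgma.nwk"))
    paths <- c(paths, upgma = f("upgma.nwk"))
  }
  if (!is.null(fit$pca)) {
    paths <- c(paths,
      pca_scores = write_tsv(
        data.frame(hap_id = rownames(fit$pca$scores), fit$pca$scores),
        f("pca_scores.tsv")),
      pca_variance = write_tsv(
        data.frame(component = seq_along(fit$pca$explained_variance_ratio),
                   explained_variance_ratio =
                     fit$pca$explained_variance_ratio),
        f("pca_variance.tsv")))
  }
  all_div <- fit$diversity[fit$diversity$group == "All", ]
  summary <- list(
    files = as.list(stats::setNames(basename(paths), names(paths))),
    params = fit$params[c("n", "L", "mu", "B", "n_perms", "seed",
                          "epsilon_ties", "use_sample_size")],
    groups = as.list(fit$params$groups),
    headline = list(
      n_haplotypes = length(fit$haplotypes$hap_id),
      modal_haplotype = fit$haplotypes$hap_id[1L],
      modal_count = unname(fit$haplotypes$total[1L]),
      hap_div_all = all_div$hap_div,
      pi_all = all_div$pi,
      amova_pct_among = fit$amova$pct_among,
      amova_pct_within = fit$amova$pct_within,
      fst = fit$amova$fst,
      fst_p = fit$amova$p_value,
      pairwise_fst = as.data.frame(fit$pairwise_fst),
      ne = fit$ne[, c("group", "ne", "se_ne", "below_1000")]))
  json <- f("summary.json")
  jsonlite::write_json(summary, json, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  paths <- c(paths, summary = json)
  invisible(paths)
}

#' Validate a run configuration
#'
#' Reads a YAML file (or takes a list) of pipeline parameters, applies
#' defaults, and rejects unknown keys and out-of-range values. Known keys:
#' `alignment`, `popmap`, `out_dir`, `mu`, `bootstrap`, `permutations`,
#' `seed`, `epsilon_ties`, `use_sample_size`, `simulate` (a [sim_config()]
#' parameter list used when no alignment is given).
#'
#' @param config path to a YAML file, or a named list (possibly empty).
#' @return A validated list of class `run_config` with all defaults
#'   filled in.
#' @export
validate_config <- function(config = list()) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  if (is.null(config)) config <- list()
  stopifnot(is.list(config))
  defaults <- list(alignment = NULL, popmap = NULL, out_dir = ".",
                   mu = 3.11e-8, bootstrap = 1000, permutations = 10000,
                   seed = 1, epsilon_ties = FALSE,
                   use_sample_size = FALSE, simulate = NULL)
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  cfg <- utils::modifyList(defaults, config)
  for (key in c("mu", "bootstrap", "permutations"))
    if (!is.numeric(cfg[[key]]) || length(cfg[[key]]) != 1L ||
        cfg[[key]] <= 0)
      stop("config key '", key, "' must be a positive number",
           call. = FALSE)
  if (cfg$permutations < 100)
    warning("permutations = ", cfg$permutations,
            " gives low-resolution p-values; consider >= 1000")
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "run_config")
}

#' Run the full pipeline from a configuration
#'
#' Orchestrates simulate-or-read, [popgen()] and
#' [write_popgen_outputs()]. When the configuration names an alignment
#' and popmap they are read; otherwise a synthetic dataset is generated
#' from the `simulate` sub-configuration (defaults apply) and also
#' written to the output directory (`alignment.fasta`, `popmap.tsv`,
#' `truth.json`). Any stage failure aborts the run and removes partial
#' outputs.
#'
#' @param config anything accepted by [validate_config()].
#' @return The `popgen` fit, invisibly, with the written paths in
#'   `attr(, "paths")`.
#' @export
run_pipeline <- function(config = list()) {
  cfg <- validate_config(config)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  on_fail <- function(stage) function(e) {
    unlink(written)
    stop("stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  }
  if (is.null(cfg$alignment)) {
    sim_args <- if (is.null(cfg$simulate)) list() else cfg$simulate
    if (is.null(sim_args$seed)) sim_args$seed <- cfg$seed
    sim <- tryCatch({
      sc <- do.call(sim_config, sim_args)
      generate_alignment(sc, mu = cfg$mu)
    }, error = on_fail("simulate"))
    aln <- sim$alignment; pops <- sim$popmap
    written <- c(written,
      write_alignment(aln, file.path(cfg$out_dir, "alignment.fasta")),
      write_tsv(data.frame(sample = names(pops), group = unname(pops)),
                file.path(cfg$out_dir, "popmap.tsv")))
    jsonlite::write_json(sim$truth[c("counts", "pooled_counts", "values",
                                     "mode", "seed")],
                         file.path(cfg$out_dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
    written <- c(written, file.path(cfg$out_dir, "truth.json"))
  } else {
    aln <- tryCatch(read_alignment(cfg$alignment), error = on_fail("read"))
    pops <- tryCatch(read_popmap(cfg$popmap, aln), error = on_fail("read"))
  }
  fit <- tryCatch(
    popgen(aln, pops, mu = cfg$mu, B = cfg$bootstrap,
           n_perms = cfg$permutations, seed = cfg$seed,
           epsilon_ties = cfg$epsilon_ties,
           use_sample_size = cfg$use_sample_size),
    error = on_fail("analysis"))
  paths <- tryCatch(write_popgen_outputs(fit, cfg$out_dir),
                    error = on_fail("write"))
  attr(fit, "paths") <- c(paths, written)
  invisible(fit)
}
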