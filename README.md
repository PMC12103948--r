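# haplodiv

Population-genetic analysis of aligned mitochondrial sequence fragments
sampled from several groups — the kind of dataset produced by sequencing
a cytochrome *b* (cyt*b*) fragment from river and hatchery populations
of a fish and asking how diversity is distributed within and among the
collection sites.

From one alignment plus a sample→group map, `haplodiv` computes:

* **Haplotypes and sites** — exact-identity haplotype collapsing with
  per-group counts, and classification of every alignment column as
  monomorphic, singleton or parsimony-informative under complete
  deletion.
* **Diversity** — Nei's unbiased haplotype diversity
  *h* = *n*/(*n*−1)·(1 − Σ*p*ᵢ²) and nucleotide diversity π (mean
  pairwise p-distance per site), with a site-bootstrap standard error
  for π.
* **Structure** — one-level distance AMOVA on squared pairwise
  difference counts (variance components *V*ₐ, *V*ᵦ, percentage
  partition, fixation index F\_ST = *V*ₐ/(*V*ₐ+*V*ᵦ)) and pairwise
  F\_ST, both with label-permutation p-values.
* **Network, trees, PCA** — a minimum-spanning haplotype network (with
  an option to retain co-minimal ties), a neighbor-joining haplotype
  tree with site-bootstrap supports, a UPGMA tree of the groups, and a
  PCA of the haplotype SNP indicator matrix.
* **Effective population size** — the coalescent chain
  θ = π·*L*/(*L*−1), *N*ₑ = θ/(4μ), SE(*N*ₑ) = SE(π)/(4μ), per group and
  pooled, flagged against the *N*ₑ = 1000 adaptability threshold.
* **Synthetic data** — a generator that emulates a four-group,
  616 bp, star-like eleven-haplotype design (exact or multinomial
  placement), so the whole pipeline runs and is testable with no
  external data.

## Worked example

```r
library(haplodiv)

sim <- generate_alignment(sim_config(seed = 42))   # 137 x 616 bp, 4 groups
fit <- popgen(sim$alignment, sim$popmap, seed = 42,
              B = 1000, n_perms = 1000)
fit
#> Population-genetic analysis: 137 sequences x 616 bp in 4 groups
#> Haplotypes: 11 (modal Hap1, 107/137 = 78%)
#> Overall haplotype diversity 0.386, nucleotide diversity 0.00117
#> AMOVA: 3.59% among / 96.41% within groups, FST = 0.0359 (p = 0.06093906)
```

The fit object holds every stage (`fit$haplotypes`, `fit$diversity`,
`fit$amova`, `fit$pairwise_fst`, `fit$network`, `fit$nj`, `fit$upgma`,
`fit$pca`, `fit$ne`). The Ne table for this run:

```r
fit$ne
#>    group   n      pi    se_pi      theta       mu       ne   se_ne below_1000
#>    Padma  40 0.00039 0.000275 0.00038983 3.11e-08  3133.66 2211.46      FALSE
#>   Jamuna  36 0.00063 0.000235 0.00063234 3.11e-08  5083.12 1887.13      FALSE
#>    Halda  32 0.00125 0.000722 0.00125230 3.11e-08 10066.68 5802.67      FALSE
#>  Culture  29 0.00254 0.000958 0.00253910 3.11e-08 20411.16 7703.37      FALSE
#>      All 137 0.00117 0.000422 0.00117430 3.11e-08  9439.76 3391.30      FALSE
```

Reading the output: 11 distinct haplotypes were found, the modal one
carried by 107/137 individuals (78%); most molecular variance lies
within groups; the Halda-like and Culture-like groups are the most
diverse and hence return the largest effective sizes, while the
Padma-like group (π ≈ 0.00039) sits lowest. `write_popgen_outputs(fit,
"out/")` writes the full TSV/newick/JSON artifact set, and
`plot(fit, type = "ne")` (or `"pca"`, `"network"`) draws the standard
figures.

A thin command-line wrapper with `simulate`, `analyze` and `all`
subcommands lives at `inst/cli/haplodiv.R`; `run_pipeline()` /
`validate_config()` expose the same orchestration from R, driven by an
optional YAML config.

## Methods

See the methods vignette (`vignettes/haplodiv-methods.Rmd`) for the
estimator definitions, parameter defaults and units, the numerical
tie-break and degenerate-input rules, what the synthetic generator does
and does not emulate, and known limitations.
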