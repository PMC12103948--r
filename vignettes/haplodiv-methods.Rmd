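---
title: "Methods: haplotype diversity, structure and effective population size"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: haplotype diversity, structure and effective population size}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(haplodiv)
```

`haplodiv` analyses an aligned fragment of a haploid, non-recombining
locus — the motivating case is a 616 bp mitochondrial cytochrome *b*
fragment sampled from several population groups of a freshwater fish —
and estimates within-group diversity, among-group structure and
coalescent effective population sizes. This vignette records the models,
the parameter choices, and the numerical decisions behind the
implementation.

## Data model

An alignment is a set of equal-length sequences over `{A, C, G, T, N, -}`,
keyed by unique sample ids, paired with a map from sample to group.
IUPAC ambiguity codes other than `N` are rejected outright: in a
haplotype analysis an unresolved base silently creates a spurious
haplotype, so a loud failure is preferable to a fold-in rule. All site
statistics use *complete deletion*: any column containing `N` or `-` in
at least one sequence is removed from the analysable site set and
counted separately, so site classification, nucleotide diversity and
pairwise distances all share one site universe and the `L` accounting
stays explicit.

## Haplotypes and site classification

Haplotypes are equivalence classes of exact string identity over all
sites. Ids `Hap1, Hap2, ...` are assigned by decreasing total count with
ties broken by first occurrence, so the modal haplotype is always
`Hap1`. A classified column is *monomorphic* (one base), a *singleton*
site (every minority base carried by exactly one sequence) or
*parsimony-informative* (at least two bases each carried by at least two
sequences); `singleton + parsimony = polymorphic` and
`monomorphic + polymorphic + excluded = L` hold by construction. Because
column patterns depend only on the weighted haplotype set, classifying
the haplotype sequences with their counts as multiplicities equals
classifying the raw alignment — a property the test suite checks on
random instances. In a group with a single sequence every site is
monomorphic by convention (the singleton definition degenerates).

## Diversity

Haplotype (gene) diversity uses Nei's unbiased estimator
$h = \frac{n}{n-1}\left(1 - \sum_i p_i^2\right)$ with $p_i = c_i/n$.
Nucleotide diversity is the plain mean pairwise p-distance per
analysable site,
$\pi = \binom{n}{2}^{-1} \sum_{i<j} d_{ij} / L_\mathrm{eff}$,
with **no** small-sample factor: the $L/(L-1)$-type correction of the
coalescent estimator chain is applied once, in the theta step, never in
$\pi$ itself, so the two stages stay separable and their composition
matches the standard printed arithmetic of this estimator chain.

The standard error of $\pi$ comes from a site bootstrap: the
$L_\mathrm{eff}$ columns are resampled with replacement $B$ times
(default $B = 1000$), $\pi$ is recomputed per replicate from the
per-site pair-mismatch contributions, and the sample standard deviation
(denominator $B-1$) over replicates is reported. For a single variable
column the bootstrap converges on the closed-form standard deviation of
a resampled site mean, which the tests verify against an exact
enumeration.

## AMOVA and pairwise FST

Structure is assessed by one-level distance AMOVA on squared pairwise
difference counts $d_{ij}^2$:

$$SSD_\mathrm{total} = \frac{1}{N}\sum_{i<j} d_{ij}^2, \qquad
  SSD_\mathrm{within} = \sum_g \frac{1}{n_g}\sum_{i<j \in g} d_{ij}^2,$$

with $SSD_\mathrm{among}$ their difference, mean squares on $G-1$ and
$N-G$ degrees of freedom, the average group size
$n' = (N - \sum_g n_g^2/N)/(G-1)$, variance components
$V_b = MS_\mathrm{within}$ and $V_a = (MS_\mathrm{among} -
MS_\mathrm{within})/n'$, and fixation index
$F_{ST} = V_a/(V_a+V_b)$. $V_a$ can legitimately be negative in small or
unbalanced samples; it is reported raw, and only the display percentage
floors it at zero (both values are emitted). Significance comes from
permuting group labels over individuals, with the add-one estimate
$p = (1 + \#\{F_{ST}^* \ge F_{ST}\})/(B_p + 1)$ so $p$ is never zero;
the default is $B_p = 10{,}000$ permutations, which stabilises small
p-values at desk-time cost. Pairwise $F_{ST}$ runs the same two-group
machinery per pair with permutations restricted to that pair; negative
values are reported as computed and flagged, and stars mark $p<0.05$ and
$p<0.01$ in the written table. When every sequence is identical both
components are zero and $F_{ST}$ is reported as `NaN` with a warning
rather than silently coerced.

## Network, trees and PCA

The haplotype network is a minimum-spanning tree (Kruskal) over the
haplotype Hamming graph, with equal-weight ties broken by the smaller
index pair for determinism. With `epsilon_ties = TRUE`, every edge that
joins two components still separate at the start of its weight level is
retained, producing reticulations exactly where equally short
alternative connections exist.

The haplotype tree is Saitou–Nei neighbor joining (via `ape`). On
non-additive inputs NJ can emit negative branch lengths; these are
clamped to zero with the deficit moved to the sister branch, preserving
path lengths through the parent node. Bootstrap supports resample sites
with replacement, rebuild the NJ tree per replicate and report the
percentage of replicates containing each internal bipartition; the
stored tree always carries the full values, and only the display newick
masks supports at or below 50%. The group-level tree is UPGMA
(average-linkage `hclust`) on the pairwise $F_{ST}$ matrix, floored at
zero since $F_{ST}$ is used as a dissimilarity; the output is
ultrametric by construction.

The haplotype PCA encodes each polymorphic site as one 0/1 indicator
column per non-major allele, column-centres, and eigendecomposes the
covariance — one unweighted row per haplotype. Axis signs are fixed by
forcing the largest-magnitude loading of each component positive so
score plots are reproducible. Under the clean star-shaped default
simulation the first two components carry roughly half of the SNP
variance; real data with site reuse (homoplasy) concentrate more
variance in the leading plane, so the share observed on synthetic data
is not a prediction for real alignments.

## Effective population size

The coalescent chain is
$\theta = \pi \cdot L/(L-1)$, $N_e = \theta/(4\mu)$ and
$SE(N_e) = SE(\pi)/(4\mu)$, with $L$ the fragment length in bp. Using
the *sequence length* in the theta correction is unconventional (the
classical factor uses the number of sampled sequences) but is the
definition this estimator chain is specified with, and for
$L = 616$ the factor is within 0.2% of unity, so the choice is nearly
immaterial at this locus; a `use_sample_size` switch provides the
classical form, off by default. The default mutation rate
$\mu = 3.11 \times 10^{-8}$ per site is a literature cytochrome-*b* rate
for fishes; its time unit is not resolved here and is carried opaquely
into $N_e$. Groups with $N_e < 1000$ individuals are flagged against the
widely cited minimum effective size for retaining adaptive potential.

## What the synthetic generator emulates — and what it does not

The generator reproduces the sampling design the analysis assumes: four
groups of 40/36/32/29 individuals, a 616 bp fragment, eleven haplotypes
on a star-shaped substitution graph (a dominant hub carried by 107 of
137 individuals, most haplotypes one substitution from the hub, one at
two steps with a further one-step descendant, one at four steps), with
group-private and group-shared haplotypes. The default per-group counts
were fixed once, jointly constrained by the hub total (107), the
modal-haplotype share per group, the singleton/parsimony footprint of
each group, and the overall minor-haplotype shares; they are an
illustrative reconstruction, not observed data. Substitutions are placed
at fresh positions (infinite sites), so configured step counts equal
realized Hamming distances and the haplotype distance matrix is additive
on the graph — which is what makes exact parameter recovery testable.

Exact mode places the configured counts verbatim and is the pipeline's
zero-noise fixed point: diversity, counts and $N_e$ come back with zero
error. Multinomial mode draws counts from configured probabilities and
supports the statistical property tests (unbiasedness of $\hat h$ and
$\hat\pi$, error shrinking with sample size, null calibration of
permutation p-values).

The generator deliberately does **not** emulate: homoplasy or site
reuse (real data can show fewer polymorphic sites than total
substitutions), sequencing error or missing data, within-group
genealogy (no coalescent simulation, migration or growth), or length
variation. Passing tests therefore validate the estimators and their
composition, not the biological realism of any particular dataset.

## Numerical and design choices

* **Repository shape.** The package is organised around one analysis
  entry point, `popgen()`, returning a classed S3 fit with `print`,
  `summary` and `plot` methods, with every stage also exported as a
  composable function; internals are base R plus `ape` for tree and
  FASTA handling.
* **Seeding.** Every stochastic stage takes an explicit seed; `popgen()`
  spawns independent per-stage sub-seeds from one master seed, so stages
  can be rerun in isolation and the full fit is byte-reproducible. RNG
  state is always restored after use.
* **Tie-breaks.** MST edges sort by (weight, smaller index pair); NJ
  Q-ties and UPGMA merge ties follow the deterministic orderings of
  `ape::nj` and `hclust`.
* **Display rounding** is centralised in the writers (h to 3 dp, π to
  5 dp, FST to 5 dp, Ne to 2 dp); full-precision columns are always
  written alongside.
* **Degenerate inputs** fail loudly: ragged or mis-alphabet FASTA,
  uncovered or duplicated popmap rows, monomorphic PCA input, `n < 2`
  diversity calls. Monomorphic AMOVA yields `NaN` FST with a warning.
* **Validation problem sizes.** The suite exercises the default
  137 × 616 design end to end; brute-force oracle comparisons use 100
  random AMOVA instances at $N \le 8$, NJ recovery on random additive
  trees with up to 8 taxa, exhaustive spanning-tree enumeration up to 6
  haplotypes, 200-replicate parameter recovery at group-size scales
  ×1/×4/×10, and 200 label-shuffled null datasets at 1000 permutations
  each for the uniformity of permutation p-values. These sizes were
  chosen to make the oracles exact or near-exact while keeping the suite
  quick to run.

## Known limitations

Site classification and distances ignore columns with any missing data,
which is conservative but can discard information in gappy alignments.
The AMOVA is strictly one level (no region/group nesting) and uses raw
difference counts (no substitution-model correction), matching the
p-distance convention of the rest of the pipeline. The NJ tree replaces
likelihood-based inference; the minimum-spanning network is not a
median-joining network (no inferred median vectors). $N_e$ inherits the
unresolved time units of $\mu$ and rests on equilibrium assumptions that
short mtDNA fragments test only weakly; its standard error reflects
site-resampling uncertainty in $\pi$ only.
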