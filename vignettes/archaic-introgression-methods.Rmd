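---
title: "Methods: testing archaic introgression against incomplete lineage sorting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: testing archaic introgression against incomplete lineage sorting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(archintro)
```

## The inference problem

A haplotype segregating in a modern population can resemble archaic
genomes for two reasons: it entered recently by admixture
(introgression), or both lineages retained the same ancestral
polymorphism since their split (incomplete lineage sorting, ILS). The
two hypotheses make sharply different predictions about *length*.
Recombination whittles ancestral segments down over the whole time since
the common ancestor, whereas an introgressed tract has only been exposed
to recombination since admixture — a few thousand generations rather
than tens of thousands. `archintro` implements the length-based test and
its supporting evidence.

## The ILS survival model

Around any focal site, the distance (in Morgans) to the first
recombination that disrupts the shared ancestral segment is, in each
direction, approximately Exponential with rate equal to the total branch
length $G$ (in generations) separating the two lineages — each
generation on either branch is an independent opportunity for crossover
per Morgan. The two sides being independent, the total retained length
is Gamma(shape $2$, rate $G$), with survival function

$$P(L \ge m) = (1 + G\,m)\,e^{-G\,m}, \qquad E[L] = 2/G .$$

`ils_probability(m_cM, branch_human_gens, branch_archaic_gens)` takes
the genetic length in cM (1 Morgan = 100 cM, fixed) and the two branch
lengths, and reports $G$, the expected length and the probability.

Decisions made here:

* **$G$ is the sum of the two branch inputs** (defaults 21,500 and
  19,500 generations, so $G = 41{,}000$). The function takes branches
  rather than a pre-summed total so the provenance of $G$ is always
  explicit in the call.
* **Shape-2 (two-sided) survival is the default** because a haplotype
  block extends in both directions from its defining variants;
  `sides = 1` exposes the one-sided survival $e^{-Gm}$ for sensitivity
  analysis. The tests pin the implementation to the independent oracle
  `pgamma(m, shape = 2, rate = G, lower.tail = FALSE)` at $10^{-12}$
  relative tolerance.
* `fragment_percentile()` ranks a query length among genome-wide
  introgressed fragment lengths with ties counted *below* (strictly
  shorter fragments), documented rather than configurable.

## LD block calling

The block around a focal proxy SNP is delimited by the *last* upstream
and downstream variants whose haplotypic $r^2$ with the proxy strictly
exceeds the threshold (default 0.8). We read "last" as the outermost
qualifying variant within a finite search window (default 1 Mb each
side), tolerating internal dips below the threshold: boundary variants
in real data are routinely non-adjacent in $r^2$ rank, and LD-proxy
style tools list all window variants. Consequences:

* raising the threshold can only shrink the block (tested property);
* if no variant qualifies on a side, that boundary is the focal site
  itself and a zero-span block is returned rather than an error;
* $r^2$ is the squared Pearson correlation of phased allele indicators
  (haplotypic, not genotypic composite — the panel is phased); a
  monomorphic column has no defined $r^2$ and yields `NA`, which can
  never qualify as a boundary. The test suite checks $r^2$ against an
  independent LD-coefficient oracle $D^2/(p_A q_A p_B q_B)$.

Genetic length converts the boundary coordinates through a cumulative-cM
map by linear interpolation (`block_genetic_length()`). Extrapolation
beyond the map anchors is refused: a map that does not cover the block
is a data problem, not something to paper over.

## Site filtering and archaic representation

`filter_sites()` applies, in one idempotent pass: accessibility mask;
multiallelic removal (multiallelic records are *retained and flagged* at
read time so the filter is observable); strict missing-data removal
(any individual); segregating-in-the-merged-panel; and optional removal
of sites heterozygous in any archaic. Archaic genomes are unphased, so
each is stored as two genotype rows; once archaic-het sites are gone the
rows are identical and `collapse_archaics()` keeps a single
pseudo-haplotype per genome — one representative chromosome per archaic.
Half-called archaic genotypes are treated as missing (the conservative
reading; they are indistinguishable from no-calls for our purposes).

Rooting uses the inferred ancestral sequence: sites with unknown
ancestral state cannot be polarised and are dropped before the ancestral
row is appended (`add_ancestral_haplotype()`).

## Distance trees

Maximum-likelihood tree search is deliberately replaced by neighbor
joining on pairwise-difference (Hamming) distances, reported per
retained site (the "mutations per site" scale). At the scale this
analysis operates — tens of segregating sites, shallow divergence, and a
claim that is about *clustering*, not fine topology — distance and ML
topologies coincide, and NJ is exactly reproducible and testable against
closed forms: the suite requires exact recovery of additive four-taxon
matrices and the three-point solution for three taxa. Negative NJ branch
lengths are clamped to zero. Bootstrap support resamples *sites* with
replacement, rebuilds the distance matrix and the NJ tree, and counts
bipartitions (`nj_tree()`) or the monophyly of a chosen taxon set
(`clade_support()`); both are seed-deterministic. Identical haplotypes
are deduplicated first (`dedup_haplotypes()`, first occurrence kept,
multiplicities reported) — support values are about distinct sequences,
not sample counts.

## Tajima's D

`tajimas_d()` implements the classical statistic
$D = (\pi - S/a_1)/\sqrt{e_1 S + e_2 S(S-1)}$ with constants computed
from the haplotype count; $\pi$ uses the site-frequency form
$\sum_j 2 p_j(1-p_j)\,n/(n-1)$, which the tests verify equals the mean
pairwise Hamming distance. $D$ is flagged undefined (`NA`) when $S = 0$
or $n < 4$ rather than reported as 0.

The sliding scan (`sliding_tajima()`) uses physical 10-kb windows
advanced by a step, and reports at each step position the *average of D
over all windows covering that position*, excluding undefined windows —
the only reading under which per-step averaging of overlapping windows
is meaningful. The literal step is 1 bp; the desk-scale default is
100 bp, and the suite checks the two agree closely on a small region
(the coarse track is an approximation, not an alias). A site-count
stepping mode is available behind `by = "sites"` since the unit of
"steps of 1" is ambiguous in common usage; bp is the default.

## Enzyme kinetics

Two velocity models: Michaelis–Menten $v = V_{max}S/(K_m+S)$ and
substrate inhibition $v = V_{max}S/(K_m + S(1+S/K_i))$, which peaks at
$S^\ast = \sqrt{K_m K_i}$. `global_fit()` minimises the unweighted
residual sum of squares jointly across datasets (no weighting is
assumed; a heteroscedastic scheme would need replicate-level variance
estimates the typical 3-replicate design cannot support). Km is
`shared` (one value across enzyme variants — the stabilising assumption
under which $V_{max}$ comparisons are made), `fixed` at a supplied
value, or `free` per dataset; Ki is shared except under `free`.

Numerics: parameters are optimised on the log scale (positivity without
constraints), Nelder–Mead to locate the basin then a BFGS polish;
starting values are $V_{max,0} = \max v$, $K_{m,0} = S$ at half-max,
$K_{i,0} = \max S$. Asymptotic 95% CIs use
$\mathrm{cov} = s^2 (J^\top J)^{-1}$ with the numeric residual Jacobian
at the optimum and a $t$ quantile on $N - p$ degrees of freedom. The
choice between the two models "by best fit" is operationalised as an
extra-sum-of-squares F-test at $\alpha = 0.05$ (`select_model()`) —
an interpretation, stated as such. A 200-replicate study in the
acceptance suite confirms ≥90% CI coverage of each true $V_{max}$ at 5%
noise.

## What the synthetic generator emulates — and what it does not

`simulate_panel()` is a mosaic mutation-drop model, not a coalescent:

* **Modern background**: independent sites with derived counts drawn
  from the neutral site-frequency spectrum $P(i) \propto 1/i$. This
  preserves $E[\pi] = E[S]/a_1$ *exactly* (for any $S$,
  $E[D \mid S] = 0$), which is what makes the neutral-mode Tajima
  acceptance test well-posed. Default density 0.8 segregating sites/kb,
  a realistic panel-scale SNV density for a human cohort.
* **Archaic genomes** share a pool of private derived alleles at
  `divergence_scale` × the modern density (default 1.0 ≈ 0.8/kb —
  the order of archaic-lineage-specific divergence), plus per-genome
  private hom-derived sites (0.05/kb) that let the *source* archaic be
  identified, plus heterozygous sites (0.05/kb) that exercise the
  archaic-het filter.
* **The tract**: one shared interval centred in the region, per-side
  length Exponential(mean $100/g$ cM) with $g = 2000$ generations —
  the same clock the ILS module assumes, giving an internal consistency
  check. Carriers (default 5% of 100 haplotypes) copy the source
  archaic inside the tract and are ordinary moderns outside. Default
  region 1 Mb at 1 cM/Mb keeps edge truncation of the tract negligible
  ($P < 10^{-4}$ per side).

Not emulated: background LD and its decay (non-tract sites are
independent), population structure and varying carrier tract ends
(all carriers share one tract — as after a recent common carrier
ancestor), gene conversion, sequencing and phasing error, and
coalescent variance in archaic divergence. A green end-to-end test
therefore establishes that the *pipeline logic* recovers a planted
signal of realistic magnitude under the model's own clock — not that
the method is robust to every artefact of real panels.

All generators draw from a single RNG seeded per call and restore the
caller's RNG state; identical seeds give bit-identical output, which the
pipeline inherits (byte-identical `report.json` for identical config).

## Degenerate inputs and tie-breaking

* `r_squared()` on a monomorphic column: `NA`, signalled, never 0.
* Allele-sharing group majorities are strict; a 50/50 tie is emitted as
  its own category (`tie_A`/`tie_B`) with `NA` sharing flags.
* `nearest_archaic()` reports exact ties as a set.
* Boundary ties at equal distance resolve to the more distal variant
  (conservative: never shortens the block the ILS test evaluates).
* `fragment_percentile` on an empty list, negative lengths, decreasing
  genetic maps, unphased modern genotypes: errors, not coercions.

## Known limitations

* The ILS test assumes a single representative haplotype length and a
  locally constant recombination rate between map anchors.
* NJ support values are for the deduplicated haplotype set; highly
  recombined panels can make the carrier clade non-monophyletic even
  when introgression is real.
* The kinetics CIs are asymptotic; at very low noise or few
  concentrations, profile-likelihood intervals would be preferable.
* The CLI is a thin dispatcher over the R API and intentionally has no
  workflow-manager integration.
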