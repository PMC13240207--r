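# archintro

Tools for deciding whether a deeply divergent haplotype segregating in a
modern human population was introduced by archaic (Neanderthal/Denisovan)
admixture, or merely persisted by incomplete lineage sorting (ILS) — plus
the enzyme-kinetics fitting needed to compare the protein variants such a
haplotype carries.

The package is aimed at population geneticists who have a phased panel VCF,
an archaic all-sites VCF, an accessibility mask and a recombination map,
and want the standard chain of evidence in one tested toolbox:

1. **LD haplotype block.** Around a focal proxy SNP, the block runs from
   the last upstream to the last downstream variant with haplotypic
   r² > 0.8 (`call_block()`); its genetic length comes from linear
   interpolation of a cumulative-cM map (`block_genetic_length()`).
2. **ILS survival test.** Under the recombination clock, the ancestral
   segment retained around a site after a total branch length of *G*
   generations is Gamma(shape 2, rate *G*) in Morgans, so

       P(L ≥ m) = (1 + G·m)·exp(−G·m)

   (`ils_probability()`). A block too long for this probability to be
   appreciable must have entered by gene flow. `fragment_percentile()`
   ranks the block among genome-wide introgressed fragment lengths.
3. **Archaic affinity.** Pairwise-difference (Hamming) distances,
   per-site allele-sharing tracks, nearest-archaic assignment and a
   neighbor-joining tree rooted on the inferred ancestral sequence with a
   site-resampling bootstrap (`distance_matrix()`, `allele_sharing_track()`,
   `nearest_archaic()`, `nj_tree()`).
4. **Neutrality scan.** Tajima's D in 10-kb sliding windows with per-step
   averaging (`tajimas_d()`, `sliding_tajima()`).
5. **Kinetics.** Michaelis–Menten and substrate-inhibition
   (v = Vmax·S/(Km + S·(1+S/Ki))) dose-response fitting, globally across
   enzyme variants with a shared or fixed Km and asymptotic 95% CIs on
   Vmax (`global_fit()`), standard-curve conversion
   (`rfu_to_concentration()`) and `percent_change()` arithmetic.

Everything is exercisable offline: `simulate_panel()` generates a phased
panel with a planted introgressed tract (per-side tract length
Exponential(100/g cM), g generations after admixture), three archaic
pseudo-genomes, a recombination map, a mask and ground truth;
`simulate_fragments()` and `simulate_kinetic_dataset()` cover the other
inputs. `run_pipeline()` chains the whole analysis deterministically from
a seed.

## Worked example

The headline calculation needs no data files. A block bounded at
chr8:18218773 and chr8:18307287, with modern-human and archaic branch
lengths of 21,500 and 19,500 generations and a genetic length of 0.018 cM:

```r
library(archintro)
block_span(18218773, 18307287)   # 88514
format_kb(88514)                 # "89 kb"
print(ils_probability(0.018))
#> <ils_result> m = 0.018 cM, G = 21500 + 19500 = 41000 generations
#>   expected shared length 0.004878 cM; P(L >= m) = 0.00523
```

P ≈ 5.2 × 10⁻³: a shared segment of that genetic length is very unlikely
to have survived unbroken since the archaic/modern divergence, so the
haplotype is better explained by introgression. At the longer map estimate
of 0.0731 cM the probability drops to 2.98 × 10⁻¹².

End-to-end on synthetic data (seed-deterministic; ~2 s):

```r
rep <- run_pipeline(sim_config(seed = 1), bootstrap = 50)
rep$truth[c("tract_start", "tract_end")]    # planted: 381565 529230
rep$block[c("upstream", "downstream", "span")]
#> $upstream   382150
#> $downstream 527327
#> $span       "145 kb"
rep$block$genetic_length_cM                 # 0.145177
rep$ils$probability                         # 8.542671e-25
rep$fragment_percentile                     # 0.768
rep$affinity$nearest[[1]]                   # $label "arch1"; $count 0
rep$affinity$carrier_archaic_clade_support  # 1
```

The called block recovers the planted tract to within the nearest
informative sites; every carrier haplotype is closest to the source
archaic; the carrier + archaic clade has full bootstrap support; and the
planted block's ILS survival probability is vanishingly small — the same
inference chain as on real data.

A command-line front end with subcommands (`simulate`, `filter`, `block`,
`ils`, `fragrank`, `tree`, `share`, `tajima`, `kinfit`, `run`) is installed
as `exec/archintro`; `archintro --help` lists every default.

## Documentation

The methods vignette (`vignettes/archaic-introgression-methods.Rmd`)
describes the models, parameter choices, what the synthetic generator does
and does not emulate, and numerical decisions.
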