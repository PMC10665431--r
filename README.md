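# auxotrophr

Genome-based inference of amino acid auxotrophy in bacteria.

Many bacteria have lost the ability to synthesize one or more amino acids
and must acquire them from their environment or from neighbouring cells.
`auxotrophr` is for microbial ecologists and comparative genomicists who
want to (i) call such auxotrophies from genome annotations, (ii) quantify
how reliable those calls are against experimentally known phenotypes, (iii)
map the prevalence of auxotrophy across habitats from 16S rRNA amplicon
surveys, and (iv) relate auxotrophy to genome size, biosynthetic cost and
functional gene content — the signature of genome streamlining.

## The model

For each of 17 amino acids plus chorismate (the aromatic precursor;
alanine, aspartate and glutamate are excluded because they arise by
transamination), a biosynthesis pathway is one or more alternative routes,
each an ordered set of enzymatic steps. From protein-hit evidence a step is
*present* when it has at least one **medium-confidence candidate**:

- identity ≥ 40% and coverage ≥ 70% against a characterized pathway
  protein, **or** identity ≥ 30% and coverage ≥ 80%;
- and, when the protein also aligns to characterized proteins with other
  functions, `bits_pathway > bits_other` (strictly).

A compound is scored by its most complete route. With `m` of `t` steps
missing, the genome is called **auxotrophic** for the compound when

```
m / t  >=  threshold / 100        (threshold = 40 by default)
```

evaluated in exact integer arithmetic (`100 m >= threshold * t`), so a
pathway missing exactly 40% of its genes is always called. The 40% default
is the operating point at which the false-positive rate against genomes
known to grow on minimal media drops to a few per mille while sensitivity
to known auxotrophies is retained; `threshold_sweep()` re-derives it from
any labeled panel.

Habitat mapping matches each amplicon sequence variant (ASV) to reference
16S rRNA genes by gap-free sliding-window Hamming distance, allowing one
substitution (99.6% identity over 250 bp). ASVs need more than 10 reads and
at least 10% sample occupancy to be retained; habitat summaries
(% prototrophs, mean auxotrophies per taxon, share of single-compound
auxotrophs, read coverage) are computed over the deduplicated set of
matched genomes. Genomic correlates use Pearson correlations (genome size,
completeness, P-bond biosynthetic cost), Welch t-tests (isolate vs
assembled genomes) and per-COG-category Mann-Whitney U tests with
Bonferroni correction, reported as log2-fold ratios between the strict
auxotroph class (≥ 2 auxotrophies) and prototrophs (0).

A seeded synthetic-data generator (`simulate_study()`) produces pathway
databases, per-genome hit evidence with planted knockouts, genome metadata,
COG profiles with planted enrichment, and habitat ASV tables with planted
auxotroph prevalence, so the whole pipeline is testable end to end with
known ground truth.

## Worked example

```r
library(auxotrophr)

cfg <- sim_config(seed = 7, n_genomes = 200,
                  habitat_specs = list(habitat_spec("gut_like", 30, 120, 0.55)))
sim <- simulate_study(cfg)

profiles <- profile_genomes(sim$evidence, sim$pathways,
                            genome_ids = sim$records$genome_id)
profiles
#> Auxotrophy profiles: 200 genome(s) x 18 compounds at threshold 40 %
#>   auxotrophic calls: 182 of 3600 genome-compound pairs

fp <- false_positive_rate(profiles, sim$labels)
fn <- false_negative_rate(profiles, sim$labels)
cat(sprintf("FP rate: %.3f%%   FN rate: %.3f%%\n",
            100 * fp$overall, 100 * fn$overall))
#> FP rate: 0.000%   FN rate: 0.000%

filt    <- filter_asvs(sim$asv$tables[["gut_like"]])
matches <- match_asvs(filt$table$asv_seqs, sim$asv$references)
summarize_habitat(filt$table, matches, profiles)
#>   pct_asvs_with_genomes pct_prototrophs mean_n_auxotrophies pct_single_auxotrophy
#> 1                  93.3            45.5                 0.8                  62.3

ct <- correlate(sim$records$genome_size, profiles$genomes$n_auxotrophies)
cat(sprintf("r(genome size, auxotrophies) = %.2f (p = %.2g, n = %d)\n",
            ct$r, ct$p, ct$n))
#> r(genome size, auxotrophies) = -0.44 (p = 5e-11, n = 200)
```

On this clean synthetic panel every planted knockout is recovered (FP = FN
= 0), the habitat summary recovers the planted 55% auxotroph prevalence
(45.5% prototrophs among matched taxa), and the planted negative
association between genome size and auxotrophy count comes back at
r = −0.44.

A command-line wrapper over the same functions is installed at
`inst/scripts/auxotrophr-cli` with subcommands `simulate`, `profile`,
`calibrate`, `habitat` and `correlates`; see `?aux_cli`.

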