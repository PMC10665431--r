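---
title: "Inferring amino acid auxotrophy from genomes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring amino acid auxotrophy from genomes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(auxotrophr)
```

`auxotrophr` infers which amino acids a bacterial genome cannot synthesize,
calibrates how much to trust those calls, maps auxotrophy prevalence across
habitats from 16S rRNA amplicon data, and relates auxotrophy to genomic
correlates of streamlining. This vignette explains the model, its
assumptions, the tunable parameters, the synthetic-data generator used for
testing, and the design decisions taken where the problem was genuinely
open.

## The calling model

Biosynthesis of each of 17 amino acids and chorismate is represented as a
`pathway_definition()`: one or more alternative routes, each an ordered set
of enzymatic steps. Alanine, aspartate and glutamate are excluded because
they can be produced by transamination of central-metabolism
intermediates, and transaminase substrate annotation is unreliable; calling
absence of their pathways would mostly measure annotation noise.

Evidence arrives as one row per candidate protein hit per step
(`identity`, `coverage`, `bits_pathway`, `bits_other`). A hit is a valid
medium-confidence candidate (`evaluate_candidate()`) when it satisfies
either identity ≥ 40% and coverage ≥ 70%, or identity ≥ 30% and coverage
≥ 80%, and in both cases out-scores any alignment to characterized
proteins of other function (`bits_pathway > bits_other`, strictly; an
absent competing alignment imposes no constraint). All boundaries are
inclusive because the thresholds are stated as "at least". Only this
medium-confidence tier is modeled: the calling rule needs a present/absent
decision per step, not a confidence ladder.

A step is present when at least one hit passes; a step with no evidence
rows at all is absent — absence of evidence is the annotation tool's
absent state, and the calibration explicitly measures the cost of that
convention on incomplete genomes.

### Scoring over alternative routes

Where a compound has alternative routes, `pathway_missing_fraction()`
scores the genome by the route minimizing the missing fraction `m/t` (ties
broken towards the shorter route, then towards the first listed). This is
the conservative reading: a genome is only called auxotrophic when even
its most complete route is badly broken, which minimizes false auxotrophy
calls, consistent with the calibration goal below. The alternative —
pooling the union of route genes — would punish genomes for lacking routes
they never needed. Route comparison uses integer cross-multiplication
(`m1 * t2` vs `m2 * t1`), never floating-point fractions.

### The threshold, in exact arithmetic

`call_compound_auxotrophy(m, t, threshold)` returns `100 * m >= threshold
* t`. The default threshold of 40% is the calibrated operating point: on
validation panels of genomes known to synthesize everything, lower
thresholds inflate the false-positive rate (incomplete assemblies lose the
odd gene), while 40% holds false positives at the per-mille level at an
acceptable false-negative cost. Because a missing fraction of exactly 2/5
must be called auxotrophic ("at least 40%"), the comparison is integer,
immune to floating-point drift; the test suite verifies agreement with the
real-valued comparison over every fraction with denominator ≤ 50.

### Genome inclusion filters

`filter_genomes()` applies, in order: completeness strictly greater than
95% (a genome at exactly 95.0 is rejected), no chimerism signal, and — for
metagenome-assembled and single-cell genomes only — presence of an
assembled 16S rRNA gene, required downstream for ASV matching. Isolate
genomes without an annotated 16S are kept, since the 16S requirement
exists to serve habitat mapping of MAGs/SAGs, whose missing 16S usually
reflects assembly gaps. Counts removed per rule are reported so the
filtering is auditable.

## Calibration

Validation labels are genome × compound pairs with a known
can/cannot-synthesize phenotype. Three operating characteristics are
computed:

- `false_positive_rate()` pools all labeled synthesizable pairs (the rate
  is per erroneous prediction); a per-compound breakdown and per-genome
  mean are also returned, since the pooled and per-genome denominators are
  both defensible and differ on unbalanced panels.
- `false_negative_rate()` is the unweighted mean over genomes of the
  proportion of each genome's known auxotrophies that were missed,
  matching the per-genome phrasing of the quantity.
- `genome_level_accuracy()` asks the coarser question — is the genome
  auxotrophic for at least one compound? — which is robust to the model's
  tendency to under-count auxotrophies per genome.

`threshold_sweep()` recomputes profiles over a threshold grid and selects
the smallest threshold whose FP rate meets the target (default 0.004).
Smallest-qualifying is this package's policy: among thresholds satisfying
the FP constraint it maximizes sensitivity. FP is non-increasing and FN
non-decreasing in the threshold on fixed evidence, so the selection is
well-defined; a sweep in which no grid point qualifies returns an explicit
none-selected flag rather than an arbitrary choice.

## Habitat mapping

`match_asvs()` slides each ASV gap-free along every reference 16S sequence
and accepts references containing a window within `max_mismatch = 1`
substitutions — 99.6% identity for 250 bp fragments
(`mismatch_identity_pct(250, 1)`). Design choices:

- Substitution-only (Hamming) matching: at amplicon scale a 1-mismatch
  criterion is substitution semantics; indel-tolerant alignment would
  silently loosen it.
- IUPAC ambiguity codes in references match when the code covers the ASV
  base, so reference Ns are not penalized; ASVs themselves must be
  unambiguous A/C/G/T, as denoised amplicon variants are.
- Ties between equally close genomes are broken deterministically
  (lexicographically smallest genome id) and flagged `ambiguous`, making
  runs reproducible while preserving the information that the assignment
  was not unique.

`filter_asvs()` retains ASVs with strictly more than 10 reads per habitat
occurring in at least 10% of samples ("occurred in" is read as presence,
count > 0, not a per-sample read threshold). `summarize_habitat()` computes
trait metrics over the *deduplicated* matched genomes, so a taxon whose
reads split across several ASVs matching the same genome counts once;
abundance-weighted auxotroph coverage is reported alongside, since
taxon-level and read-weighted prevalence answer different questions.
`compare_habitats()` runs all pairwise two-sided Mann-Whitney U tests with
Bonferroni correction over the number of pairs and derives a compact
letter display from maximal cliques of the non-significant-pair graph.
With small tie-free groups the p-values are exact (two fully separated
groups of four attain the minimal 2/70); with ties `stats::wilcox.test`
falls back to the corrected normal approximation, which is the standard
behaviour of the routine practitioners use.

## Genomic correlates

`cog_prevalence()` corrects COG category counts for genome size by
normalizing to the total annotated genes per genome (proportions summing
to 1). Gene-count normalization is the default because "prevalence per
genome" is a compositional statement about gene repertoire; a per-megabase
density mode is provided for users who prefer length normalization — the
two differ only through coding density, and the choice is exposed rather
than hidden. `cog_enrichment()` contrasts the strict auxotroph class
(≥ 2 auxotrophies — conservative, since single-auxotrophy calls are the
most error-prone) against genomes with none, using per-category
Mann-Whitney tests, Bonferroni correction over categories tested, and
log2-fold ratios of group means; a zero mean in either group yields an
explicit undefined-ratio flag instead of an infinite log ratio.
`correlate()` and `group_compare()` wrap Pearson, Mann-Whitney and Welch t
tests with degenerate-input guards (zero-variance vectors return an
undefined flag, groups under two observations error). Shapiro-Wilk
screening (`normality_screen()`) is advisory only: it logs, and gates
nothing. The shipped biosynthetic cost table (`amino_acid_costs()`) lists
P-bonds per molecule for the 17 amino acids; chorismate has no published
cost and is absent, so cost correlations run over 17 points unless a
custom table is supplied.

## The synthetic-data generator

`simulate_study()` emulates the pipeline's inputs with planted ground
truth. What it does and does not model:

- **Pathways**: route/step counts drawn uniformly from configured ranges
  (defaults 1–3 routes of 3–10 steps, bracketing typical amino acid
  pathway sizes); step ids are globally unique. Real pathways share
  enzymes between compounds; sharing is not modeled because the calling
  logic operates per step id either way.
- **Knockouts**: each genome × compound is knocked out with probability
  `auxotrophy_rate` (default 0.05 per compound, giving roughly 60% of
  genomes at least one auxotrophy — within the range observed across real
  habitats). A knockout removes `ceiling(0.5 × length)` steps from *every*
  route, so planted auxotrophies sit safely above the 40% threshold; a
  shallow mode (`knockout_fraction < 0.4`) exists to exercise false
  negatives.
- **Evidence**: surviving steps get hits that pass the candidate rules by
  construction; `gene_dropout` deletes evidence rows to emulate incomplete
  assemblies; `decoy_rate` adds sub-threshold hits to absent steps
  (identity below 30%, so they fail both branches). Decoys verify that
  failing evidence is inert; they are not a model of homology noise.
- **16S and ASVs**: 16S sequences are random (1200–1550 nt) — matching
  only needs Hamming structure, not phylogeny — and ASVs are 250 nt
  windows with 0–1 substitutions, plus a configurable fraction with 3
  substitutions that must go unmatched, emulating taxa without
  representative genomes. Because sequences are random, cross-matching
  between genomes is effectively impossible; the generator therefore does
  not exercise the ambiguous-tie path (constructed fixtures in the tests
  do).
- **Abundances**: log-normal taxon means with per-sample multinomial
  sampling — enough structure to exercise the read-count and occupancy
  filters, with no attempt at ecological realism (no spatial structure,
  no per-sample presence model).
- **Genome size**: linear in the planted auxotrophy count
  (default intercept 5.2 Mb, slope −0.2 Mb per auxotrophy, 0.4 Mb noise),
  chosen to put the size–auxotrophy correlation near the magnitude
  reported for real genome collections (about −0.4).
- **COG composition**: Dirichlet-multinomial per genome (concentration
  400 over 23 categories). Genomes with ≥ 2 planted auxotrophies have the
  enriched categories (defaults J, O — translation and protein turnover)
  up-weighted by `cog_effect` (1.5), with the excess mass absorbed
  entirely by the depleted set (defaults E, G, K, T — amino acid and
  carbohydrate transport/metabolism, transcription, signal transduction).
  This balanced design is deliberate: a plain multiplicative boost shifts
  *every* other category downward through compositional closure, and at
  100 genomes per group those closure shifts become statistically
  detectable, so "unplanted" categories would be flagged for a purely
  arithmetic reason. Planting both directions matches the empirical
  observation that streamlined auxotroph genomes trade transport and
  regulatory genes for translation machinery, and leaves unplanted
  categories with exactly zero expected shift.

Determinism: every generator stage derives its own sub-seed from the
configuration seed and restores the caller's RNG state, so identical
configurations produce bit-identical outputs and a single `--seed` governs
the whole CLI.

What passing tests on these data do and do not show: they verify the
pipeline's logic — rule boundaries, route minimization, filter semantics,
rate definitions, recovery of planted signals — under a generative model
that is far simpler than real genomes. They do not validate biological
accuracy on real annotation pipelines, homology-search noise, phylogenetic
correlation between taxa, or compositional idiosyncrasies of real COG
repertoires.

## Problem sizes and numerical choices

The test suite and the acceptance script run, by design, at moderate
sizes: 500-genome panels for calibration (about 108k evidence rows), a
300-taxon / 50-sample habitat for prevalence recovery, 100 genomes per
group over 20 replicates for enrichment recovery, and 1,000 random
pathways against the exhaustive route-enumeration oracle. These sizes give
binomial standard errors small enough for the planted effects to be
unambiguous while a full run stays within a few minutes on one core.

Numerical conventions, collected: threshold and route comparisons in
integer arithmetic; percentages on the 0–100 scale in files, proportions
0–1 in memory; Bonferroni as `min(1, p × m)`; tie-breaks deterministic and
flagged; degenerate inputs (zero-variance vectors, empty groups, zero
annotated genes, labeled pairs without predictions) raise typed errors or
explicit NA flags rather than silent values.

## Known limitations

- Calls are annotation-level: genes absent from the evidence because of
  assembly or annotation failure are indistinguishable from true loss;
  the completeness filter and the calibrated threshold mitigate but do
  not remove this.
- The union-of-routes question (whether the missing fraction should pool
  route genes when routes differ in length) has no authoritative answer;
  best-route is implemented and documented, and single-route definitions
  reproduce the plain fraction.
- Matching assumes the amplicon region is present verbatim in the
  reference 16S; multi-copy 16S heterogeneity and indels are out of scope.
- The generator's simplifications above mean quantitative results on
  synthetic data (e.g. exact FP rates under dropout) characterize the
  method, not any real genome collection.
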