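---
title: "Hybrid abundance-occupancy core microbiome extraction with CI/NorCI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hybrid abundance-occupancy core microbiome extraction with CI/NorCI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(corescope)
```

## The problem

A core microbiome is the set of microbial taxa shared across a host
population — the members most likely to matter for host physiology. For
developing marine invertebrate larvae (the motivating system is the sea
cucumber *Apostichopus japonicus*, reared from fertilized egg to juvenile
over multiple years), the question splits into an *early-life core* shared
across all developmental stages and *stage cores* tied to single stages:
a pioneer core on the fertilized egg (FE), a juvenile core (JN), and
initial/later-stage cores delimited by gut development (preGD = FE, GL, EA;
postGD = LA, PT, JN — the community reorganizes between early and late
auricularia, when the gut forms and feeding begins).

Because "core" has no consensus definition, `corescope` implements a hybrid
one that joins three criteria:

1. **Abundance** — the taxon belongs to the shortest abundance-ranked prefix
   that accumulates 75% of all reads.
2. **Occupancy** — the taxon is detected in strictly more than 70% of
   samples.
3. **Core Index** — among the top-20 most abundant taxa, the taxon's
   normalized Core Index exceeds 0.3.

## The Core Index model

For a taxon with total reads $s$ across a dataset of $S$ total reads,
detected in $n$ of $N$ samples,

$$CI = \frac{f \cdot n \cdot s}{N \cdot S}, \qquad
NorCI = \frac{CI' - CI_{min}}{CI_{max} - CI_{min}}$$

where $f$ is the taxon's frequency within the dataset and $CI_{min}$,
$CI_{max}$ are taken over the evaluated set. The published definition of
$f$ and $s$ speaks of per-taxon and total "sequence length"; amplicon reads
are uniform in length, so length totals are proportional to read counts,
and we interpret $s$, $S$ as read counts and $f = s/S$ as the taxon's
relative read frequency. That gives $CI = (n/N)(s/S)^2$, bounded in
$[0, 1]$ with the maximum attained only by a taxon owning every read in
every sample. The alternative reading $f = n/N$ is available as
`f_definition = "occupancy"` so either convention can be reproduced; both
are monotone in $(n, s)$, and for taxa with equal occupancy they rank
identically.

Numerical choices worth stating:

* NorCI is normalized over exactly the evaluated collection (the top-20
  taxa for the whole-dataset core; the candidate pool for a stage core),
  because the index is computed separately per analysis. When every CI in a
  set is equal, NorCI is undefined; we return `NA` with a warning rather
  than an arbitrary constant.
* Both the "over 70%" occupancy rule and the "NorCI > 0.3" rule are strict
  inequalities; the occupancy comparison snaps `threshold * N` to the
  nearest integer when it is within 1e-9 of one, so "exactly 70% of 10
  samples" is excluded by arithmetic rather than by floating-point luck.
* Abundance ranking breaks ties lexicographically by taxon name, making
  every report deterministic.
* The final `core` label requires all three criteria jointly; each flag is
  also reported separately so a reader can extract either a pure
  abundance-occupancy core or a pure CI core from the same table.

## Preprocessing

Organelle (mitochondrial/chloroplast) features are removed by
case-insensitive substring match over the raw and canonical lineage strings
— database capitalization varies, and substrings ("mitochondri") catch both
"Mitochondria" and "mitochondrial". Presence/absence for all occupancy
logic is computed **after** organelle filtering and (if enabled)
rarefaction, since occupancy on an unfiltered table counts contaminant
reads as presence.

Rarefaction subsamples each sample without replacement (hypergeometric) to
a common depth — the dataset minimum by default; 5683 reads per sample in
reproduction mode, the depth used for the original larval dataset. Whether
to rarefy before or after filtering is exposed in the pipeline
configuration; the default is filter-then-rarefy so that the evened depth
is spent on informative reads.

Rank collapse sums features sharing a label at the requested rank
(order/family/genus; `asv` is the identity) and conserves totals exactly;
features unassigned at that rank are pooled under
`Unclassified_<nearest assigned parent>` so reads are never silently lost.

## Stage cores and the enrichment screen

A stage core is extracted in two steps. First a candidate pool is built
from (i) taxa significantly enriched in the target stage and (ii) taxa
exclusive to it (detected in at least one of its samples and in none of
any other larval stage), with provenance tags; an externally computed
candidate list (e.g. genuine LEfSe output) can be supplied instead. Second,
CI/NorCI are computed for the pool over the scope's samples and members
with NorCI > 0.3 are the stage core.

The enrichment screen is a documented stand-in for LEfSe (whose full
algorithm — subclass Wilcoxon tests and bootstrapped LDA — is a published
tool and out of scope): a per-taxon Kruskal–Wallis test across stages,
exact by full permutation enumeration when the design has at most 10
samples, plus an effect score on LEfSe's conventional $10^6$-scaled
log10 axis,
$\log_{10}(1 + |\bar{x}_{target} - \bar{x}_{other}| \cdot 10^6 / 2)$,
with the 3.5 cut-off; a taxon must also be *enriched* (not depleted) in
the target class. Significance uses the per-test p < 0.05 convention by
default, matching the screen it stands in for. We considered making
Benjamini–Hochberg adjustment the default, but with six stage groups a
taxon cleanly elevated in one stage of five samples among 28 cannot fall
below p ≈ 0.01 (perfect one-group separation yields H ≈ 12 on 5 df), so BH
across ~150 taxa would structurally never admit single-stage candidates;
BH remains available (`adjust = TRUE`, config `adjust_p`) and the
effect-score cut-off is what controls false calls in either mode — under a
null design (fold-change 1) the call rate stays well under alpha.

Two scope conventions exist for stage CI: computing $N, S, n, s$ on the
scope's samples only (default, `scope = "restricted"`) or on all larval
samples (`scope = "global"`). We default to restricted because a pool of
stage-specific candidates only discriminates within that stage's own
sample set; the choice is configurable since the source analysis does not
state it. Seawater samples are excluded from all stage-core computations
by habitat filter. For the preGD/postGD scopes no enrichment pool is
prescribed; the default pool is the scope's own top-20 most abundant taxa
(provenance `"abundance"`), which the reports flag as an inference.

## What the synthetic generator emulates

`synthetic_spec()` encodes the study conditions: 28 larval samples over six
stages (5,5,5,5,4,4) and three rearing years, with

* 4 universal core taxa at 8% target relative abundance, present in every
  sample;
* 2 stage-enriched taxa per stage, at 20× the background level in their own
  stage;
* 1 stage-exclusive taxon each for FE and JN at 40% target abundance in its
  stage (a dominant pioneer — the magnitude that makes a pioneer core call
  meaningful);
* 150 sparse background taxa, each present in a sample with probability
  0.25 at a 0.005 target level, with lognormal year-batch multipliers
  (sd 0.5) applied to background taxa only — planted cores persist across
  years while the background fluctuates, mirroring the study design;
* ~5% organelle-contaminant features with Chloroplast/Mitochondria
  lineages;
* lognormal sequencing depth (median 20,000 reads, log-sd 0.3), and counts
  drawn Dirichlet-multinomial with concentration 50× the expected
  composition.

The background level 0.005 is chosen so the planted target abundances sum
to 0.92 < 1 in the fullest stage (FE), keeping the composition feasible;
target weights are renormalized per sample, so realized core abundances
run ~7–11% depending on stage. Year assignment cycles within each stage so
every stage spans all years.

What the generator does **not** emulate: phylogenetic correlation between
taxa, compositional interactions (one taxon's bloom suppressing another
beyond the multinomial constraint), chimeras/denoising artifacts, or
copy-number variation. Passing recovery tests therefore demonstrates that
the extraction logic is correct under realistic overdispersion and batch
structure — not that the thresholds are optimal for any particular real
dataset.

Recovery benchmarks run the full pipeline (filter → rarefy → collapse to
family → classify) over 25 generator seeds and require ≥ 95% precision and
recall for the universal core, and the planted FE-exclusive taxon recovered
as the *sole* pioneer core member in ≥ 90% of seeds. These problem sizes
(25 seeds × 28 samples × ~175 features) keep the whole benchmark under a
minute while leaving the binomial noise on a 25-seed rate visible.

## The growth assay module

The probiotic feeding-trial statistics stop at the specific growth rate,
$SGR(\%) = 100 (\ln L_t - \ln L_0)/t$, and per-group mean ± standard error
summaries. SGR is unit-invariant and antisymmetric under swapping lengths.
The Bayes-factor test applied to the original growth data is off-the-shelf
statistical software on unpublished raw measurements; the module emits the
per-animal SGR table so any external test can be applied.

## Pipeline determinism

`run_pipeline()` executes filter → (rarefy) → collapse → classify →
stage cores per configured rank from one validated configuration, and
writes per-rank and per-scope TSV reports, a JSON manifest (normalized
config, seed, input checksums) and a plain-text summary. All randomness
(generator, rarefaction) flows from the single configured seed, reports
contain no timestamps, and the manifest's `config` entry replayed through
`run_pipeline()` reproduces every output byte-identically — the property
the test suite asserts directly.

## Known limitations

* The CI interpretation ($f = s/S$, lengths read as counts) is a judgment
  call on an ambiguous published definition; both readings are implemented,
  but only one can be the default.
* The enrichment screen is a stand-in: it reproduces LEfSe's role
  (candidate detection at p < 0.05 with an effect cut-off), not its
  algorithm. Supplying a genuine LEfSe result file is supported and takes
  precedence.
* Stage-core extraction with a candidate pool of one member is refused
  (NorCI needs two points); a dataset whose screen yields a single
  candidate needs an externally widened pool.
* Exact permutation p-values are enumerated only for designs with ≤ 10
  samples; larger designs use the tie-corrected chi-squared approximation,
  as standard.
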