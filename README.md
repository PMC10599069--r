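# corescope

Hybrid abundance–occupancy core microbiome extraction with Core Index
scoring, for amplicon (16S rRNA gene) feature tables.

## What it solves

Developing marine invertebrate larvae — the motivating system is the sea
cucumber *Apostichopus japonicus*, reared from fertilized egg (FE) through
gastrula (GL), early/late auricularia (EA/LA) and pentactula (PT) to
juvenile (JN) — host a microbiome that reorganizes as the gut develops.
Identifying its *core* members (the taxa shared across the host population,
and the stage-specific pioneers that colonize fertilized eggs or juveniles)
requires a defensible, reproducible definition. `corescope` implements a
hybrid one that joins three criteria:

1. **Abundance** — membership in the shortest abundance-ranked prefix of
   taxa accumulating 75% of total reads;
2. **Occupancy** — detection in strictly more than 70% of samples;
3. **Core Index** — among the top-20 most abundant taxa,

   CI = f·n·s / (N·S),  NorCI = (CI′ − CI_min) / (CI_max − CI_min),

   with `s` the taxon's reads, `S` total reads, `n` the samples containing
   it, `N` total samples, and `f = s/S` its dataset frequency; taxa with
   NorCI > 0.3 pass.

A taxon is `core` only when all three hold. Stage cores (pioneer FE,
juvenile JN, preGD/postGD) are extracted from candidate pools built by an
enrichment screen (a documented Kruskal–Wallis + effect-score stand-in for
LEfSe, or an externally supplied LEfSe result) together with
stage-exclusivity detection, scored by CI/NorCI over the stage's own
samples.

The package also ships a Dirichlet-multinomial synthetic community
generator with planted ground truth (universal cores, stage-enriched,
stage-exclusive, background and organelle features; year batch structure;
lognormal depths) so every stage of the pipeline is testable without any
sequencing download, plus specific-growth-rate summaries for probiotic
feeding assays.

## Worked example

```r
library(corescope)

ds  <- generate_dataset(synthetic_spec(seed = 1))   # 28 samples, 6 stages
ft  <- filter_organelles(ds$table, ds$taxonomy)     # drop organelle reads
rf  <- rarefy(ft, seed = 1)                         # even depth, no replacement
fam <- collapse_rank(rf, ds$taxonomy, "family")     # family-level table

scores <- classify_core(fam)
subset(as.data.frame(scores), core_label == "core")
#>              taxon occupancy_frac abundance_share      ci norci
#>  Marinobacteraceae              1          0.0939 0.00882 1.000
#>  Flavobacteriaceae              1          0.0926 0.00858 0.973
#>   Rhodobacteraceae              1          0.0841 0.00707 0.801
#>   Alteromonadaceae              1          0.0791 0.00625 0.707
```

The four planted universal-core families — present in 100% of samples,
each ~8–9% of reads, NorCI 0.71–1.00 — are exactly the taxa labelled
`core`; stage-enriched, stage-exclusive and background taxa all fail the
occupancy or NorCI criterion.

Pioneer (FE) stage core, from an enrichment + exclusivity candidate pool:

```r
rel  <- to_relative(fam)
pool <- assemble_candidate_pool(enrichment_screen(rel, ds$metadata, "FE"),
                                detect_exclusive_taxa(fam, ds$metadata, "FE"))
res  <- stage_core_extraction(fam, ds$metadata, "FE", pool)
res$scores[, c("taxon", "ci", "norci", "provenance", "core")]
#>                    taxon        ci   norci provenance  core
#> 1         Idiomarinaceae 1.034e-01 1.00000       both  TRUE
#> 2          Colwelliaceae 1.566e-02 0.15145   enriched FALSE
#> 3 Pseudoalteromonadaceae 7.590e-03 0.07339   enriched FALSE
#> 4            BgFamily023 1.354e-07 0.00000  exclusive FALSE
```

The planted FE-exclusive family dominates the FE samples (CI 0.10 over the
5 FE samples) and is the sole pioneer core member; merely enriched
families score an order of magnitude lower and stay below the 0.3 NorCI
threshold.

Everything end-to-end, from one config:

```r
run_pipeline(list(simulate = TRUE, seed = 1), "run1")
# writes core_<rank>.tsv (order/family/genus/asv), stage_core_<scope>.tsv
# (FE/JN/preGD/postGD), manifest.json, summary.txt — byte-identical on rerun
```

Growth assay: `specific_growth_rate(10, 20, 30)` returns `2.3105` (%/day),
and `summarize_growth()` gives per-group mean ± SE tables.

## Layout

- `R/` — feature-table types and TSV IO, preprocessing (organelle filter,
  rarefaction, rank collapse), CI/NorCI core metrics, stage-core
  extraction and enrichment screen, synthetic generator, growth-assay
  statistics, pipeline driver.
- `tests/testthat/` — unit, property and end-to-end recovery tests.
- `vignettes/core-microbiome-extraction.Rmd` — the methods vignette: model,
  parameter meanings and defaults, generator assumptions, numerical
  choices, limitations.
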