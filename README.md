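# xorgan — cross-species organ transcriptome comparison

`xorgan` asks a comparative question: *which organs of one species does a
focal organ of another species resemble transcriptionally?* It was built for
the classic setting in evolutionary physiology where an organ with no direct
counterpart — for instance the tunicate **endostyle**, the ventral pharyngeal
groove thought to prefigure the vertebrate thyroid — is characterised by
projecting its marker genes onto the organ panels of better-annotated
species through protein-level homology.

The package is aimed at transcriptomics researchers who have expression
tables (counts, TPM, FPKM/RPKM) and pairwise protein-alignment hit tables in
hand, and want a reproducible, tested path from those inputs to per-organ
similarity statistics.

## The statistics at its core

1. **Organ-specific genes (OSGs).** Focal genes with a homolog in a
   reference species are screened against the reference organ panel: a
   candidate is *eliminated* if its homolog's expression exceeds a ceiling
   (default 0.5, strict) in **any** non-excluded reference organ, and
   survivors must exceed a floor (default 1.0, strict) in the focal organ:

   `OSG(g) ⟺ x_focal(g) > 1.0 ∧ max_{o ∉ excluded} x_ref(h(g), o) ≤ 0.5`

2. **Similarity ratio.** OSGs are projected through a second homolog map
   onto a target species' organ panel; per organ, the ratio is the fraction
   of mapped OSG homologs expressed there (TPM > 1, strict):

   `ratio(o) = |{g ∈ OSG_mapped : x_target(h'(g), o) > 1}| / |OSG_mapped|`

3. **Tissue-enriched genes and similarity index.** In a consensus organ
   atlas, a gene is *tissue-enriched* when its expression in one tissue is
   at least 4-fold (inclusive) its maximum anywhere else. The similarity
   index of a tissue is the fraction of its enriched genes whose focal
   homolog is expressed above FPKM 5 (strict) in the focal organ.

4. **Support machinery.** Counts→TPM/FPKM conversion by effective
   transcript length, pseudobulk summation of single-cell counts, best-hit /
   unique / reciprocal homolog maps with a deterministic tie-break chain
   (bitscore → e-value → identity → subject id), shared/organ-only expressed
   gene partitions, hypergeometric over-representation with
   Benjamini–Hochberg FDR, sample correlation and PCA QC, and a synthetic
   two-species generator with planted ground truth.

## Worked example

Everything below runs offline on the built-in generator (planted truth:
150 OSGs; the gill of the simulated target panel is planted with an
expressed fraction of 0.70):

```r
library(xorgan)

sim <- simulate_dataset(sim_config(seed = 42))
map <- restrict_unique(best_hit_map(sim$hits$focal_reference))
osg <- call_osgs(sim$focal, "endostyle", sim$reference, map,
                 osg_config(excluded_reference_organs = "endostyle"))
osg
#> OSGResult: 150 OSGs from 4800 candidates (4650 eliminated by reference ceiling, 1200 unscreened)

map_ft <- restrict_unique(best_hit_map(sim$hits$focal_target))
head(similarity_ratio(osg, map_ft, sim$target), 5)
#>         organ     ratio expressed_count mapped_total
#> 1        gill 0.7200000             108          150
#> 2 head_kidney 0.6333333              95          150
#> 3     thyroid 0.6066667              91          150
#> 4       brain 0.5933333              89          150
#> 5      thymus 0.5200000              78          150

enr <- call_tissue_enriched(sim$atlas)           # 27 tissues, 50 genes each
map_af <- restrict_unique(best_hit_map(sim$hits$atlas_focal))
head(similarity_index(enr, map_af, sim$focal, "endostyle"), 3)
#>    tissue     index positive_count denominator
#> 1 thyroid 0.6315789             24          38
#> 2    lung 0.6250000             25          40
#> 3 choroid 0.6097561             25          41
```

Reading the output: all 150 planted OSGs are recovered (the 4650
eliminations are decoy genes planted to violate the reference ceiling); the
gill ratio 0.72 estimates the planted 0.70 within binomial error on
n = 150; the index table ranks atlas tissues by the fraction of their
enriched-gene homologs active in the focal organ.

The same analysis runs from files through the CLI (`exec/xorgan`) or the
orchestrator:

```sh
xorgan simulate --out-dir sim/ --seed 42
xorgan run --config run.yaml        # see ?run_config for the schema
```

`run_all()` writes every stage table plus `report.json` (input checksums,
thresholds, stage counts, per-organ ratios) under the configured output
directory.

## Documentation

`vignettes/cross-species-organ-comparison.Rmd` describes the model, every
threshold and its default, what the synthetic generator does and does not
emulate, and the package's numerical conventions (strict vs inclusive
boundaries, tie-breaks, degenerate inputs).
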