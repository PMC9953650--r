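---
title: "Cross-species organ transcriptome comparison with xorgan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-species organ transcriptome comparison with xorgan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xorgan)
```

## The problem

Some organs have no one-to-one counterpart across phyla. The tunicate
endostyle — a ciliated, mucus-secreting pharyngeal groove with a
thyroid-like iodine-concentrating region — is the motivating case: to say
which vertebrate organs it resembles, one cannot align organs directly, only
genes. `xorgan` implements the marker-projection strategy: define the focal
organ's specific genes against a related species' organ panel, push those
genes through homolog maps into other species, and summarise, per organ or
tissue, how much of the marker set is active there.

All comparisons reduce to counting genes above expression cut-offs, so the
package is deliberately explicit about units, aggregation and boundary
conventions; these conventions are the main content of this vignette.

## The model and its assumptions

### Organ-specific genes

Given a focal expression profile $x_f$ (FPKM), a reference organ panel
$x_r$ (RPKM, organs $o \in O$) and an injective homolog map $h$, gene $g$
is an organ-specific gene (OSG) of the focal organ iff

$$ x_f(g) > \tau_f \quad\wedge\quad \max_{o \in O \setminus E} x_r(h(g), o) \le \tau_r $$

with focal floor $\tau_f = 1.0$, reference ceiling $\tau_r = 0.5$, and $E$
the excluded reference organs (typically the reference species' own copy of
the focal organ — it is expected to express the same program and would
otherwise veto every true marker). Both thresholds are **strict**
("larger than"); values sitting exactly on a threshold do not pass. Only
genes with a homolog are candidates: an unmapped gene cannot be screened
against the reference panel, so it is reported separately as `unscreened`
rather than silently treated as specific.

The elimination is per-organ (ANY-organ): a single reference organ above
the ceiling removes the candidate. This is the conservative reading of a
screen designed to produce markers absent everywhere else.

FPKM and RPKM are treated as one numeric scale distinguished only by tag;
when a comparison mixes the two tags a warning is emitted but no conversion
is applied, since both are length- and depth-normalised to the same units.

### Similarity ratio

OSGs are mapped into a target species (map $h'$). The denominator is the
number of OSGs with a target homolog — unmapped OSGs are reported but
cannot contribute to any organ, so including them would deflate every organ
equally while adding no contrast. Per target organ $o$,

$$ \mathrm{ratio}(o) = \frac{|\{g : x_t(h'(g), o) > 1\ \mathrm{TPM}\}|}{|\mathrm{OSG}_{\mathrm{mapped}}|}. $$

### Tissue-enriched genes and similarity index

In a consensus atlas (one column per tissue), gene $g$ is enriched in
tissue $t$ iff

$$ x_a(g,t) \ge 4 \cdot \max_{t' \ne t} x_a(g,t') \quad\wedge\quad x_a(g,t) \ge \mathrm{floor}, $$

The fold boundary is **inclusive** ("at least four-fold"), unlike the
strict expression thresholds. When the off-tissue maximum is zero the fold
condition is vacuous and only the floor (default 1, atlas units) applies —
without it, a gene detected in a single tissue at trace level would count
as enriched. Under this max-versus-rest rule with fold > 1, a gene is
enriched in at most one tissue, so the per-tissue sets are disjoint by
construction.

The similarity index of tissue $t$ is the fraction of its enriched genes
whose focal homolog exceeds FPKM 5 (strict) in the focal organ. Two
denominators are offered: `MAPPED` (enriched genes with a focal homolog;
the default, since genes without homologs are unobservable in the focal
species) and `FULL_SET` (the whole enriched list; lower bounds the index).
Tissues with an empty denominator are reported as `NA`, never as zero — an
unobservable tissue is not a dissimilar tissue.

### Homolog maps

Best-hit maps keep, per query, the hit with maximal bitscore. The full
tie-break chain — bitscore, then minimal e-value, then maximal percent
identity, then lexicographically smallest subject id — is a package
convention chosen for cross-platform determinism; alignment tools only
guarantee the first criterion. `restrict_unique` resolves many-to-one
collisions by the same chain (plus smallest focal id last), yielding an
injective map; `reciprocal_map` intersects mutual best hits. Self-hits are
excluded by default (relevant only when both species share an id
namespace). No e-value or identity floor is applied by default; both are
available as arguments.

### Enrichment statistics

Over-representation uses the one-sided hypergeometric upper tail
$p = \sum_{i=k}^{\min(K,n)} \binom{K}{i}\binom{N-K}{n-i} / \binom{N}{n}$
with Benjamini–Hochberg adjustment across tested terms, both implemented in
the package (the BH step-up literally, the tail via the standard library's
`phyper`) and verified against exhaustive subset enumeration for all
$N \le 12$ — so the pipeline needs no external enrichment tool and the
arithmetic itself is under test. Annotation sets are intersected with the
background first; terms with fewer than 3 background genes are skipped by
default as noise.

## Tunable parameters

| parameter | default | units | role |
|---|---|---|---|
| `reference_max` | 0.5 | FPKM/RPKM | OSG elimination ceiling, strict, per reference organ |
| `focal_min` | 1.0 | FPKM | OSG focal floor, strict |
| projection `threshold` | 1.0 | TPM | similarity-ratio expression cut, strict |
| `fold` | 4 | ratio | tissue enrichment, inclusive |
| `floor` | 1 | atlas units | enrichment guard for zero background |
| index `threshold` | 5.0 | FPKM | similarity-index cut, strict |
| `expressed` | 1.0 | FPKM | expressed-gene sets for overlap/QC, strict |
| `rule` | mean | — | replicate aggregation before thresholding |

The replicate-aggregation rule deserves a note: whether organ-level values
are per-replicate or replicate-averaged before thresholding is genuinely
underdetermined in this style of analysis, so it is configuration (`mean`,
`any` = max, `all` = min) rather than a guess baked in. `mean` is the
default because thresholding the mean is the least sensitive to single
outlier replicates.

## The synthetic world

`simulate_dataset()` emits a two-species comparison with planted truth; its
defaults *are* the stated world of the validation suite and are not moved
to make tests pass:

* 6,000 focal genes, one focal organ (endostyle) with 3 replicates; 6,000
  reference genes across 11 organs (an ascidian-like panel including the
  reference's own endostyle); 6,000 target genes across 12 organs (a
  fish-like panel); a 27-tissue atlas with 50 planted enriched genes per
  tissue.
* 80% of focal genes have a one-to-one reference homolog; 150 planted OSGs
  with focal expression uniform in [5, 50] (≥2× margin above the floor) and
  reference expression below 0.3 (margin below the 0.5 ceiling) in every
  non-excluded organ. The excluded organ is planted *high* (1–10) for OSG
  partners, so recovery genuinely requires the exclusion mechanism rather
  than passing vacuously.
* Every non-planted mapped gene violates exactly one rule: half are
  focal-low (≤ 0.5), half reference-high (≥ 1 in one random organ), making
  precision failures detectable.
* Per target organ, mapped OSG homologs are expressed (uniform [5, 50],
  i.e. well above TPM 1) independently with a configured probability
  (default panel spans 0.25–0.70, gill at 0.70); non-expressed homologs sit
  in [0.01, 0.2]. The realized draw is recorded in the truth record, so
  noiseless ratios must match it *exactly*, and configured fractions
  binomially. Target columns are renormalised over background genes only,
  so TPM columns sum to exactly 10⁶ without disturbing planted values.
* Enriched atlas genes exceed their off-tissue maximum by a 6× margin
  (above the 4× rule); background atlas genes vary within 0.5–1.5× of a
  per-gene base, bounding their max/rest ratio at 3× so they can never be
  called. The atlas is emitted noise-free at every noise level because the
  planted-set recovery contract is stated unconditionally.
* Baseline expression is log-normal (meanlog 1, sdlog 1.2 on the FPKM
  scale) — the conventional stand-in for bulk abundance distributions that
  keeps threshold crossings realistic. Optional multiplicative log-normal
  noise (`noise_sd`, default 0) perturbs focal/reference/target values; a
  negative-binomial count generator (`simulate_counts`) covers the COUNTS
  pathway.
* Hit tables give every true pair the top bitscore for its query; decoys
  (default 3 per query) get strictly lower scores, so best-hit maps
  round-trip the truth. All draws flow from one integer seed; outputs are
  byte-identical across runs.

What the generator does **not** emulate: gene-length or GC bias,
correlated expression programs, dropout, batch effects, many-to-many
orthology, or alignment errors in which the best hit is not the true
ortholog. A green recovery test therefore establishes that the *calling
logic* is correct under the stated margins — not that the thresholds are
robust to biological noise sources the generator does not model.

## Numerical choices and degenerate inputs

* Strict (`>`) boundaries everywhere except the inclusive 4-fold rule;
  boundary tests pin both directions.
* TPM validation: columns must sum to 10⁶ within relative 10⁻⁶; conversion
  from counts guarantees this by construction and rejects all-zero columns
  (undefined normalisation) naming the sample.
* OSG output is ordered by descending focal expression with gene id as the
  deterministic tie-break; profile tables sort by descending ratio/index
  (`NA` last).
* Constant samples yield `NA` correlations with a warning, not an error;
  PCA fixes component signs by forcing the largest-magnitude loading
  positive.
* Empty homolog maps, unknown organ labels, empty queries/backgrounds and
  ratio denominators of zero are hard errors; an empty similarity-index
  denominator is `NA` per tissue (the profile survives).

## Design choices that were genuinely open

* **Candidate universe.** OSG candidates are restricted to mapped genes
  because the screen is defined on homolog *pairs*; the `unscreened`
  residue is surfaced so users can see what the map excluded.
* **Ratio denominators.** `MAPPED` for both the similarity ratio and the
  index (with `FULL_SET` selectable for the index), on the ground that a
  ratio should condition on observability.
* **Config format.** The orchestrator takes a single YAML file mirroring
  every CLI flag, so `run_all()` is a thin composition of the standalone
  subcommands, and all randomness lives in the generator — analysis stages
  are deterministic by construction.
* **Excluded-organ planting.** The generator plants the excluded reference
  organ high rather than low (see above); the alternative would have let
  the exclusion parameter be dead code under test.

## Known limitations

* One-to-one maps only; paralog families are collapsed to the single best
  pair, which can understate similarity for expanded families.
* No statistical test accompanies the similarity ratio or index; they are
  descriptive fractions, and their binomial error is only quantified on
  synthetic data where the truth is planted.
* Unit mixing (FPKM vs RPKM) is warned about, not corrected; TPM vs FPKM
  mixing in a comparison is the user's responsibility.
* The atlas taxonomy is the single "enriched" tier; graded categories
  (group-enriched, enhanced) are out of scope.
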