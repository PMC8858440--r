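---
title: "Pathway-centric meta-analysis of untargeted metabolomics: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pathway-centric meta-analysis of untargeted metabolomics: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pathmeta)
```

## Why pathway-centric

Untargeted LC-MS metabolomics detects *features* — (m/z, retention time)
peaks with an intensity and, after a group comparison, a p-value — not
metabolites. Archived studies cannot be re-fragmented: the samples are gone,
so a feature's identity stays putative. Comparing two archived studies
feature-by-feature is therefore fragile; comparing them at the level of
*pathway activity inferred from putative annotations* is robust, because a
pathway statistic aggregates over many features and never commits to any
single identification. `pathmeta` performs that comparison: each study is
annotated and scored on its own terms, and the evidence is pooled at the
compound-set level.

## The pipeline, stage by stage

### Parsing and partitioning

Peak lists arrive as tsv/csv in one of three header dialects (`generic`,
`xcms` diffreports, `workbench` feature tables); the delimiter is
auto-detected and each feature is tagged with its source file so every
downstream hit remains traceable. Per study the user sets three parameters:

| parameter | meaning | domain | default |
|---|---|---|---|
| `p_cutoff` | feature significance threshold | (0, 1] | 0.05 |
| `mz_tol_ppm` | relative mass tolerance for annotation | > 0 ppm | 10 |
| `intensity_cutoff` | reference-list intensity floor | ≥ 0 | 0 |

The *reference* list (the enrichment background) is every feature passing
the intensity floor; the *significant* list is the subset with
`p_value < p_cutoff`. Two deliberate conventions: the comparison is strict
(`<`, the common convention for feature lists), and features lacking an
intensity are kept when the floor is 0 but dropped once a floor is set —
the only deterministic reading when inputs are heterogeneous. Defaults are
the values a practitioner would start from on a Q-TOF platform; tolerance
should be tightened (3–5 ppm) for well-calibrated instruments and relaxed
for older archives.

Studies representing different analytical modalities of the same biological
experiment (HILIC/RP, positive/negative ESI) can share a `group` label;
their matched compound sets are unioned into one analytical unit before
cross-study merging, so complementary coverage adds up without double
counting studies.

### Putative annotation

Each reference feature is expanded under the adduct rules of its ionization
mode. A rule (mass shift $\Delta$, charge $z$, multiplicity $n$) maps an
observed m/z to a candidate neutral mass

$$M = \frac{mz \cdot |z| - \Delta}{n},$$

and the candidate matches a model compound of mass $M_0$ when
$|M - M_0| / M_0 \times 10^6 \le$ `mz_tol_ppm` (the denominator is the model
mass, the standard convention). The default rule table covers the common
electrospray species — positive M+H, M+Na, M+K, M+NH4, M+H−H2O, 2M+H;
negative M−H, M+Cl, M−H−H2O, 2M−H — with shifts computed as exact ion
masses (electron included); e.g. the water-loss protonated ion is
$+1.007276 - 18.010565 = -17.003289$ Da. The table is plain data
(`default_adducts()`) and fully user-replaceable, because the right set
depends on the chromatography and the matrix.

A compound matched by several features or adducts appears once in the
compound sets with the best significant-feature p-value, but *all*
contributing (feature, adduct) pairs are retained so reports can later be
filtered by adduct or source study without re-running anything.

Named-metabolite tables from repository studies enter as *confirmed*
matches, resolved by compound id or by normalized (lower-cased,
whitespace-collapsed) name/alias. A confirmed record with a p-value obeys
the study cutoff like any feature; one without a p-value is treated as
significant by default — an archived identification usually *is* a reported
dysregulation — with `confirmed_as = "reference"` available for the
conservative reading.

### Enrichment: the EASE-adjusted exact test

For a universe of $N$ matched reference compounds with $n$ significant ones,
a pathway holding $m$ universe compounds and $k$ significant hits scores

$$p \;=\; P\!\left(X \ge \max(k - 1,\, 0)\right), \qquad
  X \sim \mathrm{Hypergeometric}(N, m, n),$$

with $p \equiv 1$ when the decremented count is zero. The decrement (the
EASE variant of Fisher's exact test) deliberately discounts single-compound
hits: putative annotation generates them in large numbers by chance, and a
pathway should not look active on the strength of one ambiguous mass.
Pathways sharing no compound with the universe are omitted; ties in $p$ are
broken by descending hits, then pathway id, so output order is total and
reproducible.

### Cross-study merging

The merged universe is the union of per-unit matched reference compounds.
Two merge policies exist because "jointly dysregulated" admits two readings:

* **union** (default): a compound significant in *any* study enters the
  merged significant set, carrying its best (smallest) per-study p-value —
  this drives the enrichment test, maximising coverage;
* **shared**: the set is restricted to compounds significant in at least
  `min_studies` studies — the strict intersection reading.

Rather than privileging one reading, the shared-metabolite count per pathway
is always computed and reported regardless of the enrichment mode, and
`filter_results()` thresholds on it by default (`min_shared = 10` mirrors
the common reporting rule of requiring at least ten jointly dysregulated
features before a pathway is tabled). Display filters prune provenance and
recompute displayed counts only — p-values are never silently recomputed.

### Permutation validation

The raw EASE p-values are not trustworthy as stated probabilities: the
universe is small, annotation is many-to-many, and pathway sizes vary. The
null model therefore resamples *features*, not compounds: each round draws,
uniformly without replacement from every unit's reference features, a
pseudo-significant list of the observed size, re-derives compound sets
through the same annotation index, merges them across units exactly as the
observed statistic was merged, and scores every pathway. Pooling rounds
gives the null distribution, and

$$p_{\mathrm{adj}} = \frac{1 + \#\{v \in \mathrm{null}: v \le p\}}
                          {1 + |\mathrm{null}|}$$

is the empirical adjustment — assumption-free, never zero, monotone in $p$.
Resampling features rather than compounds matters: a compound reachable
through three adducts is three times easier to hit by chance, and the null
inherits exactly that bias. A `gamma` alternative fits a gamma distribution
to $-\log_{10}$ of the null values (location 0) and takes its upper tail —
useful smoothing when permutations are few — falling back to the empirical
estimate with a warning when the null is degenerate. Defaults: 100
permutations, seed 42, empirical adjustment.

Results are invariant to study input order: units are processed in sorted
study-id order internally, including inside the permutation loop.

### Multi-omics overlay

The overlay is annotation-only. Gene hits are the intersection of a
pathway's gene symbols with the uploaded list (upper-cased; loci are matched
as opaque case-insensitive strings — no locus-to-symbol mapping is
attempted, a documented limitation); protein hits intersect the pathway's
UniProt accessions (isoform suffixes stripped) with the uploaded list,
falling back to gene-symbol matching for pathways without UniProt
annotation, since protein lists are frequently supplied as symbols. No joint
metabolite–omics statistic is computed: the two data types answer the same
question at different regulatory levels, and collapsing them into one score
would manufacture precision. The overlay never alters the metabolite-level
results.

## The synthetic generator

`simulate_study()` emulates exactly the structure the pipeline consumes and
nothing more: enriched-pathway compounds appear once each at the m/z of a
randomly drawn mode-appropriate adduct with Gaussian ppm jitter and p-values
from $\mathrm{Beta}(a, 1)$ (the standard one-parameter alternative;
$P(p < c) = c^a$, so the default $a = 0.05$ puts ~86% of enriched features
under a 0.05 cutoff); background features re-draw non-enriched compounds
with uniform p; decoys take m/z uniform over the model's mass range so false
matches arise purely through the tolerance window, isolating the matcher's
specificity. Defaults — 100 background features, 20% decoys, 2 ppm jitter —
describe a modest, well-calibrated Q-TOF study.

What it does *not* emulate: retention-time structure, isotope envelopes,
in-source fragments, correlated intensities, batch effects, or
platform-specific missingness. Passing tests therefore certify the
*statistical machinery* — calibration, power, determinism — on data whose
generative process is known; they say nothing about annotation accuracy on
real spectra, which is bounded by the mass-only identification problem
itself.

## Numerical and design notes

* **Exact tails.** The hypergeometric tail is computed by `phyper`; the test
  suite checks it against explicit binomial-coefficient enumeration to
  1e-12 over every configuration with $N \le 60$.
* **Window matching.** Compound lookup uses a sorted-mass window opened by
  1e-9 relative and then the exact ppm criterion, so results are identical
  to a brute-force scan at any scale.
* **Determinism.** All randomness flows through explicit integer seeds
  (`withr::with_seed`); two runs of the CLI with one config are
  byte-identical, and a `run_manifest.json` (config echo, seed, version)
  accompanies every output directory.
* **Degenerate inputs** fail loudly and early: an empty matched universe, a
  shared merge with no shared compounds, a significant list exceeding the
  reference, invalid thresholds, and referentially broken models are all
  distinct error classes with the offending identifiers in the message.
  Unresolvable confirmed-metabolite names are warnings, not errors.

**Calibration-study design.** The type-I-error simulation in the test suite
(200 null-mode two-study meta-analyses) uses a liberal per-study feature
cutoff of 0.075 with 400 background features rather than the analysis
default of 0.05/100. The reason is intrinsic to the discrete EASE score on a
45-compound toy universe: the statistic is identically 1 both when a pathway
has $k \le 1$ hits (too few significant compounds) and when the merged
significant set saturates the universe ($n \ge N - 1$, where
$P(X \ge m - 1) = 1$ for every pathway). A meaningful uniformity check needs
the merged significant set to cover most-but-not-all of the universe;
solving $1 - (1 - q_1)^2 \approx 0.85$ for the per-study coverage $q_1$
gives the 0.075 cutoff. With a genome-scale model (thousands of compounds,
thousands of features) the same non-degenerate regime arises at conventional
cutoffs, so this is a property of the deliberately tiny test model, not of
the method. Problem sizes throughout the suite — two studies of ~500
features against the 45-compound model, 100 permutations, 50–200 replicates
— were chosen as the smallest configurations at which the checked properties
are statistically meaningful.

## Known limitations

* Mass-only annotation cannot distinguish isomers; everything downstream of
  an ambiguous mass is shared by its isomers. The pathway-level statistic
  mitigates but does not remove this.
* The EASE decrement plus a small universe makes the raw p-value extremely
  conservative and discrete; always interpret the permutation-adjusted
  value.
* The bundled toy model is a testing device. Real analyses should load a
  genome-scale metabolic model via `read_metabolic_model()` (JSON or
  TSV-pair schema).
* Merging assumes studies measure comparable biology; no between-study
  heterogeneity statistic (e.g. a random-effects weight) is computed —
  best-p selection is a coverage strategy, not an effect-size synthesis.
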