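---
title: "Integrating cross-species neurodegeneration modifier screens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Integrating cross-species neurodegeneration modifier screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Genetic modifier screens for neurodegenerative disease models — polyglutamine
(Htt/SCA) constructs, alpha-synuclein, tau, mutant SOD1 and amyloid-beta —
have been run in *C. elegans*, *S. cerevisiae* and *D. melanogaster* at scales
from a handful of candidate genes to the whole genome. Each screen reports a
hit list in its own species' identifiers, so the headline question — *which
regulators recur across independent screens?* — cannot be answered by naive
set intersection. `ndscreen` makes the comparison well-defined by projecting
every hit onto a single reference gene space (the *C. elegans* genome) through
precomputed orthology maps, deduplicating the union into a regulator catalog,
and scanning the catalog for genes attributed to two or more studies.

The pipeline is deliberately a *consumer* of curated inputs: hit lists, alias
tables, orthology maps, functional annotations and interaction edges are data
files. No BLAST, database query or literature mining happens at run time,
which is what makes every stage testable offline.

## Pipeline model

For study $i$ with hit set $H_i$ (native identifiers), the reference-space
projection is

$$ W_i \;=\; \bigcup_{h \in H_i} \mathrm{orth}_{\mathrm{ce}}(h), $$

where $\mathrm{orth}_{\mathrm{ce}}$ maps a normalized identifier to the set of
its worm orthologues (identity for worm genes; possibly empty; possibly
larger than one). One-to-many relations are fully expanded — a single fly
14-3-3 gene legitimately contributes two worm paralogues, and the yeast/fly
acyl-CoA oxidase genes contribute seven — which is why a study's distinct
orthologue count can exceed its hit count. The regulator catalog is
$\bigcup_i W_i$ with per-gene evidence $(study, source\ gene, effect)$, and
the overlap set at threshold $k$ is $\{g : |\{i : g \in W_i\}| \ge k\}$ with
$k = 2$ by default. "More than one study" counts publications: two uses of
the same disease model in the same species still count as two studies.

A worked end-to-end run:

```{r}
library(ndscreen)
studies <- load_fixture("table1_catalog")   # 28 screens
summarize_catalog(studies)                  # 950 reported, 675 orthologues

map <- load_fixture("orthology_groups")
worm_orthologues(map, "yeast", "POX1")      # 7 worm acyl-CoA oxidases
worm_orthologues(map, "fly", "CG31196")     # F52D10.3, M117.2

overlaps <- load_fixture("table2_overlaps") # 34 curated entries
```

## Identifier normalization

Set algebra requires one canonical string per gene. Normalization (i) trims
whitespace and stray trailing commas seen in curated tables, (ii) strips a
single trailing lowercase isoform letter from worm *sequence names*
(`ZK742.1a` → `ZK742.1`) — the analysis unit is the gene, not the transcript —
and (iii) resolves aliases case-insensitively against a species-scoped table,
preserving the table's canonical casing. Gene symbols (`sir-2.1`) never match
the sequence-name pattern and are left intact. Unresolved identifiers pass
through as canonical-by-identity and are *kept*, flagged unresolved, so that
catalog accounting stays conservative rather than silently shrinking.

Two hard constraints make normalization idempotent (a property test checks
this over randomized identifier styles): no alias may map to two canonical
values, and no canonical value may itself be an alias of something else.

## Paralogue grouping

When one source gene maps to several worm paralogues, each paralogue enters
the catalog separately; a curated table would print them as one row. The
package reproduces that presentation by *post-hoc* grouping: overlap entries
whose full evidence signatures — the sorted set of (study, source species,
source gene) attributions — are identical are merged into one multi-gene
entry. Grouping is explicit rather than baked into the set algebra so the
34-entries-but-35-sequence-names bookkeeping of the curated table stays
auditable: the fixture loads as 34 entries carrying 35 worm genes.

## Overlap significance (an explicit extension)

The source analysis asserts that the observed sharing is notable without a
formal test, so the statistical module is clearly labelled an extension and
is off by default in the pipeline. Under the null, each study draws its
$s_i$ distinct mapped worm genes uniformly without replacement from a shared
universe of $U$ eligible genes, independently across studies. With
$p_i = s_i/U$, the expected number of genes hit at least twice is

$$ U\Big[1 - \prod_i (1-p_i) - \sum_i p_i \prod_{j \ne i}(1-p_j)\Big], $$

which the tests cross-check against exhaustive enumeration at toy sizes
($U=10$, sizes $5,5$ gives exactly $2.5$). The permutation p-value uses the
add-one estimator $(1 + \#\{T^{null} \ge T^{obs}\})/(1 + n_{perm})$, which is
never zero and is monotone in the observed count. Defaults:
$n_{perm} = 10^4$, seed 17, one seeded generator per run (caller RNG state
is restored).

The universe $U$ matters and the source never defines it. The default is the
number of worm genes reachable through the loaded orthology map — screens
can only report mappable genes — with an override (e.g. ~20,000 for the
whole genome) exposed for sensitivity analysis. Uniform sampling carries no
model of screen bias (essentiality, RNAi efficacy); that is a documented
limitation, not a knob.

## The synthetic-data generator

`generate_synthetic_dataset()` emits a complete input bundle (study catalog,
hit lists, OrthoMCL-style groups, aliases, annotations, PPI edges) plus a
truth manifest, deterministically from its configuration. Defaults mirror
the curated corpus the pipeline targets: 28 studies split 13 worm / 6 yeast /
9 fly, per-study hit counts in 1–100, genome-scale universes (20,000 /
6,000 / 14,000), ~50% orthology coverage for non-worm hits (the curated
corpus maps 27% of yeast and 70% of fly identifications), a 5% one-to-many
rate, 34 planted shared regulators appearing in 2–5 studies each, and a
12-class functional vocabulary. Species identifier styles are imitated
(worm sequence names with optional isoform-letter noise, fly `CG#####`,
yeast `Y...W`) so normalization is exercised realistically.

Planted genes are *guaranteed* to appear, via orthology, in their assigned
studies; the coverage fraction therefore thins only background mappings.
The coverage-monotonicity property is accordingly tested on the mapped
fraction of calls rather than on planted recall, which is 1 by construction
whenever planting is feasible (infeasible configurations error before any
file is written). Paralogue pairs are planted as one non-worm source gene
with two worm orthologues and identical study evidence, which is exactly
the condition `group_paralogue_entries()` tests for.

`disjoint_background = TRUE` forces background source genes *and* their worm
targets to be drawn without replacement globally, making the planted set the
unique overlap; this is what turns "recall = precision = 1" into an exact,
assertable property rather than a high-probability event. With independent
backgrounds (the default) incidental overlaps can and should occur; 100
null-generated datasets (nothing planted) give a roughly uniform p-value
distribution in the acceptance suite.

What a green synthetic test does *not* establish: the generator draws hits
uniformly, so it validates bookkeeping (projection, union, dedup, grouping,
counting), not robustness to real screens' biases, batch effects of
curation, or orthology-map errors.

## Numerical and design choices

* **Deterministic outputs.** Orthologue sets, overlap entries and all written
  tables are lexicographically ordered; byte-identical reruns are a test.
* **Union semantics for orthology evidence.** Groups files and pairwise
  tables merge by union with no confidence weighting, matching how pooled
  database/BLAST curation was used upstream. Worm genes never expand to worm
  paralogues through the map (identity only); paralogy enters only through
  explicit grouping.
* **Counts validate loudly, mismatches warn.** A hit list whose length
  disagrees with the catalog's reported count warns rather than fails —
  published counts and supplementary lists are known to disagree (one fly
  study reports 32 modifiers but 34 worm orthologues, a one-to-many
  expansion). Structural problems (missing columns, duplicate study ids,
  alias conflicts, out-of-vocabulary classes, within-species "ortholog"
  rows) are hard errors.
* **Expression flags.** Curated strings `Yes/yes`, `No`, `No?`, `?` normalize
  to `yes/no/unknown` with `No?` → `no` and `?` → `unknown`; genes absent
  from the table are `unknown`, never dropped.
* **Effect direction** (suppressor/enhancer) is carried through evidence but
  ignored for overlap membership; the curated overlap table does not require
  concordant direction.
* **Disease models** are a closed five-code vocabulary (P, S, T, SOD,
  Abeta); polyQ constructs of any repeat length and SCA constructs share
  code P. A study testing two models is one study for overlap counting.
* **Human orthologue labels.** Labels stated in the source text or its
  interaction figure are tagged as such in the fixture; the remainder are
  standard database symbols shipped as a clearly marked curated-synthetic
  stand-in for the unavailable supplementary table.

## Known limitations

* The full 624-gene distinct catalog of the curated corpus requires the
  original per-study supplementary hit lists, which are not shipped; the
  package proves the corresponding machinery on ground-truthed synthetic
  corpora and enforces the conservation bound (distinct union ≤ sum of
  per-study distinct counts) everywhere.
* The null model treats studies as exchangeable uniform samplers; p-values
  should be read as a calibrated "more than independent-uniform chance"
  statement, not as a model of screen biology.
* Orthology quality is taken on faith from the supplied maps; there is no
  scoring, no reconciliation beyond union, and no inference for genes absent
  from the maps.
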