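---
title: "Predicting food-drug interactions on homogeneous chemical similarity graphs"
author: "fdinet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting food-drug interactions on homogeneous chemical similarity graphs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fdinet)
```

## The problem and the modelling idea

Food–drug interactions (FDIs) are poorly catalogued: unlike drug–drug or
drug–target interactions there is no sizeable curated benchmark. The
modelling idea in `fdinet` is to sidestep the missing ground truth by
making the graph *homogeneous*: every node is a chemical structure —
either a drug or a food-compound instance — and every edge is a structural
similarity. Because all nodes are the same type, the drug–drug similarity
subnetwork (where external interaction knowledge *does* exist) can be used
to measure how well a link-prediction method recovers held-out edges, and
that measurement transfers to the food–drug portion of the same graph.

## Dataset construction

**Drugs.** A DrugBank-dialect XML is filtered to drugs that are in the
`approved` group, of `small molecule` type, and carry at least one
drug-interaction description mentioning metabolism. The metabolism rule is
a case-insensitive keyword match on the description text
(`metabolismPattern` argument): the source databases describe
"metabolism (increase or decrease)" interactions in prose, and a keyword
match is the reproducible stand-in for that prose category. FDIs
predominantly act through metabolic mechanisms, which is why the drug set
is restricted this way. Drugs without a SMILES are excluded with a
warning.

**Food compounds.** Composition records survive when the citation type is
`DATABASE` and the source type is `COMPOUND` (discarding text-mined and
nutrient rows), when they map to a compound with a SMILES and a usable
content amount, and — by default — when the compound has at least one
reported health effect (`healthEffectFilter = FALSE` relaxes this for
corpora without a health-effect table). Each surviving (food, compound)
pair becomes one node named `FOODxxxx_FDBxxxxx_CompoundName`; the same
compound in two foods is deliberately two nodes, because its content — and
therefore its interaction-relevant dose — differs per food.

**Contribution scores.** Within a food, a compound's contribution is

$$c_i = \frac{\text{content}_i}{\sum_j \text{content}_j}$$

with the sum running over the compounds that survived all filters. Summing
over *included* compounds (rather than asserting the total is 100 g/100 g)
is deliberate: filtering removes records, so renormalization is required
for the scores to lie in [0, 1] and sum to one per food. Content is in
mg/100 g. When a source reports a content *range* rather than a scalar,
the range collapses via `contentRangeMode`: `"max"` (default — the
conservative choice for interaction risk, since the question is whether a
food *can* carry enough of a compound to matter), `"min"`, or `"mean"`.
This is a genuine ambiguity in range-valued sources, which is why it is a
configuration option rather than a constant.

## The similarity graph

Fingerprints are Morgan/circular fingerprints of radius 2 hashed to 2048
bits — the standard ECFP4 configuration. The bit length is an
implementer's convention (sources rarely state it); both radius and
length are arguments. Fingerprinting is delegated to RDKit through one
batched Python subprocess per node set; everything downstream is computed
in R. Similarity is the Tanimoto coefficient, defined as 0 when both bit
sets are empty, and pairs with an empty fingerprint score 0 rather than
erroring so one exotic molecule cannot abort a batch.

Two thresholds shape the graph:

* **Tanimoto threshold** (`tanimotoThreshold`, default 0.6, inclusive
  $\ge$). Most pairwise similarities fall between 0.3 and 0.6; 0.6 keeps
  the graph sparse without starving it, and published practice for
  Tanimoto cutoffs spans roughly 0.5–0.85.
* **Contribution-stage threshold** (`contributionThreshold`, default 0.5;
  0.3 for a deliberately more diverse "relaxed" batch), applied after each
  edge's score is multiplied by its pair contribution factor: 1 for
  drug–drug pairs (similarity is preserved), the compound's contribution
  for drug–food pairs, and the *larger* contribution for food–food pairs.
  Whether this second threshold reads the updated weight or the raw
  Tanimoto score is ambiguous in the procedure's narrative; the package
  defaults to the updated weight and exposes `on = "score"` as the other
  reading.

Thresholding leaves disconnected components (the **disjoint** graph). Some
neighborhood scorers are uninformative across components, so `joinify()`
builds the **joint** variant: components are chained in seeded random
order, one uniformly chosen node per component, with bridge edges of
weight `1e-5` — small enough to be near-inert in weighted scoring. A chain
is used because the construction only requires connectivity; it adds the
fewest edges (components − 1) and the least artificial structure. Bridges
are tagged: evaluation never treats them as recoverable links, and
shortest-path predictions whose minimal path crosses a bridge are flagged
(`uses_bridge`) and can be excluded (`excludeBridgePaths`).

## Link-prediction scorers

**Shortest-path (SP_2, SP_3).** Dijkstra finds, for every non-adjacent
pair, the path minimizing the *sum of similarity weights*; pairs whose
minimal path has exactly 2 (or 3) edges are emitted with that sum as the
score. Because minimizing a similarity sum prefers *weak* paths, the final
ranking is taken in descending score order, preferring candidates backed
by higher similarity. The alternative treatment — invert the scores into
dissimilarities and rank ascending — is available as `invertRank = TRUE`.
Two further choices are worth recording: only the single Dijkstra-minimal
path is scored (no aggregation over equal-length alternatives), and pairs
already adjacent in the training graph are never emitted, since
predictions must be new links.

**Neighborhood indices.** With $\Gamma(\cdot)$ the neighbor set and $k_z$
the degree of a common neighbor $z$:

* common neighbors $|\Gamma(a)\cap\Gamma(b)|$;
* Adamic–Adar $\sum_z 1/\log k_z$ — natural logarithm by default (the
  convention in network science when no base is stated; `logBase` is an
  argument). A common neighbor of degree ≤ 1 is impossible in a
  well-formed graph and is guarded to contribute 0 with a warning;
* resource allocation $\sum_z 1/k_z$;
* Jaccard and Dice, with the identity $\mathrm{Dice} = 2J/(1+J)$;
* L3 $= \sum_{a\!-\!u\!-\!v\!-\!b} A_{au}A_{uv}A_{vb}/\sqrt{k_u k_v}$ over
  simple 3-edge paths, where $A$ is the *weighted* adjacency and $k_u,
  k_v$ are unweighted degrees.

Except for L3, the neighborhood indices read only the unweighted neighbor
structure of the thresholded graph — edge weights enter those scorers
nowhere, which is a known limitation of the family. Methods emit only
pairs with positive score (a pair with no common neighbor or no 3-path
carries no evidence and is not a prediction). Ranking is descending by
score with lexicographic `(node_a, node_b)` tie-breaking, so ranks are
deterministic and permutation-invariant.

## Evaluation protocols

`splitLinks()` removes a seeded random fraction (default 0.3) of eligible
links — drug–drug only, or all links; never bridges — and the four
`runEvaluation()` harnesses are: (1) DD-link recovery with every method;
(2) recovery of links that are additionally present in an external
known-DDI list; (3) recovery over all link types; (4) recovery of a
gold-standard list of (food, drug) pairs that were never in the graph,
matched after `aggregateFoodLevel()` reduces compound-level predictions to
per-(food, drug) maxima. Protocols 1–3 repeat 10 times by default and
report mean ± sd.

Metrics: precision@top-k for k = 1%, 2%, 5% of the ranked list, with
$k = \lceil \mathrm{percent} \times n \rceil$ (the ceiling guarantees
$k \ge 1$; the rounding rule is otherwise unstated in the procedure's
description). The confusion sweep walks thresholds from the minimum to the
maximum predicted score in steps of 0.1 (the maximum is appended if the
grid misses it); "above threshold" is strict (>), matching the stated
rule, and held-out links the method never proposed count as false
negatives at every threshold — they are known links the method failed to
find. AUC is the trapezoid over (FPR, TPR) with (0,0) and (1,1) anchors so
the integral is well defined when the grid does not reach the extremes;
the PRC area is the trapezoid over (recall, precision) after dropping
points with undefined precision (tp + fp = 0). Because the score scales
differ across methods (counts for CN, sums for SP), a fixed 0.1 step
yields method-dependent grids — a comparability caveat inherited from the
procedure, not corrected here. The degenerate single-threshold case
returns counts without areas.

## Synthetic data: what it emulates and what it does not

The fixture generator (`fixtureSpec()`, `generateDrugbankFixture()`,
`generateFoodbFixture()`) emits byte-reproducible corpora containing
exactly the fields the filters read: drug type and group, interaction
descriptions (a seeded fraction mentioning metabolism — the default
world has half the approved small molecules qualifying, plus 10% biotech
and 10% experimental distractors), SMILES properties, and content rows
that deliberately violate one filter each (ARTICLE citation, NUTRIENT
source, missing content, missing SMILES, missing health effect). Content
amounts are uniform on [1, 1000] mg/100 g, the scale on which real
composition examples live (phytic acid: thousands of mg/100 g). SMILES
come from a vetted list of real molecules (ethanol first) extended by
homologous decorated chains, so similarity values are genuine ECFP4
Tanimoto coefficients, not stubs.

What the fixtures do *not* emulate: realistic food compositions, the size
and similarity distribution of the licensed corpora, or their curation
quirks. A green test therefore establishes that the machinery — filters,
normalization, thresholds, scorers, protocols — is correct, not that the
headline performance numbers of any published full-corpus analysis are
reproduced; those depend on data that cannot ship with a package.

The `planted_partition` toy graph is the evaluation workhorse: 150 nodes
in two clusters, within-cluster edge probability 0.6, across 0.05, weights
uniform on [0.6, 1]. The parameters were chosen a priori by a power
argument: a Tanimoto threshold of 0.6 carves dense blocks out of a
chemical similarity matrix (high within-block density), while incidental
cross-block similarity is sparse; under those densities a
common-neighbor-based scorer concentrates its top ranks on within-cluster
pairs, where the removed links live, and a random ranking spreads over the
much larger candidate pool — so recovery beats chance with a comfortable
margin, which is exactly what a recovery benchmark should be able to
detect.

## Numerical and reproducibility choices

* Thresholds are inclusive ($\ge$), matching the ">= 0.6" convention;
  zero-similarity pairs are always dropped.
* Unordered pairs are stored canonically (`node_a < node_b`); ranking ties
  break lexicographically; all randomness (fixtures, bridges, splits)
  flows from one seed through `stageSeed()`, a documented hash that keeps
  every derived seed a valid 32-bit integer and lets a stage be re-run in
  isolation.
* Degenerate inputs fail loudly and specifically: a food whose included
  contents sum to zero names the food; a food-compound node without a
  contribution names the node; removing all eligible links is an error.
* The resolved configuration is written beside every pipeline run, and two
  runs from the same configuration produce byte-identical summaries.

## Limitations

* Neighborhood scorers ignore edge weights (L3 excepted); a weighted
  reformulation is future work.
* SP_2 and SP_3 are scored separately; no accumulated path score is
  offered, so SP_3's weak standalone ranking is visible rather than
  blended away.
* The explicit food-item-node representation (foods as nodes linked to
  their compounds by contribution-weighted edges) is not implemented; the
  package works at compound level and reports food-level results by
  aggregation, which loses within-food interaction structure.
* Fingerprinting requires a Python RDKit on the PATH; there is no pure-R
  fallback because no installed R chemistry toolkit provides ECFP4.
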