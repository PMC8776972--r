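# fdinet

Food–drug interactions (FDIs) arise when dietary constituents alter the
pharmacokinetics or pharmacodynamics of a drug — grapefruit juice slowing
cyclosporine metabolism, vitamin K antagonizing warfarin. Curated FDI
databases barely exist, so `fdinet` treats FDI discovery as **link
prediction on a homogeneous chemical graph**: every node is a chemical
entity (an approved small-molecule drug, or one food-compound instance per
food), so known drug–drug interactions can stand in as ground truth for
evaluating food–drug predictions made on the very same graph. The package
is aimed at cheminformatics and pharmacology researchers who want to rank
candidate FDIs from structure and composition data alone.

## The model

1. **Nodes.** Drugs are filtered to approved small molecules with at least
   one metabolism-related interaction description. Food compounds come from
   composition records (citation type `DATABASE`, source type `COMPOUND`,
   mapped to a compound with a SMILES and a reported health effect), one
   node per compound *per food*: `FOOD00005_FDB000633_Kaempferol` and
   `FOOD00008_FDB000633_Kaempferol` are distinct nodes.

2. **Edges — structure similarity profile.** Every unordered pair gets a
   Tanimoto coefficient T(a,b) = |A∩B| / |A∪B| over Morgan/ECFP4
   fingerprints (radius 2, 2048 bits), labelled DD / FF / FD by node kinds.
   Pairs with T ≥ 0.6 survive thresholding.

3. **Composition re-weighting.** Each compound's contribution within its
   food is its content divided by the food's total content over included
   compounds (so contributions sum to 1 per food). An edge's weight becomes
   `score × factor` where the factor is 1 for DD pairs, the compound's
   contribution for FD pairs, and the larger contribution for FF pairs. A
   second, more relaxed threshold (default 0.5) is applied to the updated
   weight.

4. **Disjoint vs joint graphs.** Thresholding leaves disconnected
   components ("disjoint"). The "joint" variant chains all components with
   near-inert bridge edges of weight 1e-5 (one random node per component),
   so neighborhood scorers can operate globally; bridges never count as
   recoverable links.

5. **Scorers.** Shortest-path scores SP_2 / SP_3 (Dijkstra minimum
   weight-sum paths of exactly 2 or 3 edges; ranked descending, preferring
   higher similarity support) and six neighborhood indices over common
   neighbors Γ: Adamic–Adar Σ 1/log k_z, common neighbors |Γ(a)∩Γ(b)|,
   Jaccard, resource allocation Σ 1/k_z, Dice, and the degree-normalized
   3-path score L3 = Σ A_au A_uv A_vb / √(k_u k_v).

6. **Evaluation.** Remove a random 30% of links (drug–drug only, or all),
   re-predict, and score the ranking by precision@top-1/2/5%, a
   threshold-sweep confusion procedure (step 0.1 from the minimum to the
   maximum score), trapezoidal AUC and precision–recall area; plus a
   gold-standard recovery protocol with food-level aggregation.

## Worked example

Everything is runnable offline: the fixture generator emits a seeded
DrugBank-dialect XML and FooDB-dialect JSON corpus, and the pipeline runs
end to end on it.

```r
library(fdinet)
cfg <- runConfig(outDir = file.path(tempdir(), "run"),
                 fixtures = fixtureSpec(nDrugs = 25, nFoods = 4,
                                        fractionMetabolismDdi = 1, seed = 5),
                 graphVariant = "joint", methods = c("sp2", "ra"), seed = 11)
res <- runPipeline(cfg)
#> stage ingest: 21 drugs, 13 food-compound nodes
#> stage ssp: fingerprinting 34 nodes (radius 2, 2048 bits)
#> stage graph: 21/561 pairs pass Tanimoto >= 0.6
#> stage graph: 5 edges pass contribution-stage threshold >= 0.5
#> stage predict: method sp2
#> stage predict: method ra

res$graph
#> SimilarityGraph: 34 nodes (21 drugs, 13 food compounds), 33 edges
#>   subnetworks: DD=14 FF=4 FD=15; bridges=28; components=1

head(res$predictions$ra, 3)
#>    node_a                           node_b method score rank uses_bridge
#> 1 DB00001                          DB00004     ra   0.5    1       FALSE
#> 2 DB00001                          DB00016     ra   0.5    2       FALSE
#> 3 DB00002 FOOD00003_FDB000005_Compound_005     ra   0.5    3       FALSE
```

Of the 25 requested drugs, 21 survive the approved/small-molecule/
metabolism filter (the rest are biotech or experimental distractors); 21 of
the 561 node pairs clear the Tanimoto threshold and 5 edges survive
contribution re-weighting, after which 28 bridges connect the components
into one joint graph. The top resource-allocation predictions are
non-adjacent pairs sharing one common neighbor of degree 2 (score
1/2): two drug–drug candidates, then a drug/food-compound candidate.

The composition rule on its own:

```r
entries <- data.frame(
  food_id = "FOOD00006", compound_id = c("FDB000474", "FDB000556"),
  node_id = c("FOOD00006_FDB000474_L-Lysine", "FOOD00006_FDB000556_L-Alanine"),
  orig_content = NA, contribution = c(0.007301117, 0.009780473))
pairContribution("FOOD00006_FDB000474_L-Lysine",
                 "FOOD00006_FDB000556_L-Alanine", entries)
#> [1] 0.009780473
```

A food–food similarity edge between these two compounds is rescaled by the
larger of the two contributions.

A command-line wrapper with subcommands `fixtures`, `ingest`, `ssp`,
`build-graph`, `predict`, `evaluate` and `run-all` is installed at
`inst/scripts/fdinet.R`.

## Acceptance script

`scripts/acceptance.R` recomputes the package's acceptance quantities from
scratch by running the installed package (currently: the food–food pair
contribution factor for the worked FOOD00006 L-Lysine / L-Alanine example)
and writes them as JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

## Documentation

The methods vignette (`vignettes/food-drug-graphs.Rmd`) describes the
model, its parameters and defaults, the synthetic-data design, numerical
choices and known limitations.
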