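# decoybench

Negative-data benchmarks and recovery analytics for virtual screening.

## The problem

Virtual high-throughput screening (VHTS) pipelines are funnels: docking
first, then increasingly expensive rescoring (MM-GBSA/MM-PBSA, free-energy
methods) on an ever smaller pool of molecules. Validating such a pipeline
needs *negative* data — ligands known (or safely presumed) not to bind — in
quantity, and decoys whose molecular properties match the actives; otherwise
enrichment numbers are inflated by property bias rather than earned by the
scoring method. Experimentally measured inactives are expensive and never
property-matched. `decoybench` builds negative data computationally, two
ways, and evaluates any scoring stage on the result:

1. **Randomized pairing.** Every ligand of a curated protein–ligand
   structure collection is paired with noncognate protein structures.
   The positive and negative ligand sets then contain *the same molecules*,
   so property matching is perfect by construction, and every ligand and
   every protein serves as its own control. Because structure collections
   are degenerate (several entries can share one protein accession), a
   "random" pairing can silently be a true binder; `decoybench` relabels
   those cases from the protein-identity annotations.
2. **Constitutional-isomer decoys.** For each active, the package
   enumerates connected heavy-atom structures with the same molecular
   formula (its constitutional isomers), filters chemically unreasonable
   ones (cumulated double bonds in small rings, optionally more), and
   samples a seeded decoy set. Isomers share the active's formula and
   weight exactly, and sit close in donor/acceptor/rotor space.

Scoring output from external tools (docking scores, CNN pose scores,
MM-GB(PB)SA enthalpies, RMSDs) enters as long-format tables, usually from
several independent replicas of a stochastic scoring stage. The analytics
are replica-aware:

- **Recovery curves** — sorted score vs. rank with a 95% band: at each rank
  r the band summarises the r-th best score across replicas,
  mean ± t(0.975, R−1)·SE (or a min–max envelope).
- **Rank confidence intervals** — for a compound with per-replica ranks
  r₁…r_R: mean ± t(0.975, R−1)·SE, rounded outward and clipped to [1, N′].
- **Enrichment factor** — EF(x) = (a_top/n_top)/(A/N′) with
  n_top = ⌈x·N′⌉; EF is 1 in expectation for a random ranking and
  (min(n_top, A)/n_top)/(A/N′) for perfect separation.
- **Violin summaries** of active ranks per metric, and mean/best replica
  aggregation with a registered better-direction per metric.

Seeded synthetic generators (score tables with planted active/decoy
separation and per-replica noise; structure collections with controlled
identity degeneracy) make the whole stack testable without running any
docking.

## Worked example

```r
library(decoybench)
library(dplyr)

# --- randomized-pairing benchmark: 29 structures, 25 noncognate ligands
#     each, identity degeneracy planting 26 cross-structure binders
coll  <- generate_synthetic_collection(29, degeneracy_groups(29, 26), seed = 1)
pairs <- build_randomized_pairs(coll, 25, seed = 1, force_same_identity = TRUE) |>
  relabel_by_identity(coll)
summarize_set(pairs)
#>   n_pairs n_redock n_crossdock n_binder n_decoy ratio
#> 1     754       29         725       55     699 1:13

# --- analytics on a synthetic 78-compound score table (3 actives,
#     75 decoys, 4 replicas, 1.5 kcal/mol planted separation)
scores <- generate_synthetic_scores(
  synthetic_score_config(shift = 1.5, noise = 0.3, seed = 42))
rk <- aggregate_replicas(scores, "gnina_affinity", "mean")

recovery_positions(rk, scores)      # where the actives landed
#>   pair_id  rank
#> 1 ACT002      5
#> 2 ACT003     12
#> 3 ACT001     31

enrichment_factor(rk, scores, 0.10)[, c("n_top", "n_actives_top", "ef", "ef_max")]
#>   n_top n_actives_top    ef ef_max
#> 1     8             1  3.25   9.75

rank_confidence(scores, "gnina_affinity", pairs = c("ACT001", "ACT002", "ACT003"))
#>   pair_id n_replicas point lower upper width
#> 1 ACT001           4 31.50    15    48    33
#> 2 ACT002           4  5.25     3     7     4
#> 3 ACT003           4 13.00     9    17     8
```

Reading: the top 10% of 78 compounds is ⌈7.8⌉ = 8 compounds; one of the
three actives made that cut, so EF(10%) = (1/8)/(3/78) = 3.25 against a
maximum of 9.75. The rank intervals show how far a stochastic scorer can
move a compound between replicas at this noise level — ACT001 anywhere
between rank 15 and 48 with 95% confidence.

Isomer decoys, one line:

```r
ds <- sample_decoys(mol_from_smiles("CCCCCCO", id = "hexanol"),
                    n_per_active = 25, seed = 1)
glance(ds)         # 1 active, 25 decoys, ratio "1:25"
property_match_report(ds)   # mw gap across the set: exactly 0
```

Plots: `autoplot(score_band(scores, "gnina_affinity"))`,
`plot_rank_violins(scores, c("gnina_affinity"))`,
`plot_rank_intervals(rank_confidence(scores, "gnina_affinity"))`.

A command-line front end (subcommands `randomize`, `label`, `summarize`,
`isomers`, `match-report`, `simulate-scores`, `rank`, `recover`, `enrich`,
`manifest`) lives at
`system.file("cli", "decoybench.R", package = "decoybench")`.

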