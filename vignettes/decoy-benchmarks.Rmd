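---
title: "Building negative-data benchmarks and reading replica-aware recovery analytics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building negative-data benchmarks and reading replica-aware recovery analytics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(decoybench)
library(dplyr)
```

Structure-based virtual screening pipelines are validated by how early they
surface known binders in a ranked list. That measurement is only as good as
its negative data: decoys must be plentiful and property-matched to the
actives, or the apparent enrichment reflects property bias rather than the
scoring method. This package builds negative data computationally — by
randomizing ligands over noncognate protein structures and by enumerating
constitutional isomers of the actives — and evaluates scoring output with
analytics that take the stochasticity of docking and MD replicas seriously.
This vignette records the models, the conventions, and the reasoning behind
the choices that were genuinely open.

## The molecular model

Molecules are heavy-atom graphs: element labels, formal charges, explicit
Kekulé bond orders (1–3) and an implicit hydrogen count per atom. There is
no aromaticity perception anywhere — benzene is a cyclohexatriene graph —
because both isomer enumeration and the sanity filters are defined on
explicit bond orders, and a Kekulé representation makes every rule exact.
Hydrogens stay implicit internally (enumeration operates on heavy atoms
only) and are materialised as explicit atoms on SDF export, which is what
docking preparation tools expect. SMILES input in aromatic (lowercase) form
is kekulized through Open Babel when `ChemmineOB` is available; stereo
markers are dropped on input since only constitution is modelled.

Default valences are C 4, N 3, O 2, S 2, P 3, halogens 1; hypervalent
sulfur (4/6) and phosphorus (5) are opt-in flags of the enumerator, which
keeps drug-like chemical space as the default without silently exploding
the search. Formal charge shifts the cap where that is textbook behaviour
(ammonium nitrogen counts 4, alkoxide oxygen 1).

Property descriptors follow the simplest defensible conventions, pinned by
the test suite rather than left to a black box:

* donors: N/O atoms bearing at least one hydrogen;
* acceptors: every N and O; an optional `amide_rules` flag excludes amide
  nitrogens and pyrrole-type ring nitrogens;
* rotatable bonds: single, non-ring bonds whose two ends both have
  heavy-atom degree ≥ 2 (so terminal methyls and hydroxyls do not count);
  the same flag excludes amide C–N bonds;
* ring count: cyclomatic number of the heavy-atom skeleton;
* weights from IUPAC 2021 standard atomic masses, reported to two
  decimals.

These conventions match Open Babel's counts on the molecules the tests
cross-check. Molecular surface areas, logP, protonation and tautomer
states, and all 3D properties are out of scope; protonation in particular
is delegated to external preparation tools.

## Enumerating constitutional isomers

The enumerator answers: *given a molecular formula, what are all connected
heavy-atom structures consistent with the valences?* Because every atom's
free valence is filled with hydrogens, the hydrogen count of the formula
fixes the total bond order exactly:

$$B \;=\; \tfrac{1}{2}\Big(\sum_i v_i - n_H\Big),$$

where \(v_i\) are the heavy-atom valences. A formula is infeasible when
\(B\) is negative, fractional, or below \(n-1\) (connectivity); the result
is then an explicit empty set, not an error.

Generation is an orderly depth-first search over the upper triangle of the
bond-order matrix: atoms are sorted into element classes, pairs are visited
in fixed row-major order, and each pair receives an order 0–3 under
residual-valence and bond-budget pruning. Two symmetry devices keep the
search tractable:

1. a *connected-growth rule*: within an element class, atom \(j\) may
   receive its first bond only after atom \(j-1\) has one (the
   lexicographically maximal representative of every isomorphism class
   survives this rule, so no class is lost);
2. *canonical-form rejection*: each completed connected structure is
   reduced to a canonical string (a BLISS canonical labeling of a
   vertex-coloured expansion where every bond becomes an auxiliary vertex
   coloured by its order) and kept only if unseen.

Output is sorted by canonical form, so enumeration order is deterministic,
and truncation at `max_isomers` cuts a fixed search order — identical
inputs always give identical output. The tests hold the enumerator to a
deliberately naive second implementation (exhaustive labeled-matrix
enumeration with a backtracking isomorphism matcher, no canonical forms)
on a panel of small formulas, and to the published isomer counts of the
alkane series.

```{r enum}
length(enumerate_isomers("C6H14"))   # the five hexanes
attr(enumerate_isomers("CH5"), "feasible")
```

### Sanity filtering

Raw enumeration admits valence-legal but chemically unreasonable
structures; the dominant offenders are cumulated double bonds (an atom
carrying two double bonds) inside small rings. Filter rules are named,
enabled individually, and applied first-match-wins so each rejection is
attributable to exactly one rule:

* `cumulene_in_ring` (default on): cumulated double bonds at an atom
  sitting in a ring of ≤ 8 members. The size threshold is a judgment
  call — small-ring cumulenes are geometrically strained while large-ring
  ones are known chemistry — and is configurable.
* `cumulene_any` (off): any cumulated double bonds; linear allenes pass
  when off.
* `triple_in_ring` (off): triple bonds in rings of ≤ 8 members.

Filtering is idempotent, and the report keeps the exact accounting
(`kept + rejected = input`).

### Decoy sampling and property matching

`sample_decoys()` draws, for each active, `n_per_active` isomers uniformly
without replacement from the filtered pool of the active's formula, after
removing anything isomorphic to an active. One integer seed governs all
sampling; enumeration itself is deterministic. When a pool is smaller than
the request, the whole pool is returned with a recorded shortfall rather
than silently fewer decoys. Uniform sampling is a choice: nothing forces a
particular policy for picking a few dozen decoys out of an isomer universe
that can be much larger, and uniformity is the neutral default.

`property_match_report()` summarises each descriptor for actives and
decoys side by side. For pure isomer decoys the molecular-weight gap is
exactly zero — that is the point of isomer decoys — while donor, acceptor
and rotor distributions remain close but not identical. The report
describes; it never judges.

## Randomized protein–ligand pairing

`build_randomized_pairs()` gives every structure its own cognate ligand
back (a redocking pair, a guaranteed binder) plus *k* noncognate ligands
drawn uniformly without replacement (crossdocking pairs, presumed decoys).
Uniform, per-structure-independent sampling under one global seed is again
the neutral choice. Structure collections are frequently degenerate —
several entries share one protein accession — so a random pairing can
silently be a true binder. `relabel_by_identity()` applies the known-binder
relation: by default the cognate relation expanded over identity
duplicates (each ligand binds its source structure's protein identity,
hence any other structure of that identity), extensible with user-supplied
known binders. Relabeling changes labels only, never membership, and is
idempotent.

A 29-structure collection with 25 crossdock ligands per structure yields
754 pairs. How many crossdocks the relabeling flips to binders depends on
which ligands the randomization happens to deal onto degenerate
structures. For a *fixture* that must reproduce a fixed accounting, that
is the wrong kind of randomness, so the synthetic collection generator
controls it: `degeneracy_groups(n, b)` assembles identity-group sizes g
with \(\sum g(g-1) = b\), and `build_randomized_pairs(...,
force_same_identity = TRUE)` always includes same-identity ligands among a
structure's crossdock draw (the remaining slots stay random). The planted
count is then exact and seed-independent:

```{r random}
coll  <- generate_synthetic_collection(29, degeneracy_groups(29, 26), seed = 1)
pairs <- build_randomized_pairs(coll, 25, seed = 1, force_same_identity = TRUE) |>
  relabel_by_identity(coll)
summarize_set(pairs)
```

The summary ratio is reported as `"1:r"` with r the nearest integer to
decoys/actives (here 699/55 = 12.7, printed 1:13). Binding-site
definitions, docking boxes and the docking runs themselves are not
modelled; `docking_manifest()` emits the per-pair job list an external
docking stage needs, and `protocol_manifest()` does the frame arithmetic
for MD stages (`floor(length/interval)`, frame 0 excluded: 25 ns sampled
every 100 ps is 250 frames).

## Replica-aware recovery analytics

Stochastic docking and quasiergodic MD give different answers on each run,
so scoring stages are run in R independent replicas and the analytics
treat the replica spread as the uncertainty of the ranking. Conventions,
all pinned by tests:

* Rank 1 is the best score in the metric's registered direction; ties
  break by pair id lexicographically, so rankings are reproducible.
* Pairs without a value under a metric/replica are excluded (N′ < N) and
  listed in a completeness report — no imputation. This mirrors how failed
  MD runs are handled in practice.
* Replica aggregation is `mean` or `best` (min for lower-is-better, max
  for higher-is-better).
* Rank intervals: per-replica ranks, mean ± t(0.975, R−1)·SE, rounded
  *outward* (floor/ceiling) and clipped to [1, N′]. With R as small as 4
  the t-interval is the defensible parametric option, but since the
  construction is a judgment call it is pluggable: `ci = "range"` gives
  the conservative min–max envelope. Identical replicas collapse to
  zero-width intervals.
* Score bands: at each rank r, the r-th best score from each replica is
  summarised the same way; the mean curve is monotone in the metric's
  direction by construction. Replicas of unequal coverage are aligned on
  the pairs present in all of them, with dropped pairs reported.
* Active placements are computed both as *rank of mean scores* and *mean
  of per-replica ranks*; the two coincide exactly for identical replicas
  and may legitimately differ otherwise — both are reported.
* Enrichment: EF(x) = (a_top/n_top)/(A/N′) with n_top = ⌈x·N′⌉ (ceiling,
  so the top 10% of 78 compounds is 8). EF is undefined without actives
  and says so explicitly.
* Violin summaries use linear-interpolation quantiles (R's default
  type 7), pooled across all actives or kept per active — both poolings
  exist because either can be the right picture depending on whether
  individual actives are tracked.

## The synthetic score generator

`generate_synthetic_scores()` emulates the *shape and statistics* of a
scored benchmark, not any particular docking engine: each pair has a
latent base score (decoys from a normal distribution, actives shifted by
δ toward the metric's better end) and each replica observes the base score
plus independent Gaussian noise σ. The defaults — 3 actives, 75 decoys, 4
replicas of a predicted-affinity metric centred at −6 kcal/mol with 1
kcal/mol spread, δ = 2 and σ = 0.3 kcal/mol — describe a small,
isomer-decoy-sized benchmark with a clear but imperfect planted signal.

Two analytic anchors calibrate the stack: at δ = 0 the actives are
exchangeable with decoys and EF(10%) has expectation 1 (the tests check
the mean over 200 seeds against three Monte-Carlo standard errors); as
δ/σ grows, all actives occupy ranks 1..A in every replica and EF attains
its analytic maximum, (min(n_top, A)/n_top)/(A/N′) = 9.75 for the
78-compound shape.

What the generator does *not* emulate — and therefore what passing tests
cannot show about real data: correlation between metrics and between
replicas, heavy-tailed or multimodal score distributions, pose-dependent
failure patterns (missingness here is injected at random in tests, not
coupled to scores), and any structure–score relationship at all. It
validates the arithmetic and the statistical behaviour of the analytics,
not the chemistry of any scoring function.

## Problem sizes and numerical notes

The shipped tests and the acceptance script run at desk scale, chosen so
the whole suite completes in well under an hour on one core: enumeration
oracles on formulas up to 6–7 heavy atoms, fixture actives with 6–7 heavy
atoms (isomer pools of 32–74 after filtering), the 29-structure/754-pair
randomization, 78-compound score tables, and 200-seed null calibrations.
Enumeration beyond ~12 heavy atoms grows combinatorially; `max_isomers`
truncates reproducibly, and sampling from a truncated pool is then a
documented approximation to uniform-over-universe sampling.

Degenerate inputs are handled explicitly rather than defensively:
infeasible formulas return empty feasible-flagged sets; empty molecules,
disconnected SMILES, valence violations and unknown filter rules are
structured errors naming the offence; EF without actives and rank
intervals with fewer than two replicas return flagged results. All
tabular output writers stamp tool version, seed and a configuration hash
into header comment lines, so every CSV is traceable to its settings.

## Known limitations

Stereochemistry is entirely outside the model: enantiomers and
diastereomers collapse to one constitution, which is the correct notion
for constitutional-isomer decoys but means decoy sets cannot distinguish
stereoisomeric actives. The sanity filters encode two motifs, not a
synthesizability model — genuinely strained or reactive structures beyond
cumulenes and small-ring alkynes pass. The isomer pathway assumes the
active's formula is small enough to enumerate meaningfully. And the
analytics rank whatever scores they are given; they cannot detect that an
upstream scoring stage was run with the wrong settings, only how well its
ranking recovers the labeled actives.
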