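---
title: "Scoring lipid reaction networks: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring lipid reaction networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lipidpath)
```

## The problem

A quantitative lipidomics table reports abundances of lipid molecular
species across replicated samples of two biological conditions. Enzymatic
regulation rarely moves one species in isolation: an activated
acyltransferase or phospholipase shifts the balance between its substrate
and product subclasses across all matching acyl compositions at once.
`lipidpath` turns an abundance table into calls on reaction steps and
reaction chains — *active* (shifted toward the product in the condition of
interest), *suppressed* (the reverse), or neither — and annotates each
call with the human genes encoding the catalysing enzymes.

## From names to a network

Species names are normalised to a subclass code plus a sum composition,
total carbons and double-bond equivalents over all chains. The parser is
total: any name it cannot resolve, or whose subclass is outside the
41-subclass registry, is classed *unrecognised* and reported, never
silently dropped. Conventions worth stating explicitly:

* chain-level compositions (`PC 18:0/20:4`) are summed; sn-positions,
  double-bond positions and stereochemistry are deliberately discarded;
* sphingoid `d`/`t` prefixes contribute hydroxyl count only (`d18:1` is
  18:1 with two hydroxyls, equivalently `18:1;O2`); the base and the
  N-acyl chain are summed like any other chains;
* ether linkages make distinct subclasses: `O-PC` is not `PC`. A
  plasmalogen `P-` prefix is normalised to `O-` with one extra double-bond
  equivalent, the common shorthand equivalence. This is a documented
  convention choice; the alternative (a separate `P-` registry branch)
  would double the ether inventory without changing any balance rule;
* legacy synonyms `DAG`/`TAG`/`MAG` map to `DG`/`TG`/`MG`.

The reaction database ships as three TSV files (registry, reactions,
named subsets) so users can inspect, diff or override it. It covers the
mammalian glycerophospholipid, glycerolipid and sphingolipid
interconversions plus an explicit fatty-acid elongation/desaturation
network: 94 reactions over 41 subclasses. Three curation points are
deliberate:

* **Composition-specific fatty-acid steps.** Elongases and desaturases are
  chain-length- and unsaturation-specific (ELOVL2 elongates C20–22
  polyunsaturates, ELOVL6 saturates/monounsaturates, SCD introduces the
  first double bond), so fatty-acid reactions are enumerated as explicit
  species-level steps (`FA(22:5)->FA(24:5)`, annotated ELOVL2) rather than
  one generic +2-carbon rule. Matching a step requires both exact FA
  species in the file.
* **Collapsed CDP-DG routes.** Syntheses that traverse CDP-diacylglycerol
  (PA→PG, PA→PI, PA→PS) are single edges carrying the CDS genes together
  with the downstream synthase; no CDP-DG node is introduced, since the
  intermediate is rarely quantified in routine lipidomics.
* **Cardiolipin edges.** PG→CL and PC→CL are modelled as
  composition-preserving transfers because the balance-rule vocabulary has
  no condensation kind. Real CL sum compositions (four chains) seldom
  equal a PC/PG composition, so these edges will rarely instantiate; they
  are retained for datasets that report CL at half-molecule resolution.
  This is a known limitation.
* Gene lists follow the published reference annotations exactly where
  those exist, even where curation judgement might differ (the PG→LPG
  list includes CRLS1; the dhSM→dhCer step carries the sphingomyelin
  synthase genes SGMS1/SGMS2). Fidelity to the reference wins so that the
  gene-reproduction checks are meaningful.

Matching instantiates a reaction when the dataset contains species whose
compositions balance: equality for headgroup transfers and sphingolipid
headgroup steps, substrate + fatty-acid = product for acylation, the
symmetric rule for deacylation, +2 carbons for elongation, +1 double bond
for desaturation. Acylation chemically consumes a fatty-acyl chain, so it
only matches when a balancing FA (or fatty-acyl-CoA) species is present in
the file. Whether the *hydrolysis* direction should also demand the
released FA is genuinely open; the package requires it by default, keeping
the two directions symmetric, and exposes
`require_fa_for_deacylation = FALSE` for the permissive reading. The
dihydroceramide desaturation step (dhCer→Cer) is modelled as
composition-preserving, consistent with datasets that index dihydro
species by their N-acyl sum composition; users whose tables count the base
saturation in C:D will see that step fail to match.

## The statistical model

For an instantiated edge, the per-sample activity is

\[ a_j = \ln\frac{\sum_{p \in P} x_{pj} + \epsilon}{\sum_{s \in S} x_{sj} + \epsilon}, \]

the log of total product over total substrate abundance, with the
pseudo-count \(\epsilon\) set to half the smallest positive abundance in
the file so that occasional zeros do not produce infinities. The activity
is a flux *proxy*: it reflects the standing balance between pools, not a
measured rate. An alternative statistic, the product fraction
\(P/(P+S)\), sits behind the same `statistic` switch; the log-ratio is the
default because it is exactly normal under the multiplicative noise model
below and antisymmetric under swapping the conditions.

The reaction Z-score compares activities between conditions:

* unpaired: \(z = (\bar a_I - \bar a_C) / \sqrt{s_I^2/n_I + s_C^2/n_C}\)
  (Welch form, sample variances);
* paired: \(z = \bar d / (s_d/\sqrt{n})\) on per-pair differences.

The statistic is read on the standard-normal scale, so the default
significance level 0.05 corresponds to the one-sided threshold
z > 1.645, and \(p = 1 - \Phi(z)\). This normal-scale mapping is a
deliberate simplification: at small replicate counts the statistic is
t-distributed and the call is anti-conservative (the one-sided exceedance
of 1.645 is about 0.069 at n = 5 per group, 0.059 at n = 10, converging to
0.05 as n grows). The package documents rather than corrects this, because
the 1.645 correspondence is the method's stated contract; the calibration
test therefore checks the attained level at n = 100 per condition, where
the normal approximation holds, using roughly 2,300 mutually independent
null edges. No multiple-testing correction is applied — each edge and
chain is called marginally at the chosen alpha.

Degenerate cases are resolved deterministically: zero variance with equal
means gives z = 0; zero variance with unequal means gives a signed
infinite score whose status follows the sign; edges with fewer than two
usable replicates in either condition stay unscored. Samples in which
every contributing abundance is missing, or both sides are entirely zero,
are dropped for that edge with a warning.

Chains of k consecutive reactions combine by the Stouffer rule
\(z_{path} = \sum_i z_i / \sqrt{k}\), which preserves single-reaction
scores (k = 1) and is exactly invertible — `invert_chain_z()` recovers a
step score from a chain score, the consistency device used by the
package's reference checks. Pathway significance applies the same 1.645
threshold to \(z_{path}\).

## Enumeration and the most-active rule

Chains are simple directed paths (no repeated node) of one to `max_len`
reactions, seeded at every node. The default cap of 6 keeps enumeration
finite on the cyclic subgraphs the database contains (PC→DG and DG→PC
both exist) while exceeding the longest chains the reference tables
report (4 steps). Enumeration with a larger cap is a superset of a
smaller one, and chains of every length are reported simultaneously —
a one-step chain and its extensions can all be significant.

Where a substrate feeds several branches, the *most-active* view selects
one route per starting substrate by a greedy walk: at each node take the
sign-consistent continuation (positive scores for active routes, negative
for suppressed) with the highest |z|, never revisiting a node; ties break
toward the lexicographically smaller product label so the selection is
deterministic. The walk's combined score is then subject to the usual
threshold. Note that a branch rejected by the greedy rule can still be a
significant chain in the full enumeration — with step scores 3.083
(PC→DG), 2.054 (DG→MG) and −0.408 (DG→PA), the route PC→DG→MG (3.632) is
selected, yet PC→DG→PA (1.891) remains above threshold; the greedy view is
a display convention, not a claim that other routes are null.

## The synthetic-data generator

`simulate_dataset()` emulates the input the analysis consumes: every
species has a lognormal baseline (its own log-mean, common log-sd
`sigma`, default 0.2 — typical of well-replicated targeted lipidomics),
replicates are independent draws, and a planted effect multiplies the
product species of a named reaction by `fold` in the condition of
interest. Defaults are five replicates per condition, matching the
"three or more" recommendation with headroom. Under this generator the
log-ratio activity is exactly normal with mean shifted by ln(fold), giving
the closed-form expectation
\(E[z] \approx \ln(\text{fold}) / \sqrt{\sigma_a^2 (1/n_I + 1/n_C)}\)
used by the power oracle (a 2-fold effect at sigma = 0.1, n = 5 yields
E[z] ≈ 7.8, so ≥95% detection is expected and observed).

What the generator does *not* emulate — and hence what passing tests do
not establish about real data: heteroscedastic instrument noise,
correlated species (co-regulation beyond the planted edge), non-MCAR
missingness, batch effects, and compositional closure from total-signal
normalisation. The generator is a correctness instrument for the
statistical machinery, not a simulator of mass-spectrometry physics.

## Determinism and exports

Node and edge orderings are lexicographic everywhere; exports (node-link
JSON graph, TXT edge list, TSV result tables) are byte-stable for a fixed
input and configuration, with z fixed to three decimals in all rendered
output. The same seed reproduces a simulated CSV byte for byte.

## Problem sizes used by the checks

The bundled checks run at desk scale by design: panels of 5–40 species
for matching and scoring, 200 random strings for parser totality, 10
random panels (≤20 species) against the brute-force matching oracle, 50
seeds for the power check, 25 seeds per fold level for monotonicity, and
one 2,304-edge null network at n = 100 per condition for level
calibration. The end-to-end check plants a triacylglycerol accumulation,
a polyunsaturated-FA elongation and a suppressed ether-lipid deacylation
in one synthetic table and recovers all three through the CSV → network →
tables path.

## Known limitations

* Small-sample anti-conservativeness of the normal-scale mapping, as
  above; with two replicates per condition calls should be treated as
  exploratory.
* The activity statistic is a pool-balance proxy; it cannot distinguish
  increased forward flux from decreased reverse flux, and reactions
  sharing species produce correlated scores.
* Cardiolipin and other multi-chain condensations only match when the
  data's sum compositions happen to align with the preserving rule.
* Gene annotations are human symbols; for other species the user should
  map orthologues (mouse Pemt vs human PEMT and similar cases).
* No FDR control; the reported chains overlap heavily by construction
  (a chain and its sub-chains are all reported).
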