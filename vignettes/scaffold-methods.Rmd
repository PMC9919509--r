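---
title: "Character optimisation and fossil placement on a fixed scaffold"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Character optimisation and fossil placement on a fixed scaffold}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(morphoscaffold)
```

## The problem

Morphological matrices for hyper-diverse clades — the motivating case is a
set of 54 carpometacarpus characters scored across 132 extant passerines,
ten outgroups, and a handful of fragmentary Oligocene fossils — are too
homoplastic to resolve a reliable topology on their own. The productive
analysis design is therefore *scaffold-based*: extant relationships are
fixed to a phylogenomic backbone, characters are optimised onto that
backbone to diagnose clades, and only the fossils are free parameters, to be
placed by the data. `morphoscaffold` implements that workflow end to end:

1. **I/O** — NEXUS character matrices (discrete, continuous, mixed; ordered
   flags in an ASSUMPTIONS `TYPESET`; `(01)` polymorphisms), Newick trees,
   deterministic TSV reports.
2. **Parsimony optimisation** — exact minimum steps and full
   most-parsimonious-reconstruction (MPR) state sets for every node, for
   unordered, ordered, and continuous characters.
3. **Synapomorphy diagnosis** — a rule-based classifier for
   (clade, character, state) triples: unreversed synapomorphies, retained
   plesiomorphies, near-ubiquitous diagnostic states, ambiguity.
4. **Bayesian fossil placement** — Metropolis-coupled MCMC under the Mkv
   model with four-category discrete-gamma rate variation, branch-attachment
   posteriors, clade-membership posterior probabilities (BPPs), and 50%
   majority-rule consensus trees.
5. **Simulation** — a seeded generator of matrices and fossil rows with the
   statistical structure the analysis assumes, so every stage is testable
   without the original data.

## Parsimony optimisation

All discrete optimisation runs through the Sankoff dynamic programme, which
is exact for arbitrary symmetric step costs and — unlike the textbook
union/intersection Fitch pass — handles hard polytomies without special
cases. Unordered characters use unit costs (`fitch_optimise()` is that
special case); ordered multistate characters use `|i - j|` costs, the
standard encoding of transformation series that pass through intermediate
states.

MPR sets come from a down-pass/up-pass pair: state `s` belongs to node `v`'s
MPR set iff fixing `v = s` still admits a reconstruction at the global
minimum. We deliberately report full MPR sets rather than ACCTRAN/DELTRAN
resolutions, because the diagnosis rules reason from ambiguity ("the state
is also reconstructable at the sister node") and a single resolution would
hide exactly the information they need. One deterministic resolution (ties
broken toward no change, then toward the lowest state) is still provided for
change lists; it realises exactly `steps` changes.

Missing (`?`) and inapplicable (`-`) cells are distinguished in storage but
both enter inference as the full state set: a taxon with no data can never
create steps nor falsify presence. Continuous characters use linear
(Manhattan) parsimony; because the objective is piecewise linear and convex
in each node value, optima lie on the grid of observed tip values, over
which the dynamic programme is run exactly, yielding per-node optimal
intervals.

Two quantities support homoplasy bookkeeping:

* `count_state_origins()` reports the minimum and maximum number of
  *origins* of a state over all MPRs — branches on which a transition into
  the state occurs, plus one if the state is reconstructed at the root
  (ancestral origination; without this convention the all-derived
  reconstruction of a symmetric four-tip case would count zero origins,
  which is not what "arises independently" means).
* `homoplasy_indices()` computes the consistency index `ci = m/s` and
  retention index `ri = (g - s)/(g - m)`. With polymorphic cells, `m` is the
  minimal *hitting set* (unordered) or *hitting range* (ordered) over scored
  cells minus one — the union of observed states would overcount and could
  push `ci` above 1. `ri` is reported as `NA` when `g = m`.

## Synapomorphy diagnosis

For a registered clade, a derived state is an **unreversed synapomorphy**
(`*`) when (i) it is present in every *scored* clade member (missing data do
not falsify presence, but are recorded; by default a polymorphic cell
containing the state counts as presence), (ii) it is the sole MPR state at
the clade's ancestral node in every MPR, and (iii) it is absent from the MPR
set of the immediate sister clade's ancestral node in every MPR (a stricter
reading than "not unambiguously present", which is available behind
`sister_mode = "not_unambiguous"`). A state unambiguously reconstructed at
the clade's MRCA *and* at its parent is a **retained plesiomorphy** (`§`).
Ubiquitous states failing (ii) or (iii) only through reconstruction
ambiguity are reported as such — this is diagnostic information, not
noise — and near-ubiquitous states are reported with their complete
exception lists. Every record carries the evaluated criteria, so each
classification is auditable.

Edge cases: when the clade's MRCA is the root there is no sister and
criterion (iii) is skipped (flagged in the record); when the sister is
ambiguous because of a polytomy, (iii) must hold at every co-child.
Characters with zero optimised steps are diagnostic of nothing and are
dropped from clade diagnoses. `unique_synapomorphy_scan()` additionally
requires tree-wide uniqueness (`min_origins = max_origins = 1`, outgroups
included) — the strictest notion of a "truly unique" synapomorphy.

## The Mkv likelihood and the placement sampler

The likelihood is the k-state symmetric Mk model per character (each
character with its own `k`), with branch lengths in expected changes per
character, a discrete-gamma rate mixture (default four equal-probability
categories represented by their conditional means), and the "variable"
ascertainment correction: each character's likelihood is divided by the
probability of being variable, since morphological matrices exclude
constant characters. Constant-pattern probabilities are computed with
complete dummy data (the standard correction), and by the symmetry of Mk a
single pruning pass per rate suffices. The pruning kernel is implemented in
C++ with per-node rescaling; it is validated against full enumeration with
matrix-exponential transition probabilities to 1e-10 relative tolerance.

The sampler holds the extant backbone fixed. Its state is: backbone branch
lengths, the gamma shape `alpha`, and, per floating fossil, an attachment
(a backbone branch or another fossil's pendant branch, a position along it,
and a pendant length). Moves: re-attach a fossil to a uniformly chosen
eligible branch (45%), rescale a branch or pendant length (30%), rescale
`alpha` (15%), slide an attachment point (10%). Priors the source analyses
leave implicit are explicit defaults here: exponential(10) on branch and
pendant lengths, exponential(1) on `alpha`, uniform attachment over eligible
branches. Runs use Metropolis coupling (default two runs of four chains,
incremental heating temperature 0.1, swap proposals between a random
adjacent pair each generation); only each run's cold chain is sampled,
burn-in (default 25%) is removed per run, and post-burn-in samples are
pooled. A between-run average SD of attachment frequencies is reported as a
convergence diagnostic — reported, not enforced.

Summaries report, per fossil, the posterior over attachment branches and
both **crown** and **total-clade** membership BPPs for every registered
clade (attachment to a clade's stem branch counts only toward the total
clade); nesting monotonicity of BPPs holds exactly by construction.
"Halfcompat" consensus is interpreted strictly: the 50% majority-rule tree
contains exactly the splits above one half, with supports annotated. Group
BPPs (all fossils of a named group inside a clade in the same sample) are
available because published analyses often report membership for a set of
fossils jointly.

An exhaustive parsimony attachment scan (`attach_parsimony_scan()`) serves
as a fast, independent cross-check: every backbone branch is tried, the
added steps are reported, and ties are broken by postorder index so the
ranking is deterministic.

## The synthetic-data generator

`example_scaffold()` builds a reproducible passerine-like backbone — a
paraphyletic outgroup series, an optional constrained stem fossil sister to
the crown, a species-poor deepest crown branch, and two large radiations
with nested named subclades — with 142 backbone tips by default and total
length 8 expected changes per unit-rate character. `simulate_matrix()`
evolves 49 discrete plus 5 continuous characters by default: unordered
characters under Mk, ordered ones (about 20% of multistate characters) under
a nearest-neighbour stepping chain, continuous ratios under Brownian motion,
all event-based so the truth record lists every change. Missing,
inapplicable, and polymorphic cells are sprinkled at low rates; constrained
stem-fossil tips receive heavy extra missingness (default 70%), emulating
fragmentary material.

Two generator choices deserve justification:

* **Rates.** Per-character rates are lognormal with median 0.3 (≈ 2.4
  expected changes per character across the tree) and `sdlog` 0.7. This
  yields consistency indices mostly between 0.3 and 1 — substantial
  homoplasy, as real carpometacarpus data show — while leaving characters
  informative. A much faster regime (~7 changes per character) saturates the
  characters: in calibration runs both the Bayesian sampler and the
  independent parsimony scan then agreed on placements away from the true
  branch, i.e. the information is genuinely destroyed, which is not the
  regime the motivating studies operate in (they place fossils at BPPs near
  1 from matrices of this size).
* **Planted markers.** `planted` characters change state exactly once, on a
  named clade's stem, with zero background rate. They emulate the
  clade-diagnostic states real matrices carry (published diagnoses list
  several diagnostic states per major subclade) and give simulation truth
  against which synapomorphy recovery is measured exactly. Pure-Mk
  characters with iid rates contain no clade-correlated signal, so a
  recovery benchmark without planted markers understates what real data
  support.

Fossil rows are drawn exactly: the state at the attachment point comes from
the Markov bridge between the realised endpoint states of the host branch
(Brownian bridge for continuous characters), evolves down the pendant, and
is then masked at the requested missingness. With position 1 and pendant 0
the fossil row equals the child node's realised states, a useful identity
for tests.

What passing simulation-based tests does **not** show: real characters are
not independent, rates are not lognormal, missingness in fossils is
anatomically structured rather than uniform, and real diagnostic states
carry exceptions and reversals. Results on synthetic data bound what the
machinery can do under its own assumptions, not what any particular
empirical matrix supports.

## Validation scales and numerical choices

The test suite validates, among others: parsimony steps and full MPR sets
against exhaustive enumeration on 200 random trees of up to 6 tips with up
to 4 states, missing cells, and polymorphism (exact agreement required);
linear parsimony against grid brute force; the pruning likelihood against
enumeration with exact matrix exponentials on trees of up to 5 tips (1e-10
relative); the sum of variable-coded pattern probabilities (exactly 1 for
enumerable cases); perfect precision and recall of planted synapomorphy
markers on the 142-tip study-scale fixture, with a criteria audit under
boosted background homoplasy; uniformity of the attachment posterior for an
all-missing fossil on a 20-tip backbone (chi-square goodness of fit on a
200,000-generation run, 3,000 post-burn-in samples); and placement recovery
over 20 replicates at 60% fossil missingness on a 33-tip scaffold with
planted diagnostic markers (median crown BPP of the true family-level clade
at least 0.8, 8,000 generations per replicate). These problem sizes are the
package's validation choices: large enough to exercise the study regime,
small enough to enumerate or replicate exactly.

Numerical conventions: optimality comparisons use an absolute tolerance of
1e-9 on step counts (costs are integral); origin counting requires integer
costs and caps its cost dimension at the optimum; likelihood partials are
rescaled per node; degenerate inputs (all-missing columns, empty record
lists, zero-length branches, `alpha <= 0`, missing fractions outside [0,1])
are rejected or handled exactly as documented on each function.

## Known limitations

* No tree search, implied weighting, asymmetric step matrices, or
  Dollo/Camin–Sokal variants; the backbone is an input, never inferred.
* No tip dating or clock models; branch lengths are in expected changes.
* The sampler proposes attachments uniformly, which mixes well at the tested
  scales but would benefit from locality-aware moves on much larger trees;
  generation loops are in R around a C++ likelihood kernel, so very long
  runs (tens of millions of generations) are possible but slow.
* The Mkv correction conditions on variability with complete dummy data;
  matrices filtered by stricter criteria (e.g. parsimony-informativeness)
  would need a different correction.
* Family-level placement of heavily incomplete fossils is information-
  limited: without clade-diagnostic characters in the matrix, no method can
  recover it, and the package's own parsimony scan is the quickest way to
  see whether a given fossil's scored cells carry such signal.
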