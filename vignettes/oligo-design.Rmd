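---
title: "Designing gapped antisense oligo pools for RNaseH-mediated RNA depletion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing gapped antisense oligo pools for RNaseH-mediated RNA depletion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oligotiler)
```

## The problem

Total RNA is dominated by ribosomal RNA. One economical way to remove it
before RNA-seq library construction is to hybridize single-stranded
antisense DNA oligos to the rRNA and digest the resulting RNA–DNA
heteroduplexes with RNaseH. Classical designs tile the target end-to-end
with 50-mers; that is wasteful, because digestion fragments between oligos
are discarded anyway by the post-digestion size selection (typically
>200 nt). If oligos are placed with untiled gaps of at most ~30 nt, complete
digestion leaves fragments of at most the gap length, and even partial
digestion — one cut near the center of each hybridized oligo — leaves
fragments of roughly `gap + half of each flanking oligo` (~70 nt for 39–40-nt
oligos and 30-nt gaps), all comfortably below the size cutoff. Shorter
(39–40 nt) oligos additionally qualify for value pricing from synthesis
vendors, so a sparse design can cut reagent cost severalfold.

`oligotiler` implements this design problem: thermodynamically constrained,
sparsely gapped tiling of one target RNA, and compact shared pools that
simultaneously target several divergent variants of an RNA (for example the
maternal and somatic rRNAs of zebrafish, which are ~86% identical).

## Hybrid melting temperature

Oligos must remain hybridized at the digestion temperature, so each
candidate is screened by the predicted melting temperature of its RNA–DNA
duplex. Stability is computed by the nearest-neighbor model: enthalpy and
entropy are sums over adjacent dinucleotide stacks, read along the target
RNA 5'→3', using the RNA–DNA hybrid parameters of Sugimoto et al. (1995).
The table ships as a plain-text resource
(`inst/extdata/nn_rna_dna_sugimoto1995.tsv`) so it can be audited or
replaced, e.g. by a newer hybrid parameter set, without code changes.

The temperature is evaluated exactly as

$$T_m(^\circ C) = \frac{\Delta H - \Delta H_{init}}
 {\Delta S + R\,\ln(1/[\text{oligo}]) + 16.6\,\log_{10}([\text{Na}^+])}
 - 273.15$$

with $\Delta H$ converted to cal/mol before the division (keeping
$\Delta S$ in cal/(K·mol) — the classic 1000× pitfall), the helix
initiation term $\Delta H_{init} = -3.1$ kcal/mol, $R = 1.987$ cal/(K·mol),
and the salt term inside the denominator. Two numerical choices deserve
mention:

* **Oligo concentration units.** The design concentration defaults to
  $5\times10^{-2}$ mol/L (a literal 50 mM reading); a 50 nM reading
  (`oligo_conc = 5e-8`) is supported as an explicit alternative. Ratio
  properties — such as how much an 8-fold concentration change shifts
  $T_m$ — are nearly unit-choice invariant; absolute $T_m$ values are not,
  which is why the value in force is part of `thermo_config()` and echoed
  by the command-line tool.
* **The $\ln(1/[\text{oligo}])$ form** makes predicted $T_m$ *decrease*
  as the oligo concentration rises. This is the formula as adopted, kept
  deliberately un-"corrected": swapping in a conventional
  $\ln([\text{oligo}]/4)$ form would silently change every predicted value.
  Under the default configuration, raising the concentration 8-fold (the
  span between the design concentration and typical usage concentrations)
  shifts a random 39–40-mer's $T_m$ by about 1.6 °C in the median — the
  shift the acceptance script measures.

A wildcard (IUPAC-degenerate) oligo reports the minimum $T_m$ over its
unambiguous expansions: a conservative guarantee that every species in the
mixture stays hybridized.

## Greedy gapped tiling

Oligos are placed left to right; each placement starts as far from the end
of the previous oligo as the gap bound allows (the 5' end acts as a virtual
previous oligo at coordinate 0, so the leading gap obeys the same bound).
Within the allowed start window, the placed candidate is the one with the
largest start whose $T_m$ lies in the ideal range. Ties at the same start
prefer the longer oligo — it covers more and pushes the next window further,
which is exactly the greedy objective — then the $T_m$ closest to the middle
of the range, then (unreachably, but defined) the lexicographically smaller
footprint. When no candidate in the window is in range, the candidate with
$T_m$ closest to the range boundary is retained and flagged, preferring the
larger start and then the longer oligo. Runs of `N` cannot be covered; a
long `N` run (or any uncoverable stretch) produces a flagged oversized gap
rather than an error.

**Terminal adjustment.** Near the 3' end, spending the full gap budget
could strand an untiled tail longer than the bound. The effective gap for
the next placement is therefore
`min(max_gap, floor((remaining - n*len_min) / (n + 1)))`, where
`n = ceiling((remaining - max_gap) / (len_max + max_gap))` is the minimal
number of oligos still required. The two length bounds play different
roles deliberately: the *count* `n` is smallest when the longest oligos are
used, while the *balancing* term assumes the shortest, so the schedule
stays feasible whichever lengths the thermodynamics end up preferring. Far
from the end this evaluates to `max_gap` exactly; approaching the end it
shrinks smoothly to distribute the remaining slack over the remaining gaps
(a 40-nt target admits exactly one forced, flush placement).

**Refinement.** After the greedy pass, a second phase rebalances each oligo
within the span bounded by its neighbors, maximizing its smaller flanking
gap. A move is accepted only if that minimum strictly improves, neither
neighbor drops below its pre-refinement minimum, no gap grows beyond the
bound (or its already-flagged size), and the oligo's $T_m$ stays in range;
flagged out-of-range oligos are left where the greedy put them. Passes
repeat left to right until a fixpoint, capped at five passes — the cap
guarantees termination, and in practice a fixpoint is reached in one or
two. These rules make refinement monotone: no oligo's minimum flanking gap
ever decreases, which is one of the package's tested invariants.

The design is fully deterministic: identical inputs and parameters produce
identical tilings.

## Shared pools for divergent variants

Two strategies produce a compact pool that targets several variants of an
RNA at once:

* **Unaligned (exact reuse).** The first target is tiled normally. For
  each subsequent target, oligos from the first design with exact
  complementary matches are placed at *all* matching loci (extra coverage
  can only help depletion), and only the remaining untiled regions are
  tiled fresh. An oligo counts as `common` only when it is placed in every
  target; with more than two targets, reuse is restricted to oligos that
  match in all of them, which keeps the pool arithmetic
  (`pool = common + wildcard + unique`) exact for any number of pools.
* **Aligned (wildcard consensus).** From a user-supplied alignment (e.g.
  from MUSCLE or MAFFT; the package validates but never computes
  alignments) a consensus is built: identical columns keep their base,
  mismatch columns get the IUPAC code of exactly the observed bases, and
  any column with a gap is masked. The consensus is tiled first; candidates
  may not span masked columns, and a candidate spanning wildcard columns is
  kept only while its expansion count (product of column degeneracies) is
  within `max_expansion` (default 2, i.e. at most one two-fold wildcard,
  orderable as a two-oligo mixture). Retained consensus oligos serve every
  row — `common` if degeneracy-free, `wildcard` otherwise — with
  coordinates mapped from alignment columns back to each row's ungapped
  coordinates; each row's residual regions are then tiled individually
  (`unique`). Residual regions shorter than the oligo minimum are treated
  as gaps and flagged when they exceed the gap bound.

## Parameters

| parameter | default | meaning |
|---|---|---|
| `tm_min`, `tm_max` | 70, 80 °C | ideal hybrid melting range at digestion temperature |
| `len_min`, `len_max` | 39, 40 nt | oligo length (short enough for value pricing) |
| `max_gap` | 30 nt | longest untiled run; bounds complete-digestion fragments |
| `max_expansion` | 2 | most unambiguous oligos a wildcard oligo may represent |
| `oligo_conc` | 5e-2 mol/L | design oligo concentration in the Tm formula |
| `na_conc` | 0.2 mol/L | monovalent salt in the Tm formula |

## Synthetic fixtures: what they emulate, and what they do not

All tests run on programmatically generated sequences, so the package is
testable without downloads.

* `make_synthetic_target()` draws i.i.d. bases at a requested GC content.
  Real rRNA has domain-scale GC structure and secondary structure that
  i.i.d. sequence lacks; passing tests therefore demonstrate constraint
  satisfaction and algorithmic invariants, not depletion efficacy on any
  particular genome.
* `make_divergent_pair()` emulates a divergent rRNA variant pair at a
  requested identity. Divergence is *clustered*: substitutions are confined
  to variable blocks (20–80 nt) alternating with conserved blocks
  (60–150 nt), because that is how real rRNA variants diverge — expansion
  segments drift while core regions stay identical — and it is the regime
  in which shared pools are useful at all. Under uniform substitution at
  86% identity, a conserved 39-mer is a ~0.3% event and shared designs
  degenerate to two independent ones; clustered divergence reproduces the
  realistic situation in which a substantial fraction of oligos can be
  shared. The substitution count is exact, so realized identity is within
  1/length of the request.
* `random_oligo_set()` draws oligo lengths uniformly from the length range
  and a GC fraction uniformly from the GC band, fixing base counts so the
  realized GC always lies inside the band. It drives the thermodynamic
  property checks (oracle agreement, concentration sensitivity).

Test problem sizes are chosen at desk scale: tiling fixtures of 120–900 nt
(200 of them for the property suite), shared-design pairs of 1.2–1.5 knt,
and single rRNA-scale targets up to 4.1 knt — large enough to exercise
terminal adjustment, flags and multi-region reuse, small enough to keep the
full suite fast.

## Degenerate inputs and edge behavior

* Targets shorter than `len_min` yield an empty, flagged tiling — never an
  error. All-`N` targets likewise.
* A window admitting no candidate (long `N` run, masked consensus stretch,
  short uncoverable remainder) produces the earliest possible downstream
  placement and a flagged oversized gap.
* A degenerate $T_m$ denominator (non-physical parameter combinations) is
  an error, as are non-positive concentrations.
* Coordinates are 0-based half-open internally and in BED output, 1-based
  inclusive in the oligo table; both writers state their convention. Tm is
  printed to two decimals, full precision is kept internally.

## Known limitations

* The greedy-plus-refinement procedure is not a globally minimal tiling;
  it reproduces the sparse-design behavior and then verifies constraint
  satisfaction, not optimality.
* No duplex secondary-structure, dangling-end or mismatch thermodynamics;
  off-target screening (e.g. BLAST against a transcriptome) is out of
  scope and should be done downstream.
* Exact reuse tolerates no mismatches; variants more divergent than the
  wildcard budget simply fall through to per-target unique oligos.
* The melting-temperature formula is used as adopted (see above); its
  absolute values depend on the concentration-unit reading, so compare
  $T_m$ values only within one configuration.

## A worked example

```{r example}
t <- make_synthetic_target(1500, gc = 0.5, seed = 42)
des <- design_oligos(t, tiling_params(), thermo_config())
des
head(oligo_table(des), 3)
summarize_design(des, unit_price = 4.64, baseline_unit_price = 19)
max(predicted_fragment_lengths(des, "complete"))
max(predicted_fragment_lengths(des, "partial"))
```
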