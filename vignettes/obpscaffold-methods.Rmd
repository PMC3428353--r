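---
title: "Methods: cysteine-scaffold evolution in insect OBP families"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cysteine-scaffold evolution in insect OBP families}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(obpscaffold)
```

## The biological problem

Classic insect odorant-binding proteins (OBPs) carry six conserved
cysteines, C1–C6, forming three disulphide bonds with connectivity
C1–C3, C2–C5, C4–C6. Two evolutionary phenomena motivate this package:
repeated loss of canonical cysteines across insect OBP families (the
minus-C subfamilies), and the lineage-specific emergence of tandem
*double-domain* OBPs, single genes encoding two concatenated OBP
domains, one of which has typically itself become minus-C. The package
quantifies three questions:

1. How many independent cysteine-loss events does a family's gene tree
   imply, and which branches carry them?
2. Do two-cysteine losses hit disulphide-bonded pairs more often than
   random loss predicts?
3. Which genes are double-domain, and where is the boundary between the
   two domains?

## Cysteine profiling

An alignment column is a canonical-cysteine candidate when at least
`min_fraction` (default 0.5) of sequences carry a cysteine there. Among
candidates, the C2/C3 pair is anchored by the scaffold hallmark that
exactly three ungapped residues separate them in at least `min_fraction`
of the sequences spanning both columns; C1 is the best-occupied
candidate upstream and C4–C6 the three best downstream. Where no
hallmark pair exists the six best-occupied candidates are taken in
order. This deliberately enforces only the best-supported spacing
constraint of the fold: published motif definitions vary, and the
three-residue C2–C3 gap is the one feature shared by all of them. The
search is invariant to record order and to all-gap columns, and on
simulated families it recovers the generator's true columns exactly.

Majority occupancy has a real failure mode: when a loss occurred near
the root of the family, most genes lack the cysteine and no threshold
can see the column (in a family where ~58 of 90 genes lack C2/C5, those
columns fall below one half occupancy). For such data the locator's
*reference mode* reads the columns off named sequences known to retain
the full scaffold; the pipeline exposes this as `reference_ids`.

Per sequence, each canonical column is scored present (cysteine),
absent, or unknown. The distinction between absent and unknown matters
for the downstream parsimony: a gap *inside* the aligned sequence is a
deletion and counts as a genuine loss, while a gap in the leading or
trailing gap run of an incomplete sequence is missing data and excludes
that sequence for that character only — a 3'-truncated gene still
informs C1–C4. Extra cysteines are counted from the mature-protein start
(`mature_start`, default alignment column 25, i.e. after a typical
signal peptide; configurable rather than predicted, to avoid an external
signal-peptide predictor).

Subfamily calls: any canonical absence gives minus-C; a full scaffold
plus at least `plus_c_min_extra` extra mature-region cysteines gives
plus-C; otherwise classic. The plus-C threshold defaults to 2: "more
than six cysteines" is ambiguous for one stray cysteine, and two extras
(enough for an additional disulphide) avoid spurious plus-C calls.
Profiles with unknown entries are reported as `incomplete`, not forced
into a subfamily.

## Parsimony mapping of losses

Losses are mapped per cysteine onto a rooted gene tree under Dollo
parsimony by default: the cysteine is ancestrally present and never
regained. Under these assumptions a loss on a branch makes every
descendant absent, so an admissible event branch is one whose scored
descendants are all absent, and the minimum reconstruction is the set of
*maximal* such subtrees. This placement is simultaneously minimal and
root-most; root-most tie-breaking maximises the genes attributed to each
event and is deterministic. The test suite checks the event count
against a brute-force minimum over all branch subsets on a thousand
random trees.

Dollo is the biologically sensible default — regaining a lost cysteine
requires a reversal that restores a disulphide partner — but a Fitch
mode (regain allowed) is provided for sensitivity analysis; its
reconstruction is cross-checked against an independent generic parsimony
scorer in the tests. Multifurcations are treated as hard polytomies.
Losses of different cysteines assigned to the same branch are merged
into one multi-cysteine event, matching how joint losses such as C2/C5
are tabulated as single events.

## The bond-bias binomial test

Conditional on a two-cysteine event, the first loss leaves five
remaining cysteines of which exactly one is the lost cysteine's
disulphide partner, so under random loss the pair is a bonded pair with
probability q = 1/5. With x two-cysteine events of which y hit a bonded
pair, the reported p-value is the upper binomial tail
P(Y ≥ y | x, q), computed via `pbinom(y - 1, x, q, lower.tail = FALSE)`
rather than naive summation. Events losing one or three cysteines are
excluded from x, since the pairing argument only applies to exactly two
losses. q is exposed as a parameter for sensitivity analysis. The
packaged event table gives x = 13, y = 11 and p ≈ 1.07e-06.

The site-model LRT helper computes chi-square upper tails from
*reported* likelihood-ratio statistics, and independently recomputes
2·(lnL_alt − lnL_null) from the reported log-likelihoods. Published
model tables are not always internally consistent — in the packaged
table every row's reported statistic differs from 2·ΔlnL — so the two
are reported side by side with a flag rather than silently reconciled.
The M8a-vs-M8 row ships with df = 2 (marked `assumed` in the fixture)
because only df = 2 reproduces its reported p-value.

## Double-domain detection and delimitation

A tandem duplication shows up in a protein self-comparison dotplot as a
high-scoring run parallel to the main diagonal, at an offset equal to
the repeat length. `self_dotplot()` computes the windowed mean BLOSUM62
score for every pair of window start positions and scans each
off-main diagonal for runs. The defaults — window 15 residues, mean
score ≥ 1.0 per residue, run length ≥ 30 window positions — are chosen
so that exact repeats are always detected while shuffled controls yield
no runs (both properties are asserted in the tests); all three are
user-settable, since the original interactive dotplot analyses had no
published thresholds.

A gene is called **double** with either two non-overlapping
cysteine-scaffold matches, or exceptional length (> 250 aa, the
published cut-off for the wasp genes) together with an off-diagonal run.
It is called **vestigial double** with one intact scaffold plus at least
two of three remnant-evidence types — a stray cysteine outside the
matched domain, a splice site in the remnant, an exon count exceeding a
single domain's two — mirroring the three-evidence argument used for
the wasp gene that retains only its former second domain's first exon,
splice site and first cysteine.

The boundary (first residue of domain 2) is estimated as the start of
the second copy of the best dotplot run. One numerical subtlety: a
window passes the score threshold once roughly half its residues are
homologous, so a run whose start is interior to the diagonal begins
about half a window before the true junction, and the estimate adds
`window %/% 2` — except when the run abuts the diagonal's left edge,
where homology extends to the sequence start and an exact tandem repeat
of length L correctly yields boundary L + 1. The estimate is then
snapped to the nearest splice-site residue within `snap_radius` (default
10 residues; beyond that the dotplot boundary stands), subject to the
constraint that domain 1 wholly precedes the boundary's scaffold and
domain 2 wholly contains its own. If no candidate boundary separates
interleaved scaffolds, the boundary is ambiguous and an error lists the
candidates. Splitting at the boundary and rejoining is byte-identical by
construction and asserted in the tests.

## What the simulator emulates — and what it does not

`simulate_family()` generates a rooted random gene tree whose root
sequence carries the six-cysteine scaffold with a three-residue C2–C3
gap and the other inter-cysteine gaps drawn from generous envelopes
around classic-OBP spacings (C1–C2 20–32, C3–C4 28–42, C4–C5 and C5–C6
8–14 residues). Along each branch:

* background substitutions replace non-canonical sites with probability
  `substitution_rate` (default 0.02 per site per branch), uniformly over
  the nineteen non-cysteine residues;
* each extant canonical cysteine is lost with per-branch hazard
  `loss_rate` (default 0.02), multiplied by `partner_multiplier` when
  its disulphide partner is already lost — including losses earlier on
  the same branch, visited in random order, so the multiplier can
  produce same-branch double losses. `partner_multiplier = 1` is the
  random-loss null; under it the fraction of two-loss events hitting a
  bonded pair is 1/5 by symmetry, which the tests verify by Monte
  Carlo. Large multipliers embody the relaxed-constraint hypothesis and
  demonstrably enrich bonded double losses;
* with probability `fusion_probability` (default 0) the mature region is
  duplicated in tandem, at most once per lineage (no triple domains,
  matching observed architectures). The second domain carries no signal
  peptide, and its cysteines are thereafter ordinary sites free to decay
  by substitution — which is exactly how the real second domains became
  minus-C.

The default family size is 20 genes of 160 residues (24-residue
signal-like leader + mature domain), giving fusion genes of 296
residues. Each domain receives two exons with an internal phase-1
intron, and fused genes gain a phase-0 inter-domain intron exactly at
the junction, echoing the observed conservation of gene structure
between the two domains.

Deliberate simplifications, and their consequences for what passing
tests show: substitutions are uniform with no rate heterogeneity and
never create cysteines, so plus-C genes and spurious scaffold matches
cannot arise by drift (plus-C classification is exercised by explicit
construction instead); there are no indels, so the true alignment is
gap-free for single-domain genes and column location is easier than on
real MSAs; no pseudogenisation or expression data is simulated.
Simulation results therefore validate the *inference machinery* — they
do not show that the thresholds are optimal for divergent real
alignments, where column location should lean on reference mode and
curated alignments.

Determinism: the full configuration including the seed fixes every
output byte-for-byte, which the tests assert.

## Numerical and degenerate-input choices

* Alignment columns and residue positions are 1-based throughout.
* Binomial and chi-square tails come from `pbinom`/`pchisq` upper
  tails, never 1-minus-CDF subtraction; for df = 2 the chi-square tail
  is exp(−s/2) and is tested against that closed form to 1e-12.
* Event-table rows are ordered by lost-set size, then cysteine index,
  making reports reproducible run-to-run.
* The fixture loader validates the tables' marginal totals (22 events,
  74 gene entries) and refuses a corrupted file.
* Degenerate inputs error early and specifically: ragged alignments name
  the offending record, empty files report "no records", leaf/profile
  mismatches list the symmetric difference, and sequences shorter than
  the dotplot window are rejected.

## Validation problem sizes

The test suite validates parsimony against brute force on 1000 random
trees of up to 8 leaves, calibrates the simulator's null over 500
replicate families of 12 genes, checks exact event-log recovery on
30 low-rate families of 15 genes, and measures fusion recall/specificity
over more than 200 simulated genes — sizes at which the brute-force and
enumeration oracles are exact and the whole suite runs in well under a
minute. The exact-recovery check is conditional on its stated
precondition: when two independent events hit the same cysteine on
branches that tile a clade, parsimony correctly merges them into one
root-most event, so such families are excluded from the exact-match
assertion rather than miscounted as failures.

## Known limitations

* Tree topologies are consumed, not inferred; errors in the input tree
  propagate directly into event counts.
* Dollo's no-regain assumption is untestable from presence/absence data
  alone; the Fitch mode bounds the sensitivity of conclusions to it.
* The bond-bias test conditions on the observed number of two-cysteine
  events and treats events as independent; deep nonindependence (e.g.
  shared mutational biases across clades) is outside its null.
* Majority-occupancy column location degrades on families dominated by
  minus-C genes; use reference mode there.
* The vestigial-double call requires gene-structure input for two of its
  three evidence types; on bare protein sequences only the stray
  cysteine is visible and the call falls back to single.
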