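---
title: "Validating Hi-C scaffolds with optical label maps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating Hi-C scaffolds with optical label maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scaffval)
```

## The problem

Hi-C scaffolding orders and orients assembly contigs from chromatin contact
frequencies. The statistic is powerful — it reaches chromosome scale — but
indirect: contact frequency only correlates with genomic proximity, so a
fraction of the joins it makes are wrong (misplaced contigs, flipped
orientations, chimeric fusions of different chromosomes), and every join it
makes carries a made-up gap size, because contact counts say nothing about
the physical distance between two joined contigs. Optical genome mapping is
the natural orthogonal check: it images single DNA molecules labelled at
nicking-enzyme recognition motifs, so a consensus optical map is a direct
physical measurement of label order *and* inter-label distance. Where an
in-silico digest of the scaffold disagrees with the optical map, the
scaffold is suspect; where long reads fail to span a Hi-C junction, the
suspicion is confirmed.

`scaffval` implements this validation loop as code: in-silico digestion,
map-to-scaffold alignment, breakpoint extraction, cross-enzyme conflict
calling, junction classification, gap-size estimation, long-read junction
support, scaffold cutting, and before/after contiguity statistics — together
with a fully ground-truthed simulator used to measure the method's recall
and false-positive behaviour.

## What the simulator emulates

`sim_config()` / `simulate_dataset()` generate:

* a uniform-composition genome (default 5 Mb in 2 chromosomes) fragmented
  into contigs (default 40, minimum 80 kb) separated by *true physical gaps*
  drawn from Normal(2000, 700) bp truncated at 100 bp. Neither the gap-size
  distribution nor the contig-size distribution is taken from any published
  table; 2 kb-scale gaps make every fixed 100 bp filler physically wrong (the
  situation the method is designed to expose) while remaining small enough
  that 15 kb reads still span correct junctions;
* a Hi-C-style observed layout: same contigs, every junction closed with a
  fixed 100 bp `N` filler tagged `HIC` (the "user-determined fixed gap
  length" behaviour of contact-based scaffolders — 930 gaps totalling
  93,000 bp in the motivating assembly implies exactly this constant), plus
  the requested misjoin edits. A translocation swaps two non-adjacent
  placements, an inversion flips one placement, a fusion exchanges the tails
  of two scaffolds. Each edit records one disrupted junction; edits lock the
  contigs flanking recorded junctions so later edits cannot disturb them,
  keeping the ground truth unambiguous;
* noisy label maps per chromosome and enzyme (defaults Nt.BspQI `GCTCTTC`
  and Nb.BssSI `CACGAG`): the exact in-silico site list, condensed at the
  1 kb instrument resolution, each interval perturbed with Gaussian noise of
  SD `400 * sqrt(L/1000)` bp (the standard square-root error model for
  single-molecule sizing), labels dropped at 10% and false labels added at
  0.5 per 100 kb;
* read alignments drawn from the *true* genome (lognormal lengths, median
  15 kb; 30-fold coverage), emitted as PAF records in observed-layout
  coordinates and split wherever the read's true locus is discontiguous in
  the observed layout. An intact junction therefore accumulates
  single-record spanning reads; a misjoined junction gets none, by
  construction.

What the simulator does *not* emulate — and hence what green tests do not
certify about real data: repeat sequence (uniform random DNA has no
paralogy, so wrong-location alignments are rarer than in a real genome),
haplotype divergence, chimeric contigs (misjoins here are always at
junctions), molecule-level optical artefacts (the consensus map is
simulated directly), and base-call errors in reads (reads are emitted as
ground-truth alignments, not sequences).

## The alignment model

Label maps are aligned by local dynamic programming over label indices.
Matching query label `i` to reference label `j`, extending a chain from
`(i-a, j-b)`, scores

```
match_bonus - penalty(q_int, r_int) - (b-1) miss_penalty - (a-1) false_penalty
```

with the sizing penalty `(q-r)^2 / (sigma^2 max(r,1000)/1000)` — the squared
sizing error in units of the expected measurement variance. Reference
intervals containing a declared Hi-C gap are special: the filler length is
a placeholder, not a measurement, so the declared bases are replaced by a
free non-negative quantity (only a *deficit* of physical length is
penalised). This is what lets an alignment span a junction whose true gap is
20 kb though 100 bp is declared — the situation behind gap-size-only
conflicts — without believing the filler.

Three mechanisms keep chains honest, and all three exist because a local
alignment with plain `max(0, ...)` resets can otherwise *drain through* a
misjoined region on coincidental matches and resume on the far side,
hiding the very junctions the method must expose:

* an X-drop inside the recurrence (`max_drop`, default 12): a chain may
  never fall more than 12 score units below its own running maximum, so
  every DP cell holds the score of one coherent local segment;
* stitching (`stitch_alignments()`): segments of the same query, reference
  and orientation that are collinear and *size-consistent* (the skipped
  stretch must be the same physical length on both maps, with slack per
  declared gap) are re-joined, so a sag caused by a run of missed or false
  labels is not mistaken for a structural termination. Size consistency is
  the discriminator: a misjoin's flanks are separated by foreign sequence
  whose length matches the displaced sequence only by coincidence;
* continuation suppression (`suppress_collinear_terminations()`): a
  right/left termination pair whose chains demonstrably continue collinearly
  (anchor pairs a few steps in from the ragged ends, same size-consistency
  test, within 300 kb) is removed — unless another alignment occupies the
  intervening reference region, which is the signature of genuinely
  misplaced sequence and vetoes the suppression.

A breakpoint is an alignment end with at least `trailing_k` (default 10)
unaligned labels remaining on *both* maps on the same side, at least 30 kb
from both map ends (`end_guard`), and — in the pipeline — with continuation
evidence: some of the next 60 query labels must be aligned by another
chain. At a real misjoin the displaced query provably continues somewhere
else; a ragged unalignable map tail is claimed by nothing and is noise,
not structure.
Breakpoints from both enzyme channels are clustered by single linkage
within 50 kb into conflicts; conflicts are classified `NEAR_GAP_STRUCTURAL`
(within 50 kb of a Hi-C gap), `GAP_SIZE_ONLY` (at least two independent
alignments cleanly span the gap but the implied physical size contradicts
the declared filler by more than `max(10 kb, declared)`), or `INTERNAL`.

### Why these scoring defaults

Score units are arbitrary; what matters is separation. The defaults
(`match_bonus` 3, `miss_penalty`/`false_penalty` 4, `min_score` 30 on
stitched chains, `min_matched_labels` 9, `lookback` 5) were set by two
opposing constraints measured on the simulator: the dense channel (CACGAG
sites every ~2.4 kb in random sequence, against interval noise of ~600 bp)
supports long spurious chains if skips are cheap, which drives the skip
penalties and thresholds *up*; the sparse channel (GCTCTTC, ~8 kb spacing)
fragments under noise if they rise too far, which is why small fragments
are retained internally (down to 3 pairs) and only the stitched chains face
the reporting thresholds. `sigma` equals the generator's noise scale — the
aligner believes the instrument's stated error model, and a user applying
the package to other data should set both to their instrument's value.

### Numerical conventions

Scaffold coordinates are 0-based half-open internally; AGP I/O converts to
1-based inclusive; CMAP positions are written 1-based with one decimal.
Breakpoints sit at the last matched reference label on the broken side
(conservative, always label-anchored), so a conflict can sit one or two
label intervals (typically 10–25 kb) away from the true junction; the 50 kb
clustering and near-gap windows absorb this. The N50 uses the
descending-cumulative-sum rule. Published percentage summaries mix rounding
conventions, so `percentage_summary()` makes the mode (`nearest` or
`floor`) an explicit argument and reports never rely on a hidden default.
Degenerate inputs: empty label maps align to nothing; an empty breakpoint
set yields an empty conflict table and an unchanged layout; N50 of an empty
length set is an error rather than 0.

## Junction support from long reads

`spans_junction()` operationalises "a read properly aligned across the
gap": one primary record covering the gap plus `min_anchor` (1 kb) on each
side at mapping quality ≥ 20. Split records never combine — a read broken
across a junction is evidence *against* the join. Junctions are classed
`UNSUPPORTED` (0 spanning reads), `WEAK` (1–4) or `SUPPORTED` (≥ 5); the
threshold of five reads reflects the working convention that fewer than
five spanning reads leaves a junction unconfirmed.

## Cutting and statistics

`cut_at_conflicts()` splits scaffolds at confirmed structural conflicts:
a conflict within 50 kb of a gap removes that gap (filler bases dropped,
contig bases conserved exactly); an internal conflict splits the containing
contig into two components. Cutting can only decrease N50 and increase
scaffold count — the before/after tables from `assembly_stats()` and
`compare_runs()` quantify the contiguity cost of honesty, which is the
method's central trade: conflict resolution fragments the assembly now so
that anchoring (out of scope here) can rebuild it correctly.

## The synthetic experiments and their problem sizes

The package's own evaluation, mirrored by `tests/testthat/test-acceptance.R`
and `scripts/acceptance.R`, uses:

* *recovery*: one 5 Mb, 2-chromosome, 40-contig dataset with 8 injected
  misjoins (4 translocations, 2 inversions, 2 fusions), generator seed 42 —
  measured outcomes: at least 7 of 8 recorded junctions produce a
  `NEAR_GAP_STRUCTURAL` conflict within 50 kb, at most one conflict at an
  intact junction, every misjoined junction `UNSUPPORTED` and ≥ 95% of
  intact junctions `SUPPORTED`;
* *null soundness*: the same configuration without misjoins over 20 seeds
  (1–20) — at least 95% of runs must report zero conflicts, and a
  conflict-free run must leave the layout untouched;
* *oracle equivalence*: the DP against exhaustive chain enumeration on 200
  instances of 4–6 labels per side (with the X-drop unconstrained so the
  classic local optimum is the target), N50 against a candidate scan on
  1000 random length sets, motif finding against a sliding-window scan on
  100 sequences;
* *gap-size recovery*: a 400 kb two-contig chromosome with a 5 kb true gap
  declared as 100 bp — exact recovery at zero noise, and mean bias within
  3 standard errors over 200 noise seeds at `sigma` 400.

These sizes keep the full suite within a few minutes on one CPU while
leaving each statistical check enough replicates to be meaningful.

## Known limitations

* The aligner is exhaustive O(nq × nr × lookback²) per orientation — fine
  for megabase-scale simulations and single chromosomes, not tuned for
  repeated genome-scale production use (no banding).
* Misjoins landing within ~30 kb of a scaffold end are invisible
  (`end_guard`), the price of ignoring ragged map-end artefacts.
* A misplaced segment whose length coincides with the sequence it displaced
  *and* whose own content fails to align can escape both the stitching
  discriminator and the occupancy veto; in the default two-channel setup
  this requires the coincidence on both enzymes simultaneously.
* Inversion breakpoints are attracted toward the inverted contig's centre
  (label patterns are locally mirror-symmetric there), so positions are
  less precise for inversions than for translocations or fusions.
* The second hybrid-scaffolding step — re-anchoring the cut sequences into
  map-ordered scaffolds with measured gap sizes — is out of scope; the
  package reports implied gap sizes but does not rebuild scaffolds.
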