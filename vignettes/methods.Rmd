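---
title: "Detecting miRNA-directed gene activation through enhancers: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting miRNA-directed gene activation through enhancers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirtrio)
```

## The model

`mirtrio` screens for a specific, unconventional regulatory architecture:
a nuclear miRNA binds enhancer DNA, the enhancer is activated, and the
genes it regulates go up. The observable signature pursued here is a
**trio**: a predicted physical miRNA:enhancer interaction, an a-priori
enhancer:gene association (supplied by the user, e.g. from expression
correlation within a topologically associated domain), and a positive
rank correlation between miRNA and gene expression across samples.

None of the three signals is sufficient alone. Sequence-level binding
predictions over short (~22 nt) RNAs are noisy; expression correlation is
rife with confounding. The pipeline therefore treats binding prediction
as a *gate* and correlation as the *score*, with multiplicity control
inside the gate's output.

### Binding: three interchangeable mechanisms

Because the physical mechanism of miRNA-enhancer engagement is unsettled,
three predictors are provided, and a consensus layer can intersect them.

**Seed match + global alignment.** A site must contain an exact copy of
the user-supplied seed (DNA form) or its reverse complement. The genomic
site is extended by 14 bp on the side where the rest of the mature miRNA
would pair — downstream for forward-seed matches, upstream for
reverse-complement matches — so the window (seed ~7 nt + 14 bp ≈ 21 nt)
can host a typical mature sequence. The full mature miRNA (as DNA;
reverse-complemented for reverse-orientation matches so both strings are
in target-strand sense) is aligned globally with affine gaps. Identity is
`100 * matches / alignment_length`, gap columns included in the
denominator (the convention of the classical global aligner this mimics),
and a site survives only if PI strictly exceeds 50.

One deliberate deviation from that classical tool: end gaps are penalized
like internal gaps. Free end gaps make the "optimal alignment" depend on
a second cost model; a single affine cost (gap of length L costs
`open + L * extend`) is what our exhaustive-enumeration test oracle
scores, and for near-equal-length sequences the difference is immaterial.

**miRanda-style duplex scan.** A local alignment of the miRNA (3′→5′)
against the target strand (5′→3′) under the published miRanda constants
(+5 Watson–Crick, +1 G:T wobble, −3 mismatch, −9/−4 gaps), with every
substitution column pairing miRNA positions 2–8 multiplied by 4 — the
seed dominance that makes a scrambled-seed site unable to reach the 140
score cutoff even when the rest pairs perfectly (5·15 = 75 < 140). Both
enhancer strands are scanned; coordinates are always reported on the +
strand. Gap columns are not seed-scaled; this is a choice, exposed with
every other constant in `miranda_params()`.

The energy filter is a *surrogate*: a nearest-neighbor stack sum over
adjacent paired columns with an embedded, synthetic approximation of
RNA/DNA-hybrid stacking free energies, without initiation or loop terms.
It is monotone (every additional Watson–Crick pair makes the energy at
most more negative), zero for an empty pairing, and negative for any
Watson–Crick duplex of ≥ 5 nt — the properties the pipeline relies on.
It is *not* a folding energy, and the vignette is the place to say so
plainly; set `energy_model = "none"` to disable it.

**Triplex search.** Hoogsteen-bonded triplexes form when a
single-stranded RNA lies in the major groove of a purine-rich duplex.
Both enhancer strands are evaluated as the candidate purine strand;
the miRNA window is scanned forward for the parallel motifs
(pyrimidine motif U·A:T / C·G:C, and the GT motif G·G:C / U·A:T) and
reversed for the antiparallel purine motif (A·A:T / G·G:C). A site is an
equal-length gapless pairing with at most a 19% invalid-triplet rate and
length ≥ 11 — thresholds relaxed from triplex-tool defaults because a
22-nt RNA cannot carry long perfect tracts. A minimum guanine fraction
on the purine strand (default 0.1, permissive; not specified upstream)
reflects the G-richness requirement of stable triplexes. Known
limitation: real triplex tools scan the GT motif in both orientations;
here it is grouped with the parallel motifs.

### Scoring: Spearman + per-miRNA Benjamini-Hochberg

Each candidate (miRNA family, gene) pair is scored with Spearman's rank
correlation across samples (≥ 8 enforced; average ranks for ties). The
two-sided p-value uses the t approximation with n−2 degrees of freedom;
at |rho| = 1 the statistic degenerates and the p-value is set to the
smallest positive double rather than zero, keeping downstream BH
arithmetic finite. Zero-variance expression vectors are dropped, not
scored.

BH adjustment is applied *within each miRNA family*, with m equal to that
family's candidate gene count — the literal reading of "the number of
miRNA:gene pairs for one miRNA". Trios pass at adjusted p < 0.05.
A sign filter (SCC > 0) is on by default: the model is activation, and
negative correlations contradict it. The upstream description never
states a sign rule, so the filter is exposed (`positive_only = FALSE`,
CLI `--no-positive-only`).

### Consensus layer

Mirroring the downstream use-case logic for CAGE-style data, where one
gene has several promoters: gene expression is proxied either by the
promoter with the highest SCC against the miRNA (mode a) or by the
per-sample sum over promoters (mode b). Duplex trios must be (1) found by
both duplex methods, (2) on an enhancer linked to ≥ 2 distinct genes
(counted in the *input* link table, not among surviving trios — a
deliberate reading), and (3) supported under both aggregation modes;
independently, any trio with SCC ≥ 0.8 in any of the four
method × mode sets is added back (the rescue is an unconditional union,
per its "we also added" phrasing). Triplex trios need multi-gene
enhancers and mode agreement. A generalization of the literature's
ad-hoc multi-enhancer exception is available as
`rescue_min_enhancers = N` (pairs supported by ≥ N distinct enhancers
bypass the mode-agreement rule); it is off by default.

## The synthetic world

`generate_fixture()` emits a complete, deterministic input bundle. Its
defaults are the package's stated test world, chosen once:

| parameter | default | why |
|---|---|---|
| enhancers | 24 × 300 bp | hundreds-of-bp regulatory elements; ≥ 20 decoys for false-positive accounting |
| miRNA families | 6 × 21 nt | typical mature length; 3 planted, 3 decoys |
| genes | 15 | ≥ 10 decoy genes |
| samples | 12 | above the ≥ 8 floor, small enough for rank arithmetic to be exact |
| planted trios | 2 seed-site + 1 triplex-site, target SCC 0.9 | both mechanisms; comfortably above the 0.8 rescue threshold but not degenerate |
| noise | 0.25 on log2 scale | visible magnitude jitter that never reorders samples |

Planted signal is constructed, not simulated: a seed-site trio embeds the
full mature sequence in its enhancer (seed exactly present, alignment PI
≈ 90, and a perfect duplex on the opposite strand for the miRanda route);
a triplex-site trio uses a pyrimidine-rich miRNA whose purine-strand
target (U→A, C→G) is embedded directly. Expression is generated on a log
scale and exponentiated (CAGE-like positive values). Correlation is
calibrated at the *rank* level: the gene's rank vector starts as a copy
of the miRNA's and random transpositions are accepted only when they move
the Spearman correlation toward the target, which converges within ~0.01
of it; the magnitude jitter is bounded below half the rank spacing, so
ranks — and therefore the realized SCC — are exact functions of the seed.

What a green planted-recovery test establishes: the detectors find the
planted site classes among random decoys, the statistics keep the planted
pairs, and BH limits decoy discoveries near its nominal rate. What it
does not establish: behavior on real genomic base composition, repeat
structure, TAD-derived link tables, or any biological claim.

## Numerical and degenerate-input choices

* Alignment tie-breaks are deterministic (diagonal, then up, then left),
  so reruns are byte-identical; scores are halves (gap extend 0.5) and
  compared exactly in tests.
* Overlapping seed occurrences are all reported; a palindromic seed
  (equal to its reverse complement) is reported once, as forward.
* Seeds shorter than 4 nt are rejected (they would match almost
  anywhere); a seed missing from its mature sequence warns but does not
  fail, since seeds are free user input.
* One best site per (mature miRNA, enhancer) pair feeds trio assembly in
  every mode (max PI / max score / longest-then-cleanest triplex, ties to
  the smallest coordinate); the triplex detector keeps its full hit list
  as an audit attribute and file.
* Hits on enhancers absent from the link table, and candidates missing
  from the expression tables, are skipped and counted, never silently
  lost; the counts go to the run log.
* The spearman p-value approximation is compared against a Monte-Carlo
  permutation oracle in the tests with a documented tolerance
  (±0.05, or a factor of 3 when the permutation p is below 0.01) —
  exact enumeration at n = 12 is out of any test budget.

## Known limitations

* The duplex energy surrogate is not a thermodynamic model; rely on the
  score filter when in doubt.
* The GT triplex motif is scanned parallel-only.
* Expression-based scoring uses family-level miRNA expression: all mature
  forms of one family share the family vector, and one trio row is
  emitted per mature form.
* Differential-expression pre-filtering and the construction of the
  enhancer:gene interactome are the user's responsibility; both are
  consumed as inputs by design.
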