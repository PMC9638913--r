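---
title: "Modelling RNA sequence and structure specificity with ssmotif"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling RNA sequence and structure specificity with ssmotif}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssmotif)
library(dplyr)
```

## The modelling problem

RNA-binding proteins (RBPs) recognize RNA through primary sequence, secondary
structure, or both: some bind a specific sequence exposed in a hairpin loop,
some require double-stranded context, and many simply prefer accessible
(unpaired) instances of a sequence motif. In vitro selection experiments
(SELEX-, RBNS- or RNAcompete-style) yield a pool of RBP-bound probes and a
background pool; the modelling task is to summarize what distinguishes them in
a form a biologist can read: a small set of weighted motifs, each tagged with
how much structure information it carries.

`ssmotif` does this in two stages. First it generates a large, deliberately
redundant collection of candidate motifs (position frequency matrices, PFMs)
under seven annotation alphabets; then an L1-regularized logistic regression,
followed by an iterative simplification loop, prunes the collection down to
the few motifs that carry the predictive signal. Because sequence-only,
structure-only and combined alphabets compete on equal footing inside one
regression, the surviving motifs directly measure how much of the binding
signal is structural.

## Probe annotation: seven alphabets

Each probe must arrive with a secondary structure in dot-bracket notation.
The package deliberately takes dot-brackets as *input* (files in the Vienna
alternating sequence/structure layout, or a `dotbracket` column) so that the
whole pipeline, including all tests, runs without an external folding engine;
`fold_probes()` is a thin optional hook that shells out to `RNAfold -p` and
extracts the centroid structure when only FASTA is available. The centroid
(rather than minimum-free-energy) structure is the intended input because it
summarizes the thermodynamic ensemble rather than a single extreme.

`classify_contexts()` decomposes the structure into loops and labels every
base with one of seven contexts: `L`/`R` for the left/right strand of a
helix, `H` hairpin loop, `B` bulge (a one-sided internal loop), `T` internal
loop, `M` multiloop, `E` external/unpaired. Two letterwise projections
coarsen this to a four-letter alphabet (`P` paired, `L` hairpin loop, `U`
external, `M` any other loop) and a two-letter paired/unpaired alphabet.
Combining each structure alphabet with the nucleotide gives the 8-, 16- and
28-letter product alphabets, so every probe carries exactly seven annotation
strings. Flanked probes (constant primer sequences around a randomized
region) are annotated in full but trimmed to the variable region, because the
flanks are shared by every probe and would otherwise dominate discovery.

Coordinates are 1-based closed intervals throughout, following base R
(`substr`) and Bioconductor (IRanges) convention. Pseudoknot bracket layers
are rejected explicitly: centroid structures never contain them, and passing
one through silently would corrupt every downstream annotation.

## Motif discovery

The default discoverer enumerates all k-mers of width 4–6 observed in either
probe set, tests per-probe presence enrichment in the bound set with a
one-sided Fisher's exact test (computed through the hypergeometric tail, so
hundreds of thousands of k-mers vectorize), Bonferroni-corrects over the
number of k-mers actually tested, and keeps at most the 40 most significant
non-redundant seeds at a corrected p < 0.01. Redundancy is greedy: a seed
within Hamming distance 1 of an already-selected seed of the same width is
skipped — a cheap stand-in for the motif-erasure strategy of suffix-tree
discoverers. Each PFM is then built from the positional letter counts of the
seed's exact matching sites in the bound set, with a pseudocount of 0.1 per
cell. Presence/absence at the probe level (rather than total occurrence
counts) makes the test robust to probe-length differences.

An external STREME backend with an identical output contract can be selected
(`backend = "streme"`, flags `-pvt 0.01 -minw 4 -maxw 6` and a custom
alphabet file written by `write_meme_alphabet()`); it requires the MEME suite
on the PATH and is opt-in precisely so the package has no hard external
dependency.

Width bounds of 4–6 let partial and standard-size motifs both surface; the
cap of 40 and the 0.01 corrected threshold are applied together (retention
requires both).

## Scanning: the top-four-window sum

Every PFM is scored along every probe annotation of its own alphabet with a
log-odds score in bits against a uniform background,
$\sum_j \log_2\big(p_j(x_j)\,/\,(1/|A|)\big)$, with matrix entries floored at
$10^{-3}$ before the log so a single mismatch cannot send a window to
$-\infty$. The uniform background makes scores comparable across alphabets of
different sizes. The per-probe feature is the sum of the four best windows:
one strong site and up to three secondary sites contribute, which lets the
same feature capture both single-site and multivalent binding. Probes shorter
than the PFM width receive the hard floor value $4w\log_2(10^{-3}|A|)$
instead of an error so mixed-length (CLIP-style) inputs survive scanning.

## Regression and simplification

Features are z-scored with statistics from the training split before the L1
fit; the penalty is scale-sensitive, and raw motif scores have
alphabet-dependent ranges, so unstandardized fits would implicitly favour
large alphabets. Columns that are *exactly* identical after standardization
are collapsed onto their first occurrence in canonical column order
(sequence first, then structure, then product alphabets). This situation is
not hypothetical: on unstructured probes, the sequence alphabet and the three
product alphabets carry literally the same information, the same motif is
rediscovered in all four, and the L1 solution is then non-unique — which
duplicate receives the weight would be an accident of the optimizer's
coordinate ordering. Collapsing makes the attribution deterministic and
conservative: weight lands on the simplest alphabet that explains the data.

The penalty strength is selected from a 33-point log-spaced grid on
$[10^{-4}, 10^{4}]$ by stratified 5-fold cross-validated AUROC on the
training split, ties breaking toward the stronger penalty (the sparser
model). A deterministic grid was chosen over Bayesian search so that two runs
with the same seed are bit-identical; the grid is dense enough that the
subsequent simplification loop, which multiplies the strength by 1.25 per
step, starts well inside the plateau of near-optimal strengths.

Simplification refits with the penalty scaled by 1.25 each iteration and
re-evaluates AUROC on a held-aside validation split, stopping once the AUROC
falls below $0.5 + 0.9\,(\mathrm{AUROC}_0 - 0.5)$ — i.e. once less than 90%
of the initial *predictive power* (AUROC above chance) remains. The last
model still satisfying the bound is returned, so the reported model always
retains at least 90% of the initial power by construction; the wording
"iterate until the AUROC drops" leaves open whether the first-failing or
last-passing model is kept, and the last-passing choice is the one under
which the retention guarantee is an invariant rather than an expectation.
If the initial model is no better than chance the loop is skipped with a
warning and the initial model returned unchanged.

Data are split 50% motif discovery / 20% regression training / 5% regression
validation / 25% held-out test (stratified by label, largest-remainder
rounding, seeded), i.e. 75% training-side and 25% held out. Validation AUROC
in the loop is always recomputed on the same 5% split.

## Interpretation metrics

Motif "weights" are absolute standardized coefficients. Two summaries are
reported. The per-alphabet weight proportion divides each alphabet's total
absolute coefficient mass by the model total: a pure sequence binder scores 1
in the sequence column. The paired-base weight fraction splits each
structure-inclusive PFM's information content (IC, $\log_2|A|$ minus column
entropy) between paired and unpaired contexts in proportion to the column's
probability mass on paired-context symbols (`P` in the 2- and 4-letter
alphabets, `L`/`R` in the 7-letter ones), then averages the per-PFM paired
shares weighted by coefficient magnitude. Probability-mass weighting of the
column IC is the package's concrete reading of "information content
contributed by paired bases"; no closed-form attribution is canonical, and
this one is symmetric, sums with the unpaired share to each PFM's total IC,
and is invariant to renaming symbols within a pairedness class. Negative
coefficients enter by magnitude — sign is reported separately in the motif
report — because the metrics measure *contribution*, not direction.

## The gap-HMM extension

Multi-domain RBPs often bind two sub-motifs separated by a variable gap. The
gap-HMM places the discovered PFMs of one alphabet into a hidden Markov
model: a recursive `begin` state, one state per PFM position whose emissions
are the PFM column and are never updated, one recursive gap state per
*ordered* PFM pair (self-pairs included, so repeated sites and both
orientations of a spacing are representable), and a recursive `end` state.
Begin and each PFM-final state connect to every PFM start (motifs may abut
back-to-back); PFM-internal states chain strictly forward so a motif always
occurs in full. Transitions (and only transitions) are trained by Baum–Welch
— at most 10 PFMs per model and at most 10 000 training probes, or half when
fewer than 20 000 are available — and probes are scored by forward-algorithm
log-probability. The seven per-alphabet log-probabilities feed a
cross-validated random forest. The HMM stage ships as an opt-in subcommand
(`ssmotif hmm`) rather than part of the default pipeline: it reveals spacing
preferences but does not reliably improve plain scoring.

## The simulator and what passing tests mean

`generate_dataset()` emulates one selection experiment: fixed-length
randomized probes (default N40, uniform base composition) with optional
constant flanks; a consensus motif planted in a configurable fraction of
positive probes (default 0.5, roughly the strong-enrichment regime of a late
selection cycle); and three planting modes — unstructured, hairpin-embedded
(the motif inside the loop of a stem of Watson–Crick pairs, default stem 4,
emitted with the matching dot-bracket), and bipartite (two sub-motifs with a
uniform random gap). Structures are emitted by construction rather than by
folding, so tests are folder-free and the truth table records exactly where
every plant sits. G·U wobble pairs are not generated, keeping the emitted
structures consistent with what a thermodynamic folder would produce for the
same stems.

The simulator is deliberately simpler than real selection data: backgrounds
are i.i.d. (no pool-composition bias), negatives are emitted unfolded (so in
hairpin mode *any* pairing signal separates the classes, not only the
motif-bearing hairpin), and there is no sequencing error or cycle-to-cycle
enrichment dynamics. Passing recovery tests therefore demonstrates that the
machinery identifies and correctly attributes planted signal under clean
conditions; they do not certify performance on real pools, where enrichment
is weaker and structure signal subtler.

One arithmetic consequence of the 50% plant rate is worth spelling out:
half the positive probes are pure background, so the *overall*
positive-versus-negative AUROC of even a perfect model is bounded near 0.75.
Recovery checks that quote AUROC > 0.9 are therefore computed against the
generator's truth labels — actually-planted positives versus negatives —
which is the discrimination the model is supposed to achieve.

## Problem sizes and numerical choices

The shipped tests train full pipelines at 1 000–2 000 probes per side with
40-base probes: large enough that discovery p-values, the CV grid and the
simplification loop behave as they do at scale, small enough to iterate on.
Replicated recovery suites (20 seeds per scenario) use 1 000 probes per side.
Key defaults: PFM probability floor $10^{-3}$; discovery pseudocount 0.1;
Bonferroni family = k-mers actually tested per alphabet; penalty grid
$10^{-4}$–$10^{4}$ (33 points); simplification factor 1.25 and retention
0.9; EM stopping at relative log-likelihood improvement $<10^{-4}$ or 100
iterations. Ties in discovery significance break lexicographically; ties in
the CV grid break toward the sparser model; `max.col` tie-breaking in the
scanner is fixed to "first". All randomness flows from explicit integer
seeds through `withr::with_seed`, so every result in the README and the
acceptance script is bit-reproducible.

## Known limitations

Single structure per probe (no ensemble probabilities); no pseudoknots; no
reverse-complement scanning (RNA is single-stranded); PFMs are position
independent, so strictly covarying positions are only captured indirectly;
the discoverer's exact-match PFM construction yields sharp motifs and relies
on the width range and redundancy rules, rather than site realignment, to
express degeneracy. Continuous-affinity data (rather than bound/background
sets) are out of scope.

## A worked example

```{r example, eval = FALSE}
cfg <- generator_config(n_probes = 2000, probe_length = 40, plant_rate = 0.5,
                        motif = "UGCAUG", structure_mode = "none", seed = 7)
ds <- generate_dataset(cfg)
model <- ss_train(ds$positive, ds$negative, ss_config(seed = 7))
glance(model)
tidy(model)
alphabet_weight_proportions(model)
paired_weight_fraction(model)
autoplot(model)
```
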