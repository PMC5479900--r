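---
title: "Screening for S-RNase-based gametophytic self-incompatibility: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening for S-RNase-based gametophytic self-incompatibility: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gsiScreen)
```

## The screening problem

In S-RNase-based gametophytic self-incompatibility (GSI), as characterised in
Solanaceae, Rosaceae and Plantaginaceae, the female determinant is a
style-expressed ribonuclease of the RNase-T2 family (an S-RNase) and the
pollen side acts through SLF/SFB F-box proteins adapted to the SCF complex by
an SSK1 protein, a type-I SKP1-like protein with a diagnostic C-terminus.
Asking whether a new plant lineage uses this system reduces, on the female
side, to a candidate-gene screen over its proteomes and transcriptomes:

1. **Homology** — the gene is similar, at the amino-acid level, to RNase-T2
   genes related to S-RNase-based GSI;
2. **Pattern 4 absent** — at a diagnostic position near the conserved
   RNase-T2 active site, an arginine ("amino-acid pattern 4") occurs only in
   non-S-lineage (S-like) RNase-T2 proteins, so its determinate absence is a
   requirement; alternative residues such as `CGS`/`CSS` at that position are
   compatible with the S-RNase lineage;
3. **Basic pI** — S-RNases are basic proteins, typically pI 8–10; the screen
   requires pI above a threshold (default 7.5);
4. **Style-restricted expression** — S-RNases are mainly expressed in the
   style.

Two auxiliary sources of evidence complete the screen: an **intron rule**
(S-RNases carry only one or two introns) and **clade placement** against a
labelled reference panel — a gene that falls inside the Class-I or Class-II
RNase-T2 clades rather than the S-RNase clade is vetoed. On the pollen side,
SSK1 candidacy requires a type-I SKP1-like protein, a C-terminal
WAFE-variant motif and pollen-restricted expression.

`gsiScreen` implements each stage as an explicit, testable operation and
combines them into per-gene verdicts (`candidate`, `rejected`,
`inconclusive`).

## Isoelectric points

Charges follow the Henderson–Hasselbalch model: at pH $p$ the net charge is

$$Q(p) = \sum_{b \in \{\mathrm{Nterm,K,R,H}\}} \frac{n_b}{1+10^{\,p-pK_b}}
       - \sum_{a \in \{\mathrm{Cterm,D,E,C,Y}\}} \frac{n_a}{1+10^{\,pK_a-p}},$$

which is strictly decreasing in $p$, so the isoelectric point (the root of
$Q$) is unique and depends only on residue composition. It is located by
bisection on $[0, 14]$, iterating until both the residual charge and the pH
bracket fall below the tolerance (default $10^{-4}$). Requiring both matters
numerically: around the pI of weakly charged peptides the titration curve is
nearly flat, and a charge-only stopping rule can halt centi-pH-units away
from the true root.

pKa values are data, not code. Two named tables ship with the package —
`"expasy-bjellqvist-like"` (default) and `"emboss-like"` — and custom tables
are accepted, because published pI values depend on an upstream calculator
whose constants are rarely stated; making the table explicit means a change
of table can never silently flip a screening verdict. Cysteines are treated
as fully ionisable (no disulfide model), `X` residues carry no charge, and
pI is computed on the sequence as given (no signal-peptide cleavage), which
the report notes. The screening threshold (7.5) is configurable separately
from the table for the same reason.

## Motif analytics

Amino-acid patterns are configuration, not code: each `pattern_spec` names
an anchor regular expression locating the conserved active-site region
(default `KHG[ST]`, a second-histidine-motif-style anchor), an offset window
after the anchor (default residues 1–5), and a site regex evaluated inside
the window. The shipped set defines `pattern4` (`R`, S-like indicative) and
the S-lineage-compatible `cgs`/`css` alternatives; slots for patterns 1–3
exist but are marked provisional, since their full residue definitions are
curation constants that a user may refine without touching code. An absent
anchor yields an *indeterminate* hit — never a negative — because the
diagnostic position cannot be located.

The SKP1/SSK1 C-terminus is analysed with the grammar
`W-A-F-x{0,3}-[DE]`, matched leftmost within the final 25 residues. This
minimal grammar covers the canonical `WAFE` and the observed inserted
variants (`WAFGE`, `WAFAE`) while still detecting decoys: a motif like
`WAFDLICL` matches at the immediate aspartate but fails the tail rules, and
`WAFEPQQ` fails the terminal-acidity rule. SSK1 consistency requires a
type-I protein, the acidic motif, a 5–9 residue tail and a terminal D (an
E-terminal switch exists because the D rule, while universal in reference
SSK1s, is a curation decision). The conserved Rosaceae tail `GVDED` is
flagged but never required. Type I/II calling uses a 250-residue threshold
(typical SKP1 proteins are ~150–190 residues; type II proteins are "much
longer" chimerics), strict inequality, configurable.

## Expression

FPKM is the closed form $C \cdot 10^9 / (N \cdot L)$ with $C$ the fragment
count, $N$ the library's total mapped fragments and $L$ the transcript
length in nt (transcript length, not effective length; for multi-isoform
genes the longest transcript is the conventional choice). Tissue
specificity uses a two-threshold scheme — expressed at FPKM ≥ 1, absent at
≤ 0.5, ambiguous between — because published screens report
presence/absence without numeric cutoffs and a single knife-edge threshold
makes specificity calls unstable; ambiguous values count as evidence of
expression when rejecting a specificity claim, the conservative direction
for a screen. A gene is tissue-specific when exactly one tissue is
expressed and all others absent. Replicate libraries are collapsed before
calling (FPKM averaged; counts and library sizes summed). Criterion 4
offers two stringencies: *strict* (style-specific) and *permissive*
(expressed in style, absent in leaf), the latter accommodating S-RNases
with low stigma/style expression; strict is the default.

## Clade placement

Reference-based classification replaces visual clade reading on a
maximum-likelihood tree with a deterministic, desk-scale equivalent:
optimal global pairwise alignment (Needleman–Wunsch/Gotoh, BLOSUM62, gap
open 11 / extend 1, affine cost $11 + L$) against the panel, Poisson-
corrected distances $d = -\ln(1-p)$ on non-gap columns (capped at 10), and
neighbor joining. ML tree inference is not the contribution here — clade
*membership* is the decision-relevant output — and NJ placement is exactly
testable: on an additive matrix it provably recovers the generating
topology and branch lengths, which the test suite verifies against a
brute-force least-squares search over all unrooted topologies. Q-matrix
ties break at the lowest index pair; a negative branch length at a join is
clamped to zero with the deficit moved to its sibling, preserving the path
length between the joined nodes. The tree is rooted at the panel's
outgroup when one is labelled (mirroring the fungal-outgroup convention of
RNase-T2 phylogenies), else at the midpoint; the query takes the majority
class of its sister group (strictly > 0.5), widening one node toward the
root once before reporting `unresolved`.

Homology gating (criterion 1) uses the self-normalised score
$\max_r s(q,r) / s(q,q)$, clamped to $[0,1]$, with a default gate of 0.25.
The gate is evaluated against all RNase-T2 panel classes, not the S-RNase
class alone: the published screens retrieved family-level homologs first
and then let pattern and clade evidence separate S-lineage from S-like
genes, and gating at family level reproduces that flow (an S-like gene is
rejected for carrying pattern 4 and placing in Class-I, not for failing
retrieval).

## The decision engine

Per gene, each criterion yields `pass`, `fail` or `unknown`. Missing
evidence — no gene model, no expression row — yields `unknown`, never
`fail`: genome-only species legitimately lack expression data, and the
engine must degrade gracefully. A gene is a `candidate` only when every
criterion is a known pass and placement is not vetoed; any fail rejects
(with machine-readable reasons that re-evaluate against the stored
features); otherwise the gene is `inconclusive` and listed for follow-up.
Evidence the screen cannot compute from sequence and expression alone —
allelic diversity, positive selection, co-segregation in crosses — is out
of scope and surfaces as an explicit unknown rather than a guess. The
verdict set partitions the input: every gene is exactly one of candidate,
rejected or inconclusive, and lowering `ip_threshold` or `homology_gate`
can only grow the candidate set (monotonicity, covered by tests).

## The synthetic-data generator

Real inputs for this screen are unpublished genomes and
assembly-version-dependent transcriptomes, so verification uses a seeded
generator whose defaults define the test conditions: 200 genes of which
10% are planted S-RNase-like positives (conserved-site anchor with a
non-pattern-4 site, pI forced into [8, 10] by greedy acidic↔basic residue
swaps at unprotected positions, 1–2 introns, style-restricted expression),
15% S-like RNase-T2 genes (pattern 4 present, pI in [4.5, 7], broad
expression, 4–7 introns), 5% SSK1-like genes (type-I length, `WAFE+GVDED`
or `WAFGE`+tail C-termini, pollen-restricted), 10% broadly expressed SKP1
genes with decoy C-termini, 5% type-II chimerics, and 55% unrelated
background. Family structure comes from mutating shared seed sequences
(18% per-residue for queries, 12% for the labelled reference panel), so
homology scores and clade placement behave like a real gene family;
background genes are unrelated draws from a typical globular-protein
residue model. Expression noise is lognormal (multiplicative, strictly
positive) around per-class tissue means at the FPKM scale, and raw counts
are derived by inverting the FPKM formula, so normalisation is exercised
end to end; intron counts are realised as literal exon structures in the
emitted GFF3. The generator never emits a real biological sequence — the
planted motifs and anchors are the only fixed substrings — and it verifies
its own output with the package's extractors before returning.

What the generator does *not* emulate bounds what passing tests show:
planted positives are genuine mutant relatives of the panel, whereas real
candidates may sit at awkward phylogenetic depths; expression is clean
lognormal noise with no batch structure, mapping artefacts or isoform
switching; sequences carry no indels relative to their family seed, so
alignment is easier than on real homologs; and decoys are planted rather
than discovered. Perfect recovery on this dataset demonstrates that the
decision logic and its plumbing are correct, not that the thresholds are
optimal for any particular genome.

## Problem sizes and numerical choices

The shipped tests run the full screens on the default 200-gene dataset,
compare bisection pI values with a $10^{-4}$-step grid oracle on 200
random peptides (agreement within $10^{-3}$ pH), verify neighbor joining
against brute-force least squares on 50 random 4–6-taxon additive
matrices, and check byte-identical reruns of the simulate-and-screen
pipeline on a 60-gene dataset; unit tests use 40-gene datasets. These
sizes were chosen so the whole suite exercises every code path in a couple
of minutes on a laptop while the oracles stay exhaustive.

Other numerical decisions: distances are capped at 10 before NJ; all
report writers emit no timestamps, so identical inputs give byte-identical
outputs; intron counts take the minimum over isoforms, since screens
report one number per gene and the least-interrupted transcript is the
relevant comparison to the 1–2-intron rule; GFF3 coordinates are 1-based
inclusive; and residue letters normalise to upper case with `X` tolerated
(charge-inert, pattern-inert, flagged above 10% content).

## Known limitations

Pairwise-to-reference placement cannot represent alignment uncertainty or
rate heterogeneity the way ML inference with branch support can; it is a
classification device, not a phylogeny. Patterns 1–3 ship as provisional
slots pending curated residue definitions. The pI model ignores
post-translational modification and structure. The screen's positive
evidence is necessarily incomplete — diversity, selection and segregation
data are required before any candidate can be called a functional
S-determinant.
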