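---
title: "Context-dependent substitution analysis: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Context-dependent substitution analysis: models, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctxsub)
```

## The inference problem

Plastome substitution dynamics depend on local sequence context: the bases
flanking a site modulate misincorporation, mismatch repair and the
spontaneous decay of modified bases, so that transition and transversion
rates — and the base composition a neutral site drifts toward — vary
strongly across tetranucleotide contexts. `ctxsub` estimates these effects
from aligned triplets (ingroup pair + outgroup) at fourfold-degenerate
(FFD) third codon positions and noncoding (NC) positions, the two site
classes where selection on the base identity is weakest.

The estimation chain is: locus filters → column polarization → per-context
4×4 count matrices → complementary folding → rates, ts:tv, ATI classes,
stationary vectors with bootstrap uncertainty, CpG odds ratios, and
FFD-vs-NC comparisons. This vignette records the modeling assumptions, the
parameter defaults and why they hold, the numerical choices, and what the
synthetic-data tests do and do not establish.

## Polarization by outgroup parsimony

For ingroup bases $x_1, x_2$ and outgroup base $o$ at one column:

- $x_1 = x_2 = o$: conserved, increments the diagonal $M_{AA}$;
- $x_1 \neq x_2$ and $o$ equals exactly one of them: the matching base is
  ancestral, the other derived, incrementing $M_{AD}$;
- $x_1 = x_2 \neq o$, or three distinct states: discarded.

The third rule is a deliberate choice. Columns where the ingroups agree but
differ from the outgroup imply a change on the deeper (unsampled) lineage;
counting them as conserved would contaminate the diagonal with sites whose
ancestral state is uncertain, and counting them as substitutions would
assign a change to the wrong branch. Discarding them loses a small amount
of data but keeps both the diagonal and the off-diagonal counts clean.
Double hits within the ingroup pair are not corrected for; counts are raw
inferred substitutions, so all rates are per-site per-triplet-comparison
quantities, not time-calibrated rates.

## Context definition and eligibility

A site's context is the flanking tetranucleotide $\{N_2 N_1 [N_0] N_1
N_2\}$. We require the four context bases to be gap-free, unambiguous and
*identical across all three sequences*: if the context itself changed
within the triplet, the context assignment of the focal substitution would
be ill-defined. Columns failing this are skipped and tallied (they are the
dominant skip reason at higher divergence; at 0.04 substitutions/site per
branch roughly a third of columns lose a flank somewhere in the triplet).
This eligibility requirement means *detection* of a substitution is
incomplete in a divergence-dependent way, while the polarization of the
columns that are emitted stays essentially error-free until double hits
become common — the two effects are measured separately by the recovery
metrics (`detection_rate` vs `polarization_sensitivity`).

For FFD sites the codon grid is read in frame; a third position is eligible
when the codon's first two bases form one of the eight fourfold-degenerate
prefixes (CT, GT, TC, CC, AC, GC, CG, GG) and are shared across the
triplet, and the context is completed across the codon boundary by the
next codon's first two bases (also shared). This yields exactly 8 × 16 =
128 possible FFD contexts. The last codon of a CDS has no downstream
context and is skipped, as is any codon whose five-column window touches a
gap or ambiguity code. NC columns closer than two positions to an
alignment end are skipped for lack of context.

## Locus filters

CDS alignments with more than 30 total gap characters (summed over all
three rows) and intergenic alignments shorter than 70 columns are
excluded. "Total gaps" is interpreted as gap characters, not gap openings
— the simplest reading — and both boundaries are inclusive on the keep
side (exactly 30 gaps or exactly 70 columns passes). The choice shifts
which loci pass but none of the downstream arithmetic.

## Complementary folding

With no evidence of strand asymmetry, a context and its reverse complement
describe one process read from opposite strands, so their matrices are
combined: counts of the non-canonical member are complement-transformed
($M'_{\bar A \bar D} \mathrel{+}= M_{AD}$, which on the fixed A,C,G,T
order is reversal of both matrix dimensions) and added to the canonical
member (the lexicographically smaller of the pair). The 256 NC contexts
fold to 136 canonical classes (120 pairs + 16 self-complementary). The 16
self-complementary contexts are stored once with their own complement
transform added, which doubles their totals but leaves every rate, ratio
and stationary vector unchanged; the convention is recorded in the output
metadata rather than silently halved, so count conservation remains
auditable. FFD contexts are folded by the same transform even though the
reverse complement of an FFD context generally does not carry an FFD
prefix; the canonical key is then just a label for the strand-symmetric
equivalence class.

## Stationary vectors and their bootstrap

Row-normalizing a folded count matrix (diagonal included) gives the
empirical one-step transition matrix $P$; the stationary vector solves
$\pi P = \pi$, computed by left eigen-decomposition and normalized to sum
to one, with the residual checked against a $10^{-9}$ tolerance. A context
with any empty row, or whose support graph is not strongly connected
(checked by boolean reachability within four steps), is flagged
(`zero_row` / `reducible`) and excluded from equilibrium analyses instead
of being assigned a fabricated vector. $\pi$ is *not* a prediction of
long-run composition — contexts do not stay conserved — but a summary
statistic of the substitution dynamics within a context, comparable across
contexts.

Sampling error of equilibrium A+T is estimated by a bootstrap that keeps
each row's diagonal and off-diagonal total fixed and redraws the row's
substitutions multinomially from the observed off-diagonal cells, 1000
resamples by default. Resampled matrices that become reducible are dropped
and counted. Each context's random stream is derived deterministically
from (master seed, site class, context) so results are independent of
iteration order; with all rows concentrated in a single off-diagonal cell
the resamples cannot vary and the bootstrap sd is exactly 0.

## ATI, reporting threshold and comparisons

The AT Index weights A/T occurrences in the context, 3 for each inner
flank and 2 for each outer flank (range 0–10); contexts with ATI > 9 are
classified A+T-rich and ATI < 5 G+C-rich. These integer weights are the
simplest set consistent with the published class thresholds, and both the
weights and thresholds are arguments, since any monotone reweighting
preserving the two threshold classes would serve. Summary outputs report
only contexts with at least 25 substitutions; all matrices are retained in
the serialized output, so the threshold is a reporting filter, not a data
filter.

FFD-vs-NC (and cross-dataset) comparisons report the least-squares $r^2$
over shared reportable contexts, the percentage of contexts with a strict
excess, and a Bayes factor for that count against an even split. The
Bayes-factor method is a binomial point null $p = 0.5$ against a uniform
Beta(1,1) alternative, $\mathrm{BF}_{10} = \frac{1/(n+1)}{\binom{n}{k}
0.5^n}$, cross-checked in the tests against numerical quadrature; the
method name is echoed in the output metadata because other reasonable BF
constructions would give different numbers. Correlations are computed on
raw rates by default with a log10 option, since the appropriate scale for
rate-like quantities is genuinely debatable.

## The synthetic-data generator

The simulator evolves a root sequence independently along the three
branches of a star tree, with per-site rates looked up from the current
tetranucleotide context; after every substitution the neighboring sites'
rates are re-read, so contexts co-evolve. Sampling uses thinning
(uniformization): candidate events arrive as a Poisson process at the
global maximal leaving rate and are accepted with probability
actual/maximal given the current state — exact for this neighbor-dependent
process and far cheaper than recomputing total rates after every event.
Two immutable flanking bases pad each end so terminal sites have defined
contexts. No indels are generated (gap handling is tested with hand-built
fixtures), and CDS roots are constrained only structurally: concatenated
codons with stop codons rejected at the root; selection is not modeled,
matching the neutral-site framing of the analysis.

Defaults are chosen once to emulate a plastome-like regime: composition
$\pi = (0.32, 0.18, 0.18, 0.32)$ (A+T-rich, as organelle genomes are), an
HKY-style rate skeleton whose transition multiplier falls linearly with
ATI from 3 (G+C-rich contexts, ts:tv > 1) to 0.8 (A+T-rich contexts,
ts:tv < 1), a 1.23× multiplier on the CpG-deamination transitions (C→T
with 3′ G, G→A with 5′ C), rates scaled to a mean leaving rate of 1 per
site per unit branch length, and branch lengths of 0.01 — closely related
congeners, where multiple hits are rare ($O(t^2)$). Note that in this
model the measured CpG odds ratio exceeds the raw 1.23 multiplier because
the ATI-dependent ts:tv is confounded with the CpG contrast (a G/C
neighbor both defines the CpG class and lowers ATI);
`expected_cpg_tables()` computes the model-implied marginal OR exactly,
and it is that number the recovery analysis compares against — with a
context-independent ts:tv the expected OR is exactly the multiplier.

What passing the recovery tests shows: polarization, context assignment,
accumulation, folding and the statistics reproduce known generator
properties from data of realistic size. What it does not show: robustness
to alignment error, indels, selection on "neutral" sites, strand-asymmetric
processes, or rate variation among loci — none of which the generator
emulates. Real-data conclusions inherit those caveats.

## Problem sizes and numerical choices

The test suite and acceptance checks run the simulator at $10^5$–$1.2
\times 10^5$ noncoding sites with branch lengths 0.01 (recovery,
stationary and strand-symmetry properties) and the analysis workflow at
$1.8\times10^5$ NC + $4.2\times10^5$ CDS columns with branch lengths 0.04
— deep enough that most contexts clear the 25-substitution reporting
threshold while double hits stay modest. Pooled (not per-context) ts:tv is
used for recovery checks at the $10^5$-site scale: with substitutions
spread over 136 context classes, a per-context ratio near the reporting
threshold carries ~40% sampling noise, so the per-context estimator is
validated instead by pooling contexts that share the generator's ratio.
Equilibrium recovery is similarly validated by pooling contexts with
identical generator stationary vectors (ATI groups in the contrast model),
which removes estimator noise without touching the signal.

Other numerics: stationary residual tolerance $10^{-9}$; power iteration
(5000 steps) as the independent oracle in tests; seeds derived by a 31-base
rolling hash folded into the master seed modulo $2^{31}-19$; alignment
columns are 1-based throughout the R interfaces. Degenerate inputs are
flagged, not guessed at: all-zero matrices yield missing rates (not 0),
empty rows yield missing row rates, zero transversions yield an explicit
undefined ts:tv flag, and an empty post-filter locus set is an error.

## Known limitations

- Counts are uncorrected for multiple hits; at the divergences the method
  is intended for (≤ a few percent per branch) the bias is small but
  nonzero, and it grows with the branch to the outgroup.
- Context-eligibility losses make absolute site counts
  divergence-dependent; rates within a context are unbiased by this, but
  cross-dataset comparisons of absolute counts are not meaningful.
- The strand-symmetry assumption behind folding is inherited from the
  reference analyses; a genuinely strand-asymmetric process would be
  averaged away.
- G+C-rich contexts are rare in A+T-rich genomes, so their matrices are
  often below the reporting threshold or reducible — an intrinsic data
  limitation, surfaced by flags rather than imputed around.
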