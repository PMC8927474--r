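---
title: "Calling structural variants from 4x long reads: models and design"
author: "svlite"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling structural variants from 4x long reads: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical models, the tunable parameters,
the synthetic-data design and the numerical choices behind `svlite`. It
states no empirical numbers beyond what the test suite and
`scripts/acceptance.R` compute.

## The problem regime

A single nanopore flowcell gives roughly 4-fold genome coverage of reads
averaging several kilobases with ~10% errors. A heterozygous structural
variant (SV) junction is then spanned by about two reads, and the depth
of a 10 kbp interval is estimated from about five reads, so both
evidence channels are individually weak. All of `svlite`'s design
follows from combining weak channels and refusing to let any single one
decide: split reads propose junctions, depth proposes copy-number
regions, a dynamic program turns either into base-pair breakpoints, and
realignment arbitrates.

## Depth model

The genome is partitioned into intervals of `L` bp (default 10,000 bp;
shorter intervals run out of reads at 4x, longer ones blur
breakpoints). Every sample profile is normalized to a 4x genome-wide
mean so samples of different yield are comparable. A reference panel of
normal samples supplies a per-interval mean `mu` and standard deviation
`sigma`; `sigma` is floored at `sigma_min = 0.3` fold-coverage units so
that small panels cannot produce degenerate zero-variance intervals,
and intervals with `mu < mu_min = 0.5` (N gaps, unmappable or telomeric
repeat tracts) are masked out of every test.

For observed depth `d`, the two hypotheses are `N(mu, sigma^2)` (no SV)
and `N(mu_SV, sigma^2)` with `mu_SV = 0.5 mu` (deletion) or `1.5 mu`
(duplication) - the heterozygous expectations. The log-likelihood ratio
is linear in `d`:

\[
\mathrm{llr}_{del}(d) = \frac{\mu(0.75\mu - d)}{2\sigma^2},\qquad
\mathrm{llr}_{dup}(d) = \frac{\mu(d - 1.25\mu)}{2\sigma^2} .
\]

An interval is *abnormal* when its llr is strictly positive; the tie at
`d = 0.75 mu` goes to normal so that degenerate inputs never flag.
Homozygous events use the same heterozygous-mean flagging (they are
further from the null than the alternative, so they flag a fortiori)
and are labelled afterwards by nearest mean: a deletion region is
called homozygous when its mean depth is closer to 0 than to `0.5 mu`,
a duplication when closer to `2 mu` than to `1.5 mu`.

Abnormal intervals are merged left to right, bridging up to
`max_gap = 2` normal intervals - enough to absorb single-interval
dropouts without fusing distinct events. A merged region is scored by
`Lambda = 2 max(0, sum llr)` over its usable intervals and referred to
a chi-square distribution with **one** degree of freedom (one free
parameter, the copy-number state); regions with `p <= 0.05` survive.
The degrees of freedom, the clipping at zero and the summation over
intervals are design choices of this package; the selection of maximal
abnormal runs before testing makes the test anti-conservative, which is
acceptable because depth regions are only *candidates* - they must
still find a supporting read and pass realignment validation.

The interval-resolution recovery property in the test suite is checked
in an averaging regime (per-interval aligned-base counts in 100 bp
units, a few percent relative noise). At raw single-sample 4x
granularity the rough breakpoints are intrinsically coarser; this is
precisely why the refinement step tolerates window-sized offsets.

## Candidate discovery from alignments

Split-read candidates come from pairs of alignment segments adjacent on
the forward read (gap or overlap at most 200 bp on the read; larger
unexplained gaps look like chimeric reads, which are a known false
positive source, and are not paired). The junction is typed purely by
reference geometry, and the stored geometry (junction read offset `q`,
exit coordinate `s`, entry coordinate `e`, segment strands) is
canonicalization-independent, so reads from either strand of the same
molecule produce identical candidates. Tandem orientation is assumed
for duplications; dispersed duplications surface as BND. Deletions of
at least `min_sv_len = 1000` bp are also harvested from long `D` CIGAR
operations. Insertions are out of scope.

## The one-free-jump dynamic program

Given a candidate junction, the read window `Q[q-w .. q+w]` is aligned
against two reference pieces `R[s-w .. s+W]` and `R[e-W .. e+w]`
(defaults `w = 2000`, `W = 10000`). Within each piece the alignment is
affine (`match +2, mismatch -4, gap open -4, gap extend -2`, a gap of
length `k` costing `open + k * extend`; values follow common
ONT-tuned conventions). Exactly one jump from the first piece to the
second is allowed at zero cost - the SV itself is never penalized. The
score is

\[
\max_{q', a, b} F(q', a) + B(q', b) + \text{jump},
\]

with `F` the best score of the window prefix ending at piece-1 offset
`a` (free start) and `B` of the suffix starting at piece-2 offset `b`
(free end). Row-maxima of two semi-global passes give the optimum in
`O(|Q| (|RA| + |RB|))` time and linear memory, independent of SV size.
The no-jump score (the window against either piece alone) is computed
from the same passes; the jump is *used* only when it strictly beats
the no-jump score, which keeps fully-alignable reads from fabricating
junctions. Ties break towards the smallest `q'`, then `a`, then `b`,
which left-aligns junctions inside microhomology tracts and makes
output deterministic. A refinement is accepted when the jump was used
and the score reaches `tau = 0.6` of the perfect-match score of the
window; the threshold quantifies "alignment not good enough", which the
underlying method leaves open.

The window geometry gives an asymmetric offset tolerance: the exit
breakpoint may err by up to `W` towards the event (and `w` away from
it), and symmetrically for the entry side. Depth-derived rough
breakpoints bracket the true event from outside, which is exactly the
tolerated direction. Minus-strand junction sides mirror the windows and
reverse-complement the piece, so inversions draw their second piece
from the opposite strand and breakends may draw from different contigs.

## Terminal deletions

A terminal deletion has a single internal breakpoint and no junction
sequence, so the split-read/SV-DP machinery does not apply. `svlite`
refines terminal depth regions by read-boundary pileup: reads from the
truncated haplotype stop exactly at the breakpoint, so the modal
alignment endpoint inside the region's inner edge (searched within the
merge overshoot, edge -3L .. +L) estimates the breakpoint; at least two
boundary reads are required, mirroring the global `min_support`.
Validation replaces the score-margin rule with an end-pileup allele
frequency: a heterozygous truncation stops about half of the
breakpoint-covering reads (AF ~ 0.5) while random read-end collisions
on an intact contig sit near 0.15 at 4x with 8 kbp reads, so the
terminal AF threshold is the midpoint, 0.3 - the same nearest-midpoint
logic as the zygosity rule. An AF estimated from fewer than three
breakpoint-covering reads carries no information, so such calls fail
with reason `low_depth` rather than passing on an empty denominator. A terminal depth loss whose breakpoint
coincides with a validated BND is suppressed: it is the footprint of an
unbalanced translocation, not a separate event.

## Validation and QUAL

The alternative reference splices the conjectured variant from the
flanks (`F = 5000` bp): deletions join the outer flanks, duplications
carry two copies, inversions reverse-complement the inner segment,
breakends join flanks across contigs honoring orientation. Inversions
have two novel junctions and reads may support either. A read supports
the call when its junction-proximal window aligns to the alternative at
least `delta = 20` score units (ten matched bases' worth) better than
to the unaltered reference and crosses the junction by at least 200 bp
on both sides - the crossing requirement prevents flank-only support.
The candidate passes with `>= 2` supporting reads and allele frequency
`>= 0.2` among junction-spanning reads; both a count and a frequency
are enforced because "attracts more reads" is ambiguous between the
two readings. Supporting reads are then re-checked against the whole
genome through the k-mer anchor index (excluding the candidate's own
windows); a read whose best alternative locus explains it nearly as
well is discounted, and the candidate needs `min_support` surviving
reads. Finally `QUAL = min(60, 10 log10(1 + sum of score gains))`,
rounded to one decimal - a package-defined combination of the
validation features.

Calls that fail validation are still written to the VCF with their fail
reasons in FILTER (`no_support`, `low_af`, `multi_locus`). Benchmarking
follows the standard protocol of filtering candidate calls by size
(>= 1000 bp) and type only, so a junction correctly refined from a
single read at 4x still counts towards sensitivity while the FILTER
column carries the validation verdict.

## Synthetic data

The generator emulates the study conditions the caller is designed
for. References are i.i.d. random sequence with 5 kbp tandem
`TTAGGG`-repeat tracts at contig ends, mimicking telomeric repetition
(and its mapping pathologies - the tracts of all ends are mutually
homologous). Seven SV types are implanted without overlap: short
(50-100 kbp) and long (120-300 kbp) deletions, duplications
(50-150 kbp), inversions (50-200 kbp), terminal deletions
(50-200 kbp), balanced translocations (reciprocal 3' swaps) and
unbalanced translocations (a derivative chromosome joining one contig's
body to another's subtelomeric tip). Heterozygous events go to
haplotype 1 only, homozygous to both. Truth records carry exact
0-based reference breakpoints.

Reads are sampled 50/50 from the two haplotypes with log-normal lengths
(mean 8 kbp, log-sd 0.5) truncated at 20 kbp, uniform positions, random
strand and i.i.d. per-base mismatch/insertion/deletion errors (defaults
0.04/0.03/0.03; the benchmark harness uses 0.04/0.02/0.02, 8% total).
Fragments spanning a molecule end are truncated there, so chromosome
ends - original or rearranged - show read-boundary pileups; this is the
physical signal terminal-deletion refinement uses. The error model is a
parametric i.i.d. injector rather than a trained basecaller profile:
homopolymer-biased errors and chimeric reads of real nanopore data are
*not* represented, so passing tests demonstrate algorithmic
correctness under calibrated noise, not end-to-end accuracy on real
flowcells. Panels are simulated as a shared log-normal per-interval
bias (log-sd 0.15, emulating region-specific sequencing bias) times
per-sample Poisson read-count noise at 4x, normalized per sample;
terminal tract intervals get zero bias, standing in for the mappability
mask a real panel pipeline would apply, and are consequently masked by
`build_panel`'s `mu_min` rule.

The benchmark harness (`run_synthetic_benchmark()`) uses a 5 Mbp
diploid genome of seven contigs (0.5-0.9 Mbp), 14 implanted SVs (two
per type), a 24-sample panel, and 4x reads - sizes chosen so a full
run takes about a minute on one CPU while each SV type appears more
than once per replicate.

## Evaluation

Calls are matched to truth type-aware (translocation truth also accepts
BND calls) with every breakpoint within the allowance (100 or 2000 bp),
one-to-one, greedily by smallest total breakpoint distance - the
matching discipline is this package's choice. Terminal deletions are
scored on their internal breakpoint only, since the contig-end
coordinate is representation-dependent. Sensitivity at 2000 bp is
monotonically at least that at 100 bp by construction.

## Known limitations

* Insertions, mobile elements and nested/multi-jump rearrangements are
  out of scope (the DP allows exactly one free jump).
* Terminal-deletion detection relies on depth plus read-boundary
  pileups; at 4x a heterozygous terminal loss can be missed outright
  when sampling noise fills in the depth trough.
* The depth route has no GC or mappability correction beyond the panel
  itself.
* The synthetic error model is i.i.d.; real-basecaller error structure
  and chimeric artifacts are not simulated.
* Determinism is guaranteed for fixed inputs and seed; external
  aligners are run single-threaded for that reason.
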