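---
title: "Methods: paired-exome CNA and allelic-imbalance calling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: paired-exome CNA and allelic-imbalance calling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(exopair)
```

## The problem

Tumor–normal whole-exome pairs carry copy-number information in their
read-depth profiles: a region present in three copies in the tumor attracts
roughly 1.5× the reads of its diploid counterpart, a hemizygous deletion
roughly 0.5×. Exome capture, however, introduces strong per-exon efficiency
differences that dwarf these signals, so absolute depth is uninformative;
only the *matched* comparison of the same exon in case and control is. On
top of depth, the allele counts at positions heterozygous in the germline
carry a second, independent signal: loss of heterozygosity (LOH) and
allele-specific gains skew the two-allele ratio in the case even when total
depth is ambiguous — copy-neutral LOH is invisible to depth entirely.

`exopair` couples the two signals. It calls copy-number alterations (CNAs)
from per-exon coverage with a matched-pairs rank test and classifies the
allelic status of every control-heterozygous position in the case, with a
deterministic simulator and a scoring harness to measure operating
characteristics under known truth.

## Coverage model and the matched-pairs test

Analysis is two-phase. The *preprocessing* phase reduces alignments or
pileups to three small tables (per-exon mean coverage and intra-exon SD for
each sample; whole-exome median/mean coverage; paired allele counts at raw
heterozygosity candidates). The *calling* phase operates only on those
tables, so filters can be re-tuned without touching the alignments.

Both samples' per-exon coverages are scaled by their whole-exome medians
onto a common coverage-like scale (the mean of the two medians). The median
is the anchor because events themselves shift the mean; a 4-fold global
case/control imbalance disappears entirely under this normalization. The
per-exon ratio is smoothed with a pseudo-count, the coverage correction
factor (CCF): `ratio = (case_norm + CCF) / (control_norm + CCF)`.

Candidate regions come from a sliding window of `window_size` consecutive
included exons (step 1). In each window the normalized pairs are compared
with a Wilcoxon matched-pairs signed-rank test: differences `d_i = case_i −
control_i`, zeros discarded, `|d_i|` ranked ascending with mid-rank ties,
`W = Σ sign(d_i)·R_i`. With more than 10 nonzero pairs the two-sided
p-value uses the mean-zero normal approximation with
`σ_w = sqrt(N_r(N_r+1)(2N_r+1)/6)`, a Yates continuity correction
`z = (|W| − 0.5)/σ_w`, and the tail evaluated as `1 − erf(z/√2)` with the
classical five-term polynomial error-function approximation (absolute error
≤ 1.5e-7). With 10 or fewer nonzero pairs the p-value is exact: all `2^N_r`
sign assignments of the observed (possibly tied) ranks are enumerated and
`p = P(|W′| ≥ |W|)`.

Two consequences of the exact regime shape the defaults. First, a window of
`w ≤ 10` exons has an attainable p-value floor of `2^(1−w)` — a window-10
scan can never go below 0.00195, so its significance threshold must sit
above that floor. Second, the floor equals the null probability of a
unanimous-sign window, so a small-window scan unavoidably seeds a fraction
`≈ 2^(1−w)` of null windows; the magnitude filter below is what controls
them.

Significant windows become *seeds*, tagged gain or loss by the sign of the
window's median difference. Overlapping same-direction seeds coalesce into
one proto-region (step-1 windows over a single event always overlap). Each
region then grows one included exon at a time, alternating ends; an
extension is kept if and only if the test over the extended region stays
significant, and an end closes permanently at its first rejection. The
growth step is incremental — inserting one difference updates `W` through
rank-shift bookkeeping (a Fenwick tree over the chromosome's sorted unique
`|d|` values once a region exceeds 64 entries) — so whole-chromosome
expansions cost `O(log n)` per step rather than a full re-ranking.
Same-direction regions whose expanded extents touch or overlap are merged
(p recomputed); opposite-direction overlaps are truncated at the overlap
midpoint so segments stay disjoint.

Final segments then pass the remaining filters:

| Parameter        | Meaning                                                        | Presets (very_small / small / medium / large) |
|------------------|----------------------------------------------------------------|----------------------------------------------|
| `window_size`    | seed window, exons                                             | 3 / 10 / 40 / 40                             |
| `p_threshold`    | significance for seeds, extensions, segments                   | 0.26 / 5e-3 / 1e-6 / 1e-6                    |
| `ccf`            | ratio pseudo-count, coverage units                             | 5 / 5 / 10 / 10                              |
| `coverage_floor` | minimum normalized coverage, either sample                     | 5 / 5 / 0 / 0                                |
| `resdf`          | max intra-exon SD / mean, either sample                        | off / off / off / off                        |
| `sdf`            | min `mean_log2`, in chromosome-SD units                  | 2 / 0.45 / 1 / 0                             |

The four presets target the size classes 3–20, 20+, 100+ and 500+ exons.
They are jointly constrained: each window must not exceed the smallest
event of its class; each threshold must clear the window's exact-p floor
(hence 0.26 for window 3, whose floor is 0.25, and 5e-3 for window 10); and
the standard-deviation-fold filter (SDF) — which discards segments whose
`|mean_log2|` falls below `sdf` times the chromosome's log2-ratio SD — is
relaxed as events grow, because large events inflate that background SD and
a strict SDF would discard the very events being sought. The small-class
SDF of 0.45 balances suppressing unanimous-sign null seeds against keeping
single-copy gains (`log2 1.5 ≈ 0.58` before dilution by expansion). No
multiple-testing correction is applied; the threshold is a raw, exposed
operating point.

## LOH / allelic-imbalance calling

Raw candidates are control positions where at least two bases reach a fixed
count of 5; only the two most frequent bases are kept (ties broken by the
fixed order A < C < G < T for determinism). A candidate is accepted as
heterozygous when the exact two-sided binomial test of the top-allele count
against proportion 0.5 of the top-two total gives `p ≥ α` (default
`α = 0.01`). The exact test was chosen over a chi-square because candidate
depth can be as low as 10, where the asymptotic test misbehaves.

Accepted positions are re-tested in the case, on the case's own two most
frequent bases. If the case still fits heterozygosity the position is in
*conserved heterozygosity*. Two guards apply: a position whose case
allelic ratio lies in [0.4, 0.6] is kept conserved regardless of p (at very
high depth the binomial test rejects biologically meaningless 52:48
imbalances), and a case pair different from the control pair is flagged
*discordant* (possible somatic variant) and excluded from smoothing.
Otherwise the total case coverage, normalized by the whole-exome median
case/control coverage, is compared with the control total, and the fold
categorizes the event: ≤ 0.75 copy-number loss; (0.75, 1.25] copy-neutral
LOH; (1.25, 1.75] +1 gain; > 1.75 gain of two or more copies. The interior
boundaries are half-open downward so the stated endpoints 0.75 and 1.75
belong to their named classes. A position uncovered in the case is reported
as a loss with fold 0 and a low-confidence flag.

Optional smoothing replaces each call's category by the modal category in a
centered window of het positions (odd size, truncated at chromosome ends);
ties keep the raw category when it is among the winners, otherwise the
first winner in the fixed category order. The raw category is always
retained alongside.

## The simulator

The generator emits exactly what preprocessing would: per-exon coverage
tables (integer-valued, as count-derived tables are), exome statistics and
paired allele counts, plus truth tables. Per exon the case copy state is
`CNobs = CNex + rnd_cn·(2U − 1)` with `CNex = 2 + delta` inside events and
`U ~ Uniform(0,1)` independent per exon; the noise is additive and
symmetric, reading the noise factor as a maximum amplitude. Both samples
additionally carry Poisson read-counting noise, `reads ~ Poisson(cov ·
exon_len / read_len)` with 150 bp exons and 76 bp reads, which ties the
noise floor to absolute depth — the feature that makes 25× data genuinely
harder than 100× data and the coverage-imbalance designs asymmetric.
Events occupy at most one randomly placed interval per fixed-size slot, so
they never overlap, and ±1 signs alternate within a replicate so that the
exome median stays a stable normalization anchor even when events cover
most of the genome.

At heterozygous positions the case first-allele count follows
`FA = round(depth · clamp(f + rnd_ai·(2U − 1), 0, 1))`, where `f` is the
copy-state expected fraction: 1/2 diploid, 0 or 1 under loss, 1/3 or 2/3
under +1, 1/4 or 3/4 under +2, the affected allele chosen at random.
Control allele counts are `Binomial(depth, 0.5)` draws: the allelic-noise
amplitude models the aberration carried by the case, not the germline, so
control het-calling behaves uniformly across noise settings. With
`count_noise = FALSE` both noise layers are switched off and the equations
can be exercised in isolation (coverages equal `base·CNobs/2` exactly;
allele counts split evenly).

Named presets reproduce the package's reference designs: `t80` (~16
80-exon ±1 events per replicate at 100×/100×), `t8000` (11 chromosomes of
12000 exons, one 6000–10000-exon event nearly always present), `t10`,
`t4`, `t3` (small events, balanced coverage), `T25H100` and `T100H25`
(10-exon events under 4-fold imbalance), and `ai_sweep` (one chromosome,
three ~200-exon events of −1/+1/+2 copies carrying 10/6/6 het positions at
100×). Replicate sizes (10 for CNA designs, 5 for AI designs) match the
reference experiments; at these sizes the full benchmark suite runs in a
few minutes on one core. The two imbalance presets carry calibrated
copy-noise amplitudes (`rnd_cn` 0.3 and 0.87): their original noise
settings are not published, so the package fixes them, once, where the
pooled sensitivities reproduce the published operating points, and records
them in the preset. All randomness flows from the single seed in the
configuration; replicate *i* of a benchmark uses `seed + i`-style offsets.

Scoring follows the region-overlap rule: a truth event is detected when
same-direction calls jointly cover at least 80% of its exons; a call
overlapping no truth event is a false positive; a truth event needing two
or more disjoint calls to reach 80% counts as hypersegmented. AI recovery
is decomposed into the three factors that bound it: control het-calling
sensitivity inside events, AI detection among control-called truth-AI
positions, and categorization accuracy among detections.

## What the simulation does and does not show

The generator emulates capture-independent counting noise, copy-number
noise, coverage imbalance and allelic-ratio noise. It does **not** emulate
per-exon capture-efficiency variation (which the matched design cancels
but which widens the ratio distribution of real pairs), GC or mappability
bias, normal-cell contamination of the tumor, subclonality, or
sequencing-error-driven false heterozygosity. Passing benchmarks therefore
demonstrate the statistical machinery under its own model; operating
points on real pairs will be less favorable, particularly for small events
at low coverage.

## Numerical and design choices

* The test statistic is the classical signed-rank sum; the continuity
  correction shrinks `|W|` by 0.5 toward zero. Its worst-case deviation
  from the exact distribution is 0.029 at `N_r = 11` and falls below 0.02
  from `N_r = 15`; the test suite asserts these measured bounds over every
  attainable `W`.
* The seed scan prescreens windows by their rolling sign-sum: a window can
  only reach the threshold if `|Σ sign(d_i)|` exceeds a bound derived from
  the maximum `|W|` attainable at each sign imbalance. The bound is
  conservative (margins for ties), so screening is a pure optimization.
* Seed direction uses the window median difference (robust to one outlier
  exon); expansion alternates ends, left first, which makes the caller
  fully deterministic; mixed-direction regions never merge.
* Exact ties in `|d|` receive mid-ranks everywhere, including inside the
  incremental expansion state; zero differences are discarded, and an
  extension onto a zero-difference exon is always accepted (the test is
  unchanged).
* Degenerate inputs: a chromosome with fewer included exons than the
  window yields no seeds (with a warning); an exome with zero median
  coverage refuses to normalize; an empty coverage table is an error for
  exome statistics.
* Intermediate and result tables are written with 17 significant digits,
  so re-reading reproduces every double bit-exactly and reruns are
  byte-identical.

## Known limitations

* **Expansion dilution.** Because an extension only needs the whole
  extended region to stay significant, a strong event tolerates hundreds
  of appended null exons before the test finally degrades; calls around
  large events are therefore systematically wider than the event, and a
  chromosome-scale event can absorb its whole chromosome. The
  overlap-based benchmarks are insensitive to this (over-covering still
  detects), but reported boundaries of large events should be read as
  generous. A boundary-refinement pass is the natural future fix.
* **Small-window false seeds.** At window 10 the exact-p floor equals the
  null unanimity probability, so ~0.2% of null windows seed regardless of
  noise amplitude. With the small-class SDF at 0.45 the 10-exon benchmarks
  favor sensitivity over precision, and a large share of their calls are
  such sign-fluke seeds; raising `sdf` inverts the trade-off, trading
  detected events for precision.
* **Allele-loss detection is aggressive by construction.** An exact
  binomial test against 0.5 essentially always rejects a position whose
  remaining-allele fraction is within noise of 0 or 1, at any realistic
  depth. AI detection under strong allelic noise (`rnd_ai = 0.3`) is
  consequently dominated by the gain classes' conserved-band overlap and
  pools near 80%, with losses detected nearly always; a detector
  deliberately more conservative on losses would require a depth-free
  heuristic the package does not implement.
* The pileup decoder accepts the classic samtools dialect only; positions
  absent from a pileup are depth 0 by convention, and mapping-quality-0
  reads are kept unless a quality policy says otherwise.
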