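---
title: "Median-based absolute quantification: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Median-based absolute quantification: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mbaq)
```

This vignette documents the statistical model behind `mbaq`, the
assumptions it rests on, the tunable parameters, and the design decisions
made where the method leaves room for interpretation.

## The calibration model

The internal standard is a chimeric protein of concatenated tryptic
peptides. Complete tryptic digestion releases those peptides in equimolar
amounts, so every standard peptide carries the same molar quantity $S$
(fmol) into the LC-MS run. Its observed XIC peak area is

$$a_i = S \cdot e_i \cdot \eta_i,$$

where $e_i$ is the peptide's ionization efficiency (a stable property of
its sequence under fixed chromatography) and $\eta_i$ multiplicative
measurement noise. The central empirical fact the method exploits is that
for proteotypic-like peptides the $e_i$ cluster: roughly half of all such
peptides fall within ±20% of their common median, while the rest scatter
up to about ten-fold. The median area of the standard's peptides therefore
estimates $S$ times the response of a *typical* peptide, and

$$f = S / \mathrm{median}_i(a_i) \quad \text{(fmol per area unit)}$$

converts any codetected peptide's area into a molar estimate
$m_p = f\,a_p$. This is a single-point calibration: it assumes XIC area is
linear in amount through the origin over the working range (about three
orders of magnitude), and that analyte peptides' efficiencies are drawn
from the same distribution as the standard's — the analyte estimate is
unbiased only in the median-efficiency sense, which is why proteins are
quantified from several peptides with a concordance check rather than
from one.

### The standard's amount

$S$ is itself measured in-run. The standard carries scrambled versions of
a few peptides of a reference protein (serum albumin in the original
design) that is codigested at a known amount $R$. A scrambled peptide and
its native counterpart are near-identical physicochemically, so their
response factors cancel in the area ratio and

$$S = R \cdot \mathrm{median}_j\!\left(\frac{a^{\mathrm{scr}}_j}{a^{\mathrm{nat}}_j}\right).$$

Pairs in which either side was not detected (area 0) are skipped and
reported. Whether the original implementation aggregated pairs by mean or
median is not stated; `mbaq` uses the median for consistency with the
method's philosophy (robustness to one misbehaving pair). With the usual
five pairs the difference is small.

### Calibrant quality: NMA and near-median fraction

The **normalized median abundance** asks: does the standard's median
response agree with the response implied by the reference pairs? We define
the reference-derived response per fmol as
$k = \mathrm{median}_j(a^{\mathrm{nat}}_j)/R$, the expected area of one
standard peptide as $S\,k$, and

$$\mathrm{NMA} = \frac{\mathrm{median}_i(a_i)}{S\,k},$$

where the median in the numerator runs over the standard's peptides
*excluding* the scrambled reference peptides — they are the normalizers,
and including them would partially cancel the very bias NMA is meant to
expose. This normalization is a reconstruction (the original describes it
only verbally); it was chosen so that NMA equals 1 exactly at the no-bias
point, scales linearly with a uniform depression of the standard's
responses (a standard whose peptides ionize at 45% of the reference-implied
response has NMA 0.45 — the signature of sequence-reversed designs), and is
invariant to global rescaling of all areas in a run. An alternative —
computing a per-peptide NMA and taking its median — differs only in
degenerate cases.

The **near-median fraction** is the share of standard-peptide areas $a$
with $|a-m|/m \le 0.20$, $m$ the median. The 20% band follows the
method's own definition of "near-median" peptides and is configurable
(`band` argument). Roughly 0.3–0.5 indicates a standard behaving like its
design; values far below suggest chromatographic or digestion problems.

Areas equal to zero mean "not detected in this run" in aligned exports
and are excluded from every median and CV; including them would drag the
calibrant toward zero whenever alignment drops a peptide.

Calibration is per run by default, since matrix effects and ionization
drift are run-specific. `calibrate_runs(..., pooled = TRUE)` adds a pooled
calibration (median over the per-run values) for users who prefer one
factor per experiment.

## Protein quantification

Each protein's detected peptides give independent molar estimates. The
selection methods:

* **TopN / Hi-3** — the $N$ (3) most abundant peptides, averaged. Ties at
  the selection boundary are broken lexicographically by sequence so
  results are platform-independent.
* **BestN** — from the Top3 pool, every size-2 and size-3 subset is scored
  by the CV of its estimates; the lowest-CV subset is kept. On a CV tie
  the larger subset wins (more peptides, same concordance). A protein with
  exactly two detected peptides keeps that pair; its QC flag
  (`cv_percent < 20`) may still fail. Single-peptide proteins are excluded
  from quantification and reported in a separate table rather than
  silently dropped.

CV uses the sample (n−1) standard deviation — with two or three values the
population form would understate dispersion. The protein amount is the
arithmetic mean of the selected estimates. An additional mean/median
concordance filter (`mean_median_consistency()`, tolerance 15%) is
available but off by default: the CV criterion is the selection rule; the
mean/median check was only ever used as a manual validation filter.

Peptides observed under more than one protein accession cannot be
attributed and are flagged and excluded by default
(`drop_shared_peptides`); protein inference is out of scope — input tables
are assumed protein-assigned.

`copies_per_cell()` converts fmol to copies via the Avogadro constant
(6.02214076e23). `percent_error()` is $100\,|x-\hat x|/x$ against an
independent reference taken as truth; published tables that mix rounding
and truncation reproduce to within one unit of the last printed digit.
`dilution_concordance()` compares two independently quantified samples
with a known dilution factor; per-protein accuracy is
$100\,(1-|r-r_0|/r_0)$ and the summary reports the mean (the conventional
"average accuracy") with the median alongside.

## How many standard peptides does the median need?

`bootstrap_median()` draws $k$ peptides *without replacement* from the
standard's detected areas and records the median per iteration (100 by
default); the CV of those medians is the spread at $k$. Sampling without
replacement reflects the design question — "how many peptides should the
standard contain?" — a subset of distinct peptides, not a resample; a
with-replacement mode exists behind a flag. At $k$ equal to the pool size
the spread is exactly 0 by construction.

`recommend_min_peptides()` returns the smallest $k$ whose spread is below
the user's threshold *and* flat — changing by less than 10% relative over
the next two profiled $k$ — a reconstruction of "reaching a plateau". On
realistic pools the spread falls steeply to roughly 5–10 peptides and
plateaus beyond ~30, which is why `median_calibrant()` warns below 30
detected standard peptides.

One numerical caveat: with 100 iterations, each spread estimate carries
roughly 7% relative Monte-Carlo noise, which exceeds the true decrease
between adjacent $k$ in the plateau region. Monotonicity of the profile
is therefore a statement about expectations — the package's tests check
it on 3-point-smoothed profiles at widely spaced $k$ and, for adjacent
$k$, statistically over many seeds.

## Designing scrambled standard peptides

A standard peptide must behave like a proteotypic peptide while matching
no natural sequence. The designer implements this as:

1. **Digestion** (`digest_trypsin()`): cleave after K/R except before P —
   the standard trypsin rule, assumed though never spelled out in most
   protocols. Coordinates are 1-based inclusive; missed cleavages up to a
   configurable count.
2. **Proteotypic filter** (`proteotypic_filter()`): fully tryptic, no
   missed cleavage, length 7–25 (common practice; the bounds are
   arguments), no Cys/Met at internal positions (oxidation and alkylation
   variability), no Asp/Glu at the N-terminus (aspartate-effect cleavage
   artifacts).
3. **Scrambling** (`scramble_peptide()`): exactly two events — one swap of
   two non-C-terminal residues of different identity, and one substitution
   from a conservative table, preferring the middle third of the sequence
   (falling back outward), chosen so the monoisotopic mass changes. The
   C-terminal K/R is untouchable (tryptic behavior and y-ion chemistry),
   and the nonzero mass shift guarantees the product can never be confused
   with its source in a spectrum. The substitution table is S↔T, D↔E,
   N↔Q, F↔Y, and aliphatic neighbours along G < A < V < L < I, plus V↔I
   (Kyte-Doolittle 4.2 vs 4.5 — closer than several sanctioned neighbour
   pairs, and used by published scrambled designs). Only the S↔T and
   aliphatic rules are documented by the method's authors; the remainder
   of the table generalizes the same "similar side chain" principle and is
   configurable in source.
4. **Validation** (`validate_scramble()`): infers the minimal edit script
   between a native/candidate pair (pairing differing positions into
   swaps wherever residues cross-match, exhaustively — peptides are
   short), then checks: ≤2 events, at most one swap, substitutions within
   the table, unchanged C-terminus, nonzero mass delta, product ≠ source.
   Note that two substitutions with no swap is a valid script — published
   scrambled pairs use that pattern.
5. **Uniqueness** (`uniqueness_check()`): the candidate must not occur as
   a substring of any protein in the supplied proteome FASTAs nor equal
   any tryptic peptide (≤1 missed cleavage) of them. Substring matching
   subsumes the tryptic check; both are reported because a tryptic-level
   hit is the operationally dangerous one (it would coelute as a real
   peptide). Which level the original used is unstated; `mbaq` applies
   both.

Retention-time shifts are *not* predicted. The mean Kyte-Doolittle
hydropathy delta is reported as a proxy with a warning above |0.5|
(configurable); observed shifts of scrambled peptides are
instrument-specific and no portable model exists.

Sequence reversal (`reverse_except_cterm()`) is provided for completeness
but is the documented negative control: reversed peptides ionize far from
their sources (NMA near 0.45 rather than 1) and should not be used for
standard design.

## The synthetic-data generator

`simulate_dataset()` generates the study conditions the package is
validated under:

* analyte amounts log-uniform over 1–1000 fmol (three orders of
  magnitude, the method's working range);
* a 43-peptide standard chimera plus 5 native/scrambled reference pairs —
  the composition of the original designed standard — at 300 fmol, with
  1000 fmol (1 pmol) of reference protein;
* ionization efficiencies per peptide from a near-median mixture: with
  probability 0.45 uniform in [0.8, 1.2] ("near-median"), otherwise a
  lognormal tail (σ = ln(10)/4) truncated outside the ±20% band and
  capped at √10, so the realized near-median fraction matches its target
  and the overall spread stays within ten-fold;
* replicate noise lognormal with σ = 0.1 (≈10% technical CV, the level at
  which the calibrant's quality statistics show "<10% error" behavior),
  redrawn per run; 3 technical replicate runs by default, the usual
  replicate depth of the experiments this emulates;
* native/scrambled pair members share their replicate noise draw
  (coeluting twins), so realized pair-area ratios stay within the ±5%
  pair factor — matching the observed behavior of scrambled reference
  peptides;
* `dilution` scales analyte amounts only; simulating with the same `seed`
  but a different `noise_seed` yields a technical twin (same proteins,
  amounts, efficiencies; independent noise) for dilution-concordance
  studies.

What the generator does **not** emulate: missing-value mechanisms beyond
area = 0, inter-run alignment artifacts, digestion kinetics (miscleavage
rates), charge-state splitting, matrix-dependent suppression that
correlates with retention time, and protein-level interference. Passing
tests on this generator therefore demonstrate the *algorithmic*
correctness and statistical behavior of the pipeline under its own model,
not performance on any particular instrument.

A property worth knowing when interpreting recovery numbers: with a
48-peptide standard whose efficiencies come from the mixture above, the
sampling error of the standard's median is about 6% (density ≈1.1 at the
median gives SE ≈ $1/(2\cdot1.1\sqrt{48})$), and it is shared by all
proteins of a run. Per-seed median recovery error is therefore typically
around 20% but fluctuates with that calibrant draw; dilution comparisons
between twins are *more* accurate than absolute recovery because the
standard's efficiency draw cancels in the ratio.

## Problem sizes and numerical choices

The shipped tests and the acceptance script use: 1000 random instances
for the BestN-vs-enumeration oracle; 100 random instances for scale
invariance; 50 simulation seeds at 200 proteins × 5 peptides × 3 runs for
parameter recovery; one twin pair at the same size for dilution
concordance; a 230-peptide lognormal (σ = 0.8) pool profiled at
k = 3…120 with 100 iterations for the bootstrap, recommending the minimum
peptide count at a 20% spread threshold (moderate: the same 20% used as
the quantification CV threshold). These sizes were chosen to make the
statistical assertions stable while keeping a full run in the tens of
seconds.

Other numerics: medians are the built-in sample median (mean of central
order statistics for even n); CV ties in BestN resolve to the larger
subset, then to the lexicographically first enumeration; bootstrap seeds
per k are derived as `seed + 7919 * k` so profiles are reproducible and
k-independent; all randomized algorithms take explicit seeds and restore
the caller's RNG state.

## Known limitations

* The default input column mapping targets one export dialect
  (`default_column_map()`); other tools' headers must be mapped
  explicitly. Wide-format exports (one column per run) must be melted
  before import.
* Quantification assumes complete digestion of the standard; miscleaved
  standard peptides would bias the median low. The proteotypic filter
  screens candidate peptides for design, but the calibrant itself is not
  miscleavage-corrected.
* NMA requires detectable reference pairs; without them the package can
  still calibrate from a user-supplied standard amount, but no bias check
  is possible.
* Shared-peptide handling is exclusion, not apportioning.
* The scrambler searches single (swap, substitution) combinations; it
  reports failure rather than exploring multi-substitution scripts, which
  the validation mode nevertheless accepts when ≤2 events.
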