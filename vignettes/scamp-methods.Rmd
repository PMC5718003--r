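---
title: "Correlating mass and activity profiles across chromatographic fractions"
author: "scampr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Correlating mass and activity profiles across chromatographic fractions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scampr)
```

## The model

Bioassay-guided fractionation classically alternates purification and
assay rounds until single actives are isolated — slow and expensive. The
SCAMP shortcut separates the extract *once* into N sequential fractions
(33 by default here, matching 2-minute collection windows on a
preparative column), measures a high-resolution mass spectrum and one
bioactivity value per fraction, and asks, for every observed mass bin j,
how similar its intensity profile

$$M_j = (m_{1j}, \dots, m_{Nj})$$

is to the activity profile $A = (a_1, \dots, a_N)$. Both vectors are
scaled to unit Euclidean norm and compared by their dot product, reported
on a 0–100 scale:

$$C_j = 100 \sum_{k=1}^{N} a_k^0\, m_{kj}^0 .$$

For non-negative profiles $C_j \in [0, 100]$ (Cauchy–Schwarz), with 100
exactly when the bin's profile is proportional to the activity. The scale
factor of 100 is a reporting convention: published $C_j$ values and
thresholds in this field (e.g. background filters near $C_j > 30$) only
make sense on a percent-of-perfect-correlation scale, so the package
reports $C_j$ ×100 everywhere and consistently.

The underlying assumption is *additivity*: the fraction activity is
approximately a weighted sum of the amounts of the active constituents,
so an active compound's amount profile is (up to noise from the other
actives) proportional to the activity wherever it elutes. Strong synergy,
antagonism or saturating dose–response curves break this premise; the
simulator below makes the same assumption explicitly.

### Score 2: concentration dependence

$C_j$ alone is scale-free: a trace compound perfectly tracking the
activity outranks an abundant one tracking it slightly less well, even
though a trace compound cannot move a bulk assay. Score 2 therefore
multiplies by the bin's total raw intensity $I = \sum_k m_{kj}$:

$$\mathrm{Score\,2} = C_j \times I .$$

### Score 3: chromatographic grouping

One m/z bin can hide several structural isomers with different retention
behavior: the bin profile then shows separated elution bumps, and its
whole-profile $C_j$ can overstate (or average away) each individual
component. Method 3 splits every bin profile into *groups* — maximal
contiguous runs of fractions whose intensity is strictly above the
profile mean — and treats each group as an independent candidate:

$$\mathrm{Score\,3} = \frac{C_j\, \sigma^2 I}{N_f^2},$$

with $\sigma$ the population standard deviation and $I$ the sum of the
raw in-group intensities, and $N_f$ the group width in fractions. The
$\sigma^2 / N_f^2$ factor rewards sharp, concentrated elution and
penalizes broad flat profiles (solvent background, column bleed), which
tend to correlate weakly-but-positively with everything.

Two deliberate choices here:

* **Masked-profile $C_j$.** A group's correlation is computed on the
  full-length profile with out-of-group fractions zeroed, against the
  full normalized activity vector — not on a truncated subvector. This
  keeps every candidate's $C_j$ on one comparable scale. A useful
  consequence, asserted by the tests: when activity spans both elution
  regions of a two-isomer bin with comparable amplitude, each group's
  $C_j$ drops below the ungrouped value (the whole profile was borrowing
  correlation from both components); when activity covers only one
  region, grouping isolates the true contributor at $C_j \to 100$ and
  sends the other to $\approx 0$. (Note the first behavior requires the
  amplitude ratio of the two activity bumps to lie roughly within
  $(\sqrt2 - 1,\ \sqrt2 + 1)$; outside that band the on-target group's
  $C_j$ can legitimately rise above the ungrouped value.)
* **Population SD on raw intensities.** $\sigma$ uses the divide-by-$N_f$
  form — the sample SD would be undefined for every single-fraction
  group. Whether the original method computed $\sigma$ and $I$ on raw or
  on per-bin-normalized intensities is not documented; this package uses
  raw intensities, which makes Score 3 scale as (abundance)³ within a
  dataset. Absolute Score 3 values are therefore only comparable within
  one run; the ranking is what the package asserts. Published absolute
  scores may differ by constant factors under other normalization
  conventions. A single-fraction group has $\sigma = 0$ and hence
  Score 3 = 0 — isolated one-fraction spikes (noise) are structurally
  disfavored by method 3.

Ties in any ranking are broken deterministically: score descending, then
m/z ascending, then start fraction ascending.

## Preprocessing

The chain is fixed as S/N filter → blank subtraction → de-isotoping →
binning, mirroring how FT-ICR peak lists are normally reduced.

* **S/N filter** keeps peaks with S/N *strictly* greater than the
  threshold (default 4, the usual vendor export cut); peaks lacking an
  S/N value are kept and counted.
* **Blank subtraction** averages the replicate blank spectra (peaks
  merged within 1 ppm; a replicate missing a peak contributes 0 to the
  mean) and removes a sample peak only when a blank peak matches within
  tolerance *and* the sample intensity is at most `ratio` (default 3)
  times the blank intensity. The ratio guard keeps a strong genuine
  signal that happens to coincide with a trace blank peak;
  `ratio = Inf` reproduces removal on mass match alone.
* **De-isotoping** walks peaks in descending intensity (ties by
  ascending m/z); every still-retained peak queries +1…+3 × 1.0033548378
  Da (the ¹³C–¹²C mass difference) within a ppm tolerance (default 1)
  and removes lower-intensity matches. Removed peaks never query, so a
  satellite cannot delete peaks on its own. The operation is idempotent
  and never removes a fraction's base peak. An optional intensity
  plausibility check (satellite/parent ratio against the carbon-count
  expectation) exists but is off by default — the classical procedure
  tests mass differences only.
* **Binning** clusters peaks from all fractions greedily in descending
  intensity: a peak joins the nearest existing bin when within `binPpm`
  (default 0.5, matching 15 T FT-ICR accuracy) of the bin's running
  intensity-weighted centroid, else seeds a new bin. A fixed m/z grid
  would split compounds straddling grid edges; centroid clustering keeps
  each compound in one bin. Within a bin, same-fraction peaks are
  summed; total intensity is conserved exactly. The acquisition range
  defaults to m/z 120–1200 (1081 unit-resolution bins; the helper
  `countUnitBins()` does that arithmetic).

All operations canonicalize peak order first, so results are independent
of input ordering.

## Mass arithmetic

Monoisotopic masses use the NIST-recommended atomic masses (¹H
1.00782503207, ¹²C 12, ¹⁴N 14.0030740048, ¹⁶O 15.9949146196, ³²S
31.97207100, ³¹P 30.97376163). The deprotonated ion is
$[M\!-\!H]^- = M - 1.00727646688$ Da — the proton mass, i.e. the electron
stays with the ion. Dropping the electron term shifts every value by
~0.55 mDa, an order of magnitude beyond FT-ICR accuracy, and would fail
the reference checks; the tests pin all eleven standard [M−H]⁻ values to
1×10⁻⁵. Masses are carried at full double precision and rounded only for
display (5 dp). Candidate matching reports signed mDa errors,
`(observed − calculated) × 1000`, sorted by magnitude. De-novo formula
generation and adducts other than [M−H]⁻ are out of scope.

## Enrichment evaluation

A ranked list with known actives is summarized by its enrichment curve —
the fraction of actives recovered as a function of how far down the list
one screens — and the trapezoidal area under it. The default convention
(`"roc"`) advances x by 1/n_inactive per inactive and y by 1/n_active per
active: it is the only convention in which the two anchor claims hold
exactly for finite lists — an ideal ranking scores 1.0 and random scoring
0.5 in expectation. The literal "percent of database screened" x-axis is
available as `"screened"`; under it an ideal ranking reaches only
$1 - n_\mathrm{active}/(2n)$. Candidates with tied scores contribute one
diagonal segment (the average over their orderings), so ties cannot make
the AUC depend on input order. Matching candidates to known actives is by
ppm tolerance on the bin center (default 1 ppm, configurable — published
rankings never state their matching tolerance, so it must be a
parameter).

## The simulator's stated world

`simulationConfig()` fixes a concrete, realistic experiment so that every
pipeline stage can be tested against ground truth without any external
data:

* 33 sequential fractions; 200 compounds uniform over m/z 120–1200;
  8 planted actives.
* Gaussian elution with SD 1.0–2.0 fractions (peaks a few minutes wide
  under 2-min collection windows), centers uniform over the fractions.
* Log-normal abundances, meanlog = log(2×10⁴), sdlog = 1.5 — a few
  dominant constituents over a long trace tail, as in real extracts.
* **Actives are drawn from compounds at or above the 90th abundance
  percentile.** This is a statement about the assay, not a convenience: a
  bulk radical-scavenging measurement on whole fractions can only be
  driven by major constituents, and validated reference actives in this
  kind of experiment are well-detected, nanogram-quantified compounds.
  Pilot simulations make the flip side explicit: if actives are drawn
  from the whole abundance distribution, Score 3's intensity factor
  (∝ abundance³) swamps the correlation signal and enrichment collapses
  toward AUC ≈ 0.8 — low-abundance actives are invisible to the method by
  construction, which users should understand as a method limitation,
  not a simulator artifact.
* Potency weights log-normal (sdlog 0.25); activity
  $a_k = \sum_i w_i\,\mathrm{amount}_{ik}$ over actives, rescaled to a
  0–100 assay-like scale, plus Gaussian noise with SD 5% of the maximum,
  clipped at 0.
* 40 background peaks shared between blanks and all fractions (±10–20%
  intensity jitter), 3 replicate blank spectra; 25 random noise peaks
  per fraction at 0.5–6× the noise floor (most fall under the S/N > 4
  cut); S/N = intensity / noise floor (250 counts); +1/+2 ¹³C satellites
  at the binomial-expected ratios for a carbon count of ≈ m/z / 22;
  0.1 ppm Gaussian mass jitter.
* One mandatory seed drives every draw; the global RNG state is saved
  and restored, and identical seeds give identical datasets.

What the simulator does **not** emulate: ionization suppression,
retention-time drift between fractions in minutes, isotopic fine
structure beyond the +1/+2 ¹³C expectation, correlated assay error, and
compound-dependent response factors. A green end-to-end test therefore
establishes that the implementation recovers planted signals under the
stated assumptions — not that the method succeeds on any given real
extract.

With these defaults the full method-3 pipeline recovers the planted
actives robustly (pilot over 50 seeds: mean enrichment AUC ≈ 0.96, on
average ≈ 7 of 8 actives in the top 20); the test suite asserts
AUC ≥ 0.9 and ≥ 6/8 in the top 20 at one fixed seed.

## Numerical and degenerate-input choices

* All-zero profiles (bin or activity) give $C_j = 0$; candidates are
  retained with score 0 rather than dropped.
* `normalizeVector()` maps the zero vector to itself (flagged degenerate
  downstream) instead of erroring.
* The discretized Gaussian elution profile is computed with the max
  subtracted before exponentiation, so widths down to the
  indicator-function limit are stable.
* The optional $C_j$ background filter (`minCj`) is off by default:
  published usage varies between thresholds of 30 and 33, so no default
  is asserted; it only removes candidates with $C_j \le$ the threshold.
* Readers reject NaN/Inf cells and name the offending row; activity
  files must cover fractions 1..N without duplicates or gaps; whether an
  external binned matrix is raw, per-row unit-norm, or per-row
  percent-of-maximum is detected and recorded in the object metadata
  rather than silently rescaled. The %DPPH-remaining → activity
  conversion (`100 − x`) is an explicit reader option, never implicit.

## Known limitations

* Correlation is computed on non-centered, non-negative vectors; bins
  with broad low-level presence correlate mildly with everything
  (method 3's $\sigma^2/N_f^2$ factor is the designed counterweight).
* Multiple actives dilute each other's $C_j$ (with $n$ comparable
  disjoint actives, each caps near $100/\sqrt{n}$); discrimination then
  leans on the intensity terms.
* Score 3 = 0 for single-fraction groups — a genuinely sharp compound
  eluting entirely within one fraction is invisible to method 3.
* No multiple-testing control and no uncertainty on AUC differences are
  provided; the ranking is a prioritization device, not an inference.
* Formula assignment is candidate matching only; no de-novo elucidation.
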