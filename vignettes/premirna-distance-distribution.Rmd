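---
title: "Methods: the pre-miRNA distance distribution and panel similarity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the pre-miRNA distance distribution and panel similarity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(premirdist)
```

# The problem

A miRNA biomarker panel is a set of miRNAs reported for a disease,
vaccine response, or other condition. When the panels of two conditions
contain highly similar sequences, that similarity is circumstantial
evidence of an association between the conditions. "Similar" needs a
yardstick: this package builds it from the precursor (stem-loop)
sequences themselves, by computing every pairwise distance in a hairpin
catalog and fitting a reference distribution, so that any distance can
be expressed as a percentile rank. Precursor sequences are used rather
than mature ~22-nt sequences because the mature duplex is excised from
the precursor, which carries more sequence context.

# Distance model

## Alignment

Hairpins are 50–180 nt and unequal in length, so each pair is first
globally aligned (Needleman–Wunsch, end-to-end, via Biostrings). The
default scoring is a NUC44-style nucleotide scheme: match +5, mismatch
−4, gap-open 8 and gap-extend 8 as penalty magnitudes (a length-k gap
costs 8 + 8k). All four values are exposed through
`alignment_params()`; published distances for a catalog are exactly
reproducible only under the scoring they were computed with, and the
original toolbox settings behind the published human-catalog numbers
are not fully documented, so agreement at the third decimal rather than
the sixth should be expected across reasonable scoring choices.

Columns containing a gap are excluded from both the compared-site count
L and the mismatch count X by default (the standard p-distance
convention); `gap_columns = "counted-as-mismatch"` keeps them and
scores them as differences. The aligner's traceback is deterministic,
and `align_pair()` additionally canonicalizes the argument order before
aligning, so (L, X) is symmetric in its arguments by construction.

A note on gap penalties: under a *linear* 8-per-column gap cost the
optimal alignment of an equal-length pair with 30% point substitutions
is not always gapless — the aligner will occasionally buy back a few
mismatches with short gaps, perturbing p̂ below the planted fraction.
The affine default (open 8, extend 8) keeps such pairs gapless, which
is what makes the planted-substitution oracle in the test-suite exact.

## Jukes–Cantor correction

The observed proportion of differing nucleotides p̂ = X/L is corrected
to substitutions per site:

$$K = -\tfrac{3}{4}\,\ln\!\left(1 - \tfrac{4}{3}\hat p\right).$$

The one-parameter model assumes equal substitution probability among
A, C, G, U — the reason the package insists on a clean four-letter
alphabet (FASTA in DNA letters is accepted, T is mapped to U; IUPAC
ambiguity codes are rejected unless explicitly allowed). The correction
diverges at p̂ ≥ 3/4: such pairs are stored as `Inf` with a parallel
`saturated` mask, never silently capped or dropped. Pairs *just below*
3/4 map to very large finite K — this is the origin of the extreme
right tail (maximum ≈ 27 substitutions/site) in the published human
catalog, a floating-point near-saturation artifact that the package
deliberately preserves rather than truncates, because the published
percentile table's 100th row is exactly such a value.

# Distribution fitting

Four candidate families are fitted by `fit_distance_distribution()`:

* **Normal**: μ = sample mean, σ = sample standard deviation with the
  n−1 denominator (at catalog scale the n vs n−1 difference is far
  below print precision). The published σ̂ = 0.44501 for the human
  catalog is a standard deviation, not a variance, as its magnitude
  shows.
* **Exponential**: maximum likelihood, mean 1/λ = sample mean.
* **Smoothed ECDF**: the step function F̂ₙ(x) = n⁻¹Σ 1{xᵢ ≤ x} is
  linearly interpolated between one node per distinct order statistic,
  placed at the midpoint plotting position (x₍ᵢ₎, (i − ½)/n) (tied
  blocks use the center of their rank range), clamped to 0 strictly
  below the minimum and to 1 at and above the maximum. The midpoint
  convention was chosen over right-continuous (x₍ᵢ₎, i/n) nodes
  because it treats the two tails symmetrically and gives the natural
  two-point behavior (for data {1, 2} the smoothed CDF at 1.5 is 0.5);
  the hard boundary clamp keeps the step function's exact boundary
  values. The jump of ½n at each end is immaterial at any realistic n.
* **Gaussian KDE**: CDF n⁻¹ Σ Φ((x − xᵢ)/h), support unbounded — a
  little probability mass below zero is accepted as a model artifact
  rather than clipped, matching how the published human-catalog model
  was specified.

## Bandwidth

The default bandwidth is `reference_bandwidth()` = 0.00973513
(substitutions/site), the documented value of the published human
hairpin model, so that the reference percentile table is reproducible
from the raw catalog. Its origin is unstated in the source material and
it is far below the normal-reference rule's value for those data
(≈ 0.026), so `bandwidth = "auto"` — which implements
h = 1.06·min(sd, IQR/1.349)·n^(−1/5) — will *not* reproduce it; "auto"
is the sensible choice for any other catalog and is what the package's
own synthetic studies use.

## Numerical evaluation

Exact KDE CDF evaluation sums n kernels per point; above n = 32768 the
package switches to a grid of 2^15 abscissae spanning the data range
± 5 bandwidths, with exact CDF values at the grid points and linear
interpolation between them (`kde_mode` forces either path). At that
resolution the interpolation error is well below 1e−6 in CDF, which is
the tolerance the test-suite enforces against exact summation.
Quantiles of the KDE are found by safeguarded root-finding
(`uniroot`, tolerance 1e−10) on the CDF; the normal and exponential
families use their closed-form quantile functions, and the smoothed
ECDF inverts its piecewise-linear nodes directly. Degenerate inputs are
handled explicitly: a constant sample gives σ = 0 with a warning in the
normal family, an error for the automatic bandwidth (no spread to
scale), and a one-atom ECDF whose samples are all the atom.

# Model checking and selection

`select_model()` draws `n_check` points from each fitted model
(inverse-CDF sampling; for the KDE, a data point plus Gaussian noise of
scale h — the exact generative form of the kernel mixture) and compares
them with the data using the two-sample Kolmogorov–Smirnov test,
ranking families by p-value. D is computed exactly over the pooled
points, ties included; the p-value uses the asymptotic Kolmogorov
series at λ = √(n₁n₂/(n₁+n₂))·D, appropriate because one sample is
always very large. The default `n_check = 66` mirrors the published
protocol; it gives the comparison very low power, which the package
surfaces with a message whenever `n_check < 100` — the *ranking* is
informative, the absolute p-values are not. All sampling flows from a
single seed with per-family child seeds, so a selection table is
reproducible.

# Percentiles and panel scoring

`quantile_table()` tabulates model quantiles for q = 5, 10, …, 100,
with one deliberate convention: the q = 100 row is the maximum
*observed* distance, because the KDE's true 100% quantile is +∞ and
only the sample maximum yields a meaningful table entry.

Two percentile semantics coexist because both are used in practice:
continuous rank 100·F(d) (the default for panel scoring) and
nearest-table lookup, which returns the tabulated q whose value is
closest to d (ties to the smaller q) — the rule one applies with a
printed percentile table, reproduced by the packaged human reference
table (`reference_percentile_table()`; distance 0.81 → 15th
percentile). A panel is scored by the continuous percentile of its mean
pairwise distance; `is_similar()` applies a strict `< threshold`
verdict. No global threshold is hard-coded — the appropriate cut-off is
a scientific choice the user must supply. Saturated pairs inside a
panel are excluded from the mean with a warning (a single +∞ would
destroy the statistic silently); duplicate resolutions are kept as
distinct members, warned about, because published pair counts assume
every listed name is a member.

## Name resolution

Published panels print names like "miR-323" or "let-7a" without species
prefix, arm letter, or locus suffix. Resolution case-folds the query,
prepends the species prefix, and matches at the first successful level
of: exact identifier, locus-suffix-stripped (let-7a → hsa-let-7a-1/2/3),
then arm-letter-stripped (miR-323 → hsa-mir-323a/b). Ambiguity is
resolved by the deterministic `multi-locus-first` policy
(lexicographically first locus, with a warning listing all candidates)
unless the caller injects an explicit name→identifier map; which locus
a published analysis actually used is typically unstated, so
determinism plus auditability plus an override was preferred over
guessing.

# The synthetic generator

`generate_fixture_catalog()` draws i.i.d. sequences (uniform lengths,
configurable base composition) and is the byte-reproducible fixture
source; `plant_mutations()` substitutes an exact count of positions,
giving pairs with *known* p-distance — the oracle used throughout the
tests. `generate_family_catalog()` emulates what makes a real hairpin
catalog non-trivial: paralog families. Most families are singletons;
sizes up to 12 occur with small probability (mirroring families like
let-7 and the large clustered paralog groups); family members are
copies of a seed sequence with a planted substitution fraction uniform
on [0.02, 0.35]; composition is mildly G-rich, lengths 50–180 nt; and
multi-member families alternate arm-letter and locus-suffix naming so
that name-collision handling is exercised. The package's desk-scale
studies use the defaults (70 families, ≈ 150–200 sequences, ≈ 10⁴–2·10⁴
pairwise distances), sizes chosen to keep the full test-suite and the
acceptance script in the minutes range while leaving every code path at
realistic dimensionality.

What the generator does **not** emulate — and therefore what passing
synthetic tests do and do not show — deserves emphasis. Real catalog
distance data have an extreme near-saturation tail (K up to ≈ 27)
caused by a handful of pairs with p̂ within rounding of 3/4; i.i.d. or
family-structured random sequences never reach saturation after
alignment (the aligner finds enough chance matches), so the synthetic
distance distribution is smooth, right-skewed and *moderately* peaked,
without the outlier-inflated standard deviation of the real data. It is
precisely that inflation that makes the real catalog reject a normal
fit so decisively; on synthetic catalogs the normal baseline fits far
better, and a 66-point KS check frequently fails to reject it.
Synthetic tests therefore validate the machinery — exact distances,
correct fitting, correct ranking behavior when the truth is known —
but statements about which family wins on *real* hairpin data require
the real catalog.

# Known limitations

* Stem-loops only: mature-arm identifiers (miR-21-5p) are out of scope.
* Jukes–Cantor only: no Kimura or other corrections, by design.
* No tree building, no multiple sequence alignment, no multiple-testing
  correction across panels, and no permutation null for panel means
  (a natural future extension).
* Exact reproduction of third-party published distances depends on
  their (partially undocumented) alignment settings; the package makes
  its own defaults explicit and configurable instead of claiming
  bit-level fidelity.
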