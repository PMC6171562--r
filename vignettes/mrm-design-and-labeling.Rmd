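---
title: "MRM transition design and stable-isotope labeling analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{MRM transition design and stable-isotope labeling analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrmflux)
```

## Scope and model of the method suite

`mrmflux` is the computational side of a single-column LC-MS/MS workflow
for central-carbon, amino-acid and nucleotide metabolism on a
triple-quadrupole instrument. Each analyte is acquired as one or more
multiple-reaction-monitoring (MRM) transitions: a precursor m/z selected
in Q1 and a fragment m/z in Q3, at an empirically tuned collision energy
(CE) and retention time (RT). The package holds that transition library
in machine-readable form, recomputes every predictable Q1/Q3 from
molecular formulas, designs the labeled-channel ladders used for
^13^C/^15^N tracing, quantifies chromatographic peaks, converts channel
areas into isotopologue distributions, and simulates or fits the
kinetics of label incorporation.

## Mass arithmetic and the two mass modes

Transition settings on unit-resolution quadrupoles are printed as
integers (or one-decimal floats), so the default mass mode is *nominal*:
integer element masses, and a proton that counts as exactly 1 Da. This
reproduces the printed library bit-exactly (AMP [M+H]^+^ = 348,
glucose 6-phosphate [M−H]^−^ = 259). A *monoisotopic* mode with exact
isotope masses is available for high-resolution work; for every CHNOPS
formula in the library below ~600 Da, the rounded monoisotopic [M+H]^+^
equals the nominal value (beyond that, accumulated mass defect can shift
the rounding), which the test suite checks over the whole library.

Positive polarity always pairs with proton gain and negative with proton
loss — the only two ionization modes the methods use — and the
constructor rejects any other combination.

### OBHA derivatization stoichiometry

Carbonyl- and carboxyl-bearing metabolites (TCA-cycle acids, pyruvate,
methylglyoxal, glyoxalate, and several amino acids) are detected after
condensation with *O*-benzylhydroxylamine (OBHA, C~7~H~9~NO) activated
by EDC. Each derivatized site gains OBHA and loses water, a net formula
change of +C~7~H~7~N and exactly +105 Da nominal per site:

```{r}
ion_mz(derivatize_obha("C3H4O3", 2), "positive")   # bis-OBHA pyruvate
ion_mz(derivatize_obha("C6H8O7", 3), "positive")   # tris-OBHA citrate
```

The number of derivatized sites is a curated per-analyte attribute,
never inferred from the formula: the library records glutamate as
mono-derivatized (Q1 253) despite its two carboxyl groups, because that
is what the optimized method observes. The one systematic outlier is
glutamine-OBHA, printed at Q1 251 where the stoichiometry gives 252;
the validator flags it with its curated annotation (plausibly in-source
ammonia loss, or a typo) instead of absorbing it.

```{r}
v <- validate_library()
table(v$status)
v[v$status != "exact-match", c("entry_id", "q1_printed", "q1_predicted")]
```

### Fragment specifications

Q3 values are predictable where fragmentation is chemically curated:
nucleotides release their protonated nitrogen base (AMP 348 → adenine
136), sugar phosphates share the dihydrogen-phosphate reporter 97 in
negative mode, OBHA derivatives share the benzyl cation reporter 91
(printed 91.2), and several transitions are clean neutral losses (e.g.
the 123 Da OBHA loss behind succinate 329 → 206). Fragments without a
curated composition are stored verbatim and classified not-predictable;
the printed values remain authoritative for acquisition either way, and
prediction exists to validate the library and extend it to new
analytes. Deviations are compared after rounding to unit resolution,
since printed product values carry one decimal of calibration offset.

## Isotopologue ladder design

For a tracer element with `n_total` labelable atoms in the precursor of
which `n_frag` sit in the monitored fragment, a precursor with *k*
labels can place *j* in the fragment whenever

max(0, k − (n_total − n_frag)) ≤ j ≤ min(k, n_frag),

and the channel is (Q1 + k, Q3 + j) — unit shifts per label in nominal
mode (exact shifts 1.00336/0.99703 for ^13^C/^15^N are available for
high resolution). Because Q1 and Q3 shift independently, moieties are
resolved: for AMP monitored by base release, ^15^N has
n_total = n_frag = 5 (all nitrogens in the base, so j = k and the
ladder is the six channels 348/136 … 353/141), while ^13^C has
n_total = 10, n_frag = 5 (five base carbons, five ribose carbons; 36
feasible channels).

```{r}
amp <- load_mrm_library() |> subset(entry_id == "AMP.pos")
lad <- generate_ladder(amp, label_scheme("C", 10, 5))
select_channels(lad, "q3-tracks-fragment")[, c("name", "q1", "q3")]
```

Published tables print a subset of the grid: the suffix-free series
keeps every label in the fragment while it fits (j = k up to k = 5) and
then holds the ribose saturated (j = k − 5), plus the
fragment-unlabeled channels such as the all-ribose 353/136. The
`select_channels()` policies reproduce exactly these editorial subsets.
CE is inherited from the unlabeled base transition, since isotopic
substitution does not change fragmentation energetics at MRM precision.

## Peak detection and integration

The detector is a transparent replacement for vendor integration:
boxcar smoothing (5 points by default), local maxima, signal-to-noise
from the median absolute deviation of first differences (robust to the
peaks themselves), and bounds found by walking each flank down to a
genuine valley or to baseline return — tolerating noise-scale bumps —
with baseline-terminated bounds extended to apex ± 4 estimated sigma so
the tails enter the integral. The area is the signed trapezoidal
integral above a linear baseline between the bounds, with
locally-median endpoints so a single noisy sample cannot tilt the
baseline. On simulated Gaussian peaks at signal-to-noise 50 the median
and mean relative area errors over 200 trials are below 2%; individual
trials retain an irreducible noise variance of a few tenths of a
percent standard deviation, so single-trial errors can exceed that
bound. Detection thresholds default to SNR 5 and a 0.02 min minimum
width; these are documented defaults, not values taken from any
instrument vendor.

The synthetic-chromatogram generator (Gaussian peaks at library RTs on
a uniform grid plus clipped Gaussian noise, deterministic per seed)
emulates well-behaved single-analyte MRM traces. It does not emulate
tailing or fronting peak shapes, drifting baselines, detector
saturation, or the co-elution of sugar phosphates this column chemistry
cannot separate — so passing tests demonstrate correctness of the
algorithms, not chromatographic robustness on degraded real data.

## Isotopologue distributions and natural-abundance correction

Channel areas become mass-isotopomer distributions (MIDs) by
normalization; the three presentation formats are mutually consistent
by construction: percent label incorporation is the labeled-molecule
percentage 100 × (1 − f₀) (with atom-weighted mean enrichment exposed
separately, since the molecule-level fraction is the common reading of
"overall incorporation"), per-channel M+i intensities, and the
fractional distribution profile.

Observed intensities also contain naturally occurring heavy isotopes
(≈1.07% ^13^C, ≈0.364% ^15^N, from the packaged element table). The
correction model is the standard binomial convolution: with j tracer
labels, the remaining n_atoms − j atoms of the tracer element each
carry natural heavy probability p, so the observed distribution is
I = M·x with M[i, j] = dbinom(i − j, n_atoms − j, p), lower-triangular
with unit-sum columns over the full support. The solve is non-negative
least squares (`pracma::lsqnonneg`) rather than matrix inversion, for
robustness to noise; the residual is reported and flagged above 1e−3
relative. For derivatized analytes, `n_atoms` must count the OBHA-tag
carbons too — tag atoms contribute natural abundance like any others.
On noise-free forward-convolved data the round-trip recovers the input
to 1e−6. Whether a given published readout used corrected or raw
intensities is not always stated; both modes are exposed and the output
carries a `corrected` flag.

Moiety-resolved labeling reads the full (k, j) grid directly: the
fragment-moiety labeled fraction is the area share with j ≥ 1 and the
remainder-moiety fraction the share with k − j ≥ 1. Incomplete grids
are computed over available channels and flagged with their coverage,
never silently.

## Labeling strategies and pool-turnover kinetics

Three experiment designs determine the precursor enrichment plateau
that bounds all downstream labeling: spiking label into medium that
still contains unlabeled precursor, swapping to fully labeled medium,
or conditioning on half-strength precursor and adding the other half
labeled. The plateau is simply labeled/(labeled + unlabeled medium +
unlabeled internal pool); the conditioning design with equal halves and
a depleted internal pool gives the characteristic ~50% initial
enrichment.

Kinetic archetypes are generated by a deliberately minimal canonical
model — the pathway figures in this literature are qualitative, so the
simplest dynamics reproducing them is adopted and documented as an
interpretation: first-order well-mixed pool turnover,

dL_i/dt = (F/P_i) · (L_{i−1}^h − L_i),

with flux F, pool sizes P_i, input enrichment L₀(t), a cooperativity
exponent h on the donor fraction (h > 1 sigmoid onset, h < 1
compressed), and cyclic topology as a single recycle edge mixing a
fraction of the terminal pool into the first pool's inflow. Integration
uses `deSolve::ode` (lsoda, rtol 1e−8, atol 1e−10); time units are the
user's (hours by convention in growth experiments) and never
hard-coded. For h = 1 linear chains the solution is monotone, bounded
by the input plateau, and reaches it at steady state; a single pool
matches the closed form A(1 − e^{−(F/P)t}) to 1e−6, and each added pool
strictly lengthens the terminal half-time (the lag signature of chain
length).

Metabolites assembled from several pathway moieties (nucleotides being
the motivating case) combine per-moiety trajectories under an
independence assumption: each moiety with n_m atoms at labeled fraction
L_m contributes a Binomial(n_m, L_m), and the molecule's isotopologue
distribution is their convolution — verified against exhaustive
enumeration of joint atom states.

Fitted descriptions use three saturating families — exponential
A(1 − e^{−kt}), the two-pool lagged closed form, and the Hill-time
sigmoid A·t^h/(t₅₀^h + t^h) — via `minpack.lm::nlsLM` with bounded
parameters (A ∈ [0, 1]), rate starts from the observed half-rise time,
and an explicit degenerate path for courses that never exceed 1e−3.
Moiety comparisons report the rate ratio and half-time ratio with
percentile bootstrap intervals from residual resampling (199 replicates
by default). At 5% noise the median relative error of the recovered
rate over 50 seeded replicates stays within 15%, and nominal-95%
bootstrap intervals cover the true rate ratio in at least 90 of 100
seeded simulations — both properties are exercised directly by the test
suite at those problem sizes, chosen to probe the estimators well while
keeping the default run fast.

## Numerical and design choices

* Nominal mode uses integer arithmetic end to end; ties or rounding
  conventions therefore never arise for Q1, and printed one-decimal Q3
  values are compared after `round()`.
* Isobar resolution (Ile/Leu, Lys/Gln share Q1/Q3) picks the
  nearest-RT candidate within a window (default 0.5 min) and raises an
  explicit error on an exact tie — never a silent choice.
* The library is one CSV with an explicit method tag per row rather
  than four files, and abbreviations repeat across methods, so
  uniqueness is enforced on (abbreviation, method_tag).
* Degenerate inputs fail loudly: all-zero MIDs, inverted peak bounds,
  infeasible (k, j) channels, schemes exceeding the formula's atom
  count, and negative formula subtraction are all errors.

## Known limitations

* No retention-time or collision-energy prediction: both are empirical
  and stored.
* No positional isotopomer resolution within a moiety — MRM cannot
  distinguish it.
* No deconvolution of co-eluting sugar phosphates; the method itself
  does not separate them.
* No full ^13^C metabolic flux analysis (EMU/cumomer networks); the
  pool-chain model is for interpreting label-incorporation kinetics,
  not for estimating fluxes from them.
* The identity of the second pyruvate-standard peak is unresolved
  upstream and is not modeled.
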