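---
title: "Stereochemical discrimination from anisotropic NMR data: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stereochemical discrimination from anisotropic NMR data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(anisofit)
```

## The problem

A molecule dissolved in a weakly aligning medium no longer tumbles
isotropically. Its residual orientational order — described by the
alignment (Saupe) tensor $S$, a traceless symmetric $3\times3$ matrix with
five independent components and magnitudes around $10^{-4}$–$10^{-3}$ —
re-introduces anisotropic spin interactions at a measurable scale:
one-bond residual dipolar couplings (RDCs) of a few Hz and residual
chemical shift anisotropies (RCSAs) of tens of ppb. Both depend on the
*orientation* of internuclear vectors and shielding tensors within the
molecular frame, so they are exquisitely sensitive to relative
configuration: a wrong diastereomer's geometry cannot reproduce the full
set of observations with any single alignment tensor. The package turns
that into a quantitative test.

## Observation model

For a rigid conformer, an RDC between nuclei $a$ and $b$ is
$$D_{ab} = b_{ab}\, \mathbf u^\top S\, \mathbf u, \qquad
  b_{ab} = -\frac{\mu_0}{4\pi}\frac{\gamma_a\gamma_b \hbar}{2\pi r^3},$$
with $\mathbf u$ the internuclear unit vector and $r$ the distance
(CODATA-2018 constants; $b \approx -23.3$ kHz for C–H at 1.09 Å). An RCSA
is the contraction
$$\Delta\delta = -\tfrac{2}{3}\sum_{\alpha\beta} S_{\alpha\beta}\,
  \tilde\sigma_{\alpha\beta},$$
where $\tilde\sigma$ is the traceless symmetric part of the nuclear
shielding tensor in the conformer frame; the isotropic part is annihilated
by the traceless $S$, and the single minus sign converts shielding to the
chemical-shift scale. Both conventions are fixed once and verified by
closed-loop tests (simulate → fit → back-calculate reproduces the inputs
whatever the convention, so self-consistency, not the sign choice itself,
is what matters for discrimination).

Experimental RCSAs come referenced: measured between two alignment states
and with a chosen carbon's value subtracted to cancel isotropic drifts
(ΔΔRCSA). The design matrix applies the same subtraction to the
back-calculated coefficients; the reference atom's own (identically zero)
entry is excluded from the residuals. When a fit requests a different
reference than the data were recorded against, the observations are
re-referenced by subtracting the new reference atom's value — possible
between any two internal references or from an external reference to an
internal one, but not backwards, which the code refuses.

## The ensemble fit

Flexible molecules are modelled as a population-weighted conformer
ensemble sharing **one** alignment tensor (the single-tensor
approximation): each design-matrix row is the population average of the
per-conformer linear coefficients mapping the five tensor components to
one datum. Populations are held fixed during the fit — they come either
from Boltzmann weighting of quantum-chemical energies or from the
shift-based CASE-3D selection. Per-conformer alignment tensors are out of
scope; with typical data (11–19 RDCs + ΔΔRCSAs) they would be badly
underdetermined.

Rows and observations are divided by the per-datum uncertainty, so Hz and
ppb become commensurate, and the system is solved by SVD (minimum-norm
least squares). Singular values below $10^{-10}$ of the largest are
treated as rank deficiency — reported with a warning, never silently. An
optional "balanced" weighting mode rescales each data block to unit RMS so
a large block cannot dominate a small one; per-sigma weighting is the
default. A fit needs at least 5 rows of rank 5 to be determined.

Goodness of fit is the Q factor
$Q = \sqrt{\sum(\mathrm{exp}-\mathrm{calc})^2} / \sqrt{\sum \mathrm{exp}^2}$,
computed per block on raw values and on sigma-normalized values for
combined blocks. `discriminate()` fits every candidate configuration
against identical data and ranks by the combined Q of the primary (first)
reference scheme, breaking ties by RDC-only Q and then label; gaps below
0.005 are declared indistinguishable, since Q differences at the third
decimal are below experimental reproducibility. All reference schemes are
reported side by side — a robust assignment shows the same winner under
every reference. Uncertainty on Q and tensor elements is available by
seeded Monte-Carlo resampling of the observations within their sigmas
(default 500 draws).

## Boltzmann populations and the 5% rule

`boltzmann_weights()` maps conformer energies (Hartree) to
$w_i \propto e^{-\Delta E_i/kT}$ at a configurable temperature (default
298.15 K, the thermochemistry convention; 300 K, a typical NMR probe
temperature, is equally sensible — the choice moves populations far less
than the energy errors do). Both electronic+zero-point and Gibbs energies
are supported, since the two commonly select *different* ensembles — a
real source of ambiguity that the reporting keeps visible rather than
hiding. `select_by_population()` keeps conformers at or above the cutoff
(inclusive, so "5% or higher" keeps a conformer at exactly 5%),
renormalizes, and records the discarded mass.

## CASE-3D: ensemble selection from chemical shifts

Rather than trusting computed energies, CASE-3D asks which conformer
subset the *experimental* ¹H/¹³C shifts support. For a candidate subset,
per-conformer computed shifts are combined with simplex-constrained
populations ($p \ge 0$, $\sum p = 1$; a deterministic active-set solver,
so results are bit-reproducible) and a per-nucleus-class least-squares
line mapping computed to experimental shifts (the standard correction for
systematic DFT errors; disabled with a warning below 3 points per class).
Scaling and populations are optimized by alternation to $10^{-10}$
(single-pass and no-scaling modes exist). Every subset up to a size cap is
scored by
$$\mathrm{AICc} = n\ln(\mathrm{RSS}/n) + 2k + \frac{2k(k+1)}{n-k-1},
  \qquad k = (|\mathrm{subset}|-1) + 2\,(\text{scaled classes}),$$
and ranked deterministically (AICc, then lexicographic). ¹H residuals are
multiplied by a configurable factor (default 5) to offset their ~5–10×
smaller dispersion; a ¹³C-only mode sets it to zero, which removes the ¹H
class from both residuals and the parameter count.

**What AICc can and cannot promise.** With independent candidate
conformers, any information criterion with a +2-per-parameter penalty
admits a spurious conformer whenever its fit improvement exceeds the
penalty — for one candidate that happens with probability
$\approx P(\chi^2_1 > 2)/2 \approx 8\%$ under pure noise, more when
several candidates compete. This is a property of Akaike selection, not
of the implementation: at $n \approx 30$–60 observations we measured
~75–85% exact-subset recovery however the classes are weighted. The
small-sample correction changes the regime: with few observations (e.g.
the 7 ¹³C shifts of the default toy molecule) the $2k(k+1)/(n-k-1)$ term
grows steeply in $k$ and extra conformers are strongly penalized, giving
$\ge 90\%$ exact recovery of a 0.7/0.3 two-conformer truth from a
six-conformer pool at 0.2 ppm ¹³C noise — the regime our validation
exercises in the ¹³C-only mode. On configuration *ranking* (which
diastereomer is right) the criterion is far more robust than on exact
subset identity, because wrong-configuration shifts are systematically
offset, not noise-level perturbations.

A DP4-style posterior probability is deliberately *not* the verdict
anywhere; AIC ranking plus the anisotropic refit of the selected
ensembles is.

## The synthetic generator

The generator stands in for the spectrometer and the quantum chemistry,
emulating their outputs' *shape* while retaining full ground truth:

* **Geometries**: a stereogenic carbon bearing H, a methyl and two
  unequal alkyl chains, built from internal coordinates (C–H 1.09 Å,
  C–C 1.53 Å, tetrahedral angles, all-trans chains); conformers differ by
  rotation of the chains about their bonds to the stereocenter, emulating
  ring/substituent-rotation conformer families. A 0.02 Å seeded jitter
  (shared across conformers) breaks exact symmetry. Default size 23 atoms
  (7 carbons), configurable 10–60.
* **Alignment tensors** with chosen axial magnitude (default
  $5\times10^{-4}$) and rhombicity, uniformly random orientation.
* **Shielding tensors**: per carbon, principal components with anisotropy
  log-uniform in 30–200 ppm (aliphatic to carbonyl range) and a fixed
  orientation *relative to the atom's local bonded frame*, so tensors
  follow the structure across conformers the way DFT shieldings do; a
  2 ppm per-(atom, conformer) isotropic spread makes conformers
  distinguishable by shifts (0.15 ppm for ¹H).
* **Observables**: RDCs for every C–H pair and RCSAs for every carbon,
  population-averaged and noised (presets: 0.5 Hz, 2 ppb, 0.2 ppm ¹³C,
  0.02 ppm ¹H — realistic modern data quality, stated as presets, not as
  claims about any particular study). "Computed" shifts pass through a
  known affine map distinct from the one defining the "experimental"
  truth, so shift scaling has a genuine transform to recover.
* **Decoys**: `make_decoy_configuration()` inverts the stereocenter by
  reflecting its two smallest substituent branches through the plane of
  the two largest — an isometry (bond lengths preserved to $10^{-6}$ Å)
  and an involution. `perturb_computed_shifts()` additionally emulates a
  wrong diastereomer's *computed shift* errors as per-atom offsets
  (0.5 ppm ¹³C / 0.05 ppm ¹H defaults).

Everything is a pure function of (parameters, seed). What passing tests on
these data do **not** show: real conformers are not single-dihedral
rotamers, real shielding tensors are not random, real noise is not
Gaussian-iid, and real ensembles can be incomplete — synthetic success is
necessary, not sufficient, for trusting an assignment on real data.

## Numerical choices and degenerate inputs

* Singular values below $10^{-10}\times$max → rank-deficiency warning and
  pseudo-inverse, not failure; under 5 data → error.
* Simplex solver: KKT solves with a $10^{-12}$-scaled ridge, so exactly
  duplicated conformers split their weight deterministically and score
  equal AIC with a stable lexicographic tie order.
* Perfect shift fits (RSS = 0) report AIC $-\infty$ with a flag.
* Zero-noise simulation keeps positive sigmas (preset values) so weighted
  fits stay defined.
* Boltzmann weights subtract the minimum energy before exponentiation;
  shifting all energies is exactly neutral, but the ~$10^{-16}$ relative
  float error on ~500 Hartree inputs bounds round-trip accuracy near
  $10^{-10}$ in the weights.
* An ensemble cannot be emptied by the population cutoff (error instead).

## Validation problem sizes

The shipped validation (tests and `scripts/acceptance.R`) uses: 50
orientations for noise-free recovery (8 RDCs + 10 ΔΔRCSAs, 1 conformer);
100 random instances for the SVD-vs-normal-equations check and 125 models
against the brute-force CASE-3D oracle; 200 trials of truth-vs-decoy
discrimination at 5% relative noise (3 conformers, 16 RDCs + 7 ΔΔRCSAs);
100 trials of subset/population recovery; closed-form Boltzmann checks.
These sizes give stable rates (binomial SE ≲ 3%) while keeping a full run
around two minutes.

## Known limitations

* One alignment tensor per ensemble; media with conformer-dependent
  alignment are outside the model.
* Populations and tensor are not fitted jointly.
* Vibrational corrections to bond lengths are not applied; a uniform
  one-bond scale factor is exposed (`r_scale`, default 1).
* Only XYZ/CSV interchange; converting vendor quantum-chemistry output to
  the CSV schemas is the user's (scriptable) responsibility: extract per
  conformer the Cartesian geometry, the 9 shielding-tensor components per
  carbon, and the energies, in the documented column order.
* ¹H/¹³C only in CASE-3D; no J-couplings or NOEs.
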