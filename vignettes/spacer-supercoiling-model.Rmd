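---
title: "Torsional model of spacer-length-dependent supercoiling sensitivity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Torsional model of spacer-length-dependent supercoiling sensitivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(twistspacer)
```

## The model and its assumptions

During closed-complex formation, the sigma factor of RNA polymerase engages
the −35 and −10 hexamers simultaneously. Their relative helical orientation
is set by the length `n` of the spacer between them and by the supercoiling
density σ of the promoter region before binding. We model the intermediate
state in the elastic approximation: the spacer is a chain of torsional
springs, each relaxed at α₀(1 + σ), while RNAP imposes a fixed total twist
angle θ_P across the spacer. The resulting orientational free energy is

$$\Delta G_{or}(\sigma, n) = \frac{n}{2}\,k_\theta
  \left(\frac{\theta_P}{n} - \alpha_0 (1 + \sigma)\right)^2 ,$$

and transcription rates follow the thermodynamic rate law
$k = k_0 \exp(-\Delta G / k_BT)$.

Key assumptions, each of which bounds the model's domain of validity:

* **All of σ is available as twist.** At equilibrium most supercoiling is
  stored as writhe, but the spacer is too short to writhe before RNAP binds,
  so the one-dimensional (twist-only) approximation is used.
* **RNAP is rigid**: θ_P is a fixed angle; polymerase flexibility is
  neglected.
* **Separability.** All other supercoiling effects (notably facilitated
  promoter opening at negative σ) are assumed independent of spacer length,
  and all other spacer effects (3D conformation, hexamer spacing, specific
  contacts) independent of σ. The orientational term is then the *only*
  coupled dependence, and every relative prediction is parameter-free.
* **No twist–stretch coupling, no open-complex energetics.** These are
  deliberately out of scope.

The total free energy decomposes as
$\Delta G = \Delta G_{sc}(\sigma, s) + \Delta G_{sp}(n, s) + \Delta G_{or}(\sigma, n)$.
The first two terms are never computed individually; they enter only through
two promoter-specific constants: `q_sp` (the σ-independent offset of a spacer
variant relative to the 17-nt reference, in $k_BT$) and `r_sc` (the
spacer-independent part of a shock response, with fold-change contribution
$e^{-r_{sc}}$).

## Parameters

| parameter | default | units | origin |
|---|---|---|---|
| `k_theta` | 71.4 | $k_BT\,\mathrm{rad}^{-2}$ per step | sequence-averaged DNA twist stiffness |
| `alpha0`  | 34   | degrees per step | mean helical twist of B-DNA |
| `theta_P` | 543.32 | degrees | fixed so the 17-nt spacer is optimal at σ = −0.06 |
| `n_ref`   | 17   | nt | most frequent sigma70 spacer length |
| `sigma_ref` | −0.06 | — | standard level in exponentially growing *E. coli* |

Angles are taken in degrees at every user-facing boundary and stored in
radians internally, because the published stiffness is per squared radian.
θ_P is stored unrounded (543.32°): rounding it to 543° would displace the
zero-energy point away from (17, −0.06), and only the printed value is a
rounding convention. All log fold-changes are natural logarithms; the
printed factor/exponential statements are consistent with that convention,
and log2 is offered only as an output conversion.

The slope prefactor $k_\theta \alpha_0^2 \approx 25.1$ sets all headline
magnitudes: the log-ratio slope per nucleotide, and the shock response
difference $-k_\theta \alpha_0^2\, \Delta n\, \Delta\sigma$ per nucleotide of
spacer and unit of superhelical shift.

```{r constants}
p <- twist_params()
round(rad2deg(p$theta_P), 2)
round(p$k_theta * p$alpha0^2, 2)
round(exp(-spacer_logfc_difference(0.03, 1, p)), 2)  # one nucleotide, dsigma 0.03
```

## Exact versus linearised forms

The energy is quadratic in σ, so the finite difference across a shift
σ₀ → σ₀ + Δσ equals the derivative at the midpoint. The exact
spacer-dependent log fold-change difference therefore obeys the identity

$$\mathrm{exact} = \mathrm{linearised} \times (1 + \sigma_0 + \Delta\sigma/2),$$

which the test suite asserts at machine precision. Two consequences guided
the design:

* `logfc_under_shock()` always evaluates the exact energy difference;
  linearised forms are explicit opt-ins (`linearized = TRUE` is the default
  only for the intentionally parameter-free `spacer_logfc_difference()` and
  `relative_expression_slope()`).
* The linearisation error is $|\sigma_0 + \Delta\sigma/2|$ in relative
  terms: at σ₀ = −0.06 it stays below 7% for relaxation-sign shifts of
  magnitude up to 0.03, which is the regime in which the "within a few
  percent" statement is coherent; for overtwisting shifts of the same
  magnitude it reaches 7.5%. The property test therefore checks the 7%
  bound over relaxations, and the exact identity above (both signs)
  separately — stronger than a tolerance check.

## Sequence-dependent extension

To ask how much the spacer *sequence* (rather than length) modulates the
orientational effect, the uniform chain is generalised to heterogeneous
springs: step *i* has intrinsic twist αᵢ and stiffness kᵢ. With RNAP imposing
the total angle, elastic equilibrium gives the closed form

$$\Delta G_{or} = \frac{k_{\mathrm{eff}}}{2}\,(\theta_P - A(1+\sigma))^2,
  \qquad A = \sum_i \alpha_i,\quad k_{\mathrm{eff}} = \Big(\sum_i 1/k_i\Big)^{-1},$$

the unique elastic-equilibrium extension of the uniform model, to which it
reduces exactly for a uniform table. Tests verify the closed form against an
independent constrained-quadratic-minimisation oracle (reduced-coordinate
linear solve) to relative error below 1e−9.

Design choices that the literature leaves open, exposed as options rather
than guessed:

* **Step counting.** An `n`-nt spacer contributes `n − 1` internal steps by
  default; the two boundary steps into the hexamers are included only when
  flanking bases are supplied (`flank5`, `flank3`). Whether a published
  computation uses `n` or `n − 1` steps is not stated anywhere we could
  verify, so both are reachable.
* **Ablation baseline.** Sequence adjustments are measured against a uniform
  model built from the *table's own* averaged parameters (arithmetic means),
  so that applying both ablations (`average_alpha` + an averaged-stiffness
  table) yields exactly zero for every sequence.
* **Dinucleotide values.** Real crystallographic twist/stiffness
  compilations are not shipped; the default table
  (`dinucleotide_twist_synthetic.tsv`) is a constructed stand-in — labelled
  synthetic — that is complement-symmetric, has mean twist exactly 34°,
  twist spread of about 1° sd and roughly twofold stiffness variability.
  Every correctness test uses uniform or synthetic tables, so no result in
  this package depends on those numbers.

With this geometry the two ablations reproduce the expected ordering:
imposing the average twist (structure removed) collapses the adjustment span
to near zero, while imposing the average stiffness barely changes it —
structure, not elasticity, carries the sequence effect — and the full-model
span across random spacers stays below the effect of gaining or losing one
nucleotide.

## The three analysis pipelines

**In vitro titrations.** Activities are normalised per σ to the 17-nt
reference (geometric mean across replicate references, so reference points
map to exactly 0). σ matching is exact by default; a nearest-σ tolerance
(suggested 0.002) accommodates digitised datasets. Only the intercept
(`q_sp`) is fitted — by the mean residual after subtracting the
parameter-free orientational part, with a Student CI; the slope test fits an
unweighted OLS line and compares it to the exact derivative evaluated at the
dataset's mean σ (for a symmetric σ grid the OLS slope of a quadratic equals
exactly that midpoint derivative, which the round-trip tests exploit). Fits
are unweighted because source datasets are typically means without errors.

**Reporter shocks.** Fold-changes are computed at a single post-shock time
point (presets: 60 min for the relaxation drug, 5 min for the overtwisting
drug), from the nearest sample within half the sampling interval. The point
estimate is the ratio of mean luminescences; the 95% CI is a Student t
interval on log-ratios of replicate pairs (paired by sorted replicate id).
`fit_shock_model()` estimates (Δσ, r_sc) by least squares on log
fold-changes, profiling r_sc analytically and minimising over Δσ on a coarse
grid refined by Brent's method (tolerance 1e−12); the two-step variant pins
r_sc from the reference promoter alone. A reported `ref_fold_change` gives
the model's reference-spacer prediction, which includes the small
orientational residual on top of $e^{-r_{sc}}$; note that
$e^{-r_{sc}}$ and a quoted activation factor need not agree if the latter
was read off data (for $r_{sc} = -0.97$, $e^{0.97} = 2.64$), so both are
exposed and neither is forced.

**Genome-scale statistics.** Promoter maps use 1-based inclusive
coordinates; the spacer is the strand-symmetric gap between the hexamer
intervals, with a curated `spacer_len` column taking precedence
(mismatches warn). Analyses retain sigma70 promoters with 15–19-nt spacers
and exclude 16-nt spacers by default — empirically they respond like long
spacers, presumably because open-complex effects dominate there — while the
discriminator analysis keeps them. Classification uses adjusted p-values
(`padj < alpha`, sign of logFC); the comparison of activated versus
repressed mean spacer lengths reports both Welch (default) and
pooled-variance t-tests; the activation-proportion regression is unweighted
OLS of per-length proportions with exact binomial CIs (a weighted option
exists; whether published regressions were weighted is not stated).
"Responsive" means `padj < alpha` regardless of sign. The discriminator is
defined as the sequence strictly between the −10 hexamer and the TSS (the
definition is configurable since the term is used loosely in the
literature). Degenerate inputs are handled explicitly: constant GC groups
bypass the t-test (p = 0 or 1 by separation), perfect proportion fits report
an NA slope p-value, and empty activated/repressed groups raise classed
errors naming the group.

## What the synthetic generators emulate — and what they do not

`simulate_invitro()` draws activities from the rate law times log-normal
noise; its noise-free limit is exactly inverted by the normalisation
pipeline. `simulate_reporter()` uses logistic growth and filters the step
change in promoter activity through a first-order reporter filter with a
45-min lifetime (the kinetic form is a modelling choice; only the lifetime
is constrained), so a repressive shock read 60 min later is buffered — the
measured fold-change lies strictly between the model value and 1, matching a
discrete-convolution oracle. The analysis pipeline deliberately does *not*
deconvolve this buffering: fitted Δσ values are effective values, as they
are in the assays being emulated.

`simulate_genome_cohort()` draws spacer lengths from a distribution peaked
at 17 nt (27% mass: 0.14/0.14/0.27/0.25/0.20 over 15–19 nt — a stand-in
consistent with the published mode, not a curated-database claim), a
promoter-specific `r_sc` with sd 0.5 $k_BT$ (the real promoter-to-promoter
spread is unknown; this default is chosen for illustrative power and flagged
as such), and replicate-level noise of 0.2 on the log scale with triplicates.
P-values come from per-promoter t-tests of the simulated replicates against
zero, Benjamini–Hochberg adjusted, so the classification threshold has
exactly the semantics of the analysis pipeline. Because `r_sc` is a
*response* term (a free-energy difference across the shift), it is
identically zero when Δσ = 0, making the null cohort a genuine global null:
the BH-level false-positive control in the tests is meaningful.

What passing tests therefore show: the pipelines recover the generating
model's direction and magnitude under realistic noise. What they cannot
show: agreement with any real transcriptome or curated promoter map —
real-data p-values and database frequencies are not reproducible offline and
are replaced by direction/power properties under the stated cohort
conditions.

## Problem sizes and numerical choices

The test suite runs at desk scale: 500-seed coverage and recovery
simulations, 200-seed cohort power runs at 300 promoters, 400-seed null
calibrations, and oracle comparisons on 5-step sequences — about half a
minute in total. Spacer lengths are validated to 1–30 nt with a warning
outside 15–19 nt, where the model has been validated; the orientational
formula itself is defined for any positive length. `fit_shock_model()`
searches Δσ in [−0.12, 0.12] (well beyond physiological shifts) and is
insensitive to the grid because the profiled objective is a smooth quartic.

## Known limitations

* No writhe partition, RNAP flexibility, twist–stretch coupling or melting
  energetics; 16-nt spacers are outside the model's domain.
* The sequence extension models twist only — no roll/tilt, no A-tract
  curvature — and its default parameter table is synthetic.
* `fit_shock_model()` treats the panel as one promoter background; it does
  not model promoter-to-promoter `r_sc` heterogeneity (that belongs to the
  genome-scale statistics).
* Fold-changes are single-time-point ratios, not integrals; reporter
  buffering is emulated but never deconvolved.
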