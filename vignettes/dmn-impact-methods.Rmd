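---
title: "Methods: from head impact mechanics to DMN damage prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from head impact mechanics to DMN damage prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dmnimpact)
library(dplyr)
```

dmnimpact links the mechanics of a blunt head impact to a functional
measure of damage in the default mode network (DMN). It has two use
modes. Forward: given an impact scenario (velocity, location, angle,
impactor shape), predict the probability that at least a given
proportion of the DMN is mechanically damaged. Inverse: given an
observed functional damage load from resting-state fMRI, estimate the
impact velocity that first produces that proportion. This vignette
explains the models, the synthetic data that stands in for a
finite-element simulation library and for patient scans, the tunable
parameters, and the numerical choices — including the ones that were
genuinely open.

## Brain tissue constitutive model

Tissue stress is split into volumetric and isochoric parts,
$\sigma = \sigma_{vol} + \sigma_{iso}$, with the deformation gradient
decomposed as $F = J^{1/3} F^*$, $J = \det F$. The isochoric part is a
Gent (limiting chain extensibility) matrix term plus, for white matter,
an exponential fiber-reinforcement term along the axonal direction
$a$ (structural tensor $A_o = a \otimes a$):

$$
\sigma_{iso} = \frac{\mu_m}{J}\,
  \frac{1}{1 - (I_1^* - 3)/j_m}\,\mathrm{dev}(B^*)
  + \frac{2 k_1}{J} (I_4^* - 1)
    e^{k_2 (I_4^* - 1)^2}\,
    \mathrm{dev}(F^* A_o F^{*T}),
$$

with $B^* = F^* F^{*T}$, $I_1^* = \mathrm{tr}(F^{*T} F^*)$ and
$I_4^* = \mathrm{tr}(A_o F^{*T} F^*)$. The volumetric part is driven by
the density ratio via mass conservation, $\rho/\rho_o = 1/J$:

$$
\sigma_{vol} = -\frac{K_o}{\Lambda_o + 1}
  \left[ \left(\tfrac{\rho}{\rho_o}\right)^{\Lambda_o + 1} - 1 \right] I .
$$

Parameters ship in `inst/extdata/materials.yaml`: white matter
$\mu_m = 550$ kPa, $j_m = 1.1$, $k_1 = 2.14$ kPa, $k_2 = 0$; gray
matter $\mu_m = 450$ kPa, $j_m = 1.4$, no fiber term; both share
$\rho_o = 1140$ kg/m³, $K_o = 2.19$ GPa, $\Lambda_o = 6.15$. Three
choices here were genuinely open and are worth stating:

* **Gent factor form.** The first factor is implemented as
  $1/(1 - (I_1^*-3)/j_m)$, the standard Gent form, which reproduces the
  small-strain shear modulus $\mu_m$ exactly (verified to 0.1% in the
  tests) and diverges as $I_1^* - 3 \to j_m$. Evaluation past the limit
  raises a `dmnimpact_gent_limit` error rather than returning a
  non-physical stress.
* **$k_2$ units.** $k_2$ multiplies the square of the dimensionless
  invariant $(I_4^*-1)$ inside an exponential, so it is treated as
  dimensionless. Its calibrated value is 0, which makes the exponential
  1, but positive values are accepted and exercised in tests.
* **Shear energy rate.** The tissue damage criterion is the deviatoric
  stress power density $\mathrm{dev}(\sigma) : \mathrm{dev}(D)$
  (units MJ/m³/s), with $D$ the rate-of-deformation tensor. This is the
  single most consequential interpretation in the mechanics layer, so it
  is isolated behind one pure function, `shear_energy_rate(sigma, D)`,
  and an alternative definition (e.g. an isochoric strain-energy rate)
  could be swapped without touching anything else.

## Damage criteria

A gray-matter element is damaged when its peak shear energy rate
strictly exceeds 1 MJ/m³/s, the calibration appropriate for blunt
impact; the much higher blast-loading calibration (100 MJ/m³/s) is
retained as the named preset `"blast"`. A record is discarded as
fractured when strictly more than 4% of skull elements exceed the
ultimate strength of bone, 92.72 MPa, in peak von Mises stress (4%
is the share of skull elements spanning the full skull thickness).

The DMN template mask (template z-map thresholded at $z > 3.1$,
i.e. $p < 0.05$) is mapped to the mesh in two steps: nodes whose world
coordinates fall in a true voxel are selected under the voxel-centre
convention $v = \lfloor A^{-1} x + 0.5 \rfloor$ (0-based, matching
NIfTI semantics), then every gray element sharing at least one selected
node is taken. Restricting to gray elements is a choice: node selection
could equally be restricted before element extraction; with
at-least-one-node connectivity the two differ only at mask boundaries.
DMN damage is the percentage of these elements above the criterion.

## The synthetic simulation library

Running an explicit-dynamics finite-element head model is out of scope;
the package replaces it with a documented parametric surrogate on a toy
two-shell tetrahedral head (white core with radial fibers, gray rind,
CSF shell, skull shell; radius 9 cm). For a gray element at distance
$d$ from the impact point,

$$
e = A \left(\frac{v}{v_{ref}}\right)^{\alpha} e^{-d/\lambda}
  (1 + \beta \cos\theta)
  \left(\frac{R_{ref}}{R}\right)^{\gamma_R} (1 + \eta),
$$

and for a skull element the peak von Mises stress is
$B\, v\, (R_{ref}/R)^{\gamma_R} e^{-d/\lambda} (1+\eta)$, with
$\eta \sim N(0, \text{cv})$ truncated at $-0.9$ so the multiplicative
noise keeps fields positive. Defaults: $A = 1.5$ MJ/m³/s,
$v_{ref} = 8$ m/s, $\alpha = 2.5$, $\lambda = 0.055$ m, $\beta = 0.5$,
$\gamma_R = 0.25$, $R_{ref} = 0.036$ m, $B = 8.5$ MPa·s/m, cv $= 0.05$.
These were calibrated once, before any classifier was evaluated, so
that (i) mid-grid scenarios straddle the 1 MJ/m³/s criterion, (ii)
roughly 10% of scenarios fracture the skull (10.5% on the default
grid), and (iii) the positive-class prevalence across damage thresholds
10–90% falls off like a realistic impact library
(0.37/0.19/0.13/0.07/0.035). They were not revisited afterwards.

The default scenario grid crosses 5 impact locations × 4 impactors
(radii 0.01, 0.036, 1, 0.003 m; the flat impactor is assigned a nominal
1 m radius) × velocities 2–14 m/s in steps of 2 × angles
$\{-45°, 0°, 45°\}$: 420 records, with ~10% removed by fracture —
the size of a realistic pre-computed library. Density is configurable.

What the surrogate deliberately does **not** emulate: wave propagation
and reflections, contact mechanics, skull compliance, strain-rate
history (only peaks are modelled), and any realistic anatomy. Passing
tests therefore show that the downstream statistical machinery behaves
correctly on inputs with the right qualitative structure (monotone in
velocity, decaying with distance, sharper impactors more damaging) —
not that damage percentages on real heads would be reproduced.

## The machine-learning layer

For each damage threshold a separate binary classifier is trained:
label 1 iff the record's DMN damage percentage strictly exceeds the
threshold; fractured records must be excluded upstream. Candidate
features are velocity, five location indicators, a perpendicular-impact
flag, the impactor radius of curvature, and two DMN-geometry features
(distance from the impact point to the nearest DMN element centroid,
and the angle between the impact direction and the direction to that
centroid). The binary perpendicular flag and the continuous geometric
angle both enter as candidates and the selection decides — the two
carry different information (perpendicularity of the blow vs geometry
of the network relative to the blow).

Greedy forward selection adds the feature that maximizes mean
stratified 5-fold CV AUC of a logistic model, stopping when the best
improvement is below $10^{-4}$ (a stopping rule had to be fixed; this
value is small enough to keep any genuinely informative feature), with
ties broken by declaration order. Selection runs once on the full
library, not inside the leave-one-out loop — a deliberate, documented
optimistic bias shared by the training pre-step it mirrors.

The bagging ensemble averages probabilities from five members fitted on
z-scored continuous features (indicators pass through): logistic
regression, Gaussian (linear) discriminant analysis, $k$-nearest
neighbours with $k = \mathrm{round}(\sqrt{n})$ odd-adjusted, naive
Bayes (indicators as categorical), and an RBF support-vector machine
whose probability is a Platt sigmoid fitted on its own training
decision values (a probability is required for averaging and the
margin-based member does not provide one natively; fitting the sigmoid
on training scores keeps the whole ensemble deterministic).
Sensitivity/specificity/accuracy are reported at a 0.5 cutoff.
Leave-one-out validation pools held-out probabilities and reports the
rank AUC, Brier score and the cutoff metrics.

## Velocity inversion

`probability_velocity_curve()` sweeps velocity 1–15 m/s (step 0.1)
with everything else fixed; `plateau_and_velocity()` takes the plateau
probability $P_f$ as the mean over the top 10% of the grid (optionally
after isotonic smoothing — recommended, since the upper plateau of a
noisy ensemble oscillates) and reports the smallest grid velocity whose
probability reaches $0.95 P_f$. A window mean was chosen over the curve
maximum or last sample because it is stable against upper-plateau
oscillation; the window and level are arguments.

**Known limitation.** The 95%-of-plateau point sits on the upper tail
of the ensemble's smoothest members (LDA and naive Bayes fit pooled
across scenarios have intrinsically shallow probability-velocity
slopes), so the estimated velocity systematically overshoots the true
damage-onset velocity — by ≈1.3 m/s median on noise-free synthetic
libraries where the onset is fully identifiable from the features. A
second, sharper limitation: after z-scoring, the raw radius-of-curvature
feature cannot distinguish the three curved impactors (0.003, 0.01,
0.036 m differ by ~0.07 SD because the 1 m flat radius dominates the
scale), so when impactor sharpness drives the onset the inversion
cannot recover it. Both effects are quantified by the acceptance
analyses; a log-radius feature would remove the second but is not part
of the declared feature set.

## Functional damage from resting-state fMRI

Subject-level DMN maps come from dual regression against template
network maps: stage 1 regresses each volume on the template spatial
maps jointly (giving per-network time courses); stage 2 regresses each
voxel's series on the variance-normalized time courses jointly (giving
beta maps). Maps are z-normalized as beta over its voxelwise regression
standard error — one of several variants in use; the beta maps are also
returned, and the noiseless-recovery tests use betas because the
residual error, and with it the z denominator, vanishes there.

The single-case comparison of one patient against $N$ controls uses the
Crawford–Howell t,
$t = (\bar{x}_c - y) / (s_c \sqrt{1 + 1/N})$, with the contrast
controls > patient. Inference is by sign flipping of pooled-mean-centred
maps (valid under symmetric errors), recomputing the statistic each
permutation; by default observed and permuted maps are TFCE-enhanced
before comparison. TFCE parameters are the published defaults
$E = 0.5$, $H = 2$, 6-connectivity, with the integration step adapting
to each map (its maximum over 10, the conventional discretization — a
fixed absolute step would be degenerate on permuted maps whose flipped
control variance happens to be tiny and whose t values are huge). Voxelwise
$p = (1 + \#\{\text{perm} \ge \text{obs}\})/(n_{perm}+1)$; 5000
permutations by default, 500 in the test profile. The damage load is
the percentage of DMN-mask voxels with $p < 0.05$, optionally
intersected with a gray-matter mask.

Two statistical properties of this scheme deserve emphasis. First,
voxelwise p-values under the null are conservative, not uniform: with a
single patient, every sign flip retains the magnitude of the patient's
own deviation, so the permuted statistic is approximately
$\pm$ the observed one plus $O(\sigma/\sqrt{N})$ noise, and small
p-values cannot occur at isolated voxels. Detection power comes from
the TFCE spatial statistic, which distinguishes a spatially coherent
deficit from sign-flipped scattered noise — the planted-deficit tests
show near-complete detection with TFCE and almost none with raw t.
This is an intrinsic property of sign-flip nulls for 1-vs-N contrasts,
not an implementation artefact; a label-exchange permutation would give
uniform voxelwise p-values but only $N+1$ distinct relabelings. A flag
(`use_tfce = FALSE`) exposes the raw-t variant. Second, the TFCE
enhancement is one-sided: non-positive statistic values receive zero.

The synthetic cohort generator emulates: per-network AR(1) signal time
courses (marginal variance 1), unit-peak spatial loadings from the
templates, additive white voxel noise, and a patient whose DMN loading
is multiplied by $1-\text{effect}$ inside a quasi-contiguous region
(the mask voxels nearest the template peak) covering a configurable
fraction of the DMN mask. Defaults mirror a realistic single-case
study: 18 controls + 1 patient, 150 volumes, AR(1) coefficient 0.4,
noise SD 0.5 (about twice the per-network signal SD at mask-edge
voxels), deficit fraction 0.3. It does not emulate scanner drift,
motion, physiological noise, spatial autocorrelation of the noise, or
registration error — so the permutation tests here validate the
inferential machinery, not robustness to realistic artefacts.

## Forensic kinematics

The accident-reconstruction arithmetic is deliberately plain:
`compose_fall_height()` sums signed height components and rounds to one
decimal; `freefall_velocity()` is $\sqrt{2 g h}$ with $g = 9.81$ m/s²
(this value reproduces all the quoted velocities) and a configurable
rounding profile; `impact_force()` is $m \cdot a_g \cdot g$ in kN;
mph↔m/s uses the exact 0.44704 factor. Nine case files transcribe
published accident narratives; where a case's stated total height
disagrees with the sum of its own components (case 1: 7.3 m stated vs
7.46 m summed), the case file reproduces the stated value and reports
the component sum alongside rather than silently correcting either.
Ranges quoted from the biomechanics literature ship as constants in the
case files, not derived quantities.

## Problem sizes and reproducibility

The package's own validation uses desk-scale sizes chosen to exercise
every code path with comfortable margins: a resolution-3 toy head
(~5500 tetrahedra, ~2100 gray elements, ~280 DMN elements), the
420-record default library, 16³ voxel grids with 12–18 controls, and
300–500 permutations. Every stochastic component takes an explicit seed
and derives independent per-scenario / per-subject streams from it;
identical seeds give bit-identical libraries, ensembles, cohorts and
p-maps (asserted in the tests). `scripts/acceptance.R` re-runs the full
set of analyses from scratch at a user-supplied seed.
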