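---
title: "Models and methods in dnamech"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in dnamech}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dnamech)
```

# The rigid-base description

A duplex of $n$ base pairs carries $N = 12n - 6$ rigid-base coordinates:
six intra-basepair coordinates per pair (buckle, propeller, opening in
degrees; shear, stretch, stagger in Å) and six step coordinates per
dinucleotide step (tilt, roll, twist in degrees; shift, slide, rise in Å),
following the 3DNA sign and frame conventions. `dnamech` fixes one
canonical ordering — all intra coordinates, pair by pair, then all step
coordinates, step by step — and every reader maps into it; the coordinate
set is standard, but the ordering is a package convention.

## The non-local harmonic model

`rigid_base_model()` assumes the ensemble of coordinates $\mathbf w$ is
stationary and approximately Gaussian, so a quadratic deformation energy

$$E(\mathbf w) = \tfrac12 (\mathbf w - \hat{\mathbf w})\cdot
\mathbf K\, (\mathbf w - \hat{\mathbf w})$$

is fitted by moment matching: $\hat{\mathbf w}$ is the coordinate mean and
$\mathbf K = k_B T\,\mathbf C^{-1}$ with $\mathbf C$ the *full* $N \times
N$ covariance. Inverting the full covariance is what makes the model
non-local: the stiffness couples every base to every other base, including
intra–step and step–step couplings across the molecule. The classical
6×6 dinucleotide model is recovered as a special case by `relax()` (below).

Numerical choices:

* **Covariance normalization.** The maximum-likelihood denominator $M$ is
  the default, because the moment relations equate *population* moments;
  `unbiased = TRUE` switches to $M-1$. At the ensemble sizes this model
  needs ($M \gg N$, typically $10^4$–$10^5$ snapshots) the two differ by
  less than 0.1%.
* **Conditioning.** Estimation requires $M > N$; beyond that, any
  covariance eigenvalue below $10^{-10}$ times the largest aborts with an
  error naming the eigenvalue rather than silently pseudo-inverting. A
  near-singular covariance means some coordinate combination never moved,
  and its stiffness is simply not identified by the data.
* **Symmetry.** $\mathbf K$ is symmetrized as $(\mathbf K + \mathbf
  K^\top)/2$ after inversion to remove rounding asymmetry.
* **Units.** Energies are kcal/mol with $k_B = 0.0019872041$
  kcal mol$^{-1}$ K$^{-1}$; the default temperature is 300 K.
* **End pairs.** Terminal base pairs fray and are conventionally excluded
  from analysis; `trim_index()` drops a configurable number of end pairs
  together with their flanking steps (default one pair each side), and the
  CLI `fit` subcommand applies this before estimation. Snapshot filtering
  (`filter_snapshots()`) removes snapshots in which any *interior* pair
  has a Watson–Crick donor–acceptor distance above 4 Å; broken terminal
  pairs are ignored by the filter for the same reason they are trimmed.
  Entropies and stiffnesses are computed from the filtered ensemble.

## Relaxation, force constants, entropy

`relax()` produces the partially relaxed model over a coordinate subset
$A$: the effective stiffness after minimizing the full quadratic over the
complementary coordinates, $\tilde{\mathbf K} = \mathbf K_{AA} - \mathbf
K_{AB}\mathbf K_{BB}^{-1}\mathbf K_{BA}$, which is identical to $k_B
T\,(\mathbf C_{AA})^{-1}$. Both routes are computed on every call and
their agreement (relative $10^{-8}$) is asserted — a cheap, permanent
internal consistency check between the algebraic and statistical views.
Relaxation can only soften: no eigenvalue of $\tilde{\mathbf K}$ exceeds
that of the constrained principal submatrix, and the single-coordinate
force constant $K_a = k_B T/\mathrm{Var}(w_a)$ (`force_constant()`) never
exceeds the diagonal entry $K_{aa}$.

`conformational_entropy()` evaluates $S_c = \tfrac12 k_B \ln[(2\pi e)^N
\det \mathbf C]$ through the Cholesky log-determinant — for $N \sim 200$
the raw determinant of a covariance in mixed units over- or underflows —
and reports the intensive $s_c = S_c/N$ for comparing oligomers of
different lengths. Entropies are only comparable after
`nondimensionalize()`: distances are divided by 1 Å and angles by
$360/34 \approx 10.6°$ (one degree of helical twist per Å of canonical
rise, the conventional choice). With a single length scale and a single
angle scale, *differences* of $s_c$ between models are exactly invariant
under rescaling, which the test suite verifies to $10^{-12}$.

`half_trajectory_error()` implements the standard convergence diagnostic:
the statistic on the full series versus on each half, the error being the
mean absolute deviation of the halves from the full value. It supports
vector statistics component-wise.

# The elastic-rod description

At a longer scale the fragment is summarized by three coordinates:
global roll $\rho$ and global tilt $\tau$ — the bend angle $\vartheta$
between the z-axes of two averaged end frames, resolved through the bend
direction $\varphi$ as $\rho = \vartheta\cos\varphi$, $\tau =
\vartheta\sin\varphi$ — and the total twist $\omega$, the half-weighted
sum of local twists between the end frames. Conventions:

* **Frames.** End and middle frames are orientation averages of base-pair
  frames over small windows (default: two consecutive pairs at each end
  and at the centre). The average is the quaternion eigen-average (the
  principal eigenvector of the accumulated quaternion outer products); SVD
  projection of the summed rotation matrices is implemented alongside, and
  the two agree to machine precision for clustered orientations — the test
  suite measures this with the Frobenius metric, which is linear near zero
  angle, because the arccosine of the trace cannot resolve angles below
  $\sqrt{\varepsilon} \approx 10^{-8}$. Averages over orientations spread
  more than 90° are refused as ambiguous.
* **Bend direction.** $\varphi$ is measured in the middle frame about its
  z-axis, $\varphi = 0$ toward the major groove (+x), increasing toward
  +y, $\varphi = \pi$ toward the minor groove. The rotational sense beyond
  the two anchor points is a package convention recorded in the rod
  report. When $\vartheta = 0$ the direction is undefined; it is reported
  as 0 with an explicit `phi_defined = FALSE` flag.
* **Weights.** Total twist and contour length take interior steps at
  weight 1 and the two boundary steps at ½ (the end frames sit mid-step);
  rises are summed in Å and reported in nm.

`fit_rod()` then mirrors the rigid-base moment relations: $\hat{\mathbf
u}$ is the mean of $\mathbf u = (\rho, \tau, \omega)$ in radians, and
$\mathbf K_r = l_0\, \mathbf C_u^{-1}$ in units of length, with $l_0$ the
mean contour length, giving the energy $E_r(\mathbf u) = \frac{k_B
T}{2l_0}(\mathbf u - \hat{\mathbf u})\cdot \mathbf K_r(\mathbf u -
\hat{\mathbf u})$. `bending_stiffness()` marginalizes twist (Schur
complement) to obtain the 2×2 bending form whose diagonal entries are the
groove and backbone constants $a_g$ and $a_b$; the effective isotropic
constant is their harmonic mean, $2/a_{iso} = 1/a_g + 1/a_b$, and by the
eigenvalue bounds of quadratic forms the stiffness for bending in *any*
direction lies between $a_g$ and $a_b$. `twist_stiffness()` is the
complementary 1×1 relaxation onto $\omega$, equal to $l_0 /
\mathrm{Var}(\omega)$. No curvilinear helical axis is fitted anywhere;
the global coordinates come from frame averages only.

# Threading

`thread()` slides a window of steps along a template profile of roll,
twist and slide — the three step coordinates strongly conserved across
nucleosome structures — in 1-bp offsets. At each offset those coordinates
are constrained to the template slice and everything else relaxes, so the
energy is $\tilde E(t_k)$ under the partially relaxed model of the
window's (roll, twist, slide) set. Offsets are 0-based over the half-open
admissible range $[0, L_t - L_w]$, without periodic wrap-around at the
template ends. The energies contain no histone–DNA interaction terms and
no global superhelix geometry, so they are upper bounds on the true
deformation cost and are meaningful *relative to each other* (between
offsets and between sequences), not absolutely. `profile_summary()`
locates minima after a centred moving average of window 3 (raw energies
are kept for the statistics) and estimates the dominant spacing as the
first interior local maximum of the profile autocorrelation above 0.1.

# The synthetic generator

`ground_truth_model()` assembles an exact shape vector and stiffness from
built-in per-pair and per-step parameter tables (10 unique step types, 2
pair types), plus an exponentially decaying same-coordinate coupling
kernel between step blocks (default relative strength 0.12, decay 2
steps) that gives the stiffness the non-local character the estimator
must handle. The tables are *illustrative* B-DNA-like values — canonical
twist near 34°, rise near 3.3 Å, more negative propeller and stiffer
roll/twist for A-tract-like steps, softer TA/CA steps. They are chosen
once, for realism of magnitudes and structure, and are not calibrated to
reproduce any particular simulation's stiffness values: passing
recovery tests demonstrates that the *inference* is correct, not that the
generator matches real DNA. Features of real MD ensembles the generator
deliberately omits: anharmonicity and multimodality (e.g. BI/BII backbone
substates), autocorrelation in time (draws are iid), and broken-pair
geometry (H-bond series are injected separately by
`inject_broken_pairs()` as a filtering fixture).

Assembly enforces positive definiteness: if the coupling kernel drives
the smallest eigenvalue below $10^{-6}$ of the largest, a uniform
diagonal shift restores the floor (with a message); a shift beyond half
the largest eigenvalue aborts. `simulate()` draws iid snapshots through
the Cholesky factor of $\mathbf C = k_B T \mathbf K^{-1}$, reproducibly
per seed, with the caller's RNG state restored.

`frames_from_steps()` and its exact inverse `steps_from_frames()` use the
mid-step triad composition: with $\Gamma = \sqrt{t^2 + r^2}$ and phase
$\phi' = \operatorname{atan2}(t, r)$, the step rotation is
$R_z(\omega/2-\phi')\,R_y(\Gamma)\,R_z(\omega/2+\phi')$ and the
displacement (shift, slide, rise) is expressed in the mid-step triad
$R_z(\omega/2-\phi')\,R_y(\Gamma/2)\,R_z(\phi')$ — pure twist rotates
about z, pure roll about the mid-frame y, pure tilt about the mid-frame
x. The inverse is a ZYZ Euler extraction with two documented branch
choices: at $\Gamma = 0$ the phase is set to 0 (pure twist), and the
$(\omega, \phi')$ pair is normalized to the branch with $\omega \in
(-\pi, \pi]$, since $(\omega - 2\pi k, \phi' - \pi k)$ parameterize the
same rotation. Round-trips hold to $10^{-8}$ degrees/Å.

# Problem sizes and design choices

The validation suite runs at sizes chosen to make sampling error, not
luck, the binding constraint: stiffness recovery uses $N = 30$ ($n = 3$)
with $M = 2\times 10^5$ snapshots (expected relative Frobenius error of a
Wishart estimate $\approx N/\sqrt{M} \approx 3\%$ against a 5% bound),
rod recovery uses $M = 10^5$, and the optimizer-based relaxation oracle
runs at $N \le 36$. The bracketing property of $a_{iso}$ is checked on
1000 random SPD rod models.

Genuinely open choices resolved as package conventions: coordinate
ordering (intra first, then steps); ML covariance normalization;
0-based threading offsets, non-periodic templates; the rotational sense
of $\varphi$; frame windows of two consecutive pairs at each anchor; and
filtering before estimation wherever both are requested.

# Limitations

The harmonic models are fluctuation models: they describe the quadratic
basin around the mean and say nothing about large deformations, kinking,
or melting. Entropy values assume the Gaussian form exactly. Threading
energies are upper bounds without protein terms. The synthetic generator
validates the machinery; conclusions about real sequences require real
coordinate ensembles (e.g. 3DNA output from MD), supplied through the
documented trajectory dialect.
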