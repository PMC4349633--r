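---
title: "Probabilistic functional modes: model, inference and validation"
author: "pfmodes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Probabilistic functional modes: model, inference and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pfmodes)
```

## The problem

Resting-state fMRI records spontaneous, highly structured fluctuations of
the BOLD signal across the brain. A standard way to summarise such data is a
matrix factorisation: a run's voxels-by-time data matrix $D$ is approximated
by the product of a set of spatial maps $P$ and time courses $A$,

$$D^{(sr)} = P^{(s)} A^{(sr)} + \varepsilon^{(sr)},$$

where $s$ indexes subjects and $r$ the runs of a subject. Each column of
$P$ together with the matching row of $A$ is a *mode*: a spatial
distribution over the brain sharing a common time course. Unlike spatial or
temporal ICA, nothing here forces modes to be orthogonal or independent:
modes may overlap in space, contain anti-correlated (negative-weight)
regions, and be correlated with each other in time — properties that real
functional systems are believed to have. Identifiability comes instead from
a strongly non-Gaussian spatial prior, and each subject keeps a single set
of maps across all of their runs, so evidence is pooled over runs
automatically, weighted by each run's noise level.

`pfmodes` implements this model — probabilistic functional modes (PFMs) —
with full variational Bayesian inference, together with a ground-truth
simulator for multi-subject rfMRI and a scoring suite for comparing
decompositions.

## The hierarchical spatial model

For every voxel $v$ and mode $m$, a subject's map weight follows a
delta-Gaussian mixture:

$$P^{(s)}_{vm} \mid q^{(s)}_{vm}=1 \sim \mathcal N(\mu_{vm},
\sigma_{vm}^2), \qquad P^{(s)}_{vm} \mid q^{(s)}_{vm}=0 \sim \delta_0,
\qquad q^{(s)}_{vm} \sim \mathrm{Bernoulli}(\pi_{vm}).$$

The three group-level parameters answer three questions: does this voxel
participate in this mode at all ($\pi$), how strongly ($\mu$), and how
variable is that across subjects ($\sigma$)? $\pi$ carries a beta
hyperprior and $\sigma^2$ an inverse-gamma hyperprior. The group means
themselves carry a spike-and-slab hyperprior,

$$\mu_{vm} \mid \rho_{vm}=1 \sim \mathcal N(0, \gamma_m^{-1}), \qquad
\mu_{vm} \mid \rho_{vm}=0 \sim \delta_0, \qquad \rho_{vm} \sim
\mathrm{Bernoulli}(\lambda),$$

so $\lambda$ is interpretable as the fraction of voxels expected to be
active in a group map. Because modes are expected to be spatially extended
and overlapping, $\lambda$ must stay above $1/M$; the default is
$\min(5/M, 0.75)$. Reported group maps are the marginal posterior mean
$\mathbb E[\rho_{vm}\mu_{vm}\mid D]$, not the slab means alone.

There is deliberately no spatial smoothness or contiguity penalty and no
non-negativity constraint: this keeps the per-voxel updates independent and
the algorithm scalable to hundreds of runs.

## The temporal prior

BOLD fluctuations are dominated by the haemodynamic response function. If
the neural process is white at the sampling rate, the autocorrelation of the
observed signal is exactly the autocorrelation of the HRF,
$\mathbb E[y(t_1)y(t_2)] = \sum_\tau h(\tau)h(\tau - |t_1 - t_2|)$. We
evaluate a canonical double-gamma HRF at the repetition time (defaults:
response delay 6 s, undershoot delay 16 s, unit dispersions, undershoot
ratio 1/6, 32 s support — these are the standard values, exposed in
`pfm_config()`), build the Toeplitz matrix of its autocovariance, rescale it
to unit diagonal and ridge-regularise it to positive definiteness
($10^{-6}$ of the largest eigenvalue, doubled until positive definite).
The prior on a mode time course is then

$$A_m^{(sr)} \sim \mathcal N\!\left(0, \alpha^{-1} K_A\right),$$

with a gamma hyperprior on the precision $\alpha$. (The hyperprior on the
time-course *variance* is inverse-gamma; we parameterise the equivalent
gamma law on the precision because that is the conjugate-exponential form.)
Normalising $K_A$ to unit diagonal makes $\alpha$ interpretable as the
marginal time-course precision rather than absorbing the HRF energy. This
prior is rotationally invariant across modes: it identifies the BOLD
subspace but not the unmixing, which is the spatial prior's job.

Noise is white Gaussian per run with a voxelwise mean: precision
$\psi^{(sr)}$ with a broad gamma hyperprior, means $\nu^{(sr)}$ with a vague
$\mathcal N(0, 10^4)$ prior.

## Variational inference

The posterior is approximated by a product of factors, one per variable
block, updated by coordinate ascent on the evidence lower bound (ELBO).
All distributions are conjugate-exponential, so every update is available in
closed form and provably never decreases the bound. Design choices that the
factorisation leaves open:

* **Gated pairs stay structured.** $q(P_{vm}^{(s)}, q_{vm}^{(s)})$ is a
  Bernoulli-gated Gaussian, and $q(\mu_{vm}, \rho_{vm})$ a spike-and-slab,
  rather than fully factorised pairs — mean-field between a weight and its
  own indicator would collapse the spike.
* **Per-mode, per-run time-course factors.** $q(A)$ factorises across modes
  and runs but keeps the full $T \times T$ Gaussian per factor. The
  posterior covariance is $(\bar\alpha K_A^{-1} + c\,I)^{-1}$ for a scalar
  $c$, so it is stored as that scalar against a shared eigendecomposition of
  $K_A$ — exact reconstruction at $O(T)$ storage per factor, and solves at
  $O(T^2)$ instead of $O((MT)^3)$.
* **All log-odds use exact expectations** ($\mathbb E[\log\pi]$ etc., in
  digamma form), never plug-in means.
* **Sweep order**: subject maps, group means, group variances, mixture
  weights, time courses, temporal precision, noise — spatial before
  temporal so the time-course updates see subject-pooled maps, and each
  precision update consumes fresh second moments.
* **Warm-up sweeps.** During the first few sweeps (default 10) the
  precision-type updates (group variances, temporal precision, noise) are
  held at their broad initial values while maps, group means, mixture
  weights and time courses alternate. At realistic SNR this lets the modes
  locate the signal subspace before shrinkage engages; without it, starts
  far from the signal can collapse into an all-zero local optimum. Every
  update performed during warm-up is still an exact coordinate
  maximisation, so the ELBO trace is non-decreasing from the first sweep
  regardless.
* **Initialisation.** The `svd` scheme (default) seeds the group means with
  the top-$M$ left singular vectors of the concatenated demeaned data;
  subject slab means are perturbed around them at the scale of the maps, so
  different seeds give genuinely different starting points while the group
  skeleton stays data-driven. The `random` scheme draws subject slab means
  from $\mathcal N(0,1)$. Both are fully deterministic given the seed. Run
  time courses are then initialised by ridge regression on the initial
  maps, and noise precisions from the residual variance.
* **Convergence**: relative ELBO change below $10^{-8}$ for five
  consecutive sweeps, or `max_iter` (default 1000) sweeps.
* **Degenerate voxels** (zero variance in every run) are pinned to
  $q_{vm} = 0$ rather than left to produce NaNs.

The scale ambiguity of $PA$ (maps up, time courses down) is resolved only
softly, by the unit-diagonal $K_A$ and the $\alpha$ prior; no hard
renormalisation happens during inference. Mode elimination is emergent:
modes the data do not support are shrunk towards zero by the hierarchy, and
`mode_strengths()` flags modes whose normalised map standard deviation falls
below 0.05 rather than pruning them.

Default hyperprior values (beta(1,1) on $\pi$; gamma(10^{-3}, 10^{-3}) on
$\alpha$, $\psi$ and $1/\sigma^2$; $\gamma_m = 1$) are broad defaults chosen
by us and exposed in `pfm_config()`; they are not canonical constants.

## The simulator

`simulate_dataset()` generates multi-subject rfMRI with a fully known
ground truth, emulating a scaled-down multi-band acquisition protocol:
by default 30 subjects, 4 runs each, 1200 time points per run at TR 0.72 s
(4800 time points per subject, 144,000 in total), 12,500 voxels.

1. **Parcellation.** 200 binary, contiguous, disjoint random parcels tile a
   one-dimensional voxel line (Dirichlet widths, minimum 2 voxels). Each
   subject gets a smoothly warped copy — a low-pass-filtered Gaussian
   displacement field, monotone by construction, with the maximum shift
   bounded by 1.5 mean parcel widths — standing in for residual
   misregistration and genuine topological variability.
2. **Mode weights.** 25 modes are sparse signed weight vectors over
   parcels. Per-mode sparsities are beta-distributed with mean 0.08 and
   variance $7.5\times10^{-4}$ (about 16 parcels per mode; each parcel in
   about 2 modes). Parcel selection is Markovian, favouring neighbours of
   already-selected parcels, and weights come from an AR(1) process along
   the parcel line, so adjacent parcels carry correlated signed weights.
   Subjects deviate from the group weights by a sparse Bernoulli(0.1) mask
   of Gaussian perturbations.
3. **Neural time courses** are simulated at 0.1 s resolution with a
   group-level inter-mode correlation matrix (low-rank-plus-diagonal
   construction), perturbed per subject and per run; power below 0.1 Hz is
   boosted by a zero-phase low-pass-plus-passthrough filter (identical
   across modes, which preserves the instantaneous correlations of the
   white input exactly); finally the smallest 80% of each mode's samples by
   absolute amplitude are set exactly to zero, introducing temporal
   non-Gaussianity. Note the deliberate model mismatch: the fitted temporal
   prior assumes a *white* neural process.
4. **BOLD generation.** Parcel time courses (weights times mode series) are
   convolved with an HRF drawn per subject and parcel from a three-kernel
   double-gamma basis (canonical and two temporal-dispersion
   perturbations), resampled to the TR grid, passed through the compressive
   saturation $y = x - c\,x|x|$ (capped beyond $|x| = 1/2c$; $c = 0.25$),
   mapped to voxels through the subject's atlas, and buried in
   spatio-temporally white noise scaled post hoc so the realised SNR is
   exactly $-10$ dB (noise power ten times signal power), shared across the
   dataset by default.

Where the generator needed constants beyond the protocol above (warp
smoothness, AR coefficient 0.7, low-frequency gain 3, correlation jitters,
deviation scale 0.3), we fixed plausible values once and exposed them in
`sim_config()`.

What the simulator does *not* emulate: 3-D geometry and surface topology,
physiological and motion artefacts, spatially structured noise, and
session-level nonstationarity. Passing recovery tests on these simulations
therefore demonstrates correctness of the inference under the stated
generative assumptions, not performance on real scanner data.

## Scoring

Decompositions are compared with the *uncentered* correlation
($\sum x y / \sqrt{\sum x^2 \sum y^2}$): the factorisation is scale-ambiguous
but not shift-ambiguous, so means are kept. Estimated modes are matched to
reference modes by the Hungarian algorithm on the summed spatial and
temporal scores, each candidate pair evaluated at its better joint sign
(one flip applied to a mode's map *and* time course together; the flip is
recorded and respected by all downstream scores). Accuracies are means over
subjects (maps) and runs (time courses) of the matched correlations;
unmatched modes are reported as missing, never as zero. Inter-mode
correlation structure is scored as the RMS error, over off-diagonal
elements, of the subject-averaged difference between estimated and true
mode-by-mode correlation matrices. Test–retest reliability applies the same
matching to two fits of the same data from different seeds; eliminated-mode
pairs are flagged when the pair's map strength, normalised by the strongest
(global) component, falls below 0.05. Group inference on netmats follows
the standard recipe: Fisher transform per subject, one-sample t-test per
element, and conversion to z by two-sided tail matching preserving sign.
Partial correlations for a subset of modes are taken from the inverse
correlation matrix of the *full* mode set (i.e. after orthogonalisation
with respect to the remaining modes), with a ridge repair and warning if
the matrix is ill-conditioned. `dual_regression()` provides the standard
two-stage least-squares baseline for subject-level estimates from
group-level maps.

## Numerical choices and edge cases

* Spike/slab log-odds are computed in logit space and mapped through
  `plogis`, so saturated probabilities degrade gracefully.
* $0\log 0 = 0$ conventions in all mixture entropies; $\lambda = 1$ and
  $\rho \in \{0, 1\}$ limits handled explicitly.
* Correlation matrices perturbed in the simulator are repaired by
  eigenvalue clipping (with a warning) and renormalised to unit diagonal.
* The expected residual in the noise update uses full second moments of
  both maps and time courses, never squared means.
* `uncentered_correlation()` raises an error on zero vectors; scoring
  wrappers convert that to a missing value.
* Ties in Hungarian matching resolve deterministically (lowest reference
  index first).

## Problem sizes used by the validation suite

The test suite exercises the full pipeline at sizes a laptop handles
comfortably, chosen as scaled-down analogues of the reference protocol: the
recovery harness simulates 2000 voxels, 50 parcels, 10 modes, 8 subjects
with 2 runs of 150 time points at $-10$ dB, and fits two seeds for 150
sweeps after 15 warm-up sweeps; ELBO monotonicity is checked on twenty
random 200-voxel datasets; the shrinkage check fits five modes to
pure-noise data. The simulator statistics (parcel counts, sparsity moments,
zero fraction, SNR, time-point bookkeeping) are asserted at the reference
protocol's own values, with the voxel count reduced where only temporal
bookkeeping is at stake. `scripts/acceptance.R` recomputes the generative
statistics from scratch with the package's own samplers.

## Known limitations

* The temporal prior identifies the BOLD subspace but is rotation-invariant
  across modes; unmixing rests entirely on the spatial prior.
* Variational posteriors underestimate uncertainty, and the mean-field
  factorisation can bias strongly correlated factors; ELBO monotonicity and
  ground-truth recovery are verified, posterior calibration is not.
* Coordinate ascent finds local optima. Starts far from the signal subspace
  can converge to visibly worse optima even with warm-up; comparing fits
  from several seeds (as `test_retest()` does) is the intended workflow.
* One canonical HRF enters the prior; subject- or voxel-specific
  haemodynamics are simulated but not inferred.
* The 1-D parcel geometry of the simulator is a deliberate simplification;
  nothing in the inference depends on it.
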