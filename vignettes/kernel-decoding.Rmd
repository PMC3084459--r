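---
title: "Kernel regression decoding of fMRI time series: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kernel regression decoding of fMRI time series: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The decoding problem

`krfmri` predicts continuous stimulus ratings from 4-D fMRI time series. Each
scan is a point $\mathbf{x}_i \in \mathbb{R}^D$ (one coordinate per in-mask
voxel, $D$ in the tens of thousands at acquisition scale), and the target
$t_i$ is a per-scan rating, rescaled to $[0,1]$ and convolved with the
canonical hemodynamic response function (HRF) before it becomes the
regression target. With $N$ scans and $D \gg N$, all models here work in the
dual: the data enter only through the $N \times N$ Gram matrix
$K_{ij} = \mathbf{x}_i^\top \mathbf{x}_j$.

## Preprocessing

**Masking and smoothing.** Analysis is restricted to a gray-matter mask
(BOLD signal changes of neuronal origin are expected there; the mask also
shrinks $D$ by roughly 80%). Volumes are optionally smoothed with a
separable Gaussian (default 6 mm FWHM), with the kernel truncated at
4 sigma and renormalised at the boundary so that constant images are
preserved and no intensity is lost at brain edges. Voxels are vectorised in
a fixed raster order (x fastest, then y, then z), so weight maps can be
scattered back onto the grid bit-exactly.

**Drift removal.** Scanner time series carry slow drift (roughly
0–0.0015 Hz). A discrete-cosine-transform basis $G$ ($N \times L$,
orthonormal DCT-II columns, constant term included) spans the drift
subspace, and the residual-forming matrix
$R = I - GG^\top$ projects it out. Two properties matter:

* $L = 8$ bases over a 704-scan run at TR 1.75 s remove everything up to
  $(L-1)/(2N \cdot \mathrm{TR}) = 1/352$ Hz. This motivates including the
  constant term in the count: excluding it would put the cut-off at 1/308 Hz
  instead of the conventional 1/352 figure.
* Detrending can be applied *in kernel space*:
  $K_\text{detrended} = R^\top K R$, identical to detrending every voxel
  time series first but $O(N^2)$ instead of $O(ND)$. Non-linear kernels must
  be formed after detrending (the identity only holds for the linear Gram
  matrix), and the package refuses to detrend an RBF or polynomial kernel.

Detrending is per run by default (block-diagonal $R$; drift is
session-specific), built once over the concatenated train+test scan set and
sliced into blocks afterwards, so train and test scans see the same
projection.

## Regression models

**Kernel ridge regression (KRR).** The dual ridge solution is
$\boldsymbol\beta = (K + \lambda I)^{-1}\mathbf{t}$ with prediction
$t_* = \sum_i \beta_i K(\mathbf{x}_i, \mathbf{x}_*)$. The solve is a
Cholesky factorisation (never an explicit inverse) with a one-shot jitter
fallback of $10^{-10}\,\mathrm{tr}(K)/N$ on failure. Probabilistically KRR
is the MAP estimate under a Gaussian weight prior with precision $\alpha$
and noise variance $\sigma^2$, with $\lambda = \alpha\sigma^2$. The penalty
is chosen by cross-validation over a decade grid (default
$\lambda \in 10^{-2} \ldots 10^8$); on moderately decodable synthetic data
the held-out correlation is flat across $\lambda \in [10^2, 10^5]$, so the
exact value within that plateau matters little.

**Relevance vector regression (RVR).** Each weight of the design
$\Phi = [\mathbf{1}, K]$ gets its own Gaussian prior precision $\alpha_i$
(automatic relevance determination). Type-II maximum likelihood is iterated
with the standard fixed-point updates
($\gamma_i = 1 - \alpha_i\Sigma_{ii}$, $\alpha_i \leftarrow \gamma_i/\mu_i^2$,
$\sigma^2 \leftarrow \|\mathbf{t}-\Phi\boldsymbol\mu\|^2/(N-\sum_i\gamma_i)$)
until the log marginal likelihood changes by less than $10^{-6}$ (cap 1000
iterations). Precisions diverging past $10^{12}$ (or $10^9$ times the mean
active precision) are pruned; surviving kernel columns are the relevance
vectors. Initialisation is $\alpha_i = 1/N^2$,
$\sigma^2 = 0.1\,\mathrm{var}(\mathbf{t})$ — standard sparse-Bayes practice.
Numerical notes: the evidence is evaluated with the residual identity
$\mathbf{t}^\top C^{-1}\mathbf{t} =
\|\mathbf{t}-\Phi\boldsymbol\mu\|^2/\sigma^2 +
\boldsymbol\mu^\top A \boldsymbol\mu$ (stable as $\sigma^2 \to 0$), and
$\sigma^2$ is floored at $10^{-12}\,\mathrm{var}(\mathbf{t})$ so noise-free
constructions terminate cleanly.

**Evidence-based penalty selection.** Modelling
$\mathbf{t} \sim N(0, \theta_1 I + \theta_2 K)$ and maximising the marginal
likelihood over $\boldsymbol\theta$ gives the Gaussian-process analogue of
ridge tuning, with $\lambda = \theta_1/\theta_2$. The optimiser works in
$\log\boldsymbol\theta$ (positivity by construction) with BFGS from three
seeded restarts; because $C$ is diagonal in the eigenbasis of $K$, each
evaluation is $O(N)$ after one decomposition. An optional constant
covariance term $\theta_3\mathbf{1}\mathbf{1}^\top$ absorbs a target offset
— a bias with a Gaussian prior — and is the appropriate model when targets
are not centred.

**Weight maps.** For linear kernels the primal weights are recoverable as
$\mathbf{w} = X^\top R\boldsymbol\beta$, scattered back to the voxel grid,
and satisfy the prediction identity $t_j = \mathbf{w}^\top R\mathbf{x}_j$
exactly. This is the standard multivariate summary map for visualising which
voxels carry the decodable pattern.

## HRF-aware post-processing

Raw ratings live in $[0,1]$; predictions do not respect this. The
post-processing chain exploits the constraint:

1. **Constrained deconvolution.** With $H$ the lower-triangular Toeplitz
   convolution matrix of the canonical HRF (double-gamma, peak delay 6 s,
   undershoot delay 16 s, unit dispersions, peak:undershoot 6, 32 s support,
   peak-normalised so the $[0,1]$ box keeps the rating scale), solve the
   quadratic program
   $\min_z \|Hz - \mathbf{t}_*\|^2$ s.t. $0 \le z \le 1$. The problem is
   convex with simple bounds and is solved by L-BFGS-B with analytic
   gradient from a clipped least-squares warm start; the test suite pins the
   optimum against an independent projected-gradient solver, so any
   KKT-accurate convex QP method is an acceptable implementation.
2. **Re-convolution and temporal smoothing.** The furnished prediction is
   $H z$, then smoothed with a 1-D Gaussian of FWHM 3 scans
   (truncated/renormalised at the series edges).
3. **Temporal shifting.** Self-paced behaviours can lead the canonical
   hemodynamic delay; shifting the training target by whole scans (edge
   replication, so no spurious onsets) and inversely shifting the prediction
   tests for this. Zero padding is deliberately avoided: ratings are bounded
   baselines and zeros would inject fake events.
4. **Match filtering.** For ratings known to consist of $k$ stereotyped
   events (e.g. seven instruction periods per session), the prediction is
   cross-correlated with an event template (the average supra-threshold
   segment across training sessions, onset-aligned, peak-normalised); the
   $k$ best lags are picked greedily with an exclusion radius of one
   template length (ties to the earliest lag) and clean template copies are
   inserted on a zero baseline at fixed amplitude. Near-perfect
   reconstructions are clipped at $|r| = 1 - 10^{-7}$ before the Fisher
   transform.

## Scoring

Per (subject, rating, session) cell the score is the Pearson correlation
between prediction and convolved rating, mapped through Fisher's transform
$z = \tfrac12\log\frac{1+r}{1-r}$ and averaged. The transform is the reason
post-processing effort concentrates on already-good ratings: the gain from
$r = 0.8$ to $0.9$ is more than three times the gain from $0.2$ to $0.3$.
Cross-validation is session-wise (train on all-but-one run, predict the
held-out run, both directions for two runs).

## The synthetic generator

No public deposit of the original competition data exists, so the package
ships a generator with known ground truth:

* a smooth positive baseline field (sum of broad Gaussian bumps, not a
  constant — this exercises masking and detrending realistically);
* a gray-matter-like mask from a thresholded smooth random field (roughly
  30% of the grid);
* per-rating activation maps: Gaussian blobs confined to the mask;
* raw ratings per kind — binary blocks, spike trains (non-overlapping copies
  of the HRF response to a 3-scan boxcar, the natural shape for short
  auditory events), or smoothed bounded random walks — HRF-convolved per
  run;
* per-run drift: random cosines below 0.0015 Hz with independent phases and
  smooth spatial amplitude fields (drift is session-specific, matching the
  per-run detrending default);
* iid Gaussian noise.

Each component draws from its own seeded stream, so changing one amplitude
leaves the other components bit-identical, and signal injection is exactly
linear in the effect amplitude.

**Defaults and their rationale.** TR 1.75 s and the drift band are the
acquisition values; grid 16×16×8 with 3 runs × 128 scans is the desk scale
used throughout the tests (the 64×64×34 × 704 geometry is available by
passing those values). Signal amplitude 3, noise 1, drift 10 give held-out
correlations in the 0.6–0.9 range typical of decodable objective ratings.
Two condition choices deserve note:

* *Task band vs detrending cut-off.* At 128 scans per run, 8 DCT bases
  remove everything below 0.0156 Hz. Pipeline tests therefore use block
  ratings with a 56 s period (0.018 Hz fundamental) so the task spectrum
  sits above the cut-off — the same geometry as the full-scale design, where
  1/352 Hz is far below any task frequency. Slow continuous ratings over
  short runs would be partially removed by their own preprocessing, which is
  a property of short runs, not of the method.
* *Drift-heavy regime.* The detrending ablation uses drift amplitude 50
  (per-voxel drift sd roughly ten times the noise sd and five times the
  signal), i.e. drift dominating the variance. There, held-out correlation
  falls to roughly 0.5 without detrending and recovers to 0.85 with 8 bases;
  with the default mild drift, ridge regularisation alone absorbs the drift
  and the ablation is a wash.

**What the generator does not emulate:** subject motion and interpolation
artefacts, physiological (cardiac/respiratory) noise spectra, spatial
autocorrelation of the noise, field inhomogeneity, or eye-tracker rating
dynamics. Passing tests demonstrate correct recovery of the generative model
above, not performance on real scanner data.

## Numerical choices and degenerate inputs

* Kernel validation: square linear kernels must be symmetric to $10^{-10}$
  and have eigenvalues above $-10^{-8}\lambda_\max$; worse is an error, not
  silent clipping.
* RBF-from-linear squared distances are clamped at 0 with a warning only
  within $-10^{-8}$ numerical slack.
* Probability-map thresholding is strict (`pmap > 0.3`); an empty mask is an
  error.
* Constant targets make the Pearson correlation undefined and error;
  all-zero targets make evidence optimisation degenerate and error.
* Rank-deficient drift bases are handled through the SVD pseudo-inverse; the
  orthonormal DCT path builds $R = I - GG^\top$ directly so per-run blocks
  are exactly zero off the diagonal blocks.
* Match-filter tie-breaks go to the earliest lag; template insertion is at
  fixed (unit-peak) amplitude per event.

## Problem sizes

Tests and the acceptance script run at desk scale: grids of 8×8×4 to
16×16×8 voxels, 2–3 runs of 64–128 scans, 20-seed repetitions for
simulation contrasts, N = 200 for evidence-recovery replicates, and
704-scan single runs where the full-length drift spectrum matters. These
sizes were chosen so every contrast (detrending ablation, shift recovery,
match-filter detection, sparsity) is decided by the effect under study
rather than by Monte-Carlo noise, while a full check remains a
minutes-scale run on one CPU.

## Known limitations

* The exact HRF parameters and the noise/drift magnitudes of the original
  competition data are not published; defaults here are conventional
  (SPM-style double-gamma) and calibration choices, respectively.
* RVR uses the classic full EM updates, not the fast sequential
  marginal-likelihood variant; at $N$ of a few hundred this is inexpensive.
* Each rating is decoded independently; no multi-target coupling.
* The command-line tool operates on the dataset directory layout written by
  `simulate`/`write_dataset()`; arbitrary external NIfTI layouts should go
  through the R API (`apply_mask()` onward) directly.
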