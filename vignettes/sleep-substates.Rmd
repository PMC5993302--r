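---
title: "Discovering sleep/wake substages with a mean-covariance RBM"
author: "sleepstates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering sleep/wake substages with a mean-covariance RBM}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sleepstates)
```

## The problem

Rodent sleep is conventionally scored in three vigilance stages -
wakefulness (W), NREM sleep (NR) and REM sleep (R) - by visual inspection
of EEG and EMG telemetry in 4-second epochs. The distribution of epoch
features within each stage is, however, plainly multimodal: scatter plots
of log band ratios against log EMG show several clusters inside a single
manually scored stage. `sleepstates` implements an unsupervised pipeline
that discovers these finer *substages* as the binary latent states of a
mean-covariance restricted Boltzmann machine (mcRBM) fitted to per-epoch
spectral features, and then characterises each state by its stage
correspondence, information content, transition structure, circadian
profile, genotype specificity and homeostatic rebound after sleep
deprivation.

## From signal to model input

Each recording is cut into 4-s epochs. Per epoch we compute the power in
five bands - Delta 0.25-5, Theta 5-9, Alpha 9-12, Beta 12-20 and Gamma
20-50 Hz, half-open intervals so shared endpoints are counted once - by
Welch-averaged periodograms of 50%-overlapping Hann windows whose length
is the largest power of two not exceeding 2.048 s of samples. At the
nominal 500 Hz sampling rate this gives 1024-sample windows, i.e. a
0.49-Hz frequency resolution, and exactly two windows per epoch. Whether
band bins are summed or averaged is immaterial downstream because only
band *ratios* enter the model. The rectified EMG is integrated per epoch
by the trapezoidal rule, with each epoch's integral closed by the first
sample of the next epoch so that per-epoch values add up exactly to the
whole-recording integral.

The model input is, per epoch, the natural log of the ten pairwise band
ratios (numerator before denominator in band order: Delta/Theta,
Delta/Alpha, ..., Beta/Gamma) plus the log EMG integral - an 11-dimensional
vector. Every column is mean-centred within each subject separately. Two
consequences matter:

* the representation is invariant to any per-subject gain on the EEG, and
  the per-subject centring removes EMG gain differences, which is how
  inter-subject variability in electrode impedance is neutralised;
* log ratios are differences of log powers, so the 11 features live on an
  affine image of a 6-dimensional log-power space; the feature covariance
  is correspondingly structured, which is exactly the kind of dependency
  the covariance half of the mcRBM is designed to model.

Artifact epochs are input flags (manual annotation); no automatic artifact
detector is included. Epochs flagged as artifacts are dropped before the
ratio step, and sequence adjacency is broken at the gaps they leave.

## The model

The mcRBM couples the visible vector $v \in \mathbb{R}^{11}$ to two groups
of binary hidden units: $M_c = 11$ covariance units $h^c$ (via $F = 11$
factors) and $M_m = 10$ mean units $h^m$. Its energy is the sum of the two
group energies

$$E_c(v, h^c) = -d^\top h^c - ((\hat v^\top C)^{\,2})\, P\, h^c, \qquad
  E_m(v, h^m) = -\tfrac12 (v-b)^\top (v-b)\, c^\top h^m - v^\top W h^m,$$

where the square is elementwise, $P \le 0$ entrywise, and
$\hat v = v / (\lVert v \rVert / \sqrt{D} + 10^{-8})$ is the normalised
visible vector that keeps the covariance energy robust to outliers. Hidden
inference is factorial:
$p(h^c \mid v) = \sigma\!\big(d + ((\hat v^\top C)^2 P)^\top\big)$ and
$p(h^m \mid v) = \sigma(c + W^\top v)$. Conditioned on both hidden groups
the visibles are Gaussian with precision $C \operatorname{diag}(-P^\top
h^c)\, C^\top$ and mean $\Sigma W h^m$, so every binary configuration is a
Gaussian mode over the input features - the formal sense in which a latent
state *is* a substage. A latent state's identity is the concatenated
$(h^c, h^m)$ bit vector, packed into an integer key.

Note one printed idiosyncrasy kept deliberately: the quadratic factor in
$E_m$ multiplies $c^\top h^m$, whereas the mean-unit conditional is the
standard $\sigma(c + W^\top v)$. The two are implemented exactly as given;
training gradients for $c$ follow the conditional (the form the encoding
actually uses), and the visible bias $b$ is held at zero since inputs are
per-subject centred.

### Training

Training is stochastic-gradient contrastive divergence over minibatches of
256 epochs with learning rate $10^{-2}$. The default `"gibbs-cd"` sampler
performs one alternating Gibbs step - sample both hidden groups, resample
the visibles from the per-configuration Gaussian - and contrasts data and
reconstruction statistics computed from activation probabilities. The
Gaussian used during training adds the identity to the precision (the
proper-density anchor); without it a minibatch sample with no active
covariance unit would have unbounded conditional variance. An `"hmc-pcd"`
sampler (persistent fantasy particles updated by leapfrog dynamics on the
free energy) is available for fidelity to the original mcRBM training
recipe; all property tests pass under the default.

Four numerical choices proved load-bearing and are defaults:

* **Fixed $P$.** $P$ keeps its negative-identity initialisation. When $P$
  is learned it drifts toward a dense, nearly uniform matrix; because the
  factor loadings $C$ are column-normalised and near-orthogonal,
  $\sum_f (\hat v^\top C)_f^2$ is then essentially constant in $v$, the
  covariance-unit input becomes flat, and the covariance code degenerates
  to all-ones. The identity topology preserves one-factor-per-unit
  specialisation. Learning $P$ remains available as `learn_P = TRUE`.
* **Data-anchored initialisation.** Mean-unit hyperplanes start halfway
  between the origin and randomly drawn epochs ($w_j = x_{i_j}/2$,
  $c_j = -\lVert w_j \rVert^2/2 - 2$), and factor directions start at
  normalised random epochs. Pure small-Gaussian initialisation leaves
  units at the symmetric saddle of zero-mean data, where they either die
  or sit mid-range on a dense mode and flicker across the binarisation
  threshold.
* **Seeded restarts.** `restarts = k` trains $k$ seeded models and keeps
  the lowest final mean-field reconstruction error. The criterion is
  unsupervised and targets a specific failure: runs whose code merges two
  distinct modes reconstruct both to a common midpoint and score visibly
  worse.
* **Threshold polish.** After training, each unit's binarisation crossing
  is moved to the nearest low-density valley of its 1-D activation
  argument (within +-1 of the current crossing, 41 bins). This stabilises
  the deterministic encoding without changing what the unit separates.

### Encoding and the catalog

Epochs are encoded deterministically: activation probabilities of both
groups binarised at 0.5, ties mapped to 1. The catalog tallies each
observed configuration with its cohort-wide and per-subject counts and,
against the manual labels, the stage-probability row $p_L(y)$. Entropy
(base 2) of that row quantifies the state's ambiguity; global
informativeness is the mutual information between states and stages
normalised by the latent-state entropy, $I_n = I(X;Y)/H(X) \in [0,1]$.
Per-stage bars are reported as the MI decomposition
$I_y = \sum_x p(x,y) \log_2 \frac{p(x,y)}{p(x)p(y)}$ - one defensible
reading of a "per-stage NMI"; the per-state entropy is reported alongside,
and neither is asserted to be the only possible convention. A state is
assigned the role W, NR or R when its stage probability reaches 0.6
(boundary inclusive), else it is *transitional*. States with fewer than
`min_count = 10` epochs are flagged rare; the true pruning rule behind any
particular published state count is data-dependent, so rare states are
flagged rather than silently dropped.

## Dynamics, profiles, phenotypes

**Transitions.** $T_{ij}$ is the conditional frequency of $i \to j$ steps
among consecutively recorded epochs, pooled over the requested subjects;
adjacency breaks at artifact gaps and subject boundaries because a
transition across a removed epoch was never observed. Self-loops are
retained - at 4-s resolution the diagonal dominates and that is the
structure, not an artifact. The graph view uses a ForceAtlas2-style
layout: linear attraction along edges weighted by transition probability,
degree-weighted repulsion, self-loops excluded from forces, deterministic
under a seed. Edges below $10^{-4}$ are pruned from the display file only,
never from $T$.

**Daily profiles.** Epoch counts per state in 1-h zeitgeber-time bins
(ZT 0 = lights on; light phase ZT 0-12), fitted with a degree-6
least-squares polynomial - the lowest even degree able to express two
peaks across 24 bins; the fit is on counts, not densities. The peak is the
fitted curve's argmax on a 0.1-h grid, with the histogram argmax reported
alongside. Peaks inside the light phase are classified first-half
(< ZT 6) or second-half; REM-associated states peaking late in the light
phase are the canonical example.

**Group comparisons.** Per-state occupancy is compared between genotypes
with the classical pooled-variance two-sample t test on per-subject epoch
counts (Welch available; per-subject proportions available via
`measure = "proportion"` - the choice between counts and proportions is
left visible because both are defensible). Raw p < 0.05 flags
significance by default, Benjamini-Hochberg optionally. Zero pooled
variance with equal means reports t = 0, p = 1; with unequal means a
p = 0 sentinel with a warning.

**Discrimination.** Each subject is its occupancy distribution over the
catalog. Leave-one-subject-out classification uses a linear SVM, an LDA
and a 1-nearest-neighbour classifier under majority vote; a three-way
split falls back to the SVM. The LDA operates on a PCA reduction (at most
$n - 1 - g$ components) because occupancy vectors are collinear relative
to subject counts; the 1-NN breaks distance ties by first index so the
whole ensemble is deterministic.

**Rebound.** For a recovery day whose ZT 0-6 was sleep deprivation, the
per-hour difference recovery minus matched baseline (same subject, same
clock hours, counts per hour) is computed for ZT 6-24 and the peak is
classed immediate (ZT-6 bin), intermediate (ZT 6-12], late (> ZT 12), or
none when no difference is positive.

## The synthetic cohort generator

No recordings ship with the package, so every quantitative claim is
validated on seeded synthetic cohorts whose structure mirrors the study
designs: `three-groups` (3 genotypes x 5 subjects x 24 h, K = 9 substages,
two group-specific substages per group), `circadian-mutant` (2 x 7 x 24 h,
one group's modulation phase advanced by 2 h) and `deprivation`
(2 x 7 x 72 h: two baseline days, deprivation over ZT 0-6 of day 3, then
recovery with planted rebound bumps peaking at ZT 6.5 / 9.5 / 14.5, the
mutant group attenuated).

Emissions are parameterised in the 5-D space of log Delta/Alpha/Beta/Gamma
power relative to Theta (fixed at 1 as the ratio reference) plus log EMG:
a generic 11-vector of log ratios would violate the ratio identities,
whereas this parameterisation makes the feature step an exact linear image
of the emission Gaussian and the pipeline's gain invariance hold by
construction. Each substage has a physiologic flavour (active wake with
high, variable EMG; delta-dominant NREM; theta-dominant REM with tight
atonia) and its own diagonal covariance - covariance diversity is what
gives the model's covariance units something to encode. Mode means were
chosen once so that all pairwise distances in the 11-D feature space are
at least ~4x the within-mode noise radius; substages of the same macro
stage inevitably share a direction (all NREM variants are "delta up"), so
within-stage contrasts are carried by magnitude and by the
alpha/beta/EMG axes.

Dynamics: with probability `rho = 0.8` an epoch repeats the previous
substage; otherwise a macro stage is drawn from
$S = (1 - m) I + m \mathbf{1}\pi^\top$ with $m = 0.4$ and $\pi$ the
labeled stage mix (56.3 / 38.09 / 5.61% W/NR/R), then a substage within
that stage. This yields substage bouts of ~20 s and stage bouts of ~2 min
(fragmented mouse sleep) and makes the stationary distribution
$\pi_{\text{stage}} \cdot p(k \mid \text{stage})$ exact in closed form -
the oracle used by the stationarity test. Circadian modulation multiplies
transition *columns* by $1 + a\cos(2\pi (t - \phi)/24)$ (amplitudes
0.25-0.3; wake phases in the dark, NREM in the light, REM late light) and
rows are renormalised; emissions stay stage-pure so recovery tests remain
clean. During deprivation the sleep-substage columns are zeroed; during
recovery they are scaled by a Gaussian bump (width 0.8 h) at the planted
peak.

What the generator does **not** emulate: real within-stage spectral
drift, scorer disagreement near stage boundaries, artifacts, inter-subject
differences beyond gain (every subject shares the group's emission
means), and aperiodic/1-f background. Passing the recovery tests
therefore demonstrates that the implementation is correct and the
procedure coherent on data matching its assumptions - not that real
recordings would yield equally clean catalogs.

## Problem sizes and budgets

The validation suite runs the full pipeline on the `three-groups` preset
at its study scale (15 subjects x 21,600 epochs, 324,000 epochs total),
trains for 10 passes with 5 restarts, and checks NMI against planted
substages (>= 0.8 observed ~0.95), injectivity and >= 95% coverage of the
mode-to-state map, and 100% LOSO genotype accuracy. Rebound detection is
Monte-Carlo validated over 100 seeded deprivation cohorts. Transition
estimation is checked against a known 4x4 generator at 50,000 steps
(max entry error < 0.02). These sizes keep a full run in the low minutes
on one CPU while leaving the statistical margins comfortable.

## Known limitations

* CD-1 is a crude approximation to the likelihood gradient; the model
  selection by reconstruction restarts mitigates but does not eliminate
  run-to-run variation in how hidden capacity is allocated.
* The number of discovered states is not a tunable target: it emerges
  from training, and catalogs from real data would be larger and noisier
  than the synthetic ones (flagging of rare states exists for exactly
  this reason).
* The EDF reader covers standard 16-bit EDF with one EEG and one EMG
  channel at a common rate; EDF+ annexes (annotations, discontinuous
  records) are out of scope.
* The deterministic encoding discards posterior uncertainty; epochs near
  a polished boundary are still assigned hard codes.
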