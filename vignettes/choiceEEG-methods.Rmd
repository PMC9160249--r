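---
title: "choiceEEG: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{choiceEEG: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(choiceEEG)
```

## The scientific question

When people select between two reaching targets, the selection can be driven
externally (a stimulus instructs the response, and distractors make the
mapping harder) or internally (the chooser is free, and difficulty comes from
the two options being almost equally attractive). Two oscillatory signatures
are candidates for a general marker of this action competition: midfrontal
theta power (4–8 Hz) after stimulus onset, classically enhanced by conflict,
and sensorimotor beta power (15–30 Hz), which desynchronizes before movement
and tracks reaction time. choiceEEG implements the full analysis chain used
to compare these signatures across a 2×2 within-participant design (Context:
Instructed/Free × Difficulty: Easy/Hard), together with a synthetic-data
generator that reproduces the behavioral and oscillatory structure such a
study assumes, so every stage of the chain is testable end to end without
any recordings.

The free-choice difficulty manipulation relies on the point of subjective
equality (PSE): the left-target distance at which both targets are chosen
equally often. A preliminary psychometric phase estimates it; the main test
then places the left target at the PSE (hard: maximal uncertainty) or 4 cm
beyond it (easy: strong right preference).

## The generator

### Behavior

Per participant $i$, a PSE $\mu_i \sim \mathcal N(\mu, \sigma^2)$ (defaults
8 ± 1.2 cm) and choices
$$P(\text{right} \mid d) = \operatorname{logit}^{-1}\!\big(\beta (d - \mu_i) + b\big),$$
with slope $\beta = 0.6\,\text{cm}^{-1}$ and a rightward bias $b =
\operatorname{logit}(0.578)$. Both constants are calibrated jointly so that
the right target is chosen 57.8% of the time when the left target sits at the
PSE and about 94% of the time at PSE + 4 cm — the two percentages such a
design reports. The bias is a main-test phenomenon *relative to the measured
PSE*: the preliminary phase, which defines the PSE, draws from the unbiased
logistic, so its 50% crossing is the configured $\mu_i$ and psychometric
recovery is estimating a well-defined quantity.

Reaction times are drawn per condition from a normal truncated below at zero
(means 453/495/483/486 ms for Instructed Easy/Hard and Free Easy/Hard, plus a
shared participant offset, SD 25 ms, and a within-participant trial SD of
80 ms). Draws above the 800-ms deadline stay in the table flagged `aborted`,
so kept trials effectively follow a truncated-at-deadline distribution; with
means 3–4 SD below the deadline the truncation bias on condition means is a
fraction of a millisecond, but it exists and is why the generator flags
rather than redraws. The trial sequence is a uniform random shuffle repaired
so the same target configuration never appears twice in a row, as the design
requires; an explicit feasibility check rejects count vectors for which no
such sequence exists. The published condition means carry a reported
between-participant SD of 36–41 ms; the default participant-offset and trial
SDs were chosen once to land in that range at the published trial counts.

### EEG

Each eligible trial (non-aborted, right-directed — left-directed movements
are excluded from EEG analysis by design) gets a continuous multi-channel
segment from which stimulus-locked ([−1.2, 1.6) s) and movement-locked
([−2.0, 0.8) s) epochs are cut, so the two epoch sets are views of one
physical signal. Three components are summed:

* **1/f background.** White noise spectrally shaped to power $\propto
  1/f^{\alpha}$ ($\alpha = 1$), per-channel RMS `noise_sd` (6 units), then
  spatially mixed across channels by a Gaussian distance kernel with
  coherence length `noise_spatial_cm` (4 cm). The mixing emulates volume
  conduction: scalp potentials from deep or distributed generators are
  spatially smooth, and the surface Laplacian (below) exists precisely to
  suppress that component. A spatially *independent* background would be the
  one configuration the Laplacian amplifies hardest — we measured that it
  reduces a planted focal effect to undetectability — and corresponds to no
  physical head model. Setting `noise_spatial_cm = 0` restores independent
  channels.
* **Midfrontal theta burst.** A Hanning-windowed 6-Hz burst, 300–500 ms
  post-stimulus, with random per-trial phase (so it is induced, not evoked:
  per-trial wavelet power sees it, a cross-trial average would not). Its
  spatial profile is focal — weight 1 at Fz, 0.5 at F1 and F2 — because a
  patch of equal amplitudes has no second spatial derivative at its interior
  and would be flattened by the Laplacian. The amplitude is multiplied by
  $1 + g$ (`theta_effect`, default 0.6) in Instructed Hard only.
* **Sensorimotor beta.** An ongoing 20-Hz oscillation over the left
  sensorimotor set (peak C1, shoulders C3/Cz/FC1/CP1) whose amplitude dips by
  a raised-cosine notch over the 600 ms before movement onset. The dip depth
  is $\delta_0 + \kappa\,(rt - rt_{\mathrm{ref}})$ clipped to $[0, 0.95]$,
  with $\delta_0 = 0.5$ and coupling $\kappa = 1\,\text{s}^{-1}$. The study
  this emulates does not quantify the RT–beta coupling; $\kappa$ is a free
  generator parameter, not an empirical claim.

With `theta_effect = 0` and `beta_rt_coupling = 0` no component depends on
condition: condition labels are exchangeable and the dataset is a true null,
which is what the calibration experiments below consume. One master seed
drives everything; per-participant streams are derived deterministically, so
a dataset is bit-reproducible from its configuration.

## Preprocessing

* **Filtering**: zero-phase (forward–backward) Butterworth, 1–125 Hz
  band-pass (4th order per edge) with a 59–61 Hz band-stop. The original
  recording chain specifies only the bands; Butterworth was chosen for its
  monotone response, which keeps pass-band ripple between 4 and 30 Hz far
  below 1 dB. The stage requires the sampling rate to exceed twice the upper
  edge; synthetic data generated directly at 250 Hz is already band-limited
  and skips it.
* **Average reference**, then **surface Laplacian**: Perrin-style spherical
  splines, order $m = 4$, Legendre truncation $L = 50$, ridge
  $\lambda = 10^{-5}$, on a 9.2-cm spherical head. These are common defaults;
  the transform in the original analysis is named but not parameterised, so
  all three are exposed. The sign convention is source-positive, output
  scaled by the squared head radius. Because the transform is linear it is
  precomputed once as a channels × channels operator. Independent-component
  artifact removal is out of scope (synthetic data carries no ocular
  artifacts); the pipeline notes the skipped stage.
* **Downsampling** to 250 Hz by integer decimation (the 125-Hz low-pass above
  is the anti-alias step).

Epochs follow a half-open sample convention $[t_0, t_1)$ with 1-based
indices: an epoch has exactly $2.8 \times f_s$ samples and the lock-time
sample sits at index $\operatorname{round}(-t_0 f_s) + 1$. This avoids
double-counting boundary samples between windows such as baseline
$[-0.5, 0)$ and period of interest $[0, 0.5)$.

## Time–frequency decomposition

Morlet wavelets on a 4–80 Hz grid in 1-Hz steps with cycle count
$c(f) = 3 + 0.1\,(f - 4)$ — 3 cycles at 4 Hz rising by 0.1 per step to 10.6
at 80 Hz, which reproduces both printed endpoints exactly. Wavelets are
unit-energy with support $\pm 3\sigma_t$, $\sigma_t = c/(2\pi f)$; power is
the squared magnitude of the (FFT-computed) complex convolution, per trial
(induced power). The period of interest must clear one wavelet half-length
from the epoch borders — about 360 ms at 4 Hz, matching the ~750-ms
edge-artifact margin the epoch lengths were designed around — and the
function refuses to run otherwise.

Normalization is the relative change from a 500-ms baseline ($[-0.5, 0)$ s
pre-stimulus; $[-1.3, -0.8)$ s pre-movement): $(P - \bar B)/\bar B$, computed
per channel × frequency on the condition-averaged power, matching a
per-condition normalization scheme. Trial-level ROI power for the mixed
models is normalized by the *same* condition baseline — a deliberate
asymmetry, so trial and condition summaries share a reference. Band
averages (theta 4–8 Hz: 5 integer frequencies; beta 15–30 Hz: 16) are
unweighted means taken after baseline normalization; statistics operate on
band-averaged maps. Clustering per frequency bin was considered and not
implemented: the analyzed quantities are the two bands as wholes, and a
per-frequency search would change the multiple-comparison structure being
calibrated. Because the wavelet support never reaches across the analysis
windows from the epoch borders, the implementation trims epochs to
baseline ∪ POI ± the edge margin before decomposing (`crop` argument) —
verified to leave the analyzed values unchanged — purely to save FFT work.

## Cluster-mass permutation inference

For each paired contrast across participants, a point-wise paired $t$ is
computed per channel × time sample at 250 Hz; points with $|t|$ above the
two-sided critical value at $\alpha_{\text{form}} = 0.05$ (df $= n-1$) are
clustered under the adjacency "same electrode at consecutive samples OR
electrodes closer than 4 cm at the same sample", keeping same-sign points
together; clusters spanning fewer than 2 distinct electrodes are discarded;
the cluster statistic is the sum of member $t$ values. The null is
Monte-Carlo: random within-participant sign flips of the condition
differences (1000 by default), each permutation reduced to its maximum
$|t_{\text{sum}}|$ over clusters, jointly over positive and negative
clusters (a sign-specific null is available behind `max_type = "separate"`;
the joint maximum is the stricter and more common correction). Each observed
cluster gets
$$p = \frac{1 + \#\{\text{null} \ge |t_{\text{sum}}|\}}{1 + n_{\text{perm}}},$$
with ties counted against rejection; the +1 guarantees validity under
Monte-Carlo sampling without deduplicating sign-flip vectors.
$\alpha_{\text{form}}$ is a design choice (the method's reference
implementations default to 0.05) and is exposed in the configuration, as is
the permutation seed, which is required, never defaulted, and recorded in
outputs. Degenerate points with zero difference variance get $t = \pm 10^{12}$
rather than $\pm\infty$ so cluster masses stay ordered and finite.

The five standard contrasts are wired as: Instructed vs Free and Hard vs
Easy on cell-mean averages, the interaction as ΔInstructed (IH − IE) vs
ΔFree (FH − FE) difference maps, and the two simple effects. Theta contrasts
use stimulus-locked maps over $[0, 0.5)$ s, beta contrasts movement-locked
maps over $[-0.5, 0)$ s. The 4-cm neighbour rule uses 3-D chord distances on
the spherical montage (a physical scalp distance, not a 2-D projection);
time adjacency is consecutive samples with no minimum-duration rule.

## Trial rejection and RT matching

Flags are applied in a fixed order: `aborted` (RT > 800 ms), `rt_outlier`
(outside median ± 3 SD within participant × condition — the rule is applied
literally as written, centre = median, spread = SD, and is computed after
aborted trials are removed, the natural reading since aborted trials never
enter any analysis), `instructed_error`, `left_directed`,
`pse_band_excluded` (each Free-Hard target position whose right-choice
percentage for that participant falls outside (25%, 75%), evaluated per
position), and `participant_excluded` (below 75% right at PSE + 4 cm).
Rejection is idempotent: flags are recomputed from scratch on each call.

RTcorFree re-introduces an RT difference between the Free conditions for
control analyses: per participant, the ⌊0.25 n⌋ longest-RT surviving
right-directed Free-Easy trials and the ⌊0.25 n⌋ shortest Free-Hard trials
are flagged, only when the condition exceeds 30 trials. The count rounds
down because trials are indivisible and the rule's source does not state a
rounding. Ties break by trial order for determinism.

## Statistics

The 2×2 within-participant ANOVA is computed from per-participant paired
contrasts: each 1-df effect's $F$ is the squared contrast $t$, $\eta_p^2 =
F/(F + df_{\text{err}})$, exactly the textbook sums-of-squares decomposition
(the tests verify this against `aov`). Post-hocs are paired $t$ with
Cohen's $d = \bar d / s_d$, so $t = d\sqrt n$ holds as an identity;
Bonferroni correction uses $\min(1, m\,p)$ with family size $m$ exposed in
the configuration (default 4 for the 2×2 post-hocs; the source of the
procedure does not state its $m$). Corrected $p$ can be exactly 1.0.

Trial-level "GLMMs" are Gaussian linear mixed models — the term is read
literally — with Context, Difficulty, their interaction and centred RT as
fixed effects and a participant random intercept (the only random term
named), fitted by REML with Satterthwaite type-III $F$-tests. Denominator
degrees of freedom are data-dependent and are not reproduction targets. A
singular random-intercept fit falls back to the fixed-intercept linear model
with a warning. Whether the GLMM consumes RTcorFree-matched trials is left
as a configuration toggle (`use_rtcor`), as either reading of the procedure
is defensible.

Correlation topographies are Spearman (primary) and Pearson coefficients
between the Hard − Easy power change and the Hard − Easy RT change across
participants, per electrode and 100-ms window tiling the period of interest
(5 windows). The peak set is the `n_peak` = 3 electrodes with the largest
$|\rho|$ averaged over windows, ties broken by label order for determinism;
no multiple-comparison correction is applied across the map, which is
reported descriptively alongside the peak fits. Analysis n of 30 (with one
control analysis at 29) is configuration, not a claim: the machinery works
at any $n \ge$ 3 (5 for correlation maps).

## Calibration experiments and what they show

The package validates itself with simulation experiments whose sizes are
package choices:

* **Type-I error**: 200 null-generator datasets (20 participants, 16-channel
  reduced montage, 8 trials per Instructed cell, 500 permutations each); the
  family-wise rejection rate of the theta cluster test must sit inside the
  95% binomial band around 5%. Pilot runs during development landed at
  4–5%.
* **Planted-effect recovery**: 50 datasets with the default
  `theta_effect = 0.6` confined to Instructed Hard (20 participants, 16
  trials per Instructed cell); the IH vs IE contrast must yield a
  significant positive cluster containing ≥ 2 of the planted electrodes in
  ≥ 90% of seeds while FH vs FE stays at chance.
* **Parameter recovery**: psychometric PSE bias below 0.3 cm over 100
  simulated observers at the 8-distances × 25-trials design; mixed-model
  variance components within 25% of truth over 20 seeds.

The generator reproduces the *statistical structure* the analysis assumes —
logistic choices, truncated RT distributions, 1/f background with realistic
spatial coherence, induced band-limited bursts with condition- and
RT-dependent parameters. It deliberately does not simulate ocular or muscle
artifacts, a dipolar forward model, left-target-directed EEG, or
cross-frequency structure; passing tests therefore certify the inference
machinery and its calibration, not the physiological realism of any
particular effect size. The cluster-test calibration in particular transfers
to real data only insofar as the exchangeability assumption of the sign-flip
null holds there, which it does for within-participant condition labels.

## Degenerate inputs and numerical choices

Perfectly separated psychometric data have no finite ML slope: the fit is
flagged and the PSE falls back to the midpoint of the bracketing distances
(or NA when all choices are one-sided). Zero baseline power, empty ROI
channel sets, montages missing a required channel, periods of interest
inside the wavelet edge zone, non-integer decimation factors, fewer than 3
participants in a paired test, and unknown configuration keys are all hard
errors rather than silent repairs. Zero-variance outlier cells (SD = 0) flag
nothing; zero-variance correlation inputs yield missing coefficients.
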