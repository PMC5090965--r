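---
title: "Models and methods behind caudateKD"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind caudateKD}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

caudateKD analyses combined PET/behavioral studies of striatal dopamine-receptor
knockdown in small primates: reference-tissue kinetic modeling of dynamic PET,
voxelwise association of binding with behavior, a trial-level learning battery,
and circadian actigraphy. Because no animal data ship with the package, every
stage is paired with a seeded generator whose ground truth is known, and the
test suite exercises the full pipeline on that synthetic data. This vignette
explains the models, the tunable parameters, the numerical choices, and what
the synthetic data do and do not establish about real recordings.

## Reference-tissue kinetics

The kinetic core is the simplified reference tissue model (SRTM). A target
region's concentration relates to a reference region (cerebellum) with
negligible specific binding by

$$C_t(t) = R_1\,C_\mathrm{ref}(t) + \left(k_2 - R_1 k_{2a}\right)
  \left[C_\mathrm{ref} \otimes e^{-k_{2a} t}\right](t),
  \qquad k_{2a} = \frac{k_2}{1 + \mathrm{BP_{nd}}},$$

with three parameters: the delivery ratio $R_1$ (unitless, physiological range
roughly 0.5–1.5), the target efflux rate $k_2$ (1/min, roughly 0.1–0.5 for the
D1/D2 ligands this pipeline is aimed at), and the binding potential
$\mathrm{BP_{nd}} \ge 0$. `fit_srtm()` uses the standard basis-function
formulation: for each candidate $k_{2a}$ on a 64-point log-spaced grid over
[0.01, 1] /min the model is linear in $(R_1,\; k_2 - R_1 k_{2a})$ and is
solved by least squares; the grid minimum is polished by golden-section search
on $\log k_{2a}$, which removes grid bias at negligible cost. Negative fitted
binding potentials — possible under noise — are clamped to zero with a warning
flag rather than an error, matching parametric-imaging practice.

`logan_ref_bpnd()` implements Logan graphical analysis with a fixed reference
efflux constant $k_2'$: ordinary least squares of
$\int_0^T C_t/C_t(T)$ on $[\int_0^T C_\mathrm{ref} + C_\mathrm{ref}(T)/k_2']/C_t(T)$
over frames with mid-time at or past `t_star`. The slope is the distribution
volume ratio and $\mathrm{BP_{nd}} = \mathrm{DVR} - 1$. The default
`t_star = 30` min reflects the equilibration time of these ligands; it is
user-configurable, and on noiseless synthetic curves the residual Logan bias
decreases monotonically as `t_star` grows (a property the tests assert).
$k_2'$ is obtained by `estimate_k2prime()` from SRTM fits of signal-rich
regions (caudate, putamen); per-region $k_2/R_1$ values are pooled by the
median by default, with the mean available, since joint-fit pooling
conventions differ between analysis tools.

### Numerical choices

Measured frame values are *averages* over frames, not point samples. All
continuous-time work happens on a fine grid (0.1 min, with every frame
boundary inserted) and curves are frame-averaged by exact trapezoidal pieces.
The reconstruction of a continuous reference curve from its measured frames
interpolates frame values at frame mid-times anchored at the origin, then
applies conservative correction sweeps until the reconstruction's own frame
averages reproduce the measurements to near machine precision. The
convolution with $e^{-k_{2a}t}$ uses an exact trapezoidal recursion that
tolerates the non-uniform grid. Logan integrals use trapezoids on frame
mid-times with an implicit (0, 0) origin, because tracer activity starts at
zero.

The synthetic reference curve is a difference of two exponentials,
$A(e^{-\lambda_s t} - e^{-\lambda_f t})$ (defaults $A = 30$ kBq/mL,
$\lambda_f = 3$ /min, $\lambda_s = 0.03$ /min), frame-averaged analytically:
smooth, positive, with a realistic early peak near one minute and a slow late
washout. Frame noise is Gaussian with standard deviation
$\sigma_0/\sqrt{\Delta t}$ ($\Delta t$ the frame duration in minutes), the
usual count-statistics proxy; $\sigma_0 = 0.5$ kBq/mL·min$^{1/2}$ is used as
the study-like level in tests, giving a few percent relative noise on late
frames. The default acquisition schedule is 41 frames over 90 min
(6×10 s, 6×30 s, 11×60 s, 15×180 s, 3×600 s).

## Parametric images and voxel statistics

`parametric_bpnd_image()` applies the fixed-$k_2'$ Logan fit per voxel inside
a mask; failed voxels propagate as missing values and are counted.
`roi_percent_change()` averages BPnd over an ROI mask in a pre/post image
pair and reports $100(\mathrm{post}-\mathrm{pre})/\mathrm{pre}$.

`fit_voxel_glm()` regresses smoothed BPnd images on a behavioral score with
an intercept and (optionally) a global-mean covariate, reporting the score
t-map. With 20 scans the three-column design gives $t$ with 17 degrees of
freedom; a two-column design (global mean handled by proportional scaling
upstream, or omitted) gives 18. Both are supported because published
voxelwise analyses differ in whether the global value enters as a column —
the choice is surfaced via `global_mean` rather than hidden. Gaussian
smoothing uses $\sigma = \mathrm{FWHM}/(2\sqrt{2\ln 2})$ per axis in mm
converted to voxels, separably, with boundary handling by kernel
renormalization so constants are preserved exactly. Cluster reporting uses
26-connectivity by default (6 available), and `residualized_scatter()`
returns partial-regression values whose correlation reproduces the GLM t by
$t = r\sqrt{\mathrm{df}/(1-r^2)}$, asserted in tests to 1e-10.

## The behavioral battery

The generative behavioral model is a two-armed Q-learning agent: the chosen
stimulus value updates as $Q \leftarrow (1-\alpha)Q + \alpha R$ with
$R \in \{0,1\}$ and the unchosen value untouched. The choice logit is
$\beta(Q_A - Q_B)$ plus additive terms for a left-side bias, repeating the
previous stimulus, and repeating the previous side; a lapse probability mixes
in uniform choice; a per-trial abort hazard models the ≥15-minute response
pause that terminates a session. Left/right placement is counterbalanced
within each session (each stimulus left in exactly half the trials, order
seeded-shuffled). Sessions hold 100 trials and a phase ends at the first
complete session reaching 90% correct — the criterion is evaluated per whole
session, not by sliding window, because the session is the study's unit of
testing, and errors are counted through the criterion session inclusive.
Aborted sessions contribute their completed trials to the error count and
can never themselves be criterion sessions.

Baseline agents use $\alpha = 0.25$, $\beta = 5$, bias/stickiness terms of
0.2 logits, 5% lapse, an abort hazard of $2\times10^{-4}$ per trial (about
2% of sessions), and log-normal response times with a 1.5 s median. The
post-injection D2R-knockdown preset lowers $\beta$ to 3, raises the lapse to
8% and the abort hazard to $1.5\times10^{-3}$ (about one session in seven),
and lengthens the median response time to 2.5 s — an *impaired but still
learning* profile: asymptotic accuracy sits near the criterion, so errors to
criterion rise sharply while attainment remains typical. D1R-knockdown and
control presets are unchanged post-injection. These values were fixed once as
a realistic operating point; they are parameters of the generator, not of the
analyses.

Pair statistics (win-stay, lose-shift, simple and reward-associated side
stickiness) never cross session boundaries — overnight gaps break the
"next trial" relation — and return missing values (not zero) when no
qualifying pair exists, so small samples are excluded from group means
rather than biased. The reward-associated side-stickiness conditions on
pairs where repeating the previously touched side would have been rewarded.

Group statistics follow the split-plot design: three-way mixed ANOVA with
GROUP between subjects and TASK/REPEAT within (`mixed_anova()`, computed via
`aov()` error strata and cross-checked in the tests against an independent
stratum-projection computation), Fisher's LSD post hocs on the
subject-within-group mean square, Levene and Mauchly diagnostics, paired
pre/post t-tests on square-root-transformed aborted-session counts, and
Mann-Whitney U comparisons of pooled response times (the final 20 completed
trials of each phase; exact p for small untied pools, normal approximation
with tie correction otherwise). Square-root transforms are applied to error
and trial counts before group tests to stabilise variance.

## Change-point segmentation of learning curves

`find_change_points()` recursively bisects the cumulative-correct record: the
candidate change point in a segment maximizes the deviation from the chord
joining the segment endpoints, and is retained when a two-proportion test
between the sub-segments rejects (Fisher's exact test for segments up to 200
trials, chi-square beyond). Because the candidate is *selected* as the
maximal deviation, testing it at the nominal level would not control false
alarms; the default applies a Bonferroni correction over the candidate split
points in the segment — a union bound on the maximal statistic — which keeps
the family-wise false-alarm rate on stationary sequences below the nominal
level (empirically ~1% at $\alpha = 0.05$, $n = 200$) while a clean
0.1→0.9 rate step is still localized within ±10 trials in over 95% of runs.
The uncorrected variant is available via `correction = "none"`.

`classify_stages()` then partitions trials into bias/perseveration, chance,
and improvement stages. The bias stage runs from trial 1 to the last trial
whose *running cumulative* correct ratio is significantly below chance
(one-sided exact binomial, $\alpha = 0.01$) — the literal reading of the
stage definition. One consequence worth knowing: after a deep, long bias
stage the cumulative ratio can stay significantly below 0.5 well into a
chance-level period, so the bias boundary lags the true rate change; this is
a property of the definition, not of the implementation, and the tests
therefore check the bias boundary against its own definition while checking
the improvement boundary against the planted rate change. The improvement
stage starts after the last segment boundary whose following segment is
significantly above chance (the phase start counts as a boundary, so a
learner at 90% from trial 1 is all-improvement), and when the two
definitions overlap the bias boundary takes precedence and the improvement
onset is deferred. The three intervals always partition the record; the
coverage invariant is asserted on every segmentation.

## Actigraphy

Activity is 30-s binned counts under a 7:00–19:00 light schedule. The daily
weighted center is $\sum t_i c_i / \sum c_i$ over a midnight-anchored 24-h
window with $t_i$ the bin mid-time in hours — a linear mean, since the daily
window is fixed; a circular variant is available for phase-wrapped profiles.
Pre/post comparisons of daily centers use Mann-Whitney U. Nighttime activity
sums the 3 h after dark onset. The locomotor normalization divides the first
3 complete post-injection weekdays by the last 3 pre-injection weekdays,
weekdays by calendar day of the timestamp. The generator draws Poisson
counts from a smooth diurnal profile (raised-cosine ramps of ±1 h at the
light transitions) with a controllable phase shift; a +2 h shift over 14
days is detected as "later" at p < 0.001 essentially always.

## What the synthetic data do not show

The generators emulate structure — criterion-terminated sessions from a
plausible learner, SRTM-consistent curves on the real frame schedule,
light-entrained counts — but not everything real data contain: no
scanner-specific noise correlations or motion, no partial-volume effects, no
attenuation/reconstruction artefacts, no drift in motivation across weeks,
no inter-animal heterogeneity beyond the preset parameter sets, and
spatially independent voxel noise rather than the smooth correlated fields
of reconstructed PET. Passing tests therefore establish correctness of the
computations and calibration of the statistics under the stated models, not
robustness to every artefact of real recordings. Registration and
reconstruction are out of scope; all images are assumed spatially aligned.

## Problem sizes used in the checks

The packaged checks run at deliberately modest scale, chosen to make the
Monte-Carlo error small relative to each tolerance: a 27-point noiseless
parameter grid for kinetic recovery (relative errors well under 1%), an
8×8×4 phantom with ~20-voxel ROIs and study-like noise for the −40%
percent-change recovery (±3%), 500–1000 stationary replicates at n = 200 for
change-point calibration, 200 replicates of a 20-scan stack for GLM type-I
calibration (pooled over ~29k voxel tests), 50 random logs for exact oracle
equivalence of the trial statistics, and 20 random designs for the ANOVA
cross-validation at 6 significant digits.
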