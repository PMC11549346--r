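---
title: "Predictive learning and representational geometry: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predictive learning and representational geometry: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(predgeom)
```

This vignette documents the models behind `predgeom`, the assumptions they
make, the tunable parameters that matter, and the design choices taken
where the methodology was genuinely open. It states no empirical result
that the package's tests and acceptance script do not themselves compute.

## The scientific problem

When listeners are passively exposed to a tone stream whose triplets
follow a fixed grammar, they learn the statistics of the stream without
instruction. Two linked questions drive this package's pipeline:

1. Does learning reshape the *representational geometry* — do neural
   response patterns for tones in the same triplet grow more similar than
   patterns for tones of different triplets?
2. Is the magnitude of that reshaping linked to how strongly the brain
   *encodes prediction errors*, the currency of predictive-coding
   accounts of learning?

The package implements everything needed to pose these questions to data:
stimulus construction, a normative learner supplying prediction-error
trajectories, pattern-distance analyses across learning blocks,
information-theoretic encoding and interaction analyses, and the group
statistics. A synthetic source-level generator stands in for recordings
so that every stage is testable and the full chain is exercised end to
end as a parameter-recovery exercise.

## Stimulus streams

Both streams use a 12-tone alphabet (C, D, E, F#, G#, A# of the 4th and
5th octaves, 261.63–932.33 Hz) and consist of tone triplets under hard
constraints: every tone occurs equally often (200 times in the
800-triplet, 2400-tone stimulus-scale stream), no tone repeats
back-to-back, no triplet repeats back-to-back, and the three tones of a
triplet never span more than one octave (frequency ratio at most 2).

*High regularity*: only four triplet types recur. Because 4 types × equal
token counts must yield exactly equal tone counts, the types are four
**disjoint** ordered triples covering the alphabet; `generate_sequence()`
finds them by rejection-sampling partitions under the octave constraint,
then shuffles the 200 tokens of each type and repairs
adjacent-identical-triplet violations by local swaps (which provably
cannot create tone repeats, since distinct types share no tones).

*Low regularity*: each triplet is drawn fresh. The sampler draws ordered
triples with probabilities proportional to each tone's remaining quota,
subject to the octave span, the boundary no-repeat constraint and the
no-identical-triplet constraint, restarting the stream on the rare dead
end. Quota-proportional sampling keeps counts exactly balanced at the
end.

A `variant` argument (0–2) cyclically rotates the within-triplet order of
the high-regularity types, mirroring the counterbalancing of triplet-internal
tone order across participants; all analyses are variant-agnostic.

## The ideal observer

The learner is a single-layer softmax network over the alphabet — a
categorical Rescorla–Wagner model with a dynamic learning rate. With
one-hot input $x_t$ and weights $W_t$ (initialised uniformly at $1/12$):

$$z_t = x_t W_t,\qquad \hat y_t = \mathrm{softmax}(z_t),\qquad
\mathcal L = -\textstyle\sum_i x_{t+1,i}\ln \hat y_{t,i}$$

$$\omega = -\textstyle\sum_i \hat y_{t,i}\ln \hat y_{t,i},\qquad
PE_t = \omega\, x_t^\top(\hat y_t - x_{t+1}),\qquad
W_{t+1} = W_t - PE_t$$

The learning rate $\omega$ is the Shannon entropy of the observer's own
prediction, so updates are *precision weighted*: maximal ($\ln 12$ nats)
under complete uncertainty, vanishing as predictions sharpen. The update
touches only the weight row of the active tone. Sign conventions are
chosen so that the update descends the cross-entropy loss — the only
choice under which prediction error decays on a learnable stream and the
trained weight rows, passed through the softmax, recover the empirical
transition probabilities.

**Scalarising the matrix-valued PE.** Downstream encoding analyses need
one number per transition. Two scalarisations are implemented:
`entropy_weighted_norm` (default), $\omega\,\lVert\hat y_t -
x_{t+1}\rVert_2$, the exact L2 norm of the update; and
`entropy_weighted_surprise`, $\omega\,(-\ln \hat y_t[x_{t+1}])$. The
norm form is the default because it equals the magnitude of the actual
weight change — the quantity the learning rule itself manipulates. The
choice is recorded in every trace object. The decay-model BICs reported
by `scripts/acceptance.R` inherit this choice; their magnitudes (though
not their ordering or sign) depend on it, and on any smoothing applied
before fitting, which is why only the exponential-beats-linear ordering
is treated as the hard criterion in the tests.

**Decay-model comparison.** `fit_decay_models()` fits
$y = a e^{-bx} + c$ by Levenberg–Marquardt nonlinear least squares with
100 random restarts (unbounded parameters; restarts drawn around the
trajectory's scale with log-uniform rates) against a straight line, and
compares them with the Gaussian-likelihood BIC
$n\ln(\mathrm{RSS}/n) + k\ln n$, $k = 3$ vs $2$; the $\sigma$ term
cancels in the comparison.

## Synthetic source-level data

`generate_epochs()` produces trials × 72 parcels × 77 samples arrays
(−50…330 ms at 200 Hz — the window covers both the pre-tone baseline and
all analysis windows). The generative model per trial:

- **Evoked kernel**: a Gaussian bump centred at 100 ms (sd 20 ms), the
  latency scale of auditory evoked fields.
- **Tone patterns**: a fixed 12 × 72 Gaussian pattern matrix (amplitude
  `pattern_snr`, default 0.8 relative to unit noise) rides on a
  tone-independent evoked component (`evoked_amp`, default 1). The common
  component matters: a *gain* modulation of a zero-mean pattern would
  carry almost no linear information about the modulator across mixed
  tones, whereas real evoked responses have a mean field.
- **Learning morph**: inside a 110–130 ms band, each tone's pattern is
  pulled toward its triplet's mean pattern with coefficient growing
  linearly 0 → `gamma_max` (default 0.6) across the 5 blocks, only in the
  high-regularity condition. This plants the within-triplet convergence
  at the latency where the geometry analyses look for it.
- **PE gain**: in an encoder patch (a designated parcel plus its 5
  spatial nearest neighbours — one searchlight's extent; default centre
  parcel 41), response amplitude is multiplied by
  $1 + \beta\, z(\mathrm{pe})$ (`beta_pe`, default 0.6). The coupling is
  sized against the intrinsic information floor (see the GCMI caveat
  below) so that the planted patch is reliably the searchlight map
  maximum at the desk-scale group size; weaker couplings remain
  detectable but not reliably localisable to the exact parcel.
- **Synergy pair**: parcel $i$ carries $\mathrm{shared} + c\, z(\mathrm{pe})$
  and parcel $j$ carries $\mathrm{shared}$, kernel-gated (defaults
  $i=20$, $j=56$ — homotopic parcels far from the encoder patch;
  `shared_sd` 4, coupling 1). Each parcel alone is dominated by the
  shared masking noise; their difference reveals the prediction error —
  the textbook synergy construction. The masking amplitude is deliberately
  much larger than the coupling so that individual-parcel information stays
  small while joint information is large.
- **Noise**: Gaussian with exponential spatial covariance over centroid
  distance (scale 30 units on a ~140-unit head), optional AR(1) in time
  (off by default — the copula estimators assume exchangeable trials, and
  trial order is already non-exchangeable through the PE trajectory).

The epoch of tone $t$ is tagged with the prediction error *elicited by*
tone $t$ (the transition $t-1 \to t$); the first epoch has no error and
is dropped by the encoding analyses.

What the generator does **not** emulate: 1/f spectra, evoked-latency
variability, subject-level anatomy differences, non-Gaussian artifacts.
Passing tests therefore demonstrate that the estimators and their
plumbing are correct and that planted effects of realistic geometry are
recoverable — not that effects of the reported size exist in real
recordings.

## Crossnobis RSA

For each learning block (5 contiguous, equal partitions of the stream)
and time point, `cvmd_rdm()` estimates the squared Mahalanobis distance
between tone patterns with independent train/test folds:

$$d_{ab} = (\mu_a^{tr} - \mu_b^{tr})^\top \hat\Sigma^{-1}
(\mu_a^{te} - \mu_b^{te})$$

averaged over 10 folds. Cross-validation makes the estimator unbiased
under the null — distances fluctuate around zero and may be negative —
which is what allows block slopes to be interpreted. $\hat\Sigma$ is the
Ledoit–Wolf-shrunk covariance of the training residuals (trial minus its
tone mean), pooled across all 12 tones: with 72 features and a few
hundred trials per block, the analytic shrinkage toward a scaled identity
keeps the whitening well conditioned. The shrinkage implementation is
validated against an independent reference implementation on a frozen
fixture.

Design choices worth stating:

- Folds are stratified by tone using contiguous chunks in trial order, so
  that each fold spans a similar stage of learning.
- When a per-block tone count falls below the requested fold count (an
  issue only at reduced demo scales), the fold count is lowered to the
  sparsest cell with a warning rather than failing.
- RDMs are reordered so tones appear triplet by triplet; *within* is the
  mean of the six same-triplet pairs, *between* the mean of all
  cross-triplet pairs; exact self-pairs are excluded (their crossnobis
  value is 0 by construction and carries no geometry).
- The model-based fit is the Spearman correlation with a 0/1 RDM (zeros
  within triplets), over the upper triangle.
- Learning slopes are OLS slopes of each summary against block index
  1…5.
- The searchlight uses each parcel plus its 5 spatial nearest neighbours,
  averaging data across the 110–120 ms window (samples at 110, 115,
  120 ms on the 5 ms grid) before computing distances.
- Covariance is estimated per time point (per window average in
  searchlight mode), not pooled over time.

## Gaussian-copula mutual information

Each variable is transformed to a standard-normal marginal by the
rank-based inverse normal transform $\Phi^{-1}(r/(n+1))$ (average ranks
for ties; the $n+1$ denominator keeps quantiles finite), after which
mutual information is evaluated in closed form:

$$\mathrm{MI}(X;Y) = \frac{1}{2\ln 2}\,
\ln\frac{|\Sigma_X|\,|\Sigma_Y|}{|\Sigma_{XY}|}\ \text{bits.}$$

The estimate is invariant to any strictly increasing marginal transform
and is a robust lower bound on the true MI. No small-sample bias
correction is applied; instead all reported values are baseline-corrected
by subtracting the identical computation in the −50–0 ms pre-tone window,
which also removes sequence-autocorrelation confounds. Determinants are
computed by Cholesky factorisation with a per-pivot conditioning guard
(relative floor $10^{-12}$) that raises an error on effectively singular
joint covariances (e.g. duplicated features) rather than silently
clipping.

One caveat the tests make visible: because tone identity predicts the
prediction error (triplet-initial tones are the uncertain ones), any
parcel carrying tone-specific patterns shows nonzero MI with the PE
trajectory through that channel alone. This is a property of the design,
not a bug; the planted encoder patch is detected *above* this common
floor, and localisation is asserted at the group level where the floor
averages flat.

## Partial information decomposition

For parcel pairs $(X_1, X_2)$ and the PE trajectory $Y$:

$$\mathrm{JMI}(X_1,X_2;Y) = R + U_{X_1} + U_{X_2} + S$$

On the Gaussian copula, redundancy is the minimal-MI functional
$R = \min(\mathrm{MI}(X_1;Y), \mathrm{MI}(X_2;Y))$ — for univariate
Gaussian sources this coincides with the Williams–Beer minimum
intersection information — and the remaining atoms follow by
subtraction, so the accounting identity holds exactly by construction.
The discrete Williams–Beer $I_{\min}$ (specific-information form) is
implemented separately on finite probability tables and serves as the
exact oracle in the tests (XOR: $S = 1$ bit, $R = 0$; copy cases;
ordering agreement with the Gaussian redundancy on discretised Gaussian
triples). For exactly duplicated sources the joint covariance is
singular; the implementation returns the analytic limit
$\mathrm{JMI} = \max(\mathrm{MI}_1, \mathrm{MI}_2)$.

`pid_network()` computes all $\binom{72}{2}$ pairs per 5 ms sample in the
90–120 ms window from a single (parcels + PE) covariance per sample —
every pairwise atom is closed-form algebra on that matrix — averages over
the window, and subtracts the same computation over the baseline window
atom-wise. Negative baseline-corrected weights are clipped to zero before
betweenness centrality (path lengths need positive weights; edge length =
1/weight, normalised counts); the raw matrices are preserved. Node
strength (mean edge weight per node) is reported alongside betweenness,
as the two summarise hubness differently and the choice between them is a
genuine methodological fork.

## Group statistics

- **Cluster-based permutation**: element-wise paired $t$, cluster-forming
  threshold at the parametric two-tailed $\alpha = 0.05$ critical value
  (df = subjects − 1), clusters by adjacency separately for positive and
  negative effects, maxsum statistic, null distribution of the maximum
  absolute cluster sum under random sign flips of the paired differences;
  $p = (1 + \#\{\text{null} \ge \text{obs}\})/(1 + n_{perm})$. Temporal
  adjacency links consecutive samples; spatial adjacency links parcels
  within the 10th percentile of centroid distances (the neighbourhood
  radius is a config parameter, as any quantification of "proximity" is a
  choice).
- **NBS**: edge-wise paired $t$ thresholded at a configurable edge
  $\alpha$ (default 0.05 two-tailed), connected components of
  suprathreshold edges, component *size* (edge count) as the statistic,
  sign-flip null of the maximum component size.
- **Correlations**: right-tailed Pearson with Bonferroni multiplication.
- Sign-flip permutations sample 10 000 of the $2^n$ assignments with
  replacement by default; all permutation functions take a seed and are
  exactly reproducible.

Both permutation procedures are calibrated in the test suite: family-wise
rejection rates over 200 null replicates (1000 permutations each) must
fall inside the binomial 95% interval around 0.05.

## The study pipeline and its scales

`run_study()` composes everything: both streams, observer traces, per
virtual subject and condition the epoch generation, whole-brain and
searchlight RSA, searchlight GCMI, PID network.
The parcellation is a fixed template shared by every study (as a real
atlas would be); study seeds vary the sequences, the noise and the
virtual subjects, never the anatomy. Encoder localisation is asserted at
the level of the planted patch: all six patch parcels carry the gain, so
which of them hosts the group map maximum varies with noise at
searchlight resolution, while the maximum staying inside the patch is
the reproducible property. It then computes group contrasts
(high vs low within-triplet and model-RSA block slopes), the group
searchlight GCMI peak, the group synergy matrix, and the across-subject
correlations between the representational shift and (a) encoding
strength, (b) synergy betweenness centrality.

The "representational shift" scalar is the cluster-averaged model-RSA
block slope in the 110–120 ms window (high-regularity condition), the
cluster being the contiguous parcels surpassing the uncorrected
first-step threshold of the cluster test — with the negative
within-triplet slope available as an alternative definition via
`shift_metric`, since the scalar entering such correlations is not
uniquely determined by the method description and both readings are
defensible.

Problem sizes: the test suite runs the full recovery study at 400
triplets (1200 tones) × 8 virtual subjects with 1000 permutations, and
unit tests use 240-triplet fixtures — sizes chosen so the planted effects
are comfortably detectable while a complete run stays in the minutes
range on one core. The stimulus-scale configuration (800 triplets, 24
subjects, 10 000 permutations) is the package default elsewhere and runs
unchanged, just longer.

## Known limitations

- The Gaussian-copula estimators capture monotone dependence only;
  non-monotone encodings would need different estimators.
- Minimal-MI redundancy cannot be negative and never exceeds either
  single-source MI; more refined PID measures (e.g. pointwise or
  broadcast redundancies) are out of scope.
- The synthetic generator's noise is Gaussian and temporally white by
  default; its purpose is estimator validation and parameter recovery,
  not biophysical realism.
- Betweenness centrality on dense information networks depends on the
  clipping floor for weak edges; node strength is reported alongside as a
  robustness companion.
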