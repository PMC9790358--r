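---
title: "Models and methods behind predinfer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind predinfer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(predinfer)
```

# The task and its generative model

The predictive-inference ("coin and bucket") task asks a participant to
place a bucket on a 360-position ring to catch a coin. The coin's landing
angle $X_t$ is Gaussian around a latent mean $\mu_t$ (noise SD
$\sigma_N$, default 12°), and $\mu_t$ is resampled uniformly over the 360
integer ring positions with per-trial hazard $H = 0.125$ — a change
point. A session has 4 blocks of 75 trials; the first trial of a block
always draws a fresh mean. A coin landing within the bucket's half-width
(default 20°, inclusive) scores +10 points, otherwise −10. After placing
the bucket the participant rates confidence on a 1–100 scale.

All angular arithmetic is circular: the signed difference
`circ_diff(a, b)` lives in $(-180, 180]$, and outcomes are wrapped
Gaussians (a plain Gaussian draw taken mod 360, which is
indistinguishable from a wrapped normal at $\sigma_N \ll 360$). A linear
(non-wrapping) mode is available via configuration for comparison with
legacy analyses that treated the scale as a line; circular is the
default because the stimulus ring is physically circular.

Parameters not fixed by the task description — the outcome noise SD and
bucket half-width — default to 12° and 20°, the values used in the adult
lineage of this task, and are exposed in `task_config()`. Change points
are i.i.d. Bernoulli per trial, with no minimum separation and no
constraint that a new mean differ from the old one: the task defines
only a per-trial probability, and imposing extra structure would change
the hazard the observer should assume.

# The reduced Bayesian observer

Full Bayesian filtering under change points requires a run-length
distribution; the quasi-optimal *reduced* observer instead tracks a
single belief $B_t$ with variance $\sigma^2_{\mu,t}$ and two summary
quantities:

* **Change-point probability (CPP, $\Omega_t$)** — the posterior
  probability that outcome $X_t$ came from a freshly resampled mean:
  $$\Omega_t = \frac{H/360}{H/360 + (1-H)\,
  \mathcal{N}(\delta_t;\,0,\ \sigma_N^2 + \sigma^2_{\mu,t})},$$
  with $\delta_t = \mathrm{circ\_diff}(X_t, B_t)$ the prediction error.
* **Relative uncertainty (RU, $\tau_t$)** — belief uncertainty as a
  fraction of total predictive variance:
  $\tau_t = \sigma^2_{\mu,t} / (\sigma^2_{\mu,t} + \sigma_N^2)$.

The learning rate is $\alpha_t = \Omega_t + (1-\Omega_t)\tau_t$: fully
reset when a change point is certain, otherwise apply the stable-regime
Kalman gain. The belief moves by $\alpha_t\delta_t$ (wrapped), and the
variance updates as
$$\sigma^2_{\mu,t+1} = \Omega_t\sigma_N^2 + (1-\Omega_t)\tau_t\sigma_N^2
 + \Omega_t(1-\Omega_t)\bigl(\delta_t(1-\tau_t)\bigr)^2,$$
a mixture of the reset regime, the filtered stable regime, and the
variance contributed by ambiguity between them. With $\Omega_t = 0$ this
is exact conjugate-Gaussian filtering — after $t$ stable trials the
belief variance is $\sigma_N^2/t$, which the test suite verifies against
a dense-grid full-Bayes oracle. Full run-length filtering exists in this
package only as that test oracle, never as the production path.

Initialisation is uninformative: $B_1$ is the first outcome and
$\sigma^2_{\mu,1} = \sigma_N^2$. The observer is always conditioned on a
subject's outcome sequence with the *true* generative parameters
($H$, $\sigma_N$); nothing is fitted. This is the normative-reference
reading of "quasi-optimal": the model says what an ideal reduced learner
would do with the same evidence. The Gaussian density inside $\Omega$ is
evaluated at the circular distance rather than replaced by a von Mises
density; at $\sigma_N = 12°$ the two differ negligibly, and the Gaussian
keeps the conjugate algebra exact.

Model confidence defaults to $(1-\Omega_t)(1-\tau_t)$, a monotone
summary that falls when either a change point is suspected or the mean
is poorly known. Since downstream use only requires a monotone
uncertainty summary, two alternatives (`1 - alpha`, negative total
predictive variance) are selectable in `observer_config()`.

# The synthetic cohort

No participant data ship with the package; `simulate_cohort()` generates
agent cohorts so every downstream stage is testable. An agent places its
bucket, observes the outcome, updates an internal reduced observer *on
its own prediction errors*, and moves the bucket by
$\alpha_{\mathrm{eff}}\,\delta_t$ plus motor noise. Policies:

* `observer_coupled`: $\alpha_{\mathrm{eff}} = g\,\alpha_t$ (gain $g$);
* `fixed_alpha`: constant $\alpha_{\mathrm{eff}}$;
* `smallpe_boosted`: observer-coupled plus an additive boost when
  $|\delta_t| <$ 10° — the "excessive updating after small errors"
  phenotype.

Motor noise is signal-dependent — SD $= 0.5 + 0.15\,|$update$|$ degrees —
reflecting that large dial movements are less precise than small ones.
A constant noise floor alone would be unrealistic at small prediction
errors: dividing a fixed-magnitude placement error by a tiny $|\delta|$
manufactures enormous spurious learning rates, far beyond what the
upper-tail trimming can absorb. Confidence reports are an affine map of
model confidence (offset 10, gain 80) plus Gaussian rating noise (SD
10), rounded and clamped to 1–100. Agents start each block with the
bucket on the block's first outcome, mirroring the observer's
initialisation; the first trial's prediction error is therefore zero and
is excluded downstream anyway.

The preset cohort is 46 controls and 27 patients (split 16 unmedicated /
11 medicated in the three-group variant). Controls are pure
observer-coupled ($g = 1$); patient presets add a small-PE boost (0.6;
0.8 unmedicated, 0.15 medicated). All groups share the same confidence
policy, making confidence a true null between groups. Each subject also
gets a simulated trait-anxiety score (controls 40 ± 8, patients ≈ 55 ±
8–10) so the covariate-correlation stage has something to work with.
These presets target the *qualitative* group pattern (elevated overall
and small-PE learning rates in patients, equivalent confidence); the
quantitative group means of any real dataset depend on participant
behaviour the generator does not model — individual learning styles,
attention lapses, response-time structure, practice effects — so passing
the pattern checks says the pipeline detects the phenotype it should
detect, not that the generator reproduces human data.

# Trialwise measures and exclusions

Empirical learning rates follow the update/error ratio
$\alpha_t = \mathrm{circ\_diff}(b_{t+1}, b_t)/\delta_t$ with
$\delta_t = \mathrm{circ\_diff}(X_t, b_t)$. Exclusions, in order:

1. the last trial of each block (no subsequent placement);
2. trials with $\delta_t = 0$ (ratio undefined);
3. trials whose $\alpha_t$ strictly exceeds the 95th percentile of all
   retained learning rates pooled across subjects *within each group*.

Only the upper tail is trimmed; negative learning rates are retained.
The percentile pools trials within a group (rather than per subject)
because the threshold is defined per group; both the thresholds and the
exclusion proportions are reported, and the pipeline tests the
proportion removed between groups with a two-sample t test.

Confidence is z-scored within subject (sample SD, $n-1$), which removes
baseline differences; a constant confidence stream is an error rather
than a silent zero. Retained trials are binned into
prediction-error-magnitude tertiles. Tertile edges are computed per
subject by default — group-level bin means are then averages of
subject-level values, matching how the group comparisons are built — with
a pooled-edge mode behind a flag. All quantiles use linear interpolation
between order statistics (R's type 7), fixed and documented so results
are bit-reproducible; ties at an edge go to the lower bin.

# The three regressions

Per subject, ordinary least squares with an intercept throughout:

* **Action**: response $\alpha_t|\delta_t|$ (the update projected on the
  error direction); predictors $|\delta_t|$, $\Omega_t|\delta_t|$,
  $\tau_t|\delta_t|$, $\mathrm{hit}_t|\delta_t|$. Block-final and
  zero-PE trials drop out.
* **Confidence**: response $z_t$ (not scaled by $|\delta|$); predictors
  are the *previous* trial's $|\delta|$, $\Omega$, $\tau$ and hit; first
  trial of each block drops out.
* **Coupling**: response $|\mathrm{circ\_diff}(b_t, b_{t-1})|$, single
  predictor $|z_t - z_{t-1}|$; the slope is the action–confidence
  association strength.

Hit/miss is coded 1/0 and predictors are not standardised: betas are
compared across groups on a common construction, so rescaling would only
obscure them. Collinearity between $|\delta|$ and $\Omega|\delta|$ is
tolerated unless the design is numerically rank-deficient, in which case
the fit errors naming the offending columns. The low-PE-only refit runs
the same operations on the small-tertile subset, with one forced change:
small prediction errors always land inside the 20° bucket, so the hit
column is constant there and is dropped (`include_hit = FALSE`).

Goodness of fit is summarised by the median R² across subjects per
group. On realistic noisy agents the action model fits well while the
confidence model fits poorly — the same qualitative gap seen in human
data — because trial-level confidence carries rating noise that the
previous trial's model quantities cannot explain.

# Group statistics

`compare_groups()` implements the routing contract used throughout:
Shapiro–Wilk per group and Levene's test (both at $\alpha = 0.05$)
route to Student t, Welch t, or Wilcoxon rank-sum; the decision is
recorded in the result so analyses are auditable. Effect sizes follow
the test family: Cohen's $d = |t|\sqrt{1/n_1 + 1/n_2}$ for t tests,
Wilcoxon $r = |Z|/\sqrt{N}$ for rank tests with $N$ the total
observations entering the test. The rank-sum $Z$ uses midranks and the
tie-corrected normal approximation without continuity correction.

Learning rates across group × tertile are tested with the Welch–James
approximate-degrees-of-freedom test (Johansen's formulation, untrimmed
means), implemented here because no installed package provides it: each
group contributes its own mean vector and covariance, making the test
robust to the variance heterogeneity that learning-rate data show. It
reduces exactly to Welch's t in the two-group one-measure case, which
the tests verify to $10^{-8}$, and its type-I error is checked by
simulation under a variance-ratio-16 null. Confidence across group ×
tertile uses the classical mixed ANOVA with the Huynh–Feldt sphericity
correction (delegated to `car::Anova`; epsilon reported capped at 1, and
identically 1 for a two-level within factor). The three-group medication
battery refilters learning rates with three-group percentiles, then runs
Kruskal–Wallis with tie correction and Bonferroni-multiplied pairwise
rank-sum post-hocs. All post-hoc corrections are Bonferroni; betas are
compared uncorrected, matching the reporting style the pipeline mirrors,
and each test result carries its correction field.

# Numerical and design notes

* **Determinism**: a single seed drives everything; per-subject seeds
  are drawn deterministically from the master seed, so cohorts, reports
  and tables are bit-reproducible.
* **Antipode convention**: `circ_diff` returns +180 for both orders at
  the exact antipode (half-open interval); this is measure-zero for
  continuous data.
* **Degenerate inputs**: zero-variance confidence, all-tied rank tests,
  empty groups, missing within-factor cells, and singular Welch–James
  covariances are errors, not silent NAs.
* **Problem sizes**: the test suite runs its simulations at reduced but
  adequate scale — e.g. 100 subjects for parameter recovery, 1,000
  replicates for type-I calibration, 20 study-sized cohorts for the
  end-to-end pattern check — sizes at which the Monte-Carlo error is
  comfortably below the tolerances being asserted.

# Known limitations

The generator does not model response times, within-block learning,
attention lapses, or any fitting of agent parameters to real data. The
observer's uncertainty update is the reduced-Bayesian form given above;
other reduced variants exist, and on real data the choice can matter at
the margins even though all share the $\Omega$/$\tau$ structure. The
medication analysis is exploratory by construction: the three-group
presets encode an assumed effect profile, not an estimate of one.
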