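---
title: "Modelling effort-based decisions and their neurometabolic correlates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling effort-based decisions and their neurometabolic correlates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(effortpath)
```

## The scientific problem

People differ widely in how willing they are to invest physical or mental
effort for a reward. One candidate source of this variability is metabolic:
lactate — produced by muscle during exertion and by astrocytes in the brain,
and able to cross the blood-brain barrier — may act as a signal of energy
cost in the very cortical regions (dorsomedial prefrontal / dorsal anterior
cingulate cortex, dmPFC/dACC) that arbitrate whether an effortful action is
worth taking. Testing that idea requires an analysis chain that runs from
trial-level choice behaviour (a computational model of effort discounting),
through per-subject parameter estimation, up to inter-individual
correlation, mediation and path analysis connecting plasma lactate, regional
brain lactate, neural effort sensitivity and choice behaviour.

`effortpath` implements that whole chain on synthetic data, so every stage —
from the factorial task design to the serial path model — is executable,
testable and reproducible from a single seed, without any access to the
original cohort.

## The task

The task is a binary effort-discounting design. Each trial opposes a fixed
low option (incentive level 0, effort level 0) to a high option whose
incentive level (1–3, crossed with reward/punishment valence) and effort
level (1–3) vary independently. Each block fully crosses
2 valences × 3 incentive × 3 effort levels × 3 repetitions = 54 trials, and
a session holds four blocks, strictly alternating between physical effort
(handgrip squeezes at 55% of maximal force, 0.5–4.5 s) and mental effort
(2-back responses within 10 s), for 216 trials in total. Counting the low
option's level 0 once per valence, the incentive design has 8 levels
(4 rewards, 4 punishments) and each effort domain 4 levels. This "levels
plus a fixed level-0 reference" reading is the only small factorial
consistent with 54 trials per block, which is why `task_config()` adopts it;
monetary magnitudes beyond the 0.5 currency-unit low option are deliberately
abstract level codes, since per-subject calibration of amounts is outside
the package's scope.

The high-effort option's screen side is exactly counterbalanced (27 left /
27 right per block) and trial order is a seeded uniform permutation, so
reward and punishment trials interleave without a dedicated scheduling
algorithm.

## The choice model

For a trial with incentive difference $\Delta R$ and effort difference
$\Delta E$ (level codes), the subjective value difference between the high-
and low-effort options is

$$
\Delta SV = k_{bias}
 + \begin{cases} k_R \,\Delta R & \text{reward} \\
                 k_P \,\Delta R & \text{punishment} \end{cases}
 - \begin{cases} (k_{Ep} + k_{Fp} F)\,\Delta E & \text{physical} \\
                 \max(k_{Em} - k_{Lm} L,\, 0)\,\Delta E & \text{mental,}
   \end{cases}
$$

and the high-effort option is chosen with probability
$P(HE) = 1/(1+e^{-\Delta SV})$. The temperature is fixed at 1 — the
sensitivities absorb the scale — and there is no lapse rate.

Two internal states make the model dynamic within a block:

* **Physical fatigue** $F$ accrues only from exerted effort,
  $F \leftarrow F + E_{ch}/E_{max}$, so declining the high option leaves
  fatigue untouched and the fatigue term inflates the physical effort cost.
* **Mental learning** $L$ accrues per completed mental trial,
  $L \leftarrow L + 1/n_{trials}$, deflating the mental effort cost; the
  cost is clamped at zero so extreme $k_{Lm} L$ cannot turn effort into a
  benefit.

Both states reset at block boundaries, because maximal-performance
re-measurements bracket every block. The functional form and state
normalisations are design choices of this package: the structural roles
(fatigue inflates physical cost; practice deflates mental cost) are what
matters for the downstream statistics, and alternatives (e.g. multiplicative
fatigue) would serve the same role.

The chosen-option value `SVch` uses the low option as a zero benchmark, so
`SVch` equals $\Delta SV$ on high-effort choices and 0 otherwise. Trials
with no response are representable through a `missed` flag: they default to
the low option and are excluded from likelihoods and modulators.
Deliberation times follow a log-normal model,
$DT = \exp(b_0 - b_1 |\Delta SV| + \sigma \varepsilon)$, with defaults
$b_0 = 0.4$ (median ≈ 1.5 s at indifference), $b_1 = 0.15$, $\sigma = 0.25$
— choices near indifference take longer, which is what the DT regressors
downstream are meant to pick up.

### Default parameter values

The package-level defaults (`model_params()`) were calibrated once, at
design time, so that a cohort simulated under the default sampler reproduces
the task's observed aggregate behaviour — a preference for the high-effort
option near 58% in the physical domain and near 75% in the mental domain —
and were then frozen:

| parameter | default | role |
|---|---|---|
| `kR`, `kP` | 1, 1 | incentive sensitivities per level code |
| `kEp` | 0.7 | physical effort cost per level |
| `kEm` | 0.6 | mental effort cost per level |
| `kFp` | 0.02 | fatigue gain; over a 54-trial block cumulative fatigue reaches ~10–20 normalised units, so 0.02 yields a moderate (~20–40%) end-of-block inflation of the physical cost |
| `kLm` | 0.3 | learning gain; mental cost shrinks by up to 0.3 over a block |
| `kBias` | 0.3 | mild bias toward the high-effort option |

The recovery sampler (`default_param_sampler()`) draws log-normal
sensitivities around these values (log-SD 0.4; 0.5 for the slower
fatigue/learning gains) and a Gaussian bias (SD 1).

## Model inversion

Each subject is fitted by maximum a posteriori estimation on a transformed
scale — $\theta = \log k$ for the six non-negative sensitivities, identity
for the bias — with independent $\mathcal{N}(0,1)$ priors on each
coordinate. The objective is minimised by BFGS from five seeded starting
points (ties broken toward the smaller parameter norm; objective
convergence tolerance `reltol = 1e-10`), and model evidence is approximated
by the Laplace integral at the mode,
$\log p(y) \approx -NLP(\hat\theta) + \tfrac d2 \log 2\pi -
\tfrac 12 \log |H|$, with the Hessian obtained numerically. A
near-singular Hessian flags the evidence as unreliable rather than failing
the fit. MAP with a Laplace evidence stands in for a full variational
scheme; the downstream inter-individual statistics only consume per-subject
point estimates, which MAP supplies directly.

Physical and mental parameters are fitted jointly on the whole session:
`kR`, `kP` and `kBias` are shared across domains, which is the reading
implied by a single seven-parameter vector. The fatigue/learning
trajectories entering the likelihood are reconstructed deterministically
from the observed chosen efforts (`accumulate_states()`), so they are data,
not latent variables.

Recovery simulations (`parameter_recovery()`) simulate cohorts of subjects
from the sampler, refit each, and report true-vs-recovered correlations,
bias and RMSE on the transformed scale, plus the confusion matrix of
recovered parameters. At the task's 216 trials the incentive and effort
sensitivities recover with correlations well above 0.7; the two dynamic
gains (`kFp`, `kLm`) are only weakly identified at these trial counts —
their likelihood contribution is small and the standard-normal prior on
$\log k$ shrinks them toward 1 — which is itself a finding the report makes
visible rather than hiding.

## The synthetic cohort

`generate_cohort()` draws standardised latent variables along the
hypothesised causal chain

$$
\text{plasma lactate} \xrightarrow{0.314} \text{dmPFC/dACC lactate}
\xrightarrow{0.317} \log k_{Ep} \xrightarrow{0.403}
\text{neural effort sensitivity (Ech estimate)},
$$

each child being $r \cdot \text{parent} + \sqrt{1-r^2}\,\varepsilon$ so all
nodes stay standardised. The three default path coefficients are the
targeted inter-individual correlations; the association between dmPFC/dACC
lactate and high-physical-effort choices (about −0.33 in the targeted
structure) is *not* drawn — it must emerge through the chain and through
task simulation, because each subject's choice proportions are computed
from their own simulated 216-trial session. This keeps mediation tests at
the proportion level non-circular: nothing ever writes the outcome variable
directly from the latent chain. A consequence worth knowing is that the
realised lactate–behaviour correlation is attenuated relative to a direct
draw (the chain multiplies $0.317$ by the simulation-induced
$r(k_{Ep}, HPE) \approx -0.5$ to $-0.6$), so study-sized cohorts (n = 63)
often do not reach significance on that edge — an honest property of the
generative design, visible in the pipeline report.

The anterior insula analogue couples to dmPFC/dACC lactate at the trend
level (0.236) and carries no behavioural path of its own, encoding the
regional specificity hypothesis as the generator's null. Only `kEp` is
coupled to the lactate chain; all other behavioural parameters are drawn
independently. Lactate is in arbitrary standardised units — absolute
(mM-scale) quantification is not emulated. Missingness is injected
per-subject at rates 1/63 (plasma), 2/63 (dmPFC/dACC) and 18/63 (aIns),
matching the varying analysis Ns downstream.

What the generator does *not* emulate: measurement noise with realistic
spectroscopy error structure, non-Gaussian tails of metabolite
distributions, block-order or session-time effects, and any direct coupling
between lactate and fatigue dynamics. Tests passing on this cohort
therefore demonstrate the correctness and calibration of the analysis
chain, not the truth of the scientific claim on real data.

## Between-subject statistics

* **Outlier rule.** A subject enters an analysis only if every variable in
  that analysis lies within 3 sample SDs of that variable's median
  (`outlier_filter()`). The SD is computed about the mean on the full
  non-missing sample — the conventional sample SD — while the centring uses
  the median; the rule is applied per analysis, so Ns vary across analyses.
* **Block exclusion.** Blocks where one option was chosen on strictly more
  than 94% of trials are removed (51/54 is out, 50/54 stays).
* **Subject exclusion.** Subjects choosing the high-effort option on
  strictly more than 95% of a task's pooled 108 trials are removed (103
  out, 102 in). The rule is implemented pooled over the task's two blocks
  and literally high-effort-specific, as stated.
* **Steiger test.** Two dependent overlapping correlations are compared
  with the pooled-correlation modified Z (Fisher z difference scaled by the
  asymptotic covariance evaluated at $\bar r = (r_{12}+r_{13})/2$). The
  one-tailed direction must be supplied explicitly — there is no default,
  because the directional hypothesis belongs to the caller. Since printed
  correlations typically come from different per-analysis subsets, the
  package exposes both a printed-r entry point (`steiger_test()`) and a
  subset-recomputing one (`steiger_from_data()`), which restricts to
  complete, non-outlier cases on all three variables first.
* **Heatmaps.** `correlation_heatmap()` stars p-values at exactly
  {0.05, 0.01, 0.001}, uncorrected: multiplicity correction across the
  heatmap is intentionally out of scope.

## Mediation and path analysis

`simple_mediation()` standardises all three variables and reports the four
classic paths: `a` (X→M), `b` (M→Y given X), `c` (total) and `c'` (direct).
The mediation p-value is defined as the joint-significance value
$\max(p_a, p_b)$ — the explicit decision rule — and the verdict also
requires $|c'| < |c|$, on absolute values because mediated paths can be
negative. On standardised complete data $c = c' + ab$ holds to numerical
precision, and the suite verifies it at $10^{-10}$. A percentile bootstrap
of $a\cdot b$ (`bootstrap_indirect()`) is provided as a clearly separate
robustness companion; note that its CI is for the *standardised* indirect
effect, whose sampling variance does not vanish as residual noise goes to
zero (x and m become collinear), so "less noise" does not imply "narrower
CI" — larger samples do.

`serial_path_model()` estimates the chain X1→X2→X3→Y as the recursive
system X2~X1, X3~X1+X2, Y~X1+X2+X3 on standardised data. For a
just-identified recursive model this sequential least-squares estimator is
exactly the maximum-likelihood path solution, so no latent-variable SEM
machinery is used; $R^2$ is reported per endogenous node. A perfectly
deterministic chain makes the later regressions rank-deficient and is
rejected with an explicit error rather than returning arbitrary aliased
coefficients.

Calibration of the joint-significance rule is part of the acceptance suite:
under $b = 0$ nulls (with a real $a$ path) the rule fires at or below the
nominal rate — it is conservative, since it additionally requires
$|c'|<|c|$ — and under a strong chain (standardised links of 0.6,
n = 200) it fires essentially always. At moderate links (~0.45) its power
is intrinsically limited to ~95% by the $|c'|<|c|$ clause, because complete
mediation leaves $c' \approx 0$ while a small-sample total path
occasionally drops below it.

## Voxel masks and spectroscopy quality control

Masks are plain 3-D logical arrays on a common, pre-aligned grid
(registration and resampling are out of scope; NIfTI I/O is provided for
convenience). `density_map()` gives the per-voxel fraction of subjects
covering each location; `threshold_density(cutoff = 0.9)` keeps voxels
sampled in *at least* 90% of subjects (inclusive boundary), and
`overlap_stats()` reports mutual overlap percentages, checked against
brute-force voxel counting in the tests. `roi_mean()` extracts the mean
activity inside a subject's spectroscopy mask.

Spectroscopy quality control excludes estimates with Cramér–Rao lower
bounds strictly above 50% and corrects survivors for the CSF fraction by
rescaling to tissue water,
$c_{corr} = c_{raw}\,(f_{GM} w_{GM} + f_{WM} w_{WM} + f_{CSF} w_{CSF}) /
(f_{GM} w_{GM} + f_{WM} w_{WM})$, with water concentrations 43,300 (GM),
35,880 (WM) and 55,556 (CSF) mM. This is the simplest correction consistent
with those three constants — zero CSF is the identity, and the correction
grows monotonically with the CSF fraction; relaxation-attenuation terms of
full water-scaling schemes are intentionally not modelled, and the water
constants are arguments so the convention is swappable.

## The pipeline and reproducibility

`run_pipeline()` chains everything: cohort generation, the two behavioural
exclusion rules, per-subject MAP refits (the refitted `kEp_hat`/`kEm_hat`
enter the statistics, as they would with real data — never the generating
values), the per-analysis-filtered correlation table, the two mediations
and the serial path model. One master seed spawns per-stage substreams, so
two runs with the same configuration are byte-identical; every excluded
subject or block is attributed to a named rule, and every reported N equals
the corresponding filtered row count.

### Problem sizes

The shipped tests and the acceptance script run at sizes chosen to make the
statistical checks informative while remaining comfortable on a single CPU:
recovery at 50 simulated subjects × 216 trials (plus a 432-trial doubling
for the error-shrinkage check), rule calibration at 1000 replicates of
n = 200, generator fidelity at n = 5000 subjects without session
simulation, and the study-scale pipeline at the cohort's n = 63 with
sessions. At these sizes the generator-fidelity tolerance of ±0.03 on a
correlation is roughly a 2-standard-error band.

## Known limitations

* The value-equation's exact functional form (additive fatigue on the
  physical cost slope, linear learning on the mental cost slope, level-code
  incentives) is one defensible instantiation of the stated parameter
  roles; conclusions that depend on the precise form rather than the roles
  should be checked against alternatives.
* `kFp` and `kLm` are weakly identified at 216 trials; their recovered
  values are prior-dominated and should not be interpreted individually.
* The mediation machinery is deliberately minimal: no latent variables, no
  fit indices, no multi-group models, no multiplicity correction across
  heatmaps.
* The generator's inter-individual structure is Gaussian and linear; it
  reproduces targeted correlations, not distributional shape, and the
  lactate-to-behaviour edge is attenuated by construction (see above).
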