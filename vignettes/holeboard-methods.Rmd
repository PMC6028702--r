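---
title: "Scoring and analyzing spatial holeboard cognition data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring and analyzing spatial holeboard cognition data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The task and its measures

The spatial holeboard is a free-choice foraging maze: a square arena with 16
covered food bowls ("holes") in a 4 x 4 matrix, four of which are baited.
An animal enters through one of four doors (randomized per trial, so it must
orient by extra-maze cues rather than a fixed turn sequence) and forages
until it has found all rewards or 7.5 minutes (450 s) have passed. Because a
baited hole pays off only on the first visit, the visit sequence separates
two memory systems:

* **Working memory (WM)** — within-trial memory for already-visited
  locations: rewarded visits / all visits (including revisits) to baited
  holes.
* **Reference memory (RM)** — across-trial memory for which locations are
  ever baited: baited-hole visits / all visits. RM decomposes into a
  **rotational** component (1 / number of visits up to and including the
  first rewarded visit: orientation after entry) and a **spatial-pattern**
  component (RM over the suffix from the first reward: completing the
  learned pattern).

Seven further variables — trial duration, latency to first visit, latency to
first reward, inter-visit interval, total visits, locations visited, rewards
found — index motivation and exploration. Latencies for actions that never
happened are censored at 450 s. Trials with no rewarded visit leave the
rotational and pattern components undefined (`NA`), not zero: assigning zero
would conflate failure to orient with failure to participate, and the
undefined trials are simply absent from block means.

Raw data are ball-lift sensor events. The sensor refires when an animal
nudges the ball repeatedly, so lifts are debounced: a same-hole lift within
10 s with no other hole visited in between extends the current visit (the
window is closed on the left, open on the right — a lift at exactly 10 s is
a revisit). Each lift is compared with the immediately preceding lift, which
makes the operation idempotent and order-preserving.

## Phases, blocks, criterion

Training has four phases: habituation (4 trials, all 16 holes baited),
acquisition, and two reversals in which the animal is switched to a new
configuration (the four configurations A-D rotate across phases in four
fixed combinations). With two trials per training day, a subject completes
acquisition at the first trial `T` such that `T >= 44` and the daily mean RM
of the two consecutive days ending at `T` is at least 0.7 on both days; the
first reversal uses the same rule with a 24-trial floor; the second reversal
is fixed at 20 trials. Subjects that never qualify train to the caps (76 and
44 trials) and are flagged as non-reachers. We read "two consecutive
training days (four consecutive trials)" as day-aligned daily means because
the unit named is the training day; a sliding-window variant is available
behind `detect_criterion(sliding = TRUE)` for sensitivity analysis. When the
criterion falls between block boundaries the trailing partial block is kept
but flagged, and modeling excludes partial blocks by default — how partial
blocks should enter a block analysis is genuinely underdetermined, and
exclusion keeps the block factor balanced.

Analysis units are **trial blocks**, means of four successive trials
computed per variable over the non-missing trials. Learning-curve models use
the block grid common to all subjects in a phase (11 acquisition blocks, 6
first-reversal blocks, 5 second-reversal blocks under the default phase
lengths): blocks beyond a subject's phase minimum exist only for slow
learners, and including them would leave empty group-by-block cells.
Reversal transitions are analyzed on a two-level factor pairing each
subject's last complete pre-reversal block with its first post-reversal
block.

## The statistical battery

Per variable and phase segment the package fits, with `nlme::lme` under
REML, the linear mixed model

```
y ~ group + sex + block + group:sex + group:block + sex:block
random = ~ 1 | litter / subject
correlation = corAR1(~ block | litter / subject)
```

i.e. random intercepts for subject nested within litter plus a first-order
autoregressive residual correlation across blocks within subject; the
habituation phase is modeled the same way with trial replacing block. F
tests are sequential (`anova.lme`) with nlme's containment denominator
degrees of freedom — for a 38-subject, 15-litter cohort the subject-level
terms are tested on 1, 20 df and an 11-block factor on 10, 350 df. Durations
and latencies are log10-transformed. If the full structure fails to converge
the fit degrades deliberately (drop AR(1), then the litter level) and the
structure actually used is recorded in the result. Trials to criterion are
modeled with group, sex and their interaction plus random litter intercepts,
on reachers only. Hair cortisol (per timepoint) uses the same subject-level
model; salivary cortisol is log10-transformed with sample (pre/post) added
to the fixed effects and random slopes and intercepts per subject, degrading
to intercepts when the slope model is unidentifiable on two samples per
subject. Welch's t compares birth weights; contrast effect sizes use
`r = sqrt(F / (F + df_den))` for single-df terms (multi-df terms have no
single contrast r and are refused).

Selection round (cohorts are typically recruited in two waves) is recorded
in the metadata but not modeled by default: in the emulated design it
carried no information once litter was in the model, and any user can add
it by extending the fixed formula on the model frame. Two caveats are
documented rather than "fixed": REML AIC comparison across
random structures (the `select_random_structure()` helper) assumes identical
fixed effects, which the function enforces; and the containment df
approximation is conservative for paired designs with many litters — the
measured type-I error of the birth-weight test under the package's own null
generator is about 3%, within the 3-7% band the acceptance suite checks but
on its conservative edge.

## The cohort generator

`simulate_cohort()` is a first-class, tested model of memory-guided
foraging, not a fixture. Each subject chooses holes sequentially from a
multinomial that mixes uniform exploration with a preference for baited
holes of strength `lambda * rm_asymptote`, where the learning level
`lambda(t) = 1 - exp(-rm_rate * t)` saturates over trials. Already-visited
holes are re-chosen with probability `wm_lapse` (candidates are all visited
holes except the current one, matching how WM errors are scored and keeping
generated streams debounce-stable). Visit times accumulate through an
exponential gap model (mean 12 s); trials end at the fourth reward or 450 s.
At each reversal the learning level is reset multiplicatively (default
retention 0.5) rather than to zero, because trained animals retain
above-chance orientation after a configuration switch. Habituation trials
(all holes baited) do not advance pattern learning — there is no pattern to
learn — so acquisition starts at `lambda = 0`.

The linear-mixture choice model was preferred over a softmax because its
limits are analytic: `lambda = 0` with no lapses is a uniform non-revisiting
forager whose visit count to exhaust 4 baited holes among 16 has the exact
permutation expectation 4(16+1)/5 = 13.6, and `lambda = 1`,
`rm_asymptote = 1`, `wm_lapse = 0` produces the perfect four-visit trial.
Both limits are acceptance-tested end to end through the scorer.

Cohort structure mirrors a paired birth-weight design: 20 LBW/NBW sibling
pairs (same sex, same litter) from 15 litters, balanced 10/10 over sex,
configurations balanced within group-by-sex cells, litter- and
subject-level Gaussian random effects on the asymptote, an AR(1) trial-level
perturbation of the choice bias, and a default censoring pattern of two
early deaths plus one subject missing the second reversal (yielding the 38
analyzable subjects of the emulated design). Default parameters
(`rm_asymptote` 0.92, `rm_rate` 0.035, LBW shifts -0.04 and -0.006,
`wm_lapse` 0.1, litter/subject SDs 0.04/0.07, residual SD 0.08 with lag-1
correlation 0.3) were calibrated once against the emulated study's stated
conditions: cohort-mean RM starts near 0.25-0.35, crosses 0.7 within the
44-76-trial criterion window, acquisition trials-to-criterion average in the
high 40s to low 50s with an LBW excess of about five trials, and first
reversals complete around 30 trials. No quantitative learning-rate estimates
exist to fit, so the calibration targets these qualitative curve shapes
only.

Hair cortisol (pg/mg; weaning and five months) and salivary cortisol
(ng/mL; before and after the first individual arena trial, the standard
acute-stressor probe) are lognormal around group-by-timepoint means with a
shared per-subject effect on the log scale, mean-preserving
parameterization, and a default missingness pattern of three unusable hair
samples at weaning and one subject without usable saliva. Default hair means
inject a pre-weaning LBW excess that resolves by five months; hair
dispersion matches the emulated study's printed SEMs (about a 21% CV).
Saliva means (2.0 pre, 4.1 post) are plausible piglet values chosen once —
the emulated study plots but does not print them — and the post/pre ratio of
about 2 makes the acute rise unmistakable to the saliva model.

What the generator does **not** emulate: trial-level strategy (thigmotaxis,
entrance-specific turning), sex differences (the default sex effect is
zero), within-trial fatigue, any WM learning curve (the lapse rate is
constant, so simulated WM improves only weakly as trials shorten), or true
counter-based random substreams (subject streams are seeded from integers
drawn once from the root seed, which is reproducible but not
merge-stable under re-parallelization). Passing tests therefore certify the
scoring arithmetic, the criterion logic and the statistical calibration of
the battery — not that real pigs behave like the agent.

## Numerical choices

* Debounce window: closed-left, open-right, chained over successive lifts.
* Learning-model fits try `nlminb` first, then `optim`; scale equivariance
  of the F tests holds to ~1e-6 under the first.
* AIC ties (within 1e-6) go to the structure with fewer variance
  parameters.
* Zero-variance responses short-circuit to F = 0 rather than 0/0.
* Block means with every trial missing stay `NA` and are dropped by the
  models; censored subjects enter as unbalanced data, never imputed.
* Problem sizes in the test suite: the scoring oracle runs 10,000 random
  sequences; calibration uses 500 replicate cohorts of 8 pairs and 6
  acquisition blocks; the power grid crosses deficit multipliers
  {0.5, 1, 2} with {8, 16} pairs at 40 replicates per cell.

## Known limitations

* The exact baited-hole layouts of configurations A-D are
  apparatus-specific; the shipped registry is a plausible default and real
  deployments should supply their own YAML.
* The containment-df F tests inherit nlme's behavior; Kenward-Roger-style
  corrections are out of scope.
* Subjects with zero visits in a trial leave no event-log rows, so a
  written-then-read cohort drops such trials; the generator's exponential
  gap model makes them vanishingly rare.
* Habituation RM is identically 1 (all holes baited) and is excluded from
  the habituation model grid as degenerate.
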