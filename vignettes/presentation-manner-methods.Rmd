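---
title: "Methods: presentation manner, information search, and risky choice"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: presentation manner, information search, and risky choice}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(riskysearch)
```

## The scientific problem

When people choose between two simple risky gambles — each offering one gain
`x` (1–99 yuan) with one probability `p` (1–98%) — the way the information is
*presented* can change what they choose. If information can only be acquired
option by option (an **alternative-wise** task, ALT), within-option
integration strategies such as expected-value (EV) maximization are easy to
execute; if it can only be acquired dimension by dimension (a
**dimension-wise** task, DIM), attribute-comparison heuristics such as
**maximax** (take the larger outcome, ignore probability) are favoured. The
package implements the full chain needed to study this: stimulus generation,
a generative model of participants, maximum-likelihood strategy
classification, search-direction metrics from fixation data, and the
regression/mediation inference connecting them.

## Strategy classification model

For participant *i* and strategy *k*, the fit across *N* gamble pairs is the
deviance

$$G^2_{i,k} = -2 \sum_j^N \ln f_j(y),$$

where $f_j(y)$ is the probability the strategy assigns to the observed
choice on pair *j* under the softmax rule

$$p_j(A,B) = \frac{e^{\varphi V(A)}}{e^{\varphi V(A)} + e^{\varphi V(B)}},$$

with $V = x \cdot p$ for EV and $V = x$ for maximax, and $\varphi \ge 0$ a
per-participant choice-sensitivity parameter. Each participant–task block is
assigned the lower-$G^2$ strategy; if the best fit is no better than random
choice ($G^2 = 2N\ln 2$; 83.1777 at $N = 60$) or the two strategies tie
exactly, the block is labelled `GUESS_OR_OTHER`.

Numerical choices:

* $p_j$ is evaluated as a single logistic of $\varphi\,(V(A)-V(B))$ and its
  logarithm directly on the log scale, so $\varphi V$ up to 990 cannot
  overflow and deviances stay finite for any finite $\varphi$.
* $\hat\varphi$ minimizes $G^2$ on $[0, 10]$: valuations are at most 99
  yuan, and the softmax is saturated long before $\varphi = 10$. A 50-point
  log-spaced grid pre-scan precedes golden-section refinement (tolerance
  $10^{-6}$); the deviance is convex in $\varphi$, so the grid mainly guards
  against flat saturated regions.
* Flat profiles (degenerate stimuli with identical valuations) report
  $\hat\varphi = 0$ by a tie rule, and an exact EV/maximax tie is labelled
  `GUESS_OR_OTHER` rather than broken arbitrarily.

A property of the classification rule worth knowing: a *true* guesser is
labelled `GUESS_OR_OTHER` only rarely on strategy-conflict stimuli. Because
the EV and maximax choice margins are anti-correlated there, a guesser's
noise almost always correlates positively with one of the two strategies,
and optimizing $\varphi$ then pulls that strategy's $G^2$ below the random
baseline. The suite therefore tests the directional property (guessers are
flagged far more often than strategic agents), not a high absolute rate.

## Search measure index

Fixations are labelled by four areas of interest (`A_PROB`, `A_OUT`,
`B_PROB`, `B_OUT`); fixations shorter than 50 ms are excluded (strict
less-than), consecutive same-AOI fixations are merged, and each step between
distinct AOIs is one transition: alternative-wise ($r_a$; same option),
dimension-wise ($r_d$; same dimension), or diagonal (counted in the total
$N$ but in neither tally — the standard treatment for a 2 x 2 board). The
Böckenholt–Hynan search measure is

$$SM = \sqrt{N}\;\frac{\frac{DA}{N}(r_a - r_d) - (D - A)}
  {\sqrt{A^2(D-1) + D^2(A-1)}}
  \;\;\xrightarrow{A=D=2}\;\; \sqrt{2}\,\frac{r_a - r_d}{\sqrt{N}},$$

positive for predominantly alternative-wise search, negative for
dimension-wise. SM is computed per trial; participant-by-task means are also
emitted, and the mediation model consumes the per-trial values (the
aggregation level is genuinely open, so both are available). Trials with
fewer than two distinct-AOI fixations have no defined SM and are excluded
from aggregation.

## Synthetic participants

The generator's defaults are the study conditions the analysis presumes:

| Parameter | Default | Meaning |
|---|---|---|
| `n_participants` | 50 | within-subject, both tasks, order counterbalanced |
| `n_pairs` | 60 | `exp2` stimuli: EV and maximax conflict on every pair |
| `bias_alt` / `bias_dim` | 0.9 / 0.1 | P(transition is alternative-wise) per task |
| `phi` | log-normal, median 0.5, sdlog 0.3 | participant heterogeneity in sensitivity |
| `agent_mixture` | EV 0.90, maximax 0.05, guess 0.05 | population strategy mix |
| `coupling` | 0.3 | search-direction-to-strategy coupling (below) |
| `transitions_lambda` | Poisson(8) + 1 | transitions per trial |
| fixation durations | log-normal, median 250 ms, sdlog 0.4 | truncated at 60 ms |
| `rt_params` | ln 4.1 baseline, +0.16 ALT, −0.006/yuan, SD 0.35 | log-seconds scale |

Stimuli are drawn by rejection sampling — uniform integer outcomes and whole
percents, kept when the pair has a strict outcome/probability trade-off (no
dominance), an EV gap of at least 0.5 yuan (equal-EV pairs would make
EV-consistency coding ambiguous), and, in `exp2` mode, opposite EV and
maximax predictions. Accepted pairs are exactly uniform on the constrained
set; a 10,000-attempt budget per pair turns infeasible constraints into an
error rather than a hang. The riskier option occupies the top slot in
exactly half the pairs.

**Search-coupled choice.** The causal chain under study — task shifts search
direction, search direction shifts strategy use, strategy determines
EV-consistency — is implemented generatively. On each trial the fixation
walk is drawn first; with coupling $\kappa$ and realized alternative-wise
share $s$, an EV agent values the options by the EV rule with probability
$1 - \kappa(1-s)$ (maximax otherwise), and a maximax agent uses maximax with
probability $1 - \kappa s$. With $\kappa = 0.3$ (chosen once as a moderate,
realistic susceptibility) an EV agent follows EV on ~97% of ALT trials and
~73% of DIM trials, producing a clearly positive task effect and a genuine —
not spurious — indirect path through SM. Setting `coupling = 0` switches the
chain off, which is how the null-path simulations are built.

Response times are log-normal with a +0.16 log-s ALT effect, a −0.006
log-s/yuan EV-difference effect, residual SD 0.35 and a between-participant
baseline SD of 0.15 log-s, so the decision-time mixed model has true random
intercepts to estimate.

Reproducibility: one global seed; each participant's trial stream is
generated under a deterministically derived substream seed, so runs are
byte-identical given the config.

**What the generator does not emulate.** Fixation sequences are first-order
Markov with task-constant bias — no fatigue, learning, position (top/bottom
or left/right reading) effects, or saccade dynamics; transition counts are
independent of the gamble's content; the coupling is homogeneous across
participants, so the generator does not move *classifications* between tasks
the way real populations do (the per-task classified-EV proportions differ
only through sampling noise, unlike the real shift the two-proportion test
is designed to detect — that test is therefore verified against
reconstructed printed counts, not against the simulation). Passing tests
show the pipeline's statistical machinery is correct, not that real eye
movements look like the walk.

## Inference chain

* **Choice model**: `ev_consistent ~ task + (1 | participant) + (1 | item)`
  logistic GLMM (Laplace), task dummy-coded ALT = 1. Reported: `b`, Wald 95%
  CI, `OR = exp(b)`, z, p. Constant outcomes raise a separation error; a
  failed or singular fit is flagged `degraded` (with a fixed-effects
  fallback when the fit fails outright).
* **Decision-time model**: `log(rt) ~ task + |dEV| + |dOutcome| +
  (1 | participant) + (1 | item)` with Satterthwaite t tests.
* **Classification comparison**: pooled two-proportion z with one-tailed p —
  the convention recovered by matching printed statistics exactly
  (49/50 vs 44/50 gives z = 1.96, p = 0.025; 43/45 vs 39/45 gives z = 1.48,
  p = 0.069).
* **Mediation** (task → SM → EV-consistent choice) on the linear probability
  scale: `a` from the mediator model, `b` and the direct effect `c'` from
  the outcome model, the total effect `c` from the outcome-on-task model;
  indirect effect `ab = a·b`. With the OLS engine the fitted `c` equals
  `c' + ab` as an algebraic identity; with the mixed-model engine (default
  for point estimates, participant and item random intercepts) the identity
  is approximate. The 95% CI for `ab` is a percentile **cluster bootstrap**:
  participants are resampled with replacement (5,000 resamples by default)
  and the paths are re-estimated by OLS within each resample — the cluster
  resampling carries the within-subject dependence, and thousands of
  mixed-model refits would buy little beyond it. No multiplicity correction
  is applied anywhere.

The "insufficient clusters" guard (≥ 3 participants) makes the pipeline
driver report partial completion rather than producing a meaningless
bootstrap.

## Simulation sizes used by the test suite

Replicate-loop checks run at deliberately chosen reduced scales: strategy
recovery at the full 60-pair design over 200 replicate fits; label recovery
over 100 replicates per strategy; the null-path mediation coverage check
with 30 participants x 12 pairs, 200 bootstrap resamples and 100 replicates
(30 clusters is the smallest size at which a percentile cluster bootstrap is
conventionally trusted); and the end-to-end sign-pattern check at 40
participants x 40 pairs with 500 resamples. `scripts/acceptance.R` runs the
full 50 x 2 x 60 design with the default 5,000 resamples.

## Known limitations

* **$\hat\varphi$ is mean-biased upward at moderate sensitivity.** At
  $\varphi = 0.5$ on strategy-conflict stimuli roughly two-thirds of pairs
  are softmax-saturated; with probability ~4–5% a 60-trial block is
  perfectly strategy-consistent, the deviance is then monotone in $\varphi$
  and the bounded MLE returns the bound. The replicate *median* recovers the
  truth well (~0.56 for 0.5); the replicate *mean* does not (~1.05), and no
  choice of bound fixes a mean. Classification is unaffected — labels depend
  on the $G^2$ comparison, not on $\hat\varphi$ — and label recovery exceeds
  95% at $\varphi = 2$.
* The guessing label is conservative in name only (see above): most true
  guessers are absorbed by whichever strategy their noise resembles.
* The linear probability scale for mediation can in principle produce
  fitted probabilities outside [0, 1]; it is used because probability-
  difference effect sizes are the reporting convention this design follows.
* SM magnitudes under the default walk (|SM| ≈ 3.4 at bias 0.9, nine
  transitions) are larger than is typical of gaze data with milder
  predominance; the bias parameters are free knobs, not estimates.

## A minimal run

```{r example, eval = FALSE}
cfg <- pipeline_config(seed = 1, n_participants = 12, n_pairs = 20,
                       n_boot = 500, mediation_engine = "fixed")
res <- run_pipeline(cfg)
res$choice_model
res$mediation
tapply(res$sm_participants$mean_sm, res$sm_participants$task, mean)
```
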