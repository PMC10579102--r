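---
title: "Model-based reinforcement learning for inpatient insulin titration: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model-based reinforcement learning for inpatient insulin titration: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Hospitalized type 2 diabetes patients on subcutaneous insulin are dosed by
iterative titration: clinicians look at the seven-point capillary glucose
profile (pre/post each main meal plus bedtime) and adjust the next day's
doses. `insulinrl` treats this as a sequential decision problem: a Markov
decision process $(S, A, P, G, \gamma)$ whose steps are the seven daily
timeslots, whose actions are insulin dosing decisions (an insulin class
and an integer dose of 1–40 U, or no injection), and whose reward is a
per-measurement glycemic status score. The package learns the
environment from logged trajectories (a *patient model*), learns a dosing
policy against that environment with a joint supervised + reinforcement
objective, plans a day ahead by beam search, and evaluates policies
off-policy by weighted importance sampling. Guideline titration formulas
for the three common regimen families are implemented for head-to-head
comparison, and a synthetic cohort simulator with known ground truth makes
every stage testable without access to protected health records.

## Reward

The per-measurement reward maps blood glucose $b$ (mg/dl) to $[-1, 1]$:

$$r(b) = \begin{cases} -1, & b < 70\\
1 - \mathrm{clip}_{0,\,15.5}\!\big(10\,[c_0((\ln b)^{c_1} - c_2)]^2\big)/7.75, & b \ge 70
\end{cases}$$

with $c_0 = 1.509$, $c_1 = 1.084$, $c_2 = 5.381$ — a clipped, rescaled
version of the classic symmetric blood-glucose risk index. Under this
parenthesization the zero-risk point sits near 112.5 mg/dl
(≈6.2 mmol/L), in the euglycemic range, and the reward saturates at $-1$
both for hypoglycemia and for severe hyperglycemia. An alternative literal
grouping $\,(c_0 (\ln b)^{c_1} - c_2)^2$, whose zero-risk point would fall
near 25 mg/dl and which we therefore consider an artifact of typesetting,
is available via `magni_reward(..., grouping = "literal")` for
sensitivity analysis. The within-target-range (WTR) band is
3.9–10.0 mmol/L, inclusive at both ends, matching the time-in-range
convention. Rewards at unmeasured slots are undefined (masked), never
imputed; daily reward is the sum of a day's defined rewards.

## Patient model

The patient model consists of:

* a **representation function** $f_R$ — a stacked gated recurrent (GRU)
  sequence encoder over the per-slot observation stream; the last hidden
  vector is the patient state $s_t$. We chose a gated recurrent encoder
  as the package's sequence backbone: at the seven-slots-per-day scale the
  recurrence captures the day structure well, trains stably on hundreds of
  trajectories, and admits exact incremental stepping during online
  simulation. Positional structure is given to the encoder explicitly
  (slot one-hot, scaled day index) rather than through positional
  embeddings.
* a **dynamics function** $f_T$ mapping $(s_t, a_t)$ to $s_{t+1}$ and a
  reward estimate $\hat r_t$. It is a residual MLP,
  $s_{t+1} = s_t + \mathrm{MLP}([s_t, a_t])$; the residual form keeps
  multi-step roll-outs near the encoder's state manifold. The reward head
  reads the *resulting* state, i.e. $\hat r_t$ estimates the reward at the
  state produced by $a_t$ (the next measurement's score).
* a **prediction head** $f_P$ emitting a glucose point prediction and a
  WTR probability from any state.

Observation features per slot: glucose (scaled by 1/10; 0 where missing)
plus an explicit measurement mask, slot one-hot, scaled day index, the
*previous* slot's action (class one-hot + dose/40), and the patient's
normalized covariates. Carrying the previous action — not the current
one — keeps $s_t$ free of the action the policy is about to choose.
Missingness is a first-class mask channel end to end, which is what makes
the degraded-data simulation (`degrade_trajectory()`) meaningful.

Training minimizes $\mu L_T + L_P$ (+ the reward regression). $L_P$ is
the glucose MSE plus the WTR cross-entropy, averaged over measured slots
only. $L_T$ is the latent consistency loss: from each anchor step $t$ the
dynamics is unrolled (teacher-forced on logged actions) to depths
$k = 1..K$, and each rolled state is pulled towards the encoder state at
the same absolute step $t+k$ — one pair per target step per chain, the
cheap pairing scheme. Defaults: $\mu = 0.1$, hidden width 32, one encoder
layer, roll-out depth 5, Adam at $10^{-3}$ with weight decay $10^{-4}$,
50 epochs on batches of 32 trajectories. These are the desk-scale
defaults used throughout the tests (a few tens of seconds on one core for
a 200-patient cohort); a full-scale profile (hidden 256, 3 layers,
roll-out depth 7, 100 epochs) is a config away but is not what the
bundled experiments run. Dropout is not used at this scale; weight decay
is the only regularizer. Training aborts with a diagnostic on a
non-finite loss.

## Policy model

The policy $\pi(a\,|\,s)$ is an MLP over a 41-token vocabulary (no dose,
1..40 U); the insulin *class* at each slot comes from the regimen
schedule, so the policy only chooses dose magnitude, and slots with no
scheduled injection are forced to the no-dose token. A value MLP $V(s)$
(shared by both RL terms) is trained to regress discounted returns.

The joint objective is
$L = L_{RL1} + \varepsilon_1 L_{RL2} + \varepsilon_2 L_{SL}$ with
$\varepsilon_1 = \varepsilon_2 = 1$ (a single $\varepsilon = 1$ is
printed for both roles; we expose them separately):

* $L_{SL}$: cross-entropy of the clinician's logged token (behavior
  cloning);
* $L_{RL1}$: policy gradient on logged trajectories, weighted by the
  advantage $R_t - V(s_t)$ rather than the raw return — the value
  baseline is the stable default, raw returns sit behind
  `advantage = FALSE`;
* $L_{RL2}$: the same advantage-weighted form on trajectories *generated*
  by sampling the policy against the patient model's dynamics and reward
  head, with a discounted value bootstrap closing each roll-out.

Two numerical choices matter in practice. First, the two-stage schedule
is enforced: the policy refuses an untrained patient model. Second, joint
training begins with a warm-up phase (default: the first quarter of the
epochs) during which only $L_{SL}$ and the value regression are active;
the policy-gradient terms switch on once the policy is
imitation-initialized and the baseline is fitted. Starting REINFORCE-type
updates from a random policy with an unfitted baseline produced
high-variance updates that could undo a good imitation solution; the
warm-up removes that failure mode without changing the objective being
optimized. Exploration during model-based roll-outs is plain categorical
sampling from $\pi$.

## Planning

`plan()` performs K-step beam search over the learned dynamics
(default $K = 7$, one day; beam $B = 10$). Partial plans are scored by
accumulated discounted model reward plus a value bootstrap
$\gamma^k V(s_{t+k})$ at the current depth; the returned plan value is
$v = \sum_i \gamma^i \hat r_{t+i} + \gamma^K V(s_{t+K})$. Candidates per
expansion are the top-M policy tokens (default $M = 5$) for tractability;
`candidates = "all"` expands the full vocabulary and is what the
exhaustive-oracle tests use. Ties between equal-value plans resolve to
the lexicographically smaller dose sequence — a deliberate safety bias
toward less insulin. `recommend_day()` wraps this for prefixes ending at
bedtime.

## Off-policy evaluation

Per-step ratios $\rho_t = \pi_1(a_t|s_t)/\pi_0(a_t|s_t)$ multiply into
trajectory weights; `v_is()` is the ordinary estimator
$\sum_i (w_i/N) \sum_t \gamma^{t-1} r_{i,t}$ and `v_wis()` the
self-normalized one with effective sample size
$(\sum \rho)^2 / \sum \rho^2$. The $\gamma^{t-1}$ indexing (t from 1) is
used in both, matching the printed estimator; the trajectory weight is
interpreted as the full-trajectory product of ratios, the standard WIS
weight. The behavior policy $\pi_0$ is estimated by supervised-only
training of the same policy architecture, with output probabilities
floored (default $10^{-3}$) to guarantee support; the floor is reported
alongside results. Only injection slots contribute ratios — both policies
are forced to "none" elsewhere by the schedule.

## Guideline baselines

The three printed rule sets are implemented literally on mg/dl values
(mmol/L inputs are converted first; the tables never see mmol):
the five-branch ±2/4/6-unit table for premixed and basal regimens, and
for basal–bolus regimens the ±20% basal rule (hypoglycemia takes
precedence over the increase when both fire on one day, and percentages
round half-away-from-zero to integer units clamped to 1..40) plus the
seven-branch post-meal bolus supplement table. Post-meal glucose at or
below 140 mg/dl — below the table's first branch — yields no supplement,
the conservative reading. "Mean blood glucose during the day" is the
arithmetic mean of that day's measured values.

## The synthetic cohort

The generator stands in for the (non-shareable) inpatient EHR
environment. Each patient has latent basal glucose
($\mathcal N(9.5, 1.2^2)$ mmol/L), insulin sensitivity
($\mathcal N(0.35, 0.08^2)$ mmol/L per unit), and per-meal postprandial
rises ($\mathcal N(3.5, 0.7^2)$ mmol/L), all truncated to physiologic
ranges. Glucose at a slot is basal + meal effect − sensitivity × the
effective insulin on board, plus Gaussian noise (default sd
0.4 mmol/L), floored at 1.5 mmol/L. Insulin kinetics are deliberately
minimal: short/rapid insulin acts fully on the immediately following
post-meal slot; long-acting insulin lowers each of the next seven slots
at half weight; premixed insulin splits 50/50 into a prandial component
(next slot) and a basal component spread at quarter weight over the
three slots after that. Regimens (premixed 40%, basal-only 30%,
basal–bolus 30%) fix the injection schedule.

For every injection the generator brute-forces the dose in 1..40 that
minimizes the absolute deviation of the noise-free response from
6.5 mmol/L over the slots that injection affects — the *oracle dose*.
Logged behavior doses are oracle + rounded $\mathcal N(0, 3^2)$ jitter
clamped to 1..40: a deliberately sub-optimal clinician stand-in, so that
improving on imitation is measurable and the dose–response is identified
from dose variation. Ten percent of measurements are masked at random.
All randomness flows from one seed through per-patient substreams.

What the simulator does *not* model: carbohydrate intake and meal size
variation, insulin stacking and duration-of-action tails beyond the
stylized kinetics, circadian sensitivity drift, stress hyperglycemia,
renal clearance, or measurement error structure beyond i.i.d. Gaussian
noise. Passing the bundled experiments therefore demonstrates that the
learning and planning machinery works where the environment is learnable
and the ground truth is known — it does not certify clinical performance
on real wards, which in the source setting required tens of thousands of
admissions.

## The bundled experiment sizes

The test suite runs, per seed: 200 patients × 3 days (noiseless, jitter
sd 3 U, 10% missingness), patient model of hidden width 32 trained 50
epochs, policies trained 80 epochs (quarter warm-up) — about 1.5 minutes
per seed on one core, five seeds. Under these conditions the held-out
one-day-ahead glucose MAE falls to ≈1.5 mmol/L against a cohort standard
deviation of ≈2.15 mmol/L, and the jointly trained policy attains a mean
simulator daily reward of ≈1.6 and WTR ratio ≈0.68 versus ≈1.0 and
≈0.63 for the imitation-only ablation — the central qualitative claim,
in miniature. (The numbers quoted here are the ones those same tests
compute; they move a little with seeds.)

## Known limitations

* One action per timeslot: a basal+bolus day is represented as
  class-specific actions at their conventional slots; simultaneous
  injections of two classes at one slot are not representable.
* The value function is fitted on logged-data returns; at model-based
  roll-out states it extrapolates. With a shared encoder this has been
  benign, but it is a bias source for $L_{RL2}$ advantages.
* Noisy-OR daily aggregation (`noisy_or_daily_wtr()`) literally
  aggregates the *in-range* probabilities, matching its printed
  description, although one could argue a day is "in range" only if all
  points are; the complementary all-points product is provided behind
  `mode = "all"`.
* Records falling outside the seven slots are out of scope for the data
  layer; upstream ETL must assign them to the nearest preceding slot.
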