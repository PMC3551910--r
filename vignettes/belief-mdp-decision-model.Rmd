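---
title: "A belief-MDP account of the random-dots decision task"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A belief-MDP account of the random-dots decision task}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pomdpdots)
```

## The model

In the random-dots motion discrimination task a subject watches a field of
dots of which a fraction $c$ (the coherence) drifts coherently left or right,
and reports the direction with an eye movement whenever it chooses. The
subject is rewarded for correct choices, so it faces a joint inference and
control problem: infer the hidden stimulus from noisy spike trains, and decide
*when* enough evidence has accumulated.

`pomdpdots` treats the task as a partially observable Markov decision process
(POMDP):

* **Hidden state.** The pair (coherence $c$, direction $d$) is fixed within a
  trial and never observed. The two direction-selective MT populations fire at
  $f_{\text{pref}} = f_0 (1 + k_p c)$ and $f_{\text{null}} = f_0 (1 - k_n c)$
  spikes/s. Conditioned on a spike from the pooled population, it comes from
  the rightward-preferring pool with probability
  $p = f_R / (f_R + f_L)$, which summarizes the hidden state in a single
  number: $p > 1/2$ means rightward motion, $|p - 1/2|$ grows with coherence.
* **Observations.** Time is discretized by spike count: one step ends when
  $N$ spikes have arrived from the pooled population (the step duration is a
  Gamma($N$, $f_R + f_L$) random variable, irrelevant to the policy). The
  observation per step is the number $z \sim \text{Binomial}(N, p)$ of
  rightward spikes. The default is $N = 1$: a decision opportunity at every
  spike.
* **Belief.** With a Beta($\alpha_0$, $\beta_0$) prior on $p$, the posterior
  after observing counts is Beta($\alpha_0 + n_R$, $\beta_0 + n_L$). The
  belief therefore lives on the exact integer lattice $(t, n_R)$ with
  $n_R + n_L = Nt$ — conjugacy removes any need for discretization. The point
  estimate $\hat p = n_R / (Nt)$ is the coordinate in which the policy is
  displayed; the posterior probability of rightward motion is the regularized
  incomplete beta function $1 - I_{1/2}(\alpha, \beta)$, computed with
  `pbeta`.
* **Actions and rewards.** At each step the subject samples (one more
  observation at cost $c_s < 0$ per spike), or commits left or right, earning
  $R^+ > 0$ if correct and $R^- \le 0$ otherwise, after which the trial enters
  an absorbing state with zero reward. Because the optimal policy depends on
  rewards only through ratios, $c_s = -1$ fixes the unit.
* **Policy.** `solve_policy()` solves Bellman's equation on the belief MDP by
  backward induction from a finite horizon. The optimal policy partitions each
  lattice row into a leftward region, a sampling interval, and a rightward
  region; the rightward boundary $\theta_R(t)$ — the smallest ratio
  $n_R/(Nt)$ at which the policy commits right — *collapses* toward $1/2$ as
  evidence accumulates, without any deadline assumption: late in a trial the
  point estimate is reliable, so a small excess over $1/2$ already justifies
  stopping, while continuing to sample a possibly 0%-coherent stimulus only
  wastes sampling cost.

Forward analysis of the solved policy is exact. `first_passage()` propagates
the full probability mass over the sampling region under a true $p$ and reads
off the crossing-time distributions $h_R(t), h_L(t)$, the survival function
$g(t)$, choice probabilities, and conditional mean decision times;
conservation $\sum_t h_R + \sum_t h_L + g(T_{\max}) = 1$ holds to $10^{-10}$
by construction. `psychometric_chronometric()` tabulates accuracy and mean
reaction time across coherences, and `calibrate_time()` regresses observed
mean reaction times (ms) on predicted mean decision steps to recover the real
duration of one step and the non-decision residual time — the only two
quantities outside the POMDP, used purely for unit conversion.

## Default parameters and why

All defaults live in `default_config()` and can be overridden from YAML.

| parameter | default | meaning / rationale |
|---|---|---|
| `mt$base_rate` | 40 spikes/s | zero-coherence rate of each MT population |
| `mt$drive_pref`, `mt$drive_null` | 1.0, 0.5 | linear coherence gains; `drive_null < 1` keeps the null rate positive up to full coherence, and $p(c{=}1) < 1$ |
| `mt$spikes_per_step` | 1 | a decision opportunity per spike (most general granularity) |
| `prior` | Beta(1, 1) | uniform, symmetric; the task model assumes left/right symmetry |
| `rewards` | $c_s = -1$, $R^\pm = \pm 200$ | see below |
| `horizon` | 500 steps | see below |
| `coherences` | 0, 3.2, 6.4, 12.8, 25.6, 51.2 % | the conventional task levels |
| `lip` | bound 70 spikes/s, gain 100, floor 0, window 18 steps | physiologically plausible scales: early zero-coherence rate $\approx 20$ spikes/s rising to a $\approx 70$ spikes/s decision bound; 18 steps $\approx$ 225 ms at the step duration implied by the 80 Hz pooled MT rate |

The reward ratio is the single behaviorally meaningful knob. With
$R^\pm = \pm 200$ per unit sampling cost the solved policy produces a clearly
collapsing bound, a zero-coherence mean decision time of ~42 steps (about half
a second at the ~12.5 ms step implied by the default MT rates), accuracies
rising from 57.7% at 3.2% coherence to 98.7% at 51.2%, and zero-coherence
survival below $10^{-6}$ by step 318 — comfortably inside the certified
stationary range. These are the scales of classic monkey experiments; users
fitting data should treat the ratio as the free parameter.

The horizon of 500 steps truncates the stationary infinite-horizon problem.
Truncation is *certified*: the solver re-solves at a 25% longer horizon and
requires the integer boundary thresholds for $t \le 0.8 \cdot T_{\max}$ to
agree exactly; `first_passage()` refuses uncertified policies, and the mass
reaching the horizon row is reported as leak, never silently renormalized or
classified as a choice. Solving costs $O(T^2 (N+1))$ — about 0.1 s at the
defaults.

## Numerical choices

* Posterior tail probabilities use `pbeta(1/2, beta, alpha)` (the mirror
  identity) rather than `1 - pbeta(...)`; beta-binomial predictive weights are
  computed in log space with `lbeta`. For a symmetric prior the rightward
  probabilities of a lattice row are the exact reversal of the leftward ones,
  which makes the value table mirror-symmetric to the last bit that summation
  order allows, and the zero-coherence crossing masses *bitwise* symmetric —
  accuracy at $c = 0$ is exactly 0.5, not 0.5 up to tolerance.
* Tie-breaking is deterministic: sampling beats stopping at exact value ties
  (except at the horizon, where sampling is unavailable) and right beats left.
  Ties occur only on the lattice midline.
* The ratio boundary $\theta_R(t) = k(t)/(Nt)$ is exact, and therefore
  *sawtoothed*: the count threshold $k(t)$ never decreases, but whenever it
  increments, $(k+1)/(t+1) > k/t$. The boundary collapses in the sense that
  increases are bounded by one lattice cell, $(t-k)/(t(t+1))$, and the lower
  envelope falls monotonically to $1/2$. Smooth "collapsing bound" statements
  refer to this trend; `fit_hyperbolic_boundary()` summarizes it as
  $\theta(t) = 1/2 + a\tau/(t + \tau)$, fitted by least squares over
  log-parameters with multiple starts, flagging constant boundaries as
  degenerate instead of fitting them.
* Observation granularity is *not* exactly neutral. The belief transition for
  one $N$-spike step equals the composition of $N$ single-spike transitions
  (an exact identity, tested), but an agent deciding every $N$ spikes has
  fewer stopping opportunities than one deciding every spike: its value is
  dominated by the fine-grained agent's, and its actions differ in cells
  adjacent to the decision boundary (about 0.4% of cells at the defaults; the
  coarse agent stops one cell earlier). A tiny worked example makes the gap
  concrete: with a uniform prior, $R^\pm = \pm 4$ and $c_s = -0.5$ per spike,
  the optimal value at the root is 1.5 when deciding after each of two spikes
  but 1.0 when committed to observing both. Granularity invariance holds for
  the dynamics, approximately — not exactly — for the control problem.

## The LIP read-out

`lip_rate()` maps the belief relative to the collapsing boundary onto a
firing rate, $x(t) = \max(\text{floor},\; B + \kappa(\hat p - \theta_R(t)))$:
the rate reaches the bound $B$ exactly when the point estimate reaches the
boundary, so a first passage of the rate through $B$ *is* the policy's
rightward decision — a re-coordinatization, not a new rule (tested
bit-exactly per trial; the leftward population is the mirror construction,
with its threshold computed from counts so the mirror is also bit-exact).

Two signatures follow:

* **Urgency.** At zero coherence the expected point estimate among
  still-sampling trials is exactly $1/2$ by symmetry, so the expected rate
  $B + \kappa(1/2 - \theta_R(t))$ is a rising, stimulus-independent image of
  the collapsing boundary. `urgency_signal()` returns it together with the
  hyperbolic half-time of the underlying boundary.
* **Buildup.** `buildup_rates()` fits the early slope of the trial-averaged
  rate (survivor-conditioned: trials still sampling at each step) over a
  window starting where the boundary first exists, per coherence, and then the
  line of slope versus coherence (in %). With a gain that never engages the
  rate floor, the analytic zero-coherence buildup equals the urgency slope
  identically (a tested identity). Because the read-out is based on the
  evidence *ratio*, whose expectation is constant in time for a fixed
  stimulus, early buildup is urgency-dominated, and censoring at the
  collapsing bound compresses the stimulus dependence: with the default
  window the fitted slope-vs-coherence line comes out slightly *negative*
  rather than positive. The rising-with-coherence buildup seen in recorded
  LIP populations is not reproduced by survivor-averaged ratio read-out;
  alternative averaging conventions we examined (holding decided trials at
  their terminal rates, or including trials through their decision step)
  do not change the sign. This is a known limitation of the read-out, worth
  keeping in mind when comparing to electrophysiology.

With the default gain (100 spikes/s per unit of $\hat p - \theta_R$) the rate
floor clips extreme evidence values early in trials, where the boundary sits
near 1; the exact identities above are stated for unclamped configurations
(gain $\le$ bound − floor).

## What the simulator does and does not emulate

`simulate_trial()`/`simulate_experiment()` generate binomial spike-count
observations under the true stimulus, update the lattice belief, and act per
the solved policy, with a counter-based seeding scheme (`trial_seeds()`): a
base seed plus trial index fully determines each trial, so experiments are
reproducible and any single trial can be re-simulated in isolation. The
simulator is both the synthetic stand-in for behavioral data and the
stochastic oracle for the analytic first-passage module (they agree within
Monte Carlo error by construction of the model — the tests check 3 standard
errors at $10^5$ trials).

The generator emulates the *model's* idealizations, not the animal: Poisson
MT spiking with exact linear rate coding and no inter-neuron correlations, a
perfectly stationary stimulus, no lapses, no non-decision time (added only by
the calibration), and a subject that executes the optimal policy without
noise. Passing tests therefore validate the mathematics and the
implementation, not the claim that any animal is exactly optimal.

## Reaction-time calibration

`calibrate_time()` is ordinary least squares of observed mean RT (ms) on
predicted mean decision steps. It needs at least two distinct step values,
reproduces exact lines exactly, and reports the RMS residual; a negative
slope or intercept triggers a warning rather than an error, since both are
diagnostic of a model–data mismatch. No experimental data ship with the
package; the CLI's `calibrate` subcommand consumes any user CSV with columns
`(coherence, mean_rt_ms)`.

## Known limitations

* The boundary monotonicity and granularity invariance hold as trends and
  dynamics identities, not exactly on the lattice (see above).
* Buildup-rate coherence scaling has the wrong sign relative to recorded LIP
  under every averaging convention we examined (see above).
* The MT encoding constants are documented placeholders at plausible scales,
  not fits to electrophysiology; tuning-curve heterogeneity and spike-train
  correlations are out of scope.
* Error-trial reaction times are computed but the package's headline
  comparisons use correct trials.
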