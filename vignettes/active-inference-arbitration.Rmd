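---
title: "Planning, counterfactual learning, and entropy-based arbitration in discrete active inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Planning, counterfactual learning, and entropy-based arbitration in discrete active inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(actinf)
```

# The generative model

All agents in this package hold a categorical POMDP generative model
(`generative_model()`): a likelihood matrix $A$ mapping hidden states to
observations, an action-conditioned transition tensor $B$ with Dirichlet
concentration counts behind it, a preference distribution $C$ over
observations, a prior $D$ over the initial state and a prior $E$ over
actions.  Perception is exact Bayes (`infer_state()`): the posterior over
states is the softmax of log-prior plus log-likelihood.  All shipped
experiments are fully observable ($A = I$, observation = state), so
inference reduces to reading off the state; the machinery for generic $A$
(ambiguity terms, belief prediction, mean-field free energy) is
implemented and tested but not exercised by the experiments.

Learning of dynamics is Dirichlet count accumulation
(`learn_transition()`): each observed transition $(s, u) \to s'$ adds the
learning rate (default 1) to the corresponding count, and the affected
column of $B$ is renormalized.

**Prior counts.** The prior concentration per count entry defaults to
$1/n_{\text{states}}$, i.e. unit mass per column, rather than 1 per entry.
With hundreds of states a unit count on *every* entry would swamp the
evidence: a transition observed once would receive probability
$\approx 2/n_{\text{states}}$, and the planner could not exploit anything
it had learned within realistic episode counts.  Unit column mass means a
single observation already dominates the column.  The flat-1 prior is one
argument away (`b_prior = 1`).

# The three decision-making schemes

## Dynamic-programming planner (DPEFE)

`plan_efe()` evaluates an expected-free-energy table $G(\tau, u, s)$
backward over a finite horizon $T$:

$$G_\tau(u, s) = \underbrace{\mathrm{KL}\left[A B_u(\cdot|s) \,\|\,
C\right]}_{\text{risk}} + \underbrace{\textstyle\sum_{s'} B_u(s'|s)
H[A(\cdot|s')]}_{\text{ambiguity}} + \sum_{s'} B_u(s'|s) \sum_{u'}
\sigma\!\big(-\alpha G_{\tau+1}(\cdot, s')\big)_{u'}\, G_{\tau+1}(u', s'),$$

with $G_{T+1} \equiv 0$.  The continuation is weighted by the softmax of
the next-step table (a hard argmin is available via
`continuation = "argmin"`); the recursion is validated against a scalar,
definition-level oracle in the test suite.  Action selection is
$P(u|s) = \sigma(-\alpha G_1(\cdot, s))$ with action precision $\alpha$
(default 1).  The cost is exactly $T \cdot n_{\text{actions}} \cdot
n_{\text{states}}$ entry evaluations — linear in the planning horizon —
and the table object carries that instrumented count.

**Preferences.** `build_preference()` places a softmax bump of mass
`goal_mass` (default 0.99) on the goal observation.  This makes the
per-step risk of a known non-goal transition about
$-\log C_{\text{other}}$ nats, so learned $G$ differences between actions
are large and the $\alpha = 1$ policy is close to greedy.  A consequence
discussed under *Limitations* is that the planner arm is usually the
lower-entropy (more confident) scheme in this implementation.

**Replanning.** The table is recomputed at every episode start, and
additionally whenever `replan_interval` (default $2\,n_{\text{states}}$) new
transition counts have accumulated since the last plan.  While the model
is still being learned, a plan computed once per episode goes stale: a
stationary near-greedy policy that chases not-yet-explored transitions can
lock into closed loops and walk them for the rest of a long episode.
Replanning on an evidence interval removes that failure mode at a cost
that stays proportional to the amount of new evidence; once the
environment is mastered, episodes are shorter than the interval and
exactly one plan per episode is computed.

## Counterfactual learner (CL)

The learner maintains a strictly positive state-action mapping `CL`
(initialized to 1, i.e. a uniform policy) and acts by normalizing its
columns (`action_distribution_cl()`, the unit-precision softmax of the
log-column).  Once per episode the whole trajectory updates the mapping
(`update_cl_mapping()`):

$$CL \leftarrow CL + t\,\big\langle (1 - 2\Gamma_\tau)\,(u_\tau \otimes
s_{\tau-1}) \big\rangle,$$

so steps experienced under low risk ($\Gamma < 0.5$) strengthen the
visited (action, state) entries and high-risk steps weaken them; entries
are floored at $10^{-16}$.

**Risk dynamics.** The scalar risk $\Gamma \in [0, 1]$ is reset to 0.9 at
the start position and by any high-risk event (wall hit, pole/cart
leaving its limits, an exhausted step budget on an unsolved maze), and
otherwise decays by division, $\Gamma_t = \Gamma_{t-1} / \max(T_{goal} -
t,\, 1)$.  The package resolves the open question of what $T_{goal}$
refers to as *the time of the next positive environmental signal*,
evaluated in hindsight when the episode ends — which is when the batch
update is applied anyway (`risk_trace()`):

* the step that receives the positive signal (reaching the goal;
  balancing through the whole budget) drops the risk to zero;
* while the signal lies ahead, the division rule applies;
* when no signal is in sight (an episode that ends unsolved), the risk
  holds its reset value;
* the start-position reset applies to the *pre-action* value
  $\Gamma_0$, so the first action of a successful episode is credited,
  not punished.

Two prospective readings were implemented first and discarded: carrying
$T_{goal}$ over from the previous success makes the risk collapse to zero
during *failing* episodes, so the update reinforces entire failing
trajectories (the learner then locks into wandering loops and the risk
trace anticorrelates with difficulty); and punishing the first action of
every episode makes one-step tasks unlearnable.  Under the hindsight
trace, solved episodes are reinforced, unsolved ones are punished, the
risk settles near zero on mastered tasks and jumps back to 0.9 when the
environment mutates — the behavior the explainability analyses rely on.
For cart-pole, where survival itself is rewarded step by step, the
horizon entering the division is the episode budget, so the balanced
stretch of an episode carries near-zero risk and the failure step carries
0.9.

## Mixed agent

The mixed agent carries both schemes and a per-state bias
$\beta(s) \in [0, 1]$ (prior 0.5).  At every step, *before* acting, the
bias of the current state moves by the scaled entropy difference of the
two action distributions (`update_bias()`):

$$\beta(s) \leftarrow \mathrm{clip}_{[0,1]}\Big(\beta(s) +
\alpha_{\text{norm}} \big(H[P_{CL}(\cdot|s)] -
H[P_{DPEFE}(\cdot|s)]\big)\Big),$$

with $\alpha_{\text{norm}} = 0.1$ by default (the stabilizing
normalization constant; one step from the prior matches the closed-form
logistic `bias_closed_form()` to first order when the scale is 1/4).  The
action is drawn from the renormalized geometric mixture
(`mix_action_distributions()`)

$$P_{MM}(u|s) \propto P_{CL}(u|s)^{1-\beta(s)}\,
P_{DPEFE}(u|s)^{\beta(s)},$$

which is algebraically identical to the single softmax
$\sigma(-\beta\,\text{ff}\,G + (1-\beta)\ln CL)$ — an identity the test
suite checks to $10^{-12}$.  The EFE precision "ff" of the planner arm is
a separate parameter (`efe_precision`, default 1) kept distinct from both
$\alpha$ and $\alpha_{\text{norm}}$.

# Testbeds

**Grid worlds.** ASCII mazes (`#`/`.`/`S`/`G`, 1-based row-major state
indexing) with deterministic moves; bumping a wall or the boundary leaves
the agent in place and raises the high-risk flag.  The procedural
generator can target an exact optimal-path length: start and goal are
placed at a parity-compatible Manhattan distance and walls are added one
at a time, never disconnecting the goal and never overshooting the
target, until the breadth-first-search distance matches.  Targeted
layouts are wall-dense mazes unless `start_goal_distance` pins the pair
at the target distance (then the layout stays open — used for the easy
variant of the mutation schedule).  Baselines: `shortest_path_length()`
(breadth-first search) and `random_walk_episode_length()`.

**Cart-pole.** A self-contained implementation of the classic balancing
benchmark: gravity 9.8, cart mass 1.0, pole mass 0.1, half-length 0.5,
force ±10, explicit Euler at 0.02 s, termination at ±12° / ±2.4 units
(the mutated variant halves both).  The four state variables are binned
uniformly (3 × 3 × 6 × 3 = 162 states by default; velocity bins span ±3
and ±3.5 rad/s).  Binning ranges stay tied to the unmutated thresholds so
that state indices keep their meaning when the termination limits
tighten.

**Mutations.** A schedule entry `(episode = k, env)` swaps the
environment between episodes $k$ and $k+1$.  The agent keeps everything
it has learned (transition counts, CL mapping, bias map); its preference
vector and start prior are re-targeted to the new goal — the *task* is
given, the *dynamics* must be relearned.  The episode step budget is an
experimenter's constant and does not change at the mutation.

# Experiment design choices

* **Seeds.** A master seed spawns one child seed per (trial, episode)
  through the documented counter scheme `child_seed()`; experiment
  re-runs are bit-identical.
* **Budgets.** Maze episode budgets are set to 10× the random-walk mean
  length of the environment the agent starts in, capped (6000 steps for
  the data-efficiency comparison, 2500 for the mutating schedule, 30000
  for the 900-state maze).  Generous budgets let early episodes end at
  the goal, which is what makes model learning possible at all; the cap
  keeps runtimes bounded.  Cart-pole episodes are capped at 200 steps.
* **Scales.** The shipped analyses use a 16×16 maze (optimal path 24)
  for the planner-vs-learner comparison, a 10×10 mutating pair (optimal
  4 easy / 14 hard, mutation after 35 of 80 episodes), a 30×30 maze with
  optimal path exactly 47 for the oracle checks, cart-pole for 100–140
  episodes, and 20 seeds per condition.  These sizes are the package's
  simulation choices; the same code runs larger configurations
  unchanged.
* **"First-success episode".** Data efficiency is summarized as the
  first episode that starts a run of three consecutive episodes with
  length at most 10× the optimal path.  A single sub-threshold episode
  on a maze is dominated by random-walk luck; three in a row at an
  order-of-optimal length is evidence of a goal-reaching *policy*.  The
  threshold was fixed before the comparisons were run.
* **Bias reductions.** The bias is a per-state map; the metrics log its
  average over all states at the episode end (`beta_avg`), its average
  over visited states along the trajectory (`mean_beta`) and its value
  at the start cell (`beta_start`).

# Numerical conventions

Logarithms are floored at $10^{-16}$; softmaxes subtract the maximum
before exponentiation; probability vectors are validated to $10^{-6}$ on
entry and emitted normalized to $10^{-9}$ or better; the CL mapping is
floored at $10^{-16}$; the bias is clipped to $[0, 1]$; action sampling
uses inverse-CDF draws from R's seeded generator.  Degenerate inputs
(empty trajectories, out-of-range indices, unnormalized distributions,
stepping a terminated cart-pole or a wall cell) raise errors rather than
propagating silently.

# What the synthetic testbeds do and do not show

The grid worlds and the cart-pole are exactly the class of environment
the three schemes were designed for: small, discrete, fully observable,
with abrupt structural change as the only non-stationarity.  Passing
tests here show that the planner exploits a learned model quickly, that
the learner improves from experience alone at zero planning cost, that
the risk trace tracks task difficulty, and that the arbitration weight
moves toward the more confident scheme.  They do not show anything about
partial observability in practice (identity likelihood throughout),
continuous or high-dimensional state spaces, stochastic dynamics, or
reward structures richer than a single goal/survival signal.

# Known limitations

* **Planner-dominant arbitration.** With the default sharply peaked
  preferences, the planner's action distributions are near-deterministic
  once the model is learned, so the planner is usually the more
  confident scheme and the bias settles *above* 0.5 wherever planning
  has an opinion.  In a softer-preference regime (larger preference
  entropy, hence flatter $G$), the learner becomes the sharper scheme
  over time and the bias would settle below 0.5.  Both regimes are one
  parameter away (`goal_mass`); the package ships the sharp default and
  reports the bias trajectories it actually produces.
* **Cart-pole learning is weak.** Under the hindsight risk trace almost
  every surviving step of a failing episode carries near-zero risk, so
  the learner mostly reinforces what it already does and improves
  slowly; the risk trace and its mutation response, not the balancing
  duration, are the reproducible signals.
* **The division decay is brutal.** $\Gamma_{t-1}/\max(T_{goal}-t,1)$
  collapses to near zero within one or two steps whenever the signal is
  far ahead; most of the information in the trace is therefore carried
  by the reset and zero events, not by the decay profile.  The
  update-rule reading is recorded as an open interpretation, not
  asserted as the only one.
* **Exploration is a side effect.** Unexplored transitions keep flat
  columns whose predicted outcomes look mildly attractive under peaked
  preferences, giving the planner an implicit novelty drive.  It is
  useful in practice but is not a calibrated exploration scheme.
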