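---
title: "Imitation dynamics with observable labels: model, protocol, and boundary theory"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Imitation dynamics with observable labels: model, protocol, and boundary theory}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

```{r setup}
library(tagdilemma)
```

## The model

Agents sit on an undirected graph. Each carries a **static binary label**
(green or blue) — observable, immutable, and payoff-irrelevant in itself —
and one of four **strategies**: cooperate with all, cooperate only with
green, cooperate only with blue, defect all. Because neighbours wearing the
same label are indistinguishable, these four exhaust the behavioural
repertoire.

Interaction is a donation game. If agent $i$'s strategy tells it to
cooperate with the label of neighbour $j$, then $i$ pays one unit and $j$
receives $b > 1$ units. Payoff never accumulates; it is a function of the
current configuration:

$$p_i \;=\; \sum_{j \in \mathcal{N}_i} \big[\, b\, S_j(\lambda_i) - S_i(\lambda_j) \,\big],$$

where $S_i(\lambda) \in \{0, 1\}$ is the action rule and $\lambda_i$ the
label. `payoff()` and `payoffs()` implement exactly this sum; the identity
$\sum_i p_i = (b-1) D$, with $D$ the number of realized directed donations,
is asserted in the test suite on random states.

Dynamics are asynchronous. One **event**: a focal agent is drawn uniformly;
with probability $\mu$ it mutates, resampling its strategy uniformly from
all four (so the effective change probability is $3\mu/4$ — the literal
reading of a uniform draw over the full strategy set, which we prefer
because it keeps the mutation kernel symmetric); otherwise it copies a
neighbour drawn with probability proportional to the neighbour's fitness

$$f_j = e^{w\, p_j}.$$

The selection pressure $w$ interpolates between neutral voter-model drift
($w = 0$) and deterministic copy-the-best ($w \to \infty$). The exponential
form keeps every fitness positive, so the deterministic limit is reachable;
numerically all selection probabilities are computed as softmaxes of
$w(p_j - \max_k p_k)$, which is shift-invariant and cannot overflow, and
$w = \infty$ is handled as an argmax with uniform tie-breaking.

"Time step" throughout means one event, not one sweep. All protocol sizes
below are event counts.

### Reproducibility

Randomness comes from R's global RNG stream (`sim_state(seed = )` simply
calls `set.seed()`). Each event consumes draws in a fixed order — focal
agent, mutation coin, then either the strategy draw or the neighbour draw —
and the C++ bulk runner `run_events()` consumes the stream identically to
repeated `step_event()` calls, so the two paths produce bit-identical
trajectories from equal seeds (tested). We chose the global-stream idiom
over a per-state generator object because it is what R users expect
`set.seed()` to control, and it keeps every function a pure function of
(state, parameters, stream position).

## Populations

The reference topology is a `width × height` square lattice, periodic only
along the width: a **cylinder**, open at the two rows where the label
gradient ends. Agents in the two open rows have degree 3, all others 4; we
deliberately use no ghost cells, so the finite ends are part of the model.
The **gradient label field** makes row $r$ green with probability
$r/(H-1)$: row 0 is all blue, the top row all green, the overall green
fraction is $1/2$ and within either half the local majority holds about
$3/4$ of the agents — the number that makes the hierarchical phases
directly readable off the mean payoff. Uniform Bernoulli fields, 1D lines
and rings with patterned labels (a single central green agent, or a tiled
pattern), tori, and Erdős–Rényi graphs are provided for robustness checks;
isolated vertices in random graphs are legal but flagged, and an isolated
focal agent is an error at imitation time rather than a silent no-op.

## The phase-scan protocol

`run_point()` implements the measurement convention used everywhere:
initialise **all agents as defectors**, discard a transient, then average
observables over samples evenly spaced across a window:

* normalized mean payoff $= D/E \in [0,1]$ — realized directed donations
  over all directed neighbour pairs (1 under full cooperation, 0 under full
  defection);
* the four strategy shares, and the **discrimination index** (combined
  share of the two label-conditional strategies);
* for gradient cylinders, final-state shares per half, because the
  hierarchical phases are regional.

`phase_scan()` repeats this per $(b, w)$ cell with a fresh label field and
a fresh seed per cell, so no conclusion hinges on one label realisation.
Cell failures are recorded and skipped, not fatal.

**Desk scale.** The package defaults are a $50 \times 50$ lattice with a
$5\times10^6$-event transient and 20 samples over $10^7$ events ($\mu =
0.001$ throughout). These are the problem sizes used by the tests and the
acceptance script; the full-scale protocol ($100 \times 100$,
$2\times10^7$ plus $10^8$) is a `scan_protocol()` call away and was used
during development to check that the desk scale preserves the qualitative
structure. What the desk scale reproduces quantitatively: the
majority-cooperation hierarchy at high $b$ and high $w$ (payoff
$\approx 3/4$), the minority-cooperation hierarchy (payoff $\approx 1/4$),
the near-cooperative and near-defective extremes at weak selection. What it
shifts: the *locations* of some phase boundaries in $(b, w)$ — at this size
the minority-cooperation phase at $b = 3.5$ lives near $w \approx 0.03$–$0.3$
and reaches $w \ge 1$ only for $b \lesssim 3$ — and the weak-selection
extremes, where the voter-with-mutation stationary state retains 10–20%
strategy mixing however long the run (the drift floor: near-neutral
interfaces wander, and mutation keeps reseeding minorities). Tests against
phase *values* therefore pin points deep inside phases where the desk scale
is stable, and results at near-neutral $w$ should be read as
stationary-state values, which are not extreme at any finite size.

```{r phaseC, eval = FALSE}
g <- build_cylinder(50, 50)
labs <- assign_labels_gradient(g, seed = 1)
run_point(model_params(b = 8, w = 1, mu = 0.001), g, labs,
          scan_protocol(), seed = 1)
# normalized mean payoff ~ 0.75: each half cooperates with its local
# majority (3/4 of directed edges point at a favoured target)
```

## One-dimensional boundary theory

On a line with the leftmost agent pinned to *cooperate with all* and the
rightmost to *cooperate with blue* ($\mu = 0$), every reachable state is
two single-strategy domains with one boundary, whose integer position
performs a random walk: a birth–death chain. The move probabilities follow
from the update rule itself — the boundary moves only when one of its two
flanking agents is chosen focal and copies its neighbour across the
boundary, fitness-proportionally — and `stepping_probabilities()` computes
them from explicit payoffs via `payoff()`. Where every label within reach
is blue the two strategies act identically and the walk is exactly
unbiased; bias is confined to within three positions of a green label
(asserted as an exact, not approximate, test).

`boundary_chain()` assembles the chain and its stationary weights by
detailed balance, $\pi_{k+1}/\pi_k = P_\rightarrow(k) / P_\leftarrow(k+1)$,
accumulated in log space so strong selection cannot overflow. Interior
zero-probability moves are an error naming the offending position, because
they would disconnect the chain.

### The single-green line and the closed form

For an otherwise blue line with one green agent at $g$, the stationary odds
that the discriminating strategy covers the green agent come out in closed
form:

$$\frac{\pi(\text{discrimination dominates})}{\pi(\text{full cooperation dominates})}
  \;=\; \frac{e^{2w}}{\tanh(wb) + 1},$$

equal to $e^{(2-b)w}\cosh(wb)$ — equal to 1 at $w = 0$, dipping below 1 for
$b > 2$ at small $w$, and crossing 1 from below as $w$ grows. For
$b \gg 1$ it tends to $e^{2w}/2$, so discrimination wins for all
$w > \log(2)/2 \approx 0.3466$ *no matter how large the cooperation
benefit* — the central discrimination condition.

Two reading choices are deliberately exposed rather than hidden
(`stationary_ratio(method = )`):

* `"plateau"` — the ratio of the two unbiased plateau weights flanking the
  green agent: the infinite-line limit with equal side lengths. This is the
  quantity the closed form describes, and the package reproduces it to
  machine precision on a 41-agent line (the plateau product involves only
  the biased window, so line length does not limit the agreement).
* `"mass"` — exact aggregation of the finite chain's weights with the cut
  at "which strategy does the green agent hold" ($k \le g-1$ vs
  $k \ge g$). This includes the reflecting-end weights (the pinned end
  agents have degree 1 and different payoffs, which attracts measurable
  weight to the terminal positions at large $wb$) and is therefore the
  right comparison for the Monte-Carlo oracle, which simulates the same
  finite line.

`monte_carlo_boundary()` is that oracle: the full imitation dynamics with
pinned ends, boundary side tallied at thinned samples. Its standard error
uses **batch means** (20 consecutive batches) rather than a raw binomial
formula, because thinned samples along one trajectory are correlated; the
delta method transfers the SE to the odds ratio. Chain and oracle agree
within 3 SE across $(w, b) \in \{0.1, 0.3, 0.5\} \times \{2, 5, 10\}$ in
the test suite.

### Repeated patterns and transition lines

For a line labelled by tiling a short pattern, the stationary weight ratio
across one period, evaluated in the bulk, is a function of $b$ at fixed
$w$; `transition_line()` bisects it to the critical benefit $b^\ast$
(tolerance $10^{-6}$ on $b$, bracket $[1 + 10^{-6}, 64]$). The perfectly
alternating pattern gives $b^\ast = 2$ exactly, independent of $w$ — the
sharpest check in the acceptance suite, passing at $10^{-4}$. A pattern
with no green agent makes the two strategies indistinguishable; the walk is
globally unbiased and the function returns a **no-crossing sentinel**
(`NA` with `reason` and bracket attributes), distinct from a numerical
failure, which errors.

## Numerical and design choices

* Mutation includes the current strategy in its uniform draw (above).
* Imitation never includes the focal agent; copying an identical strategy
  is a legal no-op event.
* Selection weights: $\exp(w(p_j - \max_k p_k))$; $w = \infty$ as argmax
  with uniform tie-break. Weight accumulation uses extended precision in
  C++ to mirror R's summation, preserving trajectory-level parity.
* Detailed-balance products and side masses in log space (`logsumexp`).
* Bisection (not Brent) for $b^\ast$, matching the stated tolerance
  semantics `|Δb| ≤ 1e-6`.
* The Monte-Carlo oracle's default line is 41 agents: long enough that the
  biased window ($\pm 3$) and the end effects are well separated; the chain
  it is compared against models the same 41-agent line exactly, so end
  effects cancel from the comparison.
* Per-cell seeds in scans are `base_seed + cell index`; label fields are
  regenerated at every cell.

## What the synthetic populations do and do not emulate

The gradient cylinder realises a smooth regional-majority structure with
fully independent label draws; real social labels are spatially correlated
and multi-valued, group sizes drift, and interaction graphs are neither
regular nor static. Passing tests on these populations demonstrate the
internal consistency of the dynamics and the analytic theory — they do not
calibrate the model to any empirical discrimination data, and no parameter
here has been fitted to observations.

## Known limitations

* Desk-scale phase *boundaries* shift relative to the full-scale lattice
  (quantified above); only phase interiors are asserted quantitatively.
* The 1D theory covers the full-cooperation vs cooperate-with-blue
  competition; no analytic theory is provided for the 2D lattice, where
  interfaces are rough.
* At near-neutral selection the stationary state is mixing-limited;
  observables there carry large, slowly decaying fluctuations
  (`sd_payoff_norm` in results is the honest scale of that noise).
* Strategies are memoryless and labels binary by construction; birth–death
  or pairwise-comparison update rules and label mutation are out of scope.
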