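---
title: "Tracking abilities and difficulties with urns: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracking abilities and difficulties with urns: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(urnings)
```

## The problem

Computerized adaptive learning and testing systems must estimate person
abilities and item difficulties *while the data stream in*, and both sets
of parameters may drift over time. The standard online tracker, the Elo
Rating System (ERS), updates a rating after every response by a K-scaled
prediction error. It is fast and simple, but it has two well-known
statistical defects: the ratings have no known error distribution (so no
confidence statements or tests are possible), and under adaptive item
selection the cross-sectional spread of the ratings inflates without
bound even when the true traits are stationary.

This package implements an urn-based tracker that removes both defects,
together with the ERS baseline, a full simulation harness, and an
evaluation suite.

## The model

Responses follow the Rasch model: person $p$ with ability $\theta_p$
answers item $i$ with difficulty $\beta_i$ correctly with probability

$$\Pr(X_{pi}=1) = \frac{e^{\theta_p-\beta_i}}{1+e^{\theta_p-\beta_i}}.$$

Writing $\pi_p = \mathrm{logit}^{-1}\theta_p$ and
$\pi_i = \mathrm{logit}^{-1}\beta_i$, the same probability arises from a
*game of chance*: draw a marble from the person's (infinite) urn with
green-proportion $\pi_p$ and one from the item's urn with proportion
$\pi_i$, repeat until the colours differ, and let the person win if
theirs was green. Conditioning on unequal colours gives

$$\Pr(X_{pi}=1) =
  \frac{\pi_p(1-\pi_i)}{\pi_p(1-\pi_i)+\pi_i(1-\pi_p)},$$

which is algebraically identical to the Rasch probability.
`simulate_response()` draws directly from this conditional law rather
than running the literal repeat-until loop; the two are
distribution-equal, but the direct draw has bounded runtime and a
well-defined error for the degenerate case (both proportions at the same
boundary, where the loop would never terminate).

## The tracker

Each tracked entity is a **finite** urn: $n$ marbles, $u$ green, rating
$u/n$. After a response $X_{pi}$, an *expected outcome* $X^*_{pi}$ is
drawn by playing the same game with the current urn compositions
(`expected_outcome()`), and a marble exchange is proposed:

$$u_p^* = u_p + X_{pi} - X^*_{pi}, \qquad
  u_i^* = u_i - X_{pi} + X^*_{pi}.$$

The pair's total green count is conserved. (The source description of
the algorithm prints the item update with a second plus sign, which
would create marbles out of nothing and contradicts its own
remove-and-replace description; the conserving form above is the one
consistent with the acceptance ratio below, and is what this package
implements.)

The proposal is accepted with the Metropolis–Hastings probability

$$\min\!\left(1,\;
  \frac{u_p(n_i-u_i) + (n_p-u_p)u_i}
       {u_p^*(n_i-u_i^*) + (n_p-u_p^*)u_i^*}\right),$$

which makes the invariant law of each urn $\mathrm{Binomial}(n, \pi)$
rather than something depending on the opponents met along the way.
That known law is the tracker's selling point: the standard error of a
stationary rating is $\sqrt{\pi(1-\pi)/n}$ *by design*, so confidence
intervals (`binomial_ci()`), coverage checks (`coverage()`) and tests
for ability change come for free.

**Urn size is the accuracy dial.** Large urns mean small stationary
noise but slow reaction to true change; it plays the role of (the
inverse of) the ERS K-factor. The reference simulation uses 60 marbles
for persons and 200 for items; the empirical-replay defaults are 30 and
80.

### Adaptive selection and the matchmaking correction

Items are selected with probability proportional to a normal density on
the difference of the current logit ratings (`match_config()`,
kernel SD 1, offset 0 targets roughly 50% success). Selecting the
transition kernel based on the current state breaks the invariant law,
which is precisely the mechanism behind ERS variance inflation. The
repair multiplies the acceptance ratio by $M_{pi}(u^*)/M_{pi}(u)$, the
ratio of the probabilities of this very match under the proposed and
current ratings (`match_ratio()`), both normalised over the full item
pool. With the correction in force the stationary spread of the ratings
matches the binomial-implied spread; switching it off
(`correct_matchmaking = FALSE`) demonstrates measurable inflation — the
package's tests assert that ordering on matched seeds.

Replay of a *historical* log (`urnings()`) applies no correction: the
selection rule that produced the log is unknown, so the ratio cannot be
formed. This mirrors how the method must be deployed on data collected
under a different production system.

### Scale anchoring

Entities enter and leave real systems, so the rating scale is pinned by
a *core subset* of items whose total green count is held constant: when
an accepted update changes a core item's green count, a compensating
core item — drawn uniformly among members that still have a marble of
the needed colour — receives the opposite exchange. If no member can
compensate, the whole update is rolled back and the stall is logged.

### A finite-system caveat

Every accepted exchange conserves the *global* green total, so a closed
simulated system is confined to a hyperplane and the joint stationary
law is the product of binomials *conditioned on that total*. Two
consequences matter for testing. First, an isolated player–item pair
can never show binomial marginals (its total is frozen); the package's
distributional tests therefore embed a focal entity in a pool of 40+
items, where the conditioning is a sub-percent effect. Second, entity
ratings carry a weak common tilt (the fixed total need not equal the
population-expected total), which slightly perturbs coverage in small
systems. Both effects vanish as the system grows; neither exists for a
deployed system where entities come and go.

## The simulator

`sim_config()` defaults encode the reference study: 500 players and 100
items with $\theta, \beta \sim N(0,1)$ on the logit scale, urns 60/200
initialised half green, 1,000,000 sessions in which a uniformly random
player answers 10 adaptively selected items, kernel SD 1, correction on.
An optional jump (`jump =`) switches one player's true ability mid-run
to exercise tracking lag. The ERS arm (`engine = "elo"`) uses K = 0.25,
all ratings starting at zero, with the same kernel applied to the Elo
ratings (the reference description of its selection rule says only that
it targets about 50% correct).

What the generator deliberately does *not* emulate: player arrival and
dropout, item exposure constraints, response times, learning *during*
the run for the population at large, or polytomous/multidimensional
responses. Passing tests therefore show that the tracker recovers and
covers stationary Rasch traits under adaptive selection — not that real
learner streams satisfy the Rasch model.

### Problem sizes used in the checks

The packaged checks run the reference design at 110,000 sessions instead
of 1,000,000: every person then has ~2,200 updates and every item
~11,000, an order of magnitude past the burn-in convention (below), and
the stationary law does not depend on run length beyond that. The
variance-inflation comparison uses 200 players, 50 items and 40,000
(ERS) / 80,000 (urn) single-item sessions over 20 seeds; the urn arm of
that comparison uses urns of 30/80 so that even extreme-trait players
are fully equilibrated well before the measurement window. Jump-lag
checks use 100 players, 50 items, a burn-in of 3,000 sessions and a
jump to $\theta = 2$.

## Numerical and convention choices

- **Confidence intervals.** Two conventions are exposed.
  `method = "normal"` (default) takes the integers inside
  $n\pi \pm z\sqrt{n\pi(1-\pi)}$ — the band drawn in rating plots; its
  average coverage over a standard-normal trait population is 95.0% at
  the 95% level for both urn sizes used here. `method = "exact"` takes
  equal-tail binomial quantiles, which discreteness makes conservative
  (96.5% / 95.8% average coverage at $n$ = 60 / 200). With only 100
  items a measured coverage has a standard error around 2 percentage
  points, so observed values in the low 90s and high 90s are both
  compatible with nominal.
- **Burn-in.** "Three times the urn size" is counted as updates
  *received by an entity* (accepted or rejected), the most natural
  per-entity reading; summaries flag entities still inside it.
- **Boundary urns.** Logits of $0/n$ and $n/n$ are continuity-corrected
  by half a marble for matchmaking and logit-scale summaries, keeping
  every item selectable.
- **Degenerate games.** When both urns are all-green or both all-red the
  expected-outcome draw is undefined; the update is skipped and counted
  (`state$skips`) instead of looping forever.
- **Randomness.** Environment randomness (population draws, player and
  item selection, true responses) uses R's global RNG seeded from the
  run seed; the update decisions (expected-outcome draw, accept draw,
  anchoring pick) consume a separate buffered uniform stream with its
  own generator state. The split makes a replay of a simulated log
  reproduce the simulation's urn trajectory bit-exactly under the same
  seed, and lets `save_state()`/`load_state()` resume a run without any
  drift.
- **Acceptance-ratio arithmetic** is done in doubles (integer products
  overflow for very large urns), and selection weights are normalised in
  log space so extreme logit differences cannot underflow to an
  all-zero weight vector.

## Known limitations

- Urn sizes are fixed per entity class; adapting them to response
  frequency (growing for precision, shrinking for responsiveness) is a
  natural extension not implemented here.
- The matchmaking correction covers one-sided item selection for the
  current player; systems where players are also competitively matched
  to scarce items would need a two-sided correction.
- Replay cannot correct for the (unknown) adaptive selection that
  produced a historical log, so replayed ratings inherit a mild
  selection dependence; the reference analysis has the same property.
- The binomial error law holds for *stationary* traits. During genuine
  ability change the rating lags the truth (by design, at a speed set by
  the urn size), and interval statements are only asymptotically valid
  again after the change settles.
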