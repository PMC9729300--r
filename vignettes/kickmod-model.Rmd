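---
title: "The kickmod movement model: assumptions, parameters, and validation toolkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The kickmod movement model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

kickmod simulates the movement of 22 football players as *purely reactive*
point agents on a discrete 100 ms clock. Reactive means memoryless: at every
tick each player maps the current perceived state straight to one of seven
actions, with no learning, planning horizon, or internal state beyond the
endogenous attributes. This vignette documents the model itself — its
assumptions, every tunable parameter, and the numerical choices made where
the conceptual model is silent — and what the accompanying
verification/validation toolkit does and does not establish.

## The world

The pitch is a 110 m by 60 m rectangle, origin at the centre, x-axis along
the pitch length. Team A (players 1–11) defends the goal at x = −55 and
attacks +x; team B (12–22) the reverse. Goals are 7.32 m mouths centred on
y = 0. A 0.5 m raster grid exists only for rendering parity and role-box
rasterisation; the agents themselves move in continuous coordinates.

Each player owns a *role box*, an axis-aligned rectangle it should mostly
stay and move within. A formation is a team's set of 11 role boxes; the
offered options are 3-5-2, 4-4-2 and 4-3-3. The exact role-box extents are not part of
the conceptual model, so the shipped extents
(`inst/extdata/formations.csv`) are explicit modelling assumptions: the
goalkeeper box spans the penalty area, and defender/midfielder/forward bands
cover overlapping thirds of the pitch. They are plain-text and editable;
everything downstream adapts. Box membership is *closed* (the boundary
counts as inside) so that agents do not oscillate at edges. Side B boxes are
always the point reflection of side A's through the pitch centre.

The ball is a passive environmental actor: possessed, it rides with its
possessor; free, it advances ballistically with a per-tick friction factor.

## Players

Players carry six endogenous attributes on a 0–100 scale: energy (dynamic),
stamina, pace, shooting, agility and teamwork (static bases). The shipped
roster (`default_roster()`) gives both goalkeepers agility 10 and fills the
outfielders with heterogeneous values; energy starts at 100 for everyone.

Two mechanisms make the attributes dynamic:

* **Energy decay.** Per tick,
  `delta = base_rate * (1 + (100 - stamina)/100) * (0.5 + step_length)`,
  floored at 0. The functional form is a modelling choice (only the
  qualitative facts are given: energy falls over time, faster for low
  stamina); the default `base_rate = 0.005` makes energy decline visibly
  but not exhaust over a 5000-tick horizon. Configuration C2 switches
  consumption off entirely, under which energy is exactly constant.
* **Effective attributes.** Static abilities are scaled by energy:
  `effective = base * (floor + (1 - floor) * energy/100)` with
  `floor = 0.5`, i.e. a fully exhausted player retains half of each
  ability. Again only the direction ("abilities fluctuate with energy") is
  prescribed; the linear-with-floor shape is ours.

**Kinematics.** The hard caps are 1 m displacement and 180° turn per 100 ms
tick. The cap is scaled by the effective pace fraction
(`effective_pace / 100`), which is what makes pace kinematically
meaningful; headings always point along the realised displacement and are
unchanged when a player holds position. Positions are clamped to the pitch.

## The decision table

Perception starts from *who possesses the ball?* — four scenarios — and
resolves through a handful of causal factors to exactly one action:

| Scenario | Rule | Action |
|---|---|---|
| Opponent has it | 1st/2nd defender and ball within pressing range | Act3 get the ball |
| | else, ball close / far | Act2 mark / Act1 roam |
| No one has it | 1st/2nd defender | Act3 |
| | else, ball close / far | Act2 / Act1 |
| I have it | close to opponent goal with < 2 opponents in the corridor, **or** pressed close to own goal | Act6 shoot/clear |
| | corridor clear (0 between, or 1 and dribbling beats passing) and carrying stays in the box | Act4 carry |
| | otherwise | Act5 pass |
| Teammate has it | always | Act7 open up space |

Notes on the contested points:

* The *1st/2nd defender* are a team's two players nearest the ball; only
  they may press, capping ball pressure at two players per team. Ranks are
  computed once per tick from tick-start positions (part of perception),
  with deterministic lower-id tie-breaks.
* "Can I get the ball?" is operationalised as being a ranked defender with
  the ball inside `press_range`. The conceptual model leaves this predicate
  implicit.
* The no-possessor scenario admits more than one reading; the
  reconstruction implemented (ranked defenders chase, everyone else marks
  or roams by ball distance) is documented here as the package's own.
* Within *I have it*, the shot branch is evaluated first: a player in
  shooting range shoots rather than carries. The table rows do not state a
  precedence; this one is ours.
* Dribble skill is effective agility and pass skill effective teamwork —
  the decision factors reference dribbling/passing abilities that the
  attribute roster does not contain. Both mappings are configurable design choices.
* Goalkeepers and defenders pressed near their own goal execute Act6 as a
  defensive clearance upfield rather than an attempt on goal; goalkeepers
  execute Act2 as interposition on the ball–own-goal segment (at
  `gk_depth` metres off the goal line) whenever the ball is close.

The table logic is exposed twice: `decide_action()` evaluates the factors
geometrically from a live state, and `action_from_factors()` is the bare
mapping from already-evaluated factors. The test suite checks the bare
mapping exhaustively against an independently hand-coded oracle and checks
on live states that both routes agree.

## Action execution and ball mechanics

Movement targets: Act1 draws a uniform point in the player's own box (a new
draw each tick — reactive agents keep no target memory); Act2 heads to the
marked opponent (fixed nearest-box assignment under man-to-man, nearest
opponent to one's box under zonal); Act3 to the ball; Act4 toward the
opponent goal with the ball; Act7 to the candidate-grid point of the box
farthest from any opponent (a `act7_grid`-per-axis grid, corners included).
Act5/Act6 hold position and launch the ball.

Passes are never backward: `select_pass_target()` only considers teammates
strictly closer to the opponent goal line, maximising openness (distance to
the nearest opponent) with shortest-pass and lower-id tie-breaks. With no
forward teammate the player keeps carrying instead — the simplest total
fallback. Shots aim at a uniform point in the goal mouth plus Gaussian
scatter with s.d. `aim_noise * (100 - effective_shooting)/100`.

Ball flights move at `pass_speed` (3 m/tick) or `shot_speed` (5 m/tick) and
decay by `friction` (0.9) per tick; below `ball_stop` (0.2 m/tick) the ball
is at rest. Any player within `intercept_radius` (1 m) of the tick's flight
segment triggers a possession contest; contests are won by the highest
effective agility, exact ties uniformly at random from the run's single RNG
stream. A ball at rest is picked up through the same contest by Act3
players within `possession_radius`.

Three numerical choices deserve explicit mention because they fix
degeneracies that a naive reading produces:

* **Perimeter bounce.** No out-of-bounds events are modelled. A free ball
  that would leave the pitch reflects off the perimeter with restitution
  0.7 instead of being clamped dead onto the line: a dead clamp parks the
  ball exactly on the goal line, where play collapses into an absorbing
  boundary state (shots along the line can never cross it).
* **Launch-free zone.** On the launch tick, the first `launch_free` (2 m)
  of the flight path is exempt from interception, and in-flight balls are
  excluded from the at-rest pickup. Without this, the defender already
  pressing the passer wins the ball back in the same tick before it has
  moved, every time; completed passes become near-impossible and
  two-player contests deadlock.
* **Kickoffs without teleports.** The 1 m/tick step bound is treated as
  inviolable over the whole trace, so players are never repositioned by
  the engine. After a goal the conceding team's outfielder currently
  nearest the centre spot restarts with the ball in place; the initial
  kickoff hands the ball to team A's most advanced forward placed at the
  centre spot before the first tick.

A ball carried or landing on the goal line inside the mouth scores;
movement along the goal line never does.

## Engine, configurations, reproducibility

Within a tick, players update sequentially in a freshly shuffled order
(NetLogo-style `ask`), each perceiving the mid-tick world; then the ball
advances, goals are detected, and energies decay. Everything is recorded
every tick, so a trace of `n` ticks holds `22n` player records. A trace is
a pure function of (configuration, seed); replicate `i` of a replicate set
uses `base_seed + i - 1`, which is the documented scheme for reproducing
published runs.

The five one-factor-at-a-time configurations hold everything at the C1
baseline except one factor: C1 both teams 3-5-2, man-to-man, energy on;
C2 energy off; C3 team B 4-3-3; C4 team A 4-3-3; C5 both teams zonal.

## The analytics toolkit

* `action_frequency_series()` / `horizon_representativeness()`: per-tick
  action shares (summing to 100%) and a split-window comparison of
  within-window standard deviations, used to argue that a 5000-tick
  horizon represents the model behaviour.
* `cv_stabilization()`: the replicate-count question. Per outcome (we use
  per-action total frequencies per replicate), CV = sd/mean over the first
  k replicates, aggregated as the mean over outcomes. The stabilization
  count is the smallest k whose aggregated curve changed by less than
  `tol = 5%` over `window = 5` consecutive counts — the concrete
  tolerance-and-window criterion is this package's own; both knobs are
  arguments. Zero-mean outcomes are flagged
  and excluded.
* `relative_orientation_histogram()`: the signed smallest angle from a
  player's heading to the bearing of a target, binned into 36 classes of
  10°; class c covers [c−5°, c+5°), and the sign convention is negative =
  left turn needed. Class 0 is the headline "oriented towards the target"
  share. `relative_distance_summary()` gives the paired distance series.
* `possession_matrix()`: completed passes accumulate in a 22×22 from/to
  matrix (same-team cells only, by construction); possession changes
  between teams accumulate per winning team, without naming players.
* `role_box_occupancy()`: distance-to-box-centre distributions and
  inside-box tick fractions.
* `variability_summary()` / `deviation_from_baseline()`: per-run action
  shares compared across configurations at player, role, team or
  aggregate level.

## What the generator does and does not emulate

Traces are generated by the model itself — there is no external data. The
simulator emulates spatially constrained, attribute-modulated, reactive
movement and possession flow; it does not emulate set pieces (fouls,
offsides, corners, throw-ins, substitutions are all excluded), psychological
state, tactical adaptation, or anything data-driven. Quantities the conceptual model
does not pin down numerically (thresholds for "close", ball speeds, decay
rates) are fixed at the defaults above; consequently, passing tests
establishes internal consistency of this implementation under its stated
conditions, not fidelity to real match data — empirical calibration is
explicitly out of scope.

Two model-level behaviours are known consequences of the defaults rather
than bugs: completed forward passes are relatively rare (tight interception
radii around crowded midfields), and scoring is frequent by real-football
standards (shot scatter is small for high-shooting players and contests
near the mouth are agility-dominated, and goalkeepers have agility 10).
Both could be moved with the documented parameters without touching any
interface.

## Problem sizes used by the checks

The operational checks run the model at its study conditions: 5000-tick
runs; 30 C1 replicates for the CV curve (the orientation reference points
use the first 20, matching the replicate count at which the curve is
expected to stabilise); 20 C3 replicates; 5 replicates per configuration
for the sensitivity ordering. Unit tests use 120–600-tick runs, which are
ample for the per-tick invariants they assert.

```{r example}
library(kickmod)
tr <- run_match(preset("C1", ticks = 5000, seed = 1))
glance(tr)
relative_orientation_histogram(tr, 10, "ball")
autoplot(tr, players = c(1, 10, 18))
```
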