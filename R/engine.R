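#' Simulation configuration
#'
#' Bundles everything that determines a run: the roster, the two formations,
#' each team's marking plan, whether energy is consumed, the numeric
#' parameters, the pitch, the horizon and the seed. Together with the seed
#' the configuration fully determines the trace.
#'
#' @param ticks Number of 100 ms ticks to simulate (default 5000, i.e. 500
#'   simulated seconds).
#' @param seed Integer seed for the single RNG stream of the run.
#' @param formation_a,formation_b Formation names for teams A and B.
#' @param marking_a,marking_b Marking plan per team, `"man-to-man"` or
#'   `"zonal"`.
#' @param energy_consumption Logical; `FALSE` switches energy drain off.
#' @param params A [sim_params()] list (individual entries may be overridden
#'   by passing a modified list).
#' @param pitch A [pitch_config()].
#' @param roster A 22-row roster tibble, see [default_roster()].
#' @return An object of class `sim_config`.
#' @seealso [preset()] for the C1-C5 one-factor-at-a-time configurations.
#' @export
sim_config <- function(ticks = 5000, seed = 1,
                       formation_a = "3-5-2", formation_b = "3-5-2",
                       marking_a = "man-to-man", marking_b = "man-to-man",
                       energy_consumption = TRUE,
                       params = sim_params(), pitch = pitch_config(),
                       roster = default_roster()) {
  if (ticks < 1) abort("ticks must be >= 1", class = "kickmod_config_error")
  structure(
    list(ticks = as.integer(ticks), seed = as.integer(seed),
         formation_a = formation_a, formation_b = formation_b,
         marking_a = marking_a, marking_b = marking_b,
         energy_consumption = isTRUE(energy_consumption),
         params = params, pitch = pitch, roster = roster),
    class = "sim_config"
  )
}

#' One-factor-at-a-time configuration presets
#'
#' The five sensitivity configurations. C1 is the default setting (both teams
#' 3-5-2, man-to-man marking, energy consumed); each of C2-C5 changes exactly
#' one factor against that baseline:
#' * `C1` — default setting.
#' * `C2` — players do not consume energy.
#' * `C3` — team B plays 4-3-3 instead.
#' * `C4` — team A plays 4-3-3 instead.
#' * `C5` — both teams follow a zonal marking plan.
#'
#' @param name One of `"C1"` ... `"C5"`.
#' @param ... Further arguments passed to [sim_config()] (e.g. `ticks`,
#'   `seed`, `params`).
#' @return A [sim_config()].
#' @examples
#' preset("C2")$energy_consumption
#' @export
preset <- function(name, ...) {
  switch(name,
    C1 = sim_config(...),
    C2 = sim_config(energy_consumption = FALSE, ...),
    C3 = sim_config(formation_b = "4-3-3", ...),
    C4 = sim_config(formation_a = "4-3-3", ...),
    C5 = sim_config(marking_a = "zonal", marking_b = "zonal", ...),
    abort(paste0("unknown preset '", name, "'; valid presets are C1..C5"),
          class = "kickmod_preset_error")
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config> ", x$ticks, " ticks, seed ", x$seed, "\n",
      "  formations: A ", x$formation_a, " / B ", x$formation_b, "\n",
      "  marking: A ", x$marking_a, " / B ", x$marking_b, "\n",
      "  energy consumption: ", if (x$energy_consumption) "on" else "off",
      "\n", sep = "")
  invisible(x)
}

#' Run a match simulation
#'
#' Advances the 22 reactive agents and the ball for `config$ticks` ticks of
#' 100 ms. Within each tick the players are updated sequentially in a freshly
#' shuffled order (each perceives the current state, selects an action from
#' the decision table and executes it), then the ball advances, goals are
#' detected, and energies decay. Every tick is recorded, so the trace is a
#' pure function of the configuration and seed.
#'
#' @param config A [sim_config()] or [preset()] output.
#' @param seed Optional override of `config$seed`.
#' @return An object of class `match_trace`: a list with
#'   \describe{
#'     \item{players}{tibble `tick, player_id, team, role, x, y, heading,
#'       energy, action` (`ticks * 22` rows).}
#'     \item{ball}{tibble `tick, x, y, vx, vy, possessor`.}
#'     \item{events}{tibble `tick, kind, from, to, team` of discrete events
#'       (`pass_complete`, `possession_change_between_teams`, `shot`,
#'       `goal`).}
#'     \item{boxes}{tibble of each player's role box.}
#'     \item{config}{the generating configuration.}
#'   }
#' @examples
#' tr <- run_match(preset("C1", ticks = 50, seed = 1))
#' glance(tr)
#' @export
run_match <- function(config = preset("C1"), seed = NULL) {
  if (!inherits(config, "sim_config")) {
    abort("config must be a sim_config", class = "kickmod_config_error")
  }
  if (!is.null(seed)) config$seed <- as.integer(seed)
  set.seed(config$seed)
  w <- init_match(
    roster = config$roster,
    formation_a = build_formation(config$formation_a, "A", config$pitch),
    formation_b = build_formation(config$formation_b, "B", config$pitch),
    pitch = config$pitch, params = config$params,
    marking = c(config$marking_a, config$marking_b),
    energy_consumption = config$energy_consumption
  )
  nt <- config$ticks
  X <- matrix(0, nt, 22L); Y <- matrix(0, nt, 22L)
  H <- matrix(0, nt, 22L); E <- matrix(0, nt, 22L)
  A <- matrix(0L, nt, 22L)
  BX <- numeric(nt); BY <- numeric(nt)
  BVX <- numeric(nt); BVY <- numeric(nt); BP <- integer(nt)
  for (t in seq_len(nt)) {
    .step_tick(w)
    X[t, ] <- w$x; Y[t, ] <- w$y; H[t, ] <- w$heading
    E[t, ] <- w$energy; A[t, ] <- w$action
    BX[t] <- w$bx; BY[t] <- w$by; BVX[t] <- w$bvx; BVY[t] <- w$bvy
    BP[t] <- w$poss
  }
  players <- tibble(
    tick = rep(seq_len(nt), times = 22L),
    player_id = rep(1:22, each = nt),
    team = rep(c("A", "B")[w$team], each = nt),
    role = rep(w$role, each = nt),
    x = as.vector(X), y = as.vector(Y),
    heading = as.vector(H), energy = as.vector(E),
    action = paste0("Act", as.vector(A))
  )
  ball_tb <- tibble(tick = seq_len(nt), x = BX, y = BY, vx = BVX, vy = BVY,
                    possessor = ifelse(BP > 0L, BP, NA_integer_))
  events <- tibble(tick = w$ev_tick, kind = w$ev_kind,
                   from = w$ev_from, to = w$ev_to, team = w$ev_team)
  boxes <- tibble(player_id = 1:22, team = c("A", "B")[w$team],
                  role = w$role, xmin = w$bxmin, ymin = w$bymin,
                  xmax = w$bxmax, ymax = w$bymax)
  structure(list(players = players, ball = ball_tb, events = events,
                 boxes = boxes, config = config),
            class = "match_trace")
}

#' @export
print.match_trace <- function(x, ...) {
  cat("<match_trace> ", max(x$players$tick), " ticks, ",
      nrow(x$events), " events (",
      sum(x$events$kind == "pass_complete"), " passes, ",
      sum(x$events$kind == "goal"), " goals)\n", sep = "")
  invisible(x)
}

#' Advance a match state tick by tick
#'
#' Low-level driver behind [run_match()]: advances the given state in place
#' by `ticks` ticks (shuffled sequential player updates, ball phase, goal
#' detection, energy decay) without recording a trace. Randomness is drawn
#' from the global RNG stream; call `set.seed()` first for reproducibility.
#'
#' @param state A `match_state` from [init_match()].
#' @param ticks Number of ticks to advance.
#' @return The state, invisibly.
#' @export
step_match <- function(state, ticks = 1) {
  for (t in seq_len(ticks)) .step_tick(state)
  invisible(state)
}

#' Run replicate simulations
#'
#' Runs `n` replicates of the same configuration with seeds
#' `base_seed, base_seed + 1, ..., base_seed + n - 1`, the documented seeding
#' scheme for reproducible published runs.
#'
#' @param config A [sim_config()].
#' @param n Number of replicates (`>= 1`).
#' @param base_seed Seed of the first replicate.
#' @param .f Function applied to each trace before it is returned; use a
#'   summariser (e.g. [action_counts()]) to avoid holding all full traces in
#'   memory.
#' @return A list of length `n` of `.f(trace)` values, with the seeds as a
#'   `seeds` attribute.
#' @export
run_replicates <- function(config, n, base_seed = config$seed,
                           .f = identity) {
  if (n < 1) abort("n must be >= 1", class = "kickmod_argument_error")
  seeds <- base_seed + seq_len(n) - 1L
  out <- lapply(seeds, function(s) .f(run_match(config, seed = s)))
  attr(out, "seeds") <- seeds
  out
}

#' @rdname tidy.match_trace
#' @method glance match_trace
#' @export
glance.match_trace <- function(x, ...) {
  ev <- x$events
  tibble(
    ticks = max(x$players$tick),
    n_players = dplyr::n_distinct(x$players$player_id),
    passes = sum(ev$kind == "pass_complete"),
    possession_changes = sum(ev$kind == "possession_change_between_teams"),
    shots = sum(ev$kind == "shot"),
    goals = sum(ev$kind == "goal"),
    final_energy_mean = mean(x$players$energy[x$players$tick ==
                                                max(x$players$tick)])
  )
}

#' Tidy a match trace
#'
#' `tidy()` returns the per-tick player table; `glance()` a one-row summary
#' (event totals and mean final energy).
#'
#' @param x A `match_trace`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy match_trace
#' @export
tidy.match_trace <- function(x, ...) {
  x$players
}
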