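#' Simulation parameters
#'
#' All numeric knobs of the decision rules, kinematics, ball mechanics and
#' energy model, with their defaults. The decision thresholds operationalise
#' the qualitative "close"/"far" conditions of the action table; none of them
#' is prescribed by the underlying conceptual model, so every one is
#' configurable here and via the `params` field of [sim_config()].
#'
#' @param ball_close Metres within which the ball counts as "close" (Act-2
#'   versus Act-1 branch).
#' @param goal_close Metres within which a goal counts as "close" (shooting
#'   range and defensive-clearance range).
#' @param opponent_close Metres within which an opponent counts as pressing.
#' @param press_range Metres within which a ranked (1st/2nd) defender commits
#'   to winning the ball (Act-3).
#' @param corridor_width Width in metres of the corridor used when counting
#'   opponents between a player and the goal.
#' @param max_step Maximum displacement per tick in metres (hard cap).
#' @param pass_speed,shot_speed Launch speed of passes and shots, metres/tick.
#' @param friction Multiplicative per-tick speed decay of a free ball.
#' @param ball_stop Speed below which a free ball is considered at rest.
#' @param intercept_radius Metres within which a flying ball can be contested.
#' @param possession_radius Metres within which a rolling/held ball can be
#'   contested.
#' @param energy_base_rate Base energy drain per tick; see [decay_energy()].
#' @param attr_floor Fraction of a static attribute retained at zero energy;
#'   see [effective_attribute()].
#' @param gk_depth Metres the goalkeeper stands off the goal line when
#'   interposing between ball and goal (goalkeeper Act-2 variant).
#' @param aim_noise Metres of aim scatter (s.d.) for a player with zero
#'   effective shooting; scaled down linearly with effective shooting.
#' @param clearance_length Metres upfield a defensive clearance is aimed.
#' @param launch_free Metres of the launch-tick flight path exempt from
#'   interception (the kicked ball outpaces defenders in immediate reach).
#' @param act7_grid Number of candidate points per axis when searching the
#'   role box for the most open spot (Act-7).
#' @return A named list of parameters.
#' @export
sim_params <- function(ball_close = 15, goal_close = 20, opponent_close = 5,
                       press_range = 20, corridor_width = 4,
                       max_step = 1, pass_speed = 3, shot_speed = 5,
                       friction = 0.9, ball_stop = 0.2,
                       intercept_radius = 1, possession_radius = 1,
                       energy_base_rate = 0.005, attr_floor = 0.5,
                       gk_depth = 4, aim_noise = 8, clearance_length = 35,
                       launch_free = 2, act7_grid = 5) {
  p <- list(ball_close = ball_close, goal_close = goal_close,
            opponent_close = opponent_close, press_range = press_range,
            corridor_width = corridor_width, max_step = max_step,
            pass_speed = pass_speed, shot_speed = shot_speed,
            friction = friction, ball_stop = ball_stop,
            intercept_radius = intercept_radius,
            possession_radius = possession_radius,
            energy_base_rate = energy_base_rate, attr_floor = attr_floor,
            gk_depth = gk_depth, aim_noise = aim_noise,
            clearance_length = clearance_length, launch_free = launch_free,
            act7_grid = act7_grid)
  ok <- vapply(p, function(v) {
    is.numeric(v) && length(v) == 1 && is.finite(v) && v >= 0
  }, logical(1))
  stopifnot(all(ok))
  p
}

DEF_ROLES <- c("CB", "lCB", "rCB", "lB", "rB")

#' Initialise a match state
#'
#' Breeds the 22 player agents and the ball. Players start at the centres of
#' their role boxes with the energies given in the roster; the ball starts at
#' the pitch centre, possessed by the kickoff player of team A (its most
#' advanced outfielder, the central/lower-id forward), who is placed at the
#' centre spot.
#'
#' The returned state is a mutable environment, advanced in place by the
#' engine; use [players()] / [ball()] to inspect it as tibbles.
#'
#' @param roster 22-row attribute table, see [default_roster()].
#' @param formation_a,formation_b [build_formation()] objects for sides A/B,
#'   or formation names.
#' @param pitch A [pitch_config()].
#' @param params A [sim_params()] list.
#' @param marking Marking plan, `"man-to-man"` or `"zonal"`, length 1 or 2
#'   (team A, team B).
#' @param energy_consumption Logical; `FALSE` reproduces the C2 setting where
#'   players do not consume energy.
#' @return An environment of class `match_state`.
#' @examples
#' st <- init_match()
#' players(st)
#' @export
init_match <- function(roster = default_roster(),
                       formation_a = "3-5-2", formation_b = "3-5-2",
                       pitch = pitch_config(), params = sim_params(),
                       marking = "man-to-man", energy_consumption = TRUE) {
  roster <- validate_roster(roster)
  if (is.character(formation_a)) {
    formation_a <- build_formation(formation_a, "A", pitch)
  }
  if (is.character(formation_b)) {
    formation_b <- build_formation(formation_b, "B", pitch)
  }
  marking <- match.arg(marking, c("man-to-man", "zonal"), several.ok = TRUE)
  if (length(marking) == 1) marking <- rep(marking, 2)

  w <- new.env(parent = emptyenv())
  w$pitch <- pitch
  w$p <- params
  w$n <- 22L
  w$team <- rep(c(1L, 2L), each = 11L)
  w$attack_dir <- c(1, -1)
  w$team_idx <- list(1:11, 12:22)

  boxes <- c(formation_a$boxes, formation_b$boxes)
  w$role <- vapply(boxes, function(b) b$role, character(1))
  w$is_gk <- w$role == "G"
  w$is_def <- w$role %in% DEF_ROLES
  w$bxmin <- vapply(boxes, function(b) b$xmin, numeric(1))
  w$bxmax <- vapply(boxes, function(b) b$xmax, numeric(1))
  w$bymin <- vapply(boxes, function(b) b$ymin, numeric(1))
  w$bymax <- vapply(boxes, function(b) b$ymax, numeric(1))
  w$cx <- (w$bxmin + w$bxmax) / 2
  w$cy <- (w$bymin + w$bymax) / 2
  w$formations <- list(formation_a, formation_b)

  w$stamina <- roster$stamina
  w$pace <- roster$pace
  w$shooting <- roster$shooting
  w$agility <- roster$agility
  w$teamwork <- roster$teamwork
  w$energy <- as.numeric(roster$energy)
  w$consume <- isTRUE(energy_consumption)
  w$marking <- marking

  # fixed man-to-man assignment: nearest opposing outfield role-box centre
  w$marked <- integer(22L)
  for (i in 1:22) {
    opp <- w$team_idx[[3L - w$team[i]]]
    opp <- opp[!w$is_gk[opp]]
    d2 <- (w$cx[opp] - w$cx[i])^2 + (w$cy[opp] - w$cy[i])^2
    w$marked[i] <- opp[order(d2, opp)[1]]
  }

  # kickoff player: most advanced outfielder, central then lower id on ties
  w$kick_id <- vapply(1:2, function(t) {
    idx <- w$team_idx[[t]]
    idx <- idx[!w$is_gk[idx]]
    adv <- w$attack_dir[t] * w$cx[idx]
    idx[order(-adv, abs(w$cy[idx]), idx)[1]]
  }, integer(1))

  # cached Act-7 candidate grids (box corners always included)
  g <- max(2L, as.integer(params$act7_grid))
  w$grid_px <- vector("list", 22L)
  w$grid_py <- vector("list", 22L)
  for (i in 1:22) {
    xs <- seq(w$bxmin[i], w$bxmax[i], length.out = g)
    ys <- seq(w$bymin[i], w$bymax[i], length.out = g)
    w$grid_px[[i]] <- rep(xs, times = g)
    w$grid_py[[i]] <- rep(ys, each = g)
  }

  w$x <- w$cx
  w$y <- w$cy
  w$heading <- ifelse(w$team == 1L, 0, 180)
  w$action <- rep(NA_integer_, 22L)
  w$step_len <- numeric(22L)
  w$first_def <- c(NA_integer_, NA_integer_)
  w$second_def <- c(NA_integer_, NA_integer_)

  # ball: kicked off by team A
  w$x[w$kick_id[1]] <- 0
  w$y[w$kick_id[1]] <- 0
  w$bx <- 0; w$by <- 0; w$bvx <- 0; w$bvy <- 0
  w$bx0 <- 0; w$by0 <- 0
  w$poss <- w$kick_id[1]
  w$last_team <- 1L
  w$fl_kind <- 0L; w$fl_from <- 0L; w$fl_team <- 0L; w$fl_new <- FALSE
  w$fl_x <- numeric(22L)

  w$ev_tick <- integer(0)
  w$ev_kind <- character(0)
  w$ev_from <- integer(0)
  w$ev_to <- integer(0)
  w$ev_team <- character(0)
  w$tick <- 0L

  class(w) <- "match_state"
  w
}

#' Inspect a match state
#'
#' @param state A `match_state` from [init_match()].
#' @return `players()`: one row per player with position, heading, energy and
#'   attributes. `ball()`: a one-row tibble with the ball position, velocity
#'   and possessor (`NA` when free).
#' @export
players <- function(state) {
  tibble(
    player_id = 1:22,
    team = c("A", "B")[state$team],
    role = state$role,
    x = state$x, y = state$y,
    heading = state$heading,
    energy = state$energy,
    stamina = state$stamina, pace = state$pace,
    shooting = state$shooting, agility = state$agility,
    teamwork = state$teamwork
  )
}

#' @rdname players
#' @export
ball <- function(state) {
  tibble(x = state$bx, y = state$by, vx = state$bvx, vy = state$bvy,
         possessor = if (state$poss > 0) state$poss else NA_integer_)
}

#' @export
print.match_state <- function(x, ...) {
  cat("<match_state> tick ", x$tick, ", ball at (",
      round(x$bx, 1), ", ", round(x$by, 1), "), ",
      if (x$poss > 0) paste0("possessed by player ", x$poss) else "free",
      "\n", sep = "")
  invisible(x)
}

# record an event
.emit <- function(w, kind, from = NA_integer_, to = NA_integer_,
                  team = NA_character_) {
  k <- length(w$ev_tick) + 1L
  w$ev_tick[k] <- w$tick
  w$ev_kind[k] <- kind
  w$ev_from[k] <- from
  w$ev_to[k] <- to
  w$ev_team[k] <- team
  invisible(w)
}
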