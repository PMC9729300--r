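#' Classify a player's perception scenario
#'
#' The first stage of the reactive policy: every decision starts from the
#' question *who possesses the ball?*, which puts the player in exactly one
#' of four scenarios.
#'
#' @param state A `match_state` from [init_match()].
#' @param player_id Player id (1-22).
#' @return One of `"OPPONENT_HAS_BALL"`, `"NO_ONE_HAS_BALL"`,
#'   `"I_HAVE_BALL"`, `"TEAMMATE_HAS_BALL"`.
#' @export
classify_scenario <- function(state, player_id) {
  poss <- state$poss
  if (poss == 0L) return("NO_ONE_HAS_BALL")
  if (poss == player_id) return("I_HAVE_BALL")
  if (state$team[poss] == state$team[player_id]) return("TEAMMATE_HAS_BALL")
  "OPPONENT_HAS_BALL"
}

#' Rank a team's defenders relative to the ball
#'
#' The 1st defender is the team's player currently nearest the ball; the 2nd
#' defender is the next nearest (the immediate support). Only these two may
#' press the ball (Act-3), capping the pressure at two players per team.
#' Ties are broken deterministically by lower id.
#'
#' @param state A `match_state`.
#' @param team `"A"` or `"B"`.
#' @return Named integer vector `c(first = id, second = id)`.
#' @export
rank_defenders <- function(state, team) {
  t <- if (identical(team, "A")) 1L else if (identical(team, "B")) 2L
       else as.integer(team)
  idx <- state$team_idx[[t]]
  d2 <- (state$x[idx] - state$bx)^2 + (state$y[idx] - state$by)^2
  o <- order(d2, idx)
  c(first = idx[o[1]], second = idx[o[2]])
}

#' Count opponents inside a corridor towards a target
#'
#' Counts the opposing outfielders lying within `corridor_width / 2` of the
#' segment from the player to `to`. The opposing goalkeeper is never counted
#' (a keeper on the line does not make the path "blocked").
#'
#' @param state A `match_state`.
#' @param player_id Player whose opponents are counted.
#' @param to Target point `c(x, y)` (typically the opponent goal centre).
#' @param from Segment start; defaults to the player's position.
#' @param corridor_width Corridor width in metres.
#' @return Integer count.
#' @export
opponents_between <- function(state, player_id, to,
                              from = c(state$x[player_id],
                                       state$y[player_id]),
                              corridor_width = state$p$corridor_width) {
  if (isTRUE(all.equal(from, to))) {
    abort("from and to must differ", class = "kickmod_argument_error")
  }
  .n_between(state, state$team[player_id], from[1], from[2], to[1], to[2],
             corridor_width)
}

#' Assemble a player's decision context
#'
#' Evaluates, from the current tick only (the agents are purely reactive and
#' memoryless), every causal factor the decision table consults: the
#' scenario, the distances to ball and goals, the defender ranks, the
#' corridor count towards the opponent goal, pressing opponents, the
#' dribble/pass skill comparison (effective agility versus effective
#' teamwork), and whether the next carry step would leave the role box.
#'
#' @param state A `match_state`.
#' @param player_id Player id.
#' @return A list of named scalar factors.
#' @export
decision_context <- function(state, player_id) {
  w <- state; i <- player_id; p <- w$p
  ti <- w$team[i]
  rd <- rank_defenders(w, ti)
  gox <- w$attack_dir[ti] * w$pitch$xmax
  db <- sqrt((w$x[i] - w$bx)^2 + (w$y[i] - w$by)^2)
  opp <- w$team_idx[[3L - ti]]
  nod <- sqrt(min((w$x[opp] - w$x[i])^2 + (w$y[opp] - w$y[i])^2))
  dribble <- .eff(w, w$agility, i)
  passk <- .eff(w, w$teamwork, i)
  kin <- .move_kernel(w$x[i], w$y[i], w$heading[i], gox, 0,
                      p$max_step * .eff(w, w$pace, i) / 100, w$pitch)
  list(
    scenario = classify_scenario(w, i),
    dist_ball = db,
    dist_opp_goal = sqrt((gox - w$x[i])^2 + w$y[i]^2),
    dist_own_goal = sqrt((-gox - w$x[i])^2 + w$y[i]^2),
    is_first_or_second_defender = i %in% rd,
    ball_within_press_range = db <= p$press_range,
    ball_close = db <= p$ball_close,
    opp_goal_close = sqrt((gox - w$x[i])^2 + w$y[i]^2) <= p$goal_close,
    own_goal_close = sqrt((-gox - w$x[i])^2 + w$y[i]^2) <= p$goal_close,
    opponent_close = nod <= p$opponent_close,
    n_opponents_between = .n_between(w, ti, w$x[i], w$y[i], gox, 0),
    dribble_gt_pass = dribble > passk,
    carry_leaves_box = !(kin[1] >= w$bxmin[i] && kin[1] <= w$bxmax[i] &&
                         kin[2] >= w$bymin[i] && kin[2] <= w$bymax[i])
  )
}

#' Select a player's action for the current tick
#'
#' The full perception-to-action mapping. Given the scenario, the table
#' rules are, in order of evaluation:
#'
#' * **Opponent has the ball** — press it (Act-3) if the player is the 1st or
#'   2nd defender and the ball is within pressing range; otherwise mark the
#'   nearest opponent (Act-2) when the ball is close, or move randomly in the
#'   role box (Act-1) when it is far.
#' * **No one has the ball** — the 1st/2nd defenders chase it (Act-3);
#'   everyone else marks (Act-2) or roams (Act-1) by ball distance.
#' * **I have the ball** — shoot (Act-6) when close to the opponent goal with
#'   fewer than two opponents in the corridor, or clear defensively when
#'   pressed close to the own goal (the goalkeeper/defender variant); else
#'   carry (Act-4) when the path is clear (no opponent in the corridor, or
#'   one but dribbling beats passing) and carrying stays inside the role
#'   box; otherwise pass (Act-5). The shot branch takes precedence: a player
#'   in shooting range shoots.
#' * **Teammate has the ball** — open up space inside the role box (Act-7).
#'
#' @param state A `match_state`.
#' @param player_id Player id.
#' @param ctx Optional pre-assembled [decision_context()]; validated for
#'   consistency with the state.
#' @return Action label `"Act1"` ... `"Act7"`.
#' @export
decide_action <- function(state, player_id, ctx = NULL) {
  if (!is.null(ctx)) {
    if (identical(ctx$scenario, "I_HAVE_BALL") &&
        state$poss != player_id) {
      abort("inconsistent context: scenario says I_HAVE_BALL but the ball is possessed elsewhere",
            class = "kickmod_context_error")
    }
    if (!identical(ctx$scenario, classify_scenario(state, player_id))) {
      abort("inconsistent context: scenario does not match the state",
            class = "kickmod_context_error")
    }
  }
  # ranks are part of perception; mirror the engine's tick-start computation
  .rank_defenders_tick(state)
  paste0("Act", .decide(state, player_id))
}

#' The bare decision table
#'
#' Maps a scenario plus already-evaluated boolean/count factors to an action
#' label, without touching any geometry. This is the pure second stage of the
#' policy; [decide_action()] composes it with the perceptual factors from the
#' live state. Exposed so the table can be exercised exhaustively.
#'
#' @param scenario Scenario label as in [classify_scenario()].
#' @param is_ranked_defender Is the player the 1st or 2nd defender?
#' @param ball_within_press_range Is the ball within pressing range?
#' @param ball_close Is the ball close?
#' @param opp_goal_close,own_goal_close Goal proximity flags.
#' @param opponent_close Is an opponent pressing the player?
#' @param n_opponents_between Opponents in the corridor to the opponent goal.
#' @param dribble_gt_pass Is effective dribbling higher than passing?
#' @param carry_leaves_box Would the next carry step leave the role box?
#' @return Action label `"Act1"` ... `"Act7"`.
#' @export
action_from_factors <- function(scenario,
                                is_ranked_defender = FALSE,
                                ball_within_press_range = FALSE,
                                ball_close = FALSE,
                                opp_goal_close = FALSE,
                                own_goal_close = FALSE,
                                opponent_close = FALSE,
                                n_opponents_between = 0L,
                                dribble_gt_pass = FALSE,
                                carry_leaves_box = FALSE) {
  if (scenario == "TEAMMATE_HAS_BALL") return("Act7")
  if (scenario == "OPPONENT_HAS_BALL") {
    if (is_ranked_defender && ball_within_press_range) return("Act3")
    return(if (ball_close) "Act2" else "Act1")
  }
  if (scenario == "NO_ONE_HAS_BALL") {
    if (is_ranked_defender) return("Act3")
    return(if (ball_close) "Act2" else "Act1")
  }
  if (scenario == "I_HAVE_BALL") {
    if ((opp_goal_close && n_opponents_between < 2L) ||
        (own_goal_close && opponent_close)) {
      return("Act6")
    }
    if ((n_opponents_between == 0L ||
         (n_opponents_between == 1L && dribble_gt_pass)) &&
        !carry_leaves_box) {
      return("Act4")
    }
    return("Act5")
  }
  abort(paste0("unknown scenario '", scenario, "'"),
        class = "kickmod_context_error")
}
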