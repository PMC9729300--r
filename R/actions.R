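#' Plan the execution of a selected action
#'
#' Turns an action label into a movement target and a ball command, without
#' modifying the state:
#' * Act-1: a uniformly random point inside the player's role box.
#' * Act-2: the marked opponent's position (fixed assignment under man-to-man
#'   marking, the opponent nearest the player's role box under zonal); the
#'   goalkeeper instead takes a spot on the segment between the ball and the
#'   own goal when the ball is close.
#' * Act-3: the ball's position.
#' * Act-4: towards the opponent goal, carrying the ball.
#' * Act-5: hold position and pass to [select_pass_target()]; with no
#'   forward teammate available the player keeps carrying instead.
#' * Act-6: hold position and shoot at the goal mouth (aim scatter scales
#'   with the shooter's effective shooting); when triggered as a defensive
#'   act the ball is cleared upfield instead.
#' * Act-7: the point of the role box most distant from the nearest
#'   opponent (candidate-grid search, corners included).
#'
#' Random draws (Act-1 target, Act-6 aim) use the current RNG stream.
#'
#' @param state A `match_state`.
#' @param player_id Player id.
#' @param action Action label `"Act1"` ... `"Act7"` (or integer 1-7).
#' @return A list with `target = c(x, y)`, `ball_command` (one of `"none"`,
#'   `"pass"`, `"shoot"`, `"carry"`), and for passes `pass_to` (receiver id)
#'   or for shots `aim = c(x, y)`.
#' @export
plan_action <- function(state, player_id, action) {
  a <- if (is.character(action)) match(action, ACTION_LEVELS)
       else as.integer(action)
  if (is.na(a) || a < 1L || a > 7L) {
    abort("action must be one of Act1..Act7",
          class = "kickmod_argument_error")
  }
  pl <- .plan(state, player_id, a)
  out <- list(target = c(pl$tx, pl$ty),
              ball_command = c("none", "pass", "shoot", "carry")[pl$cmd + 1L])
  if (pl$cmd == 1L) out$pass_to <- pl$to
  if (pl$cmd == 2L) out$aim <- c(pl$ax, pl$ay)
  out
}

#' Select a pass target
#'
#' Backward passes are disallowed: only teammates strictly closer to the
#' opponent goal line than the passer are candidates. Among those the most
#' open one (largest distance to its nearest opponent) is chosen, with ties
#' broken by the shortest pass and then by lower id.
#'
#' @param state A `match_state`.
#' @param passer_id Id of the player in possession.
#' @return Receiver id, or `NA` when no teammate is ahead of the passer (the
#'   caller then falls back to carrying, Act-4).
#' @export
select_pass_target <- function(state, passer_id) {
  j <- .pass_target(state, passer_id)
  if (j == 0L) NA_integer_ else j
}

#' Resolve a possession contest
#'
#' The contender with the highest effective agility wins; exact ties are
#' broken uniformly at random with the run's RNG stream. Emits a
#' `possession_change_between_teams` event when the winner's team differs
#' from the last possessing team, and a `pass_complete` event when the
#' contest concludes a pass won by a (strictly forward) teammate of the
#' passer.
#'
#' @param state A `match_state` (modified in place).
#' @param contenders Integer vector of player ids (non-empty).
#' @return The winner's id.
#' @export
resolve_possession <- function(state, contenders) {
  .contest(state, contenders)
}

#' Advance the ball by one tick
#'
#' A possessed ball moves with its possessor. A free ball advances by its
#' velocity, slows by the friction factor, and is clamped to the pitch (no
#' out-of-bounds events are modelled). A flying ball passing within the
#' interception radius of any player (other than its launcher) triggers a
#' possession contest; crossing a goal line inside the goal mouth scores a
#' goal, after which all players reset to their role-box centres and the
#' conceding team kicks off.
#'
#' @param state A `match_state` (modified in place).
#' @return The state, invisibly.
#' @export
update_ball <- function(state) {
  .ball_phase(state)
  invisible(state)
}

#' Detect a goal crossing and reset for kickoff
#'
#' Exposed form of the goal rule used by [update_ball()]: a goal is scored
#' iff the segment from `from` to `to` crosses a goal line within the goal
#' mouth.
#'
#' @param from,to Ball positions at the start and end of a tick, `c(x, y)`.
#' @param pitch A [pitch_config()].
#' @return `NA` when no goal, otherwise `"A"` or `"B"`, the scoring team
#'   (the team attacking the crossed goal line).
#' @export
detect_goal <- function(from, to, pitch = pitch_config()) {
  for (s in c(1, -1)) {
    gx <- s * pitch$xmax
    if (from[1] == gx) next            # moving along the line is never a goal
    if ((from[1] - gx) * (to[1] - gx) < 0 || to[1] == gx) {
      tt <- (gx - from[1]) / (to[1] - from[1])
      ycross <- from[2] + tt * (to[2] - from[2])
      if (abs(ycross) <= pitch$goal_width / 2) {
        return(if (s == 1) "A" else "B")
      }
    }
  }
  NA_character_
}
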