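#' Constrained kinematic step
#'
#' Moves a player one tick towards a target under the hard kinematic caps:
#' the displacement never exceeds `max_step` (1 m per 100 ms tick by
#' default) scaled by the player's effective pace fraction
#' (`effective_attribute(pace, energy) / 100`), the turning angle is at most
#' 180 degrees (any heading is reachable in one tick), and the new position
#' is clamped to the pitch. The heading afterwards points along the actual
#' displacement and is left unchanged when the player does not move.
#'
#' @param position Current position `c(x, y)`.
#' @param heading Current heading in degrees, normalised to `(-180, 180]`.
#' @param target Target point `c(x, y)`.
#' @param pace Static pace attribute in `[0, 100]`.
#' @param energy Current energy in `[0, 100]`.
#' @param pitch A [pitch_config()].
#' @param params A [sim_params()] list (uses `max_step` and `attr_floor`).
#' @return A list with `position`, `heading`, and `step_length` (metres
#'   actually travelled).
#' @examples
#' move_with_constraints(c(0, 0), 0, c(5, 0), pace = 100, energy = 100)
#' @export
move_with_constraints <- function(position, heading, target, pace = 100,
                                  energy = 100, pitch = pitch_config(),
                                  params = sim_params()) {
  frac <- effective_attribute(pace, energy, params$attr_floor) / 100
  kin <- .move_kernel(position[1], position[2], heading,
                      target[1], target[2], params$max_step * frac, pitch)
  list(position = c(kin[1], kin[2]), heading = kin[3], step_length = kin[4])
}
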