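#' Energy decay
#'
#' Per-tick energy decrement. Energy drains faster for players with lower
#' stamina and for longer steps:
#' \deqn{\delta = r \, (1 + (100 - \mathrm{stamina})/100) \, (0.5 + \ell)}
#' where \eqn{\ell} is the step length in metres and `r` the base rate per
#' tick. The result is floored at 0, and when energy consumption is disabled
#' (configuration C2) energy is returned unchanged.
#'
#' @param energy Current energy in `[0, 100]`.
#' @param stamina Static stamina in `[0, 100]`.
#' @param step_length Distance moved this tick, metres.
#' @param base_rate Base drain per tick; see [sim_params()].
#' @param consume Logical; `FALSE` disables consumption entirely.
#' @return The updated energy (vectorised over players).
#' @examples
#' decay_energy(100, stamina = 90, step_length = 1)
#' decay_energy(100, stamina = 61, step_length = 1) # drains faster
#' @export
decay_energy <- function(energy, stamina, step_length,
                         base_rate = sim_params()$energy_base_rate,
                         consume = TRUE) {
  if (!consume) return(energy)
  delta <- base_rate * (1 + (100 - stamina) / 100) * (0.5 + step_length)
  pmax(energy - delta, 0)
}

#' Effective (energy-scaled) attribute value
#'
#' Static abilities fluctuate with the player's remaining energy: at full
#' energy the base value applies; the effective value then shrinks linearly
#' to `floor_fraction * base` at zero energy.
#'
#' @param base Static attribute value in `[0, 100]`.
#' @param energy Current energy in `[0, 100]`.
#' @param floor_fraction Fraction of the base retained at zero energy.
#' @return The effective value (vectorised).
#' @examples
#' effective_attribute(80, 100) # 80
#' effective_attribute(80, 0)   # 40 with the default floor of 0.5
#' @export
effective_attribute <- function(base, energy, floor_fraction = 0.5) {
  base * (floor_fraction + (1 - floor_fraction) * energy / 100)
}
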