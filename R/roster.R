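#' The default 22-player attribute roster
#'
#' Endogenous attributes of the 22 players (ids 1-11 team A, 12-22 team B).
#' `energy` is the only dynamic attribute: it is drained over the match as a
#' function of stamina and distance covered, and in turn scales the effective
#' value of the static abilities (pace, shooting, agility, teamwork) through
#' [effective_attribute()]. Goalkeepers (ids 1 and 12) are recognisable by
#' their very low agility.
#'
#' The same table ships as a plain-text fixture at
#' `system.file("extdata", "roster.csv", package = "kickmod")`.
#'
#' @return A tibble with columns
#'   `id, team, energy, stamina, pace, shooting, agility, teamwork`.
#' @examples
#' default_roster()
#' @export
default_roster <- function() {
  read_roster(system.file("extdata", "roster.csv", package = "kickmod"))
}

#' Read and validate a player roster
#'
#' @param path CSV file with header
#'   `id, team, energy, stamina, pace, shooting, agility, teamwork`
#'   (a `role` column, if present, is carried along but roles are always
#'   assigned from the formation slot order at initialisation).
#' @return A validated 22-row tibble.
#' @export
read_roster <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  validate_roster(df)
}

validate_roster <- function(df) {
  need <- c("id", "team", "energy", "stamina", "pace", "shooting",
            "agility", "teamwork")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0) {
    abort(paste0("roster is missing column(s): ",
                 paste(missing, collapse = ", ")),
          class = "kickmod_roster_error")
  }
  if (nrow(df) != 22) {
    abort(paste0("roster must have exactly 22 rows, got ", nrow(df)),
          class = "kickmod_roster_error")
  }
  df <- df[order(df$id), , drop = FALSE]
  if (!identical(as.integer(df$id), 1:22)) {
    abort("roster ids must be exactly 1..22", class = "kickmod_roster_error")
  }
  if (!identical(as.character(df$team), rep(c("A", "B"), each = 11))) {
    abort("ids 1-11 must be team A and ids 12-22 team B",
          class = "kickmod_roster_error")
  }
  num <- c("energy", "stamina", "pace", "shooting", "agility", "teamwork")
  vals <- as.matrix(df[num])
  if (any(!is.finite(vals)) || any(vals < 0) || any(vals > 100)) {
    abort("all attribute values must lie in [0, 100]",
          class = "kickmod_roster_error")
  }
  as_tibble(df)
}
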