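#' Write and read simulation traces
#'
#' A trace is stored as three plain-text files sharing a stem: `<stem>.csv`
#' holds the per-tick records with header
#' `tick, player_id, team, role, x, y, heading, energy, action, vx, vy,
#' possessor` — one row per player per tick plus one ball row per tick with
#' `player_id = "ball"` (only ball rows use `vx, vy, possessor`) —
#' `<stem>_events.csv` the event log (`tick, kind, from, to, team`), and
#' `<stem>_config.json` the generating configuration. The round-trip is
#' lossless (`read_trace(write_trace(tr, f))` reproduces positions, actions,
#' energies, events and configuration).
#'
#' @param trace A `match_trace`.
#' @param path Path of the main CSV file (the `.csv` suffix is added when
#'   absent); the events/config files are placed next to it.
#' @return `write_trace()`: the main path, invisibly. `read_trace()`: a
#'   `match_trace`.
#' @export
write_trace <- function(trace, path) {
  stem <- sub("\\.csv$", "", path)
  main <- paste0(stem, ".csv")
  pl <- trace$players %>%
    mutate(player_id = as.character(.data$player_id),
           vx = NA_real_, vy = NA_real_, possessor = NA_integer_)
  bl <- trace$ball %>%
    mutate(player_id = "ball", team = NA_character_, role = NA_character_,
           heading = NA_real_, energy = NA_real_, action = NA_character_) %>%
    select("tick", "player_id", "team", "role", "x", "y", "heading",
           "energy", "action", "vx", "vy", "possessor")
  readr::write_csv(bind_rows(pl, bl) %>% arrange(.data$tick), main)
  readr::write_csv(trace$events, paste0(stem, "_events.csv"))
  cfg <- trace$config
  cfg$roster <- as.data.frame(cfg$roster)
  cfg$pitch <- unclass(cfg$pitch)
  jsonlite::write_json(c(unclass(cfg), list(boxes = as.data.frame(trace$boxes))),
                       paste0(stem, "_config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(main)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  stem <- sub("\\.csv$", "", path)
  main <- paste0(stem, ".csv")
  need <- c("tick", "player_id", "team", "role", "x", "y", "heading",
            "energy", "action", "vx", "vy", "possessor")
  df <- tryCatch(
    readr::read_csv(main, show_col_types = FALSE, progress = FALSE),
    error = function(e) {
      abort(paste0("cannot parse trace file '", main, "': ",
                   conditionMessage(e)), class = "kickmod_parse_error")
    })
  missing <- setdiff(need, names(df))
  if (length(missing) > 0) {
    abort(paste0("trace file is missing column(s): ",
                 paste(missing, collapse = ", ")),
          class = "kickmod_parse_error")
  }
  nt <- max(df$tick)
  if (nrow(df) != nt * 23) {
    abort(paste0("trace file is truncated or malformed: expected ",
                 nt * 23, " rows (23 per tick), found ", nrow(df),
                 "; first suspect data line ", nrow(df) + 2),
          class = "kickmod_parse_error")
  }
  is_ball <- df$player_id == "ball"
  players <- df[!is_ball, c("tick", "player_id", "team", "role", "x", "y",
                            "heading", "energy", "action")]
  players$player_id <- as.integer(players$player_id)
  players <- as_tibble(players) %>%
    arrange(.data$player_id, .data$tick) %>%
    mutate(player_id = as.integer(.data$player_id))
  ballt <- df[is_ball, c("tick", "x", "y", "vx", "vy", "possessor")] %>%
    arrange(.data$tick)
  events <- readr::read_csv(paste0(stem, "_events.csv"),
                            show_col_types = FALSE, progress = FALSE,
                            col_types = "iciic")
  cfgl <- jsonlite::read_json(paste0(stem, "_config.json"),
                              simplifyVector = TRUE)
  boxes <- as_tibble(cfgl$boxes)
  cfg <- sim_config(
    ticks = cfgl$ticks, seed = cfgl$seed,
    formation_a = cfgl$formation_a, formation_b = cfgl$formation_b,
    marking_a = cfgl$marking_a, marking_b = cfgl$marking_b,
    energy_consumption = cfgl$energy_consumption,
    params = do.call(sim_params, cfgl$params),
    pitch = do.call(pitch_config,
                    cfgl$pitch[c("length", "width", "patch_size",
                                 "goal_width")]),
    roster = as_tibble(cfgl$roster)
  )
  structure(list(players = players, ball = as_tibble(ballt),
                 events = as_tibble(events), boxes = boxes, config = cfg),
            class = "match_trace")
}
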