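# shared fixtures: small cached runs and hand-built states/traces

.run_cache <- new.env(parent = emptyenv())

# memoised short run (unit tests); acceptance-scale runs live in
# helper-acceptance.R
cached_run <- function(preset_name = "C1", ticks = 600, seed = 1) {
  key <- paste(preset_name, ticks, seed, sep = "_")
  if (is.null(.run_cache[[key]])) {
    .run_cache[[key]] <- run_match(preset(preset_name, ticks = ticks,
                                          seed = seed))
  }
  .run_cache[[key]]
}

# a match state with hand-set positions/ball, for decision/action tests.
# positions: data frame with player_id, x, y (others stay at box centres);
# ball_at: c(x, y); possessor: id or 0 (free)
make_state <- function(positions = NULL, ball_at = c(0, 0), possessor = 0L,
                       heading = NULL, ...) {
  st <- init_match(...)
  # undo the kickoff placement so positions are exactly the box centres
  st$x <- st$cx
  st$y <- st$cy
  if (!is.null(positions)) {
    st$x[positions$player_id] <- positions$x
    st$y[positions$player_id] <- positions$y
  }
  if (!is.null(heading)) st$heading <- heading
  st$bx <- ball_at[1]; st$by <- ball_at[2]
  st$bvx <- 0; st$bvy <- 0
  st$poss <- as.integer(possessor)
  if (possessor > 0) {
    st$bx <- st$x[possessor]; st$by <- st$y[possessor]
    st$last_team <- st$team[possessor]
  }
  st$bx0 <- st$bx; st$by0 <- st$by
  st
}

# minimal hand-built match_trace for analytics unit tests
toy_trace <- function(players, ball = NULL, events = NULL, boxes = NULL) {
  nt <- max(players$tick)
  if (is.null(ball)) {
    ball <- tibble::tibble(tick = seq_len(nt), x = 0, y = 0, vx = 0, vy = 0,
                           possessor = NA_integer_)
  }
  if (is.null(events)) {
    events <- tibble::tibble(tick = integer(), kind = character(),
                             from = integer(), to = integer(),
                             team = character())
  }
  if (is.null(boxes)) {
    ids <- unique(players$player_id)
    boxes <- tibble::tibble(player_id = ids, team = "A", role = "CMF",
                            xmin = -10, ymin = -10, xmax = 10, ymax = 10)
  }
  structure(list(players = players, ball = ball, events = events,
                 boxes = boxes, config = preset("C1", ticks = nt)),
            class = "match_trace")
}

# per-tick displacement / heading-change summaries of a trace
step_stats <- function(trace) {
  pl <- dplyr::arrange(trace$players, player_id, tick)
  dplyr::summarise(
    dplyr::group_by(pl, player_id),
    max_step = max(sqrt(diff(x)^2 + diff(y)^2)),
    max_turn = if (dplyr::n() > 1)
      max(abs((diff(heading) + 180) %% 360 - 180)) else 0,
    .groups = "drop"
  )
}
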