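#' Per-tick action frequency series
#'
#' For each tick, the percentage of the 22 players executing each of the
#' seven actions; the shares at every tick sum to 100%.
#'
#' @param trace A `match_trace` (or its `players` tibble).
#' @return A tibble `tick, action, share` with 7 rows per tick (absent
#'   actions appear with share 0).
#' @export
action_frequency_series <- function(trace) {
  pl <- if (inherits(trace, "match_trace")) trace$players else trace
  if (is.null(pl) || nrow(pl) == 0) {
    abort("empty trace", class = "kickmod_argument_error")
  }
  pl %>%
    count(.data$tick, .data$action) %>%
    group_by(.data$tick) %>%
    mutate(share = 100 * .data$n / sum(.data$n)) %>%
    ungroup() %>%
    select("tick", "action", "share") %>%
    tidyr::complete(tick = unique(pl$tick), action = ACTION_LEVELS,
                    fill = list(share = 0)) %>%
    arrange(.data$tick, .data$action)
}

#' Action counts and shares at a grouping level
#'
#' Total executed-action frequencies of a single run, aggregated at the
#' individual, role, team or whole-match level. This is the outcome vector
#' used for the replicate-stabilization and sensitivity-variability
#' analyses.
#'
#' @param trace A `match_trace`.
#' @param level `"player"`, `"role"`, `"team"` or `"aggregate"`.
#' @return A tibble with the grouping column (`player_id`, `role`, `team`,
#'   or none), `action`, `n` (ticks on which it was executed) and `share`
#'   (percent within the group; each group's shares sum to 100).
#' @export
action_counts <- function(trace,
                          level = c("player", "role", "team", "aggregate")) {
  level <- match.arg(level)
  pl <- trace$players
  key <- switch(level, player = "player_id", role = "role", team = "team",
                aggregate = character(0))
  out <- pl %>%
    group_by(across(all_of(key))) %>%
    count(.data$action) %>%
    mutate(share = 100 * .data$n / sum(.data$n)) %>%
    ungroup()
  grid <- c(lapply(out[key], unique), list(action = ACTION_LEVELS))
  out %>%
    tidyr::complete(!!!grid, fill = list(n = 0L, share = 0)) %>%
    arrange(across(all_of(c(key, "action"))))
}

#' Horizon representativeness of the action series
#'
#' Splits the per-tick action-share series at `split_tick` and compares the
#' within-window standard deviation of each action's share between the two
#' windows, the check used to argue that a horizon represents the model
#' behaviour (if the series is stationary, doubling the horizon changes the
#' mean SD little).
#'
#' @param trace A `match_trace`.
#' @param split_tick Last tick of the first window (must be `< max(tick)`).
#' @return A tibble `action, sd_first, sd_second, rel_diff` where `rel_diff`
#'   is `|sd_second - sd_first| / sd_first` (0 when both are 0).
#' @export
horizon_representativeness <- function(trace, split_tick) {
  fs <- action_frequency_series(trace)
  nt <- max(fs$tick)
  if (split_tick < 1 || split_tick >= nt) {
    abort("split_tick must lie strictly inside the trace horizon",
          class = "kickmod_argument_error")
  }
  fs %>%
    mutate(window = ifelse(.data$tick <= split_tick, "first", "second")) %>%
    group_by(.data$action, .data$window) %>%
    summarise(sd = stats::sd(.data$share), .groups = "drop") %>%
    tidyr::pivot_wider(names_from = "window", values_from = "sd",
                       names_prefix = "sd_") %>%
    mutate(rel_diff = ifelse(.data$sd_first == 0 & .data$sd_second == 0, 0,
                             abs(.data$sd_second - .data$sd_first) /
                               ifelse(.data$sd_first == 0, .data$sd_second,
                                      .data$sd_first)))
}

#' Replicate stabilization by coefficient of variation
#'
#' Determines how many replicate runs are needed before the model's output
#' distribution stabilises. For each outcome variable the coefficient of
#' variation (a dimensionless, normalised measure of variance, CV = sd/mean)
#' is computed over the first `k` replicates, aggregated by the mean across
#' outcomes, giving a curve CV(k). The stabilization count is the smallest
#' `k` such that the relative change of the aggregated curve stays below
#' `tol` over the last `window` consecutive replicate counts.
#'
#' @param outcomes A replicates-by-outcomes numeric matrix or data frame
#'   (e.g. per-action total frequencies per replicate, rows in replicate
#'   order).
#' @param tol Relative-change tolerance (default 5%).
#' @param window Number of consecutive replicate counts that must stay
#'   within `tol` (default 5).
#' @return An object of class `cv_curve`: a list with `curve` (tibble
#'   `k, cv`), `stabilization` (integer, `NA` if the curve never settles
#'   within the replicates provided), `excluded` (names of zero-mean
#'   outcomes, flagged and left out of the aggregation), `tol`, `window`.
#' @examples
#' m <- matrix(rnorm(60, mean = 50, sd = 5), nrow = 30)
#' cv_stabilization(m)$stabilization
#' @export
cv_stabilization <- function(outcomes, tol = 0.05, window = 5) {
  m <- as.matrix(outcomes)
  storage.mode(m) <- "double"
  if (nrow(m) < 2) {
    abort("need at least 2 replicates", class = "kickmod_argument_error")
  }
  if (is.null(colnames(m))) colnames(m) <- paste0("outcome", seq_len(ncol(m)))
  mu <- colMeans(m)
  excluded <- colnames(m)[abs(mu) < 1e-12]
  keep <- abs(mu) >= 1e-12
  if (!any(keep)) {
    abort("all outcomes have zero mean; CV is undefined",
          class = "kickmod_argument_error")
  }
  m <- m[, keep, drop = FALSE]
  ks <- 2:nrow(m)
  cv <- vapply(ks, function(k) {
    sub <- m[1:k, , drop = FALSE]
    mean(apply(sub, 2, stats::sd) / colMeans(sub))
  }, numeric(1))
  rel <- rep(NA_real_, length(cv))
  for (j in seq_len(length(cv))[-1]) {
    rel[j] <- if (cv[j - 1] == 0 && cv[j] == 0) 0
              else abs(cv[j] - cv[j - 1]) / max(cv[j - 1], 1e-12)
  }
  stab <- NA_integer_
  for (j in seq_along(ks)) {
    if (j < window + 1) next
    win <- rel[(j - window + 1):j]
    if (all(!is.na(win)) && all(win < tol)) { stab <- ks[j]; break }
  }
  structure(list(curve = tibble(k = ks, cv = cv), stabilization = stab,
                 excluded = excluded, tol = tol, window = window),
            class = "cv_curve")
}

#' @export
print.cv_curve <- function(x, ...) {
  cat("<cv_curve> ", nrow(x$curve) + 1, " replicates; stabilises at ",
      x$stabilization, " (tol ", x$tol, ", window ", x$window, ")\n",
      sep = "")
  invisible(x)
}

#' Variability of action frequencies across configurations
#'
#' Summarises per-run action frequencies (mean, median, variance) across
#' configurations and replicates at a chosen grouping level, the sensitivity
#' analysis view of the model outcomes.
#'
#' @param freqs A tibble of per-run action shares: the row-bound output of
#'   [action_counts()] over several runs, with added identifier columns
#'   (typically `config` and `replicate`).
#' @param level Grouping level the shares were computed at: `"player"`,
#'   `"role"`, `"team"` or `"aggregate"`.
#' @return A tibble per group and action with `mean`, `median`, `variance`
#'   of the share across runs, and `n_runs`.
#' @export
variability_summary <- function(freqs,
                                level = c("player", "role", "team",
                                          "aggregate")) {
  level <- match.arg(level)
  key <- switch(level, player = "player_id", role = "role", team = "team",
                aggregate = character(0))
  if (!all(c(key, "action", "share") %in% names(freqs))) {
    abort(paste0("freqs lacks the columns for level '", level, "'"),
          class = "kickmod_argument_error")
  }
  freqs %>%
    group_by(across(all_of(c(key, "action")))) %>%
    summarise(mean = mean(.data$share), median = stats::median(.data$share),
              variance = stats::var(.data$share), n_runs = dplyr::n(),
              .groups = "drop")
}

#' Mean absolute deviation of action shares from a baseline configuration
#'
#' One-factor-at-a-time sensitivity headline: how far each configuration's
#' aggregate action-share profile moves away from the baseline.
#'
#' @param freqs Aggregate-level shares per run with columns
#'   `config, action, share` (one row per run and action).
#' @param baseline Name of the baseline configuration (default `"C1"`).
#' @return A tibble `config, deviation` where `deviation` is the mean over
#'   actions of the absolute difference between the configuration's and the
#'   baseline's mean share, in percentage points.
#' @export
deviation_from_baseline <- function(freqs, baseline = "C1") {
  prof <- freqs %>%
    group_by(.data$config, .data$action) %>%
    summarise(share = mean(.data$share), .groups = "drop")
  base <- prof %>% filter(.data$config == baseline)
  if (nrow(base) == 0) {
    abort(paste0("baseline configuration '", baseline, "' not in freqs"),
          class = "kickmod_argument_error")
  }
  prof %>%
    left_join(base %>% select("action", base_share = "share"),
              by = "action") %>%
    group_by(.data$config) %>%
    summarise(deviation = mean(abs(.data$share - .data$base_share)),
              .groups = "drop")
}

# signed relative orientation (degrees) from a heading to a bearing;
# negative = the player must turn left, per the histogram sign convention
.rel_orientation <- function(heading, bearing) {
  theta <- ((bearing - heading + 180) %% 360) - 180   # +ve = target to left
  -theta
}

.target_xy <- function(trace, target, ticks) {
  if (identical(target, "ball")) {
    b <- trace$ball
    list(x = b$x[match(ticks, b$tick)], y = b$y[match(ticks, b$tick)])
  } else {
    q <- trace$players[trace$players$player_id == target, ]
    list(x = q$x[match(ticks, q$tick)], y = q$y[match(ticks, q$tick)])
  }
}

#' Relative orientation histogram of a player towards a target
#'
#' At every tick the relative orientation is the signed smallest angle from
#' the player's heading to the bearing of the target (negative = left turn
#' needed, positive = right). It is binned into 36 classes of 10 degrees:
#' class `c` covers `[c - 5, c + 5)` degrees, so e.g. -15 to -5 fall in
#' class -10, and class 0 (within 5 degrees of facing the target) is the
#' "oriented towards the target" share.
#'
#' @param trace A `match_trace`.
#' @param player_id The observing player.
#' @param target `"ball"` or another player's id.
#' @return A tibble with 36 rows: `class` (-170, ..., -10, 0, 10, ..., 180)
#'   and `share` (percent of ticks; sums to 100).
#' @export
relative_orientation_histogram <- function(trace, player_id,
                                           target = "ball") {
  if (identical(target, player_id)) {
    abort("target must differ from player_id",
          class = "kickmod_argument_error")
  }
  p <- trace$players[trace$players$player_id == player_id, ]
  tg <- .target_xy(trace, target, p$tick)
  bearing <- atan2(tg$y - p$y, tg$x - p$x) * 180 / pi
  rel <- .rel_orientation(p$heading, bearing)
  k <- floor((rel + 5) / 10)
  k[k == -18L] <- 18L
  counts <- tabulate(match(k, -17:18), nbins = 36L)
  tibble(class = 10 * (-17:18), share = 100 * counts / sum(counts))
}

#' Relative distance of a player to a target
#'
#' @inheritParams relative_orientation_histogram
#' @return A list with `series`, a tibble `tick, distance` (metres), and
#'   `summary`, a one-row tibble `mean, sd, min, max`.
#' @export
relative_distance_summary <- function(trace, player_id, target = "ball") {
  if (identical(target, player_id)) {
    abort("target must differ from player_id",
          class = "kickmod_argument_error")
  }
  p <- trace$players[trace$players$player_id == player_id, ]
  tg <- .target_xy(trace, target, p$tick)
  d <- sqrt((tg$x - p$x)^2 + (tg$y - p$y)^2)
  list(series = tibble(tick = p$tick, distance = d),
       summary = tibble(mean = mean(d), sd = stats::sd(d),
                        min = min(d), max = max(d)))
}

#' Possession matrix
#'
#' Accumulates the event log into the who-passes-to-whom view: completed
#' passes fill a 22-by-22 from/to count matrix (rows = passer, columns =
#' receiver; only same-team cells can be non-zero), while possession
#' changes between teams are accumulated per winning team only, without
#' naming the players involved.
#'
#' @param events Event tibble of a run (`trace$events`): columns
#'   `kind, from, to, team`.
#' @return An object of class `possession_matrix`: list with `passes`
#'   (22x22 integer matrix), `interceptions` (tibble `team, n`), and
#'   `n_passes` (= `sum(passes)`).
#' @export
possession_matrix <- function(events) {
  pm <- matrix(0L, 22L, 22L, dimnames = list(from = 1:22, to = 1:22))
  pass <- events[events$kind == "pass_complete", , drop = FALSE]
  if (nrow(pass) > 0) {
    same <- (pass$from <= 11) == (pass$to <= 11)
    if (any(!same)) {
      abort("pass_complete event with players from different teams",
            class = "kickmod_data_error")
    }
    for (r in seq_len(nrow(pass))) {
      pm[pass$from[r], pass$to[r]] <- pm[pass$from[r], pass$to[r]] + 1L
    }
  }
  poss <- events[events$kind == "possession_change_between_teams", ,
                 drop = FALSE]
  inter <- tibble(team = c("A", "B"),
                  n = c(sum(poss$team == "A"), sum(poss$team == "B")))
  structure(list(passes = pm, interceptions = inter,
                 n_passes = sum(pm)), class = "possession_matrix")
}

#' @export
print.possession_matrix <- function(x, ...) {
  cat("<possession_matrix> ", x$n_passes, " completed passes; ",
      "interceptions A ", x$interceptions$n[1], ", B ",
      x$interceptions$n[2], "\n", sep = "")
  invisible(x)
}

#' Role-box occupancy statistics
#'
#' How players distribute around the centres of their role boxes: per-player
#' mean and SD of the distance to the box centre, and the fraction of ticks
#' spent inside the (closed) box.
#'
#' @param trace A `match_trace`.
#' @param boxes Role-box tibble (`player_id, xmin, ymin, xmax, ymax`);
#'   defaults to the boxes recorded in the trace.
#' @return A tibble `player_id, mean_dist, sd_dist, inside_fraction`.
#' @export
role_box_occupancy <- function(trace, boxes = trace$boxes) {
  trace$players %>%
    left_join(boxes %>% select("player_id", "xmin", "ymin", "xmax", "ymax"),
              by = "player_id") %>%
    mutate(
      cx = (.data$xmin + .data$xmax) / 2,
      cy = (.data$ymin + .data$ymax) / 2,
      dist = sqrt((.data$x - .data$cx)^2 + (.data$y - .data$cy)^2),
      inside = .data$x >= .data$xmin & .data$x <= .data$xmax &
        .data$y >= .data$ymin & .data$y <= .data$ymax
    ) %>%
    group_by(.data$player_id) %>%
    summarise(mean_dist = mean(.data$dist), sd_dist = stats::sd(.data$dist),
              inside_fraction = mean(.data$inside), .groups = "drop")
}
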