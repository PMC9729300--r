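# Internal fast kernels of the tick loop. All functions here mutate the
# match_state environment `w` in place and use the global RNG stream, so a
# run is a pure function of (config, seed). Exported wrappers with
# validation live in decision.R and actions.R.

ACTION_LEVELS <- paste0("Act", 1:7)

.norm_heading <- function(h) {
  # normalise to (-180, 180]
  h <- h %% 360
  if (h > 180) h <- h - 360
  h
}

# tick-start perception: 1st/2nd defender of each team (nearest to ball,
# ties by lower id)
.rank_defenders_tick <- function(w) {
  for (t in 1:2) {
    idx <- w$team_idx[[t]]
    d2 <- (w$x[idx] - w$bx)^2 + (w$y[idx] - w$by)^2
    o <- order(d2, idx)
    w$first_def[t] <- idx[o[1]]
    w$second_def[t] <- idx[o[2]]
  }
}

# count opposing outfielders within corridor_width/2 of segment from->to,
# never counting the opposing goalkeeper
.n_between <- function(w, team, fx, fy, tx, ty,
                       corridor = w$p$corridor_width) {
  opp <- w$team_idx[[3L - team]]
  opp <- opp[!w$is_gk[opp]]
  vx <- tx - fx; vy <- ty - fy
  L2 <- vx * vx + vy * vy
  if (L2 < 1e-18) return(0L)
  tt <- ((w$x[opp] - fx) * vx + (w$y[opp] - fy) * vy) / L2
  tt[tt < 0] <- 0; tt[tt > 1] <- 1
  dx <- fx + tt * vx - w$x[opp]
  dy <- fy + tt * vy - w$y[opp]
  sum(dx * dx + dy * dy <= (corridor / 2)^2)
}

.eff <- function(w, base, i) {
  effective_attribute(base[i], w$energy[i], w$p$attr_floor)
}

# the perception -> action table; returns integer action 1..7
.decide <- function(w, i) {
  p <- w$p
  ti <- w$team[i]
  poss <- w$poss
  scen <- if (poss == 0L) 2L
          else if (poss == i) 3L
          else if (w$team[poss] == ti) 4L
          else 1L

  if (scen == 4L) return(7L)

  if (scen == 1L || scen == 2L) {
    db <- sqrt((w$x[i] - w$bx)^2 + (w$y[i] - w$by)^2)
    is12 <- i == w$first_def[ti] || i == w$second_def[ti]
    if (scen == 1L) {
      if (is12 && db <= p$press_range) return(3L)
    } else {
      if (is12) return(3L)
    }
    if (db <= p$ball_close) return(2L) else return(1L)
  }

  # scen == 3L: I have the ball
  gox <- w$attack_dir[ti] * w$pitch$xmax           # opponent goal line x
  d_oppg <- sqrt((gox - w$x[i])^2 + w$y[i]^2)
  d_owng <- sqrt((-gox - w$x[i])^2 + w$y[i]^2)
  opp <- w$team_idx[[3L - ti]]
  nod <- sqrt(min((w$x[opp] - w$x[i])^2 + (w$y[opp] - w$y[i])^2))
  nb <- .n_between(w, ti, w$x[i], w$y[i], gox, 0)
  pressed_home <- d_owng <= p$goal_close && nod <= p$opponent_close
  if ((d_oppg <= p$goal_close && nb < 2L) || pressed_home) return(6L)

  dribble <- .eff(w, w$agility, i)
  passk <- .eff(w, w$teamwork, i)
  # would the next carry step leave my role box?
  kin <- .move_kernel(w$x[i], w$y[i], w$heading[i], gox, 0,
                      w$p$max_step * .eff(w, w$pace, i) / 100, w$pitch)
  leaving <- !(kin[1] >= w$bxmin[i] && kin[1] <= w$bxmax[i] &&
               kin[2] >= w$bymin[i] && kin[2] <= w$bymax[i])
  if ((nb == 0L || (nb == 1L && dribble > passk)) && !leaving) return(4L)
  5L
}

# constrained kinematic step: move from (x, y) toward (tx, ty) by at most
# max_step, clamped to the pitch; returns c(nx, ny, heading, step_length)
.move_kernel <- function(x, y, heading, tx, ty, max_step, pitch) {
  dx <- tx - x; dy <- ty - y
  d <- sqrt(dx * dx + dy * dy)
  if (d < 1e-12 || max_step <= 0) return(c(x, y, heading, 0))
  s <- min(max_step, d)
  nx <- x + dx / d * s
  ny <- y + dy / d * s
  nx2 <- min(max(nx, -pitch$xmax), pitch$xmax)
  ny2 <- min(max(ny, -pitch$ymax), pitch$ymax)
  ddx <- nx2 - x; ddy <- ny2 - y
  step <- sqrt(ddx * ddx + ddy * ddy)
  if (step > 1e-12) heading <- atan2(ddy, ddx) * 180 / pi
  c(nx2, ny2, .norm_heading(heading), step)
}

.move_to <- function(w, i, tx, ty) {
  kin <- .move_kernel(w$x[i], w$y[i], w$heading[i], tx, ty,
                      w$p$max_step * .eff(w, w$pace, i) / 100, w$pitch)
  w$x[i] <- kin[1]; w$y[i] <- kin[2]; w$heading[i] <- kin[3]
  w$step_len[i] <- w$step_len[i] + kin[4]
}

# pass target: most open strictly-forward teammate (no backward passes);
# openness = distance to nearest opponent, ties by shortest pass, then id.
# 0 when no teammate is strictly closer to the opponent goal line.
.pass_target <- function(w, i) {
  ti <- w$team[i]
  mates <- w$team_idx[[ti]]
  mates <- mates[mates != i]
  dir <- w$attack_dir[ti]
  fwd <- mates[dir * w$x[mates] > dir * w$x[i]]
  if (length(fwd) == 0) return(0L)
  opp <- w$team_idx[[3L - ti]]
  # nearest-opponent distance for every forward candidate at once
  dx <- outer(w$x[fwd], w$x[opp], "-")
  dy <- outer(w$y[fwd], w$y[opp], "-")
  D2 <- dx * dx + dy * dy
  openness <- sqrt(if (length(fwd) == 1L) min(D2) else
                   apply(D2, 1L, min))
  plen <- sqrt((w$x[fwd] - w$x[i])^2 + (w$y[fwd] - w$y[i])^2)
  fwd[order(-openness, plen, fwd)[1]]
}

# most open point of player i's role box: candidate grid (corners included)
# maximising distance to the nearest opponent; deterministic ties by index
.open_spot <- function(w, i) {
  px <- w$grid_px[[i]]
  py <- w$grid_py[[i]]
  opp <- w$team_idx[[3L - w$team[i]]]
  score <- rep.int(Inf, length(px))
  ox <- w$x; oy <- w$y
  for (j in opp) {
    d2 <- (px - ox[j])^2 + (py - oy[j])^2
    sel <- d2 < score
    if (any(sel)) score[sel] <- d2[sel]
  }
  bi <- which.max(score)
  c(px[bi], py[bi])
}

# possession contest: winner has highest effective agility, exact ties
# uniform at random; handles all event bookkeeping
.contest <- function(w, contenders) {
  if (length(contenders) == 0) {
    abort("possession contest with no contenders",
          class = "kickmod_contest_error")
  }
  ag <- effective_attribute(w$agility[contenders], w$energy[contenders],
                            w$p$attr_floor)
  top <- contenders[ag == max(ag)]
  winner <- if (length(top) == 1) top else top[sample.int(length(top), 1)]
  wt <- w$team[winner]
  if (w$fl_kind == 1L && wt == w$fl_team && winner != w$fl_from &&
      w$attack_dir[wt] * (w$fl_x[winner] - w$fl_x[w$fl_from]) > 0) {
    .emit(w, "pass_complete", from = w$fl_from, to = winner,
          team = c("A", "B")[wt])
  }
  if (w$last_team != 0L && wt != w$last_team) {
    .emit(w, "possession_change_between_teams", team = c("A", "B")[wt])
  }
  w$poss <- winner
  w$last_team <- wt
  w$bx <- w$x[winner]; w$by <- w$y[winner]
  w$bvx <- 0; w$bvy <- 0
  w$fl_kind <- 0L
  winner
}

.launch <- function(w, i, tx, ty, speed, kind) {
  dx <- tx - w$x[i]; dy <- ty - w$y[i]
  d <- sqrt(dx * dx + dy * dy)
  if (d < 1e-12) { dx <- w$attack_dir[w$team[i]]; dy <- 0; d <- 1 }
  w$bvx <- dx / d * speed
  w$bvy <- dy / d * speed
  w$poss <- 0L
  w$fl_kind <- kind
  w$fl_from <- i
  w$fl_team <- w$team[i]
  w$fl_new <- TRUE
  w$fl_x <- w$x
}

# turn a selected action into a movement target and ball command; pure
# except for RNG draws (Act-1 random spot, Act-6 aim). Returns
# list(tx, ty, cmd, to, ax, ay): cmd 0 = just move, 1 = pass to player
# `to`, 2 = shoot/clear at aim point (ax, ay), 3 = carry
.plan <- function(w, i, a) {
  p <- w$p
  ti <- w$team[i]
  if (a == 1L) {
    return(list(tx = runif(1, w$bxmin[i], w$bxmax[i]),
                ty = runif(1, w$bymin[i], w$bymax[i]), cmd = 0L))
  }
  if (a == 2L) {
    gx <- -w$attack_dir[ti] * w$pitch$xmax   # own goal line x
    db_goal <- sqrt((w$bx - gx)^2 + w$by^2)
    if (w$is_gk[i] && db_goal <= p$ball_close) {
      # interpose on the ball--own-goal segment
      d <- max(db_goal, 1e-9)
      depth <- min(p$gk_depth, d)
      return(list(tx = gx + (w$bx - gx) / d * depth,
                  ty = w$by / d * depth, cmd = 0L))
    }
    j <- if (w$marking[ti] == "man-to-man") w$marked[i] else {
      opp <- w$team_idx[[3L - ti]]
      opp <- opp[!w$is_gk[opp]]
      d2 <- (w$x[opp] - w$cx[i])^2 + (w$y[opp] - w$cy[i])^2
      opp[order(d2, opp)[1]]
    }
    return(list(tx = w$x[j], ty = w$y[j], cmd = 0L))
  }
  if (a == 3L) return(list(tx = w$bx, ty = w$by, cmd = 0L))
  if (a == 4L || a == 5L) {
    to <- if (a == 5L) .pass_target(w, i) else 0L
    if (a == 5L && to > 0L) {
      return(list(tx = w$x[i], ty = w$y[i], cmd = 1L, to = to))
    }
    # Act-4, or Act-5 with no forward option: keep carrying towards goal
    return(list(tx = w$attack_dir[ti] * w$pitch$xmax, ty = 0, cmd = 3L))
  }
  if (a == 6L) {
    gox <- w$attack_dir[ti] * w$pitch$xmax
    d_owng <- sqrt((-gox - w$x[i])^2 + w$y[i]^2)
    opp <- w$team_idx[[3L - ti]]
    nod <- sqrt(min((w$x[opp] - w$x[i])^2 + (w$y[opp] - w$y[i])^2))
    if (d_owng <= p$goal_close && nod <= p$opponent_close) {
      # defensive clearance upfield, not aimed at goal
      ax <- w$x[i] + w$attack_dir[ti] * p$clearance_length
      ay <- w$y[i] + runif(1, -10, 10)
    } else {
      shoot_eff <- .eff(w, w$shooting, i)
      ax <- gox
      ay <- runif(1, -w$pitch$goal_width / 2, w$pitch$goal_width / 2) +
        rnorm(1, 0, p$aim_noise * (100 - shoot_eff) / 100)
    }
    return(list(tx = w$x[i], ty = w$y[i], cmd = 2L, ax = ax, ay = ay))
  }
  spot <- .open_spot(w, i)                        # a == 7L
  list(tx = spot[1], ty = spot[2], cmd = 0L)
}

# execute a selected action for player i (movement and/or ball command)
.act <- function(w, i, a) {
  p <- w$p
  pl <- .plan(w, i, a)
  if (pl$cmd == 0L || pl$cmd == 3L) .move_to(w, i, pl$tx, pl$ty)
  if (pl$cmd == 3L && w$poss == i) { w$bx <- w$x[i]; w$by <- w$y[i] }
  if (pl$cmd == 1L) {
    .launch(w, i, w$x[pl$to], w$y[pl$to], p$pass_speed, 1L)
  } else if (pl$cmd == 2L) {
    .emit(w, "shot", from = i, team = c("A", "B")[w$team[i]])
    .launch(w, i, pl$ax, pl$ay, p$shot_speed, 2L)
  } else if (a == 3L) {
    db <- sqrt((w$x[i] - w$bx)^2 + (w$y[i] - w$by)^2)
    if (db <= p$possession_radius) {
      if (w$poss == 0L) {
        # only a ball at rest can be picked up here; a flying ball is
        # contested through the flight-path interception instead
        if (w$bvx^2 + w$bvy^2 == 0) {
          d2 <- (w$x - w$bx)^2 + (w$y - w$by)^2
          .contest(w, which(d2 <= p$possession_radius^2))
        }
      } else if (w$team[w$poss] != w$team[i]) {
        .contest(w, c(w$poss, i))
      }
    }
  }
  invisible(NULL)
}

# did the ball segment (ox,oy)->(nx,ny) cross (or land on) a goal line
# inside the goal mouth? Returns 0 (no goal) or the scoring side s = +-1.
.goal_crossed <- function(w, ox, oy, nx, ny) {
  xm <- w$pitch$xmax; gw2 <- w$pitch$goal_width / 2
  for (s in c(1, -1)) {
    gx <- s * xm
    if (ox == gx) next                       # moving along the line: no goal
    if ((ox - gx) * (nx - gx) < 0 || nx == gx) {
      tt <- (gx - ox) / (nx - ox)
      ycross <- oy + tt * (ny - oy)
      if (abs(ycross) <= gw2) return(s)
    }
  }
  0
}

.score_goal <- function(w, side, scorer_player) {
  scorer <- which(w$attack_dir == side)      # the team attacking this goal
  .emit(w, "goal",
        from = if (scorer_player > 0) scorer_player else NA_integer_,
        team = c("A", "B")[scorer])
  .reset_kickoff(w, 3L - scorer)
  invisible(NULL)
}

# ball phase: follow the possessor (scoring when carried over the goal line
# inside the mouth), or advance the free ball with friction, detecting goals
# before the perimeter bounce and contesting in-flight interceptions
.ball_phase <- function(w) {
  p <- w$p
  ox <- w$bx; oy <- w$by
  if (w$poss > 0L) {
    # use the tick-start ball position: a carrier already updated w$bx
    nx <- w$x[w$poss]; ny <- w$y[w$poss]
    s <- .goal_crossed(w, w$bx0, w$by0, nx, ny)
    if (s != 0) return(.score_goal(w, s, w$poss))
    w$bx <- nx; w$by <- ny
    w$bvx <- 0; w$bvy <- 0
    return(invisible(NULL))
  }
  if (w$bvx^2 + w$bvy^2 == 0) return(invisible(NULL))
  nx <- ox + w$bvx; ny <- oy + w$bvy
  s <- .goal_crossed(w, ox, oy, nx, ny)
  if (s != 0) {
    return(.score_goal(w, s, if (w$fl_from > 0) w$fl_from else 0L))
  }

  # reflect off the perimeter (no out-of-bounds events are modelled; a dead
  # clamp would let the ball settle exactly on the line, an absorbing state)
  xm <- w$pitch$xmax; ym <- w$pitch$ymax
  rest <- 0.7
  if (nx > xm) { nx <- 2 * xm - nx; w$bvx <- -w$bvx * rest }
  if (nx < -xm) { nx <- -2 * xm - nx; w$bvx <- -w$bvx * rest }
  if (ny > ym) { ny <- 2 * ym - ny; w$bvy <- -w$bvy * rest }
  if (ny < -ym) { ny <- -2 * ym - ny; w$bvy <- -w$bvy * rest }
  nx <- min(max(nx, -xm), xm)                 # safety for extreme speeds
  ny <- min(max(ny, -ym), ym)
  w$bx <- nx; w$by <- ny
  w$bvx <- w$bvx * p$friction
  w$bvy <- w$bvy * p$friction
  if (w$bvx^2 + w$bvy^2 < p$ball_stop^2) {
    w$bvx <- 0; w$bvy <- 0
    w$fl_kind <- 0L                                # flight fizzled out
  }

  # interception along the travelled segment; the launcher is excluded, and
  # on the launch tick so is the first `launch_free` metres of the path
  # (the kicked ball outpaces defenders in immediate reach)
  vx <- w$bx - ox; vy <- w$by - oy
  L2 <- vx * vx + vy * vy
  if (L2 > 1e-18) {
    tmin <- 0
    if (w$fl_new) {
      tmin <- min(1, p$launch_free / sqrt(L2))
      w$fl_new <- FALSE
    }
    tt <- ((w$x - ox) * vx + (w$y - oy) * vy) / L2
    tt[tt < tmin] <- tmin; tt[tt > 1] <- 1
    dx <- ox + tt * vx - w$x
    dy <- oy + tt * vy - w$y
    hit <- which(dx * dx + dy * dy <= p$intercept_radius^2)
    if (w$fl_kind > 0L) hit <- hit[hit != w$fl_from]
    if (length(hit) > 0) .contest(w, hit)
  }
  invisible(NULL)
}

# after a goal the conceding team restarts play. Players are never
# teleported (the 1 m/tick step bound must hold over the whole trace), so
# the restart hands the ball to the conceding team's kickoff player in
# place and play re-forms through the normal reactive rules.
.reset_kickoff <- function(w, kicking_team) {
  # kickoff belongs at the centre: restart with the kicking team's
  # outfielder currently nearest the centre spot (ties by lower id)
  idx <- w$team_idx[[kicking_team]]
  idx <- idx[!w$is_gk[idx]]
  d2 <- w$x[idx]^2 + w$y[idx]^2
  k <- idx[order(d2, idx)[1]]
  w$bx <- w$x[k]; w$by <- w$y[k]
  w$bvx <- 0; w$bvy <- 0
  w$poss <- k
  w$last_team <- kicking_team
  w$fl_kind <- 0L
  invisible(NULL)
}

# one full tick: shuffled sequential perceive->decide->act, then ball,
# goal detection, energy decay
.step_tick <- function(w) {
  w$tick <- w$tick + 1L
  w$bx0 <- w$bx; w$by0 <- w$by
  .rank_defenders_tick(w)
  ord <- sample.int(22L)
  for (i in ord) {
    a <- .decide(w, i)
    w$action[i] <- a
    .act(w, i, a)
  }
  .ball_phase(w)
  if (w$consume) {
    w$energy <- decay_energy(w$energy, w$stamina, w$step_len,
                             w$p$energy_base_rate, TRUE)
  }
  w$step_len[] <- 0
  invisible(NULL)
}
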