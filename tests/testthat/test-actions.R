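test_that("random roaming targets stay inside the player's role box", {
  st <- make_state(possessor = 20L)   # opponent far away with the ball
  set.seed(9)
  for (rep in 1:60) {
    pl <- plan_action(st, 6, "Act1")
    expect_equal(pl$ball_command, "none")
    expect_true(pl$target[1] >= st$bxmin[6] && pl$target[1] <= st$bxmax[6] &&
                pl$target[2] >= st$bymin[6] && pl$target[2] <= st$bymax[6])
  }
})

test_that("the goalkeeper interposes on the ball--own-goal segment", {
  st <- make_state(ball_at = c(-48, 6))   # close to team A's goal (-55, 0)
  pl <- plan_action(st, 1, "Act2")        # id 1 = team A keeper
  g <- c(-55, 0)
  v <- c(-48, 6) - g
  tt <- c(pl$target - g)
  # target = g + depth * unit(ball - goal): collinear with v, between them
  cross <- v[1] * tt[2] - v[2] * tt[1]
  expect_lt(abs(cross), 1e-9)
  expect_gte(sum(tt * v), 0)
  expect_lte(sqrt(sum(tt^2)), sqrt(sum(v^2)))
})

test_that("marking targets the assigned opponent (man-to-man) or nearest to zone (zonal)", {
  st <- make_state(possessor = 20L)
  pl <- plan_action(st, 4, "Act2")
  j <- st$marked[4]
  expect_equal(pl$target, c(st$x[j], st$y[j]))
  stz <- make_state(possessor = 20L, marking = "zonal")
  plz <- plan_action(stz, 4, "Act2")
  opp <- 13:22                       # outfield opponents
  d2 <- (stz$x[opp] - stz$cx[4])^2 + (stz$y[opp] - stz$cy[4])^2
  jz <- opp[which.min(d2)]
  expect_equal(plz$target, c(stz$x[jz], stz$y[jz]))
})

test_that("the open-space target matches a brute-force grid search", {
  # a single distant opponent: the best spot is the far box corner
  pos <- data.frame(player_id = 12:22, x = 50, y = 25)
  st <- make_state(positions = pos, possessor = 5L)
  st$x[12] <- 54; st$y[12] <- 28
  pl <- plan_action(st, 6, "Act7")
  # brute force on a 0.5 m grid of player 6's box against all opponents
  xs <- seq(st$bxmin[6], st$bxmax[6], by = 0.5)
  ys <- seq(st$bymin[6], st$bymax[6], by = 0.5)
  gr <- expand.grid(x = xs, y = ys)
  score <- rep(Inf, nrow(gr))
  for (j in 12:22) {
    score <- pmin(score, (gr$x - st$x[j])^2 + (gr$y - st$y[j])^2)
  }
  best <- gr[which.max(score), ]
  expect_equal(pl$target, c(best$x, best$y))
})

test_that("pass selection is strictly forward and prefers openness", {
  # all teammates behind the passer: no target
  pos <- data.frame(player_id = c(2:11), x = -30, y = seq(-25, 25,
                                                          length.out = 10))
  st <- make_state(positions = pos, possessor = 10L)
  st$x[10] <- 40; st$y[10] <- 0
  st$bx <- 40; st$by <- 0
  expect_true(is.na(select_pass_target(st, 10)))
  # exactly one forward teammate
  st$x[9] <- 45; st$y[9] <- 5
  expect_equal(select_pass_target(st, 10), 9)
  # two forward teammates, one unmarked: the open one wins
  st$x[8] <- 44; st$y[8] <- -5
  st$x[15] <- 45.5; st$y[15] <- 5.5    # opponent breathing on player 9
  open8 <- min(sqrt((st$x[12:22] - st$x[8])^2 + (st$y[12:22] - st$y[8])^2))
  open9 <- min(sqrt((st$x[12:22] - st$x[9])^2 + (st$y[12:22] - st$y[9])^2))
  expect_gt(open8, open9)
  expect_equal(select_pass_target(st, 10), 8)
})

test_that("possession contests go to the highest effective agility, ties at random", {
  st <- make_state(ball_at = c(0, 0))
  st$bvx <- 0; st$bvy <- 0
  # single contender
  expect_equal(resolve_possession(st, 7L), 7)
  # agility decides: player 10 (99) beats player 2 (71)
  st$poss <- 0L
  expect_equal(resolve_possession(st, c(2L, 10L)), 10)
  # an exact tie splits about evenly over seeded trials
  st$agility[2] <- 90; st$agility[18] <- 90
  set.seed(123)
  wins <- replicate(1000, {
    st$poss <- 0L
    resolve_possession(st, c(2L, 18L)) == 2
  })
  expect_gt(mean(wins), 0.45)
  expect_lt(mean(wins), 0.55)
  expect_error(resolve_possession(st, integer(0)),
               class = "kickmod_contest_error")
})

test_that("a possessed ball rides with its possessor; a free ball decays by friction", {
  st <- make_state(possessor = 5L)
  st$x[5] <- 10; st$y[5] <- -3
  update_ball(st)
  expect_equal(c(st$bx, st$by), c(10, -3))
  # free flight: speed shrinks by the friction factor each tick
  stf <- make_state(ball_at = c(0, 0))
  stf$bvx <- 3; stf$bvy <- 0
  # park everyone far from the flight path
  stf$x[] <- -40; stf$y[] <- seq(-28, 28, length.out = 22)
  update_ball(stf)
  expect_equal(c(stf$bx, stf$by), c(3, 0))
  expect_equal(stf$bvx, 3 * 0.9)
  v0 <- sqrt(stf$bvx^2 + stf$bvy^2)
  update_ball(stf)
  expect_equal(sqrt(stf$bvx^2 + stf$bvy^2), v0 * 0.9)
})

test_that("a flight within the interception radius triggers a contest", {
  st <- make_state(ball_at = c(0, 0))
  st$x[] <- -50; st$y[] <- seq(-28, 28, length.out = 22)
  st$x[15] <- 5; st$y[15] <- 0.5       # opponent 0.5 m off the path
  st$bvx <- 3; st$bvy <- 0
  st$fl_kind <- 1L; st$fl_from <- 5L; st$fl_team <- 1L
  st$fl_new <- FALSE; st$fl_x <- st$x
  st$last_team <- 1L
  update_ball(st)                       # ball passes x in [0, 3]
  update_ball(st)                       # then [3, 5.7]: within reach of 15
  expect_equal(st$poss, 15L)
  expect_true(any(st$ev_kind == "possession_change_between_teams"))
})

test_that("goals require crossing the goal mouth", {
  p <- pitch_config()
  expect_equal(detect_goal(c(54, 0), c(56, 0), p), "A")
  expect_equal(detect_goal(c(-54, 1), c(-56, 1), p), "B")
  expect_true(is.na(detect_goal(c(54, 20), c(56, 20), p)))   # wide
  expect_true(is.na(detect_goal(c(54, 0), c(54.9, 0), p)))   # short
  # landing exactly on the line inside the mouth scores
  expect_equal(detect_goal(c(54, 0), c(55, 1), p), "A")
  # moving along the goal line does not
  expect_true(is.na(detect_goal(c(55, 10), c(55, 0), p)))
})

test_that("completed passes are never backward", {
  tr <- cached_run("C1", ticks = 600, seed = 1)
  passes <- tr$events[tr$events$kind == "pass_complete", ]
  skip_if(nrow(passes) == 0, "no completed passes in this short run")
  poss <- tr$ball$possessor
  checked <- 0L
  for (r in seq_len(nrow(passes))) {
    t_done <- passes$tick[r]
    from <- passes$from[r]; to <- passes$to[r]
    hits <- which(poss[seq_len(t_done - 1)] == from)
    # possession gained and passed on within one tick leaves no recorded
    # launch tick; those passes are covered by the launch-snapshot rule
    if (length(hits) == 0) next
    launch <- max(hits)
    px <- tr$players
    fx <- px$x[px$player_id == from & px$tick == launch]
    txx <- px$x[px$player_id == to & px$tick == launch]
    dir <- if (from <= 11) 1 else -1
    # positions are recorded at tick ends, one step either side of the
    # launch instant, so allow the 2 m both players may have moved since
    expect_gt(dir * txx, dir * fx - 2)
    checked <- checked + 1L
  }
  expect_gt(checked, 0L)
})
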