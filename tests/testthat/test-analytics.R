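toy_players <- function() {
  # 3 ticks x 4 players with hand-set actions
  tibble::tibble(
    tick = rep(1:3, each = 4),
    player_id = rep(1:4, times = 3),
    team = rep(c("A", "A", "B", "B"), times = 3),
    role = rep(c("G", "CF", "G", "CF"), times = 3),
    x = 0, y = 0, heading = 0, energy = 100,
    action = c("Act1", "Act1", "Act1", "Act1",
               "Act1", "Act2", "Act2", "Act3",
               "Act7", "Act7", "Act7", "Act7")
  )
}

test_that("action shares per tick match hand counts and sum to 100", {
  fs <- action_frequency_series(toy_trace(toy_players()))
  expect_equal(nrow(fs), 3 * 7)
  get <- function(t, a) fs$share[fs$tick == t & fs$action == a]
  expect_equal(get(1, "Act1"), 100)
  expect_equal(get(2, "Act1"), 25)
  expect_equal(get(2, "Act2"), 50)
  expect_equal(get(2, "Act3"), 25)
  expect_equal(get(2, "Act7"), 0)
  expect_equal(get(3, "Act7"), 100)
  sums <- tapply(fs$share, fs$tick, sum)
  expect_true(all(abs(sums - 100) < 1e-9))
  expect_error(action_frequency_series(toy_players()[0, ]),
               class = "kickmod_argument_error")
})

test_that("action counts aggregate consistently across levels", {
  tr <- toy_trace(toy_players())
  ag <- action_counts(tr, "aggregate")
  expect_equal(sum(ag$share), 100)
  expect_equal(ag$n[ag$action == "Act1"], 5L)
  expect_equal(ag$n[ag$action == "Act7"], 4L)
  tm <- action_counts(tr, "team")
  # aggregate equals the player-weighted mean of team shares (equal teams)
  for (a in paste0("Act", 1:7)) {
    expect_equal(mean(tm$share[tm$action == a]), ag$share[ag$action == a])
  }
  pl <- action_counts(tr, "player")
  expect_equal(nrow(pl), 4 * 7)
  expect_true(all(abs(tapply(pl$share, pl$player_id, sum) - 100) < 1e-9))
})

test_that("horizon splits compare within-window variability", {
  # two identical halves: identical SDs, zero relative difference
  p <- toy_players()
  p2 <- dplyr::bind_rows(p, dplyr::mutate(p, tick = tick + 3))
  hr <- horizon_representativeness(toy_trace(p2), split_tick = 3)
  expect_true(all(abs(hr$rel_diff) < 1e-12))
  # constant series: SD 0 in both windows
  pc <- dplyr::mutate(p2, action = "Act4")
  hrc <- horizon_representativeness(toy_trace(pc), split_tick = 3)
  expect_true(all(hrc$sd_first == 0))
  expect_true(all(hrc$sd_second == 0))
  expect_true(all(hrc$rel_diff == 0))
  # hand-computed SDs: Act1 shares by tick are 100, 25, 0
  hr1 <- horizon_representativeness(toy_trace(p2), split_tick = 4)
  expect_equal(hr1$sd_first[hr1$action == "Act1"], sd(c(100, 25, 0, 100)))
  expect_equal(hr1$sd_second[hr1$action == "Act1"], sd(c(25, 0)))
  expect_error(horizon_representativeness(toy_trace(p2), split_tick = 9),
               class = "kickmod_argument_error")
})

test_that("CV stabilization matches hand calculation and flags zero means", {
  # two replicates, one outcome: CV = sd/mean
  cv <- cv_stabilization(matrix(c(8, 12), ncol = 1), window = 1)
  expect_equal(cv$curve$cv[1], sd(c(8, 12)) / 10)
  # identical replicates: flat zero curve, stabilization at the window edge
  m <- matrix(5, nrow = 12, ncol = 3)
  cvz <- cv_stabilization(m)
  expect_true(all(cvz$curve$cv == 0))
  expect_equal(cvz$stabilization, 2 + cvz$window)
  # a zero-mean outcome is excluded and reported
  m2 <- cbind(a = rep(c(4, 6), 6), b = 0)
  cv2 <- cv_stabilization(m2)
  expect_equal(cv2$excluded, "b")
  expect_error(cv_stabilization(matrix(0, nrow = 6, ncol = 2)),
               class = "kickmod_argument_error")
  expect_error(cv_stabilization(matrix(1, nrow = 1, ncol = 2)),
               class = "kickmod_argument_error")
})

test_that("stabilization count is monotone non-increasing in the tolerance", {
  set.seed(99)
  m <- matrix(rnorm(40 * 4, mean = 100, sd = 15), nrow = 40)
  tols <- c(0.01, 0.02, 0.05, 0.1, 0.2)
  stabs <- vapply(tols, function(tl) {
    s <- cv_stabilization(m, tol = tl)$stabilization
    if (is.na(s)) 1e6 else as.numeric(s)
  }, numeric(1))
  expect_true(all(diff(stabs) <= 0))
})

test_that("variability summaries: zero variance for identical runs, hand values otherwise", {
  tr <- toy_trace(toy_players())
  ag <- action_counts(tr, "aggregate")
  same <- dplyr::bind_rows(
    dplyr::mutate(ag, config = "C1", replicate = 1),
    dplyr::mutate(ag, config = "C2", replicate = 1)
  )
  vs <- variability_summary(same, "aggregate")
  expect_true(all(vs$variance == 0))
  # hand-set shares across two runs
  two <- tibble::tibble(action = rep(c("Act1", "Act2"), 2),
                        share = c(60, 40, 40, 60),
                        config = c("C1", "C1", "C2", "C2"))
  vs2 <- variability_summary(two, "aggregate")
  expect_equal(vs2$mean, c(50, 50))
  expect_equal(vs2$variance, c(var(c(60, 40)), var(c(40, 60))))
  dev <- deviation_from_baseline(two, baseline = "C1")
  expect_equal(dev$deviation[dev$config == "C2"], 20)
  expect_equal(dev$deviation[dev$config == "C1"], 0)
  expect_error(deviation_from_baseline(two, baseline = "C9"),
               class = "kickmod_argument_error")
})

test_that("relative orientation bins follow the 36-class convention", {
  # heading exactly at a static target: everything in class 0
  p <- tibble::tibble(tick = 1:10, player_id = 10, team = "A", role = "lF",
                      x = 0, y = -7, heading = 90, energy = 100,
                      action = "Act1")
  tr <- toy_trace(p)   # ball fixed at (0, 0): bearing is +90
  h <- relative_orientation_histogram(tr, 10, "ball")
  expect_equal(nrow(h), 36)
  expect_equal(sum(h$share), 100)
  expect_equal(h$share[h$class == 0], 100)
  # a -10 degree relative orientation falls in class -10 (covers -15..-5)
  # heading 80, bearing 90: must turn 10 deg left => class -10
  p$heading <- 80
  h2 <- relative_orientation_histogram(toy_trace(p), 10, "ball")
  expect_equal(h2$share[h2$class == -10], 100)
  # half-open classes [c - 5, c + 5): -5 still belongs to class 0,
  # +5 already to class +10
  p$heading <- c(rep(85, 5), rep(95, 5))   # rel orientation -5 and +5
  h3 <- relative_orientation_histogram(toy_trace(p), 10, "ball")
  expect_equal(h3$share[h3$class == 0], 50)
  expect_equal(h3$share[h3$class == 10], 50)
  # and -5.01 falls in class -10 (covers -15..-5)
  p$heading <- 84.99
  h3b <- relative_orientation_histogram(toy_trace(p), 10, "ball")
  expect_equal(h3b$share[h3b$class == -10], 100)
  # near-180 wraps into the 180 class from both sides
  p$heading <- c(rep(-86, 5), rep(-94, 5))   # rel orientation +-176
  h4 <- relative_orientation_histogram(toy_trace(p), 10, "ball")
  expect_equal(h4$share[h4$class == 180], 100)
  expect_error(relative_orientation_histogram(tr, 10, 10),
               class = "kickmod_argument_error")
})

test_that("uniform random headings spread evenly over the 36 classes", {
  set.seed(4)
  n <- 36000
  p <- tibble::tibble(tick = seq_len(n), player_id = 1, team = "A",
                      role = "G", x = 10, y = 10,
                      heading = runif(n, -180, 180), energy = 100,
                      action = "Act1")
  h <- relative_orientation_histogram(toy_trace(p), 1, "ball")
  expect_true(all(abs(h$share - 100 / 36) < 0.6))
})

test_that("relative distances are Euclidean, symmetric, and summarised", {
  p <- tibble::tibble(
    tick = rep(1:4, each = 2),
    player_id = rep(c(1, 2), 4),
    team = "A", role = "CF",
    x = c(0, 7, 0, 7, 0, 7, 3, 3), y = c(0, 0, 0, 0, 0, 0, 0, 4),
    heading = 0, energy = 100, action = "Act1"
  )
  tr <- toy_trace(p)
  rd <- relative_distance_summary(tr, 1, 2)
  expect_equal(rd$series$distance, c(7, 7, 7, 4))
  expect_equal(rd$summary$mean, mean(c(7, 7, 7, 4)))
  rd2 <- relative_distance_summary(tr, 2, 1)
  expect_equal(rd2$series$distance, rd$series$distance)
  expect_error(relative_distance_summary(tr, 1, 1),
               class = "kickmod_argument_error")
})

test_that("the possession matrix accumulates passes and team-level takes", {
  ev <- tibble::tibble(
    tick = 1:6,
    kind = c("pass_complete", "pass_complete", "pass_complete",
             "possession_change_between_teams", "pass_complete",
             "possession_change_between_teams"),
    from = c(5L, 9L, 5L, NA, 14L, NA),
    to = c(9L, 10L, 9L, NA, 20L, NA),
    team = c("A", "A", "A", "B", "B", "A")
  )
  pm <- possession_matrix(ev)
  expect_equal(pm$passes[5, 9], 2L)
  expect_equal(pm$passes[9, 10], 1L)
  expect_equal(pm$passes[14, 20], 1L)
  expect_equal(pm$n_passes, 4L)
  expect_equal(sum(pm$passes), sum(ev$kind == "pass_complete"))
  expect_true(all(diag(pm$passes) == 0))
  expect_equal(pm$interceptions$n, c(1L, 1L))
  bad <- ev; bad$to[1] <- 15L
  expect_error(possession_matrix(bad), class = "kickmod_data_error")
})

test_that("the possession matrix of a real trace equals a brute-force recount", {
  tr <- cached_run("C1", ticks = 600, seed = 1)
  pm <- possession_matrix(tr$events)
  ev <- tr$events[tr$events$kind == "pass_complete", ]
  brute <- matrix(0L, 22, 22)
  for (r in seq_len(nrow(ev))) {
    brute[ev$from[r], ev$to[r]] <- brute[ev$from[r], ev$to[r]] + 1L
  }
  expect_equal(unname(pm$passes), brute)
  expect_equal(pm$n_passes, nrow(ev))
  # same-team cells only
  idx <- which(pm$passes > 0, arr.ind = TRUE)
  if (nrow(idx) > 0) {
    expect_true(all((idx[, 1] <= 11) == (idx[, 2] <= 11)))
  }
})

test_that("role-box occupancy: centre dwellers and permanent absentees", {
  boxes <- tibble::tibble(player_id = c(1, 2), team = "A", role = "CF",
                          xmin = -10, ymin = -10, xmax = 10, ymax = 10)
  p <- tibble::tibble(
    tick = rep(1:5, each = 2), player_id = rep(c(1, 2), 5),
    team = "A", role = "CF",
    x = rep(c(0, 30), 5), y = rep(c(0, 12), 5),
    heading = 0, energy = 100, action = "Act1"
  )
  occ <- role_box_occupancy(toy_trace(p, boxes = boxes), boxes)
  expect_equal(occ$mean_dist[occ$player_id == 1], 0)
  expect_equal(occ$inside_fraction[occ$player_id == 1], 1)
  expect_equal(occ$inside_fraction[occ$player_id == 2], 0)
  expect_equal(occ$mean_dist[occ$player_id == 2],
               sqrt(30^2 + 12^2))
})
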