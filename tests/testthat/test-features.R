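test_that("stationary time counts the zero-displacement run before t", {
  tr <- tibble::tibble(t = 1:4, x = c(0, 0, 0, 1), y = 0)
  expect_identical(stationary_time(tr, 4), 2L)
  moving <- tibble::tibble(t = 1:5, x = 1:5, y = 0)
  expect_identical(stationary_time(moving, 5), 0L)
  still10 <- tibble::tibble(t = 1:10, x = 3, y = 3)
  expect_identical(stationary_time(still10, 10), 8L)
  expect_error(stationary_time(tr, 1), "preceding")
})

test_that("neighbour features count quadrants and radius balls as defined", {
  box <- empty_box(40)
  # focal at (10, 10); one still neighbour offset (+3, +3)
  tr <- make_track(list(
    Que = cbind(rep(10, 4), rep(10, 4)),
    b = cbind(rep(13, 4), rep(13, 4))
  ))
  nf <- neighbor_features(tr, "Que", 3, box)
  expect_equal(nf$nn_dist, sqrt(18))
  expect_equal(nf$nn_x, 13)
  expect_equal(unlist(nf[c("q1", "q2", "q3", "q4")]),
               c(q1 = 1, q2 = 0, q3 = 0, q4 = 0))
  expect_equal(nf$n_still, 1)
  expect_equal(nf$n_moving, 0)
  expect_equal(nf$dist_queen, 0) # the focal animal is the queen

  # a neighbour exactly 10 mm away is inside the closed still-ball
  tr2 <- make_track(list(
    Que = cbind(rep(10, 4), rep(10, 4)),
    b = cbind(rep(20, 4), rep(10, 4))
  ))
  nf2 <- neighbor_features(tr2, "Que", 3, box)
  expect_equal(nf2$n_still, 1)
  expect_equal(nf2$nn_dist, 10)

  # moving neighbour within 12 mm counts in the moving ball
  tr3 <- make_track(list(
    Que = cbind(rep(10, 5), rep(10, 5)),
    b = cbind(10 + seq(0, 4), rep(10, 5))
  ))
  nf3 <- neighbor_features(tr3, "Que", 4, box)
  expect_equal(nf3$n_moving, 1)
  expect_equal(nf3$n_still, 0)
})

test_that("the ant feature vector has 39 entries in the documented order", {
  sim <- small_ant_fixture()
  f <- derive_ant_features(sim$track, nest_geometry())
  feature_cols <- setdiff(names(f), c("id", "t", "out_prev"))
  expect_length(feature_cols, 39)
  expect_identical(feature_cols[1:5], paste0("x_l", 1:5))
  expect_identical(feature_cols[21:23],
                   c("stationary_time", "d_prev", "sub_chamber"))
  expect_identical(feature_cols[39], "dist_queen")
  counts <- f[c("q1", "q2", "q3", "q4", "n_still", "n_moving")]
  expect_true(all(counts >= 0))
  expect_true(all(counts == floor(as.matrix(counts))))
})

test_that("degenerate histories produce the forced feature values", {
  box <- empty_box(40)
  # constant position: all velocity lags zero, stationary time t - 2
  tr <- make_track(list(Que = cbind(rep(5, 9), rep(6, 9)),
                        b = cbind(rep(20, 9), rep(20, 9))))
  f <- derive_ant_features(tr, box)
  row <- dplyr::filter(f, id == "Que", t == 9)
  expect_true(all(row[paste0("vx_l", 1:5)] == 0))
  expect_true(all(row[paste0("vy_l", 1:5)] == 0))
  expect_equal(row$stationary_time, 7) # run of steps 2..8
  expect_equal(row$d_prev, 0)

  # straight-line motion (1, 0) per step from (0, 0)
  line <- make_track(list(Que = cbind(0:8, rep(2, 9)),
                          b = cbind(rep(20, 9), rep(20, 9))))
  fl <- derive_ant_features(line, box)
  r7 <- dplyr::filter(fl, id == "Que", t == 7)
  expect_true(all(r7[paste0("vx_l", 1:5)] == 1))
  expect_true(all(r7[paste0("vy_l", 1:5)] == 0))
  expect_equal(r7$d_prev, 1)
  expect_equal(unlist(r7[paste0("x_l", 1:5)], use.names = FALSE), 5:1)
})

test_that("out-of-nest animals are held at the exit with zero velocity", {
  box <- empty_box(40)
  xs <- c(5, 5, 5, 5, NA, NA, NA, NA, NA)
  tr <- make_track(list(Que = cbind(xs, xs),
                        b = cbind(rep(20, 9), rep(20, 9))))
  f <- derive_ant_features(tr, box)
  row <- dplyr::filter(f, id == "Que", t == 9)
  expect_true(row$out_prev)
  expect_true(all(row[paste0("x_l", 1:3)] == box$exit[1]))
  expect_true(all(row[paste0("y_l", 1:3)] == box$exit[2]))
  expect_true(all(row[paste0("vx_l", 1:3)] == 0))
  # out animals are excluded from the neighbour pool
  row_b <- dplyr::filter(f, id == "b", t == 9)
  expect_equal(row_b$nn_dist, sqrt(2) * 40) # sentinel: nest diagonal
  expect_equal(row_b$nn_x, 20)
  expect_equal(row_b$nn_vx, 0)
})

test_that("distance features are translation equivariant", {
  sim <- generate_ant_colony(n_animals = 4, steps = 60,
                             geom = nest_geometry(80, 40, n_chambers = 2),
                             seed = 3)
  geom1 <- nest_geometry(200, 200, n_chambers = 1, with_barriers = FALSE)
  tr1 <- tibble::as_tibble(sim$track) |>
    dplyr::mutate(x = x + 20, y = y + 30) |>
    colony_track()
  tr2 <- tibble::as_tibble(sim$track) |>
    dplyr::mutate(x = x + 27, y = y + 33) |>
    colony_track()
  f1 <- derive_ant_features(tr1, geom1)
  f2 <- derive_ant_features(tr2, geom1)
  keep <- !f1$out_prev & !f2$out_prev
  invariant <- c("nn_dist", "q1", "q2", "q3", "q4", "n_still", "n_moving",
                 "d_prev", "dist_queen", paste0("vx_l", 1:5))
  for (v in invariant) expect_equal(f1[[v]][keep], f2[[v]][keep])
  expect_equal(f1$x_l1[keep] + 7, f2$x_l1[keep])
  expect_equal(f1$y_l2[keep] + 3, f2$y_l2[keep])
})

test_that("quadrant counts never exceed the in-nest neighbour pool", {
  sim <- small_ant_fixture()
  f <- derive_ant_features(sim$track, nest_geometry())
  n_in <- length(unique(f$id)) - 1
  expect_true(all(f$q1 + f$q2 + f$q3 + f$q4 <= n_in))
})

test_that("features recomputed from a round-tripped track are identical", {
  sim <- generate_ant_colony(n_animals = 4, steps = 80, seed = 5)
  geom <- nest_geometry()
  path <- withr::local_tempfile(fileext = ".csv")
  write_tracking_csv(sim$track, path)
  back <- read_tracking_csv(path)
  expect_identical(derive_ant_features(sim$track, geom),
                   derive_ant_features(back, geom))
})

test_that("the bird-year clock starts on 1 June and wraps fractions", {
  t1 <- as.POSIXct("2010-06-01 00:00:00", tz = "UTC")
  t2 <- as.POSIXct("2010-06-02 12:00:00", tz = "UTC")
  t3 <- as.POSIXct("2011-03-01 06:00:00", tz = "UTC")
  clock <- bird_year_clock(c(t1, t2, t3))
  expect_equal(clock$day_number[1:2], c(0, 1))
  expect_equal(clock$time_of_day[1:2], c(0, 0.5))
  expect_gte(clock$day_number[3], 270) # still the 2010 bird-year
  expect_equal(clock$time_of_day[3], 0.25)
})

test_that("gull features carry lags, clock and penultimate distance", {
  tt <- as.POSIXct("2010-06-01", tz = "UTC") + 1800 * (0:39)
  still <- tibble::tibble(id = "g", t = tt, x = 100, y = 200)
  f <- derive_gull_features(still, lags = 10)
  expect_equal(nrow(f), 40 - 11)
  expect_true(all(f[paste0("vx_l", 1:10)] == 0))
  expect_equal(f$d_prev, rep(0, nrow(f)))
  expect_true(all(f$time_of_day >= 0 & f$time_of_day < 1))
  moving <- tibble::tibble(id = "g", t = tt, x = seq(0, 39) * 3, y = 0)
  fm <- derive_gull_features(moving, lags = 10)
  expect_equal(fm$d_prev, rep(3, nrow(fm)))
  expect_equal(fm$vx_l1, rep(3 / 1800, nrow(fm)))
})
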