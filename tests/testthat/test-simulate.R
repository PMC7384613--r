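test_that("a colony that can only stay still never moves", {
  # stationary is absorbing: every row transitions to state 0
  frozen <- matrix(c(1, 0, 0), 3, 3, byrow = TRUE)
  dimnames(frozen) <- list(0:2, 0:2)
  sim <- generate_ant_colony(n_animals = 4, steps = 300,
                             transition = frozen, seed = 4)
  geom <- nest_geometry()
  lab <- label_ant_states(sim$track, geom)
  expect_true(all(lab$state %in% c(0L, 1L)))
  fm <- fit_framework(sim$track, lab, geom,
                      state_learner = learner_rf(num_trees = 10),
                      velocity_learner = learner_rf(num_trees = 10), seed = 1)
  out <- simulate_movement(fm, sim$track, steps = 30, reps = 1, seed = 2)
  inn <- dplyr::filter(out, !is.na(x))
  start <- dplyr::filter(tibble::as_tibble(sim$track), t == max(t), !out)
  joined <- dplyr::inner_join(inn, start, by = "id", suffix = c("", "0"))
  expect_true(all(joined$x == joined$x0 & joined$y == joined$y0))
})

test_that("rollouts are seed-deterministic and replicates differ", {
  fx <- fit_small_framework()
  s1 <- simulate_movement(fx$model, fx$sim$track, steps = 40, reps = 2,
                          seed = 5)
  s2 <- simulate_movement(fx$model, fx$sim$track, steps = 40, reps = 2,
                          seed = 5)
  expect_identical(tibble::as_tibble(s1), tibble::as_tibble(s2))
  r1 <- dplyr::filter(s1, rep == 1)
  r2 <- dplyr::filter(s1, rep == 2)
  expect_false(identical(r1$x, r2$x))
  expect_false(identical(r1$state, r2$state))
})

test_that("rollouts depend only on the model, init window and seed", {
  fx <- fit_small_framework()
  full <- tibble::as_tibble(fx$sim$track)
  cut <- sort(unique(full$t))[900]
  init <- colony_track(dplyr::filter(full, t <= cut))
  corrupted <- full
  corrupted$x[corrupted$t > cut & !corrupted$out] <- 0
  corrupted$y[corrupted$t > cut & !corrupted$out] <- 0
  init2 <- colony_track(dplyr::filter(corrupted, t <= cut))
  a <- simulate_movement(fx$model, init, steps = 25, reps = 1, seed = 3)
  b <- simulate_movement(fx$model, init2, steps = 25, reps = 1, seed = 3)
  expect_identical(tibble::as_tibble(a), tibble::as_tibble(b))
})

test_that("SDE rollouts stay inside the nest for a thousand steps", {
  sim <- generate_ant_colony(n_animals = 5, steps = 600, seed = 11)
  geom <- nest_geometry()
  lab <- label_ant_states(sim$track, geom)
  model <- fit_sde(sim$track, lab, geom, cell_size = 10, lambda_m = 1,
                   lambda_h = 2)
  feats <- derive_ant_features(sim$track, geom)
  st <- dplyr::inner_join(dplyr::select(feats, id, t), lab, by = c("id", "t"))
  model$state_model <- fit_multinomial_backward(
    feats[c("stationary_time", "d_prev", "vx_l1", "vy_l1")], st$state
  )
  out <- simulate_movement(model, sim$track, steps = 1000, reps = 1, seed = 6)
  inn <- dplyr::filter(out, !is.na(x))
  expect_gt(nrow(inn), 0)
  expect_true(all(inn$x >= 0 & inn$x <= geom$width &
                    inn$y >= 0 & inn$y <= geom$height))
  # stationary steps have zero displacement; out steps carry no coordinates
  by_id <- out |>
    dplyr::filter(rep == 1) |>
    dplyr::group_by(id) |>
    dplyr::mutate(dx = x - dplyr::lag(x), dy = y - dplyr::lag(y)) |>
    dplyr::ungroup()
  still <- by_id$state == 0 & !is.na(by_id$dx)
  expect_true(all(by_id$dx[still] == 0 & by_id$dy[still] == 0))
  expect_true(all(is.na(out$x[out$state == 1])))
})

test_that("gull rollouts extend the track with per-state dynamics", {
  g <- default_gull_fixture()
  tr <- g$track[1:1500, ]
  st <- g$states[1:1500, ]
  utm <- latlon_to_utm(tr$lat, tr$lon)
  tr2 <- tibble::tibble(id = tr$id, t = tr$t, x = utm$x / 1000,
                        y = utm$y / 1000)
  fm <- fit_gull_framework(tr2, st, lags = 15,
                           state_learner = learner_rf(num_trees = 10),
                           velocity_learner = learner_rf(num_trees = 10),
                           seed = 2)
  out <- simulate_movement(fm, tr2[1:200, ], steps = 25, reps = 2, seed = 9)
  expect_equal(nrow(out), 2 * 25)
  step_s <- as.numeric(diff(dplyr::filter(out, rep == 1)$t), units = "secs")
  expect_true(all(step_s == fm$dt))
  expect_true(all(out$state %in% fm$state_levels))
  again <- simulate_movement(fm, tr2[1:200, ], steps = 25, reps = 2, seed = 9)
  expect_identical(tibble::as_tibble(out), tibble::as_tibble(again))
})
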