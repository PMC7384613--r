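test_that("exit velocity is the displacement to the exit point", {
  ev <- exit_velocity(100, 30, c(199, 0))
  expect_equal(unlist(ev), c(vx = 99, vy = -30))
  expect_equal(unlist(exit_velocity(199, 0, c(199, 0))), c(vx = 0, vy = 0))
  expect_equal(unlist(exit_velocity(0, 0, c(199, 0))), c(vx = 199, vy = 0))
})

test_that("sampled predictions obey the state composition rules", {
  fx <- fit_small_framework()
  pred <- predict_one_step(fx$model, fx$sim$track, times = 900:1100,
                           mode = "sampled", seed = 7)
  probs <- as.matrix(pred[c("p_0", "p_1", "p_2")])
  expect_true(all(abs(rowSums(probs) - 1) < 1e-9))

  A <- movestates:::build_track_arrays(fx$sim$track, fx$geom,
                                       movestates:::feature_config())
  it <- match(pred$t, A$times)
  ii <- match(pred$id, A$ids)
  x_prev <- A$X[cbind(it - 1, ii)]
  y_prev <- A$Y[cbind(it - 1, ii)]
  s0 <- pred$state == 0
  s1 <- pred$state == 1
  expect_true(any(s0) && any(s1))
  expect_identical(pred$x[s0], x_prev[s0]) # zero displacement, exactly
  expect_identical(pred$y[s0], y_prev[s0])
  expect_true(all(pred$x[s1] == fx$geom$exit[1]))
  expect_true(all(pred$y[s1] == fx$geom$exit[2]))
  # all predictions live inside the nest
  expect_true(all(pred$x >= 0 & pred$x <= fx$geom$width))
  expect_true(all(pred$y >= 0 & pred$y <= fx$geom$height))
})

test_that("expected-path predictions are deterministic and refittable", {
  fx <- fit_small_framework()
  p1 <- predict_one_step(fx$model, fx$sim$track, times = 1000:1020,
                         mode = "expected")
  p2 <- predict_one_step(fx$model, fx$sim$track, times = 1000:1020,
                         mode = "expected")
  expect_identical(p1, p2)
  refit <- fit_framework(fx$sim$track, fx$lab, fx$geom,
                         state_learner = learner_rf(num_trees = 30),
                         velocity_learner = learner_rf(num_trees = 30),
                         seed = 1)
  p3 <- predict_one_step(refit, fx$sim$track, times = 1000:1020,
                         mode = "expected")
  expect_identical(p1, p3)
})

test_that("a deterministic movement schedule is classified almost perfectly", {
  # animals alternate 3 still steps and 1 move: the next state is a function
  # of stationary time, so a feature-based classifier should recover it
  box <- empty_box(60)
  set.seed(2)
  mk <- function(x0, y0) {
    x <- numeric(240); y <- numeric(240)
    x[1] <- x0; y[1] <- y0
    for (t in 2:240) {
      if (t %% 4 == 0) {
        x[t] <- min(max(x[t - 1] + stats::runif(1, 0.5, 1.5), 0), 60)
        y[t] <- min(max(y[t - 1] + stats::runif(1, -1, 1), 0), 60)
      } else {
        x[t] <- x[t - 1]; y[t] <- y[t - 1]
      }
    }
    cbind(x, y)
  }
  tr <- make_track(list(Que = mk(10, 10), b = mk(30, 30), c = mk(50, 20)))
  lab <- label_ant_states(tr, box)
  fm <- fit_framework(tr, lab, box,
                      state_learner = learner_rf(num_trees = 40),
                      velocity_learner = learner_rf(num_trees = 20), seed = 3)
  pred <- predict_one_step(fm, tr, mode = "expected")
  truth <- dplyr::inner_join(dplyr::select(pred, id, t, state), lab,
                             by = c("id", "t"))
  expect_gt(mean(truth$state.x == truth$state.y), 0.95)
})

test_that("the colony-level velocity head spans two outputs per animal", {
  sim <- generate_ant_colony(n_animals = 5, steps = 300, seed = 5)
  geom <- nest_geometry()
  lab <- label_ant_states(sim$track, geom)
  fm <- fit_framework(sim$track, lab, geom, level = "colony",
                      state_learner = learner_mvrf(num_trees = 5,
                                                   max_depth = 5),
                      velocity_learner = learner_mvrf(num_trees = 5,
                                                      max_depth = 5),
                      seed = 2)
  expect_equal(fm$velocity_model$n_outputs, 2 * 5)
  expect_equal(fm$state_model$n_outputs, 5)
  pred <- predict_one_step(fm, sim$track, times = 200:205, mode = "sampled",
                           seed = 3)
  probs <- as.matrix(pred[c("p_0", "p_1", "p_2")])
  expect_true(all(abs(rowSums(probs) - 1) < 1e-9))
})

test_that("colony-level network models reduce the input with PCA", {
  sim <- generate_ant_colony(n_animals = 4, steps = 250, seed = 6)
  geom <- nest_geometry()
  lab <- label_ant_states(sim$track, geom)
  fm <- fit_framework(sim$track, lab, geom, level = "colony",
                      state_learner = learner_mlp(hidden = 8, epochs = 3),
                      velocity_learner = learner_mlp(hidden = 8, epochs = 3),
                      pca_components = 20, seed = 2)
  expect_false(is.null(fm$pca))
  expect_equal(ncol(fm$pca$rotation), 20)
  pred <- predict_one_step(fm, sim$track, times = 200:203, mode = "sampled",
                           seed = 1)
  expect_true(all(abs(rowSums(as.matrix(pred[c("p_0", "p_1", "p_2")])) - 1)
                  < 1e-6))
})

test_that("gull frameworks fit one velocity model per state", {
  g <- default_gull_fixture()
  tr <- g$track[1:2000, ]
  st <- g$states[1:2000, ]
  utm <- latlon_to_utm(tr$lat, tr$lon)
  tr2 <- tibble::tibble(id = tr$id, t = tr$t, x = utm$x / 1000,
                        y = utm$y / 1000)
  fm <- fit_gull_framework(tr2, st, lags = 15,
                           state_learner = learner_rf(num_trees = 15),
                           velocity_learner = learner_rf(num_trees = 15),
                           seed = 1)
  expect_identical(names(fm$velocity_models),
                   as.character(sort(unique(st$state))))
  pred <- predict_one_step(fm, tr2, mode = "expected")
  expect_true(all(pred$state %in% fm$state_levels))
  # predicting into a state with no model is a named error
  fm2 <- fm
  fm2$velocity_models[["1"]] <- NULL
  expect_error(predict_one_step(fm2, tr2, mode = "expected"),
               "state 1")
})
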