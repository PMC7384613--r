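# Shared slow fixture: one long AR(2) simulation on a 16 x 8 grid with
# contrasting motility regions and a quadratic potential bowl.
sde_recovery_fixture <- function() {
  if (is.null(.fixtures$sde)) {
    geom <- nest_geometry(160, 80, n_chambers = 1, with_barriers = FALSE)
    truth <- grid_surfaces(geom, cell_size = 10)
    cc <- movestates:::cell_centres(truth)
    truth$m <- ifelse(cc$x < 80, 0.6, 1.2)
    r2 <- (cc$x - 80)^2 + (cc$y - 40)^2
    truth$h <- 10 * r2 / max(r2)
    sim <- ar2_simulate(truth, beta = 0.4, steps = 30000, geom = geom,
                        seed = 7)
    track <- colony_track(tibble::tibble(id = "a", t = sim$t,
                                         x = sim$x, y = sim$y))
    states <- tibble::tibble(id = "a", t = 2:nrow(sim), state = 2L)
    .fixtures$sde <- list(geom = geom, truth = truth, track = track,
                          states = states, beta = 0.4)
  }
  .fixtures$sde
}

test_that("surface evaluation looks up the containing cell", {
  geom <- empty_box(2)
  s <- grid_surfaces(geom, cell_size = 1, m = 1, h = 5)
  expect_true(all(surface_eval(s, c(0.2, 1.7), c(0.3, 0.8))$h == 5))
  s$h <- c(1, 2, 3, 4) # 2 x 2 grid, row-major from the bottom-left
  expect_equal(surface_eval(s, 0.5, 0.5)$h, 1)
  expect_equal(surface_eval(s, 1.5, 0.5)$h, 2)
  expect_equal(surface_eval(s, 0.5, 1.5)$h, 3)
  expect_equal(surface_eval(s, 1.5, 1.5)$h, 4)
  # cell edges are half-open (right/top edge of the grid closed)
  expect_equal(surface_eval(s, 1, 0.5)$h, 2)
  expect_equal(surface_eval(s, 2, 2)$h, 4)
  expect_warning(surface_eval(s, 5, 5), "outside")
})

test_that("the potential gradient is a finite difference over cells", {
  geom <- nest_geometry(10, 1, n_chambers = 1, with_barriers = FALSE)
  s <- grid_surfaces(geom, cell_size = 1)
  g0 <- potential_gradient(s, 4.5, 0.5)
  expect_equal(unlist(g0), c(gx = 0, gy = 0))
  s$h <- seq(0.5, 9.5) # h(x) = x at cell centres
  g1 <- potential_gradient(s, c(4.5, 0.5, 9.5), rep(0.5, 3))
  expect_equal(g1$gx, c(1, 1, 1))
  expect_equal(g1$gy, c(0, 0, 0))
  # symmetric bowl: zero gradient at the minimum
  geom2 <- empty_box(3)
  s2 <- grid_surfaces(geom2, cell_size = 1)
  cc <- movestates:::cell_centres(s2)
  s2$h <- (cc$x - 1.5)^2 + (cc$y - 1.5)^2
  gmin <- potential_gradient(s2, 1.5, 1.5)
  expect_equal(unlist(gmin), c(gx = 0, gy = 0))
})

test_that("the AR(2) step reproduces its closed-form limits", {
  geom <- empty_box(10)
  s <- grid_surfaces(geom, cell_size = 1)
  # beta = 1, flat potential: mean reverts to the last position
  m1 <- ar2_step(2, 3, 4, 5, beta = 1, s)
  expect_equal(c(m1$mean_x, m1$mean_y), c(4, 5))
  # beta = 0: constant-velocity extrapolation
  m0 <- ar2_step(2, 3, 4, 5, beta = 0, s)
  expect_equal(c(m0$mean_x, m0$mean_y), c(2 * 4 - 2, 2 * 5 - 3))
  # beta = 0.5, m = 2, -grad h = (1, 0) at the origin cell
  s2 <- grid_surfaces(empty_box(10), cell_size = 1, m = 2)
  cc <- movestates:::cell_centres(s2)
  s2$h <- -cc$x # grad h = (-1, 0) everywhere
  mm <- ar2_step(0.5, 0.5, 0.5, 0.5, beta = 0.5, s2)
  expect_equal(c(mm$mean_x, mm$mean_y), c(0.5 + 0.5 * 2 * 1, 0.5))
  set.seed(1)
  draws <- ar2_step(rep(5, 4000), rep(5, 4000), rep(5, 4000), rep(5, 4000),
                    beta = 0.5, s2, sample = TRUE)
  expect_equal(stats::sd(draws$x - draws$mean_x), 2, tolerance = 0.1)
  expect_equal(stats::sd(draws$y - draws$mean_y), 2, tolerance = 0.1)
})

test_that("friction estimation recovers the generating autocorrelation", {
  fx <- sde_recovery_fixture()
  bh <- estimate_beta(fx$track, fx$states)
  expect_equal(bh, fx$beta, tolerance = 0.05)
  # white-noise velocities: no autocorrelation, beta near 1
  set.seed(3)
  wn <- cumsum(stats::rnorm(5000))
  trw <- colony_track(tibble::tibble(id = "a", t = seq_along(wn),
                                     x = wn, y = cumsum(stats::rnorm(5000))))
  stw <- tibble::tibble(id = "a", t = 2:5000, state = 2L)
  expect_equal(estimate_beta(trw, stw), 1, tolerance = 0.05)
  # near-constant velocity: autocorrelation near 1, beta near 0
  trc <- colony_track(tibble::tibble(
    id = "a", t = 1:2000,
    x = cumsum(2 + 1e-4 * stats::rnorm(2000)),
    y = cumsum(1 + 1e-4 * stats::rnorm(2000))
  ))
  stc <- tibble::tibble(id = "a", t = 2:2000, state = 2L)
  expect_lt(estimate_beta(trc, stc), 0.05)
  expect_error(estimate_beta(trc[1:5, ], stc[1:4, ]), "10 consecutive")
})

test_that("motility estimation recovers scale and regional contrast", {
  fx <- sde_recovery_fixture()
  triples <- movestates:::moving_triples(fx$track, fx$states, fx$geom)
  fit <- estimate_motility(triples, fx$beta,
                           grid_surfaces(fx$geom, cell_size = 10),
                           lambda = 1)
  n_cell <- attr(fit, "n_cell")
  rich <- n_cell >= 50
  rel_err <- abs(fit$m[rich] - fx$truth$m[rich]) / fx$truth$m[rich]
  expect_lt(stats::median(rel_err), 0.10)
  cc <- movestates:::cell_centres(fit)
  hi <- rich & cc$x >= 80
  lo <- rich & cc$x < 80
  ratio <- stats::median(fit$m[hi]) / stats::median(fit$m[lo])
  expect_equal(ratio, 2, tolerance = 0.15)
  # a huge penalty flattens the surface towards a constant
  flat <- estimate_motility(triples, fx$beta,
                            grid_surfaces(fx$geom, cell_size = 10),
                            lambda = 1e7)
  expect_lt(max(flat$m) - min(flat$m), 0.05)
})

test_that("potential estimation recovers drift direction and gauge", {
  fx <- sde_recovery_fixture()
  triples <- movestates:::moving_triples(fx$track, fx$states, fx$geom)
  surf <- estimate_motility(triples, fx$beta,
                            grid_surfaces(fx$geom, cell_size = 10),
                            lambda = 1)
  fit <- estimate_potential(triples, fx$beta, surf, lambda = 2)
  expect_equal(mean(fit$h), 0, tolerance = 1e-8) # anchored gauge
  n_cell <- attr(fit, "n_cell")
  rich <- which(n_cell >= 50)
  expect_gt(stats::cor(fit$h[rich], fx$truth$h[rich]), 0.8)
  # estimated drift points towards the bowl centre in most data-rich cells
  cc <- movestates:::cell_centres(fit)
  g <- potential_gradient(fit, cc$x[rich], cc$y[rich])
  to_centre <- cbind(80 - cc$x[rich], 40 - cc$y[rich])
  inner <- -g$gx * to_centre[, 1] - g$gy * to_centre[, 2]
  ok <- sqrt(to_centre[, 1]^2 + to_centre[, 2]^2) > 10
  expect_gt(mean(inner[ok] > 0), 0.9)

  # flat-potential data: fitted drift is below the noise floor
  geom <- fx$geom
  flat_truth <- grid_surfaces(geom, cell_size = 10, m = 1)
  simf <- ar2_simulate(flat_truth, beta = 0.4, steps = 15000, geom = geom,
                       seed = 3)
  trf <- colony_track(tibble::tibble(id = "a", t = simf$t, x = simf$x,
                                     y = simf$y))
  stf <- tibble::tibble(id = "a", t = 2:nrow(simf), state = 2L)
  trip_f <- movestates:::moving_triples(trf, stf, geom)
  sf <- estimate_motility(trip_f, 0.4, grid_surfaces(geom, cell_size = 10),
                          lambda = 1)
  sf <- estimate_potential(trip_f, 0.4, sf, lambda = 2)
  gf <- movestates:::gradient_field(sf)
  drift_mag <- 0.4 * sf$m * sqrt(gf$gx^2 + gf$gy^2)
  richf <- attr(sf, "n_cell") >= 50
  expect_lt(stats::median(drift_mag[richf]), 0.1) # noise scale is 1
})

test_that("backward selection keeps the informative predictors", {
  retained_both <- 0
  for (rep in 1:20) {
    set.seed(rep + 300)
    n <- 250
    x <- as.data.frame(matrix(stats::rnorm(n * 10), n, 10))
    eta <- 2 * x$V1 - 2 * x$V2
    pr <- 1 / (1 + exp(-eta))
    y <- ifelse(stats::runif(n) < pr, 2L, ifelse(stats::runif(n) < 0.5, 0L, 1L))
    fit <- fit_multinomial_backward(x, y)
    if (all(c("V1", "V2") %in% fit$retained)) {
      retained_both <- retained_both + 1
    }
  }
  expect_gte(retained_both, 17)
})

test_that("model nesting and degenerate inputs behave as expected", {
  set.seed(5)
  x <- as.data.frame(matrix(stats::rnorm(400), 100, 4))
  y <- sample(0:2, 100, TRUE)
  full <- nnet::multinom(y ~ ., data = cbind(x, y = factor(y)), trace = FALSE)
  red <- nnet::multinom(y ~ . - V1, data = cbind(x, y = factor(y)),
                        trace = FALSE)
  expect_lte(stats::deviance(full), stats::deviance(red) + 1e-6)
  expect_error(fit_multinomial_backward(x, rep(1, 100)), "2 state")
})

test_that("the one-step SDE path obeys the state composition rules", {
  fx <- sde_recovery_fixture()
  # small colony with all three states to exercise the composition
  sim <- generate_ant_colony(n_animals = 5, steps = 400, seed = 9)
  geom <- nest_geometry()
  lab <- label_ant_states(sim$track, geom)
  model <- fit_sde(sim$track, lab, geom, cell_size = 10, lambda_m = 1,
                   lambda_h = 2)
  # attach a state model trained on a compact feature subset
  feats <- derive_ant_features(sim$track, geom)
  st <- dplyr::inner_join(dplyr::select(feats, id, t), lab,
                          by = c("id", "t"))
  model$state_model <- fit_multinomial_backward(
    feats[c("stationary_time", "d_prev", "vx_l1", "vy_l1")], st$state
  )
  pred <- sde_predict_one_step(model, sim$track, times = 300:340,
                               mode = "expected")
  A <- movestates:::build_track_arrays(sim$track, geom,
                                       movestates:::feature_config())
  it <- match(pred$t, A$times); ii <- match(pred$id, A$ids)
  x_prev <- A$X[cbind(it - 1, ii)]; y_prev <- A$Y[cbind(it - 1, ii)]
  s0 <- pred$state == 0
  expect_true(any(s0))
  expect_identical(pred$x[s0], x_prev[s0])
  expect_identical(pred$y[s0], y_prev[s0])
  s1 <- pred$state == 1
  expect_true(all(pred$x[s1] == geom$exit[1]))
  # beta = 1 with a flat potential: moving mean equals the previous position
  m2 <- model
  m2$beta <- 1
  m2$surfaces$h <- rep(0, m2$surfaces$J)
  pred2 <- sde_predict_one_step(m2, sim$track, times = 300:340,
                                mode = "expected")
  s2 <- pred2$state == 2
  if (any(s2)) {
    expect_equal(pred2$x[s2], x_prev[s2], tolerance = 1e-9)
    expect_equal(pred2$y[s2], y_prev[s2], tolerance = 1e-9)
  }
})
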