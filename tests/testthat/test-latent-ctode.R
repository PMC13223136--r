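test_that("control interpolation is piecewise linear with constant extrapolation", {
  ev <- tibble::tibble(
    episode_id = "a",
    t_sec = c(0, 600), modality = "propofol", value = c(40, 60))
  suppressWarnings(ctr <- interpolate_controls(ev))
  expect_equal(unname(ctr(300 / 3600)[, "propofol"]), 50)   # linear midpoint
  expect_equal(unname(ctr(2)[, "propofol"]), 60)            # held beyond last record
  expect_equal(unname(ctr(0.05)[, "ketamine"]), 0)          # absent drug -> zero + warning
  one <- tibble::tibble(episode_id = "a", t_sec = 0, modality = "ketamine", value = 5)
  suppressWarnings(c1 <- interpolate_controls(one))
  expect_equal(unname(c1(c(0, 1, 10))[, "ketamine"]), rep(5, 3))  # single record constant
})

test_that("propagate matches closed-form solutions of linear systems", {
  ctr <- constant_controls()
  # zero dynamics leaves the state unchanged at any horizon
  z <- propagate(c(1, -2), 0, 24, ctr, function(z, u) c(0, 0))
  expect_equal(z, c(1, -2))
  # planar rotation: dz/dt = Az, A = [[0,1],[-1,0]], z(pi/2) = (0,-1) from (1,0)
  A <- matrix(c(0, -1, 1, 0), 2, 2)
  z <- propagate(c(1, 0), 0, pi / 2, ctr, function(z, u) as.numeric(A %*% z))
  expect_equal(z, c(0, -1), tolerance = 1e-4)
  # 20 random stable linear systems against the matrix exponential
  set.seed(7)
  for (i in 1:20) {
    M <- matrix(rnorm(9, sd = 0.4), 3, 3); diag(M) <- diag(M) - 0.5
    z0 <- rnorm(3)
    t1 <- runif(1, 0.5, 3)
    zh <- propagate(z0, 0, t1, ctr, function(z, u) as.numeric(M %*% z))
    oracle <- as.numeric(Matrix::expm(M * t1) %*% z0)
    expect_lt(max(abs(zh - oracle)), 1e-3)
  }
})

test_that("propagate satisfies the flow semigroup and convergence contracts", {
  ctr <- constant_controls(propofol = 50)
  f <- function(z, u) c(-0.3 * z[1] + 0.2 * tanh(z[2]) + 0.01 * u[1],
                        0.1 * z[1] - 0.2 * z[2])
  direct <- propagate(c(1, 1), 0, 10, ctr, f)
  via <- propagate(propagate(c(1, 1), 0, 4, ctr, f), 4, 10, ctr, f)
  expect_equal(direct, via, tolerance = 1e-5)
  # tightening tolerances converges toward the high-accuracy solution
  ref <- propagate(c(1, 1), 0, 10, ctr, f, ode_config(rtol = 1e-10, atol = 1e-12))
  e1 <- max(abs(propagate(c(1, 1), 0, 10, ctr, f, ode_config(1e-4, 1e-5)) - ref))
  e2 <- max(abs(propagate(c(1, 1), 0, 10, ctr, f, ode_config(1e-7, 1e-8)) - ref))
  expect_lt(e2, max(e1, 1e-9))
  expect_error(propagate(c(1, 1), 5, 4, ctr, f), "target time")
})

test_that("latent initialization respects widths and degenerate weights", {
  model <- fixture_model()
  z <- init_latent(rnorm(16), model$theta)
  expect_equal(dim(z), c(1L, 8L))
  zero_theta <- lapply(model$theta, function(m) m * 0)
  expect_equal(as.numeric(init_latent(rnorm(16), zero_theta)), rep(0, 8))
  expect_error(init_latent(rnorm(5), model$theta), "context width")
})

test_that("forecasts emit one positive-scale Gaussian per cytokine and horizon", {
  model <- fixture_model()
  es <- fixture_small_cohort()
  fc <- forecast_episodes(model, es, episode_ids = model$splits$test[1],
                          origins_h = 6)
  expect_equal(nrow(fc), 4L * 8L)   # 4 cytokines x 8 horizons
  expect_setequal(unique(fc$horizon_h), c(2, 4, 6, 8, 12, 16, 20, 24))
  expect_true(all(fc$sigma_log > 0))
  expect_true(all(fc$lo90 <= fc$mean & fc$mean <= fc$hi90))
  # all-zero head weights collapse the distributions across horizons
  m0 <- model
  m0$theta$dyn1_W[] <- 0; m0$theta$dyn1_b[] <- 0
  m0$theta$dyn2_b[] <- 0; m0$theta$dyn3_b[] <- 0
  m0$calibration <- NULL
  fc0 <- forecast_episodes(m0, es, episode_ids = model$splits$test[1], origins_h = 6)
  mu_by_h <- split(fc0$mu_log[fc0$cytokine == "il6"], fc0$horizon_h[fc0$cytokine == "il6"])
  expect_lt(max(abs(unlist(mu_by_h) - mu_by_h[[1]])), 1e-10)
})

test_that("training reduces the loss, honors ablations and reproduces under seed", {
  model <- fixture_model()
  expect_lt(tail(model$loss_history, 1), model$init_loss)
  expect_gt(model$counters$propagate, 0L)

  # -CT: propagation is never called (carry-forward latent)
  es <- fixture_small_cohort()
  cfg <- smoke_forecaster_config(epochs = 3L)
  mct <- train_forecaster(es, fixture_encoder(), cfg, seed = 4, ablate = "ct")
  expect_identical(mct$counters$propagate, 0L)

  # split overlap is rejected
  sp <- model$splits; sp$calib[1] <- sp$train[1]
  expect_error(train_forecaster(es, fixture_encoder(), cfg, splits = sp),
               "overlap")

  # seeded reproducibility of the loss trajectory
  m1 <- train_forecaster(es, fixture_encoder(), cfg, seed = 5)
  m2 <- train_forecaster(es, fixture_encoder(), cfg, seed = 5)
  expect_identical(m1$loss_history, m2$loss_history)
})
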