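test_that("partial dependence evaluates on the grid with calibrated bands", {
  model <- fixture_model()
  es <- fixture_small_cohort()
  pd <- partial_dependence(model, es, "propofol", grid = c(20, 40, 60, 80))
  expect_equal(nrow(pd), 4L)
  expect_true(all(pd$lo90 <= pd$predicted & pd$predicted <= pd$hi90))
  # grid outside the observed range is clamped with a warning
  expect_warning(partial_dependence(model, es, "ketamine", grid = c(0, 50)),
                 "clamping")
  # a constant model yields a flat curve
  m0 <- model
  m0$theta$dyn1_W[] <- 0; m0$theta$dyn1_b[] <- 0; m0$theta$dyn3_b[] <- 0
  m0$theta$phi1_W[] <- 0; m0$theta$phi1_b[] <- 0; m0$theta$phi2_b[] <- 0
  pd0 <- partial_dependence(m0, es, "propofol", grid = c(20, 50, 80))
  expect_lt(diff(range(pd0$predicted)), 1e-8)
})

test_that("the dose surface flags its argmin and a 1x1 grid is its own argmin", {
  model <- fixture_model()
  es <- fixture_small_cohort()
  s11 <- dose_surface(model, es, propofol_grid = 55, ketamine_grid = 5)
  expect_equal(nrow(s11), 1L)
  expect_true(s11$argmin)
  s <- dose_surface(model, es, propofol_grid = c(30, 60), ketamine_grid = c(0, 8))
  expect_equal(sum(s$argmin), 1L)
  s2 <- dose_surface(model, es, propofol_grid = c(30, 60), ketamine_grid = c(0, 8))
  expect_identical(s$predicted, s2$predicted)   # deterministic
})

test_that("integrated gradients satisfy completeness and vanish at the baseline", {
  model <- fixture_model()
  es <- fixture_small_cohort()
  id <- model$splits$test[1]
  ig <- integrated_gradients(model, es, id, steps = 256L)
  gap <- attr(ig, "prediction") - attr(ig, "baseline_prediction")
  expect_lt(abs(sum(ig$attribution) - gap), max(0.01 * abs(gap), 1e-6))
  # baseline-as-input: appending a cohort-median pseudo-episode leaves the
  # medians unchanged, so its own attributions vanish identically
  med_ev <- median_reference_episode(es, 6)
  base_es <- es
  base_es$events <- dplyr::bind_rows(es$events, med_ev)
  base_es$static <- dplyr::bind_rows(
    es$static, tibble::tibble(episode_id = "median"))
  ig0 <- integrated_gradients(model, base_es, "median", steps = 8L)
  expect_lt(max(abs(ig0$attribution)), 1e-8)
})

test_that("the trapezoid path integral is exact for a linear map", {
  # closed form: for F(x) = c'x, IG_i = c_i (x_i - b_i) at any step count
  set.seed(4)
  cvec <- rnorm(6); x <- rnorm(6); b <- rnorm(6)
  steps <- 4L
  alphas <- seq(0, 1, length.out = steps + 1)
  G <- vapply(alphas, function(a) cvec, numeric(6))   # gradient constant in x
  wts <- c(0.5, rep(1, steps - 1), 0.5) / steps
  ig <- (x - b) * as.numeric(G %*% wts)
  expect_equal(ig, cvec * (x - b), tolerance = 1e-12)
  expect_equal(sum(ig), sum(cvec * x) - sum(cvec * b), tolerance = 1e-12)
})

test_that("attribution tables are column-normalized across modalities", {
  model <- fixture_model()
  es <- fixture_small_cohort()
  at <- attribution_table(model, es, model$splits$test[1:2],
                          targets = c("il6", "tnfa"), steps = 8L)
  expect_equal(sum(at$il6), 1, tolerance = 1e-6)
  expect_equal(sum(at$tnfa), 1, tolerance = 1e-6)
  expect_equal(sum(at$composite), 1, tolerance = 1e-6)
  expect_true(all(at$il6 >= 0))
})
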