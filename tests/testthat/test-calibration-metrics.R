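make_pairs <- function(n, sigma_true = 1, sigma_reported = 1, seed = 1,
                       cytokine = "il6") {
  set.seed(seed)
  mu <- rnorm(n, 4, 1)
  tibble::tibble(cytokine = cytokine, mu_log = mu,
                 sigma_log = sigma_reported,
                 y_log = mu + rnorm(n, 0, sigma_true))
}

test_that("temperature scaling recovers miscalibration factors", {
  p <- make_pairs(4000, sigma_true = 1, sigma_reported = 1)
  expect_equal(fit_temperature(p)$T, 1, tolerance = 0.1)   # well calibrated -> T ~ 1
  p2 <- make_pairs(4000, sigma_true = 1, sigma_reported = 0.5, seed = 2)
  expect_equal(fit_temperature(p2)$T, 2, tolerance = 0.2)  # halved sigma -> T ~ 2
  # a single extreme outlier keeps T finite and positive
  p3 <- make_pairs(50, seed = 3)
  p3$y_log[1] <- p3$mu_log[1] + 500
  tt <- fit_temperature(p3)$T
  expect_true(is.finite(tt) && tt > 0)
  expect_error(fit_temperature(make_pairs(10)), "20")
  p4 <- make_pairs(30); p4$sigma_log[2] <- 0
  expect_error(fit_temperature(p4), "degenerate")
})

test_that("conformal offsets follow the finite-sample order statistic", {
  tmp <- tibble::tibble(cytokine = "il6", T = 1, n = 19L)
  # zero residuals collapse the intervals onto the mean
  p0 <- tibble::tibble(cytokine = "il6", mu_log = 1:19, sigma_log = 1, y_log = 1:19)
  expect_equal(fit_conformal(p0, tmp)$q, 0)
  # scores 1..19 at level 0.9 -> ceiling(20 * 0.9) = 18th smallest = 18
  p <- tibble::tibble(cytokine = "il6", mu_log = 0, sigma_log = 1, y_log = 1:19)
  expect_equal(fit_conformal(p, tmp)$q, 18)
  expect_error(fit_conformal(p[1:10, ], tmp), "at least")
})

test_that("two-stage calibration attains marginal coverage on exchangeable data", {
  # an intentionally overconfident forecaster: reported sigma is half the truth
  cover <- vapply(1:3, function(s) {
    cal <- make_pairs(300, sigma_true = 1, sigma_reported = 0.5, seed = s)
    tst <- make_pairs(2000, sigma_true = 1, sigma_reported = 0.5, seed = s + 100)
    tmp <- fit_temperature(cal)
    cf <- fit_conformal(cal, tmp, level = 0.9)
    half <- cf$q * tmp$T * tst$sigma_log
    mean(tst$y_log >= tst$mu_log - half & tst$y_log <= tst$mu_log + half)
  }, numeric(1))
  tol <- 1.96 * sqrt(0.9 * 0.1 / 2000)
  expect_true(all(cover >= 0.9 - tol))
  # raw half-sigma Gaussian intervals under-cover badly; the procedure repairs it
  tst <- make_pairs(2000, sigma_true = 1, sigma_reported = 0.5, seed = 9)
  raw <- mean(abs(tst$y_log - tst$mu_log) <= qnorm(0.95) * tst$sigma_log)
  expect_lt(raw, 0.85)
})

test_that("Gaussian CRPS matches its closed form, scaling and tail limits", {
  # frozen Monte-Carlo value for CRPS(N(0,1), 0): 10^6-sample estimate 0.2337
  expect_equal(crps_gaussian(0, 1, 0), 0.23369, tolerance = 1e-3)
  # positive homogeneity of degree 1
  expect_equal(crps_gaussian(3 * 1.5, 3 * 0.7, 3 * 2.2),
               3 * crps_gaussian(1.5, 0.7, 2.2), tolerance = 1e-12)
  # far-tail limit: CRPS -> |y - mean|
  expect_equal(crps_gaussian(0, 1, 50) / 50, 1, tolerance = 0.05)
  expect_error(crps_gaussian(0, 0, 1), "positive")
})

test_that("forecast metrics follow their definitions", {
  pairs <- tibble::tibble(
    cytokine = "il6", horizon_h = 12,
    mean = c(1, 3), y = c(2, 5),
    lo90 = c(2, 0), hi90 = c(2, 4),
    mu_log = log1p(c(1, 3)), sigma_log = 1, y_log = log1p(c(2, 5)))
  m <- forecast_metrics(pairs)
  expect_equal(m$mae, 1.5)
  expect_equal(m$rmse, sqrt(2.5))
  # first pair: zero-width interval exactly at the truth counts as covered
  expect_equal(m$coverage90, 0.5)
  perfect <- pairs
  perfect$mean <- perfect$y; perfect$lo90 <- perfect$y; perfect$hi90 <- perfect$y
  mp <- forecast_metrics(perfect)
  expect_equal(mp$mae, 0); expect_equal(mp$rmse, 0); expect_equal(mp$coverage90, 1)
  expect_error(forecast_metrics(pairs[0, ]), "pairs")
})

test_that("spike labels apply both criteria and AUROC is a midrank statistic", {
  s <- tibble::tibble(episode_id = "a", t_h = c(0, 5), value = c(50, 95))
  expect_equal(label_spikes(s, "relative")$spike, 1L)      # rise 45 within 6 h
  s2 <- tibble::tibble(episode_id = "a", t_h = c(0, 5), value = c(50, 85))
  expect_equal(label_spikes(s2, "relative")$spike, 0L)     # rise 35 only
  expect_equal(label_spikes(s2, "absolute")$spike, 0L)     # never reaches 100
  s3 <- tibble::tibble(episode_id = "a", t_h = c(0, 8), value = c(50, 120))
  expect_equal(label_spikes(s3, "relative")$spike, 0L)     # rise outside 6-h window
  expect_equal(label_spikes(s3, "absolute")$spike, 1L)
  expect_error(label_spikes(s3[1, ], "relative"), ">= 2 points")

  labels <- c(1, 1, 1, 1, 1, 0, 0, 0, 0, 0)
  expect_equal(spike_auroc(labels, labels), 1)             # perfect separation
  set.seed(1); sc <- runif(10)
  # invariance under strictly monotone transforms
  expect_equal(spike_auroc(sc, labels), spike_auroc(qlogis(sc), labels))
  expect_error(spike_auroc(sc, rep(1, 10)), "single class")
  # cross-check the midrank statistic against an established implementation
  skip_if_not_installed("pROC")
  sc2 <- c(sc[1:8], sc[1], sc[2])  # introduce ties
  ours <- spike_auroc(sc2, labels)
  ref <- suppressMessages(as.numeric(pROC::auc(labels, sc2, direction = "<")))
  expect_equal(ours, ref, tolerance = 1e-12)
})
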