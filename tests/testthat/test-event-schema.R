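test_that("episode I/O round-trips exactly and sorts events canonically", {
  es <- fixture_small_cohort()
  es$truth <- NULL
  d <- withr::local_tempdir()
  write_episodes(es, file.path(d, "e.csv"), file.path(d, "s.csv"))
  back <- read_episodes(file.path(d, "e.csv"), file.path(d, "s.csv"))
  expect_identical(back$events$value, es$events$value)
  expect_identical(back$events$t_sec, es$events$t_sec)
  expect_identical(back$events$modality, es$events$modality)
  expect_setequal(unique(back$events$episode_id), es$static$episode_id)

  # shuffled input emerges sorted, repeatedly (total order incl. tie-break)
  shuf <- es$events[sample(nrow(es$events)), ]
  es2 <- episode_set(shuf, es$static)
  expect_identical(es2$events$t_sec, es$events$t_sec)
  expect_identical(es2$events$modality, es$events$modality)

  # header-only tables round-trip an empty collection
  empty <- episode_set(es$events[0, ], es$static[0, ])
  write_episodes(empty, file.path(d, "e0.csv"), file.path(d, "s0.csv"))
  back0 <- read_episodes(file.path(d, "e0.csv"), file.path(d, "s0.csv"))
  expect_equal(nrow(back0$events), 0L)
})

test_that("schema violations are rejected with named errors", {
  ev <- tibble::tibble(episode_id = "a", t_sec = 0, modality = "XYZ", value = 1)
  st <- tibble::tibble(episode_id = "a")
  expect_error(episode_set(ev, st), "XYZ")
  expect_error(episode_set(ev[, -2], st), "t_sec")
  expect_error(
    episode_set(tibble::tibble(episode_id = "a", t_sec = 0, modality = "map", value = 1),
                tibble::tibble(episode_id = "a", age = 70, tbsa = 20, baux = 95)),
    "baux")
  expect_error(
    episode_set(tibble::tibble(episode_id = "a", t_sec = 0, modality = "map", value = 1),
                tibble::tibble(episode_id = "a", age = 70, tbsa = 120, baux = 190)),
    "tbsa")
})

test_that("standardizer matches hand arithmetic and stays frozen", {
  ev <- tibble::tibble(episode_id = "a", t_sec = c(0, 60, 120),
                       modality = "il6", value = c(1, 2, 3))
  es <- episode_set(ev, tibble::tibble(episode_id = "a"))
  std <- suppressWarnings(fit_standardizer(es))
  expect_equal(std$center[std$modality == "il6"], 2)
  expect_equal(std$scale[std$modality == "il6"], sqrt(2 / 3))

  # applying to the fit set gives mean 0 within 1e-6, per modality
  big <- fixture_small_cohort()
  std2 <- suppressWarnings(fit_standardizer(big))
  zed <- apply_standardizer(std2, big)
  for (m in c("map", "il6", "propofol")) {
    v <- zed$events$value[zed$events$modality == m & is.finite(zed$events$value)]
    expect_lt(abs(mean(v)), 1e-6)
    expect_equal(sqrt(mean((v - mean(v))^2)), 1, tolerance = 1e-6)
  }

  # frozen: applying to a disjoint set does not change parameters
  other <- simulate_cohort(sim_config(n = 5, seed = 999, vitals_every_min = 60))
  before <- std2
  invisible(apply_standardizer(std2, other))
  expect_identical(std2, before)

  # zero-variance modality falls back to scale 1 with a warning
  ev2 <- tibble::tibble(episode_id = "a", t_sec = c(0, 60),
                        modality = "hr", value = c(5, 5))
  expect_warning(s3 <- fit_standardizer(episode_set(ev2, tibble::tibble(episode_id = "a"))),
                 "zero variance")
  expect_equal(s3$scale[s3$modality == "hr"], 1)
})

test_that("lab masking removes the exact count, labs only, reproducibly", {
  es <- fixture_small_cohort()
  n_lab <- sum(es$events$modality %in% c("il6", "crp", "tnfa", "il10"))
  n_other <- nrow(es$events) - n_lab

  m0 <- mask_labs(es, 0)
  expect_identical(m0$events, es$events)

  m75 <- mask_labs(es, 0.75, seed = 3)
  kept_lab <- sum(m75$events$modality %in% c("il6", "crp", "tnfa", "il10"))
  expect_equal(kept_lab, n_lab - round(0.75 * n_lab))
  expect_equal(nrow(m75$events) - kept_lab, n_other)

  m75b <- mask_labs(es, 0.75, seed = 3)
  expect_identical(m75$events, m75b$events)
  expect_error(mask_labs(es, 1), "fraction")
})

test_that("analysis eligibility requires two labs in the (6, 24] hour window", {
  ev <- tibble::tibble(
    episode_id = c("a", "a", "a", "b", "b"),
    t_sec = c(7, 10, 23, 2, 25) * 3600,
    modality = "il6", value = 50)
  es <- episode_set(ev, tibble::tibble(episode_id = c("a", "b")))
  el <- analysis_eligible(es)
  expect_true(el$eligible[el$episode_id == "a"])
  expect_false(el$eligible[el$episode_id == "b"])
  expect_equal(as_relative_time(100, 40), 60)
})
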