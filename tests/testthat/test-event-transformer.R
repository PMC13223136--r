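test_that("continuous-time positional encoding has the sinusoid structure", {
  pe <- time_positional_encoding(c(0, 3600, 3600), 8)
  expect_equal(pe[1, ], rep(c(0, 1), 4))          # t = 0 -> (sin 0, cos 0, ...)
  expect_equal(pe[2, ], pe[3, ])                  # equal timestamps, equal rows
  # rotation identity: encoding at t + dt is a per-frequency rotation of t
  w <- 10000^(-(0:3) / 4)
  t1 <- 2.5; dt <- 1.25
  p1 <- time_positional_encoding(t1 * 3600, 8)
  p2 <- time_positional_encoding((t1 + dt) * 3600, 8)
  for (i in 1:4) {
    s <- p1[1, 2 * i - 1]; cc <- p1[1, 2 * i]
    rot <- c(s * cos(w[i] * dt) + cc * sin(w[i] * dt),
             cc * cos(w[i] * dt) - s * sin(w[i] * dt))
    expect_equal(c(p2[1, 2 * i - 1], p2[1, 2 * i]), rot, tolerance = 1e-12)
  }
  expect_error(time_positional_encoding(0, 7), "even")
})

test_that("event embedding distinguishes modalities and respects canonical order", {
  enc <- new_encoder(fixture_standardizer(), smoke_encoder_config(), seed = 1)
  ev1 <- tibble::tibble(episode_id = "a", t_sec = 100, modality = "map", value = 1.2)
  tok1 <- ctdose:::ad_with_tape(embed_events(ev1, enc)$val)
  expect_equal(dim(tok1), c(1L, 16L))
  ev2 <- ev1; ev2$modality <- "hr"
  tok2 <- ctdose:::ad_with_tape(embed_events(ev2, enc)$val)
  expect_false(isTRUE(all.equal(tok1, tok2)))  # same value, different modality

  # permuting events then re-sorting through episode_set gives identical tokens
  es <- fixture_small_cohort()
  ev <- es$events[es$events$episode_id == es$static$episode_id[1], ][1:20, ]
  perm <- episode_set(ev[sample(20), ], es$static[1, ])$events
  a <- ctdose:::ad_with_tape(embed_events(ev, enc)$val)
  b <- ctdose:::ad_with_tape(embed_events(perm, enc)$val)
  expect_equal(a, b)
  expect_error(embed_events(ev[0, ], enc), "empty")
})

test_that("episode encoding is deterministic, width-true and input-sensitive", {
  enc <- fixture_encoder()
  es <- fixture_small_cohort()
  ev <- es$events[es$events$episode_id == es$static$episode_id[2] &
                    es$events$t_sec <= 6 * 3600, ]
  z1 <- encode_episode(ev, enc)
  z2 <- encode_episode(ev, enc)
  expect_identical(z1, z2)
  expect_length(z1, 16L)
  expect_true(all(is.finite(z1)))
  # width-32 configuration produces a width-32 context
  enc32 <- new_encoder(fixture_standardizer(),
                       encoder_config(layers = 1L, heads = 2L, d = 32L,
                                      pretrain_epochs = 1L), seed = 2)
  expect_length(encode_episode(ev, enc32), 32L)
  # perturbing one event changes the context (non-degeneracy)
  ev2 <- ev; ev2$value[5] <- ev2$value[5] + 50
  expect_false(isTRUE(all.equal(z1, encode_episode(ev2, enc))))
  expect_error(encode_episode(ev[0, ], enc), "static-only fallback")
})

test_that("masked-value pre-training reduces the reconstruction loss", {
  enc <- fixture_encoder()
  lh <- enc$loss_history
  expect_lt(lh[length(lh)], enc$init_loss)   # below the untrained baseline
  expect_true(enc$pretrained)
  # mask rate zero is a configuration error for pre-training
  expect_error(
    pretrain_masked_modality(fixture_small_cohort(), fixture_standardizer(),
                             smoke_encoder_config(mask_rate = 0), seed = 1),
    "mask_rate")
})

test_that("pre-training is reproducible under a fixed seed", {
  es <- subset_episodes(fixture_small_cohort(),
                        fixture_small_cohort()$static$episode_id[1:8])
  cfg <- smoke_encoder_config(pretrain_epochs = 1L)
  e1 <- pretrain_masked_modality(es, fixture_standardizer(), cfg, seed = 42)
  e2 <- pretrain_masked_modality(es, fixture_standardizer(), cfg, seed = 42)
  expect_identical(e1$theta, e2$theta)
  expect_identical(e1$loss_history, e2$loss_history)
})
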