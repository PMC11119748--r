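# multi-task regressor: forward contracts, loss, training, aggregation

zero_weights <- function(emb_dim = 512L, b_int = 0, b_sev = 0) {
  w <- init_regressor_weights(1L, emb_dim)
  for (nm in c("W1", "W2", "W_int", "W_sev")) w[[nm]] <- w[[nm]] * 0
  w$b1 <- w$b1 * 0; w$b2 <- w$b2 * 0
  w$b_int <- b_int; w$b_sev <- b_sev
  w
}

test_that("zero weights with head biases pass them through; clamping applies", {
  w <- zero_weights(b_int = 3, b_sev = 7)
  p <- reg_forward(rnorm(512), w)
  expect_equal(c(p$int, p$sev), c(3, 7))
  w2 <- zero_weights(b_int = -5, b_sev = 14)
  p2 <- reg_forward(rnorm(512), w2)
  expect_equal(c(p2$int, p2$sev), c(0, 10))
})

test_that("infer mode is deterministic and range-bounded for arbitrary input", {
  w <- init_regressor_weights(8L)
  set.seed(1)
  x <- matrix(rnorm(20 * 512, 0, 50), 20)  # wild inputs
  p1 <- reg_forward(x, w)
  p2 <- reg_forward(x, w)
  expect_identical(p1, p2)
  expect_true(all(p1$int >= 0 & p1$int <= 10 & p1$sev >= 0 & p1$sev <= 10))
  expect_error(reg_forward(rnorm(100), w), class = "ps_config_error")
})

test_that("multitask loss equals the weighted sum of per-task MSEs", {
  t0 <- data.frame(int = c(1, 2, 3), sev = c(4, 5, 6))
  expect_identical(multitask_loss(t0, t0), 0)
  # crafted per-task MSEs (2, 4): residuals sqrt(2) and 2 everywhere
  pred <- data.frame(int = t0$int + sqrt(2), sev = t0$sev - 2)
  expect_equal(multitask_loss(pred, t0, c(0.5, 0.5)), 3)
  expect_equal(multitask_loss(pred, t0, c(1, 0)), 2)
  expect_equal(multitask_loss(pred, t0, c(0, 1)), 4)
  expect_error(multitask_loss(pred, t0[1:2, ]), class = "ps_validation_error")
  expect_error(multitask_loss(pred[0, ], t0[0, ]), class = "ps_validation_error")
})

test_that("multitask loss matches a brute-force oracle on random batches", {
  set.seed(99)
  for (i in 1:10) {
    n <- sample(2:30, 1)
    pred <- data.frame(int = runif(n, 0, 10), sev = runif(n, 0, 10))
    ref <- data.frame(int = runif(n, 0, 10), sev = runif(n, 0, 10))
    wts <- runif(1); wts <- c(wts, 1 - wts)
    brute <- wts[1] * sum((pred$int - ref$int)^2) / n +
      wts[2] * sum((pred$sev - ref$sev)^2) / n
    expect_equal(multitask_loss(pred, ref, wts), brute, tolerance = 1e-9)
  }
})

test_that("training descends, is seed-reproducible, and validates input", {
  cohort <- sample_cohort(cohort_spec(n_speakers = 64L, seed = 11L))
  tab <- cohort_to_training_table(cohort)
  cfg <- training_config(epochs = 6L, seed = 21L)
  fit1 <- train_regressor(tab, cfg)
  expect_length(fit1$loss_trace, 6L)
  expect_lt(fit1$loss_trace[6], fit1$loss_trace[1])
  fit2 <- train_regressor(tab, cfg)
  expect_identical(fit1$loss_trace, fit2$loss_trace)
  expect_identical(fit1$weights$W1, fit2$weights$W1)
  expect_error(train_regressor(list(embeddings = tab$embeddings[0, ],
                                    targets = tab$targets[0, ]), cfg),
               class = "ps_validation_error")
})

test_that("duplicated targets keep the two heads in lockstep", {
  cohort <- sample_cohort(cohort_spec(n_speakers = 48L, seed = 31L))
  tab <- cohort_to_training_table(cohort)
  tab$targets$sev <- tab$targets$int  # SEV duplicates INT
  init <- init_regressor_weights(41L, 512L)
  init$W_sev <- init$W_int
  init$b_sev <- init$b_int
  fit <- train_regressor(tab, training_config(epochs = 4L, seed = 41L),
                         init_weights = init)
  # symmetric start + identical targets => identical head trajectories,
  # hence equal per-task losses at every step
  expect_equal(fit$weights$W_sev, fit$weights$W_int, tolerance = 1e-12)
  expect_equal(fit$weights$b_sev, fit$weights$b_int, tolerance = 1e-12)
})

test_that("the paper recipe recovers scores from a linear synthetic cohort", {
  tr <- sample_cohort(cohort_spec(n_speakers = 200L, seed = 171L))
  te <- sample_cohort(cohort_spec(n_speakers = 100L, seed = 871L))
  fit <- train_regressor(cohort_to_training_table(tr),
                         training_config(seed = 171L))
  p <- predict_scores(te$embeddings, fit$weights)
  expect_gte(spearman(p$int, te$speakers$int), 0.9)
  expect_gte(spearman(p$sev, te$speakers$sev), 0.9)
})

test_that("recording-level prediction honors strategy and range", {
  cohort <- sample_cohort(cohort_spec(n_speakers = 3L, seed = 51L))
  w <- synth_passage_audio(cohort$speakers[2, ], seed = 8L)
  ext <- init_random_weights(61L)
  const <- zero_weights(b_int = 4.5, b_sev = 2.5)
  # constant regressor: segments mean equals the whole-recording value
  p_whole <- predict_recording(w, ext, const, strategy = "whole")
  p_segs <- predict_recording(w, ext, const, strategy = "segments")
  expect_equal(p_whole, c(int = 4.5, sev = 2.5))
  expect_equal(p_segs, p_whole)
  trained <- init_regressor_weights(71L)
  p <- predict_recording(w, ext, trained, strategy = "segments")
  expect_true(all(p >= 0 & p <= 10))
})

test_that("speaker-disjoint split covers all ids exactly once", {
  ids <- sprintf("SPK%03d", 1:37)
  sp <- split_speakers(ids, prop_train = 0.8, seed = 3L)
  expect_length(intersect(sp$train, sp$test), 0L)
  expect_setequal(c(sp$train, sp$test), ids)
  expect_identical(sp, split_speakers(ids, prop_train = 0.8, seed = 3L))
})

test_that("training config validates the stated invariants", {
  cfg <- training_config()
  expect_equal(cfg$learning_rate, 0.001)
  expect_identical(cfg$batch_size, 8L)
  expect_identical(cfg$epochs, 20L)
  expect_equal(cfg$dropout, 0.2)
  expect_equal(cfg$loss_weights, c(0.5, 0.5))
  expect_error(training_config(loss_weights = c(0.6, 0.6)),
               class = "ps_validation_error")
  expect_error(training_config(dropout = 1), class = "ps_validation_error")
})
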