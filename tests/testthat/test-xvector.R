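# front end, statistics pooling, embedding extraction, weight handling

test_that("framing yields the closed-form frame count and mean normalization", {
  w <- make_tone(180, dur = 1.0, n_harm = 3L)
  ff <- compute_features(w)
  expect_identical(nrow(ff), 98L)   # floor((16000 - 400) / 160) + 1
  expect_identical(ncol(ff), 24L)
  expect_true(all(abs(colMeans(ff)) < 1e-6))
  expect_error(compute_features(make_tone(180, dur = 0.3)),
               class = "ps_validation_error")
})

test_that("pure silence sits at the configured log floor", {
  w <- waveform(numeric(SR), SR)
  ff <- compute_features(w, mean_norm = FALSE, log_floor = 1e-10)
  expect_true(all(ff == log(1e-10)))
})

test_that("statistics pooling matches hand-computed mean and population sd", {
  expect_equal(statistics_pool(matrix(c(0, 2), 2, 1)), c(1, 1))
  v <- c(3, -1, 2)
  expect_equal(statistics_pool(matrix(v, 5, 3, byrow = TRUE)),
               c(v, 0, 0, 0))
  set.seed(42)
  for (i in 1:5) {
    m <- matrix(rnorm(17 * 6), 17)
    mu <- apply(m, 2, mean)
    sd_pop <- sqrt(apply(m, 2, function(x) mean((x - mean(x))^2)))
    expect_equal(statistics_pool(m), c(mu, sd_pop), tolerance = 1e-12)
    perm <- m[sample(nrow(m)), ]
    expect_equal(statistics_pool(perm), statistics_pool(m), tolerance = 1e-12)
  }
  expect_error(statistics_pool(matrix(numeric(0), 0, 3)),
               class = "ps_validation_error")
})

test_that("pooling over concatenated identical halves equals pooling one half", {
  set.seed(7)
  m <- matrix(rnorm(40), 10)
  expect_equal(statistics_pool(rbind(m, m)), statistics_pool(m),
               tolerance = 1e-12)
})

test_that("embeddings are 512-dimensional and deterministic for any duration", {
  wts <- init_random_weights(13L)
  short <- make_tone(140, dur = 1, n_harm = 4L)
  long <- make_tone(140, dur = 10, n_harm = 4L)
  e1 <- extract_embedding(short, wts)
  e2 <- extract_embedding(long, wts)
  expect_length(e1, 512L)
  expect_length(e2, 512L)
  expect_true(all(is.finite(e1)) && all(is.finite(e2)))
  expect_identical(e1, extract_embedding(short, wts))
  # both tap layers honor the fixed-length contract
  expect_length(extract_embedding(short, wts, tap = "first"), 512L)
  expect_false(identical(extract_embedding(short, wts, tap = "first"), e1))
})

test_that("appending 100 ms of silence moves the embedding by under 10 percent", {
  # passage-scale (5 s) non-stationary fixture; a short stationary tone has
  # near-zero feature variance after mean normalization and is degenerate
  wts <- init_random_weights(13L)
  w <- speech_like_tone(5)
  padded <- waveform(c(w$samples, numeric(SR %/% 10)), SR)
  e <- extract_embedding(w, wts)
  ep <- extract_embedding(padded, wts)
  expect_lt(sqrt(sum((e - ep)^2)) / sqrt(sum(e^2)), 0.10)
})

test_that("within-speaker cosine similarity exceeds between-speaker", {
  wts <- init_random_weights(29L)
  clip <- function(f0, n_harm, seed) {
    set.seed(seed)
    t <- (seq_len(SR) - 1) / SR
    x <- Reduce(`+`, lapply(seq_len(n_harm), function(h) {
      sin(2 * pi * h * f0 * t + runif(1, 0, 2 * pi)) / h
    }))
    waveform(0.8 * x / max(abs(x)), SR)
  }
  emb_a <- lapply(1:10, function(s) extract_embedding(clip(110, 8L, s), wts))
  emb_b <- lapply(1:10, function(s) {
    extract_embedding(clip(260, 3L, 100 + s), wts)
  })
  within <- c(
    utils::combn(10, 2, function(ij) cosine_sim(emb_a[[ij[1]]], emb_a[[ij[2]]])),
    utils::combn(10, 2, function(ij) cosine_sim(emb_b[[ij[1]]], emb_b[[ij[2]]]))
  )
  between <- as.vector(outer(1:10, 1:10, Vectorize(function(i, j) {
    cosine_sim(emb_a[[i]], emb_b[[j]])
  })))
  expect_gt(mean(within), mean(between))
})

test_that("seeded weights are reproducible, distinct across seeds, serializable", {
  w1 <- init_random_weights(5L)
  w2 <- init_random_weights(5L)
  w3 <- init_random_weights(6L)
  expect_identical(w1$frame, w2$frame)
  expect_identical(w1$segment, w2$segment)
  expect_false(identical(w1$frame[[1]]$W, w3$frame[[1]]$W))

  f <- tempfile(fileext = ".rds")
  save_extractor_weights(w1, f)
  expect_identical(load_extractor_weights(f)$frame, w1$frame)
})

test_that("plain-text weight interchange round-trips through the manifest", {
  w <- init_random_weights(3L)
  d <- tempfile()
  export_weights_tsv(w, d)
  man <- read.table(file.path(d, "manifest.tsv"), header = TRUE, sep = "\t")
  expect_identical(nrow(man), 7L)  # 5 frame + 2 segment layers
  back <- import_weights_tsv(d)
  expect_equal(back$frame[[2]]$W, w$frame[[2]]$W, tolerance = 1e-15)
  expect_equal(back$segment[[1]]$b, w$segment[[1]]$b, tolerance = 1e-15)
  tone <- make_tone(200, dur = 1, n_harm = 3L)
  expect_equal(extract_embedding(tone, back), extract_embedding(tone, w),
               tolerance = 1e-10)
})

test_that("shape mismatches are configuration errors naming the layer", {
  w <- init_random_weights(4L)
  w$frame[[3]]$W <- w$frame[[3]]$W[, 1:100]
  err <- expect_error(extract_embedding(make_tone(200), w),
                      class = "ps_config_error")
  expect_match(conditionMessage(err), "frame layer 3")
  w2 <- init_random_weights(4L)
  w2$segment[[2]]$W <- matrix(0, 10, 10)
  err2 <- expect_error(validate_extractor_weights(w2),
                       class = "ps_config_error")
  expect_match(conditionMessage(err2), "segment layer 2")
})
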