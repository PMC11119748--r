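# Spearman, RMSE, ICC (two-way mixed, absolute agreement), evaluation report

test_that("spearman matches hand computation and rank invariance", {
  expect_equal(spearman(1:5, 1:5), 1)
  expect_equal(spearman(c(1, 2, 3), c(3, 1, 2)), -0.5)  # 1 - 6*9/(3*8)
  x <- c(0.2, 1.4, 3.3, 2.2, 5.0, 4.1)
  y <- c(2.0, 1.1, 4.4, 3.9, 4.0, 6.2)
  expect_equal(spearman(x, y), spearman(x, exp(y)))
  expect_equal(spearman(x, y), spearman(y, x))
  expect_error(spearman(x, y[1:3]), class = "ps_validation_error")
  expect_error(spearman(c(1, 2), c(2, 1)), class = "ps_validation_error")
  expect_error(spearman(rep(2, 5), 1:5), class = "ps_validation_error")
})

test_that("spearman equals Pearson on mid-ranks, including ties", {
  set.seed(12)
  for (i in 1:8) {
    x <- sample(0:10, 25, replace = TRUE)  # clinical scores tie often
    y <- pmin(10, pmax(0, x + rnorm(25, 0, 2)))
    expect_equal(spearman(x, y), cor(rank(x), rank(y)), tolerance = 1e-12)
  }
})

test_that("rmse satisfies its hand cases and symmetry", {
  expect_identical(rmse(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(rmse(c(4, -2), c(1, 1)), 3)   # residuals (3, -3)
  expect_equal(rmse(1:10 + 0.7, 1:10), 0.7)  # constant offset
  set.seed(3)
  a <- runif(20); b <- runif(20)
  expect_equal(rmse(a, b), rmse(b, a))
  expect_error(rmse(a, b[1:3]), class = "ps_validation_error")
})

test_that("ICC is 1 for identical judges and penalizes systematic bias", {
  base <- c(2, 5, 7, 9, 4, 6, 1, 8)
  r_same <- matrix(base, 8, 4)
  expect_equal(icc_absolute_agreement(r_same, "single"), 1)
  expect_equal(icc_absolute_agreement(r_same, "average"), 1)
  r_bias <- cbind(base, base, base, base + 1)  # one judge offset
  expect_lt(icc_absolute_agreement(r_bias, "single"), 1)
  expect_lt(icc_absolute_agreement(r_bias, "average"), 1)
})

test_that("ICC reproduces reference values frozen from an external oracle", {
  # ICC(A,1) / ICC(A,k) for this matrix computed once with Python pingouin
  m <- matrix(c(9, 2, 5, 8,
                6, 1, 3, 2,
                8, 4, 6, 8,
                7, 1, 2, 6,
                10, 5, 6, 9,
                6, 2, 4, 7), 6, 4, byrow = TRUE)
  expect_equal(icc_absolute_agreement(m, "single"), 0.289764, tolerance = 1e-5)
  expect_equal(icc_absolute_agreement(m, "average"), 0.620051, tolerance = 1e-5)
})

test_that("negative estimates are reported unless floored", {
  set.seed(8)
  r <- matrix(rnorm(40, 5, 1), 20, 2)  # no subject effect at all
  v <- icc_absolute_agreement(r, "single")
  expect_lt(v, 0.3)
  if (v < 0) expect_identical(icc_absolute_agreement(r, "single",
                                                     floor_negative = TRUE), 0)
  expect_gte(icc_absolute_agreement(r, "single", floor_negative = TRUE), 0)
  expect_error(icc_absolute_agreement(matrix(1:6, 6, 1)),
               class = "ps_validation_error")
})

test_that("simulated panels concentrate near the variance-components closed form", {
  # s ~ N(5, 2), b ~ N(0, 1), e ~ N(0, 1): ICC(A,1) = 4 / (4 + 1 + 1)
  sim_icc <- function(n, k, seed) {
    set.seed(seed)
    s <- rnorm(n, 5, 2); b <- rnorm(k, 0, 1)
    r <- outer(s, rep(1, k)) + outer(rep(1, n), b) + matrix(rnorm(n * k), n)
    icc_absolute_agreement(r, "single")
  }
  v <- sim_icc(500, 6, 1234)
  expect_lt(abs(v - 2 / 3), 0.05)
  # estimator consistency: error shrinks with n (averaged over replicates)
  err_small <- mean(abs(vapply(1:8, function(s) sim_icc(60, 6, s), 0) - 2 / 3))
  err_big <- mean(abs(vapply(1:8, function(s) sim_icc(960, 6, s), 0) - 2 / 3))
  expect_lt(err_big, err_small)
})

test_that("evaluate matches on the id intersection and records n", {
  ref <- data.frame(id = sprintf("P%02d", 1:10),
                    int = seq(1, 10), sev = seq(10, 1))
  perfect <- evaluate(ref, ref)
  expect_equal(perfect$spearman_int, 1)
  expect_equal(perfect$rmse_sev, 0)
  expect_identical(perfect$n, 10L)

  pred <- ref[3:10, ]
  pred$int <- pred$int + c(0.5, -0.5)
  rep2 <- evaluate(pred, ref)
  expect_identical(rep2$n, 8L)
  expect_equal(rep2$rmse_int, 0.5)

  disjoint <- ref; disjoint$id <- sprintf("Q%02d", 1:10)
  expect_error(evaluate(disjoint, ref), class = "ps_validation_error")
})

test_that("injected noise of sd 1 yields RMSE near 1 at n = 500", {
  set.seed(77)
  ref <- data.frame(id = seq_len(500), int = runif(500, 0, 10),
                    sev = runif(500, 0, 10))
  pred <- ref
  pred$int <- pred$int + rnorm(500)
  pred$sev <- pred$sev + rnorm(500)
  rep <- evaluate(pred, ref)
  expect_gt(rep$rmse_int, 0.8); expect_lt(rep$rmse_int, 1.2)
  expect_gt(rep$rmse_sev, 0.8); expect_lt(rep$rmse_sev, 1.2)
})

test_that("ratings matrices round-trip as TSV and validate their scale", {
  r <- ratings_matrix(matrix(runif(24, 0, 10), 6, 4,
                             dimnames = list(sprintf("S%d", 1:6),
                                             sprintf("J%d", 1:4))))
  f <- tempfile(fileext = ".tsv")
  write_ratings_tsv(r, f)
  back <- read_ratings_tsv(f)
  expect_equal(unclass(back), unclass(r), tolerance = 1e-9,
               ignore_attr = FALSE)
  expect_error(ratings_matrix(matrix(11, 3, 3)), class = "ps_validation_error")
  expect_error(ratings_matrix(matrix(1, 1, 5)), class = "ps_validation_error")
})
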