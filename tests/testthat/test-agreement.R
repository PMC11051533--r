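mk_set <- function(coords, obs, rep = 1L, subject = "s") {
  landmark_set(coords, subject, obs, repeat_id = rep)
}

test_that("landmark errors are distances to the design's ground truth", {
  a <- mk_set(rbind(P = c(0, 0, 0)), "a")
  b <- mk_set(rbind(P = c(2, 0, 0)), "b")
  err <- landmark_errors(list(a, b), "INTER")
  expect_equal(sort(err$error), c(1, 1))
  # identical observations give zero error
  err0 <- landmark_errors(list(a, mk_set(rbind(P = c(0, 0, 0)), "a", 2)),
                          "INTRA")
  expect_equal(err0$error, c(0, 0))
  # random 3-observer sets match direct norm computation
  set.seed(9)
  obs <- lapply(1:3, function(i) {
    co <- matrix(rnorm(9), 3, 3,
                 dimnames = list(c("P", "Q", "R"), NULL))
    mk_set(co, paste0("o", i))
  })
  err3 <- landmark_errors(obs, "INTER")
  gt <- Reduce(`+`, lapply(obs, `[[`, "coordinates")) / 3
  for (i in 1:3) {
    d <- sqrt(rowSums((obs[[i]]$coordinates - gt)^2))
    got <- err3$error[err3$observer == paste0("o", i)]
    expect_equal(unname(got), unname(d))
  }
  # METHOD compares the automated set with the expert mean
  auto <- mk_set(rbind(P = c(1, 1, 1)), "AUTO")
  em <- landmark_errors(list(a, b), "METHOD", auto = auto)
  expect_equal(em$error, sqrt(0 + 1 + 1))
  expect_error(landmark_errors(list(a, b), "INTRA"), "single observer")
})

test_that("measurement errors use absolute differences from the mean", {
  df <- data.frame(subject = "s", observer = "o1", "repeat" = 1:3,
                   abbreviation = "AP MFC", value_mm = c(10, 12, 14),
                   check.names = FALSE)
  err <- measurement_errors(df, "INTRA")
  expect_equal(sort(err$error), c(0, 2, 2))
  inter <- data.frame(subject = "s", observer = c("o1", "o2"),
                      "repeat" = 1L, abbreviation = "AP MFC",
                      value_mm = c(10, 13), check.names = FALSE)
  auto <- data.frame(subject = "s", observer = "AUTO", "repeat" = 1L,
                     abbreviation = "AP MFC", value_mm = 10,
                     check.names = FALSE)
  em <- measurement_errors(inter, "METHOD", auto = auto)
  expect_equal(em$error, 1.5)
})

test_that("quartile summaries implement the 1.5 IQR rule exactly", {
  qs <- quartile_summary(c(1, 2, 3, 4, 5))
  expect_equal(qs$median, 3)
  expect_equal(qs$iqr, qs$q3 - qs$q1)
  expect_equal(qs$outlier_low, qs$q1 - 1.5 * qs$iqr)
  expect_equal(qs$outlier_high, qs$q3 + 1.5 * qs$iqr)
  expect_length(qs$outlier_ids, 0)
  # quartiles follow the interpolating (type 7) convention
  expect_equal(qs$q1, unname(quantile(1:5, 0.25, type = 7)))
  qs2 <- quartile_summary(c(1, 1, 1, 1, 100))
  expect_equal(qs2$outlier_ids, 5L)
  qs3 <- quartile_summary(rep(2, 10))
  expect_equal(qs3$iqr, 0)
  expect_error(quartile_summary(numeric(0)), "no samples")
})

test_that("ICC is 1 for identical raters and near 0 for pure rater offset", {
  set.seed(14)
  x <- rnorm(10)
  same <- cbind(x, x, x)
  r <- icc(same, "TWO_WAY_RANDOM")
  expect_equal(r$value, 1, tolerance = 1e-12)
  # large systematic offset with small subject variance: absolute agreement
  # penalizes the bias
  small <- rnorm(10, sd = 0.1)
  off <- cbind(small, small + 50)
  expect_lt(icc(off, "TWO_WAY_RANDOM")$value, 0.05)
  # degenerate all-equal table reports 1 with a flag
  dg <- icc(matrix(3, 4, 3), "TWO_WAY_MIXED")
  expect_true(dg$degenerate)
  expect_equal(dg$value, 1)
  expect_error(icc(matrix(1:3, 3, 1)), ">= 2")
})

test_that("Bland-Altman limits equal bias +/- 1.96 SD by direct computation", {
  expect_error(bland_altman(1, 1), ">= 2")
  ba0 <- bland_altman(c(1, 2, 3), c(1, 2, 3))
  expect_equal(ba0$bias, 0)
  expect_equal(ba0$loa_low, 0)
  expect_equal(ba0$loa_high, 0)
  ba1 <- bland_altman(c(1, 2, 3), c(2, 3, 4))
  expect_equal(ba1$bias, 1)
  expect_equal(ba1$sd_diff, 0)
  set.seed(6)
  m <- rnorm(20); a <- m + rnorm(20, 0.5, 0.3)
  ba <- bland_altman(m, a)
  expect_equal(ba$bias, mean(a - m))
  expect_equal(ba$loa_high, mean(a - m) + 1.96 * sd(a - m))
  expect_true(ba$loa_low <= ba$bias && ba$bias <= ba$loa_high)
})

test_that("success rates are the empirical CDF of the errors", {
  sc <- success_rates(c(1, 2, 3, 5), c(0.5, 4, 10))
  expect_equal(sc$rates, c(0, 0.75, 1))
  set.seed(7)
  e <- rexp(50)
  grid <- seq(0.1, 5, by = 0.1)
  sc2 <- success_rates(e, grid)
  expect_equal(sc2$rates, ecdf(e)(grid))
  expect_true(all(diff(sc2$rates) >= 0))
  expect_error(success_rates(e, c(-1, 2)), "> 0")
})

test_that("per-subject outlier counts recover planted gross errors", {
  set.seed(8)
  df <- data.frame(
    subject = rep(paste0("s", 1:5), each = 4),
    item = rep(c("A", "B", "C", "D"), times = 5),
    comparison = "METHOD",
    error = rep(c(1, 1.2, 1.4, 1.1), times = 5)
  )
  df$error[df$subject == "s3" & df$item == "B"] <- 50   # planted
  out <- outliers_per_subject(df)
  expect_equal(out$n_outliers[out$subject == "s3"], 1)
  expect_true(all(out$n_outliers[out$subject != "s3"] == 0))
})
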