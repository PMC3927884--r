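test_that("normalization centres and scales by the sample SD", {
  ts <- time_series("A", "run_count", "pooled", 2001:2003, c(1, 2, 3))
  nz <- normalize_series(ts)
  expect_equal(nz$values, c(-1, 0, 1))
  expect_equal(mean(nz$values), 0, tolerance = 1e-12)
  expect_equal(sd(nz$values), 1, tolerance = 1e-12)
  ## idempotent within tolerance
  expect_equal(normalize_series(nz)$values, nz$values, tolerance = 1e-12)
  expect_error(normalize_series(time_series("A", "run_count", "pooled",
                                            2001L, 5)), "2 records")
  expect_error(normalize_series(time_series("A", "run_count", "pooled",
                                            2001:2004, rep(7, 4))), "constant")
})

test_that("Theil-Sen slope is the all-pairs median", {
  yrs <- 1990:2009
  exact <- time_series("A", "mean_length", "F", yrs, 3 - 0.75 * (yrs - 1990))
  expect_equal(theil_sen(exact), -0.75, tolerance = 1e-12)
  ## 3 points with an outlier: pairwise slopes {1, 49.5, 98}, median 49.5
  out <- time_series("A", "run_count", "pooled", 1:3, c(1, 2, 100))
  expect_equal(theil_sen(out), 49.5)
  expect_equal(theil_sen(time_series("A", "run_count", "pooled", 1:5,
                                     rep(2, 5))), 0)

  ## brute-force oracle on 100 random gapped series
  set.seed(101)
  for (i in 1:100) {
    n <- sample(4:15, 1)
    yrs <- sort(sample(1970:2010, n))
    v <- rnorm(n)
    ts <- time_series("A", "run_count", "pooled", yrs, v)
    slopes <- c()
    for (a in 1:(n - 1)) for (b in (a + 1):n)
      slopes <- c(slopes, (v[b] - v[a]) / (yrs[b] - yrs[a]))
    expect_equal(theil_sen(ts), median(slopes), tolerance = 1e-12)
  }
})

test_that("Mann-Kendall S, tau and categories behave at the extremes", {
  up <- time_series("A", "run_count", "pooled", 1:5, c(1, 2, 3, 4, 5))
  r <- mann_kendall(up)
  expect_equal(r$mk_S, 10L)
  expect_equal(r$tau, 1)
  expect_equal(r$category, "significant increase")

  down <- time_series("A", "run_count", "pooled", 1:4, c(4, 3, 2, 1))
  r2 <- mann_kendall(down)
  expect_equal(r2$mk_S, -6L)
  expect_equal(r2$tau, -1)

  tied <- time_series("A", "run_count", "pooled", 1:5, rep(3, 5))
  r3 <- mann_kendall(tied)
  expect_equal(r3$mk_S, 0L)
  expect_equal(r3$p_value, 1)
  expect_equal(r3$category, "no change")

  ## S flips sign under series reversal
  set.seed(102)
  for (i in 1:25) {
    n <- sample(5:20, 1)
    v <- rnorm(n)
    f <- mann_kendall(time_series("A", "run_count", "pooled", 1:n, v))
    b <- mann_kendall(time_series("A", "run_count", "pooled", 1:n, rev(v)))
    expect_equal(f$mk_S, -b$mk_S)
  }
})

test_that("Mann-Kendall type-I error is calibrated on white noise", {
  set.seed(103)
  rej <- mean(replicate(1000, {
    v <- rnorm(20)
    mann_kendall(time_series("A", "run_count", "pooled", 1:20, v))$p_value < 0.05
  }))
  expect_gte(rej, 0.03)
  expect_lte(rej, 0.07)
})

test_that("slope comparisons reproduce one-way ANOVA and flag offsets", {
  ## hand-computed one-way ANOVA on a 3-group toy table
  toy <- data.frame(slope = c(1, 2, 3, 2, 3, 4, 6, 7, 8),
                    stock = rep(c("a", "b", "c"), each = 3))
  res <- slope_comparison(toy, "stock")
  gm <- mean(toy$slope)
  ssb <- 3 * sum((tapply(toy$slope, toy$stock, mean) - gm)^2)
  ssw <- sum((toy$slope - rep(tapply(toy$slope, toy$stock, mean), each = 3))^2)
  f_hand <- (ssb / 2) / (ssw / 6)
  expect_equal(unname(res$anova$`F value`[1]), f_hand, tolerance = 1e-9)

  ## identical slope sets: F ~ 0, Tukey p ~ 1
  same <- data.frame(slope = rep(c(1, 2, 3), 2),
                     stock = rep(c("a", "b"), each = 3))
  r0 <- slope_comparison(same, "stock")
  expect_lt(unname(r0$anova$`F value`[1]), 1e-9)
  expect_gt(r0$tukey$stock[1, "p adj"], 0.999)

  ## strong offset: factor significant, offset pair flagged
  set.seed(104)
  off <- data.frame(slope = c(rnorm(6, 0, 0.1), rnorm(6, 5, 0.1),
                              rnorm(5, 0, 0.1)),
                    stock = c(rep("a", 6), rep("b", 6), rep("c", 5)))
  r1 <- slope_comparison(off, "stock")
  expect_lt(unname(r1$anova$`Pr(>F)`[1]), 0.01)
  expect_lt(r1$tukey$stock["b-a", "p adj"], 0.01)
  expect_gt(r1$tukey$stock["c-a", "p adj"], 0.05)

  expect_error(slope_comparison(data.frame(slope = 1:3, stock = "a"), "stock"),
               "single level")
})

test_that("trend_table tallies the five categories and closes", {
  set.seed(105)
  series <- c(
    lapply(1:3, function(i)
      simulate_series(25, slope = -3, noise_sd = 1, seed = 200 + i,
                      river_code = paste0("D", i))),
    lapply(1:2, function(i)
      time_series(paste0("F", i), "mean_length", "F", 1991:2000, rep(10, 10))))
  tt <- trend_table(series, normalize_run_size = FALSE)
  expect_equal(nrow(tt$per_series), 5L)
  expect_equal(sum(tt$counts), 5L)
  expect_equal(unname(tt$counts["significant decline"]), 3L)
  expect_equal(unname(tt$counts["no change"]), 2L)
  empty <- trend_table(list())
  expect_equal(sum(empty$counts), 0L)
})
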