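test_that("Cohen's d and its qualitative bands follow the definitions", {
  a <- as.numeric(scale(rnorm(40))) + 1   # mean exactly 1, sd exactly 1
  b <- as.numeric(scale(rnorm(40)))       # mean exactly 0, sd exactly 1
  ct <- independent_comparison(a, b)
  expect_equal(ct$effect_size_d, 1.0, tolerance = 1e-9)
  expect_identical(ct$d_band, "large")
  expect_identical(cohen_band(0.1), "small")
  expect_identical(cohen_band(0.5), "moderate")
  expect_identical(cohen_band(1.43), "very large")
  # identical samples: zero pooled variance is refused
  expect_error(independent_comparison(rep(1, 5), rep(1, 5)), "pooled variance")
  # d = 0 when the two groups coincide distributionally
  ct0 <- independent_comparison(b, as.numeric(scale(rnorm(40))))
  expect_equal(ct0$effect_size_d, 0, tolerance = 1e-9)
  expect_identical(ct0$d_band, "small")
})

test_that("Cohen's d is antisymmetric and affine-invariant", {
  set.seed(31)
  a <- rnorm(25, 1); b <- rnorm(25)
  d1 <- independent_comparison(a, b)$effect_size_d
  d2 <- independent_comparison(b, a)$effect_size_d
  expect_equal(d1, -d2, tolerance = 1e-12)
  d3 <- independent_comparison(3 * a + 7, 3 * b + 7)$effect_size_d
  expect_equal(d3, d1, tolerance = 1e-12)
})

test_that("paired limb test handles identical and degenerate inputs", {
  x <- c(0.5, 0.6, 0.7, 0.8)
  ct <- suppressWarnings(paired_limb_test(x, x))
  expect_equal(ct$statistic, 0)
  expect_equal(ct$p_value, 1)
  expect_warning(res <- paired_limb_test(x + 0.3, x), "degenerate")
  expect_equal(res$p_value, 0)
  expect_error(paired_limb_test(1:3, 1:4), "equal length")
})

test_that("paired test power matches the Monte-Carlo oracle", {
  set.seed(71)
  n <- 30; reps <- 400
  hits <- 0
  for (i in seq_len(reps)) {
    base <- rnorm(n)
    plegic <- base + rnorm(n, 0.5, 1) # within-pair shift of 0.5 SD of the diff...
    p <- paired_limb_test(plegic, base)$p_value
    if (p < 0.05) hits <- hits + 1
  }
  # analytic power for a paired t-test with effect 0.5 at n = 30 is ~0.75
  expect_gt(hits / reps, 0.65)
  expect_lt(hits / reps, 0.85)
})

test_that("assumption checks flag heteroscedasticity and pass under the null", {
  set.seed(41)
  # identical groups: Levene statistic is exactly zero
  dat0 <- data.frame(v = rep(c(1, 2, 3, 4), 2),
                     group = rep(c("a", "b"), each = 4))
  out0 <- check_assumptions(dat0, "v")
  expect_equal(out0$statistic[out0$test == "levene"], 0, tolerance = 1e-12)
  reps <- 100
  null_ok <- 0; alt_hit <- 0
  for (i in seq_len(reps)) {
    dat <- data.frame(v = rnorm(60), group = rep(c("a", "b"), each = 30))
    out <- check_assumptions(dat, "v")
    if (all(out$p_value > 0.05)) null_ok <- null_ok + 1
    dat$v[dat$group == "b"] <- rnorm(30, sd = sqrt(10))
    out2 <- check_assumptions(dat, "v")
    if (out2$p_value[out2$test == "levene"] < 0.05) alt_hit <- alt_hit + 1
  }
  expect_gte(null_ok / reps, 0.80)   # joint non-rejection of 3 tests at alpha 0.05
  expect_gte(alt_hit / reps, 0.90)   # 10x variance at n = 30 is nearly always caught
  expect_error(check_assumptions(
    data.frame(v = rep(1, 6), group = rep(c("a", "b"), 3)), "v"), "Degenerate")
})

test_that("speed-adjusted ANCOVA isolates group, covariate and interaction", {
  set.seed(51)
  n <- 30
  dat <- data.frame(group = rep(c("stroke", "healthy"), each = n),
                    ssws = c(rnorm(n, 0.6, 0.2), rnorm(n, 1.4, 0.2)))
  # outcome depends on speed only, identically in both groups
  dat$y <- 10 + 5 * dat$ssws + rnorm(2 * n, 0, 0.01)
  res <- ancova_adjusted(dat, "y")
  tt <- tidy(res)
  expect_equal(tt$df2, rep(2 * n - 4, 3))
  expect_lt(tt$f[tt$term == "group"], 1)
  expect_lt(tt$f[tt$term == "interaction"], 1)
  expect_gt(tt$f[tt$term == "covariate"], 100)
  expect_lt(tt$p_value[tt$term == "covariate"], 1e-10)
  # parameter recovery from the model's own generative process
  dat$y <- ifelse(dat$group == "stroke", 40 + 10 * dat$ssws,
                  30 + 25 * dat$ssws) + rnorm(2 * n, 0, 0.5)
  mod <- attr(ancova_adjusted(dat, "y"), "model")
  cf <- coef(mod)
  # with sum contrasts the interaction coefficient is half the slope gap
  expect_equal(abs(unname(2 * cf["g1:x"])), 15, tolerance = 1.5)
  # collinear input: covariate constant within a group
  dat$ssws[dat$group == "stroke"] <- 0.6
  expect_error(ancova_adjusted(dat, "y"), "collinear")
  gl <- glance(res)
  expect_true(all(c("r_squared", "sigma", "df_residual") %in% names(gl)))
})

test_that("t-test and interaction type-I error are near nominal (quick check)", {
  set.seed(61)
  reps <- 300; n <- 30
  hit_t <- 0; hit_i <- 0
  for (i in seq_len(reps)) {
    a <- rnorm(n); b <- rnorm(n)
    if (independent_comparison(a, b)$p_value < 0.05) hit_t <- hit_t + 1
    dat <- data.frame(group = rep(c("a", "b"), each = n),
                      ssws = rnorm(2 * n, 1, 0.3), y = rnorm(2 * n))
    tt <- tidy(ancova_adjusted(dat, "y"))
    if (tt$p_value[tt$term == "interaction"] < 0.05) hit_i <- hit_i + 1
  }
  expect_gt(hit_t / reps, 0.02); expect_lt(hit_t / reps, 0.09)
  expect_gt(hit_i / reps, 0.02); expect_lt(hit_i / reps, 0.09)
})

test_that("a speed-by-group slope difference of realistic size is detected", {
  set.seed(81)
  reps <- 200; n <- 30
  hits <- 0
  for (i in seq_len(reps)) {
    dat <- data.frame(group = rep(c("stroke", "healthy"), each = n),
                      ssws = c(rnorm(n, 0.6, 0.23), rnorm(n, 1.4, 0.23)))
    slope <- ifelse(dat$group == "stroke", 10, 40)  # 30 %/(m/s) gap
    dat$y <- 40 + slope * dat$ssws + rnorm(2 * n, 0, 7.5)
    tt <- tidy(ancova_adjusted(dat, "y"))
    if (tt$p_value[tt$term == "interaction"] < 0.05) hits <- hits + 1
  }
  expect_gte(hits / reps, 0.80)
})

test_that("Pearson correlations are exact on linear data and unbiased", {
  dat <- data.frame(x = 1:10, y = 2 * (1:10) + 1, z = -(1:10))
  expect_equal(correlate_pair(dat, "x", "y")$r, 1, tolerance = 1e-12)
  expect_equal(correlate_pair(dat, "x", "z")$r, -1, tolerance = 1e-12)
  expect_error(correlate_pair(data.frame(x = rep(1, 5), y = 1:5), "x", "y"),
               "variance")
  set.seed(91)
  rho <- -0.70; n <- 30; reps <- 2000
  rs <- vapply(seq_len(reps), function(i) {
    x <- rnorm(n); y <- rho * x + sqrt(1 - rho^2) * rnorm(n)
    cor(x, y)
  }, numeric(1))
  expect_lt(abs(mean(rs) - rho), 0.05)
})
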