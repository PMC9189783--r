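test_that("two-level factorial is the full +/-1 cube in Yates order", {
  d <- two_level_factorial(toy_factors(2L))
  expect_equal(unname(d$coded),
               rbind(c(-1, -1), c(1, -1), c(-1, 1), c(1, 1)))
  d5 <- two_level_factorial(toy_factors(5L))
  expect_equal(nrow(d5$coded), 32L)
  expect_equal(colSums(d5$coded), rep(0, 5), ignore_attr = TRUE)
  # pairwise orthogonality of the coded columns
  ip <- crossprod(d5$coded)
  expect_equal(unname(ip - diag(diag(ip))), matrix(0, 5, 5))
  fs13 <- factor_set(paste0("f", 1:13), rep(0, 13), rep(1, 13))
  expect_error(two_level_factorial(fs13), "k > 12")
})

test_that("ccrd reproduces the bundled design census and axial levels", {
  fs <- protease_factors()
  d <- ccrd(fs, n_center = 8, alpha = 2)
  expect_equal(as.vector(table(d$point_class)), c(32L, 10L, 8L))
  expect_equal(nrow(d$coded), 50L)
  # axial high of the first factor on the actual scale: 46.9 + 2 * 1.2
  expect_equal(max(d$actual[, "cpe"]), 49.3)
  expect_equal(min(d$actual[, "mg"]), 0.05)
  # columnwise balance of the whole coded matrix
  expect_equal(colSums(d$coded), rep(0, 5), ignore_attr = TRUE)
  # rotatable alpha for a full 2^5 factorial portion
  dr <- ccrd(fs, n_center = 6, alpha = "rotatable")
  expect_equal(attr(dr, "alpha"), 32^0.25)
})

test_that("the bundled 50-run table classifies as 32 factorial + 10 axial + 8 center", {
  d <- study_design()
  expect_equal(as.vector(table(d$point_class)), c(32L, 10L, 8L))
  grp <- replicate_groups(d)
  expect_equal(length(unique(grp)), 43L) # distinct design points
  expect_equal(max(table(grp)), 8L)      # the replicated center
})

test_that("coding and decoding are exact inverses", {
  fs <- protease_factors()
  expect_equal(drop(code_levels(c(46.9, 23.9, 6.13, 0.27, 0.031), fs)),
               rep(0, 5), ignore_attr = TRUE)
  expect_equal(drop(code_levels(c(48.1, 23.9, 6.13, 0.27, 0.031), fs))[1], 1,
               ignore_attr = TRUE)
  expect_equal(drop(code_levels(c(46.9, 23.9, 6.13, 0.05, 0.031), fs))[4], -2,
               ignore_attr = TRUE)
  set.seed(42)
  for (i in 1:20) {
    x <- matrix(runif(10, -3, 3), 2, 5)
    expect_equal(code_levels(decode_levels(x, fs), fs), x,
                 ignore_attr = TRUE, tolerance = 1e-12)
    a <- decode_levels(x, fs)
    expect_equal(decode_levels(code_levels(a, fs), fs), a,
                 ignore_attr = TRUE, tolerance = 1e-12)
  }
})

test_that("first-order fit recovers exact coefficients and contrast oracle", {
  fs <- toy_factors(2L)
  d <- two_level_factorial(fs)
  y <- 3 + 2 * d$coded[, 1] - d$coded[, 2]
  fit <- fit_first_order(d, y)
  expect_equal(unname(fit$b), c(2, -1))
  expect_equal(fit$b0, 3)
  # orthogonal-design contrast oracle: b_i = sum(z_i * y) / n
  d5 <- two_level_factorial(toy_factors(5L))
  set.seed(7)
  y5 <- rnorm(32)
  fit5 <- fit_first_order(d5, y5)
  expect_equal(unname(fit5$b), as.vector(crossprod(d5$coded, y5) / 32),
               tolerance = 1e-10)
  # constant response: zero slopes, intercept = mean
  fitc <- fit_first_order(d5, rep(4.2, 32))
  expect_equal(unname(fitc$b), rep(0, 5))
  expect_equal(fitc$b0, 4.2)
})

test_that("steepest ascent steps are proportional to coefficients and climb", {
  fs <- toy_factors(2L)
  d <- two_level_factorial(fs)
  # replicate the cube so coefficient t-tests have residual df
  coded <- rbind(d$coded, d$coded, d$coded)
  set.seed(1)
  y <- 5 + 2 * coded[, 1] + 1 * coded[, 2] + rnorm(nrow(coded), sd = 0.05)
  fit <- fit_first_order(coded, y)
  expect_true(all(fit$significant))
  path <- steepest_ascent_path(fit, fs, base = fs$center, step_size = 1,
                               n_steps = 4)
  delta <- attr(path, "coded_delta")
  expect_equal(delta[1, ] / delta[1, 1], c(1, fit$b[2] / fit$b[1]),
               ignore_attr = TRUE, tolerance = 1e-12)
  # direction parallel to the fitted gradient (cosine similarity 1)
  g <- fit$b / sqrt(sum(fit$b^2))
  step1 <- delta[1, ] / sqrt(sum(delta[1, ]^2))
  expect_equal(sum(g * step1), 1, tolerance = 1e-10)
  # a negative coefficient walks that factor downhill
  y2 <- 5 - 2 * coded[, 1] + 1 * coded[, 2] + rnorm(nrow(coded), sd = 0.05)
  fit2 <- fit_first_order(coded, y2)
  path2 <- steepest_ascent_path(fit2, fs, base = fs$center)
  expect_true(all(diff(path2$f1) < 0))
  # on a plane with a quadratic cap the best step beats the base point
  true_resp <- function(z) 5 + 2 * z[, 1] + z[, 2] - 0.4 * rowSums(z^2)
  pathc <- steepest_ascent_path(fit, fs, base = fs$center, step_size = 0.5,
                                n_steps = 10)
  vals <- true_resp(code_levels(as.matrix(pathc[, c("f1", "f2")]), fs))
  expect_gt(max(vals), true_resp(matrix(0, 1, 2)))
  expect_lt(vals[10], max(vals)) # rises then falls along the path
})

test_that("degenerate screening inputs are refused", {
  fs <- toy_factors(2L)
  d <- two_level_factorial(fs)
  y <- rep(1, 4)
  fit <- fit_first_order(d, y)
  expect_error(steepest_ascent_path(fit, fs, base = fs$center),
               "zero|significant")
  expect_error(factor_set("a", 0, 1), "at least 2")
  expect_error(factor_set(c("a", "b"), c(0, 1), c(1, 1)), "exceed")
})
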