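test_that("noiseless quadratic surfaces are recovered exactly", {
  fs <- protease_factors()
  d <- ccrd(fs, n_center = 8, alpha = 2)
  set.seed(11)
  beta <- rnorm(21, sd = 3)
  y <- predict(surface_from_coefficients(beta, 5), d$coded)
  fit <- fit_quadratic(d, y)
  expect_equal(unname(fit$coefficients), beta, tolerance = 1e-8)
  expect_equal(fit$r2, 1, tolerance = 1e-12)
})

test_that("refit of the bundled activity data matches the published surface", {
  d <- study_design()
  y <- study_runs()$activity_exp
  fit <- fit_quadratic(d, y)
  expect_equal(length(fit$coefficients), 21L)
  expect_gt(fit$r2, 0.97)
  # interaction terms of the refit equal the published ones exactly:
  # rounding of the response cannot touch them on this orthogonal design
  pub <- protease_surface()$coefficients
  inter <- grep(":", names(pub), value = TRUE)
  expect_equal(fit$coefficients[inter], pub[inter], tolerance = 5e-3)
  # the refit intercept sits within 1% of the published constant term
  expect_rel(fit$coefficients[1], pub[1], 0.01)
  # the published surface itself evaluates to its constant at the origin
  expect_equal(unname(predict(protease_surface(), rep(0, 5))), 312416)
})

test_that("r2 is invariant under the coded/actual affine reparameterization", {
  runs <- study_runs()
  y <- runs$activity_exp
  coded <- study_design()$coded
  actual <- as.matrix(runs[, c("cpe", "csl", "casein", "mg", "mn")])
  colnames(actual) <- colnames(coded)
  r2_coded <- fit_quadratic(coded, y)$r2
  r2_actual <- fit_quadratic(actual, y)$r2
  expect_equal(r2_coded, r2_actual, tolerance = 1e-9)
})

test_that("prediction reproduces fitted values with basis-orthogonal residuals", {
  d <- study_design()
  y <- study_runs()$activity_exp
  fit <- fit_quadratic(d, y)
  expect_equal(predict(fit, d$coded), fit$fitted, tolerance = 1e-9)
  X <- fermopt:::quadratic_basis(d$coded)
  expect_equal(max(abs(crossprod(X, fit$residuals))) / sum(abs(y)), 0,
               tolerance = 1e-10)
})

test_that("anova decomposition is additive with replicate-based dfs", {
  d <- study_design()
  y <- study_runs()$activity_exp
  fit <- fit_quadratic(d, y)
  an <- surface_anova(fit)
  get <- function(src, col) an[an$source == src, col]
  expect_equal(get("Model", "ss") + get("Residual", "ss"), get("Total", "ss"),
               tolerance = 1e-6 * get("Total", "ss"))
  expect_equal(get("Lack of fit", "ss") + get("Pure error", "ss"),
               get("Residual", "ss"),
               tolerance = 1e-6 * get("Residual", "ss"))
  # 50 runs, 21 terms, 43 distinct points, 8 replicated center runs
  expect_equal(get("Residual", "df"), 29)
  expect_equal(get("Pure error", "df"), 7)
  expect_equal(get("Lack of fit", "df"), 22)
  expect_lt(get("Model", "p"), 1e-4)
})

test_that("pure error vanishes when replicates agree and LOF needs replicates", {
  fs <- protease_factors()
  d <- ccrd(fs, n_center = 8, alpha = 2)
  y <- predict(protease_surface(), d$coded) # replicates identical
  y <- y + seq_along(y) * 0 # keep numeric
  # perturb non-center rows only so SSE > 0 but pure error stays 0
  idx <- d$point_class != "center"
  y[idx] <- y[idx] + rep_len(c(-1, 1), sum(idx)) * 50
  an <- surface_anova(fit_quadratic(d, y))
  expect_equal(an[an$source == "Pure error", "ss"], 0)
  # a design with no replicated rows reports LOF as unavailable
  d1 <- ccrd(fs, n_center = 1, alpha = 2)
  set.seed(2)
  y1 <- predict(protease_surface(), d1$coded) + rnorm(nrow(d1$coded), sd = 100)
  an1 <- surface_anova(fit_quadratic(d1, y1))
  expect_true(is.na(an1[an1$source == "Lack of fit", "ss"]))
})

test_that("parameter error shrinks linearly with the noise level", {
  fs <- protease_factors()
  d <- ccrd(fs, n_center = 8, alpha = 2)
  truth <- protease_surface()
  err_at <- function(sd) {
    e <- vapply(1:5, function(s) {
      sim <- simulate_doe(surface_truth(truth, sd), d, seed = s)
      max(abs(fit_quadratic(d, sim$response)$coefficients -
                truth$coefficients))
    }, numeric(1))
    mean(e)
  }
  e1 <- err_at(100); e2 <- err_at(1000)
  expect_gt(e2 / e1, 5)   # roughly linear in sigma
  expect_lt(e2 / e1, 20)
})

test_that("insufficient or singular designs are refused", {
  d <- two_level_factorial(toy_factors(2L))
  expect_error(fit_quadratic(d, rnorm(4)), "more runs")
  # 25 runs of a 5-factor cube fragment cannot estimate 21 terms + pure quads
  coded <- two_level_factorial(toy_factors(5L))$coded[1:25, ]
  expect_error(fit_quadratic(coded, rnorm(25)), "singular|more runs")
})
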