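test_that("range normalization maps the endpoints and midpoint correctly", {
  expect_equal(normalize_range(c(2, 5, 8), 2, 8), c(-1, 0, 1))
  x <- runif(20, -3, 7)
  expect_equal(denormalize_range(normalize_range(x, -3, 7), -3, 7), x)
  expect_error(normalize_range(1, 2, 2), "exceed")
})

test_that("data splits have the conventional sizes and are seed-stable", {
  s <- split_data(50, seed = 1)
  expect_equal(lengths(s), c(train = 34L, val = 8L, test = 8L))
  expect_equal(sort(unlist(s)), 1:50, ignore_attr = TRUE)
  expect_identical(split_data(50, seed = 1), s)
  expect_false(identical(split_data(50, seed = 2), s))
  # splitting leaves the global RNG stream untouched
  set.seed(99); before <- runif(1)
  set.seed(99); invisible(split_data(50, seed = 5)); after <- runif(1)
  expect_identical(before, after)
})

test_that("forward pass obeys the network algebra", {
  spec <- ann_spec(n_inputs = 3, n_hidden = 4, seed = 1)
  w0 <- rep(0, fermopt:::n_weights(spec))
  w0[length(w0)] <- 1.7 # output bias only
  X <- matrix(runif(15, -1, 1), 5, 3)
  expect_equal(ann_forward(list(weights = w0, spec = spec), X), rep(1.7, 5))
  # saturation: huge input weights drive hidden units to +/-1
  wsat <- c(rep(50, 12), rep(0, 4), rep(1, 4), 0)
  out <- ann_forward(list(weights = wsat, spec = spec),
                     matrix(c(1, 1, 1, -1, -1, -1), 2, 3, byrow = TRUE))
  expect_equal(out, c(4, -4), tolerance = 1e-10)
  expect_error(ann_forward(list(weights = w0, spec = spec),
                           matrix(0, 2, 5)), "expects")
})

test_that("analytic Jacobian agrees with central finite differences", {
  spec <- ann_spec(n_inputs = 4, n_hidden = 5, seed = 3)
  w <- fermopt:::init_weights(spec)
  set.seed(3)
  X <- matrix(runif(28, -1, 1), 7, 4)
  J <- ann_jacobian(w, X, spec)
  h <- 1e-6
  fd <- vapply(seq_along(w), function(i) {
    wp <- w; wm <- w
    wp[i] <- wp[i] + h; wm[i] <- wm[i] - h
    (ann_forward(list(weights = wp, spec = spec), X) -
       ann_forward(list(weights = wm, spec = spec), X)) / (2 * h)
  }, numeric(nrow(X)))
  expect_equal(J, fd, tolerance = 1e-6, ignore_attr = TRUE)
  # and for the logistic activation
  spec2 <- ann_spec(n_inputs = 4, n_hidden = 5, activation = "logistic",
                    seed = 3)
  J2 <- ann_jacobian(w, X, spec2)
  fd2 <- vapply(seq_along(w), function(i) {
    wp <- w; wm <- w
    wp[i] <- wp[i] + h; wm[i] <- wm[i] - h
    (ann_forward(list(weights = wp, spec = spec2), X) -
       ann_forward(list(weights = wm, spec = spec2), X)) / (2 * h)
  }, numeric(nrow(X)))
  expect_equal(J2, fd2, tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("LM training interpolates an easy noiseless linear target", {
  set.seed(5)
  X <- matrix(runif(80, -1, 1), 40, 2)
  y <- 0.3 * X[, 1] - 0.2 * X[, 2]
  fit <- train_ann(X, y, ann_spec(n_inputs = 2, n_hidden = 3, seed = 1,
                                  max_epochs = 200))
  yn <- normalize_range(y, min(y), max(y))
  Xn <- cbind(normalize_range(X[, 1], min(X[, 1]), max(X[, 1])),
              normalize_range(X[, 2], min(X[, 2]), max(X[, 2])))
  pred_n <- ann_forward(fit, Xn[fit$split$train, ])
  expect_lt(mean((yn[fit$split$train] - pred_n)^2), 1e-6)
})

test_that("training is bit-reproducible and early stopping honors best validation", {
  runs <- study_runs()
  X <- as.matrix(runs[, c("cpe", "csl", "casein", "mg", "mn")])
  y <- runs$activity_exp
  spec <- ann_spec(seed = 4)
  f1 <- train_ann(X, y, spec)
  f2 <- train_ann(X, y, spec)
  expect_identical(f1$weights, f2$weights)
  expect_identical(f1$trace, f2$trace)
  # returned weights achieve the minimum validation mse seen in the trace
  va <- f1$split$val
  yn <- normalize_range(y, f1$y_min, f1$y_max)
  Xn <- vapply(1:5, function(j) normalize_range(X[, j], f1$x_min[j],
                                                f1$x_max[j]),
               numeric(nrow(X)))
  val_mse <- mean((yn[va] - ann_forward(f1, Xn[va, ]))^2)
  expect_equal(val_mse, min(f1$trace$val_mse), tolerance = 1e-12)
})

test_that("a 12-unit network can overfit 34 noisy training points", {
  runs <- study_runs()
  X <- as.matrix(runs[, c("cpe", "csl", "casein", "mg", "mn")])
  y <- runs$activity_exp
  # disable early stopping to expose the overfit, motivating the stop rule
  fit <- train_ann(X, y, ann_spec(seed = 1, max_val_fail = 10000L,
                                  max_epochs = 200))
  last <- fit$trace[nrow(fit$trace), ]
  expect_lt(last$train_mse, min(fit$trace$val_mse))
})

test_that("LM converges superlinearly on a quadratic bowl", {
  # one linear output neuron with fixed inputs is a linear least-squares
  # problem: LM with shrinking mu reduces to Gauss-Newton and lands in
  # one or two accepted steps
  set.seed(8)
  X <- matrix(runif(40, -1, 1), 20, 2)
  y <- 0.4 * X[, 1] + 0.1 * X[, 2] + 0.05
  fit <- train_ann(X, y, ann_spec(n_inputs = 2, n_hidden = 2, seed = 2,
                                  max_epochs = 50))
  expect_lt(min(fit$trace$train_mse), 1e-6)
  # training mse is monotonically non-increasing (accepted steps only)
  expect_true(all(diff(fit$trace$train_mse) <= 1e-15))
})
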