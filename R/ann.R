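with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Min-max normalization to [-1, 1] and its inverse
#'
#' `normalize_range()` applies the affine map
#' \eqn{y = (2x - (x_{max}+x_{min})) / (x_{max}-x_{min})}, sending
#' `xmin` to -1, `xmax` to +1 and their midpoint to 0.
#' `denormalize_range()` inverts it.
#'
#' @param x,y numeric vectors.
#' @param xmin,xmax the reference range; `xmax` must exceed `xmin`.
#' @return Numeric vector of the same length.
#' @examples
#' normalize_range(c(0, 5, 10), 0, 10)  # -1, 0, 1
#' @export
normalize_range <- function(x, xmin, xmax) {
  if (!is.finite(xmin) || !is.finite(xmax) || xmax <= xmin)
    stop("'xmax' must exceed 'xmin'")
  (2 * x - (xmax + xmin)) / (xmax - xmin)
}

#' @rdname normalize_range
#' @export
denormalize_range <- function(y, xmin, xmax) {
  if (!is.finite(xmin) || !is.finite(xmax) || xmax <= xmin)
    stop("'xmax' must exceed 'xmin'")
  (y * (xmax - xmin) + (xmax + xmin)) / 2
}

#' Random train/validation/test split
#'
#' Randomly partitions `1:n` into train/validation/test index sets. The
#' validation and test sizes are `round(f * n)` and the training set takes
#' the remainder, so the conventional 0.70/0.15/0.15 split of 50 runs
#' gives 34/8/8. Deterministic for a given seed.
#'
#' @param n number of samples (>= 3).
#' @param fractions length-3 numeric summing to 1.
#' @param seed integer RNG seed.
#' @return A list with integer vectors `train`, `val` and `test`.
#' @examples
#' lengths(split_data(50, seed = 1))  # 34, 8, 8
#' @export
split_data <- function(n, fractions = c(0.70, 0.15, 0.15), seed = 1L) {
  if (n < 3L) stop("need at least 3 samples to split")
  if (length(fractions) != 3L || abs(sum(fractions) - 1) > 1e-8)
    stop("'fractions' must be three numbers summing to 1")
  n_val <- round(fractions[2L] * n)
  n_test <- round(fractions[3L] * n)
  perm <- with_seed(seed, sample.int(n))
  list(
    train = sort(perm[seq_len(n - n_val - n_test)]),
    val = sort(perm[n - n_val - n_test + seq_len(n_val)]),
    test = sort(perm[n - n_test + seq_len(n_test)])
  )
}

#' Specification of a two-layer feed-forward network
#'
#' A single hidden layer of sigmoidal units and a linear output unit,
#' trained by damped (Levenberg-Marquardt) least squares on data
#' normalized to [-1, 1]. "Sigmoidal" defaults to `tanh`; the logistic
#' unit is available via `activation = "logistic"`.
#'
#' @param n_inputs number of input variables.
#' @param n_hidden hidden-layer width (default 12).
#' @param activation hidden activation, `"tanh"` or `"logistic"`.
#' @param fractions train/validation/test split fractions.
#' @param max_epochs maximum LM iterations.
#' @param mu0,mu_up,mu_down initial damping and its multiplicative
#'   adjustment on failure / success.
#' @param mu_max damping ceiling; training stops when exceeded.
#' @param max_val_fail consecutive validation-error increases tolerated
#'   before early stopping.
#' @param seed integer seed controlling the split and weight init.
#' @return A list of class `ann_spec`.
#' @export
ann_spec <- function(n_inputs = 5L, n_hidden = 12L,
                     activation = c("tanh", "logistic"),
                     fractions = c(0.70, 0.15, 0.15),
                     max_epochs = 1000L, mu0 = 1e-3, mu_up = 10,
                     mu_down = 0.1, mu_max = 1e10,
                     max_val_fail = 6L, seed = 1L) {
  activation <- match.arg(activation)
  if (n_hidden < 1L) stop("'n_hidden' must be at least 1")
  if (length(fractions) != 3L || abs(sum(fractions) - 1) > 1e-8)
    stop("'fractions' must sum to 1")
  structure(list(n_inputs = as.integer(n_inputs),
                 n_hidden = as.integer(n_hidden),
                 activation = activation, fractions = fractions,
                 max_epochs = as.integer(max_epochs), mu0 = mu0,
                 mu_up = mu_up, mu_down = mu_down, mu_max = mu_max,
                 max_val_fail = as.integer(max_val_fail),
                 seed = as.integer(seed)),
            class = "ann_spec")
}

act_fun <- function(z, activation) {
  if (activation == "tanh") tanh(z) else stats::plogis(z)
}

act_grad <- function(a, activation) {
  if (activation == "tanh") 1 - a^2 else a * (1 - a)
}

n_weights <- function(spec) {
  spec$n_hidden * spec$n_inputs + spec$n_hidden + spec$n_hidden + 1L
}

unpack_weights <- function(w, spec) {
  H <- spec$n_hidden; k <- spec$n_inputs
  i <- 0L
  W1 <- matrix(w[i + seq_len(H * k)], H, k); i <- i + H * k
  b1 <- w[i + seq_len(H)]; i <- i + H
  W2 <- w[i + seq_len(H)]; i <- i + H
  b2 <- w[i + 1L]
  list(W1 = W1, b1 = b1, W2 = W2, b2 = b2)
}

init_weights <- function(spec) {
  H <- spec$n_hidden; k <- spec$n_inputs
  with_seed(spec$seed, {
    c(stats::runif(H * k, -0.5, 0.5) / sqrt(k),
      stats::runif(H, -0.5, 0.5) / sqrt(k),
      stats::runif(H, -0.5, 0.5) / sqrt(H),
      stats::runif(1L, -0.5, 0.5) / sqrt(H))
  })
}

#' Forward pass of a feed-forward network
#'
#' Evaluates `W2 . act(W1 x + b1) + b2` for each row of `X`. Inputs are
#' expected on the normalized [-1, 1] scale.
#'
#' @param fit an `ann_fit` (or a list with `weights` and `spec`).
#' @param X numeric matrix with one column per input.
#' @return Numeric vector of network outputs (normalized scale).
#' @export
ann_forward <- function(fit, X) {
  spec <- fit$spec
  if (is.null(dim(X))) X <- matrix(X, nrow = 1L)
  if (ncol(X) != spec$n_inputs)
    stop("input has ", ncol(X), " columns; network expects ", spec$n_inputs)
  wl <- unpack_weights(fit$weights, spec)
  A <- act_fun(X %*% t(wl$W1) + rep(wl$b1, each = nrow(X)), spec$activation)
  drop(A %*% wl$W2 + wl$b2)
}

#' Jacobian of network output with respect to the weights
#'
#' Analytic derivative matrix (one row per sample, one column per weight,
#' in packing order W1, b1, W2, b2). This is the `J` of the damped
#' Gauss-Newton update `(J'J + mu I) delta = J' e`.
#'
#' @param weights packed weight vector.
#' @param X input matrix (normalized scale).
#' @param spec the `ann_spec`.
#' @return Numeric matrix `nrow(X)` by `length(weights)`.
#' @export
ann_jacobian <- function(weights, X, spec) {
  wl <- unpack_weights(weights, spec)
  n <- nrow(X); H <- spec$n_hidden; k <- spec$n_inputs
  A <- act_fun(X %*% t(wl$W1) + rep(wl$b1, each = n), spec$activation)
  G <- act_grad(A, spec$activation) # n x H
  GW <- sweep(G, 2L, wl$W2, "*")    # d out / d (pre-activation_h)
  J_W1 <- matrix(0, n, H * k)
  for (j in seq_len(k))
    J_W1[, (j - 1L) * H + seq_len(H)] <- GW * X[, j]
  cbind(J_W1, GW, A, 1)
}

# keep column order of ann_jacobian consistent with unpack_weights:
# W1 is stored column-major (H x k), i.e. blocks of H per input column.

#' Train a feed-forward network by Levenberg-Marquardt
#'
#' Normalizes inputs and target to [-1, 1] (min-max over the supplied
#' data), splits the samples into train/validation/test sets, and
#' minimizes the training SSE by damped Gauss-Newton steps
#' `(J'J + mu I) delta = J' e`. The damping `mu` shrinks by `mu_down`
#' after every accepted step and grows by `mu_up` until a step improves
#' the SSE; training stops at `max_epochs`, when `mu` exceeds `mu_max`,
#' or after `max_val_fail` consecutive epochs without a new best
#' validation error. The returned weights are those of the best
#' validation epoch.
#'
#' @param X numeric matrix of inputs (original scale), one row per sample.
#' @param y numeric response (original scale).
#' @param spec an [ann_spec()].
#' @return An object of class `ann_fit`: packed `weights`, the `spec`,
#'   normalization ranges, `split` indices, a per-epoch `trace`
#'   (epoch, mu, train/validation MSE on the normalized scale) and
#'   per-set `performance` (MSE and r2 on the original scale).
#' @examples
#' X <- matrix(runif(60, -1, 1), 30, 2)
#' y <- 0.3 * X[, 1] - 0.2 * X[, 2]
#' fit <- train_ann(X, y, ann_spec(n_inputs = 2, n_hidden = 3, seed = 1))
#' fit$performance["train", "mse"]
#' @export
train_ann <- function(X, y, spec = ann_spec()) {
  stopifnot(inherits(spec, "ann_spec"))
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X)
  if (ncol(X) != spec$n_inputs)
    stop("X has ", ncol(X), " columns; spec expects ", spec$n_inputs)
  if (length(y) != n) stop("length(y) must equal nrow(X)")
  x_min <- apply(X, 2L, min); x_max <- apply(X, 2L, max)
  y_min <- min(y); y_max <- max(y)
  Xn <- mapply(function(j, lo, hi) normalize_range(X[, j], lo, hi),
               seq_len(ncol(X)), x_min, x_max)
  Xn <- matrix(Xn, nrow = n)
  yn <- normalize_range(y, y_min, y_max)
  split <- split_data(n, spec$fractions, spec$seed)
  tr <- split$train; va <- split$val
  w <- init_weights(spec)
  mu <- spec$mu0
  fit_tmp <- list(weights = w, spec = spec)
  sse <- function(w, idx) {
    fit_tmp$weights <- w
    sum((yn[idx] - ann_forward(fit_tmp, Xn[idx, , drop = FALSE]))^2)
  }
  train_sse <- sse(w, tr)
  val_mse_of <- function(w) if (length(va)) sse(w, va) / length(va) else NA_real_
  best_val <- val_mse_of(w)
  best_w <- w
  val_fail <- 0L
  trace <- vector("list", spec$max_epochs)
  stopped <- "max_epochs"
  P <- n_weights(spec)
  for (epoch in seq_len(spec$max_epochs)) {
    fit_tmp$weights <- w
    e <- yn[tr] - ann_forward(fit_tmp, Xn[tr, , drop = FALSE])
    J <- ann_jacobian(w, Xn[tr, , drop = FALSE], spec)
    JtJ <- crossprod(J)
    Jte <- crossprod(J, e)
    repeat {
      delta <- tryCatch(
        solve(JtJ + mu * diag(P), Jte),
        error = function(err) NULL
      )
      new_sse <- if (is.null(delta)) Inf else sse(w + drop(delta), tr)
      if (!is.finite(new_sse) && !is.null(delta))
        stop("non-finite training loss at epoch ", epoch,
             " (mu = ", mu, ", train SSE = ", train_sse, ")")
      if (new_sse < train_sse) {
        w <- w + drop(delta)
        train_sse <- new_sse
        mu <- mu * spec$mu_down
        break
      }
      mu <- mu * spec$mu_up
      if (mu > spec$mu_max) break
    }
    val_mse <- val_mse_of(w)
    trace[[epoch]] <- c(epoch = epoch, mu = mu,
                        train_mse = train_sse / length(tr),
                        val_mse = val_mse)
    if (!is.na(val_mse)) {
      if (val_mse < best_val) {
        best_val <- val_mse
        best_w <- w
        val_fail <- 0L
      } else {
        val_fail <- val_fail + 1L
        if (val_fail >= spec$max_val_fail) { stopped <- "validation"; break }
      }
    } else if (train_sse / length(tr) < 1e-16) {
      best_w <- w; stopped <- "train_mse"; break
    }
    if (mu > spec$mu_max) { stopped <- "mu_overflow"; break }
  }
  if (is.na(best_val)) best_w <- w
  fit <- structure(
    list(weights = best_w, spec = spec,
         x_min = x_min, x_max = x_max, y_min = y_min, y_max = y_max,
         split = split, stopped = stopped,
         trace = as.data.frame(do.call(rbind, trace[!vapply(trace, is.null, TRUE)]))),
    class = "ann_fit"
  )
  pred <- predict(fit, X)
  perf <- t(vapply(split, function(idx) {
    if (!length(idx)) return(c(mse = NA_real_, r2 = NA_real_))
    m <- mean((y[idx] - pred[idx])^2)
    c(mse = m, r2 = 1 - sum((y[idx] - pred[idx])^2) /
        sum((y[idx] - mean(y[idx]))^2))
  }, numeric(2)))
  overall <- c(mse = mean((y - pred)^2),
               r2 = 1 - sum((y - pred)^2) / sum((y - mean(y))^2))
  fit$performance <- rbind(perf, overall = overall)
  fit
}

#' @export
predict.ann_fit <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  if (is.null(dim(newdata)) && length(newdata) == object$spec$n_inputs)
    X <- matrix(newdata, nrow = 1L)
  Xn <- vapply(seq_len(ncol(X)),
               function(j) normalize_range(X[, j], object$x_min[j],
                                           object$x_max[j]),
               numeric(nrow(X)))
  Xn <- matrix(Xn, nrow = nrow(X))
  denormalize_range(ann_forward(object, Xn), object$y_min, object$y_max)
}

#' @export
print.ann_fit <- function(x, ...) {
  cat("Feed-forward network", x$spec$n_inputs, "-", x$spec$n_hidden,
      "- 1 (", x$spec$activation, "), trained", nrow(x$trace),
      "epochs, stop:", x$stopped, "\n")
  print(round(x$performance, 6))
  invisible(x)
}
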