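#' Train the base multilayer perceptron classifier
#'
#' Fits a single-hidden-layer network (tanh hidden units, logistic output)
#' to a fully imputed standardized table by full-batch Adam gradient
#' descent on the binomial log-loss with an L2 weight penalty, stopping
#' early on held-out log-loss. When `hidden` is a vector, each width is
#' trained and the one with the lowest validation log-loss is kept. The
#' fitted network is the black box `g(x) = logit P(outcome | x)` that the
#' anchored ANOVA decomposition later takes apart.
#'
#' @param data A standardized, fully imputed tibble (see [standardize()],
#'   [impute_zero()]).
#' @param outcome Name of the 0/1 outcome column.
#' @param hidden Candidate hidden-layer widths; default `c(4, 8, 16)`.
#' @param l2 L2 penalty on the weights (not biases); default `1e-3`.
#' @param seed Integer seed controlling initialization and the validation
#'   split; training is reproducible per seed.
#' @param validation_fraction Fraction of rows held out for early stopping.
#' @param max_epochs,patience Early-stopping schedule: training stops when
#'   the validation log-loss has not improved for `patience` epochs, or at
#'   `max_epochs`.
#' @param learning_rate Adam step size.
#' @return An object of class `prn_mlp` (weights, architecture, training
#'   history).
#' @export
fit_mlp <- function(data, outcome = attr(data, "outcome") %||% "outcome",
                    hidden = c(4, 8, 16), l2 = 1e-3, seed = 1,
                    validation_fraction = 0.2, max_epochs = 500,
                    patience = 20, learning_rate = 0.05) {
  cols <- predictor_cols(data, outcome)
  X <- as_numeric_matrix(data, cols)
  if (anyNA(X)) abort("Predictors contain missing values; impute first.")
  y <- data[[outcome]]
  check_binary(y, outcome)
  if (length(unique(y)) < 2L) abort("Both outcome classes must be present.")

  withr::local_seed(as.integer(seed))
  n <- nrow(X)
  n_val <- max(1L, round(validation_fraction * n))
  val <- sample.int(n, n_val)
  tr <- setdiff(seq_len(n), val)

  fits <- lapply(hidden, function(h) {
    mlp_train_adam(X[tr, , drop = FALSE], y[tr], X[val, , drop = FALSE], y[val],
                   h, l2, max_epochs, patience, learning_rate)
  })
  best <- which.min(vapply(fits, function(f) f$val_loss, 0))
  fit <- fits[[best]]
  structure(list(W1 = fit$W1, b1 = fit$b1, w2 = fit$w2, b2 = fit$b2,
                 hidden = hidden[best], columns = cols, seed = seed,
                 l2 = l2, history = fit$history,
                 widths_tried = tibble(hidden = hidden,
                                       val_loss = vapply(fits, function(f) f$val_loss, 0))),
            class = "prn_mlp")
}

mlp_forward <- function(W1, b1, w2, b2, X) {
  A <- tanh(sweep(X %*% W1, 2, b1, "+"))
  drop(A %*% w2) + b2
}

log_loss <- function(eta, y) {
  # numerically stable binomial log-loss from the linear predictor
  mean(ifelse(eta > 0, log1p(exp(-eta)) + (1 - y) * eta,
              log1p(exp(eta)) - y * eta))
}

mlp_train_adam <- function(Xtr, ytr, Xval, yval, h, l2, max_epochs, patience, lr) {
  d <- ncol(Xtr); ntr <- nrow(Xtr)
  W1 <- matrix(stats::rnorm(d * h, 0, 0.5 / sqrt(d)), d, h)
  b1 <- rep(0, h)
  w2 <- stats::rnorm(h, 0, 0.5 / sqrt(h))
  b2 <- logit(pmin(pmax(mean(ytr), 1e-6), 1 - 1e-6))
  params <- list(W1 = W1, b1 = b1, w2 = w2, b2 = b2)
  m <- lapply(params, function(p) p * 0)
  v <- lapply(params, function(p) p * 0)
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  best <- list(loss = Inf, params = params, epoch = 0L)
  history <- numeric(0)
  wait <- 0L
  for (epoch in seq_len(max_epochs)) {
    A <- tanh(sweep(Xtr %*% params$W1, 2, params$b1, "+"))
    eta <- drop(A %*% params$w2) + params$b2
    r <- (sigmoid(eta) - ytr) / ntr
    g_w2 <- drop(crossprod(A, r)) + 2 * l2 * params$w2
    g_b2 <- sum(r)
    dz <- (r %o% params$w2) * (1 - A^2)
    g_W1 <- crossprod(Xtr, dz) + 2 * l2 * params$W1
    g_b1 <- colSums(dz)
    grads <- list(W1 = g_W1, b1 = g_b1, w2 = g_w2, b2 = g_b2)
    for (nm in names(params)) {
      m[[nm]] <- beta1 * m[[nm]] + (1 - beta1) * grads[[nm]]
      v[[nm]] <- beta2 * v[[nm]] + (1 - beta2) * grads[[nm]]^2
      mhat <- m[[nm]] / (1 - beta1^epoch)
      vhat <- v[[nm]] / (1 - beta2^epoch)
      params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
    }
    val_eta <- mlp_forward(params$W1, params$b1, params$w2, params$b2, Xval)
    vl <- log_loss(val_eta, yval)
    if (!is.finite(vl)) abort("Training diverged; try a smaller learning rate.")
    history <- c(history, vl)
    if (vl < best$loss - 1e-9) {
      best <- list(loss = vl, params = params, epoch = epoch)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= patience) break
    }
  }
  c(best$params, list(val_loss = best$loss, history = history,
                      stopped_epoch = best$epoch))
}

#' Evaluate a model's logit on standardized rows
#'
#' Generic accessor for the log-odds of any fitted prnet model (base MLP,
#' wrapped function, or partial response network) on a standardized table
#' or matrix.
#'
#' @param model A fitted model.
#' @param data Standardized tibble or numeric matrix whose columns match
#'   the model's training columns.
#' @return Numeric vector of log-odds.
#' @export
predict_logit <- function(model, data) UseMethod("predict_logit")

model_matrix <- function(model, data) {
  if (is.matrix(data)) {
    if (ncol(data) != length(model$columns)) {
      abort(sprintf("Expected %d columns, got %d.", length(model$columns), ncol(data)))
    }
    storage.mode(data) <- "double"
    return(data)
  }
  missing_cols <- setdiff(model$columns, names(data))
  if (length(missing_cols)) {
    abort(sprintf("Missing predictor column(s): %s", paste(missing_cols, collapse = ", ")))
  }
  as_numeric_matrix(data, model$columns)
}

#' @export
predict_logit.prn_mlp <- function(model, data) {
  mlp_forward(model$W1, model$b1, model$w2, model$b2, model_matrix(model, data))
}

#' @export
predict.prn_mlp <- function(object, newdata, type = c("link", "response"), ...) {
  type <- match.arg(type)
  eta <- predict_logit(object, newdata)
  if (type == "response") sigmoid(eta) else eta
}

#' @export
print.prn_mlp <- function(x, ...) {
  cat(sprintf("<prn_mlp> %d inputs, %d tanh hidden units; best val log-loss %.4f\n",
              length(x$columns), x$hidden, min(x$history)))
  invisible(x)
}

#' @method glance prn_mlp
#' @export
glance.prn_mlp <- function(x, ...) {
  tibble(hidden = x$hidden, n_inputs = length(x$columns),
         val_log_loss = min(x$history), epochs = length(x$history),
         seed = x$seed)
}

#' Wrap an arbitrary function as a black-box logit model
#'
#' Lets any vectorized function of a numeric matrix stand in for a trained
#' network, so known generating functions can be pushed through the
#' anchored decomposition and compared against their closed forms.
#'
#' @param fun Function taking an `n x d` matrix and returning `n` logits.
#' @param columns Character vector of input column names.
#' @return An object of class `prn_blackbox` usable with [predict_logit()]
#'   and [decompose_logit()].
#' @export
as_blackbox <- function(fun, columns) {
  structure(list(fun = fun, columns = columns), class = "prn_blackbox")
}

#' @export
predict_logit.prn_blackbox <- function(model, data) {
  drop(model$fun(model_matrix(model, data)))
}
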