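#' Build the partial response network from a selected model
#'
#' Constructs the self-explaining modular network: one subnetwork per
#' response retained by the lasso, each a replica of the base MLP's hidden
#' layer restricted to the response's variable(s) with every other input
#' clamped at the anchor (the zero vector in standardized units). A
#' univariate module computes `scale * (h(x_i) - h(0))`; a bivariate module
#' computes the shared-weight inclusion-exclusion
#' `scale * (h(x_i, x_j) - h(x_i, 0) - h(0, x_j) + h(0, 0))`, so the
#' anchored-zero and slice-zero identities hold by construction and remain
#' exact under any later weight update. Output scales start at the lasso
#' coefficients and the global intercept at the lasso intercept, so at
#' initialization the PRN logit equals the lasso-GAM logit everywhere.
#'
#' @param base The fitted [fit_mlp()] base model.
#' @param gam A selected [prn_lasso][select_responses()] model whose
#'   decomposition was computed from `base`.
#' @return An object of class `prn_network`.
#' @export
build_prn <- function(base, gam) {
  if (is.null(gam$selected)) abort("Run select_responses() first.")
  decomp <- gam$decomp
  if (is.null(decomp)) abort("The lasso model carries no decomposition; refit from response_features().")
  modules <- lapply(gam$selected, function(nm) {
    r <- decomp$responses[[nm]]
    if (is.null(r)) abort(sprintf("Response `%s` is not in the decomposition.", nm))
    if (!all(r$vars %in% base$columns)) {
      abort(sprintf("Response `%s` references variables absent from the base model.", nm))
    }
    idx <- match(r$vars, base$columns)
    list(term = nm, vars = r$vars, idx = idx,
         kinds = r$kinds, order = r$order,
         Wm = base$W1[idx, , drop = FALSE], b1 = base$b1, w2 = base$w2,
         scale = unname(gam$beta[nm]))
  })
  names(modules) <- gam$selected
  structure(list(modules = modules, intercept = gam$intercept,
                 columns = base$columns, anchor = decomp$anchor,
                 meta = list(retrained = FALSE)),
            class = "prn_network")
}

# Inclusion-exclusion masks (columns of the module's own variables to keep)
# and signs for one module.
module_terms <- function(order) {
  if (order == 1L) {
    list(masks = list(TRUE, FALSE), signs = c(1, -1))
  } else {
    list(masks = list(c(TRUE, TRUE), c(TRUE, FALSE), c(FALSE, TRUE), c(FALSE, FALSE)),
         signs = c(1, -1, -1, 1))
  }
}

# Forward pass of one module on the full input matrix; returns the
# module's additive logit contribution (scale included).
module_output <- function(mod, X) {
  Xm <- X[, mod$idx, drop = FALSE]
  tt <- module_terms(mod$order)
  out <- 0
  for (t in seq_along(tt$signs)) {
    Xt <- sweep(Xm, 2, as.numeric(tt$masks[[t]]), "*")
    out <- out + tt$signs[t] * drop(tanh(sweep(Xt %*% mod$Wm, 2, mod$b1, "+")) %*% mod$w2)
  }
  mod$scale * out
}

#' @export
predict_logit.prn_network <- function(model, data) {
  X <- model_matrix(model, data)
  eta <- rep(model$intercept, nrow(X))
  for (mod in model$modules) eta <- eta + module_output(mod, X)
  eta
}

#' @export
predict.prn_network <- function(object, newdata, type = c("link", "response"), ...) {
  type <- match.arg(type)
  eta <- predict_logit(object, newdata)
  if (type == "response") sigmoid(eta) else eta
}

#' @export
print.prn_network <- function(x, ...) {
  cat(sprintf("<prn_network> %d modules (%s); intercept %.4f%s\n",
              length(x$modules), paste(names(x$modules), collapse = ", "),
              x$intercept,
              if (isTRUE(x$meta$retrained)) "; retrained" else "; at initialization"))
  invisible(x)
}

#' @method glance prn_network
#' @export
glance.prn_network <- function(x, ...) {
  tibble(n_modules = length(x$modules), intercept = x$intercept,
         retrained = isTRUE(x$meta$retrained),
         epochs = x$meta$stopped_epoch %||% 0L)
}

#' Retrain the partial response network
#'
#' Optimizes all module weights, output scales and the global intercept
#' jointly by full-batch Adam on the binomial log-loss, with early
#' stopping on a seeded held-out split. The modular architecture is never
#' altered: no cross-module connection can appear, so each module's output
#' still depends only on its declared variable(s), and the inclusion-
#' exclusion parameterization keeps every module exactly zero at the
#' anchor throughout training.
#'
#' @param model A [build_prn()] network.
#' @param data Standardized, imputed training rows.
#' @param outcome Outcome column name.
#' @param seed Seed for the validation split.
#' @param epochs Maximum epochs (default 500); `0` returns the model
#'   unchanged.
#' @param learning_rate Adam step size.
#' @param validation_fraction Held-out fraction for early stopping.
#' @param patience Early-stopping patience (default 20).
#' @param l2 L2 penalty on module weights.
#' @return The retrained `prn_network`, with checkpoint losses in
#'   `meta$checkpoints`.
#' @export
retrain_prn <- function(model, data, outcome = attr(data, "outcome") %||% "outcome",
                        seed = 1, epochs = 500, learning_rate = 0.01,
                        validation_fraction = 0.2, patience = 20, l2 = 1e-4) {
  if (epochs == 0) return(model)
  X <- model_matrix(model, data)
  y <- data[[outcome]]
  check_binary(y, outcome)
  withr::local_seed(as.integer(seed))
  n <- nrow(X)
  n_val <- max(1L, round(validation_fraction * n))
  val <- sample.int(n, n_val)
  tr <- setdiff(seq_len(n), val)
  Xtr <- X[tr, , drop = FALSE]; ytr <- y[tr]
  Xval <- X[val, , drop = FALSE]; yval <- y[val]
  ntr <- length(tr)

  mods <- model$modules
  icpt <- model$intercept
  # Adam state per parameter
  zero_like <- function(mod) list(Wm = mod$Wm * 0, b1 = mod$b1 * 0,
                                  w2 = mod$w2 * 0, scale = 0)
  mstate <- lapply(mods, zero_like); vstate <- lapply(mods, zero_like)
  m_i <- 0; v_i <- 0
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  best <- list(loss = Inf, mods = mods, icpt = icpt, epoch = 0L)
  checkpoints <- numeric(0)
  wait <- 0L

  # Clamped (masked) input matrices never change during training, so they
  # are built once. A term whose mask is all-FALSE sees the anchor (zero)
  # input: its activations are identical across rows, so it is evaluated
  # on a single row (`NULL` marker) and its input-weight gradient is zero.
  clamp_inputs <- function(XX) {
    lapply(mods, function(mod) {
      Xm <- XX[, mod$idx, drop = FALSE]
      tt <- module_terms(mod$order)
      lapply(tt$masks, function(msk) {
        if (!any(msk)) return(NULL)
        if (all(msk)) Xm else sweep(Xm, 2, as.numeric(msk), "*")
      })
    })
  }
  Xtr_terms <- clamp_inputs(Xtr)
  Xval_terms <- clamp_inputs(Xval)

  # One pass computing both the logit and the per-term activations.
  forward_cache <- function(mods, icpt, X_terms, n) {
    eta <- rep(icpt, n)
    cache <- vector("list", length(mods))
    for (k in seq_along(mods)) {
      mod <- mods[[k]]
      tt <- module_terms(mod$order)
      Acache <- vector("list", length(tt$signs))
      h <- 0
      for (t in seq_along(tt$signs)) {
        Xt <- X_terms[[k]][[t]]
        if (is.null(Xt)) {
          A0 <- tanh(mod$b1)
          Acache[[t]] <- A0
          h <- h + tt$signs[t] * sum(A0 * mod$w2)
        } else {
          A <- tanh(sweep(Xt %*% mod$Wm, 2, mod$b1, "+"))
          Acache[[t]] <- A
          h <- h + tt$signs[t] * drop(A %*% mod$w2)
        }
      }
      eta <- eta + mod$scale * h
      cache[[k]] <- list(A = Acache, h = h)
    }
    list(eta = eta, cache = cache)
  }

  for (epoch in seq_len(epochs)) {
    fw <- forward_cache(mods, icpt, Xtr_terms, ntr)
    r <- (sigmoid(fw$eta) - ytr) / ntr
    g_i <- sum(r)
    rsum <- g_i
    grads <- lapply(seq_along(mods), function(k) {
      mod <- mods[[k]]
      tt <- module_terms(mod$order)
      gW <- mod$Wm * 0; gb <- mod$b1 * 0; gw2 <- mod$w2 * 0
      rw2 <- NULL
      for (t in seq_along(tt$signs)) {
        s <- tt$signs[t]
        Xt <- Xtr_terms[[k]][[t]]
        A <- fw$cache[[k]]$A[[t]]
        if (is.null(Xt)) {
          # anchor term: constant across rows; no input-weight gradient
          gw2 <- gw2 + s * rsum * A
          gb <- gb + s * rsum * mod$w2 * (1 - A^2)
        } else {
          if (is.null(rw2)) rw2 <- r %o% mod$w2
          gw2 <- gw2 + s * drop(crossprod(A, r))
          dz <- s * rw2 * (1 - A^2)
          gW <- gW + crossprod(Xt, dz)
          gb <- gb + colSums(dz)
        }
      }
      list(Wm = mod$scale * gW + 2 * l2 * mod$Wm,
           b1 = mod$scale * gb,
           w2 = mod$scale * gw2 + 2 * l2 * mod$w2,
           scale = sum(r * fw$cache[[k]]$h))
    })
    for (k in seq_along(mods)) {
      for (nm in c("Wm", "b1", "w2", "scale")) {
        mstate[[k]][[nm]] <- beta1 * mstate[[k]][[nm]] + (1 - beta1) * grads[[k]][[nm]]
        vstate[[k]][[nm]] <- beta2 * vstate[[k]][[nm]] + (1 - beta2) * grads[[k]][[nm]]^2
        mhat <- mstate[[k]][[nm]] / (1 - beta1^epoch)
        vhat <- vstate[[k]][[nm]] / (1 - beta2^epoch)
        mods[[k]][[nm]] <- mods[[k]][[nm]] - learning_rate * mhat / (sqrt(vhat) + eps)
      }
    }
    m_i <- beta1 * m_i + (1 - beta1) * g_i
    v_i <- beta2 * v_i + (1 - beta2) * g_i^2
    icpt <- icpt - learning_rate * (m_i / (1 - beta1^epoch)) /
      (sqrt(v_i / (1 - beta2^epoch)) + eps)

    vl <- log_loss(forward_cache(mods, icpt, Xval_terms, length(yval))$eta, yval)
    if (!is.finite(vl)) abort("PRN retraining diverged; try a smaller learning rate.")
    if (vl < best$loss - 1e-9) {
      best <- list(loss = vl, mods = mods, icpt = icpt, epoch = epoch)
      checkpoints <- c(checkpoints, vl)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= patience) break
    }
  }
  out <- model
  out$modules <- best$mods
  out$intercept <- best$icpt
  out$meta <- list(retrained = TRUE, stopped_epoch = best$epoch,
                   val_loss = best$loss, checkpoints = checkpoints, seed = seed)
  out
}

#' Second selection pass: from the PRN to the PRN-Lasso
#'
#' Re-applies the decompose-then-select procedure to the retrained
#' network's own logit. Candidate responses are exactly the network's
#' modules (the PRN cannot contain effects outside them), so the anchored
#' decomposition recovers each module's function and the lasso prunes or
#' reweights the set. The result is the final PRN-Lasso model.
#'
#' @param model A retrained [prn_network].
#' @param data Standardized, imputed training rows.
#' @param outcome Outcome column name.
#' @param nfolds,seed,rule Passed to [fit_response_lasso()] and
#'   [select_responses()].
#' @param n_grid Grid resolution for the stored response curves.
#' @return A selected `prn_lasso` whose decomposition is of the PRN.
#' @export
prn_to_lasso <- function(model, data, outcome = attr(data, "outcome") %||% "outcome",
                         nfolds = 10, seed = 1, rule = "min_cv", n_grid = 101) {
  terms <- vapply(model$modules, function(m) paste(m$vars, collapse = ":"), "")
  decomp <- decompose_logit(model, data, max_order = 2, n_grid = n_grid,
                            terms = unname(terms), outcome = outcome)
  feats <- response_features(decomp, data)
  path <- fit_response_lasso(feats, data[[outcome]], nfolds = nfolds, seed = seed)
  path$decomp <- decomp
  select_responses(path, rule = rule)
}
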