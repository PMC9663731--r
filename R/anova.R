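#' Anchored functional ANOVA decomposition of a model's logit
#'
#' Decomposes the log-odds surface `g(x)` of any fitted model into an
#' intercept `g(anchor)` plus univariate and bivariate partial responses,
#' by cutting the surface at the median anchor (the zero vector in
#' standardized units): `f_i(t) = g(anchor with x_i = t) - g(anchor)` and
#' `f_ij(s, t) = g(anchor with x_i = s, x_j = t) - f_i(s) - f_j(t) -
#' g(anchor)`. Every univariate response is exactly zero at the anchor and
#' every bivariate response is exactly zero along both anchor slices, so a
#' patient sitting at the median contributes nothing on any term.
#'
#' Continuous grids are equally spaced quantiles of the training data
#' (anchor inserted, duplicates removed); binary columns are evaluated at
#' their two standardized levels only. Grids serve serialization, plotting
#' and explanation; model-dependent quantities (features, residuals) are
#' always computed by calling the model directly.
#'
#' @param model A fitted model with a [predict_logit()] method.
#' @param data The standardized training tibble (used for grids and column
#'   kinds).
#' @param max_order 1 for main effects only, 2 to add all variable pairs.
#' @param n_grid Number of quantile grid points for continuous columns.
#' @param max_pairs Optional cap on the number of bivariate responses kept
#'   (the top ones by grid variance); `Inf` keeps all `d(d-1)/2`.
#' @param terms Optional character vector of response names (`"x"` or
#'   `"x:y"`) restricting the candidate set, e.g. to a network's own
#'   modules in the second selection pass.
#' @param outcome Outcome column name to exclude from predictors.
#' @return An object of class `prn_anova`: intercept, named list of
#'   responses, and a link to the source model.
#' @export
decompose_logit <- function(model, data, max_order = 2, n_grid = 101,
                            max_pairs = Inf, terms = NULL,
                            outcome = attr(data, "outcome") %||% "outcome") {
  stopifnot(max_order %in% c(1, 2))
  cols <- model$columns
  d <- length(cols)
  sc <- table_schema(data, outcome)
  kinds <- stats::setNames(sc$kind[match(cols, sc$column)], cols)
  grids <- lapply(cols, function(nm) {
    x <- data[[nm]]
    x <- x[!is.na(x)]
    if (kinds[[nm]] == "binary") {
      sort(unique(x))
    } else {
      g <- unname(stats::quantile(x, seq(0, 1, length.out = n_grid), type = 7))
      sort(unique(c(g, 0)))
    }
  })
  names(grids) <- cols
  g0 <- univariate_cut(model, d, integer(0), numeric(0), 1L)

  responses <- list()
  for (i in seq_len(d)) {
    gi <- grids[[i]]
    cut <- univariate_cut(model, d, i, gi)
    # anchor within the batch when possible, making the anchored-zero
    # identity exact in floating point
    i0 <- match(0, gi)
    vals <- if (!is.na(i0)) cut - cut[i0] else cut - g0
    responses[[cols[i]]] <- new_response(cols[i], i, list(gi), vals,
                                         kinds[cols[i]])
  }
  if (max_order == 2 && d >= 2) {
    pair_idx <- utils::combn(d, 2)
    if (!is.null(terms)) {
      keep_pair <- vapply(seq_len(ncol(pair_idx)), function(p) {
        any(terms %in% c(paste(cols[pair_idx[1, p]], cols[pair_idx[2, p]], sep = ":"),
                         paste(cols[pair_idx[2, p]], cols[pair_idx[1, p]], sep = ":")))
      }, TRUE)
      pair_idx <- pair_idx[, keep_pair, drop = FALSE]
    }
    pair_resps <- lapply(seq_len(ncol(pair_idx)), function(p) {
      i <- pair_idx[1, p]; j <- pair_idx[2, p]
      gi <- grids[[i]]; gj <- grids[[j]]
      X <- matrix(0, length(gi) * length(gj), d)
      X[, i] <- rep(gi, times = length(gj))
      X[, j] <- rep(gj, each = length(gi))
      gij <- matrix(predict_logit(model, X), length(gi), length(gj))
      # subtract the anchor slices of this same batch, so the slice-zero
      # identity holds exactly in floating point
      i0 <- match(0, gi); j0 <- match(0, gj)
      fij <- if (!is.na(i0) && !is.na(j0)) {
        gij - gij[, j0] -
          matrix(gij[i0, ], length(gi), length(gj), byrow = TRUE) + gij[i0, j0]
      } else {
        gij - responses[[cols[i]]]$values -
          matrix(responses[[cols[j]]]$values, length(gi), length(gj),
                 byrow = TRUE) - g0
      }
      new_response(c(cols[i], cols[j]), c(i, j), list(gi, gj), fij,
                   kinds[c(cols[i], cols[j])])
    })
    names(pair_resps) <- vapply(seq_len(ncol(pair_idx)), function(p) {
      paste(cols[pair_idx[1, p]], cols[pair_idx[2, p]], sep = ":")
    }, "")
    if (is.finite(max_pairs) && length(pair_resps) > max_pairs) {
      vr <- vapply(pair_resps, function(r) stats::var(as.vector(r$values)), 0)
      pair_resps <- pair_resps[order(-vr)[seq_len(max_pairs)]]
    }
    responses <- c(responses, pair_resps)
  }
  if (!is.null(terms)) {
    keep <- vapply(names(responses), function(nm) {
      r <- responses[[nm]]
      alt <- if (r$order == 2L) paste(rev(r$vars), collapse = ":") else nm
      nm %in% terms || alt %in% terms
    }, TRUE)
    responses <- responses[keep]
  }
  structure(list(intercept = g0, responses = responses, columns = cols,
                 kinds = kinds, model = model,
                 anchor = attr(data, "anchor")),
            class = "prn_anova")
}

new_response <- function(vars, idx, grids, values, kinds) {
  structure(list(vars = vars, idx = idx, grids = grids, values = values,
                 kinds = unname(kinds), order = length(vars)),
            class = "prn_response")
}

# g evaluated at the anchor cut with columns `idx` set to `values` (a grid
# vector for one column, or recycled scalar); returns vector of logits.
univariate_cut <- function(model, d, idx, values, n = length(values)) {
  X <- matrix(0, max(n, 1L), d)
  if (length(idx)) X[, idx] <- values
  predict_logit(model, X)
}

#' Evaluate a stored partial response by interpolation
#'
#' Continuous axes use piecewise-linear interpolation on the stored grid
#' with linear extrapolation beyond it (so, e.g., an era effect can be
#' projected forward in time); binary axes are exact lookups at the two
#' standardized levels, and any other value is an error. Bivariate
#' responses interpolate bilinearly.
#'
#' @param response A `prn_response` from [decompose_logit()].
#' @param values Numeric vector (order 1) or a 2-column matrix / data
#'   frame / list of two vectors (order 2), in standardized units.
#' @return Numeric vector of logit contributions.
#' @export
evaluate_response <- function(response, values) {
  if (response$order == 1L) {
    x <- as.numeric(if (is.data.frame(values) || is.list(values)) values[[1]] else values)
    axis_eval_1d(response$grids[[1]], response$values, x,
                 response$kinds[1], response$vars[1])
  } else {
    if (is.data.frame(values)) values <- as.matrix(values)
    if (is.list(values)) values <- cbind(values[[1]], values[[2]])
    s <- as.numeric(values[, 1]); t <- as.numeric(values[, 2])
    bilinear_eval(response, s, t)
  }
}

axis_index <- function(grid, x, kind, var) {
  if (kind == "binary") {
    ix <- vapply(x, function(v) {
      hit <- which(abs(grid - v) < 1e-8)
      if (!length(hit)) {
        abort(sprintf("Value %g is not a standardized {0,1} level of binary variable `%s`.",
                      v, var))
      }
      hit[1]
    }, 1L)
    list(i = pmax(ix - (ix == length(grid)), 1L), w = as.numeric(ix == length(grid)))
  } else {
    i <- findInterval(x, grid, all.inside = TRUE)
    list(i = i, w = (x - grid[i]) / (grid[i + 1L] - grid[i]))
  }
}

axis_eval_1d <- function(grid, values, x, kind, var) {
  a <- axis_index(grid, x, kind, var)
  values[a$i] * (1 - a$w) + values[a$i + 1L] * a$w
}

bilinear_eval <- function(response, s, t) {
  gi <- response$grids[[1]]; gj <- response$grids[[2]]
  ai <- axis_index(gi, s, response$kinds[1], response$vars[1])
  aj <- axis_index(gj, t, response$kinds[2], response$vars[2])
  V <- response$values
  V[cbind(ai$i, aj$i)] * (1 - ai$w) * (1 - aj$w) +
    V[cbind(ai$i + 1L, aj$i)] * ai$w * (1 - aj$w) +
    V[cbind(ai$i, aj$i + 1L)] * (1 - ai$w) * aj$w +
    V[cbind(ai$i + 1L, aj$i + 1L)] * ai$w * aj$w
}

# Model-direct response values on data rows: the model is called on
# anchor cuts of the actual rows, never interpolated. For a partial
# response network the generic anchored cuts reduce exactly to the
# module outputs (modules are additive and vanish on anchor slices), so
# they are used directly when every requested term has a module.
response_values_direct <- function(model, decomp, data) {
  X <- model_matrix(model, data)
  if (inherits(model, "prn_network")) {
    mod_terms <- vapply(model$modules, function(m) paste(m$vars, collapse = ":"), "")
    match_mod <- function(r) {
      nm <- paste(r$vars, collapse = ":")
      alt <- paste(rev(r$vars), collapse = ":")
      k <- match(nm, mod_terms)
      if (is.na(k)) k <- match(alt, mod_terms)
      k
    }
    ks <- vapply(decomp$responses, match_mod, 1L)
    if (!anyNA(ks)) {
      out <- lapply(seq_along(ks), function(j) {
        module_output(model$modules[[ks[j]]], X)
      })
      names(out) <- names(decomp$responses)
      return(out)
    }
  }
  d <- ncol(X)
  g0 <- decomp$intercept
  uni <- list()
  for (r in decomp$responses) {
    if (r$order == 1L) {
      Xi <- matrix(0, nrow(X), d)
      Xi[, r$idx] <- X[, r$idx]
      uni[[r$vars]] <- predict_logit(model, Xi) - g0
    }
  }
  out <- list()
  for (nm in names(decomp$responses)) {
    r <- decomp$responses[[nm]]
    if (r$order == 1L) {
      out[[nm]] <- uni[[r$vars]]
    } else {
      Xij <- matrix(0, nrow(X), d)
      Xij[, r$idx] <- X[, r$idx]
      fi <- uni[[r$vars[1]]] %||% (predict_logit(model, zero_but(X, d, r$idx[1])) - g0)
      fj <- uni[[r$vars[2]]] %||% (predict_logit(model, zero_but(X, d, r$idx[2])) - g0)
      out[[nm]] <- predict_logit(model, Xij) - fi - fj - g0
    }
  }
  out
}

zero_but <- function(X, d, idx) {
  Z <- matrix(0, nrow(X), d)
  Z[, idx] <- X[, idx]
  Z
}

#' Residual of the order-2 truncated reconstruction
#'
#' Computes, per row, `g(x) - [f0 + sum of retained responses(x)]` with all
#' responses evaluated through the model directly. For a purely additive
#' model (or additive plus the retained pairwise terms) the residual is
#' zero to numerical precision; otherwise it is exactly the mass sitting in
#' components of order three and higher.
#'
#' @param decomp A [decompose_logit()] result.
#' @param data Standardized rows.
#' @return A tibble with columns `.row` and `residual`, with the root mean
#'   square in attribute `rms`.
#' @export
reconstruction_residual <- function(decomp, data) {
  model <- decomp$model
  g <- predict_logit(model, model_matrix(model, data))
  vals <- response_values_direct(model, decomp, data)
  fit <- decomp$intercept + Reduce(`+`, vals, accumulate = FALSE)
  res <- g - fit
  structure(tibble(.row = seq_along(res), residual = res),
            rms = sqrt(mean(res^2)))
}

#' @export
print.prn_anova <- function(x, ...) {
  n1 <- sum(vapply(x$responses, function(r) r$order, 1L) == 1L)
  n2 <- length(x$responses) - n1
  cat(sprintf("<prn_anova> intercept %.4f; %d univariate + %d bivariate partial responses\n",
              x$intercept, n1, n2))
  invisible(x)
}

#' @method tidy prn_anova
#' @export
tidy.prn_anova <- function(x, ...) {
  purrr::map_dfr(names(x$responses), function(nm) {
    r <- x$responses[[nm]]
    if (r$order == 1L) {
      tibble(term = nm, order = 1L, var1 = r$vars[1], var2 = NA_character_,
             x1 = r$grids[[1]], x2 = NA_real_, value = as.numeric(r$values))
    } else {
      tibble(term = nm, order = 2L, var1 = r$vars[1], var2 = r$vars[2],
             x1 = rep(r$grids[[1]], times = length(r$grids[[2]])),
             x2 = rep(r$grids[[2]], each = length(r$grids[[1]])),
             value = as.numeric(r$values))
    }
  })
}
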