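# Structured-text (JSON) serialization with exact numeric round-trip.
# Weights and grids are written with full precision (digits = NA), so a
# reloaded model reproduces logits bit-for-bit.

#' Write or read a fitted prnet object as JSON
#'
#' Supports [fit_mlp()] models, [compute_anchor()] tables,
#' [decompose_logit()] decompositions (without the source-model link) and
#' [build_prn()] networks. Numbers are written in full precision so
#' predictions from a reloaded model are bit-identical.
#'
#' @param x A supported object.
#' @param path Output (input) file path.
#' @return `write_model` returns `path` invisibly; `read_model` the
#'   reconstructed object.
#' @export
write_model <- function(x, path) {
  payload <- if (inherits(x, "prn_mlp")) {
    list(type = "prn_mlp", W1 = x$W1, b1 = x$b1, w2 = x$w2, b2 = x$b2,
         hidden = x$hidden, columns = x$columns, seed = x$seed, l2 = x$l2)
  } else if (inherits(x, "prn_anchor")) {
    list(type = "prn_anchor", column = x$column, kind = x$kind,
         anchor = x$anchor, scale = x$scale)
  } else if (inherits(x, "prn_network")) {
    list(type = "prn_network", intercept = x$intercept, columns = x$columns,
         anchor = anchor_to_list(x$anchor),
         retrained = isTRUE(x$meta$retrained),
         modules = lapply(unname(x$modules), function(m) {
           list(term = m$term, vars = m$vars, idx = m$idx, kinds = m$kinds,
                order = m$order, Wm = m$Wm, b1 = m$b1, w2 = m$w2,
                scale = m$scale)
         }))
  } else if (inherits(x, "prn_anova")) {
    list(type = "prn_anova", intercept = x$intercept, columns = x$columns,
         kinds = unname(x$kinds),
         anchor = anchor_to_list(x$anchor),
         responses = lapply(unname(x$responses), function(r) {
           list(vars = r$vars, idx = r$idx, grids = r$grids,
                values = r$values, kinds = r$kinds, order = r$order)
         }))
  } else {
    abort("Unsupported object class for write_model().")
  }
  # digits = I(17): 17 significant digits round-trip IEEE doubles exactly
  jsonlite::write_json(payload, path, digits = I(17), auto_unbox = FALSE,
                       pretty = FALSE)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = FALSE)
  type <- unlist(p$type)
  num <- function(x) as.numeric(unlist(x))
  chr <- function(x) as.character(unlist(x))
  mat <- function(x) do.call(rbind, lapply(x, num))
  switch(type,
    prn_mlp = structure(list(
      W1 = mat(p$W1), b1 = num(p$b1), w2 = num(p$w2), b2 = num(p$b2),
      hidden = as.integer(unlist(p$hidden)), columns = chr(p$columns),
      seed = num(p$seed), l2 = num(p$l2), history = numeric(0)),
      class = "prn_mlp"),
    prn_anchor = new_anchor_tbl(chr(p$column), chr(p$kind),
                                num(p$anchor), num(p$scale)),
    prn_network = {
      modules <- lapply(p$modules, function(m) {
        list(term = chr(m$term), vars = chr(m$vars),
             idx = as.integer(unlist(m$idx)), kinds = chr(m$kinds),
             order = as.integer(unlist(m$order)),
             Wm = mat(m$Wm), b1 = num(m$b1), w2 = num(m$w2),
             scale = num(m$scale))
      })
      names(modules) <- vapply(modules, `[[`, "", "term")
      structure(list(modules = modules, intercept = num(p$intercept),
                     columns = chr(p$columns),
                     anchor = anchor_from_list(p$anchor),
                     meta = list(retrained = isTRUE(unlist(p$retrained)))),
                class = "prn_network")
    },
    prn_anova = {
      responses <- lapply(p$responses, function(r) {
        order <- as.integer(unlist(r$order))
        grids <- lapply(r$grids, num)
        values <- if (order == 1L) num(r$values) else mat(r$values)
        new_response(chr(r$vars), as.integer(unlist(r$idx)), grids, values,
                     chr(r$kinds))
      })
      names(responses) <- vapply(responses, function(r) {
        paste(r$vars, collapse = ":")
      }, "")
      cols <- chr(p$columns)
      structure(list(intercept = num(p$intercept), responses = responses,
                     columns = cols,
                     kinds = stats::setNames(chr(p$kinds), cols),
                     model = NULL, anchor = anchor_from_list(p$anchor)),
                class = "prn_anova")
    },
    abort(sprintf("Unknown serialized type `%s`.", type))
  )
}

anchor_to_list <- function(a) {
  if (is.null(a)) return(NULL)
  list(column = a$column, kind = a$kind, anchor = a$anchor, scale = a$scale)
}

anchor_from_list <- function(a) {
  if (is.null(a) || !length(a)) return(NULL)
  num <- function(x) as.numeric(unlist(x))
  chr <- function(x) as.character(unlist(x))
  new_anchor_tbl(chr(a$column), chr(a$kind), num(a$anchor), num(a$scale))
}

new_anchor_tbl <- function(column, kind, anchor, scale) {
  structure(tibble(column = column, kind = kind, anchor = anchor, scale = scale),
            class = c("prn_anchor", class(tibble())))
}
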