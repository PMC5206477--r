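#' Serialise fitted models to JSON
#'
#' Trees serialise as nested `(j, s, left, right)` nodes with leaf
#' constants; SVR models as dual coefficients, support rows, bias and
#' configuration; ensembles as lists of member serialisations. The JSON
#' is self-contained enough to re-evaluate the model elsewhere.
#'
#' @param model a fitted `rtree`, `esvr`, `bagging` or `rt_boost` object.
#' @param path optional file path; when given the JSON is written there
#'   and the path returned invisibly.
#' @return A JSON string (class `json`), or `path` invisibly.
#' @export
model_to_json <- function(model, path = NULL) {
  lst <- model_to_list(model)
  js <- jsonlite::toJSON(lst, auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(path))
  }
  js
}

model_to_list <- function(model) UseMethod("model_to_list")

#' @export
model_to_list.rtree <- function(model) {
  nd <- model$nodes
  build <- function(id) {
    if (is.na(nd$j[id]))
      return(list(leaf = TRUE, cm = nd$cm[id], n = nd$n_node[id],
                  sse = nd$sse_node[id]))
    list(leaf = FALSE, j = nd$j[id], s = nd$s[id],
         n = nd$n_node[id], sse = nd$sse_node[id],
         left = build(nd$left[id]), right = build(nd$right[id]))
  }
  list(type = "rtree", control = unclass(model$control),
       feature_names = model$feature_names, root = build(1L))
}

#' @export
model_to_list.esvr <- function(model) {
  list(type = "esvr", config = model$config,
       dual_coefs = model$dual_coefs,
       support_X = apply(model$support_X, 1L, as.numeric,
                         simplify = FALSE),
       b = model$b, N = model$N)
}

#' @export
model_to_list.bagging <- function(model) {
  list(type = "bagging", base = model$base, B = model$B,
       seeds = model$seeds,
       members = lapply(model$members, function(m)
         if (inherits(m, "constant_predictor"))
           list(type = "constant", value = m$value)
         else model_to_list(m)))
}

#' @export
model_to_list.rt_boost <- function(model) {
  list(type = "rt_boost", f0 = model$f0, nu = model$nu, M = model$M,
       stage_losses = model$stage_losses,
       stages = lapply(model$stages, model_to_list))
}
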