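# Flat-file model persistence (JSON with full-precision numbers).

pack_obj <- function(x) {
  if (is.matrix(x)) list(.matrix = TRUE, dim = dim(x), data = as.vector(x))
  else if (is.list(x) && !is.data.frame(x)) lapply(x, pack_obj)
  else x
}

unpack_obj <- function(x) {
  if (is.list(x) && isTRUE(x$.matrix))
    matrix(unlist(x$data), unlist(x$dim)[1L], unlist(x$dim)[2L])
  else if (is.list(x)) lapply(x, unpack_obj)
  else x
}

#' Save / load a trained model
#'
#' Serialises peak models, NMF bases and frame detectors to a documented
#' flat JSON file (full-precision numbers, matrices stored with explicit
#' dimensions, class recorded in a `.type` field).
#'
#' @param model A `peak_models`, `nmf_model`, `gmm_detector` or
#'   `nn_detector`.
#' @param path File path.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, c("peak_models", "nmf_model", "gmm_detector",
                              "nn_detector", "diag_gmm")))
  payload <- pack_obj(unclass(model))
  payload$.type <- class(model)[1L]
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE,
                                 simplifyMatrix = FALSE)
  type <- payload$.type
  payload$.type <- NULL
  obj <- unpack_obj(payload)
  obj <- rapply(obj, function(v) if (is.list(v) && is.null(names(v))) unlist(v) else v,
                how = "replace", classes = "list")
  restore <- function(o) {
    if (identical(type, "peak_models")) {
      o$lambda_s <- structure(o$lambda_s, class = "diag_gmm")
      o$lambda_n <- structure(o$lambda_n, class = "diag_gmm")
    }
    structure(o, class = type)
  }
  restore(obj)
}
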