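#' Read and write parameter sets as structured config files
#'
#' Serializes any [ring_params()] / [reduced_params()] /
#' [tristable_params()] object to a flat JSON key-value file whose keys
#' mirror the constructor arguments, and reads such a file back into a
#' validated parameter object. Round-tripping reproduces the object
#' exactly, so a config file plus a seed fully determines a run.
#'
#' @param params a parameter object.
#' @param path file path.
#' @return `write_params_json()` returns `path` invisibly;
#'   `read_params_json()` returns the parameter object.
#' @examples
#' f <- tempfile(fileext = ".json")
#' write_params_json(ring_params(I0 = 0.9, beta = 0, eps = 0.04), f)
#' read_params_json(f)$I0
#' @export
write_params_json <- function(params, path) {
  stopifnot(inherits(params, "multistable_params"))
  out <- params
  out[["model"]] <- class(params)[1]
  out <- lapply(out, function(v)
    if (is.numeric(v) && is.infinite(v)) "Inf" else v)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_params_json
#' @export
read_params_json <- function(path) {
  raw <- jsonlite::read_json(path)
  model <- raw$model
  raw$model <- NULL
  raw <- lapply(raw, function(v) {
    if (identical(v, "Inf")) Inf
    else if (is.integer(v)) as.numeric(v)   # JSON carries no int/dbl split
    else v
  })
  ctor <- switch(model,
                 ring_params = ring_params,
                 reduced_params = reduced_params,
                 tristable_params = tristable_params,
                 stop("unknown model type in config: ", model))
  do.call(ctor, raw)
}
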