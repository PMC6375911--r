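#' @noRd
pp_log <- function(..., verbose = getOption("petrelpop.verbose", TRUE)) {
  if (isTRUE(verbose)) message("[petrelpop] ", ...)
  invisible(NULL)
}

# Deterministic child seed below 2^31, derived from a user seed and an index.
#' @noRd
derive_seed <- function(seed, index = 0L) {
  s <- (as.double(seed) %% 2147483647) + 1
  as.integer(((s * 48271 + as.double(index) * 7919) %% 2147483629) + 1)
}

#' Write a run manifest describing inputs, parameters and seed
#'
#' Every analysis step records what it consumed so that a run can be
#' reproduced from the manifest alone.
#'
#' @param path output JSON path.
#' @param inputs named list or character vector of input descriptions.
#' @param params named list of parameters.
#' @param seed integer seed used for the run (or `NULL`).
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, inputs = list(), params = list(), seed = NULL) {
  obj <- list(
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    inputs = inputs,
    params = params,
    seed = seed
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}
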