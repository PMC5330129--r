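#' @importFrom rlang %||%
#' @importFrom generics tidy glance
#' @importFrom tibble as_tibble
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' @export
tibble::as_tibble

# half-up rounding to `digits` decimals, used for report display (raw values
# are kept alongside); base round() is half-even which disagrees on .5 ties
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# run `expr` under a fixed RNG seed without disturbing the caller's RNG state
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# atomic file write: write to a sibling temp file, then rename into place
write_atomic <- function(path, writer) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writer(tmp)
  if (!file.rename(tmp, path)) {
    stop("could not write to ", path, call. = FALSE)
  }
  invisible(path)
}
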