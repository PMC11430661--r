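# shared internal helpers

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a deterministic child seed from a base seed and an index, staying
# inside the 32-bit integer range.
derive_seed <- function(seed, index) {
  as.integer((as.double(seed) * 1000003 + index * 7919) %% .Machine$integer.max)
}

stop_arg <- function(...) stop(..., call. = FALSE)

assert_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || !is.finite(x)) {
    stop_arg("`", name, "` must be a single finite number")
  }
  invisible(x)
}

assert_tau <- function(tau) {
  if (!is.numeric(tau) || any(is.na(tau)) || any(tau <= 0) || any(tau >= 1)) {
    stop_arg("quantile level `tau` must lie strictly between 0 and 1")
  }
  invisible(tau)
}

extdata_path <- function(file) {
  path <- system.file("extdata", file, package = "flipnorms")
  if (!nzchar(path)) {
    # during in-source testing (pkgload) system.file already resolves; this is
    # a hard failure otherwise
    stop_arg("packaged data file not found: ", file)
  }
  path
}
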