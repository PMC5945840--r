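# Internal helpers: classed conditions (so the CLI can map them to exit
# codes) and seed scoping that never leaks into the caller's RNG state.

stop_input <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("dfareg_input_error", "dfareg_error")))
}

stop_param <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("dfareg_param_error", "dfareg_error")))
}

stop_degenerate <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("dfareg_degenerate_error", "dfareg_error")))
}

# Evaluate `code` under `seed` and restore the caller's RNG state afterwards.
# seed = NULL means: use (and advance) the current RNG stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop_param("seed must be a single finite number, got %s",
               paste(format(seed), collapse = ", "))
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Deterministic per-replicate child seeds from one master seed, so Monte
# Carlo results do not depend on evaluation order. Part of the documented
# reproducibility contract of the significance module.
child_seeds <- function(seed, n) {
  with_seed(seed, sample.int(2147483646L, n))
}

check_series <- function(x, name = deparse(substitute(x)), min_len = 1L) {
  if (!is.numeric(x)) stop_input("%s must be numeric", name)
  if (length(x) < min_len) {
    stop_input("%s must have at least %d observations, got %d",
               name, min_len, length(x))
  }
  if (!all(is.finite(x))) {
    stop_input("%s contains non-finite values (first at position %d)",
               name, which(!is.finite(x))[1L])
  }
  invisible(x)
}

check_equal_length <- function(...) {
  lens <- lengths(list(...))
  if (length(unique(lens)) != 1L) {
    stop_input("series must have equal lengths, got %s",
               paste(lens, collapse = ", "))
  }
  invisible(lens[1L])
}
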