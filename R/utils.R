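# Internal helpers: structured error conditions and logging.

apa_error <- function(class, message, ...) {
  stop(errorCondition(message, ...,
                      class = c(class, "apa_error", "error", "condition")))
}

apa_log <- function(...) {
  if (isTRUE(getOption("apakit.verbose", FALSE))) {
    message("[apakit] ", sprintf(...))
  }
  invisible(NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Run an expression with a temporarily seeded RNG, restoring the caller's
# RNG state afterwards so generators are reproducible without side effects.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Atomic text write: write to a sibling temp file, then rename.
write_atomic <- function(writer, path) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writer(tmp)
  if (!file.rename(tmp, path)) {
    file.copy(tmp, path, overwrite = TRUE)
    unlink(tmp)
  }
  invisible(path)
}

stopifnot_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    apa_error("apa_schema_error", sprintf("'%s' must be a finite number", name),
              field = name)
  }
  if (positive && x <= 0) {
    apa_error("apa_schema_error", sprintf("'%s' must be > 0", name), field = name)
  }
  invisible(x)
}
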