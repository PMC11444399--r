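# Classed error helpers: every contract violation raises a condition whose
# class downstream code and tests can match on, e.g. "canicoh_invalid_spec".

abort_canicoh <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "canicoh_error")))
}

stopifnot_scalar_num <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    abort_canicoh(sprintf("`%s` must be a finite numeric scalar", name),
                  "canicoh_invalid_spec")
  if (positive && x <= 0)
    abort_canicoh(sprintf("`%s` must be > 0", name), "canicoh_invalid_spec")
  invisible(x)
}

# Run `code` with a fixed RNG seed, restoring the caller's RNG state after.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    genv <- globalenv()
    had <- exists(".Random.seed", envir = genv, inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
    on.exit({
      if (had) assign(".Random.seed", old, envir = genv)
      else if (exists(".Random.seed", envir = genv, inherits = FALSE))
        rm(".Random.seed", envir = genv)
    })
    set.seed(as.integer(seed))
  }
  force(code)
}
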