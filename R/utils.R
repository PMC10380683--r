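#' @keywords internal
"_PACKAGE"

# Derive reproducible sub-seeds from one master seed so pipeline stages
# (simulation, partitioning, noise) consume independent streams and can be
# re-run in isolation. Seeds stay below 2^31 - 1.
derive_seeds <- function(seed, n) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max - 1L, n)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_dq <- function(msg, class, ...) {
  stop(structure(class = c(class, "dualAAVquant_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1), ...)))
}
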