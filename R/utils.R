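# internal helpers

# evaluate `code` under set.seed(seed), restoring the caller's RNG state
withSeed <- function(seed, code) {
  gv <- globalenv()
  had <- exists(".Random.seed", envir = gv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = gv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = gv)
    else if (exists(".Random.seed", envir = gv, inherits = FALSE))
      rm(".Random.seed", envir = gv)
  })
  set.seed(seed)
  code
}

# derive a reproducible sub-seed from a base seed and a counter,
# kept inside the 32-bit integer range
deriveSeed <- function(seed, counter) {
  as.integer((as.numeric(seed) + 1000003 * as.numeric(counter)) %%
               .Machine$integer.max)
}

msg <- function(..., verbose = TRUE) {
  if (isTRUE(verbose)) message(...)
  invisible(NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
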