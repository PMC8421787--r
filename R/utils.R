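`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# RNG stream.
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  code
}

# Deterministic sub-seed for a (stage, run) pair, kept under 2^31.
sub_seed <- function(seed, stage, run = 0L) {
  s <- (abs(as.numeric(seed)) %% 1e5) * 20011 + stage * 101 + run
  as.integer(s %% 2147483647)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

assert_that <- function(ok, fmt, ...) if (!isTRUE(ok)) stopf(fmt, ...)

# Coerce mask-like input (logical/0-1 numeric array) to logical array.
as_mask <- function(x, name = "mask") {
  if (inherits(x, "tissue_volume")) stopf("%s must be a binary mask, not a tissue volume", name)
  a <- x
  if (is.numeric(a)) {
    assert_that(all(a %in% c(0, 1)), "%s must contain only 0/1 values", name)
    a <- a == 1
  }
  assert_that(is.logical(a) && length(dim(a)) == 3L, "%s must be a 3D logical array", name)
  a
}
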