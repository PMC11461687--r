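#' Derive a child seed from a master seed
#'
#' Deterministic seed splitting for independent random streams. Streams are
#' indexed by one or more small non-negative integers; the child seed is a
#' fixed affine hash of the master seed and the stream indices, reduced
#' modulo 2^31 - 1 so it is always a valid positive R integer.
#'
#' @param seed master seed (integer).
#' @param ... one or more non-negative integer stream indices.
#' @return a positive integer seed.
#' @export
#' @examples
#' child_seed(1, 3)
#' child_seed(1, 3, 2)
child_seed <- function(seed, ...) {
  idx <- c(...)
  stopifnot(length(idx) >= 1, all(idx >= 0))
  m <- 2147483647 # 2^31 - 1, prime
  h <- as.numeric(seed) %% m
  for (i in idx) {
    h <- (h * 48271 + as.numeric(i) + 1) %% m
  }
  as.integer(h + 1)
}

## Run code with a local RNG state seeded at `seed`; global RNG untouched.
with_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## Floor POSIXct to whole minutes, returned as numeric minutes since a base.
minutes_since <- function(t, base) {
  floor(as.numeric(difftime(t, base, units = "mins")))
}

stop_cf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) length(x) == 1 && is.numeric(x) && !is.na(x) &&
  x == as.integer(x)

## canonical multiset label for a set of resource-type names: sorted, "+"-joined
multiset_label <- function(types) paste(sort(types), collapse = "+")

## inverse of multiset_label
split_multiset <- function(label) strsplit(label, "+", fixed = TRUE)[[1]]
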