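#' Evaluate an expression with a temporary RNG seed
#'
#' Sets the RNG to a reproducible state, evaluates `code`, and restores the
#' caller's RNG state afterwards, so seeded helpers never perturb the global
#' random stream.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @export
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

#' Derive a child seed from a parent seed and a tag
#'
#' A single user-facing seed fans out to per-component seeds through this
#' deterministic derivation, so pipeline stages are reproducible piecewise.
#' The result is always in `[1, 2^31 - 2]`.
#'
#' @param seed Integer parent seed.
#' @param tag Character or integer tag naming the consumer.
#' @return An integer seed.
#' @export
derive_seed <- function(seed, tag) {
  stopifnot(length(seed) == 1L, length(tag) == 1L)
  m <- 2147483647                       # 2^31 - 1, Mersenne prime
  h <- as.double(abs(as.integer(seed))) %% m
  bytes <- utf8ToInt(paste0("::", as.character(tag)))
  for (b in bytes) h <- (h * 131 + b) %% m
  as.integer(h %% (m - 1)) + 1L
}

# consistent condition classes so callers can test for specific failures
dm_stop <- function(class, fmt, ...) {
  stop(structure(
    class = c(class, "dendromod_error", "error", "condition"),
    list(message = sprintf(fmt, ...), call = sys.call(-1))
  ))
}

#' Fingerprint a parameter object
#'
#' MD5 hash of the binary serialization of `x`; used to assert that frozen
#' parameters are bit-identical before and after training.
#'
#' @param x Any R object.
#' @return Character MD5 hex digest.
#' @export
param_fingerprint <- function(x) {
  f <- tempfile(fileext = ".bin")
  on.exit(unlink(f), add = TRUE)
  con <- file(f, "wb")
  serialize(x, con, version = 2L)
  close(con)
  unname(tools::md5sum(f))
}

# soft-threshold operator used by the sparse decompositions
soft_threshold <- function(x, t) sign(x) * pmax(abs(x) - t, 0)

# flip signs so the largest-magnitude entry of each row is positive
fix_row_signs <- function(W) {
  if (nrow(W) == 0L) return(W)
  for (i in seq_len(nrow(W))) {
    j <- which.max(abs(W[i, ]))
    if (length(j) && W[i, j] < 0) W[i, ] <- -W[i, ]
  }
  W
}

`%||%` <- function(a, b) if (is.null(a)) b else a
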