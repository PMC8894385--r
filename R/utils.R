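# Internal helpers shared across modules.

#' Evaluate code with a temporary RNG seed
#'
#' Sets the seed, runs `code`, and restores the caller's RNG state so that
#' generators are reproducible without clobbering the session RNG.
#'
#' @param seed Integer seed, or `NULL` to use the current RNG stream.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1L)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Derive a per-unit child seed from a root seed, kept inside 32-bit range.
child_seed <- function(seed, i) {
  if (is.null(seed)) return(NULL)
  (as.integer(seed) %% 1000003L) * 1009L + as.integer(i)
}

# FNV-1a hash of a character scalar, for lightweight provenance stamps.
fnv1a <- function(x) {
  bytes <- utf8ToInt(paste(x, collapse = "\n"))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
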