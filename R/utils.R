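# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state
# afterwards.  seed = NULL leaves the current stream untouched.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# Normal draws constrained positive by redrawing (not clamping): clamping
# would pile mass at zero and distort the distributions the chi-square fit
# compares.  More than `max_rounds` rounds of redraws means the requested
# (mean, sd) puts most of its mass at or below zero; that is a degenerate
# spec, not sampling bad luck.
rnorm_pos <- function(n, mean, sd, max_rounds = 100L) {
  x <- stats::rnorm(n, mean, sd)
  rounds <- 0L
  while (any(bad <- x <= 0)) {
    rounds <- rounds + 1L
    if (rounds > max_rounds) {
      stop("could not draw positive values from normal(", mean, ", ", sd,
           ") after ", max_rounds, " redraw rounds; degenerate specification",
           call. = FALSE)
    }
    x[bad] <- stats::rnorm(sum(bad), mean, sd)
  }
  x
}

# Cheap deterministic checksum used to tag outputs with their generating
# configuration.  An identity check for provenance, not a cryptographic hash.
config_hash <- function(x) {
  raw <- serialize(x, connection = NULL, version = 2)
  v <- as.numeric(raw)
  w <- (seq_along(v) %% 251) + 1
  sprintf("%08x", as.integer(sum(v * w) %% 2147483647))
}

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# strip S3 classes recursively so nested spec objects serialise as plain
# JSON structures
unclass_deep <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_deep) else x
}

# (mean, sd) pair validator used by the distributional specs
check_pair <- function(x, name, positive_mean = FALSE) {
  if (!is.numeric(x) || length(x) != 2L || any(!is.finite(x)))
    stop(name, " must be a finite numeric (mean, sd) pair", call. = FALSE)
  if (x[2] < 0) stop(name, " sd must be >= 0", call. = FALSE)
  if (positive_mean && x[1] <= 0)
    stop(name, " mean must be > 0", call. = FALSE)
  c(mean = unname(x[1]), sd = unname(x[2]))
}
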