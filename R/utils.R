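#' @keywords internal
"_PACKAGE"

#' @importFrom stats approx kruskal.test p.adjust pchisq rlnorm rnorm sd
#'   uniroot wilcox.test aggregate
#' @importFrom utils packageVersion
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

## Evaluate `code` with a temporary RNG state seeded at `seed`,
## restoring the caller's .Random.seed afterwards.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

## Centered moving average; width coerced to the nearest odd sample count.
## Edges use a shrunken (one-sided truncated) window so the output has the
## same length as the input.
moving_average <- function(x, width) {
  width <- as.integer(width)
  if (width <= 1L) return(x)
  if (width %% 2L == 0L) width <- width + 1L
  half <- width %/% 2L
  cs <- cumsum(c(0, x))
  n <- length(x)
  i <- seq_len(n)
  lo <- pmax(i - half, 1L)
  hi <- pmin(i + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

## Central-difference derivative (one-sided at the ends), dt in seconds.
central_diff <- function(x, dt) {
  n <- length(x)
  if (n < 3L) stop("need at least 3 samples to differentiate", call. = FALSE)
  d <- numeric(n)
  d[2:(n - 1L)] <- (x[3:n] - x[1:(n - 2L)]) / (2 * dt)
  d[1L] <- (x[2L] - x[1L]) / dt
  d[n] <- (x[n] - x[n - 1L]) / dt
  d
}

stopifnot_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0) {
    stop(sprintf("`%s` must be a positive scalar", name), call. = FALSE)
  }
  invisible(x)
}

## Tiny polynomial rolling hash of a character vector; used to stamp CLI
## runs so a config + seed pair can be recognized later.
config_hash <- function(x) {
  bytes <- utf8ToInt(paste(x, collapse = "\n"))
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}
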