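# Internal helpers shared across modules.

# Run `expr` under a fixed RNG seed without disturbing the caller's stream.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Rounding half away from zero (base round() rounds half to even).
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# Contiguous runs of TRUE in a logical vector -> matrix [start, end] (inclusive).
true_runs <- function(flag) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  cbind(start = starts[keep], end = ends[keep])
}

# Trapezoidal integral of y over uniform/irregular grid x.
trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum((y[-1] + y[-n]) * diff(x)) / 2
}

# Inverse-CDF draw from a normal truncated to (lower, upper).
rtruncnorm1 <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  pl <- stats::pnorm(lower, mean, sd)
  pu <- stats::pnorm(upper, mean, sd)
  stats::qnorm(pl + stats::runif(n) * (pu - pl), mean, sd)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_input <- function(...) stop(..., call. = FALSE)

check_number <- function(x, name, lower = -Inf, strict = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_input(sprintf("`%s` must be a single finite number", name))
  }
  bad <- if (strict) x <= lower else x < lower
  if (bad) {
    stop_input(sprintf(
      "`%s` must be %s %s", name, if (strict) ">" else ">=", format(lower)
    ))
  }
  invisible(x)
}

CANALS <- c("HC", "AC", "PC")
SIDES <- c("left", "right")
GAIN_COLS <- c("gain_rhc", "gain_lhc", "gain_rac", "gain_lac", "gain_rpc", "gain_lpc")
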