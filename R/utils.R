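#' Centered rolling mean with truncated edges
#'
#' Rolling mean of width `window`, centered; near the edges the window is
#' truncated to the available support (so the output has no NA padding and
#' the same length as the input). `NA` values are dropped from each window.
#'
#' @param x numeric vector.
#' @param window integer window width in samples.
#' @return numeric vector, same length as `x`.
#' @keywords internal
rolling_mean <- function(x, window) {
  stopifnot(window >= 1L)
  n <- length(x)
  half_lo <- (window - 1L) %/% 2L
  half_hi <- window %/% 2L
  ok <- !is.na(x)
  xs <- cumsum(c(0, ifelse(ok, x, 0)))
  cs <- cumsum(c(0L, as.integer(ok)))
  lo <- pmax(seq_len(n) - half_lo, 1L)
  hi <- pmin(seq_len(n) + half_hi, n)
  tot <- xs[hi + 1L] - xs[lo]
  cnt <- cs[hi + 1L] - cs[lo]
  out <- tot / cnt
  out[cnt == 0L] <- NA_real_
  out
}

# run expr with a locally-scoped RNG state seeded by `seed`
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

assert_week <- function(x, arg = "week") {
  if (!is.numeric(x) || length(x) != MINUTES_PER_WEEK)
    stop(sprintf("`%s` must be a numeric vector of length %d (one week of minutes)",
                 arg, MINUTES_PER_WEEK), call. = FALSE)
  invisible(x)
}

assert_prob <- function(p, arg) {
  if (!is.numeric(p) || any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop(sprintf("`%s` must lie in [0, 1]", arg), call. = FALSE)
  invisible(p)
}

is_binary <- function(labels) {
  all(labels %in% c(0L, 1L, 0, 1, TRUE, FALSE))
}

as_label01 <- function(labels) {
  if (is.logical(labels)) return(as.integer(labels))
  if (!is_binary(labels)) stop("labels must be binary (0/1 or logical)", call. = FALSE)
  as.integer(labels)
}
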