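# Internal utilities shared across modules.

#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so seeded generators behave as pure functions of their inputs.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
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

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

clamp01 <- function(x) clamp(x, 0, 1)

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Separable Gaussian smoothing of a matrix
#'
#' Reflection padding at the borders keeps the smoothed field unbiased near
#' the edges (no darkening), which matters because the synthetic cover field
#' is rescaled from its empirical range.
#'
#' @param m numeric matrix.
#' @param sigma_px kernel standard deviation in pixels; `<= 0` is a no-op.
#' @keywords internal
gauss_blur <- function(m, sigma_px) {
  if (sigma_px <= 0) return(m)
  r <- max(1L, ceiling(3 * sigma_px))
  k <- stats::dnorm(seq(-r, r), sd = sigma_px)
  k <- k / sum(k)
  smooth1 <- function(v) {
    n <- length(v)
    # reflect: pad with mirrored samples so filter() has full support
    vp <- c(v[pmin(r:1, n)], v, v[pmax(n - seq_len(r) + 1L, 1L)])
    as.numeric(stats::filter(vp, k, sides = 2))[(r + 1L):(r + n)]
  }
  m1 <- apply(m, 2L, smooth1)
  t(apply(t(m1), 2L, smooth1))
}

#' Block mean of a matrix
#'
#' Averages non-overlapping `f x f` blocks; trailing rows/columns that do not
#' complete a block are dropped. `NA` propagates into the block mean.
#' @keywords internal
block_mean <- function(m, f) {
  f <- as.integer(f)
  stopifnot(f >= 1L)
  nr <- nrow(m) %/% f
  nc <- ncol(m) %/% f
  if (nr < 1L || nc < 1L) stop("matrix smaller than one block")
  m <- m[seq_len(nr * f), seq_len(nc * f), drop = FALSE]
  m2 <- matrix(colMeans(matrix(m, nrow = f)), nrow = nr)          # rows
  t(matrix(colMeans(matrix(t(m2), nrow = f)), nrow = nc))         # cols
}

stop_wfvc <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
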