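#' Wilson score interval for a binomial proportion
#'
#' @param x Number of successes (vectorised).
#' @param n Number of trials (vectorised, same length as `x` or length 1).
#' @param conf Confidence level, default 0.95.
#' @return A list with components `estimate`, `lower`, `upper`, `se`. Entries
#'   where `n == 0` are `NA`.
#' @examples
#' wilson_ci(7, 10)
#' @export
wilson_ci <- function(x, n, conf = 0.95) {
  stopifnot(length(conf) == 1L, conf > 0, conf < 1)
  z <- qnorm(1 - (1 - conf) / 2)
  n <- rep_len(n, length(x))
  p <- ifelse(n > 0, x / n, NA_real_)
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  half <- (z / denom) * sqrt(p * (1 - p) / n + z^2 / (4 * n^2))
  list(
    estimate = p,
    lower = pmax(0, centre - half),
    upper = pmin(1, centre + half),
    se = ifelse(n > 0, sqrt(pmax(p * (1 - p), 0) / n), NA_real_)
  )
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`; restores the
# caller's RNG state afterwards. seed = NULL leaves the RNG alone.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    abort("`seed` must be a single integer or NULL.", class = "fairaudit_error_config")
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Column-wise cumulative sums of a matrix without an R-level loop.
col_cumsum <- function(m) {
  if (!is.matrix(m)) m <- as.matrix(m)
  nr <- nrow(m)
  nc <- ncol(m)
  if (nr == 0L || nc == 0L) return(m)
  v <- cumsum(as.vector(m))
  out <- matrix(v, nrow = nr)
  if (nc > 1L) {
    offset <- c(0, out[nr, -nc])
    out <- out - rep(offset, each = nr)
  }
  out
}

# Count of values strictly below each cutoff. `sorted` must be ascending.
count_below <- function(sorted, cutoffs) {
  findInterval(cutoffs, sorted, left.open = TRUE)
}

# Deterministic sub-seed derivation: keeps everything below 2^31 - 1.
derive_seed <- function(root, i, j = 0L) {
  as.integer((as.double(root) + 7919 * i + 104729 * j) %% 2147483629 + 1)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
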