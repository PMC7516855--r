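# Run `expr` under a fixed RNG seed without touching global RNG state.
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Generate a fractal (fractional-Brownian) surface
#'
#' Spectral synthesis: Gaussian white noise is filtered in the Fourier
#' domain with a power-law amplitude `f^-(H + 1)` (power spectrum
#' `f^-(2H + 2)`), which yields a surface whose spatial autocorrelation
#' increases with the Hurst exponent `H`. The empirical variogram of the
#' result has log-log slope close to `2H` at small lags. This is the
#' neutral-landscape generator used throughout the package in place of any
#' external simulator.
#'
#' @param rows,cols grid size (>= 2 each).
#' @param hurst Hurst exponent H, strictly in (0, 1); lower H gives a
#'   rougher, less autocorrelated surface.
#' @param seed integer seed; the same seed always yields the same surface,
#'   and the global RNG state is left untouched.
#' @return A `rows` x `cols` numeric matrix.
#' @export
generate_fractal_surface <- function(rows, cols, hurst, seed) {
  if (rows < 2L || cols < 2L)
    stop("`rows` and `cols` must be >= 2", call. = FALSE)
  if (!is.finite(hurst) || hurst <= 0 || hurst >= 1)
    stop("`hurst` must lie strictly in (0, 1)", call. = FALSE)
  with_local_seed(seed, {
    noise <- matrix(stats::rnorm(rows * cols), rows, cols)
    fr <- fft_freq(rows)
    fc <- fft_freq(cols)
    f <- sqrt(outer(fr^2, fc^2, "+"))
    filt <- f^(-(hurst + 1))
    filt[1L, 1L] <- 0  # zero mean: drop the DC component
    z <- Re(stats::fft(stats::fft(noise) * filt, inverse = TRUE))
    z / (rows * cols)
  })
}

fft_freq <- function(n) {
  k <- seq_len(n) - 1L
  ifelse(k <= n %/% 2, k, k - n) / n
}

#' Classify a surface into classes of given proportions by rank
#'
#' Cells are ranked (ties broken by row-major scan order) and assigned so
#' that class `c` receives the rounded cumulative share of cells: every
#' class count is within one cell of `proportion * N`.
#'
#' @param surface numeric matrix; `NA` cells become nodata.
#' @param proportions nonnegative fractions summing to 1; class labels are
#'   `0..length(proportions) - 1` in increasing order of surface value.
#' @return A [categorical_raster()].
#' @export
classify_by_quantile <- function(surface, proportions) {
  stopifnot(is.matrix(surface))
  check_proportions(proportions)
  ok <- !is.na(surface)
  if (!any(ok))
    stop("empty input: all-nodata surface", call. = FALSE)
  # row-major vector so that order()'s stable tie-breaking is scan order
  vt <- as.vector(t(surface))
  okt <- !is.na(vt)
  lab_t <- rep(NA_integer_, length(vt))
  lab_t[okt] <- rank_classify(vt[okt], proportions)
  categorical_raster(matrix(lab_t, nrow(surface), ncol(surface), byrow = TRUE))
}

#' Simulate a neutral landscape mosaic
#'
#' Composes [generate_fractal_surface()] and [classify_by_quantile()]: a
#' Hurst-controlled fractal surface carved into classes of fixed
#' proportions, the standard neutral-landscape recipe for studying how
#' spatial aggregation affects pattern metrics.
#'
#' @param rows,cols grid size.
#' @param hurst Hurst exponent in (0, 1).
#' @param n_classes number of classes (ignored if `proportions` given).
#' @param proportions per-class fractions summing to 1; default equal.
#' @param seed integer seed.
#' @return A [categorical_raster()].
#' @examples
#' r <- simulate_landscape(32, 32, hurst = 0.6, n_classes = 6, seed = 1)
#' wdist(r, 4)
#' @export
simulate_landscape <- function(rows, cols, hurst, n_classes = 6,
                               proportions = NULL, seed = 1) {
  p <- proportions %||% rep.int(1 / n_classes, n_classes)
  surf <- generate_fractal_surface(rows, cols, hurst, seed)
  classify_by_quantile(surf, p)
}

#' Randomize the first k rows of a mosaic
#'
#' Permutes the cells of the first `k_rows` rows uniformly at random,
#' jointly across those rows (a cell may move to any position within the
#' randomized block). Remaining rows are untouched and the class
#' composition of the whole raster is exactly preserved. This emulates the
#' construction of progressively dissimilar copies of a seed image.
#'
#' @param raster a [categorical_raster()].
#' @param k_rows number of top rows to randomize, `0..nrow`.
#' @param seed integer seed.
#' @return A [categorical_raster()].
#' @export
randomize_rows <- function(raster, k_rows, seed) {
  stopifnot(inherits(raster, "categorical_raster"))
  nr <- nrow(raster$values)
  if (k_rows < 0L || k_rows > nr)
    stop("`k_rows` must be between 0 and ", nr, call. = FALSE)
  if (k_rows == 0L) return(raster)
  v <- raster$values
  block <- v[seq_len(k_rows), , drop = FALSE]
  shuffled <- with_local_seed(seed, sample(as.vector(block)))
  v[seq_len(k_rows), ] <- matrix(shuffled, k_rows, ncol(v))
  categorical_raster(v)
}

#' Deterministic test mosaics
#'
#' Small canonical patterns: `"checkerboard"` alternates two classes by
#' cell parity, `"stripes"` alternates two classes by row, `"uniform"` is
#' a single class, `"all_distinct"` gives every cell its own class.
#'
#' @param name one of `"checkerboard"`, `"stripes"`, `"uniform"`,
#'   `"all_distinct"`.
#' @param rows,cols grid size (>= 1 each).
#' @return A [categorical_raster()].
#' @export
make_fixture <- function(name = c("checkerboard", "stripes", "uniform",
                                  "all_distinct"),
                         rows, cols) {
  name <- match.arg(name)
  stopifnot(rows >= 1L, cols >= 1L)
  m <- switch(name,
    checkerboard = outer(seq_len(rows), seq_len(cols),
                         function(i, j) (i + j) %% 2L),
    stripes = matrix(rep(seq_len(rows) %% 2L, cols), rows, cols),
    uniform = matrix(0L, rows, cols),
    all_distinct = matrix(seq_len(rows * cols), rows, cols))
  categorical_raster(matrix(as.integer(m), rows, cols))
}
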