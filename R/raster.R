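#' Categorical raster (landscape mosaic)
#'
#' Constructs the basic container for a landscape mosaic: a rectangular grid
#' of integer class labels, with optional nodata cells. Nodata cells are
#' stored as `NA` and are excluded from the cell count `N`, from all class
#' counts, and from connected components (a patch never spans a nodata cell).
#'
#' @param values integer matrix of class labels; `NA` marks nodata.
#' @param nodata optional label; cells equal to it are converted to `NA`.
#' @return An object of class `categorical_raster`: a list with `values`
#'   (integer matrix, `NA` = nodata) and `n_valid` (number of non-nodata
#'   cells, the `N` of all entropy formulas).
#' @examples
#' r <- categorical_raster(matrix(c(1L, 1L, 2L, 2L), 2, byrow = TRUE))
#' r$n_valid
#' @export
categorical_raster <- function(values, nodata = NULL) {
  if (!is.matrix(values))
    stop("`values` must be a matrix", call. = FALSE)
  if (nrow(values) < 1L || ncol(values) < 1L)
    stop("raster must have at least one row and one column", call. = FALSE)
  if (is.double(values)) {
    if (any(is.finite(values) & values != round(values)))
      stop("class labels must be integers", call. = FALSE)
    storage.mode(values) <- "integer"
  }
  if (!is.integer(values))
    stop("`values` must contain integer class labels", call. = FALSE)
  if (!is.null(nodata))
    values[values == as.integer(nodata)] <- NA_integer_
  n_valid <- sum(!is.na(values))
  if (n_valid < 1L)
    stop("raster contains no valid (non-nodata) cells", call. = FALSE)
  structure(list(values = values, n_valid = n_valid),
            class = "categorical_raster")
}

#' @export
print.categorical_raster <- function(x, ...) {
  v <- x$values
  cat(sprintf("<categorical_raster> %d x %d, N = %d valid cells, %d classes\n",
              nrow(v), ncol(v), x$n_valid,
              length(unique(v[!is.na(v)]))))
  invisible(x)
}

#' @export
dim.categorical_raster <- function(x) dim(x$values)

#' @export
as.matrix.categorical_raster <- function(x, ...) x$values

nodata_mask <- function(x) is.na(x$values)

#' Read a landscape mosaic from a whitespace-delimited text grid
#'
#' Each line of the file is one raster row (line 1 = top row); tokens are
#' integer class labels separated by whitespace.
#'
#' @param path path to the text file.
#' @param nodata optional integer label to treat as nodata.
#' @return A [categorical_raster()].
#' @export
read_text_grid <- function(path, nodata = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L)
    stop("empty input: no grid rows in ", path, call. = FALSE)
  toks <- strsplit(trimws(lines), "\\s+")
  widths <- lengths(toks)
  if (length(unique(widths)) != 1L)
    stop("ragged grid: rows have differing numbers of columns in ", path,
         call. = FALSE)
  flat <- unlist(toks, use.names = FALSE)
  vals <- suppressWarnings(as.integer(flat))
  bad <- is.na(vals) | (suppressWarnings(as.numeric(flat)) != vals)
  if (any(is.na(suppressWarnings(as.numeric(flat)))) || any(bad, na.rm = TRUE))
    stop("non-integer token in grid: ",
         flat[which(is.na(vals) | bad)[1L]], call. = FALSE)
  m <- matrix(vals, nrow = length(lines), ncol = widths[1L], byrow = TRUE)
  categorical_raster(m, nodata = nodata)
}

#' Write a landscape mosaic as a text grid
#'
#' Inverse of [read_text_grid()]: one line per row, labels separated by a
#' single space. Nodata cells are written as the given `nodata` label.
#'
#' @param x a [categorical_raster()].
#' @param path output path.
#' @param nodata label to write for nodata cells (required if any exist).
#' @export
write_text_grid <- function(x, path, nodata = NULL) {
  stopifnot(inherits(x, "categorical_raster"))
  v <- x$values
  if (anyNA(v)) {
    if (is.null(nodata))
      stop("raster has nodata cells; supply a `nodata` label to write",
           call. = FALSE)
    v[is.na(v)] <- as.integer(nodata)
  }
  writeLines(apply(v, 1L, paste, collapse = " "), path)
}

#' Read a grayscale image as a landscape mosaic
#'
#' Decodes a PNG, JPEG or TIFF image, converts it to a single 8-bit gray
#' channel, and treats each distinct gray level (0--255) as one class.
#' RGB images are converted to luminance with the Rec. 601 weights
#' (0.2989 R + 0.5870 G + 0.1140 B) before 8-bit rounding; an alpha channel,
#' if present, is ignored.
#'
#' @param path path to a `.png`, `.jpg`/`.jpeg`, or `.tif`/`.tiff` file.
#' @return A [categorical_raster()] with labels in 0..255 and no nodata.
#' @export
read_image_grayscale <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png  = png::readPNG(path),
    jpg  = ,
    jpeg = jpeg::readJPEG(path),
    tif  = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format '.", ext,
         "': use PNG, JPEG or TIFF", call. = FALSE))
  if (length(dim(img)) == 3L) {
    d <- dim(img)
    plane <- function(k) matrix(img[, , k], d[1L], d[2L])
    img <- if (d[3L] >= 3L) {
      0.2989 * plane(1L) + 0.5870 * plane(2L) + 0.1140 * plane(3L)
    } else {
      plane(1L)  # gray (+alpha) stored as planes
    }
  }
  g <- matrix(as.integer(round(img * 255)), nrow(img), ncol(img))
  g[g < 0L] <- 0L
  g[g > 255L] <- 255L
  categorical_raster(g)
}

#' Quantization rule for continuous surfaces
#'
#' Describes how a continuous raster (e.g. a DEM, where cell categories are
#' formed according to elevation) is carved into classes.
#'
#' @param mode one of `"distinct"` (one class per distinct value),
#'   `"equal"` (equal-width intervals over the data range), `"edges"`
#'   (explicit breakpoints), `"quantile"` (rank-based, equal or given
#'   proportions).
#' @param n_bins number of classes for `"equal"` / `"quantile"`.
#' @param edges strictly increasing breakpoints for `"edges"`; the interior
#'   edges delimit the bins, so the two outermost bins are unbounded and
#'   out-of-range values fall into them.
#' @param proportions optional per-class fractions for `"quantile"`
#'   (defaults to equal shares of `n_bins`).
#' @return An object of class `quantization_rule`.
#' @export
quantization_rule <- function(mode = c("distinct", "equal", "edges", "quantile"),
                              n_bins = NULL, edges = NULL,
                              proportions = NULL) {
  mode <- match.arg(mode)
  if (mode %in% c("equal", "quantile")) {
    if (mode == "quantile" && !is.null(proportions)) {
      check_proportions(proportions)
      n_bins <- length(proportions)
    }
    if (is.null(n_bins) || n_bins < 1L)
      stop("`n_bins` >= 1 required for mode '", mode, "'", call. = FALSE)
  }
  if (mode == "edges") {
    if (is.null(edges) || length(edges) < 2L || any(diff(edges) <= 0))
      stop("`edges` must be strictly increasing with length >= 2",
           call. = FALSE)
  }
  structure(list(mode = mode, n_bins = n_bins, edges = edges,
                 proportions = proportions),
            class = "quantization_rule")
}

check_proportions <- function(p) {
  if (any(p < 0) || abs(sum(p) - 1) > 1e-9)
    stop("proportions must be nonnegative and sum to 1", call. = FALSE)
  invisible(p)
}

#' Quantize a continuous surface into a categorical raster
#'
#' Bin labels are 0-based indices `0..n_bins - 1`. Intervals are half-open
#' `[lo, hi)` with the last bin closed, so a value equal to an interior edge
#' goes to the upper bin. `NA` cells in the surface become nodata.
#'
#' @param surface numeric matrix, finite where not `NA`.
#' @param rule a [quantization_rule()].
#' @return A [categorical_raster()].
#' @export
quantize <- function(surface, rule) {
  stopifnot(is.matrix(surface), inherits(rule, "quantization_rule"))
  ok <- !is.na(surface)
  if (!any(ok))
    stop("empty input: all-nodata surface", call. = FALSE)
  if (any(!is.finite(surface[ok])))
    stop("surface must be finite where not NA", call. = FALSE)
  v <- surface[ok]
  lab <- switch(rule$mode,
    distinct = match(v, sort(unique(v))) - 1L,
    equal = {
      rng <- range(v)
      if (rng[1L] == rng[2L]) {
        rep.int(0L, length(v))  # degenerate range: one class
      } else {
        edges <- seq(rng[1L], rng[2L], length.out = rule$n_bins + 1L)
        bin_by_interior_edges(v, edges[-c(1L, length(edges))])
      }
    },
    edges = bin_by_interior_edges(v, rule$edges[-c(1L, length(rule$edges))]),
    quantile = {
      p <- rule$proportions %||% rep.int(1 / rule$n_bins, rule$n_bins)
      rank_classify(v, p)
    })
  out <- matrix(NA_integer_, nrow(surface), ncol(surface))
  out[ok] <- lab
  categorical_raster(out)
}

# findInterval counts edges <= x, so x equal to an interior edge lands in
# the upper bin, as required.
bin_by_interior_edges <- function(v, interior) {
  as.integer(findInterval(v, interior))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Rank-based classification with ties broken by position (scan order of the
# vector passed in). Class c receives cells between the rounded cumulative
# proportion boundaries, so each class count is within 1 of p_c * N.
rank_classify <- function(v, proportions) {
  check_proportions(proportions)
  n <- length(v)
  bounds <- round(cumsum(proportions) * n)
  bounds[length(bounds)] <- n
  sizes <- diff(c(0, bounds))
  ord <- order(v)  # stable: ties keep original (scan) order
  lab <- integer(n)
  lab[ord] <- rep.int(seq_along(sizes) - 1L, sizes)
  lab
}

#' Write entropy results to CSV
#'
#' One row per result, in the order given, with header
#' `file,n,m,connectivity,wc,ws,wdist,s_absolute`. Floating-point columns
#' are written at 6 significant digits; reruns on identical input produce
#' byte-identical files.
#'
#' @param results list of `entropy_result` objects (see [wdist()]); each may
#'   carry a `file` attribute naming its source, otherwise the list name or
#'   an empty string is used.
#' @param path output path.
#' @export
write_results <- function(results, path) {
  header <- "file,n,m,connectivity,wc,ws,wdist,s_absolute"
  rows <- vapply(seq_along(results), function(i) {
    r <- results[[i]]
    stopifnot(inherits(r, "entropy_result"))
    fname <- attr(r, "file") %||% names(results)[i] %||% ""
    if (is.na(fname)) fname <- ""
    paste(fname, r$n, r$m, r$connectivity,
          formatC(r$wc, digits = 6, format = "g"),
          formatC(r$ws, digits = 6, format = "g"),
          formatC(r$wdist, digits = 6, format = "g"),
          formatC(r$s_absolute, digits = 6, format = "g"),
          sep = ",")
  }, character(1L))
  writeLines(c(header, rows), path)
}
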