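#' Batch entropy computation over many raster files
#'
#' Reads each input, computes the Wasserstein Boltzmann entropy at the
#' requested connectivities, and optionally writes a CSV (see
#' [write_results()]). Files are processed in parallel when `jobs > 1`
#' (one task per file, via forked workers), but the output is identical
#' for any worker count: results are re-assembled in input order, so
#' parallelism is purely a speedup, never a semantics change. A file that
#' fails to read or parse is recorded as an error and the remaining files
#' are still processed.
#'
#' @param inputs character vector of file paths.
#' @param connectivity `"4"`, `"8"` or `"both"` (default `"4"`, the
#'   traditional neighbor rule).
#' @param format `"text"`, `"image"`, or `"auto"` (dispatch on extension:
#'   `.txt`/`.asc` text, `.png`/`.jpg`/`.jpeg`/`.tif`/`.tiff` image).
#' @param nodata optional nodata label for text grids.
#' @param quantize_rule optional [quantization_rule()] applied to the cell
#'   values after reading (e.g. to bin a DEM stored as a text grid).
#' @param jobs worker count, >= 1.
#' @param output optional CSV path.
#' @return A list with `results` (flat list of `entropy_result`, one per
#'   (file, connectivity), input order) and `errors` (named character
#'   vector of per-file error messages, empty if all succeeded).
#' @export
run_batch <- function(inputs, connectivity = c("4", "8", "both"),
                      format = c("auto", "text", "image"),
                      nodata = NULL, quantize_rule = NULL,
                      jobs = 1L, output = NULL) {
  if (length(inputs) == 0L)
    stop("`inputs` must be nonempty", call. = FALSE)
  connectivity <- match.arg(as.character(connectivity[1L]),
                            c("4", "8", "both"))
  format <- match.arg(format)
  jobs <- max(1L, as.integer(jobs))
  conns <- if (connectivity == "both") c(4L, 8L) else as.integer(connectivity)

  one_file <- function(path) {
    tryCatch({
      r <- read_any(path, format, nodata, quantize_rule)
      res <- lapply(conns, function(k) {
        out <- wdist(r, k)
        attr(out, "file") <- path
        out
      })
      list(ok = TRUE, results = res)
    }, error = function(e) list(ok = FALSE, message = conditionMessage(e)))
  }

  per_file <- if (jobs > 1L) {
    parallel::mclapply(inputs, one_file, mc.cores = jobs)
  } else {
    lapply(inputs, one_file)
  }

  ok <- vapply(per_file, `[[`, logical(1L), "ok")
  errors <- vapply(per_file[!ok], `[[`, character(1L), "message")
  names(errors) <- inputs[!ok]
  for (p in names(errors))
    message("mosaicentropy: error in ", p, ": ", errors[[p]])
  results <- do.call(c, lapply(per_file[ok], `[[`, "results"))
  if (is.null(results)) results <- list()
  if (!is.null(output))
    write_results(results, output)
  invisible(list(results = results, errors = errors))
}

read_any <- function(path, format, nodata, quantize_rule) {
  if (!file.exists(path))
    stop("cannot open input file: ", path, call. = FALSE)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("png", "jpg", "jpeg", "tif", "tiff"))
      "image" else "text"
  }
  r <- switch(format,
    text  = read_text_grid(path, nodata = nodata),
    image = read_image_grayscale(path))
  if (!is.null(quantize_rule)) {
    surf <- r$values + 0  # labels reinterpreted as a continuous surface
    r <- quantize(surf, quantize_rule)
  }
  r
}
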