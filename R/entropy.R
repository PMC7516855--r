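#' Class composition of a mosaic
#'
#' Counts the cells of each class over the valid (non-nodata) part of the
#' raster: the `Ni` of the entropy formulas.
#'
#' @param raster a [categorical_raster()].
#' @return A list with `counts` (named integer vector, class label -> Ni),
#'   `m` (number of classes) and `n_total` (N).
#' @export
class_composition <- function(raster) {
  stopifnot(inherits(raster, "categorical_raster"))
  v <- raster$values[!is.na(raster$values)]
  counts <- table(v)
  structure(list(counts = stats::setNames(as.integer(counts), names(counts)),
                 m = length(counts),
                 n_total = raster$n_valid),
            class = "class_composition")
}

#' Patch (continuous-space) inventory of a mosaic
#'
#' For each class, the mosaic is binarized (that class against everything
#' else) and connected components are labeled under the requested neighbor
#' rule; the size `rij` of every component is recorded. Components never
#' span nodata cells. All classes are labeled in a single pass over the
#' same-class adjacency graph, which is equivalent to the per-class
#' binarize-and-label procedure because components of different classes can
#' never touch.
#'
#' @param raster a [categorical_raster()].
#' @param connectivity 4 (edge neighbors) or 8 (edges plus diagonals).
#' @return A list with `sizes` (list: class label -> integer vector of
#'   component sizes), `connectivity`, and `all_sizes` (the pooled multiset).
#' @export
component_inventory <- function(raster, connectivity = 4) {
  stopifnot(inherits(raster, "categorical_raster"))
  connectivity <- check_connectivity(connectivity)
  v <- raster$values
  nr <- nrow(v); nc <- ncol(v)
  idx <- matrix(seq_len(nr * nc), nr, nc)

  same_class_edges <- function(a, b) {
    a <- as.vector(a); b <- as.vector(b)
    keep <- !is.na(v[a]) & !is.na(v[b]) & v[a] == v[b]
    cbind(a[keep], b[keep])
  }
  el <- list()
  if (nc > 1L)  # horizontal
    el[[length(el) + 1L]] <- same_class_edges(idx[, -nc], idx[, -1L])
  if (nr > 1L)  # vertical
    el[[length(el) + 1L]] <- same_class_edges(idx[-nr, ], idx[-1L, ])
  if (connectivity == 8L && nr > 1L && nc > 1L) {
    el[[length(el) + 1L]] <- same_class_edges(idx[-nr, -nc], idx[-1L, -1L])
    el[[length(el) + 1L]] <- same_class_edges(idx[-1L, -nc], idx[-nr, -1L])
  }
  edges <- do.call(rbind, el)

  g <- igraph::make_empty_graph(n = nr * nc, directed = FALSE)
  if (!is.null(edges) && nrow(edges) > 0L)
    g <- igraph::add_edges(g, t(edges))
  comp <- igraph::components(g)

  valid <- which(!is.na(v))
  memb <- comp$membership[valid]
  sizes_all <- as.integer(table(memb))
  comp_class <- v[valid][!duplicated(memb)]
  first_ids <- unique(memb)
  # table() orders by membership id; align classes accordingly
  comp_class <- comp_class[match(sort(first_ids), first_ids)]

  by_class <- split(sizes_all, comp_class)
  structure(list(sizes = by_class,
                 all_sizes = sizes_all,
                 connectivity = connectivity),
            class = "component_inventory")
}

check_connectivity <- function(connectivity) {
  if (!length(connectivity) == 1L || !connectivity %in% c(4, 8))
    stop("`connectivity` must be 4 or 8", call. = FALSE)
  as.integer(connectivity)
}

#' Extended-logarithmic histogram of a size multiset
#'
#' Expands every `ln(s!)` into `ln 1 + ln 2 + ... + ln s` and counts, for
#' each bin `k`, how many terms `ln k` appear: `a_k` equals the number of
#' elements of `sizes` that are at least `k`.
#'
#' @param sizes positive integers (class counts Ni, or patch sizes rij).
#' @return A list of class `log_term_histogram` with `mass` (vector indexed
#'   by bin `k = 1..max(sizes)`) and `total_mass` (`sum(sizes)`).
#' @export
log_term_histogram <- function(sizes) {
  if (length(sizes) == 0L)
    stop("`sizes` must be a nonempty multiset", call. = FALSE)
  sizes <- as.integer(sizes)
  if (anyNA(sizes) || any(sizes < 1L))
    stop("all sizes must be integers >= 1", call. = FALSE)
  tab <- tabulate(sizes, nbins = max(sizes))
  mass <- rev(cumsum(rev(tab)))  # a_k = #{s >= k}
  structure(list(mass = mass, total_mass = sum(sizes)),
            class = "log_term_histogram")
}

#' Wasserstein cost of transport from the Dirac reference
#'
#' The Dirac reference puts all mass at bin `ln 1 = 0`, so the 1-D
#' Wasserstein cost to the extended-logarithmic distribution is just
#' transported mass times transported distance summed over bins:
#' `sum_k (a_k / total) * ln k`. The closed form is
#' `sum_s ln(s!) / total`; both routes must agree.
#'
#' @param hist a [log_term_histogram()].
#' @return Cost in nats.
#' @export
dirac_transport_cost <- function(hist) {
  stopifnot(inherits(hist, "log_term_histogram"))
  k <- seq_along(hist$mass)
  sum(hist$mass / hist$total_mass * log(k))
}

#' Theoretical maximum transport cost
#'
#' Cost of transporting the Dirac mass into the most uniform state
#' distribution: mass `1/N` on each bin `ln 1 .. ln N`, i.e.
#' `ln(N!) / N`, computed with log-gamma so no factorial is ever formed.
#'
#' @param n_total total cell count N (>= 2; for N = 1 the maximum cost is 0
#'   and normalization is undefined).
#' @return Cost in nats.
#' @export
max_transport_cost <- function(n_total) {
  if (n_total < 2)
    stop("degenerate input: n_total must be >= 2 (maximum cost is 0 for N = 1)",
         call. = FALSE)
  lgamma(n_total + 1) / n_total
}

#' Normalized transport cost of a size multiset
#'
#' The Wasserstein cost of the multiset's extended-logarithmic histogram
#' against the Dirac reference, divided by the theoretical maximum
#' [max_transport_cost()]. In closed form this is
#' `sum_s ln(s!) / ln(N!)`: 0 iff every size is 1, 1 iff the multiset is
#' the single block `{N}`.
#'
#' @param sizes positive integers summing to `n_total`.
#' @param n_total total cell count N (>= 2).
#' @return Unitless value in `[0, 1]`.
#' @export
normalized_cost <- function(sizes, n_total) {
  hist <- log_term_histogram(sizes)
  if (hist$total_mass != n_total)
    stop("mass mismatch: sum(sizes) = ", hist$total_mass,
         " but n_total = ", n_total, call. = FALSE)
  dirac_transport_cost(hist) / max_transport_cost(n_total)
}

#' Wasserstein metric-based Boltzmann entropy of a mosaic
#'
#' The central computation. `Wc` is the normalized transport cost of the
#' class-count multiset (composition); `Ws` is that of the patch-size
#' multiset under the chosen connectivity (configuration); the relative
#' entropy is `Wdist = (1 - Wc)(1 - Ws)`; `s_absolute` is the absolute
#' extended Boltzmann entropy of [absolute_entropy()]. Higher `Wdist`
#' means more disorder: a one-class, one-patch mosaic has `Wdist = 0`,
#' a mosaic in which every cell is its own class has `Wdist = 1`.
#'
#' @param raster a [categorical_raster()] with at least 2 valid cells.
#' @param connectivity 4 or 8.
#' @return An object of class `entropy_result`: a list with `n`, `m`,
#'   `connectivity`, `wc`, `ws`, `wdist` and `s_absolute` (nats).
#' @examples
#' r <- categorical_raster(matrix(c(1L, 1L, 2L, 2L), 2, byrow = TRUE))
#' wdist(r, connectivity = 4)
#' @export
wdist <- function(raster, connectivity = 4) {
  stopifnot(inherits(raster, "categorical_raster"))
  connectivity <- check_connectivity(connectivity)
  n <- raster$n_valid
  if (n < 2L)
    stop("degenerate input: N >= 2 required to normalize", call. = FALSE)
  comp <- class_composition(raster)
  inv <- component_inventory(raster, connectivity)
  wc <- normalized_cost(comp$counts, n)
  ws <- normalized_cost(inv$all_sizes, n)
  structure(list(n = n,
                 m = comp$m,
                 connectivity = connectivity,
                 wc = wc,
                 ws = ws,
                 wdist = (1 - wc) * (1 - ws),
                 s_absolute = absolute_entropy_parts(n, comp$counts,
                                                     inv$all_sizes)),
            class = "entropy_result")
}

#' Absolute extended Boltzmann entropy
#'
#' `S = ln N! - sum_i ln Ni! - sum_ij ln rij!` with `kB = 1`, where `Ni`
#' are the class counts and `rij` the patch sizes under the chosen
#' connectivity. Computed via log-gamma throughout, so no factorial
#' overflow can occur. The value can be negative (a one-class, one-patch
#' mosaic gives `-ln N!`); it is reported as defined, without clamping.
#'
#' @param raster a [categorical_raster()].
#' @param connectivity 4 or 8.
#' @return Entropy in nats.
#' @export
absolute_entropy <- function(raster, connectivity = 4) {
  stopifnot(inherits(raster, "categorical_raster"))
  connectivity <- check_connectivity(connectivity)
  comp <- class_composition(raster)
  inv <- component_inventory(raster, connectivity)
  absolute_entropy_parts(raster$n_valid, comp$counts, inv$all_sizes)
}

absolute_entropy_parts <- function(n, class_counts, patch_sizes) {
  lgamma(n + 1) - sum(lgamma(class_counts + 1)) - sum(lgamma(patch_sizes + 1))
}

#' Entropy under both connectivities
#'
#' Convenience wrapper computing [wdist()] at 4- and 8-neighbor
#' connectivity (class composition is counted once; it does not depend on
#' the neighbor rule).
#'
#' @param raster a [categorical_raster()].
#' @param connectivity `"4"`, `"8"` or `"both"`.
#' @return A list of `entropy_result` objects, one per connectivity.
#' @export
mosaic_entropy <- function(raster, connectivity = c("both", "4", "8")) {
  connectivity <- match.arg(as.character(connectivity[1L]),
                            c("both", "4", "8"))
  conns <- if (connectivity == "both") c(4L, 8L) else as.integer(connectivity)
  lapply(conns, function(k) wdist(raster, k))
}

#' @export
print.entropy_result <- function(x, digits = 6, ...) {
  cat(sprintf("Wasserstein Boltzmann entropy (%d-neighbor connectivity)\n",
              x$connectivity))
  cat(sprintf("  N = %d cells, m = %d classes\n", x$n, x$m))
  cat(sprintf("  Wc    = %.*g   (composition)\n", digits, x$wc))
  cat(sprintf("  Ws    = %.*g   (configuration)\n", digits, x$ws))
  cat(sprintf("  Wdist = %.*g   (relative entropy)\n", digits, x$wdist))
  cat(sprintf("  S     = %.*g nats (absolute)\n", digits, x$s_absolute))
  invisible(x)
}

#' @export
summary.entropy_result <- function(object, ...) {
  print(object, ...)
}

#' @export
as.data.frame.entropy_result <- function(x, ...) {
  data.frame(n = x$n, m = x$m, connectivity = x$connectivity,
             wc = x$wc, ws = x$ws, wdist = x$wdist,
             s_absolute = x$s_absolute)
}
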