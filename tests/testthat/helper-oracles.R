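# Independent oracles used across the test files. These deliberately avoid
# the code paths they check: exact digit-vector factorials instead of
# lgamma, stack-based flood fill instead of graph components.

# ln(n!) from the exact big-integer factorial, carried as a little-endian
# base-1e4 digit vector. The log is recovered from the leading digits plus
# the digit count, which is exact to ~15 significant figures.
exact_log_factorial <- function(n) {
  stopifnot(n >= 0)
  if (n <= 1) return(0)
  base <- 1e4
  d <- 1
  for (i in 2:n) {
    prod <- d * i
    carry <- 0
    for (j in seq_along(prod)) {
      t <- prod[j] + carry
      prod[j] <- t %% base
      carry <- t %/% base
    }
    while (carry > 0) {
      prod <- c(prod, carry %% base)
      carry <- carry %/% base
    }
    d <- prod
  }
  nd <- length(d)
  top <- 0
  for (j in nd:max(1L, nd - 4L))
    top <- top + d[j] * base^(j - nd)
  log(top) + (nd - 1) * log(base)
}

# Closed-form normalized cost: sum_s ln(s!) / ln(N!), via exact factorials
# when N is small enough, else via summed logs (still independent of
# lgamma and of the histogram route).
oracle_normalized_cost <- function(sizes, n_total, exact = FALSE) {
  lf <- if (exact) exact_log_factorial else function(n) sum(log(seq_len(n)))
  sum(vapply(sizes, lf, numeric(1))) / lf(n_total)
}

# Connected components by explicit flood fill; returns per-class size lists
# keyed by class label, scan order.
flood_components <- function(v, connectivity) {
  nr <- nrow(v); nc <- ncol(v)
  offs <- cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  if (connectivity == 8)
    offs <- rbind(offs, cbind(c(-1, -1, 1, 1), c(-1, 1, -1, 1)))
  seen <- matrix(FALSE, nr, nc)
  sizes <- list()
  for (r in seq_len(nr)) for (cc in seq_len(nc)) {
    if (seen[r, cc] || is.na(v[r, cc])) next
    cls <- v[r, cc]
    stack <- matrix(c(r, cc), ncol = 2)
    seen[r, cc] <- TRUE
    sz <- 0L
    while (nrow(stack) > 0L) {
      p <- stack[nrow(stack), ]
      stack <- stack[-nrow(stack), , drop = FALSE]
      sz <- sz + 1L
      for (k in seq_len(nrow(offs))) {
        qr <- p[1] + offs[k, 1]; qc <- p[2] + offs[k, 2]
        if (qr >= 1 && qr <= nr && qc >= 1 && qc <= nc &&
            !seen[qr, qc] && !is.na(v[qr, qc]) && v[qr, qc] == cls) {
          seen[qr, qc] <- TRUE
          stack <- rbind(stack, c(qr, qc))
        }
      }
    }
    key <- as.character(cls)
    sizes[[key]] <- c(sizes[[key]], sz)
  }
  sizes
}

# Random test mosaic: uniform class labels, optional nodata holes.
random_raster <- function(nr, nc, n_classes, p_nodata = 0) {
  v <- matrix(sample.int(n_classes, nr * nc, replace = TRUE), nr, nc)
  if (p_nodata > 0) {
    holes <- runif(nr * nc) < p_nodata
    if (all(holes)) holes[1] <- FALSE
    v[holes] <- NA_integer_
  }
  categorical_raster(v)
}
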