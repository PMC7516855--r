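two_block <- function() categorical_raster(matrix(c(1L, 1L, 2L, 2L), 2,
                                                  byrow = TRUE))

test_that("class_composition counts cells per class, excluding nodata", {
  cc <- class_composition(two_block())
  expect_equal(cc$counts, c("1" = 2L, "2" = 2L))
  expect_equal(cc$m, 2L)
  expect_equal(cc$n_total, 4L)

  cc <- class_composition(make_fixture("checkerboard", 4, 4))
  expect_equal(unname(cc$counts), c(8L, 8L))

  r <- categorical_raster(matrix(c(1L, NA, 1L, 2L), 2, byrow = TRUE))
  cc <- class_composition(r)
  expect_equal(cc$counts, c("1" = 2L, "2" = 1L))
  expect_equal(cc$n_total, 3L)
})

test_that("component labeling matches the flood-fill oracle", {
  inv <- component_inventory(two_block(), 4)
  expect_equal(lapply(inv$sizes, as.integer), list("1" = 2L, "2" = 2L))

  cb <- make_fixture("checkerboard", 4, 4)
  inv4 <- component_inventory(cb, 4)
  expect_length(inv4$all_sizes, 16L)     # isolated cells under 4-connectivity
  expect_true(all(inv4$all_sizes == 1L))
  inv8 <- component_inventory(cb, 8)
  expect_equal(sort(inv8$all_sizes), c(8L, 8L))  # diagonals join each color

  expect_error(component_inventory(cb, 6), "connectivity")

  withr::local_seed(101)
  for (i in 1:25) {
    r <- random_raster(sample(2:12, 1), sample(2:12, 1), sample(2:6, 1),
                       p_nodata = ifelse(i %% 5 == 0, 0.15, 0))
    for (conn in c(4, 8)) {
      got <- component_inventory(r, conn)$sizes
      want <- flood_components(r$values, conn)
      expect_equal(lapply(got, sort), lapply(want, sort)[names(got)])
    }
  }
})

test_that("extended-logarithmic histogram expands ln(s!) term by term", {
  h <- log_term_histogram(c(3, 2))
  expect_equal(h$mass, c(2, 2, 1))
  expect_equal(h$total_mass, 5)

  h <- log_term_histogram(c(1, 1, 1))
  expect_equal(h$mass, 3)
  expect_equal(h$total_mass, 3)

  h <- log_term_histogram(4)
  expect_equal(h$mass, rep(1, 4))

  expect_error(log_term_histogram(integer(0)), "nonempty")
  expect_error(log_term_histogram(c(2, 0)), ">= 1")
})

test_that("Dirac transport cost equals mean transported distance", {
  expect_equal(dirac_transport_cost(log_term_histogram(c(1, 1, 1))), 0)
  # (2 ln2 + ln3)/5, from exact factorials (ln3! + ln2!)/5
  expect_equal(dirac_transport_cost(log_term_histogram(c(3, 2))),
               0.4969813299576001, tolerance = 1e-12)
  expect_equal(dirac_transport_cost(log_term_histogram(4)),
               0.7945134575869864, tolerance = 1e-12)
})

test_that("maximum cost is ln(N!)/N and rejects degenerate N", {
  expect_equal(max_transport_cost(2), log(2) / 2)
  expect_equal(max_transport_cost(4), log(24) / 4)
  expect_error(max_transport_cost(1), "degenerate")
})

test_that("normalized cost hits its closed form and its extremes", {
  expect_equal(normalized_cost(4, 4), 1)
  expect_equal(normalized_cost(c(1, 1, 1, 1), 4), 0)
  expect_equal(normalized_cost(c(2, 2), 4), 2 * log(2) / log(24),
               tolerance = 1e-12)
  expect_error(normalized_cost(c(2, 2), 5), "mass mismatch")
})

test_that("wdist reproduces the exact worked examples", {
  res <- wdist(two_block(), 4)
  # oracle: Wc = Ws = 2 ln2 / ln24, Wdist = (1 - Wc)^2
  expect_equal(res$wc, 0.4362085839710631, tolerance = 1e-12)
  expect_equal(res$ws, res$wc, tolerance = 1e-12)
  expect_equal(res$wdist, 0.3178607607879138, tolerance = 1e-12)
  expect_equal(res$s_absolute, log(24 / 16), tolerance = 1e-12)

  u <- make_fixture("uniform", 3, 4)
  res <- wdist(u, 4)
  expect_equal(res$wc, 1)
  expect_equal(res$ws, 1)
  expect_equal(res$wdist, 0)

  ad <- make_fixture("all_distinct", 2, 2)
  res <- wdist(ad, 4)
  expect_equal(res$wc, 0)
  expect_equal(res$ws, 0)
  expect_equal(res$wdist, 1)
  expect_equal(res$s_absolute, log(24), tolerance = 1e-12)

  expect_error(wdist(categorical_raster(matrix(1L)), 4), "degenerate")
})

test_that("absolute entropy matches the exact-factorial oracle for small N", {
  expect_equal(absolute_entropy(two_block(), 4), log(24 / 16),
               tolerance = 1e-12)
  expect_equal(absolute_entropy(make_fixture("uniform", 2, 2), 4),
               -log(24), tolerance = 1e-12)

  withr::local_seed(5)
  for (i in 1:20) {
    r <- random_raster(sample(2:4, 1), sample(2:5, 1), sample(2:4, 1))
    n <- r$n_valid
    cc <- class_composition(r)
    for (conn in c(4, 8)) {
      sizes <- component_inventory(r, conn)$all_sizes
      want <- exact_log_factorial(n) -
        sum(vapply(cc$counts, exact_log_factorial, numeric(1))) -
        sum(vapply(sizes, exact_log_factorial, numeric(1)))
      expect_equal(absolute_entropy(r, conn), want, tolerance = 1e-9)
    }
  }
  # all-distinct raster: S = ln N! exactly
  for (n in c(4L, 9L, 16L)) {
    r <- make_fixture("all_distinct", floor(sqrt(n)), floor(sqrt(n)))
    expect_equal(absolute_entropy(r, 4), exact_log_factorial(r$n_valid),
                 tolerance = 1e-9)
  }
})

test_that("histogram route and closed form agree on random mosaics", {
  withr::local_seed(2024)
  for (i in 1:40) {
    r <- random_raster(sample(2:12, 1), sample(2:12, 1), sample(2:6, 1))
    n <- r$n_valid
    cc <- class_composition(r)
    expect_equal(wdist(r, 4)$wc, oracle_normalized_cost(cc$counts, n),
                 tolerance = 1e-10)
    for (conn in c(4, 8)) {
      sizes <- component_inventory(r, conn)$all_sizes
      expect_equal(wdist(r, conn)$ws, oracle_normalized_cost(sizes, n),
                   tolerance = 1e-10)
    }
  }
})

test_that("structural invariants hold on random mosaics", {
  withr::local_seed(99)
  for (i in 1:30) {
    r <- random_raster(sample(2:12, 1), sample(2:12, 1), sample(2:6, 1))
    n <- r$n_valid
    res4 <- wdist(r, 4); res8 <- wdist(r, 8)

    # mass conservation: classes and components both partition the cells
    expect_equal(log_term_histogram(class_composition(r)$counts)$total_mass, n)
    expect_equal(log_term_histogram(component_inventory(r, 4)$all_sizes)$total_mass,
                 n)

    # bounds and the Wdist identity
    for (res in list(res4, res8)) {
      expect_true(res$wc >= 0 && res$wc <= 1)
      expect_true(res$ws >= 0 && res$ws <= 1)
      expect_true(res$wdist >= 0 && res$wdist <= 1)
      expect_equal(res$wdist, (1 - res$wc) * (1 - res$ws), tolerance = 1e-12)
    }

    # merging components under 8-connectivity never lowers Ws
    expect_true(res8$ws >= res4$ws - 1e-12)
    expect_true(res8$wdist <= res4$wdist + 1e-12)

    # relabeling classes changes nothing
    labs <- unique(as.vector(r$values))
    perm <- sample(labs)
    v2 <- matrix(perm[match(r$values, labs)], nrow(r$values))
    res4b <- wdist(categorical_raster(v2), 4)
    expect_equal(res4b$wc, res4$wc, tolerance = 1e-12)
    expect_equal(res4b$ws, res4$ws, tolerance = 1e-12)
    expect_equal(res4b$s_absolute, res4$s_absolute, tolerance = 1e-9)

    # spatial rearrangement leaves Wc (composition) unchanged
    v3 <- matrix(sample(as.vector(r$values)), nrow(r$values))
    expect_equal(wdist(categorical_raster(v3), 4)$wc, res4$wc,
                 tolerance = 1e-12)
  }
})

test_that("mosaic_entropy at 'both' returns one result per connectivity", {
  res <- mosaic_entropy(two_block(), "both")
  expect_length(res, 2L)
  expect_equal(vapply(res, `[[`, integer(1), "connectivity"), c(4L, 8L))
  df <- do.call(rbind, lapply(res, as.data.frame))
  expect_equal(df$n, c(4L, 4L))
  expect_output(print(res[[1]]), "Wdist")
})
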