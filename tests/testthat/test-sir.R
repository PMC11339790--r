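# The spatial-information-retained rearrangement and multi-scale extractor.

test_that("spatial_split tiles the map exactly once, in row-major order", {
  set.seed(21)
  x <- array(rnorm(16 * 16 * 3 * 2), dim = c(16, 16, 3, 2))
  g <- spatial_split(x, 2, 2)
  expect_equal(length(g$chunks), 64L)                 # k at the /4 scale
  expect_equal(dim(g$chunks[[1]]), c(2L, 2L, 3L, 2L))
  # element multiset conserved
  expect_equal(sort(unlist(g$chunks)), sort(as.vector(x)))

  # coordinate-tagging oracle: fill the map with its own (row, col) codes and
  # verify each chunk holds the expected tile in row-major order
  coord <- array(0, dim = c(8, 8, 1, 1))
  for (r in 1:8) for (c2 in 1:8) coord[r, c2, 1, 1] <- 100 * r + c2
  gc2 <- spatial_split(coord, 4, 4)
  expect_equal(length(gc2$chunks), 4L)
  # chunk 2 is rows 1-4, cols 5-8 (m outer, n inner)
  expect_equal(gc2$chunks[[2]][, , 1, 1], coord[1:4, 5:8, 1, 1])
  expect_equal(gc2$chunks[[3]][, , 1, 1], coord[5:8, 1:4, 1, 1])

  # non-divisible sizes are a shape error; target == size is the identity
  expect_error(spatial_split(x, 3, 3), "not divisible")
  one <- spatial_split(x, 16, 16)
  expect_equal(length(one$chunks), 1L)
  expect_identical(one$chunks[[1]], x)
})

test_that("chunk_concat stacks channel blocks in declared order; inverse is exact", {
  set.seed(22)
  x <- array(rnorm(12 * 12 * 5 * 2), dim = c(12, 12, 5, 2))
  g <- spatial_split(x, 4, 4)
  y <- chunk_concat(g)
  expect_equal(dim(y), c(4L, 4L, 5L * 9L, 2L))
  # block j equals chunk j, checked against an explicit double-loop oracle
  for (j in c(1, 5, 9)) {
    m <- (j - 1) %/% 3 + 1
    n <- (j - 1) %% 3 + 1
    oracle <- x[((m - 1) * 4 + 1):(m * 4), ((n - 1) * 4 + 1):(n * 4), , ,
                drop = FALSE]
    expect_identical(y[, , ((j - 1) * 5 + 1):(j * 5), , drop = FALSE], oracle)
  }
  # bit-exact reconstruction
  expect_identical(chunk_unsplit(y, g$grid_rows, g$grid_cols), x)
  # single-chunk grid concatenates to the chunk itself
  g1 <- spatial_split(x, 12, 12)
  expect_identical(chunk_concat(g1), x)
})

test_that("element counts are conserved through the rearrangement", {
  for (side in c(32L, 64L, 128L)) {
    x <- array(seq_len(side^2 * 4), dim = c(side, side, 4L, 1L))
    y <- ns$sir_rearrange(x, side %/% 8L, side %/% 8L)
    expect_equal(prod(dim(y)), prod(dim(x)))
    expect_equal(sort(as.vector(y)), sort(as.vector(x)))
  }
})

test_that("chunk count is 64/16/4 per scale for any side divisible by 32", {
  m <- build_variant("BL+SpatialAtt+MS", tiny_config(), seed = 31)
  for (side in c(64L, 128L)) {
    st <- extract_multiscale(m, random_batch(side, 1))
    d4 <- dim(st$s4)
    ks <- vapply(1:3, function(i) {
      di <- dim(st[[i]])
      length(spatial_split(st[[i]], d4[1], d4[2])$chunks)
    }, numeric(1))
    expect_equal(ks, c(64, 16, 4))
  }
})

test_that("backbone stage contracts hold on a reduced model", {
  cfg <- tiny_config()
  m <- build_variant("BL", cfg, seed = 32)
  st <- extract_multiscale(m, random_batch(128, 3))
  sides <- vapply(st, function(s) dim(s)[1], numeric(1))
  expect_equal(unname(sides), 128 / c(4, 8, 16, 32))
  chans <- vapply(st, function(s) dim(s)[3], numeric(1))
  expect_equal(unname(chans), 4 * cfg$width * 2^(0:3))
  expect_equal(unname(vapply(st, function(s) dim(s)[4], numeric(1))), rep(3, 4))
  expect_error(extract_multiscale(m, random_batch(60, 1)), "divisible by 32")
})

test_that("channel rescale emits the configured widths, nonnegative, same grid", {
  m <- build_variant("BL+SpatialAtt+MS", tiny_config(), seed = 33)
  st <- extract_multiscale(m, random_batch(64, 2))
  for (i in 1:3) {
    r <- ns$nn_forward(m$sir$rescale[[i]], st[[i]], FALSE)
    expect_equal(dim(r)[3], tiny_config()$o_channels[i])
    expect_equal(dim(r)[c(1, 2, 4)], dim(st[[i]])[c(1, 2, 4)])
    expect_gte(min(r), 0)
  }
})

test_that("vectorized extractor equals the naive-loop reference", {
  m <- build_variant("BL+SpatialAtt+MS", tiny_config(), seed = 34)
  x <- random_batch(64, 2, seed = 35)
  fast <- sir_extract(m, x)
  slow <- ns$sir_extract_reference(m$backbone, m$sir, x)
  expect_equal(dim(fast), dim(slow))
  expect_lt(max(abs(fast - slow)), 1e-10)
})

test_that("sir_extract is deterministic in eval mode and batch-consistent", {
  m <- build_variant("BL+SelfAtt+MS", tiny_config(), seed = 36)
  x <- random_batch(64, 3, seed = 37)
  f1 <- sir_extract(m, x)
  f2 <- sir_extract(m, x)
  expect_identical(f1, f2)
  expect_equal(dim(f1)[4], 3L)
  # single image vs packed in a batch
  single <- sir_extract(m, x[, , , 1, drop = FALSE])
  expect_equal(single[, , , 1], f1[, , , 1], tolerance = 1e-12)
  # non-MS variants refuse
  bl <- build_variant("BL", tiny_config(), seed = 38)
  expect_error(sir_extract(bl, x), "no multi-scale extractor")
})
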