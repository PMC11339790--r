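# Attention modules, mask gating, aggregation head, loss, and variant wiring.

test_that("spatial attention yields a [0,1] single-channel map on the input grid", {
  set.seed(41)
  att <- ns$spatial_attention_new(8, widths = c(8L, 4L))
  x <- array(rnorm(6 * 6 * 8 * 2), dim = c(6, 6, 8, 2))
  a <- ns$nn_forward(att, x, FALSE)
  expect_equal(dim(a), c(6L, 6L, 1L, 2L))
  expect_true(all(a >= 0 & a <= 1))
  # weighting by an all-ones map is the identity
  ones <- array(1, dim = c(6, 6, 1, 2))
  expect_identical(x * ones[, , rep(1, 8), ], x)
})

test_that("uniform self-attention with identity value averages over positions", {
  set.seed(42)
  sa <- ns$self_attention_new(5)
  sa$uniform_attention <- TRUE
  sa$identity_value <- TRUE
  sa$use_residual <- FALSE
  x <- array(rnorm(4 * 4 * 5 * 2), dim = c(4, 4, 5, 2))
  out <- ns$nn_forward(sa, x, FALSE)
  for (n in 1:2) {
    mu <- colMeans(matrix(x[, , , n], nrow = 16))   # closed-form spatial mean
    for (ch in 1:5) {
      expect_equal(as.vector(out[, , ch, n]), rep(mu[ch], 16), tolerance = 1e-12)
    }
  }
})

test_that("self-attention is permutation-equivariant over spatial positions", {
  set.seed(43)
  sa <- ns$self_attention_new(6)
  x <- array(rnorm(3 * 3 * 6 * 1), dim = c(3, 3, 6, 1))
  out <- ns$nn_forward(sa, x, FALSE)
  P <- 9
  perm <- sample(P)
  Xp <- matrix(x[, , , 1], nrow = P)[perm, ]
  xp <- array(array(Xp, dim = c(3, 3, 6)), dim = c(3, 3, 6, 1))
  outp <- ns$nn_forward(sa, xp, FALSE)
  expect_equal(matrix(outp[, , , 1], nrow = P),
               matrix(out[, , , 1], nrow = P)[perm, ], tolerance = 1e-10)
  expect_equal(dim(out), dim(x))
})

test_that("apply_mask gates features elementwise after downsampling", {
  set.seed(44)
  feat <- array(rnorm(4 * 4 * 3 * 2), dim = c(4, 4, 3, 2))
  ones <- matrix(1, 16, 16)
  expect_identical(apply_mask(feat, ones), feat)
  zeros <- matrix(0, 16, 16)
  expect_true(all(apply_mask(feat, zeros) == 0))
  # half-plane mask: rows 1-8 on, 9-16 off -> feature rows 1-2 kept
  half <- rbind(matrix(1, 8, 16), matrix(0, 8, 16))
  gated <- apply_mask(feat, half)
  expect_identical(gated[1:2, , , ], feat[1:2, , , ])
  expect_true(all(gated[3:4, , , ] == 0))
  expect_error(apply_mask(feat, matrix(1, 15, 15)), "not reducible")
})

test_that("aggregation head: GAP of a constant feature is that constant", {
  set.seed(45)
  h <- ns$head_new(3, hidden = 4L)
  g <- ns$gap_new()
  const <- array(rep(c(1.5, -2, 0.25), each = 25), dim = c(5, 5, 3, 1))
  pooled <- ns$nn_forward(g, const, FALSE)
  expect_equal(as.vector(pooled), c(1.5, -2, 0.25))
  # one scalar logit per sample, probability strictly inside (0,1)
  x <- array(rnorm(5 * 5 * 3 * 4), dim = c(5, 5, 3, 4))
  logit <- ns$nn_forward(h, x, FALSE)
  expect_length(logit, 4L)
  p <- 1 / (1 + exp(-logit))
  expect_true(all(p > 0 & p < 1))
})

test_that("binary cross-entropy matches its closed forms and a loop oracle", {
  expect_equal(bce_loss(0, 1), log(2), tolerance = 1e-12)
  expect_equal(bce_loss(0, 0), log(2), tolerance = 1e-12)
  expect_lt(bce_loss(20, 1), 1e-8)
  expect_error(bce_loss(c(1, 2), c(0, 2)), "binary")
  set.seed(46)
  z <- rnorm(50, sd = 3)
  q <- rbinom(50, 1, 0.5)
  p <- 1 / (1 + exp(-z))
  oracle <- mean(-(q * log(p) + (1 - q) * log(1 - p)))
  expect_equal(bce_loss(z, q), oracle, tolerance = 1e-10)
  # gradient consistent with finite differences
  gnum <- vapply(seq_along(z), function(i) {
    zp <- z; zp[i] <- zp[i] + 1e-6
    zm <- z; zm[i] <- zm[i] - 1e-6
    (bce_loss(zp, q) - bce_loss(zm, q)) / 2e-6
  }, numeric(1))
  expect_equal(as.vector(ns$bce_grad(z, q)), gnum, tolerance = 1e-6)
})

test_that("all five variants construct; unknown names fail with the valid list", {
  for (v in MODEL_VARIANTS) {
    m <- build_variant(v, tiny_config(), seed = 47)
    expect_s3_class(m, "iqa_model")
    expect_equal(m$variant, v)
  }
  expect_error(build_variant("BL+FooAtt", tiny_config()), "valid variants")
  # multi-scale attention variant has strictly more parameters than the baseline
  expect_gt(n_parameters(build_variant("BL+SpatialAtt+MS", tiny_config(), seed = 1)),
            n_parameters(build_variant("BL", tiny_config(), seed = 1)))
})

test_that("wired multi-scale model equals the step-by-step composition", {
  m <- build_variant("BL+SpatialAtt+MS", tiny_config(), seed = 48)
  x <- random_batch(64, 2, seed = 49)
  wired <- ns$model_forward(m, x, training = FALSE)
  f <- sir_extract(m, x)
  a <- ns$nn_forward(m$att, f, FALSE)
  gated <- f * a[, , rep(1L, dim(f)[3]), , drop = FALSE]
  logit <- ns$nn_forward(m$head, gated, FALSE)
  expect_equal(wired$logit, logit, tolerance = 1e-12)

  msa <- build_variant("BL+SelfAtt+MS", tiny_config(), seed = 50)
  wired2 <- ns$model_forward(msa, x, training = FALSE)
  f2 <- sir_extract(msa, x)
  gated2 <- f2 * ns$nn_forward(msa$att, f2, FALSE)
  expect_equal(wired2$logit, ns$nn_forward(msa$head, gated2, FALSE),
               tolerance = 1e-12)
})

test_that("all variants share the input contract and score contract", {
  x <- random_batch(64, 2, seed = 51)
  masks <- array(1L, dim = c(64, 64, 2))
  for (v in MODEL_VARIANTS) {
    m <- build_variant(v, tiny_config(), seed = 52)
    pred <- predict_quality(m, x, masks = masks)
    expect_equal(nrow(pred), 2L)
    expect_true(all(pred$probability > 0 & pred$probability < 1))
    expect_true(all(pred$label %in% c(0L, 1L)))
    expect_equal(pred$label, as.integer(pred$probability > 0.5))
  }
  # BL+MASK requires masks
  expect_error(predict_quality(build_variant("BL+MASK", tiny_config(), seed = 1), x),
               "requires eye-area masks")
})
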