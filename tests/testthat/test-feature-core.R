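# Preprocessing, frozen feature cores, and the batch-normalizing head.

test_that("crop sizes follow the degrees-times-resolution rule", {
  # 420 px at 63 px/deg: the central 2.65 deg is a 167 px crop
  expect_identical(preprocess_spec(2.65, 63, 14)$crop_px, 167)
  # 12 deg at 14 px/deg is 168 px
  expect_identical(preprocess_spec(12, 14, 14)$crop_px, 168)
  expect_error(preprocess_image(matrix(0, 32, 32), preprocess_spec(10, 10, 10)),
               "does not fit")
})

test_that("full-frame crop at the source resolution is the identity", {
  img <- matrix(runif(32 * 32, 0, 255), 32)
  spec <- preprocess_spec(3.2, 10, 10)
  expect_identical(spec$crop_px, 32)
  expect_equal(preprocess_image(img, spec), img)
})

test_that("doubling the target resolution doubles the output side", {
  img <- sim_images(1, size = 64, seed = 2)$images
  s1 <- preprocess_spec(4, 16, 8)
  s2 <- preprocess_spec(4, 16, 16)
  o1 <- preprocess_image(img, s1)
  o2 <- preprocess_image(img, s2)
  expect_lte(abs(dim(o2)[2] - 2 * dim(o1)[2]), 1)
  # bilinear path works too
  o3 <- preprocess_image(img, preprocess_spec(4, 16, 8, "bilinear"))
  expect_identical(dim(o3), dim(o1))
})

test_that("gabor bank is zero on constant input and orientation selective", {
  core <- fix_core_cardinal()
  flat <- core_features(core, array(128, c(1, 32, 32)))
  expect_lt(max(abs(flat)), 1e-9)

  # a full-field grating at a channel's orientation/frequency/phase drives
  # that channel hardest among channels sharing frequency and phase
  sz <- 48
  xy <- seq_len(sz)
  full <- gabor_core(orientations = 4, frequencies = 0.15, phases = 0)
  for (k in c(1, 3)) {
    th <- full$params$theta[k]
    u <- outer(rep(1, sz), xy) * cos(th) + outer(xy, rep(1, sz)) * sin(th)
    grat <- 128 + 100 * cos(2 * pi * 0.15 * u)
    f <- core_features(full, array(grat, c(1, sz, sz)))
    resp <- apply(abs(f[1, , , ]), 3, mean)
    expect_identical(which.max(resp), as.integer(k))
  }
})

test_that("cores are frozen and deterministic", {
  imgs <- sim_images(2, size = 32, seed = 5)
  g <- core_features(fix_core_cardinal(), imgs)
  expect_identical(g, core_features(fix_core_cardinal(), imgs))

  rc1 <- random_convnet_core(seed = 11)
  rc2 <- random_convnet_core(seed = 11)
  expect_identical(core_features(rc1, imgs), core_features(rc2, imgs))
  expect_false(identical(core_features(rc1, imgs),
                         core_features(random_convnet_core(seed = 12), imgs)))
  expect_true(all(core_features(rc1, imgs) >= 0))
  expect_error(core_features(structure(list(), class = "feature_core"), imgs),
               "unknown feature core")
})

test_that("custom core adapter validates the declared channel count", {
  fwd <- function(arr) array(1, c(dim(arr)[1], 4, 4, 3))
  cc <- custom_core(fwd, channels = 3, id = "toy")
  expect_identical(dim(core_features(cc, sim_images(2, 32, seed = 1)))[4], 3L)
  bad <- custom_core(fwd, channels = 5)
  expect_error(core_features(bad, sim_images(2, 32, seed = 1)))
})

test_that("feature head follows the normalize-scale-shift-rectify form", {
  # eval mode with unit running stats: a deterministic affine map + relu
  h <- feature_head(1, eps = 0)
  x <- array(c(-2, 0, 1), c(3, 1, 1, 1))
  out <- feature_head_forward(x, h, "eval")
  expect_equal(drop(out$phi), c(0, 0, 1))           # gamma 1, beta 0: relu(x)
  h$gamma <- 2; h$beta <- 1
  out2 <- feature_head_forward(x, h, "eval")
  expect_equal(drop(out2$phi)[3], 3)                # 2 * 1 + 1
  expect_equal(drop(out2$phi)[1], 0)                # 2 * (-2) + 1 rectified
  # eval mode mutates nothing
  expect_identical(out2$head, h)
})

test_that("train mode blends running statistics like a two-pass oracle", {
  set.seed(4)
  h <- feature_head(2, momentum = 0.1)
  x1 <- array(rnorm(40 * 2, mean = 3, sd = 2), c(40, 1, 1, 2))
  x2 <- array(rnorm(40 * 2, mean = 3, sd = 2), c(40, 1, 1, 2))
  out <- feature_head_forward(x1, h, "train")
  out <- feature_head_forward(x2, out$head, "train")

  # independent two-pass oracle for the blended statistics
  m <- 0.1
  rm_ <- c(0, 0); rv <- c(1, 1)
  for (x in list(x1, x2)) {
    M <- matrix(x, ncol = 2)
    bm <- colMeans(M)
    bv <- apply(M, 2, function(v) mean((v - mean(v))^2))
    rm_ <- (1 - m) * rm_ + m * bm
    rv <- (1 - m) * rv + m * bv * nrow(M) / (nrow(M) - 1)
  }
  expect_equal(out$head$running_mean, rm_, tolerance = 1e-12)
  expect_equal(out$head$running_var, rv, tolerance = 1e-12)

  # train-mode normalization: batch statistics give mean 0 / var 1 per
  # channel before rectification
  pre <- matrix(out$pre, ncol = 2)
  xh <- matrix(out$xhat, ncol = 2)
  expect_equal(colMeans(xh), c(0, 0), tolerance = 1e-10)
  expect_equal(apply(xh, 2, function(v) mean(v^2)), c(1, 1), tolerance = 1e-3)
  expect_true(all(out$phi >= 0))
})
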