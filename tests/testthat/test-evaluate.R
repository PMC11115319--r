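# Reliability and performance estimators.

test_that("noise variance is the repeat variance averaged over images", {
  expect_equal(noise_variance(rbind(c(3, 3, 3), c(5, 5, 5))), 0)
  expect_equal(noise_variance(rbind(c(0, 2))), 2)    # unbiased: ((0-1)^2+(2-1)^2)/1
  expect_error(noise_variance(matrix(1:5, 5, 1)), "single repeat")

  set.seed(6)
  counts <- array(rpois(75 * 45, 5), c(75, 45, 1))
  expect_equal(noise_variance(counts), 5, tolerance = 0.5)
})

test_that("explainable variance separates signal from observation noise", {
  # no noise, means differ across images: EV = 1
  counts <- array(rep(c(1, 5, 9), each = 1), c(3, 1, 1))[, c(1, 1), , drop = FALSE]
  ev1 <- explainable_variance(counts)
  expect_equal(ev1$ev, 1)
  expect_equal(ev1$var_noise, 0)

  set.seed(11)
  # identical mean across images, pure noise: EV ~ 0
  pure <- array(rnorm(100 * 40, 0, 2), c(100, 40, 1))
  expect_equal(explainable_variance(pure)$ev, 0, tolerance = 0.06)

  # signal variance 1, noise variance 3: EV ~ 1/4
  sig <- rnorm(200, 0, 1)
  obs <- array(sig + rnorm(200 * 60, 0, sqrt(3)), c(200, 60, 1))
  expect_equal(explainable_variance(obs)$ev, 0.25, tolerance = 0.05)

  expect_warning(explainable_variance(array(2, c(4, 3, 1))), "zero total")
})

test_that("the reliability filter removes EV strictly below threshold", {
  # a neuron exactly at 0.15 is retained; below is removed
  expect_identical(filter_reliable(c(0.10, 0.15, 0.20)), c(2L, 3L))
  expect_identical(filter_reliable(c(0.01, 0.1)), integer(0))

  set.seed(3)
  evs <- runif(1000, -0.5, 1)
  brute <- which(vapply(seq_along(evs), function(i) evs[i] >= 0.15, logical(1)))
  expect_identical(filter_reliable(evs), brute)
})

test_that("FEVE is one for perfect noise-free predictions and zero for the mean", {
  # noise-free data, predictions equal to the per-image responses
  resp <- c(2, 4, 8, 1, 6)
  counts <- array(rep(resp, 2), c(5, 2, 1))
  f <- feve(matrix(resp), counts)
  expect_equal(f$feve, 1)

  set.seed(13)
  rates <- rgamma(75, 4)
  counts <- array(rpois(75 * 200, rates), c(75, 200, 1))
  # grand-mean predictor explains none of the signal variance
  f0 <- feve(matrix(mean(rates), 75), counts)
  expect_equal(f0$feve, 0, tolerance = 0.05)
  # oracle predictor (the generating rates) explains it all
  f1 <- feve(matrix(rates), counts)
  expect_equal(f1$feve, 1, tolerance = 0.05)
  expect_warning(
    feve(matrix(rates), array(rpois(75 * 2, 5), c(75, 2, 1))),
    "non-positive"
  )
})

test_that("test correlation is affine-invariant and centered for null predictions", {
  set.seed(5)
  counts <- array(rpois(20 * 10 * 2, 4), c(20, 10, 2))
  mr <- apply(counts, c(1, 3), mean)
  pred <- 2 * mr + 3                          # positive affine transform
  out <- mean_test_correlation(pred, counts)
  expect_equal(out$correlation, c(1, 1))
  out_neg <- mean_test_correlation(-pred, counts)
  expect_equal(out_neg$correlation, c(-1, -1))

  # independent random predictions: mean correlation near zero
  null_pred <- matrix(rnorm(75 * 50), 75, 50)
  null_counts <- array(rpois(75 * 10 * 50, 4), c(75, 10, 50))
  expect_lt(abs(mean_test_correlation(null_pred, null_counts)$mean), 0.05)

  expect_warning(mean_test_correlation(matrix(1, 20, 2), counts), "undefined")
  expect_error(mean_test_correlation(matrix(1, 2, 1),
                                     array(1, c(2, 2, 1))), "3 test images")
})

test_that("selectivity index matches a brute-force threshold oracle", {
  # uniform responses: A ~ 0.5, SI ~ 0
  u <- seq(0, 1, length.out = 5000)
  s <- selectivity_index(u)
  expect_equal(s$A, 0.5, tolerance = 0.01)
  expect_equal(s$SI, 0, tolerance = 0.02)

  # one image responds, the rest are silent: SI close to 1
  sparse <- c(rep(0, 99), 10)
  expect_gt(selectivity_index(sparse)$SI, 0.95)

  # arbitrary vector vs explicit enumeration over the 100 thresholds
  set.seed(21)
  r <- rgamma(83, 1.5)
  th <- seq(min(r), max(r), length.out = 100)
  fr <- numeric(100)
  for (i in 1:100) fr[i] <- sum(r > th[i]) / length(r)
  A_oracle <- mean(fr)
  got <- selectivity_index(r)
  expect_equal(got$A, A_oracle)
  expect_equal(got$SI, 1 - 2 * A_oracle)

  # invariant under positive affine rescaling
  expect_equal(selectivity_index(3 * r + 7)$SI, got$SI)
  expect_warning(selectivity_index(rep(2, 10)), "constant")
})

test_that("evaluate() assembles per-neuron scores and a filtered summary", {
  ds <- fix_tiny_dataset()
  m <- fix_single_fit("cardinal")
  sc <- evaluate(m, ds)
  expect_s3_class(sc, "model_score")
  expect_identical(nrow(sc$neurons), 8L)
  expect_identical(sc$retained, filter_reliable(sc$neurons$ev, 0.15))
  expect_true(all(c("ev", "test_corr", "feve", "si") %in% names(sc$neurons)))
  expect_output(print(sc), "neurons retained")
})
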