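test_that("unmasked-run mean is derived from the masking ratio", {
  spec <- maskSpec(r = 0.15, l0_s = 3)
  expect_equal(spec$l1_s * 32, 544)          # 96 * 0.85 / 0.15 samples at 32 Hz
  expect_error(maskSpec(r = 0), "r > 0")
  expect_error(maskSpec(r = 1), "r < 1")
})

test_that("mask sampler hits the configured ratio and run length", {
  set.seed(2)
  m <- sampleMask(4e5, maskSpec(), fs = 32)
  expect_lt(abs(mean(m) - 0.15), 0.02)      # coarse; the calibration suite
  r <- rle(m)                               # checks the tight bounds
  expect_lt(abs(mean(r$lengths[r$values]) / 32 - 3), 0.3)
})

test_that("masking zeroes exactly the masked positions", {
  seg <- list(eda = rep(1, 20), temp = rep(2, 5))
  masks <- list(eda = rep(c(TRUE, FALSE), 10), temp = rep(FALSE, 5))
  out <- applyMask(seg, masks)
  expect_equal(sum(out$eda == 0), 10)
  expect_identical(out$temp, seg$temp)
  none <- applyMask(seg, list(eda = rep(FALSE, 20), temp = rep(FALSE, 5)))
  expect_identical(none, seg)
  all0 <- applyMask(seg, list(eda = rep(TRUE, 20), temp = rep(TRUE, 5)))
  expect_true(all(unlist(all0) == 0))
  expect_error(applyMask(seg, list(eda = TRUE, temp = rep(TRUE, 5))),
               "mismatch")
})

test_that("masked RMSE has its closed forms and ignores unmasked positions", {
  orig <- list(a = rep(1, 10), b = rep(1, 6))
  recon <- orig
  masks <- list(a = c(rep(TRUE, 4), rep(FALSE, 6)), b = rep(FALSE, 6))
  expect_equal(mpLoss(orig, recon, masks), 0)

  recon0 <- list(a = rep(0, 10), b = rep(0, 6))
  expect_equal(mpLoss(orig, recon0, masks), 1)      # 4 masked unit errors

  # metamorphic: arbitrary perturbation of unmasked coordinates is invisible
  recon_p <- recon0
  recon_p$a[5:10] <- rnorm(6, 100)
  recon_p$b <- rnorm(6, -50)
  expect_equal(mpLoss(orig, recon_p, masks), 1)

  expect_error(mpLoss(orig, recon, list(a = rep(FALSE, 10), b = rep(FALSE, 6))),
               "empty mask")
})

test_that("transformations are uniform, seeded and length-preserving", {
  set.seed(14)
  draws <- sampleTransforms(6e4)
  expect_true(all(abs(table(draws) / 6e4 - 1 / 6) < 0.01))
  set.seed(7); a <- sampleTransforms(6)
  set.seed(7); b <- sampleTransforms(6)
  expect_identical(a, b)
  expect_length(a, 6)

  x <- as.numeric(scale(cumsum(rnorm(256))))
  set.seed(3)
  for (k in seq_along(transformKinds())) {
    y <- applyTransform(x, k)
    expect_length(y, length(x))
    if (k > 1) expect_false(isTRUE(all.equal(y, x)),
                            label = transformKinds()[k])
  }
  expect_identical(applyTransform(x, "identity"), x)   # bit-exact
  set.seed(4)
  y <- applyTransform(x, "gaussian_noise", noise_sd = 0.1)
  expect_equal(sd(y - x), 0.1, tolerance = 0.15)
  set.seed(5)
  yp <- applyTransform(x, "permutation")
  expect_equal(sort(yp), sort(x))                       # rearrangement only
  expect_error(applyTransform(x, "frobnicate"), "unknown")
})

test_that("channel-average cross-entropy has its closed forms", {
  expect_equal(tpLoss(matrix(0, 6, 6), rep(1L, 6)), log(6))
  big <- matrix(-1e3, 6, 6); big[cbind(1:6, c(2, 4, 1, 6, 3, 5))] <- 1e3
  expect_equal(tpLoss(big, c(2L, 4L, 1L, 6L, 3L, 5L)), 0)
  # half uniform, half one-hot correct -> ln 6 / 2
  mix <- rbind(matrix(0, 3, 6), big[1:3, ])
  expect_equal(tpLoss(mix, c(1L, 1L, 1L, 2L, 4L, 1L)), log(6) / 2)
  expect_error(tpLoss(matrix(0, 6, 5), rep(1L, 6)), "channels x 6")
  # random one-hot labels with matching one-hot predictions are lossless
  set.seed(21)
  for (i in 1:5) {
    y <- sample.int(6, 6, replace = TRUE)
    lg <- matrix(-1e3, 6, 6); lg[cbind(1:6, y)] <- 1e3
    expect_equal(tpLoss(lg, y), 0)
  }
})

test_that("per-channel mask lengths follow each channel's sampling rate", {
  fs <- c(acc_x = 4, acc_y = 4, acc_z = 4, bvp = 8, eda = 2, temp = 1)
  segs <- toy_segments(n = 2, omega = 4, fs = fs)
  set.seed(1)
  masks <- sampleSegmentMasks(segs, 1)
  for (ch in names(fs)) expect_length(masks[[ch]], 4 * fs[[ch]])
})
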