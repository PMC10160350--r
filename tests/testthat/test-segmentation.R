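test_that("sharpness matches a hand convolution and behaves under blur", {
  expect_equal(sharpness(matrix(13, 10, 10)), 0)
  # hand-computed 3x3 case with replicate padding
  fr <- matrix(c(0, 0, 0, 0, 255, 0, 0, 0, 0), 3, 3)
  lap <- matrix(0, 3, 3)
  padded <- rbind(fr[1, ], fr, fr[3, ])
  padded <- cbind(padded[, 1], padded, padded[, 3])
  for (y in 1:3) for (x in 1:3) {
    lap[y, x] <- padded[y, x + 1] + padded[y + 2, x + 1] +
      padded[y + 1, x] + padded[y + 1, x + 2] - 4 * padded[y + 1, x + 1]
  }
  expect_equal(sharpness(fr), mean((lap - mean(lap))^2))
  # blurring strictly reduces the focus measure
  set.seed(21)
  sharp <- matrix(sample(0:255, 40 * 40, replace = TRUE), 40, 40)
  k <- matrix(1 / 25, 5, 5)
  blurred <- matrix(0, 40, 40)
  pad <- rbind(sharp[c(1, 1), ], sharp, sharp[c(40, 40), ])
  pad <- cbind(pad[, c(1, 1)], pad, pad[, c(40, 40)])
  for (y in 1:40) for (x in 1:40) {
    blurred[y, x] <- sum(pad[y:(y + 4), x:(x + 4)] * k)
  }
  expect_gt(sharpness(sharp), sharpness(blurred))
})

test_that("a static scene is all background after warmup", {
  m <- background_model(30, 20, warmup = 5, seed = 3)
  fr <- matrix(60, 20, 30)
  for (i in 1:100) mask <- bg_subtract(m, fr)
  expect_equal(sum(mask), 0)
})

test_that("KNN classification agrees with a per-pixel reference", {
  m <- background_model(40, 40, warmup = 2, seed = 7)
  bgf <- matrix(12, 40, 40)
  bg_subtract(m, bgf); bg_subtract(m, bgf)
  fr <- bgf
  fr[10:30, 5:25] <- 200  # a bright square appears
  mask <- bg_subtract(m, fr)
  ref <- bf_knn_mask(rep(list(bgf), 10), fr, 400, 3)
  expect_equal(mask, ref)
  sq <- matrix(FALSE, 40, 40); sq[10:30, 5:25] <- TRUE
  expect_gte(mean(mask[sq] == 255), 0.95)
  expect_lt(mean(mask[!sq] == 255), 0.01)
})

test_that("a stationary object is absorbed into the background", {
  m <- background_model(20, 20, n_samples = 4, k_required = 2,
                        history = 30, warmup = 2, seed = 13)
  bgf <- matrix(10, 20, 20)
  bg_subtract(m, bgf); bg_subtract(m, bgf)
  obj <- bgf; obj[5:15, 5:15] <- 220
  for (i in 1:400) mask <- bg_subtract(m, obj)
  expect_equal(sum(mask), 0)
})

test_that("background subtraction is deterministic under a fixed seed", {
  run <- function() {
    m <- background_model(25, 25, warmup = 3, seed = 99)
    set.seed(1)
    masks <- lapply(1:30, function(i) {
      bg_subtract(m, matrix(sample(0:40, 625, replace = TRUE), 25, 25))
    })
    masks
  }
  expect_identical(run(), run())
})

test_that("morphology matches the exhaustive set definition", {
  # single pixel is erased by a 3x3 erosion
  m <- matrix(0, 7, 7); m[4, 4] <- 255
  expect_equal(sum(erode(m, struct_el(3))), 0)
  # 5x5 foreground erodes to its 3x3 centre (border counts as background)
  m2 <- matrix(255, 5, 5)
  e2 <- erode(m2, struct_el(3))
  expect_equal(sum(e2 == 255), 9)
  expect_true(all(e2[2:4, 2:4] == 255))
  # random masks against the brute-force oracle, several kernels
  set.seed(31)
  for (i in 1:40) {
    m3 <- matrix(sample(c(0, 255), 144, replace = TRUE, prob = c(0.55, 0.45)),
                 12, 12)
    it <- sample(1:2, 1)
    expect_equal(erode(m3, struct_el(3, iterations = it)),
                 bf_morph(m3, it, it, TRUE))
    expect_equal(dilate(m3, struct_el(3, iterations = it)),
                 bf_morph(m3, it, it, FALSE))
    expect_equal(erode(m3, struct_el(c(1, 5))), bf_morph(m3, 0, 2, TRUE))
  }
  expect_error(erode(matrix(3, 4, 4), struct_el(3)), "binary")
  expect_error(struct_el(4), "odd")
})

test_that("erosion is anti-extensive, dilation extensive, opening idempotent", {
  set.seed(41)
  se <- struct_el(3)
  for (i in 1:25) {
    m <- matrix(sample(c(0, 255), 400, replace = TRUE, prob = c(0.6, 0.4)),
                20, 20)
    er <- erode(m, se)
    di <- dilate(m, se)
    expect_true(all(er <= m))
    expect_true(all(di >= m))
    opened <- dilate(erode(m, se), se)
    expect_equal(dilate(erode(opened, se), se), opened)
  }
})

test_that("opening removes sub-kernel components without bbox growth", {
  m <- matrix(0, 30, 30)
  m[10:20, 10:20] <- 255   # 11x11 block survives
  m[3, 3] <- 255           # isolated pixel dies
  m[25, 5:6] <- 255        # 1x2 speck dies
  opened <- dilate(erode(m, struct_el(3)), struct_el(3))
  expect_equal(sum(opened[1:8, ]), 0)
  expect_equal(sum(opened[25, ]), 0)
  on <- which(opened == 255, arr.ind = TRUE)
  expect_gte(min(on[, 1]), 10); expect_lte(max(on[, 1]), 20)
  expect_gte(min(on[, 2]), 10); expect_lte(max(on[, 2]), 20)
})
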