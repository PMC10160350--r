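test_that("contours: empty mask, filled square, component-count oracle", {
  expect_equal(find_contours(matrix(0, 10, 10)), list())
  m <- matrix(0, 20, 20); m[6:15, 4:13] <- 255
  cc <- find_contours(m)
  expect_length(cc, 1)
  expect_equal(attr(cc[[1]], "n_pixels"), 100)
  # boundary polygon runs through pixel centres: shoelace area (10-1)^2
  expect_equal(contour_area(cc[[1]]), 81)
  set.seed(17)
  for (i in 1:30) {
    m2 <- matrix(sample(c(0, 255), 20 * 20, replace = TRUE,
                        prob = c(0.7, 0.3)), 20, 20)
    expect_equal(length(find_contours(m2)), bf_component_count(m2))
  }
})

test_that("contour pixel sets partition the foreground", {
  set.seed(19)
  m <- random_blob_mask(40, 40, 6)
  cc <- find_contours(m)
  pix <- sort(unlist(lapply(cc, attr, "pixels")))
  expect_equal(pix, which(m > 0))
})

test_that("largest-object selection agrees with per-blob pixel counts", {
  m <- matrix(0, 30, 30)
  m[2:11, 2:11] <- 255    # 100 px
  m[15:29, 14:28] <- 255  # 225 px
  cc <- find_contours(m)
  expect_equal(attr(select_largest(cc), "n_pixels"), 225)
  expect_null(select_largest(list()))
  set.seed(23)
  for (i in 1:15) {
    # well-separated discs with distinct radii so both area notions agree
    radii <- sample(seq(2, 8, by = 1.5))[1:3]
    m2 <- matrix(0, 60, 60)
    centers <- list(c(12, 12), c(12, 45), c(45, 28))
    for (j in 1:3) {
      m2 <- pmax(m2, make_ellipse_mask(60, 60, centers[[j]][1],
                                       centers[[j]][2], radii[j], radii[j]))
    }
    cc2 <- find_contours(m2)
    best <- which.max(vapply(cc2, attr, integer(1), "n_pixels"))
    expect_equal(attr(select_largest(cc2), "label"),
                 attr(cc2[[best]], "label"))
  }
})

test_that("ellipse fit recovers analytic ellipses and circles", {
  t <- seq(0, 2 * pi, length.out = 120)[-120]
  f <- fit_ellipse(cbind(50 + 30 * cos(t), 50 + 10 * sin(t)))
  expect_equal(f$major_axis_px, 60, tolerance = 0.01)
  expect_equal(f$minor_axis_px, 20, tolerance = 0.01)
  expect_equal(f$center, c(50, 50), tolerance = 0.01)
  fc <- fit_ellipse(cbind(20 + 15 * cos(t), 33 + 15 * sin(t)))
  expect_equal(fc$major_axis_px, 30, tolerance = 0.01)
  expect_equal(fc$minor_axis_px, 30, tolerance = 0.01)
  expect_null(fit_ellipse(cbind(1:4, 1:4)))          # too few points
  expect_null(fit_ellipse(cbind(1:10, 2 * (1:10))))  # collinear
})

test_that("noisy rotated ellipse matches a dense re-fit oracle within 2%", {
  set.seed(29)
  phi <- 37 * pi / 180
  t <- runif(100, 0, 2 * pi)
  x <- 60 + 30 * cos(t) * cos(phi) - 10 * sin(t) * sin(phi) + rnorm(100, 0, 0.3)
  y <- 60 + 30 * cos(t) * sin(phi) + 10 * sin(t) * cos(phi) + rnorm(100, 0, 0.3)
  f <- fit_ellipse(cbind(x, y))
  td <- seq(0, 2 * pi, length.out = 2000)
  dense <- cbind(60 + 30 * cos(td) * cos(phi) - 10 * sin(td) * sin(phi),
                 60 + 30 * cos(td) * sin(phi) + 10 * sin(td) * cos(phi))
  oracle <- fit_ellipse(dense)
  expect_equal(f$major_axis_px, oracle$major_axis_px, tolerance = 0.02)
  expect_equal(f$minor_axis_px, oracle$minor_axis_px, tolerance = 0.02)
  expect_equal(f$orientation_deg, oracle$orientation_deg, tolerance = 0.02)
})

test_that("ellipse fit is rotation- and translation-equivariant", {
  set.seed(37)
  t <- seq(0, 2 * pi, length.out = 80)[-80]
  base <- cbind(25 * cos(t), 9 * sin(t))
  f0 <- fit_ellipse(base)
  for (ang in c(15, 63, 118, 170)) {
    r <- ang * pi / 180
    R <- matrix(c(cos(r), sin(r), -sin(r), cos(r)), 2, 2)
    shift <- runif(2, -30, 30)
    f1 <- fit_ellipse(sweep(base %*% t(R), 2, -shift))
    expect_equal(f1$major_axis_px, f0$major_axis_px, tolerance = 0.01)
    expect_equal(f1$minor_axis_px, f0$minor_axis_px, tolerance = 0.01)
    expect_equal(f1$orientation_deg %% 180, ang %% 180, tolerance = 0.5)
  }
})

test_that("axes from rasterized ellipses track truth across sizes", {
  set.seed(43)
  for (case in list(c(15, 8), c(25, 10), c(40, 25), c(60, 40), c(100, 55))) {
    a <- case[1]; b <- case[2]
    phi <- runif(1, 0, pi)
    m <- make_ellipse_mask(260, 260, 130.3, 129.6, a, b, phi)
    meas <- measure_object(find_contours(m)[[1]], m, c(0, 0, 260, 260))
    expect_equal(meas$major_axis_px, 2 * a, tolerance = 0.02)
    expect_equal(meas$minor_axis_px, 2 * b, tolerance = 0.02)
  }
})

test_that("object brightness equals the masked mean and edge distance the box gap", {
  m <- make_ellipse_mask(60, 90, 40, 30, 12, 7, 0.4)
  gray <- matrix(0, 60, 90)
  gray[m == 255] <- 200
  meas <- measure_object(find_contours(m)[[1]], gray, c(0, 0, 90, 60))
  expect_equal(meas$brightness, 200)
  set.seed(47)
  for (i in 1:10) {
    mb <- random_blob_mask(40, 50, 3)
    gr <- matrix(runif(2000, 0, 255), 40, 50)
    cc <- find_contours(mb)
    for (ct in cc) {
      mm <- measure_object(ct, gr, c(0, 0, 50, 40))
      if (!is.null(mm)) {
        expect_equal(mm$brightness, mean(gr[attr(ct, "pixels")]))
      }
    }
  }
  # centre at x = 10 in a 900-wide crop: nearest edge is 10 px away
  m2 <- make_ellipse_mask(600, 900, 10, 300, 4, 4)
  meas2 <- measure_object(find_contours(m2)[[1]], m2, c(0, 0, 900, 600))
  expect_equal(meas2$edge_distance_px, 10, tolerance = 0.2)
})

test_that("species profiles load with the published filter windows", {
  profiles <- load_species_profiles()
  expect_setequal(names(profiles),
                  c("daphnia", "eucyclops_mesocyclops", "diaphanosoma",
                    "heterocope", "polyphemus", "scapholebrius"))
  d <- profiles$daphnia
  expect_equal(c(d$min_area_px, d$max_area_px), c(1500, 4000))
  expect_equal(c(d$min_lw_ratio, d$max_lw_ratio), c(1.2, 1.7))
  expect_equal(d$min_brightness, 30)
  expect_equal(d$optimal_percentile, 93L)
  expect_equal(d$min_sharpness, 1.8)
  expect_equal(d$min_edge_distance_px, 10)
  expect_equal(default_species_profile()$name, "daphnia")
})

test_that("the species filter accepts/rejects with ordered reasons", {
  d <- default_species_profile()
  base <- list(area_px = 2000, major_axis_px = 60, minor_axis_px = 40,
               brightness = 40, sharpness = 2.0, edge_distance_px = 50)
  expect_true(apply_species_filter(base, d)$accept)
  lose <- function(field, value) {
    m <- base; m[[field]] <- value
    apply_species_filter(m, d)
  }
  expect_equal(lose("area_px", 1000)$reason, "area")
  expect_equal(lose("area_px", 5000)$reason, "area")
  expect_equal(lose("minor_axis_px", 20)$reason, "lw_ratio")  # L/W = 3
  expect_equal(lose("brightness", 10)$reason, "brightness")
  expect_equal(lose("sharpness", 1.0)$reason, "sharpness")
  expect_equal(lose("edge_distance_px", 5)$reason, "edge")
  # order: an all-failing measurement reports the first criterion
  bad <- list(area_px = 10, major_axis_px = 60, minor_axis_px = 10,
              brightness = 1, sharpness = 0, edge_distance_px = 0)
  expect_equal(apply_species_filter(bad, d)$reason, "area")
})

test_that("relaxing any threshold never decreases the accepted count", {
  set.seed(53)
  ms <- lapply(1:200, function(i) {
    list(area_px = runif(1, 500, 6000), major_axis_px = runif(1, 40, 90),
         minor_axis_px = runif(1, 25, 60), brightness = runif(1, 0, 90),
         sharpness = runif(1, 0, 5), edge_distance_px = runif(1, 0, 40))
  })
  count <- function(p) sum(vapply(ms, function(m) {
    apply_species_filter(m, p)$accept
  }, logical(1)))
  tight <- species_profile("t", 1500, 4000, 1.2, 1.7, 30, 93)
  for (relaxed in list(
    species_profile("r", 1000, 4000, 1.2, 1.7, 30, 93),
    species_profile("r", 1500, 5000, 1.2, 1.7, 30, 93),
    species_profile("r", 1500, 4000, 1.1, 1.8, 30, 93),
    species_profile("r", 1500, 4000, 1.2, 1.7, 20, 93),
    species_profile("r", 1500, 4000, 1.2, 1.7, 30, 93, min_sharpness = 1),
    species_profile("r", 1500, 4000, 1.2, 1.7, 30, 93,
                    min_edge_distance_px = 5))) {
    expect_gte(count(relaxed), count(tight))
  }
})
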