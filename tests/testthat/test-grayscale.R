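test_that("polygon rasterization matches closed-form pixel counts", {
  # full-frame rectangle captures every pixel
  full <- rasterizePolygon(
    polygonROI("kidney", rbind(c(0, 0), c(11, 0), c(11, 8), c(0, 8))), 12, 9)
  expect_equal(nInside(full), 12 * 9)

  # axis-aligned rectangle (2,2)-(5,4): 4 x 3 pixels, boundary inclusive
  rect <- rasterizePolygon(
    polygonROI("kidney", rbind(c(2, 2), c(5, 2), c(5, 4), c(2, 4))), 10, 10)
  expect_equal(nInside(rect), 12)

  # vertices outside the image are refused
  expect_error(
    rasterizePolygon(polygonROI("kidney", rbind(c(0, 0), c(12, 0), c(6, 5))), 10, 10),
    "outside")
})

test_that("rasterized area tracks the shoelace area for random triangles", {
  set.seed(42)
  for (i in 1:20) {
    v <- cbind(runif(3, 0, 99), runif(3, 0, 79))
    a <- shoelaceArea(v)
    if (a < 25) next  # skip slivers; the bound below is for large triangles
    m <- rasterizePolygon(polygonROI("kidney", v), 100, 80)
    expect_lt(abs(nInside(m) - a), 2 * polygonPerimeter(v))
  }
})

test_that("rasterization is translation-equivariant", {
  set.seed(8)
  v <- cbind(runif(6, 10, 30), runif(6, 10, 25))
  base <- rasterizePolygon(polygonROI("kidney", v), 70, 60)
  for (shift in list(c(5, 0), c(0, 7), c(13, 9))) {
    moved <- rasterizePolygon(
      polygonROI("kidney", sweep(v, 2, shift, "+")), 70, 60)
    got <- which(moved@inside, arr.ind = TRUE)
    want <- which(base@inside, arr.ind = TRUE)
    want[, 1] <- want[, 1] + shift[2]; want[, 2] <- want[, 2] + shift[1]
    expect_equal(got[order(got[, 1], got[, 2]), , drop = FALSE],
                 want[order(want[, 1], want[, 2]), , drop = FALSE],
                 ignore_attr = TRUE)
  }
})

test_that("regionPixels returns masked intensities in row-major order", {
  img <- GrayImage(matrix(c(0L, 128L, 200L, 255L), 2, 2, byrow = TRUE))
  all_in <- new("RegionMask", inside = matrix(TRUE, 2, 2))
  expect_identical(regionPixels(img, all_in), c(0L, 128L, 200L, 255L))

  one <- new("RegionMask", inside = matrix(c(FALSE, TRUE, FALSE, FALSE), 2, 2))
  expect_identical(regionPixels(img, one), 200L)  # pixel (x=0, y=1)

  const <- GrayImage(matrix(9L, 4, 4))
  checker <- new("RegionMask",
                 inside = outer(1:4, 1:4, function(i, j) (i + j) %% 2 == 0))
  expect_identical(regionPixels(const, checker), rep(9L, 8L))

  expect_error(regionPixels(img, checker), "dimensions differ")
  empty <- new("RegionMask", inside = matrix(FALSE, 2, 2))
  expect_error(regionPixels(img, empty), "empty region")
})

test_that("GSM is the sample median with exact even-n tie handling", {
  g <- computeGSM(c(7L, 7L, 7L))
  expect_equal(gsm(g), 7)
  expect_equal(g@n, 3L)
  expect_equal(g@sd, 0)

  expect_equal(gsm(computeGSM(c(10L, 20L, 30L, 40L))), 25)
  expect_equal(gsm(computeGSM(c(0L, 1L))), 0.5)  # exact .5 preserved
  expect_error(computeGSM(integer(0)), "empty region")

  # sort-based oracle: odd n picks the (n+1)/2-th order statistic
  set.seed(11)
  draws <- sample(0:255, 10001L, replace = TRUE)
  expect_equal(gsm(computeGSM(draws)), sort(draws)[5001L])

  # property over sizes up to 1e5, even and odd
  for (n in c(2L, 17L, 100L, 4999L, 100000L)) {
    x <- sample(0:255, n, replace = TRUE)
    s <- sort(x)
    want <- if (n %% 2L) s[(n + 1L) / 2L] else (s[n / 2L] + s[n / 2L + 1L]) / 2
    expect_equal(gsm(computeGSM(x)), want)
  }
})

test_that("default brightness ranges are a valid 14-band tiling", {
  rng <- defaultBrightnessRanges()
  b <- bandTable(rng)
  expect_equal(nBands(rng), 14L)
  expect_equal(b$lo[1], 0L)
  expect_equal(b$hi[14], 255L)
  expect_true(all(b$lo[-1] == b$hi[-14] + 1L))
  expect_equal(rangeSource(rng), "fallback_uniform")

  # a non-tiling configuration is refused at construction
  bad <- b; bad$hi[3] <- bad$hi[3] - 1L
  expect_error(brightnessRanges(bad), "tile")
})

test_that("brightness distribution partitions the region exactly", {
  rng <- defaultBrightnessRanges()
  b <- bandTable(rng)

  # constant region: 100% in the unique containing band
  d <- brightnessDistribution(rep(100L, 50L), rng)
  band <- which(b$lo <= 100 & 100 <= b$hi)
  expect_equal(d@percentage[band], 100)
  expect_equal(sum(d@percentage[-band]), 0)

  # one pixel of every level: percentage = 100 * width / 256 per band
  d <- brightnessDistribution(0:255, rng)
  expect_equal(d@percentage, 100 * (b$hi - b$lo + 1) / 256)

  # large uniform sample: within 1% absolute of the binomial expectation
  set.seed(5)
  d <- brightnessDistribution(sample(0:255, 100000L, replace = TRUE), rng)
  expect_true(all(abs(d@percentage - 100 * (b$hi - b$lo + 1) / 256) < 1))

  # partition property over random cases
  for (i in 1:10) {
    px <- sample(0:255, sample(1:2000, 1), replace = TRUE)
    d <- brightnessDistribution(px, rng)
    expect_equal(sum(d@counts), length(px))
    expect_lt(abs(sum(d@percentage) - 100), 1e-9)
  }
  expect_error(brightnessDistribution(integer(0), rng), "empty region")
})

test_that("pseudocolor rendering recolors exactly the masked pixels", {
  rng <- defaultBrightnessRanges()
  b <- bandTable(rng)
  set.seed(21)
  img <- GrayImage(matrix(sample(0:255, 30 * 20, replace = TRUE), 20, 30))
  mask <- rasterizePolygon(
    polygonROI("kidney", rbind(c(3, 3), c(20, 3), c(20, 15), c(3, 15))), 30, 20)
  out <- pseudocolorRender(img, mask, rng)
  expect_equal(dim(out), c(20L, 30L, 3L))

  # outside pixels keep their gray triple
  outsideIdx <- which(!mask@inside, arr.ind = TRUE)
  for (ch in 1:3)
    expect_equal(out[, , ch][!mask@inside], intensities(img)[!mask@inside])

  # recolored pixel count equals the inside count
  gray3 <- out[, , 1] == out[, , 2] & out[, , 2] == out[, , 3]
  grayHexes <- sprintf("#%02X%02X%02X", 0:255, 0:255, 0:255)
  nonGrayBands <- sum(!(toupper(b$color) %in% grayHexes))
  expect_equal(nonGrayBands, 13L)  # only the white top band is a gray triple

  # constant region renders exactly one color inside the mask
  cimg <- GrayImage(matrix(100L, 20, 30))
  cout <- pseudocolorRender(cimg, mask, rng)
  insideCols <- unique(cbind(cout[, , 1][mask@inside], cout[, , 2][mask@inside],
                             cout[, , 3][mask@inside]))
  expect_equal(nrow(insideCols), 1L)
  band <- which(b$lo <= 100 & 100 <= b$hi)
  expect_equal(as.integer(insideCols),
               as.integer(grDevices::col2rgb(b$color[band])))

  # a band absent from the region leaves its color absent from the output
  hexOut <- sprintf("#%02X%02X%02X", cout[, , 1], cout[, , 2], cout[, , 3])
  expect_false(toupper(b$color[1]) %in% toupper(hexOut[as.vector(mask@inside)]))

  expect_error(pseudocolorRender(img, new("RegionMask", inside = matrix(TRUE, 2, 2)), rng),
               "dimensions differ")
})
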