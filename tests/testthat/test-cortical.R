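.uniformField <- function(val = c(signal = 10, reference = 10), n = 41L,
                          pixelSize = 1) {
  chans <- lapply(val, function(v) matrix(v, n, n))
  new("ImageField", channels = chans, pixelSize = pixelSize,
      channelRoles = c(signal = "signal", reference = "reference"))
}

test_that("background zeroing subtracts the region mean and clips at zero", {
  img <- .uniformField(c(signal = 25, reference = 13))
  # cytoplasm block sits 10 (signal) / 3 (reference) above the background
  img@channels$signal[10:30, 10:30] <- 35
  img@channels$reference[10:30, 10:30] <- 16
  bg <- matrix(FALSE, 41, 41); bg[1:5, ] <- TRUE
  z <- zeroBackground(img, bg)
  expect_equal(getChannel(z, "signal")[20, 20], 10)
  expect_equal(getChannel(z, "reference")[20, 20], 3)
  expect_equal(getChannel(z, "signal")[40, 40], 0)   # clipped, not negative
  # already-zero background: identity
  z2 <- zeroBackground(z, bg)
  expect_identical(getChannel(z2, "signal"), getChannel(z, "signal"))
  expect_error(zeroBackground(img, matrix(FALSE, 41, 41)),
               "empty background")
})

test_that("background estimated from a synthetic tile removes the offset", {
  spec <- renderSpec(textureCV = 0, seed = 17)
  rc <- renderCell(generateCellGeometry("bipolar", seed = 17), spec)
  bg <- !rc$truth@cellMask
  z <- zeroBackground(rc$image, bg)
  resid <- mean(getChannel(z, "signal")[bg])
  # post-op background mean is far below the read-noise sigma
  expect_lt(abs(resid), 0.5 * spec@noise$readSigma)
})

test_that("cortical band of a disk matches the annulus closed form", {
  th <- seq(0, 2 * pi, length.out = 257)[-257]
  # disk of radius 20 um at pixel size 0.5 -> radius 40 px
  circ <- cbind(45 + 40 * cos(th), 45 + 40 * sin(th))
  mask <- contourToMask(circ, c(91L, 91L))
  band <- corticalBand(mask, circ, widthUm = 5, pixelSize = 0.5)
  expect_equal(sum(band) / sum(mask), (20^2 - 15^2) / 20^2,
               tolerance = 0.03)
  # saturation: width beyond the inradius covers the whole cell
  expect_warning(bandAll <- corticalBand(mask, circ, widthUm = 50,
                                         pixelSize = 0.5),
                 "band equals the whole cell")
  expect_identical(bandAll, mask)
})

test_that("band membership equals the exact distance criterion", {
  set.seed(8)
  poly <- randomStarPolygon(n = 25, rMin = 10, rMax = 22, center = c(26, 26))
  mask <- contourToMask(poly, c(53L, 53L))
  band <- corticalBand(mask, poly, widthUm = 6, pixelSize = 1)
  idx <- which(mask)
  py <- (idx - 1L) %% 53L; px <- (idx - 1L) %/% 53L
  d <- distOracleR(px, py, poly)
  expect_identical(as.vector(band[idx]), d <= 6)
})

test_that("uniform symmetric cell gives quarter fractions and unit ratios", {
  img <- .uniformField()
  sq <- cbind(c(-0.5, 40.5, 40.5, -0.5), c(-0.5, -0.5, 40.5, 40.5))
  cc <- new("CellContour", vertices = sq, cellId = "sq", axisAngle = 0)
  mask <- matrix(TRUE, 41, 41)
  part <- partitionQuadrants(cc, mask, pixelSize = 1)
  m <- domainFluorescence(img, part, mask)
  expect_equal(m$fraction, rep(0.25, 8), tolerance = 0.002)
  expect_equal(m$ratio, rep(1, 8), tolerance = 1e-12)
})

test_that("identical channels give unit ratios regardless of geometry", {
  set.seed(4)
  poly <- randomStarPolygon(n = 18, rMin = 8, rMax = 19, center = c(22, 22))
  cc <- new("CellContour", vertices = poly, cellId = "p", axisAngle = 1.1)
  mask <- contourToMask(cc, c(45L, 45L))
  base <- matrix(runif(45 * 45, 1, 50), 45, 45)
  img <- new("ImageField", channels = list(signal = base, reference = base),
             pixelSize = 1,
             channelRoles = c(signal = "signal", reference = "reference"))
  part <- partitionQuadrants(cc, mask, pixelSize = 1)
  m <- domainFluorescence(img, part, mask)
  expect_equal(m$ratio, rep(1, 8), tolerance = 1e-12)
})

test_that("fractions conserve to one and respect nucleus exclusion", {
  rc <- renderCell(generateCellGeometry("bipolar", seed = 23), renderSpec(seed = 23))
  tr <- rc$truth
  cc <- segmentFromTruth(tr)
  part <- partitionQuadrants(cc, tr@cellMask, pixelSize = 0.25)
  m <- domainFluorescence(rc$image, part, tr@cellMask, tr@nucleusMask)
  for (ch in c("signal", "reference"))
    expect_equal(sum(m$fraction[m$channel == ch]), 1, tolerance = 1e-9)
  # adding arbitrary intensity inside the nucleus changes nothing
  img2 <- rc$image
  img2@channels$signal[tr@nucleusMask] <-
    img2@channels$signal[tr@nucleusMask] + 1e5
  m2 <- domainFluorescence(img2, part, tr@cellMask, tr@nucleusMask)
  expect_equal(m2$sum, m$sum)
  expect_equal(m2$ratio, m$ratio)
})

test_that("scaling a channel leaves fractions and ratios unchanged", {
  rc <- renderCell(generateCellGeometry("monopolar_away", seed = 29),
                   renderSpec(seed = 29))
  tr <- rc$truth
  part <- partitionQuadrants(segmentFromTruth(tr), tr@cellMask,
                             pixelSize = 0.25)
  m <- domainFluorescence(rc$image, part, tr@cellMask, tr@nucleusMask)
  img2 <- rc$image
  img2@channels$signal <- img2@channels$signal * 7.3
  m2 <- domainFluorescence(img2, part, tr@cellMask, tr@nucleusMask)
  expect_equal(m2$fraction, m$fraction, tolerance = 1e-12)
  expect_equal(m2$ratio, m$ratio, tolerance = 1e-12)
})

test_that("cortical measurement recovers a planted enrichment ratio", {
  spec <- quietSpec(corticalEnrichment = c(NSB = 1.5, ANTI = 1, ANT = 1,
                                           POST = 1))
  rc <- renderCell(generateCellGeometry("bipolar", seed = 31), spec)
  tr <- rc$truth
  cc <- segmentFromTruth(tr)
  part <- partitionQuadrants(cc, tr@cellMask, pixelSize = 0.25)
  band <- corticalBand(tr@cellMask, cc, 5, 0.25)
  m <- domainFluorescence(rc$image, part, tr@cellMask, tr@nucleusMask,
                          region = "cortex", band = band)
  r <- ratioMatrix(m)
  expect_equal(unname(r[1, "NSB"] / mean(r[1, c("ANTI", "ANT", "POST")])),
               1.5, tolerance = 0.05)
})

test_that("ratio profile summarises cells with 2xSD error bars", {
  mk <- function(id, ratios) data.frame(cell_id = id, region = "whole_cell",
    domain = domainLabels(), channel = "signal", sum = 1,
    fraction = 0.25, ratio = ratios)
  prof <- ratioProfile(rbind(mk("a", c(1, 1, 1, 1)), mk("b", c(3, 1, 1, 1))))
  s <- prof$summary
  expect_equal(s$mean[s$domain == "NSB"], 2)
  expect_equal(s$two_sd[s$domain == "NSB"], 2 * sqrt(2))
  expect_equal(s$sd[s$domain == "ANTI"], 0)
  one <- ratioProfile(mk("a", c(1, 1, 1, 1)))
  expect_equal(one$summary$mean, rep(1, 4))
  expect_equal(one$summary$sd, rep(0, 4))
  # missing-domain cells are dropped with a message
  bad <- mk("c", c(NA, 1, 1, 1))
  expect_message(prof2 <- ratioProfile(rbind(mk("a", c(1, 1, 1, 1)), bad)),
                 "dropping")
  expect_equal(unique(prof2$cells$cell_id), "a")
})
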