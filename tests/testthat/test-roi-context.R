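test_that("expandBBox grows each edge by a percentage of the side and clamps", {
  expect_identical(expandBBox(c(100, 100, 200, 200), 0, c(1000, 1000)),
                   c(100L, 100L, 200L, 200L))
  # 50% of a 100-px side = 50 px per edge
  expect_identical(expandBBox(c(100, 100, 200, 200), 50, c(1000, 1000)),
                   c(50L, 50L, 250L, 250L))
  # clamping at the image origin
  expect_identical(expandBBox(c(0, 0, 100, 100), 50, c(1000, 1000)),
                   c(0L, 0L, 150L, 150L))
  expect_error(expandBBox(c(100, 100, 200, 200), -1, c(1000, 1000)), "non-negative")
  expect_error(expandBBox(c(100, 100, 2000, 200), 10, c(1000, 1000)), "outside")
})

test_that("expandBBox always contains the input box (property)", {
  set.seed(1)
  for (i in 1:50) {
    shp <- c(sample(200:600, 1), sample(200:600, 1))
    r0 <- sample(0:(shp[1] - 20), 1); c0 <- sample(0:(shp[2] - 20), 1)
    b <- c(r0, c0, r0 + sample(10:(shp[1] - r0), 1),
           c0 + sample(10:(shp[2] - c0), 1))
    p <- runif(1, 0, 120)
    e <- expandBBox(b, p, shp)
    expect_true(e[1] <= b[1] && e[2] <= b[2] && e[3] >= b[3] && e[4] >= b[4])
    expect_true(all(e >= 0) && e[3] <= shp[1] && e[4] <= shp[2])
  }
})

test_that("multi-scale extraction yields one 224x224 ROI per scale, nested by scale", {
  rg <- gradientRegion(1000, 1000, c(400, 420, 560, 580))
  rs <- extractMultiscaleROIs(rg, c(50, 60, 70, 80, 100))
  expect_equal(nROIs(rs), 5L)
  prov <- roiProvenance(rs)
  expect_equal(prov$scale_percent, c(50, 60, 70, 80, 100))
  expect_true(all(vapply(roiList(rs), function(r) all(dim(r) == 224L), logical(1))))
  # containment of pre-resize crops: expanded boxes are nested for a < b
  shp <- dim(regionImage(rg))
  for (i in 1:4) {
    a <- expandBBox(regionBBox(rg), prov$scale_percent[i], shp)
    b <- expandBBox(regionBBox(rg), prov$scale_percent[i + 1], shp)
    expect_true(b[1] <= a[1] && b[2] <= a[2] && b[3] >= a[3] && b[4] >= a[4])
  }
  expect_error(extractMultiscaleROIs(rg, numeric(0)), "non-empty")
  # scale 0 is the tight bbox crop
  rs0 <- extractMultiscaleROIs(rg, 0)
  expect_equal(nROIs(rs0), 1L)
  expect_equal(dim(roiList(rs0)[[1]]), c(224L, 224L))
})

test_that("isotropic rescale fixes the smaller side at 256 and keeps aspect", {
  expect_equal(dim(isotropicRescaleToBase(matrix(0, 128, 160))), c(256L, 320L))
  x <- matrix(runif(256 * 300), 256, 300)
  expect_identical(isotropicRescaleToBase(x), x)  # already at base
  # 512 * 256/300 = 436.9 -> 437 (round half-up)
  expect_equal(dim(isotropicRescaleToBase(matrix(0, 300, 512))), c(256L, 437L))
})

test_that("multi-context extraction emits 11 ROIs in fixed order with correct windows", {
  rg <- gradientRegion(900, 900, c(300, 280, 556, 600))  # 256 x 320 crop
  rs <- extractMulticontextROIs(rg)
  expect_equal(nROIs(rs), 11L)
  prov <- roiProvenance(rs)
  expect_equal(prov$crop_position,
               c("full", "TL", "TR", "BL", "BR", "C", "TL", "TR", "BL", "BR", "C"))
  expect_equal(prov$flipped, c(rep(FALSE, 6), rep(TRUE, 5)))
  expect_true(all(vapply(roiList(rs), function(r) all(dim(r) == 224L), logical(1))))
  # derived corner/center offsets for a 256 x 320 rescaled crop
  off <- massContext:::.contextOffsets(256L, 320L)
  expect_equal(unname(off$TL), c(0L, 0L))
  expect_equal(unname(off$TR), c(0L, 96L))
  expect_equal(unname(off$BL), c(32L, 0L))
  expect_equal(unname(off$BR), c(32L, 96L))
  expect_equal(unname(off$C), c(16L, 48L))
  # square crop: offsets floor to halves; all 11 still emitted
  off2 <- massContext:::.contextOffsets(256L, 256L)
  expect_equal(unname(off2$C), c(16L, 16L))
  rgSq <- gradientRegion(600, 600, c(100, 100, 300, 300))
  expect_equal(nROIs(extractMulticontextROIs(rgSq)), 11L)
  # MC1 subset
  rs1 <- extractMulticontextROIs(rg, "MC1")
  expect_equal(nROIs(rs1), 3L)
  expect_equal(roiProvenance(rs1)$crop_position, c("full", "C", "C"))
})

test_that("flipping is an involution and window contents match the rescaled crop", {
  rg <- gradientRegion(900, 900, c(300, 280, 556, 600))
  rs <- extractMulticontextROIs(rg)
  rois <- roiList(rs)
  # flip(flip(x)) == x, and flipped ROIs are the flips of their partners
  for (i in 2:6) {
    fl <- rois[[i + 5L]]
    expect_identical(fl[, rev(seq_len(ncol(fl)))], rois[[i]])
  }
  # TL window equals the top-left 224x224 of the rescaled crop
  crop <- massContext:::cropBBox(regionImage(rg), regionBBox(rg))
  res <- isotropicRescaleToBase(crop)
  expect_identical(rois[[2]], res[1:224, 1:224])
})

test_that("ROI extraction is deterministic across runs", {
  rg <- gradientRegion(700, 800, c(200, 250, 430, 520))
  a <- extractMulticontextROIs(rg)
  b <- extractMulticontextROIs(rg)
  expect_identical(roiList(a), roiList(b))
  expect_identical(roiProvenance(a), roiProvenance(b))
})
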