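test_that("binning identity: one event lands in exactly one pixel", {
  ev <- miniEvents(cbind(12.5, 37.5), fieldSize = c(100, 100))
  img <- renderEvents(ev, pixelSize = 5, kernelSigma = 0)
  px <- pixelMatrix(img)
  expect_equal(sum(px > 0), 1L)
  ## half-open convention: x = 12.5 -> column 3 (0-based 2), y -> row 8
  expect_equal(px[8, 3], 1)
  ## an event exactly on the upper bound stays in the last pixel
  imgB <- renderEvents(miniEvents(cbind(100, 100)), pixelSize = 5,
                       kernelSigma = 0)
  expect_equal(pixelMatrix(imgB)[20, 20], 1)
})

test_that("rendering conserves mass for any kernel and weights", {
  set.seed(5)
  for (sigma in c(0, 5, 10, 25)) {
    xy <- cbind(runif(500, 0, 400), runif(500, 0, 400))
    w <- runif(500, 0.5, 3)
    ev <- miniEvents(xy, fieldSize = c(400, 400), weight = w)
    img <- renderEvents(ev, pixelSize = 5, kernelSigma = sigma)
    expect_lt(abs(sum(pixelMatrix(img)) - sum(w)) / sum(w), 1e-9)
  }
  ## empty table renders a zero image of the right shape
  e0 <- miniEvents(matrix(numeric(0), 0, 2), fieldSize = c(200, 300))
  i0 <- renderEvents(e0)
  expect_equal(dim(pixelMatrix(i0)), c(60, 40))
  expect_true(all(pixelMatrix(i0) == 0))
})

test_that("rendering is translation-equivariant for interior events", {
  set.seed(8)
  xy <- cbind(runif(60, 150, 250), runif(60, 150, 250))
  ev1 <- miniEvents(xy, fieldSize = c(400, 400))
  ev2 <- miniEvents(xy + 50, fieldSize = c(400, 400))  # 10 pixels
  p1 <- pixelMatrix(renderEvents(ev1, pixelSize = 5, kernelSigma = 8))
  p2 <- pixelMatrix(renderEvents(ev2, pixelSize = 5, kernelSigma = 8))
  expect_equal(p2[11:80, 11:80], p1[1:70, 1:70], tolerance = 1e-12)
})

test_that("out-of-bounds events are reported by row", {
  ev <- new("EventTable",
            events = data.frame(x_nm = c(10, 20), y_nm = c(10, 20),
                                frame = c(0L, 0L), weight = c(1, 1)),
            fieldSize = c(100, 100), source = "simulated")
  ev@events$x_nm[2] <- 500   # bypass constructor validation
  expect_error(renderEvents(ev), "rows: 2")
})

test_that("quantization respects 16 bits and records its scale", {
  set.seed(9)
  ev <- miniEvents(cbind(runif(2000, 0, 300), runif(2000, 0, 300)),
                   fieldSize = c(300, 300))
  img <- renderEvents(ev, kernelSigma = 10)
  q <- quantizeImage(img)
  expect_true(all(pixelMatrix(q) >= 0 & pixelMatrix(q) <= 65535))
  expect_true(q@quantized)
  ## scale maps the 99.9th percentile to ~60000
  pos <- pixelMatrix(img)[pixelMatrix(img) > 0]
  expect_equal(as.numeric(quantile(pos, 0.999)) * q@intensityScale, 60000,
               tolerance = 1e-6)
  back <- toDensity(q)
  expect_lt(max(abs(pixelMatrix(back) - pixelMatrix(img))),
            1 / q@intensityScale)
})

test_that("quantized images round-trip losslessly through TIFF", {
  set.seed(10)
  ev <- miniEvents(cbind(runif(500, 0, 200), runif(500, 0, 200)),
                   fieldSize = c(200, 200))
  q <- quantizeImage(renderEvents(ev, kernelSigma = 10))
  tmp <- tempfile(fileext = ".tif")
  writeRenderedTiff(q, tmp)
  back <- readRenderedTiff(tmp)
  expect_identical(pixelMatrix(back), pixelMatrix(q))
  expect_equal(pixelSize(back), pixelSize(q))
  expect_equal(back@intensityScale, q@intensityScale)
})

test_that("threshold policies behave on constant, two-level and real images", {
  const <- new("RenderedImage", pixels = matrix(3.5, 10, 10), pixelSize = 5,
               intensityScale = NA_real_, quantized = FALSE)
  expect_equal(estimateThreshold(const, "percentile", 70), 3.5)
  two <- new("RenderedImage",
             pixels = matrix(rep(c(1, 9), each = 50), 10, 10), pixelSize = 5,
             intensityScale = NA_real_, quantized = FALSE)
  thr <- estimateThreshold(two, "otsu")
  expect_gt(thr, 1); expect_lt(thr, 9)
  ## density policy: an absolute physical scale
  expect_equal(estimateThreshold(const, "density", value = 1,
                                 footprint = 900), 25 / 900)
  expect_equal(estimateThreshold(const, "fixed", value = 2.2), 2.2)
  zero <- new("RenderedImage", pixels = matrix(0, 5, 5), pixelSize = 5,
              intensityScale = NA_real_, quantized = FALSE)
  expect_error(estimateThreshold(zero, "percentile"), "no signal")
})

test_that("default threshold separates channel pixels from background", {
  cfg <- simConfig(fieldSize = c(4000, 4000), labelingEfficiency = 1,
                   seed = 31)
  sc <- buildScene(cfg)
  img <- renderEvents(simulateEvents(sc), kernelSigma = 7.5)
  thr <- estimateThreshold(img, "density")
  mask <- pixelMatrix(img) >= thr
  ## true channel-bearing pixels
  tmask <- matrix(FALSE, nrow(mask), ncol(mask))
  for (i in seq_len(nrow(sc@channels))) {
    x <- sc@channels[i, 1]; y <- sc@channels[i, 2]
    cs <- max(1, ceiling((x - 15) / 5)):min(ncol(mask), ceiling((x + 15) / 5))
    rs <- max(1, ceiling((y - 15) / 5)):min(nrow(mask), ceiling((y + 15) / 5))
    tmask[rs, cs] <- TRUE
  }
  ## ~14% of channel-bearing pixels carry too little blink mass to clear
  ## one event per footprint (geometric blink statistics), so recovery
  ## plateaus just under 0.9 at the default detection threshold
  expect_gt(sum(mask & tmask) / sum(tmask), 0.85)   # channel recovery
  expect_lt(sum(mask & !tmask) / sum(!tmask), 0.05) # background leakage
})
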