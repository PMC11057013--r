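vocFixture <- function(path, objects) {
  lines <- c("<annotation>", "<filename>fix.png</filename>",
             "<size><width>200</width><height>400</height><depth>3</depth></size>")
  for (o in objects)
    lines <- c(lines, "<object>", sprintf("<name>%s</name>", o$name),
               sprintf("<bndbox><xmin>%s</xmin><ymin>%s</ymin><xmax>%s</xmax><ymax>%s</ymax></bndbox>",
                       o$xmin, o$ymin, o$xmax, o$ymax), "</object>")
  writeLines(c(lines, "</annotation>"), path)
  path
}

test_that("VOC XML reading maps corners to centers and validates classes", {
  f <- withr::local_tempfile(fileext = ".xml")
  vocFixture(f, list(list(name = "G", xmin = 10, ymin = 10, xmax = 30, ymax = 50),
                     list(name = "G", xmin = 50, ymin = 50, xmax = 70, ymax = 70),
                     list(name = "G", xmin = 100, ymin = 100, xmax = 120, ymax = 140),
                     list(name = "R", xmin = 5, ymin = 5, xmax = 25, ymax = 25)))
  ann <- readVocXml(f)
  expect_equal(nrow(ann$boxes), 4)
  cen <- labelCensus(ann$boxes)
  expect_equal(c(cen$n_G, cen$n_R, cen$total), c(3, 1, 4))
  expect_equal(unlist(ann$boxes[1, c("cx", "cy", "w", "h")], use.names = FALSE),
               c(20, 30, 20, 40))
  # empty object list
  f2 <- withr::local_tempfile(fileext = ".xml")
  vocFixture(f2, list())
  expect_equal(nrow(readVocXml(f2)$boxes), 0)
  # unknown class is a labeled error
  f3 <- withr::local_tempfile(fileext = ".xml")
  vocFixture(f3, list(list(name = "weed", xmin = 1, ymin = 1, xmax = 5, ymax = 5)))
  expect_error(readVocXml(f3), "weed")
})

test_that("YOLO txt export normalizes and round-trips", {
  ann <- tinyAnn(makeBoxes(100, 200, 20, 40, "G"), H = 400, W = 200)
  f <- withr::local_tempfile(fileext = ".txt")
  writeYoloTxt(ann, f)
  expect_equal(readLines(f), "0 0.500000 0.500000 0.100000 0.100000")
  rb <- readYoloTxt(f, width = 200, height = 400)
  expect_equal(rb$cx, 100); expect_equal(rb$h, 40); expect_equal(rb$cls, "G")
  # empty annotation produces an empty file
  f2 <- withr::local_tempfile(fileext = ".txt")
  writeYoloTxt(tinyAnn(makeBoxes()), f2)
  expect_length(readLines(f2), 0)
  expect_equal(nrow(readYoloTxt(f2)), 0)
})

test_that("VOC -> YOLO -> VOC round trip preserves boxes within a pixel", {
  set.seed(7)
  b <- makeBoxes(c(40.5, 120, 77), c(60, 200.25, 333), c(30, 44, 21),
                 c(18, 62, 40), c("G", "R", "G"))
  ann <- tinyAnn(b, H = 400, W = 200)
  d <- withr::local_tempdir()
  writeVocXml(ann, file.path(d, "a.xml"))
  meta <- readVocXml(file.path(d, "a.xml"))
  writeYoloTxt(AnnotatedImage(imageData(ann), meta$boxes, "a"),
               file.path(d, "a.txt"))
  back <- readYoloTxt(file.path(d, "a.txt"), width = 200, height = 400)
  expect_equal(back[, 1:4], b[, 1:4], tolerance = 1 / 200)
  expect_equal(back$cls, b$cls)
})

test_that("resize scales boxes by the image factors", {
  # 1/8-scale stand-in for the capture-resolution to working-resolution step
  b <- makeBoxes(c(252, 100), c(113, 50), c(60, 30), c(40, 20), c("G", "R"))
  r <- resizeWithBoxes(AnnotatedImage(array(0.5, c(227, 504, 3)), b, "big"),
                       175, 79)
  expect_equal(dim(imageData(r))[1:2], c(79L, 175L))
  expect_equal(boxes(r)$cx, b$cx * 175 / 504)
  expect_equal(boxes(r)$cy, b$cy * 79 / 227)
  expect_equal(boxes(r)$w, b$w * 175 / 504)
  # identity resize leaves boxes unchanged; centered boxes stay centered
  small <- tinyAnn(makeBoxes(32, 32, 10, 10, "G"), H = 64, W = 64)
  ri <- resizeWithBoxes(small, 64, 64)
  expect_equal(boxes(ri), boxes(small))
  rc <- resizeWithBoxes(small, 128, 96)
  expect_equal(boxes(rc)$cx, 64); expect_equal(boxes(rc)$cy, 48)
})

test_that("dataset split is seeded, disjoint and exhaustive with 9:1 sizes", {
  s <- splitDataset(seq_len(10), 0.9, seed = 3)
  expect_length(s$train, 9); expect_length(s$test, 1)
  big <- splitDataset(seq_len(12000), 0.9, seed = 3)
  expect_length(big$train, 10800); expect_length(big$test, 1200)
  expect_setequal(c(big$train, big$test), seq_len(12000))
  expect_length(intersect(big$train, big$test), 0)
  expect_identical(splitDataset(seq_len(100), 0.9, seed = 5),
                   splitDataset(seq_len(100), 0.9, seed = 5))
  expect_error(splitDataset(integer(), 0.9, 1), "empty")
})

test_that("label census counts classes and is additive over shards", {
  expect_equal(labelCensus(character())$total, 0)
  a <- labelCensus(c("G", "G", "R"))
  b <- labelCensus(makeBoxes(1:2, 1:2, 1, 1, c("R", "R")))
  expect_equal(a$total, 3); expect_equal(b$n_R, 2)
  pooled <- labelCensus(list(c("G", "G", "R"), makeBoxes(1:2, 1:2, 1, 1, c("R", "R"))))
  expect_equal(pooled$n_G, a$n_G + b$n_G)
  expect_equal(pooled$n_R, a$n_R + b$n_R)
  expect_equal(pooled$total, pooled$n_G + pooled$n_R)
})

test_that("PNG image io round-trips", {
  img <- array(runif(32 * 48 * 3), c(32, 48, 3))
  f <- withr::local_tempfile(fileext = ".png")
  writeImagePNG(img, f)
  back <- readImagePNG(f)
  expect_identical(dim(back), c(32L, 48L, 3L))
  expect_equal(back, img, tolerance = 1 / 255)
})
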