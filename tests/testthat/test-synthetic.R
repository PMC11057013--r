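test_that("scenes honor pod counts, rotten fraction and determinism", {
  sp <- sceneSpec(nPods = 20, rottenFraction = 0.25, adhesion = "none",
                  width = 480L, height = 480L, seed = 31L)
  sc <- generateScene(sp)
  cen <- labelCensus(boxes(sc))
  expect_equal(nrow(boxes(sc)), 20)          # annotation per drawn pod
  expect_equal(cen$n_R, 5)                   # round(20 * 0.25)
  expect_equal(cen$n_G, 15)
  all_g <- generateScene(sceneSpec(nPods = 6, rottenFraction = 0,
                                   width = 256L, height = 256L, seed = 3L))
  expect_true(all(boxes(all_g)$cls == "G"))
  sc2 <- generateScene(sp)
  expect_identical(imageData(sc), imageData(sc2))
  expect_identical(boxes(sc), boxes(sc2))
})

test_that("adhesion strata constrain pairwise box overlap as specified", {
  ns <- asNamespace("podrot")
  pairIoUs <- function(sc) {
    m <- ns$iouMatrix(boxes(sc), boxes(sc)); diag(m) <- 0; m[upper.tri(m)]
  }
  for (sd in 1:5) {
    none <- pairIoUs(generateScene(sceneSpec(8, 0.3, "none", seed = sd,
                                             width = 320L, height = 320L)))
    expect_equal(max(none), 0)
    sl <- pairIoUs(generateScene(sceneSpec(8, 0.3, "slight", seed = sd,
                                           width = 320L, height = 320L)))
    expect_gt(max(sl), 0)
    expect_lte(max(sl), 0.3)
    sv <- pairIoUs(generateScene(sceneSpec(8, 0.3, "severe", seed = sd,
                                           width = 320L, height = 320L)))
    expect_gt(max(sv), 0.3)
  }
})

test_that("infeasible placement raises a placement error", {
  expect_error(generateScene(sceneSpec(nPods = 200, adhesion = "none",
                                       width = 64L, height = 64L, seed = 1L),
                             maxTries = 20L),
               "placement error")
})

test_that("validation sets are stratified and reproducible", {
  s <- generateValidationSet(2, sceneSpec(nPods = 5, width = 128L, height = 128L),
                             seed = 8)
  expect_length(s, 6)
  expect_equal(table(attr(s, "stratum"))[c("none", "slight", "severe")],
               table(rep(c("none", "slight", "severe"), each = 2))[
                 c("none", "slight", "severe")])
  s2 <- generateValidationSet(2, sceneSpec(nPods = 5, width = 128L, height = 128L),
                              seed = 8)
  expect_identical(lapply(s, imageData), lapply(s2, imageData))
})

test_that("pooled rotten fraction matches the per-scene rounding exactly", {
  specs <- lapply(1:200, function(i)
    sceneSpec(nPods = 10, rottenFraction = 0.3, adhesion = "none",
              width = 160L, height = 160L, seed = i))
  counts <- vapply(specs, function(sp) {
    # counts are fixed before drawing, so read them from a cheap small scene
    cen <- labelCensus(boxes(generateScene(sp)))
    c(cen$n_R, cen$total)
  }, c(0, 0))
  expect_equal(sum(counts[1, ]) / sum(counts[2, ]), 0.3)
})

test_that("ground-truth grading closes the loop to the grading module", {
  sc15 <- generateScene(sceneSpec(nPods = 20, rottenFraction = 0.25,
                                  adhesion = "none", width = 480L,
                                  height = 480L, seed = 31L))
  g <- groundTruthGrading(list(sc15))
  expect_equal(g$rate, 0.25)
  expect_equal(g$grade, 5L)
  allR <- generateScene(sceneSpec(nPods = 5, rottenFraction = 1,
                                  adhesion = "none", width = 256L,
                                  height = 256L, seed = 2L))
  allG <- generateScene(sceneSpec(nPods = 5, rottenFraction = 0,
                                  adhesion = "none", width = 256L,
                                  height = 256L, seed = 2L))
  gg <- groundTruthGrading(list(allR, allG))
  expect_equal(gg$grade, c(9L, 1L))
})

test_that("scene sets round-trip through disk with exact annotations", {
  s <- smallSceneSet(1)
  d <- withr::local_tempdir()
  man <- writeSceneSet(s, d)
  expect_equal(nrow(man), 3)
  expect_true(all(c("stratum", "rate", "grade") %in% names(man)))
  xmls <- list.files(d, pattern = "\\.xml$", full.names = TRUE)
  expect_length(xmls, 3)
  meta <- readVocXml(xmls[1])
  expect_equal(nrow(meta$boxes), nrow(boxes(s[[1]])))
  expect_equal(meta$boxes$cx, boxes(s[[1]])$cx, tolerance = 1e-6)
  img <- readImagePNG(file.path(d, "img0001.png"))
  expect_equal(dim(img), dim(imageData(s[[1]])))
})
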