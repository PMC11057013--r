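test_that("greedy matching assigns TP/FP/FN per class", {
  gt <- makeBoxes(c(10, 30, 50), c(10, 30, 50), 8, 8, c("G", "G", "R"))
  perfect <- gt; perfect$conf <- 1
  m <- matchDetections(perfect, gt)
  expect_equal(sum(m$tp), 3); expect_equal(sum(m$fp), 0); expect_equal(sum(m$fn), 0)
  # a far-away prediction is FP and every truth unmatched
  far <- makeBoxes(200, 200, 8, 8, "G", conf = 0.9)
  m2 <- matchDetections(far, gt)
  expect_equal(sum(m2$fp), 1); expect_equal(sum(m2$fn), 3)
  # two predictions on one truth: higher confidence claims it
  dup <- makeBoxes(c(10, 10.5), c(10, 10), 8, 8, "G", conf = c(0.7, 0.9))
  m3 <- matchDetections(dup, makeBoxes(10, 10, 8, 8, "G"))
  expect_equal(unname(m3$tp["G"]), 1); expect_equal(unname(m3$fp["G"]), 1)
  expect_equal(m3$matches$pred, 1)   # rank-1 (conf 0.9) prediction matched
  # counts are consistent with totals per class
  expect_equal(unname(m$tp["G"] + m$fn["G"]), 2)
  expect_equal(unname(m$tp["R"] + m$fn["R"]), 1)
})

test_that("precision and recall are percentage ratios, scale invariant", {
  expect_equal(precisionPct(9, 1), 90)
  expect_equal(precisionPct(0, 5), 0)
  expect_equal(precisionPct(7, 0), 100)
  expect_equal(recallPct(9, 1), 90)
  expect_equal(recallPct(0, 3), 0)
  expect_equal(recallPct(4, 0), 100)
  expect_equal(precisionPct(90, 10), precisionPct(9, 1))
  expect_equal(recallPct(45, 5), recallPct(9, 1))
  expect_error(precisionPct(0, 0), "undefined")
  expect_error(recallPct(0, 0), "undefined")
})

test_that("average precision matches the brute-force envelope oracle", {
  expect_equal(averagePrecision(1, TRUE, 1), 1)
  expect_equal(averagePrecision(c(0.9, 0.8), c(FALSE, FALSE), 3), 0)
  set.seed(55)
  for (i in 1:500) {
    nGt <- sample(1:10, 1)
    nPred <- sample(1:10, 1)
    conf <- runif(nPred)
    isTp <- runif(nPred) < 0.6
    # cannot have more TPs than truths
    if (sum(isTp) > nGt) isTp[which(isTp)[-seq_len(nGt)]] <- FALSE
    expect_equal(averagePrecision(conf, isTp, nGt),
                 bruteForceAP(conf, isTp, nGt), tolerance = 1e-9)
  }
})

test_that("all-point AP integrates the envelope over recall", {
  # 3 gt, 4 preds: TP TP FP TP by confidence rank
  conf <- c(0.9, 0.8, 0.7, 0.6); isTp <- c(TRUE, TRUE, FALSE, TRUE)
  # exact hand value: P(r) envelope = 1 up to r=2/3, then 3/4
  expect_equal(averagePrecision(conf, isTp, 3, interpolation = "allpoint"),
               2 / 3 * 1 + 1 / 3 * 3 / 4, tolerance = 1e-12)
})

test_that("mean AP averages class APs on the percent scale", {
  expect_equal(meanAveragePrecision(c(0.8, 1.0)), 90)
  expect_equal(meanAveragePrecision(c(0.73, 0.73)), 73)
  expect_equal(meanAveragePrecision(c(0.2, 0.9)), meanAveragePrecision(c(0.9, 0.2)))
  expect_error(meanAveragePrecision(numeric()), "empty")
})

test_that("image-level correctness demands zero FP and FN in both classes", {
  gt <- makeBoxes(c(10, 30), c(10, 30), 8, 8, c("G", "R"))
  perfect <- gt; perfect$conf <- 1
  expect_true(imageLevelCorrect(perfect, gt))
  expect_false(imageLevelCorrect(perfect[1, ], gt))               # one missed
  extra <- rbind(perfect, makeBoxes(60, 60, 8, 8, "G", conf = 0.8))
  expect_false(imageLevelCorrect(extra, gt))                      # one spurious
  # right class, wrong location
  moved <- perfect; moved$cx[1] <- 100
  expect_false(imageLevelCorrect(moved, gt))
})

test_that("comparison precision reproduces the printed image-level accuracies", {
  expect_equal(comparisonPrecision(142, 150), 94.67)
  expect_equal(comparisonPrecision(50, 50), 100)
  expect_equal(comparisonPrecision(0, 25), 0)
  expect_error(comparisonPrecision(5, 0), "RS")
  expect_error(comparisonPrecision(10, 5), "AS")
})

test_that("k-fold splits partition all items reproducibly", {
  f <- kfoldSplits(10, 5, seed = 4)
  expect_length(f, 5)
  expect_true(all(lengths(lapply(f, `[[`, "validation")) == 2))
  vals <- unlist(lapply(f, `[[`, "validation"))
  expect_setequal(vals, 1:10)
  expect_length(vals, 10)
  for (k in seq_along(f))
    expect_length(intersect(f[[k]]$train, f[[k]]$validation), 0)
  expect_identical(kfoldSplits(23, 5, seed = 9), kfoldSplits(23, 5, seed = 9))
  # uneven n spreads remainder
  f2 <- kfoldSplits(23, 5, seed = 9)
  expect_setequal(unlist(lapply(f2, `[[`, "validation")), 1:23)
  expect_true(all(lengths(lapply(f2, `[[`, "validation")) %in% 4:5))
  expect_error(kfoldSplits(3, 5), "at least")
  expect_error(kfoldSplits(10, 1), "k must")
})

test_that("dataset evaluation of a perfect detector is 100% across the board", {
  scenes <- smallSceneSet(2)
  gts <- lapply(scenes, boxes)
  preds <- lapply(gts, function(g) { g$conf <- 1; g })
  ev <- evaluateDetections(preds, gts)
  expect_equal(ev$precision, 100)
  expect_equal(ev$recall, 100)
  expect_equal(ev$mAP, 100)
  expect_equal(ev$cp, 100)
  expect_equal(unname(ev$tally["AS"]), length(scenes))
})

test_that("dataset evaluation degrades sensibly for an imperfect detector", {
  scenes <- smallSceneSet(2)
  gts <- lapply(scenes, boxes)
  # drop one pod per image and add one far spurious box
  preds <- lapply(gts, function(g) {
    g$conf <- 0.9
    g <- g[-1, , drop = FALSE]
    rbind(g, makeBoxes(5, 5, 4, 4, "G", conf = 0.3))
  })
  ev <- evaluateDetections(preds, gts)
  expect_lt(ev$cp, 100)
  expect_lt(ev$recall, 100)
  expect_lt(ev$mAP, 100)
  expect_equal(unname(ev$tally["RS"]), length(scenes))
})
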