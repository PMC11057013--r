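test_that("IoU matches hand geometry and the rasterization oracle", {
  a <- makeBoxes(1, 1, 2, 2, "G"); b <- makeBoxes(2, 2, 2, 2, "G")
  expect_equal(boxIoU(a, b), 1 / 7, tolerance = 1e-12)
  expect_equal(boxIoU(b, a), boxIoU(a, b))          # symmetry
  expect_equal(boxIoU(a, a), 1)
  expect_equal(boxIoU(a, makeBoxes(10, 10, 2, 2, "G")), 0)
  set.seed(101)
  err <- vapply(1:200, function(i) {
    p <- randomBox(); q <- randomBox()
    abs(boxIoU(p, q) - rasterIoU(p, q))
  }, 0)
  expect_lt(max(err), 1e-3)
})

test_that("invalid boxes are rejected", {
  expect_error(makeBoxes(0, 0, -1, 2, "G"), "invalid box")
  expect_error(boxIoU(list(cx = 0, cy = 0, w = 0, h = 1),
                      list(cx = 0, cy = 0, w = 1, h = 1)), "invalid box")
})

test_that("regression terms reproduce the hand-derived disjoint-pair case", {
  t <- boxRegressionTerms(makeBoxes(0, 0, 2, 2, "G"), makeBoxes(10, 0, 2, 2, "G"))
  expect_equal(t$iou, 0)
  expect_equal(t$alpha, 0)                 # alpha = 0 branch since IoU < 0.5
  expect_equal(t$center_dist_sq, 100)
  expect_equal(t$enclosure_w, 12)
  expect_equal(t$enclosure_h, 2)
  expect_equal(t$enclosure_diag_sq, 148)
  # identical boxes: all distance terms collapse
  t0 <- boxRegressionTerms(makeBoxes(3, 4, 2, 5, "G"), makeBoxes(3, 4, 2, 5, "G"))
  expect_equal(t0$iou, 1)
  expect_equal(t0$center_dist_sq, 0)
  expect_equal(t0$enclosure_diag_sq, 0)
  expect_equal(t0$v, 0)
  # equal aspect ratio kills v
  tv <- boxRegressionTerms(makeBoxes(0, 0, 2, 4, "G"), makeBoxes(9, 9, 3, 6, "G"))
  expect_equal(tv$v, 0)
  # alpha in [0, 1] with high overlap
  th <- boxRegressionTerms(makeBoxes(0, 0, 4, 4, "G"), makeBoxes(0.2, 0, 4, 5, "G"))
  expect_gt(th$iou, 0.5)
  expect_gt(th$alpha, 0)
  expect_lte(th$alpha, 1)
  expect_equal(th$alpha, th$v / (1 - th$iou + th$v))
})

test_that("geometric term invariants hold on random pairs", {
  set.seed(202)
  for (i in 1:100) {
    p <- randomBox(); q <- randomBox()
    t <- boxRegressionTerms(p, q)
    expect_gte(t$iou, 0); expect_lte(t$iou, 1)
    expect_lte(t$center_dist_sq, t$enclosure_diag_sq + 1e-9)
    expect_gte(t$enclosure_w, abs(p$cx - q$cx))
    expect_gte(t$v, 0)
  }
})

test_that("CIoU loss matches its closed form and vanishes only at identity", {
  expect_equal(ciouLoss(makeBoxes(3, 4, 2, 5, "G"), makeBoxes(3, 4, 2, 5, "G")), 0)
  expect_equal(ciouLoss(makeBoxes(0, 0, 2, 2, "G"), makeBoxes(10, 0, 2, 2, "G")),
               1 + 100 / 148, tolerance = 1e-9)
  # concentric same-aspect boxes: only the IoU complement survives
  p <- makeBoxes(5, 5, 2, 2, "G"); g <- makeBoxes(5, 5, 4, 4, "G")
  expect_equal(ciouLoss(p, g), 1 - boxIoU(p, g), tolerance = 1e-9)
  set.seed(303)
  for (i in 1:50) {
    p <- randomBox(); q <- randomBox()
    if (all(unlist(p[1:4]) == unlist(q[1:4]))) next
    expect_gt(ciouLoss(p, q), 0)
  }
})

test_that("EIoU loss matches its closed form, reduces correctly, is symmetric", {
  expect_equal(eiouLoss(makeBoxes(1, 2, 3, 4, "G"), makeBoxes(1, 2, 3, 4, "G")), 0)
  expect_equal(eiouLoss(makeBoxes(0, 0, 2, 2, "G"), makeBoxes(0, 0, 4, 4, "G")),
               1.25, tolerance = 1e-6)
  set.seed(404)
  for (i in 1:50) {
    p <- randomBox()
    # equal-size boxes: width/height terms vanish; also equals CIoU there
    q <- p; q$cx <- p$cx + runif(1, -3, 3); q$cy <- p$cy + runif(1, -3, 3)
    t <- boxRegressionTerms(p, q)
    expect_equal(eiouLoss(p, q),
                 1 - t$iou + t$center_dist_sq / (t$enclosure_diag_sq + 1e-9),
                 tolerance = 1e-9)
    expect_equal(eiouLoss(p, q), ciouLoss(p, q), tolerance = 1e-9)
    # symmetry in the arguments
    r <- randomBox()
    expect_equal(eiouLoss(p, r), eiouLoss(r, p), tolerance = 1e-12)
  }
})

test_that("EIoU loss is monotone under translation away from the target", {
  gt <- makeBoxes(0, 0, 4, 3, "G")
  shifts <- seq(0, 30, by = 0.5)
  losses <- vapply(shifts, function(s)
    eiouLoss(makeBoxes(s, 0, 4, 3, "G"), gt), 0)
  expect_true(all(diff(losses) >= -1e-12))
})

test_that("focal weighting recovers EIoU at gamma 0 and gates by IoU", {
  p <- makeBoxes(0, 0, 2, 2, "G"); g <- makeBoxes(1, 1, 2, 2, "G")
  expect_equal(focalEiouLoss(p, g, gamma = 0), eiouLoss(p, g))
  expect_equal(focalEiouLoss(p, makeBoxes(50, 50, 2, 2, "G"), gamma = 0.5), 0)
  expect_equal(focalEiouLoss(p, p, gamma = 2), 0)
  expect_error(focalEiouLoss(p, g, gamma = -1), "gamma")
})

test_that("total loss is the weighted sum of its components", {
  expect_equal(totalLoss(list(l_cla = 0, l_loc = 0, l_conf = 0)), 0)
  expect_equal(totalLoss(list(l_cla = 0.1, l_loc = 0.2, l_conf = 0.3)), 0.6)
  expect_equal(totalLoss(list(l_cla = 0.3, l_loc = 0.1, l_conf = 0.2)), 0.6)
  expect_equal(totalLoss(list(l_cla = 1, l_loc = 2, l_conf = 4),
                         weights = c(2, 1, 0.5)), 6)
  expect_error(totalLoss(list(l_cla = -1, l_loc = 0, l_conf = 0)), "invalid loss")
})
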