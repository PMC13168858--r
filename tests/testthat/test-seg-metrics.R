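test_that("overlap scores match hand-counted examples and conventions", {
  a <- rect_mask(20, 20, 1:10, 1:10)
  b <- rect_mask(20, 20, 6:15, 1:10)   # 5x10 overlap of two 10x10 squares
  expect_equal(overlap_scores(a, b), c(dice = 0.5, iou = 1 / 3))
  expect_equal(overlap_scores(a, a), c(dice = 1, iou = 1))
  expect_equal(overlap_scores(a, rect_mask(20, 20, 11:20, 11:20)),
               c(dice = 0, iou = 0))
  empty <- matrix(FALSE, 4, 4)
  expect_equal(overlap_scores(empty, empty), c(dice = 1, iou = 1))
  expect_equal(overlap_scores(empty, rect_mask(4, 4, 1, 1)),
               c(dice = 0, iou = 0))
  expect_error(overlap_scores(a, matrix(FALSE, 3, 3)), "shape")
})

test_that("overlap scores are symmetric with dice >= iou", {
  set.seed(42)
  for (i in 1:100) {
    a <- rand_mask(); b <- rand_mask()
    s1 <- overlap_scores(a, b); s2 <- overlap_scores(b, a)
    expect_identical(s1, s2)
    expect_gte(s1[["dice"]], s1[["iou"]])
  }
})

test_that("Hungarian matching equals the exhaustive optimum (<= 6 instances)", {
  set.seed(7)
  for (rep in 1:25) {
    np <- sample(1:6, 1); nt <- sample(1:6, 1)
    preds <- replicate(np, rand_mask(8, 8, 0.4), simplify = FALSE)
    truths <- replicate(nt, rand_mask(8, 8, 0.4), simplify = FALSE)
    iou <- outer(seq_len(np), seq_len(nt),
                 Vectorize(function(i, j)
                   overlap_scores(preds[[i]], truths[[j]])[["iou"]]))
    got <- match_instances(preds, truths, iou_threshold = 1e-9)
    expect_equal(sum(got$pairs$iou), brute_best_iou(iou), tolerance = 1e-12)
  }
})

test_that("matching applies the IoU threshold and handles edge cases", {
  a <- rect_mask(10, 10, 1:5, 1:10)       # 50 px
  b <- rect_mask(10, 10, 3:7, 1:10)       # IoU 30/70 = 0.43 < 0.5
  m <- match_instances(list(a), list(b), iou_threshold = 0.5)
  expect_equal(nrow(m$pairs), 0)
  expect_equal(m$false_positives, 1L)
  expect_equal(m$false_negatives, 1L)
  m2 <- match_instances(list(a), list(a))
  expect_equal(m2$pairs$iou, 1)
  expect_length(m2$false_positives, 0)
  empty <- match_instances(list(), list(a))
  expect_equal(nrow(empty$pairs), 0)
  expect_equal(empty$false_negatives, 1L)
  expect_error(match_instances(list(a), list(a), iou_threshold = 0), "0, 1")
})

test_that("COCO metrics reproduce hand-computed PR integration", {
  # perfect predictions at every IoU
  gt <- list(rect_mask(30, 30, 1:5, 1:5), rect_mask(30, 30, 10:15, 10:15))
  perfect <- lapply(gt, function(m) list(mask = m, confidence = 1))
  expect_equal(coco_detection_metrics(perfect, gt),
               c(ap50 = 100, ap50_95 = 100, ar50_95 = 100))
  # no predictions
  expect_equal(coco_detection_metrics(list(), gt),
               c(ap50 = 0, ap50_95 = 0, ar50_95 = 0))
  # no truths: undefined
  expect_true(all(is.na(coco_detection_metrics(perfect, list()))))

  # 3 truths; one prediction with IoU exactly 0.6, one false positive:
  # AP = 34/101 at thresholds 0.50/0.55/0.60, 0 above; AR = (3 * 1/3) / 10
  t1 <- rect_mask(10, 40, 1, 1:20)
  p1 <- rect_mask(10, 40, 1, 6:25)        # intersection 15, union 25
  t2 <- rect_mask(10, 40, 5, 1:10)
  t3 <- rect_mask(10, 40, 9, 1:10)
  fp <- rect_mask(10, 40, 5, 25:30)
  got <- coco_detection_metrics(
    list(list(mask = p1, confidence = 0.9), list(mask = fp, confidence = 0.8)),
    list(t1, t2, t3))
  expect_equal(got[["ap50"]], 100 * 34 / 101, tolerance = 1e-10)
  expect_equal(got[["ap50_95"]], 100 * 3 * (34 / 101) / 10, tolerance = 1e-10)
  expect_equal(got[["ar50_95"]], 10, tolerance = 1e-10)
})

test_that("ap50 >= ap50_95 for random prediction sets", {
  set.seed(11)
  for (rep in 1:10) {
    gt <- replicate(3, rand_mask(10, 10, 0.4), simplify = FALSE)
    preds <- lapply(gt, function(m) {
      noisy <- m
      flip <- sample(length(m), 8)
      noisy[flip] <- !noisy[flip]
      list(mask = noisy, confidence = runif(1))
    })
    got <- coco_detection_metrics(preds, gt)
    expect_gte(got[["ap50"]], got[["ap50_95"]])
  }
})

test_that("macro/micro aggregation matches pooled-pixel oracle", {
  # two classes, dice 1.0 and 0.0, equal pixel counts -> macro 0.5
  a <- rect_mask(10, 10, 1:5, 1:10)
  b <- rect_mask(10, 10, 6:10, 1:10)
  sc <- rbind(score_frame_masks(list(iris = a, pupil = a),
                                list(iris = a, pupil = b)))
  agg <- aggregate_structure_scores(sc)
  expect_equal(unname(agg$macro[["dice"]]), 50)
  # single class: macro == micro
  sc1 <- score_frame_masks(list(iris = a), list(iris = b))
  agg1 <- aggregate_structure_scores(sc1)
  expect_equal(agg1$macro, agg1$micro)
  # unequal pixel counts: micro equals direct pooling
  set.seed(5)
  scores <- do.call(rbind, lapply(1:4, function(i) {
    score_frame_masks(list(iris = rand_mask(9, 9, 0.5),
                           pupil = rand_mask(9, 9, 0.2)),
                      list(iris = rand_mask(9, 9, 0.5),
                           pupil = rand_mask(9, 9, 0.2)), image = i)
  }))
  agg2 <- aggregate_structure_scores(scores)
  ni <- sum(scores$n_intersect); np <- sum(scores$n_pred)
  ng <- sum(scores$n_truth)
  expect_equal(unname(agg2$micro[["dice"]]), 100 * 2 * ni / (np + ng))
  expect_equal(unname(agg2$micro[["iou"]]), 100 * ni / (np + ng - ni))
  expect_error(aggregate_structure_scores(NULL), "aggregate")
})
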