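test_that("trivial inputs pass through the filters", {
  expect_equal(length(postprocess(list())), 0L)
  d <- raw_detection(11, 0.9, rect_mask(1:3, 1:3, c(6, 6)))
  out <- postprocess(list(d))
  expect_length(out, 1L)
  expect_identical(out[[1]], d)
})

test_that("a same-mask duplicate with a different label is removed geometrically", {
  m <- rect_mask(2:5, 2:5, c(8, 8))
  dets <- list(raw_detection(26, 0.9, m), raw_detection(27, 0.8, m))
  out <- postprocess(dets)
  expect_length(out, 1L)
  expect_equal(out[[1]]$score, 0.9)
  expect_equal(out[[1]]$label, 26L)
  # ablating the geometric check lets both distinct labels survive
  out2 <- postprocess(dets, postprocess_config(geometric_filter = FALSE))
  expect_length(out2, 2L)
  expect_setequal(sapply(out2, `[[`, "label"), c(26L, 27L))
})

test_that("filter stages interact as in the four-detection fixture", {
  dim <- c(10, 20)
  mA <- rect_mask(1:5, 1:5, dim)
  mB <- rect_mask(1:5, 10:14, dim)  # disjoint from A
  A <- raw_detection(36, 0.95, mA)
  B <- raw_detection(36, 0.90, mB)
  C <- raw_detection(37, 0.85, mB)  # same mask as B
  D <- raw_detection(38, 0.40, rect_mask(7:9, 1:3, dim))
  dets <- list(A, B, C, D)
  # all filters: B falls to the duplicate-label check, which frees C to pass
  # the geometric check (B occupied nothing); D falls to the score filter
  out <- postprocess(dets)
  expect_equal(sapply(out, `[[`, "label"), c(36L, 37L))
  expect_equal(sapply(out, `[[`, "score"), c(0.95, 0.85))
  # duplicate filter ablated: B survives, C is now geometrically covered by B
  out2 <- postprocess(dets, postprocess_config(duplicate_filter = FALSE))
  expect_equal(sapply(out2, `[[`, "score"), c(0.95, 0.90))
  expect_equal(sapply(out2, `[[`, "label"), c(36L, 36L))
  expect_equal(attr(out2, "discarded")[["score"]], 1L)
  expect_equal(attr(out2, "discarded")[["geometric"]], 1L)
})

test_that("threshold boundaries and tie-breaking are deterministic", {
  dim <- c(6, 12)
  at_threshold <- raw_detection(11, 0.5, rect_mask(1:3, 1:3, dim))
  expect_length(postprocess(list(at_threshold)), 1L)  # score == 0.5 survives
  # novel fraction exactly at 0.5 survives
  base <- raw_detection(12, 0.9, rect_mask(1:4, 1:4, dim))
  half <- raw_detection(13, 0.8, rect_mask(1:4, 3:6, dim))  # 8 of 16 px new
  expect_length(postprocess(list(base, half)), 2L)
  # equal scores: ascending label code wins the earlier slot
  m1 <- rect_mask(1:3, 1:3, dim); m2 <- rect_mask(1:3, 7:9, dim)
  out <- postprocess(list(raw_detection(14, 0.7, m2), raw_detection(12, 0.7, m1)))
  expect_equal(sapply(out, `[[`, "label"), c(12L, 14L))
})

test_that("mismatched grids are rejected", {
  d1 <- raw_detection(11, 0.9, rect_mask(1:2, 1:2, c(6, 6)))
  d2 <- raw_detection(12, 0.8, rect_mask(1:2, 1:2, c(8, 8)))
  expect_error(postprocess(list(d1, d2)), "grid")
})

test_that("postprocess is idempotent and monotone under random fixtures", {
  set.seed(21)
  for (k in 1:120) {
    dets <- rand_detections(sample(0:8, 1))
    cfg <- rand_config()
    out <- postprocess(dets, cfg)
    # idempotence
    expect_equal(postprocess(out, cfg), out, ignore_attr = TRUE)
    # removing a non-selected input never changes the output
    if (length(dets) > length(out)) {
      sel_ids <- match(sapply(out, function(d) digest_det(d)),
                       sapply(dets, function(d) digest_det(d)))
      drop <- setdiff(seq_along(dets), sel_ids)[1]
      out_drop <- postprocess(dets[-drop], cfg)
      expect_equal(out_drop, out, ignore_attr = TRUE)
    }
    # raising the score threshold never enlarges the output
    cfg_hi <- postprocess_config(
      score_threshold = min(1, cfg$score_threshold + 0.2),
      novel_fraction_threshold = cfg$novel_fraction_threshold,
      score_filter = cfg$score_filter,
      duplicate_filter = cfg$duplicate_filter,
      geometric_filter = cfg$geometric_filter
    )
    expect_lte(length(postprocess(dets, cfg_hi)), length(out))
  }
})

test_that("duplicate-label ablation leaves the label set unchanged when the geometric filter is off", {
  set.seed(22)
  for (k in 1:60) {
    dets <- rand_detections(sample(1:8, 1))
    with_dup <- postprocess(dets, postprocess_config(geometric_filter = FALSE))
    no_dup <- postprocess(dets, postprocess_config(geometric_filter = FALSE,
                                                   duplicate_filter = FALSE))
    expect_setequal(unique(sapply(with_dup, `[[`, "label")),
                    unique(sapply(no_dup, `[[`, "label")))
  }
})

test_that("the greedy pass agrees with the brute-force oracle", {
  set.seed(23)
  for (k in 1:200) {
    dets <- rand_detections(sample(0:8, 1))
    cfg <- rand_config()
    expect_equal(postprocess(dets, cfg), oracle_postprocess(dets, cfg),
                 ignore_attr = TRUE)
  }
})
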