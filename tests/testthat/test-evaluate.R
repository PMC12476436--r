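test_that("greedy IoU matching assigns pairs one-to-one above the threshold", {
  ann <- toy_annotation()
  teeth <- reference_teeth(ann)
  dim <- c(20L, 40L)
  # identical mask -> matched at IoU 1; disjoint mask -> FP
  preds <- list(raw_detection(11, 0.9, teeth[[1]]$mask),
                raw_detection(13, 0.8, rect_mask(12:16, 30:38, dim)))
  m <- match_detections(preds, ann)
  expect_equal(nrow(m$pairs), 1L)
  expect_equal(m$pairs$iou, 1.0)
  expect_equal(m$pairs$ref_label, 11L)
  expect_equal(m$fp_label, 13L)
  expect_setequal(m$fn_label, c(21L, 36L, 47L))
  # two predictions over one reference: the higher-IoU one wins, other is FP
  big <- rect_mask(2:8, 2:8, dim)          # == reference 11, IoU 1
  part <- rect_mask(2:8, 2:5, dim)         # IoU 4/7 with reference 11
  m2 <- match_detections(list(raw_detection(11, 0.6, part),
                              raw_detection(11, 0.5, big)),
                         list(teeth[[1]]))
  expect_equal(m2$pairs$pred_index, 2L)
  expect_equal(m2$fp_index, 1L)
  expect_error(match_detections(preds, ann, iou_threshold = 0), "0, 1")
  expect_error(match_detections(preds, ann, iou_threshold = 1.5), "0, 1")
})

test_that("implants never count as reference teeth: overlap with them is FP", {
  dim <- c(20L, 40L)
  teeth <- lapply(all_fdi_codes(), function(code) {
    if (code == 11) reference_tooth(code, "tooth", rect_mask(2:8, 2:8, dim))
    else if (code == 21) reference_tooth(code, "implant")
    else reference_tooth(code, "missing")
  })
  ann <- reference_annotation(1L, 40L, 20L, teeth, c(upper = "I", lower = "I"))
  pred <- raw_detection(21, 0.9, rect_mask(2:8, 12:18, dim))  # implant region
  m <- match_detections(list(pred), ann)
  expect_equal(nrow(m$pairs), 0L)
  expect_equal(m$fp_label, 21L)
  expect_equal(m$fn_label, 11L)
})

test_that("the tooth confusion matrix books matches, misses and false detections", {
  ann <- toy_annotation()
  teeth <- reference_teeth(ann)
  # perfect prediction of the 4-tooth toy image
  perfect <- lapply(teeth, function(t) raw_detection(t$label, 0.95, t$mask))
  cm <- tooth_confusion(match_detections(perfect, ann))
  expect_equal(sum(diag(cm$counts[1:32, 1:32])), 4)
  expect_equal(sum(cm$counts["FP", ]), 0)
  expect_equal(sum(cm$counts[, "FN"]), 0)
  # a matched pair labeled 36 predicted as 37 lands off-diagonal
  mislab <- lapply(teeth, function(t) {
    raw_detection(if (t$label == 36) 37L else t$label, 0.95, t$mask)
  })
  cm2 <- tooth_confusion(match_detections(mislab, ann))
  expect_equal(cm2$counts["36", "37"], 1L)
  expect_equal(cm2$counts["36", "36"], 0L)
  # normalized rows sum to one where non-empty
  rs <- rowSums(cm2$counts)
  expect_true(all(abs(rowSums(cm2$normalized)[rs > 0] - 1) < 1e-12))
  expect_true(all(rowSums(cm2$normalized)[rs == 0] == 0))
})

test_that("scalar rates follow the stated definitions and stay undefined at 0/0", {
  r <- rates_from_counts(tp = 3, fp = 1, fn = 1, correct_label = 2,
                         total_positions = 32)
  expect_equal(r$sensitivity, 3 / 4)
  expect_equal(r$precision, 3 / 4)
  expect_equal(r$f1, 6 / 8)
  expect_equal(r$label_accuracy, 2 / 3)
  expect_equal(r$tn, 32 - 4 - 1)  # absent positions minus FP
  expect_equal(r$specificity, 27 / 28)
  degenerate <- rates_from_counts(0, 0, 0)
  expect_true(is.na(degenerate$sensitivity))
  expect_true(is.na(degenerate$precision))
  expect_true(is.na(degenerate$f1))
})

test_that("Kennedy confusion tallies jaws and rejects unknown classes", {
  all_eq <- kennedy_confusion(c("I", "II", "FULL"), c("I", "II", "FULL"))
  expect_equal(sum(diag(all_eq$counts)), 3)
  expect_equal(all_eq$accuracy, 1.0)
  one <- kennedy_confusion("II", "I")
  expect_equal(one$accuracy, 0)
  expect_equal(one$counts["I", "II"], 1L)
  expect_error(kennedy_confusion("V", "I"), "V")
  expect_error(kennedy_confusion(c("I", "II"), "I"), "length")
})

test_that("corpus evaluation keeps exact detection bookkeeping", {
  corpus <- simulate_corpus(25, noise = noise_config(seed = 41))
  out <- run_pipeline(corpus$detections, corpus$references)
  m <- out$report$metrics
  n_ref <- sum(vapply(corpus$references,
                      function(a) length(reference_teeth(a)), integer(1)))
  n_pred <- sum(lengths(out$filtered))
  expect_equal(m$tp + m$fn, n_ref)           # every reference tooth accounted
  expect_equal(m$tp + m$fp, n_pred)          # every prediction accounted
  expect_equal(m$correct_label + m$mislabeled, m$tp)
  cm <- out$report$tooth$counts
  expect_equal(sum(cm[1:32, ]), n_ref)       # reference rows sum to teeth
  expect_equal(sum(cm["FP", ]), m$fp)
  expect_equal(sum(cm[, "FN"]), m$fn)
  expect_equal(out$report$kennedy$n, 50L)
})

test_that("the ablation harness reports per-config counts", {
  clean <- simulate_corpus(6, noise = noise_config_zero(51))
  configs <- list(
    full = postprocess_config(),
    no_geometric = postprocess_config(geometric_filter = FALSE),
    no_duplicate = postprocess_config(duplicate_filter = FALSE),
    score_only = postprocess_config(duplicate_filter = FALSE,
                                    geometric_filter = FALSE)
  )
  tab <- ablation_run(clean$detections, clean$references, configs)
  # a corpus without duplicates or noise: the filters are no-ops
  expect_equal(length(unique(tab$n_selected)), 1L)
  expect_equal(length(unique(tab$tp)), 1L)
  expect_true(all(tab$kennedy_accuracy == 1))
  # a corpus of same-mask duplicates: ablating the geometric filter
  # strictly increases the surviving detections
  dup <- simulate_corpus(6, noise = noise_config(
    seed = 52, p_miss = 0, spurious_rate = 0, duplicate_rate = 1,
    same_mask_frac = 1, mislabel_prob = 0, mask_jitter_sd = 0,
    score_correct = c(9, 2), score_error = c(9, 2)
  ))
  tab2 <- ablation_run(dup$detections, dup$references, configs)
  expect_gt(tab2[tab2$config == "no_geometric", "n_selected"],
            tab2[tab2$config == "full", "n_selected"])
})
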