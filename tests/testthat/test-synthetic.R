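test_that("a fixed seed reproduces the corpus exactly", {
  c1 <- simulate_corpus(4, noise = noise_config(seed = 61))
  c2 <- simulate_corpus(4, noise = noise_config(seed = 61))
  expect_identical(serialize(c1, NULL), serialize(c2, NULL))
  c3 <- simulate_corpus(4, noise = noise_config(seed = 62))
  expect_false(identical(serialize(c1, NULL), serialize(c3, NULL)))
})

test_that("presence priors drive the dentition and the attached classes", {
  full <- generate_reference(4, noise = noise_config(seed = 63,
                                                     presence_prior = rep(1, 8)))
  for (ann in full) {
    expect_length(reference_teeth(ann), 32L)
    expect_equal(unname(ann$kennedy), c("FULL", "FULL"))
  }
  # second molars forced absent: every jaw is bilateral free-end
  prior <- rep(1, 8); prior[7] <- 0
  free_end <- generate_reference(4, noise = noise_config(seed = 64,
                                                         presence_prior = prior))
  for (ann in free_end) {
    expect_equal(unname(ann$kennedy), c("I", "I"))
  }
})

test_that("zero noise reproduces the reference detections verbatim", {
  corpus <- simulate_corpus(3, noise = noise_config_zero(65))
  for (i in seq_along(corpus$references)) {
    teeth <- reference_teeth(corpus$references[[i]])
    dets <- corpus$detections[[i]]
    expect_length(dets, length(teeth))
    expect_equal(sapply(dets, `[[`, "label"), sapply(teeth, `[[`, "label"))
    expect_true(all(sapply(dets, `[[`, "score") == 1))
    for (k in seq_along(teeth)) {
      expect_identical(dets[[k]]$mask$idx, teeth[[k]]$mask$idx)
    }
  }
})

test_that("extreme noise settings behave as configured", {
  refs <- generate_reference(2, noise = noise_config(seed = 66))
  # every tooth missed: empty detector output
  all_missed <- corrupt_to_detections(refs[[1]],
                                      noise_config(seed = 66, p_miss = 1,
                                                   spurious_rate = 0))
  expect_length(all_missed, 0L)
  # duplicate rate 1 in same-mask mode: each tooth appears twice with
  # identical masks and different labels; full post-processing restores
  # exactly one instance per tooth
  noise_dup <- noise_config(seed = 66, p_miss = 0, spurious_rate = 0,
                            duplicate_rate = 1, same_mask_frac = 1,
                            mislabel_prob = 0, mask_jitter_sd = 0,
                            score_correct = NULL, score_error = c(9, 2))
  dets <- corrupt_to_detections(refs[[1]], noise_dup)
  n_teeth <- length(reference_teeth(refs[[1]]))
  expect_length(dets, 2L * n_teeth)
  for (k in seq_len(n_teeth)) {
    a <- dets[[2 * k - 1]]; b <- dets[[2 * k]]
    expect_identical(a$mask$idx, b$mask$idx)
    expect_false(a$label == b$label)
  }
  kept <- postprocess(dets)
  expect_length(kept, n_teeth)
  expect_setequal(sapply(kept, `[[`, "label"),
                  sapply(reference_teeth(refs[[1]]), `[[`, "label"))
})

test_that("adjacent rendered teeth overlap slightly but far below the novel-fraction cut", {
  refs <- generate_reference(2, noise = noise_config(seed = 67,
                                                     presence_prior = rep(1, 8)))
  for (ann in refs) {
    teeth <- reference_teeth(ann)
    labs <- sapply(teeth, `[[`, "label")
    for (jaw in c("upper", "lower")) {
      arc <- jaw_arc(jaw)
      for (k in 1:15) {
        a <- teeth[[match(arc[k], labs)]]$mask
        b <- teeth[[match(arc[k + 1], labs)]]$mask
        frac <- length(intersect(a$idx, b$idx)) / min(mask_area(a), mask_area(b))
        expect_gt(frac, 0)
        expect_lt(frac, 0.4)
      }
    }
  }
})

test_that("invalid configurations are rejected", {
  expect_error(noise_config(p_miss = 1.2))
  expect_error(noise_config(presence_prior = rep(0.5, 7)))
  expect_error(scene_config(tooth_rx = rep(0, 8)))
  expect_error(ellipse_mask(5, 5, 0, 3, c(10, 10)), "degenerate")
})
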