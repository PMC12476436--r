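#' Synthetic panoramic scene geometry
#'
#' Layout parameters for rendered dentitions: each jaw's 16 positions are
#' placed at equal pitch along a shallow parabolic arc spanning the image
#' width (emulating the unfolded dental arch of a panoramic radiograph), and
#' every tooth is rendered as a filled ellipse sized by its morphological
#' class. Widths are chosen so that adjacent teeth overlap by a small
#' fraction of the smaller mask — far below the 50% novel-pixel cut of the
#' geometric filter, so correct detections always survive it. Realism is not
#' a goal; only the overlap topology that the filters and the matcher
#' discriminate on is emulated.
#'
#' @param width,height image grid size in pixels
#' @param margin horizontal margin before the first tooth center band
#' @param upper_y,lower_y vertical center of each jaw's arc at the midline
#' @param arch_curvature parabolic coefficient; tooth centers rise by
#'   `arch_curvature * dx^2` toward the image edges
#' @param tooth_ry vertical half-axis of every tooth ellipse
#' @param tooth_rx horizontal half-axes by tooth index 1..8 (central incisor
#'   to third molar)
#' @param size_jitter relative half-range of per-tooth uniform size jitter
#' @return a `scene_config` object
#' @export
scene_config <- function(width = 640, height = 320, margin = 20,
                         upper_y = 120, lower_y = 210,
                         arch_curvature = 1e-4, tooth_ry = 26,
                         tooth_rx = c(20, 20, 20.5, 20.5, 20.5, 22.5, 22.5, 21),
                         size_jitter = 0.04) {
  stopifnot(width > 0, height > 0, tooth_ry > 0, length(tooth_rx) == 8L,
            all(tooth_rx > 0), size_jitter >= 0, size_jitter < 1)
  structure(
    list(width = as.integer(width), height = as.integer(height),
         margin = margin, upper_y = upper_y, lower_y = lower_y,
         arch_curvature = arch_curvature, tooth_ry = tooth_ry,
         tooth_rx = tooth_rx, size_jitter = size_jitter),
    class = "scene_config"
  )
}

# Nominal center and half-axes of a position's ellipse.
.tooth_geometry <- function(code, scene) {
  jaw <- fdi_jaw(code)
  slot <- match(code, jaw_arc(jaw))
  pitch <- (scene$width - 2 * scene$margin) / 16
  cx <- scene$margin + (slot - 0.5) * pitch
  base <- if (jaw == "upper") scene$upper_y else scene$lower_y
  cy <- base - scene$arch_curvature * (cx - scene$width / 2)^2
  idx <- fdi_index(code)
  list(cx = cx, cy = cy, rx = scene$tooth_rx[idx], ry = scene$tooth_ry)
}

#' Detector noise model configuration
#'
#' Parameters of the simulated instance-segmentation error modes:
#' * `presence_prior` — per-index probability that a position holds an
#'   abutment tooth, same for all quadrants; defaults anchored at an overall
#'   missing rate of 32.4%, canine prevalence 91.4%, and wisdom-tooth
#'   prevalence 20.5%, with the remaining indices interpolated smoothly;
#' * `p_miss` — probability that a reference tooth yields no detection;
#' * `spurious_rate` — Poisson mean of extra detections per image, placed in
#'   edentulous gaps or over implant regions;
#' * `duplicate_rate` — probability of a duplicate proposal per emitted
#'   detection, split by `same_mask_frac` into the same-proposal mode
#'   (identical mask, different class) and the shifted-proposal mode
#'   (strongly overlapping mask, same class);
#' * `mislabel_prob` — per-index probability that an emitted detection
#'   carries a confused FDI label; confusion targets an adjacent index of
#'   the same morphological group within the quadrant, and is heaviest
#'   among the mutually similar molars;
#' * `score_correct`/`score_error` — Beta shape pairs for confidence scores
#'   of correct vs erroneous instances (correct skewed high, erroneous
#'   skewed low, overlapping so the 0.5 score threshold is exercised);
#'   `NULL` means a degenerate score of exactly 1.
#'
#' The same seed always reproduces the identical corpus.
#'
#' @param seed integer RNG seed for corpus generation
#' @param presence_prior numeric(8) in `[0, 1]`, by tooth index
#' @param implant_prob probability that an absent position holds an implant
#' @param p_miss false-negative rate
#' @param spurious_rate expected spurious detections per image
#' @param duplicate_rate duplicate-proposal probability per detection
#' @param same_mask_frac fraction of duplicates in same-mask mode
#' @param mislabel_prob numeric(8) (or scalar) label-confusion probability by
#'   tooth index
#' @param mask_jitter_sd pixel s.d. of the mask translation jitter
#' @param score_correct,score_error Beta shape pairs, or `NULL` for exact 1
#' @return a `noise_config` object
#' @export
noise_config <- function(seed = 1L,
                         presence_prior = c(0.78, 0.75, 0.914, 0.72, 0.70,
                                            0.68, 0.66, 0.205),
                         implant_prob = 0.10,
                         p_miss = 0.03,
                         spurious_rate = 0.4,
                         duplicate_rate = 0.15,
                         same_mask_frac = 0.5,
                         mislabel_prob = c(0.03, 0.03, 0.01, 0.04, 0.04,
                                           0.08, 0.08, 0.08),
                         mask_jitter_sd = 1.5,
                         score_correct = c(9, 2),
                         score_error = c(3, 4)) {
  if (length(mislabel_prob) == 1L) mislabel_prob <- rep(mislabel_prob, 8L)
  probs <- c(presence_prior, implant_prob, p_miss, duplicate_rate,
             same_mask_frac, mislabel_prob)
  stopifnot(length(presence_prior) == 8L, length(mislabel_prob) == 8L,
            all(probs >= 0), all(probs <= 1), spurious_rate >= 0,
            mask_jitter_sd >= 0)
  structure(
    list(seed = as.integer(seed), presence_prior = presence_prior,
         implant_prob = implant_prob, p_miss = p_miss,
         spurious_rate = spurious_rate, duplicate_rate = duplicate_rate,
         same_mask_frac = same_mask_frac, mislabel_prob = mislabel_prob,
         mask_jitter_sd = mask_jitter_sd,
         score_correct = score_correct, score_error = score_error),
    class = "noise_config"
  )
}

#' @rdname noise_config
#' @details `noise_config_zero()` is the noiseless setting: no misses,
#'   spurious detections, duplicates, mislabels, or jitter, and scores of
#'   exactly 1 — the corrupted detections equal the reference.
#' @export
noise_config_zero <- function(seed = 1L) {
  noise_config(seed = seed, p_miss = 0, spurious_rate = 0, duplicate_rate = 0,
               mislabel_prob = 0, mask_jitter_sd = 0,
               score_correct = NULL, score_error = NULL)
}

.draw_score <- function(shape) {
  if (is.null(shape)) 1 else stats::rbeta(1L, shape[1L], shape[2L])
}

# Confused label: adjacent index within the same morphological group, same
# quadrant. Never returns the input code.
.confuse_label <- function(code, avoid = integer(0)) {
  i <- fdi_index(code)
  q <- fdi_quadrant(code)
  cand_by_index <- list(2L, 1L, c(2L, 4L), 5L, 4L,
                        c(7L, 8L), c(6L, 8L), c(7L, 6L))
  weight_by_index <- list(1, 1, c(0.5, 0.5), 1, 1,
                          c(0.7, 0.3), c(0.5, 0.5), c(0.7, 0.3))
  cand <- cand_by_index[[i]]
  w <- weight_by_index[[i]]
  codes <- 10L * q + cand
  ok <- !(codes %in% avoid)
  if (any(ok)) { codes <- codes[ok]; w <- w[ok] }
  if (length(codes) == 1L) codes else sample(codes, 1L, prob = w)
}

#' Generate reference annotations
#'
#' Samples per-position presence from the priors, assigns implants among
#' absent positions, renders masks for present teeth along the arch, and
#' attaches the Kennedy class of each jaw as derived by [classify_jaw()]
#' (expert labels are rule-derived by construction, so
#' [validate_reference_consistency()] agrees 100% on generated corpora).
#'
#' @param n_images number of images to generate (>= 1)
#' @param scene a [scene_config()]
#' @param noise a [noise_config()] (presence priors, implant probability, seed)
#' @return list of [reference_annotation()] objects with image ids `1..n`
#' @export
generate_reference <- function(n_images, scene = scene_config(),
                               noise = noise_config()) {
  stopifnot(n_images >= 1L)
  set.seed(noise$seed %% 2147483647L)
  dim <- c(scene$height, scene$width)
  lapply(seq_len(n_images), function(i) {
    teeth <- lapply(all_fdi_codes(), function(code) {
      idx <- fdi_index(code)
      if (stats::runif(1L) < noise$presence_prior[idx]) {
        g <- .tooth_geometry(code, scene)
        s <- 1 + stats::runif(2L, -scene$size_jitter, scene$size_jitter)
        reference_tooth(code, "tooth",
                        ellipse_mask(g$cx, g$cy, g$rx * s[1L], g$ry * s[2L], dim))
      } else if (stats::runif(1L) < noise$implant_prob) {
        reference_tooth(code, "implant")
      } else {
        reference_tooth(code, "missing")
      }
    })
    labels <- vapply(teeth, `[[`, integer(1), "label")
    present <- labels[vapply(teeth, function(t) t$status == "tooth", logical(1))]
    kennedy <- c(
      upper = .kennedy_core(jaw_arc("upper") %in% present),
      lower = .kennedy_core(jaw_arc("lower") %in% present)
    )
    reference_annotation(i, scene$width, scene$height, teeth, kennedy)
  })
}

#' Corrupt a reference annotation into simulated raw detections
#'
#' Applies the noise model to one annotated image: each reference tooth is
#' independently missed with `p_miss`; survivors are emitted with a jittered
#' mask, a possibly confused label, and a high-regime score; duplicate
#' proposals are injected in the two modes (identical mask with a different
#' class, or a shifted strongly-overlapping mask with the same class) with
#' low-regime scores; spurious low-score instances are placed in edentulous
#' gaps or over implant positions. Deterministic given `(noise$seed,
#' image_id)`.
#'
#' @param ann a [reference_annotation()] with masks
#' @param noise a [noise_config()]
#' @param scene the [scene_config()] used to generate `ann` (needed to place
#'   spurious detections at empty positions)
#' @return list of [raw_detection()] objects
#' @export
corrupt_to_detections <- function(ann, noise = noise_config(),
                                  scene = scene_config()) {
  stopifnot(inherits(ann, "reference_annotation"))
  set.seed((noise$seed + 1009L * as.integer(ann$image_id)) %% 2147483647L)
  dim <- c(ann$height, ann$width)
  dets <- list()
  for (t in reference_teeth(ann)) {
    if (stats::runif(1L) < noise$p_miss) next
    mask <- t$mask
    if (noise$mask_jitter_sd > 0) {
      sh <- round(stats::rnorm(2L, 0, noise$mask_jitter_sd))
      mask <- mask_shift(mask, sh[1L], sh[2L])
    }
    label <- if (stats::runif(1L) < noise$mislabel_prob[fdi_index(t$label)]) {
      .confuse_label(t$label)
    } else {
      t$label
    }
    dets[[length(dets) + 1L]] <-
      raw_detection(label, .draw_score(noise$score_correct), mask)
    if (stats::runif(1L) < noise$duplicate_rate) {
      if (stats::runif(1L) < noise$same_mask_frac) {
        dup_label <- .confuse_label(t$label, avoid = label)
        dup_mask <- mask
      } else {
        dup_label <- label
        sh <- round(stats::rnorm(2L, 0, 4))
        dup_mask <- mask_shift(mask, sh[1L], sh[2L])
      }
      dets[[length(dets) + 1L]] <-
        raw_detection(dup_label, .draw_score(noise$score_error), dup_mask)
    }
  }
  if (noise$spurious_rate > 0) {
    empty <- Filter(function(t) t$status != "tooth", ann$teeth)
    n_sp <- stats::rpois(1L, noise$spurious_rate)
    if (length(empty) && n_sp > 0L) {
      for (k in seq_len(n_sp)) {
        slot <- empty[[sample.int(length(empty), 1L)]]
        g <- .tooth_geometry(slot$label, scene)
        dets[[length(dets) + 1L]] <-
          raw_detection(slot$label, .draw_score(noise$score_error),
                        ellipse_mask(g$cx, g$cy, 0.9 * g$rx, 0.9 * g$ry, dim))
      }
    }
  }
  dets
}

#' Generate a full synthetic corpus
#'
#' References plus corrupted detections for `n_images` images, fully
#' determined by `noise$seed`.
#'
#' @inheritParams generate_reference
#' @return list with `references` (annotations) and `detections` (aligned
#'   list of raw detection lists)
#' @export
simulate_corpus <- function(n_images, scene = scene_config(),
                            noise = noise_config()) {
  refs <- generate_reference(n_images, scene, noise)
  dets <- lapply(refs, corrupt_to_detections, noise = noise, scene = scene)
  list(references = refs, detections = dets)
}
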