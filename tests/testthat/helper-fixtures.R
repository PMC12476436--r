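# Shared fixture builders and independent oracles.

# Rectangle mask on a small grid (1-based inclusive pixel ranges).
rect_mask <- function(rows, cols, dim) {
  m <- matrix(FALSE, dim[1], dim[2])
  m[rows, cols] <- TRUE
  mask_from_matrix(m)
}

# Random blob: a random rectangle, optionally perturbed by pixel noise.
rand_blob <- function(dim, rng_rows = dim[1], rng_cols = dim[2]) {
  r <- sort(sample.int(rng_rows, 2))
  c <- sort(sample.int(rng_cols, 2))
  rect_mask(r[1]:r[2], c[1]:c[2], dim)
}

# Random detection fixture exercising ties, duplicates and shared masks.
rand_detections <- function(n, dim = c(12, 12), labels = c(35L, 36L, 37L, 38L)) {
  dets <- list()
  for (k in seq_len(n)) {
    mask <- if (k > 1 && runif(1) < 0.35) {
      prev <- dets[[sample.int(k - 1, 1)]]$mask
      if (runif(1) < 0.5) prev else mask_shift(prev, sample(-2:2, 1), sample(-2:2, 1))
    } else {
      rand_blob(dim)
    }
    if (mask_area(mask) == 0) mask <- rand_blob(dim)
    score <- sample(seq(0.2, 1, by = 0.05), 1)  # coarse grid to force ties
    dets[[k]] <- raw_detection(sample(labels, 1), score, mask)
  }
  dets
}

# Independent brute-force restatement of the greedy filtering rules, working
# on full-frame logical matrices. Deliberately unoptimized; kept apart from
# the production path.
oracle_postprocess <- function(dets, config) {
  if (!length(dets)) return(list())
  scores <- sapply(dets, function(d) d$score)
  labels <- sapply(dets, function(d) d$label)
  ord <- order(-scores, labels, seq_along(dets))
  dim <- dets[[1]]$mask$dim
  occ <- matrix(FALSE, dim[1], dim[2])
  sel <- list()
  for (k in ord) {
    d <- dets[[k]]
    mm <- as.matrix(d$mask)
    if (config$score_filter && d$score < config$score_threshold) next
    if (config$duplicate_filter &&
        d$label %in% sapply(sel, function(s) s$label)) next
    if (config$geometric_filter &&
        sum(mm & !occ) / sum(mm) < config$novel_fraction_threshold) next
    occ <- occ | mm
    sel <- c(sel, list(d))
  }
  sel
}

# Random filter configuration (thresholds on a coarse grid, random ablations).
rand_config <- function() {
  postprocess_config(
    score_threshold = sample(c(0.3, 0.5, 0.7), 1),
    novel_fraction_threshold = sample(c(0.3, 0.5, 0.7), 1),
    score_filter = runif(1) < 0.8,
    duplicate_filter = runif(1) < 0.8,
    geometric_filter = runif(1) < 0.8
  )
}

# Fingerprint of a detection, to map selected outputs back to input slots.
digest_det <- function(d) {
  paste(d$label, d$score, paste(d$mask$idx, collapse = ","))
}

# Arc-ordered logical(16) from the low 16 bits of an integer.
bits16 <- function(b) bitwAnd(bitwShiftR(b, 0:15), 1L) == 1L

# Tiny fully annotated image: four teeth (11, 21, 36, 47) on a 20x40 grid.
toy_annotation <- function(image_id = 1L) {
  dim <- c(20L, 40L)
  masks <- list(`11` = rect_mask(2:8, 2:8, dim),
                `21` = rect_mask(2:8, 12:18, dim),
                `36` = rect_mask(12:18, 2:8, dim),
                `47` = rect_mask(12:18, 12:18, dim))
  teeth <- lapply(all_fdi_codes(), function(code) {
    key <- as.character(code)
    if (!is.null(masks[[key]])) reference_tooth(code, "tooth", masks[[key]])
    else reference_tooth(code, "missing")
  })
  reference_annotation(image_id, dim[2], dim[1], teeth,
                       c(upper = "I", lower = "II"))
}
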