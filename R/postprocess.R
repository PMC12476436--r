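#' Post-processing configuration
#'
#' Settings for the three-stage duplicate-suppression filter applied to raw
#' detections. Each stage can be ablated independently:
#' * score filter — discard candidates with `score < score_threshold`
#'   (a score exactly at the threshold survives);
#' * duplicate-label filter — discard a candidate whose FDI position is
#'   already occupied by a previously selected (higher-scoring) instance;
#' * geometric filter — discard a candidate whose novel pixel fraction
#'   against the union of previously selected masks is below
#'   `novel_fraction_threshold` (exactly at the threshold survives).
#'
#' Both default thresholds are 0.5; neither is critical in practice because
#' correct neighboring teeth overlap only slightly while duplicate proposals
#' cover essentially the same pixels.
#'
#' @param score_threshold minimum surviving score, in `[0, 1]`
#' @param novel_fraction_threshold minimum surviving novel pixel fraction,
#'   in `[0, 1]`
#' @param score_filter,duplicate_filter,geometric_filter enable flags
#' @return a `postprocess_config` object
#' @export
postprocess_config <- function(score_threshold = 0.5,
                               novel_fraction_threshold = 0.5,
                               score_filter = TRUE,
                               duplicate_filter = TRUE,
                               geometric_filter = TRUE) {
  stopifnot(score_threshold >= 0, score_threshold <= 1,
            novel_fraction_threshold >= 0, novel_fraction_threshold <= 1,
            is.logical(score_filter), is.logical(duplicate_filter),
            is.logical(geometric_filter))
  structure(
    list(score_threshold = score_threshold,
         novel_fraction_threshold = novel_fraction_threshold,
         score_filter = isTRUE(score_filter),
         duplicate_filter = isTRUE(duplicate_filter),
         geometric_filter = isTRUE(geometric_filter)),
    class = "postprocess_config"
  )
}

#' Filter raw detections to a cleaned dentition estimate
#'
#' Greedy single pass over the candidates in order of decreasing score
#' (ties broken by ascending FDI code, then input order, for determinism):
#' each candidate is discarded by the first enabled filter that rejects it
#' — score below threshold, FDI position already occupied by a selected
#' instance, or novel pixel fraction against the union of previously
#' *selected* masks below threshold — and selected otherwise. Discarded
#' instances occupy nothing. Filters act per image; all detections must
#' share one image grid.
#'
#' @param detections list of [raw_detection()] objects from one image
#' @param config a [postprocess_config()]
#' @return the selected subset, in selection (decreasing-score) order, with
#'   attribute `"discarded"` counting rejections per filter stage.
#' @examples
#' m <- mask_from_matrix(matrix(c(1, 1, 0, 0), 2, 2))
#' d <- list(raw_detection(26, 0.9, m), raw_detection(27, 0.8, m))
#' length(postprocess(d))  # the same-mask duplicate is removed: 1
#' @export
postprocess <- function(detections, config = postprocess_config()) {
  stopifnot(inherits(config, "postprocess_config"))
  counts <- c(score = 0L, duplicate_label = 0L, geometric = 0L)
  if (!length(detections)) {
    return(structure(list(), discarded = counts))
  }
  stopifnot(all(vapply(detections, inherits, logical(1), "raw_detection")))
  dims <- vapply(detections, function(d) d$mask$dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stop("detections lie on mismatched image grids", call. = FALSE)
  }
  scores <- vapply(detections, `[[`, numeric(1), "score")
  if (any(is.nan(scores))) stop("NaN detection score", call. = FALSE)
  labels <- vapply(detections, `[[`, integer(1), "label")
  ord <- order(-scores, labels, seq_along(detections))

  npix <- prod(dims[, 1])
  occupied <- logical(npix)
  selected_labels <- integer(0)
  selected <- vector("list", length(detections))
  n_sel <- 0L
  for (k in ord) {
    d <- detections[[k]]
    if (config$score_filter && d$score < config$score_threshold) {
      counts["score"] <- counts["score"] + 1L
      next
    }
    if (config$duplicate_filter && d$label %in% selected_labels) {
      counts["duplicate_label"] <- counts["duplicate_label"] + 1L
      next
    }
    if (config$geometric_filter) {
      novel <- sum(!occupied[d$mask$idx]) / length(d$mask$idx)
      if (novel < config$novel_fraction_threshold) {
        counts["geometric"] <- counts["geometric"] + 1L
        next
      }
    }
    occupied[d$mask$idx] <- TRUE
    selected_labels <- c(selected_labels, d$label)
    n_sel <- n_sel + 1L
    selected[[n_sel]] <- d
  }
  structure(selected[seq_len(n_sel)], discarded = counts)
}

#' Post-process every image of a corpus
#'
#' @param detections_by_image list (one element per image) of detection lists
#' @param config a [postprocess_config()]
#' @return list of selected-detection lists, same names/order as the input
#' @export
postprocess_corpus <- function(detections_by_image, config = postprocess_config()) {
  lapply(detections_by_image, postprocess, config = config)
}
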