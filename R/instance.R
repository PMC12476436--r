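#' Kennedy class labels
#'
#' The five jaw classes handled by the rule engine: I (bilateral shortened
#' tooth row), II (unilateral shortened row), III (bounded gap), IV (single
#' anterior gap across the midline), and FULL for a fully dentate jaw
#' (wisdom teeth disregarded).
#'
#' @export
kennedy_levels <- function() c("I", "II", "III", "IV", "FULL")

#' One raw detector output instance
#'
#' A detection as emitted by an instance-segmentation model: an FDI position
#' label, a confidence score in `[0, 1]`, a binary segmentation mask, and the
#' mask's tight bounding box (derived — masks are authoritative).
#'
#' @param label a single valid FDI code
#' @param score confidence in `[0, 1]`, finite
#' @param mask a non-empty `tooth_mask`
#' @return a `raw_detection` object
#' @export
raw_detection <- function(label, score, mask) {
  fdi_validate(label)
  stopifnot(length(label) == 1L, length(score) == 1L)
  if (!is.finite(score) || score < 0 || score > 1) {
    stop("detection score must be finite and in [0, 1], got ", score, call. = FALSE)
  }
  stopifnot(inherits(mask, "tooth_mask"))
  if (mask_area(mask) == 0L) stop("a detection mask must be non-empty", call. = FALSE)
  structure(
    list(label = as.integer(label), score = as.numeric(score), mask = mask,
         bbox = mask_bbox(mask)),
    class = "raw_detection"
  )
}

#' @export
print.raw_detection <- function(x, ...) {
  cat(sprintf("<detection %d score=%.3f area=%d>\n",
              x$label, x$score, mask_area(x$mask)))
  invisible(x)
}

#' Reference status of one FDI position
#'
#' @param label a single valid FDI code
#' @param status `"tooth"`, `"implant"`, or `"missing"`
#' @param mask a non-empty `tooth_mask` when `status == "tooth"`; otherwise
#'   `NULL` (implants carry no mask requirement and never count as reference
#'   teeth for detection metrics)
#' @return a `reference_tooth` object
#' @export
reference_tooth <- function(label, status, mask = NULL) {
  fdi_validate(label)
  status <- match.arg(status, c("tooth", "implant", "missing"))
  if (status == "tooth") {
    stopifnot(inherits(mask, "tooth_mask"))
    if (mask_area(mask) == 0L) stop("a present tooth must have a non-empty mask", call. = FALSE)
  } else if (status == "missing" && !is.null(mask)) {
    stop("a missing position cannot carry a mask", call. = FALSE)
  }
  structure(list(label = as.integer(label), status = status, mask = mask),
            class = "reference_tooth")
}

#' Per-image reference annotation
#'
#' Exactly 32 position entries (missing positions explicit), plus the
#' expert Kennedy class of each jaw.
#'
#' @param image_id scalar identifier
#' @param width,height image grid size in pixels
#' @param teeth list of 32 [reference_tooth()] objects, one per FDI position
#' @param kennedy named character vector `c(upper = ..., lower = ...)` with
#'   values from [kennedy_levels()]
#' @return a `reference_annotation` object
#' @export
reference_annotation <- function(image_id, width, height, teeth, kennedy) {
  labels <- vapply(teeth, function(t) t$label, integer(1))
  if (length(teeth) != 32L || !setequal(labels, all_fdi_codes()) ||
      anyDuplicated(labels)) {
    stop("annotation for image ", image_id,
         " must contain exactly one entry per FDI position", call. = FALSE)
  }
  if (!setequal(names(kennedy), c("upper", "lower")) ||
      !all(kennedy %in% kennedy_levels())) {
    stop("annotation for image ", image_id,
         " needs kennedy classes named upper/lower from ",
         paste(kennedy_levels(), collapse = "/"), call. = FALSE)
  }
  dim <- c(as.integer(height), as.integer(width))
  for (t in teeth) {
    if (t$status == "tooth" && !identical(t$mask$dim, dim)) {
      stop("mask of tooth ", t$label, " in image ", image_id,
           " is not on the image grid", call. = FALSE)
    }
  }
  structure(
    list(image_id = image_id, width = as.integer(width),
         height = as.integer(height),
         teeth = teeth[order(labels)],
         kennedy = kennedy[c("upper", "lower")]),
    class = "reference_annotation"
  )
}

#' @export
print.reference_annotation <- function(x, ...) {
  st <- vapply(x$teeth, function(t) t$status, character(1))
  cat(sprintf("<reference image %s (%dx%d): %d teeth, %d implants, %d missing; upper %s, lower %s>\n",
              format(x$image_id), x$width, x$height,
              sum(st == "tooth"), sum(st == "implant"), sum(st == "missing"),
              x$kennedy[["upper"]], x$kennedy[["lower"]]))
  invisible(x)
}

#' Reference teeth of an annotation
#'
#' @param ann a `reference_annotation`
#' @return the list of entries with status `"tooth"`
#' @export
reference_teeth <- function(ann) {
  stopifnot(inherits(ann, "reference_annotation"))
  Filter(function(t) t$status == "tooth", ann$teeth)
}
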