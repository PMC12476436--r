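#' COCO-style instance JSON I/O
#'
#' Detections and references travel as COCO-style instance JSON: an `images`
#' array (id, width, height), a `categories` array enumerating the 32 FDI
#' codes as category *names* (ids are arbitrary — readers map by name), and
#' an `annotations` array. Detection annotations carry a `score`; reference
#' annotations carry a `status` (`"tooth"`, `"implant"`, `"missing"`) and
#' the per-image `kennedy` classes sit on the image entries. Masks are
#' encoded as uncompressed column-major RLE on write; readers also accept
#' polygon encodings.
#'
#' @name coco_io
NULL

.schema_error <- function(path, image_id, field, msg) {
  stop(sprintf("%s: image %s: field '%s': %s", path,
               format(image_id), field, msg), call. = FALSE)
}

.fdi_categories <- function() {
  lapply(seq_along(all_fdi_codes()), function(k) {
    list(id = k, name = as.character(all_fdi_codes()[k]))
  })
}

.category_map <- function(cats, path) {
  ids <- vapply(cats, function(c) as.integer(c$id), integer(1))
  names_ <- vapply(cats, function(c) as.character(c$name), character(1))
  codes <- suppressWarnings(as.integer(names_))
  if (anyNA(codes) || !all(codes %in% all_fdi_codes())) {
    stop(path, ": category names must be the 32 FDI codes; found '",
         names_[which(is.na(codes) | !(codes %in% all_fdi_codes()))[1L]],
         "'", call. = FALSE)
  }
  stats::setNames(codes, ids)
}

.decode_segmentation <- function(seg, dim, path, image_id) {
  if (is.null(seg)) .schema_error(path, image_id, "segmentation", "missing mask")
  if (!is.null(seg$counts)) {
    mask_from_rle(unlist(seg$counts), dim)
  } else {
    mask_from_polygon(lapply(seg, unlist), dim)
  }
}

.encode_annotation <- function(det_or_mask, id, image_id, cat_id) {
  mask <- if (inherits(det_or_mask, "tooth_mask")) det_or_mask else det_or_mask$mask
  bb <- mask_bbox(mask)
  list(id = id, image_id = image_id, category_id = cat_id,
       segmentation = mask_to_rle(mask),
       bbox = c(bb[1L], bb[2L], bb[3L] - bb[1L], bb[4L] - bb[2L]),
       area = mask_area(mask))
}

.code_to_catid <- function() {
  stats::setNames(seq_along(all_fdi_codes()), all_fdi_codes())
}

#' Write detections to COCO-style JSON
#'
#' @param detections_by_image list of [raw_detection()] lists
#' @param images data.frame with columns `id`, `width`, `height`, aligned
#'   with `detections_by_image`
#' @param path output file
#' @export
write_detections <- function(detections_by_image, images, path) {
  stopifnot(nrow(images) == length(detections_by_image))
  catid <- .code_to_catid()
  anns <- list(); n <- 0L
  for (i in seq_len(nrow(images))) {
    for (d in detections_by_image[[i]]) {
      n <- n + 1L
      a <- .encode_annotation(d, n, images$id[i], unname(catid[as.character(d$label)]))
      a$score <- d$score
      anns[[n]] <- a
    }
  }
  obj <- list(
    images = lapply(seq_len(nrow(images)), function(i) {
      list(id = images$id[i], width = images$width[i], height = images$height[i])
    }),
    categories = .fdi_categories(),
    annotations = anns
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read detections from COCO-style JSON
#'
#' @param path input file
#' @return list with `images` (data.frame `id`, `width`, `height`) and
#'   `detections` (list of [raw_detection()] lists, aligned with `images`)
#' @export
read_detections <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  for (f in c("images", "categories", "annotations")) {
    if (is.null(obj[[f]])) stop(path, ": missing '", f, "' array", call. = FALSE)
  }
  cat_map <- .category_map(obj$categories, path)
  images <- data.frame(
    id = vapply(obj$images, function(im) as.integer(im$id), integer(1)),
    width = vapply(obj$images, function(im) as.integer(im$width), integer(1)),
    height = vapply(obj$images, function(im) as.integer(im$height), integer(1))
  )
  dets <- stats::setNames(rep(list(list()), nrow(images)), images$id)
  for (a in obj$annotations) {
    iid <- as.character(as.integer(a$image_id))
    row <- match(as.integer(a$image_id), images$id)
    if (is.na(row)) .schema_error(path, a$image_id, "image_id", "unknown image")
    code <- cat_map[as.character(as.integer(a$category_id))]
    if (is.na(code)) .schema_error(path, a$image_id, "category_id", "unknown category")
    if (is.null(a$score)) .schema_error(path, a$image_id, "score", "missing")
    dim <- c(images$height[row], images$width[row])
    mask <- .decode_segmentation(a$segmentation, dim, path, a$image_id)
    dets[[iid]] <- c(dets[[iid]], list(raw_detection(code, a$score, mask)))
  }
  list(images = images, detections = dets)
}

#' Write reference annotations to COCO-style JSON
#'
#' @param references list of [reference_annotation()] objects
#' @param path output file
#' @export
write_reference <- function(references, path) {
  catid <- .code_to_catid()
  anns <- list(); n <- 0L
  for (ann in references) {
    for (t in ann$teeth) {
      n <- n + 1L
      if (t$status == "tooth") {
        a <- .encode_annotation(t, n, ann$image_id,
                                unname(catid[as.character(t$label)]))
      } else {
        a <- list(id = n, image_id = ann$image_id,
                  category_id = unname(catid[as.character(t$label)]))
      }
      a$status <- t$status
      anns[[n]] <- a
    }
  }
  obj <- list(
    images = lapply(references, function(ann) {
      list(id = ann$image_id, width = ann$width, height = ann$height,
           kennedy = list(upper = ann$kennedy[["upper"]],
                          lower = ann$kennedy[["lower"]]))
    }),
    categories = .fdi_categories(),
    annotations = anns
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read reference annotations from COCO-style JSON
#'
#' Validates the schema: every image must account for all 32 FDI positions
#' and carry both per-jaw Kennedy classes.
#'
#' @param path input file
#' @return list of [reference_annotation()] objects
#' @export
read_reference <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  for (f in c("images", "categories", "annotations")) {
    if (is.null(obj[[f]])) stop(path, ": missing '", f, "' array", call. = FALSE)
  }
  cat_map <- .category_map(obj$categories, path)
  by_image <- split(
    obj$annotations,
    vapply(obj$annotations, function(a) as.integer(a$image_id), integer(1))
  )
  lapply(obj$images, function(im) {
    iid <- as.integer(im$id)
    if (is.null(im$kennedy) || is.null(im$kennedy$upper) || is.null(im$kennedy$lower)) {
      .schema_error(path, iid, "kennedy", "missing per-jaw classes")
    }
    anns <- by_image[[as.character(iid)]]
    if (is.null(anns)) .schema_error(path, iid, "annotations", "no entries")
    dim <- c(as.integer(im$height), as.integer(im$width))
    teeth <- lapply(anns, function(a) {
      code <- cat_map[as.character(as.integer(a$category_id))]
      if (is.na(code)) .schema_error(path, iid, "category_id", "unknown category")
      status <- a$status
      if (is.null(status) || !status %in% c("tooth", "implant", "missing")) {
        .schema_error(path, iid, "status", "must be tooth/implant/missing")
      }
      mask <- if (status == "tooth") {
        .decode_segmentation(a$segmentation, dim, path, iid)
      } else NULL
      reference_tooth(unname(code), status, mask)
    })
    labels <- vapply(teeth, `[[`, integer(1), "label")
    missing_pos <- setdiff(all_fdi_codes(), labels)
    if (length(missing_pos)) {
      .schema_error(path, iid, "annotations",
                    paste("position", missing_pos[1L], "not accounted for"))
    }
    reference_annotation(iid, as.integer(im$width), as.integer(im$height),
                         teeth,
                         c(upper = im$kennedy$upper, lower = im$kennedy$lower))
  })
}

#' Image metadata table of a reference corpus
#'
#' @param references list of [reference_annotation()] objects
#' @return data.frame with `id`, `width`, `height`
#' @export
images_meta <- function(references) {
  data.frame(
    id = vapply(references, function(a) as.integer(a$image_id), integer(1)),
    width = vapply(references, `[[`, integer(1), "width"),
    height = vapply(references, `[[`, integer(1), "height")
  )
}

#' Run the full pipeline: post-process, classify, evaluate
#'
#' @param detections_by_image list of raw detection lists, aligned with
#'   `references`
#' @param references list of [reference_annotation()] objects
#' @param config a [postprocess_config()]
#' @param iou_threshold matching threshold for the evaluation
#' @return list with `filtered` (selected detections per image), `report`
#'   (an `evaluation_report`), and `consistency` (the
#'   [validate_reference_consistency()] table)
#' @export
run_pipeline <- function(detections_by_image, references,
                         config = postprocess_config(),
                         iou_threshold = 1 / 3) {
  filtered <- postprocess_corpus(detections_by_image, config)
  list(
    filtered = filtered,
    report = evaluate_corpus(filtered, references, iou_threshold = iou_threshold),
    consistency = validate_reference_consistency(references)
  )
}
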