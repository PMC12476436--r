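#' Per-jaw tooth presence map
#'
#' Boolean presence over the 16 FDI positions of one jaw, in anatomical arc
#' order (see [jaw_arc()]). Presence means an abutment tooth: implants,
#' pontics, and root residues count as absent.
#'
#' @param jaw `"upper"` or `"lower"`
#' @param present either a logical vector of length 16 in arc order, or an
#'   integer vector of present FDI codes belonging to the jaw
#' @return a `jaw_presence_map`
#' @export
jaw_presence_map <- function(jaw, present) {
  jaw <- match.arg(jaw, c("upper", "lower"))
  arc <- jaw_arc(jaw)
  if (is.logical(present)) {
    if (length(present) != 16L || anyNA(present)) {
      stop("presence map needs exactly 16 non-missing logical entries", call. = FALSE)
    }
    p <- present
  } else {
    present <- fdi_validate(present)
    if (!all(fdi_jaw(present) == jaw)) {
      stop("presence codes include positions outside the ", jaw, " jaw", call. = FALSE)
    }
    p <- arc %in% present
  }
  names(p) <- arc
  structure(list(jaw = jaw, present = p), class = "jaw_presence_map")
}

#' @export
print.jaw_presence_map <- function(x, ...) {
  cat(sprintf("<%s jaw: %d/16 present [%s]>\n", x$jaw, sum(x$present),
              paste(ifelse(x$present, "#", "."), collapse = "")))
  invisible(x)
}

# Core rule engine on an arc-ordered logical(16). Arc slots: 1 and 16 are the
# wisdom teeth, 2 and 15 the second molars, 8 and 9 the central incisors;
# slots 2..15 are indices 7..1|1..7. Kept lean: called 65k+ times by
# exhaustive property checks.
.kennedy_core <- function(p) {
  molars <- p[2L] + p[15L]
  if (molars == 0L) return("I")
  if (molars == 1L) return("II")
  inner <- p[2:15]
  absent <- which(!inner)
  if (!length(absent)) return("FULL")
  if (!inner[7L] && !inner[8L] && all(diff(absent) == 1L)) return("IV")
  "III"
}

#' Kennedy classification of one jaw
#'
#' Applies the rules in fixed priority order:
#' 1. both second molars (17/27 or 37/47) absent — class I
#'    (bilateral shortened tooth row);
#' 2. exactly one second molar absent — class II (unilateral);
#' 3. both second molars present, both central incisors (11/21 or 31/41)
#'    absent, and the absent positions among indices 1-7 form a single
#'    contiguous run in arc order (the remaining rows are closed) — class IV;
#' 4. otherwise, any other position of index 1-7 absent — class III;
#' 5. otherwise FULL.
#'
#' Wisdom teeth (index 8) are ignored by every rule, so a jaw missing only
#' its third molars is FULL. The earlier rules pre-empt the later ones: a jaw
#' missing 47 as well as 31 and 41 is II, not IV.
#'
#' @param m a [jaw_presence_map()]
#' @return one of [kennedy_levels()]
#' @examples
#' classify_jaw(jaw_presence_map("upper", setdiff(jaw_arc("upper"), c(17, 27))))  # "I"
#' @export
classify_jaw <- function(m) {
  if (!inherits(m, "jaw_presence_map")) {
    stop("classify_jaw expects a jaw_presence_map", call. = FALSE)
  }
  .kennedy_core(m$present)
}

#' Presence maps from selected detections
#'
#' A position is present when at least one selected detection carries its
#' label; duplicate labels (possible when the duplicate-label filter is
#' ablated) still yield presence once.
#'
#' @param selected list of [raw_detection()] objects from one image
#' @return list with elements `upper` and `lower`, each a [jaw_presence_map()]
#' @export
presence_from_detections <- function(selected) {
  labels <- vapply(selected, `[[`, integer(1), "label")
  list(
    upper = jaw_presence_map("upper", jaw_arc("upper") %in% labels),
    lower = jaw_presence_map("lower", jaw_arc("lower") %in% labels)
  )
}

#' Presence maps of a reference annotation
#'
#' Status `"tooth"` counts as present; implants and missing positions are
#' absent (they are not abutment teeth).
#'
#' @param ann a [reference_annotation()]
#' @return list with elements `upper` and `lower`
#' @export
reference_presence <- function(ann) {
  stopifnot(inherits(ann, "reference_annotation"))
  labels <- vapply(reference_teeth(ann), `[[`, integer(1), "label")
  list(
    upper = jaw_presence_map("upper", jaw_arc("upper") %in% labels),
    lower = jaw_presence_map("lower", jaw_arc("lower") %in% labels)
  )
}

#' Check expert Kennedy classes against the rule engine
#'
#' Re-derives each jaw's class from the reference tooth annotation (status
#' `"tooth"` means present) and compares with the recorded expert class.
#' Disagreement is a reported finding, not an error. A jaw with no abutment
#' teeth at all among indices 1-7 classifies as I and is flagged as fully
#' edentulous.
#'
#' @param anns a single [reference_annotation()] or a list of them
#' @return a data.frame with columns `image_id`, `jaw`, `expert`, `derived`,
#'   `agree`, `edentulous`
#' @export
validate_reference_consistency <- function(anns) {
  if (inherits(anns, "reference_annotation")) anns <- list(anns)
  rows <- lapply(anns, function(ann) {
    maps <- reference_presence(ann)
    data.frame(
      image_id = rep(ann$image_id, 2L),
      jaw = c("upper", "lower"),
      expert = unname(ann$kennedy[c("upper", "lower")]),
      derived = c(classify_jaw(maps$upper), classify_jaw(maps$lower)),
      edentulous = c(!any(maps$upper$present[2:15]),
                     !any(maps$lower$present[2:15])),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out$agree <- out$expert == out$derived
  out[, c("image_id", "jaw", "expert", "derived", "agree", "edentulous")]
}
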