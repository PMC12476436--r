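#' FDI two-digit tooth notation
#'
#' Permanent-dentition tooth positions are written as two-digit codes
#' `10 * quadrant + index`: quadrant 1 = upper right, 2 = upper left,
#' 3 = lower left, 4 = lower right; index 1 (central incisor) through
#' 8 (third molar / wisdom tooth). Exactly 32 positions exist.
#'
#' Internally every operation decomposes a code into its
#' `(quadrant, index)` pair before doing arithmetic; the two-digit
#' integer is a serialization, not the working representation.
#'
#' @param quadrant integer vector in 1..4
#' @param index integer vector in 1..8
#' @return [fdi_position()] returns the integer two-digit code(s).
#' @examples
#' fdi_position(1, 7)   # 17, upper-right second molar
#' fdi_flip(11)         # 21
#' @export
fdi_position <- function(quadrant, index) {
  quadrant <- as.integer(quadrant)
  index <- as.integer(index)
  bad <- is.na(quadrant) | is.na(index) | quadrant < 1L | quadrant > 4L |
    index < 1L | index > 8L
  if (any(bad)) {
    stop("invalid FDI quadrant/index pair: (", quadrant[bad][1L], ", ",
         index[bad][1L], ")", call. = FALSE)
  }
  10L * quadrant + index
}

#' All 32 FDI position codes
#'
#' @return integer vector of the 32 codes, quadrant-major (11..18, 21..28,
#'   31..38, 41..48).
#' @export
all_fdi_codes <- function() {
  as.integer(outer(c(10L, 20L, 30L, 40L), 1:8, `+`))
}

#' Validate FDI codes
#'
#' @param code integer vector of candidate two-digit codes
#' @return the codes, invisibly coerced to integer; invalid codes abort with a
#'   message naming the first offending code.
#' @export
fdi_validate <- function(code) {
  code <- suppressWarnings(as.integer(code))
  q <- code %/% 10L
  i <- code %% 10L
  bad <- is.na(code) | q < 1L | q > 4L | i < 1L | i > 8L
  if (any(bad)) {
    offender <- if (all(is.na(code[bad]))) "NA" else code[bad & !is.na(code)][1L]
    stop("invalid FDI code: ", offender, call. = FALSE)
  }
  invisible(code)
}

#' @rdname fdi_position
#' @param code integer vector of valid two-digit codes
#' @export
fdi_quadrant <- function(code) {
  fdi_validate(code)
  as.integer(code) %/% 10L
}

#' @rdname fdi_position
#' @export
fdi_index <- function(code) {
  fdi_validate(code)
  as.integer(code) %% 10L
}

#' Jaw and side of an FDI position
#'
#' @param code integer vector of valid two-digit codes
#' @return `fdi_jaw`: `"upper"` (quadrants 1, 2) or `"lower"` (3, 4);
#'   `fdi_side`: `"right"` (quadrants 1, 4) or `"left"` (2, 3).
#' @export
fdi_jaw <- function(code) {
  q <- fdi_quadrant(code)
  ifelse(q <= 2L, "upper", "lower")
}

#' @rdname fdi_jaw
#' @export
fdi_side <- function(code) {
  q <- fdi_quadrant(code)
  ifelse(q == 1L | q == 4L, "right", "left")
}

.tooth_classes <- c("central-incisor", "lateral-incisor", "canine",
                    "first-premolar", "second-premolar",
                    "first-molar", "second-molar", "third-molar")

#' Morphological tooth class of a position
#'
#' Determined solely by the index: 1 maps to central-incisor, ..., 8 to
#' third-molar. Morphologically similar groups (notably the molars) are where
#' detectors confuse labels most.
#'
#' @param code integer vector of valid two-digit codes
#' @return character vector of class names
#' @export
tooth_class <- function(code) {
  .tooth_classes[fdi_index(code)]
}

#' Mirror an FDI position across the midline
#'
#' Horizontal image flips swap the left and right quadrants (1 with 2, 3 with
#' 4) while the index is unchanged; applying the flip twice is the identity.
#' Used, e.g., to remap labels of horizontally flipped training images.
#'
#' @param code integer vector of valid two-digit codes
#' @return integer vector of flipped codes
#' @export
fdi_flip <- function(code) {
  q <- fdi_quadrant(code)
  i <- fdi_index(code)
  qf <- c(2L, 1L, 4L, 3L)[q]
  10L * qf + i
}

#' Position-level predicates used by the Kennedy rules
#'
#' @param code a single valid two-digit code
#' @return a list with `code`, `quadrant`, `index`, `jaw`, `side`,
#'   `tooth_class`, `is_second_molar` (codes 17, 27, 37, 47),
#'   `is_central_incisor` (11, 21, 31, 41) and `is_wisdom` (index 8).
#' @export
fdi_predicates <- function(code) {
  fdi_validate(code)
  stopifnot(length(code) == 1L)
  i <- fdi_index(code)
  list(
    code = as.integer(code),
    quadrant = fdi_quadrant(code),
    index = i,
    jaw = fdi_jaw(code),
    side = fdi_side(code),
    tooth_class = tooth_class(code),
    is_second_molar = i == 7L,
    is_central_incisor = i == 1L,
    is_wisdom = i == 8L
  )
}

#' Anatomical arc order of a jaw's 16 positions
#'
#' Positions ordered along the dental arch: right side from the third molar
#' inward to the central incisor, then left side outward (upper:
#' 18, 17, ..., 11, 21, ..., 28; lower: 48, 47, ..., 41, 31, ..., 38). This
#' ordering makes "across the midline" contiguous, which the Kennedy class-IV
#' rule relies on.
#'
#' @param jaw `"upper"` or `"lower"`
#' @return integer vector of 16 codes in arc order
#' @export
jaw_arc <- function(jaw) {
  jaw <- match.arg(jaw, c("upper", "lower"))
  if (jaw == "upper") {
    c(10L + 8:1, 20L + 1:8)
  } else {
    c(40L + 8:1, 30L + 1:8)
  }
}
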