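#' Binary pixel masks on the image grid
#'
#' A `tooth_mask` is a set of pixels on an `h x w` image grid, stored as a
#' sorted vector of column-major linear indices plus the grid dimensions.
#' All operations have set semantics on the full image grid, so results are
#' identical to computing on full-frame bitmaps. The grid is row-major
#' top-left in image terms: pixel (row r, column c), r in 1..h, c in 1..w,
#' has linear index `(c - 1) * h + r` and covers the half-open box
#' `[c-1, c) x [r-1, r)` in zero-based pixel coordinates.
#'
#' @param idx integer vector of linear pixel indices (1-based, column-major)
#' @param dim integer vector `c(h, w)` of the image grid
#' @return a `tooth_mask` object
#' @export
tooth_mask <- function(idx, dim) {
  dim <- as.integer(dim)
  stopifnot(length(dim) == 2L, all(dim >= 1L))
  idx <- sort(unique(as.integer(idx)))
  if (length(idx) && (idx[1L] < 1L || idx[length(idx)] > prod(dim))) {
    stop("mask pixel index out of the image grid", call. = FALSE)
  }
  structure(list(idx = idx, dim = dim), class = "tooth_mask")
}

#' @rdname tooth_mask
#' @param m a logical (or 0/1) matrix, rows = image rows
#' @export
mask_from_matrix <- function(m) {
  tooth_mask(which(m != 0), dim(m))
}

#' @rdname tooth_mask
#' @param x a `tooth_mask`
#' @param ... unused
#' @export
as.matrix.tooth_mask <- function(x, ...) {
  m <- matrix(FALSE, x$dim[1L], x$dim[2L])
  m[x$idx] <- TRUE
  m
}

#' @export
print.tooth_mask <- function(x, ...) {
  cat(sprintf("<tooth_mask: %d px on %dx%d grid>\n",
              length(x$idx), x$dim[1L], x$dim[2L]))
  invisible(x)
}

#' @rdname tooth_mask
#' @export
mask_area <- function(x) {
  stopifnot(inherits(x, "tooth_mask"))
  length(x$idx)
}

#' Tight bounding box of a mask
#'
#' @param x a non-empty `tooth_mask`
#' @return numeric `c(x_min, y_min, x_max, y_max)`, zero-based, half-open
#'   (`x_max`/`y_max` exclusive), in pixel units.
#' @export
mask_bbox <- function(x) {
  stopifnot(inherits(x, "tooth_mask"))
  if (!length(x$idx)) stop("bounding box of an empty mask is undefined", call. = FALSE)
  h <- x$dim[1L]
  r <- (x$idx - 1L) %% h + 1L
  c <- (x$idx - 1L) %/% h + 1L
  c(min(c) - 1L, min(r) - 1L, max(c), max(r))
}

#' Translate a mask on its grid
#'
#' Pixels shifted outside the grid are clipped away.
#'
#' @param x a `tooth_mask`
#' @param dx,dy integer shift in columns / rows
#' @return the shifted `tooth_mask`
#' @export
mask_shift <- function(x, dx, dy) {
  stopifnot(inherits(x, "tooth_mask"))
  h <- x$dim[1L]; w <- x$dim[2L]
  r <- (x$idx - 1L) %% h + 1L + as.integer(dy)
  c <- (x$idx - 1L) %/% h + 1L + as.integer(dx)
  keep <- r >= 1L & r <= h & c >= 1L & c <= w
  tooth_mask((c[keep] - 1L) * h + r[keep], x$dim)
}

.check_same_grid <- function(a, b) {
  if (!identical(a$dim, b$dim)) {
    stop("masks live on different image grids (", paste(a$dim, collapse = "x"),
         " vs ", paste(b$dim, collapse = "x"), ")", call. = FALSE)
  }
}

#' Intersection-over-Union of two masks
#'
#' `|a intersect b| / |a union b|` of the two pixel sets. An IoU of 1/3
#' corresponds to a Dice coefficient of 1/2. Undefined (an error) when both
#' masks are empty.
#'
#' @param a,b `tooth_mask` objects on the same grid
#' @return a number in `[0, 1]`
#' @export
mask_iou <- function(a, b) {
  stopifnot(inherits(a, "tooth_mask"), inherits(b, "tooth_mask"))
  .check_same_grid(a, b)
  na <- length(a$idx); nb <- length(b$idx)
  if (na == 0L && nb == 0L) {
    stop("IoU of two empty masks is undefined", call. = FALSE)
  }
  ni <- length(intersect(a$idx, b$idx))
  ni / (na + nb - ni)
}

#' Fraction of a candidate mask not yet occupied
#'
#' The share of the candidate's pixels that are "new", i.e. not contained in
#' the occupied set. This is the quantity the geometric duplicate filter
#' thresholds: a candidate mostly covered by previously selected instances is
#' a duplicate proposal, while small overlaps with neighboring teeth are
#' expected and pass.
#'
#' @param candidate a non-empty `tooth_mask`
#' @param occupied a `tooth_mask` of already-claimed pixels (may be empty)
#' @return a number in `[0, 1]`
#' @export
novel_pixel_fraction <- function(candidate, occupied) {
  stopifnot(inherits(candidate, "tooth_mask"), inherits(occupied, "tooth_mask"))
  .check_same_grid(candidate, occupied)
  n <- length(candidate$idx)
  if (n == 0L) stop("novel pixel fraction of an empty candidate is undefined", call. = FALSE)
  sum(!(candidate$idx %in% occupied$idx)) / n
}

# ---- COCO-style mask encodings -------------------------------------------

#' Uncompressed run-length encoding of a mask
#'
#' COCO-convention RLE: the flattened column-major pixel sequence is encoded
#' as alternating run lengths starting with a (possibly zero) run of
#' background pixels.
#'
#' @param x a `tooth_mask`
#' @return a list with `size = c(h, w)` and integer `counts`
#' @export
mask_to_rle <- function(x) {
  stopifnot(inherits(x, "tooth_mask"))
  n <- prod(x$dim)
  idx <- x$idx
  if (!length(idx)) return(list(size = x$dim, counts = n))
  # boundaries between runs: positions where membership changes
  starts <- idx[c(TRUE, diff(idx) > 1L)]
  ends <- idx[c(diff(idx) > 1L, TRUE)]
  counts <- integer(0)
  prev_end <- 0L
  for (k in seq_along(starts)) {
    counts <- c(counts, starts[k] - prev_end - 1L, ends[k] - starts[k] + 1L)
    prev_end <- ends[k]
  }
  if (prev_end < n) counts <- c(counts, n - prev_end)
  list(size = x$dim, counts = as.integer(counts))
}

#' @rdname mask_to_rle
#' @param counts integer run lengths (background run first)
#' @param dim integer `c(h, w)`
#' @export
mask_from_rle <- function(counts, dim) {
  counts <- as.integer(counts)
  dim <- as.integer(dim)
  if (any(counts < 0L) || sum(counts) != prod(dim)) {
    stop("RLE counts do not tile a ", dim[1L], "x", dim[2L], " grid", call. = FALSE)
  }
  ends <- cumsum(counts)
  starts <- c(1L, ends[-length(ends)] + 1L)
  on <- seq_along(counts) %% 2L == 0L  # even runs are foreground
  idx <- unlist(lapply(which(on & counts > 0L), function(k) starts[k]:ends[k]),
                use.names = FALSE)
  tooth_mask(idx, dim)
}

#' Rasterize COCO-style polygons to a mask
#'
#' Even-odd scanline fill over pixel centers: pixel (r, c) is covered when its
#' center `(c - 0.5, r - 0.5)` (zero-based coordinates) lies inside an odd
#' number of polygon boundaries.
#'
#' @param polygons a list of numeric vectors `c(x1, y1, x2, y2, ...)` in
#'   zero-based pixel coordinates
#' @param dim integer `c(h, w)`
#' @return a `tooth_mask`
#' @export
mask_from_polygon <- function(polygons, dim) {
  dim <- as.integer(dim)
  h <- dim[1L]; w <- dim[2L]
  if (is.numeric(polygons)) polygons <- list(polygons)
  idx <- integer(0)
  for (poly in polygons) {
    if (length(poly) < 6L || length(poly) %% 2L != 0L) {
      stop("polygon must be a flat x,y list with at least 3 vertices", call. = FALSE)
    }
    px <- poly[seq(1L, length(poly), 2L)]
    py <- poly[seq(2L, length(poly), 2L)]
    nx <- c(px[-1L], px[1L]); ny <- c(py[-1L], py[1L])
    rows <- seq_len(h)
    for (r in rows[rows - 0.5 >= min(py) & rows - 0.5 <= max(py)]) {
      yc <- r - 0.5
      crosses <- (py <= yc & ny > yc) | (ny <= yc & py > yc)
      if (!any(crosses)) next
      xc <- px[crosses] + (yc - py[crosses]) * (nx[crosses] - px[crosses]) /
        (ny[crosses] - py[crosses])
      xc <- sort(xc)
      for (k in seq(1L, length(xc) - 1L, by = 2L)) {
        c0 <- ceiling(xc[k] + 0.5)
        c1 <- ceiling(xc[k + 1L] + 0.5) - 1L
        c0 <- max(c0, 1L); c1 <- min(c1, w)
        if (c0 <= c1) idx <- c(idx, (c0:c1 - 1L) * h + r)
      }
    }
  }
  tooth_mask(idx, dim)
}

#' Filled-ellipse mask
#'
#' Axis-aligned ellipse centered at `(cx, cy)` in zero-based pixel
#' coordinates with half-axes `rx`, `ry`; a pixel belongs to the mask when
#' its center lies inside the ellipse. Used by the synthetic scene renderer.
#'
#' @param cx,cy center, zero-based pixel coordinates
#' @param rx,ry half-axes in pixels (positive)
#' @param dim integer `c(h, w)`
#' @return a `tooth_mask`
#' @export
ellipse_mask <- function(cx, cy, rx, ry, dim) {
  if (rx <= 0 || ry <= 0) stop("degenerate ellipse: non-positive half-axis", call. = FALSE)
  h <- as.integer(dim[1L]); w <- as.integer(dim[2L])
  cols <- seq_len(w)
  cols <- cols[abs(cols - 0.5 - cx) < rx]
  idx <- integer(0)
  for (c in cols) {
    hh <- ry * sqrt(1 - ((c - 0.5 - cx) / rx)^2)
    r0 <- max(1L, as.integer(ceiling(cy - hh + 0.5)))
    r1 <- min(h, as.integer(ceiling(cy + hh + 0.5) - 1))
    if (r0 <= r1) idx <- c(idx, (c - 1L) * h + r0:r1)
  }
  if (!length(idx)) stop("degenerate ellipse: rasterizes to zero pixels", call. = FALSE)
  tooth_mask(idx, c(h, w))
}
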