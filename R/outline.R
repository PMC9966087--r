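#' Closed outline contours
#'
#' An `outline` is an ordered, closed sequence of 2-D points describing one
#' digitized structure of one specimen (head capsule with stylets, head
#' capsule alone, stylets, or whole body with/without stylets).  The last
#' point implicitly connects back to the first; orientation is always
#' counter-clockwise (positive signed area) after construction.
#'
#' @param points two-column numeric matrix (or coercible) of x,y vertices.
#'   Consecutive duplicate points are merged with a warning; if the last
#'   point repeats the first it is dropped (closure is implicit).
#' @param structure_class one of `"head_with_stylets"`, `"head_capsule"`,
#'   `"stylet"`, `"body_with_stylets"`, `"body_without_stylets"`.
#' @param specimen_id identifier string carried through the pipeline.
#' @param scale optional physical units per coordinate unit (e.g. mm/px);
#'   `NA` means coordinates are dimensionless.
#' @return an object of class `outline`: a list with elements `points`
#'   (n x 2 matrix), `closed` (always `TRUE`), `structure_class`,
#'   `specimen_id` and `scale`.
#' @examples
#' sq <- outline(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)))
#' outline_perimeter(sq)   # 4
#' outline_area(sq)        # 1
#' @export
outline <- function(points, structure_class = "head_with_stylets",
                    specimen_id = "unnamed", scale = NA_real_) {
  points <- as.matrix(points)
  if (ncol(points) != 2L)
    stop("outline points must have two columns (x, y)", call. = FALSE)
  storage.mode(points) <- "double"
  if (anyNA(points) || any(!is.finite(points)))
    stop("outline points must be finite", call. = FALSE)
  structure_class <- match.arg(structure_class, outline_structure_classes())

  # drop an explicit closing vertex; closure is implicit
  n <- nrow(points)
  if (n >= 2L && all(points[1L, ] == points[n, ]))
    points <- points[-n, , drop = FALSE]

  points <- merge_duplicate_vertices(points)
  if (nrow(points) < 3L)
    stop("degenerate contour: fewer than 3 distinct points", call. = FALSE)
  if (outline_perimeter_of(points) <= 0)
    stop("degenerate contour: zero perimeter", call. = FALSE)
  if (abs(signed_area(points)) <= 0)
    stop("degenerate contour: zero enclosed area (collinear points)",
         call. = FALSE)

  # normalize orientation to counter-clockwise
  if (signed_area(points) < 0)
    points <- points[rev(seq_len(nrow(points))), , drop = FALSE]

  structure(
    list(points = points, closed = TRUE, structure_class = structure_class,
         specimen_id = specimen_id, scale = scale),
    class = "outline"
  )
}

outline_structure_classes <- function() {
  c("head_with_stylets", "head_capsule", "stylet",
    "body_with_stylets", "body_without_stylets")
}

merge_duplicate_vertices <- function(points) {
  n <- nrow(points)
  if (n < 2L) return(points)
  dup <- c(FALSE, rowSums(abs(diff(points))) == 0)
  if (any(dup)) {
    warning(sprintf("merged %d duplicate consecutive point(s)", sum(dup)),
            call. = FALSE)
    points <- points[!dup, , drop = FALSE]
  }
  points
}

#' @export
print.outline <- function(x, ...) {
  cat(sprintf("<outline> %s | %s | %d points | perimeter %.4g\n",
              x$specimen_id, x$structure_class, nrow(x$points),
              outline_perimeter(x)))
  invisible(x)
}

# shoelace signed area of an implicitly closed polygon (positive = CCW)
signed_area <- function(points) {
  x <- points[, 1L]; y <- points[, 2L]
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  sum(x * yn - xn * y) / 2
}

outline_perimeter_of <- function(points) {
  closed <- rbind(points, points[1L, ])
  sum(sqrt(rowSums(diff(closed)^2)))
}

#' Perimeter and enclosed area of an outline
#'
#' @param c an [outline] object.
#' @return `outline_perimeter()`: total arc length around the closed
#'   contour; `outline_area()`: shoelace area (positive, since outlines
#'   are stored counter-clockwise).
#' @export
outline_perimeter <- function(c) {
  stopifnot(inherits(c, "outline"))
  outline_perimeter_of(c$points)
}

#' @rdname outline_perimeter
#' @export
outline_area <- function(c) {
  stopifnot(inherits(c, "outline"))
  signed_area(c$points)
}

#' Resample an outline to equally spaced points
#'
#' Places `n_points` points at equal arc-length intervals along the closed
#' contour, starting at the contour's first point.  Equal spacing is what
#' puts all specimens on a common footing before elliptic Fourier
#' decomposition.
#'
#' @param c an [outline].
#' @param n_points number of points, at least 8.
#' @return a new [outline] with `n_points` vertices.
#' @export
resample_contour <- function(c, n_points) {
  stopifnot(inherits(c, "outline"))
  if (!is.numeric(n_points) || length(n_points) != 1L || n_points < 8 ||
      n_points != round(n_points))
    stop("n_points must be an integer >= 8", call. = FALSE)
  n_points <- as.integer(n_points)

  pts <- rbind(c$points, c$points[1L, ])
  seg <- sqrt(rowSums(diff(pts)^2))
  s <- c(0, cumsum(seg))           # cumulative arc length at each vertex
  total <- s[length(s)]
  target <- total * (seq_len(n_points) - 1L) / n_points

  # locate each target arc length on the polyline
  idx <- findInterval(target, s, rightmost.closed = TRUE)
  idx[idx >= length(s)] <- length(s) - 1L
  frac <- (target - s[idx]) / seg[idx]
  new_pts <- pts[idx, , drop = FALSE] +
    frac * (pts[idx + 1L, , drop = FALSE] - pts[idx, , drop = FALSE])

  out <- c
  out$points <- new_pts
  out
}

#' Write an outline as a CSV point list
#'
#' One `x,y` pair per line; lines beginning with `#` are comments; closure
#' is implicit.  This is the package's plain-text interchange dialect and
#' round-trips bit-exactly with [read_outline].
#'
#' @param c an [outline].
#' @param path file to write.
#' @return `path`, invisibly.
#' @export
write_outline_csv <- function(c, path) {
  stopifnot(inherits(c, "outline"))
  header <- c(
    sprintf("# specimen_id: %s", c$specimen_id),
    sprintf("# structure_class: %s", c$structure_class)
  )
  if (!is.na(c$scale)) header <- c(header, sprintf("# scale: %.17g", c$scale))
  body <- sprintf("%.17g,%.17g", c$points[, 1L], c$points[, 2L])
  writeLines(c(header, body), path)
  invisible(path)
}
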