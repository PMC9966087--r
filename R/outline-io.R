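#' Read a closed outline from file
#'
#' Supports three plain-text dialects used for digitized larval outlines:
#' \describe{
#'   \item{`csv`}{one `x,y` pair per line, `#` comments, closure implicit
#'     (the dialect written by [write_outline_csv]).}
#'   \item{`svg`}{an SVG 1.1 document; path data restricted to the
#'     M/L/C/Q/Z commands (absolute or relative).  Bezier curves are
#'     flattened to polylines at a chordal tolerance.  Exactly one closed
#'     subpath must be present unless `subpath` selects one.  SVG's
#'     downward y-axis is flipped on ingestion (`flip_y = TRUE`) so that
#'     all internal geometry is right-handed.}
#'   \item{`chain`}{Freeman 8-direction chain code: line 1 holds the
#'     `x y` start coordinate, subsequent lines whitespace-separated codes
#'     0-7 (0 = +x, 2 = +y, 4 = -x, 6 = -y; odd codes diagonal).  The code
#'     sequence must return to the start.}
#' }
#'
#' @param path file to read.
#' @param format `"csv"`, `"svg"` or `"chain"`; inferred from the file
#'   extension when omitted.
#' @param structure_class,specimen_id passed to [outline]; `specimen_id`
#'   defaults to the file base name (CSV header comments override it).
#' @param subpath for SVG input with several closed subpaths: which one to
#'   take (1-based, in document order).
#' @param flatten_tol chordal tolerance for Bezier flattening, as a
#'   fraction of the path bounding-box diagonal (default 0.001).
#' @param flip_y flip the y-axis of SVG input (default `TRUE`).
#' @return an [outline], orientation normalized to counter-clockwise.
#' @export
read_outline <- function(path, format = c("auto", "csv", "svg", "chain"),
                         structure_class = "head_with_stylets",
                         specimen_id = NULL, subpath = NULL,
                         flatten_tol = 0.001, flip_y = TRUE) {
  format <- match.arg(format)
  if (!file.exists(path))
    stop(sprintf("file not found: %s", path), call. = FALSE)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, svg = "svg", chain = "chain", chn = "chain", "csv")
  }
  if (is.null(specimen_id))
    specimen_id <- tools::file_path_sans_ext(basename(path))

  switch(format,
    csv   = read_outline_csv(path, structure_class, specimen_id),
    svg   = read_outline_svg(path, structure_class, specimen_id,
                             subpath, flatten_tol, flip_y),
    chain = read_outline_chain(path, structure_class, specimen_id)
  )
}

read_outline_csv <- function(path, structure_class, specimen_id) {
  lines <- readLines(path, warn = FALSE)
  meta <- grep("^#", lines, value = TRUE)
  get_meta <- function(key) {
    m <- grep(sprintf("^#\\s*%s:", key), meta, value = TRUE)
    if (length(m)) trimws(sub(sprintf("^#\\s*%s:", key), "", m[1L])) else NULL
  }
  if (!is.null(v <- get_meta("specimen_id"))) specimen_id <- v
  if (!is.null(v <- get_meta("structure_class"))) structure_class <- v
  scale <- if (!is.null(v <- get_meta("scale"))) as.numeric(v) else NA_real_

  body <- trimws(sub("#.*$", "", lines))
  body <- body[nzchar(body)]
  if (!length(body))
    stop("degenerate contour: no coordinate lines in CSV", call. = FALSE)
  parts <- strsplit(body, "[,;[:space:]]+")
  if (any(lengths(parts) != 2L))
    stop("malformed CSV outline: expected one 'x,y' pair per line",
         call. = FALSE)
  xy <- matrix(as.numeric(unlist(parts)), ncol = 2L, byrow = TRUE)
  if (anyNA(xy))
    stop("malformed CSV outline: non-numeric coordinate", call. = FALSE)
  outline(xy, structure_class, specimen_id, scale)
}

read_outline_chain <- function(path, structure_class, specimen_id) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2L)
    stop("malformed chain-code file: need start line and codes", call. = FALSE)
  start <- as.numeric(strsplit(lines[1L], "[[:space:]]+")[[1L]])
  if (length(start) != 2L || anyNA(start))
    stop("malformed chain-code file: line 1 must be 'x y'", call. = FALSE)
  codes <- as.integer(unlist(strsplit(lines[-1L], "[[:space:]]+")))
  if (anyNA(codes) || any(codes < 0L | codes > 7L))
    stop("malformed chain-code file: codes must be integers 0-7",
         call. = FALSE)
  if (length(codes) < 3L)
    stop("degenerate contour: fewer than 3 chain moves", call. = FALSE)

  # Freeman 8-neighbourhood steps, code 0 = +x, counter-clockwise
  dx <- c(1, 1, 0, -1, -1, -1, 0, 1)[codes + 1L]
  dy <- c(0, 1, 1, 1, 0, -1, -1, -1)[codes + 1L]
  x <- start[1L] + cumsum(dx)
  y <- start[2L] + cumsum(dy)
  if (x[length(x)] != start[1L] || y[length(y)] != start[2L])
    stop("unclosed chain code: moves do not return to the start",
         call. = FALSE)
  pts <- cbind(c(start[1L], x[-length(x)]), c(start[2L], y[-length(y)]))
  outline(pts, structure_class, specimen_id)
}

read_outline_svg <- function(path, structure_class, specimen_id,
                             subpath, flatten_tol, flip_y) {
  doc <- xml2::read_xml(path)
  paths <- xml2::xml_find_all(doc, ".//*[local-name() = 'path']")
  if (!length(paths))
    stop("no <path> element in SVG file", call. = FALSE)
  d_all <- unlist(lapply(paths, function(p) xml2::xml_attr(p, "d")))
  subpaths <- unlist(lapply(d_all, svg_path_subpaths, tol = flatten_tol),
                     recursive = FALSE)
  closed <- Filter(function(s) s$closed, subpaths)
  if (!length(closed)) {
    if (length(subpaths))
      stop("unclosed path: SVG subpath lacks a Z close command",
           call. = FALSE)
    stop("no path data in SVG file", call. = FALSE)
  }
  if (length(closed) > 1L && is.null(subpath))
    stop(sprintf(paste0("ambiguous SVG: %d closed subpaths; ",
                        "pass subpath = <index> to select one"),
                 length(closed)), call. = FALSE)
  sel <- if (is.null(subpath)) 1L else as.integer(subpath)
  if (sel < 1L || sel > length(closed))
    stop("subpath index out of range", call. = FALSE)
  pts <- closed[[sel]]$points
  dimnames(pts) <- NULL
  if (flip_y) pts[, 2L] <- -pts[, 2L]
  outline(pts, structure_class, specimen_id)
}

# ---- SVG path-data parsing ------------------------------------------------

# Tokenize path data and flatten into a list of subpaths, each a list
# (points = matrix, closed = logical).  Only M/L/C/Q/Z (and their relative
# forms) are accepted; curves are flattened by adaptive de Casteljau
# subdivision at a chordal tolerance expressed as a fraction of the overall
# control-point bounding-box diagonal.
svg_path_subpaths <- function(d, tol = 0.001) {
  if (is.na(d) || !nzchar(trimws(d))) return(list())
  tokens <- svg_tokenize_path(d)

  nums <- suppressWarnings(as.numeric(tokens))
  diag_len <- {
    v <- nums[!is.na(nums)]
    if (length(v) >= 4L) {
      xs <- v[seq(1L, length(v) - 1L, by = 2L)]
      ys <- v[seq(2L, length(v), by = 2L)]
      sqrt(diff(range(xs))^2 + diff(range(ys))^2)
    } else 1
  }
  abs_tol <- max(tol * diag_len, 1e-12)

  subpaths <- list()
  cur <- NULL            # growing point matrix of the current subpath
  pos <- c(0, 0)
  start <- c(0, 0)
  i <- 1L
  cmd <- ""
  take <- function(k) {
    if (i + k - 1L > length(tokens))
      stop("malformed SVG path data: truncated arguments", call. = FALSE)
    v <- suppressWarnings(as.numeric(tokens[i:(i + k - 1L)]))
    if (anyNA(v))
      stop("malformed SVG path data: expected number", call. = FALSE)
    i <<- i + k
    v
  }
  flush_subpath <- function(is_closed) {
    if (!is.null(cur) && nrow(cur) >= 1L)
      subpaths[[length(subpaths) + 1L]] <<-
        list(points = cur, closed = is_closed)
    cur <<- NULL
  }

  while (i <= length(tokens)) {
    tok <- tokens[i]
    if (tok %in% c("M", "m", "L", "l", "C", "c", "Q", "q", "Z", "z")) {
      cmd <- tok
      i <- i + 1L
      if (cmd %in% c("Z", "z")) {
        flush_subpath(TRUE)
        pos <- start
      }
      next
    }
    if (!nzchar(cmd))
      stop("malformed SVG path data: coordinates before any command",
           call. = FALSE)
    rel <- cmd %in% c("m", "l", "c", "q")
    base <- switch(tolower(cmd),
      m = {
        p <- take(2L); if (rel) p <- pos + p
        flush_subpath(FALSE)       # implicit new subpath
        start <- p; pos <- p
        cur <- matrix(p, ncol = 2L)
        cmd <- if (cmd == "m") "l" else "L"   # subsequent pairs are linetos
        NULL
      },
      l = {
        p <- take(2L); if (rel) p <- pos + p
        cur <- rbind(cur, p); pos <- p
        NULL
      },
      c = {
        v <- take(6L)
        ctrl <- matrix(v, ncol = 2L, byrow = TRUE)
        if (rel) ctrl <- sweep(ctrl, 2L, pos, "+")
        seg <- flatten_bezier(rbind(pos, ctrl), abs_tol)
        cur <- rbind(cur, seg[-1L, , drop = FALSE])
        pos <- ctrl[3L, ]
        NULL
      },
      q = {
        v <- take(4L)
        ctrl <- matrix(v, ncol = 2L, byrow = TRUE)
        if (rel) ctrl <- sweep(ctrl, 2L, pos, "+")
        seg <- flatten_bezier(rbind(pos, ctrl), abs_tol)
        cur <- rbind(cur, seg[-1L, , drop = FALSE])
        pos <- ctrl[2L, ]
        NULL
      },
      stop(sprintf("unsupported SVG path command '%s' (only M/L/C/Q/Z)",
                   cmd), call. = FALSE)
    )
  }
  flush_subpath(FALSE)
  subpaths
}

svg_tokenize_path <- function(d) {
  # reject unsupported commands early with a clear message
  bad <- regmatches(d, gregexpr("[A-DF-Za-df-z]", d))[[1L]]
  bad <- setdiff(unique(bad), c("M", "m", "L", "l", "C", "c", "Q", "q",
                                "Z", "z", "e", "E"))
  if (length(bad))
    stop(sprintf("unsupported SVG path command(s): %s (only M/L/C/Q/Z)",
                 paste(bad, collapse = " ")), call. = FALSE)
  d <- gsub("([MmLlCcQqZz])", " \\1 ", d)
  d <- gsub(",", " ", d)
  d <- gsub("(?<=[0-9.eE])-", " -", d, perl = TRUE)   # "1-2" -> "1 -2"
  d <- gsub("e -", "e-", d, fixed = TRUE)             # undo exponent split
  d <- gsub("E -", "E-", d, fixed = TRUE)
  tokens <- strsplit(trimws(d), "[[:space:]]+")[[1L]]
  tokens[nzchar(tokens)]
}

# Adaptive flattening of a quadratic (3 rows) or cubic (4 rows) Bezier
# given as a control-point matrix including both endpoints.
flatten_bezier <- function(ctrl, tol, depth = 0L) {
  p0 <- ctrl[1L, ]; pn <- ctrl[nrow(ctrl), ]
  inner <- ctrl[-c(1L, nrow(ctrl)), , drop = FALSE]
  chord <- pn - p0
  clen <- sqrt(sum(chord^2))
  dev <- if (clen < 1e-300) {
    sqrt(max(rowSums(sweep(inner, 2L, p0)^2)))
  } else {
    # perpendicular distance of control points from the chord
    max(abs((inner[, 1L] - p0[1L]) * chord[2L] -
            (inner[, 2L] - p0[2L]) * chord[1L]) / clen)
  }
  if (dev <= tol || depth >= 24L) return(rbind(p0, pn))
  left_right <- de_casteljau_split(ctrl)
  a <- flatten_bezier(left_right$left, tol, depth + 1L)
  b <- flatten_bezier(left_right$right, tol, depth + 1L)
  rbind(a, b[-1L, , drop = FALSE])
}

de_casteljau_split <- function(ctrl, t = 0.5) {
  left <- ctrl[1L, , drop = FALSE]
  right <- ctrl[nrow(ctrl), , drop = FALSE]
  work <- ctrl
  while (nrow(work) > 1L) {
    work <- (1 - t) * work[-nrow(work), , drop = FALSE] +
      t * work[-1L, , drop = FALSE]
    left <- rbind(left, work[1L, ])
    right <- rbind(work[nrow(work), ], right)
  }
  list(left = left, right = right)
}
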