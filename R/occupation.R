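# run code under a fixed seed without disturbing the caller's RNG stream
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

#' Convex hull area of a 2-D point set
#'
#' Shoelace area of the convex hull; the quantitative counterpart of the
#' shaded "occupied area" in PC1 x PC2 scatterplots.  Fewer than 3 points,
#' or collinear points, have area 0.
#'
#' @param points two-column matrix of coordinates.
#' @return non-negative hull area (score units squared).
#' @export
hull_area <- function(points) {
  points <- as.matrix(points)
  if (!nrow(points)) return(0)
  if (ncol(points) != 2L)
    stop("points must have two columns", call. = FALSE)
  if (anyNA(points) || any(!is.finite(points)))
    stop("non-finite coordinate in hull_area input", call. = FALSE)
  v <- hull_vertices(points)
  if (nrow(v) < 3L) return(0)
  abs(signed_area(v))
}

# CCW-ordered convex hull vertices (chull returns clockwise order)
hull_vertices <- function(points) {
  points <- unique(as.matrix(points))
  if (nrow(points) < 3L) return(points)
  idx <- grDevices::chull(points)
  v <- points[rev(idx), , drop = FALSE]
  if (nrow(v) >= 3L && signed_area(v) < 0)
    v <- v[rev(seq_len(nrow(v))), , drop = FALSE]
  v
}

#' Per-group morphospace occupation
#'
#' Computes, for every distinct group label (typically epoch: Cretaceous,
#' Eocene, extant), the convex hull of that group's specimens in a chosen
#' pair of PC axes, its area and specimen count.
#'
#' @param scores score matrix with columns `PC1`, `PC2`, ... (or plain
#'   column indices), rows aligned with `labels`.
#' @param labels group label per score row.
#' @param pcs pair of component indices defining the occupation plane
#'   (default `c(1, 2)`, matching published PC1 x PC2 scatterplots).
#' @return a list of `group_occupation` records, one per distinct label
#'   (in order of first appearance): `group`, `hull_vertices` (CCW
#'   matrix), `area`, `n`, and `degenerate` (`TRUE` when n < 3 or the
#'   points are collinear, in which case area is 0).
#' @export
group_occupation <- function(scores, labels, pcs = c(1, 2)) {
  scores <- as.matrix(scores)
  if (length(labels) != nrow(scores))
    stop("labels must align with score rows", call. = FALSE)
  if (length(pcs) != 2L)
    stop("pcs must be a pair of component indices", call. = FALSE)
  xy <- scores[, pcs, drop = FALSE]
  groups <- unique(as.character(labels))
  lapply(groups, function(g) {
    p <- xy[as.character(labels) == g, , drop = FALSE]
    v <- hull_vertices(p)
    a <- if (nrow(v) < 3L) 0 else abs(signed_area(v))
    structure(
      list(group = g, hull_vertices = v, area = a, n = nrow(p),
           degenerate = a == 0),
      class = "group_occupation"
    )
  })
}

#' @export
print.group_occupation <- function(x, ...) {
  cat(sprintf("<occupation> %s | n = %d | hull area %.4g%s\n", x$group,
              x$n, x$area, if (x$degenerate) " (degenerate)" else ""))
  invisible(x)
}

#' Area of overlap between two occupation hulls
#'
#' Convex-polygon intersection by Sutherland-Hodgman clipping.  Used e.g.
#' to test whether one epoch's occupied area lies entirely inside
#' another's (`hull_overlap(a, b) == a$area`).
#'
#' @param a,b `group_occupation` records (or plain CCW vertex matrices).
#' @return non-negative overlap area; 0 when the hulls are disjoint or
#'   either is degenerate.
#' @export
hull_overlap <- function(a, b) {
  va <- if (inherits(a, "group_occupation")) a$hull_vertices else as.matrix(a)
  vb <- if (inherits(b, "group_occupation")) b$hull_vertices else as.matrix(b)
  if (nrow(va) < 3L || nrow(vb) < 3L) return(0)
  inter <- clip_convex(va, vb)
  if (is.null(inter) || nrow(inter) < 3L) return(0)
  abs(signed_area(inter))
}

# Sutherland-Hodgman: clip subject polygon by each edge of a convex CCW
# clip polygon
clip_convex <- function(subject, clip) {
  out <- subject
  nc <- nrow(clip)
  for (i in seq_len(nc)) {
    if (is.null(out) || nrow(out) == 0L) return(NULL)
    A <- clip[i, ]; B <- clip[if (i == nc) 1L else i + 1L, ]
    inp <- out
    out <- NULL
    np <- nrow(inp)
    side <- (B[1L] - A[1L]) * (inp[, 2L] - A[2L]) -
      (B[2L] - A[2L]) * (inp[, 1L] - A[1L])
    inside <- side >= -1e-12
    for (j in seq_len(np)) {
      k <- if (j == np) 1L else j + 1L
      P <- inp[j, ]; Q <- inp[k, ]
      if (inside[j]) out <- rbind(out, P)
      if (inside[j] != inside[k]) {
        denom <- side[j] - side[k]
        t <- if (abs(denom) < 1e-300) 0 else side[j] / denom
        out <- rbind(out, P + t * (Q - P))
      }
    }
  }
  out
}

#' Old-versus-expanded subset comparison
#'
#' Compares the hull area of a subset of specimens (e.g. those available
#' to an earlier study) with the hull area of the full set, in the
#' occupation plane.  Because a subset's hull is contained in the full
#' hull, the ratio lies in [0, 1]; a ratio well below 1 means the added
#' specimens genuinely expand the occupied morphospace.
#'
#' @param scores score matrix with row names = specimen ids.
#' @param subset_ids ids forming the subset (must all be present).
#' @param pcs occupation plane (default PC1 x PC2).
#' @return list `area_subset`, `area_full`, `ratio`.
#' @export
subset_comparison <- function(scores, subset_ids, pcs = c(1, 2)) {
  scores <- as.matrix(scores)
  ids <- rownames(scores)
  if (is.null(ids))
    stop("scores must carry specimen ids as row names", call. = FALSE)
  missing <- setdiff(subset_ids, ids)
  if (length(missing))
    stop(sprintf("unknown specimen id(s): %s",
                 paste(utils::head(missing, 5L), collapse = ", ")),
         call. = FALSE)
  xy <- scores[, pcs, drop = FALSE]
  area_full <- hull_area(xy)
  area_subset <- hull_area(xy[ids %in% subset_ids, , drop = FALSE])
  ratio <- if (area_full > 0) area_subset / area_full else 0
  list(area_subset = area_subset, area_full = area_full, ratio = ratio)
}

#' Specimen-accumulation curve of hull area
#'
#' For each subset size k = 1..n, records the mean and 2.5/97.5
#' percentile bounds of the convex hull area over `n_resamples` uniform
#' without-replacement subsets.  Subsets are drawn as prefixes of random
#' specimen permutations (each resample is one accumulation order), so
#' within every resample the area grows monotonically with k and the
#' mean curve is non-decreasing for any seed.  The curve's approach to a
#' plateau (or failure to) is the saturation diagnostic: a flat tail
#' means new specimens no longer enlarge the occupied morphospace.
#'
#' @param scores score matrix (one group's specimens), n >= 3 rows.
#' @param n_resamples resamples per subset size (>= 1).
#' @param seed integer seed; the same seed reproduces the curve exactly.
#' @param pcs occupation plane.
#' @return an `accumulation_curve`: data.frame `k`, `mean_area`,
#'   `ci_low`, `ci_high` plus attributes `n_resamples` and `seed`.
#' @export
accumulation_curve <- function(scores, n_resamples = 200L, seed = 1L,
                               pcs = c(1, 2)) {
  scores <- as.matrix(scores)
  n <- nrow(scores)
  if (n < 3L)
    stop("need at least 3 specimens for an accumulation curve",
         call. = FALSE)
  if (!is.numeric(n_resamples) || n_resamples < 1)
    stop("n_resamples must be >= 1", call. = FALSE)
  n_resamples <- as.integer(n_resamples)
  xy <- scores[, pcs, drop = FALSE]

  areas <- with_seed(seed, {
    vapply(seq_len(n_resamples), function(r) {
      ord <- sample.int(n)
      vapply(seq_len(n), function(k)
        hull_area(xy[ord[seq_len(k)], , drop = FALSE]), 0)
    }, numeric(n))
  })                                       # n x n_resamples
  curve <- data.frame(
    k = seq_len(n),
    mean_area = rowMeans(areas),
    ci_low = apply(areas, 1L, stats::quantile, 0.025, type = 7),
    ci_high = apply(areas, 1L, stats::quantile, 0.975, type = 7)
  )
  # k = n has a single possible subset: exact value, zero-width interval
  full <- hull_area(xy)
  curve$mean_area[n] <- full
  curve$ci_low[n] <- full
  curve$ci_high[n] <- full
  structure(curve, n_resamples = n_resamples, seed = seed,
            class = c("accumulation_curve", "data.frame"))
}

#' Relative tail slope of an accumulation curve
#'
#' Least-squares slope of `mean_area` over the last `tail_fraction` of
#' subset sizes, normalized by the full-group hull area (units: fraction
#' of total area per added specimen).  Values near zero indicate
#' saturation; the default reporting threshold is 0.005.
#'
#' @param curve an [accumulation_curve] with at least 5 subset sizes.
#' @param tail_fraction fraction of the k-range forming the tail
#'   (default 0.2).
#' @param saturated_below reporting threshold for the `saturated` flag.
#' @return list `slope` (normalized), `saturated` (logical), `tail_k`
#'   (the k values used).
#' @export
saturation_slope <- function(curve, tail_fraction = 0.2,
                             saturated_below = 0.005) {
  stopifnot(inherits(curve, "accumulation_curve") || is.data.frame(curve))
  if (nrow(curve) < 5L)
    stop("curve must have at least 5 subset sizes", call. = FALSE)
  n <- nrow(curve)
  n_tail <- max(2L, ceiling(tail_fraction * n))
  tail_rows <- curve[(n - n_tail + 1L):n, ]
  if (nrow(tail_rows) < 2L)
    stop("tail shorter than 2 points", call. = FALSE)
  full <- curve$mean_area[n]
  slope_abs <- stats::coef(stats::lm(mean_area ~ k, data = tail_rows))[["k"]]
  slope <- if (full > 0) slope_abs / full else 0
  list(slope = slope, saturated = slope < saturated_below,
       tail_k = tail_rows$k)
}

#' Full occupation report
#'
#' Bundles per-group occupation, the pairwise overlap matrix, optional
#' subset ratios and per-group accumulation curves into one list, and
#' optionally writes it as JSON.
#'
#' @param scores score matrix with specimen-id row names.
#' @param labels group label per row.
#' @param pcs occupation plane.
#' @param subset_ids optional ids for an old-vs-expanded comparison.
#' @param n_resamples,seed accumulation-curve settings; curves are
#'   computed for groups with at least 3 specimens.
#' @param path optional JSON output file.
#' @return the report list, invisibly if `path` is given.
#' @export
occupation_report <- function(scores, labels, pcs = c(1, 2),
                              subset_ids = NULL, n_resamples = 200L,
                              seed = 1L, path = NULL) {
  occ <- group_occupation(scores, labels, pcs)
  names(occ) <- vapply(occ, function(o) o$group, "")
  groups <- names(occ)
  overlap <- matrix(0, length(groups), length(groups),
                    dimnames = list(groups, groups))
  for (i in seq_along(groups)) for (j in seq_along(groups))
    overlap[i, j] <- hull_overlap(occ[[i]], occ[[j]])

  curves <- lapply(occ, function(o) {
    if (o$n < 3L) return(NULL)
    idx <- as.character(labels) == o$group
    cv <- accumulation_curve(scores[idx, , drop = FALSE],
                             n_resamples = n_resamples, seed = seed,
                             pcs = pcs)
    sat <- saturation_slope(cv)
    list(curve = as.data.frame(cv), slope = sat$slope,
         saturated = sat$saturated)
  })
  report <- list(
    groups = lapply(occ, function(o)
      list(group = o$group, n = o$n, area = o$area,
           degenerate = o$degenerate,
           hull_vertices = unname(apply(o$hull_vertices, 1L, as.numeric,
                                        simplify = FALSE)))),
    overlap = overlap,
    subset = if (!is.null(subset_ids))
      subset_comparison(scores, subset_ids, pcs),
    accumulation = curves,
    settings = list(pcs = pcs, n_resamples = n_resamples, seed = seed)
  )
  if (!is.null(path)) {
    json_report <- report
    # named nested lists keep group labels in the JSON overlap matrix
    json_report$overlap <- lapply(
      stats::setNames(groups, groups),
      function(g) as.list(overlap[g, ]))
    jsonlite::write_json(json_report, path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    return(invisible(report))
  }
  report
}
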