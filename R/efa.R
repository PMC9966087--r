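#' Elliptic Fourier decomposition of a closed outline
#'
#' Computes elliptic Fourier coefficients of a closed polygonal contour by
#' exact line-segment integration of the arc-length parametrization (the
#' closed-form sums over polygon segments, not an FFT).  Each harmonic n
#' contributes four coefficients: `a_n`, `b_n` project the x-coordinate on
#' cos/sin, `c_n`, `d_n` the y-coordinate.  `A0`, `C0` are the arc-length
#' mean point of the outline.
#'
#' @param c an [outline] (closed, counter-clockwise).
#' @param n_harmonics number of harmonics to compute (>= 1).
#' @return an object of class `efa_coef`: list with `A0`, `C0`, numeric
#'   vectors `an`, `bn`, `cn`, `dn` of length `n_harmonics`,
#'   `n_harmonics`, and `normalized = FALSE`.
#' @seealso [efa_normalize], [efa_reconstruct]
#' @examples
#' circ <- outline(cbind(2 * cos(seq(0, 2 * pi, length.out = 91)[-91]),
#'                       2 * sin(seq(0, 2 * pi, length.out = 91)[-91])))
#' k <- efa_decompose(circ, 4)
#' k$an[1]  # ~2 (circle radius)
#' k$dn[1]  # ~2
#' @export
efa_decompose <- function(c, n_harmonics = 20L) {
  stopifnot(inherits(c, "outline"))
  if (!is.numeric(n_harmonics) || length(n_harmonics) != 1L ||
      n_harmonics < 1 || n_harmonics != round(n_harmonics))
    stop("n_harmonics must be a positive integer", call. = FALSE)
  n_harmonics <- as.integer(n_harmonics)

  pts <- rbind(c$points, c$points[1L, ])
  d <- diff(pts)
  dt <- sqrt(rowSums(d^2))
  if (sum(dt) <= 0)
    stop("degenerate contour: zero perimeter", call. = FALSE)
  T_per <- sum(dt)
  t <- c(0, cumsum(dt))
  phi <- 2 * pi * t / T_per                    # length K+1, phi[1] = 0

  sx <- d[, 1L] / dt                           # per-segment slopes dx/dt
  sy <- d[, 2L] / dt

  n <- seq_len(n_harmonics)
  # cos/sin(n * phi) at segment end points; matrices K x N
  cos_e <- cos(outer(phi[-1L], n)); cos_s <- cos(outer(phi[-length(phi)], n))
  sin_e <- sin(outer(phi[-1L], n)); sin_s <- sin(outer(phi[-length(phi)], n))
  pref <- T_per / (2 * pi^2 * n^2)

  an <- pref * colSums(sx * (cos_e - cos_s))
  bn <- pref * colSums(sx * (sin_e - sin_s))
  cn <- pref * colSums(sy * (cos_e - cos_s))
  dn <- pref * colSums(sy * (sin_e - sin_s))

  # arc-length mean point (exact for piecewise-linear coordinates)
  A0 <- sum(dt * (pts[-nrow(pts), 1L] + pts[-1L, 1L]) / 2) / T_per
  C0 <- sum(dt * (pts[-nrow(pts), 2L] + pts[-1L, 2L]) / 2) / T_per

  structure(
    list(A0 = A0, C0 = C0, an = an, bn = bn, cn = cn, dn = dn,
         n_harmonics = n_harmonics, normalized = FALSE,
         specimen_id = c$specimen_id, structure_class = c$structure_class),
    class = "efa_coef"
  )
}

#' @export
print.efa_coef <- function(x, ...) {
  cat(sprintf("<efa_coef> %s | %d harmonics | %s\n", x$specimen_id,
              x$n_harmonics,
              if (x$normalized) "normalized" else "raw"))
  invisible(x)
}

#' Normalize elliptic Fourier coefficients by the first-harmonic ellipse
#'
#' Removes position, size, rotation and starting point: the outline is
#' centred (A0 = C0 = 0), rotated so the semi-major axis of the first
#' harmonic ellipse lies along +x, phase-shifted so the parametrization
#' starts on that axis, and scaled by the semi-major axis length.  After
#' normalization `a_1 = 1` exactly and `b_1 = c_1 = 0` (to numerical
#' precision), so coefficient vectors of similarity-transformed copies of
#' one shape coincide.
#'
#' The starting-point phase has a pi ambiguity (either end of the
#' semi-major axis); it is resolved deterministically by requiring the
#' even-harmonic coefficient of largest magnitude to be positive.
#' Chirality is kept as real signal by default; `reflect = TRUE`
#' additionally standardizes mirror images (requiring the
#' largest-magnitude odd-harmonic b/c coefficient to be positive), so
#' that dorsal and ventral views of the same structure map to the same
#' coefficients when mixed in one analysis.
#'
#' @param coeffs an `efa_coef` object from [efa_decompose].
#' @param reflect standardize reflection (force `d_1 > 0`)?  Default
#'   `FALSE`.
#' @return list with `coeffs` (normalized `efa_coef`) and `params`, a
#'   `norm_params` record (`scale`, `rotation`, `phase`, `reflected`,
#'   plus the removed `A0`, `C0`) which exactly inverts the transform via
#'   [efa_denormalize].
#' @export
efa_normalize <- function(coeffs, reflect = FALSE) {
  stopifnot(inherits(coeffs, "efa_coef"))
  a1 <- coeffs$an[1L]; b1 <- coeffs$bn[1L]
  c1 <- coeffs$cn[1L]; d1 <- coeffs$dn[1L]
  if (max(abs(c(a1, b1, c1, d1))) < 1e-12)
    stop("degenerate first harmonic: cannot normalize", call. = FALSE)

  # starting-point phase from the first-harmonic ellipse
  theta <- 0.5 * atan2(2 * (a1 * b1 + c1 * d1),
                       a1^2 + c1^2 - b1^2 - d1^2)
  axis_len <- function(th) {
    sqrt((a1 * cos(th) + b1 * sin(th))^2 + (c1 * cos(th) + d1 * sin(th))^2)
  }
  if (axis_len(theta + pi / 2) > axis_len(theta)) theta <- theta + pi / 2

  align <- function(th) {
    shift <- phase_shift_coef(coeffs, th)
    psi <- atan2(shift$cn[1L], shift$an[1L])
    list(rot = rotate_coef(shift, psi), theta = th, psi = psi)
  }
  apply_mirror <- function(k) {
    k$bn <- -k$bn
    k$cn <- -k$cn
    k
  }
  cand <- align(theta)
  eps_mag <- 1e-12 * abs(cand$rot$an[1L])

  # Reflection standardization first: mirroring a (counter-clockwise)
  # outline across the x-axis and reversing traversal negates every b_n
  # and c_n while leaving a_n and d_n unchanged.  The odd harmonics
  # (n >= 3) are unaffected by the pi phase flip below, so deciding
  # chirality from the largest-magnitude odd-harmonic b/c coefficient is
  # independent of the phase choice; mirror-image pairs then map to
  # identical coefficient vectors.
  reflected <- FALSE
  if (isTRUE(reflect) && coeffs$n_harmonics >= 3L) {
    odd <- seq(3L, coeffs$n_harmonics, by = 2L)
    probe <- c(cand$rot$bn[odd], cand$rot$cn[odd])
    pick <- probe[which.max(abs(probe))]
    reflected <- length(pick) > 0L && abs(pick) > eps_mag && pick < 0
  }
  if (reflected) cand$rot <- apply_mirror(cand$rot)

  # The phase is only defined modulo pi: starting at either end of the
  # semi-major axis aligns a_1 to +x after rotation.  The two candidates
  # differ exactly in the sign of every even-harmonic coefficient, so
  # the tie is broken deterministically by requiring the even-harmonic
  # coefficient of largest magnitude (after any reflection) to be
  # positive; the argmax is stable under small shape perturbations, so
  # nearby shapes normalize consistently.
  chosen <- cand
  if (coeffs$n_harmonics >= 2L) {
    even <- seq(2L, coeffs$n_harmonics, by = 2L)
    probe <- c(cand$rot$an[even], cand$rot$bn[even],
               cand$rot$cn[even], cand$rot$dn[even])
    pick <- probe[which.max(abs(probe))]
    if (length(pick) && abs(pick) > eps_mag && pick < 0) {
      chosen <- align(theta + pi)
      if (reflected) chosen$rot <- apply_mirror(chosen$rot)
    }
  }
  rot <- chosen$rot
  theta <- chosen$theta
  psi <- chosen$psi
  scale <- rot$an[1L]
  if (scale <= 0)
    stop("degenerate first harmonic: zero semi-major axis", call. = FALSE)

  out <- rot
  out$an <- rot$an / scale; out$bn <- rot$bn / scale
  out$cn <- rot$cn / scale; out$dn <- rot$dn / scale
  out$an[1L] <- 1                 # exact by construction
  params <- structure(
    list(scale = scale, rotation = wrap_pi(psi), phase = wrap_pi(theta),
         reflected = reflected, A0 = coeffs$A0, C0 = coeffs$C0),
    class = "norm_params"
  )
  out$A0 <- 0; out$C0 <- 0
  out$normalized <- TRUE
  list(coeffs = out, params = params)
}

#' Invert a first-harmonic-ellipse normalization
#'
#' @param coeffs a normalized `efa_coef`.
#' @param params the `norm_params` returned by [efa_normalize].
#' @return the original unnormalized `efa_coef` (up to floating point).
#' @export
efa_denormalize <- function(coeffs, params) {
  stopifnot(inherits(coeffs, "efa_coef"), inherits(params, "norm_params"))
  out <- coeffs
  if (params$reflected) {
    out$bn <- -out$bn
    out$cn <- -out$cn
  }
  out$an <- out$an * params$scale; out$bn <- out$bn * params$scale
  out$cn <- out$cn * params$scale; out$dn <- out$dn * params$scale
  out <- rotate_coef(out, -params$rotation)
  out <- phase_shift_coef(out, -params$phase)
  out$A0 <- params$A0; out$C0 <- params$C0
  out$normalized <- FALSE
  out
}

wrap_pi <- function(x) {
  y <- (x + pi) %% (2 * pi) - pi
  if (y <= -pi) y <- y + 2 * pi   # keep in (-pi, pi]
  y
}

# shift the parametrization start by theta (per harmonic n: rotate the
# (cos, sin) basis by n * theta)
phase_shift_coef <- function(coeffs, theta) {
  n <- seq_len(coeffs$n_harmonics)
  ct <- cos(n * theta); st <- sin(n * theta)
  out <- coeffs
  out$an <- coeffs$an * ct + coeffs$bn * st
  out$bn <- -coeffs$an * st + coeffs$bn * ct
  out$cn <- coeffs$cn * ct + coeffs$dn * st
  out$dn <- -coeffs$cn * st + coeffs$dn * ct
  out
}

# rotate the outline in the plane by -psi (align semi-major axis with +x)
rotate_coef <- function(coeffs, psi) {
  cp <- cos(psi); sp <- sin(psi)
  out <- coeffs
  out$an <- cp * coeffs$an + sp * coeffs$cn
  out$cn <- -sp * coeffs$an + cp * coeffs$cn
  out$bn <- cp * coeffs$bn + sp * coeffs$dn
  out$dn <- -sp * coeffs$bn + cp * coeffs$dn
  out
}

#' Reconstruct an outline from elliptic Fourier coefficients
#'
#' Evaluates the truncated Fourier series at equally spaced parameter
#' values.  The result is returned as an `outline`-classed object without
#' re-validation (a pure-DC coefficient set legitimately reconstructs to a
#' single repeated point).
#'
#' @param coeffs an `efa_coef`.
#' @param n_points number of points to evaluate (>= 8).
#' @return an [outline]-classed object with `n_points` vertices.
#' @export
efa_reconstruct <- function(coeffs, n_points = 200L) {
  stopifnot(inherits(coeffs, "efa_coef"))
  if (!is.numeric(n_points) || length(n_points) != 1L || n_points < 8 ||
      n_points != round(n_points))
    stop("n_points must be an integer >= 8", call. = FALSE)
  n_points <- as.integer(n_points)

  phi <- 2 * pi * (seq_len(n_points) - 1L) / n_points
  n <- seq_len(coeffs$n_harmonics)
  C <- cos(outer(phi, n)); S <- sin(outer(phi, n))
  x <- coeffs$A0 + C %*% coeffs$an + S %*% coeffs$bn
  y <- coeffs$C0 + C %*% coeffs$cn + S %*% coeffs$dn

  structure(
    list(points = cbind(as.numeric(x), as.numeric(y)), closed = TRUE,
         structure_class = coeffs$structure_class %||% "head_with_stylets",
         specimen_id = coeffs$specimen_id %||% "reconstruction",
         scale = NA_real_),
    class = "outline"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- coefficient vectors and tables ---------------------------------------

#' Flatten coefficients to a named vector and back
#'
#' The canonical layout is `A0, C0, a1, b1, c1, d1, a2, ..., d_N` — the
#' column order used by the TSV coefficient table.
#'
#' @param coeffs an `efa_coef`.
#' @return `coef_to_vector()`: named numeric vector;
#'   `vector_to_coef()`: an `efa_coef` rebuilt from such a vector.
#' @export
coef_to_vector <- function(coeffs) {
  stopifnot(inherits(coeffs, "efa_coef"))
  N <- coeffs$n_harmonics
  v <- c(coeffs$A0, coeffs$C0,
         as.numeric(rbind(coeffs$an, coeffs$bn, coeffs$cn, coeffs$dn)))
  names(v) <- c("A0", "C0",
                paste0(c("a", "b", "c", "d"), rep(seq_len(N), each = 4L)))
  v
}

#' @rdname coef_to_vector
#' @param v named numeric vector in canonical layout.
#' @param normalized mark the rebuilt object as normalized?
#' @param specimen_id,structure_class metadata to attach.
#' @export
vector_to_coef <- function(v, normalized = FALSE, specimen_id = "unnamed",
                           structure_class = "head_with_stylets") {
  if ((length(v) - 2L) %% 4L != 0L)
    stop("coefficient vector length must be 2 + 4 * n_harmonics",
         call. = FALSE)
  N <- (length(v) - 2L) %/% 4L
  h <- matrix(v[-(1:2)], nrow = 4L)
  structure(
    list(A0 = unname(v[1L]), C0 = unname(v[2L]),
         an = h[1L, ], bn = h[2L, ], cn = h[3L, ], dn = h[4L, ],
         n_harmonics = N, normalized = normalized,
         specimen_id = specimen_id, structure_class = structure_class),
    class = "efa_coef"
  )
}

#' Write/read a coefficient table (TSV)
#'
#' One row per specimen; columns `specimen_id`, `A0`, `C0`, `a1`..`d_N`
#' (SHAPE-compatible export order).
#'
#' @param coef_list list of `efa_coef` objects with equal harmonic count.
#' @param path TSV file.
#' @return `write_coef_table()`: `path`, invisibly; `read_coef_table()`:
#'   a list of `efa_coef` objects.
#' @export
write_coef_table <- function(coef_list, path) {
  stopifnot(length(coef_list) >= 1L)
  mats <- lapply(coef_list, coef_to_vector)
  if (length(unique(lengths(mats))) != 1L)
    stop("all coefficient sets must have the same number of harmonics",
         call. = FALSE)
  df <- data.frame(
    specimen_id = vapply(coef_list, function(k) k$specimen_id, ""),
    do.call(rbind, mats), check.names = FALSE
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_coef_table
#' @param normalized mark rows as normalized on read?
#' @export
read_coef_table <- function(path, normalized = FALSE) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE)
  lapply(seq_len(nrow(df)), function(i) {
    v <- as.numeric(df[i, -1L])
    names(v) <- colnames(df)[-1L]
    vector_to_coef(v, normalized = normalized,
                   specimen_id = as.character(df$specimen_id[i]))
  })
}
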