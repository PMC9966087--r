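# shared fixtures built in code

unit_square <- function() {
  outline(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)))
}

circle_outline <- function(r = 2, n = 360, phase = 0) {
  th <- phase + 2 * pi * (seq_len(n) - 1L) / n
  outline(cbind(r * cos(th), r * sin(th)))
}

# irregular star-convex polygon, reproducible
random_star_polygon <- function(seed, n_vert = 9, rmin = 0.5, rmax = 1.5) {
  set.seed(seed)
  th <- sort(stats::runif(n_vert, 0, 2 * pi))
  r <- stats::runif(n_vert, rmin, rmax)
  outline(cbind(r * cos(th), r * sin(th)))
}

rotate_pts <- function(p, a) {
  p %*% rbind(c(cos(a), sin(a)), c(-sin(a), cos(a)))
}

translate_pts <- function(p, v) sweep(p, 2L, v, "+")

# independent EFA oracle: dense trapezoidal quadrature of the arc-length
# parametrization (never calls efa_decompose)
efa_quadrature_oracle <- function(c, n_harmonics, n_samples = 1e5) {
  dense <- resample_contour(c, n_samples)
  pts <- dense$points
  T_per <- outline_perimeter(dense)
  t <- T_per * (seq_len(n_samples) - 1L) / n_samples
  res <- list(an = numeric(n_harmonics), bn = numeric(n_harmonics),
              cn = numeric(n_harmonics), dn = numeric(n_harmonics))
  for (n in seq_len(n_harmonics)) {
    w <- 2 * pi * n * t / T_per
    res$an[n] <- 2 * mean(pts[, 1L] * cos(w))
    res$bn[n] <- 2 * mean(pts[, 1L] * sin(w))
    res$cn[n] <- 2 * mean(pts[, 2L] * cos(w))
    res$dn[n] <- 2 * mean(pts[, 2L] * sin(w))
  }
  res$A0 <- mean(pts[, 1L])
  res$C0 <- mean(pts[, 2L])
  res
}

# standard coefficient pipeline used across tests
normalized_coefs <- function(contours, n_harmonics = 12L) {
  lapply(contours, function(ct)
    efa_normalize(efa_decompose(ct, n_harmonics))$coeffs)
}

# small end-to-end synthetic run: contours -> EFA -> PCA -> per-group areas
epoch_hull_areas <- function(seed, dispersion = c(3, 2, 1), n_per = 25L,
                             equal_mixture = FALSE) {
  eps <- default_epochs()
  for (i in seq_along(eps)) {
    eps[[i]]$n <- n_per
    eps[[i]]$dispersion <- dispersion[i]
    if (equal_mixture)
      eps[[i]]$mixture <- c(triangular = 0.4, pentagonal = 0.3, broad = 0.3)
  }
  cfg <- cohort_config(eps, seed = seed, n_points = 128L, n_harmonics = 12L)
  coh <- generate_cohort(cfg)
  m <- fit_morphospace(coef_matrix(normalized_coefs(coh$contours)))
  areas <- vapply(group_occupation(m$scores, coh$metadata$epoch),
                  function(o) o$area, 0)
  names(areas) <- names(eps)
  areas
}
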