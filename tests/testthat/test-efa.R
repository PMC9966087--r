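test_that("circle decomposition recovers the analytic coefficients", {
  circ <- circle_outline(r = 2, n = 360)
  k <- efa_decompose(circ, 4)
  expect_equal(k$an[1L], 2, tolerance = 1e-3)
  expect_equal(k$dn[1L], 2, tolerance = 1e-3)
  expect_lt(abs(k$bn[1L]), 1e-3)
  expect_lt(abs(k$cn[1L]), 1e-3)
  expect_lt(max(abs(c(k$an[-1L], k$bn[-1L], k$cn[-1L], k$dn[-1L]))), 1e-3)
  expect_equal(c(k$A0, k$C0), c(0, 0), tolerance = 1e-9)
})

test_that("closed-form segment sums match dense quadrature on polygons", {
  shapes <- list(unit_square(), random_star_polygon(1),
                 random_star_polygon(2, n_vert = 12),
                 random_star_polygon(5, n_vert = 5))
  for (s in shapes) {
    k <- efa_decompose(s, 6)
    o <- efa_quadrature_oracle(s, 6)
    expect_equal(k$an, o$an, tolerance = 1e-6)
    expect_equal(k$bn, o$bn, tolerance = 1e-6)
    expect_equal(k$cn, o$cn, tolerance = 1e-6)
    expect_equal(k$dn, o$dn, tolerance = 1e-6)
    expect_equal(k$A0, o$A0, tolerance = 1e-6)
    expect_equal(k$C0, o$C0, tolerance = 1e-6)
  }
})

test_that("translation shifts only the DC terms", {
  poly <- random_star_polygon(4)
  k1 <- efa_decompose(poly, 8)
  k2 <- efa_decompose(outline(translate_pts(poly$points, c(10, -5))), 8)
  expect_equal(k1$an, k2$an, tolerance = 1e-12)
  expect_equal(k1$bn, k2$bn, tolerance = 1e-12)
  expect_equal(k1$cn, k2$cn, tolerance = 1e-12)
  expect_equal(k1$dn, k2$dn, tolerance = 1e-12)
  expect_equal(k2$A0 - k1$A0, 10, tolerance = 1e-9)
  expect_equal(k2$C0 - k1$C0, -5, tolerance = 1e-9)
})

test_that("normalization is invariant to similarity transforms", {
  poly <- resample_contour(random_star_polygon(7), 240)
  v0 <- coef_to_vector(efa_normalize(efa_decompose(poly, 12))$coeffs)
  expect_equal(unname(v0["a1"]), 1)          # exact by construction
  expect_lt(abs(v0["b1"]), 1e-9)
  expect_lt(abs(v0["c1"]), 1e-9)
  expect_equal(unname(v0[c("A0", "C0")]), c(0, 0))

  n <- nrow(poly$points)
  for (case in list(list(s = 2, a = pi / 6, shift = n / 4),
                    list(s = 0.4, a = 2.1, shift = n / 2),
                    list(s = 1, a = 0, shift = 3L),
                    list(s = 5, a = -1.2, shift = 0L))) {
    p <- case$s * rotate_pts(poly$points, case$a)
    p <- translate_pts(p, c(-3, 11))
    if (case$shift > 0) {
      sh <- as.integer(case$shift)
      p <- p[c((sh + 1L):n, 1L:sh), ]
    }
    v <- coef_to_vector(efa_normalize(efa_decompose(outline(p), 12))$coeffs)
    expect_equal(v, v0, tolerance = 1e-9)
  }
})

test_that("normalization parameters exactly invert the transform", {
  poly <- resample_contour(random_star_polygon(8), 200)
  raw <- efa_decompose(poly, 10)
  nn <- efa_normalize(raw)
  expect_true(nn$coeffs$normalized)
  expect_gt(nn$params$scale, 0)
  expect_true(nn$params$rotation > -pi && nn$params$rotation <= pi)
  expect_true(nn$params$phase > -pi && nn$params$phase <= pi)
  back <- efa_denormalize(nn$coeffs, nn$params)
  expect_equal(coef_to_vector(back), coef_to_vector(raw),
               tolerance = 1e-9)
})

test_that("degenerate first harmonic is rejected", {
  k <- efa_decompose(unit_square(), 4)
  k$an[1L] <- 0; k$bn[1L] <- 0; k$cn[1L] <- 0; k$dn[1L] <- 0
  expect_error(efa_normalize(k), "degenerate first harmonic")
})

test_that("reflection standardization forces d1 > 0 and is recorded", {
  poly <- resample_contour(random_star_polygon(9), 200)
  mirrored <- outline(cbind(poly$points[, 1L], -poly$points[, 2L]))
  n1 <- efa_normalize(efa_decompose(poly, 10), reflect = TRUE)
  n2 <- efa_normalize(efa_decompose(mirrored, 10), reflect = TRUE)
  expect_gt(n1$coeffs$dn[1L], 0)
  expect_gt(n2$coeffs$dn[1L], 0)
  expect_equal(coef_to_vector(n1$coeffs), coef_to_vector(n2$coeffs),
               tolerance = 1e-9)
  # without the flag, chirality separates the two
  m1 <- efa_normalize(efa_decompose(poly, 10))$coeffs
  m2 <- efa_normalize(efa_decompose(mirrored, 10))$coeffs
  expect_false(isTRUE(all.equal(coef_to_vector(m1), coef_to_vector(m2),
                                tolerance = 1e-6)))
})

test_that("reconstruction reproduces analytic shapes", {
  # circle coefficients only
  k <- vector_to_coef(c(A0 = 0, C0 = 0, a1 = 2, b1 = 0, c1 = 0, d1 = 2))
  rec <- efa_reconstruct(k, 64)
  expect_equal(sqrt(rowSums(rec$points^2)), rep(2, 64), tolerance = 1e-9)
  # DC only: every point at (3, 4)
  k0 <- vector_to_coef(c(A0 = 3, C0 = 4, a1 = 0, b1 = 0, c1 = 0, d1 = 0))
  rec0 <- efa_reconstruct(k0, 8)
  expect_equal(rec0$points, matrix(c(3, 4), 8, 2, byrow = TRUE),
               tolerance = 1e-12)
  expect_error(efa_reconstruct(k, 7), "n_points")
})

test_that("decompose-reconstruct round trip is a shrinking perturbation", {
  # re-decomposition by arc length reparametrizes the truncated curve,
  # so the round trip is not an exact identity; it must be small, shrink
  # toward zero with deviation from a circle, and contract on iteration
  g <- generate_outline(morphotype_spec("triangular", noise_sd = 0),
                        n_points = 512)$contour
  k1 <- efa_decompose(g, 20)
  k2 <- efa_decompose(efa_reconstruct(k1, 2048), 20)
  k3 <- efa_decompose(efa_reconstruct(k2, 2048), 20)
  d12 <- max(abs(coef_to_vector(k1) - coef_to_vector(k2)))
  d23 <- max(abs(coef_to_vector(k2) - coef_to_vector(k3)))
  expect_lt(d12, 0.02)
  expect_lt(d23, d12)

  th <- seq(0, 2 * pi, length.out = 513)[-513]
  near_circle <- outline(cbind((1 + 0.01 * cos(3 * th)) * cos(th),
                               (1 + 0.01 * cos(3 * th)) * sin(th)))
  kk1 <- efa_decompose(near_circle, 10)
  kk2 <- efa_decompose(efa_reconstruct(kk1, 2048), 10)
  expect_lt(max(abs(coef_to_vector(kk1) - coef_to_vector(kk2))), 1e-6)
})

test_that("reconstruction error is monotone non-increasing in harmonics", {
  poly <- resample_contour(random_star_polygon(12), 400)
  # reconstruction at n equally spaced parameter values corresponds to
  # the same arc-length positions as equal resampling of the original,
  # so the pointwise mean distance is the partial-sum truncation error
  ref <- poly$points
  k <- efa_decompose(poly, 20)
  err <- vapply(1:16, function(h) {
    kh <- k
    keep <- seq_len(h)
    kh$an <- k$an[keep]; kh$bn <- k$bn[keep]
    kh$cn <- k$cn[keep]; kh$dn <- k$dn[keep]
    kh$n_harmonics <- h
    rec <- efa_reconstruct(kh, 400)
    mean(sqrt(rowSums((rec$points - ref)^2)))
  }, 0)
  expect_true(all(diff(err) <= 1e-9))
})

test_that("coefficient tables round-trip through TSV", {
  tmp <- withr::local_tempdir()
  contours <- list(a = random_star_polygon(21), b = random_star_polygon(22))
  contours$a$specimen_id <- "a"; contours$b$specimen_id <- "b"
  coefs <- normalized_coefs(contours, 8)
  f <- file.path(tmp, "coef.tsv")
  write_coef_table(coefs, f)
  back <- read_coef_table(f, normalized = TRUE)
  expect_equal(length(back), 2L)
  expect_equal(coef_to_vector(back[[1L]]), coef_to_vector(coefs[[1L]]),
               tolerance = 1e-12)
  expect_identical(back[[2L]]$specimen_id, "b")
})
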