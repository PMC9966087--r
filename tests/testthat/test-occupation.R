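scored <- function(m) {
  colnames(m) <- c("PC1", "PC2")
  rownames(m) <- sprintf("s%03d", seq_len(nrow(m)))
  m
}

test_that("hull area matches analytic and Monte-Carlo values", {
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  expect_equal(hull_area(sq), 1)
  expect_equal(hull_area(cbind(1:5, 2 * (1:5))), 0)   # collinear
  expect_equal(hull_area(sq[1:2, ]), 0)
  expect_error(hull_area(rbind(c(0, 0), c(Inf, 1))), "non-finite")

  # 200 uniform points in the unit disc vs rejection-sampling oracle
  set.seed(10)
  th <- stats::runif(200, 0, 2 * pi)
  rr <- sqrt(stats::runif(200))
  pts <- cbind(rr * cos(th), rr * sin(th))
  a <- hull_area(pts)
  v <- hull_vertices(pts)
  mc <- local({
    set.seed(11)
    q <- cbind(stats::runif(1e6, -1, 1), stats::runif(1e6, -1, 1))
    inside <- rep(TRUE, nrow(q))
    nv <- nrow(v)
    for (i in seq_len(nv)) {
      A <- v[i, ]; B <- v[if (i == nv) 1L else i + 1L, ]
      inside <- inside &
        ((B[1L] - A[1L]) * (q[, 2L] - A[2L]) -
           (B[2L] - A[2L]) * (q[, 1L] - A[1L])) >= 0
    }
    4 * mean(inside)
  })
  expect_equal(a, mc, tolerance = 0.02)
})

test_that("hull area is monotone under point insertion", {
  set.seed(12)
  pts <- matrix(stats::rnorm(120), ncol = 2L)
  areas <- vapply(3:60, function(k)
    hull_area(pts[seq_len(k), , drop = FALSE]), 0)
  expect_true(all(diff(areas) >= -1e-12))
})

test_that("group occupation orders, flags and contains correctly", {
  set.seed(13)
  disp <- c(Cretaceous = 3, Eocene = 2, extant = 1)
  pts <- do.call(rbind, lapply(names(disp), function(g)
    matrix(stats::rnorm(80, 0, disp[[g]]), ncol = 2L)))
  labels <- rep(names(disp), each = 40L)
  occ <- group_occupation(scored(pts), labels)
  areas <- vapply(occ, function(o) o$area, 0)
  expect_equal(vapply(occ, function(o) o$group, ""), names(disp))
  expect_true(areas[1L] > areas[2L] && areas[2L] > areas[3L])

  # every member inside or on its hull; hull vertices CCW and convex
  for (o in occ) {
    v <- o$hull_vertices
    nv <- nrow(v)
    expect_gt(larvamorph:::signed_area(v), 0)
    cross <- vapply(seq_len(nv), function(i) {
      a <- v[i, ]; b <- v[i %% nv + 1L, ]; c <- v[(i + 1L) %% nv + 1L, ]
      (b[1L] - a[1L]) * (c[2L] - b[2L]) - (b[2L] - a[2L]) * (c[1L] - b[1L])
    }, 0)
    expect_true(all(cross >= -1e-9))
    member <- pts[labels == o$group, , drop = FALSE]
    for (i in seq_len(nv)) {
      a <- v[i, ]; b <- v[i %% nv + 1L, ]
      expect_true(all((b[1L] - a[1L]) * (member[, 2L] - a[2L]) -
                        (b[2L] - a[2L]) * (member[, 1L] - a[1L]) >= -1e-9))
    }
  }

  tiny <- group_occupation(scored(pts[1:2, ]), c("g", "g"))
  expect_equal(tiny[[1L]]$area, 0)
  expect_equal(tiny[[1L]]$n, 2L)
  expect_true(tiny[[1L]]$degenerate)
})

test_that("hull overlap handles identity, shift and disjoint cases", {
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  expect_equal(hull_overlap(sq, sq), 1)
  expect_equal(hull_overlap(sq, translate_pts(sq, c(0.5, 0))), 0.5)
  expect_equal(hull_overlap(sq, translate_pts(sq, c(5, 0))), 0)
  # overlap bounded by the smaller area; nesting gives the inner area
  inner <- 0.25 + 0.5 * sq   # centred quarter square inside sq
  expect_equal(hull_overlap(sq, inner), 0.25, tolerance = 1e-12)
  set.seed(14)
  for (i in 1:10) {
    a <- matrix(stats::rnorm(20), ncol = 2L)
    b <- matrix(stats::rnorm(20), ncol = 2L)
    va <- larvamorph:::hull_vertices(a)
    vb <- larvamorph:::hull_vertices(b)
    ov <- hull_overlap(va, vb)
    expect_lte(ov, min(hull_area(a), hull_area(b)) + 1e-9)
    expect_gte(ov, 0)
  }
})

test_that("subset comparison bounds and identities hold", {
  set.seed(15)
  pts <- scored(matrix(stats::rnorm(100), ncol = 2L))
  all_ids <- rownames(pts)
  full <- subset_comparison(pts, all_ids)
  expect_equal(full$ratio, 1)
  expect_error(subset_comparison(pts, c("nope")), "unknown")

  # interior points of a square without its corners span less
  grid <- scored(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1),
                       cbind(stats::runif(20, 0.2, 0.8),
                             stats::runif(20, 0.2, 0.8))))
  inner_ids <- rownames(grid)[-(1:4)]
  expect_lt(subset_comparison(grid, inner_ids)$ratio, 1)

  # ratio rises with subset fraction on average
  set.seed(16)
  fractions <- c(0.25, 0.5, 0.75)
  mean_ratio <- vapply(fractions, function(f) {
    mean(vapply(1:30, function(r) {
      ids <- sample(all_ids, round(f * length(all_ids)))
      subset_comparison(pts, ids)$ratio
    }, 0))
  }, 0)
  expect_true(all(diff(mean_ratio) > 0))
  expect_true(all(mean_ratio < 1))
})

test_that("accumulation curves are monotone, exact at k = n, reproducible", {
  set.seed(17)
  pts <- scored(matrix(stats::runif(60), ncol = 2L))
  cv <- accumulation_curve(pts, n_resamples = 60, seed = 5)
  expect_true(all(diff(cv$mean_area) >= -1e-12))
  expect_equal(cv$mean_area[nrow(cv)], hull_area(pts))
  expect_equal(cv$ci_high[nrow(cv)], cv$ci_low[nrow(cv)])
  expect_true(all(cv$ci_low <= cv$mean_area + 1e-12) &&
                all(cv$mean_area <= cv$ci_high + 1e-12))
  cv2 <- accumulation_curve(pts, n_resamples = 60, seed = 5)
  expect_identical(as.data.frame(cv), as.data.frame(cv2))
  cv3 <- accumulation_curve(pts, n_resamples = 60, seed = 6)
  expect_false(identical(cv$mean_area, cv3$mean_area))
  expect_error(accumulation_curve(pts, n_resamples = 0, seed = 1),
               "n_resamples")
  expect_error(accumulation_curve(pts[1:2, ], 10, 1), "at least 3")
})

test_that("saturation slope separates bounded from heavy-tailed scores", {
  flat <- structure(data.frame(k = 1:10, mean_area = rep(2, 10),
                               ci_low = 2, ci_high = 2),
                    class = c("accumulation_curve", "data.frame"))
  expect_equal(saturation_slope(flat)$slope, 0)
  expect_true(saturation_slope(flat)$saturated)

  linear <- structure(data.frame(k = 1:10, mean_area = as.numeric(1:10),
                                 ci_low = 1:10, ci_high = 1:10),
                      class = c("accumulation_curve", "data.frame"))
  expect_equal(saturation_slope(linear, 0.2)$slope, 0.1)

  set.seed(18)
  unif <- scored(matrix(stats::runif(400), 200, 2))
  s_unif <- saturation_slope(accumulation_curve(unif, 80, seed = 5))$slope
  expect_lt(s_unif, 0.01)
  heavy <- scored(matrix(stats::rt(120, df = 2), 60, 2))
  s_heavy <- saturation_slope(accumulation_curve(heavy, 80, seed = 5))$slope
  expect_gt(s_heavy, s_unif)
  expect_error(saturation_slope(flat[1:3, ]), "at least 5")
})

test_that("occupation report bundles all statistics as valid JSON", {
  tmp <- withr::local_tempdir()
  set.seed(19)
  pts <- scored(matrix(stats::rnorm(60), ncol = 2L))
  labels <- rep(c("Cretaceous", "Eocene", "extant"), each = 10L)
  f <- file.path(tmp, "occ.json")
  rep1 <- occupation_report(pts, labels, subset_ids = rownames(pts)[1:15],
                            n_resamples = 30, seed = 2, path = f)
  obj <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_setequal(names(obj$groups), c("Cretaceous", "Eocene", "extant"))
  expect_equal(obj$overlap$Cretaceous$Cretaceous,
               rep1$groups$Cretaceous$area, tolerance = 1e-12)
  expect_equal(obj$subset$ratio, rep1$subset$ratio, tolerance = 1e-12)
  expect_true(all(vapply(rep1$accumulation, function(a) !is.null(a), TRUE)))
})
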