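# synthetic coefficient matrix with canonical names, first columns
# carrying the signal
gaussian_coef_matrix <- function(n = 500, sds = c(2, 1), p_extra = 11,
                                 seed = 1) {
  set.seed(seed)
  X <- cbind(matrix(stats::rnorm(n * length(sds)), n) %*% diag(sds),
             matrix(stats::rnorm(n * p_extra, 0, 1e-8), n, p_extra))
  nh <- ceiling((length(sds) + p_extra - 1L) / 4) + 1L
  nms <- c("d1", paste0(c("a", "b", "c", "d"), rep(2:nh, each = 4L)))
  colnames(X) <- nms[seq_len(ncol(X))]
  rownames(X) <- sprintf("s%03d", seq_len(n))
  X
}

test_that("covariance PCA recovers a known spectrum and identities", {
  X <- gaussian_coef_matrix(sds = c(2, 1))
  m <- fit_morphospace(X)
  expect_equal(m$eigenvalues[1L], 4, tolerance = 0.15 * 4)
  expect_equal(m$eigenvalues[2L], 1, tolerance = 0.15)
  expect_lt(m$eigenvalues[3L], 1e-6)
  # trace identity
  expect_equal(sum(m$eigenvalues), sum(apply(X, 2L, stats::var)),
               tolerance = 1e-9)
  # variance proportions sum to one, non-increasing
  expect_equal(sum(m$variance_explained), 1, tolerance = 1e-9)
  expect_true(all(diff(m$variance_explained) <= 1e-12))
  # eigenvalues sorted, scores variance equals eigenvalue
  expect_true(all(diff(m$eigenvalues) <= 1e-12))
  expect_equal(apply(m$scores, 2L, stats::var), unname(m$eigenvalues),
               tolerance = 1e-6, ignore_attr = TRUE)
  # centered, uncorrelated scores; orthonormal eigenvectors
  expect_lt(max(abs(colMeans(m$scores))), 1e-9)
  cv <- stats::cov(m$scores)
  expect_lt(max(abs(cv[upper.tri(cv)])), 1e-6 * m$eigenvalues[1L])
  G <- crossprod(m$eigenvectors)
  expect_equal(G, diag(ncol(G)), tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("degenerate and invalid inputs are handled", {
  X <- gaussian_coef_matrix(n = 5)
  same <- X[rep(1L, 5L), ]
  rownames(same) <- paste0("r", 1:5)
  m <- fit_morphospace(same)
  expect_equal(max(m$eigenvalues), 0)
  expect_equal(m$n_effective, 0L)
  expect_error(fit_morphospace(X[1:2, ]), "at least 3")
})

test_that("constant normalization columns are dropped and reinserted", {
  X <- gaussian_coef_matrix(n = 40)
  full <- cbind(A0 = 0, C0 = 0, a1 = 1, b1 = 0, c1 = 0, X)
  m <- fit_morphospace(full)
  expect_false(any(c("a1", "b1", "c1") %in% rownames(m$eigenvectors)))
  back <- morphospace_backproject(m, m$scores[3L, ])
  expect_equal(unname(back[1L, "a1"]), 1)
  expect_equal(unname(back[1L, c("b1", "c1")]), c(0, 0))
  # full-rank projection then back-projection recovers the row
  expect_equal(back[1L, colnames(full)], full[3L, ], tolerance = 1e-9)
})

test_that("effective-PC rules implement both criteria", {
  expect_equal(effective_pcs(c(4, 1, 1, 1, 1), pc_rule("gt_mean")), 1L)
  expect_equal(effective_pcs(c(2, 2, 0, 0), pc_rule("gt_mean")), 2L)
  # printed per-analysis proportion vectors with a 2% retention threshold
  head_stylets <- c(52.5, 24.8, 7.5, 3.9, 3.0, 2.5, 1.0, 0.9, 0.8, 0.7,
                    0.6, 0.5, 0.4, 0.3, 0.3, 0.2, 0.2, 0.2) / 100
  expect_equal(effective_pcs(head_stylets, pc_rule("proportion_ge", 0.02)),
               6L)
  expect_error(effective_pcs(numeric(0)), "empty")
  expect_error(effective_pcs(c(1, 2)), "sorted")
})

test_that("reconstruction along a PC is linear and sector-local", {
  m <- fit_morphospace(gaussian_coef_matrix(n = 60))
  mean_shape <- reconstruct_along_pc(m, 1, 0, 64)
  plus <- reconstruct_along_pc(m, 1, 2, 64)
  minus <- reconstruct_along_pc(m, 1, -2, 64)
  expect_equal((plus$points + minus$points) / 2, mean_shape$points,
               tolerance = 1e-12)
  expect_error(reconstruct_along_pc(m, 99, 1), "rank")

  # cohort varying only in labrum length: PC1 extremes differ in the
  # labrum sector and (up to normalization coupling) nowhere else
  specs <- lapply(seq(0.35, 0.75, length.out = 20), function(len)
    morphotype_spec("triangular", labrum_length_rel = len, noise_sd = 0))
  contours <- lapply(seq_along(specs), function(i) {
    g <- generate_outline(specs[[i]], 256,
                          specimen_id = sprintf("s%02d", i))$contour
    g
  })
  coefs <- normalized_coefs(contours, 12)
  mm <- fit_morphospace(coef_matrix(coefs))
  expect_gt(mm$variance_explained[1L], 0.9)
  lo <- reconstruct_along_pc(mm, 1, -2, 360)
  hi <- reconstruct_along_pc(mm, 1, 2, 360)
  # size normalization spreads part of a labrum-length change over the
  # whole outline (a longer labrum enlarges the scaling semi-major
  # axis), so localization is tested as concentration: the best
  # contiguous quarter of the outline must capture well over the
  # uniform-share (25%) of the squared point difference, and contain
  # the global maximum
  e2 <- rowSums((hi$points - lo$points)^2)
  n <- length(e2)
  w <- n %/% 4L
  cs <- cumsum(c(e2, e2))
  win <- vapply(seq_len(n), function(i)
    cs[i + w - 1L] - (if (i > 1L) cs[i - 1L] else 0), 0)
  best <- which.max(win)
  expect_gt(max(win) / sum(e2), 0.4)
  in_window <- ((which.max(e2) - best) %% n) < w
  expect_true(in_window)
})

test_that("morphotype clusters are recovered in effective-PC space", {
  types <- c("triangular", "trident", "broad")
  eps <- lapply(types, function(t)
    list(n = 30L, dispersion = 1, mixture = stats::setNames(1, t)))
  names(eps) <- types
  cfg <- cohort_config(eps, seed = 3, n_points = 128L, n_harmonics = 12L,
                       noise_sd = 0.02)
  coh <- generate_cohort(cfg)
  m <- fit_morphospace(coef_matrix(normalized_coefs(coh$contours)))
  sc <- m$scores[, seq_len(max(m$n_effective, 2L)), drop = FALSE]
  truth <- coh$metadata$morphotype
  set.seed(99)
  km <- stats::kmeans(sc, centers = 3L, nstart = 25L)
  purity <- sum(vapply(split(truth, km$cluster),
                       function(g) max(table(g)), 0)) / length(truth)
  expect_gte(purity, 0.9)
})

test_that("scores table and model JSON are written and re-readable", {
  tmp <- withr::local_tempdir()
  X <- gaussian_coef_matrix(n = 30)
  m <- fit_morphospace(X)
  f <- file.path(tmp, "scores.tsv")
  write_scores_table(m, f, k = 4L)
  back <- utils::read.table(f, sep = "\t", header = TRUE)
  expect_equal(nrow(back), 30L)
  expect_equal(back$PC1, unname(m$scores[, 1L]), tolerance = 1e-12)
  j <- file.path(tmp, "model.json")
  write_model_json(m, j)
  obj <- jsonlite::read_json(j, simplifyVector = TRUE)
  expect_equal(obj$n_effective, m$n_effective)
  expect_equal(obj$eigenvalues, unname(m$eigenvalues), tolerance = 1e-12)
})
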