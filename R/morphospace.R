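#' Assemble a coefficient matrix from normalized coefficient sets
#'
#' @param coef_list list of normalized `efa_coef` objects with equal
#'   harmonic counts.
#' @return numeric matrix, one row per specimen, columns in the canonical
#'   `A0, C0, a1..d_N` layout, row names = specimen ids.
#' @export
coef_matrix <- function(coef_list) {
  stopifnot(length(coef_list) >= 1L)
  if (!all(vapply(coef_list, function(k) isTRUE(k$normalized), TRUE)))
    stop("all coefficient sets must be normalized first", call. = FALSE)
  rows <- lapply(coef_list, coef_to_vector)
  if (length(unique(lengths(rows))) != 1L)
    stop("coefficient sets differ in harmonic count", call. = FALSE)
  m <- do.call(rbind, rows)
  rownames(m) <- vapply(coef_list, function(k) k$specimen_id, "")
  m
}

#' Fit a PCA morphospace on normalized Fourier coefficients
#'
#' Principal component analysis of the covariance matrix (not the
#' correlation matrix: after first-harmonic-ellipse normalization all
#' coefficients share one scale).  The constant columns `a1`, `b1`, `c1`
#' (fixed at 1, 0, 0 by normalization) are dropped before the
#' decomposition and reinserted on reconstruction.  Eigenvector signs
#' follow a deterministic convention: the largest-magnitude loading of
#' each component is positive.
#'
#' @param coeff_matrix specimens x coefficients matrix in canonical
#'   layout (see [coef_matrix]), at least 3 rows.
#' @param pc_rule effective-component rule from [pc_rule]; default
#'   `proportion_ge(0.02)`.
#' @param structure_class which of the five structure analyses this
#'   morphospace represents (metadata only).
#' @return an object of class `morphospace`: `mean` (coefficient means of
#'   the retained columns), `eigenvectors` (columns, orthonormal),
#'   `eigenvalues` (descending, >= 0), `scores` (specimens x components),
#'   `variance_explained`, `n_effective`, `constant_cols` (the dropped
#'   columns and their fixed values), `rule`, `structure_class`.
#' @export
fit_morphospace <- function(coeff_matrix,
                            pc_rule = larvamorph::pc_rule(),
                            structure_class = "head_with_stylets") {
  m <- as.matrix(coeff_matrix)
  if (nrow(m) < 3L)
    stop("need at least 3 specimens to fit a morphospace", call. = FALSE)
  if (anyNA(m) || any(!is.finite(m)))
    stop("coefficient matrix contains non-finite values", call. = FALSE)
  if (is.null(colnames(m)))
    stop("coefficient matrix must carry canonical column names",
         call. = FALSE)

  const_names <- intersect(c("a1", "b1", "c1"), colnames(m))
  constant_cols <- if (length(const_names)) {
    stats::setNames(colMeans(m[, const_names, drop = FALSE]), const_names)
  } else {
    stats::setNames(numeric(0), character(0))
  }
  keep <- setdiff(colnames(m), const_names)
  X <- m[, keep, drop = FALSE]

  mu <- colMeans(X)
  Xc <- sweep(X, 2L, mu)
  cv <- stats::cov(X)
  eig <- eigen(cv, symmetric = TRUE)
  ev <- pmax(eig$values, 0)
  vec <- eig$vectors

  # deterministic sign: largest-|loading| positive per component
  for (j in seq_len(ncol(vec))) {
    i <- which.max(abs(vec[, j]))
    if (vec[i, j] < 0) vec[, j] <- -vec[, j]
  }
  rownames(vec) <- keep
  colnames(vec) <- paste0("PC", seq_len(ncol(vec)))

  scores <- Xc %*% vec
  total <- sum(ev)
  var_expl <- if (total > 0) ev / total else rep(0, length(ev))
  n_eff <- if (total > 0) effective_pcs(ev, pc_rule) else 0L

  structure(
    list(mean = mu, eigenvectors = vec, eigenvalues = ev, scores = scores,
         variance_explained = var_expl, n_effective = n_eff,
         constant_cols = constant_cols, rule = pc_rule,
         structure_class = structure_class),
    class = "morphospace"
  )
}

#' @export
print.morphospace <- function(x, ...) {
  cat(sprintf(
    "<morphospace> %s | %d specimens | %d effective PCs (%.1f%% variance)\n",
    x$structure_class, nrow(x$scores), x$n_effective,
    100 * sum(x$variance_explained[seq_len(x$n_effective)])))
  invisible(x)
}

#' Effective-principal-component rules
#'
#' Two selection rules for how many components count as "effective":
#' `proportion_ge` retains every component whose share of total variance
#' is at least `threshold` (default 0.02, i.e. 2%); `gt_mean` retains
#' components whose eigenvalue strictly exceeds the mean eigenvalue
#' (Kaiser-Guttman on the covariance spectrum).
#'
#' @param rule `"proportion_ge"` or `"gt_mean"`.
#' @param threshold variance share cutoff for `proportion_ge`.
#' @return a `pc_rule` object.
#' @export
pc_rule <- function(rule = c("proportion_ge", "gt_mean"), threshold = 0.02) {
  rule <- match.arg(rule)
  if (rule == "proportion_ge" &&
      (!is.numeric(threshold) || threshold <= 0 || threshold > 1))
    stop("threshold must be in (0, 1]", call. = FALSE)
  structure(list(rule = rule, threshold = threshold), class = "pc_rule")
}

#' Count effective principal components
#'
#' @param eigenvalues non-negative eigenvalues sorted descending (raw
#'   variances or proportions — only relative size matters for
#'   `proportion_ge`).
#' @param rule a [pc_rule].
#' @return integer count of effective components.
#' @examples
#' effective_pcs(c(4, 1, 1, 1, 1), pc_rule("gt_mean"))          # 1
#' effective_pcs(c(52.5, 24.8, 7.5, 3.9, 3.0, 2.5, 1.0, 0.8),
#'               pc_rule("proportion_ge", 0.02))                # 6
#' @export
effective_pcs <- function(eigenvalues, rule = pc_rule()) {
  if (!length(eigenvalues))
    stop("empty eigenvalue vector", call. = FALSE)
  if (any(eigenvalues < 0) || is.unsorted(rev(eigenvalues)))
    stop("eigenvalues must be non-negative and sorted descending",
         call. = FALSE)
  stopifnot(inherits(rule, "pc_rule"))
  total <- sum(eigenvalues)
  if (total == 0) return(0L)
  switch(rule$rule,
    gt_mean = sum(eigenvalues > mean(eigenvalues)),
    proportion_ge = sum(eigenvalues / total >= rule$threshold)
  ) |> as.integer()
}

#' Project coefficient rows into a fitted morphospace (and back)
#'
#' @param model a `morphospace`.
#' @param coeff_matrix matrix (or single row) in the canonical layout used
#'   at fit time.
#' @return `morphospace_project()`: score matrix;
#'   `morphospace_backproject()`: coefficient rows rebuilt from scores
#'   (constant columns reinserted).
#' @export
morphospace_project <- function(model, coeff_matrix) {
  stopifnot(inherits(model, "morphospace"))
  m <- coeff_matrix
  if (is.null(dim(m))) m <- matrix(m, nrow = 1L, dimnames = list(NULL, names(coeff_matrix)))
  X <- m[, rownames(model$eigenvectors), drop = FALSE]
  sweep(X, 2L, model$mean) %*% model$eigenvectors
}

#' @rdname morphospace_project
#' @param scores score matrix (specimens x components).
#' @export
morphospace_backproject <- function(model, scores) {
  stopifnot(inherits(model, "morphospace"))
  s <- scores
  if (is.null(dim(s))) s <- matrix(s, nrow = 1L)
  X <- s %*% t(model$eigenvectors[, seq_len(ncol(s)), drop = FALSE])
  X <- sweep(X, 2L, model$mean, "+")
  # reinsert the constant normalization columns and complete the
  # canonical layout (absent columns take their normalized defaults:
  # A0 = C0 = 0, a1 = 1, b1 = c1 = 0)
  have <- c(rownames(model$eigenvectors), names(model$constant_cols))
  harm <- suppressWarnings(as.integer(sub("^[abcd]", "",
                                          grep("^[abcd]", have,
                                               value = TRUE))))
  N <- max(harm, 1L, na.rm = TRUE)
  canon <- c("A0", "C0",
             paste0(c("a", "b", "c", "d"), rep(seq_len(N), each = 4L)))
  out <- matrix(0, nrow(X), length(canon),
                dimnames = list(rownames(s), canon))
  out[, "a1"] <- 1
  out[, rownames(model$eigenvectors)] <- X
  for (nm in names(model$constant_cols))
    out[, nm] <- model$constant_cols[[nm]]
  out
}

#' Reconstruct the outline at a position along one principal component
#'
#' Rebuilds the coefficient vector `mean + k_sd * sqrt(eigenvalue) *
#' eigenvector`, reinserts the constant normalization columns, and
#' inverse-transforms it to an outline.  Used to visualize what shape
#' feature a component encodes (e.g. slender vs broad head capsules at
#' the PC1 extremes).
#'
#' @param model a `morphospace`.
#' @param pc component index (1-based, within the model's rank).
#' @param k_sd position along the component in standard deviations;
#'   0 gives the mean shape.
#' @param n_points points in the reconstructed outline.
#' @return an [outline].
#' @export
reconstruct_along_pc <- function(model, pc, k_sd = 0, n_points = 200L) {
  stopifnot(inherits(model, "morphospace"))
  rank <- sum(model$eigenvalues > max(model$eigenvalues[1L], 1e-300) * 1e-12)
  if (!is.numeric(pc) || length(pc) != 1L || pc < 1 || pc > max(rank, 1L) ||
      pc != round(pc))
    stop(sprintf("pc must be an integer in 1..%d (model rank)", rank),
         call. = FALSE)
  p <- ncol(model$scores)
  s <- numeric(p)
  s[pc] <- k_sd * sqrt(model$eigenvalues[pc])
  v <- morphospace_backproject(model, s)[1L, ]
  k <- vector_to_coef(v, normalized = TRUE,
                      specimen_id = sprintf("PC%d %+0.1f SD", pc, k_sd),
                      structure_class = model$structure_class)
  efa_reconstruct(k, n_points)
}

#' Export scores and the fitted model
#'
#' `write_scores_table()` writes a TSV with `specimen_id`, optional
#' grouping columns, and `PC1..PCk`; `write_model_json()` archives the
#' model (mean, eigenvalues, eigenvectors, rule, class) as JSON.
#'
#' @param model a `morphospace`.
#' @param path output file.
#' @param metadata optional data.frame with a `specimen_id` column to be
#'   joined on score row names (e.g. epoch labels).
#' @param k number of score columns to write (default: all).
#' @return `path`, invisibly.
#' @export
write_scores_table <- function(model, path, metadata = NULL, k = NULL) {
  stopifnot(inherits(model, "morphospace"))
  if (is.null(k)) k <- ncol(model$scores)
  df <- data.frame(specimen_id = rownames(model$scores) %||%
                     as.character(seq_len(nrow(model$scores))),
                   model$scores[, seq_len(k), drop = FALSE],
                   check.names = FALSE)
  if (!is.null(metadata)) {
    stopifnot("specimen_id" %in% colnames(metadata))
    df <- merge(df, metadata, by = "specimen_id", all.x = TRUE, sort = FALSE)
    df <- df[, c("specimen_id", setdiff(colnames(metadata), "specimen_id"),
                 paste0("PC", seq_len(k)))]
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_scores_table
#' @export
write_model_json <- function(model, path) {
  stopifnot(inherits(model, "morphospace"))
  obj <- list(
    structure_class = model$structure_class,
    rule = unclass(model$rule),
    n_effective = model$n_effective,
    mean = as.list(model$mean),
    eigenvalues = model$eigenvalues,
    variance_explained = model$variance_explained,
    eigenvectors = apply(model$eigenvectors, 2L, identity, simplify = FALSE),
    coefficient_names = rownames(model$eigenvectors),
    constant_cols = as.list(model$constant_cols)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
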