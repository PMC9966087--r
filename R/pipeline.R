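#' Pipeline configuration
#'
#' Bundles every setting of the outline-to-occupation analysis chain.
#' Input is either a directory of CSV outlines plus a metadata TSV
#' (columns `specimen_id`, `epoch`, ...), or a synthetic
#' [cohort_config] to be generated on the fly.
#'
#' @param input for directory input
#'   `list(type = "dir", outline_dir = ..., metadata = ...)`; for
#'   synthetic input `list(type = "synthetic", cohort = cohort_config())`.
#' @param structure_class which structure analysis this run represents.
#' @param n_points resampling point count before decomposition.
#' @param n_harmonics harmonics to keep (1-64).
#' @param reflect standardize mirror images (see [efa_normalize]).
#' @param rule effective-PC rule from [pc_rule].
#' @param pcs occupation plane, default PC1 x PC2.
#' @param n_resamples,seed accumulation-curve settings.
#' @param subset_ids optional specimen ids for an old-vs-expanded
#'   comparison.
#' @param out_dir output directory.
#' @param make_plots write figure files?
#' @param skip_missing skip included specimens whose outline file is
#'   absent instead of aborting (directory input only).
#' @return a `pipeline_config` object.
#' @export
pipeline_config <- function(input, structure_class = "head_with_stylets",
                            n_points = 256L, n_harmonics = 20L,
                            reflect = FALSE, rule = pc_rule(),
                            pcs = c(1, 2), n_resamples = 200L, seed = 1L,
                            subset_ids = NULL, out_dir = tempfile("run_"),
                            make_plots = TRUE, skip_missing = FALSE) {
  if (!is.list(input) || is.null(input$type) ||
      !input$type %in% c("dir", "synthetic"))
    stop("input must be list(type = 'dir', ...) or list(type = 'synthetic', ...)",
         call. = FALSE)
  if (input$type == "dir") {
    if (is.null(input$outline_dir) || !dir.exists(input$outline_dir))
      stop("input$outline_dir must be an existing directory", call. = FALSE)
    if (is.null(input$metadata) || !file.exists(input$metadata))
      stop("input$metadata must be an existing file", call. = FALSE)
  } else if (!inherits(input$cohort, "cohort_config")) {
    stop("synthetic input needs input$cohort = cohort_config(...)",
         call. = FALSE)
  }
  if (n_harmonics < 1 || n_harmonics > 64)
    stop("n_harmonics must be in 1..64", call. = FALSE)
  structure_class <- match.arg(structure_class, outline_structure_classes())
  structure(
    list(input = input, structure_class = structure_class,
         n_points = as.integer(n_points),
         n_harmonics = as.integer(n_harmonics), reflect = reflect,
         rule = rule, pcs = pcs, n_resamples = as.integer(n_resamples),
         seed = as.integer(seed), subset_ids = subset_ids,
         out_dir = out_dir, make_plots = make_plots,
         skip_missing = skip_missing),
    class = "pipeline_config"
  )
}

#' Run the full outline-to-occupation pipeline
#'
#' Executes the analysis chain: ingest (or generate) outlines →
#' arc-length resampling → elliptic Fourier decomposition →
#' first-harmonic-ellipse normalization → covariance PCA morphospace →
#' per-epoch convex-hull occupation, overlaps, optional subset
#' comparison and accumulation curves.  All tabular artifacts
#' (`coefficients.tsv`, `scores.tsv`, `model.json`, `occupation.json`)
#' plus a run manifest (`manifest.json`: configuration echo, seed,
#' package version, artifact checksums) are written to the output
#' directory; a rerun with the same configuration and inputs is
#' bit-identical for tables and JSON.
#'
#' @param config a [pipeline_config].
#' @return invisibly, a list with `model`, `occupation`, `metadata`,
#'   `coefficients` (matrix), `artifacts` (file paths).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  if (config$input$type == "synthetic") {
    cohort <- generate_cohort(config$input$cohort)
    contours <- cohort$contours
    metadata <- cohort$metadata
  } else {
    metadata <- utils::read.table(config$input$metadata, sep = "\t",
                                  header = TRUE, stringsAsFactors = FALSE)
    if (!all(c("specimen_id", "epoch") %in% colnames(metadata)))
      stop("metadata must carry specimen_id and epoch columns",
           call. = FALSE)
    if ("included_in_analysis" %in% colnames(metadata))
      metadata <- filter_for_analysis(metadata)
    files <- file.path(config$input$outline_dir,
                       paste0(metadata$specimen_id, ".csv"))
    missing <- metadata$specimen_id[!file.exists(files)]
    if (length(missing)) {
      if (!config$skip_missing)
        stop(sprintf("missing outline file(s) for: %s",
                     paste(missing, collapse = ", ")), call. = FALSE)
      message(sprintf("skipping %d specimen(s) without outline files",
                      length(missing)))
      keep <- file.exists(files)
      metadata <- metadata[keep, , drop = FALSE]
      files <- files[keep]
    }
    contours <- lapply(seq_along(files), function(i)
      read_outline(files[i], format = "csv",
                   structure_class = config$structure_class,
                   specimen_id = metadata$specimen_id[i]))
    names(contours) <- metadata$specimen_id
  }
  message(sprintf("ingest: %d contours (%s)", length(contours),
                  config$structure_class))
  mismatch <- vapply(contours, function(ct)
    !identical(ct$structure_class, config$structure_class), TRUE)
  if (any(mismatch))
    stop(sprintf("structure-class mismatch for %d contour(s): run expects %s",
                 sum(mismatch), config$structure_class), call. = FALSE)

  coefs <- lapply(contours, function(ct) {
    rs <- resample_contour(ct, config$n_points)
    efa_normalize(efa_decompose(rs, config$n_harmonics),
                  reflect = config$reflect)$coeffs
  })
  message(sprintf("efa: %d specimens x %d harmonics", length(coefs),
                  config$n_harmonics))
  m <- coef_matrix(coefs)

  model <- fit_morphospace(m, pc_rule = config$rule,
                           structure_class = config$structure_class)
  message(sprintf("morphospace: %d effective PCs of %d", model$n_effective,
                  ncol(model$scores)))

  labels <- metadata$epoch[match(rownames(model$scores),
                                 metadata$specimen_id)]
  occ <- occupation_report(model$scores, labels, pcs = config$pcs,
                           subset_ids = config$subset_ids,
                           n_resamples = config$n_resamples,
                           seed = config$seed,
                           path = file.path(config$out_dir,
                                            "occupation.json"))

  paths <- c(
    coefficients = file.path(config$out_dir, "coefficients.tsv"),
    scores = file.path(config$out_dir, "scores.tsv"),
    model = file.path(config$out_dir, "model.json"),
    occupation = file.path(config$out_dir, "occupation.json")
  )
  write_coef_table(coefs, paths[["coefficients"]])
  write_scores_table(model, paths[["scores"]],
                     metadata = metadata[, c("specimen_id", "epoch")])
  write_model_json(model, paths[["model"]])

  if (isTRUE(config$make_plots)) {
    fig <- file.path(config$out_dir, "morphospace.png")
    p <- plot_morphospace(model$scores, labels,
                          variance = model$variance_explained,
                          pcs = config$pcs)
    ggplot2::ggsave(fig, p, width = 7, height = 5, dpi = 150)
    paths <- c(paths, figure = fig)
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("larvamorph")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed,
    config = serialize_config(config),
    n_specimens = length(contours),
    checksums = as.list(tools::md5sum(unname(paths)))
  )
  names(manifest$checksums) <- basename(unname(paths))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(model = model, occupation = occ, metadata = metadata,
                 coefficients = m,
                 artifacts = c(paths,
                               manifest = file.path(config$out_dir,
                                                    "manifest.json"))))
}

serialize_config <- function(config) {
  cfg <- unclass(config)
  cfg$rule <- unclass(cfg$rule)
  if (cfg$input$type == "synthetic") {
    cfg$input$cohort <- unclass(cfg$input$cohort)
  }
  cfg
}

#' PC1 x PC2 morphospace scatterplot with hull shading
#'
#' Scatter of specimens in an occupation plane, one shaded convex hull
#' per group (groups with fewer than 3 non-collinear specimens are drawn
#' as points only, with a warning).  Axis labels carry the
#' variance-explained percentages when supplied.
#'
#' @param scores score matrix.
#' @param labels group label per row.
#' @param variance optional per-PC variance proportions for axis labels.
#' @param pcs pair of component indices.
#' @param overlay_ids optional specimen ids drawn as a second, nested
#'   occupied area on top of the full one (old-vs-expanded display).
#' @param file optional output file (written via [ggplot2::ggsave]).
#' @return the ggplot object (invisibly if `file` is given).
#' @export
plot_morphospace <- function(scores, labels, variance = NULL, pcs = c(1, 2),
                             overlay_ids = NULL, file = NULL) {
  scores <- as.matrix(scores)
  df <- data.frame(x = scores[, pcs[1L]], y = scores[, pcs[2L]],
                   group = as.character(labels))
  occ <- group_occupation(scores, labels, pcs)
  hulls <- do.call(rbind, lapply(occ, function(o) {
    if (o$degenerate) {
      warning(sprintf("group '%s' has a degenerate hull (n = %d); %s",
                      o$group, o$n, "drawn as points only"),
              call. = FALSE)
      return(NULL)
    }
    data.frame(x = o$hull_vertices[, 1L], y = o$hull_vertices[, 2L],
               group = o$group)
  }))
  lab <- function(i) {
    if (is.null(variance)) sprintf("PC%d", pcs[i])
    else sprintf("PC%d (%.1f%%)", pcs[i], 100 * variance[pcs[i]])
  }
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                        colour = .data$group)) +
    ggplot2::geom_point(size = 1.8) +
    ggplot2::labs(x = lab(1L), y = lab(2L), colour = "group",
                  fill = "group") +
    ggplot2::theme_minimal()
  if (!is.null(hulls))
    p <- p + ggplot2::geom_polygon(
      data = hulls,
      ggplot2::aes(fill = .data$group), alpha = 0.2, show.legend = FALSE)
  if (!is.null(overlay_ids)) {
    ids <- rownames(scores)
    sub <- scores[ids %in% overlay_ids, pcs, drop = FALSE]
    v <- hull_vertices(sub)
    if (nrow(v) >= 3L)
      p <- p + ggplot2::geom_polygon(
        data = data.frame(x = v[, 1L], y = v[, 2L]),
        ggplot2::aes(x = .data$x, y = .data$y),
        inherit.aes = FALSE, fill = NA, colour = "black",
        linetype = "22")
  }
  if (!is.null(file)) {
    ggplot2::ggsave(file, p, width = 7, height = 5, dpi = 150)
    return(invisible(p))
  }
  p
}

#' Size-scaled morphotype comparison panels
#'
#' Draws outlines grouped by labrum morphotype at a common physical
#' scale: each contour is normalized to unit bounding-box diagonal and
#' then multiplied by the specimen's body length, so rendered extents
#' are proportional to true size.  Specimens without a usable length are
#' omitted with a message.
#'
#' @param records data.frame with `specimen_id`, `labrum_morphotype` (or
#'   `morphotype`) and `body_length_mm` columns.
#' @param contours named list of [outline]s keyed by specimen id.
#' @param file optional output figure file.
#' @return the ggplot object; its `data` holds the scaled coordinates
#'   (columns `x`, `y`, `specimen_id`, `morphotype`).
#' @export
plot_size_panels <- function(records, contours, file = NULL) {
  stopifnot(is.data.frame(records))
  mt_col <- intersect(c("labrum_morphotype", "morphotype"),
                      colnames(records))[1L]
  if (is.na(mt_col))
    stop("records must carry a morphotype column", call. = FALSE)
  rows <- list()
  x_off <- stats::setNames(rep(0, length(unique(records[[mt_col]]))),
                           unique(records[[mt_col]]))
  for (i in seq_len(nrow(records))) {
    id <- records$specimen_id[i]
    len <- records$body_length_mm[i]
    ct <- contours[[as.character(id)]]
    if (is.null(ct) || is.na(len) || len <= 0) {
      message(sprintf("omitting specimen %s (no scalable length/outline)",
                      id))
      next
    }
    pts <- ct$points
    ctr <- colMeans(pts)
    pts <- sweep(pts, 2L, ctr)
    diag_len <- sqrt(sum((apply(pts, 2L, max) - apply(pts, 2L, min))^2))
    pts <- pts / diag_len * len
    mt <- as.character(records[[mt_col]][i])
    half_w <- diff(range(pts[, 1L])) / 2
    pts[, 1L] <- pts[, 1L] + x_off[[mt]] + half_w
    x_off[[mt]] <- x_off[[mt]] + 2 * half_w + 0.2 * len
    rows[[length(rows) + 1L]] <- data.frame(
      x = pts[, 1L], y = pts[, 2L], specimen_id = as.character(id),
      morphotype = mt)
  }
  if (!length(rows))
    stop("no specimen with a usable length to draw at scale",
         call. = FALSE)
  df <- do.call(rbind, rows)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                        group = .data$specimen_id)) +
    ggplot2::geom_polygon(fill = "grey70", colour = "grey20",
                          linewidth = 0.3) +
    ggplot2::facet_wrap(~morphotype, scales = "free_x", ncol = 1L) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = "mm") +
    ggplot2::theme_minimal()
  if (!is.null(file)) {
    ggplot2::ggsave(file, p, width = 7, height = 8, dpi = 150)
    return(invisible(p))
  }
  p
}
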