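#' Load the packaged long-nosed antlion specimen inventory
#'
#' Returns the 98-specimen inventory of fossil and extant long-nosed
#' antlion (psychopsid) larvae shipped with the package: 52 records from
#' the prior literature (12 extant, 12 Eocene, 28 Upper Cretaceous; these
#' carry only epoch and provenance — per-specimen details were not
#' republished, and the assignment of inventory numbers 1-52 to epochs is
#' bookkeeping, not historical order) plus 46 newly studied specimens
#' (44 Upper Cretaceous Kachin-amber larvae with PED repository numbers,
#' per-specimen body lengths and labrum morphotypes, and 2 Eocene
#' Baltic-amber larvae known from photographs).
#'
#' Lengths printed as ranges are stored as midpoints with
#' `length_is_estimate = TRUE`; where a measured and an estimated length
#' both exist the estimate is stored and the measurement noted.  Nine of
#' the new records are flagged `included_in_analysis = FALSE` (outline
#' too concealed, deformed or incomplete to digitize, or known only from
#' an inadequate photograph).
#'
#' @return a data.frame with columns `specimen_no` (integer, unique),
#'   `repository_id`, `epoch` (`Cretaceous`/`Eocene`/`extant`),
#'   `provenance` (`prior_study`/`this_study`), `included_in_analysis`
#'   (logical), `body_length_mm`, `length_is_estimate` (logical),
#'   `labrum_morphotype` and `notes`.
#' @export
load_paper_metadata <- function() {
  path <- system.file("extdata", "psychopsid_specimens.tsv",
                      package = "larvamorph")
  sum_path <- system.file("extdata", "psychopsid_specimens.md5",
                          package = "larvamorph")
  if (!nzchar(path) || !file.exists(path))
    stop("specimen fixture missing from package installation",
         call. = FALSE)
  if (nzchar(sum_path) && file.exists(sum_path)) {
    expected <- strsplit(trimws(readLines(sum_path, warn = FALSE)[1L]),
                         "[[:space:]]+")[[1L]][1L]
    actual <- unname(tools::md5sum(path))
    if (!identical(actual, expected))
      stop(sprintf(
        "specimen fixture corrupt: md5 %s does not match recorded %s",
        actual, expected), call. = FALSE)
  }
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          na.strings = "", quote = "",
                          stringsAsFactors = FALSE)
  df$included_in_analysis <- as.logical(df$included_in_analysis)
  df$length_is_estimate <- as.logical(df$length_is_estimate)
  df$notes[is.na(df$notes)] <- ""
  df$repository_id[is.na(df$repository_id)] <- ""
  validate_specimen_records(df)
  df
}

validate_specimen_records <- function(df) {
  req <- c("specimen_no", "repository_id", "epoch", "provenance",
           "included_in_analysis", "body_length_mm", "length_is_estimate",
           "labrum_morphotype")
  missing <- setdiff(req, colnames(df))
  if (length(missing))
    stop(sprintf("specimen table lacks column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  if (anyDuplicated(df$specimen_no))
    stop("specimen_no values must be unique", call. = FALSE)
  if (!all(df$epoch %in% c("Cretaceous", "Eocene", "extant")))
    stop("unknown epoch label", call. = FALSE)
  if (!all(df$provenance %in% c("prior_study", "this_study")))
    stop("unknown provenance label", call. = FALSE)
  bl <- df$body_length_mm
  if (any(!is.na(bl) & bl <= 0))
    stop("body_length_mm must be positive when present", call. = FALSE)
  new_cret <- df$provenance == "this_study" & df$epoch == "Cretaceous"
  if (!all(startsWith(df$repository_id[new_cret], "PED")))
    stop("newly studied Cretaceous records must carry PED repository ids",
         call. = FALSE)
  invisible(df)
}

#' Restrict records to those entering the shape analysis
#'
#' Drops records flagged `included_in_analysis = FALSE` (concealed,
#' deformed or incompletely preserved specimens), preserving order.
#'
#' @param records specimen data.frame as from [load_paper_metadata].
#' @return the filtered data.frame.
#' @export
filter_for_analysis <- function(records) {
  stopifnot(is.data.frame(records),
            "included_in_analysis" %in% colnames(records))
  records[records$included_in_analysis, , drop = FALSE]
}

#' Count specimens by epoch and provenance
#'
#' @param records specimen data.frame.
#' @return a contingency table of epoch x provenance.
#' @export
specimen_counts <- function(records) {
  stopifnot(is.data.frame(records))
  table(epoch = factor(records$epoch,
                       levels = c("Cretaceous", "Eocene", "extant")),
        provenance = factor(records$provenance,
                            levels = c("prior_study", "this_study")))
}

#' Head-capsule length and maximum width of an outline
#'
#' Projects the outline onto a given anteroposterior axis: `head_length`
#' is the extent of the projections onto the axis, `head_width_max` the
#' extent onto the perpendicular — the caliper measurements taken on
#' digitized head capsules (length of the head capsule, width at the
#' maximum expansion).
#'
#' @param c an [outline].
#' @param axis non-zero 2-D direction vector of the length axis
#'   (normalized internally).
#' @return list `head_length`, `head_width_max`, and `body_length`
#'   (carried from `body_length` argument, `NA` by default).
#' @param body_length optional total body length to carry along.
#' @export
measure_head <- function(c, axis = c(0, 1), body_length = NA_real_) {
  stopifnot(inherits(c, "outline"))
  axis <- as.numeric(axis)
  if (length(axis) != 2L || sqrt(sum(axis^2)) < 1e-300)
    stop("axis must be a non-zero 2-D vector", call. = FALSE)
  u <- axis / sqrt(sum(axis^2))
  v <- c(-u[2L], u[1L])
  along <- c$points %*% u
  across <- c$points %*% v
  list(head_length = diff(range(along)),
       head_width_max = diff(range(across)),
       body_length = body_length)
}
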