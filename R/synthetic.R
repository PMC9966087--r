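#' Parametric morphotype specification for synthetic larval outlines
#'
#' Describes one long-nosed-antlion-like head-with-stylets shape as a
#' star-convex radial template: a smooth head capsule of a given
#' width/length aspect, a forward (anterior) labrum protrusion whose
#' prong count follows the labrum morphotype, and two stylet lobes.
#' All lengths are relative to the head half-length.
#'
#' Prong counts by type: `triangular`, `pentagonal` and `broad` carry a
#' single apex (progressively broader and lower); `trident` carries 3
#' prongs, `pentadent` 5, and `trident_bifid` 3 with the middle prong
#' split in two.
#'
#' @param labrum_type one of `"triangular"`, `"pentagonal"`, `"trident"`,
#'   `"trident_bifid"`, `"pentadent"`, `"broad"`.
#' @param labrum_length_rel labrum protrusion length / head half-length.
#' @param labrum_width_rel angular half-width of the labrum sector
#'   (radians).
#' @param spine_length_rel relative length of the flanking spines in the
#'   trident family (fraction of the middle prong).
#' @param head_aspect head width / head length.
#' @param stylet_curvature angular offset of the stylet lobes
#'   (0 = straight, symmetric).
#' @param stylet_length_rel stylet lobe length / head half-length.
#' @param noise_sd standard deviation of smooth multiplicative radial
#'   noise (0 = deterministic template).
#' @return a `morphotype_spec` object.
#' @export
morphotype_spec <- function(labrum_type = "triangular",
                            labrum_length_rel = 0.5,
                            labrum_width_rel = 0.3,
                            spine_length_rel = 0.55,
                            head_aspect = 0.85,
                            stylet_curvature = 0,
                            stylet_length_rel = 0.9,
                            noise_sd = 0.01) {
  labrum_type <- match.arg(labrum_type, labrum_types())
  for (nm in c("labrum_length_rel", "labrum_width_rel", "spine_length_rel",
               "head_aspect", "stylet_length_rel")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop(sprintf("%s must be a positive number", nm), call. = FALSE)
  }
  if (!is.numeric(noise_sd) || noise_sd < 0)
    stop("noise_sd must be >= 0", call. = FALSE)
  if (labrum_width_rel > 0.9)
    stop("labrum_width_rel too large: labrum sector would swallow stylets",
         call. = FALSE)
  structure(
    list(labrum_type = labrum_type, labrum_length_rel = labrum_length_rel,
         labrum_width_rel = labrum_width_rel,
         spine_length_rel = spine_length_rel, head_aspect = head_aspect,
         stylet_curvature = stylet_curvature,
         stylet_length_rel = stylet_length_rel, noise_sd = noise_sd),
    class = "morphotype_spec"
  )
}

labrum_types <- function() {
  c("triangular", "pentagonal", "trident", "trident_bifid", "pentadent",
    "broad")
}

# prong centres (radians, relative to the labrum axis) and relative
# amplitudes for each labrum type; w = angular half-width of the sector
labrum_prongs <- function(type, w, spine_rel) {
  switch(type,
    triangular = list(mu = 0, amp = 1, sd = w / 2.2),
    pentagonal = list(mu = 0, amp = 0.7, sd = w / 1.4),
    broad = list(mu = 0, amp = 0.45, sd = w / 1.1),
    trident = list(mu = c(-0.72, 0, 0.72) * w,
                   amp = c(spine_rel, 1, spine_rel),
                   sd = rep(w / 7, 3L)),
    trident_bifid = list(mu = c(-0.74, -0.16, 0.16, 0.74) * w,
                         amp = c(spine_rel, 0.95, 0.95, spine_rel),
                         sd = rep(w / 9, 4L)),
    pentadent = list(mu = c(-0.8, -0.4, 0, 0.4, 0.8) * w,
                     amp = c(spine_rel, spine_rel, 1, spine_rel,
                             spine_rel),
                     sd = rep(w / 11, 5L))
  )
}

#' Generate one synthetic larval outline
#'
#' Builds a closed counter-clockwise contour in polar form around the
#' origin: head-capsule ellipse (aspect `head_aspect`, anterior at +y)
#' plus labrum prongs in the anterior sector and two stylet lobes, with
#' smooth multiplicative radial noise of standard deviation `noise_sd`
#' (a low-order random Fourier perturbation, so the contour stays smooth
#' and closed).  The same `seed` always reproduces the same contour.
#'
#' @param spec a [morphotype_spec].
#' @param n_points points on the contour (default 256).
#' @param seed integer seed for the noise; `NULL` draws from the current
#'   RNG stream.
#' @param specimen_id id to attach.
#' @return list `contour` (an [outline]) and `ground_truth` (the spec).
#' @export
generate_outline <- function(spec, n_points = 256L, seed = NULL,
                             specimen_id = "synthetic") {
  stopifnot(inherits(spec, "morphotype_spec"))
  phi <- 2 * pi * (seq_len(n_points) - 1L) / n_points
  r <- radial_template(spec, phi)

  if (spec$noise_sd > 0) {
    noise_fun <- function() {
      m <- 1:6
      eps <- stats::rnorm(6L, 0, spec$noise_sd / sqrt(6))
      psi <- stats::runif(6L, 0, 2 * pi)
      1 + colSums(eps * cos(outer(m, phi) + psi))
    }
    mult <- if (is.null(seed)) noise_fun() else with_seed(seed, noise_fun())
    r <- r * mult
  }
  if (any(r <= 0))
    stop("invalid ratios: radial template is not positive", call. = FALSE)
  pts <- cbind(r * cos(phi), r * sin(phi))
  list(contour = outline(pts, "head_with_stylets", specimen_id),
       ground_truth = spec)
}

# deterministic radial template (no noise); anterior (labrum) at phi = pi/2
radial_template <- function(spec, phi) {
  a <- spec$head_aspect / 2          # half-width (x)
  b <- 0.5                           # half-length (y)
  r_head <- a * b / sqrt((b * cos(phi))^2 + (a * sin(phi))^2)

  w <- spec$labrum_width_rel
  pr <- labrum_prongs(spec$labrum_type, w, spec$spine_length_rel)
  d <- wrap_angle(phi - pi / 2)
  labrum <- rowSums(vapply(seq_along(pr$mu), function(k) {
    spec$labrum_length_rel * pr$amp[k] *
      exp(-(d - pr$mu[k])^2 / (2 * pr$sd[k]^2))
  }, numeric(length(phi))))

  sty_ang <- pi / 2 + c(-1, 1) * (w + 0.55) +
    spec$stylet_curvature * c(-1, 1)
  stylets <- rowSums(vapply(sty_ang, function(mu) {
    spec$stylet_length_rel * exp(-wrap_angle(phi - mu)^2 / (2 * 0.12^2))
  }, numeric(length(phi))))

  r_head + labrum + stylets
}

wrap_angle <- function(x) atan2(sin(x), cos(x))

#' Cohort configuration for the synthetic generator
#'
#' Defines the per-epoch composition of a simulated fauna.  The defaults
#' emulate the study system: three epochs with specimen counts matching
#' the analysable inventory (64 Cretaceous, 13 Eocene, 12 extant),
#' morphotype-parameter dispersion multipliers 3:2:1 (Cretaceous most
#' disparate), and epoch-specific labrum-morphotype mixtures — the
#' trident/pentadent family occurs only in the Cretaceous mixture,
#' mirroring the restriction of trident-bearing larvae to Cretaceous
#' amber.
#'
#' @param epochs named list; each element a list with `n` (>= 3),
#'   `dispersion` (> 0) and `mixture` (named weights over labrum types,
#'   summing to 1).
#' @param seed integer base seed; each specimen derives its own
#'   substream from it by counter, so generation order does not matter.
#' @param n_points contour points per specimen.
#' @param n_harmonics harmonic count for downstream decomposition.
#' @param noise_sd per-specimen radial noise.
#' @return a `cohort_config` object.
#' @export
cohort_config <- function(epochs = default_epochs(), seed = 1L,
                          n_points = 256L, n_harmonics = 20L,
                          noise_sd = 0.01) {
  stopifnot(is.list(epochs), length(epochs) >= 1L,
            !is.null(names(epochs)))
  for (nm in names(epochs)) {
    e <- epochs[[nm]]
    if (!is.list(e) || is.null(e$n) || is.null(e$dispersion) ||
        is.null(e$mixture))
      stop(sprintf("epoch '%s' needs n, dispersion and mixture", nm),
           call. = FALSE)
    if (e$n < 3) stop("each epoch needs n >= 3", call. = FALSE)
    if (e$dispersion <= 0) stop("dispersion must be > 0", call. = FALSE)
    if (abs(sum(e$mixture) - 1) > 1e-8)
      stop(sprintf("epoch '%s': mixture weights must sum to 1", nm),
           call. = FALSE)
    if (!all(names(e$mixture) %in% labrum_types()))
      stop(sprintf("epoch '%s': unknown labrum type in mixture", nm),
           call. = FALSE)
  }
  structure(list(epochs = epochs, seed = as.integer(seed),
                 n_points = as.integer(n_points),
                 n_harmonics = as.integer(n_harmonics),
                 noise_sd = noise_sd),
            class = "cohort_config")
}

#' @rdname cohort_config
#' @export
default_epochs <- function() {
  list(
    Cretaceous = list(
      n = 64L, dispersion = 3,
      mixture = c(triangular = 0.20, pentagonal = 0.10, trident = 0.30,
                  trident_bifid = 0.20, pentadent = 0.10, broad = 0.10)),
    Eocene = list(
      n = 13L, dispersion = 2,
      mixture = c(triangular = 0.50, pentagonal = 0.30, broad = 0.20)),
    extant = list(
      n = 12L, dispersion = 1,
      mixture = c(triangular = 0.60, pentagonal = 0.40))
  )
}

# base template parameters per labrum type; per-specimen values jitter
# around these on the log scale with sd = dispersion * base coefficient
# of variation
base_morphotype <- function(type) {
  base <- list(
    triangular    = list(len = 0.55, wid = 0.22, asp = 0.90),
    pentagonal    = list(len = 0.35, wid = 0.45, asp = 1.00),
    trident       = list(len = 0.75, wid = 0.40, asp = 0.75),
    trident_bifid = list(len = 0.70, wid = 0.42, asp = 0.75),
    pentadent     = list(len = 0.70, wid = 0.50, asp = 0.75),
    broad         = list(len = 0.25, wid = 0.65, asp = 1.10)
  )[[type]]
  morphotype_spec(labrum_type = type, labrum_length_rel = base$len,
                  labrum_width_rel = base$wid, head_aspect = base$asp)
}

#' Generate a synthetic cohort of larval outlines
#'
#' Draws, for every epoch in the configuration, the requested number of
#' specimens: each specimen samples a labrum morphotype from the epoch's
#' mixture and jitters the morphotype's template parameters (labrum
#' length, head aspect, stylet length and curvature) with a scatter
#' scaled by the epoch's dispersion multiplier — a larger multiplier
#' directly produces a wider cloud in shape space.  Each specimen uses
#' its own counter-derived RNG substream, so results are reproducible
#' and independent of generation order.
#'
#' @param config a [cohort_config].
#' @return list `contours` (list of [outline]), `metadata` (data.frame
#'   `specimen_id`, `epoch`, `morphotype`), `ground_truth` (list of
#'   per-specimen [morphotype_spec]), `config`.
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  base_cv <- 0.06
  contours <- list(); truth <- list()
  meta <- list()
  counter <- 0L
  for (ep in names(config$epochs)) {
    e <- config$epochs[[ep]]
    for (i in seq_len(e$n)) {
      counter <- counter + 1L
      sub_seed <- (config$seed %% 1000003L) * 2003L + counter * 7919L
      sub_seed <- sub_seed %% 2147483629L
      id <- sprintf("%s_%03d", ep, i)
      drawn <- with_seed(sub_seed, {
        type <- sample(names(e$mixture), 1L, prob = e$mixture)
        tmpl <- base_morphotype(type)
        jit <- function(x, cv) x * exp(stats::rnorm(1L, 0, e$dispersion * cv))
        spec <- morphotype_spec(
          labrum_type = type,
          labrum_length_rel = jit(tmpl$labrum_length_rel, base_cv),
          labrum_width_rel = min(jit(tmpl$labrum_width_rel, base_cv / 2), 0.85),
          spine_length_rel = tmpl$spine_length_rel,
          head_aspect = jit(tmpl$head_aspect, base_cv),
          stylet_curvature = stats::rnorm(1L, 0, e$dispersion * 0.03),
          stylet_length_rel = jit(tmpl$stylet_length_rel, base_cv),
          noise_sd = config$noise_sd
        )
        generate_outline(spec, n_points = config$n_points, seed = NULL,
                         specimen_id = id)
      })
      contours[[id]] <- drawn$contour
      truth[[id]] <- drawn$ground_truth
      meta[[id]] <- data.frame(specimen_id = id, epoch = ep,
                               morphotype = drawn$ground_truth$labrum_type)
    }
  }
  list(contours = contours, metadata = do.call(rbind, c(meta, list(make.row.names = FALSE))),
       ground_truth = truth, config = config)
}

#' Export a synthetic cohort to disk
#'
#' Writes one CSV outline per specimen plus a `metadata.tsv`, the layout
#' consumed by [run_pipeline] in directory-input mode.
#'
#' @param cohort result of [generate_cohort].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (id in names(cohort$contours))
    write_outline_csv(cohort$contours[[id]],
                      file.path(dir, paste0(id, ".csv")))
  utils::write.table(cohort$metadata, file.path(dir, "metadata.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
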