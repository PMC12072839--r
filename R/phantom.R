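#' Phantom specification for a synthetic seed cross-section
#'
#' Describes the geometry and raster properties of a synthetic seed-like
#' cross-section: an elliptical body on a uniform background, optionally
#' containing thin elongated cracks.  Defaults place a mid-range corn
#' kernel (12.6 x 8.54 mm) on a 256 x 256 raster at 0.06 mm/px.
#'
#' @param body_semi_axes Numeric pair, ellipse semi-axes in mm
#'   (half-extent along image columns, half-extent along rows).
#' @param pixel_pitch mm per pixel.
#' @param image_shape Integer pair, raster size as (rows, cols).
#' @param crack_count Optional non-negative integer: draw exactly this
#'   many cracks, ignoring any scenario damage target.  `NULL` (default)
#'   means the crack area is driven by the load scenario or an explicit
#'   target fraction.
#' @param crack_width_px Crack stroke width in pixels (>= 1 whenever any
#'   crack is drawn).
#' @param crack_length_frac Crack length as a fraction of the body
#'   diameter (major axis), in (0, 1].
#' @param boundary_band_px Half-width (chessboard distance, pixels) of the
#'   boundary label band on each side of every solid/damage interface;
#'   0 disables the band and leaves a two-class object.
#' @param intensity_solid,intensity_damage,intensity_background 8-bit
#'   intensity levels (0-255); solid and damage must differ.
#' @param noise_sd Standard deviation of additive Gaussian intensity
#'   noise, in grey levels; 0 gives an exact three-level raster.
#' @param polarity `"cracks-dark"` (canonical: solid bright, cracks dark)
#'   or `"cracks-bright"` (the raster is written colour-inverted, as
#'   tomography viewers often render it for crack visibility).
#' @param fill_damage Test hook: paint the whole body as damage.
#'
#' @return An object of class `phantom_spec`.
#' @seealso [generate_slice()], [generate_stack()]
#' @examples
#' spec <- phantom_spec()
#' spec$body_semi_axes / spec$pixel_pitch  # body semi-axes in pixels
#' @export
phantom_spec <- function(body_semi_axes = c(6.3, 4.27),
                         pixel_pitch = 0.06,
                         image_shape = c(256L, 256L),
                         crack_count = NULL,
                         crack_width_px = 3L,
                         crack_length_frac = 0.4,
                         boundary_band_px = 0L,
                         intensity_solid = 200L,
                         intensity_damage = 60L,
                         intensity_background = 10L,
                         noise_sd = 0,
                         polarity = c("cracks-dark", "cracks-bright"),
                         fill_damage = FALSE) {
  polarity <- match.arg(polarity)
  if (length(body_semi_axes) != 2L || any(body_semi_axes <= 0))
    stop_seedmd("seedmd_parameter_error", "body_semi_axes must be two positive lengths (mm)")
  if (pixel_pitch <= 0)
    stop_seedmd("seedmd_parameter_error", "pixel_pitch must be positive")
  image_shape <- as.integer(image_shape)
  if (length(image_shape) != 2L || any(image_shape < 1L))
    stop_seedmd("seedmd_parameter_error", "image_shape must be two positive pixel counts")
  if (!is.null(crack_count)) {
    crack_count <- as.integer(crack_count)
    if (length(crack_count) != 1L || is.na(crack_count) || crack_count < 0L)
      stop_seedmd("seedmd_parameter_error", "crack_count must be a single non-negative integer")
  }
  crack_width_px <- as.integer(crack_width_px)
  if (crack_length_frac <= 0 || crack_length_frac > 1)
    stop_seedmd("seedmd_parameter_error", "crack_length_frac must lie in (0, 1]")
  boundary_band_px <- as.integer(boundary_band_px)
  if (boundary_band_px < 0L)
    stop_seedmd("seedmd_parameter_error", "boundary_band_px must be non-negative")
  ints <- c(intensity_solid, intensity_damage, intensity_background)
  if (any(ints < 0) || any(ints > 255))
    stop_seedmd("seedmd_parameter_error", "intensities must lie in [0, 255]")
  if (intensity_solid == intensity_damage)
    stop_seedmd("seedmd_parameter_error", "intensity_solid and intensity_damage must differ")
  if (noise_sd < 0)
    stop_seedmd("seedmd_parameter_error", "noise_sd must be non-negative")
  # body must fit inside the raster at the given pitch
  semi_px <- body_semi_axes / pixel_pitch           # (cols, rows) half-extents
  if (2 * semi_px[1] > image_shape[2] || 2 * semi_px[2] > image_shape[1])
    stop_seedmd("seedmd_sizing_error",
                "body (%.1f x %.1f px) does not fit inside a %d x %d image",
                2 * semi_px[1], 2 * semi_px[2], image_shape[1], image_shape[2])
  structure(list(body_semi_axes = as.numeric(body_semi_axes),
                 pixel_pitch = pixel_pitch,
                 image_shape = image_shape,
                 crack_count = crack_count,
                 crack_width_px = crack_width_px,
                 crack_length_frac = crack_length_frac,
                 boundary_band_px = boundary_band_px,
                 intensity_solid = as.integer(intensity_solid),
                 intensity_damage = as.integer(intensity_damage),
                 intensity_background = as.integer(intensity_background),
                 noise_sd = noise_sd,
                 polarity = polarity,
                 fill_damage = isTRUE(fill_damage)),
            class = "phantom_spec")
}

#' Virtual external-load scenario
#'
#' Encodes the factor structure of the loading experiment: load nature
#' (static platform compression vs dynamic striker impact), specimen
#' placement (vertical or horizontal), and load magnitude expressed as a
#' fraction of the critical force F_kr at which the specimen fully
#' deforms.  The response parameters define the phantom's damage level:
#' the target damage fraction is `baseline` at 0.3 F_kr and rises
#' monotonically to `baseline * fold_span` at 0.9 F_kr (see
#' [damage_response()]).
#'
#' @param load_type `"static"` or `"dynamic"`.
#' @param orientation `"vertical"` or `"horizontal"` specimen placement.
#' @param load_fraction Load as a fraction of F_kr, in (0, 1]; the
#'   standard grid is 0.3, 0.45, 0.6, 0.75, 0.9.
#' @param baseline Damage area fraction at 0.3 F_kr.
#' @param fold_span Ratio of the damage fraction at 0.9 F_kr to the
#'   baseline (>= 1).  Defaults: 6 for static load, 3 for dynamic, the
#'   magnitudes reported for corn seeds.
#' @param shape Positive exponent controlling the curvature of the
#'   response between the two anchor loads (1 = geometric interpolation).
#' @param replicate_noise_sd Between-slice standard deviation of the
#'   per-slice damage target, modelling specimen heterogeneity.
#'
#' @return An object of class `load_scenario`.
#' @examples
#' sc <- load_scenario("static", "vertical", 0.9)
#' damage_response(sc)  # baseline * fold_span
#' @export
load_scenario <- function(load_type = c("static", "dynamic"),
                          orientation = c("vertical", "horizontal"),
                          load_fraction = 0.3,
                          baseline = 0.02,
                          fold_span = NULL,
                          shape = 1,
                          replicate_noise_sd = 0) {
  load_type <- match.arg(load_type)
  orientation <- match.arg(orientation)
  if (load_fraction <= 0 || load_fraction > 1)
    stop_seedmd("seedmd_parameter_error", "load_fraction must lie in (0, 1]")
  if (baseline < 0 || baseline > 1)
    stop_seedmd("seedmd_parameter_error", "baseline must lie in [0, 1]")
  if (is.null(fold_span))
    fold_span <- if (load_type == "static") 6 else 3
  if (fold_span < 1)
    stop_seedmd("seedmd_parameter_error", "fold_span must be >= 1")
  if (shape <= 0)
    stop_seedmd("seedmd_parameter_error", "shape must be positive")
  if (replicate_noise_sd < 0)
    stop_seedmd("seedmd_parameter_error", "replicate_noise_sd must be non-negative")
  structure(list(load_type = load_type, orientation = orientation,
                 load_fraction = load_fraction, baseline = baseline,
                 fold_span = fold_span, shape = shape,
                 replicate_noise_sd = replicate_noise_sd),
            class = "load_scenario")
}

#' Standard scenario grid of the virtual loading study
#'
#' Crosses load type (static, dynamic) with placement (vertical,
#' horizontal) and the standard sub-critical load grid.
#'
#' @param load_fractions Load grid as fractions of F_kr.
#' @param ... Further arguments passed to [load_scenario()] (baseline,
#'   fold spans via `fold_span`, noise).
#' @return List of 2 x 2 x `length(load_fractions)` `load_scenario`
#'   objects.
#' @examples
#' length(default_scenario_grid())  # 20 cells
#' @export
default_scenario_grid <- function(load_fractions = c(0.3, 0.45, 0.6, 0.75, 0.9),
                                  ...) {
  grid <- expand.grid(load_fraction = load_fractions,
                      orientation = c("vertical", "horizontal"),
                      load_type = c("static", "dynamic"),
                      stringsAsFactors = FALSE)
  lapply(seq_len(nrow(grid)), function(i)
    load_scenario(load_type = grid$load_type[i],
                  orientation = grid$orientation[i],
                  load_fraction = grid$load_fraction[i], ...))
}

#' Target damage fraction of a load scenario
#'
#' The phantom's dose-response: the damage area fraction equals
#' `baseline` at 0.3 F_kr and `baseline * fold_span` at 0.9 F_kr, with
#' geometric interpolation in between (curvature set by `shape`).  Load
#' fractions outside the 0.3-0.9 anchor range are clamped to it.  The
#' response is non-decreasing in the load fraction and capped at 1.
#'
#' @param scenario A [load_scenario()].
#' @return Target damage fraction in \[0, 1\].
#' @examples
#' damage_response(load_scenario("static", load_fraction = 0.3))  # baseline
#' damage_response(load_scenario("static", load_fraction = 0.9))  # 6x baseline
#' @export
damage_response <- function(scenario) {
  stopifnot(inherits(scenario, "load_scenario"))
  f <- min(max(scenario$load_fraction, 0.3), 0.9)
  t <- ((f - 0.3) / 0.6)^scenario$shape
  min(scenario$baseline * scenario$fold_span^t, 1)
}

# Logical mask of an axis-aligned ellipse evaluated at pixel centres.
# semi_px = (half-extent in cols, half-extent in rows).
ellipse_mask <- function(shape, semi_px) {
  cx <- shape[2] / 2
  cy <- shape[1] / 2
  xs <- (seq_len(shape[2]) - 0.5 - cx) / semi_px[1]
  ys <- (seq_len(shape[1]) - 0.5 - cy) / semi_px[2]
  outer(ys^2, xs^2, `+`) <= 1
}

# One random-walk crack: returns the ordered linear indices of NEW damage
# pixels (inside `domain`, not yet damage in `labels`), in draw order so
# the caller can truncate the tail to hit an exact pixel budget.
draw_crack_pixels <- function(labels, domain, width_px, length_px, shape) {
  idx <- which(domain & labels != LBL_DAMAGE)
  if (!length(idx)) return(integer(0))
  start <- idx[sample.int(length(idx), 1L)]
  r0 <- (start - 1L) %% shape[1] + 1L
  c0 <- (start - 1L) %/% shape[1] + 1L
  theta <- runif(1, 0, 2 * pi)
  steps <- max(2L, ceiling(length_px))
  turns <- rnorm(steps, 0, 0.2)
  rr <- numeric(steps); cc <- numeric(steps)
  r <- r0; ccol <- c0
  n_ok <- 0L
  for (s in seq_len(steps)) {
    theta <- theta + turns[s]
    r <- r + sin(theta)
    ccol <- ccol + cos(theta)
    ri <- as.integer(round(r)); ci <- as.integer(round(ccol))
    if (ri < 1L || ci < 1L || ri > shape[1] || ci > shape[2] || !domain[ri, ci])
      break  # crack ends at the interior margin
    n_ok <- n_ok + 1L
    rr[n_ok] <- ri; cc[n_ok] <- ci
  }
  if (!n_ok) return(integer(0))
  rr <- rr[seq_len(n_ok)]; cc <- cc[seq_len(n_ok)]
  # dilate the path to the stroke width with a square stamp
  half_lo <- (width_px - 1L) %/% 2L
  half_hi <- width_px - 1L - half_lo
  offs <- expand.grid(dr = -half_lo:half_hi, dc = -half_lo:half_hi)
  out <- integer(0)
  seen <- new.env(hash = TRUE)
  for (k in seq_len(n_ok)) {
    for (o in seq_len(nrow(offs))) {
      ri <- rr[k] + offs$dr[o]; ci <- cc[k] + offs$dc[o]
      if (ri < 1L || ci < 1L || ri > shape[1] || ci > shape[2]) next
      if (!domain[ri, ci]) next
      li <- (ci - 1L) * shape[1] + ri
      key <- as.character(li)
      if (!is.null(seen[[key]])) next
      seen[[key]] <- TRUE
      if (labels[li] != LBL_DAMAGE) out <- c(out, li)
    }
  }
  out
}

# Draw cracks into `labels` until `target_px` damage pixels exist (exact,
# the last crack is truncated along its path), or `n_cracks` cracks if
# the caller fixes the count instead.
draw_crack_field <- function(labels, body, spec, target_px = NULL,
                             n_cracks = NULL) {
  shape <- dim(labels)
  if ((is.null(target_px) || target_px == 0L) &&
      (is.null(n_cracks) || n_cracks == 0L))
    return(labels)
  if (spec$crack_width_px < 1L)
    stop_seedmd("seedmd_parameter_error",
                "crack_width_px must be >= 1 when cracks are drawn")
  # keep cracks strictly interior so they never breach the body outline
  margin_px <- spec$crack_width_px + 2L
  semi_px <- spec$body_semi_axes / spec$pixel_pitch
  interior_semi <- pmax(semi_px - margin_px, 0.5)
  domain <- ellipse_mask(shape, c(interior_semi[1], interior_semi[2])) & body
  if (!any(domain))
    stop_seedmd("seedmd_sizing_error", "body too small to hold interior cracks")
  length_px <- spec$crack_length_frac * 2 * max(semi_px)
  if (!is.null(n_cracks)) {
    for (i in seq_len(n_cracks)) {
      px <- draw_crack_pixels(labels, domain, spec$crack_width_px, length_px, shape)
      labels[px] <- LBL_DAMAGE
    }
    return(labels)
  }
  drawn <- 0L
  tries <- 0L
  while (drawn < target_px && tries < 500L) {
    tries <- tries + 1L
    px <- draw_crack_pixels(labels, domain, spec$crack_width_px, length_px, shape)
    if (!length(px)) next
    remaining <- target_px - drawn
    if (length(px) > remaining) px <- px[seq_len(remaining)]
    labels[px] <- LBL_DAMAGE
    drawn <- drawn + length(px)
  }
  labels
}

tally_truth <- function(mask) {
  n_solid <- sum(mask == LBL_SOLID)
  n_dam <- sum(mask == LBL_DAMAGE)
  n_bnd <- sum(mask == LBL_BOUNDARY)
  n_obj <- n_solid + n_dam + n_bnd
  list(area_object_px = n_obj,
       area_damage_px = n_dam,
       area_boundary_px = n_bnd,
       weighted_fraction = if (n_obj > 0) (n_dam + 0.5 * n_bnd) / n_obj else NA_real_)
}

#' Generate one synthetic cross-section
#'
#' Draws an elliptical seed body with thin random-walk cracks, returning
#' the grey-level raster, the ground-truth label mask (codes of
#' [label_codes()]) and exact pixel tallies.  Generation is a pure
#' function of `(spec, scenario, slice_index, seed)`: the RNG stream is
#' `seed + slice_index` and the caller's RNG state is untouched.
#'
#' The damage area is controlled by, in order of precedence:
#' `spec$fill_damage` (whole body damaged), `spec$crack_count` (fixed
#' number of cracks), `target_fraction`, or the scenario's
#' [damage_response()] perturbed by its `replicate_noise_sd`.  When a
#' target fraction drives the drawing, cracks are added until the damage
#' pixel count matches `round(target * object_px)` exactly (the last
#' crack is truncated along its path), so the ground truth equals the
#' request to within one pixel.
#'
#' @param spec A [phantom_spec()].
#' @param scenario Optional [load_scenario()] supplying the damage target.
#' @param slice_index Integer in 0-19; indices 0-9 are tagged horizontal
#'   sections, 10-19 vertical.
#' @param seed Non-negative integer root seed.
#' @param target_fraction Optional explicit damage area fraction in
#'   \[0, 1\], overriding the scenario response.
#' @return A `phantom_slice`: list with `raster` (integer matrix, 0-255),
#'   `mask` (integer label matrix), `truth` (exact tallies incl.
#'   `weighted_fraction`), `slice_index`, `orientation`, `pixel_pitch`,
#'   `polarity`.
#' @examples
#' sl <- generate_slice(phantom_spec(), target_fraction = 0.05, seed = 1)
#' sl$truth$weighted_fraction
#' @export
generate_slice <- function(spec, scenario = NULL, slice_index = 0L,
                           seed = 1L, target_fraction = NULL) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (!is.null(scenario)) stopifnot(inherits(scenario, "load_scenario"))
  slice_index <- as.integer(slice_index)
  if (slice_index < 0L || slice_index > 19L)
    stop_seedmd("seedmd_parameter_error", "slice_index must lie in 0..19")
  if (seed < 0) stop_seedmd("seedmd_parameter_error", "seed must be non-negative")
  if (!is.null(target_fraction) && (target_fraction < 0 || target_fraction > 1))
    stop_seedmd("seedmd_parameter_error", "target_fraction must lie in [0, 1]")

  with_local_seed(seed + slice_index, {
    shape <- spec$image_shape
    semi_px <- spec$body_semi_axes / spec$pixel_pitch
    body <- ellipse_mask(shape, semi_px)
    n_obj <- sum(body)
    if (n_obj == 0L)
      stop_seedmd("seedmd_sizing_error", "body has no pixels at this pitch")
    labels <- matrix(LBL_BACKGROUND, shape[1], shape[2])
    labels[body] <- LBL_SOLID

    if (spec$fill_damage) {
      labels[body] <- LBL_DAMAGE
    } else if (!is.null(spec$crack_count)) {
      labels <- draw_crack_field(labels, body, spec, n_cracks = spec$crack_count)
    } else {
      p <- if (!is.null(target_fraction)) target_fraction
           else if (!is.null(scenario)) {
             pt <- damage_response(scenario)
             if (scenario$replicate_noise_sd > 0)
               pt <- pt + rnorm(1, 0, scenario$replicate_noise_sd)
             min(max(pt, 0), 1)
           } else 0
      labels <- draw_crack_field(labels, body, spec,
                                 target_px = as.integer(round(p * n_obj)))
    }

    # raster reflects the physical material, before any boundary band
    raster <- matrix(spec$intensity_background, shape[1], shape[2])
    raster[labels == LBL_SOLID] <- spec$intensity_solid
    raster[labels == LBL_DAMAGE] <- spec$intensity_damage
    if (spec$noise_sd > 0)
      raster <- raster + rnorm(length(raster), 0, spec$noise_sd)
    raster <- matrix(as.integer(pmin(pmax(round(raster), 0), 255)),
                     shape[1], shape[2])
    if (spec$polarity == "cracks-bright") raster <- 255L - raster

    if (spec$boundary_band_px > 0L)
      labels <- derive_boundary(labels, spec$boundary_band_px)

    structure(list(raster = raster, mask = labels,
                   truth = tally_truth(labels),
                   slice_index = slice_index,
                   orientation = if (slice_index < 10L) "horizontal" else "vertical",
                   pixel_pitch = spec$pixel_pitch,
                   polarity = spec$polarity),
              class = "phantom_slice")
  })
}

#' Generate a 20-section phantom stack
#'
#' Emulates the tomographic sectioning convention: 10 evenly spaced
#' horizontal sections (indices 0-9) and 10 vertical sections (10-19) of
#' one virtual specimen.  Each section draws an independent 2D crack
#' field targeting the scenario's damage response; slice `i` uses RNG
#' stream `seed + i`.
#'
#' @inheritParams generate_slice
#' @param n_slices Number of sections (default 20).
#' @return A `phantom_stack`: list with `slices` (list of
#'   `phantom_slice`), `truth` (data frame of exact per-slice tallies),
#'   `spec`, `scenario`, `seed`.
#' @examples
#' st <- generate_stack(phantom_spec(), load_scenario("static"), seed = 1)
#' nrow(st$truth)  # 20
#' @export
generate_stack <- function(spec, scenario = NULL, seed = 1L,
                           target_fraction = NULL, n_slices = 20L) {
  slices <- lapply(seq_len(n_slices) - 1L, function(i)
    generate_slice(spec, scenario, slice_index = i, seed = seed,
                   target_fraction = target_fraction))
  truth <- do.call(rbind, lapply(slices, function(s)
    data.frame(slice_index = s$slice_index, orientation = s$orientation,
               area_object_px = s$truth$area_object_px,
               area_damage_px = s$truth$area_damage_px,
               area_boundary_px = s$truth$area_boundary_px,
               weighted_fraction = s$truth$weighted_fraction)))
  structure(list(slices = slices, truth = truth, spec = spec,
                 scenario = scenario, seed = as.integer(seed)),
            class = "phantom_stack")
}

#' Exact damage fraction of a label mask
#'
#' The area analogue of the actual microdamage coefficient
#' \eqn{K_{fmd} = V_{dam} / V_{BO}}: damage pixels (boundary pixels
#' counted at weight 0.5) over object pixels.  Serves as the brute-force
#' oracle for the Monte Carlo estimator.
#'
#' @param mask Integer label matrix (codes of [label_codes()]) with at
#'   least one object pixel.
#' @return Weighted damage fraction in \[0, 1\].
#' @examples
#' m <- matrix(1L, 100, 100)   # 10,000 solid pixels
#' m[1:50, 1:10] <- 2L         # 500 damage pixels
#' exact_damage_fraction(m)    # 0.05
#' @export
exact_damage_fraction <- function(mask) {
  t <- tally_truth(mask)
  if (t$area_object_px == 0L)
    stop_seedmd("seedmd_empty_domain_error", "mask contains no object pixels")
  t$weighted_fraction
}

#' @export
print.phantom_slice <- function(x, ...) {
  cat(sprintf("phantom slice %d (%s): %d x %d px, object %d px, damage fraction %.4f\n",
              x$slice_index, x$orientation, nrow(x$raster), ncol(x$raster),
              x$truth$area_object_px, x$truth$weighted_fraction))
  invisible(x)
}

#' @export
print.phantom_stack <- function(x, ...) {
  cat(sprintf("phantom stack: %d slices, mean damage fraction %.4f\n",
              length(x$slices), mean(x$truth$weighted_fraction)))
  invisible(x)
}

#' Write a phantom stack to disk
#'
#' Writes each slice as an 8-bit grayscale TIFF (or PNG), its label mask
#' as a single-channel label TIFF (codes 0-3), a JSON manifest listing
#' file, slice index, orientation and pixel pitch, and a CSV of exact
#' ground-truth tallies.
#'
#' @param stack A `phantom_stack` from [generate_stack()].
#' @param dir Output directory (created if needed).
#' @param format `"tiff"` or `"png"` for the grey rasters (masks are
#'   always TIFF).
#' @return Invisibly, the manifest path.
#' @export
write_stack <- function(stack, dir, format = c("tiff", "png")) {
  stopifnot(inherits(stack, "phantom_stack"))
  format <- match.arg(format)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ext <- if (format == "tiff") "tif" else "png"
  entries <- lapply(stack$slices, function(s) {
    img <- sprintf("slice_%02d.%s", s$slice_index, ext)
    msk <- sprintf("mask_%02d.tif", s$slice_index)
    if (format == "tiff")
      tiff::writeTIFF(s$raster / 255, file.path(dir, img), bits.per.sample = 8L)
    else
      png::writePNG(s$raster / 255, file.path(dir, img))
    tiff::writeTIFF(s$mask / 255, file.path(dir, msk), bits.per.sample = 8L)
    list(file = img, mask_file = msk, slice_index = s$slice_index,
         orientation = s$orientation, polarity = s$polarity)
  })
  manifest <- list(pixel_pitch = stack$spec$pixel_pitch,
                   bit_depth = 8L, slices = entries)
  manifest_path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  write.csv(stack$truth, file.path(dir, "ground_truth.csv"), row.names = FALSE)
  invisible(manifest_path)
}
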