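#' Construct a grayscale cross-section slice
#'
#' Lightweight container for one tomographic section.  Pixel coordinates
#' are 0-based and real-valued throughout the package: `x` is the column
#' coordinate, `y` the row coordinate, and a point (x, y) lies in the
#' pixel `(floor(y) + 1, floor(x) + 1)` of the row-major raster.
#'
#' @param pixels Integer matrix of intensities.
#' @param slice_index Integer in 0-19, unique within a stack.
#' @param orientation `"horizontal"` or `"vertical"` section.
#' @param pixel_pitch mm per pixel (may be `NA`).
#' @param polarity `"cracks-dark"` or `"cracks-bright"`.
#' @param bit_depth 8 or 16.
#' @return An object of class `bo_slice`.
#' @export
bo_slice <- function(pixels, slice_index = 0L,
                     orientation = c("horizontal", "vertical"),
                     pixel_pitch = NA_real_,
                     polarity = c("cracks-dark", "cracks-bright"),
                     bit_depth = 8L) {
  orientation <- match.arg(orientation)
  polarity <- match.arg(polarity)
  if (!is.matrix(pixels) || length(pixels) == 0L)
    stop_seedmd("seedmd_format_error", "pixels must be a non-empty matrix")
  bit_depth <- as.integer(bit_depth)
  if (!bit_depth %in% c(8L, 16L))
    stop_seedmd("seedmd_format_error", "bit_depth must be 8 or 16")
  storage.mode(pixels) <- "integer"
  structure(list(pixels = pixels, slice_index = as.integer(slice_index),
                 orientation = orientation, pixel_pitch = pixel_pitch,
                 polarity = polarity, bit_depth = bit_depth),
            class = "bo_slice")
}

#' @export
print.bo_slice <- function(x, ...) {
  cat(sprintf("cross-section %d (%s): %d x %d px, %d-bit, %s\n",
              x$slice_index, x$orientation, nrow(x$pixels), ncol(x$pixels),
              x$bit_depth, x$polarity))
  invisible(x)
}

read_gray_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    px <- tiff::readTIFF(path, as.is = TRUE)
    bps <- attr(px, "bits.per.sample")
    depth <- if (!is.null(bps)) as.integer(bps)
             else if (max(px) > 255L) 16L else 8L
  } else if (ext == "png") {
    px <- png::readPNG(path)
    px <- round(px * 255)
    depth <- 8L
  } else {
    stop_seedmd("seedmd_format_error", "unsupported image format: %s", path)
  }
  if (length(dim(px)) == 3L) {
    if (dim(px)[3] == 1L) px <- px[, , 1L]
    else stop_seedmd("seedmd_format_error",
                     "expected single-channel grayscale image: %s", path)
  }
  if (!depth %in% c(8L, 16L))
    stop_seedmd("seedmd_format_error", "unsupported bit depth (%d) in %s", depth, path)
  storage.mode(px) <- "integer"
  list(pixels = px, bit_depth = depth)
}

#' Read a cross-section stack from a manifest
#'
#' Loads the slice stack described by a JSON manifest (as written by
#' [write_stack()]): pixel data are read losslessly from TIFF/PNG and the
#' slices returned ordered by `slice_index`.
#'
#' @param manifest_path Path to a `manifest.json`.
#' @return List of [bo_slice()] objects, ordered by slice index.  The
#'   manifest is attached as attribute `"manifest"` (with its directory
#'   as `"dir"`) so mask files can be located later.
#' @export
read_stack <- function(manifest_path) {
  if (!file.exists(manifest_path))
    stop_seedmd("seedmd_io_error", "manifest not found: %s", manifest_path)
  manifest <- jsonlite::fromJSON(manifest_path, simplifyDataFrame = FALSE)
  dir <- dirname(manifest_path)
  entries <- manifest$slices
  if (is.null(entries) || !length(entries))
    stop_seedmd("seedmd_manifest_error", "manifest lists no slices")
  idx <- vapply(entries, function(e) as.integer(e$slice_index), integer(1))
  if (anyDuplicated(idx))
    stop_seedmd("seedmd_manifest_error", "duplicate slice_index in manifest: %s",
                paste(unique(idx[duplicated(idx)]), collapse = ", "))
  slices <- lapply(entries, function(e) {
    path <- file.path(dir, e$file)
    if (!file.exists(path))
      stop_seedmd("seedmd_io_error", "image file not found: %s", path)
    img <- read_gray_image(path)
    bo_slice(img$pixels, slice_index = e$slice_index,
             orientation = if (!is.null(e$orientation)) e$orientation else "horizontal",
             pixel_pitch = if (!is.null(manifest$pixel_pitch)) manifest$pixel_pitch else NA_real_,
             polarity = if (!is.null(e$polarity)) e$polarity else "cracks-dark",
             bit_depth = img$bit_depth)
  })
  slices <- slices[order(idx)]
  attr(slices, "manifest") <- manifest
  attr(slices, "dir") <- dir
  slices
}

#' Read a label mask written by [write_stack()]
#'
#' @param path Path to a label TIFF with codes 0-3.
#' @return Integer label matrix.
#' @export
read_mask <- function(path) {
  if (!file.exists(path))
    stop_seedmd("seedmd_io_error", "mask file not found: %s", path)
  px <- tiff::readTIFF(path, as.is = TRUE)
  storage.mode(px) <- "integer"
  if (!all(px %in% 0:3))
    stop_seedmd("seedmd_format_error", "mask %s contains codes outside 0..3", path)
  px
}

#' Normalize slice polarity to the cracks-dark convention
#'
#' Tomography renderings are often colour-inverted so cracks show bright;
#' the segmentation stage assumes the canonical convention (solid bright,
#' cracks and background dark).  A cracks-bright slice is inverted
#' (intensity v becomes max - v); a cracks-dark slice passes through
#' unchanged, so the operation is idempotent on the normalized form.
#'
#' @param slice A [bo_slice()].
#' @return The slice in cracks-dark polarity.
#' @export
normalize_polarity <- function(slice) {
  stopifnot(inherits(slice, "bo_slice"))
  if (slice$polarity == "cracks-dark") return(slice)
  maxv <- as.integer(2^slice$bit_depth - 1)
  slice$pixels <- maxv - slice$pixels
  slice$polarity <- "cracks-dark"
  slice
}

#' Segmentation settings
#'
#' @param bg_threshold Optional fixed intensity separating background
#'   from the object foreground; `NULL` uses a global Otsu split.
#' @param crack_threshold Optional fixed intensity below which object
#'   pixels are cracks; `NULL` uses an Otsu split of the within-object
#'   histogram guarded by a robust contrast rule (see [segment_slice()]).
#' @param min_crack_area Connected damage components smaller than this
#'   (pixels) are reassigned to solid; 0 disables the speckle filter.
#' @param boundary_band_px Boundary band half-width passed to
#'   [derive_boundary()] after segmentation; 0 keeps a two-class object.
#' @return An object of class `segmentation_config`.
#' @export
segmentation_config <- function(bg_threshold = NULL, crack_threshold = NULL,
                                min_crack_area = 5L, boundary_band_px = 0L) {
  min_crack_area <- as.integer(min_crack_area)
  boundary_band_px <- as.integer(boundary_band_px)
  if (min_crack_area < 0L || boundary_band_px < 0L)
    stop_seedmd("seedmd_parameter_error",
                "min_crack_area and boundary_band_px must be non-negative")
  structure(list(bg_threshold = bg_threshold, crack_threshold = crack_threshold,
                 min_crack_area = min_crack_area,
                 boundary_band_px = boundary_band_px),
            class = "segmentation_config")
}

# Otsu threshold over a vector of integer intensities in [0, maxv]:
# maximises between-class variance on the histogram.  Needed because the
# crack threshold must be computed within the object support only.
# Returns -Inf for a degenerate (single-level) histogram.
otsu_threshold <- function(values, maxv) {
  h <- tabulate(values + 1L, nbins = maxv + 1L)
  lv <- which(h > 0L) - 1L
  if (length(lv) < 2L) return(-Inf)
  p <- h / sum(h)
  omega <- cumsum(p)
  mu <- cumsum(p * (0:maxv))
  mu_t <- mu[maxv + 1L]
  sb <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sb[!is.finite(sb)] <- 0
  t <- which.max(sb) - 1L
  t + 0.5  # split between level t and t+1
}

#' Segment a cross-section into background / solid / damage
#'
#' Pipeline: (1) normalize polarity to cracks-dark; (2) split background
#' from foreground by a global Otsu threshold (or a fixed
#' `bg_threshold`); (3) take the largest connected foreground component
#' and fill its holes — internal cracks must belong to the object, not
#' the background — giving the object support; (4) inside the support,
#' mark as damage the pixels below the crack threshold: by default the
#' smaller of the within-support Otsu split and a robust cut
#' (median - 3 MAD of support intensities), which prevents a unimodal
#' crack-free object from being bisected; (5) reassign connected damage
#' components smaller than `min_crack_area` to solid; (6) optionally
#' relabel a boundary band via [derive_boundary()].
#'
#' @param slice A [bo_slice()] (any polarity; normalized internally).
#' @param config A [segmentation_config()].
#' @return Integer label mask (codes of [label_codes()]), same shape as
#'   the slice.
#' @export
segment_slice <- function(slice, config = segmentation_config()) {
  stopifnot(inherits(slice, "bo_slice"), inherits(config, "segmentation_config"))
  slice <- normalize_polarity(slice)
  px <- slice$pixels
  maxv <- as.integer(2^slice$bit_depth - 1)
  for (nm in c("bg_threshold", "crack_threshold")) {
    v <- config[[nm]]
    if (!is.null(v) && (v < 0 || v > maxv))
      stop_seedmd("seedmd_parameter_error", "%s = %s outside intensity range [0, %d]",
                  nm, format(v), maxv)
  }

  if (diff(range(px)) == 0L)
    stop_seedmd("seedmd_segmentation_error",
                "no foreground found (slice has a single intensity level)")
  t_bg <- if (!is.null(config$bg_threshold)) config$bg_threshold
          else EBImage::otsu(EBImage::Image(px / maxv), range = c(0, 1),
                             levels = maxv + 1L) * maxv
  fg <- px > t_bg
  if (!any(fg))
    stop_seedmd("seedmd_segmentation_error",
                "no foreground found (slice appears to be all background)")
  comps <- as.matrix(EBImage::bwlabel(fg + 0))
  sizes <- tabulate(comps[comps > 0])
  support <- (comps == which.max(sizes))
  support <- as.matrix(EBImage::fillHull(support + 0)) > 0

  sup_vals <- px[support]
  t_cr <- if (!is.null(config$crack_threshold)) config$crack_threshold
  else {
    t_otsu <- otsu_threshold(sup_vals, maxv)
    m <- median(sup_vals)
    s <- mad(sup_vals)
    robust_cut <- if (s > 0) m - 3 * s else m - 0.5
    if (is.finite(t_otsu)) min(t_otsu, robust_cut) else -Inf
  }
  damage <- support & px < t_cr

  if (config$min_crack_area > 0L && any(damage)) {
    dl <- as.matrix(EBImage::bwlabel(damage + 0))
    dsz <- tabulate(dl[dl > 0])
    small <- which(dsz < config$min_crack_area)
    if (length(small)) damage[dl %in% small] <- FALSE
  }

  mask <- matrix(LBL_BACKGROUND, nrow(px), ncol(px))
  mask[support] <- LBL_SOLID
  mask[damage] <- LBL_DAMAGE
  if (config$boundary_band_px > 0L)
    mask <- derive_boundary(mask, config$boundary_band_px)
  mask
}

#' Relabel a boundary band around solid/damage interfaces
#'
#' A raster has no measure-zero crack boundary, so "a point on the damage
#' boundary" is operationalized as a band: every solid or damage pixel
#' within `band_px` (chessboard distance, 8-neighbourhood) of a pixel of
#' the other class is relabelled boundary.  Points falling in the band
#' score \eqn{\xi = 0.5}.  `band_px = 0` returns the mask unchanged; the
#' object pixel count is conserved.
#'
#' @param mask Integer label mask containing no boundary labels yet.
#' @param band_px Non-negative band half-width in pixels.
#' @return The relabelled mask.
#' @export
derive_boundary <- function(mask, band_px) {
  band_px <- as.integer(band_px)
  if (band_px < 0L)
    stop_seedmd("seedmd_parameter_error", "band_px must be non-negative")
  if (band_px == 0L) return(mask)
  if (any(mask == LBL_BOUNDARY))
    stop_seedmd("seedmd_parameter_error", "mask already contains boundary labels")
  solid <- mask == LBL_SOLID
  damage <- mask == LBL_DAMAGE
  if (!any(damage)) return(mask)
  brush <- EBImage::makeBrush(2L * band_px + 1L, shape = "box")
  near_damage <- as.matrix(EBImage::dilate(damage * 1, brush)) > 0
  near_solid <- as.matrix(EBImage::dilate(solid * 1, brush)) > 0
  band <- (solid & near_damage) | (damage & near_solid)
  mask[band] <- LBL_BOUNDARY
  mask
}
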