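test_that("write_stack / read_stack round-trips pixel data", {
  dir <- withr::local_tempdir()
  stack <- generate_stack(small_spec(), seed = 4, target_fraction = 0.05,
                          n_slices = 4L)
  manifest <- write_stack(stack, dir)
  slices <- read_stack(manifest)
  expect_length(slices, 4L)
  expect_identical(vapply(slices, `[[`, integer(1), "slice_index"), 0:3)
  expect_identical(slices[[2]]$pixels, stack$slices[[2]]$raster)
  expect_identical(slices[[1]]$orientation, "horizontal")
  expect_equal(slices[[1]]$pixel_pitch, 0.06)
  # masks round-trip through the label TIFF codes
  mask <- read_mask(file.path(dir, "mask_00.tif"))
  expect_identical(mask, stack$slices[[1]]$mask)
})

test_that("PNG rasters round-trip like TIFF", {
  dir <- withr::local_tempdir()
  stack <- generate_stack(small_spec(), seed = 4, target_fraction = 0.05,
                          n_slices = 2L)
  manifest <- write_stack(stack, dir, format = "png")
  slices <- read_stack(manifest)
  expect_identical(slices[[1]]$pixels, stack$slices[[1]]$raster)
})

test_that("manifest problems raise classed errors naming the culprit", {
  dir <- withr::local_tempdir()
  stack <- generate_stack(small_spec(), seed = 4, n_slices = 2L)
  manifest <- write_stack(stack, dir)
  file.remove(file.path(dir, "slice_01.tif"))
  expect_error(read_stack(manifest), "slice_01", class = "seedmd_io_error")

  expect_error(read_stack(file.path(dir, "nope.json")),
               class = "seedmd_io_error")

  bad <- list(pixel_pitch = 0.06, bit_depth = 8,
              slices = list(list(file = "slice_00.tif", slice_index = 0),
                            list(file = "slice_00.tif", slice_index = 0)))
  bad_path <- file.path(dir, "dup.json")
  jsonlite::write_json(bad, bad_path, auto_unbox = TRUE)
  expect_error(read_stack(bad_path), class = "seedmd_manifest_error")
})

test_that("polarity normalisation inverts once and is idempotent", {
  px <- matrix(as.integer(c(0, 60, 200, 255)), 2, 2)
  bright <- bo_slice(px, polarity = "cracks-bright")
  dark <- normalize_polarity(bright)
  expect_identical(dark$pixels, 255L - px)
  expect_identical(dark$polarity, "cracks-dark")
  expect_identical(normalize_polarity(dark), dark)

  already <- bo_slice(px, polarity = "cracks-dark")
  expect_identical(normalize_polarity(already)$pixels, px)
})

test_that("noise-free phantom slices segment exactly", {
  sl <- generate_slice(phantom_spec(), target_fraction = 0.05, seed = 1)
  mask <- segment_slice(bo_slice(sl$raster),
                        segmentation_config(min_crack_area = 0L))
  expect_identical(mask, sl$mask)  # 100% of all pixels, speckle filter off
})

test_that("segmentation handles degenerate and crack-free slices", {
  flat <- bo_slice(matrix(10L, 64, 64))
  expect_error(segment_slice(flat), class = "seedmd_segmentation_error")

  crack_free <- generate_slice(small_spec(crack_count = 0L), seed = 5)
  mask <- segment_slice(bo_slice(crack_free$raster))
  expect_identical(sum(mask == 2L), 0L)
})

test_that("segmentation of a cracks-bright slice matches the dark original", {
  sl <- generate_slice(small_spec(polarity = "cracks-bright"),
                       target_fraction = 0.05, seed = 6)
  mask <- segment_slice(bo_slice(sl$raster, polarity = "cracks-bright"),
                        segmentation_config(min_crack_area = 0L))
  expect_identical(mask, sl$mask)
})

test_that("labels always partition the raster", {
  for (noise in c(0, 8)) {
    sl <- generate_slice(small_spec(noise_sd = noise),
                         target_fraction = 0.08, seed = 8)
    mask <- segment_slice(bo_slice(sl$raster),
                          segmentation_config(boundary_band_px = 1L))
    expect_true(all(mask %in% 0:3))
    counts <- vapply(0:3, function(k) sum(mask == k), integer(1))
    expect_identical(sum(counts), length(mask))
    expect_gt(sum(counts[-1]), 0L)  # non-empty object region
  }
})

test_that("raising the crack threshold never shrinks the damage region", {
  sl <- generate_slice(small_spec(noise_sd = 6), target_fraction = 0.08, seed = 9)
  slice <- bo_slice(sl$raster)
  counts <- vapply(c(30, 60, 90, 130, 170), function(t)
    sum(segment_slice(slice, segmentation_config(crack_threshold = t)) == 2L),
    integer(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("segmentation thresholds outside the intensity range are rejected", {
  sl <- generate_slice(small_spec(), target_fraction = 0.05, seed = 2)
  expect_error(segment_slice(bo_slice(sl$raster),
                             segmentation_config(crack_threshold = 300)),
               class = "seedmd_parameter_error")
})

test_that("boundary band relabels the interface and conserves the object", {
  m <- matrix(1L, 9, 9)
  m[5, 5] <- 2L
  b <- derive_boundary(m, 1L)
  expect_identical(sum(b == 3L), 9L)          # pixel + its 8 solid neighbours
  expect_identical(b[5, 5], 3L)
  expect_identical(sum(b != 0L), sum(m != 0L))  # partition conservation

  expect_identical(derive_boundary(m, 0L), m)
  expect_error(derive_boundary(b, 1L), class = "seedmd_parameter_error")
})
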