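#' Run the virtual loading study
#'
#' End-to-end harness over the factor grid of the loading experiment:
#' for every scenario (load type x placement x load fraction) and
#' replicate, a phantom stack is generated, each section is segmented
#' (or its ground-truth mask used directly), the Monte Carlo estimator
#' is run, and one row is appended to the study table.  Fully seeded:
#' scenario `k`, replicate `r` uses root seed
#' `seed + 100000 (k-1) + 1000 (r-1)`, with the point sampler offset by
#' 500 so generation and estimation never share an RNG stream.
#'
#' @param spec A [phantom_spec()].
#' @param scenarios List of [load_scenario()] objects (e.g.
#'   [default_scenario_grid()]).
#' @param replicates Specimens per scenario cell.
#' @param seed Integer root seed.
#' @param n_points Accepted points N per section.
#' @param confidence_level \eqn{\beta} for the interval half-widths.
#' @param segment `TRUE` to segment the phantom rasters (exercising the
#'   full pipeline); `FALSE` to estimate on the ground-truth masks.
#' @param config A [segmentation_config()] used when `segment = TRUE`.
#' @return A `study_table` data frame with one row per
#'   (scenario, replicate): `load_type`, `orientation`, `load_fraction`,
#'   `replicate_id`, `kmd`, `ci_halfwidth`, `kfmd_oracle`.
#' @export
run_virtual_study <- function(spec, scenarios = default_scenario_grid(),
                              replicates = 1L, seed = 1L,
                              n_points = 3400L, confidence_level = 0.95,
                              segment = TRUE,
                              config = segmentation_config()) {
  if (!length(scenarios))
    stop_seedmd("seedmd_parameter_error", "at least one scenario is required")
  replicates <- as.integer(replicates)
  if (replicates < 1L)
    stop_seedmd("seedmd_parameter_error", "replicates must be >= 1")
  rows <- vector("list", length(scenarios) * replicates)
  n <- 0L
  for (k in seq_along(scenarios)) {
    scn <- scenarios[[k]]
    for (r in seq_len(replicates)) {
      cell_seed <- as.integer(seed + 100000L * (k - 1L) + 1000L * (r - 1L))
      est <- tryCatch({
        stack <- generate_stack(spec, scn, seed = cell_seed)
        masks <- if (segment)
          lapply(stack$slices, function(s)
            segment_slice(bo_slice(s$raster, slice_index = s$slice_index,
                                   orientation = s$orientation,
                                   pixel_pitch = s$pixel_pitch,
                                   polarity = s$polarity),
                          config))
        else lapply(stack$slices, `[[`, "mask")
        estimate_specimen(masks, n_points = n_points,
                          confidence_level = confidence_level,
                          seed = cell_seed + 500L,
                          oracle = mean(stack$truth$weighted_fraction),
                          scenario = scn)
      }, seedmd_error = function(e) {
        stop_seedmd(class(e)[1],
                    "scenario %s/%s at %.2f F_kr (replicate %d): %s",
                    scn$load_type, scn$orientation, scn$load_fraction, r,
                    conditionMessage(e))
      })
      n <- n + 1L
      rows[[n]] <- data.frame(load_type = scn$load_type,
                              orientation = scn$orientation,
                              load_fraction = scn$load_fraction,
                              replicate_id = r,
                              kmd = est$kmd,
                              ci_halfwidth = est$ci_halfwidth,
                              kfmd_oracle = est$kfmd_oracle)
    }
  }
  tab <- do.call(rbind, rows)
  class(tab) <- c("study_table", "data.frame")
  tab
}

study_group <- function(table, load_type, orientation) {
  g <- table[table$load_type == load_type & table$orientation == orientation, ,
             drop = FALSE]
  if (!nrow(g))
    stop_seedmd("seedmd_parameter_error", "no rows for group %s/%s",
                load_type, orientation)
  g
}

#' Fold increase of damage across the load range
#'
#' The headline summary of the loading study: the mean microdamage
#' coefficient at the highest load fraction divided by the mean at the
#' lowest, within one load-type x placement group.  Magnitudes around
#' 5.5-6 (static) and 3-3.3 (dynamic) are typical for corn seeds loaded
#' from 0.3 to 0.9 F_kr.
#'
#' @param table A `study_table` from [run_virtual_study()].
#' @param load_type,orientation Group selectors.
#' @return Positive ratio.
#' @export
fold_increase <- function(table, load_type, orientation) {
  g <- study_group(table, load_type, orientation)
  fr <- sort(unique(g$load_fraction))
  if (length(fr) < 2L)
    stop_seedmd("seedmd_parameter_error",
                "fold increase needs >= 2 distinct load fractions")
  lo <- mean(g$kmd[g$load_fraction == fr[1]])
  hi <- mean(g$kmd[g$load_fraction == fr[length(fr)]])
  if (lo == 0)
    stop_seedmd("seedmd_undefined_ratio_error",
                "mean K_md at the lowest load fraction is zero")
  hi / lo
}

#' Polynomial trend of damage versus load fraction
#'
#' Least-squares polynomial fit (degree <= 2) of the microdamage
#' coefficient on the load fraction within one group, summarising the
#' smooth monotone dose-response curves of the study.
#'
#' @param table A `study_table`.
#' @param load_type,orientation Group selectors.
#' @param degree Polynomial degree, 1 or 2 (default 2).
#' @return An object of class `trend_fit`: group key, named coefficient
#'   vector (intercept first), and `r_squared` (1 for an exact fit,
#'   including the degenerate constant-response case).
#' @export
fit_trend <- function(table, load_type, orientation, degree = 2L) {
  degree <- as.integer(degree)
  if (degree < 1L || degree > 2L)
    stop_seedmd("seedmd_parameter_error", "degree must be 1 or 2")
  g <- study_group(table, load_type, orientation)
  if (length(unique(g$load_fraction)) < degree + 1L)
    stop_seedmd("seedmd_parameter_error",
                "need >= %d distinct load fractions for degree %d",
                degree + 1L, degree)
  fit <- lm(kmd ~ poly(load_fraction, degree, raw = TRUE), data = g)
  cf <- unname(coef(fit))
  names(cf) <- paste0("c", seq_along(cf) - 1L)
  tss <- sum((g$kmd - mean(g$kmd))^2)
  rss <- sum(fit$residuals^2)
  r2 <- if (tss > 0) max(0, 1 - rss / tss) else 1
  structure(list(load_type = load_type, orientation = orientation,
                 degree = degree, coefficients = cf, r_squared = r2),
            class = "trend_fit")
}

#' @export
print.trend_fit <- function(x, ...) {
  cat(sprintf("trend %s/%s: kmd = %s (R^2 = %.3f)\n",
              x$load_type, x$orientation,
              paste(sprintf("%.4g f^%d", x$coefficients,
                            seq_along(x$coefficients) - 1L), collapse = " + "),
              x$r_squared))
  invisible(x)
}

#' Write the study report
#'
#' Emits the study table (`study_table.csv`), a per-group summary with
#' fold increases (`group_summary.csv`), the trend fits
#' (`trend_fits.json`) and, optionally, one dose-response plot per
#' placement (`damage_vs_load_<orientation>.png`, static and dynamic
#' curves overlaid).  Re-running overwrites the same files
#' deterministically.
#'
#' @param table A `study_table`.
#' @param fits List of [fit_trend()] results (may be empty).
#' @param out_dir Output directory (created if needed).
#' @param plots Draw the dependence plots (default `TRUE`).
#' @return Invisibly, the written file paths.
#' @export
write_report <- function(table, fits = list(), out_dir, plots = TRUE) {
  ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir))
    stop_seedmd("seedmd_io_error", "cannot create output directory %s", out_dir)
  paths <- character(0)

  p <- file.path(out_dir, "study_table.csv")
  write.csv(as.data.frame(table), p, row.names = FALSE)
  paths <- c(paths, p)

  groups <- unique(table[, c("load_type", "orientation")])
  summ <- do.call(rbind, lapply(seq_len(nrow(groups)), function(i) {
    g <- study_group(table, groups$load_type[i], groups$orientation[i])
    data.frame(load_type = groups$load_type[i],
               orientation = groups$orientation[i],
               n_rows = nrow(g),
               kmd_min_load = mean(g$kmd[g$load_fraction == min(g$load_fraction)]),
               kmd_max_load = mean(g$kmd[g$load_fraction == max(g$load_fraction)]),
               fold_increase = tryCatch(
                 fold_increase(table, groups$load_type[i], groups$orientation[i]),
                 seedmd_error = function(e) NA_real_))
  }))
  p <- file.path(out_dir, "group_summary.csv")
  write.csv(summ, p, row.names = FALSE)
  paths <- c(paths, p)

  p <- file.path(out_dir, "trend_fits.json")
  jsonlite::write_json(lapply(fits, function(f) {
    f <- unclass(f)
    f$coefficients <- as.list(f$coefficients)  # keep c0/c1/... names in JSON
    f
  }), p, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  paths <- c(paths, p)

  if (plots) {
    for (orient in unique(table$orientation)) {
      p <- file.path(out_dir, sprintf("damage_vs_load_%s.png", orient))
      grDevices::png(p, width = 720, height = 540)
      g <- table[table$orientation == orient, , drop = FALSE]
      cols <- c(static = "blue", dynamic = "red")
      graphics::plot(NULL, xlim = range(g$load_fraction),
                     ylim = c(0, max(g$kmd) * 1.1),
                     xlab = "load fraction of F_kr",
                     ylab = "microdamage coefficient K_md",
                     main = sprintf("Damage vs external load (%s placement)", orient))
      for (lt in unique(g$load_type)) {
        gg <- g[g$load_type == lt, ]
        agg <- stats::aggregate(kmd ~ load_fraction, data = gg, FUN = mean)
        graphics::lines(agg$load_fraction, agg$kmd, col = cols[[lt]], lwd = 2)
        graphics::points(gg$load_fraction, gg$kmd, col = cols[[lt]], pch = 19)
      }
      graphics::legend("topleft", legend = names(cols), col = cols, lwd = 2)
      grDevices::dev.off()
      paths <- c(paths, p)
    }
  }
  invisible(paths)
}
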