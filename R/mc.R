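#' Sample uniform random points over the object region of a mask
#'
#' Implements the point-throwing step of the Monte Carlo estimator:
#' real-valued coordinates are drawn uniformly over the image rectangle
#' and points landing on background are rejected and regenerated — they
#' do not count towards N.  Exactly `n_points` accepted samples are
#' returned, uniformly distributed over the object region (solid, damage
#' and boundary pixels all have equal probability of capture).
#'
#' @param mask Integer label mask with at least one object pixel.
#' @param n_points Number of accepted points N (the per-section default
#'   elsewhere in the package is 3400).
#' @param seed Integer seed; identical inputs reproduce identical samples.
#' @param method `"random"` (default) for independent uniform points;
#'   `"stratified"` lays a jittered square grid over the image and keeps
#'   in-object points (repeating passes until N are collected), trading
#'   independence for lower spatial clumping.
#' @param max_attempts Cap on total generated points before the mask is
#'   declared degenerate.
#' @return Data frame with columns `x`, `y` (0-based real coordinates)
#'   and `xi` (0 damage, 0.5 boundary, 1 solid).
#' @examples
#' m <- matrix(1L, 50, 50); m[20:30, 20:22] <- 2L
#' s <- sample_points(m, 1000, seed = 1)
#' 1 - mean(s$xi)  # close to the damage fraction 33/2500
#' @export
sample_points <- function(mask, n_points, seed = 1L,
                          method = c("random", "stratified"),
                          max_attempts = 10000 * n_points) {
  method <- match.arg(method)
  n_points <- as.integer(n_points)
  if (n_points < 1L)
    stop_seedmd("seedmd_parameter_error", "n_points must be >= 1")
  if (!any(mask != LBL_BACKGROUND))
    stop_seedmd("seedmd_empty_domain_error", "mask contains no object pixels")
  nr <- nrow(mask); nc <- ncol(mask)

  with_local_seed(seed, {
    xs <- numeric(0); ys <- numeric(0); labs <- integer(0)
    attempts <- 0
    pass <- 0L
    while (length(xs) < n_points) {
      need <- n_points - length(xs)
      if (method == "random") {
        m <- max(2L * need, 512L)
        cx <- runif(m, 0, nc); cy <- runif(m, 0, nr)
      } else {
        # one jittered point per cell of a grid sized to roughly cover N
        pass <- pass + 1L
        g <- ceiling(sqrt(max(need, 16L) / mean(mask != LBL_BACKGROUND)))
        gx <- (rep(seq_len(g), each = g) - runif(g * g)) * (nc / g)
        gy <- (rep(seq_len(g), times = g) - runif(g * g)) * (nr / g)
        cx <- gx; cy <- gy
        m <- g * g
      }
      attempts <- attempts + m
      l <- mask[cbind(floor(cy) + 1, floor(cx) + 1)]
      keep <- l != LBL_BACKGROUND
      xs <- c(xs, cx[keep]); ys <- c(ys, cy[keep]); labs <- c(labs, l[keep])
      if (attempts > max_attempts)
        stop_seedmd("seedmd_degenerate_mask_error",
                    "rejection sampling exceeded %d attempts; object region too sparse",
                    max_attempts)
    }
    idx <- seq_len(n_points)
    data.frame(x = xs[idx], y = ys[idx], xi = xi_from_label(labs[idx]))
  })
}

xi_from_label <- function(label) {
  xi <- rep(NA_real_, length(label))
  xi[label == LBL_SOLID] <- 1
  xi[label == LBL_DAMAGE] <- 0
  xi[label == LBL_BOUNDARY] <- 0.5
  xi
}

#' Classify a point against a label mask
#'
#' Returns the random variable \eqn{\xi} of a sampled point: 0 when it
#' falls within a damage (crack) pixel, 0.5 on a boundary pixel, 1 in
#' solid material.  Points on background are a caller error — the
#' sampler must reject them before classification.
#'
#' @param mask Integer label mask.
#' @param x,y 0-based real coordinates (x = column, y = row); vectorized.
#' @return Numeric vector over \{0, 0.5, 1\}.
#' @export
classify_point <- function(mask, x, y) {
  nr <- nrow(mask); nc <- ncol(mask)
  if (any(x < 0 | x >= nc | y < 0 | y >= nr))
    stop_seedmd("seedmd_domain_error", "point outside the image rectangle")
  l <- mask[cbind(floor(y) + 1, floor(x) + 1)]
  if (any(l == LBL_BACKGROUND))
    stop_seedmd("seedmd_domain_error",
                "point falls on background; reject before classifying")
  xi_from_label(l)
}

#' Two-sided standard-normal quantile for a confidence level
#'
#' The factor \eqn{x_\beta} of the confidence-interval half-width: the
#' standard-normal quantile at cumulative probability \eqn{(1+\beta)/2}.
#' At \eqn{\beta = 0.95}, \eqn{x_\beta = 1.96}.
#'
#' @param confidence_level \eqn{\beta} in (0, 1).
#' @return Positive real \eqn{x_\beta}.
#' @examples
#' round(normal_quantile(0.95), 2)  # 1.96
#' @export
normal_quantile <- function(confidence_level) {
  if (any(confidence_level <= 0 | confidence_level >= 1))
    stop_seedmd("seedmd_parameter_error", "confidence_level must lie in (0, 1)")
  qnorm((1 + confidence_level) / 2)
}

#' Per-section microdamage coefficient from classified points
#'
#' Computes the Monte Carlo estimate for one cross-section:
#' \deqn{K_{md,i} = 1 - \frac{\sum_{i=1}^N \xi_i}{N}}
#' with plug-in variance
#' \deqn{D_\xi = \frac{1}{N}\sum \xi_i^2 - \left(\frac{1}{N}\sum \xi_i\right)^2}
#' and confidence-interval half-width \eqn{x_\beta \sqrt{D_\xi / N}}
#' under a normal error model.
#'
#' @param samples A data frame with an `xi` column (as returned by
#'   [sample_points()]) or a bare numeric vector of \eqn{\xi} values in
#'   \[0, 1\].
#' @param confidence_level \eqn{\beta} in (0, 1); default 0.95.
#' @param slice_index,seed Optional bookkeeping recorded on the estimate.
#' @return An object of class `slice_estimate`: `kmd_i`, `n_points`,
#'   `xi_sum`, `xi_sq_sum`, `variance`, `ci_halfwidth`,
#'   `confidence_level`, `slice_index`, `seed`.
#' @examples
#' est <- estimate_slice(c(1, 1, 0, 0.5))
#' est$kmd_i      # 0.375
#' est$variance   # 0.171875
#' @export
estimate_slice <- function(samples, confidence_level = 0.95,
                           slice_index = NA_integer_, seed = NA_integer_) {
  xi <- if (is.data.frame(samples)) samples$xi else samples
  if (is.null(xi) || length(xi) == 0L)
    stop_seedmd("seedmd_parameter_error", "no samples provided")
  if (any(is.na(xi)) || any(xi < 0 | xi > 1))
    stop_seedmd("seedmd_parameter_error", "xi values must lie in [0, 1]")
  if (any(confidence_level <= 0 | confidence_level >= 1))
    stop_seedmd("seedmd_parameter_error", "confidence_level must lie in (0, 1)")
  n <- length(xi)
  s1 <- sum(xi)
  s2 <- sum(xi^2)
  kmd <- 1 - s1 / n
  v <- max(s2 / n - (s1 / n)^2, 0)  # clamp numeric dust
  structure(list(kmd_i = kmd, n_points = n, xi_sum = s1, xi_sq_sum = s2,
                 variance = v,
                 ci_halfwidth = normal_quantile(confidence_level) * sqrt(v / n),
                 confidence_level = confidence_level,
                 slice_index = as.integer(slice_index),
                 seed = as.integer(seed)),
            class = "slice_estimate")
}

#' @export
print.slice_estimate <- function(x, ...) {
  cat(sprintf("K_md[%s] = %.4f +/- %.4f (beta = %.2f, N = %d, D_xi = %.5f)\n",
              ifelse(is.na(x$slice_index), "?", x$slice_index),
              x$kmd_i, x$ci_halfwidth, x$confidence_level, x$n_points,
              x$variance))
  invisible(x)
}

#' Aggregate per-section estimates into a specimen coefficient
#'
#' The specimen-level microdamage coefficient is the arithmetic mean of
#' the per-section coefficients over the J sections of the stack
#' (J = 20 in the standard 10 horizontal + 10 vertical protocol):
#' \deqn{K_{md} = (K_{md,1} + K_{md,2} + \dots + K_{md,J}) / J.}
#' The specimen confidence-interval half-width combines the per-section
#' variances as \eqn{x_\beta \sqrt{\sum_j D_{\xi,j}/N_j} / J}.
#'
#' @param slice_estimates List of [estimate_slice()] results; re-ordered
#'   by `slice_index` when indices are recorded.
#' @param oracle Optional exact damage fraction (the area-based actual
#'   coefficient) carried through for comparison.
#' @param scenario Optional [load_scenario()] metadata.
#' @return An object of class `specimen_estimate`: `kmd`,
#'   `ci_halfwidth`, `slice_estimates`, `kfmd_oracle`, `scenario`.
#' @examples
#' ests <- c(replicate(10, estimate_slice(rep(1, 5)), simplify = FALSE),
#'           replicate(10, estimate_slice(rep(0.8, 5)), simplify = FALSE))
#' aggregate_specimen(ests)$kmd  # 0.1
#' @export
aggregate_specimen <- function(slice_estimates, oracle = NULL, scenario = NULL) {
  if (inherits(slice_estimates, "slice_estimate"))
    slice_estimates <- list(slice_estimates)
  if (!length(slice_estimates))
    stop_seedmd("seedmd_parameter_error", "no slice estimates provided")
  stopifnot(all(vapply(slice_estimates, inherits, logical(1), "slice_estimate")))
  idx <- vapply(slice_estimates, function(e) e$slice_index, integer(1))
  if (!anyNA(idx)) slice_estimates <- slice_estimates[order(idx)]
  kmds <- vapply(slice_estimates, function(e) e$kmd_i, numeric(1))
  vars <- vapply(slice_estimates, function(e) e$variance / e$n_points, numeric(1))
  beta <- slice_estimates[[1]]$confidence_level
  structure(list(kmd = mean(kmds),
                 ci_halfwidth = normal_quantile(beta) * sqrt(sum(vars)) / length(kmds),
                 slice_estimates = slice_estimates,
                 kfmd_oracle = oracle,
                 scenario = scenario),
            class = "specimen_estimate")
}

#' @export
print.specimen_estimate <- function(x, ...) {
  cat(sprintf("specimen K_md = %.4f +/- %.4f over %d sections",
              x$kmd, x$ci_halfwidth, length(x$slice_estimates)))
  if (!is.null(x$kfmd_oracle))
    cat(sprintf("; exact K_fmd = %.4f", x$kfmd_oracle))
  cat("\n")
  invisible(x)
}

#' Estimate the specimen coefficient from a stack of masks
#'
#' Convenience wrapper running [sample_points()] and [estimate_slice()]
#' on every mask of a stack and aggregating with [aggregate_specimen()].
#' Section `i` (0-based) uses RNG stream `seed + i`, so slices are
#' independent yet the whole specimen is reproducible from one root
#' seed.
#'
#' @param masks List of label masks, ordered by slice index.
#' @param n_points Accepted points N per section (default 3400).
#' @param confidence_level \eqn{\beta} (default 0.95).
#' @param seed Root seed for the specimen.
#' @param oracle `TRUE` to compute the exact area oracle as the mean of
#'   [exact_damage_fraction()] over the masks; or a number to pass
#'   through; `NULL` to omit.
#' @param scenario Optional [load_scenario()] metadata.
#' @return A `specimen_estimate`.
#' @export
estimate_specimen <- function(masks, n_points = 3400L, confidence_level = 0.95,
                              seed = 1L, oracle = TRUE, scenario = NULL) {
  if (!length(masks))
    stop_seedmd("seedmd_parameter_error", "no masks provided")
  ests <- lapply(seq_along(masks), function(j) {
    i <- j - 1L
    s <- sample_points(masks[[j]], n_points, seed = seed + i)
    estimate_slice(s, confidence_level, slice_index = i, seed = seed + i)
  })
  orc <- if (isTRUE(oracle))
    mean(vapply(masks, exact_damage_fraction, numeric(1)))
  else if (is.numeric(oracle)) oracle
  aggregate_specimen(ests, oracle = orc, scenario = scenario)
}

#' Write specimen estimates to disk
#'
#' Emits a per-section CSV (`slice_index`, `n_points`, `kmd_i`,
#' `variance`, `ci_halfwidth`) and a specimen JSON (`kmd`,
#' `ci_halfwidth`, `kfmd_oracle`, scenario metadata, `n_points`,
#' `confidence_level`).
#'
#' @param specimen A `specimen_estimate`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the two file paths.
#' @export
write_estimates <- function(specimen, dir) {
  stopifnot(inherits(specimen, "specimen_estimate"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  per_slice <- do.call(rbind, lapply(specimen$slice_estimates, function(e)
    data.frame(slice_index = e$slice_index, n_points = e$n_points,
               kmd_i = e$kmd_i, variance = e$variance,
               ci_halfwidth = e$ci_halfwidth)))
  csv <- file.path(dir, "slice_estimates.csv")
  write.csv(per_slice, csv, row.names = FALSE)
  js <- file.path(dir, "specimen.json")
  e1 <- specimen$slice_estimates[[1]]
  jsonlite::write_json(
    list(kmd = specimen$kmd,
         ci_halfwidth = specimen$ci_halfwidth,
         kfmd_oracle = specimen$kfmd_oracle,
         n_sections = length(specimen$slice_estimates),
         n_points = e1$n_points,
         confidence_level = e1$confidence_level,
         scenario = if (!is.null(specimen$scenario))
           unclass(specimen$scenario)),
    js, auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null")
  invisible(c(csv = csv, json = js))
}
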