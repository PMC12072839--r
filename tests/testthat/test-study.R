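# Hand-built table for the arithmetic of the summaries.
toy_table <- function(kmd_fun, fractions = c(0.3, 0.45, 0.6, 0.75, 0.9)) {
  g <- expand.grid(load_fraction = fractions,
                   orientation = c("vertical", "horizontal"),
                   load_type = c("static", "dynamic"),
                   stringsAsFactors = FALSE)
  g$replicate_id <- 1L
  g$kmd <- kmd_fun(g)
  g$ci_halfwidth <- 0.001
  g$kfmd_oracle <- g$kmd
  class(g) <- c("study_table", "data.frame")
  g
}

test_that("the full factor grid yields one row per scenario cell", {
  tab <- run_virtual_study(small_spec(), default_scenario_grid(),
                           replicates = 1L, seed = 2, n_points = 200,
                           segment = FALSE)
  expect_identical(nrow(tab), 20L)
  expect_identical(sort(unique(tab$load_fraction)), c(0.3, 0.45, 0.6, 0.75, 0.9))
  expect_setequal(unique(tab$load_type), c("static", "dynamic"))
  tab2 <- run_virtual_study(small_spec(), default_scenario_grid(),
                            replicates = 1L, seed = 2, n_points = 200,
                            segment = FALSE)
  expect_identical(tab, tab2)
})

test_that("fold increase is the max-load over min-load mean ratio", {
  tab <- toy_table(function(g) 0.02 * ifelse(g$load_fraction == 0.9, 6, 1))
  expect_equal(fold_increase(tab, "static", "vertical"), 6)

  flat <- toy_table(function(g) rep(0.05, nrow(g)))
  expect_equal(fold_increase(flat, "dynamic", "horizontal"), 1)

  zero <- toy_table(function(g) ifelse(g$load_fraction == 0.3, 0, 0.1))
  expect_error(fold_increase(zero, "static", "vertical"),
               class = "seedmd_undefined_ratio_error")

  single <- toy_table(function(g) g$load_fraction, fractions = 0.3)
  expect_error(fold_increase(single, "static", "vertical"),
               class = "seedmd_parameter_error")
})

test_that("trend fits recover exact and constant relationships", {
  lin <- toy_table(function(g) 0.1 * g$load_fraction)
  fit <- fit_trend(lin, "static", "vertical", degree = 1L)
  expect_equal(unname(fit$coefficients), c(0, 0.1), tolerance = 1e-10)
  expect_equal(fit$r_squared, 1)

  flat <- toy_table(function(g) rep(0.07, nrow(g)))
  fit0 <- fit_trend(flat, "static", "vertical", degree = 1L)
  expect_equal(unname(fit0$coefficients)[2], 0, tolerance = 1e-12)
  expect_equal(fit0$r_squared, 1)  # degenerate exact fit

  single <- toy_table(function(g) g$load_fraction, fractions = c(0.3, 0.9))
  expect_error(fit_trend(single, "static", "vertical", degree = 2L),
               class = "seedmd_parameter_error")
})

test_that("trend slope is recovered from a noisy linear generator", {
  set.seed(7)
  fractions <- c(0.3, 0.45, 0.6, 0.75, 0.9)
  rows <- expand.grid(load_fraction = rep(fractions, 10))
  rows$load_type <- "static"; rows$orientation <- "vertical"
  rows$replicate_id <- 1L
  rows$kmd <- 0.15 * rows$load_fraction + rnorm(nrow(rows), 0, 0.005)
  rows$ci_halfwidth <- 0; rows$kfmd_oracle <- rows$kmd
  class(rows) <- c("study_table", "data.frame")
  fit <- fit_trend(rows, "static", "vertical", degree = 1L)
  se <- 0.005 / sqrt(sum((rows$load_fraction - mean(rows$load_fraction))^2))
  expect_lt(abs(fit$coefficients[["c1"]] - 0.15), 3 * se)
})

test_that("group means are non-decreasing when the response is noise-free", {
  tab <- run_virtual_study(small_spec(), default_scenario_grid(),
                           replicates = 1L, seed = 3, n_points = 2000,
                           segment = FALSE)
  for (lt in c("static", "dynamic")) for (orient in c("vertical", "horizontal")) {
    g <- tab[tab$load_type == lt & tab$orientation == orient, ]
    means <- tapply(g$kmd, g$load_fraction, mean)
    # allow MC noise no larger than the CI half-widths
    expect_true(all(diff(means[order(as.numeric(names(means)))]) >
                      -2 * max(g$ci_halfwidth)))
  }
})

test_that("write_report emits a consistent, re-readable report", {
  dir <- withr::local_tempdir()
  tab <- toy_table(function(g) 0.02 + 0.1 * (g$load_fraction - 0.3))
  fits <- list(fit_trend(tab, "static", "vertical", 1L))
  paths <- write_report(tab, fits, dir, plots = FALSE)
  expect_true(all(file.exists(paths)))

  back <- read.csv(file.path(dir, "study_table.csv"), stringsAsFactors = FALSE)
  expect_identical(nrow(back), 20L)
  expect_equal(back$kmd, tab$kmd)

  summ <- read.csv(file.path(dir, "group_summary.csv"))
  expect_identical(nrow(summ), 4L)
  expect_equal(summ$fold_increase,
               rep(fold_increase(tab, "static", "vertical"), 4))

  js <- jsonlite::fromJSON(file.path(dir, "trend_fits.json"),
                           simplifyDataFrame = FALSE)
  expect_length(js, 1L)
  expect_equal(unlist(js[[1]]$coefficients), fits[[1]]$coefficients)

  # empty fits collection is not an error
  paths2 <- write_report(tab, list(), dir, plots = FALSE)
  expect_length(jsonlite::fromJSON(file.path(dir, "trend_fits.json")), 0L)
})

test_that("study plots are written when requested", {
  dir <- withr::local_tempdir()
  tab <- toy_table(function(g) 0.02 + 0.1 * (g$load_fraction - 0.3))
  paths <- write_report(tab, list(), dir, plots = TRUE)
  expect_true(file.exists(file.path(dir, "damage_vs_load_vertical.png")))
  expect_true(file.exists(file.path(dir, "damage_vs_load_horizontal.png")))
})
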