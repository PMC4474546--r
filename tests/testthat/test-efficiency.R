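# Independent OLS oracle used to cross-check the fit: closed-form slope
# and intercept from centred sums, no lm() involved.
ols_oracle <- function(x, y) {
  xc <- x - mean(x)
  slope <- sum(xc * y) / sum(xc^2)
  list(slope = slope, intercept = mean(y) - slope * mean(x))
}

test_that("a perfect doubling series gives slope -3.32193 and E = 2", {
  pts <- data.frame(log10Input = c(0, -1, -2),
                    cq = c(30, 33.32193, 36.64386))
  fit <- suppressWarnings(fit_standard_curve(pts))
  expect_equal(fit$slope, -3.32193, tolerance = 1e-6)
  expect_equal(fit$efficiency, 2.0, tolerance = 1e-4)
  expect_equal(fit$intercept, 30, tolerance = 1e-5)
  expect_equal(fit$rSquared, 1, tolerance = 1e-9)
  expect_identical(fit$method, "standard-curve")
  expect_identical(fit$nPoints, 3L)

  oracle <- ols_oracle(pts$log10Input, pts$cq)
  expect_equal(fit$slope, oracle$slope, tolerance = 1e-12)
  expect_equal(fit$intercept, oracle$intercept, tolerance = 1e-12)
})

test_that("degenerate inputs raise insufficient-data errors", {
  expect_error(
    fit_standard_curve(data.frame(log10Input = c(0, 0, 0),
                                  cq = c(30, 30, 31))),
    class = "rdml_insufficient_data")
  expect_error(
    fit_standard_curve(data.frame(log10Input = c(0, -1), cq = c(30, 33))),
    class = "rdml_insufficient_data")
  expect_error(efficiency_from_per_curve(2.0),
               class = "rdml_insufficient_data")
})

test_that("a non-negative slope warns but still returns a fit", {
  pts <- data.frame(log10Input = c(0, -1, -2), cq = c(30, 29, 28.1))
  expect_warning(fit <- fit_standard_curve(pts), "slope")
  expect_true(is.finite(fit$efficiency))
})

test_that("per-curve efficiencies aggregate as mean and SEM", {
  fit <- efficiency_from_per_curve(c(1.9, 2.0, 2.1))
  expect_equal(fit$efficiency, 2.0)
  expect_equal(fit$efficiencySE, stats::sd(c(1.9, 2.0, 2.1)) / sqrt(3),
               tolerance = 1e-12)
  expect_equal(fit$efficiencySE, 0.0577350, tolerance = 1e-6)
  expect_identical(fit$method, "per-curve-sem")
  expect_true(is.na(fit$slope))

  same <- efficiency_from_per_curve(c(2.0, 2.0))
  expect_equal(same$efficiency, 2.0)
  expect_equal(same$efficiencySE, 0)
})

test_that("noise-free dilution series recover the true efficiency exactly", {
  for (E in c(1.80, 1.90, 2.00)) {
    spec <- synthetic_run_spec(
      version = "1.2", seed = 51,
      targets = list(list(id = "tgt1", trueEfficiency = E,
                          cqAtUnitInput = 35, tm = 85)),
      noiseSd = 0, cqNoiseSd = 0)
    doc <- generate_rdml_document(spec)
    pts <- standard_points_from_document(doc, "tgt1")
    fit <- suppressWarnings(fit_standard_curve(pts))
    expect_equal(fit$efficiency, E, tolerance = 1e-9)
  }
})

test_that("estimation error shrinks as the standard curve grows", {
  # 200 replicate simulations per size; mean |E_hat - E| must decrease
  # monotonically over 5 -> 10 -> 20 points.
  set.seed(52)
  true_slope <- -1 / log10(1.9)
  mean_err <- vapply(c(5, 10, 20), function(n) {
    x <- rep(seq(4, 0, length.out = 5), length.out = n)
    errs <- replicate(200, {
      cq <- 35 + true_slope * x + stats::rnorm(n, sd = 0.1)
      fit <- fit_standard_curve(data.frame(log10Input = x, cq = cq))
      abs(fit$efficiency - 1.9)
    })
    mean(errs)
  }, numeric(1))
  expect_true(all(diff(mean_err) < 0))
})

test_that("shifting all log-inputs moves only the intercept", {
  set.seed(53)
  x <- rep(seq(5, 1), each = 2)
  cq <- 35 - x / log10(1.9) + stats::rnorm(length(x), sd = 0.1)
  f1 <- fit_standard_curve(data.frame(log10Input = x, cq = cq))
  f2 <- fit_standard_curve(data.frame(log10Input = x + 3, cq = cq))
  expect_equal(f1$slope, f2$slope, tolerance = 1e-12)
  expect_equal(f1$efficiency, f2$efficiency, tolerance = 1e-12)
  expect_equal(f2$intercept, f1$intercept - 3 * f1$slope, tolerance = 1e-9)
})

test_that("standard points are collected with unit and Cq screening", {
  doc <- standard_doc(seed = 54)
  pts <- standard_points_from_document(doc, "tgt1")
  expect_identical(nrow(pts), 10L)  # 5 dilution steps x 2 replicates
  expect_identical(unique(pts$unit), "copies")
  expect_equal(sort(unique(pts$log10Input)), 1:5)

  mixed <- doc
  mixed$samples[[1]]$quantity$unit <- "ng"
  expect_error(standard_points_from_document(mixed, "tgt1"),
               class = "rdml_unit_mismatch")

  nocq <- doc
  nocq$experiments[[1]]$runs[[1]]$reactions[[1]]$data[[1]]$cq <- NULL
  expect_warning(pts2 <- standard_points_from_document(nocq, "tgt1"),
                 "lacks a Cq")
  expect_identical(nrow(pts2), 9L)
})

test_that("efficiency annotation respects the version gate and round-trips", {
  fit <- suppressWarnings(fit_standard_curve(
    data.frame(log10Input = c(0, -1, -2), cq = c(30, 33.32193, 36.64386))))

  doc12 <- compact_doc(version = "1.2", seed = 55)
  out <- annotate_target_efficiency(doc12, "tgt1", fit)
  expect_equal(out$targets[[1]]$amplificationEfficiency, fit$efficiency)
  expect_equal(out$targets[[1]]$amplificationEfficiencySE, fit$efficiencySE)

  doc11 <- compact_doc(version = "1.1", seed = 55)
  expect_error(annotate_target_efficiency(doc11, "tgt1", fit),
               class = "rdml_element_wrong_version")
  out11 <- annotate_target_efficiency(doc11, "tgt1", fit, include_se = FALSE)
  expect_equal(out11$targets[[1]]$amplificationEfficiency, fit$efficiency)
  expect_null(out11$targets[[1]]$amplificationEfficiencySE)

  # values survive the file round trip
  reread <- read_rdml(write_tmp(out))
  expect_equal(reread$targets[[1]]$amplificationEfficiency, fit$efficiency,
               tolerance = 1e-12)
  expect_equal(reread$targets[[1]]$amplificationEfficiencySE,
               fit$efficiencySE, tolerance = 1e-12)
  expect_error(annotate_target_efficiency(doc12, "missing", fit), "no target")
})
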