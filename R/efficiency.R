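# PCR amplification efficiency from a standard curve.
#
# A dilution series of known inputs gives Cq versus log10(input); ordinary
# least squares yields the slope b (cycles per 10-fold dilution) and the
# efficiency E = 10^(-1/b), the fold-increase of product per cycle
# (perfect doubling: b = -3.3219, E = 2). The standard error of E follows
# by first-order (delta-method) propagation of the slope's standard error:
#   SE(E) = E * ln(10) * SE(b) / b^2.
# Alternatively, when per-curve efficiency estimates from amplification-
# curve analysis are available, E is their mean and SE(E) the SEM.

#' Fit a standard curve and estimate amplification efficiency
#'
#' Ordinary least-squares fit of Cq on log10 input quantity. Replicate
#' standards enter as independent observations (no pre-averaging), which
#' preserves the degrees of freedom behind the standard error.
#'
#' @param points Data frame with columns `log10Input` and `cq` (one row per
#'   standard reaction), e.g. from [standard_points_from_document()].
#' @return An object of class `standard_curve_fit` with fields `slope`
#'   (cycles per log10 unit), `intercept` (cycles), `rSquared`,
#'   `efficiency` and `efficiencySE` (fold-change per cycle), `nPoints`,
#'   and `method = "standard-curve"`.
#' @export
#' @examples
#' pts <- data.frame(log10Input = c(0, -1, -2),
#'                   cq = c(30, 33.32193, 36.64386))
#' fit_standard_curve(pts)  # perfect doubling: E = 2
fit_standard_curve <- function(points) {
  stopifnot(is.data.frame(points),
            all(c("log10Input", "cq") %in% names(points)))
  points <- points[is.finite(points$log10Input) & is.finite(points$cq), ,
                   drop = FALSE]
  if (nrow(points) < 3 || length(unique(points$log10Input)) < 2) {
    rdml_abort(
      "standard-curve fit needs >= 3 points with >= 2 distinct log10 inputs",
      "rdml_insufficient_data")
  }
  fit <- stats::lm(cq ~ log10Input, data = points)
  # summary.lm warns on noise-free (numerically perfect) fits; harmless here
  smry <- suppressWarnings(summary(fit))
  coefs <- smry$coefficients
  slope <- coefs["log10Input", "Estimate"]
  slope_se <- coefs["log10Input", "Std. Error"]
  intercept <- coefs["(Intercept)", "Estimate"]
  r2 <- smry$r.squared
  if (slope >= 0) {
    warning("standard-curve slope is non-negative; the efficiency estimate is outside the meaningful range",
            call. = FALSE)
  }
  efficiency <- 10^(-1 / slope)
  efficiency_se <- efficiency * log(10) * slope_se / slope^2
  structure(list(slope = slope, intercept = intercept, rSquared = r2,
                 efficiency = efficiency, efficiencySE = abs(efficiency_se),
                 nPoints = nrow(points), method = "standard-curve"),
            class = "standard_curve_fit")
}

#' Summarise per-curve efficiency estimates
#'
#' When individual amplification-curve analysis (e.g. window-of-linearity
#' methods) supplies one efficiency value per reaction, the target-level
#' efficiency is their arithmetic mean and its uncertainty the standard
#' error of that mean.
#'
#' @param values Numeric vector of per-curve efficiency values
#'   (fold-change per cycle), at least two.
#' @return A `standard_curve_fit` with `method = "per-curve-sem"`; the
#'   slope, intercept and rSquared fields are `NA`.
#' @export
#' @examples
#' efficiency_from_per_curve(c(1.9, 2.0, 2.1))
efficiency_from_per_curve <- function(values) {
  values <- as.numeric(values)
  values <- values[is.finite(values)]
  if (length(values) < 2) {
    rdml_abort("per-curve summary needs >= 2 efficiency values",
               "rdml_insufficient_data")
  }
  structure(list(slope = NA_real_, intercept = NA_real_, rSquared = NA_real_,
                 efficiency = mean(values),
                 efficiencySE = stats::sd(values) / sqrt(length(values)),
                 nPoints = length(values), method = "per-curve-sem"),
            class = "standard_curve_fit")
}

#' @export
print.standard_curve_fit <- function(x, ...) {
  cat(sprintf("Amplification efficiency (%s, n = %d)\n", x$method, x$nPoints))
  if (x$method == "standard-curve") {
    cat(sprintf("  slope: %.5f cycles/log10  intercept: %.4f  r^2: %.5f\n",
                x$slope, x$intercept, x$rSquared))
  }
  cat(sprintf("  E = %.4f +/- %.4f (fold per cycle)\n",
              x$efficiency, x$efficiencySE))
  invisible(x)
}

#' Collect standard-curve points for a target from a document
#'
#' Walks every reaction measuring the target whose sample is of type
#' `standard` and carries a known input quantity, and returns one
#' (log10 input, Cq) point per such reaction. All standards must share one
#' quantity unit; standards with zero or negative quantity or without an
#' observed Cq are excluded with a warning.
#'
#' @param doc An [rdml_document()].
#' @param target Target id.
#' @return Data frame with columns `log10Input`, `cq`, `position`,
#'   `sample`, `unit`, suitable for [fit_standard_curve()].
#' @export
standard_points_from_document <- function(doc, target) {
  rows <- list()
  units <- character()
  for (e in doc$experiments) for (run in e$runs) for (re in run$reactions) {
    s <- find_by_id(doc$samples, re$sampleRef)
    if (is.null(s) || !identical(s$sampleType, "standard") ||
        is.null(s$quantity)) {
      next
    }
    for (d in re$data) {
      if (!identical(d$targetRef, target)) next
      if (is.null(d$cq)) {
        warning(sprintf(
          "standard '%s' at position %d lacks a Cq value; excluded",
          s$id, re$position), call. = FALSE)
        next
      }
      if (s$quantity$value <= 0) {
        warning(sprintf(
          "standard '%s' has non-positive quantity %g; excluded",
          s$id, s$quantity$value), call. = FALSE)
        next
      }
      units <- c(units, s$quantity$unit)
      rows[[length(rows) + 1]] <- data.frame(
        log10Input = log10(s$quantity$value), cq = d$cq,
        position = re$position, sample = s$id, unit = s$quantity$unit,
        stringsAsFactors = FALSE)
    }
  }
  if (length(unique(units)) > 1) {
    rdml_abort(
      sprintf("standards mix quantity units: %s",
              paste(sort(unique(units)), collapse = ", ")),
      "rdml_unit_mismatch")
  }
  if (length(rows) == 0) {
    return(data.frame(log10Input = numeric(), cq = numeric(),
                      position = integer(), sample = character(),
                      unit = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' Write an efficiency estimate into a document's target
#'
#' Sets `amplificationEfficiency` (and, for version-1.2 documents, its
#' standard error `amplificationEfficiencySE`) on the target. All other
#' content is untouched; a new document is returned.
#'
#' @param doc An [rdml_document()].
#' @param target Target id.
#' @param fit A `standard_curve_fit`.
#' @param include_se Whether to write the standard error. Defaults to
#'   `TRUE` when the fit carries one; must be `FALSE` for pre-1.2
#'   documents, which have no element for it.
#' @return The annotated document.
#' @export
annotate_target_efficiency <- function(doc, target, fit,
                                       include_se = !is.null(fit$efficiencySE) &&
                                         !is.na(fit$efficiencySE)) {
  stopifnot(inherits(doc, "rdml_document"),
            inherits(fit, "standard_curve_fit"))
  idx <- match(target, ids_of(doc$targets))
  if (is.na(idx)) {
    stop(sprintf("no target with id '%s' in document", target), call. = FALSE)
  }
  if (include_se && doc$version != "1.2") {
    rdml_abort(
      sprintf("amplificationEfficiencySE requires version 1.2 (document is %s); set include_se = FALSE or migrate first",
              doc$version),
      "rdml_element_wrong_version")
  }
  doc$targets[[idx]]$amplificationEfficiency <- fit$efficiency
  if (include_se) {
    doc$targets[[idx]]$amplificationEfficiencySE <- fit$efficiencySE
  }
  doc
}
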