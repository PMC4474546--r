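# Deterministic generator of synthetic RDML documents.
#
# Produces valid documents of all three format versions containing a
# dilution series with a known true amplification efficiency, simulated
# sigmoid amplification curves, melt curves, unknowns and a no-template
# control, so every other module is testable without external files.
#
# Amplification model: F(c) = Fb + Fmax / (1 + exp(-(c - cMid) / k)) with
# Fb = 0.05, Fmax = 1, k = 1.2; cMid is placed so the crossing of the
# quantification threshold Fthr = 0.1 falls exactly at the reaction's true
# Cq. True Cq values follow the dilution model
#   trueCq(input) = cqAtUnitInput - log10(input) / log10(trueEfficiency),
# optionally perturbed by Gaussian Cq noise; the recorded Cq is the
# analytic threshold crossing of the (continuous) curve, i.e. exactly that
# perturbed true Cq, while fluorescence noise perturbs only the stored
# curve points. Melt model: decreasing sigmoid of width 1.5 degrees C
# centred at the product's melting temperature.

amp_baseline <- 0.05
amp_fmax <- 1.0
amp_k <- 1.2
amp_threshold <- 0.1

#' Simulate a sigmoid amplification curve
#'
#' @param trueCq Cycle at which the noise-free curve crosses the
#'   quantification threshold (0.1 fluorescence units); must lie inside
#'   `(0, cycles)`.
#' @param cycles Number of cycles measured.
#' @param noiseSd Standard deviation of additive Gaussian fluorescence
#'   noise (fluorescence units).
#' @return Numeric vector of fluorescence readings at cycles `1..cycles`.
#' @export
#' @examples
#' f <- simulate_amplification(20, 40)
#' threshold_cq(f)  # ~20
simulate_amplification <- function(trueCq, cycles, noiseSd = 0) {
  stopifnot(trueCq > 0, trueCq < cycles)
  c_mid <- trueCq + amp_k * log(amp_fmax / (amp_threshold - amp_baseline) - 1)
  cyc <- seq_len(cycles)
  f <- amp_baseline + amp_fmax / (1 + exp(-(cyc - c_mid) / amp_k))
  if (noiseSd > 0) f <- f + stats::rnorm(cycles, sd = noiseSd)
  f
}

#' Quantification cycle by threshold crossing
#'
#' Linear interpolation of the first upward crossing of the quantification
#' threshold in a fluorescence series.
#'
#' @param fluorescence Numeric vector, one reading per cycle (cycle 1
#'   first).
#' @param threshold Fluorescence level defining Cq.
#' @return The fractional crossing cycle, or `NA` if the series never
#'   crosses the threshold.
#' @export
threshold_cq <- function(fluorescence, threshold = amp_threshold) {
  above <- fluorescence >= threshold
  if (!any(above)) return(NA_real_)
  i <- which(above)[1]
  if (i == 1) return(1)
  (i - 1) + (threshold - fluorescence[i - 1]) /
    (fluorescence[i] - fluorescence[i - 1])
}

#' Simulate a melt curve
#'
#' Decreasing sigmoid of fluorescence versus temperature centred at the
#' product's melting temperature (width 1.5 degrees C); in the noise-free
#' case the peak of the negative first difference falls within one step of
#' `tm`.
#'
#' @param tm Melting temperature in degrees C, inside `range`.
#' @param range Temperature window scanned.
#' @param step Scan step in degrees C.
#' @param noiseSd Additive Gaussian noise SD (fluorescence units).
#' @return Data frame with columns `temperature`, `fluorescence`.
#' @export
simulate_melt <- function(tm, range = c(60, 95), step = 0.5, noiseSd = 0) {
  stopifnot(tm > range[1], tm < range[2], step > 0)
  temps <- seq(range[1], range[2], by = step)
  f <- amp_baseline + amp_fmax / (1 + exp((temps - tm) / 1.5))
  if (noiseSd > 0) f <- f + stats::rnorm(length(f), sd = noiseSd)
  data.frame(temperature = temps, fluorescence = f)
}

#' Melting temperature from a melt curve
#'
#' The temperature at the peak of the negative first difference of
#' fluorescence (midpoint of the steepest falling step).
#'
#' @param points Data frame with `temperature` and `fluorescence` columns.
#' @return Estimated Tm in degrees C.
#' @export
melt_tm <- function(points) {
  d <- -diff(points$fluorescence)
  i <- which.max(d)
  (points$temperature[i] + points$temperature[i + 1]) / 2
}

#' Specify a synthetic RDML document
#'
#' Collects the parameters of one simulated qPCR run: plate geometry,
#' targets with their true amplification efficiencies, the dilution series
#' of standards, numbers of unknowns, cycle count, noise levels and the
#' random seed. Defaults describe a routine single-target SYBR assay: a
#' five-step 10-fold dilution series from 1e5 copies in duplicate, one
#' unknown, one no-template control, 40 cycles.
#'
#' @param version Target format version.
#' @param plate A [pcr_format()], or for version 1.0 a predefined
#'   plate-type token; defaults to `"96-well"` / 8x12.
#' @param targets List of `list(id, trueEfficiency, cqAtUnitInput, tm)`:
#'   efficiency as fold-change per cycle in `(1, 2]`, the Cq expected at
#'   unit input, and the product melting temperature.
#' @param dilutionSeries `list(topLog10Input, steps, foldPerStep,
#'   replicates)`.
#' @param unknowns Number of unknown samples.
#' @param cycles Number of amplification cycles (>= 10).
#' @param noiseSd Fluorescence noise SD (fluorescence units).
#' @param cqNoiseSd Cq noise SD (cycles), applied to the true Cq of each
#'   standard/unknown reaction.
#' @param seed Integer seed; generation is fully deterministic given the
#'   spec.
#' @return A list of class `synthetic_run_spec`.
#' @export
synthetic_run_spec <- function(version = "1.2", plate = NULL,
                               targets = list(list(id = "tgt1",
                                                   trueEfficiency = 1.9,
                                                   cqAtUnitInput = 35,
                                                   tm = 85)),
                               dilutionSeries = list(topLog10Input = 5,
                                                     steps = 5,
                                                     foldPerStep = 10,
                                                     replicates = 2),
                               unknowns = 1, cycles = 40,
                               noiseSd = 0.002, cqNoiseSd = 0, seed = 1) {
  check_version(version)
  if (is.null(plate)) {
    plate <- if (version == "1.0") "96-well" else pcr_format(8, 12)
  }
  bad <- function(msg) rdml_abort(msg, "rdml_invalid_spec")
  for (t in targets) {
    if (is.null(t$id) || !nzchar(t$id)) bad("target id must be non-empty")
    if (t$trueEfficiency <= 1 || t$trueEfficiency > 2) {
      bad("trueEfficiency must lie in (1, 2]")
    }
  }
  ds <- dilutionSeries
  if (is.null(ds$steps) || ds$steps < 1) bad("dilution series needs steps >= 1")
  if (is.null(ds$foldPerStep) || ds$foldPerStep <= 1) {
    bad("foldPerStep must exceed 1")
  }
  if (is.null(ds$replicates) || ds$replicates < 1) {
    bad("replicates must be >= 1")
  }
  if (cycles < 10) bad("cycles must be >= 10")
  if (unknowns < 0) bad("unknowns must be >= 0")
  structure(list(version = version, plate = plate, targets = targets,
                 dilutionSeries = ds, unknowns = unknowns, cycles = cycles,
                 noiseSd = noiseSd, cqNoiseSd = cqNoiseSd,
                 seed = as.integer(seed)),
            class = "synthetic_run_spec")
}

with_preserved_rng <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())))
  }
  set.seed(seed)
  force(expr)
}

#' Generate a synthetic RDML document
#'
#' Builds a complete, valid document from a [synthetic_run_spec()]: one
#' experimenter, documentation, registered dye (version >= 1.1), samples
#' (standards carrying their known quantities, unknowns, one no-template
#' control), targets, a cycling program and one experiment with one run.
#' Standards' reactions follow the dilution Cq model with simulated
#' amplification and melt curves; the no-template control carries a flat
#' noise-only curve and no Cq. Generation is fully deterministic under the
#' spec's seed.
#'
#' @param spec A [synthetic_run_spec()].
#' @return An [rdml_document()] that validates without issues.
#' @export
#' @examples
#' doc <- generate_rdml_document(synthetic_run_spec(seed = 42))
#' validate_rdml(doc)$valid
generate_rdml_document <- function(spec) {
  stopifnot(inherits(spec, "synthetic_run_spec"))
  with_preserved_rng(spec$seed, generate_rdml_document_impl(spec))
}

generate_rdml_document_impl <- function(spec) {
  version <- spec$version
  pre12 <- version != "1.2"
  doc <- rdml_document(version, dateMade = "2014-11-01T12:00:00")
  doc$experimenters <- list(rdml_experimenter(
    "exp1", firstName = "Ada", lastName = "Benchworth",
    email = "ada.benchworth@example.org"))
  doc$documentations <- list(rdml_documentation(
    "doc1", text = "synthetic dilution-series run generated by rdmlkit"))

  if (!pre12 || version == "1.1") {
    doc$dyes <- list(rdml_dye("SYBR", description = "SYBR Green I"))
  }
  dye_ref <- if (version == "1.0") NULL else "SYBR"

  ds <- spec$dilutionSeries
  log10_inputs <- ds$topLog10Input - (seq_len(ds$steps) - 1) *
    log10(ds$foldPerStep)

  samples <- list()
  for (i in seq_len(ds$steps)) {
    samples[[length(samples) + 1]] <- rdml_sample(
      sprintf("std_%02d", i),
      description = sprintf("standard, dilution step %d", i),
      sampleType = "standard",
      quantity = rdml_quantity(10^log10_inputs[i], "copies"),
      material = if (pre12) "DNA" else NULL)
  }
  for (i in seq_len(spec$unknowns)) {
    s <- rdml_sample(sprintf("unk_%02d", i),
                     description = "unknown sample",
                     sampleType = "unknown")
    if (pre12) {
      s$legacyQuality <- list(dna = "intact, A260/A280 1.9", rna = NULL)
    } else {
      s$annotations <- list(
        rdml_annotation("treatment", if (i %% 2 == 1) "control" else "treated"),
        rdml_annotation("dna quality", "intact, A260/A280 1.9"))
    }
    samples[[length(samples) + 1]] <- s
  }
  samples[[length(samples) + 1]] <- rdml_sample(
    "ntc", description = "no-template control",
    sampleType = "no-template-control")
  doc$samples <- samples

  doc$targets <- lapply(spec$targets, function(t) {
    rdml_target(t$id, description = "synthetic assay",
                targetType = "target-of-interest", dyeRef = dye_ref,
                sequences = list(forwardPrimer = "ACGTACGTACGTACGTACGT",
                                 reversePrimer = "TGCATGCATGCATGCATGCA"))
  })

  doc$thermalCyclingConditions <- list(rdml_cycling_program(
    "cyc1", description = "2-step qPCR protocol",
    steps = list(
      list(temperature = 95, duration = 600, acquire = FALSE),
      list(temperature = 95, duration = 15, acquire = FALSE),
      list(temperature = 60, duration = 60, acquire = TRUE))))

  plate <- spec$plate
  plate_type <- NULL
  if (is.character(plate)) {
    plate_type <- plate
    plate <- plate_type_to_format(plate_type)
  }

  unk_log10 <- stats::runif(
    spec$unknowns,
    min = min(log10_inputs), max = max(log10_inputs))

  reactions <- list()
  pos <- 0L
  for (t in spec$targets) {
    true_cq_of <- function(l10) t$cqAtUnitInput - l10 / log10(t$trueEfficiency)
    add_reaction <- function(sample_id, true_cq, is_ntc = FALSE) {
      pos <<- pos + 1L
      if (is_ntc) {
        fluor <- amp_baseline + (if (spec$noiseSd > 0) {
          stats::rnorm(spec$cycles, sd = spec$noiseSd)
        } else {
          numeric(spec$cycles)
        })
        d <- rdml_reaction_data(
          t$id, cq = NULL, baseline = amp_baseline,
          quantificationThreshold = amp_threshold,
          amplificationPoints = data.frame(cycle = seq_len(spec$cycles),
                                           fluorescence = fluor))
      } else {
        cq <- true_cq + (if (spec$cqNoiseSd > 0) {
          stats::rnorm(1, sd = spec$cqNoiseSd)
        } else {
          0
        })
        fluor <- simulate_amplification(cq, spec$cycles, spec$noiseSd)
        d <- rdml_reaction_data(
          t$id, cq = cq, baseline = amp_baseline,
          quantificationThreshold = amp_threshold,
          amplificationPoints = data.frame(cycle = seq_len(spec$cycles),
                                           fluorescence = fluor),
          meltingPoints = simulate_melt(t$tm %||% 85,
                                        noiseSd = spec$noiseSd))
      }
      reactions[[length(reactions) + 1]] <<- rdml_reaction(
        pos, sample_id, data = list(d))
    }
    for (i in seq_len(ds$steps)) {
      for (rep in seq_len(ds$replicates)) {
        add_reaction(sprintf("std_%02d", i), true_cq_of(log10_inputs[i]))
      }
    }
    for (i in seq_len(spec$unknowns)) {
      add_reaction(sprintf("unk_%02d", i), true_cq_of(unk_log10[i]))
    }
    add_reaction("ntc", NA, is_ntc = TRUE)
  }
  if (pos > plate$rows * plate$columns) {
    rdml_abort(sprintf("spec places %d reactions on a %d-well plate",
                       pos, plate$rows * plate$columns),
               "rdml_invalid_spec")
  }

  doc$experiments <- list(rdml_experiment(
    "exp_run", description = "synthetic experiment",
    runs = list(rdml_run("run1", description = "synthetic run",
                         pcrFormat = plate, plateType = plate_type,
                         reactions = reactions))))
  doc
}
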