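# In-memory model of an RDML document tree.
#
# Every node is a named list with a class tag; optional fields are NULL.
# Each node carries an `extra` character vector holding serialized foreign
# XML elements encountered on read, so third-party extensions survive a
# read/write round trip untouched.

#' Supported RDML format versions
#'
#' @return Character vector of the format versions this package reads,
#'   writes, validates and migrates, oldest first.
#' @export
#' @examples
#' rdml_versions()
rdml_versions <- function() c("1.0", "1.1", "1.2")

rdml_abort <- function(message, class) {
  stop(errorCondition(message, class = c(class, "rdml_error", "error")))
}

check_version <- function(version) {
  if (!is.character(version) || length(version) != 1 ||
      !version %in% rdml_versions()) {
    rdml_abort(
      sprintf("unsupported RDML version %s (supported: %s)",
              deparse(version), paste(rdml_versions(), collapse = ", ")),
      "rdml_unsupported_version")
  }
  version
}

check_id <- function(id, what) {
  if (!is.character(id) || length(id) != 1 || is.na(id) || !nzchar(id)) {
    stop(sprintf("%s id must be a non-empty string", what), call. = FALSE)
  }
  id
}

chr1_or_null <- function(x) {
  if (is.null(x)) return(NULL)
  as.character(x)[1]
}

num1_or_null <- function(x) {
  if (is.null(x) || (length(x) == 1 && is.na(x))) return(NULL)
  as.numeric(x)[1]
}

#' Create an empty RDML document
#'
#' Builds a structurally valid document of the requested format version with
#' all top-level element lists empty. Top-level lists follow the RDML tree:
#' experimenters, documentations, dyes, samples, targets, thermal cycling
#' conditions and experiments.
#'
#' @param version Format version, one of `"1.0"`, `"1.1"`, `"1.2"`.
#' @param dateMade,dateUpdated Optional ISO-8601 timestamps. Never filled in
#'   or modified automatically.
#' @return An object of class `rdml_document`.
#' @export
#' @examples
#' doc <- rdml_document("1.2")
#' doc$version
rdml_document <- function(version, dateMade = NULL, dateUpdated = NULL) {
  structure(list(
    version = check_version(version),
    dateMade = chr1_or_null(dateMade),
    dateUpdated = chr1_or_null(dateUpdated),
    experimenters = list(),
    documentations = list(),
    dyes = list(),
    samples = list(),
    targets = list(),
    thermalCyclingConditions = list(),
    experiments = list(),
    extra = character()
  ), class = "rdml_document")
}

#' @export
print.rdml_document <- function(x, ...) {
  cat(sprintf("<rdml_document version %s>\n", x$version))
  n_runs <- sum(vapply(x$experiments, function(e) length(e$runs), integer(1)))
  n_react <- sum(unlist(lapply(x$experiments, function(e)
    vapply(e$runs, function(r) length(r$reactions), integer(1)))), 0L)
  cat(sprintf(
    "  experimenters: %d  dyes: %d  samples: %d  targets: %d\n",
    length(x$experimenters), length(x$dyes), length(x$samples),
    length(x$targets)))
  cat(sprintf("  experiments: %d  runs: %d  reactions: %d\n",
              length(x$experiments), n_runs, n_react))
  invisible(x)
}

#' RDML element constructors
#'
#' Constructors for the elements held in an [rdml_document()]: the people,
#' free-text documentation, fluorescent dyes, biological samples, PCR
#' targets (assays), thermal cycling programs and experiments that make up
#' an RDML tree. All optional fields default to `NULL`.
#'
#' @param id Unique identifier within the element's top-level list.
#' @param firstName,lastName,email Optional experimenter details.
#' @param text Free documentation text.
#' @param description Optional free-text description.
#' @param sampleType One of `"unknown"`, `"standard"`,
#'   `"no-template-control"`, `"no-amplification-control"`,
#'   `"positive-control"`. Unrecognised tokens read from third-party files
#'   are kept verbatim (the validator flags them as warnings).
#' @param annotations List of [rdml_annotation()] (format version 1.2 only).
#' @param quantity Optional [rdml_quantity()] with the known input amount of
#'   a standard.
#' @param material Optional `"DNA"` or `"RNA"`: which legacy slot housed the
#'   quantity in a pre-1.2 file. Dropped when a document is upgraded to 1.2,
#'   where a single unified quantity element exists.
#' @param legacyQuality Optional `list(dna = , rna = )` of free-text nucleic
#'   acid quality descriptions used by pre-1.2 files; version 1.2 carries
#'   the same information as annotations.
#' @param targetType `"target-of-interest"` or `"reference"`.
#' @param dyeRef Identifier of a registered dye. Mandatory from version 1.1
#'   on for targets used in reaction data.
#' @param sequences Optional named list with any of `forwardPrimer`,
#'   `reversePrimer`, `probe`, `amplicon`.
#' @param amplificationEfficiency Amplification efficiency as fold-change of
#'   product per cycle (perfect doubling = 2.0). Never rescaled on read.
#' @param amplificationEfficiencySE Standard error of the efficiency, same
#'   scale (format version 1.2 only).
#' @param steps Ordered list of cycling steps, each
#'   `list(temperature = , duration = , acquire = )` (degrees Celsius,
#'   seconds, logical).
#' @param runs List of [rdml_run()].
#' @param property,value Annotation property/value strings.
#' @param unit Unit of a quantity, e.g. `"copies"` or `"ng"`.
#' @return The respective element object.
#' @name rdml_elements
NULL

#' @rdname rdml_elements
#' @export
rdml_experimenter <- function(id, firstName = NULL, lastName = NULL,
                              email = NULL) {
  structure(list(
    id = check_id(id, "experimenter"),
    firstName = chr1_or_null(firstName),
    lastName = chr1_or_null(lastName),
    email = chr1_or_null(email),
    extra = character()
  ), class = "rdml_experimenter")
}

#' @rdname rdml_elements
#' @export
rdml_documentation <- function(id, text = NULL) {
  structure(list(
    id = check_id(id, "documentation"),
    text = chr1_or_null(text),
    extra = character()
  ), class = "rdml_documentation")
}

#' @rdname rdml_elements
#' @export
rdml_dye <- function(id, description = NULL) {
  structure(list(
    id = check_id(id, "dye"),
    description = chr1_or_null(description),
    extra = character()
  ), class = "rdml_dye")
}

#' @rdname rdml_elements
#' @export
rdml_annotation <- function(property, value) {
  if (!nzchar(property)) stop("annotation property must be non-empty")
  structure(list(
    property = as.character(property)[1],
    value = as.character(value)[1],
    extra = character()
  ), class = "rdml_annotation")
}

#' @rdname rdml_elements
#' @export
rdml_quantity <- function(value, unit) {
  value <- as.numeric(value)[1]
  if (is.na(value) || value < 0) stop("quantity value must be >= 0")
  structure(list(
    value = value,
    unit = as.character(unit)[1],
    extra = character()
  ), class = "rdml_quantity")
}

sample_types <- c("unknown", "standard", "no-template-control",
                  "no-amplification-control", "positive-control")
sample_type_tokens <- c(unknown = "unkn", standard = "std",
                        `no-template-control` = "ntc",
                        `no-amplification-control` = "nac",
                        `positive-control` = "pos")
target_types <- c("target-of-interest", "reference")
target_type_tokens <- c(`target-of-interest` = "toi", reference = "ref")

#' @rdname rdml_elements
#' @export
rdml_sample <- function(id, description = NULL, sampleType = "unknown",
                        annotations = list(), quantity = NULL,
                        material = NULL, legacyQuality = NULL) {
  structure(list(
    id = check_id(id, "sample"),
    description = chr1_or_null(description),
    sampleType = as.character(sampleType)[1],
    annotations = annotations,
    quantity = quantity,
    material = chr1_or_null(material),
    legacyQuality = legacyQuality,
    extra = character()
  ), class = "rdml_sample")
}

#' @rdname rdml_elements
#' @export
rdml_target <- function(id, description = NULL,
                        targetType = "target-of-interest", dyeRef = NULL,
                        sequences = list(), amplificationEfficiency = NULL,
                        amplificationEfficiencySE = NULL) {
  seq_fields <- c("forwardPrimer", "reversePrimer", "probe", "amplicon")
  seqs <- stats::setNames(lapply(seq_fields, function(f)
    chr1_or_null(sequences[[f]])), seq_fields)
  structure(list(
    id = check_id(id, "target"),
    description = chr1_or_null(description),
    targetType = as.character(targetType)[1],
    dyeRef = chr1_or_null(dyeRef),
    sequences = seqs,
    amplificationEfficiency = num1_or_null(amplificationEfficiency),
    amplificationEfficiencySE = num1_or_null(amplificationEfficiencySE),
    extra = character()
  ), class = "rdml_target")
}

#' @rdname rdml_elements
#' @export
rdml_cycling_program <- function(id, description = NULL, steps = list()) {
  for (s in steps) {
    if (is.null(s$duration) || s$duration <= 0) {
      stop("cycling step durations must be > 0")
    }
  }
  structure(list(
    id = check_id(id, "thermalCyclingConditions"),
    description = chr1_or_null(description),
    steps = lapply(steps, function(s) list(
      temperature = as.numeric(s$temperature)[1],
      duration = as.numeric(s$duration)[1],
      acquire = isTRUE(s$acquire))),
    extra = character()
  ), class = "rdml_cycling_program")
}

#' @rdname rdml_elements
#' @export
rdml_experiment <- function(id, description = NULL, runs = list()) {
  structure(list(
    id = check_id(id, "experiment"),
    description = chr1_or_null(description),
    runs = runs,
    extra = character()
  ), class = "rdml_experiment")
}

#' Plate geometry and runs
#'
#' `pcr_format()` describes the two-dimensional reaction grid that replaced
#' the predefined plate types of RDML 1.0: the number of available reactions
#' in rows and columns, plus the labelling scheme for each axis.
#' `rdml_run()` holds one instrument run on such a plate.
#'
#' @param rows,columns Positive grid dimensions.
#' @param rowLabelScheme `"letters"` (A, B, ..., Z, AA, ...) or `"numbers"`.
#' @param columnLabelScheme Only `"numbers"` is defined.
#' @param id Run identifier, unique within its experiment.
#' @param description Optional free text.
#' @param pcrFormat A `pcr_format`.
#' @param plateType For version-1.0 documents: the predefined plate-type
#'   token the file used (kept so the file can be written back unchanged).
#' @param reactions List of [rdml_reaction()].
#' @return A `pcr_format` or `rdml_run` object.
#' @export
#' @examples
#' pcr_format(8, 12)  # a 96-well plate
pcr_format <- function(rows, columns, rowLabelScheme = "letters",
                       columnLabelScheme = "numbers") {
  rows <- as.integer(rows)
  columns <- as.integer(columns)
  if (is.na(rows) || rows < 1 || is.na(columns) || columns < 1) {
    stop("plate format needs rows >= 1 and columns >= 1")
  }
  structure(list(
    rows = rows, columns = columns,
    rowLabelScheme = match.arg(rowLabelScheme, c("letters", "numbers")),
    columnLabelScheme = match.arg(columnLabelScheme, "numbers"),
    extra = character()
  ), class = "pcr_format")
}

#' @rdname pcr_format
#' @export
rdml_run <- function(id, description = NULL, pcrFormat, plateType = NULL,
                     reactions = list()) {
  structure(list(
    id = check_id(id, "run"),
    description = chr1_or_null(description),
    pcrFormat = pcrFormat,
    plateType = chr1_or_null(plateType),
    reactions = reactions,
    extra = character()
  ), class = "rdml_run")
}

#' Reactions and per-target reaction data
#'
#' A reaction is one well of a run: it references a sample by id and holds
#' one data block per measured target, with the observed quantification
#' cycle (Cq), baseline, quantification threshold and the raw fluorescence
#' series.
#'
#' @param position 1-based linear well position, row-major on the run's
#'   plate format (version 1.0 files store a well label instead; it is
#'   converted on read).
#' @param sampleRef Identifier of the sample in the well.
#' @param data List of `rdml_reaction_data` blocks, one per target.
#' @param targetRef Identifier of the measured target.
#' @param cq Observed quantification cycle, or `NULL` (e.g. no-template
#'   controls).
#' @param baseline,quantificationThreshold Fluorescence units, optional.
#' @param amplificationPoints `data.frame(cycle, fluorescence)` with cycles
#'   strictly increasing.
#' @param meltingPoints `data.frame(temperature, fluorescence)` with
#'   temperatures (degrees Celsius) strictly increasing.
#' @return An `rdml_reaction` or `rdml_reaction_data` object.
#' @export
rdml_reaction <- function(position, sampleRef, data = list()) {
  position <- as.integer(position)
  if (is.na(position) || position < 1) stop("reaction position must be >= 1")
  structure(list(
    position = position,
    sampleRef = check_id(sampleRef, "reaction sampleRef"),
    data = data,
    extra = character()
  ), class = "rdml_reaction")
}

empty_points <- function(cols) {
  stats::setNames(
    data.frame(numeric(0), numeric(0)), cols)
}

#' @rdname rdml_reaction
#' @export
rdml_reaction_data <- function(targetRef, cq = NULL, baseline = NULL,
                               quantificationThreshold = NULL,
                               amplificationPoints = NULL,
                               meltingPoints = NULL) {
  if (is.null(amplificationPoints)) {
    amplificationPoints <- empty_points(c("cycle", "fluorescence"))
  }
  if (is.null(meltingPoints)) {
    meltingPoints <- empty_points(c("temperature", "fluorescence"))
  }
  structure(list(
    targetRef = check_id(targetRef, "reaction data targetRef"),
    cq = num1_or_null(cq),
    baseline = num1_or_null(baseline),
    quantificationThreshold = num1_or_null(quantificationThreshold),
    amplificationPoints = amplificationPoints,
    meltingPoints = meltingPoints,
    extra = character()
  ), class = "rdml_reaction_data")
}

# ---- semantic equality ------------------------------------------------------

sort_by_key <- function(items, key) {
  if (length(items) < 2) return(items)
  keys <- vapply(items, key, character(1))
  items[order(keys, method = "radix")]
}

canon_node <- function(x) {
  if (inherits(x, "rdml_document")) {
    for (f in c("experimenters", "documentations", "dyes", "samples",
                "targets", "thermalCyclingConditions", "experiments")) {
      x[[f]] <- sort_by_key(lapply(x[[f]], canon_node),
                            function(e) e$id)
    }
  } else if (inherits(x, "rdml_experiment")) {
    x$runs <- sort_by_key(lapply(x$runs, canon_node), function(r) r$id)
  } else if (inherits(x, "rdml_run")) {
    x$reactions <- lapply(x$reactions, canon_node)
    if (length(x$reactions) > 1) {
      x$reactions <- x$reactions[order(vapply(x$reactions,
                                              function(r) r$position,
                                              integer(1)))]
    }
  } else if (inherits(x, "rdml_reaction")) {
    x$data <- sort_by_key(lapply(x$data, canon_node),
                          function(d) d$targetRef)
  } else if (inherits(x, "rdml_sample")) {
    x$annotations <- sort_by_key(x$annotations,
                                 function(a) paste0(a$property, "\r", a$value))
  }
  if (!is.null(x$extra)) x$extra <- sort(x$extra, method = "radix")
  x
}

values_equal <- function(a, b, tol) {
  if (is.null(a) && is.null(b)) return(TRUE)
  if (is.null(a) || is.null(b)) return(FALSE)
  if (is.numeric(a) && is.numeric(b)) {
    if (length(a) != length(b)) return(FALSE)
    if (length(a) == 0) return(TRUE)
    na_a <- is.na(a); na_b <- is.na(b)
    if (!identical(na_a, na_b)) return(FALSE)
    ok <- abs(a - b) <= tol * pmax(1, abs(a), abs(b))
    return(all(ok | na_a))
  }
  if (is.data.frame(a) && is.data.frame(b)) {
    if (nrow(a) != nrow(b) || !identical(names(a), names(b))) return(FALSE)
    return(all(vapply(names(a), function(nm)
      values_equal(a[[nm]], b[[nm]], tol), logical(1))))
  }
  if (is.list(a) && is.list(b)) {
    nms <- union(names(a), names(b))
    if (is.null(nms) || any(!nzchar(nms))) {
      if (length(a) != length(b)) return(FALSE)
      return(all(vapply(seq_along(a), function(i)
        values_equal(a[[i]], b[[i]], tol), logical(1))))
    }
    return(all(vapply(nms, function(nm)
      values_equal(a[[nm]], b[[nm]], tol), logical(1))))
  }
  isTRUE(all.equal(a, b, check.attributes = FALSE))
}

#' Semantic equality of two RDML documents
#'
#' Compares the content of two documents ignoring the order of elements in
#' unordered lists (top-level lists, runs, reaction data blocks, sample
#' annotations) and comparing numeric fields to a relative tolerance.
#' This is the round-trip oracle: a document written to disk and read back
#' must compare equal to the original.
#'
#' @param a,b Documents (or any two model nodes of the same kind).
#' @param tol Relative numeric tolerance.
#' @return `TRUE` or `FALSE`.
#' @export
rdml_equal <- function(a, b, tol = 1e-9) {
  values_equal(canon_node(a), canon_node(b), tol)
}

# ---- lookup helpers ---------------------------------------------------------

ids_of <- function(items) vapply(items, function(x) x$id, character(1))

find_by_id <- function(items, id) {
  for (x in items) if (identical(x$id, id)) return(x)
  NULL
}

first_run <- function(doc) {
  for (e in doc$experiments) for (r in e$runs) return(r)
  NULL
}

resolve_run <- function(doc, run = NULL) {
  if (is.null(run)) {
    r <- first_run(doc)
    if (is.null(r)) stop("document contains no runs")
    return(r)
  }
  if (inherits(run, "rdml_run")) return(run)
  for (e in doc$experiments) {
    r <- find_by_id(e$runs, run)
    if (!is.null(r)) return(r)
  }
  stop(sprintf("no run with id '%s' in document", run))
}
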