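# Version-aware structural and referential validation.
#
# Rules are encoded directly over the in-memory model (the three version
# dialects differ in a handful of explicit gates) rather than delegated to
# an external schema engine; validate_rdml(schema =) accepts an XSD for an
# optional cross-check when one is available. Problems are reported, never
# thrown; severity "error" marks breaches of structure or referential
# integrity, "warning" marks vocabulary deviations and missing recommended
# metadata.

issue_row <- function(severity, code, path, message) {
  data.frame(severity = severity, code = code, path = path,
             message = message, stringsAsFactors = FALSE)
}

empty_issues <- function() {
  data.frame(severity = character(), code = character(), path = character(),
             message = character(), stringsAsFactors = FALSE)
}

check_unique_ids <- function(items, list_name) {
  out <- empty_issues()
  ids <- ids_of(items)
  dup <- unique(ids[duplicated(ids)])
  for (id in dup) {
    out <- rbind(out, issue_row(
      "error", "duplicate-id", sprintf("/%s[%s]", list_name, id),
      sprintf("identifier '%s' occurs %d times in %s list",
              id, sum(ids == id), list_name)))
  }
  out
}

check_monotone <- function(x, code, path, what, out) {
  if (length(x) > 1 && any(diff(x) <= 0)) {
    out <- rbind(out, issue_row(
      "error", code, path, sprintf("%s are not strictly increasing", what)))
  }
  out
}

#' Validate an RDML document
#'
#' Applies the version-aware rule set: identifier uniqueness within each
#' top-level list; resolvability of every sample/target/dye reference;
#' mandatory dye registration for targets used in reaction data from
#' version 1.1 on; reaction positions unique and within the plate bounds;
#' strictly increasing amplification cycles and melt temperatures; version
#' gating of 1.2-only elements (sample annotations, the unified quantity
#' element, amplificationEfficiencySE); and vocabulary conformance
#' (warnings). Issues are reported in document order.
#'
#' @param doc An [rdml_document()].
#' @param schema Optional path to an XML Schema file; when supplied, the
#'   serialized document is additionally checked against it with
#'   [xml2::xml_validate()] and any schema message is appended as an issue
#'   with code `schema-violation`.
#' @return An object of class `rdml_validation_report`: a list with
#'   `issues` (data frame: severity, code, path, message) and `valid`
#'   (`TRUE` iff no issue has severity error).
#' @seealso [format_validation_report()]
#' @export
validate_rdml <- function(doc, schema = NULL) {
  stopifnot(inherits(doc, "rdml_document"))
  v <- doc$version
  out <- empty_issues()

  for (spec in list(
    list(doc$experimenters, "experimenter"),
    list(doc$documentations, "documentation"),
    list(doc$dyes, "dye"),
    list(doc$samples, "sample"),
    list(doc$targets, "target"),
    list(doc$thermalCyclingConditions, "thermalCyclingConditions"),
    list(doc$experiments, "experiment"))) {
    out <- rbind(out, check_unique_ids(spec[[1]], spec[[2]]))
  }

  dye_ids <- ids_of(doc$dyes)
  sample_ids <- ids_of(doc$samples)
  target_ids <- ids_of(doc$targets)

  for (e in doc$experimenters) {
    if (is.null(e$email)) {
      out <- rbind(out, issue_row(
        "warning", "missing-recommended-field",
        sprintf("/experimenter[%s]", e$id),
        "experimenter has no email address"))
    }
  }

  for (s in doc$samples) {
    path <- sprintf("/sample[%s]", s$id)
    if (!s$sampleType %in% sample_types) {
      out <- rbind(out, issue_row(
        "warning", "unknown-enum-token", path,
        sprintf("sample type '%s' is not a known token", s$sampleType)))
    }
    if (length(s$annotations) > 0 && v != "1.2") {
      out <- rbind(out, issue_row(
        "error", "element-wrong-version", path,
        sprintf("sample annotations require version 1.2 (document is %s)", v)))
    }
    if (!is.null(s$legacyQuality) && v == "1.2") {
      out <- rbind(out, issue_row(
        "error", "element-wrong-version", path,
        "legacy DNA/RNA quality records are replaced by annotations in 1.2"))
    }
    if (!is.null(s$quantity) && s$quantity$value < 0) {
      out <- rbind(out, issue_row(
        "error", "invalid-value", path, "sample quantity is negative"))
    }
  }

  # Which targets appear in reaction data (for the dye-registration rule)
  used_targets <- character()
  for (e in doc$experiments) for (r in e$runs) for (re in r$reactions) {
    for (d in re$data) used_targets <- c(used_targets, d$targetRef)
  }
  used_targets <- unique(used_targets)

  for (t in doc$targets) {
    path <- sprintf("/target[%s]", t$id)
    if (!t$targetType %in% target_types) {
      out <- rbind(out, issue_row(
        "warning", "unknown-enum-token", path,
        sprintf("target type '%s' is not a known token", t$targetType)))
    }
    if (!is.null(t$dyeRef) && !t$dyeRef %in% dye_ids) {
      out <- rbind(out, issue_row(
        "error", "dangling-reference", path,
        sprintf("dyeId '%s' does not resolve to a registered dye", t$dyeRef)))
    }
    if (v %in% c("1.1", "1.2") && is.null(t$dyeRef) &&
        t$id %in% used_targets) {
      out <- rbind(out, issue_row(
        "error", "dye-unregistered", path,
        sprintf("target '%s' is used in reaction data but names no registered dye (mandatory from version 1.1)",
                t$id)))
    }
    if (!is.null(t$amplificationEfficiencySE)) {
      if (is.null(t$amplificationEfficiency)) {
        out <- rbind(out, issue_row(
          "error", "efficiency-se-without-value", path,
          "amplificationEfficiencySE present without amplificationEfficiency"))
      }
      if (v != "1.2") {
        out <- rbind(out, issue_row(
          "error", "element-wrong-version", path,
          sprintf("amplificationEfficiencySE requires version 1.2 (document is %s)", v)))
      }
    }
  }

  for (p in doc$thermalCyclingConditions) {
    path <- sprintf("/thermalCyclingConditions[%s]", p$id)
    for (i in seq_along(p$steps)) {
      if (p$steps[[i]]$duration <= 0) {
        out <- rbind(out, issue_row(
          "error", "invalid-value", sprintf("%s/step[%d]", path, i),
          "step duration must be > 0"))
      }
    }
  }

  for (e in doc$experiments) {
    out <- rbind(out, check_unique_ids(e$runs, sprintf("experiment[%s]/run", e$id)))
    for (r in e$runs) {
      rpath <- sprintf("/experiment[%s]/run[%s]", e$id, r$id)
      n_wells <- r$pcrFormat$rows * r$pcrFormat$columns
      positions <- vapply(r$reactions, function(x) x$position, integer(1))
      dup <- unique(positions[duplicated(positions)])
      for (pos in dup) {
        out <- rbind(out, issue_row(
          "error", "duplicate-position", sprintf("%s/react[%d]", rpath, pos),
          sprintf("position %d is occupied by %d reactions",
                  pos, sum(positions == pos))))
      }
      for (re in r$reactions) {
        path <- sprintf("%s/react[%d]", rpath, re$position)
        if (re$position > n_wells) {
          out <- rbind(out, issue_row(
            "error", "position-out-of-bounds", path,
            sprintf("position %d exceeds the %dx%d plate (%d wells)",
                    re$position, r$pcrFormat$rows, r$pcrFormat$columns,
                    n_wells)))
        }
        if (!re$sampleRef %in% sample_ids) {
          out <- rbind(out, issue_row(
            "error", "dangling-reference", path,
            sprintf("sampleRef '%s' does not resolve", re$sampleRef)))
        }
        if (length(re$data) == 0) {
          out <- rbind(out, issue_row(
            "error", "reaction-empty", path,
            "reaction carries no data element"))
        }
        for (d in re$data) {
          dpath <- sprintf("%s/data[%s]", path, d$targetRef)
          if (!d$targetRef %in% target_ids) {
            out <- rbind(out, issue_row(
              "error", "dangling-reference", dpath,
              sprintf("targetRef '%s' does not resolve", d$targetRef)))
          }
          out <- check_monotone(d$amplificationPoints$cycle,
                                "cycles-not-increasing", dpath,
                                "amplification cycles", out)
          out <- check_monotone(d$meltingPoints$temperature,
                                "melt-not-increasing", dpath,
                                "melt temperatures", out)
        }
      }
    }
  }

  if (!is.null(schema)) {
    xml <- rdml_to_xml(doc)
    ok <- xml2::xml_validate(xml, xml2::read_xml(schema))
    if (!isTRUE(ok)) {
      for (msg in attr(ok, "errors")) {
        out <- rbind(out, issue_row("error", "schema-violation", "/", msg))
      }
    }
  }

  structure(list(issues = out,
                 valid = !any(out$severity == "error")),
            class = "rdml_validation_report")
}

#' Render a validation report as text
#'
#' A report without issues renders exactly as `"validation successful"`;
#' otherwise one line per issue giving severity, code, path and message.
#'
#' @param report An `rdml_validation_report` from [validate_rdml()].
#' @return A character scalar.
#' @export
format_validation_report <- function(report) {
  stopifnot(inherits(report, "rdml_validation_report"))
  if (nrow(report$issues) == 0) return("validation successful")
  paste(sprintf("%s [%s] %s: %s",
                report$issues$severity, report$issues$code,
                report$issues$path, report$issues$message),
        collapse = "\n")
}

#' @export
print.rdml_validation_report <- function(x, ...) {
  cat(format_validation_report(x), "\n", sep = "")
  invisible(x)
}
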