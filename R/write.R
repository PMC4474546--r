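# Serialization of the document model to RDML XML and the zip container.
#
# Output is deterministic: elements are emitted in model order, numbers with
# a fixed 15-significant-digit format, and the container uses fixed zip
# metadata, so writing the same document twice yields byte-identical files.

fmt_num <- function(x) {
  formatC(x, digits = 15, format = "g", width = 1)
}

add_text_child <- function(parent, name, value) {
  if (!is.null(value)) xml2::xml_add_child(parent, name, as.character(value))
  invisible(parent)
}

add_num_child <- function(parent, name, value) {
  if (!is.null(value)) xml2::xml_add_child(parent, name, fmt_num(value))
  invisible(parent)
}

add_extras <- function(parent, extra) {
  for (snippet in extra) {
    xml2::xml_add_child(parent, xml2::read_xml(snippet))
  }
  invisible(parent)
}

write_quantity_xml <- function(node, sample, version) {
  q <- sample$quantity
  if (is.null(q)) return(invisible(node))
  if (version == "1.2") {
    qn <- xml2::xml_add_child(node, "quantity")
  } else {
    # pre-1.2: the quantity lives in a nucleic-acid-specific slot
    slot <- if (identical(sample$material, "RNA")) "quantityRna" else "quantityDna"
    qn <- xml2::xml_add_child(node, slot)
  }
  add_num_child(qn, "value", q$value)
  add_text_child(qn, "unit", q$unit)
  add_extras(qn, q$extra)
  invisible(node)
}

write_sample_xml <- function(parent, s, version) {
  node <- xml2::xml_add_child(parent, "sample", id = s$id)
  add_text_child(node, "description", s$description)
  token <- if (s$sampleType %in% names(sample_type_tokens)) {
    sample_type_tokens[[s$sampleType]]
  } else {
    s$sampleType  # unrecognised token from a third-party file, kept verbatim
  }
  add_text_child(node, "type", token)
  if (version == "1.2") {
    for (a in s$annotations) {
      an <- xml2::xml_add_child(node, "annotation")
      add_text_child(an, "property", a$property)
      add_text_child(an, "value", a$value)
      add_extras(an, a$extra)
    }
  }
  write_quantity_xml(node, s, version)
  if (version != "1.2" && !is.null(s$legacyQuality)) {
    add_text_child(node, "qualityDna", s$legacyQuality$dna)
    add_text_child(node, "qualityRna", s$legacyQuality$rna)
  }
  add_extras(node, s$extra)
  invisible(node)
}

write_target_xml <- function(parent, t, version) {
  node <- xml2::xml_add_child(parent, "target", id = t$id)
  add_text_child(node, "description", t$description)
  token <- if (t$targetType %in% names(target_type_tokens)) {
    target_type_tokens[[t$targetType]]
  } else {
    t$targetType
  }
  add_text_child(node, "type", token)
  add_text_child(node, "dyeId", t$dyeRef)
  seqs <- t$sequences
  if (any(!vapply(seqs, is.null, logical(1)))) {
    sn <- xml2::xml_add_child(node, "sequences")
    for (f in c("forwardPrimer", "reversePrimer", "probe", "amplicon")) {
      add_text_child(sn, f, seqs[[f]])
    }
  }
  add_num_child(node, "amplificationEfficiency", t$amplificationEfficiency)
  if (version == "1.2") {
    add_num_child(node, "amplificationEfficiencySE", t$amplificationEfficiencySE)
  }
  add_extras(node, t$extra)
  invisible(node)
}

write_cycling_xml <- function(parent, p) {
  node <- xml2::xml_add_child(parent, "thermalCyclingConditions", id = p$id)
  add_text_child(node, "description", p$description)
  for (s in p$steps) {
    sn <- xml2::xml_add_child(node, "step")
    add_num_child(sn, "temperature", s$temperature)
    add_num_child(sn, "duration", s$duration)
    add_text_child(sn, "acquire", if (isTRUE(s$acquire)) "true" else "false")
  }
  add_extras(node, p$extra)
  invisible(node)
}

write_reaction_xml <- function(parent, r, run, version) {
  well_id <- if (version == "1.0") {
    position_to_well_label(r$position, run$pcrFormat)
  } else {
    as.character(r$position)
  }
  node <- xml2::xml_add_child(parent, "react", id = well_id)
  add_text_child(node, "sample", r$sampleRef)
  for (d in r$data) {
    dn <- xml2::xml_add_child(node, "data")
    add_text_child(dn, "tar", d$targetRef)
    add_num_child(dn, "cq", d$cq)
    add_num_child(dn, "baseline", d$baseline)
    add_num_child(dn, "quantificationThreshold", d$quantificationThreshold)
    ap <- d$amplificationPoints
    if (nrow(ap) > 0) {
      ord <- order(ap$cycle)
      for (i in ord) {
        pn <- xml2::xml_add_child(dn, "adp")
        xml2::xml_add_child(pn, "cyc", as.character(ap$cycle[i]))
        xml2::xml_add_child(pn, "fluor", fmt_num(ap$fluorescence[i]))
      }
    }
    mp <- d$meltingPoints
    if (nrow(mp) > 0) {
      for (i in seq_len(nrow(mp))) {
        pn <- xml2::xml_add_child(dn, "mdp")
        xml2::xml_add_child(pn, "tmp", fmt_num(mp$temperature[i]))
        xml2::xml_add_child(pn, "fluor", fmt_num(mp$fluorescence[i]))
      }
    }
    add_extras(dn, d$extra)
  }
  add_extras(node, r$extra)
  invisible(node)
}

write_run_xml <- function(parent, run, version) {
  node <- xml2::xml_add_child(parent, "run", id = run$id)
  add_text_child(node, "description", run$description)
  if (version == "1.0") {
    token <- run$plateType
    if (is.null(token)) token <- format_to_plate_type(run$pcrFormat)
    if (is.null(token)) {
      cond <- errorCondition(
        sprintf("run '%s': no predefined 1.0 plate type matches the %dx%d format",
                run$id, run$pcrFormat$rows, run$pcrFormat$columns),
        class = c("rdml_unknown_plate_type", "rdml_error", "error"))
      stop(cond)
    }
    add_text_child(node, "plateType", token)
  } else {
    fn <- xml2::xml_add_child(node, "pcrFormat")
    add_text_child(fn, "rows", run$pcrFormat$rows)
    add_text_child(fn, "columns", run$pcrFormat$columns)
    add_text_child(fn, "rowLabel", run$pcrFormat$rowLabelScheme)
    add_text_child(fn, "columnLabel", run$pcrFormat$columnLabelScheme)
  }
  for (r in run$reactions) write_reaction_xml(node, r, run, version)
  add_extras(node, run$extra)
  invisible(node)
}

rdml_to_xml <- function(doc) {
  attrs <- list(version = doc$version)
  if (!is.null(doc$dateMade)) attrs$dateMade <- doc$dateMade
  if (!is.null(doc$dateUpdated)) attrs$dateUpdated <- doc$dateUpdated
  root <- do.call(xml2::xml_new_root, c(list(.value = "rdml"), attrs))
  for (e in doc$experimenters) {
    node <- xml2::xml_add_child(root, "experimenter", id = e$id)
    add_text_child(node, "firstName", e$firstName)
    add_text_child(node, "lastName", e$lastName)
    add_text_child(node, "email", e$email)
    add_extras(node, e$extra)
  }
  for (d in doc$documentations) {
    node <- xml2::xml_add_child(root, "documentation", id = d$id)
    add_text_child(node, "text", d$text)
    add_extras(node, d$extra)
  }
  for (d in doc$dyes) {
    node <- xml2::xml_add_child(root, "dye", id = d$id)
    add_text_child(node, "description", d$description)
    add_extras(node, d$extra)
  }
  for (s in doc$samples) write_sample_xml(root, s, doc$version)
  for (t in doc$targets) write_target_xml(root, t, doc$version)
  for (p in doc$thermalCyclingConditions) write_cycling_xml(root, p)
  for (ex in doc$experiments) {
    node <- xml2::xml_add_child(root, "experiment", id = ex$id)
    add_text_child(node, "description", ex$description)
    for (run in ex$runs) write_run_xml(node, run, doc$version)
    add_extras(node, ex$extra)
  }
  add_extras(root, doc$extra)
  xml2::xml_root(root)
}

#' Write a document to an RDML file
#'
#' Serializes the document to its version-appropriate XML form and wraps it
#' in a zip container whose single data member is named `rdml_data.xml`.
#' The document is validated first; issues of severity *error* block the
#' write unless `force = TRUE`. Output is deterministic: writing the same
#' document twice produces byte-identical files.
#'
#' @param doc An [rdml_document()].
#' @param path Destination file path.
#' @param bare_xml Write the XML document directly, without the zip
#'   container. Off by default; bare XML is accepted on read for
#'   interoperability but the container is the canonical form.
#' @param force Write even if validation reports errors.
#' @return Invisibly, a list with `entryName` and `wasBareXml` describing
#'   the container written.
#' @seealso [read_rdml()], [validate_rdml()]
#' @export
write_rdml <- function(doc, path, bare_xml = FALSE, force = FALSE) {
  stopifnot(inherits(doc, "rdml_document"))
  if (!force) {
    report <- validate_rdml(doc)
    if (!report$valid) {
      n_err <- sum(report$issues$severity == "error")
      rdml_abort(
        sprintf("refusing to write: validation reported %d error(s); first: %s (use force = TRUE to override)",
                n_err, report$issues$message[report$issues$severity == "error"][1]),
        "rdml_refused_write")
    }
  }
  xml <- rdml_to_xml(doc)
  text <- as.character(xml)
  bytes <- charToRaw(text)
  if (bare_xml) {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(bytes, con)
    return(invisible(list(entryName = NA_character_, wasBareXml = TRUE)))
  }
  zip_write_single(path, "rdml_data.xml", bytes)
  invisible(list(entryName = "rdml_data.xml", wasBareXml = FALSE))
}
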