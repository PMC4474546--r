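# Parsing RDML files (zip container or bare XML) into the document model.
#
# Unknown child elements anywhere in the tree are preserved verbatim as
# serialized snippets on their parent's `extra` field and re-emitted on
# write, so extensions from other tools survive a round trip.

source_to_xml_bytes <- function(source) {
  if (is.raw(source)) {
    if (is_zip_bytes(source)) {
      tmp <- tempfile(fileext = ".rdml")
      on.exit(unlink(tmp))
      writeBin(source, tmp)
      got <- zip_read_xml_member(tmp)
      return(list(xml_bytes = got$xml_bytes, entryName = got$entry_name,
                  wasBareXml = FALSE))
    }
    return(list(xml_bytes = source, entryName = NA_character_,
                wasBareXml = TRUE))
  }
  if (!is.character(source) || length(source) != 1) {
    stop("source must be a file path or a raw vector")
  }
  if (!file.exists(source)) {
    rdml_abort(sprintf("file '%s' does not exist", source),
               "rdml_malformed_file")
  }
  head_bytes <- readBin(source, "raw", n = 4)
  if (is_zip_bytes(head_bytes)) {
    got <- zip_read_xml_member(source)
    list(xml_bytes = got$xml_bytes, entryName = got$entry_name,
         wasBareXml = FALSE)
  } else {
    list(xml_bytes = readBin(source, "raw", n = file.size(source)),
         entryName = NA_character_, wasBareXml = TRUE)
  }
}

#' Detect the RDML format version of a file
#'
#' Reads the version attribute from the root element of the XML member
#' (or of bare XML) without parsing the whole document.
#'
#' @param source File path or raw vector holding a zip-wrapped or bare XML
#'   RDML document.
#' @return The version string carried by the file, e.g. `"1.1"`.
#' @export
detect_rdml_version <- function(source) {
  src <- source_to_xml_bytes(source)
  head_txt <- rawToChar(src$xml_bytes[seq_len(min(4096, length(src$xml_bytes)))])
  m <- regmatches(head_txt,
                  regexec("<rdml[^>]*\\sversion=\"([^\"]*)\"", head_txt))[[1]]
  if (length(m) != 2) {
    rdml_abort("no <rdml> root element with a version attribute found",
               "rdml_malformed_file")
  }
  m[2]
}

xml_child_text <- function(node, name) {
  child <- xml2::xml_find_first(node, name)
  if (inherits(child, "xml_missing")) return(NULL)
  xml2::xml_text(child)
}

xml_child_num <- function(node, name) {
  v <- xml_child_text(node, name)
  if (is.null(v)) NULL else as.numeric(v)
}

collect_extras <- function(node, known) {
  kids <- xml2::xml_children(node)
  nms <- xml2::xml_name(kids)
  unknown <- kids[!nms %in% known]
  vapply(unknown, as.character, character(1))
}

parse_quantity_node <- function(qn) {
  q <- rdml_quantity(as.numeric(xml_child_text(qn, "value")),
                     xml_child_text(qn, "unit"))
  q$extra <- collect_extras(qn, c("value", "unit"))
  q
}

parse_sample <- function(node, version) {
  known <- c("description", "type", "annotation", "quantity",
             "quantityDna", "quantityRna", "qualityDna", "qualityRna")
  token <- xml_child_text(node, "type")
  stype <- if (is.null(token)) {
    "unknown"
  } else if (token %in% sample_type_tokens) {
    names(sample_type_tokens)[match(token, sample_type_tokens)]
  } else {
    token
  }
  annotations <- lapply(xml2::xml_find_all(node, "annotation"), function(an) {
    a <- rdml_annotation(xml_child_text(an, "property"),
                         xml_child_text(an, "value"))
    a$extra <- collect_extras(an, c("property", "value"))
    a
  })
  quantity <- NULL
  material <- NULL
  qn <- xml2::xml_find_first(node, "quantity")
  if (!inherits(qn, "xml_missing")) {
    quantity <- parse_quantity_node(qn)
  } else {
    for (slot in c("quantityDna", "quantityRna")) {
      sn <- xml2::xml_find_first(node, slot)
      if (!inherits(sn, "xml_missing")) {
        quantity <- parse_quantity_node(sn)
        material <- if (slot == "quantityDna") "DNA" else "RNA"
        break
      }
    }
  }
  qual_dna <- xml_child_text(node, "qualityDna")
  qual_rna <- xml_child_text(node, "qualityRna")
  legacy <- if (is.null(qual_dna) && is.null(qual_rna)) {
    NULL
  } else {
    list(dna = qual_dna, rna = qual_rna)
  }
  s <- rdml_sample(xml2::xml_attr(node, "id"),
                   description = xml_child_text(node, "description"),
                   sampleType = stype,
                   annotations = annotations,
                   quantity = quantity,
                   material = material,
                   legacyQuality = legacy)
  s$extra <- collect_extras(node, known)
  s
}

parse_target <- function(node) {
  known <- c("description", "type", "dyeId", "sequences",
             "amplificationEfficiency", "amplificationEfficiencySE")
  token <- xml_child_text(node, "type")
  ttype <- if (is.null(token)) {
    "target-of-interest"
  } else if (token %in% target_type_tokens) {
    names(target_type_tokens)[match(token, target_type_tokens)]
  } else {
    token
  }
  seqs <- list()
  sn <- xml2::xml_find_first(node, "sequences")
  if (!inherits(sn, "xml_missing")) {
    for (f in c("forwardPrimer", "reversePrimer", "probe", "amplicon")) {
      seqs[[f]] <- xml_child_text(sn, f)
    }
  }
  t <- rdml_target(xml2::xml_attr(node, "id"),
                   description = xml_child_text(node, "description"),
                   targetType = ttype,
                   dyeRef = xml_child_text(node, "dyeId"),
                   sequences = seqs,
                   amplificationEfficiency =
                     xml_child_num(node, "amplificationEfficiency"),
                   amplificationEfficiencySE =
                     xml_child_num(node, "amplificationEfficiencySE"))
  t$extra <- collect_extras(node, known)
  t
}

parse_cycling <- function(node) {
  steps <- lapply(xml2::xml_find_all(node, "step"), function(sn) {
    list(temperature = as.numeric(xml_child_text(sn, "temperature")),
         duration = as.numeric(xml_child_text(sn, "duration")),
         acquire = identical(xml_child_text(sn, "acquire"), "true"))
  })
  p <- rdml_cycling_program(xml2::xml_attr(node, "id"),
                            description = xml_child_text(node, "description"),
                            steps = steps)
  p$extra <- collect_extras(node, c("description", "step"))
  p
}

parse_reaction_data <- function(dn) {
  known <- c("tar", "cq", "baseline", "quantificationThreshold", "adp", "mdp")
  cyc <- xml2::xml_integer(xml2::xml_find_all(dn, "adp/cyc"))
  afl <- xml2::xml_double(xml2::xml_find_all(dn, "adp/fluor"))
  tmp <- xml2::xml_double(xml2::xml_find_all(dn, "mdp/tmp"))
  mfl <- xml2::xml_double(xml2::xml_find_all(dn, "mdp/fluor"))
  d <- rdml_reaction_data(
    targetRef = xml_child_text(dn, "tar"),
    cq = xml_child_num(dn, "cq"),
    baseline = xml_child_num(dn, "baseline"),
    quantificationThreshold = xml_child_num(dn, "quantificationThreshold"),
    amplificationPoints = data.frame(cycle = cyc, fluorescence = afl),
    meltingPoints = data.frame(temperature = tmp, fluorescence = mfl))
  d$extra <- collect_extras(dn, known)
  d
}

parse_run <- function(node, version) {
  known <- c("description", "plateType", "pcrFormat", "react")
  plate_type <- NULL
  if (version == "1.0") {
    plate_type <- xml_child_text(node, "plateType")
    if (is.null(plate_type)) {
      rdml_abort(sprintf("version 1.0 run '%s' lacks a plateType element",
                         xml2::xml_attr(node, "id")),
                 "rdml_malformed_file")
    }
    format <- plate_type_to_format(plate_type)
  } else {
    fn <- xml2::xml_find_first(node, "pcrFormat")
    if (inherits(fn, "xml_missing")) {
      rdml_abort(sprintf("run '%s' lacks a pcrFormat element",
                         xml2::xml_attr(node, "id")),
                 "rdml_malformed_file")
    }
    format <- pcr_format(
      as.integer(xml_child_text(fn, "rows")),
      as.integer(xml_child_text(fn, "columns")),
      rowLabelScheme = xml_child_text(fn, "rowLabel") %||% "letters",
      columnLabelScheme = xml_child_text(fn, "columnLabel") %||% "numbers")
  }
  reactions <- lapply(xml2::xml_find_all(node, "react"), function(rn) {
    well_id <- xml2::xml_attr(rn, "id")
    position <- if (version == "1.0") {
      well_label_to_position(well_id, format)
    } else {
      as.integer(well_id)
    }
    r <- rdml_reaction(position,
                       sampleRef = xml_child_text(rn, "sample"),
                       data = lapply(xml2::xml_find_all(rn, "data"),
                                     parse_reaction_data))
    r$extra <- collect_extras(rn, c("sample", "data"))
    r
  })
  run <- rdml_run(xml2::xml_attr(node, "id"),
                  description = xml_child_text(node, "description"),
                  pcrFormat = format,
                  plateType = plate_type,
                  reactions = reactions)
  run$extra <- collect_extras(node, known)
  run
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read an RDML file
#'
#' Reads a zip-wrapped (canonical) or bare-XML RDML document of format
#' version 1.0, 1.1 or 1.2 into the in-memory model. Version-1.0 well
#' labels are converted to linear plate positions via the predefined
#' plate-type map; unknown elements anywhere in the tree are preserved
#' verbatim and written back by [write_rdml()].
#'
#' @param source File path or raw vector.
#' @return An [rdml_document()]. The attribute `"container"` carries a list
#'   with `entryName` (name of the XML member inside the zip) and
#'   `wasBareXml`.
#' @export
read_rdml <- function(source) {
  src <- source_to_xml_bytes(source)
  xml <- tryCatch(
    xml2::read_xml(src$xml_bytes),
    error = function(e) {
      rdml_abort(paste0("not well-formed XML: ", conditionMessage(e)),
                 "rdml_malformed_file")
    })
  root <- xml2::xml_root(xml)
  if (xml2::xml_name(root) != "rdml") {
    rdml_abort(sprintf("root element is <%s>, expected <rdml>",
                       xml2::xml_name(root)),
               "rdml_malformed_file")
  }
  version <- xml2::xml_attr(root, "version")
  if (is.na(version)) {
    rdml_abort("<rdml> root carries no version attribute",
               "rdml_malformed_file")
  }
  check_version(version)
  doc <- rdml_document(version,
                       dateMade = {
                         v <- xml2::xml_attr(root, "dateMade")
                         if (is.na(v)) NULL else v
                       },
                       dateUpdated = {
                         v <- xml2::xml_attr(root, "dateUpdated")
                         if (is.na(v)) NULL else v
                       })
  doc$experimenters <- lapply(
    xml2::xml_find_all(root, "experimenter"), function(node) {
      e <- rdml_experimenter(xml2::xml_attr(node, "id"),
                             firstName = xml_child_text(node, "firstName"),
                             lastName = xml_child_text(node, "lastName"),
                             email = xml_child_text(node, "email"))
      e$extra <- collect_extras(node, c("firstName", "lastName", "email"))
      e
    })
  doc$documentations <- lapply(
    xml2::xml_find_all(root, "documentation"), function(node) {
      d <- rdml_documentation(xml2::xml_attr(node, "id"),
                              text = xml_child_text(node, "text"))
      d$extra <- collect_extras(node, "text")
      d
    })
  doc$dyes <- lapply(xml2::xml_find_all(root, "dye"), function(node) {
    d <- rdml_dye(xml2::xml_attr(node, "id"),
                  description = xml_child_text(node, "description"))
    d$extra <- collect_extras(node, "description")
    d
  })
  doc$samples <- lapply(xml2::xml_find_all(root, "sample"),
                        parse_sample, version = version)
  doc$targets <- lapply(xml2::xml_find_all(root, "target"), parse_target)
  doc$thermalCyclingConditions <- lapply(
    xml2::xml_find_all(root, "thermalCyclingConditions"), parse_cycling)
  doc$experiments <- lapply(
    xml2::xml_find_all(root, "experiment"), function(node) {
      ex <- rdml_experiment(xml2::xml_attr(node, "id"),
                            description = xml_child_text(node, "description"),
                            runs = lapply(xml2::xml_find_all(node, "run"),
                                          parse_run, version = version))
      ex$extra <- collect_extras(node, c("description", "run"))
      ex
    })
  doc$extra <- collect_extras(
    root, c("experimenter", "documentation", "dye", "sample", "target",
            "thermalCyclingConditions", "experiment"))
  attr(doc, "container") <- list(entryName = src$entryName,
                                 wasBareXml = src$wasBareXml)
  doc
}
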