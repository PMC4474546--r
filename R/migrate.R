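# Version migration.
#
# Documents move between adjacent versions (1.0 <-> 1.1 <-> 1.2); requests
# spanning two steps are chained through the intermediate version and the
# reports concatenated. Every change is recorded as an action:
#   transformed - content re-housed in the target version's element
#   synthesized - an element invented to satisfy the target version
#                 (only the mandatory-dye rule does this)
#   dropped     - content with no representation in the target version

migration_action <- function(kind, path, detail) {
  data.frame(kind = kind, path = path, detail = detail,
             stringsAsFactors = FALSE)
}

empty_actions <- function() {
  data.frame(kind = character(), path = character(), detail = character(),
             stringsAsFactors = FALSE)
}

# ---- single steps -----------------------------------------------------------

migrate_10_to_11 <- function(doc, plate_map = NULL) {
  actions <- empty_actions()
  for (ei in seq_along(doc$experiments)) {
    e <- doc$experiments[[ei]]
    for (ri in seq_along(e$runs)) {
      run <- e$runs[[ri]]
      rpath <- sprintf("/experiment[%s]/run[%s]", e$id, run$id)
      if (!is.null(run$plateType)) {
        fmt <- plate_type_to_format(run$plateType, custom_map = plate_map)
        actions <- rbind(actions, migration_action(
          "transformed", rpath,
          sprintf("plate type '%s' -> pcrFormat %dx%d; well labels -> numeric positions",
                  run$plateType, fmt$rows, fmt$columns)))
        run$pcrFormat <- fmt
        run$plateType <- NULL
        e$runs[[ri]] <- run
      }
    }
    doc$experiments[[ei]] <- e
  }
  # From 1.1 on the dye element is mandatory for targets measured in
  # reaction data: synthesize a dye for each target lacking one.
  existing <- ids_of(doc$dyes)
  for (ti in seq_along(doc$targets)) {
    t <- doc$targets[[ti]]
    if (is.null(t$dyeRef)) {
      dye_id <- paste0("dye_", t$id)
      k <- 1
      while (dye_id %in% existing) {
        k <- k + 1
        dye_id <- paste0("dye_", t$id, "_", k)
      }
      doc$dyes[[length(doc$dyes) + 1]] <- rdml_dye(
        dye_id, description = "synthesized during 1.0 -> 1.1 migration")
      existing <- c(existing, dye_id)
      doc$targets[[ti]]$dyeRef <- dye_id
      actions <- rbind(actions, migration_action(
        "synthesized", sprintf("/target[%s]", t$id),
        sprintf("registered dye '%s' for target without dye information", dye_id)))
    }
  }
  doc$version <- "1.1"
  list(doc = doc, actions = actions)
}

migrate_11_to_10 <- function(doc, plate_map = NULL) {
  actions <- empty_actions()
  for (ei in seq_along(doc$experiments)) {
    e <- doc$experiments[[ei]]
    for (ri in seq_along(e$runs)) {
      run <- e$runs[[ri]]
      rpath <- sprintf("/experiment[%s]/run[%s]", e$id, run$id)
      token <- format_to_plate_type(run$pcrFormat, custom_map = plate_map)
      if (is.null(token)) {
        cond <- errorCondition(
          sprintf("%s: no predefined 1.0 plate type matches the %dx%d format",
                  rpath, run$pcrFormat$rows, run$pcrFormat$columns),
          class = c("rdml_unknown_plate_type", "rdml_error", "error"))
        stop(cond)
      }
      run$plateType <- token
      e$runs[[ri]] <- run
      actions <- rbind(actions, migration_action(
        "transformed", rpath,
        sprintf("pcrFormat %dx%d -> plate type '%s'; numeric positions -> well labels",
                run$pcrFormat$rows, run$pcrFormat$columns, token)))
    }
    doc$experiments[[ei]] <- e
  }
  doc$version <- "1.0"
  list(doc = doc, actions = actions)
}

quality_properties <- c(dna = "dna quality", rna = "rna quality")

migrate_11_to_12 <- function(doc) {
  actions <- empty_actions()
  for (si in seq_along(doc$samples)) {
    s <- doc$samples[[si]]
    path <- sprintf("/sample[%s]", s$id)
    if (!is.null(s$quantity)) {
      material <- s$material %||% "unspecified material"
      actions <- rbind(actions, migration_action(
        "transformed", path,
        sprintf("%s quantity -> unified quantity element", material)))
      s$material <- NULL
    }
    if (!is.null(s$legacyQuality)) {
      for (slot in c("dna", "rna")) {
        if (!is.null(s$legacyQuality[[slot]])) {
          s$annotations[[length(s$annotations) + 1]] <-
            rdml_annotation(quality_properties[[slot]], s$legacyQuality[[slot]])
          actions <- rbind(actions, migration_action(
            "transformed", path,
            sprintf("legacy %s quality -> annotation '%s'",
                    toupper(slot), quality_properties[[slot]])))
        }
      }
      s$legacyQuality <- NULL
    }
    doc$samples[[si]] <- s
  }
  doc$version <- "1.2"
  list(doc = doc, actions = actions)
}

migrate_12_to_11 <- function(doc) {
  actions <- empty_actions()
  for (si in seq_along(doc$samples)) {
    s <- doc$samples[[si]]
    path <- sprintf("/sample[%s]", s$id)
    kept <- list()
    legacy <- list(dna = NULL, rna = NULL)
    for (a in s$annotations) {
      slot <- names(quality_properties)[match(a$property, quality_properties)]
      if (!is.na(slot) && is.null(legacy[[slot]])) {
        legacy[[slot]] <- a$value
        actions <- rbind(actions, migration_action(
          "transformed", path,
          sprintf("annotation '%s' -> legacy %s quality record",
                  a$property, toupper(slot))))
      } else {
        kept[[length(kept) + 1]] <- a
        actions <- rbind(actions, migration_action(
          "dropped", sprintf("%s/annotation[%s]", path, a$property),
          sprintf("annotation '%s'='%s' has no representation before 1.2",
                  a$property, a$value)))
      }
    }
    s$annotations <- list()
    if (!is.null(legacy$dna) || !is.null(legacy$rna)) {
      s$legacyQuality <- legacy
    }
    if (!is.null(s$quantity) && is.null(s$material)) {
      s$material <- "DNA"
      actions <- rbind(actions, migration_action(
        "transformed", path,
        "unified quantity -> DNA quantity slot (source material ambiguous)"))
    }
    doc$samples[[si]] <- s
  }
  for (ti in seq_along(doc$targets)) {
    t <- doc$targets[[ti]]
    if (!is.null(t$amplificationEfficiencySE)) {
      actions <- rbind(actions, migration_action(
        "dropped", sprintf("/target[%s]", t$id),
        sprintf("amplificationEfficiencySE (%s) has no representation before 1.2",
                fmt_num(t$amplificationEfficiencySE))))
      doc$targets[[ti]]$amplificationEfficiencySE <- NULL
    }
  }
  doc$version <- "1.1"
  list(doc = doc, actions = actions)
}

#' Migrate a document to another RDML version
#'
#' Converts a document between format versions 1.0, 1.1 and 1.2 in either
#' direction, at the cost of minor information loss when the source stores
#' data in elements the target version does not support. Every change is
#' recorded in the returned report. Requests spanning two versions are
#' chained through the intermediate version (1.0 -> 1.1 -> 1.2) and the
#' per-step actions concatenated. The source document is never modified.
#'
#' Upgrade rules: 1.0 -> 1.1 replaces the predefined plate type with the
#' explicit row/column format (well labels become numeric positions) and
#' synthesizes a registered dye for every target that lacks one, since the
#' dye element is mandatory from 1.1 on. 1.1 -> 1.2 unifies the DNA/RNA
#' quantity housing into the single quantity element and turns legacy
#' nucleic-acid quality records into annotations. Downgrades reverse each
#' rule where possible and record one `dropped` action per element that
#' cannot be represented (sample annotations and
#' amplificationEfficiencySE when leaving 1.2).
#'
#' @param doc An [rdml_document()].
#' @param target_version One of `"1.0"`, `"1.1"`, `"1.2"`.
#' @param plate_map Optional named list of extra plate-type tokens to
#'   [pcr_format()] objects for 1.0 conversions.
#' @return A list with `document` (the migrated document) and `report`
#'   (class `rdml_migration_report`: `sourceVersion`, `targetVersion`,
#'   `steps` taken, and an `actions` data frame with columns kind, path,
#'   detail).
#' @export
#' @examples
#' doc <- generate_rdml_document(synthetic_run_spec(version = "1.0", seed = 7))
#' out <- migrate_rdml(doc, "1.2")
#' out$report$steps
migrate_rdml <- function(doc, target_version, plate_map = NULL) {
  stopifnot(inherits(doc, "rdml_document"))
  check_version(target_version)
  versions <- rdml_versions()
  from <- match(doc$version, versions)
  to <- match(target_version, versions)
  actions <- empty_actions()
  steps <- character()
  current <- doc
  while (from != to) {
    nxt <- from + sign(to - from)
    step <- switch(
      paste(versions[from], versions[nxt], sep = ">"),
      "1.0>1.1" = migrate_10_to_11(current, plate_map),
      "1.1>1.2" = migrate_11_to_12(current),
      "1.2>1.1" = migrate_12_to_11(current),
      "1.1>1.0" = migrate_11_to_10(current, plate_map))
    steps <- c(steps, paste(versions[from], "->", versions[nxt]))
    actions <- rbind(actions, step$actions)
    current <- step$doc
    from <- nxt
  }
  report <- structure(list(sourceVersion = doc$version,
                           targetVersion = target_version,
                           steps = steps,
                           actions = actions),
                      class = "rdml_migration_report")
  list(document = current, report = report)
}

#' @export
print.rdml_migration_report <- function(x, ...) {
  cat(sprintf("RDML migration %s -> %s (%d step%s, %d action%s)\n",
              x$sourceVersion, x$targetVersion,
              length(x$steps), if (length(x$steps) == 1) "" else "s",
              nrow(x$actions), if (nrow(x$actions) == 1) "" else "s"))
  if (nrow(x$actions) > 0) {
    cat(paste(sprintf("  %-11s %s: %s", x$actions$kind, x$actions$path,
                      x$actions$detail), collapse = "\n"), "\n", sep = "")
  }
  invisible(x)
}
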