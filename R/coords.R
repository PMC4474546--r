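# Well-identification conventions.
#
# RDML 1.0 identified a reaction by a well label (row letter + column
# number, "B7"); from 1.1 on a reaction carries the 1-based linear position
# in the two-dimensional plate matrix. Numbering here is row-major (A1 = 1,
# A2 = 2, ..., B1 = columns + 1), the conventional reading order of a
# plate; row letters extend A..Z, AA, AB, ... for deep formats.

row_letters_to_index <- function(letters_part) {
  chars <- utf8ToInt(toupper(letters_part)) - utf8ToInt("A") + 1L
  if (any(chars < 1 | chars > 26)) return(NA_integer_)
  as.integer(sum(chars * 26^(rev(seq_along(chars)) - 1)))
}

row_index_to_letters <- function(row) {
  out <- character(0)
  while (row > 0) {
    rem <- (row - 1) %% 26
    out <- c(intToUtf8(utf8ToInt("A") + rem), out)
    row <- (row - 1) %/% 26
  }
  paste(out, collapse = "")
}

#' Convert between well labels and linear plate positions
#'
#' `well_label_to_position()` maps a letter-row/number-column well label
#' (the RDML 1.0 convention) to the 1-based row-major linear position used
#' from RDML 1.1 on: `(row - 1) * columns + column`.
#' `position_to_well_label()` is its inverse.
#'
#' @param label Well label such as `"A1"` or `"H12"`.
#' @param position 1-based linear position.
#' @param format A [pcr_format()].
#' @return An integer position, or a character label.
#' @export
#' @examples
#' f <- pcr_format(8, 12)
#' well_label_to_position("B1", f)   # 13
#' position_to_well_label(96, f)     # "H12"
well_label_to_position <- function(label, format) {
  m <- regmatches(label, regexec("^([A-Za-z]+)([0-9]+)$", label))[[1]]
  if (length(m) != 3) {
    rdml_abort(sprintf("'%s' is not a well label (letters then digits)", label),
               "rdml_invalid_well")
  }
  row <- row_letters_to_index(m[2])
  col <- as.integer(m[3])
  if (is.na(row) || row < 1 || row > format$rows ||
      is.na(col) || col < 1 || col > format$columns) {
    rdml_abort(sprintf("well '%s' is outside the %dx%d plate",
                       label, format$rows, format$columns),
               "rdml_invalid_well")
  }
  (row - 1L) * format$columns + col
}

#' @rdname well_label_to_position
#' @export
position_to_well_label <- function(position, format) {
  position <- as.integer(position)
  n <- format$rows * format$columns
  if (is.na(position) || position < 1 || position > n) {
    rdml_abort(sprintf("position %s is outside 1..%d", position, n),
               "rdml_invalid_position")
  }
  row <- (position - 1L) %/% format$columns + 1L
  col <- (position - 1L) %% format$columns + 1L
  row_label <- if (format$rowLabelScheme == "letters") {
    row_index_to_letters(row)
  } else {
    as.character(row)
  }
  paste0(row_label, col)
}

# Shipped map of RDML 1.0 predefined plate-type tokens to grid geometry.
plate_type_table <- list(
  "96-well"   = c(rows = 8L,   columns = 12L),
  "384-well"  = c(rows = 16L,  columns = 24L),
  "48-well"   = c(rows = 6L,   columns = 8L),
  "rotor-72"  = c(rows = 72L,  columns = 1L),
  "rotor-100" = c(rows = 100L, columns = 1L)
)

#' Predefined plate types of RDML 1.0
#'
#' `rdml_plate_types()` lists the plate-type tokens this package maps;
#' `plate_type_to_format()` resolves a token to its two-dimensional
#' [pcr_format()]. Version 1.0 files described the plate by such predefined
#' tokens; 1.1 replaced them with the explicit row/column format, so this
#' map drives the 1.0 upgrade. Rotor instruments are modelled as n x 1.
#'
#' @param token Plate-type token, e.g. `"96-well"`.
#' @param custom_map Optional named list mapping extra tokens to
#'   [pcr_format()] objects, consulted before the shipped map.
#' @return `plate_type_to_format()`: a [pcr_format()];
#'   `rdml_plate_types()`: character vector of known tokens.
#' @export
#' @examples
#' plate_type_to_format("384-well")
plate_type_to_format <- function(token, custom_map = NULL) {
  if (!is.null(custom_map) && token %in% names(custom_map)) {
    return(custom_map[[token]])
  }
  geo <- plate_type_table[[token]]
  if (is.null(geo)) {
    cond <- errorCondition(
      sprintf("unknown plate type '%s'; supply a custom map to handle it", token),
      class = c("rdml_unknown_plate_type", "rdml_error", "error"))
    cond$token <- token
    stop(cond)
  }
  pcr_format(geo[["rows"]], geo[["columns"]])
}

#' @rdname plate_type_to_format
#' @export
rdml_plate_types <- function() names(plate_type_table)

# Reverse lookup for downgrades to 1.0: find a shipped token matching the
# grid, or NULL.
format_to_plate_type <- function(format, custom_map = NULL) {
  maps <- custom_map
  for (token in names(maps)) {
    f <- maps[[token]]
    if (f$rows == format$rows && f$columns == format$columns) return(token)
  }
  for (token in names(plate_type_table)) {
    geo <- plate_type_table[[token]]
    if (geo[["rows"]] == format$rows && geo[["columns"]] == format$columns) {
      return(token)
    }
  }
  NULL
}
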