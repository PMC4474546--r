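# Read-only plate reconstruction and exports.
#
# Instrument-collected data (the "react" subtree) are never modified:
# every function here takes the document and returns new values.

#' Reconstruct the plate table of a run
#'
#' Returns one row per (occupied well, target) in the run, ordered by
#' linear position then target, with the well label, sample, sample type,
#' dye and the observed Cq, baseline and quantification threshold.
#'
#' @param doc An [rdml_document()].
#' @param run A run id or `rdml_run` object; defaults to the first run of
#'   the first experiment.
#' @return A data frame with columns `position`, `well`, `sample`,
#'   `sampleType`, `target`, `dye`, `cq`, `baseline`, `threshold`. Empty
#'   wells are omitted.
#' @export
plate_table <- function(doc, run = NULL) {
  run <- resolve_run(doc, run)
  rows <- list()
  reactions <- run$reactions
  if (length(reactions) > 1) {
    reactions <- reactions[order(vapply(reactions, function(r) r$position,
                                        integer(1)))]
  }
  for (re in reactions) {
    s <- find_by_id(doc$samples, re$sampleRef)
    for (d in re$data) {
      t <- find_by_id(doc$targets, d$targetRef)
      rows[[length(rows) + 1]] <- data.frame(
        position = re$position,
        well = position_to_well_label(re$position, run$pcrFormat),
        sample = re$sampleRef,
        sampleType = if (is.null(s)) NA_character_ else s$sampleType,
        target = d$targetRef,
        dye = if (is.null(t) || is.null(t$dyeRef)) NA_character_ else t$dyeRef,
        cq = d$cq %||% NA_real_,
        baseline = d$baseline %||% NA_real_,
        threshold = d$quantificationThreshold %||% NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0) {
    return(data.frame(position = integer(), well = character(),
                      sample = character(), sampleType = character(),
                      target = character(), dye = character(),
                      cq = numeric(), baseline = numeric(),
                      threshold = numeric(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out[order(out$position, out$target, method = "radix"), , drop = FALSE]
}

csv_quote <- function(x) {
  x <- ifelse(is.na(x), "", as.character(x))
  needs <- grepl('[",\n\r]', x)
  x[needs] <- paste0('"', gsub('"', '""', x[needs]), '"')
  x
}

csv_num <- function(x) ifelse(is.na(x), "", fmt_num(x))

#' Export a run's plate view as CSV text
#'
#' `mode = "summary"` gives one row per (reaction, target) with the plate
#' table columns; `mode = "long"` gives one row per stored fluorescence
#' point with columns `position`, `target`, `kind`
#' (amplification/melt), `x` (cycle or temperature) and `y` (fluorescence).
#' Output follows RFC 4180: comma separator, `"` quoting, `.` decimal
#' point; missing values are empty fields. Rows are ordered by position,
#' then target, then x.
#'
#' @inheritParams plate_table
#' @param mode `"summary"` or `"long"`.
#' @return A character scalar of CSV text (newline-separated lines,
#'   header first).
#' @export
export_plate_csv <- function(doc, run = NULL, mode = c("summary", "long")) {
  mode <- match.arg(mode)
  run <- resolve_run(doc, run)
  if (mode == "summary") {
    tab <- plate_table(doc, run)
    lines <- c(
      "position,well,sample,sampleType,target,dye,cq,baseline,threshold",
      sprintf("%d,%s,%s,%s,%s,%s,%s,%s,%s",
              tab$position, csv_quote(tab$well), csv_quote(tab$sample),
              csv_quote(tab$sampleType), csv_quote(tab$target),
              csv_quote(tab$dye), csv_num(tab$cq), csv_num(tab$baseline),
              csv_num(tab$threshold)))
    return(paste(lines, collapse = "\n"))
  }
  series <- c(extract_curves(doc, run, kind = "amplification"),
              extract_curves(doc, run, kind = "melt"))
  rows <- list()
  for (s in series) {
    rows[[length(rows) + 1]] <- data.frame(
      position = s$reactionPosition, target = s$targetId, kind = s$kind,
      x = s$points$x, y = s$points$y, stringsAsFactors = FALSE)
  }
  header <- "position,target,kind,x,y"
  if (length(rows) == 0) return(header)
  tab <- do.call(rbind, rows)
  tab <- tab[order(tab$position, tab$target, tab$kind, tab$x,
                   method = "radix"), , drop = FALSE]
  paste(c(header,
          sprintf("%d,%s,%s,%s,%s", tab$position, csv_quote(tab$target),
                  tab$kind, fmt_num(tab$x), fmt_num(tab$y))),
        collapse = "\n")
}

#' Extract amplification or melt curves from a run
#'
#' Returns one series per (reaction, target) that stores points of the
#' requested kind, optionally restricted to given samples or targets.
#'
#' @inheritParams plate_table
#' @param kind `"amplification"` (fluorescence per cycle) or `"melt"`
#'   (fluorescence per temperature).
#' @param target,sample Optional ids to filter on.
#' @return A list of `rdml_curve` objects, each with `reactionPosition`,
#'   `targetId`, `kind` and a `points` data frame with columns `x`, `y`.
#' @export
extract_curves <- function(doc, run = NULL, kind = c("amplification", "melt"),
                           target = NULL, sample = NULL) {
  kind <- match.arg(kind)
  run <- resolve_run(doc, run)
  out <- list()
  reactions <- run$reactions
  if (length(reactions) > 1) {
    reactions <- reactions[order(vapply(reactions, function(r) r$position,
                                        integer(1)))]
  }
  for (re in reactions) {
    if (!is.null(sample) && !re$sampleRef %in% sample) next
    for (d in re$data) {
      if (!is.null(target) && !d$targetRef %in% target) next
      pts <- if (kind == "amplification") {
        data.frame(x = as.numeric(d$amplificationPoints$cycle),
                   y = d$amplificationPoints$fluorescence)
      } else {
        data.frame(x = d$meltingPoints$temperature,
                   y = d$meltingPoints$fluorescence)
      }
      if (nrow(pts) == 0) next
      out[[length(out) + 1]] <- structure(
        list(reactionPosition = re$position, targetId = d$targetRef,
             kind = kind, points = pts),
        class = "rdml_curve")
    }
  }
  out
}

svg_num <- function(x) formatC(x, digits = 6, format = "g", width = 1)

curve_palette <- c("#1b9e77", "#d95f02", "#7570b3", "#e7298a",
                   "#66a61e", "#e6ab02", "#a6761d", "#666666")

#' Render curve series as an SVG chart
#'
#' Produces a standalone SVG document with axis lines, tick labels spanning
#' the data range, and one polyline per series. All series must share one
#' kind. Styling is inline so the file renders in any viewer; output is
#' deterministic for a fixed input.
#'
#' @param series List of curves from [extract_curves()].
#' @param width,height Pixel dimensions of the chart.
#' @param xlab,ylab Axis labels; defaults follow the series kind.
#' @return A character scalar of SVG text.
#' @export
render_curves_svg <- function(series, width = 800, height = 500,
                              xlab = NULL, ylab = "fluorescence") {
  kinds <- unique(vapply(series, function(s) s$kind, character(1)))
  if (length(kinds) > 1) {
    rdml_abort(
      sprintf("cannot mix series kinds in one chart: %s",
              paste(kinds, collapse = ", ")),
      "rdml_incompatible_series")
  }
  if (is.null(xlab)) {
    xlab <- if (identical(kinds, "melt")) "temperature (°C)" else "cycle"
  }
  # 5% margins around a linear mapping of the data range into the viewBox
  mx <- 0.05 * width
  my <- 0.05 * height
  x0 <- mx * 1.6; x1 <- width - mx   # extra room for y tick labels
  y0 <- height - my * 1.6; y1 <- my  # y grows downwards in SVG
  if (length(series) > 0) {
    xs <- unlist(lapply(series, function(s) s$points$x))
    ys <- unlist(lapply(series, function(s) s$points$y))
    xr <- range(xs)
    yr <- range(ys)
    if (diff(xr) == 0) xr <- xr + c(-0.5, 0.5)
    if (diff(yr) == 0) yr <- yr + c(-0.5, 0.5)
  } else {
    xr <- c(0, 1)
    yr <- c(0, 1)
  }
  sx <- function(v) x0 + (v - xr[1]) / diff(xr) * (x1 - x0)
  sy <- function(v) y0 + (v - yr[1]) / diff(yr) * (y1 - y0)
  lines <- c(
    sprintf('<svg xmlns="http://www.w3.org/2000/svg" viewBox="0 0 %s %s" width="%s" height="%s">',
            svg_num(width), svg_num(height), svg_num(width), svg_num(height)),
    sprintf('<line x1="%s" y1="%s" x2="%s" y2="%s" stroke="black" stroke-width="1"/>',
            svg_num(x0), svg_num(y0), svg_num(x1), svg_num(y0)),
    sprintf('<line x1="%s" y1="%s" x2="%s" y2="%s" stroke="black" stroke-width="1"/>',
            svg_num(x0), svg_num(y0), svg_num(x0), svg_num(y1)))
  for (tick in pretty(xr, n = 6)) {
    if (tick < xr[1] || tick > xr[2]) next
    px <- sx(tick)
    lines <- c(lines,
      sprintf('<line x1="%s" y1="%s" x2="%s" y2="%s" stroke="black" stroke-width="1"/>',
              svg_num(px), svg_num(y0), svg_num(px), svg_num(y0 + 5)),
      sprintf('<text x="%s" y="%s" font-size="12" text-anchor="middle">%s</text>',
              svg_num(px), svg_num(y0 + 18), svg_num(tick)))
  }
  for (tick in pretty(yr, n = 6)) {
    if (tick < yr[1] || tick > yr[2]) next
    py <- sy(tick)
    lines <- c(lines,
      sprintf('<line x1="%s" y1="%s" x2="%s" y2="%s" stroke="black" stroke-width="1"/>',
              svg_num(x0 - 5), svg_num(py), svg_num(x0), svg_num(py)),
      sprintf('<text x="%s" y="%s" font-size="12" text-anchor="end">%s</text>',
              svg_num(x0 - 8), svg_num(py + 4), svg_num(tick)))
  }
  lines <- c(lines,
    sprintf('<text x="%s" y="%s" font-size="13" text-anchor="middle">%s</text>',
            svg_num((x0 + x1) / 2), svg_num(height - 4),
            xml_escape(xlab)),
    sprintf('<text x="%s" y="%s" font-size="13" text-anchor="middle" transform="rotate(-90 12 %s)">%s</text>',
            svg_num(12), svg_num((y0 + y1) / 2), svg_num((y0 + y1) / 2),
            xml_escape(ylab)))
  for (i in seq_along(series)) {
    s <- series[[i]]
    colour <- curve_palette[(i - 1) %% length(curve_palette) + 1]
    pts <- paste(sprintf("%s,%s", svg_num(sx(s$points$x)),
                         svg_num(sy(s$points$y))), collapse = " ")
    lines <- c(lines, sprintf(
      '<polyline fill="none" stroke="%s" stroke-width="1.5" points="%s"/>',
      colour, pts))
  }
  paste(c(lines, "</svg>"), collapse = "\n")
}

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}
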