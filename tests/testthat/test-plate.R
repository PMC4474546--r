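test_that("plate table reconstructs wells in position order", {
  doc <- rdml_document("1.2")
  doc$dyes <- list(rdml_dye("SYBR"))
  doc$samples <- list(rdml_sample("s1"), rdml_sample("s2"))
  doc$targets <- list(rdml_target("t1", dyeRef = "SYBR"))
  mk_data <- function(cq) rdml_reaction_data(
    "t1", cq = cq,
    amplificationPoints = data.frame(cycle = 1:3,
                                     fluorescence = c(0.05, 0.06, 0.2)))
  doc$experiments <- list(rdml_experiment("e1", runs = list(
    rdml_run("r1", pcrFormat = pcr_format(8, 12), reactions = list(
      rdml_reaction(13, "s2", data = list(mk_data(21.5))),
      rdml_reaction(1, "s1", data = list(mk_data(18.25))))))))

  tab <- plate_table(doc)
  expect_identical(nrow(tab), 2L)
  expect_identical(tab$well, c("A1", "B1"))
  expect_identical(tab$position, c(1L, 13L))
  expect_identical(tab$cq, c(18.25, 21.5))
  expect_identical(tab$dye, c("SYBR", "SYBR"))
  expect_identical(tab$sampleType, c("unknown", "unknown"))

  empty <- rdml_document("1.2")
  empty$experiments <- list(rdml_experiment("e1", runs = list(
    rdml_run("r1", pcrFormat = pcr_format(8, 12)))))
  expect_identical(nrow(plate_table(empty)), 0L)
})

test_that("all generated Cq values pass through the table unchanged", {
  doc <- standard_doc(seed = 41, cqNoiseSd = 0.1)
  tab <- plate_table(doc)
  expect_identical(nrow(tab), 12L)
  run <- doc$experiments[[1]]$runs[[1]]
  for (re in run$reactions) {
    row <- tab[tab$position == re$position, ]
    stored <- re$data[[1]]$cq
    if (is.null(stored)) {
      expect_true(is.na(row$cq))
    } else {
      expect_identical(row$cq, stored)
    }
  }
})

test_that("summary CSV has a header plus one row per reaction-target", {
  doc <- standard_doc(seed = 42)
  csv <- export_plate_csv(doc, mode = "summary")
  lines <- strsplit(csv, "\n", fixed = TRUE)[[1]]
  expect_identical(lines[1],
                   "position,well,sample,sampleType,target,dye,cq,baseline,threshold")
  expect_length(lines, 1 + 12)
  # the NTC has no Cq: empty field, not NA/NaN text
  ntc_line <- lines[grepl(",ntc,", lines)]
  expect_length(ntc_line, 1)
  expect_false(grepl("NaN|NA", ntc_line))
  fields <- strsplit(ntc_line, ",", fixed = TRUE)[[1]]
  expect_identical(fields[7], "")
})

test_that("long CSV re-import recovers the exact point sets", {
  doc <- compact_doc(seed = 43)
  csv <- export_plate_csv(doc, mode = "long")
  lines <- strsplit(csv, "\n", fixed = TRUE)[[1]]
  run <- doc$experiments[[1]]$runs[[1]]
  n_points <- sum(vapply(run$reactions, function(re)
    nrow(re$data[[1]]$amplificationPoints) +
      nrow(re$data[[1]]$meltingPoints), numeric(1)))
  expect_length(lines, 1 + n_points)

  parsed <- utils::read.csv(text = csv, stringsAsFactors = FALSE)
  for (re in run$reactions) {
    d <- re$data[[1]]
    amp <- parsed[parsed$position == re$position &
                    parsed$kind == "amplification", ]
    amp <- amp[order(amp$x), ]
    expect_equal(amp$x, as.numeric(d$amplificationPoints$cycle))
    expect_equal(amp$y, d$amplificationPoints$fluorescence,
                 tolerance = 1e-12)
    melt <- parsed[parsed$position == re$position & parsed$kind == "melt", ]
    melt <- melt[order(melt$x), ]
    expect_equal(melt$x, d$meltingPoints$temperature, tolerance = 1e-12)
    expect_equal(melt$y, d$meltingPoints$fluorescence, tolerance = 1e-12)
  }
})

test_that("curve extraction filters by kind, sample and target", {
  doc <- standard_doc(seed = 44)
  amp <- extract_curves(doc, kind = "amplification")
  expect_length(amp, 12)  # every reaction stores an amplification series
  melt <- extract_curves(doc, kind = "melt")
  expect_length(melt, 11)  # the NTC has no melt points
  expect_true(all(vapply(melt, function(s) s$kind, character(1)) == "melt"))

  only_ntc <- extract_curves(doc, kind = "amplification", sample = "ntc")
  expect_length(only_ntc, 1)
  none <- extract_curves(doc, kind = "amplification", target = "nope")
  expect_length(none, 0)

  # x values are the stored cycle numbers, passed through
  expect_identical(amp[[1]]$points$x, as.numeric(1:40))
})

test_that("SVG output is well-formed XML with one polyline per series", {
  doc <- compact_doc(seed = 45)
  series <- extract_curves(doc, kind = "amplification")
  svg <- render_curves_svg(series)
  parsed <- xml2::read_xml(svg)
  expect_identical(xml2::xml_name(parsed), "svg")
  polylines <- xml2::xml_find_all(parsed, ".//*[local-name()='polyline']")
  expect_length(polylines, length(series))

  expect_identical(render_curves_svg(series), svg)  # deterministic

  empty <- render_curves_svg(list())
  parsed_empty <- xml2::read_xml(empty)
  expect_identical(xml2::xml_name(parsed_empty), "svg")
  expect_length(
    xml2::xml_find_all(parsed_empty, ".//*[local-name()='polyline']"), 0)
  # axes are still drawn
  expect_gt(length(xml2::xml_find_all(parsed_empty,
                                      ".//*[local-name()='line']")), 1)
})

test_that("mixing curve kinds in one chart is refused", {
  doc <- compact_doc(seed = 46)
  mixed <- c(extract_curves(doc, kind = "amplification")[1],
             extract_curves(doc, kind = "melt")[1])
  expect_error(render_curves_svg(mixed), class = "rdml_incompatible_series")
})

test_that("views and exports never mutate the document", {
  doc <- standard_doc(seed = 47)
  before <- doc
  invisible(plate_table(doc))
  invisible(export_plate_csv(doc, mode = "summary"))
  invisible(export_plate_csv(doc, mode = "long"))
  invisible(render_curves_svg(extract_curves(doc, kind = "melt")))
  expect_true(rdml_equal(before, doc))
})
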