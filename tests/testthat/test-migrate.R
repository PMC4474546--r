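test_that("well labels map to row-major linear positions and back", {
  f96 <- pcr_format(8, 12)
  expect_identical(well_label_to_position("A1", f96), 1L)
  expect_identical(well_label_to_position("B1", f96), 13L)
  expect_identical(well_label_to_position("H12", f96), 96L)
  expect_identical(position_to_well_label(1, f96), "A1")
  expect_identical(position_to_well_label(96, f96), "H12")

  expect_error(position_to_well_label(97, f96),
               class = "rdml_invalid_position")
  expect_error(well_label_to_position("Z9", f96), class = "rdml_invalid_well")
  expect_error(well_label_to_position("11", f96), class = "rdml_invalid_well")
  expect_error(well_label_to_position("A0", f96), class = "rdml_invalid_well")

  # double-letter rows on deep rotor formats
  rotor <- pcr_format(100, 1)
  expect_identical(position_to_well_label(27, rotor), "AA1")
  expect_identical(well_label_to_position("AA1", rotor), 27L)
})

test_that("the coordinate mapping is a bijection on every shipped format", {
  for (token in rdml_plate_types()) {
    fmt <- plate_type_to_format(token)
    n <- fmt$rows * fmt$columns
    labels <- vapply(seq_len(n), position_to_well_label, character(1),
                     format = fmt)
    expect_identical(anyDuplicated(labels), 0L)
    back <- vapply(labels, well_label_to_position, integer(1), format = fmt)
    expect_identical(unname(back), seq_len(n))
  }
})

test_that("the shipped plate-type map covers the common geometries", {
  f <- plate_type_to_format("96-well")
  expect_identical(c(f$rows, f$columns), c(8L, 12L))
  f <- plate_type_to_format("384-well")
  expect_identical(c(f$rows, f$columns), c(16L, 24L))
  err <- expect_error(plate_type_to_format("hexagonal-7"),
                      class = "rdml_unknown_plate_type")
  expect_identical(err$token, "hexagonal-7")
  # a caller-supplied map takes precedence
  f <- plate_type_to_format("hexagonal-7",
                            custom_map = list("hexagonal-7" = pcr_format(7, 1)))
  expect_identical(f$rows, 7L)
})

test_that("1.0 upgrade converts plate type, positions and synthesizes dyes", {
  doc <- compact_doc(version = "1.0", seed = 31)
  run <- doc$experiments[[1]]$runs[[1]]
  expect_identical(run$plateType, "96-well")
  # place one reaction at well B1 to pin the coordinate composition
  doc$experiments[[1]]$runs[[1]]$reactions[[1]]$position <-
    well_label_to_position("B1", run$pcrFormat)

  out <- migrate_rdml(doc, "1.1")
  up <- out$document
  expect_identical(up$version, "1.1")
  run2 <- up$experiments[[1]]$runs[[1]]
  expect_null(run2$plateType)
  expect_identical(c(run2$pcrFormat$rows, run2$pcrFormat$columns), c(8L, 12L))
  expect_identical(run2$reactions[[1]]$position, 13L)

  expect_true(any(out$report$actions$kind == "synthesized"))
  expect_true(validate_rdml(up)$valid)
  dye_ids <- vapply(up$dyes, function(d) d$id, character(1))
  expect_true(up$targets[[1]]$dyeRef %in% dye_ids)
  # and the source document is untouched
  expect_identical(doc$version, "1.0")
  expect_null(doc$targets[[1]]$dyeRef)
})

test_that("chained migration passes through 1.1 with clean intermediates", {
  doc <- compact_doc(version = "1.0", seed = 32)
  out <- migrate_rdml(doc, "1.2")
  expect_identical(out$report$steps, c("1.0 -> 1.1", "1.1 -> 1.2"))
  expect_identical(out$document$version, "1.2")
  expect_true(validate_rdml(out$document)$valid)

  mid <- migrate_rdml(doc, "1.1")$document
  expect_true(validate_rdml(mid)$valid)
  expect_true(rdml_equal(migrate_rdml(mid, "1.2")$document, out$document))
})

test_that("downgrading from 1.2 drops annotations with one action each", {
  # unknowns = 0 so the only annotations are the injected ones
  doc <- compact_doc(version = "1.2", seed = 33, unknowns = 0)
  doc$samples[[1]]$annotations <- list(
    rdml_annotation("tissue", "liver"),
    rdml_annotation("treatment", "control"),
    rdml_annotation("operator", "ab"))
  out <- migrate_rdml(doc, "1.1")
  dropped <- out$report$actions[out$report$actions$kind == "dropped", ]
  expect_identical(nrow(dropped), 3L)
  expect_true(all(grepl("/annotation\\[", dropped$path)))
  expect_length(out$document$samples[[1]]$annotations, 0)
  expect_true(validate_rdml(out$document)$valid)
})

test_that("efficiency SE is dropped, and reported, when leaving 1.2", {
  doc <- compact_doc(version = "1.2", seed = 34, unknowns = 0)
  doc$targets[[1]]$amplificationEfficiency <- 1.91
  doc$targets[[1]]$amplificationEfficiencySE <- 0.013
  out <- migrate_rdml(doc, "1.1")
  expect_null(out$document$targets[[1]]$amplificationEfficiencySE)
  expect_identical(out$document$targets[[1]]$amplificationEfficiency, 1.91)
  dropped <- out$report$actions[out$report$actions$kind == "dropped", ]
  expect_identical(nrow(dropped), 1L)
  expect_match(dropped$path, "target\\[tgt1\\]")
})

test_that("representable content round-trips up and down without loss", {
  doc <- compact_doc(version = "1.1", seed = 35)
  up <- migrate_rdml(doc, "1.2")
  down <- migrate_rdml(up$document, "1.1")
  expect_identical(sum(down$report$actions$kind == "dropped"), 0L)
  expect_true(rdml_equal(doc, down$document))
})

test_that("legacy quality records become annotations in 1.2 and back", {
  doc <- compact_doc(version = "1.1", seed = 36)
  unk <- which(vapply(doc$samples, function(s) s$sampleType,
                      character(1)) == "unknown")[1]
  expect_false(is.null(doc$samples[[unk]]$legacyQuality))
  up <- migrate_rdml(doc, "1.2")$document
  props <- vapply(up$samples[[unk]]$annotations, function(a) a$property,
                  character(1))
  expect_true("dna quality" %in% props)
  expect_null(up$samples[[unk]]$legacyQuality)
  expect_true(validate_rdml(up)$valid)
})

test_that("downgrade to 1.0 needs a mappable plate geometry", {
  doc <- compact_doc(version = "1.1", seed = 37)
  out <- migrate_rdml(doc, "1.0")
  expect_identical(out$document$version, "1.0")
  expect_identical(out$document$experiments[[1]]$runs[[1]]$plateType,
                   "96-well")
  expect_true(validate_rdml(out$document)$valid)

  odd <- doc
  odd$experiments[[1]]$runs[[1]]$pcrFormat <- pcr_format(5, 5)
  expect_error(migrate_rdml(odd, "1.0"), class = "rdml_unknown_plate_type")
  out2 <- migrate_rdml(odd, "1.0",
                       plate_map = list("custom-25" = pcr_format(5, 5)))
  expect_identical(out2$document$experiments[[1]]$runs[[1]]$plateType,
                   "custom-25")
})

test_that("migrating to the current version is a no-op with an empty report", {
  doc <- compact_doc(version = "1.1", seed = 38)
  out <- migrate_rdml(doc, "1.1")
  expect_identical(nrow(out$report$actions), 0L)
  expect_length(out$report$steps, 0)
  expect_true(rdml_equal(doc, out$document))
})
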