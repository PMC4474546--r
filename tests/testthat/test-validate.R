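# Each defect class gets a mutation operator that injects exactly that
# defect into a clean fixture; the validator must flag it with the right
# code at a path inside the mutated subtree.

expect_issue <- function(report, code, path_fragment) {
  hits <- report$issues[report$issues$code == code, , drop = FALSE]
  expect_gt(nrow(hits), 0)
  expect_true(any(grepl(path_fragment, hits$path, fixed = TRUE)))
  expect_false(report$valid)
}

test_that("clean fixtures of all versions validate with zero issues", {
  for (v in rdml_versions()) {
    report <- validate_rdml(compact_doc(version = v, seed = 21))
    expect_true(report$valid)
    expect_identical(nrow(report$issues), 0L)
    expect_identical(format_validation_report(report),
                     "validation successful")
  }
})

test_that("dangling references are reported at the referring element", {
  doc <- compact_doc(seed = 22)
  doc$experiments[[1]]$runs[[1]]$reactions[[1]]$sampleRef <- "s_missing"
  report <- validate_rdml(doc)
  expect_issue(report, "dangling-reference", "react[1]")
  expect_identical(sum(report$issues$severity == "error"), 1L)

  doc2 <- compact_doc(seed = 22)
  doc2$targets[[1]]$dyeRef <- "dye_missing"
  expect_issue(validate_rdml(doc2), "dangling-reference", "target[tgt1]")

  doc3 <- compact_doc(seed = 22)
  doc3$experiments[[1]]$runs[[1]]$reactions[[2]]$data[[1]]$targetRef <- "t_missing"
  expect_issue(validate_rdml(doc3), "dangling-reference", "data[t_missing]")
})

test_that("duplicate identifiers are reported per top-level list", {
  doc <- compact_doc(seed = 23)
  doc$samples[[length(doc$samples) + 1]] <- doc$samples[[1]]
  expect_issue(validate_rdml(doc), "duplicate-id",
               sprintf("sample[%s]", doc$samples[[1]]$id))
})

test_that("targets used in reaction data need a registered dye from 1.1 on", {
  doc <- compact_doc(version = "1.1", seed = 24)
  doc$targets[[1]]$dyeRef <- NULL
  expect_issue(validate_rdml(doc), "dye-unregistered", "target[tgt1]")

  # same mutation in a 1.0 document is legal (dye was optional there)
  doc10 <- compact_doc(version = "1.0", seed = 24)
  expect_true(is.null(doc10$targets[[1]]$dyeRef))
  expect_true(validate_rdml(doc10)$valid)
})

test_that("plate-bound and uniqueness rules cover reaction positions", {
  doc <- compact_doc(seed = 25)
  doc$experiments[[1]]$runs[[1]]$reactions[[1]]$position <- 2000L
  expect_issue(validate_rdml(doc), "position-out-of-bounds", "react[2000]")

  doc2 <- compact_doc(seed = 25)
  doc2$experiments[[1]]$runs[[1]]$reactions[[2]]$position <-
    doc2$experiments[[1]]$runs[[1]]$reactions[[1]]$position
  expect_issue(validate_rdml(doc2), "duplicate-position", "react[")
})

test_that("non-monotone series are reported", {
  doc <- compact_doc(seed = 26)
  ap <- doc$experiments[[1]]$runs[[1]]$reactions[[1]]$data[[1]]$amplificationPoints
  ap$cycle[2] <- ap$cycle[5]
  doc$experiments[[1]]$runs[[1]]$reactions[[1]]$data[[1]]$amplificationPoints <- ap
  expect_issue(validate_rdml(doc), "cycles-not-increasing", "data[tgt1]")

  doc2 <- compact_doc(seed = 26)
  mp <- doc2$experiments[[1]]$runs[[1]]$reactions[[1]]$data[[1]]$meltingPoints
  mp$temperature[3] <- mp$temperature[1]
  doc2$experiments[[1]]$runs[[1]]$reactions[[1]]$data[[1]]$meltingPoints <- mp
  expect_issue(validate_rdml(doc2), "melt-not-increasing", "data[tgt1]")
})

test_that("1.2-only elements are version-gated", {
  doc <- compact_doc(version = "1.1", seed = 27)
  doc$samples[[1]]$annotations <- list(rdml_annotation("group", "a"))
  expect_issue(validate_rdml(doc), "element-wrong-version", "sample[")

  doc2 <- compact_doc(version = "1.1", seed = 27)
  doc2$targets[[1]]$amplificationEfficiency <- 1.9
  doc2$targets[[1]]$amplificationEfficiencySE <- 0.02
  expect_issue(validate_rdml(doc2), "element-wrong-version", "target[tgt1]")

  # the SE is fine on a 1.2 document
  doc3 <- compact_doc(version = "1.2", seed = 27)
  doc3$targets[[1]]$amplificationEfficiency <- 1.9
  doc3$targets[[1]]$amplificationEfficiencySE <- 0.02
  expect_true(validate_rdml(doc3)$valid)
})

test_that("vocabulary deviations are warnings, not errors", {
  doc <- compact_doc(seed = 28)
  doc$samples[[1]]$sampleType <- "mystery-token"
  report <- validate_rdml(doc)
  expect_true(report$valid)
  expect_true("unknown-enum-token" %in% report$issues$code)
  expect_true(all(report$issues$severity == "warning"))
  # warning lines still render
  expect_match(format_validation_report(report), "unknown-enum-token")
})

test_that("validation is idempotent and order-deterministic", {
  doc <- compact_doc(seed = 29)
  doc$experiments[[1]]$runs[[1]]$reactions[[1]]$sampleRef <- "ghost"
  doc$samples[[2]]$sampleType <- "odd"
  r1 <- validate_rdml(doc)
  r2 <- validate_rdml(doc)
  expect_identical(r1$issues, r2$issues)
  expect_identical(r1$valid, r2$valid)
})

test_that("multi-issue reports render one line per issue with its code", {
  doc <- compact_doc(seed = 30)
  doc$experiments[[1]]$runs[[1]]$reactions[[1]]$sampleRef <- "ghost1"
  doc$experiments[[1]]$runs[[1]]$reactions[[2]]$sampleRef <- "ghost2"
  report <- validate_rdml(doc)
  text <- format_validation_report(report)
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  expect_length(lines, nrow(report$issues))
  expect_true(all(grepl("dangling-reference", lines[grepl("ghost", lines)])))
})
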