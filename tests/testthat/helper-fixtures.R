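# Small fixture specs used across the suite. The compact spec keeps plates
# small (3-step dilution series, 16 cycles) so file-level tests stay fast;
# Cq values are pulled down so every reaction crosses threshold within the
# short cycle range.

compact_spec <- function(version = "1.2", seed = 1, noiseSd = 0.01,
                         cqNoiseSd = 0.1, ...) {
  synthetic_run_spec(
    version = version, seed = seed, cycles = 16,
    targets = list(list(id = "tgt1", trueEfficiency = 1.9,
                        cqAtUnitInput = 20, tm = 85)),
    dilutionSeries = list(topLog10Input = 4, steps = 3, foldPerStep = 10,
                          replicates = 1),
    noiseSd = noiseSd, cqNoiseSd = cqNoiseSd, ...)
}

compact_doc <- function(version = "1.2", seed = 1, ...) {
  generate_rdml_document(compact_spec(version = version, seed = seed, ...))
}

# Default study-condition document: 5-step 10-fold series in duplicate,
# one unknown, one NTC, 40 cycles.
standard_doc <- function(version = "1.2", seed = 1, ...) {
  generate_rdml_document(synthetic_run_spec(version = version, seed = seed,
                                            ...))
}

write_tmp <- function(doc, ...) {
  path <- tempfile(fileext = ".rdml")
  write_rdml(doc, path, ...)
  path
}

read_file_bytes <- function(path) readBin(path, "raw", n = file.size(path))
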