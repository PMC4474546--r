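# Minimal zip container support.
#
# RDML files are zip archives holding one XML document. Archives written
# here are byte-deterministic: fixed DOS timestamp, fixed flags, stable
# member order. Compression is raw deflate (the zlib wrapper produced by
# memCompress is stripped); CRC-32 is computed in R. Reading goes through
# utils::unzip, which needs no external binary.

crc32_table <- local({
  tab <- integer(256)
  for (i in 0:255) {
    c <- as.integer(i)
    for (k in 1:8) {
      c <- if (bitwAnd(c, 1L) != 0L) {
        bitwXor(bitwShiftR(c, 1L), -306674912L)  # 0xEDB88320
      } else {
        bitwShiftR(c, 1L)
      }
    }
    tab[i + 1] <- c
  }
  tab
})

crc32 <- function(bytes) {
  crc <- -1L
  tab <- crc32_table
  for (b in as.integer(bytes)) {
    crc <- bitwXor(bitwShiftR(crc, 8L),
                   tab[bitwAnd(bitwXor(crc, b), 255L) + 1L])
  }
  crc <- bitwXor(crc, -1L)
  if (crc < 0) crc + 2^32 else as.numeric(crc)
}

le_bytes <- function(x, n) {
  x <- as.numeric(x)
  out <- raw(n)
  for (i in seq_len(n)) {
    out[i] <- as.raw(x %% 256)
    x <- x %/% 256
  }
  out
}

raw_deflate <- function(bytes) {
  z <- memCompress(bytes, type = "gzip")  # zlib stream: 2-byte hdr + adler32
  z[3:(length(z) - 4)]
}

# Fixed DOS timestamp: 2014-10-01 12:00:00 (any constant works; this one is
# the release season of format version 1.2).
dos_time <- bitwOr(bitwOr(bitwShiftL(12L, 11L), bitwShiftL(0L, 5L)), 0L)
dos_date <- bitwOr(bitwOr(bitwShiftL(34L, 9L), bitwShiftL(10L, 5L)), 1L)

zip_write_single <- function(path, entry_name, bytes) {
  crc <- crc32(bytes)
  comp <- raw_deflate(bytes)
  method <- 8L
  if (length(comp) >= length(bytes)) {  # incompressible: store
    comp <- bytes
    method <- 0L
  }
  name_raw <- charToRaw(entry_name)
  local_hdr <- c(
    le_bytes(0x04034b50, 4), le_bytes(20, 2), le_bytes(0, 2),
    le_bytes(method, 2), le_bytes(dos_time, 2), le_bytes(dos_date, 2),
    le_bytes(crc, 4), le_bytes(length(comp), 4), le_bytes(length(bytes), 4),
    le_bytes(length(name_raw), 2), le_bytes(0, 2), name_raw)
  central <- c(
    le_bytes(0x02014b50, 4), le_bytes(20, 2), le_bytes(20, 2),
    le_bytes(0, 2), le_bytes(method, 2),
    le_bytes(dos_time, 2), le_bytes(dos_date, 2),
    le_bytes(crc, 4), le_bytes(length(comp), 4), le_bytes(length(bytes), 4),
    le_bytes(length(name_raw), 2), le_bytes(0, 2), le_bytes(0, 2),
    le_bytes(0, 2), le_bytes(0, 2), le_bytes(0, 4), le_bytes(0, 4),
    name_raw)
  cd_offset <- length(local_hdr) + length(comp)
  eocd <- c(
    le_bytes(0x06054b50, 4), le_bytes(0, 2), le_bytes(0, 2),
    le_bytes(1, 2), le_bytes(1, 2),
    le_bytes(length(central), 4), le_bytes(cd_offset, 4), le_bytes(0, 2))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(local_hdr, comp, central, eocd), con)
  invisible(path)
}

is_zip_bytes <- function(bytes) {
  length(bytes) >= 4 && bytes[1] == as.raw(0x50) && bytes[2] == as.raw(0x4b)
}

# Returns list(xml_bytes, entry_name) from a zip file on disk.
zip_read_xml_member <- function(path) {
  listing <- tryCatch(utils::unzip(path, list = TRUE),
                      error = function(e) NULL,
                      warning = function(w) NULL)
  if (is.null(listing) || nrow(listing) == 0) {
    rdml_abort(sprintf("'%s' is not a readable zip archive", path),
               "rdml_malformed_file")
  }
  xml_members <- listing$Name[grepl("\\.xml$", listing$Name, ignore.case = TRUE)]
  if (length(xml_members) == 0) {
    rdml_abort(sprintf("zip archive '%s' contains no XML member", path),
               "rdml_malformed_file")
  }
  entry <- if ("rdml_data.xml" %in% xml_members) {
    "rdml_data.xml"
  } else {
    warning(sprintf(
      "canonical member 'rdml_data.xml' absent; using '%s'", xml_members[1]),
      call. = FALSE)
    xml_members[1]
  }
  size <- listing$Length[listing$Name == entry][1]
  con <- unz(path, entry, open = "rb")
  on.exit(close(con))
  bytes <- readBin(con, "raw", n = size + 16)
  list(xml_bytes = bytes, entry_name = entry)
}
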