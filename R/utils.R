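# Internal helpers: GUIDs, blank handling, and a minimal ZIP writer for the
# Darwin Core Archive exporter.

# Version-4 UUIDs drawn from the R RNG, so catalogue construction is fully
# reproducible under set.seed().
new_guid <- function(n = 1) {
  vapply(seq_len(n), function(i) {
    hx <- sample(c(0:9, letters[1:6]), 32, replace = TRUE)
    hx[13] <- "4"
    hx[17] <- sample(c("8", "9", "a", "b"), 1)
    paste0(
      paste(hx[1:8], collapse = ""), "-", paste(hx[9:12], collapse = ""), "-",
      paste(hx[13:16], collapse = ""), "-", paste(hx[17:20], collapse = ""), "-",
      paste(hx[21:32], collapse = "")
    )
  }, character(1))
}

is_blank <- function(x) is.na(x) | !nzchar(trimws(as.character(x)))

`%||%` <- function(a, b) if (is.null(a)) b else a

blank_to_na <- function(x) {
  x <- as.character(x)
  x[!is.na(x) & !nzchar(trimws(x))] <- NA_character_
  x
}

na_to_blank <- function(x) ifelse(is.na(x), "", as.character(x))

# --- minimal ZIP writer -----------------------------------------------------
#
# Writes a standard ZIP archive with deflate-compressed entries; no external
# zip binary is needed. memCompress(type = "gzip") yields a zlib container
# (2-byte header, deflate data, 4-byte Adler-32), so the raw deflate stream
# is sliced from it and the CRC-32 each ZIP entry needs is computed here
# (table-driven, reflected polynomial 0xEDB88320). Archives read back with
# unzip(1) and base R's internal unzip.

crc32_table <- local({
  tab <- NULL
  function() {
    if (is.null(tab)) {
      t <- integer(256)
      for (i in 0:255) {
        c <- i
        for (k in 1:8) {
          c <- if (bitwAnd(c, 1L) != 0L) {
            bitwXor(bitwShiftR(c, 1L), -306674912L)  # 0xEDB88320
          } else {
            bitwShiftR(c, 1L)
          }
        }
        t[i + 1] <- c
      }
      tab <<- t
    }
    tab
  }
})

crc32 <- function(data) {
  tab <- crc32_table()
  crc <- -1L  # 0xFFFFFFFF
  for (b in as.integer(data)) {
    crc <- bitwXor(bitwShiftR(crc, 8L), tab[bitwAnd(bitwXor(crc, b), 255L) + 1L])
  }
  crc <- bitwXor(crc, -1L)
  if (crc < 0) as.numeric(crc) + 2^32 else as.numeric(crc)
}

int_le <- function(value, bytes) {
  out <- raw(bytes)
  for (i in seq_len(bytes)) {
    out[i] <- as.raw(value %% 256)
    value <- value %/% 256
  }
  out
}

write_zip <- function(files, zipfile, root_dir) {
  stopifnot(length(files) > 0)
  con <- file(zipfile, "wb")
  on.exit(close(con), add = TRUE)
  dostime <- int_le(0, 4)  # fixed timestamp: archives are content-addressed
  centrals <- list()
  offset <- 0
  for (name in files) {
    path <- file.path(root_dir, name)
    data <- readBin(path, "raw", file.info(path)$size)
    gz <- memCompress(data, type = "gzip")
    deflated <- gz[3:(length(gz) - 4)]  # strip zlib header and Adler-32
    crc <- int_le(crc32(data), 4)
    name_raw <- charToRaw(name)
    local <- c(
      as.raw(c(0x50, 0x4b, 0x03, 0x04)), int_le(20, 2), int_le(0, 2),
      int_le(8, 2), dostime, crc,
      int_le(length(deflated), 4), int_le(length(data), 4),
      int_le(length(name_raw), 2), int_le(0, 2), name_raw
    )
    writeBin(local, con)
    writeBin(deflated, con)
    centrals[[name]] <- list(
      crc = crc, csize = length(deflated), usize = length(data),
      name_raw = name_raw, offset = offset
    )
    offset <- offset + length(local) + length(deflated)
  }
  cd_start <- offset
  cd_len <- 0
  for (e in centrals) {
    central <- c(
      as.raw(c(0x50, 0x4b, 0x01, 0x02)), int_le(20, 2), int_le(20, 2),
      int_le(0, 2), int_le(8, 2), dostime, e$crc,
      int_le(e$csize, 4), int_le(e$usize, 4),
      int_le(length(e$name_raw), 2), int_le(0, 2), int_le(0, 2),
      int_le(0, 2), int_le(0, 2), int_le(0, 4), int_le(e$offset, 4),
      e$name_raw
    )
    writeBin(central, con)
    cd_len <- cd_len + length(central)
  }
  eocd <- c(
    as.raw(c(0x50, 0x4b, 0x05, 0x06)), int_le(0, 2), int_le(0, 2),
    int_le(length(centrals), 2), int_le(length(centrals), 2),
    int_le(cd_len, 4), int_le(cd_start, 4), int_le(0, 2)
  )
  writeBin(eocd, con)
  invisible(zipfile)
}
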