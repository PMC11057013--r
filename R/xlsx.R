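# Minimal Office Open XML spreadsheet writer. The environment provides no
# xlsx package and no external zip binary, so this writes a valid .xlsx
# container directly: a stored (uncompressed) PKZIP archive of the minimal
# OOXML part set, with CRC-32 computed in R. Numbers are typed cells,
# strings are inline strings; one sheet, no styling.

crc32table <- local({
  tab <- NULL
  function() {
    if (is.null(tab)) {
      t0 <- integer(256)
      for (n in 0:255) {
        c <- n
        for (k in 1:8)
          c <- if (bitwAnd(c, 1L) != 0L)
            bitwXor(-306674912L, bitwShiftR(c, 1) %&% 0x7FFFFFFF) else
              bitwShiftR(c, 1) %&% 0x7FFFFFFF
        t0[n + 1] <- c
      }
      tab <<- t0
    }
    tab
  }
})

`%&%` <- function(a, b) bitwAnd(a, as.integer(b))

crc32 <- function(raw) {
  tab <- crc32table()
  c <- -1L
  for (byte in as.integer(raw)) {
    idx <- bitwAnd(bitwXor(c, byte), 255L)
    c <- bitwXor(bitwShiftR(c, 8) %&% 0x00FFFFFF, tab[idx + 1])
  }
  bitwXor(c, -1L)
}

writeU16 <- function(con, x) writeBin(as.integer(x), con, size = 2, endian = "little")
writeU32 <- function(con, x) writeBin(as.integer(x), con, size = 4, endian = "little")

writeStoredZip <- function(entries, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  offsets <- integer(length(entries))
  crcs <- integer(length(entries))
  pos <- 0L
  for (i in seq_along(entries)) {
    name <- charToRaw(names(entries)[i])
    data <- entries[[i]]
    crcs[i] <- crc32(data)
    offsets[i] <- pos
    writeU32(con, 0x04034b50)
    writeU16(con, 20); writeU16(con, 0); writeU16(con, 0)   # version/flags/method
    writeU16(con, 0); writeU16(con, 0x2821)                  # time, date (2000-01-01)
    writeU32(con, crcs[i]); writeU32(con, length(data)); writeU32(con, length(data))
    writeU16(con, length(name)); writeU16(con, 0)
    writeBin(name, con); writeBin(data, con)
    pos <- pos + 30L + length(name) + length(data)
  }
  cd_start <- pos
  for (i in seq_along(entries)) {
    name <- charToRaw(names(entries)[i])
    data <- entries[[i]]
    writeU32(con, 0x02014b50)
    writeU16(con, 20); writeU16(con, 20); writeU16(con, 0); writeU16(con, 0)
    writeU16(con, 0); writeU16(con, 0x2821)
    writeU32(con, crcs[i]); writeU32(con, length(data)); writeU32(con, length(data))
    writeU16(con, length(name)); writeU16(con, 0); writeU16(con, 0)
    writeU16(con, 0); writeU16(con, 0); writeU32(con, 0); writeU32(con, offsets[i])
    writeBin(name, con)
    pos <- pos + 46L + length(name)
  }
  writeU32(con, 0x06054b50)
  writeU16(con, 0); writeU16(con, 0)
  writeU16(con, length(entries)); writeU16(con, length(entries))
  writeU32(con, pos - cd_start); writeU32(con, cd_start); writeU16(con, 0)
  invisible(path)
}

xmlEscape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

colLetter <- function(j) {
  s <- ""
  while (j > 0) { r <- (j - 1) %% 26; s <- paste0(LETTERS[r + 1], s); j <- (j - 1) %/% 26 }
  s
}

writeMinimalXlsx <- function(df, path) {
  rows <- character(nrow(df) + 1L)
  hdr <- vapply(seq_along(df), function(j)
    sprintf('<c r="%s1" t="inlineStr"><is><t>%s</t></is></c>',
            colLetter(j), xmlEscape(names(df)[j])), "")
  rows[1] <- sprintf('<row r="1">%s</row>', paste(hdr, collapse = ""))
  for (i in seq_len(nrow(df))) {
    cells <- vapply(seq_along(df), function(j) {
      v <- df[i, j]
      ref <- paste0(colLetter(j), i + 1L)
      if (is.numeric(v))
        sprintf('<c r="%s" t="n"><v>%s</v></c>', ref,
                format(v, digits = 15, scientific = FALSE))
      else
        sprintf('<c r="%s" t="inlineStr"><is><t>%s</t></is></c>', ref,
                xmlEscape(as.character(v)))
    }, "")
    rows[i + 1L] <- sprintf('<row r="%d">%s</row>', i + 1L,
                            paste(cells, collapse = ""))
  }
  sheet <- paste0('<?xml version="1.0" encoding="UTF-8" standalone="yes"?>',
    '<worksheet xmlns="http://schemas.openxmlformats.org/spreadsheetml/2006/main">',
    '<sheetData>', paste(rows, collapse = ""), '</sheetData></worksheet>')
  wb <- paste0('<?xml version="1.0" encoding="UTF-8" standalone="yes"?>',
    '<workbook xmlns="http://schemas.openxmlformats.org/spreadsheetml/2006/main" ',
    'xmlns:r="http://schemas.openxmlformats.org/officeDocument/2006/relationships">',
    '<sheets><sheet name="grading" sheetId="1" r:id="rId1"/></sheets></workbook>')
  wbrels <- paste0('<?xml version="1.0" encoding="UTF-8" standalone="yes"?>',
    '<Relationships xmlns="http://schemas.openxmlformats.org/package/2006/relationships">',
    '<Relationship Id="rId1" ',
    'Type="http://schemas.openxmlformats.org/officeDocument/2006/relationships/worksheet" ',
    'Target="worksheets/sheet1.xml"/></Relationships>')
  rels <- paste0('<?xml version="1.0" encoding="UTF-8" standalone="yes"?>',
    '<Relationships xmlns="http://schemas.openxmlformats.org/package/2006/relationships">',
    '<Relationship Id="rId1" ',
    'Type="http://schemas.openxmlformats.org/officeDocument/2006/relationships/officeDocument" ',
    'Target="xl/workbook.xml"/></Relationships>')
  ct <- paste0('<?xml version="1.0" encoding="UTF-8" standalone="yes"?>',
    '<Types xmlns="http://schemas.openxmlformats.org/package/2006/content-types">',
    '<Default Extension="rels" ContentType="application/vnd.openxmlformats-package.relationships+xml"/>',
    '<Default Extension="xml" ContentType="application/xml"/>',
    '<Override PartName="/xl/workbook.xml" ContentType="application/vnd.openxmlformats-officedocument.spreadsheetml.sheet.main+xml"/>',
    '<Override PartName="/xl/worksheets/sheet1.xml" ContentType="application/vnd.openxmlformats-officedocument.spreadsheetml.worksheet+xml"/>',
    '</Types>')
  entries <- list(
    "[Content_Types].xml" = charToRaw(ct),
    "_rels/.rels" = charToRaw(rels),
    "xl/workbook.xml" = charToRaw(wb),
    "xl/_rels/workbook.xml.rels" = charToRaw(wbrels),
    "xl/worksheets/sheet1.xml" = charToRaw(sheet))
  writeStoredZip(entries, path)
}
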