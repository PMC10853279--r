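## Minimal ZIP-container and .xlsx writers used by the synthetic fixture
## generator. Entries are stored uncompressed, with fixed timestamps so
## generated fixtures are byte-identical across runs. Reading of .xlsx
## goes through readxl; these writers exist only to produce test inputs.

.CRC32_TABLE <- local({
  poly <- -306674912L # 0xEDB88320 in two's complement
  tab <- integer(256)
  for (i in 0:255) {
    c <- i
    for (k in 1:8) {
      c <- if (bitwAnd(c, 1L) != 0L) bitwXor(bitwShiftR(c, 1L), poly) else bitwShiftR(c, 1L)
    }
    tab[i + 1L] <- c
  }
  tab
})

crc32 <- function(bytes) {
  crc <- -1L
  for (b in as.integer(bytes)) {
    crc <- bitwXor(bitwShiftR(crc, 8L),
                   .CRC32_TABLE[bitwAnd(bitwXor(crc, b), 255L) + 1L])
  }
  bitwXor(crc, -1L)
}

u16 <- function(x) writeBin(as.integer(x), raw(), size = 2, endian = "little")
u32 <- function(x) writeBin(as.integer(x), raw(), size = 4, endian = "little")

## Write `entries` (named list: entry path -> raw content) as a stored
## (uncompressed) ZIP file. Readable by utils::unzip and by any
## spreadsheet reader.
write_zip_stored <- function(entries, zipfile) {
  con <- file(zipfile, "wb")
  on.exit(close(con))
  offsets <- integer(length(entries))
  crcs <- integer(length(entries))
  pos <- 0L
  for (i in seq_along(entries)) {
    name <- charToRaw(names(entries)[[i]])
    data <- entries[[i]]
    crcs[[i]] <- crc32(data)
    offsets[[i]] <- pos
    local_hdr <- c(
      u32(0x04034b50), u16(20L), u16(0L), u16(0L), u16(0L), u16(0L),
      u32(crcs[[i]]), u32(length(data)), u32(length(data)),
      u16(length(name)), u16(0L)
    )
    writeBin(local_hdr, con)
    writeBin(name, con)
    writeBin(data, con)
    pos <- pos + length(local_hdr) + length(name) + length(data)
  }
  cd_start <- pos
  cd_size <- 0L
  for (i in seq_along(entries)) {
    name <- charToRaw(names(entries)[[i]])
    data <- entries[[i]]
    central <- c(
      u32(0x02014b50), u16(20L), u16(20L), u16(0L), u16(0L), u16(0L), u16(0L),
      u32(crcs[[i]]), u32(length(data)), u32(length(data)),
      u16(length(name)), u16(0L), u16(0L), u16(0L), u16(0L),
      u32(0L), u32(offsets[[i]])
    )
    writeBin(central, con)
    writeBin(name, con)
    cd_size <- cd_size + length(central) + length(name)
  }
  eocd <- c(
    u32(0x06054b50), u16(0L), u16(0L),
    u16(length(entries)), u16(length(entries)),
    u32(cd_size), u32(cd_start), u16(0L)
  )
  writeBin(eocd, con)
  invisible(zipfile)
}

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

col_letter <- function(j) {
  out <- ""
  while (j > 0) {
    out <- paste0(LETTERS[(j - 1) %% 26 + 1], out)
    j <- (j - 1) %/% 26
  }
  out
}

## Single-sheet .xlsx with every cell as an inline string; `df` is coerced
## to character column-wise.
write_minimal_xlsx <- function(df, path) {
  df <- as.data.frame(lapply(df, as.character), check.names = FALSE,
                      stringsAsFactors = FALSE)
  cellrow <- function(r, values) {
    cells <- vapply(seq_along(values), function(j) {
      if (is.na(values[[j]])) return("")
      sprintf('<c r="%s%d" t="inlineStr"><is><t>%s</t></is></c>',
              col_letter(j), r, xml_escape(values[[j]]))
    }, "")
    sprintf('<row r="%d">%s</row>', r, paste(cells, collapse = ""))
  }
  rows <- c(
    cellrow(1L, names(df)),
    vapply(seq_len(nrow(df)), function(i) cellrow(i + 1L, unlist(df[i, ], use.names = FALSE)), "")
  )
  sheet <- paste0(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>',
    '<worksheet xmlns="http://schemas.openxmlformats.org/spreadsheetml/2006/main">',
    '<sheetData>', paste(rows, collapse = ""), '</sheetData></worksheet>'
  )
  entries <- list(
    "[Content_Types].xml" = charToRaw(paste0(
      '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>',
      '<Types xmlns="http://schemas.openxmlformats.org/package/2006/content-types">',
      '<Default Extension="rels" ContentType="application/vnd.openxmlformats-package.relationships+xml"/>',
      '<Default Extension="xml" ContentType="application/xml"/>',
      '<Override PartName="/xl/workbook.xml" ContentType="application/vnd.openxmlformats-officedocument.spreadsheetml.sheet.main+xml"/>',
      '<Override PartName="/xl/worksheets/sheet1.xml" ContentType="application/vnd.openxmlformats-officedocument.spreadsheetml.worksheet+xml"/>',
      '</Types>'
    )),
    "_rels/.rels" = charToRaw(paste0(
      '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>',
      '<Relationships xmlns="http://schemas.openxmlformats.org/package/2006/relationships">',
      '<Relationship Id="rId1" Type="http://schemas.openxmlformats.org/officeDocument/2006/relationships/officeDocument" Target="xl/workbook.xml"/>',
      '</Relationships>'
    )),
    "xl/workbook.xml" = charToRaw(paste0(
      '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>',
      '<workbook xmlns="http://schemas.openxmlformats.org/spreadsheetml/2006/main" ',
      'xmlns:r="http://schemas.openxmlformats.org/officeDocument/2006/relationships">',
      '<sheets><sheet name="Sheet1" sheetId="1" r:id="rId1"/></sheets></workbook>'
    )),
    "xl/_rels/workbook.xml.rels" = charToRaw(paste0(
      '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>',
      '<Relationships xmlns="http://schemas.openxmlformats.org/package/2006/relationships">',
      '<Relationship Id="rId1" Type="http://schemas.openxmlformats.org/officeDocument/2006/relationships/worksheet" Target="worksheets/sheet1.xml"/>',
      '</Relationships>'
    )),
    "xl/worksheets/sheet1.xml" = charToRaw(sheet)
  )
  write_zip_stored(entries, path)
}

## Zip a directory tree (stored entries, deterministic order); fixture-side
## counterpart of extract_archive.
zip_directory <- function(dir, zipfile) {
  rel <- sort(list.files(dir, recursive = TRUE))
  entries <- stats::setNames(
    lapply(rel, function(r) readBin(file.path(dir, r), "raw", file.size(file.path(dir, r)))),
    rel
  )
  write_zip_stored(entries, zipfile)
}
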