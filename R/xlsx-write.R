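# Minimal XLSX writer.
#
# The template readers accept .xlsx workbooks, and the fixture generator has
# to be able to emit them.  No installed package writes xlsx, so this file
# implements the smallest conforming subset of SpreadsheetML: one worksheet
# per data frame, inline strings, numbers as <v>, no shared strings, no
# styles.  Entries are stored uncompressed in the zip container (CRC-32 via
# digest), which every unzip implementation and readxl accept.

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

xlsx_col_letter <- function(j) {
  s <- ""
  while (j > 0) {
    r <- (j - 1) %% 26
    s <- paste0(LETTERS[r + 1], s)
    j <- (j - 1) %/% 26
  }
  s
}

xlsx_sheet_xml <- function(df) {
  stopifnot(is.data.frame(df))
  cols <- vapply(seq_along(df), xlsx_col_letter, "")
  fmt_cell <- function(v, ref) {
    if (is.na(v)) return(sprintf('<c r="%s"/>', ref))
    if (is.numeric(v)) {
      sprintf('<c r="%s"><v>%s</v></c>', ref,
              format(v, digits = 17, scientific = FALSE, trim = TRUE))
    } else {
      sprintf('<c r="%s" t="inlineStr"><is><t>%s</t></is></c>', ref,
              xml_escape(as.character(v)))
    }
  }
  header <- vapply(seq_along(df), function(j) {
    sprintf('<c r="%s1" t="inlineStr"><is><t>%s</t></is></c>',
            cols[j], xml_escape(names(df)[j]))
  }, "")
  rows <- sprintf('<row r="1">%s</row>', paste(header, collapse = ""))
  for (i in seq_len(nrow(df))) {
    cells <- vapply(seq_along(df), function(j) {
      v <- df[[j]][i]
      if (inherits(v, "Date")) v <- format(v, "%Y-%m-%d")
      fmt_cell(v, paste0(cols[j], i + 1))
    }, "")
    rows <- c(rows, sprintf('<row r="%d">%s</row>', i + 1,
                            paste(cells, collapse = "")))
  }
  paste0('<?xml version="1.0" encoding="UTF-8" standalone="yes"?>\n',
         '<worksheet xmlns="http://schemas.openxmlformats.org/spreadsheetml/2006/main">',
         '<sheetData>', paste(rows, collapse = ""), '</sheetData></worksheet>')
}

zip_u16 <- function(x) as.raw(c(x %% 256, (x %/% 256) %% 256))
zip_u32 <- function(x) {
  x <- as.numeric(x)
  as.raw(c(x %% 256, (x %/% 256) %% 256, (x %/% 65536) %% 256,
           (x %/% 16777216) %% 256))
}

zip_crc32 <- function(data) {
  hex <- digest::digest(data, algo = "crc32", serialize = FALSE)
  hex <- formatC(hex, width = 8, flag = "0")
  sum(strtoi(substring(hex, c(1, 3, 5, 7), c(2, 4, 6, 8)), 16L) *
        c(16777216, 65536, 256, 1))
}

# files: named list of raw vectors; all entries stored (method 0)
zip_write_stored <- function(files, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  centrals <- vector("list", length(files))
  off <- 0
  for (i in seq_along(files)) {
    nm <- names(files)[i]
    data <- files[[i]]
    crc <- zip_crc32(data)
    name_raw <- charToRaw(nm)
    lfh <- c(zip_u32(67324752), zip_u16(20), zip_u16(0), zip_u16(0),
             zip_u16(0), zip_u16(0), zip_u32(crc), zip_u32(length(data)),
             zip_u32(length(data)), zip_u16(length(name_raw)), zip_u16(0))
    writeBin(c(lfh, name_raw, data), con)
    centrals[[i]] <- c(zip_u32(33639248), zip_u16(20), zip_u16(20),
                       zip_u16(0), zip_u16(0), zip_u16(0), zip_u16(0),
                       zip_u32(crc), zip_u32(length(data)),
                       zip_u32(length(data)), zip_u16(length(name_raw)),
                       zip_u16(0), zip_u16(0), zip_u16(0), zip_u16(0),
                       zip_u32(0), zip_u32(off), name_raw)
    off <- off + length(lfh) + length(name_raw) + length(data)
  }
  cd <- do.call(c, centrals)
  writeBin(cd, con)
  writeBin(c(zip_u32(101010256), zip_u16(0), zip_u16(0),
             zip_u16(length(files)), zip_u16(length(files)),
             zip_u32(length(cd)), zip_u32(off), zip_u16(0)), con)
  invisible(path)
}

#' Write a plain XLSX workbook
#'
#' Writes a named list of data frames as one worksheet each, in the minimal
#' SpreadsheetML dialect used by the package templates (header row, inline
#' strings, ISO dates as text).  Intended for emitting template files and
#' synthetic fixtures; not a general spreadsheet writer (no styles, formulas
#' or merged cells).
#'
#' @param sheets named list of data frames; names become sheet names.
#' @param path output file path (`.xlsx`).
#' @return `path`, invisibly.
#' @export
#' @examples
#' f <- tempfile(fileext = ".xlsx")
#' write_xlsx_template(list(Data = data.frame(x = 1:3)), f)
write_xlsx_template <- function(sheets, path) {
  stopifnot(is.list(sheets), length(sheets) >= 1, !is.null(names(sheets)))
  n <- length(sheets)
  ct <- paste0(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>\n',
    '<Types xmlns="http://schemas.openxmlformats.org/package/2006/content-types">',
    '<Default Extension="rels" ContentType="application/vnd.openxmlformats-package.relationships+xml"/>',
    '<Default Extension="xml" ContentType="application/xml"/>',
    '<Override PartName="/xl/workbook.xml" ContentType="application/vnd.openxmlformats-officedocument.spreadsheetml.sheet.main+xml"/>',
    paste(sprintf('<Override PartName="/xl/worksheets/sheet%d.xml" ContentType="application/vnd.openxmlformats-officedocument.spreadsheetml.worksheet+xml"/>',
                  seq_len(n)), collapse = ""),
    '</Types>')
  root_rels <- paste0(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>\n',
    '<Relationships xmlns="http://schemas.openxmlformats.org/package/2006/relationships">',
    '<Relationship Id="rId1" Type="http://schemas.openxmlformats.org/officeDocument/2006/relationships/officeDocument" Target="xl/workbook.xml"/>',
    '</Relationships>')
  wb <- paste0(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>\n',
    '<workbook xmlns="http://schemas.openxmlformats.org/spreadsheetml/2006/main" ',
    'xmlns:r="http://schemas.openxmlformats.org/officeDocument/2006/relationships"><sheets>',
    paste(sprintf('<sheet name="%s" sheetId="%d" r:id="rId%d"/>',
                  xml_escape(names(sheets)), seq_len(n), seq_len(n)),
          collapse = ""),
    '</sheets></workbook>')
  wb_rels <- paste0(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>\n',
    '<Relationships xmlns="http://schemas.openxmlformats.org/package/2006/relationships">',
    paste(sprintf('<Relationship Id="rId%d" Type="http://schemas.openxmlformats.org/officeDocument/2006/relationships/worksheet" Target="worksheets/sheet%d.xml"/>',
                  seq_len(n), seq_len(n)), collapse = ""),
    '</Relationships>')
  files <- c(
    list("[Content_Types].xml" = charToRaw(ct),
         "_rels/.rels" = charToRaw(root_rels),
         "xl/workbook.xml" = charToRaw(wb),
         "xl/_rels/workbook.xml.rels" = charToRaw(wb_rels)),
    setNames(lapply(sheets, function(df) charToRaw(xlsx_sheet_xml(df))),
             sprintf("xl/worksheets/sheet%d.xml", seq_len(n))))
  zip_write_stored(files, path)
}
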