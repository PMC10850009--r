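# Template readers for the four workbook dialects (homogeneity, stability,
# certification, long-term stability).  Each dialect exists in two
# serializations with identical content:
#   *.xlsx  -- sheet "Data" (header row + records) and optional sheet "Meta"
#              (two columns: key, value)
#   *.csv   -- leading "# key: value" comment lines for metadata, then the
#              same header row + records
# Values are immutable after import; the source file name is retained so that
# the provenance of every record can be traced back to the original upload.

read_template_file <- function(path) {
  if (!file.exists(path)) stop_format("file not found: %s", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "xlsx") {
    sheets <- readxl::excel_sheets(path)
    data_sheet <- if ("Data" %in% sheets) "Data" else sheets[1]
    data <- readxl::read_excel(path, sheet = data_sheet,
                               col_types = "text", .name_repair = "minimal")
    meta <- character(0)
    if ("Meta" %in% sheets) {
      m <- readxl::read_excel(path, sheet = "Meta", col_types = "text")
      if (ncol(m) >= 2) meta <- setNames(as.character(m[[2]]), as.character(m[[1]]))
    }
    list(data = as_tibble(data), meta = meta)
  } else if (ext %in% c("csv", "tsv", "txt")) {
    lines <- readr::read_lines(path)
    is_meta <- grepl("^#", lines)
    meta_lines <- sub("^#\\s*", "", lines[is_meta & cumsum(!is_meta) == 0])
    kv <- regmatches(meta_lines, regexec("^([^:]+):\\s*(.*)$", meta_lines))
    kv <- kv[lengths(kv) == 3]
    meta <- setNames(trimws(vapply(kv, `[`, "", 3)),
                     trimws(vapply(kv, `[`, "", 2)))
    body <- lines[!grepl("^#", lines)]
    body <- body[nzchar(trimws(body))]
    if (length(body) == 0) {
      return(list(data = tibble(), meta = meta))
    }
    delim <- if (ext == "tsv") "\t" else ","
    data <- readr::read_delim(I(paste(body, collapse = "\n")), delim = delim,
                              col_types = readr::cols(.default = "c"),
                              show_col_types = FALSE, progress = FALSE)
    list(data = as_tibble(data), meta = meta)
  } else {
    stop_format("unsupported file type '%s' (expected .xlsx or .csv): %s", ext, path)
  }
}

require_columns <- function(df, cols, path) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    stop_format("file '%s' is missing required column(s): %s",
                basename(path), paste(missing, collapse = ", "))
  }
  invisible(df)
}

parse_numeric_column <- function(x, column, path) {
  v <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(v) & !is.na(x) & nzchar(trimws(x)))
  if (length(bad) > 0) {
    stop_format("non-numeric value '%s' in column '%s', data row %d of '%s'",
                x[bad[1]], column, bad[1], basename(path))
  }
  if (anyNA(v)) {
    stop_format("missing value in column '%s', data row %d of '%s'",
                column, which(is.na(v))[1], basename(path))
  }
  v
}

check_unit_consistency <- function(df, path) {
  if (!"unit" %in% names(df)) return(invisible(df))
  bad <- df |>
    group_by(.data$analyte) |>
    summarise(k = dplyr::n_distinct(.data$unit), .groups = "drop") |>
    filter(.data$k > 1)
  if (nrow(bad) > 0) {
    stop_format("mixed units for analyte '%s' in '%s'", bad$analyte[1], basename(path))
  }
  invisible(df)
}

#' Read a homogeneity study workbook
#'
#' Reads the homogeneity template: one record per individual measurement with
#' columns `analyte`, `unit` (optional), `bottle`, `replicate` and `value`.
#' The design is the nested homogeneity layout, N bottles drawn from the batch
#' and measured n times each under repeatability conditions.
#'
#' @param path path to an `.xlsx` or `.csv` file in the homogeneity dialect.
#' @return a tibble with columns `analyte`, `unit`, `bottle`, `replicate`
#'   (integer) and `value` (numeric), carrying the source file name in
#'   attribute `source_file`.
#' @export
read_homogeneity <- function(path) {
  parsed <- read_template_file(path)
  df <- parsed$data
  if (nrow(df) == 0) stop_format("no data records found in '%s'", basename(path))
  require_columns(df, c("analyte", "bottle", "replicate", "value"), path)
  out <- tibble(
    analyte = as.character(df$analyte),
    unit = if ("unit" %in% names(df)) as.character(df$unit) else NA_character_,
    bottle = as.character(df$bottle),
    replicate = as.integer(parse_numeric_column(df$replicate, "replicate", path)),
    value = parse_numeric_column(df$value, "value", path)
  )
  check_finite(out$value, "value")
  if (any(out$replicate < 1)) stop_format("replicate indices must be positive in '%s'", basename(path))
  check_unit_consistency(out, path)
  n_bottles <- out |>
    group_by(.data$analyte) |>
    summarise(k = dplyr::n_distinct(.data$bottle), .groups = "drop")
  if (any(n_bottles$k < 2)) {
    stop_validation("analyte '%s' has fewer than 2 bottles in '%s'",
                    n_bottles$analyte[which(n_bottles$k < 2)[1]], basename(path))
  }
  attr(out, "source_file") <- basename(path)
  out
}

#' Read a stability study workbook
#'
#' Reads the stability template: dated measurements per analyte with columns
#' `analyte`, `unit` (optional), `date` (ISO-8601 day), `value` and an
#' optional `temperature` column (degrees Celsius).  When the temperature
#' column is present the file is interpreted as an accelerated (Arrhenius)
#' study with one measurement series per storage temperature; otherwise it is
#' a classical stability series per analyte.
#'
#' @param path path to an `.xlsx` or `.csv` file in the stability dialect.
#' @return a tibble with columns `analyte`, `unit`, `date` (`Date`), `value`
#'   and `temperature` (numeric, `NA` when absent), with attributes
#'   `source_file` and `arrhenius` (logical).
#' @export
read_stability <- function(path) {
  parsed <- read_template_file(path)
  df <- parsed$data
  if (nrow(df) == 0) stop_format("no data records found in '%s'", basename(path))
  require_columns(df, c("analyte", "date", "value"), path)
  has_temp <- "temperature" %in% names(df)
  out <- tibble(
    analyte = as.character(df$analyte),
    unit = if ("unit" %in% names(df)) as.character(df$unit) else NA_character_,
    date = parse_iso_date(df$date),
    value = parse_numeric_column(df$value, "value", path),
    temperature = if (has_temp) parse_numeric_column(df$temperature, "temperature", path)
                  else NA_real_
  )
  check_finite(out$value, "value")
  check_unit_consistency(out, path)
  if (!has_temp) {
    counts <- out |>
      group_by(.data$analyte) |>
      summarise(k = dplyr::n_distinct(.data$date), .groups = "drop")
    if (any(counts$k < 3)) {
      stop_validation("analyte '%s' has fewer than 3 distinct dates in '%s' (no regression possible)",
                      counts$analyte[which(counts$k < 3)[1]], basename(path))
    }
  } else {
    counts <- out |>
      group_by(.data$analyte) |>
      summarise(k = dplyr::n_distinct(.data$temperature), .groups = "drop")
    if (any(counts$k < 2)) {
      stop_validation("analyte '%s' has fewer than 2 temperature levels in '%s'",
                      counts$analyte[which(counts$k < 2)[1]], basename(path))
    }
  }
  out <- arrange(out, .data$analyte, .data$temperature, .data$date)
  attr(out, "source_file") <- basename(path)
  attr(out, "arrhenius") <- has_temp
  out
}

sanitize_lab_id <- function(path) {
  stem <- tools::file_path_sans_ext(basename(path))
  gsub("[^A-Za-z0-9_.-]+", "_", stem)
}

#' Read collaborative (certification) study workbooks
#'
#' Reads one workbook per participating laboratory and merges them into a
#' single long table.  Each file carries the replicate values of one
#' laboratory (columns `analyte`, `unit` (optional), `replicate`, `value`).
#' The laboratory identifier is taken from the metadata key `Lab` when
#' present, otherwise from the sanitized file name stem.  Source file names
#' are retained per row; measurement values are never edited after import.
#'
#' @param paths character vector of file paths, one per laboratory.
#' @return a tibble with columns `lab_id`, `analyte`, `unit`, `replicate`,
#'   `value`, `source_file`; attribute `analyte_warnings` records analytes
#'   that are not reported by every laboratory.
#' @export
read_certification <- function(paths) {
  stopifnot(length(paths) >= 1)
  tables <- lapply(paths, function(p) {
    parsed <- read_template_file(p)
    df <- parsed$data
    if (nrow(df) == 0) stop_format("no data records found in '%s'", basename(p))
    require_columns(df, c("analyte", "replicate", "value"), p)
    lab <- if ("Lab" %in% names(parsed$meta)) unname(parsed$meta[["Lab"]])
           else sanitize_lab_id(p)
    tibble(
      lab_id = as.character(lab),
      analyte = as.character(df$analyte),
      unit = if ("unit" %in% names(df)) as.character(df$unit) else NA_character_,
      replicate = as.integer(parse_numeric_column(df$replicate, "replicate", p)),
      value = parse_numeric_column(df$value, "value", p),
      source_file = basename(p)
    )
  })
  labs <- vapply(tables, function(t) t$lab_id[1], "")
  if (anyDuplicated(labs)) {
    stop_format("duplicate lab_id '%s' across input files", labs[duplicated(labs)][1])
  }
  out <- bind_rows(tables)
  check_finite(out$value, "value")
  check_unit_consistency(out, "certification inputs")
  # analytes missing from some labs are allowed but recorded
  tab <- table(out$analyte, out$lab_id) > 0
  partial <- rownames(tab)[rowSums(tab) < ncol(tab)]
  if (length(partial) > 0) {
    warn(sprintf("analyte(s) not reported by every laboratory: %s",
                 paste(partial, collapse = ", ")),
         class = "certifyr_partial_analytes")
  }
  attr(out, "source_files") <- basename(paths)
  attr(out, "analyte_warnings") <- partial
  out
}

lts_definitions <- c("1s", "2s", "CI", "1sx", "2sx")

# convert a declared uncertainty to an absolute single standard deviation
lts_uncertainty_to_1s <- function(value, definition, mu) {
  switch(definition,
         "1s" = value,
         "2s" = value / 2,
         "CI" = value / 2, # expanded k = 2 interval half-width (flagged)
         "1sx" = value * mu,
         "2sx" = value * mu / 2,
         stop_format("unknown uncertainty definition '%s' (valid: %s)",
                     definition, paste(lts_definitions, collapse = ", ")))
}

#' Read a long-term stability (LTS) monitoring workbook
#'
#' Reads the monitoring template: a metadata block describing the certified
#' parameter (`analyte`, `unit`, `certified_value`, `uncertainty_value`,
#' `uncertainty_definition`, `certification_date`) followed by dated
#' measurements (`date`, `value`, optional `comment`).  The declared
#' uncertainty is converted to an absolute single standard deviation
#' according to its definition: `1s` as is, `2s` and `CI` halved (`CI` is
#' interpreted as a k = 2 expanded interval half-width and flagged as such),
#' `1sx`/`2sx` as relative values scaled by the certified value (and halved
#' for `2sx`).  Metadata are frozen after import; data points can only be
#' appended and only their comments edited (see [add_point()],
#' [set_comment()]).
#'
#' @param path path to an `.xlsx` or `.csv` file in the LTS dialect.
#' @return an object of class `lts_dataset`.
#' @export
read_lts <- function(path) {
  parsed <- read_template_file(path)
  meta <- as.list(parsed$meta)
  if (tolower(tools::file_ext(path)) == "xlsx" && length(meta) == 0) {
    stop_format("LTS workbook '%s' has no Meta sheet", basename(path))
  }
  required <- c("analyte", "certified_value", "uncertainty_value",
                "uncertainty_definition", "certification_date")
  missing <- setdiff(required, names(meta))
  if (length(missing) > 0) {
    stop_format("LTS metadata in '%s' is missing: %s", basename(path),
                paste(missing, collapse = ", "))
  }
  definition <- trimws(meta$uncertainty_definition)
  if (!definition %in% lts_definitions) {
    stop_format("unknown uncertainty_definition '%s' in '%s' (valid: %s)",
                definition, basename(path), paste(lts_definitions, collapse = ", "))
  }
  mu <- suppressWarnings(as.numeric(meta$certified_value))
  uval <- suppressWarnings(as.numeric(meta$uncertainty_value))
  if (is.na(mu)) stop_format("certified_value missing or non-numeric in '%s'", basename(path))
  if (is.na(uval) || uval < 0) stop_format("uncertainty_value missing or invalid in '%s'", basename(path))
  df <- parsed$data
  if (nrow(df) == 0) stop_format("no data records found in '%s'", basename(path))
  require_columns(df, c("date", "value"), path)
  points <- tibble(
    date = parse_iso_date(df$date),
    value = parse_numeric_column(df$value, "value", path),
    comment = if ("comment" %in% names(df)) as.character(df$comment) else NA_character_
  )
  new_lts_dataset(
    meta = list(
      analyte = as.character(meta$analyte),
      unit = as.character(meta$unit %||% NA_character_),
      certified_value = mu,
      uncertainty_value = uval,
      uncertainty_definition = definition,
      u_abs_1s = lts_uncertainty_to_1s(uval, definition, mu),
      ci_interpreted_as_k2 = identical(definition, "CI"),
      certification_date = parse_iso_date(meta$certification_date, "certification_date")
    ),
    points = points,
    source_file = basename(path)
  )
}
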