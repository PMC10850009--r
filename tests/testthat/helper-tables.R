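# in-code builders for small test tables and template files

homog_table <- function(values_by_bottle, analyte = "Hg", unit = "mg/kg") {
  purrr::imap_dfr(values_by_bottle, function(vals, b) {
    tibble::tibble(analyte = analyte, unit = unit,
                   bottle = if (is.character(b)) b else sprintf("B%d", b),
                   replicate = seq_along(vals), value = vals)
  })
}

cert_table <- function(values_by_lab, analyte = "A", unit = "mg/kg") {
  purrr::imap_dfr(values_by_lab, function(vals, lab) {
    tibble::tibble(lab_id = lab, analyte = analyte, unit = unit,
                   replicate = seq_along(vals), value = vals,
                   source_file = paste0(lab, ".csv"))
  })
}

stab_table <- function(dates, values, analyte = "A", unit = "mg/kg",
                       temperature = NA_real_) {
  tibble::tibble(analyte = analyte, unit = unit, date = as.Date(dates),
                 value = values, temperature = temperature)
}

write_csv_lines <- function(lines, ext = "csv") {
  f <- tempfile(fileext = paste0(".", ext))
  writeLines(lines, f)
  f
}

lts_csv <- function(points = "2023-04-01,4.01,\n2023-07-01,4.03,\n2023-10-01,3.98,checked",
                    definition = "2s", value = "0.17", mu = "4.00",
                    drop = character(0)) {
  meta <- c(analyte = "Hg", unit = "mg/kg", certified_value = mu,
            uncertainty_value = value, uncertainty_definition = definition,
            certification_date = "2023-01-01")
  meta <- meta[setdiff(names(meta), drop)]
  write_csv_lines(c(sprintf("# %s: %s", names(meta), meta),
                    "date,value,comment", strsplit(points, "\n")[[1]]))
}

# monthly date grid such that months_elapsed() is exactly 0, 1, 2, ... is not
# possible on a day calendar; tests therefore construct exact responses from
# the computed month axis instead
linear_series <- function(n, b0 = 10, b1 = 1, start = as.Date("2022-01-01"),
                          step_days = 30) {
  dates <- start + (seq_len(n) - 1) * step_days
  m <- certifyr::months_elapsed(dates)
  stab_table(dates, b0 + b1 * m)
}
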