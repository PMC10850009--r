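test_that("homogeneity reader parses the template and validates its invariants", {
  fx <- make_fixture(fixture_spec_soil_hg(), seed = 11, dir = tempfile())
  tab <- read_homogeneity(fx$paths$homogeneity)
  expect_equal(nrow(tab), 48) # 12 bottles x 4 replicates
  expect_equal(dplyr::n_distinct(tab$bottle), 12)
  expect_type(tab$value, "double")
  expect_identical(attr(tab, "source_file"), "homogeneity.csv")

  # missing required column is named in the error
  f <- write_csv_lines(c("analyte,bottle,value", "Hg,B1,4.0", "Hg,B2,4.1"))
  expect_error(read_homogeneity(f), "replicate", class = "certifyr_format_error")

  # non-numeric cell is reported with its location
  f <- write_csv_lines(c("analyte,bottle,replicate,value",
                         "Hg,B1,1,4.0", "Hg,B1,2,oops", "Hg,B2,1,4.1"))
  expect_error(read_homogeneity(f), "oops.*row 2", class = "certifyr_format_error")

  # empty data sheet
  f <- write_csv_lines("analyte,bottle,replicate,value")
  expect_error(read_homogeneity(f), "no data", class = "certifyr_format_error")

  # fewer than 2 bottles
  f <- write_csv_lines(c("analyte,bottle,replicate,value",
                         "Hg,B1,1,4.0", "Hg,B1,2,4.1"))
  expect_error(read_homogeneity(f), "2 bottles", class = "certifyr_validation_error")
})

test_that("stability reader normalizes dates and detects degenerate series", {
  fx <- make_fixture(fixture_spec_soil_hg(), seed = 11, dir = tempfile())
  tab <- read_stability(fx$paths$stability)
  expect_s3_class(tab$date, "Date")
  expect_false(attr(tab, "arrhenius"))

  f <- write_csv_lines(c("analyte,date,value", "A,2022-01-01,1",
                         "A,2022-01-01,1.1", "A,2022-01-01,0.9"))
  expect_error(read_stability(f), "3 distinct dates",
               class = "certifyr_validation_error")

  f <- write_csv_lines(c("analyte,date,value", "A,not-a-date,1",
                         "A,2022-02-01,1", "A,2022-03-01,1"))
  expect_error(read_stability(f), "not-a-date", class = "certifyr_format_error")

  f <- write_csv_lines(c("analyte,unit,date,value", "A,mg/kg,2022-01-01,1",
                         "A,g/kg,2022-02-01,1", "A,mg/kg,2022-03-01,1"))
  expect_error(read_stability(f), "mixed units", class = "certifyr_format_error")

  # temperature column switches to the accelerated layout
  fxa <- make_fixture(fixture_spec_arrhenius(), seed = 11, dir = tempfile())
  ta <- read_stability(fxa$paths$arrhenius)
  expect_true(attr(ta, "arrhenius"))
  expect_equal(sort(unique(ta$temperature)), c(-80, 10, 25, 40, 55))
})

test_that("certification reader merges per-laboratory files with provenance", {
  fx <- make_fixture(fixture_spec_soil_hg(), seed = 11, dir = tempfile())
  tab <- read_certification(fx$paths$certification)
  expect_equal(dplyr::n_distinct(tab$lab_id), 16)
  expect_true(all(c("L4", "L14") %in% tab$lab_id))
  expect_true(all(nzchar(tab$source_file)))

  # lab id from metadata beats filename
  f1 <- write_csv_lines(c("# Lab: LAB_A", "analyte,replicate,value",
                          "Hg,1,4.0", "Hg,2,4.1"))
  t1 <- read_certification(f1)
  expect_equal(unique(t1$lab_id), "LAB_A")

  # filename stem fallback
  f2 <- file.path(tempdir(), "lab B7.csv")
  writeLines(c("analyte,replicate,value", "Hg,1,4.2", "Hg,2,4.3"), f2)
  t2 <- read_certification(f2)
  expect_equal(unique(t2$lab_id), "lab_B7")

  # duplicate lab ids across files are refused
  f3 <- write_csv_lines(c("# Lab: LAB_A", "analyte,replicate,value", "Hg,1,4.4"))
  expect_error(read_certification(c(f1, f3)), "duplicate",
               class = "certifyr_format_error")

  # differing analyte sets across labs: warning, not error
  f4 <- write_csv_lines(c("# Lab: LAB_C", "analyte,replicate,value",
                          "Hg,1,4.0", "Pb,1,10"))
  expect_warning(merged <- read_certification(c(f1, f4)),
                 class = "certifyr_partial_analytes")
  expect_equal(attr(merged, "analyte_warnings"), "Pb")
})

test_that("LTS reader freezes metadata and converts every uncertainty definition", {
  # 2s: half of the declared value
  d <- read_lts(lts_csv(definition = "2s", value = "0.17", mu = "4.00"))
  expect_equal(d$meta$u_abs_1s, 0.085)
  expect_false(d$meta$ci_interpreted_as_k2)

  # relative single variance: scaled by the certified value
  d <- read_lts(lts_csv(definition = "1sx", value = "0.02", mu = "4.00"))
  expect_equal(d$meta$u_abs_1s, 0.08)

  d <- read_lts(lts_csv(definition = "1s", value = "0.1"))
  expect_equal(d$meta$u_abs_1s, 0.1)
  d <- read_lts(lts_csv(definition = "2sx", value = "0.02", mu = "4.00"))
  expect_equal(d$meta$u_abs_1s, 0.04)
  # CI treated as a k = 2 expanded half-width, and flagged as interpretation
  d <- read_lts(lts_csv(definition = "CI", value = "0.17", mu = "4.00"))
  expect_equal(d$meta$u_abs_1s, 0.085)
  expect_true(d$meta$ci_interpreted_as_k2)

  expect_error(read_lts(lts_csv(definition = "3s")), "1s, 2s, CI, 1sx, 2sx",
               class = "certifyr_format_error")
  expect_error(read_lts(lts_csv(drop = "certified_value")), "certified_value",
               class = "certifyr_format_error")
})
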