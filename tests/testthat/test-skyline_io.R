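# Parsing the three tab-delimited inputs and writing/reading reports.

test_that("Skyline export rows map fields directly and preserve order", {
  p <- write_export_file(c(
    "EDALNETR\t2\ty4\t1\trun01\t15321.5",
    "EDALNETR\t2\ty5\t1\trun01\t8000",
    "EDALNETR\t2\ty4\t1\trun02\t0"
  ))
  df <- parse_skyline_export(p)
  expect_equal(nrow(df), 3L)
  expect_equal(df$peptide_sequence[1], "EDALNETR")
  expect_equal(df$precursor_charge[1], 2L)
  expect_equal(df$fragment_ion[1], "y4")
  expect_equal(df$product_charge[1], 1L)
  expect_equal(df$replicate_name[1], "run01")
  expect_equal(df$peak_area, c(15321.5, 8000, 0))
  expect_equal(df$replicate_name, c("run01", "run01", "run02"))
})

test_that("all accepted missing-value spellings map to missing, never zero", {
  spellings <- c("", "#N/A", "NA", "NaN")
  p <- write_export_file(sprintf("PEPK\t2\ty4\t1\trun%02d\t%s",
                                 seq_along(spellings), spellings))
  df <- parse_skyline_export(p)
  expect_true(all(is.na(df$peak_area)))
  # non-numeric garbage is also missing, not zero
  p2 <- write_export_file("PEPK\t2\ty4\t1\trun01\tnot-a-number")
  expect_true(is.na(parse_skyline_export(p2)$peak_area))
})

test_that("export header matching is case/separator tolerant and mappable", {
  p <- write_export_file(
    "PEPK\t2\ty4\t1\trun01\t5",
    header = "peptide_sequence\tPRECURSOR CHARGE\tFragment.Ion\tproduct charge\tReplicate_Name\tarea")
  expect_equal(parse_skyline_export(p)$peak_area, 5)
  pm <- write_export_file("PEPK\t2\ty4\t1\trun01\t5",
                          header = "Seq\tQ1z\tIon\tQ3z\tFile\tTotalArea")
  df <- parse_skyline_export(pm, column_map = list(
    peptide_sequence = "Seq", precursor_charge = "Q1z", fragment_ion = "Ion",
    product_charge = "Q3z", replicate_name = "File", peak_area = "TotalArea"))
  expect_equal(df$replicate_name, "run01")
})

test_that("export format errors name the offending column or line", {
  p <- write_export_file("PEPK\t2\ty4\t1\trun01\t5",
                         header = "Peptide Sequence\tPrecursor Charge\tFragment Ion\tProduct Charge\tReplicate Name\tHeight")
  expect_error(parse_skyline_export(p), "Area")
  empty <- withr::local_tempfile(fileext = ".tsv")
  writeLines(character(0), empty)
  expect_error(parse_skyline_export(empty), "empty")
  bad <- write_export_file("PEPK\t0\ty4\t1\trun01\t5")
  expect_error(parse_skyline_export(bad), "charge")
  neg <- write_export_file("PEPK\t2\ty4\t1\trun01\t-3")
  expect_error(parse_skyline_export(neg), "negative")
})

test_that("metadata rows parse with conditional annotations validated", {
  p <- write_metadata_file(c(
    "run01\tcalibration\t\t1\t\t3",
    "run40\tqc\t2\t3\tlow\t",
    "blank1\tblank\t\t1\t\t"
  ))
  df <- parse_metadata(p)
  expect_equal(df$sample_type, c("calibration", "qc", "blank"))
  expect_equal(df$calibration_point, c(3L, NA, NA))
  expect_equal(df$concentration_level, c(NA, "low", NA))
  expect_equal(df$day, c(NA, 2L, NA))
  expect_equal(df$replicate_index, c(1L, 3L, 1L))
  expect_equal(df$run_order, 1:3)
})

test_that("metadata invariant violations error", {
  dup <- write_metadata_file(c("run01\tcalibration\t\t1\t\t1",
                               "run01\tcalibration\t\t2\t\t1"))
  expect_error(parse_metadata(dup), "duplicate")
  badtype <- write_metadata_file("run01\tsolvent\t\t1\t\t")
  expect_error(parse_metadata(badtype), "sample type")
  nocal <- write_metadata_file("run01\tcalibration\t\t1\t\t")
  expect_error(parse_metadata(nocal), "calibration")
  qc_with_point <- write_metadata_file("run01\tqc\t1\t1\tlow\t2")
  expect_error(parse_metadata(qc_with_point), "mismatch")
  blank_with_level <- write_metadata_file("run01\tblank\t\t1\thigh\t")
  expect_error(parse_metadata(blank_with_level), "mismatch")
})

test_that("dilution map is sorted and strictly monotone", {
  p <- write_dilution_file(c(2, 1, 3), c(1, 0.1, 10))
  df <- parse_dilution_map(p)
  expect_equal(df$calibration_point, 1:3)
  expect_equal(df$theoretical_concentration, c(0.1, 1, 10))

  seven <- write_dilution_file(1:7, c(0.01, 0.1, 0.5, 1, 5, 10, 100))
  expect_equal(nrow(parse_dilution_map(seven)), 7L)

  bad <- write_dilution_file(c(1, 2), c(10, 1))
  expect_error(parse_dilution_map(bad), "increase")
  dup <- write_dilution_file(c(1, 1), c(1, 2))
  expect_error(parse_dilution_map(dup), "duplicate")
})

test_that("reports round-trip through write_report/read_report", {
  assay <- make_rc_assay(slopes = c(10, 20))
  rc <- response_curve(assay)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_report(rc, path)
  lines <- readLines(path)
  expect_equal(length(lines), nrow(rc$results) + 1L)
  expect_equal(strsplit(lines[1], "\t")[[1]], names(rc$results))

  back <- read_report(path)
  expect_equal(names(back), names(rc$results))
  expect_equal(back$Peptide, rc$results$Peptide)
  expect_equal(back$`LLOQ.CaliPoint`, rc$results$`LLOQ.CaliPoint`)
  expect_equal(back$`LOD.usedSpiked`, rc$results$`LOD.usedSpiked`)
  # numeric fields agree to the printed precision
  expect_equal(back$`Curve.Slope`, rc$results$`Curve.Slope`,
               tolerance = 1e-5)
  expect_equal(back$`Curve.SlopeStdErr(%)`, rc$results$`Curve.SlopeStdErr(%)`,
               tolerance = 1e-3)
})

test_that("an empty row list writes a header-only file and NA cells render as NA", {
  assay <- make_rc_assay(slopes = c(10, 20))
  rc <- response_curve(assay)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_report(rc$results[0, ], path)
  expect_equal(length(readLines(path)), 1L)

  # NA cells are the literal string "NA"
  df <- rc$results[1, ]
  df$`LLOQ.CaliPoint` <- NA_integer_
  df$`Carryover.percent` <- NA_real_
  write_report(df, path)
  cells <- strsplit(readLines(path)[2], "\t")[[1]]
  expect_equal(cells[match("LLOQ.CaliPoint", names(df))], "NA")
  expect_equal(cells[match("Carryover.percent", names(df))], "NA")
})
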