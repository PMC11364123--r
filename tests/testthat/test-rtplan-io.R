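test_that("JSON round trip is the identity on randomized plans", {
  tmp <- withr::local_tempfile(fileext = ".json")
  ok <- vapply(1:1000, function(seed) {
    p <- random_tiny_plan(seed)
    write_json_plan(p, tmp)
    plans_equal(read_json_plan(tmp), p)
  }, logical(1))
  expect_true(all(ok))
  # and one deep field-by-field comparison
  p <- random_tiny_plan(1001)
  write_json_plan(p, tmp)
  expect_plan_equal(read_json_plan(tmp), p)
})

test_that("JSON schema violations name the offending field path", {
  tmp <- withr::local_tempfile(fileext = ".json")
  p <- random_tiny_plan(1)
  write_json_plan(p, tmp)
  doc <- jsonlite::read_json(tmp)

  doc2 <- doc; doc2$beams <- list()
  jsonlite::write_json(doc2, tmp, auto_unbox = TRUE)
  expect_error(read_json_plan(tmp), "beams")

  doc2 <- doc; doc2$beams[[1]]$control_points[[2]]$cmf <- NULL
  jsonlite::write_json(doc2, tmp, auto_unbox = TRUE)
  expect_error(read_json_plan(tmp), "beams\\[1\\].control_points\\[2\\].cmf")

  # bank_b above bank_a at one leaf names the leaf index
  doc2 <- doc
  cp1 <- doc2$beams[[1]]$control_points[[1]]
  cp1$bank_b_mm[[2]] <- cp1$bank_a_mm[[2]] + 1
  doc2$beams[[1]]$control_points[[1]] <- cp1
  jsonlite::write_json(doc2, tmp, auto_unbox = TRUE)
  expect_error(read_json_plan(tmp), "leaf pair 2")

  doc2 <- doc; doc2$schema <- "99"
  jsonlite::write_json(doc2, tmp, auto_unbox = TRUE)
  expect_error(read_json_plan(tmp), "schema")
})

test_that("DICOM round trip reproduces the plan model", {
  tmp <- withr::local_tempfile(fileext = ".dcm")
  for (seed in c(2, 17, 23)) {
    p <- random_tiny_plan(seed)
    write_dicom_plan(p, tmp)
    expect_plan_equal(read_dicom_plan(tmp), p, tol = 1e-6)
  }
})

test_that("DICOM and JSON readers agree on paired fixtures", {
  td <- withr::local_tempdir()
  p <- generate_plan("head_and_neck", 0.6, seed = 31, n_cp = 20)
  write_dicom_plan(p, file.path(td, "p.dcm"))
  write_json_plan(p, file.path(td, "p.json"))
  expect_plan_equal(read_dicom_plan(file.path(td, "p.dcm")),
                    read_json_plan(file.path(td, "p.json")), tol = 1e-6)
})

test_that("reader parses a DICOM-RT Plan produced by an independent writer", {
  td <- withr::local_tempdir()
  p <- random_tiny_plan(5)
  write_json_plan(p, file.path(td, "plan.json"))
  script <- file.path(td, "make_dcm.py")
  writeLines(c(
    "import json, sys",
    "import pydicom",
    "from pydicom.dataset import Dataset, FileDataset, FileMetaDataset",
    "plan = json.load(open(sys.argv[1]))",
    "meta = FileMetaDataset()",
    "meta.MediaStorageSOPClassUID = '1.2.840.10008.5.1.4.1.1.481.5'",
    "meta.MediaStorageSOPInstanceUID = '1.2.3.4'",
    "meta.TransferSyntaxUID = '1.2.840.10008.1.2.1'",
    "ds = FileDataset(sys.argv[2], {}, file_meta=meta, preamble=b'\\0'*128)",
    "ds.Modality = 'RTPLAN'",
    "ds.RTPlanLabel = plan['id']",
    "ds.RTPlanDescription = 'site=' + plan['site']",
    "dr = Dataset(); dr.TargetPrescriptionDose = plan['prescribed_dose_gy']",
    "ds.DoseReferenceSequence = [dr]",
    "fg = Dataset(); fg.NumberOfFractionsPlanned = 1",
    "fg.ReferencedBeamSequence = []",
    "ds.FractionGroupSequence = [fg]",
    "ds.BeamSequence = []",
    "for bi, bj in enumerate(plan['beams'], start=1):",
    "    rb = Dataset(); rb.ReferencedBeamNumber = bi",
    "    rb.BeamMeterset = bj['meterset_mu']",
    "    fg.ReferencedBeamSequence.append(rb)",
    "    bm = Dataset(); bm.BeamNumber = bi; bm.BeamName = bj['id']",
    "    bm.BeamType = 'DYNAMIC'; bm.TreatmentDeliveryType = 'TREATMENT'",
    "    bm.FinalCumulativeMetersetWeight = 1.0",
    "    mlc = Dataset(); mlc.RTBeamLimitingDeviceType = 'MLCX'",
    "    mlc.NumberOfLeafJawPairs = len(bj['leaf_boundaries_mm']) - 1",
    "    mlc.LeafPositionBoundaries = bj['leaf_boundaries_mm']",
    "    bm.BeamLimitingDeviceSequence = [mlc]",
    "    bm.NumberOfControlPoints = len(bj['control_points'])",
    "    bm.ControlPointSequence = []",
    "    for ci, cp in enumerate(bj['control_points']):",
    "        c = Dataset(); c.ControlPointIndex = ci",
    "        c.CumulativeMetersetWeight = cp['cmf']",
    "        if ci == 0:",
    "            c.DoseRateSet = bj['dose_rate_mu_min']",
    "        jx = Dataset(); jx.RTBeamLimitingDeviceType = 'ASYMX'",
    "        jx.LeafJawPositions = cp['jaw_x_mm']",
    "        jy = Dataset(); jy.RTBeamLimitingDeviceType = 'ASYMY'",
    "        jy.LeafJawPositions = cp['jaw_y_mm']",
    "        ml = Dataset(); ml.RTBeamLimitingDeviceType = 'MLCX'",
    "        ml.LeafJawPositions = cp['bank_b_mm'] + cp['bank_a_mm']",
    "        c.BeamLimitingDevicePositionSequence = [jx, jy, ml]",
    "        bm.ControlPointSequence.append(c)",
    "    ds.BeamSequence.append(bm)",
    "ds.save_as(sys.argv[2], enforce_file_format=True)"), script)
  out <- file.path(td, "plan.dcm")
  status <- system2("python", c(script, file.path(td, "plan.json"), out),
                    stdout = TRUE, stderr = TRUE)
  expect_true(file.exists(out),
              info = paste(status, collapse = "\n"))
  expect_plan_equal(read_dicom_plan(out), p, tol = 1e-6)
})

test_that("DICOM reader filters static beams and flags broken plans", {
  tmp <- withr::local_tempfile(fileext = ".dcm")
  p <- random_tiny_plan(9)
  write_dicom_plan(p, tmp)
  raw <- readBin(tmp, "raw", file.info(tmp)$size)
  # flip the first beam's type DYNAMIC -> STATIC (same length)
  pat <- charToRaw("DYNAMIC ")
  hit <- which(vapply(seq_len(length(raw) - 7), function(i)
    all(raw[i:(i + 7)] == pat), logical(1)))[1]
  raw[hit:(hit + 7)] <- charToRaw("STATIC  ")
  writeBin(raw, tmp)
  if (length(p$beams) > 1) {
    got <- read_dicom_plan(tmp)
    expect_equal(length(got$beams), length(p$beams) - 1)
  } else {
    expect_error(read_dicom_plan(tmp), "no dynamic MLC beams")
  }
})

test_that("dose grid round trips through CSV and DICOM", {
  g <- random_dose_grid(4)
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_dose_csv(g, tmp)
  g2 <- read_dose_csv(tmp)
  expect_equal(g2$origin, g$origin)
  expect_equal(g2$spacing, g$spacing)
  expect_equal(g2$values, g$values, tolerance = 1e-7)

  tmp2 <- withr::local_tempfile(fileext = ".dcm")
  write_dicom_dose(g, tmp2)
  g3 <- read_dicom_dose(tmp2)
  expect_equal(g3$origin, g$origin)
  expect_equal(g3$spacing, g$spacing)
  expect_equal(g3$values, g$values, tolerance = 1e-6)
})
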