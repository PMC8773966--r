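test_that("decay_rate uses the clinical 0.693 constant", {
  expect_equal(decay_rate(6.0067), 0.115371168861, tolerance = 1e-9)
  expect_equal(decay_rate(6.02), 0.11511627907, tolerance = 1e-9)
  expect_lt(decay_rate(1e6), 1e-6)
  expect_equal(decay_rate(6.0067, ln2 = TRUE), log(2) / 6.0067)
  expect_error(decay_rate(0), "positive")
  expect_error(decay_rate(-3), "positive")
})

test_that("lean body mass matches the James formula hand calculations", {
  expect_equal(lean_body_mass(70, 170, "female"), 49.8065743945,
               tolerance = 1e-9)
  expect_equal(lean_body_mass(80, 180, "male"), 64.2962962963,
               tolerance = 1e-9)
  # ratio term vanishes for very tall subjects
  expect_equal(lean_body_mass(70, 1e6, "female"), 1.07 * 70,
               tolerance = 1e-6)
  expect_error(lean_body_mass(0, 170, "female"), "positive")
  # extreme weight/height ratio drives LBM negative
  expect_error(lean_body_mass(200, 100, "female"), "non-positive")
})

test_that("decay correction reproduces the worked chronology", {
  dc <- decay_correction(worked_patient())
  expect_equal(dc$decay1, 0.990431805206, tolerance = 1e-9)
  expect_equal(dc$decay2, 1.01941458692, tolerance = 1e-9)
  expect_equal(dc$decay_scan, 0.707432184338, tolerance = 1e-9)
  expect_equal(dc$actual_activity_mbq, 476.179006284, tolerance = 1e-9)
  # factor ranges implied by the timestamp ordering
  expect_true(dc$decay1 > 0 && dc$decay1 <= 1)
  expect_gte(dc$decay2, 1)
  expect_true(dc$decay_scan > 0 && dc$decay_scan <= 1)
})

test_that("decay correction agrees with the independent two-step oracle", {
  pats <- list(
    worked_patient(),
    patient_record("P02", "male", 85, 182, 650, 5,
                   "2021-05-10T08:30", "2021-05-10T08:42",
                   "2021-05-10T08:44", "2021-05-10T11:02"),
    patient_record("P03", "female", 55, 158, 720, 35,
                   "2021-06-01T10:00", "2021-06-01T10:00",
                   "2021-06-01T10:01", "2021-06-01T14:30"))
  for (p in pats) {
    dc <- decay_correction(p)
    expect_equal(dc$actual_activity_mbq, oracle_actual_activity(p),
                 tolerance = 1e-9)
  }
})

test_that("degenerate chronologies reduce to the closed forms", {
  t0 <- "2021-03-01T09:00"
  same <- patient_record("P04", "female", 70, 170, 700, 0, t0, t0, t0, t0)
  expect_equal(decay_correction(same)$actual_activity_mbq, 700)
  # residual equal to the assay with all times equal leaves no net activity
  expect_error(
    decay_correction(
      patient_record("P05", "female", 70, 170, 700, 699.9999999,
                     t0, t0, t0, t0)),
    NA)  # still positive
  expect_error(
    {
      p <- patient_record("P06", "female", 70, 170, 700, 699, t0, t0, t0, t0)
      p$post_injection_activity_mbq <- 700  # force the degenerate case
      decay_correction(p)
    },
    "not positive")
})

test_that("actual activity strictly decreases with later scan times", {
  base <- worked_patient()
  scans <- sprintf("2021-03-01T%02d:05", 12:18)
  acts <- vapply(scans, function(s) {
    p <- patient_record("P01", "female", 70, 170, 700, 20,
                        "2021-03-01T09:00", "2021-03-01T09:05",
                        "2021-03-01T09:10", s)
    decay_correction(p)$actual_activity_mbq
  }, 0)
  expect_true(all(diff(acts) < 0))
  expect_equal(acts[[1]], decay_correction(base)$actual_activity_mbq)
})

test_that("SUV conversion is correct, linear and invertible", {
  expect_equal(suv_from_concentration(30000, 49.8065743945, 476.179006284),
               3.13788976859, tolerance = 1e-9)
  expect_identical(suv_from_concentration(0, 49.81, 476.6), 0)
  # linearity in the concentration
  expect_equal(suv_from_concentration(2 * 12345, 49.81, 476.6),
               2 * suv_from_concentration(12345, 49.81, 476.6))
  # algebraic inverse round trip
  suv <- suv_from_concentration(12345, 49.81, 476.6)
  conc_back <- suv * 476.6 * 1e6 / (49.81 * 1000)
  expect_equal(conc_back, 12345, tolerance = 1e-12)
  expect_error(suv_from_concentration(100, 49.81, 0), "activity")
  expect_error(suv_from_concentration(100, 0, 476.6), "lean body mass")
})

test_that("suv_volume applies the conversion voxelwise and preserves shape", {
  p <- worked_patient()
  vol <- activity_volume(array(30000, c(4, 5, 6)), spacing_mm = c(2, 2, 3))
  sv <- suv_volume(vol, p)
  expect_identical(dim(sv$grid), dim(vol$grid))
  expect_identical(sv$spacing_mm, vol$spacing_mm)
  expect_equal(unique(as.vector(sv$grid)), 3.13788976859, tolerance = 1e-9)
  expect_identical(sv$patient_id, "P01")

  zero <- suv_volume(activity_volume(array(0, c(3, 3, 3))), p)
  expect_true(all(zero$grid == 0))

  # identity: residual 0, all timestamps equal -> conc * LBM * 1000 / A
  t0 <- "2021-03-01T09:00"
  pid <- patient_record("P07", "female", 70, 170, 700, 0, t0, t0, t0, t0)
  sv2 <- suv_volume(activity_volume(array(50000, c(2, 2, 2))), pid)
  expect_equal(unique(as.vector(sv2$grid)),
               50000 * lean_body_mass(70, 170, "female") * 1000 / 7e8,
               tolerance = 1e-12)
})

test_that("patient record validation enforces the chronology and activities", {
  expect_error(
    patient_record("X", "female", 70, 170, 700, 20,
                   "2021-03-01T09:06", "2021-03-01T09:05",
                   "2021-03-01T09:10", "2021-03-01T12:05"),
    "ordered")
  expect_error(
    patient_record("X", "female", 70, 170, 20, 700,
                   "2021-03-01T09:00", "2021-03-01T09:05",
                   "2021-03-01T09:10", "2021-03-01T12:05"),
    "exceed")
  expect_error(
    patient_record("X", "female", -70, 170, 700, 20,
                   "2021-03-01T09:00", "2021-03-01T09:05",
                   "2021-03-01T09:10", "2021-03-01T12:05"),
    "weight")
  expect_error(parse_suv_time("03/01/2021 9:00"), "ISO-8601")
})

test_that("patient records round-trip through CSV", {
  pats <- list(P01 = worked_patient())
  path <- withr::local_tempfile(fileext = ".csv")
  write_patients_csv(pats, path)
  back <- read_patients(path)
  expect_identical(names(back), "P01")
  expect_equal(back$P01$weight_kg, 70)
  expect_equal(back$P01$scan_time, worked_patient()$scan_time)
  expect_equal(decay_correction(back$P01)$actual_activity_mbq,
               decay_correction(worked_patient())$actual_activity_mbq)
})
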