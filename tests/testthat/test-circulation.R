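test_that("clinical-record validation rejects inconsistent measurements", {
  expect_error(clinical_record(80, 84, 82, 64, 4.9, 60), "sbp > dbp")
  expect_error(clinical_record(132, 84, 140, 64, 4.9, 60), "between")
  expect_error(clinical_record(132, 84, 102, -1, 4.9, 60), "positive")
  rec <- gen_patient_record()
  expect_s3_class(rec, "clinical_record")
  expect_equal(rec$map, 102)
  expect_equal(rec$sv, 64)
})

test_that("calibration applies the clinical formulas", {
  rec <- gen_patient_record()
  p <- calibrate(rec)
  expect_equal(p$R_total, 102 / 4.9, tolerance = 1e-12)   # 20.82 mmHg.min/L
  expect_equal(p$C, 64 / 48, tolerance = 1e-12)           # 1.33 mL/mmHg
  expect_equal(p$Zc, 0.05 * p$R_total)
  expect_equal(p$cycle_period, 1.0)   # 60 bpm from the record
  expect_equal(p$systole_duration, 0.3)
  # R = MAP/Q proportionality
  rec2 <- clinical_record(132, 84, 102, 64, 9.8, 60)
  expect_equal(calibrate(rec2)$R_total, p$R_total / 2)
})

test_that("a flat elastance produces no ejection and flows never reverse", {
  p <- circ_params(R_total = 20.8, C = 1.33, Zc = 1.04, Emax = 0.08,
                   Emin = 0.08, cycle_period = 1, systole_duration = 0.3)
  sim <- simulate_circulation(p, n_cycles = 10)
  # without contraction there is no pulsatile pumping (a flaccid ventricle
  # held at venous pressure still passes a steady trickle)
  expect_lt(sim$metrics$SV, 0.1)
  expect_lt(sim$metrics$SBP - sim$metrics$DBP, 0.1)
  expect_true(all(sim$trace$q_ao >= 0))
})

test_that("the calibrated, refined model reproduces the cuff pressures", {
  fx <- patient_fixture()
  m <- fx$sim$metrics
  expect_true(attr(fx$refined, "converged"))
  expect_lt(abs(m$SBP - 132), 1)
  expect_lt(abs(m$DBP - 84), 1)
  expect_gt(m$EDV, 136)
  expect_lt(m$EDV, 138.5)
  expect_true(fx$sim$periodic)
})

test_that("refinement of already-matching parameters stops immediately", {
  fx <- patient_fixture()
  again <- refine_to_cuff(fx$refined, fx$record, tol = 1)
  expect_true(attr(again, "converged"))
  expect_equal(nrow(attr(again, "history")), 1)
  expect_equal(again$C, fx$refined$C)
})

test_that("a zero pressure tolerance is refused as unattainable", {
  fx <- patient_fixture()
  expect_warning(out <- refine_to_cuff(fx$refined, fx$record, tol = 0),
                 "tolerance")
  expect_false(attr(out, "converged"))
})

test_that("the periodic beat conserves volume", {
  b <- patient_fixture()$sim$final_beat
  drift <- abs(b$v_lv[nrow(b)] - b$v_lv[1]) / patient_fixture()$sim$metrics$SV
  expect_lt(drift, 1e-3)
})

test_that("mean aortic pressure obeys the Windkessel identity", {
  fx <- patient_fixture()
  b <- fx$sim$final_beat
  R_s <- fx$refined$R_total * 0.06
  q_mean <- fx$sim$metrics$SV / fx$refined$cycle_period
  expect_lt(abs(mean(b$p_ao) - R_s * q_mean) / (R_s * q_mean), 0.01)
})

test_that("with negligible characteristic impedance pulse pressure approaches SV/C", {
  # long RC time constant so the ejection pulse acts on a near-ideal
  # 2-element Windkessel
  p <- circ_params(R_total = 150, C = 1.0, Zc = 0.3, Emax = 15, Emin = 0.08,
                   cycle_period = 1, systole_duration = 0.3)
  sim <- simulate_circulation(p, n_cycles = 80, periodicity_tol = 5e-5)
  m <- sim$metrics
  expect_gt(m$SV, 1)
  expect_lt(abs((m$SBP - m$DBP) - m$SV / p$C) / (m$SV / p$C), 0.10)
})

test_that("the PV loop is closed and traversed counterclockwise", {
  b <- patient_fixture()$sim$final_beat
  v <- b$v_lv; pl <- b$p_lv
  n <- length(v); j <- c(2:n, 1)
  signed_area <- sum(v * pl[j] - v[j] * pl) / 2
  expect_gt(signed_area, 0)   # counterclockwise in (V, P)
  expect_lt(abs(v[n] - v[1]), 0.5)
})

test_that("pv_metrics reproduces closed-form cases", {
  # rectangular loop 60 mL wide x 100 mmHg tall -> stroke work 6000 mmHg.mL
  v <- c(seq(60, 120, length.out = 50), rep(120, 50),
         seq(120, 60, length.out = 50), rep(60, 50))
  pl <- c(rep(10, 50), seq(10, 110, length.out = 50), rep(110, 50),
          seq(110, 10, length.out = 50))
  ejecting <- seq_along(v) %in% 101:150   # the descending-volume segment
  beat <- tibble::tibble(t = seq_along(v) * 1e-3, p_lv = pl, p_ao = pl,
                         v_lv = v, q_ao = as.numeric(ejecting))
  m <- pv_metrics(beat, bsa = 1.9)
  expect_equal(m$stroke_work, 6000, tolerance = 0.05)
  expect_equal(m$EDV, 120)
  expect_equal(m$ESV, 60)
  # EF definition on the stated volumes
  expect_equal((137 - 54.8) / 137, 0.6, tolerance = 1e-12)
  # Zva scales inversely with indexed stroke volume
  m2 <- pv_metrics(beat, bsa = 2 * 1.9)
  expect_equal(m2$Zva, 2 * m$Zva)
  expect_warning(m3 <- pv_metrics(beat), "BSA")
  expect_true(is.na(m3$Zva))
})

test_that("trace and record files round-trip", {
  fx <- patient_fixture()
  path <- withr::local_tempfile(fileext = ".csv")
  write_trace_csv(fx$sim, path)
  back <- read_trace_csv(path)
  expect_equal(nrow(back), nrow(fx$sim$trace))
  expect_equal(back$p_ao, fx$sim$trace$p_ao, tolerance = 1e-6)
  jpath <- withr::local_tempfile(fileext = ".json")
  write_record_json(fx$record, jpath)
  rec2 <- read_record_json(jpath)
  expect_equal(rec2$sbp, 132)
  expect_equal(rec2$valve_orifice_area, 414)
})
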