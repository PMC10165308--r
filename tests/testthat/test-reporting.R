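test_that("deviation report computes per-entry and summary statistics", {
  model <- data.frame(compartment = rep(c("liver", "tumour"), each = 2),
                      scan = rep(1:2, 2), value = c(1, 1, 2, 2))
  achieved0 <- data.frame(model[, 1:2], value = model$value, u = 0.01)
  rep0 <- deviation_report(achieved0, model)
  expect_true(all(rep0$rows$deviation_pct == 0))
  expect_equal(rep0$mean_deviation$value, 0)
  expect_true(all(rep0$rows$agrees))
  # synthetic offsets {+1, -1, +2, -2}%: mean 0, SD = sqrt(10/3)
  achieved1 <- achieved0
  achieved1$value <- model$value * (1 + c(0.01, -0.01, 0.02, -0.02))
  rep1 <- deviation_report(achieved1, model)
  expect_equal(rep1$mean_deviation$value, 0, tolerance = 1e-9)
  expect_equal(rep1$mean_deviation$u, sqrt(10 / 3), tolerance = 1e-9)
  # misaligned keys are named
  expect_error(deviation_report(achieved0[-4, ], model), "tumour 2")
})

test_that("underfill range excludes overfills and rounds to 2 decimals", {
  bg <- c(98.25, 98.25, 98.25, 98.35, 98.28, 98.24)
  r <- underfill_range(bg)
  expect_identical(r$range, c(1.65, 1.76))
  expect_length(r$overfill_pct, 0)
  # permutation invariance
  expect_identical(underfill_range(rev(bg))$range, r$range)
  expect_identical(underfill_range(c(100, 100))$range, c(0, 0))
  expect_identical(underfill_range(99)$range, c(1, 1))
  # the overfilled scan is excluded and reported separately
  med <- c(99.05, 97.19, 102.04, 97.47, 97.72, 97.19)
  rm_ <- underfill_range(med)
  expect_equal(rm_$range, c(0.95, 2.81))
  expect_equal(rm_$overfill_pct, 2.04)
  expect_error(underfill_range(numeric(0)), "at least one")
})

test_that("fill table renders concise notation and round-trips", {
  ref <- reference_fill_fractions()
  tab <- fill_table(ref)
  expect_equal(tab$text["background", "scan1"], "98.25(3)")
  expect_equal(tab$text["liver", "scan1"], "100.08(1)")
  expect_equal(tab$text["tumour", "scan6"], "94.8(1)")
  back <- parse_fill_table(tab)
  ord <- order(back$compartment, back$scan)
  ord0 <- order(ref$compartment, ref$scan)
  expect_equal(back$fill_pct[ord], ref$fill_pct[ord0])
  expect_equal(back$fill_u_pct[ord], ref$fill_u_pct[ord0])
  # rendering a parsed table reproduces the same text (idempotence)
  tab2 <- fill_table(back)
  expect_identical(tab2$text[rownames(tab$text), colnames(tab$text)], tab$text)
  expect_error(fill_table(ref[0, ]), "alignment")
  expect_error(fill_table(ref[-1, ]), "alignment")
  # CSV export
  path <- tempfile(fileext = ".csv")
  write_fill_table_csv(tab, path)
  expect_true(file.exists(path))
})

test_that("activity maps conserve total activity", {
  p <- toy_phantom()
  ct <- data.frame(compartment = c("background", "other"),
                   conc_MBq_per_mL = c(0.5, 2.0))
  map <- export_activity_map(p, ct)
  vox_mL <- prod(p$spacing) / 1000
  # uniform-per-compartment: totals match concentration x compartment volume
  expect_equal(sum(map) * vox_mL,
               0.5 * sum(p$labels == 1L) * vox_mL +
                 2.0 * sum(p$labels == 2L) * vox_mL,
               tolerance = 1e-12)
  expect_error(export_activity_map(p, ct[1, , drop = FALSE]), "other")
})

test_that("default phantom activity map matches the schedule at 24 h", {
  p <- default_phantom()
  sch <- default_schedule()
  ct <- concentrations_at(sch, times = 24)
  map <- export_activity_map(p, ct)
  vox_mL <- prod(p$spacing) / 1000
  vols <- phantom_volumes(p)
  for (role in c("liver", "tumour", "medulla-L")) {
    id <- vols$id[vols$role == role]
    conc <- ct$conc_MBq_per_mL[ct$compartment == role]
    expect_equal(sum(map[p$labels == id]) * vox_mL,
                 conc * vols$volume_mL[vols$role == role],
                 tolerance = 1e-6)
  }
  # total activity is conserved exactly across the whole map
  per_comp <- vapply(seq_len(nrow(vols)), function(i) {
    role <- ifelse(vols$role[i] == "body", "background", vols$role[i])
    ct$conc_MBq_per_mL[ct$compartment == role] * vols$volume_mL[i]
  }, numeric(1))
  expect_equal(sum(map) * vox_mL, sum(per_comp), tolerance = 1e-6)
  # NIfTI export carries the voxel spacing
  path <- tempfile(fileext = ".nii.gz")
  export_activity_map(p, ct, path)
  img <- RNifti::readNifti(path)
  expect_equal(RNifti::pixdim(img), p$spacing)
  expect_equal(max(abs(img - map)), 0, tolerance = 1e-6)
})

test_that("run summary records provenance", {
  path <- tempfile(fileext = ".json")
  write_run_summary(path, inputs = list(phantom = "default"),
                    config = list(a = 1))
  js <- jsonlite::read_json(path)
  expect_equal(js$package, "phantomforge")
  expect_true(nzchar(js$config_md5))
})
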