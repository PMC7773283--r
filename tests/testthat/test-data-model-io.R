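test_that("axial grid enforces origin, monotonicity and uniform spacing", {
  g <- axial_grid(seq(0, 300, by = 1))
  expect_equal(g$dz, 1)
  expect_equal(g$L_sas, 300)
  expect_error(axial_grid(c(0, 2, 1)), "increasing")
  expect_error(axial_grid(c(1, 2, 3)), "z = 0")
  expect_error(axial_grid(c(0, 1, 3)), "uniformly")
})

test_that("axial profile validates the open-SAS invariant", {
  g <- axial_grid(0:3)
  expect_error(axial_profile(g, A_c = 40, A_d = 38, P_c = 13, P_d = 21),
               "dura area must exceed cord area")
  expect_error(axial_profile(g, A_c = -1, A_d = 38, P_c = 13, P_d = 21),
               "non-negative")
  p <- axial_profile(g, A_c = 14.4, A_d = 38.21, P_c = 13.39, P_d = 21.53)
  expect_length(p$A_c, 4)
})

test_that("profile reader handles constant-area tables and bad input", {
  path <- write_profile_csv(data.frame(z = 0:3, A_c = 14.40, A_d = 38.21,
                                       P_c = 13.39, P_d = 21.53))
  p <- read_axial_profile(path)
  expect_s3_class(p, "axial_profile")
  expect_equal(p$grid$dz, 1)
  expect_equal(p$grid$L_sas, 3)
  expect_equal(unique(p$A_c), 14.40)

  empty <- tempfile(fileext = ".csv"); file.create(empty)
  expect_error(read_axial_profile(empty), "empty|parse")

  bad <- write_profile_csv(data.frame(z = c(0, 2, 1), A_c = 1, A_d = 2,
                                      P_c = 1, P_d = 1))
  expect_error(read_axial_profile(bad), "increasing")

  miss <- write_profile_csv(data.frame(z = 0:3, A_c = 1, A_d = 2, P_c = 1))
  expect_error(read_axial_profile(miss), "P_d")
})

test_that("profile reader resamples non-uniform grids with a warning", {
  path <- write_profile_csv(data.frame(z = c(0, 1, 3, 6), A_c = c(1, 2, 4, 7),
                                       A_d = 10, P_c = 3, P_d = 5))
  expect_warning(p <- read_axial_profile(path), "resampling")
  expect_equal(p$grid$dz, 2)
  # A_c is linear in z, so linear resampling is exact
  expect_equal(p$A_c, 1 + p$grid$z, tolerance = 1e-12)
})

test_that("waveform reader sorts levels and enforces structure", {
  t <- seq(0, 0.5, by = 0.05)
  df <- do.call(rbind, lapply(c(250, 0, 110), function(z) {
    data.frame(level_z = z, t = t, Q = -sin(t))
  }))
  path <- write_profile_csv(df)
  ws <- read_flow_waveforms(path)
  expect_length(ws, 3)
  expect_equal(vapply(ws, function(w) w$level_z, numeric(1)), c(0, 110, 250))
  # T inferred as range plus one step
  expect_equal(ws[[1]]$T, 0.55)

  single <- write_profile_csv(df[df$level_z == 0, ])
  expect_error(read_flow_waveforms(single), ">= 2")

  df_bad <- df; df_bad$Q <- as.character(df_bad$Q); df_bad$Q[5] <- "x"
  expect_error(read_flow_waveforms(write_profile_csv(df_bad)), "row 5")
})

test_that("flip_sign dialect negates flow on read", {
  t <- seq(0, 0.5, by = 0.1)
  df <- rbind(data.frame(level_z = 0, t = t, Q = 1),
              data.frame(level_z = 10, t = t, Q = 1))
  ws <- read_flow_waveforms(write_profile_csv(df),
                            table_dialect(flip_sign = TRUE))
  expect_true(all(ws[[1]]$Q == -1))
})

test_that("summary tables round-trip at full precision", {
  rec <- data.frame(parameter = rep(c("V_sas", "A_c"), each = 2),
                    unit = rep(c("mL", "mm^2"), each = 2),
                    group = c("cervical", "lumbar", "cervical", "lumbar"),
                    timepoint = "PRE-2",
                    mean = c(7.17123456789, 7.43, 14.4, 15.47),
                    sd = c(0.82, 0.79, 2.72, 3.07))
  path <- tempfile(fileext = ".csv")
  write_summary_table(rec, path)
  back <- read_summary_table(path)
  m <- merge(rec, back, by = c("parameter", "group", "timepoint"))
  expect_equal(m$mean.x, m$mean.y, tolerance = 1e-12)
  expect_equal(m$sd.x, m$sd.y, tolerance = 1e-12)

  rec_bad <- rec; rec_bad$unit[2] <- "L"
  expect_error(write_summary_table(rec_bad, tempfile()), "mixed units")
})

test_that("pooling cell means reproduces the arithmetic grand mean", {
  rec <- data.frame(parameter = "V_sas", unit = "mL",
                    group = rep(c("cervical", "lumbar"), 3),
                    timepoint = rep(c("PRE-2", "POST-1", "POST-2"), each = 2),
                    mean = c(7.17, 7.43, 6.57, 6.99, 6.68, 7.15), sd = 0.7)
  pooled <- pooled_summary(rec)
  expect_equal(pooled$n_cells, 6)
  expect_equal(pooled$pooled_mean, mean(rec$mean), tolerance = 1e-15)

  one <- pooled_summary(rec[1, ])
  expect_equal(one$pooled_mean, 7.17)
})
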