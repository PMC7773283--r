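test_that("cohort generation is seed-reproducible", {
  cfg <- synthetic_config(n_per_group = 2)
  a <- generate_cohort(cfg, seed = 9)
  b <- generate_cohort(cfg, seed = 9)
  expect_identical(a, b)
  c2 <- generate_cohort(cfg, seed = 10)
  expect_false(identical(a$waveforms, c2$waveforms))
})

test_that("geometry generator hits its cohort-mean targets", {
  cfg <- synthetic_config(n_per_group = 25, target_A_sas = 23.7)
  geo <- generate_geometry(cfg, seed = 4)
  mean_A_sas <- mean(vapply(geo$profiles, function(p) mean(p$A_sas), numeric(1)))
  expect_lt(abs(mean_A_sas - 23.7) / 23.7, 0.02)

  # SAS volume lands at the few-mL scale of a small primate
  v <- vapply(geo$profiles, function(p) summarize_geometry(p)$V_sas, numeric(1))
  expect_gt(mean(v), 5); expect_lt(mean(v), 9)

  # zero between-subject spread makes identical profiles (up to length)
  cfg0 <- synthetic_config(n_per_group = 2, geom_sdlog = 0, L_sd = 0)
  geo0 <- generate_geometry(cfg0, seed = 1)
  expect_equal(geo0$profiles[[1]]$A_sas, geo0$profiles[[2]]$A_sas,
               tolerance = 1e-12)
})

test_that("waveforms carry the configured pulse structure", {
  cfg <- synthetic_config(noise_q = 0, T_sd = 0, amp_sdlog = 0)
  geo <- generate_geometry(cfg, seed = 2)
  wv <- generate_waveforms(cfg, geo, seed = 3)
  w <- wv$waveforms[[1]]
  # caudal systole: minima negative; amplitude decays caudally
  mins <- vapply(w, function(x) min(x$Q), numeric(1))
  expect_true(all(mins < 0))
  # amplitude peaks in the cervical spine (above the FM value) and
  # decays monotonically caudal of the cervical maximum
  expect_gt(max(abs(mins[2:3])), abs(mins[1]))
  expect_true(all(diff(abs(mins)[-(1:2)]) < 0))
  # cervical systolic peak amplitude and timing in the physiological window
  i_cerv <- 2:3
  expect_true(all(-mins[i_cerv] > 0.15 & -mins[i_cerv] < 0.6))
  t_pk <- vapply(w[i_cerv], function(x) x$t[which.min(x$Q)], numeric(1))
  expect_true(all(t_pk > 0.08 & t_pk < 0.18))

  # zero amplitude gives identically zero flow
  cfg0 <- synthetic_config(q0 = 0, noise_q = 0)
  wv0 <- generate_waveforms(cfg0, geo, seed = 3)
  expect_true(all(vapply(wv0$waveforms[[1]], function(x) max(abs(x$Q)), numeric(1)) == 0))

  expect_error(synthetic_config(pwv = 0), "positive")
})

test_that("noiseless pipeline recovers the true PWV within 1%", {
  cfg <- synthetic_config(noise_q = 0, T_sd = 0, amp_sdlog = 0)
  geo <- generate_geometry(cfg, seed = 5)
  wv <- generate_waveforms(cfg, geo, seed = 6)
  w <- lapply(wv$waveforms[[1]], normalize_cycle, T_ref = 0.53)
  pw <- pulse_wave_velocity(fit_spatiotemporal(w))
  expect_lt(abs(pw$PWV - cfg$pwv) / cfg$pwv, 0.01)
})

test_that("catheter effect attenuates per the subject's own reduction", {
  cfg <- synthetic_config(n_per_group = 2)
  geo <- generate_geometry(cfg, seed = 7)
  md <- data.frame(id = names(geo$profiles),
                   group = rep(c("cervical", "lumbar"), each = 2))
  eff <- apply_catheter_effect(geo, md, cfg)
  expect_equal(unname(eff$attenuation), unname(1 - eff$reduction),
               tolerance = 1e-15)
  expect_true(all(eff$reduction >= 0 & eff$reduction < 1))
  # cervical (longer in-SAS path) attenuates more than lumbar
  expect_gt(mean(eff$reduction[md$group == "cervical"]),
            mean(eff$reduction[md$group == "lumbar"]))
  # post profiles gained the catheter perimeter
  expect_gt(mean(eff$profiles_post[[1]]$P_sas), mean(geo$profiles[[1]]$P_sas))

  # no catheter: cohort passes through unchanged
  cfg_none <- synthetic_config(n_per_group = 2,
                               catheters = list(cervical = NULL, lumbar = NULL))
  eff0 <- apply_catheter_effect(geo, md, cfg_none)
  expect_identical(eff0$profiles_post, geo$profiles)
  expect_true(all(eff0$attenuation == 1))
})

test_that("generated files pass the package's own readers", {
  cfg <- synthetic_config(n_per_group = 1, nt = 16)
  co <- generate_cohort(cfg, seed = 12)
  dir <- tempfile(); write_cohort(co, dir)
  p <- read_axial_profile(file.path(dir, "NHP01_PRE-2_profile.csv"))
  expect_s3_class(p, "axial_profile")
  w <- read_flow_waveforms(file.path(dir, "NHP01_PRE-2_waveforms.csv"))
  expect_length(w, length(cfg$levels))
  expect_equal(w[[1]]$T, co$waveforms[["PRE-2"]][["NHP01"]][[1]]$T,
               tolerance = 1e-9)
})
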