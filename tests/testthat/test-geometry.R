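test_that("catheter footprint walks segments from the tip", {
  g <- axial_grid(seq(0, 310, by = 1))
  fp <- catheter_footprint(catheter_spec(tip_z = 60, entry_z = 310), g)
  z <- g$z
  # distal 100 mm: OD 0.99; beyond: OD 1.98
  expect_equal(unique(fp$A_cath[z >= 60 & z < 160]), pi / 4 * 0.99^2,
               tolerance = 1e-12)
  expect_equal(unique(fp$A_cath[z >= 160 & z <= 310]), pi / 4 * 1.98^2,
               tolerance = 1e-12)
  expect_equal(unique(fp$P_cath[z >= 160 & z <= 310]), pi * 1.98,
               tolerance = 1e-12)
  expect_true(all(fp$A_cath[z < 60] == 0))

  # lumbar-like: in-SAS path entirely within the distal segment
  fp_l <- catheter_footprint(catheter_spec(tip_z = 250, entry_z = 310), g)
  expect_equal(unique(fp_l$OD[fp_l$OD > 0]), 0.99)

  # zero-length path has no footprint
  fp0 <- catheter_footprint(catheter_spec(tip_z = 100, entry_z = 100), g)
  expect_true(all(fp0$A_cath == 0))

  short <- catheter_spec(tip_z = 0, entry_z = 300,
                         segments = data.frame(length = 100, od = 1, id = 0.5))
  expect_error(catheter_footprint(short, g), "cannot span")
})

test_that("derived SAS profile matches hand arithmetic", {
  p <- axial_profile(axial_grid(0:3), A_c = 14.40, A_d = 38.21,
                     P_c = 13.39, P_d = 21.53)
  d <- derive_sas_profile(p)
  expect_equal(unique(d$A_sas), 23.81, tolerance = 1e-12)
  expect_equal(unique(d$P_sas), 34.92, tolerance = 1e-12)

  # unit-radius circle: D_h equals the diameter
  circ <- derive_sas_profile(axial_profile(axial_grid(0:3), A_c = 0.01,
                                           A_d = pi + 0.01, P_c = 0, P_d = 2 * pi))
  expect_equal(unique(circ$D_h), 2, tolerance = 1e-10)

  # with an OD-1.98 catheter along the whole grid
  g <- axial_grid(0:3)
  p2 <- axial_profile(g, A_c = 10, A_d = 33.66, P_c = 15.36, P_d = 23.00)
  cath <- catheter_spec(0, 3, segments = data.frame(length = 10, od = 1.98, id = 1.19))
  d2 <- derive_sas_profile(p2, catheter_footprint(cath, g))
  expect_equal(unique(d2$A_sas), 23.66 - pi / 4 * 1.98^2, tolerance = 1e-12)
  expect_equal(unique(d2$P_sas), 38.36 + pi * 1.98, tolerance = 1e-12)
  expect_equal(unique(d2$D_h), 4 * (23.66 - pi / 4 * 1.98^2) / (38.36 + pi * 1.98),
               tolerance = 1e-12)
})

test_that("catheter adjustment is conservative and monotone in OD", {
  g <- axial_grid(seq(0, 300, by = 1))
  p <- uniform_profile(derive = TRUE)
  cath <- catheter_spec(55, 290)
  with_c <- derive_sas_profile(p, catheter_footprint(cath, g))
  restored <- derive_sas_profile(with_c, NULL)
  expect_identical(restored$A_sas, p$A_sas)
  expect_identical(restored$P_sas, p$P_sas)

  # D_h strictly decreases as OD grows where the footprint is present
  d_h_at <- function(od) {
    cc <- catheter_spec(55, 290, segments = data.frame(length = 400, od = od,
                                                       id = od / 2))
    derive_sas_profile(p, catheter_footprint(cc, g))$D_h[g$z == 150]
  }
  ods <- c(0.5, 0.99, 1.5, 1.98)
  expect_true(all(diff(vapply(ods, d_h_at, numeric(1))) < 0))

  # an impossibly fat catheter is rejected, naming the position
  fat <- catheter_spec(55, 290, segments = data.frame(length = 400, od = 6, id = 3))
  expect_error(derive_sas_profile(p, catheter_footprint(fat, g)), "z = 55")
})

test_that("geometry summaries agree with analytic integrals", {
  p <- uniform_profile(L = 300, A_c = 10, A_d = 33.66, P_c = 15.36, P_d = 23.00)
  s <- summarize_geometry(p)
  expect_equal(s$V_sas, 23.66 * 300 / 1000, tolerance = 1e-10)
  expect_equal(s$V_c, 10 * 300 / 1000, tolerance = 1e-10)
  expect_equal(s$SA_sas, (15.36 + 23.00) * 300 / 100, tolerance = 1e-10)
  expect_equal(s$SA_sas, s$SA_c + s$SA_d, tolerance = 1e-15)
  expect_equal(s$V_sas, s$V_d - s$V_c, tolerance = 1e-15)

  # linear profile: trapezoid is exact
  g <- axial_grid(seq(0, 100, by = 1))
  lin <- axial_profile(g, A_c = 1 + 0.02 * g$z, A_d = 30 - 0.05 * g$z,
                       P_c = 10, P_d = 20)
  sl <- summarize_geometry(lin)
  expect_equal(sl$V_c, (1 * 100 + 0.02 * 100^2 / 2) / 1000, tolerance = 1e-10)
  expect_equal(sl$V_d, (30 * 100 - 0.05 * 100^2 / 2) / 1000, tolerance = 1e-10)

  # V_sas is the exact difference of the two integrals
  same <- axial_profile(g, A_c = 5, A_d = 5.001, P_c = 1, P_d = 1)
  expect_equal(summarize_geometry(same)$V_sas, 0.001 * 100 / 1000,
               tolerance = 1e-10)
})

test_that("axial normalization rescales lengths and preserves linear fields", {
  g1 <- axial_grid(seq(0, 300, by = 1))
  p1 <- axial_profile(g1, A_c = 5, A_d = 30, P_c = 10, P_d = 20)
  out <- normalize_axial(list(p1), L_mean = 300)
  expect_equal(out[[1]]$grid$L_sas, 300)
  expect_equal(out[[1]]$A_c, p1$A_c, tolerance = 1e-12)

  # linear A_sas under a 2x stretch equals the linear function at the
  # stretched coordinates
  g2 <- axial_grid(seq(0, 600, by = 2))
  p2 <- axial_profile(g2, A_c = 1, A_d = 2 + 0.01 * g2$z, P_c = 1, P_d = 1)
  n2 <- normalize_axial(list(p2), L_mean = 300)[[1]]
  expect_equal(n2$A_d, 2 + 0.01 * (n2$grid$z * 2), tolerance = 1e-10)

  two <- normalize_axial(list(
    axial_profile(axial_grid(seq(0, 280, by = 1)), 5, 30, 10, 20),
    axial_profile(axial_grid(seq(0, 320, by = 1)), 5, 30, 10, 20)), L_mean = 300)
  expect_equal(vapply(two, function(p) p$grid$L_sas, numeric(1)), c(300, 300))
})
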