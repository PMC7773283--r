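# shared builders for small in-code fixtures

uniform_profile <- function(L = 300, dz = 1, A_c = 14.40, A_d = 38.06,
                            P_c = 15, P_d = 23.36, derive = FALSE) {
  p <- axial_profile(axial_grid(seq(0, L, by = dz)),
                     A_c = A_c, A_d = A_d, P_c = P_c, P_d = P_d)
  if (derive) derive_sas_profile(p) else p
}

# analytic separable oscillatory field sampled as waveforms
sine_waveforms <- function(zs = c(0, 25, 55, 110, 180, 250), q0 = 0.3,
                           Tt = 0.53, nt = 32, decay = 150) {
  t <- seq(0, Tt, length.out = nt + 1)[seq_len(nt)]
  lapply(zs, function(z) {
    flow_waveform(z, t, -q0 * exp(-z / decay) * sin(2 * pi * t / Tt), T = Tt)
  })
}

# flow field with a prescribed systolic-peak arrival time per z
travelling_field <- function(arrival, zs, Tt = 0.53, nt = 64, amp = 1) {
  t <- seq(0, Tt, length.out = nt + 1)[seq_len(nt)]
  Q <- t(vapply(seq_along(zs), function(i) {
    -amp * cos(2 * pi * ((t - arrival[i]) %% Tt) / Tt)
  }, numeric(nt)))
  structure(list(z = zs, t = t, Q = Q, T = Tt, levels = zs),
            class = "flow_field")
}

write_profile_csv <- function(df, path = tempfile(fileext = ".csv")) {
  write.csv(df, path, row.names = FALSE)
  path
}

# long-table generator matching the mixed model's own structure:
# per-subject random intercept/linear/quadratic curves plus iid noise,
# with a group effect beta3 on the second cell
simulate_lme_table <- function(n_per_cell = 20, nz = 11, beta3 = 0,
                               sd_re = c(1, 0.5, 0.5), sigma = 1,
                               parameter = "A_sas") {
  n <- 2 * n_per_cell
  ids <- sprintf("S%02d", seq_len(n))
  group <- rep(c("cervical", "lumbar"), each = n_per_cell)
  age <- rnorm(n, 4.6, 0.4)
  weight <- rnorm(n, 4.4, 1.2)
  x1 <- seq(0, 1, length.out = nz)
  rows <- lapply(seq_len(n), function(i) {
    b <- rnorm(3, 0, sd_re)
    x2 <- as.numeric(group[i] == "lumbar")
    y <- 10 + 2 * x1 - 1.5 * x1^2 + beta3 * x2 + 0.3 * age[i] + 0.2 * weight[i] +
      b[1] + b[2] * x1 + b[3] * x1^2 + rnorm(nz, 0, sigma)
    data.frame(id = ids[i], timepoint = "PRE-2", z = x1 * 300,
               parameter = parameter, value = y)
  })
  values <- do.call(rbind, rows)
  metadata <- data.frame(id = ids, group = group, age = pmax(age, 1),
                         weight = pmax(weight, 1))
  assemble_long_table(values, metadata)
}
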