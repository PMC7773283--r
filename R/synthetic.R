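## Synthetic cohort generator. Emulates the study conditions of a
## small-primate intrathecal implantation experiment: smoothly
## tapering cord/dura profiles over a ~30 cm spine, two-harmonic
## pulsatile flow waveforms whose amplitude decays caudally and whose
## systolic peak propagates at a finite pulse wave velocity,
## per-subject heart-period and size variability, group-level catheter
## attenuation driven by the Hagen-Poiseuille estimator, and
## measurement noise. Ground truth is recorded for recovery tests.

#' Configuration for the synthetic cohort generator
#'
#' Defaults emulate a cynomolgus-monkey implantation study: four
#' subjects per implantation group, a 300 mm subarachnoid space,
#' cohort-mean geometry near 15.4 / 23.7 mm^2 cord / SAS area and
#' 13.9 / 22.1 mm cord / dura perimeter, flow measured at six axial
#' levels with a 0.53 s mean heart period, systolic peaks of a few
#' tenths of a mL/s arriving 100-150 ms into the cycle in the cervical
#' spine, and a 1.15 m/s pulse wave velocity. Catheters enter near the
#' caudal end of the sac with the tip at the mid-cervical (cervical
#' group) or thoracolumbar (lumbar group) level.
#'
#' @param n_per_group Subjects per implantation group.
#' @param L_mean,L_sd Cohort mean and SD of SAS length (mm).
#' @param dz Axial grid spacing (mm).
#' @param target_A_c,target_A_sas Cohort-mean cord and SAS
#'   cross-sectional areas (mm^2).
#' @param target_P_c,target_P_d Cohort-mean cord and dura perimeters
#'   (mm).
#' @param geom_sdlog Log-SD of the per-subject geometric size factor.
#' @param q0 Systolic flow amplitude scale (mL/s) at the cervical peak.
#' @param amp_sdlog Log-SD of the per-subject flow amplitude factor.
#' @param pwv True pulse wave velocity (m/s).
#' @param t_systole Systolic-peak time at the foramen magnum (s).
#' @param pulse_a2 Relative second-harmonic amplitude of the pulse.
#' @param T_mean,T_sd Mean and SD of the cardiac period (s).
#' @param levels Flow measurement levels (mm, on the reference
#'   \code{L_mean}-long spine; rescaled per subject).
#' @param nt Time samples per cardiac cycle.
#' @param noise_q SD of additive Gaussian flow noise (mL/s).
#' @param catheters Per-group catheter placement: named list with
#'   \code{tip_z}/\code{entry_z} (mm on the reference spine) and
#'   optionally \code{segments}; \code{NULL} for no catheter.
#' @return An object of class \code{synthetic_config}.
#' @export
synthetic_config <- function(n_per_group = 4L,
                             L_mean = 300, L_sd = 15, dz = 1,
                             target_A_c = 15.4, target_A_sas = 23.7,
                             target_P_c = 13.9, target_P_d = 22.1,
                             geom_sdlog = 0.06,
                             q0 = 0.4, amp_sdlog = 0.25,
                             pwv = 1.15, t_systole = 0.10, pulse_a2 = 0.35,
                             T_mean = 0.53, T_sd = 0.03,
                             levels = c(0, 25, 55, 110, 180, 250),
                             nt = 32L, noise_q = 0.005,
                             catheters = list(
                               cervical = list(tip_z = 55, entry_z = 290),
                               lumbar = list(tip_z = 210, entry_z = 290))) {
  stopifnot(n_per_group >= 1, L_mean > 0, L_sd >= 0, dz > 0,
            target_A_c > 0, target_A_sas > 0, target_P_c > 0, target_P_d > 0,
            q0 >= 0, T_mean > 0, T_sd >= 0, nt >= 8, noise_q >= 0)
  if (!is.finite(pwv) || pwv <= 0) stop("true PWV must be positive", call. = FALSE)
  structure(as.list(environment()), class = "synthetic_config")
}

## smooth positive shape templates on the normalized axial coordinate
## s in [0, 1], scaled to unit mean so targets multiply through
shape_template <- function(s_pts, v_pts) {
  f <- splinefun(s_pts, v_pts, method = "natural")
  norm <- mean(f(seq(0, 1, length.out = 401L)))
  function(s) f(s) / norm
}

sas_shape_points <- function() {
  list(s = c(0, 0.1, 0.3, 0.5, 0.7, 0.9, 1),
       A_sas = c(37, 30, 26, 24, 22, 18, 16),
       A_c   = c(18, 20, 16, 14, 12, 10, 6),
       g     = c(0.8, 1.0, 0.85, 0.55, 0.35, 0.15, 0.05))
}

lognormal_factor <- function(n, sdlog) exp(rnorm(n, 0, sdlog) - sdlog^2 / 2)

#' Generate per-subject synthetic geometry
#'
#' Builds each subject's axial profile from smooth taper templates
#' (natural splines through control points) for SAS area and cord
#' area, scaled by per-subject lognormal size factors with unit mean so
#' cohort means converge to the configured targets. The dura area is
#' cord plus SAS area by construction, and perimeters follow a
#' square-root-of-area shape scaled to the perimeter targets.
#'
#' @param config A [synthetic_config()].
#' @param seed Integer seed.
#' @return List with \code{profiles} (named list of derived
#'   [axial_profile()]s, catheter-free) and \code{truth} (per-subject
#'   \code{L_sas} and size factors).
#' @export
generate_geometry <- function(config, seed) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(seed)
  pts <- sas_shape_points()
  if (any(pts$A_sas <= 0) || any(pts$A_c < 0)) {
    stop("geometry templates must keep the SAS open (A_d > A_c)", call. = FALSE)
  }
  sh_sas <- shape_template(pts$s, pts$A_sas)
  sh_c <- shape_template(pts$s, pts$A_c)
  n <- 2L * config$n_per_group
  ids <- sprintf("NHP%02d", seq_len(n))
  L <- pmax(0.5 * config$L_mean, rnorm(n, config$L_mean, config$L_sd))
  f_area <- lognormal_factor(n, config$geom_sdlog)
  profiles <- list(); truth <- list()
  for (i in seq_len(n)) {
    z <- seq(0, L[i], by = config$dz)
    if (z[length(z)] < L[i]) z <- c(z, L[i])
    z <- seq(0, L[i], length.out = length(z))
    s <- z / L[i]
    A_sas <- config$target_A_sas * sh_sas(s) * f_area[i]
    A_c <- config$target_A_c * sh_c(s) * f_area[i]
    if (any(A_sas <= 0)) stop("template yields a closed SAS (A_d <= A_c)", call. = FALSE)
    A_d <- A_c + A_sas
    f_per <- sqrt(f_area[i])
    p_shape_c <- sqrt(pmax(A_c / f_area[i], 0))
    p_shape_d <- sqrt(A_d / f_area[i])
    P_c <- config$target_P_c * p_shape_c / mean(p_shape_c) * f_per
    P_d <- config$target_P_d * p_shape_d / mean(p_shape_d) * f_per
    profiles[[ids[i]]] <- derive_sas_profile(
      axial_profile(axial_grid(z), A_c = A_c, A_d = A_d, P_c = P_c, P_d = P_d))
    truth[[ids[i]]] <- list(L_sas = L[i], f_area = f_area[i])
  }
  list(profiles = profiles, truth = truth)
}

## two-harmonic pulse, numerically normalized so its maximum is 1 at
## phase 0; returns the pulse function of cycle fraction u
make_pulse <- function(a2) {
  base <- function(u) sin(2 * pi * u) + a2 * sin(4 * pi * u)
  ug <- seq(0, 1, length.out = 4001L)
  u_pk <- ug[which.max(base(ug))]
  pk <- base(u_pk)
  function(u) base((u + u_pk) %% 1) / pk
}

#' Generate per-subject synthetic flow waveforms
#'
#' Samples, at each measurement level, the travelling pulsatile flow
#' \deqn{Q(z, t) = -q_0\, g(z)\, s\!\big((t - t_{sys} - z/c) \bmod T\big) + \epsilon,}
#' with a two-harmonic pulse \eqn{s} (unit peak), caudally decaying
#' amplitude profile \eqn{g(z)}, pulse wave speed \eqn{c}, per-subject
#' cardiac period and lognormal amplitude factor, and additive Gaussian
#' noise. Caudal (systolic) flow is negative; the systolic peak at
#' level \eqn{z} arrives at \eqn{t_{sys} + z/c}.
#'
#' @param config A [synthetic_config()].
#' @param geometry Output of [generate_geometry()].
#' @param seed Integer seed.
#' @param amp_scale Optional named per-subject extra amplitude factor
#'   (e.g. catheter attenuation); default 1.
#' @return List with \code{waveforms} (per subject, a list of
#'   [flow_waveform()]s sorted rostral to caudal) and \code{truth}
#'   (per-subject period, amplitude factor, systolic amplitudes and
#'   arrival times per level, and the true PWV in m/s).
#' @export
generate_waveforms <- function(config, geometry, seed, amp_scale = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(seed)
  pts <- sas_shape_points()
  g_fun <- shape_template(pts$s, pts$g)
  g_scale <- max(g_fun(seq(0, 1, length.out = 401L)))
  pulse <- make_pulse(config$pulse_a2)
  ids <- names(geometry$profiles)
  c_mm <- config$pwv * 1000  # m/s -> mm/s
  waveforms <- list(); truth <- list()
  for (id in ids) {
    L <- geometry$truth[[id]]$L_sas
    T_i <- max(0.3, rnorm(1L, config$T_mean, config$T_sd))
    amp_i <- lognormal_factor(1L, config$amp_sdlog)
    extra <- if (!is.null(amp_scale) && id %in% names(amp_scale)) amp_scale[[id]] else 1
    zl <- config$levels * (L / config$L_mean)
    t <- seq(0, T_i, length.out = config$nt + 1L)[seq_len(config$nt)]
    wl <- list(); amp_z <- numeric(0); arr_z <- numeric(0)
    for (z in zl) {
      gz <- g_fun(z / L) / g_scale
      a <- config$q0 * gz * amp_i * extra
      u <- ((t - config$t_systole - z / c_mm) / T_i) %% 1
      Q <- -a * pulse(u) + rnorm(length(t), 0, config$noise_q)
      wl[[length(wl) + 1L]] <- flow_waveform(z, t, Q, T = T_i)
      amp_z <- c(amp_z, a); arr_z <- c(arr_z, config$t_systole + z / c_mm)
    }
    waveforms[[id]] <- wl
    truth[[id]] <- list(T = T_i, amp_factor = amp_i * extra, levels_z = zl,
                        systolic_amplitude = amp_z, arrival_t = arr_z,
                        PWV = config$pwv)
  }
  list(waveforms = waveforms, truth = truth)
}

#' Apply the catheter effect to a pre-implantation cohort
#'
#' For each subject, maps the group's catheter onto the subject's own
#' geometry, derives the with-catheter profile (area subtracted,
#' perimeter added), computes the subject's Hagen-Poiseuille flow
#' reduction, and returns post-implantation profiles together with the
#' per-subject attenuation factors \code{1 - reduction} used to scale
#' post-implantation flow amplitudes. Groups with a \code{NULL}
#' catheter are passed through unchanged (attenuation 1).
#'
#' @param geometry Output of [generate_geometry()].
#' @param metadata Data frame with columns \code{id}, \code{group}.
#' @param config A [synthetic_config()].
#' @return List with \code{profiles_post} (derived, catheter-adjusted),
#'   \code{attenuation} (named per-subject factor) and
#'   \code{reduction} (named per-subject predicted flow reduction).
#' @export
apply_catheter_effect <- function(geometry, metadata, config) {
  stopifnot(inherits(config, "synthetic_config"))
  profiles_post <- list(); attenuation <- list(); reduction <- list()
  for (id in names(geometry$profiles)) {
    grp <- metadata$group[match(id, metadata$id)]
    cc <- config$catheters[[grp]]
    if (is.null(cc)) {
      profiles_post[[id]] <- geometry$profiles[[id]]
      attenuation[[id]] <- 1; reduction[[id]] <- 0
      next
    }
    L <- geometry$truth[[id]]$L_sas
    sc <- L / config$L_mean
    cath <- catheter_spec(cc$tip_z * sc, min(cc$entry_z * sc, L),
                          segments = if (is.null(cc$segments)) default_catheter_segments()
                                     else cc$segments)
    red <- tryCatch(hagen_poiseuille_reduction(geometry$profiles[[id]], cath),
                    error = function(e) {
                      stop(sprintf("catheter incompatible with subject %s: %s",
                                   id, conditionMessage(e)), call. = FALSE)
                    })
    profiles_post[[id]] <- red$profile_post
    attenuation[[id]] <- 1 - red$reduction
    reduction[[id]] <- red$reduction
  }
  list(profiles_post = profiles_post,
       attenuation = unlist(attenuation), reduction = unlist(reduction))
}

#' Generate a full synthetic implantation cohort
#'
#' Orchestrates [generate_geometry()], [generate_waveforms()] and
#' [apply_catheter_effect()] into a three-timepoint cohort: one
#' pre-implantation scan (\code{PRE-2}) and two post-implantation scans
#' (\code{POST-1}, \code{POST-2}) whose flow amplitudes are attenuated
#' by each subject's own Hagen-Poiseuille reduction, with fresh
#' measurement noise per scan. The same seed and configuration always
#' reproduce the same cohort.
#'
#' @param config A [synthetic_config()].
#' @param seed Integer seed.
#' @return An object of class \code{csf_cohort}: \code{metadata} (id,
#'   group, age, weight), \code{profiles} and \code{waveforms} (nested
#'   timepoint -> subject), \code{truth} (ground-truth generator state
#'   including per-subject attenuation), and the \code{config}.
#' @export
generate_cohort <- function(config = synthetic_config(), seed = 1L) {
  stopifnot(inherits(config, "synthetic_config"))
  seed <- as.integer(seed)
  set.seed(seed)
  n <- 2L * config$n_per_group
  metadata <- data.frame(
    id = sprintf("NHP%02d", seq_len(n)),
    group = rep(c("cervical", "lumbar"), each = config$n_per_group),
    age = round(pmax(2, rnorm(n, 4.6, 0.4)), 1),
    weight = round(pmax(2, rnorm(n, 4.4, 1.2)), 1))
  geometry <- generate_geometry(config, seed + 1L)
  pre <- generate_waveforms(config, geometry, seed + 2L)
  eff <- apply_catheter_effect(geometry, metadata, config)
  post1 <- generate_waveforms(config, geometry, seed + 3L, amp_scale = eff$attenuation)
  post2 <- generate_waveforms(config, geometry, seed + 4L, amp_scale = eff$attenuation)
  structure(list(
    metadata = metadata,
    profiles = list("PRE-2" = geometry$profiles,
                    "POST-1" = eff$profiles_post,
                    "POST-2" = eff$profiles_post),
    waveforms = list("PRE-2" = pre$waveforms,
                     "POST-1" = post1$waveforms,
                     "POST-2" = post2$waveforms),
    truth = list(geometry = geometry$truth,
                 flow = list("PRE-2" = pre$truth, "POST-1" = post1$truth,
                             "POST-2" = post2$truth),
                 attenuation = eff$attenuation,
                 reduction = eff$reduction),
    config = config, seed = seed),
    class = "csf_cohort")
}

#' @export
print.csf_cohort <- function(x, ...) {
  cat(sprintf("<csf_cohort> %d subjects (%s), %d timepoints, seed %d\n",
              nrow(x$metadata),
              paste(table(x$metadata$group), names(table(x$metadata$group)),
                    collapse = " + "),
              length(x$profiles), x$seed))
  invisible(x)
}

#' Write a synthetic cohort to disk in the reader dialects
#'
#' Emits, per subject and timepoint, the axial profile and waveform
#' CSVs in exactly the format [read_axial_profile()] and
#' [read_flow_waveforms()] consume, plus \code{metadata.csv} and a
#' \code{ground_truth.json}.
#'
#' @param cohort A \code{csf_cohort}.
#' @param dir Output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "csf_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(cohort$metadata, file.path(dir, "metadata.csv"), row.names = FALSE)
  for (tp in names(cohort$profiles)) {
    for (id in names(cohort$profiles[[tp]])) {
      p <- cohort$profiles[[tp]][[id]]
      write.csv(data.frame(z = p$grid$z, A_c = p$A_c, A_d = p$A_d,
                           P_c = p$P_c, P_d = p$P_d),
                file.path(dir, sprintf("%s_%s_profile.csv", id, tp)),
                row.names = FALSE)
      w <- cohort$waveforms[[tp]][[id]]
      wdf <- do.call(rbind, lapply(w, function(x) {
        data.frame(level_z = x$level_z, t = x$t, Q = x$Q, T = x$T)
      }))
      write.csv(wdf, file.path(dir, sprintf("%s_%s_waveforms.csv", id, tp)),
                row.names = FALSE)
    }
  }
  jsonlite::write_json(cohort$truth, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
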