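## Cardiac-gated flow processing: cycle normalization, the
## spatio-temporal smoothing-spline surface Q(z, t), peak/amplitude and
## stroke-volume extraction, and pulse wave velocity from the slope of
## systolic-peak arrival time along the spine.

#' Normalize a waveform to a reference cardiac cycle
#'
#' Affinely rescales the time axis so the cycle spans
#' \code{[0, T_ref)}. Flow values are untouched (only timing is
#' normalized, so extrema and sample counts are preserved; rescaling Q
#' would change stroke volume).
#'
#' @param w A [flow_waveform()].
#' @param T_ref Reference cardiac period (s); default 0.53.
#' @return A [flow_waveform()] with period \code{T_ref}.
#' @export
normalize_cycle <- function(w, T_ref = 0.53) {
  stopifnot(inherits(w, "flow_waveform"))
  if (!is.finite(T_ref) || T_ref <= 0) stop("T_ref must be positive", call. = FALSE)
  flow_waveform(w$level_z, w$t * (T_ref / w$T), w$Q, T = T_ref)
}

#' Fit the spatio-temporal CSF flow surface
#'
#' Smooths per-level waveforms into a continuous surface
#' \code{Q(z, t)} over one cardiac cycle. The default smoother is a
#' tensor-product penalized spline (cubic in z, cyclic cubic in t,
#' fitted with \code{mgcv}; the smoothing parameter is chosen by
#' generalized cross-validation). \code{smoothing} may instead be a
#' fixed non-negative smoothing parameter, or \code{"none"} for pure
#' separable interpolation (cubic spline across levels, periodic cubic
#' spline in time), which reproduces the input samples exactly.
#'
#' All waveforms must share a common normalized time grid (see
#' [normalize_cycle()]).
#'
#' @param waveforms List of [flow_waveform()] at two or more distinct
#'   levels.
#' @param smoothing \code{"gcv"} (default), a non-negative number, or
#'   \code{"none"}.
#' @param nz,nt Size of the output evaluation grid.
#' @return An object of class \code{flow_field}: vectors \code{z} (mm)
#'   and \code{t} (s), flow matrix \code{Q} (\code{nz} x \code{nt},
#'   mL/s) and period \code{T}.
#' @export
fit_spatiotemporal <- function(waveforms, smoothing = "gcv", nz = NULL, nt = 64L) {
  if (length(waveforms) < 2L) stop("need waveforms at >= 2 levels", call. = FALSE)
  lapply(waveforms, function(w) stopifnot(inherits(w, "flow_waveform")))
  zs <- vapply(waveforms, function(w) w$level_z, numeric(1))
  if (anyDuplicated(zs)) stop("duplicate waveform levels", call. = FALSE)
  o <- order(zs)
  waveforms <- waveforms[o]; zs <- zs[o]
  Ts <- vapply(waveforms, function(w) w$T, numeric(1))
  t0 <- waveforms[[1L]]$t
  same <- all(abs(Ts - Ts[1L]) < 1e-9) &&
    all(vapply(waveforms, function(w) {
      length(w$t) == length(t0) && max(abs(w$t - t0)) < 1e-9
    }, logical(1)))
  if (!same) {
    stop("waveforms must share a common normalized time grid; apply normalize_cycle first",
         call. = FALSE)
  }
  Tcyc <- Ts[1L]
  Qin <- do.call(rbind, lapply(waveforms, function(w) w$Q))  # levels x time
  if (is.null(nz)) nz <- max(31L, length(zs) * 6L)
  z_out <- sort(unique(c(seq(zs[1L], zs[length(zs)], length.out = nz), zs)))
  nz <- length(z_out)
  t_out <- seq(0, Tcyc, length.out = nt + 1L)[seq_len(nt)]

  if (identical(smoothing, "none")) {
    # separable interpolation: spline across z per time column, then a
    # periodic spline in t per output level
    Qz <- apply(Qin, 2L, function(col) {
      if (length(zs) == 2L) approx(zs, col, xout = z_out)$y
      else spline(zs, col, xout = z_out, method = "natural")$y
    })                                                     # nz x ntin
    Qzt <- t(apply(Qz, 1L, function(row) {
      spline(c(t0, Tcyc), c(row, row[1L]), xout = t_out, method = "periodic")$y
    }))
  } else {
    dat <- data.frame(z = rep(zs, times = length(t0)),
                      tt = rep(t0, each = length(zs)),
                      Q = as.vector(Qin))
    kz <- min(length(zs), 6L)
    kt <- min(length(t0), 10L)
    form <- Q ~ te(z, tt, bs = c("cr", "cc"), k = c(kz, kt))
    knots <- list(tt = seq(0, Tcyc, length.out = kt))
    fit <- if (identical(smoothing, "gcv")) {
      mgcv::gam(form, data = dat, knots = knots, method = "GCV.Cp")
    } else {
      sp <- as.numeric(smoothing)
      if (!is.finite(sp) || sp < 0) stop("smoothing must be 'gcv', 'none' or >= 0",
                                         call. = FALSE)
      mgcv::gam(form, data = dat, knots = knots, sp = c(sp, sp))
    }
    newd <- expand.grid(z = z_out, tt = t_out)
    Qzt <- matrix(predict(fit, newdata = newd), nrow = nz)
  }
  structure(list(z = z_out, t = t_out, Q = Qzt, T = Tcyc, levels = zs),
            class = "flow_field")
}

#' @export
print.flow_field <- function(x, ...) {
  cat(sprintf("<flow_field> %d z-points x %d time samples, z in [%g, %g] mm, T = %g s\n",
              length(x$z), length(x$t), min(x$z), max(x$z), x$T))
  invisible(x)
}

#' Extract peak systolic/diastolic flow and amplitude
#'
#' Peak systolic flow \code{Q_sys(z)} is the most caudal (most
#' negative) flow over the cycle, peak diastolic flow \code{Q_dia(z)}
#' the most cranial (most positive), and the flow amplitude is
#' \eqn{Q_a(z) = Q_{dia}(z) - Q_{sys}(z)}.
#'
#' @param field A \code{flow_field} from [fit_spatiotemporal()].
#' @return Data frame with columns \code{z}, \code{Q_sys},
#'   \code{Q_dia}, \code{Q_a} (mL/s).
#' @export
extract_peaks <- function(field) {
  stopifnot(inherits(field, "flow_field"))
  Q_sys <- apply(field$Q, 1L, min)
  Q_dia <- apply(field$Q, 1L, max)
  data.frame(z = field$z, Q_sys = Q_sys, Q_dia = Q_dia, Q_a = Q_dia - Q_sys)
}

#' Stroke volume along the spine
#'
#' The oscillatory CSF volume displaced per cardiac cycle at each axial
#' level, \eqn{SV(z) = \int_0^T |Q(z,t)|\,dt}, integrated by the
#' trapezoidal rule with the cycle closed periodically (the sample at
#' \code{t = T} is taken equal to the one at \code{t = 0}).
#'
#' @param field A \code{flow_field}.
#' @return Data frame with columns \code{z} and \code{SV} (mL).
#' @export
stroke_volume <- function(field) {
  stopifnot(inherits(field, "flow_field"))
  tt <- c(field$t, field$T)
  SV <- apply(field$Q, 1L, function(q) pracma::trapz(tt, abs(c(q, q[1L]))))
  data.frame(z = field$z, SV = SV)
}

#' Pulse wave velocity from systolic-peak arrival times
#'
#' Locates the arrival time of the systolic flow peak (the minimum of
#' \code{Q(z, .)}, refined by local parabolic interpolation on the
#' cyclic time grid) at each axial position, fits an ordinary
#' least-squares line of arrival time against position, and reports the
#' pulse wave velocity as the inverse slope, converted to m/s. PWV is
#' positive for a caudally propagating peak. If the arrival times are
#' constant (zero slope) the PWV is flagged as infinite rather than
#' failing.
#'
#' When the field records its measurement levels (as fields fitted by
#' [fit_spatiotemporal()] do), arrival times are taken at those levels
#' only: between widely spaced levels the interpolated surface blends
#' time-shifted pulses, which systematically distorts peak timing,
#' whereas at the measured levels the peak is anchored by data.
#' Set \code{at = "grid"} to use every z-position of the field.
#'
#' @param field A \code{flow_field} with at least 3 z-positions.
#' @param at \code{"levels"} (default; falls back to the full grid when
#'   no measurement levels are recorded) or \code{"grid"}.
#' @return An object of class \code{pwv_estimate}: \code{PWV} (m/s,
#'   possibly \code{Inf}), \code{slope} (s/mm), \code{arrival}
#'   (data frame of \code{z}, \code{arrival_t}), and \code{degenerate}
#'   (logical flag for the constant-arrival case).
#' @export
pulse_wave_velocity <- function(field, at = c("levels", "grid")) {
  stopifnot(inherits(field, "flow_field"))
  at <- match.arg(at)
  use_z <- field$z
  Qm <- field$Q
  if (at == "levels" && !is.null(field$levels)) {
    rows <- vapply(field$levels, function(zl) which.min(abs(field$z - zl)), integer(1))
    use_z <- field$z[rows]
    Qm <- field$Q[rows, , drop = FALSE]
  }
  if (length(use_z) < 3L) stop("need >= 3 axial positions for PWV", call. = FALSE)
  nt <- length(field$t)
  dt <- field$T / nt
  arrival <- apply(Qm, 1L, function(q) {
    i <- which.min(q)
    im <- if (i == 1L) nt else i - 1L
    ip <- if (i == nt) 1L else i + 1L
    den <- q[im] - 2 * q[i] + q[ip]
    off <- if (abs(den) > .Machine$double.eps * max(abs(q), 1)) {
      0.5 * (q[im] - q[ip]) / den
    } else 0
    (field$t[i] + max(-0.5, min(0.5, off)) * dt) %% field$T
  })
  fit <- lm(arrival ~ z, data = data.frame(z = use_z, arrival = arrival))
  slope <- unname(coef(fit)[2L])  # s/mm
  degenerate <- !is.finite(slope) || abs(slope) < .Machine$double.eps * 1e3
  PWV <- if (degenerate) Inf else (1 / slope) / 1000  # mm/s -> m/s
  structure(list(PWV = PWV, slope = slope,
                 arrival = data.frame(z = use_z, arrival_t = arrival),
                 degenerate = degenerate),
            class = "pwv_estimate")
}

#' @export
print.pwv_estimate <- function(x, ...) {
  cat(sprintf("<pwv_estimate> PWV = %s m/s%s\n",
              format(x$PWV, digits = 4),
              if (x$degenerate) " (degenerate: constant arrival times)" else ""))
  invisible(x)
}

#' Summarize a flow field
#'
#' Convenience wrapper bundling [extract_peaks()], [stroke_volume()]
#' and [pulse_wave_velocity()] into one per-level summary.
#'
#' @param field A \code{flow_field}.
#' @return An object of class \code{flow_summary}: data frame
#'   \code{profile} (z, Q_sys, Q_dia, Q_a, SV), scalar \code{PWV}
#'   (m/s) and the full \code{pwv} estimate (with per-level arrival
#'   times).
#' @export
summarize_flow <- function(field) {
  pk <- extract_peaks(field)
  sv <- stroke_volume(field)
  pwv <- pulse_wave_velocity(field)
  prof <- cbind(pk, SV = sv$SV)
  structure(list(profile = prof, PWV = pwv$PWV, pwv = pwv), class = "flow_summary")
}
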