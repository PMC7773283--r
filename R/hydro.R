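## Dimensionless hydrodynamic characterization: mean velocities,
## Reynolds numbers (hydraulic-diameter, Stokes-layer and nerve-root
## based), Womersley number, Keulegan-Carpenter number and the Hall
## critical value for Honji-type oscillatory instability.

#' Spatial mean velocities from flow and SAS area
#'
#' \eqn{\bar U_{sys}(z) = Q_{sys}(z)/A_{sas}(z)} and likewise for
#' diastole, converted to cm/s (mL/s over mm^2 gives mm/s x 10; one
#' factor of 100 overall: \code{U[cm/s] = 100 Q[mL/s] / A[mm^2]}).
#'
#' @param Q_sys,Q_dia Peak systolic/diastolic flow (mL/s).
#' @param A_sas SAS cross-sectional area (mm^2), positive.
#' @return Data frame with columns \code{U_sys}, \code{U_dia} (cm/s).
#' @export
mean_velocities <- function(Q_sys, Q_dia, A_sas) {
  if (any(!is.finite(A_sas)) || any(A_sas <= 0)) {
    stop(sprintf("A_sas must be positive everywhere (first violation at index %d)",
                 which(!is.finite(A_sas) | A_sas <= 0)[1L]), call. = FALSE)
  }
  data.frame(U_sys = 100 * Q_sys / A_sas, U_dia = 100 * Q_dia / A_sas)
}

#' Dimensionless hydrodynamic numbers along the spine
#'
#' Computes, per axial position, from the peak-systolic mean velocity
#' magnitude \eqn{|\bar U_{sys}|} (internally in mm/s), hydraulic
#' diameter \eqn{D_h} (mm), kinematic viscosity \eqn{\nu} (mm^2/s),
#' angular frequency \eqn{\omega = 2\pi/T} and nerve-root diameter
#' \eqn{D_{NR}} (mm):
#' \itemize{
#'   \item Reynolds number \eqn{Re = |U| D_h / \nu};
#'   \item Stokes-layer thickness \eqn{\delta = \sqrt{2\nu/\omega}} and
#'     \eqn{Re_\delta = |U| \delta / \nu};
#'   \item nerve-root Reynolds number \eqn{Re_{NR} = |U| D_{NR} / \nu};
#'   \item Womersley number \eqn{\alpha = (D_h/2)\sqrt{\omega/\nu}};
#'   \item Keulegan-Carpenter number \eqn{K = |U| T / D_{NR}};
#'   \item \eqn{\beta = Re_{NR}/K = D_{NR}^2/(\nu T)}, which is
#'     velocity-independent, and the Hall critical value
#'     \eqn{K_{cr} = 5.778\,\beta^{-1/4}(1 + 0.205\,\beta^{-1/4})}.
#' }
#' All numbers use the velocity magnitude, so they are non-negative;
#' the instability thresholds they are compared against are defined on
#' magnitudes.
#'
#' @param U_sys Peak systolic mean velocity (cm/s; sign ignored).
#' @param D_h Hydraulic diameter (mm).
#' @param fluid A [fluid_properties()].
#' @param nr A [nerve_root_model()].
#' @return An object of class \code{hydro_summary}: data frame
#'   \code{profile} (U_sys, Re, alpha, Re_delta, Re_NR, K) plus scalars
#'   \code{delta} (mm), \code{beta}, \code{K_cr}, \code{nu}, \code{T}.
#'   With an axial nerve-root profile \code{beta}/\code{K_cr} are
#'   vectors.
#' @examples
#' dimensionless_numbers(0.92, D_h = 2.67, fluid_properties(), nerve_root_model())
#' @export
dimensionless_numbers <- function(U_sys, D_h, fluid = fluid_properties(),
                                  nr = nerve_root_model()) {
  stopifnot(inherits(fluid, "fluid_properties"), inherits(nr, "nerve_root_model"))
  d_nr <- nr$D_NR
  if (!(length(d_nr) %in% c(1L, length(U_sys)))) {
    stop("nerve-root profile length must be 1 or match the grid", call. = FALSE)
  }
  U <- abs(U_sys) * 10  # cm/s -> mm/s
  nu <- fluid$nu; Tc <- fluid$T_ref; omega <- fluid$omega
  delta <- sqrt(2 * nu / omega)
  beta <- d_nr^2 / (nu * Tc)
  K_cr <- hall_critical_k(beta)
  prof <- data.frame(
    U_sys = U_sys,
    Re = U * D_h / nu,
    alpha = (D_h / 2) * sqrt(omega / nu),
    Re_delta = U * delta / nu,
    Re_NR = U * d_nr / nu,
    K = U * Tc / d_nr)
  structure(list(profile = prof, delta = delta, beta = beta, K_cr = K_cr,
                 nu = nu, T = Tc),
            class = "hydro_summary")
}

#' Hall critical Keulegan-Carpenter number
#'
#' \eqn{K_{cr}(\beta) = 5.778\,\beta^{-1/4}(1 + 0.205\,\beta^{-1/4})}:
#' the onset threshold for Honji-type instability of oscillatory flow
#' around a cylinder, strictly decreasing in \eqn{\beta}.
#'
#' @param beta Frequency parameter \eqn{\beta = D^2/(\nu T)}, positive.
#' @return Critical Keulegan-Carpenter number(s).
#' @export
hall_critical_k <- function(beta) {
  if (any(!is.finite(beta)) || any(beta <= 0)) stop("beta must be positive", call. = FALSE)
  5.778 * beta^(-0.25) * (1 + 0.205 * beta^(-0.25))
}

#' Assess flow-regime and instability margins
#'
#' Flags three margins from a [dimensionless_numbers()] summary:
#' laminarity (max \eqn{Re} against the pipe-flow transition value
#' 2300), conditional turbulence in oscillatory flow (max
#' \eqn{Re_\delta} against 550) and Honji-type instability around
#' nerve roots (max \eqn{K} against the Hall critical \eqn{K_{cr}}).
#'
#' @param summary A \code{hydro_summary}.
#' @return An object of class \code{instability_report} with the
#'   maxima, thresholds and logical flags.
#' @export
instability_assessment <- function(summary) {
  stopifnot(inherits(summary, "hydro_summary"))
  p <- summary$profile
  K_cr_min <- min(summary$K_cr)
  rep <- list(
    max_Re = max(p$Re), Re_threshold = 2300,
    laminar = max(p$Re) < 2300,
    max_Re_delta = max(p$Re_delta), Re_delta_threshold = 550,
    conditionally_turbulent = max(p$Re_delta) >= 550,
    max_K = max(p$K), K_cr = K_cr_min,
    honji_unstable = max(p$K) >= K_cr_min)
  structure(rep, class = "instability_report")
}

#' @export
print.instability_report <- function(x, ...) {
  cat("<instability_report>\n")
  cat(sprintf("  max Re       = %8.2f vs %6g : %s\n", x$max_Re, x$Re_threshold,
              if (x$laminar) "laminar" else "transitional/turbulent"))
  cat(sprintf("  max Re_delta = %8.2f vs %6g : %s\n", x$max_Re_delta,
              x$Re_delta_threshold,
              if (x$conditionally_turbulent) "conditional turbulence possible"
              else "no conditional turbulence"))
  cat(sprintf("  max K        = %8.2f vs %6.2f : %s\n", x$max_K, x$K_cr,
              if (x$honji_unstable) "Honji-type instability possible"
              else "below Honji instability threshold"))
  invisible(x)
}
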