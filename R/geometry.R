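## SAS geometry: catheter footprint mapping, derived SAS profiles
## (area, wetted perimeter, hydraulic diameter), scalar volume/surface
## summaries, and axial-length normalization across subjects.

#' Map a catheter onto an axial grid
#'
#' Computes the occluded cross-sectional area \eqn{A_{cath}(z) =
#' (\pi/4)\,OD(z)^2} and the added wetted perimeter \eqn{P_{cath}(z) =
#' \pi\,OD(z)} of an indwelling catheter at each grid position. The
#' outer diameter at a position is found by walking the segment table
#' caudally from the tip; both quantities are zero outside
#' \code{[tip_z, entry_z]}, and any catheter length beyond the entry
#' site lies outside the SAS and contributes nothing.
#'
#' @param cath A [catheter_spec()].
#' @param grid An [axial_grid()].
#' @return An object of class \code{catheter_footprint} with elements
#'   \code{A_cath} (mm^2), \code{P_cath} (mm) and \code{OD} (mm), each
#'   one value per grid point.
#' @examples
#' g <- axial_grid(seq(0, 310, by = 1))
#' fp <- catheter_footprint(catheter_spec(tip_z = 60, entry_z = 310), g)
#' range(fp$A_cath[fp$A_cath > 0])
#' @export
catheter_footprint <- function(cath, grid) {
  stopifnot(inherits(cath, "catheter_spec"), inherits(grid, "axial_grid"))
  z <- grid$z
  span <- cath$entry_z - cath$tip_z
  total <- sum(cath$segments$length)
  if (span > 0 && total < span - 1e-9) {
    stop(sprintf("catheter segments (%g mm) cannot span tip to entry (%g mm)",
                 total, span), call. = FALSE)
  }
  OD <- numeric(length(z))
  if (span > 0) {
    inside <- z >= cath$tip_z & z <= cath$entry_z
    d <- z[inside] - cath$tip_z                  # distance from the tip
    ends <- cumsum(cath$segments$length)
    idx <- findInterval(d, ends, left.open = FALSE) + 1L  # d == boundary opens next segment
    idx[idx > nrow(cath$segments)] <- nrow(cath$segments)
    OD[inside] <- cath$segments$od[idx]
  }
  structure(list(A_cath = pi / 4 * OD^2, P_cath = pi * OD, OD = OD, grid = grid),
            class = "catheter_footprint")
}

#' Derive SAS area, wetted perimeter and hydraulic diameter
#'
#' Fills in the derived SAS quantities of an axial profile:
#' \deqn{A_{sas}(z) = A_d(z) - A_c(z) - A_{cath}(z),}
#' \deqn{P_{sas}(z) = P_c(z) + P_d(z) + P_{cath}(z),}
#' \deqn{D_h(z) = 4 A_{sas}(z) / P_{sas}(z).}
#' The wetted perimeter is the cord plus dura perimeter, plus the
#' catheter's outer perimeter where one is present; the catheter lumen
#' is treated as occluded (its cross-section is subtracted wholesale).
#' Without a footprint the catheter terms are zero, so re-deriving a
#' catheter-adjusted profile with \code{footprint = NULL} restores the
#' unadjusted quantities exactly.
#'
#' @param profile An [axial_profile()].
#' @param footprint A [catheter_footprint()] on the same grid, or
#'   \code{NULL} for a catheter-free SAS.
#' @return The profile with \code{A_sas}, \code{P_sas}, \code{D_h}
#'   filled in.
#' @export
derive_sas_profile <- function(profile, footprint = NULL) {
  stopifnot(inherits(profile, "axial_profile"))
  n <- length(profile$grid$z)
  A_cath <- P_cath <- numeric(n)
  if (!is.null(footprint)) {
    stopifnot(inherits(footprint, "catheter_footprint"))
    if (length(footprint$A_cath) != n) {
      stop("footprint grid does not match the profile grid", call. = FALSE)
    }
    A_cath <- footprint$A_cath
    P_cath <- footprint$P_cath
  }
  A_sas <- profile$A_d - profile$A_c - A_cath
  if (any(A_sas <= 0)) {
    bad <- profile$grid$z[which(A_sas <= 0)[1L]]
    stop(sprintf("catheter occludes the SAS at z = %g mm (A_sas <= 0)", bad),
         call. = FALSE)
  }
  P_sas <- profile$P_c + profile$P_d + P_cath
  if (any(P_sas <= 0)) stop("wetted perimeter must be positive", call. = FALSE)
  profile$A_sas <- A_sas
  profile$P_sas <- P_sas
  profile$D_h <- 4 * A_sas / P_sas
  profile
}

#' Integrate scalar geometry summaries
#'
#' Trapezoidal axial integration of the area and perimeter profiles
#' into volumes (mL) and surface areas (cm^2):
#' \eqn{V_x = \int A_x\,dz}, \eqn{SA_x = \int P_x\,dz}. The composite
#' identities \eqn{SA_{sas} = SA_c + SA_d} (cord plus dura; nerve roots
#' are excluded) and \eqn{V_{sas} = V_d - V_c} hold by construction.
#'
#' @param profile An [axial_profile()].
#' @return An object of class \code{geometry_summary}: \code{SA_c},
#'   \code{SA_d}, \code{SA_sas} (cm^2), \code{V_c}, \code{V_d},
#'   \code{V_sas} (mL), \code{L_sas} (mm).
#' @export
summarize_geometry <- function(profile) {
  stopifnot(inherits(profile, "axial_profile"))
  z <- profile$grid$z
  if (length(z) < 2L) stop("need at least 2 grid points to integrate", call. = FALSE)
  V_c <- pracma::trapz(z, profile$A_c) / 1000   # mm^3 -> mL
  V_d <- pracma::trapz(z, profile$A_d) / 1000
  SA_c <- pracma::trapz(z, profile$P_c) / 100   # mm^2 -> cm^2
  SA_d <- pracma::trapz(z, profile$P_d) / 100
  structure(list(SA_c = SA_c, SA_d = SA_d, SA_sas = SA_c + SA_d,
                 V_c = V_c, V_d = V_d, V_sas = V_d - V_c,
                 L_sas = profile$grid$L_sas),
            class = "geometry_summary")
}

#' @export
print.geometry_summary <- function(x, ...) {
  cat(sprintf("<geometry_summary> V_sas = %.3f mL, SA_sas = %.2f cm^2, L_sas = %g mm\n",
              x$V_sas, x$SA_sas, x$L_sas))
  invisible(x)
}

#' Normalize axial profiles to a common SAS length
#'
#' Rescales each subject's axial coordinate by \code{L_mean / L_sas}
#' and linearly resamples every defined field onto a common uniform
#' grid of length \code{L_mean}, so axial distributions can be compared
#' and averaged across subjects with different spine lengths.
#'
#' @param profiles List of [axial_profile()] objects.
#' @param L_mean Target common SAS length (mm); typically the cohort
#'   mean \code{L_sas}.
#' @param dz Grid spacing of the common grid (mm); default 1.
#' @return List of profiles on the shared grid.
#' @export
normalize_axial <- function(profiles, L_mean, dz = 1) {
  if (!length(profiles)) stop("no profiles to normalize", call. = FALSE)
  if (!is.finite(L_mean) || L_mean <= 0) stop("L_mean must be positive", call. = FALSE)
  z_common <- seq(0, L_mean, by = dz)
  if (abs(z_common[length(z_common)] - L_mean) > 1e-9) z_common <- c(z_common, L_mean)
  grid <- axial_grid(seq(0, L_mean, length.out = length(z_common)))
  lapply(profiles, function(p) {
    stopifnot(inherits(p, "axial_profile"))
    zs <- p$grid$z * (L_mean / p$grid$L_sas)
    res <- function(v) if (is.null(v)) NULL else approx(zs, v, xout = grid$z, rule = 2)$y
    out <- axial_profile(grid, A_c = res(p$A_c), A_d = res(p$A_d),
                         P_c = res(p$P_c), P_d = res(p$P_d))
    out$A_sas <- res(p$A_sas); out$P_sas <- res(p$P_sas); out$D_h <- res(p$D_h)
    out
  })
}
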